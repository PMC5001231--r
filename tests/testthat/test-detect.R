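# Builds a two-condition synthetic dataset: a noise genome in both
# conditions, with selected gene blocks overwritten by noisy concordant
# modules in condition A only, or in both conditions.
make_screen_fixture <- function(n_genes = 300, N = 40, block = 15,
                                a_only = 3, both = 3, sigma = 0.05) {
  expr_a <- noise_genome(n_genes, N)
  expr_b <- noise_genome(n_genes, N)
  mods <- list()
  at <- 1
  for (i in seq_len(a_only)) {
    idx <- at:(at + block - 1)
    expr_a[idx, ] <- add_gaussian_noise(make_correlated_matrix(block, N), sigma)
    mods[[paste0("a_only_", i)]] <- rownames(expr_a)[idx]
    at <- at + block
  }
  for (i in seq_len(both)) {
    idx <- at:(at + block - 1)
    expr_a[idx, ] <- add_gaussian_noise(make_correlated_matrix(block, N), sigma)
    expr_b[idx, ] <- add_gaussian_noise(make_correlated_matrix(block, N), sigma)
    mods[[paste0("both_", i)]] <- rownames(expr_a)[idx]
    at <- at + block
  }
  list(expr_a = expr_a, expr_b = expr_b, modules = mods)
}

test_that("module resolution drops missing genes and enforces the minimum size", {
  expr <- noise_genome(20, 10)
  expect_identical(resolve_module(c("g1", "g5"), expr), c("g1", "g5"))
  expect_warning(found <- resolve_module(c("g1", "g2", "nope"), expr),
                 "1 of 3")
  expect_identical(found, c("g1", "g2"))
  expect_error(suppressWarnings(resolve_module(c("g1", "zz"), expr)),
               "fewer than 2")
  expect_error(resolve_module(c("g1", "g1", "g2"), expr), "duplicate")
})

test_that("scoring a planted module yields a large z and is seed-deterministic", {
  set.seed(51)
  expr <- noise_genome(400, 40)
  expr[1:50, ] <- add_gaussian_noise(make_correlated_matrix(50, 40), 0.05)
  planted <- paste0("g", 1:50)
  s1 <- score_module_in_condition(planted, expr, M = 200, seed = 9)
  expect_gt(s1$z, 10)
  s2 <- score_module_in_condition(planted, expr, M = 200, seed = 9)
  expect_identical(s1$z, s2$z)
  # a random module from the same background stays near the null
  s3 <- score_module_in_condition(paste0("g", 301:350), expr, M = 200, seed = 9)
  expect_lt(abs(s3$z), 4)
})

test_that("screen separates planted condition-specific modules from shared ones", {
  set.seed(52)
  fx <- make_screen_fixture()
  res <- screen_modules(fx$modules, fx$expr_a, fx$expr_b,
                        alpha = 0.05, M = 200, seed = 52)
  expect_equal(res$verdict[grepl("^a_only", res$module)],
               rep("specific_to_a", 3))
  expect_equal(res$verdict[grepl("^both", res$module)],
               rep("concordant_both", 3))
  expect_equal(attr(res, "tau"), bonferroni_z_threshold(0.05, 6))
  # verdicts partition the module list
  expect_equal(nrow(res), length(fx$modules))
  expect_true(all(res$verdict %in% c("specific_to_a", "specific_to_b",
                                     "concordant_both", "concordant_neither")))
})

test_that("identical conditions yield no condition-specific calls", {
  set.seed(53)
  expr <- noise_genome(150, 20)
  expr[1:10, ] <- add_gaussian_noise(make_correlated_matrix(10, 20), 0.1)
  mods <- list(m1 = paste0("g", 1:10), m2 = paste0("g", 51:60))
  res <- screen_modules(mods, expr, expr, M = 100, seed = 3)
  expect_identical(res$z_a, res$z_b)  # same matrix, same per-size sub-seed
  expect_false(any(grepl("^specific", res$verdict)))
})

test_that("swapping the condition matrices swaps the specific verdicts exactly", {
  set.seed(54)
  fx <- make_screen_fixture(a_only = 2, both = 1)
  fwd <- screen_modules(fx$modules, fx$expr_a, fx$expr_b, M = 100, seed = 8)
  rev <- screen_modules(fx$modules, fx$expr_b, fx$expr_a, M = 100, seed = 8)
  expect_identical(fwd$z_a, rev$z_b)
  expect_identical(fwd$z_b, rev$z_a)
  map <- c(specific_to_a = "specific_to_b", specific_to_b = "specific_to_a",
           concordant_both = "concordant_both",
           concordant_neither = "concordant_neither")
  expect_identical(unname(map[fwd$verdict]), rev$verdict)
})

test_that("raising alpha never decreases the number of significant calls", {
  set.seed(55)
  fx <- make_screen_fixture(a_only = 2, both = 2, sigma = 0.4)
  counts <- sapply(c(0.001, 0.01, 0.05, 0.2), function(a) {
    r <- screen_modules(fx$modules, fx$expr_a, fx$expr_b, alpha = a,
                        M = 100, seed = 4)
    sum(r$z_a >= attr(r, "tau"))
  })
  expect_true(all(diff(counts) >= 0))
})

test_that("pure-noise conditions produce essentially no specific calls", {
  set.seed(56)
  expr_a <- noise_genome(300, 25)
  expr_b <- noise_genome(300, 25)
  mods <- lapply(1:10, function(i) paste0("g", ((i - 1) * 20 + 1):(i * 20)))
  names(mods) <- paste0("m", 1:10)
  res <- screen_modules(mods, expr_a, expr_b, alpha = 0.05, M = 100, seed = 6)
  expect_lte(sum(grepl("^specific", res$verdict)), 1)
})

test_that("unresolvable modules are flagged, not fatal", {
  set.seed(57)
  expr <- noise_genome(50, 12)
  mods <- list(ok = paste0("g", 1:5), ghost = c("x1", "x2", "x3"))
  expect_warning(res <- screen_modules(mods, expr, expr, M = 50, seed = 2),
                 "ghost")
  expect_equal(res$verdict[res$module == "ghost"], "concordant_neither")
  expect_true(is.na(res$z_a[res$module == "ghost"]))
})

test_that("a two-level sample map splits one matrix into two conditions", {
  expr <- noise_genome(20, 10)
  groups <- setNames(rep(c("tumor", "control"), each = 5), colnames(expr))
  pair <- split_by_condition(expr, groups)
  expect_named(pair, c("control", "tumor"))
  expect_equal(ncol(pair$tumor), 5)
  expect_identical(pair$tumor, expr[, 1:5])
  expect_error(split_by_condition(expr, rep("x", 10)), "two levels")
  expect_error(split_by_condition(expr, groups[1:3]), "cover all samples")
})
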