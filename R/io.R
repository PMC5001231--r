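#' Read a delimited expression table
#'
#' Expects a rectangular table with a header row of sample identifiers and
#' the first column holding gene identifiers (the common genes-in-rows
#' layout; use `orientation = "samples_in_rows"` to transpose after
#' reading). Non-numeric cells and duplicate identifiers are reported with
#' their location.
#'
#' @param path File path.
#' @param sep Field delimiter (default tab; use `","` for CSV).
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`.
#' @param log2p1 Apply `log2(x + 1)` after reading (default `FALSE`; the
#'   concordance statistics are defined on the matrix as given).
#' @param duplicates `"error"` (default) or `"first"` to keep the first
#'   occurrence of a duplicated gene identifier.
#' @return Numeric matrix with gene rownames and sample colnames, validated
#'   by [validate_expression_matrix()].
#' @export
read_expression_table <- function(path, sep = "\t",
                                  orientation = c("genes_in_rows", "samples_in_rows"),
                                  log2p1 = FALSE,
                                  duplicates = c("error", "first")) {
  orientation <- match.arg(orientation)
  duplicates <- match.arg(duplicates)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character", quote = "\"")
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("empty or single-column table: ", path)
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    if (duplicates == "error")
      stop("duplicate identifiers in first column of ", path, ": ",
           paste(utils::head(dups, 5), collapse = ", "),
           if (length(dups) > 5) ", ..." else "")
    keep <- !duplicated(ids)
    warning("keeping first occurrence of ", length(dups),
            " duplicated identifier(s)")
    df <- df[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)[1, , drop = TRUE]
    stop(sprintf("non-numeric cell at row '%s', column '%s': \"%s\"",
                 ids[bad[1]], colnames(vals)[bad[2]], vals[bad[1], bad[2]]))
  }
  dimnames(num) <- list(ids, colnames(vals))
  if (orientation == "samples_in_rows") num <- t(num)
  if (log2p1) {
    if (any(num < 0)) stop("log2(x + 1) requested but matrix has negative values")
    num <- log2(num + 1)
  }
  validate_expression_matrix(num, min_samples = 1L)
  num
}

#' Write an expression matrix as a delimited table
#'
#' Inverse of [read_expression_table()]: gene identifiers in the first
#' column (header `gene_id`), sample identifiers as the header row.
#'
#' @param x Numeric matrix with dimnames.
#' @param path Output path.
#' @param sep Field delimiter (default tab).
#' @export
write_expression_table <- function(x, path, sep = "\t") {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene modules from a GMT or plain-list file
#'
#' GMT lines are `name TAB description TAB gene1 TAB gene2 ...`; a plain
#' list is one gene per line and yields a single module named after the
#' file. Duplicate genes within a module are dropped with a warning. An
#' empty file yields an empty list.
#'
#' @param path File path.
#' @param format `"auto"` (default: GMT when any line has >= 3 tab-separated
#'   fields), `"gmt"`, or `"list"`.
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path, format = c("auto", "gmt", "list")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(stats::setNames(list(), character(0)))
  if (format == "auto")
    format <- if (any(lengths(strsplit(lines, "\t", fixed = TRUE)) >= 3L))
      "gmt" else "list"
  if (format == "list") {
    genes <- trimws(lines)
    if (anyDuplicated(genes)) {
      warning("dropping ", sum(duplicated(genes)), " duplicate gene(s)")
      genes <- unique(genes)
    }
    return(stats::setNames(list(genes),
                           sub("\\.[^.]*$", "", basename(path))))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L)
    stop("malformed GMT line ", short[1], " in ", path,
         ": expected name, description and at least one gene")
  mods <- lapply(seq_along(fields), function(i) {
    genes <- fields[[i]][-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("module '", fields[[i]][1], "' (line ", i, "): dropping ",
              sum(duplicated(genes)), " duplicate gene(s)")
      genes <- unique(genes)
    }
    genes
  })
  names(mods) <- vapply(fields, `[`, character(1), 1L)
  mods
}

#' Write a results table with a reproducibility header
#'
#' Emits records with deterministic column order and `#`-prefixed metadata
#' lines (package version, seed, any extra config) so runs can be diffed.
#' Numeric columns are formatted to 6 significant digits in TSV; JSON
#' carries full precision of the same rounded values.
#'
#' @param records Data frame of results.
#' @param path Output path.
#' @param format `"tsv"` (default) or `"json"`.
#' @param seed Seed used for the run, recorded in the header (optional).
#' @param config Named list of extra metadata for the header (optional).
#' @export
write_report <- function(records, path, format = c("tsv", "json"),
                         seed = NULL, config = NULL) {
  format <- match.arg(format)
  stopifnot(is.data.frame(records))
  num <- vapply(records, is.numeric, logical(1))
  records[num] <- lapply(records[num], signif, digits = 6L)
  meta <- c(sprintf("version=%s", as.character(utils::packageVersion("ccindex"))),
            if (!is.null(seed)) sprintf("seed=%s", seed),
            if (!is.null(config))
              sprintf("%s=%s", names(config),
                      vapply(config, base::format, character(1))))
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "tsv") {
    writeLines(paste0("# ", meta), con)
    utils::write.table(records, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(metadata = as.list(stats::setNames(meta, NULL)), records = records),
      con, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}
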