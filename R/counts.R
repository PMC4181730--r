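#' Construct a count matrix
#'
#' Container for a gene-by-library table of non-negative integer read counts,
#' the basic input of all normalization and testing functions. Library sizes
#' default to column sums but may be supplied externally (e.g. total mapped
#' reads, which can exceed the sum over tabulated genes).
#'
#' @param counts Numeric matrix of non-negative integers, genes in rows,
#'   libraries in columns. Row names are gene identifiers, column names
#'   library names; both are generated if missing.
#' @param gene_ids Optional character vector of unique gene identifiers
#'   overriding `rownames(counts)`.
#' @param lib_names Optional character vector of unique library names
#'   overriding `colnames(counts)`.
#' @param lib_sizes Optional positive totals per library; defaults to column
#'   sums of `counts`.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix), `lib_sizes` (named numeric).
#' @examples
#' cm <- count_matrix(matrix(c(10, 30, 20, 40), 2, 2))
#' lib_sizes(cm)
#' @export
count_matrix <- function(counts, gene_ids = NULL, lib_names = NULL,
                         lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts))
    stop("counts must be numeric")
  if (nrow(counts) < 1L)
    stop("count matrix needs at least one gene")
  if (!is.null(gene_ids)) rownames(counts) <- gene_ids
  if (!is.null(lib_names)) colnames(counts) <- lib_names
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("lib", seq_len(ncol(counts)))
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("negative or non-integer count at gene '%s', library '%s'",
                 rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]]))
  dup <- anyDuplicated(rownames(counts))
  if (dup)
    stop(sprintf("duplicate gene id '%s'", rownames(counts)[dup]))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate library names")
  storage.mode(counts) <- "double"
  if (is.null(lib_sizes)) {
    lib_sizes <- colSums(counts)
  } else {
    lib_sizes <- as.numeric(lib_sizes)
    if (length(lib_sizes) != ncol(counts))
      stop("lib_sizes must have one entry per library")
    if (any(lib_sizes <= 0))
      stop("lib_sizes must be positive")
  }
  names(lib_sizes) <- colnames(counts)
  structure(list(counts = counts, lib_sizes = lib_sizes),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d libraries\n",
              nrow(x$counts), ncol(x$counts)))
  cat("library sizes:\n")
  print(x$lib_sizes)
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Library totals of a count matrix
#' @param x A `count_matrix`.
#' @return Named numeric vector of library sizes.
#' @export
lib_sizes <- function(x) x$lib_sizes

#' Gene identifiers of a count matrix
#' @param x A `count_matrix`.
#' @return Character vector of gene ids in table order.
#' @export
gene_ids <- function(x) rownames(x$counts)

as_count_matrix <- function(x) {
  if (inherits(x, "count_matrix")) x else count_matrix(x)
}

#' Read a count table from tab-separated text
#'
#' Expects a header row of library names and a first column of gene
#' identifiers, followed by one integer count column per library. Gene order
#' is preserved; library sizes are set to column sums unless `lib_sizes` is
#' given.
#'
#' @param path Path to the table.
#' @param sep Field separator, default tab.
#' @param lib_sizes Optional external library totals (e.g. total mapped
#'   reads) overriding column sums.
#' @return A [count_matrix].
#' @export
read_counts <- function(path, sep = "\t", lib_sizes = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, comment.char = "#",
                           colClasses = "character", quote = "")
  if (ncol(tab) < 3L)
    stop("count table needs at least 2 library columns")
  ids <- tab[[1L]]
  dup <- anyDuplicated(ids)
  if (dup) stop(sprintf("duplicate gene id '%s'", ids[dup]))
  m <- matrix(NA_real_, nrow(tab), ncol(tab) - 1L,
              dimnames = list(ids, colnames(tab)[-1L]))
  for (j in 2L:ncol(tab)) {
    v <- suppressWarnings(as.numeric(tab[[j]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad) > 0L)
      stop(sprintf("invalid count '%s' at gene '%s', column '%s'",
                   tab[[j]][bad[1L]], ids[bad[1L]], colnames(tab)[j]))
    m[, j - 1L] <- v
  }
  count_matrix(m, lib_sizes = lib_sizes)
}

#' Write a count matrix as tab-separated text
#'
#' Inverse of [read_counts()]: `read_counts(write_counts(x, f))` recovers
#' the counts, gene ids and library names.
#'
#' @param x A [count_matrix].
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, sep = "\t") {
  x <- as_count_matrix(x)
  df <- data.frame(gene_id = gene_ids(x), x$counts, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Two-condition design for a set of libraries
#'
#' Maps each library to one of exactly two condition labels and records the
#' reference library used for normalization factors.
#'
#' @param condition Named character vector: names are library names, values
#'   condition labels (exactly two distinct labels).
#' @param reference Reference library name; defaults to the first library.
#' @return An object of class `group_design`.
#' @examples
#' group_design(c(a1 = "A", a2 = "A", b1 = "B"))
#' @export
group_design <- function(condition, reference = NULL) {
  condition <- vapply(condition, as.character, character(1L))
  if (is.null(names(condition)) || any(!nzchar(names(condition))))
    stop("condition must be a named vector (library -> condition label)")
  if (anyDuplicated(names(condition)))
    stop("each library may appear only once in the design")
  lev <- unique(condition)
  if (length(lev) != 2L)
    stop("design must have exactly two distinct condition labels")
  if (is.null(reference)) reference <- names(condition)[1L]
  if (!reference %in% names(condition))
    stop(sprintf("reference library '%s' not in design", reference))
  structure(list(condition = condition, levels = lev, reference = reference),
            class = "group_design")
}

#' @export
print.group_design <- function(x, ...) {
  cat("group_design:", length(x$condition), "libraries,",
      "conditions", paste(x$levels, collapse = " vs "),
      "| reference:", x$reference, "\n")
  invisible(x)
}

#' Read a library-to-condition design table
#'
#' Two tab-separated columns, `library` and `condition`, with a header row.
#'
#' @param path Path to the design file.
#' @param reference Optional reference library name.
#' @param sep Field separator.
#' @return A [group_design].
#' @export
read_design <- function(path, reference = NULL, sep = "\t") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) stop("design file needs columns: library, condition")
  cond <- tab[[2L]]
  names(cond) <- tab[[1L]]
  group_design(cond, reference = reference)
}

check_design <- function(counts, design) {
  libs <- colnames(counts$counts)
  if (!setequal(libs, names(design$condition)) ||
      length(libs) != length(design$condition))
    stop("design libraries do not match count matrix libraries")
  invisible(TRUE)
}

#' Write per-gene test results with normalization metadata
#'
#' Produces a tab-separated table, one row per tested gene, with the observed
#' counts, M/A values where defined, p- and Q-values and the DE call. Header
#' comment lines record the normalization method, per-library factors,
#' thresholds and seed so a run is reproducible from its output alone.
#'
#' @param result A `de_test` object (see [de_test()]).
#' @param factors A `norm_factors` object from the same count matrix.
#' @param path Output path.
#' @param seed Optional seed to record in the header.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, factors, path, seed = NULL) {
  stopifnot(inherits(result, "de_test"), inherits(factors, "norm_factors"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("# immnorm results"),
    sprintf("# test=%s q_threshold=%.17g", result$method, result$q_threshold),
    sprintf("# norm_factor lib=%s method=%s value=%.17g",
            names(factors$factors), factors$method, factors$factors),
    if (!is.null(seed)) sprintf("# seed=%d", as.integer(seed))
  ), con)
  if (identical(factors$method, "imm") && !is.null(factors$trace)) {
    for (lib in names(factors$trace)) {
      tr <- factors$trace[[lib]]
      writeLines(sprintf("# imm_trace lib=%s iter=%d factor=%.17g n_excluded=%d",
                         lib, seq_len(nrow(tr)), tr$factor, tr$n_excluded), con)
    }
  }
  tab <- result$table
  num <- vapply(tab, is.numeric, logical(1L))
  out <- tab
  out[num] <- lapply(tab[num], function(v) sprintf("%.17g", v))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a results table written by [write_results()]
#'
#' @param path Path to a results file.
#' @return A data frame with one row per gene; numeric columns restored at
#'   full printed precision.
#' @export
read_results <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE)
}
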