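#' Per-gene M and A values for a pair of libraries
#'
#' For libraries k (target) and r (reference), computes the log2 fold change
#' of proportions M = log2((Y_gk/T_k) / (Y_gr/T_r)) and the average log2
#' abundance A = 0.5 * log2((Y_gk/T_k) * (Y_gr/T_r)). Genes with a zero count
#' in either library are flagged invalid and carry NA, since their
#' log fold change cannot be calculated.
#'
#' @param counts A [count_matrix] (or plain matrix).
#' @param k,r Target and reference library, by index or name; must differ.
#' @param totals Optional pair of positive totals (T_k, T_r) used as
#'   proportion denominators; defaults to the library sizes.
#' @return Object of class `ma_profile`: list with `gene_id`, `M`, `A`,
#'   `valid`, `pair` (names of k and r), `totals_used`.
#' @examples
#' cm <- count_matrix(cbind(a = c(40, 10), b = c(10, 10)),
#'                    lib_sizes = c(1000, 1000))
#' compute_ma(cm, "a", "b")$M
#' @export
compute_ma <- function(counts, k, r, totals = NULL) {
  counts <- as_count_matrix(counts)
  libs <- colnames(counts$counts)
  k <- if (is.character(k)) match(k, libs) else as.integer(k)
  r <- if (is.character(r)) match(r, libs) else as.integer(r)
  if (is.na(k) || is.na(r) || k < 1L || r < 1L || k > length(libs) ||
      r > length(libs))
    stop("library not found")
  if (k == r) stop("target and reference library must differ")
  if (is.null(totals)) totals <- counts$lib_sizes[c(k, r)]
  totals <- as.numeric(totals)
  if (length(totals) != 2L || any(!is.finite(totals)) || any(totals <= 0))
    stop("totals must be two positive numbers")
  yk <- counts$counts[, k]
  yr <- counts$counts[, r]
  valid <- unname(yk > 0 & yr > 0)
  M <- A <- rep(NA_real_, length(yk))
  pk <- yk[valid] / totals[1L]
  pr <- yr[valid] / totals[2L]
  M[valid] <- log2(pk / pr)
  A[valid] <- 0.5 * log2(pk * pr)
  structure(list(gene_id = gene_ids(counts), M = M, A = A, valid = valid,
                 pair = libs[c(k, r)], totals_used = totals),
            class = "ma_profile")
}

#' @export
print.ma_profile <- function(x, ...) {
  cat(sprintf("ma_profile: %s vs %s (%d genes, %d valid)\n",
              x$pair[1L], x$pair[2L], length(x$M), sum(x$valid)))
  invisible(x)
}
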