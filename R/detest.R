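# Per-gene tests for two-condition count comparison, Benjamini-Hochberg
# adjustment and DE calling. All tests condition on the gene's total count,
# with "effective" library totals (totals scaled by the normalization
# factor) defining the null proportion.

# Two-sided exact binomial p for one gene: sum of probabilities of all
# outcomes no more likely than the observed one, with a small relative
# tolerance for ties. Exact enumeration unless n exceeds max_exact_n, in
# which case a continuity-corrected normal approximation is used.
binom_two_sided <- function(y, n, p0, tie_tol = 1e-7, max_exact_n = Inf) {
  if (n == 0L) return(1)
  if (n > max_exact_n) {
    mu <- n * p0
    sd <- sqrt(n * p0 * (1 - p0))
    z <- (abs(y - mu) - 0.5) / sd
    return(min(1, 2 * stats::pnorm(z, lower.tail = FALSE)))
  }
  pr <- stats::dbinom(0:n, n, p0)
  pobs <- pr[y + 1L]
  min(1, sum(pr[pr <= pobs * (1 + tie_tol)]))
}

#' Two-library exact test with effective totals
#'
#' Exact test of equal expression between two single libraries: conditional
#' on n = y_k + y_r, y_k is Binomial(n, p0) under the null with
#' p0 = T_k_eff / (T_k_eff + T_r_eff), and the two-sided p-value sums the
#' probabilities of all outcomes whose probability does not exceed that of
#' the observed y_k (relative tie tolerance `tie_tol`). With effective
#' totals from [effective_totals()] this is the amended Fisher/sage exact
#' test used inside the IMM iteration.
#'
#' @param y_k,y_r Non-negative counts (vectorized over genes).
#' @param T_k_eff,T_r_eff Positive effective totals for the two libraries.
#' @param tie_tol Relative tolerance treating probabilities as tied with the
#'   observed one (default 1e-7).
#' @param max_exact_n Totals above this switch to a continuity-corrected
#'   normal approximation; default `Inf` (always exact).
#' @return Vector of p-values in [0, 1]; genes with y_k = y_r = 0 get p = 1.
#' @examples
#' two_library_exact_p(0, 10, 1000, 1000)  # 2/1024
#' @export
two_library_exact_p <- function(y_k, y_r, T_k_eff, T_r_eff,
                                tie_tol = 1e-7, max_exact_n = Inf) {
  if (any(y_k < 0) || any(y_r < 0)) stop("counts must be non-negative")
  if (T_k_eff <= 0 || T_r_eff <= 0) stop("effective totals must be positive")
  p0 <- T_k_eff / (T_k_eff + T_r_eff)
  n <- y_k + y_r
  vapply(seq_along(n), function(i)
    binom_two_sided(y_k[i], n[i], p0, tie_tol, max_exact_n), numeric(1L))
}

#' Group-summed exact Poisson test
#'
#' For a gene with counts across replicated libraries in two conditions, the
#' condition sums s1, s2 are Poisson, so conditional on s1 + s2 the first sum
#' is binomial with success probability equal to condition 1's share of the
#' summed effective totals; the two-sided p-value is computed as in
#' [two_library_exact_p()]. With one library per condition the two tests
#' coincide.
#'
#' @param counts_g Per-library counts for one gene (or a gene-by-library
#'   matrix), with library names matching the design.
#' @param design A [group_design].
#' @param eff_totals Named per-library positive effective totals.
#' @param ... Passed to the binomial summation (`tie_tol`, `max_exact_n`).
#' @return P-value (or vector of p-values for a matrix input).
#' @export
poisson_exact_group_p <- function(counts_g, design, eff_totals, ...) {
  if (is.null(dim(counts_g)))
    counts_g <- matrix(counts_g, nrow = 1L,
                       dimnames = list(NULL, names(counts_g)))
  libs <- colnames(counts_g)
  if (is.null(libs)) stop("counts must carry library names")
  if (!all(libs %in% names(design$condition)))
    stop("design does not cover all libraries")
  g1 <- libs[design$condition[libs] == design$levels[1L]]
  g2 <- libs[design$condition[libs] == design$levels[2L]]
  s1 <- rowSums(counts_g[, g1, drop = FALSE])
  s2 <- rowSums(counts_g[, g2, drop = FALSE])
  t1 <- sum(eff_totals[g1])
  t2 <- sum(eff_totals[g2])
  two_library_exact_p(s1, s2, t1, t2, ...)
}

#' Poisson likelihood-ratio test
#'
#' Poisson model with the log effective total as offset: under the null the
#' rate is common to both conditions, under the alternative each condition
#' has its own rate, both in closed form (group count sum over group
#' effective-total sum). Twice the log-likelihood ratio is referred to a
#' chi-squared distribution with 1 degree of freedom; 0*log(0) is taken as 0
#' and an all-zero gene gets p = 1.
#'
#' @inheritParams poisson_exact_group_p
#' @return P-value (or vector for a matrix input).
#' @export
poisson_lr_p <- function(counts_g, design, eff_totals) {
  if (is.null(dim(counts_g)))
    counts_g <- matrix(counts_g, nrow = 1L,
                       dimnames = list(NULL, names(counts_g)))
  libs <- colnames(counts_g)
  if (is.null(libs)) stop("counts must carry library names")
  if (any(eff_totals[libs] <= 0)) stop("effective totals must be positive")
  g1 <- libs[design$condition[libs] == design$levels[1L]]
  g2 <- libs[design$condition[libs] == design$levels[2L]]
  s1 <- rowSums(counts_g[, g1, drop = FALSE])
  s2 <- rowSums(counts_g[, g2, drop = FALSE])
  t1 <- sum(eff_totals[g1])
  t2 <- sum(eff_totals[g2])
  s <- s1 + s2
  tt <- t1 + t2
  xlogx <- function(x, rate_ratio) ifelse(x == 0, 0, x * log(rate_ratio))
  lr <- 2 * (xlogx(s1, (s1 / t1) / (s / tt)) +
             xlogx(s2, (s2 / t2) / (s / tt)))
  lr[s == 0] <- 0
  stats::pchisq(lr, df = 1L, lower.tail = FALSE)
}

# Dispatch used by imm_norm() and de_test(): p-values for every row of Y.
gene_pvalues <- function(Y, design, eff_totals, test, ...) {
  switch(test,
    fisher = {
      libs <- colnames(Y)
      l1 <- libs[design$condition[libs] == design$levels[1L]]
      l2 <- libs[design$condition[libs] == design$levels[2L]]
      two_library_exact_p(Y[, l1], Y[, l2], eff_totals[[l1]],
                          eff_totals[[l2]], ...)
    },
    poisson_exact = poisson_exact_group_p(Y, design, eff_totals, ...),
    poisson_lr = poisson_lr_p(Y, design, eff_totals),
    stop(sprintf("unknown test '%s'", test)))
}

#' Benjamini-Hochberg Q-values
#'
#' Raw adjusted value Q = p * count / rank, with average ranks for tied
#' p-values, followed by the step-up enforcement (cumulative minimum from
#' the largest p downward) and clipping at 1. `stepup = FALSE` returns the
#' raw rank formula alone, in which case Q is not guaranteed monotone and
#' threshold calls may be non-nested.
#'
#' @param p Vector of p-values in [0, 1].
#' @param stepup Apply the step-up cumulative minimum (default TRUE).
#' @return Vector of Q-values, same order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' @export
bh_adjust <- function(p, stepup = TRUE) {
  if (length(p) == 0L) return(numeric(0L))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  n <- length(p)
  q <- p * n / rank(p, ties.method = "average")
  if (stepup) {
    o <- order(p, decreasing = TRUE)
    q[o] <- cummin(q[o])
  }
  pmin(q, 1)
}

#' Assemble DE calls from p-values
#'
#' Adjusts p-values, ranks genes (ties broken by input position) and flags
#' genes with Q strictly below the threshold.
#'
#' @param p Per-gene p-values.
#' @param gene_id Optional gene identifiers (default g1, g2, ...).
#' @param q_threshold Call threshold on Q (strict `<`).
#' @param method Label recorded on the result.
#' @param stepup Passed to [bh_adjust()].
#' @return A `de_test` object: list with `table` (data frame gene_id, p, q,
#'   rank, de), `method`, `q_threshold`.
#' @export
call_de <- function(p, gene_id = NULL, q_threshold = 1e-4,
                    method = "unspecified", stepup = TRUE) {
  if (q_threshold <= 0 || q_threshold >= 1)
    stop("q_threshold must be in (0, 1)")
  if (is.null(gene_id))
    gene_id <- if (length(p)) paste0("g", seq_along(p)) else character(0L)
  q <- bh_adjust(p, stepup = stepup)
  rk <- if (length(p)) order(order(p, seq_along(p))) else integer(0L)
  tab <- data.frame(gene_id = as.character(gene_id), p = as.numeric(p),
                    q = q, rank = rk, de = q < q_threshold,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, method = method, q_threshold = q_threshold),
            class = "de_test")
}

#' Test all genes under a fitted normalization
#'
#' The final calling stage: every gene (including any excluded during IMM
#' iteration) is tested with the fitted factors. For an `imm_fit` the
#' effective totals are the retained-gene library sums scaled by the
#' factors; for TMM / library-size factors the library sizes are scaled.
#'
#' @param counts A [count_matrix].
#' @param design A [group_design]; optional for two libraries.
#' @param factors A `norm_factors` object (from [imm_norm()], [tmm_norm()]
#'   or [libsize_norm()]).
#' @param test Test tag as in [imm_norm()]; defaults to the fit's test, or
#'   `"fisher"` / `"poisson_exact"` by design shape.
#' @param q_threshold Final FDR-style call threshold (default 1e-4).
#' @param stepup Passed to [bh_adjust()].
#' @return A `de_test` object.
#' @export
de_test <- function(counts, design = NULL, factors, test = NULL,
                    q_threshold = 1e-4, stepup = TRUE) {
  counts <- as_count_matrix(counts)
  stopifnot(inherits(factors, "norm_factors"))
  libs <- colnames(counts$counts)
  if (is.null(design)) {
    if (!is.null(factors$design)) design <- factors$design
    else if (length(libs) == 2L)
      design <- group_design(stats::setNames(libs, libs),
                             reference = factors$reference)
    else stop("a group_design is required for more than two libraries")
  }
  check_design(counts, design)
  one_per_group <- all(table(design$condition) == 1L)
  if (is.null(test))
    test <- if (!is.null(factors$test)) factors$test
            else if (one_per_group) "fisher" else "poisson_exact"
  totals <- if (!is.null(factors$retained_totals)) factors$retained_totals
            else counts$lib_sizes
  eff <- effective_totals_vec(totals[libs], factors$factors[libs])
  p <- gene_pvalues(counts$counts, design, eff, test)
  call_de(p, gene_id = gene_ids(counts), q_threshold = q_threshold,
          method = paste(factors$method, test, sep = "+"), stepup = stepup)
}

#' @export
print.de_test <- function(x, ...) {
  cat(sprintf("de_test (%s): %d genes, %d called DE at Q < %g\n",
              x$method, nrow(x$table), sum(x$table$de), x$q_threshold))
  invisible(x)
}

#' @export
summary.de_test <- function(object, ...) {
  print(object)
  cat("smallest p-values:\n")
  print(utils::head(object$table[order(object$table$rank), ], 5L),
        row.names = FALSE)
  invisible(object)
}
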