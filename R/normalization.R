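# Normalization factors: library-size baseline, TMM (doubly trimmed weighted
# mean of M), and IMM (iterated median of M with DE-gene exclusion).
#
# Convention: the factor f_k for library k against reference r multiplies k's
# totals (effective total T_k * sqrt(f), reference T_r / sqrt(f)), so a gene
# whose M equals log2(f_k) sits exactly on the null of the downstream exact
# test.

new_norm_factors <- function(method, factors, reference, trace = NULL,
                             excluded = NULL, converged = NA, extra = NULL) {
  stopifnot(abs(factors[[reference]] - 1) == 0)
  obj <- c(list(method = method, factors = factors, reference = reference,
                trace = trace, excluded = excluded, converged = converged),
           extra)
  class(obj) <- if (method == "imm") c("imm_fit", "norm_factors") else
    "norm_factors"
  obj
}

resolve_ref <- function(counts, reference) {
  libs <- colnames(counts$counts)
  if (is.null(reference)) return(libs[1L])
  if (is.numeric(reference)) reference <- libs[as.integer(reference)]
  if (is.na(reference) || !reference %in% libs)
    stop("reference library not found")
  reference
}

#' Library-size normalization factors (identity baseline)
#'
#' All scaling factors are 1: between-library adjustment is carried entirely
#' by the library sizes N_k.
#'
#' @param counts A [count_matrix].
#' @param reference Reference library (name or index); defaults to the first.
#' @return A `norm_factors` object with method `"library_size"`.
#' @export
libsize_norm <- function(counts, reference = NULL) {
  counts <- as_count_matrix(counts)
  reference <- resolve_ref(counts, reference)
  f <- rep(1, ncol(counts$counts))
  names(f) <- colnames(counts$counts)
  new_norm_factors("library_size", f, reference)
}

tmm_pair_factor <- function(counts, k, r, trim_M = 0.30, trim_A = 0.05) {
  ma <- compute_ma(counts, k, r)
  tmm_factor(ma, counts, trim_M = trim_M, trim_A = trim_A)
}

#' TMM factor for one library pair
#'
#' Trimmed mean of M-values: genes with a zero in either library are dropped,
#' then the upper and lower `trim_M` fraction by M and `trim_A` fraction by A
#' are removed (per tail, rank-based; boundary ties retained), and the factor
#' is 2 to the weighted mean of the surviving M values with inverse
#' approximate-variance weights
#' w_g = (N_k - Y_gk)/(N_k Y_gk) + (N_r - Y_gr)/(N_r Y_gr).
#'
#' @param ma An `ma_profile` from [compute_ma()].
#' @param counts The [count_matrix] the profile was computed from.
#' @param trim_M Fraction trimmed from each tail of M (default 0.30).
#' @param trim_A Fraction trimmed from each tail of A (default 0.05).
#' @return The scaling factor (positive scalar) for library k vs r.
#' @export
tmm_factor <- function(ma, counts, trim_M = 0.30, trim_A = 0.05) {
  stopifnot(inherits(ma, "ma_profile"))
  counts <- as_count_matrix(counts)
  if (trim_M < 0 || trim_M >= 0.5 || trim_A < 0 || trim_A >= 0.5)
    stop("trim fractions must be in [0, 0.5)")
  v <- which(ma$valid)
  if (length(v) == 0L) stop("no genes with positive counts in both libraries")
  M <- ma$M[v]
  A <- ma$A[v]
  n <- length(v)
  loM <- floor(n * trim_M) + 1L; hiM <- n + 1L - loM
  loA <- floor(n * trim_A) + 1L; hiA <- n + 1L - loA
  rM <- rank(M); rA <- rank(A)
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep))
    stop("no genes survive trimming; use smaller trim_M/trim_A")
  kk <- match(ma$pair[1L], colnames(counts$counts))
  rr <- match(ma$pair[2L], colnames(counts$counts))
  yk <- counts$counts[v, kk][keep]
  yr <- counts$counts[v, rr][keep]
  Nk <- counts$lib_sizes[kk]
  Nr <- counts$lib_sizes[rr]
  w <- (Nk - yk) / (Nk * yk) + (Nr - yr) / (Nr * yr)
  2 ^ (sum(M[keep] / w) / sum(1 / w))
}

#' TMM normalization factors for all libraries against a reference
#'
#' @param counts A [count_matrix].
#' @param reference Reference library (name or index); defaults to the first.
#' @param trim_M,trim_A Per-tail trim fractions, see [tmm_factor()].
#' @return A `norm_factors` object with method `"tmm"`; the reference factor
#'   is exactly 1.
#' @export
tmm_norm <- function(counts, reference = NULL, trim_M = 0.30, trim_A = 0.05) {
  counts <- as_count_matrix(counts)
  reference <- resolve_ref(counts, reference)
  libs <- colnames(counts$counts)
  f <- vapply(libs, function(l) {
    if (l == reference) 1 else
      tmm_pair_factor(counts, l, reference, trim_M, trim_A)
  }, numeric(1L))
  new_norm_factors("tmm", f, reference)
}

#' Initial IMM factor: median of M-values
#'
#' The starting scaling factor of the iterated-median procedure: 2 raised to
#' the median of the valid (both counts positive) M values. For a library
#' against a copy of itself all M are 0 and the factor is exactly 1.
#'
#' @param ma An `ma_profile` from [compute_ma()].
#' @return Positive scaling factor.
#' @export
imm_initial_factor <- function(ma) {
  stopifnot(inherits(ma, "ma_profile"))
  M <- ma$M[ma$valid]
  if (length(M) == 0L)
    stop("no genes with positive counts in both libraries")
  2 ^ stats::median(M)
}

#' Effective library totals under a normalization factor
#'
#' Splits a scaling factor f for library k against reference r symmetrically
#' across the pair: the target total is multiplied and the reference total
#' divided by sqrt(f), so the exact-test null proportion
#' T_k_eff / (T_k_eff + T_r_eff) absorbs the factor. The ratio of the outputs
#' equals the input ratio times f.
#'
#' @param T_k,T_r Positive library totals (target, reference).
#' @param factor Positive scaling factor of k relative to r.
#' @return Numeric pair (T_k_eff, T_r_eff).
#' @examples
#' effective_totals(1000, 1000, 4)  # c(2000, 500)
#' @export
effective_totals <- function(T_k, T_r, factor) {
  if (any(c(T_k, T_r, factor) <= 0) || any(!is.finite(c(T_k, T_r, factor))))
    stop("totals and factor must be positive and finite")
  s <- sqrt(factor)
  c(T_k * s, T_r / s)
}

# Per-library effective totals for a factor vector (reference factor 1).
# Within any pair (k, r) the ratio T_k f_k / (T_r f_r) equals the
# pairwise sqrt-split rule's ratio, so tests agree with effective_totals().
effective_totals_vec <- function(totals, factors) totals * factors

# One pass of factor estimation over the retained gene set: per non-reference
# library, median of M computed with retained valid-gene totals.
imm_factors_once <- function(counts, reference, retained) {
  libs <- colnames(counts$counts)
  Y <- counts$counts
  r <- match(reference, libs)
  f <- rep(1, length(libs)); names(f) <- libs
  for (k in seq_along(libs)) {
    if (k == r) next
    valid <- retained & Y[, k] > 0 & Y[, r] > 0
    if (!any(valid))
      stop(sprintf("no usable genes for library '%s' vs reference", libs[k]))
    totals <- c(sum(Y[valid, k]), sum(Y[valid, r]))
    M <- log2((Y[valid, k] / totals[1L]) / (Y[valid, r] / totals[2L]))
    f[k] <- 2 ^ stats::median(M)
  }
  f
}

#' Iterated median of M-values (IMM) normalization
#'
#' Estimates per-library scaling factors by iterating between (i) the median
#' of M-values over the currently retained genes, with proportions computed
#' against retained-gene totals, and (ii) an exact or likelihood-ratio test
#' of every retained gene using effective totals derived from the current
#' factors, excluding genes with Benjamini-Hochberg Q-value below
#' `q_threshold` from subsequent factor estimation. Iteration stops when no
#' new genes are excluded and the factor change is below `tol` on the log2
#' scale. The goal is an invariant set of non-differentially-expressed genes
#' that anchors the normalization even when differential expression is
#' abundant and asymmetric.
#'
#' @param counts A [count_matrix].
#' @param design Optional [group_design]; required when libraries are
#'   replicated. With exactly two libraries and no design, each library is
#'   its own condition.
#' @param reference Reference library (name or index); defaults to the first
#'   (or the design's reference).
#' @param test Per-gene test used during iteration and by [de_test()]:
#'   `"fisher"` (two single libraries, exact binomial), `"poisson_exact"`
#'   (group-summed exact binomial) or `"poisson_lr"` (Poisson likelihood
#'   ratio, chi-squared with 1 df). Default picks `"fisher"` for a
#'   one-library-per-condition design, else `"poisson_exact"`.
#' @param q_threshold Q-value below which a gene is excluded during
#'   iteration (default 0.005; this is an exclusion threshold, not the final
#'   FDR level).
#' @param max_iter Hard iteration cap (default 20); hitting it flags the fit
#'   as non-converged with a warning rather than an error.
#' @param tol Convergence tolerance on |log2 f_{j+1} - log2 f_j|.
#' @return An object of class `imm_fit` (inheriting `norm_factors`) with
#'   elements `factors` (named, reference = 1), `trace` (per non-reference
#'   library: data frame of per-iteration factor and cumulative exclusions),
#'   `excluded` (gene ids called DE during iteration), `converged`,
#'   `n_iter`, `test`, `q_threshold`.
#' @examples
#' set.seed(1)
#' y <- matrix(rpois(400, 50), 200, 2, dimnames = list(NULL, c("a", "b")))
#' fit <- imm_norm(count_matrix(y))
#' coef(fit)
#' @export
imm_norm <- function(counts, design = NULL, reference = NULL, test = NULL,
                     q_threshold = 0.005, max_iter = 20L, tol = 1e-6) {
  counts <- as_count_matrix(counts)
  libs <- colnames(counts$counts)
  if (is.null(design)) {
    if (length(libs) != 2L)
      stop("a group_design is required for more than two libraries")
    design <- group_design(stats::setNames(libs, libs),
                           reference = resolve_ref(counts, reference))
  }
  check_design(counts, design)
  reference <- resolve_ref(counts, if (is.null(reference)) design$reference
                           else reference)
  one_per_group <- all(table(design$condition) == 1L)
  if (is.null(test)) test <- if (one_per_group) "fisher" else "poisson_exact"
  test <- match.arg(test, c("fisher", "poisson_exact", "poisson_lr"))
  if (test == "fisher" && !one_per_group)
    stop("test 'fisher' requires exactly one library per condition")
  if (q_threshold <= 0 || q_threshold >= 1)
    stop("q_threshold must be in (0, 1)")

  Y <- counts$counts
  ids <- gene_ids(counts)
  retained <- rep(TRUE, nrow(Y))
  nonref <- setdiff(libs, reference)
  trace <- lapply(nonref, function(l) data.frame(iter = integer(),
                                                 factor = numeric(),
                                                 n_excluded = integer()))
  names(trace) <- nonref
  f_prev <- NULL
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    f <- imm_factors_once(counts, reference, retained)
    test_totals <- colSums(Y[retained, , drop = FALSE])
    if (any(test_totals <= 0)) stop("a library has no reads on retained genes")
    eff <- effective_totals_vec(test_totals, f)
    p <- gene_pvalues(Y[retained, , drop = FALSE], design, eff, test)
    q <- bh_adjust(p)
    new_de <- which(retained)[q < q_threshold]
    n_excl_after <- sum(!retained) + length(new_de)
    for (l in nonref)
      trace[[l]] <- rbind(trace[[l]],
                          data.frame(iter = iter, factor = f[[l]],
                                     n_excluded = n_excl_after))
    # the factor is a function of the retained set only: with no new
    # exclusions the next factor would repeat this one, so we are at the
    # fixed point (and the |log2 change| < tol condition holds trivially)
    stable <- is.null(f_prev) ||
      max(abs(log2(f[nonref]) - log2(f_prev[nonref]))) < tol ||
      length(new_de) == 0L
    if (length(new_de) == 0L && stable) {
      converged <- TRUE
      f_prev <- f
      break
    }
    retained[new_de] <- FALSE
    if (!any(retained)) stop("all genes excluded during IMM iteration")
    f_prev <- f
  }
  if (!converged)
    warning(sprintf("IMM did not converge within %d iterations", max_iter))
  new_norm_factors("imm", f_prev, reference,
                   trace = trace, excluded = ids[!retained],
                   converged = converged,
                   extra = list(n_iter = iter, test = test,
                                q_threshold = q_threshold,
                                retained_totals = colSums(
                                  Y[retained, , drop = FALSE]),
                                design = design))
}

#' @export
print.norm_factors <- function(x, ...) {
  cat(sprintf("norm_factors (%s), reference '%s'\n", x$method, x$reference))
  print(signif(x$factors, 6))
  invisible(x)
}

#' @export
print.imm_fit <- function(x, ...) {
  cat(sprintf("IMM normalization fit (reference '%s', test '%s')\n",
              x$reference, x$test))
  print(signif(x$factors, 6))
  cat(sprintf("%d iterations (%s), %d genes excluded at Q < %g\n",
              x$n_iter, if (x$converged) "converged" else "NOT converged",
              length(x$excluded), x$q_threshold))
  invisible(x)
}

#' @export
summary.imm_fit <- function(object, ...) {
  cat(sprintf("IMM normalization fit\n  reference: %s\n  test: %s\n",
              object$reference, object$test))
  cat(sprintf("  converged: %s in %d iterations\n", object$converged,
              object$n_iter))
  cat(sprintf("  genes excluded during iteration: %d\n",
              length(object$excluded)))
  cat("  factors:\n")
  print(signif(object$factors, 6))
  cat("  iteration trace:\n")
  for (l in names(object$trace)) {
    cat(sprintf("   library %s:\n", l))
    print(object$trace[[l]], row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.norm_factors <- function(object, ...) object$factors

#' MA plot of an IMM fit
#'
#' Plots A against M for the first non-reference library versus the
#' reference, marks genes excluded during iteration, and draws the final
#' log2 factor as a horizontal line.
#'
#' @param x An `imm_fit`.
#' @param counts The [count_matrix] the fit was computed from.
#' @param lib Non-reference library to plot; defaults to the first.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.imm_fit <- function(x, counts, lib = NULL, ...) {
  counts <- as_count_matrix(counts)
  if (is.null(lib)) lib <- names(x$trace)[1L]
  ma <- compute_ma(counts, lib, x$reference)
  excl <- ma$gene_id %in% x$excluded
  graphics::plot(ma$A, ma$M, pch = 20, cex = 0.4,
                 col = ifelse(excl, "red", "grey40"),
                 xlab = "A (average log2 abundance)",
                 ylab = "M (log2 fold change)", ...)
  graphics::abline(h = log2(x$factors[[lib]]), col = "blue", lwd = 2)
  invisible(x)
}
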