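# Poisson count simulator with known DE structure, and false-discovery-curve
# scoring of normalization/test combinations.

#' Simulation configuration
#'
#' Describes a two-condition count simulation: per-gene baseline expression
#' is sampled from an empirical count distribution (or a built-in
#' heavy-tailed log-normal surrogate), converted to proportions of total RNA
#' output, modified by unique-to-group and differential-expression
#' multipliers, rescaled within each condition to the target library size,
#' and finally observed as independent Poisson counts (technical
#' replicates).
#'
#' @param n_genes Number of genes.
#' @param lib_sizes Target library size(s) N_k; a scalar is recycled across
#'   all 2 * n_reps_per_group libraries.
#' @param n_reps_per_group Libraries per condition (1 = two-library design).
#' @param prop_unique Fraction of genes expressed only in condition 1 (true
#'   mean zero in condition 2).
#' @param prop_de Fraction of the remaining genes that are differentially
#'   expressed at `fold`.
#' @param fold Fold change of DE genes (> 0).
#' @param prop_up Fraction of DE genes higher in condition 1; drawn per gene
#'   as Bernoulli unless `exact_counts`.
#' @param mean_source Optional vector of non-negative observed counts to
#'   resample baseline expression from; default draws from a log-normal with
#'   `meanlog`, `sdlog`.
#' @param meanlog,sdlog Parameters of the built-in log-normal surrogate.
#' @param exact_counts Assign the up/down split deterministically (rounded
#'   counts) instead of per-gene Bernoulli.
#' @param seed Optional seed applied by [simulate_counts()].
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 10000L, lib_sizes = 1e6,
                       n_reps_per_group = 1L, prop_unique = 0.1,
                       prop_de = 0.3, fold = 4, prop_up = 0.9,
                       mean_source = NULL, meanlog = 4, sdlog = 2,
                       exact_counts = FALSE, seed = NULL) {
  n_genes <- as.integer(n_genes)
  n_reps_per_group <- as.integer(n_reps_per_group)
  stopifnot(n_genes >= 1L, n_reps_per_group >= 1L, fold > 0,
            prop_unique >= 0, prop_de >= 0, prop_up >= 0, prop_up <= 1,
            prop_unique + prop_de <= 1)
  K <- 2L * n_reps_per_group
  if (length(lib_sizes) == 1L) lib_sizes <- rep(lib_sizes, K)
  if (length(lib_sizes) != K)
    stop(sprintf("lib_sizes must have length 1 or %d", K))
  if (any(lib_sizes <= 0)) stop("lib_sizes must be positive")
  if (!is.null(mean_source)) {
    if (any(mean_source < 0) || !any(mean_source > 0))
      stop("mean_source must be non-negative with at least one positive value")
  }
  structure(list(n_genes = n_genes, lib_sizes = as.numeric(lib_sizes),
                 n_reps_per_group = n_reps_per_group,
                 prop_unique = prop_unique, prop_de = prop_de, fold = fold,
                 prop_up = prop_up, mean_source = mean_source,
                 meanlog = meanlog, sdlog = sdlog,
                 exact_counts = isTRUE(exact_counts), seed = seed),
            class = "sim_config")
}

# Library names and design implied by a config: condition A libraries first.
sim_design <- function(config) {
  n <- config$n_reps_per_group
  libs <- c(paste0("A", seq_len(n)), paste0("B", seq_len(n)))
  group_design(stats::setNames(rep(c("A", "B"), each = n), libs),
               reference = libs[1L])
}

#' Sample baseline expression proportions
#'
#' Draws `n_genes` baseline expression values with replacement from the
#' empirical source (or the log-normal surrogate) and normalizes them to
#' proportions of total RNA output, i.e. the relative mean expression each
#' gene would have in an undisturbed library.
#'
#' @param config A [sim_config()].
#' @return Numeric vector of proportions summing to 1.
#' @export
sample_baseline_means <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  base <- if (!is.null(config$mean_source))
    config$mean_source[sample.int(length(config$mean_source),
                                  config$n_genes, replace = TRUE)]
  else
    stats::rlnorm(config$n_genes, config$meanlog, config$sdlog)
  # resampling zeros from an empirical source is allowed; keep the gene but
  # give it a negligible positive mass so proportions stay well defined
  if (sum(base) <= 0) stop("sampled baseline expression is all zero")
  base / sum(base)
}

#' Impose ground-truth DE structure on baseline proportions
#'
#' Assigns disjoint gene categories: `prop_unique` of genes become
#' unique-to-group (condition 2 mean zero), then `prop_de` of the remainder
#' become DE at `fold` (direction Bernoulli(`prop_up`) per gene, or exact
#' rounded counts when `exact_counts`); all others are null. Per-condition
#' expression is renormalized to proportions and scaled to each library's
#' target size, so the expected library sum is N_k and the composition bias
#' induced by asymmetric DE is reflected in the true per-condition RNA
#' output.
#'
#' @param baseline Proportions from [sample_baseline_means()].
#' @param config A [sim_config()].
#' @return A `truth_model`: list with `labels` (null / de_up / de_down /
#'   unique), `mu` (gene-by-library true Poisson means), `total_output`
#'   (per-library relative total RNA output S), `design`.
#' @export
apply_truth <- function(baseline, config) {
  stopifnot(inherits(config, "sim_config"))
  G <- config$n_genes
  stopifnot(length(baseline) == G)
  labels <- rep("null", G)
  n_unique <- round(config$prop_unique * G)
  idx_unique <- sample.int(G, n_unique)
  labels[idx_unique] <- "unique"
  rest <- setdiff(seq_len(G), idx_unique)
  n_de <- round(config$prop_de * length(rest))
  idx_de <- rest[sample.int(length(rest), n_de)]
  if (config$exact_counts) {
    n_up <- round(config$prop_up * n_de)
    up <- rep(FALSE, n_de)
    up[sample.int(n_de, n_up)] <- TRUE
  } else {
    up <- stats::runif(n_de) < config$prop_up
  }
  labels[idx_de[up]] <- "de_up"
  labels[idx_de[!up]] <- "de_down"

  m1 <- rep(1, G); m2 <- rep(1, G)
  m2[labels == "unique"] <- 0
  m1[labels == "de_up"] <- config$fold
  m2[labels == "de_down"] <- config$fold
  x1 <- baseline * m1
  x2 <- baseline * m2
  S <- c(A = sum(x1), B = sum(x2))
  design <- sim_design(config)
  cond <- design$condition
  mu <- vapply(seq_along(cond), function(k) {
    x <- if (cond[k] == "A") x1 else x2
    x / S[[cond[k]]] * config$lib_sizes[k]
  }, numeric(G))
  colnames(mu) <- names(cond)
  rownames(mu) <- paste0("g", seq_len(G))
  structure(list(labels = labels, mu = mu,
                 total_output = stats::setNames(S[cond], names(cond)),
                 design = design),
            class = "truth_model")
}

#' True normalization factor implied by a truth model
#'
#' For a null gene, M between libraries k and r equals
#' log2(S_r / S_k), so the factor the normalization should recover for
#' library k against reference r is S_r / S_k (1 when conditions have equal
#' total RNA output).
#'
#' @param truth A `truth_model`.
#' @param k,r Library names or indices.
#' @return Positive scalar.
#' @export
true_factor <- function(truth, k, r) {
  S <- truth$total_output
  if (is.character(k)) k <- match(k, names(S))
  if (is.character(r)) r <- match(r, names(S))
  unname(S[r] / S[k])
}

#' Draw Poisson counts from a truth model
#'
#' Independent Poisson observation of every gene-by-library mean; replicate
#' libraries share their condition's mean structure (technical replicates).
#'
#' @param truth A `truth_model` from [apply_truth()].
#' @param config The matching [sim_config()].
#' @return A `sim_dataset`: list with `counts` (a [count_matrix]) and
#'   `truth`.
#' @export
draw_counts <- function(truth, config) {
  stopifnot(inherits(truth, "truth_model"))
  mu <- truth$mu
  y <- matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu),
              dimnames = dimnames(mu))
  structure(list(counts = count_matrix(y), truth = truth),
            class = "sim_dataset")
}

#' Simulate a complete dataset
#'
#' Runs the full generative pipeline: baseline sampling, truth assignment,
#' Poisson observation. Setting `config$seed` (or `seed`) makes the result
#' bit-reproducible.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A `sim_dataset`.
#' @examples
#' d <- simulate_counts(sim_config(n_genes = 500, lib_sizes = 1e4, seed = 7))
#' table(d$truth$labels)
#' @export
simulate_counts <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- config$seed
  if (!is.null(seed)) set.seed(seed)
  baseline <- sample_baseline_means(config)
  truth <- apply_truth(baseline, config)
  draw_counts(truth, config)
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("sim_dataset:\n")
  print(x$counts)
  print(table(x$truth$labels))
  invisible(x)
}

#' False-discovery curve
#'
#' Ranks genes by ascending p-value (stable in input order) and counts, for
#' every cut n, how many of the top-n genes are truly null. Unique-to-group
#' genes are removed before ranking by default, so the curve is computed
#' among genes common to both conditions.
#'
#' @param p Per-gene p-values covering all genes of `truth`.
#' @param truth A `truth_model`.
#' @param restrict_common Drop unique-to-group genes first (default TRUE).
#' @return An `fd_curve`: data frame with `n_selected` and
#'   `false_discoveries` (non-decreasing, pointwise at most `n_selected`).
#' @export
fd_curve <- function(p, truth, restrict_common = TRUE) {
  stopifnot(inherits(truth, "truth_model"))
  if (length(p) != length(truth$labels))
    stop("p must have one value per gene in truth")
  keep <- if (restrict_common) truth$labels != "unique"
          else rep(TRUE, length(p))
  p <- p[keep]
  lab <- truth$labels[keep]
  o <- order(p, seq_along(p))
  fd <- cumsum(lab[o] == "null")
  structure(data.frame(n_selected = seq_along(fd), false_discoveries = fd),
            class = c("fd_curve", "data.frame"),
            restricted_to_common = restrict_common)
}

norm_by_tag <- function(tag, counts, design, test, ...) {
  switch(tag,
    libsize = ,
    library_size = libsize_norm(counts, reference = design$reference),
    tmm = tmm_norm(counts, reference = design$reference, ...),
    imm = imm_norm(counts, design = design, test = test, ...),
    stop(sprintf("unknown normalization '%s'", tag)))
}

#' Benchmark normalization/test combinations on simulated data
#'
#' For each seeded replicate simulation: generate counts, fit each
#' normalization, test all genes, and record the false-discovery curve among
#' common genes. Curves are averaged pointwise across replicates.
#'
#' @param config A [sim_config()].
#' @param methods List of `c(normalization, test)` pairs, e.g.
#'   `list(c("imm", "poisson_exact"), c("tmm", "poisson_exact"))`.
#'   Normalization tags: `libsize`, `tmm`, `imm`.
#' @param n_sims Number of replicate simulations.
#' @param seed Base seed; replicate i uses `seed + i - 1`.
#' @return An `fd_comparison`: list with `methods` (labels), `n_selected`,
#'   `mean` (named list of mean curves) and `per_seed` (named list of
#'   n_sims-by-n matrices).
#' @export
run_comparison <- function(config, methods, n_sims = 10L, seed = 1L) {
  stopifnot(inherits(config, "sim_config"), length(methods) >= 1L)
  labels <- vapply(methods, function(m) paste(m, collapse = "+"),
                   character(1L))
  per_seed <- NULL
  n_common <- NA_integer_
  for (i in seq_len(n_sims)) {
    d <- simulate_counts(config, seed = seed + i - 1L)
    design <- d$truth$design
    for (j in seq_along(methods)) {
      m <- methods[[j]]
      fit <- norm_by_tag(m[1L], d$counts, design, m[2L])
      res <- de_test(d$counts, design, fit, test = m[2L])
      cur <- fd_curve(res$table$p, d$truth)
      if (is.null(per_seed)) {
        n_common <- nrow(cur)
        per_seed <- lapply(labels, function(l)
          matrix(NA_real_, n_sims, n_common))
        names(per_seed) <- labels
      }
      per_seed[[j]][i, ] <- cur$false_discoveries
    }
  }
  structure(list(methods = labels, n_selected = seq_len(n_common),
                 mean = lapply(per_seed, colMeans), per_seed = per_seed,
                 n_sims = n_sims, seed = seed),
            class = "fd_comparison")
}

#' @export
print.fd_comparison <- function(x, ...) {
  cat(sprintf("fd_comparison: %d replicate simulations\n", x$n_sims))
  at <- unique(pmin(max(x$n_selected), c(100L, 500L, max(x$n_selected))))
  for (m in x$methods)
    cat(sprintf("  %-28s mean FD at n=%s: %s\n", m,
                paste(at, collapse = "/"),
                paste(signif(x$mean[[m]][at], 4), collapse = "/")))
  invisible(x)
}

#' Long-format table of a benchmark
#'
#' @param x An `fd_comparison`.
#' @param ... Unused.
#' @return Data frame with columns method, seed, n_selected,
#'   false_discoveries.
#' @export
as.data.frame.fd_comparison <- function(x, ...) {
  do.call(rbind, lapply(x$methods, function(m) {
    do.call(rbind, lapply(seq_len(x$n_sims), function(i)
      data.frame(method = m, seed = x$seed + i - 1L,
                 n_selected = x$n_selected,
                 false_discoveries = x$per_seed[[m]][i, ])))
  }))
}
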