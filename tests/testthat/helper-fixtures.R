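# Shared fixtures and independent brute-force oracles.

# Frozen 20-gene two-library fixture with a wide abundance range; literal
# values so the fixture is stable across sessions.
fixture20 <- function() {
  y <- matrix(c(
    105L,  13L, 280L,  24L,  60L,  63L, 936L,  24L,  46L,  83L,
    235L,  29L,  69L,  11L,  27L, 427L,  27L,  35L,  84L, 633L,
     88L,  36L, 342L,  12L,  76L,  43L, 1039L, 18L,  33L, 110L,
    276L,  16L,  95L,   5L,  20L, 395L,  13L,  53L,  66L, 587L),
    nrow = 20L, ncol = 2L,
    dimnames = list(paste0("g", 1:20), c("lib1", "lib2")))
  count_matrix(y)
}

tmp_counts_file <- function(cm, dir = withr::local_tempdir(.local_envir =
                                                             parent.frame())) {
  path <- file.path(dir, "counts.tsv")
  write_counts(cm, path)
  path
}

# Independent exact-test oracle: enumerate all n + 1 binomial outcomes and
# sum those no more probable than the observed one. Outcomes tied with the
# observed probability in exact arithmetic (e.g. the mirror outcome at
# p0 = 0.5) can differ by an ulp in floating point, so ties are recognised
# at a tiny relative tolerance.
oracle_exact_p <- function(y_k, y_r, p0) {
  n <- y_k + y_r
  if (n == 0L) return(1)
  pr <- dbinom(0:n, n, p0)
  min(1, sum(pr[pr <= pr[y_k + 1L] * (1 + 1e-9)]))
}

# Independent TMM oracle: sort, trim each criterion by explicit sorted
# positions, intersect, and take the weighted mean by the printed formula.
oracle_tmm <- function(cm, k = 2L, r = 1L, trim_M = 0.30, trim_A = 0.05) {
  y <- cm$counts
  N <- cm$lib_sizes
  keep <- y[, k] > 0 & y[, r] > 0
  yk <- y[keep, k]; yr <- y[keep, r]
  M <- log2((yk / N[k]) / (yr / N[r]))
  A <- 0.5 * log2((yk / N[k]) * (yr / N[r]))
  n <- length(M)
  lo <- floor(n * trim_M) + 1L; hi <- n + 1L - lo
  keepM <- seq_len(n) %in% order(M)[lo:hi]
  lo <- floor(n * trim_A) + 1L; hi <- n + 1L - lo
  keepA <- seq_len(n) %in% order(A)[lo:hi]
  sel <- keepM & keepA
  w <- (N[k] - yk[sel]) / (N[k] * yk[sel]) + (N[r] - yr[sel]) / (N[r] * yr[sel])
  2 ^ (sum(M[sel] / w) / sum(1 / w))
}

# Two-library design for a count matrix (each library its own condition).
pair_design <- function(cm) {
  libs <- colnames(cm$counts)
  group_design(stats::setNames(libs, libs), reference = libs[1L])
}
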