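test_that("baseline proportions are normalized and respect the source", {
  cfg <- sim_config(n_genes = 50, lib_sizes = 1e4,
                    mean_source = rep(100, 5), seed = 1)
  set.seed(1)
  prop <- sample_baseline_means(cfg)
  expect_equal(sum(prop), 1)
  expect_true(all(prop == prop[1]))  # constant source: equal proportions
  cfg2 <- sim_config(n_genes = 500, lib_sizes = 1e4)
  set.seed(2)
  prop2 <- sample_baseline_means(cfg2)
  expect_equal(sum(prop2), 1)
  expect_error(sim_config(mean_source = c(0, 0)), "positive")
})

test_that("simulation is bit-reproducible under a fixed seed", {
  cfg <- sim_config(n_genes = 300, lib_sizes = 5e4, seed = 9)
  d1 <- simulate_counts(cfg)
  d2 <- simulate_counts(cfg)
  expect_identical(d1$counts$counts, d2$counts$counts)
  expect_identical(d1$truth$labels, d2$truth$labels)
  d3 <- simulate_counts(cfg, seed = 10)
  expect_false(identical(d1$counts$counts, d3$counts$counts))
})

test_that("truth labels partition genes per the configured fractions", {
  cfg <- sim_config(n_genes = 2000, lib_sizes = 1e5, prop_unique = 0.1,
                    prop_de = 0.3)
  set.seed(3)
  truth <- apply_truth(sample_baseline_means(cfg), cfg)
  tab <- table(factor(truth$labels,
                      c("null", "de_up", "de_down", "unique")))
  expect_equal(sum(tab), 2000)
  expect_equal(unname(tab["unique"]), 200)
  expect_equal(unname(tab["de_up"] + tab["de_down"]), round(0.3 * 1800))
  # no DE, no unique: all null
  cfg0 <- sim_config(n_genes = 100, lib_sizes = 1e4, prop_unique = 0,
                     prop_de = 0)
  set.seed(4)
  truth0 <- apply_truth(sample_baseline_means(cfg0), cfg0)
  expect_true(all(truth0$labels == "null"))
  expect_equal(unname(true_factor(truth0, "B1", "A1")), 1)
})

test_that("DE direction concentrates at the configured up fraction", {
  cfg <- sim_config(n_genes = 10000, lib_sizes = 1e5, prop_unique = 0,
                    prop_de = 0.5, prop_up = 0.9)
  set.seed(5)
  truth <- apply_truth(sample_baseline_means(cfg), cfg)
  n_up <- sum(truth$labels == "de_up")
  n_de <- n_up + sum(truth$labels == "de_down")
  expect_lt(abs(n_up / n_de - 0.9), 0.02)
  # deterministic split option
  cfg2 <- sim_config(n_genes = 1000, lib_sizes = 1e5, prop_unique = 0,
                     prop_de = 0.5, prop_up = 0.9, exact_counts = TRUE)
  set.seed(6)
  t2 <- apply_truth(sample_baseline_means(cfg2), cfg2)
  expect_equal(sum(t2$labels == "de_up"), round(0.9 * 500))
})

test_that("true means encode fold changes and unique-to-group zeros", {
  cfg <- sim_config(n_genes = 400, lib_sizes = c(1e5, 2e5), prop_unique = 0.1,
                    prop_de = 0.3, fold = 4, prop_up = 1)
  set.seed(7)
  truth <- apply_truth(sample_baseline_means(cfg), cfg)
  mu <- truth$mu
  S <- truth$total_output
  expect_true(all(mu[truth$labels == "unique", "B1"] == 0))
  # within a condition the column sums to the library size
  expect_equal(unname(colSums(mu)), c(1e5, 2e5))
  # de_up genes: 4-fold after undoing library size and total output scaling
  up <- truth$labels == "de_up"
  ratio <- (mu[up, "A1"] / 1e5 * S[["A1"]]) / (mu[up, "B1"] / 2e5 * S[["B1"]])
  expect_equal(unname(ratio), rep(4, sum(up)))
  # null genes have equal means after the same rescaling
  nul <- truth$labels == "null"
  ratio0 <- (mu[nul, "A1"] / 1e5 * S[["A1"]]) /
    (mu[nul, "B1"] / 2e5 * S[["B1"]])
  expect_equal(unname(ratio0), rep(1, sum(nul)))
})

test_that("Poisson draws reproduce the configured means", {
  cfg <- sim_config(n_genes = 400, lib_sizes = 2e4, prop_unique = 0,
                    prop_de = 0)
  set.seed(8)
  truth <- apply_truth(rep(1 / 400, 400), cfg)
  expect_true(all(truth$mu == 50))
  d <- draw_counts(truth, cfg)
  expect_lt(abs(mean(d$counts$counts) - 50), 3 * sqrt(50 / 800))
  # zero mean always draws zero
  cfgu <- sim_config(n_genes = 200, lib_sizes = 2e4, prop_unique = 0.5,
                     prop_de = 0)
  set.seed(9)
  du <- simulate_counts(cfgu)
  expect_true(all(du$counts$counts[du$truth$labels == "unique", "B1"] == 0))
})

test_that("false-discovery curves count nulls among the top-ranked genes", {
  labs <- c("de_up", "null", "de_up", "null", "null", "de_up")
  truth <- structure(list(labels = labs), class = "truth_model")
  cur <- fd_curve(c(.01, .02, .03, .04, .05, .06), truth)
  expect_equal(cur$false_discoveries, c(0, 1, 1, 2, 3, 3))
  # oracle p-values: no false discoveries up to the number of DE genes
  p_oracle <- ifelse(labs == "null", 1, 0)
  expect_equal(fd_curve(p_oracle, truth)$false_discoveries[1:3], c(0, 0, 0))
  # all-null truth: the curve is the diagonal
  tn <- structure(list(labels = rep("null", 5)), class = "truth_model")
  expect_equal(fd_curve(rep(0.5, 5), tn)$false_discoveries, 1:5)
  # unique genes are excluded from the common-gene curve
  tu <- structure(list(labels = c("unique", "null", "de_up")),
                  class = "truth_model")
  expect_equal(nrow(fd_curve(c(.1, .2, .3), tu)), 2L)
  expect_equal(nrow(fd_curve(c(.1, .2, .3), tu, restrict_common = FALSE)), 3L)
  expect_error(fd_curve(c(.1, .2), tu), "per gene")
})

test_that("curves are monotone, bounded, and identical for repeated methods", {
  cfg <- sim_config(n_genes = 400, lib_sizes = 2e5, prop_de = 0.3,
                    prop_up = 0.9, prop_unique = 0.1)
  cmp <- run_comparison(cfg, list(c("tmm", "poisson_exact"),
                                  c("tmm", "poisson_exact")),
                        n_sims = 2, seed = 42)
  expect_equal(cmp$per_seed[[1]], cmp$per_seed[[2]])
  for (m in cmp$methods) {
    fd <- cmp$per_seed[[m]]
    expect_true(all(apply(fd, 1, function(v) all(diff(v) >= 0))))
    expect_true(all(t(fd) <= cmp$n_selected))
  }
})
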