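test_that("two-library exact p-values match hand enumeration", {
  expect_equal(two_library_exact_p(5, 5, 1000, 1000), 1)
  expect_equal(two_library_exact_p(0, 10, 1000, 1000), 2 / 1024)
  expect_equal(two_library_exact_p(3, 0, 500, 500), 0.25)
  expect_equal(two_library_exact_p(0, 0, 10, 10), 1)
  expect_error(two_library_exact_p(-1, 2, 10, 10), "non-negative")
  expect_error(two_library_exact_p(1, 2, 0, 10), "positive")
})

test_that("exact test equals the enumeration oracle over a grid of totals", {
  for (p0 in c(0.3, 0.5, 0.7)) {
    Tk <- 1000 * p0; Tr <- 1000 * (1 - p0)
    for (n in c(1L, 2L, 7L, 20L, 30L)) {
      yk <- 0:n
      got <- two_library_exact_p(yk, n - yk, Tk, Tr)
      want <- vapply(yk, function(y) oracle_exact_p(y, n - y, p0), numeric(1))
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("exact test agrees with statmod's sage test at matching totals", {
  skip_if_not_installed("statmod")
  yk <- c(5, 0, 17, 120, 3)
  yr <- c(9, 12, 3, 80, 3)
  expect_equal(two_library_exact_p(yk, yr, 1000, 1500),
               statmod::sage.test(yk, yr, 1000, 1500), tolerance = 1e-12)
})

test_that("tests are symmetric under exchanging the two groups", {
  yk <- c(0, 3, 10, 25)
  yr <- c(7, 3, 2, 25)
  expect_equal(two_library_exact_p(yk, yr, 800, 1200),
               two_library_exact_p(yr, yk, 1200, 800))
  cm <- count_matrix(cbind(a1 = c(4, 9), a2 = c(6, 1),
                           b1 = c(2, 8), b2 = c(1, 12)))
  d1 <- group_design(c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  d2 <- group_design(c(a1 = "B", a2 = "B", b1 = "A", b2 = "A"))
  eff <- c(a1 = 100, a2 = 120, b1 = 90, b2 = 110)
  expect_equal(poisson_exact_group_p(cm$counts, d1, eff),
               poisson_exact_group_p(cm$counts, d2, eff))
  expect_equal(poisson_lr_p(cm$counts, d1, eff),
               poisson_lr_p(cm$counts, d2, eff))
})

test_that("group exact test reduces to the two-library test for single libraries", {
  cm <- fixture20()
  des <- pair_design(cm)
  eff <- c(lib1 = 3000, lib2 = 3500)
  expect_equal(poisson_exact_group_p(cm$counts, des, eff),
               two_library_exact_p(cm$counts[, 1], cm$counts[, 2],
                                   3000, 3500))
  # group sums behave like a single aggregated pair
  expect_equal(poisson_exact_group_p(c(a = 5, b = 5),
                                     group_design(c(a = "A", b = "B")),
                                     c(a = 100, b = 100)), 1)
  expect_equal(poisson_exact_group_p(c(a = 0, b = 10),
                                     group_design(c(a = "A", b = "B")),
                                     c(a = 100, b = 100)),
               2 / 1024, tolerance = 1e-12)
})

test_that("Poisson LR statistic matches the closed-form pooled/split likelihoods", {
  des <- group_design(c(a = "A", b = "B"))
  expect_equal(poisson_lr_p(c(a = 7, b = 7), des, c(a = 500, b = 500)), 1)
  lr <- 2 * (10 * log(10 / 15) + 20 * log(20 / 15))
  expect_equal(poisson_lr_p(c(a = 10, b = 20), des, c(a = 500, b = 500)),
               pchisq(lr, 1, lower.tail = FALSE))
  expect_equal(round(lr, 3), 3.398)
  # all-zero gene is uninformative, not an error
  expect_equal(poisson_lr_p(c(a = 0, b = 0), des, c(a = 500, b = 500)), 1)
  # zero in one group uses the 0*log(0) = 0 convention
  expect_equal(poisson_lr_p(c(a = 0, b = 8), des, c(a = 500, b = 500)),
               pchisq(2 * 8 * log(2), 1, lower.tail = FALSE))
})

test_that("LR test holds its size under a replicated null simulation", {
  set.seed(77)
  mu <- 40
  y <- matrix(rpois(2000 * 4, mu), 2000, 4,
              dimnames = list(NULL, c("a1", "a2", "b1", "b2")))
  des <- group_design(c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  eff <- colSums(y)
  p <- poisson_lr_p(y, des, eff)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
})

test_that("BH adjustment applies the rank formula with step-up enforcement", {
  expect_equal(bh_adjust(0.005), 0.005)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.01, 0.04, 0.03, 0.002)
  expect_true(all(bh_adjust(p) >= p))
  # step-up agrees with the reference implementation on tie-free input
  expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  # paper-literal raw formula: no cumulative minimum
  expect_equal(bh_adjust(c(0.01, 0.012), stepup = FALSE),
               c(0.02, 0.012))
  # ties share an average rank
  expect_equal(bh_adjust(c(0.02, 0.02), stepup = FALSE),
               c(0.02 * 2 / 1.5, 0.02 * 2 / 1.5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_length(bh_adjust(numeric(0)), 0L)
})

test_that("DE calls use a strict threshold and deterministic ranks", {
  res <- call_de(c(0.001, 0.004), q_threshold = 0.005)
  # q = p * 2 / rank then step-up: (0.002, 0.004)
  expect_equal(res$table$q, c(0.002, 0.004))
  expect_equal(res$table$de, c(TRUE, TRUE))
  res2 <- call_de(c(0.002, 0.006), q_threshold = 0.005)
  expect_equal(res2$table$q, c(0.004, 0.006))
  expect_equal(res2$table$de, c(TRUE, FALSE))  # strictly less than
  # ties ranked by input position
  res3 <- call_de(c(0.5, 0.1, 0.5), q_threshold = 0.5)
  expect_equal(res3$table$rank, c(2L, 1L, 3L))
  expect_equal(nrow(call_de(numeric(0))$table), 0L)
  expect_error(call_de(0.5, q_threshold = 0), "q_threshold")
})

test_that("de_test tests every gene including those excluded during IMM iteration", {
  d <- simulate_counts(sim_config(n_genes = 600, lib_sizes = 3e5,
                                  prop_de = 0.3, prop_up = 0.9,
                                  prop_unique = 0.1), seed = 21)
  fit <- imm_norm(d$counts, d$truth$design)
  res <- de_test(d$counts, d$truth$design, fit, q_threshold = 1e-4)
  expect_equal(nrow(res$table), 600L)
  expect_true(all(res$table$p >= 0 & res$table$p <= 1))
  expect_identical(res$table$de, res$table$q < 1e-4)
  # genes with zero counts everywhere are never DE
  y <- d$counts$counts
  y[1, ] <- 0
  res0 <- de_test(count_matrix(y), d$truth$design, fit)
  expect_equal(res0$table$p[1], 1)
  expect_false(res0$table$de[1])
})
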