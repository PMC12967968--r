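test_that("group descriptives are exact sample statistics", {
  data <- tibble::tibble(S = c(0.2, 0.4, 0.6, 0.5),
                         group = c("a", "a", "a", "b"))
  out <- describe_groups(data)
  a <- out[out$group == "a", ]
  expect_equal(a$mean, 0.4)
  expect_equal(a$median, 0.4)
  expect_equal(a$min, 0.2)
  expect_equal(a$max, 0.6)
  expect_equal(a$sd, sd(c(0.2, 0.4, 0.6)))
  b <- out[out$group == "b", ]
  expect_equal(b$min, 0.5)
  expect_equal(b$median, 0.5)
  expect_equal(b$max, 0.5)
  expect_true(is.na(b$sd))  # single row: sample sd undefined
  expect_error(describe_groups(tibble::tibble(S = 1)), "group")
})

test_that("Kruskal-Wallis matches the hand value and the library route", {
  out <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(out$H, 32 / 7, tolerance = 1e-12)
  expect_equal(out$df, 2)
  # identical groups: fully interleaved ranks, no effect
  same <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_gt(same$p_value, 0.5)
  expect_equal(same$H, oracle_kruskal(list(c(1, 2, 3), c(1, 2, 3))),
               tolerance = 1e-12)
  # independent library route on tied data
  set.seed(42)
  x <- sample(seq(0, 1, 0.1), 30, replace = TRUE)
  g <- rep(c("a", "b", "c"), each = 10)
  ours <- kruskal_wallis(split(x, g))
  ref <- stats::kruskal.test(x, factor(g))
  expect_equal(ours$H, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  # all values identical across groups: H defined as 0
  expect_equal(kruskal_wallis(list(c(1, 1), c(1, 1)))$H, 0)
})

test_that("Dunn z, raw and adjusted p behave as specified", {
  same <- dunn_posthoc(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$z, 0)
  expect_equal(same$p_adjusted, 1)
  sep <- dunn_posthoc(list(lo = c(1, 2), hi = c(5, 6)))
  # mean ranks 1.5 vs 3.5; z = -2 / sqrt((4*5/12) * (1/2 + 1/2))
  expect_equal(abs(sep$z), 2 / sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(abs(sep$z), abs(oracle_dunn_z(list(c(1, 2), c(5, 6)))),
               tolerance = 1e-12)
  # Bonferroni never decreases p and caps at 1
  set.seed(8)
  g <- random_tied_groups()
  out <- dunn_posthoc(g)
  expect_true(all(out$p_adjusted >= out$p_value - 1e-15))
  expect_true(all(out$p_adjusted <= 1))
  expect_equal(out$p_adjusted, pmin(1, 3 * out$p_value), tolerance = 1e-12)
  # Bonferroni-significant pairs are a subset of raw-significant pairs
  expect_true(all(!(out$p_adjusted < 0.05) | out$p_value < 0.05))
})

test_that("rank statistics agree with the brute-force oracle under ties", {
  set.seed(99)
  for (i in 1:60) {
    g <- random_tied_groups(k = sample(2:4, 1))
    expect_equal(kruskal_wallis(g)$H, oracle_kruskal(g), tolerance = 1e-9)
    expect_equal(dunn_posthoc(g)$z, unname(oracle_dunn_z(g)),
                 tolerance = 1e-9)
  }
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(12)
  g <- list(runif(8), runif(5), runif(7))
  h0 <- kruskal_wallis(g)$H
  expect_equal(kruskal_wallis(lapply(g, exp))$H, h0, tolerance = 1e-12)
  expect_equal(kruskal_wallis(lapply(g, function(x) x^3 + 2))$H, h0,
               tolerance = 1e-12)
})

test_that("Shapiro-Wilk behaves as expected under normal and degenerate input", {
  set.seed(21)
  ok <- replicate(100, {
    x <- rnorm(20)
    unname(shapiro.test(x)$statistic) > 0.9
  })
  expect_gt(mean(ok), 0.9)  # typical W under H0 is high
  const <- tibble::tibble(S = rep(0.5, 10), group = "g")
  expect_error(shapiro_by_group(const), "constant")
  short <- tibble::tibble(S = c(0.1, 0.2), group = "g")
  expect_error(shapiro_by_group(short), "3")
})

test_that("the validation report bundles all panels coherently", {
  co <- simulate_cohort(seed = 4)
  rep <- validate_cohort(co)
  expect_s3_class(rep, "nx_validation")
  expect_equal(nrow(rep$descriptives), 3)
  expect_equal(nrow(rep$normality), 3)
  expect_equal(nrow(rep$posthoc), 3)
  expect_equal(rep$omnibus$df, 2)
  # novice scores are heavily tied at the floor: markedly less normal
  W <- setNames(rep$normality$W, rep$normality$group)
  expect_lt(W[["novice"]], W[["expert"]])
  # tidy/glance follow broom conventions
  expect_identical(tidy(rep), rep$posthoc)
  gl <- glance(rep)
  expect_equal(gl$n, 60)
  expect_equal(gl$H, rep$omnibus$H)
  expect_error(validate_cohort(co[co$group == "novice", ]), "2 groups")
})
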