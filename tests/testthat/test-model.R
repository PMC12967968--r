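test_that("membership functions reproduce hand-evaluated values", {
  p <- nx_params()
  cases <- list(
    # d, s, T, I, F
    list(0, 0, 1, 0, 0),
    list(3.0, 0, 0, 0, 0.75),
    list(0.5, 0.05, (5 / 6) * (5 / 6), (1 / 3) * (1 / 6), 1 / 6),
    list(4.0, 0, 0, 0, 1),
    list(1.5, 0.15, 0.25, 0.5, 0.5),
    list(1.5, 0.30, 0, 1, 1),
    list(3.0, 0.25, 0, 0, 0.8333333333333333)
  )
  for (cs in cases) {
    expect_equal(nx_truth(cs[[1]], cs[[2]], p), cs[[3]], tolerance = 1e-12)
    expect_equal(nx_indeterminacy(cs[[1]], cs[[2]], p), cs[[4]],
                 tolerance = 1e-12)
    expect_equal(nx_falsity(cs[[1]], cs[[2]], p), cs[[5]], tolerance = 1e-12)
  }
  # triangular kernel zeroes outside the ambiguous zone
  expect_equal(nx_indeterminacy(3.0, 0.25, p), 0)
  expect_equal(nx_indeterminacy(0, 0.25, p), 0)
})

test_that("competence score combines the triple and respects its bounds", {
  expect_equal(competence_score(1, 0, 0), 1)
  expect_equal(competence_score(0, 0, 1), 1 / 3)
  expect_equal(competence_score(0, 1, 1), 0)
  expect_error(competence_score(1.2, 0, 0), "\\[0, 1\\]")
  expect_error(competence_score(0.5, -0.1, 0), "\\[0, 1\\]")
})

test_that("nx_evaluate composes the formulas and keeps extra columns", {
  out <- nx_evaluate(tibble::tibble(
    d = c(0, 1.5, 4.0), s = c(0, 0.15, 0), who = c("a", "b", "c")))
  expect_s3_class(out, "tbl_df")
  expect_equal(out$T, c(1, 0.25, 0))
  expect_equal(out$I, c(0, 0.5, 0))
  expect_equal(out$F, c(0, 0.5, 1))
  expect_equal(out$S, c(1, 1.25 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(out$who, c("a", "b", "c"))
  expect_error(nx_evaluate(tibble::tibble(d = -1, s = 0)), "row")
  expect_equal(nx_evaluate(tibble::tibble(d = -1, s = 0),
                           rectify = "truncate")$S, 1)
})

test_that("parameter construction enforces the clinical invariants", {
  expect_error(nx_params(d_max = 0), "d_max")
  expect_error(nx_params(s_max = -0.1), "s_max")
  expect_error(nx_params(d_mid = 4.5), "d_mid")      # d_mid >= d_crit
  expect_error(nx_params(d_mid = 3.5, d_crit = 5), "d_max")  # d_mid > d_max
  expect_error(nx_truth(0.5, Inf, nx_params()), "finite")
  expect_error(nx_truth(-0.5, 0, nx_params()), "non-negative")
  p <- nx_params(d_max = 2, s_max = 0.5, d_crit = 3, d_mid = 1, d_range = 0.5)
  expect_equal(nx_truth(1, 0.25, p), 0.25)
})

test_that("band classification assigns boundary scores upward", {
  b <- nx_bands()
  expect_equal(as.character(classify_band(0.85, b)), "expert")
  expect_equal(as.character(classify_band(0.70, b)), "expert")
  expect_equal(as.character(classify_band(1 / 3, b)), "at-risk")
  expect_equal(as.character(classify_band(c(0, 0.3, 0.5, 1), b)),
               c("unsafe", "at-risk", "indeterminate", "expert"))
  expect_true(is.ordered(classify_band(0.5, b)))
  expect_error(classify_band(1.2, b), "\\[0, 1\\]")
  expect_error(nx_bands(cuts = c(0.5, 0.3)), "increasing")
  expect_error(nx_bands(labels = c("a", "b")), "label")
})

test_that("classical rule passes on distance alone, boundary inclusive", {
  expect_equal(classical_pass(c(1.9, 2.0, 2.01)), c(TRUE, TRUE, FALSE))
  # instability plays no role: same verdicts whatever s would have been
  expect_true(classical_pass(1.9))
  expect_error(classical_pass(1, cutoff = 0), "cutoff")
})

test_that("T, I, F, S stay inside [0,1] over a large random domain", {
  set.seed(101)
  n <- 1e5
  d <- c(runif(n, 0, 12), 0, 3, 4, 1.5, 100)
  s <- c(runif(n + 5, 0, 2))
  p <- nx_params()
  tt <- nx_truth(d, s, p)
  ii <- nx_indeterminacy(d, s, p)
  ff <- nx_falsity(d, s, p)
  ss <- competence_score(tt, ii, ff)
  for (v in list(tt, ii, ff, ss)) {
    expect_true(all(v >= 0 & v <= 1))
  }
  expect_true(all(tt + ii + ff >= 0 & tt + ii + ff <= 3))
  expect_equal(ss, (2 + tt - ii - ff) / 3, tolerance = 1e-9)
})

test_that("S is non-increasing in instability at fixed deviation", {
  p <- nx_params()
  s_axis <- seq(0, 1, by = 0.01)
  for (d0 in c(0, 0.5, 1.5, 2.5, 3.5, 4.5)) {
    S <- nx_evaluate(tibble::tibble(d = d0, s = s_axis), p)$S
    expect_true(all(diff(S) <= 1e-12))
  }
})

test_that("S is non-increasing in deviation up to the mid-risk centre", {
  p <- nx_params()
  d_axis <- seq(0, p$d_mid, by = 0.01)
  for (s0 in c(0, 0.05, 0.15, 0.25, 0.35)) {
    S <- nx_evaluate(tibble::tibble(d = d_axis, s = s0), p)$S
    expect_true(all(diff(S) <= 1e-12))
  }
})

test_that("score saturates exactly at 1/3 beyond the critical deviation", {
  grid <- tidyr::expand_grid(d = seq(4, 10, by = 0.5), s = seq(0, 1, by = 0.1))
  S <- nx_evaluate(grid)$S
  expect_true(all(S == 1 / 3))
})

test_that("a steady-looking but unstable attempt defeats the classical rule", {
  out <- nx_evaluate(tibble::tibble(d = 1.9, s = 0.29))
  expect_true(classical_pass(out$d))
  expect_lt(out$S, 0.5)
  expect_equal(out$T, (1 - 1.9 / 3) * (1 - 0.29 / 0.3), tolerance = 1e-12)
  expect_equal(out$S, (2 + out$T - out$I - out$F) / 3, tolerance = 1e-12)
})
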