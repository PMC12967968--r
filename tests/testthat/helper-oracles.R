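# Independent oracles, deliberately written without reusing any package
# internals: brute-force mid-ranks, a from-scratch Kruskal-Wallis and
# Dunn computation, and a scalar transliteration of the membership
# formulas for grid-vs-scalar equivalence checks.

`%||%` <- function(x, y) if (is.null(x)) y else x

# mid-ranks by explicit sort-and-average (no rank())
oracle_midrank <- function(x) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    smaller <- sum(x < x[i])
    equal <- sum(x == x[i])
    # positions smaller+1 ... smaller+equal share the average rank
    out[i] <- smaller + (equal + 1) / 2
  }
  out
}

oracle_kruskal <- function(groups) {
  k <- length(groups)
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- oracle_midrank(pooled)
  g <- rep.int(seq_len(k), lengths(groups))
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, sum)^2 / lengths(groups)) - 3 * (N + 1)
  ties <- 0
  for (v in unique(pooled)) {
    t <- sum(pooled == v)
    ties <- ties + (t^3 - t)
  }
  C <- 1 - ties / (N^3 - N)
  if (C <= 0) 0 else H / C
}

oracle_dunn_z <- function(groups) {
  k <- length(groups)
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- oracle_midrank(pooled)
  g <- rep.int(seq_len(k), lengths(groups))
  rbar <- tapply(r, g, mean)
  ties <- 0
  for (v in unique(pooled)) {
    t <- sum(pooled == v)
    ties <- ties + (t^3 - t)
  }
  var_core <- N * (N + 1) / 12 - ties / (12 * (N - 1))
  out <- c()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se <- sqrt(var_core * (1 / length(groups[[i]]) + 1 / length(groups[[j]])))
      out <- c(out, if (se == 0) 0 else (rbar[[i]] - rbar[[j]]) / se)
    }
  }
  out
}

# scalar reference evaluation of the neutrosophic model with defaults
# d_max 3, s_max 0.3, d_crit 4, d_mid 1.5, d_range 1.5
oracle_evaluate <- function(d, s) {
  tt <- max(0, 1 - d / 3) * max(0, 1 - s / 0.3)
  ii <- max(0, 1 - abs(d - 1.5) / 1.5) * min(1, s / 0.3)
  ff <- max(min(1, d / 4), min(1, s / 0.3))
  c(T = tt, I = ii, F = ff, S = (2 + tt - ii - ff) / 3)
}

random_tied_groups <- function(k = 3, max_n = 5) {
  lapply(seq_len(k), function(i) {
    n <- sample(2:max_n, 1)
    # coarse grid of values forces plenty of exact ties
    sample(seq(0, 1, by = 0.25), n, replace = TRUE)
  })
}
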