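#' Per-group descriptive statistics of the competence score
#'
#' @param data A data frame with a numeric `S` column and a `group`
#'   column (e.g. the output of [simulate_cohort()]).
#' @return A tibble with one row per group: `n`, `mean`, `sd`, `median`,
#'   `min`, `max` of S. `sd` uses the sample (n - 1) convention and is
#'   `NA` for single-row groups.
#' @export
describe_groups <- function(data) {
  check_cohort(data)
  dplyr::summarise(
    dplyr::group_by(data, group),
    n = dplyr::n(),
    mean = mean(S),
    sd = sd(S),
    median = median(S),
    min = min(S),
    max = max(S),
    .groups = "drop"
  )
}

check_cohort <- function(data, need_group = TRUE) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  if (!"S" %in% names(data)) {
    abort("`data` must contain a competence-score column `S` (run `nx_evaluate()` first).")
  }
  if (need_group && !"group" %in% names(data)) {
    abort("`data` must contain a `group` column.")
  }
  if (need_group && any(table(data$group) < 1L)) {
    abort("every group must contain at least one row.")
  }
  invisible(NULL)
}

# mid-ranks (average ranks for ties), the rank convention used by both
# the Kruskal-Wallis and Dunn statistics
midrank <- function(x) rank(x, ties.method = "average")

tie_sizes <- function(x) {
  tab <- table(x)
  as.numeric(tab[tab > 1L])
}

#' Tie-corrected Kruskal-Wallis omnibus test
#'
#' Rank-based one-way comparison of k groups. With pooled mid-ranks
#' `R_i` summed per group,
#' `H = (12 / (N (N + 1)) * sum(R_i^2 / n_i) - 3 (N + 1)) / C`, where the
#' tie correction is `C = 1 - sum(t^3 - t) / (N^3 - N)` over tie-group
#' sizes `t`. The p-value uses the chi-squared approximation with k - 1
#' degrees of freedom. When every pooled value is identical H is defined
#' as 0 (p = 1).
#'
#' @param groups A list of numeric vectors, one per group (>= 2 groups,
#'   each non-empty). Alternatively a data frame with columns `S` and
#'   `group`.
#' @return A one-row tibble: `H`, `df`, `p_value`.
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))  # H = 32/7
#' @export
kruskal_wallis <- function(groups) {
  groups <- as_group_list(groups)
  k <- length(groups)
  n_i <- lengths(groups)
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- midrank(pooled)
  rank_sums <- vapply(split(r, rep.int(seq_len(k), n_i)), sum, numeric(1))
  H_raw <- 12 / (N * (N + 1)) * sum(rank_sums^2 / n_i) - 3 * (N + 1)
  t <- tie_sizes(pooled)
  C <- 1 - sum(t^3 - t) / (N^3 - N)
  H <- if (C <= 0) 0 else H_raw / C  # C = 0 iff all values identical
  p <- pchisq(H, df = k - 1, lower.tail = FALSE)
  tibble::tibble(H = H, df = k - 1, p_value = p)
}

as_group_list <- function(groups) {
  if (is.data.frame(groups)) {
    check_cohort(groups)
    groups <- split(groups$S, groups$group)
  }
  if (!is.list(groups) || length(groups) < 2L) {
    abort("need at least 2 groups.")
  }
  if (any(lengths(groups) == 0L)) abort("every group must be non-empty.")
  ok <- vapply(groups, function(g) is.numeric(g) && !anyNA(g) &&
                 all(is.finite(g)), logical(1))
  if (!all(ok)) abort("group values must be finite numeric.")
  groups
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Rank-based pairwise z tests following a Kruskal-Wallis omnibus. For
#' groups i, j with pooled mid-rank means `Rbar`,
#' `z = (Rbar_i - Rbar_j) / sqrt((N (N + 1) / 12 - sum(t^3 - t) / (12 (N - 1))) * (1/n_i + 1/n_j))`,
#' with two-sided normal p-values, Bonferroni-adjusted over all
#' m = k (k - 1) / 2 comparisons: `p_adj = min(1, m p)`.
#'
#' @inheritParams kruskal_wallis
#' @param alpha Significance level for the `significant` flag
#'   (default 0.05, applied to the adjusted p).
#' @return A tibble with one row per pair: `comparison`, `z`, `p_value`
#'   (raw), `p_adjusted` (Bonferroni), `significant`.
#' @export
dunn_posthoc <- function(groups, alpha = 0.05) {
  groups <- as_group_list(groups)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  k <- length(groups)
  n_i <- unname(lengths(groups))
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- midrank(pooled)
  rbar <- unname(vapply(split(r, rep.int(seq_len(k), n_i)), mean, numeric(1)))
  t <- tie_sizes(pooled)
  tie_term <- sum(t^3 - t) / (12 * (N - 1))
  var_core <- N * (N + 1) / 12 - tie_term
  m <- k * (k - 1) / 2
  pairs <- utils::combn(k, 2L)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(col) {
    i <- pairs[1L, col]; j <- pairs[2L, col]
    se <- sqrt(var_core * (1 / n_i[i] + 1 / n_i[j]))
    z <- if (se == 0) 0 else (rbar[i] - rbar[j]) / se
    p <- 2 * pnorm(-abs(z))
    tibble::tibble(
      comparison = paste(names(groups)[i], "vs", names(groups)[j]),
      z = z,
      p_value = p,
      p_adjusted = min(1, m * p)
    )
  })
  res$significant <- res$p_adjusted < alpha
  res
}

#' Per-group Shapiro-Wilk normality tests
#'
#' @inheritParams describe_groups
#' @param alpha Significance level for the `normal` verdict.
#' @return A tibble with one row per group: `W`, `p_value`, `normal`.
#'   Groups need 3 to 5000 non-identical values; a constant group is an
#'   error (the test is undefined there).
#' @export
shapiro_by_group <- function(data, alpha = 0.05) {
  check_cohort(data)
  groups <- split(data$S, data$group)
  purrr::imap_dfr(groups, function(x, g) {
    if (length(x) < 3L || length(x) > 5000L) {
      abort("Shapiro-Wilk needs between 3 and 5000 values per group.")
    }
    if (diff(range(x)) == 0) {
      abort(sprintf("group '%s' has constant scores; normality test undefined.", g))
    }
    sw <- shapiro.test(x)
    tibble::tibble(group = g, W = unname(sw$statistic), p_value = sw$p.value)
  }) |>
    dplyr::mutate(normal = p_value >= alpha)
}

#' Full nonparametric validation of a scored cohort
#'
#' Reproduces the standard assessment pipeline on any evaluated cohort:
#' per-group descriptives of S, per-group Shapiro-Wilk normality, a
#' tie-corrected Kruskal-Wallis omnibus test, and Dunn's post-hoc
#' pairwise comparisons with Bonferroni correction. The nonparametric
#' branch is always run and reported; the normality panel records
#' whether the parametric assumption would have held.
#'
#' @inheritParams describe_groups
#' @param alpha Significance level (default 0.05) used for every
#'   verdict column.
#' @return An object of class `nx_validation`: a list with tibbles
#'   `descriptives`, `normality`, `omnibus`, `posthoc`, plus `alpha` and
#'   `normality_violated` (TRUE if any group rejects normality).
#' @examples
#' cohort <- simulate_cohort(seed = 7)
#' rep <- validate_cohort(cohort)
#' glance(rep)
#' @export
validate_cohort <- function(data, alpha = 0.05) {
  check_cohort(data)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single number in (0, 1).")
  }
  if (length(unique(data$group)) < 2L) {
    abort("validation needs at least 2 groups.")
  }
  groups <- split(data$S, data$group)
  normality <- shapiro_by_group(data, alpha = alpha)
  omnibus <- kruskal_wallis(groups)
  structure(list(
    descriptives = describe_groups(data),
    normality = normality,
    omnibus = omnibus,
    posthoc = dunn_posthoc(groups, alpha = alpha),
    alpha = alpha,
    normality_violated = any(!normality$normal)
  ), class = "nx_validation")
}

#' @export
print.nx_validation <- function(x, ...) {
  cat("Neutrosophic cohort validation (alpha =", x$alpha, ")\n\n")
  cat("Descriptive statistics of S by group:\n")
  print(x$descriptives)
  cat("\nShapiro-Wilk normality:\n")
  print(x$normality)
  cat(sprintf("\nKruskal-Wallis omnibus: H = %.4f, df = %d, p = %.3g\n",
              x$omnibus$H, x$omnibus$df, x$omnibus$p_value))
  cat("\nDunn post-hoc (Bonferroni):\n")
  print(x$posthoc)
  invisible(x)
}

#' Tidy a cohort validation report
#'
#' Returns the pairwise Dunn comparisons as a tibble (one row per
#' comparison), the component of the report with per-term structure.
#'
#' @param x An `nx_validation` object.
#' @param ... Unused.
#' @return A tibble: `comparison`, `z`, `p_value`, `p_adjusted`,
#'   `significant`.
#' @export
tidy.nx_validation <- function(x, ...) {
  x$posthoc
}

#' One-row summary of a cohort validation report
#'
#' @param x An `nx_validation` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_groups`, `n`, `H`, `df`, `p_value`,
#'   `normality_violated`, `n_significant_pairs`, `alpha`.
#' @export
glance.nx_validation <- function(x, ...) {
  tibble::tibble(
    n_groups = nrow(x$descriptives),
    n = sum(x$descriptives$n),
    H = x$omnibus$H,
    df = x$omnibus$df,
    p_value = x$omnibus$p_value,
    normality_violated = x$normality_violated,
    n_significant_pairs = sum(x$posthoc$significant),
    alpha = x$alpha
  )
}
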