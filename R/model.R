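#' Model parameters for the neutrosophic competence model
#'
#' The five clinical constants that shape the three membership functions.
#' Defaults follow commonly reported accuracy constraints in stereotactic
#' neurosurgery (deep brain stimulation in particular): deviations within
#' roughly 2 mm are generally acceptable, ~3 mm is the upper bound of
#' accepted targeting error, and ~4 mm marks clearly unsafe placement.
#'
#' @param d_max Distance normaliser of the Truth function (mm). Truth's
#'   distance factor decays linearly from 1 at `d = 0` to 0 at `d = d_max`.
#'   Default 3.0.
#' @param s_max Upper accepted limit of motor instability (model units),
#'   used to normalise instability in all three membership functions.
#'   Default 0.30.
#' @param d_crit Deviation marking unacceptable placement (mm); the
#'   Falsity distance component saturates at 1 there. Default 4.0.
#' @param d_mid Centre of the mid-risk (ambiguous) deviation zone (mm);
#'   the Indeterminacy kernel peaks there. Default 1.5.
#' @param d_range Half-width of the ambiguous zone (mm); the kernel
#'   reaches zero at `d_mid +/- d_range`. Default 1.5.
#'
#' @details
#' All five values must be strictly positive and `d_mid < d_crit`,
#' `d_mid <= d_max`. The instability scale is deliberately treated as a
#' dimensionless "model unit": every formula uses only the ratio
#' `s / s_max`, so any consistent unit for `s` and `s_max` works.
#'
#' @return An object of class `nx_params` (a named list).
#' @seealso [nx_evaluate()], [nx_truth()]
#' @examples
#' p <- nx_params()
#' nx_truth(0.5, 0.05, p)
#' @export
nx_params <- function(d_max = 3.0, s_max = 0.30, d_crit = 4.0,
                      d_mid = 1.5, d_range = 1.5) {
  vals <- list(d_max = d_max, s_max = s_max, d_crit = d_crit,
               d_mid = d_mid, d_range = d_range)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort(sprintf("`%s` must be a single finite number > 0 (got %s).",
                    nm, format(v)))
    }
  }
  if (vals$d_mid >= vals$d_crit) {
    abort("`d_mid` must be strictly less than `d_crit`.")
  }
  if (vals$d_mid > vals$d_max) {
    abort("`d_mid` must not exceed `d_max`.")
  }
  structure(vals, class = "nx_params")
}

#' @export
print.nx_params <- function(x, ...) {
  cat("Neutrosophic model parameters\n")
  cat(sprintf("  d_max   %.4g mm (Truth distance normaliser)\n", x$d_max))
  cat(sprintf("  s_max   %.4g    (instability normaliser)\n", x$s_max))
  cat(sprintf("  d_crit  %.4g mm (unsafe deviation threshold)\n", x$d_crit))
  cat(sprintf("  d_mid   %.4g mm (mid-risk centre)\n", x$d_mid))
  cat(sprintf("  d_range %.4g mm (ambiguous-zone half-width)\n", x$d_range))
  invisible(x)
}

check_ds <- function(d, s) {
  if (!is.numeric(d) || !is.numeric(s)) {
    abort("`d` and `s` must be numeric.")
  }
  if (anyNA(d) || anyNA(s) || any(!is.finite(d)) || any(!is.finite(s))) {
    abort("`d` and `s` must be finite and non-missing.")
  }
  if (any(d < 0) || any(s < 0)) {
    abort("`d` and `s` must be non-negative; rectify raw draws first (see `rectify()`).")
  }
  if (length(d) != length(s) && length(d) != 1L && length(s) != 1L) {
    abort("`d` and `s` must have equal length (or length 1).")
  }
  invisible(NULL)
}

check_params <- function(p) {
  if (!inherits(p, "nx_params")) {
    abort("`params` must be created with `nx_params()`.")
  }
  invisible(NULL)
}

#' Neutrosophic membership functions
#'
#' Truth, Indeterminacy and Falsity memberships of one or more attempts,
#' each a function of spatial deviation `d` (mm) and motor instability `s`
#' (model units). All three are vectorised over `d` and `s` and return
#' values in \[0, 1\].
#'
#' * **Truth** (competent performance):
#'   `T = max(0, 1 - d/d_max) * max(0, 1 - s/s_max)` — the product of two
#'   rectified linear decays; zero once either variable reaches its
#'   normaliser.
#' * **Falsity** (unsafe performance):
#'   `F = max(min(1, d/d_crit), min(1, s/s_max))` — a safety-critical
#'   worst case of the two capped linear components; 1 whenever
#'   `d >= d_crit` or `s >= s_max`.
#' * **Indeterminacy** (borderline performance):
#'   `I = max(0, 1 - |d - d_mid|/d_range) * min(1, s/s_max)` — a
#'   triangular kernel centred at the mid-risk deviation, scaled by
#'   normalised instability; zero for steady hands or deviations outside
#'   the ambiguous zone.
#'
#' @param d Spatial deviation(s) in mm, finite and `>= 0`.
#' @param s Motor instability value(s), finite and `>= 0`.
#' @param params An [nx_params()] object.
#' @return A numeric vector in \[0, 1\].
#' @examples
#' p <- nx_params()
#' nx_truth(c(0, 0.5, 3), c(0, 0.05, 0), p)
#' nx_falsity(1.5, 0.15, p)
#' nx_indeterminacy(1.5, 0.15, p)
#' @export
nx_truth <- function(d, s, params = nx_params()) {
  check_params(params)
  check_ds(d, s)
  pmax(0, 1 - d / params$d_max) * pmax(0, 1 - s / params$s_max)
}

#' @rdname nx_truth
#' @export
nx_falsity <- function(d, s, params = nx_params()) {
  check_params(params)
  check_ds(d, s)
  pmax(pmin(1, d / params$d_crit), pmin(1, s / params$s_max))
}

#' @rdname nx_truth
#' @export
nx_indeterminacy <- function(d, s, params = nx_params()) {
  check_params(params)
  check_ds(d, s)
  pmax(0, 1 - abs(d - params$d_mid) / params$d_range) *
    pmin(1, s / params$s_max)
}

#' Neutrosophic competence score
#'
#' Collapses a single-valued neutrosophic triple into one bounded score,
#' `S = (2 + T - I - F) / 3`. S is strictly increasing in Truth and
#' strictly decreasing in Indeterminacy and Falsity: active error and
#' unresolved uncertainty are penalised alike. With each component in
#' \[0, 1\], S lies in \[0, 1\]; the fully saturated error state
#' (T = 0, I = 0, F = 1) gives the floor value 1/3 typical of large
#' deviations.
#'
#' @param truth,indeterminacy,falsity Membership values in \[0, 1\]
#'   (vectorised).
#' @return Numeric vector of scores in \[0, 1\].
#' @examples
#' competence_score(1, 0, 0)    # 1, perfect
#' competence_score(0, 0, 1)    # 1/3, the saturation floor
#' @export
competence_score <- function(truth, indeterminacy, falsity) {
  for (nm in c("truth", "indeterminacy", "falsity")) {
    v <- get(nm)
    if (!is.numeric(v) || anyNA(v) || any(v < 0 | v > 1)) {
      abort(sprintf("`%s` must be numeric in [0, 1].", nm))
    }
  }
  (2 + truth - indeterminacy - falsity) / 3
}

#' Evaluate attempts under the neutrosophic model
#'
#' The core scoring verb: takes a data frame with columns `d` (deviation,
#' mm) and `s` (instability) — one row per attempt — and returns a tibble
#' with the membership columns `T`, `I`, `F` and the competence score `S`
#' appended. Any other columns (e.g. `group`) are preserved, as is row
#' order.
#'
#' @param data A data frame with numeric columns `d` and `s`.
#' @param params An [nx_params()] object.
#' @param rectify One of `"none"` (default: negative inputs are an
#'   error), `"truncate"` or `"absolute"` — how to coerce negative raw
#'   values to the non-negative domain before scoring (see [rectify()]).
#' @return A tibble: the input columns plus `T`, `I`, `F`, `S`.
#' @examples
#' attempts <- tibble::tibble(d = c(0, 1.5, 4), s = c(0, 0.15, 0))
#' nx_evaluate(attempts)
#' @export
nx_evaluate <- function(data, params = nx_params(),
                        rectify = c("none", "truncate", "absolute")) {
  rectify <- match.arg(rectify)
  check_params(params)
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  missing_cols <- setdiff(c("d", "s"), names(data))
  if (length(missing_cols)) {
    abort(paste0("`data` must contain column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  out <- tibble::as_tibble(data)
  if (rectify != "none") {
    out$d <- rectify(out$d, mode = rectify)
    out$s <- rectify(out$s, mode = rectify)
  }
  bad <- which(!is.finite(out$d) | !is.finite(out$s) | out$d < 0 | out$s < 0)
  if (length(bad)) {
    abort(sprintf(
      "Non-finite or negative (d, s) at row(s) %s; pass `rectify = \"truncate\"` or \"absolute\" to coerce negatives.",
      paste(utils::head(bad, 5L), collapse = ", ")))
  }
  tv <- nx_truth(out$d, out$s, params)
  iv <- nx_indeterminacy(out$d, out$s, params)
  fv <- nx_falsity(out$d, out$s, params)
  out$T <- tv
  out$I <- iv
  out$F <- fv
  out$S <- competence_score(tv, iv, fv)
  out
}

#' Competence bands on the score scale
#'
#' Ordered cut points on S and the labels of the intervals they delimit.
#' Defaults place cuts at S = 0.3, 0.5 and 0.7, the contour levels that
#' separate unsafe, at-risk, indeterminate and expert regions of the
#' competence landscape.
#'
#' @param cuts Strictly increasing cut points, each in (0, 1).
#' @param labels One label per interval (`length(cuts) + 1` of them),
#'   ordered from lowest to highest band.
#' @return An object of class `nx_bands`.
#' @examples
#' b <- nx_bands()
#' classify_band(c(0.1, 1/3, 0.6, 0.85), b)
#' @export
nx_bands <- function(cuts = c(0.3, 0.5, 0.7),
                     labels = c("unsafe", "at-risk", "indeterminate", "expert")) {
  if (!is.numeric(cuts) || length(cuts) < 1L || anyNA(cuts) ||
      any(cuts <= 0) || any(cuts >= 1)) {
    abort("`cuts` must be numeric, each strictly inside (0, 1).")
  }
  if (is.unsorted(cuts, strictly = TRUE)) {
    abort("`cuts` must be strictly increasing.")
  }
  labels <- as.character(labels)
  if (length(labels) != length(cuts) + 1L || anyDuplicated(labels)) {
    abort("`labels` must supply one distinct label per interval (length(cuts) + 1).")
  }
  structure(list(cuts = as.numeric(cuts), labels = labels),
            class = "nx_bands")
}

#' @export
print.nx_bands <- function(x, ...) {
  edges <- c(0, x$cuts, 1)
  cat("Competence bands on S:\n")
  for (i in seq_along(x$labels)) {
    close_right <- if (i == length(x$labels)) "]" else ")"
    cat(sprintf("  [%g, %g%s  %s\n", edges[i], edges[i + 1L],
                close_right, x$labels[i]))
  }
  invisible(x)
}

#' Classify competence scores into bands
#'
#' Assigns each score the label of the half-open interval containing it.
#' Intervals are left-closed, right-open (a score exactly on a cut point
#' is assigned upward), except the top interval which is closed at 1.
#'
#' @param S Numeric score(s) in \[0, 1\].
#' @param bands An [nx_bands()] object.
#' @return A factor with the band labels as ordered levels.
#' @export
classify_band <- function(S, bands = nx_bands()) {
  if (!inherits(bands, "nx_bands")) abort("`bands` must come from `nx_bands()`.")
  if (!is.numeric(S) || anyNA(S) || any(S < 0 | S > 1)) {
    abort("`S` must be numeric in [0, 1].")
  }
  idx <- findInterval(S, c(0, bands$cuts, 1), rightmost.closed = TRUE)
  factor(bands$labels[idx], levels = bands$labels, ordered = TRUE)
}

#' Classical distance-threshold verdict
#'
#' The conventional geometric pass/fail rule: an attempt passes iff its
#' deviation satisfies `d <= cutoff` (default 2 mm). Instability is
#' ignored entirely — which is exactly the blind spot the neutrosophic
#' score is designed to expose (see [discordance_table()]).
#'
#' @param d Deviation(s) in mm, finite and `>= 0`.
#' @param cutoff Positive pass threshold in mm (default 2).
#' @return Logical vector: `TRUE` for pass.
#' @examples
#' classical_pass(c(1.9, 2, 2.01))
#' @export
classical_pass <- function(d, cutoff = 2.0) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L ||
      !is.finite(cutoff) || cutoff <= 0) {
    abort("`cutoff` must be a single finite number > 0.")
  }
  if (!is.numeric(d) || anyNA(d) || any(!is.finite(d)) || any(d < 0)) {
    abort("`d` must be finite and non-negative.")
  }
  d <= cutoff
}
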