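#' Regular evaluation grid over the deviation-instability plane
#'
#' Defaults cover the full operating range of the model: deviations
#' 0-5 mm (all class priors plus the saturation region beyond d_crit)
#' and instabilities 0-0.35 (past the s_max normaliser).
#'
#' @param d_min,d_max,d_step Deviation axis (mm).
#' @param s_min,s_max,s_step Instability axis.
#' @return An object of class `nx_grid` with axis vectors `d` and `s`.
#' @export
grid_spec <- function(d_min = 0, d_max = 5, d_step = 0.02,
                      s_min = 0, s_max = 0.35, s_step = 0.005) {
  for (ax in list(c(d_min, d_max, d_step), c(s_min, s_max, s_step))) {
    if (anyNA(ax) || any(!is.finite(ax))) abort("grid bounds must be finite.")
    if (ax[1] >= ax[2]) abort("grid min must be below max.")
    if (ax[3] <= 0) abort("grid step must be positive.")
  }
  g <- structure(list(d = seq(d_min, d_max, by = d_step),
                      s = seq(s_min, s_max, by = s_step)),
                 class = "nx_grid")
  if (length(g$d) < 2L || length(g$s) < 2L) {
    abort("grid needs at least 2 points per axis.")
  }
  if (any(g$d < 0) || any(g$s < 0)) abort("grid axes must be non-negative.")
  g
}

#' Membership-function profiles along deviation
#'
#' Evaluates Truth, Indeterminacy and Falsity along a deviation axis at
#' fixed instability levels — the curves that show how the three
#' memberships trade off as the tip drifts from the target. The default
#' levels s = 0.05, 0.15, 0.25 span steady, moderate and high
#' instability.
#'
#' @param s_levels Instability levels (each `>= 0`).
#' @param d_axis Deviation axis (mm), at least 2 non-negative points.
#' @param params An [nx_params()] object.
#' @return A long tibble: `s_level`, `d`, `membership`
#'   (`"T"`/`"I"`/`"F"`), `value`.
#' @export
membership_profiles <- function(s_levels = c(0.05, 0.15, 0.25),
                                d_axis = seq(0, 5, by = 0.02),
                                params = nx_params()) {
  check_params(params)
  if (!is.numeric(d_axis) || length(d_axis) < 2L || anyNA(d_axis) ||
      any(!is.finite(d_axis)) || any(d_axis < 0)) {
    abort("`d_axis` must be >= 2 finite non-negative values.")
  }
  if (!is.numeric(s_levels) || length(s_levels) < 1L || anyNA(s_levels) ||
      any(!is.finite(s_levels)) || any(s_levels < 0)) {
    abort("`s_levels` must be finite non-negative values.")
  }
  purrr::map_dfr(s_levels, function(s0) {
    tibble::tibble(
      s_level = s0,
      d = d_axis,
      T = nx_truth(d_axis, s0, params),
      I = nx_indeterminacy(d_axis, s0, params),
      F = nx_falsity(d_axis, s0, params)
    )
  }) |>
    tidyr::pivot_longer(cols = c("T", "I", "F"), names_to = "membership",
                        values_to = "value") |>
    dplyr::mutate(membership = factor(membership, levels = c("T", "I", "F")))
}

#' Competence surface over a deviation-instability grid
#'
#' Evaluates the full neutrosophic bundle at every grid node, cell by
#' cell identical to scalar evaluation. The result is a long tibble
#' (one row per node) carrying the grid and parameters as attributes;
#' use [surface_matrix()] to extract any quantity as a d-by-s matrix.
#'
#' @param grid An [grid_spec()] object.
#' @param params An [nx_params()] object.
#' @param bands An [nx_bands()] object used to label each node.
#' @return A tibble of class `nx_surface`: `d`, `s`, `T`, `I`, `F`,
#'   `S`, `band`.
#' @examples
#' surf <- competence_surface(grid_spec(d_step = 0.25, s_step = 0.05))
#' surface_matrix(surf, "S")[1, 1]  # S(0, 0) = 1
#' @export
competence_surface <- function(grid = grid_spec(), params = nx_params(),
                               bands = nx_bands()) {
  if (!inherits(grid, "nx_grid")) abort("`grid` must come from `grid_spec()`.")
  check_params(params)
  nodes <- tidyr::expand_grid(d = grid$d, s = grid$s)
  out <- nx_evaluate(nodes, params)
  out$band <- classify_band(out$S, bands)
  class(out) <- c("nx_surface", class(out))
  attr(out, "grid") <- grid
  attr(out, "params") <- params
  attr(out, "bands") <- bands
  out
}

#' Extract one surface quantity as a matrix
#'
#' @param surface An [competence_surface()] result.
#' @param what One of `"T"`, `"I"`, `"F"`, `"S"`, `"band"`.
#' @return A matrix with one row per deviation value and one column per
#'   instability value (dimnames carry the axis values); `"band"` gives
#'   a character matrix.
#' @export
surface_matrix <- function(surface, what = "S") {
  if (!inherits(surface, "nx_surface")) {
    abort("`surface` must come from `competence_surface()`.")
  }
  what <- match.arg(what, c("T", "I", "F", "S", "band"))
  grid <- attr(surface, "grid")
  v <- surface[[what]]
  if (what == "band") v <- as.character(v)
  matrix(v, nrow = length(grid$d), ncol = length(grid$s), byrow = TRUE,
         dimnames = list(as.character(grid$d), as.character(grid$s)))
}

#' Decision regions in the deviation-instability plane
#'
#' Classifies every node of the competence surface into its band — the
#' crisp region map showing how competence is determined by deviation
#' and instability jointly.
#'
#' @inheritParams competence_surface
#' @return A tibble: `d`, `s`, `S`, `band`.
#' @export
decision_regions <- function(grid = grid_spec(), params = nx_params(),
                             bands = nx_bands()) {
  surf <- competence_surface(grid, params, bands)
  dplyr::select(tibble::as_tibble(surf), d, s, S, band)
}

#' Super-level-set masks at the band contour levels
#'
#' For each requested level c returns the mask of grid nodes with
#' `S >= c`. Levels are on the score scale, so the sets are nested:
#' a higher level's set is contained in every lower level's set.
#'
#' @param surface An [competence_surface()] result.
#' @param levels Contour levels (default: the surface's band cuts).
#' @return A named list of logical matrices (d by s), one per level.
#' @export
contour_masks <- function(surface, levels = NULL) {
  if (!inherits(surface, "nx_surface")) {
    abort("`surface` must come from `competence_surface()`.")
  }
  levels <- levels %||% attr(surface, "bands")$cuts
  Smat <- surface_matrix(surface, "S")
  out <- lapply(levels, function(cv) Smat >= cv)
  names(out) <- format(levels, trim = TRUE)
  out
}

#' Classical-vs-neutrosophic discordance audit
#'
#' Flags the false positives of the classical distance rule: attempts
#' that pass `d <= cutoff` while the neutrosophic score places them
#' below the top competence band. These are exactly the cases — low
#' deviation achieved with an unsteady hand — that a purely geometric
#' criterion cannot see.
#'
#' @param data An evaluated cohort (columns `d`, `s`, `S`; `group` kept
#'   if present).
#' @param cutoff Classical pass threshold in mm (default 2).
#' @param bands An [nx_bands()] object.
#' @return The input tibble plus `classical` (`"pass"`/`"fail"`),
#'   `band`, and `discordant` (`TRUE` for classical passes below the
#'   top band).
#' @examples
#' shaky <- tibble::tibble(d = 1.9, s = 0.29)
#' discordance_table(nx_evaluate(shaky))
#' @export
discordance_table <- function(data, cutoff = 2.0, bands = nx_bands()) {
  check_cohort(data, need_group = FALSE)
  if (!all(c("d", "s") %in% names(data))) {
    abort("`data` must contain `d` and `s` columns.")
  }
  out <- tibble::as_tibble(data)
  pass <- classical_pass(out$d, cutoff)
  out$classical <- ifelse(pass, "pass", "fail")
  out$band <- classify_band(out$S, bands)
  top_band <- bands$labels[length(bands$labels)]
  out$discordant <- pass & out$band != top_band
  out
}
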