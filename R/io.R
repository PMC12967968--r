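#' Read a table of attempts from CSV
#'
#' Expects columns `d`, `s` and optionally `group`; extra columns are
#' preserved. Malformed or non-numeric rows are reported with their row
#' numbers.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_attempts <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  # base reader: strtod parsing round-trips %.17g doubles exactly
  out <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  missing_cols <- setdiff(c("d", "s"), names(out))
  if (length(missing_cols)) {
    abort(sprintf("%s: missing column(s) %s.", path,
                  paste(missing_cols, collapse = ", ")))
  }
  for (col in c("d", "s")) {
    vals <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(vals) | !is.finite(vals))
    if (length(bad)) {
      abort(sprintf("%s: non-numeric or missing `%s` at data row(s) %s.",
                    path, col, paste(utils::head(bad, 5L), collapse = ", ")))
    }
    out[[col]] <- vals
  }
  out
}

#' Write an evaluated cohort to CSV (with provenance sidecar)
#'
#' Columns are ordered `d, s, T, I, F, S, group`; values are serialised
#' at full precision so that write-then-read round-trips exactly. When
#' the cohort carries provenance attributes (seed, parameters, group
#' specs) a YAML sidecar `<path>.meta.yaml` records them.
#'
#' @param data An evaluated cohort tibble.
#' @param path Output CSV path.
#' @param sidecar Write the metadata sidecar (default TRUE when
#'   provenance is present).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path, sidecar = TRUE) {
  check_cohort(data, need_group = FALSE)
  lead <- intersect(c("d", "s", "T", "I", "F", "S", "group"), names(data))
  data <- dplyr::relocate(tibble::as_tibble(data), dplyr::all_of(lead))
  # %.17g guarantees an exact double round-trip through the text file
  printable <- dplyr::mutate(data, dplyr::across(
    dplyr::where(is.double), ~ sprintf("%.17g", .x)))
  readr::write_csv(printable, path)
  seed <- attr(data, "seed")
  if (isTRUE(sidecar) && !is.null(seed)) {
    params <- attr(data, "params")
    specs <- attr(data, "specs")
    meta <- list(
      seed = seed,
      rectify_mode = attr(data, "rectify_mode"),
      params = unclass(params),
      groups = lapply(unname(specs), unclass)
    )
    yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  }
  invisible(path)
}

#' Read an evaluated cohort back from CSV
#'
#' @param path CSV path written by [write_cohort()].
#' @return A tibble.
#' @export
read_cohort <- function(path) {
  out <- read_attempts(path)
  check_cohort(out, need_group = FALSE)
  out
}

#' Run configuration for the end-to-end pipeline
#'
#' Bundles everything a full run needs: model parameters, group specs,
#' seed, band thresholds, classical cutoff, grid, alpha. Any component
#' omitted falls back to its default.
#'
#' @param params An [nx_params()] object.
#' @param specs List of [group_spec()] objects.
#' @param seed Integer seed.
#' @param bands An [nx_bands()] object.
#' @param classical_cutoff Classical pass threshold (mm).
#' @param grid An [grid_spec()] object.
#' @param alpha Significance level.
#' @param rectify_mode `"truncate"` or `"absolute"`.
#' @return An object of class `nx_config`.
#' @export
run_config <- function(params = nx_params(), specs = default_group_specs(),
                       seed = 1L, bands = nx_bands(),
                       classical_cutoff = 2.0, grid = grid_spec(),
                       alpha = 0.05,
                       rectify_mode = c("truncate", "absolute")) {
  rectify_mode <- match.arg(rectify_mode)
  check_params(params)
  if (!inherits(bands, "nx_bands")) abort("`bands` must come from `nx_bands()`.")
  if (!inherits(grid, "nx_grid")) abort("`grid` must come from `grid_spec()`.")
  if (!all(vapply(specs, inherits, logical(1), "nx_group_spec"))) {
    abort("`specs` must be a list of `group_spec()` objects.")
  }
  if (classical_cutoff <= 0) abort("`classical_cutoff` must be > 0.")
  structure(list(params = params, specs = specs, seed = as.integer(seed),
                 bands = bands, classical_cutoff = classical_cutoff,
                 grid = grid, alpha = alpha, rectify_mode = rectify_mode),
            class = "nx_config")
}

#' Read a run configuration from a YAML file
#'
#' A flat structured-text config. Recognised keys (all optional):
#' `d_max`, `s_max`, `d_crit`, `d_mid`, `d_range`; `band_cuts`,
#' `band_labels`; `classical_cutoff`; `seed`; `alpha`; `rectify_mode`;
#' `n_per_group`; `grid: {d_min, d_max, d_step, s_min, s_max, s_step}`;
#' `groups:` a list of `{label, n, mu_d, sigma_d, mu_s, sigma_s}`
#' entries (replacing the three defaults).
#'
#' @param path YAML file path.
#' @return An `nx_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config not found: %s", path))
  raw <- yaml::read_yaml(path)
  pargs <- raw[intersect(c("d_max", "s_max", "d_crit", "d_mid", "d_range"),
                         names(raw))]
  params <- do.call(nx_params, pargs)
  bands <- nx_bands(
    cuts = raw$band_cuts %||% c(0.3, 0.5, 0.7),
    labels = raw$band_labels %||%
      c("unsafe", "at-risk", "indeterminate", "expert")
  )
  specs <- if (!is.null(raw$groups)) {
    lapply(raw$groups, function(g) do.call(group_spec, g))
  } else {
    default_group_specs(n_per_group = raw$n_per_group %||% 20L)
  }
  grid <- if (!is.null(raw$grid)) do.call(grid_spec, raw$grid) else grid_spec()
  run_config(
    params = params, specs = specs, seed = raw$seed %||% 1L,
    bands = bands, classical_cutoff = raw$classical_cutoff %||% 2.0,
    grid = grid, alpha = raw$alpha %||% 0.05,
    rectify_mode = raw$rectify_mode %||% "truncate"
  )
}
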