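#' Specification of one simulated performance class
#'
#' A class is defined by independent Gaussian priors on deviation and
#' instability: `d ~ N(mu_d, sigma_d)`, `s ~ N(mu_s, sigma_s)` (sigma is
#' a standard deviation), plus a label and a group size.
#'
#' @param label Group label (character scalar).
#' @param n Number of attempts to draw (>= 1).
#' @param mu_d,sigma_d Mean and SD of the deviation prior (mm);
#'   `sigma_d >= 0`.
#' @param mu_s,sigma_s Mean and SD of the instability prior;
#'   `sigma_s >= 0`.
#' @return An object of class `nx_group_spec`.
#' @seealso [default_group_specs()] for the three canonical classes.
#' @export
group_spec <- function(label, n, mu_d, sigma_d, mu_s, sigma_s) {
  if (!is.character(label) || length(label) != 1L || is.na(label) ||
      !nzchar(label)) {
    abort("`label` must be a non-empty string.")
  }
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 ||
      n != round(n)) {
    abort("`n` must be a whole number >= 1.")
  }
  for (nm in c("mu_d", "mu_s")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort(sprintf("`%s` must be a single finite number.", nm))
    }
  }
  for (nm in c("sigma_d", "sigma_s")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      abort(sprintf("`%s` must be a single finite number >= 0.", nm))
    }
  }
  structure(list(label = label, n = as.integer(n),
                 mu_d = mu_d, sigma_d = sigma_d,
                 mu_s = mu_s, sigma_s = sigma_s),
            class = "nx_group_spec")
}

#' The three canonical performance classes
#'
#' Gaussian priors for the expert, indeterminate and novice profiles of
#' the simulated stereotactic cohort, 20 attempts each:
#' experts `d ~ N(0.5, 0.20)`, `s ~ N(0.05, 0.01)`; indeterminate
#' `d ~ N(2.0, 0.30)`, `s ~ N(0.15, 0.05)`; novices `d ~ N(4.0, 0.50)`,
#' `s ~ N(0.25, 0.07)`.
#'
#' @param n_per_group Attempts per class (default 20).
#' @return A named list of three [group_spec()] objects.
#' @export
default_group_specs <- function(n_per_group = 20L) {
  list(
    expert = group_spec("expert", n_per_group, 0.5, 0.20, 0.05, 0.01),
    indeterminate = group_spec("indeterminate", n_per_group, 2.0, 0.30, 0.15, 0.05),
    novice = group_spec("novice", n_per_group, 4.0, 0.50, 0.25, 0.07)
  )
}

#' Rectify raw Gaussian draws onto the non-negative domain
#'
#' Deviation and instability are physically non-negative, so raw
#' Gaussian draws must be rectified. Two conventions are supported:
#' `"truncate"` (default) clamps at zero, `max(0, x)`; `"absolute"`
#' reflects, `|x|`. With the default class priors negative draws are
#' rare, so the two modes give nearly identical cohorts.
#'
#' @param x Finite numeric vector.
#' @param mode `"truncate"` or `"absolute"`.
#' @return Non-negative numeric vector.
#' @examples
#' rectify(c(-0.3, 0.7))                     # 0.0 0.7
#' rectify(c(-0.3, 0.7), mode = "absolute")  # 0.3 0.7
#' @export
rectify <- function(x, mode = c("truncate", "absolute")) {
  mode <- match.arg(mode)
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort("`x` must be finite numeric.")
  }
  switch(mode, truncate = pmax(0, x), absolute = abs(x))
}

#' Draw performance vectors for one class
#'
#' Samples `n` independent `(d, s)` pairs from the class priors and
#' rectifies them to the non-negative domain. Deterministic for a fixed
#' seed.
#'
#' @param spec A [group_spec()].
#' @param seed Optional integer seed (applied via a local RNG state when
#'   supplied).
#' @param rectify_mode Passed to [rectify()].
#' @return A tibble with columns `d`, `s`, `group`.
#' @export
sample_group <- function(spec, seed = NULL,
                         rectify_mode = c("truncate", "absolute")) {
  rectify_mode <- match.arg(rectify_mode)
  if (!inherits(spec, "nx_group_spec")) {
    abort("`spec` must come from `group_spec()`.")
  }
  draw <- function() {
    tibble::tibble(
      d = rectify(rnorm(spec$n, spec$mu_d, spec$sigma_d), rectify_mode),
      s = rectify(rnorm(spec$n, spec$mu_s, spec$sigma_s), rectify_mode),
      group = spec$label
    )
  }
  if (is.null(seed)) draw() else withr_seed(seed, draw())
}

# evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != round(seed)) {
    abort("`seed` must be a single whole number.")
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulate and score a multi-class cohort
#'
#' Runs the full generative pipeline: draw `(d, s)` for every class,
#' rectify, evaluate the three membership functions and the competence
#' score, and assemble everything into one structured table. Identical
#' `(specs, params, seed, rectify_mode)` give byte-identical output.
#'
#' @param specs A list of [group_spec()] objects (default: the three
#'   canonical classes of [default_group_specs()]).
#' @param params An [nx_params()] object.
#' @param seed Integer seed for reproducibility (default 1).
#' @param rectify_mode Passed to [rectify()].
#' @return A tibble with columns `d`, `s`, `T`, `I`, `F`, `S`, `group`
#'   (one row per attempt, grouped rows in spec order) carrying the
#'   provenance attributes `seed`, `params`, `specs` and `rectify_mode`.
#' @examples
#' cohort <- simulate_cohort(seed = 42)
#' dplyr::count(cohort, group)
#' @export
simulate_cohort <- function(specs = default_group_specs(),
                            params = nx_params(), seed = 1L,
                            rectify_mode = c("truncate", "absolute")) {
  rectify_mode <- match.arg(rectify_mode)
  check_params(params)
  if (inherits(specs, "nx_group_spec")) specs <- list(specs)
  if (!is.list(specs) || length(specs) == 0L ||
      !all(vapply(specs, inherits, logical(1), "nx_group_spec"))) {
    abort("`specs` must be a non-empty list of `group_spec()` objects.")
  }
  raw <- withr_seed(seed, purrr::map(specs, function(sp) {
    tibble::tibble(
      d = rectify(rnorm(sp$n, sp$mu_d, sp$sigma_d), rectify_mode),
      s = rectify(rnorm(sp$n, sp$mu_s, sp$sigma_s), rectify_mode),
      group = sp$label
    )
  }))
  cohort <- nx_evaluate(dplyr::bind_rows(raw), params)
  cohort <- dplyr::relocate(cohort, "d", "s", "T", "I", "F", "S", "group")
  attr(cohort, "seed") <- as.integer(seed)
  attr(cohort, "params") <- params
  attr(cohort, "specs") <- specs
  attr(cohort, "rectify_mode") <- rectify_mode
  cohort
}
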