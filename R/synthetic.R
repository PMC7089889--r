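#' Measurement noise model for virtual experiments
#'
#' Gaussian, independent noise per reading: per-gauge strain standard
#' deviations (microstrain) with defaults equal to the in vitro gauge
#' repeatability, and an isotropic displacement uncertainty of one
#' micrometre per point for the DIC-like full-field measurement.
#'
#' @param gauge_sd Per-gauge strain SD in microstrain (recycled to the
#'   number of gauges).
#' @param dic_sd Displacement SD in metres (default 1e-6).
#' @param seed Integer seed fixing all draws.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(gauge_sd = c(5.2, 8.5, 2.9, 12.7), dic_sd = 1e-6,
                        seed = 1L) {
  if (any(gauge_sd < 0) || dic_sd < 0) stop("noise SDs must be >= 0")
  structure(list(gauge_sd = gauge_sd, dic_sd = dic_sd,
                 seed = as.integer(seed)), class = "noise_model")
}

# evaluate expr under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Default incremental load schedule
#'
#' Load levels in body-weight multiples covering the in vitro ramp from
#' 0.33 BW to 3.5 BW.
#'
#' @return Numeric vector of BW multiples.
#' @export
default_load_schedule <- function() {
  c(0.33, 0.5, 1.0, 1.5, 2.0, 2.5, 3.0, 3.5)
}

#' Generate virtual strain-gauge readings
#'
#' Emulates instrumented loading of the construct: the true gauge
#' strains at one body weight are scaled linearly to each load step
#' (linear elasticity) and perturbed with independent Gaussian noise per
#' reading.
#'
#' @param truth Named numeric vector of true gauge strains (microstrain)
#'   at 1.0 BW, e.g. from [virtual_gauge()].
#' @param noise A [noise_model()].
#' @param steps Load schedule in BW multiples (default
#'   [default_load_schedule()]); all steps must lie in `[0.33, 3.5]`.
#' @return A `virtual_experiment`: list with `readings` (steps x gauges,
#'   microstrain), `steps`, `truth` and the noise model.
#' @export
gen_gauge_readings <- function(truth, noise = noise_model(),
                               steps = default_load_schedule()) {
  stopifnot(inherits(noise, "noise_model"))
  if (any(is.na(truth))) stop("missing gauge truth value")
  if (any(steps < 0.33 - 1e-9) || any(steps > 3.5 + 1e-9))
    stop("load steps must lie within 0.33 to 3.5 BW")
  ng <- length(truth)
  sds <- rep(noise$gauge_sd, length.out = ng)
  readings <- with_seed(noise$seed, {
    vapply(seq_len(ng), function(g)
      truth[g] * steps + stats::rnorm(length(steps), 0, sds[g]),
      numeric(length(steps)))
  })
  readings <- matrix(readings, nrow = length(steps), ncol = ng,
                     dimnames = list(NULL, names(truth)))
  structure(list(readings = readings, steps = steps, truth = truth,
                 noise = noise), class = "virtual_experiment")
}

#' Per-gauge mean strain at one body weight from a virtual experiment
#'
#' Each reading is normalised by its load step and the steps averaged,
#' the estimator an instrumented test would report as the mean strain
#' per body weight.
#'
#' @param exp A `virtual_experiment`.
#' @return Named numeric vector (microstrain at 1.0 BW).
#' @export
experiment_gauge_means <- function(exp) {
  stopifnot(inherits(exp, "virtual_experiment"))
  colMeans(sweep(exp$readings, 1, exp$steps, "/"))
}

#' Generate a DIC-like noisy displacement field sample
#'
#' True nodal displacements over the camera-visible region perturbed by
#' isotropic Gaussian noise per point.
#'
#' @param u A `displacement_field`.
#' @param region Node indices of the visible region (see
#'   [dic_region()]).
#' @param noise A [noise_model()].
#' @return List with `nodes`, `u` (noisy displacements, m) and `truth`.
#' @export
gen_dic_field <- function(u, region, noise = noise_model()) {
  stopifnot(inherits(noise, "noise_model"))
  if (length(region) == 0) stop("DIC region is empty")
  truth <- unclass(u)[region, , drop = FALSE]
  noisy <- with_seed(noise$seed + 1L,
                     truth + matrix(stats::rnorm(length(truth), 0,
                                                 noise$dic_sd),
                                    nrow(truth), 3))
  list(nodes = region, u = noisy, truth = truth)
}

#' Published validation table fixtures
#'
#' The printed mean gauge strains (in vitro with SD, in silico) and the
#' displacement spans per global axis for the single-body-weight
#' validation load case, as packaged fixture files.
#'
#' @return A list with data frames `strain` (gauge, invitro_mean,
#'   invitro_sd, insilico_mean) and `displacement` (axis, invitro_span,
#'   insilico_span).
#' @export
fixtures_table2 <- function() {
  dir <- system.file("extdata", package = "osseofe")
  list(
    strain = utils::read.csv(file.path(dir, "table2_strain.csv")),
    displacement = utils::read.csv(file.path(dir,
                                             "table2_displacement.csv")))
}

#' Published load-case component fixture
#'
#' @return Data frame with the force components (N) of the two stance
#'   load cases.
#' @export
fixtures_table1 <- function() {
  utils::read.csv(system.file("extdata", "table1.csv",
                              package = "osseofe"))
}
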