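#' Lin's concordance correlation coefficient
#'
#' Agreement of paired measurements with the identity line,
#' `rho_c = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)`, computed
#' with population (1/n) moments.  Unlike Pearson correlation it
#' penalises both scale and location shifts, so `|rho_c| <= |r|`.
#'
#' @param x Reference values (measurement role).
#' @param y Predicted values (model role).
#' @return Concordance coefficient in `[-1, 1]`.
#' @examples
#' lins_ccc(c(0.795, 0.53, 0.067), c(0.821, 0.561, 0.0749))  # 0.997
#' @export
lins_ccc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop("paired samples of equal length >= 2 are required")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("samples must be finite")
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxy <- mean(x * y) - mx * my
  sx2 <- mean(x^2) - mx^2
  sy2 <- mean(y^2) - my^2
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0)
    stop("zero variance and equal means: concordance is undefined")
  2 * sxy / denom
}

#' Percent error of a prediction against a reference
#'
#' `100 * |predicted - reference| / |reference|`.
#'
#' @param reference Reference (measured) value; must be non-zero.
#' @param predicted Predicted (model) value.
#' @return Percent error (vectorised).
#' @export
percent_error <- function(reference, predicted) {
  if (any(reference == 0)) stop("reference value must be non-zero")
  100 * abs(predicted - reference) / abs(reference)
}

#' Richardson extrapolation over three uniformly refined meshes
#'
#' Given a solution quantity on meshes with edge lengths `(2h, h, h/2)`,
#' estimates the observed convergence order
#' `p = log((u_2h - u_h) / (u_h - u_h2)) / log(2)`, the extrapolated
#' mesh-independent value `u* = u_h2 + (u_h2 - u_h) / (2^p - 1)` and the
#' relative discretisation error at the finest level.  A constant
#' sequence is reported as already converged; an oscillating
#' (non-monotone) sequence raises an error asking for further
#' refinement.
#'
#' @param values Numeric vector `c(u_2h, u_h, u_h2)` ordered coarse to
#'   fine.
#' @param r Refinement ratio between levels (default 2).
#' @return An object of class `richardson_result`: list with `order`,
#'   `extrapolated`, `rel_error` (at the finest level) and `converged`.
#' @export
richardson <- function(values, r = 2) {
  if (length(values) != 3 || any(!is.finite(values)))
    stop("exactly three finite solution values are required")
  if (r <= 1) stop("refinement ratio must exceed 1")
  d1 <- values[1] - values[2]
  d2 <- values[2] - values[3]
  if (d1 == 0 && d2 == 0) {
    out <- list(order = NA_real_, extrapolated = values[3],
                rel_error = 0, converged = TRUE)
    class(out) <- "richardson_result"
    return(out)
  }
  if (d1 * d2 <= 0)
    stop("non-monotone (oscillatory) convergence; refine the mesh further")
  p <- log(d1 / d2) / log(r)
  u_star <- values[3] - d2 / (r^p - 1)
  out <- list(order = p, extrapolated = u_star,
              rel_error = abs(values[3] - u_star) /
                max(abs(u_star), .Machine$double.xmin),
              converged = FALSE)
  class(out) <- "richardson_result"
  out
}

#' @export
print.richardson_result <- function(x, ...) {
  if (x$converged && is.na(x$order)) {
    cat("<richardson> constant sequence: converged, relative error 0\n")
  } else {
    cat(sprintf(
      "<richardson> observed order p = %.3f, u* = %.6g, rel error %.3g%%\n",
      x$order, x$extrapolated, 100 * x$rel_error))
  }
  invisible(x)
}

#' One-at-a-time sensitivity summary
#'
#' For a set of model variants sharing gauge sites, reports one sample
#' standard deviation (n - 1) of the gauge strain across variants as a
#' percentage of the mean at that gauge.  Gauges with zero mean are
#' flagged as undefined (NA) rather than failing.
#'
#' @param strains Numeric matrix, gauges in rows and model variants in
#'   columns (>= 2 columns).
#' @return A `sensitivity_result` data frame with `gauge`, `mean`, `sd`
#'   and `sensitivity_pct`.
#' @export
oat_sensitivity <- function(strains) {
  strains <- as.matrix(strains)
  if (ncol(strains) < 2) stop("at least two model variants are required")
  m <- rowMeans(strains)
  s <- apply(strains, 1, stats::sd)
  pct <- ifelse(m == 0, NA_real_, 100 * s / abs(m))
  if (any(m == 0))
    message("oat_sensitivity: zero-mean gauge(s) flagged as undefined")
  out <- data.frame(
    gauge = if (!is.null(rownames(strains))) rownames(strains)
    else paste0("gauge", seq_along(m)),
    mean = m, sd = s, sensitivity_pct = pct, row.names = NULL)
  class(out) <- c("sensitivity_result", "data.frame")
  out
}

#' Default one-at-a-time variant grid
#'
#' Builds a roster of model variants perturbing, one at a time, the
#' material moduli (bone EX/EY/EZ, cement E, stem E) by a relative
#' fraction and the load orientation angles by a fixed offset.  Each
#' variant is a list with optionally modified `materials` and `orient`
#' entries.
#'
#' @param materials Baseline material cards.
#' @param orient Baseline [orientation()].
#' @param rel Relative material perturbation (default 0.1).
#' @param angle_delta Orientation perturbation in degrees (default 1).
#' @return Named list of variants (including the baseline).
#' @export
oat_variants <- function(materials, orient = orientation(), rel = 0.1,
                         angle_delta = 1) {
  variants <- list(baseline = list(materials = materials, orient = orient))
  perturb_bone <- function(which, f) {
    m <- materials
    b <- m$bone_layer
    b[[which]] <- b[[which]] * f
    card <- material_card("orthotropic", EX = b$EX, EY = b$EY, EZ = b$EZ,
                          nuXY = b$nuXY, nuYZ = b$nuYZ, nuXZ = b$nuXZ,
                          GXY = b$GXY, GYZ = b$GYZ, GXZ = b$GXZ,
                          frame = b$frame, density = b$density,
                          name = b$name)
    m$bone_layer <- card
    m$outer_bone <- card
    m
  }
  for (par in c("EX", "EY", "EZ")) {
    for (s in c(1 - rel, 1 + rel)) {
      variants[[sprintf("bone_%s_%+.0f%%", par, 100 * (s - 1))]] <-
        list(materials = perturb_bone(par, s), orient = orient)
    }
  }
  for (part in c("cement", "stem")) {
    for (s in c(1 - rel, 1 + rel)) {
      m <- materials
      m[[part]] <- material_card("isotropic", E = m[[part]]$E * s,
                                 nu = m[[part]]$nu, name = m[[part]]$name)
      variants[[sprintf("%s_E_%+.0f%%", part, 100 * (s - 1))]] <-
        list(materials = m, orient = orient)
    }
  }
  for (ang in c("adduction", "flexion")) {
    for (s in c(-angle_delta, angle_delta)) {
      o <- orient
      o[[ang]] <- o[[ang]] + s
      variants[[sprintf("%s_%+g_deg", ang, s)]] <-
        list(materials = materials, orient = do.call(orientation, unclass(o)))
    }
  }
  variants
}

#' Run a one-at-a-time sensitivity study
#'
#' Solves the assembly for every variant in the grid (same mesh, variant
#' materials and load orientation) and reads the virtual gauges.
#'
#' @param mesh An assembly mesh.
#' @param variants A variant grid from [oat_variants()].
#' @param sites Gauge sites (default [default_gauge_sites()]).
#' @param mass,g Load magnitude parameters passed to [lc1()].
#' @return Matrix of gauge strains (microstrain), gauges x variants, to
#'   feed [oat_sensitivity()].
#' @export
run_oat <- function(mesh, variants, sites = default_gauge_sites(),
                    mass = 86, g = 9.8) {
  res <- matrix(NA_real_, nrow = length(sites), ncol = length(variants),
                dimnames = list(names(sites), names(variants)))
  for (v in seq_along(variants)) {
    var <- variants[[v]]
    sys <- assemble(mesh, var$materials)
    lc <- lc1(mass = mass, g = g, orient = var$orient)
    u <- fe_solve(sys, lc)
    tf <- strain_stress(sys, u)
    res[, v] <- vapply(sites, function(s) virtual_gauge(tf, s), numeric(1))
  }
  res
}
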