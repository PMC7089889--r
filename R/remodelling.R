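#' Adaptive bone remodelling thresholds
#'
#' The mechanostat homeostasis band expressed as strain energy density
#' per unit mass: below the band bone is likely to resorb, above it to
#' appose.  The mass-specific thresholds (J g^-1) are converted to
#' volumetric SED bounds (J m^-3) with an apparent cortical density.
#'
#' @param lower,upper Band limits in J g^-1 (defaults 0.0036 and 0.0044).
#' @param density Apparent density in g cm^-3 used for the conversion
#'   (default 1.8, a typical cortical value).
#' @return An object of class `remodelling_thresholds`.
#' @export
thresholds <- function(lower = 0.0036, upper = 0.0044, density = 1.8) {
  if (!(lower > 0 && upper > lower)) stop("need 0 < lower < upper")
  if (density <= 0) stop("density must be positive")
  structure(list(lower = lower, upper = upper, density = density),
            class = "remodelling_thresholds")
}

#' Volumetric SED bounds of the homeostasis band
#'
#' `bound (J m^-3) = threshold (J g^-1) * density (g cm^-3) * 1e6`;
#' the defaults give (6480, 7920) J m^-3.
#'
#' @param t A [thresholds()] object.
#' @return Numeric vector `c(lower, upper)` in J m^-3.
#' @export
sed_bounds <- function(t) {
  stopifnot(inherits(t, "remodelling_thresholds"))
  c(lower = t$lower * t$density * 1e6,
    upper = t$upper * t$density * 1e6)
}

#' Classify periprosthetic bone slices against the SED band
#'
#' For every slice of the bone layer, computes the area fractions of the
#' cross section whose SED falls below (resorption), within
#' (homeostasis), or above (apposition) the band.  Fractions are exact
#' element-area weights on the structured mesh: each element contributes
#' its volume divided by its axial extent.
#'
#' @param sed_field A `sed_field` from [sed()] on a solved case.
#' @param mesh The assembly mesh carrying slice indices (see
#'   [assign_slices()]).
#' @param t A [thresholds()] object.
#' @return A `slice_report` data frame with columns `slice`, `area`
#'   (m^2), `fraction_below`, `fraction_within`, `fraction_above`.
#' @export
classify <- function(sed_field, mesh = NULL, t = thresholds()) {
  stopifnot(inherits(sed_field, "sed_field"),
            inherits(t, "remodelling_thresholds"))
  slice <- if (!is.null(sed_field$slice)) sed_field$slice else mesh$slice
  if (all(is.na(slice)))
    stop("no slice indices assigned; call assign_slices() first")
  b <- sed_bounds(t)
  sel <- which(!is.na(slice))
  sl <- slice[sel]
  area_w <- sed_field$volume[sel] / sed_field$height[sel]
  U <- sed_field$U[sel]
  ns <- max(sl)
  if (length(unique(sl)) < ns)
    stop("empty slice encountered in classification")
  agg <- function(w) as.numeric(tapply(w, factor(sl, levels = 1:ns), sum,
                                       default = 0))
  area <- agg(area_w)
  below <- agg(area_w * (U < b["lower"]))
  above <- agg(area_w * (U > b["upper"]))
  rep_df <- data.frame(
    slice = 1:ns, area = area,
    fraction_below = below / area,
    fraction_above = above / area)
  rep_df$fraction_within <- 1 - rep_df$fraction_below - rep_df$fraction_above
  rep_df <- rep_df[, c("slice", "area", "fraction_below",
                       "fraction_within", "fraction_above")]
  attr(rep_df, "bounds") <- b
  attr(rep_df, "labels") <- c(fraction_below = "resorption",
                              fraction_within = "homeostasis",
                              fraction_above = "apposition")
  class(rep_df) <- c("slice_report", "data.frame")
  rep_df
}

#' Stem stiffness sweep
#'
#' Re-solves the same meshed assembly with the stem Young's modulus set
#' to each requested value (all other properties unchanged), classifies
#' every solution against the SED band, and summarises peak SED in the
#' periprosthetic bone layer and on the periosteal (outer bone surface)
#' elements, with percentage differences between consecutive moduli.
#'
#' @param mesh An assembly mesh with slices assigned.
#' @param materials Baseline material cards (see
#'   [default_material_cards()]).
#' @param lc A [load_case()].
#' @param moduli Stem Young's moduli in Pa (default 20, 115, 210 GPa).
#' @param t A [thresholds()] object.
#' @return A `stiffness_sweep` object: list with `reports` (one
#'   `slice_report` per modulus), `peaks` data frame and
#'   `peak_changes` between consecutive moduli.
#' @export
stiffness_sweep <- function(mesh, materials, lc,
                            moduli = c(20e9, 115e9, 210e9),
                            t = thresholds()) {
  if (any(!is.finite(moduli)) || any(moduli <= 0))
    stop("stem moduli must be positive")
  f <- equivalent_face_loads(lc, mesh)
  outer_ring <- max(mesh$ring[mesh$part == "outer_bone"])
  periosteal <- mesh$part == "outer_bone" & mesh$ring == outer_ring
  reports <- vector("list", length(moduli))
  names(reports) <- sprintf("%g", moduli)
  peaks <- data.frame()
  for (i in seq_along(moduli)) {
    E <- moduli[i]
    cards <- materials
    cards$stem <- material_card("isotropic", E = E, nu = cards$stem$nu,
                                name = sprintf("stem %.0f GPa", E / 1e9))
    sys <- assemble(mesh, cards)
    u <- tryCatch(fe_solve(sys, f), error = function(e)
      stop(sprintf("solve failed for stem modulus %.3g Pa: %s", E,
                   conditionMessage(e))))
    tf <- strain_stress(sys, u)
    sf <- sed(tf)
    reports[[i]] <- classify(sf, mesh, t)
    peaks <- rbind(peaks, data.frame(
      modulus = E,
      peak_sed_bone_layer = max(sf$U[mesh$part == "bone_layer"]),
      peak_sed_periosteal = max(sf$U[periosteal]),
      mean_sed_bone_layer = sum((sf$U * sf$volume)[mesh$part == "bone_layer"]) /
        sum(sf$volume[mesh$part == "bone_layer"])))
  }
  pct <- function(v) 100 * (v[-length(v)] - v[-1]) / v[-1]
  peak_changes <- data.frame(
    comparison = sprintf("%g vs %g GPa", moduli[-length(moduli)] / 1e9,
                         moduli[-1] / 1e9),
    peak_sed_bone_layer_pct = pct(peaks$peak_sed_bone_layer),
    peak_sed_periosteal_pct = pct(peaks$peak_sed_periosteal))
  structure(list(moduli = moduli, reports = reports, peaks = peaks,
                 peak_changes = peak_changes, thresholds = t),
            class = "stiffness_sweep")
}

#' @export
print.stiffness_sweep <- function(x, ...) {
  cat("<stiffness_sweep> stem moduli (GPa):",
      paste(x$moduli / 1e9, collapse = ", "), "\n")
  print(x$peaks)
  invisible(x)
}

#' Distal-to-proximal trend of slice fractions
#'
#' Mean per-step relative change of the apposition (`fraction_above`)
#' and resorption (`fraction_below`) area fractions across slices,
#' reported in percent.  Steps with a zero-valued baseline fraction are
#' skipped with a note.
#'
#' @param report A `slice_report` from [classify()].
#' @param slices Slice indices to include (default slices 1-10 when
#'   available, else all).
#' @return Named numeric vector with `apposition_pct` and
#'   `resorption_pct` mean changes.
#' @export
trend <- function(report, slices = NULL) {
  stopifnot(inherits(report, "slice_report"))
  if (is.null(slices))
    slices <- seq_len(min(10L, nrow(report)))
  if (length(slices) < 2) stop("need at least two slices for a trend")
  rep_sub <- report[report$slice %in% slices, ]
  step_mean <- function(f) {
    base <- f[-length(f)]
    delta <- diff(f)
    ok <- base != 0
    if (!all(ok))
      message(sprintf("trend: skipped %d step(s) with zero baseline",
                      sum(!ok)))
    if (!any(ok)) return(NA_real_)
    mean(delta[ok] / base[ok]) * 100
  }
  c(apposition_pct = step_mean(rep_sub$fraction_above),
    resorption_pct = step_mean(rep_sub$fraction_below))
}
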