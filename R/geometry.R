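#' Parametric implant--cement--bone assembly specification
#'
#' Describes the idealised concentric assembly used throughout the
#' package: a tapered metal stem (with a small axial cannulation so the
#' annular structured mesh has a regular core), a cement mantle, a
#' uniform periprosthetic bone layer, and an outer cortical bone wall
#' that continues proximally beyond the stem tip up to the residual bone
#' length.  All dimensions are SI metres.  The global frame is
#' X = lateral (+), Y = proximal (+), Z = anterior (+); the distal end of
#' the assembly is at y = 0.
#'
#' @param stem_length Stem length (default 0.12).
#' @param stem_diameter_distal,stem_diameter_proximal Stem diameters at the
#'   distal and proximal (tip) ends; the stem tapers proximally
#'   (12 mm to 9 mm by default).
#' @param stem_bore_diameter Diameter of the small axial cannulation at the
#'   stem centre (default 1.5 mm; under 2 percent of the stem
#'   cross-sectional area).
#' @param cement_thickness_distal Cement mantle thickness at the distal end
#'   (default 1 mm).
#' @param cement_taper_rule Either "uniform" (constant distal thickness) or
#'   "linear_increase_proximal" (linear growth to
#'   `cement_thickness_proximal`).
#' @param cement_thickness_proximal Cement thickness at the stem tip when
#'   the taper rule is "linear_increase_proximal" (default 2 mm).
#' @param bone_layer_thickness Uniform periprosthetic bone layer thickness
#'   (default 2 mm).
#' @param outer_bone_wall_thickness Outer cortical wall thickness
#'   (default 5 mm).
#' @param residual_length Residual bone length from the distal cut
#'   (default 0.201).
#' @param collar_diameter Diameter of the implant collar/spigot footprint
#'   at the distal face (default 18 mm); distal-face nodes inside this
#'   radius form the fixed node set.
#' @param element_edge_length Target element edge length (default
#'   0.625 mm).
#' @param element_order "linear" (8-node) or "quadratic" (20-node)
#'   hexahedra.
#' @param sectors Optional explicit circumferential sector count
#'   (a multiple of 4); by default derived from the edge length with a
#'   floor of 32 so that the polygonal approximation of each circular
#'   boundary stays within a fraction of a percent of the true area.
#' @return An object of class `assembly_spec`.
#' @export
assembly_spec <- function(stem_length = 0.12,
                          stem_diameter_distal = 0.012,
                          stem_diameter_proximal = 0.009,
                          stem_bore_diameter = 0.0015,
                          cement_thickness_distal = 0.001,
                          cement_taper_rule = c("linear_increase_proximal",
                                                "uniform"),
                          cement_thickness_proximal = 0.002,
                          bone_layer_thickness = 0.002,
                          outer_bone_wall_thickness = 0.005,
                          residual_length = 0.201,
                          collar_diameter = 0.018,
                          element_edge_length = 0.000625,
                          element_order = c("linear", "quadratic"),
                          sectors = NULL) {
  cement_taper_rule <- match.arg(cement_taper_rule)
  element_order <- match.arg(element_order)
  spec <- list(
    stem_length = stem_length,
    stem_diameter_distal = stem_diameter_distal,
    stem_diameter_proximal = stem_diameter_proximal,
    stem_bore_diameter = stem_bore_diameter,
    cement_thickness_distal = cement_thickness_distal,
    cement_taper_rule = cement_taper_rule,
    cement_thickness_proximal = cement_thickness_proximal,
    bone_layer_thickness = bone_layer_thickness,
    outer_bone_wall_thickness = outer_bone_wall_thickness,
    residual_length = residual_length,
    collar_diameter = collar_diameter,
    element_edge_length = element_edge_length,
    element_order = element_order,
    sectors = sectors)
  class(spec) <- "assembly_spec"
  validate_assembly_spec(spec)
  spec
}

validate_assembly_spec <- function(spec) {
  dims <- unlist(spec[c("stem_length", "stem_diameter_distal",
                        "stem_diameter_proximal", "stem_bore_diameter",
                        "cement_thickness_distal", "bone_layer_thickness",
                        "outer_bone_wall_thickness", "residual_length",
                        "collar_diameter", "element_edge_length")])
  if (any(!is.finite(dims)) || any(dims <= 0))
    stop("all assembly dimensions must be positive and finite")
  if (spec$stem_diameter_proximal > spec$stem_diameter_distal)
    stop("the stem must taper: proximal diameter must not exceed distal")
  if (spec$stem_bore_diameter >= spec$stem_diameter_proximal)
    stop("stem bore must be smaller than the proximal stem diameter")
  if (spec$cement_taper_rule == "linear_increase_proximal" &&
      spec$cement_thickness_proximal < spec$cement_thickness_distal)
    stop("cement thickness must be >= its distal value everywhere")
  if (spec$stem_length >= spec$residual_length)
    stop("stem length must be less than the residual bone length")
  if (!is.null(spec$sectors) &&
      (spec$sectors < 8 || spec$sectors %% 4 != 0))
    stop("sectors must be a multiple of 4, at least 8")
  invisible(spec)
}

#' @export
print.assembly_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "<assembly_spec> stem %.0f mm (d %.1f->%.1f mm), cement %s,\n",
    "  bone layer %.1f mm, wall %.1f mm, residual %.0f mm, edge %.3g mm, %s\n"),
    x$stem_length * 1e3, x$stem_diameter_distal * 1e3,
    x$stem_diameter_proximal * 1e3, x$cement_taper_rule,
    x$bone_layer_thickness * 1e3, x$outer_bone_wall_thickness * 1e3,
    x$residual_length * 1e3, x$element_edge_length * 1e3, x$element_order))
  invisible(x)
}

#' Cross-sectional slice specification for the periprosthetic bone layer
#'
#' Slices are equidistant axial bins along the bone layer used for the
#' remodelling area analysis; the default is 11 slices 1.09 mm apart
#' starting at the distal end of the bone layer (the osteotomy face).
#'
#' @param number_of_slices Number of slices (default 11).
#' @param spacing Axial slice spacing in metres (default 1.09 mm).
#' @param origin Axial position of the distal face of slice 1 (default 0,
#'   the distal end of the bone layer).
#' @return An object of class `slice_spec`.
#' @export
slice_spec <- function(number_of_slices = 11, spacing = 0.00109,
                       origin = 0) {
  stopifnot(number_of_slices >= 1, spacing > 0, origin >= 0)
  structure(list(number_of_slices = as.integer(number_of_slices),
                 spacing = spacing, origin = origin),
            class = "slice_spec")
}

# -- internal geometry helpers ------------------------------------------------

# Interface radii at axial positions y (vectorised).  Beyond the stem tip
# the bone radii are frozen at their tip values (the proximal tube).
radii_at <- function(spec, y) {
  yc <- pmin(y, spec$stem_length)
  f <- yc / spec$stem_length
  r_stem <- (1 - f) * spec$stem_diameter_distal / 2 +
    f * spec$stem_diameter_proximal / 2
  t_cem <- if (spec$cement_taper_rule == "uniform") {
    rep(spec$cement_thickness_distal, length(yc))
  } else {
    (1 - f) * spec$cement_thickness_distal + f * spec$cement_thickness_proximal
  }
  r_cem <- r_stem + t_cem
  r_bone <- r_cem + spec$bone_layer_thickness
  r_outer <- r_bone + spec$outer_bone_wall_thickness
  list(bore = rep(spec$stem_bore_diameter / 2, length(yc)),
       stem = r_stem, cement = r_cem, bone = r_bone, outer = r_outer)
}

part_names <- c("stem", "cement", "bone_layer", "outer_bone")

default_divisions <- function(spec, slices = NULL) {
  e <- spec$element_edge_length
  r <- radii_at(spec, c(0, spec$stem_length))
  thick <- cbind(
    stem = r$stem - r$bore,
    cement = r$cement - r$stem,
    bone_layer = r$bone - r$cement,
    outer_bone = r$outer - r$bone)
  nr <- pmax(1L, as.integer(round(colMeans(thick) / e)))
  names(nr) <- part_names
  ntheta <- if (!is.null(spec$sectors)) as.integer(spec$sectors) else
    max(32L, 4L * as.integer(round(2 * pi * max(r$outer) / e / 4)))
  slice_sub <- if (is.null(slices)) NULL else
    max(1L, as.integer(round(slices$spacing / e)))
  band_end <- if (is.null(slices)) 0 else
    slices$origin + slices$number_of_slices * slices$spacing
  if (band_end > spec$stem_length + 1e-12)
    stop("slice band extends beyond the bone layer")
  n_pre <- if (is.null(slices) || slices$origin <= 0) 0L else
    max(1L, as.integer(round(slices$origin / e)))
  n_plug <- max(1L, as.integer(round((spec$stem_length - band_end) / e)))
  if (abs(spec$stem_length - band_end) < 1e-12) n_plug <- 0L
  n_tube <- max(1L, as.integer(round(
    (spec$residual_length - spec$stem_length) / e)))
  list(ntheta = ntheta, nr = nr, slice_sub = slice_sub,
       n_pre = n_pre, n_plug = n_plug, n_tube = n_tube)
}

scale_divisions <- function(div, factor) {
  sc <- function(n) {
    out <- pmax(1L, as.integer(round(n / factor)))
    names(out) <- names(n)
    out
  }
  div$nr <- sc(div$nr)
  div$ntheta <- max(8L, 2L * as.integer(round(div$ntheta / (2 * factor))))
  if (!is.null(div$slice_sub)) div$slice_sub <- sc(div$slice_sub)
  if (div$n_pre > 0) div$n_pre <- sc(div$n_pre)
  if (div$n_plug > 0) div$n_plug <- sc(div$n_plug)
  div$n_tube <- sc(div$n_tube)
  div
}

axial_stations <- function(spec, slices, div) {
  ys <- 0
  lay_slice <- integer(0)
  if (!is.null(slices)) {
    if (div$n_pre > 0) {
      ys <- c(ys, slices$origin * seq_len(div$n_pre) / div$n_pre)
      lay_slice <- c(lay_slice, rep(NA_integer_, div$n_pre))
    }
    k <- div$slice_sub
    for (s in seq_len(slices$number_of_slices)) {
      y1 <- slices$origin + s * slices$spacing
      y0 <- y1 - slices$spacing
      ys <- c(ys, y0 + (slices$spacing) * seq_len(k) / k)
      lay_slice <- c(lay_slice, rep(s, k))
    }
  }
  if (div$n_plug > 0) {
    y0 <- ys[length(ys)]
    ys <- c(ys, y0 + (spec$stem_length - y0) * seq_len(div$n_plug) / div$n_plug)
    lay_slice <- c(lay_slice, rep(NA_integer_, div$n_plug))
  }
  n_plug_layers <- length(ys) - 1L
  y0 <- ys[length(ys)]
  ys <- c(ys, y0 + (spec$residual_length - y0) * seq_len(div$n_tube) /
            div$n_tube)
  lay_slice <- c(lay_slice, rep(NA_integer_, div$n_tube))
  list(ys = ys, lay_slice = lay_slice, n_plug_layers = n_plug_layers)
}

#' Build the structured hexahedral assembly mesh
#'
#' Generates a conforming structured mesh of concentric rings x
#' circumferential sectors x axial layers.  Interfaces between parts
#' share nodes (fully bonded).  When a [slice_spec()] is supplied the
#' axial stations are aligned with the slice boundaries and slice indices
#' are assigned to the bone-layer elements.
#'
#' Two node sets are populated from the geometry: `distal_fixed_face`
#' (nodes on the distal face within the collar/spigot footprint,
#' emulating the potted spigot with the collar bonded to the distal bone)
#' and `proximal_load_face` (all nodes on the proximal face).  The set
#' `outer_surface` holds the periosteal surface nodes used for virtual
#' strain gauges and the DIC-like region.
#'
#' @param spec An [assembly_spec()].
#' @param slices Optional [slice_spec()]; when given, slice indices are
#'   assigned as by [assign_slices()].
#' @return An object of class `assembly_mesh`.
#' @export
build_assembly_mesh <- function(spec, slices = NULL) {
  validate_assembly_spec(spec)
  div <- default_divisions(spec, slices)
  build_mesh_core(spec, slices, div)
}

build_mesh_core <- function(spec, slices, div) {
  d <- if (spec$element_order == "quadratic") 2L else 1L
  ax <- axial_stations(spec, slices, div)
  ys <- ax$ys
  NL <- length(ys) - 1L
  nr <- div$nr
  NR <- sum(nr)
  nt <- div$ntheta
  ibone <- sum(nr[c("stem", "cement", "bone_layer")])  # bone-layer outer ring

  # doubled-grid dimensions (d = 1 for linear, 2 for quadratic)
  gR <- d * NR + 1L
  gT <- d * nt
  gS <- d * NL + 1L
  # axial position of grid station
  gy <- numeric(gS)
  gy[seq(1, gS, by = d)] <- ys
  if (d == 2L) gy[seq(2, gS - 1, by = 2)] <- (ys[-1] + ys[-length(ys)]) / 2

  # ring bookkeeping in grid units: part and local fraction of each ring
  ring_bounds <- cumsum(c(0, nr)) * d   # grid ring index of part boundaries
  ring_part <- integer(gR)              # part of the segment a ring sits in
  ring_frac <- numeric(gR)
  for (p in seq_along(part_names)) {
    lo <- ring_bounds[p]; hi <- ring_bounds[p + 1]
    sel <- seq(lo, hi) + 1L
    ring_part[sel] <- p
    ring_frac[sel] <- (seq(lo, hi) - lo) / (hi - lo)
  }

  # node presence mask
  ir <- rep(seq_len(gR) - 1L, times = gT * gS)
  it <- rep(rep(seq_len(gT) - 1L, each = gR), times = gS)
  iy <- rep(seq_len(gS) - 1L, each = gR * gT)
  present <- rep(TRUE, length(ir))
  if (d == 2L)
    present <- (ir %% 2L + it %% 2L + iy %% 2L) <= 1L
  in_tube <- gy[iy + 1L] > spec$stem_length + 1e-12
  present <- present & (!in_tube | ir >= d * ibone)

  nid <- integer(length(ir))
  nid[present] <- seq_len(sum(present))
  n_nodes <- sum(present)

  # coordinates
  ring_lohi <- function(y) {
    r <- radii_at(spec, y)
    rbind(r$bore, r$stem, r$cement, r$bone, r$outer)
  }
  xyz <- matrix(0, n_nodes, 3)
  idp <- which(present)
  yv <- gy[iy[idp] + 1L]
  bounds <- ring_lohi(yv)  # 5 x n
  pv <- ring_part[ir[idp] + 1L]
  fv <- ring_frac[ir[idp] + 1L]
  r_lo <- bounds[cbind(pv, seq_along(idp))]
  r_hi <- bounds[cbind(pv + 1L, seq_along(idp))]
  rv <- r_lo + fv * (r_hi - r_lo)
  thv <- 2 * pi * it[idp] / gT
  xyz[, 1] <- rv * cos(thv)
  xyz[, 2] <- yv
  xyz[, 3] <- rv * sin(thv)

  nid_at <- function(jr, jt, jy) {
    jt <- jt %% gT
    nid[jr + 1L + gR * (jt + gT * jy)]
  }

  # elements
  conn_list <- vector("list", NL)
  meta_list <- vector("list", NL)
  cumr <- cumsum(nr)
  for (L in seq_len(NL)) {
    rings <- if (L > ax$n_plug_layers) seq(ibone + 1L, NR) else seq_len(NR)
    grid <- expand.grid(i = rings, j = seq_len(nt) - 1L)
    i <- grid$i; j <- grid$j
    ir0 <- d * (i - 1L); ir1 <- d * i
    is0 <- d * j; is1 <- d * (j + 1L)
    iy0 <- d * (L - 1L); iy1 <- d * L
    conn <- cbind(
      nid_at(ir0, is0, iy0), nid_at(ir0, is1, iy0),
      nid_at(ir1, is1, iy0), nid_at(ir1, is0, iy0),
      nid_at(ir0, is0, iy1), nid_at(ir0, is1, iy1),
      nid_at(ir1, is1, iy1), nid_at(ir1, is0, iy1))
    if (d == 2L) {
      irm <- ir0 + 1L; ism <- is0 + 1L; iym <- iy0 + 1L
      conn <- cbind(conn,
        nid_at(ir0, ism, iy0), nid_at(irm, is1, iy0),
        nid_at(ir1, ism, iy0), nid_at(irm, is0, iy0),
        nid_at(ir0, ism, iy1), nid_at(irm, is1, iy1),
        nid_at(ir1, ism, iy1), nid_at(irm, is0, iy1),
        nid_at(ir0, is0, iym), nid_at(ir0, is1, iym),
        nid_at(ir1, is1, iym), nid_at(ir1, is0, iym))
    }
    conn_list[[L]] <- conn
    meta_list[[L]] <- data.frame(
      ring = i, sector = j, layer = L,
      part = findInterval(i - 0.5, c(0, cumr)),
      height = ys[L + 1L] - ys[L])
  }
  elems <- do.call(rbind, conn_list)
  meta <- do.call(rbind, meta_list)
  storage.mode(elems) <- "integer"

  part <- factor(part_names[meta$part], levels = part_names)
  slice <- rep(NA_integer_, nrow(meta))
  if (!is.null(slices)) {
    sl <- ax$lay_slice[meta$layer]
    slice[part == "bone_layer" & !is.na(sl)] <-
      sl[part == "bone_layer" & !is.na(sl)]
  }

  # centroids and cylindrical coordinates
  cx <- matrix(xyz[elems[, 1:8], 1], ncol = 8)
  cy <- matrix(xyz[elems[, 1:8], 2], ncol = 8)
  cz <- matrix(xyz[elems[, 1:8], 3], ncol = 8)
  centroid <- cbind(rowMeans(cx), rowMeans(cy), rowMeans(cz))
  centroid_cyl <- cbind(r = sqrt(centroid[, 1]^2 + centroid[, 3]^2),
                        theta = atan2(centroid[, 3], centroid[, 1]) %% (2 * pi),
                        y = centroid[, 2])

  vols <- .hex_volumes(xyz, elems)
  if (vols$min_detJ <= 0)
    stop(sprintf("mesh generation produced an invalid element (min detJ = %g)",
                 vols$min_detJ))

  node_r <- sqrt(xyz[, 1]^2 + xyz[, 3]^2)
  r_out_node <- radii_at(spec, xyz[, 2])$outer
  node_sets <- list(
    distal_fixed_face = which(xyz[, 2] < 1e-9 &
                                node_r <= spec$collar_diameter / 2 + 1e-9),
    proximal_load_face = which(xyz[, 2] > spec$residual_length - 1e-9),
    outer_surface = which(node_r >= r_out_node - 1e-9))

  mesh <- structure(list(
    nodes = xyz, elems = elems, part = part, slice = slice,
    ring = meta$ring, sector = meta$sector, layer = meta$layer,
    height = meta$height, volume = vols$volume,
    centroid = centroid, centroid_cyl = centroid_cyl,
    node_sets = node_sets, spec = spec, slices = slices,
    divisions = div, order = spec$element_order,
    min_detJ = vols$min_detJ), class = "assembly_mesh")
  mesh
}

#' @export
print.assembly_mesh <- function(x, ...) {
  cat(sprintf(
    "<assembly_mesh> %d %s hexahedra, %d nodes (%d sectors x %d rings)\n",
    nrow(x$elems), x$order, nrow(x$nodes), x$divisions$ntheta,
    sum(x$divisions$nr)))
  v <- part_volumes(x)
  cat("  part volumes (cm^3):",
      paste(sprintf("%s %.2f", names(v), v * 1e6), collapse = ", "), "\n")
  if (any(!is.na(x$slice)))
    cat(sprintf("  slices assigned: %d\n", max(x$slice, na.rm = TRUE)))
  invisible(x)
}

#' Uniformly refine or coarsen an assembly mesh
#'
#' Rebuilds the mesh from its stored specification with every division
#' count scaled by `1 / factor`: `factor = 0.5` halves the element edge
#' length (8x the elements), `factor = 2` doubles it, and `factor = 1`
#' returns an identical mesh.  Part geometry and labels are preserved.
#'
#' @param mesh An [assembly_mesh()][build_assembly_mesh].
#' @param factor Positive refinement ratio relative to the current mesh.
#' @return A new `assembly_mesh`.
#' @export
refine <- function(mesh, factor) {
  stopifnot(inherits(mesh, "assembly_mesh"))
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0)
    stop("refinement factor must be a positive number")
  if (factor == 1) return(mesh)
  div <- scale_divisions(mesh$divisions, factor)
  build_mesh_core(mesh$spec, mesh$slices, div)
}

#' Assign remodelling slice indices to bone-layer elements
#'
#' Bins bone-layer elements into equidistant axial slices by centroid.
#' The slice band must lie within the axial extent of the bone layer and
#' every slice must receive at least one element.
#'
#' @param mesh An assembly mesh.
#' @param slices A [slice_spec()].
#' @return The mesh with its `slice` element field replaced.
#' @export
assign_slices <- function(mesh, slices) {
  stopifnot(inherits(mesh, "assembly_mesh"), inherits(slices, "slice_spec"))
  band_end <- slices$origin + slices$number_of_slices * slices$spacing
  if (slices$origin < -1e-12 || band_end > mesh$spec$stem_length + 1e-12)
    stop("slices lie outside the bone layer axial extent")
  yc <- mesh$centroid_cyl[, "y"]
  idx <- floor((yc - slices$origin) / slices$spacing) + 1L
  idx[yc < slices$origin | idx > slices$number_of_slices] <- NA_integer_
  idx[mesh$part != "bone_layer"] <- NA_integer_
  counts <- tabulate(idx, nbins = slices$number_of_slices)
  if (any(counts == 0))
    stop(sprintf("slice(s) %s contain no bone-layer elements; refine axially",
                 paste(which(counts == 0), collapse = ", ")))
  mesh$slice <- as.integer(idx)
  mesh$slices <- slices
  mesh
}

#' Meshed part volumes
#'
#' @param mesh An assembly mesh.
#' @return Named numeric vector of per-part meshed volumes (m^3).
#' @export
part_volumes <- function(mesh) {
  tapply(mesh$volume, mesh$part, sum, default = 0)
}

#' Analytic part volumes of the specified assembly
#'
#' Exact volumes of the cylindrical/conical shells described by the spec,
#' integrating the linearly tapering interface radii (Simpson's rule,
#' exact for the quadratic integrand).
#'
#' @param spec An [assembly_spec()].
#' @return Named numeric vector of volumes (m^3).
#' @export
analytic_part_volumes <- function(spec) {
  L <- spec$stem_length
  ann <- function(which_out, which_in, y) {
    r <- radii_at(spec, y)
    pi * (r[[which_out]]^2 - r[[which_in]]^2)
  }
  simpson <- function(f) (L / 6) * (f(0) + 4 * f(L / 2) + f(L))
  v <- c(
    stem = simpson(function(y) ann("stem", "bore", y)),
    cement = simpson(function(y) ann("cement", "stem", y)),
    bone_layer = simpson(function(y) ann("bone", "cement", y)),
    outer_bone = simpson(function(y) ann("outer", "bone", y)) +
      (spec$residual_length - L) * ann("outer", "bone", L))
  v
}

#' Cross-section properties of the meshed assembly at an axial station
#'
#' Per-part cross-sectional area and second moments of area at axial
#' position `y`, evaluated for the geometry the mesh actually represents:
#' polygonal boundaries for linear meshes (straight circumferential
#' chords) and circular boundaries for quadratic meshes (curved edges).
#' `Iz = int x^2 dA` governs bending about the global Z axis and
#' `Ix = int z^2 dA` bending about X.  Used by the transformed-section
#' verification oracles.
#'
#' @param mesh An assembly mesh.
#' @param y Axial station (m).
#' @return A data frame with columns `part`, `A`, `Ix`, `Iz`.
#' @export
section_properties <- function(mesh, y) {
  spec <- mesh$spec
  r <- radii_at(spec, y)
  radii <- rbind(bore = r$bore, stem = r$stem, cement = r$cement,
                 bone = r$bone, outer = r$outer)[, 1]
  if (mesh$order == "quadratic") {
    A_fun <- function(rr) pi * rr^2
    I_fun <- function(rr) pi * rr^4 / 4
  } else {
    n <- mesh$divisions$ntheta
    th <- 2 * pi * (seq_len(n) - 1) / n
    A_fun <- function(rr) {
      x <- rr * cos(th); z <- rr * sin(th)
      x2 <- c(x[-1], x[1]); z2 <- c(z[-1], z[1])
      sum(x * z2 - x2 * z) / 2
    }
    I_fun <- function(rr) {  # int x^2 dA of the inscribed n-gon
      x <- rr * cos(th); z <- rr * sin(th)
      x2 <- c(x[-1], x[1]); z2 <- c(z[-1], z[1])
      sum((x^2 + x * x2 + x2^2) * (x * z2 - x2 * z)) / 12
    }
  }
  lo <- c("bore", "stem", "cement", "bone")
  hi <- c("stem", "cement", "bone", "outer")
  present <- if (y > spec$stem_length + 1e-12)
    part_names == "outer_bone" else rep(TRUE, 4)
  Av <- vapply(radii, A_fun, numeric(1))
  Iv <- vapply(radii, I_fun, numeric(1))
  out <- data.frame(
    part = part_names,
    A = Av[hi] - Av[lo],
    Ix = Iv[hi] - Iv[lo],
    Iz = Iv[hi] - Iv[lo],
    row.names = NULL)
  out[present, , drop = FALSE]
}
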