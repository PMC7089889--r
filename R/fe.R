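#' Assemble the linear-elastic system for an assembly mesh
#'
#' Builds the global sparse stiffness matrix with full Gauss integration
#' (2x2x2 for linear, 3x3x3 for quadratic hexahedra).  Cylindrical-frame
#' material cards are rotated to the global frame per circumferential
#' sector at the element centroid angle.  The distal fixed node set is
#' constrained in all three components.
#'
#' @param mesh An assembly mesh.
#' @param materials Named list of [material_card()]s covering every part
#'   present in the mesh (`stem`, `cement`, `bone_layer`, `outer_bone`).
#' @return An object of class `fe_system` with the stiffness matrix, the
#'   per-element constitutive matrices and the constrained DOF
#'   bookkeeping.
#' @export
assemble <- function(mesh, materials) {
  stopifnot(inherits(mesh, "assembly_mesh"))
  parts <- levels(mesh$part)[unique(as.integer(mesh$part))]
  missing <- setdiff(parts, names(materials))
  if (length(missing))
    stop("missing material card(s) for part(s): ",
         paste(missing, collapse = ", "))
  Cm <- element_constitutive(mesh, materials)
  asm <- .hex_assemble(mesh$nodes, mesh$elems, Cm)
  if (asm$min_detJ <= 0)
    stop(sprintf("non-positive Jacobian in assembly (min detJ = %g)",
                 asm$min_detJ))
  n_dof <- 3L * nrow(mesh$nodes)
  K <- Matrix::sparseMatrix(i = asm$i, j = asm$j, x = asm$x,
                            dims = c(n_dof, n_dof))
  fixed_nodes <- mesh$node_sets$distal_fixed_face
  fixed <- as.vector(vapply(fixed_nodes, function(n) 3L * (n - 1L) + 1:3,
                            integer(3)))
  free <- setdiff(seq_len(n_dof), fixed)
  sys <- structure(list(K = K, mesh = mesh, materials = materials,
                        Cm = Cm, fixed = fixed, free = free,
                        cache = new.env(parent = emptyenv())),
                   class = "fe_system")
  sys
}

# one 6x6 constitutive matrix per element, flattened column-major
element_constitutive <- function(mesh, materials) {
  ne <- nrow(mesh$elems)
  Cm <- matrix(0, 36, ne)
  ntheta <- mesh$divisions$ntheta
  for (p in levels(mesh$part)) {
    sel <- which(mesh$part == p)
    if (!length(sel)) next
    card <- materials[[p]]
    if (card$frame == "cylindrical") {
      C0 <- stiffness_matrix(card)
      Q <- NULL
      for (j in sort(unique(mesh$sector[sel]))) {
        th <- 2 * pi * (j + 0.5) / ntheta
        M <- bond_matrix(cylindrical_basis(th))
        Cj <- M %*% C0 %*% t(M)
        Cm[, sel[mesh$sector[sel] == j]] <- as.vector(Cj)
      }
    } else {
      Cm[, sel] <- as.vector(stiffness_matrix(card))
    }
  }
  Cm
}

#' @export
print.fe_system <- function(x, ...) {
  cat(sprintf("<fe_system> %d DOF (%d fixed), %d elements\n",
              nrow(x$K), length(x$fixed), nrow(x$mesh$elems)))
  invisible(x)
}

#' Solve the constrained linear-elastic system
#'
#' Direct sparse Cholesky factorisation of the free-DOF stiffness.  The
#' factor is cached on the system object (in an environment) so repeated
#' load cases reuse it.  The relative residual must not exceed 1e-8 and
#' reaction forces are checked to balance the applied resultant.
#'
#' @param system An [assemble()]d `fe_system`.
#' @param loads Either a [load_case()] or a numeric nodal force vector of
#'   length `3 * n_nodes`.
#' @return A `displacement_field`: an `n_nodes x 3` matrix (m) with
#'   attributes `residual`, `reactions` (component sums) and `f`.
#' @export
fe_solve <- function(system, loads) {
  stopifnot(inherits(system, "fe_system"))
  f <- if (inherits(loads, "load_case"))
    equivalent_face_loads(loads, system$mesh) else as.numeric(loads)
  if (length(f) != nrow(system$K))
    stop("load vector length does not match the number of DOFs")
  free <- system$free
  cache <- system$cache
  if (is.null(cache$factor)) {
    cache$Kff <- system$K[free, free]
    cache$factor <- tryCatch(
      Matrix::Cholesky(Matrix::forceSymmetric(cache$Kff), LDL = FALSE,
                       super = TRUE),
      error = function(e)
        stop("system is not positive definite after constraints ",
             "(under-constrained model): ", conditionMessage(e)))
  }
  u_free <- as.numeric(Matrix::solve(cache$factor, f[free], system = "A"))
  fn <- sqrt(sum(f[free]^2))
  res <- if (fn > 0) {
    sqrt(sum((as.numeric(cache$Kff %*% u_free) - f[free])^2)) / fn
  } else 0
  if (res > 1e-8)
    stop(sprintf("solver failed to reach the residual contract: %.3g", res))
  u <- numeric(nrow(system$K))
  u[free] <- u_free
  reac <- as.numeric(system$K[system$fixed, , drop = FALSE] %*% u) -
    f[system$fixed]
  comp <- (system$fixed - 1L) %% 3L + 1L
  reactions <- vapply(1:3, function(k) sum(reac[comp == k]), numeric(1))
  U <- matrix(u, ncol = 3, byrow = TRUE)
  structure(U, class = "displacement_field", residual = res,
            reactions = reactions, f = f)
}

#' Strain, stress and strain-energy-density recovery
#'
#' Evaluates element-centroid strain and stress and the
#' integration-point-averaged strain energy density for a solved
#' displacement field.
#'
#' @param system The `fe_system` used for the solve.
#' @param u A `displacement_field` from [fe_solve()].
#' @return A `tensor_field`: list with `strain` and `stress`
#'   (6 x n_elements, Voigt order xx, yy, zz, yz, xz, xy with engineering
#'   shears), `sed` (J m^-3), `volume` (m^3) and the mesh.
#' @export
strain_stress <- function(system, u) {
  stopifnot(inherits(system, "fe_system"))
  U <- unclass(u)
  flds <- .hex_fields(system$mesh$nodes, system$mesh$elems, system$Cm, U)
  structure(list(strain = flds$strain, stress = flds$stress,
                 sed = flds$sed, volume = flds$volume,
                 mesh = system$mesh, u = U,
                 cache = new.env(parent = emptyenv())),
            class = "tensor_field")
}

#' Strain energy density field
#'
#' For a solved `tensor_field` the per-element SED is the
#' integration-point average of `U = sigma : epsilon / 2`; for a
#' hand-built field (lists with `stress`, `strain`, `volume`) it is
#' evaluated from the supplied tensors directly.  Negative densities
#' beyond round-off indicate an inconsistent constitutive state and raise
#' an error.
#'
#' @param tensors A `tensor_field` or a list with `strain`, `stress`
#'   (6 x n, engineering Voigt) and `volume`.
#' @return An object of class `sed_field`: list with `U` (J m^-3),
#'   `volume` (m^3), and when available `part` and `slice` vectors.
#' @export
sed <- function(tensors) {
  if (inherits(tensors, "tensor_field") && !is.null(tensors$sed)) {
    U <- tensors$sed
  } else {
    U <- 0.5 * colSums(tensors$stress * tensors$strain)
  }
  scale <- max(abs(U), 1)
  if (any(U < -1e-12 * scale))
    stop("negative strain energy density: inconsistent stress/strain pair")
  U <- pmax(U, 0)
  mesh <- tensors$mesh
  structure(list(U = U, volume = tensors$volume,
                 part = if (!is.null(mesh)) mesh$part,
                 slice = if (!is.null(mesh)) mesh$slice,
                 height = if (!is.null(mesh)) mesh$height),
            class = "sed_field")
}

#' Virtual uniaxial strain gauge site
#'
#' A gauge site on the periosteal (outer) bone surface, measuring axial
#' (global Y) strain over a finite gauge length, like the 1 mm foil
#' gauges bonded to the specimen.
#'
#' @param y Axial station of the gauge centre (m).
#' @param theta Circumferential angle (radians; 0 = lateral, pi = medial).
#' @param gauge_length Gauge length (m, default 0.001).
#' @param label Optional label.
#' @return An object of class `gauge_site`.
#' @export
gauge_site <- function(y, theta, gauge_length = 0.001, label = NULL) {
  stopifnot(is.finite(y), is.finite(theta), gauge_length > 0)
  structure(list(y = y, theta = theta %% (2 * pi),
                 gauge_length = gauge_length, label = label),
            class = "gauge_site")
}

#' Default gauge roster: distal/proximal pairs, medial and lateral
#'
#' Gauge 1 = distal medial, 2 = proximal medial, 3 = distal lateral,
#' 4 = proximal lateral, mirroring a two-level medial/lateral
#' instrumentation of the residual femur over the stem.
#'
#' @param y_distal,y_proximal Axial stations of the two gauge levels (m).
#' @return List of four [gauge_site()]s.
#' @export
default_gauge_sites <- function(y_distal = 0.030, y_proximal = 0.095) {
  list(gauge1 = gauge_site(y_distal, pi, label = "distal medial"),
       gauge2 = gauge_site(y_proximal, pi, label = "proximal medial"),
       gauge3 = gauge_site(y_distal, 0, label = "distal lateral"),
       gauge4 = gauge_site(y_proximal, 0, label = "proximal lateral"))
}

# nodal axial strain on the outer surface: strain evaluated at each
# element's own nodes (outermost-ring elements only), then averaged per
# node over incident elements; cached on the tensor field
surface_nodal_eyy <- function(tensors) {
  cache <- tensors$cache
  if (!is.null(cache$eyy)) return(cache$eyy)
  mesh <- tensors$mesh
  outer_ring <- max(mesh$ring[mesh$part == "outer_bone"])
  sel <- which(mesh$part == "outer_bone" & mesh$ring == outer_ring)
  surf_nodes <- mesh$node_sets$outer_surface
  conn <- mesh$elems[sel, , drop = FALSE]
  eyy_nodes <- .hex_nodal_eyy(mesh$nodes, conn, tensors$u)
  nid <- as.vector(t(conn))
  ee <- as.vector(eyy_nodes)
  keep <- nid %in% surf_nodes
  num <- tapply(ee[keep], nid[keep], sum)
  den <- tapply(rep(1, sum(keep)), nid[keep], sum)
  out <- list(nodes = as.integer(names(num)), eyy = as.numeric(num / den))
  cache$eyy <- out
  out
}

#' Read a virtual strain gauge
#'
#' Mean axial (YY) strain over the outer-surface nodes lying within the
#' gauge footprint: the axial window is the gauge length (or one local
#' element, if larger) centred at the site, restricted to the nearest
#' circumferential node column.  Falls back to the single nearest surface
#' node for degenerate footprints.
#'
#' @param tensors A `tensor_field` from [strain_stress()].
#' @param site A [gauge_site()].
#' @return Axial strain in microstrain.
#' @export
virtual_gauge <- function(tensors, site) {
  stopifnot(inherits(site, "gauge_site"))
  mesh <- tensors$mesh
  sn <- surface_nodal_eyy(tensors)
  X <- mesh$nodes[sn$nodes, , drop = FALSE]
  th <- atan2(X[, 3], X[, 1]) %% (2 * pi)
  dth <- abs((th - site$theta + pi) %% (2 * pi) - pi)
  sector_half <- pi / mesh$divisions$ntheta + 1e-9
  col_sel <- dth <= sector_half
  if (!any(col_sel))
    col_sel <- dth <= min(dth) + 1e-9
  # local element height at the gauge station (outer-ring elements)
  outer_sel <- mesh$part == "outer_bone"
  dy <- abs(mesh$centroid_cyl[outer_sel, "y"] - site$y)
  local_h <- mesh$height[outer_sel][which.min(dy)]
  half <- max(site$gauge_length, local_h) / 2
  in_window <- col_sel & abs(X[, 2] - site$y) <= half + 1e-12
  if (!any(in_window)) {
    dist <- abs(X[, 2] - site$y)
    dist[!col_sel] <- Inf
    if (!is.finite(min(dist))) stop("gauge footprint is empty")
    in_window <- dist <= min(dist) + 1e-12
  }
  mean(sn$eyy[in_window]) * 1e6
}

#' Displacement span over a region
#'
#' Span of one displacement component over a node region, taken between
#' the symmetric quantiles of a confidence interval so that outlying
#' nodal values are omitted (`ci = 0.95` spans the 2.5th to 97.5th
#' percentiles; `ci = 1` gives max - min).
#'
#' @param u A `displacement_field` (or any numeric matrix/vector).
#' @param axis 1/2/3 or "x"/"y"/"z".
#' @param region Node indices; required when `u` is a matrix.
#' @param ci Central fraction retained (default 0.95).
#' @return Span in the units of `u`.
#' @export
displacement_span <- function(u, axis = "y", region = NULL, ci = 0.95) {
  stopifnot(ci > 0, ci <= 1)
  vals <- if (is.matrix(u)) {
    k <- if (is.character(axis)) match(tolower(axis), c("x", "y", "z"))
    else as.integer(axis)
    if (is.null(region)) stop("a node region is required")
    if (length(region) == 0) stop("node region is empty")
    u[region, k]
  } else as.numeric(u)
  if (!length(vals)) stop("node region is empty")
  q <- stats::quantile(vals, c((1 - ci) / 2, 1 - (1 - ci) / 2),
                       names = FALSE, type = 7)
  q[2] - q[1]
}

#' Outer-surface node region emulating the camera-visible DIC patch
#'
#' @param mesh An assembly mesh.
#' @param y_range Axial window (m); default 20 mm above the distal end to
#'   just short of the proximal face.
#' @param theta_range Optional circumferential window (radians,
#'   `c(from, to)` anticlockwise); default the full circumference.
#' @return Integer node indices.
#' @export
dic_region <- function(mesh, y_range = c(0.02, 0.18), theta_range = NULL) {
  ids <- mesh$node_sets$outer_surface
  X <- mesh$nodes[ids, , drop = FALSE]
  keep <- X[, 2] >= y_range[1] & X[, 2] <= y_range[2]
  if (!is.null(theta_range)) {
    th <- atan2(X[, 3], X[, 1]) %% (2 * pi)
    span <- (theta_range[2] - theta_range[1]) %% (2 * pi)
    keep <- keep & ((th - theta_range[1]) %% (2 * pi)) <= span
  }
  ids[keep]
}

#' Energy balance of a solved case
#'
#' Compares total strain energy `sum(U * V)` with the external work
#' `f^T u / 2`; the two agree to round-off for a consistent solve.
#'
#' @param tensors A `tensor_field`.
#' @param u The corresponding `displacement_field`.
#' @return List with `strain_energy`, `external_work` (J) and
#'   `rel_error`.
#' @export
energy_balance <- function(tensors, u) {
  W_int <- sum(sed(tensors)$U * tensors$volume)
  f <- attr(u, "f")
  W_ext <- 0.5 * sum(f * as.numeric(t(unclass(u))))
  list(strain_energy = W_int, external_work = W_ext,
       rel_error = abs(W_int - W_ext) / max(abs(W_ext), .Machine$double.xmin))
}

#' Global equilibrium check of a solved case
#'
#' @param u A `displacement_field` from [fe_solve()].
#' @return List with `applied`, `reactions` (N, per component) and
#'   `rel_error` of their sum.
#' @export
equilibrium_check <- function(u) {
  f <- attr(u, "f")
  applied <- vapply(1:3, function(k)
    sum(f[seq(k, length(f), by = 3)]), numeric(1))
  reactions <- attr(u, "reactions")
  list(applied = applied, reactions = reactions,
       rel_error = sqrt(sum((applied + reactions)^2)) /
         max(sqrt(sum(applied^2)), .Machine$double.xmin))
}

#' Transformed-section oracle strains
#'
#' Closed-form axial and bending surface strains of the bonded concentric
#' composite, used to verify the solver: under a pure axial force the
#' far-field axial strain is `-F / sum(E_i A_i)`; under a bending moment
#' `Mz` about Z the axial strain at lateral offset `x` is
#' `Mz * x / sum(E_i Iz_i)`.  Areas and second moments come from
#' [section_properties()], i.e. from the geometry the mesh actually
#' represents, and the axial modulus of the orthotropic bone is EY.
#'
#' @param mesh An assembly mesh.
#' @param materials Named list of material cards.
#' @param F Axial force magnitude (N).
#' @param Mz Bending moment about Z (N m).
#' @param y Axial station (m).
#' @param x Lateral offset from the section axis (m).
#' @return Axial strain (dimensionless).
#' @export
composite_axial_strain <- function(mesh, materials, F, y = NULL) {
  if (is.null(y)) y <- mesh$spec$stem_length / 2
  sp <- section_properties(mesh, y)
  EA <- sum(vapply(seq_len(nrow(sp)), function(i)
    axial_modulus(materials[[sp$part[i]]]) * sp$A[i], numeric(1)))
  -F / EA
}

#' @rdname composite_axial_strain
#' @export
composite_bending_strain <- function(mesh, materials, Mz, y, x) {
  sp <- section_properties(mesh, y)
  EI <- sum(vapply(seq_len(nrow(sp)), function(i)
    axial_modulus(materials[[sp$part[i]]]) * sp$Iz[i], numeric(1)))
  Mz * x / EI
}

axial_modulus <- function(card) {
  if (card$kind == "isotropic") card$E else card$EY
}
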