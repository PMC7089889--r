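#' Elastic material card
#'
#' Defines an isotropic or orthotropic linear-elastic material.  Orthotropic
#' cards may be expressed in the cylindrical material frame used for
#' diaphyseal cortical bone, where the local X axis is radial, Y axial
#' (along the bone) and Z circumferential; such cards are rotated to the
#' global frame per element with [rotate_to_global()].
#'
#' Poisson ratios follow the compliance convention `nuXY = -eps_Y / eps_X`
#' under uniaxial stress along X, so the conjugate ratios follow from
#' compliance symmetry, `nuYX = nuXY * EY / EX`.
#'
#' @param kind "isotropic" or "orthotropic".
#' @param E,nu Young's modulus (Pa) and Poisson ratio (isotropic case).
#' @param EX,EY,EZ Directional Young's moduli (Pa, orthotropic case).
#' @param nuXY,nuYZ,nuXZ Poisson ratios (orthotropic case).
#' @param GXY,GYZ,GXZ Shear moduli (Pa, orthotropic case).
#' @param frame "global" or "cylindrical" (X = radial, Y = axial,
#'   Z = circumferential).
#' @param density Optional apparent density in g cm^-3.
#' @param name Optional label used in reports.
#' @return An object of class `material_card`.
#' @examples
#' cement <- material_card("isotropic", E = 2e9, nu = 0.40)
#' stiffness_matrix(cement)[1, 1]  # 4.286 GPa
#' @export
material_card <- function(kind = c("isotropic", "orthotropic"),
                          E = NULL, nu = NULL,
                          EX = NULL, EY = NULL, EZ = NULL,
                          nuXY = NULL, nuYZ = NULL, nuXZ = NULL,
                          GXY = NULL, GYZ = NULL, GXZ = NULL,
                          frame = c("global", "cylindrical"),
                          density = NULL, name = NULL) {
  kind <- match.arg(kind)
  frame <- match.arg(frame)
  card <- if (kind == "isotropic") {
    stopifnot(is.numeric(E), E > 0, is.numeric(nu), nu > -1, nu < 0.5)
    list(kind = kind, E = E, nu = nu, frame = frame)
  } else {
    mods <- c(EX = EX, EY = EY, EZ = EZ, GXY = GXY, GYZ = GYZ, GXZ = GXZ)
    if (any(!is.finite(mods)) || any(mods <= 0))
      stop("all orthotropic moduli must be positive and finite")
    list(kind = kind, EX = EX, EY = EY, EZ = EZ,
         nuXY = nuXY, nuYZ = nuYZ, nuXZ = nuXZ,
         GXY = GXY, GYZ = GYZ, GXZ = GXZ, frame = frame)
  }
  card$density <- density
  card$name <- name
  class(card) <- "material_card"
  # invariant: the resulting stiffness must be symmetric positive definite
  stiffness_matrix(card)
  card
}

#' @export
print.material_card <- function(x, ...) {
  if (x$kind == "isotropic") {
    cat(sprintf("<material_card> %s isotropic: E = %.4g GPa, nu = %.3g\n",
                if (is.null(x$name)) "" else x$name, x$E / 1e9, x$nu))
  } else {
    cat(sprintf(
      "<material_card> %s orthotropic (%s frame): E = (%.4g, %.4g, %.4g) GPa\n",
      if (is.null(x$name)) "" else x$name, x$frame,
      x$EX / 1e9, x$EY / 1e9, x$EZ / 1e9))
  }
  invisible(x)
}

#' Constitutive stiffness matrix in Voigt notation
#'
#' Returns the 6x6 stiffness matrix relating engineering strain
#' `(exx, eyy, ezz, gyz, gxz, gxy)` to stress, in the card's own frame.
#' The orthotropic matrix is obtained by inverting the compliance matrix
#' completed through compliance symmetry.  Inadmissible constants (a
#' non-positive-definite matrix) raise an error naming the offending
#' eigenvalue.
#'
#' @param card A [material_card()].
#' @return A symmetric positive-definite 6x6 matrix (Pa).
#' @export
stiffness_matrix <- function(card) {
  stopifnot(inherits(card, "material_card"))
  if (card$kind == "isotropic") {
    E <- card$E
    nu <- card$nu
    lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
    mu <- E / (2 * (1 + nu))
    C <- diag(c(rep(lam + 2 * mu, 3), rep(mu, 3)))
    C[1:3, 1:3][upper.tri(diag(3)) | lower.tri(diag(3))] <- lam
  } else {
    S <- matrix(0, 6, 6)
    S[1, 1] <- 1 / card$EX
    S[2, 2] <- 1 / card$EY
    S[3, 3] <- 1 / card$EZ
    S[1, 2] <- S[2, 1] <- -card$nuXY / card$EX
    S[1, 3] <- S[3, 1] <- -card$nuXZ / card$EX
    S[2, 3] <- S[3, 2] <- -card$nuYZ / card$EY
    S[4, 4] <- 1 / card$GYZ
    S[5, 5] <- 1 / card$GXZ
    S[6, 6] <- 1 / card$GXY
    C <- solve(S)
    C <- (C + t(C)) / 2
  }
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stop(sprintf(
      "elastic constants are inadmissible: stiffness eigenvalue %.4g <= 0",
      min(ev)))
  C
}

# Bond stress-transformation matrix for a rotation whose columns are the
# local material axes expressed in global coordinates (sigma_glob = Q sigma_loc Q^T).
bond_matrix <- function(Q) {
  a <- Q
  M <- matrix(0, 6, 6)
  idx <- list(c(1, 1), c(2, 2), c(3, 3), c(2, 3), c(1, 3), c(1, 2))
  for (r in 1:6) {
    i <- idx[[r]][1]; j <- idx[[r]][2]
    for (c in 1:3) M[r, c] <- a[i, c] * a[j, c]
    M[r, 4] <- a[i, 2] * a[j, 3] + a[i, 3] * a[j, 2]
    M[r, 5] <- a[i, 1] * a[j, 3] + a[i, 3] * a[j, 1]
    M[r, 6] <- a[i, 1] * a[j, 2] + a[i, 2] * a[j, 1]
  }
  M
}

#' Rotate a cylindrical-frame stiffness into the global frame
#'
#' For a card defined in the cylindrical material frame (X = radial,
#' Y = axial, Z = circumferential), returns the 6x6 stiffness in global
#' coordinates at circumferential angle `theta` (radians, measured from
#' the global +X axis towards +Z).  Cards already in the global frame are
#' returned unchanged with a warning.
#'
#' @param card A [material_card()].
#' @param theta Circumferential angle in radians.
#' @return A 6x6 stiffness matrix in the global frame.
#' @export
rotate_to_global <- function(card, theta) {
  C <- stiffness_matrix(card)
  if (card$frame != "cylindrical") {
    warning("card is already in the global frame; returning it unchanged")
    return(C)
  }
  Q <- cylindrical_basis(theta)
  M <- bond_matrix(Q)
  M %*% C %*% t(M)
}

# Local material axes (radial, axial, circumferential) in global coords.
cylindrical_basis <- function(theta) {
  cbind(c(cos(theta), 0, sin(theta)),
        c(0, 1, 0),
        c(-sin(theta), 0, cos(theta)))
}

#' Density--modulus power law
#'
#' Young's modulus from apparent density, `E = a * rho^b`, the standard
#' relation used to map bone mineral density to stiffness.
#'
#' @param a Coefficient in Pa per (g cm^-3)^b; must be positive.
#' @param b Dimensionless exponent; must be positive.
#' @return An object of class `power_law_card`.
#' @export
power_law_card <- function(a, b) {
  stopifnot(is.numeric(a), a > 0, is.numeric(b), b > 0)
  structure(list(a = a, b = b), class = "power_law_card")
}

#' @rdname power_law_card
#' @param rho Apparent density in g cm^-3; must be positive.
#' @param law A [power_law_card()].
#' @export
density_modulus <- function(rho, law) {
  stopifnot(inherits(law, "power_law_card"))
  if (any(!is.finite(rho)) || any(rho <= 0)) stop("density must be positive")
  law$a * rho^law$b
}

#' Baseline material cards for the implant assembly
#'
#' The stem is titanium alloy (E = 115 GPa, nu = 0.30), the cement mantle
#' PMMA (E = 2 GPa, nu = 0.40), and both bone parts use an idealised
#' orthotropic cortical bone model expressed in the cylindrical material
#' frame (EX = 12, EY = 20, EZ = 13.4 GPa).  Stem modulus variants
#' represent cobalt-chromium (210 GPa) and porous tantalum (20 GPa) stems.
#'
#' @param stem_modulus Stem Young's modulus in Pa (default 115 GPa).
#' @param bone_density Apparent cortical density in g cm^-3 used for
#'   SED-per-mass threshold conversion (default 1.8).
#' @return Named list of [material_card()]s with elements `stem`,
#'   `cement`, `bone_layer` and `outer_bone`.
#' @export
default_material_cards <- function(stem_modulus = 115e9, bone_density = 1.8) {
  bone <- material_card(
    "orthotropic",
    EX = 12e9, EY = 20e9, EZ = 13.4e9,
    nuXY = 0.22, nuYZ = 0.35, nuXZ = 0.38,
    GXY = 5.61e9, GYZ = 6.23e9, GXZ = 4.53e9,
    frame = "cylindrical", density = bone_density, name = "cortical bone")
  list(
    stem = material_card("isotropic", E = stem_modulus, nu = 0.30,
                         name = "stem"),
    cement = material_card("isotropic", E = 2e9, nu = 0.40, name = "PMMA"),
    bone_layer = bone,
    outer_bone = bone)
}

#' Read material cards from a YAML file
#'
#' The packaged defaults file `system.file("extdata", "materials.yaml",
#' package = "osseofe")` carries the baseline cards and the stem modulus
#' variants.
#'
#' @param path Path to a YAML file of material definitions.
#' @return Named list of [material_card()]s.
#' @export
read_material_cards <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(m) {
    do.call(material_card, m)
  })
}
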