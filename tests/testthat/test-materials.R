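cortical_bone_card <- function() default_material_cards()$bone_layer

test_that("isotropic stiffness matches the Lame closed form", {
  C <- stiffness_matrix(material_card("isotropic", E = 2e9, nu = 0.40))
  expect_equal(C[1, 1], 2e9 * (1 - 0.4) / ((1 + 0.4) * (1 - 2 * 0.4)))
  expect_equal(C[1, 1] / 1e9, 4.2857, tolerance = 1e-4)
  # nu = 0: normal block diagonal with E on the diagonal
  C0 <- stiffness_matrix(material_card("isotropic", E = 7e9, nu = 0))
  expect_equal(C0[1:3, 1:3], diag(rep(7e9, 3)))
})

test_that("the orthotropic cortical bone card is positive definite", {
  C <- stiffness_matrix(cortical_bone_card())
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  expect_equal(C, t(C))
})

test_that("completed compliance is symmetric (nu_ji = nu_ij Ej / Ei)", {
  b <- cortical_bone_card()
  S <- solve(stiffness_matrix(b))
  expect_equal(S, t(S), tolerance = 1e-12)
  # conjugate ratio recovered from the compliance matrix
  nuYX <- -S[1, 2] * b$EY
  expect_equal(nuYX, b$nuXY * b$EY / b$EX, tolerance = 1e-12)
})

test_that("inadmissible constants are rejected with the eigenvalue named", {
  expect_error(
    material_card("orthotropic", EX = 1e9, EY = 1e9, EZ = 1e9,
                  nuXY = 0.9, nuYZ = 0.9, nuXZ = 0.9,
                  GXY = 1e9, GYZ = 1e9, GXZ = 1e9),
    "eigenvalue")
})

test_that("strain energy is positive for random strains (PD property)", {
  C <- stiffness_matrix(cortical_bone_card())
  set.seed(42)
  for (i in 1:100) {
    e <- stats::rnorm(6)
    expect_gt(0.5 * sum(e * (C %*% e)), 0)
  }
})

test_that("frame rotation matches the explicit tensor-rotation oracle", {
  b <- cortical_bone_card()
  C <- stiffness_matrix(b)
  for (th in c(0.3, pi / 2, 2.1)) {
    Q <- osseofe:::cylindrical_basis(th)
    expect_equal(rotate_to_global(b, th), rotate_tensor_oracle(C, Q),
                 tolerance = 1e-10)
  }
})

test_that("zero rotation permutes the cylindrical axes onto global axes", {
  b <- cortical_bone_card()
  C <- stiffness_matrix(b)
  R0 <- rotate_to_global(b, 0)
  # at theta = 0 radial == +X, axial == +Y, circumferential == +Z
  expect_equal(R0, C, tolerance = 1e-12)
})

test_that("rotation leaves an isotropic card unchanged", {
  iso <- material_card("isotropic", E = 115e9, nu = 0.3,
                       frame = "cylindrical")
  C <- stiffness_matrix(iso)
  for (th in c(0.1, 1.0, 2.5))
    expect_equal(rotate_to_global(iso, th), C, tolerance = 1e-9)
})

test_that("a quarter turn swaps the radial and circumferential roles", {
  b <- cortical_bone_card()
  C <- stiffness_matrix(b)
  R <- rotate_to_global(b, pi / 2)
  # global X now aligned with -circumferential, global Z with +radial
  expect_equal(R[1, 1], C[3, 3], tolerance = 1e-9)
  expect_equal(R[3, 3], C[1, 1], tolerance = 1e-9)
  expect_equal(R[2, 2], C[2, 2], tolerance = 1e-9)
})

test_that("rotation preserves the bulk-stiffness invariant C_iijj", {
  b <- cortical_bone_card()
  C <- stiffness_matrix(b)
  for (th in c(0.7, 1.9))
    expect_equal(sum(rotate_to_global(b, th)[1:3, 1:3]),
                 sum(C[1:3, 1:3]), tolerance = 1e-12)
})

test_that("global-frame cards pass through rotation with a warning", {
  iso <- material_card("isotropic", E = 1e9, nu = 0.3)
  expect_warning(Cg <- rotate_to_global(iso, 1), "global")
  expect_equal(Cg, stiffness_matrix(iso))
})

test_that("the density-modulus power law evaluates directly", {
  expect_equal(density_modulus(2, power_law_card(10e9, 1)), 20e9)
  expect_equal(density_modulus(1, power_law_card(6.95e9, 2.4)), 6.95e9)
  expect_equal(density_modulus(1.8, power_law_card(6.95e9, 3)) / 1e9,
               40.5324)
  expect_error(density_modulus(-1, power_law_card(1e9, 2)), "positive")
})

test_that("packaged material defaults load from the YAML file", {
  cards <- read_material_cards(system.file("extdata", "materials.yaml",
                                           package = "osseofe"))
  expect_equal(cards$stem$E, 115e9)
  expect_equal(cards$stem_flexible$E, 20e9)
  expect_equal(cards$stem_stiff$E, 210e9)
  expect_equal(cards$bone$EY, 20e9)
  expect_equal(cards$bone$frame, "cylindrical")
})
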