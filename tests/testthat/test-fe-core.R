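test_that("single-element stiffness matches an independent quadrature oracle", {
  C <- stiffness_matrix(material_card("isotropic", E = 3e9, nu = 0.3))
  # a deliberately distorted hexahedron
  set.seed(11)
  X <- unit_cube(0.01) + matrix(stats::runif(24, -5e-4, 5e-4), 8, 3)
  conn <- matrix(1:8, 1)
  asm <- osseofe:::.hex_assemble(X, conn, matrix(as.vector(C), 36, 1))
  K <- matrix(0, 24, 24)
  K[cbind(asm$i, asm$j)] <- asm$x
  expect_equal(K, hex8_stiffness_oracle(X, C), tolerance = 1e-10)
  expect_equal(K, t(K), tolerance = 1e-9)
})

test_that("rigid-body motions produce zero internal force", {
  C <- stiffness_matrix(material_card("isotropic", E = 3e9, nu = 0.3))
  X <- unit_cube(0.01)
  asm <- osseofe:::.hex_assemble(X, matrix(1:8, 1),
                                 matrix(as.vector(C), 36, 1))
  K <- matrix(0, 24, 24)
  K[cbind(asm$i, asm$j)] <- asm$x
  u_trans <- rep(c(1e-3, -2e-3, 5e-4), 8)
  expect_equal(max(abs(K %*% u_trans)), 0, tolerance = 1e-9)
})

test_that("the assembled system is linear in the constitutive matrix", {
  m <- model_lc1_small()
  cards2 <- lapply(m$materials, function(cd) {
    if (cd$kind == "isotropic")
      material_card("isotropic", E = 2 * cd$E, nu = cd$nu)
    else
      material_card("orthotropic", EX = 2 * cd$EX, EY = 2 * cd$EY,
                    EZ = 2 * cd$EZ, nuXY = cd$nuXY, nuYZ = cd$nuYZ,
                    nuXZ = cd$nuXZ, GXY = 2 * cd$GXY, GYZ = 2 * cd$GYZ,
                    GXZ = 2 * cd$GXZ, frame = cd$frame)
  })
  sys2 <- assemble(m$mesh, cards2)
  d <- sys2$K - 2 * m$sys$K
  expect_lt(max(abs(d@x)) / max(abs(m$sys$K@x)), 1e-12)
})

test_that("missing material cards are reported", {
  m <- model_lc1_small()
  expect_error(assemble(m$mesh, m$materials[c("stem", "cement")]),
               "missing material card")
})

test_that("zero load gives zero displacement; solutions scale linearly", {
  m <- model_lc1_small()
  u0 <- fe_solve(m$sys, numeric(nrow(m$sys$K)))
  expect_equal(max(abs(u0)), 0)
  f <- equivalent_face_loads(lc1(), m$mesh)
  u2 <- fe_solve(m$sys, 2.5 * f)
  expect_equal(unclass(u2), 2.5 * unclass(m$u), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("residual and equilibrium contracts hold on the solved case", {
  m <- model_lc1_small()
  expect_lt(attr(m$u, "residual"), 1e-8)
  eq <- equilibrium_check(m$u)
  expect_lt(eq$rel_error, 1e-8)
  expect_equal(eq$applied, as.numeric(lc1()$F), tolerance = 1e-9)
})

test_that("energy balance holds: sum(U V) = f^T u / 2", {
  m <- model_lc1_small()
  eb <- energy_balance(m$tf, m$u)
  expect_lt(eb$rel_error, 1e-8)
  expect_gt(eb$strain_energy, 0)
})

test_that("a uniform stretch is reproduced exactly (patch test)", {
  m <- model_lc1_small()
  U <- cbind(0, 1e-4 * m$mesh$nodes[, 2], 0)
  fl <- osseofe:::.hex_fields(m$mesh$nodes, m$mesh$elems, m$sys$Cm, U)
  expect_equal(range(fl$strain[2, ]), c(1e-4, 1e-4), tolerance = 1e-10)
})

test_that("isotropic uniaxial stress shows the Poisson effect", {
  E <- 10e9; nu <- 0.3
  C <- stiffness_matrix(material_card("isotropic", E = E, nu = nu))
  # displacement field of uniaxial stress along y
  X <- unit_cube(0.01)
  eps_y <- 1e-4
  U <- cbind(-nu * eps_y * X[, 1], eps_y * X[, 2], -nu * eps_y * X[, 3])
  fl <- osseofe:::.hex_fields(X, matrix(1:8, 1),
                              matrix(as.vector(C), 36, 1), U)
  expect_equal(fl$strain[1, 1], -nu * eps_y, tolerance = 1e-12)
  expect_equal(fl$stress[2, 1], E * eps_y, tolerance = 1e-9)
  expect_equal(fl$stress[1, 1], 0, tolerance = 1e-3 * E * eps_y)
})

test_that("recovered strains match finite differences of the interpolant", {
  set.seed(3)
  X <- unit_cube(0.01) + matrix(stats::runif(24, -6e-4, 6e-4), 8, 3)
  Ue <- matrix(stats::rnorm(24, 0, 1e-5), 8, 3)
  C <- stiffness_matrix(material_card("isotropic", E = 1e9, nu = 0.25))
  fl <- osseofe:::.hex_fields(X, matrix(1:8, 1),
                              matrix(as.vector(C), 36, 1), Ue)
  expect_equal(fl$strain[, 1], hex8_fd_strain_oracle(X, Ue),
               tolerance = 1e-6)
})

test_that("SED closed forms hold for hand-built tensor fields", {
  # uniaxial stress
  E <- 5e9; sig <- 2e6
  tens <- list(stress = matrix(c(sig, 0, 0, 0, 0, 0)),
               strain = matrix(c(sig / E, 0, 0, 0, 0, 0)),
               volume = 1)
  expect_equal(sed(tens)$U, sig^2 / (2 * E))
  # pure shear
  G <- 2e9; gam <- 1e-3
  tens <- list(stress = matrix(c(0, 0, 0, G * gam, 0, 0)),
               strain = matrix(c(0, 0, 0, gam, 0, 0)), volume = 1)
  expect_equal(sed(tens)$U, G * gam^2 / 2)
  # zero strain
  tens <- list(stress = matrix(numeric(6)), strain = matrix(numeric(6)),
               volume = 1)
  expect_equal(sed(tens)$U, 0)
  # inconsistent pair is rejected
  bad <- list(stress = matrix(c(-1e6, 0, 0, 0, 0, 0)),
              strain = matrix(c(1e-4, 0, 0, 0, 0, 0)), volume = 1)
  expect_error(sed(bad), "negative strain energy")
})

test_that("axial strain of the bonded composite matches -F / sum(EA)", {
  m <- model_axial()
  oracle <- composite_axial_strain(m$mesh, m$materials, m$F, y = 0.12)
  g <- virtual_gauge(m$tf, gauge_site(0.12, 0))
  expect_equal(g, oracle * 1e6, tolerance = 0.02)
  # and the far field is uniform across parts
  mid <- abs(m$mesh$centroid_cyl[, "y"] - 0.12) < 0.01
  for (p in levels(m$mesh$part)) {
    sel <- mid & m$mesh$part == p
    expect_equal(mean(m$tf$strain[2, sel]), oracle, tolerance = 0.02)
  }
})

test_that("surface strain under a tip load follows Euler-Bernoulli", {
  m <- model_beam()
  r_out <- 0.014
  for (y in c(0.03, 0.05, 0.07)) {
    g <- virtual_gauge(m$tf, gauge_site(y, 0))
    oracle <- composite_bending_strain(m$mesh, m$materials,
                                       Mz = m$F * (m$L - y), y = y,
                                       x = r_out) * 1e6
    expect_equal(abs(g), abs(oracle), tolerance = 0.03)
  }
})

test_that("virtual gauges read constant and linear fields faithfully", {
  m <- model_lc1_small()
  mesh <- m$mesh
  # constant axial strain: u_y = c * y
  sysc <- m$sys
  U <- cbind(0, -5e-4 * mesh$nodes[, 2], 0)
  tf <- structure(list(strain = osseofe:::.hex_fields(
    mesh$nodes, mesh$elems, sysc$Cm, U)$strain,
    mesh = mesh, u = U, cache = new.env()), class = "tensor_field")
  expect_equal(virtual_gauge(tf, gauge_site(0.05, pi)), -500,
               tolerance = 1e-6)
  # strain linear in y: u_y = a y^2 / 2 -> eps_yy = a y
  a <- 1e-3
  U2 <- cbind(0, a * mesh$nodes[, 2]^2 / 2, 0)
  tf2 <- structure(list(strain = NULL, mesh = mesh, u = U2,
                        cache = new.env()), class = "tensor_field")
  g <- virtual_gauge(tf2, gauge_site(0.06, 0))
  expect_equal(g, a * 0.06 * 1e6, tolerance = 0.02)
})

test_that("displacement spans implement the percentile contract", {
  vals <- seq(0, 100, by = 1)
  expect_equal(displacement_span(vals, ci = 0.95), 95)
  expect_equal(displacement_span(vals, ci = 1), 100)
  set.seed(9)
  z <- stats::rnorm(1000)
  expect_equal(displacement_span(z, ci = 0.95), 2 * 1.96,
               tolerance = 0.05)
  expect_error(displacement_span(matrix(1, 2, 3), axis = "x",
                                 region = integer(0)), "empty")
})

test_that("the DIC region selects outer-surface nodes in the window", {
  mesh <- model_lc1_small()$mesh
  ids <- dic_region(mesh, y_range = c(0.03, 0.1))
  expect_gt(length(ids), 0)
  expect_true(all(mesh$nodes[ids, 2] >= 0.03 &
                    mesh$nodes[ids, 2] <= 0.1))
  r <- sqrt(mesh$nodes[ids, 1]^2 + mesh$nodes[ids, 3]^2)
  r_out <- osseofe:::radii_at(mesh$spec, mesh$nodes[ids, 2])$outer
  expect_true(all(abs(r - r_out) < 1e-8))
})
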