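small_spec <- function(element_edge_length = 0.006, ...) {
  assembly_spec(element_edge_length = element_edge_length, ...)
}

test_that("spec invariants are enforced", {
  expect_s3_class(assembly_spec(), "assembly_spec")
  expect_error(assembly_spec(stem_length = -1), "positive")
  expect_error(assembly_spec(stem_diameter_proximal = 0.013), "taper")
  expect_error(assembly_spec(cement_thickness_proximal = 5e-4),
               "distal value")
  expect_error(assembly_spec(stem_length = 0.3), "residual")
  expect_error(assembly_spec(stem_bore_diameter = 0.01), "bore")
  expect_error(assembly_spec(sectors = 13), "multiple of 4")
})

test_that("meshed part volumes match the analytic shell volumes within 1%", {
  for (spec in list(small_spec(),
                    small_spec(cement_taper_rule = "uniform"))) {
    mesh <- build_assembly_mesh(spec)
    pv <- part_volumes(mesh)
    av <- analytic_part_volumes(spec)
    expect_equal(as.numeric(pv), as.numeric(av), tolerance = 0.01)
  }
})

test_that("a quadratic mesh captures the curved boundaries almost exactly", {
  spec <- small_spec(element_order = "quadratic", sectors = 16,
                     residual_length = 0.1, stem_length = 0.06)
  mesh <- build_assembly_mesh(spec)
  expect_equal(as.numeric(part_volumes(mesh)),
               as.numeric(analytic_part_volumes(spec)), tolerance = 1e-3)
  expect_gt(mesh$min_detJ, 0)
})

test_that("parts tile the assembly with no gaps or overlaps", {
  mesh <- build_assembly_mesh(small_spec())
  expect_equal(sum(part_volumes(mesh)), sum(mesh$volume),
               tolerance = 1e-9)
  # all four parts present, interfaces share nodes (conforming count)
  expect_setequal(levels(mesh$part)[unique(as.integer(mesh$part))],
                  c("stem", "cement", "bone_layer", "outer_bone"))
  expect_gt(mesh$min_detJ, 0)
})

test_that("mesh generation is deterministic", {
  m1 <- build_assembly_mesh(small_spec(), slice_spec())
  m2 <- build_assembly_mesh(small_spec(), slice_spec())
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$elems, m2$elems)
})

test_that("centroid cylindrical coordinates satisfy r^2 = x^2 + z^2", {
  mesh <- build_assembly_mesh(small_spec())
  expect_equal(mesh$centroid_cyl[, "r"]^2,
               mesh$centroid[, 1]^2 + mesh$centroid[, 3]^2,
               tolerance = 1e-12)
})

test_that("node sets are populated and sit where they should", {
  mesh <- build_assembly_mesh(small_spec())
  fixed <- mesh$node_sets$distal_fixed_face
  expect_gt(length(fixed), 0)
  expect_true(all(mesh$nodes[fixed, 2] < 1e-9))
  r_fixed <- sqrt(mesh$nodes[fixed, 1]^2 + mesh$nodes[fixed, 3]^2)
  expect_true(all(r_fixed <= mesh$spec$collar_diameter / 2 + 1e-9))
  top <- mesh$node_sets$proximal_load_face
  expect_true(all(abs(mesh$nodes[top, 2] - mesh$spec$residual_length)
                  < 1e-9))
})

test_that("uniform cement rule keeps a constant mantle thickness", {
  spec <- small_spec(cement_taper_rule = "uniform")
  for (y in c(0, 0.05, spec$stem_length)) {
    r <- osseofe:::radii_at(spec, y)
    expect_equal(r$cement - r$stem, spec$cement_thickness_distal)
  }
})

test_that("halving the edge length scales the element count by ~8", {
  m1 <- build_assembly_mesh(small_spec(sectors = 16))
  m2 <- build_assembly_mesh(small_spec(element_edge_length = 0.003,
                                       sectors = 32))
  expect_equal(nrow(m2$elems) / nrow(m1$elems), 8, tolerance = 0.25)
})

test_that("refine preserves geometry and is exact at factor 1", {
  mesh <- build_assembly_mesh(small_spec(sectors = 16), slice_spec())
  expect_identical(refine(mesh, 1), mesh)
  coarse <- refine(mesh, 2)
  expect_lt(nrow(coarse$elems), nrow(mesh$elems))
  expect_equal(as.numeric(part_volumes(coarse)),
               as.numeric(analytic_part_volumes(mesh$spec)),
               tolerance = 0.01)
  fine <- refine(mesh, 0.5)
  expect_gt(nrow(fine$nodes), nrow(mesh$nodes))
  expect_equal(nrow(fine$elems), 8L * nrow(mesh$elems))
  expect_error(refine(mesh, 0), "positive")
})

test_that("slices are assigned one per element band with positive areas", {
  mesh <- build_assembly_mesh(small_spec(), slice_spec())
  sl <- mesh$slice[!is.na(mesh$slice)]
  expect_setequal(unique(sl), 1:11)
  expect_true(all(mesh$part[!is.na(mesh$slice)] == "bone_layer"))
  # per-slice cross-section area approximates the bone-layer annulus
  for (s in c(1, 6, 11)) {
    sel <- which(mesh$slice == s)
    area <- sum(mesh$volume[sel] / mesh$height[sel])
    y_mid <- (s - 0.5) * 0.00109
    r <- osseofe:::radii_at(mesh$spec, y_mid)
    expect_equal(area, pi * (r$bone^2 - r$cement^2), tolerance = 0.02)
  }
})

test_that("out-of-band slice specs are rejected", {
  mesh <- build_assembly_mesh(small_spec())
  expect_error(assign_slices(mesh, slice_spec(spacing = 0.02)),
               "outside the bone layer")
  expect_error(build_assembly_mesh(small_spec(stem_length = 0.011),
                                   slice_spec()),
               "beyond the bone layer")
})
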