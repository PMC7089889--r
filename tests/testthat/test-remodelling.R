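fake_sed_field <- function(U, area, slice = rep(1L, length(U)),
                           height = 1) {
  structure(list(U = U, volume = area * height, slice = slice,
                 height = rep(height, length(U)), part = NULL),
            class = "sed_field")
}

test_that("threshold conversion to volumetric SED bounds is linear", {
  expect_equal(as.numeric(sed_bounds(thresholds())), c(6480, 7920))
  expect_equal(as.numeric(sed_bounds(thresholds(density = 3.6))),
               2 * c(6480, 7920))
  b <- sed_bounds(thresholds(lower = 0.0044 - 1e-9, upper = 0.0044))
  expect_lt(b["upper"] - b["lower"], 1e-2)
  expect_error(thresholds(lower = 0.005, upper = 0.004), "lower < upper")
  expect_error(thresholds(density = 0), "density")
})

test_that("classification splits slice areas across the band correctly", {
  t <- thresholds()
  # all within
  r <- classify(fake_sed_field(rep(7000, 4), rep(1, 4)), t = t)
  expect_equal(as.numeric(r[1, c("fraction_below", "fraction_within",
                                 "fraction_above")]), c(0, 1, 0))
  # two-bin split
  r <- classify(fake_sed_field(c(5000, 9000), c(1, 1)), t = t)
  expect_equal(as.numeric(r[1, c("fraction_below", "fraction_within",
                                 "fraction_above")]), c(0.5, 0, 0.5))
  # hand-weighted three-element slice
  r <- classify(fake_sed_field(c(6000, 7000, 8000), c(1, 2, 1)), t = t)
  expect_equal(as.numeric(r[1, c("fraction_below", "fraction_within",
                                 "fraction_above")]), c(0.25, 0.5, 0.25))
  expect_equal(r$area[1], 4)
})

test_that("fractions sum to one in every slice of a solved sweep", {
  sw <- model_sweep()$sweep
  for (r in sw$reports) {
    expect_equal(r$fraction_below + r$fraction_within + r$fraction_above,
                 rep(1, nrow(r)), tolerance = 1e-12)
    expect_true(all(r$area > 0))
    expect_equal(nrow(r), 11)
  }
})

test_that("mean bone-layer SED decreases as the stem stiffens", {
  sw <- model_sweep()$sweep
  expect_true(all(diff(sw$peaks$mean_sed_bone_layer) < 0))
  expect_true(all(diff(sw$peaks$peak_sed_bone_layer) < 0))
  expect_true(all(diff(sw$peaks$peak_sed_periosteal) < 0))
  expect_true(all(sw$peak_changes$peak_sed_bone_layer_pct > 0))
})

test_that("apposition shrinks and resorption grows with stem stiffness", {
  sw <- model_sweep()$sweep
  rep20 <- sw$reports[[1]]; rep115 <- sw$reports[[2]]
  rep210 <- sw$reports[[3]]
  distal <- 1:5
  # per-slice monotone direction across moduli
  expect_true(all(rep115$fraction_above <= rep20$fraction_above + 1e-12))
  expect_true(all(rep210$fraction_above <= rep115$fraction_above + 1e-12))
  expect_true(all(rep115$fraction_below >= rep20$fraction_below - 1e-12))
  expect_true(all(rep210$fraction_below >= rep115$fraction_below - 1e-12))
  # strictly, over the distal slices in aggregate
  expect_gt(sum(rep20$fraction_above[distal]),
            sum(rep210$fraction_above[distal]))
  expect_lt(sum(rep20$fraction_below[distal]),
            sum(rep210$fraction_below[distal]))
})

test_that("apposition falls and resorption rises moving proximally", {
  sw <- model_sweep()$sweep
  for (k in c(2, 3)) {  # baseline and stiff stems
    tr <- trend(sw$reports[[k]])
    expect_lt(tr["apposition_pct"], 0)
    expect_gt(tr["resorption_pct"], 0)
  }
})

test_that("quadrupling the load scales SED by sixteen", {
  m <- model_lc1_small()
  f <- equivalent_face_loads(lc1(), m$mesh)
  u4 <- fe_solve(m$sys, 4 * f)
  tf4 <- strain_stress(m$sys, u4)
  expect_equal(sed(tf4)$U, 16 * sed(m$tf)$U, tolerance = 1e-9)
})

test_that("trend summarises per-step relative changes", {
  mk_report <- function(above, below) {
    r <- data.frame(slice = seq_along(above), area = 1,
                    fraction_below = below,
                    fraction_within = 1 - above - below,
                    fraction_above = above)
    class(r) <- c("slice_report", "data.frame")
    r
  }
  r <- mk_report(rep(0.4, 5), rep(0.1, 5))
  expect_equal(as.numeric(trend(r)), c(0, 0))
  r <- mk_report(c(0.1, 0.2, 0.4), c(0.1, 0.2, 0.4))
  expect_equal(as.numeric(trend(r)), c(100, 100))
  r <- mk_report(c(0.4, 0.3, 0.2), c(0.2, 0.2, 0.2))
  expect_equal(as.numeric(trend(r))[1], -29.16667, tolerance = 1e-6)
  # zero baselines are skipped with a note
  r <- mk_report(c(0, 0.2, 0.4), c(0.1, 0.1, 0.1))
  expect_message(tr <- trend(r), "skipped")
  expect_equal(as.numeric(tr)[1], 100)
})

test_that("repeated moduli give identical reports", {
  m <- model_lc1_small()
  sw <- stiffness_sweep(m$mesh, m$materials, lc2(),
                        moduli = c(115e9, 115e9))
  expect_equal(sw$reports[[1]], sw$reports[[2]])
})
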