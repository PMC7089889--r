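# Solved models shared across test files (built once per test run).

.model_cache <- new.env(parent = emptyenv())

cached_model <- function(name, build) {
  if (is.null(.model_cache[[name]])) .model_cache[[name]] <- build()
  .model_cache[[name]]
}

# coarse meshed baseline assembly, validation load case solved
model_lc1_small <- function() cached_model("lc1_small", function() {
  spec <- assembly_spec(element_edge_length = 0.004, sectors = 16)
  mesh <- build_assembly_mesh(spec, slice_spec())
  materials <- default_material_cards()
  sys <- assemble(mesh, materials)
  u <- fe_solve(sys, lc1())
  tf <- strain_stress(sys, u)
  list(spec = spec, mesh = mesh, materials = materials, sys = sys,
       u = u, tf = tf)
})

# stem stiffness sweep on a mesh with enough circumferential resolution
# for stable area fractions
model_sweep <- function() cached_model("sweep", function() {
  spec <- assembly_spec(element_edge_length = 0.004)
  mesh <- build_assembly_mesh(spec, slice_spec())
  materials <- default_material_cards()
  sweep <- stiffness_sweep(mesh, materials, lc2())
  list(mesh = mesh, materials = materials, sweep = sweep)
})

# long uniform-section bonded composite under pure axial load (the
# transformed-section verification geometry)
model_axial <- function() cached_model("axial", function() {
  spec <- assembly_spec(stem_length = 0.24, residual_length = 0.26,
                        stem_diameter_distal = 0.012,
                        stem_diameter_proximal = 0.012,
                        cement_taper_rule = "uniform",
                        element_edge_length = 0.005)
  mesh <- build_assembly_mesh(spec)
  materials <- default_material_cards()
  sys <- assemble(mesh, materials)
  u <- fe_solve(sys, load_case(0, -842.8, 0, lever_arm = c(0, 0, 0)))
  tf <- strain_stress(sys, u)
  list(spec = spec, mesh = mesh, materials = materials, sys = sys,
       u = u, tf = tf, F = 842.8)
})

# homogeneous uniform cylinder under a transverse tip load, quadratic
# elements (the beam-theory verification geometry)
model_beam <- function() cached_model("beam", function() {
  spec <- assembly_spec(stem_length = 0.10, residual_length = 0.12,
                        stem_diameter_distal = 0.012,
                        stem_diameter_proximal = 0.012,
                        cement_taper_rule = "uniform",
                        element_edge_length = 0.005,
                        element_order = "quadratic", sectors = 16)
  mesh <- build_assembly_mesh(spec)
  iso <- material_card("isotropic", E = 20e9, nu = 0.3)
  materials <- list(stem = iso, cement = iso, bone_layer = iso,
                    outer_bone = iso)
  sys <- assemble(mesh, materials)
  u <- fe_solve(sys, load_case(100, 0, 0, lever_arm = c(0, 0, 0)))
  tf <- strain_stress(sys, u)
  list(spec = spec, mesh = mesh, materials = materials, sys = sys,
       u = u, tf = tf, F = 100, L = 0.12)
})

# three-level mesh convergence study of the gauge strains under the
# validation load; gauge sites sit on stations present at every level
model_richardson <- function() cached_model("richardson", function() {
  spec <- assembly_spec(element_edge_length = 0.004, sectors = 16)
  materials <- default_material_cards()
  sites <- list(g1 = gauge_site(0.032, pi), g2 = gauge_site(0.096, pi),
                g3 = gauge_site(0.032, 0), g4 = gauge_site(0.096, 0))
  base <- build_assembly_mesh(spec)
  vals <- vapply(c(2, 1, 0.5), function(f) {
    mesh <- refine(base, f)
    sys <- assemble(mesh, default_material_cards())
    u <- fe_solve(sys, lc1())
    tf <- strain_stress(sys, u)
    vapply(sites, function(s) virtual_gauge(tf, s), numeric(1))
  }, numeric(length(sites)))
  list(values = t(vals), sites = sites)  # rows: coarse, base, fine
})
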