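test_that("equal concentrations everywhere are a fixed point without flux or removal", {
  grid <- coarse_grid()
  params <- transport_params(J_sc = 0, v_b = 0)  # k_pcl, k_e follow v_b
  ops <- assemble_operators(grid, params)
  st <- zero_state(ops)
  cval <- 3.7
  st$C_vs[] <- cval; st$C_b[] <- cval; st$C_vp <- cval; st$C_ap <- cval
  r <- transport_rhs(st, ops)
  expect_lt(max(abs(r$dC_vs)), 1e-12 * cval)
  expect_lt(max(abs(r$dC_b)), 1e-12 * cval)
  expect_lt(abs(r$dC_vp), 1e-12 * cval)
  expect_lt(abs(r$dC_ap), 1e-12 * cval)
})

test_that("endothelial exchange is k_p times the concentration jump per unit area", {
  ops <- coarse_ops()
  st <- zero_state(ops)
  st$C_vs[] <- 1  # C_vs - C_b = 1 at every lumen surface element
  r_b <- transport_rhs(st, ops)$dC_b
  cp <- ops$coupling
  expected <- 1e-6 * ops$deg / (cp$A_cl * ops$ds_m)  # k_p = 1e-6 m/s
  expect_equal(r_b, expected, tolerance = 1e-12)
  # and zero flux at equality
  st$C_b[] <- 1
  r0 <- transport_rhs(st, ops)
  expect_lt(max(abs(r0$dC_b - advection_rates(st$C_b, st$C_ap, 6.5e-4,
                                              cp$k_pcl, ops$ds_m))),
            1e-15)
})

test_that("zero state stays zero without flux; influx first touches only the top layer", {
  ops0 <- assemble_operators(coarse_grid(), transport_params(J_sc = 0))
  tr <- simulate(grid = coarse_grid(), params = transport_params(J_sc = 0),
                 t_end = 1)
  st <- tr$states[[1]]
  expect_equal(max(abs(st$C_vs)), 0)
  expect_equal(st$C_vp, 0)

  ops <- coarse_ops()
  one <- step(zero_state(ops), dt_stable(ops, "explicit"), ops, "explicit")
  tmap <- tissue_index_map(coarse_grid())
  top <- tmap[, , 1][tmap[, , 1] > 0]
  expect_true(all(one$C_vs[top] > 0))
  expect_equal(max(abs(one$C_vs[-top])), 0)
})

test_that("IMEX and explicit marching conserve mass up to boundary fluxes", {
  for (m in c("imex", "explicit")) {
    tr <- simulate(grid = coarse_grid(), params = transport_params(),
                   t_end = 2, output_times = c(1, 2), method = m)
    expect_lt(max(abs(tr$mass_log$residual_rel)), 1e-10)
    expect_true(all(tr$states[[2]]$C_vs >= 0))
    expect_true(all(tr$states[[2]]$C_b >= 0))
  }
})

test_that("a destabilising time step is rejected with a diagnostic", {
  ops <- coarse_ops()
  st <- random_state(ops)
  expect_error(step(st, 1e4, ops, "explicit"), "dt|negative|finite")
})

test_that("a periodic cosine mode decays at the analytic diffusion rate", {
  geom <- build_unit_cell(box_geometry())
  grid <- classify_nodes(geom, 20, include_loop = FALSE)
  params <- transport_params(J_sc = 0, v_b = 0)
  ops <- assemble_operators(grid, params)
  Lx <- geom$cell_length * 1e-6
  lam <- params$D_vs * (2 * pi / Lx)^2
  xs <- (array(grid$x, dim = grid$dims) * 1e-6)[ops$tmap > 0]
  st <- zero_state(ops)
  st$C_vs <- 1 + 0.5 * cos(2 * pi * xs / Lx)  # offset keeps positivity
  t_end <- 5
  tr <- simulate(grid = grid, params = params, t_end = t_end, dt = 0.02,
                 init = st)
  exact <- 1 + 0.5 * cos(2 * pi * xs / Lx) * exp(-lam * t_end)
  err <- sqrt(mean((tr$states[[1]]$C_vs - exact)^2))
  expect_lt(err, 5e-3)  # dominated by the O(dx^2) spatial error at 20 um
})

test_that("diffusion-only steady state matches the linear closed form", {
  geom <- build_unit_cell(box_geometry())
  params <- transport_params(v_b = 0, k_p = 0)
  st <- steady_state(geom, params, resolution = 20, bottom_bc = "sink",
                     include_loop = FALSE)
  expect_true(attr(st, "converged"))
  ops <- attr(st, "ops")
  z_m <- (array(rep(ops$grid$z, each = prod(ops$grid$dims[1:2])),
                dim = ops$grid$dims))[ops$tmap > 0] * 1e-6
  L_m <- geom$params$slab_depth * 1e-6
  exact <- params$J_sc * (L_m - z_m) / params$D_vs
  expect_lt(max(abs(st$C_vs - exact)) / max(exact), 1e-6)
})

test_that("pure accumulation has no steady state and is flagged", {
  geom <- build_unit_cell(box_geometry())
  params <- transport_params(v_b = 0, k_p = 0)
  expect_warning(
    st <- steady_state(geom, params, resolution = 20,
                       bottom_bc = "zero_flux", include_loop = FALSE),
    "non-converged")
  expect_false(attr(st, "converged"))
})

test_that("the steady solver satisfies the semi-discrete equations it claims to solve", {
  ops <- coarse_ops()
  sys <- plexisim:::steady_system(ops)
  st <- random_state(ops)
  u <- c(st$C_vs, st$C_b, st$C_vp, st$C_ap)
  r <- transport_rhs(st, ops)
  rv <- c(r$dC_vs, r$dC_b, r$dC_vp, r$dC_ap)
  expect_lt(max(abs(as.numeric(sys$A %*% u) + sys$b - rv)) / max(abs(rv)),
            1e-12)

  st_ss <- coarse_steady()
  expect_true(attr(st_ss, "converged"))
  expect_lt(attr(st_ss, "steadiness"), 1e-6)
  expect_true(all(st_ss$C_vs >= 0))
  expect_gt(st_ss$C_vp, st_ss$C_ap)  # loop outlet feeds the venule layer
})

test_that("laterally averaged outputs are invariant to a periodic lateral shift", {
  geom <- build_unit_cell(box_geometry())
  grid <- classify_nodes(geom, 20, include_loop = FALSE)
  params <- transport_params(v_b = 0)
  ops <- assemble_operators(grid, params)
  tmap <- tissue_index_map(grid)
  set.seed(11)
  f <- array(stats::runif(prod(grid$dims)), dim = grid$dims)
  f_shift <- f[c(grid$dims[1], seq_len(grid$dims[1] - 1)), , ]
  run <- function(arr) {
    st <- zero_state(ops)
    st$C_vs <- arr[tmap > 0]
    tr <- simulate(grid = grid, params = params, t_end = 1, dt = 0.05,
                   init = st, include_loop = FALSE)
    prof <- depth_profile(tr$states[[1]], grid, "lateral_mean", params)
    prof$concentration
  }
  expect_equal(run(f), run(f_shift), tolerance = 1e-12)
})

test_that("a zero-length horizon returns only the initial state", {
  tr <- simulate(grid = coarse_grid(), params = transport_params(),
                 t_end = 0)
  expect_length(tr$states, 1L)
  expect_equal(tr$states[[1]]$time, 0)
  expect_equal(max(abs(tr$states[[1]]$C_vs)), 0)
})
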