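test_that("uniform fields give constant profiles and trivial statistics", {
  grid <- coarse_grid()
  params <- transport_params(J_sc = 0)
  ops <- assemble_operators(grid, params)
  st <- zero_state(ops)
  cval <- 2.5
  st$C_vs[] <- cval; st$C_b[] <- cval; st$C_vp <- cval; st$C_ap <- cval
  for (tg in c("arteriole_adjacent", "venule_adjacent", "lateral_mean")) {
    prof <- depth_profile(st, grid, tg, params)
    expect_equal(prof$concentration, rep(cval, grid$dims[[3]]))
  }
  prof <- depth_profile(st, grid, "lateral_mean", params)
  expect_equal(top_bottom_ratio(prof), 1)  # J_sc = 0: surface equals bulk

  cp <- ops$coupling
  expect_equal(plexus_mean_concentration(st, cp), cval)
  st$C_vp <- 2; st$C_ap <- 0  # equal volumes: mean is 1
  expect_equal(plexus_mean_concentration(st, cp), 1)
  expect_error(depth_profile(st, grid, "no_such_line"), "tag")
})

test_that("surfaceless or zero-surface profiles are rejected by the ratio", {
  grid <- coarse_grid()
  st <- zero_state(coarse_ops())
  prof_nosurf <- depth_profile(st, grid, "lateral_mean")  # no params given
  expect_error(top_bottom_ratio(prof_nosurf), "surface")
  prof0 <- depth_profile(st, grid, "lateral_mean",
                         transport_params(J_sc = 0))
  expect_error(top_bottom_ratio(prof0), "zero")
})

test_that("standard steady profiles reproduce the published shape", {
  st <- coarse_steady()
  ops <- attr(st, "ops")
  pa <- depth_profile(st, ops$grid, "arteriole_adjacent", transport_params())
  pv <- depth_profile(st, ops$grid, "venule_adjacent", transport_params())
  # venule-adjacent concentrations dominate just above the plexus
  band <- pa$depth_um >= 350 & pa$depth_um <= 400
  expect_true(all(pv$concentration[band] >= pa$concentration[band]))
  # concentration decreases with depth down to the plexus...
  upper <- pa$depth_um < 350
  expect_true(all(diff(pa$concentration[upper]) < 0))
  # ...reaches its minimum in or near the plexus, and is higher below it
  k_min <- which.min(pa$concentration)
  expect_gte(pa$depth_um[k_min], 350)
  expect_lte(pa$depth_um[k_min], 460)
  below <- pa$depth_um >= 450 & pa$depth_um < 500
  expect_gt(mean(pa$concentration[below]), min(pa$concentration))
})

test_that("below/top ratio equals the linear closed form for pure diffusion", {
  geom <- build_unit_cell(box_geometry())
  params <- transport_params(v_b = 0, k_p = 0)
  st <- steady_state(geom, params, resolution = 20, bottom_bc = "sink",
                     include_loop = FALSE)
  prof <- depth_profile(st, attr(st, "ops")$grid, "lateral_mean", params)
  # C(z) = J (L - z) / D: band mean over [450, 500) vs surface value
  L <- 800e-6
  zs <- prof$depth_um[prof$depth_um >= 450 & prof$depth_um < 500] * 1e-6
  expected <- mean(L - zs) / L
  expect_equal(top_bottom_ratio(prof), expected, tolerance = 1e-6)
})

test_that("sealing the endothelium starves the plexus compartments", {
  grid <- coarse_grid()
  cp <- plexus_coupling(grid, transport_params())
  open <- simulate(grid = grid, params = transport_params(),
                   t_end = 5)$states[[1]]
  sealed <- simulate(grid = grid, params = transport_params(k_p = 0),
                     t_end = 5)$states[[1]]
  expect_gt(plexus_mean_concentration(open, cp),
            plexus_mean_concentration(sealed, cp))
  expect_equal(plexus_mean_concentration(sealed, cp), 0)
})

test_that("a single-value sweep equals a standalone run and repeats bit-identically", {
  sw <- run_sweep("velocity", 6.5e-4, geometry = coarse_geometry(),
                  resolution = 20)
  st <- coarse_steady()
  cp <- attr(st, "ops")$coupling
  expect_equal(sw$C_plex, plexus_mean_concentration(st, cp))
  sw2 <- run_sweep("velocity", 6.5e-4, geometry = coarse_geometry(),
                   resolution = 20)
  expect_identical(sw$C_plex, sw2$C_plex)
  expect_identical(sw$profiles[[1]]$lateral_mean$concentration,
                   sw2$profiles[[1]]$lateral_mean$concentration)
})

test_that("velocity and density sweeps reproduce the published orderings", {
  vs <- c(1, 0.75, 0.5, 0.25, 0.1) * 6.5e-4
  sw <- run_sweep("velocity", vs, geometry = coarse_geometry(),
                  resolution = 20)
  expect_true(all(sw$converged))
  # slower blood leaves more drug in and above the plexus
  expect_true(all(diff(sw$C_plex) > 0))  # vs are descending
  above <- vapply(sw$profiles, function(pr) {
    p <- pr$lateral_mean
    mean(p$concentration[p$depth_um >= 300 & p$depth_um < 400])
  }, numeric(1))
  expect_true(all(diff(above) > 0))

  swd <- run_sweep("pore_density", c(0.11, 0.19, 0.25),
                   geometry = coarse_geometry(), resolution = 20)
  expect_true(all(diff(swd$C_plex) > 0))  # more pores, higher C_plex
})

test_that("the depth sweep peaks between the swept 400 and 500 um", {
  sw <- run_sweep("plexus_depth", c(400, 450, 500),
                  geometry = coarse_geometry(), resolution = 20)
  expect_true(all(sw$converged))
  fit <- fit_surface(sw$values_si, sw$C_plex, "quadratic")
  ext <- quadratic_extremum(fit)
  expect_equal(ext$kind, "maximum")
  expect_gt(ext$x_star * 1e6, 400)
  expect_lt(ext$x_star * 1e6, 500)
})

test_that("plexus-size sweep scales the layers symmetrically about a fixed mid-depth", {
  sw <- run_sweep("plexus_size", c(30, 50, 70, 90),
                  geometry = coarse_geometry(), resolution = 20,
                  keep_states = TRUE)
  expect_true(all(sw$converged))
  for (q in seq_along(sw$values)) {
    g <- attr(sw$states[[q]], "ops")$grid$geom
    b <- g$plexus_layer_bounds
    expect_equal((b$venule[1] + b$arteriole[2]) / 2, 425)  # mid fixed
    expect_equal(b$arteriole[2] - b$venule[1], sw$values[q])
  }
})
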