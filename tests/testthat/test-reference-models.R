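test_that("homogeneous model is the clipped linear profile", {
  spec <- depth_model_spec("homogeneous", D = 1e-10, L = 500e-6, J = 1)
  prof <- homogeneous_steady(spec, c(0, 250, 500, 600))
  c0 <- 1 * 500e-6 / 1e-10
  expect_equal(prof$concentration[1], c0)       # J L / D at the surface
  expect_equal(prof$concentration[2], c0 / 2)   # affine: half at L/2
  expect_equal(prof$concentration[3], 0)        # sink
  expect_equal(prof$concentration[4], 0)        # clipped below the sink
})

test_that("distributed elimination satisfies flux continuity and exponential decay", {
  spec <- depth_model_spec("distributed_elimination", D = 1e-10,
                           k_el = 1e-3, J = 1)
  ell <- sqrt(spec$D / spec$k_el)  # decay length
  prof <- distributed_elimination_steady(spec, c(0, ell * 1e6))
  c0 <- spec$J / sqrt(spec$D * spec$k_el)
  expect_equal(prof$concentration[1], c0)
  expect_equal(prof$concentration[2], c0 / exp(1))
  # -D dC/dz at z = 0 equals J (analytic derivative)
  expect_equal(spec$D * c0 * sqrt(spec$k_el / spec$D), spec$J)
  # halving k_el raises C at every positive depth
  z <- seq(50, 750, by = 50)
  for (k in c(1e-2, 1e-3, 1e-4)) {
    hi <- depth_model_spec("distributed_elimination", D = 1e-10, k_el = k)
    lo <- depth_model_spec("distributed_elimination", D = 1e-10, k_el = k / 2)
    expect_true(all(distributed_elimination_steady(lo, z)$concentration >
                    distributed_elimination_steady(hi, z)$concentration))
  }
  expect_error(distributed_elimination_steady(
    depth_model_spec("distributed_elimination", D = 1e-10, k_el = 0), z),
    "homogeneous")
})

test_that("convection-dispersion roots satisfy the characteristic identity", {
  # residual of D lambda^2 - v lambda - k_el = 0 over a parameter grid
  for (D in c(1e-11, 1e-10, 1e-9)) for (v in c(0, 1e-8, 1e-6)) {
    for (k in c(1e-4, 1e-3, 1e-2)) {
      lam <- (v - sqrt(v^2 + 4 * D * k)) / (2 * D)
      expect_lt(abs(D * lam^2 - v * lam - k) / k, 1e-10)
    }
  }
})

test_that("convection-dispersion limits chain to the simpler models", {
  z <- seq(0, 800, by = 25)
  # v = 0 reduces exactly to distributed elimination
  de <- depth_model_spec("distributed_elimination", D = 1e-10, k_el = 1e-3)
  cd0 <- depth_model_spec("convection_dispersion_elimination", D = 1e-10,
                          k_el = 1e-3, v = 0)
  expect_equal(convection_dispersion_steady(cd0, z)$concentration,
               distributed_elimination_steady(de, z)$concentration,
               tolerance = 1e-12)
  # k_el = 0 with downward convection sustains a constant profile
  cdk <- depth_model_spec("convection_dispersion_elimination", D = 1e-10,
                          k_el = 0, v = 1e-6)
  prof <- convection_dispersion_steady(cdk, z)
  expect_equal(diff(range(prof$concentration)), 0)
  # degenerate v = k_el = 0 rejected
  expect_error(convection_dispersion_steady(
    depth_model_spec("convection_dispersion_elimination", D = 1e-10), z),
    "degenerate")
  # convection always flattens the surface gradient relative to pure
  # distributed elimination with the same D and k_el
  for (v in c(1e-8, 1e-7, 1e-6)) {
    cd <- depth_model_spec("convection_dispersion_elimination", D = 1e-10,
                           k_el = 1e-3, v = v)
    pd <- convection_dispersion_steady(cd, z)
    lam_cd <- (cd$v - sqrt(cd$v^2 + 4 * cd$D * cd$k_el)) / (2 * cd$D)
    grad_cd <- abs(attr(pd, "surface") * lam_cd)
    grad_de <- de$J / de$D
    expect_lt(grad_cd, grad_de)
  }
})

test_that("the comparison table normalises every model to 1 at the surface", {
  depths <- seq(0, 800, by = 20)
  sim <- plexisim:::new_depth_profile(depths, exp(-depths / 300),
                                      tag = "lateral_mean", surface = 1)
  specs <- list(
    homogeneous = depth_model_spec("homogeneous", D = 1e-10, L = 500e-6),
    distributed_elimination = depth_model_spec("distributed_elimination",
                                               D = 1e-10, k_el = 1e-3)
  )
  cmp <- compare_models(specs, sim)
  expect_equal(unlist(cmp[1, -1]), c(homogeneous = 1,
                                     distributed_elimination = 1,
                                     simulation = 1))
  # identical specs give identical columns
  cmp2 <- compare_models(list(a = specs[[1]], b = specs[[1]]), sim)
  expect_identical(cmp2$a, cmp2$b)
})

test_that("the plexus simulation exceeds the slope-matched linear model at depth", {
  st <- coarse_steady()
  ops <- attr(st, "ops")
  prof <- depth_profile(st, ops$grid, "lateral_mean", transport_params())
  specs <- matched_reference_specs(prof, D = 1e-10)
  cmp <- compare_models(specs, prof)
  deep <- cmp$depth_um > 450
  expect_true(all(cmp$simulation[deep] > cmp$homogeneous[deep]))
  # the slope-matched exponential keeps decaying while the simulation
  # plateaus below the plexus
  expect_gt(cmp$simulation[nrow(cmp)], cmp$distributed_elimination[nrow(cmp)])
})
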