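# Small unit cell used to probe the discrete lumen cross-section at fine
# resolutions without building millions of nodes.
small_loop_geometry <- function(lumen = 10) {
  geometry_params(slab_depth = 160, loop_apex_depth = 20, loop_width = 40,
                  loop_spacing = 40, loop_length = 40,
                  lumen_diameter = lumen, plexus_top_depth = 60,
                  plexus_total_thickness = 20,
                  arteriole_layer_thickness = 10,
                  venule_layer_thickness = 10, pore_density = 0.1)
}

test_that("discrete lumen cross-section approximates the circle and refines", {
  g <- build_unit_cell(small_loop_geometry())
  exact <- pi * (5e-6)^2
  a5 <- lumen_cross_section(classify_nodes(g, 5))
  expect_lt(abs(a5 - exact) / exact, 0.3)
  a25 <- lumen_cross_section(classify_nodes(g, 2.5))
  expect_lt(abs(a25 - exact), abs(a5 - exact))
  # degenerate inputs are rejected
  expect_error(geometry_params(lumen_diameter = 0), "lumen_diameter")
  box <- classify_nodes(build_unit_cell(box_geometry()), 20,
                        include_loop = FALSE)
  expect_error(lumen_cross_section(box), "no lumen")
})

test_that("coupling constants match their defining geometry", {
  grid <- coarse_grid()
  params <- transport_params()
  cp <- plexus_coupling(grid, params)
  g <- grid$geom
  cell_area <- g$cell_length * g$cell_width * 1e-12
  pore_area <- nrow(g$pores$footprints) * g$pores$side^2 * 1e-12
  expect_equal(cp$V_vp, 25e-6 * (cell_area - pore_area))
  expect_equal(cp$V_ap, 25e-6 * (cell_area - pore_area))
  expect_equal(cp$A_cl, pi * (10e-6)^2)  # 20 um lumen
  expect_equal(cp$k_e, params$v_b * cp$A_cl)
  # discrete cross-section within one cell area of pi r^2
  expect_lt(abs(cp$A_cl_discrete - cp$A_cl), (20e-6)^2 + 1e-18)
  # interface areas within a few faces of the vessel-occupied lateral area
  expect_lt(abs(cp$A_vp - (cell_area - pore_area)), 3 * cp$a_face)
  expect_lt(abs(cp$A_ap - (cell_area - pore_area)), 3 * cp$a_face)
})

test_that("compartment balances implement conservative transfer channels", {
  ops <- coarse_ops()
  params <- transport_params()
  cp <- ops$coupling

  # loop outlet delivers to the venule compartment; the inlet draw vanishes
  # when the arteriole compartment is empty
  st <- zero_state(ops)
  st$C_b[length(st$C_b)] <- 2
  r <- plexus_rhs(st, params, cp)
  expect_gt(r[["dC_vp"]], 0)
  expect_equal(r[["dC_ap"]], 0)

  # with removal switched off and no flux, total mass is exactly conserved
  params0 <- transport_params(J_sc = 0, v_b = 0)
  ops0 <- assemble_operators(coarse_grid(), params0)
  st0 <- random_state(ops0)
  r0 <- transport_rhs(st0, ops0)
  cp0 <- ops0$coupling
  dmass <- sum(r0$dC_vs) * ops0$V_cell +
    sum(r0$dC_b) * cp0$A_cl * ops0$ds_m +
    r0$dC_vp * cp0$V_vp + r0$dC_ap * cp0$V_ap
  scale <- max(abs(r0$dC_vs)) * ops0$V_cell
  expect_lt(abs(dmass), 1e-12 * scale)

  # with k_e > 0, no applied flux and only C_ap charged, the system loses
  # mass at exactly k_e * C_ap
  ops1 <- assemble_operators(coarse_grid(), transport_params(J_sc = 0))
  cp1 <- ops1$coupling
  st1 <- zero_state(ops1)
  st1$C_ap <- 4
  r1 <- transport_rhs(st1, ops1)
  dmass1 <- sum(r1$dC_vs) * ops1$V_cell +
    sum(r1$dC_b) * cp1$A_cl * ops1$ds_m +
    r1$dC_vp * cp1$V_vp + r1$dC_ap * cp1$V_ap
  expect_equal(dmass1, -cp1$k_e * st1$C_ap, tolerance = 1e-12)

  expect_error(transport_params(k1 = -1), "k1")
  expect_error(transport_params(k_p = -1), "k_p")
})

test_that("swapping k1 and k2 mirrors the compartment trajectories", {
  gm <- geometry_params(plexus_top_depth = 375)  # plexus centred in the slab
  gr <- classify_nodes(build_unit_cell(gm), c(20, 20, 25),
                       include_loop = FALSE)
  pa <- transport_params(J_sc = 0, v_b = 0, k1 = 3e-6, k2 = 7e-6)
  pb <- transport_params(J_sc = 0, v_b = 0, k1 = 7e-6, k2 = 3e-6)
  oa <- assemble_operators(gr, pa)
  ob <- assemble_operators(gr, pb)
  sa <- zero_state(oa); sa$C_vp <- 1
  sb <- zero_state(ob); sb$C_ap <- 1
  for (i in 1:40) {
    sa <- step(sa, 0.5, oa)
    sb <- step(sb, 0.5, ob)
  }
  expect_equal(sa$C_vp, sb$C_ap, tolerance = 1e-12)
  expect_equal(sa$C_ap, sb$C_vp, tolerance = 1e-12)
})
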