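# Independent brute-force solver and manufactured-solution convergence
# machinery. The stepping here is written as naive explicit loops over
# nodes and deliberately shares no discretisation code with the sparse-
# matrix solver in transport.R; it exists to validate that solver.

#' One fully explicit brute-force step
#'
#' Advances the complete state by forward Euler using naive loops over every
#' node and neighbour pair, re-deriving all coupling coefficients (exchange
#' areas, compartment volumes, advection fluxes) from the labelled grid
#' independently of [assemble_operators()]. Restricted to small grids; use
#' it only to cross-check the main solver.
#'
#' @param state A `sim_state`.
#' @param dt Time step (s).
#' @param grid A `labeled_grid` (at most 20 x 20 x 50 nodes).
#' @param params A [transport_params()] object.
#' @param bottom_bc `"zero_flux"` or `"sink"`.
#' @return The advanced `sim_state`.
#' @export
brute_force_step <- function(state, dt, grid, params,
                             bottom_bc = c("zero_flux", "sink")) {
  bottom_bc <- match.arg(bottom_bc)
  nx <- grid$dims[[1]]; ny <- grid$dims[[2]]; nz <- grid$dims[[3]]
  if (nx > 20L || ny > 20L || nz > 50L) {
    stop("brute_force_step: grid ", nx, "x", ny, "x", nz,
         " too large for the brute-force oracle (max 20x20x50)",
         call. = FALSE)
  }
  lab <- grid$labels
  L_TIS <- node_labels[["tissue"]]; L_POR <- node_labels[["pore"]]
  L_LA <- node_labels[["lumen_arteriole"]]; L_LV <- node_labels[["lumen_venule"]]
  L_PV <- node_labels[["plexus_venule"]]; L_PA <- node_labels[["plexus_arteriole"]]
  dx <- grid$spacing[["dx"]] * UM; dy <- grid$spacing[["dy"]] * UM
  dz <- grid$spacing[["dz"]] * UM
  D <- params$D_vs; k_p <- params$k_p
  V_cell <- dx * dy * dz

  # independent re-derivation of compartment constants
  g <- grid$geom; gp <- g$params
  cell_area <- g$cell_length * g$cell_width * UM^2
  pore_area <- nrow(g$pores$footprints) * g$pores$side^2 * UM^2
  V_vp <- gp$venule_layer_thickness * UM * (cell_area - pore_area)
  V_ap <- gp$arteriole_layer_thickness * UM * (cell_area - pore_area)
  half <- gp$plexus_total_thickness / 2 * UM
  k1 <- if (is.null(params$k1)) params$D_p / half else params$k1
  k2 <- if (is.null(params$k2)) params$D_p / half else params$k2
  k_pcl <- if (is.null(params$k_pcl)) params$v_b else params$k_pcl

  has_lumen <- !is.null(grid$lumen) && grid$lumen$n > 0L
  A_cl <- 0; ds <- 0; N <- 0L
  chain_pos <- NULL  # linear node index -> chain position
  s_node <- 0
  if (has_lumen) {
    N <- grid$lumen$n
    ds <- grid$lumen$ds * UM
    A_cl <- pi * (gp$lumen_diameter / 2 * UM)^2
    s_node <- pi * gp$lumen_diameter * UM * grid$lumen$length * UM / N
    chain_pos <- integer(nx * ny * nz)
    chain_pos[grid$lumen$idx] <- seq_len(N)
  }
  k_e <- params$v_b * A_cl

  tmap <- tissue_index_map(grid)
  C <- state$C_vs; C_b <- state$C_b
  C_vp <- state$C_vp; C_ap <- state$C_ap

  wrap <- function(i, n) if (i < 1L) n else if (i > n) 1L else i
  deg <- integer(N)  # tissue-neighbour count per lumen chain node
  if (has_lumen) {
    for (m in seq_len(N)) {
      lin <- grid$lumen$idx[m]
      i <- ((lin - 1L) %% nx) + 1L
      j <- (((lin - 1L) %/% nx) %% ny) + 1L
      k <- ((lin - 1L) %/% (nx * ny)) + 1L
      d <- 0L
      for (dir in 1:6) {
        ii <- i; jj <- j; kk <- k
        if (dir == 1L) ii <- wrap(i + 1L, nx)
        if (dir == 2L) ii <- wrap(i - 1L, nx)
        if (dir == 3L) jj <- wrap(j + 1L, ny)
        if (dir == 4L) jj <- wrap(j - 1L, ny)
        if (dir == 5L) kk <- k + 1L
        if (dir == 6L) kk <- k - 1L
        if (kk < 1L || kk > nz) next
        if (lab[ii, jj, kk] == L_TIS || lab[ii, jj, kk] == L_POR) d <- d + 1L
      }
      deg[m] <- d
    }
  }

  r_t <- numeric(length(C))
  q_vp_tis <- 0; q_ap_tis <- 0  # amount/s into compartments from tissue
  for (i in seq_len(nx)) for (j in seq_len(ny)) for (k in seq_len(nz)) {
    lb <- lab[i, j, k]
    if (lb != L_TIS && lb != L_POR) next
    u <- tmap[i, j, k]
    acc <- 0
    for (dir in 1:6) {
      ii <- i; jj <- j; kk <- k; h2 <- dx^2
      if (dir == 1L) { ii <- wrap(i + 1L, nx) }
      if (dir == 2L) { ii <- wrap(i - 1L, nx) }
      if (dir == 3L) { jj <- wrap(j + 1L, ny); h2 <- dy^2 }
      if (dir == 4L) { jj <- wrap(j - 1L, ny); h2 <- dy^2 }
      if (dir == 5L) { kk <- k + 1L; h2 <- dz^2 }
      if (dir == 6L) { kk <- k - 1L; h2 <- dz^2 }
      if (kk < 1L || kk > nz) next
      if ((dir <= 2L && nx == 1L) || (dir %in% 3:4 && ny == 1L)) next
      nb <- lab[ii, jj, kk]
      if (nb == L_TIS || nb == L_POR) {
        acc <- acc + D * (C[tmap[ii, jj, kk]] - C[u]) / h2
      } else if (nb == L_PV && dir == 5L) {
        acc <- acc + k_p * (C_vp - C[u]) / dz
        q_vp_tis <- q_vp_tis + k_p * dx * dy * (C[u] - C_vp)
      } else if (nb == L_PA && dir == 6L) {
        acc <- acc + k_p * (C_ap - C[u]) / dz
        q_ap_tis <- q_ap_tis + k_p * dx * dy * (C[u] - C_ap)
      } else if (nb == L_LA || nb == L_LV) {
        m <- chain_pos[ii + (jj - 1L) * nx + (kk - 1L) * nx * ny]
        if (deg[m] > 0L) {
          a <- s_node / deg[m]
          acc <- acc + k_p * a * (C_b[m] - C[u]) / V_cell
        }
      }
    }
    if (k == 1L) acc <- acc + params$J_sc / dz
    if (k == nz && bottom_bc == "sink") acc <- acc - 2 * D * C[u] / dz^2
    r_t[u] <- acc
  }

  r_b <- numeric(N)
  if (has_lumen) {
    for (m in seq_len(N)) {
      f_in <- if (m == 1L) k_pcl * C_ap else params$v_b * C_b[m - 1L]
      f_out <- if (m == N) k_pcl * C_b[m] else params$v_b * C_b[m]
      acc <- (f_in - f_out) / ds
      lin <- grid$lumen$idx[m]
      i <- ((lin - 1L) %% nx) + 1L
      j <- (((lin - 1L) %/% nx) %% ny) + 1L
      k <- ((lin - 1L) %/% (nx * ny)) + 1L
      if (deg[m] > 0L) {
        a <- s_node / deg[m]
        for (dir in 1:6) {
          ii <- i; jj <- j; kk <- k
          if (dir == 1L) ii <- wrap(i + 1L, nx)
          if (dir == 2L) ii <- wrap(i - 1L, nx)
          if (dir == 3L) jj <- wrap(j + 1L, ny)
          if (dir == 4L) jj <- wrap(j - 1L, ny)
          if (dir == 5L) kk <- k + 1L
          if (dir == 6L) kk <- k - 1L
          if (kk < 1L || kk > nz) next
          if (lab[ii, jj, kk] == L_TIS || lab[ii, jj, kk] == L_POR) {
            acc <- acc + k_p * a * (C[tmap[ii, jj, kk]] - C_b[m]) /
              (A_cl * ds)
          }
        }
      }
      r_b[m] <- acc
    }
  }

  has_plexus <- any(lab == L_PV) || any(lab == L_PA)
  r_vp <- 0; r_ap <- 0
  if (has_plexus && V_vp > 0 && V_ap > 0) {
    A_int <- cell_area - pore_area
    ex12 <- k1 * A_int * C_vp
    ex21 <- k2 * A_int * C_ap
    q_vp <- q_vp_tis + ex21 - ex12
    q_ap <- q_ap_tis + ex12 - ex21 - k_e * C_ap
    if (has_lumen) {
      q_vp <- q_vp + k_pcl * A_cl * C_b[N]
      q_ap <- q_ap - k_pcl * A_cl * C_ap
    }
    r_vp <- q_vp / V_vp
    r_ap <- q_ap / V_ap
  }

  out <- state
  out$time <- state$time + dt
  out$C_vs <- C + dt * r_t
  out$C_b <- C_b + dt * r_b
  out$C_vp <- C_vp + dt * r_vp
  out$C_ap <- C_ap + dt * r_ap
  out
}

#' Oracle total mass
#'
#' Independent mass audit companion to [brute_force_step()].
#'
#' @param state A `sim_state`.
#' @param grid The `labeled_grid`.
#' @param params A [transport_params()] object.
#' @return Total amount in the system.
#' @export
brute_force_mass <- function(state, grid, params) {
  g <- grid$geom; gp <- g$params
  dx <- grid$spacing[["dx"]] * UM; dy <- grid$spacing[["dy"]] * UM
  dz <- grid$spacing[["dz"]] * UM
  cell_area <- g$cell_length * g$cell_width * UM^2
  pore_area <- nrow(g$pores$footprints) * g$pores$side^2 * UM^2
  V_vp <- gp$venule_layer_thickness * UM * (cell_area - pore_area)
  V_ap <- gp$arteriole_layer_thickness * UM * (cell_area - pore_area)
  m <- sum(state$C_vs) * dx * dy * dz + state$C_vp * V_vp +
    state$C_ap * V_ap
  if (!is.null(grid$lumen) && grid$lumen$n > 0L && length(state$C_b) > 0L) {
    A_cl <- pi * (gp$lumen_diameter / 2 * UM)^2
    m <- m + sum(state$C_b) * A_cl * (grid$lumen$ds * UM)
  }
  m
}

diffusion_box_geometry <- function() {
  geometry_params(slab_depth = 240, loop_apex_depth = 60,
                  loop_width = 170, loop_spacing = 70,
                  plexus_top_depth = 120, plexus_total_thickness = 60,
                  arteriole_layer_thickness = 30,
                  venule_layer_thickness = 30,
                  pore_density = 1, pore_seed = 1L)
}

#' Manufactured-solution convergence study
#'
#' Runs the main solver against analytic solutions and reports the observed
#' convergence order between successive grid refinements.
#'
#' * `diffusion_only`: a laterally periodic cosine mode
#'   `C = cos(2 pi x / l) exp(-lambda t)` on a vessel-free box (all-pore
#'   plexus, no loop), integrated with the IMEX stepper at a fixed small dt;
#'   second-order spatial accuracy is expected.
#' * `advection_only`: a Gaussian pulse advected along the lumen chain by
#'   the upwind scheme, against the exact translated profile; first-order
#'   accuracy is expected.
#' * `coupled`: the diffusion case marched through the fully explicit
#'   stepping path with all coupling coefficients zero; reduces to the
#'   diffusion orders.
#'
#' @param case `"diffusion_only"`, `"advection_only"` or `"coupled"`.
#' @param resolutions Strictly refining spacings in um (at least 3); each
#'   successive pair should halve.
#' @param t_end Integration horizon (s).
#' @return A `convergence_report` data frame (`case`, `resolution_um`,
#'   `l2_error`, `order`), with attribute `monotone` flagging whether errors
#'   decrease throughout.
#' @export
manufactured_convergence <- function(case = c("diffusion_only",
                                              "advection_only", "coupled"),
                                     resolutions = NULL, t_end = NULL) {
  case <- match.arg(case)
  if (is.null(resolutions)) {
    resolutions <- if (case == "advection_only") c(10, 5, 2.5, 1.25)
                   else c(30, 15, 7.5)
  }
  if (length(resolutions) < 3L || any(diff(resolutions) >= 0)) {
    stop("manufactured_convergence: need >= 3 strictly refining resolutions",
         call. = FALSE)
  }
  errs <- numeric(length(resolutions))
  if (case %in% c("diffusion_only", "coupled")) {
    if (is.null(t_end)) t_end <- 2
    geom <- build_unit_cell(diffusion_box_geometry())
    params <- transport_params(J_sc = 0, k_p = 0, v_b = 0)
    Lx <- geom$cell_length * UM
    lam <- params$D_vs * (2 * pi / Lx)^2
    for (q in seq_along(resolutions)) {
      grid <- classify_nodes(geom, resolutions[q], include_loop = FALSE)
      ops <- assemble_operators(grid, params)
      xarr <- array(grid$x, dim = grid$dims) * UM
      xs <- xarr[ops$tmap > 0L]
      st <- zero_state(ops)
      st$C_vs <- cos(2 * pi * xs / Lx)
      if (case == "diffusion_only") {
        # dt refined with dx^2 so the first-order temporal error converges
        # at the same rate as the second-order spatial error
        dt <- 0.05 * (resolutions[q] / resolutions[1])^2
        method <- "imex"
      } else {
        dt <- 0.4 / (2 * params$D_vs *
                     (1 / ops$dx^2 + 1 / ops$dy^2 + 1 / ops$dz^2))
        method <- "explicit"
      }
      nstep <- ceiling(t_end / dt)
      dt <- t_end / nstep
      for (s in seq_len(nstep)) {
        r <- transport_rhs(st, ops, include_diffusion = (method == "explicit"))
        if (method == "explicit") {
          st$C_vs <- st$C_vs + dt * r$dC_vs
        } else {
          key <- sprintf("chol_%.17g", dt)
          fac <- ops$cache[[key]]
          if (is.null(fac)) {
            M <- Matrix::Diagonal(ops$n_t) -
              dt * Matrix::forceSymmetric(ops$Ldiff)
            fac <- Matrix::Cholesky(M, LDL = FALSE)
            ops$cache[[key]] <- fac
          }
          st$C_vs <- as.numeric(Matrix::solve(fac, st$C_vs + dt * r$dC_vs))
        }
        st$time <- st$time + dt
      }
      exact <- cos(2 * pi * xs / Lx) * exp(-lam * t_end)
      errs[q] <- sqrt(mean((st$C_vs - exact)^2))
    }
  } else {
    v <- 6.5e-4
    L <- 800 * UM
    sigma <- L / 12
    s0 <- L / 4
    if (is.null(t_end)) t_end <- 0.3 * L / v
    f <- function(s) exp(-((s - s0) / sigma)^2)
    for (q in seq_along(resolutions)) {
      ds <- resolutions[q] * UM
      N <- round(L / ds)
      s_mid <- (seq_len(N) - 0.5) * ds
      Cb <- f(s_mid)
      dt <- 0.4 * ds / v
      nstep <- ceiling(t_end / dt)
      dt <- t_end / nstep
      for (s in seq_len(nstep)) {
        Cb <- Cb + dt * advection_rates(Cb, C_in = 0, v_b = v, k_pcl = v,
                                        ds = ds)
      }
      errs[q] <- sqrt(mean((Cb - f(s_mid - v * t_end))^2))
    }
  }
  ratio <- log(resolutions[-length(resolutions)] / resolutions[-1])
  order <- c(NA_real_, log(errs[-length(errs)] / errs[-1]) / ratio)
  structure(
    data.frame(case = case, resolution_um = resolutions, l2_error = errs,
               order = order),
    monotone = all(diff(errs) < 0),
    # the asymptotic estimate: order observed on the finest grid pair
    observed_order = order[length(order)],
    class = c("convergence_report", "data.frame")
  )
}

#' Observed convergence order of a report
#'
#' The finest-pair order estimate, i.e. the asymptotic observed order.
#'
#' @param report A `convergence_report`.
#' @return A single numeric order.
#' @export
observed_order <- function(report) {
  stopifnot(inherits(report, "convergence_report"))
  attr(report, "observed_order")
}
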