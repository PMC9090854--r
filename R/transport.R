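# Coupled transport solver: implicit 7-point diffusion on tissue and pore
# nodes (periodic laterally, flux-injection top, zero-flux or sink bottom),
# explicit first-order upwind advection along the capillary-loop chain,
# explicit endothelial and compartment exchange. Everything internal to this
# module is SI; grids carry micrometre coordinates.

#' Assemble the discrete transport operators
#'
#' Builds the sparse diffusion operator over tissue and pore unknowns, the
#' top-flux source vector, the lumen-tissue exchange area matrix (lumen
#' surface `pi d L` distributed uniformly over lumen nodes and equally over
#' each node's tissue neighbours), the compartment coupling, and the scalar
#' coefficients used by the time stepper and the steady solver.
#'
#' @param grid A `labeled_grid` from [classify_nodes()].
#' @param params A [transport_params()] object.
#' @param bottom_bc `"zero_flux"` (default) or `"sink"` (zero concentration
#'   at the slab bottom; used for closed-form verification).
#' @return An object of class `transport_operators`.
#' @export
assemble_operators <- function(grid, params,
                               bottom_bc = c("zero_flux", "sink")) {
  stopifnot(inherits(grid, "labeled_grid"))
  validate_transport_params(params)
  bottom_bc <- match.arg(bottom_bc)
  nx <- grid$dims[[1]]; ny <- grid$dims[[2]]; nz <- grid$dims[[3]]
  dx <- grid$spacing[["dx"]] * UM
  dy <- grid$spacing[["dy"]] * UM
  dz <- grid$spacing[["dz"]] * UM
  D <- params$D_vs
  tmap <- tissue_index_map(grid)
  n_t <- max(tmap)

  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  add_axis <- function(perm_from, perm_to, coef) {
    sel <- perm_from > 0L & perm_to > 0L
    a <- perm_from[sel]; b <- perm_to[sel]
    ti <<- c(ti, a, b, a, b)
    tj <<- c(tj, b, a, a, b)
    tx <<- c(tx, rep(coef, 2L * length(a)), rep(-coef, 2L * length(a)))
  }
  if (nx > 1L) add_axis(tmap, tmap[c(2:nx, 1L), , , drop = FALSE], D / dx^2)
  if (ny > 1L) add_axis(tmap, tmap[, c(2:ny, 1L), , drop = FALSE], D / dy^2)
  if (nz > 1L) {
    add_axis(tmap[, , 1:(nz - 1L), drop = FALSE],
             tmap[, , 2:nz, drop = FALSE], D / dz^2)
  }
  sink_idx <- integer(0)
  if (bottom_bc == "sink") {
    sink_idx <- tmap[, , nz][tmap[, , nz] > 0L]
    ti <- c(ti, sink_idx); tj <- c(tj, sink_idx)
    tx <- c(tx, rep(-2 * D / dz^2, length(sink_idx)))
  }
  Ldiff <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(n_t, n_t))

  b_in <- numeric(n_t)
  top_idx <- tmap[, , 1L][tmap[, , 1L] > 0L]
  b_in[top_idx] <- params$J_sc / dz

  coupling <- plexus_coupling(grid, params)

  E <- NULL; deg <- numeric(0); a_t <- numeric(n_t)
  ds_m <- 0
  if (coupling$has_lumen) {
    lum <- grid$lumen
    N <- lum$n
    ds_m <- lum$ds * UM
    s_node <- pi * lum$diameter * UM * lum$length * UM / N
    li <- integer(0); lj <- integer(0); lx <- numeric(0)
    ii <- ((lum$idx - 1L) %% nx) + 1L
    jj <- (((lum$idx - 1L) %/% nx) %% ny) + 1L
    kk <- ((lum$idx - 1L) %/% (nx * ny)) + 1L
    for (m in seq_len(N)) {
      nbrs <- integer(0)
      i <- ii[m]; j <- jj[m]; k <- kk[m]
      cand <- rbind(
        c(if (i == nx) 1L else i + 1L, j, k),
        c(if (i == 1L) nx else i - 1L, j, k),
        c(i, if (j == ny) 1L else j + 1L, k),
        c(i, if (j == 1L) ny else j - 1L, k),
        if (k < nz) c(i, j, k + 1L), if (k > 1L) c(i, j, k - 1L)
      )
      for (r in seq_len(nrow(cand))) {
        t_id <- tmap[cand[r, 1L], cand[r, 2L], cand[r, 3L]]
        if (t_id > 0L) nbrs <- c(nbrs, t_id)
      }
      if (length(nbrs) > 0L) {
        a_share <- s_node / length(nbrs)
        li <- c(li, rep(m, length(nbrs))); lj <- c(lj, nbrs)
        lx <- c(lx, rep(a_share, length(nbrs)))
      }
    }
    E <- Matrix::sparseMatrix(i = li, j = lj, x = lx,
                              dims = c(N, n_t))
    deg <- Matrix::rowSums(E)
    a_t <- as.numeric(Matrix::colSums(E))
  }

  ops <- list(
    grid = grid, params = params, coupling = coupling,
    n_t = n_t, tmap = tmap,
    Ldiff = Ldiff, b_in = b_in, top_idx = top_idx, sink_idx = sink_idx,
    E = E, deg = deg, a_t = a_t, ds_m = ds_m,
    dx = dx, dy = dy, dz = dz,
    V_cell = dx * dy * dz,
    A_top = nx * ny * dx * dy,
    bottom_bc = bottom_bc,
    cache = new.env(parent = emptyenv())
  )
  class(ops) <- "transport_operators"
  ops
}

#' Zero initial state
#'
#' @param ops A `transport_operators` object.
#' @return A `sim_state` with zero concentration everywhere at time 0.
#' @export
zero_state <- function(ops) {
  nb <- if (ops$coupling$has_lumen) ops$grid$lumen$n else 0L
  structure(list(time = 0, C_vs = numeric(ops$n_t), C_b = numeric(nb),
                 C_vp = 0, C_ap = 0), class = "sim_state")
}

# Conservative first-order upwind advection along the lumen chain. Blood
# flows inlet (arteriole) -> apex -> outlet (venule); the inlet face carries
# flux k_pcl * C_in from the arteriole compartment and the outlet face
# delivers k_pcl * C_b[N] to the venule compartment.
advection_rates <- function(C_b, C_in, v_b, k_pcl, ds) {
  N <- length(C_b)
  if (N == 0L) return(numeric(0))
  flux_in <- c(k_pcl * C_in, v_b * C_b[-N])
  flux_out <- c(v_b * C_b[-N], k_pcl * C_b[N])
  if (N == 1L) {
    flux_in <- k_pcl * C_in
    flux_out <- k_pcl * C_b
  }
  (flux_in - flux_out) / ds
}

#' Semi-discrete rates of change of the full state
#'
#' @param state A `sim_state`.
#' @param ops A `transport_operators` object.
#' @param include_diffusion Set `FALSE` to omit the diffusion operator (the
#'   implicitly treated part of the IMEX step).
#' @return List with `dC_vs`, `dC_b`, `dC_vp`, `dC_ap`.
#' @export
transport_rhs <- function(state, ops, include_diffusion = TRUE) {
  p <- ops$params; cp <- ops$coupling
  C <- state$C_vs
  r_t <- if (include_diffusion) as.numeric(ops$Ldiff %*% C) else numeric(ops$n_t)
  r_t <- r_t + ops$b_in
  kpdz <- p$k_p / ops$dz
  if (cp$has_plexus) {
    r_t[cp$vp_idx] <- r_t[cp$vp_idx] + kpdz * (state$C_vp - C[cp$vp_idx])
    r_t[cp$ap_idx] <- r_t[cp$ap_idx] + kpdz * (state$C_ap - C[cp$ap_idx])
  }
  r_b <- numeric(0)
  if (cp$has_lumen) {
    r_t <- r_t + (p$k_p / ops$V_cell) *
      (as.numeric(Matrix::t(ops$E) %*% state$C_b) - ops$a_t * C)
    r_b <- advection_rates(state$C_b, state$C_ap, p$v_b, cp$k_pcl, ops$ds_m) +
      (p$k_p / (cp$A_cl * ops$ds_m)) *
      (as.numeric(ops$E %*% C) - ops$deg * state$C_b)
  }
  comp <- if (cp$has_plexus) plexus_rhs(state, p, cp) else c(0, 0)
  list(dC_vs = r_t, dC_b = r_b, dC_vp = comp[[1]], dC_ap = comp[[2]])
}

#' Largest stable time step for the explicit terms
#'
#' @param ops A `transport_operators` object.
#' @param method `"imex"` (diffusion implicit) or `"explicit"`.
#' @return Time step in seconds.
#' @export
dt_stable <- function(ops, method = c("imex", "explicit")) {
  method <- match.arg(method)
  p <- ops$params; cp <- ops$coupling
  rate <- 0  # largest explicit decay rate (1/s)
  if (cp$has_lumen) {
    rate <- max(rate, max(p$v_b, cp$k_pcl) / ops$ds_m)
    if (length(ops$deg) > 0L && max(ops$deg) > 0) {
      rate <- max(rate, p$k_p * max(ops$deg) / (cp$A_cl * ops$ds_m))
    }
    if (max(ops$a_t) > 0) rate <- max(rate, p$k_p * max(ops$a_t) / ops$V_cell)
  }
  if (cp$has_plexus) {
    rate <- max(rate, p$k_p / ops$dz)
    out_vp <- p$k_p * cp$A_vp + cp$k1 * cp$A_int
    out_ap <- p$k_p * cp$A_ap + cp$k2 * cp$A_int +
      cp$k_pcl * cp$A_cl + cp$k_e
    if (cp$V_vp > 0) rate <- max(rate, out_vp / cp$V_vp)
    if (cp$V_ap > 0) rate <- max(rate, out_ap / cp$V_ap)
  }
  if (method == "explicit") {
    rate <- max(rate, 2 * p$D_vs * (1 / ops$dx^2 + 1 / ops$dy^2 +
                                    1 / ops$dz^2))
  }
  if (rate <= 0) rate <- p$D_vs / ops$dz^2  # diffusion-scale fallback
  0.5 / rate
}

check_state_sane <- function(x, what, scale) {
  if (any(!is.finite(x))) {
    stop("step: non-finite ", what, " after step (solver diverged); ",
         "reduce dt or check parameters", call. = FALSE)
  }
  tol <- -1e-8 * max(scale, 1e-300)
  if (any(x < tol)) {
    stop("step: negative ", what, " after step (min = ", min(x),
         "); dt violates the stability bound, see dt_stable()",
         call. = FALSE)
  }
  pmax(x, 0)
}

#' Advance the state one time step
#'
#' IMEX stepping: diffusion is integrated implicitly (backward Euler, sparse
#' Cholesky factorised once per dt and cached), while advection, endothelial
#' exchange and the compartment balances are explicit forward Euler. The
#' fully explicit mode applies forward Euler to everything and is used for
#' verification against the brute-force oracle.
#'
#' @param state A `sim_state`.
#' @param dt Time step (s), positive and within [dt_stable()] for the
#'   explicit terms.
#' @param ops A `transport_operators` object.
#' @param method `"imex"` or `"explicit"`.
#' @return The advanced `sim_state`; attributes `step_influx` and
#'   `step_removed` carry the boundary mass fluxes of the step for the mass
#'   audit.
#' @export
step <- function(state, dt, ops, method = c("imex", "explicit")) {
  method <- match.arg(method)
  stopifnot(dt > 0)
  p <- ops$params; cp <- ops$coupling
  removed <- dt * cp$k_e * state$C_ap
  if (method == "explicit") {
    r <- transport_rhs(state, ops, include_diffusion = TRUE)
    C_new <- state$C_vs + dt * r$dC_vs
    if (length(ops$sink_idx) > 0L) {
      removed <- removed + dt * sum(2 * p$D_vs / ops$dz^2 *
                                    state$C_vs[ops$sink_idx]) * ops$V_cell
    }
  } else {
    r <- transport_rhs(state, ops, include_diffusion = FALSE)
    Cs <- state$C_vs + dt * r$dC_vs
    key <- sprintf("chol_%.17g", dt)
    fac <- ops$cache[[key]]
    if (is.null(fac)) {
      M <- Matrix::Diagonal(ops$n_t) - dt * Matrix::forceSymmetric(ops$Ldiff)
      fac <- Matrix::Cholesky(M, LDL = FALSE)
      ops$cache[[key]] <- fac
    }
    C_new <- as.numeric(Matrix::solve(fac, Cs))
    if (length(ops$sink_idx) > 0L) {
      removed <- removed + dt * sum(2 * p$D_vs / ops$dz^2 *
                                    C_new[ops$sink_idx]) * ops$V_cell
    }
  }
  scale <- max(abs(state$C_vs), abs(state$C_b), abs(state$C_vp),
               abs(state$C_ap), 0)
  out <- state
  out$time <- state$time + dt
  out$C_vs <- check_state_sane(C_new, "tissue concentration", scale)
  out$C_b <- check_state_sane(state$C_b + dt * r$dC_b,
                              "lumen concentration", scale)
  out$C_vp <- check_state_sane(state$C_vp + dt * r$dC_vp,
                               "venule-plexus concentration", scale)
  out$C_ap <- check_state_sane(state$C_ap + dt * r$dC_ap,
                               "arteriole-plexus concentration", scale)
  attr(out, "step_influx") <- dt * p$J_sc * ops$A_top
  attr(out, "step_removed") <- removed
  out
}

#' Total drug amount in the system
#'
#' Sum of tissue, lumen and compartment contents. With zero applied flux and
#' zero systemic removal this is conserved by the solver to roundoff.
#'
#' @param state A `sim_state`.
#' @param ops A `transport_operators` object.
#' @return Amount (concentration times m3).
#' @export
total_mass <- function(state, ops) {
  cp <- ops$coupling
  m <- sum(state$C_vs) * ops$V_cell + state$C_vp * cp$V_vp +
    state$C_ap * cp$V_ap
  if (cp$has_lumen) m <- m + sum(state$C_b) * cp$A_cl * ops$ds_m
  m
}

resolve_grid <- function(geom, resolution, grid, include_loop = TRUE) {
  if (!is.null(grid)) return(grid)
  if (inherits(geom, "geometry_params")) geom <- build_unit_cell(geom)
  stopifnot(inherits(geom, "skin_geometry"))
  classify_nodes(geom, resolution, include_loop = include_loop)
}

#' Time-integrate the coupled model
#'
#' Marches the state from `init` (zero by default) to `t_end`, recording the
#' state at `output_times` and logging the mass balance: at every output time
#' the cumulative influx `J_sc * A_top * t`, cumulative systemic removal
#' `integral k_e C_ap dt`, and the relative residual of the audit
#' `mass - mass0 - influx + removal` are reported.
#'
#' @param geom A `geometry_params` or `skin_geometry` (ignored when `grid`
#'   is supplied).
#' @param params A [transport_params()] object.
#' @param resolution Grid spacing in um (see [classify_nodes()]).
#' @param t_end Final time (s); `0` returns only the initial state.
#' @param output_times Times at which to record states (default `t_end`).
#' @param dt Time step; defaults to [dt_stable()].
#' @param init Initial `sim_state` (default zero).
#' @param method `"imex"` or `"explicit"`.
#' @param bottom_bc Bottom boundary condition, see [assemble_operators()].
#' @param grid Optional pre-built `labeled_grid`.
#' @param include_loop Passed to [classify_nodes()] when building the grid.
#' @return A `sim_trajectory`: list of `states`, the `mass_log` data frame,
#'   and the operators used.
#' @export
simulate <- function(geom = geometry_params(), params = transport_params(),
                     resolution = 20, t_end = 1, output_times = NULL,
                     dt = NULL, init = NULL,
                     method = c("imex", "explicit"),
                     bottom_bc = "zero_flux", grid = NULL,
                     include_loop = TRUE) {
  method <- match.arg(method)
  stopifnot(t_end >= 0)
  grid <- resolve_grid(geom, resolution, grid, include_loop)
  ops <- assemble_operators(grid, params, bottom_bc)
  state <- if (is.null(init)) zero_state(ops) else init
  if (is.null(output_times)) output_times <- t_end
  output_times <- sort(unique(output_times))
  if (t_end == 0 || length(output_times) == 0) {
    ml <- data.frame(time = state$time, mass = total_mass(state, ops),
                     influx_cum = 0, removed_cum = 0, residual_rel = 0)
    return(structure(list(states = list(state), mass_log = ml, ops = ops),
                     class = "sim_trajectory"))
  }
  if (is.null(dt)) dt <- dt_stable(ops, method)
  states <- vector("list", length(output_times))
  mass0 <- total_mass(state, ops)
  influx <- 0; removed <- 0
  rows <- vector("list", length(output_times))
  for (q in seq_along(output_times)) {
    target <- output_times[q]
    while (state$time < target - 1e-12 * max(target, 1)) {
      dtn <- min(dt, target - state$time)
      state <- step(state, dtn, ops, method)
      influx <- influx + attr(state, "step_influx")
      removed <- removed + attr(state, "step_removed")
    }
    states[[q]] <- state
    m <- total_mass(state, ops)
    resid <- m - mass0 - influx + removed
    rows[[q]] <- data.frame(
      time = state$time, mass = m, influx_cum = influx,
      removed_cum = removed,
      residual_rel = resid / max(influx, .Machine$double.xmin)
    )
  }
  structure(list(states = states, mass_log = do.call(rbind, rows),
                 ops = ops),
            class = "sim_trajectory")
}

# Assemble the steady-state linear system A u + b = 0 over the blocks
# [tissue | lumen | C_vp, C_ap]. Applying A to a state vector reproduces
# transport_rhs() exactly (tested); the steady solution is u = solve(A, -b).
steady_system <- function(ops) {
  p <- ops$params; cp <- ops$coupling
  n_t <- ops$n_t
  use_lumen <- cp$has_lumen && (p$k_p > 0 || p$v_b > 0 || cp$k_pcl > 0)
  use_plex <- cp$has_plexus && (p$k_p > 0 || (use_lumen && cp$k_pcl > 0))
  N <- if (use_lumen) ops$grid$lumen$n else 0L
  off_b <- n_t
  off_c <- n_t + N
  ntot <- n_t + N + if (use_plex) 2L else 0L
  ivp <- off_c + 1L; iap <- off_c + 2L

  tri <- methods::as(ops$Ldiff, "TsparseMatrix")
  ti <- tri@i + 1L; tj <- tri@j + 1L; tx <- tri@x
  add <- function(i, j, x) {
    ti <<- c(ti, i); tj <<- c(tj, j); tx <<- c(tx, x)
  }
  kpdz <- p$k_p / ops$dz
  if (use_plex) {
    # tissue <-> compartments
    if (length(cp$vp_idx) > 0L && p$k_p > 0) {
      add(cp$vp_idx, cp$vp_idx, rep(-kpdz, length(cp$vp_idx)))
      add(cp$vp_idx, rep(ivp, length(cp$vp_idx)),
          rep(kpdz, length(cp$vp_idx)))
      add(rep(ivp, length(cp$vp_idx)), cp$vp_idx,
          rep(p$k_p * cp$a_face / cp$V_vp, length(cp$vp_idx)))
      add(ivp, ivp, -p$k_p * cp$A_vp / cp$V_vp)
    }
    if (length(cp$ap_idx) > 0L && p$k_p > 0) {
      add(cp$ap_idx, cp$ap_idx, rep(-kpdz, length(cp$ap_idx)))
      add(cp$ap_idx, rep(iap, length(cp$ap_idx)),
          rep(kpdz, length(cp$ap_idx)))
      add(rep(iap, length(cp$ap_idx)), cp$ap_idx,
          rep(p$k_p * cp$a_face / cp$V_ap, length(cp$ap_idx)))
      add(iap, iap, -p$k_p * cp$A_ap / cp$V_ap)
    }
    # inter-compartment exchange and systemic removal
    add(ivp, ivp, -cp$k1 * cp$A_int / cp$V_vp)
    add(ivp, iap, cp$k2 * cp$A_int / cp$V_vp)
    add(iap, ivp, cp$k1 * cp$A_int / cp$V_ap)
    add(iap, iap, -(cp$k2 * cp$A_int + cp$k_e) / cp$V_ap)
  }
  if (use_lumen) {
    # exchange lumen <-> tissue
    if (p$k_p > 0) {
      le <- methods::as(ops$E, "TsparseMatrix")
      if (length(le@x) > 0L) {
        lei <- le@i + 1L; lej <- le@j + 1L
        add(lej, off_b + lei, p$k_p * le@x / ops$V_cell)
        nz_t <- which(ops$a_t > 0)
        add(nz_t, nz_t, -p$k_p * ops$a_t[nz_t] / ops$V_cell)
        add(off_b + lei, lej, p$k_p * le@x / (cp$A_cl * ops$ds_m))
        nz_b <- which(ops$deg > 0)
        add(off_b + nz_b, off_b + nz_b,
            -p$k_p * ops$deg[nz_b] / (cp$A_cl * ops$ds_m))
      }
    }
    # upwind advection along the chain
    if (N > 1L) {
      add(off_b + 2:N, off_b + 1:(N - 1L), rep(p$v_b / ops$ds_m, N - 1L))
      add(off_b + 1:(N - 1L), off_b + 1:(N - 1L),
          rep(-p$v_b / ops$ds_m, N - 1L))
    }
    add(off_b + N, off_b + N, -cp$k_pcl / ops$ds_m)
    if (use_plex) {
      add(off_b + 1L, iap, cp$k_pcl / ops$ds_m)            # inlet fed by C_ap
      add(ivp, off_b + N, cp$k_pcl * cp$A_cl / cp$V_vp)    # outlet -> venule
      add(iap, iap, -cp$k_pcl * cp$A_cl / cp$V_ap)         # inlet draw
    }
  }
  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(ntot, ntot))
  b <- numeric(ntot)
  b[seq_len(n_t)] <- ops$b_in
  list(A = A, b = b, n_t = n_t, N = N, use_lumen = use_lumen,
       use_plex = use_plex)
}

# Direct solve of the steady system A u = -b. The tissue block is symmetric
# negative definite (diffusion plus exchange sinks), so it is factorised
# with a sparse Cholesky and the few lumen/compartment unknowns are solved
# through a small dense Schur complement; this is much faster than a
# general sparse LU of the full nonsymmetric system. A singular tissue
# block (no exit path for the applied flux) makes the Cholesky fail, which
# steady_state() reports as non-convergence.
solve_steady <- function(sys) {
  n_t <- sys$n_t
  ntot <- nrow(sys$A)
  nv <- ntot - n_t
  M <- -Matrix::forceSymmetric(sys$A[seq_len(n_t), seq_len(n_t)])
  # a semidefinite tissue block (no exit path) must surface as failure,
  # not as a CHOLMOD warning with a garbage factor
  ch <- withCallingHandlers(
    Matrix::Cholesky(M, LDL = FALSE),
    warning = function(w) stop("tissue block is singular: ",
                               conditionMessage(w), call. = FALSE))
  b_t <- sys$b[seq_len(n_t)]
  if (nv == 0L) return(as.numeric(Matrix::solve(ch, b_t)))
  vi <- n_t + seq_len(nv)
  B <- sys$A[seq_len(n_t), vi, drop = FALSE]
  Cm <- sys$A[vi, seq_len(n_t), drop = FALSE]
  Dw <- as.matrix(sys$A[vi, vi, drop = FALSE])
  Y <- as.matrix(Matrix::solve(ch, cbind(b_t, as.matrix(B))))
  y_b <- Y[, 1L]
  Y_B <- Y[, -1L, drop = FALSE]
  S <- Dw + as.matrix(Cm %*% Y_B)
  rhs_w <- -sys$b[vi] - as.numeric(Cm %*% y_b)
  w <- solve(S, rhs_w)
  c(y_b + as.numeric(Y_B %*% w), w)
}

#' Solve for the steady state directly
#'
#' The model is linear, so the steady state solves the sparse system given
#' by setting all rates to zero; a direct sparse solve replaces time
#' marching. The returned state is checked against the operational criterion:
#' the largest rate of change, scaled by the slab diffusion time
#' `L^2 / D_vs` and the solution magnitude, must be below `tol`. If the
#' system has no steady state (e.g. no exit path for the applied flux), the
#' solve is singular and a zero state flagged `converged = FALSE` is returned
#' with a warning.
#'
#' @param geom A `geometry_params` or `skin_geometry`.
#' @param params A [transport_params()] object.
#' @param resolution Grid spacing in um.
#' @param tol Relative steadiness tolerance (default `1e-6`).
#' @param bottom_bc `"zero_flux"` or `"sink"`.
#' @param include_loop Passed to [classify_nodes()].
#' @param grid Optional pre-built `labeled_grid`.
#' @return A `sim_state` with attributes `converged` (logical), `steadiness`
#'   (the criterion value) and `ops` (the operators, for post-processing).
#' @export
steady_state <- function(geom = geometry_params(),
                         params = transport_params(), resolution = 20,
                         tol = 1e-6, bottom_bc = "zero_flux",
                         include_loop = TRUE, grid = NULL) {
  grid <- resolve_grid(geom, resolution, grid, include_loop)
  ops <- assemble_operators(grid, params, bottom_bc)
  sys <- steady_system(ops)
  state <- zero_state(ops)
  u <- tryCatch(solve_steady(sys), error = function(e) NULL)
  ok <- !is.null(u) && all(is.finite(u))
  if (ok) {
    resid <- as.numeric(sys$A %*% u) + sys$b
    scale <- max(abs(u), .Machine$double.xmin)
    t_char <- (ops$grid$geom$params$slab_depth * UM)^2 / params$D_vs
    steadiness <- max(abs(resid)) * t_char / scale
    ok <- steadiness < tol && min(u) > -1e-8 * scale
  }
  if (!ok) {
    warning("steady_state: no steady state reached (system singular or ",
            "residual above tolerance); returning zero state flagged ",
            "non-converged", call. = FALSE)
    attr(state, "converged") <- FALSE
    attr(state, "steadiness") <- NA_real_
    attr(state, "ops") <- ops
    return(state)
  }
  state$C_vs <- pmax(u[seq_len(sys$n_t)], 0)
  if (sys$use_lumen) {
    state$C_b <- pmax(u[sys$n_t + seq_len(sys$N)], 0)
  }
  if (sys$use_plex) {
    state$C_vp <- max(u[sys$n_t + sys$N + 1L], 0)
    state$C_ap <- max(u[sys$n_t + sys$N + 2L], 0)
  }
  state$time <- Inf
  attr(state, "converged") <- TRUE
  attr(state, "steadiness") <- steadiness
  attr(state, "ops") <- ops
  state
}

#' @export
print.sim_state <- function(x, ...) {
  cat("<sim_state>\n")
  cat(sprintf("  time: %g s\n", x$time))
  cat(sprintf("  tissue field: %d unknowns, range [%.4g, %.4g]\n",
              length(x$C_vs), min(x$C_vs), max(x$C_vs)))
  if (length(x$C_b) > 0L) {
    cat(sprintf("  lumen chain: %d nodes, range [%.4g, %.4g]\n",
                length(x$C_b), min(x$C_b), max(x$C_b)))
  }
  cat(sprintf("  C_vp = %.4g, C_ap = %.4g\n", x$C_vp, x$C_ap))
  if (!is.null(attr(x, "converged"))) {
    cat(sprintf("  converged: %s (steadiness %.3g)\n", attr(x, "converged"),
                attr(x, "steadiness")))
  }
  invisible(x)
}
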