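# Two well-stirred compartments for the venular and arteriolar layers of the
# subpapillary plexus, and their couplings to the tissue field and the
# capillary loop. All quantities here are SI (m, m2, m3, m/s, m3/s).

UM <- 1e-6  # metres per micrometre

#' Transport parameters
#'
#' Physical constants of the coupled transport model. `k1` (venule-to-
#' arteriole), `k2` (arteriole-to-venule) and `k_pcl` (loop-end transfer)
#' have no literature values; left `NULL` they default, at coupling time, to
#' `k1 = k2 = D_p / (plexus_total_thickness / 2)` (an inter-layer diffusion
#' exchange velocity) and `k_pcl = v_b` (convective delivery at the loop
#' ends).
#'
#' @param D_vs Diffusivity in viable skin (m2/s).
#' @param D_p Diffusivity in the plexus pores / inter-vessel tissue (m2/s).
#' @param v_b Blood speed along the capillary-loop centerline (m/s).
#' @param k_p Endothelial permeability of the capillary walls (m/s).
#' @param J_sc Constant flux entering the top of the viable skin
#'   (amount m-2 s-1); the model is linear, so results scale with `J_sc`.
#' @param k1,k2,k_pcl Exchange velocities (m/s) or `NULL` for the defaults
#'   above.
#' @return An object of class `transport_params`.
#' @export
transport_params <- function(D_vs = 1e-10, D_p = D_vs, v_b = 6.5e-4,
                             k_p = 1e-6, J_sc = 1, k1 = NULL, k2 = NULL,
                             k_pcl = NULL) {
  p <- list(D_vs = D_vs, D_p = D_p, v_b = v_b, k_p = k_p, J_sc = J_sc,
            k1 = k1, k2 = k2, k_pcl = k_pcl)
  class(p) <- "transport_params"
  validate_transport_params(p)
  p
}

validate_transport_params <- function(p) {
  for (f in c("D_vs", "D_p", "v_b", "k_p", "J_sc")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("transport_params: field '", f,
           "' must be a finite nonnegative number", call. = FALSE)
    }
  }
  if (p$D_vs <= 0) stop("transport_params: field 'D_vs' must be positive",
                        call. = FALSE)
  for (f in c("k1", "k2", "k_pcl")) {
    v <- p[[f]]
    if (!is.null(v) && (!is.numeric(v) || length(v) != 1L || !is.finite(v) ||
                        v < 0)) {
      stop("transport_params: field '", f,
           "' must be NULL or a finite nonnegative number", call. = FALSE)
    }
  }
  invisible(p)
}

#' Discrete cross-sectional area of the capillary lumen
#'
#' Counts lumen nodes of the arteriole limb in a transverse grid slice midway
#' between the loop apex and the plexus top, and multiplies by the lateral
#' cell area. This is the discrete analogue of integrating the lumen
#' cross-section, and converges to `pi * (d/2)^2` with refinement.
#'
#' @param grid A `labeled_grid` containing a lumen.
#' @return Cross-sectional area in m2.
#' @export
lumen_cross_section <- function(grid) {
  stopifnot(inherits(grid, "labeled_grid"))
  if (is.null(grid$lumen) || grid$lumen$n == 0L) {
    stop("lumen_cross_section: grid contains no lumen nodes", call. = FALSE)
  }
  p <- grid$geom$params
  zmid <- (p$loop_apex_depth + p$plexus_top_depth) / 2
  k <- which.min(abs(grid$z - zmid))
  slice <- grid$labels[, , k]
  cnt <- sum(slice == node_labels[["lumen_arteriole"]])
  if (cnt == 0L) {  # fall back to either limb, halved
    cnt <- sum(slice == node_labels[["lumen_arteriole"]] |
               slice == node_labels[["lumen_venule"]]) / 2
  }
  if (cnt == 0L) {
    stop("lumen_cross_section: no lumen nodes in the transverse slice",
         call. = FALSE)
  }
  cnt * grid$spacing[["dx"]] * grid$spacing[["dy"]] * UM^2
}

#' Compartment coupling constants
#'
#' Derives, from the labelled grid and transport parameters, everything the
#' compartment balances need: nominal compartment volumes
#' (layer thickness x (cell area - pore area)), tissue interface node sets and
#' areas (tissue faces above the venular layer; below the arteriolar layer),
#' the discrete lumen cross-section `A_cl`, the systemic removal coefficient
#' `k_e = v_b * A_cl`, and resolved values of `k1`, `k2`, `k_pcl`.
#'
#' @param grid A `labeled_grid`.
#' @param params A [transport_params()] object.
#' @return An object of class `plexus_coupling`.
#' @export
plexus_coupling <- function(grid, params) {
  stopifnot(inherits(grid, "labeled_grid"))
  validate_transport_params(params)
  g <- grid$geom; p <- g$params
  dx <- grid$spacing[["dx"]]; dy <- grid$spacing[["dy"]]
  dz <- grid$spacing[["dz"]]
  nx <- grid$dims[[1]]; ny <- grid$dims[[2]]; nz <- grid$dims[[3]]
  cell_area <- g$cell_length * g$cell_width * UM^2
  pore_area <- nrow(g$pores$footprints) * g$pores$side^2 * UM^2
  V_vp <- p$venule_layer_thickness * UM * (cell_area - pore_area)
  V_ap <- p$arteriole_layer_thickness * UM * (cell_area - pore_area)

  tmap <- tissue_index_map(grid)
  lab <- grid$labels
  # tissue faces immediately above a venule-plexus node
  kv <- which(apply(lab == node_labels[["plexus_venule"]], 3, any))
  ka <- which(apply(lab == node_labels[["plexus_arteriole"]], 3, any))
  vp_idx <- integer(0); ap_idx <- integer(0)
  if (length(kv) > 0L) {
    k <- min(kv)
    if (k > 1L) {
      sel <- lab[, , k] == node_labels[["plexus_venule"]] & tmap[, , k - 1L] > 0L
      vp_idx <- tmap[, , k - 1L][sel]
    }
  }
  if (length(ka) > 0L) {
    k <- max(ka)
    if (k < nz) {
      sel <- lab[, , k] == node_labels[["plexus_arteriole"]] &
        tmap[, , k + 1L] > 0L
      ap_idx <- tmap[, , k + 1L][sel]
    }
  }
  a_face <- dx * dy * UM^2
  A_vp <- length(vp_idx) * a_face
  A_ap <- length(ap_idx) * a_face
  # internal venule/arteriole interface: the full vessel-occupied lateral
  # area, independent of how many boundary faces the lumen ends occupy
  A_int <- cell_area - pore_area

  has_lumen <- !is.null(grid$lumen) && grid$lumen$n > 0L
  # nominal cross-section: grid-independent, so k_e (and with it the
  # steady-state concentration scale) does not change under refinement;
  # lumen_cross_section() remains the discrete measurement of the same area
  A_cl <- if (has_lumen) pi * (p$lumen_diameter / 2 * UM)^2 else 0
  A_cl_discrete <- if (has_lumen) lumen_cross_section(grid) else 0
  k_e <- params$v_b * A_cl
  half <- p$plexus_total_thickness / 2 * UM
  k1 <- if (is.null(params$k1)) params$D_p / half else params$k1
  k2 <- if (is.null(params$k2)) params$D_p / half else params$k2
  k_pcl <- if (is.null(params$k_pcl)) params$v_b else params$k_pcl

  structure(list(
    V_vp = V_vp, V_ap = V_ap, A_vp = A_vp, A_ap = A_ap, A_int = A_int,
    A_cl = A_cl, A_cl_discrete = A_cl_discrete, k_e = k_e,
    k1 = k1, k2 = k2, k_pcl = k_pcl,
    a_face = a_face, vp_idx = vp_idx, ap_idx = ap_idx,
    cell_area = cell_area, pore_area = pore_area,
    has_lumen = has_lumen, has_plexus = length(vp_idx) + length(ap_idx) > 0L
  ), class = "plexus_coupling")
}

#' Compartment balance rates
#'
#' The venular compartment gains from the tissue face above it (permeability
#' `k_p` over area `A_vp`), from the arteriole compartment (`k2`), and from
#' the capillary-loop outlet (`k_pcl * A_cl * C_b_end`); it loses to the
#' arteriole compartment (`k1`). The arteriolar compartment additionally
#' loses to the loop inlet (`k_pcl * A_cl * C_ap`, conservative) and to the
#' systemic circulation (`k_e * C_ap`, the model's only exit). Every
#' conservative transfer appears with opposite sign in exactly one donor and
#' one recipient balance.
#'
#' @param state A `sim_state` (see [simulate()]).
#' @param params A [transport_params()] object.
#' @param coupling A [plexus_coupling()] object consistent with the state.
#' @return Numeric `c(dC_vp, dC_ap)` in concentration per second.
#' @export
plexus_rhs <- function(state, params, coupling) {
  stopifnot(inherits(coupling, "plexus_coupling"))
  validate_transport_params(params)
  k_p <- params$k_p
  a <- coupling$a_face
  C_vp <- state$C_vp; C_ap <- state$C_ap
  nb <- length(state$C_b)
  C_b_end <- if (nb > 0L) state$C_b[nb] else 0
  ex12 <- coupling$k1 * coupling$A_int * C_vp   # venule -> arteriole
  ex21 <- coupling$k2 * coupling$A_int * C_ap   # arteriole -> venule
  q_vp <- k_p * a * sum(state$C_vs[coupling$vp_idx] - C_vp) +
    ex21 - ex12 + coupling$k_pcl * coupling$A_cl * C_b_end
  q_ap <- k_p * a * sum(state$C_vs[coupling$ap_idx] - C_ap) +
    ex12 - ex21 - coupling$k_pcl * coupling$A_cl * C_ap -
    coupling$k_e * C_ap
  c(dC_vp = if (coupling$V_vp > 0) q_vp / coupling$V_vp else 0,
    dC_ap = if (coupling$V_ap > 0) q_ap / coupling$V_ap else 0)
}
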