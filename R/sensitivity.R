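# Post-processing of steady states (depth profiles, plexus-mean
# concentration, below/top ratio) and the four sensitivity sweeps: plexus
# size, plexus depth, blood velocity, pore density.

#' Concentration field as a 3-D array
#'
#' Expands a state onto the full grid: tissue/pore nodes carry the 3-D
#' field, lumen nodes the blood concentration at their chain position, and
#' plexus vessel nodes the respective compartment concentration.
#'
#' @param state A `sim_state`.
#' @param grid The `labeled_grid` the state was computed on.
#' @return Numeric array with the grid's dimensions.
#' @export
field_array <- function(state, grid) {
  tmap <- tissue_index_map(grid)
  arr <- array(NA_real_, dim = dim(grid$labels))
  sel <- tmap > 0L
  arr[sel] <- state$C_vs[tmap[sel]]
  arr[grid$labels == node_labels[["plexus_venule"]]] <- state$C_vp
  arr[grid$labels == node_labels[["plexus_arteriole"]]] <- state$C_ap
  if (!is.null(grid$lumen) && length(state$C_b) == grid$lumen$n) {
    arr[grid$lumen$idx] <- state$C_b
  }
  arr
}

new_depth_profile <- function(depth_um, concentration, tag, surface = NA_real_,
                              plexus_bottom_um = NA_real_, x_um = NA_real_,
                              y_um = NA_real_) {
  structure(
    data.frame(depth_um = depth_um, concentration = concentration),
    tag = tag, surface = surface, plexus_bottom_um = plexus_bottom_um,
    x_um = x_um, y_um = y_um,
    class = c("depth_profile", "data.frame")
  )
}

#' Concentration versus depth along a vertical sampling line
#'
#' Samples the field along the vertical line one grid cell laterally outward
#' from the lumen surface of the named limb (the concentration "adjacent to
#' the arteriole/venule"). Within the plexus layers the respective
#' compartment concentration is reported. The profile's `surface` attribute
#' holds the concentration extrapolated to z = 0 through the applied-flux
#' boundary condition (`C + J_sc dz / (2 D_vs)`), used by
#' [top_bottom_ratio()].
#'
#' @param state A `sim_state`.
#' @param grid The `labeled_grid` of the run.
#' @param tag `"arteriole_adjacent"`, `"venule_adjacent"` or
#'   `"lateral_mean"` (laterally averaged over the whole cell, vessel areas
#'   weighted by their compartment concentration).
#' @param params The [transport_params()] of the run (for the surface
#'   extrapolation; optional).
#' @return A `depth_profile` data frame (`depth_um`, `concentration`).
#' @export
depth_profile <- function(state, grid, tag = c("arteriole_adjacent",
                                               "venule_adjacent",
                                               "lateral_mean"),
                          params = NULL) {
  if (!is.character(tag) || length(tag) != 1L ||
      !tag %in% c("arteriole_adjacent", "venule_adjacent", "lateral_mean")) {
    stop("depth_profile: unknown tag '", paste(tag, collapse = "/"),
         "'; use 'arteriole_adjacent', 'venule_adjacent' or 'lateral_mean'",
         call. = FALSE)
  }
  geom <- grid$geom
  dz <- grid$spacing[["dz"]]
  pb <- geom$plexus_layer_bounds$arteriole[2]
  surf_extra <- function(cval) {
    if (is.null(params)) return(NA_real_)
    cval + params$J_sc * (dz / 2 * UM) / params$D_vs
  }
  if (tag == "lateral_mean") {
    arr <- field_array(state, grid)
    conc <- apply(arr, 3L, mean, na.rm = TRUE)
    top <- surf_extra(mean(arr[, , 1L]))
    return(new_depth_profile(grid$z, conc, tag, surface = top,
                             plexus_bottom_um = pb))
  }
  cl <- geom$centerline
  r <- geom$params$lumen_diameter / 2
  dx <- grid$spacing[["dx"]]
  x_t <- if (tag == "arteriole_adjacent") cl$x_arteriole - r - dx
         else cl$x_venule + r + dx
  x_t <- ((x_t %% geom$cell_length) + geom$cell_length) %% geom$cell_length
  i <- which.min(abs(grid$x - x_t))
  j <- which.min(abs(grid$y - cl$y))
  col_lab <- grid$labels[i, j, ]
  if (any(col_lab == node_labels[["lumen_arteriole"]] |
          col_lab == node_labels[["lumen_venule"]])) {
    # sampling line clipped the lumen; move one more cell outward
    i <- if (tag == "arteriole_adjacent") {
      if (i == 1L) grid$dims[[1]] else i - 1L
    } else {
      if (i == grid$dims[[1]]) 1L else i + 1L
    }
    col_lab <- grid$labels[i, j, ]
  }
  tmap <- tissue_index_map(grid)
  conc <- vapply(seq_along(grid$z), function(k) {
    lb <- col_lab[k]
    if (lb == node_labels[["plexus_venule"]]) state$C_vp
    else if (lb == node_labels[["plexus_arteriole"]]) state$C_ap
    else if (tmap[i, j, k] > 0L) state$C_vs[tmap[i, j, k]]
    else NA_real_
  }, numeric(1))
  new_depth_profile(grid$z, conc, tag,
                    surface = surf_extra(conc[1L]),
                    plexus_bottom_um = pb,
                    x_um = grid$x[i], y_um = grid$y[j])
}

#' Volume-weighted mean plexus concentration
#'
#' The response variable of all four sensitivity sweeps: the average
#' concentration over both plexus compartments, weighted by their volumes.
#'
#' @param state A `sim_state`.
#' @param coupling A [plexus_coupling()] object.
#' @return A single concentration.
#' @export
plexus_mean_concentration <- function(state, coupling) {
  stopifnot(inherits(coupling, "plexus_coupling"))
  vtot <- coupling$V_vp + coupling$V_ap
  if (vtot <= 0) return(NA_real_)
  (coupling$V_vp * state$C_vp + coupling$V_ap * state$C_ap) / vtot
}

#' Ratio of below-plexus to surface concentration
#'
#' Mean concentration over the band immediately below the arteriole plexus
#' layer (default 50 um thick), divided by the concentration at the top of
#' the viable skin (the profile's `surface` attribute).
#'
#' @param profile A `depth_profile` whose attributes carry the surface value
#'   and the plexus bottom depth.
#' @param band_um Thickness of the averaging band below the plexus (um).
#' @return The ratio as a fraction.
#' @export
top_bottom_ratio <- function(profile, band_um = 50) {
  stopifnot(inherits(profile, "depth_profile"))
  top <- attr(profile, "surface")
  pb <- attr(profile, "plexus_bottom_um")
  if (is.null(top) || is.na(top)) {
    stop("top_bottom_ratio: profile has no surface concentration; rebuild ",
         "it with the run's transport parameters", call. = FALSE)
  }
  if (top == 0) {
    stop("top_bottom_ratio: surface concentration is zero", call. = FALSE)
  }
  sel <- profile$depth_um >= pb & profile$depth_um < pb + band_um
  if (!any(sel)) {
    stop("top_bottom_ratio: profile does not cover the ", band_um,
         " um band below the plexus", call. = FALSE)
  }
  mean(profile$concentration[sel], na.rm = TRUE) / top
}

sweep_geometry <- function(name, value, g) {
  if (name == "plexus_size") {
    mid <- g$plexus_top_depth + g$plexus_total_thickness / 2
    g$plexus_top_depth <- mid - value / 2
    g$plexus_total_thickness <- value
    g$arteriole_layer_thickness <- value / 2
    g$venule_layer_thickness <- value / 2
  } else if (name == "plexus_depth") {
    g$plexus_top_depth <- value
  }
  do.call(geometry_params, unclass(g))
}

#' Run a sensitivity sweep
#'
#' One steady-state run per parameter value; all runs share the base
#' configuration except the swept parameter. The plexus-size sweep keeps the
#' plexus mid-depth fixed and scales both layers symmetrically; the depth
#' sweep moves the plexus top with the thickness fixed; the velocity sweep
#' varies `v_b` (with `k_pcl` tracking it when left at its default); the
#' pore-density sweep varies the pore area fraction at a fixed seed.
#'
#' @param name One of `"plexus_size"`, `"plexus_depth"`, `"velocity"`,
#'   `"pore_density"`.
#' @param values Swept values: um for size and depth, m/s for velocity,
#'   fraction for density.
#' @param geometry Base [geometry_params()].
#' @param transport Base [transport_params()].
#' @param resolution Grid spacing in um.
#' @param tol Steadiness tolerance passed to [steady_state()].
#' @param keep_states Keep the full states in the result (memory-heavy).
#' @return A `sweep_result`: per-value `C_plex`, profiles (arteriole- and
#'   venule-adjacent plus lateral mean), below/top ratios and run metadata.
#' @export
run_sweep <- function(name = c("plexus_size", "plexus_depth", "velocity",
                               "pore_density"),
                      values, geometry = geometry_params(),
                      transport = transport_params(), resolution = 20,
                      tol = 1e-6, keep_states = FALSE) {
  name <- match.arg(name)
  stopifnot(length(values) >= 1L, all(is.finite(values)))
  values_si <- switch(name,
    plexus_size = values * UM, plexus_depth = values * UM,
    velocity = values, pore_density = values)
  n <- length(values)
  C_plex <- rep(NA_real_, n)
  ratio <- rep(NA_real_, n)
  converged <- rep(FALSE, n)
  profiles <- vector("list", n)
  states <- if (keep_states) vector("list", n) else NULL
  for (q in seq_len(n)) {
    g <- geometry
    tp <- transport
    if (name %in% c("plexus_size", "plexus_depth")) {
      g <- sweep_geometry(name, values[q], g)
    } else if (name == "velocity") {
      tp$v_b <- values[q]
    } else {
      g$pore_density <- values[q]
      g <- do.call(geometry_params, unclass(g))
    }
    st <- steady_state(g, tp, resolution = resolution, tol = tol)
    converged[q] <- isTRUE(attr(st, "converged"))
    ops <- attr(st, "ops")
    if (converged[q]) {
      C_plex[q] <- plexus_mean_concentration(st, ops$coupling)
      pr <- list(
        arteriole = depth_profile(st, ops$grid, "arteriole_adjacent", tp),
        venule = depth_profile(st, ops$grid, "venule_adjacent", tp),
        lateral_mean = depth_profile(st, ops$grid, "lateral_mean", tp)
      )
      profiles[[q]] <- pr
      ratio[q] <- top_bottom_ratio(pr$lateral_mean)
    }
    if (keep_states) states[[q]] <- st
  }
  res <- structure(list(
    parameter = name, values = values, values_si = values_si,
    C_plex = C_plex, below_top_ratio = ratio, converged = converged,
    profiles = profiles, states = states,
    meta = list(resolution = resolution, tol = tol,
                pore_seed = geometry$pore_seed)
  ), class = "sweep_result")
  if (!all(converged)) {
    attr(res, "partial") <- TRUE
    warning("run_sweep: non-converged runs at ", name, " = ",
            paste(values[!converged], collapse = ", "), call. = FALSE)
  }
  res
}

#' Summary table of a sweep
#'
#' @param object A `sweep_result`.
#' @param ... Unused.
#' @return Data frame: parameter, value (native units), value in SI, C_plex,
#'   below/top ratio and convergence flag per run.
#' @export
summary.sweep_result <- function(object, ...) {
  data.frame(
    parameter = object$parameter, value = object$values,
    value_si = object$values_si, C_plex = object$C_plex,
    below_top_ratio = object$below_top_ratio, converged = object$converged
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> parameter:", x$parameter, "\n")
  print(summary(x))
  invisible(x)
}

#' Long-format table of all sweep profiles
#'
#' @param sweep A `sweep_result`.
#' @return Data frame with columns `parameter`, `value`, `line_tag`,
#'   `depth_um`, `concentration` — the layout used by the CSV exports.
#' @export
sweep_profiles_long <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  out <- list()
  for (q in seq_along(sweep$values)) {
    pr <- sweep$profiles[[q]]
    if (is.null(pr)) next
    for (tag in names(pr)) {
      p <- pr[[tag]]
      out[[length(out) + 1L]] <- data.frame(
        parameter = sweep$parameter, value = sweep$values[q],
        line_tag = attr(p, "tag"), depth_um = p$depth_um,
        concentration = p$concentration
      )
    }
  }
  do.call(rbind, out)
}
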