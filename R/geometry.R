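# Geometry of the periodic dermal unit cell: one capillary loop, two
# subpapillary-plexus layers and avascular pores. Lengths are in micrometres
# throughout this module; the transport solver converts to SI once.

#' Node label codes used by [classify_nodes()]
#'
#' Integer codes for the region each grid node belongs to: `tissue`,
#' `lumen_arteriole`, `lumen_venule`, `plexus_venule`, `plexus_arteriole`,
#' `pore`.
#'
#' @format Named integer vector of length 6.
#' @export
node_labels <- c(
  tissue = 1L, lumen_arteriole = 2L, lumen_venule = 3L,
  plexus_venule = 4L, plexus_arteriole = 5L, pore = 6L
)

#' Geometric parameters of the skin unit cell
#'
#' Defines the periodic computational unit cell of superficial dermis: an
#' 800 um slab containing one hairpin capillary loop (apex at 150 um depth,
#' 170 um wide, loops spaced 70 um apart) and a two-layer subpapillary plexus
#' (venular layer on top of the arteriolar layer, 25 um each, top at 400 um).
#' A fraction `pore_density` of the plexus lateral area is occupied by
#' avascular pores through which tissue diffusion bypasses the vessels.
#'
#' @param slab_depth Depth of the viable-skin slab (um).
#' @param loop_apex_depth Depth of the capillary-loop apex below the
#'   epidermal-dermal junction (um).
#' @param loop_width Lateral distance between the two limbs of a loop (um).
#' @param loop_spacing Distance between neighbouring loops (um); the unit
#'   cell has lateral extent `loop_width + loop_spacing`.
#' @param loop_length Nominal anatomical loop length (um); retained for
#'   reporting. The constructed limbs descend from the apex to the plexus
#'   top, i.e. vertical reticular venules are treated as extensions of the
#'   venular limb.
#' @param lumen_diameter Capillary lumen diameter (um).
#' @param plexus_top_depth Depth of the top of the subpapillary plexus (um).
#' @param plexus_total_thickness Total plexus thickness (um).
#' @param arteriole_layer_thickness,venule_layer_thickness Thickness of the
#'   two plexus layers (um); must sum to `plexus_total_thickness`.
#' @param pore_density Fraction of plexus lateral area occupied by pores.
#' @param pore_seed Integer seed for the deterministic pore layout.
#' @return An object of class `geometry_params`.
#' @export
geometry_params <- function(slab_depth = 800, loop_apex_depth = 150,
                            loop_width = 170, loop_spacing = 70,
                            loop_length = 215, lumen_diameter = 10,
                            plexus_top_depth = 400,
                            plexus_total_thickness = 50,
                            arteriole_layer_thickness = plexus_total_thickness / 2,
                            venule_layer_thickness = plexus_total_thickness / 2,
                            pore_density = 0.11, pore_seed = 1L) {
  p <- list(
    slab_depth = slab_depth, loop_apex_depth = loop_apex_depth,
    loop_width = loop_width, loop_spacing = loop_spacing,
    loop_length = loop_length, lumen_diameter = lumen_diameter,
    plexus_top_depth = plexus_top_depth,
    plexus_total_thickness = plexus_total_thickness,
    arteriole_layer_thickness = arteriole_layer_thickness,
    venule_layer_thickness = venule_layer_thickness,
    pore_density = pore_density, pore_seed = as.integer(pore_seed)
  )
  class(p) <- "geometry_params"
  validate_geometry_params(p)
  p
}

validate_geometry_params <- function(p) {
  num_fields <- setdiff(names(p), "pore_seed")
  for (f in num_fields) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || !is.finite(p[[f]])) {
      stop("geometry_params: field '", f, "' must be a finite number", call. = FALSE)
    }
  }
  pos <- c("slab_depth", "loop_apex_depth", "loop_width", "loop_spacing",
           "loop_length", "lumen_diameter", "plexus_top_depth",
           "plexus_total_thickness")
  for (f in pos) if (p[[f]] <= 0) {
    stop("geometry_params: field '", f, "' must be positive", call. = FALSE)
  }
  if (p$plexus_top_depth + p$plexus_total_thickness >= p$slab_depth) {
    stop("geometry_params: invalid 'plexus_top_depth': plexus_top_depth + ",
         "plexus_total_thickness must be < slab_depth", call. = FALSE)
  }
  if (p$loop_apex_depth >= p$plexus_top_depth) {
    stop("geometry_params: invalid 'loop_apex_depth': must be above the ",
         "plexus (loop_apex_depth < plexus_top_depth)", call. = FALSE)
  }
  if (abs(p$arteriole_layer_thickness + p$venule_layer_thickness -
          p$plexus_total_thickness) > 1e-9 * p$plexus_total_thickness) {
    stop("geometry_params: invalid 'arteriole_layer_thickness': layer ",
         "thicknesses must sum to plexus_total_thickness", call. = FALSE)
  }
  if (p$pore_density < 0 || p$pore_density > 1) {
    stop("geometry_params: invalid 'pore_density': must be in [0, 1]",
         call. = FALSE)
  }
  invisible(p)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the global
# RNG stream is restored afterwards so geometry construction is pure.
with_local_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  expr
}

#' Build the periodic unit cell
#'
#' Constructs the unit-cell geometry: a square lateral cell of side
#' `loop_width + loop_spacing`, a planar hairpin loop centerline (arteriole
#' limb rising from the plexus top to the apex, a horizontal apex segment,
#' and a venule limb descending back to the plexus top), the two plexus layer
#' depth intervals (venular above arteriolar, half-open `[top, bottom)`), and
#' the seeded pore layout.
#'
#' @param params A [geometry_params()] object.
#' @return An object of class `skin_geometry`.
#' @examples
#' g <- build_unit_cell(geometry_params())
#' g$cell_length  # 240 um
#' @export
build_unit_cell <- function(params) {
  validate_geometry_params(params)
  cell <- params$loop_width + params$loop_spacing
  x_a <- (cell - params$loop_width) / 2
  x_v <- x_a + params$loop_width
  y0 <- cell / 2
  ztop <- params$plexus_top_depth
  apex <- params$loop_apex_depth
  vertices <- rbind(
    c(x_a, y0, ztop),   # arteriole limb inlet (at plexus top)
    c(x_a, y0, apex),   # apex, arteriole side
    c(x_v, y0, apex),   # apex, venule side
    c(x_v, y0, ztop)    # venule limb outlet (at plexus top)
  )
  seg_len <- sqrt(rowSums((vertices[-1, , drop = FALSE] -
                           vertices[-nrow(vertices), , drop = FALSE])^2))
  zv_top <- ztop
  zv_bot <- ztop + params$venule_layer_thickness
  za_bot <- zv_bot + params$arteriole_layer_thickness
  geom <- structure(list(
    params = params,
    cell_length = cell, cell_width = cell,
    centerline = list(vertices = vertices, seg_lengths = seg_len,
                      cum_lengths = c(0, cumsum(seg_len)),
                      total_length = sum(seg_len),
                      x_arteriole = x_a, x_venule = x_v, y = y0),
    plexus_layer_bounds = list(venule = c(zv_top, zv_bot),
                               arteriole = c(zv_bot, za_bot)),
    pores = NULL
  ), class = "skin_geometry")
  place_pores(geom, params$pore_density, params$pore_seed)
}

#' Place avascular pores through the plexus layers
#'
#' Pores are vertical prismatic channels through both plexus layers, realised
#' as square footprints on a regular lateral lattice. A seeded permutation of
#' the lattice sites is drawn once and the first `n` sites are used, where
#' `n` makes the covered area fraction match `density` as closely as the
#' lattice allows (within 0.5 percentage points). The construction is
#' deterministic given `seed` and monotone in `density` (raising the density
#' only adds pores).
#'
#' @param geom A `skin_geometry`.
#' @param density Target lateral-area fraction in `[0, 1]`.
#' @param seed Integer seed.
#' @return The geometry with its `pores` component replaced.
#' @export
place_pores <- function(geom, density, seed = geom$params$pore_seed) {
  stopifnot(inherits(geom, "skin_geometry"))
  if (!is.numeric(density) || length(density) != 1L || !is.finite(density) ||
      density < 0 || density > 1) {
    stop("place_pores: invalid 'density': must be a fraction in [0, 1]",
         call. = FALSE)
  }
  n_lat <- max(10L, as.integer(round(geom$cell_length / 20)))
  side <- geom$cell_length / n_lat
  n_sites <- n_lat^2
  n_pores <- as.integer(round(density * n_sites))
  perm <- with_local_seed(seed, sample.int(n_sites))
  sites <- sort(perm[seq_len(n_pores)])
  ix <- (sites - 1L) %% n_lat          # 0-based lattice column
  iy <- (sites - 1L) %/% n_lat         # 0-based lattice row
  footprints <- data.frame(
    x0 = ix * side, y0 = iy * side, side = rep(side, n_pores)
  )
  achieved <- n_pores / n_sites
  if (abs(achieved - density) > 0.005) {
    stop("place_pores: lattice cannot realise density ", density,
         " within 0.5 percentage points", call. = FALSE)
  }
  geom$pores <- list(footprints = footprints, density_target = density,
                     density_achieved = achieved, seed = as.integer(seed),
                     lattice_n = n_lat, side = side)
  geom
}

# TRUE for lateral points (x, y) lying inside any pore footprint.
in_pore_footprint <- function(geom, x, y) {
  fp <- geom$pores$footprints
  inside <- rep(FALSE, length(x))
  if (is.null(fp) || nrow(fp) == 0L) return(inside)
  for (r in seq_len(nrow(fp))) {
    inside <- inside | (x >= fp$x0[r] & x < fp$x0[r] + fp$side[r] &
                        y >= fp$y0[r] & y < fp$y0[r] + fp$side[r])
  }
  inside
}

# Distance from points P (n x 3) to segment AB, plus arclength of projection.
point_segment_distance <- function(px, py, pz, a, b, s0) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- ((px - a[1]) * ab[1] + (py - a[2]) * ab[2] + (pz - a[3]) * ab[3]) / len2
  t <- pmin(pmax(t, 0), 1)
  dx <- px - (a[1] + t * ab[1])
  dy <- py - (a[2] + t * ab[2])
  dz <- pz - (a[3] + t * ab[3])
  list(dist = sqrt(dx^2 + dy^2 + dz^2), s = s0 + t * sqrt(len2))
}

# Nearest distance to the loop centerline and the arclength of the closest
# point, for arbitrary point sets.
centerline_distance <- function(geom, px, py, pz) {
  cl <- geom$centerline
  best <- rep(Inf, length(px))
  s_best <- rep(0, length(px))
  for (k in seq_len(nrow(cl$vertices) - 1L)) {
    res <- point_segment_distance(px, py, pz,
                                  cl$vertices[k, ], cl$vertices[k + 1L, ],
                                  cl$cum_lengths[k])
    upd <- res$dist < best
    best[upd] <- res$dist[upd]
    s_best[upd] <- res$s[upd]
  }
  list(dist = best, s = s_best)
}

#' Classify grid nodes by region
#'
#' Lays a cell-centered structured grid over the unit cell (z positive
#' downward, 0-based lattice origin at the top corner) and assigns every node
#' exactly one label: `tissue`, `lumen_arteriole`/`lumen_venule` (nodes within
#' half a lumen diameter of the centerline, above the plexus), `plexus_venule`
#' / `plexus_arteriole` (vessel-occupied plexus layers) or `pore`. Lumen nodes
#' are ordered by their projected centerline arclength, forming the 1-D chain
#' on which blood concentration is advected.
#'
#' @param geom A `skin_geometry`.
#' @param resolution Grid spacing in um; a single number or `c(dx, dy, dz)`.
#'   Each spacing must divide the corresponding cell extent.
#' @param include_loop If `FALSE`, no lumen nodes are created (used for
#'   manufactured-solution verification on a pure diffusion box).
#' @return An object of class `labeled_grid`.
#' @export
classify_nodes <- function(geom, resolution, include_loop = TRUE) {
  stopifnot(inherits(geom, "skin_geometry"))
  res <- if (length(resolution) == 1L) rep(resolution, 3L) else resolution
  if (length(res) != 3L || any(!is.finite(res)) || any(res <= 0)) {
    stop("classify_nodes: resolution must be one or three positive spacings",
         call. = FALSE)
  }
  ext <- c(geom$cell_length, geom$cell_width, geom$params$slab_depth)
  n <- ext / res
  if (any(abs(n - round(n)) > 1e-6)) {
    stop("classify_nodes: resolution (", paste(res, collapse = ", "),
         ") must divide the cell extents (", paste(ext, collapse = ", "), ")",
         call. = FALSE)
  }
  n <- as.integer(round(n))
  nx <- n[1]; ny <- n[2]; nz <- n[3]
  dx <- res[1]; dy <- res[2]; dz <- res[3]
  x <- (seq_len(nx) - 0.5) * dx
  y <- (seq_len(ny) - 0.5) * dy
  z <- (seq_len(nz) - 0.5) * dz

  labels <- array(node_labels[["tissue"]], dim = c(nx, ny, nz))

  # Plexus layers (half-open [top, bottom) in node-center depth), with pores.
  pv <- geom$plexus_layer_bounds$venule
  pa <- geom$plexus_layer_bounds$arteriole
  kv <- which(z >= pv[1] & z < pv[2])
  ka <- which(z >= pa[1] & z < pa[2])
  if (length(kv) == 0L || length(ka) == 0L) {
    stop("classify_nodes: dz = ", dz, " too coarse to resolve the plexus ",
         "layers; use a finer grid", call. = FALSE)
  }
  xy <- expand.grid(x = x, y = y)
  pore_lateral <- in_pore_footprint(geom, xy$x, xy$y)
  pore_mask <- matrix(pore_lateral, nx, ny)
  for (k in kv) labels[, , k] <- ifelse(pore_mask, node_labels[["pore"]],
                                        node_labels[["plexus_venule"]])
  for (k in ka) labels[, , k] <- ifelse(pore_mask, node_labels[["pore"]],
                                        node_labels[["plexus_arteriole"]])

  lumen <- NULL
  if (include_loop) {
    d <- geom$params$lumen_diameter
    if (d <= 0) stop("classify_nodes: lumen diameter must be positive",
                     call. = FALSE)
    if (d < max(dx, dy)) {
      stop("classify_nodes: resolution too coarse to resolve the ",
           d, " um lumen (need max(dx, dy) <= lumen_diameter); use a finer ",
           "grid or a wider lumen", call. = FALSE)
    }
    r <- d / 2
    ztop <- geom$params$plexus_top_depth
    cand_k <- which(z < ztop)
    grd <- expand.grid(x = x, y = y, z = z[cand_k])
    cd <- centerline_distance(geom, grd$x, grd$y, grd$z)
    is_lum <- cd$dist < r
    lum_lin <- which(is_lum)
    # linear index into the full array
    idx_full <- function(ii, jj, kk) ii + (jj - 1L) * nx + (kk - 1L) * nx * ny
    ii <- ((lum_lin - 1L) %% nx) + 1L
    jj <- (((lum_lin - 1L) %/% nx) %% ny) + 1L
    kk <- cand_k[((lum_lin - 1L) %/% (nx * ny)) + 1L]
    lin <- idx_full(ii, jj, kk)
    s_lum <- cd$s[lum_lin]

    # Guarantee every centerline point maps to at least one lumen node:
    # force-label the node nearest each densely sampled centerline point.
    cl <- geom$centerline
    s_smp <- seq(0, cl$total_length, by = min(dz, dx, dy) / 2)
    pts <- centerline_points(geom, s_smp)
    nearest_idx <- function(v, dv, nv) pmin(pmax(as.integer(
      floor(v / dv - 1e-9) + 1L), 1L), nv)
    fi <- nearest_idx(pts[, 1], dx, nx)
    fj <- nearest_idx(pts[, 2], dy, ny)
    fk <- pmin(nearest_idx(pts[, 3], dz, nz), max(which(z < ztop)))
    flin <- idx_full(fi, fj, fk)
    fs <- s_smp
    new <- !(flin %in% lin)
    lin <- c(lin, flin[new])
    s_lum <- c(s_lum, fs[new])
    dup <- duplicated(lin)
    lin <- lin[!dup]; s_lum <- s_lum[!dup]
    # never overwrite plexus/pore labels (lumen lives above the plexus)
    ok <- labels[lin] == node_labels[["tissue"]]
    lin <- lin[ok]; s_lum <- s_lum[ok]

    ord <- order(s_lum, lin)
    lin <- lin[ord]; s_lum <- s_lum[ord]
    limb <- ifelse(s_lum <= cl$total_length / 2, "arteriole", "venule")
    labels[lin] <- ifelse(limb == "arteriole",
                          node_labels[["lumen_arteriole"]],
                          node_labels[["lumen_venule"]])
    N <- length(lin)
    lumen <- list(
      idx = lin, s = s_lum, limb = limb, n = N,
      ds = cl$total_length / N, length = cl$total_length, diameter = d
    )
  }

  structure(list(
    geom = geom, spacing = c(dx = dx, dy = dy, dz = dz),
    dims = c(nx = nx, ny = ny, nz = nz),
    x = x, y = y, z = z, labels = labels, lumen = lumen
  ), class = "labeled_grid")
}

# 3-D points on the centerline at arclengths s.
centerline_points <- function(geom, s) {
  cl <- geom$centerline
  s <- pmin(pmax(s, 0), cl$total_length)
  out <- matrix(0, length(s), 3L)
  for (k in seq_len(nrow(cl$vertices) - 1L)) {
    lo <- cl$cum_lengths[k]; hi <- cl$cum_lengths[k + 1L]
    sel <- s >= lo & (s < hi | (k == nrow(cl$vertices) - 1L & s <= hi))
    if (!any(sel)) next
    t <- (s[sel] - lo) / (hi - lo)
    a <- cl$vertices[k, ]; b <- cl$vertices[k + 1L, ]
    out[sel, ] <- cbind(a[1] + t * (b[1] - a[1]),
                        a[2] + t * (b[2] - a[2]),
                        a[3] + t * (b[3] - a[3]))
  }
  out
}

#' Count grid nodes per region label
#'
#' @param grid A `labeled_grid`.
#' @return Named integer vector over the six label classes.
#' @export
label_counts <- function(grid) {
  stopifnot(inherits(grid, "labeled_grid"))
  tab <- tabulate(grid$labels, nbins = 6L)
  names(tab) <- names(node_labels)
  tab
}

#' Map grid nodes to tissue-field unknowns
#'
#' Tissue and pore nodes carry the 3-D concentration field; vessel (lumen and
#' plexus) nodes do not. Returns an integer array of the grid's shape holding
#' the unknown index of each tissue/pore node and 0 elsewhere. The ordering
#' (by linear node index) is shared by the solver and the oracle.
#'
#' @param grid A `labeled_grid`.
#' @return Integer array, same dimensions as `grid$labels`.
#' @export
tissue_index_map <- function(grid) {
  tmap <- array(0L, dim = dim(grid$labels))
  sel <- grid$labels == node_labels[["tissue"]] |
    grid$labels == node_labels[["pore"]]
  tmap[sel] <- seq_len(sum(sel))
  tmap
}

#' @export
print.skin_geometry <- function(x, ...) {
  p <- x$params
  cat("<skin_geometry>\n")
  cat(sprintf("  unit cell: %g x %g x %g um\n", x$cell_length, x$cell_width,
              p$slab_depth))
  cat(sprintf("  capillary loop: apex %g um, width %g um, lumen %g um, centerline %g um\n",
              p$loop_apex_depth, p$loop_width, p$lumen_diameter,
              x$centerline$total_length))
  cat(sprintf("  plexus: venule layer [%g, %g) um, arteriole layer [%g, %g) um\n",
              x$plexus_layer_bounds$venule[1], x$plexus_layer_bounds$venule[2],
              x$plexus_layer_bounds$arteriole[1],
              x$plexus_layer_bounds$arteriole[2]))
  cat(sprintf("  pores: %d footprints, area fraction %.4f (target %.4f, seed %d)\n",
              nrow(x$pores$footprints), x$pores$density_achieved,
              x$pores$density_target, x$pores$seed))
  invisible(x)
}

#' @export
print.labeled_grid <- function(x, ...) {
  cat("<labeled_grid>\n")
  cat(sprintf("  dims: %d x %d x %d at (%g, %g, %g) um\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cnt <- label_counts(x)
  cat("  labels:", paste(sprintf("%s=%d", names(cnt), cnt), collapse = " "),
      "\n")
  if (!is.null(x$lumen)) {
    cat(sprintf("  lumen chain: %d nodes, ds = %.2f um\n", x$lumen$n,
                x$lumen$ds))
  }
  invisible(x)
}

#' Tabular summary of a geometry
#'
#' @param object A `skin_geometry`.
#' @param ... Unused.
#' @return A data frame of named geometric quantities (um or fraction).
#' @export
summary.skin_geometry <- function(object, ...) {
  p <- object$params
  data.frame(
    quantity = c("cell_length", "cell_width", "slab_depth", "loop_apex_depth",
                 "loop_width", "loop_spacing", "lumen_diameter",
                 "centerline_length", "plexus_top_depth",
                 "plexus_total_thickness", "pore_density_achieved"),
    value = c(object$cell_length, object$cell_width, p$slab_depth,
              p$loop_apex_depth, p$loop_width, p$loop_spacing,
              p$lumen_diameter, object$centerline$total_length,
              p$plexus_top_depth, p$plexus_total_thickness,
              object$pores$density_achieved),
    unit = c(rep("um", 10), "fraction")
  )
}
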