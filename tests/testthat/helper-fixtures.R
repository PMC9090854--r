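# Shared fixtures. The coarse configuration uses a 20 um grid with a 20 um
# lumen so the capillary loop stays resolvable; heavy objects are memoised
# across test files.

.fix <- new.env(parent = emptyenv())

coarse_geometry <- function(...) {
  geometry_params(lumen_diameter = 20, ...)
}

coarse_grid <- function() {
  if (is.null(.fix$grid)) {
    .fix$grid <- classify_nodes(build_unit_cell(coarse_geometry()), 20)
  }
  .fix$grid
}

coarse_ops <- function() {
  if (is.null(.fix$ops)) {
    .fix$ops <- assemble_operators(coarse_grid(), transport_params())
  }
  .fix$ops
}

# standard steady run on the coarse grid
coarse_steady <- function() {
  if (is.null(.fix$steady)) {
    .fix$steady <- steady_state(coarse_geometry(), transport_params(),
                                resolution = 20)
  }
  .fix$steady
}

# a vessel-free diffusion box: every plexus node is pore, no loop
box_geometry <- function(...) {
  geometry_params(pore_density = 1, ...)
}

random_state <- function(ops, seed = 7) {
  st <- zero_state(ops)
  set.seed(seed)
  st$C_vs <- stats::runif(ops$n_t)
  if (length(st$C_b) > 0L) st$C_b <- stats::runif(length(st$C_b))
  st$C_vp <- 0.5
  st$C_ap <- 0.3
  st
}

rel_dev <- function(a, b, scale = max(abs(a), abs(b))) {
  max(abs(a - b)) / scale
}
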