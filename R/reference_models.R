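# Steady-state closed forms of the simpler depthwise dermal transport
# models used for side-by-side comparison with the full plexus simulation:
# the homogeneous membrane, distributed elimination, and
# convection-dispersion-elimination models.

#' Specification of a depthwise comparison model
#'
#' @param model `"homogeneous"`, `"distributed_elimination"` or
#'   `"convection_dispersion_elimination"`.
#' @param D Diffusion (or dispersion) coefficient (m2/s).
#' @param k_el First-order elimination rate representing capillary uptake
#'   (1/s); unused by the homogeneous model.
#' @param v Downward convection velocity (m/s); used only by the
#'   convection-dispersion model.
#' @param L Sink depth (m); used only by the homogeneous model.
#' @param J Applied flux at z = 0 (amount m-2 s-1).
#' @return An object of class `depth_model_spec`.
#' @export
depth_model_spec <- function(model = c("homogeneous",
                                       "distributed_elimination",
                                       "convection_dispersion_elimination"),
                             D, k_el = 0, v = 0, L = NA_real_, J = 1) {
  model <- match.arg(model)
  if (!is.numeric(D) || D <= 0) {
    stop("depth_model_spec: D must be positive", call. = FALSE)
  }
  if (k_el < 0 || v < 0 || J < 0) {
    stop("depth_model_spec: k_el, v and J must be nonnegative",
         call. = FALSE)
  }
  if (model == "homogeneous" && (!is.finite(L) || L <= 0)) {
    stop("depth_model_spec: homogeneous model needs a positive sink ",
         "depth L", call. = FALSE)
  }
  structure(list(model = model, D = D, k_el = k_el, v = v, L = L, J = J),
            class = "depth_model_spec")
}

ref_profile <- function(depths_um, conc, model, surface) {
  new_depth_profile(depths_um, conc, tag = model, surface = surface)
}

#' Homogeneous membrane model, steady state
#'
#' Linear profile `C(z) = J (L - z) / D`, zero at and below the sink depth.
#'
#' @param spec A `depth_model_spec` with `model = "homogeneous"`.
#' @param depths_um Depths at which to evaluate (um).
#' @return A `depth_profile`.
#' @export
homogeneous_steady <- function(spec, depths_um) {
  stopifnot(inherits(spec, "depth_model_spec"), spec$model == "homogeneous")
  z <- depths_um * UM
  conc <- pmax(spec$J * (spec$L - z) / spec$D, 0)
  ref_profile(depths_um, conc, spec$model, surface = spec$J * spec$L / spec$D)
}

#' Distributed-elimination model, steady state
#'
#' Depthwise diffusion with first-order removal on a semi-infinite domain:
#' `C(z) = (J / sqrt(D k_el)) exp(-sqrt(k_el / D) z)`. The flux continuity
#' `-D C'(0) = J` holds identically.
#'
#' @param spec A `depth_model_spec` with `model =
#'   "distributed_elimination"` and `k_el > 0`.
#' @param depths_um Depths at which to evaluate (um).
#' @return A `depth_profile`.
#' @export
distributed_elimination_steady <- function(spec, depths_um) {
  stopifnot(inherits(spec, "depth_model_spec"),
            spec$model == "distributed_elimination")
  if (spec$k_el <= 0) {
    stop("distributed_elimination_steady: k_el = 0 has no steady decay; ",
         "use the homogeneous model instead", call. = FALSE)
  }
  z <- depths_um * UM
  lam <- sqrt(spec$k_el / spec$D)
  c0 <- spec$J / sqrt(spec$D * spec$k_el)
  ref_profile(depths_um, c0 * exp(-lam * z), spec$model, surface = c0)
}

#' Convection-dispersion-elimination model, steady state
#'
#' Steady solutions of `D C'' - v C' - k_el C = 0` with downward convection:
#' `C(z) = C0 exp(lambda_- z)` where `lambda_-` is the negative (decaying)
#' root of `D lambda^2 - v lambda - k_el = 0` and `C0` satisfies flux
#' continuity `(-D lambda_- + v) C0 = J` at the surface. With `v = 0` this
#' reduces exactly to the distributed-elimination model; with `k_el = 0` the
#' decaying root vanishes and pure downward convection sustains a constant
#' profile `C = J / v`.
#'
#' @param spec A `depth_model_spec` with `model =
#'   "convection_dispersion_elimination"`.
#' @param depths_um Depths at which to evaluate (um).
#' @return A `depth_profile`.
#' @export
convection_dispersion_steady <- function(spec, depths_um) {
  stopifnot(inherits(spec, "depth_model_spec"),
            spec$model == "convection_dispersion_elimination")
  if (spec$v == 0 && spec$k_el == 0) {
    stop("convection_dispersion_steady: degenerate spec (v = 0 and ",
         "k_el = 0)", call. = FALSE)
  }
  z <- depths_um * UM
  lam <- (spec$v - sqrt(spec$v^2 + 4 * spec$D * spec$k_el)) / (2 * spec$D)
  c0 <- spec$J / (spec$v - spec$D * lam)
  ref_profile(depths_um, c0 * exp(lam * z), spec$model, surface = c0)
}

eval_depth_model <- function(spec, depths_um) {
  switch(spec$model,
    homogeneous = homogeneous_steady(spec, depths_um),
    distributed_elimination = distributed_elimination_steady(spec, depths_um),
    convection_dispersion_elimination =
      convection_dispersion_steady(spec, depths_um))
}

#' Reference model specs matched to a simulated profile
#'
#' The published comparison gives no coefficients for the simpler models, so
#' defaults are derived from the full simulation: each model's surface slope
#' is matched to the simulated profile's initial log-slope
#' `mu = -C'(0)/C(0)` — the homogeneous sink depth is `1/mu`, the
#' distributed-elimination rate is `k_el = D mu^2`, and the
#' convection-dispersion model reuses that `k_el` with the supplied
#' convection velocity (its surface gradient is then necessarily shallower).
#'
#' @param sim_profile A `depth_profile` from the full simulation.
#' @param D Tissue diffusivity (m2/s).
#' @param v Convection velocity for the dispersion model (m/s).
#' @param J Applied flux (amount m-2 s-1).
#' @return Named list of three `depth_model_spec` objects.
#' @export
matched_reference_specs <- function(sim_profile, D, v = 1e-7, J = 1) {
  stopifnot(inherits(sim_profile, "depth_profile"))
  c1 <- sim_profile$concentration[1]
  c2 <- sim_profile$concentration[2]
  dz <- (sim_profile$depth_um[2] - sim_profile$depth_um[1]) * UM
  mu <- max((c1 - c2) / (dz * (c1 + c2) / 2), .Machine$double.eps)
  list(
    homogeneous = depth_model_spec("homogeneous", D = D, L = 1 / mu, J = J),
    distributed_elimination = depth_model_spec(
      "distributed_elimination", D = D, k_el = D * mu^2, J = J),
    convection_dispersion_elimination = depth_model_spec(
      "convection_dispersion_elimination", D = D, k_el = D * mu^2, v = v,
      J = J)
  )
}

#' Side-by-side model comparison table
#'
#' Evaluates each closed-form model on the simulated profile's depth grid and
#' normalises every column (including the simulation) to its surface value,
#' so all curves start at 1 at z = 0.
#'
#' @param specs Named list of `depth_model_spec` objects.
#' @param sim_profile A `depth_profile` from the full simulation (its
#'   `surface` attribute is required for normalisation).
#' @return Data frame: `depth_um`, one normalised column per model, and
#'   `simulation`.
#' @export
compare_models <- function(specs, sim_profile) {
  stopifnot(inherits(sim_profile, "depth_profile"))
  if (!is.list(specs) || is.null(names(specs)) || any(names(specs) == "")) {
    stop("compare_models: specs must be a named list of depth_model_spec",
         call. = FALSE)
  }
  surf <- attr(sim_profile, "surface")
  if (is.null(surf) || is.na(surf) || surf == 0) {
    stop("compare_models: simulated profile has no surface value to ",
         "normalise by", call. = FALSE)
  }
  depths <- sim_profile$depth_um
  out <- data.frame(depth_um = depths)
  for (nm in names(specs)) {
    pr <- eval_depth_model(specs[[nm]], depths)
    out[[nm]] <- pr$concentration / attr(pr, "surface")
  }
  out$simulation <- sim_profile$concentration / surf
  out
}
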