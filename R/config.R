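# Run configuration: flat YAML sections validated against the geometry and
# transport constructors. Lengths in the geometry section are micrometres,
# transport constants SI; the conversion happens once, inside the model
# constructors.

config_sections <- function() {
  list(
    geometry = names(formals(geometry_params)),
    transport = names(formals(transport_params)),
    numerics = c("resolution", "steady_tol", "dt", "horizon", "bottom_bc",
                 "include_loop"),
    sweep = c("name", "values"),
    output = c("dir", "formats"),
    seed = NULL
  )
}

#' Default run configuration
#'
#' All published defaults: the standard geometry (150/170/70/800 um loop
#' and slab, plexus top 400 um, two 25 um layers, 11% pores), blood velocity
#' 0.65 mm/s, endothelial permeability 1e-6 m/s, unit applied flux.
#'
#' @return A `run_config` list.
#' @export
default_config <- function() {
  structure(list(
    geometry = unclass(geometry_params()),
    transport = unclass(transport_params()),
    numerics = list(resolution = 20, steady_tol = 1e-6, dt = NULL,
                    horizon = NULL, bottom_bc = "zero_flux",
                    include_loop = TRUE),
    sweep = list(name = NULL, values = NULL),
    output = list(dir = ".", formats = "csv"),
    seed = 1L
  ), class = "run_config")
}

#' Load and validate a run configuration
#'
#' Reads a YAML file, rejects unknown sections or keys by name, merges the
#' values over the defaults, and validates the result through
#' [geometry_params()] and [transport_params()] so that any invariant
#' violation is reported against the offending field. An empty file yields
#' the full default configuration.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A validated `run_config` with attribute `hash` (a stable content
#'   hash used for output provenance).
#' @export
load_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop("load_config: config file not found: ", path, call. = FALSE)
    }
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  known <- config_sections()
  bad <- setdiff(names(user), names(known))
  if (length(bad) > 0L) {
    stop("load_config: unknown config section(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cfg <- default_config()
  for (sec in names(user)) {
    if (sec == "seed") {
      cfg$seed <- as.integer(user$seed)
      next
    }
    keys <- names(user[[sec]])
    badk <- setdiff(keys, known[[sec]])
    if (length(badk) > 0L) {
      stop("load_config: unknown key(s) in section '", sec, "': ",
           paste(badk, collapse = ", "), call. = FALSE)
    }
    # NULL values (written as '~' by save_config) mean "keep the default";
    # assigning them would silently delete the key
    for (k in keys) {
      if (!is.null(user[[sec]][[k]])) cfg[[sec]][[k]] <- user[[sec]][[k]]
    }
  }
  cfg$geometry$pore_seed <- cfg$seed
  cfg$geometry <- unclass(do.call(geometry_params, cfg$geometry))
  cfg$transport <- unclass(do.call(transport_params, cfg$transport))
  if (!is.null(cfg$sweep$name) &&
      !cfg$sweep$name %in% c("plexus_size", "plexus_depth", "velocity",
                             "pore_density")) {
    stop("load_config: unknown sweep name '", cfg$sweep$name, "'",
         call. = FALSE)
  }
  if (!cfg$numerics$bottom_bc %in% c("zero_flux", "sink")) {
    stop("load_config: numerics.bottom_bc must be 'zero_flux' or 'sink'",
         call. = FALSE)
  }
  attr(cfg, "hash") <- config_hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' Save a run configuration
#'
#' Writes the effective configuration as YAML; [load_config()] on the result
#' reproduces it exactly.
#'
#' @param cfg A `run_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  out <- unclass(cfg)
  attr(out, "hash") <- NULL
  yaml::write_yaml(out, path)
  invisible(path)
}

# Polynomial rolling hash over the serialised YAML text: a small stable
# content hash for output provenance (no cryptographic intent).
config_hash <- function(cfg) {
  out <- unclass(cfg)
  attr(out, "hash") <- NULL
  txt <- yaml::as.yaml(out)
  bytes <- utf8ToInt(txt)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> hash:", attr(x, "hash"), "\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}
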