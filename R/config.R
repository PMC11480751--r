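## Run configuration: nested key/value sections with unit-annotated keys,
## YAML on disk, validated against the engine defaults (unknown keys are
## rejected with their path).

#' Default run configuration
#'
#' Returns the full configuration for an engine with the fitted escape
#' motility parameters as defaults: `phi_B = 2.7` rad, `v_jump = 26.6` and
#' `v_return = 7.6` um/s, `lambda_minus = 0.0413` and `lambda_plus = 0.4186`
#' s^-1, `c_star = 2.5` uM, colony radius `a = 4.3` um.  The point engine
#' defaults to the standard escape protocol (150 colonies at the interface
#' for 17 s); the squirmer engine to a hexagonal `n_layers x 10` lattice
#' against the wall.
#'
#' @param engine `"point"` or `"squirmer"`.
#' @return a nested list of class `"run_config"`.
#' @export
default_config <- function(engine = c("point", "squirmer")) {
  engine <- match.arg(engine)
  cfg <- list(
    engine = engine,
    seed = 1L,
    environment = list(
      oxygen = list(C0_uM = 250, D_C_um2_s = 2000, c_star_uM = 2.5,
                    enabled = TRUE),
      magnetic = list(phi_B_rad = 2.7, k_per_s = 10)
    ),
    motility = list(v_jump_um_s = 26.6, v_return_um_s = 7.6,
                    D_um2_s = 0.05, D_r_rad2_s = 0.002,
                    lambda_minus_per_s = 0.0413, lambda_plus_per_s = 0.4186),
    clock = list(dt_s = 1e-3, t_final_s = 17, record_every = 33L),
    init = list(n_colonies = 150L, x0_um = 0, jitter_um = 4.3, phi0_rad = NULL,
                mode0 = "jump")
  )
  if (engine == "squirmer") {
    cfg$environment$magnetic <- list(phi_B_rad = pi, k_per_s = 10)
    cfg$clock <- list(dt_s = 5e-4, t_final_s = 20, record_every = 200L)
    cfg$init <- NULL
    cfg$squirmer <- list(beta = 1, a_um = 4.3, eta_Pa_s = 1e-3,
                         contact_eps = 1e-3, rep_strength_pN = 2,
                         rep_range_um = 0.215, neighbor_cutoff = 3,
                         lub_normal = 1, lub_tangential = 1,
                         domain_width_um = NULL)
    cfg$lattice <- list(n_layers = 2L, n_per_layer = 10L, spacing = 2.2,
                        wall_offset_um = NULL)
  }
  class(cfg) <- "run_config"
  cfg
}

## keys whose value may legitimately be NULL (meaning "derive a default")
.nullable_keys <- c("init.phi0_rad", "squirmer.domain_width_um",
                    "lattice.wall_offset_um")

check_unknown <- function(cfg, ref, path = character()) {
  for (nm in names(cfg)) {
    p <- paste(c(path, nm), collapse = ".")
    if (!nm %in% names(ref))
      stop("unknown config key: ", p, call. = FALSE)
    if (is.list(ref[[nm]]) && !is.null(cfg[[nm]])) {
      if (!is.list(cfg[[nm]]))
        stop("config key ", p, " must be a section", call. = FALSE)
      check_unknown(cfg[[nm]], ref[[nm]], c(path, nm))
    }
  }
}

#' Validate (and complete) a run configuration
#'
#' Fills omitted fields from [default_config()], rejects unknown keys with
#' their full path, and checks ranges/finiteness of all physical values.
#'
#' @param config a (possibly partial) configuration list.
#' @return a complete, validated `run_config`.
#' @export
validate_config <- function(config) {
  if (is.null(config$engine)) config$engine <- "point"
  ref <- default_config(config$engine)
  check_unknown(unclass(config), unclass(ref))
  cfg <- modifyList(unclass(ref), unclass(config))
  ## modifyList drops NULL assignments; restore nullable keys
  class(cfg) <- "run_config"

  req_pos <- function(val, key) {
    if (is.null(val) || !is.numeric(val) || !is.finite(val) || val <= 0)
      stop("config key ", key, " must be a finite number > 0", call. = FALSE)
  }
  req_nonneg <- function(val, key) {
    if (is.null(val) || !is.numeric(val) || !is.finite(val) || val < 0)
      stop("config key ", key, " must be a finite number >= 0", call. = FALSE)
  }
  with(cfg$environment$oxygen, {
    req_pos(C0_uM, "environment.oxygen.C0_uM")
    req_pos(D_C_um2_s, "environment.oxygen.D_C_um2_s")
    req_pos(c_star_uM, "environment.oxygen.c_star_uM")
  })
  req_nonneg(cfg$environment$magnetic$k_per_s, "environment.magnetic.k_per_s")
  with(cfg$motility, {
    req_nonneg(v_jump_um_s, "motility.v_jump_um_s")
    req_nonneg(v_return_um_s, "motility.v_return_um_s")
    req_nonneg(D_um2_s, "motility.D_um2_s")
    req_nonneg(D_r_rad2_s, "motility.D_r_rad2_s")
    req_pos(lambda_minus_per_s, "motility.lambda_minus_per_s")
    req_pos(lambda_plus_per_s, "motility.lambda_plus_per_s")
  })
  if (cfg$motility$lambda_plus_per_s < cfg$motility$lambda_minus_per_s)
    stop("config: motility.lambda_plus_per_s must be >= lambda_minus_per_s",
         call. = FALSE)
  req_pos(cfg$clock$dt_s, "clock.dt_s")
  req_pos(cfg$clock$t_final_s, "clock.t_final_s")
  req_pos(cfg$clock$record_every, "clock.record_every")
  if (!is.null(cfg$init)) {
    req_nonneg(cfg$init$n_colonies, "init.n_colonies")
    req_nonneg(cfg$init$jitter_um, "init.jitter_um")
  }
  if (!is.null(cfg$squirmer)) {
    with(cfg$squirmer, {
      req_pos(a_um, "squirmer.a_um")
      req_pos(eta_Pa_s, "squirmer.eta_Pa_s")
      req_pos(contact_eps, "squirmer.contact_eps")
      req_nonneg(rep_strength_pN, "squirmer.rep_strength_pN")
      req_pos(rep_range_um, "squirmer.rep_range_um")
      req_pos(neighbor_cutoff, "squirmer.neighbor_cutoff")
    })
    if (cfg$squirmer$neighbor_cutoff <= 2)
      stop("config: squirmer.neighbor_cutoff must exceed 2 (units of a)",
           call. = FALSE)
    req_pos(cfg$lattice$n_layers, "lattice.n_layers")
    req_pos(cfg$lattice$n_per_layer, "lattice.n_per_layer")
    if (cfg$lattice$spacing < 2)
      stop("config: lattice.spacing must be >= 2 colony radii ",
           "(centres at least one diameter apart)", call. = FALSE)
  }
  if (!is.numeric(cfg$seed) || !is.finite(cfg$seed))
    stop("config: seed must be an integer", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Load a run configuration from a YAML file
#'
#' Omitted fields are filled with the fitted defaults; unknown keys are
#' rejected.  An empty file yields the full default configuration.
#'
#' @param path YAML file path.
#' @return a validated `run_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  validate_config(raw)
}

#' Save a run configuration to YAML
#'
#' The saved file round-trips: `load_config(save_config(cfg, f))` resolves
#' to the same configuration.
#'
#' @param config a `run_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(drop_null(unclass(config)), path)
  invisible(path)
}

drop_null <- function(x) {
  if (!is.list(x)) return(x)
  x <- x[!vapply(x, is.null, logical(1))]
  lapply(x, drop_null)
}

## short stable hash of a configuration (for output headers)
config_hash <- function(config) {
  s <- paste(deparse(drop_null(unclass(config))), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config: %s engine, seed %d, hash %s>\n",
              x$engine, x$seed, config_hash(x)))
  utils::str(drop_null(unclass(x)), give.attr = FALSE)
  invisible(x)
}

#' Run a simulation from a configuration
#'
#' Dispatches to [run_point_simulation()] or [run_squirmer_simulation()]
#' according to `config$engine`.
#'
#' @param config a `run_config`.
#' @return a `trajectory_set`.
#' @export
run_simulation <- function(config) {
  config <- validate_config(config)
  switch(config$engine,
         point = run_point_simulation(config),
         squirmer = run_squirmer_simulation(config))
}
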