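# shared fixtures: small, fast run configurations built in code

quick_point_cfg <- function(n = 20, t_final = 4, seed = 1, ...) {
  cfg <- default_config("point")
  cfg$init$n_colonies <- n
  cfg$clock$t_final_s <- t_final
  cfg$seed <- seed
  edits <- list(...)
  if (length(edits)) cfg <- utils::modifyList(cfg, edits)
  cfg
}

quick_squirmer_cfg <- function(n_layers = 2, t_final = 2, seed = 1, ...) {
  cfg <- default_config("squirmer")
  cfg$lattice$n_layers <- n_layers
  cfg$clock$t_final_s <- t_final
  cfg$seed <- seed
  edits <- list(...)
  if (length(edits)) cfg <- utils::modifyList(cfg, edits)
  cfg
}

# deterministic point configuration: no noise, no reversals (sensing off)
deterministic_point_cfg <- function(n = 1, t_final = 1, k = 5, phi0 = 0.7,
                                    dt = 1e-3) {
  cfg <- quick_point_cfg(n = n, t_final = t_final)
  cfg$motility$D_um2_s <- 0
  cfg$motility$D_r_rad2_s <- 0
  cfg$environment$oxygen$enabled <- FALSE
  cfg$environment$magnetic$k_per_s <- k
  cfg$init$jitter_um <- 0
  cfg$init$x0_um <- 500
  cfg$init$phi0_rad <- phi0
  cfg$clock$dt_s <- dt
  cfg$clock$record_every <- 1L
  cfg
}

# closed form of the deterministic alignment equation dphi/dt = k sin(phi_B - phi)
alignment_closed_form <- function(t, phi0, phi_B, k) {
  phi_B - 2 * atan(tan((phi_B - phi0) / 2) * exp(-k * t))
}
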