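# shared builders for the suite

dom_rect40 <- function() domain_spec("periodic_rectangle", L = 40, H = 40)
dom_cyl <- function(L = 40, R = 6) domain_spec("capped_cylinder", L = L, radius = R)
dom_box17 <- function() domain_spec("box", L = 17, H = 17, W2 = 17)

default_dyn <- function(r_c = 0.002, ...) dynamic_params(r_c = r_c, ...)

# a quiet configuration: no nucleation, no stochastic switching
quiet_config <- function(domain, initial_mts, T_end, seed = 1L, ...) {
  sim_config(domain,
             dynamic_params(r_c = 0, r_r = 0, ...),
             nucleation_params("ISO", r_n = 0),
             T_end = T_end, obs_interval = max(T_end / 4, 1),
             seed = seed, initial_mts = initial_mts)
}

# random toy configuration for cross-engine comparisons: deterministic
# collision dynamics (no stochastic switching, P_cat 0 or 1)
toy_oracle_config <- function(seed, n_mt = 10L, T_end = 60, P_cat = 1) {
  set.seed(seed)
  dom <- domain_spec("periodic_rectangle", L = 20, H = 20)
  im <- data.frame(face = 1L,
                   x = stats::runif(n_mt, 0, 20),
                   y = stats::runif(n_mt, 0, 20),
                   theta = stats::runif(n_mt, -pi, pi),
                   length = stats::runif(n_mt, 2, 6))
  sim_config(dom, dynamic_params(r_c = 0, r_r = 0, P_cat = P_cat),
             nucleation_params("ISO", r_n = 0),
             T_end = T_end, obs_interval = T_end, seed = seed,
             initial_mts = im)
}
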