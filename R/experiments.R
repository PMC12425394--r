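# Preset in-silico experiments and result-bundle IO. Presets are desk-scale
# reproductions of the study designs (reduced horizons and replicate counts,
# configurable via overrides); all randomness flows from one seed through
# per-replicate derived streams that are echoed in the bundle.

.derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483629 + 1)
}

.preset_names <- c("homogeneity", "alignment_curve", "cylinder_orientation",
                   "geometry_sweep", "nucleation_diag")

# run n replicates of a config (varying only the seed); returns per-replicate
# summaries and the sims themselves
.run_replicates <- function(cfg, n, seed, keep_sims = FALSE) {
  sums <- vector("list", n)
  sims <- if (keep_sims) vector("list", n) else NULL
  for (k in seq_len(n)) {
    ck <- cfg
    ck$seed <- .derive_seed(seed, k)
    sim <- run_simulation(ck)
    om <- order_metrics(sim$snapshot, cfg$domain)
    sums[[k]] <- data.frame(replicate = k, seed = ck$seed, status = sim$status,
                            density = om$density, S2 = om$S2,
                            Theta2 = om$Theta2, R2 = om$R2,
                            Theta2_3d = om$Theta2_3d,
                            class = ifelse(is.na(om$class), "empty", om$class),
                            renormalized_R2 = om$renormalized_R2,
                            n_c = sim$n_c, n_bound = sim$n_bound,
                            n_unbound = sim$n_unbound)
    if (keep_sims) sims[[k]] <- sim
  }
  list(summary = do.call(rbind, sums), sims = sims)
}

# binomial 95% confidence interval for a class fraction
.binom_ci <- function(x, n) {
  if (n == 0) return(c(NA_real_, NA_real_))
  bt <- stats::binom.test(x, n)
  as.numeric(bt$conf.int)
}

#' Run a preset in-silico experiment
#'
#' Available presets (all desk-scale by default; `overrides` merge over the
#' preset defaults and are echoed in the result):
#' \describe{
#'   \item{homogeneity}{Axial density profiles over time on a transversely
#'     oriented capped cylinder (L = 40, R = 6) for the three nucleation
#'     modes, each at its reference catastrophe rate (LDD 0.00275,
#'     GDD 0.003, ISO 0.002).}
#'   \item{alignment_curve}{Median final S2 versus the control parameter G on
#'     a periodic square, per nucleation mode.}
#'   \item{cylinder_orientation}{Replicate orientation fractions
#'     (transverse / longitudinal / other, with binomial 95 percent CIs) on
#'     cylinders 40 x 12 and 60 x 18 micrometres at r_c = 0.00225, with
#'     optional global (cap catastrophe) and local (rescue) biases.}
#'   \item{geometry_sweep}{Orientation outcomes on boxes and cylinders of
#'     equal total area (1734 square micrometres) across aspect ratios at
#'     r_c = 0.00175, with octant-projection coordinates.}
#'   \item{nucleation_diag}{Cumulative nucleation counts and bound-fraction
#'     versus local-density logs for LDD on a periodic square at
#'     r_c = 0.0025.}
#' }
#'
#' @param name preset name.
#' @param overrides named list; recognized keys per preset include
#'   `T_end`, `replicates`, `modes`, `G_values`, `r_c`, `L`, `bias`
#'   (one of `"none"`, `"global"`, `"local_transverse"`,
#'   `"local_longitudinal"`), `b_max`, `lengths`, `shapes`.
#' @param seed master seed; per-replicate seeds are derived from it.
#' @return a result bundle (list) with the preset name, resolved settings,
#'   result tables and per-replicate summaries.
#' @export
run_preset <- function(name, overrides = list(), seed = 1L) {
  name <- match.arg(name, .preset_names)
  ov <- function(key, default) {
    if (!is.null(overrides[[key]])) overrides[[key]] else default
  }
  bundle <- switch(
    name,
    homogeneity = {
      T_end <- ov("T_end", 4000)
      reps <- ov("replicates", 2L)
      modes <- ov("modes", c("LDD", "GDD", "ISO"))
      rcs <- ov("r_c", c(LDD = 0.00275, GDD = 0.003, ISO = 0.002))
      dom <- domain_spec("capped_cylinder", L = ov("L", 40), radius = 6)
      profs <- list(); sums <- list()
      for (mode in modes) {
        cfg <- sim_config(dom, dynamic_params(r_c = rcs[[mode]]),
                          nucleation_params(mode), T_end = T_end,
                          obs_interval = max(100, T_end / 8))
        rr <- .run_replicates(cfg, reps, seed + match(mode, modes),
                              keep_sims = TRUE)
        sums[[mode]] <- cbind(mode = mode, rr$summary)
        for (k in seq_len(reps)) {
          pr <- density_profile(rr$sims[[k]]$snapshot, dom)
          profs[[paste(mode, k)]] <- cbind(mode = mode, replicate = k,
                                           time = rr$sims[[k]]$t_final, pr)
        }
      }
      list(profiles = do.call(rbind, profs), summary = do.call(rbind, sums),
           settings = list(T_end = T_end, replicates = reps, r_c = as.list(rcs)))
    },
    alignment_curve = {
      T_end <- ov("T_end", 8000)
      reps <- ov("replicates", 5L)
      modes <- ov("modes", c("LDD", "GDD", "ISO"))
      Gs <- ov("G_values", c(-0.35, -0.25, -0.15))
      L <- ov("L", 32)
      dom <- domain_spec("periodic_rectangle", L = L, H = L)
      rows <- list(); sums <- list()
      for (mode in modes) for (g in Gs) {
        dyn0 <- dynamic_params(r_c = 0.002)
        rn_ref <- if (mode == "LDD") 4.5e-4 else 0.001
        rc <- rc_for_G(g, rn_ref, dyn0)
        cfg <- sim_config(dom, dynamic_params(r_c = rc),
                          nucleation_params(mode), T_end = T_end,
                          obs_interval = T_end / 4)
        rr <- .run_replicates(cfg, reps, seed + 100 * match(mode, modes) + round(-1000 * g))
        sm <- rr$summary
        G_meas <- if (mode == "LDD") {
          rn_eff <- effective_rn(stats::median(sm$n_c), T_end, dom$area)
          if (rn_eff > 0) control_G(dynamic_params(r_c = rc), rn_eff) else NA_real_
        } else g
        rows[[paste(mode, g)]] <-
          data.frame(mode = mode, G_target = g, r_c = rc, G = G_meas,
                     S2_median = stats::median(sm$S2, na.rm = TRUE),
                     S2_q10 = stats::quantile(sm$S2, 0.1, na.rm = TRUE, names = FALSE),
                     S2_q90 = stats::quantile(sm$S2, 0.9, na.rm = TRUE, names = FALSE))
        sums[[paste(mode, g)]] <- cbind(mode = mode, G_target = g, sm)
      }
      list(curve = do.call(rbind, rows), summary = do.call(rbind, sums),
           settings = list(T_end = T_end, replicates = reps, L = L,
                           G_values = Gs))
    },
    cylinder_orientation = {
      T_end <- ov("T_end", 8000)
      reps <- ov("replicates", 8L)
      modes <- ov("modes", c("LDD", "ISO"))
      sizes <- ov("sizes", list(c(L = 40, D = 12), c(L = 60, D = 18)))
      bias <- ov("bias", "none")
      b_max <- ov("b_max", 0.08)
      rc <- ov("r_c", 0.00225)
      rows <- list(); sums <- list()
      for (mode in modes) for (sz in sizes) {
        dom <- domain_spec("capped_cylinder", L = sz[["L"]],
                           radius = sz[["D"]] / 2)
        dyn <- dynamic_params(
          r_c = rc,
          cap_rc_factor = if (bias == "global") 1.08 else 1,
          b_max = if (bias %in% c("local_transverse", "local_longitudinal"))
            b_max else 0,
          theta_r = if (bias == "local_longitudinal") 0 else 90)
        cfg <- sim_config(dom, dyn, nucleation_params(mode), T_end = T_end,
                          obs_interval = T_end / 4)
        rr <- .run_replicates(cfg, reps, seed + round(sz[["L"]]) +
                                1000 * match(mode, modes))
        sm <- rr$summary
        nt <- sum(sm$class == "transverse"); nl <- sum(sm$class == "longitudinal")
        cit <- .binom_ci(nt, reps); cil <- .binom_ci(nl, reps)
        rows[[paste(mode, sz[["L"]])]] <-
          data.frame(mode = mode, L = sz[["L"]], D = sz[["D"]], bias = bias,
                     n = reps, frac_transverse = nt / reps,
                     ci_t_lo = cit[1], ci_t_hi = cit[2],
                     frac_longitudinal = nl / reps,
                     ci_l_lo = cil[1], ci_l_hi = cil[2])
        sums[[paste(mode, sz[["L"]])]] <-
          cbind(mode = mode, L = sz[["L"]], bias = bias, sm)
      }
      list(fractions = do.call(rbind, rows), summary = do.call(rbind, sums),
           settings = list(T_end = T_end, replicates = reps, r_c = rc,
                           bias = bias, b_max = b_max))
    },
    geometry_sweep = {
      T_end <- ov("T_end", 8000)
      reps <- ov("replicates", 4L)
      modes <- ov("modes", c("LDD", "ISO"))
      rc <- ov("r_c", 0.00175)
      area <- 2 * pi * 6 * (40 + 6)   # reference cylinder L = 40, R = 6
      lengths <- ov("lengths", c(24, 40, 56))
      shapes <- ov("shapes", c("capped_cylinder", "box"))
      rows <- list(); sums <- list()
      for (mode in modes) for (shape in shapes) for (L in lengths) {
        dom <- if (shape == "capped_cylinder") {
          # area = 2 pi R (L + R) -> solve for R
          R <- (-L + sqrt(L^2 + 2 * area / pi)) / 2
          domain_spec("capped_cylinder", L = L, radius = R)
        } else {
          # square cross-section W: 2(LW + LW + W^2) -> W
          W <- (-2 * L + sqrt(4 * L^2 + 2 * area)) / 2
          domain_spec("box", L = L, H = W, W2 = W)
        }
        cfg <- sim_config(dom, dynamic_params(r_c = rc),
                          nucleation_params(mode), T_end = T_end,
                          obs_interval = T_end / 4)
        rr <- .run_replicates(cfg, reps, seed + round(L) +
                                1000 * match(mode, modes) +
                                10000 * match(shape, shapes))
        sm <- rr$summary
        o3 <- lapply(seq_len(reps), function(k) {
          c(sm$R2[k], sm$Theta2_3d[k])
        })
        rows[[paste(mode, shape, L)]] <-
          cbind(mode = mode, shape = shape, L = L, area = dom$area, sm)
        sums[[paste(mode, shape, L)]] <- rows[[paste(mode, shape, L)]]
      }
      list(orientations = do.call(rbind, rows),
           summary = do.call(rbind, sums),
           settings = list(T_end = T_end, replicates = reps, r_c = rc,
                           area = area, lengths = lengths))
    },
    nucleation_diag = {
      T_end <- ov("T_end", 4000)
      rc <- ov("r_c", 0.0025)
      L <- ov("L", 40)
      dom <- domain_spec("periodic_rectangle", L = L, H = L)
      cfg <- sim_config(dom, dynamic_params(r_c = rc),
                        nucleation_params("LDD"), T_end = T_end,
                        obs_interval = 50, seed = .derive_seed(seed, 1L),
                        record_local_density = TRUE)
      sim <- run_simulation(cfg)
      list(time_series = sim$time_series, nucleations = sim$nucleations,
           summary = data.frame(replicate = 1L, seed = cfg$seed,
                                n_c = sim$n_c, n_bound = sim$n_bound,
                                n_unbound = sim$n_unbound),
           settings = list(T_end = T_end, r_c = rc, L = L))
    })
  bundle$preset <- name
  bundle$seed <- seed
  bundle$overrides <- overrides
  class(bundle) <- "cm_bundle"
  bundle
}

#' Write / read a result bundle
#'
#' `write_bundle` stores every data.frame element of the bundle as a CSV and
#' the remaining settings as JSON; `read_bundle` restores the same structure.
#' A round trip preserves values (to double precision).
#'
#' @param bundle a bundle from [run_preset()] (any list of data.frames and
#'   JSON-serializable settings works).
#' @param dir directory to write to / read from (created if needed).
#' @return `write_bundle` returns `dir` invisibly; `read_bundle` the bundle.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- list()
  for (nm in names(bundle)) {
    el <- bundle[[nm]]
    if (is.data.frame(el)) {
      utils::write.csv(el, file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    } else {
      meta[[nm]] <- el
    }
  }
  jsonlite::write_json(meta, file.path(dir, "bundle.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  stopifnot(dir.exists(dir))
  out <- jsonlite::read_json(file.path(dir, "bundle.json"),
                             simplifyVector = TRUE)
  for (f in list.files(dir, pattern = "\\.csv$")) {
    nm <- sub("\\.csv$", "", f)
    out[[nm]] <- utils::read.csv(file.path(dir, f))
  }
  class(out) <- "cm_bundle"
  out
}
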