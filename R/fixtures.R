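# Deterministic toy-array builders, brute-force oracles and statistical test
# helpers. Everything here is an independent reference path: the generators
# emit the same snapshot format the simulator writes, and the two oracle
# engines share no code with the event-driven core beyond the geometry
# module.

# snapshot row(s) for one straight surface path laid with advance()
.toy_path <- function(domain, face, x, y, theta, length, mt_id = 1L,
                      plus_state = "growing") {
  adv <- advance(domain, face, x, y, theta, length)
  pc <- adv$pieces
  pc <- pc[pc[, "len"] > 1e-12, , drop = FALSE]
  n <- nrow(pc)
  u2 <- pc[, "px"] + pc[, "len"] * pc[, "dx"]
  v2 <- pc[, "py"] + pc[, "len"] * pc[, "dy"]
  e1 <- t(vapply(seq_len(n), function(k) {
    embed3d(domain, pc[k, "face"], pc[k, "px"], pc[k, "py"])
  }, numeric(3)))
  e2 <- t(vapply(seq_len(n), function(k) {
    embed3d(domain, pc[k, "face"], u2[k], v2[k])
  }, numeric(3)))
  data.frame(mt_id = mt_id, seg_index = seq_len(n),
             face_id = as.integer(pc[, "face"]),
             u1 = pc[, "px"], v1 = pc[, "py"], u2 = u2, v2 = v2,
             x1 = e1[, 1], y1 = e1[, 2], z1 = e1[, 3],
             x2 = e2[, 1], y2 = e2[, 2], z2 = e2[, 3],
             theta = atan2(pc[, "dy"], pc[, "dx"]),
             plus_state = plus_state)
}

#' Toy-array generators
#'
#' Deterministic builders of segment snapshots for tests and metric anchors:
#' `toy_transverse_ring` lays one closed transverse ring (at axial position
#' `u0`); `toy_longitudinal_lines` lays `n` full-length longitudinal lines at
#' evenly spaced transverse positions; `toy_uniform_isotropic` lays `n`
#' segments of length `len` at uniform random positions and orientations
#' (current RNG stream); `toy_single_band` concentrates `n` transverse rings
#' inside an axial band of the given width centred at `u0`.
#'
#' @param domain a `cm_domain`.
#' @param u0 axial position, micrometres.
#' @param n number of segments / lines / rings.
#' @param len segment length, micrometres.
#' @param width band width, micrometres.
#' @return segment snapshot data.frame (see [array_snapshot()]).
#' @export
toy_transverse_ring <- function(domain, u0 = domain$L / 2) {
  width <- if (domain$shape == "capped_cylinder") domain$C else domain$H
  .toy_path(domain, 1L, u0, 0, pi / 2, width)
}

#' @rdname toy_transverse_ring
#' @export
toy_longitudinal_lines <- function(domain, n = 8L) {
  width <- if (domain$shape == "capped_cylinder") domain$C else domain$H
  do.call(rbind, lapply(seq_len(n), function(k) {
    .toy_path(domain, 1L, 0, (k - 0.5) * width / n, 0, domain$L, mt_id = k)
  }))
}

#' @rdname toy_transverse_ring
#' @export
toy_uniform_isotropic <- function(domain, n = 1000L, len = 2) {
  pts <- sample_surface_point(domain, n)
  ths <- stats::runif(n, -pi, pi)
  do.call(rbind, lapply(seq_len(n), function(k) {
    .toy_path(domain, pts$face[k], pts$x[k], pts$y[k], ths[k], len, mt_id = k)
  }))
}

#' @rdname toy_transverse_ring
#' @export
toy_single_band <- function(domain, width = 2, u0 = domain$L / 2, n = 10L) {
  us <- u0 + (stats::runif(n) - 0.5) * width
  do.call(rbind, lapply(seq_len(n), function(k) {
    w <- if (domain$shape == "capped_cylinder") domain$C else domain$H
    .toy_path(domain, 1L, us[k], 0, pi / 2, w, mt_id = k)
  }))
}

#' Brute-force crossing sweep for a tip path
#'
#' Exhaustive intersection of a straight tip path (across faces) with every
#' segment of a static snapshot, sorted by distance along the path. This is
#' the independent oracle for the engine's collision search.
#'
#' @param domain a `cm_domain`.
#' @param segs segment snapshot data.frame.
#' @param face,x,y,theta tip position and direction.
#' @param horizon path length to sweep, micrometres.
#' @param min_dist crossings closer than this along the path are dropped.
#' @return data.frame with `dist`, `mt_id`, `theta_seg`, `face`, `x`, `y`
#'   ordered by `dist`; zero rows if no crossing.
#' @export
brute_force_collisions <- function(domain, segs, face, x, y, theta, horizon,
                                   min_dist = 1e-9) {
  out <- data.frame(dist = numeric(0), mt_id = integer(0),
                    theta_seg = numeric(0), face = integer(0),
                    x = numeric(0), y = numeric(0))
  if (is.null(segs) || nrow(segs) == 0L) return(out)
  rays <- .snapshot_rays(segs)
  adv <- advance(domain, face, x, y, theta, horizon)
  pieces <- adv$pieces
  off <- 0
  acc <- list()
  for (i in seq_len(nrow(pieces))) {
    pc <- pieces[i, ]
    if (pc["len"] > 0) {
      sel <- which(rays$face == pc["face"])
      for (j in sel) {
        den <- pc["dx"] * rays$dy[j] - pc["dy"] * rays$dx[j]
        if (abs(den) < 1e-12) next
        qx <- rays$px[j] - pc["px"]; qy <- rays$py[j] - pc["py"]
        t_ray <- (qx * rays$dy[j] - qy * rays$dx[j]) / den
        t_seg <- (qx * pc["dy"] - qy * pc["dx"]) / den
        if (t_ray < 0 || t_ray > pc["len"]) next
        if (t_seg < -1e-9 || t_seg > rays$len[j] + 1e-9) next
        d <- off + t_ray
        if (d <= min_dist) next
        acc[[length(acc) + 1L]] <-
          data.frame(dist = d, mt_id = rays$mt_id[j],
                     theta_seg = atan2(rays$dy[j], rays$dx[j]),
                     face = as.integer(pc["face"]),
                     x = pc["px"] + t_ray * pc["dx"],
                     y = pc["py"] + t_ray * pc["dy"])
      }
    }
    off <- off + pc["len"]
  }
  if (!length(acc)) return(out)
  res <- do.call(rbind, acc)
  res[order(res$dist), , drop = FALSE]
}

#' Fixed-timestep reference engine
#'
#' An independent small-timestep integrator for toy runs on the periodic
#' rectangle: every step, plus and minus ends move by their kinematic rates,
#' state switches are drawn as Bernoulli trials with probability `rate * dt`,
#' and tip displacements are swept against all covered segments for
#' crossings, resolved with the same angle rules as the event engine. Used
#' to cross-validate the event-driven core (collision sequences agree to a
#' time tolerance of `dt` on deterministic toy configurations); far too slow
#' for production runs.
#'
#' No nucleation is performed: the run starts from `config$initial_mts`.
#'
#' @param config a `cm_config` on a periodic rectangle with `initial_mts`.
#' @param dt time step, seconds (at most 0.01 for the stated tolerance).
#' @return list with `events` (data.frame `time, event, mt_id, other_id`) and
#'   `mts` (final polylines, internal format).
#' @export
small_dt_reference <- function(config, dt = 0.01) {
  stopifnot(inherits(config, "cm_config"),
            config$domain$shape == "periodic_rectangle", dt <= 0.01)
  dom <- config$domain
  dyn <- config$dynamics
  vp <- dyn$v_plus; vm <- dyn$v_minus; vt <- dyn$v_tm
  im <- config$initial_mts
  stopifnot(!is.null(im), nrow(im) > 0)
  if (is.null(im$length)) im$length <- 0
  n <- nrow(im)
  # polylines: list of matrices (px, py, dx, dy, s0); plus extents
  mts <- vector("list", n)
  plus <- numeric(n); minus <- numeric(n); state <- rep(1L, n)
  alive <- rep(TRUE, n)
  wrap <- function(x, m) ((x %% m) + m) %% m
  for (k in seq_len(n)) {
    mts[[k]] <- matrix(c(wrap(im$x[k], dom$L), wrap(im$y[k], dom$H),
                         cos(im$theta[k]), sin(im$theta[k]), 0), 1, 5)
    plus[k] <- im$length[k]
  }
  ev <- list()
  log_ev <- function(t, type, i, j = 0L) {
    ev[[length(ev) + 1L]] <<- data.frame(time = t, event = type,
                                         mt_id = i, other_id = j)
  }
  tip_point <- function(k) {
    pl <- mts[[k]]
    r <- nrow(pl)
    s <- plus[k] - pl[r, 5]
    c(pl[r, 1] + s * pl[r, 3], pl[r, 2] + s * pl[r, 4], pl[r, 3], pl[r, 4], r)
  }
  # all covered sub-segments of mt k as rows (px, py, dx, dy, len, owner)
  covered <- function(k) {
    pl <- mts[[k]]
    r <- nrow(pl)
    out <- NULL
    for (q in seq_len(r)) {
      s1 <- max(pl[q, 5], minus[k])
      s2 <- min(if (q < r) pl[q + 1, 5] else plus[k], plus[k])
      if (s2 - s1 > 1e-12) {
        # split at periodic wraps so coordinates stay canonical; seam jumps
        # are applied explicitly so near-seam points cannot stall
        x0 <- wrap(pl[q, 1] + (s1 - pl[q, 5]) * pl[q, 3], dom$L)
        y0 <- wrap(pl[q, 2] + (s1 - pl[q, 5]) * pl[q, 4], dom$H)
        rem <- s2 - s1
        guard <- 0L
        while (rem > 1e-12 && guard < 1000L) {
          guard <- guard + 1L
          ex <- .rect_exit(x0, y0, pl[q, 3], pl[q, 4], dom$L, dom$H)
          take <- min(rem, ex$t)
          if (take > 1e-12) {
            out <- rbind(out, c(x0, y0, pl[q, 3], pl[q, 4], take, k))
          }
          x0 <- x0 + take * pl[q, 3]; y0 <- y0 + take * pl[q, 4]
          rem <- rem - take
          if (take >= ex$t - 1e-12 && ex$wall > 0L) {
            if (ex$wall == 1L) x0 <- x0 + dom$L
            else if (ex$wall == 2L) x0 <- x0 - dom$L
            else if (ex$wall == 3L) y0 <- y0 + dom$H
            else y0 <- y0 - dom$H
          }
        }
      }
    }
    out
  }
  t <- 0
  nsteps <- ceiling(config$T_end / dt)
  for (step in seq_len(nsteps)) {
    t_next <- min(t + dt, config$T_end)
    h <- t_next - t
    # state switches (Bernoulli approximations of the exponential clocks)
    for (k in which(alive)) {
      if (state[k] == 1L && dyn$r_c > 0 && stats::runif(1) < dyn$r_c * h) {
        state[k] <- 2L
        log_ev(t_next, "catastrophe", k)
      } else if (state[k] == 2L && dyn$r_r > 0 && stats::runif(1) < dyn$r_r * h) {
        tp <- tip_point(k)
        mts[[k]] <- mts[[k]][seq_len(tp[5]), , drop = FALSE]
        state[k] <- 1L
        log_ev(t_next, "rescue", k)
      }
    }
    # collect all covered segments once per step
    segtab <- do.call(rbind, lapply(which(alive), covered))
    for (k in which(alive)) {
      minus[k] <- minus[k] + vt * h
      if (state[k] == 2L) {
        plus[k] <- plus[k] - vm * h
        # drop polyline rows the plus end has retracted past
        pl <- mts[[k]]
        keep <- pl[, 5] < plus[k] - 1e-12
        keep[1] <- TRUE
        mts[[k]] <- pl[keep, , drop = FALSE]
        if (plus[k] <= minus[k]) {
          alive[k] <- FALSE
          log_ev(t_next, "disappearance", k)
        }
        next
      }
      # growing: sweep the tip displacement against other covered segments.
      # The tip position is tracked locally with explicit seam jumps so a
      # tip sitting within double precision of a seam still makes progress.
      adv_left <- vp * h
      tp <- tip_point(k)
      x0 <- wrap(tp[1], dom$L); y0 <- wrap(tp[2], dom$H)
      dxk <- tp[3]; dyk <- tp[4]
      iter <- 0L
      while (adv_left > 1e-12 && alive[k] && state[k] == 1L) {
        iter <- iter + 1L
        if (iter > 1000L) stop("reference sweep failed to progress")
        ex <- .rect_exit(x0, y0, dxk, dyk, dom$L, dom$H)
        seg_len <- min(adv_left, ex$t)
        best <- NULL
        if (!is.null(segtab)) {
          den <- dxk * segtab[, 4] - dyk * segtab[, 3]
          qx <- segtab[, 1] - x0; qy <- segtab[, 2] - y0
          t_ray <- (qx * segtab[, 4] - qy * segtab[, 3]) / den
          t_seg <- (qx * dyk - qy * dxk) / den
          ok <- segtab[, 6] != k & abs(den) >= 1e-12 &
            t_ray >= 1e-9 & t_ray <= seg_len &
            t_seg >= -1e-9 & t_seg <= segtab[, 5] + 1e-9
          if (any(ok)) {
            j <- which(ok)[which.min(t_ray[ok])]
            best <- c(t_ray[j], segtab[j, 6],
                      atan2(segtab[j, 4], segtab[j, 3]))
          }
        }
        if (is.null(best)) {
          plus[k] <- plus[k] + seg_len
          adv_left <- adv_left - seg_len
          x0 <- x0 + seg_len * dxk; y0 <- y0 + seg_len * dyk
          if (seg_len >= ex$t - 1e-12 && ex$wall > 0L) {
            if (ex$wall == 1L) x0 <- x0 + dom$L
            else if (ex$wall == 2L) x0 <- x0 - dom$L
            else if (ex$wall == 3L) y0 <- y0 + dom$H
            else y0 <- y0 - dom$H
          }
          next
        }
        plus[k] <- plus[k] + best[1]
        adv_left <- adv_left - best[1]
        x0 <- x0 + best[1] * dxk; y0 <- y0 + best[1] * dyk
        th_tip <- atan2(dyk, dxk)
        dth <- .wrap_angle(th_tip - best[3])
        ang <- abs(dth); if (ang > pi / 2) ang <- pi - ang
        out <- resolve_collision(ang * 180 / pi, dyn)
        tc <- t_next  # event time resolved at step resolution
        if (out == "zipper") {
          log_ev(tc, "zipper", k, best[2])
          sgn <- if (cos(dth) >= 0) 1 else -1
          dxk <- sgn * cos(best[3]); dyk <- sgn * sin(best[3])
          mts[[k]] <- rbind(mts[[k]],
                            c(wrap(x0, dom$L), wrap(y0, dom$H), dxk, dyk,
                              plus[k]))
        } else if (out == "catastrophe") {
          log_ev(tc, "induced_catastrophe", k, best[2])
          state[k] <- 2L
          break
        } else {
          log_ev(tc, "crossover", k, best[2])
        }
      }
    }
    t <- t_next
    if (!any(alive)) break
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(time = numeric(0), event = character(0),
               mt_id = integer(0), other_id = integer(0))
  list(events = events, mts = mts, plus = plus, minus = minus,
       state = state, alive = alive)
}

#' Distribution-test helpers
#'
#' Thin wrappers with pre-registered defaults used by the validation suite:
#' `dist_check_ks` runs a Kolmogorov-Smirnov test of `samples` against a
#' distribution function, `dist_check_chisq` a chi-squared test of observed
#' counts against expected probabilities.
#'
#' @param samples numeric sample vector.
#' @param cdf a cumulative distribution function (as for [stats::ks.test()]).
#' @param ... passed to the underlying test.
#' @param counts observed counts per bin.
#' @param probs expected bin probabilities (normalized internally).
#' @return the p-value.
#' @export
dist_check_ks <- function(samples, cdf, ...) {
  stats::ks.test(samples, cdf, ...)$p.value
}

#' @rdname dist_check_ks
#' @export
dist_check_chisq <- function(counts, probs) {
  stats::chisq.test(counts, p = probs / sum(probs))$p.value
}
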