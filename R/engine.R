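# Event-driven simulation core.
#
# Representation: a microtubule is a STATIC polyline of face-local straight
# segments (laid down as the tip grows, zippers and crosses seams) plus two
# moving arclength offsets: plus_pos (growing at v_plus or shrinking at
# v_minus) and minus_pos (treadmilling up at v_tm). Segment geometry never
# moves; the covered part of segment k is [max(s0_k, minus_pos),
# min(send_k, plus_pos)]. A crossing between two trajectories is therefore a
# fixed spatial point and collision timing reduces to comparing arrival and
# coverage times, which are linear in t between events.
#
# Scheduling is lazy: candidate collisions are predicted with the kinematic
# state at scan time and re-validated when the event is popped; an invalid
# pop triggers a fresh scan from the current tip position. Events that
# restore or create lattice coverage (nucleation, zippering, seam crossing,
# rescue) are swept against all stored tip paths so that an earlier
# collision can preempt a scheduled one. Stochastic switching uses
# exponential waiting times, resampled whenever the effective rate changes
# (face crossing under the cap bias, direction change under the rescue
# bias); this is statistically exact by memorylessness.

# event type codes; ties at equal time break by (type, mt id)
.EV_SWITCH <- 1L; .EV_COLLISION <- 2L; .EV_FACECROSS <- 3L
.EV_PATHEXT <- 4L; .EV_DISAPPEAR <- 5L; .EV_VERTEX <- 6L
.EV_APPEAR <- 7L; .EV_OBSERVE <- 8L; .EV_END <- 9L

#' Resolve a collision outcome from the collision angle
#'
#' Shallow collisions (angle not exceeding the bundling threshold `theta_c`)
#' zipper: the plus end reorients alongside the encountered microtubule.
#' Steep collisions trigger an induced catastrophe with probability `P_cat`,
#' otherwise the tip crosses over. The boundary angle `theta == theta_c`
#' zippers (closed interval, fixed for determinism). Uses the current RNG
#' stream.
#'
#' @param theta collision angle in degrees, in `[0, 90]` (the acute angle
#'   between the tip direction and the target, mod 180).
#' @param dynamics a `cm_dynamic_params`.
#' @return `"zipper"`, `"catastrophe"` or `"crossover"`.
#' @export
resolve_collision <- function(theta, dynamics) {
  stopifnot(theta >= 0, theta <= 90)
  if (theta <= dynamics$theta_c) return("zipper")
  if (stats::runif(1) < dynamics$P_cat) "catastrophe" else "crossover"
}

#' Effective catastrophe rate at a surface point
#'
#' The base rate `r_c` everywhere except cylinder caps, where it is
#' multiplied by `cap_rc_factor` (the global bias).
#'
#' @param domain a `cm_domain`.
#' @param face face id of the tip.
#' @param dynamics a `cm_dynamic_params`.
#' @return rate in 1/s.
#' @export
effective_rc <- function(domain, face, dynamics) {
  on_cap <- domain$shape == "capped_cylinder" && face != 1L
  dynamics$r_c * (if (on_cap) dynamics$cap_rc_factor else 1)
}

#' Effective rescue rate for a tip direction
#'
#' `r_r * (1 + rr_extra(theta))` with
#' `rr_extra = (b_max / 2) * (1 + cos(2 * (theta - theta_r)))`
#' (the orientation-dependent local bias; `b_max = 0` disables it).
#'
#' @param theta tip direction, radians, face-local.
#' @param dynamics a `cm_dynamic_params`.
#' @return rate in 1/s.
#' @export
effective_rr <- function(theta, dynamics) {
  thr <- dynamics$theta_r * pi / 180
  dynamics$r_r * (1 + dynamics$b_max / 2 * (1 + cos(2 * (theta - thr))))
}

# ---- event queue (C++ binary heap; see src/kernels.cpp) ------------------

.hp_push <- function(st, t, ty, id, vr, aux = 0) {
  cpp_heap_push(st$heap, t, ty, id, vr, aux)
  invisible(NULL)
}

# pops into st$pt, st$pty, st$pid, st$pvr, st$paux; FALSE if empty
.hp_pop <- function(st) {
  e <- cpp_heap_pop(st$heap)
  if (!length(e)) return(FALSE)
  st$pt <- e[1]; st$pty <- e[2]; st$pid <- as.integer(e[3])
  st$pvr <- as.integer(e[4]); st$paux <- e[5]
  TRUE
}

# ---- engine state ---------------------------------------------------------

.en_new_state <- function(cfg) {
  st <- new.env(parent = emptyenv())
  st$cfg <- cfg
  st$dom <- cfg$domain
  st$dyn <- cfg$dynamics
  st$nuc <- cfg$nucleation
  st$vp <- cfg$dynamics$v_plus; st$vm <- cfg$dynamics$v_minus
  st$vt <- cfg$dynamics$v_tm
  st$A <- cfg$domain$area
  st$hor <- cfg$scan_horizon
  st$P <- 10L                       # tip-path pieces per microtubule
  mc <- 256L
  st$mt_cap <- mc
  st$m_alive <- logical(mc); st$m_state <- integer(mc)
  st$m_t0 <- numeric(mc); st$m_plus0 <- numeric(mc); st$m_minus0 <- numeric(mc)
  st$m_tv <- integer(mc); st$m_rv <- integer(mc)
  st$m_last <- integer(mc); st$m_face <- integer(mc); st$m_theta <- numeric(mc)
  st$m_pcolt <- rep(Inf, mc); st$m_pcolrow <- integer(mc); st$m_pcolsG <- numeric(mc)
  st$mtsegs <- vector("list", mc)
  st$n_mt <- 0L
  sc <- 1024L
  st$seg_cap <- sc
  st$s_face <- integer(sc); st$s_px <- numeric(sc); st$s_py <- numeric(sc)
  st$s_dx <- numeric(sc); st$s_dy <- numeric(sc)
  st$s_s0 <- numeric(sc); st$s_send <- numeric(sc)
  st$s_mt <- integer(sc); st$s_alive <- logical(sc)
  st$n_seg <- 0L
  st$faceidx <- replicate(length(cfg$domain$faces), integer(0), simplify = FALSE)
  tpc <- mc * st$P
  st$tp_used <- logical(tpc); st$tp_mt <- integer(tpc); st$tp_face <- integer(tpc)
  st$tp_px <- numeric(tpc); st$tp_py <- numeric(tpc)
  st$tp_dx <- numeric(tpc); st$tp_dy <- numeric(tpc)
  st$tp_s0 <- numeric(tpc); st$tp_len <- numeric(tpc)
  st$heap <- cpp_heap_new()
  st$n_c <- 0L; st$n_bound <- 0L; st$n_unbound <- 0L
  st$n_zip <- 0L; st$n_icat <- 0L; st$n_cross <- 0L; st$n_events <- 0L
  # nucleation log (grown by doubling)
  nl <- 1024L
  st$nl_t <- numeric(nl); st$nl_kind <- integer(nl); st$nl_face <- integer(nl)
  st$nl_x <- numeric(nl); st$nl_y <- numeric(nl); st$nl_theta <- numeric(nl)
  st$nl_parent <- integer(nl); st$nl_rel <- numeric(nl); st$nl_rho <- numeric(nl)
  st$n_nl <- 0L
  st$ts <- list()
  el <- 256L
  st$el_t <- numeric(el); st$el_type <- integer(el)
  st$el_mt <- integer(el); st$el_other <- integer(el); st$n_el <- 0L
  st$ang_sampler <- relative_angle_sampler(cfg$nucleation)
  st$status <- "ok"
  st
}

.en_grow_mts <- function(st) {
  mc <- st$mt_cap
  st$m_alive <- c(st$m_alive, logical(mc))
  st$m_state <- c(st$m_state, integer(mc))
  st$m_t0 <- c(st$m_t0, numeric(mc))
  st$m_plus0 <- c(st$m_plus0, numeric(mc))
  st$m_minus0 <- c(st$m_minus0, numeric(mc))
  st$m_tv <- c(st$m_tv, integer(mc))
  st$m_rv <- c(st$m_rv, integer(mc))
  st$m_last <- c(st$m_last, integer(mc))
  st$m_face <- c(st$m_face, integer(mc))
  st$m_theta <- c(st$m_theta, numeric(mc))
  st$m_pcolt <- c(st$m_pcolt, rep(Inf, mc))
  st$m_pcolrow <- c(st$m_pcolrow, integer(mc))
  st$m_pcolsG <- c(st$m_pcolsG, numeric(mc))
  st$mtsegs <- c(st$mtsegs, vector("list", mc))
  tpc <- mc * st$P
  st$tp_used <- c(st$tp_used, logical(tpc))
  st$tp_mt <- c(st$tp_mt, integer(tpc))
  st$tp_face <- c(st$tp_face, integer(tpc))
  st$tp_px <- c(st$tp_px, numeric(tpc))
  st$tp_py <- c(st$tp_py, numeric(tpc))
  st$tp_dx <- c(st$tp_dx, numeric(tpc))
  st$tp_dy <- c(st$tp_dy, numeric(tpc))
  st$tp_s0 <- c(st$tp_s0, numeric(tpc))
  st$tp_len <- c(st$tp_len, numeric(tpc))
  st$mt_cap <- 2L * mc
}

.en_append_seg <- function(st, i, face, x, y, dx, dy, s0, send = Inf) {
  n <- st$n_seg + 1L
  if (n > st$seg_cap) {
    sc <- st$seg_cap
    st$s_face <- c(st$s_face, integer(sc))
    st$s_px <- c(st$s_px, numeric(sc)); st$s_py <- c(st$s_py, numeric(sc))
    st$s_dx <- c(st$s_dx, numeric(sc)); st$s_dy <- c(st$s_dy, numeric(sc))
    st$s_s0 <- c(st$s_s0, numeric(sc)); st$s_send <- c(st$s_send, numeric(sc))
    st$s_mt <- c(st$s_mt, integer(sc)); st$s_alive <- c(st$s_alive, logical(sc))
    st$seg_cap <- 2L * sc
  }
  st$s_face[n] <- face; st$s_px[n] <- x; st$s_py[n] <- y
  st$s_dx[n] <- dx; st$s_dy[n] <- dy
  st$s_s0[n] <- s0; st$s_send[n] <- send
  st$s_mt[n] <- i; st$s_alive[n] <- TRUE
  st$n_seg <- n
  st$faceidx[[face]] <- c(st$faceidx[[face]], n)
  st$mtsegs[[i]] <- c(st$mtsegs[[i]], n)
  n
}

.en_plus_at <- function(st, i, t) {
  st$m_plus0[i] + (t - st$m_t0[i]) *
    (if (st$m_state[i] == 1L) st$vp else -st$vm)
}

.en_minus_at <- function(st, i, t) {
  st$m_minus0[i] + (t - st$m_t0[i]) * st$vt
}

.en_set0 <- function(st, i, t) {
  st$m_plus0[i] <- .en_plus_at(st, i, t)
  st$m_minus0[i] <- .en_minus_at(st, i, t)
  st$m_t0[i] <- t
}

.en_clear_tp <- function(st, i) {
  base <- (i - 1L) * st$P
  st$tp_used[(base + 1L):(base + st$P)] <- FALSE
}

# Scan the tip's future straight path across faces; store the path pieces,
# schedule seam crossings and the first predicted collision (or a
# path-extension rescan at the lookahead horizon).
.en_scan_tip <- function(st, i, t, min_dist = 1e-9) {
  last <- st$m_last[i]
  plus <- .en_plus_at(st, i, t)
  x <- st$s_px[last] + (plus - st$s_s0[last]) * st$s_dx[last]
  y <- st$s_py[last] + (plus - st$s_s0[last]) * st$s_dy[last]
  face <- st$s_face[last]
  th <- atan2(st$s_dy[last], st$s_dx[last])
  adv <- advance(st$dom, face, x, y, th, st$hor, max_pieces = st$P)
  pieces <- adv$pieces
  np <- nrow(pieces)
  base <- (i - 1L) * st$P
  st$tp_used[(base + 1L):(base + st$P)] <- FALSE
  off <- 0
  hit <- NULL
  hit_piece <- 0L
  for (k in seq_len(np)) {
    r <- base + k
    st$tp_used[r] <- TRUE; st$tp_mt[r] <- i
    st$tp_face[r] <- as.integer(pieces[k, 1])
    st$tp_px[r] <- pieces[k, 2]; st$tp_py[r] <- pieces[k, 3]
    st$tp_dx[r] <- pieces[k, 4]; st$tp_dy[r] <- pieces[k, 5]
    st$tp_s0[r] <- plus + off; st$tp_len[r] <- pieces[k, 6]
    if (is.null(hit) && pieces[k, 6] > 0) {
      cand <- st$faceidx[[pieces[k, 1]]]
      if (length(cand)) {
        h <- cpp_best_hit(pieces[k, 2], pieces[k, 3], pieces[k, 4], pieces[k, 5],
                          pieces[k, 6], off, min_dist, cand,
                          st$s_px, st$s_py, st$s_dx, st$s_dy,
                          st$s_s0, st$s_send, st$s_mt, st$s_alive,
                          st$m_t0, st$m_plus0, st$m_minus0, st$m_state,
                          st$m_alive, st$vp, st$vm, st$vt,
                          t, st$vp, i, last)
        if (h[1] >= 0) { hit <- h; hit_piece <- k }
      }
    }
    off <- off + pieces[k, 6]
  }
  st$m_face[i] <- face
  st$m_theta[i] <- th
  # seam crossings strictly before the collision (or all of them if none)
  nb <- if (is.null(hit)) np - 1L else hit_piece - 1L
  if (nb >= 1L) {
    cum <- cumsum(pieces[seq_len(np), 6])
    for (j in seq_len(nb)) {
      .hp_push(st, t + cum[j] / st$vp, .EV_FACECROSS, i, st$m_tv[i], aux = j + 1L)
    }
  }
  if (!is.null(hit)) {
    tc <- t + hit[1] / st$vp
    st$m_pcolt[i] <- tc
    st$m_pcolrow[i] <- as.integer(hit[2])
    st$m_pcolsG[i] <- hit[3]
    .hp_push(st, tc, .EV_COLLISION, i, st$m_tv[i])
  } else {
    st$m_pcolt[i] <- Inf
    .hp_push(st, t + off / st$vp, .EV_PATHEXT, i, st$m_tv[i])
  }
  invisible(NULL)
}

# A lattice ray was created or re-extended: preempt scheduled collisions of
# tips whose stored paths cross it earlier than their current candidate.
.en_new_seg_check <- function(st, row, t) {
  res <- cpp_seg_vs_paths(st$s_face[row], st$s_px[row], st$s_py[row],
                          st$s_dx[row], st$s_dy[row],
                          st$s_s0[row], st$s_send[row], st$s_mt[row],
                          st$tp_used, st$tp_mt, st$tp_face,
                          st$tp_px, st$tp_py, st$tp_dx, st$tp_dy,
                          st$tp_s0, st$tp_len,
                          st$m_t0, st$m_plus0, st$m_minus0, st$m_state,
                          st$m_alive, st$vp, st$vm, st$vt, t)
  tips <- res$tip
  if (!length(tips)) return(invisible(NULL))
  for (j in seq_along(tips)) {
    tip <- tips[j]
    if (res$time[j] < st$m_pcolt[tip] - 1e-12) {
      st$m_pcolt[tip] <- res$time[j]
      st$m_pcolrow[tip] <- row
      st$m_pcolsG[tip] <- res$sG[j]
      .hp_push(st, res$time[j], .EV_COLLISION, tip, st$m_tv[tip])
    }
  }
  invisible(NULL)
}

.en_schedule_switch <- function(st, i, t) {
  rate <- if (st$m_state[i] == 1L) {
    effective_rc(st$dom, st$m_face[i], st$dyn)
  } else {
    effective_rr(st$m_theta[i], st$dyn)
  }
  if (rate > 0) {
    .hp_push(st, t + stats::rexp(1, rate), .EV_SWITCH, i, st$m_rv[i])
  }
  invisible(NULL)
}

.en_create_mt <- function(st, t, face, x, y, theta, length0 = 0) {
  i <- st$n_mt + 1L
  if (i > st$mt_cap) .en_grow_mts(st)
  st$n_mt <- i
  st$m_alive[i] <- TRUE; st$m_state[i] <- 1L
  st$m_t0[i] <- t; st$m_plus0[i] <- length0; st$m_minus0[i] <- 0
  st$m_tv[i] <- 1L; st$m_rv[i] <- 1L
  st$m_pcolt[i] <- Inf
  st$mtsegs[i] <- list(integer(0))
  rows <- integer(0)
  if (length0 > 0) {
    adv <- advance(st$dom, face, x, y, theta, length0)
    s0 <- 0
    for (k in seq_len(nrow(adv$pieces))) {
      pc <- adv$pieces[k, ]
      send <- if (k == nrow(adv$pieces)) Inf else s0 + pc["len"]
      rows <- c(rows, .en_append_seg(st, i, as.integer(pc["face"]),
                                     pc["px"], pc["py"], pc["dx"], pc["dy"],
                                     s0, send))
      s0 <- s0 + pc["len"]
    }
  } else {
    rows <- .en_append_seg(st, i, face, x, y, cos(theta), sin(theta), 0)
  }
  st$m_last[i] <- rows[length(rows)]
  st$m_face[i] <- st$s_face[st$m_last[i]]
  st$m_theta[i] <- atan2(st$s_dy[st$m_last[i]], st$s_dx[st$m_last[i]])
  .en_scan_tip(st, i, t)
  .en_schedule_switch(st, i, t)
  for (r in rows) .en_new_seg_check(st, r, t)
  .en_log_event(st, t, 7L, i)
  i
}

.en_kill_mt <- function(st, i) {
  st$m_alive[i] <- FALSE
  st$s_alive[st$mtsegs[[i]]] <- FALSE
  .en_clear_tp(st, i)
  st$m_pcolt[i] <- Inf
  invisible(NULL)
}

.en_catastrophe_at <- function(st, i, t) {
  .en_set0(st, i, t)
  st$s_send[st$m_last[i]] <- st$m_plus0[i]
  st$m_state[i] <- 2L
  st$m_tv[i] <- st$m_tv[i] + 1L
  st$m_rv[i] <- st$m_rv[i] + 1L
  .en_clear_tp(st, i)
  st$m_pcolt[i] <- Inf
  .en_schedule_switch(st, i, t)
  gap <- st$m_plus0[i] - st$m_minus0[i]
  .hp_push(st, t + gap / (st$vm + st$vt), .EV_DISAPPEAR, i, st$m_tv[i])
  if (st$dyn$b_max > 0) .en_schedule_vertex(st, i, t)
  invisible(NULL)
}

.en_schedule_vertex <- function(st, i, t) {
  last <- st$m_last[i]
  if (st$s_s0[last] > st$m_minus0[i] + 1e-12 && st$s_s0[last] > 0) {
    tv <- t + (st$m_plus0[i] - st$s_s0[last]) / st$vm
    .hp_push(st, tv, .EV_VERTEX, i, st$m_tv[i], aux = last)
  }
  invisible(NULL)
}

.en_rescue_at <- function(st, i, t) {
  .en_set0(st, i, t)
  plus <- st$m_plus0[i]
  rows <- st$mtsegs[[i]]
  rows <- rows[st$s_alive[rows]]
  jj <- which(st$s_s0[rows] <= plus + 1e-12)
  j <- rows[jj[length(jj)]]
  drop <- rows[rows > j]
  if (length(drop)) st$s_alive[drop] <- FALSE
  st$m_last[i] <- j
  st$s_send[j] <- Inf
  st$m_state[i] <- 1L
  st$m_tv[i] <- st$m_tv[i] + 1L
  st$m_rv[i] <- st$m_rv[i] + 1L
  .en_scan_tip(st, i, t)
  .en_schedule_switch(st, i, t)
  .en_new_seg_check(st, j, t)
  invisible(NULL)
}

.EL_TYPES <- c("zipper", "induced_catastrophe", "crossover", "catastrophe",
               "rescue", "disappearance", "nucleation")

.en_log_event <- function(st, t, type, mt, other = 0L) {
  n <- st$n_el + 1L
  if (n > length(st$el_t)) {
    g <- length(st$el_t)
    st$el_t <- c(st$el_t, numeric(g)); st$el_type <- c(st$el_type, integer(g))
    st$el_mt <- c(st$el_mt, integer(g)); st$el_other <- c(st$el_other, integer(g))
  }
  st$el_t[n] <- t; st$el_type[n] <- type
  st$el_mt[n] <- mt; st$el_other[n] <- other
  st$n_el <- n
  invisible(NULL)
}

.en_log_nucleation <- function(st, t, kind, face, x, y, theta, parent, rel, rho) {
  n <- st$n_nl + 1L
  if (n > length(st$nl_t)) {
    g <- length(st$nl_t)
    st$nl_t <- c(st$nl_t, numeric(g)); st$nl_kind <- c(st$nl_kind, integer(g))
    st$nl_face <- c(st$nl_face, integer(g))
    st$nl_x <- c(st$nl_x, numeric(g)); st$nl_y <- c(st$nl_y, numeric(g))
    st$nl_theta <- c(st$nl_theta, numeric(g))
    st$nl_parent <- c(st$nl_parent, integer(g))
    st$nl_rel <- c(st$nl_rel, numeric(g)); st$nl_rho <- c(st$nl_rho, numeric(g))
  }
  st$nl_t[n] <- t; st$nl_kind[n] <- kind; st$nl_face[n] <- face
  st$nl_x[n] <- x; st$nl_y[n] <- y; st$nl_theta[n] <- theta
  st$nl_parent[n] <- parent; st$nl_rel[n] <- rel; st$nl_rho[n] <- rho
  st$n_nl <- n
  invisible(NULL)
}

# cast one meta-trajectory; returns list(d = hit distance or NA, row, pieces)
.en_meta_cast <- function(st, face, x, y, ang, t) {
  adv <- advance(st$dom, face, x, y, ang, st$nuc$R_max, max_pieces = 8L)
  pieces <- adv$pieces
  off <- 0
  for (k in seq_len(nrow(pieces))) {
    if (pieces[k, 6] > 0) {
      cand <- st$faceidx[[pieces[k, 1]]]
      if (length(cand)) {
        h <- cpp_best_hit(pieces[k, 2], pieces[k, 3], pieces[k, 4], pieces[k, 5],
                          pieces[k, 6], off, 0, cand,
                          st$s_px, st$s_py, st$s_dx, st$s_dy,
                          st$s_s0, st$s_send, st$s_mt, st$s_alive,
                          st$m_t0, st$m_plus0, st$m_minus0, st$m_state,
                          st$m_alive, st$vp, st$vm, st$vt,
                          t, -1, 0L, 0L)
        if (h[1] >= 0) {
          return(list(d = h[1], row = as.integer(h[2]),
                      hx = pieces[k, 2] + (h[1] - off) * pieces[k, 4],
                      hy = pieces[k, 3] + (h[1] - off) * pieces[k, 5],
                      hface = as.integer(pieces[k, 1]), pieces = pieces,
                      hit_k = k))
        }
      }
    }
    off <- off + pieces[k, 6]
  }
  list(d = NA_real_, row = NA_integer_, pieces = pieces, hit_k = NA_integer_)
}

# local density over the grid cells touched by the meta-trajectories
# (periodic rectangle only; cells of side local_cell), i.e. lattice length
# clipped to the touched cells divided by their total area
.en_local_density <- function(st, casts, t) {
  if (st$dom$shape != "periodic_rectangle") return(NA_real_)
  cell <- st$cfg$local_cell
  L <- st$dom$L; H <- st$dom$H
  ncx <- max(1L, round(L / cell)); ncy <- max(1L, round(H / cell))
  wx <- L / ncx; wy <- H / ncy
  ids <- integer(0)
  for (cs in casts) {
    pieces <- cs$pieces
    lim <- if (is.na(cs$d)) Inf else cs$d
    off <- 0
    for (k in seq_len(nrow(pieces))) {
      plen <- min(pieces[k, 6], lim - off)
      if (plen <= 0) break
      ns <- max(2L, ceiling(plen / (0.25 * cell)) + 1L)
      s <- seq(0, plen, length.out = ns)
      cx <- floor(((pieces[k, 2] + s * pieces[k, 4]) %% L) / wx)
      cy <- floor(((pieces[k, 3] + s * pieces[k, 5]) %% H) / wy)
      cx[cx >= ncx] <- ncx - 1L; cy[cy >= ncy] <- ncy - 1L
      ids <- c(ids, cx * ncy + cy)
      off <- off + pieces[k, 6]
      if (off >= lim) break
    }
  }
  ids <- unique(ids)
  if (!length(ids)) return(NA_real_)
  # clip covered parts of all alive segments to the touched cells
  rows <- which(st$s_alive[seq_len(st$n_seg)])
  if (!length(rows)) return(0)
  m <- st$s_mt[rows]
  dtv <- t - st$m_t0[m]
  plus <- st$m_plus0[m] + dtv * ifelse(st$m_state[m] == 1L, st$vp, -st$vm)
  minus <- st$m_minus0[m] + dtv * st$vt
  lo <- pmax(st$s_s0[rows], minus)
  hi <- pmin(st$s_send[rows], plus)
  keep <- hi - lo > 1e-9
  rows <- rows[keep]; lo <- lo[keep]; hi <- hi[keep]
  if (!length(rows)) return(0)
  x1 <- st$s_px[rows] + (lo - st$s_s0[rows]) * st$s_dx[rows]
  y1 <- st$s_py[rows] + (lo - st$s_s0[rows]) * st$s_dy[rows]
  dx <- st$s_dx[rows]; dy <- st$s_dy[rows]
  len <- hi - lo
  total <- 0
  for (id in ids) {
    cx <- id %/% ncy; cy <- id %% ncy
    x_lo <- cx * wx; y_lo <- cy * wy
    # Liang-Barsky clipping of each covered segment against the cell
    t0 <- rep(0, length(rows)); t1 <- len
    p1 <- -dx; q1 <- x1 - x_lo
    p2 <- dx;  q2 <- x_lo + wx - x1
    p3 <- -dy; q3 <- y1 - y_lo
    p4 <- dy;  q4 <- y_lo + wy - y1
    ok <- rep(TRUE, length(rows))
    for (pp in list(list(p1, q1), list(p2, q2), list(p3, q3), list(p4, q4))) {
      p <- pp[[1]]; q <- pp[[2]]
      para <- abs(p) < 1e-12
      ok <- ok & !(para & q < 0)
      r <- ifelse(para, NA_real_, q / p)
      t0 <- ifelse(!para & p < 0, pmax(t0, r), t0)
      t1 <- ifelse(!para & p > 0, pmin(t1, r), t1)
    }
    total <- total + sum(pmax(0, t1 - t0)[ok], na.rm = TRUE)
  }
  total / (length(ids) * wx * wy)
}

.en_total_length <- function(st, t) {
  ids <- which(st$m_alive[seq_len(st$n_mt)])
  if (!length(ids)) return(0)
  dtv <- t - st$m_t0[ids]
  plus <- st$m_plus0[ids] + dtv * ifelse(st$m_state[ids] == 1L, st$vp, -st$vm)
  minus <- st$m_minus0[ids] + dtv * st$vt
  sum(pmax(plus - minus, 0))
}

# uniform surface point without data.frame overhead: c(face, x, y)
.en_sample_point <- function(st) {
  dom <- st$dom
  nf <- length(dom$faces)
  f <- if (nf == 1L) 1L else sample.int(nf, 1L, prob = dom$face_areas)
  fc <- dom$faces[[f]]
  if (identical(fc$type, "disk")) {
    r <- fc$R * sqrt(stats::runif(1))
    a <- stats::runif(1, 0, 2 * pi)
    c(f, r * cos(a), r * sin(a))
  } else {
    c(f, stats::runif(1, 0, fc$a), stats::runif(1, 0, fc$b))
  }
}

# one nucleation complex appearance / ISO-GDD nucleation event
.en_appear <- function(st, t) {
  nuc <- st$nuc
  if (nuc$mode == "ISO") {
    pt <- .en_sample_point(st)
    th <- stats::runif(1, -pi, pi)
    .en_create_mt(st, t, as.integer(pt[1]), pt[2], pt[3], th)
    st$n_c <- st$n_c + 1L; st$n_unbound <- st$n_unbound + 1L
    .en_log_nucleation(st, t, 3L, as.integer(pt[1]), pt[2], pt[3], th,
                       NA_integer_, NA_real_, NA_real_)
    return(invisible(NULL))
  }
  if (nuc$mode == "GDD") {
    rho <- .en_total_length(st, t) / st$A
    rates <- gdd_split(rho, nuc)
    acc <- (rates[1] + rates[2]) / nuc$r_n
    if (stats::runif(1) >= acc) return(invisible(NULL))  # thinning
    bound <- stats::runif(1) < rates[1] / (rates[1] + rates[2])
    if (bound) {
      ids <- which(st$m_alive[seq_len(st$n_mt)])
      dtv <- t - st$m_t0[ids]
      plus <- st$m_plus0[ids] + dtv * ifelse(st$m_state[ids] == 1L, st$vp, -st$vm)
      minus <- st$m_minus0[ids] + dtv * st$vt
      lens <- pmax(plus - minus, 0)
      j <- if (length(ids) == 1L) 1L else sample.int(length(ids), 1L, prob = lens)
      pid <- ids[j]
      a <- stats::runif(1, minus[j], plus[j])
      rows <- st$mtsegs[[pid]]
      rows <- rows[st$s_alive[rows]]
      kk <- which(st$s_s0[rows] <= a + 1e-12)
      rr <- rows[kk[length(kk)]]
      px <- st$s_px[rr] + (a - st$s_s0[rr]) * st$s_dx[rr]
      py <- st$s_py[rr] + (a - st$s_s0[rr]) * st$s_dy[rr]
      thp <- atan2(st$s_dy[rr], st$s_dx[rr])
      rel <- st$ang_sampler(1L)
      th <- .wrap_angle(thp + rel)
      .en_create_mt(st, t, st$s_face[rr], px, py, th)
      st$n_c <- st$n_c + 1L; st$n_bound <- st$n_bound + 1L
      .en_log_nucleation(st, t, 1L, st$s_face[rr], px, py, th, pid, rel, NA_real_)
    } else {
      pt <- .en_sample_point(st)
      th <- stats::runif(1, -pi, pi)
      .en_create_mt(st, t, as.integer(pt[1]), pt[2], pt[3], th)
      st$n_c <- st$n_c + 1L; st$n_unbound <- st$n_unbound + 1L
      .en_log_nucleation(st, t, 2L, as.integer(pt[1]), pt[2], pt[3], th,
                         NA_integer_, NA_real_, NA_real_)
    }
    return(invisible(NULL))
  }
  # LDD
  pt <- .en_sample_point(st)
  N <- nuc$N_meta
  th1 <- stats::runif(1, 0, 2 * pi)
  casts <- vector("list", N)
  d <- rep(NA_real_, N)
  pface <- as.integer(pt[1])
  for (k in seq_len(N)) {
    casts[[k]] <- .en_meta_cast(st, pface, pt[2], pt[3],
                                th1 + 2 * pi * (k - 1L) / N, t)
    d[k] <- casts[[k]]$d
  }
  ih <- which(!is.na(d))
  p <- if (length(ih)) p_reach(d[ih], nuc) else numeric(0)
  sum_p <- sum(p) / N
  if (nuc$rescaled) {
    p_bound <- sum_p
    p_unbound <- (nuc$alpha_unbound / nuc$alpha_bound) * (1 - sum_p)
  } else {
    p_bound <- nuc$alpha_bound * sum_p
    p_unbound <- nuc$alpha_unbound * (1 - sum_p)
  }
  u <- stats::runif(1)
  if (u >= p_bound + p_unbound) return(invisible(NULL))  # dissociation
  rho_loc <- if (st$cfg$record_local_density) {
    .en_local_density(st, casts, t)
  } else NA_real_
  if (u < p_bound) {
    j <- if (length(ih) == 1L) 1L else sample.int(length(ih), 1L, prob = p)
    cs <- casts[[ih[j]]]
    pid <- st$s_mt[cs$row]
    thp <- atan2(st$s_dy[cs$row], st$s_dx[cs$row])
    rel <- st$ang_sampler(1L)
    th <- .wrap_angle(thp + rel)
    .en_create_mt(st, t, cs$hface, cs$hx, cs$hy, th)
    st$n_c <- st$n_c + 1L; st$n_bound <- st$n_bound + 1L
    .en_log_nucleation(st, t, 1L, cs$hface, cs$hx, cs$hy, th, pid, rel, rho_loc)
  } else {
    th <- stats::runif(1, -pi, pi)
    .en_create_mt(st, t, pface, pt[2], pt[3], th)
    st$n_c <- st$n_c + 1L; st$n_unbound <- st$n_unbound + 1L
    .en_log_nucleation(st, t, 2L, pface, pt[2], pt[3], th, NA_integer_,
                       NA_real_, rho_loc)
  }
  invisible(NULL)
}

.en_appear_rate <- function(st) {
  nuc <- st$nuc
  r <- switch(nuc$mode,
              ISO = nuc$r_n,
              GDD = nuc$r_n,
              LDD = if (nuc$rescaled) nuc$alpha_bound * nuc$r_ins else nuc$r_ins)
  r * st$A
}

.en_observe <- function(st, t) {
  rows <- which(st$s_alive[seq_len(st$n_seg)])
  total <- 0; S2 <- NA_real_; Th2 <- NA_real_
  if (length(rows)) {
    m <- st$s_mt[rows]
    dtv <- t - st$m_t0[m]
    plus <- st$m_plus0[m] + dtv * ifelse(st$m_state[m] == 1L, st$vp, -st$vm)
    minus <- st$m_minus0[m] + dtv * st$vt
    lo <- pmax(st$s_s0[rows], minus)
    hi <- pmin(st$s_send[rows], plus)
    len <- pmax(hi - lo, 0)
    total <- sum(len)
    pl <- st$s_face[rows] == 1L & len > 0
    if (any(pl)) {
      stv <- s2_theta2(atan2(st$s_dy[rows[pl]], st$s_dx[rows[pl]]), len[pl])
      S2 <- stv$S2; Th2 <- stv$Theta2
    }
  }
  st$ts[[length(st$ts) + 1L]] <-
    c(time = t, density = total / st$A,
      n_mt = sum(st$m_alive[seq_len(st$n_mt)]),
      S2 = S2, Theta2 = Th2, n_c = st$n_c,
      n_bound = st$n_bound, n_unbound = st$n_unbound)
  total / st$A
}

#' Run an event-driven cortical array simulation
#'
#' Simulates microtubule dynamic instability with treadmilling,
#' angle-dependent collision resolution and the configured nucleation mode
#' from an empty array (or the configured initial condition) up to
#' `T_end`. Fully reproducible given `config$seed`.
#'
#' @param config a `cm_config` from [sim_config()].
#' @return object of class `cm_sim`: list with the final segment `snapshot`
#'   (see [array_snapshot()]), the observable `time_series`, the
#'   `nucleations` log, counters, the echoed `config` and a `status`
#'   (`"ok"` or `"density_cap"`).
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "cm_config"))
  set.seed(config$seed)
  st <- .en_new_state(config)
  t_end <- config$T_end
  # initial condition
  if (!is.null(config$initial_mts) && nrow(config$initial_mts) > 0) {
    im <- config$initial_mts
    if (is.null(im$length)) im$length <- 0
    for (k in seq_len(nrow(im))) {
      .en_create_mt(st, 0, im$face[k], im$x[k], im$y[k], im$theta[k],
                    length0 = im$length[k])
    }
  }
  rate <- .en_appear_rate(st)
  if (rate > 0) .hp_push(st, stats::rexp(1, rate), .EV_APPEAR, 0L, 0L)
  .en_observe(st, 0)
  if (config$obs_interval < t_end) {
    .hp_push(st, config$obs_interval, .EV_OBSERVE, 0L, 0L)
  }
  .hp_push(st, t_end, .EV_END, 0L, 0L)
  guard <- 0L
  while (.hp_pop(st)) {
    t <- st$pt; ty <- st$pty; i <- st$pid
    guard <- guard + 1L
    if (guard > 5e7) { st$status <- "event_limit"; break }
    if (ty == .EV_END) { .en_observe(st, t); break }
    if (ty == .EV_OBSERVE) {
      dens <- .en_observe(st, t)
      if (dens > config$density_cap) { st$status <- "density_cap"; break }
      if (t + config$obs_interval < t_end - 1e-9) {
        .hp_push(st, t + config$obs_interval, .EV_OBSERVE, 0L, 0L)
      }
      next
    }
    if (ty == .EV_APPEAR) {
      st$n_events <- st$n_events + 1L
      .en_appear(st, t)
      .hp_push(st, t + stats::rexp(1, rate), .EV_APPEAR, 0L, 0L)
      next
    }
    # per-microtubule events: validate version
    if (!st$m_alive[i]) next
    if (ty == .EV_SWITCH) {
      if (st$pvr != st$m_rv[i]) next
      st$n_events <- st$n_events + 1L
      if (st$m_state[i] == 1L) {
        .en_log_event(st, t, 4L, i)
        .en_catastrophe_at(st, i, t)
      } else {
        .en_log_event(st, t, 5L, i)
        .en_rescue_at(st, i, t)
      }
      next
    }
    if (st$pvr != st$m_tv[i]) next
    if (ty == .EV_COLLISION) {
      if (st$m_state[i] != 1L) next
      if (abs(t - st$m_pcolt[i]) > 1e-9) next
      row <- st$m_pcolrow[i]
      sG <- st$m_pcolsG[i]
      mtar <- st$s_mt[row]
      valid <- st$s_alive[row] && st$m_alive[mtar] &&
        sG >= .en_minus_at(st, mtar, t) - 1e-7 &&
        sG <= .en_plus_at(st, mtar, t) + 1e-7
      st$n_events <- st$n_events + 1L
      if (!valid) {
        st$m_tv[i] <- st$m_tv[i] + 1L
        .en_scan_tip(st, i, t)
        next
      }
      th_t <- atan2(st$s_dy[row], st$s_dx[row])
      dth <- .wrap_angle(st$m_theta[i] - th_t)
      ang <- abs(dth)
      if (ang > pi / 2) ang <- pi - ang
      out <- resolve_collision(ang * 180 / pi, st$dyn)
      if (out == "zipper") {
        st$n_zip <- st$n_zip + 1L
        .en_log_event(st, t, 1L, i, mtar)
        .en_set0(st, i, t)
        plus <- st$m_plus0[i]
        last <- st$m_last[i]
        st$s_send[last] <- plus
        sgn <- if (cos(dth) >= 0) 1 else -1
        hx <- st$s_px[row] + (sG - st$s_s0[row]) * st$s_dx[row]
        hy <- st$s_py[row] + (sG - st$s_s0[row]) * st$s_dy[row]
        nr <- .en_append_seg(st, i, st$s_face[row], hx, hy,
                             sgn * st$s_dx[row], sgn * st$s_dy[row], plus)
        st$m_last[i] <- nr
        st$m_tv[i] <- st$m_tv[i] + 1L
        st$m_rv[i] <- st$m_rv[i] + 1L
        .en_scan_tip(st, i, t)
        .en_schedule_switch(st, i, t)
        .en_new_seg_check(st, nr, t)
      } else if (out == "catastrophe") {
        st$n_icat <- st$n_icat + 1L
        .en_log_event(st, t, 2L, i, mtar)
        .en_catastrophe_at(st, i, t)
      } else {
        st$n_cross <- st$n_cross + 1L
        .en_log_event(st, t, 3L, i, mtar)
        st$m_tv[i] <- st$m_tv[i] + 1L
        .en_scan_tip(st, i, t, min_dist = 1e-9)
      }
      next
    }
    if (ty == .EV_FACECROSS) {
      if (st$m_state[i] != 1L) next
      st$n_events <- st$n_events + 1L
      k <- as.integer(st$paux)
      r <- (i - 1L) * st$P + k
      .en_set0(st, i, t)
      last <- st$m_last[i]
      st$s_send[last] <- st$m_plus0[i]
      nr <- .en_append_seg(st, i, st$tp_face[r], st$tp_px[r], st$tp_py[r],
                           st$tp_dx[r], st$tp_dy[r], st$m_plus0[i])
      st$m_last[i] <- nr
      st$m_face[i] <- st$tp_face[r]
      st$m_theta[i] <- atan2(st$tp_dy[r], st$tp_dx[r])
      st$m_rv[i] <- st$m_rv[i] + 1L
      .en_schedule_switch(st, i, t)
      .en_new_seg_check(st, nr, t)
      next
    }
    if (ty == .EV_PATHEXT) {
      if (st$m_state[i] != 1L) next
      st$n_events <- st$n_events + 1L
      st$m_tv[i] <- st$m_tv[i] + 1L
      .en_scan_tip(st, i, t)
      next
    }
    if (ty == .EV_DISAPPEAR) {
      if (st$m_state[i] != 2L) next
      st$n_events <- st$n_events + 1L
      .en_log_event(st, t, 6L, i)
      .en_kill_mt(st, i)
      next
    }
    if (ty == .EV_VERTEX) {
      if (st$m_state[i] != 2L) next
      st$n_events <- st$n_events + 1L
      .en_set0(st, i, t)
      last <- as.integer(st$paux)
      st$s_alive[last] <- FALSE
      rows <- st$mtsegs[[i]]
      rows <- rows[st$s_alive[rows]]
      if (!length(rows)) { .en_kill_mt(st, i); next }
      j <- rows[length(rows)]
      st$m_last[i] <- j
      st$m_face[i] <- st$s_face[j]
      st$m_theta[i] <- atan2(st$s_dy[j], st$s_dx[j])
      st$m_rv[i] <- st$m_rv[i] + 1L
      .en_schedule_switch(st, i, t)
      .en_schedule_vertex(st, i, t)
      next
    }
  }
  t_final <- min(t_end, st$pt)
  snapshot <- .en_snapshot(st, t_final)
  ts <- as.data.frame(do.call(rbind, st$ts))
  nl <- if (st$n_nl > 0) {
    idx <- seq_len(st$n_nl)
    data.frame(time = st$nl_t[idx],
               kind = c("bound", "unbound", "iso")[st$nl_kind[idx]],
               face_id = st$nl_face[idx], u = st$nl_x[idx], v = st$nl_y[idx],
               theta = st$nl_theta[idx], parent_id = st$nl_parent[idx],
               relative_angle = st$nl_rel[idx],
               local_density = st$nl_rho[idx])
  } else {
    data.frame(time = numeric(0), kind = character(0), face_id = integer(0),
               u = numeric(0), v = numeric(0), theta = numeric(0),
               parent_id = integer(0), relative_angle = numeric(0),
               local_density = numeric(0))
  }
  eidx <- seq_len(st$n_el)
  elog <- data.frame(time = st$el_t[eidx],
                     event = .EL_TYPES[st$el_type[eidx]],
                     mt_id = st$el_mt[eidx], other_id = st$el_other[eidx])
  structure(list(config = config, status = st$status, t_final = t_final,
                 snapshot = snapshot, time_series = ts, nucleations = nl,
                 event_log = elog,
                 n_c = st$n_c, n_bound = st$n_bound, n_unbound = st$n_unbound,
                 counts = c(events = st$n_events, zipper = st$n_zip,
                            induced_catastrophe = st$n_icat,
                            crossover = st$n_cross)),
            class = "cm_sim")
}

# build the covered-segment snapshot at time t
.en_snapshot <- function(st, t) {
  rows <- which(st$s_alive[seq_len(st$n_seg)])
  empty <- data.frame(mt_id = integer(0), seg_index = integer(0),
                      face_id = integer(0), u1 = numeric(0), v1 = numeric(0),
                      u2 = numeric(0), v2 = numeric(0),
                      x1 = numeric(0), y1 = numeric(0), z1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0), z2 = numeric(0),
                      theta = numeric(0), plus_state = character(0))
  if (!length(rows)) return(empty)
  m <- st$s_mt[rows]
  dtv <- t - st$m_t0[m]
  plus <- st$m_plus0[m] + dtv * ifelse(st$m_state[m] == 1L, st$vp, -st$vm)
  minus <- st$m_minus0[m] + dtv * st$vt
  lo <- pmax(st$s_s0[rows], minus)
  hi <- pmin(st$s_send[rows], plus)
  keep <- hi - lo > 1e-9
  rows <- rows[keep]; lo <- lo[keep]; hi <- hi[keep]; m <- m[keep]
  if (!length(rows)) return(empty)
  u1 <- st$s_px[rows] + (lo - st$s_s0[rows]) * st$s_dx[rows]
  v1 <- st$s_py[rows] + (lo - st$s_s0[rows]) * st$s_dy[rows]
  u2 <- st$s_px[rows] + (hi - st$s_s0[rows]) * st$s_dx[rows]
  v2 <- st$s_py[rows] + (hi - st$s_s0[rows]) * st$s_dy[rows]
  e1 <- t(vapply(seq_along(rows), function(k) {
    embed3d(st$dom, st$s_face[rows[k]], u1[k], v1[k])
  }, numeric(3)))
  e2 <- t(vapply(seq_along(rows), function(k) {
    embed3d(st$dom, st$s_face[rows[k]], u2[k], v2[k])
  }, numeric(3)))
  seg_index <- stats::ave(seq_along(rows), m, FUN = seq_along)
  data.frame(mt_id = m, seg_index = seg_index, face_id = st$s_face[rows],
             u1 = u1, v1 = v1, u2 = u2, v2 = v2,
             x1 = e1[, 1], y1 = e1[, 2], z1 = e1[, 3],
             x2 = e2[, 1], y2 = e2[, 2], z2 = e2[, 3],
             theta = atan2(st$s_dy[rows], st$s_dx[rows]),
             plus_state = c("growing", "shrinking")[st$m_state[m]])
}

#' @export
print.cm_sim <- function(x, ...) {
  cat("<cm_sim>", x$config$domain$shape,
      sprintf("T = %g s, status = %s\n", x$config$T_end, x$status))
  cat(sprintf("  %d nucleations (%d bound, %d unbound), %d events\n",
              x$n_c, x$n_bound, x$n_unbound, x$counts[["events"]]))
  cat(sprintf("  final: %d segments, density %.3f / um\n",
              nrow(x$snapshot),
              sum(sqrt((x$snapshot$u2 - x$snapshot$u1)^2 +
                         (x$snapshot$v2 - x$snapshot$v1)^2)) /
                x$config$domain$area))
  invisible(x)
}

#' Segment snapshot of a finished simulation
#'
#' One row per covered face-local straight segment piece, with face-local
#' and embedded 3D endpoints. This is the exchange format consumed by the
#' observable functions and the toy-array generators.
#'
#' @param sim a `cm_sim` from [run_simulation()].
#' @return data.frame with columns `mt_id, seg_index, face_id, u1, v1, u2,
#'   v2, x1, y1, z1, x2, y2, z2, theta, plus_state`.
#' @export
array_snapshot <- function(sim) {
  stopifnot(inherits(sim, "cm_sim"))
  sim$snapshot
}
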