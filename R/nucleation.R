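# Nucleation modes.
#
# ISO: uniform positions and orientations at areal rate r_n.
# GDD: r_n is split globally into a microtubule-bound part
#      r_n * rho / (rho + rho_half) and an unbound remainder.
# LDD: complexes appear at rate r_ins; each appearance is resolved locally
#      and instantaneously by N meta-trajectories (radii standing in for the
#      complex's diffusion path), giving a bound nucleation, an unbound
#      nucleation, or dissociation.

#' GDD rate split
#'
#' Splits the total nucleation rate into microtubule-bound and unbound parts
#' given the global array density.
#'
#' @param rho total array density (total microtubule length / area),
#'   1/micrometre.
#' @param params a `cm_nucleation_params`.
#' @return named numeric vector `c(bound = ..., unbound = ...)` in
#'   per-square-micrometre per-second units. `bound + unbound == r_n` exactly
#'   (before any `unbound_factor` variant scaling, which applies to the
#'   unbound share only).
#' @export
gdd_split <- function(rho, params) {
  stopifnot(rho >= 0)
  rb <- params$r_n * rho / (rho + params$rho_half)
  ru <- (params$r_n - rb) * params$unbound_factor
  c(bound = rb, unbound = ru)
}

#' Probability that a complex reaches a lattice before nucleating unbound
#'
#' The diffusion time to cover distance `d` is approximated by the expected
#' time for a mean squared displacement of `d`, `tau = d^2 / (4 D)`; the
#' complex survives unbound nucleation over that time with probability
#' `exp(-r_u * tau)`.
#'
#' @param d distance to the intersected lattice, micrometres.
#' @param params a `cm_nucleation_params`.
#' @return probability in (0, 1].
#' @export
p_reach <- function(d, params) {
  stopifnot(all(d >= 0))
  exp(-params$r_u * d^2 / (4 * params$D_nc))
}

#' Effective areal nucleation rate from a nucleation count
#'
#' @param n_c number of nucleation events up to time `T_end`.
#' @param T_end duration, seconds.
#' @param A domain area, square micrometres.
#' @return rate in per square micrometre per second.
#' @export
effective_rn <- function(n_c, T_end, A) {
  stopifnot(T_end > 0, A > 0)
  n_c / (T_end * A)
}

# Continuous (sideways) part of the daughter-angle distribution: an angular
# density proportional to the partial area swept from a focal point of an
# ellipse with eccentricity eps, main axis at +/- theta_b from the parent.
# Each branch integrates to 1 over a full circle.
.ellipse_branch_density <- function(x, eps) {
  (1 - eps^2)^1.5 / (2 * pi) * (1 - eps * cos(x))^-2
}

#' Continuous part of the daughter-angle density
#'
#' The full distribution is `f_forward * delta(theta) + f_backward *
#' delta(theta - pi)` plus this continuous sideways part (left and right
#' branches weighted by `f_left`, `f_right`).
#'
#' @param theta angle(s) relative to the parent, radians, in `(-pi, pi]`.
#' @param params a `cm_nucleation_params`.
#' @return density values.
#' @export
branch_angle_density <- function(theta, params) {
  tb <- params$theta_b * pi / 180
  params$f_left * .ellipse_branch_density(theta - tb, params$eccentricity) +
    params$f_right * .ellipse_branch_density(theta + tb, params$eccentricity)
}

# Precompute the inverse CDF of the centred branch shape (1 - eps cos x)^-2
# on a 0.1 degree grid.
.branch_shape_table <- function(eps) {
  x <- seq(-pi, pi, length.out = 3601L)
  f <- .ellipse_branch_density(x, eps)
  cdf <- c(0, cumsum((f[-1] + f[-length(f)]) / 2 * diff(x)))
  cdf <- cdf / cdf[length(cdf)]
  list(x = x, cdf = cdf)
}

#' Sampler of daughter angles relative to the parent
#'
#' Returns a function `f(n)` drawing `n` relative angles from the nucleation
#' angle distribution: exactly parallel with probability `f_forward`, exactly
#' antiparallel with `f_backward`, otherwise from the left/right ellipse
#' branches (numerically inverted CDF tabulated at 0.1 degree resolution).
#' Uses the current RNG stream.
#'
#' @param params a `cm_nucleation_params`.
#' @return function of `n` returning angles in `(-pi, pi]`.
#' @export
relative_angle_sampler <- function(params) {
  tab <- .branch_shape_table(params$eccentricity)
  tb <- params$theta_b * pi / 180
  probs <- c(params$f_forward, params$f_backward, params$f_left, params$f_right)
  function(n) {
    comp <- sample.int(4L, n, replace = TRUE, prob = probs)
    out <- numeric(n)
    out[comp == 2L] <- pi
    side <- which(comp >= 3L)
    if (length(side)) {
      u <- stats::runif(length(side))
      xi <- stats::approx(tab$cdf, tab$x, xout = u, ties = "ordered")$y
      out[side] <- ifelse(comp[side] == 3L, tb + xi, -tb + xi)
    }
    w <- ((out + pi) %% (2 * pi)) - pi
    w[w == -pi] <- pi   # antiparallel convention: theta in (-pi, pi]
    w
  }
}

# --- ray casting against a static segment snapshot (R reference path) ------

# Normalise a snapshot data.frame into ray form: face, px, py, dx, dy, len.
.snapshot_rays <- function(segs) {
  dx <- segs$u2 - segs$u1
  dy <- segs$v2 - segs$v1
  len <- sqrt(dx^2 + dy^2)
  ok <- len > 0
  data.frame(mt_id = segs$mt_id[ok], face = segs$face_id[ok],
             px = segs$u1[ok], py = segs$v1[ok],
             dx = dx[ok] / len[ok], dy = dy[ok] / len[ok], len = len[ok])
}

# First intersection of a surface ray with a static segment set.
# Returns NULL or list(dist, mt_id, theta_seg, face, x, y).
.cast_ray <- function(domain, face, x, y, theta, segs_rays, max_dist,
                      min_dist = 1e-9) {
  adv <- advance(domain, face, x, y, theta, max_dist)
  pieces <- adv$pieces
  off <- 0
  for (i in seq_len(nrow(pieces))) {
    pc <- pieces[i, ]
    if (pc["len"] > 0) {
      sel <- segs_rays$face == pc["face"]
      if (any(sel)) {
        s <- segs_rays[sel, ]
        den <- pc["dx"] * s$dy - pc["dy"] * s$dx
        ok <- abs(den) > 1e-12
        qx <- s$px - pc["px"]; qy <- s$py - pc["py"]
        t_ray <- (qx * s$dy - qy * s$dx) / den
        t_seg <- (qx * pc["dy"] - qy * pc["dx"]) / den
        ok <- ok & t_ray >= 0 & t_ray <= pc["len"] &
          t_seg >= -1e-9 & t_seg <= s$len + 1e-9 &
          (off + t_ray) > min_dist
        if (any(ok)) {
          j <- which(ok)[which.min(t_ray[ok])]
          return(list(dist = unname(off + t_ray[j]), mt_id = s$mt_id[j],
                      theta_seg = atan2(s$dy[j], s$dx[j]),
                      face = as.integer(pc["face"]),
                      x = unname(pc["px"] + t_ray[j] * pc["dx"]),
                      y = unname(pc["py"] + t_ray[j] * pc["dy"])))
        }
      }
    }
    off <- off + pc["len"]
  }
  NULL
}

#' Resolve one LDD complex appearance against a segment snapshot
#'
#' Casts `N_meta` meta-trajectories from the appearance point (first at a
#' uniform random angle, the rest spaced `2*pi/N_meta`), each stopping at the
#' first microtubule lattice intersection or at `R_max`, and draws the
#' outcome: a bound nucleation on an intersected lattice, an unbound
#' nucleation at the appearance point with uniform orientation, or
#' dissociation (`"none"`). Among intersecting trajectories the bound one is
#' chosen with probability proportional to its reach probability.
#'
#' This standalone version operates on a static segment snapshot (as written
#' by [array_snapshot()] or built by the toy-array generators); the simulation
#' engine applies the identical rules to its live state.
#'
#' @param domain a `cm_domain`.
#' @param face,x,y appearance point.
#' @param segs segment snapshot data.frame (columns `mt_id, face_id, u1, v1,
#'   u2, v2`), or `NULL` for an empty array.
#' @param params a `cm_nucleation_params` with `mode = "LDD"`.
#' @param angle_sampler optional function from [relative_angle_sampler()]
#'   (built on the fly if missing).
#' @param first_angle optional fixed angle of the first meta-trajectory
#'   (for tests).
#' @return list with `kind` (`"none"`, `"unbound"`, `"bound"`), `face`, `x`,
#'   `y`, `theta` (absolute direction), `parent` (mt id or `NA`),
#'   `rel_angle`, and diagnostic vectors `d` (hit distances, `NA` where the
#'   trajectory reached `R_max`) and `p` (reach probabilities of hits).
#' @export
ldd_resolve <- function(domain, face, x, y, segs, params,
                        angle_sampler = NULL, first_angle = NULL) {
  stopifnot(params$mode == "LDD")
  N <- params$N_meta
  th1 <- if (is.null(first_angle)) stats::runif(1, 0, 2 * pi) else first_angle
  angles <- th1 + 2 * pi * (seq_len(N) - 1L) / N
  rays <- if (is.null(segs) || nrow(segs) == 0L) NULL else .snapshot_rays(segs)
  d <- rep(NA_real_, N)
  hits <- vector("list", N)
  if (!is.null(rays)) {
    for (i in seq_len(N)) {
      h <- .cast_ray(domain, face, x, y, angles[i], rays, params$R_max)
      if (!is.null(h)) { d[i] <- h$dist; hits[[i]] <- h }
    }
  }
  ih <- which(!is.na(d))
  p <- if (length(ih)) p_reach(d[ih], params) else numeric(0)
  sum_p <- sum(p) / N
  if (params$rescaled) {
    p_bound <- sum_p
    p_unbound <- (params$alpha_unbound / params$alpha_bound) * (1 - sum_p)
  } else {
    p_bound <- params$alpha_bound * sum_p
    p_unbound <- params$alpha_unbound * (1 - sum_p)
  }
  u <- stats::runif(1)
  out <- list(kind = "none", face = face, x = x, y = y, theta = NA_real_,
              parent = NA_integer_, rel_angle = NA_real_, d = d, p = p)
  if (u < p_bound) {
    j <- if (length(ih) == 1L) 1L else sample.int(length(ih), 1L, prob = p)
    h <- hits[[ih[j]]]
    if (is.null(angle_sampler)) angle_sampler <- relative_angle_sampler(params)
    rel <- angle_sampler(1L)
    out$kind <- "bound"
    out$face <- h$face; out$x <- h$x; out$y <- h$y
    out$parent <- h$mt_id
    out$rel_angle <- rel
    out$theta <- .wrap_angle(h$theta_seg + rel)
  } else if (u < p_bound + p_unbound) {
    out$kind <- "unbound"
    out$theta <- stats::runif(1, -pi, pi)
  }
  out
}

.wrap_angle <- function(a) ((a + pi) %% (2 * pi)) - pi
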