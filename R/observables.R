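# Array-level metrics: planar nematic order parameter and orientation,
# surface-corrected 3D order and most-avoided direction, orientation
# classification, axial density profiles, the control parameter G and the
# octant projection used for orientation distribution plots.

#' Planar nematic order parameter and orientation
#'
#' `S2 = sqrt(<<cos 2 theta>>^2 + <<sin 2 theta>>^2)` with `<<.>>` the
#' length-weighted mean over segments, and
#' `Theta2 = atan(<<sin 2 theta>> / (<<cos 2 theta>> + S2))`.
#'
#' @param theta segment direction angles, radians.
#' @param lengths segment lengths, micrometres.
#' @return list with `S2` in `[0, 1]` and `Theta2` in radians
#'   (`(-pi/2, pi/2]`); both `NA` if the total length is zero.
#' @export
s2_theta2 <- function(theta, lengths) {
  w <- sum(lengths)
  if (!is.finite(w) || w <= 0) return(list(S2 = NA_real_, Theta2 = NA_real_))
  c2 <- sum(lengths * cos(2 * theta)) / w
  s2 <- sum(lengths * sin(2 * theta)) / w
  S2 <- sqrt(c2^2 + s2^2)
  list(S2 = S2, Theta2 = atan2(s2, c2 + S2))
}

# Length-weighted mean of u (x) u over embedded unit tangents.
.order_tensor <- function(tangents, lengths) {
  M <- crossprod(tangents * sqrt(lengths))
  M / sum(lengths)
}

# Order tensor of the analytic isotropic array on the domain: area-weighted
# average of tangent-plane isotropy per face (mantle averaged over azimuth).
.iso_tensor <- function(domain) {
  M <- matrix(0, 3, 3)
  for (f in domain$faces) {
    Mf <- if (identical(f$type, "mantle")) {
      diag(c(0.5, 0.25, 0.25))
    } else {
      (tcrossprod(f$eu) + tcrossprod(f$ev)) / 2
    }
    M <- M + f$area * Mf
  }
  M / domain$area
}

# Smallest generalized eigenpair of M n = mu M_iso n, restricted to the range
# of M_iso. Returns list(mu, n, tie).
.min_gen_eig <- function(M, M_iso, tol = 1e-9) {
  eb <- eigen(M_iso, symmetric = TRUE)
  keep <- eb$values > tol
  W <- eb$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(eb$values[keep]), sum(keep))
  A <- t(W) %*% M %*% W
  ea <- eigen((A + t(A)) / 2, symmetric = TRUE)
  k <- length(ea$values)
  mu_min <- ea$values[k]
  tied <- which(ea$values < mu_min + tol)
  tie <- length(tied) > 1L
  best <- k
  if (tie) {
    # deterministic tie-break: prefer the direction with the largest
    # component on the lowest-index axis (x, then y, then z)
    cand <- vapply(tied, function(j) {
      v <- W %*% ea$vectors[, j]
      v / sqrt(sum(v^2))
    }, numeric(3))
    score <- round(abs(t(cand)), 9)
    o <- order(score[, 1], score[, 2], score[, 3], decreasing = TRUE)
    best <- tied[o[1]]
  }
  n <- W %*% ea$vectors[, best]
  n <- as.numeric(n / sqrt(sum(n^2)))
  list(mu = max(ea$values[best], 0), n = n, tie = tie)
}

#' Surface-corrected 3D order parameter and most-avoided direction
#'
#' Builds the length-weighted second-moment tensor `M` of embedded unit
#' tangents and compares it with the tensor `M_iso` of the analytic isotropic
#' array on the same domain. The most-avoided direction `n` minimizes the
#' generalized Rayleigh quotient `n' M n / n' M_iso n`; the corrected order
#' parameter is `R2 = 1 - min quotient`, clipped to `[0, 1]`, so an isotropic
#' array scores 0 in expectation and a perfectly transverse array on a
#' cylinder scores 1 with `n` along the cylinder axis. Directions outside the
#' span of `M_iso` (e.g. the normal of a planar domain) carry no information
#' and are excluded.
#'
#' @param tangents n x 3 matrix of embedded unit tangent vectors.
#' @param lengths segment lengths (weights).
#' @param domain a `cm_domain`.
#' @return list with `orientation3d` (unit 3-vector), `Theta2_3d` (degrees in
#'   `[0, 90]`, angle between `orientation3d` and the long axis), `R2`, and
#'   `tie` (TRUE if the minimizing direction was degenerate and broken
#'   deterministically).
#' @export
orientation3d_r2 <- function(tangents, lengths, domain) {
  stopifnot(sum(lengths) > 0)
  M <- .order_tensor(tangents, lengths)
  ge <- .min_gen_eig(M, .iso_tensor(domain))
  R2 <- min(max(1 - ge$mu, 0), 1)
  th <- acos(min(abs(ge$n[1]), 1)) * 180 / pi
  th <- 90 - abs(90 - th)  # fold into [0, 90]
  list(orientation3d = ge$n, Theta2_3d = th, R2 = R2, tie = ge$tie)
}

#' Classify an array orientation
#'
#' Transverse when the most-avoided direction is within 10 degrees of the
#' long axis, longitudinal when more than 80 degrees away, otherwise
#' `"other"`.
#'
#' @param Theta2_3d angle in degrees, `[0, 90]`.
#' @return `"transverse"`, `"longitudinal"` or `"other"`.
#' @export
classify_orientation <- function(Theta2_3d) {
  stopifnot(all(Theta2_3d >= 0 & Theta2_3d <= 90))
  ifelse(Theta2_3d < 10, "transverse",
         ifelse(Theta2_3d > 80, "longitudinal", "other"))
}

#' Maximum attainable R2 for a perfect transverse or longitudinal array
#'
#' Used to renormalize `R2` for arrays classified transverse or longitudinal
#' (oblique orientations are not renormalized).
#'
#' @param domain a `cm_domain`.
#' @param class `"transverse"` or `"longitudinal"`.
#' @return the `R2` of a synthetic perfectly ordered array of that
#'   orientation on the domain.
#' @export
r2_max <- function(domain, class = c("transverse", "longitudinal")) {
  class <- match.arg(class)
  M <- if (class == "longitudinal") {
    diag(c(1, 0, 0))
  } else if (domain$shape == "box") {
    W <- domain$H; W2 <- domain$W2
    diag(c(0, W / (W + W2), W2 / (W + W2)))
  } else if (domain$shape == "capped_cylinder") {
    diag(c(0, 0.5, 0.5))
  } else {
    diag(c(0, 1, 0))
  }
  ge <- .min_gen_eig(M, .iso_tensor(domain))
  min(max(1 - ge$mu, 0), 1)
}

#' Axial density profile
#'
#' Total segment length per axial bin divided by the bin's surface area.
#' On cylinders only the mantle is binned (caps are excluded); on periodic
#' rectangles the whole face is binned along `u`. Conservation holds:
#' `sum(density * bin_area)` equals the binned total length.
#'
#' @param segs segment snapshot data.frame (columns `face_id, u1, v1, u2, v2`).
#' @param domain a `cm_domain` (periodic rectangle or capped cylinder).
#' @param bin_width bin width along the long axis, micrometres.
#' @return data.frame with `bin_center`, `density` (1/micrometre) and
#'   `bin_area`.
#' @export
density_profile <- function(segs, domain, bin_width = 1) {
  stopifnot(domain$shape %in% c("periodic_rectangle", "capped_cylinder"))
  width <- if (domain$shape == "capped_cylinder") domain$C else domain$H
  edges <- seq(0, domain$L, by = bin_width)
  if (edges[length(edges)] < domain$L) edges <- c(edges, domain$L)
  nb <- length(edges) - 1L
  dens <- numeric(nb)
  s <- segs[segs$face_id == 1L, , drop = FALSE]
  if (nrow(s) > 0) {
    len <- sqrt((s$u2 - s$u1)^2 + (s$v2 - s$v1)^2)
    a <- pmin(s$u1, s$u2); b <- pmax(s$u1, s$u2)
    du <- b - a
    for (k in seq_len(nb)) {
      ov <- pmax(0, pmin(b, edges[k + 1]) - pmax(a, edges[k]))
      contrib <- ifelse(du > 1e-12, len * ov / du,
                        ifelse(a >= edges[k] & (a < edges[k + 1] | (k == nb & a <= edges[k + 1])),
                               len, 0))
      dens[k] <- sum(contrib)
    }
  }
  areas <- diff(edges) * width
  data.frame(bin_center = (edges[-1] + edges[-length(edges)]) / 2,
             density = dens / areas, bin_area = areas)
}

#' Control parameter G
#'
#' Dimensionless ratio of the interaction length scale to the intrinsic
#' (interaction-free) microtubule length, adjusted for minus-end
#' treadmilling:
#' `G = (2 (v+ - vtm)^2 (v- + vtm) / (r_n v+ (v+ + v-)))^(1/3) *
#'      (r_r / (v- + vtm) - r_c / (v+ - vtm))`.
#' Negative values correspond to the bounded-growth regime; non-negative
#' values (unbounded growth) are accepted with a warning.
#'
#' @param dynamics a `cm_dynamic_params`.
#' @param r_n areal nucleation rate (for LDD use the measured effective rate
#'   from [effective_rn()]).
#' @return G (dimensionless).
#' @export
control_G <- function(dynamics, r_n) {
  stopifnot(r_n > 0)
  vp <- dynamics$v_plus; vm <- dynamics$v_minus; vt <- dynamics$v_tm
  stopifnot(vp > vt, vm + vt > 0)
  lint <- (2 * (vp - vt)^2 * (vm + vt) / (r_n * vp * (vp + vm)))^(1 / 3)
  G <- lint * (dynamics$r_r / (vm + vt) - dynamics$r_c / (vp - vt))
  if (G >= 0) warning("G >= 0: unbounded-growth parameterization")
  G
}

#' Catastrophe rate that realizes a target control parameter
#'
#' Inverts [control_G()] for `r_c` at fixed rescue rate, speeds and
#' nucleation rate; convenient for sweeps parameterized directly in G.
#'
#' @param G target control parameter (negative in the bounded regime).
#' @param r_n areal nucleation rate.
#' @param dynamics a `cm_dynamic_params` (its `r_c` is ignored).
#' @return catastrophe rate in 1/s.
#' @export
rc_for_G <- function(G, r_n, dynamics) {
  vp <- dynamics$v_plus; vm <- dynamics$v_minus; vt <- dynamics$v_tm
  lint <- (2 * (vp - vt)^2 * (vm + vt) / (r_n * vp * (vp + vm)))^(1 / 3)
  (dynamics$r_r / (vm + vt) - G / lint) * (vp - vt)
}

#' Octant projection of an orientation vector
#'
#' Maps a unit orientation vector (long axis = x) into the positive octant by
#' reflections and projects it to screen coordinates such that the three axis
#' unit vectors appear as three corners equidistant from the centre and the
#' body diagonal appears at the centre: `X = (-|y| + |z|) / (2 sqrt(2))`,
#' `Y = |x| - (|y| + |z|) / 2`. Transverse arrays plot at the top.
#'
#' @param v unit 3-vector.
#' @return named numeric vector `c(X = , Y = )`.
#' @export
octant_project <- function(v) {
  stopifnot(length(v) == 3)
  c(X = (-abs(v[2]) + abs(v[3])) / (2 * sqrt(2)),
    Y = abs(v[1]) - (abs(v[2]) + abs(v[3])) / 2)
}

#' Vertical histogram coordinate of an orientation vector
#'
#' `C2 = |x| - 0.5 * sqrt(y^2 + z^2)`: +1 for a transverse array (avoided
#' direction along the axis), -0.5 for orientation vectors perpendicular to
#' the axis.
#'
#' @param v unit 3-vector.
#' @return scalar in `[-0.5, 1]`.
#' @export
c2_coordinate <- function(v) {
  stopifnot(length(v) == 3)
  abs(v[1]) - 0.5 * sqrt(v[2]^2 + v[3]^2)
}

# Embedded unit tangents + lengths from a snapshot, subdividing mantle
# segments (which embed as helical arcs) into short chunks.
.snapshot_tangents <- function(segs, domain, chunk = 0.5) {
  tang <- matrix(numeric(0), ncol = 3)
  lens <- numeric(0)
  if (nrow(segs) == 0L) return(list(tangents = tang, lengths = lens))
  rows_t <- vector("list", nrow(segs))
  rows_l <- vector("list", nrow(segs))
  for (i in seq_len(nrow(segs))) {
    f <- domain$faces[[segs$face_id[i]]]
    dx <- segs$u2[i] - segs$u1[i]; dy <- segs$v2[i] - segs$v1[i]
    len <- sqrt(dx^2 + dy^2)
    if (len <= 0) next
    th <- atan2(dy, dx)
    if (identical(f$type, "mantle") && abs(dy) > 1e-12) {
      n <- max(1L, ceiling(abs(dy) / chunk))
      tmid <- (seq_len(n) - 0.5) / n
      tg <- t(vapply(tmid, function(s) {
        tangent3d(domain, segs$face_id[i],
                  segs$u1[i] + s * dx, segs$v1[i] + s * dy, th)
      }, numeric(3)))
      rows_t[[i]] <- tg
      rows_l[[i]] <- rep(len / n, n)
    } else {
      rows_t[[i]] <- matrix(tangent3d(domain, segs$face_id[i],
                                      segs$u1[i], segs$v1[i], th), 1, 3)
      rows_l[[i]] <- len
    }
  }
  list(tangents = do.call(rbind, rows_t), lengths = unlist(rows_l))
}

#' Full order metrics of a segment snapshot
#'
#' Planar `S2`/`Theta2` (on the unrolled mantle only for cylinders, on the
#' whole face for periodic rectangles, omitted for boxes), the 3D
#' most-avoided-direction metrics, the orientation class and, for transverse
#' or longitudinal arrays, the renormalized `R2`.
#'
#' @param segs segment snapshot data.frame.
#' @param domain a `cm_domain`.
#' @return list of metrics.
#' @export
order_metrics <- function(segs, domain) {
  out <- list(S2 = NA_real_, Theta2 = NA_real_, R2 = NA_real_,
              Theta2_3d = NA_real_, orientation3d = rep(NA_real_, 3),
              class = NA_character_, renormalized_R2 = NA_real_,
              total_length = 0, density = 0)
  if (nrow(segs) == 0L) return(out)
  dx <- segs$u2 - segs$u1; dy <- segs$v2 - segs$v1
  len <- sqrt(dx^2 + dy^2)
  out$total_length <- sum(len)
  out$density <- out$total_length / domain$area
  pla <- if (domain$shape == "box") integer(0) else which(segs$face_id == 1L)
  if (length(pla)) {
    st <- s2_theta2(atan2(dy[pla], dx[pla]), len[pla])
    out$S2 <- st$S2; out$Theta2 <- st$Theta2
  }
  tg <- .snapshot_tangents(segs, domain)
  if (length(tg$lengths)) {
    o3 <- orientation3d_r2(tg$tangents, tg$lengths, domain)
    out$R2 <- o3$R2
    out$Theta2_3d <- o3$Theta2_3d
    out$orientation3d <- o3$orientation3d
    out$class <- classify_orientation(o3$Theta2_3d)
    if (out$class %in% c("transverse", "longitudinal")) {
      out$renormalized_R2 <- o3$R2 / r2_max(domain, out$class)
    }
  }
  out
}
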