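# Simulation surfaces: collections of flat faces with isometric transition
# maps. Trajectories are straight within a face and continue across seams /
# edges by unfolding, so direction is continuous in the unfolded plane and
# there is no event or penalty at an edge.
#
# Conventions: lengths in micrometres, angles in radians, face-local
# direction angle theta measured from the face u-axis; on every face where
# the domain's long (L) axis has a projection, the u-axis is aligned with it,
# so theta = 0 is longitudinal and theta = +/- pi/2 transverse.

#' Define a simulation domain
#'
#' Constructs a closed or periodic surface made of flat faces:
#' a periodic rectangle, a capped cylinder (periodic rectangular mantle of
#' width `2*pi*radius` plus two disk caps), or a box (six rectangular faces
#' with explicit edge unfolding).
#'
#' @param shape one of `"periodic_rectangle"`, `"capped_cylinder"`, `"box"`.
#' @param L domain length (the long axis), micrometres.
#' @param H second dimension: rectangle height / box width, micrometres.
#' @param W2 box third dimension, micrometres (box only).
#' @param radius cylinder radius, micrometres (cylinder only).
#' @return an object of class `cm_domain`.
#' @examples
#' dom <- domain_spec("capped_cylinder", L = 40, radius = 6)
#' total_area(dom)
#' @export
domain_spec <- function(shape = c("periodic_rectangle", "capped_cylinder", "box"),
                        L, H = NULL, W2 = NULL, radius = NULL) {
  shape <- match.arg(shape)
  stopifnot(is.numeric(L), length(L) == 1L, L > 0)
  dom <- list(shape = shape, L = L)
  if (shape == "periodic_rectangle") {
    stopifnot(!is.null(H), H > 0)
    dom$H <- H
    dom$faces <- list(.face_rect(1L, a = L, b = H,
                                 origin = c(0, 0, 0), eu = c(1, 0, 0), ev = c(0, 1, 0),
                                 per_u = TRUE, per_v = TRUE))
  } else if (shape == "capped_cylinder") {
    stopifnot(!is.null(radius), radius > 0)
    dom$R <- radius
    C <- 2 * pi * radius
    dom$C <- C
    mantle <- .face_rect(1L, a = L, b = C, origin = c(0, 0, 0),
                         eu = c(1, 0, 0), ev = NA, per_u = FALSE, per_v = TRUE)
    mantle$type <- "mantle"
    cap_lo <- .face_disk(2L, R = radius, x3 = 0)
    cap_hi <- .face_disk(3L, R = radius, x3 = L)
    dom$faces <- list(mantle, cap_lo, cap_hi)
  } else {
    stopifnot(!is.null(H), H > 0, !is.null(W2), W2 > 0)
    dom$H <- H
    dom$W2 <- W2
    dom$faces <- .box_faces(L, H, W2)
    dom$edges <- .box_edge_table(dom$faces)
  }
  dom$face_areas <- vapply(dom$faces, function(f) f$area, numeric(1))
  dom$area <- sum(dom$face_areas)
  class(dom) <- "cm_domain"
  dom
}

.face_rect <- function(id, a, b, origin, eu, ev, per_u = FALSE, per_v = FALSE) {
  list(id = id, type = "rect", a = a, b = b, origin = origin, eu = eu, ev = ev,
       per_u = per_u, per_v = per_v, area = a * b)
}

.face_disk <- function(id, R, x3) {
  # cap local coordinates (p, q) map directly onto global (y, z)
  list(id = id, type = "disk", R = R, x3 = x3, origin = c(x3, 0, 0),
       eu = c(0, 1, 0), ev = c(0, 0, 1), area = pi * R^2)
}

.box_faces <- function(L, W, W2) {
  list(
    .face_rect(1L, L, W,  origin = c(0, 0, 0),  eu = c(1, 0, 0), ev = c(0, 1, 0)),  # bottom z=0
    .face_rect(2L, L, W,  origin = c(0, 0, W2), eu = c(1, 0, 0), ev = c(0, 1, 0)),  # top z=W2
    .face_rect(3L, L, W2, origin = c(0, 0, 0),  eu = c(1, 0, 0), ev = c(0, 0, 1)),  # front y=0
    .face_rect(4L, L, W2, origin = c(0, W, 0),  eu = c(1, 0, 0), ev = c(0, 0, 1)),  # back y=W
    .face_rect(5L, W, W2, origin = c(0, 0, 0),  eu = c(0, 1, 0), ev = c(0, 0, 1)),  # left x=0
    .face_rect(6L, W, W2, origin = c(L, 0, 0),  eu = c(0, 1, 0), ev = c(0, 0, 1))   # right x=L
  )
}

# Edge endpoints of rect face edge k (1: u=0, 2: u=a, 3: v=0, 4: v=b) in 3D.
.edge_pts3 <- function(f, k) {
  uv <- switch(k,
               rbind(c(0, 0), c(0, f$b)),
               rbind(c(f$a, 0), c(f$a, f$b)),
               rbind(c(0, 0), c(f$a, 0)),
               rbind(c(0, f$b), c(f$a, f$b)))
  t(apply(uv, 1, function(p) f$origin + p[1] * f$eu + p[2] * f$ev))
}

# In-plane outward normal (3D) of rect face edge k.
.edge_out3 <- function(f, k) {
  switch(k, -f$eu, f$eu, -f$ev, f$ev)
}

# Match box edges pairwise by their shared 3D endpoints.
.box_edge_table <- function(faces) {
  recs <- list()
  for (f in faces) for (k in 1:4) {
    recs[[length(recs) + 1L]] <- list(face = f$id, k = k, pts = .edge_pts3(f, k))
  }
  n <- length(recs)
  tab <- vector("list", n)
  key <- function(pts) {
    p <- round(pts, 9)
    o <- order(p[, 1], p[, 2], p[, 3])
    paste(p[o, ], collapse = ",")
  }
  keys <- vapply(recs, function(r) key(r$pts), character(1))
  for (i in seq_len(n)) {
    j <- setdiff(which(keys == keys[i]), i)
    stopifnot(length(j) == 1L)
    tab[[i]] <- list(face = recs[[i]]$face, k = recs[[i]]$k,
                     nbr_face = recs[[j]]$face, nbr_k = recs[[j]]$k)
  }
  names(tab) <- paste0(vapply(recs, function(r) r$face, integer(1)), ".",
                       vapply(recs, function(r) r$k, integer(1)))
  tab
}

#' Total surface area of a domain
#'
#' Exact analytic area: `L*H` for the periodic rectangle,
#' `2*pi*R*(L + R)` for the capped cylinder, `2*(L*H + L*W2 + H*W2)` for the box.
#'
#' @param domain a `cm_domain`.
#' @return area in square micrometres.
#' @export
total_area <- function(domain) {
  stopifnot(inherits(domain, "cm_domain"))
  domain$area
}

#' Embed a surface point in 3D
#'
#' @param domain a `cm_domain`.
#' @param face face id.
#' @param x,y face-local coordinates.
#' @return numeric 3-vector (micrometres).
#' @export
embed3d <- function(domain, face, x, y) {
  f <- domain$faces[[face]]
  if (identical(f$type, "mantle")) {
    phi <- y / domain$R
    c(x, domain$R * cos(phi), domain$R * sin(phi))
  } else if (identical(f$type, "disk")) {
    c(f$x3, x, y)
  } else {
    f$origin + x * f$eu + y * f$ev
  }
}

#' Unit 3D tangent of a surface direction
#'
#' @inheritParams embed3d
#' @param theta face-local direction angle, radians.
#' @return unit numeric 3-vector lying in the face's tangent plane.
#' @export
tangent3d <- function(domain, face, x, y, theta) {
  f <- domain$faces[[face]]
  du <- cos(theta); dv <- sin(theta)
  if (identical(f$type, "mantle")) {
    phi <- y / domain$R
    c(du, -dv * sin(phi), dv * cos(phi))
  } else {
    du * f$eu + dv * f$ev
  }
}

# Distance along (dx,dy) from (x,y) to the rectangle boundary; returns
# list(t, wall) with wall in 1:4 (u=0, u=a, v=0, v=b) or t = Inf.
.rect_exit <- function(x, y, dx, dy, a, b) {
  t_best <- Inf; wall <- 0L
  if (dx < 0) { t <- max(-x / dx, 0);      if (t < t_best) { t_best <- t; wall <- 1L } }
  if (dx > 0) { t <- max((a - x) / dx, 0); if (t < t_best) { t_best <- t; wall <- 2L } }
  if (dy < 0) { t <- max(-y / dy, 0);      if (t < t_best) { t_best <- t; wall <- 3L } }
  if (dy > 0) { t <- max((b - y) / dy, 0); if (t < t_best) { t_best <- t; wall <- 4L } }
  list(t = t_best, wall = wall)
}

# First exit of a ray from a disk of radius R (start inside or on boundary).
.disk_exit <- function(x, y, dx, dy, R) {
  pd <- x * dx + y * dy
  disc <- pd * pd - (x * x + y * y - R * R)
  if (disc < 0) disc <- 0
  max(-pd + sqrt(disc), 0)
}

#' Advance a point along the surface
#'
#' Moves arclength `s` from `(face, x, y)` in direction `theta`, straight
#' within each face, crossing seams and edges by isometric unfolding. Returns
#' the traversed pieces (one row per face-local straight sub-segment) and the
#' terminal point/direction. Crossing an edge carries no event or penalty.
#'
#' A trajectory hitting a box corner or the rim of a cap exactly at a face
#' corner is perturbed by 1e-9 micrometres along the edge (tie-break).
#'
#' @inheritParams tangent3d
#' @param s arclength to advance, micrometres (`s >= 0`).
#' @param max_pieces safety cap on the number of face-local pieces.
#' @return list with `pieces` (matrix with columns `face, px, py, dx, dy, len`)
#'   and `face`, `x`, `y`, `theta` for the terminal state.
#' @export
advance <- function(domain, face, x, y, theta, s, max_pieces = 1024L) {
  stopifnot(s >= 0)
  dx <- cos(theta); dy <- sin(theta)
  pieces <- matrix(numeric(0), ncol = 6,
                   dimnames = list(NULL, c("face", "px", "py", "dx", "dy", "len")))
  if (s == 0) {
    return(list(pieces = pieces, face = face, x = x, y = y, theta = theta))
  }
  if (domain$shape == "periodic_rectangle") {
    m <- cpp_rect_pieces(domain$L, domain$H, x, y, dx, dy, s, max_pieces)
    pieces <- m[, 1:6, drop = FALSE]
    colnames(pieces) <- c("face", "px", "py", "dx", "dy", "len")
    return(list(pieces = pieces, face = 1L, x = m[1, 7], y = m[1, 8],
                theta = theta))
  }
  rows <- vector("list", 16L)
  nr <- 0L
  rem <- s
  repeat {
    f <- domain$faces[[face]]
    if (identical(f$type, "disk")) {
      t_exit <- .disk_exit(x, y, dx, dy, f$R)
    } else {
      ex <- .rect_exit(x, y, dx, dy, f$a, f$b)
      t_exit <- ex$t; wall <- ex$wall
    }
    len <- min(rem, t_exit)
    nr <- nr + 1L
    if (nr > length(rows)) rows <- c(rows, vector("list", length(rows)))
    rows[[nr]] <- c(face, x, y, dx, dy, len)
    rem <- rem - len
    x <- x + len * dx; y <- y + len * dy
    if (rem <= 1e-12 && len < t_exit) break
    if (rem <= 0 && len >= t_exit) { rem <- 0 }  # ends exactly on a boundary: still transition
    # transition to the neighbouring face
    tr <- .transition(domain, face, x, y, dx, dy,
                      wall = if (identical(f$type, "disk")) NA_integer_ else wall)
    face <- tr$face; x <- tr$x; y <- tr$y; dx <- tr$dx; dy <- tr$dy
    if (rem <= 0) break
    if (nr >= max_pieces) break
  }
  pieces <- do.call(rbind, rows[seq_len(nr)])
  colnames(pieces) <- c("face", "px", "py", "dx", "dy", "len")
  list(pieces = pieces, face = face, x = x, y = y, theta = atan2(dy, dx))
}

# Apply the seam/edge transition at the current boundary point.
.transition <- function(domain, face, x, y, dx, dy, wall) {
  f <- domain$faces[[face]]
  if (domain$shape == "periodic_rectangle") {
    if (wall == 1L) x <- x + f$a else if (wall == 2L) x <- x - f$a
    if (wall == 3L) y <- y + f$b else if (wall == 4L) y <- y - f$b
    return(list(face = face, x = x, y = y, dx = dx, dy = dy))
  }
  if (domain$shape == "capped_cylinder") {
    R <- domain$R; C <- domain$C
    if (identical(f$type, "mantle")) {
      if (wall == 3L) return(list(face = face, x = x, y = y + C, dx = dx, dy = dy))
      if (wall == 4L) return(list(face = face, x = x, y = y - C, dx = dx, dy = dy))
      phi <- (y %% C) / R
      cp <- cos(phi); sp <- sin(phi)
      px <- R * cp; py <- R * sp
      if (wall == 1L) {        # onto low cap: inward is -r_hat, du<0
        ndx <- dx * cp - dy * sp
        ndy <- dx * sp + dy * cp
        return(list(face = 2L, x = px, y = py, dx = ndx, dy = ndy))
      } else {                 # onto high cap: inward is -r_hat, du>0
        ndx <- -dx * cp - dy * sp
        ndy <- -dx * sp + dy * cp
        return(list(face = 3L, x = px, y = py, dx = ndx, dy = ndy))
      }
    } else {
      # leaving a cap across its rim onto the mantle
      phi <- atan2(y, x)
      cp <- cos(phi); sp <- sin(phi)
      ar <- dx * cp + dy * sp      # outward radial component (> 0)
      bt <- -dx * sp + dy * cp     # tangential component (along +v)
      v <- (R * phi) %% C
      if (f$id == 2L) {
        return(list(face = 1L, x = 0, y = v, dx = ar, dy = bt))
      } else {
        return(list(face = 1L, x = domain$L, y = v, dx = -ar, dy = bt))
      }
    }
  }
  # box
  .box_transition(domain, face, x, y, dx, dy, wall)
}

.box_transition <- function(domain, face, x, y, dx, dy, wall) {
  f <- domain$faces[[face]]
  # corner tie-break: nudge 1e-9 along the edge into its interior
  eps <- 1e-9
  if (wall <= 2L) {
    if (y < eps) y <- eps else if (y > f$b - eps) y <- f$b - eps
  } else {
    if (x < eps) x <- eps else if (x > f$a - eps) x <- f$a - eps
  }
  e <- domain$edges[[paste0(face, ".", wall)]]
  g <- domain$faces[[e$nbr_face]]
  P <- f$origin + x * f$eu + y * f$ev
  d3 <- dx * f$eu + dy * f$ev
  pts <- .edge_pts3(f, wall)
  ehat <- pts[2, ] - pts[1, ]
  ehat <- ehat / sqrt(sum(ehat^2))
  nA_out <- .edge_out3(f, wall)
  nB_in <- -.edge_out3(g, e$nbr_k)
  alpha <- sum(d3 * ehat)
  beta <- sum(d3 * nA_out)
  d3n <- alpha * ehat + beta * nB_in
  xn <- sum((P - g$origin) * g$eu)
  yn <- sum((P - g$origin) * g$ev)
  xn <- min(max(xn, 0), g$a)
  yn <- min(max(yn, 0), g$b)
  list(face = g$id, x = xn, y = yn, dx = sum(d3n * g$eu), dy = sum(d3n * g$ev))
}

#' Sample points uniformly over the domain surface
#'
#' @param domain a `cm_domain`.
#' @param n number of points.
#' @return data.frame with columns `face`, `x`, `y`.
#' @export
sample_surface_point <- function(domain, n = 1L) {
  fid <- sample.int(length(domain$faces), n, replace = TRUE,
                    prob = domain$face_areas)
  x <- numeric(n); y <- numeric(n)
  for (i in seq_len(n)) {
    f <- domain$faces[[fid[i]]]
    if (identical(f$type, "disk")) {
      r <- f$R * sqrt(stats::runif(1))
      a <- stats::runif(1, 0, 2 * pi)
      x[i] <- r * cos(a); y[i] <- r * sin(a)
    } else {
      x[i] <- stats::runif(1, 0, f$a)
      y[i] <- stats::runif(1, 0, f$b)
    }
  }
  data.frame(face = fid, x = x, y = y)
}
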