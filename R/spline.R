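# Spline-based path construction: interpolating cubic spline through control
# points, arc-length parameterization, equidistant base-pair placement,
# parallel transport of reference frames, writhe, and helical twisting.

#' Fit an interpolating spline through control points
#'
#' Fits componentwise cubic interpolating splines against a chord-length
#' parameter.  Open paths use natural end conditions; closed paths use
#' periodic end conditions so the curve is smoothly periodic.  An arc-length
#' table is built by composite Gauss-Legendre quadrature on a fine parameter
#' grid.
#'
#' @param control_points Numeric matrix (>= 4 rows) of x, y, z in nm, or a
#'   path to a whitespace/CSV text file with one point per line.
#' @param closed Logical; fit a periodic (closed) curve.
#' @param n_table Number of subintervals in the arc-length table.
#' @return An object of class `spline_path` with elements `fx, fy, fz`
#'   (spline functions of the parameter), `tmax`, `closed`, `grid`,
#'   `arc` (cumulative arc length at `grid`, nm) and `length` (total arc
#'   length, nm).
#' @export
fit_spline <- function(control_points, closed = FALSE, n_table = 2048L) {
  cp <- as_control_points(control_points)
  if (nrow(cp) < 4)
    stop("at least four control points are required to fit the spline")
  d <- sqrt(rowSums((cp[-1, , drop = FALSE] - cp[-nrow(cp), , drop = FALSE])^2))
  if (any(d < 1e-12))
    stop("degenerate input: consecutive control points coincide")
  if (closed) {
    gap <- sqrt(sum((cp[1, ] - cp[nrow(cp), ])^2))
    pts <- if (gap < 1e-12) cp else rbind(cp, cp[1, ])
    d <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
    u <- c(0, cumsum(d))
    method <- "periodic"
  } else {
    pts <- cp
    u <- c(0, cumsum(d))
    method <- "natural"
  }
  fx <- stats::splinefun(u, pts[, 1], method = method)
  fy <- stats::splinefun(u, pts[, 2], method = method)
  fz <- stats::splinefun(u, pts[, 3], method = method)
  tmax <- u[length(u)]
  speed <- function(t) sqrt(fx(t, deriv = 1)^2 + fy(t, deriv = 1)^2 +
                              fz(t, deriv = 1)^2)
  grid <- seq(0, tmax, length.out = n_table + 1L)
  arc <- c(0, cumsum(gauss_legendre_segments(speed, grid)))
  structure(list(fx = fx, fy = fy, fz = fz, tmax = tmax, closed = closed,
                 speed = speed, grid = grid, arc = arc,
                 length = arc[length(arc)]),
            class = "spline_path")
}

as_control_points <- function(x) {
  if (is.character(x) && length(x) == 1) x <- read_control_points(x)
  cp <- as.matrix(x)
  storage.mode(cp) <- "double"
  if (ncol(cp) != 3 || anyNA(cp)) stop("control points must be finite x y z rows")
  dimnames(cp) <- NULL
  cp
}

#' Read control points from a text file
#'
#' One point per line, `x y z` in nm, whitespace- or comma-separated; lines
#' starting with `#` are ignored.
#'
#' @param path File path.
#' @return Numeric matrix with 3 columns.
#' @export
read_control_points <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  vals <- lapply(strsplit(ln, "[,[:space:]]+"), as.numeric)
  if (!all(lengths(vals) == 3)) stop("each control-point line must hold 3 numbers")
  do.call(rbind, vals)
}

# Composite 7-point Gauss-Legendre quadrature of f over consecutive segments
# of `grid`; returns one integral per segment.
gauss_legendre_segments <- function(f, grid) {
  gl_x <- c(-0.9491079123427585, -0.7415311855993945, -0.4058451513773972, 0,
            0.4058451513773972, 0.7415311855993945, 0.9491079123427585)
  gl_w <- c(0.1294849661688697, 0.2797053914892766, 0.3818300505051189,
            0.4179591836734694, 0.3818300505051189, 0.2797053914892766,
            0.1294849661688697)
  a <- grid[-length(grid)]
  b <- grid[-1]
  h <- (b - a) / 2
  m <- (a + b) / 2
  acc <- 0
  for (k in seq_along(gl_x)) acc <- acc + gl_w[k] * f(m + h * gl_x[k])
  acc * h
}

spline_point <- function(path, t) {
  cbind(path$fx(t), path$fy(t), path$fz(t))
}

spline_tangent <- function(path, t) {
  d <- cbind(path$fx(t, deriv = 1), path$fy(t, deriv = 1), path$fz(t, deriv = 1))
  d / sqrt(rowSums(d^2))
}

# Invert the arc-length table: parameter t at which cumulative arc = s.
# Table lookup refined by Newton iterations on the quadrature integrand.
arc_to_param <- function(path, s) {
  t0 <- stats::approx(path$arc, path$grid, xout = s, rule = 2)$y
  for (i in 1:4) {
    # residual arc from nearest table node, integrated finely
    si <- stats::approx(path$grid, path$arc, xout = t0, rule = 2)$y
    # local linearization with exact speed
    sp <- path$speed(t0)
    t0 <- t0 + (s - si) / sp
    t0 <- pmin(pmax(t0, 0), path$tmax)
  }
  t0
}

#' Place equidistant base-pair positions along a spline
#'
#' Distributes points at equal arc-length spacing (default 0.34 nm, the mean
#' base-pair rise).  When `n_bp` is omitted the count follows from the arc
#' length and any residual is spread uniformly over all gaps; the effective
#' spacing is reported via a message.  When `n_bp` is given the spacing is
#' rescaled to fit the fixed spline geometry.
#'
#' @param path A `spline_path`.
#' @param spacing Target spacing, nm.
#' @param n_bp Optional base-pair count.
#' @return List with `origins` (n x 3), `tangents` (n x 3, unit rows),
#'   `spacing` (effective, nm) and `closed`.
#' @export
sample_equidistant <- function(path, spacing = 0.34, n_bp = NULL) {
  L <- path$length
  if (is.null(n_bp)) {
    if (spacing > L) stop("requested spacing exceeds the arc length")
    n_bp <- if (path$closed) max(3L, as.integer(round(L / spacing)))
            else as.integer(floor(L / spacing + 1e-9)) + 1L
  }
  n_bp <- as.integer(n_bp)
  if (n_bp < 2) stop("n_bp must be at least 2")
  eff <- if (path$closed) L / n_bp else L / (n_bp - 1)
  if (abs(eff - spacing) > 1e-9)
    message(sprintf("spacing adjusted from %.4f to %.6f nm to fit the arc length",
                    spacing, eff))
  s <- if (path$closed) eff * (seq_len(n_bp) - 1L) else eff * (seq_len(n_bp) - 1L)
  t <- arc_to_param(path, s)
  list(origins = spline_point(path, t), tangents = spline_tangent(path, t),
       spacing = eff, closed = path$closed)
}

#' Parallel-transport reference frames along sampled positions
#'
#' Sets each frame's z axis to the local tangent and propagates the normal
#' by the minimal rotation carrying one tangent onto the next, so the frame
#' field carries zero intrinsic twist.  The initial normal is the global +x
#' axis projected perpendicular to the first tangent (+y if nearly
#' parallel) - a deterministic rule.
#'
#' @param samples List from [sample_equidistant()], or a list with `origins`
#'   and `tangents` matrices.
#' @param closed Logical; defaults to the sample's flag.
#' @return A `path_frames` list: `frames` array (n_bp, 4, 3), `spacing`,
#'   `closed`, `twist_per_step` (0 before twisting).
#' @export
transport_frames <- function(samples, closed = samples$closed) {
  tg <- samples$tangents
  og <- samples$origins
  n <- nrow(og)
  nz <- sqrt(rowSums(tg^2))
  if (any(nz < 1e-12)) stop("zero-length tangent")
  tg <- tg / nz
  z0 <- tg[1, ]
  ref <- if (abs(z0[1]) > 0.999) c(0, 1, 0) else c(1, 0, 0)
  x <- ref - sum(ref * z0) * z0
  x <- x / sqrt(sum(x^2))
  fr <- array(NA_real_, c(n, 4, 3))
  y <- cross3(z0, x)
  fr[1, , ] <- rbind(og[1, ], x, y, z0)
  for (i in 2:n) {
    R <- minimal_rotation(tg[i - 1, ], tg[i, ])
    x <- as.numeric(R %*% x)
    # guard against drift off the normal plane
    x <- x - sum(x * tg[i, ]) * tg[i, ]
    x <- x / sqrt(sum(x^2))
    y <- cross3(tg[i, ], x)
    fr[i, , ] <- rbind(og[i, ], x, y, tg[i, ])
  }
  structure(list(frames = fr, spacing = samples$spacing, closed = closed,
                 twist_per_step = 0),
            class = "path_frames")
}

# Minimal rotation matrix carrying unit vector a onto unit vector b.
minimal_rotation <- function(a, b) {
  v <- cross3(a, b)
  s <- sqrt(sum(v^2))
  c <- sum(a * b)
  if (s < 1e-14) {
    if (c > 0) return(diag(3))
    stop("antiparallel tangents: minimal rotation undefined")
  }
  ang <- atan2(s, c)
  rotation_matrix(v / s * ang)
}

#' Writhe of a space curve by the discrete Gauss double sum
#'
#' Exact pairwise solid-angle formula for polygonal curves (the method of
#' Klenin and Langowski, method 1a), skipping self and adjacent segment
#' pairs.  Defined for closed curves; for open chains pass
#' `allow_open = TRUE` to obtain the open-chain Gauss integral.
#'
#' @param origins n x 3 matrix of vertex positions (nm).
#' @param closed Logical.
#' @param allow_open Permit evaluation on open chains.
#' @return Writhe (dimensionless).
#' @export
compute_writhe <- function(origins, closed = TRUE, allow_open = FALSE) {
  og <- as.matrix(origins)
  n <- nrow(og)
  if (n < 4) stop("need at least 4 origins for a writhe estimate")
  if (!closed && !allow_open)
    stop("writhe is undefined for open chains (set allow_open = TRUE)")
  # segment list
  if (closed) {
    p1 <- og
    p2 <- og[c(2:n, 1), , drop = FALSE]
    ns <- n
  } else {
    p1 <- og[-n, , drop = FALSE]
    p2 <- og[-1, , drop = FALSE]
    ns <- n - 1L
  }
  total <- 0
  for (i in seq_len(ns - 2L)) {
    jmax <- if (closed && i == 1L) ns - 1L else ns
    js <- seq.int(i + 2L, jmax)
    if (length(js) == 0) next
    total <- total + sum(writhe_pair_vec(p1[i, ], p2[i, ],
                                         p1[js, , drop = FALSE],
                                         p2[js, , drop = FALSE]))
  }
  2 * total
}

# Vectorized Gauss-integral contribution of segment (a1,a2) against segments
# (b1,b2) rows: the signed solid angle / 4pi of each pair.
writhe_pair_vec <- function(a1, a2, b1, b2) {
  r13 <- sweep(b1, 2, a1)      # b1 - a1 rows? careful: r13 = p3 - p1
  # use convention: segment 1 = p1->p2 (a), segment 2 = p3->p4 (b)
  p1 <- a1; p2 <- a2
  r13 <- sweep(b1, 2, p1)
  r14 <- sweep(b2, 2, p1)
  r23 <- sweep(b1, 2, p2)
  r24 <- sweep(b2, 2, p2)
  n1 <- rowcross(r13, r14)
  n2 <- rowcross(r14, r24)
  n3 <- rowcross(r24, r23)
  n4 <- rowcross(r23, r13)
  n1 <- rownorm1(n1); n2 <- rownorm1(n2); n3 <- rownorm1(n3); n4 <- rownorm1(n4)
  ang <- asin(clip1(rowSums(n1 * n2))) + asin(clip1(rowSums(n2 * n3))) +
         asin(clip1(rowSums(n3 * n4))) + asin(clip1(rowSums(n4 * n1)))
  r12 <- p2 - p1
  r34 <- b2 - b1
  sgn <- sign(rowSums(rowcross(r34, matrix(r12, nrow(b1), 3, byrow = TRUE)) * r13))
  out <- ang * sgn / (4 * pi)
  out[!is.finite(out)] <- 0
  out
}

rowcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

rownorm1 <- function(m) {
  nn <- sqrt(rowSums(m^2))
  nn[nn < 1e-14] <- Inf       # degenerate pair contributes zero
  m / nn
}

clip1 <- function(x) pmin(1, pmax(-1, x))

#' Impose helical twist on transported frames
#'
#' Open chains: frame `i` is rotated about its own z axis by
#' `i * 360 / bp_per_turn` degrees, giving a 10.5 bp/turn helix by default.
#' Closed chains: the relaxed twist `Tw0` is the integer nearest
#' `n_bp / bp_per_turn` (closure requires whole turns); the imposed total
#' twist follows the White-Fuller relation `Tw_new = Tw0 + dLk - Wr`, spread
#' uniformly over all steps, so the resulting linking number is
#' `Tw0 + dLk`.
#'
#' @param pf A `path_frames` object from [transport_frames()].
#' @param bp_per_turn Base pairs per helical turn (default 10.5).
#' @param dLk Integer linking-number difference (closed chains only).
#' @return The twisted `path_frames`, with `twist_per_step`, `writhe`,
#'   `Tw0` fields set.
#' @export
apply_twist <- function(pf, bp_per_turn = 10.5, dLk = 0) {
  if (bp_per_turn <= 0) stop("bp_per_turn must be positive")
  fr <- pf$frames
  n <- dim(fr)[1]
  if (pf$closed) {
    if (abs(dLk - round(dLk)) > 1e-9)
      stop("dLk must be an integer for closed topologies")
    dLk <- round(dLk)
    wr <- compute_writhe(fr[, 1, ], closed = TRUE)
    Tw0 <- round(n / bp_per_turn)
    Tw_new <- Tw0 + dLk - wr
    per_step <- 360 * Tw_new / n
    message(sprintf("closed topology: Tw0 = %d turns, Wr = %.4f, twist %.4f deg/step",
                    Tw0, wr, per_step))
  } else {
    if (!identical(dLk, 0) && !isTRUE(all.equal(dLk, 0)))
      warning("dLk is ignored for open chains")
    wr <- NA_real_
    Tw0 <- NA_real_
    per_step <- 360 / bp_per_turn
  }
  for (i in seq_len(n)) {
    ang <- per_step * (i - 1)
    fr[i, 2:4, ] <- rotate_triad_about_z(fr[i, 2:4, ], ang)
  }
  out <- pf
  out$frames <- fr
  out$twist_per_step <- per_step
  out$writhe <- wr
  out$Tw0 <- Tw0
  out
}
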