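# Rigid-base geometric analysis: base-frame fitting from atomic coordinates,
# the 12 rigid parameters, linking number via the White-Fuller relation,
# persistence length and total curvature.

PARAM_NAMES <- c("shear", "stretch", "stagger", "buckle", "propeller", "opening",
                 "shift", "slide", "rise", "tilt", "roll", "twist")

#' Fit base reference frames from atomic coordinates
#'
#' Least-squares rigid superposition (Kabsch) of each base template's ring
#' atoms onto the observed coordinates; the base frame is the transformed
#' template frame.  Antisense-strand frames are flipped 180 degrees about
#' their x axis so both frames of a pair are co-oriented.
#'
#' @param atomic An `atomic_model` (or data frame with the same columns).
#' @return List with `watson` and `crick` arrays (n_bp, 4, 3) of per-base
#'   frames (crick frames already flipped), and `sequence`.
#' @export
fit_base_frames <- function(atomic) {
  resmap <- c(DA = "A", DT = "T", DG = "G", DC = "C", DU = "U",
              `5CM` = "C", `7MG` = "G",
              A = "A", T = "T", G = "G", C = "C", U = "U")
  fit_chain <- function(chain_id) {
    sub <- atomic[atomic$chain == chain_id, , drop = FALSE]
    ids <- sort(unique(sub$resid))
    out <- array(NA_real_, c(length(ids), 4, 3))
    codes <- character(length(ids))
    for (k in seq_along(ids)) {
      res <- sub[sub$resid == ids[k], , drop = FALSE]
      rn <- res$resname[1]
      code <- resmap[rn]
      if (is.na(code)) stop("unknown residue name '", rn, "' at resid ", ids[k])
      tpl <- base_template(code)
      # superpose on all template atoms (ring + exocyclic + C1'): the wider
      # footprint halves the noise amplification of the fitted frame origin
      fitset <- rownames(tpl$atoms)
      m <- match(fitset, res$name)
      if (anyNA(m))
        stop("missing ring atoms for resid ", ids[k], " (", rn, "): ",
             paste(fitset[is.na(m)], collapse = ", "))
      obs <- as.matrix(res[m, c("x", "y", "z")])
      ref <- tpl$atoms[fitset, , drop = FALSE]
      kb <- kabsch(ref, obs)
      # template frame is the identity, so the fitted frame is (R, t):
      # triad rows are t(R)
      out[k, 1, ] <- kb$t
      out[k, 2:4, ] <- t(kb$R)
      codes[k] <- code
    }
    list(frames = out, codes = codes)
  }
  w <- fit_chain("A")
  cr <- fit_chain("B")
  n <- dim(w$frames)[1]
  if (dim(cr$frames)[1] != n) stop("strand lengths differ; cannot pair")
  # pair chain B residue (n - i + 1) with chain A residue i, flip about x
  crick <- array(NA_real_, c(n, 4, 3))
  for (i in seq_len(n)) {
    f <- matrix(cr$frames[n - i + 1L, , ], 4, 3)
    crick[i, 1, ] <- f[1, ]
    crick[i, 2, ] <- f[2, ]
    crick[i, 3, ] <- -f[3, ]
    crick[i, 4, ] <- -f[4, ]
  }
  list(watson = w$frames, crick = crick,
       sequence = paste(w$codes, collapse = ""))
}

# Optimal rotation R and translation t with obs ~ ref %*% t(R) + t
# (i.e. lab = R %*% template + t), det(R) = +1.
kabsch <- function(ref, obs) {
  cr <- colMeans(ref)
  co <- colMeans(obs)
  H <- t(sweep(ref, 2, cr)) %*% sweep(obs, 2, co)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- co - as.numeric(R %*% cr)
  list(R = R, t = t)
}

#' Compute the 12 rigid base-pair parameters
#'
#' Returns an array of shape (t, n_bp, 12) ordered
#' shear, stretch, stagger, buckle, propeller, opening (intra-base-pair),
#' then shift, slide, rise, tilt, roll, twist (step).  Step slot `i` holds
#' the step from base pair `i` to `i + 1`; for open chains the final step
#' slot is `NA`, for closed chains it holds the wrap step.  Translations in
#' nm, rotations in degrees.
#'
#' Intra parameters are computed from the co-oriented Watson and (flipped)
#' Crick base frames resolved in their mid-frame; when only base-pair
#' frames are available (generated structures) the intra parameters are
#' zero by construction.
#'
#' @param x A `dna_structure`, or an `atomic_model`.
#' @return Numeric array (t, n_bp, 12) with parameter dimnames.
#' @export
compute_rigid_parameters <- function(x) {
  if (inherits(x, "atomic_model")) x <- structure_from_atomic(x)
  stopifnot(inherits(x, "dna_structure"))
  nt <- n_time(x)
  n <- n_bp(x)
  out <- array(NA_real_, c(nt, n, 12),
               dimnames = list(NULL, NULL, PARAM_NAMES))
  for (tt in seq_len(nt)) {
    if (!is.null(x$base_frames)) {
      bf <- x$base_frames
      for (i in seq_len(n)) {
        w <- matrix(bf$watson[i, , ], 4, 3)
        c2 <- matrix(bf$crick[i, , ], 4, 3)
        out[tt, i, 1:6] <- step_from_frames(c2, w)
      }
    } else {
      out[tt, , 1:6] <- 0
    }
    last <- if (x$circular) n else n - 1L
    for (i in seq_len(last)) {
      j <- if (i == n) 1L else i + 1L
      out[tt, i, 7:12] <- step_from_frames(get_frame(x, i, tt),
                                           get_frame(x, j, tt))
    }
  }
  out
}

# Rebuild a dna_structure (base-pair frames + per-base frames) from atoms.
structure_from_atomic <- function(atomic) {
  bf <- fit_base_frames(atomic)
  n <- dim(bf$watson)[1]
  fr <- array(NA_real_, c(1, n, 4, 3))
  for (i in seq_len(n)) {
    fr[1, i, , ] <- midframe(matrix(bf$crick[i, , ], 4, 3),
                             matrix(bf$watson[i, , ], 4, 3))
  }
  st <- dna_structure(bf$sequence, fr,
                      circular = classify_circular(fr))
  st$base_frames <- bf
  st
}

# Twist angles of the ribbon about the base-pair origin polygon.  The
# marker (frame x axis) is projected perpendicular to each polygon segment
# and transported across bends by the minimal rotation between consecutive
# segment directions; the per-joint angle is the residual rotation of the
# marker about the new segment.  With the twist measured about the same
# polygon whose Gauss-sum writhe is computed, the discrete White-Fuller
# relation Lk = Tw + Wr is exact (integer Lk for closed chains).
transport_twist_angles <- function(frames, closed) {
  n <- dim(frames)[1]
  og <- matrix(frames[, 1, ], n, 3)
  nxt <- if (closed) c(2:n, 1L) else 2:n
  e <- og[nxt, , drop = FALSE] - og[if (closed) 1:n else 1:(n - 1L), , drop = FALSE]
  e <- e / sqrt(rowSums(e^2))
  ns <- nrow(e)
  # perpendicular marker on each segment, from the frame x axis at its tail
  u <- matrix(NA_real_, ns, 3)
  for (k in seq_len(ns)) {
    xk <- frames[k, 2, ]
    v <- xk - sum(xk * e[k, ]) * e[k, ]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-8) {  # marker parallel to the segment: fall back to y axis
      xk <- frames[k, 3, ]
      v <- xk - sum(xk * e[k, ]) * e[k, ]
      nv <- sqrt(sum(v^2))
    }
    u[k, ] <- v / nv
  }
  last <- if (closed) ns else ns - 1L
  ang <- numeric(last)
  for (k in seq_len(last)) {
    j <- if (k == ns) 1L else k + 1L
    R <- minimal_rotation(e[k, ], e[j, ])
    ut <- as.numeric(R %*% u[k, ])
    ang[k] <- atan2(sum(cross3(ut, u[j, ]) * e[j, ]), sum(ut * u[j, ])) * RAD2DEG
  }
  ang
}

#' Linking number, twist and writhe of a structure
#'
#' `Tw` is the summed frame twist about the local helical axis (by the
#' parallel-transport decomposition, including the wrap step when closed),
#' `Wr` the Gauss-sum writhe of the base-pair origin polygon, and
#' `Lk = Tw + Wr`.  For a closed chain `Lk` is an integer topological
#' invariant.  For open chains `Tw` is reported and `Wr`/`Lk` require
#' `allow_open = TRUE`.
#'
#' @param x A `dna_structure`.
#' @param frame_index Time frame.
#' @param allow_open Evaluate the open-chain Gauss integral for open
#'   structures.
#' @return List with `Lk`, `Tw`, `Wr`.
#' @export
compute_linking_number <- function(x, frame_index = 1L, allow_open = FALSE) {
  stopifnot(inherits(x, "dna_structure"))
  fr <- array(x$frames[frame_index, , , ], c(n_bp(x), 4, 3))
  tw <- sum(transport_twist_angles(fr, x$circular)) / 360
  if (!x$circular && !allow_open) {
    return(list(Lk = NA_real_, Tw = tw, Wr = NA_real_))
  }
  wr <- compute_writhe(fr[, 1, ], closed = x$circular, allow_open = TRUE)
  list(Lk = tw + wr, Tw = tw, Wr = wr)
}

#' Persistence length from tangent correlations
#'
#' Fits `<z_i . z_(i+m)>`, averaged over positions and time frames, to
#' `exp(-m h / l_p)` with `h` the mean rise, by log-linear least squares
#' restricted to separations `m <= n_bp / 2` with correlations above 0.05
#' (the noise-dominated tail is excluded).  A rigid straight chain returns
#' `Inf`.
#'
#' @param x A `dna_structure` (use multiple time frames for an ensemble).
#' @return Persistence length, nm.
#' @export
persistence_length <- function(x) {
  stopifnot(inherits(x, "dna_structure"))
  n <- n_bp(x)
  if (n < 20) stop("chain too short for a persistence-length estimate")
  nt <- n_time(x)
  mmax <- n %/% 2L
  corr <- numeric(mmax)
  cnt <- numeric(mmax)
  rises <- numeric(0)
  for (tt in seq_len(nt)) {
    z <- matrix(x$frames[tt, , 4, ], n, 3)
    o <- matrix(x$frames[tt, , 1, ], n, 3)
    rises <- c(rises, sqrt(rowSums((o[-1, , drop = FALSE] - o[-n, , drop = FALSE])^2)))
    for (m in seq_len(mmax)) {
      dots <- rowSums(z[1:(n - m), , drop = FALSE] * z[(1 + m):n, , drop = FALSE])
      corr[m] <- corr[m] + sum(dots)
      cnt[m] <- cnt[m] + length(dots)
    }
  }
  corr <- corr / cnt
  h <- mean(rises)
  keep <- which(corr > 0.05)
  if (!length(keep)) stop("tangent correlations decay too fast to fit")
  m <- keep
  lc <- log(corr[keep])
  slope <- sum(m * lc) / sum(m^2)     # through-origin LS of log C vs m
  if (slope >= -1e-12) return(Inf)
  -h / slope
}

#' Total curvature from step parameters
#'
#' Sum over steps of `sqrt(tilt^2 + roll^2)`, per time frame, in degrees.
#'
#' @param params Array from [compute_rigid_parameters()] (or a
#'   `dna_structure`, which is analyzed first).
#' @return Numeric vector, one value per time frame.
#' @export
total_curvature <- function(params) {
  if (inherits(params, "dna_structure")) params <- compute_rigid_parameters(params)
  stopifnot(length(dim(params)) == 3, dim(params)[3] == 12)
  apply(params, 1, function(m)
    sum(sqrt(m[, 10]^2 + m[, 11]^2), na.rm = TRUE))
}
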