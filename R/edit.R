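# Structure editing: mutation, Hoogsteen flips, methylation, extension and
# connection of duplexes.  Edits are pure: they return a modified copy.

check_positions <- function(x, positions) {
  positions <- as.integer(positions)
  if (anyDuplicated(positions)) stop("duplicate positions")
  if (any(positions < 1L) || any(positions > n_bp(x)))
    stop("position out of range 1..", n_bp(x))
  positions
}

#' Mutate bases in a structure
#'
#' Changes nucleobases at the given positions.  With `complementary = TRUE`
#' (default) the paired position on the antisense strand is set to the
#' complement of the new code; otherwise the partner is left untouched
#' (non-complementary pairing).  Frames are unchanged.
#'
#' @param x A `dna_structure`.
#' @param mapping Named list or vector: names are 1-based base-pair indices,
#'   values single-letter codes.
#' @param complementary Keep the antisense strand complementary.
#' @return The edited `dna_structure`.
#' @examples
#' dna <- make(sequence = "ATATAT")
#' mutate(dna, c("1" = "G"))$sequence
#' @export
mutate <- function(x, mapping, complementary = TRUE) {
  stopifnot(inherits(x, "dna_structure"))
  idx <- check_positions(x, as.integer(names(mapping)))
  codes <- toupper(unlist(mapping, use.names = FALSE))
  bad <- which(!codes %in% BASE_ALPHABET)
  if (length(bad)) stop("unknown base code: ", paste(codes[bad], collapse = ", "))
  ch <- sequence_chars(x)
  ach <- rev(strsplit(x$anti_sequence, "")[[1]])  # partner of position i
  ch[idx] <- codes
  if (complementary) ach[idx] <- complement_chars(codes)
  x$sequence <- paste(ch, collapse = "")
  x$anti_sequence <- paste(rev(ach), collapse = "")
  x$methylated[idx] <- FALSE
  x
}

#' Flip bases about the glycosidic bond
#'
#' Rotates the reference-strand nucleobase at each position about its
#' glycosidic bond (C1'-N9 for purines, C1'-N1 for pyrimidines).  The
#' default 180 degrees converts a Watson-Crick-Franklin pair to the
#' Hoogsteen configuration; flipping twice restores the original.  Only the
#' base atoms move; the base-pair frame is unchanged and the pair is tagged
#' as Hoogsteen.
#'
#' @param x A `dna_structure`.
#' @param positions 1-based base-pair indices.
#' @param angle Rotation angle in degrees (default 180).
#' @return The edited `dna_structure`.
#' @export
flip <- function(x, positions, angle = 180) {
  stopifnot(inherits(x, "dna_structure"), is.finite(angle))
  idx <- check_positions(x, positions)
  ch <- sequence_chars(x)
  for (i in idx) {
    if (!has_template(ch[i]))
      stop("no atomic template for base '", ch[i], "' at position ", i)
  }
  x$flip_angle[idx] <- (x$flip_angle[idx] + angle) %% 360
  x$hoogsteen[idx] <- abs(x$flip_angle[idx] - 180) < 1e-9
  x
}

#' Methylate cytosine or guanine bases
#'
#' Adds the methyl carbon at the C5 position of cytosine (5-methylcytosine)
#' or at N7 of guanine.  With `cpg_auto = TRUE` the reference strand is
#' scanned for CpG dinucleotides and the cytosine of each is methylated.
#' Re-methylation is a no-op with a warning.
#'
#' @param x A `dna_structure`.
#' @param positions 1-based indices of C or G bases (exclusive with
#'   `cpg_auto`).
#' @param cpg_auto Automatically methylate cytosines at CpG sites.
#' @return The edited `dna_structure`.
#' @examples
#' dna <- make(sequence = "ACGCGT")
#' which(methylate(dna, cpg_auto = TRUE)$methylated)  # 2 and 4
#' @export
methylate <- function(x, positions = NULL, cpg_auto = FALSE) {
  stopifnot(inherits(x, "dna_structure"))
  if (is.null(positions) == !cpg_auto)
    stop("provide exactly one of positions or cpg_auto")
  ch <- sequence_chars(x)
  if (cpg_auto) {
    idx <- which(ch[-length(ch)] == "C" & ch[-1] == "G")
  } else {
    idx <- check_positions(x, positions)
    notcg <- idx[!ch[idx] %in% c("C", "G")]
    if (length(notcg))
      stop("only C or G can be methylated (offending position(s): ",
           paste(notcg, collapse = ", "), ")")
  }
  already <- idx[x$methylated[idx]]
  if (length(already)) {
    warning("position(s) already methylated: ", paste(already, collapse = ", "))
    idx <- setdiff(idx, already)
  }
  x$methylated[idx] <- TRUE
  x
}

#' Extend a linear structure
#'
#' Appends base pairs beyond the chosen terminus.  The default shape is a
#' straight continuation along the terminal frame's z axis at 0.34 nm rise
#' and the default helical twist; with `control_points` the extension
#' follows a user spline starting at the terminal origin.  The new base
#' pairs plus `margin` terminal base pairs of the original structure are
#' marked free for subsequent minimization; everything else is fixed.
#'
#' @param x A linear `dna_structure`.
#' @param n_bp Number of base pairs to add (exclusive with `sequence`).
#' @param sequence Sequence of the extension, 5'->3'.
#' @param forward Extend beyond the 3' end (default) or the 5' end.
#' @param margin Number of original terminal base pairs also freed.
#' @param control_points Optional shape for the extension.
#' @param frame_index Time frame to extend.
#' @param bp_per_turn Helical repeat for the straight extension.
#' @return The extended `dna_structure`.
#' @export
extend <- function(x, n_bp = NULL, sequence = NULL, forward = TRUE,
                   margin = 1L, control_points = NULL, frame_index = 1L,
                   bp_per_turn = 10.5) {
  stopifnot(inherits(x, "dna_structure"))
  if (x$circular) stop("cannot extend a circular structure")
  if (is.null(n_bp) == is.null(sequence))
    stop("provide exactly one of n_bp or sequence")
  if (is.null(n_bp)) n_bp <- nchar(sequence)
  n_bp <- as.integer(n_bp)
  if (n_bp < 1) stop("extension must add at least one base pair")
  n0 <- dnaforge::n_bp(x)
  if (is.null(sequence))
    sequence <- paste(sample(c("A", "C", "G", "T"), n_bp, replace = TRUE),
                      collapse = "")

  term <- if (forward) get_frame(x, n0, frame_index) else get_frame(x, 1L, frame_index)
  if (is.null(control_points)) {
    new_frames <- straight_continuation(term, n_bp, forward, bp_per_turn)
  } else {
    new_frames <- spline_continuation(term, n_bp, forward, bp_per_turn,
                                      control_points)
  }

  nt <- n_time(x)
  fr <- array(NA_real_, c(nt, n0 + n_bp, 4, 3))
  for (tt in seq_len(nt)) {
    if (forward) {
      fr[tt, 1:n0, , ] <- x$frames[tt, , , ]
      fr[tt, (n0 + 1):(n0 + n_bp), , ] <- new_frames
    } else {
      fr[tt, 1:n_bp, , ] <- new_frames
      fr[tt, (n_bp + 1):(n_bp + n0), , ] <- x$frames[tt, , , ]
    }
  }
  seq_new <- if (forward) paste0(x$sequence, sequence)
             else paste0(sequence, x$sequence)
  out <- dna_structure(seq_new, fr, circular = FALSE)
  out$methylated <- if (forward) c(x$methylated, rep(FALSE, n_bp))
                    else c(rep(FALSE, n_bp), x$methylated)
  out$hoogsteen <- if (forward) c(x$hoogsteen, rep(FALSE, n_bp))
                   else c(rep(FALSE, n_bp), x$hoogsteen)
  out$flip_angle <- if (forward) c(x$flip_angle, rep(0, n_bp))
                    else c(rep(0, n_bp), x$flip_angle)
  margin <- max(0L, as.integer(margin))
  out$free <- if (forward)
    seq.int(max(1L, n0 - margin + 1L), n0 + n_bp)
  else
    seq.int(1L, min(n_bp + margin, n_bp + n0))
  out
}

# ideal straight B-helix continuation beyond a terminal frame
straight_continuation <- function(term, n_add, forward, bp_per_turn) {
  s <- c(0, 0, 0.34, 0, 0, 360 / bp_per_turn)
  out <- array(NA_real_, c(n_add, 4, 3))
  f <- term
  if (forward) {
    for (k in seq_len(n_add)) {
      f <- frames_from_step(f, s)
      out[k, , ] <- f
    }
  } else {
    for (k in seq_len(n_add)) {
      f <- inverse_step_frame(f, s)
      out[n_add - k + 1L, , ] <- f
    }
  }
  out
}

# frame a such that frames_from_step(a, s) = b
inverse_step_frame <- function(b, s) {
  v <- s[4:6] * DEG2RAD
  Rf <- rotation_matrix(v)
  Rh <- rotation_matrix(v / 2)
  tb <- frame_triad(b)
  ta <- Rf %*% tb                  # triad_b = t(Rf) ta  =>  ta = Rf tb
  tm <- t(Rh) %*% ta
  oa <- frame_origin(b) - as.numeric(t(tm) %*% s[1:3])
  rbind(oa, ta, deparse.level = 0)
}

spline_continuation <- function(term, n_add, forward, bp_per_turn, control_points) {
  cp <- as_control_points(control_points)
  path <- fit_spline(cp, closed = FALSE)
  smp <- sample_equidistant(path, n_bp = n_add + 1L)
  pf <- transport_frames(smp, closed = FALSE)
  pf <- apply_twist(pf, bp_per_turn = bp_per_turn)
  # register the first sampled frame onto the terminal frame, then drop it
  f0 <- matrix(pf$frames[1, , ], 4, 3)
  R <- t(frame_triad(term)) %*% frame_triad(f0)   # maps f0 axes onto term axes
  fr <- array(NA_real_, c(n_add, 4, 3))
  for (k in seq_len(n_add)) {
    g <- matrix(pf$frames[k + 1L, , ], 4, 3)
    fr[k, 1, ] <- as.numeric(R %*% (g[1, ] - f0[1, ])) + frame_origin(term)
    fr[k, 2:4, ] <- g[2:4, ] %*% t(R)
  }
  if (!forward) fr <- fr[rev(seq_len(n_add)), , , drop = FALSE]
  fr
}

#' Connect two linear structures with a bridging segment
#'
#' Joins the 3' end of `a` to the 5' end of `b` by interpolating a straight
#' segment between the terminal origins.  When `n_bp` is omitted the bridge
#' length is chosen to give a neutral twist register: candidate counts near
#' `gap / 0.34` are scored by the squared deviation of the net twist
#' required between the fixed terminal frames from the relaxed twist of
#' that many steps, and the smallest minimizer wins.  The bridge plus
#' `margin` base pairs on each side of the two junctions are marked free
#' for minimization.
#'
#' @param a,b Linear `dna_structure` objects.
#' @param n_bp Optional bridge length override.
#' @param sequence Optional bridge sequence (length must match the chosen
#'   bridge length).
#' @param margin Base pairs on each side of the junctions also freed.
#' @param bp_per_turn Helical repeat used for the twist register.
#' @param frame_index Time frame.
#' @return A single `dna_structure` of length `n_bp(a) + bridge + n_bp(b)`,
#'   with attribute `bridge_n` recording the bridge length.
#' @export
connect <- function(a, b, n_bp = NULL, sequence = NULL, margin = 1L,
                    bp_per_turn = 10.5, frame_index = 1L) {
  stopifnot(inherits(a, "dna_structure"), inherits(b, "dna_structure"))
  if (a$circular || b$circular) stop("cannot connect circular structures")
  na <- dnaforge::n_bp(a)
  nb <- dnaforge::n_bp(b)
  fa <- get_frame(a, na, frame_index)   # 3' terminal frame of a
  fb <- get_frame(b, 1L, frame_index)   # 5' terminal frame of b
  gap <- sqrt(sum((frame_origin(fb) - frame_origin(fa))^2))
  if (is.null(n_bp)) {
    if (gap < 0.34)
      stop("termini closer than one step (", round(gap, 3),
           " nm); supply n_bp explicitly")
    n_bp <- optimal_bridge_n(fa, fb, gap, bp_per_turn)
  }
  n_bp <- as.integer(n_bp)
  if (n_bp < 1) stop("bridge must contain at least one base pair")
  if (is.null(sequence))
    sequence <- paste(sample(c("A", "C", "G", "T"), n_bp, replace = TRUE),
                      collapse = "")
  if (nchar(sequence) != n_bp) stop("bridge sequence length must equal n_bp")

  # seed bridge frames on the straight segment with interpolated twist
  dirv <- (frame_origin(fb) - frame_origin(fa)) / gap
  fr_bridge <- array(NA_real_, c(n_bp, 4, 3))
  vrot <- rotation_vector(frame_triad(fa), frame_triad(fb), degrees = FALSE)
  for (k in seq_len(n_bp)) {
    u <- k / (n_bp + 1)
    tri <- t(rotation_matrix(vrot * u)) %*% frame_triad(fa)
    fr_bridge[k, 1, ] <- frame_origin(fa) + u * gap * dirv
    fr_bridge[k, 2:4, ] <- orthonormalize_triad(tri)
  }

  nt <- min(n_time(a), n_time(b))
  ntot <- na + n_bp + nb
  fr <- array(NA_real_, c(1, ntot, 4, 3))
  fr[1, 1:na, , ] <- a$frames[frame_index, , , ]
  fr[1, (na + 1):(na + n_bp), , ] <- fr_bridge
  fr[1, (na + n_bp + 1):ntot, , ] <- b$frames[frame_index, , , ]
  out <- dna_structure(paste0(a$sequence, sequence, b$sequence), fr,
                       circular = FALSE)
  out$methylated <- c(a$methylated, rep(FALSE, n_bp), b$methylated)
  out$hoogsteen <- c(a$hoogsteen, rep(FALSE, n_bp), b$hoogsteen)
  out$flip_angle <- c(a$flip_angle, rep(0, n_bp), b$flip_angle)
  margin <- max(0L, as.integer(margin))
  out$free <- seq.int(max(1L, na - margin + 1L), min(ntot, na + n_bp + margin))
  attr(out, "bridge_n") <- n_bp
  out
}

# Choose the bridge length by brute force over candidates near gap/0.34:
# with n bridge base pairs there are n + 1 steps between the fixed terminal
# frames; the required net twist (principal twist between the terminal
# triads plus whole turns) should sit closest to the relaxed twist
# (n + 1) * 360 / bp_per_turn.  Ties break to the smaller n.
optimal_bridge_n <- function(fa, fb, gap, bp_per_turn) {
  vrot <- rotation_vector(frame_triad(fa), frame_triad(fb))
  psi <- vrot[3]                       # principal twist component, degrees
  n0 <- gap / 0.34
  cand <- seq.int(max(2L, floor(n0) - 5L), ceiling(n0) + 5L)
  pen <- vapply(cand, function(n) {
    target <- (n + 1) * 360 / bp_per_turn
    k <- round((target - psi) / 360)
    (psi + 360 * k - target)^2
  }, 0)
  cand[which.min(pen)]
}
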