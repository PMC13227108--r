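# The central container: a double-stranded DNA structure as a sequence plus
# an ordered grid of base-pair reference frames per time frame.

#' Construct a DNA structure object
#'
#' @param sequence Reference-strand sequence, 5'->3', over the code alphabet.
#' @param frames Array of base-pair frames, shape (t, n_bp, 4, 3): per base
#'   pair the origin (nm) followed by the x, y, z triad rows.
#' @param circular Logical topology flag.
#' @param dLk Integer linking-number difference imposed at generation, or
#'   `NA`.
#' @return An object of class `dna_structure` with fields `sequence`,
#'   `anti_sequence`, `frames`, `circular`, `dLk`, `methylated`,
#'   `hoogsteen`, `free` (indices free to move in minimization, or NULL for
#'   all).
#' @export
dna_structure <- function(sequence, frames, circular = FALSE, dLk = NA) {
  if (length(dim(frames)) == 3) {
    frames <- array(frames, c(1, dim(frames)))
  }
  stopifnot(length(dim(frames)) == 4, dim(frames)[3] == 4, dim(frames)[4] == 3)
  n_bp <- dim(frames)[2]
  if (nchar(sequence) != n_bp)
    stop("sequence length (", nchar(sequence), ") does not match n_bp (", n_bp, ")")
  ch <- strsplit(sequence, "")[[1]]
  bad <- which(!ch %in% BASE_ALPHABET)
  if (length(bad))
    stop("unknown base code at position(s) ", paste(bad, collapse = ", "))
  structure(list(sequence = sequence,
                 anti_sequence = complement(sequence),
                 frames = frames,
                 circular = isTRUE(circular),
                 dLk = dLk,
                 methylated = rep(FALSE, n_bp),
                 hoogsteen = rep(FALSE, n_bp),
                 flip_angle = rep(0, n_bp),
                 free = NULL,
                 base_frames = NULL),
            class = "dna_structure")
}

#' @export
print.dna_structure <- function(x, ...) {
  cat(sprintf("<dna_structure> %d bp, %d time frame(s), %s%s\n",
              n_bp(x), n_time(x),
              if (x$circular) "circular" else "linear",
              if (!is.na(x$dLk) && x$dLk != 0) sprintf(", dLk = %+d", x$dLk) else ""))
  s <- x$sequence
  cat("  5'-", if (nchar(s) > 60) paste0(substr(s, 1, 57), "...") else s, "-3'\n",
      sep = "")
  invisible(x)
}

#' Number of base pairs / time frames in a structure
#' @param x A `dna_structure`.
#' @return Integer count.
#' @export
n_bp <- function(x) dim(x$frames)[2]

#' @rdname n_bp
#' @export
n_time <- function(x) dim(x$frames)[1]

# 4 x 3 frame matrix of base pair i at time t
get_frame <- function(x, i, t = 1L) {
  matrix(x$frames[t, i, , ], 4, 3)
}

set_frame <- function(x, i, f, t = 1L) {
  x$frames[t, i, , ] <- f
  x
}

# n_bp x 3 matrix of origins at time t
origins <- function(x, t = 1L) {
  matrix(x$frames[t, , 1, ], ncol = 3)
}

sequence_chars <- function(x) strsplit(x$sequence, "")[[1]]

#' Classify a frame set as circular by end proximity
#'
#' A structure is classified circular when the origins of the first and last
#' base pairs are closer than 1 nm and the chain has more than 20 base
#' pairs; the length requirement guards short fragments with coincidentally
#' close ends.  An explicit user flag always overrides the rule.
#'
#' @param frames (t, n_bp, 4, 3) array, (n_bp, 4, 3) array, or a
#'   `dna_structure`.
#' @param n_bp Base-pair count (inferred when omitted).
#' @return Logical.
#' @export
classify_circular <- function(frames, n_bp = NULL) {
  if (inherits(frames, "dna_structure")) frames <- frames$frames
  if (length(dim(frames)) == 3) frames <- array(frames, c(1, dim(frames)))
  if (is.null(n_bp)) n_bp <- dim(frames)[2]
  if (n_bp < 1) stop("need at least one base pair")
  d <- sqrt(sum((frames[1, 1, 1, ] - frames[1, n_bp, 1, ])^2))
  (d < 1.0) && (n_bp > 20)
}

#' Generate a DNA structure from sequence and/or shape
#'
#' At least one of `sequence`, `n_bp`, `control_points` must be given.
#' Missing sequence: random over A, C, G, T (requires `seed`).  Missing
#' shape: a straight line along +z, or - when `circular` and no control
#' points - a planar circle of circumference `n_bp * 0.34` nm.  The shape
#' pipeline is spline fit, equidistant sampling at 0.34 nm, parallel
#' transport, then helical twisting at `bp_per_turn` with the requested
#' linking-number difference imposed through the White-Fuller relation.
#'
#' @param sequence Optional sequence string.
#' @param n_bp Optional base-pair count.
#' @param control_points Optional >= 4 control points (matrix or file path),
#'   nm.
#' @param circular Closed topology flag.
#' @param dLk Integer linking-number difference (closed only).
#' @param bp_per_turn Helical repeat, default 10.5 bp/turn.
#' @param spacing Base-pair spacing along the path, nm.
#' @param seed RNG seed for a random sequence.
#' @return A `dna_structure` with a single time frame.
#' @examples
#' dna <- make(sequence = strrep("AT", 10))
#' dna
#' @export
make <- function(sequence = NULL, n_bp = NULL, control_points = NULL,
                 circular = FALSE, dLk = 0, bp_per_turn = 10.5,
                 spacing = 0.34, seed = NULL) {
  if (is.null(sequence) && is.null(n_bp) && is.null(control_points))
    stop("provide at least one of sequence, n_bp, control_points")
  if (!is.null(sequence) && !is.null(n_bp) && nchar(sequence) != n_bp)
    stop("sequence length and n_bp disagree")
  if (!circular && !identical(dLk, 0) && !isTRUE(all.equal(dLk, 0))) {
    warning("dLk is ignored for linear structures")
    dLk <- 0
  }
  if (is.null(n_bp) && !is.null(sequence)) n_bp <- nchar(sequence)

  if (is.null(control_points)) {
    if (is.null(n_bp)) stop("n_bp or sequence required without control points")
    if (circular) {
      r <- n_bp * spacing / (2 * pi)
      th <- seq(0, 2 * pi, length.out = 13)[-13]
      control_points <- cbind(r * cos(th), r * sin(th), 0)
    } else {
      L <- (n_bp - 1) * spacing
      control_points <- cbind(0, 0, seq(0, max(L, spacing), length.out = 8))
    }
  }
  path <- fit_spline(control_points, closed = circular)
  smp <- sample_equidistant(path, spacing = spacing, n_bp = n_bp)
  pf <- transport_frames(smp, closed = circular)
  pf <- apply_twist(pf, bp_per_turn = bp_per_turn, dLk = dLk)
  n <- dim(pf$frames)[1]

  if (is.null(sequence)) {
    if (!is.null(seed)) set.seed(seed)
    sequence <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                      collapse = "")
  } else if (nchar(sequence) != n) {
    stop("sequence length ", nchar(sequence),
         " does not match sampled base-pair count ", n)
  }
  st <- dna_structure(sequence, pf$frames, circular = circular,
                      dLk = if (circular) round(dLk) else NA)
  st
}

#' Build an atomic model from a structure
#'
#' Places the idealized base templates rigidly on the base-pair frames: the
#' sense-strand residue by the frame itself and the antisense residue
#' (the complement) by the frame composed with a 180-degree rotation about
#' its x axis, the standard complementary-strand flip.  Flipped (Hoogsteen)
#' and methylated bases are honored.
#'
#' @param x A `dna_structure`.
#' @param frame_index Time frame to materialize (1-based).
#' @return An `atomic_model`: data frame of atoms with columns `name`,
#'   `element`, `resname`, `resid`, `chain`, `x`, `y`, `z` (nm) plus the
#'   structure's sequence as attribute.
#' @export
to_atomic <- function(x, frame_index = 1L) {
  stopifnot(inherits(x, "dna_structure"))
  ch <- sequence_chars(x)
  n <- n_bp(x)
  rows <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    f <- get_frame(x, i, frame_index)
    rows[[i]] <- place_residue(ch[i], f, flip_anti = FALSE,
                               resid = i, chain = "A",
                               methylated = x$methylated[i],
                               flip_angle = x$flip_angle[i])
  }
  anti <- complement_chars(ch)
  for (i in seq_len(n)) {
    f <- get_frame(x, i, frame_index)
    # chain B residue numbering runs 5'->3' on the antisense strand
    rows[[n + (n - i + 1L)]] <- place_residue(anti[i], f, flip_anti = TRUE,
                                              resid = n - i + 1L, chain = "B",
                                              methylated = FALSE,
                                              flip_angle = 0)
  }
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  structure(atoms, class = c("atomic_model", "data.frame"),
            sequence = x$sequence, circular = x$circular)
}

place_residue <- function(code, frame, flip_anti, resid, chain,
                          methylated = FALSE, flip_angle = 0) {
  tpl <- base_template(code)
  pos <- tpl$atoms
  nm <- rownames(pos)
  if (methylated) {
    ma <- methyl_atom(tpl)
    pos <- rbind(pos, ma$pos)
    nm <- c(nm, ma$name)
  }
  if (abs(flip_angle %% 360) > 1e-12) {
    pos <- rotate_base_about_glycosidic(pos, nm, tpl, flip_angle)
  }
  tr <- frame[2:4, , drop = FALSE]
  if (flip_anti) {
    # 180-degree rotation about the frame x axis: y and z rows negate
    tr <- rbind(tr[1, ], -tr[2, ], -tr[3, ], deparse.level = 0)
  }
  lab <- sweep(pos %*% tr, 2, frame[1, ], `+`)   # t(A %*% t(pos)) = pos %*% triad
  resname <- if (methylated && code %in% names(METHYL_RESNAME))
    METHYL_RESNAME[[code]]
  else if (code %in% names(RESNAME_MAP)) RESNAME_MAP[[code]]
  else paste0("X", code, "X")
  data.frame(name = nm,
             element = substr(nm, 1, 1),
             resname = resname,
             resid = resid,
             chain = chain,
             x = lab[, 1], y = lab[, 2], z = lab[, 3],
             stringsAsFactors = FALSE)
}

# Position of the added methyl carbon: cytosine C5-methyl (5-methylcytosine)
# extends the ring plane along the centroid->C5 direction at 0.15 nm;
# guanine is methylated at N7 in the same in-plane construction.
methyl_atom <- function(tpl) {
  site <- if (tpl$code %in% PURINE_CODES) "N7" else "C5"
  ring <- tpl$atoms[tpl$ring_atoms, , drop = FALSE]
  ctr <- colMeans(ring)
  v <- tpl$atoms[site, ] - ctr
  v <- v / sqrt(sum(v^2))
  list(name = if (site == "C5") "C5M" else "C7M",
       pos = tpl$atoms[site, ] + 0.15 * v)
}

rotate_base_about_glycosidic <- function(pos, nm, tpl, angle) {
  p1 <- pos[match(tpl$glycosidic_atoms[1], nm), ]
  p2 <- pos[match(tpl$glycosidic_atoms[2], nm), ]
  axis <- p2 - p1
  base_idx <- which(nm != tpl$glycosidic_atoms[1])  # rotate base, keep C1'
  pos[base_idx, ] <- rotate_points_about_axis(pos[base_idx, , drop = FALSE],
                                              p1, axis, angle)
  pos
}
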