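# Readers and writers: the frame-array text format (bit-exact round trips),
# PDB input/output (via bio3d for reading), parameter CSV, and deterministic
# test fixtures.

#' Write base-pair frames as text
#'
#' One line per base pair carrying 12 floats (`%.9f`): origin then the x, y,
#' z triad rows, in nm.  Time frames are separated by blank lines.  A header
#' comment records the sequence and the circular flag, so the file alone
#' reconstructs the structure.
#'
#' @param x A `dna_structure`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_frames <- function(x, path) {
  stopifnot(inherits(x, "dna_structure"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sequence=%s circular=%s", x$sequence,
                     if (x$circular) "true" else "false"), con)
  nt <- n_time(x)
  n <- n_bp(x)
  for (tt in seq_len(nt)) {
    for (i in seq_len(n)) {
      f <- get_frame(x, i, tt)
      writeLines(paste(sprintf("%.9f", as.numeric(t(f))), collapse = " "), con)
    }
    if (tt < nt) writeLines("", con)
  }
  invisible(path)
}

#' Load a structure from frames
#'
#' Accepts either a path to a frame-array text file written by
#' [write_frames()] or a numeric array of shape (t, n_bp, 4, 3) plus a
#' sequence.  Validates the shape, the triad orthonormality (tolerance
#' 1e-6, with automatic re-orthonormalization up to 1e-3) and the sequence
#' length, then applies the circular classification rule to the first time
#' frame (an explicit `circular` overrides it).
#'
#' @param x File path or (t, n_bp, 4, 3) array (also accepts (n_bp, 4, 3)).
#' @param sequence Sequence string (required for array input; overrides the
#'   file header when given).
#' @param circular Optional explicit topology flag.
#' @return A `dna_structure`.
#' @export
load_frames <- function(x, sequence = NULL, circular = NULL) {
  if (is.character(x) && length(x) == 1) {
    parsed <- read_frame_file(x)
    arr <- parsed$frames
    if (is.null(sequence)) sequence <- parsed$sequence
    if (is.null(circular)) circular <- parsed$circular
  } else {
    arr <- x
  }
  if (length(dim(arr)) == 3) arr <- array(arr, c(1, dim(arr)))
  if (length(dim(arr)) != 4 || dim(arr)[3] != 4 || dim(arr)[4] != 3)
    stop("frame array must have shape (t, n_bp, 4, 3)")
  if (is.null(sequence)) stop("a sequence is required")
  if (nchar(sequence) != dim(arr)[2])
    stop("sequence length ", nchar(sequence), " does not match n_bp ", dim(arr)[2])
  for (tt in seq_len(dim(arr)[1])) {
    for (i in seq_len(dim(arr)[2])) {
      tr <- matrix(arr[tt, i, 2:4, ], 3, 3)
      dev <- max(abs(tr %*% t(tr) - diag(3)))
      if (dev > 1e-3)
        stop("non-orthonormal triad at time ", tt, ", base pair ", i,
             " (deviation ", signif(dev, 3), ")")
      if (dev > 1e-6) arr[tt, i, 2:4, ] <- orthonormalize_triad(tr)
    }
  }
  circ <- if (is.null(circular)) classify_circular(arr) else isTRUE(circular)
  if (is.null(circular))
    message("topology auto-classified as ", if (circ) "circular" else "linear")
  dna_structure(sequence, arr, circular = circ)
}

read_frame_file <- function(path) {
  ln <- readLines(path, warn = FALSE)
  seqv <- NULL
  circ <- NULL
  hdr <- grep("^#", ln, value = TRUE)
  if (length(hdr)) {
    m <- regmatches(hdr[1], regexec("sequence=([A-Za-z]+)", hdr[1]))[[1]]
    if (length(m) == 2) seqv <- m[2]
    m <- regmatches(hdr[1], regexec("circular=(true|false)", hdr[1]))[[1]]
    if (length(m) == 2) circ <- identical(m[2], "true")
  }
  ln <- ln[!grepl("^#", ln)]
  blocks <- split(ln, cumsum(ln == ""))
  blocks <- lapply(blocks, function(b) b[nzchar(b)])
  blocks <- blocks[lengths(blocks) > 0]
  nt <- length(blocks)
  n <- length(blocks[[1]])
  arr <- array(NA_real_, c(nt, n, 4, 3))
  for (tt in seq_len(nt)) {
    if (length(blocks[[tt]]) != n) stop("inconsistent base-pair counts across time frames")
    vals <- lapply(strsplit(trimws(blocks[[tt]]), "[[:space:]]+"), as.numeric)
    if (!all(lengths(vals) == 12)) stop("each frame line must hold 12 numbers")
    for (i in seq_len(n)) arr[tt, i, , ] <- matrix(vals[[i]], 4, 3, byrow = TRUE)
  }
  list(frames = arr, sequence = seqv, circular = circ)
}

#' Write an atomic model (or structure) to PDB
#'
#' Coordinates are converted from the internal nm to the PDB-standard
#' Angstrom at the boundary.  Chains A (sense) and B (antisense), residues
#' numbered from 1 per chain.  A `dna_structure` with several time frames
#' produces a multi-model PDB.
#'
#' @param x An `atomic_model` or a `dna_structure`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  models <- if (inherits(x, "atomic_model")) list(x)
            else lapply(seq_len(n_time(x)), function(tt) to_atomic(x, tt))
  multi <- length(models) > 1
  for (mm in seq_along(models)) {
    if (multi) writeLines(sprintf("MODEL     %4d", mm), con)
    at <- models[[mm]]
    serial <- 0L
    prev_chain <- at$chain[1]
    for (k in seq_len(nrow(at))) {
      if (at$chain[k] != prev_chain) {
        serial <- serial + 1L
        writeLines(sprintf("TER   %5d      %3s %1s%4d",
                           serial, at$resname[k - 1], prev_chain,
                           at$resid[k - 1]), con)
        prev_chain <- at$chain[k]
      }
      serial <- serial + 1L
      nm <- at$name[k]
      nmfmt <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
      writeLines(sprintf("ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                         serial, nmfmt, at$resname[k], at$chain[k], at$resid[k],
                         at$x[k] * 10, at$y[k] * 10, at$z[k] * 10, 1.0, 0.0,
                         at$element[k]), con)
    }
    writeLines(sprintf("TER   %5d      %3s %1s%4d",
                       serial + 1L, at$resname[nrow(at)], at$chain[nrow(at)],
                       at$resid[nrow(at)]), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Load a DNA structure from a PDB file
#'
#' Reads the file with bio3d, maps residues to base templates, fits base
#' frames per model by rigid superposition, and pairs the strands by index
#' complementarity.  Multi-model PDBs become trajectories (t > 1).
#'
#' @param path PDB file.
#' @param chains Optional length-2 chain IDs (sense, antisense); required
#'   when the file holds more than two nucleic chains.
#' @return A `dna_structure` (with fitted per-base frames for the first
#'   model attached).
#' @export
load_structure_file <- function(path, chains = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading PDB files requires the bio3d package")
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  known <- c("DA", "DT", "DG", "DC", "DU", "5CM", "7MG", "A", "T", "G", "C", "U")
  nuc <- at[at$resid %in% known, , drop = FALSE]
  if (!nrow(nuc)) stop("no recognizable nucleic residues in ", path)
  ch_ids <- unique(nuc$chain)
  if (is.null(chains)) {
    if (length(ch_ids) != 2)
      stop("found ", length(ch_ids), " nucleic chains; specify `chains`")
    chains <- ch_ids
  }
  nmodels <- nrow(pdb$xyz)
  frames_list <- vector("list", nmodels)
  seqv <- NULL
  for (mm in seq_len(nmodels)) {
    xyz <- matrix(pdb$xyz[mm, ], ncol = 3, byrow = TRUE)
    df <- data.frame(name = at$elety,
                     element = substr(at$elety, 1, 1),
                     resname = at$resid,
                     resid = at$resno,
                     chain = ifelse(at$chain == chains[1], "A",
                                    ifelse(at$chain == chains[2], "B", "?")),
                     x = xyz[, 1] / 10, y = xyz[, 2] / 10, z = xyz[, 3] / 10,
                     stringsAsFactors = FALSE)
    df <- df[df$chain %in% c("A", "B") & df$resname %in% known, , drop = FALSE]
    bf <- fit_base_frames(df)
    n <- dim(bf$watson)[1]
    fr1 <- array(NA_real_, c(n, 4, 3))
    for (i in seq_len(n))
      fr1[i, , ] <- midframe(matrix(bf$crick[i, , ], 4, 3),
                             matrix(bf$watson[i, , ], 4, 3))
    frames_list[[mm]] <- fr1
    if (mm == 1) { seqv <- bf$sequence; bf1 <- bf }
  }
  n <- dim(frames_list[[1]])[1]
  arr <- array(NA_real_, c(nmodels, n, 4, 3))
  for (mm in seq_len(nmodels)) arr[mm, , , ] <- frames_list[[mm]]
  st <- dna_structure(seqv, arr, circular = classify_circular(arr))
  st$base_frames <- bf1
  st
}

#' Write rigid parameters as CSV
#'
#' One row per time frame and base pair with the 12 named parameter
#' columns.
#'
#' @param params Array from [compute_rigid_parameters()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_parameters_csv <- function(params, path) {
  nt <- dim(params)[1]
  n <- dim(params)[2]
  df <- do.call(rbind, lapply(seq_len(nt), function(tt) {
    d <- as.data.frame(matrix(params[tt, , ], n, 12))
    names(d) <- PARAM_NAMES
    cbind(time = tt, bp = seq_len(n), d)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Generate deterministic test fixtures
#'
#' Emits, for the requested kind, a PDB file, a frame-array text file and a
#' CSV of the expected rigid parameters into `dir`.  `noisy-trajectory`
#' adds seeded Gaussian frame noise (sigma 0.01 nm on origins).
#'
#' @param kind One of `linear`, `circle`, `supercoiled`, `noisy-trajectory`.
#' @param n_bp Base-pair count.
#' @param seed RNG seed.
#' @param dir Output directory.
#' @return Named list of file paths.
#' @export
make_fixture <- function(kind = c("linear", "circle", "supercoiled",
                                  "noisy-trajectory"),
                         n_bp = 80, seed = 1, dir = tempdir()) {
  kind <- match.arg(kind)
  set.seed(seed)
  st <- switch(kind,
    linear = make(n_bp = n_bp, seed = seed),
    circle = make(n_bp = n_bp, circular = TRUE, seed = seed),
    supercoiled = make(n_bp = n_bp, circular = TRUE, dLk = 3, seed = seed),
    `noisy-trajectory` = {
      base <- make(n_bp = n_bp, seed = seed)
      nt <- 5L
      arr <- array(NA_real_, c(nt, n_bp, 4, 3))
      for (tt in seq_len(nt)) {
        arr[tt, , , ] <- base$frames[1, , , ]
        arr[tt, , 1, ] <- arr[tt, , 1, ] + stats::rnorm(n_bp * 3, 0, 0.01)
      }
      dna_structure(base$sequence, arr, circular = FALSE)
    })
  stem <- file.path(dir, paste0("fixture-", kind, "-", n_bp))
  paths <- list(pdb = paste0(stem, ".pdb"),
                frames = paste0(stem, ".frames.txt"),
                params = paste0(stem, ".params.csv"))
  write_pdb(st, paths$pdb)
  write_frames(st, paths$frames)
  write_parameters_csv(compute_rigid_parameters(st), paths$params)
  paths
}
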