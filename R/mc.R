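# Metropolis Monte Carlo relaxation of base-pair frame chains under a
# quadratic rigid-base-step elastic energy with hard-sphere excluded volume.
#
# Moves: crankshaft rotations of interior frame blocks about the axis
# joining two chain points (topology-safe for closed chains) and, for open
# chains, terminal step perturbations that rigidly carry the outer segment.
# The hard wall is applied as outright rejection, which together with a
# bounded per-move displacement prevents chain passage and so conserves the
# linking number of closed chains.

#' Elastic model for base-pair steps
#'
#' Quadratic energy about an equilibrium step, in kT at 300 K.  The default
#' stiffness is diagonal: tilt/roll from a bending persistence length of
#' 50 nm and twist from a torsional persistence length of 100 nm (converted
#' at the 0.34 nm rise), translations stiff (sigma ~ 0.01 nm).
#'
#' @param equilibrium_step Step 6-vector (shift, slide, rise nm; tilt, roll,
#'   twist degrees).
#' @param stiffness 6 x 6 symmetric positive-semidefinite matrix, kT units
#'   per nm^2 / deg^2.
#' @param lp_bend Bending persistence length, nm (used when `stiffness` is
#'   omitted).
#' @param lp_twist Torsional persistence length, nm.
#' @param sigma_translation Translational fluctuation scale, nm.
#' @return An `elastic_model` list.
#' @export
elastic_model <- function(equilibrium_step = c(0, 0, 0.34, 0, 0, 360 / 10.5),
                          stiffness = NULL,
                          lp_bend = 50, lp_twist = 100,
                          sigma_translation = 0.01) {
  h <- equilibrium_step[3]
  if (is.null(stiffness)) {
    k_bend  <- (lp_bend / h) * (pi / 180)^2    # kT per deg^2
    k_twist <- (lp_twist / h) * (pi / 180)^2
    k_tr <- 1 / sigma_translation^2            # kT per nm^2
    stiffness <- diag(c(k_tr, k_tr, k_tr, k_bend, k_bend, k_twist))
  }
  stiffness <- as.matrix(stiffness)
  stopifnot(all(dim(stiffness) == c(6, 6)))
  if (max(abs(stiffness - t(stiffness))) > 1e-9)
    stop("stiffness must be symmetric")
  ev <- eigen(stiffness, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-9) stop("stiffness must be positive semidefinite")
  structure(list(equilibrium_step = equilibrium_step, stiffness = stiffness),
            class = "elastic_model")
}

#' Monte Carlo configuration
#'
#' @param seed RNG seed (required: runs are deterministic given seed).
#' @param temperature Kelvin; the energy scale is kT at 300 K, so Metropolis
#'   acceptance uses `exp(-dE * 300 / temperature)`.
#' @param ev_diameter Hard-sphere diameter on base-pair origins, nm.
#' @param ev_min_separation Chain separation (steps) beyond which the
#'   excluded-volume check applies; closer pairs are exempt so local helical
#'   stacking is never self-rejecting.
#' @param fixed_indices 1-based base-pair indices whose frames never move.
#' @param max_sweeps Sweep budget (one sweep ~ n_bp attempted moves).
#' @param crank_amplitude Maximum crankshaft rotation, degrees.
#' @param step_amplitude Scale of terminal step perturbations (fraction of
#'   thermal sd).
#' @param trace_writhe Record the writhe per sweep (closed chains).
#' @param record_steps Record the first step's 6-vector once per sweep
#'   (used e.g. for equipartition checks).
#' @return An `mc_config` list.
#' @export
mc_config <- function(seed, temperature = 300, ev_diameter = 2.0,
                      ev_min_separation = 5L, fixed_indices = integer(0),
                      max_sweeps = 200L, crank_amplitude = 30,
                      step_amplitude = 1.0, trace_writhe = NULL,
                      record_steps = FALSE) {
  if (missing(seed) || is.null(seed)) stop("an RNG seed is required")
  stopifnot(crank_amplitude > 0, step_amplitude > 0, temperature > 0)
  structure(list(seed = as.integer(seed), temperature = temperature,
                 ev_diameter = ev_diameter,
                 ev_min_separation = as.integer(ev_min_separation),
                 fixed_indices = as.integer(fixed_indices),
                 max_sweeps = as.integer(max_sweeps),
                 crank_amplitude = crank_amplitude,
                 step_amplitude = step_amplitude,
                 trace_writhe = trace_writhe,
                 record_steps = isTRUE(record_steps)),
            class = "mc_config")
}

#' Elastic energy of a structure
#'
#' `E = 1/2 sum_steps (x - x0)' K (x - x0)` in kT, where `x` are the step
#' parameters of consecutive base-pair frames; closed structures include the
#' wrap step.  Returns `Inf` when the excluded-volume constraint is violated
#' (the hard-wall sentinel).
#'
#' @param x A `dna_structure`.
#' @param model An `elastic_model`.
#' @param config Optional `mc_config` supplying the excluded-volume check.
#' @param frame_index Time frame.
#' @return Energy in kT.
#' @export
elastic_energy <- function(x, model, config = NULL, frame_index = 1L) {
  if (n_bp(x) < 2) stop("need at least 2 base pairs")
  if (!is.null(config) &&
      !excluded_volume_ok(origins(x, frame_index), config, circular = x$circular))
    return(Inf)
  steps <- structure_steps(x, frame_index)
  dx <- sweep(steps, 2, model$equilibrium_step)
  0.5 * sum((dx %*% model$stiffness) * dx)
}

# all step 6-vectors of a structure (rows), including the wrap step if closed
structure_steps <- function(x, frame_index = 1L) {
  n <- n_bp(x)
  idx <- if (x$circular) cbind(1:n, c(2:n, 1)) else cbind(1:(n - 1), 2:n)
  t(apply(idx, 1, function(ij)
    step_from_frames(get_frame(x, ij[1], frame_index),
                     get_frame(x, ij[2], frame_index))))
}

#' Hard-sphere excluded-volume check
#'
#' `TRUE` iff every pair of base-pair origins more than `ev_min_separation`
#' steps apart along the chain (circularly for closed chains) is at distance
#' >= `ev_diameter`.
#'
#' @param origins n x 3 matrix, nm.
#' @param config An `mc_config`.
#' @param circular Measure chain separation circularly.
#' @return Logical.
#' @export
excluded_volume_ok <- function(origins, config, circular = FALSE) {
  n <- nrow(origins)
  msep <- config$ev_min_separation
  d2min <- config$ev_diameter^2
  for (i in seq_len(n - 1L)) {
    js <- seq.int(i + 1L, n)
    sep <- js - i
    if (circular) sep <- pmin(sep, n - sep)
    js <- js[sep > msep]
    if (!length(js)) next
    di <- sweep(origins[js, , drop = FALSE], 2, origins[i, ])
    if (any(rowSums(di^2) < d2min)) return(FALSE)
  }
  TRUE
}

# excluded-volume check of a moved subset against the rest and itself
ev_ok_subset <- function(og, moved, config, circular) {
  n <- nrow(og)
  msep <- config$ev_min_separation
  d2min <- config$ev_diameter^2
  others <- setdiff(seq_len(n), moved)
  for (i in moved) {
    sep <- abs(others - i)
    if (circular) sep <- pmin(sep, n - sep)
    js <- others[sep > msep]
    if (length(js)) {
      di <- sweep(og[js, , drop = FALSE], 2, og[i, ])
      if (any(rowSums(di^2) < d2min)) return(FALSE)
    }
  }
  TRUE
}

#' Metropolis Monte Carlo relaxation
#'
#' Relaxes a structure toward the elastic equilibrium while honoring fixed
#' indices and, for closed chains, conserving the linking number through
#' the hard-sphere wall.  Only canonical-base structures can be minimized.
#'
#' @param x A `dna_structure` (canonical bases only).
#' @param model An `elastic_model`.
#' @param config An `mc_config`.
#' @param frame_index Time frame to relax.
#' @return A `minimization_result`: `structure`, `energy_trace` (kT per
#'   sweep), `writhe_trace` (closed chains), `tau`, `converged`,
#'   `acceptance_rate`.
#' @export
minimize <- function(x, model = elastic_model(), config, frame_index = 1L) {
  stopifnot(inherits(x, "dna_structure"), inherits(config, "mc_config"))
  if (!all(sequence_chars(x) %in% c("A", "C", "G", "T", "U")))
    stop("non-canonical bases are incompatible with MC minimization")
  n <- n_bp(x)
  circular <- x$circular
  fixed <- sort(unique(config$fixed_indices))
  if (!is.null(x$free)) fixed <- sort(unique(c(fixed, setdiff(seq_len(n), x$free))))
  movable <- setdiff(seq_len(n), fixed)
  if (!length(movable)) stop("no movable base pairs")
  trace_wr <- if (is.null(config$trace_writhe)) circular else config$trace_writhe

  set.seed(config$seed)
  beta <- 300 / config$temperature
  K <- model$stiffness
  x0 <- model$equilibrium_step

  # working copies: frames as an (n, 4, 3) array for the chosen time frame
  fr <- array(x$frames[frame_index, , , ], c(n, 4, 3))
  step_of <- function(i, j)
    step_from_frames(matrix(fr[i, , ], 4, 3), matrix(fr[j, , ], 4, 3))
  step_energy <- function(s) { d <- s - x0; 0.5 * sum(d * (K %*% d)) }

  # cache per-step energies
  nsteps <- if (circular) n else n - 1L
  step_idx <- cbind(seq_len(nsteps), if (circular) c(2:n, 1) else 2:n)
  e_steps <- vapply(seq_len(nsteps),
                    function(k) step_energy(step_of(step_idx[k, 1], step_idx[k, 2])),
                    0)
  if (!excluded_volume_ok(fr[, 1, ], config, circular = circular))
    warning("initial structure violates the excluded-volume constraint")

  # thermal sd for terminal step proposals
  sd6 <- config$step_amplitude / sqrt(pmax(diag(K), 1e-12) * beta)

  energy_trace <- numeric(0)
  writhe_trace <- numeric(0)
  step_trace <- if (config$record_steps)
    matrix(NA_real_, config$max_sweeps, 6,
           dimnames = list(NULL, c("shift", "slide", "rise", "tilt", "roll", "twist")))
  else NULL
  accepted <- 0L
  attempted <- 0L
  is_fixed <- rep(FALSE, n); is_fixed[fixed] <- TRUE

  for (sweep in seq_len(config$max_sweeps)) {
    for (mv in seq_len(n)) {
      attempted <- attempted + 1L
      p_term <- if (!circular) { if (n < 3L) 1 else 0.5 } else 0
      if (p_term > 0 && stats::runif(1) < p_term) {
        res <- try_pivot(fr, n, sd6, is_fixed)
        if (is.null(res)) next
        k <- res$step_k
        e_new <- step_energy(step_of2(res$fr, step_idx[k, 1], step_idx[k, 2]))
        dE <- e_new - e_steps[k]
        if (!ev_ok_subset(res$fr[, 1, ], res$moved, config, circular)) next
        if (dE <= 0 || stats::runif(1) < exp(-beta * dE)) {
          fr <- res$fr
          e_steps[k] <- e_new
          accepted <- accepted + 1L
        }
      } else {
        res <- try_crankshaft(fr, n, circular, config$crank_amplitude, is_fixed)
        if (is.null(res)) next
        ks <- res$steps_changed
        e_new <- vapply(ks, function(k)
          step_energy(step_of2(res$fr, step_idx[k, 1], step_idx[k, 2])), 0)
        dE <- sum(e_new) - sum(e_steps[ks])
        if (!ev_ok_subset(res$fr[, 1, ], res$moved, config, circular)) next
        if (dE <= 0 || stats::runif(1) < exp(-beta * dE)) {
          fr <- res$fr
          e_steps[ks] <- e_new
          accepted <- accepted + 1L
        }
      }
    }
    if (sweep %% 10L == 0L) {
      # control floating-point drift from chained rigid maps
      for (i in seq_len(n)) fr[i, 2:4, ] <- orthonormalize_triad(fr[i, 2:4, ])
      e_steps <- vapply(seq_len(nsteps),
                        function(k) step_energy(step_of2(fr, step_idx[k, 1],
                                                         step_idx[k, 2])),
                        0)
    }
    if (config$record_steps)
      step_trace[sweep, ] <- step_of2(fr, step_idx[1, 1], step_idx[1, 2])
    energy_trace <- c(energy_trace, sum(e_steps))
    if (trace_wr)
      writhe_trace <- c(writhe_trace, compute_writhe(fr[, 1, ], closed = circular,
                                                     allow_open = TRUE))
  }

  # re-orthonormalize accumulated drift before returning
  for (i in seq_len(n)) fr[i, 2:4, ] <- orthonormalize_triad(fr[i, 2:4, ])
  out <- x
  out$frames[frame_index, , , ] <- fr
  fit <- if (length(energy_trace) >= 20) fit_convergence(energy_trace)
         else list(tau = NA_real_, converged = FALSE)
  structure(list(structure = out,
                 energy_trace = energy_trace,
                 writhe_trace = if (trace_wr) writhe_trace else NULL,
                 tau = fit$tau, converged = fit$converged,
                 acceptance_rate = accepted / max(1L, attempted),
                 step_trace = step_trace),
            class = "minimization_result")
}

step_of2 <- function(fr, i, j)
  step_from_frames(matrix(fr[i, , ], 4, 3), matrix(fr[j, , ], 4, 3))

# Crankshaft: rotate the frames strictly between chain points i and j about
# the axis joining their origins.  Returns NULL when the move is impossible
# or touches fixed indices.
try_crankshaft <- function(fr, n, circular, amplitude, is_fixed) {
  if (circular) {
    i <- sample.int(n, 1)
    len <- sample.int(max(2L, n %/% 2L), 1) + 1L   # block span >= 2 steps
    j <- ((i - 1L + len) %% n) + 1L
    inner <- (seq.int(i + 1L, i + len - 1L) - 1L) %% n + 1L
  } else {
    if (n < 3) return(NULL)
    i <- sample.int(n - 2L, 1)
    j <- i + 1L + sample.int(n - i - 1L, 1)
    inner <- seq.int(i + 1L, j - 1L)
  }
  if (!length(inner)) return(NULL)
  if (any(is_fixed[inner])) return(NULL)
  axis <- fr[j, 1, ] - fr[i, 1, ]
  a2 <- sum(axis^2)
  if (a2 < 1e-12) return(NULL)
  axis <- axis / sqrt(a2)
  # cap the rotation so no bead is displaced by more than ev_guard nm in a
  # single move: together with the hard wall this forbids chain passage
  og_in <- matrix(fr[inner, 1, ], length(inner), 3)
  rel <- sweep(og_in, 2, fr[i, 1, ])
  perp2 <- rowSums(rel^2) - (rel %*% axis)^2
  r_max <- sqrt(max(perp2, 0))
  ev_guard <- 1.0
  cap <- if (r_max > 1e-9) 2 * asin(min(1, ev_guard / (2 * r_max))) * RAD2DEG
         else amplitude
  amp <- min(amplitude, cap)
  ang <- stats::runif(1, -amp, amp)
  R <- rotation_matrix(axis * ang * DEG2RAD)
  piv <- fr[i, 1, ]
  m <- length(inner)
  og <- matrix(fr[inner, 1, ], m, 3)
  fr[inner, 1, ] <- sweep(sweep(og, 2, piv) %*% t(R), 2, piv, `+`)
  tri <- matrix(array(fr[inner, 2:4, ], c(m, 3, 3)), m * 3L, 3L)
  fr[inner, 2:4, ] <- array(tri %*% t(R), c(m, 3, 3))
  ks <- if (circular) c(i, ((j - 2L) %% n) + 1L) else c(i, j - 1L)
  list(fr = fr, moved = inner, steps_changed = ks)
}

# Pivot move (open chains): redraw one step 6-vector from a Gaussian
# proposal about its current value and rigidly carry the outer segment
# (toward the nearer of the two ends chosen at random).  Changes exactly
# one step, so bends and twists anywhere along an open chain relax
# directly; rejected outright when the moved segment contains fixed
# indices.
try_pivot <- function(fr, n, sd6, is_fixed) {
  k <- sample.int(n - 1L, 1)
  tail_side <- stats::runif(1) < 0.5
  moved <- if (tail_side) seq.int(k + 1L, n) else seq.int(1L, k)
  if (any(is_fixed[moved])) return(NULL)
  a <- matrix(fr[k, , ], 4, 3)
  b <- matrix(fr[k + 1L, , ], 4, 3)
  if (tail_side) {
    s <- step_from_frames(a, b)
    s_new <- s + stats::rnorm(6, 0, sd6)
    if (sqrt(sum(s_new[4:6]^2)) >= 179) return(NULL)
    new_anchor <- frames_from_step(a, s_new)
    old_anchor <- b
  } else {
    s <- step_from_frames(b, a)
    s_new <- s + stats::rnorm(6, 0, sd6)
    if (sqrt(sum(s_new[4:6]^2)) >= 179) return(NULL)
    new_anchor <- frames_from_step(b, s_new)
    old_anchor <- a
  }
  # rigid map carrying the old anchor frame onto the new one; the anchor
  # triads are re-orthonormalized first so the map is orthogonal to machine
  # precision (otherwise anchor drift would compound exponentially through
  # successive segment transforms)
  R <- t(orthonormalize_triad(new_anchor[2:4, ])) %*%
    orthonormalize_triad(old_anchor[2:4, ])
  anchor_idx <- if (tail_side) k + 1L else k
  rest <- setdiff(moved, anchor_idx)
  fr[anchor_idx, , ] <- new_anchor
  if (length(rest)) {
    m <- length(rest)
    og <- matrix(fr[rest, 1, ], m, 3)
    fr[rest, 1, ] <- sweep(sweep(og, 2, old_anchor[1, ]) %*% t(R), 2,
                           new_anchor[1, ], `+`)
    tri <- matrix(array(fr[rest, 2:4, ], c(m, 3, 3)), m * 3L, 3L)
    fr[rest, 2:4, ] <- array(tri %*% t(R), c(m, 3, 3))
  }
  list(fr = fr, moved = moved, step_k = k)
}

#' Fit an exponential decay to a relaxation trace
#'
#' Least-squares fit of `f(t) = c + a * exp(-t / tau)`.  A run is converged
#' when the trace is at least five decay times long and the fitted plateau
#' is stable between the two halves of the trace (relative change < 5%);
#' near-constant traces converge trivially with `tau ~ 0`.
#'
#' @param trace Numeric vector of per-sweep values (>= 20 points).
#' @return List with `tau` (sweeps) and `converged`.
#' @export
fit_convergence <- function(trace) {
  if (any(!is.finite(trace))) stop("non-finite trace values")
  if (length(trace) < 20) stop("need at least 20 trace points")
  t <- seq_along(trace) - 1
  rng <- diff(range(trace))
  scale <- max(abs(trace), 1e-12)
  if (rng < 1e-8 * scale)
    return(list(tau = 0, converged = TRUE))
  fit1 <- fit_exp_decay(t, trace)
  if (is.null(fit1)) return(list(tau = Inf, converged = FALSE))
  tau <- fit1$tau
  noise_sd <- sqrt(fit1$rss / length(trace))   # residual scatter of the fit
  half <- length(trace) %/% 2
  fa <- fit_exp_decay(t[1:half], trace[1:half])
  fb <- fit_exp_decay(t[(half + 1):length(trace)], trace[(half + 1):length(trace)])
  plateau_stable <- !is.null(fa) && !is.null(fb) &&
    abs(fb$c - fa$c) <= max(0.05 * max(abs(fa$c), abs(fb$c), 0.05 * rng),
                            2.5 * noise_sd)
  tail_n <- max(4L, length(trace) %/% 5L)
  tail_vals <- trace[(length(trace) - tail_n + 1):length(trace)]
  tail_flat <- diff(range(tail_vals)) <= 0.25 * rng
  converged <- is.finite(tau) && length(trace) >= 5 * tau &&
    plateau_stable && tail_flat
  list(tau = tau, converged = converged)
}

# grid-search + linear least squares for c + a exp(-t/tau)
fit_exp_decay <- function(t, y) {
  n <- length(t)
  if (n < 6) return(NULL)
  span <- max(t) - min(t)
  taus <- exp(seq(log(span / 200), log(span * 10), length.out = 60))
  best <- NULL
  for (tau in taus) {
    e <- exp(-(t - t[1]) / tau)
    X <- cbind(1, e)
    cf <- tryCatch(qr.solve(X, y), error = function(e) NULL)
    if (is.null(cf)) next
    r <- sum((y - X %*% cf)^2)
    if (is.null(best) || r < best$rss)
      best <- list(tau = tau, c = cf[1], a = cf[2], rss = r)
  }
  if (is.null(best)) return(NULL)
  # refine tau locally by golden-section on the profiled RSS
  f <- function(tau) {
    e <- exp(-(t - t[1]) / tau)
    X <- cbind(1, e)
    cf <- qr.solve(X, y)
    sum((y - X %*% cf)^2)
  }
  opt <- stats::optimize(f, c(best$tau / 3, best$tau * 3))
  tau <- opt$minimum
  e <- exp(-(t - t[1]) / tau)
  cf <- qr.solve(cbind(1, e), y)
  list(tau = tau, c = cf[1], a = cf[2], rss = opt$objective)
}

#' Sample structures directly from the elastic model
#'
#' Draws independent Gaussian step vectors about the equilibrium step with
#' covariance `K^-1 kT` and chains them into frames - the thermal ensemble
#' of the rigid-base-step model, used e.g. for persistence-length
#' estimation.
#'
#' @param model An `elastic_model`.
#' @param n_bp Base pairs per sample.
#' @param n_samples Number of conformations.
#' @param seed RNG seed.
#' @param temperature Kelvin (scales the covariance by T/300).
#' @return A `dna_structure` with `n_samples` time frames and a random
#'   canonical sequence.
#' @export
sample_ensemble <- function(model, n_bp, n_samples = 100, seed, temperature = 300) {
  if (missing(seed)) stop("an RNG seed is required")
  set.seed(seed)
  K <- model$stiffness
  x0 <- model$equilibrium_step
  # covariance (T/300) K^-1 via eigendecomposition (supports semidefinite K)
  eg <- eigen(K, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  amp <- ifelse(lam > 1e-12, sqrt((temperature / 300) / lam), 0)
  L <- eg$vectors %*% diag(amp)
  fr <- array(NA_real_, c(n_samples, n_bp, 4, 3))
  f0 <- new_frame()
  for (s in seq_len(n_samples)) {
    f <- f0
    fr[s, 1, , ] <- f
    z <- matrix(stats::rnorm(6 * (n_bp - 1)), 6)
    steps <- x0 + L %*% z
    for (i in 2:n_bp) {
      f <- frames_from_step(f, steps[, i - 1])
      if (i %% 128L == 0L) f[2:4, ] <- orthonormalize_triad(f[2:4, ])
      fr[s, i, , ] <- f
    }
  }
  sq <- paste(sample(c("A", "C", "G", "T"), n_bp, replace = TRUE), collapse = "")
  dna_structure(sq, fr, circular = FALSE)
}
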