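test_that("elastic energy is zero at equilibrium and quadratic away from it", {
  dna <- suppressMessages(make(n_bp = 30, seed = 2))
  em <- elastic_model()
  expect_lt(elastic_energy(dna, em), 1e-12)

  # single step with twist at equilibrium + 10 degrees, diagonal K
  k_twist <- em$stiffness[6, 6]
  arr <- array(NA_real_, c(1, 2, 4, 3))
  arr[1, 1, , ] <- new_frame()
  arr[1, 2, , ] <- frames_from_step(new_frame(), c(0, 0, 0.34, 0, 0, 360 / 10.5 + 10))
  two <- dna_structure("AT", arr)
  expect_equal(elastic_energy(two, em), 0.5 * k_twist * 100, tolerance = 1e-9)

  # rigid-body invariance
  R <- rotation_matrix(c(0.4, -0.2, 1.1))
  fr <- dna$frames
  for (i in seq_len(30)) {
    fr[1, i, 1, ] <- as.numeric(R %*% fr[1, i, 1, ]) + c(3, 1, -2)
    fr[1, i, 2:4, ] <- fr[1, i, 2:4, ] %*% t(R)
  }
  moved <- dna_structure(dna$sequence, fr)
  expect_lt(abs(elastic_energy(moved, em) - elastic_energy(dna, em)), 1e-9)
})

test_that("excluded volume exempts local neighbors and flags distant contacts", {
  dna <- suppressMessages(make(n_bp = 60, seed = 2))
  cfg <- mc_config(seed = 1)
  # straight B-DNA: every checked pair (separation > 5) is > 2 nm apart
  expect_true(excluded_volume_ok(dnaforge:::origins(dna), cfg))

  og <- dnaforge:::origins(dna)
  og[40, ] <- og[20, ] + c(1.9, 0, 0)   # separation 20, distance 1.9 < 2.0
  expect_false(excluded_volume_ok(og, cfg))

  # widely spaced beads: bringing chain neighbors (separation <= 5) to
  # contact stays allowed
  og2 <- cbind(0, 0, seq(0, 21, by = 3))      # 8 beads, 3 nm apart
  og2[5, ] <- og2[4, ] + c(0, 0, 1.5)         # separation 1: exempt
  expect_true(excluded_volume_ok(og2, cfg))
  og3 <- cbind(0, 0, seq(0, 21, by = 3))
  og3[7, ] <- og3[1, ] + c(1.9, 0, 0)         # separation 6: checked
  expect_false(excluded_volume_ok(og3, cfg))
})

test_that("minimization honors fixed endpoints and converges on relaxed input", {
  dna <- suppressMessages(make(n_bp = 30, seed = 3))
  cfg <- mc_config(seed = 5, max_sweeps = 25, fixed_indices = c(1L, 30L),
                   temperature = 1, crank_amplitude = 0.05,
                   step_amplitude = 0.001)
  res <- minimize(dna, config = cfg)
  expect_equal(res$structure$frames[1, 1, , ], dna$frames[1, 1, , ])
  expect_equal(res$structure$frames[1, 30, , ], dna$frames[1, 30, , ])
  # essentially a fixed point: the trace stays at a tiny fraction of the
  # ~90 kT thermal energy of this chain at 300 K, and frames barely move
  expect_true(all(res$energy_trace < 0.05))
  expect_lt(max(abs(res$structure$frames - dna$frames)), 0.01)

  hg <- flip(dna, 3)
  hg <- mutate(hg, c("2" = "B"))
  expect_error(minimize(hg, config = cfg), "non-canonical")
})

test_that("single free step samples the equipartition variances", {
  arr <- array(NA_real_, c(1, 2, 4, 3))
  arr[1, 1, , ] <- new_frame()
  arr[1, 2, , ] <- frames_from_step(new_frame(), c(0, 0, 0.34, 0, 0, 360 / 10.5))
  two <- dna_structure("AT", arr)
  em <- elastic_model()
  # no hard wall; both terminal moves perturb the same (only) step
  nsweep <- 200000L
  cfg <- mc_config(seed = 8, max_sweeps = nsweep, ev_diameter = 0,
                   step_amplitude = 1.0, record_steps = TRUE)
  res <- minimize(two, em, cfg)
  expect_gt(res$acceptance_rate * nsweep * 2, 1e5)  # >= 1e5 accepted moves
  v_target <- 1 / diag(em$stiffness)                 # K^-1 kT, diagonal K
  v_got <- apply(res$step_trace, 2, stats::var)
  expect_true(all(abs(v_got - v_target) / v_target < 0.1))
  # and the mean stays at the equilibrium step
  expect_lt(max(abs(colMeans(res$step_trace) - em$equilibrium_step) /
                  sqrt(v_target)), 0.05)
})

test_that("minimization is deterministic for a fixed seed", {
  dna <- suppressMessages(make(n_bp = 70, circular = TRUE, dLk = 2, seed = 4))
  cfg <- mc_config(seed = 11, max_sweeps = 10)
  r1 <- minimize(dna, config = cfg)
  r2 <- minimize(dna, config = cfg)
  expect_identical(r1$structure$frames, r2$structure$frames)
  expect_identical(r1$energy_trace, r2$energy_trace)
})

test_that("closed-chain minimization conserves the linking number", {
  for (dlk in c(0, 3, 6)) {
    dna <- suppressMessages(make(n_bp = 70, circular = TRUE, dLk = dlk, seed = 4))
    lk0 <- compute_linking_number(dna)$Lk
    for (seed in c(1, 2)) {
      res <- minimize(dna, config = mc_config(seed = seed, max_sweeps = 15))
      lk1 <- compute_linking_number(res$structure)$Lk
      expect_equal(lk1, lk0, tolerance = 1e-6,
                   label = sprintf("Lk after MC (dLk %d seed %d)", dlk, seed))
    }
  }
})

test_that("energy relaxes from a strained start", {
  # straight duplex with two 20-degree roll kinks
  n <- 40
  arr <- array(NA_real_, c(1, n, 4, 3))
  f <- new_frame()
  arr[1, 1, , ] <- f
  for (i in 2:n) {
    s <- c(0, 0, 0.34, 0, if (i %in% c(14, 28)) 20 else 0, 360 / 10.5)
    f <- frames_from_step(f, s)
    arr[1, i, , ] <- f
  }
  dna <- dna_structure(strrep("A", n), arr)
  res <- minimize(dna, config = mc_config(seed = 3, max_sweeps = 80,
                                          temperature = 10))
  nt <- length(res$energy_trace)
  first <- stats::median(res$energy_trace[1:(nt %/% 10)])
  last <- stats::median(res$energy_trace[(nt - nt %/% 10):nt])
  expect_lte(last, first)
})

test_that("exponential convergence fitting recovers known decays", {
  t <- 0:500
  tr <- 10 * exp(-t / 50) + 2
  fit <- fit_convergence(tr)
  expect_equal(fit$tau, 50, tolerance = 0.05)
  expect_true(fit$converged)

  cst <- fit_convergence(rep(3.3, 40))
  expect_equal(cst$tau, 0)
  expect_true(cst$converged)

  ramp <- fit_convergence(seq(0, 10, length.out = 60))
  expect_false(ramp$converged)

  expect_error(fit_convergence(c(rep(1, 30), NA)), "non-finite")
  expect_error(fit_convergence(1:10), "at least 20")
})
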