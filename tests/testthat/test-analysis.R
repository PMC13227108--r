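test_that("base-frame fitting recovers frames exactly, under noise, and equivariantly", {
  dna <- suppressMessages(make(n_bp = 12, seed = 13))
  at <- to_atomic(dna)
  gen <- array(dna$frames[1, , , ], c(12, 4, 3))
  bf <- fit_base_frames(at)
  expect_lt(max(abs(bf$watson - gen)), 1e-6)

  # 0.01 nm Gaussian coordinate noise: origins recovered within 0.02 nm
  set.seed(17)
  noisy <- at
  noisy$x <- noisy$x + stats::rnorm(nrow(at), 0, 0.01)
  noisy$y <- noisy$y + stats::rnorm(nrow(at), 0, 0.01)
  noisy$z <- noisy$z + stats::rnorm(nrow(at), 0, 0.01)
  bfn <- fit_base_frames(noisy)
  err3d <- sqrt(rowSums((bfn$watson[, 1, ] - gen[, 1, ])^2))
  expect_lt(sqrt(mean(err3d^2)), 0.02)   # ring-fit noise amplification bound
  expect_lt(max(err3d), 0.05)

  # rigid-body equivariance
  R <- rotation_matrix(c(0.2, 0.9, -0.5))
  shift <- c(4, -7, 2)
  rot <- at
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
  rot$x <- xyz[, 1] + shift[1]
  rot$y <- xyz[, 2] + shift[2]
  rot$z <- xyz[, 3] + shift[3]
  bfr <- fit_base_frames(rot)
  for (i in 1:12) {
    expect_lt(max(abs(bfr$watson[i, 1, ] -
                        (as.numeric(R %*% gen[i, 1, ]) + shift))), 1e-9)
    expect_lt(max(abs(bfr$watson[i, 2:4, ] - gen[i, 2:4, ] %*% t(R))), 1e-9)
  }

  bad <- at[!(at$resid == 3 & at$chain == "A" & at$name == "N3"), ]
  class(bad) <- class(at)
  expect_error(fit_base_frames(bad), "missing ring atoms")
})

test_that("rigid parameters reproduce a prescribed step sequence", {
  set.seed(19)
  n <- 25
  steps <- cbind(stats::rnorm(n - 1, 0, 0.05),
                 stats::rnorm(n - 1, 0, 0.05),
                 stats::rnorm(n - 1, 0.34, 0.02),
                 stats::rnorm(n - 1, 0, 4),
                 stats::rnorm(n - 1, 0, 4),
                 stats::rnorm(n - 1, 34.3, 3))
  arr <- array(NA_real_, c(1, n, 4, 3))
  f <- new_frame()
  arr[1, 1, , ] <- f
  for (i in 2:n) {
    f <- frames_from_step(f, steps[i - 1, ])
    arr[1, i, , ] <- f
  }
  st <- dna_structure(strrep("A", n), arr)
  p <- compute_rigid_parameters(st)
  expect_equal(dim(p), c(1, n, 12))
  expect_lt(max(abs(p[1, 1:(n - 1), 7:12] - steps)), 1e-8)
  expect_true(all(p[1, , 1:6] == 0))
})

test_that("parameter arrays carry one slice per trajectory frame", {
  base <- suppressMessages(make(n_bp = 21, seed = 23))
  nt <- 4
  arr <- array(NA_real_, c(nt, 21, 4, 3))
  for (tt in seq_len(nt)) arr[tt, , , ] <- base$frames[1, , , ]
  st <- dna_structure(base$sequence, arr)
  p <- compute_rigid_parameters(st)
  expect_equal(dim(p)[1], nt)
  expect_equal(dim(p)[3], 12)
})

test_that("linking numbers obey White-Fuller and chirality", {
  circ <- suppressMessages(make(n_bp = 210, circular = TRUE, seed = 2))
  lk <- compute_linking_number(circ)
  expect_equal(lk$Lk, 20, tolerance = 1e-6)
  expect_lt(abs(lk$Wr), 1e-6)

  mini <- suppressMessages(make(n_bp = 200, circular = TRUE, dLk = 6, seed = 2))
  relaxed <- round(200 / 10.5)
  expect_equal(compute_linking_number(mini)$Lk - relaxed, 6, tolerance = 1e-6)
  res <- minimize(mini, config = mc_config(seed = 31, max_sweeps = 12))
  expect_equal(compute_linking_number(res$structure)$Lk - relaxed, 6,
               tolerance = 1e-6)

  # mirror image negates Tw, Wr and Lk
  fr <- circ$frames
  fr[1, , , 3] <- -fr[1, , , 3]      # reflect z; triads become left-handed,
  fr[1, , 3, ] <- -fr[1, , 3, ]      # restore handedness by flipping y
  mir <- dna_structure(circ$sequence, fr, circular = TRUE)
  lkm <- compute_linking_number(mir)
  expect_equal(lkm$Lk, -lk$Lk, tolerance = 1e-6)
  expect_equal(lkm$Tw, -lk$Tw, tolerance = 1e-6)

  lin <- suppressMessages(make(n_bp = 30, seed = 2))
  open <- compute_linking_number(lin)
  expect_true(is.na(open$Lk))
  # 29 segments -> 28 interior joints of the segment-framed ribbon
  expect_equal(open$Tw, 28 * (360 / 10.5) / 360, tolerance = 1e-6)
})

test_that("persistence length is recovered from model ensembles", {
  # rigid straight duplex: infinite persistence length
  stiffd <- suppressMessages(make(n_bp = 40, seed = 3))
  expect_equal(persistence_length(stiffd), Inf)

  em <- elastic_model(lp_bend = 50)
  ens <- sample_ensemble(em, n_bp = 300, n_samples = 200, seed = 41)
  lp <- persistence_length(ens)
  expect_lt(abs(lp - 50) / 50, 0.15)

  # deterministic arc: correlation cos(m * theta) -> analytic lp
  n <- 60
  theta <- 2        # degrees of pure roll per step
  arr <- array(NA_real_, c(1, n, 4, 3))
  f <- new_frame()
  arr[1, 1, , ] <- f
  for (i in 2:n) {
    f <- frames_from_step(f, c(0, 0, 0.34, 0, theta, 0))
    arr[1, i, , ] <- f
  }
  arc <- dna_structure(strrep("A", n), arr)
  lp_arc <- persistence_length(arc)
  # log cos(m*theta) ~ -(m h / lp): fitted lp is finite and deterministic
  expect_true(is.finite(lp_arc))
  lp2 <- persistence_length(arc)
  expect_identical(lp_arc, lp2)

  expect_error(persistence_length(suppressMessages(make(n_bp = 10, seed = 1))),
               "too short")
})

test_that("total curvature sums step bend magnitudes", {
  lin <- suppressMessages(make(n_bp = 30, seed = 5))
  expect_lt(total_curvature(lin), 1e-6)

  # planar circle from pure-roll steps of theta: total = n * theta
  n <- 72
  theta <- 5
  arr <- array(NA_real_, c(1, n, 4, 3))
  f <- new_frame()
  arr[1, 1, , ] <- f
  for (i in 2:n) {
    f <- frames_from_step(f, c(0, 0, 0.34, 0, theta, 0))
    arr[1, i, , ] <- f
  }
  ringish <- dna_structure(strrep("A", n), arr)
  expect_equal(total_curvature(ringish), (n - 1) * theta, tolerance = 1e-9)

  # oracle: sum of bend angles between consecutive z axes (small-bend regime)
  dna <- suppressMessages(make(n_bp = 100, circular = TRUE, seed = 5))
  tc <- total_curvature(dna)
  z <- matrix(dna$frames[1, , 4, ], 100, 3)
  bends <- acos(pmin(1, rowSums(z * z[c(2:100, 1), ]))) * 180 / pi
  expect_lt(abs(tc - sum(bends)) / sum(bends), 0.02)
})
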