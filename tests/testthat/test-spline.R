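test_that("spline fitting interpolates and measures arc length", {
  # straight line: 4 collinear points 1 nm apart
  cp <- cbind(0, 0, 0:3)
  p <- fit_spline(cp)
  expect_equal(p$length, 3, tolerance = 1e-8)
  tg <- spline_tangent(p, seq(0, p$tmax, length.out = 7))
  expect_true(all(abs(sweep(tg, 2, c(0, 0, 1))) < 1e-9))

  # closed circle: arc length 2*pi*R
  R <- 5
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  circ <- fit_spline(cbind(R * cos(th), R * sin(th), 0), closed = TRUE)
  expect_equal(circ$length, 2 * pi * R, tolerance = 1e-3 * 2 * pi * R)

  expect_error(fit_spline(cbind(0, 0, 0:2)), "four control points")
  expect_error(fit_spline(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))),
               "degenerate")
})

test_that("equidistant sampling spaces origins uniformly in arc length", {
  # straight 3.4 nm path at default spacing: 11 origins, gaps 0.34
  p <- fit_spline(cbind(0, 0, seq(0, 3.4, length.out = 5)))
  s <- sample_equidistant(p)
  expect_equal(nrow(s$origins), 11)
  gaps <- sqrt(rowSums(diff(s$origins)^2))
  expect_true(all(abs(gaps - 0.34) < 1e-6))

  # closed circle with n_bp given: closing gap equals internal gaps
  th <- seq(0, 2 * pi, length.out = 17)[-17]
  R <- 200 * 0.34 / (2 * pi)
  circ <- fit_spline(cbind(R * cos(th), R * sin(th), 0), closed = TRUE)
  sc <- suppressMessages(sample_equidistant(circ, n_bp = 200))
  og <- sc$origins
  allgaps <- sqrt(rowSums((og[c(2:200, 1), ] - og)^2))
  expect_lt(diff(range(allgaps)), 1e-6)

  # wiggly open path: arc-length separations all equal
  set.seed(5)
  cp <- cbind(seq(0, 9, length.out = 10), sin(1:10), cos(seq(1, 5, length.out = 10)))
  pw <- fit_spline(cp)
  sw <- suppressMessages(sample_equidistant(pw, n_bp = 40))
  # measure separations along the curve via fine polyline
  tt <- seq(0, pw$tmax, length.out = 20001)
  fine <- spline_point(pw, tt)
  arc <- c(0, cumsum(sqrt(rowSums(diff(fine)^2))))
  idx <- vapply(seq_len(40), function(i)
    which.min(rowSums(sweep(fine, 2, sw$origins[i, ])^2)), 0L)
  seps <- diff(arc[idx])
  expect_lt(diff(range(seps)), 2e-3)  # limited by the fine-polyline lookup

  expect_error(sample_equidistant(p, n_bp = 1), "at least 2")
  expect_error(sample_equidistant(p, spacing = 10), "exceeds")
})

test_that("parallel transport carries frames without intrinsic twist", {
  # straight line: all triads identical
  p <- fit_spline(cbind(0, 0, seq(0, 3.4, length.out = 5)))
  pf <- transport_frames(sample_equidistant(p))
  n <- dim(pf$frames)[1]
  for (i in 2:n)
    expect_lt(max(abs(pf$frames[i, 2:4, ] - pf$frames[1, 2:4, ])), 1e-9)

  # planar closed circle: holonomy of the transported frame is zero
  th <- seq(0, 2 * pi, length.out = 25)[-25]
  circ <- fit_spline(cbind(10 * cos(th), 10 * sin(th), 0), closed = TRUE)
  pfc <- transport_frames(suppressMessages(sample_equidistant(circ, n_bp = 120)))
  f1 <- matrix(pfc$frames[1, , ], 4, 3)
  fn <- matrix(pfc$frames[120, , ], 4, 3)
  R <- minimal_rotation(fn[4, ], f1[4, ])
  xt <- as.numeric(R %*% fn[2, ])
  mismatch <- atan2(sum(cross3(xt, f1[2, ]) * f1[4, ]), sum(xt * f1[2, ])) * 180 / pi
  expect_lt(abs(mismatch), 1e-6)

  # helical path: zero per-step rotation about the local z before twisting
  s <- seq(0, 4 * pi, length.out = 30)
  hel <- fit_spline(cbind(2 * cos(s), 2 * sin(s), 0.5 * s))
  pfh <- transport_frames(suppressMessages(sample_equidistant(hel, n_bp = 50)))
  for (i in 1:49) {
    a <- matrix(pfh$frames[i, , ], 4, 3)
    b <- matrix(pfh$frames[i + 1, , ], 4, 3)
    R <- minimal_rotation(a[4, ], b[4, ])
    xt <- as.numeric(R %*% a[2, ])
    tw <- atan2(sum(cross3(xt, b[2, ]) * b[4, ]), sum(xt * b[2, ])) * 180 / pi
    expect_lt(abs(tw), 1e-6)
  }
})

test_that("discrete writhe matches geometry and chirality expectations", {
  th <- seq(0, 2 * pi, length.out = 201)[-201]
  ring <- cbind(cos(th), sin(th), 0) * 10
  expect_lt(abs(compute_writhe(ring, closed = TRUE)), 1e-10)

  # trefoil projection vs dense quadrature oracle
  sv <- seq(0, 2 * pi, length.out = 241)[-241]
  tref <- t(vapply(sv, trefoil_curve, numeric(3)))
  wr <- compute_writhe(tref, closed = TRUE)
  wr_oracle <- writhe_quadrature_oracle(trefoil_curve, n = 2400)
  expect_lt(abs(wr - wr_oracle), 1e-3)

  # mirror image negates writhe
  mir <- tref
  mir[, 3] <- -mir[, 3]
  expect_equal(compute_writhe(mir, closed = TRUE), -wr, tolerance = 1e-10)

  expect_error(compute_writhe(ring, closed = FALSE), "allow_open")
})

test_that("apply_twist imposes the helical repeat and the White-Fuller twist", {
  # open 22 bp at default repeat: per-step z rotation 360/10.5
  p <- fit_spline(cbind(0, 0, seq(0, 0.34 * 21, length.out = 6)))
  pf <- apply_twist(transport_frames(sample_equidistant(p, n_bp = 22)))
  for (i in 1:21) {
    s <- step_from_frames(matrix(pf$frames[i, , ], 4, 3),
                          matrix(pf$frames[i + 1, , ], 4, 3))
    expect_equal(unname(s["twist"]), 360 / 10.5, tolerance = 1e-9)
  }

  # planar 210 bp circle, dLk = 0: per-step twist 360 * 20 / 210
  th <- seq(0, 2 * pi, length.out = 25)[-25]
  R210 <- 210 * 0.34 / (2 * pi)
  circ <- fit_spline(cbind(R210 * cos(th), R210 * sin(th), 0), closed = TRUE)
  pfc <- suppressMessages(
    apply_twist(transport_frames(sample_equidistant(circ, n_bp = 210))))
  expect_equal(pfc$twist_per_step, 360 * 20 / 210, tolerance = 1e-6)

  # planar 200 bp circle, dLk = 6: linking number Tw0 + 6
  dna <- suppressMessages(make(n_bp = 200, circular = TRUE, dLk = 6))
  lk <- compute_linking_number(dna)
  expect_equal(lk$Lk, round(200 / 10.5) + 6, tolerance = 1e-6)

  expect_error(suppressMessages(apply_twist(pfc, dLk = 0.5)), "integer")
  expect_error(apply_twist(pf, bp_per_turn = -1), "positive")
})

test_that("White-Fuller closure holds across shapes and dLk values", {
  th <- seq(0, 2 * pi, length.out = 25)[-25]
  shapes <- list(
    circle = cbind(12 * cos(th), 12 * sin(th), 0),
    ellipse = cbind(16 * cos(th), 9 * sin(th), 0),
    saddle = cbind(12 * cos(th), 12 * sin(th), 2.5 * cos(2 * th))
  )
  for (nm in names(shapes)) {
    for (dlk in c(-3, 0, 6)) {
      dna <- suppressMessages(
        make(n_bp = 150, circular = TRUE, dLk = dlk,
             control_points = shapes[[nm]]))
      lk <- compute_linking_number(dna)
      expect_equal(lk$Lk, lk$Tw + lk$Wr, tolerance = 1e-9)
      expect_equal(lk$Lk, round(150 / 10.5) + dlk, tolerance = 1e-6,
                   label = paste("Lk for", nm, "dLk", dlk))
    }
  }
})

test_that("mirroring control points negates writhe, preserves twist magnitude", {
  th <- seq(0, 2 * pi, length.out = 25)[-25]
  cp <- cbind(12 * cos(th), 12 * sin(th), 2.5 * cos(2 * th))
  a <- suppressMessages(make(n_bp = 150, circular = TRUE, control_points = cp))
  cp2 <- cp
  cp2[, 3] <- -cp2[, 3]
  b <- suppressMessages(make(n_bp = 150, circular = TRUE, control_points = cp2))
  la <- compute_linking_number(a)
  lb <- compute_linking_number(b)
  expect_equal(lb$Wr, -la$Wr, tolerance = 1e-6)
})
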