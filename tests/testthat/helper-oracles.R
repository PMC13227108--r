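# Shared generators and independent oracles used across the suite.

# random right-handed orthonormal triad (rows x, y, z)
random_triad <- function() {
  repeat {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                  2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                  2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
                3, 3, byrow = TRUE)
    tr <- t(R)  # rows are the rotated basis vectors
    # keep away from the 180-degree ambiguity used by mid-frame operations
    ang <- acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2)))
    if (ang < 3.0) return(tr)
  }
}

random_frame <- function() {
  new_frame(stats::rnorm(3, sd = 2), random_triad())
}

# independent axis-angle via the complex eigendecomposition matrix logarithm
matrix_log_oracle <- function(R) {
  ei <- eigen(R)
  lg <- ei$vectors %*% diag(log(ei$values)) %*% solve(ei$vectors)
  lg <- Re(lg)
  c(lg[3, 2], lg[1, 3], lg[2, 1]) * 180 / pi
}

# dense midpoint double-sum Gauss integral for a smooth closed curve given
# as a parametric function on [0, 2*pi)
writhe_quadrature_oracle <- function(curve_fn, n = 2000) {
  s <- (seq_len(n) - 0.5) / n * 2 * pi
  h <- 2 * pi / n
  eps <- 1e-6
  r <- t(vapply(s, curve_fn, numeric(3)))
  tg <- (t(vapply(s + eps, curve_fn, numeric(3))) -
         t(vapply(s - eps, curve_fn, numeric(3)))) / (2 * eps)
  total <- 0
  for (i in seq_len(n - 1)) {
    js <- seq.int(i + 1, n)
    dr <- sweep(r[js, , drop = FALSE], 2, r[i, ])
    d3 <- (rowSums(dr^2))^(3 / 2)
    cr <- cbind(tg[i, 2] * tg[js, 3] - tg[i, 3] * tg[js, 2],
                tg[i, 3] * tg[js, 1] - tg[i, 1] * tg[js, 3],
                tg[i, 1] * tg[js, 2] - tg[i, 2] * tg[js, 1])
    total <- total + sum(rowSums(cr * (-dr)) / d3)
  }
  2 * total * h^2 / (4 * pi)
}

# trefoil-like closed space curve (nm scale)
trefoil_curve <- function(s) {
  c(sin(s) + 2 * sin(2 * s), cos(s) - 2 * cos(2 * s), -sin(3 * s)) * 3
}

ideal_linear <- function(n = 30, seed = 1) {
  suppressMessages(make(n_bp = n, seed = seed))
}
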