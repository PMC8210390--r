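# Independent oracles used across the suite. These deliberately avoid the
# package's solver internals: brute-force lattices, direct summation,
# hand-coded transforms.

# coarse-to-fine lattice search over (A, B, T1) for M = A - B exp(-TD/T1);
# returns the lattice minimizer and the final grid steps
oracle_t1_grid <- function(signal, delays, passes = 3L, n_grid = 21L) {
  a_rng <- range(signal) + c(-1, 1) * diff(range(signal))
  b_rng <- c(0.1 * diff(range(signal)), 4 * diff(range(signal)))
  t_rng <- c(1, 10000)
  best <- NULL
  for (pass in seq_len(passes)) {
    As <- seq(a_rng[1], a_rng[2], length.out = n_grid)
    Bs <- seq(b_rng[1], b_rng[2], length.out = n_grid)
    Ts <- exp(seq(log(t_rng[1]), log(t_rng[2]), length.out = n_grid))
    rss_best <- Inf
    for (t1 in Ts) {
      e <- exp(-delays / t1)
      for (A in As) for (B in Bs) {
        r <- signal - (A - B * e)
        rss <- sum(r * r)
        if (rss < rss_best) { rss_best <- rss; best <- c(A = A, B = B, T1 = t1) }
      }
    }
    zoom <- function(rng, x, frac = 0.2) {
      w <- diff(rng) * frac
      unname(c(max(rng[1], x - w), min(rng[2], x + w)))
    }
    a_rng <- zoom(a_rng, best[["A"]]); b_rng <- zoom(b_rng, best[["B"]])
    t_rng <- exp(zoom(log(t_rng), log(best[["T1"]])))
  }
  list(par = best,
       step = c(A = diff(a_rng) / (n_grid - 1), B = diff(b_rng) / (n_grid - 1),
                T1 = best[["T1"]] * (exp(diff(log(t_rng)) / (n_grid - 1)) - 1)))
}

# 2-parameter lattice for S = S0 exp(-TE/T2)
oracle_t2_grid <- function(signal, echoes, passes = 3L, n_grid = 41L) {
  s_rng <- c(0.2, 4) * max(signal)
  t_rng <- c(0.5, 500)
  best <- NULL
  for (pass in seq_len(passes)) {
    Ss <- seq(s_rng[1], s_rng[2], length.out = n_grid)
    Ts <- exp(seq(log(t_rng[1]), log(t_rng[2]), length.out = n_grid))
    rss_best <- Inf
    for (t2 in Ts) {
      e <- exp(-echoes / t2)
      for (s0 in Ss) {
        r <- signal - s0 * e
        rss <- sum(r * r)
        if (rss < rss_best) { rss_best <- rss; best <- c(S0 = s0, T2 = t2) }
      }
    }
    w_s <- diff(s_rng) * 0.15; w_t <- diff(log(t_rng)) * 0.15
    s_rng <- unname(c(max(0.01, best[["S0"]] - w_s), best[["S0"]] + w_s))
    t_rng <- exp(c(log(best[["T2"]]) - w_t, log(best[["T2"]]) + w_t))
  }
  list(par = best,
       step = c(S0 = diff(s_rng) / (n_grid - 1),
                T2 = best[["T2"]] * (exp(diff(log(t_rng)) / (n_grid - 1)) - 1)))
}

# hand-coded sRGB (D65) -> XYZ -> CIELAB, independent of grDevices
oracle_srgb_to_lab <- function(rgb255) {
  v <- rgb255 / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- as.numeric(M %*% lin)
  wp <- c(0.95047, 1, 1.08883)              # D65
  f <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- f(xyz[1] / wp[1]); fy <- f(xyz[2] / wp[2]); fz <- f(xyz[3] / wp[3])
  c(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

# point-in-polygon by ray casting (crossing number), hand-coded
oracle_point_in_poly <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]; xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# shoelace area, hand-coded
oracle_shoelace <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

# exact power of the two-sided pooled two-sample t-test via the noncentral t
oracle_t_power <- function(n, delta, sd, alpha = 0.05) {
  df <- 2 * n - 2
  ncp <- delta / (sd * sqrt(2 / n))
  tc <- qt(1 - alpha / 2, df)
  pt(-tc, df, ncp) + 1 - pt(tc, df, ncp)
}

# star-shaped random polygon around a centre (for rasterization oracles)
random_star_polygon <- function(n = 24L, r_base = 3, r_amp = 1, center = c(0, 0)) {
  th <- sort(runif(n, 0, 2 * pi))
  r <- r_base + runif(n, -r_amp, r_amp)
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}
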