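# Independent oracles used to cross-check the package's solvers.  Each one
# takes a deliberately different computational route from the code it
# checks.

# Closed-form cubic for free protein in the three-component competition
# system, via polynomial root finding.  Expanding
#   Pf (KD + Pf)(Ki + Pf) + L0 Pf (Ki + Pf) + I0 Pf (KD + Pf)
#     - P0 (KD + Pf)(Ki + Pf) = 0
# gives a monic cubic in Pf.
oracle_cubic_pfree <- function(P0, L0, I0, KD, Ki) {
  a2 <- KD + Ki + L0 + I0 - P0
  a1 <- KD * Ki + L0 * Ki + I0 * KD - P0 * (KD + Ki)
  a0 <- -P0 * KD * Ki
  roots <- polyroot(c(a0, a1, a2, 1))
  re <- Re(roots[abs(Im(roots)) < 1e-7 * (1 + abs(Re(roots)))])
  re <- re[re >= -1e-9 & re <= P0 * (1 + 1e-9)]
  if (length(re) == 0) stop("cubic oracle found no feasible root")
  min(max(re[1], 0), P0)
}

# Plain dense bisection on the free-protein balance, no Newton step.
oracle_bisect_pfree <- function(P0, L0, I0, KD, Ki, iters = 200) {
  f <- function(pf) pf * (1 + L0 / (KD + pf) + I0 / (Ki + pf)) - P0
  lo <- 0; hi <- P0
  for (k in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

oracle_pl <- function(P0, L0, I0, KD, Ki) {
  pf <- oracle_bisect_pfree(P0, L0, I0, KD, Ki)
  pf * L0 / (KD + pf)
}

# Monte-Carlo SASA: sample uniform points on each expanded sphere and count
# the fraction outside all other expanded spheres.
oracle_mc_sasa <- function(xyz, radii, probe = 1.4, n_mc = 1e5, seed = 1) {
  set.seed(seed)
  r_ext <- radii + probe
  n <- nrow(xyz)
  total <- 0
  for (i in seq_len(n)) {
    u <- matrix(rnorm(3 * n_mc), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    p <- sweep(u * r_ext[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, n_mc)
    for (j in seq_len(n)[-i]) {
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      free <- free & d2 > r_ext[j]^2
    }
    total <- total + 4 * pi * r_ext[i]^2 * mean(free)
  }
  total
}

# Independent ITC heat accounting: after each injection solve the 1:1
# quadratic for bound complex directly (smaller root of
# x^2 - (N Mt + Xt + KD) x + N Mt Xt = 0) and difference the cumulative
# heats with the displaced-volume correction.
oracle_itc_heats <- function(protocol, N, KD, dH, offset = 0) {
  dv <- protocol$injection_volumes
  dv_cum <- cumsum(dv)
  corr <- 1 - dv_cum / (2 * protocol$V0)
  Mt <- protocol$cell_conc * corr * N
  Xt <- protocol$syringe_conc * (dv_cum / protocol$V0) * corr
  b <- Mt + Xt + KD
  bound <- (b - sqrt(b^2 - 4 * Mt * Xt)) / 2
  Q <- bound * dH * protocol$V0 * 1e-3
  Qprev <- c(0, Q[-length(Q)])
  Q - Qprev + (dv / protocol$V0) * (Q + Qprev) / 2 + offset
}
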