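test_that("two-component quadratic gives the physical root", {
  # evaluated against the closed form and checked by back-substitution
  pl0 <- solve_two_component(5, 100, 50)
  expect_equal(pl0, 3.29589, tolerance = 1e-5)
  expect_lt(abs((5 - pl0) * (100 - pl0) / pl0 - 50), 1e-10)

  expect_equal(solve_two_component(5, 0, 50), 0)
  expect_equal(solve_two_component(5, 100, 1e-9), 5, tolerance = 1e-8)
  expect_error(solve_two_component(-1, 100, 50), "non-negative")
  expect_error(solve_two_component(5, 100, 0), "positive")
})

test_that("forward competition solver reduces to known limits", {
  # inert competitor (huge Ki)
  st <- solve_competition(5, 100, 10, 50, 1e12)
  expect_equal(st$PL, solve_two_component(5, 100, 50), tolerance = 1e-9)
  expect_lt(st$PI, 1e-10)
  # no competitor at all
  st0 <- solve_competition(5, 100, 0, 50, 1)
  expect_equal(st0$PL, 3.29589, tolerance = 1e-5)
  expect_equal(st0$PI, 0)
  # frozen from the bisection oracle
  st2 <- solve_competition(5, 100, 10, 50, 4.134)
  expect_equal(st2$PL, 2.0000, tolerance = 1e-4)
  expect_equal(st2$PI, 1.9797, tolerance = 1e-4)
})

test_that("species states conserve mass and satisfy mass action", {
  set.seed(101)
  n <- 10000
  P0 <- 10^runif(n, -2, 3)
  L0 <- 10^runif(n, -2, 3)
  I0 <- 10^runif(n, -2, 3)
  KD <- 10^runif(n, -3, 4)
  Ki <- 10^runif(n, -3, 4)
  st <- solve_competition(P0, L0, I0, KD, Ki)
  expect_true(all(unlist(st) >= 0))
  expect_lt(max(abs(st$Pfree + st$PL + st$PI - P0) / pmax(P0, 1e-12)), 1e-9)
  expect_lt(max(abs(st$Lfree + st$PL - L0) / pmax(L0, 1e-12)), 1e-9)
  expect_lt(max(abs(st$Ifree + st$PI - I0) / pmax(I0, 1e-12)), 1e-9)
  ok <- st$PL > 1e-12 & st$PI > 1e-12
  expect_lt(max(abs(st$Pfree[ok] * st$Lfree[ok] / st$PL[ok] - KD[ok]) / KD[ok]), 1e-8)
  expect_lt(max(abs(st$Pfree[ok] * st$Ifree[ok] / st$PI[ok] - Ki[ok]) / Ki[ok]), 1e-8)
})

test_that("forward solver matches cubic and bisection oracles on a log grid", {
  kds <- 10^seq(-3, 4, length.out = 12)
  kis <- 10^seq(-3, 4, length.out = 12)
  for (kd in kds) for (ki in kis) {
    st <- solve_competition(5, 100, 10, kd, ki)
    pf_cubic <- oracle_cubic_pfree(5, 100, 10, kd, ki)
    pl_bis <- oracle_pl(5, 100, 10, kd, ki)
    expect_lt(abs(st$PL - pl_bis), 1e-8)
    expect_lt(abs(st$Pfree - pf_cubic), 1e-7 * (1 + pf_cubic))
  }
})

test_that("PL is monotone in competitor concentration and affinity", {
  i0 <- seq(0, 100, length.out = 25)
  pl_i <- solve_competition(5, 100, i0, 50, 2)$PL
  expect_true(all(diff(pl_i) <= 1e-12))
  ki <- 10^seq(-2, 3, length.out = 25)
  pl_k <- solve_competition(5, 100, 10, 50, ki)$PL
  expect_true(all(diff(pl_k) >= -1e-12))
})

test_that("weak-binding limit linearizes", {
  # KD far above all totals: PL -> P0*L0/KD
  kd <- 1e4 * 100
  pl <- solve_two_component(5, 100, kd)
  expect_equal(pl, 5 * 100 / kd, tolerance = 0.01)
})

test_that("competitor-bound inversion round-trips and clamps", {
  r <- infer_competitor_bound(5, 100, 50, 2)
  expect_equal(r$PI, 1.9796, tolerance = 1e-4)
  expect_equal(r$flag, "ok")
  # back-substitute into the competitive quadratic for PL
  P0e <- 5 - r$PI
  pl_back <- (P0e + 100 + 50 - sqrt((P0e + 100 + 50)^2 - 4 * P0e * 100)) / 2
  expect_lt(abs(pl_back - 2) / 2, 1e-10)

  expect_equal(infer_competitor_bound(5, 100, 50, 3.29589)$PI, 0,
               tolerance = 1e-4)
  expect_equal(infer_competitor_bound(5, 100, 50, 0)$PI, 5)
  expect_error(infer_competitor_bound(5, 100, 50, 5), "min")
  # slightly super-stoichiometric PL is flagged, not fatal
  expect_equal(infer_competitor_bound(5, 100, 50, 3.4)$flag,
               "no_displacement")
})

test_that("Ki from species is Eq-1 arithmetic with guards", {
  expect_equal(ki_from_species(5, 10, 1.9796, 2), 4.134, tolerance = 1e-3)
  expect_equal(ki_from_species(5, 10, 0.5, 3), 1.5 * 9.5 / 0.5)
  expect_equal(suppressWarnings(ki_from_species(5, 10, 10, 0)), 0)
  expect_warning(ki_from_species(5, 10, 0, 2), "undetermined")
  expect_error(ki_from_species(5, 10, 11, 0), "exceeds")
  expect_error(ki_from_species(5, 10, 3, 3), "exceeds")
})

test_that("forward -> inversion -> Ki round-trip recovers the input", {
  set.seed(7)
  for (k in 1:200) {
    ki_true <- 10^runif(1, -2, 3)
    i0 <- 10^runif(1, 0, 2)
    st <- solve_competition(5, 100, i0, 50, ki_true)
    if (st$PL >= min(5, 100) || st$PI < 1e-9) next
    pi_ <- infer_competitor_bound(5, 100, 50, st$PL)$PI
    ki_back <- ki_from_species(5, i0, pi_, st$PL)
    expect_equal(ki_back, ki_true, tolerance = 1e-8)
  }
})
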