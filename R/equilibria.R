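#' Two-component binding equilibrium: complex concentration
#'
#' Solves the 1:1 protein--ligand mass-action equilibrium for the complex
#' concentration, taking the physically meaningful (smaller) root of the
#' binding quadratic
#' \deqn{[PL_0] = \frac{P_0 + L_0 + K_D - \sqrt{(P_0 + L_0 + K_D)^2 - 4 P_0 L_0}}{2}.}
#'
#' All concentrations are in micromolar throughout the package; no unit
#' conversion happens inside the computational core.
#'
#' @param P0 Total protein concentration (uM). Vectorised.
#' @param L0 Total ligand concentration (uM). Vectorised.
#' @param KD Dissociation constant of the complex (uM). Vectorised.
#' @return Complex concentration `PL0` (uM), with `0 <= PL0 <= min(P0, L0)`.
#' @examples
#' solve_two_component(5, 100, 50)   # ~3.296 uM
#' @export
solve_two_component <- function(P0, L0, KD) {
  check_conc(P0 = P0, L0 = L0)
  check_conc_pos(KD = KD)
  b <- P0 + L0 + KD
  disc <- b^2 - 4 * P0 * L0
  # disc = (P0 - L0)^2 + KD^2 + 2 KD (P0 + L0) >= 0 always for valid input
  stopifnot(all(disc >= 0))
  # smaller root computed in its numerically stable form 2*P0*L0 / (b + sqrt(disc))
  pl <- ifelse(P0 * L0 == 0, 0, 2 * P0 * L0 / (b + sqrt(disc)))
  pmin(pl, pmin(P0, L0))
}

#' Three-component competitive binding equilibrium (forward solver)
#'
#' Solves the protein--spy--competitor mass-action system for all species
#' concentrations.  Free protein `Pf` is the root of the strictly increasing
#' function
#' \deqn{f(P_f) = P_f \left(1 + \frac{L_0}{K_D + P_f} + \frac{I_0}{K_i + P_f}\right) - P_0}
#' on `[0, P0]`, located by bisection and polished by Newton iteration to
#' relative tolerance 1e-12.  The closed-form cubic is deliberately not used
#' here (it is numerically fragile for extreme parameters); it serves as an
#' independent oracle in the test suite.
#'
#' @param P0,L0,I0 Total protein, spy and competitor concentrations (uM).
#' @param KD Protein--spy dissociation constant (uM).
#' @param Ki Protein--competitor dissociation constant (uM).
#' @return A `species_state`: list with components `Pfree`, `Lfree`, `Ifree`,
#'   `PL`, `PI` (all uM, vectorised over the inputs).
#' @examples
#' st <- solve_competition(5, 100, 10, 50, 4.134)
#' st$PL  # ~2.0 uM
#' @export
solve_competition <- function(P0, L0, I0, KD, Ki) {
  check_conc(P0 = P0, L0 = L0, I0 = I0)
  check_conc_pos(KD = KD, Ki = Ki)
  n <- max(length(P0), length(L0), length(I0), length(KD), length(Ki))
  P0 <- rep_len(P0, n); L0 <- rep_len(L0, n); I0 <- rep_len(I0, n)
  KD <- rep_len(KD, n); Ki <- rep_len(Ki, n)

  f <- function(pf) pf * (1 + L0 / (KD + pf) + I0 / (Ki + pf)) - P0

  lo <- rep(0, n)
  hi <- P0
  # degenerate: no protein -> analytic zero state, bracket collapses
  for (iter in seq_len(100)) {
    mid <- (lo + hi) / 2
    pos <- f(mid) > 0
    hi[pos] <- mid[pos]
    lo[!pos] <- mid[!pos]
  }
  pf <- (lo + hi) / 2
  # Newton polish; derivative of f is 1 + L0*KD/(KD+pf)^2 + I0*Ki/(Ki+pf)^2 >= 1
  for (iter in seq_len(5)) {
    fp <- 1 + L0 * KD / (KD + pf)^2 + I0 * Ki / (Ki + pf)^2
    step <- f(pf) / fp
    pf <- pmin(pmax(pf - step, 0), P0)
  }
  resid <- abs(f(pf)) / pmax(P0, 1)
  if (any(resid > 1e-9)) {
    stop("competition solver failed to converge; max residual ",
         format(max(resid)), " at index ", which.max(resid))
  }
  pl <- pf * L0 / (KD + pf)
  pi_ <- pf * I0 / (Ki + pf)
  state <- list(Pfree = pf, Lfree = L0 - pl, Ifree = I0 - pi_,
                PL = pl, PI = pi_)
  class(state) <- "species_state"
  state
}

#' @export
print.species_state <- function(x, ...) {
  cat("Competitive binding equilibrium (uM):\n")
  print(data.frame(Pfree = x$Pfree, Lfree = x$Lfree, Ifree = x$Ifree,
                   PL = x$PL, PI = x$PI), ...)
  invisible(x)
}

#' Infer bound competitor from an observed spy-complex concentration
#'
#' Closed-form inversion of the competitive quadratic: given the observed
#' protein--spy complex concentration `PL`, returns the protein--competitor
#' complex concentration
#' \deqn{[PI] = \frac{P_0 L_0 - (P_0 + L_0 + K_D)\,[PL] + [PL]^2}{L_0 - [PL]}.}
#'
#' Values slightly outside the feasible interval `[0, P0 - PL]` (within
#' `clamp_tol`, as produced by measurement noise) are clamped and flagged;
#' larger violations raise an error, since gross infeasibility signals bad
#' input rather than noise.
#'
#' @param P0,L0 Total protein and spy concentrations (uM).
#' @param KD Protein--spy dissociation constant (uM).
#' @param PL Observed protein--spy complex concentration (uM); must satisfy
#'   `0 <= PL < min(P0, L0)`.
#' @param clamp_tol Absolute clamping tolerance (uM, default 1e-6).
#' @return List with `PI` (uM) and `flag` (`"ok"`, `"clamped"` or
#'   `"no_displacement"` when `PL` exceeds the competitor-free value `PL0`).
#' @export
infer_competitor_bound <- function(P0, L0, KD, PL, clamp_tol = 1e-6) {
  check_conc(P0 = P0, L0 = L0, PL = PL)
  check_conc_pos(KD = KD)
  if (PL >= min(P0, L0)) {
    stop("PL (", PL, " uM) must be below min(P0, L0) = ", min(P0, L0))
  }
  pl0 <- solve_two_component(P0, L0, KD)
  if (PL > pl0) {
    # super-stoichiometric: more spy complex than the competitor-free
    # equilibrium allows, so no displacement is evidenced
    return(list(PI = 0, flag = "no_displacement"))
  }
  pi_ <- (P0 * L0 - (P0 + L0 + KD) * PL + PL^2) / (L0 - PL)
  flag <- "ok"
  upper <- P0 - PL
  if (pi_ < 0 || pi_ > upper) {
    if (pi_ > -clamp_tol && pi_ < upper + clamp_tol) {
      pi_ <- min(max(pi_, 0), upper)
      if (flag == "ok") flag <- "clamped"
    } else {
      stop("inferred PI = ", format(pi_), " uM is infeasible (allowed [0, ",
           format(upper), "])")
    }
  }
  list(PI = pi_, flag = flag)
}

#' Competitor dissociation constant from equilibrium species
#'
#' Direct evaluation of the competitive-binding mass-action relation
#' \deqn{K_i = \frac{(P_0 - [PI] - [PL])\,(I_0 - [PI])}{[PI]},}
#' where `P0 - PI - PL` is the free protein and `I0 - PI` the free
#' competitor.
#'
#' @param P0,I0 Total protein and competitor concentrations (uM).
#' @param PI Protein--competitor complex concentration (uM), `0 < PI <= I0`.
#' @param PL Protein--spy complex concentration (uM).
#' @return `Ki` in uM (>= 0), or `NA` with a warning condition when `PI = 0`
#'   (no displacement: Ki is undetermined from the data).
#' @export
ki_from_species <- function(P0, I0, PI, PL) {
  check_conc(P0 = P0, I0 = I0, PI = PI, PL = PL)
  if (PI > I0) stop("PI (", PI, ") exceeds total competitor I0 (", I0, ")")
  if (PI == I0) return(0)  # saturated competitor: Ki -> 0 limit
  if (PI + PL > P0 * (1 + 1e-12)) {
    stop("PI + PL (", PI + PL, ") exceeds total protein P0 (", P0, ")")
  }
  if (PI == 0) {
    warning("PI = 0: Ki undetermined (no displacement)")
    return(NA_real_)
  }
  max((P0 - PI - PL) * (I0 - PI) / PI, 0)
}

# internal argument checks -------------------------------------------------

check_conc <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    x <- args[[nm]]
    if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
      stop(nm, " must be finite and non-negative (uM)")
    }
  }
  invisible(TRUE)
}

check_conc_pos <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    x <- args[[nm]]
    if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
      stop(nm, " must be finite and strictly positive (uM)")
    }
  }
  invisible(TRUE)
}
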