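# Seeded generators emulating each assay modality.  Every generator is a
# pure function of (parameters, seed): the RNG is seeded explicitly inside
# and the caller's random state is restored on exit.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Default assay constants of the displacement experiment
#'
#' Protein 5 uM, spy 100 uM with KD 50 uM; spy transverse relaxation rates
#' 3 s^-1 free and 245.7 s^-1 bound (the bound-state rate is calibrated so
#' that the observed fast-exchange rate under these assay conditions is
#' 11 s^-1); CPMG displacement delay 0.133 s; GHR-derived competitors at
#' 10 uM, EpoR-derived at 50 uM; 4 replicates; 1% multiplicative integral
#' noise.
#'
#' @return Named list of constants.
#' @export
assay_defaults <- function() {
  list(P0 = 5, L0 = 100, KD_spy = 50,
       R2_free = 3, R2_bound = 245.7,
       delay = 0.133,
       I0_ghr = 10, I0_epor = 50,
       n_replicates = 4, cpmg_noise = 0.01)
}

#' Simulate a CPMG relaxation series
#'
#' Two-state fast-exchange observable model: the bound fraction of the spy
#' `fb = PL/L0` comes from the equilibrium solver, the observed rate is the
#' population-weighted average `R2_obs = (1 - fb) R2_free + fb R2_bound`,
#' and intensities decay mono-exponentially with multiplicative Gaussian
#' noise: `I(t) = I0 exp(-t R2_obs) (1 + eps)`.
#'
#' @param P0,L0,KD Two-component system (uM); `P0 = 0` gives the free-spy
#'   series.
#' @param I0_comp,Ki Optional competitor (uM): when given, the bound
#'   fraction comes from the three-component solver.
#' @param R2_free,R2_bound Spy relaxation rates free/bound (s^-1),
#'   `R2_bound >= R2_free > 0`.
#' @param delays CPMG filter delays (s).
#' @param I0 Amplitude at t = 0 (a.u.).
#' @param noise_sd Multiplicative noise sd (default 0.01).
#' @param seed RNG seed.
#' @param label Condition tag.
#' @return A [cpmg_series] with attribute `truth` (list: `fb`, `R2_obs`).
#' @export
gen_cpmg_series <- function(P0, L0, KD, I0_comp = 0, Ki = Inf,
                            R2_free = 3, R2_bound = 245.7,
                            delays = c(0.05, 0.1, 0.2, 0.4, 0.8),
                            I0 = 1000, noise_sd = 0.01, seed = 1,
                            label = "") {
  if (R2_free <= 0 || R2_bound < R2_free) {
    stop("need R2_bound >= R2_free > 0")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  fb <- if (L0 == 0) 0 else if (I0_comp > 0 && is.finite(Ki)) {
    solve_competition(P0, L0, I0_comp, KD, Ki)$PL / L0
  } else {
    solve_two_component(P0, L0, KD) / L0
  }
  r2_obs <- (1 - fb) * R2_free + fb * R2_bound
  eps <- with_seed(seed, stats::rnorm(length(delays), 0, noise_sd))
  ints <- I0 * exp(-delays * r2_obs) * (1 + eps)
  s <- cpmg_series(delays, ints, label = label)
  attr(s, "truth") <- list(fb = fb, R2_obs = r2_obs)
  s
}

#' Simulate a displacement panel with known true affinities
#'
#' For each peptide the three-component equilibrium is solved at its true
#' Ki; the free-spy and with-protein integrals follow the fast-exchange
#' relaxation model at the displacement delay, and the with-competitor
#' integral interpolates linearly in the remaining bound-spy fraction
#' between them (the linear-response assumption the inference equations
#' themselves make).  Each replicate carries independent multiplicative
#' noise on all three integrals.
#'
#' @param true_ki Named numeric vector of true competitor Ki (uM); names
#'   become peptide ids.
#' @param I0_comp Total competitor concentration(s) (uM), recycled.
#' @param P0,L0,KD Assay system (uM); defaults from [assay_defaults()].
#' @param R2_free,R2_bound Spy relaxation rates (s^-1).
#' @param delay CPMG displacement delay (s, default 0.133).
#' @param n_replicates Replicates per peptide (default 4).
#' @param I0 Amplitude (a.u.).
#' @param noise_sd Multiplicative integral noise sd (default 0.01).
#' @param seed RNG seed.
#' @return List with `table` (displacement table, one row per peptide x
#'   replicate; schema of [analyze_displacement_table()]) and `truth`
#'   (data frame: peptide_id, true Ki, noiseless f).
#' @export
gen_displacement_panel <- function(true_ki, I0_comp = 10, P0 = 5, L0 = 100,
                                   KD = 50, R2_free = 3, R2_bound = 245.7,
                                   delay = 0.133, n_replicates = 4,
                                   I0 = 1000, noise_sd = 0.01, seed = 1) {
  if (any(true_ki <= 0)) stop("true Ki must be positive")
  ids <- names(true_ki)
  if (is.null(ids)) ids <- sprintf("pep%02d", seq_along(true_ki))
  n_pep <- length(true_ki)
  I0_comp <- rep_len(I0_comp, n_pep)

  pl0 <- solve_two_component(P0, L0, KD)
  fb_p <- pl0 / L0
  r2_p <- (1 - fb_p) * R2_free + fb_p * R2_bound
  IF0 <- I0 * exp(-delay * R2_free)
  IP0 <- I0 * exp(-delay * r2_p)

  st <- solve_competition(rep(P0, n_pep), rep(L0, n_pep), I0_comp,
                          rep(KD, n_pep), true_ki)
  f_true <- st$PL / pl0
  II0 <- IF0 - f_true * (IF0 - IP0)

  tab <- with_seed(seed, {
    rows <- lapply(seq_len(n_pep), function(i) {
      eps <- matrix(stats::rnorm(3 * n_replicates, 0, noise_sd),
                    nrow = n_replicates)
      data.frame(peptide_id = ids[i],
                 IF = IF0 * (1 + eps[, 1]),
                 IP = IP0 * (1 + eps[, 2]),
                 II = II0[i] * (1 + eps[, 3]),
                 P0_uM = P0, L0_uM = L0, KD_spy_uM = KD,
                 I0_uM = I0_comp[i],
                 replicate = seq_len(n_replicates),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  rownames(tab) <- NULL
  list(table = tab,
       truth = data.frame(peptide_id = ids, ki_true = unname(true_ki),
                          f_true = f_true, stringsAsFactors = FALSE))
}

#' Simulate an SPR steady-state titration
#'
#' 1:1 isotherm responses `Rmax C/(KD + C)` on a concentration series with
#' additive Gaussian noise.
#'
#' @param KD Dissociation constant (uM).
#' @param Rmax Saturating response (RU).
#' @param concentrations Analyte series (uM); default the seven-point
#'   assay series ([spr_default_concentrations()]).
#' @param noise_sd Additive response noise sd (RU, default 1).
#' @param seed RNG seed.
#' @return An [spr_titration] with attribute `truth`.
#' @export
gen_spr_titration <- function(KD, Rmax, concentrations = spr_default_concentrations(),
                              noise_sd = 1, seed = 1) {
  if (KD <= 0 || Rmax <= 0) stop("KD and Rmax must be positive")
  ideal <- Rmax * concentrations / (KD + concentrations)
  eps <- with_seed(seed, stats::rnorm(length(concentrations), 0, noise_sd))
  tit <- spr_titration(concentrations, ideal + eps, noise_sd = noise_sd)
  attr(tit, "truth") <- list(KD = KD, Rmax = Rmax)
  tit
}

#' Simulate an ITC titration
#'
#' Per-injection heats from the one-set-of-sites model
#' ([itc_expected_heats()]) with additive Gaussian noise scaled to the
#' largest heat magnitude.
#'
#' @param protocol An [itc_protocol].
#' @param N,KD,dH,offset Model parameters (see [itc_expected_heats()]).
#' @param noise_frac Noise sd as a fraction of the largest absolute heat
#'   (default 0.02).
#' @param seed RNG seed.
#' @return Numeric vector of noisy heats (ucal) with attribute `truth`.
#' @export
gen_itc_titration <- function(protocol, N, KD, dH, offset = 0,
                              noise_frac = 0.02, seed = 1) {
  q <- itc_expected_heats(protocol, N, KD, dH, offset)
  sd <- noise_frac * max(abs(q))
  eps <- with_seed(seed, stats::rnorm(length(q), 0, sd))
  out <- q + eps
  attr(out, "truth") <- list(N = N, KD = KD, dH = dH, offset = offset,
                             noise_sd = sd)
  out
}

#' Deterministic toy structures for interface testing
#'
#' Small hand-placed atom arrangements exercising the surface and contact
#' machinery: `"single_sphere"` (one carbon), `"far_dimer"` (two chains
#' 100 A apart, zero buried area), `"touching_dimer"` (two small clusters
#' in contact), `"hbond_pair"` (an N-H...O-like arrangement with covalent
#' antecedents across two chains).
#'
#' @param preset One of `"single_sphere"`, `"far_dimer"`,
#'   `"touching_dimer"`, `"hbond_pair"`.
#' @return A `structure_model`.
#' @export
gen_toy_complex <- function(preset = c("single_sphere", "far_dimer",
                                       "touching_dimer", "hbond_pair")) {
  preset <- match.arg(preset)
  at <- function(chain, resno, resid, atom, element, x, y, z) {
    data.frame(chain = chain, resno = resno, resid = resid, atom = atom,
               element = element, x = x, y = y, z = z,
               stringsAsFactors = FALSE)
  }
  atoms <- switch(preset,
    single_sphere = at("A", 1, "ALA", "CB", "C", 0, 0, 0),
    far_dimer = rbind(
      at("A", 1, "ALA", "CB", "C", 0, 0, 0),
      at("B", 1, "ALA", "CB", "C", 100, 0, 0)),
    touching_dimer = rbind(
      at("A", 1, "ALA", "CB", "C", 0, 0, 0),
      at("A", 1, "ALA", "CG", "C", 1.5, 0, 0),
      at("B", 1, "ALA", "CB", "C", 5.0, 0.5, 0),
      at("B", 1, "ALA", "CG", "C", 6.5, 0.5, 0)),
    hbond_pair = rbind(
      at("A", 1, "GLY", "CA", "C", -1.47, 0, 0),
      at("A", 1, "GLY", "N",  "N", 0, 0, 0),
      at("B", 2, "GLY", "O",  "O", 2.9, 0, 0),
      at("B", 2, "GLY", "C",  "C", 4.13, 0.4, 0)))
  structure_model(atoms, model_id = paste0("toy_", preset))
}
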