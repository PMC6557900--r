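#' ITC titration protocol
#'
#' Injection protocol for a single-cell isothermal titration calorimetry
#' experiment.  Defaults mirror a standard small-volume instrument protocol:
#' a 0.4 ul initial injection (discarded during analysis) followed by 19
#' injections of 2 ul, cell volume 200 ul.
#'
#' @param cell_conc Macromolecule concentration in the cell (uM).
#' @param syringe_conc Titrant concentration in the syringe (uM).
#' @param V0 Active cell volume (ul).
#' @param injection_volumes Injection volumes (ul), in order.
#' @param first_injection_discarded Should the first injection be excluded
#'   from fitting? (Its volume still displaces cell contents.)
#' @param temperature Temperature (K).
#' @return An object of class `itc_protocol`.
#' @export
itc_protocol <- function(cell_conc, syringe_conc, V0 = 200,
                         injection_volumes = c(0.4, rep(2, 19)),
                         first_injection_discarded = TRUE,
                         temperature = 298) {
  if (cell_conc <= 0 || syringe_conc <= 0) {
    stop("cell and syringe concentrations must be positive (uM)")
  }
  if (V0 <= 0 || any(injection_volumes <= 0)) {
    stop("volumes must be positive (ul)")
  }
  structure(list(cell_conc = cell_conc, syringe_conc = syringe_conc,
                 V0 = V0, injection_volumes = as.numeric(injection_volumes),
                 first_injection_discarded = first_injection_discarded,
                 temperature = temperature),
            class = "itc_protocol")
}

#' @export
print.itc_protocol <- function(x, ...) {
  cat("ITC protocol: cell ", x$cell_conc, " uM, syringe ", x$syringe_conc,
      " uM, V0 = ", x$V0, " ul\n  ", length(x$injection_volumes),
      " injections (", paste(unique(x$injection_volumes), collapse = "/"),
      " ul)", if (x$first_injection_discarded) ", first discarded", "\n",
      sep = "")
  invisible(x)
}

# Displacement-corrected total concentrations after each injection
# (standard single-cell instrument convention): with cumulative injected
# volume dV, Mt = cell*(1 - dV/(2 V0)), Xt = syringe*(dV/V0)*(1 - dV/(2 V0)).
itc_totals <- function(protocol) {
  dv_cum <- cumsum(protocol$injection_volumes)
  corr <- 1 - dv_cum / (2 * protocol$V0)
  list(Mt = protocol$cell_conc * corr,
       Xt = protocol$syringe_conc * (dv_cum / protocol$V0) * corr,
       dv = protocol$injection_volumes, dv_cum = dv_cum)
}

#' Expected per-injection heats for a one-set-of-sites titration
#'
#' Computes the Wiseman one-set-of-sites model.  After injection i, with
#' displacement-corrected totals `Mt_i` (macromolecule) and `Xt_i`
#' (titrant), the cumulative heat is
#' \deqn{Q_i = \frac{N\,Mt_i\,\Delta H\,V_0}{2}\left[A_i - \sqrt{A_i^2 - \frac{4 Xt_i}{N\,Mt_i}}\right],
#'       \quad A_i = 1 + \frac{Xt_i}{N\,Mt_i} + \frac{K_D}{N\,Mt_i},}
#' and the measured per-injection heat corrects for the displaced volume:
#' \deqn{\Delta Q_i = Q_i - Q_{i-1} + \frac{dV_i}{V_0}\,\frac{Q_i + Q_{i-1}}{2} + \mathrm{offset}.}
#'
#' @param protocol An [itc_protocol].
#' @param N Stoichiometry (sites per macromolecule).
#' @param KD Dissociation constant (uM).
#' @param dH Binding enthalpy (kcal/mol).
#' @param offset Constant heat of dilution per injection (ucal).
#' @return Numeric vector of per-injection heats (ucal), one per injection
#'   including any discarded first injection.
#' @export
itc_expected_heats <- function(protocol, N, KD, dH, offset = 0) {
  if (!inherits(protocol, "itc_protocol")) stop("protocol must be an itc_protocol")
  if (N <= 0) stop("N must be positive")
  if (KD <= 0) stop("KD must be positive (uM)")
  tot <- itc_totals(protocol)
  nm <- N * tot$Mt
  A <- 1 + tot$Xt / nm + KD / nm
  disc <- pmax(A^2 - 4 * tot$Xt / nm, 0)
  # uM * ul * kcal/mol = 1e-12 mol * 1e3 cal/mol = 1e-3 ucal
  Q <- (nm * dH * protocol$V0 / 2) * (A - sqrt(disc)) * 1e-3
  Qprev <- c(0, Q[-length(Q)])
  dq <- Q - Qprev + (tot$dv / protocol$V0) * (Q + Qprev) / 2
  dq + offset
}

#' Fit the one-set-of-sites ITC model
#'
#' Nonlinear least squares over (N, KD, dH, offset) against per-injection
#' heats, by Levenberg-Marquardt with analytic model residuals; on failure,
#' restarts from alternative KD initializations.  The first injection is
#' excluded when the protocol says so.  Reports the Wiseman
#' c-value (`c = N * cell_conc / KD`) and flags low-confidence
#' stoichiometry when `c < 1` (the isotherm is too shallow to pin N down).
#'
#' @param protocol An [itc_protocol].
#' @param heats Per-injection heats (ucal), one per injection in protocol
#'   order (including a discarded first injection, if any).
#' @param start Optional named list overriding starting values
#'   (`N`, `KD`, `dH`, `offset`).
#' @return An object of class `itc_fit` with `N`, `KD` (uM), `dH`
#'   (kcal/mol), `offset` (ucal), `rss`, `c_value`, `low_confidence_N`,
#'   `fitted`, `protocol`, `heats`.
#' @examples
#' prot <- itc_protocol(cell_conc = 50, syringe_conc = 750)
#' q <- itc_expected_heats(prot, N = 1, KD = 1.1, dH = -10)
#' fit_itc(prot, q)
#' @export
fit_itc <- function(protocol, heats, start = NULL) {
  if (!inherits(protocol, "itc_protocol")) stop("protocol must be an itc_protocol")
  n_inj <- length(protocol$injection_volumes)
  if (length(heats) != n_inj) {
    stop("expected ", n_inj, " heats, got ", length(heats))
  }
  use <- rep(TRUE, n_inj)
  if (protocol$first_injection_discarded) use[1] <- FALSE
  if (sum(use) < 5) stop("need at least 5 usable injections")

  obs <- heats[use]
  # crude starts: total integrated heat ~ N * cell moles * dH
  dh0 <- sum(obs) / (protocol$cell_conc * protocol$V0 * 1e-3)
  if (!is.finite(dh0) || dh0 == 0) dh0 <- -5
  starts <- list(
    c(N = 1, KD = protocol$cell_conc / 100, dH = dh0, offset = 0),
    c(N = 1, KD = protocol$cell_conc / 10, dH = dh0, offset = 0),
    c(N = 1, KD = protocol$cell_conc, dH = dh0, offset = 0),
    c(N = 1, KD = protocol$cell_conc * 10, dH = 2 * dh0, offset = 0),
    c(N = 1, KD = protocol$cell_conc * 50, dH = 4 * dh0, offset = 0)
  )
  if (!is.null(start)) {
    s0 <- starts[[1]]
    s0[names(start)] <- unlist(start)
    starts <- c(list(s0), starts)
  }

  resid_fn <- function(p) {
    obs - itc_expected_heats(protocol, N = exp(p[["logN"]]),
                             KD = exp(p[["logKD"]]), dH = p[["dH"]],
                             offset = p[["offset"]])[use]
  }

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(logN = log(s[["N"]]), logKD = log(s[["KD"]]),
                dH = s[["dH"]], offset = s[["offset"]]),
        fn = resid_fn,
        control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                             maxiter = 1000)),
      error = function(e) NULL)
    # info 1-4: converged; info 5 (iteration cap) still yields a usable
    # minimum when the isotherm is shallow and the N/dH ridge is flat
    if (!is.null(fit) && fit$info >= 1 && fit$info <= 5 &&
        all(is.finite(fit$par)) && all(is.finite(fit$fvec))) {
      if (is.null(best) || sum(fit$fvec^2) < sum(best$fvec^2)) best <- fit
    }
  }
  if (is.null(best)) {
    stop("ITC fit did not converge from any of ", length(starts),
         " initializations")
  }
  N <- exp(best$par[["logN"]])
  KD <- exp(best$par[["logKD"]])
  dH <- best$par[["dH"]]
  offset <- best$par[["offset"]]
  c_value <- N * protocol$cell_conc / KD
  out <- list(N = N, KD = KD, dH = dH, offset = offset,
              rss = sum(best$fvec^2), c_value = c_value,
              low_confidence_N = c_value < 1,
              fitted = itc_expected_heats(protocol, N, KD, dH, offset),
              used = use, protocol = protocol, heats = heats)
  class(out) <- "itc_fit"
  out
}

#' @export
print.itc_fit <- function(x, digits = 4, ...) {
  cat("One-set-of-sites ITC fit\n")
  cat("  N = ", format(x$N, digits = digits),
      ",  KD = ", format(x$KD, digits = digits), " uM,  dH = ",
      format(x$dH, digits = digits), " kcal/mol,  offset = ",
      format(x$offset, digits = digits), " ucal\n", sep = "")
  cat("  Wiseman c = ", format(x$c_value, digits = digits),
      if (x$low_confidence_N) "  (c < 1: stoichiometry poorly determined)",
      "\n", sep = "")
  invisible(x)
}

#' @export
coef.itc_fit <- function(object, ...) {
  c(N = object$N, KD = object$KD, dH = object$dH, offset = object$offset)
}

#' @export
predict.itc_fit <- function(object, ...) object$fitted

#' @export
residuals.itc_fit <- function(object, ...) {
  (object$heats - object$fitted)[object$used]
}

#' @export
plot.itc_fit <- function(x, ...) {
  tot <- itc_totals(x$protocol)
  ratio <- tot$Xt / tot$Mt
  plot(ratio[x$used], x$heats[x$used], xlab = "molar ratio",
       ylab = "heat per injection (ucal)",
       main = sprintf("KD = %.3g uM, N = %.2f, dH = %.3g kcal/mol",
                      x$KD, x$N, x$dH), ...)
  lines(ratio[x$used], x$fitted[x$used])
  invisible(x)
}

#' Read per-injection ITC heats from CSV
#'
#' Expects columns `injection_index`, `volume_ul`, `heat_ucal`.
#'
#' @param path CSV file path.
#' @return Data frame sorted by injection index.
#' @export
read_itc_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("injection_index", "volume_ul", "heat_ucal")
  if (!all(need %in% names(df))) {
    stop("ITC CSV must have columns: ", paste(need, collapse = ", "))
  }
  df[order(df$injection_index), ]
}
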