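#' SPR steady-state titration
#'
#' Container for a steady-state surface plasmon resonance concentration
#' series: equilibrium responses at a set of analyte concentrations.  The
#' default assay uses a seven-point series (0.08, 0.25, 0.7, 2.2, 6.7, 20,
#' 60 uM).
#'
#' @param concentrations Analyte concentrations (uM), strictly positive and
#'   distinct; at least 3.
#' @param responses Steady-state responses (RU), same length.
#' @param noise_sd Optional response noise estimate (RU), used for signal
#'   triage.
#' @return An object of class `spr_titration`.
#' @export
spr_titration <- function(concentrations, responses, noise_sd = NULL) {
  if (length(concentrations) != length(responses)) {
    stop("concentrations and responses must have the same length")
  }
  if (length(concentrations) < 3) stop("need at least 3 concentrations")
  if (any(!is.finite(concentrations)) || any(concentrations <= 0)) {
    stop("concentrations must be finite and strictly positive (uM)")
  }
  if (anyDuplicated(concentrations)) stop("concentrations must be distinct")
  if (any(!is.finite(responses))) stop("responses must be finite")
  structure(list(concentrations = as.numeric(concentrations),
                 responses = as.numeric(responses),
                 noise_sd = noise_sd),
            class = "spr_titration")
}

#' Default SPR concentration series (uM)
#'
#' The seven-point two-fold-ish dilution series used throughout the assay:
#' 0.08, 0.25, 0.7, 2.2, 6.7, 20 and 60 uM.
#'
#' @return Numeric vector of 7 concentrations (uM).
#' @export
spr_default_concentrations <- function() {
  c(0.08, 0.25, 0.7, 2.2, 6.7, 20, 60)
}

#' Fit SPR steady-state 1:1 binding isotherm
#'
#' Least-squares fit of the Langmuir isotherm
#' \deqn{R_{eq}(C) = \frac{R_{max} C}{K_D + C}}
#' to a steady-state titration, followed by signal triage
#' ([classify_spr_signal()]): `"quantified"`, `"weak"` (signal detected but
#' saturation not achieved) or `"n.d."` (signal not detected).
#'
#' @param tit An [spr_titration].
#' @param max_conc Highest concentration regarded as tested (uM); fitted KD
#'   beyond it means saturation was not achieved. Defaults to the highest
#'   concentration in the titration.
#' @param noise_sd Response noise (RU) for triage; defaults to
#'   `tit$noise_sd`, else 1 RU.
#' @return An object of class `spr_fit` with `KD` (uM), `Rmax` (RU), `rss`,
#'   `status`, `fitted`, `titration`.
#' @examples
#' conc <- spr_default_concentrations()
#' tit <- spr_titration(conc, 100 * conc / (10 + conc))
#' fit_spr_steady_state(tit)  # KD = 10, Rmax = 100
#' @export
fit_spr_steady_state <- function(tit, max_conc = NULL, noise_sd = NULL) {
  if (!inherits(tit, "spr_titration")) stop("tit must be an spr_titration")
  C <- tit$concentrations
  R <- tit$responses
  if (is.null(max_conc)) max_conc <- max(C)
  if (is.null(noise_sd)) noise_sd <- if (!is.null(tit$noise_sd)) tit$noise_sd else 1

  rmax0 <- max(R) * 1.5
  if (rmax0 <= 0) rmax0 <- 1
  half <- rmax0 / 2 / 1.5
  kd0 <- C[which.min(abs(R - half))]
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(C)

  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(logKD = log(kd0), logRmax = log(rmax0)),
      fn = function(p) R - exp(p[["logRmax"]]) * C / (exp(p[["logKD"]]) + C),
      control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                           maxiter = 500)
    ),
    error = function(e) NULL)

  converged <- !is.null(fit) && fit$info >= 1 && fit$info <= 4
  if (converged) {
    KD <- exp(fit$par[["logKD"]])
    Rmax <- exp(fit$par[["logRmax"]])
    rss <- sum(fit$fvec^2)
    fitted <- Rmax * C / (KD + C)
  } else {
    KD <- NA_real_; Rmax <- NA_real_; rss <- NA_real_; fitted <- rep(NA_real_, length(C))
  }
  out <- list(KD = KD, Rmax = Rmax, rss = rss, converged = converged,
              fitted = fitted, max_conc = max_conc, noise_sd = noise_sd,
              titration = tit, status = NA_character_)
  class(out) <- "spr_fit"
  out$status <- classify_spr_signal(tit, out, noise_sd = noise_sd,
                                    max_conc = max_conc)
  out
}

#' Triage an SPR titration by signal quality
#'
#' Implements the panel reporting rule: `"n.d."` (signal not detected) when
#' the maximal response stays below 3x the response noise; `"weak"` (signal
#' detected but saturation was not achieved) when the fit failed or the
#' fitted KD exceeds the highest tested concentration; `"quantified"`
#' otherwise.
#'
#' @param tit An [spr_titration].
#' @param fit An [fit_spr_steady_state()] result (possibly non-converged).
#' @param noise_sd Response noise (RU).
#' @param max_conc Highest tested concentration (uM).
#' @return One of `"n.d."`, `"weak"`, `"quantified"`.
#' @export
classify_spr_signal <- function(tit, fit, noise_sd = 1, max_conc = NULL) {
  if (is.null(max_conc)) max_conc <- max(tit$concentrations)
  if (max(tit$responses) < 3 * noise_sd) return("n.d.")
  if (!isTRUE(fit$converged) || !is.finite(fit$KD) || fit$KD > max_conc) {
    return("weak")
  }
  "quantified"
}

#' @export
print.spr_fit <- function(x, digits = 4, ...) {
  cat("SPR steady-state 1:1 affinity fit [", x$status, "]\n", sep = "")
  if (x$converged) {
    cat("  KD = ", format(x$KD, digits = digits), " uM,  Rmax = ",
        format(x$Rmax, digits = digits), " RU,  RSS = ",
        format(x$rss, digits = digits), "\n", sep = "")
  } else {
    cat("  fit did not converge\n")
  }
  invisible(x)
}

#' @export
coef.spr_fit <- function(object, ...) c(KD = object$KD, Rmax = object$Rmax)

#' @export
predict.spr_fit <- function(object, newdata = NULL, ...) {
  C <- if (is.null(newdata)) object$titration$concentrations else {
    if (is.list(newdata)) newdata$concentrations else newdata
  }
  object$Rmax * C / (object$KD + C)
}

#' @export
residuals.spr_fit <- function(object, ...) {
  object$titration$responses - object$fitted
}

#' @export
plot.spr_fit <- function(x, ...) {
  C <- x$titration$concentrations
  plot(C, x$titration$responses, log = "x", xlab = "concentration (uM)",
       ylab = "steady-state response (RU)",
       main = sprintf("KD = %.3g uM [%s]", x$KD, x$status), ...)
  cc <- exp(seq(log(min(C)), log(max(C)), length.out = 200))
  if (x$converged) lines(cc, x$Rmax * cc / (x$KD + cc))
  invisible(x)
}

#' Read an SPR titration table from CSV
#'
#' Expects columns `conc_uM`, `response_RU` and optionally `replicate`;
#' returns one [spr_titration] per replicate.
#'
#' @param path CSV file path.
#' @return List of [spr_titration] objects, named by replicate.
#' @export
read_spr_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("conc_uM", "response_RU")
  if (!all(need %in% names(df))) {
    stop("SPR CSV must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(df$replicate)) df$replicate <- 1
  lapply(split(df, df$replicate), function(d) {
    spr_titration(d$conc_uM, d$response_RU)
  })
}
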