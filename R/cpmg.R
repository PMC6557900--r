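#' CPMG relaxation series
#'
#' Container for a ligand-observed CPMG experiment: peak integrals measured
#' at a set of relaxation (filter) delays.
#'
#' @param delays Relaxation delays t (s); at least two distinct positive
#'   values.
#' @param intensities Peak integrals I(t) (arbitrary units); strictly
#'   positive.
#' @param label Optional condition tag, e.g. `"spy alone"` or
#'   `"spy + protein"`.
#' @return An object of class `cpmg_series`.
#' @export
cpmg_series <- function(delays, intensities, label = "") {
  if (length(delays) != length(intensities)) {
    stop("delays and intensities must have the same length")
  }
  if (length(unique(delays)) < 2) stop("need at least 2 distinct delays")
  if (any(!is.finite(delays)) || any(delays <= 0)) {
    stop("delays must be finite and positive (s)")
  }
  if (any(!is.finite(intensities)) || any(intensities <= 0)) {
    stop("intensities must be finite and positive for fitting")
  }
  structure(list(delays = as.numeric(delays),
                 intensities = as.numeric(intensities),
                 label = label),
            class = "cpmg_series")
}

#' @export
print.cpmg_series <- function(x, ...) {
  cat("CPMG series", if (nzchar(x$label)) paste0(" [", x$label, "]"), ": ",
      length(x$delays), " delays, t in [", min(x$delays), ", ",
      max(x$delays), "] s\n", sep = "")
  invisible(x)
}

#' Fit transverse relaxation time by mono-exponential decay
#'
#' Fits \eqn{I(t) = I(0) e^{-t/T_2}} to a CPMG series by nonlinear least
#' squares in intensity space (noise on peak integrals is closer to additive
#' than log-additive).  Starting values come from the log-linear regression
#' `log I ~ t`, which is already exact for noiseless data.
#'
#' @param series A [cpmg_series] (or anything coercible via
#'   `cpmg_series(delays, intensities)`).
#' @return An object of class `cpmg_fit` with components `I0` (fitted
#'   amplitude), `T2` (s), `R2` (s^-1, exactly `1/T2`), `rss`, `n`,
#'   `fitted`, `series`.
#' @seealso [cpmg_series()], [gen_cpmg_series()]
#' @examples
#' s <- cpmg_series(c(0.05, 0.1, 0.2, 0.4, 0.8), 1000 * exp(-c(0.05, 0.1, 0.2, 0.4, 0.8) / 0.25))
#' fit <- fit_t2(s)
#' fit$T2   # 0.25
#' fit$R2   # 4
#' @export
fit_t2 <- function(series) {
  if (!inherits(series, "cpmg_series")) {
    stop("series must be a cpmg_series object")
  }
  t <- series$delays
  y <- series$intensities

  # log-linear initialization: log I = log I0 - t/T2
  init <- stats::lm.fit(cbind(1, t), log(y))$coefficients
  I0_0 <- exp(init[[1]])
  rate0 <- -init[[2]]
  if (!is.finite(rate0) || rate0 <= 0) rate0 <- 1 / max(t)

  fit <- minpack.lm::nls.lm(
    par = c(logI0 = log(I0_0), logR2 = log(rate0)),
    fn = function(p) y - exp(p[["logI0"]]) * exp(-t * exp(p[["logR2"]])),
    control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                         maxiter = 200)
  )
  if (fit$info < 1 || fit$info > 4) {
    stop("T2 fit did not converge: ", fit$message)
  }
  I0 <- exp(fit$par[["logI0"]])
  R2 <- exp(fit$par[["logR2"]])
  out <- list(I0 = I0, T2 = 1 / R2, R2 = R2,
              rss = sum(fit$fvec^2), n = length(t),
              fitted = I0 * exp(-t * R2), series = series)
  class(out) <- "cpmg_fit"
  out
}

#' @export
print.cpmg_fit <- function(x, digits = 4, ...) {
  cat("Mono-exponential CPMG relaxation fit",
      if (nzchar(x$series$label)) paste0(" [", x$series$label, "]"), "\n",
      sep = "")
  cat("  I(0) = ", format(x$I0, digits = digits),
      ",  T2 = ", format(x$T2, digits = digits), " s",
      ",  R2 = ", format(x$R2, digits = digits), " s^-1\n", sep = "")
  cat("  RSS = ", format(x$rss, digits = digits), " on ", x$n, " points\n",
      sep = "")
  invisible(x)
}

#' @export
coef.cpmg_fit <- function(object, ...) {
  c(I0 = object$I0, T2 = object$T2, R2 = object$R2)
}

#' @export
predict.cpmg_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$series$delays else {
    if (is.list(newdata)) newdata$delays else newdata
  }
  object$I0 * exp(-t * object$R2)
}

#' @export
residuals.cpmg_fit <- function(object, ...) {
  object$series$intensities - object$fitted
}

#' @export
plot.cpmg_fit <- function(x, ...) {
  t <- x$series$delays
  plot(t, x$series$intensities, xlab = "CPMG delay (s)",
       ylab = "peak integral (a.u.)",
       main = sprintf("T2 = %.3g s (R2 = %.3g s^-1)", x$T2, x$R2), ...)
  tt <- seq(0, max(t), length.out = 200)
  lines(tt, x$I0 * exp(-tt * x$R2))
  invisible(x)
}

#' Read CPMG series from CSV
#'
#' Expects columns `delay_s`, `intensity` and optionally `label`; one series
#' per label.
#'
#' @param path CSV file path.
#' @return A list of [cpmg_series], one per distinct label.
#' @export
read_cpmg_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("delay_s", "intensity")
  if (!all(need %in% names(df))) {
    stop("CPMG CSV must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(df$label)) df$label <- ""
  lapply(split(df, df$label), function(d) {
    cpmg_series(d$delay_s, d$intensity, label = d$label[1])
  })
}

#' Write CPMG series to CSV
#'
#' @param series A [cpmg_series] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cpmg_csv <- function(series, path) {
  if (inherits(series, "cpmg_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, function(s) {
    data.frame(delay_s = s$delays, intensity = s$intensities,
               label = s$label)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
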