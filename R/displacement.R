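#' Fraction of spy-complex remaining from an integral triplet
#'
#' Converts the three measured 19F peak integrals of a displacement
#' experiment into the fraction of protein--spy complex remaining,
#' \deqn{f = \frac{I_F - I_I}{I_F - I_P} = \frac{[PL]}{[PL_0]},}
#' where `IF` is the spy integral free in solution, `IP` with protein, and
#' `II` with protein plus competitor.
#'
#' @param IF,IP,II Peak integrals (a.u.), all positive.
#' @param window_min Minimum assay window `(IF - IP)/IF` (default 0.1):
#'   below this the triplet carries no usable displacement information.
#' @param clamp_tol Tolerance for clamping f into `[0, 1]` (default 0.05);
#'   values further outside raise an error.
#' @return List with `f` (in `[0, 1]`) and `flag` (`"ok"` or `"clamped"`).
#' @export
fraction_spy_bound <- function(IF, IP, II, window_min = 0.1,
                               clamp_tol = 0.05) {
  if (any(!is.finite(c(IF, IP, II))) || any(c(IF, IP, II) <= 0)) {
    stop("integrals IF, IP, II must be finite and positive")
  }
  window <- (IF - IP) / IF
  if (window < window_min) {
    stop("no assay window: (IF - IP)/IF = ", format(window),
         " below minimum ", window_min)
  }
  f <- (IF - II) / (IF - IP)
  flag <- "ok"
  if (f < 0 || f > 1) {
    if (f >= -clamp_tol && f <= 1 + clamp_tol) {
      f <- min(max(f, 0), 1)
      flag <- "clamped"
    } else {
      stop("displacement fraction f = ", format(f),
           " outside [", -clamp_tol, ", ", 1 + clamp_tol, "]")
    }
  }
  list(f = f, flag = flag)
}

#' Competitor Ki from a displacement integral triplet
#'
#' Full inference pipeline of the ligand-observed 19F displacement assay:
#' the competitor-free spy complex `PL0` is computed from the two-component
#' quadratic, the observed complex `PL = f * PL0` from the integral triplet,
#' the bound competitor `PI` by closed-form inversion of the competitive
#' quadratic, and finally
#' \eqn{K_i = (P_0 - PI - PL)(I_0 - PI)/PI}.
#'
#' Censoring: a triplet showing no displacement (`f = 1`) cannot bound Ki
#' from above, and complete displacement (`f = 0`) cannot bound it from
#' below.  In those cases `Ki` is `NA` and `ki_bound` carries the
#' quantitation limit computed at `f = 1 - censor_margin` resp.
#' `f = censor_margin` (explicit censoring rather than infinities).
#'
#' @param IF,IP,II Peak integrals (a.u.); see [fraction_spy_bound()].
#' @param P0 Total protein concentration (uM; assay default 5).
#' @param L0 Total spy concentration (uM; assay default 100).
#' @param KD Protein--spy dissociation constant (uM; assay default 50).
#' @param I0 Total competitor concentration (uM; assay default 10).
#' @param window_min,clamp_tol Passed to [fraction_spy_bound()].
#' @param censor_margin Displacement fraction margin defining the
#'   quantitation bounds (default 0.02).
#' @return An object of class `ki_result`: list with `Ki`, `PL0`, `f`,
#'   `PL`, `PI` (uM), `flag` (`"ok"`, `"clamped"`, `"no_displacement"`,
#'   `"complete_displacement"`) and `ki_bound` (uM, `NA` unless censored).
#' @examples
#' ki_from_displacement(100, 40, 63.59, P0 = 5, L0 = 100, KD = 50, I0 = 10)
#' @export
ki_from_displacement <- function(IF, IP, II, P0 = 5, L0 = 100, KD = 50,
                                 I0 = 10, window_min = 0.1,
                                 clamp_tol = 0.05, censor_margin = 0.02) {
  fr <- fraction_spy_bound(IF, IP, II, window_min = window_min,
                           clamp_tol = clamp_tol)
  pl0 <- solve_two_component(P0, L0, KD)
  f <- fr$f

  ki_at <- function(frac) {
    pl <- frac * pl0
    pi_ <- infer_competitor_bound(P0, L0, KD, pl)$PI
    ki_from_species(P0, I0, PI = pi_, PL = pl)
  }

  if (f >= 1) {
    # no displacement observed: Ki is only bounded from below
    res <- list(Ki = NA_real_, PL0 = pl0, f = 1, PL = pl0, PI = 0,
                flag = "no_displacement",
                ki_bound = ki_at(1 - censor_margin))
  } else if (f <= 0) {
    # complete displacement: Ki below the lower quantitation limit
    res <- list(Ki = NA_real_, PL0 = pl0, f = 0, PL = 0, PI = P0,
                flag = "complete_displacement",
                ki_bound = ki_at(censor_margin))
  } else {
    pl <- f * pl0
    inf <- infer_competitor_bound(P0, L0, KD, pl)
    ki <- ki_from_species(P0, I0, PI = inf$PI, PL = pl)
    flag <- if (fr$flag == "clamped" || inf$flag == "clamped") "clamped" else "ok"
    res <- list(Ki = ki, PL0 = pl0, f = f, PL = pl, PI = inf$PI,
                flag = flag, ki_bound = NA_real_)
  }
  class(res) <- "ki_result"
  res
}

#' @export
print.ki_result <- function(x, digits = 4, ...) {
  cat("Displacement Ki inference [", x$flag, "]\n", sep = "")
  cat("  f = ", format(x$f, digits = digits),
      ",  PL0 = ", format(x$PL0, digits = digits),
      " uM,  PL = ", format(x$PL, digits = digits),
      " uM,  PI = ", format(x$PI, digits = digits), " uM\n", sep = "")
  if (x$flag == "no_displacement") {
    cat("  Ki > ", format(x$ki_bound, digits = digits),
        " uM (no displacement; upper quantitation limit)\n", sep = "")
  } else if (x$flag == "complete_displacement") {
    cat("  Ki < ", format(x$ki_bound, digits = digits),
        " uM (complete displacement; lower quantitation limit)\n", sep = "")
  } else {
    cat("  Ki = ", format(x$Ki, digits = digits), " uM\n", sep = "")
  }
  invisible(x)
}

#' Aggregate replicate affinity measurements
#'
#' Arithmetic mean and standard error of the mean (sample sd / sqrt(n))
#' across independent replicate experiments, the convention used for
#' four-replicate panel reporting.
#'
#' @param values Numeric vector of per-replicate Ki or KD values (uM);
#'   `NA`s are dropped.
#' @return List with `mean`, `sem` (`NA` with `sem_defined = FALSE` when
#'   n = 1) and `n`.
#' @export
aggregate_replicates <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("no finite values to aggregate")
  n <- length(values)
  list(mean = mean(values),
       sem = if (n > 1) stats::sd(values) / sqrt(n) else NA_real_,
       sem_defined = n > 1,
       n = n)
}

#' Analyze a displacement table (per-replicate Ki, then aggregate)
#'
#' Runs [ki_from_displacement()] on every row of a displacement table and
#' aggregates per peptide with [aggregate_replicates()].  Replicates are
#' analyzed individually and then averaged; integrals are never averaged
#' before inference.
#'
#' @param df Data frame with columns `peptide_id`, `IF`, `IP`, `II`,
#'   `P0_uM`, `L0_uM`, `KD_spy_uM`, `I0_uM`, `replicate`.
#' @param ... Passed to [ki_from_displacement()].
#' @return A data frame with one row per peptide: `peptide_id`, `ki_mean`,
#'   `ki_sem`, `n_ok`, `n_replicates`, `flags` (comma-collapsed).
#' @export
analyze_displacement_table <- function(df, ...) {
  need <- c("peptide_id", "IF", "IP", "II", "P0_uM", "L0_uM",
            "KD_spy_uM", "I0_uM")
  if (!all(need %in% names(df))) {
    stop("displacement table must have columns: ",
         paste(need, collapse = ", "))
  }
  res <- lapply(split(df, df$peptide_id), function(d) {
    fits <- lapply(seq_len(nrow(d)), function(i) {
      ki_from_displacement(d$IF[i], d$IP[i], d$II[i], P0 = d$P0_uM[i],
                           L0 = d$L0_uM[i], KD = d$KD_spy_uM[i],
                           I0 = d$I0_uM[i], ...)
    })
    kis <- vapply(fits, function(f) f$Ki, numeric(1))
    flags <- vapply(fits, function(f) f$flag, character(1))
    ok <- is.finite(kis)
    agg <- if (any(ok)) aggregate_replicates(kis[ok]) else
      list(mean = NA_real_, sem = NA_real_, n = 0)
    data.frame(peptide_id = d$peptide_id[1],
               ki_mean = agg$mean, ki_sem = agg$sem,
               n_ok = sum(ok), n_replicates = nrow(d),
               flags = paste(flags, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Read a displacement table from CSV
#'
#' @param path CSV with the schema described in
#'   [analyze_displacement_table()].
#' @return Data frame.
#' @export
read_displacement_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
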