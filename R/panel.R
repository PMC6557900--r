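#' Load a peptide affinity panel
#'
#' Reads and validates a mutant-peptide panel table: one row per peptide,
#' with SPR dissociation constants (KD) and NMR displacement inhibition
#' constants (Ki), both as mean +/- s.e.m. across replicates.  Each panel
#' (e.g. the GHR-derived and EpoR-derived series) must contain exactly one
#' wild-type row, each sequence exactly one phosphotyrosine written `pY`,
#' and every position label must parse (see [parse_position_label()]).
#'
#' @param path CSV with columns `peptide_id`, `panel`, `sequence`,
#'   `position_label`, `kd_spr_uM`, `kd_spr_sem`, `ki_nmr_uM`,
#'   `ki_nmr_sem`.
#' @return A data frame of class `panel_table` with an added integer
#'   `offset` column (position relative to pY; `NA` for wild-type).
#' @export
load_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("peptide_id", "panel", "sequence", "position_label",
            "kd_spr_uM", "kd_spr_sem", "ki_nmr_uM", "ki_nmr_sem")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("panel table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$peptide_id)) {
    stop("duplicate peptide_ids: ",
         paste(unique(df$peptide_id[duplicated(df$peptide_id)]),
               collapse = ", "))
  }
  n_py <- vapply(df$sequence, function(s) {
    lengths(regmatches(s, gregexpr("pY", s, fixed = TRUE)))
  }, integer(1))
  if (any(n_py != 1)) {
    stop("sequences must contain exactly one pY; offending rows: ",
         paste(df$peptide_id[n_py != 1], collapse = ", "))
  }
  for (p in unique(df$panel)) {
    n_wt <- sum(df$position_label[df$panel == p] == "WT")
    if (n_wt != 1) {
      stop("panel ", p, " must contain exactly one wild-type row (found ",
           n_wt, ")")
    }
  }
  df$offset <- vapply(df$position_label, parse_position_label, numeric(1))
  class(df) <- c("panel_table", "data.frame")
  df
}

#' Parse a mutation position label into an offset relative to pY
#'
#' Labels follow the pY-relative convention: `"WT"` (wild-type, offset
#' `NA`), `"pY(+4)"` (alanine scan at pY+4), or `"V(-3)R"` (point mutation
#' at pY-3).  Both the ASCII hyphen and the typographic minus are accepted.
#'
#' @param label Position label string.
#' @return Integer offset (negative = N-terminal of pY), or `NA` for
#'   wild-type.
#' @export
parse_position_label <- function(label) {
  if (label == "WT") return(NA_real_)
  lab <- gsub("−", "-", label)
  m <- regmatches(lab, regexec("\\(([+-]?[0-9]+)\\)", lab))[[1]]
  if (length(m) < 2) stop("cannot parse position label: ", label)
  as.numeric(m[2])
}

#' Packaged mutant-panel fixture
#'
#' The 23-peptide two-panel fixture shipped with the package (13 GHR-derived
#' and 10 EpoR-derived peptides: wild-types, two V(-3) point mutants and a
#' full alanine scan), with SPR KD and NMR Ki means +/- s.e.m. from
#' four-replicate measurements.
#'
#' @return A `panel_table` (see [load_panel()]).
#' @export
reference_panel <- function() {
  load_panel(system.file("extdata", "peptide_panel.csv",
                         package = "bindfit", mustWork = TRUE))
}

#' Cross-assay concordance of a panel
#'
#' Pearson correlation between the two orthogonal affinity measurements
#' (SPR KD and NMR Ki), by default on log10-transformed values pooled
#' across panels — affinities are log-normally distributed, and the
#' correlation of their logs is the standard agreement measure for
#' orthogonal binding assays.
#'
#' @param panel A `panel_table`.
#' @param transform `"log10"` (default) or `"none"`.
#' @param pool `"both_panels"` (default) or a panel name to restrict to.
#' @return An object of class `concordance_report`: list with `n`, `r`,
#'   `r_squared`, `transform`.
#' @examples
#' assay_concordance(reference_panel())  # R^2 ~ 0.74
#' @export
assay_concordance <- function(panel, transform = c("log10", "none"),
                              pool = "both_panels") {
  transform <- match.arg(transform)
  df <- as.data.frame(panel)
  if (!identical(pool, "both_panels")) df <- df[df$panel %in% pool, ]
  ok <- is.finite(df$kd_spr_uM) & is.finite(df$ki_nmr_uM)
  df <- df[ok, ]
  if (nrow(df) < 3) stop("need at least 3 records with both assay values")
  x <- df$kd_spr_uM
  y <- df$ki_nmr_uM
  if (transform == "log10") {
    x <- log10(x); y <- log10(y)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in an assay column; correlation undefined")
  }
  r <- stats::cor(x, y)
  out <- list(n = nrow(df), r = r, r_squared = r^2, transform = transform)
  class(out) <- "concordance_report"
  out
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Cross-assay concordance (KD vs Ki, ", x$transform, " scale):\n",
      sep = "")
  cat(sprintf("  n = %d pairs, r = %.3f, R^2 = %.2f\n", x$n, x$r,
              x$r_squared))
  invisible(x)
}

#' Per-peptide fold-changes relative to wild-type
#'
#' Computes, for every peptide and each assay, the affinity ratio
#' mutant/wild-type within its panel.  A fold-change above 1 means weakened
#' binding (larger dissociation constant).
#'
#' @param panel A `panel_table`.
#' @return Data frame with `peptide_id`, `panel`, `position_label`,
#'   `offset`, `fc_spr`, `fc_nmr` (fold-changes; `NA` where a value is
#'   missing).
#' @examples
#' fc <- fold_changes(reference_panel())
#' fc[fc$peptide_id == "GHR_V-3R", ]  # 6-fold by SPR
#' @export
fold_changes <- function(panel) {
  df <- as.data.frame(panel)
  out <- do.call(rbind, lapply(split(df, df$panel), function(d) {
    wt <- d[d$position_label == "WT", ]
    if (nrow(wt) != 1 || !is.finite(wt$kd_spr_uM) || !is.finite(wt$ki_nmr_uM)) {
      stop("panel ", d$panel[1], " lacks a wild-type row with finite values")
    }
    data.frame(peptide_id = d$peptide_id, panel = d$panel,
               position_label = d$position_label, offset = d$offset,
               fc_spr = d$kd_spr_uM / wt$kd_spr_uM,
               fc_nmr = d$ki_nmr_uM / wt$ki_nmr_uM,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Call binding hotspots from an alanine scan
#'
#' Identifies peptide positions whose alanine substitution weakens binding
#' by at least `threshold`-fold.  The default combination rule takes the
#' geometric mean of the two assays' fold-changes — a position is a hotspot
#' only when the loss of affinity is supported jointly by both orthogonal
#' measurements.  Alternatives: `"either"` (at least threshold-fold in at
#' least one assay) and `"both"` (in each assay separately).  Only
#' alanine-scan rows (labels of the form `pY(+/-n)`) are scanned; wild-type
#' and non-alanine point mutants are excluded.
#'
#' @param panel A `panel_table`, or a fold-change table from
#'   [fold_changes()].
#' @param rule `"geometric_mean"` (default), `"either"` or `"both"`.
#' @param threshold Fold-change threshold (default 2).
#' @return An object of class `hotspot_report`: list with `table` (per
#'   scanned position: panel, label, offset, per-assay fold-changes,
#'   combined `score`, logical `hotspot`), `hotspots` (named list of called
#'   position labels per panel), `rule`, `threshold`.
#' @examples
#' call_hotspots(reference_panel())
#' @export
call_hotspots <- function(panel, rule = c("geometric_mean", "either", "both"),
                          threshold = 2) {
  rule <- match.arg(rule)
  fc <- if (inherits(panel, "panel_table")) fold_changes(panel) else panel
  scan <- fc[grepl("^pY\\(", fc$position_label), ]
  if (any(!is.finite(scan$fc_spr) | !is.finite(scan$fc_nmr))) {
    stop("both assays' fold-changes must be available at scanned positions")
  }
  score <- switch(rule,
    geometric_mean = sqrt(scan$fc_spr * scan$fc_nmr),
    either = pmax(scan$fc_spr, scan$fc_nmr),
    both = pmin(scan$fc_spr, scan$fc_nmr))
  tab <- data.frame(panel = scan$panel, position_label = scan$position_label,
                    offset = scan$offset, fc_spr = scan$fc_spr,
                    fc_nmr = scan$fc_nmr, score = score,
                    hotspot = score >= threshold, stringsAsFactors = FALSE)
  tab <- tab[order(tab$panel, tab$offset), ]
  rownames(tab) <- NULL
  hotspots <- lapply(split(tab, tab$panel), function(d) {
    d$position_label[d$hotspot]
  })
  out <- list(table = tab, hotspots = hotspots, rule = rule,
              threshold = threshold)
  class(out) <- "hotspot_report"
  out
}

#' @export
print.hotspot_report <- function(x, digits = 3, ...) {
  cat("Alanine-scan hotspot report (rule: ", x$rule, " >= ", x$threshold,
      ")\n", sep = "")
  for (p in names(x$hotspots)) {
    cat("  ", p, ": ",
        if (length(x$hotspots[[p]])) paste(x$hotspots[[p]], collapse = ", ")
        else "(none)", "\n", sep = "")
  }
  print(x$table, digits = digits)
  invisible(x)
}

#' Write a panel table to CSV
#'
#' @param panel A `panel_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  df <- as.data.frame(panel)
  df$offset <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
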