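#' Druggability score of a binding site
#'
#' Evaluates `Dscore = 0.094*sqrt(n) + 0.60*e - 0.324*p` exactly, with no
#' clamping, from the three pocket descriptors: site-point count `n`,
#' enclosure factor `e` and hydrophilicity factor `p`.
#'
#' @param n site-point count (>= 0).
#' @param e enclosure factor in \[0, 1\].
#' @param p hydrophilicity factor (>= 0).
#' @return numeric Dscore (vectorised).
#' @examples
#' dscore(54, 0.66, 0.28) # 0.996, the HDM2 median
#' @export
dscore <- function(n, e, p) {
  if (any(n < 0, na.rm = TRUE) || any(e < 0, na.rm = TRUE) || any(p < 0, na.rm = TRUE)) {
    .err("ppidrugg_domain", "n, e and p must be non-negative")
  }
  0.094 * sqrt(n) + 0.60 * e - 0.324 * p
}

.PPI_CLASSES <- c("very druggable", "druggable", "moderately druggable", "difficult")

#' Four-class PPI druggability classification
#'
#' The PPI-specific scheme: Dscore >= 1.0 very druggable; >= 0.75 and
#' < 1.0 druggable; >= 0.5 and < 0.75 moderately druggable; < 0.5
#' difficult. A site that was not detected (`NA` score, the ND state)
#' classifies as difficult; where a plot or correlation needs a number, ND
#' carries the surrogate value 0.
#'
#' @param score numeric Dscore(s); `NA` encodes ND.
#' @return character vector of class labels.
#' @examples
#' classify_ppi(c(1.20, 0.93, 0.60, NA))
#' @export
classify_ppi <- function(score) {
  if (any(score < 0, na.rm = TRUE)) .err("ppidrugg_domain", "score must be >= 0 or ND (NA)")
  out <- ifelse(is.na(score), "difficult",
    ifelse(score >= 1.0, "very druggable",
      ifelse(score >= 0.75, "druggable",
        ifelse(score >= 0.5, "moderately druggable", "difficult")
      )
    )
  )
  out
}

#' Halgren's three-class druggability classification
#'
#' The original SiteMap interpretation: Dscore < 0.8 difficult, >= 1.0
#' very druggable, druggable in between. (The published rule says
#' "greater than 1"; the boundary is taken as inclusive here for
#' consistency with the four-class scheme.)
#'
#' @param score numeric Dscore(s) >= 0; `NA` (ND) maps to difficult.
#' @return character vector of class labels.
#' @export
classify_halgren <- function(score) {
  if (any(score < 0, na.rm = TRUE)) .err("ppidrugg_domain", "score must be >= 0")
  ifelse(is.na(score) | score < 0.8, "difficult",
    ifelse(score >= 1.0, "very druggable", "druggable")
  )
}

#' Assemble a per-structure druggability record
#'
#' @param structure_id label of the crystal structure.
#' @param target protein target label.
#' @param form one of `"apo"`, `"protein_peptide_bound"`, `"ligand_bound"`.
#' @param descriptors a `site_descriptors` object from [detect_site()],
#'   or a list with fields `detected`, `n`, `e`, `p`.
#' @return one-row data.frame with descriptors, Dscore and both class
#'   labels (`dscore` is `NA` for ND records, which classify as difficult).
#' @export
druggability_record <- function(structure_id, target, form, descriptors) {
  form <- match.arg(form, c("apo", "protein_peptide_bound", "ligand_bound"))
  det <- isTRUE(descriptors$detected)
  ds <- if (det) dscore(descriptors$n, descriptors$e, descriptors$p) else NA_real_
  data.frame(
    structure_id = structure_id, target = target, form = form,
    detected = det,
    n = if (det) descriptors$n else NA_integer_,
    e = if (det) descriptors$e else NA_real_,
    p = if (det) descriptors$p else NA_real_,
    dscore = ds,
    ppi_class = classify_ppi(ds),
    halgren_class = classify_halgren(ds),
    stringsAsFactors = FALSE
  )
}

#' Per-target summary statistics
#'
#' Median, sample standard deviation (n - 1 denominator), minimum and
#' maximum of Dscore and of the three descriptors, per structural form and
#' overall. The even-count median is the mean of the two middle values
#' (which is how half-integer pocket sizes such as 19.5 or 50.5 arise).
#' ND records are counted but excluded from the statistics. Single-record
#' groups report `NA` standard deviation.
#'
#' @param records data.frame of druggability records (see
#'   [druggability_record()]); may span several targets.
#' @return data.frame of class `target_summary`, one row per target x
#'   form (plus an `"overall"` row per target).
#' @export
aggregate_target <- function(records) {
  if (!nrow(records)) .err("ppidrugg_invalid", "no records to aggregate")
  stat_row <- function(df, target, form) {
    ok <- df$detected
    one <- function(v) {
      v <- v[ok]
      if (!length(v)) {
        c(median = NA_real_, sd = NA_real_, min = NA_real_, max = NA_real_)
      } else {
        c(
          median = median(v), sd = if (length(v) > 1) sd(v) else NA_real_,
          min = min(v), max = max(v)
        )
      }
    }
    vals <- c(dscore = list(one(df$dscore)), n = list(one(df$n)),
      e = list(one(df$e)), p = list(one(df$p)))
    out <- data.frame(
      target = target, form = form, n_structures = nrow(df),
      n_nd = sum(!ok), stringsAsFactors = FALSE
    )
    for (v in names(vals)) {
      s <- vals[[v]]
      out[[paste0("median_", v)]] <- s[["median"]]
      out[[paste0("sd_", v)]] <- s[["sd"]]
      out[[paste0("min_", v)]] <- s[["min"]]
      out[[paste0("max_", v)]] <- s[["max"]]
    }
    out
  }
  res <- list()
  for (tg in unique(records$target)) {
    sub <- records[records$target == tg, , drop = FALSE]
    res[[length(res) + 1]] <- stat_row(sub, tg, "overall")
    for (fm in intersect(c("apo", "protein_peptide_bound", "ligand_bound"), unique(sub$form))) {
      res[[length(res) + 1]] <- stat_row(sub[sub$form == fm, , drop = FALSE], tg, fm)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("target_summary", class(out))
  out
}

#' Percent reduction of a median score
#'
#' `round(100 * (reference - other) / reference)` to the nearest integer —
#' the arithmetic behind statements like "a 33% decrease in median Dscore
#' relative to the ligand-bound form".
#'
#' @param reference_median reference (e.g. ligand-bound) median, > 0.
#' @param other_median comparison (e.g. apo) median.
#' @return integer percentage.
#' @examples
#' percent_reduction(1.09, 0.73) # 33
#' @export
percent_reduction <- function(reference_median, other_median) {
  if (any(reference_median <= 0)) .err("ppidrugg_domain", "reference median must be positive")
  round(100 * (reference_median - other_median) / reference_median)
}

#' Pearson correlation and coefficient of determination
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#'   `NA` pairs are dropped; if `nd_as_zero` is `TRUE`, `NA` values are
#'   instead imputed as 0 first (the plotting convention for ND targets).
#' @param x_name,y_name labels carried into the result.
#' @param nd_as_zero impute `NA` (ND) as 0 instead of dropping.
#' @return object of class `correlation_result`: list with `r`, `r2`,
#'   `n_points` and the labels.
#' @export
pearson_r2 <- function(x, y, x_name = deparse(substitute(x)),
                       y_name = deparse(substitute(y)), nd_as_zero = FALSE) {
  if (length(x) != length(y)) .err("ppidrugg_invalid", "x and y lengths differ")
  if (nd_as_zero) {
    x[is.na(x)] <- 0
    y[is.na(y)] <- 0
  }
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) .err("ppidrugg_invalid", "need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) .err("ppidrugg_undefined_correlation", "constant series")
  r <- cor(x, y)
  structure(list(x_name = x_name, y_name = y_name, r = r, r2 = r^2,
    n_points = length(x)), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(
    "<correlation_result> %s vs %s: r = %.3f, R2 = %.3f (n = %d)\n",
    x$x_name, x$y_name, x$r, x$r2, x$n_points
  ))
  invisible(x)
}

#' Convert IC50 to pIC50
#'
#' @param ic50 half-maximal inhibitory concentration in molar units, > 0.
#' @return `-log10(ic50)` (vectorised).
#' @examples
#' pic50(50e-9) # 7.301
#' @export
pic50 <- function(ic50) {
  if (any(ic50 <= 0, na.rm = TRUE)) .err("ppidrugg_domain", "IC50 must be positive")
  -log10(ic50)
}
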