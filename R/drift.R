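# Reference-peptide drift normalization.
#
# A constant amount of a 6-peptide x 5-level tenfold isotopologue mix is
# spiked into every injection. Because the nominal amount never changes,
# any trend of the reference signal across the injection sequence is
# technical drift. Each reference peptide's areas are scaled to intensity
# ratios IR_ij = A_ij / mean_j(A_ij); the per-injection mean ratio over the
# selected calibration peptides, IR-bar_j, yields a multiplicative
# correction factor CF_j = 1 / IR-bar_j applied to every peptide quantity
# of injection j.

#' Select calibration reference peptides by linearity
#'
#' Ranks reference peptides by the coefficient of determination (R^2) of an
#' ordinary least-squares fit of peak area against injection index, and
#' keeps the `k` most linear ones (ties broken by peptide id). Mirrors the
#' practice of calibrating on the reference peptides with the most linear
#' signal change across the run sequence.
#'
#' @param area matrix of reference peak areas, peptides x injections.
#' @param k number of peptides to select.
#' @return integer vector of selected row indices, sorted.
#' @export
select_reference_peptides <- function(area, k = 4) {
  ok <- apply(area, 1, function(x) all(is.finite(x)) && any(x > 0))
  if (sum(ok) < k)
    insufficient_data_error(sprintf(
      "only %d reference peptide(s) with nonzero areas; %d required",
      sum(ok), k))
  j <- seq_len(ncol(area))
  r2 <- apply(area, 1, function(x) {
    if (stats::sd(x) == 0) return(0)
    stats::cor(x, j)^2
  })
  r2[!ok] <- -Inf
  sort(order(-r2, seq_along(r2))[seq_len(k)])
}

#' Build a reference panel from spike-in areas
#'
#' Assembles the drift-calibration bookkeeping from a long-format reference
#' table: the area matrix at the calibration dilution level, per-peptide
#' mean areas, intensity ratios, per-injection mean ratios over the
#' selected peptides, and correction factors.
#'
#' @param reference long data.frame (injection_index, peptide_set, level,
#'   area) as produced by [generate_transitions()].
#' @param level calibration dilution level index (default 3, the 0.01x
#'   isotopologue of the tenfold series 0.0001x..1x).
#' @param k number of calibration peptides.
#' @param selected optional explicit peptide-set indices, bypassing the
#'   R^2 ranking.
#' @return object of class `reference_panel`: list(area, peptide_mean, ir,
#'   selected, injection_mean_ratio, correction_factor, level).
#' @export
reference_panel <- function(reference, level = 3, k = 4, selected = NULL) {
  sub <- reference[reference$level == level, ]
  if (nrow(sub) == 0)
    config_error(sprintf("no reference rows at level %s", level))
  sets <- sort(unique(sub$peptide_set))
  inj <- sort(unique(sub$injection_index))
  area <- matrix(NA_real_, length(sets), length(inj),
                 dimnames = list(paste0("ref", sets), inj))
  area[cbind(match(sub$peptide_set, sets), match(sub$injection_index, inj))] <-
    sub$area
  if (anyNA(area))
    validation_error("reference panel is not complete over injections")
  if (is.null(selected)) selected <- select_reference_peptides(area, k = k)
  peptide_mean <- rowMeans(area)
  if (any(peptide_mean[selected] <= 0))
    validation_error("selected reference peptide with nonpositive mean area")
  ir <- area / peptide_mean
  imr <- colMeans(ir[selected, , drop = FALSE])
  if (any(imr <= 0))
    validation_error("degenerate reference: nonpositive mean intensity ratio")
  structure(list(area = area, peptide_mean = peptide_mean, ir = ir,
                 selected = selected, injection_mean_ratio = imr,
                 correction_factor = 1 / imr, level = level),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf(
    "reference_panel: %d peptides x %d injections (level %s), selected: %s\n",
    nrow(x$area), ncol(x$area), x$level,
    paste(rownames(x$area)[x$selected], collapse = ", ")))
  fit <- fit_drift(x)
  cat(sprintf("  drift fit: slope %.5f, intercept %.4f, R^2 %.3f\n",
              fit$slope, fit$intercept, fit$r_squared))
  invisible(x)
}

#' Fit the linear drift of mean intensity ratios
#'
#' Ordinary least-squares regression of the per-injection mean intensity
#' ratio on the 1-based injection index. Accepts either a
#' [reference_panel()] (uses its mean-ratio series) or a bare numeric ratio
#' series. The fit is a drift diagnostic; correction factors use the
#' observed per-injection ratios, not the fitted line.
#'
#' @param x reference_panel or numeric vector of mean ratios.
#' @return object of class `drift_fit`: list(slope, intercept, r_squared).
#' @export
fit_drift <- function(x) {
  y <- if (inherits(x, "reference_panel")) x$injection_mean_ratio
       else as.numeric(x)
  n <- length(y)
  if (n < 3) insufficient_data_error("at least 3 injections required")
  j <- seq_len(n)
  slope <- sum((j - mean(j)) * (y - mean(y))) / sum((j - mean(j))^2)
  intercept <- mean(y) - slope * mean(j)
  tss <- sum((y - mean(y))^2)
  rss <- sum((y - intercept - slope * j)^2)
  r2 <- if (tss <= 0) 1 else max(0, min(1, 1 - rss / tss))
  structure(list(slope = slope, intercept = intercept, r_squared = r2),
            class = "drift_fit")
}

#' @export
print.drift_fit <- function(x, ...) {
  cat(sprintf("drift_fit: y = %.6f %+.6f * j, R^2 = %.4f\n",
              x$intercept, x$slope, x$r_squared))
  invisible(x)
}

#' Per-injection correction factors
#'
#' CF_j = 1 / IR-bar_j, the reciprocal of the mean intensity ratio of the
#' selected reference peptides at injection j. Multiplying injection j's
#' quantities by CF_j flattens the reference ratio series to mean 1 (a
#' refit drift line has slope zero).
#'
#' @param x reference_panel or numeric vector of mean intensity ratios.
#' @return numeric vector of correction factors, one per injection, named
#'   by injection index when available.
#' @export
compute_correction_factors <- function(x) {
  imr <- if (inherits(x, "reference_panel")) x$injection_mean_ratio
         else as.numeric(x)
  if (any(!is.finite(imr) | imr <= 0))
    validation_error("mean intensity ratios must be positive and finite")
  1 / imr
}

#' Apply correction factors to a peptide matrix
#'
#' Multiplies every peptide quantity by its injection's correction factor.
#' Zeros (missing values) stay zero.
#'
#' @param m peptide-level [abundance_matrix()] with an `injection`
#'   attribute (column -> injection index), or a bare matrix with
#'   `injection` supplied.
#' @param cf correction factors named by injection index (or positionally
#'   indexed 1..N).
#' @param injection optional integer vector mapping columns to injections.
#' @return the corrected matrix with stage flag "corrected".
#' @export
apply_correction <- function(m, cf, injection = NULL) {
  if (is.null(injection)) injection <- attr(m, "injection")
  if (is.null(injection)) injection <- seq_len(ncol(m))
  if (length(injection) != ncol(m))
    mapping_error("injection mapping length does not match matrix columns")
  key <- if (!is.null(names(cf))) match(as.character(injection), names(cf))
         else match(injection, seq_along(cf))
  if (anyNA(key))
    mapping_error(sprintf(
      "no correction factor for injection(s) %s",
      paste(utils::head(injection[is.na(key)], 5), collapse = ", ")))
  out <- sweep(unclass_matrix(m), 2, as.numeric(cf)[key], "*")
  if (inherits(m, "abundance_matrix")) {
    res <- abundance_matrix(out, level = attr(m, "level"),
                            stages = union(attr(m, "stages"), "corrected"))
    attr(res, "injection") <- attr(m, "injection")
    attr(res, "peptide_map") <- attr(m, "peptide_map")
    res
  } else out
}

#' Percent coefficient of variation
#'
#' 100 x sample standard deviation (n-1 denominator) divided by the mean.
#'
#' @param values numeric vector with at least 2 values and nonzero mean.
#' @return CV in percent.
#' @export
percent_cv <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2)
    insufficient_data_error("at least 2 values required for a CV")
  m <- mean(values)
  if (m == 0) validation_error("CV undefined for mean zero")
  100 * stats::sd(values) / m
}

#' Reference CV diagnostic
#'
#' Mean percent CV of the selected reference peptides' areas across
#' injections, before or after applying the panel's correction factors.
#' The drift correction is expected to reduce this CV.
#'
#' @param panel a [reference_panel()].
#' @param corrected apply correction factors first?
#' @return mean percent CV across selected peptides.
#' @export
reference_cv <- function(panel, corrected = FALSE) {
  a <- panel$area[panel$selected, , drop = FALSE]
  if (corrected) a <- sweep(a, 2, panel$correction_factor, "*")
  mean(apply(a, 1, percent_cv))
}

# strip abundance_matrix class/attrs down to the numeric matrix
unclass_matrix <- function(m) {
  out <- unclass(m)
  attributes(out) <- list(dim = dim(m), dimnames = dimnames(m))
  out
}
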