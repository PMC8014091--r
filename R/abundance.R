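# Abundance matrices and the protein-level preprocessing pipeline:
# roll-up -> half-minimum imputation -> log2 -> covariate residualization.
# Stage flags advance strictly in that order.

.stage_order <- c("corrected", "imputed", "log2", "residualized")

#' Abundance matrix container
#'
#' A numeric entities x samples matrix carrying its level (peptide or
#' protein) and ordered preprocessing stage flags
#' (corrected / imputed / log2 / residualized).
#'
#' @param values numeric matrix, entities in rows.
#' @param level "peptide" or "protein".
#' @param stages character vector of completed stages.
#' @return object of class `abundance_matrix` (a matrix with attributes).
#' @export
abundance_matrix <- function(values, level = c("peptide", "protein"),
                             stages = character()) {
  level <- match.arg(level)
  stopifnot(is.matrix(values))
  bad <- setdiff(stages, .stage_order)
  if (length(bad)) config_error(sprintf("unknown stage(s): %s",
                                        paste(bad, collapse = ", ")))
  structure(values, level = level,
            stages = .stage_order[.stage_order %in% stages],
            class = c("abundance_matrix", class(values)))
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d %s(s) x %d sample(s); stages: %s\n",
              nrow(x), attr(x, "level"), ncol(x),
              if (length(attr(x, "stages")))
                paste(attr(x, "stages"), collapse = " -> ") else "(raw)"))
  invisible(x)
}

.has_stage <- function(m, stage) stage %in% attr(m, "stages")

.require_stage_before <- function(m, stage, op) {
  if (.has_stage(m, stage))
    ordering_error(sprintf("%s must run before the %s stage", op, stage))
}

#' Roll peptide quantities up to proteins
#'
#' Protein (entity) quantity per sample is the sum of its peptides'
#' corrected quantities. Every peptide must map to exactly one roll-up
#' entity (via the target list or the matrix's `peptide_map` attribute).
#'
#' @param m peptide-level abundance matrix.
#' @param targets target list data.frame (protein, peptide), or NULL to use
#'   the `peptide_map` attribute.
#' @return protein-level [abundance_matrix()] inheriting stage flags and
#'   the `injection` attribute.
#' @export
rollup_proteins <- function(m, targets = NULL) {
  if (attr(m, "level") != "peptide")
    ordering_error("rollup_proteins expects a peptide-level matrix")
  map <- if (!is.null(targets)) {
    tg <- targets[!isTRUE(targets$is_reference) & !targets$is_reference, ]
    stats::setNames(tg$protein, tg$peptide)
  } else attr(m, "peptide_map")
  if (is.null(map)) mapping_error("no peptide-to-protein mapping available")
  prot <- map[rownames(m)]
  if (anyNA(prot))
    mapping_error(sprintf(
      "unmapped peptide(s): %s",
      paste(utils::head(rownames(m)[is.na(prot)], 5), collapse = ", ")))
  vals <- rowsum(unclass_matrix(m), group = prot)
  vals <- vals[order(rownames(vals)), , drop = FALSE]
  out <- abundance_matrix(vals, level = "protein",
                          stages = attr(m, "stages"))
  attr(out, "injection") <- attr(m, "injection")
  out
}

#' Half-minimum imputation of missing (zero) values
#'
#' Replaces each zero by one half of the row's minimum nonzero value, the
#' conventional noise-floor imputation for rare missing values in targeted
#' proteomics. Rows with no nonzero value cannot define a half-minimum and
#' are dropped with a warning naming them. Must run before log2.
#'
#' @param m abundance matrix (peptide or protein level, pre-log).
#' @return the imputed matrix with stage flag "imputed", an `imputed_mask`
#'   attribute and an `imputation_report` attribute
#'   (list: n_imputed, n_total, fraction, dropped).
#' @export
impute_half_min <- function(m) {
  .require_stage_before(m, "log2", "impute_half_min")
  .require_stage_before(m, "imputed", "impute_half_min (already imputed)")
  vals <- unclass_matrix(m)
  all_zero <- rowSums(vals > 0) == 0
  dropped <- rownames(vals)[all_zero]
  if (length(dropped)) {
    warning(sprintf("dropping %d all-zero row(s): %s", length(dropped),
                    paste(utils::head(dropped, 5), collapse = ", ")))
    vals <- vals[!all_zero, , drop = FALSE]
  }
  mask <- vals == 0
  if (any(mask)) {
    half_min <- apply(vals, 1, function(x) min(x[x > 0]) / 2)
    # column-major recycling: linear index k maps to row (k-1) %% n + 1
    vals[mask] <- rep(half_min, ncol(vals))[which(mask)]
  }
  out <- abundance_matrix(vals, level = attr(m, "level"),
                          stages = union(attr(m, "stages"), "imputed"))
  attr(out, "imputed_mask") <- mask
  attr(out, "injection") <- attr(m, "injection")
  attr(out, "imputation_report") <- list(
    n_imputed = sum(mask), n_total = length(vals),
    fraction = sum(mask) / length(vals), dropped = dropped)
  out
}

#' Imputation report accessor
#' @param m an imputed abundance matrix.
#' @return list(n_imputed, n_total, fraction, dropped).
#' @export
imputation_report <- function(m) attr(m, "imputation_report")

#' Log2 transform
#'
#' Elementwise log base 2. All values must be strictly positive; impute
#' zeros first ([impute_half_min()]).
#'
#' @param m abundance matrix.
#' @return transformed matrix with stage flag "log2".
#' @export
log2_transform <- function(m) {
  .require_stage_before(m, "log2", "log2_transform (already log2)")
  .require_stage_before(m, "residualized", "log2_transform")
  vals <- unclass_matrix(m)
  if (any(vals <= 0))
    ordering_error("nonpositive values present; run impute_half_min first")
  out <- abundance_matrix(log2(vals), level = attr(m, "level"),
                          stages = union(attr(m, "stages"), "log2"))
  attr(out, "imputed_mask") <- attr(m, "imputed_mask")
  attr(out, "injection") <- attr(m, "injection")
  attr(out, "imputation_report") <- attr(m, "imputation_report")
  out
}

#' Residualize covariates from a log2 matrix
#'
#' Per entity, fits ordinary least squares on the sample covariates
#' (default age, sex, PMI; sex coded 0/1 with male = 1) and returns the
#' residuals plus the entity's grand mean, so that group locations remain
#' interpretable downstream. Constant covariates are dropped with a
#' warning. Residuals are exactly orthogonal to each retained centered
#' covariate.
#'
#' @param m log2-stage abundance matrix (samples in columns).
#' @param metadata data.frame with one row per sample, matched to columns
#'   by `case_id` (or by order when ids are absent).
#' @param covariates character vector of metadata column names.
#' @return residualized matrix with stage flag "residualized" and a
#'   `covariate_coefficients` attribute (entities x covariates).
#' @export
residualize_covariates <- function(m, metadata,
                                   covariates = c("age_death", "sex", "pmi")) {
  if (!.has_stage(m, "log2"))
    ordering_error("residualize_covariates requires the log2 stage")
  .require_stage_before(m, "residualized", "residualize_covariates (already)")
  idx <- if (!is.null(metadata$case_id) && !is.null(colnames(m)))
    match(colnames(m), metadata$case_id) else seq_len(ncol(m))
  if (anyNA(idx))
    mapping_error(sprintf(
      "sample(s) missing from metadata: %s",
      paste(utils::head(colnames(m)[is.na(idx)], 5), collapse = ", ")))
  md <- metadata[idx, , drop = FALSE]
  X <- matrix(1, ncol(m), 1, dimnames = list(NULL, "(Intercept)"))
  for (cv in covariates) {
    x <- md[[cv]]
    if (is.null(x)) config_error(sprintf("covariate %s not in metadata", cv))
    if (is.character(x) || is.factor(x))
      x <- as.integer(as.character(x) == "M")
    x <- as.numeric(x)
    if (anyNA(x)) config_error(sprintf("covariate %s has missing values", cv))
    if (stats::sd(x) == 0) {
      warning(sprintf("dropping constant covariate %s", cv))
      next
    }
    X <- cbind(X, stats::setNames(data.frame(x), cv)[[1]])
    colnames(X)[ncol(X)] <- cv
  }
  vals <- unclass_matrix(m)
  fit <- stats::lm.fit(X, t(vals))
  resid <- t(fit$residuals)
  coefs <- t(fit$coefficients)
  out_vals <- resid + rowMeans(vals)
  dimnames(out_vals) <- dimnames(vals)
  out <- abundance_matrix(out_vals, level = attr(m, "level"),
                          stages = union(attr(m, "stages"), "residualized"))
  attr(out, "injection") <- attr(m, "injection")
  attr(out, "covariate_coefficients") <- coefs
  out
}

#' Full protein-level preprocessing
#'
#' Convenience wrapper: impute -> log2 -> residualize in the enforced
#' order.
#'
#' @inheritParams residualize_covariates
#' @return residualized log2 protein matrix.
#' @export
preprocess_matrix <- function(m, metadata,
                              covariates = c("age_death", "sex", "pmi")) {
  residualize_covariates(log2_transform(impute_half_min(m)),
                         metadata, covariates)
}
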