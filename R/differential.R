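# Differential insolubility statistics: pairwise volcano tables (Student
# t, equal variance, no multiple-testing adjustment), one-way ANOVA and
# Kruskal-Wallis omnibus tests, and module-wise significance fractions.

.p_floor <- 1e-300

.parse_comparison <- function(comparison) {
  parts <- strsplit(comparison, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2)
    config_error("comparison must be of the form 'disease/control'")
  parts
}

#' Pairwise volcano table
#'
#' Per entity: log2 fold change = mean(log2 disease) - mean(log2 control)
#' on the residualized matrix, two-sample two-tailed equal-variance Student
#' t p-value, and an up/down/unchanged flag at the |fold change| > 1.5
#' (i.e. |log2 FC| > log2 1.5) and p < 0.05 rule. P-values are not
#' adjusted for multiple testing, matching the small-cohort convention for
#' this assay, and are floored at 1e-300.
#'
#' @param m log2-scale protein abundance matrix (samples in columns).
#' @param metadata data.frame with case_id and group.
#' @param comparison string "disease/control", e.g. "AD/CTL".
#' @param fc_threshold linear fold-change threshold (default 1.5).
#' @param p_threshold significance threshold (default 0.05).
#' @return data.frame: entity, comparison, log2fc, p_t, flag.
#' @export
volcano <- function(m, metadata, comparison, fc_threshold = 1.5,
                    p_threshold = 0.05) {
  parts <- .parse_comparison(comparison)
  idx <- match(colnames(m), metadata$case_id)
  grp <- as.character(metadata$group[idx])
  a <- which(grp == parts[1]); b <- which(grp == parts[2])
  if (length(a) < 2 || length(b) < 2)
    insufficient_data_error(sprintf(
      "groups %s/%s need at least 2 samples each (have %d/%d)",
      parts[1], parts[2], length(a), length(b)))
  vals <- unclass_matrix(m)
  xa <- vals[, a, drop = FALSE]; xb <- vals[, b, drop = FALSE]
  na <- length(a); nb <- length(b)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- apply(xa, 1, stats::var); vb <- apply(xb, 1, stats::var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  tstat <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * stats::pt(-abs(tstat), df = na + nb - 2)
  p[!is.finite(p)] <- 1
  p <- pmax(p, .p_floor)
  log2fc <- ma - mb
  flag <- rep("unchanged", nrow(vals))
  flag[log2fc > log2(fc_threshold) & p < p_threshold] <- "up"
  flag[log2fc < -log2(fc_threshold) & p < p_threshold] <- "down"
  data.frame(entity = rownames(vals), comparison = comparison,
             log2fc = log2fc, p_t = p, flag = flag,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Omnibus group tests per entity
#'
#' One-way ANOVA F-test and Kruskal-Wallis H-test p-values across all
#' groups, with star annotations at 0.05 / 0.01 / 0.001. Entities whose
#' values are tied within every group are degenerate: a warning is issued
#' and p = 1 is reported.
#'
#' @param m log2-scale protein matrix.
#' @param metadata data.frame with case_id and group.
#' @return data.frame: entity, p_anova, p_kw, stars_anova, stars_kw.
#' @export
omnibus_tests <- function(m, metadata) {
  idx <- match(colnames(m), metadata$case_id)
  grp <- factor(as.character(metadata$group[idx]))
  tab <- table(grp)
  if (sum(tab >= 2) < 2)
    insufficient_data_error("need at least 2 groups with 2+ samples")
  vals <- unclass_matrix(m)
  n_degenerate <- 0L
  res <- t(apply(vals, 1, function(x) {
    if (all(tapply(x, grp, function(v) length(unique(v)) == 1))) {
      n_degenerate <<- n_degenerate + 1L
      return(c(1, 1))
    }
    pa <- stats::anova(stats::lm(x ~ grp))[["Pr(>F)"]][1]
    pk <- suppressWarnings(stats::kruskal.test(x, grp)$p.value)
    c(pa, pk)
  }))
  if (n_degenerate > 0)
    warning(sprintf("%d entities had all values tied within every group",
                    n_degenerate))
  p_anova <- pmax(res[, 1], .p_floor)
  p_kw <- pmax(res[, 2], .p_floor)
  data.frame(entity = rownames(vals), p_anova = p_anova, p_kw = p_kw,
             stars_anova = significance_stars(p_anova),
             stars_kw = significance_stars(p_kw),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Module significance fractions
#'
#' For each module and pairwise comparison: the fraction of module members
#' with p < 0.05, and the mean log2 fold change of those significant
#' members (the heat color value of the stacked-bar display).
#'
#' @param results combined volcano table (possibly several comparisons).
#' @param partition a module partition (or named assignment vector).
#' @param p_threshold member significance threshold.
#' @return data.frame: module, comparison, n_members, n_significant,
#'   fraction, mean_log2fc_significant.
#' @export
module_significance_fraction <- function(results, partition,
                                         p_threshold = 0.05) {
  assign <- if (inherits(partition, "module_partition"))
    partition$assignment else partition
  mods <- sort(unique(assign[assign > 0]))
  comps <- unique(results$comparison)
  out <- list()
  for (mod in mods) {
    members <- names(assign)[assign == mod]
    sub_all <- results[results$entity %in% members, ]
    if (nrow(sub_all) == 0) {
      warning(sprintf("module %d absent from differential results", mod))
      next
    }
    for (cmp in comps) {
      sub <- sub_all[sub_all$comparison == cmp, ]
      sig <- sub$p_t < p_threshold
      out[[length(out) + 1L]] <- data.frame(
        module = mod, comparison = cmp, n_members = nrow(sub),
        n_significant = sum(sig),
        fraction = if (nrow(sub)) sum(sig) / nrow(sub) else NA_real_,
        mean_log2fc_significant =
          if (any(sig)) mean(sub$log2fc[sig]) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
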