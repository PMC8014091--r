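# Signed weighted co-abundance network, implemented from scratch:
# biweight midcorrelation, soft-threshold selection by scale-free fit,
# signed adjacency, mean-denominator topological overlap, average-linkage
# clustering with a simplified dynamic hybrid tree cut (static height cut,
# minimum module size, PAM-like assignment of leftovers), module
# eigenproteins, kME cleanup / reassignment / eigenprotein merging, and
# module-trait / pathology correlations.
#
# Bit-compatibility with the reference WGCNA implementation is not a goal;
# planted-structure recovery and oracle equivalence of the algebraic
# primitives are the correctness criteria.

#' Network configuration
#'
#' Parameters of the signed co-abundance network. Defaults follow the
#' settings established for protein abundance networks: power 23, signed
#' adjacency on biweight midcorrelation, mean-denominator TOM, merge cut
#' height 0.07, PAM stage respecting the dendrogram, reassignment p 0.05,
#' minimum kME 0.30, deep split 4, minimum module size 5, scale-free target
#' R^2 0.80.
#'
#' @param beta soft-threshold power.
#' @param merge_cut_height eigenprotein dissimilarity below which modules
#'   merge (modules merge when eigenprotein correlation > 1 - this).
#' @param pam_stage,pam_respects_dendro PAM-like assignment of unlabelled
#'   entities, optionally restricted to the entity's dendrogram branch.
#' @param reassign_threshold_p p-value for moving an entity to a module
#'   with significantly higher kME.
#' @param min_kme_to_stay minimum own-module kME.
#' @param deep_split split sensitivity 0-4 (higher cuts deeper).
#' @param min_module_size smallest allowed module.
#' @param tom_denominator "mean" or "min".
#' @param scale_free_target_r2 target scale-free fit for power selection.
#' @return object of class `network_config`.
#' @export
network_config <- function(beta = 23, merge_cut_height = 0.07,
                           pam_stage = TRUE, pam_respects_dendro = TRUE,
                           reassign_threshold_p = 0.05,
                           min_kme_to_stay = 0.30, deep_split = 4,
                           min_module_size = 5,
                           tom_denominator = c("mean", "min"),
                           scale_free_target_r2 = 0.80) {
  if (beta < 1) config_error("beta must be at least 1")
  if (merge_cut_height <= 0 || merge_cut_height >= 1)
    config_error("merge_cut_height must lie in (0, 1)")
  if (min_module_size < 2) config_error("min_module_size must be at least 2")
  if (!deep_split %in% 0:4) config_error("deep_split must be 0..4")
  structure(list(beta = beta, merge_cut_height = merge_cut_height,
                 pam_stage = pam_stage,
                 pam_respects_dendro = pam_respects_dendro,
                 reassign_threshold_p = reassign_threshold_p,
                 min_kme_to_stay = min_kme_to_stay, deep_split = deep_split,
                 min_module_size = min_module_size,
                 tom_denominator = match.arg(tom_denominator),
                 scale_free_target_r2 = scale_free_target_r2),
            class = "network_config")
}

#' Biweight midcorrelation
#'
#' Robust correlation weighting observations by `w = (1 - u^2)^2` for
#' `|u| < 1`, `u = (x - median) / (9 MAD)` (unscaled MAD). A variable with
#' zero MAD falls back to Pearson weighting (mean-centering, unit
#' weights). Constant variables have undefined correlation and yield NA.
#'
#' @param x numeric vector, or matrix with variables in columns when `y`
#'   is NULL.
#' @param y optional second vector.
#' @return scalar correlation, or a symmetric correlation matrix.
#' @export
bicor <- function(x, y = NULL) {
  if (is.null(y)) {
    stopifnot(is.matrix(x))
    return(.bicor_matrix(x))
  }
  .bicor_matrix(cbind(x, y))[1, 2]
}

.bicor_prepare <- function(x) {
  # returns the weighted centered column, or NULL when constant
  med <- stats::median(x)
  madx <- stats::median(abs(x - med))
  if (madx == 0) {
    if (stats::sd(x) == 0) return(NULL)
    xc <- x - mean(x)                      # Pearson fallback
  } else {
    u <- (x - med) / (9 * madx)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    xc <- (x - med) * w
  }
  nrm <- sqrt(sum(xc^2))
  if (nrm == 0) return(NULL)
  xc / nrm
}

.bicor_matrix <- function(X) {
  if (nrow(X) < 3)
    insufficient_data_error("bicor requires at least 3 observations")
  cols <- lapply(seq_len(ncol(X)), function(j) .bicor_prepare(X[, j]))
  bad <- vapply(cols, is.null, TRUE)
  if (any(bad)) {
    warning(sprintf("%d constant variable(s): correlation undefined (NA)",
                    sum(bad)))
    cols[bad] <- list(rep(NA_real_, nrow(X)))
  }
  W <- do.call(cbind, cols)
  R <- crossprod(W)
  R[R > 1] <- 1; R[R < -1] <- -1
  diag(R) <- ifelse(bad, NA_real_, 1)
  dimnames(R) <- list(colnames(X), colnames(X))
  R
}

#' Student p-value for a correlation
#'
#' Two-tailed p from the t transform `t = r sqrt((n-2)/(1-r^2))`.
#'
#' @param r correlation(s).
#' @param n number of observations.
#' @return p-value(s).
#' @export
cor_p_value <- function(r, n) {
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  pmax(2 * stats::pt(-abs(t), df = n - 2), 1e-300)
}

#' Signed adjacency transform
#'
#' `a_ij = ((1 + rho_ij)/2)^beta`, mapping correlations to (0,1) while
#' preserving sign information; the diagonal is 1.
#'
#' @param correlations symmetric correlation matrix with unit diagonal.
#' @param beta soft-threshold power (>= 1).
#' @return adjacency matrix in [0,1].
#' @export
signed_adjacency <- function(correlations, beta) {
  if (beta < 1) config_error("beta must be at least 1")
  a <- ((1 + correlations) / 2)^beta
  diag(a) <- 1
  a
}

#' Scale-free topology fit for candidate powers
#'
#' For each candidate power: build the signed adjacency, compute the
#' connectivity distribution, bin connectivities and regress log10
#' frequency on log10 mean connectivity; report the fit R^2 and mean
#' connectivity.
#'
#' @param m protein x sample matrix (or a precomputed correlation matrix
#'   with `is_cor = TRUE`).
#' @param powers candidate powers.
#' @param n_bins connectivity histogram bins.
#' @param is_cor is `m` already a correlation matrix?
#' @return data.frame: power, r_squared, slope, mean_k.
#' @export
scale_free_fit <- function(m, powers = c(1:10, seq(12, 30, 2)), n_bins = 10,
                           is_cor = FALSE) {
  R <- if (is_cor) m else .bicor_matrix(t(m))
  out <- lapply(powers, function(b) {
    a <- signed_adjacency(R, b)
    k <- colSums(a) - 1
    br <- unique(stats::quantile(k, probs = seq(0, 1, length.out = n_bins + 1)))
    if (length(br) < 3) return(data.frame(power = b, r_squared = 0,
                                          slope = 0, mean_k = mean(k)))
    bin <- cut(k, breaks = br, include.lowest = TRUE)
    pk <- tapply(k, bin, length) / length(k)
    mk <- tapply(k, bin, mean)
    ok <- is.finite(pk) & is.finite(mk) & pk > 0 & mk > 0
    x <- log10(mk[ok]); y <- log10(pk[ok])
    sxx <- sum((x - mean(x))^2)
    if (sxx == 0) return(data.frame(power = b, r_squared = 0, slope = 0,
                                    mean_k = mean(k)))
    slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
    r2 <- if (sum((y - mean(y))^2) == 0) 1 else
      slope^2 * sxx / sum((y - mean(y))^2)
    data.frame(power = b, r_squared = r2, slope = slope, mean_k = mean(k))
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Select the soft-threshold power from an R^2 profile
#'
#' The lowest power whose scale-free R^2 reaches the target; if none
#' reaches it, the plateau power: the first power whose R^2 gain over the
#' previous candidate falls below `plateau_gain`.
#'
#' @param powers candidate powers (ascending).
#' @param r_squared matching R^2 values.
#' @param target_r2 target fit (default 0.80).
#' @param plateau_gain minimum gain defining the plateau (default 0.01).
#' @return the selected power.
#' @export
select_power_from_r2 <- function(powers, r_squared, target_r2 = 0.80,
                                 plateau_gain = 0.01) {
  if (length(powers) < 2) config_error("at least 2 candidate powers required")
  hit <- which(r_squared >= target_r2)
  if (length(hit)) return(powers[min(hit)])
  gains <- diff(r_squared)
  flat <- which(gains < plateau_gain)
  if (length(flat)) powers[min(flat) + 1L] else powers[length(powers)]
}

#' Pick the soft-threshold power
#'
#' Runs [scale_free_fit()] over the candidates and applies
#' [select_power_from_r2()].
#'
#' @inheritParams scale_free_fit
#' @param target_r2 target scale-free R^2.
#' @return list(power, diagnostics).
#' @export
pick_soft_power <- function(m, powers = c(1:10, seq(12, 30, 2)),
                            target_r2 = 0.80, is_cor = FALSE) {
  if (!is_cor && nrow(m) < 30)
    insufficient_data_error("at least 30 entities required")
  d <- scale_free_fit(m, powers, is_cor = is_cor)
  list(power = select_power_from_r2(d$power, d$r_squared, target_r2),
       diagnostics = d)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (L_ij + a_ij) / (denom_ij - a_ij + 1)` with
#' `L_ij = sum_{u != i,j} a_iu a_uj`, connectivity
#' `k_i = sum_{u != i} a_iu`, and `denom_ij` the mean (or min) of `k_i`
#' and `k_j`. Diagonal is 1; `1 - TOM` is the clustering dissimilarity.
#'
#' @param adjacency symmetric adjacency in [0,1].
#' @param denominator "mean" or "min".
#' @return TOM similarity matrix.
#' @export
tom_similarity <- function(adjacency, denominator = c("mean", "min")) {
  denominator <- match.arg(denominator)
  if (!isSymmetric(unname(adjacency), tol = 1e-10))
    validation_error("adjacency must be symmetric")
  if (any(adjacency < -1e-12) || any(adjacency > 1 + 1e-12))
    validation_error("adjacency entries must lie in [0,1]")
  A <- adjacency
  d <- diag(A)
  AA <- A %*% A
  L <- AA - sweep(A, 1, d, "*") - sweep(A, 2, d, "*")  # exclude u = i and u = j
  k <- colSums(A) - d
  denom <- if (denominator == "mean") outer(k, k, "+") / 2
           else outer(k, k, pmin)
  tom <- (L + A) / (denom - A + 1)
  diag(tom) <- 1
  tom[tom > 1] <- 1; tom[tom < 0] <- 0
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' TOM dissimilarity
#' @param adjacency adjacency matrix.
#' @param denominator "mean" or "min".
#' @return 1 - TOM.
#' @export
tom_dissimilarity <- function(adjacency, denominator = "mean")
  1 - tom_similarity(adjacency, denominator)

# Adaptive cut height: evaluate every merge height and choose the cut
# producing the most clusters of at least min_module_size. deep_split
# trades splitting sensitivity for robustness: below the maximum
# sensitivity (4), cuts whose module count falls within (4 - deep_split)
# of the best are allowed and the highest such cut (coarsest partition)
# is taken. Ties prefer the higher cut, which assigns more members.
.cut_height <- function(hc, min_module_size, deep_split) {
  hs <- sort(unique(hc$height))
  if (length(hs) == 1) return(hs)
  cl <- stats::cutree(hc, h = hs)
  if (is.null(dim(cl))) cl <- matrix(cl, ncol = 1)
  n_big <- apply(cl, 2, function(x) sum(table(x) >= min_module_size))
  target <- max(n_big) - (4 - deep_split)
  ok <- which(n_big >= max(1, target))
  hs[max(ok)]
}

#' Detect modules by tree cutting
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity
#' followed by a simplified dynamic hybrid cut: a static cut at a
#' deep-split-controlled fraction of the tallest merge, removal of
#' clusters below the minimum module size, and (PAM stage) assignment of
#' leftover entities to the nearest module by average dissimilarity —
#' restricted to the entity's dendrogram branch when
#' `pam_respects_dendro`. Modules are labelled M1..Mk by decreasing size;
#' 0 marks unassigned entities.
#'
#' @param dissimilarity square dissimilarity matrix (1 - TOM).
#' @param config a [network_config()].
#' @return object of class `module_partition`: list(assignment, hclust,
#'   cut_height, config).
#' @export
cut_modules <- function(dissimilarity, config = network_config()) {
  n <- nrow(dissimilarity)
  ids <- rownames(dissimilarity)
  if (is.null(ids)) ids <- paste0("E", seq_len(n))
  if (n < config$min_module_size) {
    warning("fewer entities than min_module_size: all unassigned")
    return(structure(list(assignment = stats::setNames(integer(n), ids),
                          hclust = NULL, cut_height = NA_real_,
                          config = config), class = "module_partition"))
  }
  hc <- stats::hclust(stats::as.dist(dissimilarity), method = "average")
  h <- .cut_height(hc, config$min_module_size, config$deep_split)
  cl <- stats::cutree(hc, h = h)
  sizes <- table(cl)
  keep <- as.integer(names(sizes)[sizes >= config$min_module_size])
  assign <- ifelse(cl %in% keep, cl, 0L)

  if (config$pam_stage && any(assign == 0L) && length(keep)) {
    # branch membership at a height between the cut and the root
    branch <- if (config$pam_respects_dendro)
      stats::cutree(hc, h = (h + max(hc$height)) / 2) else rep(1L, n)
    for (i in which(assign == 0L)) {
      cand <- unique(assign[assign > 0L & branch == branch[i]])
      if (!length(cand)) next
      avg <- vapply(cand, function(mod)
        mean(dissimilarity[i, assign == mod]), 1.0)
      best <- which.min(avg)
      # assign when distinctly closer to that module than to the rest of
      # the assigned entities (scale-free nearness criterion)
      rest <- assign > 0L & assign != cand[best]
      if (!any(rest) || avg[best] < mean(dissimilarity[i, rest]))
        assign[i] <- cand[best]
    }
  }
  assign <- .relabel_by_size(assign)
  names(assign) <- ids
  structure(list(assignment = assign, hclust = hc, cut_height = h,
                 config = config), class = "module_partition")
}

.relabel_by_size <- function(assign) {
  mods <- setdiff(unique(assign), 0L)
  if (!length(mods)) return(assign)
  sizes <- vapply(mods, function(m) sum(assign == m), 1L)
  new <- stats::setNames(seq_along(mods), mods[order(-sizes, mods)])
  out <- assign
  out[assign > 0L] <- new[as.character(assign[assign > 0L])]
  as.integer(out)
}

#' @export
print.module_partition <- function(x, ...) {
  n_mod <- length(setdiff(unique(x$assignment), 0L))
  cat(sprintf("module_partition: %d entities, %d modules, %d unassigned\n",
              length(x$assignment), n_mod, sum(x$assignment == 0L)))
  invisible(x)
}

#' Module eigenprotein
#'
#' The first right singular vector of the member-standardized submatrix
#' (each member z-scored across samples): a unit-norm, sample-length
#' summary profile. The sign is fixed so the eigenprotein correlates
#' positively with the module's mean profile (ties broken toward a
#' positive first coordinate). A single-member module returns the member's
#' standardized profile (unit norm).
#'
#' @param m protein x sample matrix.
#' @param members character or integer index of module members.
#' @return list(eigenprotein, var_explained).
#' @export
module_eigenprotein <- function(m, members) {
  sub <- unclass_matrix(m)[members, , drop = FALSE]
  Xs <- t(scale(t(sub)))                      # member-standardized
  Xs[!is.finite(Xs)] <- 0
  if (nrow(Xs) == 1) {
    v <- Xs[1, ]
    nrm <- sqrt(sum(v^2))
    v <- if (nrm > 0) v / nrm else v
    return(list(eigenprotein = v, var_explained = 1))
  }
  sv <- svd(Xs, nu = 0, nv = 1)
  v <- sv$v[, 1]
  ve <- sv$d[1]^2 / sum(sv$d^2)
  avg <- colMeans(Xs)
  s <- sum(v * avg)
  if (s < 0 || (s == 0 && v[1] < 0)) v <- -v
  list(eigenprotein = stats::setNames(v, colnames(m)), var_explained = ve)
}

#' Eigenproteins and kME for a partition
#'
#' @param m protein x sample matrix.
#' @param partition module partition (or assignment vector).
#' @return list(eigenproteins: modules x samples, var_explained, kme:
#'   proteins x modules biweight midcorrelation to each eigenprotein).
#' @export
compute_eigenproteins <- function(m, partition) {
  assign <- if (inherits(partition, "module_partition"))
    partition$assignment else partition
  mods <- sort(setdiff(unique(assign), 0L))
  if (!length(mods))
    return(list(eigenproteins = NULL, var_explained = NULL, kme = NULL))
  eig <- t(vapply(mods, function(mod) {
    module_eigenprotein(m, names(assign)[assign == mod])$eigenprotein
  }, numeric(ncol(m))))
  rownames(eig) <- paste0("M", mods)
  ve <- vapply(mods, function(mod)
    module_eigenprotein(m, names(assign)[assign == mod])$var_explained, 1.0)
  kme <- suppressWarnings(
    .bicor_matrix(cbind(t(unclass_matrix(m)), t(eig))))
  kme <- kme[seq_len(nrow(m)), nrow(m) + seq_along(mods), drop = FALSE]
  dimnames(kme) <- list(rownames(m), paste0("M", mods))
  list(eigenproteins = eig, var_explained = stats::setNames(ve, rownames(eig)),
       kme = kme, modules = mods)
}

# one-sided test that r2 > r1 at the same n (Fisher z, independence
# approximation; a conservative stand-in for the dependent-correlation test)
.cor_diff_p <- function(r1, r2, n) {
  z <- (atanh(pmin(r2, 0.999999)) - atanh(pmin(r1, 0.999999))) /
    sqrt(2 / (n - 3))
  stats::pnorm(z, lower.tail = FALSE)
}

#' Merge close modules and clean memberships
#'
#' Fixed-point iteration (capped at 100 rounds): (1) merge the module pair
#' with the highest eigenprotein correlation while it exceeds
#' `1 - merge_cut_height`; (2) drop members whose own-module kME falls
#' below `min_kme_to_stay` to the unassigned bin; (3) reassign an entity
#' to the module where its kME is significantly higher than at home
#' (one-sided correlation-difference test at `reassign_threshold_p`).
#' Modules are relabelled by decreasing size and eigenproteins recomputed.
#'
#' @param partition pre-merge [cut_modules()] partition.
#' @param m protein x sample matrix.
#' @param config a [network_config()].
#' @return final `module_partition` with eigenproteins, var_explained and
#'   kme attached.
#' @export
merge_and_clean <- function(partition, m, config = partition$config) {
  assign <- partition$assignment
  n_samples <- ncol(m)
  for (round in seq_len(100)) {
    changed <- FALSE
    eg <- compute_eigenproteins(m, assign)
    if (is.null(eg$eigenproteins)) break

    # 1. merge closest pair above the correlation threshold
    if (nrow(eg$eigenproteins) >= 2) {
      ec <- suppressWarnings(.bicor_matrix(t(eg$eigenproteins)))
      diag(ec) <- -Inf
      best <- which(ec == max(ec), arr.ind = TRUE)[1, ]
      if (max(ec) > 1 - config$merge_cut_height) {
        m1 <- eg$modules[best[1]]; m2 <- eg$modules[best[2]]
        assign[assign == m2] <- m1
        changed <- TRUE
      }
    }
    if (!changed) {
      eg <- compute_eigenproteins(m, assign)
      own <- eg$kme[cbind(seq_along(assign),
                          match(paste0("M", assign),
                                colnames(eg$kme)))]
      # 2. kME cleanup
      weak <- which(assign > 0 & !is.na(own) &
                      own < config$min_kme_to_stay)
      if (length(weak)) {
        assign[weak] <- 0L
        changed <- TRUE
      } else {
        # 3. reassignment to a significantly better module
        for (i in which(assign > 0)) {
          krow <- eg$kme[i, ]
          best_mod <- which.max(krow)
          own_col <- match(paste0("M", assign[i]), colnames(eg$kme))
          if (best_mod != own_col &&
              .cor_diff_p(krow[own_col], krow[best_mod], n_samples) <
                config$reassign_threshold_p) {
            assign[i] <- eg$modules[best_mod]
            changed <- TRUE
          }
        }
      }
    }
    # drop emptied / undersized modules
    for (mod in setdiff(unique(assign), 0L)) {
      if (sum(assign == mod) < config$min_module_size) {
        assign[assign == mod] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
    if (round == 100) warning("merge_and_clean did not converge in 100 rounds")
  }
  assign <- stats::setNames(.relabel_by_size(assign), names(assign))
  eg <- compute_eigenproteins(m, assign)
  structure(list(assignment = assign, hclust = partition$hclust,
                 cut_height = partition$cut_height, config = config,
                 eigenproteins = eg$eigenproteins,
                 var_explained = eg$var_explained, kme = eg$kme),
            class = "module_partition")
}

#' Relatedness order of modules
#'
#' Leaf order of average-linkage clustering of eigenprotein dissimilarity
#' (1 - correlation), used to display related modules adjacently.
#'
#' @param eigenproteins modules x samples matrix.
#' @return integer leaf order.
#' @export
module_relatedness_order <- function(eigenproteins) {
  if (is.null(eigenproteins) || nrow(eigenproteins) < 2)
    return(seq_len(max(1, nrow(eigenproteins))))
  d <- 1 - suppressWarnings(.bicor_matrix(t(eigenproteins)))
  stats::hclust(stats::as.dist(d), method = "average")$order
}

#' Module-trait correlations
#'
#' Biweight midcorrelation of each module eigenprotein with each trait
#' (numeric pathology scores plus one-vs-rest diagnosis indicators), with
#' Student p-values and star annotations. Constant traits are flagged NA.
#'
#' @param partition final partition with eigenproteins.
#' @param metadata case metadata (case_id, group, cerad, braak, ...).
#' @param traits names of numeric metadata columns to correlate.
#' @param diagnoses group levels to binarize one-vs-rest (default all).
#' @return data.frame: module, trait, rho, p, stars.
#' @export
module_trait_correlations <- function(partition, metadata,
                                      traits = c("cerad", "braak"),
                                      diagnoses = NULL) {
  eig <- partition$eigenproteins
  if (is.null(eig)) config_error("partition has no eigenproteins")
  idx <- match(colnames(eig), metadata$case_id)
  if (anyNA(idx)) mapping_error("eigenprotein samples missing from metadata")
  md <- metadata[idx, , drop = FALSE]
  if (is.null(diagnoses)) diagnoses <- levels(factor(as.character(md$group)))
  trait_mat <- lapply(traits, function(tr) as.numeric(md[[tr]]))
  names(trait_mat) <- traits
  for (g in diagnoses)
    trait_mat[[paste0("dx_", g)]] <- as.numeric(md$group == g)
  n <- ncol(eig)
  out <- list()
  for (mod in rownames(eig)) {
    for (tr in names(trait_mat)) {
      x <- trait_mat[[tr]]
      if (stats::sd(x) == 0) {
        out[[length(out) + 1L]] <- data.frame(
          module = mod, trait = tr, rho = NA_real_, p = NA_real_,
          stars = NA_character_, stringsAsFactors = FALSE)
        next
      }
      rho <- suppressWarnings(bicor(eig[mod, ], x))
      p <- cor_p_value(rho, n)
      out[[length(out) + 1L]] <- data.frame(
        module = mod, trait = tr, rho = rho, p = p,
        stars = significance_stars(p), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Rank proteins by correlation to pathology profiles
#'
#' Biweight midcorrelation of every protein profile with the amyloid-beta
#' and tau entity profiles across samples, ranked descending.
#'
#' @param m protein x sample matrix.
#' @param abeta,tau row names of the anchor entities.
#' @return data.frame: entity, bicor_abeta, rank_abeta, bicor_tau,
#'   rank_tau; sorted by bicor_tau descending.
#' @export
pathology_ranking <- function(m, abeta = "ABETA", tau = "MAPT") {
  vals <- unclass_matrix(m)
  for (anchor in c(abeta, tau))
    if (!anchor %in% rownames(vals))
      config_error(sprintf("anchor entity %s not in matrix", anchor))
  R <- suppressWarnings(
    .bicor_matrix(cbind(t(vals), t(vals[c(abeta, tau), , drop = FALSE]))))
  nb <- nrow(vals)
  ra <- R[seq_len(nb), nb + 1L]
  rt <- R[seq_len(nb), nb + 2L]
  out <- data.frame(entity = rownames(vals), bicor_abeta = ra,
                    rank_abeta = rank(-ra, ties.method = "min"),
                    bicor_tau = rt,
                    rank_tau = rank(-rt, ties.method = "min"),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$bicor_tau), ]
}

#' Build the full co-abundance network
#'
#' Convenience driver: bicor correlations, signed adjacency at the
#' configured power, mean-denominator TOM, tree cut and merge/cleanup.
#'
#' @param m protein x sample matrix (log2, residualized).
#' @param config a [network_config()].
#' @return final `module_partition`.
#' @export
build_network <- function(m, config = network_config()) {
  R <- suppressWarnings(.bicor_matrix(t(unclass_matrix(m))))
  if (anyNA(R)) {
    # constant entities cannot be clustered; treat their correlation as 0
    R[is.na(R)] <- 0
    diag(R) <- 1
  }
  A <- signed_adjacency(R, config$beta)
  D <- 1 - tom_similarity(A, config$tom_denominator)
  pre <- cut_modules(D, config)
  merge_and_clean(pre, m, config)
}
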