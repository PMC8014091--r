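# Synthetic PRM cohort generator.
#
# Emulates a 44-case, 4-group targeted PRM study of the sarkosyl-insoluble
# brain proteome: 870 target peptides rolling up to 390 entities (385
# RNA-binding proteins plus MAPT, APP, an Abeta roll-up entity and two
# standard slots), a 6-peptide x 5-level tenfold-dilution reference
# spike-in, multiplicative injection-order signal drift, planted
# co-abundance modules with disease-specific insolubility shifts, lognormal
# measurement noise and rare missing values.

# Group-level demographic / neuropathology distributions used by
# generate_cohort(); means and SDs mirror the cohort summary table of the
# study design this generator emulates.
.group_params <- list(
  CTL    = list(age = c(76.0, 10.5), pmi = c(7.3, 3.9),  male = 0.500,
                cerad = c(0.2, 0.4), braak = c(1.6, 0.9), abc = c(0.5, 0.5)),
  AsymAD = list(age = c(82.5, 9.7),  pmi = c(17.5, 9.6), male = 0.625,
                cerad = c(2.8, 0.5), braak = c(3.0, 1.2), abc = c(1.8, 0.5)),
  AD     = list(age = c(76.4, 7.4),  pmi = c(9.5, 8.2),  male = 0.667,
                cerad = c(3.0, 0.0), braak = c(5.9, 0.3), abc = c(3.0, 0.0)),
  PD     = list(age = c(75.1, 6.0),  pmi = c(12.9, 7.6), male = 0.750,
                cerad = c(0.2, 0.4), braak = c(2.2, 1.3), abc = c(0.4, 0.5))
)

#' Default planted module sizes
#'
#' A fixed, size-ordered partition of `n_proteins` entities into
#' `n_modules` co-abundance modules with sizes between `min_size` and
#' `max_size`. The default (29 modules over 390 proteins, sizes 5-60)
#' exhausts the protein list so that every entity belongs to one planted
#' module.
#'
#' @param n_modules number of modules.
#' @param n_proteins total entities to cover.
#' @param min_size,max_size allowed module size range.
#' @return integer vector of length `n_modules`, decreasing, summing to at
#'   most `n_proteins`.
#' @export
default_module_sizes <- function(n_modules = 29, n_proteins = 390,
                                 min_size = 5, max_size = 60) {
  if (n_modules == 29 && n_proteins == 390 && min_size == 5 && max_size == 60) {
    return(c(60, 40, 30, 25, 20, 18, 16, 14, 13, 12, 11, 10, 10, 10,
             9, 9, 8, 8, 8, 7, 7, 7, 6, 6, 6, 5, 5, 5, 5))
  }
  # generic fallback: geometric-ish ramp, clipped and adjusted to fit
  sizes <- round(seq(max_size, min_size, length.out = n_modules))
  sizes <- pmax(min_size, pmin(max_size, sizes))
  while (sum(sizes) > n_proteins) {
    i <- which.max(sizes)
    if (sizes[i] <= min_size) break
    sizes[i] <- sizes[i] - 1L
  }
  if (sum(sizes) > n_proteins)
    config_error("module sizes cannot fit into n_proteins")
  sort(as.integer(sizes), decreasing = TRUE)
}

#' Default planted disease effects
#'
#' Log2 insolubility shifts planted on whole modules in specific disease
#' groups, emulating the qualitative pattern reported for the insoluble
#' brain proteome: an amyloid/tau-containing snRNP-like module enriched in
#' AsymAD and further in AD, a nuclear-speckle-like module enriched in AD
#' only, and translation/transcription-like modules depleted in PD and AD.
#'
#' @param tau_module index of the module that carries MAPT/APP/ABETA.
#' @return data.frame with columns `module`, `group`, `log2fc`.
#' @export
default_effect_table <- function(tau_module = 6L) {
  data.frame(
    module = c(tau_module, tau_module, 9L, 12L, 15L),
    group  = c("AsymAD", "AD", "AD", "PD", "AD"),
    log2fc = c(0.8, 1.2, 1.0, -1.0, -0.8),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic study generator. Defaults emulate
#' the study design: 12/8/12/12 cases across CTL/AsymAD/AD/PD, 870 peptides
#' over 390 roll-up entities, 29 planted modules at within-module
#' correlation 0.7, a linear multiplicative injection drift with slope
#' -0.0167 and intercept 1.417 (ratio units), lognormal measurement noise,
#' and a 0.73% missing-completely-at-random rate on the protein matrix.
#'
#' @param n_cases named integer vector of group sizes (CTL, AsymAD, AD, PD).
#' @param n_proteins,n_peptides totals for the target list.
#' @param module_sizes integer vector of planted module sizes.
#' @param within_module_cor correlation between members of a module.
#' @param biological_sd per-protein biological SD in log2 units.
#' @param effect_table data.frame (module, group, log2fc) of planted shifts.
#' @param covariate_effects named numeric (age, sex, pmi) slopes in log2
#'   units per year / per male / per hour.
#' @param drift_slope,drift_intercept linear drift in ratio units per
#'   injection; `drift_profile` (a positive vector of length n injections)
#'   overrides the line when supplied.
#' @param noise_cv lognormal measurement coefficient of variation.
#' @param missing_rate probability a protein x sample cell is missing.
#' @param n_gps number of pooled-standard injections interleaved.
#' @param tau_module module that hosts the MAPT/APP/ABETA entities.
#' @param extra_entities names of the configurable extra roll-up slots.
#' @param reference list describing the spike-in mix (n_sets, n_levels,
#'   base_area, noisy_sets, noisy_cv_multiplier).
#' @param baseline_log2_mean,baseline_log2_sd protein baseline abundance
#'   distribution (log2 peak-area units).
#' @param seed integer seed; every generator call is deterministic given it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_cases = c(CTL = 12L, AsymAD = 8L, AD = 12L, PD = 12L),
                       n_proteins = 390L, n_peptides = 870L,
                       module_sizes = default_module_sizes(29L, n_proteins),
                       within_module_cor = 0.7,
                       biological_sd = 0.5,
                       effect_table = default_effect_table(),
                       covariate_effects = c(age = 0.01, sex = 0.15, pmi = 0.01),
                       drift_slope = -0.0167, drift_intercept = 1.417,
                       drift_profile = NULL,
                       noise_cv = 0.15,
                       missing_rate = 0.0073,
                       n_gps = 6L,
                       tau_module = 6L,
                       extra_entities = c("STD1", "STD2"),
                       reference = list(n_sets = 6L, n_levels = 5L,
                                        base_area = 5e5,
                                        noisy_sets = c(1L, 6L),
                                        noisy_cv_multiplier = 4),
                       baseline_log2_mean = 20, baseline_log2_sd = 1.5,
                       seed = 1L) {
  groups <- c("CTL", "AsymAD", "AD", "PD")
  if (is.null(names(n_cases))) names(n_cases) <- groups
  if (any(n_cases < 0)) config_error("group sizes must be nonnegative")
  if (sum(n_cases) < 1) config_error("at least one case is required")
  if (n_peptides < n_proteins)
    config_error("n_peptides must be at least n_proteins")
  if (missing_rate < 0 || missing_rate >= 1)
    config_error("missing_rate must lie in [0, 1)")
  if (any(module_sizes < 2))
    config_error("module sizes must be at least 2")
  if (sum(module_sizes) > n_proteins)
    config_error("module sizes exceed n_proteins")
  if (within_module_cor < 0 || within_module_cor > 1)
    config_error("within_module_cor must lie in [0, 1]")
  structure(list(
    n_cases = stats::setNames(as.integer(n_cases), names(n_cases)),
    n_proteins = as.integer(n_proteins),
    n_peptides = as.integer(n_peptides),
    module_sizes = as.integer(module_sizes),
    within_module_cor = within_module_cor, biological_sd = biological_sd,
    effect_table = effect_table, covariate_effects = covariate_effects,
    drift_slope = drift_slope, drift_intercept = drift_intercept,
    drift_profile = drift_profile, noise_cv = noise_cv,
    missing_rate = missing_rate, n_gps = as.integer(n_gps),
    tau_module = as.integer(tau_module), extra_entities = extra_entities,
    reference = reference,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    seed = as.integer(seed)), class = "sim_config")
}

.truncnorm <- function(n, mean, sd, lower = 0) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lower)
  }
  x
}

.score <- function(n, mean, sd, max) {
  pmin(max, pmax(0, round(stats::rnorm(n, mean, sd))))
}

#' Injection drift profile
#'
#' Multiplicative per-injection drift factor shared by every peptide of an
#' injection: `drift_profile` verbatim when set, otherwise the linear ratio
#' series `intercept + slope * j` for injections `j = 1..n`.
#'
#' @param config a [sim_config()].
#' @param n_injections number of injections.
#' @return positive numeric vector of length `n_injections`.
#' @export
drift_profile <- function(config, n_injections) {
  d <- if (!is.null(config$drift_profile)) {
    if (length(config$drift_profile) != n_injections)
      config_error("drift_profile length must equal the number of injections")
    config$drift_profile
  } else {
    config$drift_intercept + config$drift_slope * seq_len(n_injections)
  }
  if (any(d <= 0)) config_error("drift factors must be strictly positive")
  d
}

#' Generate the synthetic case cohort
#'
#' Draws case metadata for the configured group sizes: age at death and PMI
#' from group-specific truncated normal distributions, sex from the group
#' male proportions, CERAD (0-3), Braak (0-6) and ABC (0-3) scores from
#' rounded truncated normals matching the group means, and a binary DLB
#' neocortex score for PD cases. Cases are randomly permuted over the
#' injection sequence with `n_gps` pooled-standard injections at evenly
#' spaced positions.
#'
#' @param config a [sim_config()].
#' @return data.frame of case records with attribute `gps_injections`
#'   (integer positions of the pooled-standard injections).
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  groups <- names(config$n_cases)
  n_total <- sum(config$n_cases)
  rows <- lapply(groups, function(g) {
    n <- config$n_cases[[g]]
    if (n == 0L) return(NULL)
    p <- .group_params[[g]]
    data.frame(
      case_id = sprintf("%s_%02d", g, seq_len(n)),
      group = g,
      age_death = round(.truncnorm(n, p$age[1], p$age[2]), 1),
      sex = ifelse(stats::runif(n) < p$male, "M", "F"),
      pmi = round(.truncnorm(n, p$pmi[1], p$pmi[2]), 1),
      cerad = .score(n, p$cerad[1], p$cerad[2], 3),
      braak = .score(n, p$braak[1], p$braak[2], 6),
      abc = .score(n, p$abc[1], p$abc[2], 3),
      dlb_neocortex = if (g == "PD") stats::rbinom(n, 1, 0.5) else NA_integer_,
      stringsAsFactors = FALSE
    )
  })
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  n_inj <- n_total + config$n_gps
  gps_pos <- if (config$n_gps > 0)
    unique(round(seq(1, n_inj, length.out = config$n_gps))) else integer()
  case_pos <- setdiff(seq_len(n_inj), gps_pos)
  cohort$injection_index <- sample(case_pos, n_total)
  cohort$group <- factor(cohort$group, levels = groups)
  attr(cohort, "gps_injections") <- gps_pos
  cohort
}

.random_peptide <- function(n, min_len = 7, max_len = 14) {
  # tryptic-looking: internal residues exclude K/R, C-terminal K or R
  internal <- c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M",
                "N", "P", "Q", "S", "T", "V", "W", "Y")
  lens <- sample(min_len:max_len, n, replace = TRUE)
  vapply(lens, function(l) {
    paste0(paste(sample(internal, l - 1, replace = TRUE), collapse = ""),
           sample(c("K", "R"), 1))
  }, character(1))
}

#' Generate the synthetic target list
#'
#' Builds the PRM inclusion/target list: 385 RBP entities with two or three
#' tryptic peptides each, 35 MAPT peptides, 9 APP peptides outside the
#' amyloid-beta region, 3 peptides inside APP residues 597-638 that roll up
#' to the separate "ABETA" entity, one peptide per extra standard slot, and
#' the 6 x 5 isotopologue reference mix rows (flagged `is_reference`, not
#' counted among the target peptides).
#'
#' @param config a [sim_config()].
#' @return data.frame (TargetList) with columns protein, peptide, charge,
#'   precursor_mz, start_pos, end_pos, is_reference, reference_level.
#' @export
generate_target_list <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n_special <- 3L + length(config$extra_entities)  # MAPT, APP, ABETA + extras
  n_rbp <- config$n_proteins - n_special
  if (n_rbp < 1) config_error("n_proteins too small for the special entities")
  rbp_names <- sprintf("RBP%03d", seq_len(n_rbp))

  n_mapt <- 35L; n_app <- 9L; n_abeta <- 3L
  n_extra <- length(config$extra_entities)
  n_rbp_pep <- config$n_peptides - n_mapt - n_app - n_abeta - n_extra
  if (n_rbp_pep < n_rbp)
    config_error("n_peptides too small to give every protein a peptide")
  base <- n_rbp_pep %/% n_rbp
  extra <- n_rbp_pep %% n_rbp
  pep_counts <- rep(base, n_rbp) + c(rep(1L, extra), rep(0L, n_rbp - extra))

  protein <- c(rep(rbp_names, pep_counts),
               rep("MAPT", n_mapt), rep("APP", n_app), rep("ABETA", n_abeta),
               config$extra_entities)
  n_pep <- length(protein)
  peptide <- .random_peptide(n_pep)
  while (anyDuplicated(peptide)) {
    dup <- duplicated(peptide)
    peptide[dup] <- .random_peptide(sum(dup))
  }
  charge <- sample(c(2L, 3L), n_pep, replace = TRUE, prob = c(0.8, 0.2))

  start_pos <- rep(NA_integer_, n_pep)
  end_pos <- rep(NA_integer_, n_pep)
  # APP_695 coordinates; the amyloid-beta region spans residues 597-638
  app_idx <- which(protein == "APP")
  app_starts <- sort(sample(setdiff(seq(1, 550, by = 18), 580:650), n_app))
  start_pos[app_idx] <- app_starts
  end_pos[app_idx] <- app_starts +
    nchar(peptide[app_idx]) - 1L
  abeta_idx <- which(protein == "ABETA")
  ab_starts <- 597L + c(0L, 14L, 28L)[seq_len(n_abeta)]
  start_pos[abeta_idx] <- ab_starts
  end_pos[abeta_idx] <- pmin(638L, ab_starts + nchar(peptide[abeta_idx]) - 1L)

  targets <- data.frame(
    protein = protein, peptide = peptide, charge = charge,
    precursor_mz = NA_real_, start_pos = start_pos, end_pos = end_pos,
    is_reference = FALSE, reference_level = NA_integer_,
    stringsAsFactors = FALSE
  )
  targets$precursor_mz <- compute_precursor_mz(targets$peptide, targets$charge)

  ref_seq <- .random_peptide(config$reference$n_sets)
  ref <- expand.grid(set = seq_len(config$reference$n_sets),
                     level = seq_len(config$reference$n_levels))
  ref_rows <- data.frame(
    protein = "REFMIX",
    peptide = sprintf("%s/%d", ref_seq[ref$set], ref$level),
    charge = 2L,
    precursor_mz = compute_precursor_mz(ref_seq[ref$set], 2L),
    start_pos = NA_integer_, end_pos = NA_integer_,
    is_reference = TRUE, reference_level = as.integer(ref$level),
    stringsAsFactors = FALSE
  )
  out <- rbind(targets, ref_rows)
  rownames(out) <- NULL
  out
}

#' Planted module assignment
#'
#' Deterministic mapping of roll-up entities to planted modules: entities
#' fill the configured module sizes in order, and the MAPT/APP/ABETA
#' entities are swapped into the configured `tau_module`. Entities beyond
#' the planted sizes (none under the default sizes) are background
#' (module 0).
#'
#' @param targets a target list from [generate_target_list()].
#' @param config a [sim_config()].
#' @return named integer vector entity -> module index (0 = background).
#' @export
module_assignment <- function(targets, config = sim_config()) {
  entities <- unique(targets$protein[!targets$is_reference])
  n <- length(entities)
  sizes <- config$module_sizes
  assign <- integer(n)
  assign[seq_len(min(n, sum(sizes)))] <-
    rep(seq_along(sizes), sizes)[seq_len(min(n, sum(sizes)))]
  names(assign) <- entities
  tm <- config$tau_module
  if (tm <= length(sizes)) {
    for (sp in intersect(c("MAPT", "APP", "ABETA"), entities)) {
      if (assign[sp] != tm) {
        swap <- setdiff(names(assign)[assign == tm],
                        c("MAPT", "APP", "ABETA"))[1]
        if (!is.na(swap)) {
          assign[swap] <- assign[sp]
          assign[sp] <- tm
        }
      }
    }
  }
  assign
}

# True log2 protein abundances for the case samples: baseline + planted
# module factors + disease shifts + covariate slopes. No measurement noise.
.simulate_truth <- function(cohort, targets, config) {
  assign <- module_assignment(targets, config)
  entities <- names(assign)
  n_prot <- length(entities)
  n_cases <- nrow(cohort)
  r <- config$within_module_cor
  baseline <- stats::rnorm(n_prot, config$baseline_log2_mean,
                           config$baseline_log2_sd)
  n_mod <- length(config$module_sizes)
  factors <- matrix(stats::rnorm(n_mod * n_cases), n_mod, n_cases)
  eps <- matrix(stats::rnorm(n_prot * n_cases), n_prot, n_cases)
  shared <- matrix(0, n_prot, n_cases)
  in_mod <- assign > 0
  shared[in_mod, ] <- sqrt(r) * factors[assign[in_mod], , drop = FALSE]
  unique_part <- eps
  unique_part[in_mod, ] <- sqrt(1 - r) * eps[in_mod, , drop = FALSE]
  T <- baseline + config$biological_sd * (shared + unique_part)

  if (nrow(config$effect_table)) {
    for (i in seq_len(nrow(config$effect_table))) {
      ef <- config$effect_table[i, ]
      rows <- which(assign == ef$module)
      cols <- which(as.character(cohort$group) == ef$group)
      if (length(rows) && length(cols))
        T[rows, cols] <- T[rows, cols] + ef$log2fc
    }
  }
  ce <- config$covariate_effects
  sex01 <- as.integer(cohort$sex == "M")
  cov_shift <- ce[["age"]] * (cohort$age_death - mean(cohort$age_death)) +
    ce[["sex"]] * (sex01 - mean(sex01)) +
    ce[["pmi"]] * (cohort$pmi - mean(cohort$pmi))
  T <- sweep(T, 2, cov_shift, "+")
  dimnames(T) <- list(entities, cohort$case_id)
  list(log2_true = T, assignment = assign)
}

.lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sigma^2 / 2, sigma))
}

#' Generate transition-level peak areas and the reference spike-in panel
#'
#' Expands the planted protein truth into Skyline-style transition rows:
#' each peptide carries a fixed ionization weight, 3-6 y-ion fragments with
#' fixed fractional intensities, a shared multiplicative injection drift,
#' and lognormal measurement noise. Pooled-standard (GPS) injections carry
#' the across-case mean quantities. A `missing_rate` fraction of protein x
#' case cells is zeroed across all of the protein's transitions. The
#' reference mix rows follow the 6 x 5 tenfold design times the same drift.
#'
#' @param cohort from [generate_cohort()].
#' @param targets from [generate_target_list()].
#' @param config the same [sim_config()].
#' @return list with elements `transitions` (data.frame: injection_index,
#'   sample_id, protein, peptide, charge, fragment_ion, area), `reference`
#'   (injection_index, peptide_set, level, area) and `truth` (planted log2
#'   matrix, module assignment, effect table, drift, missing mask).
#' @export
generate_transitions <- function(cohort, targets, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  truth <- .simulate_truth(cohort, targets, config)
  T <- truth$log2_true
  gps_pos <- attr(cohort, "gps_injections")
  n_inj <- nrow(cohort) + length(gps_pos)
  drift <- drift_profile(config, n_inj)

  # sample layout over injections
  inj_sample <- character(n_inj)
  inj_sample[cohort$injection_index] <- cohort$case_id
  if (length(gps_pos))
    inj_sample[gps_pos] <- sprintf("GPS%d", seq_along(gps_pos))

  q_case <- 2^T                                    # proteins x cases, linear
  q_gps <- rowMeans(q_case)
  Q <- matrix(0, nrow(q_case), n_inj,
              dimnames = list(rownames(q_case), inj_sample))
  Q[, cohort$injection_index] <- q_case
  if (length(gps_pos)) Q[, gps_pos] <- q_gps

  # missing protein x case cells (zeros through every transition)
  miss <- matrix(FALSE, nrow(Q), n_inj)
  if (config$missing_rate > 0) {
    m_case <- matrix(stats::runif(nrow(q_case) * ncol(q_case)) <
                       config$missing_rate, nrow(q_case))
    miss[, cohort$injection_index] <- m_case
  }
  Q[miss] <- 0

  tg <- targets[!targets$is_reference, ]
  n_pep <- nrow(tg)
  pep_weight <- 2^stats::rnorm(n_pep, 0, 1)
  n_frag <- sample(3:6, n_pep, replace = TRUE)
  frag_of_pep <- rep(seq_len(n_pep), n_frag)
  frag_label <- unlist(lapply(n_frag, function(k) paste0("y", 2 + seq_len(k))))
  frag_w <- stats::runif(length(frag_of_pep), 0.2, 1)
  frag_w <- frag_w / ave(frag_w, frag_of_pep, FUN = sum)

  n_rows_per_inj <- length(frag_of_pep)
  prot_idx <- match(tg$protein, rownames(Q))
  base_area <- Q[prot_idx, , drop = FALSE] * pep_weight     # peptide x inj
  # transition rows: fragment share x drift x noise
  tr_area <- base_area[frag_of_pep, , drop = FALSE] * frag_w
  tr_area <- sweep(tr_area, 2, drift, "*")
  noise <- matrix(.lognormal_noise(length(tr_area), config$noise_cv),
                  nrow(tr_area))
  tr_area <- tr_area * noise

  transitions <- data.frame(
    injection_index = rep(seq_len(n_inj), each = n_rows_per_inj),
    sample_id = rep(inj_sample, each = n_rows_per_inj),
    protein = rep(tg$protein[frag_of_pep], n_inj),
    peptide = rep(tg$peptide[frag_of_pep], n_inj),
    charge = rep(tg$charge[frag_of_pep], n_inj),
    fragment_ion = rep(frag_label, n_inj),
    area = as.vector(tr_area),
    stringsAsFactors = FALSE
  )

  # reference spike-in: constant nominal amount per injection, tenfold levels
  rf <- config$reference
  set_weight <- 2^stats::rnorm(rf$n_sets, 0, 0.5)
  grid <- expand.grid(set = seq_len(rf$n_sets), level = seq_len(rf$n_levels),
                      injection = seq_len(n_inj))
  nominal <- rf$base_area * set_weight[grid$set] *
    10^(grid$level - rf$n_levels)
  cv_vec <- ifelse(grid$set %in% rf$noisy_sets,
                   config$noise_cv * rf$noisy_cv_multiplier, config$noise_cv)
  ref_noise <- vapply(cv_vec, function(cv) .lognormal_noise(1, cv), 1.0)
  reference <- data.frame(
    injection_index = grid$injection,
    peptide_set = grid$set,
    level = grid$level,
    area = nominal * drift[grid$injection] * ref_noise,
    stringsAsFactors = FALSE
  )

  list(transitions = transitions, reference = reference,
       truth = list(log2_true = T, assignment = truth$assignment,
                    effect_table = config$effect_table, drift = drift,
                    missing = miss, gps_injections = gps_pos,
                    injection_sample = inj_sample))
}

#' Simulate a protein-level abundance matrix directly
#'
#' Shortcut around the transition layer: planted truth on the log2 scale
#' plus protein-level lognormal measurement noise and missing zeros, on the
#' linear scale. Used for fast statistical calibration studies; the full
#' transition path ([generate_transitions()]) is the fidelity reference.
#'
#' @param config a [sim_config()].
#' @return list: `matrix` (entities x cases, linear scale, zeros where
#'   missing), `cohort`, `truth`.
#' @export
simulate_protein_matrix <- function(config = sim_config()) {
  cohort <- generate_cohort(config)
  targets <- generate_target_list(config)
  set.seed(config$seed + 3L)
  truth <- .simulate_truth(cohort, targets, config)
  M <- 2^truth$log2_true
  M <- M * matrix(.lognormal_noise(length(M), config$noise_cv), nrow(M))
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(length(M)) < config$missing_rate, nrow(M))
    M[miss] <- 0
  } else miss <- matrix(FALSE, nrow(M), ncol(M))
  list(matrix = M, cohort = cohort,
       truth = c(truth, list(missing = miss)))
}

#' Generate synthetic annotation (gene-set) tables
#'
#' Builds one term per planted module covering a fraction of its members
#' plus random bystanders, and additional pure-noise terms, over the
#' background of all roll-up entities. Supports testing Fisher
#' over-representation and the target-list builder without any ontology
#' download.
#'
#' @param targets a target list.
#' @param config a [sim_config()].
#' @param coverage fraction of module members included in the matched term.
#' @param n_noise_terms number of random terms.
#' @param noise_term_size size of each random term.
#' @return named list term -> character vector of entity symbols.
#' @export
generate_annotation_sets <- function(targets, config = sim_config(),
                                     coverage = 0.8, n_noise_terms = 20,
                                     noise_term_size = 25) {
  set.seed(config$seed + 4L)
  assign <- module_assignment(targets, config)
  background <- names(assign)
  sets <- list()
  for (m in sort(unique(assign[assign > 0]))) {
    members <- names(assign)[assign == m]
    keep <- sample(members, max(2, round(coverage * length(members))))
    extras <- sample(setdiff(background, members),
                     max(1, round(0.2 * length(keep))))
    sets[[sprintf("TERM_M%02d", m)]] <- sort(c(keep, extras))
  }
  for (i in seq_len(n_noise_terms)) {
    sets[[sprintf("TERM_RND%02d", i)]] <-
      sort(sample(background, noise_term_size))
  }
  sets
}
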