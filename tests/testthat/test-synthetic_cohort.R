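test_that("default cohort has the 12/8/12/12 group design and valid scores", {
  co <- generate_cohort(sim_config(seed = 11))
  expect_equal(as.vector(table(co$group)), c(12, 8, 12, 12))
  expect_equal(nrow(co), 44)
  expect_true(all(co$age_death >= 0) && all(co$pmi >= 0))
  expect_true(all(co$cerad %in% 0:3))
  expect_true(all(co$braak %in% 0:6))
  expect_true(all(co$abc %in% 0:3))
  expect_true(all(is.na(co$dlb_neocortex[co$group != "PD"])))
  expect_true(all(co$dlb_neocortex[co$group == "PD"] %in% 0:1))
  # injections: 44 cases + 6 pooled standards = 50, all distinct
  gps <- attr(co, "gps_injections")
  expect_length(gps, 6)
  expect_setequal(c(co$injection_index, gps), 1:50)
})

test_that("group means track the configured demographics", {
  # large per-group n so sample means settle near their targets
  cfg <- sim_config(n_cases = c(CTL = 400L, AsymAD = 400L,
                                AD = 400L, PD = 400L), seed = 3)
  co <- generate_cohort(cfg)
  byg <- split(co, co$group)
  expect_equal(mean(byg$CTL$age_death), 76.0, tolerance = 0.03)
  expect_equal(mean(byg$AsymAD$age_death), 82.5, tolerance = 0.03)
  expect_equal(mean(byg$AD$cerad), 3.0, tolerance = 0.01)
  expect_equal(mean(byg$CTL$cerad), 0.2, tolerance = 0.5)
  expect_equal(mean(byg$AD$braak), 5.9, tolerance = 0.1)
  expect_equal(mean(byg$PD$sex == "M"), 0.75, tolerance = 0.1)
})

test_that("degenerate and invalid cohort configurations behave per contract", {
  cfg1 <- sim_config(n_cases = c(CTL = 1L, AsymAD = 0L, AD = 0L, PD = 0L),
                     n_gps = 0L)
  co1 <- generate_cohort(cfg1)
  expect_equal(nrow(co1), 1)
  expect_equal(as.character(co1$group), "CTL")
  expect_error(sim_config(n_cases = c(CTL = -1L, AsymAD = 8L,
                                      AD = 12L, PD = 12L)),
               class = "config_error")
  expect_error(sim_config(n_cases = c(CTL = 0L, AsymAD = 0L,
                                      AD = 0L, PD = 0L)),
               class = "config_error")
  expect_error(sim_config(n_peptides = 100L, n_proteins = 390L),
               class = "config_error")
  expect_error(sim_config(missing_rate = 1), class = "config_error")
})

test_that("same seed reproduces cohort, targets and transitions exactly", {
  cfg <- small_config(seed = 42)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  expect_identical(generate_target_list(cfg), generate_target_list(cfg))
  co <- generate_cohort(cfg); tg <- generate_target_list(cfg)
  expect_identical(generate_transitions(co, tg, cfg),
                   generate_transitions(co, tg, cfg))
})

test_that("default target list matches the 870-peptide / 390-entity design", {
  tg <- generate_target_list(sim_config(seed = 5))
  tt <- tg[!tg$is_reference, ]
  expect_equal(nrow(tt), 870)
  expect_equal(length(unique(tt$protein)), 390)
  expect_equal(sum(tt$protein == "MAPT"), 35)
  expect_equal(sum(tt$protein == "APP"), 9)
  expect_equal(sum(tt$protein == "ABETA"), 3)
  # amyloid-beta region peptides sit inside APP_695 residues 597-638
  ab <- tt[tt$protein == "ABETA", ]
  expect_true(all(ab$start_pos >= 597 & ab$end_pos <= 638))
  app <- tt[tt$protein == "APP", ]
  expect_true(all(app$end_pos < 597 | app$start_pos > 638))
  # every entity has at least one peptide; peptides unique
  expect_true(all(table(tt$protein) >= 1))
  expect_false(anyDuplicated(tt$peptide) > 0)
  expect_true(all(tt$precursor_mz > 0))
})

test_that("reference mix follows the 6 x 5 tenfold design in every injection", {
  cfg <- small_config(seed = 9, noise_cv = 0)
  co <- generate_cohort(cfg); tg <- generate_target_list(cfg)
  gen <- generate_transitions(co, tg, cfg)
  ref <- gen$reference
  expect_equal(sort(unique(ref$peptide_set)), 1:6)
  expect_equal(sort(unique(ref$level)), 1:5)
  # strictly increasing by exactly 10x between successive levels
  for (inj in unique(ref$injection_index)) for (s in 1:6) {
    a <- ref$area[ref$injection_index == inj & ref$peptide_set == s]
    a <- a[order(ref$level[ref$injection_index == inj &
                             ref$peptide_set == s])]
    expect_equal(a[-1] / a[-5], rep(10, 4), tolerance = 1e-12)
  }
})

test_that("noise-free generator output carries the drift exactly", {
  cfg <- small_config(seed = 13, noise_cv = 0, missing_rate = 0)
  co <- generate_cohort(cfg); tg <- generate_target_list(cfg)
  gen <- generate_transitions(co, tg, cfg)
  n_inj <- nrow(co) + cfg$n_gps
  d <- drift_profile(cfg, n_inj)
  # reference ratio at injection j equals the drift line up to its mean
  panel <- reference_panel(gen$reference)
  expect_equal(panel$injection_mean_ratio, setNames(d / mean(d),
                                                    names(panel$injection_mean_ratio)),
               tolerance = 1e-12)
  # per-peptide summed areas across GPS injections scale exactly with drift
  gps <- attr(co, "gps_injections")
  tr <- gen$transitions[gen$transitions$injection_index %in% gps, ]
  sums <- tapply(tr$area, list(tr$peptide, tr$injection_index), sum)
  base <- sums[, 1] / d[gps[1]]
  for (k in seq_along(gps))
    expect_equal(sums[, k], base * d[gps[k]], tolerance = 1e-9)
})

test_that("planted log2 group differences equal the effect table at zero noise", {
  cfg <- small_config(seed = 21, noise_cv = 0, missing_rate = 0,
                      within_module_cor = 0, biological_sd = 0,
                      covariate_effects = c(age = 0, sex = 0, pmi = 0))
  sim <- simulate_protein_matrix(cfg)
  lg <- log2(sim$matrix)
  grp <- as.character(sim$cohort$group)
  assign <- sim$truth$assignment
  for (i in seq_len(nrow(cfg$effect_table))) {
    ef <- cfg$effect_table[i, ]
    members <- names(assign)[assign == ef$module]
    fc <- rowMeans(lg[members, grp == ef$group, drop = FALSE]) -
      rowMeans(lg[members, grp == "CTL", drop = FALSE])
    expect_equal(unname(fc), rep(ef$log2fc, length(members)),
                 tolerance = 1e-9)
  }
})

test_that("missingness hits the protein matrix at the configured binomial rate", {
  counts <- vapply(1:12, function(s) {
    sim <- simulate_protein_matrix(sim_config(seed = s))
    sum(sim$matrix == 0)
  }, 1.0)
  n_vals <- 390 * 44
  rate <- sum(counts) / (12 * n_vals)
  se <- sqrt(0.0073 * (1 - 0.0073) / (12 * n_vals))
  expect_lt(abs(rate - 0.0073), 4 * se)
  # expected count per dataset is ~125
  expect_equal(mean(counts), 0.0073 * 17160, tolerance = 0.15)
})

test_that("planted within-module correlation is realized in the truth matrix", {
  cfg <- sim_config(seed = 31, noise_cv = 0, missing_rate = 0)
  sim <- simulate_protein_matrix(cfg)
  assign <- sim$truth$assignment
  m1 <- names(assign)[assign == 1]
  cm <- cor(t(sim$truth$log2_true[m1, ]))
  off <- cm[upper.tri(cm)]
  expect_equal(mean(off), 0.7, tolerance = 0.08)
})
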