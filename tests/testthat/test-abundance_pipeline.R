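pep_matrix <- function(vals, peptides, samples, map = NULL) {
  m <- abundance_matrix(matrix(vals, length(peptides),
                               dimnames = list(peptides, samples)),
                        level = "peptide", stages = "corrected")
  if (!is.null(map)) attr(m, "peptide_map") <- map
  m
}

test_that("protein roll-up equals grouped peptide sums", {
  m <- pep_matrix(c(3, 7, 2, 1, 5, 4), c("a", "b", "c"), c("s1", "s2"),
                  map = c(a = "P1", b = "P1", c = "P2"))
  out <- rollup_proteins(m)
  expect_equal(unclass(out)["P1", ], c(s1 = 3 + 7, s2 = 1 + 5))
  expect_equal(unclass(out)["P2", ], c(s1 = 2, s2 = 4))
  expect_equal(attr(out, "level"), "protein")
  # random instance vs independent grouped-sum oracle
  set.seed(12)
  peps <- paste0("pep", 1:40)
  prots <- sample(paste0("P", 1:9), 40, replace = TRUE)
  vals <- matrix(runif(40 * 6), 40)
  m2 <- pep_matrix(vals, peps, paste0("s", 1:6),
                   map = setNames(prots, peps))
  out2 <- rollup_proteins(m2)
  for (p in unique(prots))
    expect_equal(unclass(out2)[p, ],
                 colSums(vals[prots == p, , drop = FALSE]),
                 ignore_attr = TRUE, tolerance = 1e-12)
  # unmapped peptide errors
  attr(m2, "peptide_map") <- setNames(prots[-1], peps[-1])
  expect_error(rollup_proteins(m2), class = "mapping_error")
})

test_that("default synthetic pipeline yields the 390 x 44 protein matrix", {
  fr <- run_frontend(sim_config(seed = 19))
  expect_equal(dim(fr$protein_cases), c(390L, 44L))
  expect_equal(length(unclass(fr$protein_cases)), 17160L)
})

test_that("half-minimum imputation follows the row-wise rule", {
  m <- abundance_matrix(matrix(c(4, 0, 8,
                                 1, 2, 3), 2, byrow = TRUE,
                               dimnames = list(c("r1", "r2"), NULL)),
                        level = "protein", stages = "corrected")
  out <- impute_half_min(m)
  expect_equal(unclass(out)["r1", ], c(4, 2, 8), ignore_attr = TRUE)
  expect_equal(unclass(out)["r2", ], c(1, 2, 3), ignore_attr = TRUE)
  rep <- imputation_report(out)
  expect_equal(rep$n_imputed, 1L)
  expect_equal(rep$fraction, 1 / 6)
  expect_true(unname(attr(out, "imputed_mask")["r1", 2]))
  # all-zero row dropped with warning
  m2 <- abundance_matrix(matrix(c(0, 0, 0, 5, 0, 10), 2, byrow = TRUE,
                                dimnames = list(c("dead", "ok"), NULL)),
                         level = "protein")
  expect_warning(out2 <- impute_half_min(m2), "dead")
  expect_equal(rownames(out2), "ok")
  expect_equal(unclass(out2)["ok", ], c(5, 2.5, 10), ignore_attr = TRUE)
})

test_that("log2 transform enforces positivity and ordering", {
  m <- abundance_matrix(matrix(c(8, 1, 2, 4), 2,
                               dimnames = list(c("a", "b"), NULL)),
                        level = "protein", stages = c("corrected", "imputed"))
  lg <- log2_transform(m)
  expect_equal(unclass(lg), log2(unclass(m)), ignore_attr = TRUE)
  expect_equal(unname(unclass(lg)["a", 1]), 3)
  expect_equal(unname(unclass(lg)["b", 1]), 0)
  # log2 of a ratio = difference of transforms
  expect_equal(unclass(lg)[, 2] - unclass(lg)[, 1],
               log2(unclass(m)[, 2] / unclass(m)[, 1]), ignore_attr = TRUE)
  m0 <- abundance_matrix(matrix(c(1, 0), 1), level = "protein")
  expect_error(log2_transform(m0), class = "ordering_error")
  expect_error(log2_transform(lg), class = "ordering_error")
  expect_error(impute_half_min(lg), class = "ordering_error")
})

test_that("residualization matches the normal-equations oracle and is orthogonal", {
  set.seed(23)
  md <- data.frame(case_id = paste0("s", 1:30),
                   age_death = runif(30, 60, 95),
                   sex = sample(c("M", "F"), 30, TRUE),
                   pmi = runif(30, 2, 30))
  vals <- matrix(rnorm(5 * 30, 20), 5,
                 dimnames = list(paste0("p", 1:5), md$case_id))
  m <- abundance_matrix(vals, level = "protein",
                        stages = c("corrected", "imputed", "log2"))
  out <- residualize_covariates(m, md)
  X <- cbind(1, md$age_death, as.integer(md$sex == "M"), md$pmi)
  for (i in 1:5) {
    want <- oracle_ols_resid(vals[i, ], X) + mean(vals[i, ])
    expect_equal(unclass(out)[i, ], want, ignore_attr = TRUE,
                 tolerance = 1e-10)
    # exact orthogonality to each centered covariate
    for (j in 2:4)
      expect_lt(abs(sum((unclass(out)[i, ] - mean(unclass(out)[i, ])) *
                          (X[, j] - mean(X[, j])))), 1e-8)
  }
  # stage ordering: must be log2 first
  raw <- abundance_matrix(vals, level = "protein")
  expect_error(residualize_covariates(raw, md), class = "ordering_error")
  # constant covariate dropped with warning
  md2 <- md; md2$pmi <- 5
  expect_warning(out2 <- residualize_covariates(m, md2), "pmi")
  expect_equal(dim(out2), dim(m))
})

test_that("a null generator (no effects, no noise) passes through unchanged", {
  cfg <- small_config(seed = 29,
                      covariate_effects = c(age = 0, sex = 0, pmi = 0),
                      noise_cv = 0, missing_rate = 0, biological_sd = 0,
                      within_module_cor = 0)
  cfg$effect_table <- cfg$effect_table[0, ]
  sim <- simulate_protein_matrix(cfg)
  m <- abundance_matrix(sim$matrix, level = "protein", stages = "corrected")
  lg <- log2_transform(impute_half_min(m))
  out <- residualize_covariates(lg, sim$cohort)
  expect_equal(unclass(out), unclass(lg), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("planted covariate slopes are recovered by the regression", {
  slopes <- vapply(1:5, function(s) {
    cfg <- small_config(seed = 100 + s,
                        covariate_effects = c(age = 0.05, sex = 0, pmi = 0),
                        noise_cv = 0.05, missing_rate = 0)
    sim <- simulate_protein_matrix(cfg)
    m <- log2_transform(impute_half_min(
      abundance_matrix(sim$matrix, level = "protein", stages = "corrected")))
    out <- residualize_covariates(m, sim$cohort)
    mean(attr(out, "covariate_coefficients")[, "age_death"])
  }, 1.0)
  expect_lt(abs(mean(slopes) - 0.05), 0.01)
})

test_that("roll-up and imputation commute with sample reordering", {
  set.seed(31)
  peps <- paste0("pep", 1:20)
  prots <- sample(paste0("P", 1:5), 20, replace = TRUE)
  vals <- matrix(runif(20 * 8), 20)
  vals[sample(length(vals), 10)] <- 0
  m <- pep_matrix(vals, peps, paste0("s", 1:8), map = setNames(prots, peps))
  perm <- sample(8)
  mp <- pep_matrix(vals[, perm], peps, paste0("s", 1:8)[perm],
                   map = setNames(prots, peps))
  a <- suppressWarnings(impute_half_min(rollup_proteins(m)))
  b <- suppressWarnings(impute_half_min(rollup_proteins(mp)))
  expect_equal(unclass(a)[, paste0("s", 1:8)],
               unclass(b)[, paste0("s", 1:8)], tolerance = 1e-12)
})
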