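test_that("bicor matches the textbook oracle and Pearson limits", {
  set.seed(61)
  # perfect linear relations
  x <- rnorm(20)
  expect_equal(bicor(x, 2 * x + 1), 1, tolerance = 1e-12)
  expect_equal(bicor(x, -x), -1, tolerance = 1e-12)
  # random Gaussian pairs: oracle equality; Pearson proximity at large n
  for (rep in 1:20) {
    a <- rnorm(20); b <- rnorm(20) + 0.5 * a
    expect_equal(bicor(a, b), oracle_bicor(a, b), tolerance = 1e-12)
  }
  for (rep in 1:10) {
    a <- rnorm(200); b <- rnorm(200) + 0.5 * a
    expect_lt(abs(bicor(a, b) - cor(a, b)), 0.05)
  }
  # an outlier damages Pearson far more than bicor
  a <- rnorm(30); b <- a + rnorm(30, 0, 0.1)
  b[1] <- 50
  expect_gt(bicor(a, b), cor(a, b))
  # zero-MAD variable falls back to mean-centered (Pearson) weighting,
  # matching the oracle's fallback branch
  z <- c(rep(0, 16), 3, -3, 2, -2, 1.5, -1.5, 1, -1)   # MAD 0, sd > 0
  y <- 0.8 * z + rnorm(24)
  expect_equal(bicor(z, y), oracle_bicor(z, y), tolerance = 1e-12)
  expect_gt(bicor(z, y), 0.3)
  # constant vector -> NA with warning
  expect_warning(r <- bicor(rep(1, 10), rnorm(10)))
  expect_true(is.na(r))
  expect_error(bicor(1:2, 1:2), class = "insufficient_data_error")
})

test_that("signed adjacency maps correlations into [0,1] with the power law", {
  R <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(signed_adjacency(matrix(c(1, 1, 1, 1), 2), 23)[1, 2], 1)
  expect_equal(signed_adjacency(matrix(c(1, -1, -1, 1), 2), 23)[1, 2], 0)
  expect_equal(signed_adjacency(matrix(c(1, 0, 0, 1), 2), 23)[1, 2],
               0.5^23, tolerance = 1e-15)
  expect_error(signed_adjacency(R, 0.5), class = "config_error")
})

test_that("TOM equals the hand-computed 3-node case and the loop oracle", {
  # hand computation: a12=0.5, a13=0.2, a23=0.4
  A <- matrix(c(1, 0.5, 0.2,
                0.5, 1, 0.4,
                0.2, 0.4, 1), 3, byrow = TRUE)
  # k = (0.7, 0.9, 0.6); L12 = a13*a32 = 0.08
  # TOM12 = (0.08 + 0.5)/((0.7+0.9)/2 - 0.5 + 1) = 0.58/1.3
  tom <- tom_similarity(A)
  expect_equal(tom[1, 2], 0.58 / 1.3, tolerance = 1e-12)
  expect_equal(tom[1, 3], (0.5 * 0.4 + 0.2) / ((0.7 + 0.6) / 2 - 0.2 + 1),
               tolerance = 1e-12)
  expect_equal(diag(tom), rep(1, 3))
  # identity adjacency: no shared neighbors, no edges
  expect_equal(tom_similarity(diag(4)) - diag(4), matrix(0, 4, 4))
  # random instances against the triple-loop oracle, both denominators
  set.seed(67)
  for (rep in 1:5) {
    n <- sample(5:20, 1)
    R <- cor(matrix(rnorm(n * 30), 30))
    A <- signed_adjacency(R, 6)
    expect_equal(tom_similarity(A, "mean"), oracle_tom(A, "mean"),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(tom_similarity(A, "min"), oracle_tom(A, "min"),
                 tolerance = 1e-12, ignore_attr = TRUE)
    tm <- tom_similarity(A)
    expect_true(isSymmetric(tm))
    expect_true(all(tm >= 0 & tm <= 1))
    d <- tom_dissimilarity(A)
    expect_true(all(diag(d) == 0) && all(d >= 0))
  }
  expect_error(tom_similarity(matrix(c(1, 0.2, 0.5, 1), 2)),
               class = "validation_error")
})

test_that("soft power selection follows the target and plateau rules", {
  expect_equal(select_power_from_r2(c(6, 12, 23), c(0.5, 0.85, 0.9)), 12)
  # no power reaches 0.80; plateau (gain < 0.01) first reached at 16
  expect_equal(select_power_from_r2(c(8, 12, 16, 20),
                                    c(0.50, 0.70, 0.705, 0.71)), 16)
  expect_error(select_power_from_r2(6, 0.9), class = "config_error")
  # scale-free-ish planted data: selected power achieves the target
  cfg <- sim_config(seed = 71)
  sim <- simulate_protein_matrix(cfg)
  m <- preprocess_matrix(
    abundance_matrix(sim$matrix, level = "protein", stages = "corrected"),
    sim$cohort)
  pick <- pick_soft_power(unclass(m), powers = c(2, 4, 6, 9, 12, 16, 20, 23))
  expect_true(pick$power %in% c(2, 4, 6, 9, 12, 16, 20, 23))
  best <- pick$diagnostics[pick$diagnostics$power == pick$power, ]
  expect_true(best$r_squared >= 0.80 ||
                pick$power > min(pick$diagnostics$power))
})

test_that("planted blocks are recovered exactly by the tree cut", {
  # two blocks of 10: within 0.1, between 0.9
  D <- matrix(0.9, 20, 20)
  D[1:10, 1:10] <- 0.1; D[11:20, 11:20] <- 0.1
  diag(D) <- 0
  rownames(D) <- colnames(D) <- paste0("e", 1:20)
  part <- cut_modules(D, network_config())
  expect_equal(length(setdiff(unique(part$assignment), 0)), 2)
  expect_equal(length(unique(part$assignment[1:10])), 1)
  expect_equal(length(unique(part$assignment[11:20])), 1)
  # all equal dissimilarities -> a single module (documented tie rule)
  De <- matrix(0.5, 12, 12); diag(De) <- 0
  rownames(De) <- colnames(De) <- paste0("x", 1:12)
  pe <- cut_modules(De, network_config())
  expect_equal(length(setdiff(unique(pe$assignment), 0)), 1)
  # fewer entities than min size -> all unassigned with warning
  Ds <- matrix(0.5, 3, 3); diag(Ds) <- 0
  expect_warning(ps <- cut_modules(Ds, network_config()))
  expect_true(all(ps$assignment == 0))
})

test_that("eigenprotein matches closed forms and the power-iteration oracle", {
  # identical profiles: eigenprotein proportional, variance explained 1
  prof <- sin(1:12)
  m <- rbind(p1 = prof, p2 = prof, p3 = prof)
  colnames(m) <- paste0("s", 1:12)
  e <- module_eigenprotein(m, c("p1", "p2", "p3"))
  expect_equal(e$var_explained, 1, tolerance = 1e-12)
  zprof <- (prof - mean(prof)) / sd(prof)
  expect_equal(e$eigenprotein, setNames(zprof / sqrt(sum(zprof^2)),
                                        colnames(m)), tolerance = 1e-9)
  expect_gt(cor(e$eigenprotein, prof), 0.999)
  # two orthogonal members: the 2x2 SVD splits variance evenly (1/2);
  # two perfectly anticorrelated members are rank one (all variance)
  o1 <- rep(c(1, -1), 6); o2 <- rep(c(1, 1, -1, -1), 3)
  m2 <- rbind(a = o1, b = o2)
  colnames(m2) <- paste0("s", 1:12)
  e2 <- module_eigenprotein(m2, c("a", "b"))
  expect_equal(e2$var_explained, 0.5, tolerance = 1e-9)
  m3 <- rbind(a = prof, b = -2 * prof)
  colnames(m3) <- paste0("s", 1:12)
  e3a <- module_eigenprotein(m3, c("a", "b"))
  expect_equal(e3a$var_explained, 1, tolerance = 1e-9)
  # random module vs power iteration
  set.seed(73)
  for (rep in 1:5) {
    M <- matrix(rnorm(8 * 15), 8,
                dimnames = list(paste0("p", 1:8), paste0("s", 1:15)))
    e3 <- module_eigenprotein(M, paste0("p", 1:8))
    Xs <- t(scale(t(M)))
    v <- oracle_first_right_sv(Xs)
    if (sum(v * colMeans(Xs)) < 0) v <- -v
    expect_equal(unname(e3$eigenprotein), v, tolerance = 1e-8)
    expect_equal(sum(e3$eigenprotein^2), 1, tolerance = 1e-12)
  }
  # single member: its standardized unit-norm profile
  e1 <- module_eigenprotein(m, "p1")
  expect_equal(sum(e1$eigenprotein^2), 1, tolerance = 1e-12)
})

test_that("merging and kME cleanup behave per the module rules", {
  set.seed(79)
  n_s <- 40
  f <- rnorm(n_s)
  # one true module artificially split in two by labels
  mk <- function(k) t(replicate(k, sqrt(0.8) * f + sqrt(0.2) * rnorm(n_s)))
  M <- rbind(mk(6), mk(6))
  rownames(M) <- paste0("p", 1:12)
  colnames(M) <- paste0("s", 1:n_s)
  part <- structure(list(assignment = setNames(c(rep(1L, 6), rep(2L, 6)),
                                               rownames(M)),
                         hclust = NULL, cut_height = NA,
                         config = network_config()),
                    class = "module_partition")
  merged <- merge_and_clean(part, M)
  expect_equal(length(setdiff(unique(merged$assignment), 0)), 1)
  expect_true(all(merged$assignment == 1))
  # an unrelated member with low kME is evicted to the unassigned bin
  M2 <- rbind(mk(7), outlier = rnorm(n_s))
  rownames(M2) <- c(paste0("p", 1:7), "outlier")
  colnames(M2) <- paste0("s", 1:n_s)
  part2 <- structure(list(assignment = setNames(rep(1L, 8), rownames(M2)),
                          hclust = NULL, cut_height = NA,
                          config = network_config()),
                     class = "module_partition")
  clean <- merge_and_clean(part2, M2)
  expect_equal(unname(clean$assignment["outlier"]), 0L)
  expect_true(all(clean$assignment[paste0("p", 1:7)] == 1L))
})

test_that("module labels are deterministic and ordered by size", {
  cfg <- small_config(seed = 83)
  sim <- simulate_protein_matrix(cfg)
  m <- preprocess_matrix(
    abundance_matrix(sim$matrix, level = "protein", stages = "corrected"),
    sim$cohort)
  p1 <- build_network(m)
  p2 <- build_network(m)
  expect_identical(p1$assignment, p2$assignment)
  sizes <- table(p1$assignment[p1$assignment > 0])
  expect_true(all(diff(as.vector(sizes)) <= 0))
})

test_that("planted module structure is recovered with high ARI", {
  cfg <- small_config(seed = 89)
  sim <- simulate_protein_matrix(cfg)
  m <- preprocess_matrix(
    abundance_matrix(sim$matrix, level = "protein", stages = "corrected"),
    sim$cohort)
  part <- build_network(m)
  truth <- sim$truth$assignment[names(part$assignment)]
  skip_if_not_installed("mclust")
  expect_gte(mclust::adjustedRandIndex(part$assignment, truth), 0.9)
  expect_lte(abs(length(setdiff(unique(part$assignment), 0)) -
                   length(cfg$module_sizes)), 1)
})

test_that("module-trait correlations match the bicor + Student-t oracle", {
  set.seed(97)
  n <- 10
  eig <- matrix(rnorm(2 * n), 2,
                dimnames = list(c("M1", "M2"), paste0("s", 1:n)))
  md <- data.frame(case_id = paste0("s", 1:n),
                   group = rep(c("AD", "CTL"), each = 5),
                   cerad = c(3, 2, 3, 3, 2, 0, 1, 0, 0, 1),
                   braak = c(6, 5, 5, 6, 4, 1, 2, 1, 0, 2))
  part <- structure(list(eigenproteins = eig), class = "module_partition")
  out <- module_trait_correlations(part, md)
  for (i in seq_len(nrow(out))) {
    tr <- out$trait[i]
    x <- switch(tr, cerad = md$cerad, braak = md$braak,
                dx_AD = as.numeric(md$group == "AD"),
                dx_CTL = as.numeric(md$group == "CTL"))
    r <- oracle_bicor(eig[out$module[i], ], x)
    expect_equal(out$rho[i], r, tolerance = 1e-10)
    tt <- r * sqrt((n - 2) / (1 - r^2))
    expect_equal(out$p[i], 2 * pt(-abs(tt), n - 2), tolerance = 1e-10)
  }
  # eigenprotein equal to the trait vector: rho 1
  eig2 <- rbind(M1 = md$cerad + 0.001 * rnorm(n))
  colnames(eig2) <- md$case_id
  part2 <- structure(list(eigenproteins = eig2), class = "module_partition")
  out2 <- module_trait_correlations(part2, md, traits = "cerad",
                                    diagnoses = character())
  expect_gt(out2$rho[1], 0.999)
})

test_that("trait correlations find the planted disease module", {
  cfg <- small_config(seed = 101)
  sim <- simulate_protein_matrix(cfg)
  m <- preprocess_matrix(
    abundance_matrix(sim$matrix, level = "protein", stages = "corrected"),
    sim$cohort)
  part <- build_network(m)
  # identify the recovered module matching planted module 2 (AD +1.2)
  truth <- sim$truth$assignment
  members <- names(truth)[truth == 2]
  lab <- names(which.max(table(part$assignment[members])))
  out <- module_trait_correlations(part, sim$cohort)
  row <- out[out$module == paste0("M", lab) & out$trait == "dx_AD", ]
  expect_gt(row$rho, 0)
  expect_lt(row$p, 0.05)
})

test_that("pathology ranking puts planted co-aggregating entities on top", {
  cfg <- small_config(seed = 103)
  sim <- simulate_protein_matrix(cfg)
  m <- preprocess_matrix(
    abundance_matrix(sim$matrix, level = "protein", stages = "corrected"),
    sim$cohort)
  rk <- pathology_ranking(m)
  expect_equal(rk$bicor_tau[rk$entity == "MAPT"], 1, tolerance = 1e-9)
  expect_equal(rk$bicor_abeta[rk$entity == "ABETA"], 1, tolerance = 1e-9)
  # members of the tau-hosting module rank above the median
  truth <- sim$truth$assignment
  mates <- setdiff(names(truth)[truth == truth[["MAPT"]]],
                   c("MAPT", "ABETA", "APP"))
  expect_lt(median(rk$rank_tau[rk$entity %in% mates]),
            nrow(rk) / 2)
  # anti-planted members (PD-depleted module) correlate negatively or
  # weakly with tau relative to module mates
  expect_gt(mean(rk$bicor_tau[rk$entity %in% mates]),
            mean(rk$bicor_tau))
  expect_error(pathology_ranking(m, abeta = "NOPE"),
               class = "config_error")
})
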