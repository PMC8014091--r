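# Independent brute-force oracles. Deliberately written in the plainest
# possible style (loops, textbook formulas), sharing no code with the
# package implementations they check.

# textbook biweight midcorrelation of two vectors
oracle_bicor <- function(x, y) {
  prep <- function(v) {
    med <- median(v)
    madv <- median(abs(v - med))
    if (madv == 0) return((v - mean(v)))
    u <- (v - med) / (9 * madv)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    (v - med) * w
  }
  a <- prep(x); b <- prep(y)
  sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
}

# triple-loop topological overlap
oracle_tom <- function(A, denom = "mean") {
  n <- nrow(A)
  out <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) { out[i, j] <- 1; next }
    L <- 0
    for (u in 1:n) if (u != i && u != j) L <- L + A[i, u] * A[u, j]
    ki <- sum(A[i, -i]); kj <- sum(A[j, -j])
    d <- if (denom == "mean") (ki + kj) / 2 else min(ki, kj)
    out[i, j] <- (L + A[i, j]) / (d - A[i, j] + 1)
  }
  out
}

# normal-equations OLS residuals of y on design X
oracle_ols_resid <- function(y, X) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  as.vector(y - X %*% beta)
}

# power-iteration first right singular vector of a matrix
oracle_first_right_sv <- function(M, iters = 5000) {
  v <- rep(1, ncol(M)) / sqrt(ncol(M))
  for (i in seq_len(iters)) {
    v2 <- t(M) %*% (M %*% v)
    v <- as.vector(v2) / sqrt(sum(v2^2))
  }
  v
}

# exhaustive two-tailed Fisher exact p: sum of hypergeometric probabilities
# of all tables (at fixed margins) no more probable than the observed one
oracle_fisher_p <- function(q, m_size, t_size, N) {
  qs <- max(0, m_size + t_size - N):min(m_size, t_size)
  probs <- dhyper(qs, t_size, N - t_size, m_size)
  p_obs <- dhyper(q, t_size, N - t_size, m_size)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# rank-sum Kruskal-Wallis H statistic with tie correction
oracle_kruskal_h <- function(x, g) {
  r <- rank(x)
  n <- length(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * mean(ri)^2)) - 3 * (n + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# pooled two-sample t statistic and p
oracle_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, p = 2 * pt(-abs(t), nx + ny - 2))
}

# simple-regression slope/intercept/R2 by the closed-form normal equations
oracle_ols_line <- function(y) {
  x <- seq_along(y)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  pred <- intercept + slope * x
  list(slope = slope, intercept = intercept,
       r2 = 1 - sum((y - pred)^2) / sum((y - mean(y))^2))
}

# small default config for fast end-to-end tests: 60 proteins, 120
# peptides, 8 modules of sizes summing to 60
small_config <- function(seed = 7, ...) {
  sim_config(n_proteins = 60L, n_peptides = 120L,
             module_sizes = c(14L, 10L, 8L, 7L, 6L, 5L, 5L, 5L),
             effect_table = data.frame(module = c(2L, 3L),
                                       group = c("AD", "PD"),
                                       log2fc = c(1.2, -1.0)),
             tau_module = 2L, seed = seed, ...)
}

# run the quantification + normalization + preprocessing front end
run_frontend <- function(cfg) {
  co <- generate_cohort(cfg)
  tg <- generate_target_list(cfg)
  gen <- generate_transitions(co, tg, cfg)
  pm <- quantify_peptides(gen$transitions)
  panel <- reference_panel(gen$reference)
  cf <- setNames(panel$correction_factor, colnames(panel$area))
  corrected <- apply_correction(pm, cf)
  prot <- rollup_proteins(corrected, tg)
  cases <- intersect(colnames(prot), co$case_id)
  pc <- abundance_matrix(unclass(prot)[, cases, drop = FALSE],
                         level = "protein", stages = "corrected")
  list(cohort = co, targets = tg, gen = gen, panel = panel,
       peptides = pm, corrected = corrected, protein = prot,
       protein_cases = pc, final = preprocess_matrix(pc, co))
}
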