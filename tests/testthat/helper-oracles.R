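# Independent oracles used by the test suite. Each takes a deliberately
# different arithmetic route than the package implementation so agreement is
# evidence, not tautology.

# ---- index formulas via power/natural-log decompositions -----------------

oracle_ar <- function(A, R) 1 + (log(R) - log(A)) / log(10)

oracle_quicki <- function(I, G_mmol, f = 18.0182) {
  log(10) / log(I * (G_mmol * f))
}

oracle_homa <- function(I, G) (I / 22.5) * G

oracle_bennett <- function(I, G) 1 / (log(I) * log(G))

oracle_mcauley_tg <- function(I, TG) exp(2.63) * I^(-0.28) * TG^(-0.31)

oracle_mcauley_ins <- function(I) exp(2.63) * I^(-0.28)

oracle_irar <- function(I, G_mmol, A, R, f = 18.0182) {
  (log(I) + log(G_mmol * f)) / log(10) * (1 + (log(R) - log(A)) / log(10))
}

# random valid index inputs (positive, QUICKI-feasible)
random_index_inputs <- function(n) {
  tibble::tibble(
    insulin = exp(runif(n, log(2), log(40))),
    glucose = runif(n, 3, 15),
    adiponectin = exp(runif(n, log(1), log(30))),
    resistin = exp(runif(n, log(2), log(60))),
    tg = runif(n, 0.5, 4)
  )
}

# ---- explicit full-vs-reduced least-squares F for the group factor -------

oracle_ancova_f <- function(y, g, cov) {
  g <- as.factor(g)
  Xf <- model.matrix(~ g + cov)
  Xr <- model.matrix(~ cov)
  rss_f <- sum(qr.resid(qr(Xf), y)^2)
  rss_r <- sum(qr.resid(qr(Xr), y)^2)
  df1 <- nlevels(g) - 1
  df2 <- length(y) - ncol(Xf)
  ((rss_r - rss_f) / df1) / (rss_f / df2)
}

# ---- MANCOVA statistics through matrix identities (no eigenvalues) -------

oracle_mancova_stats <- function(Y, g, cov) {
  g <- as.factor(g)
  Xf <- model.matrix(~ g + cov)
  Xr <- model.matrix(~ cov)
  Pf <- Xf %*% solve(crossprod(Xf)) %*% t(Xf)
  Pr <- Xr %*% solve(crossprod(Xr)) %*% t(Xr)
  E <- t(Y) %*% (diag(nrow(Y)) - Pf) %*% Y
  H <- t(Y) %*% (Pf - Pr) %*% Y
  c(
    pillai = sum(diag(H %*% solve(H + E))),
    wilks = det(E) / det(H + E),
    hotelling = sum(diag(solve(E) %*% H)),
    roy = max(Re(eigen(solve(E) %*% H, only.values = TRUE)$values))
  )
}

# ---- brute-force Spearman: rank then textbook Pearson --------------------

oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# ---- independent BCa reimplementation (same draw-order contract) ---------
#
# Strata in sorted order; within a stratum all B replicates drawn by one
# sample.int(n_s, n_s * B, replace = TRUE) call, filled column-major into a
# B x n_s matrix. Statistic: the stratum-preserving mean.

oracle_bca_mean <- function(x, strata, B, level, seed) {
  set.seed(seed)
  n <- length(x)
  strata <- as.character(strata)
  keys <- sort(unique(strata))
  idx <- matrix(NA_integer_, nrow = B, ncol = n)
  col0 <- 0
  for (k in keys) {
    pos <- which(strata == k)
    ns <- length(pos)
    idx[, (col0 + 1):(col0 + ns)] <-
      matrix(pos[sample.int(ns, ns * B, replace = TRUE)], nrow = B)
    col0 <- col0 + ns
  }
  tstar <- apply(idx, 1, function(i) mean(x[i]))
  th <- mean(x)
  jack <- vapply(seq_len(n), function(i) mean(x[-i]), numeric(1))
  z0 <- qnorm((sum(tstar < th) + 0.5 * sum(tstar == th)) / B)
  d <- mean(jack) - jack
  a <- sum(d^3) / (6 * sum(d^2)^1.5)
  alpha <- c((1 - level) / 2, (1 + level) / 2)
  za <- qnorm(alpha)
  adj <- pnorm(z0 + (z0 + za) / (1 - a * (z0 + za)))
  ts <- sort(tstar)
  vapply(adj, function(al) {
    rk <- (B + 1) * al
    k <- floor(rk)
    if (k < 1) return(ts[1])
    if (k >= B) return(ts[B])
    ql <- qnorm(k / (B + 1)); qh <- qnorm((k + 1) / (B + 1))
    ts[k] + (qnorm(al) - ql) / (qh - ql) * (ts[k + 1] - ts[k])
  }, numeric(1))
}

# small four-group cohort reused across tests
small_cohort <- function(seed = 1, scale = 0.1) {
  generate_cohort(default_cohort_spec(scale = scale), seed = seed)
}
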