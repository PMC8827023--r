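# shared fixture builders; everything is generated in code under fixed seeds

# sire/dam/progeny trio, parents first
trio_pedigree <- function() {
  pedigree(c("s", "d", "c"), c("0", "0", "s"), c("0", "0", "d"))
}

# star pedigree: one sire, n progeny out of unknown dams
star_pedigree <- function(n_prog = 20L) {
  pedigree(c("S", paste0("P", seq_len(n_prog))),
           c("0", rep("S", n_prog)),
           rep("0", n_prog + 1L))
}

# random symmetric positive-definite matrix with unit-scale diagonal
rand_pd <- function(n) {
  L <- matrix(rnorm(n * n, sd = 1 / sqrt(n)), n)
  M <- tcrossprod(L) + diag(0.5, n)
  dimnames(M) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  M
}

# APY decomposition of a random PD matrix with the first nc animals as core
rand_apy <- function(n, nc) {
  G <- rand_pd(n)
  ids <- rownames(G)
  build_apy_decomposition(G, ids[seq_len(nc)], ids[-seq_len(nc)])
}

# exact reliabilities from dense inversion of diag(d) + alpha * A^-1
exact_pedigree_rel <- function(ped, d, alpha) {
  Ainv <- as.matrix(build_a_inverse(ped))
  K <- alpha * Ainv
  diag(K) <- diag(K) + d
  1 - diag(solve(K)) * alpha
}

# independent straight-line evaluation of the multi-trait working matrix:
# re-coded from the covariance-adjustment formula, sharing no code with
# adjust_multitrait()
mt_adjust_oracle <- function(rel, G0, R0, m, Q) {
  nt <- length(rel)
  O <- diag(rel * diag(R0) / ((1 - rel) * diag(G0)), nt)
  ginv_sub <- function(M, keep) {
    Z <- matrix(0, nt, nt)
    if (any(keep)) Z[keep, keep] <- solve(M[keep, keep, drop = FALSE])
    Z
  }
  sqrtO <- diag(sqrt(diag(O)), nt)
  t_own <- sqrtO %*% ginv_sub(R0, diag(O) > 0) %*% sqrtO
  G0i <- solve(G0)
  Qd <- diag(Q, nt)
  QRQ <- Qd %*% R0 %*% Qd
  prog <- matrix(0, nt, nt)
  for (j in seq_len(nt)) {
    prog <- prog + (1 / 3) * m[j] * G0i -
      (2 / 3) * m[j] * G0i %*%
        solve((4 / 3) * G0i + ginv_sub(QRQ, Q == 1)) %*% ((2 / 3) * G0i)
  }
  W <- solve(t_own + G0i + prog)
  1 - diag(W) / diag(G0)
}

# three growth traits with realistic heritabilities and correlations
three_trait_vc <- function() {
  h2 <- c(0.4, 0.3, 0.3)
  rg <- matrix(c(1, 0.5, 0.35,
                 0.5, 1, 0.55,
                 0.35, 0.55, 1), 3)
  re <- matrix(c(1, 0.25, 0.15,
                 0.25, 1, 0.3,
                 0.15, 0.3, 1), 3)
  su <- sqrt(h2)
  se <- sqrt(1 - h2)
  variance_components(G0 = outer(su, su) * rg, R0 = outer(se, se) * re)
}

# regression/agreement summary between approximate and exact reliabilities
agreement <- function(approx, exact) {
  fit <- stats::lm(exact ~ approx)
  list(corr = stats::cor(approx, exact),
       mac = mean(abs(approx - exact)),
       intercept = unname(stats::coef(fit)[1L]),
       slope = unname(stats::coef(fit)[2L]))
}
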