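#' Exact GBLUP prediction error variances by dense inversion
#'
#' Reference implementation: inverts `diag(d) + alpha * Ginv` densely and
#' returns the diagonal scaled by `sigma_e2`.  `Ginv` is either the dense
#' inverse of a genomic relationship matrix or the blockwise-assembled APY
#' inverse of an `apy_decomposition`.  Straight-line dense algebra, no block
#' shortcuts; intended as a validation oracle at desk scale.
#'
#' @param G dense genomic relationship matrix, or an `apy_decomposition`.
#' @param d non-negative diagonal weights (record information / ERC), ordered
#'   as the rows of `G` (core-then-noncore for an APY decomposition).
#' @param alpha variance ratio `sigma_e2 / sigma_u2`.
#' @param sigma_e2 residual variance (default 1).
#' @return numeric vector: `sigma_e2 * diag((diag(d) + alpha * Ginv)^-1)`.
#' @export
exact_gblup_pev <- function(G, d, alpha, sigma_e2 = 1) {
  Ginv <- if (inherits(G, "apy_decomposition")) apy_inverse_dense(G)
          else solve(G)
  n <- nrow(Ginv)
  if (length(d) != n) stop("d length mismatch")
  K <- alpha * Ginv
  diag(K) <- diag(K) + d
  unname(sigma_e2 * diag(solve(K)))
}

#' Exact single-step reliabilities by dense mixed-model inversion
#'
#' Reference implementation of the benchmark: builds the full mixed-model
#' coefficient matrix of the animal model with cross-classified fixed effects
#' and the single-step relationship inverse
#' `H^-1 = A^-1 + [0 0; 0 Ginv - A22^-1]` (with `Ginv` the APY inverse when
#' an `apy_decomposition` is given), inverts it densely, and converts the
#' animal-block diagonal to reliabilities `1 - sigma_e2 * diag / sigma_u2`.
#' Computed trait by trait.  Desk-scale only (a memory guard refuses
#' pedigrees above `max_n` animals).
#'
#' @param ped a sorted `pedigree`.
#' @param records records data frame (animal-id column plus effects and
#'   traits).
#' @param effects cross-classified fixed-effect column names.
#' @param traits trait column names.
#' @param vc a `variance_components` matching `length(traits)`.
#' @param apy an `apy_decomposition` of the genotyped animals, or `NULL` for
#'   pedigree BLUP.
#' @param id animal-id column name.
#' @param max_n refuse pedigrees larger than this (default 6000).
#' @return matrix of exact reliabilities, animals (pedigree order) x traits.
#' @export
exact_ssgblup_reliability <- function(ped, records, effects, traits, vc,
                                      apy = NULL, id = "animal",
                                      max_n = 6000L) {
  check_sorted(ped)
  n <- ped$n
  if (n > max_n)
    stop("pedigree too large for the dense oracle; use a scaled-down ",
         "configuration (n <= ", max_n, ")")
  stopifnot(inherits(vc, "variance_components"),
            length(traits) == vc$ntraits)
  records <- as.data.frame(records)
  Ainv <- as.matrix(build_a_inverse(ped))
  Hinv <- Ainv
  if (!is.null(apy)) {
    gids <- c(apy$core_ids, apy$noncore_ids)
    gi <- match(gids, ped$id)
    if (anyNA(gi)) stop("genotyped id not in pedigree")
    A22 <- build_a22(ped, gids)
    Hinv[gi, gi] <- Hinv[gi, gi] + apy_inverse_dense(apy) - solve(A22)
  }

  out <- matrix(NA_real_, n, length(traits),
                dimnames = list(ped$id, traits))
  ai_all <- match(as.character(records[[id]]), ped$id)
  if (anyNA(ai_all)) stop("record for animal absent from pedigree")
  for (t in seq_along(traits)) {
    obs <- !is.na(records[[traits[t]]])
    nr <- sum(obs)
    alpha <- vc$alpha[t]
    if (nr == 0L) {
      out[, t] <- 0
      next
    }
    ai <- ai_all[obs]
    ef <- records[obs, effects, drop = FALSE]
    for (j in seq_along(ef)) ef[[j]] <- factor(ef[[j]])
    X <- stats::model.matrix(~., data = ef)
    qrX <- qr(X)
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    p <- ncol(X)
    W <- Matrix::sparseMatrix(i = seq_len(nr), j = ai, x = 1,
                              dims = c(nr, n))
    WtW <- tabulate(ai, nbins = n)
    XtW <- as.matrix(Matrix::crossprod(Matrix::Matrix(X, sparse = TRUE), W))
    K <- matrix(0, p + n, p + n)
    K[seq_len(p), seq_len(p)] <- crossprod(X)
    K[seq_len(p), p + seq_len(n)] <- XtW
    K[p + seq_len(n), seq_len(p)] <- t(XtW)
    K[p + seq_len(n), p + seq_len(n)] <- alpha * Hinv
    diag(K)[p + seq_len(n)] <- diag(K)[p + seq_len(n)] + WtW
    Kinv_diag <- diag(chol2inv(chol(K)))[p + seq_len(n)]
    pev <- vc$sigma_e2[t] * Kinv_diag
    out[, t] <- pmin(pmax(1 - pev / vc$sigma_u2[t], 0), 1 - 1e-15)
  }
  out
}
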