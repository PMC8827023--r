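#' Assemble the shifted APY system D + alpha * G_APY^-1
#'
#' Adds per-animal record weights to the diagonal of the scaled APY inverse,
#' keeping its block-sparse structure: a dense core block `Kcc`, a dense
#' core-by-noncore block `Kcn` and a positive diagonal noncore block `knn`.
#'
#' @param apy an `apy_decomposition`.
#' @param d_weights non-negative record weights (diagonal D or ERCs), ordered
#'   core-then-noncore, length `nc + nn`.
#' @param alpha variance ratio `sigma_e2 / sigma_u2`.
#' @return object of class `shifted_system` with elements `Kcc`, `Kcn`,
#'   `knn`, `alpha`, `d`, `ids` (core then noncore), `nc`, `nn`.
#' @export
assemble_shifted_system <- function(apy, d_weights, alpha) {
  stopifnot(inherits(apy, "apy_decomposition"), alpha > 0)
  nc <- length(apy$core_ids)
  nn <- length(apy$noncore_ids)
  d_weights <- as.numeric(d_weights)
  if (length(d_weights) != nc + nn)
    stop("d_weights must have one entry per genotyped animal (core first)")
  if (any(d_weights < 0)) stop("negative record weight")
  d_core <- d_weights[seq_len(nc)]
  d_non <- d_weights[nc + seq_len(nn)]
  if (nn) {
    PM <- apy$Pnc / apy$Mnn                      # Mnn^-1 Pnc
    Kcc <- alpha * (apy$Gcc_inv + crossprod(apy$Pnc, PM))
    Kcn <- -alpha * t(PM)
    knn <- d_non + alpha / apy$Mnn
  } else {
    Kcc <- alpha * apy$Gcc_inv
    Kcn <- matrix(0, nc, 0L)
    knn <- numeric(0)
  }
  diag(Kcc) <- diag(Kcc) + d_core
  structure(list(Kcc = Kcc, Kcn = Kcn, knn = knn, alpha = alpha,
                 d = d_weights, ids = c(apy$core_ids, apy$noncore_ids),
                 nc = nc, nn = nn),
            class = "shifted_system")
}

#' Diagonal of the inverted shifted APY system by block-sparse inversion
#'
#' Extracts `diag((D + alpha * G_APY^-1)^-1)` exactly, exploiting the
#' dense-core / diagonal-noncore structure: with `U = Kcn knn^-1`, the core
#' block of the inverse is `T = (Kcc - U Kcn')^-1` (a Schur complement,
#' inverted by Cholesky) and the noncore diagonal is
#' `1/knn_i + u_i' T u_i` with `u_i` the i-th column of `U`.  No
#' noncore-by-noncore matrix is formed; the extra workspace is of core x
#' noncore size.
#'
#' Prediction error variances are `PEV = sigma_e2 * diag` and reliabilities
#' `rel = 1 - PEV / sigma_u2` with `sigma_u2 = sigma_e2 / alpha`.
#'
#' @param sys a `shifted_system`.
#' @param sigma_e2 residual variance (trait units squared), default 1 (the
#'   raw inverse diagonal is always returned alongside).
#' @return data frame of class `reliability_table` with columns `animal`,
#'   `diag_inv` (raw inverse diagonal), `pev`, `rel`, `group`
#'   (`core`/`noncore`); attribute `stage = "gblup"`.
#' @export
block_sparse_pev <- function(sys, sigma_e2 = 1) {
  stopifnot(inherits(sys, "shifted_system"), sigma_e2 > 0)
  nc <- sys$nc
  nn <- sys$nn
  if (nn) {
    U <- sweep(sys$Kcn, 2L, sys$knn, "/")        # Kcn knn^-1, nc x nn
    Tinv <- sys$Kcc - tcrossprod(U, sys$Kcn)     # Schur complement
    ch <- tryCatch(chol(Tinv), error = function(e)
      stop("Schur complement of the shifted system is not positive-definite"))
    Tm <- chol2inv(ch)
    dia_core <- diag(Tm)
    dia_non <- 1 / sys$knn + colSums(U * (Tm %*% U))
    dia <- c(dia_core, dia_non)
  } else {
    ch <- tryCatch(chol(sys$Kcc), error = function(e)
      stop("shifted core block is not positive-definite"))
    dia <- diag(chol2inv(ch))
  }
  sigma_u2 <- sigma_e2 / sys$alpha
  pev <- sigma_e2 * dia
  rel <- pmin(pmax(1 - pev / sigma_u2, 0), 1 - 1e-15)
  out <- data.frame(animal = sys$ids, diag_inv = dia, pev = pev, rel = rel,
                    group = rep(c("core", "noncore"), c(nc, nn)),
                    stringsAsFactors = FALSE)
  attr(out, "stage") <- "gblup"
  class(out) <- c("reliability_table", "data.frame")
  out
}
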