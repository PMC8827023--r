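#' Variance components
#'
#' Container for single-trait (`sigma_u2`, `sigma_e2`) or multiple-trait
#' (`G0`, `R0`) variance components.  For multiple traits the per-trait
#' single-trait components are the diagonals of `G0` and `R0`.
#'
#' @param sigma_u2,sigma_e2 genetic and residual variances (single trait).
#' @param G0,R0 genetic and residual covariance matrices among traits
#'   (symmetric positive-definite), for multiple-trait models.
#' @return object of class `variance_components` with elements `G0`, `R0`,
#'   `ntraits`, `sigma_u2`, `sigma_e2` (per-trait vectors) and `alpha`
#'   (`sigma_e2 / sigma_u2`, per trait).
#' @export
variance_components <- function(sigma_u2 = NULL, sigma_e2 = NULL,
                                G0 = NULL, R0 = NULL) {
  if (is.null(G0) != is.null(R0))
    stop("G0 and R0 must be supplied together")
  if (is.null(G0)) {
    if (is.null(sigma_u2) || is.null(sigma_e2))
      stop("supply either sigma_u2/sigma_e2 or G0/R0")
    G0 <- matrix(sigma_u2, 1, 1)
    R0 <- matrix(sigma_e2, 1, 1)
  }
  G0 <- as.matrix(G0); R0 <- as.matrix(R0)
  check_spd <- function(M, nm) {
    if (!isSymmetric(M, tol = 1e-8)) stop(nm, " must be symmetric")
    if (min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stop(nm, " must be positive-definite")
  }
  check_spd(G0, "G0"); check_spd(R0, "R0")
  if (!identical(dim(G0), dim(R0))) stop("G0 and R0 dimensions differ")
  su <- diag(G0); se <- diag(R0)
  structure(list(G0 = G0, R0 = R0, ntraits = nrow(G0),
                 sigma_u2 = su, sigma_e2 = se, alpha = se / su),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Variance components for", x$ntraits, "trait(s)\n")
  cat("  sigma_u2:", signif(x$sigma_u2, 4), "\n")
  cat("  sigma_e2:", signif(x$sigma_e2, 4), "\n")
  cat("  alpha   :", signif(x$alpha, 4), "\n")
  invisible(x)
}

#' Reliability from an effective record contribution
#'
#' Converts information expressed in record equivalents q into a reliability,
#' `rel = q / (q + alpha)` with `alpha = sigma_e2 / sigma_u2`.
#'
#' @param q non-negative effective record contribution(s).
#' @param alpha variance ratio `sigma_e2 / sigma_u2` (> 0).
#' @return reliability in `[0, 1)`, same length as `q`.
#' @export
rel_from_erc <- function(q, alpha) {
  stopifnot(alpha > 0)
  if (any(q < 0)) stop("negative effective record contribution")
  q / (q + alpha)
}

#' Effective record contribution from a reliability
#'
#' Inverse of [rel_from_erc()]: `q = alpha * rel / (1 - rel)`.
#'
#' @param rel reliability value(s) in `[0, 1)`.
#' @param alpha variance ratio `sigma_e2 / sigma_u2` (> 0).
#' @return non-negative record equivalents, same length as `rel`.
#' @export
erc_from_rel <- function(rel, alpha) {
  stopifnot(alpha > 0)
  if (any(rel < 0) || any(rel >= 1))
    stop("reliability must lie in [0, 1)")
  alpha * rel / (1 - rel)
}

#' Approximate per-animal record information (diagonal D)
#'
#' Approximates the diagonal of W'(I - X(X'X)^-X')W -- the record information
#' left after absorbing the cross-classified fixed effects -- in two passes
#' over the records.  Pass 1 counts records per fixed-effect level (per trait,
#' over records with a non-missing value for that trait); pass 2 gives each
#' record the weight `max(0, 1 - sum_effects 1/n_level)` and accumulates the
#' weights per animal.  Records missing a trait contribute 0 for that trait.
#'
#' Only cross-classified effects enter the weights; covariates are not part of
#' the model this approximation serves.
#'
#' @param records data frame with one row per record; must contain the column
#'   named by `id`, one column per effect in `effects` and one column per
#'   trait in `traits` (`NA` = missing).
#' @param effects character vector of cross-classified fixed-effect columns.
#' @param traits character vector of trait columns.
#' @param ped a `pedigree`; every record's animal must appear in it.
#' @param id name of the animal-id column, default `"animal"`.
#' @return object of class `record_info`: list with `d_own`
#'   (`ped$n x length(traits)` matrix of absorbed record weights, rows in
#'   pedigree order), `weights` (per record, per trait) and `traits`.
#' @export
approx_record_information <- function(records, effects, traits, ped,
                                      id = "animal") {
  records <- as.data.frame(records)
  need <- c(id, effects, traits)
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack column(s): ", paste(miss, collapse = ", "))
  check_sorted(ped)
  ai <- match(as.character(records[[id]]), ped$id)
  if (anyNA(ai))
    stop("record for animal absent from pedigree: ",
         records[[id]][which(is.na(ai))[1L]])

  nt <- length(traits)
  nr <- nrow(records)
  w <- matrix(0, nr, nt, dimnames = list(NULL, traits))
  d_own <- matrix(0, ped$n, nt, dimnames = list(ped$id, traits))
  for (t in seq_len(nt)) {
    obs <- !is.na(records[[traits[t]]])
    if (!any(obs)) next
    loss <- numeric(sum(obs))
    for (ef in effects) {
      lev <- as.character(records[[ef]][obs])
      nlev <- table(lev)
      loss <- loss + 1 / as.numeric(nlev[lev])
    }
    wt <- pmax(0, 1 - loss)
    w[obs, t] <- wt
    acc <- rowsum(wt, group = ai[obs])
    d_own[as.integer(rownames(acc)), t] <- acc
  }
  structure(list(d_own = d_own, weights = w, traits = traits),
            class = "record_info")
}

#' @export
print.record_info <- function(x, ...) {
  cat("Record information for", nrow(x$d_own), "animals,",
      length(x$traits), "trait(s)\n")
  for (t in x$traits)
    cat(sprintf("  %s: %d animals with d_own > 0, mean %.3f\n", t,
                sum(x$d_own[, t] > 0), mean(x$d_own[x$d_own[, t] > 0, t])))
  invisible(x)
}
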