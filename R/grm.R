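#' Genotype container
#'
#' Validates a dosage matrix (animals x markers, values 0/1/2) and attaches
#' allele frequencies.  Missing dosages are imputed to the nearest integer of
#' `2 * freq` (frequency computed from the observed dosages of that marker),
#' keeping the dosage domain in \{0, 1, 2\}.
#'
#' @param dosages integer/numeric matrix, animals in rows, markers in columns;
#'   entries 0, 1, 2 or `NA`.
#' @param ids animal identifiers (default: rownames).
#' @param allele_freq optional per-marker allele frequencies in (0, 1);
#'   computed from the dosages when not supplied.
#' @return object of class `genotype_matrix` with elements `ids`, `dosages`,
#'   `allele_freq`.
#' @export
genotype_matrix <- function(dosages, ids = rownames(dosages),
                            allele_freq = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(ids)) stop("animal ids required")
  ids <- as.character(ids)
  if (length(ids) != nrow(dosages)) stop("ids/dosages dimension mismatch")
  if (anyDuplicated(ids)) stop("duplicated genotyped animal id")
  obs_freq <- colMeans(dosages, na.rm = TRUE) / 2
  if (anyNA(dosages)) {
    for (k in which(colSums(is.na(dosages)) > 0L)) {
      fill <- round(2 * obs_freq[k])
      dosages[is.na(dosages[, k]), k] <- fill
    }
  }
  if (!all(dosages %in% c(0, 1, 2)))
    stop("dosages must be 0, 1 or 2")
  if (is.null(allele_freq)) allele_freq <- colMeans(dosages) / 2
  if (length(allele_freq) != ncol(dosages))
    stop("allele_freq length must equal the number of markers")
  rownames(dosages) <- ids
  structure(list(ids = ids, dosages = dosages,
                 allele_freq = as.numeric(allele_freq)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotypes:", length(x$ids), "animals x", ncol(x$dosages), "markers\n")
  invisible(x)
}

#' Genomic relationship matrix
#'
#' VanRaden method 1: dosages centered by twice the allele frequency,
#' `G = Z Z' / (2 * sum_k p_k (1 - p_k))`.
#'
#' @param gt a `genotype_matrix` (or a plain dosage matrix, converted with
#'   observed frequencies).
#' @return dense symmetric matrix with the genotyped ids as dimnames.
#' @export
build_grm <- function(gt) {
  if (!inherits(gt, "genotype_matrix")) gt <- genotype_matrix(gt)
  if (length(gt$ids) < 2L) stop("need at least two genotyped animals")
  p <- gt$allele_freq
  poly <- p > 0 & p < 1
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  if (!any(poly) || denom <= 0)
    stop("all markers are monomorphic; genomic relationship undefined")
  Z <- sweep(gt$dosages, 2L, 2 * p, "-")
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(gt$ids, gt$ids)
  G
}

#' Blend a genomic relationship matrix
#'
#' Returns `beta * G + (1 - beta) * B`, where `B` is the pedigree
#' relationship matrix among genotyped animals (A22) when available, else the
#' identity.  Blending guarantees a positive-definite core block for the APY
#' decomposition.
#'
#' @param G dense symmetric genomic relationship matrix.
#' @param B blending target (A22 or identity); `NULL` means identity.
#' @param beta blending weight in (0, 1], default 0.95.
#' @return blended dense symmetric matrix.
#' @export
blend_grm <- function(G, B = NULL, beta = 0.95) {
  if (beta <= 0 || beta > 1) stop("beta must lie in (0, 1]")
  if (is.null(B)) B <- diag(nrow(G))
  if (!all(dim(B) == dim(G))) stop("G and B dimensions differ")
  out <- beta * G + (1 - beta) * B
  dimnames(out) <- dimnames(G)
  out
}

#' Select core animals for APY
#'
#' Partitions the genotyped animals into a core and a noncore set.  Method
#' `"random"` draws `n_core` animals uniformly without replacement
#' (deterministic given `seed`); method `"given"` validates a user-supplied
#' core list.
#'
#' @param ids genotyped animal identifiers.
#' @param n_core number of core animals (method `"random"`).
#' @param method `"random"` or `"given"`.
#' @param seed integer seed for the random draw (the caller's RNG state is
#'   left untouched).
#' @param core_ids user-supplied core list (method `"given"`).
#' @return list with `core_ids` and `noncore_ids` (disjoint, exhaustive).
#' @export
select_core <- function(ids, n_core = NULL, method = c("random", "given"),
                        seed = NULL, core_ids = NULL) {
  method <- match.arg(method)
  ids <- as.character(ids)
  n <- length(ids)
  if (method == "random") {
    if (is.null(n_core) || n_core < 1L || n_core > n)
      stop("n_core must lie in [1, number of genotyped animals]")
    core <- local_seed_sample(ids, n_core, seed)
  } else {
    core_ids <- as.character(core_ids)
    if (anyDuplicated(core_ids)) stop("duplicated ids in core list")
    if (!all(core_ids %in% ids)) stop("core list contains non-genotyped ids")
    core <- core_ids
  }
  list(core_ids = core, noncore_ids = setdiff(ids, core))
}

# sample() under a private RNG stream; restores the caller's .Random.seed
local_seed_sample <- function(x, size, seed) {
  if (is.null(seed)) return(sample(x, size))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample(x, size)
}

#' APY decomposition of a genomic relationship matrix
#'
#' Builds the blocks of the APY representation of G and of its sparse
#' inverse: `Gcc` (core block) and its inverse, `Pnc = Gnc Gcc^-1`
#' (regressions of noncore on core animals) and the diagonal
#' `Mnn = diag(Gnn - Gnc Gcc^-1 Gcn)` of conditional noncore variances.
#' `Mnn` is computed row by row; no noncore x noncore matrix is ever formed.
#'
#' @param G dense symmetric genomic relationship matrix with id dimnames
#'   (blend first if the core block is not positive-definite).
#' @param core_ids,noncore_ids partition of the genotyped ids.
#' @return object of class `apy_decomposition` with elements `core_ids`,
#'   `noncore_ids`, `Gcc`, `Gcn`, `Gcc_inv`, `Pnc`, `Mnn`.
#' @export
build_apy_decomposition <- function(G, core_ids, noncore_ids) {
  ids <- rownames(G)
  if (is.null(ids)) stop("G needs id dimnames")
  core_ids <- as.character(core_ids)
  noncore_ids <- as.character(noncore_ids)
  if (length(intersect(core_ids, noncore_ids)))
    stop("core and noncore sets overlap")
  if (!setequal(c(core_ids, noncore_ids), ids))
    stop("core + noncore must partition the genotyped animals")
  ci <- match(core_ids, ids)
  ni <- match(noncore_ids, ids)
  Gcc <- G[ci, ci, drop = FALSE]
  Gcn <- G[ci, ni, drop = FALSE]
  ch <- tryCatch(chol(Gcc), error = function(e)
    stop("core block is not positive-definite; blend G first (blend_grm)"))
  Gcc_inv <- chol2inv(ch)
  dimnames(Gcc_inv) <- dimnames(Gcc)
  if (length(ni)) {
    Pnc <- crossprod(Gcn, Gcc_inv)            # nn x nc
    Mnn <- diag(G)[ni] - rowSums(Pnc * t(Gcn))
    if (any(Mnn <= 0))
      stop("non-positive conditional variance (Mnn) for a noncore animal; ",
           "blend G or enlarge the core")
  } else {
    Pnc <- matrix(0, 0L, length(ci))
    Mnn <- numeric(0)
  }
  structure(list(core_ids = core_ids, noncore_ids = noncore_ids,
                 Gcc = Gcc, Gcn = Gcn, Gcc_inv = Gcc_inv,
                 Pnc = Pnc, Mnn = Mnn),
            class = "apy_decomposition")
}

#' @export
print.apy_decomposition <- function(x, ...) {
  cat("APY decomposition:", length(x$core_ids), "core,",
      length(x$noncore_ids), "noncore animals\n")
  invisible(x)
}

#' Dense APY genomic relationship matrix and its inverse
#'
#' Blockwise assembly of `G_APY` and `G_APY^-1` from an APY decomposition,
#' core animals first.  Intended for validation at desk scale.
#'
#' @param apy an `apy_decomposition`.
#' @return dense symmetric matrix (core-then-noncore order).
#' @export
apy_grm_dense <- function(apy) {
  nn <- length(apy$noncore_ids)
  if (nn == 0L) {
    out <- apy$Gcc
  } else {
    Gnn <- apy$Pnc %*% apy$Gcn
    diag(Gnn) <- diag(Gnn) + apy$Mnn
    out <- rbind(cbind(apy$Gcc, apy$Gcn),
                 cbind(t(apy$Gcn), Gnn))
  }
  ids <- c(apy$core_ids, apy$noncore_ids)
  dimnames(out) <- list(ids, ids)
  out
}

#' @rdname apy_grm_dense
#' @export
apy_inverse_dense <- function(apy) {
  nn <- length(apy$noncore_ids)
  if (nn == 0L) {
    out <- apy$Gcc_inv
  } else {
    PM <- apy$Pnc / apy$Mnn                     # Mnn^-1 Pnc
    out <- rbind(cbind(apy$Gcc_inv + crossprod(apy$Pnc, PM), -t(PM)),
                 cbind(-PM, diag(1 / apy$Mnn, nn)))
  }
  ids <- c(apy$core_ids, apy$noncore_ids)
  dimnames(out) <- list(ids, ids)
  out
}
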