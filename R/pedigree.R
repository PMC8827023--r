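#' Build and sort a pedigree
#'
#' Constructs a `pedigree` object from animal/sire/dam triples and sorts it so
#' that every parent precedes all of its progeny.  Animals are classified into
#' non-overlapping generations: founders (both parents unknown) receive
#' generation code 0 and every other animal a code one larger than the maximum
#' code of its known parents.  Ordering is by generation code, stable within a
#' generation by input order.
#'
#' Unknown parents are coded `"0"`, `NA` or `""` in the input.  A parent that
#' is referenced but never declared as an animal is added as a founder with a
#' warning.  A cycle (an animal that is its own ancestor) is an error.
#'
#' @param animal character or integer vector of animal identifiers (unique).
#' @param sire,dam parent identifiers, same length as `animal`; `"0"`, `NA` or
#'   `""` mean unknown.
#' @param sex optional vector of sex codes, carried along for reporting only.
#' @return An object of class `pedigree`: a list with elements `id` (character,
#'   in sorted order), `sire`/`dam` (integer positions of the parents in the
#'   sorted order, `NA` if unknown), `gen` (integer generation codes) and `n`.
#' @examples
#' ped <- pedigree(c("c", "s", "d"), c("s", "0", "0"), c("d", "0", "0"))
#' ped$id   # parents first
#' @export
pedigree <- function(animal, sire, dam, sex = NULL) {
  animal <- as.character(animal)
  sire <- as.character(sire)
  dam <- as.character(dam)
  if (anyNA(animal) || any(animal %in% c("0", "")))
    stop("animal ids must be non-missing and distinct from the unknown-parent code \"0\"")
  if (anyDuplicated(animal))
    stop("duplicated animal id: ", animal[duplicated(animal)][1L])
  n0 <- length(animal)
  if (length(sire) != n0 || length(dam) != n0)
    stop("animal, sire and dam must have equal length")
  unk <- function(x) is.na(x) | x == "0" | x == ""
  sire[unk(sire)] <- NA_character_
  dam[unk(dam)] <- NA_character_

  # auto-add parents that appear only as parents
  extra <- setdiff(c(sire, dam), c(animal, NA_character_))
  if (length(extra)) {
    warning(length(extra), " parent(s) not declared as animals; added as founders")
    animal <- c(extra, animal)
    sire <- c(rep(NA_character_, length(extra)), sire)
    dam <- c(rep(NA_character_, length(extra)), dam)
    if (!is.null(sex)) sex <- c(rep(NA, length(extra)), sex)
  }
  n <- length(animal)
  si <- match(sire, animal)
  di <- match(dam, animal)

  # generation codes by relaxation; at most n passes, else there is a cycle
  gen <- ifelse(is.na(si) & is.na(di), 0L, NA_integer_)
  for (pass in seq_len(n)) {
    todo <- which(is.na(gen))
    if (!length(todo)) break
    progress <- FALSE
    for (i in todo) {
      gs <- if (is.na(si[i])) 0L else gen[si[i]]
      gd <- if (is.na(di[i])) 0L else gen[di[i]]
      if (!is.na(gs) && !is.na(gd)) {
        gen[i] <- max(gs, gd) + 1L
        progress <- TRUE
      }
    }
    if (!progress) break
  }
  if (anyNA(gen)) {
    bad <- animal[which(is.na(gen))[1L]]
    stop("pedigree cycle detected involving animal ", bad)
  }

  ord <- order(gen, seq_len(n))
  pos <- integer(n)
  pos[ord] <- seq_len(n)
  obj <- list(
    id = animal[ord],
    sire = pos[si][ord],
    dam = pos[di][ord],
    gen = gen[ord],
    sex = if (is.null(sex)) NULL else sex[ord],
    n = n
  )
  class(obj) <- "pedigree"
  obj
}

#' Sort a pedigree parents-first
#'
#' Accepts either a `pedigree` object (re-sorted, a no-op if already valid) or
#' a data frame whose first three columns are animal, sire and dam.
#'
#' @param ped a `pedigree` or a data frame with columns animal, sire, dam.
#' @return a sorted `pedigree` object.
#' @export
sort_pedigree <- function(ped) {
  if (inherits(ped, "pedigree")) {
    return(pedigree(ped$id,
                    ifelse(is.na(ped$sire), NA, ped$id[ped$sire]),
                    ifelse(is.na(ped$dam), NA, ped$id[ped$dam]),
                    sex = ped$sex))
  }
  ped <- as.data.frame(ped)
  if (ncol(ped) < 3L) stop("pedigree data frame needs columns animal, sire, dam")
  sex <- if (ncol(ped) >= 4L) ped[[4L]] else NULL
  pedigree(ped[[1L]], ped[[2L]], ped[[3L]], sex = sex)
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree with", x$n, "animals in", max(x$gen) + 1L, "generation(s)\n")
  cat("  founders:", sum(x$gen == 0L), "\n")
  invisible(x)
}

#' @export
as.data.frame.pedigree <- function(x, ...) {
  data.frame(animal = x$id,
             sire = ifelse(is.na(x$sire), "0", x$id[x$sire]),
             dam = ifelse(is.na(x$dam), "0", x$id[x$dam]),
             gen = x$gen,
             stringsAsFactors = FALSE)
}

check_sorted <- function(ped) {
  if (!inherits(ped, "pedigree"))
    stop("expected a 'pedigree' object (see pedigree() / sort_pedigree())")
  idx <- seq_len(ped$n)
  ok <- (is.na(ped$sire) | ped$sire < idx) & (is.na(ped$dam) | ped$dam < idx)
  if (!all(ok)) stop("pedigree is not sorted parents-first")
  invisible(TRUE)
}

#' Inverse of the numerator relationship matrix
#'
#' Assembles the sparse inverse of the pedigree (numerator) relationship
#' matrix A by Henderson's rules for a non-inbred pedigree: each animal
#' contributes with Mendelian-sampling precision 2 when both parents are
#' known, 4/3 when one is known and 1 when none is.
#'
#' @param ped a sorted `pedigree`.
#' @return a symmetric sparse `Matrix` of dimension `ped$n`.
#' @export
build_a_inverse <- function(ped) {
  check_sorted(ped)
  n <- ped$n
  s <- ped$sire
  d <- ped$dam
  nk <- (!is.na(s)) + (!is.na(d))
  b <- c(1, 4 / 3, 2)[nk + 1L]
  ii <- seq_len(n)

  ti <- ii; tj <- ii; tx <- b                       # (i,i) += b
  hs <- !is.na(s)
  ti <- c(ti, ii[hs], s[hs], s[hs])
  tj <- c(tj, s[hs], ii[hs], s[hs])
  tx <- c(tx, -b[hs] / 2, -b[hs] / 2, b[hs] / 4)    # sire terms
  hd <- !is.na(d)
  ti <- c(ti, ii[hd], d[hd], d[hd])
  tj <- c(tj, d[hd], ii[hd], d[hd])
  tx <- c(tx, -b[hd] / 2, -b[hd] / 2, b[hd] / 4)    # dam terms
  hb <- hs & hd
  ti <- c(ti, s[hb], d[hb])
  tj <- c(tj, d[hb], s[hb])
  tx <- c(tx, b[hb] / 4, b[hb] / 4)                 # sire x dam cross terms
  Ainv <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(n, n))
  Matrix::forceSymmetric(Ainv)
}

#' Numerator relationship matrix by the tabular method
#'
#' Dense recursive construction of A on a sorted pedigree under the
#' non-inbred convention: A = T D T' with the breeding-value recursion
#' `u_i = 0.5 u_s + 0.5 u_d + phi_i` and Mendelian-sampling variances
#' `D_ii` of 1/2 (both parents known), 3/4 (one) or 1 (none), so the
#' diagonal is `0.25 (a_ss + 2 a_sd + a_dd) + D_ii`.  This is the exact
#' inverse pair of the Henderson rules in [build_a_inverse()] on any
#' pedigree, related matings included.  Intended for desk-scale pedigrees
#' (a few thousand animals).
#'
#' @param ped a sorted `pedigree`.
#' @return dense symmetric matrix, rows/columns in pedigree order.
#' @export
build_a <- function(ped) {
  check_sorted(ped)
  n <- ped$n
  A <- matrix(0, n, n)
  s <- ped$sire
  d <- ped$dam
  for (i in seq_len(n)) {
    dii <- 1
    vpar <- 0
    if (i > 1L) {
      j <- seq_len(i - 1L)
      rs <- if (is.na(s[i])) 0 else A[s[i], j]
      rd <- if (is.na(d[i])) 0 else A[d[i], j]
      aij <- 0.5 * (rs + rd)
      A[i, j] <- aij
      A[j, i] <- aij
    }
    if (!is.na(s[i])) {
      dii <- dii - 0.25
      vpar <- vpar + 0.25 * A[s[i], s[i]]
    }
    if (!is.na(d[i])) {
      dii <- dii - 0.25
      vpar <- vpar + 0.25 * A[d[i], d[i]]
    }
    if (!is.na(s[i]) && !is.na(d[i])) vpar <- vpar + 0.5 * A[s[i], d[i]]
    A[i, i] <- vpar + dii
  }
  dimnames(A) <- list(ped$id, ped$id)
  A
}

#' Pedigree relationship matrix among genotyped animals
#'
#' Computes A22, the block of the numerator relationship matrix restricted to
#' the genotyped animals, with relationship paths through non-genotyped
#' ancestors preserved (full tabular recursion, then subsetting).
#'
#' @param ped a sorted `pedigree`.
#' @param genotyped_ids identifiers of the genotyped animals (subset of
#'   `ped$id`).
#' @return dense symmetric matrix with rows/columns in the order of
#'   `genotyped_ids`.
#' @export
build_a22 <- function(ped, genotyped_ids) {
  check_sorted(ped)
  genotyped_ids <- as.character(genotyped_ids)
  idx <- match(genotyped_ids, ped$id)
  if (anyNA(idx))
    stop("genotyped id not in pedigree: ", genotyped_ids[which(is.na(idx))[1L]])
  A <- build_a(ped)
  A[idx, idx, drop = FALSE]
}
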