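#' Genomic (GBLUP) reliability step for genotyped animals
#'
#' Solves the shifted APY system with pedigree-stage effective record
#' contributions as diagonal weights and returns genomic reliabilities for
#' the genotyped animals.
#'
#' @param apy an `apy_decomposition`.
#' @param erc effective record contributions, one per genotyped animal,
#'   ordered core-then-noncore.
#' @param vc a `variance_components` (single trait) or a list with
#'   `sigma_u2`, `sigma_e2`.
#' @return `reliability_table` (stage `"gblup"`), see [block_sparse_pev()].
#' @export
gblup_reliability_step <- function(apy, erc, vc) {
  alpha <- vc$sigma_e2[1L] / vc$sigma_u2[1L]
  sys <- assemble_shifted_system(apy, erc, alpha)
  block_sparse_pev(sys, sigma_e2 = vc$sigma_e2[1L])
}

#' Pedigree reliability of genotyped animals without non-genotyped information
#'
#' Approximates, for the genotyped animals, the reliability that their
#' pedigree-stage effective record contributions would give through pedigree
#' relationships alone (the "A22" reliabilities): the pedigree approximation
#' is rerun with own-information equal to the ERC for genotyped animals and
#' zero for all others, so relationship paths through non-genotyped ancestors
#' are kept but those ancestors carry no information of their own.
#'
#' With `exact = TRUE` the dense system `diag(ERC) + alpha * A22^-1` is
#' inverted instead (desk-scale validation mode).
#'
#' @param ped a sorted `pedigree`.
#' @param erc_genotyped named or ordered ERC vector for `genotyped_ids`.
#' @param genotyped_ids genotyped animal identifiers.
#' @param alpha variance ratio.
#' @param exact logical; dense validation mode (default `FALSE`).
#' @param ... passed to [approx_pedigree_reliability()].
#' @return numeric vector of reliabilities, one per `genotyped_ids`.
#' @export
a22_reliability_step <- function(ped, erc_genotyped, genotyped_ids, alpha,
                                 exact = FALSE, ...) {
  check_sorted(ped)
  genotyped_ids <- as.character(genotyped_ids)
  gi <- match(genotyped_ids, ped$id)
  if (anyNA(gi)) stop("genotyped id not in pedigree")
  if (exact) {
    A22 <- build_a22(ped, genotyped_ids)
    K <- alpha * solve(A22)
    diag(K) <- diag(K) + erc_genotyped
    dia <- unname(diag(solve(K)))
    return(pmin(pmax(1 - dia * alpha, 0), 1 - 1e-15))
  }
  q_own <- numeric(ped$n)
  q_own[gi] <- erc_genotyped
  fit <- approx_pedigree_reliability(ped, q_own, alpha, ...)
  fit$rel[gi]
}

#' Combine pedigree, genomic and A22 reliabilities
#'
#' Effective-record-contribution additivity: the net genomic gain is the
#' information in the genomic step not already counted through pedigree
#' relationships among genotyped animals,
#' `q_final = max(0, q(rel_ped) + q(rel_gblup) - q(rel_a22))` with
#' `q(r) = alpha r / (1 - r)`; the combined reliability is
#' `q_final / (q_final + alpha)`.
#'
#' @param rel_ped,rel_gblup,rel_a22 reliability vectors in `[0, 1)` for the
#'   genotyped animals.
#' @param alpha variance ratio.
#' @return combined reliability vector.
#' @export
combine_reliabilities <- function(rel_ped, rel_gblup, rel_a22, alpha) {
  q <- pmax(0, erc_from_rel(rel_ped, alpha) + erc_from_rel(rel_gblup, alpha) -
              erc_from_rel(rel_a22, alpha))
  rel_from_erc(q, alpha)
}

#' Propagate genomic reliabilities to non-genotyped animals
#'
#' For each genotyped animal, back-solves (Steffensen) the own-information
#' `q*` that reproduces its combined reliability when all other animals'
#' pedigree-stage contributions are held fixed; the pedigree approximation is
#' then rerun with `q_own = q*` for genotyped animals and the original record
#' information for non-genotyped animals.  Non-genotyped reliabilities are
#' read from that run; genotyped animals keep their combined values.
#'
#' @param ped a sorted `pedigree`.
#' @param d_own per-animal own-record information (pedigree order).
#' @param rel_final_genotyped combined reliabilities for `genotyped_ids`.
#' @param genotyped_ids genotyped animal identifiers.
#' @param alpha variance ratio.
#' @param ped_fit pedigree-stage fit from [approx_pedigree_reliability()]
#'   (recomputed when omitted); supplies the frozen `q_par + q_prog`.
#' @param ... passed to [approx_pedigree_reliability()].
#' @return list with `rel` (all animals, pedigree order; stage `"final"`),
#'   `erc_final` (the back-solved own-information of genotyped animals, the
#'   original `d_own` elsewhere) and `backsolve_failures`.
#' @export
propagate_to_nongenotyped <- function(ped, d_own, rel_final_genotyped,
                                      genotyped_ids, alpha, ped_fit = NULL,
                                      ...) {
  check_sorted(ped)
  gi <- match(as.character(genotyped_ids), ped$id)
  if (anyNA(gi)) stop("genotyped id not in pedigree")
  if (is.null(ped_fit))
    ped_fit <- approx_pedigree_reliability(ped, d_own, alpha, ...)
  q_rel <- ped_fit$q_par + ped_fit$q_prog      # relative information, frozen

  q_star <- numeric(length(gi))
  failures <- 0L
  for (k in seq_along(gi)) {
    i <- gi[k]
    fmap <- function(q) (q + q_rel[i]) / (q + q_rel[i] + alpha)
    bs <- backsolve_erc_steffensen(rel_final_genotyped[k], fmap,
                                   alpha = alpha)
    if (!bs$converged) {
      failures <- failures + 1L
      q_star[k] <- erc_from_rel(rel_final_genotyped[k], alpha)
    } else q_star[k] <- bs$q
  }
  if (failures)
    warning(failures, " genotyped animal(s) fell back to direct ERC conversion")

  q_own <- as.numeric(d_own)
  q_own[gi] <- q_star
  fit <- approx_pedigree_reliability(ped, q_own, alpha, ...)
  rel <- fit$rel
  rel[gi] <- rel_final_genotyped
  list(rel = rel, erc_final = q_own, backsolve_failures = failures)
}

# generalized inverse restricted to kept traits, zero elsewhere
masked_inverse <- function(M, keep) {
  out <- matrix(0, nrow(M), ncol(M))
  if (any(keep)) out[keep, keep] <- solve(M[keep, keep, drop = FALSE])
  out
}

#' Multiple-trait reliability adjustment
#'
#' Adjusts per-trait single-trait reliabilities for the information carried
#' across traits by the genetic (`G0`) and residual (`R0`) covariances.  For
#' each animal a working prediction-error matrix of trait dimension is formed,
#' `W = (O^{1/2} R0~^{-1} O^{1/2} + G0^{-1} + sum_j m_j B)^{-1}`, where
#' `O_jj = rel_j R0_jj / ((1 - rel_j) G0_jj)` are effective observations per
#' trait (the unique diagonal recovering the single-trait reliability when
#' there is one trait and no progeny term), `R0~^{-1}` is the inverse of `R0`
#' restricted to traits with `O_jj > 0`, `m_j` counts progeny with records
#' for trait j, and the progeny information matrix is
#' `B = (1/3) G0^{-1} - (2/3) G0^{-1} ((4/3) G0^{-1} + (Q R0 Q)^-)^{-1}
#' (2/3) G0^{-1}` with `Q` the 0/1 diagonal of non-missing traits and
#' `(.)^-` the inverse restricted to non-missing traits.  The adjusted
#' reliability of trait j is `1 - W_jj / G0_jj`, clamped to `[0, 1)`.
#'
#' @param rel matrix of single-trait reliabilities, animals x traits.
#' @param G0,R0 genetic and residual covariance matrices among traits.
#' @param m matrix of per-trait progeny counts, animals x traits.
#' @param Q 0/1 matrix of trait non-missingness, animals x traits.
#' @return matrix of adjusted reliabilities, animals x traits.
#' @export
adjust_multitrait <- function(rel, G0, R0, m, Q) {
  vc <- variance_components(G0 = G0, R0 = R0)   # validates symmetry/PD
  G0 <- vc$G0; R0 <- vc$R0
  nt <- vc$ntraits
  rel <- as.matrix(rel); m <- as.matrix(m); Q <- as.matrix(Q)
  stopifnot(ncol(rel) == nt, all(dim(m) == dim(rel)), all(dim(Q) == dim(rel)))
  if (any(rel < 0 | rel >= 1)) stop("reliabilities must lie in [0, 1)")
  if (any(m < 0)) stop("negative progeny count")
  if (!all(Q %in% c(0, 1))) stop("Q entries must be 0 or 1")
  G0inv <- solve(G0)
  out <- matrix(0, nrow(rel), nt, dimnames = dimnames(rel))
  for (a in seq_len(nrow(rel))) {
    r <- rel[a, ]
    O <- r * diag(R0) / ((1 - r) * diag(G0))
    sqO <- sqrt(O)
    own <- outer(sqO, sqO) * masked_inverse(R0, O > 0)
    qk <- Q[a, ] == 1
    QRQ_inv <- masked_inverse(R0 * outer(Q[a, ], Q[a, ]), qk)
    inner <- solve((4 / 3) * G0inv + QRQ_inv)
    B <- (1 / 3) * G0inv -
      (2 / 3) * G0inv %*% inner %*% ((2 / 3) * G0inv)
    W <- solve(own + G0inv + sum(m[a, ]) * B)
    out[a, ] <- pmin(pmax(1 - diag(W) / diag(G0), 0), 1 - 1e-15)
  }
  out
}

#' Run the single-step reliability approximation (engine)
#'
#' Executes, per trait: (1) pedigree reliability approximation and conversion
#' to effective record contributions; (2) genomic step on the shifted APY
#' system; (3) pedigree reliability of genotyped animals through A22 alone;
#' (4) combination by ERC additivity; (5) Steffensen back-solve and
#' propagation to non-genotyped animals.  With more than one trait the
#' per-trait results are then adjusted with [adjust_multitrait()].
#'
#' Most users call [ssgblup_rel()], the formula interface around this engine.
#'
#' @param ped a sorted `pedigree`.
#' @param records records data frame (see [approx_record_information()]).
#' @param effects cross-classified fixed-effect column names.
#' @param traits trait column names.
#' @param vc a `variance_components`.
#' @param apy an `apy_decomposition` of the genotyped animals, or `NULL` for
#'   a pedigree-only analysis.
#' @param id animal-id column in `records`.
#' @param max_rounds,tol controls for [approx_pedigree_reliability()].
#' @return object of class `ssgblup_rel`.
#' @export
run_ssgblup <- function(ped, records, effects, traits, vc, apy = NULL,
                        id = "animal", max_rounds = 20L, tol = 1e-5) {
  check_sorted(ped)
  stopifnot(inherits(vc, "variance_components"))
  if (length(traits) != vc$ntraits)
    stop("number of traits and variance-component dimension differ")
  info <- approx_record_information(records, effects, traits, ped, id = id)
  gids <- if (is.null(apy)) character(0) else c(apy$core_ids, apy$noncore_ids)
  gi <- match(gids, ped$id)
  if (anyNA(gi)) stop("genotyped id not in pedigree")
  nt <- vc$ntraits
  n <- ped$n

  rel_ped <- rel_gblup <- rel_a22 <- rel_final <- matrix(NA_real_, n, nt)
  erc_ped <- erc_final <- matrix(NA_real_, n, nt)
  timings <- c()
  for (t in seq_len(nt)) {
    alpha <- vc$alpha[t]
    t0 <- proc.time()[3L]
    ped_fit <- approx_pedigree_reliability(ped, info$d_own[, t], alpha,
                                           max_rounds = max_rounds, tol = tol)
    rel_ped[, t] <- ped_fit$rel
    erc_ped[, t] <- erc_from_rel(ped_fit$rel, alpha)
    t1 <- proc.time()[3L]
    timings <- c(timings, pedigree = unname(t1 - t0))
    if (length(gids)) {
      gb <- gblup_reliability_step(apy, erc_ped[gi, t],
                                   list(sigma_u2 = vc$sigma_u2[t],
                                        sigma_e2 = vc$sigma_e2[t]))
      rel_gblup[gi, t] <- gb$rel
      t2 <- proc.time()[3L]
      rel_a22[gi, t] <- a22_reliability_step(ped, erc_ped[gi, t], gids, alpha,
                                             max_rounds = max_rounds,
                                             tol = tol)
      t3 <- proc.time()[3L]
      rel_final[gi, t] <- combine_reliabilities(rel_ped[gi, t],
                                                rel_gblup[gi, t],
                                                rel_a22[gi, t], alpha)
      prop <- propagate_to_nongenotyped(ped, info$d_own[, t],
                                        rel_final[gi, t], gids, alpha,
                                        ped_fit = ped_fit,
                                        max_rounds = max_rounds, tol = tol)
      rel_final[, t] <- prop$rel
      erc_final[, t] <- prop$erc_final
      t4 <- proc.time()[3L]
      timings <- c(timings, gblup = unname(t2 - t1), a22 = unname(t3 - t2),
                   propagation = unname(t4 - t3))
    } else {
      rel_final[, t] <- rel_ped[, t]
      erc_final[, t] <- info$d_own[, t]
    }
  }

  rel_mt <- NULL
  if (nt > 1L) {
    t0 <- proc.time()[3L]
    mQ <- progeny_and_missingness(ped, records, traits, id = id)
    rel_mt <- adjust_multitrait(rel_final, vc$G0, vc$R0, mQ$m, mQ$Q)
    timings <- c(timings, multitrait = unname(proc.time()[3L] - t0))
  }

  group <- rep("nongenotyped", n)
  if (length(gids)) {
    group[match(apy$core_ids, ped$id)] <- "core"
    group[match(apy$noncore_ids, ped$id)] <- "noncore"
  }
  tab <- do.call(rbind, lapply(seq_len(nt), function(t) {
    data.frame(animal = ped$id, trait = traits[t], group = group,
               rel_pedigree = rel_ped[, t], rel_gblup = rel_gblup[, t],
               rel_a22 = rel_a22[, t], rel_final = rel_final[, t],
               rel_mt = if (is.null(rel_mt)) NA_real_ else rel_mt[, t],
               pev = (1 - rel_final[, t]) * vc$sigma_u2[t],
               erc_pedigree = erc_ped[, t], erc_final = erc_final[, t],
               stringsAsFactors = FALSE)
  }))
  structure(list(table = tab, traits = traits, vc = vc,
                 genotyped_ids = gids, n_animals = n,
                 rel_final = if (is.null(rel_mt)) rel_final else rel_mt,
                 timings = timings),
            class = "ssgblup_rel")
}

# per-animal progeny counts per trait and own-record missingness indicator
progeny_and_missingness <- function(ped, records, traits, id = "animal") {
  n <- ped$n
  nt <- length(traits)
  ai <- match(as.character(records[[id]]), ped$id)
  m <- matrix(0, n, nt)
  Q <- matrix(0, n, nt)
  for (t in seq_len(nt)) {
    has_rec <- tabulate(ai[!is.na(records[[traits[t]]])], nbins = n) > 0L
    Q[has_rec, t] <- 1
    for (p in which(has_rec)) {
      if (!is.na(ped$sire[p])) m[ped$sire[p], t] <- m[ped$sire[p], t] + 1
      if (!is.na(ped$dam[p])) m[ped$dam[p], t] <- m[ped$dam[p], t] + 1
    }
  }
  list(m = m, Q = Q)
}

#' Reliabilities for single-step genomic BLUP with the APY inverse
#'
#' Fits the reliability approximation for an animal model with
#' cross-classified fixed effects, from a pedigree, phenotype records and
#' (optionally) SNP genotypes.  The model is `y = Xb + Wu + e` with
#' `Var(u) = G_APY sigma_u2` for genotyped animals embedded in a single-step
#' relationship structure; reliabilities are `1 - PEV / sigma_u2`.
#'
#' @param formula model formula: trait (or `cbind(trait1, trait2, ...)`) on
#'   the left, cross-classified fixed effects on the right, e.g.
#'   `pwg ~ cg + sex`.  Non-factor right-hand-side terms are dropped with a
#'   warning (covariates play no role in the record-information
#'   approximation).
#' @param data records data frame; one row per record, with an animal-id
#'   column (`id`), the effect columns and the trait columns.
#' @param pedigree a `pedigree`, or a data frame passed to [sort_pedigree()].
#' @param genotypes a `genotype_matrix` of the genotyped animals, or `NULL`
#'   for a pedigree-only analysis.
#' @param vc a `variance_components`; or pass `sigma_u2`/`sigma_e2` (single
#'   trait) or `G0`/`R0` (multi-trait) directly.
#' @param sigma_u2,sigma_e2,G0,R0 variance components, used when `vc` is
#'   missing.
#' @param n_core number of core animals (random core); default
#'   `ceiling(sqrt(n_genotyped) * 4)` capped at the number genotyped.
#' @param core_ids explicit core list (overrides `n_core`).
#' @param beta blending weight for [blend_grm()] (default 0.95, blended
#'   towards A22).
#' @param seed seed for the random core draw.
#' @param id animal-id column name in `data` (default `"animal"`).
#' @param max_rounds,tol pedigree-approximation controls.
#' @return an object of class `ssgblup_rel`; see [run_ssgblup()].  Methods:
#'   `print`, `summary`, `plot`, `as.data.frame`.
#' @examples
#' sim <- simulate_population(sim_config(n_founders = 40, n_generations = 3,
#'                                       seed = 1))
#' fit <- ssgblup_rel(t1 ~ cg + sex, data = sim$records,
#'                    pedigree = sim$pedigree, genotypes = sim$genotypes,
#'                    sigma_u2 = 0.3, sigma_e2 = 0.7, n_core = 10, seed = 1)
#' summary(fit)
#' @export
ssgblup_rel <- function(formula, data, pedigree, genotypes = NULL,
                        vc = NULL, sigma_u2 = NULL, sigma_e2 = NULL,
                        G0 = NULL, R0 = NULL,
                        n_core = NULL, core_ids = NULL, beta = 0.95,
                        seed = 1L, id = "animal",
                        max_rounds = 20L, tol = 1e-5) {
  data <- as.data.frame(data)
  lhs <- formula[[2L]]
  traits <- if (is.call(lhs) && identical(lhs[[1L]], as.name("cbind")))
    vapply(as.list(lhs)[-1L], deparse, "") else deparse(lhs)
  effects <- attr(stats::terms(formula[-2L]), "term.labels")
  # numeric columns are covariates; only cross-classified effects are used
  is_cov <- effects %in% names(data) &
    vapply(effects, function(ef) is.numeric(data[[ef]]) &&
             !is.factor(data[[ef]]), TRUE)
  if (any(is_cov)) {
    warning("dropping covariate term(s): ",
            paste(effects[is_cov], collapse = ", "))
    effects <- effects[!is_cov]
  }
  if (!inherits(pedigree, "pedigree")) pedigree <- sort_pedigree(pedigree)
  if (is.null(vc))
    vc <- variance_components(sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
                              G0 = G0, R0 = R0)
  apy <- NULL
  if (!is.null(genotypes)) {
    if (!inherits(genotypes, "genotype_matrix"))
      genotypes <- genotype_matrix(genotypes)
    G <- build_grm(genotypes)
    A22 <- build_a22(pedigree, genotypes$ids)
    G <- blend_grm(G, A22, beta = beta)
    if (is.null(core_ids)) {
      if (is.null(n_core))
        n_core <- min(length(genotypes$ids),
                      ceiling(4 * sqrt(length(genotypes$ids))))
      part <- select_core(genotypes$ids, n_core, "random", seed = seed)
    } else {
      part <- select_core(genotypes$ids, method = "given",
                          core_ids = core_ids)
    }
    apy <- build_apy_decomposition(G, part$core_ids, part$noncore_ids)
  }
  out <- run_ssgblup(pedigree, data, effects, traits, vc, apy = apy,
                     id = id, max_rounds = max_rounds, tol = tol)
  out$call <- match.call()
  out
}
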