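#' Configuration for the synthetic livestock population
#'
#' Defines a multi-generation population with discrete (non-overlapping)
#' generations, random mating, gene-dropped biallelic genotypes and
#' phenotypes under a contemporary-group + sex fixed-effect model.  Defaults
#' give a small single-trait population with heritability 0.3 on a unit
#' phenotypic variance.
#'
#' @param n_founders number of founder animals (generation 0).
#' @param n_generations number of offspring generations.
#' @param n_matings dams mated per generation (each to one random sire).
#' @param progeny_per_mating offspring per mating.
#' @param sire_fraction fraction of the previous generation's males used as
#'   sires (at least one).
#' @param n_markers biallelic markers for the gene drop.
#' @param freq_range range of founder allele frequencies (uniform).
#' @param n_genotyped number of genotyped animals, taken from the most recent
#'   generations first; `NULL` means `round(prop_genotyped * n_total)`.
#' @param prop_genotyped proportion genotyped when `n_genotyped` is `NULL`.
#' @param n_cg contemporary groups per generation.
#' @param cg_sd standard deviation of contemporary-group effects (trait
#'   units).
#' @param sex_effect additive fixed effect of the second sex (trait units).
#' @param vc a `variance_components` (single- or multi-trait).
#' @param missing_prob per-trait probability that a record's trait value is
#'   missing.
#' @param founder_records logical; do founders have records (default FALSE,
#'   the usual livestock shape where base animals are unrecorded).
#' @param seed integer seed; the whole simulation is reproducible given it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 200L, n_generations = 4L,
                       n_matings = 80L, progeny_per_mating = 2L,
                       sire_fraction = 0.1, n_markers = 1000L,
                       freq_range = c(0.05, 0.95),
                       n_genotyped = NULL, prop_genotyped = 0.2,
                       n_cg = 20L, cg_sd = 0.5, sex_effect = 0.3,
                       vc = variance_components(sigma_u2 = 0.3,
                                                sigma_e2 = 0.7),
                       missing_prob = 0, founder_records = FALSE,
                       seed = 1L) {
  stopifnot(n_founders >= 2L, n_generations >= 0L, n_matings >= 1L,
            progeny_per_mating >= 1L, n_markers >= 1L,
            all(missing_prob >= 0 & missing_prob <= 1),
            sire_fraction > 0, sire_fraction <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a livestock population
#'
#' Generates a pedigree by discrete generations with random mating, true
#' breeding values by the Mendelian-sampling recursion
#' `u_i = 0.5 u_s + 0.5 u_d + phi_i` with `Var(phi) = 0.5 G0` (founders:
#' `G0`), genotypes by gene drop of founder haplotypes with allele
#' frequencies drawn uniformly from `freq_range`, and phenotypes
#' `y = mu + cg + sex + u + e` with residual covariance `R0`.  The genotyped
#' subset is taken from the most recent generations first, mimicking the
#' genotyping pattern of livestock populations.
#'
#' @param cfg a `sim_config`.
#' @return list with `pedigree` (sorted), `genotypes` (a `genotype_matrix`
#'   for the genotyped subset), `records` (data frame: animal, cg, sex, one
#'   column per trait `t1...`), `true_bv` (animals x traits), `config`.
#' @export
simulate_population <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  nt <- cfg$vc$ntraits
  Lg <- chol(cfg$vc$G0)
  Lr <- chol(cfg$vc$R0)

  # ---- pedigree ----
  id <- paste0("F", seq_len(cfg$n_founders))
  sire <- dam <- rep(NA_integer_, cfg$n_founders)
  gen <- rep(0L, cfg$n_founders)
  sex <- sample(c("M", "F"), cfg$n_founders, replace = TRUE)
  # guarantee both sexes among founders
  if (length(unique(sex)) == 1L) sex[1L] <- setdiff(c("M", "F"), sex[1L])
  for (g in seq_len(cfg$n_generations)) {
    prev <- which(gen == g - 1L)
    males <- prev[sex[prev] == "M"]
    females <- prev[sex[prev] == "F"]
    if (!length(males) || !length(females))
      stop("generation ", g - 1L, " lacks one sex; infeasible mating design")
    n_sires <- max(1L, round(cfg$sire_fraction * length(males)))
    sires <- if (length(males) == 1L) males else sample(males, n_sires)
    n_mat <- min(cfg$n_matings, length(females))
    dams <- if (length(females) == 1L) females else sample(females, n_mat)
    noff <- n_mat * cfg$progeny_per_mating
    off_sire <- rep(sample(sires, n_mat, replace = TRUE),
                    each = cfg$progeny_per_mating)
    off_dam <- rep(dams, each = cfg$progeny_per_mating)
    start <- length(id)
    id <- c(id, paste0("G", g, "_", seq_len(noff)))
    sire <- c(sire, off_sire)
    dam <- c(dam, off_dam)
    gen <- c(gen, rep(g, noff))
    sex <- c(sex, sample(c("M", "F"), noff, replace = TRUE))
  }
  n <- length(id)
  ped <- pedigree(id,
                  ifelse(is.na(sire), NA, id[sire]),
                  ifelse(is.na(dam), NA, id[dam]), sex = sex)
  # generation-ordered construction: pedigree order equals input order
  stopifnot(identical(ped$id, id))

  # ---- true breeding values ----
  u <- matrix(0, n, nt)
  founders <- is.na(sire) & is.na(dam)
  u[founders, ] <- matrix(stats::rnorm(sum(founders) * nt), ncol = nt) %*% Lg
  for (i in which(!founders)) {
    pa <- 0.5 * (u[sire[i], ] + u[dam[i], ])
    u[i, ] <- pa + sqrt(0.5) * (stats::rnorm(nt) %*% Lg)
  }
  rownames(u) <- id
  colnames(u) <- paste0("t", seq_len(nt))

  # ---- gene drop ----
  p <- stats::runif(cfg$n_markers, cfg$freq_range[1L], cfg$freq_range[2L])
  H1 <- matrix(0L, n, cfg$n_markers)
  H2 <- matrix(0L, n, cfg$n_markers)
  nf <- sum(founders)
  H1[founders, ] <- matrix(stats::rbinom(nf * cfg$n_markers, 1L, rep(p, each = nf)),
                           nf, cfg$n_markers)
  H2[founders, ] <- matrix(stats::rbinom(nf * cfg$n_markers, 1L, rep(p, each = nf)),
                           nf, cfg$n_markers)
  for (i in which(!founders)) {
    pick <- stats::runif(cfg$n_markers) < 0.5
    H1[i, ] <- ifelse(pick, H1[sire[i], ], H2[sire[i], ])
    pick <- stats::runif(cfg$n_markers) < 0.5
    H2[i, ] <- ifelse(pick, H1[dam[i], ], H2[dam[i], ])
  }
  ng <- if (is.null(cfg$n_genotyped)) round(cfg$prop_genotyped * n)
        else cfg$n_genotyped
  ng <- max(2L, min(ng, n))
  g_idx <- order(gen, decreasing = TRUE)[seq_len(ng)]   # recent first
  g_idx <- sort(g_idx)
  gt <- genotype_matrix(H1[g_idx, , drop = FALSE] + H2[g_idx, , drop = FALSE],
                        ids = id[g_idx])

  # ---- records ----
  rec_idx <- if (cfg$founder_records) seq_len(n) else which(gen > 0L)
  if (!length(rec_idx)) rec_idx <- seq_len(n)
  cg <- paste0("g", gen[rec_idx], "c",
               sample.int(cfg$n_cg, length(rec_idx), replace = TRUE))
  cg_eff <- stats::rnorm(length(unique(cg)), 0, cfg$cg_sd)
  names(cg_eff) <- unique(cg)
  e <- matrix(stats::rnorm(length(rec_idx) * nt), ncol = nt) %*% Lr
  y <- u[rec_idx, , drop = FALSE] + e +
    cg_eff[cg] + ifelse(sex[rec_idx] == "M", cfg$sex_effect, 0)
  mp <- rep_len(cfg$missing_prob, nt)
  for (t in seq_len(nt))
    if (mp[t] > 0)
      y[stats::runif(length(rec_idx)) < mp[t], t] <- NA_real_
  records <- data.frame(animal = id[rec_idx], cg = cg, sex = sex[rec_idx],
                        stringsAsFactors = FALSE)
  records[colnames(u)] <- as.data.frame(y)

  list(pedigree = ped, genotypes = gt, records = records, true_bv = u,
       config = cfg)
}
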