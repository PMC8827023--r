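test_that("a zero-generation configuration yields founders only", {
  sim <- simulate_population(sim_config(n_founders = 30, n_generations = 0,
                                        founder_records = TRUE, seed = 1))
  expect_equal(sim$pedigree$n, 30)
  expect_true(all(sim$pedigree$gen == 0L))
  expect_true(all(is.na(sim$pedigree$sire)))
})

test_that("near-zero residual variance makes phenotypes track breeding values", {
  vc <- variance_components(sigma_u2 = 0.3, sigma_e2 = 0.3e-7)
  sim <- simulate_population(sim_config(n_founders = 40, n_generations = 2,
                                        n_matings = 30, cg_sd = 0, sex_effect = 0,
                                        vc = vc, seed = 2))
  ai <- match(sim$records$animal, sim$pedigree$id)
  expect_gte(cor(sim$records$t1, sim$true_bv[ai, 1]), 0.999)
})

test_that("founder breeding-value variance matches the genetic variance", {
  vars <- vapply(1:10, function(s) {
    sim <- simulate_population(sim_config(n_founders = 2000,
                                          n_generations = 0,
                                          n_markers = 2, founder_records = TRUE,
                                          seed = s))
    var(sim$true_bv[, 1])
  }, numeric(1))
  expect_true(all(abs(vars - 0.3) / 0.3 < 0.15))
})

test_that("gene-dropped full sibs show the expected genomic relationship", {
  # full-sib families at >= 5000 markers; G centered at the founder
  # (base-population) allele frequencies to avoid sample-centering bias
  sim <- simulate_population(sim_config(n_founders = 80, n_generations = 1,
                                        n_matings = 40, progeny_per_mating = 2,
                                        n_markers = 5000, n_genotyped = 160,
                                        seed = 3))
  ped <- sim$pedigree
  founders <- sim$genotypes$ids[match(sim$genotypes$ids, ped$id) %in%
                                  which(ped$gen == 0L)]
  base_freq <- colMeans(sim$genotypes$dosages[founders, ]) / 2
  offspring <- setdiff(sim$genotypes$ids, founders)
  gt <- genotype_matrix(sim$genotypes$dosages[offspring, ],
                        allele_freq = base_freq)
  G <- build_grm(gt)
  ids <- gt$ids
  idx <- match(ids, ped$id)
  offd <- c()
  for (i in seq_along(ids)) for (j in seq_len(i - 1L)) {
    a <- idx[i]; b <- idx[j]
    if (!is.na(ped$sire[a]) && !is.na(ped$sire[b]) &&
        ped$sire[a] == ped$sire[b] && ped$dam[a] == ped$dam[b])
      offd <- c(offd, G[ids[i], ids[j]])
  }
  expect_gte(length(offd), 20)
  expect_lt(abs(mean(offd) - 0.5), 0.05)
})

test_that("simulation is reproducible bit-for-bit given a seed", {
  cfg <- sim_config(n_founders = 30, n_generations = 2, n_matings = 20,
                    seed = 9)
  s1 <- simulate_population(cfg)
  s2 <- simulate_population(cfg)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$genotypes$dosages, s2$genotypes$dosages)
  expect_identical(s1$true_bv, s2$true_bv)
})

test_that("the dense GBLUP oracle handles its closed-form cases", {
  lambda <- 4
  G <- diag(6)
  expect_equal(exact_gblup_pev(G, rep(0, 6), lambda, sigma_e2 = 2),
               rep(2 / lambda, 6), tolerance = 1e-12)
  set.seed(5)
  for (rep in 1:5) {
    apy <- rand_apy(30, 6)
    d <- runif(30, 0, 4)
    bp <- block_sparse_pev(assemble_shifted_system(apy, d, lambda),
                           sigma_e2 = 2)
    expect_equal(bp$pev, exact_gblup_pev(apy, d, lambda, 2),
                 tolerance = 1e-9)
  }
})

test_that("the dense mixed-model oracle is self-consistent", {
  sim <- simulate_population(sim_config(n_founders = 60, n_generations = 3,
                                        n_matings = 50, seed = 6))
  vc <- variance_components(sigma_u2 = 0.3, sigma_e2 = 0.7)
  rel <- exact_ssgblup_reliability(sim$pedigree, sim$records, c("cg", "sex"),
                                   "t1", vc)
  expect_true(all(rel >= 0 & rel < 1))
  # founders without records or progeny would be 0; recorded animals gain
  ai <- unique(match(sim$records$animal, sim$pedigree$id))
  expect_true(all(rel[ai, 1] > 0))
  # no records at all: zero reliability everywhere
  rec0 <- sim$records
  rec0$t1 <- NA_real_
  rel0 <- exact_ssgblup_reliability(sim$pedigree, rec0, c("cg", "sex"),
                                    "t1", vc)
  expect_true(all(rel0 == 0))
})

test_that("the oracle refuses pedigrees beyond its memory guard", {
  sim <- simulate_population(sim_config(n_founders = 30, n_generations = 1,
                                        n_matings = 10, seed = 7))
  expect_error(exact_ssgblup_reliability(sim$pedigree, sim$records,
                                         c("cg", "sex"), "t1",
                                         variance_components(0.3, 0.7),
                                         max_n = 10),
               "scaled-down")
})
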