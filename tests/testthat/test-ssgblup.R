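vc1 <- function() variance_components(sigma_u2 = 0.3, sigma_e2 = 0.7)

test_that("the genomic step with zero ERC and identity GRM gives zero", {
  G <- diag(5)
  dimnames(G) <- list(paste0("g", 1:5), paste0("g", 1:5))
  apy <- build_apy_decomposition(G, paste0("g", 1:2), paste0("g", 3:5))
  out <- gblup_reliability_step(apy, rep(0, 5), vc1())
  expect_equal(out$rel, rep(0, 5))
})

test_that("a single genotyped animal reduces to the scalar ERC formula", {
  G <- matrix(1, 1, 1, dimnames = list("g1", "g1"))
  # two animals needed for a partition; use an identity pair, all core
  G <- diag(2); dimnames(G) <- list(c("g1", "g2"), c("g1", "g2"))
  apy <- build_apy_decomposition(G, c("g1", "g2"), character(0))
  q <- c(4, 0)
  out <- gblup_reliability_step(apy, q, vc1())
  alpha <- 0.7 / 0.3
  expect_equal(out$rel, rel_from_erc(q, alpha), tolerance = 1e-12)
})

test_that("the genomic step equals dense inversion at 400 genotyped", {
  set.seed(61)
  apy <- rand_apy(400, 80)
  erc <- rexp(400, rate = 0.5)
  out <- gblup_reliability_step(apy, erc, vc1())
  pev_ref <- exact_gblup_pev(apy, erc, 0.7 / 0.3, sigma_e2 = 0.7)
  rel_ref <- 1 - pev_ref / 0.3
  expect_lt(max(abs(out$rel - pmax(rel_ref, 0))), 1e-8)
})

test_that("A22 reliabilities vanish without genotyped information", {
  ped <- trio_pedigree()
  out <- a22_reliability_step(ped, c(0, 0), c("s", "d"), alpha = 2)
  expect_equal(out, c(0, 0))
})

test_that("an unrelated genotyped animal keeps its scalar reliability", {
  ped <- pedigree(c("x", "y"), c("0", "0"), c("0", "0"))
  out <- a22_reliability_step(ped, 4, "x", alpha = 2)
  expect_equal(out, 4 / 6, tolerance = 1e-9)
  exact <- a22_reliability_step(ped, 4, "x", alpha = 2, exact = TRUE)
  expect_equal(exact, 4 / 6, tolerance = 1e-9)
})

test_that("approximate A22 reliabilities track the dense A22 system", {
  sim <- simulate_population(sim_config(n_founders = 60, n_generations = 3,
                                        n_matings = 50, seed = 62))
  ped <- sim$pedigree
  gids <- sim$genotypes$ids
  set.seed(63)
  erc <- rexp(length(gids), 0.3)
  alpha <- 7 / 3
  appr <- a22_reliability_step(ped, erc, gids, alpha)
  ex <- a22_reliability_step(ped, erc, gids, alpha, exact = TRUE)
  expect_gte(cor(appr, ex), 0.97)
})

test_that("combining reliabilities follows ERC additivity", {
  alpha <- 3
  # genomics adds nothing when the genomic and A22 steps agree
  expect_equal(combine_reliabilities(0.4, 0.55, 0.55, alpha), 0.4)
  # no pedigree information: the genomic value carries through
  expect_equal(combine_reliabilities(0, 0.5, 0, alpha), 0.5)
  # hand-computed: q = 2 + 3 - 9/7 = 26/7, rel = 26/47
  expect_equal(combine_reliabilities(0.4, 0.5, 0.3, alpha), 26 / 47,
               tolerance = 1e-12)
  # clamping at zero information
  expect_equal(combine_reliabilities(0.1, 0.1, 0.9, alpha), 0)
  # identity holds whenever unclamped, and genomic gain is never harmful
  set.seed(64)
  rp <- runif(50, 0, 0.9); rg <- runif(50, 0, 0.9); ra <- runif(50, 0, 0.9)
  rf <- combine_reliabilities(rp, rg, ra, alpha)
  q <- erc_from_rel(rp, alpha) + erc_from_rel(rg, alpha) -
    erc_from_rel(ra, alpha)
  ok <- q >= 0
  expect_equal(erc_from_rel(rf[ok], alpha), q[ok], tolerance = 1e-9)
  gain <- rg >= ra
  expect_true(all(rf[gain] >= rp[gain] - 1e-12))
})

test_that("propagation is the identity when nothing genomic is added", {
  sim <- simulate_population(sim_config(n_founders = 40, n_generations = 2,
                                        n_matings = 30, seed = 65))
  ped <- sim$pedigree
  info <- approx_record_information(sim$records, c("cg", "sex"), "t1", ped)
  alpha <- 7 / 3
  fit <- approx_pedigree_reliability(ped, info$d_own[, 1], alpha)
  gids <- sim$genotypes$ids
  gi <- match(gids, ped$id)
  prop <- propagate_to_nongenotyped(ped, info$d_own[, 1], fit$rel[gi],
                                    gids, alpha, ped_fit = fit)
  expect_lt(max(abs(prop$rel - fit$rel)), 1e-3)
  expect_equal(prop$backsolve_failures, 0L)
})

test_that("multi-trait adjustment collapses exactly in the degenerate cases", {
  for (r in c(0.05, 0.3, 0.62, 0.85)) {
    out <- adjust_multitrait(matrix(r, 1, 1), matrix(0.3, 1, 1),
                             matrix(0.7, 1, 1), matrix(0, 1, 1),
                             matrix(1, 1, 1))
    expect_equal(out[1, 1], r, tolerance = 1e-12)
  }
  G0 <- diag(c(0.3, 0.4, 0.5))
  R0 <- diag(c(0.7, 0.6, 0.5))
  rel <- matrix(c(0.2, 0.5, 0.8), 1)
  out <- adjust_multitrait(rel, G0, R0, matrix(0, 1, 3), matrix(1, 1, 3))
  expect_equal(out, rel, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("multi-trait adjustment matches an independent evaluation", {
  vc <- three_trait_vc()
  set.seed(66)
  cases <- list(
    list(rel = c(0.5, 0.3, 0), m = c(3, 3, 0), Q = c(1, 1, 0)),
    list(rel = c(0.7, 0.2, 0.4), m = c(0, 0, 0), Q = c(1, 0, 1)),
    list(rel = c(0, 0, 0), m = c(0, 0, 0), Q = c(0, 0, 0)),
    list(rel = c(0.9, 0.85, 0.6), m = c(10, 5, 2), Q = c(1, 1, 1))
  )
  for (cs in cases) {
    got <- adjust_multitrait(matrix(cs$rel, 1), vc$G0, vc$R0,
                             matrix(cs$m, 1), matrix(cs$Q, 1))
    want <- mt_adjust_oracle(cs$rel, vc$G0, vc$R0, cs$m, cs$Q)
    expect_equal(got[1, ], pmin(pmax(want, 0), 1 - 1e-15),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_true(all(got >= 0 & got < 1))
  }
  # two traits, genetic correlation 0.6, second trait missing
  G0 <- matrix(c(0.3, 0.6 * sqrt(0.3 * 0.5), 0.6 * sqrt(0.3 * 0.5), 0.5), 2)
  R0 <- matrix(c(0.7, 0.1, 0.1, 0.5), 2)
  got <- adjust_multitrait(matrix(c(0.5, 0), 1), G0, R0,
                           matrix(3, 1, 2), matrix(c(1, 0), 1))
  want <- mt_adjust_oracle(c(0.5, 0), G0, R0, c(3, 3), c(1, 0))
  expect_equal(got[1, ], want, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("a run without genotypes is the pedigree-only approximation", {
  sim <- simulate_population(sim_config(n_founders = 40, n_generations = 2,
                                        n_matings = 30, seed = 67))
  fit <- ssgblup_rel(t1 ~ cg + sex, data = sim$records,
                     pedigree = sim$pedigree, sigma_u2 = 0.3, sigma_e2 = 0.7)
  info <- approx_record_information(sim$records, c("cg", "sex"), "t1",
                                    sim$pedigree)
  ref <- approx_pedigree_reliability(sim$pedigree, info$d_own[, 1], 0.7 / 0.3)
  expect_equal(fit$table$rel_final, ref$rel)
  expect_true(all(fit$table$group == "nongenotyped"))
})

test_that("an all-genotyped all-core run matches the dense MME oracle", {
  sim <- simulate_population(sim_config(n_founders = 100, n_generations = 2,
                                        n_matings = 80,
                                        progeny_per_mating = 1,
                                        sire_fraction = 0.5, n_cg = 8,
                                        n_genotyped = 10000, seed = 68))
  ped <- sim$pedigree
  expect_identical(length(sim$genotypes$ids), ped$n)   # everyone genotyped
  fit <- ssgblup_rel(t1 ~ cg + sex, data = sim$records, pedigree = ped,
                     genotypes = sim$genotypes, sigma_u2 = 0.3,
                     sigma_e2 = 0.7, n_core = ped$n, seed = 1)
  G <- blend_grm(build_grm(sim$genotypes), build_a22(ped, sim$genotypes$ids))
  apy <- build_apy_decomposition(G, sim$genotypes$ids, character(0))
  exact <- exact_ssgblup_reliability(ped, sim$records, c("cg", "sex"), "t1",
                                     vc1(), apy = apy)
  expect_lte(mean(abs(fit$table$rel_final - exact[, 1])), 0.02)
})

test_that("a three-trait run meets the single-trait quality bar per trait", {
  # pedigree / genotyped / core proportions mirror a beef-cattle multi-trait
  # evaluation at roughly 1/50 scale
  vc <- three_trait_vc()
  cfg <- sim_config(n_founders = 400, n_generations = 4, n_matings = 300,
                    progeny_per_mating = 3, n_genotyped = 400, n_cg = 20,
                    vc = vc, missing_prob = c(0.1, 0.2, 0.3), seed = 69)
  sim <- simulate_population(cfg)
  fit <- ssgblup_rel(cbind(t1, t2, t3) ~ cg + sex, data = sim$records,
                     pedigree = sim$pedigree, genotypes = sim$genotypes,
                     vc = vc, n_core = 210, seed = 7)
  G <- blend_grm(build_grm(sim$genotypes),
                 build_a22(sim$pedigree, sim$genotypes$ids))
  part <- select_core(sim$genotypes$ids, 210, seed = 7)
  apy <- build_apy_decomposition(G, part$core_ids, part$noncore_ids)
  exact <- exact_ssgblup_reliability(sim$pedigree, sim$records,
                                     c("cg", "sex"), c("t1", "t2", "t3"),
                                     vc, apy = apy)
  for (t in 1:3) {
    tab <- fit$table[fit$table$trait == paste0("t", t), ]
    ag <- agreement(tab$rel_final, exact[, t])
    expect_gte(ag$corr, 0.97)
    expect_lte(ag$mac, 0.03)
  }
  # adjusted reliabilities remain valid and present for every animal
  expect_true(all(fit$table$rel_mt >= 0 & fit$table$rel_mt < 1))
})
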