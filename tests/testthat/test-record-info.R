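make_flat_ped <- function(ids) pedigree(ids, rep("0", length(ids)),
                                        rep("0", length(ids)))

test_that("a record in a level of five keeps weight 0.8", {
  ids <- paste0("a", 1:5)
  rec <- data.frame(animal = ids, eff = "L1", t1 = rnorm(5))
  info <- approx_record_information(rec, "eff", "t1", make_flat_ped(ids))
  expect_equal(unname(info$d_own[, 1]), rep(0.8, 5))
})

test_that("a record alone in its level is fully absorbed", {
  rec <- data.frame(animal = c("a", "b"), eff = c("solo", "solo2"),
                    t1 = c(1, 2))
  info <- approx_record_information(rec, "eff", "t1",
                                    make_flat_ped(c("a", "b")))
  expect_equal(unname(info$d_own[, 1]), c(0, 0))
})

test_that("single cross-classified effect matches dense absorption exactly", {
  set.seed(21)
  n <- 150
  ids <- paste0("a", seq_len(n))
  rec <- data.frame(animal = ids,
                    eff = sample(paste0("L", 1:12), n, replace = TRUE),
                    t1 = rnorm(n))
  info <- approx_record_information(rec, "eff", "t1", make_flat_ped(ids))
  X <- stats::model.matrix(~ 0 + factor(eff), rec)
  Dex <- 1 - diag(X %*% solve(crossprod(X)) %*% t(X))
  expect_equal(unname(info$d_own[, 1]), unname(Dex), tolerance = 1e-12)
})

test_that("two crossed effects track dense absorption closely", {
  set.seed(22)
  n <- 200
  # contemporary groups of strongly varying size, as in field data
  cg <- sample(12, n, replace = TRUE, prob = rgamma(12, 2))
  ids <- paste0("a", seq_len(n))
  rec <- data.frame(animal = ids, cg = cg,
                    sex = sample(c("M", "F"), n, replace = TRUE),
                    t1 = rnorm(n))
  info <- approx_record_information(rec, c("cg", "sex"), "t1",
                                    make_flat_ped(ids))
  X <- stats::model.matrix(~ factor(cg) + sex, rec)
  Dex <- 1 - diag(X %*% solve(crossprod(X)) %*% t(X))
  expect_gte(cor(info$d_own[, 1], Dex), 0.99)
})

test_that("missing trait values contribute no information", {
  rec <- data.frame(animal = c("a", "b", "c"), eff = "L",
                    t1 = c(1, NA, 3), t2 = c(NA, NA, NA))
  info <- approx_record_information(rec, "eff", c("t1", "t2"),
                                    make_flat_ped(c("a", "b", "c")))
  expect_equal(unname(info$d_own[, "t1"]), c(0.5, 0, 0.5))
  expect_equal(unname(info$d_own[, "t2"]), c(0, 0, 0))
})

test_that("records for animals outside the pedigree are rejected", {
  rec <- data.frame(animal = "ghost", eff = "L", t1 = 1)
  expect_error(approx_record_information(rec, "eff", "t1",
                                         make_flat_ped("a")),
               "absent from pedigree")
})

test_that("ERC conversions are exact inverses and handle the endpoints", {
  expect_equal(rel_from_erc(0, 2), 0)
  expect_equal(rel_from_erc(3, 3), 0.5)
  expect_equal(erc_from_rel(0, 2), 0)
  expect_equal(erc_from_rel(0.5, 3), 3)
  for (alpha in c(0.5, 7 / 3, 9)) {
    q <- alpha * 10^seq(-6, 1, length.out = 40)
    expect_equal(erc_from_rel(rel_from_erc(q, alpha), alpha), q,
                 tolerance = 1e-14)
    r <- seq(0, 0.95, by = 0.05)
    expect_equal(rel_from_erc(erc_from_rel(r, alpha), alpha), r,
                 tolerance = 1e-14)
  }
  expect_error(erc_from_rel(1, 2), "\\[0, 1\\)")
  expect_error(rel_from_erc(-1, 2), "negative")
})
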