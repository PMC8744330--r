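test_that("Fisher enrichment equals the hypergeometric tail-sum oracle", {
  uni <- sprintf("g%03d", 1:100)
  set <- uni[1:10]
  module <- uni[c(1:8, 50:61)]  # overlap 8, module 20
  res <- fisher_enrichment(module, set, uni)
  expect_equal(res$overlap, 8)
  expect_equal(res$p, hyper_tail_oracle(8, 20, 10, 100), tolerance = 1e-14)
  expect_equal(res$fold_enrichment, (8 / 20) / (10 / 100))
  # boundary: module identical to the set
  res2 <- fisher_enrichment(set, set, uni)
  expect_equal(res2$overlap, 10)
  expect_equal(res2$p, hyper_tail_oracle(10, 10, 10, 100), tolerance = 1e-14)
  # zero overlap: one-tailed P(X >= 0) = 1
  res3 <- fisher_enrichment(uni[90:99], uni[1:5], uni)
  expect_equal(res3$p, 1)
  expect_equal(res3$fold_enrichment, 0)
  # empty module reported as NA fold enrichment with p = 1
  res4 <- fisher_enrichment(character(), set, uni)
  expect_equal(res4$p, 1)
  expect_true(is.na(res4$fold_enrichment))
  # random margins sweep against the oracle
  set.seed(51)
  for (i in 1:40) {
    u <- sample(20:200, 1)
    universe <- sprintf("u%04d", seq_len(u))
    s <- sample(universe, sample(1:min(50, u), 1))
    m <- sample(universe, sample(1:min(80, u), 1))
    res <- fisher_enrichment(m, s, universe)
    expect_equal(res$p,
                 hyper_tail_oracle(res$overlap, res$module_size, res$set_size, u),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(rep(0.3, 5)), rep(0.3, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(52)
  for (i in 1:20) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("module eigengene matches the SVD oracle with the orientation rule", {
  set.seed(53)
  # identical profiles: variance explained = 1, score proportional to profile
  base <- rnorm(30)
  m1 <- matrix(rep(base, 5), 5, 30, byrow = TRUE) +
    matrix(rnorm(150, 0, 1e-6), 5)
  rownames(m1) <- paste0("g", 1:5); colnames(m1) <- paste0("s", 1:30)
  eg <- module_eigengene(m1, rownames(m1))
  expect_gt(eg$variance_explained, 0.999)
  expect_gt(cor(eg$score, base), 0.999)
  # negating all genes leaves the oriented eigengene's direction anchored
  eg_neg <- module_eigengene(-m1, rownames(m1))
  expect_gt(cor(eg_neg$score, colMeans(t(scale(t(-m1))))), 0.99)
  # random module: SVD oracle
  m2 <- matrix(rnorm(20 * 50), 20, 50,
               dimnames = list(paste0("g", 1:20), paste0("s", 1:50)))
  eg2 <- module_eigengene(m2, rownames(m2), module_id = "M9")
  z <- t(scale(t(m2)))
  sv <- svd(z)
  ref <- sv$v[, 1]
  if (cor(ref, colMeans(z)) < 0) ref <- -ref
  expect_equal(unname(eg2$score), ref, tolerance = 1e-8)
  expect_equal(eg2$variance_explained, sv$d[1]^2 / sum(sv$d^2), tolerance = 1e-10)
  expect_identical(glance(eg2)$module_id, "M9")
  expect_equal(nrow(tidy(eg2)), 50)
})

test_that("age correlation: monotone limit, midrank ties, type-I calibration", {
  ages <- rep(seq(25, 75, 10), each = 4)
  rising <- seq_along(ages) * 1.0
  rc <- age_correlation(rising, ages)
  expect_equal(rc$rho, cor(rank(rising), rank(ages)), tolerance = 1e-12)
  expect_gt(rc$rho, 0.95)
  # tie-heavy fixture equals Pearson on midranks
  set.seed(54)
  score <- rnorm(length(ages))
  rc2 <- age_correlation(score, ages)
  expect_equal(rc2$rho, cor(rank(score), rank(ages)), tolerance = 1e-12)
  # type-I error near nominal under independence
  rej <- vapply(1:1000, function(i) {
    age_correlation(rnorm(24), sample(seq(25, 75, 10), 24, TRUE))$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
  expect_true(is.na(age_correlation(rep(1, 10), ages[1:10])$rho))
})

test_that("SnG module flagging finds planted enrichment and respects thresholds", {
  # hand-built hierarchies: tissue1 module A holds 30/50 SnGs
  uni <- sprintf("g%04d", 1:500)
  sng <- uni[1:50]
  hier1 <- tibble::tibble(
    module_id = c("M1", "M1.1", "M1.2"),
    parent_id = c(NA, "M1", "M1"),
    depth = c(0L, 1L, 1L),
    members = list(uni[1:200], c(sng[1:30], uni[101:170]), uni[171:200]),
    n_genes = c(200L, 100L, 30L)
  )
  fl <- flag_sng_modules(list(tissue1 = hier1), sng,
                         universes = list(tissue1 = uni))
  expect_identical(fl$module_id, "M1.1")
  expect_equal(fl$overlap, 30)
  # disjoint SnG set: nothing flagged
  fl0 <- flag_sng_modules(list(tissue1 = hier1), uni[400:450],
                          universes = list(tissue1 = uni))
  expect_equal(nrow(fl0), 0)
  # alpha_q = 1 returns every overlapping module
  fl1 <- flag_sng_modules(list(tissue1 = hier1), sng,
                          universes = list(tissue1 = uni), alpha_q = 1)
  expect_setequal(fl1$module_id, c("M1.1"))
  all_tab <- attr(fl1, "all")
  expect_true(all(all_tab$q <= 1))
})

test_that("presence/flagging pipeline keeps planted sensitivity across seeds", {
  # planted enrichment recovery with decoy modules, multiple seeds
  uni <- sprintf("g%04d", 1:600)
  sng <- uni[1:40]
  hits <- vapply(1:10, function(sd) {
    set.seed(sd)
    planted <- c(sample(sng, 25), sample(uni[41:600], 35))
    decoys <- lapply(1:20, function(i) sample(uni[41:600], 40))
    hier <- tibble::tibble(
      module_id = c("root", "P", paste0("D", 1:20)),
      parent_id = c(NA, rep("root", 21)),
      depth = c(0L, rep(1L, 21)),
      members = c(list(uni), list(planted), decoys),
      n_genes = c(600L, 60L, rep(40L, 20))
    )
    fl <- flag_sng_modules(list(t1 = hier), sng, universes = list(t1 = uni))
    identical(fl$module_id, "P")
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
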