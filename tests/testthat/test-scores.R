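build_adjust_fixture <- function(n = 60, seed = 2) {
  set.seed(seed)
  covs <- data.frame(
    age = runif(n, 5, 60),
    sex = sample(c("F", "M"), n, replace = TRUE),
    batch = sample(c("B1", "B2", "B3"), n, replace = TRUE)
  )
  group <- rep(c("D21", "T21"), length.out = n)
  list(covs = covs, group = group)
}

test_that("covariate adjustment removes a constructed age effect exactly", {
  fx <- build_adjust_fixture()
  # pair ages across groups so age is exactly orthogonal to the kept term
  fx$covs$age <- rep(fx$covs$age[seq(1, 59, by = 2)], each = 2)
  y <- 2 * fx$covs$age + 3 * (fx$group == "T21")
  values <- cbind(feat = y)
  rownames(values) <- sprintf("S%02d", seq_along(y))
  m <- fit_covariate_adjustment(values, fx$covs["age"], keep = fx$group)
  adj <- apply_adjustment(m, values, fx$covs["age"])
  expect_lt(abs(cor(adj[, 1], fx$covs$age)), 1e-6)
  # group contrast preserved after adjustment (refit oracle)
  fit <- lm(adj[, 1] ~ fx$group)
  expect_equal(unname(coef(fit)[2]), 3, tolerance = 1e-9)
})

test_that("adjustment is idempotent, centered at reference covariates and
           equalizes batch-only differences", {
  fx <- build_adjust_fixture(n = 80, seed = 4)
  set.seed(9)
  b_eff <- c(B1 = 0, B2 = 1.5, B3 = -2)
  y <- 0.1 * fx$covs$age + b_eff[fx$covs$batch] + rnorm(80, sd = 0.01)
  values <- cbind(feat = y)
  rownames(values) <- sprintf("S%02d", 1:80)
  m <- fit_covariate_adjustment(values, fx$covs[c("age", "batch")],
                                keep = fx$group)
  adj <- apply_adjustment(m, values, fx$covs[c("age", "batch")])
  # idempotence: refitting the model on adjusted data finds nothing left
  # to remove, so a second adjustment pass is the identity
  m2 <- fit_covariate_adjustment(adj, fx$covs[c("age", "batch")],
                                 keep = fx$group)
  expect_lt(max(abs(m2$coefficients)), 1e-6)
  adj_fix <- apply_adjustment(m2, adj, fx$covs[c("age", "batch")])
  expect_equal(adj_fix, adj, tolerance = 1e-9)

  # two samples differing only in batch end up equal
  i <- which(fx$covs$batch == "B2")[1]
  j <- which(fx$covs$batch == "B3")[1]
  covs_ij <- fx$covs[c(i, j), ]
  covs_ij$age <- 30
  vals_ij <- cbind(feat = 0.1 * 30 + b_eff[covs_ij$batch])
  adj_ij <- apply_adjustment(m, vals_ij, covs_ij)
  expect_equal(adj_ij[1, 1], adj_ij[2, 1], tolerance = 0.05)
})

test_that("hand-rolled adjustment matches limma's batch-effect removal up
           to a per-feature constant", {
  skip_if_not_installed("limma")
  fx <- build_adjust_fixture(n = 100, seed = 8)
  set.seed(10)
  values <- matrix(rnorm(100 * 5), 100, 5,
                   dimnames = list(sprintf("S%03d", 1:100), paste0("F", 1:5)))
  values <- values + outer(fx$covs$age, rep(0.05, 5)) +
    outer(as.numeric(factor(fx$covs$batch)), rep(1, 5))
  m <- fit_covariate_adjustment(values, fx$covs[c("age", "batch")],
                                keep = fx$group)
  ours <- apply_adjustment(m, values, fx$covs[c("age", "batch")])
  theirs <- t(limma::removeBatchEffect(
    t(values),
    batch = fx$covs$batch,
    covariates = fx$covs$age,
    design = model.matrix(~ fx$group)
  ))
  delta <- ours - theirs
  # identical up to a per-feature constant (different centering conventions)
  expect_lt(max(apply(delta, 2, function(x) diff(range(x)))), 1e-8)
})

test_that("rank-deficient designs and missing covariates are rejected", {
  fx <- build_adjust_fixture()
  covs <- fx$covs
  covs$age2 <- covs$age  # collinear
  values <- cbind(feat = rnorm(60))
  expect_error(
    fit_covariate_adjustment(values, covs[c("age", "age2")], keep = fx$group),
    "collinear"
  )
  m <- fit_covariate_adjustment(values, fx$covs["age"], keep = fx$group)
  expect_error(apply_adjustment(m, values, data.frame(sex = fx$covs$sex)),
               "missing covariate")
})

test_that("reference Z-scores standardize the reference group and scale
           others", {
  set.seed(5)
  x <- matrix(rnorm(50 * 4, mean = 10, sd = 2), 50, 4,
              dimnames = list(sprintf("S%02d", 1:50), paste0("F", 1:4)))
  ref <- rownames(x)[1:20]
  zs <- reference_zscores(x, ref)
  expect_equal(unname(colMeans(zs$z[ref, ])), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(zs$z[ref, ], 2, sd)), rep(1, 4), tolerance = 1e-12)
  mu <- zs$stats$mean[1]
  sg <- zs$stats$sd[1]
  probe <- x
  probe["S50", 1] <- mu + 2 * sg
  zs2 <- reference_zscores(probe, ref)
  expect_equal(unname(zs2$z["S50", 1]), 2, tolerance = 1e-12)

  degen <- x
  degen[ref, 2] <- 7
  zs3 <- reference_zscores(degen, ref)
  expect_equal(zs3$rejected, "F2")
  expect_false("F2" %in% colnames(zs3$z))
})

test_that("ISG panel selection applies the fold-change, q and chr21 rules", {
  de <- tibble::tibble(
    gene = c("G1", "G2", "G3", "MX1", "G4"),
    fold_change = c(1.6, 1.4, 2.0, 3.0, 1.5),
    q = c(0.01, 0.01, 0.2, 0.001, 0.05)
  )
  panel <- select_isg_panel(de, c("G1", "G2", "G3", "MX1"))
  expect_equal(panel$genes, "G1")
  # FC exactly 1.5 qualifies ("at least 1.5")
  panel2 <- select_isg_panel(de, c("G1", "G4"))
  expect_setequal(panel2$genes, c("G1", "G4"))
  expect_equal(select_isg_panel(de, character(0))$genes, character(0))
  expect_error(select_isg_panel(de, "UNKNOWN"), "absent")
})

test_that("composite scores sum their breakdown and are additive over
           disjoint panels", {
  z <- rbind(S1 = c(1, 2, 0, -1), S2 = c(0, 0, 0, 0))
  colnames(z) <- paste0("F", 1:4)
  s <- composite_score(z, paste0("F", 1:4))
  expect_equal(s$score, c(2, 0))
  expect_equal(rowSums(attr(s, "breakdown")), setNames(s$score, s$sample_id))
  a <- composite_score(z, c("F1", "F2"))$score
  b <- composite_score(z, c("F3", "F4"))$score
  expect_equal(a + b, s$score)
  # duplicating features doubles the score
  dz <- cbind(z, z)
  colnames(dz) <- paste0("F", 1:8)
  expect_equal(composite_score(dz, paste0("F", 1:8))$score, 2 * s$score)
  expect_error(composite_score(z, "F9"), "missing")
})

test_that("Mann-Whitney comparison matches enumeration and is shift
           invariant", {
  r <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$statistic), 9)  # all y above x -> U = n1*n2
  expect_equal(r$p, mw_oracle(c(1, 2, 3), c(4, 5, 6)), tolerance = 1e-12)
  expect_equal(r$p, 0.1)  # 2/20 labelings as extreme
  expect_equal(r$median_diff, 3)

  r0 <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$median_diff, 0)
  expect_equal(r0$p, 1)

  set.seed(11)
  x <- rnorm(8); y <- rnorm(9)
  r1 <- compare_groups(x, y)
  r2 <- compare_groups(x + 5, y + 5)
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p, r2$p)
  expect_error(compare_groups(numeric(0), 1), "non-empty")
})

test_that("Mann-Whitney agrees with the enumeration oracle on random
           small instances", {
  set.seed(23)
  for (i in 1:25) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- round(rnorm(n1), 3); y <- round(rnorm(n2, 0.5), 3)
    if (anyDuplicated(c(x, y))) next
    expect_equal(compare_groups(x, y)$p, mw_oracle(x, y), tolerance = 1e-10)
  }
})

test_that("paired Wilcoxon matches sign enumeration, handles symmetry and
           all-zero differences", {
  before <- cbind(e1 = c(5, 6, 7, 8, 9))
  after <- before - c(1, 2, 3, 4, 5)
  r <- compare_paired(before, after)
  expect_equal(r$p, 0.0625)  # 2 * (1 / 2^5)
  expect_equal(r$q, r$p)

  # antisymmetric differences: p = 1
  b2 <- cbind(e1 = rep(0, 6))
  a2 <- cbind(e1 = c(1.5, -1.5, 2.5, -2.5, 3.5, -3.5))
  expect_equal(compare_paired(b2, a2)$p, 1)

  expect_warning(r0 <- compare_paired(cbind(e1 = 1:5), cbind(e1 = 1:5)),
                 "all paired differences are zero")
  expect_equal(r0$p, 1)

  set.seed(31)
  for (i in 1:20) {
    n <- sample(5:10, 1)
    d <- round(rnorm(n, 0.3), 3)
    d <- d[d != 0]
    if (anyDuplicated(abs(d)) || length(d) < 4) next
    r <- suppressWarnings(compare_paired(cbind(e = rep(0, length(d))),
                                         cbind(e = d)))
    expect_equal(r$p, wsr_oracle(d), tolerance = 1e-10)
  }
})

test_that("BH across paired endpoints matches the direct step-up", {
  set.seed(13)
  before <- matrix(rnorm(12 * 6), 12, 6,
                   dimnames = list(NULL, paste0("e", 1:6)))
  after <- before + matrix(rnorm(12 * 6, 0.4), 12, 6)
  r <- compare_paired(before, after)
  expect_equal(r$q, bh_oracle(r$p), tolerance = 1e-12)
})
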