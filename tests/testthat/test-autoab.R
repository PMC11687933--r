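make_mad_matrix <- function(values, ids = NULL) {
  m <- as.matrix(values)
  if (is.null(rownames(m))) rownames(m) <- sprintf("S%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("AG%02d", seq_len(ncol(m)))
  m
}

test_that("MAD transform matches the hand-computed example and rejects
           degenerate samples", {
  m <- make_mad_matrix(rbind(c(1, 2, 3, 4, 100)))
  out <- mad_transform(m)
  # median 3, raw MAD 1 -> (x - 3)/1
  expect_equal(unname(out[1, ]), c(-2, -1, 0, 1, 97))

  const <- make_mad_matrix(rbind(c(5, 5, 5, 5)))
  expect_error(mad_transform(const), "degenerate.*S01")
})

test_that("MAD transform is invariant to per-sample positive affine
           rescaling", {
  set.seed(42)
  for (i in 1:20) {
    x <- make_mad_matrix(rbind(rnorm(15, 100, 20), rnorm(15, 50, 5)))
    shift <- runif(2, -10, 10)
    scl <- runif(2, 0.5, 4)
    y <- x * scl + shift
    expect_equal(mad_transform(y), mad_transform(x), tolerance = 1e-10)
  }
})

test_that("low-bead wells are excluded before the transform", {
  arr <- structure(
    list(
      mfi = make_mad_matrix(rbind(c(1, 2, 3, 4, 1e6))),
      bead_count = rbind(c(50, 50, 50, 50, 5))
    ),
    class = "antigen_array"
  )
  out <- mad_transform(arr)
  expect_true(is.na(out[1, 5]))
  # remaining values standardized over the 4 surviving wells
  expect_equal(unname(out[1, 1:4]), (c(1, 2, 3, 4) - 2.5) / 1)
})

test_that("positivity thresholds use the control percentile with a strict
           inequality", {
  ctrl <- make_mad_matrix(cbind(0:9))
  test <- make_mad_matrix(cbind(c(8.5, 8.1, -1)))
  rownames(test) <- c("T1", "T2", "T3")
  m <- rbind(ctrl, test)
  pos <- call_positivity(m, control_ids = rownames(ctrl), percentile = 0.90)
  expect_equal(unname(pos$thresholds), 8.1)  # type-7 90th percentile of 0..9
  expect_true(pos$calls["T1", 1])            # 8.5 > 8.1
  expect_false(pos$calls["T2", 1])           # exactly at threshold -> negative
  expect_false(pos$calls["T3", 1])

  # all test values below the control minimum: zero positives
  low <- make_mad_matrix(cbind(rep(-5, 4)))
  rownames(low) <- paste0("L", 1:4)
  pos2 <- call_positivity(rbind(ctrl, low), rownames(ctrl))
  expect_equal(sum(pos2$calls[paste0("L", 1:4), ]), 0)

  expect_error(call_positivity(m, control_ids = rownames(ctrl)[1:4]),
               "at least 5")
})

test_that("control positivity never exceeds the percentile complement plus
           discreteness", {
  set.seed(7)
  n_ctrl <- 60
  m <- make_mad_matrix(matrix(rnorm(100 * 50), 100, 50))
  ctrl_ids <- rownames(m)[1:n_ctrl]
  pos <- call_positivity(m, ctrl_ids, percentile = 0.90)
  ctrl_rate <- colMeans(pos$calls[ctrl_ids, ])
  expect_true(all(ctrl_rate <= 0.10 + 1 / n_ctrl))
})

test_that("detection filter removes antigens under the threshold and keeps
           the boundary", {
  calls <- matrix(FALSE, 40, 3,
                  dimnames = list(sprintf("S%02d", 1:40), c("A", "B", "C")))
  calls[1:17, 1] <- TRUE  # 17 positives -> removed
  calls[1:18, 2] <- TRUE  # 18 positives -> retained
  pos <- structure(list(calls = calls, thresholds = c(A = 1, B = 1, C = 1)),
                   class = "positivity_table")
  f <- filter_detected(pos, min_samples = 18)
  expect_equal(colnames(f$calls), "B")
  expect_setequal(f$removed, c("A", "C"))
  f0 <- filter_detected(pos, min_samples = 0)
  expect_equal(colnames(f0$calls), c("A", "B", "C"))
})

test_that("Fisher enrichment reproduces the cross-product odds ratio and
           the enumeration p-value", {
  calls <- matrix(FALSE, 180, 1, dimnames = list(sprintf("S%03d", 1:180), "AG"))
  groups <- setNames(rep(c("T21", "D21"), c(120, 60)), rownames(calls))
  calls[1:30, 1] <- TRUE         # T21: 30 positive, 90 negative
  calls[121:123, 1] <- TRUE      # D21: 3 positive, 57 negative
  res <- fisher_enrichment(
    structure(list(calls = calls), class = "positivity_table"),
    groups, case_level = "T21"
  )
  expect_equal(res$odds_ratio, (30 * 57) / (90 * 3), tolerance = 1e-12)
  expect_equal(res$p, fisher_oracle(30, 90, 3, 57), tolerance = 1e-9)

  # identical rates, balanced groups: OR 1, p 1
  calls2 <- calls
  calls2[, 1] <- rep(c(TRUE, FALSE), 90)
  groups2 <- setNames(rep(c("T21", "D21"), each = 90), rownames(calls))
  res2 <- fisher_enrichment(
    structure(list(calls = calls2), class = "positivity_table"),
    groups2, case_level = "T21"
  )
  expect_equal(res2$odds_ratio, 1)
  expect_equal(res2$p, 1)
})

test_that("enrichment q-values are BH: monotone in sorted p and >= p", {
  set.seed(1)
  calls <- matrix(runif(200 * 30) < 0.15, 200, 30,
                  dimnames = list(sprintf("S%03d", 1:200),
                                  sprintf("AG%02d", 1:30)))
  groups <- setNames(rep(c("T21", "D21"), each = 100), rownames(calls))
  res <- fisher_enrichment(
    structure(list(calls = calls), class = "positivity_table"),
    groups, case_level = "T21"
  )
  expect_true(all(res$q >= res$p - 1e-12))
  o <- order(res$p)
  expect_true(all(diff(res$q[o]) >= -1e-12))
  expect_equal(res$q, bh_oracle(res$p), tolerance = 1e-12)
})

test_that("condition associations respect the minimum-case filter", {
  n <- 60
  calls <- matrix(FALSE, n, 1, dimnames = list(sprintf("S%02d", 1:n), "AG"))
  participants <- tibble::tibble(
    sample_id = rownames(calls),
    condition_rare = c(rep(TRUE, 4), rep(FALSE, n - 4)),
    condition_ok = c(rep(TRUE, 5), rep(FALSE, n - 5))
  )
  calls[1:5, 1] <- TRUE  # positivity only within the 'ok' cases
  pos <- structure(list(calls = calls), class = "positivity_table")
  res <- condition_association(pos, participants, min_cases = 5)
  expect_equal(names(res$skipped), "rare")
  expect_equal(unname(res$skipped["rare"]), 4L)
  expect_equal(unique(res$results$condition), "ok")
  row <- res$results[1, ]
  expect_gt(row$odds_ratio, 1)
  expect_equal(row$p, fisher_oracle(row$a, row$b, row$c, row$d),
               tolerance = 1e-9)
})

test_that("burden counts, empty subsets and the >=1 complement", {
  calls <- matrix(FALSE, 4, 5,
                  dimnames = list(paste0("S", 1:4), paste0("AG", 1:5)))
  calls[1, 1:3] <- TRUE
  calls[2, 1] <- TRUE
  pos <- structure(list(calls = calls), class = "positivity_table")
  b <- positivity_burden(pos, paste0("AG", 1:5))
  expect_equal(b$burden$n_positive, c(3, 1, 0, 0))
  expect_equal(
    b$cumulative$fraction_at_least_k[1],
    1 - mean(b$burden$n_positive == 0)
  )
  b0 <- positivity_burden(pos, character(0))
  expect_true(all(b0$burden$n_positive == 0))
  expect_error(positivity_burden(pos, "NOPE"), "unknown antigen")
})

test_that("burden is exchangeable under permutation of antigen labels", {
  set.seed(3)
  calls <- matrix(runif(50 * 8) < 0.3, 50, 8,
                  dimnames = list(sprintf("S%02d", 1:50), paste0("AG", 1:8)))
  pos <- structure(list(calls = calls), class = "positivity_table")
  b1 <- positivity_burden(pos, paste0("AG", 1:8))
  b2 <- positivity_burden(pos, sample(paste0("AG", 1:8)))
  expect_equal(b1$burden, b2$burden)
  expect_equal(b1$cumulative, b2$cumulative)
})

test_that("TPO index arithmetic, percentile threshold and validity guard", {
  expect_equal(tpo_index(50, 10, 90, c(0, 1))$index, 0.5)
  expect_equal(tpo_index(10, 10, 90, c(0, 1))$index, 0)
  controls <- seq(0, 0.9, by = 0.1)
  r <- tpo_index(0.88 * 80 + 10, 10, 90, controls)  # index 0.88
  expect_equal(r$index, 0.88)
  expect_equal(r$threshold, 0.855)  # type-7 95th percentile of 0.0..0.9
  expect_true(r$call)
  expect_error(tpo_index(50, 90, 90, c(0, 1)), "assay invalid")
})

test_that("ANA ratio rule is >= at the cutoff", {
  expect_true(ana_call(2.1, 1)$call)
  expect_false(ana_call(2.09, 1)$call)
  r <- ana_call(5, 5)
  expect_equal(r$index, 1)
  expect_false(r$call)
  expect_error(ana_call(1, 0), "positive")
})
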