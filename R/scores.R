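# Composite interferon and cytokine scores
#
# Nuisance-covariate adjustment (age, sex, batch/source), Z-scoring against
# a euploid reference cohort, ISG panel selection from a differential
# expression table, composite scores as sums of per-feature Z-scores, and
# the group (Mann-Whitney) and paired (Wilcoxon signed-rank) comparisons
# used to report them.

#' Fit a nuisance-covariate adjustment model
#'
#' Per feature, an ordinary least-squares fit of the feature on the grouping
#' term of interest plus the nuisance covariates; only the nuisance
#' coefficients are stored, together with reference values (numeric
#' covariates: their mean; factors: the first level) so that applying the
#' model at the reference covariates is the identity.
#'
#' @param values numeric matrix, samples x features.
#' @param covariates data frame of nuisance covariates (rows aligned to
#'   `values`), e.g. age, sex, batch.
#' @param keep optional vector/factor for the biological grouping to retain
#'   (e.g. karyotype); included in the design during fitting so the nuisance
#'   coefficients are not contaminated by group differences, never
#'   subtracted.
#' @return object of class `adjustment_model`.
#' @export
fit_covariate_adjustment <- function(values, covariates, keep = NULL) {
  values <- as.matrix(values)
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == nrow(values))
  factor_levels <- lapply(covariates, function(x) {
    if (is.numeric(x)) NULL else levels(factor(x))
  })
  nuis <- nuisance_design(covariates, factor_levels)
  full <- nuis
  if (!is.null(keep)) {
    keep_mm <- stats::model.matrix(~ factor(keep))[, -1, drop = FALSE]
    colnames(keep_mm) <- paste0(".keep", seq_len(ncol(keep_mm)))
    full <- cbind(keep_mm, nuis)
  }
  qrX <- qr(cbind(1, full))
  if (qrX$rank < ncol(full) + 1) {
    bad <- colnames(full)[qrX$pivot[seq(qrX$rank + 1, ncol(full) + 1)] - 1]
    stop_config("rank-deficient design; collinear column(s): %s",
                paste(bad, collapse = ", "))
  }
  allcoef <- qr.coef(qr(cbind(`(Intercept)` = 1, full)), values)
  coefs <- allcoef[colnames(nuis), , drop = FALSE]
  # reference point: numeric covariates at their mean, factors at level 1
  ref <- colMeans(nuis)
  is_dummy <- apply(nuis, 2, function(x) all(x %in% c(0, 1)))
  ref[is_dummy] <- 0
  structure(
    list(coefficients = coefs, reference = ref, columns = colnames(nuis),
         covariate_names = names(covariates), factor_levels = factor_levels),
    class = "adjustment_model"
  )
}

# Expand covariates into a dummy-coded nuisance design using the factor
# levels recorded at fit time, so applying the model to a covariate subset
# with fewer observed levels still works.
nuisance_design <- function(covariates, factor_levels) {
  cols <- list()
  for (nm in names(factor_levels)) {
    lev <- factor_levels[[nm]]
    if (is.null(lev)) {
      cols[[nm]] <- as.numeric(covariates[[nm]])
    } else {
      f <- factor(covariates[[nm]], levels = lev)
      if (anyNA(f) && !anyNA(covariates[[nm]])) {
        stop_config("covariate '%s' has level(s) unseen at fit time", nm)
      }
      for (lv in lev[-1]) {
        cols[[paste0(nm, lv)]] <- as.numeric(f == lv)
      }
    }
  }
  do.call(cbind, cols)
}

#' Apply a nuisance-covariate adjustment
#'
#' adjusted = observed - sum over nuisance terms of coefficient x
#' (covariate - reference value). Samples at the reference covariates are
#' unchanged; group contrasts are preserved exactly.
#'
#' @param model an `adjustment_model`.
#' @param values numeric matrix, samples x features.
#' @param covariates data frame with the same covariates used in the fit.
#' @return adjusted matrix, same shape as `values`.
#' @export
apply_adjustment <- function(model, values, covariates) {
  values <- as.matrix(values)
  covariates <- as.data.frame(covariates)
  missing_cov <- setdiff(model$covariate_names, names(covariates))
  if (length(missing_cov)) {
    stop_config("missing covariate(s): %s", paste(missing_cov, collapse = ", "))
  }
  if (anyNA(covariates[model$covariate_names])) {
    bad <- rownames(values)[!stats::complete.cases(covariates[model$covariate_names])]
    stop_config("missing covariate values for sample(s): %s",
                paste(bad, collapse = ", "))
  }
  nuis <- nuisance_design(covariates, model$factor_levels)
  nuis <- nuis[, model$columns, drop = FALSE]
  centered <- sweep(nuis, 2, model$reference, "-")
  values - centered %*% model$coefficients
}

#' Z-scores against a reference group
#'
#' z = (x - mu_ref) / sigma_ref per feature, with mu/sigma computed on the
#' (already adjusted) reference samples — conventionally the euploid
#' controls. Features with zero reference variance are dropped and reported.
#'
#' @param adjusted numeric matrix, samples x features.
#' @param reference_ids row names of the reference samples (>= 3).
#' @return list: `z` matrix, `stats` tibble (`feature`, `mean`, `sd`),
#'   `rejected` feature names with zero reference sd.
#' @export
reference_zscores <- function(adjusted, reference_ids) {
  adjusted <- as.matrix(adjusted)
  if (length(reference_ids) < 3) stop_config("need >= 3 reference samples")
  if (!all(reference_ids %in% rownames(adjusted))) {
    stop_config("reference ids missing from matrix")
  }
  ref <- adjusted[reference_ids, , drop = FALSE]
  mu <- colMeans(ref)
  sig <- apply(ref, 2, sd)
  rejected <- colnames(adjusted)[sig == 0]
  keep <- sig > 0
  z <- sweep(sweep(adjusted[, keep, drop = FALSE], 2, mu[keep], "-"),
             2, sig[keep], "/")
  list(
    z = z,
    stats = tibble::tibble(feature = colnames(adjusted)[keep],
                           mean = mu[keep], sd = sig[keep]),
    rejected = rejected
  )
}

#' Select the interferon-stimulated-gene score panel
#'
#' Panel = candidate genes whose differential-expression fold-change is at
#' least `min_fc` (so exactly 1.5 qualifies) with q below `q_max`, excluding
#' chromosome-21-encoded genes (IFNAR2, MX1, MX2 by default) whose dosage
#' elevation reflects the trisomy itself rather than interferon signaling.
#'
#' @param de differential-expression table with columns `gene`, one of
#'   `fold_change` or `log2fc`, and `q`.
#' @param isg_candidates candidate gene names; all must appear in `de`.
#' @param chr21_genes genes excluded for being chromosome-21-encoded.
#' @param min_fc minimum fold-change (linear scale).
#' @param q_max significance threshold (exclusive).
#' @return object of class `isg_panel`: list with `genes`, `thresholds`,
#'   `excluded_chr21`.
#' @export
select_isg_panel <- function(de, isg_candidates,
                             chr21_genes = c("IFNAR2", "MX1", "MX2"),
                             min_fc = 1.5, q_max = 0.1) {
  missing_genes <- setdiff(isg_candidates, de$gene)
  if (length(missing_genes)) {
    stop_config("candidate(s) absent from DE table: %s",
                paste(missing_genes, collapse = ", "))
  }
  de <- de[match(isg_candidates, de$gene), ]
  fc <- if ("fold_change" %in% names(de)) de$fold_change else 2^de$log2fc
  pass <- fc >= min_fc & de$q < q_max & !(de$gene %in% chr21_genes)
  structure(
    list(
      genes = de$gene[pass],
      thresholds = c(min_fc = min_fc, q_max = q_max),
      excluded_chr21 = intersect(isg_candidates, chr21_genes)
    ),
    class = "isg_panel"
  )
}

#' Composite score as a sum of per-feature Z-scores
#'
#' Per sample, the sum of Z-scores over the panel features. Two
#' standardization modes are recorded: `"internal"` (Z computed across the
#' compared sample set, e.g. all trial timepoints pooled) and `"reference"`
#' (Z against euploid-reference statistics).
#'
#' @param z numeric Z-score matrix, samples x features.
#' @param features panel feature names (or an `isg_panel`); all must be
#'   columns of `z`.
#' @param type score label, e.g. `"IFN"` or `"cytokine"`.
#' @param mode `"internal"` or `"reference"`.
#' @return tibble (`sample_id`, `type`, `mode`, `score`) with the
#'   per-feature breakdown matrix in attribute `"breakdown"`.
#' @export
composite_score <- function(z, features, type = "IFN",
                            mode = c("reference", "internal")) {
  mode <- match.arg(mode)
  if (inherits(features, "isg_panel")) features <- features$genes
  missing_feat <- setdiff(features, colnames(z))
  if (length(missing_feat)) {
    stop_config("feature(s) missing from Z matrix: %s",
                paste(missing_feat, collapse = ", "))
  }
  sub <- z[, features, drop = FALSE]
  out <- tibble::tibble(
    sample_id = rownames(z), type = type, mode = mode,
    score = unname(rowSums(sub))
  )
  attr(out, "breakdown") <- sub
  out
}

#' Internal-mode Z-scores
#'
#' Standardizes each feature across the supplied sample set itself (mean 0,
#' sd 1 over all rows) — the standardization used when comparing trial
#' samples across timepoints without an external reference.
#'
#' @param values numeric matrix, samples x features.
#' @return Z-score matrix.
#' @export
internal_zscores <- function(values) {
  values <- as.matrix(values)
  scale(values)[, , drop = FALSE]
}

#' Two-group comparison: median difference + Mann-Whitney U
#'
#' MD = median(y) - median(x). The exact U null distribution is used when
#' both groups have at most 12 observations and there are no ties;
#' otherwise the normal approximation with midranks, tie-corrected variance
#' and continuity correction.
#'
#' @param x,y numeric vectors (reference group first).
#' @param alternative passed to [stats::wilcox.test()].
#' @return tibble: `median_diff`, `statistic` (U for `y` vs `x`), `p`,
#'   `exact`.
#' @export
compare_groups <- function(x, y, alternative = "two.sided") {
  if (!length(x) || !length(y)) stop_config("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 12 && length(y) <= 12 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(y, x, alternative = alternative, exact = exact,
                       correct = TRUE)
  )
  tibble::tibble(
    median_diff = median(y) - median(x),
    statistic = unname(wt$statistic),
    p = wt$p.value,
    exact = exact
  )
}

#' Paired comparisons across endpoints: Wilcoxon signed-rank + BH
#'
#' For each endpoint, a two-sided signed-rank test of the paired
#' differences, exact when there are at most 15 non-zero differences (zeros
#' dropped, as is conventional) and no ties; BH correction across the
#' family of endpoint comparisons. An endpoint with all differences zero
#' gets p = 1 with a warning.
#'
#' @param before,after matrices or data frames, participants x endpoints,
#'   or numeric vectors for a single endpoint.
#' @return tibble: `endpoint`, `n_pairs`, `n_nonzero`, `statistic` (V), `p`,
#'   `q`, `exact`.
#' @export
compare_paired <- function(before, after) {
  before <- as.matrix(before)
  after <- as.matrix(after)
  stopifnot(dim(before) == dim(after))
  endpoints <- colnames(before)
  if (is.null(endpoints)) endpoints <- paste0("endpoint", seq_len(ncol(before)))
  res <- lapply(seq_len(ncol(before)), function(j) {
    d <- after[, j] - before[, j]
    d <- d[is.finite(d)]
    nz <- d[d != 0]
    if (length(nz) == 0) {
      warning("all paired differences are zero for ", endpoints[j])
      return(tibble::tibble(endpoint = endpoints[j], n_pairs = length(d),
                            n_nonzero = 0L, statistic = NA_real_, p = 1,
                            exact = TRUE))
    }
    if (length(nz) < 4) {
      warning("fewer than 4 non-zero differences for ", endpoints[j],
              "; p-value has little resolution")
    }
    exact <- length(nz) <= 15 && !anyDuplicated(abs(nz))
    wt <- suppressWarnings(
      stats::wilcox.test(nz, exact = exact, correct = TRUE)
    )
    tibble::tibble(endpoint = endpoints[j], n_pairs = length(d),
                   n_nonzero = length(nz), statistic = unname(wt$statistic),
                   p = wt$p.value, exact = exact)
  })
  out <- dplyr::bind_rows(res)
  out$q <- bh_adjust(out$p)
  out
}
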