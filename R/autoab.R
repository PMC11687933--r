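# Bead-array autoantibody analysis
#
# Per-sample MAD standardization of raw MFI, positivity calling against the
# euploid-control percentile, detection filtering, Fisher-exact enrichment
# with BH correction, condition associations within the T21 group, burden
# summaries, and the two scalar assays (anti-TPO index, ANA OD ratio).

#' Per-sample MAD transform of raw MFI
#'
#' Removes sample-specific array background by standardizing each sample
#' (row) to `(MFI - median(MFI)) / MAD(MFI)`, where the median and MAD are
#' taken over that sample's antigens. The raw MAD is used (consistency
#' constant 1 by default) so the transformed units are directly "MADs from
#' the sample median". The transform is invariant to per-sample affine
#' rescaling with positive scale.
#'
#' @param array an `antigen_array` or a numeric matrix (samples x antigens).
#' @param mad_constant scale factor passed to [stats::mad()]; 1 keeps the
#'   raw median absolute deviation, 1.4826 would make it a normal-consistent
#'   scale estimate.
#' @param qc_min_beads wells with bead counts below this are set to `NA`
#'   before the transform (only applies when bead counts are available).
#' @return numeric matrix of MAD scores, same dimnames as the input.
#' @export
mad_transform <- function(array, mad_constant = 1, qc_min_beads = 20) {
  mfi <- if (inherits(array, "antigen_array")) array$mfi else as.matrix(array)
  if (inherits(array, "antigen_array") && !is.null(array$bead_count)) {
    mfi[array$bead_count < qc_min_beads] <- NA_real_
  }
  n_ok <- rowSums(is.finite(mfi))
  if (any(n_ok < 3)) {
    stop_config(
      "samples with <3 finite MFI values: %s",
      paste(rownames(mfi)[n_ok < 3], collapse = ", ")
    )
  }
  med <- apply(mfi, 1, median, na.rm = TRUE)
  madv <- apply(mfi, 1, stats::mad, constant = mad_constant, na.rm = TRUE)
  if (any(madv == 0)) {
    stop_config(
      "degenerate sample(s) with zero MAD: %s",
      paste(rownames(mfi)[madv == 0], collapse = ", ")
    )
  }
  sweep(sweep(mfi, 1, med, "-"), 1, madv, "/")
}

#' Call antigen positivity against control samples
#'
#' For each antigen the threshold is the empirical `percentile` (default
#' 90th) of the MAD scores of the control (euploid) samples; a sample is
#' called positive when its score is strictly greater than the threshold.
#'
#' @param mad numeric matrix of MAD scores (samples x antigens).
#' @param control_ids row names of the control samples (at least 5).
#' @param percentile control percentile defining the threshold.
#' @param type percentile convention (see [stats::quantile()]).
#' @return list of class `positivity_table`: logical `calls` matrix,
#'   per-antigen `thresholds`, the `percentile` and `control_ids` used.
#' @export
call_positivity <- function(mad, control_ids, percentile = 0.90, type = 7) {
  missing_ids <- setdiff(control_ids, rownames(mad))
  if (length(missing_ids)) {
    stop_config("control ids not in matrix: %s", paste(missing_ids, collapse = ", "))
  }
  if (length(control_ids) < 5) stop_config("need at least 5 control samples")
  thr <- apply(
    mad[control_ids, , drop = FALSE], 2,
    function(x) percentile(x, percentile, type = type)
  )
  calls <- sweep(mad, 2, thr, ">")
  calls[!is.finite(mad)] <- NA
  structure(
    list(calls = calls, thresholds = thr, percentile = percentile,
         control_ids = control_ids),
    class = "positivity_table"
  )
}

#' Drop antigens detected in too few samples
#'
#' Removes antigens with positive calls in fewer than `min_samples` samples
#' (strictly fewer; an antigen detected in exactly `min_samples` is kept).
#' With `count = "measured"` the filter counts non-missing measurements
#' instead of positive calls.
#'
#' @param pos a `positivity_table`.
#' @param min_samples detection threshold (default 18, i.e. <10% of a
#'   180-sample experiment).
#' @param count what "detected" counts: `"positive"` calls (default) or
#'   `"measured"` non-missing wells.
#' @return filtered `positivity_table` with the removed antigen names in
#'   `$removed`.
#' @export
filter_detected <- function(pos, min_samples = 18, count = c("positive", "measured")) {
  count <- match.arg(count)
  n_det <- if (count == "positive") {
    colSums(pos$calls, na.rm = TRUE)
  } else {
    colSums(!is.na(pos$calls))
  }
  keep <- n_det >= min_samples
  out <- pos
  out$calls <- pos$calls[, keep, drop = FALSE]
  out$thresholds <- pos$thresholds[keep]
  out$removed <- colnames(pos$calls)[!keep]
  out
}

# Two-sided (or one-sided) Fisher exact p plus cross-product odds ratio with
# Haldane 0.5 correction when any cell is empty. Table layout:
#   a = group1 positive, b = group1 negative, c = group2 positive, d = group2 negative
fisher_2x2 <- function(a, b, c, d, alternative = "two.sided") {
  p <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                          alternative = alternative)$p.value
  cells <- c(a, b, c, d)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  list(p = min(p, 1), odds_ratio = or)
}

#' Antigen enrichment between karyotype groups
#'
#' Per antigen, a 2x2 Fisher's exact test of positivity in T21 versus D21,
#' with Benjamini-Hochberg q-values across the tested antigens and
#' cross-product odds ratios (Haldane 0.5 correction when a cell is zero).
#'
#' @param pos a `positivity_table`.
#' @param groups named character vector (or factor) of group labels indexed
#'   by sample id; exactly two levels, e.g. karyotype.
#' @param case_level the level treated as "cases" (numerator of the odds
#'   ratio); defaults to the first of the sorted unique labels ("D21" vs
#'   "T21" sorts T21 second, so set this explicitly — the pipeline passes
#'   `"T21"`).
#' @param alternative `"two.sided"` (default) or `"greater"` for pure
#'   overrepresentation.
#' @return tibble: `antigen`, cell counts `a,b,c,d` (case+/-, control+/-),
#'   `odds_ratio`, `p`, `q`.
#' @export
fisher_enrichment <- function(pos, groups, case_level = NULL,
                              alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  calls <- pos$calls
  groups <- groups[rownames(calls)]
  if (anyNA(groups)) stop_config("every sample needs a group label")
  lev <- sort(unique(as.character(groups)))
  if (length(lev) != 2) stop_config("exactly two groups required")
  if (is.null(case_level)) case_level <- lev[1]
  ctrl_level <- setdiff(lev, case_level)
  if (!any(groups == case_level) || !any(groups == ctrl_level)) {
    stop_config("both groups must be non-empty")
  }
  res <- lapply(colnames(calls), function(ag) {
    x <- calls[, ag]
    ok <- !is.na(x)
    a <- sum(x[ok] & groups[ok] == case_level)
    b <- sum(!x[ok] & groups[ok] == case_level)
    cc <- sum(x[ok] & groups[ok] == ctrl_level)
    d <- sum(!x[ok] & groups[ok] == ctrl_level)
    ft <- fisher_2x2(a, b, cc, d, alternative)
    tibble::tibble(antigen = ag, a = a, b = b, c = cc, d = d,
                   odds_ratio = ft$odds_ratio, p = ft$p)
  })
  out <- dplyr::bind_rows(res)
  out$q <- bh_adjust(out$p)
  out
}

#' Autoantibody-condition associations within one karyotype group
#'
#' For each (antigen, condition) pair, Fisher's exact test of positivity in
#' cases versus controls among the supplied samples (conventionally the T21
#' group only). Conditions with fewer than `min_cases` cases are skipped and
#' reported. BH correction is applied per condition across antigens.
#'
#' @param pos a `positivity_table` restricted to one karyotype group.
#' @param participants participant tibble containing `sample_id` and logical
#'   `condition_*` columns.
#' @param conditions condition names (without the `condition_` prefix);
#'   default all present.
#' @param min_cases minimum case count for a condition to be tested.
#' @return list with `results` tibble (`condition`, `antigen`, counts,
#'   `odds_ratio`, `p`, `q`) and `skipped` (condition -> case count).
#' @export
condition_association <- function(pos, participants, conditions = NULL,
                                  min_cases = 5) {
  ids <- rownames(pos$calls)
  meta <- participants[match(ids, participants$sample_id), ]
  cond_cols <- grep("^condition_", names(meta), value = TRUE)
  if (is.null(conditions)) conditions <- sub("^condition_", "", cond_cols)
  skipped <- integer(0)
  res <- list()
  for (cond in conditions) {
    col <- paste0("condition_", cond)
    if (!col %in% names(meta)) stop_config("unknown condition: %s", cond)
    is_case <- meta[[col]]
    n_cases <- sum(is_case, na.rm = TRUE)
    if (n_cases < min_cases) {
      skipped[cond] <- n_cases
      next
    }
    grp <- setNames(ifelse(is_case, "case", "control"), ids)
    tab <- fisher_enrichment(pos, grp, case_level = "case")
    tab <- dplyr::mutate(tab, condition = cond, .before = 1)
    res[[cond]] <- tab
  }
  list(results = dplyr::bind_rows(res), skipped = skipped)
}

#' Per-sample autoantibody burden
#'
#' Counts, for each sample, how many antigens of a subset it is positive
#' for, and summarizes the fraction of samples with at least k positives.
#'
#' @param pos a `positivity_table`.
#' @param antigen_subset antigens to count over (default: all in `pos`).
#' @return list with `burden` tibble (`sample_id`, `n_positive`) and
#'   `cumulative` tibble (`k`, `fraction_at_least_k`).
#' @export
positivity_burden <- function(pos, antigen_subset = NULL) {
  if (is.null(antigen_subset)) antigen_subset <- colnames(pos$calls)
  unknown <- setdiff(antigen_subset, colnames(pos$calls))
  if (length(unknown)) {
    stop_config("unknown antigen id(s): %s", paste(unknown, collapse = ", "))
  }
  sub <- pos$calls[, antigen_subset, drop = FALSE]
  counts <- rowSums(sub, na.rm = TRUE)
  kmax <- max(counts, 0)
  ks <- if (kmax >= 1) seq_len(kmax) else integer(0)
  cumfrac <- vapply(ks, function(k) mean(counts >= k), numeric(1))
  list(
    burden = tibble::tibble(sample_id = rownames(sub),
                            n_positive = unname(counts)),
    cumulative = tibble::tibble(k = ks, fraction_at_least_k = cumfrac)
  )
}

#' Anti-TPO index and positivity call
#'
#' Index = (sample signal - negative control signal) / (positive control
#' signal - negative control signal); positive when strictly above the 95th
#' percentile of healthy-control indices.
#'
#' @param sample_signal,neg_signal,pos_signal assay signals; `pos_signal`
#'   must exceed `neg_signal`.
#' @param control_values indices of healthy control samples.
#' @param percentile control percentile for the threshold (default 0.95).
#' @param type percentile convention.
#' @return tibble with `assay`, `index`, `threshold`, `call`.
#' @export
tpo_index <- function(sample_signal, neg_signal, pos_signal, control_values,
                      percentile = 0.95, type = 7) {
  if (pos_signal <= neg_signal) {
    stop_config("assay invalid: positive control signal must exceed negative control")
  }
  index <- (sample_signal - neg_signal) / (pos_signal - neg_signal)
  thr <- percentile(control_values, percentile, type = type)
  tibble::tibble(assay = "TPO", index = index, threshold = thr, call = index > thr)
}

#' ANA positivity from OD ratio
#'
#' Ratio = sample OD / negative-control OD; positive when the ratio is at
#' least the cutoff (>= 2.1 by the kit's convention, so a ratio of exactly
#' 2.1 is positive).
#'
#' @param od_sample,od_negative optical densities; `od_negative` must be > 0.
#' @param cutoff positivity cutoff on the ratio.
#' @return tibble with `assay`, `index` (the ratio), `threshold`, `call`.
#' @export
ana_call <- function(od_sample, od_negative, cutoff = 2.1) {
  if (any(od_negative <= 0)) stop_config("negative-control OD must be positive")
  ratio <- od_sample / od_negative
  tibble::tibble(assay = "ANA", index = ratio, threshold = cutoff,
                 call = ratio >= cutoff)
}
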