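# Plasma analyte preprocessing and mixed-model differential abundance
#
# Replicate-well handling, detection-range flagging, per-plate min/max
# imputation of censored wells, extreme-outlier fencing per karyotype,
# random-intercept mixed models on log2 concentration, BH-corrected
# differential abundance, and the age-versus-karyotype effect
# decomposition.

#' Preprocess a long-format analyte table
#'
#' Out-of-range wells are replaced by the minimum (below range) or maximum
#' (above range) in-range calculated concentration for that analyte on the
#' same plate/batch — never by the assay limits themselves — then replicate
#' wells are averaged. Zero or negative calculated concentrations are
#' treated as below range so the later log2 is always defined. Analytes
#' with more than 10% of wells out of range are flagged (strictly more:
#' 10/100 is not flagged, 11/100 is); plates with no in-range well for an
#' analyte are dropped for that analyte and reported.
#'
#' @param raw tibble with columns `sample_id`, `analyte`, `plate`, `well`,
#'   `conc`, `range_flag` (`"in"`, `"below"`, `"above"`); extra columns
#'   (e.g. `source`) are carried through.
#' @param flag_threshold fraction of out-of-range wells above which an
#'   analyte is flagged.
#' @return list: `data` collapsed tibble (one row per sample-analyte with
#'   `conc`), `flagged` tibble (`analyte`, `frac_out_of_range`), `dropped`
#'   tibble of (plate, analyte) pairs with no in-range values.
#' @export
preprocess_analytes <- function(raw, flag_threshold = 0.10) {
  stopifnot(all(c("sample_id", "analyte", "plate", "conc", "range_flag")
                %in% names(raw)))
  raw <- dplyr::mutate(raw, range_flag = ifelse(
    .data$range_flag == "in" & (!is.finite(.data$conc) | .data$conc <= 0),
    "below", .data$range_flag
  ))
  raw$conc[raw$range_flag != "in"] <- NA_real_

  oor <- dplyr::summarise(
    dplyr::group_by(raw, .data$analyte),
    frac_out_of_range = mean(.data$range_flag != "in"), .groups = "drop"
  )
  flagged <- oor[oor$frac_out_of_range > flag_threshold, ]

  env <- dplyr::summarise(
    dplyr::group_by(raw, .data$plate, .data$analyte),
    plate_min = suppressWarnings(min(.data$conc, na.rm = TRUE)),
    plate_max = suppressWarnings(max(.data$conc, na.rm = TRUE)),
    .groups = "drop"
  )
  dropped <- env[!is.finite(env$plate_min), c("plate", "analyte")]
  dat <- dplyr::left_join(raw, env, by = c("plate", "analyte"))
  dat <- dat[is.finite(dat$plate_min), ]
  dat$conc <- ifelse(dat$range_flag == "below", dat$plate_min,
              ifelse(dat$range_flag == "above", dat$plate_max, dat$conc))

  extra <- setdiff(names(raw), c("sample_id", "analyte", "plate", "well",
                                 "conc", "range_flag"))
  collapsed <- dplyr::summarise(
    dplyr::group_by(dat, .data$sample_id, .data$analyte, .data$plate,
                    dplyr::across(dplyr::all_of(extra))),
    conc = mean(.data$conc), .groups = "drop"
  )
  list(data = collapsed, flagged = flagged, dropped = dropped)
}

#' Random-intercept mixed model on log2 concentration
#'
#' REML fit of `log2(conc) ~ group + age + sex + (1 | source)` (the design
#' is supplied as a data frame plus formula pieces). When the random-
#' intercept variance is estimated at zero the fixed effects coincide with
#' ordinary least squares; with a single grouping level the model falls
#' back to a fixed-effects-only fit with a warning. P-values use
#' Satterthwaite degrees of freedom by default (the convention of the
#' lmerTest fitter), or a normal Wald approximation.
#'
#' @param data data frame containing the outcome and covariates.
#' @param formula mixed-model formula, e.g.
#'   `y ~ karyotype + age + sex + (1 | source)`.
#' @param df_method `"satterthwaite"` or `"wald"`.
#' @return object of class `lmm_fit`: tibble `fixed` (`term`, `estimate`,
#'   `se`, `statistic`, `p`), `varcor` (random-intercept and residual
#'   variance), `loglik`, and the underlying `model`.
#' @export
fit_mixed_model <- function(data, formula,
                            df_method = c("satterthwaite", "wald")) {
  df_method <- match.arg(df_method)
  bars <- lme4::findbars(formula)
  grp_var <- if (length(bars)) utils::tail(all.vars(bars[[1]]), 1) else NULL
  single_source <- !is.null(grp_var) &&
    length(unique(data[[grp_var]])) < 2
  if (is.null(grp_var) || single_source) {
    if (single_source) {
      warning("single grouping level for random effect; fitting fixed effects only")
    }
    fixed_formula <- lme4::nobars(formula)
    fit <- stats::lm(fixed_formula, data = data)
    sm <- summary(fit)$coefficients
    fixed <- tibble::tibble(
      term = rownames(sm), estimate = unname(sm[, 1]), se = unname(sm[, 2]),
      statistic = unname(sm[, 3]), p = unname(sm[, 4])
    )
    return(structure(
      list(fixed = fixed,
           varcor = c(source = 0, residual = summary(fit)$sigma^2),
           loglik = as.numeric(stats::logLik(fit)), model = fit,
           df_method = "t"),
      class = "lmm_fit"
    ))
  }
  fit <- suppressMessages(lmerTest::lmer(formula, data = data, REML = TRUE))
  sm <- stats::coef(summary(fit, ddf = "Satterthwaite"))
  est <- sm[, "Estimate"]
  se <- sm[, "Std. Error"]
  if (df_method == "satterthwaite") {
    stat <- sm[, "t value"]
    p <- sm[, "Pr(>|t|)"]
  } else {
    stat <- est / se
    p <- 2 * pnorm(-abs(stat))
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  fixed <- tibble::tibble(term = rownames(sm), estimate = unname(est),
                          se = unname(se), statistic = unname(stat),
                          p = unname(p))
  structure(
    list(
      fixed = fixed,
      varcor = setNames(vc$vcov, vc$grp),
      loglik = as.numeric(stats::logLik(fit)),
      model = fit,
      df_method = df_method
    ),
    class = "lmm_fit"
  )
}

#' Differential abundance of plasma analytes
#'
#' Per analyte: collapse replicates (via [preprocess_analytes()] upstream),
#' mask extreme outliers per karyotype, fit the random-intercept mixed model
#' on log2 concentration with age and sex as fixed covariates, extract the
#' group coefficient, and BH-correct across analytes at q < `fdr`.
#'
#' @param analytes collapsed analyte tibble (`sample_id`, `analyte`,
#'   `conc`, `source`).
#' @param participants participant tibble with `sample_id`, `karyotype`,
#'   `age`, `sex`.
#' @param group_col participant column holding the two-level group
#'   (default `"karyotype"`).
#' @param case_level level treated as the case group (default `"T21"`).
#' @param fdr significance threshold on q.
#' @param mask_k outlier fence multiplier (3 x IQR); `NULL` disables
#'   masking.
#' @param df_method passed to [fit_mixed_model()].
#' @return tibble: `analyte`, `log2fc` (group effect, log2 units), `se`,
#'   `p`, `q`, `significant`, `n_used`, `n_masked`.
#' @export
differential_abundance <- function(analytes, participants,
                                   group_col = "karyotype",
                                   case_level = "T21", fdr = 0.1,
                                   mask_k = 3,
                                   df_method = c("satterthwaite", "wald")) {
  df_method <- match.arg(df_method)
  dat <- dplyr::inner_join(analytes, participants, by = "sample_id")
  dat$group <- factor(dat[[group_col]] == case_level,
                      levels = c(FALSE, TRUE),
                      labels = c("control", "case"))
  rows <- lapply(split(dat, dat$analyte), function(d) {
    d <- d[is.finite(d$conc) & d$conc > 0, ]
    n0 <- nrow(d)
    if (!is.null(mask_k)) {
      m <- suppressWarnings(mask_outliers(log2(d$conc), d$group, k = mask_k))
      d <- d[m$keep, ]
    }
    if (nrow(d) < 8 || length(unique(d$group)) < 2) {
      return(NULL)
    }
    d$logc <- log2(d$conc)
    fit <- withCallingHandlers(
      fit_mixed_model(d, logc ~ group + age + sex + (1 | source),
                      df_method = df_method),
      warning = function(w) invokeRestart("muffleWarning")
    )
    g <- fit$fixed[fit$fixed$term == "groupcase", ]
    tibble::tibble(
      analyte = d$analyte[1], log2fc = g$estimate, se = g$se, p = g$p,
      n_used = nrow(d), n_masked = n0 - nrow(d)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < fdr
  out[order(out$analyte), ]
}

#' Karyotype-versus-age effect decomposition
#'
#' Per analyte: the karyotype effect from the mixed model across both
#' groups, and the age effect from a linear regression of log2
#' concentration on age within the T21 cohort. Each family is BH-corrected
#' separately and analytes are classified as `"T21 only"`, `"age only"`,
#' `"both"` or `"ns"` at q < `fdr`.
#'
#' @inheritParams differential_abundance
#' @return tibble: `analyte`, `t21_log2fc`, `t21_q`, `age_slope`, `age_q`,
#'   `class`.
#' @export
age_karyotype_effects <- function(analytes, participants, fdr = 0.1,
                                  case_level = "T21") {
  t21_ids <- participants$sample_id[participants$karyotype == case_level]
  if (length(unique(round(participants$age, 6))) < 3) {
    stop_config("degenerate age distribution")
  }
  da <- differential_abundance(analytes, participants, fdr = fdr,
                               case_level = case_level)
  dat <- dplyr::inner_join(analytes, participants, by = "sample_id")
  dat <- dat[dat$sample_id %in% t21_ids & is.finite(dat$conc) & dat$conc > 0, ]
  age_rows <- lapply(split(dat, dat$analyte), function(d) {
    sm <- summary(stats::lm(log2(conc) ~ age, data = d))$coefficients
    tibble::tibble(analyte = d$analyte[1], age_slope = sm["age", 1],
                   age_p = sm["age", 4])
  })
  age_tab <- dplyr::bind_rows(age_rows)
  age_tab$age_q <- bh_adjust(age_tab$age_p)
  out <- dplyr::inner_join(
    dplyr::select(da, "analyte", t21_log2fc = "log2fc", t21_q = "q"),
    dplyr::select(age_tab, "analyte", "age_slope", "age_q"),
    by = "analyte"
  )
  t21_sig <- out$t21_q < fdr
  age_sig <- out$age_q < fdr
  out$class <- dplyr::case_when(
    t21_sig & age_sig ~ "both",
    t21_sig ~ "T21 only",
    age_sig ~ "age only",
    .default = "ns"
  )
  out
}
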