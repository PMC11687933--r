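# Synthetic cohort generator
#
# Emulates the statistical structure of a trisomy-21 (T21) cohort study with
# a euploid (D21) comparison group plus a small open-label JAK-inhibitor
# trial: autoantibody bead-array MFI with sample-specific background and
# group-dependent positivity, log-normal plasma analytes with detection-limit
# censoring, interferon-stimulated-gene (ISG) expression elevated in T21,
# logistic-normal immune-cell compositions, and longitudinal trial
# trajectories with a multiplicative treatment effect and sporadic
# immune-trigger spikes. Every generator draws from its own RNG substream of
# the root seed, so regenerating one table never perturbs another.

#' Default generative parameter tables
#'
#' Study-default parameter tables for the synthetic generators: a 380-antigen
#' array with 25 truly enriched autoantigens, a 54-analyte plasma panel, a
#' 16-ISG expression panel with chromosome-21 decoys and null genes, a
#' 10-cluster baseline composition, and a 10-participant trial design.
#' Each can be subset or edited and passed back into [synth_config()].
#'
#' @param n_antigens,n_elevated array size and number of enriched antigens.
#' @return a tibble (or list, for the trial) of generative parameters.
#' @export
default_antigen_params <- function(n_antigens = 380, n_elevated = 25) {
  stopifnot(n_elevated < n_antigens)
  ag <- sprintf("AG%03d", seq_len(n_antigens))
  elevated <- seq_len(n_elevated)
  pos_t21 <- rep(0.05, n_antigens)
  # spread of effect strengths among the truly enriched antigens
  pos_t21[elevated] <- seq(0.15, 0.50, length.out = n_elevated)
  tibble::tibble(
    antigen = ag,
    bg_loc = seq(-0.5, 0.5, length.out = n_antigens),
    bg_scale = 0.3,
    pos_prob_t21 = pos_t21,
    pos_prob_d21 = 0.05,
    pos_shift = 3
  )
}

#' @rdname default_antigen_params
#' @export
default_analyte_params <- function() {
  analytes <- c(
    "TNF-a", "IL-6", "CRP", "IP-10",
    sprintf("CYT%02d", seq_len(50))
  )
  n <- length(analytes)
  fc <- rep(0, n)
  fc[1:4] <- c(0.6, 0.8, 1.0, 1.0)          # the cytokine-score analytes
  fc[5:14] <- 0.5                            # other elevated markers
  slope <- rep(0, n)
  slope[c(3, 5, 6)] <- c(0.02, 0.01, 0.01)   # CRP-like age trajectories
  baseline <- seq(2, 8, length.out = n)
  tibble::tibble(
    analyte = analytes,
    baseline = baseline,
    t21_log2fc = fc,
    age_slope = slope,
    plate_sd = 0.15,
    source_sd = 0.2,
    resid_sd = 0.5,
    rep_sd = 0.1,
    lower_limit = 2^(baseline - 2.5),
    upper_limit = 2^(baseline + 4)
  )
}

#' @rdname default_antigen_params
#' @export
default_isg_params <- function() {
  isgs <- c(
    "IFI44L", "IFI44", "IFI27", "IFI6", "IFIT1", "IFIT3", "ISG15", "RSAD2",
    "SIGLEC1", "USP18", "LY6E", "EPSTI1", "HERC5", "OAS1", "OAS3", "BPGM"
  )
  chr21 <- c("IFNAR2", "MX1", "MX2")
  nulls <- sprintf("NULL%02d", seq_len(8))
  genes <- c(isgs, chr21, nulls)
  fc <- c(
    seq(log2(1.5), log2(3), length.out = length(isgs)),
    rep(log2(2), length(chr21)),
    rep(0, length(nulls))
  )
  tibble::tibble(
    gene = genes,
    baseline = seq(3, 7, length.out = length(genes)),
    t21_log2fc = fc,
    batch_sd = 0.2,
    resid_sd = 0.5,
    chr21 = genes %in% chr21
  )
}

#' @rdname default_antigen_params
#' @export
default_cluster_params <- function() {
  base <- c(0.30, 0.20, 0.15, 0.10, 0.08, 0.06, 0.05, 0.03, 0.02, 0.01)
  shift <- rep(0, 10)
  shift[2] <- -0.5  # B-cell-like depletion
  shift[5] <- 0.7   # TEMRA-like enrichment
  shift[7] <- 0.5   # basophil-like enrichment
  tibble::tibble(
    cluster = sprintf("CL%02d", seq_len(10)),
    baseline = base,
    t21_logodds = shift,
    sd = 0.4
  )
}

#' @rdname default_antigen_params
#' @export
default_trial_params <- function() {
  list(
    n_participants = 10,
    weeks = c(0, 2, 8, 16),
    measurements = tibble::tibble(
      measurement = c("ifn_score", "cytokine_score", "anti_TPO", "anti_TG"),
      baseline_meanlog = log(c(8, 6, 120, 3)),
      baseline_sdlog = c(0.5, 0.5, 1.2, 1.0),
      treatment_log2fc = c(-1.0, -0.8, -0.7, -0.6)
    ),
    noise_sd = 0.15,
    trigger_events = list()
  )
}

#' Configuration of the synthetic cohort
#'
#' Bundles every generative parameter behind the synthetic cohort and trial.
#' The defaults mirror the design of the emulated study: 120 T21 and 60 D21
#' participants in the autoantibody arm, high T21 prevalence of autoimmune
#' thyroid disease (53.1%), immune skin conditions (43%) and celiac disease
#' (9.6%), a 54-analyte plasma panel with detection limits, a 16-gene ISG
#' panel with T21 fold-changes of at least 1.5 plus chromosome-21-encoded
#' decoys (IFNAR2, MX1, MX2), a 10-cluster logistic-normal composition, and
#' a 10-participant trial sampled at weeks 0/2/8/16.
#'
#' @param seed root seed; every generator derives an independent substream.
#' @param n_t21,n_d21 group sizes.
#' @param age_range numeric length-2, years.
#' @param sex_prob probability of female sex.
#' @param prevalence named list with elements `T21` and `D21`, each a named
#'   vector of condition prevalences.
#' @param antigen_params,analyte_params,isg_params,cluster_params data frames
#'   of per-feature generative parameters (see the package vignette).
#' @param trial_params list describing the trial arm.
#' @param antigen_sample_sd sd of the per-sample array background (log-MFI).
#' @return object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_t21 = 120L,
                         n_d21 = 60L,
                         age_range = c(2, 57),
                         sex_prob = 0.5,
                         prevalence = list(
                           T21 = c(AITD = 0.531, skin = 0.43, celiac = 0.096),
                           D21 = c(AITD = 0.05, skin = 0.10, celiac = 0.01)
                         ),
                         antigen_params = default_antigen_params(),
                         analyte_params = default_analyte_params(),
                         isg_params = default_isg_params(),
                         cluster_params = default_cluster_params(),
                         trial_params = default_trial_params(),
                         antigen_sample_sd = 0.5) {
  if (n_t21 + n_d21 < 2) stop_config("need at least 2 participants")
  check_prob(sex_prob, "sex_prob")
  for (g in names(prevalence)) check_prob(prevalence[[g]], paste0("prevalence$", g))
  if (length(age_range) != 2 || age_range[1] >= age_range[2]) {
    stop_config("age_range must be (min, max) with min < max")
  }
  check_prob(antigen_params$pos_prob_t21, "pos_prob_t21")
  check_prob(antigen_params$pos_prob_d21, "pos_prob_d21")
  if (any(analyte_params$lower_limit >= analyte_params$upper_limit)) {
    stop_config("detection limits need lower < upper")
  }
  if (abs(sum(cluster_params$baseline) - 1) > 1e-9) {
    stop_config("cluster baseline composition must sum to 1")
  }
  if (!0 %in% trial_params$weeks) stop_config("trial weeks must include 0 (baseline)")
  structure(
    list(
      seed = as.integer(seed), n_t21 = as.integer(n_t21), n_d21 = as.integer(n_d21),
      age_range = age_range, sex_prob = sex_prob, prevalence = prevalence,
      antigen_params = antigen_params, analyte_params = analyte_params,
      isg_params = isg_params, cluster_params = cluster_params,
      trial_params = trial_params, antigen_sample_sd = antigen_sample_sd
    ),
    class = "synth_config"
  )
}

#' Generate the participant table
#'
#' Ages are uniform over `age_range`, sex is Bernoulli(`sex_prob`), and each
#' configured condition flag is Bernoulli with the karyotype-specific
#' prevalence. Deterministic given the config seed.
#'
#' @param config a [synth_config()].
#' @return tibble with `sample_id`, `karyotype`, `age`, `sex` and one logical
#'   `condition_<name>` column per configured condition.
#' @export
generate_participants <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_t21 + config$n_d21
  with_substream(config$seed, 1L, {
    out <- tibble::tibble(
      sample_id = sprintf("P%04d", seq_len(n)),
      karyotype = rep(c("T21", "D21"), c(config$n_t21, config$n_d21)),
      age = runif(n, config$age_range[1], config$age_range[2]),
      sex = ifelse(rbinom(n, 1, config$sex_prob) == 1, "Female", "Male")
    )
    conds <- unique(unlist(lapply(config$prevalence, names)))
    for (cond in conds) {
      pr <- vapply(out$karyotype, function(k) {
        p <- config$prevalence[[k]][cond]
        if (is.na(p)) 0 else unname(p)
      }, numeric(1))
      out[[paste0("condition_", cond)]] <- rbinom(n, 1, pr) == 1
    }
    out
  })
}

#' Generate a synthetic autoantibody bead array
#'
#' log-MFI is a per-sample background (normal around a sample-specific
#' location) plus a per-antigen offset; samples drawn positive at their
#' karyotype's positivity probability receive an additive positive shift in
#' log-MFI. Raw MFI is the exponential. Ground-truth positivity labels are
#' retained in `$truth` for testing.
#'
#' @param participants output of [generate_participants()].
#' @param config a [synth_config()].
#' @return object of class `antigen_array`: list with `mfi` and `bead_count`
#'   matrices (samples x antigens), `samples` metadata and `truth` labels.
#' @export
generate_antigen_array <- function(participants, config) {
  stopifnot(inherits(config, "synth_config"))
  ap <- config$antigen_params
  if (nrow(ap) == 0) stop_config("antigen_params is empty")
  n <- nrow(participants)
  m <- nrow(ap)
  with_substream(config$seed, 2L, {
    sample_bg <- rnorm(n, mean = 6, sd = config$antigen_sample_sd)
    t21 <- participants$karyotype == "T21"
    pos_prob <- matrix(rep(ap$pos_prob_d21, each = n), n, m)
    pos_prob[t21, ] <- matrix(rep(ap$pos_prob_t21, each = n), n, m)[t21, ]
    truth <- matrix(rbinom(n * m, 1, pos_prob) == 1, n, m)
    logmfi <- sample_bg +
      matrix(rep(ap$bg_loc, each = n), n, m) +
      matrix(rnorm(n * m, sd = rep(ap$bg_scale, each = n)), n, m) +
      truth * matrix(rep(ap$pos_shift, each = n), n, m)
    mfi <- exp(logmfi)
    bead <- matrix(rpois(n * m, 50), n, m)
    dimnames(mfi) <- dimnames(bead) <- dimnames(truth) <-
      list(participants$sample_id, ap$antigen)
    structure(
      list(mfi = mfi, bead_count = bead, samples = participants, truth = truth),
      class = "antigen_array"
    )
  })
}

#' Generate a synthetic plasma analyte table
#'
#' log2 concentration = baseline + t21_log2fc x \[T21\] + age_slope x age +
#' plate effect + source effect + biological noise; each sample-analyte pair
#' is measured in two replicate wells with small technical noise. Wells
#' falling outside the configured detection limits are recorded as
#' below/above-range flags with a missing concentration (never clipped), so
#' the downstream imputation path is always exercised.
#'
#' @inheritParams generate_antigen_array
#' @return long tibble: `sample_id`, `analyte`, `plate`, `source`, `well`,
#'   `conc` (pg/mL, `NA` when out of range), `range_flag` in
#'   `c("in", "below", "above")`.
#' @export
generate_analyte_table <- function(participants, config) {
  stopifnot(inherits(config, "synth_config"))
  ap <- config$analyte_params
  if (nrow(ap) == 0) stop_config("analyte_params is empty")
  n <- nrow(participants)
  with_substream(config$seed, 3L, {
    # plates and sources mix karyotypes, as in the assayed cohort
    plate <- sprintf("plate%02d", sample(rep(seq_len(ceiling(n / 40)),
                                             length.out = n)))
    source <- sprintf("S%d", sample.int(4, n, replace = TRUE))
    plates <- unique(plate)
    sources <- unique(source)
    rows <- lapply(seq_len(nrow(ap)), function(j) {
      p <- ap[j, ]
      plate_eff <- setNames(rnorm(length(plates), sd = p$plate_sd), plates)
      source_eff <- setNames(rnorm(length(sources), sd = p$source_sd), sources)
      base <- p$baseline +
        p$t21_log2fc * (participants$karyotype == "T21") +
        p$age_slope * participants$age +
        plate_eff[plate] + source_eff[source] +
        rnorm(n, sd = p$resid_sd)
      tibble::tibble(
        sample_id = rep(participants$sample_id, 2),
        analyte = p$analyte,
        plate = rep(plate, 2),
        source = rep(source, 2),
        well = rep(1:2, each = n),
        conc = 2^(rep(base, 2) + rnorm(2 * n, sd = p$rep_sd)),
        lower = p$lower_limit, upper = p$upper_limit
      )
    })
    out <- dplyr::bind_rows(rows)
    out$range_flag <- ifelse(out$conc < out$lower, "below",
      ifelse(out$conc > out$upper, "above", "in")
    )
    out$conc[out$range_flag != "in"] <- NA_real_
    out$lower <- out$upper <- NULL
    out
  })
}

#' Generate a synthetic expression table with DE ground truth
#'
#' FPKM-like values are log-normal: log2 FPKM = baseline + t21_log2fc x
#' \[T21\] + batch effect + noise. Genes configured with a fold-change of at
#' least 1.5 (and not flagged as chromosome-21-encoded) are the intended ISG
#' panel. A ground-truth differential-expression table (`gene`, `log2fc`,
#' `fold_change`, `q`, `chr21`) is attached as `$de_truth`.
#'
#' @inheritParams generate_antigen_array
#' @return list of class `expression_table` with `fpkm` (samples x genes),
#'   `batch` (per-sample), and `de_truth`.
#' @export
generate_expression_table <- function(participants, config) {
  stopifnot(inherits(config, "synth_config"))
  gp <- config$isg_params
  if (nrow(gp) == 0) stop_config("isg_params is empty")
  n <- nrow(participants)
  m <- nrow(gp)
  with_substream(config$seed, 4L, {
    batch <- sprintf("B%d", sample(rep(seq_len(ceiling(n / 48)),
                                       length.out = n)))
    batches <- unique(batch)
    log2fpkm <- vapply(seq_len(m), function(j) {
      p <- gp[j, ]
      be <- setNames(rnorm(length(batches), sd = p$batch_sd), batches)
      p$baseline + p$t21_log2fc * (participants$karyotype == "T21") +
        be[batch] + rnorm(n, sd = p$resid_sd)
    }, numeric(n))
    fpkm <- 2^log2fpkm
    dimnames(fpkm) <- list(participants$sample_id, gp$gene)
    de_truth <- tibble::tibble(
      gene = gp$gene,
      log2fc = gp$t21_log2fc,
      fold_change = 2^gp$t21_log2fc,
      q = ifelse(abs(gp$t21_log2fc) > 0, 1e-4, 0.5),
      chr21 = gp$chr21
    )
    structure(
      list(fpkm = fpkm, batch = setNames(batch, participants$sample_id),
           de_truth = de_truth, samples = participants),
      class = "expression_table"
    )
  })
}

#' Generate a synthetic cell-cluster frequency table
#'
#' Per-sample compositions follow a logistic-normal: cluster log-odds are the
#' log of the baseline composition plus a per-cluster T21 shift plus normal
#' noise, mapped through softmax. Rows sum to one by construction and every
#' proportion is strictly inside (0, 1).
#'
#' @inheritParams generate_antigen_array
#' @param level gating-level label stored with the rows.
#' @return long tibble: `sample_id`, `level`, `cluster`, `proportion`.
#' @export
generate_frequency_table <- function(participants, config, level = "live") {
  stopifnot(inherits(config, "synth_config"))
  cp <- config$cluster_params
  n <- nrow(participants)
  k <- nrow(cp)
  with_substream(config$seed, 5L, {
    z <- matrix(log(cp$baseline), n, k, byrow = TRUE) +
      outer(participants$karyotype == "T21", cp$t21_logodds) +
      matrix(rnorm(n * k, sd = rep(cp$sd, each = n)), n, k)
    p <- exp(z)
    p <- p / rowSums(p)
    tibble::tibble(
      sample_id = rep(participants$sample_id, k),
      level = level,
      cluster = rep(cp$cluster, each = n),
      proportion = as.vector(p)
    )
  })
}

#' Generate a synthetic trial time-series
#'
#' Baselines are drawn from a T21-like log-normal distribution per
#' measurement; every post-baseline value is the baseline multiplied by
#' `2^treatment_log2fc` with multiplicative log2-scale noise. Configured
#' trigger events (immune stimuli such as a vaccination or infection before
#' a visit) multiply the affected participant-week value by their spike
#' factor and set the `trigger` flag.
#'
#' @param config a [synth_config()]; uses `config$trial_params`.
#' @return tibble: `participant`, `week`, `measurement`, `value`, `trigger`.
#' @export
generate_trial_series <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  tp <- config$trial_params
  if (!0 %in% tp$weeks) stop_config("trial weeks must include 0")
  with_substream(config$seed, 6L, {
    ids <- sprintf("T%02d", seq_len(tp$n_participants))
    rows <- lapply(seq_len(nrow(tp$measurements)), function(j) {
      m <- tp$measurements[j, ]
      base <- rlnorm(tp$n_participants, m$baseline_meanlog, m$baseline_sdlog)
      do.call(rbind, lapply(tp$weeks, function(w) {
        v <- if (w == 0) base else {
          base * 2^(m$treatment_log2fc + rnorm(tp$n_participants, sd = tp$noise_sd))
        }
        data.frame(
          participant = ids, week = w, measurement = m$measurement,
          value = v, trigger = FALSE, stringsAsFactors = FALSE
        )
      }))
    })
    out <- tibble::as_tibble(do.call(rbind, rows))
    for (ev in tp$trigger_events) {
      hit <- out$participant == ev$participant &
        out$week == ev$week & out$measurement == ev$measurement
      out$value[hit] <- out$value[hit] * ev$spike
      out$trigger[hit] <- TRUE
    }
    out
  })
}

#' Simulate a full cohort bundle
#'
#' Runs every generator off the same root seed and returns all tables in a
#' `cohort_bundle`, checking that every sample id in each data table exists
#' in the participant table.
#'
#' @param config a [synth_config()].
#' @param trial include the trial arm (default `TRUE`).
#' @return list of class `cohort_bundle` with elements `participants`,
#'   `antigen_array`, `analytes`, `expression`, `frequencies`, `trial`.
#' @export
simulate_cohort <- function(config = synth_config(), trial = TRUE) {
  participants <- generate_participants(config)
  bundle <- structure(
    list(
      participants = participants,
      antigen_array = generate_antigen_array(participants, config),
      analytes = generate_analyte_table(participants, config),
      expression = generate_expression_table(participants, config),
      frequencies = generate_frequency_table(participants, config),
      trial = if (trial) generate_trial_series(config) else NULL,
      config = config
    ),
    class = "cohort_bundle"
  )
  ids <- participants$sample_id
  stopifnot(
    !anyDuplicated(ids),
    all(rownames(bundle$antigen_array$mfi) %in% ids),
    all(bundle$analytes$sample_id %in% ids),
    all(rownames(bundle$expression$fpkm) %in% ids),
    all(bundle$frequencies$sample_id %in% ids)
  )
  bundle
}
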