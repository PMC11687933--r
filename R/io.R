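# Table I/O, configuration and pipeline orchestration
#
# TSV (tab-delimited, UTF-8, header row) is the canonical dialect; CSV is
# accepted on read (delimiter sniffed from the header line). Every reader
# validates against exactly one schema. The run configuration is YAML, all
# randomness flows from its single seed, and `run_pipeline()` executes the
# stages in dependency order, writing every intermediate table plus a JSON
# manifest.

table_schemas <- list(
  participants = list(
    required = c(sample_id = "character", karyotype = "character",
                 age = "numeric", sex = "character"),
    extras = TRUE
  ),
  analytes = list(
    required = c(sample_id = "character", analyte = "character",
                 plate = "character", source = "character",
                 well = "numeric", conc = "numeric", range_flag = "character"),
    extras = TRUE
  ),
  frequencies = list(
    required = c(sample_id = "character", level = "character",
                 cluster = "character", proportion = "numeric"),
    extras = FALSE
  ),
  trial = list(
    required = c(participant = "character", week = "numeric",
                 measurement = "character", value = "numeric"),
    extras = TRUE
  ),
  safety = list(
    required = c(participant = "character", event = "character",
                 grade = "numeric", attribution = "character",
                 serious = "logical"),
    extras = TRUE
  ),
  de_results = list(
    required = c(gene = "character", log2fc = "numeric", q = "numeric"),
    extras = TRUE
  )
)

sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t"
  else if (grepl(",", header)) ","
  else stop_config("cannot detect delimiter (expected TSV or CSV): %s", path)
}

#' Read and validate a table
#'
#' Reads a TSV (or CSV) file and validates it against one of the package's
#' named schemas, coercing the required columns to their semantic types.
#' Missing required columns, unknown columns (when the schema forbids
#' extras), and uncoercible values are reported by name.
#'
#' @param path file path.
#' @param schema schema name, one of `names(dsimmune:::table_schemas)`.
#' @return validated tibble.
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) stop_config("file not found: %s", path)
  if (!schema %in% names(table_schemas)) {
    stop_config("unknown schema '%s'", schema)
  }
  sc <- table_schemas[[schema]]
  delim <- sniff_delim(path)
  dat <- utils::read.delim(path, sep = delim, stringsAsFactors = FALSE,
                           check.names = FALSE)
  missing_cols <- setdiff(names(sc$required), names(dat))
  if (length(missing_cols)) {
    stop_config("schema '%s': missing required column(s): %s",
                schema, paste(missing_cols, collapse = ", "))
  }
  if (!sc$extras) {
    extra <- setdiff(names(dat), names(sc$required))
    if (length(extra)) {
      stop_config("schema '%s' allows no extra columns; found: %s",
                  schema, paste(extra, collapse = ", "))
    }
  }
  for (col in names(sc$required)) {
    type <- sc$required[[col]]
    coerced <- switch(type,
      numeric = suppressWarnings(as.numeric(dat[[col]])),
      character = as.character(dat[[col]]),
      logical = as.logical(dat[[col]])
    )
    bad <- which(is.na(coerced) & !is.na(dat[[col]]) & dat[[col]] != "NA")
    if (length(bad)) {
      stop_config("column '%s' has malformed values at row(s): %s",
                  col, paste(head(bad, 5), collapse = ", "))
    }
    dat[[col]] <- coerced
  }
  tibble::as_tibble(dat)
}

#' Write a table as TSV
#'
#' @param x data frame.
#' @param path output path; parent directories are created.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "dsimmune_run",
    positivity_percentile = 0.90,
    min_detected = 18,
    fdr = 0.1,
    min_cases = 5,
    flag_threshold = 0.10,
    uln = list(anti_TPO = 60, anti_TG = 4),
    score_mode = "reference",
    endpoint_weeks = c(2, 8, 16)
  )
}

#' Load a run configuration
#'
#' Reads a YAML config, fills defaults, validates ranges, and returns the
#' effective configuration (also echoed via `message()` for provenance).
#' An empty or absent file yields all defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return named list of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_config("config not found: %s", path)
    user <- yaml::read_yaml(path)
    if (length(user)) cfg[names(user)] <- user
  }
  for (par in c("positivity_percentile", "fdr", "flag_threshold")) {
    v <- cfg[[par]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop_config("parameter '%s' = %s out of range [0, 1]", par, format(v))
    }
  }
  if (cfg$min_detected < 0 || cfg$min_cases < 0) {
    stop_config("count thresholds must be non-negative")
  }
  cfg$seed <- as.integer(cfg$seed)
  message("effective config: ", jsonlite::toJSON(cfg, auto_unbox = TRUE))
  structure(cfg, class = "run_config")
}

#' Run the full synthetic-cohort pipeline
#'
#' Executes the stages in dependency order — simulate, autoantibody
#' positivity/enrichment, composite scores, analyte differential abundance,
#' compositional regression, trial endpoints — writing every intermediate
#' table as TSV under `config$out_dir` plus a JSON manifest (package
#' version, seed, per-stage timings). Rerunning with the same config
#' reproduces identical tables.
#'
#' @param config a `run_config` from [load_config()].
#' @param synth optional [synth_config()]; defaults to the study-default
#'   generator seeded from `config$seed`.
#' @return (invisibly) list with the output directory and the in-memory
#'   stage results.
#' @export
run_pipeline <- function(config = load_config(), synth = NULL) {
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(synth)) synth <- synth_config(seed = config$seed)
  timings <- c()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stop_config("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  bundle <- stage("simulate", simulate_cohort(synth))
  write_table(bundle$participants, file.path(out_dir, "participants.tsv"))
  write_table(bundle$analytes, file.path(out_dir, "analytes.tsv"))
  write_table(bundle$frequencies, file.path(out_dir, "frequencies.tsv"))
  write_table(bundle$trial, file.path(out_dir, "trial.tsv"))

  autoab <- stage("autoab", {
    mads <- mad_transform(bundle$antigen_array)
    d21 <- bundle$participants$sample_id[bundle$participants$karyotype == "D21"]
    pos <- call_positivity(mads, d21, percentile = config$positivity_percentile)
    pos <- filter_detected(pos, min_samples = config$min_detected)
    groups <- setNames(bundle$participants$karyotype,
                       bundle$participants$sample_id)
    enr <- fisher_enrichment(pos, groups, case_level = "T21")
    hits <- enr$antigen[enr$q < config$fdr]
    burden <- positivity_burden(pos, hits)
    assoc <- condition_association(
      structure(list(calls = pos$calls[groups[rownames(pos$calls)] == "T21", ,
                                       drop = FALSE],
                     thresholds = pos$thresholds),
                class = "positivity_table"),
      bundle$participants, min_cases = config$min_cases
    )
    list(positivity = pos, enrichment = enr, hits = hits, burden = burden,
         association = assoc)
  })
  write_table(autoab$enrichment, file.path(out_dir, "autoab_enrichment.tsv"))
  write_table(autoab$burden$cumulative, file.path(out_dir, "autoab_burden.tsv"))

  scores <- stage("scores", {
    expr <- bundle$expression
    panel <- select_isg_panel(
      expr$de_truth,
      isg_candidates = expr$de_truth$gene,
      min_fc = 1.5, q_max = config$fdr
    )
    logf <- log2(expr$fpkm + 1)
    covs <- data.frame(
      age = bundle$participants$age,
      sex = bundle$participants$sex,
      batch = unname(expr$batch[bundle$participants$sample_id])
    )
    adj_model <- fit_covariate_adjustment(logf, covs,
                                          keep = bundle$participants$karyotype)
    adj <- apply_adjustment(adj_model, logf, covs)
    d21 <- bundle$participants$sample_id[bundle$participants$karyotype == "D21"]
    zs <- reference_zscores(adj, d21)
    ifn <- composite_score(zs$z, panel, type = "IFN", mode = "reference")
    t21_scores <- ifn$score[bundle$participants$karyotype == "T21"]
    d21_scores <- ifn$score[bundle$participants$karyotype == "D21"]
    cmp <- compare_groups(d21_scores, t21_scores)
    list(panel = panel, ifn = ifn, comparison = cmp)
  })
  write_table(scores$ifn, file.path(out_dir, "ifn_scores.tsv"))

  markers <- stage("markers", {
    prep <- preprocess_analytes(bundle$analytes,
                                flag_threshold = config$flag_threshold)
    da <- differential_abundance(prep$data, bundle$participants,
                                 fdr = config$fdr)
    # cytokine score: sum of reference Z-scores of TNF-a, IL-6, CRP, IP-10
    score_analytes <- c("TNF-a", "IL-6", "CRP", "IP-10")
    cyt <- NULL
    if (all(score_analytes %in% prep$data$analyte)) {
      wide <- tidyr::pivot_wider(
        prep$data[prep$data$analyte %in% score_analytes,
                  c("sample_id", "analyte", "conc")],
        names_from = "analyte", values_from = "conc"
      )
      keep_ids <- wide$sample_id[stats::complete.cases(wide)]
      meta <- bundle$participants[match(keep_ids,
                                        bundle$participants$sample_id), ]
      src <- prep$data$source[match(keep_ids, prep$data$sample_id)]
      mat <- log2(as.matrix(wide[match(keep_ids, wide$sample_id),
                                 score_analytes]))
      rownames(mat) <- keep_ids
      covs <- data.frame(age = meta$age, sex = meta$sex, source = src)
      adjm <- fit_covariate_adjustment(mat, covs, keep = meta$karyotype)
      adj <- apply_adjustment(adjm, mat, covs)
      d21_ids <- intersect(keep_ids,
                           bundle$participants$sample_id[
                             bundle$participants$karyotype == "D21"])
      zsc <- reference_zscores(adj, d21_ids)
      cyt <- composite_score(zsc$z, score_analytes, type = "cytokine",
                             mode = "reference")
    }
    list(prep = prep, da = da, cytokine = cyt)
  })
  write_table(markers$da, file.path(out_dir, "analyte_differential_abundance.tsv"))
  if (!is.null(markers$cytokine)) {
    write_table(markers$cytokine, file.path(out_dir, "cytokine_scores.tsv"))
  }

  composition <- stage("composition", {
    freqs <- bundle$frequencies
    meta <- bundle$participants[match(freqs$sample_id,
                                      bundle$participants$sample_id), ]
    fits <- list()
    for (cl in unique(freqs$cluster)) {
      idx <- freqs$cluster == cl
      y <- freqs$proportion[idx]
      m <- meta[idx, ]
      mask <- suppressWarnings(mask_outliers(y, m$karyotype))
      y <- squeeze_proportions(y[mask$keep], sum(mask$keep))
      m <- m[mask$keep, ]
      X <- stats::model.matrix(~ karyotype + age + sex, data = m)
      fits[[cl]] <- fit_beta_regression(y, X)
    }
    summarize_fold_changes(fits, group_coef = "karyotypeT21", fdr = config$fdr)
  })
  write_table(composition, file.path(out_dir, "composition_results.tsv"))

  trial <- stage("trial", {
    series <- bundle$trial
    dec <- lapply(config$endpoint_weeks, function(w) {
      cd <- count_decreasing(series, "ifn_score", w)
      tibble::tibble(week = w, measurement = "ifn_score",
                     n_decreased = cd$n_decreased,
                     n_evaluable = cd$n_evaluable)
    })
    uln <- lapply(names(config$uln), function(m) {
      uln_response(series, m, config$uln[[m]],
                   weeks = setdiff(config$endpoint_weeks, 2))
    })
    names(uln) <- names(config$uln)
    list(decreasing = dplyr::bind_rows(dec), uln = uln)
  })
  write_table(trial$decreasing, file.path(out_dir, "trial_decreasing.tsv"))

  manifest <- list(
    package = "dsimmune",
    version = as.character(utils::packageVersion("dsimmune")),
    seed = config$seed,
    timings_sec = as.list(timings),
    tables = list.files(out_dir, pattern = "[.]tsv$")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(
    out_dir = out_dir, autoab = autoab, scores = scores, markers = markers,
    composition = composition, trial = trial, bundle = bundle
  ))
}

#' @importFrom dplyr .data
NULL
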