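#' @importFrom stats quantile median mad sd var lm coef resid fisher.test
#'   wilcox.test p.adjust plogis qlogis rnorm runif rbinom rpois rlnorm
#'   optim dbeta lgamma setNames model.matrix pnorm pt complete.cases
#' @importFrom utils head
NULL

# Run code under a reproducible RNG substream derived from a root seed.
# Each table generator uses its own fixed offset so adding a new table
# never perturbs the draws of an existing one.
with_substream <- function(seed, offset, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  sub <- (abs(as.integer(seed)) %% 1000003L) * 2011L + as.integer(offset)
  sub <- sub %% .Machine$integer.max
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(sub)
  force(code)
}

# Empirical percentile with an explicit convention (default: type 7,
# linear interpolation). Exposed so thresholding stays auditable.
percentile <- function(x, p, type = 7) {
  stats::quantile(x, probs = p, type = type, names = FALSE, na.rm = TRUE)
}

#' Tukey-style outlier fences
#'
#' Flags values more than `k` times the interquartile range below the first
#' or above the third quartile. With `k = 3` this is the "extreme outlier"
#' rule used throughout the cohort analyses: fences collapse onto the
#' quartiles when the IQR is zero, and equality with a fence is never
#' flagged (the rule is strictly "more than").
#'
#' @param x numeric vector.
#' @param k fence multiplier (default 3).
#' @param type percentile convention passed to [stats::quantile()].
#' @return logical vector, `TRUE` where `x` is an extreme outlier.
#' @export
iqr_outliers <- function(x, k = 3, type = 7) {
  q1 <- percentile(x, 0.25, type = type)
  q3 <- percentile(x, 0.75, type = type)
  iqr <- q3 - q1
  (x < q1 - k * iqr) | (x > q3 + k * iqr)
}

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper over [stats::p.adjust()] kept as a single choke point so
#' every module corrects p-values the same way (q < 0.1 is the working
#' significance threshold throughout).
#'
#' @param p numeric vector of p-values.
#' @return vector of BH q-values.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

check_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_config("%s must be probabilities in [0,1]", what)
  }
  invisible(x)
}
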