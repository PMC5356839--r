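# Control-based normalization of nCounter counts, in the platform's
# canonical three steps: (1) background subtraction from the negative
# controls, (2) technical scaling from the positive-control spike-ins with
# exclusion of lanes whose scaling factor falls outside [0.3, 3], and
# (3) biological (RNA-content) scaling from the housekeeping genes with
# exclusion outside [0.1, 10].

POS_FACTOR_RANGE <- c(0.3, 3)
BIO_FACTOR_RANGE <- c(0.1, 10)

geomean <- function(x, pseudocount = 0.5) {
  x <- ifelse(x <= 0, pseudocount, x)
  exp(mean(log(x)))
}

#' Subtract negative-control background
#'
#' Per sample, the background is estimated from the negative-control probes
#' and subtracted from every non-negative-control count, flooring at zero.
#'
#' @param m a [count_matrix] at stage `"raw"`.
#' @param estimator background statistic over the negative controls:
#'   plain mean (default, vendor baseline), mean plus two standard
#'   deviations, or the maximum.
#' @return a [count_matrix] at stage `"background_subtracted"`, with the
#'   per-sample background stored in `m$norm`.
#' @export
subtract_background <- function(m, estimator = c("mean", "mean2sd", "max")) {
  require_stage(m, "raw")
  estimator <- match.arg(estimator)
  neg <- class_counts(m, "Negative")
  if (nrow(neg) == 0) {
    stop("codeset has no Negative probes; cannot estimate background",
         call. = FALSE)
  }
  bg <- switch(estimator,
    mean = colMeans(neg),
    mean2sd = colMeans(neg) + 2 * apply(neg, 2, stats::sd),
    max = apply(neg, 2, max))
  target <- m$codeset$code_class != "Negative"
  m$counts[target, ] <- pmax(sweep(m$counts[target, , drop = FALSE], 2, bg),
                             0)
  m$norm <- data.frame(sample_id = m$samples$sample_id, background = bg,
                       pos_factor = NA_real_, bio_factor = NA_real_,
                       status = "retained", reason = "",
                       stringsAsFactors = FALSE, row.names = NULL)
  advance_stage(m, "background_subtracted")
}

# shared machinery for the two scaling steps: factor_i = (cohort arithmetic
# mean of per-sample geometric means of the control probes) / (sample i's
# geometric mean); the whole lane is multiplied by factor_i.
control_factors <- function(m, class, pseudocount) {
  ctrl <- class_counts(m, class)
  gm <- apply(ctrl, 2, geomean, pseudocount = pseudocount)
  list(factor = mean(gm) / gm, geomean = gm)
}

#' Technical (positive-control) normalization
#'
#' Scales every lane so the geometric means of its six positive-control
#' spike-ins agree across the cohort. Lanes whose scaling factor falls
#' outside `[0.3, 3]` indicate technical failure and are excluded from all
#' downstream stages.
#'
#' @param m a [count_matrix] at stage `"background_subtracted"`.
#' @param pseudocount value substituted for nonpositive control counts
#'   before taking logs.
#' @return list with `matrix` (retained lanes, stage `"tech_normalized"`)
#'   and `report` (per-sample factors and exclusion verdicts so far).
#' @export
technical_normalize <- function(m, pseudocount = 0.5) {
  require_stage(m, "background_subtracted")
  cf <- control_factors(m, "Positive", pseudocount)
  rep <- m$norm
  rep$pos_factor <- cf$factor
  out <- cf$factor < POS_FACTOR_RANGE[1] | cf$factor > POS_FACTOR_RANGE[2]
  rep$status[out] <- "excluded_technical"
  rep$reason[out] <- sprintf("pos_factor %.4g outside [%g, %g]",
                             cf$factor[out], POS_FACTOR_RANGE[1],
                             POS_FACTOR_RANGE[2])
  m$counts <- sweep(m$counts, 2, cf$factor, `*`)
  m$norm <- rep
  m <- advance_stage(m, "tech_normalized")
  m <- subset_samples(m, rep$sample_id[!out])
  m$norm <- rep  # keep excluded lanes in the bookkeeping
  list(matrix = m, report = rep)
}

#' Biological (housekeeping) normalization
#'
#' Scales every retained lane so the geometric means of the housekeeping
#' genes agree across the cohort, correcting for RNA input. Lanes whose
#' factor falls outside `[0.1, 10]` (poor-quality RNA) are excluded.
#'
#' @param m a [count_matrix] at stage `"tech_normalized"` (as returned by
#'   [technical_normalize]; its `norm` slot carries earlier verdicts).
#' @param pseudocount as in [technical_normalize].
#' @return list with `matrix` (retained lanes, stage `"bio_normalized"`)
#'   and `report` (the full normalization report).
#' @export
biological_normalize <- function(m, pseudocount = 0.5) {
  require_stage(m, "tech_normalized")
  hk <- class_counts(m, "Housekeeping")
  if (nrow(hk) == 0) {
    stop("codeset has no Housekeeping probes", call. = FALSE)
  }
  cf <- control_factors(m, "Housekeeping", pseudocount)
  all_zero <- apply(hk, 2, function(x) all(x <= 0))
  rep <- if (!is.null(m$norm)) m$norm else
    data.frame(sample_id = m$samples$sample_id, background = NA_real_,
               pos_factor = NA_real_, bio_factor = NA_real_,
               status = "retained", reason = "", stringsAsFactors = FALSE)
  idx <- match(m$samples$sample_id, rep$sample_id)
  rep$bio_factor[idx] <- cf$factor
  out <- cf$factor < BIO_FACTOR_RANGE[1] | cf$factor > BIO_FACTOR_RANGE[2] |
    all_zero
  rep$status[idx][out] <- "excluded_biological"
  rep$reason[idx][out] <- ifelse(all_zero[out],
    "all housekeeping counts zero; bio_factor undefined",
    sprintf("bio_factor %.4g outside [%g, %g]", cf$factor[out],
            BIO_FACTOR_RANGE[1], BIO_FACTOR_RANGE[2]))
  m$counts <- sweep(m$counts, 2, cf$factor, `*`)
  m$norm <- rep
  m <- advance_stage(m, "bio_normalized")
  m <- subset_samples(m, m$samples$sample_id[!out])
  m$norm <- rep
  list(matrix = m, report = rep)
}

#' Full normalization pipeline with QC exclusion
#'
#' Runs [subtract_background], [technical_normalize] and
#' [biological_normalize] in order. Technical exclusion is decided before
#' biological factors are computed, and both exclusions are irrevocable.
#'
#' @inheritParams subtract_background
#' @inheritParams technical_normalize
#' @return list with `matrix` (retained lanes at stage `"bio_normalized"`)
#'   and `report`: one row per input lane with `sample_id`, `background`,
#'   `pos_factor`, `bio_factor`, `status` (`retained`,
#'   `excluded_technical`, `excluded_biological`) and `reason`.
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n_class_a = 8, n_class_b = 6,
#'                                   n_degraded_a = 1, n_degraded_b = 0,
#'                                   seed = 1))
#' nm <- normalize_ncounter(sim$matrix)
#' table(nm$report$status)
normalize_ncounter <- function(m, estimator = c("mean", "mean2sd", "max"),
                               pseudocount = 0.5) {
  m <- subtract_background(m, estimator = estimator)
  tech <- technical_normalize(m, pseudocount = pseudocount)
  bio <- biological_normalize(tech$matrix, pseudocount = pseudocount)
  bio
}

#' Write a normalization report as TSV
#'
#' @param report the `report` element of [normalize_ncounter]'s result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_norm_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
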