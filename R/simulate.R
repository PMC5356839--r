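# nCounter-like two-class cohort simulator. Endogenous and housekeeping
# probes are negative-binomial (panel counts are overdispersed relative to
# Poisson); positive controls follow the conventional 6-point geometric
# spike-in ladder with Poisson noise; negative controls are low-mean
# Poisson background. Lane-to-lane scale variation is log-normal, and
# "degraded" lanes (poor-quality archival RNA) have every probe except the
# post-extraction positive spike-ins collapsed by a common factor.

#' Simulation configuration
#'
#' Defaults state the emulated study design: 36 class-A (MPM) and 17
#' class-B (MH) lanes of a 117-gene panel, 66 differentially expressed
#' genes (35 up, 31 down in MPM) with |log2 fold change| drawn uniformly
#' from `[1, 2.5]`, and 13 degraded lanes (11 MPM, 2 MH) that fail
#' biological QC.
#'
#' @param n_class_a,n_class_b lanes per class (A = MPM-like, B = MH-like).
#' @param n_genes endogenous genes; 117 uses the packaged panel's gene
#'   names, other values use synthetic names.
#' @param n_de planted differentially expressed genes.
#' @param n_up number of planted genes up in class A; the rest are down
#'   (default splits `n_de` in the 35:31 proportion).
#' @param log2fc_range range of |log2 fold change| for planted genes.
#' @param dispersion negative-binomial size parameter (larger = less
#'   overdispersed).
#' @param lane_scale_sd SD of the log-normal lane scale factors (log scale).
#' @param background_mean Poisson mean of the negative controls.
#' @param hk_mean baseline housekeeping count level.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   per-gene endogenous baselines.
#' @param pos_ladder spike-in positive-control ladder (fmol-equivalents).
#' @param pos_scale counts per ladder unit.
#' @param n_degraded_a,n_degraded_b degraded lanes per class.
#' @param degraded_factor signal collapse factor of degraded lanes.
#' @param correlated_blocks optional list of integer vectors (gene indices)
#'   given shared intra-block variation, exercising the correlation filter;
#'   planted DE genes falling in one block share a direction (a block
#'   models a co-regulated module).
#' @param block_sdlog SD (log scale) of the shared block factor.
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_class_a = 36, n_class_b = 17, n_genes = 117,
                       n_de = 66, n_up = NULL, log2fc_range = c(1, 2.5),
                       dispersion = 10, lane_scale_sd = 0.2,
                       background_mean = 4, hk_mean = 2000,
                       baseline_meanlog = log(400), baseline_sdlog = 1,
                       pos_ladder = c(128, 32, 8, 2, 0.5, 0.125),
                       pos_scale = 230,
                       n_degraded_a = 11, n_degraded_b = 2,
                       degraded_factor = 1 / 20,
                       correlated_blocks = NULL, block_sdlog = 0.8,
                       seed = NULL) {
  cfg <- as.list(environment())
  if (is.null(cfg$n_up)) cfg$n_up <- round(n_de * 35 / 66)
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(n_class_a >= 0 && n_class_b >= 0, "negative class size")
  chk(n_genes >= 1, "n_genes must be >= 1")
  chk(n_de >= 0 && n_de <= n_genes, "n_de must be in [0, n_genes]")
  chk(cfg$n_up >= 0 && cfg$n_up <= n_de, "n_up must be in [0, n_de]")
  chk(all(log2fc_range >= 0) && length(log2fc_range) == 2,
      "log2fc_range must be two nonnegative values")
  chk(dispersion > 0, "dispersion must be > 0")
  chk(lane_scale_sd >= 0, "lane_scale_sd must be >= 0")
  chk(background_mean > 0 && hk_mean > 0 && pos_scale > 0,
      "all means must be > 0")
  chk(length(pos_ladder) == 6 && all(pos_ladder > 0),
      "pos_ladder must be 6 positive values")
  chk(n_degraded_a <= n_class_a && n_degraded_b <= n_class_b,
      "more degraded lanes than lanes")
  chk(degraded_factor > 0 && degraded_factor <= 1,
      "degraded_factor must be in (0, 1]")
  if (!is.null(correlated_blocks)) {
    chk(all(unlist(correlated_blocks) %in% seq_len(n_genes)),
        "correlated_blocks indices out of range")
  }
  if (length(problems)) {
    stop("invalid simulation config: ", paste(problems, collapse = "; "),
         call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

sim_codeset <- function(cfg) {
  if (cfg$n_genes == 117) {
    cs <- default_codeset()
  } else {
    endo <- sprintf("G%04d", seq_len(cfg$n_genes))
    hk <- c("CLTC", "GAPDH", "GUSB", "HPRT1", "PGK1", "TUBB")
    pos <- sprintf("POS_%s(%s)", LETTERS[1:6],
                   format(cfg$pos_ladder, trim = TRUE, scientific = FALSE))
    neg <- sprintf("NEG_%s(0)", LETTERS[1:8])
    cs <- codeset(c(endo, hk, pos, neg),
                  rep(c("Endogenous", "Housekeeping", "Positive", "Negative"),
                      c(cfg$n_genes, 6, 6, 8)),
                  codeset_name = sprintf("synthetic_%d", cfg$n_genes))
  }
  cs
}

# housekeeping genes get fixed, distinct baseline levels (stable by design)
HK_LEVELS <- c(0.5, 0.8, 1, 1.2, 2, 3)

#' Simulate an nCounter-like two-class cohort
#'
#' Draws a raw-count cohort under the configured generative model and
#' returns it alongside the sealed ground truth (planted effects, degraded
#' lanes, lane scales) for oracle-based testing.
#'
#' @param cfg a [sim_config].
#' @return list with `matrix` (a raw [count_matrix]) and `truth`: a list
#'   with `de_genes` (gene, direction, log2fc), `degraded_sample_ids`,
#'   `labels`, `lane_scale`, and `baseline`.
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n_class_a = 6, n_class_b = 4,
#'                                   n_degraded_a = 0, n_degraded_b = 0,
#'                                   seed = 7))
#' sim$matrix
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  cs <- sim_codeset(cfg)
  endo <- probes_of_class(cs, "Endogenous")
  n_a <- cfg$n_class_a; n_b <- cfg$n_class_b; n <- n_a + n_b
  ids <- c(sprintf("ME_%02d", seq_len(n_a)), sprintf("IP_%02d", seq_len(n_b)))
  labels <- rep(c("MPM", "MH"), c(n_a, n_b))
  # ages drawn to mirror the cohorts' reported ranges (MPM older than MH)
  ages <- round(c(stats::runif(n_a, 43, 85), stats::runif(n_b, 18, 85)))

  baseline <- stats::setNames(
    stats::rlnorm(cfg$n_genes, cfg$baseline_meanlog, cfg$baseline_sdlog),
    endo)
  de_idx <- if (cfg$n_de > 0) sort(sample.int(cfg$n_genes, cfg$n_de))
            else integer(0)
  dir_up <- rep(FALSE, cfg$n_genes)
  if (cfg$n_de > 0) {
    dir_up[sample(de_idx, cfg$n_up)] <- TRUE
  }
  lfc <- numeric(cfg$n_genes)
  lfc[de_idx] <- stats::runif(cfg$n_de, cfg$log2fc_range[1],
                              cfg$log2fc_range[2]) *
    ifelse(dir_up[de_idx], 1, -1)
  # a correlated block models a co-regulated module: DE members share one
  # direction, otherwise opposing class effects cancel the planted
  # intra-block correlation
  if (!is.null(cfg$correlated_blocks)) {
    for (block in cfg$correlated_blocks) {
      de_in <- intersect(block, de_idx)
      if (length(de_in) > 1) {
        dir_up[de_in] <- dir_up[de_in[1]]
        lfc[de_in] <- abs(lfc[de_in]) * if (dir_up[de_in[1]]) 1 else -1
      }
    }
  }

  lane_scale <- stats::rlnorm(n, 0, cfg$lane_scale_sd)
  degraded <- c(utils::head(seq_len(n_a), cfg$n_degraded_a),
                n_a + utils::head(seq_len(n_b), cfg$n_degraded_b))
  collapse <- ifelse(seq_len(n) %in% degraded, cfg$degraded_factor, 1)

  # per-sample endogenous means: baseline x class effect x lane x collapse
  mu <- outer(baseline, lane_scale * collapse)
  mu[, labels == "MPM"] <- mu[, labels == "MPM"] * 2^lfc
  if (!is.null(cfg$correlated_blocks)) {
    for (block in cfg$correlated_blocks) {
      shared <- stats::rlnorm(n, 0, cfg$block_sdlog)
      mu[block, ] <- sweep(mu[block, , drop = FALSE], 2, shared, `*`)
    }
  }
  endo_counts <- matrix(
    stats::rnbinom(length(mu), mu = mu, size = cfg$dispersion),
    nrow = nrow(mu))
  hk_mu <- outer(cfg$hk_mean * HK_LEVELS, lane_scale * collapse)
  hk_counts <- matrix(
    stats::rnbinom(length(hk_mu), mu = hk_mu, size = cfg$dispersion),
    nrow = 6)
  pos_mu <- outer(cfg$pos_ladder * cfg$pos_scale, lane_scale)
  pos_counts <- matrix(stats::rpois(length(pos_mu), pos_mu), nrow = 6)
  neg_counts <- matrix(
    stats::rpois(8 * n, cfg$background_mean * rep(collapse, each = 8)),
    nrow = 8)

  counts <- rbind(endo_counts, hk_counts, pos_counts, neg_counts)
  samples <- data.frame(sample_id = ids, label = labels, age = ages,
                        batch_id = "sim", stringsAsFactors = FALSE)
  m <- count_matrix(counts, cs, samples, stage = "raw")
  truth <- list(
    de_genes = data.frame(
      gene = endo[de_idx],
      direction = ifelse(dir_up[de_idx], "up_in_MPM", "down_in_MPM"),
      log2fc = lfc[de_idx], stringsAsFactors = FALSE),
    degraded_sample_ids = ids[degraded],
    labels = stats::setNames(labels, ids),
    lane_scale = stats::setNames(lane_scale, ids),
    baseline = baseline,
    config = cfg)
  list(matrix = m, truth = truth)
}

#' Simulate an unlabeled blind test set
#'
#' Draws samples from the same generative model as [simulate_cohort] but
#' blinds the labels in the sample metadata; the truth is sealed in the
#' returned `truth` for post-hoc scoring.
#'
#' @param cfg a [sim_config] describing the generative model (its class
#'   sizes and degraded-lane counts are overridden).
#' @param n_a,n_b blind samples drawn from class A (MPM-like) and B.
#' @param truth optional truth of a previously simulated training cohort;
#'   if supplied, its planted effects and baselines are reused so that the
#'   blind samples come from the identical population.
#' @param seed overrides `cfg$seed` for the blind draw.
#' @return as [simulate_cohort], with labels `UNKNOWN` in the matrix and
#'   the real labels in `truth$labels`.
#' @export
make_blind_set <- function(cfg, n_a = 9, n_b = 5, truth = NULL,
                           seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  cfg2 <- unclass(cfg)
  cfg2$n_class_a <- n_a
  cfg2$n_class_b <- n_b
  cfg2$n_degraded_a <- 0
  cfg2$n_degraded_b <- 0
  if (!is.null(seed)) cfg2$seed <- seed
  cfg2 <- do.call(sim_config, cfg2)
  if (n_a + n_b == 0) {
    cs <- sim_codeset(cfg2)
    m <- count_matrix(matrix(0, nrow(cs), 0), cs,
                      data.frame(sample_id = character(0),
                                 label = character(0)))
    return(list(matrix = m, truth = list(
      labels = character(0), de_genes = NULL, config = cfg2)))
  }
  if (!is.null(cfg2$seed)) set.seed(cfg2$seed)
  if (is.null(truth)) {
    sim <- simulate_cohort(cfg2)
  } else {
    # redraw counts only, from the sealed population of the training truth
    sim <- resample_from_truth(cfg2, truth, n_a, n_b)
  }
  real <- sim$truth$labels
  sim$matrix$samples$label <- "UNKNOWN"
  sim$matrix$samples$sample_id <- sprintf("BLIND_%02d",
                                          seq_len(n_a + n_b))
  colnames(sim$matrix$counts) <- sim$matrix$samples$sample_id
  names(real) <- sim$matrix$samples$sample_id
  sim$truth$labels <- real
  names(sim$truth$lane_scale) <- sim$matrix$samples$sample_id
  list(matrix = sim$matrix, truth = sim$truth)
}

# draw new lanes from an existing truth (same baselines and planted
# effects); used so blind sets match the training population exactly
resample_from_truth <- function(cfg, truth, n_a, n_b) {
  cs <- sim_codeset(cfg)
  endo <- probes_of_class(cs, "Endogenous")
  n <- n_a + n_b
  ids <- c(sprintf("ME_%02d", seq_len(n_a)), sprintf("IP_%02d", seq_len(n_b)))
  labels <- rep(c("MPM", "MH"), c(n_a, n_b))
  ages <- round(c(stats::runif(n_a, 41, 80), stats::runif(n_b, 27, 79)))
  baseline <- truth$baseline[endo]
  lfc <- stats::setNames(numeric(length(endo)), endo)
  lfc[truth$de_genes$gene] <- truth$de_genes$log2fc
  lane_scale <- stats::rlnorm(n, 0, cfg$lane_scale_sd)
  mu <- outer(baseline, lane_scale)
  mu[, labels == "MPM"] <- mu[, labels == "MPM"] * 2^lfc
  endo_counts <- matrix(
    stats::rnbinom(length(mu), mu = mu, size = cfg$dispersion),
    nrow = nrow(mu))
  hk_mu <- outer(cfg$hk_mean * HK_LEVELS, lane_scale)
  hk_counts <- matrix(
    stats::rnbinom(length(hk_mu), mu = hk_mu, size = cfg$dispersion),
    nrow = 6)
  pos_mu <- outer(cfg$pos_ladder * cfg$pos_scale, lane_scale)
  pos_counts <- matrix(stats::rpois(length(pos_mu), pos_mu), nrow = 6)
  neg_counts <- matrix(stats::rpois(8 * n, cfg$background_mean), nrow = 8)
  counts <- rbind(endo_counts, hk_counts, pos_counts, neg_counts)
  samples <- data.frame(sample_id = ids, label = labels, age = ages,
                        batch_id = "sim_blind", stringsAsFactors = FALSE)
  m <- count_matrix(counts, cs, samples, stage = "raw")
  truth_out <- truth
  truth_out$degraded_sample_ids <- character(0)
  truth_out$labels <- stats::setNames(labels, ids)
  truth_out$lane_scale <- stats::setNames(lane_scale, ids)
  truth_out$config <- cfg
  list(matrix = m, truth = truth_out)
}

#' Write a simulated cohort as RCC lane files
#'
#' One instrument-style RCC file per lane, plus a `labels.tsv` and a sealed
#' `truth.json`.
#'
#' @param sim result of [simulate_cohort] or [make_blind_set].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_rcc <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- sim$matrix
  for (j in seq_len(ncol(m$counts))) {
    meta <- m$samples[j, , drop = FALSE]
    counts <- data.frame(code_class = m$codeset$code_class,
                         name = m$codeset$name,
                         accession = m$codeset$accession,
                         count = m$counts[, j], stringsAsFactors = FALSE)
    write_rcc(meta, counts,
              file.path(dir, paste0(meta$sample_id, ".RCC")))
  }
  utils::write.table(m$samples, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
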