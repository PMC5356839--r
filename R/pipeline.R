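# End-to-end orchestration: simulate (or read) -> normalize -> differential
# expression -> clustering -> USC training -> blind prediction, with every
# stage's output written to a run directory, plus consistency checks of the
# packaged reference tables.

#' Load the packaged reference classifier descriptions
#'
#' The two published USC classifiers for the panel: hyperparameters
#' (Delta 1 / 0.5, rho 0.7), LOOCV mistake counts, fold-average gene
#' counts, and the 22- and 40-gene predictive lists.
#'
#' @return list with `params` (data frame) and `genes` (named list of
#'   canonicalized gene vectors).
#' @export
reference_classifiers <- function() {
  pdir <- system.file("extdata", package = "mesoUSC")
  params <- utils::read.delim(file.path(pdir, "reference_classifier_params.tsv"),
                              stringsAsFactors = FALSE)
  genes <- utils::read.delim(file.path(pdir, "reference_classifier_genes.tsv"),
                             stringsAsFactors = FALSE)
  genes$gene <- canonical_symbol(genes$gene)
  list(params = params, genes = split(genes$gene, genes$model))
}

#' Load the packaged reference blind-set predictions
#'
#' The published blind-test outcome for the panel: 14 pleural samples with
#' the molecular class and discriminant score from each classifier and the
#' final histological class (9 MPM, 5 MH; all concordant).
#'
#' @return data frame, one row per blind sample.
#' @export
reference_blind_predictions <- function() {
  path <- system.file("extdata", "reference_blind_predictions.tsv",
                      package = "mesoUSC", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Verify the packaged reference tables against the implementation
#'
#' Four checks tie the packaged fixtures to the statistics code:
#' (a) every reference Z/p pair is reproduced by [z_to_p] within `5e-6`
#' absolute (the printed Z is rounded to 5 decimals);
#' (b) significance counts at `p < 0.05` are 35 up / 31 down and at
#' `p < 0.005` are 25 up / 18 down;
#' (c) 66 genes in total reach `p < 0.05`;
#' (d) the classifier gene lists have 22 and 40 entries.
#'
#' @param de optional replacement for [reference_de_results] (used to test
#'   sensitivity of the checks).
#' @param classifiers optional replacement for [reference_classifiers].
#' @return data frame with one row per check: `check`, `pass`, `detail`.
#' @export
verify_reference <- function(de = reference_de_results(),
                             classifiers = reference_classifiers()) {
  checks <- list()
  dev <- abs(z_to_p(de$z) - de$p)
  bad <- which(dev > 5e-6)
  checks[["z_to_p"]] <- list(
    pass = length(bad) == 0,
    detail = if (length(bad)) {
      paste0("mismatch at ", paste(de$gene[bad], collapse = ", "),
             " (max dev ", format(max(dev), digits = 3), ")")
    } else sprintf("all %d rows within 5e-6 (max dev %s)", nrow(de),
                   format(max(dev), digits = 3)))
  c05 <- count_significant(de, 0.05)
  c005 <- count_significant(de, 0.005)
  checks[["counts_0.05"]] <- list(
    pass = all(c05 == c(35, 31)),
    detail = sprintf("(%d up, %d down) at p<0.05", c05[1], c05[2]))
  checks[["counts_0.005"]] <- list(
    pass = all(c005 == c(25, 18)),
    detail = sprintf("(%d up, %d down) at p<0.005", c005[1], c005[2]))
  checks[["total_0.05"]] <- list(
    pass = sum(c05) == 66,
    detail = sprintf("%d genes at p<0.05", sum(c05)))
  len <- lengths(classifiers$genes)
  checks[["classifier_sizes"]] <- list(
    pass = identical(sort(as.integer(len)), c(22L, 40L)),
    detail = paste(len, collapse = ", "))
  data.frame(check = names(checks),
             pass = vapply(checks, `[[`, TRUE, "pass"),
             detail = vapply(checks, `[[`, "", "detail"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Run the full pipeline on a simulated or on-disk cohort
#'
#' Executes simulate/read, normalization with QC, differential expression,
#' two-way clustering, USC training with LOOCV grid search, and (optionally)
#' blind-set prediction, writing per-stage TSV/JSON outputs under
#' `out_dir`.
#'
#' @param sim_cfg a [sim_config] for a simulated run, or `NULL` when
#'   reading RCC files from `input_dir`.
#' @param input_dir directory of RCC lane files (used when `sim_cfg` is
#'   `NULL`).
#' @param out_dir output directory; created if needed. `NULL` writes
#'   nothing.
#' @param blind_n_a,blind_n_b size of the simulated blind set (0/0 skips
#'   the test phase; ignored for on-disk input).
#' @param blind_seed seed of the blind draw (defaults to `sim_cfg$seed + 1`).
#' @param alphas significance thresholds reported from the DE stage.
#' @param grid_rho,grid_delta USC hyperparameter grid.
#' @param ... further arguments to [usc_train].
#' @return list with `normalized`, `report`, `de`, `de_counts`,
#'   `sample_tree`, `gene_tree`, `cut`, `usc` (model + report),
#'   `blind_predictions`, `blind_truth`, `summary`.
#' @export
run_pipeline <- function(sim_cfg = NULL, input_dir = NULL, out_dir = NULL,
                         blind_n_a = 9, blind_n_b = 5, blind_seed = NULL,
                         alphas = c(0.05, 0.005),
                         grid_rho = seq(0.5, 1, by = 0.1),
                         grid_delta = seq(0, 2, by = 0.25), ...) {
  if (is.null(sim_cfg) && is.null(input_dir)) {
    stop("provide either sim_cfg or input_dir", call. = FALSE)
  }
  truth <- NULL
  if (!is.null(sim_cfg)) {
    sim <- simulate_cohort(sim_cfg)
    raw <- sim$matrix
    truth <- sim$truth
  } else {
    raw <- read_rcc_dir(input_dir)
  }
  norm <- normalize_ncounter(raw)
  m <- norm$matrix
  de <- run_diffexp(m)
  de_counts <- lapply(stats::setNames(alphas, paste0("alpha_", alphas)),
                      function(a) count_significant(de, a))
  sample_tree <- hca(m, "samples")
  gene_tree <- hca(m, "genes")
  cut <- cut_two(m, tree = sample_tree)
  usc <- usc_train(m, grid_rho = grid_rho, grid_delta = grid_delta, ...)

  blind_pred <- NULL; blind_truth <- NULL
  if (!is.null(sim_cfg) && blind_n_a + blind_n_b > 0) {
    if (is.null(blind_seed) && !is.null(sim_cfg$seed)) {
      blind_seed <- sim_cfg$seed + 1L
    }
    blind <- make_blind_set(sim_cfg, blind_n_a, blind_n_b, truth = truth,
                            seed = blind_seed)
    bn <- normalize_ncounter(blind$matrix)
    blind_pred <- usc_predict(usc$model, bn$matrix)
    blind_truth <- blind$truth$labels[bn$matrix$samples$sample_id]
  }
  summary <- list(
    n_input = ncol(raw$counts), n_retained = ncol(m$counts),
    excluded = norm$report$sample_id[norm$report$status != "retained"],
    de_counts = de_counts,
    usc_best = usc$report$best, usc_mistakes = usc$report$mistakes,
    n_predictive_genes = length(usc$report$predictive_genes),
    blind_correct = if (!is.null(blind_pred))
      sum(blind_pred$molecular_class == blind_truth) else NA_integer_,
    seed = if (!is.null(sim_cfg)) sim_cfg$seed else NA_integer_,
    package_version = as.character(utils::packageVersion("mesoUSC")))
  res <- list(normalized = m, report = norm$report, de = de,
              de_counts = de_counts, sample_tree = sample_tree,
              gene_tree = gene_tree, cut = cut, usc = usc,
              blind_predictions = blind_pred, blind_truth = blind_truth,
              summary = summary)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_norm_report(res$report, file.path(out_dir, "normalization_report.tsv"))
  utils::write.table(res$de, file.path(out_dir, "de_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tree_to_newick(res$sample_tree, file.path(out_dir, "sample_tree.nwk"))
  tree_to_newick(res$gene_tree, file.path(out_dir, "gene_tree.nwk"))
  cut_df <- data.frame(sample_id = names(res$cut$assignments),
                       cluster = res$cut$assignments, row.names = NULL)
  utils::write.table(cut_df, file.path(out_dir, "sample_clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  usc_model_to_json(res$usc$model, file.path(out_dir, "usc_model.json"))
  utils::write.table(res$usc$report$grid, file.path(out_dir, "usc_grid.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$blind_predictions)) {
    utils::write.table(res$blind_predictions,
                       file.path(out_dir, "blind_predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(res$summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}
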