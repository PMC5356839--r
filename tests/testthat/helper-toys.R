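# Small in-code fixtures shared across test files.

# a miniature codeset: configurable endogenous genes plus 2 HK, 2 POS, 3 NEG
toy_codeset <- function(n_endo = 4) {
  codeset(
    name = c(sprintf("GENE%02d", seq_len(n_endo)), "HK1", "HK2",
             "POS_A", "POS_B", "NEG_A", "NEG_B", "NEG_C"),
    code_class = rep(c("Endogenous", "Housekeeping", "Positive", "Negative"),
                     c(n_endo, 2, 2, 3)),
    codeset_name = "toy")
}

# a count matrix over toy_codeset with given endogenous counts; controls
# default to flat values so normalization factors are exactly 1
toy_matrix <- function(endo, hk = NULL, pos = NULL, neg = NULL,
                       labels = NULL, stage = "raw") {
  n <- ncol(endo)
  if (is.null(hk)) hk <- matrix(100, 2, n)
  if (is.null(pos)) pos <- matrix(200, 2, n)
  if (is.null(neg)) neg <- matrix(0, 3, n)
  if (is.null(labels)) labels <- rep(c("MPM", "MH"), length.out = n)
  cs <- toy_codeset(nrow(endo))
  counts <- rbind(endo, hk, pos, neg)
  samples <- data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                        label = labels, stringsAsFactors = FALSE)
  count_matrix(counts, cs, samples, stage = stage)
}

# skip all normalization bookkeeping: stamp a matrix as bio_normalized
as_normalized <- function(m) {
  m$stage <- "bio_normalized"
  m
}

# a lane in read_rcc() shape built from a codeset and a count vector
toy_lane <- function(cs, counts, sample_id = "L1", label = "UNKNOWN",
                     age = NA_real_) {
  list(meta = data.frame(sample_id = sample_id, label = label, age = age,
                         batch_id = NA_character_, stringsAsFactors = FALSE),
       counts = data.frame(code_class = cs$code_class, name = cs$name,
                           accession = cs$accession, count = counts,
                           stringsAsFactors = FALSE))
}

# standard small simulated cohort for classifier tests (well separated)
toy_cohort <- function(seed = 7, n_a = 12, n_b = 8, n_genes = 30,
                       n_de = 12, ...) {
  cfg <- sim_config(n_class_a = n_a, n_class_b = n_b, n_genes = n_genes,
                    n_de = n_de, n_degraded_a = 0, n_degraded_b = 0,
                    seed = seed, ...)
  simulate_cohort(cfg)
}
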