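STAGES <- c("raw", "background_subtracted", "tech_normalized", "bio_normalized")

#' Construct a probes-by-samples count matrix
#'
#' The central container of the workflow: a numeric matrix of probe counts
#' (rows follow the codeset order, columns the samples) together with the
#' codeset, per-sample metadata, and the processing stage. Counts are raw
#' nonnegative integers off the instrument and become reals after
#' normalization.
#'
#' @param counts numeric matrix, probes x samples, entries >= 0.
#' @param cs a [codeset]; `nrow(counts)` must equal `nrow(cs)`.
#' @param samples data frame with columns `sample_id` (unique), `label`
#'   (one of `"MPM"`, `"MH"`, `"UNKNOWN"`), optional `age`, `batch_id`.
#' @param stage one of `"raw"`, `"background_subtracted"`,
#'   `"tech_normalized"`, `"bio_normalized"`.
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, cs, samples, stage = "raw") {
  stopifnot(inherits(cs, "codeset"), is.matrix(counts))
  stage <- match.arg(stage, STAGES)
  if (nrow(counts) != nrow(cs)) {
    stop("counts has ", nrow(counts), " rows but codeset has ", nrow(cs),
         " probes", call. = FALSE)
  }
  if (!is.data.frame(samples) || !all(c("sample_id", "label") %in% names(samples))) {
    stop("samples must be a data frame with sample_id and label", call. = FALSE)
  }
  if (ncol(counts) != nrow(samples)) {
    stop("counts has ", ncol(counts), " columns but ", nrow(samples),
         " samples described", call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id", call. = FALSE)
  }
  bad <- setdiff(unique(samples$label), c("MPM", "MH", "UNKNOWN"))
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and nonnegative", call. = FALSE)
  }
  if (!"age" %in% names(samples)) {
    samples$age <- rep(NA_real_, nrow(samples))
  }
  if (!"batch_id" %in% names(samples)) {
    samples$batch_id <- rep(NA_character_, nrow(samples))
  }
  dimnames(counts) <- list(cs$name, samples$sample_id)
  structure(list(counts = counts, codeset = cs, samples = samples,
                 stage = stage, norm = NULL),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix: %d probes x %d samples, stage=%s>\n",
              nrow(x$counts), ncol(x$counts), x$stage))
  lab <- table(x$samples$label)
  cat("  labels:", paste(sprintf("%s=%d", names(lab), lab), collapse = " "), "\n")
  invisible(x)
}

# internal: advance the stage, enforcing forward-only transitions
advance_stage <- function(m, to) {
  from_i <- match(m$stage, STAGES)
  to_i <- match(to, STAGES)
  if (is.na(to_i) || to_i != from_i + 1L) {
    stop("invalid stage transition ", m$stage, " -> ", to, call. = FALSE)
  }
  m$stage <- to
  m
}

require_stage <- function(m, stage) {
  if (!identical(m$stage, stage)) {
    stop("expected a count_matrix at stage '", stage, "', got '", m$stage,
         "'", call. = FALSE)
  }
  invisible(m)
}

#' Subset a count matrix to chosen samples
#'
#' @param m a [count_matrix].
#' @param sample_ids character vector of sample ids to keep (order kept).
#' @return a [count_matrix] at the same stage.
#' @export
subset_samples <- function(m, sample_ids) {
  stopifnot(inherits(m, "count_matrix"))
  missing <- setdiff(sample_ids, m$samples$sample_id)
  if (length(missing)) {
    stop("unknown sample id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  keep <- match(sample_ids, m$samples$sample_id)
  m$counts <- m$counts[, keep, drop = FALSE]
  m$samples <- m$samples[keep, , drop = FALSE]
  rownames(m$samples) <- NULL
  if (!is.null(m$norm)) m$norm <- m$norm[m$norm$sample_id %in% sample_ids, ]
  m
}

#' Extract counts for one code class
#'
#' @param m a [count_matrix].
#' @param class one of the four code classes.
#' @return numeric matrix (probes of that class x samples).
#' @export
class_counts <- function(m, class = c("Endogenous", "Housekeeping",
                                      "Positive", "Negative")) {
  class <- match.arg(class)
  m$counts[m$codeset$code_class == class, , drop = FALSE]
}

#' Read / write a count matrix as TSV
#'
#' Layout: probes as rows; first two columns `CodeClass` and `Name`,
#' remaining columns one per sample. Sample labels/ages are not part of this
#' format and must be supplied separately on read.
#'
#' @param path file path.
#' @param samples optional data frame (`sample_id`, `label`, `age`); defaults
#'   to all-`UNKNOWN` metadata derived from the column names.
#' @param stage stage of the stored counts.
#' @return `read_count_tsv` returns a [count_matrix]; `write_count_tsv`
#'   returns `path` invisibly.
#' @export
read_count_tsv <- function(path, samples = NULL, stage = "raw") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("CodeClass", "Name") %in% names(df))) {
    stop("count TSV lacks CodeClass/Name columns: ", path, call. = FALSE)
  }
  cs <- codeset(ifelse(df$CodeClass == "Endogenous",
                       canonical_symbol(df$Name), df$Name),
                df$CodeClass, codeset_name = basename(path))
  cnt <- as.matrix(df[, setdiff(names(df), c("CodeClass", "Name", "Accession")),
                      drop = FALSE])
  storage.mode(cnt) <- "double"
  if (is.null(samples)) {
    samples <- data.frame(sample_id = colnames(cnt), label = "UNKNOWN",
                          stringsAsFactors = FALSE)
  }
  count_matrix(cnt, cs, samples, stage = stage)
}

#' @rdname read_count_tsv
#' @param m a [count_matrix].
#' @export
write_count_tsv <- function(m, path) {
  stopifnot(inherits(m, "count_matrix"))
  out <- data.frame(CodeClass = m$codeset$code_class, Name = m$codeset$name,
                    m$counts, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
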