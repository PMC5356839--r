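CODE_CLASSES <- c("Endogenous", "Housekeeping", "Positive", "Negative")

# Symbol variants seen across the panel's source tables. The custom panel
# predates current HGNC usage and its tables mix spellings; all user-facing
# joins go through canonical_symbol() so the variants are harmless.
GENE_SYNONYMS <- c(
  MK167 = "MKI67",
  PKM2  = "PKM",
  DNMT3 = "DNMT3A",
  DNTM1 = "DNMT1",
  TGFR2 = "TGFBR2",
  Gli1  = "GLI1",
  Gli2  = "GLI2",
  LAMP1 = "LAMC1"
)

#' Canonicalize gene symbols of the mesothelioma panel
#'
#' Maps known spelling variants of the 117-gene panel (e.g. `Gli2`, `PKM2`,
#' `MK167`) to their canonical HGNC symbols. Symbols without a known variant
#' are returned unchanged.
#'
#' @param x character vector of gene symbols.
#' @return character vector of the same length with canonical symbols.
#' @export
#' @examples
#' canonical_symbol(c("Gli2", "PKM2", "BAP1"))
canonical_symbol <- function(x) {
  stopifnot(is.character(x))
  hit <- x %in% names(GENE_SYNONYMS)
  x[hit] <- unname(GENE_SYNONYMS[x[hit]])
  x
}

#' Construct a probe codeset
#'
#' A codeset is the fixed probe content of an nCounter assay: endogenous
#' targets, housekeeping references, and spike-in positive/negative controls.
#'
#' @param name,code_class,accession parallel character vectors describing one
#'   probe per element; `code_class` must be one of `"Endogenous"`,
#'   `"Housekeeping"`, `"Positive"`, `"Negative"`.
#' @param codeset_name free-text label for the codeset.
#' @return an object of class `codeset`: a data frame with columns
#'   `name`, `code_class`, `accession` and attribute `codeset_name`.
#' @export
codeset <- function(name, code_class, accession = NA_character_,
                    codeset_name = "custom") {
  stopifnot(is.character(name), length(name) > 0)
  if (any(!nzchar(name)) || anyNA(name)) {
    stop("probe names must be nonempty", call. = FALSE)
  }
  if (anyDuplicated(name)) {
    stop("duplicate probe names in codeset: ",
         paste(unique(name[duplicated(name)]), collapse = ", "), call. = FALSE)
  }
  code_class <- as.character(code_class)
  bad <- setdiff(unique(code_class), CODE_CLASSES)
  if (length(bad)) {
    stop("unknown code class(es): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  cs <- data.frame(name = name,
                   code_class = code_class,
                   accession = rep_len(as.character(accession), length(name)),
                   stringsAsFactors = FALSE)
  attr(cs, "codeset_name") <- codeset_name
  class(cs) <- c("codeset", "data.frame")
  cs
}

#' The packaged 117-gene mesothelioma differential-diagnosis panel
#'
#' Returns the packaged codeset used throughout: 117 endogenous targets
#' deregulated in epithelioid malignant pleural mesothelioma, 6 housekeeping
#' references (CLTC, GAPDH, GUSB, HPRT1, PGK1, TUBB), 6 spike-in positive
#' controls and 8 spike-in negative controls (137 probes in total).
#'
#' @return a [codeset].
#' @export
#' @examples
#' cs <- default_codeset()
#' table(cs$code_class)
default_codeset <- function() {
  path <- system.file("extdata", "codeset_mpm_panel.tsv", package = "mesoUSC",
                      mustWork = TRUE)
  read_codeset(path, codeset_name = "mpm_mh_117")
}

#' Read / write a codeset as TSV
#'
#' The TSV has columns `CodeClass`, `Name`, `Accession` (vendor column
#' order); gene names are canonicalized on read.
#'
#' @param path file path.
#' @param codeset_name label attached to the returned codeset.
#' @return `read_codeset` returns a [codeset]; `write_codeset` returns
#'   `path` invisibly.
#' @export
read_codeset <- function(path, codeset_name = basename(path)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("CodeClass", "Name")
  if (!all(need %in% names(df))) {
    stop("codeset file lacks required columns CodeClass/Name: ", path,
         call. = FALSE)
  }
  nm <- ifelse(df$CodeClass == "Endogenous",
               canonical_symbol(df$Name), df$Name)
  acc <- if ("Accession" %in% names(df)) df$Accession else NA_character_
  codeset(nm, df$CodeClass, acc, codeset_name = codeset_name)
}

#' @rdname read_codeset
#' @param cs a [codeset].
#' @export
write_codeset <- function(cs, path) {
  stopifnot(inherits(cs, "codeset"))
  out <- data.frame(CodeClass = cs$code_class, Name = cs$name,
                    Accession = cs$accession)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.codeset <- function(x, ...) {
  cat(sprintf("<codeset '%s': %d probes (%s)>\n",
              attr(x, "codeset_name"), nrow(x),
              paste(sprintf("%d %s", table(factor(x$code_class, CODE_CLASSES)),
                            CODE_CLASSES), collapse = ", ")))
  invisible(x)
}

probes_of_class <- function(cs, class) {
  cs$name[cs$code_class == class]
}
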