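# RCC: the per-lane count file emitted by the nCounter digital analyzer.
# Sectioned comma-separated text, sections delimited by <Tag>...</Tag>.
# Unknown sections and attributes are tolerated and ignored.

parse_rcc_sections <- function(lines) {
  open <- grep("^<[A-Za-z_]+>\\s*$", lines)
  close <- grep("^</[A-Za-z_]+>\\s*$", lines)
  sections <- list()
  for (i in seq_along(open)) {
    tag <- sub("^<([A-Za-z_]+)>\\s*$", "\\1", lines[open[i]])
    end <- close[close > open[i]]
    if (!length(end)) stop("RCC format error: unterminated section <", tag, ">",
                           call. = FALSE)
    end <- end[1]
    if (sub("^</([A-Za-z_]+)>\\s*$", "\\1", lines[end]) != tag) {
      stop("RCC format error: mismatched section tags near <", tag, ">",
           call. = FALSE)
    }
    body <- lines[setdiff(seq(open[i] + 1L, end - 1L), integer(0))]
    if (open[i] + 1L > end - 1L) body <- character(0)
    sections[[tag]] <- body
  }
  sections
}

kv_pairs <- function(body) {
  body <- body[nzchar(trimws(body))]
  if (!length(body)) return(character(0))
  parts <- strsplit(body, ",", fixed = TRUE)
  stats::setNames(vapply(parts, function(p) {
    if (length(p) >= 2) paste(p[-1], collapse = ",") else ""
  }, ""), vapply(parts, `[`, "", 1))
}

#' Read one nCounter RCC lane file
#'
#' Parses the sectioned comma-separated RCC dialect. The `Code_Summary`
#' section is mandatory; sample label (`ClassLabel`) and `Age` are read from
#' `Sample_Attributes` when present.
#'
#' @param path path to an RCC file.
#' @return list with elements `meta` (data frame: `sample_id`, `label`,
#'   `age`, `batch_id`) and `counts` (data frame: `code_class`, `name`,
#'   `accession`, `count`).
#' @export
read_rcc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("RCC format error: empty file: ", path, call. = FALSE)
  sections <- parse_rcc_sections(lines)
  if (is.null(sections$Code_Summary)) {
    stop("RCC format error: missing Code_Summary section: ", path,
         call. = FALSE)
  }
  cs_lines <- sections$Code_Summary
  cs_lines <- cs_lines[nzchar(trimws(cs_lines))]
  if (length(cs_lines) < 2) {
    stop("RCC format error: empty Code_Summary: ", path, call. = FALSE)
  }
  tab <- utils::read.csv(text = paste(cs_lines, collapse = "\n"),
                         stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  need <- c("CodeClass", "Name", "Count")
  if (!all(need %in% names(tab))) {
    stop("RCC format error: Code_Summary lacks ",
         paste(setdiff(need, names(tab)), collapse = "/"), ": ", path,
         call. = FALSE)
  }
  cnt <- suppressWarnings(as.numeric(tab$Count))
  if (anyNA(cnt)) {
    stop("RCC value error: non-numeric count for probe ",
         tab$Name[which(is.na(cnt))[1]], " in ", path, call. = FALSE)
  }
  if (any(cnt < 0)) {
    stop("RCC value error: negative count for probe ",
         tab$Name[which(cnt < 0)[1]], " in ", path, call. = FALSE)
  }
  nm <- ifelse(tab$CodeClass == "Endogenous", canonical_symbol(tab$Name),
               tab$Name)
  if (anyDuplicated(nm)) {
    stop("RCC format error: duplicate probe name ",
         nm[duplicated(nm)][1], " in ", path, call. = FALSE)
  }
  attrs <- kv_pairs(sections$Sample_Attributes %||% character(0))
  age <- suppressWarnings(as.numeric(attrs["Age"]))
  label <- attrs["ClassLabel"]
  if (is.na(label) || !label %in% c("MPM", "MH")) label <- "UNKNOWN"
  meta <- data.frame(
    sample_id = if (!is.na(attrs["ID"]) && nzchar(attrs["ID"])) attrs["ID"]
                else sub("\\.rcc$", "", basename(path), ignore.case = TRUE),
    label = label,
    age = if (length(age)) age else NA_real_,
    batch_id = if (!is.na(attrs["CartridgeID"])) attrs["CartridgeID"]
               else NA_character_,
    stringsAsFactors = FALSE, row.names = NULL)
  counts <- data.frame(code_class = tab$CodeClass, name = nm,
                       accession = if ("Accession" %in% names(tab))
                         tab$Accession else NA_character_,
                       count = cnt, stringsAsFactors = FALSE)
  list(meta = meta, counts = counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write one nCounter RCC lane file
#'
#' Emits the sectioned dialect that [read_rcc] parses back identically.
#'
#' @param meta data frame row with `sample_id`, `label`, optionally `age`
#'   and `batch_id`.
#' @param counts data frame with `code_class`, `name`, optionally
#'   `accession`, and nonnegative integer `count`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rcc <- function(meta, counts, path) {
  stopifnot(all(c("code_class", "name", "count") %in% names(counts)))
  if (any(counts$count < 0) || any(counts$count != round(counts$count))) {
    stop("RCC counts must be nonnegative integers", call. = FALSE)
  }
  acc <- if ("accession" %in% names(counts)) counts$accession else ""
  acc[is.na(acc)] <- ""
  age <- if ("age" %in% names(meta) && !is.na(meta$age)) meta$age else ""
  batch <- if ("batch_id" %in% names(meta) && !is.na(meta$batch_id))
    meta$batch_id else ""
  lines <- c(
    "<Header>", "FileVersion,1.7", "SoftwareVersion,mesoUSC", "</Header>",
    "<Sample_Attributes>",
    paste0("ID,", meta$sample_id),
    paste0("ClassLabel,", meta$label),
    paste0("Age,", age),
    paste0("CartridgeID,", batch),
    "</Sample_Attributes>",
    "<Lane_Attributes>", "ID,1", "FovCount,280", "FovCounted,280",
    "</Lane_Attributes>",
    "<Code_Summary>",
    "CodeClass,Name,Accession,Count",
    paste(counts$code_class, counts$name, acc,
          format(counts$count, scientific = FALSE, trim = TRUE), sep = ","),
    "</Code_Summary>")
  ok <- try(writeLines(lines, path), silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop("failed to write RCC file: ", path, call. = FALSE)
  }
  invisible(path)
}

#' Compare a lane's probes against an expected codeset
#'
#' @param lane a lane as returned by [read_rcc].
#' @param cs the expected [codeset].
#' @return list with `extra` (probe names present in the lane only) and
#'   `missing` (codeset probes absent from the lane).
#' @export
check_codeset <- function(lane, cs) {
  list(extra = setdiff(lane$counts$name, cs$name),
       missing = setdiff(cs$name, lane$counts$name))
}

#' Assemble lanes into a raw count matrix
#'
#' Columns follow the input lane order; rows follow the codeset order
#' regardless of each lane's probe ordering. Probes present in a lane but
#' not in the codeset are dropped and recorded in the `"mismatch"`
#' attribute of the result.
#'
#' @param lanes list of lanes as returned by [read_rcc].
#' @param cs the [codeset] defining the row universe.
#' @return a [count_matrix] at stage `"raw"`.
#' @export
assemble_matrix <- function(lanes, cs) {
  stopifnot(inherits(cs, "codeset"), length(lanes) > 0)
  mismatch <- list()
  cols <- lapply(lanes, function(lane) {
    chk <- check_codeset(lane, cs)
    if (length(chk$missing)) {
      stop("lane '", lane$meta$sample_id, "' is missing probe(s): ",
           paste(chk$missing, collapse = ", "), call. = FALSE)
    }
    if (length(chk$extra)) {
      mismatch[[lane$meta$sample_id]] <<- chk$extra
    }
    lane$counts$count[match(cs$name, lane$counts$name)]
  })
  counts <- do.call(cbind, cols)
  samples <- do.call(rbind, lapply(lanes, `[[`, "meta"))
  rownames(samples) <- NULL
  m <- count_matrix(counts, cs, samples, stage = "raw")
  attr(m, "mismatch") <- mismatch
  m
}

#' Read a directory of RCC files into a count matrix
#'
#' @param dir directory containing `*.RCC` files.
#' @param cs expected [codeset]; defaults to the packaged panel.
#' @return a [count_matrix] at stage `"raw"`, lanes in lexicographic file
#'   order.
#' @export
read_rcc_dir <- function(dir, cs = default_codeset()) {
  files <- sort(list.files(dir, pattern = "\\.rcc$", ignore.case = TRUE,
                           full.names = TRUE))
  if (!length(files)) stop("no RCC files found in ", dir, call. = FALSE)
  assemble_matrix(lapply(files, read_rcc), cs)
}
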