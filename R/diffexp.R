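# Per-gene two-group comparison by the Mann-Whitney U test, standardized to
# a Z with midrank ties, tie-corrected variance and a continuity correction
# (the "adjusted Z" of classical desktop statistics packages), converted to
# a two-sided p through the normal approximation. Sign convention: the
# benign group (MH) is the first group, so genes higher in MPM get a
# negative Z.

#' Standardized Mann-Whitney statistic for two groups
#'
#' Computes the U statistic of `x_mh` (first group) from midranks and
#' standardizes it with the tie-corrected variance and, by default, a 0.5
#' continuity correction. Genes upregulated in the second group (MPM)
#' therefore yield negative `z`.
#'
#' @param x_mh,x_mpm numeric vectors of expression values for the two
#'   groups (benign first).
#' @param continuity apply the 0.5 continuity correction.
#' @param tie_correction use the tie-corrected variance.
#' @return list with `z`, two-sided `p`, and the raw `U` of the first group.
#' @export
#' @examples
#' mann_whitney_z(c(1, 2, 3), c(4, 5, 6))
mann_whitney_z <- function(x_mh, x_mpm, continuity = TRUE,
                           tie_correction = TRUE) {
  n1 <- length(x_mh); n2 <- length(x_mpm)
  if (n1 == 0 || n2 == 0) stop("both groups must be nonempty", call. = FALSE)
  pooled <- c(x_mh, x_mpm)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  n <- n1 + n2
  if (tie_correction) {
    t <- table(pooled)
    s2 <- n1 * n2 / 12 * ((n + 1) - sum(t^3 - t) / (n * (n - 1)))
  } else {
    s2 <- n1 * n2 * (n + 1) / 12
  }
  if (s2 <= 0) return(list(z = 0, p = 1, U = U))
  dev <- U - mu
  if (continuity) dev <- dev - sign(dev) * 0.5  # classical half-unit shift
  z <- dev / sqrt(s2)
  list(z = z, p = z_to_p(z), U = U)
}

#' Exact two-sided Mann-Whitney p by enumeration
#'
#' Enumerates all assignments of the pooled values to the two groups
#' (midranks preserved, so ties are handled exactly) and returns the
#' probability of a U deviation at least as extreme as observed. Intended
#' as an oracle for small samples.
#'
#' @inheritParams mann_whitney_z
#' @param max_n refuse enumeration above this total sample size.
#' @return exact two-sided p-value.
#' @export
mann_whitney_exact_p <- function(x_mh, x_mpm, max_n = 14) {
  n1 <- length(x_mh); n2 <- length(x_mpm); n <- n1 + n2
  if (n1 == 0 || n2 == 0) stop("both groups must be nonempty", call. = FALSE)
  if (n > max_n) stop("exact enumeration limited to n <= ", max_n,
                      call. = FALSE)
  r <- rank(c(x_mh, x_mpm))
  mu <- n1 * n2 / 2
  obs <- abs(sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2 - mu)
  combos <- utils::combn(n, n1)
  u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(abs(u_all - mu) >= obs - 1e-9)
}

#' Convert a standardized statistic to a two-sided normal p-value
#'
#' @param z finite standardized statistic (vectorized).
#' @return `2 * (1 - pnorm(|z|))`.
#' @export
z_to_p <- function(z) {
  stopifnot(all(is.finite(z)))
  2 * stats::pnorm(-abs(z))
}

#' Per-gene differential expression between MPM and MH
#'
#' Applies [mann_whitney_z] to every endogenous gene of a normalized count
#' matrix, MH as the first group. Results are laid out by direction
#' (up in MPM first) and sorted by increasing p within direction.
#'
#' @param m a [count_matrix] at stage `"bio_normalized"` whose samples carry
#'   `MPM`/`MH` labels.
#' @param continuity,tie_correction passed to [mann_whitney_z].
#' @return data frame with columns `gene`, `z`, `p`, `direction`
#'   (`up_in_MPM` iff `z < 0`; zero-z genes are reported as `down_in_MPM`).
#' @export
run_diffexp <- function(m, continuity = TRUE, tie_correction = TRUE) {
  require_stage(m, "bio_normalized")
  lab <- m$samples$label
  i_mh <- which(lab == "MH"); i_mpm <- which(lab == "MPM")
  if (length(i_mh) < 2 || length(i_mpm) < 2) {
    stop("need at least 2 samples per class (have ", length(i_mh), " MH, ",
         length(i_mpm), " MPM)", call. = FALSE)
  }
  expr <- class_counts(m, "Endogenous")
  res <- t(apply(expr, 1, function(x) {
    r <- mann_whitney_z(x[i_mh], x[i_mpm], continuity = continuity,
                        tie_correction = tie_correction)
    c(z = r$z, p = r$p)
  }))
  out <- data.frame(gene = rownames(expr), z = res[, "z"], p = res[, "p"],
                    direction = ifelse(res[, "z"] < 0, "up_in_MPM",
                                       "down_in_MPM"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(match(out$direction, c("up_in_MPM", "down_in_MPM")),
                   out$p, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Count significant genes by direction
#'
#' @param results data frame as returned by [run_diffexp] (columns `p`,
#'   `direction`).
#' @param alpha significance threshold in (0, 1); strict `p < alpha`.
#' @return named integer vector `c(n_up, n_down)`.
#' @export
count_significant <- function(results, alpha) {
  stopifnot(is.numeric(alpha), alpha > 0, alpha < 1)
  sig <- results[results$p < alpha, ]
  c(n_up = sum(sig$direction == "up_in_MPM"),
    n_down = sum(sig$direction == "down_in_MPM"))
}

#' Spearman correlation of gene expression with age
#'
#' Computed over all labelled samples together and within each label group,
#' mirroring the check that apparent class differences are not an age
#' artefact (the benign and malignant cohorts differ in mean age).
#'
#' @param m a [count_matrix] at stage `"bio_normalized"`.
#' @param ages optional numeric vector of ages matching the samples;
#'   defaults to `m$samples$age`.
#' @return data frame with `gene`, `group` (`all`, `MPM`, `MH`),
#'   `rho_spearman`, `p`, and `constant` flag (rho reported 0 for
#'   zero-variance expression).
#' @export
age_correlation <- function(m, ages = NULL) {
  require_stage(m, "bio_normalized")
  if (is.null(ages)) ages <- m$samples$age
  if (anyNA(ages)) stop("ages required for all samples", call. = FALSE)
  expr <- class_counts(m, "Endogenous")
  groups <- list(all = seq_len(ncol(expr)))
  for (g in intersect(c("MPM", "MH"), unique(m$samples$label))) {
    groups[[g]] <- which(m$samples$label == g)
  }
  do.call(rbind, lapply(names(groups), function(gname) {
    idx <- groups[[gname]]
    res <- t(apply(expr[, idx, drop = FALSE], 1, function(x) {
      if (stats::sd(x) == 0 || stats::sd(ages[idx]) == 0) {
        return(c(rho = 0, p = 1, constant = 1))
      }
      ct <- suppressWarnings(
        stats::cor.test(x, ages[idx], method = "spearman"))
      c(rho = unname(ct$estimate), p = ct$p.value, constant = 0)
    }))
    data.frame(gene = rownames(expr), group = gname,
               rho_spearman = res[, "rho"], p = res[, "p"],
               constant = as.logical(res[, "constant"]),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Load the packaged reference differential-expression table
#'
#' The published per-gene Z and p values for the 117-gene panel (58 up, 59
#' down in MPM), stored as a plain-text fixture. Gene symbols are
#' canonicalized on load.
#'
#' @return data frame with `gene`, `z`, `p`, `direction`.
#' @export
reference_de_results <- function() {
  path <- system.file("extdata", "reference_de_results.tsv",
                      package = "mesoUSC", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$gene <- canonical_symbol(df$gene)
  df
}
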