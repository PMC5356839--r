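# Uncorrelated Shrunken Centroid (USC) classification.
#
# Shrunken-centroid core: per gene i and class k the standardized centroid
# difference d_ik = (xbar_ik - xbar_i) / (m_k * (s_i + s0)) is soft-
# thresholded by Delta; genes whose differences all shrink to zero carry no
# class signal and are dropped. The surviving candidates are then screened
# for redundancy: walking them in decreasing order of |d'|, a gene is kept
# only if its absolute Pearson correlation with every already-kept gene is
# <= rho. Samples are assigned to the class whose shrunken centroid is
# nearest in the (s_i + s0)-standardized squared metric, with a -2 log(prior)
# offset. (rho, Delta) are chosen by leave-one-out cross-validation.

#' Expression matrix handed to the classifier
#'
#' Extracts the endogenous genes of a normalized count matrix on the
#' classifier's working scale.
#'
#' @param m a [count_matrix] at stage `"bio_normalized"`.
#' @param scale `"log2"` (default): `log2(count + 1)`; or `"linear"`.
#' @return numeric matrix, genes x samples.
#' @export
usc_input <- function(m, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  x <- class_counts(m, "Endogenous")
  if (scale == "log2") log2(x + 1) else x
}

#' Fit unshrunk class centroids
#'
#' Computes per-gene overall and class centroids, the pooled within-class
#' standard deviation, the dispersion offset `s0` (median of the pooled
#' SDs), class size factors `m_k = sqrt(1/n_k - 1/n)`, standardized
#' differences `d_ik`, and class priors. In `standardization = "plain"`
#' mode, `m_k = 1` and `s0 = 0`, so Delta is read directly in pooled-SD
#' units.
#'
#' @param X numeric matrix, genes x samples, with rownames.
#' @param labels class label per sample (2 or more classes, each with at
#'   least 2 samples).
#' @param standardization `"lineage"` (default) or `"plain"`, see above.
#' @return an object of class `usc_model` (unshrunk: no genes selected yet).
#' @export
usc_fit_centroids <- function(X, labels,
                              standardization = c("lineage", "plain")) {
  standardization <- match.arg(standardization)
  stopifnot(is.matrix(X), !is.null(rownames(X)))
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(X))
  classes <- sort(unique(labels))
  n_k <- table(factor(labels, classes))
  if (length(classes) < 2) stop("need at least 2 classes", call. = FALSE)
  if (any(n_k < 2)) {
    stop("class(es) with fewer than 2 samples: ",
         paste(classes[n_k < 2], collapse = ", "), call. = FALSE)
  }
  n <- ncol(X)
  K <- length(classes)
  flat <- apply(X, 1, stats::sd) == 0
  if (any(flat)) {
    warning("dropping ", sum(flat), " zero-variance gene(s): ",
            paste(utils::head(rownames(X)[flat], 5), collapse = ", "),
            if (sum(flat) > 5) ", ..." else "", call. = FALSE)
    X <- X[!flat, , drop = FALSE]
  }
  overall <- rowMeans(X)
  cent <- vapply(classes, function(k)
    rowMeans(X[, labels == k, drop = FALSE]), numeric(nrow(X)))
  ss <- vapply(classes, function(k) {
    xk <- X[, labels == k, drop = FALSE]
    rowSums((xk - cent[, k])^2)
  }, numeric(nrow(X)))
  pooled_sd <- sqrt(rowSums(ss) / (n - K))
  s0 <- if (standardization == "lineage") stats::median(pooled_sd) else 0
  m_k <- if (standardization == "lineage") sqrt(1 / n_k - 1 / n)
         else stats::setNames(rep(1, K), classes)
  denom <- outer(pooled_sd + s0, as.numeric(m_k))
  d <- (cent - overall) / denom
  colnames(d) <- classes
  structure(list(
    genes_all = rownames(X), classes = classes,
    overall_centroid = overall, class_centroids = cent,
    pooled_sd = pooled_sd, s0 = s0,
    m_k = stats::setNames(as.numeric(m_k), classes),
    priors = stats::setNames(as.numeric(n_k) / n, classes),
    d = d, d_shrunk = NULL, shrunken_centroids = NULL,
    delta = NA_real_, rho = NA_real_,
    candidates = NULL, selected_genes = NULL,
    standardization = standardization, scale = NA_character_),
    class = "usc_model")
}

#' Soft-threshold the centroid differences
#'
#' Applies `d'_ik = sign(d_ik) * max(|d_ik| - delta, 0)` and rebuilds the
#' shrunken class centroids `xbar'_ik = xbar_i + m_k (s_i + s0) d'_ik`.
#' Genes whose differences all shrink to zero leave the candidate set;
#' survivors are ranked by `max_k |d'_ik|` (descending, ties by gene name).
#'
#' @param model a `usc_model` from [usc_fit_centroids].
#' @param delta shrinkage threshold, `>= 0`, in standardized-difference
#'   units.
#' @return the model with `d_shrunk`, `shrunken_centroids` and ranked
#'   `candidates` filled in.
#' @export
usc_shrink <- function(model, delta) {
  stopifnot(inherits(model, "usc_model"), delta >= 0)
  d <- model$d
  ds <- sign(d) * pmax(abs(d) - delta, 0)
  denom <- outer(model$pooled_sd + model$s0, model$m_k[model$classes])
  model$d_shrunk <- ds
  model$shrunken_centroids <- model$overall_centroid + denom * ds
  colnames(model$shrunken_centroids) <- model$classes
  score <- apply(abs(ds), 1, max)
  cand <- model$genes_all[score > 0]
  model$candidates <- cand[order(-score[score > 0], cand)]
  model$delta <- delta
  model
}

#' Remove highly correlated candidate genes
#'
#' Greedy pass over the shrinkage survivors in rank order: a gene is kept
#' only if its absolute Pearson correlation (on the training data) with
#' every already-kept gene does not exceed `rho`. With `rho = 1` the filter
#' is disabled.
#'
#' @param model a shrunk `usc_model` (after [usc_shrink]).
#' @param X the training expression matrix the model was fit on.
#' @param rho correlation-removal threshold in `[0, 1]`.
#' @param cor_mat optional precomputed gene correlation matrix of `X`
#'   (rownames/colnames = genes), to avoid recomputation across a grid.
#' @return the model with `selected_genes` and `rho` set.
#' @export
usc_correlation_filter <- function(model, X, rho, cor_mat = NULL) {
  stopifnot(inherits(model, "usc_model"), rho >= 0, rho <= 1)
  cand <- model$candidates
  if (is.null(cand)) stop("model not shrunk yet; call usc_shrink()",
                          call. = FALSE)
  if (!length(cand)) {
    stop("empty candidate set: delta = ", model$delta,
         " shrank every gene to zero", call. = FALSE)
  }
  if (rho >= 1 || length(cand) == 1) {
    model$selected_genes <- cand
    model$rho <- rho
    return(model)
  }
  if (is.null(cor_mat)) {
    cor_mat <- suppressWarnings(stats::cor(t(X[cand, , drop = FALSE])))
    cor_mat[!is.finite(cor_mat)] <- 0
  }
  kept <- cand[1]
  for (g in cand[-1]) {
    if (all(abs(cor_mat[g, kept]) <= rho)) kept <- c(kept, g)
  }
  model$selected_genes <- kept
  model$rho <- rho
  model
}

#' Per-class discriminant scores and prediction for one sample
#'
#' `score_k(x) = sum_i (x_i - xbar'_ik)^2 / (s_i + s0)^2 - 2 log pi_k` over
#' the selected genes; the predicted class minimizes the score and the
#' discriminant score is the (nonnegative) margin by which it wins. Exact
#' score ties go to the larger-prior class (then to the first class in
#' sort order), flagged in the result.
#'
#' @param model a trained `usc_model` with `selected_genes`.
#' @param x named numeric vector of expression values (model scale)
#'   covering the selected genes.
#' @return list with `scores` (per class), `molecular_class`,
#'   `discriminant_score`, `tie` flag.
#' @export
usc_discriminant <- function(model, x) {
  sel <- model$selected_genes
  if (is.null(sel)) stop("model has no selected genes; train it first",
                         call. = FALSE)
  missing <- setdiff(sel, names(x))
  if (length(missing)) {
    stop("expression value missing for gene(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  i <- match(sel, model$genes_all)
  denom <- (model$pooled_sd[i] + model$s0)^2
  scores <- vapply(model$classes, function(k) {
    sum((x[sel] - model$shrunken_centroids[i, k])^2 / denom) -
      2 * log(model$priors[k])
  }, 0)
  o <- order(scores, -model$priors[model$classes], model$classes)
  win <- model$classes[o[1]]
  margin <- scores[o[2]] - scores[o[1]]
  list(scores = scores, molecular_class = win,
       discriminant_score = as.numeric(margin),
       tie = isTRUE(all.equal(unname(scores[o[1]]), unname(scores[o[2]]))))
}

# one (delta x rho) sweep for a fixed training set; returns selected gene
# sets per grid point plus the fitted shrunken models per delta
sweep_grid <- function(fit, X_train, grid_delta, grid_rho) {
  cor_mat <- suppressWarnings(stats::cor(t(X_train)))
  cor_mat[!is.finite(cor_mat)] <- 0
  res <- list()
  for (delta in grid_delta) {
    sm <- usc_shrink(fit, delta)
    for (rho in grid_rho) {
      key <- paste(delta, rho, sep = "|")
      if (!length(sm$candidates)) {
        res[[key]] <- NULL  # infeasible at this delta
      } else {
        cand <- sm$candidates
        res[[key]] <- usc_correlation_filter(
          sm, X_train, rho,
          cor_mat = cor_mat[cand, cand, drop = FALSE])
      }
    }
  }
  res
}

#' Train the USC classifier with LOOCV hyperparameter selection
#'
#' For every `(rho, delta)` grid point the leave-one-out cross-validation
#' error is computed with a full refit per fold (centroids, shrinkage and
#' correlation filter). The best point minimizes the mistake count, ties
#' preferring sparser models (larger `delta`, then smaller `rho`); the
#' final model is refit on all samples at that point. Deterministic: no
#' randomness is involved.
#'
#' @param x a [count_matrix] at stage `"bio_normalized"` with `MPM`/`MH`
#'   labels, or a genes-x-samples matrix (then `labels` is required).
#' @param labels class labels when `x` is a plain matrix.
#' @param grid_rho,grid_delta hyperparameter grid.
#' @param scale working scale, see [usc_input].
#' @param standardization see [usc_fit_centroids].
#' @return list with `model` (final `usc_model`) and `report`: `mistakes`
#'   (LOOCV misclassifications at the chosen point), `average_genes` (mean
#'   selected-set size over the LOOCV folds), `predictive_genes` (selection
#'   of the final full-data fit), `best` (chosen `rho`, `delta`), and
#'   `grid` (the full LOOCV error surface).
#' @export
usc_train <- function(x, labels = NULL,
                      grid_rho = seq(0.5, 1, by = 0.1),
                      grid_delta = seq(0, 2, by = 0.25),
                      scale = c("log2", "linear"),
                      standardization = c("lineage", "plain")) {
  scale <- match.arg(scale)
  standardization <- match.arg(standardization)
  if (inherits(x, "count_matrix")) {
    labels <- x$samples$label
    X <- usc_input(x, scale)
  } else {
    stopifnot(is.matrix(x), !is.null(labels))
    X <- x
  }
  stopifnot(length(grid_rho) > 0, length(grid_delta) > 0)
  n <- ncol(X)
  keys <- as.vector(outer(grid_delta, grid_rho, paste, sep = "|"))
  mistakes <- stats::setNames(rep(0L, length(keys)), keys)
  sizes <- stats::setNames(rep(0, length(keys)), keys)
  for (f in seq_len(n)) {
    X_tr <- X[, -f, drop = FALSE]
    fit <- usc_fit_centroids(X_tr, labels[-f], standardization)
    models <- sweep_grid(fit, X_tr, grid_delta, grid_rho)
    for (key in keys) {
      mdl <- models[[key]]
      if (is.null(mdl)) {
        mistakes[key] <- mistakes[key] + 1L  # nothing selected: cannot call
        next
      }
      pred <- usc_discriminant(mdl, X[, f])
      if (pred$molecular_class != labels[f]) {
        mistakes[key] <- mistakes[key] + 1L
      }
      sizes[key] <- sizes[key] + length(mdl$selected_genes)
    }
  }
  grid <- data.frame(do.call(rbind, strsplit(keys, "|", fixed = TRUE)),
                     stringsAsFactors = FALSE)
  names(grid) <- c("delta", "rho")
  grid$delta <- as.numeric(grid$delta)
  grid$rho <- as.numeric(grid$rho)
  grid$mistakes <- as.integer(mistakes[keys])
  grid$average_genes <- sizes[keys] / n

  # feasibility: the full-data fit must select at least one gene
  full_fit <- usc_fit_centroids(X, labels, standardization)
  full_models <- sweep_grid(full_fit, X, grid_delta, grid_rho)
  grid$feasible <- !vapply(full_models[keys], is.null, TRUE)
  if (!any(grid$feasible)) {
    stop("training failure: every grid point selects zero genes",
         call. = FALSE)
  }
  cand <- grid[grid$feasible, ]
  cand <- cand[order(cand$mistakes, -cand$delta, cand$rho), ]
  best <- cand[1, ]
  final <- full_models[[paste(best$delta, best$rho, sep = "|")]]
  final$scale <- scale
  report <- list(mistakes = best$mistakes,
                 average_genes = best$average_genes,
                 predictive_genes = final$selected_genes,
                 best = list(rho = best$rho, delta = best$delta),
                 grid = grid)
  list(model = final, report = report)
}

#' Predict classes of unknown samples
#'
#' @param model a trained `usc_model` from [usc_train].
#' @param x a [count_matrix] at stage `"bio_normalized"` (transformed to
#'   the model's working scale automatically) or a genes-x-samples matrix
#'   already on that scale.
#' @return data frame with `sample_id`, `molecular_class`,
#'   `discriminant_score`, `tie`.
#' @export
usc_predict <- function(model, x) {
  stopifnot(inherits(model, "usc_model"))
  X <- if (inherits(x, "count_matrix")) usc_input(x, model$scale) else x
  if (is.null(colnames(X))) colnames(X) <- paste0("S", seq_len(ncol(X)))
  out <- lapply(seq_len(ncol(X)), function(j) {
    p <- usc_discriminant(model, X[, j])
    data.frame(sample_id = colnames(X)[j],
               molecular_class = p$molecular_class,
               discriminant_score = p$discriminant_score,
               tie = p$tie, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.usc_model <- function(x, ...) {
  cat(sprintf("<usc_model: %d classes (%s), delta=%s, rho=%s, %s genes selected>\n",
              length(x$classes), paste(x$classes, collapse = "/"),
              format(x$delta), format(x$rho),
              if (is.null(x$selected_genes)) "no"
              else length(x$selected_genes)))
  invisible(x)
}

#' Serialize / restore a USC model as JSON
#'
#' @param model a trained `usc_model`.
#' @param path file path.
#' @return `usc_model_to_json` returns `path` invisibly;
#'   `usc_model_from_json` returns the restored `usc_model`.
#' @export
usc_model_to_json <- function(model, path) {
  stopifnot(inherits(model, "usc_model"))
  payload <- unclass(model)
  # named atomic vectors lose their names in JSON arrays; keep these as maps
  payload$m_k <- as.list(payload$m_k)
  payload$priors <- as.list(payload$priors)
  payload$class_centroids <- as.data.frame(payload$class_centroids)
  payload$shrunken_centroids <- as.data.frame(payload$shrunken_centroids)
  payload$d <- as.data.frame(payload$d)
  payload$d_shrunk <- as.data.frame(payload$d_shrunk)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname usc_model_to_json
#' @export
usc_model_from_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (fld in c("class_centroids", "shrunken_centroids", "d", "d_shrunk")) {
    payload[[fld]] <- as.matrix(payload[[fld]])
    rownames(payload[[fld]]) <- payload$genes_all
  }
  for (fld in c("overall_centroid", "pooled_sd")) {
    payload[[fld]] <- stats::setNames(as.numeric(payload[[fld]]),
                                      payload$genes_all)
  }
  for (fld in c("m_k", "priors")) {
    payload[[fld]] <- unlist(payload[[fld]])
  }
  structure(payload, class = "usc_model")
}
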