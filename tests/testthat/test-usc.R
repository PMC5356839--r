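# hand toy used in several places: 2 genes x 4 samples, two classes
toy_X <- function() {
  X <- matrix(c(1, 10,
                3, 12,
                7, 20,
                9, 22), nrow = 2,
              dimnames = list(c("g1", "g2"), c("a1", "a2", "b1", "b2")))
  list(X = X, labels = c("A", "A", "B", "B"))
}

test_that("centroid fit matches hand arithmetic", {
  t <- toy_X()
  fit <- usc_fit_centroids(t$X, t$labels)
  # per gene: class means (2, 8) and (11, 21); overall 5 and 16
  expect_equal(unname(fit$class_centroids), matrix(c(2, 11, 8, 21), 2),
               ignore_attr = TRUE)
  expect_equal(unname(fit$overall_centroid), c(5, 16))
  # pooled sd: each class contributes (x - mean)^2 = 2 per gene; n - K = 2
  s <- sqrt((2 + 2) / 2)
  expect_equal(unname(fit$pooled_sd), c(s, s))
  expect_equal(fit$s0, s)  # median over two equal values
  m_k <- sqrt(1 / 2 - 1 / 4)
  expect_equal(unname(fit$m_k), rep(m_k, 2))
  d_expect <- (2 - 5) / (m_k * (s + s))
  expect_equal(fit$d["g1", "A"], d_expect)
  expect_equal(fit$d["g1", "B"], -d_expect)
  expect_equal(unname(fit$priors), c(0.5, 0.5))
})

test_that("plain standardization mode drops m_k and s0", {
  t <- toy_X()
  fit <- usc_fit_centroids(t$X, t$labels, standardization = "plain")
  s <- sqrt(2)
  expect_equal(fit$d["g1", "A"], (2 - 5) / s)
  expect_equal(fit$s0, 0)
})

test_that("d is scale-equivariant and zero for equal class means", {
  t <- toy_X()
  fit1 <- usc_fit_centroids(t$X, t$labels)
  fit2 <- usc_fit_centroids(2 * t$X, t$labels)
  expect_equal(fit1$d, fit2$d)  # doubling expression leaves d unchanged
  X <- rbind(t$X, g3 = c(4, 6, 4, 6))  # identical class means on g3
  fit3 <- usc_fit_centroids(X, t$labels)
  expect_equal(unname(fit3$d["g3", ]), c(0, 0))
})

test_that("degenerate fits error or warn as specified", {
  t <- toy_X()
  expect_error(usc_fit_centroids(t$X, c("A", "A", "A", "B")),
               "fewer than 2 samples")
  X <- rbind(t$X, flat = rep(3, 4))
  expect_warning(fit <- usc_fit_centroids(X, t$labels), "zero-variance")
  expect_false("flat" %in% fit$genes_all)
})

test_that("soft thresholding shrinks, drops, and rebuilds centroids", {
  t <- toy_X()
  fit <- usc_fit_centroids(t$X, t$labels)
  s0 <- usc_shrink(fit, 0)
  expect_equal(s0$d_shrunk, fit$d)  # delta = 0 is the identity
  expect_equal(s0$shrunken_centroids, fit$class_centroids)
  expect_setequal(s0$candidates, c("g1", "g2"))

  d_abs <- abs(fit$d[1, "A"])
  s_half <- usc_shrink(fit, d_abs / 2)
  expect_equal(abs(s_half$d_shrunk[1, "A"]), d_abs / 2)
  # |d| = 0.9 with delta = 1 -> gene leaves candidacy
  fit2 <- fit
  fit2$d[] <- c(0.9, -0.9, 0.9, 0.9) * matrix(c(1, 1, -1, -1), 2)
  s_big <- usc_shrink(fit2, 1)
  expect_identical(s_big$candidates, character(0))
  expect_error(usc_correlation_filter(s_big, t$X, 0.7), "empty candidate")
})

test_that("candidate sets are nested as delta grows", {
  sim <- toy_cohort(seed = 91)
  m <- normalize_ncounter(sim$matrix)$matrix
  fit <- usc_fit_centroids(usc_input(m), m$samples$label)
  prev <- NULL
  for (delta in seq(0, 2, by = 0.25)) {
    cand <- usc_shrink(fit, delta)$candidates
    if (!is.null(prev)) expect_true(all(cand %in% prev))
    prev <- cand
  }
})

test_that("correlation filter obeys its invariant and the greedy oracle", {
  sim <- toy_cohort(seed = 93, n_a = 15, n_b = 10,
                    correlated_blocks = list(1:4, 5:7))
  m <- normalize_ncounter(sim$matrix)$matrix
  X <- usc_input(m)
  fit <- usc_shrink(usc_fit_centroids(X, m$samples$label), 0.25)
  for (rho in c(0.5, 0.7, 0.9)) {
    sel <- usc_correlation_filter(fit, X, rho)$selected_genes
    expect_true(all(sel %in% fit$candidates))
    r <- abs(cor(t(X[sel, , drop = FALSE])))
    diag(r) <- 0
    expect_lte(max(r), rho + 1e-12)
    # independent greedy oracle over the ranked candidate list
    rall <- abs(cor(t(X[fit$candidates, , drop = FALSE])))
    kept <- character(0)
    for (g in fit$candidates) {
      if (!length(kept) || all(rall[g, kept] <= rho)) kept <- c(kept, g)
    }
    expect_identical(sel, kept)
  }
  # rho = 1 disables the filter
  expect_identical(usc_correlation_filter(fit, X, 1)$selected_genes,
                   fit$candidates)
})

test_that("a duplicated gene is removed, keeping the higher-ranked copy", {
  X <- matrix(c(1, 3, 7, 9,
                1, 3, 7, 9), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g1copy"), paste0("s", 1:4)))
  fit <- usc_shrink(usc_fit_centroids(X, c("A", "A", "B", "B")), 0)
  # identical |d'| -> lexicographic rank puts g1 first
  expect_identical(fit$candidates, c("g1", "g1copy"))
  sel <- usc_correlation_filter(fit, X, 0.7)$selected_genes
  expect_identical(sel, "g1")  # r = 1 between the copies removes the second
})

test_that("discriminant scores match hand arithmetic and tie rules", {
  t <- toy_X()
  model <- usc_correlation_filter(
    usc_shrink(usc_fit_centroids(t$X, t$labels), 0), t$X, 1)
  # sample equal to the class-A centroid: raw term 0, class A wins
  xa <- model$shrunken_centroids[, "A"]
  names(xa) <- model$genes_all
  pa <- usc_discriminant(model, xa)
  expect_identical(pa$molecular_class, "A")
  expect_equal(unname(pa$scores["A"]), -2 * log(0.5))
  # hand-computed score of an arbitrary point
  x <- c(g1 = 4, g2 = 18)
  denom <- (model$pooled_sd + model$s0)^2
  sc <- sapply(c("A", "B"), function(k)
    sum((x - model$shrunken_centroids[, k])^2 / denom) - 2 * log(0.5))
  ph <- usc_discriminant(model, x)
  expect_equal(unname(ph$scores), unname(sc))
  expect_equal(ph$discriminant_score, abs(diff(sc)), ignore_attr = TRUE)
  # exactly equidistant point with equal priors: margin 0, tie flagged
  mid <- (model$shrunken_centroids[, "A"] + model$shrunken_centroids[, "B"]) / 2
  names(mid) <- model$genes_all
  pm <- usc_discriminant(model, mid)
  expect_equal(pm$discriminant_score, 0)
  expect_true(pm$tie)
  expect_error(usc_discriminant(model, c(g1 = 1)), "g2")
})

test_that("rho=1, delta=0, equal priors reduces to nearest centroid", {
  set.seed(111)
  for (rep in 1:100) {
    n_g <- sample(4:8, 1)
    X_tr <- matrix(rnorm(n_g * 8), n_g,
                   dimnames = list(paste0("g", 1:n_g), paste0("s", 1:8)))
    labels <- rep(c("A", "B"), each = 4)
    x_new <- rnorm(n_g)
    names(x_new) <- rownames(X_tr)
    fit <- usc_train(X_tr, labels, grid_rho = 1, grid_delta = 0)
    pred <- usc_discriminant(fit$model, x_new)
    # oracle: plain nearest centroid in the (s_i + s0)-standardized metric
    cent <- sapply(c("A", "B"), function(k)
      rowMeans(X_tr[, labels == k]))
    pooled <- sqrt((rowSums((X_tr[, 1:4] - cent[, "A"])^2) +
                    rowSums((X_tr[, 5:8] - cent[, "B"])^2)) / 6)
    s0 <- median(pooled)
    dist2 <- colSums((x_new - cent)^2 / (pooled + s0)^2)
    expect_identical(pred$molecular_class,
                     names(which.min(dist2)))
  }
})

test_that("training on separated classes is mistake-free and deterministic", {
  sim <- toy_cohort(seed = 121, n_a = 12, n_b = 8)
  m <- normalize_ncounter(sim$matrix)$matrix
  fit1 <- usc_train(m)
  fit2 <- usc_train(m)
  expect_identical(fit1$report, fit2$report)  # bit-identical rerun
  expect_identical(fit1$report$mistakes, 0L)
  expect_true(all(c("delta", "rho", "mistakes", "average_genes", "feasible")
                  %in% names(fit1$report$grid)))
  expect_identical(nrow(fit1$report$grid), 6L * 9L)
  # selected predictive genes are planted DE genes
  expect_true(all(fit1$report$predictive_genes %in% sim$truth$de_genes$gene))
  # re-predicting the training samples reproduces the labels
  self <- usc_predict(fit1$model, m)
  expect_identical(self$molecular_class, m$samples$label)
  # a sample identical to a training sample gets that sample's class
  X <- usc_input(m)
  one <- X[, 3, drop = FALSE]
  colnames(one) <- "copy"
  expect_identical(usc_predict(fit1$model, one)$molecular_class,
                   self$molecular_class[3])
})

test_that("single-point grid (rho=1, delta=0) keeps every varying gene", {
  sim <- toy_cohort(seed = 131)
  m <- normalize_ncounter(sim$matrix)$matrix
  fit <- usc_train(m, grid_rho = 1, grid_delta = 0)
  expect_identical(sort(fit$report$predictive_genes),
                   sort(fit$model$genes_all))
})

test_that("permuted labels drive LOOCV error toward the majority rate", {
  errs <- numeric(4)
  for (s in seq_along(errs)) {
    sim <- toy_cohort(seed = 140 + s, n_a = 8, n_b = 8, n_genes = 20,
                      n_de = 8)
    m <- normalize_ncounter(sim$matrix)$matrix
    set.seed(1000 + s)
    m$samples$label <- sample(m$samples$label)
    fit <- usc_train(m, grid_rho = c(0.7, 1), grid_delta = c(0, 0.5, 1))
    errs[s] <- fit$report$mistakes / ncol(m$counts)
  }
  expect_gt(mean(errs), 0.2)  # nothing close to the separable regime's 0
})

test_that("blind prediction recovers generator truth end to end", {
  cfg <- sim_config(n_class_a = 12, n_class_b = 8, n_genes = 40, n_de = 20,
                    n_degraded_a = 0, n_degraded_b = 0, seed = 151)
  sim <- simulate_cohort(cfg)
  m <- normalize_ncounter(sim$matrix)$matrix
  fit <- usc_train(m, grid_rho = c(0.7, 1), grid_delta = seq(0, 1, 0.5))
  blind <- make_blind_set(cfg, n_a = 5, n_b = 4, truth = sim$truth,
                          seed = 152)
  bm <- normalize_ncounter(blind$matrix)$matrix
  pred <- usc_predict(fit$model, bm)
  truth <- blind$truth$labels[pred$sample_id]
  expect_gte(sum(pred$molecular_class == truth), 8L)
  expect_true(all(pred$discriminant_score >= 0))
})

test_that("model JSON serialization round-trips predictions", {
  sim <- toy_cohort(seed = 161)
  m <- normalize_ncounter(sim$matrix)$matrix
  fit <- usc_train(m, grid_rho = c(0.7, 1), grid_delta = c(0.5, 1))
  path <- withr::local_tempfile(fileext = ".json")
  usc_model_to_json(fit$model, path)
  back <- usc_model_from_json(path)
  expect_identical(back$selected_genes, fit$model$selected_genes)
  expect_equal(usc_predict(back, m), usc_predict(fit$model, m))
})
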