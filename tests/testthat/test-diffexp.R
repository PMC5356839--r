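test_that("degenerate inputs: identical groups and empty groups", {
  r <- mann_whitney_z(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$z, 0)
  expect_equal(r$p, 1)
  expect_error(mann_whitney_z(numeric(0), 1:3), "nonempty")
  # all values identical across both groups: zero variance path
  r2 <- mann_whitney_z(rep(5, 4), rep(5, 6))
  expect_equal(c(r2$z, r2$p), c(0, 1))
})

test_that("adjusted Z matches the independent wilcox.test oracle", {
  set.seed(101)
  for (i in 1:25) {
    n1 <- sample(3:15, 1); n2 <- sample(3:15, 1)
    x <- sample(0:30, n1, replace = TRUE)  # integer draws force ties
    y <- sample(5:35, n2, replace = TRUE)
    ours <- mann_whitney_z(x, y)
    oracle <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(ours$p, oracle$p.value, tolerance = 1e-12)
    # U of the first group, as wilcox.test reports it
    expect_equal(ours$U, unname(oracle$statistic))
  }
})

test_that("sign convention: genes higher in MPM get negative z", {
  r <- mann_whitney_z(x_mh = c(1, 2, 3), x_mpm = c(10, 11, 12))
  expect_lt(r$z, 0)
  # swapping groups negates z, p unchanged
  s <- mann_whitney_z(c(10, 11, 12), c(1, 2, 3))
  expect_equal(s$z, -r$z)
  expect_equal(s$p, r$p)
})

test_that("exact enumeration agrees with closed-form tail for 3 vs 3", {
  # A={1,2,3}, B={4,5,6}: the observed U=0 is one of the two most extreme
  # of the choose(6,3)=20 equally likely assignments -> p = 2/20
  expect_equal(mann_whitney_exact_p(c(1, 2, 3), c(4, 5, 6)), 2 / 20)
  expect_error(mann_whitney_exact_p(1:10, 1:10), "enumeration limited")
})

test_that("normal approximation tracks the exact enumeration oracle", {
  # exhaustive over every achievable tie-free U for all splits with
  # n1 + n2 <= 12: the worst-case gap is 0.0881 (attained at 2 vs 2) and
  # shrinks monotonically-ish with n; typical gaps are far smaller
  worst <- 0
  typical <- c()
  for (n1 in 2:10) for (n2 in n1:10) {
    if (n1 + n2 > 12) next
    r <- seq_len(n1 + n2)
    combos <- utils::combn(n1 + n2, n1)
    mu <- n1 * n2 / 2
    us <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    for (u in unique(us)) {
      p_ex <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
      dev <- u - mu
      dev <- dev - sign(dev) * 0.5
      p_no <- 2 * pnorm(-abs(dev) / sqrt(n1 * n2 * (n1 + n2 + 1) / 12))
      worst <- max(worst, abs(p_ex - p_no))
      typical <- c(typical, abs(p_ex - p_no))
    }
  }
  expect_lt(worst, 0.09)
  expect_lt(median(typical), 0.01)

  # under ties the normal approximation can be off by >0.1 at these sizes
  # (which is why the enumeration oracle exists); validate the enumeration
  # itself against an independent Monte-Carlo permutation route
  set.seed(202)
  for (rep in 1:5) {
    x <- sample(1:4, 5, replace = TRUE)
    y <- sample(2:5, 5, replace = TRUE)
    pooled <- c(x, y)
    r <- rank(pooled)
    mu <- 5 * 5 / 2
    obs <- abs(sum(r[1:5]) - 15 - mu)
    mc <- mean(replicate(4000, {
      idx <- sample(10, 5)
      abs(sum(r[idx]) - 15 - mu) >= obs - 1e-9
    }))
    expect_lt(abs(mc - mann_whitney_exact_p(x, y)), 0.03)
  }

  # at 8 vs 8 (the smallest class size the workflow meets in practice)
  # random draws agree to ~0.011, the exhaustive worst case at that size
  set.seed(203)
  for (rep in 1:20) {
    x <- rnorm(8); y <- rnorm(8)
    expect_lt(abs(mann_whitney_z(x, y)$p - mann_whitney_exact_p(x, y, max_n = 16)),
              0.011)
  }
})

test_that("z_to_p is the two-sided normal tail", {
  expect_equal(z_to_p(0), 1)
  expect_equal(z_to_p(1.96), 2 * pnorm(-1.96))
  expect_equal(z_to_p(-3), z_to_p(3))
  expect_error(z_to_p(Inf), "finite")
})

test_that("run_diffexp output layout and invariances", {
  sim <- toy_cohort(seed = 55, n_a = 10, n_b = 8)
  m <- normalize_ncounter(sim$matrix)$matrix
  de <- run_diffexp(m)
  expect_identical(nrow(de), sum(m$codeset$code_class == "Endogenous"))
  expect_identical(de$direction, ifelse(de$z < 0, "up_in_MPM", "down_in_MPM"))
  # sorted by p ascending within direction
  for (d in unique(de$direction)) {
    expect_false(is.unsorted(de$p[de$direction == d]))
  }
  # invariant to sample column order
  perm <- rev(seq_len(ncol(m$counts)))
  m2 <- subset_samples(m, m$samples$sample_id[perm])
  expect_equal(run_diffexp(m2), de)
  # fewer than 2 samples per class errors
  expect_error(
    run_diffexp(subset_samples(m, m$samples$sample_id[m$samples$label == "MPM"])),
    "at least 2 samples")
})

test_that("planted effects are recovered with high power", {
  cfg <- sim_config(n_class_a = 25, n_class_b = 15, n_degraded_a = 0,
                    n_degraded_b = 0, seed = 77)
  sim <- simulate_cohort(cfg)
  m <- normalize_ncounter(sim$matrix)$matrix
  de <- run_diffexp(m)
  planted <- sim$truth$de_genes
  hit <- de$p[match(planted$gene, de$gene)] < 0.05
  expect_gte(mean(hit), 0.9)
  # recovered directions match the planted ones among significant genes
  dir <- de$direction[match(planted$gene, de$gene)]
  expect_true(all(dir[hit] == planted$direction[hit]))
})

test_that("count_significant reproduces the reference tallies", {
  de <- reference_de_results()
  expect_identical(count_significant(de, 0.05), c(n_up = 35L, n_down = 31L))
  expect_identical(count_significant(de, 0.005), c(n_up = 25L, n_down = 18L))
  expect_identical(count_significant(de, 0.9999), c(n_up = 58L, n_down = 59L))
  expect_error(count_significant(de, 1.2))
})

test_that("age correlation: perfect, reversed, and constant expression", {
  sim <- toy_cohort(seed = 66, n_a = 6, n_b = 6)
  m <- as_normalized(sim$matrix)
  ages <- m$samples$age
  m$counts[1, ] <- rank(ages) * 10      # expression = age rank
  m$counts[2, ] <- 42                   # constant
  ac <- age_correlation(m)
  all_grp <- ac[ac$group == "all", ]
  expect_equal(all_grp$rho_spearman[all_grp$gene == rownames(m$counts)[1]], 1)
  expect_equal(all_grp$rho_spearman[all_grp$gene == rownames(m$counts)[2]], 0)
  expect_true(all_grp$constant[all_grp$gene == rownames(m$counts)[2]])
  # antisymmetry under reversed ages
  ac_rev <- age_correlation(m, ages = -ages)
  expect_equal(ac_rev$rho_spearman[ac_rev$group == "all"],
               -all_grp$rho_spearman)
  # per-group rows exist for both labels
  expect_setequal(unique(ac$group), c("all", "MPM", "MH"))
})
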