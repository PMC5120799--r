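test_that("4:1 splits partition the lines with the canonical 144/36 sizes", {
  splits <- make_cv_splits(180, n_reps = 100, seed = 3)
  expect_length(splits, 100)
  for (sp in splits) {
    expect_length(sp$train, 144)
    expect_length(sp$test, 36)
    expect_length(intersect(sp$train, sp$test), 0)
    expect_setequal(c(sp$train, sp$test), 1:180)
  }
  expect_identical(splits, make_cv_splits(180, n_reps = 100, seed = 3))
  expect_false(identical(splits[[1]], splits[[2]]))
})

test_that("standardized accuracy is Pearson r over sqrt(h2)", {
  expect_equal(standardized_accuracy(1:5, 1:5, 1), 1)
  expect_equal(standardized_accuracy(c(1, 2, 3), c(3, 2, 1), 0.81),
               -1 / 0.9, tolerance = 1e-12)
  null_mean <- mean(vapply(1:100, function(s) {
    set.seed(s)
    standardized_accuracy(rnorm(50), rnorm(50), 0.8)
  }, numeric(1)))
  expect_lt(abs(null_mean), 0.1)
  expect_true(is.na(standardized_accuracy(rep(1, 5), rnorm(5), 0.9)))
  expect_error(standardized_accuracy(1:2, 1:2, 0.9), "3")
})

test_that("cross-validated accuracy saturates on strong signal and nulls on scrambled data", {
  sim <- tiny_population(n_lines = 90, seed = 40)
  qtl <- 17
  y <- as.numeric(sim$coded[, qtl]) + rnorm(90, 0, 0.05)
  names(y) <- rownames(sim$coded)
  splits <- make_cv_splits(90, n_reps = 15, seed = 5)
  res <- run_cv("rrblup", sim$coded, y, h2 = 1, splits)
  expect_gt(res$mean, 0.95)
  # scrambling the genotype-phenotype pairing removes the signal
  null_means <- vapply(1:5, function(s) {
    set.seed(s)
    run_cv("rrblup", sim$coded, sample(y), h2 = 1, splits)$mean
  }, numeric(1))
  expect_lt(abs(mean(null_means)), 0.12)
  # determinism under a fixed split list
  res2 <- run_cv("rrblup", sim$coded, y, h2 = 1, splits)
  expect_equal(res$mean, res2$mean, tolerance = 1e-12)
})

test_that("every CV replication scores only held-out lines", {
  sim <- tiny_population(n_lines = 50, seed = 41)
  y <- rnorm(50)
  splits <- make_cv_splits(50, n_reps = 10, seed = 7)
  for (sp in splits) {
    expect_length(intersect(sp$train, sp$test), 0)
    expect_setequal(union(sp$train, sp$test), 1:50)
  }
  # run_cv refuses overlapping splits
  bad <- splits
  bad[[1]]$test <- c(bad[[1]]$test, bad[[1]]$train[1])
  expect_error(run_cv("rrblup", sim$coded, y, 1, bad))
})

test_that("training-size sweep evaluates the grid and skips impossible values", {
  sim <- tiny_population(n_lines = 80, seed = 42)
  arch <- sample_qtl_architecture(sim$map, "polygenic-like", 0.9, seed = 43)
  g <- genetic_values(sim$geno, arch)
  g <- (g - mean(g)) / sd(g)
  set.seed(44)
  y <- g + rnorm(80, 0, 0.4)
  res <- sweep_accuracy("training_size", c(30, 60), sim$coded, y, 0.9,
                        n_reps = 10, seed = 8)
  expect_equal(res$value, c(30, 60))
  expect_true(all(is.finite(res$mean_accuracy)))
  expect_warning(
    sweep_accuracy("training_size", 500, sim$coded, y, 0.9, n_reps = 2),
    "skipped")
})

test_that("mean accuracy is nondecreasing in training size on polygenic data", {
  # aggregated over meta-replicates; more training data cannot hurt on average
  trend <- vapply(1:5, function(meta) {
    map <- make_genetic_map(4, 30, 100)
    geno <- simulate_dh_population(map, 100, seed = meta)
    coded <- impute_missing(encode_finf(geno))
    arch <- sample_qtl_architecture(map, "polygenic-like", 0.9, seed = meta + 10)
    g <- genetic_values(geno, arch)
    g <- (g - mean(g)) / sd(g)
    set.seed(meta + 20)
    y <- g + rnorm(100, 0, 0.3)
    res <- sweep_accuracy("training_size", c(25, 50, 80), coded, y, 0.9,
                          n_reps = 12, seed = meta)
    cor(res$value, res$mean_accuracy, method = "spearman")
  }, numeric(1))
  expect_gt(median(trend), 0)
})

test_that("marker-density sweep with all markers matches standard CV, fewer markers stay close", {
  sim <- tiny_population(n_lines = 80, n_chrom = 4, markers_per_chrom = 50,
                         seed = 45)
  arch <- sample_qtl_architecture(sim$map, "polygenic-like", 0.9, seed = 46)
  g <- genetic_values(sim$geno, arch)
  g <- (g - mean(g)) / sd(g)
  set.seed(47)
  y <- g + rnorm(80, 0, 0.3)
  res <- sweep_accuracy("marker_density", c(50, 200), sim$coded, y, 0.9,
                        map = sim$map, n_reps = 15, seed = 9)
  splits <- make_cv_splits(80, n_reps = 15, seed = 9)
  ref <- run_cv("rrblup", sim$coded, y, 0.9, splits, seed = 9)
  expect_equal(res$mean_accuracy[res$value == 200], ref$mean,
               tolerance = 1e-12)
  # moderate densities track the all-marker accuracy closely
  expect_lt(abs(res$mean_accuracy[1] - res$mean_accuracy[2]), 0.1)
})

test_that("environment sweep at k = N_E equals standard CV on the same splits", {
  sim <- tiny_population(n_lines = 60, seed = 48)
  arch <- sample_qtl_architecture(sim$map, "polygenic-like", 0.9, seed = 49)
  des <- trial_design_for_h2(0.9, genetic_var = 1, n_env = 4)
  ph <- simulate_phenotypes(sim$geno, arch, des, 1, seed = 50)
  blues <- compute_blues(ph)
  y <- blues$trait[match(rownames(sim$geno), blues$line)]
  names(y) <- rownames(sim$geno)
  res <- sweep_accuracy("environments", 4, sim$coded, y, 0.9,
                        records = ph, n_reps = 8, seed = 10)
  splits <- make_cv_splits(60, n_reps = 8, seed = 10)
  ref <- run_cv("rrblup", sim$coded, y, 0.9, splits, seed = 10)
  expect_equal(res$mean_accuracy, ref$mean, tolerance = 1e-10)
  # fewer environments: accuracy drops but stays positive here
  res2 <- sweep_accuracy("environments", 2, sim$coded, y, 0.9,
                         records = ph, n_reps = 8, seed = 10)
  expect_true(is.finite(res2$mean_accuracy))
})

test_that("independent validation standardizes by training heritability and checks markers", {
  map <- make_genetic_map(4, 30, 100)
  geno <- simulate_dh_population(map, 120, seed = 51)
  coded <- impute_missing(encode_finf(geno))
  arch <- sample_qtl_architecture(map, "polygenic-like", 0.9, seed = 52)
  des <- trial_design_for_h2(0.9, genetic_var = 1, n_env = 4)
  ph <- simulate_phenotypes(geno, arch, des, 1, seed = 53)
  blues <- compute_blues(ph)
  y <- blues$trait[match(rownames(geno), blues$line)]

  # degenerate panel = the training population itself
  self <- independent_validation(coded, y, 0.9, coded, y)
  fit <- fit_rrblup(y, coded)
  expect_equal(self$correlation, cor(fit$fitted, y), tolerance = 1e-10)

  panel <- simulate_validation_panel(map, arch, 117, 0.5, seed = 54)
  pb <- compute_blues(panel$pheno)
  pc <- impute_missing(encode_finf(panel$geno))
  py <- pb$trait[match(rownames(panel$geno), pb$line)]
  val <- independent_validation(coded, y, 0.9, pc, py)
  expect_equal(val$n_common_markers, nrow(map))
  expect_lt(val$accuracy, self$accuracy)

  expect_error(independent_validation(coded, y, 0.9,
                                      pc[, 1:10, drop = FALSE], py),
               "common markers")
})

test_that("cross-population accuracy with partial sharing sits between no and full sharing", {
  accs <- vapply(1:10, function(s) {
    map <- make_genetic_map(3, 25, 100)
    geno <- simulate_dh_population(map, 100, seed = s)
    coded <- impute_missing(encode_finf(geno))
    arch <- sample_qtl_architecture(map, "polygenic-like", 0.9, seed = s + 60)
    des <- trial_design_for_h2(0.9, genetic_var = 1, n_env = 3)
    ph <- simulate_phenotypes(geno, arch, des, 1, seed = s + 70)
    blues <- compute_blues(ph)
    y <- blues$trait[match(rownames(geno), blues$line)]
    one <- function(share) {
      panel <- simulate_validation_panel(map, arch, 80, share, seed = s + 80)
      pb <- compute_blues(panel$pheno)
      pc <- impute_missing(encode_finf(panel$geno))
      py <- pb$trait[match(rownames(panel$geno), pb$line)]
      independent_validation(coded, y, 0.9, pc, py)$accuracy
    }
    c(one(0), one(0.5), one(1))
  }, numeric(3))
  m <- rowMeans(accs)
  expect_gt(m[2], m[1])
  expect_lt(m[2], m[3])
})
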