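test_that("genetic map construction spans chromosomes and is deterministic", {
  map1 <- make_genetic_map(1, 2, 100)
  expect_equal(nrow(map1), 2)
  expect_equal(diff(map1$pos_cM), 100)
  expect_equal(length(unique(map1$chrom)), 1)

  big <- make_genetic_map(19, 720, 120)
  expect_equal(nrow(big), 19 * 720)

  a <- make_genetic_map(2, 5, 50, seed = 3)
  b <- make_genetic_map(2, 5, 50, seed = 3)
  expect_identical(a, b)

  expect_error(make_genetic_map(0, 5, 50), "n_chrom")
  expect_error(make_genetic_map(2, 1, 50), "markers_per_chrom")

  # positions nondecreasing within chromosome, unique marker ids
  expect_true(all(tapply(big$pos_cM, big$chrom,
                         function(x) all(diff(x) >= 0))))
  expect_false(any(duplicated(big$marker)))
})

test_that("DH lines are fully homozygous with whole-chromosome haplotypes at 0 cM", {
  map0 <- make_genetic_map(2, 5, 0)
  geno <- simulate_dh_population(map0, 40, seed = 5)
  expect_equal(sum(geno == 1L), 0)
  # zero-length chromosome: every line carries one parental haplotype
  for (ch in unique(map0$chrom)) {
    sub <- geno[, map0$marker[map0$chrom == ch]]
    expect_true(all(apply(sub, 1, function(x) length(unique(x)) == 1)))
  }
  expect_error(simulate_dh_population(map0, 0), "n_lines")
})

test_that("adjacent-marker recombination matches the Haldane map function", {
  map <- data.frame(marker = c("a", "b"), chrom = "C01",
                    pos_cM = c(0, 50), pos_bp = c(0L, 1L))
  geno <- simulate_dh_population(map, 10000, seed = 42)
  expect_equal(sum(geno == 1L), 0)
  r_true <- (1 - exp(-2 * 50 / 100)) / 2   # 0.3160603
  rec <- mean(geno[, "a"] != geno[, "b"])
  se <- sqrt(r_true * (1 - r_true) / 10000)
  expect_lt(abs(rec - r_true), 3 * se)
})

test_that("population-scale simulation is reproducible and heterozygote-free", {
  map <- make_genetic_map(19, 40, 120)
  g1 <- simulate_dh_population(map, 180, seed = 7)
  g2 <- simulate_dh_population(map, 180, seed = 7)
  expect_identical(g1, g2)
  expect_equal(dim(g1), c(180, nrow(map)))
  expect_equal(sum(g1 == 1L), 0)
  expect_true(all(g1 %in% c(0L, 2L)))
})

test_that("architecture presets respect their variance-share contracts", {
  map <- make_genetic_map(5, 50, 120)
  pop <- simulate_dh_population(map, 400, seed = 1)

  major <- sample_qtl_architecture(map, "major-QTL-like", 0.98, seed = 2)
  expect_equal(nrow(major$additive), 10)
  big2 <- major$additive[order(-abs(major$additive$effect)), ][1:2, ]
  chr <- map$chrom[match(big2$marker, map$marker)]
  expect_equal(length(unique(chr)), 2)
  # the two majors jointly carry ~75% of the genetic variance
  share2 <- sum(big2$effect^2) / sum(major$additive$effect^2)
  expect_equal(share2, 0.75, tolerance = 1e-10)

  poly <- sample_qtl_architecture(map, "polygenic-like", 0.96, seed = 3)
  expect_gte(nrow(poly$additive), 20)
  shares <- poly$additive$effect^2 / sum(poly$additive$effect^2)
  expect_lt(max(shares), 0.17)

  epi <- sample_qtl_architecture(map, "epistatic-like", 0.9, seed = 4,
                                 epistatic_fraction = 0.25)
  expect_gt(nrow(epi$epistatic), 0)

  expect_error(sample_qtl_architecture(map, "polygenic-like", 0),
               "target_h2")
  expect_error(sample_qtl_architecture(map, "no-such-preset", 0.5))
})

test_that("phenotype simulation rescales genetic variance exactly and is deterministic", {
  sim <- tiny_population(n_lines = 100)
  arch <- sample_qtl_architecture(sim$map, "polygenic-like", 0.9, seed = 5)
  des <- trial_design(n_env = 4, n_rep = 3, var_env = 1, var_gxe = 0.3,
                      var_rep_within_env = 0.1, var_error = 0.5)
  ph <- simulate_phenotypes(sim$geno, arch, des, genetic_var_target = 2.5,
                            seed = 6)
  g <- attr(ph, "genetic_values")
  expect_equal(var(g), 2.5, tolerance = 1e-12)
  expect_equal(nrow(ph), 100 * 4 * 3)
  ph2 <- simulate_phenotypes(sim$geno, arch, des, genetic_var_target = 2.5,
                             seed = 6)
  expect_identical(ph, ph2)

  # degenerate design: plot value equals the line's genetic value
  des0 <- trial_design(n_env = 2, n_rep = 2, var_env = 0, var_gxe = 0,
                       var_rep_within_env = 0, var_error = 0)
  ph0 <- simulate_phenotypes(sim$geno, arch, des0, genetic_var_target = 1,
                             seed = 7)
  g0 <- attr(ph0, "genetic_values")
  expect_equal(ph0$value, unname(g0[ph0$line]), tolerance = 1e-12)

  geno_na <- sim$geno
  geno_na[1, 1] <- NA
  expect_error(simulate_phenotypes(geno_na, arch, des), "missing")
})

test_that("missingness injection hits its target rate and errors corrupt calls", {
  sim <- tiny_population(n_lines = 200)
  g <- inject_missing_and_errors(sim$geno, missing_rate = 0.02,
                                 error_rate = 0, seed = 3)
  expect_lt(abs(mean(is.na(g)) - 0.02), 0.005)
  ge <- inject_missing_and_errors(sim$geno, missing_rate = 0,
                                  error_rate = 0.05, seed = 4)
  expect_lt(abs(mean(ge != sim$geno) - 0.05), 0.01)
})

test_that("validation panel is inbred, sized as requested, and validates sharing bounds", {
  map <- make_genetic_map(4, 30, 100)
  arch <- sample_qtl_architecture(map, "polygenic-like", 0.9, seed = 1)
  panel <- simulate_validation_panel(map, arch, n_lines = 117,
                                     shared_qtl_fraction = 0.5, seed = 2)
  expect_equal(nrow(panel$geno), 117)
  expect_equal(sum(panel$geno == 1L), 0)
  expect_equal(length(unique(panel$pheno$env)), 1)
  expect_equal(length(unique(panel$pheno$rep)), 3)
  expect_true(all(colnames(panel$geno) %in% map$marker))
  expect_error(simulate_validation_panel(map, arch, 50,
                                         shared_qtl_fraction = 1.5),
               "shared_qtl_fraction")
})

test_that("shared-QTL fraction orders cross-population transfer accuracy", {
  # Monte-Carlo over seeds: accuracy(share=0) ~ 0 < accuracy(0.5) < accuracy(1)
  map <- make_genetic_map(4, 25, 100)
  acc <- function(share, seeds) {
    vapply(seeds, function(s) {
      set.seed(s)
      geno <- simulate_dh_population(map, 120, seed = s)
      arch <- sample_qtl_architecture(map, "polygenic-like", 0.9,
                                      seed = s + 100)
      des <- trial_design_for_h2(0.9, genetic_var = 1, n_env = 3)
      ph <- simulate_phenotypes(geno, arch, des, 1, seed = s + 200)
      blues <- compute_blues(ph)
      coded <- impute_missing(encode_finf(geno))
      y <- blues$trait[match(rownames(geno), blues$line)]
      panel <- simulate_validation_panel(map, arch, 80, share,
                                         seed = s + 300)
      pb <- compute_blues(panel$pheno)
      pc <- impute_missing(encode_finf(panel$geno))
      fit <- fit_rrblup(y, coded)
      cor(predict(fit, pc), pb$trait[match(rownames(panel$geno), pb$line)])
    }, numeric(1))
  }
  seeds <- 1:12
  a0 <- mean(acc(0, seeds))
  a5 <- mean(acc(0.5, seeds))
  a1 <- mean(acc(1, seeds))
  expect_lt(abs(a0), 0.15)
  expect_gt(a5, a0)
  expect_gt(a1, a5)
})

test_that("CSV round-trips preserve genotypes, maps and phenotype records", {
  sim <- tiny_population(n_lines = 15, n_chrom = 2, markers_per_chrom = 8)
  g <- inject_missing_and_errors(sim$geno, missing_rate = 0.05, seed = 1)
  tmp <- tempfile(fileext = ".csv")
  write_genotype_csv(g, tmp)
  expect_identical(read_genotype_csv(tmp), g)
  tmp2 <- tempfile(fileext = ".csv")
  write_map_csv(sim$map, tmp2)
  expect_equal(read_map_csv(tmp2), sim$map)
  arch <- sample_qtl_architecture(sim$map, "polygenic-like", 0.8, seed = 2)
  ph <- simulate_phenotypes(sim$geno, arch,
                            trial_design(2, 2, var_error = 0.1), 1, seed = 3)
  tmp3 <- tempfile(fileext = ".csv")
  write_pheno_csv(ph, tmp3)
  back <- read_pheno_csv(tmp3)
  expect_equal(back$value, ph$value, tolerance = 1e-10)
  unlink(c(tmp, tmp2, tmp3))
})
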