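# Genotype call codes used throughout: 2 = parent-1 homozygote,
# 0 = parent-2 homozygote, 1 = heterozygote, NA = missing.

#' Build a genetic map
#'
#' Constructs a marker map with evenly spaced marker positions along each
#' chromosome, spanning the full chromosome length (first marker at 0 cM,
#' last at `chrom_length_cM`). Physical positions are laid down at a nominal
#' 0.5 Mb/cM so downstream tie-break rules that prefer markers with a
#' physical alignment have something to work with.
#'
#' @param n_chrom Number of chromosomes (>= 1).
#' @param markers_per_chrom Markers per chromosome (>= 2).
#' @param chrom_length_cM Chromosome length in centimorgan (> 0 unless a
#'   degenerate zero-length chromosome is wanted).
#' @param seed Integer seed, accepted for interface symmetry with the other
#'   generators; the map itself is deterministic.
#' @return A `data.frame` with columns `marker`, `chrom`, `pos_cM`, `pos_bp`,
#'   markers sorted by position within chromosome.
#' @examples
#' map <- make_genetic_map(2, 5, 120)
#' @export
make_genetic_map <- function(n_chrom, markers_per_chrom, chrom_length_cM,
                             seed = 1L) {
  if (n_chrom < 1 || markers_per_chrom < 2)
    stop("n_chrom must be >= 1 and markers_per_chrom >= 2")
  if (chrom_length_cM < 0) stop("chrom_length_cM must be >= 0")
  chrom <- sprintf("C%02d", seq_len(n_chrom))
  pos <- seq(0, chrom_length_cM, length.out = markers_per_chrom)
  map <- data.frame(
    marker = sprintf("%s_M%04d", rep(chrom, each = markers_per_chrom),
                     rep(seq_len(markers_per_chrom), n_chrom)),
    chrom = rep(chrom, each = markers_per_chrom),
    pos_cM = rep(pos, n_chrom),
    pos_bp = as.integer(round(rep(pos, n_chrom) * 5e5)),
    stringsAsFactors = FALSE
  )
  map
}

#' Simulate a biparental doubled haploid population
#'
#' Simulates DH lines derived from the F1 of two fully homozygous parents
#' that carry opposite alleles at every marker (only markers polymorphic
#' between the parents are represented). Each line results from a single
#' meiosis: crossovers follow the Haldane model (no interference), so the
#' recombination fraction between adjacent markers at distance d cM is
#' r = (1 - exp(-2 d / 100)) / 2, and the resulting gamete is doubled,
#' giving fully homozygous lines.
#'
#' @param map Genetic map from [make_genetic_map()] (or any data frame with
#'   `marker`, `chrom`, `pos_cM`).
#' @param n_lines Number of DH lines (>= 1).
#' @param seed Integer seed.
#' @return Integer matrix (lines x markers) with codes 2 (parent-1
#'   homozygote) and 0 (parent-2 homozygote); DH lines carry no
#'   heterozygous calls. Row names are line ids, column names marker ids.
#' @export
simulate_dh_population <- function(map, n_lines, seed = 1L) {
  if (n_lines < 1) stop("n_lines must be >= 1")
  stopifnot(all(c("marker", "chrom", "pos_cM") %in% names(map)))
  set.seed(seed)
  chroms <- unique(map$chrom)
  geno <- matrix(NA_integer_, nrow = n_lines, ncol = nrow(map),
                 dimnames = list(sprintf("L%04d", seq_len(n_lines)),
                                 map$marker))
  for (ch in chroms) {
    idx <- which(map$chrom == ch)
    d <- diff(map$pos_cM[idx])
    r <- (1 - exp(-2 * d / 100)) / 2
    # origin of the first marker, then cumulative crossover switches
    start <- matrix(stats::rbinom(n_lines, 1L, 0.5), ncol = 1)
    if (length(r) > 0) {
      xo <- matrix(stats::rbinom(n_lines * length(r), 1L, rep(r, each = n_lines)),
                   nrow = n_lines)
      orig <- (start[, 1] + t(apply(cbind(0L, xo), 1, cumsum))) %% 2L
    } else {
      orig <- start
    }
    geno[, idx] <- ifelse(orig == 0L, 2L, 0L)
  }
  geno
}

#' Inject missing calls and genotyping errors
#'
#' Adds missingness and (optionally) genotyping errors to a call matrix so
#' that quality-control filters have realistic work to do. An error turns a
#' call into one of the other two call codes, chosen at random.
#'
#' @param geno Call matrix with codes in \{2, 0, 1, NA\}.
#' @param missing_rate Per-call probability of being set to missing.
#' @param error_rate Per-call probability of a miscall (applied before
#'   missingness).
#' @param seed Integer seed.
#' @return The corrupted call matrix.
#' @export
inject_missing_and_errors <- function(geno, missing_rate = 0.02,
                                      error_rate = 0, seed = 1L) {
  stopifnot(missing_rate >= 0, missing_rate <= 1,
            error_rate >= 0, error_rate <= 1)
  set.seed(seed)
  n <- length(geno)
  if (error_rate > 0) {
    err <- which(stats::runif(n) < error_rate & !is.na(geno))
    for (i in err) {
      others <- setdiff(c(0L, 1L, 2L), geno[i])
      geno[i] <- sample(others, 1L)
    }
  }
  if (missing_rate > 0) {
    geno[stats::runif(n) < missing_rate] <- NA_integer_
  }
  geno
}

#' Sample a QTL architecture
#'
#' Draws a trait architecture in one of three regimes observed for seed
#' quality traits in biparental rapeseed material:
#' \describe{
#'   \item{`major-QTL-like`}{two large-effect loci on distinct chromosomes
#'     jointly explaining about 75\% of the genetic variance (effect-size
#'     ratio roughly 45:31 as seen for erucic acid), plus a small-effect
#'     polygenic background.}
#'   \item{`polygenic-like`}{25 QTL with geometrically decaying effects,
#'     the largest explaining under 17\% of the genetic variance (the oil
#'     content regime).}
#'   \item{`epistatic-like`}{a polygenic additive base plus additive x
#'     additive pairs contributing `epistatic_fraction` of the genetic
#'     variance.}
#' }
#' Effects are expressed on the +/-1 parental coding; their absolute scale
#' is irrelevant because [simulate_phenotypes()] rescales genetic values to
#' a target variance.
#'
#' @param map Genetic map.
#' @param preset One of `"major-QTL-like"`, `"polygenic-like"`,
#'   `"epistatic-like"`.
#' @param target_h2 Intended broad-sense heritability, in (0, 1]; stored on
#'   the architecture and used by [trial_design_for_h2()].
#' @param seed Integer seed.
#' @param epistatic_fraction Fraction of genetic variance contributed by
#'   additive x additive pairs under the epistatic preset.
#' @return An object of class `qtl_architecture`: list with `additive`
#'   (data.frame marker/effect), `epistatic` (data.frame marker_i/marker_j/
#'   effect), `polygenic_sd`, `target_h2`, `preset`.
#' @export
sample_qtl_architecture <- function(map, preset = c("major-QTL-like",
                                                    "polygenic-like",
                                                    "epistatic-like"),
                                    target_h2, seed = 1L,
                                    epistatic_fraction = 0.25) {
  preset <- match.arg(preset)
  if (!is.numeric(target_h2) || target_h2 <= 0 || target_h2 > 1)
    stop("target_h2 must be in (0, 1]")
  set.seed(seed)
  chroms <- unique(map$chrom)
  epi <- data.frame(marker_i = character(), marker_j = character(),
                    effect = numeric(), stringsAsFactors = FALSE)
  if (preset == "major-QTL-like") {
    if (length(chroms) < 2) stop("major-QTL-like preset needs >= 2 chromosomes")
    ch2 <- sample(chroms, 2)
    m1 <- sample(map$marker[map$chrom == ch2[1]], 1)
    m2 <- sample(map$marker[map$chrom == ch2[2]], 1)
    # variance shares ~ effect^2 on +/-1 coding at allele freq 1/2:
    # 45:31 for the two majors (75% of genetic variance leaving 25% to
    # an 8-locus background)
    bg <- sample(setdiff(map$marker, c(m1, m2)), 8)
    bg_eff <- sqrt(0.25 / 8) * sample(c(-1, 1), 8, replace = TRUE)
    additive <- data.frame(
      marker = c(m1, m2, bg),
      effect = c(sqrt(0.75 * 45 / 76), -sqrt(0.75 * 31 / 76), bg_eff),
      stringsAsFactors = FALSE
    )
    poly_sd <- 0
  } else {
    n_qtl <- min(25L, max(2L, floor(nrow(map) / 2)))
    mk <- sample(map$marker, n_qtl)
    decay <- 0.92
    shares <- decay^(2 * (seq_len(n_qtl) - 1))
    shares <- shares / sum(shares)           # max share ~0.155 < 0.17
    eff <- sqrt(shares) * sample(c(-1, 1), n_qtl, replace = TRUE)
    additive <- data.frame(marker = mk, effect = eff,
                           stringsAsFactors = FALSE)
    poly_sd <- 0
    if (preset == "epistatic-like") {
      stopifnot(epistatic_fraction >= 0, epistatic_fraction < 1)
      # polygenic digenic epistasis: many pairs, matching the model class
      # of an additive-by-additive relationship kernel
      n_pair <- min(20L, floor((nrow(map) - n_qtl) / 2))
      pm <- matrix(sample(setdiff(map$marker, mk), 2 * n_pair), ncol = 2)
      pe <- sqrt(rep(1 / n_pair, n_pair)) * sample(c(-1, 1), n_pair,
                                                   replace = TRUE)
      # scale so additive:epistatic variance is (1-f):f
      additive$effect <- additive$effect * sqrt(1 - epistatic_fraction)
      pe <- pe * sqrt(epistatic_fraction)
      epi <- data.frame(marker_i = pm[, 1], marker_j = pm[, 2],
                        effect = pe, stringsAsFactors = FALSE)
    }
  }
  structure(list(additive = additive, epistatic = epi,
                 polygenic_sd = poly_sd, target_h2 = target_h2,
                 preset = preset),
            class = "qtl_architecture")
}

#' Compute true genetic values of lines under an architecture
#'
#' Additive + additive x additive + polygenic terms on the +/-1 parental
#' coding, before any variance rescaling.
#'
#' @param geno Complete call matrix (no NA).
#' @param arch `qtl_architecture`.
#' @param polygenic_draw Optional pre-drawn polygenic deviations (length
#'   `nrow(geno)`); drawn internally if `NULL` and `polygenic_sd > 0`.
#' @return Numeric vector of genetic values, one per line.
#' @export
genetic_values <- function(geno, arch, polygenic_draw = NULL) {
  code <- geno - 1  # 2/0 -> +1/-1, het -> 0
  g <- rep(0, nrow(geno))
  if (nrow(arch$additive) > 0) {
    Z <- code[, arch$additive$marker, drop = FALSE]
    g <- g + as.vector(Z %*% arch$additive$effect)
  }
  if (nrow(arch$epistatic) > 0) {
    for (k in seq_len(nrow(arch$epistatic))) {
      g <- g + arch$epistatic$effect[k] *
        code[, arch$epistatic$marker_i[k]] * code[, arch$epistatic$marker_j[k]]
    }
  }
  if (arch$polygenic_sd > 0) {
    if (is.null(polygenic_draw))
      polygenic_draw <- stats::rnorm(nrow(geno), 0, arch$polygenic_sd)
    g <- g + polygenic_draw
  }
  g
}

#' Multi-environment trial design
#'
#' @param n_env Number of environments N_E.
#' @param n_rep Replicates per environment N_R (RCBD blocks).
#' @param var_env Environment main-effect variance.
#' @param var_gxe Genotype x environment interaction variance.
#' @param var_rep_within_env Replicate-within-environment variance.
#' @param var_error Plot residual variance.
#' @return A `trial_design` list.
#' @export
trial_design <- function(n_env, n_rep = 3, var_env = 1, var_gxe = 0,
                         var_rep_within_env = 0, var_error = 0) {
  stopifnot(n_env >= 1, n_rep >= 1, var_env >= 0, var_gxe >= 0,
            var_rep_within_env >= 0, var_error >= 0)
  structure(list(n_env = as.integer(n_env), n_rep = as.integer(n_rep),
                 var_env = var_env, var_gxe = var_gxe,
                 var_rep_within_env = var_rep_within_env,
                 var_error = var_error),
            class = "trial_design")
}

#' Derive a trial design that yields a target heritability
#'
#' Splits the non-genetic variance between G x E and plot error in the
#' proportion seen for seed oil content (0.71 : 1.17) and scales both so
#' that H2 = vG / (vG + vGxE/N_E + vE/(N_E N_R)) equals the target.
#'
#' @param target_h2 Target broad-sense heritability in (0, 1].
#' @param genetic_var Genetic variance the phenotypes will be scaled to.
#' @param n_env,n_rep Design constants.
#' @param var_env Environment main-effect variance (does not enter H2).
#' @return A `trial_design`.
#' @export
trial_design_for_h2 <- function(target_h2, genetic_var = 1, n_env = 11,
                                n_rep = 3, var_env = genetic_var) {
  stopifnot(target_h2 > 0, target_h2 <= 1)
  # H2 = vG / (vG + k * s) with s the total non-genetic scale and
  # k = w_gxe/NE + w_err/(NE*NR), weights normalized from 0.71 / 1.17
  w <- c(gxe = 0.71, err = 1.17) / (0.71 + 1.17)
  k <- w["gxe"] / n_env + w["err"] / (n_env * n_rep)
  s <- if (target_h2 == 1) 0 else genetic_var * (1 - target_h2) / (target_h2 * k)
  trial_design(n_env = n_env, n_rep = n_rep, var_env = var_env,
               var_gxe = unname(s * w["gxe"]),
               var_rep_within_env = 0.1 * genetic_var,
               var_error = unname(s * w["err"]))
}

#' Simulate multi-environment RCBD phenotypes
#'
#' Plot values follow
#' `value = mu + G_line + E_env + GxE_(line,env) + R_(rep within env) + error`
#' with the genetic values rescaled so their empirical line-to-line variance
#' equals `genetic_var_target` exactly, and all random terms drawn
#' independently with the design variances.
#'
#' @param geno Complete call matrix (lines x markers, no missing calls).
#' @param arch `qtl_architecture`.
#' @param design `trial_design`.
#' @param genetic_var_target Target empirical variance of line genetic
#'   values.
#' @param seed Integer seed.
#' @param trait Trait label used in the output records.
#' @param mu Grand mean.
#' @return A `data.frame` of plot records: `line`, `env`, `rep`, `trait`,
#'   `value`, with attribute `"genetic_values"` (named vector of the true,
#'   rescaled line genetic values).
#' @export
simulate_phenotypes <- function(geno, arch, design, genetic_var_target = 1,
                                seed = 1L, trait = "trait", mu = 0) {
  if (anyNA(geno))
    stop("genotype matrix contains missing calls; phenotypes require complete genotypes")
  stopifnot(inherits(design, "trial_design"), genetic_var_target >= 0)
  set.seed(seed)
  g <- genetic_values(geno, arch)
  if (stats::var(g) > 0 && genetic_var_target > 0) {
    g <- (g - mean(g)) / stats::sd(g) * sqrt(genetic_var_target)
  } else if (genetic_var_target == 0) {
    g <- rep(0, length(g))
  }
  names(g) <- rownames(geno)
  n <- length(g); ne <- design$n_env; nr <- design$n_rep
  envs <- sprintf("E%02d", seq_len(ne))
  env_eff <- stats::rnorm(ne, 0, sqrt(design$var_env))
  gxe <- matrix(stats::rnorm(n * ne, 0, sqrt(design$var_gxe)), n, ne)
  rep_eff <- matrix(stats::rnorm(ne * nr, 0, sqrt(design$var_rep_within_env)),
                    ne, nr)
  rec <- expand.grid(rep = seq_len(nr), env = seq_len(ne),
                     line = seq_len(n), KEEP.OUT.ATTRS = FALSE)
  val <- mu + g[rec$line] + env_eff[rec$env] +
    gxe[cbind(rec$line, rec$env)] + rep_eff[cbind(rec$env, rec$rep)] +
    stats::rnorm(nrow(rec), 0, sqrt(design$var_error))
  out <- data.frame(line = rownames(geno)[rec$line],
                    env = envs[rec$env],
                    rep = sprintf("R%d", rec$rep),
                    trait = trait, value = as.numeric(val),
                    stringsAsFactors = FALSE)
  attr(out, "genetic_values") <- g
  out
}

#' Simulate a genetically distant validation panel
#'
#' Generates fully inbred lines that are not part of the biparental cross:
#' per-marker allele frequencies are drawn from a spread distribution around
#' 0.5 and markers segregate independently, so the panel's LD structure is
#' unrelated to the DH map phase. Only a fraction of the DH architecture's
#' QTL remain effective in the panel; the remainder are replaced by
#' panel-private QTL of the same magnitudes (so total genetic variance is
#' comparable but does not transfer). Phenotypes come from a
#' single-environment, 3-replicate trial.
#'
#' @param map Genetic map (panel markers are the same set, emulating the
#'   common-marker intersection used for cross-population prediction).
#' @param arch DH `qtl_architecture`.
#' @param n_lines Panel size.
#' @param shared_qtl_fraction Fraction of additive QTL shared with the DH
#'   population, in \[0, 1\].
#' @param allele_freq_spread Half-width of the uniform allele-frequency
#'   distribution around 0.5 (truncated to \[0.05, 0.95\]).
#' @param seed Integer seed.
#' @param genetic_var_target Target genetic variance in the panel.
#' @param var_error Plot residual variance of the panel trial.
#' @return List with `geno` (call matrix) and `pheno` (plot records).
#' @export
simulate_validation_panel <- function(map, arch, n_lines = 117,
                                      shared_qtl_fraction = 0.5,
                                      allele_freq_spread = 0.3, seed = 1L,
                                      genetic_var_target = 1,
                                      var_error = 0.3) {
  if (shared_qtl_fraction < 0 || shared_qtl_fraction > 1)
    stop("shared_qtl_fraction must be in [0, 1]")
  stopifnot(n_lines >= 1, allele_freq_spread >= 0, allele_freq_spread <= 0.45)
  set.seed(seed)
  m <- nrow(map)
  p <- pmin(pmax(stats::runif(m, 0.5 - allele_freq_spread,
                              0.5 + allele_freq_spread), 0.05), 0.95)
  geno <- matrix(2L * stats::rbinom(n_lines * m, 1L, rep(p, each = n_lines)),
                 nrow = n_lines,
                 dimnames = list(sprintf("V%04d", seq_len(n_lines)),
                                 map$marker))
  n_qtl <- nrow(arch$additive)
  n_shared <- round(shared_qtl_fraction * n_qtl)
  shared <- if (n_shared > 0) sample(seq_len(n_qtl), n_shared) else integer()
  panel_arch <- arch
  if (n_shared < n_qtl) {
    repl <- setdiff(seq_len(n_qtl), shared)
    free <- setdiff(map$marker, arch$additive$marker)
    panel_arch$additive$marker[repl] <- sample(free, length(repl))
  }
  panel_arch$epistatic <- panel_arch$epistatic[0, , drop = FALSE]
  des <- trial_design(n_env = 1, n_rep = 3, var_env = 0, var_gxe = 0,
                      var_rep_within_env = 0.05 * genetic_var_target,
                      var_error = var_error)
  pheno <- simulate_phenotypes(geno, panel_arch, des,
                               genetic_var_target = genetic_var_target,
                               seed = seed + 1L, trait = "trait")
  list(geno = geno, pheno = pheno)
}

#' Write / read the plain-text exchange formats
#'
#' Genotype CSV: rows = lines, columns = markers, codes \{2, 0, 1, NA\}.
#' Map CSV: `marker`, `chrom`, `pos_cM`, `pos_bp`. Phenotype CSV: long
#' format `line`, `env`, `rep`, `trait`, `value`.
#'
#' @param geno,map,pheno Objects as produced by the simulators.
#' @param path Output file path.
#' @return The input object, invisibly (writers); the parsed object
#'   (readers).
#' @name io
NULL

#' @rdname io
#' @export
write_genotype_csv <- function(geno, path) {
  df <- data.frame(line = rownames(geno), geno, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(geno)
}

#' @rdname io
#' @export
read_genotype_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  geno <- as.matrix(df[, -1, drop = FALSE])
  mode(geno) <- "integer"
  rownames(geno) <- df[[1]]
  geno
}

#' @rdname io
#' @export
write_map_csv <- function(map, path) {
  utils::write.csv(map, path, row.names = FALSE, quote = FALSE)
  invisible(map)
}

#' @rdname io
#' @export
read_map_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname io
#' @export
write_pheno_csv <- function(pheno, path) {
  utils::write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(pheno)
}

#' @rdname io
#' @export
read_pheno_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
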