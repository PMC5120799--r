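#' Adjusted entry means (BLUEs)
#'
#' Least-squares genotype means from a two-way fixed model
#' `value ~ genotype + environment` with sum-to-zero environment effects,
#' fitted per trait on the plot-level records. For complete balanced data
#' this equals the raw across-plot mean of each line; with missing
#' genotype-environment cells the means are corrected by the estimated
#' environment effects.
#'
#' @param records Plot-level data frame with columns `line`, `env`, `rep`,
#'   `trait`, `value`.
#' @return A `data.frame` `line` x one column per trait, with the adjusted
#'   entry means. Lines without records for a trait carry `NA`.
#' @export
compute_blues <- function(records) {
  stopifnot(all(c("line", "env", "trait", "value") %in% names(records)))
  lines <- sort(unique(records$line))
  out <- data.frame(line = lines, stringsAsFactors = FALSE)
  for (tr in unique(records$trait)) {
    d <- records[records$trait == tr, ]
    d$line <- factor(d$line, levels = lines[lines %in% d$line])
    d$env <- factor(d$env)
    if (nlevels(d$env) > 1) {
      X <- stats::model.matrix(~ 0 + line + env, data = d,
                               contrasts.arg = list(env = stats::contr.sum))
    } else {
      X <- stats::model.matrix(~ 0 + line, data = d)
    }
    fit <- stats::lm.fit(X, d$value)
    b <- fit$coefficients[seq_len(nlevels(d$line))]
    out[[tr]] <- b[match(paste0("line", lines), names(b))]
  }
  out
}

#' Variance components of a multi-environment RCBD trial
#'
#' With all effects random in
#' `value ~ genotype + environment + genotype:environment + environment:rep`,
#' estimates the genotypic variance, the genotype x environment interaction
#' variance, the replicate-within-environment variance and the plot error
#' variance. Balanced data (every line x environment x replicate cell
#' observed exactly once) are solved in closed form by equating observed to
#' expected mean squares of the two-way ANOVA; unbalanced data are fitted
#' by REML via \pkg{lme4}. Negative moment solutions are truncated at 0.
#'
#' @param records Plot-level records for a single trait (column `trait` may
#'   be present; if several traits are present, pass one at a time).
#' @return A `variance_components` list: `sigma2_G`, `sigma2_GxE`,
#'   `sigma2_rep`, `sigma2_error`, `n_env`, `n_rep` (average replicates per
#'   environment), `method`, and `single_env` flag (G x E inseparable).
#' @export
estimate_variance_components <- function(records) {
  stopifnot(all(c("line", "env", "rep", "value") %in% names(records)))
  if ("trait" %in% names(records) && length(unique(records$trait)) > 1)
    stop("pass records for a single trait")
  line <- factor(records$line); env <- factor(records$env)
  rp <- factor(records$rep); y <- records$value
  ng <- nlevels(line); ne <- nlevels(env)
  nr_per_env <- tapply(rp, env, function(x) length(unique(x)))
  nr_avg <- mean(nr_per_env)
  single_env <- ne < 2
  tab <- table(line, env, rp)
  balanced <- !single_env && all(tab == 1)
  if (balanced) {
    nr <- nlevels(rp)
    gm <- mean(y)
    m_g <- tapply(y, line, mean)
    m_e <- tapply(y, env, mean)
    m_ge <- tapply(y, list(line, env), mean)
    m_er <- tapply(y, list(env, rp), mean)
    ms_g <- ne * nr * sum((m_g - gm)^2) / (ng - 1)
    ms_ge <- nr * sum((m_ge - outer(m_g, rep(1, ne)) -
                         outer(rep(1, ng), m_e) + gm)^2) /
      ((ng - 1) * (ne - 1))
    dev_er <- m_er - matrix(as.vector(m_e), nrow(m_er), ncol(m_er))
    ms_r <- ng * sum(dev_er^2) / (ne * (nr - 1))
    ss_tot <- sum((y - gm)^2)
    ss_err <- ss_tot - ne * nr * sum((m_g - gm)^2) -
      ng * nr * sum((m_e - gm)^2) -
      nr * sum((m_ge - outer(m_g, rep(1, ne)) - outer(rep(1, ng), m_e) + gm)^2) -
      ng * sum(dev_er^2)
    df_err <- (ng - 1) * ne * (nr - 1)
    ms_err <- ss_err / df_err
    s2e <- max(ms_err, 0)
    s2ge <- max((ms_ge - ms_err) / nr, 0)
    s2g <- max((ms_g - ms_ge) / (ne * nr), 0)
    s2r <- max((ms_r - ms_err) / ng, 0)
    method <- "anova-ems"
  } else if (single_env) {
    warning("single environment: sigma2_GxE not separable, set to 0")
    gm <- mean(y)
    m_g <- tapply(y, line, mean)
    nr <- nlevels(rp)
    ms_g <- nr * sum((m_g - gm)^2) / (ng - 1)
    m_r <- tapply(y, rp, mean)
    ms_r <- ng * sum((m_r - gm)^2) / (nr - 1)
    ss_err <- sum((y - m_g[line] - m_r[rp] + gm)^2)
    ms_err <- ss_err / ((ng - 1) * (nr - 1))
    s2e <- max(ms_err, 0)
    s2g <- max((ms_g - ms_err) / nr, 0)
    s2ge <- 0
    s2r <- max((ms_r - ms_err) / ng, 0)
    method <- "anova-ems-single-env"
  } else {
    d <- data.frame(y = y, line = line, env = env,
                    er = interaction(env, rp), ge = interaction(line, env))
    fit <- lme4::lmer(y ~ (1 | line) + (1 | env) + (1 | ge) + (1 | er),
                      data = d,
                      control = lme4::lmerControl(
                        check.nobs.vs.nlev = "ignore",
                        check.nobs.vs.nRE = "ignore"))
    vc <- as.data.frame(lme4::VarCorr(fit))
    get <- function(g) {
      v <- vc$vcov[vc$grp == g]
      if (length(v) == 0) 0 else v
    }
    s2g <- get("line"); s2ge <- get("ge"); s2r <- get("er")
    s2e <- vc$vcov[vc$grp == "Residual"]
    method <- "reml-lmer"
  }
  structure(list(sigma2_G = unname(s2g), sigma2_GxE = unname(s2ge),
                 sigma2_rep = unname(s2r), sigma2_error = unname(s2e),
                 n_env = ne, n_rep = unname(nr_avg), method = method,
                 single_env = single_env),
            class = "variance_components")
}

#' Broad-sense heritability on an entry-mean basis
#'
#' `H2 = sigma2_G / (sigma2_G + sigma2_GxE / N_E + sigma2_error /
#' (N_E * N_R))`, the fraction of the variance among entry means that is
#' genotypic, given `N_E` environments and `N_R` replicates per
#' environment. No shrinkage or adjustment is applied.
#'
#' @param vc A `variance_components` object, or a list/vector supplying
#'   `sigma2_G`, `sigma2_GxE`, `sigma2_error`, `n_env`, `n_rep`.
#' @return Heritability in \[0, 1\].
#' @examples
#' broad_sense_heritability(list(sigma2_G = 2.64, sigma2_GxE = 0.71,
#'                               sigma2_error = 1.17, n_env = 11, n_rep = 3))
#' @export
broad_sense_heritability <- function(vc) {
  s2g <- vc$sigma2_G; s2ge <- vc$sigma2_GxE; s2e <- vc$sigma2_error
  ne <- vc$n_env; nr <- vc$n_rep
  stopifnot(s2g >= 0, s2ge >= 0, s2e >= 0, ne >= 1, nr >= 1)
  denom <- s2g + s2ge / ne + s2e / (ne * nr)
  if (denom <= 0) stop("all variance components are zero: H2 undefined")
  s2g / denom
}

#' Pairwise trait correlations on entry means
#'
#' Pearson correlations between trait BLUEs with two-sided p-values from
#' the t-distribution with n - 2 degrees of freedom; significance is
#' flagged at P < 0.001. Constant traits yield `NA` correlations.
#'
#' @param blues BLUE table from [compute_blues()] (first column `line`).
#' @param alpha Significance level for the `significant` flag.
#' @return List of matrices `r`, `p`, `n`, `significant`.
#' @export
trait_correlations <- function(blues, alpha = 0.001) {
  traits <- setdiff(names(blues), "line")
  k <- length(traits)
  r <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      x <- blues[[traits[i]]]; y <- blues[[traits[j]]]
      ok <- !is.na(x) & !is.na(y)
      n <- sum(ok)
      nmat[i, j] <- n
      if (n < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
      rr <- stats::cor(x[ok], y[ok])
      r[i, j] <- rr
      if (i == j) {
        p[i, j] <- 0
      } else {
        tt <- rr * sqrt((n - 2) / (1 - rr^2))
        p[i, j] <- 2 * stats::pt(-abs(tt), df = n - 2)
      }
    }
  }
  list(r = r, p = p, n = nmat, significant = p < alpha)
}
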