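#' Random 4:1 cross-validation splits
#'
#' Each replication draws an independent random split of the lines into a
#' training set of `round(train_fraction * n)` lines and a test set of the
#' remainder (144 / 36 for the canonical 180-line population). Per-
#' replication seeds are derived deterministically from the master seed so
#' any single replication can be reproduced in isolation.
#'
#' @param n_lines Number of lines (>= 10).
#' @param n_reps Number of replications (default 100).
#' @param train_fraction Training fraction (default 0.8).
#' @param seed Master seed.
#' @return List of length `n_reps`; each element has `train` and `test`
#'   integer index vectors.
#' @export
make_cv_splits <- function(n_lines, n_reps = 100, train_fraction = 0.8,
                           seed = 1L) {
  stopifnot(n_lines >= 10, n_reps >= 1, train_fraction > 0,
            train_fraction < 1)
  n_train <- round(train_fraction * n_lines)
  lapply(seq_len(n_reps), function(r) {
    set.seed((seed * 1000L + r) %% .Machine$integer.max)
    train <- sort(sample(n_lines, n_train))
    list(train = train, test = setdiff(seq_len(n_lines), train))
  })
}

#' Heritability-standardized prediction accuracy
#'
#' Pearson correlation between predicted and observed values divided by
#' the square root of the trait heritability, estimating the correlation
#' with the true genetic values.
#'
#' @param predicted,observed Numeric vectors (>= 3 pairs, nonconstant).
#' @param h2 Heritability in (0, 1\].
#' @return The standardized accuracy (may exceed 1 in absolute value only
#'   through sampling noise; bounded by 1/sqrt(h2)).
#' @export
standardized_accuracy <- function(predicted, observed, h2) {
  stopifnot(h2 > 0, h2 <= 1, length(predicted) == length(observed))
  if (length(predicted) < 3) stop("need at least 3 pairs")
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0)
    return(NA_real_)
  stats::cor(predicted, observed) / sqrt(h2)
}

# fit on the training rows of `coded`/`y` and predict the test rows
.fit_predict_method <- function(method, coded_tr, y_tr, coded_te,
                                bayescpi_iter, bayescpi_burn, seed,
                                mas_q = 0.1) {
  switch(method,
    rrblup = {
      fit <- fit_rrblup(y_tr, coded_tr)
      predict(fit, coded_te)
    },
    gblup = {
      fit <- fit_gblup(y_tr, build_grm(coded_tr), coded = coded_tr)
      predict(fit, coded_te)
    },
    egblup = {
      G <- build_grm(coded_tr)
      fit <- fit_gblup(y_tr, G, K2 = build_epistatic_kernel(G),
                       coded = coded_tr)
      predict(fit, coded_te)
    },
    bayescpi = {
      fit <- fit_bayescpi(y_tr, coded_tr, n_iter = bayescpi_iter,
                          burn_in = bayescpi_burn, seed = seed)
      predict(fit, coded_te)
    },
    mas = mas_fit_predict(coded_tr, y_tr, coded_te, q = mas_q),
    stop(sprintf("unknown method '%s'", method))
  )
}

#' Cross-validated prediction accuracy of one method
#'
#' Runs the chosen prediction method over a list of train/test splits,
#' computing the heritability-standardized accuracy in each replication on
#' the test lines only. For `"mas"` the full QTL detection (cofactor
#' selection, scan, FDR) is rerun inside every training set. For
#' `"bayescpi"` a reduced chain is used by default; pass the full
#' 20000/6000 settings for production runs.
#'
#' @param method One of `"rrblup"`, `"gblup"`, `"bayescpi"`, `"egblup"`,
#'   `"mas"`.
#' @param coded Imputed coded matrix for all lines.
#' @param y Entry means for all lines (same order as `coded` rows).
#' @param h2 Trait heritability used for standardization.
#' @param splits Split list from [make_cv_splits()]; reusing one list
#'   across methods gives paired comparisons.
#' @param bayescpi_iter,bayescpi_burn Chain settings for BayesCpi.
#' @param seed Base seed for the per-replication BayesCpi chains.
#' @param mas_q FDR level for the in-training QTL detection of MAS.
#' @return An `accuracy_result` list: `accuracy` (per replication), `mean`,
#'   `sd`, `method`.
#' @export
run_cv <- function(method, coded, y, h2, splits,
                   bayescpi_iter = 2000, bayescpi_burn = 600, seed = 1L,
                   mas_q = 0.1) {
  stopifnot(nrow(coded) == length(y))
  acc <- vapply(seq_along(splits), function(r) {
    sp <- splits[[r]]
    stopifnot(length(intersect(sp$train, sp$test)) == 0)
    pred <- .fit_predict_method(method,
                                coded[sp$train, , drop = FALSE], y[sp$train],
                                coded[sp$test, , drop = FALSE],
                                bayescpi_iter, bayescpi_burn,
                                seed = seed + r, mas_q = mas_q)
    standardized_accuracy(pred, y[sp$test], h2)
  }, numeric(1))
  structure(list(accuracy = acc, mean = mean(acc, na.rm = TRUE),
                 sd = stats::sd(acc, na.rm = TRUE), method = method),
            class = "accuracy_result")
}

#' Resource sweeps: training size, marker density, environments
#'
#' Evaluates mean cross-validated accuracy over a grid of one design
#' factor, holding everything else fixed:
#' \describe{
#'   \item{`training_size`}{per replication, a random subset of n lines
#'     trains the model and all remaining lines are tested.}
#'   \item{`marker_density`}{per grid value m, markers are taken evenly
#'     spaced along the map and standard 4:1 cross-validation is run.}
#'   \item{`environments`}{per grid value k, a random subset of k
#'     environments is drawn (without replacement) per replication,
#'     training entry means are recomputed from those environments only,
#'     and test lines are evaluated against their all-environment entry
#'     means.}
#' }
#'
#' @param factor One of `"training_size"`, `"marker_density"`,
#'   `"environments"`.
#' @param grid Numeric vector of grid values (lines, markers or
#'   environments). Values exceeding the available resources are skipped
#'   with a warning.
#' @param coded Imputed coded matrix for all lines.
#' @param y All-environment entry means (used as the evaluation truth).
#' @param h2 Heritability for standardization.
#' @param method Prediction method (default `"rrblup"`).
#' @param records Plot-level records; required for the environments sweep.
#' @param map Genetic map; required for the marker-density sweep.
#' @param n_reps Replications per grid value (default 100).
#' @param seed Master seed.
#' @param ... Passed to [run_cv()].
#' @return A `data.frame`: `factor`, `value`, `mean_accuracy`,
#'   `sd_accuracy`, `n_reps`.
#' @export
sweep_accuracy <- function(factor = c("training_size", "marker_density",
                                      "environments"),
                           grid, coded, y, h2, method = "rrblup",
                           records = NULL, map = NULL, n_reps = 100,
                           seed = 1L, ...) {
  factor <- match.arg(factor)
  n <- nrow(coded)
  out <- data.frame()
  for (v in grid) {
    if (factor == "training_size") {
      if (v >= n) {
        warning(sprintf("training size %d exceeds available lines; skipped", v))
        next
      }
      splits <- lapply(seq_len(n_reps), function(r) {
        set.seed((seed * 1000L + r) %% .Machine$integer.max)
        tr <- sort(sample(n, v))
        list(train = tr, test = setdiff(seq_len(n), tr))
      })
      res <- run_cv(method, coded, y, h2, splits, seed = seed, ...)
    } else if (factor == "marker_density") {
      if (is.null(map)) stop("marker-density sweep needs the map")
      if (v > ncol(coded)) {
        warning(sprintf("marker count %d exceeds available markers; skipped", v))
        next
      }
      sub <- evenly_spaced_markers(map, colnames(coded), v)
      splits <- make_cv_splits(n, n_reps = n_reps, seed = seed)
      res <- run_cv(method, coded[, sub, drop = FALSE], y, h2, splits,
                    seed = seed, ...)
    } else {
      if (is.null(records)) stop("environments sweep needs the plot records")
      envs <- unique(records$env)
      if (v > length(envs)) {
        warning(sprintf("%d environments requested, %d available; skipped",
                        v, length(envs)))
        next
      }
      splits <- make_cv_splits(n, n_reps = n_reps, seed = seed)
      acc <- vapply(seq_len(n_reps), function(r) {
        sp <- splits[[r]]
        set.seed((seed * 1000L + 500L + r) %% .Machine$integer.max)
        env_sub <- sample(envs, v)
        rec_sub <- records[records$env %in% env_sub, ]
        blues_sub <- compute_blues(rec_sub)
        tr_lines <- rownames(coded)[sp$train]
        y_tr <- blues_sub[[setdiff(names(blues_sub), "line")[1]]][
          match(tr_lines, blues_sub$line)]
        pred <- .fit_predict_method(method, coded[sp$train, , drop = FALSE],
                                    y_tr, coded[sp$test, , drop = FALSE],
                                    2000, 600, seed = seed + r)
        standardized_accuracy(pred, y[sp$test], h2)
      }, numeric(1))
      res <- list(accuracy = acc, mean = mean(acc, na.rm = TRUE),
                  sd = stats::sd(acc, na.rm = TRUE))
    }
    out <- rbind(out, data.frame(factor = factor, value = v,
                                 mean_accuracy = res$mean,
                                 sd_accuracy = res$sd, n_reps = n_reps))
  }
  out
}

#' Evenly spaced marker subset along the map
#'
#' @param map Genetic map.
#' @param markers Available marker ids.
#' @param m Number of markers wanted.
#' @return Character vector of `m` marker ids spread evenly along the
#'   genome (by cumulative map position).
#' @export
evenly_spaced_markers <- function(map, markers, m) {
  map <- map[map$marker %in% markers, ]
  map <- map[order(map$chrom, map$pos_cM), ]
  if (m >= nrow(map)) return(map$marker)
  idx <- unique(round(seq(1, nrow(map), length.out = m)))
  map$marker[idx]
}

#' Independent-population validation
#'
#' Trains RR-BLUP on the full training population, predicts a genetically
#' unrelated panel on the common markers (panel lines coded with the
#' training centering), and reports the accuracy standardized with the
#' training population's heritability.
#'
#' @param train_coded,train_y Training coded matrix and entry means.
#' @param h2_train Training-population heritability.
#' @param panel_coded Panel coded matrix (marker columns intersected with
#'   training; at least 50 common markers required).
#' @param panel_y Panel entry means (same line order).
#' @return List: `accuracy`, `correlation`, `n_common_markers`,
#'   `predictions`.
#' @export
independent_validation <- function(train_coded, train_y, h2_train,
                                   panel_coded, panel_y) {
  common <- intersect(colnames(train_coded), colnames(panel_coded))
  if (length(common) < 50)
    stop(sprintf("only %d common markers (need >= 50)", length(common)))
  fit <- fit_rrblup(train_y, train_coded[, common, drop = FALSE])
  pred <- predict(fit, panel_coded[, common, drop = FALSE])
  r <- stats::cor(pred, panel_y)
  list(accuracy = r / sqrt(h2_train), correlation = r,
       n_common_markers = length(common), predictions = pred)
}
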