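# Helpers -------------------------------------------------------------------

# residual sum of squares of y on X (intercept added), via QR
.rss <- function(X, y) {
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  sum(fit$residuals^2)
}

.bic <- function(rss, n, k) n * log(rss / n) + k * log(n)

#' Stepwise cofactor selection by BIC
#'
#' Forward selection with backward elimination after each inclusion on the
#' (representative) marker matrix. A move is accepted only if it strictly
#' lowers `BIC = n log(RSS/n) + k log(n)` (k counts fitted coefficients
#' including the intercept). Selection stops when no move improves the BIC
#' or when the size cap `floor(n/5)` is reached.
#'
#' @param coded Imputed coded matrix of representative markers (one per
#'   genetic bin, so no two cofactors can come from the same bin).
#' @param y Entry-mean (BLUE) vector, one value per line.
#' @param max_cofactors Size cap; defaults to `floor(length(y) / 5)`.
#' @return A `cofactor_set` list: `markers` (ordered ids), `indices`,
#'   `bic_trace` (BIC after each accepted move, starting from the
#'   intercept-only model).
#' @export
select_cofactors <- function(coded, y, max_cofactors = NULL) {
  n <- length(y)
  stopifnot(nrow(coded) == n)
  if (n <= 10) stop("need more than 10 lines")
  if (is.null(max_cofactors)) max_cofactors <- floor(n / 5)
  m <- ncol(coded)
  sel <- integer(0)
  rss0 <- sum((y - mean(y))^2)
  if (rss0 == 0) {
    return(structure(list(markers = character(0), indices = integer(0),
                          bic_trace = numeric(0)),
                     class = "cofactor_set"))
  }
  bic_cur <- .bic(rss0, n, 1)
  trace <- bic_cur
  repeat {
    improved <- FALSE
    # forward step: best single addition, computed by residualizing all
    # candidates against the current model
    if (length(sel) < max_cofactors) {
      Xc <- cbind(1, coded[, sel, drop = FALSE])
      q <- qr(Xc)
      ry <- qr.resid(q, y)
      cand <- setdiff(seq_len(m), sel)
      RX <- qr.resid(q, coded[, cand, drop = FALSE])
      ssx <- colSums(RX^2)
      ok <- ssx > 1e-10
      if (any(ok)) {
        gain <- (crossprod(RX, ry)[, 1])^2 / pmax(ssx, 1e-300)
        gain[!ok] <- 0
        best <- which.max(gain)
        rss_new <- sum(ry^2) - gain[best]
        bic_new <- .bic(max(rss_new, 1e-300), n, length(sel) + 2)
        if (bic_new < bic_cur - 1e-10) {
          sel <- c(sel, cand[best])
          bic_cur <- bic_new
          trace <- c(trace, bic_cur)
          improved <- TRUE
        }
      }
    }
    # backward steps: drop any cofactor whose removal lowers BIC
    if (length(sel) > 1) {
      repeat {
        dropped <- FALSE
        for (d in seq_along(sel)) {
          rest <- sel[-d]
          rss_d <- .rss(coded[, rest, drop = FALSE], y)
          bic_d <- .bic(max(rss_d, 1e-300), n, length(rest) + 1)
          if (bic_d < bic_cur - 1e-10) {
            sel <- rest
            bic_cur <- bic_d
            trace <- c(trace, bic_cur)
            dropped <- TRUE
            break
          }
        }
        if (!dropped) break
      }
    }
    if (!improved) break
  }
  structure(list(markers = colnames(coded)[sel], indices = sel,
                 bic_trace = trace),
            class = "cofactor_set")
}

#' Cofactor-based genome-wide QTL scan
#'
#' For every marker, compares the full model (tested marker + cofactors)
#' against the reduced model (cofactors only) with a partial F-test.
#' Cofactors collinear with the tested marker (`r^2 > collinearity_r2`,
#' same marker, or same genetic bin if `bins` is given) are dropped from
#' both models for that test. Markers that leave the full model
#' rank-deficient are skipped (`NA` p-value, `skipped` flag).
#'
#' @param coded Imputed coded matrix (the markers to test).
#' @param y BLUE vector.
#' @param cofactors A `cofactor_set` from [select_cofactors()] (its markers
#'   must be columns of `coded`), or `NULL` for a plain single-marker scan.
#' @param collinearity_r2 Cofactor exclusion threshold (default 0.8).
#' @param bins Optional named vector mapping marker id to bin id.
#' @return A `data.frame`: `marker`, `p_value`, `effect`, `skipped`.
#' @export
scan_genome <- function(coded, y, cofactors = NULL, collinearity_r2 = 0.8,
                        bins = NULL) {
  n <- length(y)
  stopifnot(nrow(coded) == n)
  cof_idx <- if (is.null(cofactors)) integer(0) else
    match(cofactors$markers, colnames(coded))
  if (anyNA(cof_idx)) stop("cofactor markers not present in coded matrix")
  m <- ncol(coded)
  p_value <- effect <- rep(NA_real_, m)
  skipped <- logical(m)
  Xcof <- coded[, cof_idx, drop = FALSE]
  r2_with_cof <- if (length(cof_idx) > 0)
    suppressWarnings(stats::cor(coded, Xcof))^2 else
    matrix(0, m, 0)
  for (j in seq_len(m)) {
    drop <- logical(length(cof_idx))
    if (length(cof_idx) > 0) {
      drop <- cof_idx == j | (!is.na(r2_with_cof[j, ]) &
                                r2_with_cof[j, ] > collinearity_r2)
      if (!is.null(bins)) {
        drop <- drop | (bins[colnames(coded)[cof_idx]] ==
                          bins[colnames(coded)[j]])
      }
    }
    Xr <- cbind(1, Xcof[, !drop, drop = FALSE])
    qr_r <- qr(Xr)
    Xf <- cbind(Xr, coded[, j])
    qf <- qr(Xf)
    if (qf$rank <= qr_r$rank) {  # marker adds nothing estimable
      skipped[j] <- TRUE
      next
    }
    rss_r <- sum(qr.resid(qr_r, y)^2)
    res_f <- qr.resid(qf, y)
    rss_f <- sum(res_f^2)
    df2 <- n - qf$rank
    if (df2 <= 0) {
      skipped[j] <- TRUE
      next
    }
    Fstat <- (rss_r - rss_f) / (rss_f / df2)
    p_value[j] <- stats::pf(Fstat, 1, df2, lower.tail = FALSE)
    cf <- qr.coef(qf, y)
    effect[j] <- cf[length(cf)]
  }
  data.frame(marker = colnames(coded), p_value = p_value, effect = effect,
             skipped = skipped, stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg FDR significance flags
#'
#' Step-up procedure at level `q`: with ordered p-values p_(1) <= ... <=
#' p_(m), the largest k with p_(k) <= k q / m and all smaller p-values are
#' declared significant.
#'
#' @param p_values Vector of p-values in (0, 1\]; `NA`s are never flagged
#'   and do not count toward m.
#' @param q FDR level (default 0.1).
#' @return Logical vector of significance flags, same length as input.
#' @export
fdr_adjust <- function(p_values, q = 0.1) {
  flags <- rep(FALSE, length(p_values))
  ok <- !is.na(p_values)
  p <- p_values[ok]
  m <- length(p)
  if (m == 0) return(flags)
  o <- order(p)
  thresh <- seq_len(m) * q / m
  below <- p[o] <= thresh
  if (any(below)) {
    kmax <- max(which(below))
    sig <- logical(m)
    sig[o[seq_len(kmax)]] <- TRUE
    flags[ok] <- sig
  }
  flags
}

#' Phenotypic variance explained by significant markers
#'
#' Joint PVE is 100 times the adjusted R^2 of the multiple regression of
#' the entry means on all significant markers (after dropping exact
#' within-set collinearity). Each marker's own PVE is its last-in
#' increment: the drop in adjusted R^2 when it is removed from the joint
#' model, floored at 0.
#'
#' @param coded Imputed coded matrix.
#' @param y BLUE vector.
#' @param significant Character vector of significant marker ids (or
#'   integer indices).
#' @return List with `per_marker` (named numeric, percent) and `joint`
#'   (percent).
#' @export
estimate_pve <- function(coded, y, significant) {
  if (is.character(significant))
    significant <- match(significant, colnames(coded))
  significant <- significant[!is.na(significant)]
  if (length(significant) == 0)
    return(list(per_marker = numeric(0), joint = 0))
  n <- length(y)
  X <- coded[, significant, drop = FALSE]
  # drop exactly collinear columns (same bin duplicates)
  q <- qr(cbind(1, X))
  keep_cols <- q$pivot[seq_len(q$rank)] - 1
  keep_cols <- keep_cols[keep_cols > 0]
  X <- X[, sort(keep_cols), drop = FALSE]
  k <- ncol(X)
  if (k >= n - 1) {
    warning("more significant markers than lines allow: ridge fallback")
    Xc <- scale(X, scale = FALSE)
    yc <- y - mean(y)
    lambda <- 1e-3 * sum(Xc^2) / k
    b <- solve(crossprod(Xc) + diag(lambda, k), crossprod(Xc, yc))
    r2 <- 1 - sum((yc - Xc %*% b)^2) / sum(yc^2)
    return(list(per_marker = stats::setNames(rep(NA_real_, k), colnames(X)),
                joint = 100 * max(r2, 0)))
  }
  adj_r2 <- function(Xm) {
    p <- ncol(Xm)
    rss <- .rss(Xm, y)
    tss <- sum((y - mean(y))^2)
    r2 <- 1 - rss / tss
    1 - (1 - r2) * (n - 1) / (n - p - 1)
  }
  joint <- adj_r2(X)
  per <- vapply(seq_len(k), function(i) {
    max(joint - adj_r2(X[, -i, drop = FALSE]), 0)
  }, numeric(1))
  if (k == 1) per <- max(joint, 0)
  list(per_marker = stats::setNames(100 * per, colnames(X)),
       joint = 100 * max(joint, 0))
}

#' Full QTL detection pipeline on one data set
#'
#' Cofactor selection, genome-wide scan and BH-FDR flagging in one call.
#'
#' @inheritParams scan_genome
#' @param q FDR level.
#' @param max_cofactors Passed to [select_cofactors()].
#' @param compute_pve Attach the [estimate_pve()] result for the
#'   significant set (skippable when only the significance flags are
#'   needed, e.g. inside cross-validated marker-assisted selection).
#' @return A `data.frame` like [scan_genome()] plus `significant`, with
#'   attributes `cofactors` and (if requested) `pve`.
#' @export
qtl_scan <- function(coded, y, q = 0.1, collinearity_r2 = 0.8,
                     bins = NULL, max_cofactors = NULL, compute_pve = TRUE) {
  cof <- select_cofactors(coded, y, max_cofactors = max_cofactors)
  res <- scan_genome(coded, y, cof, collinearity_r2 = collinearity_r2,
                     bins = bins)
  res$significant <- fdr_adjust(res$p_value, q = q)
  attr(res, "cofactors") <- cof
  if (compute_pve)
    attr(res, "pve") <- estimate_pve(coded, y, res$marker[res$significant])
  res
}

#' Marker-assisted selection: fit on training lines, predict test lines
#'
#' Reruns the entire QTL detection (cofactor selection, scan, FDR) inside
#' the training set, fits an ordinary multiple regression on the
#' training-significant markers and predicts the test lines as
#' `intercept + coded genotypes x coefficients`. An empty significant set
#' predicts the training mean for every test line.
#'
#' @param train_coded,train_y Training coded matrix and entry means.
#' @param test_coded Test coded matrix (same marker columns).
#' @param q FDR level used inside the training set.
#' @param ... Passed to [qtl_scan()].
#' @return Numeric vector of test-line predictions, with attribute
#'   `"markers"` (the selected marker ids).
#' @export
mas_fit_predict <- function(train_coded, train_y, test_coded, q = 0.1, ...) {
  scan <- qtl_scan(train_coded, train_y, q = q, compute_pve = FALSE, ...)
  sig <- scan$marker[scan$significant & !is.na(scan$p_value)]
  if (length(sig) == 0) {
    pred <- rep(mean(train_y), nrow(test_coded))
    attr(pred, "markers") <- character(0)
    return(pred)
  }
  X <- cbind(1, train_coded[, sig, drop = FALSE])
  qx <- qr(X)
  keep <- qx$pivot[seq_len(qx$rank)]
  X <- X[, keep, drop = FALSE]
  b <- qr.coef(qr(X), train_y)
  Xt <- cbind(1, test_coded[, sig, drop = FALSE])[, keep, drop = FALSE]
  pred <- as.vector(Xt %*% b)
  attr(pred, "markers") <- sig
  pred
}
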