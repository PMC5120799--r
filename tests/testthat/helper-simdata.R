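# Shared fixture builders: everything is generated in code at test time.

# small map + DH population + coded matrix, used by many tests
tiny_population <- function(n_lines = 60, n_chrom = 3, markers_per_chrom = 30,
                            chrom_length = 100, seed = 11) {
  map <- make_genetic_map(n_chrom, markers_per_chrom, chrom_length)
  geno <- simulate_dh_population(map, n_lines, seed = seed)
  coded <- impute_missing(encode_finf(geno))
  list(map = map, geno = geno, coded = coded)
}

# a call matrix built explicitly from per-marker call vectors
call_matrix <- function(...) {
  cols <- list(...)
  m <- do.call(cbind, cols)
  rownames(m) <- sprintf("L%02d", seq_len(nrow(m)))
  if (is.null(names(cols)) || any(names(cols) == ""))
    colnames(m) <- sprintf("M%02d", seq_len(ncol(m)))
  m
}

# brute-force bin oracle: exhaustive pairwise r^2 = 1 check + connected
# components by repeated expansion (independent of the union-find in the
# package)
oracle_bins <- function(geno) {
  coded <- encode_finf(geno)
  m <- ncol(coded)
  adj <- matrix(FALSE, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      x <- coded[, i]; y <- coded[, j]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) >= 3 && sd(x[ok]) > 0 && sd(y[ok]) > 0) {
        adj[i, j] <- abs(cor(x[ok], y[ok])) > 1 - 1e-9
      }
    }
  }
  diag(adj) <- TRUE
  comp <- rep(NA_integer_, m)
  cur <- 0L
  for (i in seq_len(m)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    frontier <- i
    comp[i] <- cur
    while (length(frontier) > 0) {
      nb <- which(apply(adj[frontier, , drop = FALSE], 2, any) & is.na(comp))
      comp[nb] <- cur
      frontier <- nb
    }
  }
  comp
}

# exhaustive best-subset BIC oracle over <= 10 markers
oracle_best_subset_bic <- function(coded, y) {
  m <- ncol(coded)
  stopifnot(m <= 10)
  n <- length(y)
  best <- integer(0)
  best_bic <- n * log(sum((y - mean(y))^2) / n) + log(n)
  for (size in seq_len(m)) {
    for (sub in utils::combn(m, size, simplify = FALSE)) {
      X <- cbind(1, coded[, sub, drop = FALSE])
      rss <- sum(lm.fit(X, y)$residuals^2)
      bic <- n * log(max(rss, 1e-300) / n) + (size + 1) * log(n)
      if (bic < best_bic) {
        best <- sub
        best_bic <- bic
      }
    }
  }
  best
}
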