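#' Per-marker quality statistics
#'
#' Missing rate over all calls; minor allele frequency and heterozygosity
#' over non-missing calls. Allele counting treats a heterozygote as one copy
#' of each parental allele. Markers with no observed calls are flagged
#' monomorphic with `NA` frequencies.
#'
#' @param geno Call matrix with codes \{2, 0, 1, NA\} (see
#'   [simulate_dh_population()]).
#' @return A `data.frame` with one row per marker: `marker`, `missing_rate`,
#'   `maf`, `het_rate`, `monomorphic`.
#' @export
compute_marker_stats <- function(geno) {
  if (length(geno) == 0 || nrow(geno) == 0 || ncol(geno) == 0)
    stop("empty genotype matrix")
  n <- nrow(geno)
  n_obs <- colSums(!is.na(geno))
  n_p1 <- colSums(geno == 2L, na.rm = TRUE)
  n_het <- colSums(geno == 1L, na.rm = TRUE)
  p1_freq <- ifelse(n_obs > 0, (2 * n_p1 + n_het) / (2 * n_obs), NA_real_)
  maf <- pmin(p1_freq, 1 - p1_freq)
  data.frame(
    marker = colnames(geno),
    missing_rate = (n - n_obs) / n,
    maf = maf,
    het_rate = ifelse(n_obs > 0, n_het / n_obs, NA_real_),
    monomorphic = is.na(maf) | maf == 0,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Marker quality-control filter
#'
#' Removes markers that are monomorphic, have a missing rate above
#' `max_missing`, a minor allele frequency below `min_maf`, or a
#' heterozygosity above `max_het`; the line set is never changed. The
#' default thresholds are the standard 5\% rules for DH material.
#'
#' @inheritParams compute_marker_stats
#' @param max_missing,min_maf,max_het Thresholds in \[0, 1\].
#' @return The filtered call matrix (possibly with zero columns).
#' @export
filter_markers <- function(geno, max_missing = 0.05, min_maf = 0.05,
                           max_het = 0.05) {
  stopifnot(max_missing >= 0, max_missing <= 1, min_maf >= 0, min_maf <= 1,
            max_het >= 0, max_het <= 1)
  st <- compute_marker_stats(geno)
  keep <- !st$monomorphic & st$missing_rate <= max_missing &
    st$maf >= min_maf & st$het_rate <= max_het
  keep[is.na(keep)] <- FALSE
  geno[, keep, drop = FALSE]
}

#' F-infinity coding of homozygous marker genotypes
#'
#' Codes the reference parent's homozygote as +1, the other homozygote as
#' -1 and heterozygotes as 0 (DH lines should carry none; coding them 0 is
#' a robustness concession). Missing calls stay `NA` for later imputation.
#'
#' @inheritParams compute_marker_stats
#' @param reference_parent `"parent1"` (call code 2 maps to +1) or
#'   `"parent2"`.
#' @return Numeric lines x markers matrix with values in \{+1, -1, 0, NA\}
#'   and attribute `"reference_parent"`.
#' @export
encode_finf <- function(geno, reference_parent = c("parent1", "parent2")) {
  reference_parent <- match.arg(reference_parent)
  bad <- !(geno %in% c(0L, 1L, 2L)) & !is.na(geno)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("unknown call code at line '%s', marker '%s'",
                 rownames(geno)[(i - 1) %% nrow(geno) + 1],
                 colnames(geno)[(i - 1) %/% nrow(geno) + 1]))
  }
  coded <- geno - 1
  mode(coded) <- "double"
  if (reference_parent == "parent2") coded <- -coded
  attr(coded, "reference_parent") <- reference_parent
  coded
}

#' Mean imputation of missing coded calls
#'
#' Replaces each missing entry by the column mean of the observed codes;
#' observed entries are untouched.
#'
#' @param coded Coded matrix from [encode_finf()].
#' @return The imputed matrix.
#' @export
impute_missing <- function(coded) {
  full_na <- colSums(!is.na(coded)) == 0
  if (any(full_na))
    stop(sprintf("marker(s) with no observed calls: %s",
                 paste(colnames(coded)[full_na], collapse = ", ")))
  cm <- colMeans(coded, na.rm = TRUE)
  idx <- which(is.na(coded), arr.ind = TRUE)
  if (nrow(idx) > 0) coded[idx] <- cm[idx[, 2]]
  coded
}

#' Pairwise linkage disequilibrium as squared Pearson correlation
#'
#' Computed over the lines with non-missing calls at both markers; at least
#' three such lines are required. If either marker has zero variance on the
#' jointly observed lines the LD is undefined and `NA` is returned.
#'
#' @param coded Coded matrix.
#' @param i,j Marker indices or names.
#' @return `r^2` in \[0, 1\], or `NA`.
#' @export
pairwise_ld <- function(coded, i, j) {
  x <- coded[, i]; y <- coded[, j]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stop("fewer than 3 jointly observed lines")
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Genetic bins and representative markers
#'
#' Groups markers into genetic bins: equivalence classes of markers whose
#' observed calls are identical or exactly complementary on the jointly
#' observed lines (pairwise r^2 = 1), i.e. markers separated by no observed
#' recombination event. Because missingness can make the r^2 = 1 relation
#' non-transitive, bins are the connected components of the r^2 = 1 graph,
#' built per chromosome (genetic bins are local by nature). From each bin
#' one representative is chosen: least missing rate, ties broken by
#' presence of a physical position, then smallest bp, then marker id.
#'
#' @inheritParams compute_marker_stats
#' @param stats Marker statistics from [compute_marker_stats()]; computed
#'   if `NULL`.
#' @param map Genetic map restricted to (or superset of) the matrix's
#'   markers.
#' @return A `data.frame` with one row per marker: `marker`, `chrom`,
#'   `bin_id`, `representative` (logical).
#' @export
bin_and_select_representatives <- function(geno, stats = NULL, map) {
  if (is.null(stats)) stats <- compute_marker_stats(geno)
  map <- map[match(colnames(geno), map$marker), , drop = FALSE]
  if (anyNA(map$marker)) stop("markers missing from the map")
  coded <- encode_finf(geno)
  bin_id <- integer(ncol(geno))
  next_bin <- 0L
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    r2 <- suppressWarnings(
      stats::cor(coded[, idx, drop = FALSE],
                 use = "pairwise.complete.obs"))^2
    adj <- !is.na(r2) & r2 > 1 - 1e-9
    comp <- connected_components(adj)
    bin_id[idx] <- comp + next_bin
    next_bin <- next_bin + max(comp)
  }
  has_bp <- if ("pos_bp" %in% names(map)) !is.na(map$pos_bp) else
    rep(FALSE, nrow(map))
  bp <- if ("pos_bp" %in% names(map)) map$pos_bp else rep(NA_real_, nrow(map))
  rep_flag <- logical(ncol(geno))
  for (b in unique(bin_id)) {
    members <- which(bin_id == b)
    ord <- order(stats$missing_rate[members], !has_bp[members],
                 bp[members], stats$marker[members], na.last = TRUE)
    rep_flag[members[ord[1]]] <- TRUE
  }
  data.frame(marker = colnames(geno), chrom = map$chrom,
             bin_id = sprintf("bin%05d", bin_id),
             representative = rep_flag,
             stringsAsFactors = FALSE, row.names = NULL)
}

# connected components of a symmetric logical adjacency matrix
# (union-find; small helper used by the binning step)
connected_components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (i in seq_len(n)) {
    for (j in which(adj[i, ])) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Greedy LD pruning
#'
#' Visits markers in map order within each chromosome and keeps a marker
#' only if its r^2 with every previously kept marker on the same chromosome
#' is at most `r2_max`. The kept set therefore has all pairwise
#' within-chromosome r^2 <= `r2_max`. Exact duplicates (r^2 = 1) are
#' always dropped, even at `r2_max = 1`.
#'
#' @param coded Coded (imputed or complete) matrix.
#' @param map Genetic map covering the matrix's markers.
#' @param r2_max LD threshold (default 0.95).
#' @return The pruned coded matrix.
#' @export
prune_ld <- function(coded, map, r2_max = 0.95) {
  map <- map[match(colnames(coded), map$marker), , drop = FALSE]
  keep <- character(0)
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    idx <- idx[order(map$pos_cM[idx])]
    kept_cols <- NULL
    for (i in idx) {
      x <- coded[, i]
      if (stats::sd(x, na.rm = TRUE) == 0) next
      if (is.null(kept_cols)) {
        kept_cols <- i
      } else {
        r2 <- suppressWarnings(
          stats::cor(x, coded[, kept_cols, drop = FALSE],
                     use = "pairwise.complete.obs"))^2
        if (all(is.na(r2) | (r2 <= r2_max & r2 < 1 - 1e-9)))
          kept_cols <- c(kept_cols, i)
      }
    }
    keep <- c(keep, colnames(coded)[kept_cols])
  }
  coded[, keep, drop = FALSE]
}

#' Quality-control report
#'
#' One call that runs the QC filter, binning and representative selection
#' and returns a per-marker report table.
#'
#' @inheritParams bin_and_select_representatives
#' @inheritParams filter_markers
#' @return A `data.frame`: `marker`, `missing_rate`, `maf`, `het_rate`,
#'   `kept`, `bin_id`, `representative` (the last two `NA` for markers
#'   removed by QC).
#' @export
qc_report <- function(geno, map, max_missing = 0.05, min_maf = 0.05,
                      max_het = 0.05) {
  st <- compute_marker_stats(geno)
  filtered <- filter_markers(geno, max_missing, min_maf, max_het)
  st$kept <- st$marker %in% colnames(filtered)
  st$bin_id <- NA_character_
  st$representative <- NA
  if (ncol(filtered) > 0) {
    bins <- bin_and_select_representatives(filtered, map = map)
    i <- match(bins$marker, st$marker)
    st$bin_id[i] <- bins$bin_id
    st$representative[i] <- bins$representative
  }
  st
}
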