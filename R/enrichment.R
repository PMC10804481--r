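#' Permutation test for interval overlap
#'
#' Tests whether a set of query loci (e.g. crossover intervals) overlaps
#' a feature set (e.g. genes) more or less often than expected by
#' chance. The observed statistic is the number of queries overlapping at
#' least one feature by at least 1 bp. Each permutation places the same
#' number of loci, with the same widths, independently and uniformly at
#' random within the background regions (placements weighted by the
#' number of valid start positions per background interval; overlaps
#' among placed loci are permitted). Empirical p-values use the add-one
#' estimator `(r + 1) / (n + 1)`, so the smallest attainable p is
#' `1 / (n_perm + 1)`.
#'
#' @param queries,features,background data.frames with `chrom`, `start`,
#'   `end` (0-based half-open). Every query must fit inside at least one
#'   background interval.
#' @param n_perm Number of permutations.
#' @param seed Optional RNG seed.
#' @param keep_distribution Retain the permuted counts in the result.
#' @return Object of class `"permutation_test"`: observed count, permuted
#'   mean and quantiles, `p_enrich`, `p_deplete`, `n_perm`.
#' @export
permute_overlap <- function(queries, features, background, n_perm = 10000,
                            seed = NULL, keep_distribution = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  nq <- nrow(queries)
  if (nq == 0) stop("no query intervals")
  qgr <- .df_to_gr(queries)
  fgr <- GenomicRanges::reduce(.df_to_gr(features))
  observed <- sum(IRanges::overlapsAny(qgr, fgr))

  # concatenated-genome coordinates: offset chromosomes into disjoint
  # ranges separated by gaps wider than any query
  widths <- queries$end - queries$start
  if (any(widths <= 0)) stop("queries must have positive width")
  bg <- background[order(background$chrom, background$start), , drop = FALSE]
  chroms <- unique(bg$chrom)
  span <- vapply(chroms, function(c) max(bg$end[bg$chrom == c]), numeric(1))
  gap <- max(widths) + 1
  offset <- stats::setNames(cumsum(c(0, span[-length(span)] + gap)), chroms)
  bg_s <- bg$start + offset[bg$chrom]
  bg_e <- bg$end + offset[bg$chrom]
  f_s <- features$start + offset[as.character(features$chrom)]
  f_e <- features$end + offset[as.character(features$chrom)]
  fo <- order(f_s)
  fint <- .merge_intervals(f_s[fo], f_e[fo])

  hits <- matrix(FALSE, n_perm, nq)
  for (w in unique(widths)) {
    cols <- which(widths == w)
    valid <- bg_e - bg_s - w + 1
    usable <- valid > 0
    if (!any(usable)) {
      stop("a query of width ", w, " fits inside no background interval")
    }
    nn <- n_perm * length(cols)
    iv <- sample.int(sum(usable), nn, replace = TRUE,
                     prob = valid[usable])
    s <- bg_s[usable][iv] + floor(stats::runif(nn) * valid[usable][iv])
    # placed [s, s + w) overlaps a feature [fs, fe) iff s in [fs-w+1, fe-1]
    lo <- fint$start - w + 1
    hi <- fint$end - 1
    m <- .merge_intervals(lo, hi + 1)   # half-open hit regions
    bounds <- as.vector(rbind(m$start, m$end))
    inside <- findInterval(s, bounds) %% 2 == 1
    hits[, cols] <- inside
  }
  perm_counts <- rowSums(hits)
  res <- structure(list(
    observed = observed, n_perm = n_perm,
    p_enrich = (sum(perm_counts >= observed) + 1) / (n_perm + 1),
    p_deplete = (sum(perm_counts <= observed) + 1) / (n_perm + 1),
    perm_mean = mean(perm_counts),
    perm_quantiles = stats::quantile(perm_counts, c(0.025, 0.5, 0.975)),
    statistic = "n_overlapping_queries"),
    class = "permutation_test")
  if (keep_distribution) res$perm_counts <- perm_counts
  res
}

.df_to_gr <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end))
}

.merge_intervals <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  list(start = c(out_s, ms), end = c(out_e, me))
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("Permutation test (%s): observed %.4g, permuted mean %.4g (n = %d)\n",
              x$statistic, x$observed, x$perm_mean, x$n_perm))
  cat(sprintf("  p(enrich) = %.4g, p(deplete) = %.4g\n",
              x$p_enrich, x$p_deplete))
  invisible(x)
}

#' Pairwise nucleotide diversity over a gene
#'
#' Computes per-site and per-gene pairwise diversity (pi) from a matrix of
#' haploid accession calls. Per qualifying site (missing-call fraction at
#' most `max_missing` and at least two non-missing calls),
#' `pi = 2 j (m - j) / (m (m - 1))` over the `m` non-missing calls of
#' which `j` carry the alternate allele; this equals the mean pairwise
#' difference over all accession pairs. The per-gene value is the mean
#' over qualifying sites, monomorphic covered sites included.
#'
#' @param genotypes Accession x site matrix with values 0 (reference),
#'   1 (alternate) or NA (missing; heterozygous calls should be set NA
#'   upstream for an inbred, effectively haploid species).
#' @param max_missing Maximum missing-call fraction per site.
#' @return list: `pi` (per-gene mean; NA when no site qualifies),
#'   `per_site` (data.frame site, m, j, pi, qualifying), `n_sites` used.
#' @export
pairwise_pi <- function(genotypes, max_missing = 0.15) {
  if (nrow(genotypes) < 2) stop("need at least 2 accessions")
  n_acc <- nrow(genotypes)
  m <- colSums(!is.na(genotypes))
  j <- colSums(genotypes == 1, na.rm = TRUE)
  qual <- (1 - m / n_acc) <= max_missing & m >= 2
  pi_site <- ifelse(m >= 2, 2 * j * (m - j) / (m * (m - 1)), NA_real_)
  per_site <- data.frame(site = seq_len(ncol(genotypes)), m = m, j = j,
                         pi = pi_site, qualifying = qual)
  list(pi = if (any(qual)) mean(pi_site[qual]) else NA_real_,
       per_site = per_site, n_sites = sum(qual))
}

#' Permutation test of zone-gene diversity against arm genes
#'
#' Compares the median per-gene diversity of zone genes (e.g. genes in
#' the low-recombining zones) with the medians of repeated equal-sized
#' draws (without replacement) from the chromosome-arm gene pool.
#' Add-one empirical p-values; enrichment means the observed median is
#' greater.
#'
#' @param zone_pi Per-gene pi values for the zone genes.
#' @param arm_pi Per-gene pi values for the arm gene pool (must be larger
#'   than the zone set).
#' @param n_perm Number of permutations.
#' @param seed Optional RNG seed.
#' @param keep_distribution Retain permuted medians.
#' @return A `"permutation_test"` object on the median statistic.
#' @export
diversity_permutation <- function(zone_pi, arm_pi, n_perm = 1000,
                                  seed = NULL, keep_distribution = FALSE) {
  # sorting makes the result invariant to input record order
  zone_pi <- sort(zone_pi[!is.na(zone_pi)])
  arm_pi <- sort(arm_pi[!is.na(arm_pi)])
  k <- length(zone_pi)
  if (k == 0) stop("zone gene set is empty")
  if (length(arm_pi) <= k) stop("arm gene pool must exceed the zone set size")
  if (!is.null(seed)) set.seed(seed)
  observed <- stats::median(zone_pi)
  perm <- vapply(seq_len(n_perm),
                 function(i) stats::median(sample(arm_pi, k)), numeric(1))
  res <- structure(list(
    observed = observed, n_perm = n_perm,
    p_enrich = (sum(perm >= observed) + 1) / (n_perm + 1),
    p_deplete = (sum(perm <= observed) + 1) / (n_perm + 1),
    perm_mean = mean(perm),
    perm_quantiles = stats::quantile(perm, c(0.025, 0.5, 0.975)),
    statistic = "median_pi"), class = "permutation_test")
  if (keep_distribution) res$perm_medians <- perm
  res
}

#' Mask and coverage-filter genes for diversity analysis
#'
#' Removes genes overlapping any mask region (repeats, organellar
#' insertions, assembly inversions) and genes whose sequencing coverage
#' across accessions falls below `min_coverage` of their length.
#'
#' @param genes data.frame with `chrom`, `start`, `end`, optional
#'   `covered_fraction` and `region_class`.
#' @param masks data.frame (chrom, start, end) or NULL.
#' @param min_coverage Minimum covered fraction.
#' @return list: `genes` (retained rows), `n_masked`, `n_low_coverage`,
#'   and `retained_by_class` when `region_class` is present.
#' @export
mask_and_filter_genes <- function(genes, masks = NULL, min_coverage = 0.5) {
  keep <- rep(TRUE, nrow(genes))
  n_masked <- 0L
  if (!is.null(masks) && nrow(masks) > 0) {
    hit <- IRanges::overlapsAny(.df_to_gr(genes), .df_to_gr(masks))
    n_masked <- sum(hit)
    keep <- keep & !hit
  }
  n_low <- 0L
  if ("covered_fraction" %in% names(genes)) {
    low <- genes$covered_fraction < min_coverage
    n_low <- sum(low & keep)
    keep <- keep & !low
  }
  out <- list(genes = genes[keep, , drop = FALSE], n_masked = n_masked,
              n_low_coverage = n_low)
  if ("region_class" %in% names(genes)) {
    out$retained_by_class <- table(genes$region_class[keep])
  }
  out
}
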