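#' Windowed genetic map from crossover calls
#'
#' Tallies crossover calls into non-overlapping windows along each
#' chromosome by call midpoint and converts the counts to genetic
#' distance: `cM = 100 * count / n_gametes` and `cM/Mb = cM / window Mb`.
#' Calls may carry fractional `weight`s (e.g. from ambiguous-boundary
#' allocation); summing window cM over a chromosome always equals
#' `100 * total weight / n_gametes`.
#'
#' @param calls data.frame with `chrom`, `start`, `end` and optional
#'   `weight` (default 1 per call).
#' @param n_gametes Number of gametes sampled by the population: one per
#'   backcross plant, two per F2 plant.
#' @param chrom_length Chromosome length in bp (named vector for several
#'   chromosomes).
#' @param window_size Tally window in bp.
#' @return data.frame (chrom, start, end, count, cm, cm_mb).
#' @export
windowed_map <- function(calls, n_gametes, chrom_length,
                         window_size = 1e5) {
  if (n_gametes <= 0) stop("'n_gametes' must be positive")
  chroms <- if (length(chrom_length) > 1) names(chrom_length)
            else unique(c(as.character(calls$chrom), "chr1"))[1]
  out <- list()
  for (chr in chroms) {
    L <- if (length(chrom_length) > 1) chrom_length[[chr]] else chrom_length
    starts <- seq(0, L - 1, by = window_size)
    ends <- pmin(starts + window_size, L)
    sel <- calls$chrom == chr
    mid <- (calls$start[sel] + calls$end[sel]) / 2
    if (any(mid < 0 | mid >= L)) stop("crossover call outside chromosome bounds")
    w <- if ("weight" %in% names(calls)) calls$weight[sel] else rep(1, sum(sel))
    idx <- findInterval(mid, starts)
    count <- as.numeric(tapply(w, factor(idx, levels = seq_along(starts)),
                               sum))
    count[is.na(count)] <- 0
    cm <- 100 * count / n_gametes
    out[[chr]] <- data.frame(chrom = chr, start = starts, end = ends,
                             count = count, cm = cm,
                             cm_mb = cm / ((ends - starts) / 1e6),
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Delineate the non-recombining zone (NRZ)
#'
#' The NRZ is the maximal run of consecutive zero-crossover windows that
#' contains (or maximally overlaps) the main satellite array. When every
#' window overlapping the array contains crossovers, no NRZ is returned
#' and a warning is raised.
#'
#' @param windows A [windowed_map()] for one chromosome.
#' @param satellite data.frame (chrom, start, end) of satellite-array
#'   features (0-based half-open).
#' @return One-row data.frame (chrom, start, end) or a zero-row frame when
#'   no crossover-free run overlaps the array.
#' @export
define_nrz <- function(windows, satellite) {
  chr <- windows$chrom[1]
  sat <- satellite[satellite$chrom == chr, , drop = FALSE]
  if (nrow(sat) == 0) stop("no satellite feature on chromosome ", chr)
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE)
  zero <- windows$count == 0
  if (!any(zero)) {
    warning("no crossover-free window on ", chr, "; NRZ undefined")
    return(empty)
  }
  r <- rle(zero)
  last <- cumsum(r$lengths)
  first <- last - r$lengths + 1L
  runs <- data.frame(first = first[r$values], last = last[r$values])
  runs$start <- windows$start[runs$first]
  runs$end <- windows$end[runs$last]
  ov <- vapply(seq_len(nrow(runs)), function(i) {
    sum(pmax(0, pmin(sat$end, runs$end[i]) - pmax(sat$start, runs$start[i])))
  }, numeric(1))
  if (all(ov == 0)) {
    warning("all satellite-overlapping windows contain crossovers on ", chr,
            "; NRZ undefined")
    return(empty)
  }
  best <- which.max(ov)
  data.frame(chrom = chr, start = runs$start[best], end = runs$end[best],
             stringsAsFactors = FALSE)
}

#' Delineate the low-recombining zones (LRZs)
#'
#' Extends outward from each NRZ boundary, accumulating window genetic
#' distance until the cumulative total first reaches `target_cm`; the
#' threshold-crossing window is included, so the attained cM lies in
#' `[target_cm, target_cm + cM of the outermost window)`. When a
#' chromosome end is reached first, the LRZ is truncated and flagged.
#'
#' @param windows A [windowed_map()] for one chromosome.
#' @param nrz One-row NRZ data.frame from [define_nrz()].
#' @param target_cm Genetic distance accumulated by each LRZ.
#' @return data.frame with rows `lrz_left` and `lrz_right`: chrom, side,
#'   start, end, attained_cm, truncated.
#' @export
define_lrz <- function(windows, nrz, target_cm = 1.0) {
  if (nrow(nrz) == 0) stop("NRZ is empty")
  chr <- windows$chrom[1]
  accumulate <- function(idx_seq) {
    acc <- 0; used <- integer(0); truncated <- TRUE
    for (i in idx_seq) {
      acc <- acc + windows$cm[i]
      used <- c(used, i)
      if (acc >= target_cm) { truncated <- FALSE; break }
    }
    list(acc = acc, used = used, truncated = truncated)
  }
  left_idx <- rev(which(windows$end <= nrz$start))
  right_idx <- which(windows$start >= nrz$end)
  l <- accumulate(left_idx)
  r <- accumulate(right_idx)
  data.frame(
    chrom = chr, side = c("lrz_left", "lrz_right"),
    start = c(if (length(l$used)) min(windows$start[l$used]) else nrz$start,
              nrz$end),
    end = c(nrz$start,
            if (length(r$used)) max(windows$end[r$used]) else nrz$end),
    attained_cm = c(l$acc, r$acc),
    truncated = c(l$truncated, r$truncated),
    stringsAsFactors = FALSE)
}

#' Per-zone summary of span, genetic distance and feature content
#'
#' @param nrz,lrz Zone frames from [define_nrz()] and [define_lrz()].
#' @param windows A [windowed_map()] for the same chromosome.
#' @param annotation Optional annotation data.frame (chrom, start, end,
#'   class) as from [simulate_annotation()].
#' @return data.frame with one row per zone plus the remaining chromosome
#'   arms: span_mb, cm, cm_mb, gene_density and te_density (features/Mb).
#' @export
zone_summary <- function(nrz, lrz, windows, annotation = NULL) {
  chr <- windows$chrom[1]
  zones <- data.frame(
    zone = c("nrz", lrz$side, "arms"),
    start = c(nrz$start, lrz$start, NA), end = c(nrz$end, lrz$end, NA),
    stringsAsFactors = FALSE)
  L <- max(windows$end)
  in_zone <- function(s, e) windows$start >= s & windows$end <= e
  arm_mask <- rep(TRUE, nrow(windows))
  res <- list()
  for (i in seq_len(nrow(zones))) {
    z <- zones[i, ]
    if (z$zone == "arms") {
      mask <- arm_mask
      span <- sum(windows$end[mask] - windows$start[mask]) / 1e6
      s <- NA; e <- NA
    } else {
      mask <- in_zone(z$start, z$end)
      arm_mask <- arm_mask & !mask
      span <- (z$end - z$start) / 1e6
      s <- z$start; e <- z$end
    }
    cm <- sum(windows$cm[mask])
    count_feat <- function(cls) {
      if (is.null(annotation)) return(NA_real_)
      a <- annotation[annotation$chrom == chr & annotation$class %in% cls, ,
                      drop = FALSE]
      if (z$zone == "arms") {
        mid <- (a$start + a$end) / 2
        nrz_lrz_lo <- min(nrz$start, lrz$start)
        nrz_lrz_hi <- max(nrz$end, lrz$end)
        sum(mid < nrz_lrz_lo | mid >= nrz_lrz_hi)
      } else {
        mid <- (a$start + a$end) / 2
        sum(mid >= s & mid < e)
      }
    }
    res[[i]] <- data.frame(
      chrom = chr, zone = z$zone, start = s, end = e, span_mb = span,
      cm = cm, cm_mb = if (span > 0) cm / span else NA_real_,
      gene_density = count_feat("gene") / span,
      te_density = count_feat(c("Gypsy/Ty3", "Helitron", "LINE",
                                "Copia/Ty1")) / span,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
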