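#' Genetic distance from fluorescent seed counts
#'
#' Estimates the genetic distance between two linked hemizygous
#' fluorescent transgenes from the counts of single-colour seeds in
#' self-fertilised progeny:
#' \deqn{cM = 100 (1 - \sqrt{1 - 2 (N_G + N_R) / N_T})}
#' where \eqn{N_G} and \eqn{N_R} are the numbers of green-alone and
#' red-alone seeds and \eqn{N_T} the total seeds counted. The square root
#' accounts for single-colour classes arising from one recombinant and
#' one non-recombinant gamete.
#'
#' @param n_green,n_red,n_total Seed counts (vectorised).
#' @return Genetic distance(s) in centiMorgans.
#' @examples
#' ftl_map_distance(50, 50, 1000)  # 100 * (1 - sqrt(0.8))
#' @export
ftl_map_distance <- function(n_green, n_red, n_total) {
  if (any(n_total == 0)) stop("'n_total' must be positive")
  if (any(n_green < 0 | n_red < 0)) stop("seed counts must be non-negative")
  rad <- 1 - 2 * (n_green + n_red) / n_total
  if (any(rad < 0)) {
    stop("recombinant seed fraction exceeds 1/2; genetic distance undefined")
  }
  100 * (1 - sqrt(rad))
}

#' Classify one genotyped recombinant plant and locate its crossovers
#'
#' Applies the genotype-transition rules for fluorescence-selected
#' recombinant plants scored at an ordered array of codominant markers
#' (genotypes `CC`, `CL`, `LL`, or `NA`). Missing genotypes are skipped
#' when locating transitions. Categories:
#' \describe{
#'   \item{singleCO}{one transition consistent with the fluorescence
#'     class (green-alone: `CL` to `LL`; red-alone: `LL` to `CL`); one
#'     crossover counted.}
#'   \item{doubleChromatid}{`CC-CL-LL` or `LL-CL-CC` pattern from a
#'     selected homozygous fluorescent seed: two independent crossovers on
#'     different chromatids, both counted.}
#'   \item{contaminant}{uniformly `CC`; excluded, none counted.}
#'   \item{doubleCOchromatid}{`CL-CC-CL-LL` or `LL-CL-CC-CL` pattern: one
#'     single-crossover chromatid plus one double-crossover chromatid;
#'     only the colour-consistent crossover is counted.}
#'   \item{ambiguousBoundary}{a counted transition whose flanking
#'     informative markers are non-adjacent (missing genotype at the
#'     breakpoint); the crossover spans several candidate intervals.}
#' }
#' Records matching no rule are flagged `unresolvable` and excluded.
#'
#' @param genotypes Character vector over the ordered markers, values in
#'   `{"CC", "CL", "LL"}` or `NA`.
#' @param color `"green"` or `"red"` fluorescence class.
#' @return list with `category`, `n_counted`, and `crossovers`: a
#'   data.frame with one row per counted crossover giving the flanking
#'   informative marker indices (`left_marker`, `right_marker`) and the
#'   spanned interval indices `first_interval`..`last_interval`
#'   (interval `i` lies between markers `i` and `i + 1`).
#' @export
call_kasp_crossovers <- function(genotypes, color = c("green", "red")) {
  color <- match.arg(color)
  out <- function(category, rows = NULL, n = if (is.null(rows)) 0L
                  else nrow(rows)) {
    list(category = category, n_counted = n, crossovers = rows)
  }
  idx <- which(!is.na(genotypes))
  if (length(idx) < 2) return(out("unresolvable"))
  g <- genotypes[idx]
  bad <- !(g %in% c("CC", "CL", "LL"))
  if (any(bad)) stop("invalid genotype code: ", g[which(bad)[1]])
  r <- rle(g)
  seqs <- r$values
  ends <- cumsum(r$lengths)

  boundary <- function(k) {
    # transition between run k and k+1, in flanking informative markers
    lm <- idx[ends[k]]; rm <- idx[ends[k] + 1L]
    data.frame(left_marker = lm, right_marker = rm,
               first_interval = lm, last_interval = rm - 1L,
               transition = paste0(seqs[k], ">", seqs[k + 1L]),
               stringsAsFactors = FALSE)
  }
  if (length(seqs) == 1) {
    if (seqs == "CC") return(out("contaminant"))
    return(out("unresolvable"))
  }
  color_pair <- if (color == "green") c("CL", "LL") else c("LL", "CL")

  category <- NULL; rows <- NULL
  if (identical(seqs, color_pair)) {
    category <- "singleCO"; rows <- boundary(1L)
  } else if (identical(seqs, c("CC", "CL", "LL")) ||
             identical(seqs, c("LL", "CL", "CC"))) {
    category <- "doubleChromatid"; rows <- rbind(boundary(1L), boundary(2L))
  } else if (identical(seqs, c("CL", "CC", "CL", "LL")) ||
             identical(seqs, c("LL", "CL", "CC", "CL"))) {
    category <- "doubleCOchromatid"
    # count only the single-crossover chromatid: the colour-consistent
    # transition (green: CL>LL; red: LL>CL)
    want <- paste0(color_pair[1], ">", color_pair[2])
    ks <- which(paste0(seqs[-length(seqs)], ">", seqs[-1]) == want)
    if (length(ks) == 0) return(out("unresolvable"))
    rows <- boundary(ks[1])
  } else {
    return(out("unresolvable"))
  }
  ambiguous <- any(rows$right_marker - rows$left_marker > 1L)
  if (category == "singleCO" && ambiguous) category <- "ambiguousBoundary"
  res <- out(category, rows)
  res$ambiguous <- ambiguous
  res
}

#' Allocate ambiguous crossovers across candidate intervals
#'
#' Each ambiguous crossover (one whose breakpoint falls in a run of
#' missing genotypes) spans two or more candidate intervals. Its unit
#' tally is divided among them in proportion to the unambiguous
#' crossovers already mapped in those intervals; when all candidates have
#' zero unambiguous support the unit is split equally. Total tally mass
#' is conserved exactly.
#'
#' @param spans list of integer vectors, each the candidate interval
#'   indices of one ambiguous crossover.
#' @param unambiguous_tally Numeric vector of per-interval unambiguous
#'   crossover counts.
#' @return Numeric vector of fractional tally additions per interval.
#' @examples
#' allocate_ambiguous(list(c(1, 2)), c(11, 9))  # 0.55, 0.45
#' @export
allocate_ambiguous <- function(spans, unambiguous_tally) {
  add <- numeric(length(unambiguous_tally))
  for (sp in spans) {
    w <- unambiguous_tally[sp]
    tot <- sum(w)
    frac <- if (tot > 0) w / tot else rep(1 / length(sp), length(sp))
    add[sp] <- add[sp] + frac
  }
  add
}

#' Tally crossovers from a genotyped plate of recombinant plants
#'
#' Runs [call_kasp_crossovers()] over every plant of a plate, tallies
#' unambiguous crossovers per inter-marker interval, then distributes the
#' ambiguous ones with [allocate_ambiguous()].
#'
#' @param plate data.frame as produced by [simulate_kasp_plate()]:
#'   `plant_id`, `color`, then one genotype column per marker.
#' @param interval_map A [kasp_interval_map()] whose marker count matches
#'   the plate.
#' @return list of class `"kasp_tally"`: `classification` (per-plant
#'   data.frame), `tally` (fractional per-interval crossover counts),
#'   `n_crossovers` (total counted), `n_excluded`.
#' @export
call_kasp_plate <- function(plate, interval_map) {
  stopifnot(inherits(interval_map, "kasp_interval_map"))
  geno_cols <- setdiff(names(plate), c("plant_id", "color"))
  if (length(geno_cols) != nrow(interval_map) + 1L) {
    stop("plate has ", length(geno_cols), " markers but interval map expects ",
         nrow(interval_map) + 1L)
  }
  ni <- nrow(interval_map)
  tally <- numeric(ni)
  spans <- list()
  cls <- vector("list", nrow(plate))
  for (p in seq_len(nrow(plate))) {
    g <- as.character(plate[p, geno_cols])
    res <- call_kasp_crossovers(g, plate$color[p])
    cls[[p]] <- data.frame(plant_id = plate$plant_id[p],
                           category = res$category,
                           n_counted = res$n_counted,
                           stringsAsFactors = FALSE)
    if (is.null(res$crossovers)) next
    for (i in seq_len(nrow(res$crossovers))) {
      iv <- res$crossovers$first_interval[i]:res$crossovers$last_interval[i]
      if (length(iv) == 1) {
        tally[iv] <- tally[iv] + 1
      } else {
        spans[[length(spans) + 1L]] <- iv
      }
    }
  }
  tally <- tally + allocate_ambiguous(spans, tally)
  classification <- do.call(rbind, cls)
  structure(list(classification = classification, tally = tally,
                 n_crossovers = sum(tally),
                 n_excluded = sum(classification$n_counted == 0)),
            class = "kasp_tally")
}

#' @export
print.kasp_tally <- function(x, ...) {
  cat(sprintf("KASP crossover tally: %.2f crossovers from %d plants (%d excluded)\n",
              x$n_crossovers, nrow(x$classification), x$n_excluded))
  print(table(x$classification$category))
  invisible(x)
}

# 2-cell goodness-of-fit chi-square of an observed count against its
# expectation under a fixed total; accepts fractional tallies.
.chisq_2cell <- function(obs, expe, total, correct = FALSE) {
  o <- c(obs, total - obs)
  e <- c(expe, total - expe)
  .chisq_stat_p(o, e, correct)
}

.chisq_stat_p <- function(o, e, correct) {
  if (any(e == 0 & o > 0)) return(0)
  keep <- e > 0
  adj <- if (correct) pmin(abs(o[keep] - e[keep]), 0.5) else 0
  stat <- sum((abs(o[keep] - e[keep]) - adj)^2 / e[keep])
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

# 2x2 chi-square on counts (a, A - a) vs (b, B - b); fractional tallies
# allowed, optional Yates continuity correction.
.chisq_2x2 <- function(a, tot_a, b, tot_b, correct = TRUE) {
  o <- matrix(c(a, tot_a - a, b, tot_b - b), 2, byrow = TRUE)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  .chisq_stat_p(as.vector(o), as.vector(e), correct)
}

#' Crossover hotspot and coldspot detection
#'
#' Compares the observed crossover tally of each interval with its
#' expectation under an even distribution (proportional to physical
#' interval length by default) using a 1-df chi-square on the
#' `[in-interval, elsewhere]` partition, Bonferroni-corrected over the
#' number of intervals. Intervals with adjusted p at or below `alpha` are
#' classified hotspots (observed above expected) or coldspots (below).
#'
#' @param tally Per-interval crossover counts (fractional allowed).
#' @param interval_map A [kasp_interval_map()]; its interval lengths give
#'   the expected distribution.
#' @param alpha Significance level after Bonferroni correction.
#' @param even_per_interval Expect the same count in every interval
#'   instead of proportionality to physical length.
#' @param correct Apply a continuity correction to the chi-square.
#' @return data.frame (interval, start, end, observed, expected, p,
#'   p_adj, class) with class in `{hotspot, coldspot, none}`.
#' @export
hotspot_coldspot_test <- function(tally, interval_map, alpha = 0.05,
                                  even_per_interval = FALSE,
                                  correct = FALSE) {
  stopifnot(inherits(interval_map, "kasp_interval_map"))
  len <- interval_map$end - interval_map$start
  if (any(len <= 0)) stop("interval of zero length")
  total <- sum(tally)
  if (total <= 0) stop("total tally must be positive")
  k <- length(tally)
  expe <- if (even_per_interval) rep(total / k, k) else total * len / sum(len)
  p <- vapply(seq_len(k),
              function(i) .chisq_2cell(tally[i], expe[i], total, correct),
              numeric(1))
  p_adj <- pmin(1, p * k)
  cls <- rep("none", k)
  cls[p_adj <= alpha & tally > expe] <- "hotspot"
  cls[p_adj <= alpha & tally < expe] <- "coldspot"
  data.frame(interval = interval_map$interval, start = interval_map$start,
             end = interval_map$end, observed = tally, expected = expe,
             p = p, p_adj = p_adj, class = cls, stringsAsFactors = FALSE)
}

#' Per-interval comparison of crossover maps between genotypes
#'
#' For each interval, a 2x2 chi-square compares
#' `[in-interval, elsewhere]` counts between two genotypes.
#'
#' @param tally_a,tally_b Per-interval tallies for the two genotypes (same
#'   interval map).
#' @param alpha Flagging threshold on the per-interval p-value.
#' @param correct Yates continuity correction.
#' @return data.frame (interval, observed_a, observed_b, p, significant).
#' @export
compare_genotype_maps <- function(tally_a, tally_b, alpha = 0.05,
                                  correct = FALSE) {
  if (length(tally_a) != length(tally_b)) {
    stop("tallies must share one interval map")
  }
  ta <- sum(tally_a); tb <- sum(tally_b)
  if (ta <= 0 || tb <= 0) stop("zero total tally in a genotype")
  p <- vapply(seq_along(tally_a), function(i) {
    .chisq_2x2(tally_a[i], ta, tally_b[i], tb, correct)
  }, numeric(1))
  data.frame(interval = seq_along(tally_a), observed_a = tally_a,
             observed_b = tally_b, p = p, significant = p <= alpha)
}

#' Compare regional crossover fractions between genotypes
#'
#' Tallies crossovers by genomic region (typically NRZ, LRZs and the
#' distal remainder) in a test genotype and a reference, reports each
#' region's proportion of the genotype total, and tests each region with
#' a 2x2 chi-square of `[region, elsewhere]` by `[genotype, reference]`.
#'
#' @param tally Named numeric vector of per-region crossover counts for
#'   the test genotype.
#' @param reference Named numeric vector for the reference genotype (same
#'   regions).
#' @param correct Yates continuity correction (default on, the standard
#'   for 2x2 tables).
#' @return data.frame (region, count, prop, count_ref, prop_ref, p).
#' @export
zone_fraction_test <- function(tally, reference, correct = TRUE) {
  if (!identical(names(tally), names(reference))) {
    stop("'tally' and 'reference' must cover the same named regions")
  }
  tt <- sum(tally); tr <- sum(reference)
  p <- vapply(seq_along(tally), function(i) {
    .chisq_2x2(tally[i], tt, reference[i], tr, correct)
  }, numeric(1))
  data.frame(region = names(tally), count = as.numeric(tally),
             prop = as.numeric(tally) / tt,
             count_ref = as.numeric(reference),
             prop_ref = as.numeric(reference) / tr,
             p = p, stringsAsFactors = FALSE, row.names = NULL)
}
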