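#' Sliding-window genotype track for one sample
#'
#' Genotypes overlapping windows along a chromosome from a sample's
#' per-marker allele read counts. Per window, the Col read fraction over
#' the contained markers determines the call: homozygous Col when the
#' fraction reaches `hom_threshold`, homozygous Ler when it falls below
#' `1 - hom_threshold`, heterozygous otherwise, and missing when fewer
#' than `min_markers` markers carry reads.
#'
#' @param col_reads,ler_reads Integer vectors of per-marker read counts.
#' @param positions Marker positions (bp, 0-based), sorted increasing.
#' @param chrom_length Chromosome length in bp.
#' @param window Window size in bp.
#' @param step Step size in bp.
#' @param hom_threshold Col-fraction threshold for a homozygous call.
#' @param min_markers Minimum informative (covered) markers per window.
#' @return data.frame (start, end, call, n_markers, col_fraction) with
#'   calls in `{COL_HOM, HET, LER_HOM, MISSING}`.
#' @export
genotype_windows <- function(col_reads, ler_reads, positions, chrom_length,
                             window = 70000, step = 35000,
                             hom_threshold = 0.9, min_markers = 5) {
  if (step <= 0 || window < step) stop("need window >= step > 0")
  starts <- if (chrom_length <= window) 0 else seq(0, chrom_length - window, by = step)
  if (starts[length(starts)] + window < chrom_length) {
    starts <- c(starts, chrom_length - window)
  }
  ends <- pmin(starts + window, chrom_length)
  n <- length(positions)
  if (n == 0) {
    return(data.frame(start = starts, end = ends, call = "MISSING",
                      n_markers = 0L, col_fraction = NA_real_,
                      stringsAsFactors = FALSE))
  }
  if (is.unsorted(positions)) {
    o <- order(positions)
    positions <- positions[o]
    col_reads <- col_reads[o]
    ler_reads <- ler_reads[o]
  }
  depth <- col_reads + ler_reads
  cum_col <- c(0, cumsum(col_reads))
  cum_tot <- c(0, cumsum(depth))
  cum_inf <- c(0, cumsum(depth > 0))
  lo <- findInterval(starts - 0.5, positions) + 1L
  hi <- findInterval(ends - 0.5, positions)
  csum <- cum_col[hi + 1L] - cum_col[lo]
  tsum <- cum_tot[hi + 1L] - cum_tot[lo]
  ninf <- cum_inf[hi + 1L] - cum_inf[lo]
  frac <- ifelse(tsum > 0, csum / tsum, NA_real_)
  call <- rep("MISSING", length(starts))
  ok <- ninf >= min_markers & tsum > 0
  call[ok & frac >= hom_threshold] <- "COL_HOM"
  call[ok & frac <= 1 - hom_threshold] <- "LER_HOM"
  call[ok & frac > 1 - hom_threshold & frac < hom_threshold] <- "HET"
  data.frame(start = starts, end = ends, call = call, n_markers = ninf,
             col_fraction = frac, stringsAsFactors = FALSE)
}

#' Candidate genotype transitions from a window track
#'
#' Collapses a window genotype track into maximal runs of constant call
#' (missing windows skipped) and emits the boundaries between successive
#' distinct runs as crossover candidates. Runs shorter than `min_run`
#' windows are treated as unstable noise and skipped, except at the
#' chromosome ends where a run cannot extend further. For a backcross the
#' only legal transition is between the recurrent-parent homozygote and
#' the heterozygote; for an F2, homozygote-to-homozygote boundaries
#' without an intervening heterozygous run are flagged as two-boundary
#' candidates (a single chromatid cannot switch between homozygotes).
#'
#' @param track A [genotype_windows()] track.
#' @param population `"bc1"` or `"f2"`.
#' @param backcross_parent Recurrent parent for BC1 legality.
#' @param min_run Minimum run length, in windows, for a stable genotype
#'   segment.
#' @return data.frame (left_call, right_call, region_start, region_end,
#'   status) with status in `{candidate, two_boundary, illegal}`. The
#'   number of skipped unstable runs is attached as attribute
#'   `"n_unstable_runs"`.
#' @export
detect_transitions <- function(track, population = c("bc1", "f2"),
                               backcross_parent = c("col", "ler"),
                               min_run = 2) {
  population <- match.arg(population)
  backcross_parent <- match.arg(backcross_parent)
  if (nrow(track) == 0) stop("empty track")
  tw <- track[track$call != "MISSING", , drop = FALSE]
  empty <- data.frame(left_call = character(0), right_call = character(0),
                      region_start = numeric(0), region_end = numeric(0),
                      status = character(0), stringsAsFactors = FALSE)
  if (nrow(tw) < 2) {
    attr(empty, "n_unstable_runs") <- 0L
    return(empty)
  }
  r <- rle(tw$call)
  last <- cumsum(r$lengths)
  first <- last - r$lengths + 1L
  terminal <- seq_along(r$lengths) %in% c(1L, length(r$lengths))
  stable <- r$lengths >= min_run | terminal
  n_unstable <- sum(!stable)
  runs <- data.frame(call = r$values[stable], first = first[stable],
                     last = last[stable], stringsAsFactors = FALSE)
  # merge adjacent stable runs left identical after dropping unstable ones
  if (nrow(runs) > 1) {
    keep <- c(TRUE, runs$call[-1] != runs$call[-nrow(runs)])
    grp <- cumsum(keep)
    runs <- data.frame(call = runs$call[keep],
                       first = tapply(runs$first, grp, min),
                       last = tapply(runs$last, grp, max),
                       stringsAsFactors = FALSE)
  }
  if (nrow(runs) < 2) {
    attr(empty, "n_unstable_runs") <- n_unstable
    return(empty)
  }
  legal_pair <- function(a, b) {
    if (population == "bc1") {
      hom <- if (backcross_parent == "col") "COL_HOM" else "LER_HOM"
      setequal(c(a, b), c(hom, "HET"))
    } else {
      setequal(c(a, b), c("COL_HOM", "HET")) ||
        setequal(c(a, b), c("LER_HOM", "HET"))
    }
  }
  out <- vector("list", nrow(runs) - 1L)
  for (i in seq_len(nrow(runs) - 1L)) {
    a <- runs$call[i]; b <- runs$call[i + 1L]
    status <- if (legal_pair(a, b)) "candidate"
      else if (population == "f2" &&
               setequal(c(a, b), c("COL_HOM", "LER_HOM"))) "two_boundary"
      else "illegal"
    out[[i]] <- data.frame(
      left_call = a, right_call = b,
      region_start = tw$start[runs$last[i]],
      region_end = tw$end[runs$first[i + 1L]],
      status = status, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "n_unstable_runs") <- n_unstable
  res
}

# per-marker log-likelihood ratio of genotype b over genotype a
.marker_llr <- function(col, ler, a, b, e = 0.01) {
  p <- c(COL_HOM = 1 - e, HET = 0.5, LER_HOM = e)
  col * log(p[[b]] / p[[a]]) + ler * log((1 - p[[b]]) / (1 - p[[a]]))
}

#' Refine a candidate transition to a marker-resolution crossover call
#'
#' Locates the crossover breakpoint within a candidate region by choosing
#' the inter-marker split that best separates markers supporting the left
#' genotype from markers supporting the right genotype, then walks
#' marker-by-marker outward from the split accumulating reads at
#' genotype-supporting markers. The call is only retained when at least
#' `min_reads` reads accumulate on each side; the reported interval spans
#' from the supporting marker nearest the split on the left to the
#' supporting marker nearest the split on the right (0-based half-open).
#'
#' @param candidate One row of [detect_transitions()] output.
#' @param col_reads,ler_reads,positions As in [genotype_windows()].
#' @param min_reads Minimum accumulated supporting reads per side.
#' @param error_rate Allele error rate used in marker support likelihoods.
#' @return One-row data.frame (start, end, left, right, resolution,
#'   status); status `"pass"` or a rejection reason.
#' @export
refine_crossover <- function(candidate, col_reads, ler_reads, positions,
                             min_reads = 5, error_rate = 0.01) {
  gl <- candidate$left_call; gr <- candidate$right_call
  reject <- function(reason) {
    data.frame(start = NA_real_, end = NA_real_, left = gl, right = gr,
               resolution = NA_real_, status = reason,
               stringsAsFactors = FALSE)
  }
  n <- length(positions)
  idx <- which(positions >= candidate$region_start &
               positions < candidate$region_end)
  if (length(idx) == 0) return(reject("no_markers_in_region"))
  llr <- .marker_llr(col_reads[idx], ler_reads[idx], gl, gr, error_rate)
  # split after the k-th region marker minimising cumulative llr
  cums <- c(0, cumsum(llr))
  k <- which.min(cums) - 1L
  b_left <- if (k >= 1L) idx[k] else idx[1L] - 1L
  b_right <- if (k < length(idx)) idx[k + 1L] else idx[length(idx)] + 1L
  if (b_left < 1L || b_right > n) return(reject("split_at_chromosome_end"))

  # Walk outward accumulating reads at markers supporting this side's
  # genotype; a marker with strong evidence for the other side resets the
  # accumulator (the breakpoint must lie beyond it). Returns the marker at
  # which the accumulated support reaches min_reads, so the reported
  # interval is exactly as wide as the five-read support rule requires.
  walk <- function(from, dir, genotype, other) {
    acc <- 0
    j <- from
    while (j >= 1L && j <= n) {
      d <- col_reads[j] + ler_reads[j]
      if (d > 0) {
        s <- .marker_llr(col_reads[j], ler_reads[j], other, genotype,
                         error_rate)
        if (s > 0) {
          acc <- acc + d
          if (acc >= min_reads) return(j)
        } else if (s < -2) {
          acc <- 0
        }
      }
      j <- j + dir
    }
    NA_integer_
  }
  fl <- walk(b_left, -1L, gl, gr)
  fr <- walk(b_right, +1L, gr, gl)
  if (is.na(fl)) return(reject("insufficient_left_support"))
  if (is.na(fr)) return(reject("insufficient_right_support"))
  start <- positions[fl]; end <- positions[fr]
  if (!(start < end)) return(reject("empty_interval"))
  data.frame(start = start, end = end, left = gl, right = gr,
             resolution = end - start, status = "pass",
             stringsAsFactors = FALSE)
}

# resolve an F2 homozygote-to-homozygote boundary into two crossovers
# flanking a short heterozygous tract, when marker-level evidence for the
# tract exists; otherwise reject.
.resolve_two_boundary <- function(candidate, col_reads, ler_reads, positions,
                                  min_reads, error_rate) {
  idx <- which(positions >= candidate$region_start &
               positions < candidate$region_end)
  het <- idx[col_reads[idx] > 0 & ler_reads[idx] > 0]
  if (length(het) == 0) return(NULL)
  mid1 <- (candidate$region_start + positions[het[1]]) / 2
  mid2 <- (positions[het[length(het)]] + candidate$region_end) / 2
  c1 <- data.frame(left_call = candidate$left_call, right_call = "HET",
                   region_start = candidate$region_start,
                   region_end = positions[het[length(het)]] + 1,
                   status = "candidate", stringsAsFactors = FALSE)
  c2 <- data.frame(left_call = "HET", right_call = candidate$right_call,
                   region_start = positions[het[1]],
                   region_end = candidate$region_end,
                   status = "candidate", stringsAsFactors = FALSE)
  rbind(refine_crossover(c1, col_reads, ler_reads, positions, min_reads,
                         error_rate),
        refine_crossover(c2, col_reads, ler_reads, positions, min_reads,
                         error_rate))
}

#' Sample quality control
#'
#' Flags poorly covered samples (mean reads per marker below
#' `depth_threshold`) and potentially contaminated samples (more than
#' `max_ambig_frac` of called windows with Col-allele fraction inside
#' `ambig_range`, the signature of a mixture of genotypes).
#'
#' @param col_reads,ler_reads Sample x marker read matrices.
#' @param tracks List of per-sample [genotype_windows()] tracks.
#' @param depth_threshold Mean reads/marker below which a sample is
#'   `lowCoverage`.
#' @param ambig_range Inclusive Col-fraction window flagged as ambiguous.
#' @param max_ambig_frac Maximum tolerated fraction of ambiguous windows.
#' @return data.frame (sample, mean_depth, frac_ambiguous, status) with
#'   status in `{pass, lowCoverage, contaminated}`.
#' @export
qc_samples <- function(col_reads, ler_reads, tracks, depth_threshold = 0.1,
                       ambig_range = c(0.8, 0.9), max_ambig_frac = 0.02) {
  ns <- nrow(col_reads)
  mean_depth <- rowMeans(col_reads + ler_reads)
  frac_amb <- vapply(tracks, function(tr) {
    called <- tr$call != "MISSING"
    if (!any(called)) return(0)
    f <- tr$col_fraction[called]
    mean(f >= ambig_range[1] & f <= ambig_range[2])
  }, numeric(1))
  status <- rep("pass", ns)
  status[frac_amb > max_ambig_frac] <- "contaminated"
  status[mean_depth < depth_threshold] <- "lowCoverage"
  data.frame(sample = seq_len(ns), mean_depth = mean_depth,
             frac_ambiguous = frac_amb, status = status,
             stringsAsFactors = FALSE)
}

#' Population-level double-crossover filter
#'
#' Removes clustered double crossovers that typically arise from
#' mis-genotyping. In 1-Mb sliding windows (500-kb step), the
#' double-crossover frequency is the number of samples with a double
#' crossover in the window divided by the number of samples with at
#' least one crossover midpoint in it; when it exceeds `max_frac`
#' (strictly), the double calls in that window are removed. A call
#' removed in any window is removed globally. A double crossover is a
#' pair of calls in the window whose genotypes return to the starting
#' state (X to Y then Y back to X), the signature of a mis-genotyped
#' tract; in an F2, progressive transitions on different chromatids
#' (e.g. Col/Col to Col/Ler, then Col/Ler to Ler/Ler) are two genuine
#' single crossovers and are not counted.
#'
#' @param calls Crossover call data.frame with `sample`, `chrom`, `start`,
#'   `end`.
#' @param chrom_length Chromosome length(s) in bp; a named vector for
#'   multiple chromosomes.
#' @param window,step Sliding-window geometry in bp.
#' @param max_frac Double-crossover frequency threshold (exclusive).
#' @return list with `calls` (retained) and `removed`.
#' @export
filter_double_crossovers <- function(calls, chrom_length, window = 1e6,
                                     step = 5e5, max_frac = 0.04) {
  if (nrow(calls) == 0) return(list(calls = calls, removed = calls[0, ]))
  mid <- (calls$start + calls$end) / 2
  drop <- rep(FALSE, nrow(calls))
  for (chr in unique(calls$chrom)) {
    L <- if (length(chrom_length) > 1) chrom_length[[chr]] else chrom_length
    sel <- which(calls$chrom == chr)
    m <- mid[sel]
    starts <- if (L <= window) 0 else seq(0, L - window, by = step)
    for (s in starts) {
      inw <- sel[m >= s & m < s + window]
      if (length(inw) == 0) next
      n_bearing <- length(unique(calls$sample[inw]))
      # double = a pair of calls returning to the starting genotype
      doubles <- character(0)
      dbl_idx <- integer(0)
      for (sm in unique(calls$sample[inw])) {
        ci <- inw[calls$sample[inw] == sm]
        if (length(ci) < 2) next
        ci <- ci[order(calls$start[ci])]
        ret <- which(calls$left[ci[-length(ci)]] ==
                       calls$right[ci[-1]] &
                     calls$right[ci[-length(ci)]] ==
                       calls$left[ci[-1]])
        if (length(ret)) {
          doubles <- c(doubles, sm)
          dbl_idx <- c(dbl_idx, ci[unique(c(ret, ret + 1L))])
        }
      }
      if (length(doubles) / n_bearing > max_frac) {
        drop[dbl_idx] <- TRUE
      }
    }
  }
  list(calls = calls[!drop, , drop = FALSE],
       removed = calls[drop, , drop = FALSE])
}

#' Call crossovers in a recombinant population
#'
#' Full caller: per sample, builds the sliding-window genotype track,
#' detects genotype transitions, refines each candidate against
#' marker-level read support, then applies sample quality control and the
#' population double-crossover filter.
#'
#' @param x A `"recombinant_population"` from [simulate_population()], or a
#'   list with elements `col_reads`, `ler_reads` (sample x marker
#'   matrices), `markers` (data.frame with `chrom`, `pos`) and
#'   `chrom_length`.
#' @param population `"bc1"` or `"f2"`; taken from the simulation config
#'   when `x` is a simulated population.
#' @param window,step,hom_threshold,min_markers See [genotype_windows()].
#' @param min_run See [detect_transitions()].
#' @param min_reads,error_rate See [refine_crossover()].
#' @param double_window,double_step,double_max_frac See
#'   [filter_double_crossovers()].
#' @param qc Apply sample QC (drop flagged samples' calls).
#' @param chrom_length Chromosome length; inferred from a simulated
#'   population.
#' @return list of class `"crossover_calls"`: `calls` (data.frame: sample,
#'   chrom, start, end, left, right, resolution), `qc`, `rejected`
#'   (refinement rejections), `removed_double` and `review` (illegal /
#'   unresolved transitions for manual inspection).
#' @export
call_crossovers <- function(x, population = NULL, window = 70000,
                            step = 35000, hom_threshold = 0.9,
                            min_markers = 5, min_run = 2, min_reads = 5,
                            error_rate = 0.01, double_window = 1e6,
                            double_step = 5e5, double_max_frac = 0.04,
                            qc = TRUE, chrom_length = NULL) {
  if (inherits(x, "recombinant_population")) {
    if (is.null(population)) population <- x$config$population
    if (is.null(chrom_length)) chrom_length <- x$landscape$chrom_length
    bc_parent <- x$config$backcross_parent
  } else {
    bc_parent <- "col"
    if (is.null(population) || is.null(chrom_length)) {
      stop("'population' and 'chrom_length' are required")
    }
  }
  col_m <- x$col_reads; ler_m <- x$ler_reads
  pos <- x$markers$pos
  chrom <- x$markers$chrom[1]
  ns <- nrow(col_m)

  tracks <- vector("list", ns)
  calls <- list(); rejected <- list(); review <- list()
  for (s in seq_len(ns)) {
    tr <- genotype_windows(col_m[s, ], ler_m[s, ], pos, chrom_length,
                           window, step, hom_threshold, min_markers)
    tracks[[s]] <- tr
    trans <- detect_transitions(tr, population, bc_parent, min_run)
    if (nrow(trans) == 0) next
    for (i in seq_len(nrow(trans))) {
      cand <- trans[i, ]
      if (cand$status == "candidate") {
        r <- refine_crossover(cand, col_m[s, ], ler_m[s, ], pos, min_reads,
                              error_rate)
      } else if (cand$status == "two_boundary") {
        r <- .resolve_two_boundary(cand, col_m[s, ], ler_m[s, ], pos,
                                   min_reads, error_rate)
        if (is.null(r)) {
          review[[length(review) + 1L]] <- cbind(sample = s, cand)
          next
        }
      } else {
        review[[length(review) + 1L]] <- cbind(sample = s, cand)
        next
      }
      r <- cbind(sample = s, chrom = chrom, r)
      ok <- r$status == "pass"
      if (any(ok)) calls[[length(calls) + 1L]] <- r[ok, , drop = FALSE]
      if (any(!ok)) rejected[[length(rejected) + 1L]] <- r[!ok, , drop = FALSE]
    }
  }
  bind <- function(l, proto) if (length(l)) do.call(rbind, l) else proto
  proto_call <- data.frame(sample = integer(0), chrom = character(0),
                           start = numeric(0), end = numeric(0),
                           left = character(0), right = character(0),
                           resolution = numeric(0), status = character(0),
                           stringsAsFactors = FALSE)
  calls <- bind(calls, proto_call)
  rejected <- bind(rejected, proto_call)
  review <- bind(review, NULL)

  qc_report <- qc_samples(col_m, ler_m, tracks)
  if (qc && nrow(calls)) {
    bad <- qc_report$sample[qc_report$status != "pass"]
    calls <- calls[!(calls$sample %in% bad), , drop = FALSE]
  }
  dbl <- filter_double_crossovers(calls, chrom_length, double_window,
                                  double_step, double_max_frac)
  structure(list(calls = dbl$calls, qc = qc_report, rejected = rejected,
                 removed_double = dbl$removed, review = review,
                 chrom_length = chrom_length),
            class = "crossover_calls")
}

#' @export
print.crossover_calls <- function(x, ...) {
  cat(sprintf("Crossover calls: %d retained (%d rejected at refinement, %d removed as clustered doubles)\n",
              nrow(x$calls), nrow(x$rejected), nrow(x$removed_double)))
  n_bad <- sum(x$qc$status != "pass")
  if (n_bad) cat(sprintf("  %d sample(s) failed QC\n", n_bad))
  if (nrow(x$calls)) {
    cat(sprintf("  median resolution: %.0f bp\n",
                stats::median(x$calls$resolution)))
  }
  invisible(x)
}
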