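test_that("window genotyping handles homozygous, heterozygous and empty input", {
  pos <- seq(0, 999000, by = 1000)
  n <- length(pos)
  all_col <- genotype_windows(rep(2L, n), rep(0L, n), pos, 1e6)
  expect_true(all(all_col$call == "COL_HOM"))
  het <- genotype_windows(rep(2L, n), rep(2L, n), pos, 1e6)
  expect_true(all(het$call == "HET"))
  none <- genotype_windows(integer(0), integer(0), numeric(0), 1e6)
  expect_true(all(none$call == "MISSING"))
  sparse <- genotype_windows(rep(1L, 3), rep(0L, 3), c(0, 5e5, 9e5), 1e6)
  expect_true(all(sparse$call == "MISSING"))  # below min_markers
})

test_that("window calls switch within one step of a simulated crossover", {
  pos <- seq(0, 9999000, by = 1000)
  co_at <- 2.0e6
  col <- ifelse(pos < co_at, 5L, 10L)   # HET then COL_HOM (BC1)
  ler <- ifelse(pos < co_at, 5L, 0L)
  tr <- genotype_windows(col, ler, pos, 1e7)
  switch_win <- tr[tr$call == "COL_HOM", ]
  first_hom <- min(switch_win$start)
  expect_lt(abs(first_hom - co_at), 70000 + 1)
  last_het <- max(tr$start[tr$call == "HET"])
  expect_lt(abs(last_het + 35000 - co_at), 70000 + 1)
})

test_that("window genotyping is invariant to marker order permutation", {
  set.seed(31)
  pos <- sort(sample.int(1e6, 500)) - 1
  col <- rpois(500, 2); ler <- rpois(500, 2)
  o <- sample.int(500)
  expect_identical(genotype_windows(col, ler, pos, 1e6),
                   genotype_windows(col[o], ler[o], pos[o], 1e6))
})

test_that("transition detection compresses runs and applies legality rules", {
  mk_track <- function(calls) {
    n <- length(calls)
    data.frame(start = (0:(n - 1)) * 35000, end = (0:(n - 1)) * 35000 + 70000,
               call = calls, n_markers = 50,
               col_fraction = ifelse(calls == "COL_HOM", 1,
                                     ifelse(calls == "HET", 0.5, 0)),
               stringsAsFactors = FALSE)
  }
  expect_equal(nrow(detect_transitions(mk_track(rep("HET", 10)), "bc1")), 0)
  tr <- detect_transitions(mk_track(c(rep("HET", 5), rep("COL_HOM", 5))),
                           "bc1")
  expect_equal(nrow(tr), 1)
  expect_equal(tr$status, "candidate")
  expect_equal(tr$left_call, "HET")
  # missing windows are skipped, not treated as boundaries
  with_miss <- c(rep("HET", 4), "MISSING", rep("COL_HOM", 5))
  expect_equal(nrow(detect_transitions(mk_track(with_miss), "bc1")), 1)
  # single-window interior runs are unstable noise
  alt <- mk_track(c(rep("HET", 4), "COL_HOM", "HET", "COL_HOM",
                    rep("HET", 4)))
  ta <- detect_transitions(alt, "bc1")
  expect_gte(attr(ta, "n_unstable_runs"), 2)
  expect_equal(nrow(ta), 0)
  # BC1 never legally reaches the Ler homozygote
  bad <- detect_transitions(mk_track(c(rep("HET", 5), rep("LER_HOM", 5))),
                            "bc1")
  expect_equal(bad$status, "illegal")
  # F2 hom-to-hom is a two-boundary candidate
  f2 <- detect_transitions(mk_track(c(rep("COL_HOM", 5),
                                      rep("LER_HOM", 5))), "f2")
  expect_equal(f2$status, "two_boundary")
})

test_that("refinement spans adjacent markers on dense clean data and enforces the five-read rule", {
  pos <- seq(0, 999000, by = 1000)
  n <- length(pos)
  co_idx <- 500          # crossover between markers 500 and 501
  col <- c(rep(5L, co_idx), rep(10L, n - co_idx))
  ler <- c(rep(5L, co_idx), rep(0L, n - co_idx))
  cand <- data.frame(left_call = "HET", right_call = "COL_HOM",
                     region_start = pos[co_idx] - 35000,
                     region_end = pos[co_idx + 1] + 35000,
                     status = "candidate")
  r <- refine_crossover(cand, col, ler, pos)
  expect_equal(r$status, "pass")
  expect_equal(r$start, pos[co_idx])
  expect_equal(r$end, pos[co_idx + 1])
  expect_equal(r$resolution, 1000)
  # only 4 accumulated supporting reads on the het side: rejected
  col4 <- col; ler4 <- ler
  ler4[1:co_idx] <- 0L; col4[1:co_idx] <- 0L
  ler4[co_idx - (0:1)] <- 2L; col4[co_idx - (0:1)] <- 0L  # 4 reads total
  r4 <- refine_crossover(cand, col4, ler4, pos)
  expect_equal(r4$status, "insufficient_left_support")
})

test_that("sample QC flags low coverage and genotype mixtures", {
  track_clean <- data.frame(start = 0, end = 70000, call = "HET",
                            n_markers = 50, col_fraction = 0.5)
  mk_tracks <- function(fracs) {
    data.frame(start = seq_along(fracs), end = seq_along(fracs) + 1,
               call = "HET", n_markers = 50, col_fraction = fracs)
  }
  col <- rbind(rep(1L, 100), rep(0L, 100), rep(1L, 100))
  ler <- rbind(rep(1L, 100), rep(0L, 100), rep(1L, 100))
  tracks <- list(track_clean, track_clean,
                 mk_tracks(c(rep(0.5, 95), rep(0.85, 5))))
  qc <- qc_samples(col, ler, tracks)
  expect_equal(qc$status, c("pass", "lowCoverage", "contaminated"))
  expect_lt(qc$mean_depth[2], 0.1)
  expect_gt(qc$frac_ambiguous[3], 0.02)
})

test_that("double-crossover filter removes clustered return paths above 4%", {
  mk_calls <- function(n_single, n_double) {
    singles <- data.frame(
      sample = seq_len(n_single), chrom = "chr1",
      start = 5e5 + seq_len(n_single), end = 5e5 + seq_len(n_single) + 1000,
      left = "HET", right = "COL_HOM")
    doubles <- do.call(rbind, lapply(seq_len(n_double), function(i) {
      s <- n_single + i
      data.frame(sample = s, chrom = "chr1",
                 start = c(4e5, 6e5) + i, end = c(4e5, 6e5) + i + 1000,
                 left = c("HET", "COL_HOM"), right = c("COL_HOM", "HET"))
    }))
    rbind(singles, doubles)
  }
  none <- filter_double_crossovers(mk_calls(100, 0), 1e7)
  expect_equal(nrow(none$removed), 0)
  # 5 doubles among 100 crossover-bearing samples: 5% > 4%, removed
  five <- filter_double_crossovers(mk_calls(95, 5), 1e7)
  expect_equal(sort(unique(five$removed$sample)), 96:100)
  # 4 doubles among 100: exactly 4%, strict inequality retains them
  four <- filter_double_crossovers(mk_calls(96, 4), 1e7)
  expect_equal(nrow(four$removed), 0)
  # progressive two-chromatid F2 transitions are not doubles
  f2 <- data.frame(sample = 1, chrom = "chr1", start = c(4e5, 6e5),
                   end = c(4e5, 6e5) + 1000,
                   left = c("COL_HOM", "HET"), right = c("HET", "LER_HOM"))
  expect_equal(nrow(filter_double_crossovers(f2, 1e7)$removed), 0)
})

test_that("error-free populations are called perfectly, truth inside every interval", {
  land <- study_landscape()
  pop <- simulate_population(land, simulation_config(
    n_samples = 150, mean_depth = 10, allele_error = 0,
    deterministic_reads = TRUE, interference_nu = 5, seed = 1))
  res <- call_crossovers(pop)
  st <- recovery_stats(res$calls, pop$truth$crossovers)
  expect_equal(st$sensitivity, 1)
  expect_equal(st$precision, 1)
  # F2: both chromatids recombine; precision stays perfect and nearly
  # every event is recovered (co-located trans-chromatid pairs are the
  # known exception at this population size)
  f2 <- simulate_population(land, simulation_config(
    population = "f2", n_samples = 100, mean_depth = 10, allele_error = 0,
    deterministic_reads = TRUE, interference_nu = 5, seed = 1))
  rf2 <- call_crossovers(f2)
  sf2 <- recovery_stats(rf2$calls, f2$truth$crossovers)
  expect_gte(sf2$sensitivity, 0.9)
  expect_equal(sf2$precision, 1)
})

test_that("calls within a sample stay disjoint after filtering (BC1)", {
  land <- study_landscape(total_cm = 40)
  pop <- simulate_population(land, simulation_config(
    n_samples = 150, mean_depth = 4, interference_nu = 5, seed = 13))
  res <- call_crossovers(pop)
  for (s in unique(res$calls$sample)) {
    cs <- res$calls[res$calls$sample == s, ]
    if (nrow(cs) < 2) next
    cs <- cs[order(cs$start), ]
    expect_true(all(cs$start[-1] >= cs$end[-nrow(cs)]))
  }
})
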