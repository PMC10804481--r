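test_that("simulation config validates probabilities and counts", {
  expect_error(simulation_config(allele_error = 1.5), "probabilities")
  expect_error(simulation_config(n_samples = 0), "n_samples")
  expect_error(simulation_config(mean_depth = 0), "mean_depth")
})

test_that("a zero-length map yields crossover-free samples", {
  land <- recombination_landscape(1e6, total_cm = 0)
  pop <- simulate_population(land, simulation_config(n_samples = 10,
                                                     seed = 1))
  expect_equal(nrow(pop$truth$crossovers), 0)
})

test_that("true crossovers never fall in the zero zone", {
  land <- study_landscape(total_cm = 100)
  pop <- simulate_population(land, simulation_config(n_samples = 300,
                                                     marker_spacing = 5000,
                                                     seed = 2))
  co <- pop$truth$crossovers
  expect_gt(nrow(co), 100)
  expect_false(any(co$pos >= 4e6 & co$pos < 6e6))
})

test_that("fixing the seed reproduces byte-identical populations", {
  land <- study_landscape()
  cfg <- simulation_config(n_samples = 20, marker_spacing = 5000, seed = 99)
  a <- simulate_population(land, cfg)
  b <- simulate_population(land, cfg)
  expect_identical(a$markers, b$markers)
  expect_identical(a$col_reads, b$col_reads)
  expect_identical(a$truth, b$truth)
})

test_that("allele-depth marginals match the configured mean depth", {
  land <- recombination_landscape(1e6, total_cm = 5)
  pop <- simulate_population(land, simulation_config(
    n_samples = 200, marker_spacing = 2000, mean_depth = 2, seed = 5))
  per_marker <- colMeans(pop$col_reads + pop$ler_reads)
  se <- sd(per_marker) / sqrt(length(per_marker))
  expect_lt(abs(mean(per_marker) - 2), 3 * se + 0.02)
})

test_that("contaminant and low-coverage samples carry their designed signatures", {
  land <- study_landscape()
  pop <- simulate_population(land, simulation_config(
    n_samples = 50, marker_spacing = 5000, mean_depth = 4,
    allele_error = 0, contamination_fraction = 0.2,
    low_coverage_fraction = 0.2, seed = 8))
  fl <- pop$truth$flags
  expect_gt(sum(fl$contaminant), 0)
  expect_gt(sum(fl$low_coverage), 0)
  cont <- which(fl$contaminant)[1]
  expect_equal(sum(pop$ler_reads[cont, ]), 0)
  expect_false(cont %in% pop$truth$crossovers$sample)
  low <- which(fl$low_coverage)[1]
  expect_lt(mean(pop$col_reads[low, ] + pop$ler_reads[low, ]), 0.4)
})

test_that("F2 genotypes sum two gametes and BC1 uses a fixed recurrent gamete", {
  land <- recombination_landscape(1e6, total_cm = 0)
  bc <- simulate_population(land, simulation_config(
    n_samples = 30, mean_depth = 6, marker_spacing = 2000, seed = 3))
  # without crossovers every BC1 marker keeps at least one Col dose
  frac <- colSums(bc$col_reads) / colSums(bc$col_reads + bc$ler_reads)
  expect_true(all(frac > 0.4))
  f2 <- simulate_population(land, simulation_config(
    population = "f2", n_samples = 40, mean_depth = 6,
    marker_spacing = 2000, seed = 3))
  # F2 non-recombinant samples are all-Col, all-Ler or uniformly het
  ler_tot <- rowSums(f2$ler_reads)
  col_tot <- rowSums(f2$col_reads)
  expect_true(any(ler_tot == 0) || any(col_tot == 0) ||
                any(ler_tot > 0 & col_tot > 0))
})

test_that("annotation densities are recovered and the zone satellite spans the zero zone", {
  land <- study_landscape()
  ann <- simulate_annotation(land, gene_density_arm = 268,
                             gene_density_zone = 0, seed = 10)
  genes <- ann[ann$class == "gene", ]
  expect_false(any(genes$start >= 4e6 & genes$start < 6e6))
  sat <- ann[ann$class == "CEN178", ]
  expect_equal(c(sat$start, sat$end), c(4e6, 6e6))
  # arm gene count within the Poisson 99% interval of density x span
  arm_span_mb <- (1e7 - 2e6) / 1e6
  lim <- qpois(c(0.005, 0.995), 268 * arm_span_mb)
  expect_gte(nrow(genes), lim[1])
  expect_lte(nrow(genes), lim[2])
  # Monte-Carlo recovery of configured zone densities
  zone_counts <- vapply(1:30, function(s) {
    a <- simulate_annotation(land, gene_density_arm = 50,
                             gene_density_zone = 7, seed = s)
    g <- a[a$class == "gene", ]
    sum(g$start >= 4e6 & g$start < 6e6)
  }, numeric(1))
  expect_equal(mean(zone_counts), 7 * 2, tolerance = 0.25)
})

test_that("fluorescent seed counts invert the map-distance formula", {
  z <- simulate_ftl_counts(0, n_plants = 5, seeds_per_plant = 200, seed = 1)
  expect_true(all(z$n_green == 0 & z$n_red == 0))
  expect_error(simulate_ftl_counts(120), "0, 100")
  f <- (1 - (1 - 16.5 / 100)^2) / 2
  expect_equal(f, 0.1513875)
  big <- simulate_ftl_counts(16.5, n_plants = 200, seeds_per_plant = 2000,
                             seed = 2)
  expect_equal(sum(big$n_green + big$n_red) / sum(big$n_total), f,
               tolerance = 0.02)
  # parameter recovery at 18.3 cM
  counts <- simulate_ftl_counts(18.3, n_plants = 50, seeds_per_plant = 1000,
                                seed = 3)
  est <- ftl_map_distance(counts$n_green, counts$n_red, counts$n_total)
  expect_lt(abs(mean(est) - 18.3), 0.5)
})

test_that("KASP plates encode the designed crossovers and special plants", {
  imap <- kasp_interval_map(seq(0, 1e6, by = 1e5))
  pl <- simulate_kasp_plate(imap, n_plants = 60, missing_rate = 0,
                            n_contaminants = 3, n_double_chromatid = 2,
                            seed = 4)
  geno <- as.matrix(pl$plate[, -(1:2)])
  cont <- pl$truth$category == "contaminant"
  expect_equal(sum(cont), 3)
  expect_true(all(geno[cont, ] == "CC"))
  # ordinary plants: exactly one colour-consistent transition
  ord <- which(pl$truth$category == "singleCO")
  for (p in ord) {
    r <- rle(geno[p, ])$values
    exp_seq <- if (pl$plate$color[p] == "green") c("CL", "LL")
               else c("LL", "CL")
    expect_identical(unname(r), exp_seq)
  }
  expect_error(simulate_kasp_plate(imap, n_plants = 2, n_contaminants = 3),
               "exceed")
  # per-interval crossover proportions recover the configured rates
  rates <- c(5, rep(1, 9))
  imap2 <- kasp_interval_map(seq(0, 1e6, by = 1e5), rates = rates)
  pl2 <- simulate_kasp_plate(imap2, n_plants = 2000, seed = 5)
  emp <- tabulate(pl2$truth$interval1, nbins = 10) / 2000
  expect_lt(max(abs(emp - rates / sum(rates))), 0.03)
})
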