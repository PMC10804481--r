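test_that("fluorescent map distance reproduces hand-computed values", {
  expect_equal(ftl_map_distance(0, 0, 500), 0)
  expect_equal(ftl_map_distance(125, 125, 500), 100)  # fraction 1/2
  expect_equal(ftl_map_distance(50, 50, 1000), 100 * (1 - sqrt(0.8)),
               tolerance = 1e-12)
  expect_error(ftl_map_distance(300, 300, 1000), "undefined")
  expect_error(ftl_map_distance(0, 0, 0), "positive")
  # strictly increasing in the recombinant fraction
  fr <- seq(0, 0.49, by = 0.01)
  cm <- ftl_map_distance(fr * 1000, 0, 1000)
  expect_true(all(diff(cm) > 0))
  # exact inverse of the simulator's recombinant fraction
  for (true_cm in c(1, 16.5, 18.3, 55)) {
    f <- (1 - (1 - true_cm / 100)^2) / 2
    expect_equal(ftl_map_distance(f * 1e6 / 2, f * 1e6 / 2, 1e6), true_cm,
                 tolerance = 1e-12)
  }
})

test_that("KASP caller classifies every plate archetype", {
  # expected single crossover per fluorescence class
  g <- call_kasp_crossovers(c("CL", "CL", "CL", "LL", "LL"), "green")
  expect_equal(g$category, "singleCO")
  expect_equal(g$crossovers$first_interval, 3)
  r <- call_kasp_crossovers(c("LL", "LL", "CL", "CL", "CL"), "red")
  expect_equal(r$category, "singleCO")
  expect_equal(r$crossovers$first_interval, 2)
  # two single-crossover chromatids from a homozygous fluorescent seed
  d <- call_kasp_crossovers(c("CC", "CC", "CL", "CL", "LL"), "green")
  expect_equal(d$category, "doubleChromatid")
  expect_equal(d$n_counted, 2)
  expect_equal(d$crossovers$first_interval, c(2, 4))
  d2 <- call_kasp_crossovers(c("LL", "CL", "CC", "CC", "CC"), "red")
  expect_equal(d2$category, "doubleChromatid")
  # uniform Col/Col contamination
  expect_equal(call_kasp_crossovers(rep("CC", 6), "green")$category,
               "contaminant")
  # one single-crossover chromatid plus one double-crossover chromatid
  dc <- call_kasp_crossovers(c("CL", "CC", "CL", "LL"), "green")
  expect_equal(dc$category, "doubleCOchromatid")
  expect_equal(dc$n_counted, 1)
  expect_equal(dc$crossovers$transition, "CL>LL")
  dc2 <- call_kasp_crossovers(c("LL", "CL", "CC", "CL"), "red")
  expect_equal(dc2$category, "doubleCOchromatid")
  expect_equal(dc2$crossovers$transition, "LL>CL")
  # missing genotype at the breakpoint
  amb <- call_kasp_crossovers(c("CL", "CL", NA, "LL", "LL"), "green")
  expect_equal(amb$category, "ambiguousBoundary")
  expect_equal(amb$crossovers$first_interval, 2)
  expect_equal(amb$crossovers$last_interval, 3)
  # colour-inconsistent transition with no special-case match
  expect_equal(call_kasp_crossovers(c("LL", "LL", "CL"), "green")$category,
               "unresolvable")
})

test_that("ambiguous crossovers are allocated proportionally, conserving mass", {
  expect_equal(allocate_ambiguous(list(c(1, 2)), c(11, 9)), c(0.55, 0.45))
  expect_equal(allocate_ambiguous(list(c(1, 2)), c(0, 0)), c(0.5, 0.5))
  expect_equal(allocate_ambiguous(list(c(1, 2)), c(3, 1)), c(0.75, 0.25))
  set.seed(51)
  for (i in 1:20) {
    k <- sample(3:8, 1)
    tal <- rpois(k, 4)
    spans <- lapply(1:5, function(j) sort(sample.int(k, sample(2:3, 1))))
    add <- allocate_ambiguous(spans, tal)
    expect_equal(sum(add), 5, tolerance = 1e-12)
  }
})

test_that("plate tallies conserve counted crossovers", {
  imap <- kasp_interval_map(seq(0, 1e6, by = 1e5))
  pl <- simulate_kasp_plate(imap, n_plants = 300, missing_rate = 0.02,
                            n_contaminants = 3, n_double_chromatid = 2,
                            seed = 52)
  kt <- call_kasp_plate(pl$plate, imap)
  expect_equal(sum(kt$tally), kt$n_crossovers, tolerance = 1e-9)
  expect_equal(kt$n_crossovers,
               sum(kt$classification$n_counted), tolerance = 1e-9)
  expect_equal(sum(kt$classification$category == "contaminant"), 3)
  # with no missing data the truth intervals are recovered exactly
  pl0 <- simulate_kasp_plate(imap, n_plants = 400, missing_rate = 0,
                             seed = 53)
  kt0 <- call_kasp_plate(pl0$plate, imap)
  truth_tally <- tabulate(pl0$truth$interval1, nbins = 10)
  expect_equal(kt0$tally, truth_tally)
})

test_that("hotspot chi-square matches the worked example and the binomial oracle", {
  imap <- kasp_interval_map(seq(0, 1e6, by = 1e5))
  even <- hotspot_coldspot_test(rep(10, 10), imap)
  expect_true(all(even$class == "none"))
  tal <- c(30, rep(70 / 9, 9))
  h <- hotspot_coldspot_test(tal, imap)
  expect_equal(h$p[1], pchisq((30 - 10)^2 / 10 + (70 - 90)^2 / 90, 1,
                              lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(h$class[1], "hotspot")
  expect_error(hotspot_coldspot_test(rep(0, 10), imap), "positive")
  expect_error(
    hotspot_coldspot_test(rep(1, 2),
                          kasp_interval_map(c(0, 5, 5.5) * 1e5)), NA)
  # agreement with an exact binomial oracle away from the threshold
  set.seed(54)
  n_straddle <- 0
  n_compared <- 0
  for (i in 1:40) {
    k <- sample(5:15, 1)
    pos <- sort(sample.int(2e6, k + 1)) - 1
    im <- kasp_interval_map(pos)
    total <- sample(30:200, 1)
    tal <- as.numeric(rmultinom(1, total,
                                prob = rexp(k) * (im$end - im$start)))
    res <- hotspot_coldspot_test(tal, im)
    len <- im$end - im$start
    for (j in seq_len(k)) {
      bt <- binom.test(round(tal[j]), total, len[j] / sum(len))
      oracle_p <- min(1, bt$p.value * k)
      oracle_cls <- if (oracle_p <= 0.05 && tal[j] > res$expected[j])
        "hotspot" else if (oracle_p <= 0.05 && tal[j] < res$expected[j])
        "coldspot" else "none"
      straddle <- (res$p_adj[j] <= 0.05) != (oracle_p <= 0.05)
      n_compared <- n_compared + 1
      if (straddle) n_straddle <- n_straddle + 1
      else expect_equal(res$class[j], oracle_cls)
    }
  }
  # approximate and exact tests may straddle the alpha threshold on a
  # small fraction of intervals; everywhere else they must agree
  expect_lt(n_straddle / n_compared, 0.06)
})

test_that("between-genotype interval comparisons are symmetric and powered", {
  a <- c(10, 10, 10, 10)
  same <- compare_genotype_maps(a, a)
  expect_true(all(same$p == 1))
  b <- c(40, 10, 10, 60)
  ab <- compare_genotype_maps(a, b)
  ba <- compare_genotype_maps(b, a)
  expect_equal(ab$p, ba$p)
  # doubling one interval with totals held equal is detected at n >= 100
  x <- c(20, 40, 40)
  y <- c(40, 30, 30)
  cmp <- compare_genotype_maps(x, y)
  ft <- fisher.test(matrix(c(20, 80, 40, 60), 2, byrow = TRUE))
  expect_true(cmp$significant[1])
  expect_lt(ft$p.value, 0.05)   # exact oracle agrees on the flagged interval
  expect_error(compare_genotype_maps(c(0, 0), c(1, 1)), "zero total")
})

test_that("regional crossover fractions reproduce the methylation-mutant shifts", {
  # zone tallies reconstructed from printed totals and percentages
  wt <- c(nrz = 0, lrz = 104, distal = 809)       # 913 crossovers
  cmt3 <- c(nrz = 1, lrz = 189, distal = 843)     # 1033 crossovers
  met1 <- c(nrz = 0, lrz = 67, distal = 895)      # 962 crossovers
  even <- zone_fraction_test(wt, wt)
  expect_true(all(even$p == 1))
  zc <- zone_fraction_test(cmt3, wt)
  expect_equal(round(100 * zc$prop[zc$region == "lrz"], 1), 18.3)
  expect_equal(round(100 * zc$prop_ref[zc$region == "lrz"], 1), 11.4)
  expect_lt(zc$p[zc$region == "lrz"], 1e-4)
  zm <- zone_fraction_test(met1, wt)
  expect_equal(round(100 * zm$prop[zm$region == "lrz"], 1), 7.0)
  expect_equal(zm$p[zm$region == "lrz"], 1.17e-3, tolerance = 0.01)
  # simulated 2x LRZ enrichment at n = 1000 is flagged
  set.seed(55)
  ref <- c(nrz = 0, lrz = 110, distal = 890)
  test <- c(nrz = 0, lrz = 220, distal = 780)
  expect_lt(zone_fraction_test(test, ref)$p[2], 0.001)
})
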