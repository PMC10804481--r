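#' Configuration for a simulated recombinant population
#'
#' Bundles the parameters of a simulated backcross (BC1) or F2
#' resequencing population. Defaults emulate a low-coverage resequencing
#' experiment on a recombinant mapping population: markers roughly every
#' kilobase and about one read per marker per sample.
#'
#' @param population `"bc1"` or `"f2"`.
#' @param n_samples Number of plants.
#' @param marker_spacing Mean inter-marker distance in bp (gaps are
#'   exponential, i.e. markers form a Poisson process).
#' @param mean_depth Mean reads per marker per sample.
#' @param allele_error Probability that a read reports the wrong parental
#'   allele.
#' @param missing_rate Probability that a marker is uncalled (zero reads) in
#'   a sample, in addition to Poisson depth zeros.
#' @param contamination_fraction Fraction of samples generated as
#'   non-recombinant foreign (uniformly homozygous) genotypes.
#' @param low_coverage_fraction Fraction of samples sequenced at under a
#'   twentieth of the target depth.
#' @param backcross_parent Recurrent parent of the backcross (`"col"` or
#'   `"ler"`); ignored for F2.
#' @param interference_nu Optional gamma-renewal interference strength for
#'   crossover placement. `NULL` (the default) places crossovers as a
#'   Poisson process along the genetic map; values above 1 space
#'   crossovers apart as under chiasma interference (Arabidopsis-like
#'   behaviour around 5).
#' @param deterministic_reads When `TRUE`, read depth is fixed at
#'   `round(mean_depth)` and allele reads equal their expectation exactly
#'   (no binomial sampling): idealised data for validating the caller.
#' @param seed Optional RNG seed.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(population = c("bc1", "f2"), n_samples = 100L,
                              marker_spacing = 1000, mean_depth = 1,
                              allele_error = 0.002, missing_rate = 0,
                              contamination_fraction = 0,
                              low_coverage_fraction = 0,
                              backcross_parent = c("col", "ler"),
                              interference_nu = NULL,
                              deterministic_reads = FALSE,
                              seed = NULL) {
  population <- match.arg(population)
  backcross_parent <- match.arg(backcross_parent)
  probs <- c(allele_error, missing_rate, contamination_fraction,
             low_coverage_fraction)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must be in [0, 1]")
  if (n_samples < 1) stop("'n_samples' must be at least 1")
  if (mean_depth <= 0) stop("'mean_depth' must be positive")
  structure(list(population = population, n_samples = as.integer(n_samples),
                 marker_spacing = marker_spacing, mean_depth = mean_depth,
                 allele_error = allele_error, missing_rate = missing_rate,
                 contamination_fraction = contamination_fraction,
                 low_coverage_fraction = low_coverage_fraction,
                 backcross_parent = backcross_parent,
                 interference_nu = interference_nu,
                 deterministic_reads = deterministic_reads, seed = seed),
            class = "simulation_config")
}

#' Simulate a recombinant resequencing population
#'
#' Generates markers, per-sample allele-depth matrices and a latent truth
#' set for a BC1 or F2 population under a recombination landscape.
#' Crossover counts per gamete are Poisson with mean `total_cm / 100` and
#' positions are drawn by inverse-CDF sampling of the landscape intensity.
#' BC1 plants carry one recombinant gamete plus a fixed gamete from the
#' recurrent parent; F2 plants carry two independent recombinant gametes.
#' Read depth per marker is Poisson and allele reads are binomial with the
#' expected parental allele fraction perturbed by the allele error rate.
#'
#' @param landscape A [recombination_landscape()].
#' @param config A [simulation_config()].
#' @return A list of class `"recombinant_population"` with elements
#'   `markers` (data.frame: chrom, pos, col_allele, ler_allele; `pos`
#'   0-based), `col_reads` and `ler_reads` (sample x marker integer
#'   matrices), `truth` (list: `crossovers` data.frame(sample, gamete, pos),
#'   `flags` data.frame(sample, contaminant, low_coverage)), plus the
#'   landscape and config.
#' @examples
#' land <- recombination_landscape(2e6, total_cm = 20)
#' pop <- simulate_population(land, simulation_config(n_samples = 5, seed = 1))
#' dim(pop$col_reads)
#' @export
simulate_population <- function(landscape, config = simulation_config()) {
  stopifnot(inherits(landscape, "recombination_landscape"),
            inherits(config, "simulation_config"))
  if (landscape$total_cm < 0) stop("'total_cm' must be non-negative")
  if (!is.null(config$seed)) set.seed(config$seed)
  L <- landscape$chrom_length
  ns <- config$n_samples

  # marker positions: Poisson process along the chromosome
  n_exp <- max(2, ceiling(L / config$marker_spacing * 1.3))
  gaps <- stats::rexp(n_exp, rate = 1 / config$marker_spacing)
  pos <- cumsum(gaps)
  while (sum(pos < L) < 2) pos <- c(pos, pos[length(pos)] +
                                      cumsum(stats::rexp(n_exp, 1 / config$marker_spacing)))
  pos <- floor(pos[pos < L])
  pos <- unique(pos)
  nm <- length(pos)
  alle <- .sample_allele_pairs(nm)
  markers <- data.frame(chrom = landscape$chrom, pos = pos,
                        col_allele = alle$col, ler_allele = alle$ler,
                        stringsAsFactors = FALSE)

  contaminant <- stats::runif(ns) < config$contamination_fraction
  low_cov <- !contaminant & stats::runif(ns) < config$low_coverage_fraction

  n_gam <- if (config$population == "f2") 2L else 1L
  co_list <- vector("list", ns * n_gam)
  # col-allele dosage per sample per marker (0, 1 or 2 over ploidy 2)
  dosage <- matrix(0L, ns, nm)
  fixed_col <- if (config$backcross_parent == "col") 1L else 0L
  k <- 0L
  for (s in seq_len(ns)) {
    if (contaminant[s]) {
      dosage[s, ] <- 2L * fixed_col  # foreign, uniformly homozygous
      next
    }
    d <- if (config$population == "f2") 0L else fixed_col
    for (g in seq_len(n_gam)) {
      cos <- .gamete_crossovers(landscape, config$interference_nu)
      start_col <- stats::runif(1) < 0.5
      # allele at marker = start parent flipped once per crossover to its left
      flips <- findInterval(pos, cos)
      gam <- as.integer(xor(start_col, flips %% 2 == 1))
      d <- d + gam
      k <- k + 1L
      if (length(cos) > 0) {
        co_list[[k]] <- data.frame(sample = s, gamete = g, pos = cos)
      }
    }
    dosage[s, ] <- d
  }
  crossovers <- if (k > 0) do.call(rbind, co_list[!vapply(co_list, is.null, TRUE)])
                else NULL
  if (is.null(crossovers)) {
    crossovers <- data.frame(sample = integer(0), gamete = integer(0),
                             pos = numeric(0))
  }

  depth_mean <- rep(config$mean_depth, ns)
  depth_mean[low_cov] <- config$mean_depth * 0.05
  e <- config$allele_error
  p_col <- dosage / 2
  p_obs <- p_col * (1 - 2 * e) + e
  if (config$deterministic_reads) {
    depth <- matrix(round(rep(depth_mean, nm)), ns, nm)
    col_reads <- round(depth * p_obs)
  } else {
    depth <- matrix(stats::rpois(ns * nm, rep(depth_mean, nm)), ns, nm)
    col_reads <- matrix(stats::rbinom(ns * nm, depth, p_obs), ns, nm)
  }
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(ns * nm) < config$missing_rate, ns, nm)
    depth[miss] <- 0L
    col_reads[miss] <- 0L
  }
  ler_reads <- depth - col_reads
  rownames(col_reads) <- rownames(ler_reads) <-
    sprintf("S%03d", seq_len(ns))

  structure(list(markers = markers, col_reads = col_reads,
                 ler_reads = ler_reads,
                 truth = list(crossovers = crossovers,
                              flags = data.frame(sample = seq_len(ns),
                                                 contaminant = contaminant,
                                                 low_coverage = low_cov)),
                 landscape = landscape, config = config),
            class = "recombinant_population")
}

#' @export
print.recombinant_population <- function(x, ...) {
  cat(sprintf("Simulated %s population: %d samples, %d markers, %d true crossovers\n",
              toupper(x$config$population), nrow(x$col_reads),
              nrow(x$markers), nrow(x$truth$crossovers)))
  invisible(x)
}

.sample_allele_pairs <- function(n) {
  nt <- c("A", "C", "G", "T")
  col <- sample(nt, n, replace = TRUE)
  shift <- sample.int(3, n, replace = TRUE)
  ler <- nt[((match(col, nt) - 1L + shift) %% 4L) + 1L]
  list(col = col, ler = ler)
}

#' Simulate a genome annotation track
#'
#' Places gene and transposon features along a chromosome with Poisson
#' counts around the configured densities, using the landscape's zero zone
#' as the satellite-array region. Genes inside the zone are placed at
#' `gene_density_zone`, genes elsewhere at `gene_density_arm`; transposons
#' inside the zone at `te_density_zone` and elsewhere at `te_density_arm`.
#' Gene features are made non-overlapping by truncating each gene at its
#' right neighbour; transposons may overlap. One satellite feature spans
#' the zero zone.
#'
#' @param landscape A [recombination_landscape()] with a `zero_zone`.
#' @param gene_density_arm,gene_density_zone Genes per Mb outside/inside the
#'   zone.
#' @param te_density_zone,te_density_arm Transposons per Mb inside/outside
#'   the zone.
#' @param gene_width,te_width Mean feature widths in bp.
#' @param seed Optional RNG seed.
#' @return A data.frame (chrom, start, end, name, class) with class in
#'   `{gene, Gypsy/Ty3, Helitron, CEN178}`; coordinates 0-based half-open.
#' @export
simulate_annotation <- function(landscape, gene_density_arm = 268,
                                gene_density_zone = 7, te_density_zone = 120,
                                te_density_arm = 30, gene_width = 2000,
                                te_width = 5000, seed = NULL) {
  stopifnot(inherits(landscape, "recombination_landscape"))
  if (landscape$chrom_length <= 0) stop("chromosome length must be positive")
  dens <- c(gene_density_arm, gene_density_zone, te_density_zone,
            te_density_arm)
  if (any(dens < 0)) stop("densities must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  L <- landscape$chrom_length
  zone <- landscape$zero_zone
  if (is.null(zone)) zone <- c(0, 0)
  chrom <- landscape$chrom

  regions <- rbind(
    data.frame(start = 0, end = zone[1]),
    data.frame(start = zone[1], end = zone[2]),
    data.frame(start = zone[2], end = L))
  regions$gene_dens <- c(gene_density_arm, gene_density_zone,
                         gene_density_arm)
  regions$te_dens <- c(te_density_arm, te_density_zone, te_density_arm)

  place <- function(density, width, region) {
    span_mb <- (region$end - region$start) / 1e6
    n <- stats::rpois(1, density * span_mb)
    if (n == 0) return(NULL)
    start <- sort(floor(stats::runif(n, region$start, region$end)))
    data.frame(start = start, end = pmin(start + width, region$end))
  }

  genes <- list(); tes <- list()
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    if (r$end <= r$start) next
    g <- place(r$gene_dens, gene_width, r)
    if (!is.null(g)) genes[[length(genes) + 1L]] <- g
    t1 <- place(r$te_dens, te_width, r)
    if (!is.null(t1)) tes[[length(tes) + 1L]] <- t1
  }
  out <- list()
  if (length(genes)) {
    g <- do.call(rbind, genes)
    g <- g[order(g$start), , drop = FALSE]
    # non-overlapping: truncate each gene at the next gene's start
    if (nrow(g) > 1) {
      g$end <- pmin(g$end, c(g$start[-1], Inf))
    }
    g <- g[g$end > g$start, , drop = FALSE]
    out$gene <- data.frame(chrom = chrom, start = g$start, end = g$end,
                           name = sprintf("gene%05d", seq_len(nrow(g))),
                           class = "gene", stringsAsFactors = FALSE)
  }
  if (length(tes)) {
    t1 <- do.call(rbind, tes)
    t1 <- t1[order(t1$start), , drop = FALSE]
    fam <- sample(c("Gypsy/Ty3", "Helitron"), nrow(t1), replace = TRUE,
                  prob = c(0.7, 0.3))
    out$te <- data.frame(chrom = chrom, start = t1$start, end = t1$end,
                         name = sprintf("te%05d", seq_len(nrow(t1))),
                         class = fam, stringsAsFactors = FALSE)
  }
  if (zone[2] > zone[1]) {
    out$sat <- data.frame(chrom = chrom, start = zone[1], end = zone[2],
                          name = "satellite_array", class = "CEN178",
                          stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, out)
  rownames(ann) <- NULL
  ann[order(ann$start), , drop = FALSE]
}

#' Simulate fluorescent seed counts for a reporter interval
#'
#' Inverse of the fluorescent-reporter map-distance estimator: for a true
#' genetic distance `true_cm` between two linked hemizygous fluorescent
#' transgenes, the probability that a seed is single-colour recombinant is
#' `f = (1 - (1 - true_cm/100)^2) / 2`, split equally between green-alone
#' and red-alone classes. Per-plant counts are multinomial.
#'
#' @param true_cm True genetic distance in cM, in `[0, 100]`.
#' @param n_plants Number of plants scored.
#' @param seeds_per_plant Seeds counted per plant.
#' @param seed Optional RNG seed.
#' @return data.frame (plant_id, n_green, n_red, n_total).
#' @seealso [ftl_map_distance()]
#' @export
simulate_ftl_counts <- function(true_cm, n_plants = 20L,
                                seeds_per_plant = 1000L, seed = NULL) {
  if (true_cm < 0 || true_cm > 100) stop("'true_cm' must be in [0, 100]")
  if (!is.null(seed)) set.seed(seed)
  f <- (1 - (1 - true_cm / 100)^2) / 2
  cnt <- stats::rmultinom(n_plants, seeds_per_plant, c(f / 2, f / 2, 1 - f))
  data.frame(plant_id = sprintf("plant%03d", seq_len(n_plants)),
             n_green = cnt[1, ], n_red = cnt[2, ],
             n_total = seeds_per_plant, stringsAsFactors = FALSE)
}

#' Interval map for reporter-interval genotyping
#'
#' Builds the ordered inter-marker interval map used by the KASP caller
#' and the plate simulator from marker physical positions.
#'
#' @param positions Marker positions in bp (0-based), strictly increasing.
#' @param rates Optional per-interval relative crossover rates
#'   (length `length(positions) - 1`); default uniform per bp.
#' @return data.frame (interval, start, end, rate) of class
#'   `"kasp_interval_map"`.
#' @export
kasp_interval_map <- function(positions, rates = NULL) {
  if (length(positions) < 2 || is.unsorted(positions, strictly = TRUE)) {
    stop("'positions' must be at least two strictly increasing values")
  }
  n <- length(positions) - 1L
  if (is.null(rates)) rates <- diff(positions)
  if (length(rates) != n || any(rates < 0)) {
    stop("'rates' must be ", n, " non-negative values")
  }
  structure(data.frame(interval = seq_len(n),
                       start = positions[-length(positions)],
                       end = positions[-1], rate = as.numeric(rates)),
            class = c("kasp_interval_map", "data.frame"))
}

#' Simulate a KASP genotyping plate of selected recombinant plants
#'
#' Emulates genotyping of single-colour fluorescent F2 seed selected for
#' one crossover between two reporter transgenes. Ordinary plants carry
#' one crossover placed multinomially across intervals and encoded as the
#' genotype transition expected for their fluorescence class (green-alone:
#' Col/Ler to Ler/Ler; red-alone: Ler/Ler to Col/Ler). Designated plants
#' carry two single-crossover chromatids (Col/Col to Col/Ler to Ler/Ler
#' patterns, from selected homozygous fluorescent seed) or are uniformly
#' Col/Col contaminants. Genotypes are dropped to missing at
#' `missing_rate`.
#'
#' @param interval_map A [kasp_interval_map()] with per-interval true rates.
#' @param n_plants Total plants on the plate.
#' @param missing_rate Per-genotype missing probability.
#' @param n_contaminants Number of uniformly Col/Col contaminant plants.
#' @param n_double_chromatid Number of plants carrying two single-crossover
#'   chromatids.
#' @param seed Optional RNG seed.
#' @return list with `plate` (data.frame: plant_id, color, then one column
#'   per marker with genotypes in `{CC, CL, LL, NA}`) and `truth`
#'   (data.frame: plant_id, category, interval1, interval2).
#' @export
simulate_kasp_plate <- function(interval_map, n_plants = 908L,
                                missing_rate = 0, n_contaminants = 0L,
                                n_double_chromatid = 0L, seed = NULL) {
  stopifnot(inherits(interval_map, "kasp_interval_map"))
  if (nrow(interval_map) == 0) stop("empty interval map")
  if (n_contaminants + n_double_chromatid > n_plants) {
    stop("special-case counts exceed 'n_plants'")
  }
  if (!is.null(seed)) set.seed(seed)
  ni <- nrow(interval_map)
  nmark <- ni + 1L
  prob <- interval_map$rate / sum(interval_map$rate)

  cat_v <- rep("singleCO", n_plants)
  if (n_contaminants > 0) cat_v[seq_len(n_contaminants)] <- "contaminant"
  if (n_double_chromatid > 0) {
    cat_v[n_contaminants + seq_len(n_double_chromatid)] <- "doubleChromatid"
  }
  cat_v <- sample(cat_v)
  color <- sample(c("green", "red"), n_plants, replace = TRUE)

  geno <- matrix(NA_character_, n_plants, nmark)
  iv1 <- iv2 <- rep(NA_integer_, n_plants)
  for (p in seq_len(n_plants)) {
    if (cat_v[p] == "contaminant") {
      geno[p, ] <- "CC"
      next
    }
    if (cat_v[p] == "doubleChromatid") {
      # two crossovers on different chromatids; distinct intervals so the
      # plate shows the full CC -> CL -> LL (or reverse) pattern
      if (ni < 2) stop("double-chromatid plants need at least 2 intervals")
      iv <- sort(sample.int(ni, 2, replace = FALSE, prob = prob))
      iv1[p] <- iv[1]; iv2[p] <- iv[2]
      g <- c(rep("CC", iv[1]), rep("CL", iv[2] - iv[1]),
             rep("LL", nmark - iv[2]))
      if (color[p] == "red") g <- rev(g)
      geno[p, ] <- g
      next
    }
    i <- sample.int(ni, 1, prob = prob)
    iv1[p] <- i
    g <- if (color[p] == "green") {
      c(rep("CL", i), rep("LL", nmark - i))
    } else {
      c(rep("LL", i), rep("CL", nmark - i))
    }
    geno[p, ] <- g
  }
  if (missing_rate > 0) {
    geno[matrix(stats::runif(length(geno)) < missing_rate,
                nrow(geno), ncol(geno))] <- NA_character_
  }
  plate <- data.frame(plant_id = sprintf("P%04d", seq_len(n_plants)),
                      color = color, stringsAsFactors = FALSE)
  gdf <- as.data.frame(geno, stringsAsFactors = FALSE)
  names(gdf) <- sprintf("M%02d", seq_len(nmark))
  plate <- cbind(plate, gdf)
  truth <- data.frame(plant_id = plate$plant_id, category = cat_v,
                      interval1 = iv1, interval2 = iv2,
                      stringsAsFactors = FALSE)
  # red-alone double-chromatid plates are mirrored; record mirrored intervals
  flip <- cat_v == "doubleChromatid" & color == "red"
  if (any(flip)) {
    t1 <- truth$interval1[flip]; t2 <- truth$interval2[flip]
    truth$interval1[flip] <- ni + 1L - t2
    truth$interval2[flip] <- ni + 1L - t1
  }
  list(plate = plate, truth = truth)
}
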