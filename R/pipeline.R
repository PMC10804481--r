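#' Pipeline configuration
#'
#' Builds the full configuration for [run_pipeline()], merging user
#' overrides (a named list or a YAML file) into the defaults. Every
#' parameter that affects results is serialised into the run manifest.
#'
#' @param config A named list of overrides, or a path to a YAML file.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    seed = 1L,
    landscape = list(chrom_length = 12e6, total_cm = 30,
                     zero_zone = c(4.8e6, 7.3e6),
                     flank_mb = 1.5, flank_cm = 1.2),
    population = list(type = "bc1", n_samples = 200L, marker_spacing = 1000,
                      mean_depth = 1, allele_error = 0.002,
                      missing_rate = 0, contamination_fraction = 0,
                      low_coverage_fraction = 0),
    caller = list(window = 70000, step = 35000, hom_threshold = 0.9,
                  min_markers = 5, min_run = 2, min_reads = 5,
                  double_max_frac = 0.04),
    zones = list(window = 1e5, target_cm = 1.0),
    ftl = list(true_cm = 16.5, n_plants = 20L, seeds_per_plant = 1000L),
    kasp = list(n_markers = 20L, n_plants = 200L, missing_rate = 0.01,
                n_contaminants = 0L, n_double_chromatid = 0L,
                alpha = 0.05),
    permutation = list(n_perm = 1000L))
  structure(utils::modifyList(defaults, config), class = "pipeline_config")
}

# suppression landscape implied by a pipeline config: high-rate arms,
# low-rate flanks around a central zero zone
.config_landscape <- function(cfg) {
  l <- cfg$landscape
  z <- l$zero_zone
  fl <- l$flank_mb * 1e6
  arm_span <- (l$chrom_length - (z[2] - z[1]) - 2 * fl) / 1e6
  arm_cm <- l$total_cm - 2 * l$flank_cm
  arm_rate <- arm_cm / 2 / arm_span
  flank_rate <- l$flank_cm / (fl / 1e6)
  recombination_landscape(
    l$chrom_length,
    breakpoints = c(z[1] - fl, z[1], z[2], z[2] + fl),
    rates = c(arm_rate, flank_rate, 0, flank_rate, arm_rate),
    total_cm = l$total_cm, zero_zone = z)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes simulate, marker filtering, crossover calling, zone
#' delineation, fluorescent-reporter estimation, KASP tallying with
#' hotspot detection, and a crossover-gene overlap permutation test, and
#' writes all stage outputs plus a JSON manifest into `out_dir`. Rerunning
#' with the same configuration reproduces identical outputs.
#'
#' @param config A [pipeline_config()], list of overrides, or YAML path.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with all stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  log_stage <- function(...) message(sprintf(...))

  land <- .config_landscape(config)
  pc <- config$population
  sim_cfg <- simulation_config(
    population = pc$type, n_samples = pc$n_samples,
    marker_spacing = pc$marker_spacing, mean_depth = pc$mean_depth,
    allele_error = pc$allele_error, missing_rate = pc$missing_rate,
    contamination_fraction = pc$contamination_fraction,
    low_coverage_fraction = pc$low_coverage_fraction)
  pop <- simulate_population(land, sim_cfg)
  ann <- simulate_annotation(land)
  log_stage("simulate: %d samples, %d markers, %d true crossovers",
            pc$n_samples, nrow(pop$markers), nrow(pop$truth$crossovers))
  write_marker_table(pop$markers, file.path(out_dir, "markers.tsv"))
  utils::write.table(ann, file.path(out_dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  profile <- marker_population_profile(pop$col_reads, pop$ler_reads)
  filt <- if (pc$type == "bc1") filter_bc1_markers(profile)
          else filter_f2_markers(profile)
  log_stage("filter-snps: %d/%d markers retained", sum(filt$pass),
            nrow(filt))
  utils::write.table(cbind(pop$markers, filt),
                     file.path(out_dir, "marker_filter.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  cc <- config$caller
  calls <- call_crossovers(pop, window = cc$window, step = cc$step,
                           hom_threshold = cc$hom_threshold,
                           min_markers = cc$min_markers,
                           min_run = cc$min_run, min_reads = cc$min_reads,
                           double_max_frac = cc$double_max_frac)
  log_stage("call-crossovers: %d calls retained, %d samples failed QC",
            nrow(calls$calls), sum(calls$qc$status != "pass"))
  utils::write.table(calls$calls, file.path(out_dir, "crossovers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(calls$qc, file.path(out_dir, "sample_qc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  n_gametes <- pc$n_samples * (if (pc$type == "f2") 2L else 1L)
  map <- windowed_map(calls$calls, n_gametes, land$chrom_length,
                      config$zones$window)
  sat <- ann[ann$class == "CEN178", , drop = FALSE]
  nrz <- define_nrz(map, sat)
  zones_out <- NULL
  if (nrow(nrz)) {
    lrz <- define_lrz(map, nrz, config$zones$target_cm)
    zones_out <- zone_summary(nrz, lrz, map, ann)
    bed <- data.frame(chrom = c(nrz$chrom, lrz$chrom),
                      start = c(nrz$start, lrz$start),
                      end = c(nrz$end, lrz$end),
                      name = c("NRZ", lrz$side))
    if (requireNamespace("rtracklayer", quietly = TRUE)) {
      write_bed(bed, file.path(out_dir, "zones.bed"))
    }
    utils::write.table(zones_out, file.path(out_dir, "zone_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("zones: NRZ %.2f Mb, LRZ cM %.2f / %.2f",
              (nrz$end - nrz$start) / 1e6, lrz$attained_cm[1],
              lrz$attained_cm[2])
  } else {
    log_stage("zones: no NRZ found")
  }

  ftl_counts <- simulate_ftl_counts(config$ftl$true_cm, config$ftl$n_plants,
                                    config$ftl$seeds_per_plant)
  ftl_cm <- ftl_map_distance(ftl_counts$n_green, ftl_counts$n_red,
                             ftl_counts$n_total)
  utils::write.table(cbind(ftl_counts, cm = ftl_cm),
                     file.path(out_dir, "ftl.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log_stage("ftl: mean %.2f cM over %d plants", mean(ftl_cm),
            nrow(ftl_counts))

  kc <- config$kasp
  kasp_pos <- sort(sample.int(land$chrom_length, kc$n_markers))
  imap <- kasp_interval_map(kasp_pos)
  plate <- simulate_kasp_plate(imap, kc$n_plants, kc$missing_rate,
                               kc$n_contaminants, kc$n_double_chromatid)
  ktal <- call_kasp_plate(plate$plate, imap)
  hot <- hotspot_coldspot_test(ktal$tally, imap, kc$alpha)
  utils::write.table(hot, file.path(out_dir, "kasp_intervals.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("kasp: %.1f crossovers, %d hotspot(s), %d coldspot(s)",
            ktal$n_crossovers, sum(hot$class == "hotspot"),
            sum(hot$class == "coldspot"))

  perm <- NULL
  genes <- ann[ann$class == "gene", , drop = FALSE]
  if (nrow(calls$calls) > 0 && nrow(genes) > 0) {
    bgd <- data.frame(chrom = land$chrom, start = 0,
                      end = land$chrom_length)
    perm <- permute_overlap(calls$calls[, c("chrom", "start", "end")],
                            genes, bgd, config$permutation$n_perm)
    log_stage("permtest: observed %d, p(enrich) = %.3g", perm$observed,
              perm$p_enrich)
  }

  manifest <- list(package_version = as.character(utils::packageVersion("centroscan")),
                   config = unclass(config),
                   n_markers = nrow(pop$markers),
                   n_markers_retained = sum(filt$pass),
                   n_calls = nrow(calls$calls))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(population = pop, annotation = ann, marker_filter = filt,
                 crossovers = calls, map = map, nrz = nrz,
                 zones = zones_out, ftl_cm = ftl_cm, kasp = ktal,
                 hotspots = hot, permutation = perm))
}
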