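#' Population-level marker profile
#'
#' Summarises an allele-depth matrix into the per-marker read and genotype
#' profile consumed by the population marker filters. Per sample and
#' marker, a crude genotype is assigned from the reads: heterozygous when
#' both parental alleles are observed, homozygous when only one is, and
#' ungenotyped at zero depth.
#'
#' @param col_reads,ler_reads Sample x marker read-count matrices.
#' @return data.frame with one row per marker: `col_read_total`,
#'   `total_read_total`, `n_hom_col`, `n_het`, `n_hom_ler`, `n_genotyped`.
#' @export
marker_population_profile <- function(col_reads, ler_reads) {
  stopifnot(all(dim(col_reads) == dim(ler_reads)))
  has_col <- col_reads > 0
  has_ler <- ler_reads > 0
  data.frame(
    col_read_total = colSums(col_reads),
    total_read_total = colSums(col_reads + ler_reads),
    n_hom_col = colSums(has_col & !has_ler),
    n_het = colSums(has_col & has_ler),
    n_hom_ler = colSums(!has_col & has_ler),
    n_genotyped = colSums(has_col | has_ler))
}

.profile_ratios <- function(profile) {
  n <- profile$n_genotyped
  safe <- function(x, d) ifelse(d > 0, x / d, NA_real_)
  list(col_ratio = safe(profile$col_read_total, profile$total_read_total),
       hom_col = safe(profile$n_hom_col, n),
       het = safe(profile$n_het, n),
       hom_ler = safe(profile$n_hom_ler, n),
       n = n)
}

.apply_marker_filter <- function(profile, checks) {
  reasons <- character(nrow(profile))
  pass <- rep(TRUE, nrow(profile))
  for (nm in names(checks)) {
    ok <- checks[[nm]]
    ok[is.na(ok)] <- FALSE
    bad <- !ok
    reasons[bad] <- ifelse(nzchar(reasons[bad]),
                           paste(reasons[bad], nm, sep = ","), nm)
    pass <- pass & ok
  }
  ung <- profile$n_genotyped == 0
  reasons[ung] <- "ungenotyped"
  pass[ung] <- FALSE
  data.frame(pass = pass, reason = reasons, stringsAsFactors = FALSE)
}

#' Backcross-population marker filter
#'
#' Retains markers whose population-level profile matches the segregation
#' expected in a Col x (Col/Ler F1) backcross. All five criteria use
#' strict inequalities: Col allelic read ratio in (0.6, 0.9); fraction of
#' homozygous-Col samples in (0.4, 0.7); heterozygous fraction in
#' (0.3, 0.6); homozygous-Ler fraction below 0.1; and more than
#' `min_genotyped` genotyped samples.
#'
#' @param profile A [marker_population_profile()].
#' @param min_genotyped Minimum number of genotyped samples (exclusive).
#' @return data.frame with per-marker `pass` and comma-separated `reason`
#'   codes for every failed criterion (`"ungenotyped"` for markers with no
#'   genotyped sample).
#' @export
filter_bc1_markers <- function(profile, min_genotyped = 70) {
  if (any(profile$total_read_total < 0)) stop("negative read totals")
  r <- .profile_ratios(profile)
  .apply_marker_filter(profile, list(
    col_ratio = r$col_ratio > 0.6 & r$col_ratio < 0.9,
    hom_col_ratio = r$hom_col > 0.4 & r$hom_col < 0.7,
    het_ratio = r$het > 0.3 & r$het < 0.6,
    hom_ler_ratio = r$hom_ler < 0.1,
    n_genotyped = r$n > min_genotyped))
}

#' F2-population marker filter
#'
#' Retains markers matching F2 Mendelian segregation: Col allelic read
#' ratio in (0.3, 0.7); each genotype-class fraction (homozygous Col,
#' heterozygous, homozygous Ler) in (0.1, 0.9); and more than
#' `min_genotyped` genotyped samples. All inequalities strict.
#'
#' @inheritParams filter_bc1_markers
#' @return As [filter_bc1_markers()].
#' @export
filter_f2_markers <- function(profile, min_genotyped = 5) {
  if (any(profile$total_read_total < 0)) stop("negative read totals")
  r <- .profile_ratios(profile)
  .apply_marker_filter(profile, list(
    col_ratio = r$col_ratio > 0.3 & r$col_ratio < 0.7,
    hom_col_ratio = r$hom_col > 0.1 & r$hom_col < 0.9,
    het_ratio = r$het > 0.1 & r$het < 0.9,
    hom_ler_ratio = r$hom_ler > 0.1 & r$hom_ler < 0.9,
    n_genotyped = r$n > min_genotyped))
}

#' Remove markers near repeats or structural variants
#'
#' Drops markers that fall within `flank` bp of any feature in a repeat /
#' structural-variant annotation track, the usual guard against alignment
#' artefacts around tandem repeats and indels.
#'
#' @param markers data.frame with `chrom` and 0-based `pos`.
#' @param repeat_features data.frame with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param flank Symmetric expansion of each feature, in bp.
#' @return The retained subset of `markers`.
#' @export
exclude_repeat_proximal <- function(markers, repeat_features, flank = 0) {
  if (flank < 0) stop("'flank' must be non-negative")
  if (is.null(repeat_features) || nrow(repeat_features) == 0) return(markers)
  mk <- GenomicRanges::GRanges(markers$chrom,
                               IRanges::IRanges(markers$pos + 1L, width = 1L))
  ft <- GenomicRanges::GRanges(
    repeat_features$chrom,
    IRanges::IRanges(pmax(1, repeat_features$start + 1L - flank),
                     repeat_features$end + flank))
  hit <- IRanges::overlapsAny(mk, ft)
  markers[!hit, , drop = FALSE]
}
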