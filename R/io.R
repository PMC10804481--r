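#' Read a marker table
#'
#' Reads a TSV of markers (`chrom`, `pos`, `col_allele`, `ler_allele`)
#' with 1-based positions and converts positions to the internal 0-based
#' convention. Positions must be strictly increasing within each
#' chromosome.
#'
#' @param path File path.
#' @return data.frame with 0-based `pos`.
#' @export
read_marker_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "col_allele", "ler_allele")
  if (!all(req %in% names(df))) {
    stop("marker table must have columns: ", paste(req, collapse = ", "))
  }
  df$pos <- df$pos - 1L
  .check_sorted_markers(df)
  df
}

.check_sorted_markers <- function(df) {
  for (chr in unique(df$chrom)) {
    p <- df$pos[df$chrom == chr]
    bad <- which(diff(p) <= 0)
    if (length(bad)) {
      stop("markers unsorted or duplicated on ", chr,
           " at position ", p[bad[1] + 1L] + 1L)
    }
  }
  invisible(df)
}

#' Write a marker table
#'
#' @param markers data.frame with 0-based `pos` (written 1-based).
#' @param path Output path.
#' @export
write_marker_table <- function(markers, path) {
  out <- markers
  out$pos <- out$pos + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an allele-depth matrix
#'
#' Long-format TSV with columns `sample`, `chrom`, `pos` (1-based),
#' `col_reads`, `ler_reads`; returns sample x marker matrices aligned to
#' the sorted marker set.
#'
#' @param path File path.
#' @return list: `markers` (chrom, pos 0-based), `col_reads`, `ler_reads`.
#' @export
read_depth_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  req <- c("sample", "chrom", "pos", "col_reads", "ler_reads")
  if (!all(req %in% names(df))) {
    stop("depth matrix must have columns: ", paste(req, collapse = ", "))
  }
  df$pos <- df$pos - 1L
  key <- paste(df$chrom, df$pos)
  mk <- unique(df[order(df$chrom, df$pos), c("chrom", "pos")])
  .check_sorted_markers(mk)
  samples <- sort(unique(df$sample))
  shape <- function(col) {
    m <- matrix(0L, length(samples), nrow(mk),
                dimnames = list(samples, NULL))
    m[cbind(match(df$sample, samples),
            match(key, paste(mk$chrom, mk$pos)))] <- df[[col]]
    m
  }
  list(markers = mk, col_reads = shape("col_reads"),
       ler_reads = shape("ler_reads"))
}

#' Write an allele-depth matrix in long format
#'
#' @param col_reads,ler_reads Sample x marker matrices.
#' @param markers data.frame with `chrom` and 0-based `pos`.
#' @param path Output path.
#' @export
write_depth_matrix <- function(col_reads, ler_reads, markers, path) {
  samples <- rownames(col_reads)
  if (is.null(samples)) samples <- sprintf("S%03d", seq_len(nrow(col_reads)))
  df <- data.frame(
    sample = rep(samples, times = nrow(markers)),
    chrom = rep(markers$chrom, each = nrow(col_reads)),
    pos = rep(markers$pos + 1L, each = nrow(col_reads)),
    col_reads = as.vector(col_reads), ler_reads = as.vector(ler_reads))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read genotype calls from a VCF
#'
#' Maps diploid GT fields to two-letter genotype codes (`0/0` to `CC`,
#' `0/1` or `1/0` to `CL`, `1/1` to `LL`, missing to `NA`), treating the
#' reference allele as the Col parent. When the VCF carries AD fields the
#' per-sample allele depths are returned as well.
#'
#' @param path VCF path (plain text or bgzip).
#' @return list: `markers` (chrom, pos 0-based, col_allele, ler_allele),
#'   `genotypes` (sample x marker character matrix), and `col_reads` /
#'   `ler_reads` when AD is present.
#' @export
read_genotype_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("reading VCF requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  markers <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr) - 1L,
    col_allele = as.character(rr$REF),
    ler_allele = vapply(rr$ALT, function(a) as.character(a)[1],
                        character(1)),
    stringsAsFactors = FALSE)
  .check_sorted_markers(markers)
  gt <- VariantAnnotation::geno(vcf)$GT
  map <- c("0/0" = "CC", "0|0" = "CC", "0/1" = "CL", "1/0" = "CL",
           "0|1" = "CL", "1|0" = "CL", "1/1" = "LL", "1|1" = "LL")
  geno <- t(matrix(map[gt], nrow(gt), ncol(gt),
                   dimnames = dimnames(gt)))
  out <- list(markers = markers, genotypes = geno)
  if ("AD" %in% names(VariantAnnotation::geno(vcf))) {
    ad <- VariantAnnotation::geno(vcf)$AD
    out$col_reads <- t(apply(ad, c(1, 2), function(x) x[[1]][1]))
    out$ler_reads <- t(apply(ad, c(1, 2), function(x) x[[1]][2]))
  }
  out
}

#' Write intervals as BED
#'
#' Writes 0-based half-open intervals as a sorted BED file (name in
#' column 4) via rtracklayer.
#'
#' @param regions data.frame with `chrom`, `start`, `end`, optional
#'   `name`.
#' @param path Output path ending in `.bed`.
#' @export
write_bed <- function(regions, path) {
  if (any(regions$start < 0)) stop("negative coordinates")
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("BED output requires the rtracklayer package")
  }
  regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  gr <- .df_to_gr(regions)
  if (!is.null(regions$name)) gr$name <- regions$name
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED file into a 0-based interval data.frame
#'
#' @param path BED path.
#' @return data.frame (chrom, start, end, name) with 0-based half-open
#'   coordinates.
#' @export
read_bed <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("BED input requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  if (!is.null(gr$name)) df$name <- gr$name
  df
}
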