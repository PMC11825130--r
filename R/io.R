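# Centralized coordinate conventions: VCF/GFF3 are 1-based inclusive as per
# their standards; BED and all internal region coordinates are 0-based
# half-open. Conversions happen only in this file.

.provenance_header <- function(seed = NA, config_hash = NA) {
  c(sprintf("# sweepshare %s",
            as.character(utils::packageVersion("sweepshare"))),
    sprintf("# seed=%s config=%s", seed, config_hash))
}

#' Write a haplotype matrix as a VCF file
#'
#' Writes a minimal VCF 4.2 with biallelic SNPs, phased diploid genotypes
#' (haplotypes paired in order) and the ancestral allele in the `AA` INFO
#' tag. The ancestral allele is always REF here (derived states are known by
#' construction in synthetic data).
#'
#' @param hap a [hap_matrix()] with an even `n_hap`.
#' @param path output path (`.vcf`).
#' @param ref,alt reference (= ancestral) and alternate base labels.
#' @return `path`, invisibly.
#' @export
write_population_vcf <- function(hap, path, ref = "A", alt = "G") {
  stopifnot(inherits(hap, "hap_matrix"))
  if (hap$n_hap %% 2 != 0)
    stop("n_hap must be even to pair haplotypes into diploid samples")
  n_ind <- hap$n_hap / 2
  samples <- sprintf("ind%02d", seq_len(n_ind))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", hap$chrom,
                       as.integer(hap$L)),
               "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  if (length(hap$positions)) {
    gt <- matrix(paste(hap$mat[seq(1, hap$n_hap, 2), , drop = FALSE],
                       hap$mat[seq(2, hap$n_hap, 2), , drop = FALSE],
                       sep = "|"),
                 nrow = n_ind)
    lines <- vapply(seq_along(hap$positions), function(j) {
      paste(c(hap$chrom, format(hap$positions[j], scientific = FALSE), ".",
              ref, alt, ".", "PASS", paste0("AA=", ref), "GT", gt[, j]),
            collapse = "\t")
    }, "")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a population VCF into a haplotype matrix
#'
#' Parses the restricted dialect written by [write_population_vcf()]:
#' biallelic SNPs with phased GT on one chromosome; the allele equal to the
#' `AA` tag (or REF when `AA` is absent) is coded ancestral (0).
#'
#' @param path VCF path.
#' @param L chromosome length; `NULL` reads it from the contig header.
#' @return a [hap_matrix()].
#' @export
read_population_vcf <- function(path, L = NULL) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  if (is.null(L)) {
    contig <- grep("^##contig=", hdr, value = TRUE)[1]
    L <- as.numeric(sub(".*length=([0-9]+).*", "\\1", contig))
  }
  if (length(body) == 0)
    return(hap_matrix("chr1", L, numeric(0), matrix(0L, 2, 0)))
  fields <- strsplit(body, "\t", fixed = TRUE)
  chrom <- fields[[1]][1]
  pos <- vapply(fields, function(f) as.numeric(f[2]), 0)
  ref <- vapply(fields, function(f) f[4], "")
  info <- vapply(fields, function(f) f[8], "")
  aa <- ifelse(grepl("AA=", info), sub(".*AA=([^;]+).*", "\\1", info), ref)
  gt <- lapply(fields, function(f) {
    g <- sub(":.*", "", f[-(1:9)])
    as.integer(unlist(strsplit(g, "[|/]")))
  })
  mat <- do.call(cbind, gt)
  # if AA equals ALT, flip coding so 1 = derived
  flip <- aa != ref
  mat[, flip] <- 1L - mat[, flip]
  hap_matrix(chrom, L, pos, mat)
}

# Site-level VCF read for MK inputs: unlike read_population_vcf this keeps
# fixed derived sites (derived count = n_hap), which carry the divergence
# signal. Returns chrom, pos, ref, alt, aa, derived_count, n_hap.
.read_vcf_counts <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0)
    return(data.frame(chrom = character(0), pos = numeric(0),
                      ref = character(0), alt = character(0),
                      aa = character(0), derived_count = integer(0),
                      n_hap = integer(0)))
  fields <- strsplit(body, "\t", fixed = TRUE)
  ref <- vapply(fields, function(f) f[4], "")
  alt <- vapply(fields, function(f) f[5], "")
  info <- vapply(fields, function(f) f[8], "")
  aa <- ifelse(grepl("AA=", info), sub(".*AA=([^;]+).*", "\\1", info), ref)
  gt <- lapply(fields, function(f) {
    g <- sub(":.*", "", f[-(1:9)])
    as.integer(unlist(strsplit(g, "[|/]")))
  })
  n_hap <- length(gt[[1]])
  alt_count <- vapply(gt, sum, 0L)
  derived <- ifelse(aa == ref, alt_count, n_hap - alt_count)
  data.frame(chrom = vapply(fields, function(f) f[1], ""),
             pos = vapply(fields, function(f) as.numeric(f[2]), 0),
             ref = ref, alt = alt, aa = aa,
             derived_count = as.integer(derived), n_hap = n_hap)
}

#' Write sweep regions as BED6
#'
#' Scores are the peak fitted values rescaled to `[0, 1000]` across the set.
#'
#' @param regions a `sweep_regions`.
#' @param path output path.
#' @param name_prefix region-id prefix.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path, name_prefix = "region") {
  if (nrow(regions) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  v <- regions$peak_value
  score <- if (diff(range(v)) > 0)
    round(1000 * (v - min(v)) / diff(range(v))) else rep(1000L, length(v))
  df <- data.frame(regions$chrom,
                   trimws(format(regions$start, scientific = FALSE)),
                   trimws(format(regions$end, scientific = FALSE)),
                   paste0(name_prefix, seq_len(nrow(regions))), score, ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of regions
#'
#' @param path BED path (3+ columns, 0-based half-open).
#' @param population,subspecies labels attached to the returned set.
#' @return a `sweep_regions` (peak fields `NA` unless a score column holds
#'   them).
#' @export
read_regions_bed <- function(path, population = NA_character_,
                             subspecies = NA_character_) {
  if (file.size(path) == 0)
    return(sweep_regions(data.frame(chrom = character(0), start = numeric(0),
                                    end = numeric(0), peak_bp = numeric(0),
                                    peak_value = numeric(0)),
                         population, subspecies))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  out <- data.frame(chrom = as.character(df[[1]]), start = df[[2]],
                    end = df[[3]],
                    peak_bp = (df[[2]] + df[[3]]) / 2,
                    peak_value = if (ncol(df) >= 5) df[[5]] else NA_real_)
  sweep_regions(out, population, subspecies)
}

#' Read a BED mask of callable intervals
#'
#' @param path BED path (0-based half-open); intervals are sorted and merged.
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
read_mask_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    df[[1]], IRanges::IRanges(df[[2]] + 1, df[[3]])))
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1,
             end = BiocGenerics::end(gr))
}

#' Write a mu track as TSV
#'
#' @param track a `mu_track`.
#' @param path output path.
#' @param seed,config_hash provenance recorded in the header.
#' @return `path`, invisibly.
#' @export
write_mu_track <- function(track, path, seed = NA, config_hash = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_header(seed, config_hash), con)
  utils::write.table(as.data.frame(track), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a mu track TSV written by [write_mu_track()]
#' @param path TSV path.
#' @return a `mu_track` data.frame (attributes limited to what the file
#'   carries).
#' @export
read_mu_track <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  structure(df, class = c("mu_track", "data.frame"),
            S_chrom = NA_integer_)
}

#' Write a generic results table as TSV with a provenance header
#' @param df data.frame.
#' @param path output path.
#' @param seed,config_hash provenance.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(df, path, seed = NA, config_hash = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_header(seed, config_hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a results TSV written by [write_results_tsv()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_results_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}
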