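# Fixture builders shared across test files. Everything is generated in code;
# nothing is read from disk except files these helpers write to tempdir().

default_demog <- function() demography()

# deterministic toy haplotype matrix: n_hap x S with given derived counts,
# carriers rotated so columns differ
toy_hap <- function(n_hap = 10, counts = c(1, 2, 5, 8, 9),
                    positions = seq(100, by = 1000,
                                    length.out = length(counts)),
                    L = 1e6, chrom = "chr1") {
  mat <- sapply(seq_along(counts), function(j) {
    col <- integer(n_hap)
    idx <- ((j - 1 + seq_len(counts[j]) - 1) %% n_hap) + 1
    col[idx] <- 1L
    col
  })
  hap_matrix(chrom, L, positions, mat)
}

# regions helper: build a sweep_regions from a start/end matrix
make_regions <- function(se, chrom = "chr1", population = NA_character_,
                         subspecies = NA_character_) {
  if (nrow(se) == 0) {
    df <- data.frame(chrom = character(0), start = numeric(0),
                     end = numeric(0), peak_bp = numeric(0),
                     peak_value = numeric(0))
  } else {
    df <- data.frame(chrom = chrom, start = se[, 1], end = se[, 2],
                     peak_bp = (se[, 1] + se[, 2]) / 2, peak_value = 1)
  }
  sweep_regions(df, population, subspecies)
}

# brute-force union-find clustering oracle over interval rows
# (population, region, chrom, start, end); returns component id per row
oracle_union_find <- function(df) {
  n <- nrow(df)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (df$chrom[i] == df$chrom[j] &&
        df$start[i] < df$end[j] && df$start[j] < df$end[i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, 0L)
}

# tiny FASTA + GFF3 pair written to tempdir; returns paths and the genome
# string. CDS entries: list of list(start, end, strand, phase, id)
write_toy_annotation <- function(seq, cds, chrom = "chr1") {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(paste0(">", chrom), seq), fa)
  gff <- tempfile(fileext = ".gff3")
  lines <- c("##gff-version 3")
  for (x in cds) {
    lines <- c(lines, paste(chrom, "test", "CDS", x$start, x$end, ".",
                            x$strand, x$phase %||% 0,
                            paste0("ID=cds_", x$id, ";Parent=", x$id),
                            sep = "\t"))
  }
  writeLines(lines, gff)
  list(fasta = fa, gff = gff)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
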