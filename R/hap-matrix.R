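#' Haplotype matrix of biallelic ancestral/derived states
#'
#' The unit of scan input: phased haplotypes at polymorphic biallelic sites on
#' one chromosome, with derived state coded 1 and ancestral 0.
#'
#' @param chrom chromosome identifier.
#' @param L chromosome length in bp.
#' @param positions strictly increasing 1-based bp positions, length S.
#' @param mat n_hap x S binary matrix (rows = haplotypes, columns = sites).
#' @return object of class `hap_matrix` with fields `chrom`, `L`, `positions`,
#'   `mat`, `n_hap`.
#' @export
hap_matrix <- function(chrom, L, positions, mat) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  positions <- as.numeric(positions)
  if (length(positions) != ncol(mat))
    stop("positions length must equal number of matrix columns")
  if (length(positions) > 0) {
    if (any(diff(positions) <= 0))
      stop("positions must be strictly increasing")
    if (positions[1] < 1 || positions[length(positions)] > L)
      stop("positions must lie in [1, L]")
  }
  if (!all(mat %in% c(0L, 1L)))
    stop("haplotype states must be 0/1")
  dc <- colSums(mat)
  if (length(dc) && any(dc == 0 | dc == nrow(mat)))
    stop("every site must be polymorphic in the sample")
  structure(list(chrom = as.character(chrom), L = as.numeric(L),
                 positions = positions, mat = mat, n_hap = nrow(mat)),
            class = "hap_matrix")
}

#' @export
print.hap_matrix <- function(x, ...) {
  cat(sprintf("hap_matrix: %d haplotypes, %d sites, chrom %s (L = %g bp)\n",
              x$n_hap, length(x$positions), x$chrom, x$L))
  invisible(x)
}

#' Derived allele counts per site
#' @param hap a `hap_matrix`.
#' @return integer vector of derived counts, one per site.
#' @export
derived_counts <- function(hap) colSums(hap$mat)

#' Minor allele frequency filter
#'
#' Removes sites whose minor allele frequency is below `maf_min`; sites at
#' exactly the threshold are kept (>= convention).
#'
#' @param hap a `hap_matrix`.
#' @param maf_min minimum minor allele frequency in `[0, 0.5)`.
#' @return filtered `hap_matrix`.
#' @export
maf_filter <- function(hap, maf_min) {
  stopifnot(inherits(hap, "hap_matrix"), maf_min >= 0, maf_min < 0.5)
  if (maf_min == 0) return(hap)
  dc <- derived_counts(hap)
  maf <- pmin(dc, hap$n_hap - dc) / hap$n_hap
  keep <- maf >= maf_min
  hap_matrix(hap$chrom, hap$L, hap$positions[keep],
             hap$mat[, keep, drop = FALSE])
}

#' Linkage disequilibrium r-squared between two sites
#'
#' r^2 = (p_AB - p_A p_B)^2 / (p_A (1 - p_A) p_B (1 - p_B)), computed from
#' phased haplotype columns.
#'
#' @param a,b binary haplotype vectors of equal length, both polymorphic.
#' @return value in `[0, 1]`.
#' @export
r2 <- function(a, b) {
  n <- length(a)
  if (length(b) != n) stop("columns must have equal haplotype count")
  pa <- mean(a); pb <- mean(b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1))
    stop("r2 undefined for monomorphic input")
  pab <- mean(a * b)
  (pab - pa * pb)^2 / (pa * (1 - pa) * pb * (1 - pb))
}

#' Nucleotide diversity per bp in non-overlapping windows
#'
#' Mean pairwise differences per bp: per site 2 i (n - i) / (n (n - 1)) with i
#' the derived count, summed within each window and divided by window width.
#'
#' @param hap a `hap_matrix`.
#' @param window_bp window width in bp (default 1e5). Windows tile `[1, L]`.
#' @return data.frame with `start`, `end` (0-based half-open), `S`, `pi`.
#'   Windows without segregating sites get `pi = 0` only if covered; windows
#'   with no sites report `S = 0` and `pi = 0`.
#' @export
diversity_pi <- function(hap, window_bp = 1e5) {
  stopifnot(inherits(hap, "hap_matrix"))
  n <- hap$n_hap
  dc <- derived_counts(hap)
  per_site <- 2 * dc * (n - dc) / (n * (n - 1))
  breaks <- seq(0, ceiling(hap$L / window_bp) * window_bp, by = window_bp)
  idx <- findInterval(hap$positions - 1, breaks, rightmost.closed = FALSE)
  nw <- length(breaks) - 1
  s <- tabulate(idx, nbins = nw)
  pisum <- vapply(seq_len(nw), function(w) sum(per_site[idx == w]), 0)
  width <- pmin(breaks[-1], hap$L) - breaks[-length(breaks)]
  data.frame(start = breaks[-length(breaks)], end = pmin(breaks[-1], hap$L),
             S = s, pi = pisum / width)
}

#' Tajima's D in non-overlapping windows
#'
#' D = (pi - theta_W) / sd using Tajima's variance constants; windows with
#' fewer than 3 segregating sites are reported as `NA` and flagged.
#'
#' @inheritParams diversity_pi
#' @return data.frame with `start`, `end`, `S`, `D`.
#' @export
tajimas_d <- function(hap, window_bp = 1e5) {
  stopifnot(inherits(hap, "hap_matrix"))
  n <- hap$n_hap
  dc <- derived_counts(hap)
  per_site <- 2 * dc * (n - dc) / (n * (n - 1))
  breaks <- seq(0, ceiling(hap$L / window_bp) * window_bp, by = window_bp)
  idx <- findInterval(hap$positions - 1, breaks, rightmost.closed = FALSE)
  nw <- length(breaks) - 1
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- rep(NA_real_, nw)
  s <- tabulate(idx, nbins = nw)
  for (w in seq_len(nw)) {
    S <- s[w]
    if (S < 3) next
    pi_sum <- sum(per_site[idx == w])
    thw <- S / a1
    D[w] <- (pi_sum - thw) / sqrt(e1 * S + e2 * S * (S - 1))
  }
  data.frame(start = breaks[-length(breaks)], end = pmin(breaks[-1], hap$L),
             S = s, D = D)
}
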