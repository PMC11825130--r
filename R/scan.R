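#' @useDynLib sweepshare, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Diversity-deficit sub-statistic for one SNP window
#'
#' The span a fixed number of SNPs occupies, relative to the chromosome-wide
#' SNP density, optionally rescaled by the proportion of callable bases in the
#' window: `mu_var = span * q_w * S_chrom / (L * W)`. Under neutrality the
#' expectation is near 1; a sweep's diversity deficit stretches the span and
#' inflates the statistic.
#'
#' @param first_bp,last_bp window bounds (bp of first and last SNP).
#' @param W SNPs per window (>= 2).
#' @param L chromosome length in bp.
#' @param S_chrom chromosome-wide (post-filter) SNP count.
#' @param q_w proportion of callable bases in the window span, in `(0, 1]`.
#' @return non-negative value; `q_w = 0` is rejected (window unusable).
#' @export
mu_var <- function(first_bp, last_bp, W, L, S_chrom, q_w = 1) {
  stopifnot(W >= 2, q_w > 0, q_w <= 1)
  (last_bp - first_bp) * q_w * S_chrom / (L * W)
}

#' Extreme-frequency sub-statistic for one SNP window
#'
#' The window's proportion of extreme-frequency SNPs (derived count 1 or
#' n_hap - 1), self-normalized by the chromosome-wide proportion of such SNPs.
#'
#' @param n_extreme count of extreme-frequency SNPs in the window.
#' @param W SNPs per window.
#' @param chrom_extreme_proportion chromosome-wide fraction of extreme SNPs
#'   (> 0; a chromosome with none yields mu_sfs = 1 everywhere upstream).
#' @return non-negative value.
#' @export
mu_sfs <- function(n_extreme, W, chrom_extreme_proportion) {
  stopifnot(chrom_extreme_proportion > 0)
  (n_extreme / W) / chrom_extreme_proportion
}

#' Flanking-LD contrast sub-statistic for one SNP window
#'
#' The window is split at the middle SNP; the statistic contrasts linkage
#' within each half against linkage between halves:
#' `(mean r2 left + mean r2 right) / (2 * mean r2 between + eps)`, capped.
#'
#' @param mat n_hap x W binary matrix of the window's sites.
#' @param eps regularizer in the denominator (default 1e-6).
#' @param cap upper cap avoiding eps-driven blowups (default 100).
#' @return non-negative value, or `NA` if a half has < 2 usable sites.
#' @export
mu_ld <- function(mat, eps = 1e-6, cap = 100) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  W <- ncol(mat)
  if (W < 4) stop("mu_ld needs a window of at least 4 SNPs")
  .mu_ld_windows_cpp(mat, W, eps, cap)[1]
}

#' Quality mask: proportion of callable bases over an interval
#'
#' @param mask data.frame with 0-based half-open `start`, `end` columns of
#'   callable intervals (non-overlapping, sorted), or `NULL` for fully
#'   callable.
#' @param first_bp,last_bp 1-based window bounds (inclusive).
#' @return proportion in `[0, 1]`.
#' @keywords internal
mask_proportion <- function(mask, first_bp, last_bp) {
  if (is.null(mask)) return(1)
  span0 <- first_bp - 1  # 0-based start
  span1 <- last_bp       # 0-based end (half-open)
  ov <- pmin(mask$end, span1) - pmax(mask$start, span0)
  sum(pmax(ov, 0)) / (span1 - span0)
}

#' Composite sweep-scan statistic along a chromosome
#'
#' Slides windows of `W` consecutive SNPs (step 1 SNP) over the MAF-filtered
#' haplotype matrix and computes the three sub-statistics and their product
#' mu = mu_var * mu_sfs * mu_ld per window.
#'
#' @param hap a [hap_matrix()].
#' @param W SNPs per window (default 24).
#' @param maf_min minor-allele-frequency threshold (default 0.05).
#' @param mask optional callable-interval data.frame (0-based half-open
#'   `start`, `end`); absent means fully callable.
#' @param eps,cap LD sub-statistic regularizer and cap, see [mu_ld()].
#' @return a `mu_track` data.frame with columns `chrom`, `first_bp`,
#'   `last_bp`, `center_bp`, `W`, `mu_var`, `mu_sfs`, `mu_ld`, `mu`; windows
#'   whose LD statistic is undefined or whose mask proportion is 0 are
#'   dropped (counted in `attr(, "n_skipped")`). Too few SNPs yields an empty
#'   track with a warning.
#' @export
mu_scan <- function(hap, W = 24, maf_min = 0.05, mask = NULL,
                    eps = 1e-6, cap = 100) {
  stopifnot(inherits(hap, "hap_matrix"), W >= 4)
  hap <- maf_filter(hap, maf_min)
  S <- length(hap$positions)
  empty <- data.frame(chrom = character(0), first_bp = numeric(0),
                      last_bp = numeric(0), center_bp = numeric(0),
                      W = integer(0), mu_var = numeric(0),
                      mu_sfs = numeric(0), mu_ld = numeric(0),
                      mu = numeric(0))
  if (S < W) {
    warning("fewer than W SNPs after filtering; empty track")
    return(structure(empty, class = c("mu_track", "data.frame"),
                     n_hap = hap$n_hap, L = hap$L, S_chrom = S, n_skipped = 0L))
  }
  dc <- derived_counts(hap)
  extreme <- dc == 1L | dc == hap$n_hap - 1L
  prop_extreme <- mean(extreme)
  nwin <- S - W + 1
  first_bp <- hap$positions[seq_len(nwin)]
  last_bp <- hap$positions[seq_len(nwin) + W - 1]
  n_ext <- as.numeric(stats::filter(as.numeric(extreme), rep(1, W),
                                    sides = 1))[W:S]
  ld <- .mu_ld_windows_cpp(hap$mat, as.integer(W), eps, cap)
  qw <- if (is.null(mask)) rep(1, nwin) else
    vapply(seq_len(nwin), function(i)
      mask_proportion(mask, first_bp[i], last_bp[i]), 0)
  usable <- !is.na(ld) & qw > 0
  if (prop_extreme > 0) {
    msfs <- (n_ext / W) / prop_extreme
  } else {
    message("no extreme-frequency SNPs on chromosome; mu_sfs set to 1")
    msfs <- rep(1, nwin)
  }
  mvar <- (last_bp - first_bp) * qw * S / (hap$L * W)
  out <- data.frame(chrom = hap$chrom,
                    first_bp = first_bp[usable], last_bp = last_bp[usable],
                    center_bp = (first_bp[usable] + last_bp[usable]) / 2,
                    W = W,
                    mu_var = mvar[usable], mu_sfs = msfs[usable],
                    mu_ld = ld[usable])
  out$mu <- out$mu_var * out$mu_sfs * out$mu_ld
  structure(out, class = c("mu_track", "data.frame"),
            n_hap = hap$n_hap, L = hap$L, S_chrom = S,
            n_skipped = sum(!usable))
}

#' @export
print.mu_track <- function(x, ...) {
  cat(sprintf("mu_track: %d windows (W = %s), S_chrom = %s\n",
              nrow(x), if (nrow(x)) x$W[1] else "?", attr(x, "S_chrom")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}
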