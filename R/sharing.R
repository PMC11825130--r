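#' Cluster sweep regions across populations by overlap
#'
#' Connected components of the >= 1 bp overlap graph across all populations'
#' regions (single linkage). For genomic intervals, components coincide with
#' the merged runs of the pooled intervals, which is how they are computed
#' (via [IRanges::reduce()]); the test suite checks this against a
#' brute-force union-find oracle.
#'
#' @param sets named list of `sweep_regions` (names are population labels;
#'   a `population` attribute on a set takes precedence).
#' @param subspecies named character vector mapping population label to
#'   subspecies (e.g. "maize"/"teosinte"); optional.
#' @return data.frame of clusters: `cluster`, `chrom`, `start`, `end`
#'   (merged span), `members` (comma-separated population:region ids),
#'   `populations` (comma-separated distinct labels), `n_populations`, and
#'   when subspecies are supplied `n_maize`-style per-subspecies counts
#'   (columns `n_<subspecies>`).
#' @export
cluster_regions <- function(sets, subspecies = NULL) {
  pops <- names(sets)
  if (is.null(pops)) pops <- paste0("pop", seq_along(sets))
  all_df <- do.call(rbind, lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (nrow(s) == 0) return(NULL)
    lab <- attr(s, "population")
    if (is.null(lab) || is.na(lab)) lab <- pops[i]
    data.frame(population = lab, region = seq_len(nrow(s)),
               chrom = s$chrom, start = s$start, end = s$end)
  }))
  if (is.null(all_df) || nrow(all_df) == 0)
    return(data.frame(cluster = integer(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      members = character(0), populations = character(0),
                      n_populations = integer(0)))
  # 0-based half-open -> 1-based closed IRanges; touching intervals stay apart
  gr <- GenomicRanges::GRanges(all_df$chrom,
                               IRanges::IRanges(all_df$start + 1, all_df$end))
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  hit <- GenomicRanges::findOverlaps(gr, red)
  cl <- integer(nrow(all_df))
  cl[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)
  out <- do.call(rbind, lapply(sort(unique(cl)), function(k) {
    m <- all_df[cl == k, , drop = FALSE]
    row <- data.frame(
      cluster = k, chrom = m$chrom[1],
      start = min(m$start), end = max(m$end),
      members = paste(paste0(m$population, ":", m$region), collapse = ","),
      populations = paste(sort(unique(m$population)), collapse = ","),
      n_populations = length(unique(m$population)))
    row
  }))
  rownames(out) <- NULL
  if (!is.null(subspecies)) {
    for (ssp in sort(unique(subspecies))) {
      pops_in <- names(subspecies)[subspecies == ssp]
      out[[paste0("n_", ssp)]] <- vapply(out$populations, function(p) {
        length(intersect(strsplit(p, ",")[[1]], pops_in))
      }, 0L, USE.NAMES = FALSE)
    }
  }
  out
}

#' Summarize sweep sharing across populations
#'
#' @param clusters data.frame from [cluster_regions()] (with subspecies
#'   columns when a two-subspecies contingency is wanted).
#' @param subspecies named character vector mapping population to subspecies
#'   (needed for the contingency table).
#' @return list with `contingency` (cluster counts over per-subspecies
#'   population counts, when available) and `private` (per population:
#'   clusters private to it / clusters containing it).
#' @export
sharing_summary <- function(clusters, subspecies = NULL) {
  pops <- sort(unique(unlist(strsplit(clusters$populations, ","))))
  private <- vapply(pops, function(p) {
    members <- strsplit(clusters$populations, ",")
    has <- vapply(members, function(m) p %in% m, TRUE)
    if (!any(has)) return(NA_real_)
    sum(has & clusters$n_populations == 1) / sum(has)
  }, 0)
  contingency <- NULL
  ssp_cols <- grep("^n_", names(clusters), value = TRUE)
  ssp_cols <- setdiff(ssp_cols, "n_populations")
  if (length(ssp_cols) == 2) {
    contingency <- as.data.frame(table(clusters[[ssp_cols[1]]],
                                       clusters[[ssp_cols[2]]]))
    names(contingency) <- c(ssp_cols, "n_clusters")
  }
  list(contingency = contingency,
       private = data.frame(population = pops, private_proportion = private,
                            row.names = NULL))
}

#' Sweep-calling accuracy from replicate samples
#'
#' One minus the average replicate-sharing proportion between two
#' non-overlapping samples of the same population:
#' `P = 1 - (nS/nP1 + nS/nP2) / 2`. P estimates the fraction of called
#' regions that are not reproducible (false positives); it later scales the
#' counts entering the sharing test.
#'
#' @param nS number of sweeps shared between the replicates
#'   (`nS <= min(nP1, nP2)`).
#' @param nP1,nP2 number of sweeps called in each replicate (> 0).
#' @param group optional label (e.g. subspecies).
#' @return object of class `accuracy_estimate`: list with `nS`, `nP1`, `nP2`,
#'   `P`, `group`.
#' @examples
#' accuracy_P(67, 100, 100)$P  # 0.33
#' @export
accuracy_P <- function(nS, nP1, nP2, group = NA_character_) {
  if (nP1 <= 0 || nP2 <= 0) stop("replicate sweep counts must be positive")
  if (nS > min(nP1, nP2)) stop("nS cannot exceed min(nP1, nP2)")
  if (nS < 0) stop("nS must be non-negative")
  structure(list(nS = nS, nP1 = nP1, nP2 = nP2,
                 P = 1 - (nS / nP1 + nS / nP2) / 2, group = group),
            class = "accuracy_estimate")
}

#' @export
print.accuracy_estimate <- function(x, ...) {
  cat(sprintf("accuracy estimate: nS = %g, nP1 = %g, nP2 = %g -> P = %.4f\n",
              x$nS, x$nP1, x$nP2, x$P))
  invisible(x)
}

# Exact upper-tail hypergeometric probability Pr(X >= x) by log-choose
# summation: N total, n1 successes, n2 draws.
.hyper_tail <- function(N, n1, n2, x) {
  lo <- max(0, n1 + n2 - N)
  hi <- min(n1, n2)
  if (x <= lo) return(1)
  if (x > hi) return(0)
  k <- x:hi
  sum(exp(lchoose(n1, k) + lchoose(N - n1, n2 - k) - lchoose(N, n2)))
}

# round half away from zero (base round() rounds half to even)
.round_half_up <- function(x) floor(x + 0.5)

#' Accuracy-adjusted hypergeometric test of sweep sharing
#'
#' Tests whether two populations share more sweep regions than expected by
#' chance: with `N` total testable loci, `n1`, `n2` outliers in the two
#' populations (the larger count is designated first) and `x` shared, the
#' p-value is the exact hypergeometric upper tail `Pr(X >= x)`. Calling
#' accuracy is incorporated by multiplying `N`, `n1`, `n2`, `x` by `P`
#' before the test; adjusted counts are rounded half-up and clamped so that
#' `x' <= n2' <= n1' <= N'`.
#'
#' @param N total number of loci tested (see [estimate_n_slots()]).
#' @param n1,n2 outlier counts in the two populations.
#' @param x shared-outlier count (`x <= min(n1, n2)`).
#' @param P accuracy adjustment in `(0, 1]`; `P = 1` reproduces the
#'   unadjusted test.
#' @param pair optional pair labels (length 2).
#' @return object of class `sharing_test`: list with the raw counts (ordered
#'   so `n1 >= n2`), `adjusted` counts, and `p` (raw p-value).
#' @export
shared_sweep_test <- function(N, n1, n2, x, P = 1, pair = c(NA, NA)) {
  if (P <= 0 || P > 1) stop("P must be in (0, 1]")
  if (n1 < n2) {
    tmp <- n1; n1 <- n2; n2 <- tmp
    pair <- rev(pair)
  }
  if (!(x <= n2 && n2 <= n1 && n1 <= N) || x < 0)
    stop("counts must satisfy 0 <= x <= n2 <= n1 <= N")
  Na <- .round_half_up(P * N)
  n1a <- .round_half_up(P * n1)
  n2a <- .round_half_up(P * n2)
  xa <- .round_half_up(P * x)
  # consistency clamps: x' <= n2' <= n1' <= N'
  n1a <- min(n1a, Na)
  n2a <- min(n2a, n1a)
  xa <- min(xa, n2a)
  p <- .hyper_tail(Na, n1a, n2a, xa)
  structure(list(pair = pair, N = N, n1 = n1, n2 = n2, x = x, P = P,
                 adjusted = c(N = Na, n1 = n1a, n2 = n2a, x = xa), p = p),
            class = "sharing_test")
}

#' @export
print.sharing_test <- function(x, ...) {
  cat(sprintf(
    "sharing test: N=%g n1=%g n2=%g x=%g (P=%.3g -> N'=%g n1'=%g n2'=%g x'=%g), p = %.4g\n",
    x$N, x$n1, x$n2, x$x, x$P, x$adjusted["N"], x$adjusted["n1"],
    x$adjusted["n2"], x$adjusted["x"], x$p))
  invisible(x)
}

#' Number of testable locus slots for the sharing test
#'
#' The total-locus count N is taken as the number of non-overlapping slots a
#' called region could occupy:
#' `N = floor(genome_length / (mean region length + merge_dist))`.
#'
#' @param genome_length total scanned genome length in bp.
#' @param region_lengths lengths of the called regions entering the pair's
#'   test (both populations pooled).
#' @param merge_dist merge distance used when calling regions.
#' @return integer slot count (>= 1).
#' @export
estimate_n_slots <- function(genome_length, region_lengths, merge_dist) {
  stopifnot(genome_length > 0, length(region_lengths) >= 1)
  max(1L, as.integer(genome_length %/% (mean(region_lengths) + merge_dist)))
}

#' Benjamini-Yekutieli adjustment for multiple testing
#'
#' Step-up adjustment valid under arbitrary dependence: with m p-values
#' sorted ascending, `adj_(i) = min(1, cummin from the largest of
#' p_(i) * m * c(m) / i)` where `c(m) = sum_{k=1}^m 1/k`; the original order
#' is restored.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the original order.
#' @export
adjust_pvalues_by <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  m <- length(pvals)
  if (m == 0) return(numeric(0))
  cm <- sum(1 / seq_len(m))
  ord <- order(pvals)
  ranked <- pvals[ord] * m * cm / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Pairwise sharing tests over a set of populations
#'
#' Builds the shared-outlier count for every population pair from the
#' overlap clustering, runs the accuracy-adjusted hypergeometric test, and
#' applies the Benjamini-Yekutieli correction across pairs.
#'
#' @param sets named list of `sweep_regions`.
#' @param genome_length scanned genome length in bp.
#' @param merge_dist merge distance used for region calling.
#' @param P accuracy adjustment applied to every pair (the pooled
#'   two-subspecies average by default of the workflow).
#' @param N_override optional fixed N replacing [estimate_n_slots()].
#' @return data.frame: `pop1`, `pop2`, `N`, `n1`, `n2`, `x`, adjusted
#'   counts, `p_raw`, `p_adj`.
#' @export
pairwise_sharing_tests <- function(sets, genome_length, merge_dist,
                                   P = 1, N_override = NULL) {
  pops <- names(sets)
  stopifnot(length(pops) >= 2)
  combs <- utils::combn(pops, 2)
  rows <- vector("list", ncol(combs))
  for (k in seq_len(ncol(combs))) {
    p1 <- combs[1, k]; p2 <- combs[2, k]
    a <- sets[[p1]]; b <- sets[[p2]]
    if (nrow(a) == 0 || nrow(b) == 0) next
    cl <- cluster_regions(stats::setNames(list(a, b), c(p1, p2)))
    x <- sum(cl$n_populations == 2)
    n1 <- nrow(a); n2 <- nrow(b)
    N <- if (is.null(N_override))
      estimate_n_slots(genome_length, c(a$end - a$start, b$end - b$start),
                       merge_dist) else N_override
    N <- max(N, n1, n2)
    tst <- shared_sweep_test(N, n1, n2, x, P, pair = c(p1, p2))
    rows[[k]] <- data.frame(pop1 = tst$pair[1], pop2 = tst$pair[2],
                            N = tst$N, n1 = tst$n1, n2 = tst$n2, x = tst$x,
                            N_adj = tst$adjusted["N"],
                            n1_adj = tst$adjusted["n1"],
                            n2_adj = tst$adjusted["n2"],
                            x_adj = tst$adjusted["x"],
                            p_raw = tst$p)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  rownames(out) <- NULL
  out$p_adj <- adjust_pvalues_by(out$p_raw)
  out
}
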