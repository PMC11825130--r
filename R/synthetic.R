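#' Simulate neutral haplotypes under a piecewise-constant demography
#'
#' Genealogies are generated with the sequentially Markov coalescent (SMC):
#' an exact coalescent tree is drawn at the left chromosome end and evolves
#' along the sequence by prune-regraft moves at recombination breakpoints,
#' with mutations placed as a Poisson process on the branches of each
#' marginal tree. The marginal genealogy at every position follows the
#' standard (piecewise-constant-Ne) coalescent, so per-site expectations
#' (pi = 4 Ne mu under a constant size, the 1/i neutral SFS, Tajima's D
#' centred on 0) hold, and linkage decays smoothly with distance.
#'
#' @param demog a [demography()].
#' @param n_hap haploid sample size (>= 2).
#' @param L chromosome length in bp (>= 1e5).
#' @param seed integer seed; the generator is a pure function of
#'   (arguments, seed).
#' @param chrom chromosome label.
#' @return a [hap_matrix()].
#' @examples
#' hap <- simulate_neutral_haplotypes(demography(), n_hap = 10, L = 2e5, seed = 1)
#' mean(diversity_pi(hap, 2e5)$pi)  # near 4 * 1e4 * 3e-8 = 1.2e-3
#' @export
simulate_neutral_haplotypes <- function(demog, n_hap, L, seed,
                                        chrom = "chr1") {
  stopifnot(inherits(demog, "demography"))
  if (n_hap < 2) stop("n_hap must be at least 2")
  if (L < 1e5) stop("L must be at least 1e5 bp")
  set.seed(seed)
  sim <- .smc_simulate_cpp(n_hap, L, demog$mu, demog$r,
                           demog$epochs$start, demog$epochs$Ne)
  if (length(sim$pos) == 0)
    return(hap_matrix(chrom, L, numeric(0), matrix(0L, n_hap, 0)))
  pos <- round(sim$pos)
  pos[pos < 1] <- 1
  pos[pos > L] <- L
  ord <- order(pos)
  pos <- pos[ord]
  carriers <- sim$carriers[ord]
  dup <- duplicated(pos)
  pos <- pos[!dup]
  carriers <- carriers[!dup]
  mat <- matrix(0L, n_hap, length(pos))
  for (j in seq_along(pos)) mat[carriers[[j]], j] <- 1L
  hap_matrix(chrom, L, pos, mat)
}

#' Parametric hard-sweep scenario
#'
#' A stand-in for the footprint of a completed hard sweep: within a triangular
#' footprint of halfwidth `footprint_halfwidth_bp` around `center_bp`, SNPs are
#' thinned (diversity deficit) and surviving SNPs are pushed to extreme derived
#' frequencies (SFS distortion), with both effects decaying linearly to zero at
#' the footprint edge.
#'
#' @param center_bp sweep center position.
#' @param footprint_halfwidth_bp footprint halfwidth L_s in bp (>= 0).
#' @param drop_max maximal SNP drop probability q0 at the center, in `[0, 1]`.
#' @param extreme_max maximal extremization probability h0 at the center,
#'   in `[0, 1]`.
#' @param carrier_populations character vector of population labels carrying
#'   the sweep (non-empty).
#' @return object of class `sweep_scenario`.
#' @export
sweep_scenario <- function(center_bp, footprint_halfwidth_bp,
                           drop_max = 0.9, extreme_max = 0.8,
                           carrier_populations = "pop1") {
  stopifnot(footprint_halfwidth_bp >= 0,
            drop_max >= 0, drop_max <= 1,
            extreme_max >= 0, extreme_max <= 1,
            length(carrier_populations) >= 1)
  structure(list(center_bp = center_bp,
                 footprint_halfwidth_bp = footprint_halfwidth_bp,
                 drop_max = drop_max, extreme_max = extreme_max,
                 carrier_populations = carrier_populations),
            class = "sweep_scenario")
}

#' Inject a parametric sweep footprint into a haplotype matrix
#'
#' For each SNP at distance d < L_s from the scenario center: the SNP is
#' dropped with probability `q0 * (1 - d / L_s)`; if retained, with
#' probability `h0 * (1 - d / L_s)` its derived count is resampled to 1 or
#' `n_hap - 1` (equal probability, carriers chosen uniformly). SNPs at
#' d >= L_s are untouched. Sites are never moved, so positions stay sorted
#' and the site count is non-increasing.
#'
#' @param hap a [hap_matrix()].
#' @param scenario a [sweep_scenario()]; its center must lie on the chromosome.
#' @param seed integer seed.
#' @return a [hap_matrix()].
#' @export
inject_sweep <- function(hap, scenario, seed) {
  stopifnot(inherits(hap, "hap_matrix"), inherits(scenario, "sweep_scenario"))
  if (scenario$center_bp < 1 || scenario$center_bp > hap$L)
    stop("scenario center must lie within the chromosome")
  Ls <- scenario$footprint_halfwidth_bp
  if (Ls == 0 || length(hap$positions) == 0) return(hap)
  set.seed(seed)
  d <- abs(hap$positions - scenario$center_bp)
  inside <- which(d < Ls)
  if (length(inside) == 0) return(hap)
  w <- 1 - d[inside] / Ls
  drop <- stats::runif(length(inside)) < scenario$drop_max * w
  keep_idx <- inside[!drop]
  w_keep <- w[!drop]
  mat <- hap$mat
  extremize <- stats::runif(length(keep_idx)) < scenario$extreme_max * w_keep
  for (j in which(extremize)) {
    col <- keep_idx[j]
    k <- if (stats::runif(1) < 0.5) 1L else hap$n_hap - 1L
    newcol <- integer(hap$n_hap)
    newcol[sample.int(hap$n_hap, k)] <- 1L
    mat[, col] <- newcol
  }
  keep <- sort(c(setdiff(seq_along(hap$positions), inside), keep_idx))
  hap_matrix(hap$chrom, hap$L, hap$positions[keep], mat[, keep, drop = FALSE])
}

#' Generate a multi-population dataset with a known sweep truth table
#'
#' Simulates one neutral haplotype matrix per population under its demography
#' and injects each sweep scenario into all of its carrier populations at the
#' same center. One population may be flagged for replicate sampling: it is
#' simulated at twice its haploid size and split into two disjoint halves
#' (suffixes `_rep1` / `_rep2`) that share the population's scenarios by
#' construction, emulating two non-overlapping samples of one population.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{populations}{named list; each entry a list with `demography`
#'       (a [demography()]), `n_hap`, optional `subspecies`, and optional
#'       `replicate = TRUE` to produce the split replicate pair.}
#'     \item{L}{chromosome length in bp.}
#'     \item{scenarios}{list of [sweep_scenario()]; carrier labels must name
#'       configured populations.}
#'     \item{chrom}{optional chromosome label (default "chr1").}
#'   }
#' @param seed integer seed.
#' @return list with `haplotypes` (named list of [hap_matrix()]) and
#'   `truth` (data.frame: scenario id, carrier populations, center_bp,
#'   footprint halfwidth).
#' @export
generate_multipop_dataset <- function(config, seed) {
  pops <- config$populations
  stopifnot(length(pops) >= 1, !is.null(config$L))
  scenarios <- config$scenarios %||% list()
  chrom <- config$chrom %||% "chr1"
  pop_names <- names(pops)
  for (sc in scenarios) {
    unknown <- setdiff(sc$carrier_populations, pop_names)
    if (length(unknown))
      stop("scenario references unknown population(s): ",
           paste(unknown, collapse = ", "))
  }
  set.seed(seed)
  pop_seeds <- sample.int(.Machine$integer.max, length(pops))
  scn_seeds <- matrix(sample.int(.Machine$integer.max,
                                 length(scenarios) * (length(pops) + 1)),
                      nrow = max(length(scenarios), 1))
  haps <- list()
  for (i in seq_along(pops)) {
    p <- pops[[i]]
    label <- pop_names[i]
    replicate <- isTRUE(p$replicate)
    n_sim <- if (replicate) 2L * p$n_hap else p$n_hap
    hap <- simulate_neutral_haplotypes(p$demography, n_sim, config$L,
                                       seed = pop_seeds[i], chrom = chrom)
    for (s in seq_along(scenarios)) {
      sc <- scenarios[[s]]
      if (label %in% sc$carrier_populations)
        hap <- inject_sweep(hap, sc, seed = scn_seeds[s, i])
    }
    if (replicate) {
      half <- seq_len(p$n_hap)
      split_half <- function(rows) {
        m <- hap$mat[rows, , drop = FALSE]
        dc <- colSums(m)
        poly <- dc > 0 & dc < length(rows)
        hap_matrix(chrom, config$L, hap$positions[poly],
                   m[, poly, drop = FALSE])
      }
      haps[[paste0(label, "_rep1")]] <- split_half(half)
      haps[[paste0(label, "_rep2")]] <- split_half(half + p$n_hap)
    } else {
      haps[[label]] <- hap
    }
  }
  truth <- data.frame(
    scenario = seq_along(scenarios),
    carriers = vapply(scenarios, function(sc)
      paste(sc$carrier_populations, collapse = ","), ""),
    center_bp = vapply(scenarios, function(sc) sc$center_bp, 0),
    footprint_halfwidth_bp = vapply(scenarios, function(sc)
      sc$footprint_halfwidth_bp, 0)
  )
  list(haplotypes = haps, truth = truth)
}

#' Generate unfolded-SFS count tables with a known true alpha curve
#'
#' Inverts the per-bin estimator alpha(x) = 1 - (d0/d) (p/p0): neutral
#' polymorphism counts follow the standard neutral spectrum
#' p0_i ~ Poisson(theta0 / i), and selected counts
#' p_i ~ Poisson((d / d0) (1 - alpha(x_i)) theta0 / i) with
#' alpha(x) = a + b exp(-c x), so plugging expected counts back into the
#' estimator recovers the curve exactly.
#'
#' @param a,b,c curve parameters of alpha(x) = a + b exp(-c x).
#' @param d0 neutral fixed-difference total (> 0).
#' @param d selected fixed-difference total (> 0).
#' @param theta0 neutral per-bin intensity scale (> 0).
#' @param n haploid sample size (>= 4); bins are x_i = i/n, i = 1..n-1.
#' @param seed integer seed.
#' @return a [usfs_counts()] whose `meta` records the generating parameters
#'   and the true asymptote `a + b * exp(-c)`.
#' @export
generate_usfs_counts <- function(a, b, c, d0, d, theta0, n, seed) {
  if (n < 4) stop("n must be at least 4")
  if (d0 <= 0 || d <= 0) stop("d0 and d must be positive")
  i <- seq_len(n - 1)
  x <- i / n
  alpha_x <- a + b * exp(-c * x)
  if (any(1 - alpha_x < 0))
    stop("parameters imply negative expected selected counts (alpha > 1)")
  set.seed(seed)
  p0 <- stats::rpois(n - 1, theta0 / i)
  p <- stats::rpois(n - 1, (d / d0) * (1 - alpha_x) * theta0 / i)
  usfs_counts(n = n, p = p, p0 = p0, d = d, d0 = d0,
              meta = list(a = a, b = b, c = c, theta0 = theta0,
                          true_alpha_inf = a + b * exp(-c)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
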