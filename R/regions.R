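#' Cubic smoothing spline over a mu track
#'
#' Smooths the composite statistic against window center position with
#' [stats::smooth.spline()], penalty chosen by generalized cross-validation,
#' and evaluates the fit back at every window center.
#'
#' @param track a `mu_track` from [mu_scan()] with >= 10 windows.
#' @return object of class `spline_fit`: list with `positions` (window
#'   centers, ascending), `fitted`, `spar` (chosen smoothing parameter),
#'   `chrom`.
#' @export
fit_spline <- function(track) {
  if (nrow(track) < 10) {
    warning("fewer than 10 windows; chromosome skipped")
    return(NULL)
  }
  fit <- stats::smooth.spline(track$center_bp, track$mu, cv = FALSE)
  fitted <- stats::predict(fit, x = track$center_bp)$y
  structure(list(positions = track$center_bp, fitted = fitted,
                 spar = fit$spar, chrom = track$chrom[1]),
            class = "spline_fit")
}

#' Outlier threshold from neutral coalescent simulations
#'
#' Simulates `reps` neutral chromosomes matched in sample size and length,
#' runs the full filter-scan-spline pipeline on each, pools all fitted
#' values, and returns the requested quantile. Failed replicates (too few
#' SNPs) are counted; more than 50% failures aborts.
#'
#' @param demog a [demography()].
#' @param scan_params list with `n_hap`, `L`, and optionally `W`, `maf_min`
#'   (passed through to the simulator and scanner).
#' @param reps number of neutral replicates (>= 20).
#' @param quantile outlier quantile in (0, 1); the workflow default is 0.999.
#' @param seed integer seed.
#' @return the threshold (numeric scalar) with attributes `n_failed` and,
#'   when `keep_pool = TRUE`, `pool` (all pooled fitted values) and `fits`
#'   (the per-replicate spline fits) for reuse.
#' @param keep_pool keep the pooled fitted values and per-replicate fits as
#'   attributes (used by the grid search and false-positive checks).
#' @export
neutral_threshold <- function(demog, scan_params, reps = 100,
                              quantile = 0.999, seed = 1,
                              keep_pool = FALSE) {
  stopifnot(reps >= 20, quantile > 0, quantile < 1)
  set.seed(seed)
  sim_seeds <- sample.int(.Machine$integer.max, reps)
  W <- scan_params$W %||% 24
  maf_min <- scan_params$maf_min %||% 0.05
  pool <- vector("list", reps)
  fits <- vector("list", reps)
  n_failed <- 0L
  for (i in seq_len(reps)) {
    hap <- simulate_neutral_haplotypes(demog, scan_params$n_hap,
                                       scan_params$L, seed = sim_seeds[i])
    track <- suppressWarnings(mu_scan(hap, W = W, maf_min = maf_min))
    fit <- if (nrow(track) >= 10) suppressWarnings(fit_spline(track)) else NULL
    if (is.null(fit)) {
      n_failed <- n_failed + 1L
      next
    }
    pool[[i]] <- fit$fitted
    fits[[i]] <- fit
  }
  if (n_failed > reps / 2)
    stop("more than 50% of neutral simulations failed")
  pooled <- unlist(pool)
  thr <- stats::quantile(pooled, quantile, names = FALSE)
  attr(thr, "n_failed") <- n_failed
  if (keep_pool) {
    attr(thr, "pool") <- pooled
    attr(thr, "fits") <- fits[!vapply(fits, is.null, TRUE)]
  }
  thr
}

#' Call sweep regions from a smoothed track
#'
#' Maximal runs of consecutive evaluation positions with fitted value above
#' the threshold become intervals `[first position, last position + 1)`
#' (0-based half-open); intervals separated by a gap of at most `merge_dist`
#' bp are merged. The peak is the argmax of the fitted value within each
#' merged region.
#'
#' @param fit a `spline_fit` from [fit_spline()].
#' @param threshold finite outlier threshold.
#' @param merge_dist merge distance in bp (>= 0; the workflow default is
#'   50 kb).
#' @return a `sweep_regions` data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), `peak_bp`, `peak_value`; possibly empty.
#' @export
call_regions <- function(fit, threshold, merge_dist = 5e4) {
  stopifnot(is.finite(threshold), merge_dist >= 0)
  empty <- sweep_regions(data.frame(chrom = character(0), start = numeric(0),
                                    end = numeric(0), peak_bp = numeric(0),
                                    peak_value = numeric(0)))
  if (is.null(fit)) return(empty)
  out <- fit$fitted > threshold
  if (!any(out)) return(empty)
  r <- rle(out)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1
  keep <- r$values
  runs <- data.frame(i0 = starts_i[keep], i1 = ends_i[keep])
  runs$start <- fit$positions[runs$i0]
  runs$end <- fit$positions[runs$i1] + 1
  merged <- list()
  cur <- runs[1, ]
  if (nrow(runs) > 1) {
    for (k in 2:nrow(runs)) {
      if (runs$start[k] - cur$end <= merge_dist) {
        cur$end <- runs$end[k]
        cur$i1 <- runs$i1[k]
      } else {
        merged[[length(merged) + 1]] <- cur
        cur <- runs[k, ]
      }
    }
  }
  merged[[length(merged) + 1]] <- cur
  merged <- do.call(rbind, merged)
  peak <- vapply(seq_len(nrow(merged)), function(k) {
    idx <- merged$i0[k]:merged$i1[k]
    idx[which.max(fit$fitted[idx])]
  }, 0L)
  sweep_regions(data.frame(chrom = fit$chrom, start = merged$start,
                           end = merged$end,
                           peak_bp = fit$positions[peak],
                           peak_value = fit$fitted[peak]))
}

#' Sweep-region set constructor
#'
#' @param df data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `peak_bp`, `peak_value`.
#' @param population,subspecies optional labels stored as attributes.
#' @return `sweep_regions` data.frame, sorted, with non-overlapping regions.
#' @export
sweep_regions <- function(df, population = NA_character_,
                          subspecies = NA_character_) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df)) {
    stopifnot(all(df$start < df$end))
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(df, class = c("sweep_regions", "data.frame"),
            population = population, subspecies = subspecies)
}

#' @export
print.sweep_regions <- function(x, ...) {
  cat(sprintf("sweep_regions: %d region(s)", nrow(x)))
  pop <- attr(x, "population")
  if (!is.na(pop)) cat(" [", pop, "]", sep = "")
  cat("\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

# >=1 bp overlap between 0-based half-open intervals
.overlaps_any <- function(s, e, starts, ends) {
  vapply(seq_along(s), function(i) any(s[i] < ends & starts < e[i]), TRUE)
}

#' Replicate concordance between two sweep-region sets
#'
#' A region is shared when it overlaps (>= 1 bp) any region in the other set.
#'
#' @param setA,setB `sweep_regions` on the same coordinate system.
#' @return list with `sA` = shared/|A|, `sB` = shared/|B|, `mean`; an empty
#'   set yields `NA` for its side and a warning.
#' @export
replicate_concordance <- function(setA, setB) {
  share <- function(a, b) {
    if (nrow(a) == 0) {
      warning("empty region set: concordance undefined for that side")
      return(NA_real_)
    }
    same <- outer(a$chrom, b$chrom, "==")
    ov <- outer(a$start, b$end, "<") & outer(a$end, b$start, ">") & same
    mean(apply(ov, 1, any))
  }
  sA <- share(setA, setB)
  sB <- share(setB, setA)
  list(sA = sA, sB = sB, mean = mean(c(sA, sB)))
}

#' Hyperparameter grid for the sweep-calling pipeline
#'
#' Default grids: SNP windows
#' \{10, 24, 50, 100, 200, 500\}, outlier quantiles
#' \{0.8, 0.9, 0.95, 0.99, 0.999\}, merge distances
#' \{50, 100, 200, 500\} kb.
#'
#' @param W,quantile,merge_dist candidate values.
#' @return data.frame of all combinations.
#' @export
hyperparam_grid <- function(W = c(10, 24, 50, 100, 200, 500),
                            quantile = c(0.8, 0.9, 0.95, 0.99, 0.999),
                            merge_dist = c(5e4, 1e5, 2e5, 5e5)) {
  expand.grid(W = W, quantile = quantile, merge_dist = merge_dist,
              KEEP.OUT.ATTRS = FALSE)
}

#' Hyperparameter grid search on replicate concordance
#'
#' For every grid combination, runs the scan-spline-threshold-call pipeline on
#' both members of each replicate pair and scores the combination by the mean
#' replicate concordance across pairs; returns the argmax and the full score
#' table. Neutral chromosomes are simulated once and rescanned per window
#' size, so thresholds are consistent across combinations.
#'
#' @param pairs list of replicate pairs; each pair is a list of two
#'   [hap_matrix()] objects from non-overlapping samples of one population.
#' @param demog a [demography()] used for the neutral threshold simulations
#'   (a list of demographies, one per pair, is also accepted).
#' @param grid data.frame from [hyperparam_grid()].
#' @param scan_params list with `L`, `n_hap`, optional `maf_min`.
#' @param neutral_reps neutral replicates per threshold (default 20).
#' @param seed integer seed.
#' @return list with `best` (one-row data.frame) and `table` (all
#'   combinations with their scores; failed combinations score `NA`). Ties
#'   are broken by smaller `W`, then larger `quantile`, then smaller
#'   `merge_dist`.
#' @export
grid_search <- function(pairs, demog, grid = hyperparam_grid(),
                        scan_params = list(), neutral_reps = 20, seed = 1) {
  stopifnot(length(pairs) >= 1)
  demogs <- if (inherits(demog, "demography"))
    rep(list(demog), length(pairs)) else demog
  stopifnot(length(demogs) == length(pairs))
  maf_min <- scan_params$maf_min %||% 0.05
  set.seed(seed)
  thr_seeds <- sample.int(.Machine$integer.max, length(pairs))

  ws <- sort(unique(grid$W))
  # per pair and per W: empirical fits for both replicates + neutral pool
  cache <- vector("list", length(pairs))
  for (p in seq_along(pairs)) {
    pr <- pairs[[p]]
    sp <- scan_params
    sp$n_hap <- pr[[1]]$n_hap
    sp$L <- pr[[1]]$L
    cache[[p]] <- lapply(ws, function(w) {
      fitA <- suppressWarnings(fit_spline(suppressWarnings(
        mu_scan(pr[[1]], W = w, maf_min = maf_min))))
      fitB <- suppressWarnings(fit_spline(suppressWarnings(
        mu_scan(pr[[2]], W = w, maf_min = maf_min))))
      sp$W <- w
      thr <- try(neutral_threshold(demogs[[p]], sp, reps = neutral_reps,
                                   quantile = 0.5, seed = thr_seeds[p],
                                   keep_pool = TRUE), silent = TRUE)
      pool <- if (inherits(thr, "try-error")) NULL else attr(thr, "pool")
      list(fitA = fitA, fitB = fitB, pool = pool)
    })
    names(cache[[p]]) <- as.character(ws)
  }

  score <- rep(NA_real_, nrow(grid))
  for (g in seq_len(nrow(grid))) {
    vals <- numeric(0)
    ok <- TRUE
    for (p in seq_along(pairs)) {
      cc <- cache[[p]][[as.character(grid$W[g])]]
      if (is.null(cc$fitA) || is.null(cc$fitB) || is.null(cc$pool)) {
        ok <- FALSE
        break
      }
      thr <- stats::quantile(cc$pool, grid$quantile[g], names = FALSE)
      rA <- call_regions(cc$fitA, thr, grid$merge_dist[g])
      rB <- call_regions(cc$fitB, thr, grid$merge_dist[g])
      if (nrow(rA) == 0 || nrow(rB) == 0) {
        ok <- FALSE
        break
      }
      vals <- c(vals, replicate_concordance(rA, rB)$mean)
    }
    if (ok) score[g] <- mean(vals)
  }
  tab <- cbind(grid, score = score)
  if (all(is.na(score))) stop("every grid combination failed")
  ord <- order(-score, grid$W, -grid$quantile, grid$merge_dist,
               na.last = TRUE)
  list(best = tab[ord[1], , drop = FALSE], table = tab)
}
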