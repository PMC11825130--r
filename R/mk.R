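# Fold class of a codon position: number of the three alternative bases that
# leave the amino acid unchanged, mapped to the conventional {0,2,3,4} labels
# (0-fold = none synonymous, 4-fold = all synonymous).
.fold_table <- local({
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  tab <- array(NA_integer_, dim = c(64, 3),
               dimnames = list(names(code), NULL))
  for (cod in names(code)) {
    if (code[[cod]] == "*") next
    for (pos in 1:3) {
      nt <- strsplit(cod, "")[[1]]
      nsyn <- 0L
      for (alt in setdiff(bases, nt[pos])) {
        mut <- nt
        mut[pos] <- alt
        if (code[[paste(mut, collapse = "")]] == code[[cod]])
          nsyn <- nsyn + 1L
      }
      tab[cod, pos] <- c(0L, 2L, 3L, 4L)[nsyn + 1L]
    }
  }
  tab
})

#' Classify coding positions by codon degeneracy
#'
#' Annotates every CDS genomic position with its fold class: 0-fold (every
#' substitution changes the amino acid), 2-, 3-, or 4-fold (no substitution
#' does), under the standard nuclear code. Transcript CDS segments are
#' concatenated in translation order (minus strands reverse-complemented),
#' phase-adjusted, and scanned codon by codon; codons containing ambiguous
#' bases and internal stop codons are skipped and counted. Positions claimed
#' by several transcripts with conflicting classes are resolved to the most
#' constrained class (0-fold wins; numeric minimum) by default, or dropped.
#'
#' @param genome a [Biostrings::DNAStringSet] (or path to a FASTA file).
#' @param gff a GRanges of CDS features with `Parent` (or `ID`) and `phase`
#'   metadata (or path to a GFF3 file, imported via rtracklayer).
#' @param conflicts `"constrained"` (default, 0-fold wins) or `"drop"`.
#' @return data.frame: `chrom`, `pos` (1-based), `fold`, `strand`,
#'   `codon_pos` (1-3); attribute `n_skipped` counts skipped codons and
#'   `n_conflict` conflicting positions.
#' @export
classify_degeneracy <- function(genome, gff, conflicts = c("constrained",
                                                           "drop")) {
  conflicts <- match.arg(conflicts)
  if (is.character(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  if (is.character(gff)) {
    gff <- rtracklayer::import(gff)
    gff <- gff[gff$type == "CDS"]
  }
  meta <- S4Vectors::mcols(gff)
  tx <- if ("Parent" %in% names(meta) && any(lengths(meta$Parent) > 0)) {
    vapply(as.list(meta$Parent), function(p)
      if (length(p)) p[[1]] else NA_character_, "")
  } else if ("ID" %in% names(meta)) as.character(meta$ID)
  else rep("tx1", length(gff))
  phase <- if ("phase" %in% names(meta)) as.integer(meta$phase)
           else rep(0L, length(gff))
  phase[is.na(phase)] <- 0L
  n_skipped <- 0L
  recs <- list()
  for (t in unique(tx)) {
    idx <- which(tx == t)
    seg <- gff[idx]
    strand <- as.character(BiocGenerics::strand(seg))[1]
    ord <- order(BiocGenerics::start(seg),
                 decreasing = identical(strand, "-"))
    seg <- seg[ord]
    ph <- phase[idx][ord][1]
    pos_list <- lapply(seq_along(seg), function(i) {
      p <- BiocGenerics::start(seg)[i]:BiocGenerics::end(seg)[i]
      if (identical(strand, "-")) rev(p) else p
    })
    gpos <- unlist(pos_list)  # genomic positions in translation order
    chrom <- as.character(GenomeInfoDb::seqnames(seg))[1]
    chrseq <- genome[[chrom]]
    nt <- strsplit(as.character(chrseq), "")[[1]][gpos]
    if (identical(strand, "-"))
      nt <- c(A = "T", C = "G", G = "C", T = "A", N = "N")[nt]
    if (ph > 0) {
      gpos <- gpos[-(1:ph)]
      nt <- nt[-(1:ph)]
    }
    ncod <- length(gpos) %/% 3
    if (ncod == 0) next
    use <- seq_len(ncod * 3)
    gpos <- gpos[use]; nt <- nt[use]
    codons <- paste0(nt[c(TRUE, FALSE, FALSE)], nt[c(FALSE, TRUE, FALSE)],
                     nt[c(FALSE, FALSE, TRUE)])
    good <- codons %in% rownames(.fold_table) &
      !is.na(.fold_table[match(codons, rownames(.fold_table)), 1])
    n_skipped <- n_skipped + sum(!good)
    if (!any(good)) next
    fold <- t(.fold_table[codons[good], , drop = FALSE])
    cod_idx <- which(rep(good, each = 3))
    recs[[t]] <- data.frame(chrom = chrom, pos = gpos[cod_idx],
                            fold = as.integer(fold),
                            strand = strand,
                            codon_pos = rep(1:3, sum(good)))
  }
  out <- do.call(rbind, recs)
  if (is.null(out))
    out <- data.frame(chrom = character(0), pos = integer(0),
                      fold = integer(0), strand = character(0),
                      codon_pos = integer(0))
  key <- paste(out$chrom, out$pos)
  n_conflict <- 0L
  if (anyDuplicated(key)) {
    fold_range <- tapply(out$fold, key, function(f) length(unique(f)))
    conflict_keys <- names(fold_range)[fold_range > 1]
    n_conflict <- length(conflict_keys)
    if (conflicts == "drop") {
      out <- out[!(key %in% conflict_keys), , drop = FALSE]
      key <- paste(out$chrom, out$pos)
      out <- out[!duplicated(key), , drop = FALSE]
    } else {
      ord <- order(key, out$fold)  # 0-fold first within position
      out <- out[ord, , drop = FALSE]
      out <- out[!duplicated(paste(out$chrom, out$pos)), , drop = FALSE]
    }
  } else {
    out <- out[!duplicated(key), , drop = FALSE]
  }
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  attr(out, "n_conflict") <- n_conflict
  out
}

#' Polarize sites against two outgroups
#'
#' Ancestral-state rules: a state is usable for an outgroup only when the
#' outgroup is effectively homozygous there (minor allele frequency
#' <= 0.001); higher MAF means the outgroup is treated as missing at the
#' site. The ancestral allele is the shared homozygous state of both
#' outgroups; sites homozygous in outgroup 1 but missing in outgroup 2 take
#' outgroup 1's state; sites missing in outgroup 1 are excluded; two
#' homozygous but disagreeing outgroups exclude the site (counted).
#'
#' @param og1,og2 character vectors of outgroup alleles (`NA` = missing);
#'   outgroup 1 is the better-covered outgroup.
#' @param og1_maf,og2_maf outgroup minor-allele-frequency estimates
#'   (default 0 = homozygous).
#' @return character vector of ancestral calls (`NA` where excluded), with
#'   attribute `n_disagree` counting homozygous disagreements.
#' @export
polarize_sites <- function(og1, og2, og1_maf = 0, og2_maf = 0) {
  n <- length(og1)
  og1_maf <- rep_len(og1_maf, n)
  og2_maf <- rep_len(og2_maf, n)
  og1[!is.na(og1) & og1_maf > 0.001] <- NA
  og2[!is.na(og2) & og2_maf > 0.001] <- NA
  anc <- rep(NA_character_, n)
  both <- !is.na(og1) & !is.na(og2)
  agree <- both & og1 == og2
  anc[agree] <- og1[agree]
  only1 <- !is.na(og1) & is.na(og2)
  anc[only1] <- og1[only1]
  n_disagree <- sum(both & og1 != og2)
  attr(anc, "n_disagree") <- n_disagree
  anc
}

#' Unfolded-SFS count container
#'
#' Per-frequency-bin polymorphism counts for the selected (0-fold) and
#' neutral (4-fold) site classes, plus fixed-difference totals. Subscript 0
#' denotes the neutral class throughout, following the asymptotic-MK
#' literature.
#'
#' @param n haploid sample size; bins are x_i = i/n for i = 1..n-1.
#' @param p selected polymorphic counts per bin (length n-1).
#' @param p0 neutral polymorphic counts per bin (length n-1).
#' @param d selected fixed derived differences.
#' @param d0 neutral fixed derived differences.
#' @param meta optional list of group labels / provenance.
#' @return object of class `usfs_counts`.
#' @export
usfs_counts <- function(n, p, p0, d, d0, meta = list()) {
  stopifnot(length(p) == n - 1, length(p0) == n - 1,
            all(p >= 0), all(p0 >= 0), d >= 0, d0 >= 0)
  structure(list(n = n, x = seq_len(n - 1) / n, p = p, p0 = p0,
                 d = d, d0 = d0, meta = meta),
            class = "usfs_counts")
}

#' @export
print.usfs_counts <- function(x, ...) {
  cat(sprintf("usfs_counts: n = %d (%d bins), d = %g, d0 = %g\n",
              x$n, x$n - 1, x$d, x$d0))
  invisible(x)
}

#' Build uSFS counts from site-level calls
#'
#' Tallies polymorphic sites into frequency bins and fixed derived
#' differences into totals, split by fold class: 0-fold sites feed the
#' selected side (`p`, `d`) and 4-fold sites the neutral side (`p0`, `d0`);
#' other fold classes are ignored. Sites lacking a degeneracy or ancestral
#' call must be excluded upstream (the site table is expected to be already
#' polarized).
#'
#' @param sites data.frame with columns `fold` (0/2/3/4), `derived_count`
#'   (0..n; `n` marks a fixed derived difference, 0 is monomorphic
#'   ancestral), and optionally `mutation_type` for stratification.
#' @param n haploid sample size.
#' @param by optional column name to stratify by (e.g. `"mutation_type"`).
#' @return a [usfs_counts()] or, with `by`, a named list of them.
#' @export
build_usfs <- function(sites, n, by = NULL) {
  stopifnot(all(c("fold", "derived_count") %in% names(sites)),
            all(sites$derived_count >= 0 & sites$derived_count <= n))
  if (!is.null(by)) {
    groups <- split(sites, sites[[by]])
    return(lapply(groups, build_usfs, n = n))
  }
  tally <- function(sub) {
    poly <- sub$derived_count >= 1 & sub$derived_count <= n - 1
    list(p = tabulate(sub$derived_count[poly], nbins = n - 1),
         d = sum(sub$derived_count == n))
  }
  sel <- tally(sites[sites$fold == 0, , drop = FALSE])
  neu <- tally(sites[sites$fold == 4, , drop = FALSE])
  usfs_counts(n = n, p = sel$p, p0 = neu$p, d = sel$d, d0 = neu$d)
}

#' Per-bin alpha estimates
#'
#' At each allele-frequency bin, `alpha_i = 1 - (d0/d) * (p_i / p0_i)` with
#' subscript 0 the neutral class. Bins with `p0_i = 0` are undefined (`NA`)
#' and excluded from curve fitting.
#'
#' @param u a [usfs_counts()] with `d > 0`.
#' @return data.frame with `bin`, `x`, `alpha` (`NA` where undefined).
#' @export
alpha_per_bin <- function(u) {
  stopifnot(inherits(u, "usfs_counts"))
  if (u$d <= 0) stop("alpha undefined when d = 0")
  alpha <- ifelse(u$p0 > 0, 1 - (u$d0 / u$d) * (u$p / u$p0), NA_real_)
  data.frame(bin = seq_len(u$n - 1), x = u$x, alpha = alpha)
}

# single bounded nonlinear least-squares fit of a + b exp(-c x), multi-start;
# optional quadratic (MAP) penalty pulls (a, b, log c) toward `center` with
# per-parameter precisions 1/tau2 scaled by the group's residual variance
.fit_asymptotic_one <- function(x, alpha, c_starts = c(0.5, 2, 8),
                                center = NULL, tau2 = NULL, sigma2 = NULL) {
  penalty <- function(par) {
    if (is.null(center)) return(0)
    th <- c(par[1], par[2], log(par[3]))
    sigma2 * sum((th - center)^2 / tau2)
  }
  obj <- function(par)
    sum((alpha - (par[1] + par[2] * exp(-par[3] * x)))^2) + penalty(par)
  best <- NULL
  starts <- list()
  for (c0 in c_starts) {
    e <- exp(-c0 * x)
    ab <- tryCatch(stats::coef(stats::lm(alpha ~ e)),
                   error = function(e2) c(mean(alpha), 0))
    # a is the x -> 1 asymptote of a proportion-like quantity: alpha <= 1
    starts[[length(starts) + 1]] <-
      c(a = min(unname(ab[1]), 1), b = unname(ab[2]), c = c0)
  }
  if (!is.null(center))
    starts[[length(starts) + 1]] <-
      c(a = center[1], b = center[2], c = exp(center[3]))
  for (start in starts) {
    fit <- tryCatch(
      stats::optim(start, obj, method = "L-BFGS-B",
                   lower = c(-10, -10, 1e-3), upper = c(1, 10, 100),
                   hessian = is.null(center),
                   control = list(maxit = 500, factr = 1e7)),
      error = function(e2) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) return(NULL)
  par <- best$par
  if (stats::sd(alpha) < 1e-12) {
    par <- c(a = mean(alpha), b = 0, c = NA_real_)
    return(list(par = par, sse = 0, converged = TRUE, degenerate = TRUE,
                sigma2 = 0, se2 = rep(NA_real_, 3)))
  }
  sse <- best$value - penalty(par)
  sigma2_hat <- sse / max(length(x) - 3, 1)
  # Gauss-Newton sampling variances of (a, b, log c) from the SSE Hessian
  se2 <- rep(NA_real_, 3)
  if (!is.null(best$hessian)) {
    v <- tryCatch(2 * sigma2_hat * solve(best$hessian),
                  error = function(e2) NULL)
    if (!is.null(v) && all(is.finite(diag(v))) && all(diag(v) > 0)) {
      se2 <- diag(v)
      se2[3] <- se2[3] / par[3]^2  # delta method: var(log c)
    }
  }
  list(par = par, sse = sse, converged = best$convergence == 0,
       degenerate = abs(par[2]) < 1e-8, sigma2 = sigma2_hat, se2 = se2)
}

.alpha_inf <- function(par) {
  if (is.na(par[3])) unname(par[1]) else
    unname(par[1] + par[2] * exp(-par[3]))
}

#' Fit the asymptotic alpha curve
#'
#' Fits `alpha_i = a + b * exp(-c * x_i)` to per-bin alpha estimates by
#' bounded nonlinear least squares with multi-start over `c`, and reports
#' the asymptote `alpha_inf = a + b * exp(-c)` (alpha extrapolated to
#' derived frequency 1), with bootstrap-over-bins percentile intervals.
#' Modes: `"pooled"` ignores groups; `"per-group"` fits each group
#' independently; `"partial-pooling"` fits per group and then shrinks each
#' curve parameter toward the across-group mean with random-effects
#' (DerSimonian-Laird) weights, which lowers the mean squared error of
#' `alpha_inf` when groups share hyperparameters.
#'
#' @param curves data.frame with columns `x`, `alpha`, and optionally
#'   `group`; rows with `NA` alpha are dropped. Each group needs >= 5
#'   defined bins with x in (0, 1).
#' @param mode `"pooled"`, `"per-group"` or `"partial-pooling"`.
#' @param boot bootstrap replicates for the interval (0 disables; default
#'   200).
#' @param level interval level (default 0.95).
#' @param seed seed for the bootstrap.
#' @return data.frame (one row per group): `group`, `a`, `b`, `c`,
#'   `alpha_inf`, `lower`, `upper`, `level`, `converged`, `degenerate`.
#' @export
fit_asymptotic <- function(curves, mode = c("pooled", "per-group",
                                            "partial-pooling"),
                           boot = 200, level = 0.95, seed = 1) {
  mode <- match.arg(mode)
  curves <- curves[!is.na(curves$alpha), , drop = FALSE]
  stopifnot(all(curves$x > 0 & curves$x < 1))
  if (mode == "pooled" || is.null(curves$group)) {
    curves$group <- "all"
    if (mode == "pooled") curves$group <- "all"
  }
  groups <- split(curves, curves$group)
  fit_group <- function(g) {
    if (nrow(g) < 5) stop("need >= 5 defined bins per group")
    f <- .fit_asymptotic_one(g$x, g$alpha)
    if (is.null(f)) return(list(par = c(a = NA, b = NA, c = NA),
                                converged = FALSE, degenerate = FALSE,
                                boot_par = NULL))
    boot_par <- NULL
    if (boot > 0) {
      boot_par <- matrix(NA_real_, boot, 3)
      for (r in seq_len(boot)) {
        idx <- sample.int(nrow(g), replace = TRUE)
        fb <- .fit_asymptotic_one(g$x[idx], g$alpha[idx])
        if (!is.null(fb)) boot_par[r, ] <- fb$par
      }
    }
    c(f, list(boot_par = boot_par))
  }
  set.seed(seed)
  fits <- lapply(groups, fit_group)
  if (mode == "partial-pooling" && length(fits) >= 2) {
    # empirical-Bayes hierarchy by penalized likelihood: estimate the
    # between-group variance of each parameter (a, b, log c) by
    # DerSimonian-Laird using Gauss-Newton sampling variances, then refit
    # every group jointly with a MAP penalty toward the random-effects mean.
    # The joint refit respects the strong (a, b, c) correlations that
    # coordinate-wise shrinkage would break.
    est_mat <- do.call(rbind, lapply(fits, function(f)
      c(f$par[1], f$par[2], log(f$par[3]))))
    se2_mat <- do.call(rbind, lapply(fits, function(f) f$se2))
    center <- tau2 <- rep(NA_real_, 3)
    for (j in 1:3) {
      est <- est_mat[, j]
      se2 <- se2_mat[, j]
      ok <- is.finite(est) & is.finite(se2) & se2 > 0
      if (sum(ok) < 2) next
      w <- 1 / se2[ok]
      mu_fe <- sum(w * est[ok]) / sum(w)
      Q <- sum(w * (est[ok] - mu_fe)^2)
      c_dl <- sum(w) - sum(w^2) / sum(w)
      t2 <- max(0, (Q - (sum(ok) - 1)) / c_dl)
      w_re <- 1 / (se2[ok] + t2)
      center[j] <- sum(w_re * est[ok]) / sum(w_re)
      tau2[j] <- max(t2, 1e-8)
    }
    if (all(is.finite(center))) {
      for (i in seq_along(fits)) {
        g <- groups[[i]]
        f2 <- .fit_asymptotic_one(g$x, g$alpha, center = center,
                                  tau2 = tau2, sigma2 = fits[[i]]$sigma2)
        if (!is.null(f2)) {
          fits[[i]]$par <- f2$par
          fits[[i]]$converged <- f2$converged
        }
      }
    }
  }
  out <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    ai <- .alpha_inf(f$par)
    lo <- up <- NA_real_
    if (!is.null(f$boot_par)) {
      ai_boot <- apply(f$boot_par, 1, .alpha_inf)
      qs <- stats::quantile(ai_boot, c((1 - level) / 2, 1 - (1 - level) / 2),
                            na.rm = TRUE, names = FALSE)
      lo <- min(qs[1], ai)
      up <- max(qs[2], ai)
    }
    data.frame(group = nm, a = unname(f$par[1]), b = unname(f$par[2]),
               c = unname(f$par[3]), alpha_inf = ai, lower = lo, upper = up,
               level = level, converged = f$converged,
               degenerate = f$degenerate)
  }))
  rownames(out) <- NULL
  if (any(!out$converged))
    warning("non-convergence flagged for group(s): ",
            paste(out$group[!out$converged], collapse = ", "))
  out
}

#' Mutation-type class of an ancestral/derived change
#'
#' Pools single-base changes into the classes used for GC-biased gene
#' conversion contrasts: `"AT_to_GC"` (weak to strong), `"GC_to_AT"`
#' (strong to weak), `"other"`.
#'
#' @param anc,der ancestral and derived alleles (single bases).
#' @return character vector of class labels.
#' @export
mutation_type <- function(anc, der) {
  weak <- c("A", "T")
  strong <- c("G", "C")
  ifelse(anc %in% weak & der %in% strong, "AT_to_GC",
         ifelse(anc %in% strong & der %in% weak, "GC_to_AT", "other"))
}
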