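#' Piecewise-constant demographic history
#'
#' A demography is an ordered set of epochs, each with a diploid effective
#' population size, plus per-bp per-generation mutation and recombination
#' rates. Epoch start times are in generations before present and must begin
#' at 0; the last epoch extends indefinitely into the past.
#'
#' @param epochs data.frame with columns `start` (generations before present,
#'   strictly increasing from 0) and `Ne` (diploid effective size, > 0).
#' @param mu per-bp per-generation mutation rate (default 3e-8, the rate
#'   commonly assumed for Zea).
#' @param r per-bp per-generation recombination rate.
#' @return object of class `demography`.
#' @examples
#' demography()  # single epoch, Ne = 1e4
#' demography(data.frame(start = c(0, 1e4), Ne = c(2e3, 1e4)))
#' @export
demography <- function(epochs = data.frame(start = 0, Ne = 1e4),
                       mu = 3e-8, r = 1.6e-8) {
  stopifnot(is.data.frame(epochs), all(c("start", "Ne") %in% names(epochs)))
  epochs <- epochs[order(epochs$start), c("start", "Ne"), drop = FALSE]
  if (epochs$start[1] != 0)
    stop("first epoch must start at generation 0")
  if (any(diff(epochs$start) <= 0))
    stop("epoch start generations must be strictly increasing")
  if (any(epochs$Ne <= 0))
    stop("all Ne must be positive")
  if (!is.numeric(mu) || !is.numeric(r) || mu < 0 || r < 0)
    stop("mu and r must be non-negative numeric rates")
  structure(list(epochs = epochs, mu = mu, r = r), class = "demography")
}

#' @export
print.demography <- function(x, ...) {
  cat("Piecewise-constant demography:", nrow(x$epochs), "epoch(s)\n")
  print(x$epochs, row.names = FALSE)
  cat(sprintf("mu = %g /bp/gen, r = %g /bp/gen\n", x$mu, x$r))
  invisible(x)
}

# Coalescence waiting times for n lineages under a piecewise-constant
# demography. Returns the n-1 event times (generations before present,
# increasing). Rate with k lineages in an epoch of size Ne is
# k(k-1)/2 / (2 Ne) per generation; epoch boundaries handled by redrawing
# the exponential (memorylessness).
coalescent_times <- function(n, demog) {
  starts <- demog$epochs$start
  nes <- demog$epochs$Ne
  bounds <- c(starts[-1], Inf)
  times <- numeric(n - 1)
  t <- 0
  ep <- 1L
  for (k in n:2) {
    rate <- k * (k - 1) / 2 / (2 * nes[ep])
    repeat {
      dt <- stats::rexp(1, rate)
      if (t + dt <= bounds[ep]) {
        t <- t + dt
        break
      }
      t <- bounds[ep]
      ep <- ep + 1L
      rate <- k * (k - 1) / 2 / (2 * nes[ep])
    }
    times[n - k + 1] <- t
  }
  times
}

# coalescent_times stays in R as an independent oracle for the epoch-aware
# waiting-time logic implemented in C++ (tested against each other on
# tree-height moments).
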