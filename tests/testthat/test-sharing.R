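# Sharing: overlap clustering, accuracy estimates, hypergeometric test,
# Benjamini-Yekutieli correction.

test_that("cluster_regions forms single-linkage overlap components", {
  # disjoint regions: every region its own cluster
  sets <- list(
    a = make_regions(rbind(c(0, 100), c(1000, 1100)), population = "a"),
    b = make_regions(rbind(c(500, 600)), population = "b"))
  cl <- cluster_regions(sets)
  expect_identical(nrow(cl), 3L)
  expect_true(all(cl$n_populations == 1))
  # chained overlaps A-B and B-C but not A-C: one cluster
  sets2 <- list(
    a = make_regions(rbind(c(0, 100)), population = "a"),
    b = make_regions(rbind(c(50, 250)), population = "b"),
    c = make_regions(rbind(c(200, 300)), population = "c"))
  cl2 <- cluster_regions(sets2)
  expect_identical(nrow(cl2), 1L)
  expect_identical(cl2$populations, "a,b,c")
  expect_equal(cl2$start, 0)
  expect_equal(cl2$end, 300)
  # touching half-open intervals are separate clusters
  sets3 <- list(
    a = make_regions(rbind(c(0, 100)), population = "a"),
    b = make_regions(rbind(c(100, 200)), population = "b"))
  expect_identical(nrow(cluster_regions(sets3)), 2L)
})

test_that("cluster_regions equals the brute-force union-find oracle", {
  set.seed(17)
  for (rep in 1:8) {
    npop <- sample(2:4, 1)
    sets <- lapply(seq_len(npop), function(p) {
      k <- sample(3:8, 1)
      start <- sort(sample.int(5e4, k)) * 10
      len <- sample(50:5000, k, replace = TRUE)
      make_regions(cbind(start, start + len), population = paste0("p", p))
    })
    names(sets) <- paste0("p", seq_len(npop))
    cl <- cluster_regions(sets)
    flat <- do.call(rbind, lapply(names(sets), function(nm)
      data.frame(population = nm, chrom = sets[[nm]]$chrom,
                 start = sets[[nm]]$start, end = sets[[nm]]$end)))
    comp <- oracle_union_find(flat)
    expect_identical(nrow(cl), length(unique(comp)))
    # same partition: every oracle component lies inside exactly one cluster
    flat$key <- paste0(flat$population, ":",
                       stats::ave(seq_len(nrow(flat)), flat$population,
                                  FUN = seq_along))
    members <- strsplit(cl$members, ",")
    key2cl <- integer(nrow(flat))
    for (k in seq_along(members)) key2cl[flat$key %in% members[[k]]] <- k
    expect_true(all(key2cl > 0))
    expect_identical(length(unique(paste(comp, key2cl))),
                     length(unique(comp)))
    # size multisets agree; partition covers every region once
    expect_identical(sort(as.integer(table(comp))),
                     sort(lengths(members)))
    expect_identical(sum(lengths(members)), nrow(flat))
  }
})

test_that("sharing_summary counts private proportions and contingency", {
  ssp <- c(a = "maize", b = "teosinte", c = "maize")
  sets <- list(
    a = make_regions(rbind(c(0, 100), c(1000, 1100)), population = "a"),
    b = make_regions(rbind(c(50, 120)), population = "b"),
    c = make_regions(rbind(c(5000, 5100)), population = "c"))
  cl <- cluster_regions(sets, subspecies = ssp)
  sm <- sharing_summary(cl, ssp)
  pr <- stats::setNames(sm$private$private_proportion, sm$private$population)
  expect_equal(pr[["a"]], 0.5)   # one shared, one private
  expect_equal(pr[["b"]], 0)     # its only cluster is shared
  expect_equal(pr[["c"]], 1)
  expect_identical(sum(sm$contingency$n_clusters), nrow(cl))
  # all singleton clusters: private proportion 1 everywhere
  sets1 <- list(a = make_regions(rbind(c(0, 10)), population = "a"),
                b = make_regions(rbind(c(100, 110)), population = "b"))
  sm1 <- sharing_summary(cluster_regions(sets1, ssp[1:2]), ssp[1:2])
  expect_true(all(sm1$private$private_proportion == 1))
  # one cluster containing every population: private proportion 0
  sets0 <- list(a = make_regions(rbind(c(0, 100)), population = "a"),
                b = make_regions(rbind(c(50, 150)), population = "b"))
  sm0 <- sharing_summary(cluster_regions(sets0, ssp[1:2]), ssp[1:2])
  expect_true(all(sm0$private$private_proportion == 0))
})

test_that("accuracy_P implements 1 - mean replicate-sharing proportion", {
  expect_equal(accuracy_P(0, 10, 20)$P, 1)
  expect_equal(accuracy_P(5, 5, 5)$P, 0)
  expect_equal(accuracy_P(30, 40, 60)$P, 1 - (30 / 40 + 30 / 60) / 2)
  expect_error(accuracy_P(5, 0, 10))
  expect_error(accuracy_P(11, 10, 12))
  # the published replicate-sharing proportions reproduce the printed
  # accuracy adjustments: maize 0.33, teosinte 0.20
  expect_equal(round(accuracy_P(67, 100, 100)$P, 2),
               unname(1 - palmar_chico_replicate_sharing[["maize"]]))
  expect_equal(round(accuracy_P(80, 100, 100)$P, 2), 0.20)
})

test_that("shared_sweep_test equals the exact pmf-summation oracle", {
  # worked instance: N=20, n1=5, n2=4, x=2, P=1
  oracle <- sum(sapply(2:4, function(k)
    choose(5, k) * choose(15, 4 - k) / choose(20, 4)))
  got <- shared_sweep_test(20, 5, 4, 2, P = 1)
  expect_equal(got$p, oracle, tolerance = 1e-12)
  expect_equal(round(got$p, 4), 0.2487)
  # x = 0: p = 1
  expect_equal(shared_sweep_test(20, 5, 4, 0, P = 1)$p, 1)
  # P = 1 reproduces the unadjusted counts exactly
  expect_identical(unname(got$adjusted), c(20, 5, 4, 2))
  # n1 < n2 reordered internally
  sw <- shared_sweep_test(20, 4, 5, 2, P = 1, pair = c("a", "b"))
  expect_equal(sw$p, got$p)
  expect_identical(sw$pair, c("b", "a"))
  expect_error(shared_sweep_test(20, 5, 4, 5, P = 1), "counts")
})

test_that("shared_sweep_test agrees with phyper on a lattice and is monotone", {
  for (N in c(10, 20, 30)) {
    for (n1 in c(3, 6, 9)) {
      for (n2 in c(2, 5)) {
        if (n2 > n1 || n1 > N) next
        for (x in 0:n2) {
          got <- shared_sweep_test(N, n1, n2, x, P = 1)$p
          want <- stats::phyper(x - 1, n1, N - n1, n2, lower.tail = FALSE)
          expect_equal(got, want, tolerance = 1e-12)
        }
        ps <- vapply(0:n2, function(x)
          shared_sweep_test(N, n1, n2, x, P = 1)$p, 0)
        expect_true(all(diff(ps) <= 1e-15))  # non-increasing in x
      }
    }
  }
  # monotone in N, other arguments fixed: a larger locus universe makes the
  # observed overlap rarer by chance, so the tail probability falls
  pN <- vapply(c(10, 15, 20, 40, 80), function(N)
    shared_sweep_test(N, 6, 5, 3, P = 1)$p, 0)
  expect_true(all(diff(pN) <= 1e-15))
})

test_that("accuracy adjustment scales and clamps counts coherently", {
  sw <- shared_sweep_test(100, 20, 10, 5, P = 0.33)
  expect_identical(unname(sw$adjusted),
                   c(33, 7, 3, 2))  # round-half-up of 33, 6.6, 3.3, 1.65
  a <- sw$adjusted
  expect_true(a["x"] <= a["n2"] && a["n2"] <= a["n1"] && a["n1"] <= a["N"])
  # half-up rounding keeps sharing visible at small x
  sw2 <- shared_sweep_test(100, 20, 10, 2, P = 0.25)
  expect_identical(unname(sw2$adjusted["x"]), 1)  # 0.5 rounds up, not to even
  expect_error(shared_sweep_test(10, 5, 4, 2, P = 0))
})

test_that("adjust_pvalues_by matches the closed form and p.adjust", {
  expect_equal(adjust_pvalues_by(0.37), 0.37)
  # hand computation for (0.01, 0.02, 0.5), c(3) = 11/6:
  # sorted: 0.01*3*(11/6)/1 = 0.055; 0.02*3*(11/6)/2 = 0.055;
  # 0.5*3*(11/6)/3 = 0.9167; cummin from largest keeps all
  expect_equal(adjust_pvalues_by(c(0.01, 0.02, 0.5)),
               c(0.055, 0.055, 11 / 12), tolerance = 1e-12)
  # oracle: stats::p.adjust BY on random vectors, original order restored
  set.seed(9)
  for (i in 1:25) {
    p <- stats::runif(sample(1:40, 1))
    expect_equal(adjust_pvalues_by(p), stats::p.adjust(p, "BY"),
                 tolerance = 1e-12)
  }
  # monotone in the sorted order
  p <- stats::runif(100)
  adj <- adjust_pvalues_by(p)
  expect_true(!is.unsorted(adj[order(p)]))
})

test_that("estimate_n_slots and pairwise tests wire together", {
  expect_identical(estimate_n_slots(1e8, rep(5e4, 10), 5e4), 1000L)
  sets <- list(
    a = make_regions(rbind(c(0, 1e4), c(5e5, 5.1e5), c(9e5, 9.1e5)),
                     population = "a"),
    b = make_regions(rbind(c(5e5, 5.2e5), c(2e6, 2.01e6)),
                     population = "b"))
  tst <- pairwise_sharing_tests(sets, genome_length = 1e7,
                                merge_dist = 5e4, P = 1)
  expect_identical(nrow(tst), 1L)
  expect_identical(tst$x, 1L)
  expect_identical(tst$n1, 3L)  # larger set designated first
  expect_true(tst$p_raw >= 0 && tst$p_raw <= 1)
  expect_equal(tst$p_adj, tst$p_raw)  # single test: BY identity
})

test_that("type-I error of the sharing test is controlled under null placement", {
  # 500 pairs of randomly placed non-overlapping-slot regions, P = 1;
  # rejection rate at nominal 0.05 must stay below 0.10
  set.seed(123)
  L <- 1e8; len <- 5e4; md <- 5e4
  n1 <- 30; n2 <- 25
  N <- estimate_n_slots(L, rep(len, n1 + n2), md)
  rej <- logical(500)
  for (i in 1:500) {
    s1 <- sample.int(L - len, n1); s2 <- sample.int(L - len, n2)
    x <- sum(vapply(s1, function(s) any(s < s2 + len & s2 < s + len), TRUE))
    x <- min(x, n2)
    rej[i] <- shared_sweep_test(N, n1, n2, x, P = 1)$p < 0.05
  }
  expect_lte(mean(rej), 0.10)
})

test_that("the test has power when the truth forces sharing", {
  # pairs sharing >= 50% of regions score lower p than null pairs
  set.seed(321)
  L <- 1e8; len <- 5e4; md <- 5e4; n <- 20
  N <- estimate_n_slots(L, rep(len, 2 * n), md)
  p_alt <- p_null <- numeric(50)
  for (i in 1:50) {
    shared_starts <- sample.int(L - len, n / 2)
    s1 <- c(shared_starts, sample.int(L - len, n / 2))
    s2 <- c(shared_starts, sample.int(L - len, n / 2))
    x_alt <- sum(vapply(s1, function(s) any(s < s2 + len & s2 < s + len),
                        TRUE))
    p_alt[i] <- shared_sweep_test(N, n, n, min(x_alt, n), P = 1)$p
    s1n <- sample.int(L - len, n); s2n <- sample.int(L - len, n)
    x_null <- sum(vapply(s1n, function(s) any(s < s2n + len & s2n < s + len),
                         TRUE))
    p_null[i] <- shared_sweep_test(N, n, n, min(x_null, n), P = 1)$p
  }
  expect_lt(stats::median(p_alt), stats::median(p_null))
})
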