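test_that("bp-to-cM conversion uses the per-chromosome genetic scale", {
  g <- oneChromGenome(1000000L)
  ev <- rbind(truthRow("t1", "chrA", "CO", 400000, 400000, "1,3", 1L),
              truthRow("t1", "chrA", "CO", 500000, 500000, "1,4", 2L))
  # mean 2 COs -> 100 cM over 1 Mb; 100 kb apart -> 10 cM
  d <- intercrossoverDistancesCM(ev, g, meanCo = c(chrA = 2))
  expect_equal(d, 10)
  # 0 or 1 crossover contributes no distance
  expect_length(intercrossoverDistancesCM(ev[1, ], g, meanCo = c(chrA = 2)),
                0)
  # chromosomes with zero mean crossovers are excluded with a warning
  expect_warning(
    d0 <- intercrossoverDistancesCM(ev, g, meanCo = c(chrA = 0)),
    "zero mean")
  expect_length(d0, 0)
})

test_that("cM distances are invariant to doubling the crossover rate", {
  g <- oneChromGenome(10000000L)
  mk <- function(lam, seed) {
    p <- simParams(g, meanCoPerChrom = c(chrA = lam),
                   ncoRatePerChrom = c(chrA = 0), gammaShape = 1,
                   classIFraction = 1, coGcProb = 0)
    simulateTruth(g, p, nTetrads = 400, seed = seed)
  }
  t1 <- mk(20, 31); t2 <- mk(40, 32)
  d1 <- intercrossoverDistancesCM(t1, g, nTetrads = 400)
  d2 <- intercrossoverDistancesCM(t2, g, nTetrads = 400)
  expect_lt(abs(mean(d1) - mean(d2)) / mean(d1), 0.1)
  # physical spacing halves when lambda doubles (checked on pooled means)
  bpMean <- function(tr) {
    co <- tr[tr$class == "CO", ]
    mean(unlist(tapply(co$start, co$tetrad_id,
                       function(x) if (length(x) > 1) diff(sort(x)))))
  }
  expect_lt(abs(bpMean(t2) / bpMean(t1) - 0.5), 0.1)
})

test_that("the one-pathway MLE recovers exponential data as shape 1", {
  set.seed(1)
  f <- fitGammaOnePathway(stats::rexp(10000, 0.02))
  expect_lt(abs(f@shape - 1), 0.03)
  expect_true(f@converged)
  expect_true(is.finite(f@logLik))
})

test_that("the one-pathway MLE matches a grid-search oracle", {
  set.seed(2)
  d <- stats::rgamma(200, shape = 3, rate = 0.06)
  grid <- seq(0.2, 10, by = 0.001)
  ll <- vapply(grid, function(sh)
    sum(stats::dgamma(d, sh, sh / mean(d), log = TRUE)), numeric(1))
  oracle <- grid[which.max(ll)]
  f <- fitGammaOnePathway(d)
  expect_lt(abs(f@shape - oracle), 2e-3)
})

test_that("the one-pathway MLE agrees with an independent fitter", {
  skip_if_not_installed("MASS")
  set.seed(3)
  d <- stats::rgamma(500, shape = 1.8, rate = 0.04)
  f <- fitGammaOnePathway(d)
  m <- MASS::fitdistr(d, "gamma")
  expect_lt(abs(f@shape - m$estimate[["shape"]]), 1e-2)
  expect_lt(abs(f@rate - m$estimate[["rate"]]), 1e-3)
})

test_that("gamma fitting rejects degenerate inputs", {
  expect_error(fitGammaOnePathway(5), "at least 2")
  expect_error(fitGammaOnePathway(c(1, -2, 3)), "positive")
  expect_error(fitGammaTwoPathway(c(2, 0)), "positive")
})

test_that("EM log-likelihood is monotone and reduces to one pathway", {
  set.seed(4)
  d <- c(stats::rgamma(800, 3, 0.06), stats::rgamma(400, 1, 0.02))
  fit <- fitGammaTwoPathway(d, nRestarts = 2, seed = 7)
  expect_false(is.unsorted(fit@logLikTrace))

  dPure <- stats::rgamma(2000, 3, 0.06)
  one <- fitGammaOnePathway(dPure)
  two <- fitGammaTwoPathway(dPure,
                            init = list(p = 1 - 1e-7, shape1 = one@shape,
                                        rate1 = one@rate, rate2 = 0.02))
  expect_true(two@degenerate)
  expect_lt(abs(two@shape1 - one@shape), 1e-3)
})

test_that("CoC is 1 for independent bins and 0 without observed doubles", {
  g <- GenomeMap("chrA", 50000L, 25000L)   # exactly two 25 kb bins
  mkEvents <- function(tetradsBin1, tetradsBin2) {
    rbind(
      do.call(rbind, lapply(tetradsBin1, function(i)
        truthRow(sprintf("t%03d", i), "chrA", "CO", 10000, 10000, "1,3"))),
      do.call(rbind, lapply(tetradsBin2, function(i)
        truthRow(sprintf("t%03d", i), "chrA", "CO", 40000, 40000, "1,3"))))
  }
  # p1 = p2 = 0.5 with independence: observed doubles = n/4 -> CoC = 1
  ev <- mkEvents(1:20, 11:30)
  prof <- cocProfile(ev, g, nTetrads = 40)
  adj <- prof@table[prof@table$separation_kb == 0, ]
  expect_equal(adj$coc, 1)
  expect_equal(adj$observed, 10)
  expect_equal(adj$expected, 10)
  expect_equal(prof@interferenceAdjacent, 0)

  # disjoint tetrad sets: zero observed doubles -> CoC 0, interference 1
  ev2 <- mkEvents(1:20, 21:40)
  prof2 <- cocProfile(ev2, g, nTetrads = 40)
  expect_equal(prof2@table$coc[prof2@table$separation_kb == 0], 0)
  expect_equal(prof2@interferenceAdjacent, 1)

  expect_error(cocProfile(ev[0, ], g, 40), "undefined")
})

test_that("the adjacent-class chi-square distinguishes profiles", {
  mkProf <- function(obs, expd) {
    new("CoCProfile", binSize = 25000, nTetrads = 100L,
        table = data.frame(separation_kb = 0, coc = obs / expd,
                           observed = obs, expected = expd, n_pairs = 50L),
        interferenceAdjacent = 1 - obs / expd)
  }
  same <- cocChisq(mkProf(40, 80), mkProf(40, 80))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  diff <- cocChisq(mkProf(20, 80), mkProf(75, 80))
  expect_lt(diff$p.value, 1e-6)
  # doubling all counts roughly doubles the statistic
  small <- cocChisq(mkProf(30, 60), mkProf(45, 60))
  big <- cocChisq(mkProf(60, 120), mkProf(90, 120))
  expect_lt(abs(big$statistic / small$statistic - 2), 0.2)
  expect_warning(cocChisq(mkProf(0.4, 0.5), mkProf(0.3, 0.5)), "Fisher")
})

test_that("adjacent crossover pairs classify by shared chromatids", {
  ev <- rbind(truthRow("t1", "chrA", "CO", 100000, 100000, "1,3"),
              truthRow("t1", "chrA", "CO", 300000, 300000, "1,3"),
              truthRow("t1", "chrA", "CO", 500000, 500000, "1,4"),
              truthRow("t1", "chrA", "CO", 700000, 700000, "2,3"))
  ci <- chromatidInterference(ev, minPairs = 1)
  expect_equal(unname(ci$counts),
               c(1L, 1L, 1L))  # 2-strand, 3-strand, 4-strand
  # a perfect 1:2:1 sample gives statistic 0, p = 1
  mk121 <- function() {
    rows <- list()
    id <- 0
    add <- function(a, b) {
      id <<- id + 1
      rbind(truthRow(sprintf("t%d", id), "chrA", "CO", 1e5, 1e5, a),
            truthRow(sprintf("t%d", id), "chrA", "CO", 3e5, 3e5, b))
    }
    rbind(do.call(rbind, replicate(25, add("1,3", "1,3"), simplify = FALSE)),
          do.call(rbind, replicate(50, add("1,3", "1,4"), simplify = FALSE)),
          do.call(rbind, replicate(25, add("1,3", "2,4"), simplify = FALSE)))
  }
  ci2 <- chromatidInterference(mk121())
  expect_equal(unname(ci2$counts), c(25L, 50L, 25L))
  expect_equal(ci2$statistic, 0)
  expect_equal(ci2$p.value, 1)
  # below the minimum pair count the test is suppressed
  ci3 <- chromatidInterference(ev, minPairs = 10)
  expect_true(is.na(ci3$p.value))
})

test_that("interference estimates are invariant to spore relabelling", {
  g <- toyGenome()
  p <- simParams(g, totalCo = 8, totalNco = 0, coGcProb = 0,
                 markerCount = 3000, gammaShape = 2)
  sim <- simulateTetrads(g, p, nTetrads = 30, seed = 17)
  res <- callTetrads(sim$tetrads)
  perm <- c(3L, 1L, 4L, 2L)
  permuted <- lapply(sim$tetrads, function(tt) {
    new("TetradGenotypes", tetradId = tt@tetradId,
        positions = tt@positions,
        genotypes = lapply(tt@genotypes, function(m) m[perm, ]))
  })
  resP <- callTetrads(permuted)
  expect_equal(sum(resP$events$class == "CO"),
               sum(res$events$class == "CO"))
  d <- sort(intercrossoverDistancesCM(res$events, g, nTetrads = 30))
  dP <- sort(intercrossoverDistancesCM(resP$events, g, nTetrads = 30))
  expect_equal(d, dP)
})
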