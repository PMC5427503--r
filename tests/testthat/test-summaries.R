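## Build a per-tetrad/chromosome summary data.frame from count matrices.
summaryFromCounts <- function(coMat, ncoMat = NULL) {
  if (is.null(ncoMat)) ncoMat <- coMat * 0L
  n <- nrow(coMat)
  do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(tetrad_id = sprintf("t%04d", i), chrom = colnames(coMat),
               co = coMat[i, ], nco = ncoMat[i, ], e0 = coMat[i, ] == 0L,
               row.names = NULL, stringsAsFactors = FALSE)))
}

test_that("identical datasets give null per-chromosome comparisons", {
  g <- toyGenome()
  p <- simParams(g, totalCo = 6, totalNco = 3)
  co <- simulateMeiosisCounts(g, p, 10, seed = 1)
  s <- summaryFromCounts(co, co)
  tab <- perChromosomeTable(s, s)
  expect_true(all(tab$co_p == 1))
  expect_true(all(tab$nco_p == 1))
  expect_false(any(tab$co_sig))
  expect_equal(tab$co_mean, tab$co_mean_ref)
})

test_that("a halved chromosome rate is flagged with high power", {
  g <- sgdGenome()
  pFull <- simParams(g, totalCo = 93.4, gammaShape = 1)
  lamHalf <- meanCoPerChrom(pFull)
  lamHalf["chrIV"] <- lamHalf["chrIV"] / 2
  pHalf <- simParams(g, meanCoPerChrom = lamHalf, gammaShape = 1)
  hits <- vapply(1:20, function(r) {
    a <- summaryFromCounts(simulateMeiosisCounts(g, pHalf, 20,
                                                 seed = 100 + r))
    b <- summaryFromCounts(simulateMeiosisCounts(g, pFull, 20,
                                                 seed = 300 + r))
    tab <- perChromosomeTable(a, b)
    tab$co_sig[tab$chrom == "chrIV"]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # and the simulated means track the configured rates
  big <- summaryFromCounts(simulateMeiosisCounts(g, pFull, 400, seed = 9))
  m <- tapply(big$co, big$chrom, mean)
  expect_lt(max(abs(m[names(lamHalf)] - meanCoPerChrom(pFull))), 0.6)
})

test_that("CO-NCO correlation separates coupled from independent processes", {
  chroms <- c("chrA", "chrB")
  ident <- data.frame(tetrad_id = rep(sprintf("t%03d", 1:30), each = 2),
                      chrom = rep(chroms, 30),
                      co = rep(3:32, each = 2), nco = rep(3:32, each = 2),
                      e0 = FALSE)
  r1 <- coNcoCorrelation(ident)
  expect_equal(r1$r, 1)

  set.seed(12)
  n <- 1000
  indep <- data.frame(tetrad_id = sprintf("t%04d", 1:n), chrom = "chrA",
                      co = rpois(n, 90), nco = rpois(n, 45), e0 = FALSE)
  expect_lt(abs(coNcoCorrelation(indep)$r), 0.1)

  # shared initiating events: thinning an overdispersed DSB count couples
  # the two outcomes (thinning a plain Poisson would leave them exactly
  # independent by Poisson splitting)
  N <- rnbinom(n, size = 5, mu = 150)
  coupled <- data.frame(tetrad_id = sprintf("t%04d", 1:n), chrom = "chrA",
                        co = rbinom(n, N, 0.6), nco = 0L, e0 = FALSE)
  coupled$nco <- N - coupled$co
  expect_gt(coNcoCorrelation(coupled)$r, 0.5)
  expect_error(coNcoCorrelation(indep[1:2, ]), ">= 3")
})

test_that("density-vs-length detects small-chromosome excess", {
  g <- sgdGenome()
  L <- chromLengths(g)
  # equal density: lambda proportional to length -> no correlation signal
  pEq <- simParams(g, meanCoPerChrom = 93.4 * L / sum(L), gammaShape = 1)
  sEq <- summaryFromCounts(simulateMeiosisCounts(g, pEq, 66, seed = 4))
  dEq <- densityVsLength(sEq, g)
  expect_lt(abs(dEq$r), 0.5)

  # sub-linear allocation: small chromosomes denser -> negative correlation
  w <- L^0.7 / sum(L^0.7)
  pSub <- simParams(g, meanCoPerChrom = 93.4 * w, gammaShape = 1)
  hits <- vapply(1:10, function(r) {
    s <- summaryFromCounts(simulateMeiosisCounts(g, pSub, 66,
                                                 seed = 500 + r))
    d <- densityVsLength(s, g)
    d$r < 0 && d$p.value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)

  sSub <- summaryFromCounts(simulateMeiosisCounts(g, pSub, 66, seed = 511))
  dEx <- densityVsLength(sSub, g,
                         excludeChroms = c("chrI", "chrIII", "chrVI"))
  expect_equal(dEx$n, 13)
  expect_error(densityVsLength(sSub, g,
                               excludeChroms = chromNames(g)[1:13]),
               ">= 4")
})

test_that("feature proximity profiles conserve counts and see vetoes", {
  g <- toyGenome()
  set.seed(6)
  n <- 400
  ev <- data.frame(tetrad_id = "t1", chrom = "chrA", class = "CO",
                   start = NA, end = NA,
                   midpoint = runif(n, 1, chromLengths(g)["chrA"]))
  ev$start <- ev$end <- ev$midpoint
  prof <- featureProximityProfile(ev, g, nTetrads = 10, "telomere",
                                  binKb = 10, maxKb = 80)
  inRange <- sum(pmin(ev$midpoint - 1,
                      chromLengths(g)["chrA"] - ev$midpoint) < 80000)
  expect_equal(sum(prof$count), inRange)

  # events kept away from chromosome ends leave the profile empty
  evMid <- ev
  evMid$midpoint <- runif(n, 100000, chromLengths(g)["chrA"] - 100000)
  profV <- featureProximityProfile(evMid, g, nTetrads = 10, "telomere")
  expect_true(all(profV$count == 0))

  profC <- featureProximityProfile(ev, g, nTetrads = 10, "centromere")
  expect_true(all(profC$density >= 0))
  expect_error(featureProximityProfile(ev, g, 10, "telomere", binKb = 0),
               "positive")
})

test_that("tract-length statistics compare datasets and count long tracts", {
  mkEv <- function(lens, class = "NCO", assoc = FALSE) {
    data.frame(tetrad_id = "t1", chrom = "chrA",
               class = class, start = 1, end = 1 + lens, midpoint = 1,
               chromatids = "1", gc_type = 0L, co_associated = assoc,
               direction = 0L, tract_start = 1, tract_end = 1 + lens,
               tract_min = lens, tract_mid = lens, tract_max = lens)
  }
  set.seed(7)
  drawGeom <- function(n, med) rgeom(n, 1 - 2^(-1 / med)) + 1
  a <- mkEv(drawGeom(600, 1700))
  b <- mkEv(drawGeom(600, 2200))
  same <- tractLengthStats(a, a, "nco")
  expect_gt(same$p.value, 0.99)
  hits <- vapply(1:10, function(r) {
    set.seed(700 + r)
    tractLengthStats(mkEv(drawGeom(600, 1700)),
                     mkEv(drawGeom(600, 2200)), "nco")$p.value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)

  short <- mkEv(rep(500, 50))
  expect_equal(tractLengthStats(short, short, "nco")$longFracA, 0)
  co <- mkEv(rep(5000, 20), class = "CO", assoc = TRUE)
  expect_equal(tractLengthStats(co, NULL, "co")$longFracA, 1)
  expect_error(tractLengthStats(short, NULL, "co"), "co")
})

test_that("segregation ratios sum to 100 and reflect tract coverage", {
  pos <- as.integer(seq(1000, 100000, by = 1000))   # 100 markers
  g22 <- matrix(c(0L, 0L, 1L, 1L), 4, length(pos))
  clean <- makeTetrad(pos, g22)
  tabClean <- segregationRatioTable(list(clean))
  expect_equal(unname(tabClean["2:2"]), 100)

  gConv <- g22
  gConv[1, 11:20] <- 1L          # 10 markers 1:3
  gConv[3, 51:55] <- 0L          # 5 markers 3:1
  gConv[2, 99] <- NA             # 1 missing
  mixed <- makeTetrad(pos, gConv)
  tab <- segregationRatioTable(list(mixed))
  expect_equal(sum(tab), 100)
  expect_equal(unname(tab["1:3"]), 10)
  expect_equal(unname(tab["3:1"]), 5)
  expect_equal(unname(tab["missing"]), 1)
  expect_equal(unname(tab["2:2"]), 84)

  # simulated tract coverage: non-2:2 share matches the truth tables
  rt <- wtRoundTrip()
  tabSim <- segregationRatioTable(rt$sim$tetrads[1:25])
  truth <- rt$sim$truth
  truth <- truth[truth$tetrad_id %in% sprintf("t%04d", 1:25), ]
  tracts <- truth[truth$class %in% c("CO_GC", "NCO"), ]
  nMark <- sum(lengths(rt$sim$markers))
  covered <- 0
  for (i in seq_len(nrow(tracts))) {
    mk <- rt$sim$markers[[tracts$chrom[i]]]
    covered <- covered + sum(mk >= tracts$start[i] & mk <= tracts$end[i])
  }
  expectedNon22 <- 100 * covered / (nMark * 25)
  non22 <- 100 - tabSim["2:2"]
  expect_lt(abs(non22 - expectedNon22), 0.35 * expectedNon22)
})
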