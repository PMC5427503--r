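## Shared fixtures: a small 3-chromosome toy genome, hand-built tetrads, and
## a memoized cache so expensive simulations are generated once per run.

toyGenome <- function() {
  GenomeMap(chrom = c("chrA", "chrB", "chrC"),
            length = c(1000000L, 800000L, 500000L),
            centromere = c(500000L, 300000L, 200000L))
}

oneChromGenome <- function(len = 10000000L) {
  GenomeMap(chrom = "chrA", length = len, centromere = as.integer(len / 2))
}

## Hand-built single-chromosome tetrad from a genotype matrix.
makeTetrad <- function(pos, g, chrom = "chrA", id = "tx") {
  new("TetradGenotypes", tetradId = id,
      positions = stats::setNames(list(as.integer(pos)), chrom),
      genotypes = stats::setNames(list(g), chrom))
}

## A truth-table row in the simulator's format.
truthRow <- function(id, chrom, class, start, end, chromatids,
                     coIndex = NA_integer_) {
  data.frame(tetrad_id = id, chrom = chrom, class = class, start = start,
             end = end, chromatids = chromatids, pathway = NA_integer_,
             direction = NA_integer_, co_index = coIndex,
             stringsAsFactors = FALSE)
}

.fixtureCache <- new.env(parent = emptyenv())
cachedFixture <- function(name, expr) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, expr, envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

## Wild-type-like full round-trip dataset shared by caller and acceptance
## tests (200 tetrads, full marker density).
wtRoundTrip <- function() {
  cachedFixture("wtRoundTrip", {
    g <- sgdGenome()
    p <- presetParams("wild_type", g, nTetrads = 200)
    sim <- simulateTetrads(g, p, seed = 1)
    called <- callTetrads(sim$tetrads)
    list(sim = sim, called = called, genome = g)
  })
}

## Truth-level Poisson-placement dataset (no interference), 2000 meioses.
poissonTruth <- function() {
  cachedFixture("poissonTruth", {
    g <- sgdGenome()
    p <- simParams(g, totalCo = 93.4, gammaShape = 1, classIFraction = 1,
                   totalNco = 0, coGcProb = 0)
    list(truth = simulateTruth(g, p, nTetrads = 2000, seed = 1),
         genome = g, n = 2000L)
  })
}

## Mark a true crossover resolvable when at least one informative 2:2
## marker separates it from every neighbouring event boundary on its
## tetrad/chromosome (markers inside any conversion tract are non-2:2).
resolvableCos <- function(truth, markers) {
  co <- truth[truth$class == "CO", , drop = FALSE]
  ok <- logical(nrow(co))
  for (i in seq_len(nrow(co))) {
    sub <- truth[truth$tetrad_id == co$tetrad_id[i] &
                 truth$chrom == co$chrom[i], , drop = FALSE]
    b <- co$start[i]
    own <- sub$class == "CO" & sub$co_index == co$co_index[i] &
           !is.na(sub$co_index)
    tract <- sub$class == "CO_GC" & sub$co_index == co$co_index[i] &
             !is.na(sub$co_index)
    lo <- b; hi <- b
    if (any(tract)) { lo <- min(lo, sub$start[tract]); hi <- max(hi, sub$end[tract]) }
    oth <- sub[!(own | tract), , drop = FALSE]
    leftLim <- suppressWarnings(max(-Inf, oth$end[oth$end <= b],
                                    oth$start[oth$start <= b]))
    rightLim <- suppressWarnings(min(Inf, oth$start[oth$start >= b],
                                     oth$end[oth$end >= b]))
    mk <- markers[[co$chrom[i]]]
    ok[i] <- any(mk > leftLim & mk < lo) && any(mk > hi & mk < rightLim)
  }
  co$resolvable <- ok
  co
}
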