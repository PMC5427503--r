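## Synthetic tetrad generator: gamma-renewal (Class I) + Poisson (Class II)
## crossovers, geometric gene-conversion tracts, uniform nonsister chromatid
## choice. Chromatids 1,2 are sisters carrying allele 0 (S288c); 3,4 carry
## allele 1 (YJM789).

.NONSISTER_PAIRS <- list(c(1L, 3L), c(1L, 4L), c(2L, 3L), c(2L, 4L))

#' Place SNP markers along a genome
#'
#' Markers are allocated to chromosomes proportionally to physical length
#' (largest-remainder rounding, at least 2 per chromosome) and placed
#' uniformly at random, sorted and unique within each chromosome.
#'
#' @param genome a [GenomeMap-class].
#' @param markerCount total number of markers (>= 2 per chromosome; at least
#'   32 for the 16-chromosome genome).
#' @param seed integer seed; the map is deterministic given (genome,
#'   markerCount, seed).
#' @return named list (by chromosome) of sorted integer positions.
#' @examples
#' m <- buildMarkerMap(sgdGenome(), 1000, seed = 1)
#' lengths(m)
#' @export
buildMarkerMap <- function(genome, markerCount, seed = 1L) {
  nChrom <- length(chromNames(genome))
  if (markerCount < 2L * nChrom)
    stop("markerCount must allow at least 2 markers per chromosome")
  L <- as.numeric(chromLengths(genome))
  names(L) <- chromNames(genome)
  ## 2 markers per chromosome first, the rest proportional to length
  ## (largest-remainder rounding), so the total is exactly markerCount
  rem <- markerCount - 2L * nChrom
  frac <- rem * L / sum(L)
  extra <- floor(frac)
  deficit <- rem - sum(extra)
  if (deficit > 0) {
    ord <- order(frac - extra, decreasing = TRUE)
    for (i in rep_len(ord, deficit)) extra[i] <- extra[i] + 1L
  }
  n <- 2L + extra
  set.seed(as.integer(seed))
  out <- lapply(seq_len(nChrom), function(i)
    sort(sample.int(L[i], n[i], replace = FALSE)))
  names(out) <- chromNames(genome)
  out
}

## Geometric tract lengths (bp) with configured median, support >= 1.
.drawTractLengths <- function(n, medianBp) {
  p <- 1 - 2^(-1 / medianBp)
  stats::rgeom(n, p) + 1L
}

## Stationary gamma renewal positions on [0, G] (genetic scale, cM).
## First inter-event distance from the equilibrium residual distribution
## (U * length-biased interval) so event density is uniform along the
## chromosome; subsequent gaps are Gamma(shape, rate).
.renewalPositions <- function(G, shape, rate) {
  if (G <= 0) return(numeric(0))
  pos <- numeric(0)
  x <- stats::runif(1) * stats::rgamma(1, shape + 1, rate)
  while (x <= G) {
    pos <- c(pos, x)
    x <- x + stats::rgamma(1, shape, rate)
  }
  pos
}

#' Simulate the true recombination events of one meiosis
#'
#' Class I crossovers are placed by a stationary gamma renewal process on the
#' genetic scale (shape nu, rate chosen so the per-chromosome mean count is
#' p * lambda_c); Class II crossovers by a homogeneous Poisson process with
#' mean (1 - p) * lambda_c. The genetic length of a chromosome is
#' 50 * lambda_c cM with uniform cM/bp. Crossover chromatid pairs are drawn
#' uniformly from the four nonsister combinations, independently per
#' crossover (no chromatid interference). Noncrossover tracts are
#' Poisson-per-chromosome with geometric lengths.
#'
#' @param genome a [GenomeMap-class].
#' @param params a [SimParams-class].
#' @param tetradId identifier stored in the truth rows.
#' @return data.frame of true events with columns tetrad_id, chrom, class
#'   ("CO", "CO_GC", "NCO", "GC"), start, end (bp; start == end for a
#'   crossover breakpoint), chromatids (comma string), pathway (1 interfering
#'   / 2 noninterfering, crossovers only), direction (allele gained,
#'   conversions only), co_index (links a CO_GC tract to its crossover).
#'   Uses the current RNG state; seed at the dataset level.
#' @export
simulateMeiosis <- function(genome, params, tetradId = "t001") {
  rows <- list()
  lambda <- params@meanCoPerChrom
  ncoRate <- params@ncoRatePerChrom
  p <- params@classIFraction
  nu <- params@gammaShape
  L <- chromLengths(genome)
  for (chrom in chromNames(genome)) {
    lam <- lambda[[chrom]]
    G <- 50 * lam                       # genetic length, cM
    cmPerBp <- if (lam > 0) G / L[[chrom]] else 0
    ## crossovers ---------------------------------------------------------
    cm1 <- if (lam > 0 && p > 0)
      .renewalPositions(G, nu, nu * p / 50) else numeric(0)
    n2 <- if (lam > 0 && p < 1) stats::rpois(1, (1 - p) * lam) else 0L
    cm2 <- stats::runif(n2, 0, G)
    cm <- sort(c(cm1, cm2))
    pathway <- c(rep(1L, length(cm1)), rep(2L, length(cm2)))[
      order(c(cm1, cm2))]
    bp <- if (lam > 0) pmax(1, pmin(L[[chrom]], round(cm / cmPerBp)))
          else numeric(0)
    ## de-duplicate breakpoints that round to the same bp (invariant:
    ## no two COs share an identical breakpoint)
    if (anyDuplicated(bp)) {
      keep <- !duplicated(bp)
      bp <- bp[keep]; pathway <- pathway[keep]
    }
    nCo <- length(bp)
    if (nCo > 0) {
      pairIdx <- sample.int(4L, nCo, replace = TRUE)
      pairMat <- matrix(unlist(.NONSISTER_PAIRS[pairIdx]), nrow = 2L)
      rows[[length(rows) + 1L]] <- data.frame(
        tetrad_id = tetradId, chrom = chrom, class = "CO",
        start = bp, end = bp,
        chromatids = paste(pairMat[1L, ], pairMat[2L, ], sep = ","),
        pathway = pathway, direction = NA_integer_,
        co_index = seq_len(nCo), stringsAsFactors = FALSE)
      hasTract <- stats::runif(nCo) < params@coGcProb
      if (any(hasTract)) {
        nT <- sum(hasTract)
        len <- .drawTractLengths(nT, params@coGcTractMedianBp)
        side <- sample(c(-1L, 1L), nT, replace = TRUE)
        b <- bp[hasTract]
        tStart <- ifelse(side > 0, b, pmax(1, b - len))
        tEnd <- ifelse(side > 0, pmin(L[[chrom]], b + len), b)
        donor <- ifelse(stats::runif(nT) < 0.5, pairMat[1L, hasTract],
                        pairMat[2L, hasTract])
        rows[[length(rows) + 1L]] <- data.frame(
          tetrad_id = tetradId, chrom = chrom, class = "CO_GC",
          start = tStart, end = tEnd, chromatids = as.character(donor),
          pathway = pathway[hasTract], direction = NA_integer_,
          co_index = which(hasTract), stringsAsFactors = FALSE)
      }
    }
    ## noncrossover tracts -------------------------------------------------
    nNco <- stats::rpois(1, ncoRate[[chrom]])
    if (nNco > 0) {
      len <- .drawTractLengths(nNco, params@ncoGcTractMedianBp)
      start <- pmax(1, round(stats::runif(nNco, 1, L[[chrom]]) - len / 2))
      end <- pmin(L[[chrom]], start + len)
      chromatid <- sample.int(4L, nNco, replace = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        tetrad_id = tetradId, chrom = chrom, class = "NCO",
        start = start, end = end, chromatids = as.character(chromatid),
        pathway = NA_integer_, direction = NA_integer_,
        co_index = NA_integer_, stringsAsFactors = FALSE)
    }
    ## optional complex (two-chromatid) conversions ------------------------
    if (params@complexRate > 0) {
      nCx <- stats::rpois(1, params@complexRate / length(chromNames(genome)))
      if (nCx > 0) {
        len <- .drawTractLengths(nCx, params@ncoGcTractMedianBp)
        start <- pmax(1, round(stats::runif(nCx, 1, L[[chrom]]) - len / 2))
        end <- pmin(L[[chrom]], start + len)
        for (k in seq_len(nCx)) {
          pair <- .NONSISTER_PAIRS[[sample.int(4L, 1L)]]
          rows[[length(rows) + 1L]] <- data.frame(
            tetrad_id = tetradId, chrom = chrom, class = "GC",
            start = start[k], end = end[k],
            chromatids = paste(pair, collapse = ","),
            pathway = NA_integer_, direction = NA_integer_,
            co_index = NA_integer_, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows))
    return(.emptyTruth())
  do.call(rbind, rows)
}

.emptyTruth <- function() {
  data.frame(tetrad_id = character(0), chrom = character(0),
             class = character(0), start = numeric(0), end = numeric(0),
             chromatids = character(0), pathway = integer(0),
             direction = integer(0), co_index = integer(0),
             stringsAsFactors = FALSE)
}

#' Simulate the truth tables of many meioses
#'
#' @inheritParams simulateMeiosis
#' @param nTetrads number of meioses; defaults to `params@nTetrads`.
#' @param seed integer seed; the result is bit-reproducible given
#'   (genome, params, seed).
#' @return combined truth data.frame (see [simulateMeiosis()]).
#' @export
simulateTruth <- function(genome, params, nTetrads = NULL, seed = 1L) {
  if (is.null(nTetrads)) nTetrads <- params@nTetrads
  set.seed(as.integer(seed))
  out <- lapply(seq_len(nTetrads), function(i)
    simulateMeiosis(genome, params, sprintf("t%04d", i)))
  do.call(rbind, out)
}

#' Vectorized per-chromosome crossover count sampler
#'
#' Draws realized crossover counts per chromosome for many meioses using the
#' same stationary-renewal construction as [simulateMeiosis()] (equilibrium
#' first gap, gamma subsequent gaps) plus the Poisson Class II component, but
#' without positions or chromatids. Used for Monte-Carlo calibration of the
#' obligate-crossover model.
#'
#' @inheritParams simulateMeiosis
#' @param nMeioses number of meioses.
#' @param seed integer seed.
#' @return integer matrix nMeioses x nChrom of crossover counts.
#' @export
simulateMeiosisCounts <- function(genome, params, nMeioses, seed = 1L) {
  set.seed(as.integer(seed))
  lambda <- params@meanCoPerChrom
  p <- params@classIFraction
  nu <- params@gammaShape
  counts <- matrix(0L, nrow = nMeioses, ncol = length(lambda),
                   dimnames = list(NULL, names(lambda)))
  for (j in seq_along(lambda)) {
    lam <- lambda[[j]]
    if (lam <= 0) next
    G <- 50 * lam
    nI <- integer(nMeioses)
    if (p > 0) {
      rate <- nu * p / 50
      m <- lam * p
      k <- ceiling(m + 10 * sqrt(m + 1) + 10)   # gap budget, ample w.h.p.
      cum <- stats::runif(nMeioses) * stats::rgamma(nMeioses, nu + 1, rate)
      nI <- as.integer(cum <= G)
      for (step in seq_len(k - 1L)) {
        alive <- cum <= G
        if (!any(alive)) break
        cum[alive] <- cum[alive] +
          stats::rgamma(sum(alive), nu, rate)
        nI <- nI + as.integer(cum <= G)
      }
    }
    nII <- if (p < 1) stats::rpois(nMeioses, (1 - p) * lam) else 0L
    counts[, j] <- nI + nII
  }
  counts
}

#' Render a tetrad's genotypes from its true events
#'
#' Each chromatid's genotype along the chromosome is determined by its
#' crossover history (reciprocal exchange of the two crossover chromatids
#' distal to each breakpoint); markers inside a conversion tract on a
#' chromatid take the donor (homolog) genotype. All other markers segregate
#' 2:2.
#'
#' @param truth truth data.frame for one tetrad (see [simulateMeiosis()]).
#' @param markers marker map from [buildMarkerMap()].
#' @param genome a [GenomeMap-class].
#' @param tetradId identifier; defaults to the one in `truth`.
#' @return A [TetradGenotypes-class].
#' @export
renderTetrad <- function(truth, markers, genome, tetradId = NULL) {
  if (is.null(tetradId))
    tetradId <- if (nrow(truth)) truth$tetrad_id[1] else "t001"
  positions <- genotypes <- list()
  for (chrom in chromNames(genome)) {
    pos <- markers[[chrom]]
    ev <- truth[truth$chrom == chrom, , drop = FALSE]
    cos <- ev[ev$class == "CO", , drop = FALSE]
    if (anyDuplicated(cos$start))
      stop("overlapping crossover breakpoints at identical bp on ", chrom)
    cos <- cos[order(cos$start), , drop = FALSE]
    ## Each spore strand reads one parental chromatid at any position
    ## (perm: strand -> chromatid); a crossover between parental
    ## chromatids (a, b) swaps the futures of the two strands currently
    ## reading a and b. A strand's allele is 0 while it reads chromatid
    ## 1 or 2, else 1.
    nCo <- nrow(cos)
    perm <- 1:4
    permStates <- matrix(0L, 4, nCo + 1L)  # state after k-th crossover
    permStates[, 1L] <- perm
    if (nCo > 0) {
      for (k in seq_len(nCo)) {
        chromatids <- as.integer(strsplit(cos$chromatids[k], ",")[[1]])
        sa <- which(perm == chromatids[1])
        sb <- which(perm == chromatids[2])
        perm[c(sa, sb)] <- perm[c(sb, sa)]
        permStates[, k + 1L] <- perm
      }
    }
    breaks <- c(-Inf, cos$start, Inf)
    seg <- findInterval(pos, breaks, left.open = TRUE)  # 1 .. nCo+1
    g <- matrix(0L, 4, length(pos))
    for (k in seq_len(nCo + 1L)) {
      idx <- seg == k
      if (!any(idx)) next
      g[, idx] <- ifelse(permStates[, k] <= 2L, 0L, 1L)
    }
    ## conversion tracts: the converted parental chromatid's reading
    ## strand (at the tract midpoint) takes the donor (homolog) genotype
    tracts <- ev[ev$class %in% c("CO_GC", "NCO", "GC"), , drop = FALSE]
    if (nrow(tracts)) {
      for (k in seq_len(nrow(tracts))) {
        state <- findInterval((tracts$start[k] + tracts$end[k]) / 2,
                              breaks, left.open = TRUE)
        for (cid in as.integer(strsplit(tracts$chromatids[k], ",")[[1]])) {
          strand <- which(permStates[, state] == cid)
          idx <- pos >= tracts$start[k] & pos <= tracts$end[k]
          g[strand, idx] <- 1L - g[strand, idx]
        }
      }
    }
    positions[[chrom]] <- pos
    genotypes[[chrom]] <- g
  }
  new("TetradGenotypes", tetradId = tetradId, positions = positions,
      genotypes = genotypes)
}

#' Simulate a full tetrad dataset
#'
#' Generates a marker map, the per-meiosis truth tables, and the rendered
#' four-spore genotype tables of `nTetrads` meioses.
#'
#' @inheritParams simulateTruth
#' @return list with elements `tetrads` (list of [TetradGenotypes-class]),
#'   `truth` (data.frame), `markers`, `params` and `genome`.
#' @examples
#' sim <- simulateTetrads(sgdGenome(),
#'   simParams(sgdGenome(), nTetrads = 2, markerCount = 2000), seed = 7)
#' length(sim$tetrads)
#' @export
simulateTetrads <- function(genome, params, nTetrads = NULL, seed = 1L) {
  if (is.null(nTetrads)) nTetrads <- params@nTetrads
  markers <- buildMarkerMap(genome, params@markerCount, seed = seed)
  truth <- simulateTruth(genome, params, nTetrads,
                         seed = as.integer(seed) + 1L)
  ids <- unique(truth$tetrad_id)
  if (length(ids) < nTetrads)       # meioses can be event-free
    ids <- sprintf("t%04d", seq_len(nTetrads))
  tetrads <- lapply(ids, function(id)
    renderTetrad(truth[truth$tetrad_id == id, , drop = FALSE],
                 markers, genome, tetradId = id))
  names(tetrads) <- ids
  list(tetrads = tetrads, truth = truth, markers = markers,
       params = params, genome = genome)
}
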