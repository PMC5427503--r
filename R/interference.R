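## Crossover interference statistics: one-pathway gamma MLE, two-pathway
## gamma-mixture EM (Class II shape fixed at 1), coefficient of coincidence
## on genome bins, and the chromatid-interference test.

#' Per-chromosome mean crossover counts of a dataset
#'
#' @param events event (or truth) table with columns chrom and class.
#' @param nTetrads number of meioses in the dataset.
#' @param genome a [GenomeMap-class].
#' @return named numeric of mean crossovers per chromosome per meiosis.
#' @export
observedMeanCo <- function(events, nTetrads, genome) {
  co <- events[events$class == "CO", , drop = FALSE]
  counts <- table(factor(co$chrom, levels = chromNames(genome)))
  stats::setNames(as.numeric(counts) / nTetrads, chromNames(genome))
}

#' Inter-crossover distances in centimorgans
#'
#' Distances between adjacent crossover midpoints on each chromosome of each
#' tetrad, converted from bp to cM with a uniform per-chromosome scale of
#' (50 * mean crossover count of that chromosome in this genotype) cM over
#' the chromosome's physical length -- so genotypes with different crossover
#' frequencies are compared on a common genetic scale.
#'
#' @param events event table (class == "CO" rows are used; midpoints from
#'   the `midpoint` column or (start + end) / 2).
#' @param genome a [GenomeMap-class].
#' @param nTetrads number of meioses (used when `meanCo` is NULL).
#' @param meanCo optional named per-chromosome mean crossover counts;
#'   defaults to [observedMeanCo()] on `events`.
#' @return numeric vector of pooled distances (cM). Chromosomes with zero
#'   mean crossovers are excluded with a warning.
#' @export
intercrossoverDistancesCM <- function(events, genome, nTetrads = NULL,
                                      meanCo = NULL) {
  if (is.null(meanCo)) {
    if (is.null(nTetrads))
      stop("supply nTetrads or meanCo")
    meanCo <- observedMeanCo(events, nTetrads, genome)
  }
  co <- events[events$class == "CO", , drop = FALSE]
  if (!nrow(co)) return(numeric(0))
  mid <- if ("midpoint" %in% names(co)) co$midpoint
         else (co$start + co$end) / 2
  L <- chromLengths(genome)
  zeroChrom <- names(meanCo)[meanCo <= 0 &
                             names(meanCo) %in% unique(co$chrom)]
  if (length(zeroChrom))
    warning("excluding chromosomes with zero mean crossover count: ",
            paste(zeroChrom, collapse = ", "))
  keep <- meanCo[co$chrom] > 0
  co <- co[keep, , drop = FALSE]
  mid <- mid[keep]
  cmPerBp <- 50 * meanCo[co$chrom] / L[co$chrom]
  cm <- mid * cmPerBp
  grp <- paste(co$tetrad_id, co$chrom)
  unlist(lapply(split(cm, grp), function(x)
    if (length(x) >= 2L) diff(sort(x)) else numeric(0)),
    use.names = FALSE)
}

## Gamma shape MLE: solve log(shape) - digamma(shape) = s on the log scale.
.solveGammaShape <- function(s) {
  if (!is.finite(s) || s <= 0)
    return(list(shape = NA_real_, converged = FALSE))
  f <- function(lsh) {
    sh <- exp(lsh)
    log(sh) - digamma(sh) - s
  }
  sol <- tryCatch(stats::uniroot(f, c(log(1e-4), log(1e6)),
                                 tol = 1e-12),
                  error = function(e) NULL)
  if (is.null(sol)) list(shape = NA_real_, converged = FALSE)
  else list(shape = exp(sol$root), converged = TRUE)
}

#' One-pathway gamma interference fit
#'
#' Maximum-likelihood two-parameter gamma fit to inter-crossover distances.
#' The shape solves the digamma score equation numerically; the rate is
#' closed-form given the shape. Shape 1 corresponds to no interference
#' (exponential inter-distances); shape > 1 to positive interference.
#'
#' @param distancesCm positive inter-crossover distances (cM), >= 2 values.
#' @return A [GammaFit-class].
#' @examples
#' set.seed(1)
#' fitGammaOnePathway(rgamma(500, shape = 2, rate = 0.05))
#' @export
fitGammaOnePathway <- function(distancesCm) {
  d <- distancesCm
  if (length(d) < 2L) stop("need at least 2 distances")
  if (any(!is.finite(d)) || any(d <= 0))
    stop("distances must be positive and finite")
  m <- mean(d)
  s <- log(m) - mean(log(d))
  sol <- .solveGammaShape(s)
  if (!sol$converged)
    stop("gamma shape score equation did not converge")
  shape <- sol$shape
  rate <- shape / m
  new("GammaFit", shape = shape, rate = rate,
      nDistances = length(d),
      logLik = sum(stats::dgamma(d, shape, rate, log = TRUE)),
      converged = sol$converged)
}

## One EM run for the two-pathway mixture; returns list or NULL on failure.
.emTwoPathway <- function(d, p0, nu0, r10, r20, tol, maxIter) {
  p <- p0; nu <- nu0; r1 <- r10; r2 <- r20
  trace <- numeric(0)
  degenerate <- FALSE
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    d1 <- p * stats::dgamma(d, nu, r1)
    d2 <- (1 - p) * stats::dgamma(d, 1, r2)
    tot <- d1 + d2
    if (any(tot <= 0) || any(!is.finite(tot))) return(NULL)
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    if (it > 1L && ll - trace[it - 1L] < tol) {
      converged <- TRUE
      break
    }
    w <- d1 / tot
    p <- mean(w)
    if (p < 1e-6 || p > 1 - 1e-6) {
      degenerate <- TRUE
      break
    }
    m1 <- sum(w * d) / sum(w)
    s1 <- log(m1) - sum(w * log(d)) / sum(w)
    sol <- .solveGammaShape(s1)
    if (!is.na(sol$shape)) nu <- sol$shape
    r1 <- nu / m1
    r2 <- sum(1 - w) / sum((1 - w) * d)
  }
  list(p = p, nu = nu, r1 = r1, r2 = r2, trace = trace,
       converged = converged, degenerate = degenerate)
}

#' Two-pathway gamma-mixture interference fit (EM)
#'
#' Fits p * Gamma(nu, rate1) + (1 - p) * Gamma(1, rate2) by
#' expectation-maximization: E-step responsibilities under the two-component
#' density; M-step closed-form for p and the rates, with the Class I shape
#' nu solved from the responsibility-weighted score equation. The Class II
#' shape is fixed at 1 (noninterfering exponential pathway). Initialization
#' is method-of-moments (p0 = 0.5, nu0 from the pooled one-pathway fit) plus
#' `nRestarts` random restarts; the best log-likelihood is kept.
#'
#' @param distancesCm positive inter-crossover distances (cM).
#' @param init optional list(p, shape1, rate1, rate2) initial values.
#' @param tol EM stops when the log-likelihood gain drops below this
#'   (default 1e-8).
#' @param maxIter maximum EM iterations (default 1000).
#' @param nRestarts random restarts in addition to the moment start.
#' @param seed seed for the restarts.
#' @return A [TwoPathwayFit-class]; the log-likelihood trace is
#'   non-decreasing, and a fit whose mixing proportion collapsed to 0 or 1 is
#'   flagged degenerate.
#' @export
fitGammaTwoPathway <- function(distancesCm, init = NULL, tol = 1e-8,
                               maxIter = 1000L, nRestarts = 5L,
                               seed = 1L) {
  d <- distancesCm
  if (length(d) < 2L) stop("need at least 2 distances")
  if (any(!is.finite(d)) || any(d <= 0))
    stop("distances must be positive and finite")
  starts <- list()
  if (!is.null(init)) {
    starts[[1L]] <- list(p = init$p, nu = init$shape1, r1 = init$rate1,
                         r2 = init$rate2)
  } else {
    one <- fitGammaOnePathway(d)
    m <- mean(d)
    starts[[1L]] <- list(p = 0.5, nu = max(one@shape, 1.1),
                         r1 = max(one@shape, 1.1) / m, r2 = 1 / m)
    set.seed(as.integer(seed))
    for (k in seq_len(nRestarts)) {
      nu0 <- stats::runif(1, 1.2, 6)
      starts[[k + 1L]] <- list(p = stats::runif(1, 0.2, 0.8), nu = nu0,
                               r1 = nu0 / m * stats::runif(1, 0.5, 2),
                               r2 = stats::runif(1, 0.5, 2) / m)
    }
  }
  best <- NULL
  for (st in starts) {
    fit <- .emTwoPathway(d, st$p, st$nu, st$r1, st$r2, tol, maxIter)
    if (is.null(fit)) next
    if (is.null(best) ||
        fit$trace[length(fit$trace)] > best$trace[length(best$trace)])
      best <- fit
  }
  if (is.null(best)) stop("EM failed from every start")
  new("TwoPathwayFit", p = best$p, shape1 = best$nu, rate1 = best$r1,
      rate2 = best$r2, nIter = length(best$trace),
      logLikTrace = best$trace, converged = best$converged,
      degenerate = best$degenerate)
}

#' Coefficient-of-coincidence profile on genome bins
#'
#' Partitions each chromosome into `binSize` bins; for each bin the fraction
#' p_i of tetrads with at least one crossover midpoint in it is computed.
#' For every same-chromosome bin pair the observed double-crossover count
#' (tetrads with crossovers in both bins) is compared to the expected count
#' n * p_i * p_j; pairs with zero expected frequency are excluded. Pairs are
#' grouped by the physical gap between the bins, so adjacent bins form the
#' 0-25 kb class; CoC per class is the mean of observed/expected over
#' qualifying pairs, and interference at the adjacent class is 1 - CoC.
#' Cross-chromosome pairs are excluded (interference is intra-chromosomal).
#'
#' @param events event table (class == "CO" rows used).
#' @param genome a [GenomeMap-class].
#' @param nTetrads number of meioses.
#' @param binSize bin size in bp (default 25000).
#' @param maxSeparationBp largest gap class reported (default 250 kb).
#' @return A [CoCProfile-class].
#' @export
cocProfile <- function(events, genome, nTetrads, binSize = 25000,
                       maxSeparationBp = 250000) {
  co <- events[events$class == "CO", , drop = FALSE]
  if (!nrow(co)) stop("no crossovers: CoC profile undefined")
  mid <- if ("midpoint" %in% names(co)) co$midpoint
         else (co$start + co$end) / 2
  tets <- unique(co$tetrad_id)
  if (length(tets) > nTetrads)
    stop("more tetrad ids than nTetrads")
  maxClass <- floor(maxSeparationBp / binSize)
  acc <- list(ratioSum = numeric(maxClass + 1L),
              obs = numeric(maxClass + 1L), exp = numeric(maxClass + 1L),
              n = integer(maxClass + 1L))
  L <- chromLengths(genome)
  for (chrom in chromNames(genome)) {
    onC <- co$chrom == chrom
    if (!any(onC)) next
    nBins <- ceiling(L[[chrom]] / binSize)
    if (nBins < 2L) next
    bin <- pmin(nBins, floor(mid[onC] / binSize) + 1L)
    tet <- factor(co$tetrad_id[onC], levels = tets)
    ind <- matrix(FALSE, length(tets), nBins)
    ind[cbind(as.integer(tet), bin)] <- TRUE
    pI <- colSums(ind) / nTetrads
    obsMat <- crossprod(ind)            # tetrads with COs in both bins
    for (i in seq_len(nBins - 1L)) {
      if (pI[i] == 0) next
      jMax <- min(nBins, i + maxClass + 1L)
      for (j in seq(i + 1L, jMax)) {
        if (pI[j] == 0) next
        k <- j - i                       # gap class: adjacent bins -> 1
        if (k > maxClass + 1L) next
        e <- nTetrads * pI[i] * pI[j]
        o <- obsMat[i, j]
        acc$ratioSum[k] <- acc$ratioSum[k] + o / e
        acc$obs[k] <- acc$obs[k] + o
        acc$exp[k] <- acc$exp[k] + e
        acc$n[k] <- acc$n[k] + 1L
      }
    }
  }
  keep <- acc$n > 0L
  if (!any(keep)) stop("no qualifying bin pairs: CoC profile undefined")
  k <- which(keep)
  tab <- data.frame(separation_kb = (k - 1L) * binSize / 1000,
                    coc = acc$ratioSum[k] / acc$n[k],
                    observed = acc$obs[k], expected = acc$exp[k],
                    n_pairs = acc$n[k])
  adj <- if (keep[1L]) tab$coc[tab$separation_kb == 0] else NA_real_
  new("CoCProfile", binSize = binSize, nTetrads = as.integer(nTetrads),
      table = tab, interferenceAdjacent = 1 - adj)
}

#' Chi-square comparison of double-crossover frequencies
#'
#' Compares two genotypes' observed vs expected double-crossover counts in
#' the adjacent (0-25 kb) separation class with a 2 x 2 chi-square test on
#' (observed, expected - observed); when any expected cell is below 1 a
#' Fisher exact test on the rounded table is used instead (with a warning).
#'
#' @param profileA,profileB [CoCProfile-class] objects with equal bin size.
#' @return list(statistic, p.value, method, table).
#' @export
cocChisq <- function(profileA, profileB) {
  if (profileA@binSize != profileB@binSize)
    stop("profiles must use the same bin size")
  row1 <- profileA@table[profileA@table$separation_kb == 0, ]
  row2 <- profileB@table[profileB@table$separation_kb == 0, ]
  if (!nrow(row1) || !nrow(row2))
    stop("profiles lack the adjacent separation class")
  m <- rbind(c(row1$observed, max(row1$expected - row1$observed, 0)),
             c(row2$observed, max(row2$expected - row2$observed, 0)))
  if (any(m < 1)) {
    warning("expected cell < 1; falling back on Fisher's exact test")
    ft <- stats::fisher.test(round(m))
    return(list(statistic = NA_real_, p.value = ft$p.value,
                method = "fisher", table = m))
  }
  ct <- suppressWarnings(stats::chisq.test(round(m), correct = FALSE))
  list(statistic = unname(ct$statistic), p.value = ct$p.value,
       method = "chisq", table = m)
}

#' Chromatid interference test
#'
#' Classifies each pair of adjacent crossovers on a chromosome by the number
#' of chromatids they share (2 shared = 2-strand double, 1 = 3-strand, 0 =
#' 4-strand) and tests the counts against the no-chromatid-interference
#' expectation 1:2:1 by chi-square. With fewer than `minPairs` pairs only
#' counts are reported.
#'
#' @param events event table with CO rows carrying `chromatids` ("a,b").
#' @param minPairs minimum pairs for the test (default 5).
#' @return list(counts = c(two_strand, three_strand, four_strand),
#'   statistic, p.value).
#' @export
chromatidInterference <- function(events, minPairs = 5L) {
  co <- events[events$class == "CO", , drop = FALSE]
  counts <- c(two_strand = 0L, three_strand = 0L, four_strand = 0L)
  if (nrow(co)) {
    mid <- if ("midpoint" %in% names(co)) co$midpoint
           else (co$start + co$end) / 2
    ord <- order(co$tetrad_id, co$chrom, mid)
    co <- co[ord, , drop = FALSE]
    cids <- strsplit(co$chromatids, ",")
    grp <- paste(co$tetrad_id, co$chrom)
    for (g in split(seq_len(nrow(co)), grp)) {
      if (length(g) < 2L) next
      for (q in seq_len(length(g) - 1L)) {
        shared <- length(intersect(cids[[g[q]]], cids[[g[q + 1L]]]))
        counts[3L - shared] <- counts[3L - shared] + 1L
      }
    }
  }
  if (sum(counts) < minPairs)
    return(list(counts = counts, statistic = NA_real_, p.value = NA_real_))
  ct <- suppressWarnings(
    stats::chisq.test(counts, p = c(1, 2, 1) / 4))
  list(counts = counts, statistic = unname(ct$statistic),
       p.value = ct$p.value)
}
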