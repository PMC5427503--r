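## Obligate-crossover (crossover assurance) statistics: the Poisson no-E0
## model and observed nonexchange-chromosome summaries.

#' Probability of a meiosis with no nonexchange chromosome
#'
#' Under independent (Poisson) crossovers with per-chromosome means
#' lambda_c, chromosome c is nonexchange (E0) with probability
#' exp(-lambda_c), so a meiosis avoids E0 entirely with probability
#' prod(1 - exp(-lambda_c)). Monotone increasing in every lambda_c; 0 if any
#' lambda_c is 0.
#'
#' @param lambda numeric vector of nonnegative per-chromosome crossover
#'   means.
#' @return probability in [0, 1].
#' @examples
#' poissonNoE0(rep(log(2), 16))  # 0.5^16
#' @export
poissonNoE0 <- function(lambda) {
  if (any(lambda < 0)) stop("lambda must be nonnegative")
  prod(1 - exp(-lambda))
}

#' No-E0 probability curve over genome-wide crossover number
#'
#' For each genome-wide mean N, allocates lambda_c = N * w_c and applies
#' [poissonNoE0()]; the curve is monotone increasing from 0 (N = 0)
#' towards 1.
#'
#' @param nGrid numeric vector of genome-wide mean crossover counts.
#' @param weights per-chromosome allocation weights summing to 1 (default:
#'   wild-type-like [defaultCoWeights()] on [sgdGenome()]).
#' @return data.frame with columns n_crossovers and p_no_e0.
#' @export
noE0Curve <- function(nGrid, weights = defaultCoWeights(sgdGenome())) {
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  data.frame(n_crossovers = nGrid,
             p_no_e0 = vapply(nGrid,
                              function(N) poissonNoE0(N * weights),
                              numeric(1)))
}

#' Observed nonexchange-chromosome statistics
#'
#' @param summary per-tetrad/chromosome summary from [callEvents()] (columns
#'   tetrad_id, chrom, e0).
#' @param referenceFraction optional reference proportion of E0-containing
#'   meioses; when given, a two-sided exact binomial test of the observed
#'   count against it is included.
#' @return list with `fractionWithE0` (meioses with >= 1 E0 chromosome),
#'   `nMeioses`, `nWithE0`, `perChromPct` (percent of meioses in which each
#'   chromosome is E0) and `binomP` (NA without a reference).
#' @export
observedE0Stats <- function(summary, referenceFraction = NULL) {
  if (!nrow(summary)) stop("empty summary")
  byTet <- tapply(summary$e0, summary$tetrad_id, any)
  n <- length(byTet)
  x <- sum(byTet)
  perChrom <- tapply(summary$e0, summary$chrom, mean) * 100
  binomP <- NA_real_
  if (!is.null(referenceFraction)) {
    binomP <- if (referenceFraction == 0) {
      if (x == 0) 1 else 0    # degenerate null
    } else {
      stats::binom.test(x, n, referenceFraction)$p.value
    }
  }
  list(fractionWithE0 = x / n, nMeioses = n, nWithE0 = x,
       perChromPct = perChrom, binomP = binomP)
}
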