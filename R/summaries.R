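## Descriptive statistical layer: per-chromosome tests, CO-NCO correlation,
## density-vs-length regression, feature proximity profiles, tract-length
## comparisons and segregation-ratio tables.

## Welch t-test p-value with a zero-variance shortcut.
.welchP <- function(a, b) {
  if (stats::var(a) == 0 && stats::var(b) == 0)
    return(if (mean(a) == mean(b)) 1 else 0)
  stats::t.test(a, b)$p.value
}

#' Per-chromosome crossover/noncrossover comparison table
#'
#' Mean, SD and SE of per-tetrad crossover and noncrossover counts per
#' chromosome for a dataset and a reference dataset, with per-chromosome
#' Welch two-sample t-tests (reported raw, with an optional
#' Benjamini-Hochberg column) and a P < 0.05 flag.
#'
#' @param summary,refSummary per-tetrad/chromosome summaries from
#'   [callEvents()] (>= 2 tetrads each).
#' @param adjust add BH-adjusted p-value columns (default TRUE).
#' @return data.frame, one row per chromosome.
#' @export
perChromosomeTable <- function(summary, refSummary, adjust = TRUE) {
  chroms <- unique(summary$chrom)
  stat <- function(x) c(mean = mean(x), sd = stats::sd(x),
                        se = stats::sd(x) / sqrt(length(x)))
  out <- lapply(chroms, function(ch) {
    a <- summary[summary$chrom == ch, , drop = FALSE]
    b <- refSummary[refSummary$chrom == ch, , drop = FALSE]
    if (nrow(a) < 2L || nrow(b) < 2L)
      stop("need >= 2 tetrads per dataset on ", ch)
    sa <- stat(a$co); sb <- stat(b$co)
    na <- stat(a$nco); nb <- stat(b$nco)
    data.frame(chrom = ch,
               co_mean = sa[["mean"]], co_sd = sa[["sd"]],
               co_se = sa[["se"]], co_mean_ref = sb[["mean"]],
               co_p = .welchP(a$co, b$co),
               nco_mean = na[["mean"]], nco_sd = na[["sd"]],
               nco_se = na[["se"]], nco_mean_ref = nb[["mean"]],
               nco_p = .welchP(a$nco, b$nco),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, out)
  if (adjust) {
    tab$co_p_bh <- stats::p.adjust(tab$co_p, "BH")
    tab$nco_p_bh <- stats::p.adjust(tab$nco_p, "BH")
  }
  tab$co_sig <- tab$co_p < 0.05
  tab$nco_sig <- tab$nco_p < 0.05
  tab
}

#' Correlation of per-tetrad crossover and noncrossover totals
#'
#' @param summary per-tetrad/chromosome summary (>= 3 tetrads).
#' @return list(r, p.value, n) from a two-sided Pearson test.
#' @export
coNcoCorrelation <- function(summary) {
  co <- tapply(summary$co, summary$tetrad_id, sum)
  nco <- tapply(summary$nco, summary$tetrad_id, sum)
  if (length(co) < 3L) stop("need >= 3 tetrads")
  ct <- stats::cor.test(co, nco, method = "pearson")
  list(r = unname(ct$estimate), p.value = ct$p.value, n = length(co))
}

#' Event density versus chromosome length
#'
#' Density is (50 * mean event count per meiosis) / chromosome length in kb,
#' i.e. cM per kb when applied to crossovers; regressed and correlated
#' against chromosome length in Mb. The three smallest chromosomes can be
#' excluded as in genome-wide recombination studies.
#'
#' @param summary per-tetrad/chromosome summary.
#' @param genome a [GenomeMap-class].
#' @param what "co", "nco" or "both" (CO + NCO density).
#' @param excludeChroms chromosome names dropped before the fit.
#' @return list(r, p.value, slope, n, table) where table holds per-chromosome
#'   length_mb and density; >= 4 chromosomes required after exclusion.
#' @export
densityVsLength <- function(summary, genome, what = c("co", "nco", "both"),
                            excludeChroms = NULL) {
  what <- match.arg(what)
  chroms <- setdiff(chromNames(genome), excludeChroms)
  if (length(chroms) < 4L) stop("need >= 4 chromosomes after exclusion")
  L <- chromLengths(genome)[chroms]
  m <- vapply(chroms, function(ch) {
    s <- summary[summary$chrom == ch, , drop = FALSE]
    cnt <- switch(what, co = s$co, nco = s$nco, both = s$co + s$nco)
    mean(cnt)
  }, numeric(1))
  density <- 50 * m / (L / 1000)        # cM per kb scale
  lengthMb <- L / 1e6
  ct <- stats::cor.test(density, lengthMb, method = "pearson")
  fit <- stats::lm(density ~ lengthMb)
  list(r = unname(ct$estimate), p.value = ct$p.value,
       slope = unname(stats::coef(fit)[2]), n = length(chroms),
       table = data.frame(chrom = chroms, length_mb = lengthMb,
                          density = density, row.names = NULL))
}

#' Event density profile by distance to centromere or telomere
#'
#' Events are assigned to distance bins from the feature (telomere distance
#' is the distance to the nearer chromosome end; centromere windows are
#' symmetric); densities are events per kb per tetrad.
#'
#' @param events event table.
#' @param genome a [GenomeMap-class].
#' @param nTetrads number of meioses.
#' @param feature "centromere" or "telomere".
#' @param binKb,maxKb bin width and profile extent (default 10 and 80 kb).
#' @param classes event classes profiled (default CO and NCO).
#' @return data.frame: bin_start_kb, bin_end_kb, count, density.
#' @export
featureProximityProfile <- function(events, genome, nTetrads,
                                    feature = c("centromere", "telomere"),
                                    binKb = 10, maxKb = 80,
                                    classes = c("CO", "NCO")) {
  feature <- match.arg(feature)
  if (binKb <= 0) stop("binKb must be positive")
  ev <- events[events$class %in% classes, , drop = FALSE]
  mid <- if ("midpoint" %in% names(ev)) ev$midpoint
         else (ev$start + ev$end) / 2
  L <- chromLengths(genome)[ev$chrom]
  dist <- if (feature == "centromere")
    abs(mid - centromeres(genome)[ev$chrom])
  else
    pmin(mid - 1, L - mid)
  breaks <- seq(0, maxKb * 1000, by = binKb * 1000)
  counts <- table(cut(dist, breaks, right = FALSE))
  data.frame(bin_start_kb = utils::head(breaks, -1) / 1000,
             bin_end_kb = breaks[-1] / 1000,
             count = as.integer(counts),
             density = as.integer(counts) / (nTetrads * binKb),
             row.names = NULL)
}

#' Conversion-tract length statistics and comparison
#'
#' Median mid-estimate tract lengths per class (crossover-associated vs
#' noncrossover), a two-sided Mann-Whitney test between two datasets, and
#' the long-tract fractions (> 4 kb for crossover-associated tracts, > 2 kb
#' for noncrossovers).
#'
#' @param eventsA,eventsB event tables; `eventsB` may be NULL for a
#'   single-dataset summary.
#' @param classFilter "co" (crossover-associated tracts) or "nco".
#' @return list(medianA, medianB, p.value, longFracA, longFracB, nA, nB).
#' @export
tractLengthStats <- function(eventsA, eventsB = NULL,
                             classFilter = c("co", "nco")) {
  classFilter <- match.arg(classFilter)
  pick <- function(ev) {
    x <- if (classFilter == "co")
      ev$tract_mid[ev$class == "CO" & ev$co_associated]
    else
      ev$tract_mid[ev$class == "NCO"]
    x[!is.na(x)]
  }
  longCut <- if (classFilter == "co") 4000 else 2000
  a <- pick(eventsA)
  if (!length(a))
    stop("no '", classFilter, "' conversion tracts in dataset A")
  res <- list(medianA = stats::median(a),
              longFracA = mean(a > longCut), nA = length(a),
              medianB = NA_real_, longFracB = NA_real_, nB = 0L,
              p.value = NA_real_)
  if (!is.null(eventsB)) {
    b <- pick(eventsB)
    if (!length(b))
      stop("no '", classFilter, "' conversion tracts in dataset B")
    res$medianB <- stats::median(b)
    res$longFracB <- mean(b > longCut)
    res$nB <- length(b)
    res$p.value <- stats::wilcox.test(a, b)$p.value
  }
  res
}

#' Marker segregation-ratio table
#'
#' Percentage of marker columns in each segregation class (2:2, 3:1, 1:3,
#' 4:0, 0:4, missing) over all markers of all tetrads; rows sum to 100.
#'
#' @param tetrads list of [TetradGenotypes-class].
#' @return named numeric of percentages.
#' @export
segregationRatioTable <- function(tetrads) {
  if (!length(tetrads)) stop("need >= 1 tetrad")
  lev <- c("2:2", "3:1", "1:3", "4:0", "0:4", "missing")
  counts <- stats::setNames(numeric(length(lev)), lev)
  for (tt in tetrads) {
    for (chrom in names(tt@genotypes)) {
      g <- tt@genotypes[[chrom]]
      nMiss <- sum(colSums(is.na(g)) > 0L)
      zeros <- colSums(g == 0L)
      zeros <- zeros[!is.na(zeros)]
      tab <- tabulate(zeros + 1L, nbins = 5L)  # 0:4,1:3,2:2,3:1,4:0
      counts["0:4"] <- counts["0:4"] + tab[1L]
      counts["1:3"] <- counts["1:3"] + tab[2L]
      counts["2:2"] <- counts["2:2"] + tab[3L]
      counts["3:1"] <- counts["3:1"] + tab[4L]
      counts["4:0"] <- counts["4:0"] + tab[5L]
      counts["missing"] <- counts["missing"] + nMiss
    }
  }
  100 * counts / sum(counts)
}
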