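## Formats: tab-delimited segregation tables (chrom, pos, four spore
## genotypes per tetrad), BED-like event tables (0-based half-open on disk,
## 1-based closed in memory), TSV truth tables, YAML run configs.

.GENO_OUT <- function(x) ifelse(is.na(x), ".", as.character(x))

#' Read a segregation table
#'
#' Expects a TSV with header columns tetrad_id, chrom, pos, s1, s2, s3, s4;
#' genotypes are "0", "1" or "." (missing). Rows are validated and sorted by
#' (chrom, pos) within tetrad; duplicate (tetrad, chrom, pos) rows are
#' rejected.
#'
#' @param path input file.
#' @param genome optional [GenomeMap-class]; when given, chromosome order
#'   follows it and unknown chromosomes are an error.
#' @return named list of [TetradGenotypes-class].
#' @export
readSegregation <- function(path, genome = NULL) {
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE)
  need <- c("tetrad_id", "chrom", "pos", "s1", "s2", "s3", "s4")
  if (!all(need %in% names(df)))
    stop("segregation table must have columns: ",
         paste(need, collapse = ", "))
  gcols <- c("s1", "s2", "s3", "s4")
  for (cn in gcols) {
    bad <- which(!df[[cn]] %in% c("0", "1", "."))
    if (length(bad))
      stop(sprintf("malformed genotype '%s' in column %s, line %d",
                   df[[cn]][bad[1]], cn, bad[1] + 1L))
  }
  df$pos <- as.integer(df$pos)
  key <- paste(df$tetrad_id, df$chrom, df$pos)
  if (anyDuplicated(key))
    stop("duplicate (tetrad, chrom, pos) row: ", key[duplicated(key)][1])
  if (!is.null(genome) && !all(df$chrom %in% chromNames(genome)))
    stop("unknown chromosome: ",
         setdiff(unique(df$chrom), chromNames(genome))[1])
  ## rows must be grouped by tetrad and chromosome (in order of first
  ## appearance) with positions increasing within each group
  ord <- order(df$tetrad_id, factor(df$chrom, levels = unique(df$chrom)),
               df$pos)
  if (is.unsorted(ord)) {
    warning("input not sorted by (tetrad, chrom, pos); sorting")
    df <- df[ord, , drop = FALSE]
  }
  toInt <- function(x) {
    out <- rep(NA_integer_, length(x))
    ok <- x != "."
    out[ok] <- as.integer(x[ok])
    out
  }
  out <- lapply(split(df, df$tetrad_id), function(sub) {
    chromLevels <- if (is.null(genome)) unique(sub$chrom)
                   else intersect(chromNames(genome), unique(sub$chrom))
    positions <- genotypes <- list()
    for (chrom in chromLevels) {
      sc <- sub[sub$chrom == chrom, , drop = FALSE]
      positions[[chrom]] <- sc$pos
      genotypes[[chrom]] <- rbind(toInt(sc$s1), toInt(sc$s2),
                                  toInt(sc$s3), toInt(sc$s4))
    }
    new("TetradGenotypes", tetradId = sub$tetrad_id[1],
        positions = positions, genotypes = genotypes)
  })
  out[order(names(out))]
}

#' Write a segregation table
#'
#' @param tetrads list of [TetradGenotypes-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeSegregation <- function(tetrads, path) {
  rows <- lapply(tetrads, function(tt) {
    do.call(rbind, lapply(names(tt@positions), function(chrom) {
      g <- tt@genotypes[[chrom]]
      data.frame(tetrad_id = tt@tetradId, chrom = chrom,
                 pos = tt@positions[[chrom]],
                 s1 = .GENO_OUT(g[1, ]), s2 = .GENO_OUT(g[2, ]),
                 s3 = .GENO_OUT(g[3, ]), s4 = .GENO_OUT(g[4, ]),
                 stringsAsFactors = FALSE)
    }))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an event table (BED-like TSV)
#'
#' In-memory coordinates are 1-based closed; on disk start is converted to
#' 0-based half-open BED convention (start - 1, end).
#'
#' @param events event table from [callEvents()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeEvents <- function(events, path) {
  out <- events
  out$start <- out$start - 1
  cols <- c("chrom", "start", "end", "tetrad_id", "class", "chromatids",
            "gc_type", "co_associated", "direction", "tract_min",
            "tract_mid", "tract_max")
  utils::write.table(out[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an event table written by [writeEvents()]
#'
#' @param path input file.
#' @return event data.frame with 1-based closed coordinates and `midpoint`
#'   restored.
#' @export
readEvents <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$start <- df$start + 1
  df$midpoint <- (df$start + df$end) / 2
  df
}

#' Write / read a simulation truth table
#' @param truth truth data.frame from [simulateTruth()].
#' @param path file path.
#' @return invisibly the path ([writeTruth()]) or the data.frame
#'   ([readTruth()]).
#' @export
writeTruth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Events as a GRanges
#'
#' @param events event table.
#' @param genome a [GenomeMap-class] supplying seqlengths.
#' @return a [GenomicRanges::GRanges] with the event columns as metadata.
#' @export
eventsAsGRanges <- function(events, genome = sgdGenome()) {
  gr <- GenomicRanges::GRanges(
    seqnames = events$chrom,
    ranges = IRanges::IRanges(start = events$start, end = events$end),
    seqlengths = chromLengths(genome))
  meta <- setdiff(names(events), c("chrom", "start", "end"))
  for (cn in meta) GenomicRanges::mcols(gr)[[cn]] <- events[[cn]]
  gr
}

#' Read a run configuration (YAML)
#'
#' Recognized fields: genotype (preset name), n_tetrads, total_co,
#' total_nco, class1_fraction, gamma_shape, co_gc_prob,
#' co_gc_tract_median_bp, nco_gc_tract_median_bp, marker_count, seed.
#'
#' @param path YAML file.
#' @return list(params = [SimParams-class], seed, raw = parsed list).
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  genome <- sgdGenome()
  base <- if (!is.null(cfg$genotype))
    presetParams(cfg$genotype, genome) else simParams(genome)
  override <- function(slotVal, key, as = identity)
    if (!is.null(cfg[[key]])) as(cfg[[key]]) else slotVal
  params <- simParams(
    genome,
    nTetrads = override(base@nTetrads, "n_tetrads", as.integer),
    totalCo = override(sum(base@meanCoPerChrom), "total_co", as.numeric),
    totalNco = override(sum(base@ncoRatePerChrom), "total_nco",
                        as.numeric),
    classIFraction = override(base@classIFraction, "class1_fraction",
                              as.numeric),
    gammaShape = override(base@gammaShape, "gamma_shape", as.numeric),
    coGcProb = override(base@coGcProb, "co_gc_prob", as.numeric),
    coGcTractMedianBp = override(base@coGcTractMedianBp,
                                 "co_gc_tract_median_bp", as.numeric),
    ncoGcTractMedianBp = override(base@ncoGcTractMedianBp,
                                  "nco_gc_tract_median_bp", as.numeric),
    markerCount = override(base@markerCount, "marker_count", as.integer))
  list(params = params, seed = if (is.null(cfg$seed)) 1L
                               else as.integer(cfg$seed), raw = cfg)
}
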