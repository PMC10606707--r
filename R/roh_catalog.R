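## Runs of homozygosity: per-individual maximal-run detection, the shared
## segment catalog with carrier-frequency filtering, and descriptive
## summaries (run sizes, per-sample genome coverage).

#' Detect maximal homozygous runs per individual
#'
#' A run is a maximal contiguous stretch of homozygous genotypes (dosage 0
#' or 2) within one chromosome, kept when it spans at least `min_snps`
#' markers. The default of 16 reads "more than 15 SNPs" strictly. Runs never
#' cross chromosome boundaries, and no heterozygous calls are tolerated
#' inside a run (`max_het = 0`; a positive value relaxes this for
#' genotyping-error tolerance, in which case runs are the maximal windows
#' containing at most `max_het` heterozygotes at internal positions).
#'
#' @param gd A complete `genotype_dataset`.
#' @param min_snps Minimum number of markers per run (default 16).
#' @param max_het Maximum heterozygous calls tolerated inside a run
#'   (default 0).
#' @return A `data.table` with columns `sample_id`, `chrom`, `start_idx`,
#'   `end_idx` (inclusive, global marker indices), `start_bp`, `end_bp`,
#'   `n_snps`, `length_bp`.
#' @export
detect_runs <- function(gd, min_snps = 16L, max_het = 0L) {
  stopifnot(inherits(gd, "genotype_dataset"))
  if (anyNA(gd$calls))
    stop("missing genotypes present; run impute_mode() first")
  if (min_snps < 1L) stop("min_snps must be positive")
  map <- gd$map
  chroms <- unique(map$chrom)
  out <- vector("list", 0L)
  for (ch in chroms) {
    jj <- which(map$chrom == ch)
    hom <- gd$calls[, jj, drop = FALSE] != 1L
    for (i in seq_along(gd$samples)) {
      segs <- if (max_het == 0L) hom_runs_rle(hom[i, ]) else
        hom_runs_maxhet(hom[i, ], max_het)
      if (!nrow(segs)) next
      segs <- segs[segs$len >= min_snps, , drop = FALSE]
      if (!nrow(segs)) next
      out[[length(out) + 1L]] <- data.table::data.table(
        sample_id = gd$samples[i], chrom = ch,
        start_idx = jj[segs$start], end_idx = jj[segs$end],
        start_bp = map$pos_bp[jj[segs$start]],
        end_bp = map$pos_bp[jj[segs$end]],
        n_snps = segs$len)
    }
  }
  runs <- if (length(out)) data.table::rbindlist(out) else
    data.table::data.table(sample_id = character(), chrom = character(),
                           start_idx = integer(), end_idx = integer(),
                           start_bp = integer(), end_bp = integer(),
                           n_snps = integer())
  runs[, length_bp := end_bp - start_bp]
  data.table::setkey(runs, chrom, start_idx, end_idx)
  runs[]
}

## maximal TRUE-runs of a logical vector
hom_runs_rle <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep], len = r$lengths[keep])
}

## maximal windows with at most k FALSE entries at internal positions,
## trimmed to TRUE endpoints; two-pointer sweep
hom_runs_maxhet <- function(x, k) {
  n <- length(x)
  res <- list(); left <- 1L; bad <- 0L
  right <- 0L
  starts <- integer(0); ends <- integer(0)
  while (left <= n) {
    if (right < left) { right <- left - 1L; bad <- 0L }
    while (right < n && (bad + !x[right + 1L]) <= k) {
      right <- right + 1L
      bad <- bad + !x[right]
    }
    a <- left; b <- right
    while (a <= b && !x[a]) { bad <- bad - 1L; a <- a + 1L }
    while (b >= a && !x[b]) b <- b - 1L
    if (b >= a && (!length(starts) || a > starts[length(starts)] ||
                   b > ends[length(ends)])) {
      drop <- length(starts) && starts[length(starts)] >= a &&
        ends[length(ends)] <= b
      if (drop) { starts <- starts[-length(starts)]; ends <- ends[-length(ends)] }
      starts <- c(starts, a); ends <- c(ends, b)
    }
    if (left <= right && !x[left]) bad <- bad - 1L
    left <- left + 1L
  }
  keep <- !duplicated(data.frame(starts, ends))
  ## retain only maximal (non-nested) windows
  d <- data.frame(start = starts[keep], end = ends[keep])
  if (nrow(d) > 1L) {
    d <- d[order(d$start, -d$end), ]
    maxend <- cummax(d$end)
    nested <- c(FALSE, d$end[-1L] <= maxend[-nrow(d)])
    d <- d[!nested, ]
  }
  d$len <- d$end - d$start + 1L
  d
}

#' Assemble the shared-ROH segment catalog
#'
#' Candidate segments are the distinct (chromosome, start, end) intervals of
#' all individual runs. A sample carries a segment when one of its own runs
#' fully covers the segment. Segments are kept when their carrier frequency
#' lies in `[min_freq, max_freq]` (defaults 5%--95% of individuals).
#'
#' @param runs Output of [detect_runs()].
#' @param gd The `genotype_dataset` the runs were detected on.
#' @param min_freq,max_freq Carrier-frequency window.
#' @return An object of class `roh_catalog`: a list with `segments` (a
#'   `data.table`: `segment_id`, `chrom`, `start_idx`, `end_idx`,
#'   `start_bp`, `end_bp`, `n_snps`, `n_carriers`, `carrier_frequency`),
#'   `carriers` (list of carrier sample-id vectors per segment), `samples`,
#'   and the parameters used.
#' @export
build_catalog <- function(runs, gd, min_freq = 0.05, max_freq = 0.95) {
  stopifnot(inherits(gd, "genotype_dataset"))
  if (min_freq > max_freq)
    stop("carrier-frequency window empty: min_freq > max_freq")
  n <- length(gd$samples)
  segs <- unique(runs[, .(chrom, start_idx, end_idx, start_bp, end_bp, n_snps)])
  if (!nrow(segs)) {
    segments <- data.table::data.table(
      segment_id = character(), chrom = character(), start_idx = integer(),
      end_idx = integer(), start_bp = integer(), end_bp = integer(),
      n_snps = integer(), n_carriers = integer(),
      carrier_frequency = numeric())
    return(structure(list(segments = segments, carriers = list(),
                          samples = gd$samples,
                          params = list(min_freq = min_freq,
                                       max_freq = max_freq)),
                     class = "roh_catalog"))
  }
  data.table::setkey(segs, chrom, start_idx, end_idx)
  segs[, seg_i := .I]
  ## carrier: one of the sample's own runs fully covers the segment
  ov <- runs[segs,
             .(sample_id = x.sample_id, seg_i = i.seg_i),
             on = .(chrom, start_idx <= start_idx, end_idx >= end_idx),
             allow.cartesian = TRUE]
  carrier_sets <- split(ov$sample_id, ov$seg_i)
  carrier_sets <- lapply(carrier_sets, function(s) sort(unique(s)))
  nc <- integer(nrow(segs))
  nc[as.integer(names(carrier_sets))] <- lengths(carrier_sets)
  segs[, n_carriers := nc]
  segs[, carrier_frequency := n_carriers / n]
  keep <- segs$carrier_frequency >= min_freq & segs$carrier_frequency <= max_freq
  carriers <- vector("list", nrow(segs))
  carriers[as.integer(names(carrier_sets))] <- carrier_sets
  segs <- segs[keep]
  carriers <- carriers[keep]
  segs[, seg_i := NULL]
  segs[, segment_id := sprintf("ROH_%s_%d_%d", chrom, start_bp, end_bp)]
  data.table::setcolorder(segs, c("segment_id", "chrom", "start_idx",
                                  "end_idx", "start_bp", "end_bp", "n_snps",
                                  "n_carriers", "carrier_frequency"))
  structure(list(segments = segs[], carriers = carriers,
                 samples = gd$samples,
                 params = list(min_freq = min_freq, max_freq = max_freq)),
            class = "roh_catalog")
}

#' @exportS3Method base::print
print.roh_catalog <- function(x, ...) {
  cat("roh_catalog:", nrow(x$segments), "shared segments over",
      length(x$samples), "samples; carrier frequency window [",
      x$params$min_freq, ",", x$params$max_freq, "]\n")
  invisible(x)
}

#' Samples-by-segments carrier indicator matrix
#'
#' Entry `[i, s]` is 1 when sample `i` carries segment `s` (one of its runs
#' fully covers the segment); column means reproduce `carrier_frequency`
#' exactly.
#'
#' @param catalog An `roh_catalog`.
#' @param gd The `genotype_dataset` the catalog was built from.
#' @return Integer matrix, samples in rows (dataset order), segments in
#'   columns (`segment_id` column names).
#' @export
carrier_matrix <- function(catalog, gd) {
  stopifnot(inherits(catalog, "roh_catalog"), inherits(gd, "genotype_dataset"))
  if (!identical(catalog$samples, gd$samples))
    stop("sample ids of catalog and dataset differ")
  n <- length(gd$samples)
  m <- nrow(catalog$segments)
  M <- matrix(0L, n, m, dimnames = list(gd$samples, catalog$segments$segment_id))
  for (s in seq_len(m)) M[catalog$carriers[[s]], s] <- 1L
  M
}

#' Descriptive summary of detected runs
#'
#' Run-count and size statistics, histogram tables of run sizes by SNP count
#' and by base pairs, and per-sample genome coverage: the union length of a
#' sample's runs divided by the total mapped autosome length (last minus
#' first marker position, summed over chromosomes).
#'
#' @param runs Output of [detect_runs()].
#' @param gd The `genotype_dataset` the runs were detected on.
#' @param snp_breaks,bp_breaks Histogram break points.
#' @return A list with elements `n_runs`, `snp_stats`, `bp_stats`
#'   (min/max/mean/sd), `snp_hist`, `bp_hist`, `coverage_pct` (named per
#'   sample, zero for samples with no runs) and `genome_length_bp`.
#' @export
summarize_catalog <- function(runs, gd,
                              snp_breaks = c(16, 25, 50, 100, 200, Inf),
                              bp_breaks = c(0, 1e6, 2e6, 4e6, 8e6, 16e6, Inf)) {
  stopifnot(inherits(gd, "genotype_dataset"))
  map <- gd$map
  glen <- sum(tapply(map$pos_bp, map$chrom, function(p) max(p) - min(p)))
  cov <- stats::setNames(numeric(length(gd$samples)), gd$samples)
  if (nrow(runs)) {
    usum <- runs[, {
      ir <- IRanges::reduce(IRanges::IRanges(start_bp, end_bp))
      .(union_bp = sum(as.numeric(IRanges::end(ir) - IRanges::start(ir))))
    }, by = .(sample_id, chrom)][, .(union_bp = sum(union_bp)), by = sample_id]
    cov[usum$sample_id] <- 100 * usum$union_bp / glen
  }
  stat <- function(x) if (length(x)) c(min = min(x), max = max(x),
                                       mean = mean(x), sd = stats::sd(x)) else
    c(min = NA, max = NA, mean = NA, sd = NA)
  list(
    n_runs = nrow(runs),
    snp_stats = stat(runs$n_snps),
    bp_stats = stat(runs$length_bp),
    snp_hist = if (nrow(runs)) table(cut(runs$n_snps, snp_breaks,
                                         right = FALSE)) else NULL,
    bp_hist = if (nrow(runs)) table(cut(runs$length_bp, bp_breaks,
                                        right = FALSE)) else NULL,
    coverage_pct = cov,
    genome_length_bp = glen)
}
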