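## Genotype container, PLINK v1.9 text/binary I/O, QC filters, mode
## imputation and the per-individual heterozygosity covariate.

#' Construct a genotype dataset
#'
#' A `genotype_dataset` holds a samples-by-markers matrix of counted-allele
#' dosages (0/1/2, `NA` = missing), a marker map, and a provenance log of the
#' filters that produced it.
#'
#' @param calls Integer matrix, samples in rows, markers in columns;
#'   entries 0, 1, 2 or `NA`.
#' @param map `data.frame` with columns `marker_id`, `chrom`, `pos_bp` and
#'   optionally `a1`, `a2` (counted and alternative allele labels). Positions
#'   must be strictly increasing within each chromosome.
#' @param samples Character vector of sample ids (defaults to the row names
#'   of `calls`).
#' @param provenance Character vector of processing notes.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(calls, map, samples = rownames(calls),
                             provenance = character()) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(samples)) stop("sample ids are required")
  samples <- as.character(samples)
  if (length(samples) != nrow(calls))
    stop("length(samples) must equal nrow(calls)")
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  need <- c("marker_id", "chrom", "pos_bp")
  if (!all(need %in% names(map)))
    stop("map needs columns: ", paste(need, collapse = ", "))
  if (nrow(map) != ncol(calls))
    stop("nrow(map) must equal ncol(calls): ", nrow(map), " vs ", ncol(calls))
  map$marker_id <- as.character(map$marker_id)
  map$chrom <- as.character(map$chrom)
  map$pos_bp <- as.integer(map$pos_bp)
  if (anyDuplicated(map$marker_id)) stop("duplicate marker ids")
  if (is.null(map$a1)) map$a1 <- "A"
  if (is.null(map$a2)) map$a2 <- "B"
  bad <- !(calls %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad, na.rm = TRUE)) stop("calls must be 0, 1, 2 or NA")
  ## strictly increasing positions within chromosome
  for (ch in unique(map$chrom)) {
    p <- map$pos_bp[map$chrom == ch]
    if (any(diff(p) <= 0))
      stop("marker positions not strictly increasing on chromosome ", ch)
  }
  rownames(calls) <- samples
  colnames(calls) <- map$marker_id
  structure(list(calls = calls, map = map, samples = samples,
                 provenance = as.character(provenance)),
            class = "genotype_dataset")
}

#' @exportS3Method base::print
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", length(x$samples), "samples x", nrow(x$map),
      "markers on", length(unique(x$map$chrom)), "chromosome(s)\n")
  nmiss <- sum(is.na(x$calls))
  cat("  missing calls:", nmiss,
      sprintf("(%.2f%%)\n", 100 * nmiss / length(x$calls)))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = "; "), "\n")
  invisible(x)
}

#' @exportS3Method
dim.genotype_dataset <- function(x) dim(x$calls)

#' Subset a genotype dataset by sample ids
#'
#' @param gd A `genotype_dataset`.
#' @param ids Sample ids to keep (order preserved as given).
#' @return A `genotype_dataset` restricted to `ids`.
#' @export
subset_samples <- function(gd, ids) {
  stopifnot(inherits(gd, "genotype_dataset"))
  ids <- as.character(ids)
  missing_ids <- setdiff(ids, gd$samples)
  if (length(missing_ids))
    stop("sample ids not in dataset: ", paste(head(missing_ids, 5), collapse = ", "))
  genotype_dataset(gd$calls[ids, , drop = FALSE], gd$map, ids,
                   c(gd$provenance,
                     sprintf("subset to %d of %d samples", length(ids),
                             length(gd$samples))))
}

## ---------------------------------------------------------------- PLINK I/O

#' Read PLINK genotypes (text or binary dialect)
#'
#' Reads `.ped`/`.map` (`dialect = "text"`) or `.bed`/`.bim`/`.fam`
#' (`dialect = "binary"`, SNP-major v1.9 layout). Dosage is the count of the
#' A1 allele: for the binary dialect A1 is taken from the `.bim` file; for the
#' text dialect it is the lexicographically smaller allele observed at the
#' marker. Markers are sorted by chromosome then position (with a warning if
#' the input was unsorted). Missing genotypes are preserved as `NA`.
#'
#' Note on the text dialect: because `.ped`/`.map` carry no reference-allele
#' record, a marker at which the counted allele is absent from the sample
#' (all samples dosage 0) re-reads with flipped orientation (dosage 2).
#' Heterozygosity and ROH calls are unaffected; use the binary dialect when
#' exact dosage orientation must round-trip.
#'
#' @param path_prefix Path without extension.
#' @param dialect `"text"` or `"binary"`.
#' @return A `genotype_dataset`.
#' @export
read_plink <- function(path_prefix, dialect = c("text", "binary")) {
  dialect <- match.arg(dialect)
  if (dialect == "text") read_plink_text(path_prefix) else
    read_plink_binary(path_prefix)
}

read_map_file <- function(path) {
  mp <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = c("character", "character",
                                         "numeric", "integer"))
  names(mp) <- c("chrom", "marker_id", "cm", "pos_bp")
  mp
}

sort_map <- function(map, what) {
  chrnum <- suppressWarnings(as.numeric(map$chrom))
  ord <- order(is.na(chrnum), chrnum, map$chrom, map$pos_bp)
  if (is.unsorted(ord, strictly = TRUE) || any(ord != seq_along(ord))) {
    warning(what, " not sorted by chromosome then position; sorting")
    return(ord)
  }
  seq_along(ord)
}

read_plink_text <- function(prefix) {
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  for (f in c(ped_path, map_path))
    if (!file.exists(f)) stop("file not found: ", f)
  mp <- read_map_file(map_path)
  m <- nrow(mp)
  ped <- data.table::fread(ped_path, header = FALSE, colClasses = "character",
                           data.table = FALSE)
  if (ncol(ped) != 6L + 2L * m)
    stop("sample/marker count mismatch: .ped has ", ncol(ped),
         " columns, expected ", 6L + 2L * m, " for ", m, " markers")
  samples <- as.character(ped[[2L]])
  al1 <- as.matrix(ped[, 6L + 2L * seq_len(m) - 1L, drop = FALSE])
  al2 <- as.matrix(ped[, 6L + 2L * seq_len(m), drop = FALSE])
  al1[al1 == "0"] <- NA
  al2[al2 == "0"] <- NA
  calls <- matrix(NA_integer_, nrow(ped), m)
  a1 <- a2 <- character(m)
  for (j in seq_len(m)) {
    obs <- sort(unique(stats::na.omit(c(al1[, j], al2[, j]))))
    if (length(obs) > 2L)
      stop("more than two alleles at marker ", mp$marker_id[j])
    a1[j] <- if (length(obs)) obs[1L] else "A"
    a2[j] <- if (length(obs) == 2L) obs[2L] else "B"
    ok <- !is.na(al1[, j]) & !is.na(al2[, j])
    calls[ok, j] <- (al1[ok, j] == a1[j]) + (al2[ok, j] == a1[j])
  }
  ord <- sort_map(mp, ".map")
  gd <- genotype_dataset(calls[, ord, drop = FALSE],
                         data.frame(marker_id = mp$marker_id, chrom = mp$chrom,
                                    pos_bp = mp$pos_bp, a1 = a1,
                                    a2 = a2)[ord, ],
                         samples,
                         provenance = sprintf("read %s(.ped/.map)", prefix))
  gd
}

read_plink_binary <- function(prefix) {
  bed_path <- paste0(prefix, ".bed")
  bim_path <- paste0(prefix, ".bim")
  fam_path <- paste0(prefix, ".fam")
  for (f in c(bed_path, bim_path, fam_path))
    if (!file.exists(f)) stop("file not found: ", f)
  bim <- utils::read.table(bim_path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  names(bim) <- c("chrom", "marker_id", "cm", "pos_bp", "a1", "a2")
  fam <- utils::read.table(fam_path, header = FALSE, stringsAsFactors = FALSE)
  samples <- as.character(fam[[2L]])
  n <- length(samples); m <- nrow(bim)
  raw <- readBin(bed_path, what = "raw", n = file.size(bed_path))
  if (length(raw) < 3L || raw[1L] != as.raw(0x6c) || raw[2L] != as.raw(0x1b))
    stop("bad .bed magic bytes in ", bed_path)
  if (raw[3L] != as.raw(0x01))
    stop(".bed is not in SNP-major order: ", bed_path)
  bpm <- ceiling(n / 4)            # bytes per marker
  if (length(raw) - 3L != bpm * m)
    stop("truncated or oversized .bed: have ", length(raw) - 3L,
         " genotype bytes, expected ", bpm * m)
  body <- raw[-(1:3)]
  ## unpack 2-bit codes: 00=hom A1 (dosage 2), 01=missing, 10=het, 11=hom A2
  codes <- matrix(0L, nrow = 4L * bpm, ncol = m)
  ib <- as.integer(body)
  dim(ib) <- c(bpm, m)
  for (k in 0:3) codes[seq_len(bpm) * 4L - 3L + k, ] <-
    ib %/% (4L^k) %% 4L
  codes <- codes[seq_len(n), , drop = FALSE]
  lut <- c(2L, NA_integer_, 1L, 0L)   # code 0,1,2,3 -> dosage of A1
  calls <- matrix(lut[codes + 1L], n, m)
  ord <- sort_map(bim, ".bim")
  genotype_dataset(calls[, ord, drop = FALSE],
                   data.frame(marker_id = bim$marker_id, chrom = bim$chrom,
                              pos_bp = bim$pos_bp, a1 = bim$a1,
                              a2 = bim$a2)[ord, ],
                   samples,
                   provenance = sprintf("read %s(.bed/.bim/.fam)", prefix))
}

#' Write PLINK genotypes (text or binary dialect)
#'
#' Inverse of [read_plink()]. The text dialect writes `.ped`/`.map`, the
#' binary dialect `.bed`/`.bim`/`.fam` (SNP-major). Dosage 2 is written as
#' two copies of the counted allele (`a1`), missing as `0 0` (text) or the
#' `01` code (binary).
#'
#' @param gd A `genotype_dataset`.
#' @param path_prefix Output path without extension.
#' @param dialect `"text"` or `"binary"`.
#' @return Invisibly, the files written.
#' @export
write_plink <- function(gd, path_prefix, dialect = c("text", "binary")) {
  stopifnot(inherits(gd, "genotype_dataset"))
  dialect <- match.arg(dialect)
  mp <- gd$map
  n <- length(gd$samples); m <- nrow(mp)
  if (dialect == "text") {
    files <- paste0(path_prefix, c(".ped", ".map"))
    utils::write.table(data.frame(mp$chrom, mp$marker_id, 0, mp$pos_bp),
                       files[2L], quote = FALSE, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    out <- matrix("0", n, 2L * m)
    for (j in seq_len(m)) {
      g <- gd$calls[, j]
      first <- ifelse(is.na(g), "0", ifelse(g >= 1L, mp$a1[j], mp$a2[j]))
      second <- ifelse(is.na(g), "0", ifelse(g == 2L, mp$a1[j], mp$a2[j]))
      out[, 2L * j - 1L] <- first
      out[, 2L * j] <- second
    }
    ped <- cbind(gd$samples, gd$samples, "0", "0", "0", "-9", out)
    data.table::fwrite(data.table::as.data.table(ped), files[1L], sep = " ",
                       quote = FALSE, col.names = FALSE)
  } else {
    files <- paste0(path_prefix, c(".bed", ".bim", ".fam"))
    utils::write.table(data.frame(mp$chrom, mp$marker_id, 0, mp$pos_bp,
                                  mp$a1, mp$a2),
                       files[2L], quote = FALSE, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(data.frame(gd$samples, gd$samples, 0, 0, 0, -9),
                       files[3L], quote = FALSE, sep = " ",
                       row.names = FALSE, col.names = FALSE)
    bpm <- ceiling(n / 4)
    code <- matrix(1L, 4L * bpm, m)       # pad with missing code 01
    dos2code <- function(g) ifelse(is.na(g), 1L,
                                   ifelse(g == 2L, 0L, ifelse(g == 1L, 2L, 3L)))
    code[seq_len(n), ] <- dos2code(gd$calls)
    idx <- seq_len(bpm) * 4L
    packed <- code[idx - 3L, , drop = FALSE] +
      4L * code[idx - 2L, , drop = FALSE] +
      16L * code[idx - 1L, , drop = FALSE] +
      64L * code[idx, , drop = FALSE]
    con <- file(files[1L], "wb")
    on.exit(close(con))
    writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
    writeBin(as.raw(as.vector(packed)), con)
  }
  invisible(files)
}

## ------------------------------------------------------------------ QC

#' Call-rate and autosome QC filter
#'
#' Applies the standard chip-data filters: restrict to the listed autosomes,
#' then drop individuals with call rate below `min_ind_call_rate`, then drop
#' markers with call rate below `min_snp_call_rate` (individuals before
#' markers, so a badly genotyped individual cannot drag markers down).
#' Counts of everything removed are appended to the provenance log.
#'
#' @param gd A `genotype_dataset`.
#' @param min_ind_call_rate,min_snp_call_rate Minimum acceptable call rates
#'   in `[0, 1]`.
#' @param autosomes Chromosome labels to retain, or `NULL` to keep all.
#' @return The filtered `genotype_dataset`.
#' @export
qc_filter <- function(gd, min_ind_call_rate = 0.95, min_snp_call_rate = 0.95,
                      autosomes = NULL) {
  stopifnot(inherits(gd, "genotype_dataset"))
  if (min_ind_call_rate < 0 || min_ind_call_rate > 1 ||
      min_snp_call_rate < 0 || min_snp_call_rate > 1)
    stop("call-rate thresholds must lie in [0, 1]")
  calls <- gd$calls; map <- gd$map
  n_chrom_drop <- 0L
  if (!is.null(autosomes)) {
    keep <- map$chrom %in% as.character(autosomes)
    n_chrom_drop <- sum(!keep)
    calls <- calls[, keep, drop = FALSE]
    map <- map[keep, , drop = FALSE]
  }
  if (ncol(calls) == 0L)
    stop("no markers left after autosome restriction; review `autosomes`")
  ind_cr <- rowMeans(!is.na(calls))
  keep_ind <- ind_cr >= min_ind_call_rate
  calls <- calls[keep_ind, , drop = FALSE]
  if (nrow(calls) == 0L)
    stop("no individuals left after call-rate filter; review thresholds")
  snp_cr <- colMeans(!is.na(calls))
  keep_snp <- snp_cr >= min_snp_call_rate
  calls <- calls[, keep_snp, drop = FALSE]
  map <- map[keep_snp, , drop = FALSE]
  if (ncol(calls) == 0L)
    stop("no markers left after call-rate filter; review thresholds")
  prov <- sprintf(
    "qc_filter: dropped %d non-autosomal markers, %d/%d individuals (call rate < %g), %d/%d markers (call rate < %g)",
    n_chrom_drop, sum(!keep_ind), length(keep_ind), min_ind_call_rate,
    sum(!keep_snp), length(keep_snp), min_snp_call_rate)
  genotype_dataset(calls, map, rownames(calls), c(gd$provenance, prov))
}

#' Mode imputation of residual missing genotypes
#'
#' Replaces each missing call with the most frequent genotype class (0/1/2)
#' at that marker; ties break toward the lower dosage. This is a deliberately
#' simple stand-in for pedigree-haplotype imputation: post-QC missingness is
#' small and imputation quality is not what the downstream scan estimates.
#' Pre-imputed data can bypass this step entirely.
#'
#' @param gd A `genotype_dataset`.
#' @return A complete `genotype_dataset` (no `NA` calls).
#' @export
impute_mode <- function(gd) {
  stopifnot(inherits(gd, "genotype_dataset"))
  calls <- gd$calls
  miss <- is.na(calls)
  if (!any(miss)) return(gd)
  all_missing <- colSums(!miss) == 0L
  if (any(all_missing))
    stop("markers with all calls missing: ",
         paste(head(gd$map$marker_id[all_missing], 10), collapse = ", "))
  n_imp <- sum(miss)
  for (j in which(colSums(miss) > 0L)) {
    tab <- tabulate(calls[, j] + 1L, nbins = 3L)   # counts of 0,1,2
    mode_g <- which.max(tab) - 1L                  # which.max takes first tie
    calls[miss[, j], j] <- mode_g
  }
  genotype_dataset(calls, gd$map, gd$samples,
                   c(gd$provenance,
                     sprintf("impute_mode: filled %d missing calls", n_imp)))
}

#' Per-individual heterozygosity percentage
#'
#' The genome-wide inbreeding-depression covariate: the number of
#' heterozygous SNPs per individual times 100, divided by the total number of
#' SNPs (the post-QC marker count). Requires complete genotypes.
#'
#' @param gd A complete `genotype_dataset`.
#' @return Named numeric vector of percentages in `[0, 100]`.
#' @export
heterozygosity_percent <- function(gd) {
  stopifnot(inherits(gd, "genotype_dataset"))
  if (anyNA(gd$calls))
    stop("missing genotypes present; run impute_mode() first")
  100 * rowMeans(gd$calls == 1L)
}

## -------------------------------------------------- pedigree / phenotypes

#' Construct a pedigree
#'
#' Ordered triples (individual, sire, dam); unknown parents are `NA` (the
#' code `"0"` on file). The pedigree is validated to be acyclic and is
#' topologically sorted so that parents precede offspring.
#'
#' @param id,sire,dam Character vectors; `sire`/`dam` may contain `NA`.
#' @param sex Optional character vector (`"M"`/`"F"`).
#' @param generation Optional integer vector.
#' @return A `data.frame` of class `pedigree`, parents before offspring.
#' @export
pedigree <- function(id, sire, dam, sex = NULL, generation = NULL) {
  id <- as.character(id); sire <- as.character(sire); dam <- as.character(dam)
  sire[sire %in% c("0", "")] <- NA
  dam[dam %in% c("0", "")] <- NA
  if (anyDuplicated(id)) stop("duplicate individual ids in pedigree")
  unknown <- setdiff(stats::na.omit(c(sire, dam)), id)
  if (length(unknown))
    stop("parents absent from pedigree: ", paste(head(unknown, 5), collapse = ", "))
  ped <- data.frame(id = id, sire = sire, dam = dam,
                    stringsAsFactors = FALSE)
  if (!is.null(sex)) ped$sex <- as.character(sex)
  if (!is.null(generation)) ped$generation <- as.integer(generation)
  ped <- topo_sort_pedigree(ped)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

## Kahn's algorithm; errors with a member of the cycle if one exists.
topo_sort_pedigree <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  si <- ifelse(is.na(ped$sire), NA_integer_, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), NA_integer_, idx[ped$dam])
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in idx) {
    for (p in c(si[i], di[i])) if (!is.na(p)) {
      indeg[i] <- indeg[i] + 1L
      children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (w in children[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) < n) {
    cyc <- ped$id[setdiff(idx, out)]
    stop("pedigree contains a cycle involving: ",
         paste(head(cyc, 5), collapse = ", "))
  }
  ped[out, , drop = FALSE]
}

#' Read a pedigree TSV (id, sire, dam; 0 = unknown)
#' @param path File path.
#' @return A `pedigree`.
#' @export
read_pedigree <- function(path) {
  pd <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(pd)))
    stop("pedigree file needs columns id, sire, dam: ", path)
  pedigree(pd$id, pd$sire, pd$dam, sex = pd$sex, generation = pd$generation)
}

#' Construct a litter-size phenotype table
#'
#' Repeated records per sow: parity class (1--5, 5 = fifth and later
#' litters), herd--year--season level, Total Number Born and Number Born
#' Alive. `NBA <= TNB` is enforced.
#'
#' @param sow,parity,hys,tnb,nba Parallel vectors of records.
#' @return A `data.frame` of class `phenotype_table`.
#' @export
phenotype_table <- function(sow, parity, hys, tnb, nba) {
  parity <- as.integer(parity)
  if (any(parity < 1L | parity > 5L)) stop("parity class must be in 1..5")
  tnb <- as.numeric(tnb); nba <- as.numeric(nba)
  if (any(nba > tnb)) stop("NBA must not exceed TNB")
  ph <- data.frame(sow = as.character(sow), parity = parity,
                   hys = as.character(hys), tnb = tnb, nba = nba,
                   stringsAsFactors = FALSE)
  class(ph) <- c("phenotype_table", "data.frame")
  ph
}

#' Read a phenotype TSV (sow, parity, hys, tnb, nba)
#' @param path File path.
#' @return A `phenotype_table`.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sow", "parity", "hys", "tnb", "nba")
  if (!all(need %in% names(ph)))
    stop("phenotype file needs columns sow, parity, hys, tnb, nba: ", path)
  phenotype_table(ph$sow, ph$parity, ph$hys, ph$tnb, ph$nba)
}
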