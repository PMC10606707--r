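## Per-segment carrier/non-carrier scan: refit the repeatability model once
## per catalog segment with a carrier fixed effect at fixed variance
## components, one-sided p-values for depression (effect < 0), BH-FDR, and
## summaries/merged regions of the significant segments.

#' Scan catalog segments for carrier effects on litter size
#'
#' For each shared ROH segment the base mixed model (parity, and by default
#' herd--year--season, additive and permanent-environment terms; variance
#' components fixed) is extended by one fixed carrier-indicator column and
#' re-solved. The base system is factorized once and each segment is
#' handled by a bordering solve, which is algebraically identical to the
#' full refit. The effect is the carrier-minus-non-carrier contrast
#' (piglets); its one-sided p-value targets the alternative `effect < 0`
#' (homozygosity depresses litter size). Segments whose carrier status is
#' constant across phenotyped sows are skipped with a logged reason.
#'
#' The genome-wide heterozygosity covariate is excluded from the
#' per-segment models by default (`include_covariate = FALSE`); the
#' herd--year--season term is retained by default (`include_hys = TRUE`).
#'
#' @param catalog An `roh_catalog`.
#' @param phen A `phenotype_table`.
#' @param hinv Relationship inverse over all pedigree ids.
#' @param vc Variance components (held fixed across the scan).
#' @param traits Character vector of traits to scan (`"tnb"`, `"nba"`).
#' @param include_covariate Include the heterozygosity covariate in the
#'   per-segment models?
#' @param include_hys Keep the herd--year--season random term?
#' @param het Named per-sow heterozygosity (only used when
#'   `include_covariate`).
#' @param carrier_mat Optional precomputed [carrier_matrix()]; by default
#'   carriers are taken from the catalog's carrier sets.
#' @param df Degrees of freedom of the one-sided test (`Inf` = normal).
#' @return A `data.table` of scan records: one row per segment with, per
#'   trait, `effect_<trait>`, `se_<trait>`, `p_<trait>`, `q_<trait>`
#'   (BH-FDR), plus the segment coordinates and carrier counts. Skipped
#'   segments are kept with `NA` statistics and a `skip_reason`.
#' @export
scan_roh <- function(catalog, phen, hinv, vc,
                     traits = c("tnb", "nba"),
                     include_covariate = FALSE, include_hys = TRUE,
                     het = NULL, carrier_mat = NULL, df = Inf) {
  stopifnot(inherits(catalog, "roh_catalog"),
            inherits(phen, "phenotype_table"))
  segs <- data.table::copy(catalog$segments)
  m <- nrow(segs)
  out <- segs[, .(segment_id, chrom, start_bp, end_bp, start_idx, end_idx,
                  n_snps, n_carriers, carrier_frequency)]
  out[, skip_reason := NA_character_]
  sows <- unique(phen$sow)
  ## carrier status per sow and segment (constant across a sow's records)
  carrier_of <- function(s) {
    ind <- stats::setNames(numeric(length(sows)), sows)
    ind[intersect(catalog$carriers[[s]], sows)] <- 1
    ind
  }
  for (tr in traits) {
    spec <- model_spec(trait = tr, covariate = include_covariate,
                       carrier = FALSE, hys = include_hys, df = df)
    sys <- build_mme(phen, spec, hinv, vc, het = het)
    keep <- setdiff(seq_len(nrow(sys$C)), sys$aliased)
    C <- Matrix::forceSymmetric(sys$C[keep, keep, drop = FALSE])
    ch <- Matrix::Cholesky(C, LDL = FALSE, perm = TRUE)
    theta <- as.numeric(Matrix::solve(ch, sys$rhs[keep], system = "A"))
    s2e <- sys$vc["e"]
    y <- sys$y
    Mk <- sys$M[, keep, drop = FALSE]
    eff <- se <- rep(NA_real_, m)
    for (s in seq_len(m)) {
      ind <- carrier_of(s)
      z <- ind[phen$sow]
      nz <- sum(ind)
      if (nz == 0 || nz == length(sows)) {
        out$skip_reason[s] <- sprintf(
          "carrier status constant among phenotyped sows (%d/%d carriers)",
          nz, length(sows))
        next
      }
      cvec <- as.numeric(Matrix::crossprod(Mk, z)) / s2e
      dval <- sum(z) / s2e
      b2 <- sum(z * y) / s2e
      u <- as.numeric(Matrix::solve(ch, cvec, system = "A"))
      sval <- dval - sum(cvec * u)
      if (sval <= 1e-10) {
        out$skip_reason[s] <- "carrier column confounded with base model"
        next
      }
      eff[s] <- (b2 - sum(cvec * theta)) / sval
      se[s] <- sqrt(1 / sval)
    }
    p <- rep(NA_real_, m)
    ok <- !is.na(eff)
    if (any(ok)) p[ok] <- one_sided_p(eff[ok], se[ok], "less", df = df)
    q <- rep(NA_real_, m)
    if (any(ok)) q[ok] <- bh_fdr(p[ok])
    out[[paste0("effect_", tr)]] <- eff
    out[[paste0("se_", tr)]] <- se
    out[[paste0("p_", tr)]] <- p
    out[[paste0("q_", tr)]] <- q
  }
  data.table::setattr(out, "scan_params",
                      list(traits = traits,
                           include_covariate = include_covariate,
                           include_hys = include_hys, df = df,
                           vc = vc_vec(vc)))
  out[]
}

#' Benjamini--Hochberg step-up FDR adjustment
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @return Adjusted q-values (monotone in p rank, capped at 1), `q >= p`.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Summarize a scan record table
#'
#' Per-trait counts and proportions of segments below each significance
#' threshold, and per-chromosome tallies of significant segments (the
#' Manhattan-style summary).
#'
#' @param records A scan table from [scan_roh()].
#' @param alphas Significance thresholds.
#' @return A list with `counts` (data.table: trait, alpha, n, proportion,
#'   with proportions over non-skipped segments), `n_tested`, `n_skipped`,
#'   and `by_chrom` (per trait and chromosome, segments with `p < max
#'   (alphas)` down to each threshold).
#' @export
summarize_scan <- function(records, alphas = c(0.05, 0.01, 0.001)) {
  traits <- sub("^p_", "", grep("^p_", names(records), value = TRUE))
  counts <- data.table::rbindlist(lapply(traits, function(tr) {
    p <- records[[paste0("p_", tr)]]
    ok <- !is.na(p)
    data.table::data.table(trait = tr, alpha = alphas,
                           n = vapply(alphas, function(a) sum(p[ok] < a),
                                      integer(1L)),
                           proportion = vapply(alphas, function(a)
                             if (sum(ok)) sum(p[ok] < a) / sum(ok) else 0,
                             numeric(1L)))
  }))
  by_chrom <- data.table::rbindlist(lapply(traits, function(tr) {
    p <- records[[paste0("p_", tr)]]
    data.table::rbindlist(lapply(alphas, function(a) {
      sig <- records[!is.na(p) & p < a]
      if (!nrow(sig))
        return(data.table::data.table(trait = character(), alpha = numeric(),
                                      chrom = character(), n = integer()))
      sig[, .(trait = tr, alpha = a, n = .N), by = chrom][,
          .(trait, alpha, chrom, n)]
    }))
  }))
  list(counts = counts,
       n_tested = sum(!is.na(records[[paste0("p_", traits[1L])]])),
       n_skipped = sum(!is.na(records$skip_reason)),
       by_chrom = by_chrom)
}

#' Merge overlapping significant segments into regions
#'
#' Significant segments (one-sided `p < alpha` for the given trait) that
#' overlap or are bookended on a chromosome are merged into one region
#' carrying the minimum start, maximum end, the best (smallest) p-value and
#' the member segment ids.
#'
#' @param records A scan table from [scan_roh()].
#' @param trait Trait whose p-values define significance.
#' @param alpha Significance threshold (default 0.001).
#' @return A `data.table`: `chrom`, `start_bp`, `end_bp`, `best_p`,
#'   `n_segments`, `segment_ids` (comma-separated).
#' @export
merge_regions <- function(records, trait = "tnb", alpha = 0.001) {
  pcol <- paste0("p_", trait)
  if (!pcol %in% names(records)) stop("no scan results for trait ", trait)
  sig <- records[!is.na(records[[pcol]]) & records[[pcol]] < alpha]
  if (!nrow(sig))
    return(data.table::data.table(chrom = character(), start_bp = integer(),
                                  end_bp = integer(), best_p = numeric(),
                                  n_segments = integer(),
                                  segment_ids = character()))
  sig <- data.table::copy(sig)
  sig[, p_tmp := sig[[pcol]]]
  data.table::setorder(sig, chrom, start_bp, end_bp)
  out <- sig[, {
    ir <- IRanges::IRanges(start_bp, end_bp)
    red <- IRanges::reduce(ir)         # merges overlapping and bookended
    grp <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, red))
    .(start_bp = IRanges::start(red),
      end_bp = IRanges::end(red),
      best_p = as.numeric(tapply(p_tmp, grp, min)),
      n_segments = as.integer(tapply(p_tmp, grp, length)),
      segment_ids = as.character(tapply(segment_id, grp, paste,
                                        collapse = ",")))
  }, by = chrom]
  data.table::setorder(out, chrom, start_bp)
  out[]
}
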