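## Pedigree, gene-dropped genotypes and repeated litter-size phenotypes
## with the statistical structure the analysis assumes: founder haplotypes
## drawn from per-locus allele frequencies, Poisson crossovers at meiosis
## (so autozygosity shows up as runs of homozygosity), and phenotypes built
## from exactly the repeatability model the pipeline fits, plus optional
## planted carrier effects on chosen genomic intervals.

#' Simulation configuration
#'
#' Defaults emulate a closed sow herd of the size and structure of the
#' study populations the package is designed for: roughly 330 phenotyped
#' sows with 6 litters each, 18 autosomes of dense SNPs, a sustained
#' bottleneck (eight generations of 24 animals before the herd expands)
#' that accumulates enough background autozygosity for runs of
#' homozygosity to cover a quarter to two-fifths of the genome with a
#' per-sow heterozygosity spread of a few percent, variance components of
#' a low-heritability litter-size trait, and a positive heterozygosity
#' slope of about 0.055 piglets per percent.
#'
#' @param n_founders Number of founders (>= 4).
#' @param n_generations Number of non-founder generations (>= 0).
#' @param offspring_per_generation Individuals born per generation: a single
#'   count or one count per generation. The default keeps the herd small for
#'   six burn-in generations (sustained background inbreeding, as in a
#'   closed line) and then expands it for four generations to produce the
#'   phenotyped sows.
#' @param phenotyped_generations Number of final generations whose females
#'   carry litter records (`NULL` phenotypes every non-founder female).
#' @param mating_scheme `"random"`, `"circular"` or `"partial_fullsib"`.
#' @param inbreeding_intensity In `[0, 1]`: for `partial_fullsib`, the
#'   probability that a litter's parents are full sibs; ignored otherwise.
#' @param n_chromosomes,snps_per_chromosome,chromosome_length_bp Genome
#'   layout (all chromosomes share one length).
#' @param founder_maf_range Founder minor-allele-frequency range in
#'   `(0, 0.5]`.
#' @param recomb_rate Expected crossovers per chromosome per meiosis.
#' @param varcomp_true Named vector `c(a=, p=, h=, e=)` of true variance
#'   components (squared piglets).
#' @param additive_model `"genomic"` (default): breeding values are sums of
#'   infinitesimal marker effects, so their covariance tracks the realized
#'   genomic relationships the single-step analysis models; `"pedigree"`:
#'   breeding values follow the pedigree recursion with Mendelian-sampling
#'   variance `sigma2_a (0.5 - 0.25 (F_s + F_d))`, independent of the
#'   markers.
#' @param het_slope_true True heterozygosity slope (piglets per percent).
#' @param parity_effects Five parity-class means (piglets).
#' @param n_hys Number of herd--year--season levels.
#' @param records_per_sow Litters per phenotyped sow.
#' @param mortality_rate Mean of the non-negative count subtracted from TNB
#'   to produce NBA.
#' @param planted_effects `NULL` or a `data.frame` with columns `chrom`,
#'   `start_bp`, `end_bp`, `effect` (piglets added to carriers' records;
#'   carriers are the sows homozygous across the whole interval).
#' @param seed Integer seed; the entire simulation is a deterministic
#'   function of the configuration.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_founders = 24L,
                       n_generations = 12L,
                       offspring_per_generation = c(rep(24L, 8L),
                                                    rep(165L, 4L)),
                       phenotyped_generations = 4L,
                       mating_scheme = c("partial_fullsib", "random",
                                         "circular"),
                       inbreeding_intensity = 0.05,
                       n_chromosomes = 18L,
                       snps_per_chromosome = 3192L,
                       chromosome_length_bp = 125e6,
                       founder_maf_range = c(0.05, 0.5),
                       recomb_rate = 1.25,
                       varcomp_true = c(a = 0.145, p = 0.366, h = 0.170,
                                        e = 2.901),
                       additive_model = c("genomic", "pedigree"),
                       het_slope_true = 0.055,
                       parity_effects = c(7.5, 8.0, 8.2, 8.1, 7.8),
                       n_hys = 96L,
                       records_per_sow = 6L,
                       mortality_rate = 0.26,
                       planted_effects = NULL,
                       seed = 1L) {
  mating_scheme <- match.arg(mating_scheme)
  n_generations <- as.integer(n_generations)
  offspring_per_generation <- as.integer(offspring_per_generation)
  if (n_generations > 0L)
    offspring_per_generation <- rep_len(offspring_per_generation,
                                        n_generations)
  cfg <- list(n_founders = as.integer(n_founders),
              n_generations = n_generations,
              offspring_per_generation = offspring_per_generation,
              phenotyped_generations =
                if (is.null(phenotyped_generations)) NULL else
                  min(as.integer(phenotyped_generations),
                      max(n_generations, 1L)),
              mating_scheme = mating_scheme,
              inbreeding_intensity = inbreeding_intensity,
              n_chromosomes = as.integer(n_chromosomes),
              snps_per_chromosome = as.integer(snps_per_chromosome),
              chromosome_length_bp = as.numeric(chromosome_length_bp),
              founder_maf_range = as.numeric(founder_maf_range),
              recomb_rate = recomb_rate,
              varcomp_true = vc_vec(varcomp_true),
              additive_model = match.arg(additive_model),
              het_slope_true = het_slope_true,
              parity_effects = as.numeric(parity_effects),
              n_hys = as.integer(n_hys),
              records_per_sow = as.integer(records_per_sow),
              mortality_rate = mortality_rate,
              planted_effects = planted_effects,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_founders < 4L) stop("n_founders must be >= 4")
    if (n_generations < 0L) stop("n_generations must be >= 0")
    if (n_generations > 0L && any(offspring_per_generation < 1L))
      stop("offspring_per_generation must be positive")
    if (!is.null(phenotyped_generations) && phenotyped_generations < 1L)
      stop("phenotyped_generations must be positive")
    if (any(c(n_chromosomes, snps_per_chromosome) < 1L))
      stop("genome layout counts must be positive")
    if (chromosome_length_bp < snps_per_chromosome)
      stop("chromosome_length_bp too small for the marker count")
    if (length(founder_maf_range) != 2L ||
        founder_maf_range[1L] <= 0 || founder_maf_range[2L] > 0.5 ||
        founder_maf_range[1L] > founder_maf_range[2L])
      stop("founder_maf_range must lie within (0, 0.5]")
    if (recomb_rate < 0) stop("recomb_rate must be non-negative")
    if (any(varcomp_true < 0)) stop("variance components must be non-negative")
    if (inbreeding_intensity < 0 || inbreeding_intensity > 1)
      stop("inbreeding_intensity must be in [0, 1]")
    if (length(parity_effects) != 5L)
      stop("parity_effects must have 5 values")
    if (n_hys < 1L || records_per_sow < 1L)
      stop("n_hys and records_per_sow must be positive")
    if (mortality_rate < 0) stop("mortality_rate must be non-negative")
    if (!is.null(planted_effects)) {
      pe <- planted_effects
      need <- c("chrom", "start_bp", "end_bp", "effect")
      if (!all(need %in% names(pe)))
        stop("planted_effects needs columns chrom, start_bp, end_bp, effect")
      if (any(pe$start_bp < 1 | pe$end_bp > chromosome_length_bp |
              pe$start_bp > pe$end_bp))
        stop("planted intervals must lie inside their chromosome")
      if (!all(as.character(pe$chrom) %in% as.character(seq_len(n_chromosomes))))
        stop("planted intervals reference unknown chromosomes")
    }
  })
  invisible(cfg)
}

#' Simulate a pedigree
#'
#' Founders (generation 0, alternating sexes) followed by
#' `n_generations` generations of litters of four (two of each sex, sexes
#' alternating within the sibship). Parents are drawn from the previous
#' generation under the configured mating scheme; under `partial_fullsib`
#' each litter's parents are a full-sib brother--sister pair with
#' probability `inbreeding_intensity`, random otherwise, so the knob
#' monotonically increases the mean inbreeding of the last generation.
#'
#' @param cfg A [sim_config()].
#' @return A [pedigree()] with `sex` and `generation` columns, parents
#'   before offspring.
#' @export
sim_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  nf <- cfg$n_founders
  id <- sprintf("G0_%04d", seq_len(nf))
  sex <- rep(c("M", "F"), length.out = nf)
  if (sum(sex == "M") < 2L || sum(sex == "F") < 2L)
    stop("need at least 2 founders of each sex")
  ped <- data.frame(id = id, sire = NA_character_, dam = NA_character_,
                    sex = sex, generation = 0L, stringsAsFactors = FALSE)
  litter_of <- stats::setNames(rep(NA_integer_, nf), id)   # litter tag
  for (g in seq_len(cfg$n_generations)) {
    prev <- ped[ped$generation == g - 1L, ]
    males <- prev$id[prev$sex == "M"]
    females <- prev$id[prev$sex == "F"]
    if (length(males) < 1L || length(females) < 1L)
      stop("generation ", g - 1L, " lacks parents of one sex")
    n_off <- cfg$offspring_per_generation[g]
    n_lit <- ceiling(n_off / 4L)
    ## candidate full-sib pairs: litters of the previous generation holding
    ## both sexes
    prev_lit <- litter_of[prev$id]
    sib_pairs <- NULL
    if (any(!is.na(prev_lit))) {
      spl <- split(prev$id, prev_lit)
      spl <- Filter(function(s) any(prev$sex[match(s, prev$id)] == "M") &&
                      any(prev$sex[match(s, prev$id)] == "F"), spl)
      sib_pairs <- spl
    }
    sires <- dams <- character(n_lit)
    for (l in seq_len(n_lit)) {
      use_sib <- switch(cfg$mating_scheme,
        partial_fullsib = length(sib_pairs) > 0L &&
          runif(1) < cfg$inbreeding_intensity,
        random = FALSE,
        circular = FALSE)
      if (use_sib) {
        fam <- sib_pairs[[sample.int(length(sib_pairs), 1L)]]
        fsex <- prev$sex[match(fam, prev$id)]
        sires[l] <- sample(fam[fsex == "M"], 1L)
        dams[l] <- sample(fam[fsex == "F"], 1L)
      } else if (cfg$mating_scheme == "circular" && g > 1L &&
                 length(sib_pairs) >= 2L) {
        ## sire from litter l, dam from litter l+1 (mod), among previous
        ## generation litters
        ls <- sib_pairs[[(l - 1L) %% length(sib_pairs) + 1L]]
        ld <- sib_pairs[[l %% length(sib_pairs) + 1L]]
        ssex <- prev$sex[match(ls, prev$id)]
        dsex <- prev$sex[match(ld, prev$id)]
        sires[l] <- sample(ls[ssex == "M"], 1L)
        dams[l] <- sample(ld[dsex == "F"], 1L)
      } else {
        sires[l] <- if (length(males) == 1L) males else sample(males, 1L)
        dams[l] <- if (length(females) == 1L) females else sample(females, 1L)
      }
    }
    off_id <- sprintf("G%d_%04d", g, seq_len(n_off))
    off_lit <- rep(seq_len(n_lit), each = 4L)[seq_len(n_off)]
    off_sex <- rep(c("M", "F"), length.out = n_off)
    ped <- rbind(ped, data.frame(id = off_id, sire = sires[off_lit],
                                 dam = dams[off_lit], sex = off_sex,
                                 generation = g, stringsAsFactors = FALSE))
    litter_of[off_id] <- off_lit + 1000L * g
  }
  pedigree(ped$id, ped$sire, ped$dam, sex = ped$sex,
           generation = ped$generation)
}

#' Gene-drop genotypes down a pedigree
#'
#' Founder haplotype alleles are drawn per locus at a frequency uniform in
#' `founder_maf_range`; marker positions are uniform along each chromosome.
#' Every non-founder inherits one recombined gamete per parent: the
#' crossover count is Poisson with mean `recomb_rate`, positions uniform,
#' no interference. Genotypes are coded 0/1/2 copies of the counted
#' (founder-minor) allele; there are no missing values.
#'
#' @param ped A [pedigree()] (parents before offspring, as produced by
#'   [sim_pedigree()]).
#' @param cfg A [sim_config()].
#' @param ids Samples to return (default: all pedigree members).
#' @return A complete `genotype_dataset`.
#' @export
sim_genotypes <- function(ped, cfg, ids = ped$id) {
  stopifnot(inherits(ped, "pedigree"), inherits(cfg, "sim_config"))
  check_parents_first(ped)
  set.seed(cfg$seed + 1L)
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  m <- cfg$snps_per_chromosome
  L <- cfg$chromosome_length_bp
  calls <- matrix(0L, n, m * cfg$n_chromosomes)
  map_list <- vector("list", cfg$n_chromosomes)
  for (ch in seq_len(cfg$n_chromosomes)) {
    pos <- sort(sample.int(L, m))
    p <- runif(m, cfg$founder_maf_range[1L], cfg$founder_maf_range[2L])
    hap1 <- matrix(0L, n, m)
    hap2 <- matrix(0L, n, m)
    for (i in seq_len(n)) {
      if (si[i] == 0L && di[i] == 0L) {
        hap1[i, ] <- rbinom(m, 1L, p)
        hap2[i, ] <- rbinom(m, 1L, p)
      } else {
        if (si[i] == 0L || di[i] == 0L)
          stop("individual ", ped$id[i],
               " has exactly one known parent; gene dropping needs both or none")
        hap1[i, ] <- gamete(hap1[si[i], ], hap2[si[i], ], pos, L,
                            cfg$recomb_rate)
        hap2[i, ] <- gamete(hap1[di[i], ], hap2[di[i], ], pos, L,
                            cfg$recomb_rate)
      }
    }
    calls[, (ch - 1L) * m + seq_len(m)] <- hap1 + hap2
    map_list[[ch]] <- data.frame(
      marker_id = sprintf("snp_%d_%d", ch, seq_len(m)),
      chrom = as.character(ch), pos_bp = pos,
      a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  }
  gd <- genotype_dataset(calls, do.call(rbind, map_list), ped$id,
                         provenance = "simulated by gene dropping")
  if (!identical(ids, ped$id)) gd <- subset_samples(gd, ids)
  gd
}

## one recombined gamete from a parent's two haplotypes
gamete <- function(h1, h2, pos, L, recomb_rate) {
  k <- rpois(1L, recomb_rate)
  start <- sample.int(2L, 1L) - 1L
  if (k == 0L) return(if (start == 0L) h1 else h2)
  cx <- sort(runif(k, 0, L))
  phase <- (start + findInterval(pos, cx)) %% 2L
  ifelse(phase == 0L, h1, h2)
}

check_parents_first <- function(ped) {
  idx <- seq_len(nrow(ped)); names(idx) <- ped$id
  for (col in c("sire", "dam")) {
    p <- ped[[col]]
    known <- !is.na(p)
    late <- which(known & idx[p] >= idx)
    if (length(late))
      stop("pedigree not sorted parents-before-offspring at (",
           ped$id[late[1L]], ", ", ped$sire[late[1L]], ", ",
           ped$dam[late[1L]], ")")
  }
  invisible(TRUE)
}

#' Simulate repeated litter-size records
#'
#' For every phenotyped sow and litter the record is built from exactly the
#' model the pipeline fits: parity-class mean, heterozygosity slope times
#' the sow's heterozygosity percentage (computed by
#' [heterozygosity_percent()], the same operation the analysis uses),
#' a herd--year--season effect (levels assigned uniformly at random),
#' pedigree-structured additive value, permanent sow effect, planted
#' carrier effects, and a residual. TNB is the simulated value rounded to a
#' non-negative integer; NBA is TNB minus a Poisson count (so `NBA <= TNB`
#' by construction). Phenotyped sows are the non-founder females present in
#' `gd`.
#'
#' @param ped A [pedigree()] with `sex` (and optionally `generation`).
#' @param gd A complete `genotype_dataset` covering at least the phenotyped
#'   sows.
#' @param cfg A [sim_config()].
#' @return A `phenotype_table` with attribute `truth`: a list holding the
#'   latent additive values `u`, permanent effects `p_eff`, herd--year--
#'   season effects `hys_eff`, heterozygosity `het`, the per-segment
#'   carrier indicators for planted intervals, and the continuous records
#'   before rounding.
#' @export
sim_phenotypes <- function(ped, gd, cfg) {
  stopifnot(inherits(ped, "pedigree"), inherits(gd, "genotype_dataset"),
            inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  vc <- cfg$varcomp_true
  founder <- is.na(ped$sire) & is.na(ped$dam)
  sows <- ped$id[ped$sex == "F" & !founder]
  if (!is.null(cfg$phenotyped_generations) && !is.null(ped$generation)) {
    gmin <- max(ped$generation) - cfg$phenotyped_generations + 1L
    sows <- intersect(sows, ped$id[ped$generation >= gmin])
  }
  sows <- intersect(sows, gd$samples)
  if (!length(sows)) stop("no phenotyped sows: need non-founder females in gd")
  if (identical(cfg$additive_model, "pedigree")) {
    ## additive values down the pedigree, Mendelian-sampling variance
    ## shrunk by parental inbreeding
    Fp <- inbreeding(ped)
    n <- nrow(ped)
    idx <- seq_len(n); names(idx) <- ped$id
    si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
    di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
    u <- numeric(n)
    for (i in seq_len(n)) {
      if (si[i] == 0L && di[i] == 0L) {
        u[i] <- rnorm(1L, 0, sqrt(vc["a"]))
      } else {
        msv <- vc["a"] * (1 - 0.25 * (1 + Fp[si[i]]) - 0.25 * (1 + Fp[di[i]]))
        u[i] <- 0.5 * (u[si[i]] + u[di[i]]) + rnorm(1L, 0, sqrt(max(msv, 0)))
      }
    }
    names(u) <- ped$id
  } else {
    ## genomic infinitesimal model: breeding values are sums of marker
    ## effects, centered and scaled by the base-population (founder when
    ## available, otherwise overall) allele frequencies so founders have
    ## variance sigma2_a and relatives covary by realized genomic
    ## relationship
    founders_in <- intersect(ped$id[founder], gd$samples)
    freq_base <- if (length(founders_in) >= 4L)
      colMeans(gd$calls[founders_in, , drop = FALSE]) / 2 else
      colMeans(gd$calls) / 2
    poly <- freq_base > 0 & freq_base < 1
    scale2pq <- 2 * sum(freq_base[poly] * (1 - freq_base[poly]))
    beta <- rnorm(sum(poly), 0, sqrt(vc["a"] / scale2pq))
    Zc <- sweep(gd$calls[, poly, drop = FALSE], 2L, 2 * freq_base[poly])
    u <- drop(Zc %*% beta)
    names(u) <- gd$samples
  }
  het <- heterozygosity_percent(subset_samples(gd, sows))
  p_eff <- stats::setNames(rnorm(length(sows), 0, sqrt(vc["p"])), sows)
  hys_eff <- stats::setNames(rnorm(cfg$n_hys, 0, sqrt(vc["h"])),
                             sprintf("hys%03d", seq_len(cfg$n_hys)))
  ## planted carrier indicators from the genotypes themselves
  planted <- cfg$planted_effects
  carrier_ind <- NULL
  planted_sum <- stats::setNames(numeric(length(sows)), sows)
  if (!is.null(planted) && nrow(planted)) {
    carrier_ind <- matrix(0L, length(sows), nrow(planted),
                          dimnames = list(sows, NULL))
    gsow <- subset_samples(gd, sows)
    for (s in seq_len(nrow(planted))) {
      jj <- which(gsow$map$chrom == as.character(planted$chrom[s]) &
                    gsow$map$pos_bp >= planted$start_bp[s] &
                    gsow$map$pos_bp <= planted$end_bp[s])
      if (!length(jj))
        stop("planted interval ", s, " spans no marker")
      carr <- rowSums(gsow$calls[, jj, drop = FALSE] == 1L) == 0L
      carrier_ind[, s] <- as.integer(carr)
      planted_sum <- planted_sum + carrier_ind[, s] * planted$effect[s]
    }
  }
  nrec <- cfg$records_per_sow
  rec_sow <- rep(sows, each = nrec)
  parity <- rep(seq_len(nrec), times = length(sows))
  pclass <- pmin(parity, 5L)
  hys <- sample(names(hys_eff), length(rec_sow), replace = TRUE)
  e <- rnorm(length(rec_sow), 0, sqrt(vc["e"]))
  y <- cfg$parity_effects[pclass] + cfg$het_slope_true * het[rec_sow] +
    hys_eff[hys] + u[rec_sow] + p_eff[rec_sow] + planted_sum[rec_sow] + e
  tnb <- pmax(0, round(y))
  losses <- rpois(length(y), cfg$mortality_rate)
  nba <- pmax(0, tnb - losses)
  ph <- phenotype_table(rec_sow, pclass, hys, tnb, nba)
  attr(ph, "truth") <- list(u = u, p_eff = p_eff, hys_eff = hys_eff,
                            het = het, carrier_ind = carrier_ind,
                            y_continuous = y, sows = sows)
  ph
}

#' Simulate a complete analysis-ready dataset
#'
#' Runs [sim_pedigree()], [sim_genotypes()] and [sim_phenotypes()] under
#' one configuration. The returned genotype dataset is restricted to the
#' phenotyped sows by default (only sows are genotyped in the sow-herd
#' design this emulates); `genotyped = "all"` returns every pedigree
#' member, which is what Mendelian-consistency checks need.
#'
#' @param cfg A [sim_config()].
#' @param genotyped `"sows"` or `"all"`.
#' @return A list with `pedigree`, `genotypes`, `phenotypes`, `truth` and
#'   the `config`.
#' @export
simulate_dataset <- function(cfg, genotyped = c("sows", "all")) {
  genotyped <- match.arg(genotyped)
  ped <- sim_pedigree(cfg)
  gd_all <- sim_genotypes(ped, cfg)
  phen <- sim_phenotypes(ped, gd_all, cfg)
  truth <- attr(phen, "truth")
  gd <- if (genotyped == "sows") subset_samples(gd_all, truth$sows) else gd_all
  list(pedigree = ped, genotypes = gd, phenotypes = phen, truth = truth,
       config = cfg)
}

#' Write a simulated dataset as an on-disk fixture bundle
#'
#' Writes PLINK text (`.ped`/`.map`) and binary (`.bed`/`.bim`/`.fam`)
#' genotypes for the phenotyped sows, a pedigree TSV (0 = unknown parent),
#' a phenotype TSV and a truth TSV. Identical configurations produce
#' byte-identical files.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Writable output directory (created if absent).
#' @param prefix File-name prefix (default `"sim"`).
#' @return Invisibly, a named vector of the paths written.
#' @export
fixture_bundle <- function(cfg, out_dir, prefix = "sim") {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir)
  sim <- simulate_dataset(cfg, genotyped = "sows")
  px <- file.path(out_dir, prefix)
  write_plink(sim$genotypes, px, "text")
  write_plink(sim$genotypes, px, "binary")
  ped_path <- paste0(px, "_pedigree.tsv")
  pd <- sim$pedigree
  data.table::fwrite(data.table::data.table(
    id = pd$id,
    sire = ifelse(is.na(pd$sire), "0", pd$sire),
    dam = ifelse(is.na(pd$dam), "0", pd$dam),
    sex = pd$sex, generation = pd$generation), ped_path, sep = "\t")
  phen_path <- paste0(px, "_phenotypes.tsv")
  data.table::fwrite(data.table::as.data.table(
    sim$phenotypes[, c("sow", "parity", "hys", "tnb", "nba")]),
    phen_path, sep = "\t")
  truth_path <- paste0(px, "_truth.tsv")
  tr <- sim$truth
  td <- data.table::data.table(sow = tr$sows,
                               u = unname(tr$u[tr$sows]),
                               p_eff = unname(tr$p_eff[tr$sows]),
                               het_pct = unname(tr$het[tr$sows]))
  if (!is.null(tr$carrier_ind))
    for (s in seq_len(ncol(tr$carrier_ind)))
      td[[sprintf("carrier_%d", s)]] <- tr$carrier_ind[, s]
  data.table::fwrite(td, truth_path, sep = "\t")
  invisible(c(ped = paste0(px, ".ped"), map = paste0(px, ".map"),
              bed = paste0(px, ".bed"), bim = paste0(px, ".bim"),
              fam = paste0(px, ".fam"), pedigree = ped_path,
              phenotypes = phen_path, truth = truth_path))
}
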