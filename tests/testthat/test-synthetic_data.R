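test_that("a zero-generation configuration yields founders only", {
  cfg <- sim_config(n_founders = 10, n_generations = 0, seed = 3)
  ped <- sim_pedigree(cfg)
  expect_equal(nrow(ped), 10L)
  expect_true(all(is.na(ped$sire)) && all(is.na(ped$dam)))
  expect_setequal(unique(ped$sex), c("M", "F"))
})

test_that("identical configurations reproduce identical datasets", {
  cfg <- tiny_sim_config(seed = 11)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(tiny_sim_config(seed = 11))
  expect_identical(s1$pedigree, s2$pedigree)
  expect_identical(s1$genotypes$calls, s2$genotypes$calls)
  expect_identical(s1$phenotypes, s2$phenotypes)
  s3 <- simulate_dataset(tiny_sim_config(seed = 12))
  expect_false(identical(s1$genotypes$calls, s3$genotypes$calls))
})

test_that("the inbreeding-intensity knob raises last-generation inbreeding", {
  f_last <- vapply(c(0, 0.5, 1), function(lambda) {
    cfg <- sim_config(n_founders = 16, n_generations = 3,
                      offspring_per_generation = 40,
                      mating_scheme = "partial_fullsib",
                      inbreeding_intensity = lambda,
                      n_chromosomes = 1, snps_per_chromosome = 20,
                      chromosome_length_bp = 1e6, seed = 21)
    ped <- sim_pedigree(cfg)
    ## oracle: recursive kinship, not the package's tabular A
    K <- kinship_oracle(ped)
    mean(diag(K)[ped$generation == 3] - 1)
  }, numeric(1))
  expect_gt(f_last[2], f_last[1])
  expect_gt(f_last[3], f_last[2])
  expect_gt(f_last[3], 0.15)
})

test_that("gene dropping is Mendelian-consistent at every locus", {
  cfg <- tiny_sim_config(seed = 31)
  ped <- sim_pedigree(cfg)
  gd <- sim_genotypes(ped, cfg)
  idx <- stats::setNames(seq_len(nrow(ped)), ped$id)
  ok <- TRUE
  for (i in which(!is.na(ped$sire))) {
    g <- gd$calls[i, ]
    gs <- gd$calls[idx[ped$sire[i]], ]
    gdm <- gd$calls[idx[ped$dam[i]], ]
    ## transmitted allele from a parent with dosage 0 must be 0, dosage 2
    ## must be 1; child dosage must lie between the transmissible bounds
    lo <- (gs == 2) + (gdm == 2)
    hi <- 2 - (gs == 0) - (gdm == 0)
    if (any(g < lo | g > hi)) { ok <- FALSE; break }
  }
  expect_true(ok)
  expect_false(anyNA(gd$calls))
})

test_that("without recombination chromosomes are intact founder haplotypes", {
  cfg <- sim_config(n_founders = 4, n_generations = 3,
                    offspring_per_generation = 20,
                    mating_scheme = "partial_fullsib",
                    inbreeding_intensity = 1,
                    n_chromosomes = 1, snps_per_chromosome = 60,
                    chromosome_length_bp = 1e6, recomb_rate = 0, seed = 41)
  ped <- sim_pedigree(cfg)
  gd <- sim_genotypes(ped, cfg)
  ## with 4 founders there are 8 founder haplotypes; every individual's
  ## chromosome genotype is a sum of two intact founder haplotypes, so the
  ## number of distinct genotype vectors is bounded by the number of
  ## unordered haplotype pairs among those transmitted
  n_distinct <- nrow(unique(gd$calls))
  expect_lte(n_distinct, choose(8, 2) + 8)
  ## fully homozygous chromosomes occur in an intense full-sib line and are
  ## single runs spanning the whole chromosome
  runs <- detect_runs(gd, min_snps = cfg$snps_per_chromosome)
  expect_gt(nrow(runs), 0)
  expect_true(all(runs$n_snps == cfg$snps_per_chromosome))
})

test_that("inbred matings raise ROH genome coverage over random mating", {
  mk <- function(scheme, lambda, seed) {
    cfg <- sim_config(n_founders = 20, n_generations = 3,
                      offspring_per_generation = 40,
                      mating_scheme = scheme, inbreeding_intensity = lambda,
                      n_chromosomes = 2, snps_per_chromosome = 150,
                      chromosome_length_bp = 5e7, seed = seed)
    sim <- simulate_dataset(cfg)
    runs <- detect_runs(sim$genotypes)
    mean(summarize_catalog(runs, sim$genotypes)$coverage_pct)
  }
  cov_rand <- mean(vapply(1:3, function(s) mk("random", 0, s), numeric(1)))
  cov_fs <- mean(vapply(1:3, function(s) mk("partial_fullsib", 0.9, s),
                        numeric(1)))
  expect_gt(cov_fs, cov_rand)
})

test_that("degenerate variances reduce records to the parity effects", {
  cfg <- tiny_sim_config(seed = 51,
                         varcomp_true = c(a = 0, p = 0, h = 0, e = 0),
                         het_slope_true = 0, mortality_rate = 0,
                         parity_effects = c(8, 9, 10, 9, 8))
  sim <- simulate_dataset(cfg)
  ph <- sim$phenotypes
  expect_equal(ph$tnb, c(8, 9, 10, 9, 8)[ph$parity])
  expect_equal(ph$nba, ph$tnb)
})

test_that("records respect NBA <= TNB and sows resolve everywhere", {
  cfg <- tiny_sim_config(seed = 61)
  sim <- simulate_dataset(cfg)
  ph <- sim$phenotypes
  expect_true(all(ph$nba <= ph$tnb))
  expect_true(all(ph$tnb >= 0))
  expect_true(all(ph$sow %in% sim$genotypes$samples))
  expect_true(all(ph$sow %in% sim$pedigree$id))
  expect_equal(sort(unique(ph$parity)), 1:4)
})

test_that("sow records recover the simulated heterozygosity slope", {
  ## pooled regression of record means on heterozygosity over replicates
  slopes <- ses <- numeric(4)
  for (r in 1:4) {
    cfg <- sim_config(n_founders = 30, n_generations = 3,
                      offspring_per_generation = 80,
                      n_chromosomes = 3, snps_per_chromosome = 150,
                      chromosome_length_bp = 5e7,
                      het_slope_true = 0.055, n_hys = 24, seed = 70 + r)
    sim <- simulate_dataset(cfg)
    agg <- aggregate(tnb ~ sow, data = sim$phenotypes, FUN = mean)
    agg$het <- sim$truth$het[agg$sow]
    fit <- summary(lm(tnb ~ het, data = agg))$coefficients
    slopes[r] <- fit["het", "Estimate"]
    ses[r] <- fit["het", "Std. Error"]
  }
  pooled <- mean(slopes)
  pooled_se <- sqrt(sum(ses^2)) / length(ses)
  expect_lt(abs(pooled - 0.055), 2 * pooled_se)
})

test_that("a planted effect shows up as the carrier group-mean difference", {
  ## truth-based contrast: zero slope isolates the planted effect; the
  ## default deep-pedigree structure supplies mid-frequency shared segments
  diffs <- freqs <- numeric(4)
  for (r in 1:4) {
    base <- list(n_chromosomes = 2, snps_per_chromosome = 200,
                 chromosome_length_bp = 5e7, het_slope_true = 0,
                 seed = 80 + r)
    cfg0 <- do.call(sim_config, base)
    ped <- sim_pedigree(cfg0)
    gd <- sim_genotypes(ped, cfg0)
    sows <- ped$id[ped$sex == "F" & !is.na(ped$sire)]
    gds <- subset_samples(gd, sows)
    catal <- build_catalog(detect_runs(gds), gds, 0.05, 0.95)
    seg <- catal$segments[which.min(abs(catal$segments$carrier_frequency - 0.4))]
    cfg <- do.call(sim_config, c(base, list(planted_effects = data.frame(
      chrom = seg$chrom, start_bp = seg$start_bp,
      end_bp = seg$end_bp, effect = -0.6))))
    phen <- sim_phenotypes(ped, gd, cfg)
    tr <- attr(phen, "truth")
    carrier <- tr$carrier_ind[phen$sow, 1]
    freqs[r] <- mean(tr$carrier_ind[, 1])
    diffs[r] <- mean(phen$tnb[carrier == 1]) - mean(phen$tnb[carrier == 0])
  }
  expect_true(all(freqs > 0.1 & freqs < 0.9))
  expect_equal(mean(diffs), -0.6, tolerance = 0.35)
})

test_that("planted intervals must contain at least one marker", {
  cfg <- tiny_sim_config(seed = 91)
  ped <- sim_pedigree(cfg)
  gd <- sim_genotypes(ped, cfg)
  pos <- gd$map$pos_bp[gd$map$chrom == "1"]
  gap <- which.max(diff(pos))
  cfg2 <- tiny_sim_config(seed = 91, planted_effects = data.frame(
    chrom = "1", start_bp = pos[gap] + 1, end_bp = pos[gap + 1] - 1,
    effect = -1))
  expect_error(sim_phenotypes(ped, gd, cfg2), "no marker")
})

test_that("simulated additive values track the pedigree variance structure", {
  ## founders' u variance ~ sigma2_a; inbred individuals scaled by 1 + F
  cfg <- sim_config(n_founders = 300, n_generations = 1,
                    offspring_per_generation = 100,
                    n_chromosomes = 1, snps_per_chromosome = 30,
                    chromosome_length_bp = 1e6,
                    varcomp_true = c(a = 1, p = 0, h = 0, e = 0.01),
                    additive_model = "pedigree", seed = 101)
  sim <- simulate_dataset(cfg)
  u <- sim$truth$u
  founders <- sim$pedigree$id[sim$pedigree$generation == 0]
  expect_equal(var(u[founders]), 1, tolerance = 0.3)
})

test_that("unsorted pedigrees are rejected by gene dropping", {
  ped <- pedigree(c("a", "b", "c"), c(NA, NA, "a"), c(NA, NA, "b"))
  bad <- ped[c(3, 1, 2), ]
  class(bad) <- class(ped)
  cfg <- tiny_sim_config(seed = 110)
  expect_error(sim_genotypes(bad, cfg), "parents-before-offspring")
})

test_that("fixture bundles round-trip and pass QC untouched", {
  cfg <- sim_config(n_founders = 8, n_generations = 2,
                    offspring_per_generation = 16, n_chromosomes = 2,
                    snps_per_chromosome = 50, chromosome_length_bp = 1e7,
                    n_hys = 4, records_per_sow = 3, seed = 121)
  dir1 <- withr::local_tempdir()
  paths <- fixture_bundle(cfg, dir1)
  expect_true(all(file.exists(paths)))
  gd_bin <- read_plink(file.path(dir1, "sim"), "binary")
  sim <- simulate_dataset(cfg)
  expect_equal(gd_bin$calls, sim$genotypes$calls)
  ped_back <- read_pedigree(paths["pedigree"])
  expect_setequal(ped_back$id, sim$pedigree$id)
  phen_back <- read_phenotypes(paths["phenotypes"])
  expect_equal(phen_back$tnb, sim$phenotypes$tnb)
  ## QC on complete simulated data excludes nothing
  qc <- qc_filter(gd_bin, autosomes = as.character(1:2))
  expect_equal(dim(qc$calls), dim(gd_bin$calls))
  ## same seed gives byte-identical files
  dir2 <- withr::local_tempdir()
  paths2 <- fixture_bundle(cfg, dir2)
  for (k in names(paths))
    expect_identical(unname(tools::md5sum(paths[k])),
                     unname(tools::md5sum(paths2[k])))
})
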