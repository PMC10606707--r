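## Independent brute-force oracles and small fixture builders shared by the
## test files. Oracles deliberately avoid the code paths they check.

## Brute force ROH scanner: checks every (start, end) pair of a 0/1/2 vector
## for all-homozygous content and keeps maximal windows of >= min_snps.
brute_runs_one <- function(g, min_snps) {
  n <- length(g)
  hom <- g != 1L
  out <- NULL
  for (s in seq_len(n)) for (e in s:n) {
    if (!all(hom[s:e])) next
    maximal <- (s == 1L || !hom[s - 1L]) && (e == n || !hom[e + 1L])
    if (maximal && (e - s + 1L) >= min_snps)
      out <- rbind(out, data.frame(start = s, end = e))
  }
  if (is.null(out)) data.frame(start = integer(), end = integer()) else out
}

## Recursive-kinship oracle: phi(i, j) with memoization; a(i,j) = 2 phi.
kinship_oracle <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  memo <- new.env(hash = TRUE)
  phi <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    key <- paste(i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- if (i == j) 0.5 * (1 + phi(si[i], di[i])) else
      0.5 * (phi(i, si[j]) + phi(i, di[j]))   # j later-born than i
    memo[[key]] <- val
    val
  }
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) K[i, j] <- K[j, i] <- phi(i, j)
  2 * K
}

## Interval union oracle: total covered length under end - start spans.
union_length_oracle <- function(starts, ends) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  tot <- 0; cs <- starts[1L]; ce <- ends[1L]
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] <= ce) ce <- max(ce, ends[i])
    else { tot <- tot + (ce - cs); cs <- starts[i]; ce <- ends[i] }
  }
  tot + (ce - cs)
}

## Dense GLS oracle for the repeatability model.
gls_oracle <- function(sys, hinv) {
  X <- as.matrix(sys$M[, sys$blocks$fixed, drop = FALSE])
  n <- nrow(X)
  vc <- sys$vc
  V <- vc["e"] * diag(n)
  if (!is.null(sys$blocks$hys)) {
    Th <- as.matrix(sys$M[, sys$blocks$hys, drop = FALSE])
    V <- V + vc["h"] * tcrossprod(Th)
  }
  if (!is.null(sys$blocks$u)) {
    Z <- as.matrix(sys$M[, sys$blocks$u, drop = FALSE])
    H <- solve(as.matrix(hinv$mat))
    V <- V + vc["a"] * Z %*% H %*% t(Z)
  }
  if (!is.null(sys$blocks$p)) {
    W <- as.matrix(sys$M[, sys$blocks$p, drop = FALSE])
    V <- V + vc["p"] * tcrossprod(W)
  }
  Vi <- solve(V)
  XtVi <- crossprod(X, Vi)
  beta_cov <- solve(XtVi %*% X)
  beta <- drop(beta_cov %*% (XtVi %*% sys$y))
  list(beta = beta, se = sqrt(diag(beta_cov)), Vi = Vi)
}

## Dense single-step H assembled from its closed-form blocks.
h_dense_oracle <- function(A, gi, Gb) {
  n <- nrow(A)
  ngi <- setdiff(seq_len(n), gi)
  A22 <- A[gi, gi, drop = FALSE]
  A22i <- solve(A22)
  D <- Gb - A22
  H <- A
  H[ngi, ngi] <- A[ngi, ngi] +
    A[ngi, gi] %*% A22i %*% D %*% A22i %*% A[gi, ngi]
  H[ngi, gi] <- A[ngi, gi] %*% A22i %*% Gb
  H[gi, ngi] <- t(H[ngi, gi])
  H[gi, gi] <- Gb
  H
}

## Random small genotype dataset (complete, polymorphic-leaning).
rand_gd <- function(n, m, n_chrom = 1L, p_het = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  calls <- matrix(sample(0:2, n * m, replace = TRUE,
                         prob = c((1 - p_het) / 2, p_het, (1 - p_het) / 2)),
                  n, m)
  per <- m %/% n_chrom
  chrom <- rep(as.character(seq_len(n_chrom)),
               times = c(rep(per, n_chrom - 1L), m - per * (n_chrom - 1L)))
  pos <- unlist(lapply(table(chrom)[unique(chrom)], function(k)
    sort(sample.int(1e6, k))), use.names = FALSE)
  genotype_dataset(calls,
                   data.frame(marker_id = paste0("m", seq_len(m)),
                              chrom = chrom, pos_bp = pos),
                   samples = paste0("s", seq_len(n)))
}

## Random valid pedigree: founders then offspring with parents drawn from
## earlier individuals (possibly unknown).
rand_pedigree <- function(n_founders, n_off, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  id <- paste0("i", seq_len(n_founders + n_off))
  sire <- dam <- rep(NA_character_, n_founders + n_off)
  for (k in seq_len(n_off)) {
    i <- n_founders + k
    pool <- seq_len(i - 1L)
    pr <- sample(pool, 2L, replace = FALSE)
    sire[i] <- id[pr[1L]]
    dam[i] <- id[pr[2L]]
  }
  pedigree(id, sire, dam)
}

## Small simulation configuration used across tests.
tiny_sim_config <- function(..., seed = 1L) {
  sim_config(n_founders = 12L, n_generations = 3L,
             offspring_per_generation = 32L,
             n_chromosomes = 2L, snps_per_chromosome = 120L,
             chromosome_length_bp = 2e7, n_hys = 8L, records_per_sow = 4L,
             seed = seed, ...)
}
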