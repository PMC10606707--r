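## Pedigree (A), genomic (G) and single-step combined (H-inverse)
## relationship structures for the additive genetic effect.

relationship_matrix <- function(ids, mat, kind, params = list()) {
  dimnames(mat) <- list(ids, ids)
  structure(list(ids = as.character(ids), mat = mat, kind = kind,
                 params = params),
            class = "relationship_matrix")
}

#' @exportS3Method base::print
print.relationship_matrix <- function(x, ...) {
  cat("relationship_matrix (", x$kind, "): ", length(x$ids), " individuals\n",
      sep = "")
  invisible(x)
}

#' Numerator relationship matrix (tabular method)
#'
#' Builds the pedigree-based additive relationship matrix A by the tabular
#' recurrence: for individual `i` with parents `s`, `d` (processed parents
#' before offspring), `A[i,i] = 1 + 0.5 A[s,d]` and
#' `A[j,i] = 0.5 (A[j,s] + A[j,d])`. Unknown parents are treated as
#' unrelated, non-inbred founders. The diagonal is 1 plus the individual's
#' inbreeding coefficient.
#'
#' @param ped A [pedigree()].
#' @return A dense `relationship_matrix` of kind `"A"`.
#' @export
a_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    asd <- if (s > 0L && d > 0L) A[s, d] else 0
    A[i, i] <- 1 + 0.5 * asd
    if (i > 1L) {
      j <- seq_len(i - 1L)
      rel <- 0.5 * ((if (s > 0L) A[j, s] else 0) +
                    (if (d > 0L) A[j, d] else 0))
      A[j, i] <- rel
      A[i, j] <- rel
    }
  }
  relationship_matrix(ped$id, A, "A")
}

#' Pedigree inbreeding coefficients
#' @param ped A [pedigree()].
#' @return Named numeric vector of F values.
#' @export
inbreeding <- function(ped) {
  A <- a_matrix(ped)
  stats::setNames(diag(A$mat) - 1, A$ids)
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding: the Mendelian-sampling variance of
#' individual `i` is `0.5 - 0.25 (F_s + F_d)` when both parents are known
#' (terms dropped for unknown parents), and its reciprocal drives the
#' parent--offspring contributions.
#'
#' @param ped A [pedigree()].
#' @return A sparse symmetric `relationship_matrix` of kind `"A_inverse"`.
#' @export
a_inverse <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  f <- inbreeding(ped)
  Fi <- as.numeric(f)
  ii <- jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    msv <- 1 - (if (s > 0L) 0.25 * (1 + Fi[s]) else 0) -
               (if (d > 0L) 0.25 * (1 + Fi[d]) else 0)
    al <- 1 / msv
    add(i, i, al)
    for (p in c(s, d)) if (p > 0L) {
      add(i, p, -al / 2); add(p, i, -al / 2)
      add(p, p, al / 4)
    }
    if (s > 0L && d > 0L) {
      add(s, d, al / 4); add(d, s, al / 4)
    }
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  Ainv <- Matrix::forceSymmetric((Ainv + Matrix::t(Ainv)) / 2)
  relationship_matrix(ped$id, Ainv, "A_inverse")
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' Centered cross-product of dosages scaled by `2 * sum(p * (1 - p))` with
#' observed allele frequencies; markers monomorphic in the sample are
#' dropped with a warning. The result is blended toward the pedigree
#' relationships among the genotyped individuals for invertibility:
#' `blend_alpha * G + (1 - blend_alpha) * A22`.
#'
#' @param gd A complete `genotype_dataset`.
#' Before blending, G is adjusted for base-population compatibility with
#' A22 (`a22_compat = TRUE`, the default): observed-frequency centering
#' references G to the genotyped generation, whereas pedigree
#' relationships are referenced to the founders, so in populations with
#' substantial drift or inbreeding since the base the two matrices sit on
#' different scales; the adjustment `G* = a + b G` matches the mean
#' diagonal and mean off-diagonal of G to those of A22. Skipping it biases
#' single-step variance components in deeply bottlenecked pedigrees.
#'
#' @param a22 Pedigree relationship matrix restricted to (and ordered as)
#'   the genotyped samples: a `relationship_matrix` or plain matrix. May be
#'   omitted only when `blend_alpha = 1` and `a22_compat = FALSE`.
#' @param blend_alpha Blending weight on G in `[0, 1]` (default 0.95).
#' @param a22_compat Adjust G's base to match A22 before blending?
#' @return A dense `relationship_matrix` of kind `"G"`.
#' @export
g_matrix <- function(gd, a22 = NULL, blend_alpha = 0.95,
                     a22_compat = !is.null(a22)) {
  stopifnot(inherits(gd, "genotype_dataset"))
  if (anyNA(gd$calls)) stop("missing genotypes; run impute_mode() first")
  if (blend_alpha < 0 || blend_alpha > 1) stop("blend_alpha must be in [0,1]")
  p <- colMeans(gd$calls) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all markers monomorphic; G undefined")
  if (any(!poly))
    warning(sum(!poly), " monomorphic markers dropped from G")
  M <- gd$calls[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(M, 2L, 2 * p)
  G <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  A22 <- NULL
  if (!is.null(a22)) {
    A22 <- if (inherits(a22, "relationship_matrix")) a22$mat else as.matrix(a22)
    if (!all(dim(A22) == nrow(G)))
      stop("a22 dimensions do not match the genotyped samples")
  }
  if (isTRUE(a22_compat)) {
    if (is.null(A22)) stop("a22 required when a22_compat = TRUE")
    off <- !diag(nrow(G))
    b <- (mean(diag(A22)) - mean(A22[off])) / (mean(diag(G)) - mean(G[off]))
    a <- mean(A22[off]) - b * mean(G[off])
    G <- a + b * G
  }
  if (blend_alpha < 1) {
    if (is.null(A22))
      stop("a22 required for blending when blend_alpha < 1")
    G <- blend_alpha * G + (1 - blend_alpha) * A22
  }
  relationship_matrix(gd$samples, G, "G",
                      list(blend_alpha = blend_alpha,
                           a22_compat = isTRUE(a22_compat)))
}

#' Single-step combined relationship inverse (H-inverse)
#'
#' `H^-1 = A^-1 + [0 0; 0 G_b^-1 - A22^-1]` on the genotyped block, where
#' `G_b` is the blended genomic matrix from [g_matrix()] and `A22` the
#' pedigree relationships among genotyped individuals. With no genotyped
#' individuals this reduces to `A^-1` exactly.
#'
#' @param ped A [pedigree()].
#' @param gd A complete `genotype_dataset` for the genotyped individuals
#'   (may be `NULL` when `genotyped_ids` is empty).
#' @param genotyped_ids Ids of genotyped individuals; must be a subset of
#'   the pedigree and of the dataset samples. Defaults to all dataset
#'   samples.
#' @param blend_alpha Blending weight passed to [g_matrix()].
#' @param a22_compat Base-compatibility adjustment passed to [g_matrix()].
#' @return A `relationship_matrix` of kind `"H_inverse"` over all pedigree
#'   ids (pedigree order), sparse when no genotyped block is added.
#' @export
h_inverse <- function(ped, gd = NULL,
                      genotyped_ids = if (is.null(gd)) character() else gd$samples,
                      blend_alpha = 0.95, a22_compat = TRUE) {
  stopifnot(inherits(ped, "pedigree"))
  Ainv <- a_inverse(ped)
  genotyped_ids <- as.character(genotyped_ids)
  if (!length(genotyped_ids))
    return(relationship_matrix(ped$id, Ainv$mat, "H_inverse",
                               list(blend_alpha = blend_alpha,
                                    n_genotyped = 0L)))
  missing_ids <- setdiff(genotyped_ids, ped$id)
  if (length(missing_ids))
    stop("genotyped individuals absent from pedigree: ",
         paste(head(missing_ids, 5), collapse = ", "))
  gd2 <- subset_samples(gd, genotyped_ids)
  A <- a_matrix(ped)
  gi <- match(genotyped_ids, ped$id)
  A22 <- A$mat[gi, gi, drop = FALSE]
  Gb <- g_matrix(gd2, a22 = A22, blend_alpha = blend_alpha,
                 a22_compat = a22_compat)
  Ginv <- tryCatch(chol2inv(chol(Gb$mat)), error = function(e)
    stop("blended G is singular; decrease blend_alpha (", conditionMessage(e),
         ")"))
  A22inv <- chol2inv(chol(A22))
  H <- as.matrix(Ainv$mat)
  H[gi, gi] <- H[gi, gi] + Ginv - A22inv
  H <- (H + t(H)) / 2
  relationship_matrix(ped$id, H, "H_inverse",
                      list(blend_alpha = blend_alpha,
                           n_genotyped = length(genotyped_ids),
                           genotyped_ids = genotyped_ids))
}

#' Export a relationship matrix as coordinate-list TSV
#'
#' Writes the lower triangle (including diagonal) as `i`, `j`, `value`
#' rows using 1-based positions, plus an id map file `<path>.ids`.
#'
#' @param rm A `relationship_matrix`.
#' @param path Output TSV path.
#' @param tol Entries with `|value| <= tol` are omitted.
#' @return Invisibly, `path`.
#' @export
write_relationship <- function(rm, path, tol = 0) {
  stopifnot(inherits(rm, "relationship_matrix"))
  M <- as.matrix(rm$mat)
  idx <- which(lower.tri(M, diag = TRUE) & abs(M) > tol, arr.ind = TRUE)
  dt <- data.table::data.table(i = idx[, 1L], j = idx[, 2L],
                               value = M[idx])
  data.table::setorder(dt, i, j)
  data.table::fwrite(dt, path, sep = "\t")
  data.table::fwrite(data.table::data.table(index = seq_along(rm$ids),
                                            id = rm$ids),
                     paste0(path, ".ids"), sep = "\t")
  invisible(path)
}
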