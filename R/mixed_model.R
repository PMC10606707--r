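## Repeatability animal model for litter size:
##   y = f d + X b + T h + Z u + W p + e
## with parity (plus optional heterozygosity covariate and ROH carrier
## indicator) as fixed effects, herd-year-season (h), additive genetic (u,
## single-step H structure) and permanent sow environment (p) as random
## effects. Henderson's mixed model equations, AI-REML variance components,
## and one-sided tests of targeted effects.

#' Specify a litter-size model
#'
#' @param trait `"tnb"` or `"nba"`.
#' @param covariate Include the genome-wide heterozygosity covariate?
#' @param carrier Include an ROH carrier indicator (fixed effect)?
#' @param hys Include the random herd--year--season term?
#' @param additive Include the random additive genetic term?
#' @param pe Include the random permanent-environment term?
#' @param df Degrees of freedom for one-sided tests of fixed effects;
#'   `Inf` (the default) uses the standard normal reference.
#' @return A `model_spec` list.
#' @export
model_spec <- function(trait = c("tnb", "nba"), covariate = FALSE,
                       carrier = FALSE, hys = TRUE, additive = TRUE,
                       pe = TRUE, df = Inf) {
  trait <- match.arg(tolower(trait[1L]), c("tnb", "nba"))
  structure(list(trait = trait, covariate = covariate, carrier = carrier,
                 hys = hys, additive = additive, pe = pe, df = df),
            class = "model_spec")
}

vc_vec <- function(vc) {
  if (inherits(vc, "variance_components")) vc <- vc$sigma2
  vc <- unlist(vc)
  need <- c("a", "p", "h", "e")
  if (!all(need %in% names(vc)))
    stop("variance components must be named a, p, h, e")
  vc[need]
}

## Sparse indicator matrix of a factor (records x levels)
incidence <- function(f) {
  f <- factor(f)
  Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f), x = 1,
                       dims = c(length(f), nlevels(f)),
                       dimnames = list(NULL, levels(f)))
}

## Assemble the design once: returns M = [X T Z W], y, block index map and
## the precision structure K^-1 of each random block.
assemble_design <- function(phen, spec, hinv = NULL, het = NULL,
                            carrier = NULL) {
  stopifnot(inherits(phen, "phenotype_table"), inherits(spec, "model_spec"))
  y <- phen[[spec$trait]]
  n <- nrow(phen)
  ## fixed block: intercept + parity (first observed class as reference)
  pf <- factor(phen$parity)
  X <- cbind(Matrix::Matrix(1, n, 1, sparse = TRUE,
                            dimnames = list(NULL, "(Intercept)")),
             if (nlevels(pf) > 1L)
               incidence(pf)[, -1L, drop = FALSE])
  if (!is.null(colnames(X)))
    colnames(X) <- c("(Intercept)",
                     if (nlevels(pf) > 1L)
                       paste0("parity", levels(pf)[-1L]))
  if (isTRUE(spec$covariate)) {
    if (is.null(het)) stop("covariate requested but `het` not supplied")
    hv <- het[phen$sow]
    if (anyNA(hv))
      stop("heterozygosity missing for sows: ",
           paste(head(unique(phen$sow[is.na(hv)]), 5), collapse = ", "))
    if (stats::sd(hv) == 0) stop("heterozygosity covariate is constant")
    X <- cbind(X, Matrix::Matrix(hv, n, 1, sparse = TRUE,
                                 dimnames = list(NULL, "het_pct")))
    colnames(X)[ncol(X)] <- "het_pct"
  }
  if (isTRUE(spec$carrier)) {
    if (is.null(carrier)) stop("carrier term requested but `carrier` not supplied")
    cv <- carrier[phen$sow]
    if (anyNA(cv))
      stop("carrier status missing for sows: ",
           paste(head(unique(phen$sow[is.na(cv)]), 5), collapse = ", "))
    X <- cbind(X, Matrix::Matrix(as.numeric(cv), n, 1, sparse = TRUE))
    colnames(X)[ncol(X)] <- "carrier"
  }
  blocks <- list(fixed = seq_len(ncol(X)))
  Kinv <- list()
  M <- X
  addblock <- function(M, blocks, name, Mat) {
    blocks[[name]] <- ncol(M) + seq_len(ncol(Mat))
    list(M = cbind(M, Mat), blocks = blocks)
  }
  if (isTRUE(spec$hys)) {
    Th <- incidence(phen$hys)
    r <- addblock(M, blocks, "hys", Th); M <- r$M; blocks <- r$blocks
    Kinv$hys <- Matrix::Diagonal(ncol(Th))
  }
  if (isTRUE(spec$additive)) {
    if (is.null(hinv)) stop("additive term requires `hinv`")
    stopifnot(inherits(hinv, "relationship_matrix"))
    pos <- match(phen$sow, hinv$ids)
    if (anyNA(pos))
      stop("records with sows absent from the relationship matrix: ",
           paste(head(unique(phen$sow[is.na(pos)]), 5), collapse = ", "))
    Z <- Matrix::sparseMatrix(i = seq_len(n), j = pos, x = 1,
                              dims = c(n, length(hinv$ids)),
                              dimnames = list(NULL, hinv$ids))
    r <- addblock(M, blocks, "u", Z); M <- r$M; blocks <- r$blocks
    Kinv$u <- Matrix::forceSymmetric(Matrix::Matrix(hinv$mat, sparse = TRUE))
  }
  if (isTRUE(spec$pe)) {
    W <- incidence(phen$sow)
    r <- addblock(M, blocks, "p", W); M <- r$M; blocks <- r$blocks
    Kinv$p <- Matrix::Diagonal(ncol(W))
  }
  ## alias detection in the fixed block (corner constraint: aliased columns
  ## constrained to zero)
  Xd <- as.matrix(M[, blocks$fixed, drop = FALSE])
  qrX <- qr(Xd)
  aliased <- integer(0)
  if (qrX$rank < ncol(Xd))
    aliased <- sort(qrX$pivot[(qrX$rank + 1L):ncol(Xd)])
  list(M = M, y = y, blocks = blocks, Kinv = Kinv, n = n,
       fixed_rank = qrX$rank, aliased = aliased,
       labels = colnames(M)[blocks$fixed])
}

## map variance-component vector onto the random blocks of a design
block_sigma <- function(design, vc) {
  vc <- vc_vec(vc)
  sig <- c(hys = unname(vc["h"]), u = unname(vc["a"]), p = unname(vc["p"]))
  sig[names(design$Kinv)]
}

## Henderson coefficient matrix C = M'M/s2e + blockdiag(Kinv_k / s2_k)
## (fixed block unpenalized) and right-hand side M'y/s2e. With this
## scaling, the inverse of C is directly the sampling (co)variance of the
## estimated effects.
build_coef <- function(design, vc, MtM = NULL) {
  vc <- vc_vec(vc)
  s2e <- vc["e"]
  if (s2e <= 0) stop("residual variance must be strictly positive")
  sig <- block_sigma(design, vc)
  if (length(sig) && any(sig <= 0))
    stop("variance components of included random terms must be positive")
  if (is.null(MtM)) MtM <- Matrix::crossprod(design$M)
  C <- MtM / s2e
  for (k in names(design$Kinv)) {
    idx <- design$blocks[[k]]
    C[idx, idx] <- C[idx, idx] + design$Kinv[[k]] / sig[k]
  }
  Matrix::forceSymmetric(C)
}

#' Build the mixed model equations
#'
#' Assembles Henderson's system for the repeatability model at fixed
#' variance components: identity precision for the herd--year--season and
#' permanent-environment blocks, the single-step `H^-1` for the additive
#' block, fixed effects unpenalized. With the chosen scaling the inverse
#' coefficient matrix is the sampling covariance of the solutions.
#'
#' @param phen A `phenotype_table`.
#' @param spec A [model_spec()].
#' @param hinv `relationship_matrix` of kind `H_inverse` (or `A_inverse`)
#'   over all pedigree ids; required when `spec$additive`.
#' @param vc Variance components: a `variance_components` object or a named
#'   vector `c(a=, p=, h=, e=)`.
#' @param het Named per-sow heterozygosity percentages (required when
#'   `spec$covariate`).
#' @param carrier Named per-sow 0/1 carrier indicator (required when
#'   `spec$carrier`).
#' @return An `mme_system` list: coefficient matrix `C`, right-hand side
#'   `rhs`, design `M`, response `y`, `blocks` index map, `vc`, labels of
#'   fixed columns, and indices of aliased fixed columns.
#' @export
build_mme <- function(phen, spec, hinv = NULL, vc, het = NULL,
                      carrier = NULL) {
  design <- assemble_design(phen, spec, hinv, het, carrier)
  vc <- vc_vec(vc)
  C <- build_coef(design, vc)
  rhs <- Matrix::crossprod(design$M, design$y) / vc["e"]
  structure(c(design, list(C = C, rhs = rhs, vc = vc, spec = spec)),
            class = "mme_system")
}

#' Solve the mixed model equations
#'
#' Direct sparse symmetric factorization. Fixed-block rank deficiencies are
#' handled by the corner constraint: aliased columns (detected by pivoted
#' QR of the fixed block) are constrained to zero, leaving estimable
#' contrasts unchanged. Sampling variances of targeted effects come from
#' the corresponding diagonal entries of the inverse coefficient matrix,
#' obtained by solves against unit vectors.
#'
#' @param sys An `mme_system` from [build_mme()].
#' @param targets Equation coordinates whose sampling variances are wanted:
#'   integer indices or names of fixed-effect columns.
#' @return A list with `solution` (named numeric over all equations),
#'   `se` (named, for `targets`), and `aliased` (fixed columns constrained
#'   to zero).
#' @export
solve_mme <- function(sys, targets = NULL) {
  stopifnot(inherits(sys, "mme_system"))
  keep <- setdiff(seq_len(nrow(sys$C)), sys$aliased)
  C <- sys$C[keep, keep, drop = FALSE]
  ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(C), LDL = FALSE,
                                  perm = TRUE),
                 error = function(e)
                   stop("singular mixed-model equations after constraint; ",
                        "check for confounded effects (",
                        conditionMessage(e), ")"))
  solv <- function(b) as.numeric(Matrix::solve(ch, b, system = "A"))
  sol_red <- solv(sys$rhs[keep])
  nm <- c(sys$labels,
          unlist(lapply(names(sys$Kinv), function(k)
    paste0(k, "_", seq_along(sys$blocks[[k]]))), use.names = FALSE))
  solution <- stats::setNames(numeric(nrow(sys$C)), nm)
  solution[keep] <- sol_red
  se <- NULL
  if (!is.null(targets)) {
    if (is.character(targets)) {
      ti <- match(targets, sys$labels)
      if (anyNA(ti)) stop("unknown target columns: ",
                          paste(targets[is.na(ti)], collapse = ", "))
    } else ti <- as.integer(targets)
    se <- stats::setNames(numeric(length(ti)), nm[ti])
    for (s in seq_along(ti)) {
      t_red <- match(ti[s], keep)
      if (is.na(t_red)) { se[s] <- NA_real_; next }
      ei <- numeric(length(keep)); ei[t_red] <- 1
      se[s] <- sqrt(solv(ei)[t_red])
    }
  }
  list(solution = solution, se = se, aliased = sys$aliased)
}

#' One-sided tail probability of an estimate
#'
#' Upper- or lower-tail probability of `estimate / se` under the reference
#' distribution: standard normal by default (`df = Inf`), Student-t when a
#' finite `df` is supplied.
#'
#' @param estimate,se Point estimate and its standard error (`se > 0`).
#' @param direction `"greater"` (alternative: effect > 0) or `"less"`.
#' @param df Degrees of freedom, `Inf` for normal.
#' @return Tail probability in (0, 1).
#' @export
one_sided_p <- function(estimate, se, direction = c("greater", "less"),
                        df = Inf) {
  direction <- match.arg(direction)
  if (any(se <= 0)) stop("standard error must be strictly positive")
  t <- estimate / se
  if (direction == "greater") stats::pt(t, df = df, lower.tail = FALSE)
  else stats::pt(t, df = df, lower.tail = TRUE)
}

## ------------------------------------------------------------- AI-REML

#' Variance components by average-information REML
#'
#' Estimates the variance components of the repeatability model (additive,
#' permanent environment, herd--year--season as included in `spec`, plus
#' residual) by Newton updates with the average-information matrix,
#' step-halved to respect non-negativity. Components pushed to the zero
#' boundary are pinned there and flagged. Sampling variances are the
#' diagonal of the inverse AI matrix at convergence. The ROH carrier term
#' must not be in `spec`: variance estimation precedes the scan and the
#' scan reuses these components unchanged.
#'
#' @param phen A `phenotype_table`.
#' @param spec A [model_spec()] with `carrier = FALSE`.
#' @param hinv Relationship inverse for the additive term (see
#'   [build_mme()]).
#' @param het Named per-sow heterozygosity percentages when
#'   `spec$covariate`.
#' @param init Named starting values `c(a=, p=, h=, e=)`; default splits the
#'   phenotypic variance equally over the included components.
#' @param tol Convergence tolerance on the scaled update norm.
#' @param max_iter Maximum iterations.
#' @param verbose Print the trajectory?
#' @return A `variance_components` object: `sigma2` (named: a, p, h, e;
#'   `NA` for terms not in the model), `sampling_var`, and `convergence`
#'   diagnostics (iterations, final update norm, boundary flags).
#' @export
ai_reml <- function(phen, spec, hinv = NULL, het = NULL, init = NULL,
                    tol = 1e-8, max_iter = 200L, verbose = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  if (isTRUE(spec$carrier))
    stop("ai_reml: variance estimation precedes the scan; remove the carrier term")
  design <- assemble_design(phen, spec, hinv, het, carrier = NULL)
  y <- design$y; n <- design$n
  vy <- stats::var(y)
  comp <- c(names(design$Kinv), "e")          # e.g. hys, u, p, e
  k_r <- length(comp) - 1L
  theta <- if (is.null(init)) {
    stats::setNames(rep(vy / length(comp), length(comp)), comp)
  } else {
    init <- vc_vec(init)
    blk2vc <- c(hys = "h", u = "a", p = "p")
    stats::setNames(c(unname(init[blk2vc[names(design$Kinv)]]),
                      unname(init["e"])), comp)
  }
  floorv <- 1e-8 * vy
  theta <- pmax(theta, floorv)
  MtM <- Matrix::crossprod(design$M)
  Mty <- as.numeric(Matrix::crossprod(design$M, y))
  keep <- setdiff(seq_len(nrow(MtM)), design$aliased)
  pinned <- stats::setNames(rep(FALSE, length(comp)), comp)
  traj <- list()
  upd_norm <- Inf
  AI <- NULL
  Kd <- lapply(design$Kinv, as.matrix)        # dense precision structures
  for (it in seq_len(max_iter)) {
    vc_now <- theta_to_vc(theta, comp)
    C <- build_coef(design, vc_now, MtM = MtM)
    Cd <- as.matrix(C[keep, keep, drop = FALSE])
    Ci <- tryCatch(chol2inv(chol(Cd)), error = function(e)
      stop("coefficient matrix not positive definite during AI-REML (iteration ",
           it, "): ", conditionMessage(e)))
    sol <- stats::setNames(numeric(nrow(MtM)), NULL)
    sol[keep] <- Ci %*% (Mty[keep] / theta[["e"]])
    resid <- y - as.numeric(design$M %*% sol)
    Py <- resid / theta[["e"]]
    ## gradient
    g <- stats::setNames(numeric(length(comp)), comp)
    trPV <- stats::setNames(numeric(k_r), head(comp, k_r))
    fvec <- list()
    for (k in names(design$Kinv)) {
      idx <- design$blocks[[k]]
      idx_red <- match(idx, keep)
      Ckk <- Ci[idx_red, idx_red, drop = FALSE]
      trk <- sum(Kd[[k]] * Ckk)
      uk <- sol[idx]
      uqf <- as.numeric(uk %*% (Kd[[k]] %*% uk))
      s2 <- theta[[k]]
      trPV[k] <- (length(idx) - trk / s2) / s2
      g[k] <- -0.5 * (trPV[k] - uqf / s2^2)
      fvec[[k]] <- as.numeric(design$M[, idx, drop = FALSE] %*% uk) / s2
    }
    trP <- (n - design$fixed_rank -
              sum(theta[head(comp, k_r)] * trPV)) / theta[["e"]]
    g["e"] <- -0.5 * (trP - sum(Py^2))
    fvec[["e"]] <- Py
    ## average information
    AI <- matrix(0, length(comp), length(comp), dimnames = list(comp, comp))
    Pf <- lapply(fvec, function(f) {
      b <- as.numeric(Matrix::crossprod(design$M, f))[keep] / theta[["e"]]
      (f - as.numeric(design$M[, keep, drop = FALSE] %*% (Ci %*% b))) /
        theta[["e"]]
    })
    for (a_ in comp) for (b_ in comp)
      AI[a_, b_] <- 0.5 * sum(fvec[[a_]] * Pf[[b_]])
    ## active set: pin near-zero components with downhill gradient (a tiny
    ## component otherwise dominates the AI matrix and stalls the updates)
    pinned_prev <- pinned
    pinned <- theta <= pmax(floorv * 2, 1e-5 * vy) & g < 0
    pinned["e"] <- FALSE
    free <- comp[!pinned]
    delta <- stats::setNames(numeric(length(comp)), comp)
    delta[free] <- tryCatch(
      solve(AI[free, free, drop = FALSE], g[free]),
      error = function(e) g[free] / pmax(diag(AI)[free], 1e-12))
    ## per-component clamping: a component is moved by at most a factor of
    ## ten per iteration and never below the floor, so one component
    ## heading to the boundary cannot freeze the others (a global
    ## step-halving would shrink every update and fake convergence at a
    ## non-stationary point)
    cand <- theta + delta
    cand <- pmin(pmax(cand, pmax(floorv, theta / 10)), 10 * theta)
    cand[pinned] <- floorv
    upd_norm <- sqrt(sum((cand - theta)^2)) / (sqrt(sum(theta^2)) + 1e-300)
    theta_old <- theta
    theta <- cand
    traj[[it]] <- theta
    if (verbose)
      message(sprintf("iter %d: %s | update %.3g", it,
                      paste(sprintf("%s=%.5f", comp, theta), collapse = " "),
                      upd_norm))
    if (upd_norm < tol && identical(pinned, pinned_prev)) break
  }
  if (upd_norm >= tol) {
    cond <- simpleError(sprintf(
      "AI-REML did not converge in %d iterations (last update norm %.3g)",
      max_iter, upd_norm))
    cond$trajectory <- do.call(rbind, traj)
    stop(cond)
  }
  AIfree <- AI[!pinned, !pinned, drop = FALSE]
  svar <- stats::setNames(rep(NA_real_, length(comp)), comp)
  svar[!pinned] <- diag(solve(AIfree))
  out_map <- c(hys = "h", u = "a", p = "p", e = "e")
  sigma2 <- stats::setNames(rep(NA_real_, 4L), c("a", "p", "h", "e"))
  sampling_var <- sigma2
  boundary <- stats::setNames(rep(FALSE, 4L), c("a", "p", "h", "e"))
  for (k in comp) {
    sigma2[out_map[k]] <- theta[[k]]
    sampling_var[out_map[k]] <- svar[[k]]
    boundary[out_map[k]] <- pinned[[k]]
  }
  structure(list(sigma2 = sigma2, sampling_var = sampling_var,
                 convergence = list(iterations = length(traj),
                                    update_norm = upd_norm,
                                    boundary = boundary),
                 trait = spec$trait),
            class = "variance_components")
}

theta_to_vc <- function(theta, comp) {
  v <- c(a = 1, p = 1, h = 1, e = unname(theta[["e"]]))
  if ("u" %in% comp) v["a"] <- theta[["u"]]
  if ("p" %in% comp) v["p"] <- theta[["p"]]
  if ("hys" %in% comp) v["h"] <- theta[["hys"]]
  v
}

#' Construct a variance-components object from known values
#'
#' @param a,p,h,e Additive, permanent-environment, herd--year--season and
#'   residual variances (squared piglets).
#' @return A `variance_components` object.
#' @export
variance_components <- function(a, p, h, e) {
  if (any(c(a, p, h, e) < 0)) stop("variance components must be non-negative")
  structure(list(sigma2 = c(a = a, p = p, h = h, e = e),
                 sampling_var = c(a = NA_real_, p = NA_real_, h = NA_real_,
                                  e = NA_real_),
                 convergence = NULL),
            class = "variance_components")
}

#' @exportS3Method base::print
print.variance_components <- function(x, ...) {
  cat("variance components (squared piglets):\n")
  lab <- c(a = "additive", p = "permanent env.", h = "herd-year-season",
           e = "residual")
  for (k in names(x$sigma2))
    cat(sprintf("  %-18s %8.4f%s\n", lab[k], x$sigma2[k],
                if (!is.na(x$sampling_var[k]))
                  sprintf("  (sampling var %.4g)", x$sampling_var[k]) else ""))
  if (!is.null(x$convergence))
    cat("  converged in", x$convergence$iterations, "iterations\n")
  invisible(x)
}

#' Estimate the heterozygosity-depression covariate
#'
#' Fits the model with the genome-wide heterozygosity covariate at fixed
#' variance components and reports its slope (piglets per percent
#' heterozygosity), standard error, and the one-sided p-value for the
#' alternative `d > 0` (more heterozygosity, larger litters: the signature
#' of inbreeding depression).
#'
#' @param phen A `phenotype_table`.
#' @param spec A [model_spec()]; its `covariate` flag is forced on and
#'   `carrier` off.
#' @param hinv Relationship inverse (see [build_mme()]).
#' @param vc Variance components (typically from [ai_reml()] on the same
#'   data).
#' @param het Named per-sow heterozygosity percentages.
#' @return A `covariate_estimate` list: `estimate`, `se`, `p` (one-sided),
#'   `df`.
#' @export
fit_het_covariate <- function(phen, spec, hinv, vc, het) {
  spec$covariate <- TRUE
  spec$carrier <- FALSE
  sys <- build_mme(phen, spec, hinv, vc, het = het)
  fit <- solve_mme(sys, targets = "het_pct")
  est <- unname(fit$solution["het_pct"])
  se <- unname(fit$se["het_pct"])
  structure(list(estimate = est, se = se,
                 p = one_sided_p(est, se, "greater", df = spec$df),
                 df = spec$df, trait = spec$trait),
            class = "covariate_estimate")
}

#' @exportS3Method base::print
print.covariate_estimate <- function(x, ...) {
  cat(sprintf(
    "heterozygosity covariate (%s): %.4f +/- %.4f piglets/%%, one-sided p = %.4g\n",
    toupper(x$trait), x$estimate, x$se, x$p))
  invisible(x)
}
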