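# Relationship matrices from SNPs or DMR methylation, probabilistic PCA
# for incomplete data, and R-squared comparison of kinship matrices.

#' Standardized relationship matrix from a feature matrix
#'
#' The GRM-style estimator K = Z Z' / m over column-standardized features,
#' computed pairwise-complete so missing methylation values neither bias
#' nor break the estimate: K_ij averages z_i z_j over the features
#' observed in both lines.
#'
#' @param x lines x features numeric matrix (genotype codes or per-DMR
#'   methylation levels); `NA` allowed.
#' @param standardize center and scale features first (default TRUE).
#' @return symmetric lines x lines matrix with line-id dimnames.
#' @export
kinship_from_markers <- function(x, standardize = TRUE) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- sprintf("L%03d", seq_len(nrow(x)))
  miss_frac <- rowMeans(is.na(x))
  if (any(miss_frac > 0.9))
    stop_popmeth("line '%s' is missing > 90%% of features",
                 rownames(x)[which.max(miss_frac)])
  v <- apply(x, 2, var, na.rm = TRUE)
  x <- x[, !is.na(v) & v > 0, drop = FALSE]
  if (ncol(x) == 0L) stop_popmeth("no variable features left")
  z <- if (standardize) scale(x) else x
  obs <- !is.na(z)
  z0 <- z
  z0[!obs] <- 0
  num <- tcrossprod(z0)
  den <- tcrossprod(obs * 1)
  den[den == 0] <- NA
  K <- num / den
  dimnames(K) <- list(rownames(x), rownames(x))
  K
}

#' Compare two relationship matrices
#'
#' Squared Pearson correlation of the off-diagonal (upper-triangle)
#' entries; the diagonal is removed so self-relatedness does not inflate
#' the agreement.
#'
#' @param K1,K2 relationship matrices over the same lines in the same
#'   order.
#' @return squared correlation in `[0, 1]`.
#' @export
compare_kinship <- function(K1, K2) {
  if (!all(dim(K1) == dim(K2)))
    stop_popmeth("relationship matrices have different dimensions")
  if (!is.null(rownames(K1)) && !is.null(rownames(K2)) &&
      !identical(rownames(K1), rownames(K2)))
    stop_popmeth("relationship matrices are over different line sets")
  ut <- upper.tri(K1)
  cor(K1[ut], K2[ut], use = "complete.obs")^2
}

#' Probabilistic PCA with missing values
#'
#' EM algorithm for the probabilistic PCA model x = W t + mu + eps
#' (isotropic noise), which handles missing entries by taking the
#' expectation step over observed coordinates only.  Initialization is
#' deterministic (SVD of the column-mean-imputed matrix), convergence is
#' declared when the relative change in the expected objective falls
#' below `tol`.
#'
#' @param x lines x features matrix with `NA` for missing entries; every
#'   line needs at least one observed feature.  Constant features are
#'   removed before fitting.
#' @param n_components number of components (default 3).
#' @param tol relative convergence tolerance (default 1e-6).
#' @param max_iter iteration cap (default 1000); non-convergence warns
#'   but still returns scores.
#' @return list with `scores` (lines x n_components), `loadings`
#'   (features x n_components), `sigma2`, `n_iter`, `converged`.
#' @export
ppca <- function(x, n_components = 3L, tol = 1e-6, max_iter = 1000L) {
  x <- as.matrix(x)
  if (any(rowSums(!is.na(x)) == 0L))
    stop_popmeth("some line has no observed feature")
  v <- apply(x, 2, var, na.rm = TRUE)
  keep <- !is.na(v) & v > 0
  if (!any(keep)) {
    return(list(scores = matrix(0, nrow(x), n_components,
                                dimnames = list(rownames(x), NULL)),
                loadings = NULL, sigma2 = 0, n_iter = 0L, converged = TRUE))
  }
  x <- x[, keep, drop = FALSE]
  n <- nrow(x); d <- ncol(x); q <- as.integer(n_components)
  q <- min(q, d, n - 1L)
  mu <- colMeans(x, na.rm = TRUE)
  xc <- sweep(x, 2, mu)
  obs <- !is.na(xc)
  ximp <- xc
  ximp[!obs] <- 0
  sv <- svd(ximp, nu = 0, nv = q)
  W <- sv$v %*% diag(sv$d[seq_len(q)] / sqrt(n), q, q)
  sigma2 <- max(mean(ximp^2), 1e-8)
  obj_old <- Inf
  converged <- FALSE
  iter <- 0L
  Tmat <- matrix(0, n, q)
  while (iter < max_iter) {
    iter <- iter + 1L
    # E-step per line over its observed coordinates
    resid_sum <- 0
    n_obs_total <- sum(obs)
    SW_num <- matrix(0, d, q)   # sum_i x_i <t_i>' restricted to observed rows
    A_sum <- array(0, c(d, q, q))  # per-feature sum over lines of <t t'>
    for (i in seq_len(n)) {
      oi <- obs[i, ]
      Wo <- W[oi, , drop = FALSE]
      M <- crossprod(Wo) + sigma2 * diag(q)
      Minv <- solve(M)
      xi <- xc[i, oi]
      ti <- Minv %*% crossprod(Wo, xi)
      Tmat[i, ] <- ti
      Ct <- sigma2 * Minv + tcrossprod(ti)
      SW_num[oi, ] <- SW_num[oi, ] + outer(xi, as.vector(ti))
      A_sum[oi, , ] <- A_sum[oi, , , drop = FALSE] +
        aperm(array(Ct, c(q, q, sum(oi))), c(3, 1, 2))
      resid_sum <- resid_sum + sum((xi - Wo %*% ti)^2) +
        sigma2 * sum(diag(Wo %*% Minv %*% t(Wo)))
    }
    # M-step: per-feature row of W solves its own qxq system
    W_new <- W
    for (j in seq_len(d)) {
      Aj <- matrix(A_sum[j, , ], q, q)
      if (all(Aj == 0)) next
      W_new[j, ] <- solve(Aj, SW_num[j, ])
    }
    W <- W_new
    sigma2_new <- max(resid_sum / n_obs_total, 1e-10)
    obj <- resid_sum / n_obs_total
    if (is.finite(obj_old) && abs(obj_old - obj) < tol * max(obj_old, 1e-12)) {
      sigma2 <- sigma2_new
      converged <- TRUE
      break
    }
    obj_old <- obj
    sigma2 <- sigma2_new
  }
  if (!converged)
    warning(sprintf("ppca did not converge in %d iterations", iter))
  # final E-step for scores under the last W
  for (i in seq_len(n)) {
    oi <- obs[i, ]
    Wo <- W[oi, , drop = FALSE]
    Minv <- solve(crossprod(Wo) + sigma2 * diag(q))
    Tmat[i, ] <- Minv %*% crossprod(Wo, xc[i, oi])
  }
  rownames(Tmat) <- rownames(x)
  list(scores = Tmat, loadings = W, sigma2 = sigma2, n_iter = iter,
       converged = converged)
}

#' Top genotype principal components (structure covariates)
#'
#' @param geno lines x markers matrix (0/2 codes); complete data.
#' @param n_components number of PCs (default 3).
#' @return lines x n_components score matrix.
#' @export
genotype_pcs <- function(geno, n_components = 3L) {
  v <- apply(geno, 2, var)
  z <- scale(geno[, v > 0, drop = FALSE])
  sv <- svd(z, nu = n_components, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components, n_components)
  rownames(scores) <- rownames(geno)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  scores
}

#' Pool relationship information across methylation contexts
#'
#' The ALL-context kinship can concatenate per-DMR features across
#' contexts before standardization (default) or average the per-context
#' relationship matrices; the two agree up to feature weighting.
#'
#' @param level_list named list of DMRs x lines level matrices, one per
#'   context.
#' @param method `"concatenate"` or `"average"`.
#' @return lines x lines relationship matrix.
#' @export
kinship_all_contexts <- function(level_list, method = c("concatenate", "average")) {
  method <- match.arg(method)
  if (method == "concatenate") {
    kinship_from_markers(t(do.call(rbind, level_list)))
  } else {
    Ks <- lapply(level_list, function(lv) kinship_from_markers(t(lv)))
    Reduce(`+`, Ks) / length(Ks)
  }
}
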