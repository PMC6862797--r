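# EMMAX-style mixed linear model: variance components are estimated once
# per trait by REML on the null (covariates-only) model through a spectral
# decomposition of the kinship matrix, then every marker is tested by
# generalized least squares under the fixed variance ratio.  This keeps
# the per-marker cost at O(n) after one eigendecomposition.

# Eigendecomposition of K with a PSD check; small negative eigenvalues
# (numerical) are clamped to zero.
kinship_eigen <- function(K) {
  if (!isSymmetric(unname(K), tol = 1e-8)) stop_popmeth("kinship matrix is not symmetric")
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-6 * max(abs(e$values)))
    stop_popmeth("kinship matrix is not positive semi-definite (min eigenvalue %.3g)",
                 min(e$values))
  e$values <- pmax(e$values, 0)
  e
}

# Drop collinear columns of a covariate matrix (keeps an intercept first).
prepare_covariates <- function(Q, n) {
  X <- cbind(`(Intercept)` = rep(1, n), Q)
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) {
    drop <- qr_X$pivot[-seq_len(qr_X$rank)]
    warning(sprintf("dropping %d collinear covariate column(s)", length(drop)))
    X <- X[, -drop, drop = FALSE]
  }
  X
}

#' Fit the null mixed model by REML
#'
#' Model: y = Q b + u + e with u ~ N(0, sigma_g^2 K), e ~ N(0, sigma_e^2 I).
#' The variance ratio delta = sigma_e^2 / sigma_g^2 is profiled out on the
#' spectral axis of K and optimized on log scale.
#'
#' @param y response vector (already transformed as appropriate).
#' @param K kinship matrix (PSD).
#' @param Q covariate matrix (structure PCs etc.); an intercept is always
#'   added.  `NULL` for intercept only.
#' @return an object of class `mlm_null`: rotated data, delta,
#'   `sigma_g2`, `sigma_e2`, eigen pieces, for reuse across markers.
#' @export
fit_mlm_null <- function(y, K, Q = NULL) {
  n <- length(y)
  stopifnot(nrow(K) == n)
  X <- prepare_covariates(Q, n)
  p <- ncol(X)
  e <- kinship_eigen(K)
  Ut <- t(e$vectors)
  ys <- as.vector(Ut %*% y)
  Xs <- Ut %*% X
  S <- e$values

  reml_neg_ll <- function(log_delta) {
    delta <- exp(log_delta)
    w <- S + delta
    sw <- sqrt(w)
    Xw <- Xs / sw
    yw <- ys / sw
    fit <- lm.fit(Xw, yw)
    rss <- sum(fit$residuals^2)
    sigma_g2 <- rss / (n - p)
    XtX <- crossprod(Xw)
    0.5 * ((n - p) * log(sigma_g2) + sum(log(w)) +
             determinant(XtX, logarithm = TRUE)$modulus[1] + (n - p))
  }
  f_lo <- reml_neg_ll(-10)
  f_hi <- reml_neg_ll(10)
  if (abs(f_lo - f_hi) < 1e-8 * max(1, abs(f_hi))) {
    # profile is flat in the variance ratio (K carries no signal beyond
    # iid noise, e.g. K = identity): take the homoskedastic limit so the
    # random effect vanishes and the model degenerates to OLS cleanly
    delta <- exp(30)
  } else {
    opt <- optimize(reml_neg_ll, interval = c(-10, 10))
    delta <- exp(opt$minimum)
  }
  w <- S + delta
  sw <- sqrt(w)
  fit <- lm.fit(Xs / sw, ys / sw)
  sigma_g2 <- sum(fit$residuals^2) / (n - p)
  structure(list(ys = ys, Xs = Xs, S = S, U = e$vectors, delta = delta,
                 sigma_g2 = sigma_g2, sigma_e2 = sigma_g2 * delta,
                 X = X, y = y, n = n, p = p),
            class = "mlm_null")
}

#' Test markers against a trait under a fitted null mixed model
#'
#' Each marker enters as a fixed effect with the variance ratio held at
#' the null REML estimate; beta and its Wald t-test come from weighted
#' least squares on the spectral axis (exact OLS when K is the identity).
#'
#' @param null an `mlm_null` from [fit_mlm_null()].
#' @param markers matrix (lines x markers) of marker codes, same line
#'   order as the null fit.
#' @return data.frame with `beta`, `se`, `t`, `p` per marker.
#' @export
mlm_scan <- function(null, markers) {
  markers <- as.matrix(markers)
  sw <- sqrt(null$S + null$delta)
  yw <- null$ys / sw
  Xw <- null$Xs / sw
  Gw <- (t(null$U) %*% markers) / sw
  # project covariates out of response and markers (Frisch-Waugh)
  qrX <- qr(Xw)
  yr <- qr.resid(qrX, yw)
  Gr <- qr.resid(qrX, Gw)
  gg <- colSums(Gr^2)
  gy <- colSums(Gr * yr)
  beta <- ifelse(gg > 1e-12, gy / gg, NA_real_)
  df <- null$n - null$p - 1L
  rss <- sum(yr^2) - ifelse(gg > 1e-12, beta^2 * gg, 0)
  se <- sqrt(pmax(rss, 0) / df / gg)
  tval <- beta / se
  p <- 2 * pt(-abs(tval), df)
  data.frame(beta = beta, se = se, t = tval, p = p,
             row.names = colnames(markers))
}

#' Single-marker mixed-model fit
#'
#' Convenience wrapper fitting the null model and one marker in one call.
#'
#' @param y response vector.
#' @param x marker vector.
#' @param K kinship matrix.
#' @param Q covariates (`NULL` for intercept only).
#' @return list with `beta`, `se`, `p`, `variance_components`
#'   (genetic, residual).
#' @export
fit_mlm <- function(y, x, K, Q = NULL) {
  null <- fit_mlm_null(y, K, Q)
  res <- mlm_scan(null, matrix(x, ncol = 1))
  list(beta = res$beta[1], se = res$se[1], p = res$p[1],
       variance_components = c(genetic = null$sigma_g2,
                               residual = null$sigma_e2))
}

#' Residual trait after structure and kinship adjustment
#'
#' Step 1 of the two-step association model: Y is regressed on the
#' structure covariates with a kinship random effect, and the residual
#' Y' = Y - Q b_hat - BLUP(u) carries forward to marker regression.
#'
#' @param y trait vector (inverse-normal transformed upstream).
#' @param K kinship matrix.
#' @param Q covariates (`NULL` for intercept only).
#' @return numeric vector Y' with mean ~ 0.
#' @export
residual_trait <- function(y, K, Q = NULL) {
  null <- fit_mlm_null(y, K, Q)
  w <- null$S + null$delta
  Xw <- null$Xs / sqrt(w)
  yw <- null$ys / sqrt(w)
  b <- qr.coef(qr(Xw), yw)
  fixed <- as.vector(null$X %*% b)
  resid_rot <- null$ys - null$Xs %*% b
  # BLUP on the spectral axis: E[u | y] = sigma_g2 K V^-1 (y - Xb)
  u_rot <- (null$S / w) * as.vector(resid_rot)
  u <- as.vector(null$U %*% u_rot)
  as.vector(null$y - fixed - u)
}
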