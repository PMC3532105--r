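#' Estimate the number of ICA components by minimum description length
#'
#' Eigenvalues of the subject-covariance of the voxel-subsampled data feed
#' the MDL criterion: for candidate order k,
#' `MDL(k) = -N (p - k) log(g_k / a_k) + 0.5 k (2p - k) log(N)`,
#' where `a_k`/`g_k` are the arithmetic/geometric means of the trailing
#' `p - k` eigenvalues, `p` the subject count and `N` the number of
#' (approximately uncorrelated) voxels retained. Voxel subsampling breaks
#' spatial autocorrelation: every `stride`-th voxel is kept, starting at a
#' random offset.
#'
#' @param X subjects x voxels matrix (>= 10 subjects).
#' @param stride voxel subsampling stride (1 = all voxels).
#' @param seed RNG seed for the subsample offset.
#' @param max_order largest order considered (default `p - 2`).
#' @return estimated order `k` (integer >= 1); attribute `mdl` holds the
#'   criterion curve.
#' @export
estimate_order_mdl <- function(X, stride = 1L, seed = 1L,
                               max_order = NULL) {
  p <- nrow(X)
  if (p < 10) stop_arg("need >= 10 subjects for order estimation")
  with_seed(seed, {
    off <- if (stride > 1) sample.int(stride, 1) else 1L
    idx <- seq(off, ncol(X), by = stride)
    if (length(idx) <= p)
      stop_arg("fewer voxels than subjects after subsampling")
    Xs <- X[, idx, drop = FALSE]
    Xs <- Xs - rowMeans(Xs)
    N <- length(idx)
    ev <- eigen(tcrossprod(Xs) / N, symmetric = TRUE,
                only.values = TRUE)$values
    ev <- pmax(ev, .Machine$double.eps)
    kmax <- max_order %||% (p - 2L)
    mdl <- vapply(seq_len(kmax), function(k) {
      tail_ev <- ev[(k + 1):p]
      a <- mean(tail_ev)
      g <- exp(mean(log(tail_ev)))
      -N * (p - k) * log(g / a) + 0.5 * k * (2 * p - k) * log(N)
    }, numeric(1))
    structure(which.min(mdl), mdl = mdl)
  })
}

# Moore-Penrose pseudo-inverse via SVD (small matrices only)
pinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Infomax ICA decomposition of a subject-by-voxel GMC matrix
#'
#' Source-based morphometry: the row-centred data are PCA-whitened to `k`
#' dimensions, then an unmixing matrix is fitted by natural-gradient
#' infomax with the logistic nonlinearity
#' (`dW = lr (I + (1 - 2g(Y)) Y'/v) W`), with the learning rate annealed
#' when successive updates oscillate. Spatial maps are z-scored per
#' component, loadings are defined through the pseudo-inverse
#' back-projection so that `X ~ A S + offset` reproduces the rank-k PCA
#' approximation exactly, and components are ordered by variance
#' explained, descending.
#'
#' @param X subjects x voxels matrix.
#' @param k number of components (`k <= min(dim(X))`).
#' @param learning_rate initial natural-gradient step size.
#' @param max_iter maximum iterations.
#' @param tol convergence tolerance on the relative weight-update norm.
#' @param seed RNG seed for the orthogonal initialisation.
#' @return object of class `gmc_decomposition`: `S` (k x voxels, z-scored),
#'   `A` (subjects x k), `offset` (per-subject reconstruction intercept),
#'   `k`, `variance_explained`, `iterations`, `final_update`, `converged`,
#'   `seed`. Non-convergence sets `converged = FALSE` with a warning, not
#'   an error.
#' @export
infomax_ica <- function(X, k, learning_rate = 0.01, max_iter = 512L,
                        tol = 1e-6, seed = 1L) {
  n <- nrow(X); v <- ncol(X)
  if (k > min(n, v)) stop_arg("k must be <= min(dim(X))")
  rm_ <- rowMeans(X)
  Xc <- X - rm_
  C <- tcrossprod(Xc) / v
  eg <- eigen(C, symmetric = TRUE)
  d <- pmax(eg$values[seq_len(k)], .Machine$double.eps)
  E <- eg$vectors[, seq_len(k), drop = FALSE]
  K <- diag(1 / sqrt(d), k) %*% t(E)          # whitening: k x n
  Z <- K %*% Xc                               # k x voxels, cov = I
  W <- with_seed(seed, {
    qr.Q(qr(matrix(rnorm(k * k), k, k)))      # random orthogonal start
  })
  lr <- learning_rate
  Ik <- diag(k)
  prev_dW <- NULL
  upd <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    Y <- W %*% Z
    g <- 1 / (1 + exp(-Y))
    dW <- lr * (Ik + (1 - 2 * g) %*% t(Y) / v) %*% W
    if (!all(is.finite(dW))) { lr <- lr / 2; prev_dW <- NULL; next }
    # bold-driver annealing: grow the step while updates stay aligned,
    # halve it on oscillation (sign flip of the update inner product)
    if (!is.null(prev_dW)) {
      if (sum(dW * prev_dW) < 0) lr <- lr * 0.5
      else lr <- min(lr * 1.05, 0.25)
    }
    W <- W + dW
    prev_dW <- dW
    upd <- sqrt(sum(dW^2)) / sqrt(sum(W^2))
    if (upd < tol) break
  }
  converged <- upd < tol
  if (!converged)
    warning("infomax did not converge within max_iter; returning last state")
  U <- W %*% K                                # total unmixing: k x n
  S <- U %*% Xc                               # k x voxels
  A <- pinv(U)                                # n x k back-projection
  # order components by variance explained
  tot <- sum(Xc^2)
  vexp <- vapply(seq_len(k), function(i)
    sum((A[, i, drop = FALSE] %*% S[i, , drop = FALSE])^2) / tot,
    numeric(1))
  o <- order(vexp, decreasing = TRUE)
  S <- S[o, , drop = FALSE]; A <- A[, o, drop = FALSE]
  # z-score maps; fold means and row-centering into a per-subject offset
  mu <- rowMeans(S)
  sdv <- apply(S, 1, sd)
  S <- (S - mu) / sdv
  A <- sweep(A, 2, sdv, `*`)
  offset <- as.numeric(A %*% (mu / sdv) * 1) + rm_
  recon <- A %*% S + offset
  ve <- 1 - sum((X - recon)^2) / tot
  structure(list(S = S, A = A, offset = offset, k = k,
                 variance_explained = ve, iterations = iter,
                 final_update = upd, converged = converged, seed = seed),
            class = "gmc_decomposition")
}

#' Reconstruct the data matrix from a decomposition
#' @param dec `gmc_decomposition`.
#' @export
reconstruct_gmc <- function(dec) dec$A %*% dec$S + dec$offset

#' Fix the sign ambiguity of ICA components
#'
#' Each component is flipped, loadings in tandem, so that the skewness of
#' its spatial map is non-negative; the reconstruction `A S` is unchanged
#' and the operation is idempotent.
#' @param dec `gmc_decomposition`.
#' @export
fix_signs <- function(dec) {
  sk <- apply(dec$S, 1, function(s) mean((s - mean(s))^3) / sd(s)^3)
  flip <- ifelse(sk < 0, -1, 1)
  dec$S <- dec$S * flip
  dec$A <- sweep(dec$A, 2, flip, `*`)
  dec
}

#' @export
print.gmc_decomposition <- function(x, ...) {
  cat(sprintf(
    "GMC decomposition: %d components over %d subjects x %d voxels\n",
    x$k, nrow(x$A), ncol(x$S)))
  cat(sprintf("  variance explained: %.4f | iterations: %d | converged: %s\n",
              x$variance_explained, x$iterations, x$converged))
  invisible(x)
}

# shared covariate-adjusted regression of loadings on a regressor
loading_regression <- function(A, reg, age, gender, site, reg_name) {
  k <- ncol(A)
  dat <- data.frame(.r = reg, age = age, gender = factor(gender),
                    site = factor(site))
  res <- lapply(seq_len(k), function(i) {
    fit <- lm(A[, i] ~ ., data = dat)
    cf <- summary(fit)$coefficients
    row <- grep("^\\.r", rownames(cf))[1]
    data.frame(component = i, beta = cf[row, 1], se = cf[row, 2],
               t = cf[row, 3], p = cf[row, 4])
  })
  out <- do.call(rbind, res)
  names(out)[2:5] <- paste0(c("beta", "se", "t", "p"))
  attr(out, "regressor") <- reg_name
  out
}

#' Diagnosis test on network loadings with covariates
#'
#' Per component, fits `loading ~ diagnosis + age + gender + site` (site as
#' dummy variables against a reference level) and reports the diagnosis
#' coefficient with Bonferroni control at `alpha / k` over the k networks.
#'
#' @param A subjects x components loading matrix.
#' @param diagnosis,age,gender,site subject covariates.
#' @param alpha family-wise level.
#' @return data frame per component: `beta`, `se`, `t`, `p`,
#'   `significant`; attribute `threshold = alpha / k`.
#' @export
network_group_test <- function(A, diagnosis, age, gender, site,
                               alpha = 0.05) {
  reg <- as.numeric(diagnosis == "case")
  out <- loading_regression(A, reg, age, gender, site, "diagnosis")
  thr <- alpha / ncol(A)
  out$significant <- out$p < thr
  attr(out, "threshold") <- thr
  out
}

#' Continuous-covariate regression on network loadings
#'
#' Same machinery as [network_group_test()] with a continuous regressor
#' (e.g. medication dosage).
#' @param A subjects x components loading matrix.
#' @param dose continuous regressor (must be non-degenerate).
#' @param age,gender,site subject covariates.
#' @export
loading_covariate_regression <- function(A, dose, age, gender, site) {
  if (sd(dose) == 0) stop_arg("degenerate regressor: `dose` is constant")
  loading_regression(A, dose, age, gender, site, "dose")
}
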