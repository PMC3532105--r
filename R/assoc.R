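#' Bonferroni threshold over networks x CNV features
#'
#' `alpha / (n_components * n_features)`; with a single feature this
#' reduces to `alpha / n_components`.
#' @param n_components,n_features family sizes.
#' @param alpha family-wise level.
#' @export
bonferroni_threshold <- function(n_components, n_features = 1L,
                                 alpha = 0.05) {
  stopifnot(n_components >= 1, n_features >= 1)
  alpha / (n_components * n_features)
}

#' Regress one network's loadings on a CNV feature with covariates
#'
#' Ordinary least squares `loading ~ age + gender + site + feature`; the
#' CNV term's p-value comes from its coefficient t-test, and `delta_R2` is
#' the nested-model R-squared increment (equal to the squared semi-partial
#' correlation of the feature for a single added regressor). Collinear
#' dummy columns are dropped by the rank-revealing fit with a warning;
#' estimates are unchanged.
#'
#' @param loadings numeric vector (one component's loadings).
#' @param feature CNV metric per subject (constant features are skipped:
#'   the row is returned with `NA` statistics and `skipped = TRUE`).
#' @param age,gender,site covariates.
#' @return one-row data frame: `beta`, `se`, `t`, `p`, `delta_R2`, `n`,
#'   `skipped`.
#' @export
regress_loading_on_feature <- function(loadings, feature, age, gender,
                                       site) {
  n <- length(loadings)
  if (sd(feature) == 0)
    return(data.frame(beta = NA_real_, se = NA_real_, t = NA_real_,
                      p = NA_real_, delta_R2 = NA_real_, n = n,
                      skipped = TRUE))
  dat <- data.frame(.y = loadings, age = age, gender = factor(gender),
                    site = factor(site), .f = feature)
  full <- lm(.y ~ ., data = dat)
  if (any(is.na(coef(full))))
    warning("collinear covariate column(s) dropped from the design")
  red <- lm(.y ~ . - .f, data = dat)
  cf <- summary(full)$coefficients
  row <- grep("^\\.f", rownames(cf))[1]
  data.frame(beta = cf[row, 1], se = cf[row, 2], t = cf[row, 3],
             p = cf[row, 4],
             delta_R2 = summary(full)$r.squared - summary(red)$r.squared,
             n = n, skipped = FALSE)
}

#' Full association table: components x screened features
#'
#' Runs [regress_loading_on_feature()] for every (component, feature) pair
#' and flags pairs passing the Bonferroni threshold
#' `alpha / (k * n_features)`.
#'
#' @param A subjects x components loading matrix.
#' @param features subjects x features matrix of CNV metrics.
#' @param age,gender,site covariates.
#' @param alpha family-wise level.
#' @return data frame with `component`, `feature`, the regression columns,
#'   `threshold` and `significant`.
#' @export
association_table <- function(A, features, age, gender, site,
                              alpha = 0.05) {
  features <- as.matrix(features)
  thr <- bonferroni_threshold(ncol(A), ncol(features), alpha)
  rows <- list()
  for (i in seq_len(ncol(A))) for (j in seq_len(ncol(features))) {
    r <- regress_loading_on_feature(A[, i], features[, j], age, gender,
                                    site)
    r$component <- i
    r$feature <- colnames(features)[j] %||% paste0("f", j)
    rows[[length(rows) + 1L]] <- r
  }
  out <- do.call(rbind, rows)
  out$threshold <- thr
  out$significant <- !out$skipped & out$p < thr
  out[, c("component", "feature", "beta", "se", "t", "p", "delta_R2",
          "n", "skipped", "threshold", "significant")]
}

#' Loading differences across deletion-load groups
#'
#' One-way ANOVA of a network's loadings across deletion-load levels
#' (0/1/2), with the percent reduction of each level versus the no-deletion
#' group, `100 (mean_0 - mean_l) / mean_0`. The sign convention requires a
#' positive load-0 mean; if it is negative after sign fixing, loadings are
#' flipped for reporting and the flip recorded.
#'
#' @param loadings numeric vector.
#' @param load per-subject deletion load (0/1/2).
#' @param restrict_to `"all"` or `"cases_only"`.
#' @param diagnosis required when `restrict_to = "cases_only"`.
#' @return list with `groups` (per present level: `load`, `n`, `mean`,
#'   `pct_reduction`), `F`, `p`, `flipped`, and `absent_levels`.
#' @export
deletion_group_anova <- function(loadings, load,
                                 restrict_to = c("all", "cases_only"),
                                 diagnosis = NULL) {
  restrict_to <- match.arg(restrict_to)
  if (restrict_to == "cases_only") {
    if (is.null(diagnosis)) stop_arg("cases_only requires `diagnosis`")
    keep <- diagnosis == "case"
    loadings <- loadings[keep]; load <- load[keep]
  }
  flipped <- FALSE
  m0 <- mean(loadings[load == 0])
  if (is.finite(m0) && m0 < 0) { loadings <- -loadings; flipped <- TRUE }
  levels_present <- sort(unique(load))
  absent <- setdiff(0:2, levels_present)
  groups <- do.call(rbind, lapply(levels_present, function(l) {
    data.frame(load = l, n = sum(load == l),
               mean = mean(loadings[load == l]))
  }))
  m0 <- groups$mean[groups$load == 0]
  groups$pct_reduction <- if (length(m0)) 100 * (m0 - groups$mean) / m0
                          else NA_real_
  if (length(levels_present) >= 2 &&
      all(table(load) >= 1) && sd(loadings) > 0) {
    fit <- aov(loadings ~ factor(load))
    a <- summary(fit)[[1]]
    Fv <- a$`F value`[1]; p <- a$`Pr(>F)`[1]
  } else { Fv <- 0; p <- 1 }
  list(groups = groups, F = Fv, p = p, flipped = flipped,
       absent_levels = absent)
}

#' Span of the CNV calls within a band
#'
#' From the starting position of the first call to the ending position of
#' the last: `span = max(end) - min(start)`.
#' @param calls call table (possibly empty) with `start`, `end`.
#' @return list `start`, `end`, `span` (all `NA` for an empty set).
#' @export
region_span <- function(calls) {
  if (!nrow(calls))
    return(list(start = NA_real_, end = NA_real_, span = NA_real_))
  s <- min(calls$start); e <- max(calls$end)
  list(start = s, end = e, span = e - s)
}

#' Mass-univariate voxelwise regression
#'
#' Fits `voxel ~ covariates + feature` independently at every voxel via a
#' single QR decomposition, reporting the feature's beta, t and p per
#' voxel plus Bonferroni and Benjamini-Hochberg significance maps.
#'
#' @param X subjects x voxels matrix.
#' @param feature CNV metric per subject.
#' @param covariates data frame of covariates.
#' @param alpha level for both corrected maps.
#' @return data frame per voxel: `voxel`, `beta`, `t`, `p`,
#'   `sig_bonferroni`, `sig_bh`.
#' @export
voxelwise_regression <- function(X, feature, covariates, alpha = 0.05) {
  Z <- model.matrix(~ . + feature,
                    data = cbind(covariates, feature = feature))
  qrz <- qr(Z)
  if (qrz$rank < ncol(Z)) {
    keep <- qrz$pivot[seq_len(qrz$rank)]
    Z <- Z[, keep, drop = FALSE]
    qrz <- qr(Z)
  }
  n <- nrow(Z); r <- qrz$rank
  B <- qr.coef(qrz, X)                        # coefficients x voxels
  res <- X - Z %*% B
  sigma2 <- colSums(res^2) / (n - r)
  XtXinv <- solve(crossprod(Z))
  jf <- which(colnames(Z) == "feature")
  se <- sqrt(XtXinv[jf, jf] * sigma2)
  beta <- B[jf, ]
  t <- beta / se
  p <- 2 * pt(-abs(t), n - r)
  data.frame(voxel = seq_len(ncol(X)), beta = beta, t = t, p = p,
             sig_bonferroni = p < alpha / ncol(X),
             sig_bh = p.adjust(p, "BH") < alpha)
}
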