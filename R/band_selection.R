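#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' `KMO = sum r_ij^2 / (sum r_ij^2 + sum q_ij^2)` over off-diagonal pairs,
#' where `r` are Pearson correlations and `q` the anti-image partial
#' correlations obtained from the inverse correlation matrix.  Values above
#' 0.7 indicate that PCA is applicable.  Nineteen collinear reflectance
#' bands routinely give a near-singular correlation matrix, so a small ridge
#' is added before inversion when needed.
#'
#' @param x Numeric matrix or data frame of observations x features (p >= 3).
#' @param ridge Ridge added to the correlation diagonal if it is not
#'   invertible (default 1e-8).
#' @return Overall KMO value in [0, 1].
#' @export
#' @examples
#' kmo_measure(matrix(rnorm(100), 25, 4))
kmo_measure <- function(x, ridge = 1e-8) {
  m <- as.matrix(x)
  if (ncol(m) < 3) abort("need at least 3 features")
  if (any(apply(m, 2, sd) == 0)) abort("zero variance feature")
  R <- cor(m)
  Rinv <- tryCatch(solve(R), error = function(e) {
    solve(R + diag(ridge, ncol(R)))
  })
  d <- 1 / sqrt(diag(Rinv))
  Q <- -Rinv * tcrossprod(d)       # anti-image partial correlations
  off <- upper.tri(R)
  sum(R[off]^2) / (sum(R[off]^2) + sum(Q[off]^2))
}

#' Bartlett's test of sphericity
#'
#' Tests whether the correlation matrix is the identity:
#' `chi2 = -(n - 1 - (2p + 5)/6) * ln det(R)` with `p(p-1)/2` degrees of
#' freedom and an upper-tail chi-squared p-value.
#'
#' @inheritParams kmo_measure
#' @return One-row tibble with `chi2`, `df`, `p_value`.
#' @export
#' @examples
#' bartlett_sphericity(matrix(rnorm(200), 50, 4))
bartlett_sphericity <- function(x) {
  m <- as.matrix(x)
  n <- nrow(m)
  p <- ncol(m)
  R <- cor(m)
  detR <- det(R)
  if (detR <= 0) {
    abort("singular correlation matrix; consider a ridge on R or fewer bands")
  }
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * log(detR)
  df <- p * (p - 1) / 2
  tibble::tibble(chi2 = chi2, df = df,
                 p_value = pchisq(chi2, df, lower.tail = FALSE))
}

#' Principal component decomposition on standardized features
#'
#' PCA on the correlation matrix (features standardized internally), with a
#' deterministic sign convention: each component's largest-magnitude loading
#' is positive.  Explained-variance ratios are sorted descending.
#'
#' @inheritParams kmo_measure
#' @param k Number of components to keep (1 <= k <= min(n, p)).
#' @return A `zeax_pca` list: `loadings` (p x k), `scores` (n x k),
#'   `explained_variance_ratio` (length k).
#' @export
#' @examples
#' pca_decompose(matrix(rnorm(100), 25, 4), k = 2)
pca_decompose <- function(x, k = 2) {
  m <- as.matrix(x)
  if (k <= 0) abort("k must be positive")
  k <- as.integer(k)
  if (k > min(dim(m))) abort("k must be <= min(n, p)")
  pc <- prcomp(m, center = TRUE, scale. = TRUE)
  ratio <- pc$sdev^2 / sum(pc$sdev^2)
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(loadings = load, scores = scores,
                 explained_variance_ratio = ratio[seq_len(k)]),
            class = "zeax_pca")
}

#' Variance-weighted composite score of leading components
#'
#' `F_i = sum_j ratio_j * score_ij / sum_j ratio_j` over the first `k`
#' components: a single response summarising the dominant spectral
#' variation, regressed on band reflectances to select characteristic
#' wavelengths.
#'
#' @param scores n x k (or wider) score matrix.
#' @param ratios Explained-variance ratios aligned with the score columns.
#' @param k Number of leading components to combine (default 2).
#' @return Numeric vector of per-sample composite scores.
#' @export
composite_score <- function(scores, ratios, k = 2) {
  scores <- as.matrix(scores)
  if (k > ncol(scores) || k > length(ratios)) abort("k exceeds available PCs")
  w <- ratios[seq_len(k)]
  if (sum(w) == 0) abort("ratio sum is zero")
  drop(scores[, seq_len(k), drop = FALSE] %*% w) / sum(w)
}

#' Backward stepwise selection of characteristic wavelengths
#'
#' Starts from a linear model of the response on all bands and iteratively
#' removes the predictor with the largest p-value above `alpha_remove`
#' (aliased predictors first), refitting until every surviving predictor is
#' significant.  Near-collinear bands are handled by the refit at each step.
#'
#' @param f Response vector (typically the PCA [composite_score()]).
#' @param bands Data frame or matrix of band reflectances with
#'   wavelength-named columns.
#' @param alpha_remove Removal threshold in (0, 1), default 0.05.
#' @return A `stepwise_fit` list: `selected_wavelengths_nm`, `r`, `r2`,
#'   `model` (the final `lm`), `removed` (in removal order).
#' @export
backward_stepwise <- function(f, bands, alpha_remove = 0.05) {
  if (alpha_remove <= 0 || alpha_remove >= 1) {
    abort("alpha_remove must be in (0, 1)")
  }
  x <- as.data.frame(as.matrix(bands))
  orig <- colnames(x)
  safe <- paste0("b", seq_along(orig))
  colnames(x) <- safe
  dat <- cbind(data.frame(.f = f), x)
  keep <- safe
  removed <- character(0)
  repeat {
    if (length(keep) == 0) abort("empty model: no predictor survives")
    fit <- lm(stats::reformulate(keep, ".f"), data = dat)
    sm <- suppressWarnings(summary(fit))$coefficients
    pv <- rep(1, length(keep))                 # aliased -> treated as worst
    names(pv) <- keep
    present <- intersect(rownames(sm), keep)
    pv[present] <- sm[present, 4]
    worst <- which.max(pv)
    if (pv[worst] > alpha_remove) {
      removed <- c(removed, names(pv)[worst])
      keep <- setdiff(keep, names(pv)[worst])
    } else {
      break
    }
  }
  r2 <- suppressWarnings(summary(fit))$r.squared
  structure(list(
    selected_wavelengths_nm = as.numeric(orig[match(keep, safe)]),
    r = cor(f, stats::fitted(fit)),
    r2 = r2,
    model = fit,
    removed = as.numeric(orig[match(removed, safe)])),
    class = "stepwise_fit")
}

#' Characteristic-wavelength selection pipeline
#'
#' Runs the full applicability-gated selection on a spectra table: KMO and
#' Bartlett sphericity tests, correlation-matrix PCA, the variance-weighted
#' composite score of the leading components, and backward stepwise
#' regression of that score on the band reflectances.
#'
#' @param spectra Spectra tibble.
#' @param n_pcs Number of leading components for the composite score
#'   (default 2).
#' @param alpha_remove Stepwise removal threshold (default 0.05).
#' @param max_bands Optional cap on the number of selected bands; if the
#'   stepwise survivors exceed it, the bands with the smallest absolute
#'   t statistics are dropped (with refits) until the cap is met.
#' @return A `band_selection` object (list) with fields `kmo`, `bartlett`,
#'   `pca`, `composite_scores`, `stepwise`, `selected_wavelengths_nm`.
#' @export
#' @examples
#' d <- simulate_peppers(seed = 1)
#' sel <- select_bands(d$spectra)
#' sel$selected_wavelengths_nm
select_bands <- function(spectra, n_pcs = 2, alpha_remove = 0.05,
                         max_bands = NULL) {
  m <- spectra_matrix(spectra)
  wl <- attr(m, "wavelengths_nm")
  colnames(m) <- as.character(wl)
  kmo <- kmo_measure(m)
  bart <- bartlett_sphericity(m)
  pca <- pca_decompose(m, k = n_pcs)
  f <- composite_score(pca$scores, pca$explained_variance_ratio, k = n_pcs)
  sw <- backward_stepwise(f, m, alpha_remove = alpha_remove)
  if (!is.null(max_bands)) {
    while (length(sw$selected_wavelengths_nm) > max_bands) {
      keep <- as.character(sw$selected_wavelengths_nm)
      fit <- lm(f ~ ., data = as.data.frame(m[, keep, drop = FALSE],
                                            check.names = FALSE))
      tstats <- abs(suppressWarnings(summary(fit))$coefficients[-1, 3])
      drop_wl <- keep[which.min(tstats)]
      keep <- setdiff(keep, drop_wl)
      sw <- backward_stepwise(f, m[, keep, drop = FALSE],
                              alpha_remove = 1 - 1e-12)
    }
  }
  structure(list(kmo = kmo, bartlett = bart, pca = pca,
                 composite_scores = f, stepwise = sw,
                 selected_wavelengths_nm = sw$selected_wavelengths_nm),
            class = "band_selection")
}

#' @export
print.band_selection <- function(x, ...) {
  cat(sprintf("<band_selection> KMO %.3f | Bartlett chi2 %.1f (df %d, p %.3g)\n",
              x$kmo, x$bartlett$chi2, x$bartlett$df, x$bartlett$p_value))
  cat(sprintf("  PC variance ratios: %s\n",
              paste(sprintf("%.1f%%", 100 * x$pca$explained_variance_ratio),
                    collapse = ", ")))
  cat(sprintf("  selected bands (nm): %s  (r = %.3f, R2 = %.3f)\n",
              paste(sort(x$selected_wavelengths_nm), collapse = ", "),
              x$stepwise$r, x$stepwise$r2))
  invisible(x)
}

#' @method tidy band_selection
#' @export
tidy.band_selection <- function(x, ...) {
  tibble::tibble(
    wavelength_nm = sort(x$selected_wavelengths_nm),
    selected = TRUE
  )
}

#' @method glance band_selection
#' @export
glance.band_selection <- function(x, ...) {
  tibble::tibble(
    kmo = x$kmo,
    bartlett_chi2 = x$bartlett$chi2,
    bartlett_df = x$bartlett$df,
    bartlett_p = x$bartlett$p_value,
    pc_variance = sum(x$pca$explained_variance_ratio),
    n_selected = length(x$selected_wavelengths_nm),
    stepwise_r = x$stepwise$r,
    stepwise_r2 = x$stepwise$r2
  )
}
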