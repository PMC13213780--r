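#' Ablation experiment over input configurations
#'
#' Trains five models under identical hyperparameters and the same split,
#' differing only in their inputs, to isolate the contribution of the
#' chemical modality:
#' \describe{
#'   \item{M-Spectral}{spectral data only.}
#'   \item{M-Chemical}{the two chemical indicators only (chemical branch +
#'     dense head).}
#'   \item{M-S+R}{spectra + two uninformative standard-normal noise
#'     features.}
#'   \item{M-S+N}{spectra + chemical data perturbed multiplicatively by 5%
#'     relative Gaussian noise, `x * (1 + eps)`, `eps ~ N(0, 0.05)`.}
#'   \item{M-MCSF}{spectra + authentic chemical data.}
#' }
#'
#' @param dataset A `pepper_dataset`.
#' @param split Assignment from [stratified_split()].
#' @param config [train_config()]; its seed also drives the noise draws.
#' @return An `ablation_result` tibble: `configuration`, `r2`, `rmse` on
#'   the test set.
#' @export
ablation_suite <- function(dataset, split, config = train_config()) {
  chem <- as.matrix(dataset$chemistry[c("capsanthin_g_per_kg",
                                        "total_carotenoids_g_per_kg")])
  n <- nrow(chem)
  set.seed(config$seed)
  noise_feats <- matrix(rnorm(2 * n), n, 2,
                        dimnames = list(NULL, c("noise1", "noise2")))
  perturbed <- chem * (1 + matrix(rnorm(2 * n, 0, 0.05), n, 2))
  configs <- list(
    `M-Spectral` = list(tag = "spectral", chem = NULL),
    `M-Chemical` = list(tag = "chemical", chem = chem),
    `M-S+R` = list(tag = "mcsf", chem = noise_feats),
    `M-S+N` = list(tag = "mcsf", chem = perturbed),
    `M-MCSF` = list(tag = "mcsf", chem = chem)
  )
  res <- purrr::imap_dfr(configs, function(cc, nm) {
    ex <- tryCatch(
      fusion_experiment(dataset, split, tag = cc$tag, config = config,
                        chem_override = cc$chem),
      error = function(e) abort(paste0("configuration ", nm,
                                       " failed: ", conditionMessage(e))))
    dplyr::mutate(ex$metrics[c("r2", "rmse")], configuration = nm,
                  .before = 1)
  })
  class(res) <- c("ablation_result", class(res))
  res
}

#' Sensitivity of the fusion model to chemical-feature correlation
#'
#' For each correlation level, replaces capsanthin by a synthetic proxy
#' with that Pearson correlation to the true zeaxanthin content
#' ([correlated_proxy()]), keeps total carotenoids unchanged, retrains the
#' MCSF model from scratch, and records the test-set R2.  A rising curve
#' shows the model exploiting informative priors without overfitting to
#' uninformative ones.
#'
#' @param dataset A `pepper_dataset`.
#' @param split Assignment from [stratified_split()].
#' @param rhos Increasing correlation grid in [0, 1) (default 0.2-0.95).
#' @param config [train_config()].
#' @return A `sensitivity_curve` tibble: `rho`, `r2`, `rmse`.
#' @export
sensitivity_sweep <- function(dataset, split,
                              rhos = seq(0.2, 0.95, by = 0.15),
                              config = train_config()) {
  if (is.unsorted(rhos, strictly = TRUE)) abort("rho grid must be increasing")
  zeax <- dataset$chemistry$zeaxanthin_g_per_kg
  total <- dataset$chemistry$total_carotenoids_g_per_kg
  res <- purrr::map_dfr(rhos, function(rho) {
    proxy <- correlated_proxy(zeax, rho, seed = config$seed + round(1e4 * rho))
    ex <- fusion_experiment(dataset, split, tag = "mcsf", config = config,
                            chem_override = cbind(capsanthin_proxy = proxy,
                                                  total = total))
    dplyr::mutate(ex$metrics[c("r2", "rmse")], rho = rho, .before = 1)
  })
  class(res) <- c("sensitivity_curve", class(res))
  res
}

#' Grad-CAM band saliency for a convolutional spectral model
#'
#' Gradient-weighted activation mapping along the wavelength axis: channel
#' weights are the positional average of the gradient of the output with
#' respect to the final convolutional feature map; the map is the rectified
#' channel-weighted sum of activations, linearly interpolated from pooled
#' positions back to the input bands.  Non-negative by construction.
#'
#' @param model Trained `zeax_model` with a convolutional encoder
#'   (`spectral`, `mcsf`, or `mcsf_fr`).
#' @param spectra A one-row spectra tibble (or 1 x p matrix), preprocessed
#'   the same way as the training inputs.
#' @param chemistry Chemical input for fusion models (one row).
#' @return A `saliency_map` tibble: `wavelength_nm` (band index when
#'   unnamed), `weight` (>= 0, length = number of input bands).
#' @export
grad_cam_1d <- function(model, spectra, chemistry = NULL) {
  stopifnot(inherits(model, "zeax_model"))
  if (model$tag == "chemical") abort("model has no convolutional encoder")
  if (!model$trained) abort("model is not trained")
  wl <- if (is.data.frame(spectra)) {
    suppressWarnings(as.numeric(setdiff(names(spectra), "sample_id")))
  } else {
    suppressWarnings(as.numeric(colnames(spectra)))
  }
  inp <- prepare_inputs(model, spectra, chemistry)
  if (nrow(inp$X) != 1) abort("grad_cam_1d expects a single spectrum")
  fw <- nn_forward(model$net, inp$X, inp$C, training = FALSE)
  cache <- fw$cache
  w <- model$net$w
  q <- cache$q
  p <- cache$p

  # gradient of the scalar output w.r.t. the post-ReLU conv2 activations
  if (model$tag == "spectral") {
    dH <- t(w$W4)                               # 1 x 16
    dHpre <- dH * (cache$Hpre > 0)
    dF <- dHpre %*% t(w$W3)                     # 1 x 32
  } else {
    dRr <- t(w$Wo)                              # 1 x 48
    dBN <- dRr * (cache$BNout > 0)
    dZf <- dBN * w$gamma * cache$ivar           # eval-mode batchnorm
    dFcat <- dZf %*% t(w$Wf)
    dF <- dFcat[, 1:32, drop = FALSE]
  }
  dA2 <- matrix(rep(drop(dF) / q, each = q), q, 32)   # q x 32 gradient
  channel_w <- colMeans(dA2)
  A2 <- matrix(cache$A2, q, 32)
  map_q <- relu(drop(A2 %*% channel_w))

  # pooled position k covers input bands 2k-1 and 2k
  centers <- 2 * seq_len(q) - 0.5
  map_p <- approx(centers, map_q, xout = seq_len(p), rule = 2)$y
  if (is.null(wl) || length(wl) != p || anyNA(wl)) wl <- seq_len(p)
  out <- tibble::tibble(wavelength_nm = wl, weight = pmax(map_p, 0))
  class(out) <- c("saliency_map", class(out))
  out
}

#' t-SNE embedding of pre-head model features
#'
#' Projects the feature representation entering the regression head (32-d
#' spectral or 40-d fused, see [model_features()]) into two dimensions with
#' exact t-SNE.  On two-cluster populations the fused feature space
#' typically separates the genetic backgrounds that the spectral-only space
#' leaves as a continuous gradient.
#'
#' @param model Trained `zeax_model`.
#' @param spectra Spectra tibble (preprocessed as at training time).
#' @param chemistry Chemical input for fusion models.
#' @param seed Integer seed (deterministic embedding).
#' @param perplexity t-SNE perplexity (default 15).
#' @return Tibble with `sample_id`, `dim1`, `dim2`; the feature matrix used
#'   is attached as attribute `"features"`.
#' @export
tsne_features <- function(model, spectra, chemistry = NULL, seed = 1,
                          perplexity = 15) {
  feats <- model_features(model, spectra, chemistry)
  emb <- tsne_embed(feats, perplexity = perplexity, seed = seed)
  ids <- if (is.data.frame(spectra) && "sample_id" %in% names(spectra)) {
    spectra$sample_id
  } else {
    seq_len(nrow(feats))
  }
  out <- tibble::tibble(sample_id = ids, dim1 = emb[, 1], dim2 = emb[, 2])
  attr(out, "features") <- feats
  out
}
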