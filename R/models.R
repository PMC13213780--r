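#' Build an untrained spectral / fusion model
#'
#' Constructs the compact 1-D convolutional regressor family.  All
#' convolutional variants share the same spectral encoder (two kernel-3
#' convolutions with a width-2 max pool between them and global average
#' pooling after), so the trainable parameter count does not depend on the
#' number of input bands.  Tags:
#' \describe{
#'   \item{`spectral`}{encoder + dense 32-16-1 head (2177 parameters).}
#'   \item{`mcsf`}{encoder + chemical branch (capsanthin, total carotenoids:
#'     dense 2-16 ReLU, 16-8), 40-d concatenation, dense 40-48 with batch
#'     normalization and ReLU, dense 48-1 (3929 parameters).}
#'   \item{`mcsf_fr`}{identical network to `mcsf`; the chemical input is
#'     (composite red index, total carotenoids).}
#'   \item{`chemical`}{chemical branch + dense 8-1 head only (ablation
#'     control).}
#' }
#'
#' @param tag Model tag, one of `"spectral"`, `"mcsf"`, `"mcsf_fr"`,
#'   `"chemical"`.
#' @param n_bands Number of spectral bands the model will see (>= 4;
#'   recorded for input validation, not a parameter-count driver).
#' @return An untrained `zeax_model`.
#' @export
#' @examples
#' count_parameters(build_model("spectral", 19))
#' count_parameters(build_model("mcsf", 19))
build_model <- function(tag = c("spectral", "mcsf", "mcsf_fr", "chemical"),
                        n_bands = 19) {
  tag <- match.arg(tag)
  if (tag != "chemical" && n_bands < 4) abort("n_bands must be >= 4")
  net <- nn_init(tag, seed = 0)
  structure(list(tag = tag, n_bands = as.integer(n_bands), net = net,
                 trained = FALSE, norm = NULL, config = NULL,
                 history = NULL),
            class = "zeax_model")
}

#' Count trainable parameters of a model
#'
#' Sums the element counts of all trainable tensors.  Batch-normalization
#' running statistics are buffers, not parameters, and are excluded.
#'
#' @param model A `zeax_model`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "zeax_model"))
  sum(vapply(model$net$w, length, integer(1)))
}

#' Training configuration
#'
#' Full-batch Adam on mean-squared error with early stopping on an internal
#' held-out fold.  Defaults suit the ~126-sample calibration sets this
#' package targets.
#'
#' @param epochs Maximum epochs (default 2000).
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size Mini-batch size; `NULL` (the default) trains full
#'   batch, which suits the target calibration sizes (n <= 159).
#' @param patience Early-stopping patience in epochs (default 100).
#' @param min_epochs Burn-in before early stopping may trigger (default 300;
#'   batch-normalization running statistics make the monitored validation
#'   loss unreliable in the first epochs).
#' @param weight_decay Decoupled per-step multiplicative weight decay
#'   (default 5e-3) applied to all tensors except the batch-normalization
#'   scale and shift.  Essential at these sample sizes: without it the
#'   fusion network memorizes the calibration set before the chemical
#'   branch is exploited.
#' @param val_fraction Fraction of the training data held out for early
#'   stopping (default 0.15; disabled below 10 samples).
#' @param seed Integer seed controlling weight initialization and the
#'   held-out fold.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 2000, learning_rate = 1e-3,
                         batch_size = NULL, patience = 100,
                         min_epochs = 300, weight_decay = 5e-3,
                         val_fraction = 0.15, seed = 1) {
  if (epochs <= 0) abort("epochs must be positive")
  structure(list(epochs = as.integer(epochs),
                 learning_rate = learning_rate, batch_size = batch_size,
                 patience = as.integer(patience),
                 min_epochs = as.integer(min_epochs),
                 weight_decay = weight_decay,
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "train_config")
}

chem_matrix <- function(chemistry) {
  if (is.null(chemistry)) return(NULL)
  df <- as.data.frame(chemistry)
  df <- df[vapply(df, is.numeric, logical(1))]
  m <- as.matrix(df)
  if (ncol(m) != 2) abort("chemical input must have exactly 2 numeric features")
  m
}

#' Train a spectral / fusion model
#'
#' Minimizes mean-squared error with full-batch Adam.  Spectral and chemical
#' inputs are min-max normalized per feature and the response standardized,
#' all with statistics captured from the training data and stored in the
#' fitted model, so prediction on held-out data reuses calibration
#' statistics only.  Training is deterministic given `config$seed`.
#'
#' @param model An untrained [build_model()] result.
#' @param spectra Spectra tibble (or bare numeric matrix) of the training
#'   samples; ignored for the `"chemical"` tag.
#' @param y Numeric response (zeaxanthin, g/kg).
#' @param chemistry Two-feature data frame / matrix for fusion tags.
#' @param config A [train_config()].
#' @return The trained `zeax_model` (weights, normalization statistics,
#'   loss history).
#' @export
#' @examples
#' d <- simulate_peppers(seed = 1)
#' m <- build_model("spectral", 19)
#' fit <- train_model(m, d$spectra, d$chemistry$zeaxanthin_g_per_kg,
#'                    config = train_config(epochs = 50))
train_model <- function(model, spectra, y, chemistry = NULL,
                        config = train_config()) {
  stopifnot(inherits(model, "zeax_model"))
  tag <- model$tag
  X <- NULL
  if (tag != "chemical") {
    X <- if (is.data.frame(spectra)) spectra_matrix(spectra) else
      as.matrix(spectra)
    if (ncol(X) != model$n_bands) {
      abort(sprintf("model expects %d bands, got %d", model$n_bands, ncol(X)))
    }
  }
  C <- if (tag == "spectral") NULL else chem_matrix(chemistry)
  n <- length(y)
  if (!is.null(X) && nrow(X) != n) abort("spectra/response length mismatch")
  if (!is.null(C) && nrow(C) != n) abort("chemistry/response length mismatch")

  norm <- list()
  if (!is.null(X)) {
    Xn <- minmax_normalize(X)
    norm$x <- attr(Xn, "minmax_stats")
    X <- unclass(Xn)
  }
  if (!is.null(C)) {
    Cn <- minmax_normalize(C)
    norm$c <- attr(Cn, "minmax_stats")
    C <- unclass(Cn)
  }
  norm$y <- c(mean = mean(y), sd = if (sd(y) > 0) sd(y) else 1)
  yn <- (y - norm$y["mean"]) / norm$y["sd"]

  set.seed(config$seed)
  n_val <- if (n >= 10 && config$val_fraction > 0) {
    max(1L, round(config$val_fraction * n))
  } else 0L
  val_idx <- if (n_val > 0) sample.int(n, n_val) else integer(0)
  fit_idx <- setdiff(seq_len(n), val_idx)

  net <- nn_init(tag, seed = config$seed)
  st <- adam_init(net$w)
  Xf <- Cf <- Xv <- Cv <- NULL
  if (!is.null(X)) {
    Xf <- X[fit_idx, , drop = FALSE]
    attr(Xf, "unfold") <- conv1_unfold(Xf)
    attr(Xf, "conv_idx") <- conv_indices(nrow(Xf), ncol(Xf))
    if (n_val > 0) {
      Xv <- X[val_idx, , drop = FALSE]
      attr(Xv, "unfold") <- conv1_unfold(Xv)
      attr(Xv, "conv_idx") <- conv_indices(nrow(Xv), ncol(Xv))
    }
  }
  if (!is.null(C)) {
    Cf <- C[fit_idx, , drop = FALSE]
    if (n_val > 0) Cv <- C[val_idx, , drop = FALSE]
  }
  yf <- yn[fit_idx]
  yv <- yn[val_idx]

  best <- list(loss = Inf, w = net$w, buffers = net$buffers, epoch = 0L)
  wait <- 0L
  nf <- length(yf)
  bs <- config$batch_size %||% nf
  bs <- min(bs, nf)
  wd <- config$weight_decay %||% 0
  decayable <- setdiff(names(net$w), c("gamma", "beta"))
  hist_train <- hist_val <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- if (bs < nf) sample.int(nf) else seq_len(nf)
    starts <- seq(1L, nf, by = bs)
    ep_loss <- 0
    for (s0 in starts) {
      idx <- ord[s0:min(s0 + bs - 1L, nf)]
      if (bs < nf) {
        Xb <- if (is.null(Xf)) NULL else Xf[idx, , drop = FALSE]
        Cb <- if (is.null(Cf)) NULL else Cf[idx, , drop = FALSE]
      } else {
        Xb <- Xf
        Cb <- Cf
      }
      yb <- yf[idx]
      fw <- nn_forward(net, Xb, Cb, training = TRUE)
      net$buffers <- fw$buffers
      resid <- fw$yhat - yb
      loss <- mean(resid^2)
      if (!is.finite(loss)) abort("diverged: reduce learning rate")
      ep_loss <- ep_loss + loss * length(yb)
      g <- nn_backward(net, fw$cache, 2 * resid / length(yb))
      ad <- adam_step(net$w, g, st, lr = config$learning_rate)
      net$w <- ad$w
      st <- ad$state
      if (wd > 0) {
        for (nm in decayable) {
          net$w[[nm]] <- net$w[[nm]] * (1 - wd)
        }
      }
    }
    hist_train[ep] <- ep_loss / nf
    if (n_val > 0) {
      fv <- nn_forward(net, Xv, Cv, training = FALSE)
      vloss <- mean((fv$yhat - yv)^2)
      if (!is.finite(vloss)) abort("diverged: reduce learning rate")
      hist_val[ep] <- vloss
      if (vloss < best$loss - 1e-9) {
        best <- list(loss = vloss, w = net$w, buffers = net$buffers,
                     epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (ep >= (config$min_epochs %||% 0L) && wait >= config$patience) break
      }
    } else {
      best <- list(loss = loss, w = net$w, buffers = net$buffers, epoch = ep)
    }
  }
  net$w <- best$w
  net$buffers <- best$buffers

  model$net <- net
  model$trained <- TRUE
  model$norm <- norm
  model$config <- config
  model$history <- tibble::tibble(
    epoch = seq_len(ep), train_mse = hist_train[seq_len(ep)],
    val_mse = if (n_val > 0) hist_val[seq_len(ep)] else NA_real_)
  model$best_epoch <- best$epoch
  model
}

prepare_inputs <- function(object, spectra, chemistry) {
  X <- C <- NULL
  if (object$tag != "chemical") {
    X <- if (is.data.frame(spectra)) spectra_matrix(spectra) else
      as.matrix(spectra)
    X <- unclass(minmax_normalize(X, stats = object$norm$x))
  }
  if (object$tag != "spectral") {
    C <- unclass(minmax_normalize(chem_matrix(chemistry),
                                  stats = object$norm$c))
  }
  list(X = X, C = C)
}

#' Predict zeaxanthin content from a trained model
#'
#' @param object Trained `zeax_model`.
#' @param spectra Spectra tibble or matrix (ignored by the chemical-only
#'   model).
#' @param chemistry Two-feature chemical input for fusion models.
#' @param ... Unused.
#' @return Numeric vector of predictions on the original response scale.
#' @export
predict.zeax_model <- function(object, spectra = NULL, chemistry = NULL,
                               ...) {
  if (!object$trained) abort("model is not trained")
  inp <- prepare_inputs(object, spectra, chemistry)
  fw <- nn_forward(object$net, inp$X, inp$C, training = FALSE)
  drop(fw$yhat) * object$norm$y["sd"] + object$norm$y["mean"]
}

#' Pre-head feature representation of samples
#'
#' Returns the feature vector entering the final regression head: the 32-d
#' global-average-pooled spectral encoding for the spectral model, or the
#' 40-d fused (spectral + chemical) representation for MCSF variants.  Used
#' by the t-SNE feature-space diagnostics.
#'
#' @inheritParams predict.zeax_model
#' @return Numeric matrix, one row per sample.
#' @export
model_features <- function(object, spectra = NULL, chemistry = NULL) {
  stopifnot(inherits(object, "zeax_model"))
  if (!object$trained) abort("model is not trained")
  inp <- prepare_inputs(object, spectra, chemistry)
  fw <- nn_forward(object$net, inp$X, inp$C, training = FALSE)
  switch(object$tag,
         spectral = fw$cache$Fm,
         chemical = fw$cache$C2,
         fw$cache$Fcat)
}

#' @export
print.zeax_model <- function(x, ...) {
  cat(sprintf("<zeax_model:%s> %s, %d trainable parameters\n", x$tag,
              if (x$trained) "trained" else "untrained",
              count_parameters(x)))
  invisible(x)
}

#' @method glance zeax_model
#' @export
glance.zeax_model <- function(x, ...) {
  tibble::tibble(
    tag = x$tag,
    n_parameters = count_parameters(x),
    trained = x$trained,
    epochs_run = if (is.null(x$history)) NA_integer_ else nrow(x$history),
    best_epoch = x$best_epoch %||% NA_integer_,
    final_train_mse = if (is.null(x$history)) NA_real_ else
      x$history$train_mse[nrow(x$history)])
}

#' @method tidy zeax_model
#' @export
tidy.zeax_model <- function(x, ...) {
  purrr::map_dfr(names(x$net$w), function(nm) {
    tibble::tibble(tensor = nm, n = length(x$net$w[[nm]]),
                   l2_norm = sqrt(sum(x$net$w[[nm]]^2)))
  })
}

#' Leave-one-out cross-validation
#'
#' Fits `fit_fun` n times, leaving one sample out each time, and pools the
#' out-of-fold predictions.  Validation metrics (Rv2, RMSEv) are computed on
#' the pooled vector.
#'
#' @param fit_fun `function(x_train, y_train, chem_train)` returning a
#'   prediction function `function(x_new, chem_new)`.
#' @param x Feature table/matrix (rows = samples); may be `NULL` for
#'   chemistry-only learners.
#' @param y Response vector (n >= 3).
#' @param chemistry Optional chemical feature table aligned with `y`.
#' @return Tibble with `fold`, `observed`, `predicted`.
#' @export
#' @examples
#' mean_learner <- function(x, y, chem) function(xn, cn) rep(mean(y), 1)
#' loocv(mean_learner, x = NULL, y = c(1, 2, 3))
loocv <- function(fit_fun, x, y, chemistry = NULL) {
  n <- length(y)
  if (n < 3) abort("need n >= 3 for LOOCV")
  row_sub <- function(obj, idx) {
    if (is.null(obj)) return(NULL)
    if (is.data.frame(obj)) obj[idx, , drop = FALSE] else
      obj[idx, , drop = FALSE]
  }
  preds <- vapply(seq_len(n), function(i) {
    f <- fit_fun(row_sub(x, -i), y[-i], row_sub(chemistry, -i))
    as.numeric(f(row_sub(x, i), row_sub(chemistry, i)))[1]
  }, numeric(1))
  tibble::tibble(fold = seq_len(n), observed = y, predicted = preds)
}

#' Baseline learners (random forest, backpropagation net, PLS)
#'
#' Thin wrappers over established implementations, with hyperparameters
#' recorded in the returned object: random forest
#' (`randomForest::randomForest`), a single-hidden-layer backpropagation
#' network (`nnet::nnet`, inputs standardized), and partial least squares
#' regression (`mixOmics::pls`).
#'
#' @param tag One of `"rf"`, `"bp"`, `"pls"`.
#' @param x Feature matrix or data frame.
#' @param y Numeric response.
#' @param ntree Random-forest trees (default 500).
#' @param hidden Hidden units for the BP network (default 8).
#' @param decay Weight decay for the BP network (default 1e-3).
#' @param maxit BP training iterations (default 500).
#' @param ncomp PLS components (default 2; must not exceed the rank of the
#'   centred feature matrix).
#' @param seed Seed for the stochastic learners.
#' @return A `zeax_baseline` object with a `predict()` method.
#' @export
#' @examples
#' X <- matrix(rnorm(200), 50, 4)
#' y <- X %*% c(1, 2, 0, 0) + rnorm(50, 0, 0.1)
#' fit <- fit_baseline("pls", X, y, ncomp = 4)
#' cor(predict(fit, X), y)^2
fit_baseline <- function(tag = c("rf", "bp", "pls"), x, y, ntree = 500,
                         hidden = 8, decay = 1e-3, maxit = 500, ncomp = 2,
                         seed = 1) {
  tag <- match.arg(tag)
  X <- as.matrix(x)
  set.seed(seed)
  obj <- switch(tag,
    rf = {
      fit <- randomForest::randomForest(x = X, y = as.numeric(y),
                                        ntree = ntree)
      list(fit = fit, hyper = list(ntree = ntree, seed = seed))
    },
    bp = {
      ctr <- colMeans(X)
      scl <- apply(X, 2, sd)
      scl[scl == 0] <- 1
      Xs <- scale(X, ctr, scl)
      fit <- nnet::nnet(Xs, matrix(as.numeric(y)), size = hidden,
                        linout = TRUE, decay = decay, maxit = maxit,
                        trace = FALSE)
      list(fit = fit, center = ctr, scale = scl,
           hyper = list(hidden = hidden, decay = decay, maxit = maxit,
                        seed = seed))
    },
    pls = {
      r <- qr(scale(X, scale = FALSE))$rank
      if (ncomp > r) abort("pls components exceed rank of feature matrix")
      if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
      fit <- mixOmics::pls(X, as.numeric(y), ncomp = ncomp,
                           mode = "regression")
      list(fit = fit, ncomp = ncomp, cols = colnames(X),
           hyper = list(ncomp = ncomp))
    })
  structure(c(obj, list(tag = tag)), class = "zeax_baseline")
}

#' @export
predict.zeax_baseline <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  switch(object$tag,
    rf = as.numeric(predict(object$fit, X)),
    bp = as.numeric(predict(object$fit, scale(X, object$center,
                                              object$scale))),
    pls = {
      colnames(X) <- object$cols
      as.numeric(predict(object$fit,
                         newdata = X)$predict[, 1, object$ncomp])
    })
}

#' @method glance zeax_baseline
#' @export
glance.zeax_baseline <- function(x, ...) {
  tibble::tibble(tag = x$tag,
                 hyperparameters = list(x$hyper))
}

#' One end-to-end modelling experiment on a split dataset
#'
#' Convenience driver used by the interpretability suite and the worked
#' examples: wavelet-preprocesses the spectra, optionally restricts to a
#' band subset, assembles the chemical input implied by the model tag
#' (measured capsanthin + total carotenoids for MCSF; composite red index
#' from the raw reflectance + total carotenoids for MCSF-FR), trains on the
#' calibration samples and evaluates on the test samples.
#'
#' @param dataset A `pepper_dataset` (or list with `spectra` and
#'   `chemistry` tibbles).
#' @param split Split assignment from [stratified_split()].
#' @param tag Model tag as in [build_model()].
#' @param bands Optional numeric vector of wavelengths (nm) to restrict to.
#' @param config [train_config()].
#' @param preprocess Apply [cwt_preprocess()] to the spectra (default TRUE).
#' @param chem_override Optional two-column chemical input replacing the
#'   tag-implied one (used by ablation and sensitivity analyses).
#' @return List with `fit` (the trained model), `metrics` (one-row tibble:
#'   `r2`, `rmse` on the test set), and `predictions` (tibble with
#'   `sample_id`, `observed`, `predicted`).
#' @export
fusion_experiment <- function(dataset, split, tag = "mcsf", bands = NULL,
                              config = train_config(), preprocess = TRUE,
                              chem_override = NULL) {
  spectra <- dataset$spectra
  chem <- dataset$chemistry
  y <- chem$zeaxanthin_g_per_kg
  proc <- if (preprocess) cwt_preprocess(spectra) else spectra
  if (!is.null(bands)) {
    keep <- c("sample_id", as.character(bands))
    miss <- setdiff(keep, names(proc))
    if (length(miss)) abort(paste("bands not in spectra:", miss[1]))
    proc <- proc[keep]
  }
  feats <- if (!is.null(chem_override)) {
    as.matrix(chem_override)
  } else {
    switch(tag,
      spectral = NULL,
      mcsf = ,
      chemical = as.matrix(chem[c("capsanthin_g_per_kg",
                                  "total_carotenoids_g_per_kg")]),
      mcsf_fr = cbind(cri = spectral_cri(spectra)$cri,
                      total = chem$total_carotenoids_g_per_kg))
  }
  cal <- split$split == "calibration"
  tst <- split$split == "test"
  n_bands <- ncol(proc) - 1L
  model <- build_model(tag, n_bands = max(n_bands, 4L))
  fit <- train_model(model,
                     spectra = proc[cal, , drop = FALSE],
                     y = y[cal],
                     chemistry = if (is.null(feats)) NULL else
                       feats[cal, , drop = FALSE],
                     config = config)
  pred <- predict(fit,
                  spectra = proc[tst, , drop = FALSE],
                  chemistry = if (is.null(feats)) NULL else
                    feats[tst, , drop = FALSE])
  met <- regression_metrics(y[tst], pred)
  list(fit = fit,
       metrics = met,
       predictions = tibble::tibble(sample_id = spectra$sample_id[tst],
                                    observed = y[tst], predicted = pred))
}
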