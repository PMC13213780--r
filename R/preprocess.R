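#' Read and write spectra tables
#'
#' Spectra CSVs have a `sample_id` column followed by one numeric column per
#' band, named by its wavelength in integer nm and sorted ascending.
#' `read_spectra()` validates the schema; `write_spectra()` preserves column
#' order so that a round trip reproduces the table exactly.
#'
#' @param path File path.
#' @param spectra A spectra tibble as returned by [read_spectra()] or
#'   [simulate_peppers()].
#' @return `read_spectra()` returns a tibble; `write_spectra()` returns
#'   `spectra` invisibly.
#' @export
read_spectra <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(tab)) abort("missing sample_id column")
  if (anyDuplicated(tab$sample_id)) abort("duplicated sample id")
  wl <- suppressWarnings(as.numeric(setdiff(names(tab), "sample_id")))
  if (anyNA(wl)) abort("non-wavelength column in spectra file")
  if (is.unsorted(wl, strictly = TRUE)) abort("wavelengths not increasing")
  vals <- tab[setdiff(names(tab), "sample_id")]
  if (!all(vapply(vals, is.numeric, logical(1))) || anyNA(vals)) {
    abort("non-numeric or missing reflectance value")
  }
  tab$sample_id <- as.character(tab$sample_id)
  dplyr::relocate(tab, "sample_id")
}

#' @rdname read_spectra
#' @export
write_spectra <- function(spectra, path) {
  spectra_matrix(spectra)  # validates
  readr::write_csv(spectra, path)
  invisible(spectra)
}

#' Read and write chemistry tables
#'
#' Chemistry CSVs carry per-sample pigment contents in g/kg dry exocarp:
#' `sample_id,zeaxanthin_g_per_kg,capsanthin_g_per_kg,total_carotenoids_g_per_kg`
#' (an optional `cluster` column is passed through).
#'
#' @param path File path.
#' @param chemistry A chemistry tibble.
#' @return `read_chemistry()` returns a tibble; `write_chemistry()` returns
#'   `chemistry` invisibly.
#' @export
read_chemistry <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "zeaxanthin_g_per_kg", "capsanthin_g_per_kg",
            "total_carotenoids_g_per_kg")
  miss <- setdiff(need, names(tab))
  if (length(miss)) abort(paste("missing chemistry column:", miss[1]))
  if (any(tab$zeaxanthin_g_per_kg < 0) || any(tab$capsanthin_g_per_kg < 0)) {
    abort("pigment contents must be >= 0")
  }
  tab$sample_id <- as.character(tab$sample_id)
  tab
}

#' @rdname read_chemistry
#' @export
write_chemistry <- function(chemistry, path) {
  readr::write_csv(chemistry, path)
  invisible(chemistry)
}

# Discrete ricker (Mexican-hat) kernel at scale `a` (in band units),
# recentred to exact zero mean so constant signals map to 0.
ricker_kernel <- function(scale) {
  h <- ceiling(5 * scale)
  t <- (-h):h
  k <- (1 - (t / scale)^2) * exp(-t^2 / (2 * scale^2))
  k <- k * 2 / (sqrt(3 * scale) * pi^0.25)
  k - mean(k)
}

#' Continuous wavelet preprocessing of spectra
#'
#' Computes single-scale continuous-wavelet coefficients of each spectrum
#' with a Mexican-hat (ricker) kernel and symmetric boundary extension.
#' The zero-mean kernel removes additive baseline offsets while enhancing
#' curvature features of pigment absorption bands.
#'
#' @param spectra Spectra tibble (>= 5 bands).
#' @param scale Wavelet scale in band units (> 0), default 3.
#' @param wavelet Kernel family; only `"ricker"` is implemented.
#' @return A tibble of the same shape holding wavelet coefficients.
#' @export
#' @examples
#' d <- simulate_peppers(seed = 1)
#' cwt_preprocess(d$spectra)
cwt_preprocess <- function(spectra, scale = 3, wavelet = "ricker") {
  if (scale <= 0) abort("scale must be > 0")
  wavelet <- match.arg(wavelet)
  m <- spectra_matrix(spectra)
  p <- ncol(m)
  if (p < 5) abort("need at least 5 bands")
  k <- ricker_kernel(scale)
  h <- (length(k) - 1L) %/% 2L
  # half-sample symmetric extension: ... x2 x1 | x1 .. xp | xp xp-1 ...
  pos <- (1 - h):(p + h)
  q <- (pos - 1L) %% (2L * p)
  idx <- ifelse(q < p, q + 1L, 2L * p - q)
  ext <- m[, idx, drop = FALSE]
  out <- matrix(0, nrow(m), p)
  for (j in seq_len(p)) {
    out[, j] <- ext[, j:(j + 2 * h), drop = FALSE] %*% rev(k)
  }
  as_spectra_tibble(out, spectra$sample_id, attr(m, "wavelengths_nm"))
}

#' Min-max normalization with reusable statistics
#'
#' Maps each feature column to `(x - min) / (max - min)` using either the
#' data's own range or statistics previously captured (e.g. on a calibration
#' set, to avoid information leaking into held-out data).  Values outside the
#' stored range are not clipped.  Constant columns map to the neutral 0.5.
#'
#' @param x A numeric matrix or data frame (non-numeric columns such as
#'   `sample_id` are passed through untouched).
#' @param stats Optional statistics from a previous call (the
#'   `"minmax_stats"` attribute of its result).
#' @return Object of the same type, with attribute `"minmax_stats"` (a
#'   tibble with `column`, `min`, `max`).
#' @export
#' @examples
#' minmax_normalize(matrix(1:6, ncol = 2))
minmax_normalize <- function(x, stats = NULL) {
  is_df <- is.data.frame(x)
  if (is_df) {
    num <- vapply(x, is.numeric, logical(1))
    m <- as.matrix(x[num])
  } else {
    m <- as.matrix(x)
    num <- NULL
  }
  if (!all(is.finite(m))) abort("non-finite values in input")
  cols <- colnames(m) %||% as.character(seq_len(ncol(m)))
  if (is.null(stats)) {
    stats <- tibble::tibble(column = cols,
                            min = apply(m, 2, min),
                            max = apply(m, 2, max))
  } else {
    if (!all(cols %in% stats$column)) abort("stats do not cover all columns")
    stats <- stats[match(cols, stats$column), ]
  }
  rng <- stats$max - stats$min
  out <- sweep(m, 2, stats$min, "-")
  out <- sweep(out, 2, ifelse(rng == 0, 1, rng), "/")
  out[, rng == 0] <- 0.5
  if (is_df) {
    res <- x
    res[num] <- as.data.frame(out)
  } else {
    res <- out
  }
  attr(res, "minmax_stats") <- stats
  res
}

#' Stratified calibration/test split with LOOCV fold indices
#'
#' Bins the response into quantile strata and draws test samples
#' proportionally from each stratum (largest-remainder rounding), mirroring
#' the 8:2 stratified division of a 159-sample panel into 126 calibration
#' and 33 test samples.  Calibration samples additionally receive a
#' leave-one-out fold index.
#'
#' @param data A data frame containing the response (typically the chemistry
#'   table), or a bare numeric vector.
#' @param response Column holding the stratification response (tidy-eval);
#'   ignored when `data` is a vector.
#' @param n_test Number of test samples (default 33).
#' @param n_bins Number of quantile strata (>= 2, default 5).
#' @param seed Integer seed; the same seed reproduces the split.
#' @return Tibble with `sample_id` (or `index`), `split`
#'   (`"calibration"`/`"test"`), and `fold` (LOOCV index, NA for test).
#' @export
#' @examples
#' d <- simulate_peppers(seed = 1)
#' s <- stratified_split(d$chemistry, zeaxanthin_g_per_kg, seed = 1)
#' table(s$split)
stratified_split <- function(data, response, n_test = 33, n_bins = 5,
                             seed = 1) {
  if (is.data.frame(data)) {
    y <- dplyr::pull(data, {{ response }})
    ids <- if ("sample_id" %in% names(data)) data$sample_id else
      seq_along(y)
  } else {
    y <- data
    ids <- seq_along(y)
  }
  n <- length(y)
  if (n_bins < 2) abort("n_bins must be >= 2")
  if (n_test >= n) abort("n_test must be < n")
  if (n_test < n_bins) abort("n_test must be >= n_bins")
  set.seed(seed)
  qs <- quantile(y, probs = seq(0, 1, length.out = n_bins + 1))
  stratum <- cut(y, breaks = unique(qs), include.lowest = TRUE,
                 labels = FALSE)
  sizes <- tabulate(stratum)
  target <- n_test * sizes / n
  take <- floor(target)
  rem <- n_test - sum(take)
  if (rem > 0) {
    ord <- order(target - take, decreasing = TRUE)
    take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1L
  }
  test_idx <- unlist(lapply(seq_along(sizes), function(s) {
    pool <- which(stratum == s)
    if (take[s] == 0) return(integer(0))
    pool[sample.int(length(pool), take[s])]
  }))
  split <- rep("calibration", n)
  split[test_idx] <- "test"
  fold <- rep(NA_integer_, n)
  fold[split == "calibration"] <- seq_len(sum(split == "calibration"))
  tibble::tibble(sample_id = ids, split = split, fold = fold)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum of the absolute difference between the two empirical
#' CDFs; the p-value is the asymptotic two-sided approximation.  Used to
#' check that calibration and test sets are distributionally consistent.
#'
#' @param a,b Numeric vectors (length >= 2 each).
#' @return One-row tibble with `statistic` (D) and `p_value`.
#' @export
#' @examples
#' ks_two_sample(rnorm(50), rnorm(50))
ks_two_sample <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) abort("need at least 2 values per sample")
  kt <- suppressWarnings(ks.test(a, b, exact = FALSE))
  tibble::tibble(statistic = unname(kt$statistic),
                 p_value = unname(kt$p.value))
}

#' Composite red index (CRI)
#'
#' A reflectance-ratio proxy for capsanthin content in red-ripe peppers:
#' `CRI = 0.4 R/G + 0.3 R/B + 0.2 NRGI + 0.1 RPI`, with
#' `NRGI = (R - G)/(R + G)` and `RPI = R/(R + G + B)`.  All four terms are
#' ratios, so CRI is invariant to a common scaling of the three bands.
#'
#' @param R,G,B Red, green, blue band reflectances (> 0); vectorised.
#' @return Numeric CRI values.
#' @export
#' @examples
#' compute_cri(0.6, 0.3, 0.2)
compute_cri <- function(R, G, B) {
  if (any(G <= 0) || any(B <= 0)) abort("division by non-positive band")
  if (any(R <= 0)) abort("division by non-positive band")
  nrgi <- (R - G) / (R + G)
  rpi <- R / (R + G + B)
  0.4 * R / G + 0.3 * R / B + 0.2 * nrgi + 0.1 * rpi
}

#' Default RGB band ranges
#'
#' Conventional red/green/blue centre ranges within the instrument grid.
#' The mapping is configurable because multispectral layouts differ.
#'
#' @return Named list of `c(min_nm, max_nm)` ranges.
#' @export
rgb_band_map <- function() {
  list(R = c(630, 660), G = c(515, 570), B = c(430, 470))
}

#' Extract mean R, G, B reflectance per sample
#'
#' Averages reflectance over the bands falling in each nominal colour range.
#'
#' @param spectra Spectra tibble.
#' @param band_map Named list of ranges as in [rgb_band_map()]; single-band
#'   mappings (`c(x, x)`) are allowed.
#' @return Tibble with `sample_id`, `R`, `G`, `B`.
#' @export
#' @examples
#' d <- simulate_peppers(seed = 1)
#' extract_rgb(d$spectra)
extract_rgb <- function(spectra, band_map = rgb_band_map()) {
  m <- spectra_matrix(spectra)
  wl <- attr(m, "wavelengths_nm")
  band_mean <- function(rng, name) {
    sel <- wl >= rng[1] & wl <= rng[2]
    if (!any(sel)) abort(paste0("no bands in ", name, " range"))
    unname(rowMeans(m[, sel, drop = FALSE]))
  }
  tibble::tibble(sample_id = spectra$sample_id,
                 R = band_mean(band_map$R, "R"),
                 G = band_mean(band_map$G, "G"),
                 B = band_mean(band_map$B, "B"))
}

#' Per-sample CRI from a spectra table
#'
#' Convenience wrapper combining [extract_rgb()] and [compute_cri()].
#'
#' @inheritParams extract_rgb
#' @return Tibble with `sample_id` and `cri`.
#' @export
spectral_cri <- function(spectra, band_map = rgb_band_map()) {
  rgb <- extract_rgb(spectra, band_map)
  tibble::tibble(sample_id = rgb$sample_id,
                 cri = compute_cri(rgb$R, rgb$G, rgb$B))
}
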