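#' Default multispectral band grid
#'
#' Nineteen band centres (nm) spanning 365-970 nm, the conventional layout of
#' a LED-based multispectral imaging instrument.  The grid is an assumption of
#' the synthetic generator: real instruments differ slightly, and every
#' function that consumes spectra takes the wavelengths from the table's
#' column names rather than from this constant.
#'
#' @return Numeric vector of 19 wavelengths in nm, sorted ascending.
#' @export
#' @examples
#' default_wavelengths()
default_wavelengths <- function() {
  c(365, 405, 430, 450, 470, 490, 515, 540, 570, 590,
    630, 645, 660, 690, 780, 850, 880, 940, 970)
}

#' Gaussian absorber profiles for the pigment components
#'
#' Builds unit-peak Gaussian absorbance profiles for the four spectral
#' components that shape ripe-pepper exocarp reflectance: zeaxanthin
#' (centre 460 nm, sigma 35), capsanthin (centre 475 nm, sigma 40 --
#' deliberately overlapping zeaxanthin across 430-500 nm), chlorophyll
#' (centres 450 and 670 nm), and a generic-carotenoid dip at 520 nm.
#' The zeaxanthin/capsanthin overlap is the multicollinearity that the
#' fusion model is designed to decouple.
#'
#' @param wavelengths_nm Sorted ascending numeric vector of band centres (nm)
#'   within 365-970.
#' @return A tibble with one row per component x wavelength:
#'   `component`, `wavelength_nm`, `absorbance` (unit peak, >= 0).
#' @export
#' @examples
#' p <- spectral_profiles(default_wavelengths())
#' dplyr::count(p, component)
spectral_profiles <- function(wavelengths_nm = default_wavelengths()) {
  check_wavelengths(wavelengths_nm)
  if (min(wavelengths_nm) < 365 || max(wavelengths_nm) > 970) {
    abort("wavelengths must lie within 365-970 nm")
  }
  comp <- component_definitions()
  purrr::map_dfr(comp, function(cc) {
    a <- rowSums(vapply(seq_along(cc$center_nm), function(i) {
      exp(-(wavelengths_nm - cc$center_nm[i])^2 / (2 * cc$width_nm[i]^2))
    }, numeric(length(wavelengths_nm))))
    # two-lobe chlorophyll profile is re-normalised to unit peak
    a <- a / max(a)
    tibble::tibble(component = cc$name, wavelength_nm = wavelengths_nm,
                   absorbance = a)
  })
}

component_definitions <- function() {
  list(
    list(name = "zeaxanthin",  center_nm = 460,         width_nm = 35),
    list(name = "capsanthin",  center_nm = 475,         width_nm = 40),
    list(name = "chlorophyll", center_nm = c(450, 670), width_nm = c(25, 25)),
    list(name = "carotenoid_dip", center_nm = 520,      width_nm = 30)
  )
}

profile_matrix <- function(wavelengths_nm) {
  p <- spectral_profiles(wavelengths_nm)
  m <- tidyr::pivot_wider(p, names_from = "wavelength_nm",
                          values_from = "absorbance")
  out <- as.matrix(m[-1])
  rownames(out) <- m$component
  out
}

#' Configuration for the synthetic pepper population
#'
#' Collects the parameters of the generator.  Defaults reproduce the
#' statistical structure of a ripe chili-pepper panel: n = 159 samples,
#' zeaxanthin spanning 0.237-6.64 g/kg dry exocarp with a coefficient of
#' variation near 88%, a zeaxanthin-capsanthin correlation of 0.8, and a
#' two-cluster genetic background at a 3:1 ratio (the minority cluster
#' carries a 3x higher zeaxanthin location parameter).
#'
#' @param n_samples Number of samples (>= 4).
#' @param wavelengths_nm Band grid in nm.
#' @param zeax_meanlog Log-scale location of the low-cluster zeaxanthin
#'   lognormal (g/kg).  Default log(0.6), fixed by a calibration run so the
#'   post-truncation CV matches ~88%.
#' @param zeax_lognormal_sigma Log-scale SD of zeaxanthin (default 0.757,
#'   lognormal CV sqrt(exp(sigma^2)-1) ~ 0.879 pre-truncation).
#' @param zeax_range_g_per_kg Truncation range, default c(0.237, 6.64).
#' @param zeax_capsanthin_rho Target Pearson correlation between zeaxanthin
#'   and capsanthin, in [-1, 1] (default 0.8).
#' @param capsanthin_scale Multiplier applied to the correlated capsanthin
#'   draw (capsanthin dominates ripe red peppers); default 3.
#' @param cluster_ratio Two-element vector of cluster odds, default c(3, 1):
#'   the first (low-zeaxanthin) cluster has probability 3/4.
#' @param noise_sd Reflectance noise SD (default 0.01).
#' @param amplitudes Named absorbance-per-(g/kg) amplitudes of the four
#'   components.  Defaults keep typical spectra well inside [0, 1].
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples = 159,
                             wavelengths_nm = default_wavelengths(),
                             zeax_meanlog = log(0.6),
                             zeax_lognormal_sigma = 0.757,
                             zeax_range_g_per_kg = c(0.237, 6.64),
                             zeax_capsanthin_rho = 0.8,
                             capsanthin_scale = 3,
                             cluster_ratio = c(3, 1),
                             noise_sd = 0.01,
                             amplitudes = c(zeaxanthin = 0.014,
                                            capsanthin = 0.014,
                                            chlorophyll = 0.15,
                                            carotenoid_dip = 0.004)) {
  if (n_samples < 4) abort("n_samples must be >= 4")
  if (abs(zeax_capsanthin_rho) > 1) abort("|rho| must be <= 1")
  if (zeax_range_g_per_kg[1] >= zeax_range_g_per_kg[2]) {
    abort("zeax_range_g_per_kg must satisfy min < max")
  }
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  check_wavelengths(wavelengths_nm)
  structure(list(n_samples = n_samples, wavelengths_nm = wavelengths_nm,
                 zeax_meanlog = zeax_meanlog,
                 zeax_lognormal_sigma = zeax_lognormal_sigma,
                 zeax_range_g_per_kg = zeax_range_g_per_kg,
                 zeax_capsanthin_rho = zeax_capsanthin_rho,
                 capsanthin_scale = capsanthin_scale,
                 cluster_ratio = cluster_ratio, noise_sd = noise_sd,
                 amplitudes = amplitudes),
            class = "synthetic_config")
}

#' Draw a vector with a prescribed correlation to a reference vector
#'
#' Constructs `y = rho * standardize(x) + sqrt(1 - rho^2) * eps` with
#' `eps ~ N(0, 1)`, rescaled to the empirical mean and SD of `x` and floored
#' at a small positive value, so that the population correlation of `y` with
#' `x` equals `rho`.  Used to synthesise capsanthin values of controlled
#' informativeness for the sensitivity sweep.
#'
#' @param x Numeric vector, length >= 3, non-constant.
#' @param rho Target correlation in [-1, 1].
#' @param seed Optional integer seed for the Gaussian innovation.
#' @return Numeric vector the length of `x`, strictly positive.
#' @export
#' @examples
#' z <- rlnorm(200)
#' cor(z, correlated_proxy(z, 0.8, seed = 1))
correlated_proxy <- function(x, rho, seed = NULL) {
  if (length(x) < 3) abort("x must have length >= 3")
  if (abs(rho) > 1) abort("|rho| must be <= 1")
  if (sd(x) == 0) abort("zero variance: x is constant")
  if (!is.null(seed)) set.seed(seed)
  z <- (x - mean(x)) / sd(x)
  eps <- rnorm(length(x))
  y <- rho * z + sqrt(1 - rho^2) * eps
  y <- mean(x) + sd(x) * y
  pmax(y, 1e-6)
}

#' Generate a synthetic pepper population (spectra + chemistry)
#'
#' Simulates a panel of ripe chili-pepper exocarp samples.  Zeaxanthin is
#' drawn from a two-cluster truncated lognormal (clusters at a 3:1 ratio;
#' the minority cluster's location parameter is multiplied by 3), capsanthin
#' is constructed with the configured Pearson correlation to zeaxanthin via
#' [correlated_proxy()], and total carotenoids add a positive remainder.
#' Reflectance at each band is a smooth decreasing-then-flat baseline minus
#' the content-weighted Gaussian absorber profiles of [spectral_profiles()],
#' plus Gaussian noise, clipped to [0, 1].
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return A `pepper_dataset`: list with tibbles `spectra` (sample_id + one
#'   column per band) and `chemistry` (sample_id, zeaxanthin_g_per_kg,
#'   capsanthin_g_per_kg, total_carotenoids_g_per_kg, cluster).
#' @export
#' @examples
#' d <- simulate_peppers(seed = 1)
#' d$chemistry
simulate_peppers <- function(config = synthetic_config(), seed = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  n <- config$n_samples
  wl <- config$wavelengths_nm
  p_high <- config$cluster_ratio[2] / sum(config$cluster_ratio)
  cluster <- rbinom(n, 1, p_high)             # 1 = high-zeaxanthin cluster
  meanlog <- config$zeax_meanlog + cluster * log(3)
  lo <- config$zeax_range_g_per_kg[1]
  hi <- config$zeax_range_g_per_kg[2]
  zeax <- vapply(meanlog, function(ml) {
    repeat {
      v <- rlnorm(1, ml, config$zeax_lognormal_sigma)
      if (v >= lo && v <= hi) return(v)
    }
  }, numeric(1))
  caps <- config$capsanthin_scale *
    correlated_proxy(zeax, config$zeax_capsanthin_rho)
  remainder <- rlnorm(n, log(2), 0.7)          # minor carotenoids, g/kg
  total <- zeax + caps + remainder
  # residual chlorophyll varies strongly across genotypes and dominates the
  # 450/670 nm reflectance variation, as in ripe-pepper panels
  chl <- rlnorm(n, log(0.15), 0.8)

  prof <- profile_matrix(wl)
  contents <- cbind(zeaxanthin = zeax, capsanthin = caps,
                    chlorophyll = chl, carotenoid_dip = total)
  amp <- config$amplitudes[rownames(prof)]
  absorb <- (contents %*% (prof * amp))        # n x p
  base <- baseline_curve(wl)
  refl <- sweep(-absorb, 2, base, "+") +
    matrix(rnorm(n * length(wl), 0, config$noise_sd), n)
  refl <- pmin(pmax(refl, 0), 1)
  if (all(refl == 0)) abort("saturated spectra: amplitudes drive reflectance to 0")

  ids <- sprintf("S%03d", seq_len(n))
  structure(list(
    spectra = as_spectra_tibble(refl, ids, wl),
    chemistry = tibble::tibble(
      sample_id = ids,
      zeaxanthin_g_per_kg = zeax,
      capsanthin_g_per_kg = caps,
      total_carotenoids_g_per_kg = total,
      cluster = ifelse(cluster == 1, "high", "low"))),
    class = "pepper_dataset")
}

# Smooth decreasing-then-flat baseline: visible absorption rising to a flat
# near-infrared plateau (logistic ramp 0.15 at 365 nm -> 0.75 above ~780 nm).
baseline_curve <- function(wavelengths_nm) {
  0.15 + 0.60 / (1 + exp(-(wavelengths_nm - 500) / 60))
}

#' @export
print.pepper_dataset <- function(x, ...) {
  n <- nrow(x$spectra)
  p <- ncol(x$spectra) - 1L
  cat(sprintf("<pepper_dataset> %d samples x %d bands\n", n, p))
  cat(sprintf("  zeaxanthin %.3f-%.3f g/kg (CV %.1f%%), clusters %s\n",
              min(x$chemistry$zeaxanthin_g_per_kg),
              max(x$chemistry$zeaxanthin_g_per_kg),
              100 * sd(x$chemistry$zeaxanthin_g_per_kg) /
                mean(x$chemistry$zeaxanthin_g_per_kg),
              paste(table(x$chemistry$cluster), collapse = "/")))
  invisible(x)
}
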