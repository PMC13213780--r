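#' Plot spectra coloured by a response
#'
#' @param spectra Spectra tibble.
#' @param colour_by Optional numeric vector (one value per sample), e.g.
#'   zeaxanthin content.
#' @return A ggplot object.
#' @export
plot_spectra <- function(spectra, colour_by = NULL) {
  long <- tidyr::pivot_longer(spectra, -"sample_id",
                              names_to = "wavelength_nm",
                              values_to = "reflectance") |>
    dplyr::mutate(wavelength_nm = as.numeric(.data$wavelength_nm))
  if (!is.null(colour_by)) {
    key <- tibble::tibble(sample_id = spectra$sample_id, value = colour_by)
    long <- dplyr::left_join(long, key, by = "sample_id")
    ggplot2::ggplot(long, ggplot2::aes(.data$wavelength_nm,
                                       .data$reflectance,
                                       group = .data$sample_id,
                                       colour = .data$value)) +
      ggplot2::geom_line(alpha = 0.5) +
      ggplot2::scale_colour_viridis_c(name = "zeaxanthin\n(g/kg)") +
      ggplot2::labs(x = "wavelength (nm)", y = "reflectance") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(long, ggplot2::aes(.data$wavelength_nm,
                                       .data$reflectance,
                                       group = .data$sample_id)) +
      ggplot2::geom_line(alpha = 0.4) +
      ggplot2::labs(x = "wavelength (nm)", y = "reflectance") +
      ggplot2::theme_minimal()
  }
}

#' 1:1 measured-versus-predicted plot
#'
#' @param predictions Tibble with `observed` and `predicted` columns (e.g.
#'   from [fusion_experiment()]).
#' @return A ggplot object with the y = x reference line.
#' @export
plot_one_to_one <- function(predictions) {
  ggplot2::ggplot(predictions, ggplot2::aes(.data$observed,
                                            .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "measured zeaxanthin (g/kg)",
                  y = "predicted zeaxanthin (g/kg)") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @method autoplot saliency_map
#' @export
autoplot.saliency_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$wavelength_nm, .data$weight)) +
    ggplot2::geom_col(width = 8, fill = "firebrick", alpha = 0.8) +
    ggplot2::labs(x = "wavelength (nm)", y = "Grad-CAM weight") +
    ggplot2::theme_minimal()
}

#' @method autoplot sensitivity_curve
#' @export
autoplot.sensitivity_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$rho, .data$r2)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "capsanthin-zeaxanthin correlation",
                  y = expression(test ~ R^2)) +
    ggplot2::theme_minimal()
}

#' @method autoplot ablation_result
#' @export
autoplot.ablation_result <- function(object, ...) {
  lev <- c("M-Spectral", "M-Chemical", "M-S+R", "M-S+N", "M-MCSF")
  dat <- dplyr::mutate(object,
                       configuration = factor(.data$configuration,
                                              levels = lev))
  ggplot2::ggplot(dat, ggplot2::aes(.data$configuration, .data$r2)) +
    ggplot2::geom_col(fill = "steelblue", alpha = 0.85) +
    ggplot2::labs(x = NULL, y = expression(test ~ R^2)) +
    ggplot2::theme_minimal()
}

#' @method autoplot band_selection
#' @export
autoplot.band_selection <- function(object, ...) {
  load <- object$pca$loadings
  dat <- tibble::tibble(
    wavelength_nm = as.numeric(rownames(load)),
    loading = load[, 1],
    selected = as.numeric(rownames(load)) %in%
      object$selected_wavelengths_nm)
  ggplot2::ggplot(dat, ggplot2::aes(.data$wavelength_nm, .data$loading,
                                    colour = .data$selected)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(colour = "grey70", linetype = 3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "wavelength (nm)", y = "PC1 loading",
                  colour = "selected") +
    ggplot2::theme_minimal()
}
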