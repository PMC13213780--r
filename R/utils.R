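# Internal helpers shared across modules.

# Extract the numeric reflectance matrix (samples x bands) from a spectra
# tibble whose non-id columns are named by wavelength in nm.
spectra_matrix <- function(spectra) {
  stopifnot(is.data.frame(spectra))
  if (!"sample_id" %in% names(spectra)) {
    abort("missing sample_id column in spectra table")
  }
  wl_cols <- setdiff(names(spectra), "sample_id")
  wl <- suppressWarnings(as.numeric(wl_cols))
  if (anyNA(wl)) {
    abort("spectra columns other than sample_id must be numeric wavelengths (nm)")
  }
  m <- as.matrix(spectra[wl_cols])
  storage.mode(m) <- "double"
  if (anyNA(m)) abort("spectra contain missing or non-numeric values")
  rownames(m) <- spectra$sample_id
  attr(m, "wavelengths_nm") <- wl
  m
}

as_spectra_tibble <- function(m, sample_ids, wavelengths_nm) {
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  names(out) <- as.character(wavelengths_nm)
  dplyr::bind_cols(tibble::tibble(sample_id = sample_ids), out)
}

check_wavelengths <- function(wl) {
  if (length(wl) == 0) abort("empty wavelength list")
  if (is.unsorted(wl, strictly = TRUE)) abort("wavelengths not increasing")
  invisible(wl)
}

# Sub-seeds derived from a master seed, kept within 32-bit integer range.
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max %/% 2L, n)
}

relu <- function(x) pmax(x, 0)
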