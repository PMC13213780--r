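test_that("spectra CSVs round-trip exactly and bad schemas are rejected", {
  d <- default_dataset(seed = 2, n_samples = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(d$spectra, path)
  back <- read_spectra(path)
  expect_equal(as.matrix(back[-1]), as.matrix(d$spectra[-1]),
               tolerance = 1e-12)
  expect_identical(names(back), names(d$spectra))

  bad1 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(id = "a", `450` = 0.5), bad1)
  expect_error(read_spectra(bad1), "missing sample_id")

  bad2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(sample_id = "a", `500` = 0.1, `400` = 0.2),
                   bad2)
  expect_error(read_spectra(bad2), "not increasing")

  bad3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(sample_id = c("a", "a"),
                                  `400` = c(0.1, 0.2), `500` = c(0.1, 0.2)),
                   bad3)
  expect_error(read_spectra(bad3), "duplicated")
})

test_that("chemistry CSVs round-trip and validate", {
  d <- default_dataset(seed = 2, n_samples = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_chemistry(d$chemistry, path)
  back <- read_chemistry(path)
  expect_equal(back$zeaxanthin_g_per_kg, d$chemistry$zeaxanthin_g_per_kg,
               tolerance = 1e-12)
  bad <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(sample_id = "a"), bad)
  expect_error(read_chemistry(bad), "missing chemistry column")
})

test_that("wavelet coefficients kill constants and offsets", {
  wl <- default_wavelengths()
  flat <- as_tbl <- zeaxspec:::as_spectra_tibble(
    matrix(0.42, 2, length(wl)), c("a", "b"), wl)
  cw <- cwt_preprocess(flat)
  expect_true(all(abs(as.matrix(cw[-1])) < 1e-8))

  set.seed(1)
  x <- runif(length(wl))
  sp1 <- zeaxspec:::as_spectra_tibble(rbind(x), "a", wl)
  sp2 <- zeaxspec:::as_spectra_tibble(rbind(x + 0.3), "a", wl)
  expect_equal(as.matrix(cwt_preprocess(sp1)[-1]),
               as.matrix(cwt_preprocess(sp2)[-1]), tolerance = 1e-10)
  expect_error(cwt_preprocess(sp1, scale = 0), "scale")
})

test_that("wavelet response to a spike matches direct convolution", {
  wl <- default_wavelengths()
  p <- length(wl)
  x <- rep(0, p)
  x[10] <- 1
  sp <- zeaxspec:::as_spectra_tibble(rbind(x), "a", wl)
  got <- as.numeric(as.matrix(cwt_preprocess(sp, scale = 3)[-1]))

  # independent oracle: explicit loop over the reflected signal
  k <- zeaxspec:::ricker_kernel(3)
  h <- (length(k) - 1) / 2
  reflect <- function(pos) {
    q <- (pos - 1) %% (2 * p)
    if (q < p) q + 1 else 2 * p - q
  }
  expected <- vapply(seq_len(p), function(j) {
    sum(vapply(-h:h, function(t) x[reflect(j + t)] * k[t + h + 1],
               numeric(1)))
  }, numeric(1))
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("wavelet transform is translation-equivariant away from edges", {
  wl <- seq(400, 900, length.out = 25)
  set.seed(4)
  x <- rnorm(25)
  shifted <- c(x[-1], x[1])
  c1 <- as.numeric(as.matrix(cwt_preprocess(
    zeaxspec:::as_spectra_tibble(rbind(x), "a", wl), scale = 2)[-1]))
  c2 <- as.numeric(as.matrix(cwt_preprocess(
    zeaxspec:::as_spectra_tibble(rbind(shifted), "a", wl), scale = 2)[-1]))
  mid <- 12:14  # well inside both boundaries for scale-2 kernel
  expect_equal(c2[mid - 1], c1[mid], tolerance = 1e-10)
})

test_that("min-max normalization maps, stores and reuses statistics", {
  expect_equal(as.numeric(minmax_normalize(matrix(c(1, 2, 3)))),
               c(0, 0.5, 1))
  const <- minmax_normalize(matrix(rep(2, 4)))
  expect_true(all(const == 0.5))
  train <- matrix(c(0, 1, 2, 5), 4)
  st <- attr(minmax_normalize(train), "minmax_stats")
  out <- minmax_normalize(matrix(7), stats = st)
  expect_gt(as.numeric(out), 1)  # no clipping beyond the training range
})

test_that("stratified split reproduces the 126/33 division deterministically", {
  d <- default_dataset(seed = 3)
  s1 <- stratified_split(d$chemistry, zeaxanthin_g_per_kg, seed = 7)
  s2 <- stratified_split(d$chemistry, zeaxanthin_g_per_kg, seed = 7)
  expect_identical(s1, s2)
  expect_equal(sum(s1$split == "calibration"), 126)
  expect_equal(sum(s1$split == "test"), 33)
  expect_equal(sort(unique(s1$fold[s1$split == "calibration"])), 1:126)
  expect_true(all(is.na(s1$fold[s1$split == "test"])))
  expect_error(stratified_split(d$chemistry, zeaxanthin_g_per_kg,
                                n_test = 3, n_bins = 5), "n_test")
})

test_that("per-stratum test fractions are proportional", {
  set.seed(2)
  y <- runif(1000)
  s <- stratified_split(y, n_test = 200, n_bins = 5, seed = 1)
  qs <- quantile(y, seq(0, 1, 0.2))
  stratum <- cut(y, qs, include.lowest = TRUE, labels = FALSE)
  for (k in 1:5) {
    frac <- mean(s$split[stratum == k] == "test")
    expect_lt(abs(frac - 0.2), 0.02)
  }
})

test_that("KS statistic equals the brute-force ECDF scan", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(ks_two_sample(c(0, 1), c(10, 11))$statistic, 1)
  expect_equal(ks_two_sample(c(1, 2), c(1.5, 2.5))$statistic, 0.5)
  set.seed(6)
  for (i in 1:20) {
    n1 <- sample(2:50, 1)
    n2 <- sample(2:50, 1)
    a <- rnorm(n1)
    b <- rnorm(n2, sd = runif(1, 0.5, 2))
    expect_equal(ks_two_sample(a, b)$statistic, brute_ks_d(a, b),
                 tolerance = 1e-12)
  }
  expect_error(ks_two_sample(1, c(1, 2)), "at least 2")
})

test_that("stratified splitting keeps calibration and test KS-consistent", {
  pass <- vapply(1:50, function(s) {
    d <- default_dataset(seed = s)
    sp <- stratified_split(d$chemistry, zeaxanthin_g_per_kg, seed = s)
    z <- d$chemistry$zeaxanthin_g_per_kg
    ks_two_sample(z[sp$split == "calibration"],
                  z[sp$split == "test"])$p_value > 0.05
  }, logical(1))
  expect_gte(mean(pass), 0.9)
})

test_that("CRI matches hand arithmetic and is scale-invariant", {
  expect_equal(compute_cri(0.5, 0.5, 0.5), 0.4 + 0.3 + 0 + 0.1 / 3,
               tolerance = 1e-9)
  expect_equal(compute_cri(0.6, 0.3, 0.2),
               0.8 + 0.9 + 0.2 * (0.3 / 0.9) + 0.1 * (0.6 / 1.1),
               tolerance = 1e-9)
  for (k in c(0.1, 2, 17)) {
    expect_equal(compute_cri(0.6 * k, 0.3 * k, 0.2 * k),
                 compute_cri(0.6, 0.3, 0.2), tolerance = 1e-12)
  }
  # strictly increasing in R with G, B fixed
  rs <- seq(0.1, 0.9, 0.1)
  vals <- compute_cri(rs, 0.3, 0.2)
  expect_true(all(diff(vals) > 0))
  expect_error(compute_cri(0.5, 0, 0.2), "non-positive")
})

test_that("RGB extraction averages the configured ranges", {
  wl <- default_wavelengths()
  m <- matrix(seq(0.1, by = 0.01, length.out = length(wl)), 1)
  sp <- zeaxspec:::as_spectra_tibble(m, "a", wl)
  rgb <- extract_rgb(sp)
  expect_equal(rgb$R, mean(m[wl %in% c(630, 645, 660)]))
  expect_equal(rgb$G, mean(m[wl %in% c(515, 540, 570)]))
  expect_equal(rgb$B, mean(m[wl %in% c(430, 450, 470)]))
  # single-band mapping returns those columns
  one <- extract_rgb(sp, band_map = list(R = c(645, 645), G = c(540, 540),
                                         B = c(450, 450)))
  expect_equal(one$R, m[wl == 645])
  # flat spectrum: R = G = B
  flat <- zeaxspec:::as_spectra_tibble(matrix(0.3, 1, length(wl)), "a", wl)
  frgb <- extract_rgb(flat)
  expect_equal(frgb$R, frgb$G)
  expect_equal(frgb$G, frgb$B)
  expect_error(extract_rgb(sp, band_map = list(R = c(1000, 1100),
                                               G = c(515, 570),
                                               B = c(430, 470))), "no bands")
})
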