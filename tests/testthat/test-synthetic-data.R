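# synthetic FIDs, MT series, functional studies, saturation profile

test_that("a noiseless Lorentzian integrates to its generating amplitude", {
  acq <- acq_params()
  fid <- synthesize_fid(spectral_component("PCr", 0, 1.22, 7), acq)
  spec <- fid_to_spectrum(fid)
  expect_equal(spectrum_area(spec), 1.22, tolerance = 1e-10)
  # apodization does not change the integral
  expect_equal(spectrum_area(fid_to_spectrum(apodize(fid, 15))), 1.22,
               tolerance = 1e-10)
})

test_that("J-coupled doublet gives two resolved equal lines 16 Hz apart", {
  acq <- acq_params()
  fid <- synthesize_fid(
    spectral_component("gATP", -2.5, 1, 4, n_lines = 2L, J_Hz = 16), acq)
  spec <- fid_to_spectrum(fid)
  re <- Re(spec$intensity)
  win <- which(spec$ppm > -3.5 & spec$ppm < -1.5)
  pk <- win[which(diff(sign(diff(re[win]))) == -2) + 1]  # local maxima
  pk <- pk[order(re[pk], decreasing = TRUE)][1:2]
  expect_equal(abs(diff(spec$freq_Hz[pk])), 16,
               tolerance = 2 * acq$spectral_bandwidth_Hz / acq$n_samples)
  expect_equal(re[pk[1]] / re[pk[2]], 1, tolerance = 0.02)
})

test_that("FID synthesis is reproducible for a fixed seed and scales noise by 1/sqrt(NA)", {
  acq <- acq_params()
  cmp <- default_components()
  f1 <- synthesize_fid(cmp, acq, noise_sd = 0.02, seed = 42)
  f2 <- synthesize_fid(cmp, acq, noise_sd = 0.02, seed = 42)
  expect_identical(f1$signal, f2$signal)
  f3 <- synthesize_fid(cmp, acq, noise_sd = 0.02, seed = 43)
  expect_false(identical(f1$signal, f3$signal))
  # empirical noise sd in the FID tail (signal fully decayed) vs averages
  tail_idx <- 3500:4096
  sd24 <- sd(Re(f1$signal[tail_idx]))
  acq96 <- acq_params(n_averages = 96)
  f96 <- synthesize_fid(cmp, acq96, noise_sd = 0.02, seed = 42)
  sd96 <- sd(Re(f96$signal[tail_idx]))
  expect_equal(sd24 / sd96, 2, tolerance = 0.15)
  expect_equal(sd24, 0.02 / sqrt(24), tolerance = 0.15)
})

test_that("components outside the spectral window raise an aliasing error", {
  expect_error(
    synthesize_fid(spectral_component("far", 40, 1, 7), acq_params()),
    "aliasing")
})

test_that("FID and spectrum text formats round-trip bit-exactly", {
  acq <- acq_params(n_samples = 256)
  fid <- synthesize_fid(default_components(), acq, noise_sd = 0.02, seed = 5)
  p <- withr::local_tempfile()
  write_fid(fid, p, scheme = saturation_scheme(n_pulses = 3, t_sat_s = 0.565))
  fid2 <- read_fid(p)
  expect_identical(fid2$signal, fid$signal)
  expect_identical(fid2$time_s, fid$time_s)
  expect_equal(unclass(fid2$acq), unclass(fid$acq))
  spec <- fid_to_spectrum(fid)
  p2 <- withr::local_tempfile()
  write_spectrum(spec, p2)
  spec2 <- read_spectrum(p2)
  expect_identical(spec2$intensity, spec$intensity)
  # and the spectrum inverts back to the time domain
  back <- spectrum_to_fid(spec)
  expect_equal(back$signal, fid$signal, tolerance = 1e-12)
})

test_that("MT series generator closes with the progressive estimator", {
  net <- mc_network()
  ser <- generate_mt_series(net, noise_sd = 0)
  expect_s3_class(ser, "mt_series")
  fit <- fit_progressive(ser, "PCr")
  expect_equal(unname(coef(fit)), c(0.3, 5), tolerance = 1e-6)
  fit2 <- fit_progressive(ser, "Pi")
  expect_equal(unname(coef(fit2)), c(0.2, 3), tolerance = 1e-6)
  # residual gamma-ATP under saturation within the QC bound
  sat <- ser$saturated
  expect_true(all(ser$area_gATP[sat] <= 0.07 * ser$area_gATP[!sat]))
  # Pi decays more slowly and to a lesser extent than PCr
  frac_PCr <- ser$area_PCr / ser$area_PCr[1]
  frac_Pi <- ser$area_Pi / ser$area_Pi[1]
  expect_true(all(frac_Pi[-1] > frac_PCr[-1]))
  expect_gt(min(frac_Pi), 1 / (1 + 0.3 * 5))
})

test_that("MT series generation demands the reference scan and is seeded", {
  net <- mc_network()
  no_ref <- list(saturation_scheme(offset_ppm = -2.5, t_sat_s = 1,
                                   n_pulses = 6L))
  expect_error(generate_mt_series(net, schemes = no_ref), "reference")
  s1 <- generate_mt_series(net, noise_sd = 0.02, seed = 9)
  s2 <- generate_mt_series(net, noise_sd = 0.02, seed = 9)
  expect_identical(s1, s2)
})

test_that("MT series table IO round-trips through both delimiters", {
  net <- mc_network()
  ser <- generate_mt_series(net, noise_sd = 0.01, seed = 2)
  for (sep in c("\t", ",")) {
    p <- withr::local_tempfile()
    write_mt_series(ser, p, sep = sep)
    back <- read_mt_series(p)
    expect_equal(back$area_PCr, ser$area_PCr, tolerance = 1e-12)
    expect_equal(back$t_sat_s, ser$t_sat_s)
  }
})

test_that("spectra mode suppresses the baseline equally under either irradiation", {
  net <- mc_network()
  ser <- generate_mt_series(net, noise_sd = 0, spectra = TRUE)
  fids <- attr(ser, "fids")
  # at +12 ppm only the broad baseline contributes appreciably
  probe <- function(fid) {
    spec <- fid_to_spectrum(fid)
    mean(Re(spec$intensity[spec$ppm > 11 & spec$ppm < 13]))
  }
  ref <- probe(fids[[1]])            # +15 ppm irradiation
  sat <- probe(fids[[4]])            # -2.5 ppm gamma-ATP saturation
  expect_equal(sat / ref, 1, tolerance = 0.05)
})

test_that("functional study closes exactly at zero noise and fixed truth", {
  truth <- functional_truth(k1_block_sd = 0, k2_block_sd = 0,
                            k1_sd = 0, k2_sd = 0,
                            ratio_PCr_sd = 0, ratio_Pi_sd = 0,
                            ratio_NAD_sd = 0)
  st <- generate_functional_study(n_subjects = 3, truth = truth,
                                  noise_sd = 0, seed = 1)
  rep <- run_functional_study(st, T1_PCr = 5.1, T1_Pi = 3.0)
  k1stats <- rep$stats$k1
  expect_equal(k1stats$mean_pct_change[k1stats$contrast == "ON1_vs_OFF1"], 24,
               tolerance = 1e-9)
  expect_equal(k1stats$mean_pct_change[k1stats$contrast == "ON2_vs_OFF2"], 11,
               tolerance = 1e-9)
  expect_equal(unique(round(rep$blocks$k1[rep$blocks$label == "OFF1"], 10)),
               0.35)
  expect_equal(rep$blocks$pH, rep(7, 12), tolerance = 1e-9)
})

test_that("functional generator enforces the 4-block paradigm and determinism", {
  bad <- list(list(mc_network(), mc_network(), mc_network()))
  expect_error(generate_functional_study(networks = bad), "paradigm")
  s1 <- generate_functional_study(n_subjects = 2, seed = 3)
  s2 <- generate_functional_study(n_subjects = 2, seed = 3)
  expect_identical(s1, s2)
})

test_that("saturation pulse train: complete on-resonance saturation, no bleed-over", {
  sch <- saturation_scheme(offset_ppm = -2.5, n_pulses = 18L, t_sat_s = 3)
  prof <- simulate_saturation_profile(sch, offsets_Hz = seq(-200, 200, 1))
  i0 <- which(prof$offsets_Hz == 0)
  expect_gt(prof$saturation[i0], 0.85)   # near-complete after ~3 s
  # at +/- 2.5 ppm (129 Hz at 51.7 MHz) residual saturation < 5%
  i129 <- which(abs(abs(prof$offsets_Hz) - 129) < 0.5)
  expect_true(all(prof$saturation[i129] < 0.05))
  # calibrated band: FWHM close to the 31 Hz design value
  expect_gt(prof$fwhm_Hz, 25)
  expect_lt(prof$fwhm_Hz, 40)
  expect_gt(prof$fw05_Hz, prof$fwhm_Hz)
  expect_error(simulate_saturation_profile(sch, offsets_Hz = seq(-10, 10, 1)),
               "span")
})

test_that("longer trains saturate more deeply", {
  off <- seq(-100, 100, 2)
  m <- sapply(c(3L, 18L, 50L), function(np)
    simulate_saturation_profile(saturation_scheme(n_pulses = np),
                                offsets_Hz = off)$Mz[off == 0])
  expect_true(all(diff(abs(m)) < 0))
})
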