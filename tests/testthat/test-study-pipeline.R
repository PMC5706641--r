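# end-to-end orchestration: progressive study, functional study, statistics

test_that("progressive study recovers truth exactly from a noiseless cohort", {
  net <- resting_network()
  sims <- lapply(1:6, function(i) generate_mt_series(net, noise_sd = 0))
  rep <- run_progressive_study(sims)
  expect_equal(rep$group$PCr$k, 0.37, tolerance = 1e-6)
  expect_equal(rep$group$PCr$T1int, 5.1, tolerance = 1e-5)
  expect_equal(rep$group$Pi$k, 0.19, tolerance = 1e-6)
  expect_equal(rep$group$Pi$T1int, 3.0, tolerance = 1e-5)
  expect_equal(rep$group$PCr$r_squared, 1, tolerance = 1e-9)
  # per-subject estimates identical to the group on identical data
  expect_equal(rep$per_subject$k[rep$per_subject$pool == "PCr"],
               rep(0.37, 6), tolerance = 1e-6)
})

test_that("single-subject mode equals group mode when n = 1", {
  net <- resting_network()
  ser <- generate_mt_series(net, noise_sd = 0.0183, seed = 4)
  rep <- run_progressive_study(list(ser))
  expect_equal(rep$group$PCr$k,
               rep$per_subject$k[rep$per_subject$pool == "PCr"])
  expect_equal(rep$n_subjects, 1)
})

test_that("progressive study rejects subjects on different saturation grids", {
  net <- resting_network()
  a <- generate_mt_series(net, noise_sd = 0)
  b <- a
  b$t_sat_s[3] <- 1.2
  expect_error(run_progressive_study(list(a, b)), "grid")
})

test_that("block statistics reproduce the two-subject worked example", {
  v <- rbind(OFF1 = c(0.30, 0.40), ON1 = c(0.36, 0.44),
             OFF2 = c(0.30, 0.40), ON2 = c(0.36, 0.44))
  gs <- block_statistics(v)
  r <- gs[gs$contrast == "ON1_vs_OFF1", ]
  expect_equal(r$mean_pct_change, 15)
  expect_equal(r$sd_pct_change, sqrt(50), tolerance = 1e-9)
  # paired t on differences {0.06, 0.04}: t = 0.05 / (sd/sqrt(2)) = 5
  expect_equal(r$t, 5, tolerance = 1e-9)
  expect_equal(r$p, 2 * stats::pt(-5, df = 1), tolerance = 1e-9)
  # identical columns give 0% change and p = 1
  null <- gs[gs$contrast == "OFF2_vs_OFF1", ]
  expect_equal(null$mean_pct_change, 0)
  expect_equal(null$p, 1)
})

test_that("reversing a contrast flips the sign of t but not its magnitude", {
  set.seed(8)
  v <- rbind(OFF1 = runif(5, 0.3, 0.4), ON1 = runif(5, 0.35, 0.45),
             OFF2 = runif(5, 0.3, 0.4), ON2 = runif(5, 0.35, 0.45))
  fwd <- block_statistics(v, list(c1 = list(a = "ON1", b = "OFF1")))
  rev <- block_statistics(v, list(c1 = list(a = "OFF1", b = "ON1")))
  expect_equal(abs(fwd$t), abs(rev$t))
  expect_equal(fwd$p, rev$p)
  expect_equal(sign(fwd$t), -sign(rev$t))
})

test_that("subjects with a zero reference are excluded with a warning", {
  v <- rbind(OFF1 = c(0.3, 0, 0.4), ON1 = c(0.36, 0.1, 0.44),
             OFF2 = c(0.3, 0.2, 0.4), ON2 = c(0.36, 0.1, 0.44))
  expect_warning(gs <- block_statistics(v, list(
    c1 = list(a = "ON1", b = "OFF1"))), "excluded")
  expect_equal(gs$n, 2)
})

test_that("Holm adjustment is available but off by default", {
  v <- rbind(OFF1 = c(0.30, 0.40, 0.35), ON1 = c(0.36, 0.44, 0.45),
             OFF2 = c(0.31, 0.39, 0.36), ON2 = c(0.35, 0.45, 0.44))
  expect_null(block_statistics(v)$p_holm)
  gh <- block_statistics(v, holm = TRUE)
  expect_true(all(gh$p_holm >= gh$p))
})

test_that("functional pipeline computes block physiology from the area pairs", {
  truth <- functional_truth(k1_block_sd = 0, k2_block_sd = 0, k1_sd = 0,
                            k2_sd = 0, ratio_PCr_sd = 0, ratio_Pi_sd = 0,
                            ratio_NAD_sd = 0)
  st <- generate_functional_study(n_subjects = 2, truth = truth,
                                  noise_sd = 0, seed = 1)
  rep <- run_functional_study(st, T1_PCr = 5.1, T1_Pi = 3.0)
  off1 <- rep$blocks[rep$blocks$label == "OFF1", ]
  expect_equal(off1$k1, rep(0.35, 2), tolerance = 1e-9)
  expect_equal(off1$k2, rep(0.15, 2), tolerance = 1e-9)
  expect_equal(off1$PCr_gATP, rep(1.22, 2))
  expect_equal(off1$conc_PCr, rep(3.66, 2))
  expect_equal(off1$conc_Pi, rep(1.62, 2))
  expect_equal(off1$flux_CK_mM_s, rep(0.35 * 3.66, 2), tolerance = 1e-9)
  expect_equal(off1$flux_ATPase_umol_g_min,
               rep(0.15 * 1.62 * 60 / 1.1, 2), tolerance = 1e-9)
  expect_equal(off1$pH, rep(7, 2), tolerance = 1e-9)
})

test_that("functional pipeline rejects incomplete paradigms and flags negative rates", {
  st <- generate_functional_study(n_subjects = 2, seed = 2)
  expect_error(run_functional_study(st[st$label != "ON2", ]), "paradigm")
  st2 <- generate_functional_study(n_subjects = 2, noise_sd = 0, seed = 3,
                                   truth = functional_truth(
                                     k1_block_sd = 0, k2_block_sd = 0))
  st2$area_Pi_sat[1] <- st2$area_Pi_ref[1] * 1.05  # noise pushed Minf > M0
  expect_warning(rep <- run_functional_study(st2), "negative")
  expect_true(rep$blocks$k2_negative[1])
  expect_lt(rep$blocks$k2[1], 0)
})

test_that("OFF2 vs OFF1 is a valid null: p values look uniform across seeds", {
  ps <- vapply(1:60, function(s) {
    st <- generate_functional_study(n_subjects = 6, seed = 400 + s)
    rep <- suppressWarnings(run_functional_study(st))
    rep$stats$k1$p[rep$stats$k1$contrast == "OFF2_vs_OFF1"]
  }, numeric(1))
  expect_gt(mean(ps > 0.5), 0.25)          # not systematically small
  expect_lt(mean(ps < 0.05), 0.18)         # type-I error near nominal
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("reports serialize to flat JSON with calibrations recorded", {
  net <- resting_network()
  sims <- lapply(1:2, function(i) generate_mt_series(net, noise_sd = 0))
  prep <- run_progressive_study(sims)
  p <- withr::local_tempfile(fileext = ".json")
  write_report(prep, p)
  j <- jsonlite::read_json(p)
  expect_equal(j$k1_per_s, 0.37, tolerance = 1e-6)
  st <- generate_functional_study(n_subjects = 3, seed = 5)
  frep <- suppressWarnings(run_functional_study(st))
  p2 <- withr::local_tempfile(fileext = ".json")
  write_report(frep, p2)
  j2 <- jsonlite::read_json(p2)
  expect_equal(j2$ph_pKa, 6.77)
  expect_true(!is.null(j2$k1_pct_change_ON1_vs_OFF1))
})
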