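test_that("the relative correction factor follows its defining ratio", {
  expect_equal(compute_rcf(5, 100, 5, 100), 1)
  # masses from the mixed reference at 20 ul, areas = measured means
  expect_equal(compute_rcf(12.28, 3571.0, 9.92, 3332.7), 1.1552955,
               tolerance = 1e-6)
  expect_equal(compute_rcf(12.28, 3571.0, 7.70, 1892.7), 0.8452780,
               tolerance = 1e-6)
  # both sit within 1% of the reported per-volume factors 1.15 and 0.85
  expect_equal(compute_rcf(12.28, 3571.0, 9.92, 3332.7), 1.15, tolerance = 0.01)
  expect_equal(compute_rcf(12.28, 3571.0, 7.70, 1892.7), 0.85, tolerance = 0.01)
  expect_error(compute_rcf(0, 1, 1, 1), class = "herbqc_domain_error")
})

test_that("reciprocal correction factors multiply to one", {
  set.seed(11)
  for (i in 1:25) {
    w <- runif(2, 1, 20); a <- runif(2, 100, 5000)
    f_ks <- compute_rcf(w[1], a[1], w[2], a[2])
    f_sk <- compute_rcf(w[2], a[2], w[1], a[1])
    expect_equal(f_ks * f_sk, 1, tolerance = 1e-12)
  }
})

test_that("rcf_summary reproduces the reported durability statistics", {
  s <- rcf_summary(rcf_series[-1], irs = "D")
  fa <- s[s$component == "f_A", ]
  expect_equal(round(fa$mean, 2), 1.63)
  expect_equal(round(fa$rsd_pct, 2), 1.56)
  expect_equal(round(s$mean[s$component == "f_F"], 2), 1.15)
  expect_equal(round(s$mean[s$component == "f_B9"], 2), 0.84)
  expect_true(all(s$rsd_pct < 3))
})

test_that("rcf_summary handles degenerate and inconsistent inputs", {
  same <- data.frame(f_A = rep(1.6, 4), f_F = rep(1.1, 4))
  s <- rcf_summary(same)
  expect_equal(s$mean, c(1.6, 1.1))
  expect_equal(s$rsd_pct, c(0, 0))

  expect_error(rcf_summary(data.frame(f_A = 1.6)),
               class = "herbqc_insufficient_data_error")
  expect_error(rcf_summary(data.frame(f_A = c(1.6, 1.7), f_F = c(1.1, NA))),
               class = "herbqc_consistency_error")

  # RSD is scale-free: rescaling every replicate leaves it unchanged
  s2 <- rcf_summary(rcf_series[-1] * 3.7)
  expect_equal(s2$rsd_pct, rcf_summary(rcf_series[-1])$rsd_pct,
               tolerance = 1e-12)
})

test_that("replicate_summary reproduces the reported validation RSDs", {
  p <- replicate_summary(precision_d)
  expect_equal(round(p$mean, 1), 3571.0)
  expect_equal(round(p$rsd_pct, 2), 0.50)

  r <- replicate_summary(repeatability_d)
  expect_equal(round(r$mean, 1), 3451.0)
  expect_equal(round(r$rsd_pct, 2), 1.41)

  s <- replicate_summary(stability_d)
  expect_equal(round(s$mean, 1), 3474.5)
  expect_equal(round(s$rsd_pct, 2), 0.56)

  expect_equal(replicate_summary(rep(5, 4))$rsd_pct, 0)
  expect_error(replicate_summary(3), class = "herbqc_insufficient_data_error")
})

test_that("spike recovery matches the reported rates", {
  expect_equal(recovery(5.715, 5.700, 11.425)$rate_pct, 100.18, tolerance = 1e-4)
  expect_equal(recovery(5.717, 5.700, 11.488)$rate_pct, 101.25, tolerance = 1e-4)
  expect_equal(recovery(3, 2, 5)$rate_pct, 100)  # exact spike return
  expect_error(recovery(1, 0, 2), class = "herbqc_domain_error")
})

test_that("single-point external standardisation behaves linearly", {
  expect_equal(esm_content(100, 100, 40, 40), 100)
  expect_equal(esm_content(3451.0, 3571.0, 12.28, 40), 29.668356,
               tolerance = 1e-6)
  expect_equal(esm_content(3451.0 / 2, 3571.0, 12.28, 40),
               29.668356 / 2, tolerance = 1e-6)
  expect_error(esm_content(-1, 1, 1, 1), class = "herbqc_domain_error")
})

test_that("QAMS content reduces to ESM for the reference component itself", {
  # s = k: f = 1 and a_s = a_k gives exactly the IRS content
  w_k <- 11.87
  expect_equal(qams_content(3451.0, 3451.0, w_k, 1, 40), 100 * w_k / 40)
  expect_equal(qams_content(1797.3, 3451.0, 11.87, 1.15, 40), 13.439048,
               tolerance = 1e-6)
  expect_error(qams_content(1, 1, 1, 0, 1), class = "herbqc_domain_error")
})

test_that("QAMS equals ESM to machine precision on noise-free data", {
  cfg <- synth_config(noise_cv = 0)
  series <- gen_reference_series(cfg)
  samples <- gen_sample_injections(cfg, n_injections = 1)
  mk <- cfg$markers
  ref <- series[["ref_20ul"]]
  ref_hits <- assign_markers(ref, mk)
  smp_hits <- assign_markers(samples[[1]], mk)
  w_ref <- mk$ref_conc_mg_ml * 20
  f <- compute_rcf(w_ref[mk$name == "D"], ref_hits$area[ref_hits$marker == "D"],
                   w_ref, ref_hits$area)
  esm <- esm_content(smp_hits$area, ref_hits$area, w_ref, 40)
  w_k <- esm[mk$name == "D"] / 100 * 40
  qams <- qams_content(smp_hits$area, smp_hits$area[mk$name == "D"],
                       w_k, f, 40)
  expect_equal(qams, esm, tolerance = 1e-9)
  # single-point ESM at a power-law detector is biased by (m_smp/m_ref)^(b-1);
  # with the near-unit printed slopes that bias stays within ~2.5%
  expect_equal(esm, unname(cfg$true_content_pct[mk$name]), tolerance = 0.025)
})

test_that("with a linear detector the noise-free pipeline recovers true contents exactly", {
  mk1 <- dplyr::mutate(default_markers(), slope = 1)
  cfg <- synth_config(markers = mk1, noise_cv = 0)
  ref_hits <- assign_markers(gen_reference_series(cfg)[["ref_20ul"]], mk1)
  smp_hits <- assign_markers(gen_sample_injections(cfg, 1)[[1]], mk1)
  esm <- esm_content(smp_hits$area, ref_hits$area, mk1$ref_conc_mg_ml * 20, 40)
  expect_equal(esm, unname(cfg$true_content_pct[mk1$name]), tolerance = 1e-9)
})

test_that("under multiplicative noise the QAMS-ESM discrepancy stays of order CV", {
  cv <- 0.02
  cfg <- synth_config(noise_cv = cv, seed = 99)
  series <- gen_reference_series(cfg)
  samples <- gen_sample_injections(cfg, n_injections = 6)
  mk <- cfg$markers
  ref_hits <- assign_markers(series[["ref_20ul"]], mk)
  w_ref <- mk$ref_conc_mg_ml * 20
  f <- compute_rcf(w_ref[mk$name == "D"], ref_hits$area[ref_hits$marker == "D"],
                   w_ref, ref_hits$area)
  rel <- purrr::map_dbl(samples, function(s) {
    hits <- assign_markers(s, mk)
    esm <- esm_content(hits$area, ref_hits$area, w_ref, 40)
    w_k <- esm[mk$name == "D"] / 100 * 40
    qams <- qams_content(hits$area, hits$area[mk$name == "D"], w_k, f, 40)
    max(abs(qams / esm - 1))
  })
  expect_lt(max(rel), 10 * cv)
})

test_that("compare_methods runs a paired t-test and guards degenerate cases", {
  contents <- tidyr::expand_grid(batch = as.character(1:5),
                                 marker = c("A", "F"))
  contents$content <- c(2.07, 9.91, 1.63, 4.73, 3.83, 14.38, 3.14, 12.92,
                        10.57, 3.66)
  same <- compare_methods(contents, contents)
  expect_true(all(same$degenerate))
  expect_equal(same$p, c(1, 1))
  expect_true(all(same$agrees))

  shifted <- dplyr::mutate(contents, content = content + 1)
  sh <- compare_methods(contents, shifted)
  expect_true(all(sh$degenerate))
  expect_equal(sh$mean_diff, c(1, 1))
  expect_equal(sh$p, c(0, 0))

  expect_error(compare_methods(contents[contents$batch == "1", ],
                               shifted[shifted$batch == "1", ]),
               class = "herbqc_insufficient_data_error")
  expect_error(compare_methods(contents, contents[-1, ]),
               class = "herbqc_consistency_error")
})

test_that("small unbiased noise rarely produces a significant QAMS-ESM difference", {
  base <- tidyr::expand_grid(batch = as.character(1:5), marker = "D")
  base$content <- c(19.05, 13.29, 23.66, 28.53, 8.91)
  set.seed(123)
  reject <- purrr::map_lgl(1:1000, function(i) {
    noisy <- dplyr::mutate(base, content = content + rnorm(5, 0, 0.01))
    compare_methods(base, noisy)$p <= 0.05
  })
  # an unbiased 5%-level paired t-test keeps p > 0.05 at its nominal rate
  expect_gte(mean(!reject), 0.93)
})
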