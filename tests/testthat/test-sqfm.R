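test_that("macro-qualitative similarity is 1 exactly for proportional profiles", {
  y <- c(3560, 640, 1830, 1310, 410)
  expect_equal(sqfm_sm(y, y), 1)
  expect_equal(sqfm_sm(2 * y, y), 1)
  expect_equal(sqfm_sm(y / 7, y), 1)
})

test_that("macro-qualitative similarity matches the hand-computed oracle", {
  # cos = 10/14; ratio term = (1/3 + 1 + 3)/sqrt(3 * (1/9 + 1 + 9))
  expect_equal(sqfm_sm(c(1, 2, 3), c(3, 2, 1)), 0.75054075, tolerance = 1e-7)
  expect_error(sqfm_sm(c(1, 2), c(1, 2, 3)), class = "herbqc_domain_error")
  expect_error(sqfm_sm(c(1, 0), c(1, 2)), class = "herbqc_domain_error")
})

test_that("the quantitative measures C and P follow their closed forms", {
  y <- c(3, 2, 1)
  expect_equal(sqfm_c(y, y), 100)
  expect_equal(sqfm_c(2 * y, y), 200)
  expect_equal(sqfm_c(c(1, 2, 3), y), 100 * 10 / 14, tolerance = 1e-12)

  expect_equal(sqfm_p(y, y), 100)
  expect_equal(sqfm_p(2 * y, y), 200)
  expect_equal(sqfm_p(c(1, 2, 3), y), 100 * (6 / 6) * (10 / 14),
               tolerance = 1e-12)
})

test_that("P_m and alpha combine C and P as mean and relative divergence", {
  y <- c(5, 4, 3)
  pa <- sqfm_pm_alpha(y, y)
  expect_equal(pa$p_m_pct, 100)
  expect_equal(pa$alpha, 0)
  # equal totals and symmetric profiles: C = P so alpha vanishes
  pa2 <- sqfm_pm_alpha(c(1, 2, 3), c(3, 2, 1))
  expect_equal(pa2$p_m_pct, 100 * 10 / 14, tolerance = 1e-10)
  expect_equal(pa2$alpha, 0, tolerance = 1e-12)
})

test_that("similarity invariances: S_m and alpha are scale-free, P_m is linear", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(5:12, 1)
    x <- runif(n, 10, 5000); y <- runif(n, 10, 5000); c0 <- runif(1, 0.2, 5)
    expect_gt(sqfm_sm(x, y), 0)
    expect_lte(sqfm_sm(x, y), 1 + 1e-12)
    expect_equal(sqfm_sm(c0 * x, y), sqfm_sm(x, y), tolerance = 1e-12)
    pa <- sqfm_pm_alpha(x, y); pas <- sqfm_pm_alpha(c0 * x, y)
    expect_equal(pas$p_m_pct, c0 * pa$p_m_pct, tolerance = 1e-9)
    expect_equal(pas$alpha, pa$alpha, tolerance = 1e-9)
    # proportionality is the only way to reach S_m = 1
    expect_lt(sqfm_sm(x + runif(n, 1, 10), y), 1)
    expect_equal(sqfm_sm(c0 * y, y), 1, tolerance = 1e-12)
  }
})

test_that("the reference fingerprint is the batch-wise mean profile", {
  fm <- fingerprint_matrix(data.frame(batch_id = c("a", "b"),
                                      p1 = c(1, 3), p2 = c(2, 2), p3 = c(3, 1)))
  expect_equal(unname(build_rfp(fm)), c(2, 2, 2))

  same <- fingerprint_matrix(data.frame(batch_id = c("a", "b", "c"),
                                        p1 = rep(4, 3), p2 = rep(9, 3)))
  expect_equal(unname(build_rfp(same)), c(4, 9))

  set.seed(5)
  m <- matrix(runif(55, 10, 100), nrow = 5)
  fm2 <- fingerprint_matrix(
    dplyr::bind_cols(tibble::tibble(batch_id = paste0("b", 1:5)),
                     stats::setNames(as.data.frame(m), paste0("p", 1:11))))
  # independent brute-force mean
  expected <- vapply(seq_len(11), function(j) sum(m[, j]) / 5, numeric(1))
  expect_equal(unname(build_rfp(fm2)), expected)
})

test_that("grading maps each reported batch to its published grade", {
  g <- sqfm_grade(batch_sqfm$s_m, batch_sqfm$p_m, batch_sqfm$alpha)
  expect_equal(g$grade, batch_sqfm$grade)
  expect_equal(g$quality, batch_sqfm$quality)
  # per-parameter grades for the three spot-checked batches
  expect_equal(unlist(g[2, c("grade_s_m", "grade_p_m", "grade_alpha")],
                      use.names = FALSE), c(2, 7, 2))
  expect_equal(unlist(g[4, c("grade_s_m", "grade_p_m", "grade_alpha")],
                      use.names = FALSE), c(2, 4, 3))
  expect_equal(unlist(g[5, c("grade_s_m", "grade_p_m", "grade_alpha")],
                      use.names = FALSE), c(5, 1, 5))
  # the reference's self-evaluation is always grade 1
  self <- sqfm_grade(1, 100, 0)
  expect_equal(self$grade, 1L)
  expect_equal(self$quality, "Best")
})

test_that("grading is monotone in each parameter", {
  set.seed(17)
  for (i in 1:40) {
    s <- runif(1, 0.4, 1); p <- runif(1, 40, 160); a <- runif(1, 0, 0.6)
    g0 <- sqfm_grade(s, p, a)$grade
    worse_s <- max(s - runif(1, 0, 0.2), 1e-3)
    worse_p <- 100 + (p - 100) * (1 + runif(1, 0, 0.5))
    worse_a <- a + runif(1, 0, 0.2)
    expect_gte(sqfm_grade(worse_s, p, a)$grade, g0)
    expect_gte(sqfm_grade(s, worse_p, a)$grade, g0)
    expect_gte(sqfm_grade(s, p, worse_a)$grade, g0)
  }
})

test_that("batch evaluation appends the reference self-row and grades all batches", {
  fm <- fingerprint_matrix(data.frame(batch_id = c("a", "b", "c"),
                                      p1 = rep(10, 3), p2 = rep(20, 3)))
  ev <- sqfm_evaluate(fm)
  expect_equal(nrow(ev), 4)
  expect_equal(ev$grade, rep(1L, 4))
  rfp_row <- ev[ev$batch == "RFP", ]
  expect_equal(rfp_row$s_m, 1)
  expect_equal(rfp_row$p_m_pct, 100)
  expect_equal(rfp_row$alpha, 0)

  expect_s3_class(tidy(ev), "tbl_df")
  gl <- glance(ev)
  expect_equal(gl$n_batches, 3)
  expect_equal(gl$worst_grade, 1)
})

test_that("evaluation recovers the generator's planted scale profile", {
  cfg <- synth_config(n_batches = 2, batch_scales = c(1, 0.5),
                      shape_noise_cv = 0)
  fp <- gen_fingerprints(cfg)
  ev <- sqfm_evaluate(fp$fingerprints)
  b2 <- ev[ev$batch == "batch2", ]
  expect_equal(b2$s_m, 1, tolerance = 1e-12)
  expect_equal(b2$alpha, 0, tolerance = 1e-12)
  expect_equal(b2$p_m_pct, 100 * 0.5 / 0.75, tolerance = 1e-9)
  expect_equal(ev$p_m_pct[ev$batch != "RFP"], fp$truth$expected_c_pct,
               tolerance = 1e-9)
})

test_that("custom grading tables are validated", {
  bad <- sqfm_grading()
  bad$s_m_floor[2] <- 0.99  # no longer non-increasing
  expect_error(sqfm_grade(0.9, 100, 0.05, grading = bad),
               class = "herbqc_validation_error")
  expect_error(sqfm_grade(1.2, 100, 0), class = "herbqc_domain_error")
})
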