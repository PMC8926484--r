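# Shared fixtures, built in code.

# quick peak-table constructor
pt <- function(rts, areas, id = "inj", volume = 20) {
  peak_table(data.frame(peak_id = seq_along(rts), rt = rts, area = areas),
             injection_id = id, volume_ul = volume)
}

# Reported reference values for the four-saponin assay (saponins D, A, F, B9
# of Pulsatilla chinensis total-saponin extract) used as frozen oracles.

# relative correction factors across the seven-volume injection series
rcf_series <- data.frame(
  volume_ul = c(3, 5, 10, 15, 20, 25, 30),
  f_A  = c(1.62, 1.59, 1.63, 1.61, 1.63, 1.66, 1.66),
  f_F  = c(1.13, 1.14, 1.13, 1.17, 1.15, 1.17, 1.18),
  f_B9 = c(0.80, 0.86, 0.82, 0.83, 0.85, 0.85, 0.87))

# replicate saponin-D peak areas: precision (repeated injection),
# repeatability (parallel preparations), stability (time series)
precision_d     <- c(3562.5, 3559.8, 3578.2, 3546.3, 3585.6, 3593.4)
repeatability_d <- c(3438.0, 3399.3, 3491.0, 3527.9, 3434.5, 3415.5)
stability_d     <- c(3474.3, 3449.1, 3494.7, 3476.9, 3455.8, 3496.4)

# spike-recovery records (mg): analyte in sample, amount added, total found,
# and the reported recovery rate (%)
spike_records <- data.frame(
  marker = rep(c("D", "A", "F", "B9"), each = 6),
  content_mg = c(5.720, 5.715, 5.712, 5.715, 5.717, 5.720,
                 0.630, 0.629, 0.629, 0.629, 0.629, 0.630,
                 2.590, 2.588, 2.587, 2.588, 2.589, 2.590,
                 2.550, 2.548, 2.547, 2.548, 2.549, 2.550),
  added_mg = rep(c(5.700, 0.630, 2.590, 2.550), each = 6),
  measured_mg = c(11.525, 11.425, 11.435, 11.421, 11.488, 11.539,
                  1.262, 1.264, 1.272, 1.261, 1.272, 1.272,
                  5.216, 5.187, 5.241, 5.234, 5.245, 5.219,
                  5.100, 5.082, 5.113, 5.077, 5.090, 5.084),
  reported_rate = c(101.83, 100.18, 100.40, 100.11, 101.25, 102.08,
                    100.31, 100.83, 102.08, 100.32, 101.98, 101.94,
                    101.38, 100.35, 102.47, 102.16, 102.56, 101.51,
                    99.98, 99.37, 100.66, 99.20, 99.64, 99.35))

# published SQFM parameters and grades of the five evaluated batches
batch_sqfm <- data.frame(
  batch = as.character(1:5),
  s_m = c(0.936, 0.934, 0.952, 0.938, 0.718),
  p_m = c(91.8, 54.4, 104.7, 117.3, 104.3),
  alpha = c(0.06, 0.078, 0.004, 0.117, 0.257),
  grade = c(2L, 7L, 1L, 4L, 5L),
  quality = c("Better", "Defective", "Best", "Fine", "Moderate"))
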