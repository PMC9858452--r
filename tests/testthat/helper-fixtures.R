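library(tibble)
library(dplyr)

# noiseless SK curve on a schedule
sk_curve <- function(c0 = 0, c_inf = 40, k = 0.03,
                     times = digestion_schedule("SINGLE_ENZYME")) {
  tibble(time_min = times, value = c0 + (c_inf - c0) * (1 - exp(-k * times)))
}

# noiseless 2-fraction CPS curve
cps_curve <- function(fractions = tibble(c_inf = c(30, 20), k = c(0.1, 0.01),
                                         t_start = c(0, 30)),
                      c0 = 0, times = digestion_schedule("SINGLE_ENZYME")) {
  v <- rep(c0, length(times))
  for (j in seq_len(nrow(fractions))) {
    act <- times > fractions$t_start[j]
    v[act] <- v[act] + fractions$c_inf[j] *
      (1 - exp(-fractions$k[j] * (times[act] - fractions$t_start[j])))
  }
  tibble(time_min = times, value = v)
}

# long digestogram wrapper around a single curve
as_digesto_table <- function(curve, sample_id = "S1", protocol = "PANCREATIN",
                             replicate = 1, basis = "REDUCING_SUGAR_NORMALIZED") {
  tibble(sample_id = sample_id, protocol = protocol, replicate = replicate,
         basis = basis, time_min = curve$time_min, value = curve$value)
}

# GI / GL vectors as printed for the eight calibration biscuits
table3_gi <- c(9, 9, 11, 13, 13, 13, 16, 30)
table3_gl <- c(1.27, 2.00, 2.44, 2.37, 2.35, 2.34, 2.98, 4.76)
table3_carb <- c(14.15, 22.24, 22.14, 18.21, 18.10, 18.00, 18.65, 15.86)
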