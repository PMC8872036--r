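# Shared fixtures and frozen oracle values.
#
# The "oracle" values below were computed independently of the package
# code, by evaluating the closed forms with 30-digit arbitrary-precision
# arithmetic, and are frozen here.

oracle <- list(
  carbon_fraction_c5h8 = 0.881618931575625,
  conc_1pptv_isoprene_stp = 0.00245482733088510, # 298.15 K, 101.325 kPa
  cl_1000 = 0.999640178931468,
  ct_303_15 = 0.963248133930242,
  std_factor_16_5c_880par = 5.68065182740738,
  mt_std_293_15 = 2.45960311115695,             # exp(0.9)
  gamma_303_297 = 1.06504252975805,
  gamma_293_288 = 0.285765657485206,
  cce_standard = 0.938929640891595,
  ft_293_288 = 742.156098483359,
  warming_megan_293_288_p4_tracking = 172.654674688275,
  e_opt_288 = 0.973504511919943,
  eq1_example = 30.5561214096557,               # dC 0.001, Q 1500, S 0.04909
  warming_3c_percent = 178.693167325747,        # 100 exp(3 * 0.1935)
  warming_4c_percent = 216.842261999065,
  a_true_default = 0.1935
)

# Hand-constructed enclosure records with an exactly-known exponential
# truth: one record at exactly 20 degC per enclosure so the reference-bin
# normalization constant is exactly 1.
make_exact_enclosure <- function(a = 0.1935, e20 = c(50, 120),
                                 temps = c(5, 10, 15, 20, 25, 30),
                                 q = 1500, s = 0.04909) {
  t0 <- as.POSIXct("2019-06-10 10:00:00", tz = ast_timezone())
  rows <- lapply(seq_along(e20), function(e) {
    er <- e20[e] * exp(a * (temps - 20))
    data.frame(
      timestamp = t0 + seq_along(temps) * 3600, # 11:00 onward, all daytime
      enclosure_id = sprintf("enc%02d", e),
      kind = "surface", vegetation_class = "salix", compound = "isoprene",
      c_in = 0.001, c_out = 0.001 + er * s / q,
      q = q, s = s, m_dry = NA_real_,
      t_enclosure = temps, rh = 70, par = 1000,
      er_true = er, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# Timestamps at given fractional hours on one AST day.
ts_at_hours <- function(hours, day = "2019-06-15") {
  as.POSIXct(paste(day, "00:00:00"), tz = ast_timezone()) + hours * 3600
}
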