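#!/usr/bin/env Rscript
# Measured (reference) arm: paired pressure + Doppler-like flow.
#
# Per subject: calibrate the pressure beat to the brachial cuff values,
# Fourier-decompose both channels, form the input impedance spectrum,
# take SVR from its 0 Hz value, the characteristic impedance as the mean
# modulus of harmonics 3-10 (outliers excluded), and separate the
# pressure into forward/backward waves at that Zc.

suppressMessages(library(hemowave))

coh <- read_cohort("results/cohort")
message("Analyzing ", length(coh$subjects), " subjects (measured arm) ...")
meas <- analyze_cohort(coh, "measured")
utils::write.csv(meas, "results/measured_arm.csv", row.names = FALSE)

fmt <- function(x) sprintf("%.3g (%.3g)", mean(x), sd(x))
message("  SV  ", fmt(meas$sv), " ml")
message("  SVR ", fmt(meas$svr), " mmHg*s/ml")
message("  Zc  ", fmt(meas$zc), " mmHg*s/ml")
message("  Pf  ", fmt(meas$pf_amp), " mmHg, Pb ", fmt(meas$pb_amp), " mmHg")
message("  RM  ", fmt(meas$rm))
message("Written: results/measured_arm.csv")
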