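#!/usr/bin/env Rscript
# Trial-averaged detection of sub-threshold depolarisations: for steps of
# 0.5-2.5 mV, how many trials must be averaged before the response clears
# SNR 1? Writes results/subthreshold_snr.csv.

suppressMessages(library(voltim))
dir.create("results", showWarnings = FALSE)

rows <- list()
for (amp in seq(0.5, 2.5, by = 0.5)) {
  r <- run_scenario(list(scenario = "subthreshold", seed = 20260904,
                         params = list(amplitude_mv = amp)))
  tab <- r$tables$snr_vs_n
  tab$amplitude_mv <- amp
  rows[[length(rows) + 1]] <- tab
  cat(sprintf("%.1f mV: SNR %.2f after 25 trials (%.2f single-trial)\n",
              amp, tab$snr[tab$n == 25], tab$snr[tab$n == 1]))
}
write.csv(do.call(rbind, rows), "results/subthreshold_snr.csv",
          row.names = FALSE)
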