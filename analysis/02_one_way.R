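#!/usr/bin/env Rscript
# One-way deterministic sensitivity analysis: each ranged parameter is moved
# to its bounds with everything else held at base, and the early-initiation
# vs enalapril ICER recorded at each bound (tornado table).

suppressPackageStartupMessages(library(svcea))

outdir <- "results"
dir.create(outdir, showWarnings = FALSE)

inputs <- base_case_inputs()
params <- inputs$params
lt <- inputs$lt
config <- system.file("extdata", "base_case.yaml", package = "svcea")

tor <- tornado(params, lt)
print(tor, digits = 5)
export_tornado_csv(tor, file.path(outdir, "tornado.csv"))
write_manifest(run_manifest(config, horizon = params$horizon_cycles),
               file.path(outdir, "tornado_manifest.json"))

widest <- tor[1, ]
message(sprintf(
  "Widest bar: %s (ICER %.1f to %.1f USD/QALY over [%g, %g])",
  widest$parameter, widest$icer_low, widest$icer_high, widest$low,
  widest$high
))
max_icer <- max(c(tor$icer_low, tor$icer_high))
message(sprintf(
  "Largest one-way ICER %.1f USD/QALY %s the WTP threshold of %.1f",
  max_icer, if (max_icer < params$wtp) "stays below" else "exceeds",
  params$wtp
))
message("Wrote ", file.path(outdir, "tornado.csv"))
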