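#!/usr/bin/env Rscript
# Runs the whole synthetic study in order. Each numbered script is
# standalone and re-reads its inputs from results/study/, so any stage can
# also be re-run on its own.

for (script in sprintf("analysis/%02d_%s.R", 1:7,
                       c("simulate", "modules", "scoring", "discrimination",
                         "enrichment_markers", "proximity", "report"))) {
  message("==> ", script)
  source(script, echo = FALSE)
}
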