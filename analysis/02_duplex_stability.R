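#!/usr/bin/env Rscript
# Sliding-window duplex-stability (dG) profile of the promoter construct
# from unified nearest-neighbor thermodynamics at 25 C, 1 M NaCl.

suppressMessages(library(curvafm))
dir.create("results", showWarnings = FALSE)

p <- synthetic_promoter()
prof <- dG_profile(p, window_len = 150, step = 1)
write_dG_tsv(prof, "results/dG_profile.tsv")

gm <- attr(prof, "global_mean")
message(sprintf("global mean step dG: %.3f kcal/mol", gm))
weakest <- prof$center[which.max(prof$dG)]
message(sprintf(
  "least stable 150 bp window centered at %+d bp (dG %.3f kcal/mol)",
  weakest, max(prof$dG)))
inside <- prof$center >= -137 & prof$center <= -64
message(sprintf("mean window dG over PRRII: %.3f kcal/mol (%+.3f vs global)",
                mean(prof$dG[inside]), mean(prof$dG[inside]) - gm))
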