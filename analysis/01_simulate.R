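#!/usr/bin/env Rscript
# Stage 1: simulate an experiment-1-like loop-design two-channel dataset
# (3 groups x 8 queens, 12 sub-arrays / 24 sample-channels, transcripts
# printed in duplicate) with known ground truth, and write the raw inputs
# the rest of the workflow consumes.

suppressMessages(library(looparray))

out <- "results"
dir.create(out, showWarnings = FALSE)

spec <- effect_spec(n_transcripts = 500, seed = 20260901)
sim <- generate_experiment(spec)

write_design(sim$design, file.path(out, "design.txt"))
write_intensities(sim$intensities, file.path(out, "intensities.tsv"))
writeLines(sim$truth$de_transcripts, file.path(out, "truth_de.txt"))

message("Simulated ", spec$n_transcripts, " transcripts x ",
        nrow(sim$design$channels), " channels on ", sim$design$n_arrays,
        " arrays; ", length(sim$truth$de_transcripts),
        " transcripts carry planted group effects (SD ",
        spec$treatment_effect_sd, " log2 units).")
message("Dye-swap balance per group:")
print(table(sim$design$channels$group, sim$design$channels$dye))
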