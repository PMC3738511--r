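#!/usr/bin/env Rscript
# Stage 3: spot-level filtering and log2 transform. Channel values below the
# array background (300) become missing; spots present on fewer than 20 of
# the 24 sample-channels are dropped; surviving intensities are log2-scaled.

suppressMessages(library(looparray))

out <- "results"
design <- read_design(file.path(out, "design.txt"))
raw <- read_intensities(file.path(out, "intensities.tsv"), design)

filt <- filter_spots(raw, design, min_intensity = 300, min_present = 20)
expr <- log2_transform(filt$intensities)

write.table(expr, file.path(out, "expression.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
rep <- filt$report
writeLines(jsonlite::toJSON(unclass(rep), auto_unbox = TRUE, pretty = TRUE),
           file.path(out, "filter_report.json"))

message("Filtering: ", rep$n_spots_in, " spots in; ",
        rep$n_low_intensity_cells, " channel values below ",
        rep$min_intensity, " set missing; ", rep$n_spots_removed_presence,
        " spots dropped by the presence rule (< ", rep$min_present, " of ",
        2 * rep$n_arrays, " channels); ", rep$n_spots_out, " spots retained.")
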