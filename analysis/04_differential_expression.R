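#!/usr/bin/env Rscript
# Stage 4: two-stage mixed-model differential expression. Global REML
# normalization (dye + block fixed; array, array:dye, array:block random),
# then a per-transcript mixed ANOVA (treatment + spot + dye fixed; array
# random; Kenward-Roger small-sample inference) on the residuals, with BH
# FDR control per p-value family. Also reports recovery against the
# simulation's ground truth and the pairwise-set accounting.

suppressMessages(library(looparray))

out <- "results"
design <- read_design(file.path(out, "design.txt"))
expr <- read.delim(file.path(out, "expression.tsv"), comment.char = "#")
truth_de <- readLines(file.path(out, "truth_de.txt"))

de <- run_de(expr, design, q_threshold = 0.001, de_set = "overall")

write.table(de$table, file.path(out, "de_results.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(de$contrasts, file.path(out, "de_contrasts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(de$significant, file.path(out, "significant_q001.txt"))

norm <- de$normalization
message("Normalization (", norm$method, "): dye contrast ",
        round(norm$dye_contrast, 3), "; variance components ",
        paste(names(norm$varcomp), round(norm$varcomp, 4), sep = "=",
              collapse = ", "))
message(de$n_tested, " transcripts tested; ", length(de$significant),
        " significant at q < 0.001 (overall treatment test).")
tp <- sum(de$significant %in% truth_de)
message("Ground-truth recovery: ", tp, " of ", length(truth_de),
        " planted DE transcripts detected (", length(de$significant) - tp,
        " false discoveries).")

# pairwise accounting (the Venn view of the three group contrasts)
pw <- de$significant_pairwise
for (nm in names(pw)) message("  ", nm, ": ", length(pw[[nm]]), " significant")
if (length(pw) == 3) {
  v <- venn_counts(pw)
  vdf <- data.frame(region = names(v), count = as.integer(v))
  write.table(vdf, file.path(out, "venn_pairwise.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  # are the two environment-style contrasts asymmetric in size?
  sizes <- lengths(pw)
  top2 <- sort(sizes, decreasing = TRUE)[1:2]
  pt <- proportion_test(top2[1], top2[2])
  message("Equal-split test on the two largest pairwise sets (",
          paste(top2, collapse = " vs "), "): G = ", round(pt$G, 2),
          ", p = ", signif(pt$p_G, 3))
}
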