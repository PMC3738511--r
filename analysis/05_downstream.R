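#!/usr/bin/env Rscript
# Stage 5: downstream multivariate and set statistics on the DE results:
# PCA variance partition of the significant transcripts, k-means and Ward
# clustering of their profiles, overlap/representation-factor statistics,
# term enrichment with ancestor (slim) mapping, and the qPCR-style
# normalization example.

suppressMessages(library(looparray))

out <- "results"
design <- read_design(file.path(out, "design.txt"))
expr <- read.delim(file.path(out, "expression.tsv"), comment.char = "#")
sig <- readLines(file.path(out, "significant_q001.txt"))

de <- run_de(expr, design, q_threshold = 0.001)
res <- de$normalization$residuals
res$transcript <- design$spots$transcript[match(res$spot, design$spots$spot)]
res$channel <- paste(res$array, res$dye)

## PCA of the significant transcripts (channels as observations)
sub <- res[res$transcript %in% sig, ]
mat <- tapply(sub$residual, list(sub$channel, sub$transcript), mean,
              na.rm = TRUE)
mat <- mat[stats::complete.cases(mat), , drop = FALSE]
grp <- design$channels$group[match(rownames(mat),
                                   paste(design$channels$array,
                                         design$channels$dye))]
pp <- pca_partition(mat, data.frame(group = grp))
message("PCA of ", ncol(mat), " significant transcripts:")
print(pp)
write.table(data.frame(component = seq_along(pp$pct_variance),
                       pct_variance = pp$pct_variance),
            file.path(out, "pca_variance.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

## k-means (k = 2) and Ward tree on the DE transcript profiles
km <- kmeans_clusters(t(mat), k = 2, seed = 20260905)
message("k-means split the DE transcripts into clusters of ",
        paste(table(km$assignments), collapse = " and "), ".")
write.table(data.frame(transcript = names(km$assignments),
                       cluster = km$assignments),
            file.path(out, "kmeans_clusters.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
tree <- ward_tree(t(mat))
message("Ward tree built over ", ncol(mat), " transcripts (first merge ",
        "height ", round(tree$height[1], 3), ").")

## overlap of the two largest pairwise sets, with representation factor
pw <- de$significant_pairwise
if (length(pw) >= 2) {
  sizes <- sort(lengths(pw), decreasing = TRUE)
  a <- pw[[names(sizes)[1]]]; b <- pw[[names(sizes)[2]]]
  ov <- hypergeom_overlap(length(a), length(b), length(intersect(a, b)),
                          de$n_tested)
  message("Overlap of '", names(sizes)[1], "' and '", names(sizes)[2],
          "': ", ov$overlap, " shared of (", ov$n1, ", ", ov$n2,
          ") in a universe of ", ov$N, "; representation factor ",
          round(ov$representation_factor, 2), ", p = ", signif(ov$p, 3))
}

## enrichment against a generated annotation with a planted term, plus the
## single-count ancestor mapping of the significant terms
ga <- generate_annotation(n_genes = 1000, enrichment_strength = 5,
                          seed = 20260906)
er <- enrich_terms(ga$truth$significant_genes, ga$annotation,
                   ga$annotation$universe)
hit <- er$term[!is.na(er$q) & er$p < 0.05]
message("Enrichment: ", length(hit), " terms at p < 0.05; top term ",
        er$term[1], ifelse(er$term[1] == ga$truth$planted_term,
                           " (the planted term).", "."))
write.table(er, file.path(out, "enrichment.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
ac <- map_to_ancestors(hit, ga$annotation)
message("Ancestor mapping (single count): ", ac$n_assigned,
        " of ", length(hit), " enriched terms assigned; counts: ",
        paste(names(ac$counts), ac$counts, sep = "=", collapse = ", "))

## qPCR-style relative expression with a rank test
set.seed(20260907)
groups <- rep(c("haplo", "los"), each = 8)
target <- rlnorm(16, log(50), 0.3) * ifelse(groups == "los", 1.6, 1)
hk <- cbind(rlnorm(16, log(40), 0.1), rlnorm(16, log(60), 0.1))
rel <- qpcr_relative(target, hk, groups, reference = "haplo")
kw <- kruskal_wallis(rel, groups)
message("qPCR example: mean relative expression in 'los' = ",
        round(mean(rel[groups == "los"]), 2), " (haplo = 1); ",
        "Kruskal-Wallis H = ", round(kw$H, 2), ", p = ", signif(kw$p, 3))
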