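# Shared fixture builders (all generated in code; no data files).

# A minimal hand-built design: n_arrays two-channel arrays, one sample per
# channel, groups assigned round-robin.
tiny_design <- function(n_arrays = 2, n_transcripts = 2, duplicate_spots = 1,
                        groups = c("g1", "g2")) {
  pos <- seq_len(2 * n_arrays)
  channels <- data.frame(
    array = paste0("A", ceiling(pos / 2)),
    dye = ifelse(pos %% 2 == 1, "Cy3", "Cy5"),
    sample = paste0("s", pos),
    group = rep(groups, length.out = length(pos)))
  tr <- paste0("t", seq_len(n_transcripts))
  spots <- data.frame(
    spot = paste0(rep(tr, each = duplicate_spots), "_",
                  seq_len(duplicate_spots)),
    transcript = rep(tr, each = duplicate_spots),
    duplicate = rep(seq_len(duplicate_spots), n_transcripts),
    block = "B1")
  array_design(channels, spots)
}

# Complete intensity grid for a design with a constant or supplied value.
full_intensities <- function(design, value = 1000) {
  ch <- design$channels
  sp <- design$spots$spot
  out <- data.frame(
    spot = rep(sp, each = nrow(ch)),
    array = rep(ch$array, length(sp)),
    dye = rep(ch$dye, length(sp)),
    stringsAsFactors = FALSE)
  out$intensity <- rep(value, length.out = nrow(out))
  out
}

# Per-gene long data frame under the gene model's own assumptions:
# group effects + per-array random effect + residual noise.
simulate_gene_data <- function(design, group_effects = NULL, sd_array = 0.1,
                               sd_resid = 0.2) {
  ch <- design$channels
  sp <- design$spots
  d <- data.frame(
    spot = rep(sp$spot, each = nrow(ch)),
    array = rep(ch$array, nrow(sp)),
    dye = rep(ch$dye, nrow(sp)),
    stringsAsFactors = FALSE)
  grp <- ch$group[match(paste(d$array, d$dye), paste(ch$array, ch$dye))]
  arrays <- unique(ch$array)
  a_eff <- stats::setNames(stats::rnorm(length(arrays), 0, sd_array), arrays)
  ge <- if (is.null(group_effects))
    stats::setNames(rep(0, length(unique(grp))), unique(grp))
  else group_effects
  d$residual <- ge[grp] + a_eff[d$array] +
    stats::rnorm(nrow(d), 0, sd_resid)
  d
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}
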