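#' Build a loop-design channel layout
#'
#' Arranges samples in a canonical interleaved loop order -- one sample from
#' each group in turn (reversing direction on alternate rounds when the
#' number of groups is even) -- and assigns consecutive pairs to the two
#' channels of one sub-array with opposite dyes (odd positions Cy3, even
#' positions Cy5). Interleaving makes arrays mix treatment groups, so array
#' effects are not confounded with treatment, and for even group sizes it
#' balances the dye swap within every group (e.g. 4 Cy3 / 4 Cy5 for
#' 8-sample groups, 3/3 for 6-sample groups); an odd total leaves the last
#' array with one unused channel.
#'
#' @param groups named integer vector or named list of sample counts per
#'   group (e.g. `c(haplo = 8, win = 8, los = 8)`).
#' @param plex number of sub-arrays available per slide (default 12); total
#'   samples must not exceed `2 * plex`.
#' @param n_transcripts,duplicate_spots,n_blocks spot-layout parameters:
#'   each transcript is printed `duplicate_spots` times and spots are dealt
#'   round-robin into `n_blocks` print blocks.
#' @return an [array_design].
#' @export
make_loop_design <- function(groups, plex = 12, n_transcripts = 100,
                             duplicate_spots = 2, n_blocks = 4) {
  counts <- unlist(groups)
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    names(counts) <- paste0("g", seq_along(counts))
  total <- sum(counts)
  if (total > 2 * plex)
    stop("total samples (", total, ") exceed channel capacity 2 * plex = ",
         2 * plex)
  # dye swap first: within each group, odd sample indices get Cy3 and even
  # get Cy5 (so even group sizes split exactly in half); then the Cy3 and
  # Cy5 channel lists are dealt round-robin over groups -- with the group
  # order rotated by one for Cy5 -- and paired index-by-index onto arrays,
  # so the two channels of an array come from different groups and array
  # effects are not confounded with treatment
  gnames <- names(counts)
  deal <- function(per_group) {
    # per_group: named list of sample ids; interleave one per group in turn
    out <- character(0)
    while (any(lengths(per_group) > 0)) {
      for (g in names(per_group)) {
        if (length(per_group[[g]])) {
          out <- c(out, per_group[[g]][1])
          per_group[[g]] <- per_group[[g]][-1]
        }
      }
    }
    out
  }
  ids <- lapply(gnames, function(g) sprintf("%s_%02d", g, seq_len(counts[[g]])))
  names(ids) <- gnames
  cy3 <- deal(lapply(ids, function(s) s[seq_along(s) %% 2 == 1L]))
  rot <- c(gnames[-1], gnames[1])
  cy5 <- deal(lapply(stats::setNames(rot, rot),
                     function(g) ids[[g]][seq_along(ids[[g]]) %% 2 == 0L]))
  n_arr <- max(length(cy3), length(cy5))
  channels <- data.frame(
    array = sprintf("A%02d", c(seq_along(cy3), seq_along(cy5))),
    dye = rep(c("Cy3", "Cy5"), c(length(cy3), length(cy5))),
    sample = c(cy3, cy5), stringsAsFactors = FALSE)
  grp_of <- stats::setNames(rep(gnames, lengths(ids)), unlist(ids))
  channels$group <- unname(grp_of[channels$sample])

  tr <- sprintf("t%04d", seq_len(n_transcripts))
  spots <- data.frame(
    transcript = rep(tr, each = duplicate_spots),
    duplicate = rep(seq_len(duplicate_spots), times = n_transcripts),
    stringsAsFactors = FALSE)
  spots$spot <- paste0(spots$transcript, "_s", spots$duplicate)
  spots$block <- sprintf("B%d", ((seq_len(nrow(spots)) - 1L) %% n_blocks) + 1L)
  array_design(channels, spots[, c("spot", "transcript", "duplicate", "block")])
}

#' Parameters of a synthetic loop-design experiment
#'
#' Bundles the generating parameters for [generate_experiment()]. The
#' defaults describe a 3-group, 8-samples-per-group experiment on a 12-plex
#' slide (24 sample-channels) with transcripts printed in duplicate, a dye
#' offset of 1 log2 unit on Cy5, array / array-by-dye / array-by-block
#' random standard deviations of 0.5 / 0.3 / 0.2 log2 units, residual SD
#' 0.2, and 10% of transcripts carrying group effects drawn from
#' N(0, 1 log2 unit) per non-reference group.
#'
#' @param n_transcripts number of transcripts on the platform.
#' @param duplicate_spots spots printed per transcript.
#' @param groups named vector of samples per group.
#' @param fraction_de fraction of transcripts given a treatment effect.
#' @param treatment_effect_sd SD (log2 units) of per-group effects for DE
#'   transcripts.
#' @param dye_effect fixed log2 offset added to Cy5 channels.
#' @param block_effects numeric vector of fixed log2 offsets, one per print
#'   block (its length sets the number of blocks).
#' @param sd_array,sd_array_dye,sd_array_block SDs of the array,
#'   array-by-dye and array-by-block random effects (log2 units), shared by
#'   all transcripts (the components the global normalization model
#'   removes).
#' @param sd_transcript_array SD of per-(transcript, array) random effects
#'   (log2 units), shared by a transcript's duplicate spots and both dyes on
#'   an array: the within-gene array correlation that the per-transcript
#'   model's random array term captures.
#' @param sd_residual residual SD (log2 units).
#' @param baseline_mean grand mean log2 intensity.
#' @param transcript_sd SD of per-transcript baseline offsets.
#' @param missing_rate fraction of cells set missing at random.
#' @param plex sub-arrays per slide.
#' @param seed integer seed; [generate_experiment()] is bit-reproducible
#'   given the spec.
#' @return list of class `effect_spec`.
#' @export
effect_spec <- function(n_transcripts = 500, duplicate_spots = 2,
                        groups = c(haplo = 8, win = 8, los = 8),
                        fraction_de = 0.1, treatment_effect_sd = 1.0,
                        dye_effect = 1.0,
                        block_effects = c(0.25, -0.25, 0.1, -0.1),
                        sd_array = 0.5, sd_array_dye = 0.3,
                        sd_array_block = 0.2, sd_transcript_array = 0.1,
                        sd_residual = 0.25,
                        baseline_mean = 10, transcript_sd = 0.5,
                        missing_rate = 0, plex = 12, seed = 1) {
  stopifnot(fraction_de >= 0, fraction_de <= 1,
            missing_rate >= 0, missing_rate < 1,
            sd_array >= 0, sd_array_dye >= 0, sd_array_block >= 0,
            sd_transcript_array >= 0,
            sd_residual >= 0, treatment_effect_sd >= 0,
            n_transcripts >= 1, duplicate_spots >= 1)
  structure(as.list(environment()), class = "effect_spec")
}

#' Generate a synthetic loop-design two-channel experiment
#'
#' Simulates raw intensities under the same two-stage model the pipeline
#' fits: on the log2 scale, signal = baseline + transcript offset +
#' treatment effect (DE transcripts, per non-reference group) + dye offset +
#' block offset + array + array-by-dye + array-by-block Gaussian random
#' effects (global, removed by normalization) + per-(transcript, array)
#' Gaussian effects (the within-gene array correlation the per-transcript
#' model absorbs) + Gaussian residual; raw intensity = 2^signal. Missing
#' cells are injected completely at random. Fully deterministic given
#' `spec$seed`.
#'
#' @param spec an [effect_spec()].
#' @return list: `intensities` (long data frame `spot`, `array`, `dye`,
#'   `intensity`), `design` (the [array_design]), `truth` (class
#'   `synthetic_truth`: `de_transcripts`, `effects` matrix (DE transcripts x
#'   non-reference groups), `reference_group`, realized random effects
#'   `array_effects`, `array_dye_effects`, `array_block_effects`, and the
#'   `spec`).
#' @export
generate_experiment <- function(spec) {
  stopifnot(inherits(spec, "effect_spec"))
  set.seed(spec$seed)
  n_blocks <- length(spec$block_effects)
  design <- make_loop_design(spec$groups, plex = spec$plex,
                             n_transcripts = spec$n_transcripts,
                             duplicate_spots = spec$duplicate_spots,
                             n_blocks = n_blocks)
  ch <- design$channels
  sp <- design$spots
  tr <- unique(sp$transcript)
  arrays <- unique(ch$array)
  blocks <- sprintf("B%d", seq_len(n_blocks))
  groups <- unique(ch$group)
  ref <- groups[1]

  n_de <- round(spec$fraction_de * spec$n_transcripts)
  de <- sort(sample(tr, n_de))
  eff <- matrix(0, nrow = n_de, ncol = length(groups) - 1L,
                dimnames = list(de, groups[-1]))
  if (n_de > 0 && length(groups) > 1L)
    eff[] <- stats::rnorm(length(eff), 0, spec$treatment_effect_sd)

  t_off <- stats::setNames(stats::rnorm(length(tr), 0, spec$transcript_sd), tr)
  a_eff <- stats::setNames(stats::rnorm(length(arrays), 0, spec$sd_array),
                           arrays)
  ad_key <- paste(rep(arrays, each = 2), c("Cy3", "Cy5"))
  ad_eff <- stats::setNames(stats::rnorm(length(ad_key), 0, spec$sd_array_dye),
                            ad_key)
  ab_key <- paste(rep(arrays, each = n_blocks), rep(blocks, length(arrays)))
  ab_eff <- stats::setNames(stats::rnorm(length(ab_key), 0,
                                         spec$sd_array_block), ab_key)
  ta_eff <- matrix(stats::rnorm(length(tr) * length(arrays), 0,
                                spec$sd_transcript_array),
                   nrow = length(tr), dimnames = list(tr, arrays))
  blk_eff <- stats::setNames(spec$block_effects, blocks)

  grid <- intensity_grid(design)
  g_tr <- sp$transcript[match(grid$spot, sp$spot)]
  g_blk <- sp$block[match(grid$spot, sp$spot)]
  g_grp <- ch$group[match(paste(grid$array, grid$dye),
                          paste(ch$array, ch$dye))]
  treat <- numeric(nrow(grid))
  hit <- g_tr %in% de & g_grp != ref
  if (any(hit)) treat[hit] <- eff[cbind(g_tr[hit], g_grp[hit])]

  signal <- spec$baseline_mean + t_off[g_tr] + treat +
    ifelse(grid$dye == "Cy5", spec$dye_effect, 0) +
    blk_eff[g_blk] + a_eff[grid$array] +
    ad_eff[paste(grid$array, grid$dye)] +
    ab_eff[paste(grid$array, g_blk)] +
    ta_eff[cbind(g_tr, grid$array)] +
    stats::rnorm(nrow(grid), 0, spec$sd_residual)
  grid$intensity <- 2^unname(signal)
  if (spec$missing_rate > 0) {
    miss <- stats::runif(nrow(grid)) < spec$missing_rate
    grid$intensity[miss] <- NA_real_
  }
  truth <- structure(list(de_transcripts = de, effects = eff,
                          reference_group = ref,
                          transcript_offsets = t_off,
                          array_effects = a_eff,
                          array_dye_effects = ad_eff,
                          array_block_effects = ab_eff,
                          spec = spec),
                     class = "synthetic_truth")
  list(intensities = grid, design = design, truth = truth)
}

#' Generate a random annotation with one planted enriched term
#'
#' Builds a random gene-to-term incidence over `n_genes` genes and
#' `n_terms` terms plus a small ancestor slim map, and draws a "significant"
#' gene set in which members of the planted term are over-sampled at odds
#' `enrichment_strength` (strength 1 = no planted signal).
#'
#' @param n_genes,n_terms universe and term counts.
#' @param planted_term index (1-based) of the term to enrich.
#' @param enrichment_strength sampling odds multiplier for the planted
#'   term's genes.
#' @param n_significant size of the drawn significant set.
#' @param term_size_range inclusive range of genes per term.
#' @param n_ancestors ancestors in the slim map (terms are dealt to them
#'   round-robin).
#' @param seed integer seed.
#' @return list: `annotation` (an [annotation_map]), `truth` (list with
#'   `significant_genes`, `planted_term`).
#' @export
generate_annotation <- function(n_genes = 1000, n_terms = 20,
                                planted_term = 1, enrichment_strength = 5,
                                n_significant = 100,
                                term_size_range = c(30, 80),
                                n_ancestors = 5, seed = 1) {
  stopifnot(n_terms >= 1, enrichment_strength >= 1)
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  terms <- sprintf("T%03d", seq_len(n_terms))
  g2t <- do.call(rbind, lapply(terms, function(tm) {
    size <- sample(seq(term_size_range[1], term_size_range[2]), 1)
    data.frame(gene = sample(genes, size), term = tm,
               stringsAsFactors = FALSE)
  }))
  ancestors <- sprintf("ANC%02d", seq_len(n_ancestors))
  slim <- data.frame(term = terms,
                     ancestor = rep(ancestors, length.out = n_terms),
                     stringsAsFactors = FALSE)
  planted <- terms[planted_term]
  in_planted <- genes %in% g2t$gene[g2t$term == planted]
  w <- ifelse(in_planted, enrichment_strength, 1)
  sig <- sample(genes, n_significant, prob = w / sum(w))
  list(annotation = annotation_map(g2t, slim, genes),
       truth = list(significant_genes = sig, planted_term = planted))
}
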