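test_that("noise-free dye structure is removed exactly", {
  des <- make_loop_design(c(g1 = 4, g2 = 4), plex = 4, n_transcripts = 100,
                          duplicate_spots = 1, n_blocks = 2)
  expr <- full_intensities(des, 1)
  expr$value <- ifelse(expr$dye == "Cy5", 1, -1)
  expr$intensity <- NULL
  fit <- fit_normalization(expr, des)
  expect_lt(max(abs(fit$residuals$residual)), 1e-8)
  expect_equal(fit$dye_contrast, 2, tolerance = 1e-8)
  # per-dye residual means vanish
  for (d in c("Cy3", "Cy5"))
    expect_lt(abs(mean(fit$residuals$residual[fit$residuals$dye == d])), 1e-6)
})

test_that("the collapsed-cell REML engine matches lme4 on simulated data", {
  sim <- generate_experiment(effect_spec(n_transcripts = 120, seed = 21,
                                         missing_rate = 0.03))
  expr <- log2_transform(filter_spots(sim$intensities, sim$design)$intensities)
  fc <- fit_normalization(expr, sim$design, engine = "cells")
  fl <- fit_normalization(expr, sim$design, engine = "lmer")
  expect_equal(fc$fixed, fl$fixed, tolerance = 1e-5)
  expect_equal(fc$varcomp, fl$varcomp, tolerance = 1e-3)
  expect_equal(fc$logLik, fl$logLik, tolerance = 1e-6)
  expect_lt(max(abs(fc$residuals$residual - fl$residuals$residual)), 1e-4)
})

test_that("single-dye or all-missing input is a design error", {
  des <- tiny_design(n_arrays = 2)
  expr <- full_intensities(des, 1000)
  expr$value <- log2(expr$intensity)
  expect_error(fit_normalization(expr[expr$dye == "Cy3", ], des),
               "both dyes")
  expr$value <- NA_real_
  expect_error(fit_normalization(expr, des), "missing")
})

test_that("array variance components vanish under pure noise", {
  vcs <- t(vapply(1:10, function(s) {
    sim <- generate_experiment(effect_spec(
      n_transcripts = 150, duplicate_spots = 1, fraction_de = 0,
      dye_effect = 0, block_effects = rep(0, 4), sd_array = 0,
      sd_array_dye = 0, sd_array_block = 0, sd_transcript_array = 0,
      sd_residual = 0.2, transcript_sd = 0, seed = 300 + s))
    expr <- log2_transform(sim$intensities)
    fit_normalization(expr, sim$design)$varcomp
  }, numeric(4)))
  resid_var <- 0.2^2
  for (term in c("array", "array_dye", "array_block"))
    expect_lt(mean(vcs[, term]), 0.05 * resid_var)
  expect_equal(mean(vcs[, "residual"]), resid_var, tolerance = 0.05)
})

test_that("variance components and dye effect are recovered (quick check)", {
  est <- t(vapply(1:5, function(s) {
    sim <- generate_experiment(effect_spec(
      n_transcripts = 500, duplicate_spots = 1, fraction_de = 0,
      sd_array = 0.5, sd_array_dye = 0.3, sd_array_block = 0,
      sd_transcript_array = 0, sd_residual = 0.2, dye_effect = 1,
      transcript_sd = 0, seed = 400 + s))
    expr <- log2_transform(sim$intensities)
    fit <- fit_normalization(expr, sim$design)
    c(dye = fit$dye_contrast, fit$varcomp[c("array", "array_dye",
                                            "residual")])
  }, numeric(4)))
  med <- apply(est, 2, median)
  expect_equal(med[["dye"]], 1, tolerance = 0.15)
  expect_equal(med[["array"]], 0.25, tolerance = 0.5)
  expect_equal(med[["array_dye"]], 0.09, tolerance = 0.5)
  expect_equal(med[["residual"]], 0.04, tolerance = 0.2)
})

test_that("a noise-free gene recovers group means exactly", {
  des <- make_loop_design(c(g1 = 8, g2 = 8, g3 = 8), n_transcripts = 1,
                          duplicate_spots = 2)
  ch <- des$channels
  d <- data.frame(spot = rep(des$spots$spot, each = 24),
                  array = rep(ch$array, 2), dye = rep(ch$dye, 2))
  grp <- ch$group[match(paste(d$array, d$dye), paste(ch$array, ch$dye))]
  d$residual <- c(g1 = 0, g2 = 1, g3 = 2)[grp]
  fit <- fit_gene(d, des)
  expect_equal(fit$contrasts$estimate, c(1, 2, 1), tolerance = 1e-10)
  expect_lt(fit$p, 1e-100)
  expect_equal(unname(fit$group_means["g2"] - fit$group_means["g1"]), 1,
               tolerance = 1e-10)
})

test_that("gene fits agree with the mixed-model reference implementation", {
  library(lmerTest)
  des <- make_loop_design(c(g1 = 8, g2 = 8, g3 = 8), n_transcripts = 1,
                          duplicate_spots = 2)
  set.seed(77)
  for (i in 1:6) {
    d <- simulate_gene_data(des, group_effects = c(g1 = 0, g2 = 0.3,
                                                   g3 = -0.2),
                            sd_array = 0.15, sd_resid = 0.2)
    if (i > 3) d$residual[sample(nrow(d), 6)] <- NA
    dd <- d[!is.na(d$residual), ]
    sp <- des$spots; ch <- des$channels
    dd$dup <- factor(sp$duplicate[match(dd$spot, sp$spot)])
    dd$group <- factor(ch$group[match(paste(dd$array, dd$dye),
                                      paste(ch$array, ch$dye))])
    ref <- lmerTest::lmer(
      residual ~ group + dup + dye + (1 | array), data = dd,
      control = lme4::lmerControl(check.conv.singular = "ignore"))
    a <- suppressMessages(anova(ref, ddf = "Satterthwaite"))
    mine <- fit_gene(d, des, df_method = "satterthwaite")
    expect_equal(mine$F, a["group", "F value"], tolerance = 1e-5)
    expect_equal(mine$df2, a["group", "DenDF"], tolerance = 1e-3)
    expect_equal(mine$p, a["group", "Pr(>F)"], tolerance = 1e-5)
    expect_equal(unname(mine$varcomp["array"]),
                 as.data.frame(lme4::VarCorr(ref))$vcov[1],
                 tolerance = 1e-4)
  }
})

test_that("pairwise contrasts match emmeans with Satterthwaite df", {
  library(lmerTest)
  library(emmeans)
  des <- make_loop_design(c(g1 = 8, g2 = 8, g3 = 8), n_transcripts = 1,
                          duplicate_spots = 2)
  set.seed(88)
  d <- simulate_gene_data(des, group_effects = c(g1 = 0, g2 = 0.5, g3 = 1),
                          sd_array = 0.2, sd_resid = 0.25)
  sp <- des$spots; ch <- des$channels
  dd <- d
  dd$dup <- factor(sp$duplicate[match(dd$spot, sp$spot)])
  dd$group <- factor(ch$group[match(paste(dd$array, dd$dye),
                                    paste(ch$array, ch$dye))])
  ref <- lmerTest::lmer(residual ~ group + dup + dye + (1 | array),
                        data = dd)
  em <- as.data.frame(pairs(emmeans(ref, "group", lmer.df = "satterthwaite"),
                            adjust = "none"))
  mine <- fit_gene(d, des, df_method = "satterthwaite")
  # emmeans reports group1 - group2; ours is group2 - group1
  expect_equal(mine$contrasts$estimate, -em$estimate, tolerance = 1e-6)
  expect_equal(mine$contrasts$se, em$SE, tolerance = 1e-6)
  expect_equal(mine$contrasts$df, em$df, tolerance = 1e-3)
  expect_equal(mine$contrasts$p, em$p.value, tolerance = 1e-5)
})

test_that("the Kenward-Roger adjustment matches the reference implementation", {
  library(lmerTest)
  library(pbkrtest)
  des <- make_loop_design(c(g1 = 8, g2 = 8, g3 = 8), n_transcripts = 1,
                          duplicate_spots = 2)
  set.seed(555)
  for (i in 1:5) {
    d <- simulate_gene_data(des, group_effects = c(g1 = 0, g2 = 0.3,
                                                   g3 = -0.1),
                            sd_array = 0.15, sd_resid = 0.2)
    dd <- d
    sp <- des$spots; ch <- des$channels
    dd$dup <- factor(sp$duplicate[match(dd$spot, sp$spot)])
    dd$group <- factor(ch$group[match(paste(dd$array, dd$dye),
                                      paste(ch$array, ch$dye))])
    big <- lme4::lmer(residual ~ group + dup + dye + (1 | array), data = dd,
                      control = lme4::lmerControl(
                        check.conv.singular = "ignore"))
    small <- lme4::lmer(residual ~ dup + dye + (1 | array), data = dd,
                        control = lme4::lmerControl(
                          check.conv.singular = "ignore"))
    ref <- pbkrtest::KRmodcomp(big, small)$stats
    mine <- fit_gene(d, des, df_method = "kenward-roger")
    expect_equal(mine$F, ref$Fstat, tolerance = 1e-3)
    expect_equal(mine$df2, ref$ddf, tolerance = 1e-2)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-3)
  }
})

test_that("degenerate gene designs are skipped with a reason, not an error", {
  des <- make_loop_design(c(g1 = 8, g2 = 8), n_transcripts = 1,
                          duplicate_spots = 1)
  d <- simulate_gene_data(des)
  ch <- des$channels
  grp <- ch$group[match(paste(d$array, d$dye), paste(ch$array, ch$dye))]
  d$residual[grp == "g2"] <- NA
  fit <- fit_gene(d, des)
  expect_s3_class(fit, "gene_fit")
  expect_false(is.na(fit$skip_reason))
  expect_true(is.na(fit$p))
})

test_that("null p-values are approximately uniform under the gene model", {
  des <- make_loop_design(c(g1 = 8, g2 = 8, g3 = 8), n_transcripts = 1,
                          duplicate_spots = 2)
  set.seed(4242)
  cache <- new.env(parent = emptyenv())
  ps <- replicate(2000, {
    d <- simulate_gene_data(des, sd_array = 0.1, sd_resid = 0.2)
    fit_gene(d, des, .cache = cache)$p
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("BH adjustment matches the hand-computed step-up examples", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(9)
  p <- stats::runif(200)
  perm <- sample(200)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-14)
})

test_that("run_de declares planted genes and is deterministic", {
  sim <- generate_experiment(effect_spec(n_transcripts = 150,
                                         treatment_effect_sd = 2, seed = 31))
  expr <- log2_transform(filter_spots(sim$intensities, sim$design)$intensities)
  de1 <- run_de(expr, sim$design, q_threshold = 0.01)
  de2 <- run_de(expr, sim$design, q_threshold = 0.01)
  expect_identical(de1$table, de2$table)
  expect_gt(length(de1$significant), 0)
  expect_true(all(de1$significant %in% sim$truth$de_transcripts))
  expect_true(all(de1$significant %in% de1$table$transcript))
  # pairwise families are adjusted separately and feed the union option
  deu <- run_de(expr, sim$design, q_threshold = 0.01,
                de_set = "union-pairwise")
  expect_setequal(deu$significant,
                  unique(unlist(deu$significant_pairwise)))
  expect_error(run_de(expr, sim$design, q_threshold = 1.5), "\\(0, 1\\)")
})

test_that("stronger planted effects are detected at least as often", {
  hits <- vapply(c(0.5, 1, 2), function(es) {
    sim <- generate_experiment(effect_spec(n_transcripts = 120,
                                           treatment_effect_sd = es,
                                           baseline_mean = 13,
                                           seed = 55))
    expr <- log2_transform(filter_spots(sim$intensities,
                                        sim$design)$intensities)
    de <- run_de(expr, sim$design, q_threshold = 0.05)
    sum(de$significant %in% sim$truth$de_transcripts)
  }, numeric(1))
  expect_true(all(diff(hits) >= 0))
})
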