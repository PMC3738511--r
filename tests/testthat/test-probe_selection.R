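test_that("ratios are computed against the transcript median", {
  expect_equal(compute_ratios(c(100, 200, 400)), c(0.5, 1, 2))
  expect_equal(compute_ratios(c(5, 5, 5, 5)), rep(1, 4))
  expect_equal(compute_ratios(c(10, 10, 10, 10, 10, 10, 100)),
               c(rep(1, 6), 10))
  # even count: median is the mean of the central order statistics
  expect_equal(compute_ratios(c(1, 2, 3, 4)), c(1, 2, 3, 4) / 2.5)
  expect_error(compute_ratios(numeric(0)), "at least one")
  expect_error(compute_ratios(c(0, 0, 0)), "degenerate")
})

test_that("candidate counts route to the documented rules", {
  cand <- function(green, red = green) {
    data.frame(transcript = "t", probe = paste0("p", seq_along(green)),
               green = green, red = red)
  }
  two <- select_probe(cand(c(100, 200)))
  expect_equal(two$rule, "pair_max")
  expect_equal(two$probe, "p2")
  # order invariance for the pair rule
  rev2 <- select_probe(cand(c(200, 100)))
  expect_equal(rev2$probe, "p1")

  four <- select_probe(cand(c(100, 200, 300, 2000)))
  expect_equal(four$rule, "ratio_3to6")
  # median 250, ratios (0.4, 0.8, 1.2, 8): top ratio >= 3, take second highest
  expect_equal(four$probe, "p3")

  seven <- select_probe(cand(c(10, 10, 10, 10, 10, 10, 100)))
  expect_equal(seven$rule, "ratio_7_with_removal")
  expect_equal(seven$removed_probe, "p7")
  # recomputed ratios all tie at 1: lowest input index wins
  expect_equal(seven$probe, "p1")

  one <- select_probe(cand(400))
  expect_equal(one$rule, "single")
  expect_length(one$qc_flags, 0)
  low <- select_probe(data.frame(transcript = "t", probe = "p1",
                                 green = 400, red = 120))
  expect_equal(low$qc_flags, "single_probe_low_intensity")

  empty <- data.frame(transcript = character(0), probe = character(0),
                      green = numeric(0), red = numeric(0))
  expect_error(select_probe(empty), "no candidate")
  expect_error(select_probe(cand(1:8)), "more than 7")
})

test_that("a ratio exactly at the cutoff is kept in both regimes", {
  # 3-6 case: acceptance requires ratio < 3 strictly
  cand4 <- data.frame(transcript = "t", probe = paste0("p", 1:4),
                      green = c(100, 100, 100, 300), red = 100)
  # median 100, top ratio exactly 3: not accepted, pick second highest
  out <- select_probe(cand4)
  expect_equal(out$probe, "p1")
  # 7 case: removal requires ratio > 3 strictly; exactly 3 stays
  cand7 <- data.frame(transcript = "t", probe = paste0("p", 1:7),
                      green = c(rep(100, 6), 300), red = 100)
  out7 <- select_probe(cand7)
  expect_equal(out7$probe, "p7")
  expect_true(is.na(out7$removed_probe))
})

test_that("the choice is scale-free for ratio-based rules", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(3:7, 1)
    g <- stats::runif(n, 50, 5000)
    cand <- data.frame(transcript = "t", probe = paste0("p", 1:n),
                       green = g, red = g)
    scaled <- cand
    scaled$green <- scaled$green * 7.3
    expect_equal(select_probe(cand)$probe, select_probe(scaled)$probe)
  }
})

test_that("platform selection routes cases and matches the rule oracle", {
  pilot <- rbind(
    data.frame(transcript = "tA", probe = "pA1", green = 500, red = 500,
               category = "EWGM"),
    data.frame(transcript = "tB", probe = c("pB1", "pB2"),
               green = c(100, 200), red = 100, category = "EWOGM"),
    data.frame(transcript = "tC", probe = paste0("pC", 1:7),
               green = c(10, 10, 10, 10, 10, 10, 100), red = 10,
               category = "GM"))
  sel <- select_platform(pilot)
  expect_equal(nrow(sel$choices), 3)
  expect_setequal(sel$choices$rule,
                  c("single", "pair_max", "ratio_7_with_removal"))
  expect_equal(as.vector(sel$category_counts[c("EWGM", "EWOGM", "GM")]),
               c(1, 1, 1))

  empty <- select_platform(pilot[0, ])
  expect_equal(nrow(empty$choices), 0)

  set.seed(101)
  for (i in 1:200) {
    n <- sample(1:7, 1)
    g <- stats::runif(n, 10, 5000)
    cand <- data.frame(transcript = "t", probe = paste0("p", 1:n),
                       green = g, red = g)
    expect_equal(select_probe(cand)$probe,
                 paste0("p", oracle_select_probe(g, g)))
  }
})
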