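test_that("a single planted factor captures the leading component", {
  set.seed(61)
  n <- 20
  env <- rep(c("single", "paired"), each = n / 2)
  shift <- stats::rnorm(50, 0, 2)
  mat <- outer(as.numeric(env == "paired"), shift) +
    matrix(stats::rnorm(n * 50, 0, 0.05), n)
  pp <- pca_partition(mat, data.frame(environment = env))
  expect_gte(pp$pct_variance[1], 99)
  expect_equal(unname(pp$assigned_factor[1]), "environment")
  # permuting samples permutes scores but not the variance shares
  perm <- sample(n)
  pp2 <- pca_partition(mat[perm, ], data.frame(environment = env[perm]))
  expect_equal(pp2$pct_variance, pp$pct_variance, tolerance = 1e-10)
  expect_error(pca_partition(mat[1, , drop = FALSE],
                             data.frame(environment = "a")), "at least 2")
})

test_that("k-means recovers planted blocks and handles degeneracy", {
  set.seed(62)
  up <- matrix(stats::rnorm(40 * 20, 0, 0.2), 40, 20) +
    matrix(rep(c(2, -2), each = 10), 40, 20, byrow = TRUE)
  dn <- -up[1:30, ] + matrix(stats::rnorm(30 * 20, 0, 0.2), 30, 20)
  mat <- rbind(up, dn)
  rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  km <- kmeans_clusters(mat, k = 2, seed = 99)
  truth <- rep(1:2, c(40, 30))
  expect_equal(adjusted_rand_index(km$assignments, truth), 1)
  km2 <- kmeans_clusters(mat, k = 2, seed = 99)
  expect_identical(km$assignments, km2$assignments)

  same <- matrix(1, 5, 4)
  deg <- kmeans_clusters(same, k = 2, seed = 1)
  expect_true(deg$degenerate)
  expect_true(all(deg$assignments == 1))
  expect_error(kmeans_clusters(mat, k = 2000, seed = 1), "exceeds")
})

test_that("Ward clustering merges by minimum variance increase", {
  mat <- rbind(c(0, 0), c(0, 0), c(5, 5), c(9, 9))
  tree <- ward_tree(mat)
  expect_equal(sort(abs(tree$merge[1, ])), c(1, 2))  # duplicates first
  # 3 colinear points: the brute-force Ward criterion fixes the first merge
  mat3 <- cbind(c(0, 1, 10), 0)
  tree3 <- ward_tree(mat3)
  expect_equal(sort(abs(tree3$merge[1, ])), oracle_ward_merges(mat3)[[1]])
  # heights are invariant to row permutation
  set.seed(63)
  m <- matrix(stats::rnorm(60), 12)
  expect_equal(sort(ward_tree(m)$height),
               sort(ward_tree(m[sample(12), ])$height), tolerance = 1e-10)
  expect_error(ward_tree(rbind(c(1, NaN), c(0, 0))), "non-finite")
})

test_that("venn regions are disjoint, complete, and match enumeration", {
  v <- venn_counts(list(A = c("1", "2", "3"), B = c("2", "3", "4")))
  expect_equal(unname(v[c("A", "B", "A&B")]), c(1, 1, 2))
  expect_equal(sum(v), 4)
  d <- venn_counts(list(A = c("1", "2"), B = c("3", "4")))
  expect_equal(unname(d["A&B"]), 0)
  set.seed(64)
  for (i in 1:20) {
    sets <- lapply(1:3, function(j) sample(as.character(1:30),
                                           sample(0:20, 1)))
    names(sets) <- c("X", "Y", "Z")
    v3 <- venn_counts(sets)
    expect_equal(sum(v3), length(unique(unlist(sets))))
    # brute-force membership enumeration
    u <- unique(unlist(sets))
    pat <- vapply(u, function(e) paste(names(sets)[vapply(sets, function(s)
      e %in% s, logical(1))], collapse = "&"), character(1))
    for (reg in names(v3))
      expect_equal(unname(v3[reg]), sum(pat == reg))
  }
})

test_that("overlap statistics reproduce exact enumeration on small cases", {
  ov <- hypergeom_overlap(2, 2, 2, 4)
  expect_equal(ov$representation_factor, 2)
  expect_equal(ov$p, 1 / 6, tolerance = 1e-14)
  # RF is 1 exactly at the independence expectation
  ov1 <- hypergeom_overlap(10, 20, 4, 50)
  expect_equal(ov1$representation_factor, 1)
  expect_error(hypergeom_overlap(10, 20, 15, 50), "overlap")
  expect_error(hypergeom_overlap(60, 20, 5, 50), "universe")
  set.seed(65)
  for (i in 1:50) {
    N <- sample(5:60, 1)
    n1 <- sample(N, 1); n2 <- sample(N, 1)
    ks <- max(0, n1 + n2 - N):min(n1, n2)
    k <- ks[sample.int(length(ks), 1)]
    expect_equal(hypergeom_overlap(n1, n2, k, N)$p,
                 oracle_hyper_tail(k, n1, n2, N), tolerance = 1e-12)
  }
})

test_that("the equal-proportion test reports both G and Pearson forms", {
  eq <- proportion_test(10, 10)
  expect_equal(eq$G, 0)
  expect_equal(eq$p_G, 1)
  pt <- proportion_test(404, 477)
  expect_equal(pt$G, 6.0557, tolerance = 1e-4)
  expect_equal(pt$chisq_pearson, (404 - 477)^2 / 881, tolerance = 1e-12)
  expect_lt(pt$p_G, 0.05)
  z <- proportion_test(0, 20)
  expect_equal(z$chisq_pearson, 20)
  expect_error(proportion_test(0, 0), "both counts")
})

test_that("Fisher's exact test matches brute-force table enumeration", {
  expect_equal(fisher_exact(rbind(c(1, 9), c(9, 1))), 0.0011, tolerance = 0.02)
  expect_equal(fisher_exact(rbind(c(5, 5), c(5, 5))), 1)
  set.seed(66)
  for (i in 1:40) {
    tab <- matrix(sample(0:15, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact(tab), oracle_fisher(tab), tolerance = 1e-9)
  }
})

test_that("term enrichment reproduces the exact hypergeometric tail", {
  genes <- sprintf("g%02d", 1:20)
  g2t <- data.frame(gene = genes[1:5], term = "T1")
  ann <- annotation_map(g2t, data.frame(term = "T1", ancestor = "M"), genes)
  res <- enrich_terms(genes[c(1, 2, 3, 10, 11)], ann, genes)
  expect_equal(res$p[res$term == "T1"], 1126 / 15504, tolerance = 1e-12)
  # no hits: p = P(X >= 0) = 1
  res0 <- enrich_terms(genes[10:14], ann, genes)
  expect_equal(res0$p[res0$term == "T1"], 1)
  # EASE shifts one observed hit away: a single hit becomes p = 1
  res1 <- enrich_terms(genes[c(1, 10, 11, 12, 13)], ann, genes, ease = TRUE)
  expect_equal(res1$p[res1$term == "T1"], 1)
  expect_error(enrich_terms(genes[1], ann, character(0)), "non-empty")
  expect_error(enrich_terms("alien", ann, genes), "subset")
})

test_that("ancestor mapping uses single-count list semantics", {
  slim <- data.frame(term = c("t1", "t2", "t2"),
                     ancestor = c("M", "M", "D"))
  ac <- map_to_ancestors(c("t1", "t2"), slim)
  expect_equal(ac$counts[["M"]], 2)
  expect_equal(ac$counts[["D"]], 1)
  expect_equal(ac$n_assigned, 2)
  expect_equal(ac$unassigned, 0)
  ac2 <- map_to_ancestors(c("t1", "t9"), slim)
  expect_equal(ac2$unassigned, 1)
  ac3 <- map_to_ancestors(c("t1", "t1"), slim)
  expect_equal(ac3$counts[["M"]], 2)  # duplicates count twice
})

test_that("qPCR normalization and the rank test match hand computation", {
  hk <- rbind(c(4, 9), c(4, 9))
  rel <- qpcr_relative(c(6, 12), hk, group = c("ref", "trt"),
                       reference = "ref")
  expect_equal(unname(rel), c(1, 2))
  expect_error(qpcr_relative(c(6, 12), rbind(c(0, 9), c(4, 9)),
                             c("ref", "trt"), "ref"), "positive")
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(round(kw$H, 3), 3.857)
  same <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$H, 0)
  # invariance under strictly monotone transforms
  x <- list(stats::rexp(8), stats::rexp(8) + 0.3)
  expect_equal(kruskal_wallis(x)$H,
               kruskal_wallis(lapply(x, function(v) exp(v)))$H,
               tolerance = 1e-12)
})
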