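#' PCA variance partition over a gene set
#'
#' Principal component analysis with samples as observations and genes as
#' variables (mean-centered, covariance scale), reporting the percentage of
#' total variance carried by each component and associating each retained
#' component with the design factor whose levels explain its scores best
#' (largest R-squared of a one-way regression of the scores on the factor).
#'
#' @param mat numeric matrix, samples in rows, genes in columns.
#' @param factors data frame of design factors (one row per sample).
#' @param n_components number of components to retain for the association
#'   table (default `min(nrow - 1, 5)`).
#' @return object of class `pca_partition`: `pct_variance` (all components,
#'   % of total), `scores`, `r_squared` (retained components x factors),
#'   `assigned_factor` (named character vector).
#' @export
pca_partition <- function(mat, factors, n_components = NULL) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("need at least 2 samples (rows)")
  factors <- as.data.frame(factors, stringsAsFactors = FALSE)
  stopifnot(nrow(factors) == nrow(mat))
  for (f in names(factors)) {
    lv <- table(factors[[f]])
    if (any(lv < 2L))
      stop("factor ", f, " has a level with fewer than 2 samples")
  }
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  vars <- pc$sdev^2
  pct <- 100 * vars / sum(vars)
  k <- if (is.null(n_components)) min(nrow(mat) - 1L, 5L) else n_components
  k <- min(k, ncol(pc$x))
  r2 <- matrix(NA_real_, k, ncol(factors),
               dimnames = list(colnames(pc$x)[seq_len(k)], names(factors)))
  for (i in seq_len(k)) {
    for (j in seq_along(factors)) {
      fit <- stats::lm(pc$x[, i] ~ factor(factors[[j]]))
      r2[i, j] <- summary(fit)$r.squared
    }
  }
  assigned <- apply(r2, 1, function(r) names(factors)[which.max(r)])
  structure(list(pct_variance = pct, scores = pc$x, r_squared = r2,
                 assigned_factor = assigned),
            class = "pca_partition")
}

#' @export
print.pca_partition <- function(x, ...) {
  k <- nrow(x$r_squared)
  for (i in seq_len(k))
    cat(sprintf("  PC%d: %.1f%% of variance, associated with %s (R2 = %.3f)\n",
                i, x$pct_variance[i], x$assigned_factor[i],
                max(x$r_squared[i, ])))
  invisible(x)
}

#' K-means clustering of expression profiles
#'
#' Euclidean k-means on row-standardized profiles (each gene centered and
#' scaled to unit standard deviation; constant rows are mapped to zero).
#' Deterministic given `seed`.
#'
#' @param mat numeric matrix, genes in rows.
#' @param k number of clusters (default 2).
#' @param seed integer seed (required: k-means restarts are stochastic).
#' @param nstart random restarts (default 10).
#' @param standardize row-standardize before clustering (default `TRUE`).
#' @return list of class `kmeans_result`: `assignments` (named integer
#'   vector), `inertia` (total within-cluster sum of squares), `centers`,
#'   `degenerate` (TRUE when fewer distinct rows than clusters, in which
#'   case all rows get cluster 1).
#' @export
kmeans_clusters <- function(mat, k = 2, seed, nstart = 10,
                            standardize = TRUE) {
  mat <- as.matrix(mat)
  if (missing(seed)) stop("seed is required")
  if (k < 2L) stop("k must be at least 2")
  if (k > nrow(mat)) stop("k exceeds the number of rows")
  x <- mat
  if (standardize) {
    mu <- rowMeans(x)
    sd <- apply(x, 1, stats::sd)
    x <- sweep(x, 1, mu)
    x <- sweep(x, 1, ifelse(sd > 0, sd, 1), "/")
  }
  n_distinct <- nrow(unique(x))
  if (n_distinct < k) {
    assign <- stats::setNames(rep(1L, nrow(x)), rownames(mat))
    return(structure(list(assignments = assign, inertia = 0,
                          centers = matrix(colMeans(x), 1),
                          degenerate = TRUE),
                     class = "kmeans_result"))
  }
  set.seed(seed)
  km <- stats::kmeans(x, centers = k, nstart = nstart)
  structure(list(assignments = stats::setNames(km$cluster, rownames(mat)),
                 inertia = km$tot.withinss, centers = km$centers,
                 degenerate = FALSE),
            class = "kmeans_result")
}

#' Ward hierarchical clustering
#'
#' Agglomerative clustering with Ward's minimum-variance criterion
#' (`hclust(method = "ward.D2")` on Euclidean distances).
#'
#' @param mat numeric matrix, rows are the objects to cluster.
#' @return an [stats::hclust] dendrogram.
#' @export
ward_tree <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("need at least 2 rows")
  if (any(!is.finite(mat))) stop("matrix contains non-finite values")
  stats::hclust(stats::dist(mat), method = "ward.D2")
}

#' Venn region counts for 2 or 3 gene sets
#'
#' @param sets named list of 2 or 3 character vectors.
#' @return named integer vector of disjoint region counts (3 regions for two
#'   sets, 7 for three), summing to the size of the union.
#' @export
venn_counts <- function(sets) {
  sets <- lapply(sets, unique)
  m <- length(sets)
  if (!m %in% 2:3) stop("venn_counts supports 2 or 3 sets")
  nm <- names(sets)
  if (is.null(nm) || any(!nzchar(nm))) nm <- LETTERS[seq_len(m)]
  all_el <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_el %in% s, logical(length(all_el)))
  if (length(all_el) == 1L) member <- matrix(member, nrow = 1)
  pattern <- apply(member, 1, function(b) paste(nm[b], collapse = "&"))
  combos <- unlist(lapply(seq_len(m), function(k)
    utils::combn(nm, k, paste, collapse = "&")))
  counts <- stats::setNames(integer(length(combos)), combos)
  tb <- table(pattern)
  counts[names(tb)] <- as.integer(tb)
  counts
}

#' Hypergeometric overlap test with representation factor
#'
#' For two gene sets of sizes `n1` and `n2` drawn from a universe of size
#' `N`, tests whether their `overlap` exceeds the independence expectation
#' `n1 * n2 / N`. The representation factor is the ratio of observed to
#' expected overlap; the p-value is the upper-tail hypergeometric
#' probability P(X >= overlap).
#'
#' @param n1,n2 set sizes.
#' @param overlap observed intersection size.
#' @param N universe size.
#' @return list of class `overlap_result`: `n1`, `n2`, `overlap`, `N`,
#'   `expected`, `representation_factor`, `p`.
#' @export
hypergeom_overlap <- function(n1, n2, overlap, N) {
  if (n1 > N || n2 > N) stop("set sizes cannot exceed the universe")
  if (overlap > min(n1, n2)) stop("overlap cannot exceed min(n1, n2)")
  if (overlap < max(0, n1 + n2 - N)) stop("overlap impossible for these sizes")
  expected <- n1 * n2 / N
  rf <- if (expected > 0) overlap / expected else NA_real_
  p <- stats::phyper(overlap - 1, n1, N - n1, n2, lower.tail = FALSE)
  structure(list(n1 = n1, n2 = n2, overlap = overlap, N = N,
                 expected = expected, representation_factor = rf, p = p),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap %d of (%d, %d) in universe %d: RF = %.3g, p = %.3g\n",
              x$overlap, x$n1, x$n2, x$N, x$representation_factor, x$p))
  invisible(x)
}

#' Two-count equal-proportion test
#'
#' Tests whether two counts are consistent with an equal split, reporting
#' both the likelihood-ratio G statistic
#' `G = 2 [a log(2a/(a+b)) + b log(2b/(a+b))]` (the headline statistic) and
#' the Pearson chi-square `(a - b)^2 / (a + b)`, each on 1 df.
#'
#' @param countA,countB non-negative counts, not both zero.
#' @return list: `G`, `p_G`, `chisq_pearson`, `p_pearson`, `df` (= 1).
#' @export
proportion_test <- function(countA, countB) {
  if (countA < 0 || countB < 0) stop("counts must be non-negative")
  n <- countA + countB
  if (n == 0) stop("both counts are zero")
  xlogx <- function(k) if (k == 0) 0 else k * log(2 * k / n)
  G <- 2 * (xlogx(countA) + xlogx(countB))
  pearson <- (countA - countB)^2 / n
  list(G = G, p_G = stats::pchisq(G, 1, lower.tail = FALSE),
       chisq_pearson = pearson,
       p_pearson = stats::pchisq(pearson, 1, lower.tail = FALSE),
       df = 1)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact p-value: the total probability of tables (with the
#' observed margins) no more probable than the observed one.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return the two-sided p-value.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  stats::fisher.test(table)$p.value
}

#' Hypergeometric term enrichment
#'
#' For each annotation term, tests over-representation of the term's genes
#' in a query set against a background: upper-tail hypergeometric with
#' universe `N = |background|`, term size `K = |term in background|`, query
#' size `n = |query|`, hits `k = |term in query|`. The conservative EASE
#' variant computes the tail at `k - 1` hits. q-values are BH-adjusted
#' across terms.
#'
#' @param query character vector of genes, a subset of `background`.
#' @param annotation an [annotation_map].
#' @param background character vector of background genes (the enrichment
#'   universe; must be supplied explicitly).
#' @param ease use the EASE variant (default `FALSE`).
#' @return data frame of class `enrichment_result`: `term`, `k`, `n`, `K`,
#'   `N`, `p`, `q`, sorted by `p`.
#' @export
enrich_terms <- function(query, annotation, background, ease = FALSE) {
  stopifnot(inherits(annotation, "annotation_map"))
  background <- unique(as.character(background))
  if (!length(background)) stop("background must be non-empty")
  query <- unique(as.character(query))
  if (!all(query %in% background))
    stop("query must be a subset of the background")
  g2t <- annotation$gene2term
  g2t <- g2t[g2t$gene %in% background, , drop = FALSE]
  terms <- unique(g2t$term)
  N <- length(background)
  n <- length(query)
  rows <- lapply(terms, function(tm) {
    genes <- g2t$gene[g2t$term == tm]
    K <- length(genes)
    k <- sum(query %in% genes)
    k_eff <- if (ease) max(k - 1L, 0L) else k
    p <- stats::phyper(k_eff - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, n = n, K = K, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0))
  } else {
    out$q <- bh_adjust(out$p)
    out <- out[order(out$p, out$term), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Single-count mapping of terms to ancestor (slim) categories
#'
#' Each input term increments each of its mapped ancestors by exactly one
#' ("single count"); input is treated as a list, so a duplicated term counts
#' twice. Terms with no ancestor go to an unassigned bucket.
#'
#' @param terms character vector of terms (list semantics).
#' @param slim an [annotation_map] (its `slim` table is used) or a data
#'   frame with columns `term`, `ancestor`.
#' @return list of class `ancestor_counts`: `counts` (named integer vector
#'   per ancestor), `unassigned`, `n_assigned` (input terms with at least
#'   one ancestor).
#' @export
map_to_ancestors <- function(terms, slim) {
  sm <- if (inherits(slim, "annotation_map")) slim$slim else
    as.data.frame(slim, stringsAsFactors = FALSE)
  stopifnot(all(c("term", "ancestor") %in% names(sm)))
  anc_of <- split(sm$ancestor, sm$term)
  counts <- integer(0)
  unassigned <- 0L
  n_assigned <- 0L
  for (tm in terms) {
    anc <- unique(anc_of[[tm]])
    if (is.null(anc) || !length(anc)) {
      unassigned <- unassigned + 1L
    } else {
      n_assigned <- n_assigned + 1L
      for (a in anc) counts[a] <- (if (is.na(counts[a])) 0L else counts[a]) + 1L
    }
  }
  structure(list(counts = counts, unassigned = unassigned,
                 n_assigned = n_assigned),
            class = "ancestor_counts")
}

#' qPCR relative expression and rank test
#'
#' `qpcr_relative` normalizes a target gene's expression to the geometric
#' mean of housekeeping genes per sample, then rescales so the reference
#' group's mean is 1. `kruskal_wallis` is the ties-corrected Kruskal-Wallis
#' rank-sum test across groups.
#'
#' @param target numeric vector of target-gene values, one per sample.
#' @param housekeeping numeric matrix (samples x housekeeping genes) of
#'   strictly positive values; a vector is taken as a single housekeeper.
#' @param group factor/character of group labels per sample.
#' @param reference the reference group label (its mean relative expression
#'   is scaled to 1).
#' @return `qpcr_relative`: numeric vector of relative expressions.
#' @export
qpcr_relative <- function(target, housekeeping, group, reference) {
  hk <- as.matrix(housekeeping)
  if (any(hk <= 0)) stop("housekeeping values must be strictly positive")
  stopifnot(length(target) == nrow(hk), length(group) == length(target))
  if (!reference %in% group) stop("reference group not found")
  gm <- exp(rowMeans(log(hk)))
  rel <- target / gm
  rel / mean(rel[group == reference])
}

#' @rdname qpcr_relative
#' @param values numeric vector of observations (or a list of numeric
#'   vectors, one per group, in which case `group` is ignored).
#' @return `kruskal_wallis`: list with `H` (ties-corrected statistic), `df`,
#'   `p`.
#' @export
kruskal_wallis <- function(values, group = NULL) {
  if (is.list(values)) {
    group <- rep(seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  if (length(unique(group)) < 2L) stop("need at least 2 groups")
  kt <- stats::kruskal.test(values, factor(group))
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}
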