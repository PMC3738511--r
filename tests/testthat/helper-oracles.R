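# Independent brute-force oracles. These are deliberately literal, slow
# transcriptions of the definitions, kept free of any package code.

# Probe ranking: returns the index of the probe a literal reading of the
# ranking rules would pick. green/red are intensity vectors in input order.
oracle_select_probe <- function(green, red, cutoff = 3) {
  n <- length(green)
  med <- function(x) {
    s <- sort(x)
    if (length(s) %% 2 == 1) s[(length(s) + 1) / 2]
    else (s[length(s) / 2] + s[length(s) / 2 + 1]) / 2
  }
  if (n == 1) return(1L)
  if (n == 2) {
    # "we selected the one with higher intensity"
    if (green[2] > green[1]) return(2L) else return(1L)
  }
  ratios <- green / med(green)
  # rank by ratio, ties by input position
  ord <- order(-ratios, seq_len(n))
  if (n <= 6) {
    if (ratios[ord[1]] < cutoff) return(ord[1])
    return(ord[2])
  }
  # n == 7: remove the top probe if its ratio exceeds the cutoff, recompute
  if (ratios[ord[1]] > cutoff) {
    left <- setdiff(seq_len(n), ord[1])
    r2 <- green[left] / med(green[left])
    return(left[order(-r2, seq_along(r2))[1]])
  }
  ord[1]
}

# BH step-up by the definition q_(i) = min_{j >= i} p_(j) * m / j, capped.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Upper-tail hypergeometric by direct summation of the pmf.
oracle_hyper_tail <- function(k, n1, n2, N) {
  js <- k:min(n1, n2)
  js <- js[js >= max(0, n1 + n2 - N)]
  if (!length(js)) return(0)
  sum(choose(n1, js) * choose(N - n1, n2 - js)) / choose(N, n2)
}

# Two-sided Fisher exact p by enumeration of all tables with the observed
# margins: sum the probabilities of tables no more probable than observed.
oracle_fisher <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(ks, function(k)
    choose(c1, k) * choose(n - c1, r1 - k) / choose(n, r1), numeric(1))
  p_obs <- probs[ks == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Classical two-way fixed-effects ANOVA F for the treatment term by direct
# residual-sum-of-squares reduction.
oracle_anova_F <- function(y, group, dup, dye) {
  full <- stats::lm(y ~ group + dup + dye)
  red <- stats::lm(y ~ dup + dye)
  rss_f <- sum(stats::residuals(full)^2)
  rss_r <- sum(stats::residuals(red)^2)
  q <- full$rank - red$rank
  dfr <- length(y) - full$rank
  ((rss_r - rss_f) / q) / (rss_f / dfr)
}

# Ward merge order on a small point set: at each step merge the pair of
# clusters whose union minimally increases the total within-cluster SSE.
oracle_ward_merges <- function(mat) {
  clusters <- lapply(seq_len(nrow(mat)), identity)
  sse <- function(idx) {
    sub <- mat[idx, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL; best_inc <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      inc <- sse(c(clusters[[i]], clusters[[j]])) -
        sse(clusters[[i]]) - sse(clusters[[j]])
      if (inc < best_inc) { best_inc <- inc; best <- c(i, j) }
    }
    merges[[length(merges) + 1]] <-
      sort(c(clusters[[best[1]]], clusters[[best[2]]]))[1:2]
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  merges
}
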