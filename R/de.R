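#' Benjamini-Hochberg step-up adjustment
#'
#' Returns q-values `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, in
#' the order of the input (the standard BH step-up transform, delegated to
#' [stats::p.adjust()]).
#'
#' @param pvals numeric vector of p-values in `[0, 1]`; `NA`s propagate.
#' @return numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvals))
  out[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  out
}

#' Differential expression over a loop-design experiment
#'
#' Runs the two-stage mixed-model analysis: global normalization
#' ([fit_normalization()]), then the per-transcript mixed ANOVA
#' ([fit_gene()]) on the normalization residuals, then Benjamini-Hochberg
#' adjustment within each p-value family (the overall treatment test, and
#' each pairwise group contrast separately). The headline DE set is the set
#' significant by the overall treatment test at `q < q_threshold`
#' (`de_set = "overall"`); `de_set = "union-pairwise"` instead takes the
#' union of the pairwise-contrast sets.
#'
#' @param expr long-format log2 expression (`spot`, `array`, `dye`, `value`).
#' @param design the companion [array_design].
#' @param q_threshold FDR threshold in (0, 1) (e.g. 0.001 for a large
#'   experiment, 0.1 for a low-powered one).
#' @param de_set which family defines the headline DE set: `"overall"`
#'   (default) or `"union-pairwise"`.
#' @param random_array,df_method passed to [fit_gene()].
#' @return object of class `de_result`: `table` (per transcript: F, df1,
#'   df2, p, q, skip_reason), `contrasts` (long data frame with per-contrast
#'   estimate, p and q), `significant` (character vector, the headline set),
#'   `significant_pairwise` (named list of per-contrast sets),
#'   `q_threshold`, `de_set`, `n_tested`, `normalization`.
#' @export
run_de <- function(expr, design, q_threshold = 0.001,
                   de_set = c("overall", "union-pairwise"),
                   random_array = TRUE,
                   df_method = c("kenward-roger", "satterthwaite")) {
  de_set <- match.arg(de_set)
  df_method <- match.arg(df_method)
  if (!is.numeric(q_threshold) || q_threshold <= 0 || q_threshold >= 1)
    stop("q_threshold must lie in (0, 1)")
  norm <- fit_normalization(expr, design)

  res <- norm$residuals
  res$transcript <- design$spots$transcript[match(res$spot, design$spots$spot)]
  idx <- split(seq_len(nrow(res)), res$transcript)

  cache <- new.env(parent = emptyenv())
  fits <- lapply(idx, function(i)
    fit_gene(res[i, c("spot", "array", "dye", "residual")], design,
             random_array = random_array, df_method = df_method,
             .cache = cache))
  transcripts <- names(idx)

  tab <- data.frame(
    transcript = transcripts,
    F = vapply(fits, function(f) f$F, numeric(1)),
    df1 = vapply(fits, function(f) f$df1, numeric(1)),
    df2 = vapply(fits, function(f) f$df2, numeric(1)),
    p = vapply(fits, function(f) f$p, numeric(1)),
    skip_reason = vapply(fits, function(f) f$skip_reason, character(1)),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  tab$q <- bh_adjust(tab$p)

  clist <- lapply(seq_along(fits), function(k) {
    cf <- fits[[k]]$contrasts
    if (is.null(cf)) return(NULL)
    cbind(transcript = transcripts[k], cf, stringsAsFactors = FALSE)
  })
  contrasts <- do.call(rbind, clist)
  sig_pair <- list()
  if (!is.null(contrasts) && nrow(contrasts)) {
    rownames(contrasts) <- NULL
    fam <- paste(contrasts$group1, contrasts$group2, sep = " vs ")
    contrasts$q <- NA_real_
    for (f in unique(fam)) {
      i <- fam == f
      contrasts$q[i] <- bh_adjust(contrasts$p[i])
      sig_pair[[f]] <- contrasts$transcript[i & !is.na(contrasts$q) &
                                              contrasts$q < q_threshold]
    }
  }

  significant <- if (de_set == "overall") {
    tab$transcript[!is.na(tab$q) & tab$q < q_threshold]
  } else {
    unique(unlist(sig_pair, use.names = FALSE))
  }

  structure(list(table = tab, contrasts = contrasts,
                 significant = significant,
                 significant_pairwise = sig_pair,
                 q_threshold = q_threshold, de_set = de_set,
                 n_tested = sum(is.na(tab$skip_reason)),
                 normalization = norm),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat("de_result:", x$n_tested, "transcripts tested;",
      length(x$significant), "significant at q <", x$q_threshold,
      paste0("(", x$de_set, ")"), "\n")
  for (f in names(x$significant_pairwise))
    cat("  ", f, ":", length(x$significant_pairwise[[f]]), "significant\n")
  invisible(x)
}
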