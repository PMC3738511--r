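#' Probe intensity ratios relative to the transcript median
#'
#' For a transcript with several candidate probes, each probe is scored as
#' its intensity divided by the median intensity over all of the
#' transcript's probes (the probe being scored included). The median of an
#' even count is the mean of the two central order statistics.
#'
#' @param intensities numeric vector of non-negative intensities, one per
#'   candidate probe.
#' @return numeric vector of ratios, same order as the input.
#' @export
compute_ratios <- function(intensities) {
  if (!length(intensities)) stop("need at least one intensity")
  if (any(is.na(intensities)) || any(intensities < 0))
    stop("intensities must be non-negative and non-missing")
  med <- stats::median(intensities)
  if (med == 0) stop("degenerate transcript: median intensity is zero")
  intensities / med
}

#' Select one probe per transcript from pilot-array intensities
#'
#' Implements the pilot-array ranking used to reduce multiple candidate
#' probes per transcript to one. Candidate counts route to different rules:
#' \describe{
#'   \item{1 probe}{pass-through (`single`), with a QC flag when either
#'     channel is below `background` (the single-probe case is the only one
#'     checked on both dyes).}
#'   \item{2 probes}{the one with higher green intensity (`pair_max`).}
#'   \item{3--6 probes}{green-channel ratios against the transcript median;
#'     the highest-ratio probe if its ratio is strictly below `ratio_cutoff`,
#'     otherwise the second-highest-ratio probe (`ratio_3to6`).}
#'   \item{7 probes}{as above, but when the highest ratio is strictly above
#'     `ratio_cutoff` that probe is removed once, ratios are recomputed over
#'     the remaining six and the new highest-ratio probe is taken
#'     (`ratio_7_with_removal`).}
#' }
#' Ties are broken by the lowest candidate index in input order.
#'
#' @param candidates data frame with columns `transcript`, `probe`, `green`,
#'   `red` and optionally `category` (one of EWGM, EWOGM, GM, GMRWOM).
#' @param ratio_cutoff outlier cutoff on the intensity/median ratio
#'   (default 3).
#' @param background background intensity level used for the single-probe
#'   dual-dye QC check (default 300).
#' @return a list of class `probe_choice`: `transcript`, `probe` (chosen id),
#'   `rule`, `ratios` (named by probe; `NULL` for n <= 2), `removed_probe`
#'   (or `NA`), `qc_flags` (character vector).
#' @export
select_probe <- function(candidates, ratio_cutoff = 3, background = 300) {
  candidates <- as.data.frame(candidates, stringsAsFactors = FALSE)
  n <- nrow(candidates)
  if (!n) stop("no candidate probes")
  if (n > 7L) stop("more than 7 candidate probes for transcript ",
                   candidates$transcript[1])
  if (anyDuplicated(candidates$probe))
    stop("duplicate probe ids within transcript ", candidates$transcript[1])
  if (any(candidates$green < 0) || (!is.null(candidates$red) && any(candidates$red < 0)))
    stop("intensities must be non-negative")
  tr <- candidates$transcript[1]
  qc <- character(0)
  ratios <- NULL
  removed <- NA_character_

  if (n == 1L) {
    rule <- "single"
    red1 <- if (is.null(candidates$red)) candidates$green[1] else
      candidates$red[1]
    if (candidates$green[1] < background || red1 < background)
      qc <- c(qc, "single_probe_low_intensity")
    pick <- 1L
  } else if (n == 2L) {
    rule <- "pair_max"
    pick <- which.max(candidates$green)  # which.max: first index on ties
  } else if (n <= 6L) {
    rule <- "ratio_3to6"
    ratios <- compute_ratios(candidates$green)
    ord <- order(-ratios, seq_len(n))
    if (ratios[ord[1]] < ratio_cutoff) {
      pick <- ord[1]
    } else {
      pick <- ord[2]
      if (ratios[ord[2]] >= ratio_cutoff)
        qc <- c(qc, "second_ratio_above_cutoff")
    }
  } else {  # n == 7
    rule <- "ratio_7_with_removal"
    ratios <- compute_ratios(candidates$green)
    ord <- order(-ratios, seq_len(n))
    if (ratios[ord[1]] > ratio_cutoff) {
      removed <- candidates$probe[ord[1]]
      keep <- setdiff(seq_len(n), ord[1])
      r2 <- compute_ratios(candidates$green[keep])
      pick <- keep[order(-r2, seq_along(r2))[1]]
    } else {
      pick <- ord[1]
    }
  }
  if (!is.null(ratios)) names(ratios) <- candidates$probe
  structure(list(transcript = tr, probe = candidates$probe[pick],
                 rule = rule, ratios = ratios, removed_probe = removed,
                 qc_flags = qc),
            class = "probe_choice")
}

#' Select probes for a whole platform from pilot-array data
#'
#' Applies [select_probe()] to every transcript of a pilot table and tallies
#' the rules applied and (when present) the transcript categories.
#'
#' @param pilot data frame with columns `transcript`, `probe`, `green`,
#'   `red`, optionally `category`.
#' @inheritParams select_probe
#' @return list of class `platform_selection`: `choices` (data frame with
#'   columns transcript, probe, rule, removed_probe, qc_flags), `rule_counts`,
#'   `category_counts`.
#' @export
select_platform <- function(pilot, ratio_cutoff = 3, background = 300) {
  pilot <- as.data.frame(pilot, stringsAsFactors = FALSE)
  if (!nrow(pilot)) {
    return(structure(list(choices = data.frame(transcript = character(0),
                                               probe = character(0),
                                               rule = character(0),
                                               removed_probe = character(0),
                                               qc_flags = character(0),
                                               stringsAsFactors = FALSE),
                          rule_counts = table(character(0)),
                          category_counts = table(character(0))),
                     class = "platform_selection"))
  }
  idx <- split(seq_len(nrow(pilot)), pilot$transcript)
  rows <- lapply(idx, function(i) {
    ch <- tryCatch(select_probe(pilot[i, , drop = FALSE], ratio_cutoff,
                                background),
                   error = function(e) stop("transcript ",
                                            pilot$transcript[i[1]], ": ",
                                            conditionMessage(e), call. = FALSE))
    data.frame(transcript = ch$transcript, probe = ch$probe, rule = ch$rule,
               removed_probe = ch$removed_probe,
               qc_flags = paste(ch$qc_flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  choices <- do.call(rbind, rows)
  rownames(choices) <- NULL
  cat_counts <- if ("category" %in% names(pilot)) {
    first <- !duplicated(pilot$transcript)
    table(pilot$category[first])
  } else table(character(0))
  structure(list(choices = choices, rule_counts = table(choices$rule),
                 category_counts = cat_counts),
            class = "platform_selection")
}

#' @export
print.platform_selection <- function(x, ...) {
  cat("platform_selection:", nrow(x$choices), "transcripts\n")
  print(x$rule_counts)
  if (length(x$category_counts)) print(x$category_counts)
  invisible(x)
}
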