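#' Loop-design experiment map
#'
#' An `array_design` describes a two-color loop-design experiment: which
#' sample was hybridized to which (array, dye) channel and to which treatment
#' group it belongs, plus the spot layout of the platform (which transcript
#' each spot interrogates, its duplicate index when transcripts are printed
#' in pairs, and its print block).
#'
#' @param channels data frame with columns `array`, `dye`, `sample`, `group`.
#'   Dyes must be `"Cy3"`/`"Cy5"` (any case).
#' @param spots data frame with columns `spot`, `transcript`, `duplicate`,
#'   `block`. `duplicate` is a positive integer index (1, 2, ... for
#'   transcripts printed more than once).
#'
#' @return An object of class `array_design`: a list with elements
#'   `channels`, `spots`, `n_arrays` and `loop_connected`. `loop_connected`
#'   reports whether the samples form a single cycle through shared arrays;
#'   it is informational and never enforced (designs hybridizing each sample
#'   once, e.g. 24 samples on a 12-plex slide, are never loop-connected in
#'   the graph sense).
#' @export
array_design <- function(channels, spots) {
  channels <- as.data.frame(channels, stringsAsFactors = FALSE)
  spots <- as.data.frame(spots, stringsAsFactors = FALSE)
  need_ch <- c("array", "dye", "sample", "group")
  if (!all(need_ch %in% names(channels)))
    stop("channels must have columns: ", paste(need_ch, collapse = ", "))
  need_sp <- c("spot", "transcript", "duplicate", "block")
  if (!all(need_sp %in% names(spots)))
    stop("spots must have columns: ", paste(need_sp, collapse = ", "))
  channels$dye <- normalize_dye(channels$dye)
  for (cc in c("array", "sample", "group")) channels[[cc]] <- as.character(channels[[cc]])
  for (cc in c("spot", "transcript", "block")) spots[[cc]] <- as.character(spots[[cc]])
  spots$duplicate <- as.integer(spots$duplicate)

  key <- paste(channels$array, channels$dye)
  if (anyDuplicated(key)) {
    bad <- key[duplicated(key)][1]
    stop("duplicate (array, dye) channel: ", bad)
  }
  if (anyDuplicated(channels$sample))
    stop("sample ids must be unique across channels: ",
         channels$sample[duplicated(channels$sample)][1])
  if (any(is.na(spots$duplicate)) || any(spots$duplicate < 1L))
    stop("duplicate index must be a positive integer")
  if (anyDuplicated(spots$spot))
    stop("spot ids must be unique: ", spots$spot[duplicated(spots$spot)][1])
  if (!nrow(channels)) stop("design has no channels")
  if (!nrow(spots)) stop("design has no spots")

  structure(
    list(channels = channels[order(channels$array, channels$dye), , drop = FALSE],
         spots = spots,
         n_arrays = length(unique(channels$array)),
         loop_connected = is_loop_connected(channels)),
    class = "array_design")
}

normalize_dye <- function(x) {
  x <- as.character(x)
  out <- c(cy3 = "Cy3", cy5 = "Cy5")[tolower(x)]
  if (any(is.na(out)))
    stop("unknown dye token: ", x[is.na(out)][1], " (expected Cy3 or Cy5)")
  unname(out)
}

# Samples form one cycle through shared arrays: the sample/array bipartite
# graph, projected onto samples, must be connected with every sample of
# degree 2 (hybridized on exactly two arrays).
is_loop_connected <- function(channels) {
  arr <- split(channels$sample, channels$array)
  deg <- table(channels$sample)
  if (any(deg != 2L)) return(FALSE)
  if (any(lengths(arr) != 2L)) return(FALSE)
  adj <- lapply(arr, identity)
  samples <- unique(channels$sample)
  nbr <- stats::setNames(vector("list", length(samples)), samples)
  for (pair in adj) {
    nbr[[pair[1]]] <- c(nbr[[pair[1]]], pair[2])
    nbr[[pair[2]]] <- c(nbr[[pair[2]]], pair[1])
  }
  seen <- samples[1]
  frontier <- samples[1]
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(nbr[frontier])), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == length(samples)
}

#' @export
print.array_design <- function(x, ...) {
  cat("array_design:", nrow(x$channels), "channels on", x$n_arrays, "arrays;",
      nrow(x$spots), "spots /", length(unique(x$spots$transcript)),
      "transcripts\n")
  grp <- table(x$channels$group)
  cat("  groups:", paste(names(grp), grp, sep = "=", collapse = ", "), "\n")
  cat("  loop-connected:", x$loop_connected, "\n")
  invisible(x)
}

#' Read or write a loop-design file
#'
#' The design file is UTF-8, tab-delimited, with `#` comments and two
#' sections: a `[channels]` section (columns array, dye, sample, group) and a
#' `[spots]` section (columns spot, transcript, duplicate, block).
#'
#' @param path file path.
#' @return `read_design` returns an [array_design]; `write_design` returns
#'   `path` invisibly.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  sec <- cumsum(grepl("^\\[", lines))
  headers <- grepl("^\\[", lines)
  parse_section <- function(name, ncol_expect) {
    tag <- paste0("[", name, "]")
    idx <- which(lines == tag)
    if (length(idx) != 1L) stop("design file must contain one ", tag, " section")
    body <- lines[seq_along(lines) > idx & sec == sec[idx] & !headers]
    if (length(body) < 2L) stop("section ", tag, " is empty")
    fields <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(fields) != ncol_expect))
      stop("malformed line in ", tag, ": ",
           body[lengths(fields) != ncol_expect][1])
    m <- do.call(rbind, fields)
    df <- as.data.frame(m[-1, , drop = FALSE], stringsAsFactors = FALSE)
    names(df) <- m[1, ]
    df
  }
  channels <- parse_section("channels", 4L)
  spots <- parse_section("spots", 4L)
  # re-check channel duplication with line context before construction
  key <- paste(channels$array, tolower(channels$dye))
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("design file declares a duplicate (array, dye) channel: ", dup)
  }
  array_design(channels, spots)
}

#' @rdname read_design
#' @param design an [array_design].
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "array_design"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# loop-design experiment map", con)
  writeLines("[channels]", con)
  writeLines(paste("array", "dye", "sample", "group", sep = "\t"), con)
  ch <- design$channels
  writeLines(paste(ch$array, ch$dye, ch$sample, ch$group, sep = "\t"), con)
  writeLines("[spots]", con)
  writeLines(paste("spot", "transcript", "duplicate", "block", sep = "\t"), con)
  sp <- design$spots
  writeLines(paste(sp$spot, sp$transcript, sp$duplicate, sp$block, sep = "\t"), con)
  invisible(path)
}
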