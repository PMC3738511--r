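#' Read a two-channel intensity table
#'
#' Reads a GPR-like long-format, tab-delimited table with columns
#' `spot`, `array`, `dye`, `intensity` and returns the complete
#' spot-by-channel grid declared by the companion design, with `NA` marking
#' missing cells (absent rows or `NA` entries).
#'
#' @param path tab-delimited file; `#` lines are comments; intensity cells
#'   may be empty or `NA`.
#' @param design the companion [array_design]; all keys in the file are
#'   validated against it.
#' @return data frame with columns `spot`, `array`, `dye`, `intensity`
#'   covering every (spot, channel) combination of the design.
#' @export
read_intensities <- function(path, design) {
  stopifnot(inherits(design, "array_design"))
  if (!file.exists(path)) stop("intensity file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "character",
                                         "numeric"))
  need <- c("spot", "array", "dye", "intensity")
  if (!all(need %in% names(df)))
    stop("intensity table must have columns: ", paste(need, collapse = ", "))
  df$dye <- normalize_dye(df$dye)
  if (any(!is.na(df$intensity) & df$intensity < 0))
    stop("negative intensity: ",
         df$intensity[!is.na(df$intensity) & df$intensity < 0][1])
  ch_key <- paste(design$channels$array, design$channels$dye)
  bad_ch <- !(paste(df$array, df$dye) %in% ch_key)
  if (any(bad_ch))
    stop("intensity row references a channel not in the design: ",
         paste(df$array[bad_ch][1], df$dye[bad_ch][1]))
  bad_sp <- !(df$spot %in% design$spots$spot)
  if (any(bad_sp))
    stop("intensity row references a spot not in the design: ",
         df$spot[bad_sp][1])
  if (anyDuplicated(paste(df$spot, df$array, df$dye)))
    stop("duplicate (spot, array, dye) rows in intensity table")
  full <- intensity_grid(design)
  i <- match(paste(full$spot, full$array, full$dye),
             paste(df$spot, df$array, df$dye))
  full$intensity <- df$intensity[i]
  full
}

# complete (spot x channel) grid in canonical order
intensity_grid <- function(design) {
  ch <- design$channels
  sp <- design$spots$spot
  data.frame(
    spot = rep(sp, each = nrow(ch)),
    array = rep(ch$array, times = length(sp)),
    dye = rep(ch$dye, times = length(sp)),
    stringsAsFactors = FALSE)
}

#' @rdname read_intensities
#' @param intensities long-format data frame as returned by
#'   `read_intensities` (missing cells as `NA`; `NA` rows are written with an
#'   empty intensity field).
#' @export
write_intensities <- function(intensities, path) {
  need <- c("spot", "array", "dye", "intensity")
  stopifnot(all(need %in% names(intensities)))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# two-channel intensities (long format)", con)
  writeLines(paste(need, collapse = "\t"), con)
  val <- ifelse(is.na(intensities$intensity), "NA",
                format(intensities$intensity, digits = 15, trim = TRUE,
                       scientific = FALSE))
  writeLines(paste(intensities$spot, intensities$array, intensities$dye,
                   val, sep = "\t"), con)
  invisible(path)
}

#' Gene-to-term annotation with an ancestor slim map
#'
#' Container for term enrichment and ancestor ("slim") mapping: de-duplicated
#' gene-to-term mappings, term-to-ancestor mappings, and the gene universe.
#'
#' @param gene2term data frame with columns `gene`, `term`.
#' @param slim data frame with columns `term`, `ancestor`; self-loops
#'   (term equal to its ancestor) are dropped with a warning.
#' @param universe character vector of all gene labels. Annotated genes
#'   outside the universe are dropped with a warning; the number dropped is
#'   recorded in `$n_dropped`.
#' @return object of class `annotation_map` with elements `gene2term`,
#'   `slim`, `universe`, `n_dropped`.
#' @export
annotation_map <- function(gene2term, slim, universe) {
  gene2term <- unique(as.data.frame(gene2term, stringsAsFactors = FALSE))
  slim <- unique(as.data.frame(slim, stringsAsFactors = FALSE))
  stopifnot(all(c("gene", "term") %in% names(gene2term)),
            all(c("term", "ancestor") %in% names(slim)))
  universe <- unique(as.character(universe))
  out <- !(gene2term$gene %in% universe)
  n_dropped <- sum(out)
  if (n_dropped) {
    warning(n_dropped, " annotated gene(s) outside the universe dropped")
    gene2term <- gene2term[!out, , drop = FALSE]
  }
  loops <- slim$term == slim$ancestor
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped from slim map")
    slim <- slim[!loops, , drop = FALSE]
  }
  structure(list(gene2term = gene2term, slim = slim, universe = universe,
                 n_dropped = n_dropped),
            class = "annotation_map")
}

#' @rdname annotation_map
#' @param gene2term_path,slim_path two-column tab-delimited files
#'   (gene, term) and (term, ancestor), `#` comments allowed.
#' @export
read_annotation <- function(gene2term_path, slim_path, universe) {
  read2 <- function(path, nm) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE,
                            colClasses = "character")
    if (ncol(df) < 2) stop("expected two columns in ", path)
    stats::setNames(df[, 1:2], nm)
  }
  annotation_map(read2(gene2term_path, c("gene", "term")),
                 read2(slim_path, c("term", "ancestor")),
                 universe)
}

#' @export
print.annotation_map <- function(x, ...) {
  cat("annotation_map:", length(unique(x$gene2term$gene)), "genes,",
      length(unique(x$gene2term$term)), "terms,",
      length(unique(x$slim$ancestor)), "ancestors;",
      length(x$universe), "genes in universe\n")
  invisible(x)
}
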