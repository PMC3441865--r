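# Recombination-hotspot track: per-chromosome sorted, merged [start, end)
# intervals, 0-based half-open (native BED semantics pass through).

#' Construct a hotspot track
#'
#' Sorts intervals per chromosome and merges overlapping or abutting ones,
#' so the long-range criterion counts recombination regions rather than
#' bookkeeping fragments.
#'
#' @param intervals Data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return A tibble of class `hotspot_track` with merged intervals sorted
#'   by (chrom, start).
#' @export
hotspot_track <- function(intervals = tibble(chrom = character(),
                                             start = integer(),
                                             end = integer())) {
  iv <- as_tibble(intervals)
  stopifnot(all(c("chrom", "start", "end") %in% names(iv)))
  if (nrow(iv) > 0L) {
    if (any(iv$start >= iv$end)) {
      stop("hotspot intervals require start < end", call. = FALSE)
    }
    merged <- lapply(split(iv, iv$chrom), function(d) {
      # IRanges is 1-based closed; [start, end) maps to [start + 1, end]
      r <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
      tibble(chrom = d$chrom[[1L]],
             start = IRanges::start(r) - 1L,
             end = IRanges::end(r))
    })
    iv <- dplyr::arrange(dplyr::bind_rows(merged), .data$chrom, .data$start)
  } else {
    iv <- tibble(chrom = character(), start = integer(), end = integer())
  }
  class(iv) <- c("hotspot_track", class(tibble()))
  iv
}

#' Read a recombination-hotspot track from BED3
#'
#' BED is natively 0-based half-open, so coordinates pass through
#' unchanged. Intervals are sorted and merged per chromosome on load.
#'
#' @param path Path to a BED3 file (track/browser/comment lines are
#'   skipped).
#' @return A `hotspot_track`.
#' @export
read_hotspots_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lines_kept <- lines[keep]
  if (length(lines_kept) == 0L) return(hotspot_track())
  fields <- strsplit(lines_kept, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L)) {
    bad <- which(keep)[lengths(fields) < 3L][[1L]]
    stop("BED line ", bad, " has fewer than 3 fields", call. = FALSE)
  }
  chrom <- vapply(fields, `[`, "", 1L)
  start <- as.integer(vapply(fields, `[`, "", 2L))
  end <- as.integer(vapply(fields, `[`, "", 3L))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(keep)[which(is.na(start) | is.na(end))][[1L]]
    stop("BED line ", bad, " has a non-numeric coordinate", call. = FALSE)
  }
  if (any(start >= end)) {
    bad <- which(keep)[which(start >= end)][[1L]]
    stop("BED line ", bad, " has start >= end", call. = FALSE)
  }
  hotspot_track(tibble(chrom = chrom, start = start, end = end))
}

#' Write a hotspot track as BED3
#'
#' @param track A `hotspot_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hotspots_bed <- function(track, path) {
  readr::write_tsv(as_tibble(track)[, c("chrom", "start", "end")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}
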