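# Interval-set helpers. Tracks are tibbles (chrom, start, end[, name]) with
# 0-based half-open coordinates; set arithmetic goes through IRanges.

.as_iranges_by_chrom <- function(track) {
  track <- as_tibble(track)
  split(IRanges::IRanges(start = track$start + 1L, end = track$end), track$chrom)
}

.from_iranges <- function(lst) {
  out <- imap(lst, function(ir, chrom) {
    if (length(ir) == 0) return(NULL)
    tibble(chrom = chrom, start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  })
  out <- list_rbind(out)
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(chrom = character(0), start = integer(0), end = integer(0)))
  }
  arrange(out, .data$chrom, .data$start)
}

#' Merge overlapping intervals of a track
#'
#' @param track Interval tibble (`chrom`, `start`, `end`), 0-based half-open.
#' @return The merged (non-overlapping, sorted) track. Book-ended intervals
#'   (`[a,b) [b,c)`) are merged too.
#' @export
merge_intervals <- function(track) {
  if (nrow(as_tibble(track)) == 0) {
    return(tibble(chrom = character(0), start = integer(0), end = integer(0)))
  }
  .from_iranges(map(.as_iranges_by_chrom(track), IRanges::reduce))
}

.expand_clip <- function(track, by, chrom_lengths = NULL) {
  track <- mutate(as_tibble(track),
                  start = pmax(.data$start - by, 0L),
                  end = .data$end + by)
  if (!is.null(chrom_lengths)) {
    lens <- setNames(chrom_lengths$length, chrom_lengths$chrom)
    track <- mutate(track, end = pmin(.data$end, lens[.data$chrom]))
  }
  merge_intervals(track)
}

.setdiff_tracks <- function(a, b) {
  ia <- .as_iranges_by_chrom(a)
  ib <- .as_iranges_by_chrom(b)
  out <- imap(ia, function(ir, chrom) {
    other <- ib[[chrom]]
    if (is.null(other)) ir else IRanges::setdiff(ir, other)
  })
  .from_iranges(out)
}

#' CpG island shores and shelves
#'
#' Shores are the 1.5 kb bands flanking each CpG island (minus the islands
#' themselves); shelves the next 1.5 kb out (minus islands and shores). Both
#' are clipped at chromosome bounds when lengths are supplied, merged, and
#' pairwise disjoint from the inner layers by construction.
#'
#' @param cgi CpG island track (`chrom`, `start`, `end`), merged or not.
#' @param chrom_lengths Optional tibble (`chrom`, `length`) for clipping.
#' @param width Band width in bp (default 1500).
#' @return List with merged `shore` and `shelf` tracks.
#' @examples
#' cgi <- tibble::tibble(chrom = "chr1", start = 10000L, end = 11000L)
#' build_shores_shelves(cgi)
#' @export
build_shores_shelves <- function(cgi, chrom_lengths = NULL, width = 1500) {
  cgi <- merge_intervals(cgi)
  ext1 <- .expand_clip(cgi, width, chrom_lengths)
  ext2 <- .expand_clip(cgi, 2L * width, chrom_lengths)
  shore <- .setdiff_tracks(ext1, cgi)
  shelf <- .setdiff_tracks(ext2, ext1)
  list(shore = shore, shelf = shelf)
}

#' Annotate CpGs by track membership
#'
#' Point-in-interval membership (half-open: start inclusive, end exclusive)
#' of each CpG in each named track. CpGs on chromosomes absent from every
#' track simply get all-FALSE rows; CpGs on chromosomes unknown to
#' `chrom_lengths` (when given) are dropped with a warning.
#'
#' @param cpgs CpG tibble (`cpg_id`, `chrom`, `pos`).
#' @param tracks Named list of interval tibbles.
#' @param chrom_lengths Optional tibble (`chrom`, `length`) naming the known
#'   chromosomes.
#' @return Tibble: `cpg_id` plus one logical column per track.
#' @export
annotate_cpgs <- function(cpgs, tracks, chrom_lengths = NULL) {
  cpgs <- as_tibble(cpgs)
  stopifnot(is.list(tracks), !is.null(names(tracks)))
  if (!is.null(chrom_lengths)) {
    known <- cpgs$chrom %in% chrom_lengths$chrom
    if (any(!known)) {
      warn(sprintf("dropping %d CpG(s) on unknown chromosomes", sum(!known)))
      cpgs <- cpgs[known, , drop = FALSE]
    }
  }
  out <- tibble(cpg_id = cpgs$cpg_id)
  for (nm in names(tracks)) {
    tr <- merge_intervals(tracks[[nm]])
    member <- logical(nrow(cpgs))
    for (ch in unique(cpgs$chrom)) {
      idx <- cpgs$chrom == ch
      sub <- tr[tr$chrom == ch, , drop = FALSE]
      if (nrow(sub) == 0) next
      # merged+sorted: a point is covered iff the nearest start to its left
      # belongs to an interval whose end is beyond it
      j <- findInterval(cpgs$pos[idx], sub$start)
      member[idx] <- j > 0 & cpgs$pos[idx] < sub$end[pmax(j, 1L)]
    }
    out[[nm]] <- member
  }
  out
}

#' Extract a ChromHMM state group as a track
#'
#' Filters a ChromHMM BED track (state number as the leading integer of the
#' `name` column, e.g. `"4_Strong_Enhancer"`) to the requested states and
#' merges the result. Typical groupings: promoters = states 1-3, strong
#' enhancers = 4-5, weak enhancers = 6-7, insulator = 8.
#'
#' @param track Interval tibble with a `name` column.
#' @param states Integer vector of state numbers to keep.
#' @return Merged interval tibble.
#' @export
chromhmm_state_track <- function(track, states) {
  track <- as_tibble(track)
  stopifnot("name" %in% names(track))
  state_no <- suppressWarnings(as.integer(sub("^([0-9]+).*$", "\\1", track$name)))
  if (anyNA(state_no)) abort("every name must start with a state number")
  merge_intervals(track[state_no %in% states, c("chrom", "start", "end")])
}
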