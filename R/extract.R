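# Parsing of SAGE concatemer sequences.  A concatemer is a cloned string of
# ditags delimited by the NlaIII recognition site CATG (the anchoring
# enzyme); each ditag carries two 10-nt transcript tags ligated tail-to-tail,
# the second reverse-complemented.  Duplicate ditags are PCR amplification
# artifacts and are excluded before counting.

#' Construct a SAGE tag-count library
#'
#' A `tag_library` is a named multiset of 10-nt tags: a named integer vector
#' of per-tag counts plus the library total.  It is the unit compared by
#' [sage_dge()].
#'
#' @param counts Named integer vector; names are 10-nt tags over `ACGT`,
#'   values are non-negative counts.  Duplicate tag names are summed.
#' @param name Library name (e.g. the mouse strain the library came from).
#' @return An object of class `tag_library` with elements `name`, `counts`
#'   (sorted by decreasing count) and `total`.
#' @export
#' @examples
#' tag_library(c(ACGTACGTAC = 5L, GGGGTTTTAA = 2L), name = "demo")
tag_library <- function(counts, name = "library") {
  if (length(counts) == 0L) {
    counts <- integer(0)
  } else {
    if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
      stop("`counts` must be a named vector of tag counts", call. = FALSE)
    }
    bad <- !grepl("^[ACGT]{10}$", names(counts))
    if (any(bad)) {
      stop("tags must be 10 nt over ACGT; offending tag: ",
           names(counts)[bad][1], call. = FALSE)
    }
    if (any(counts < 0) || any(counts != round(counts))) {
      stop("tag counts must be non-negative integers", call. = FALSE)
    }
    counts <- vapply(split(as.integer(counts), names(counts)), sum, 0L)
    counts <- counts[counts > 0L]
    counts <- counts[order(-counts, names(counts))]
  }
  structure(list(name = name, counts = counts, total = sum(counts)),
            class = "tag_library")
}

#' @export
print.tag_library <- function(x, n = 6L, ...) {
  cat(sprintf("SAGE tag library '%s': %d total tags, %d unique\n",
              x$name, x$total, length(x$counts)))
  if (length(x$counts)) {
    shown <- utils::head(x$counts, n)
    cat(paste0("  ", names(shown), "  ", shown, collapse = "\n"), "\n")
    if (length(x$counts) > n) cat(sprintf("  ... %d more tags\n",
                                          length(x$counts) - n))
  }
  invisible(x)
}

#' Locate anchoring-enzyme sites in a sequence
#'
#' Returns the 0-based start positions of every `CATG` occurrence, including
#' overlapping ones.
#'
#' @param sequence A single uppercased DNA string.
#' @return Integer vector of 0-based positions, strictly increasing; empty
#'   when there is no site.
#' @export
#' @examples
#' find_anchor_sites("CATGCATG")  # 0 4
find_anchor_sites <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  hits <- gregexpr("(?=CATG)", sequence, perl = TRUE)[[1]]
  if (hits[1] < 0L) return(integer(0))
  as.integer(hits) - 1L
}

#' Parse a concatemer read into candidate ditags
#'
#' One candidate per consecutive anchor pair; sequence before the first
#' anchor and after the last is ignored.  Candidates outside the length
#' window or containing `N` are discarded and tallied.
#'
#' @param sequence A single DNA string (uppercased on ingest).
#' @param id Read identifier recorded with each ditag.
#' @param min_len,max_len Ditag length window; defaults 20-24 nt (two 10-nt
#'   tags, tolerating a few untrimmed middle bases).
#' @return A data frame with columns `sequence`, `read_id`, `offset`
#'   (0-based start of the ditag, first base after the anchor), with an
#'   attribute `discarded` counting rejected anchor intervals.
#' @export
parse_ditags <- function(sequence, id = "read", min_len = 20L, max_len = 24L) {
  stopifnot(min_len >= 20L, min_len <= max_len)
  sequence <- toupper(sequence)
  sites <- find_anchor_sites(sequence)
  empty <- data.frame(sequence = character(0), read_id = character(0),
                      offset = integer(0), stringsAsFactors = FALSE)
  if (length(sites) < 2L) {
    attr(empty, "discarded") <- 0L
    return(empty)
  }
  start <- sites[-length(sites)] + 4L   # first base after the anchor
  end <- sites[-1]                      # base before the next anchor, half-open
  len <- end - start
  cand <- substring(sequence, start + 1L, end)
  keep <- len >= min_len & len <= max_len & !grepl("N", cand, fixed = TRUE)
  out <- data.frame(sequence = cand[keep], read_id = rep(id, sum(keep)),
                    offset = start[keep], stringsAsFactors = FALSE)
  attr(out, "discarded") <- sum(!keep)
  out
}

#' Split a ditag into its two tags
#'
#' The first tag is the leading 10 nt as sequenced; the second is the
#' reverse complement of the trailing 10 nt (tags are ligated tail-to-tail).
#' Middle bases of ditags longer than 20 nt are ignored.
#'
#' @param ditag Character vector of ditag sequences, each at least 20 nt.
#' @return A two-column character matrix (`tag1`, `tag2`).
#' @export
#' @examples
#' split_ditag("ACGTACGTACCCCCCCCCCC")
split_ditag <- function(ditag) {
  n <- nchar(ditag)
  if (any(n < 20L)) {
    stop("ditag shorter than 20 nt cannot hold two 10-nt tags", call. = FALSE)
  }
  cbind(tag1 = substr(ditag, 1L, TAG_LEN),
        tag2 = revcomp(substring(ditag, n - TAG_LEN + 1L, n)))
}

#' Remove duplicate ditags
#'
#' Exact-sequence duplicates are collapsed to the first occurrence; they are
#' overwhelmingly PCR amplification artifacts rather than independent
#' observations.  Tag-pair-level collapsing (ignoring middle bases) is
#' available behind `by_tag_pair`.
#'
#' @param ditags Character vector of ditag sequences.
#' @param by_tag_pair Collapse on the (tag1, tag2) pair instead of the full
#'   sequence.  Default `FALSE`.
#' @return List with `ditags` (first occurrences, order preserved) and
#'   `n_removed`.
#' @export
dedup_ditags <- function(ditags, by_tag_pair = FALSE) {
  key <- if (by_tag_pair && length(ditags)) {
    tags <- split_ditag(ditags)
    paste(tags[, 1L], tags[, 2L])
  } else {
    ditags
  }
  keep <- !duplicated(key)
  list(ditags = ditags[keep], n_removed = sum(!keep))
}

#' Extract a tag-count library from concatemer reads
#'
#' Composes [parse_ditags()], [dedup_ditags()] and [split_ditag()]: every
#' retained post-deduplication ditag contributes both of its tags, so the
#' library total is exactly twice the retained ditag count.  A run report
#' (reads seen, anchors found, ditags parsed/discarded/deduplicated) is
#' attached as attribute `report` and logged as `key=value` lines to
#' standard error.
#'
#' @param reads Named character vector of concatemer sequences (e.g. from
#'   [read_fasta()]).  Reads shorter than 24 nt are skipped with a warning.
#' @param name Library name.
#' @param min_len,max_len Ditag length window, as in [parse_ditags()].
#' @param dedup Exclude duplicate ditags (default `TRUE`).
#' @return A [tag_library()] with attribute `report`.
#' @export
extract_library <- function(reads, name = "library", min_len = 20L,
                            max_len = 24L, dedup = TRUE) {
  if (length(reads) && is.null(names(reads))) {
    names(reads) <- paste0("read", seq_along(reads))
  }
  reads <- toupper(reads)
  short <- nchar(reads) < 24L
  if (any(short)) {
    warning(sum(short), " read(s) shorter than 24 nt skipped", call. = FALSE)
    reads <- reads[!short]
  }
  anchors <- 0L
  discarded <- 0L
  ditags <- character(0)
  for (i in seq_along(reads)) {
    anchors <- anchors + length(find_anchor_sites(reads[[i]]))
    d <- parse_ditags(reads[[i]], id = names(reads)[i], min_len, max_len)
    discarded <- discarded + attr(d, "discarded")
    ditags <- c(ditags, d$sequence)
  }
  # read order must not matter: canonicalize before first-occurrence dedup
  ditags <- sort(ditags)
  n_removed <- 0L
  if (dedup) {
    dd <- dedup_ditags(ditags)
    ditags <- dd$ditags
    n_removed <- dd$n_removed
  }
  counts <- integer(0)
  if (length(ditags)) {
    tags <- split_ditag(ditags)
    tab <- table(c(tags[, 1L], tags[, 2L]))
    counts <- as.integer(tab)
    names(counts) <- names(tab)
  }
  lib <- tag_library(counts, name = name)
  report <- c(reads = length(reads), anchors = anchors,
              ditags_parsed = length(ditags) + n_removed,
              ditags_discarded = discarded, ditags_removed_dup = n_removed,
              ditags_retained = length(ditags))
  report_lines("extract_library", library = name, report)
  attr(lib, "report") <- report
  lib
}
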