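# Virtual tag-to-gene annotation.  A virtual tag database catalogues, for
# every cDNA, the 10 nucleotides immediately 3' of the 3'-most NlaIII site
# (CATG); observed tags are then annotated through an ordered cascade of
# such databases, excluding ambiguous tags (mapping to more than one gene)
# and single-copy tags.

#' Extract the virtual SAGE tag of cDNA sequences
#'
#' Returns the 10 nt immediately 3' of the 3'-most `CATG` that has at least
#' 10 downstream nucleotides.  If the 3'-most site is too close to the 3'
#' end, the next site upstream is used and flagged as a fallback (a
#' truncated cDNA record would otherwise lose its gene); strict mode
#' disables the fallback.
#'
#' @param sequence Character vector of cDNA sequences (uppercased
#'   internally).
#' @param strict If `TRUE`, only the 3'-most site is considered and
#'   sequences whose 3'-most site lacks 10 downstream nucleotides yield
#'   `NA`.
#' @return Character vector of tags (`NA` where no qualifying site exists)
#'   with a logical attribute `fallback` marking upstream-site rescues.
#' @export
#' @examples
#' extract_virtual_tag("TTTCATGACGTACGTACG")
extract_virtual_tag <- function(sequence, strict = FALSE) {
  sequence <- toupper(sequence)
  out <- rep(NA_character_, length(sequence))
  fallback <- rep(FALSE, length(sequence))
  for (i in seq_along(sequence)) {
    sites <- find_anchor_sites(sequence[i])
    if (!length(sites)) next
    room <- nchar(sequence[i]) - (sites + 4L) >= TAG_LEN
    if (strict) {
      last <- sites[length(sites)]
      if (room[length(sites)]) {
        out[i] <- substr(sequence[i], last + 5L, last + 4L + TAG_LEN)
      }
    } else if (any(room)) {
      pick <- max(which(room))
      site <- sites[pick]
      out[i] <- substr(sequence[i], site + 5L, site + 4L + TAG_LEN)
      fallback[i] <- pick < length(sites)
    }
  }
  attr(out, "fallback") <- fallback
  out
}

#' Build a virtual tag-to-gene database tier
#'
#' One entry per cDNA record with a qualifying virtual tag.  A tag hit by
#' cDNAs of more than one distinct gene symbol is flagged ambiguous;
#' multiple transcripts of the same gene sharing a tag are not.  Gene
#' identity is the whitespace-trimmed, case-sensitive symbol string.
#'
#' @param cdna Data frame with columns `transcript_id`, `gene`, `sequence`
#'   (e.g. from [simulate_transcriptome()] or a parsed cDNA FASTA with
#'   `>transcript_id|gene_symbol` headers, see [read_cdna_fasta()]).
#' @param tier_name Name recorded for this database tier.
#' @param strict Passed to [extract_virtual_tag()].
#' @return An object of class `virtual_tag_db`: list with `tier`, `entries`
#'   (data frame `tag`, `gene`, `transcript_id`, `fallback`) and
#'   `ambiguous` (named logical by tag).
#' @export
build_tag_db <- function(cdna, tier_name = "tier1", strict = FALSE) {
  stopifnot(all(c("transcript_id", "gene", "sequence") %in% names(cdna)))
  gene <- trimws(cdna$gene)
  if (any(!nzchar(gene))) {
    stop("cDNA records must carry a non-empty gene symbol", call. = FALSE)
  }
  tags <- extract_virtual_tag(cdna$sequence, strict = strict)
  keep <- !is.na(tags)
  entries <- data.frame(tag = tags[keep], gene = gene[keep],
                        transcript_id = cdna$transcript_id[keep],
                        fallback = attr(tags, "fallback")[keep],
                        stringsAsFactors = FALSE)
  entries <- unique(entries)
  entries <- entries[order(entries$tag, entries$gene, entries$transcript_id), ]
  rownames(entries) <- NULL
  n_genes <- vapply(split(entries$gene, entries$tag),
                    function(gg) length(unique(gg)), 0L)
  structure(list(tier = tier_name, entries = entries,
                 ambiguous = n_genes > 1L),
            class = "virtual_tag_db")
}

#' @export
print.virtual_tag_db <- function(x, ...) {
  cat(sprintf("Virtual tag database '%s': %d tags (%d ambiguous), %d entries\n",
              x$tier, length(x$ambiguous), sum(x$ambiguous),
              nrow(x$entries)))
  invisible(x)
}

#' Read a cDNA FASTA with `>transcript_id|gene_symbol` headers
#'
#' @param path FASTA file path.
#' @return Data frame with columns `transcript_id`, `gene`, `sequence`.
#' @export
read_cdna_fasta <- function(path) {
  seqs <- read_fasta(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  data.frame(transcript_id = trimws(vapply(parts, `[`, "", 1L)),
             gene = trimws(vapply(parts, function(p) p[min(2L, length(p))], "")),
             sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write a database tier to TSV (`tag`, `gene`, `transcript`)
#'
#' @param db A `virtual_tag_db`.
#' @param path File path.
#' @export
write_tag_db <- function(db, path) {
  stopifnot(inherits(db, "virtual_tag_db"))
  write_tsv(data.frame(tag = db$entries$tag, gene = db$entries$gene,
                       transcript = db$entries$transcript_id,
                       stringsAsFactors = FALSE), path)
}

#' Read a database tier from TSV
#'
#' Accepts the serialization of [write_tag_db()] or any pre-built
#' tag-to-gene table with columns `tag` and `gene` (optional `transcript`),
#' the form in which external annotation resources are supplied.
#'
#' @param path File path.
#' @param tier_name Name recorded for the tier; defaults to the file name.
#' @return A `virtual_tag_db`.
#' @export
read_tag_db <- function(path, tier_name = NULL) {
  df <- read_tsv(path)
  if (!all(c("tag", "gene") %in% names(df))) {
    stop("tag database table must have columns `tag` and `gene`: ", path,
         call. = FALSE)
  }
  if (is.null(tier_name)) tier_name <- sub("\\.[^.]*$", "", basename(path))
  entries <- data.frame(tag = df$tag, gene = trimws(df$gene),
                        transcript_id = if ("transcript" %in% names(df))
                          df$transcript else NA_character_,
                        fallback = FALSE, stringsAsFactors = FALSE)
  entries <- entries[order(entries$tag, entries$gene), ]
  rownames(entries) <- NULL
  n_genes <- vapply(split(entries$gene, entries$tag),
                    function(gg) length(unique(gg)), 0L)
  structure(list(tier = tier_name, entries = entries,
                 ambiguous = n_genes > 1L),
            class = "virtual_tag_db")
}

#' Annotate a tag library through prioritized database tiers
#'
#' Tags with count below `min_count` are excluded outright (single-copy
#' exclusion at the default `min_count = 2`) and not searched.  Remaining
#' tags are looked up tier by tier in priority order: the first tier
#' containing the tag decides.  An unambiguous hit assigns the gene; an
#' ambiguous hit (tag mapping to several genes) is final and does **not**
#' fall through to later tiers — re-interpreting an ambiguous tag with a
#' lower-priority source would silently overrule the exclusion.  Tags
#' absent from every tier are unmapped.
#'
#' @param library A [tag_library()].
#' @param tiers A `virtual_tag_db` or non-empty list of them, highest
#'   priority first.
#' @param min_count Minimum per-library tag count searched (default 2).
#' @return Data frame with columns `tag`, `count`, `status` (one of
#'   `assigned`, `ambiguous`, `unmapped`, `excluded_single_copy`), `gene`
#'   and `tier`; one row per tag in the library.
#' @export
annotate_tags <- function(library, tiers, min_count = 2L) {
  stopifnot(inherits(library, "tag_library"))
  if (inherits(tiers, "virtual_tag_db")) tiers <- list(tiers)
  if (!length(tiers)) stop("`tiers` must be a non-empty list", call. = FALSE)
  stopifnot(all(vapply(tiers, inherits, TRUE, "virtual_tag_db")))
  if (!is_count_scalar(min_count) || min_count < 1) {
    stop("`min_count` must be an integer >= 1", call. = FALSE)
  }
  tags <- names(library$counts)
  counts <- unname(library$counts)
  status <- rep("unmapped", length(tags))
  gene <- rep(NA_character_, length(tags))
  tier <- rep(NA_character_, length(tags))
  low <- counts < min_count
  status[low] <- "excluded_single_copy"
  open <- which(!low)
  for (db in tiers) {
    if (!length(open)) break
    hit <- match(tags[open], names(db$ambiguous))
    found <- !is.na(hit)
    if (!any(found)) next
    idx <- open[found]
    amb <- db$ambiguous[hit[found]]
    status[idx] <- ifelse(amb, "ambiguous", "assigned")
    tier[idx] <- db$tier
    uni <- idx[!amb]
    if (length(uni)) {
      first_gene <- vapply(split(db$entries$gene, db$entries$tag),
                           `[`, "", 1L)
      gene[uni] <- first_gene[tags[uni]]
    }
    open <- open[!found]
  }
  data.frame(tag = tags, count = counts, status = status, gene = gene,
             tier = tier, stringsAsFactors = FALSE)
}
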