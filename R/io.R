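# Shared readers/writers.  One TSV dialect throughout: tab-separated, single
# header line, UTF-8, NA for missing, no quoting.

write_tsv <- function(df, path) {
  if (is.character(path)) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA", fileEncoding = "UTF-8")
  } else {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
  }
  invisible(path)
}

read_tsv <- function(path, ...) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

#' Read and write FASTA files
#'
#' Sequences are handled as named character vectors; names are the full FASTA
#' headers.  Reading uppercases sequences, as required by the tag extractor.
#'
#' @param path File path.
#' @param seqs Named character vector of sequences.
#' @return `read_fasta()` returns a named character vector; `write_fasta()`
#'   returns `path` invisibly.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- names(set)
  out
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(unname(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read and write tag-count tables
#'
#' Tag-count tables are two-column TSV files (`tag`, `count`) with one header
#' line, the on-disk form of a [tag_library()].
#'
#' @param path File path.
#' @param lib A `tag_library`.
#' @param name Library name; defaults to the file name without extension.
#' @return `read_tag_counts()` returns a `tag_library`; `write_tag_counts()`
#'   returns `path` invisibly.
#' @export
read_tag_counts <- function(path, name = NULL) {
  df <- read_tsv(path)
  if (!all(c("tag", "count") %in% names(df))) {
    stop("tag-count table must have columns `tag` and `count`: ", path,
         call. = FALSE)
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  counts <- as.integer(df$count)
  names(counts) <- df$tag
  tag_library(counts, name = name)
}

#' @rdname read_tag_counts
#' @export
write_tag_counts <- function(lib, path) {
  stopifnot(inherits(lib, "tag_library"))
  write_tsv(data.frame(tag = names(lib$counts), count = unname(lib$counts),
                       stringsAsFactors = FALSE), path)
}

#' Read a gene-set file
#'
#' One symbol per line; blank lines and `#` comments are ignored.
#'
#' @param path File path.
#' @param name Set name; defaults to the file name without extension.
#' @return A [gene_set()].
#' @export
read_gene_set <- function(path, name = NULL) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  gene_set(lines, name = name)
}

#' Read a human expression table
#'
#' TSV with columns `gene`, `logFC`, `q`, `compartment` (values
#' `glomerulus` or `tubulointerstitium`), as consumed by
#' [concordance_table()].
#'
#' @param path File path.
#' @return A data frame with the four columns above.
#' @export
read_human_expression <- function(path) {
  df <- read_tsv(path)
  need <- c("gene", "logFC", "q", "compartment")
  if (!all(need %in% names(df))) {
    stop("human expression table must have columns ",
         paste(need, collapse = ", "), ": ", path, call. = FALSE)
  }
  df[need]
}

#' Plain-text key-value run configuration files
#'
#' Serializes a flat named list to `key = value` lines and back.  Vector
#' values are comma-separated; types are restored heuristically (numbers as
#' numeric, `TRUE`/`FALSE` as logical, everything else as character), so that
#' a write/read round trip is the identity for configurations made of
#' numbers, flags and strings.
#'
#' @param config Named list of scalar or vector values.
#' @param path File path.
#' @return `read_run_config()` returns a named list; `write_run_config()`
#'   returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)), all(nzchar(names(config))))
  vals <- vapply(config, function(v)
    paste(format(v, scientific = FALSE, trim = TRUE), collapse = ","),
    FUN.VALUE = character(1))
  writeLines(paste(names(config), vals, sep = " = "), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  eq <- regexpr("=", lines, fixed = TRUE)
  if (any(eq < 0L)) stop("malformed config line: ", lines[eq < 0L][1],
                         call. = FALSE)
  keys <- trimws(substr(lines, 1L, eq - 1L))
  vals <- trimws(substr(lines, eq + 1L, nchar(lines)))
  parse_one <- function(v) {
    parts <- trimws(strsplit(v, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) {
      if (all(num == round(num)) && all(abs(num) < .Machine$integer.max)) {
        return(as.integer(num))
      }
      return(num)
    }
    if (all(parts %in% c("TRUE", "FALSE"))) return(as.logical(parts))
    parts
  }
  out <- lapply(vals, parse_one)
  names(out) <- keys
  out
}
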