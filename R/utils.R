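#' @importFrom stats cor dhyper p.adjust phyper pnorm rbinom rmultinom runif
#' @importFrom utils read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")
ANCHOR <- "CATG"
TAG_LEN <- 10L

#' Reverse complement of DNA strings
#'
#' Thin vectorized wrapper around [Biostrings::reverseComplement()] returning
#' plain character vectors, convenient for 10-nt SAGE tags and 20-nt ditags.
#'
#' @param x Character vector of DNA sequences over `A`, `C`, `G`, `T`, `N`.
#' @return Character vector of reverse complements, same length as `x`.
#' @export
#' @examples
#' revcomp(c("CATG", "GGGGGGGGGG"))
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# stop() with the offending field name, used by config validation
fail_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

is_count_scalar <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == round(x)
}

# key=value run-report lines on stderr, silenced via suppressMessages()
report_lines <- function(event, ...) {
  kv <- c(...)
  if (length(kv)) {
    kv <- paste(names(kv), unname(kv), sep = "=", collapse = " ")
    message(sprintf("event=%s %s", event, kv))
  } else {
    message(sprintf("event=%s", event))
  }
}

# uniform random DNA strings of length `len`
random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = len)
  apply(m, 2L, paste0, collapse = "")
}

# destroy every CATG occurrence in `x` by mutating its final G; loops because
# a mutation can in principle create a new site upstream
scrub_anchor <- function(x) {
  repeat {
    hit <- regexpr(ANCHOR, x, fixed = TRUE)
    idx <- which(hit > 0L)
    if (!length(idx)) return(x)
    pos <- hit[idx] + 3L
    substr(x[idx], pos, pos) <- sample(c("A", "C", "T"), length(idx),
                                       replace = TRUE)
  }
}
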