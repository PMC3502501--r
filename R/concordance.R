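# Gene-set intersection, enrichment and cross-species concordance: the
# downstream identification of glomerular genes among the differentially
# expressed tags, and their comparison against compartment-resolved human
# biopsy expression.

#' Construct a gene set
#'
#' Symbols are whitespace-trimmed and deduplicated case-insensitively
#' (first-seen casing preserved); matching everywhere in the package is
#' case-insensitive exact string comparison, with no orthology inference.
#'
#' @param symbols Character vector of gene symbols.
#' @param name Set name.
#' @return An object of class `gene_set` with elements `name` and
#'   `symbols`.
#' @export
gene_set <- function(symbols, name = "set") {
  symbols <- trimws(as.character(symbols))
  symbols <- symbols[nzchar(symbols) & !is.na(symbols)]
  symbols <- symbols[!duplicated(toupper(symbols))]
  structure(list(name = name, symbols = symbols), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("Gene set '%s': %d symbols\n", x$name, length(x$symbols)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$symbols)

#' Intersect gene sets
#'
#' Case-insensitive intersection of two or more sets; the returned casing
#' is the first set's.
#'
#' @param ... Two or more [gene_set()] objects (or one list of them).
#' @return A [gene_set()] named by concatenating the input names.
#' @export
intersect_gene_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1]], "gene_set")) {
    sets <- sets[[1]]
  }
  stopifnot(all(vapply(sets, inherits, TRUE, "gene_set")))
  if (length(sets) < 2L) {
    stop("intersection needs at least 2 gene sets", call. = FALSE)
  }
  keep <- sets[[1]]$symbols
  for (s in sets[-1]) {
    keep <- keep[toupper(keep) %in% toupper(s$symbols)]
  }
  gene_set(keep, name = paste(vapply(sets, `[[`, "", "name"),
                              collapse = " & "))
}

#' Right-tailed hypergeometric set enrichment
#'
#' Probability of observing at least the realized overlap between a
#' selected gene set and an annotation set when `|selected|` genes are
#' drawn from the universe without replacement — the right-tailed Fisher
#' exact test used to score functional enrichment.
#'
#' @param selected,annotation,universe [gene_set()] objects;
#'   `selected` and `annotation` must be subsets of `universe`
#'   (case-insensitively).
#' @return Right-tailed p-value.
#' @export
enrichment_fisher <- function(selected, annotation, universe) {
  stopifnot(inherits(selected, "gene_set"), inherits(annotation, "gene_set"),
            inherits(universe, "gene_set"))
  uni <- toupper(universe$symbols)
  sel <- toupper(selected$symbols)
  ann <- toupper(annotation$symbols)
  if (!all(sel %in% uni)) {
    stop("`selected` is not a subset of `universe`", call. = FALSE)
  }
  if (!all(ann %in% uni)) {
    stop("`annotation` is not a subset of `universe`", call. = FALSE)
  }
  overlap <- sum(sel %in% ann)
  phyper(overlap - 1, length(ann), length(uni) - length(ann), length(sel),
         lower.tail = FALSE)
}

#' Direction of a two-library tag contrast from raw counts
#'
#' `"up"` iff the raw count in library 1 (the disease-model analog) exceeds
#' that in library 2; ties classify `"down"`.  This raw-count rule with
#' ties down is the classification that reproduces the published 53
#' up / 14 down tally for the glomerular gene table, whose one tied gene is
#' counted as downregulated.
#'
#' @param x_raw,y_raw Non-negative integer counts (vectors recycle).
#' @return Character vector of `"up"`/`"down"`.
#' @export
#' @examples
#' classify_direction(54, 14)  # up
#' classify_direction(14, 14)  # down (tie rule)
classify_direction <- function(x_raw, y_raw) {
  if (any(x_raw < 0) || any(y_raw < 0) ||
      any(x_raw != round(x_raw)) || any(y_raw != round(y_raw))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  ifelse(x_raw > y_raw, "up", "down")
}

#' Cross-species concordance against a human expression table
#'
#' Matches mouse differential-expression records to a compartment-resolved
#' human expression table (gene, logFC versus control, FDR q-value,
#' compartment) by case-insensitive symbol.  A matched record is concordant
#' when the mouse direction and the sign of the human logFC agree
#' (`logFC = 0` has no sign and is never concordant), and significant when
#' `q <= q_threshold` (inclusive).  Mouse genes absent from the human table
#' are reported separately as "not spotted" and excluded from the
#' denominators.
#'
#' @param mouse_records Data frame with columns `gene` and `direction`
#'   (e.g. a [sage_dge()] table or a fixture-derived frame); rows without a
#'   gene symbol are dropped.
#' @param human_records Data frame with columns `gene`, `logFC`, `q`,
#'   `compartment`; at most one row per (gene, compartment).
#' @param q_threshold Significance boundary on q (default 0.05,
#'   inclusive).
#' @return Data frame with one row per matched (gene, compartment):
#'   `gene`, `mouse_direction`, `logFC`, `q`, `compartment`, `concordant`,
#'   `significant`.  Attributes: `not_spotted` (unmatched mouse genes) and
#'   `summary` (named counts: matched, concordant,
#'   concordant_significant, and per-compartment concordant counts).
#' @export
concordance_table <- function(mouse_records, human_records,
                              q_threshold = 0.05) {
  stopifnot(all(c("gene", "direction") %in% names(mouse_records)),
            all(c("gene", "logFC", "q", "compartment") %in%
                  names(human_records)))
  if (any(human_records$q < 0 | human_records$q > 1, na.rm = TRUE)) {
    stop("human q-values must lie in [0, 1]", call. = FALSE)
  }
  key <- paste(toupper(trimws(human_records$gene)),
               human_records$compartment)
  if (anyDuplicated(key)) {
    stop("duplicate (gene, compartment) in human table: ",
         human_records$gene[duplicated(key)][1], call. = FALSE)
  }
  mouse <- mouse_records[!is.na(mouse_records$gene) &
                           nzchar(trimws(mouse_records$gene)), ]
  mkey <- toupper(trimws(mouse$gene))
  hkey <- toupper(trimws(human_records$gene))
  hit <- match(hkey, mkey)
  matched <- which(!is.na(hit))
  dir <- mouse$direction[hit[matched]]
  lfc <- human_records$logFC[matched]
  rec <- data.frame(gene = human_records$gene[matched],
                    mouse_direction = dir,
                    logFC = lfc,
                    q = human_records$q[matched],
                    compartment = human_records$compartment[matched],
                    stringsAsFactors = FALSE)
  rec$concordant <- (rec$mouse_direction == "up" & rec$logFC > 0) |
    (rec$mouse_direction == "down" & rec$logFC < 0)
  rec$significant <- rec$q <= q_threshold
  not_spotted <- unique(mouse$gene[!(mkey %in% hkey)])
  summ <- c(matched = nrow(rec),
            concordant = sum(rec$concordant),
            concordant_significant = sum(rec$concordant & rec$significant),
            significant = sum(rec$significant))
  for (comp in unique(rec$compartment)) {
    summ[paste0("concordant_", comp)] <-
      sum(rec$concordant & rec$compartment == comp)
  }
  report_lines("concordance_table", summ,
               not_spotted = length(not_spotted))
  attr(rec, "not_spotted") <- not_spotted
  attr(rec, "summary") <- summ
  rec
}

#' Count significant records
#'
#' Number of records with `q <= q_threshold` (inclusive boundary, so a
#' record printed exactly at the threshold counts).
#'
#' @param records Data frame with a `q` column (e.g. from
#'   [concordance_table()] or a fixture).
#' @param q_threshold Threshold (default 0.05).
#' @return Integer count.
#' @export
count_significant <- function(records, q_threshold = 0.05) {
  stopifnot("q" %in% names(records))
  sum(records$q <= q_threshold, na.rm = TRUE)
}
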