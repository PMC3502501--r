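#' Packaged reference tables from the mouse kidney SAGE comparison
#'
#' Verbatim transcriptions of the published summary tables of the
#' sclerosis-prone (ROP-Os/+) versus sclerosis-resistant (C57-Os/+) kidney
#' SAGE comparison, shipped as plain TSV under `inst/extdata`:
#'
#' * `"T1"` — library sizes: per-strain total and unique tag counts.
#' * `"T2"` — the 50 most significant differentially expressed annotated
#'   tags (`tag`, `rop_os`, `c57_os`, `p_value`, `gene_symbol`,
#'   `gene_name`).
#' * `"T3"` — the 67 differentially expressed glomerular genes
#'   (`gene_symbol`, `rop_os`, `c57_os`, `p_value`).
#' * `"T5"` — transcripts compared against micro-dissected human FSGS
#'   biopsies: scaled mouse counts plus human log fold change and q-value
#'   per compartment (17 rows with a glomerular gene and one
#'   tubulointerstitium-only row).
#'
#' The transcriptions are data, not corrections: internal inconsistencies of
#' the printed tables (duplicated genes under different counts, p-values
#' that no single two-library test reproduces, a tag annotated with
#' mismatched symbol and name) are preserved as printed.  Printed p-values
#' are kept as character strings to avoid reformatting them.
#'
#' @param table_id One of `"T1"`, `"T2"`, `"T3"`, `"T5"`.
#' @return A data frame; columns as described above.
#' @export
#' @examples
#' sage_fixture("T1")
sage_fixture <- function(table_id) {
  files <- c(T1 = "table1.tsv", T2 = "table2.tsv", T3 = "table3.tsv",
             T5 = "table5.tsv")
  if (length(table_id) != 1L || !table_id %in% names(files)) {
    stop("unknown fixture table id: ", paste(table_id, collapse = ", "),
         " (expected one of T1, T2, T3, T5)", call. = FALSE)
  }
  path <- system.file("extdata", files[[table_id]], package = "sagedge",
                      mustWork = TRUE)
  col <- switch(table_id,
    T1 = c(library = "character", total_tags = "integer",
           unique_tags = "integer"),
    T2 = c(tag = "character", rop_os = "integer", c57_os = "integer",
           p_value = "character", gene_symbol = "character",
           gene_name = "character"),
    T3 = c(gene_symbol = "character", rop_os = "integer",
           c57_os = "integer", p_value = "character"),
    T5 = c(rop_count = "numeric", c57_count = "numeric",
           glom_gene = "character", glom_logfc = "numeric",
           glom_q = "numeric", tub_gene = "character",
           tub_logfc = "numeric", tub_q = "numeric"))
  read_tsv(path, colClasses = unname(col))
}

#' Human expression records from the packaged cross-species table
#'
#' Reshapes the `"T5"` fixture into the long per-compartment form consumed
#' by [concordance_table()]: one row per (gene, compartment) with `logFC`
#' and `q`.
#'
#' @param compartment `"glomerulus"`, `"tubulointerstitium"` or `"both"`
#'   (default).
#' @return A data frame with columns `gene`, `logFC`, `q`, `compartment`.
#' @export
fixture_human_expression <- function(compartment = c("both", "glomerulus",
                                                     "tubulointerstitium")) {
  compartment <- match.arg(compartment)
  t5 <- sage_fixture("T5")
  glom <- data.frame(gene = t5$glom_gene, logFC = t5$glom_logfc,
                     q = t5$glom_q, compartment = "glomerulus",
                     stringsAsFactors = FALSE)
  glom <- glom[!is.na(glom$gene), ]
  tub <- data.frame(gene = t5$tub_gene, logFC = t5$tub_logfc, q = t5$tub_q,
                    compartment = "tubulointerstitium",
                    stringsAsFactors = FALSE)
  tub <- tub[!is.na(tub$gene), ]
  out <- switch(compartment, both = rbind(glom, tub), glomerulus = glom,
                tubulointerstitium = tub)
  rownames(out) <- NULL
  out
}
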