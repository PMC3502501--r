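# Synthetic comparative-SAGE data with a ground-truth ledger.  The generator
# emulates a pair of pooled kidney libraries: a heavy-tailed (Zipf) transcript
# abundance law, a designated subset of differentially expressed genes with
# exact fold changes, cDNA records from which virtual tags can be extracted,
# and concatemer reads carrying PCR-duplicate ditags.

#' Configuration for the synthetic SAGE generator
#'
#' Defaults emulate the reference two-library comparison: totals of 22,989
#' and 26,599 tags and roughly 10,000 unique tags per library, with the top
#' tag in the high hundreds and a long tail of singletons.
#'
#' @param n_genes Number of genes in the synthetic transcriptome.
#' @param zipf_exponent Exponent of the Zipf abundance law over gene ranks
#'   (> 0; larger means steeper).
#' @param library_totals Integer pair `(N1, N2)`: exact tag totals of the
#'   two libraries.
#' @param frac_differential Proportion of genes labelled differentially
#'   expressed (in `[0, 1)`; `round(frac_differential * n_genes)` genes).
#' @param fold_changes Fold changes (> 1) assigned cyclically to the
#'   differential genes, which alternate up/down.
#' @param duplicate_ditag_rate Proportion of emitted ditags duplicated
#'   verbatim, modelling PCR amplification artifacts (in `[0, 1)`).
#' @param ambiguous_tag_fraction Proportion of genes sharing a tag pairwise
#'   with another gene (in `[0, 1)`; rounded down to an even gene count).
#' @param tagless_gene_fraction Proportion of genes whose cDNA carries no
#'   anchor site and therefore no tag (in `[0, 1)`).
#' @param cdna_length_range Integer pair: cDNA length bounds (min >= 30 nt).
#' @param seed Integer seed; every stochastic draw flows from it.
#' @return An object of class `sage_sim_config`.
#' @export
sage_sim_config <- function(n_genes = 30000L,
                            zipf_exponent = 0.8,
                            library_totals = c(22989L, 26599L),
                            frac_differential = 0.01,
                            fold_changes = c(4, 2),
                            duplicate_ditag_rate = 0.05,
                            ambiguous_tag_fraction = 0.02,
                            tagless_gene_fraction = 0.01,
                            cdna_length_range = c(200L, 1500L),
                            seed = 1L) {
  if (!is_count_scalar(n_genes) || n_genes < 1) {
    fail_field("n_genes", "must be a positive integer")
  }
  if (!is.numeric(zipf_exponent) || length(zipf_exponent) != 1L ||
      is.na(zipf_exponent) || zipf_exponent <= 0) {
    fail_field("zipf_exponent", "must be a real > 0")
  }
  if (length(library_totals) != 2L ||
      !all(vapply(library_totals, is_count_scalar, TRUE)) ||
      any(library_totals < 1)) {
    fail_field("library_totals", "must be a pair of positive integers")
  }
  check_prop <- function(x, field, closed_top = FALSE) {
    hi_ok <- if (closed_top) x <= 1 else x < 1
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || !hi_ok) {
      fail_field(field, sprintf("must be a proportion in [0, 1%s",
                                if (closed_top) "]" else ")"))
    }
  }
  # frac_differential = 1 is rejected: fold changes are imposed exactly by
  # renormalizing the null genes, so some null mass must remain
  check_prop(frac_differential, "frac_differential")
  check_prop(duplicate_ditag_rate, "duplicate_ditag_rate")
  check_prop(ambiguous_tag_fraction, "ambiguous_tag_fraction")
  # a fully tagless transcriptome is a legal degenerate case (no library
  # can be drawn from it, but the ledger and cDNA are well defined)
  check_prop(tagless_gene_fraction, "tagless_gene_fraction",
             closed_top = TRUE)
  if (!is.numeric(fold_changes) || length(fold_changes) < 1L ||
      any(is.na(fold_changes)) || any(fold_changes <= 1)) {
    fail_field("fold_changes", "must be a non-empty list of reals > 1")
  }
  if (length(cdna_length_range) != 2L ||
      !all(vapply(cdna_length_range, is_count_scalar, TRUE)) ||
      cdna_length_range[1] < 30 ||
      cdna_length_range[1] > cdna_length_range[2]) {
    fail_field("cdna_length_range",
               "must be an increasing integer pair with min >= 30")
  }
  if (!is_count_scalar(seed)) fail_field("seed", "must be an integer")
  structure(list(n_genes = as.integer(n_genes),
                 zipf_exponent = as.numeric(zipf_exponent),
                 library_totals = as.integer(library_totals),
                 frac_differential = frac_differential,
                 fold_changes = as.numeric(fold_changes),
                 duplicate_ditag_rate = duplicate_ditag_rate,
                 ambiguous_tag_fraction = ambiguous_tag_fraction,
                 tagless_gene_fraction = tagless_gene_fraction,
                 cdna_length_range = as.integer(cdna_length_range),
                 seed = as.integer(seed)),
            class = "sage_sim_config")
}

#' @export
print.sage_sim_config <- function(x, ...) {
  cat("Synthetic SAGE configuration\n")
  for (f in names(x)) {
    cat(sprintf("  %-24s %s\n", f, paste(x[[f]], collapse = ", ")))
  }
  invisible(x)
}

# Tags are drawn without an internal CATG and without a terminal "C" or
# "CA", which guarantees that no ditag (tagA + revcomp(tagB)) can contain an
# anchor site across the ligation junction -- parsing then round-trips the
# generator's ledger exactly.
random_tags <- function(n, existing = character(0)) {
  out <- character(0)
  while (length(out) < n) {
    cand <- random_dna(2L * (n - length(out)) + 8L, TAG_LEN)
    ok <- !grepl(ANCHOR, cand, fixed = TRUE) &
      substr(cand, 10L, 10L) != "C" &
      substr(cand, 9L, 10L) != "CA"
    cand <- cand[ok]
    cand <- setdiff(unique(cand), c(existing, out))
    out <- c(out, cand)
  }
  out[seq_len(n)]
}

#' Generate the gene-level ground truth
#'
#' Builds the ground-truth ledger without realizing cDNA sequences: gene to
#' tag assignments (including deliberate pairwise tag sharing and tagless
#' genes), per-library expression proportions under the Zipf law, and
#' differential labels with exact fold changes.  [simulate_transcriptome()]
#' adds the sequences; both are deterministic functions of the
#' configuration.
#'
#' @param config A [sage_sim_config()].
#' @return An object of class `sage_truth`: a list with `config` and a data
#'   frame `genes` (columns `gene`, `tag`, `label`, `fold_change`, `prop1`,
#'   `prop2`).  Tagless genes have `tag = NA`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sage_sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  gene <- sprintf("Gene%05d", seq_len(n))

  n_tagless <- round(config$tagless_gene_fraction * n)
  tagless <- sample(n, n_tagless)
  tagged <- setdiff(seq_len(n), tagless)

  n_amb <- round(config$ambiguous_tag_fraction * n)
  n_amb <- n_amb - n_amb %% 2L
  if (n_amb > length(tagged)) {
    fail_field("ambiguous_tag_fraction",
               "requests more shared-tag genes than tagged genes")
  }
  amb <- sample(tagged, n_amb)

  tag <- rep(NA_character_, n)
  n_distinct <- length(tagged) - n_amb / 2L
  pool <- random_tags(n_distinct)
  solo <- setdiff(tagged, amb)
  tag[solo] <- pool[seq_along(solo)]
  if (n_amb > 0L) {
    shared <- pool[length(solo) + seq_len(n_amb / 2L)]
    tag[amb] <- rep(shared, each = 2L)
  }

  # Zipf abundance over a random permutation of gene ranks
  z <- sample(seq_len(n))^(-config$zipf_exponent)
  z <- z / sum(z)

  n_diff <- round(config$frac_differential * n)
  eligible <- solo  # differential labels go to genes with a private tag
  if (n_diff > length(eligible)) {
    fail_field("frac_differential",
               "requests more differential genes than unshared tagged genes")
  }
  diff_idx <- sample(eligible, n_diff)
  label <- rep("null", n)
  fc <- rep(NA_real_, n)
  prop1 <- prop2 <- z
  if (n_diff > 0L) {
    up <- diff_idx[seq_len(n_diff) %% 2L == 1L]
    dn <- diff_idx[seq_len(n_diff) %% 2L == 0L]
    label[up] <- "up"
    label[dn] <- "down"
    fc[diff_idx] <- rep_len(config$fold_changes, n_diff)
    s <- sqrt(fc[diff_idx])
    sgn <- ifelse(label[diff_idx] == "up", 1, -1)
    prop1[diff_idx] <- z[diff_idx] * s^sgn
    prop2[diff_idx] <- z[diff_idx] / s^sgn
  }
  null_idx <- which(label == "null")
  c1 <- (1 - sum(prop1[-null_idx])) / sum(z[null_idx])
  c2 <- (1 - sum(prop2[-null_idx])) / sum(z[null_idx])
  if (length(null_idx) < n) {
    if (c1 <= 0 || c2 <= 0) {
      fail_field("frac_differential",
                 "differential mass exceeds the library; lower it or the fold changes")
    }
    prop1[null_idx] <- z[null_idx] * c1
    prop2[null_idx] <- z[null_idx] * c2
  }

  genes <- data.frame(gene = gene, tag = tag, label = label,
                      fold_change = fc, prop1 = prop1, prop2 = prop2,
                      stringsAsFactors = FALSE)
  structure(list(config = config, genes = genes), class = "sage_truth")
}

#' @export
print.sage_truth <- function(x, ...) {
  g <- x$genes
  shared <- !is.na(g$tag) &
    (duplicated(g$tag, incomparables = NA) |
       duplicated(g$tag, fromLast = TRUE, incomparables = NA))
  cat(sprintf(paste0("Synthetic SAGE ground truth: %d genes ",
                     "(%d tagless, %d sharing tags, %d up, %d down)\n"),
              nrow(g), sum(is.na(g$tag)), sum(shared),
              sum(g$label == "up"), sum(g$label == "down")))
  invisible(x)
}

#' Generate a synthetic cDNA transcriptome
#'
#' Realizes one cDNA record per gene.  For tagged genes the sequence is
#' built so that the 3'-most anchor site (`CATG`) with at least 10
#' downstream nucleotides is immediately followed by the gene's ground-truth
#' tag; upstream anchor sites may occur freely, as in real cDNA.  Tagless
#' genes carry no anchor site at all.
#'
#' @param config A [sage_sim_config()].
#' @return A list with `cdna` (data frame: `transcript_id`, `gene`,
#'   `sequence`) and `truth` (the [simulate_truth()] ledger).
#' @export
simulate_transcriptome <- function(config) {
  truth <- simulate_truth(config)
  set.seed(config$seed + 1L)
  g <- truth$genes
  n <- nrow(g)
  len <- sample(seq(config$cdna_length_range[1], config$cdna_length_range[2]),
                n, replace = TRUE)
  seqs <- character(n)
  tagged <- !is.na(g$tag)
  for (i in seq_len(n)) {
    if (tagged[i]) {
      tail_len <- sample(0:30, 1L)
      prefix_len <- max(len[i] - 14L - tail_len, 10L)
      prefix <- random_dna(1L, prefix_len)
      body <- paste0(g$tag[i], scrub_anchor(random_dna(1L, tail_len)))
      # a site can still straddle the tag|tail boundary; its final G is
      # always in the tail, so mutating it never touches the tag
      repeat {
        p <- regexpr(ANCHOR, body, fixed = TRUE)
        if (p < 0L) break
        substr(body, p + 3L, p + 3L) <- sample(c("A", "C", "T"), 1L)
      }
      seqs[i] <- paste0(prefix, ANCHOR, body)
    } else {
      seqs[i] <- scrub_anchor(random_dna(1L, len[i]))
    }
  }
  cdna <- data.frame(transcript_id = paste0(g$gene, ".1"), gene = g$gene,
                     sequence = seqs, stringsAsFactors = FALSE)
  list(cdna = cdna, truth = truth)
}

#' Draw paired tag-count libraries from the ground truth
#'
#' Each library is a single multinomial draw of exactly
#' `config$library_totals` tags over the tagged genes' renormalized true
#' proportions (pooled-library design: no per-animal replication).  Counts
#' of genes sharing a tag accumulate on that tag.
#'
#' @param config The [sage_sim_config()] used to produce `truth`.
#' @param truth The matching [simulate_truth()] ledger.
#' @return A list with `lib1` and `lib2` ([tag_library()] objects named
#'   `"library1"`/`"library2"`) and `gene_counts`, a genes-by-2 integer
#'   matrix of the underlying per-gene draws (rownames are gene ids).
#' @export
simulate_tag_counts <- function(config, truth) {
  stopifnot(inherits(config, "sage_sim_config"), inherits(truth, "sage_truth"))
  if (!identical(unclass(truth$config), unclass(config))) {
    stop("`truth` was generated under a different configuration", call. = FALSE)
  }
  set.seed(config$seed + 2L)
  g <- truth$genes
  tagged <- which(!is.na(g$tag))
  if (!length(tagged)) stop("no tagged genes to sample from", call. = FALSE)
  gene_counts <- matrix(0L, nrow = length(tagged), ncol = 2L,
                        dimnames = list(g$gene[tagged], c("lib1", "lib2")))
  libs <- vector("list", 2L)
  for (l in 1:2) {
    p <- g[[paste0("prop", l)]][tagged]
    draw <- rmultinom(1L, config$library_totals[l], p / sum(p))[, 1L]
    gene_counts[, l] <- as.integer(draw)
    counts <- draw
    names(counts) <- g$tag[tagged]
    libs[[l]] <- tag_library(counts, name = paste0("library", l))
  }
  list(lib1 = libs[[1]], lib2 = libs[[2]], gene_counts = gene_counts)
}

#' Assemble concatemer reads from tag-count libraries
#'
#' Tags are drawn without replacement from the library multiset and ligated
#' pairwise into 20-nt ditags (`tagA` followed by the reverse complement of
#' `tagB`); an odd leftover tag is paired with a random filler tag recorded
#' in the ledger.  Duplicate ditags are then injected at
#' `duplicate_ditag_rate` (verbatim copies of already-emitted ditags,
#' modelling PCR amplification of a ligation product), and the ditag pool is
#' packed into concatemer reads of the form
#' `CATG | ditag | CATG | ditag | ... | CATG`.
#'
#' @param lib1,lib2 [tag_library()] objects (e.g. from
#'   [simulate_tag_counts()]).
#' @param config The [sage_sim_config()] carrying the seed and duplicate
#'   rate.
#' @param ditags_per_read Integer range of ditags packed into one read.
#' @return A list with one element per library, each a list of `reads`
#'   (named character vector), `ledger` (the emitted ditag multiset before
#'   duplication), `injected_duplicates` (count) and `filler_tag` (the
#'   filler tag or `NA`).
#' @export
simulate_concatemers <- function(lib1, lib2, config,
                                 ditags_per_read = c(10L, 40L)) {
  stopifnot(inherits(lib1, "tag_library"), inherits(lib2, "tag_library"),
            inherits(config, "sage_sim_config"))
  set.seed(config$seed + 3L)
  out <- list()
  for (l in 1:2) {
    lib <- if (l == 1L) lib1 else lib2
    tags <- rep(names(lib$counts), lib$counts)
    if (any(!grepl("^[ACGT]{10}$", tags))) {
      stop("library tags must be 10 nt over ACGT", call. = FALSE)
    }
    tags <- sample(tags)
    filler <- NA_character_
    if (length(tags) %% 2L == 1L) {
      filler <- random_tags(1L, existing = names(lib$counts))
      tags <- c(tags, filler)
    }
    half <- length(tags) / 2L
    ditags <- paste0(tags[seq_len(half)], revcomp(tags[half + seq_len(half)]))
    n_inject <- round(config$duplicate_ditag_rate * length(ditags))
    injected <- if (n_inject > 0L) sample(ditags, n_inject, replace = TRUE)
                else character(0)
    pool <- sample(c(ditags, injected))
    reads <- character(0)
    while (length(pool)) {
      k <- min(sample(seq(ditags_per_read[1], ditags_per_read[2]), 1L),
               length(pool))
      reads <- c(reads, paste0(ANCHOR, paste(pool[seq_len(k)],
                                             collapse = ANCHOR), ANCHOR))
      pool <- pool[-seq_len(k)]
    }
    names(reads) <- sprintf("%s_read%05d", lib$name, seq_along(reads))
    out[[lib$name]] <- list(reads = reads, ledger = ditags,
                            injected_duplicates = n_inject,
                            filler_tag = filler)
  }
  out
}

#' Tag counts implied by a ditag ledger after duplicate collapsing
#'
#' Companion oracle to [simulate_concatemers()]: collapses the emitted ditag
#' multiset to unique sequences (exactly what duplicate-ditag exclusion
#' recovers at zero sequencing error) and counts both tags of each.
#'
#' @param ledger Character vector of emitted ditags.
#' @param name Library name for the returned [tag_library()].
#' @return A [tag_library()].
#' @export
ledger_tag_counts <- function(ledger, name = "ledger") {
  ditags <- unique(ledger)
  if (!length(ditags)) return(tag_library(integer(0), name = name))
  tags <- split_ditag(ditags)
  tab <- table(c(tags[, 1L], tags[, 2L]))
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  tag_library(counts, name = name)
}

#' Run the full synthetic pipeline input generation
#'
#' Convenience wrapper: ground truth, cDNA transcriptome, paired tag counts
#' and concatemer reads from one configuration.
#'
#' @param config A [sage_sim_config()].
#' @param concatemers Also assemble concatemer reads (default `TRUE`; the
#'   slowest step at large library totals).
#' @param transcriptome Also realize cDNA sequences (default `TRUE`).
#' @return A list with `truth`, `cdna` (or `NULL`), `counts` (from
#'   [simulate_tag_counts()]) and `concatemers` (or `NULL`).
#' @export
sage_simulate <- function(config, concatemers = TRUE, transcriptome = TRUE) {
  cdna <- NULL
  if (transcriptome) {
    tr <- simulate_transcriptome(config)
    truth <- tr$truth
    cdna <- tr$cdna
  } else {
    truth <- simulate_truth(config)
  }
  counts <- simulate_tag_counts(config, truth)
  conc <- if (concatemers) {
    simulate_concatemers(counts$lib1, counts$lib2, config)
  }
  list(truth = truth, cdna = cdna, counts = counts, concatemers = conc)
}
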