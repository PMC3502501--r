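# The synthetic-data generator and its ground-truth ledger.

test_that("configuration validation names the offending field", {
  expect_error(sage_sim_config(n_genes = 0), "n_genes")
  expect_error(sage_sim_config(zipf_exponent = -1), "zipf_exponent")
  expect_error(sage_sim_config(library_totals = c(10, 0)), "library_totals")
  expect_error(sage_sim_config(frac_differential = 1), "frac_differential")
  expect_error(sage_sim_config(fold_changes = c(2, 1)), "fold_changes")
  expect_error(sage_sim_config(duplicate_ditag_rate = 1),
               "duplicate_ditag_rate")
  expect_error(sage_sim_config(cdna_length_range = c(500, 200)),
               "cdna_length_range")
  expect_error(sage_sim_config(seed = 1.5), "seed")
})

test_that("ground-truth proportions sum to one and fold changes are exact", {
  cfg <- sage_sim_config(n_genes = 400, frac_differential = 0.1,
                         fold_changes = c(3, 5), seed = 9)
  truth <- simulate_truth(cfg)
  g <- truth$genes
  expect_equal(sum(g$prop1), 1, tolerance = 1e-12)
  expect_equal(sum(g$prop2), 1, tolerance = 1e-12)
  expect_equal(sum(g$label != "null"), round(0.1 * 400))
  up <- g$label == "up"
  dn <- g$label == "down"
  expect_equal(g$prop1[up] / g$prop2[up], g$fold_change[up],
               tolerance = 1e-9)
  expect_equal(g$prop2[dn] / g$prop1[dn], g$fold_change[dn],
               tolerance = 1e-9)
  expect_true(all(g$fold_change[up | dn] %in% c(3, 5)))
})

test_that("transcriptome sequences encode the ledger tag at the 3'-most site", {
  # single gene round trip: extract_virtual_tag recovers gene_to_tag
  cfg1 <- sage_sim_config(n_genes = 1, tagless_gene_fraction = 0,
                          ambiguous_tag_fraction = 0, frac_differential = 0,
                          cdna_length_range = c(60, 120), seed = 3)
  tr1 <- simulate_transcriptome(cfg1)
  expect_equal(as.vector(extract_virtual_tag(tr1$cdna$sequence)),
               tr1$truth$genes$tag)

  # fully tagless transcriptome has no tags at all
  cfg0 <- sage_sim_config(n_genes = 20, tagless_gene_fraction = 1,
                          ambiguous_tag_fraction = 0, frac_differential = 0,
                          cdna_length_range = c(60, 120), seed = 4)
  tr0 <- simulate_transcriptome(cfg0)
  expect_true(all(is.na(tr0$truth$genes$tag)))
  expect_true(all(is.na(extract_virtual_tag(tr0$cdna$sequence))))

  # every non-tagless gene agrees with the ledger
  sim <- small_sim()
  vt <- as.vector(extract_virtual_tag(sim$cdna$sequence))
  expect_equal(vt, sim$truth$genes$tag)
})

test_that("the designated ambiguous fraction shares tags pairwise", {
  cfg <- sage_sim_config(n_genes = 100, ambiguous_tag_fraction = 0.1,
                         tagless_gene_fraction = 0, frac_differential = 0,
                         cdna_length_range = c(60, 200), seed = 11)
  tr <- simulate_transcriptome(cfg)
  # brute-force duplicate-tag scan over all realized sequences
  vt <- as.vector(extract_virtual_tag(tr$cdna$sequence))
  tab <- table(vt)
  shared <- names(tab)[tab > 1]
  participants <- tr$cdna$gene[vt %in% shared]
  expect_equal(length(participants), 10L)
  expect_true(all(tab[shared] == 2L))
})

test_that("tag-count draws conserve totals and are seed-reproducible", {
  cfg <- sage_sim_config(n_genes = 50, library_totals = c(100, 100),
                         frac_differential = 0, ambiguous_tag_fraction = 0,
                         tagless_gene_fraction = 0, seed = 21)
  truth <- simulate_truth(cfg)
  a <- simulate_tag_counts(cfg, truth)
  expect_equal(a$lib1$total, 100L)
  expect_equal(a$lib2$total, 100L)
  b <- simulate_tag_counts(cfg, truth)
  expect_identical(a$lib1$counts, b$lib1$counts)
  expect_identical(a$lib2$counts, b$lib2$counts)

  other <- simulate_truth(sage_sim_config(n_genes = 51, seed = 21))
  expect_error(simulate_tag_counts(cfg, other), "different configuration")
})

test_that("null libraries agree within binomial sampling error", {
  cfg <- sage_sim_config(n_genes = 800, library_totals = c(40000, 40000),
                         frac_differential = 0, ambiguous_tag_fraction = 0,
                         tagless_gene_fraction = 0, seed = 31)
  truth <- simulate_truth(cfg)
  cnt <- simulate_tag_counts(cfg, truth)
  tags <- union(names(cnt$lib1$counts), names(cnt$lib2$counts))
  x <- cnt$lib1$counts[tags]; x[is.na(x)] <- 0L
  y <- cnt$lib2$counts[tags]; y[is.na(y)] <- 0L
  p1 <- x / cnt$lib1$total
  p2 <- y / cnt$lib2$total
  pbar <- (x + y) / (cnt$lib1$total + cnt$lib2$total)
  se <- sqrt(pbar * (1 - pbar) * (1 / cnt$lib1$total + 1 / cnt$lib2$total))
  within <- abs(p1 - p2) <= 4 * se
  expect_gte(mean(within), 0.95)
})

test_that("concatemer reads have the anchored ditag structure", {
  t1 <- "ACGTACGTAC"
  t2 <- "GGGGGGGGGG"
  lib <- tag_library(setNames(c(1L, 1L), c(t1, t2)), name = "tiny")
  cfg <- sage_sim_config(n_genes = 10, duplicate_ditag_rate = 0, seed = 2)
  cc <- simulate_concatemers(lib, lib, cfg)
  # the single ditag pairs the two tags one way or the other
  expect_true(cc[[1]]$ledger %in%
                c(paste0(t1, revcomp(t2)), paste0(t2, revcomp(t1))))
  expect_true(grepl("CATGACGTACGTACCCCCCCCCCCCATG", cc[[1]]$reads, fixed = TRUE) ||
                grepl(paste0("CATG", t2, revcomp(t1), "CATG"),
                      cc[[1]]$reads, fixed = TRUE))
  expect_equal(cc[[1]]$injected_duplicates, 0L)
  # zero injection rate: duplicates in the ledger are only random collisions
  sim0 <- small_sim()
  cfg0 <- sage_sim_config(n_genes = 40, library_totals = c(60, 60),
                          duplicate_ditag_rate = 0,
                          ambiguous_tag_fraction = 0,
                          tagless_gene_fraction = 0, frac_differential = 0,
                          seed = 13)
  tr0 <- simulate_truth(cfg0)
  cnt0 <- simulate_tag_counts(cfg0, tr0)
  cc0 <- simulate_concatemers(cnt0$lib1, cnt0$lib2, cfg0)
  expect_equal(cc0[[1]]$injected_duplicates, 0L)
  # odd totals get a recorded filler tag
  odd <- tag_library(setNames(3L, t1), name = "odd")
  cco <- simulate_concatemers(odd, odd, cfg)
  expect_false(is.na(cco[[1]]$filler_tag))
  expect_equal(length(cco[[1]]$ledger), 2L)
})

test_that("regeneration under an identical seed is bit-identical", {
  cfg <- sage_sim_config(n_genes = 120, library_totals = c(500, 600),
                         seed = 77, cdna_length_range = c(60, 300))
  a <- sage_simulate(cfg)
  b <- sage_simulate(cfg)
  expect_identical(a$truth$genes, b$truth$genes)
  expect_identical(a$cdna, b$cdna)
  expect_identical(a$counts$lib1$counts, b$counts$lib1$counts)
  expect_identical(a$concatemers[[1]]$reads, b$concatemers[[1]]$reads)
})
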