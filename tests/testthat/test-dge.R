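# Digital differential-expression statistics against independent oracles.

test_that("Audic-Claverie matches its closed form on hand cases", {
  # equal libraries, x = 2, y = 1: P(1|2) = C(3,1)/2^4 = 3/16,
  # lower tail = 1/8 + 3/16 = 5/16, upper = 7/8, two-sided = 5/8
  expect_equal(audic_claverie_p(2, 1, 1000, 1000), 5 / 8, tolerance = 1e-12)
  # no-information case: doubled tail capped at 1
  expect_equal(audic_claverie_p(0, 0, 1000, 1000), 1)
  # published top contrast (15 vs 0 at the two library totals) against
  # term-by-term summation
  expect_equal(audic_claverie_p(15, 0, 22989, 26599),
               ac_oracle(15, 0, 22989, 26599), tolerance = 1e-12)
  expect_error(audic_claverie_p(-1, 0, 10, 10), "contrast")
  expect_error(audic_claverie_p(5, 1, 4, 10), "contrast")
})

test_that("Fisher exact test matches full table enumeration", {
  # symmetric table
  expect_equal(fisher_exact_p(7, 7, 500, 500), 1)
  # enumeration oracle on the [[5,95],[0,100]] table
  expect_equal(fisher_exact_p(5, 0, 100, 100),
               fisher_oracle(5, 0, 100, 100), tolerance = 1e-12)
  # right tail at the maximum feasible count equals the point mass
  expect_equal(fisher_exact_p(3, 0, 3, 100, tail = "right"),
               dhyper(3, 3, 100, 3), tolerance = 1e-12)
  # agreement with the independent stats::fisher.test route
  for (case in list(c(5, 1, 200, 300), c(0, 9, 22989, 26599),
                    c(14, 39, 22989, 26599))) {
    ft <- fisher.test(matrix(c(case[1], case[3] - case[1],
                               case[2], case[4] - case[2]), nrow = 2,
                             byrow = TRUE))
    expect_equal(fisher_exact_p(case[1], case[2], case[3], case[4]),
                 ft$p.value, tolerance = 1e-9)
  }
})

test_that("pooled two-proportion z test matches direct arithmetic", {
  expect_equal(proportion_z_p(10, 12, 1000, 1200), 1)
  # published Glud1 contrast: z recomputed spreadsheet-style
  x <- 54; y <- 14; n1 <- 22989; n2 <- 26599
  pbar <- (x + y) / (n1 + n2)
  z <- (x / n1 - y / n2) / sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  expect_gt(z, 5.4); expect_lt(z, 5.6)
  expect_equal(proportion_z_p(x, y, n1, n2), 2 * pnorm(-z),
               tolerance = 1e-12)
  # doubling counts and totals keeps proportions but shrinks p
  expect_lt(proportion_z_p(2 * x, 2 * y, 2 * n1, 2 * n2),
            proportion_z_p(x, y, n1, n2))
  # no-information convention
  expect_equal(suppressMessages(proportion_z_p(0, 0, 10, 10)), 1)
})

test_that("exact tests match brute-force oracles on a sampled grid", {
  set.seed(1)
  for (i in 1:40) {
    n1 <- sample(20:2000, 1); n2 <- sample(20:2000, 1)
    x <- sample(0:min(50, n1), 1); y <- sample(0:min(50, n2), 1)
    expect_equal(audic_claverie_p(x, y, n1, n2), ac_oracle(x, y, n1, n2),
                 tolerance = 1e-10, label = sprintf("ac(%d,%d,%d,%d)",
                                                    x, y, n1, n2))
    expect_equal(fisher_exact_p(x, y, n1, n2),
                 fisher_oracle(x, y, n1, n2), tolerance = 1e-10,
                 label = sprintf("fisher(%d,%d,%d,%d)", x, y, n1, n2))
    expect_equal(fisher_exact_p(x, y, n1, n2, tail = "right"),
                 fisher_oracle(x, y, n1, n2, tail = "right"),
                 tolerance = 1e-10)
  }
})

test_that("two-sided tests are symmetric and monotone in imbalance", {
  cases <- expand.grid(x = c(0, 1, 3, 10, 25), y = c(0, 2, 7, 25))
  for (i in seq_len(nrow(cases))) {
    x <- cases$x[i]; y <- cases$y[i]
    expect_equal(fisher_exact_p(x, y, 500, 800),
                 fisher_exact_p(y, x, 800, 500), tolerance = 1e-12)
    expect_equal(suppressMessages(proportion_z_p(x, y, 500, 800)),
                 suppressMessages(proportion_z_p(y, x, 800, 500)),
                 tolerance = 1e-12)
    # the conditional Audic-Claverie test is symmetric only up to one
    # point mass (it conditions on the library-1 count)
    pm <- max(dnbinom(y, size = x + 1, prob = 500 / 1300),
              dnbinom(x, size = y + 1, prob = 800 / 1300))
    expect_lte(abs(audic_claverie_p(x, y, 500, 800) -
                     audic_claverie_p(y, x, 800, 500)),
               2 * pm + 1e-12)
  }
  # fixed x + y = 20, N1 = N2: p non-increasing as |x - y| grows
  for (fun in list(audic_claverie_p, fisher_exact_p)) {
    p <- vapply(10:20, function(x) fun(x, 20 - x, 1000, 1000), 0)
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("fold change normalizes to the larger library with tie -> down", {
  eq <- fold_change(7, 7, 1000, 1000)
  expect_equal(eq$fc, 1)
  expect_equal(eq$direction, "down")
  expect_equal(fold_change(15, 0, 25000, 25000)$fc, 16)
  # swap symmetry: fc invariant, direction flips
  a <- fold_change(9, 2, 22989, 26599)
  b <- fold_change(2, 9, 26599, 22989)
  expect_equal(a$fc, b$fc)
  expect_equal(a$direction, "up")
  expect_equal(b$direction, "down")
  # normalization scales the smaller library up
  expect_equal(fold_change(10, 10, 500, 1000)$x_norm, 20)
})

test_that("multiplicity adjustment is step-up BH, order preserved", {
  expect_equal(adjust_p(0.03), 0.03)
  expect_equal(adjust_p(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_p(rep(0.2, 5)), rep(0.2, 5))
  shuffled <- c(0.04, 0.01, 0.03, 0.02)
  expect_equal(adjust_p(shuffled), rep(0.04, 4))
  expect_true(all(adjust_p(shuffled) >= shuffled))
  expect_equal(adjust_p(c(0.01, 0.5), method = "bonferroni"), c(0.02, 1))
  expect_error(adjust_p(c(0.5, 0)), "0, 1")
})

test_that("the two-library fit covers the tag union and sorts by evidence", {
  lib1 <- tag_library(c(AAAAAAAAAA = 30L, CCCCCCCCCC = 5L, GGGGGGGGGG = 2L),
                      name = "rop")
  lib2 <- tag_library(c(AAAAAAAAAA = 4L, CCCCCCCCCC = 5L, TTTTTTTTTT = 6L),
                      name = "c57")
  fit <- suppressMessages(sage_dge(lib1, lib2))
  tab <- fit$table
  expect_setequal(tab$tag, c("AAAAAAAAAA", "CCCCCCCCCC", "GGGGGGGGGG",
                             "TTTTTTTTTT"))
  # union handling: tag absent from one library enters with count 0
  expect_equal(tab$y[tab$tag == "GGGGGGGGGG"], 0L)
  expect_equal(tab$x[tab$tag == "TTTTTTTTTT"], 0L)
  # sorted by ascending primary p
  expect_true(!is.unsorted(tab$p_ac))
  expect_true(all(tab$p_adj >= tab$p_ac))
  expect_equal(tab$direction, ifelse(tab$x_norm > tab$y_norm, "up", "down"))
  # identical libraries: exact tests all 1 (to rounding), no focus tags
  same <- suppressMessages(sage_dge(lib1, lib1))
  expect_equal(same$table$p_ac, rep(1, 3), tolerance = 1e-9)
  expect_equal(same$table$p_fisher, rep(1, 3), tolerance = 1e-9)
  expect_equal(sum(same$table$is_focus), 0L)
  expect_equal(nrow(select_focus_genes(same, fc_threshold = 1.0001,
                                       alpha = 0.999999)), 0L)
})

test_that("focus selection uses strict thresholds under the and/or rule", {
  rec <- data.frame(tag = c("A", "B", "C", "D"),
                    fc = c(2.0, 1.1, 3.0, 2.5),
                    p_adj = c(0.5, 0.01, 0.01, 0.5),
                    stringsAsFactors = FALSE)
  sel_or <- select_focus_genes(rec)
  expect_setequal(sel_or$tag, c("B", "C", "D"))  # fc exactly 2 excluded
  sel_and <- select_focus_genes(rec, rule = "and")
  expect_setequal(sel_and$tag, "C")
  # "or" selection is a superset of the adjusted-significant set
  sim <- small_sim()
  fit <- sage_dge(sim$counts$lib1, sim$counts$lib2)
  sel <- select_focus_genes(fit)
  expect_true(all(fit$table$tag[fit$table$p_adj < 0.05] %in% sel$tag))
})

test_that("rank concordance is a proper Spearman correlation", {
  rec <- data.frame(p_ac = c(0.01, 0.2, 0.5, 0.9),
                    p_fisher = c(0.02, 0.3, 0.6, 0.95),
                    p_z = c(0.9, 0.5, 0.2, 0.01))
  expect_equal(rank_concordance(rec, "ac", "ac"), 1)
  expect_equal(rank_concordance(rec, "ac", "fisher"), 1)
  expect_equal(rank_concordance(rec, "ac", "z"), -1)
  expect_error(rank_concordance(rec[1:2, ]), "at least 3")
  expect_error(rank_concordance(rec, "ac", "banana"), "unknown method")
})

test_that("fit methods print, summarize and export coherently", {
  sim <- small_sim()
  fit <- sage_dge(sim$counts$lib1, sim$counts$lib2)
  expect_s3_class(fit, "sage_dge")
  expect_output(print(fit), "SAGE differential expression")
  s <- summary(fit)
  expect_output(print(s), "focus tags")
  expect_equal(s$n_tags, nrow(fit$table))
  expect_equal(s$n_focus, sum(fit$table$is_focus))
  expect_identical(as.data.frame(fit), fit$table)
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
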