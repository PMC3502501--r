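# Two-library digital differential-expression statistics.  A SAGE contrast
# is (x, y, N1, N2): tag counts x and y in libraries of total size N1 and
# N2.  Under the digital-expression model the counts are binomially
# distributed thinnings of the underlying transcript abundance, which
# licenses three tests: the Audic-Claverie posterior-tail test, Fisher's
# exact test on the 2x2 table, and the pooled two-proportion z test.

check_contrast <- function(x, y, n1, n2) {
  if (any(is.na(x) | is.na(y) | is.na(n1) | is.na(n2)) ||
      any(x < 0) || any(y < 0) || any(n1 < 1) || any(n2 < 1) ||
      any(x > n1) || any(y > n2) ||
      any(x != round(x)) || any(y != round(y)) ||
      any(n1 != round(n1)) || any(n2 != round(n2))) {
    stop("invalid tag contrast: need 0 <= x <= N1, 0 <= y <= N2, ",
         "integer counts, N1, N2 >= 1", call. = FALSE)
  }
}

# never report an exact zero p-value
floor_p <- function(p) pmax(p, .Machine$double.xmin)

#' Audic-Claverie significance of a digital expression difference
#'
#' Two-sided test for a tag observed `x` times in a library of `N1` tags
#' and `y` times in a library of `N2` tags.  With `r = N2/N1`, the
#' probability of observing `k` in the second library given `x` in the
#' first is
#' \deqn{P(k \mid x) = r^k \frac{(x+k)!}{x!\,k!\,(1+r)^{x+k+1}},}
#' the posterior predictive of a Poisson rate under a flat prior.  The
#' reported p-value doubles the smaller of the two tails at `y` and is
#' capped at 1.
#'
#' `P(k | x)` is exactly the negative-binomial mass with size `x + 1` and
#' success probability `N1/(N1 + N2)`, so both tails are evaluated through
#' the regularized incomplete beta function (via [stats::pnbinom()]); this
#' keeps tiny upper tails accurate where the complement `1 - P(k < y)`
#' would cancel catastrophically.
#'
#' The test conditions on the count observed in library 1, so it is not
#' exactly invariant under swapping the libraries: the two orientations
#' differ by at most one point mass `P(y | x)`, negligible whenever the
#' p-value is small.
#'
#' @param x,y Tag counts in libraries 1 and 2 (vectors recycle).
#' @param n1,n2 Library totals.
#' @return Vector of two-sided p-values in `(0, 1]`.
#' @export
#' @examples
#' audic_claverie_p(15, 0, 22989, 26599)
audic_claverie_p <- function(x, y, n1, n2) {
  check_contrast(x, y, n1, n2)
  n <- max(length(x), length(y), length(n1), length(n2))
  x <- rep_len(x, n); y <- rep_len(y, n)
  n1 <- rep_len(n1, n); n2 <- rep_len(n2, n)
  q <- n1 / (n1 + n2)  # 1/(1 + r)
  lower <- stats::pnbinom(y, size = x + 1, prob = q)
  upper <- ifelse(y == 0, 1,
                  stats::pnbinom(pmax(y - 1, 0), size = x + 1, prob = q,
                                 lower.tail = FALSE))
  floor_p(pmin(1, 2 * pmin(lower, upper)))
}

#' Fisher's exact test for a tag contrast
#'
#' Exact hypergeometric test on the table `[[x, N1 - x], [y, N2 - y]]`,
#' conditioning on the combined tag count `x + y`.  The two-sided p-value
#' sums all tables whose probability does not exceed the observed table's
#' (point-mass definition); the right tail is `P(count >= x)` at fixed
#' margins, the form used for set enrichment.
#'
#' @param x,y Tag counts in libraries 1 and 2 (vectors recycle).
#' @param n1,n2 Library totals.
#' @param tail `"two_sided"` (default) or `"right"`.
#' @return Vector of p-values in `(0, 1]`.
#' @export
fisher_exact_p <- function(x, y, n1, n2, tail = c("two_sided", "right")) {
  tail <- match.arg(tail)
  check_contrast(x, y, n1, n2)
  n <- max(length(x), length(y), length(n1), length(n2))
  x <- rep_len(x, n); y <- rep_len(y, n)
  n1 <- rep_len(n1, n); n2 <- rep_len(n2, n)
  p <- numeric(n)
  for (i in seq_len(n)) {
    s <- x[i] + y[i]
    if (tail == "right") {
      p[i] <- phyper(x[i] - 1, n1[i], n2[i], s, lower.tail = FALSE)
    } else {
      support <- max(0, s - n2[i]):min(n1[i], s)
      d <- dhyper(support, n1[i], n2[i], s)
      obs <- dhyper(x[i], n1[i], n2[i], s)
      # relative tolerance mirrors the conventional treatment of ties in
      # floating-point table probabilities
      p[i] <- min(1, sum(d[d <= obs * (1 + 1e-7)]))
    }
  }
  floor_p(p)
}

#' Pooled two-proportion z test for a tag contrast
#'
#' Normal-approximation test of equal tag proportions,
#' `z = (x/N1 - y/N2) / sqrt(pbar (1 - pbar) (1/N1 + 1/N2))` with pooled
#' `pbar = (x + y)/(N1 + N2)`; `p = 2 * pnorm(-|z|)`.  Contrasts with
#' `x + y = 0` carry no information and return 1 (logged to standard
#' error).
#'
#' @param x,y Tag counts in libraries 1 and 2 (vectors recycle).
#' @param n1,n2 Library totals.
#' @return Vector of two-sided p-values in `(0, 1]`.
#' @export
proportion_z_p <- function(x, y, n1, n2) {
  check_contrast(x, y, n1, n2)
  n <- max(length(x), length(y), length(n1), length(n2))
  x <- rep_len(x, n); y <- rep_len(y, n)
  n1 <- rep_len(n1, n); n2 <- rep_len(n2, n)
  pbar <- (x + y) / (n1 + n2)
  se <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  z <- (x / n1 - y / n2) / se
  p <- 2 * pnorm(-abs(z))
  zero <- x + y == 0
  if (any(zero)) {
    report_lines("proportion_z_p", zero_count_contrasts = sum(zero))
    p[zero] <- 1
  }
  floor_p(pmin(p, 1))
}

#' Normalized fold change of a tag contrast
#'
#' Counts are scaled up to the larger library total
#' (`x' = x * max(N1, N2)/N1`, likewise `y'`) and a pseudocount keeps
#' zero-count contrasts finite: `fc = (x' + c)/(y' + c)` oriented so that
#' `fc >= 1`.  Direction is `"up"` (library 1 higher) when `x' > y'`,
#' `"down"` otherwise — ties classify down.
#'
#' @param x,y Tag counts in libraries 1 and 2 (vectors recycle).
#' @param n1,n2 Library totals.
#' @param pseudocount Positive pseudocount `c` (default 1).
#' @return Data frame with columns `x_norm`, `y_norm`, `fc`, `direction`.
#' @export
#' @examples
#' fold_change(15, 0, 25000, 25000)  # fc 16
fold_change <- function(x, y, n1, n2, pseudocount = 1) {
  check_contrast(x, y, n1, n2)
  stopifnot(pseudocount > 0)
  n <- max(length(x), length(y), length(n1), length(n2))
  x <- rep_len(x, n); y <- rep_len(y, n)
  n1 <- rep_len(n1, n); n2 <- rep_len(n2, n)
  nref <- pmax(n1, n2)
  xn <- x * nref / n1
  yn <- y * nref / n2
  up <- xn > yn
  fc <- ifelse(xn >= yn, (xn + pseudocount) / (yn + pseudocount),
               (yn + pseudocount) / (xn + pseudocount))
  data.frame(x_norm = xn, y_norm = yn, fc = fc,
             direction = ifelse(up, "up", "down"),
             stringsAsFactors = FALSE)
}

#' Multiple-testing adjustment for tag p-values
#'
#' Benjamini-Hochberg step-up by default (the standard choice for
#' expression screens), Bonferroni behind the flag.  Input order is
#' preserved.
#'
#' @param p Vector of p-values in `(0, 1]`.
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @return Adjusted p-values in `(0, 1]`, same order as the input.
#' @export
adjust_p <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  p.adjust(p, method = method)
}

#' Two-library digital differential expression
#'
#' The central fit: contrasts every tag in the union of two SAGE libraries
#' (a tag absent from one library enters with count 0), computes all three
#' test statistics ([audic_claverie_p()], [fisher_exact_p()],
#' [proportion_z_p()]), normalized fold changes, the multiplicity-adjusted
#' primary p-value, and the focus flag under the selection rule used for
#' network analysis (fold change above `fc_threshold` and/or adjusted
#' p below `alpha`).
#'
#' @param lib1,lib2 [tag_library()] objects; library 1 is the condition of
#'   interest (the disease-model analog), library 2 the comparator.
#' @param method Primary test: `"ac"` (Audic-Claverie, default),
#'   `"fisher"` or `"z"`.
#' @param fc_threshold,alpha,rule Focus-gene selection parameters, see
#'   [select_focus_genes()].
#' @param correction Multiplicity correction, see [adjust_p()].
#' @param pseudocount Passed to [fold_change()].
#' @param annotation Optional annotation data frame from [annotate_tags()]
#'   (or any data frame with columns `tag` and `gene`) used to attach gene
#'   symbols.
#' @return An object of class `sage_dge`: list with `table` (one
#'   [DgeRecord][sage_dge] row per tag, sorted by ascending primary p,
#'   ties by descending normalized difference then tag), `method`,
#'   `correction`, `n1`, `n2`, `lib_names` and the selection parameters.
#'   The table columns are `tag`, `gene`, `x`, `y`, `x_norm`, `y_norm`,
#'   `fc`, `direction`, `p_ac`, `p_fisher`, `p_z`, `p_adj`, `is_focus`.
#' @seealso [select_focus_genes()], [rank_concordance()]
#' @export
sage_dge <- function(lib1, lib2, method = c("ac", "fisher", "z"),
                     fc_threshold = 2, alpha = 0.05, rule = c("or", "and"),
                     correction = c("BH", "bonferroni"), pseudocount = 1,
                     annotation = NULL) {
  stopifnot(inherits(lib1, "tag_library"), inherits(lib2, "tag_library"))
  if (lib1$total < 1 || lib2$total < 1) {
    stop("both libraries must be non-empty", call. = FALSE)
  }
  method <- match.arg(method)
  rule <- match.arg(rule)
  correction <- match.arg(correction)
  tags <- sort(union(names(lib1$counts), names(lib2$counts)))
  x <- unname(lib1$counts[tags]); x[is.na(x)] <- 0L
  y <- unname(lib2$counts[tags]); y[is.na(y)] <- 0L
  n1 <- lib1$total; n2 <- lib2$total
  fc <- fold_change(x, y, n1, n2, pseudocount = pseudocount)
  tab <- data.frame(tag = tags, gene = NA_character_, x = x, y = y,
                    fc, stringsAsFactors = FALSE)
  tab$p_ac <- audic_claverie_p(x, y, n1, n2)
  tab$p_fisher <- fisher_exact_p(x, y, n1, n2)
  tab$p_z <- proportion_z_p(x, y, n1, n2)
  primary <- tab[[paste0("p_", method)]]
  tab$p_adj <- adjust_p(primary, method = correction)
  if (!is.null(annotation)) {
    stopifnot(all(c("tag", "gene") %in% names(annotation)))
    tab$gene <- annotation$gene[match(tab$tag, annotation$tag)]
  }
  ord <- order(primary, -abs(tab$x_norm - tab$y_norm), tab$tag)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  tab$is_focus <- focus_mask(tab, fc_threshold, alpha, rule)
  structure(list(table = tab, method = method, correction = correction,
                 n1 = n1, n2 = n2,
                 lib_names = c(lib1$name, lib2$name),
                 fc_threshold = fc_threshold, alpha = alpha, rule = rule),
            class = "sage_dge")
}

focus_mask <- function(records, fc_threshold, alpha, rule) {
  hit_fc <- records$fc > fc_threshold        # strict inequalities
  hit_p <- records$p_adj < alpha
  if (rule == "or") hit_fc | hit_p else hit_fc & hit_p
}

#' Select focus genes from a differential-expression fit
#'
#' The selection rule feeding network analysis: a tag qualifies with a
#' normalized fold change strictly above `fc_threshold` **and/or** an
#' adjusted p-value strictly below `alpha` (default rule `"or"`, mirroring
#' the original and/or criterion; `"and"` requires both).
#'
#' @param records A `sage_dge` object or its `table` data frame.
#' @param fc_threshold Fold-change threshold (default 2).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param rule `"or"` (default) or `"and"`.
#' @return The qualifying rows of the record table, `is_focus` set.
#' @export
select_focus_genes <- function(records, fc_threshold = 2, alpha = 0.05,
                               rule = c("or", "and")) {
  rule <- match.arg(rule)
  if (inherits(records, "sage_dge")) records <- records$table
  mask <- focus_mask(records, fc_threshold, alpha, rule)
  out <- records[mask, , drop = FALSE]
  out$is_focus <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Rank concordance between two test statistics
#'
#' Spearman correlation (average ranks for ties) of two methods' p-values
#' over the fitted contrasts — the check that the competing digital
#' expression tests order the tags comparably.
#'
#' @param records A `sage_dge` object or its `table` data frame (>= 3
#'   rows).
#' @param method_a,method_b Test names among `"ac"`, `"fisher"`, `"z"`.
#' @return Spearman's rho.
#' @export
rank_concordance <- function(records, method_a = "ac", method_b = "fisher") {
  if (inherits(records, "sage_dge")) records <- records$table
  if (nrow(records) < 3L) {
    stop("rank concordance needs at least 3 records", call. = FALSE)
  }
  cols <- paste0("p_", c(method_a, method_b))
  if (!all(cols %in% names(records))) {
    stop("unknown method; expected ac, fisher or z", call. = FALSE)
  }
  cor(records[[cols[1]]], records[[cols[2]]], method = "spearman")
}

#' @export
print.sage_dge <- function(x, n = 8L, ...) {
  cat(sprintf("SAGE differential expression: %s (N1=%d) vs %s (N2=%d)\n",
              x$lib_names[1], x$n1, x$lib_names[2], x$n2))
  cat(sprintf("  %d tags tested; primary test: %s; correction: %s\n",
              nrow(x$table), x$method, x$correction))
  cat(sprintf("  focus rule: fc > %g %s p_adj < %g -> %d focus tags\n",
              x$fc_threshold, x$rule, x$alpha, sum(x$table$is_focus)))
  top <- utils::head(x$table[, c("tag", "gene", "x", "y", "fc", "direction",
                                 paste0("p_", x$method), "p_adj")], n)
  print(format(top, digits = 3))
  invisible(x)
}

#' @export
summary.sage_dge <- function(object, ...) {
  tab <- object$table
  primary <- tab[[paste0("p_", object$method)]]
  out <- list(
    n_tags = nrow(tab),
    totals = c(object$n1, object$n2),
    lib_names = object$lib_names,
    method = object$method,
    n_focus = sum(tab$is_focus),
    n_sig_adj = sum(tab$p_adj < object$alpha),
    n_fc = sum(tab$fc > object$fc_threshold),
    focus_up = sum(tab$is_focus & tab$direction == "up"),
    focus_down = sum(tab$is_focus & tab$direction == "down"),
    rho_ac_fisher = if (nrow(tab) >= 3L) rank_concordance(tab, "ac", "fisher")
                    else NA_real_,
    min_p = min(primary))
  class(out) <- "summary.sage_dge"
  out
}

#' @export
print.summary.sage_dge <- function(x, ...) {
  cat(sprintf("Two-library SAGE contrast: %s (N1=%d) vs %s (N2=%d)\n",
              x$lib_names[1], x$totals[1], x$lib_names[2], x$totals[2]))
  cat(sprintf("  tags tested            %d\n", x$n_tags))
  cat(sprintf("  primary test           %s (min p = %.3g)\n", x$method,
              x$min_p))
  cat(sprintf("  adjusted p significant %d\n", x$n_sig_adj))
  cat(sprintf("  fold-change qualified  %d\n", x$n_fc))
  cat(sprintf("  focus tags             %d (%d up, %d down)\n", x$n_focus,
              x$focus_up, x$focus_down))
  cat(sprintf("  Spearman rho (AC vs Fisher p) %.3f\n", x$rho_ac_fisher))
  invisible(x)
}

#' @export
as.data.frame.sage_dge <- function(x, ...) x$table

#' MA-style plot of a SAGE differential-expression fit
#'
#' Log2 mean normalized abundance against log2 fold change (signed by
#' direction), focus tags highlighted.
#'
#' @param x A `sage_dge` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sage_dge <- function(x, ...) {
  tab <- x$table
  a <- log2((tab$x_norm + tab$y_norm) / 2 + 1)
  m <- ifelse(tab$direction == "up", 1, -1) * log2(tab$fc)
  graphics::plot(a, m, pch = 16, cex = 0.4,
                 col = ifelse(tab$is_focus, "firebrick", "grey50"),
                 xlab = "log2 mean normalized count",
                 ylab = "log2 fold change (library 1 / library 2)", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Write a differential-expression results table
#'
#' TSV with the record columns in fit order (tag, gene, raw and normalized
#' counts, fold change, direction, the three p-values, adjusted p, focus
#' flag).
#'
#' @param fit A `sage_dge` object.
#' @param path File path.
#' @export
write_dge <- function(fit, path) {
  stopifnot(inherits(fit, "sage_dge"))
  write_tsv(fit$table, path)
}
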