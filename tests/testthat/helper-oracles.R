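# Independent oracles, deliberately on different computational routes than
# the package (term recurrences and lchoose enumeration instead of
# log-gamma tail accumulation / dhyper).

# Audic-Claverie by term-by-term summation of the closed form,
# P(k|x) = r^k (x+k)! / (x! k! (1+r)^(x+k+1)), via the ratio recurrence
# P(k)/P(k-1) = r (x+k) / (k (1+r)).
ac_oracle <- function(x, y, n1, n2) {
  r <- n2 / n1
  term <- 1 / (1 + r)^(x + 1)          # P(0 | x)
  lower <- term
  if (y >= 1) {
    for (k in 1:y) {
      term <- term * r * (x + k) / (k * (1 + r))
      lower <- lower + term
    }
  }
  # upper tail summed forwards from k = y (term currently P(y | x)) until
  # the geometric decay makes additions negligible -- no 1 - sum
  # cancellation
  upper <- term
  k <- y
  repeat {
    k <- k + 1
    term <- term * r * (x + k) / (k * (1 + r))
    upper <- upper + term
    if (term <= upper * 1e-17 || term == 0) break
  }
  min(1, 2 * min(min(lower, 1), min(upper, 1)))
}

# Fisher exact by full enumeration of all feasible 2x2 tables at fixed
# margins, probabilities from lchoose.
fisher_oracle <- function(x, y, n1, n2, tail = "two_sided") {
  s <- x + y
  support <- max(0, s - n2):min(n1, s)
  p <- exp(lchoose(n1, support) + lchoose(n2, s - support) -
             lchoose(n1 + n2, s))
  if (tail == "right") {
    sum(p[support >= x])
  } else {
    obs <- p[support == x]
    min(1, sum(p[p <= obs * (1 + 1e-7)]))
  }
}

# Right-tailed hypergeometric enrichment by enumeration over overlaps.
enrich_oracle <- function(overlap, n_sel, n_ann, n_uni) {
  ks <- max(0, n_sel - (n_uni - n_ann)):min(n_sel, n_ann)
  p <- exp(lchoose(n_ann, ks) + lchoose(n_uni - n_ann, n_sel - ks) -
             lchoose(n_uni, n_sel))
  sum(p[ks >= overlap])
}

# memoise expensive simulated objects across test files
.sage_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .sage_cache)) {
    assign(key, force(expr), envir = .sage_cache)
  }
  get(key, envir = .sage_cache)
}

# a paper-scale two-library fit under the generator defaults
paper_scale_fit <- function() {
  cached("paper_fit", {
    cfg <- sage_sim_config(seed = 20120719)
    truth <- simulate_truth(cfg)
    cnt <- simulate_tag_counts(cfg, truth)
    list(cfg = cfg, truth = truth, counts = cnt,
         fit = sage_dge(cnt$lib1, cnt$lib2))
  })
}

# small simulation shared by round-trip and annotation tests
small_sim <- function() {
  cached("small_sim", {
    cfg <- sage_sim_config(n_genes = 250, library_totals = c(1500, 1800),
                           frac_differential = 0.04,
                           ambiguous_tag_fraction = 0.08,
                           tagless_gene_fraction = 0.04,
                           cdna_length_range = c(60, 400), seed = 42)
    tr <- simulate_transcriptome(cfg)
    cnt <- simulate_tag_counts(cfg, tr$truth)
    conc <- simulate_concatemers(cnt$lib1, cnt$lib2, cfg)
    list(cfg = cfg, truth = tr$truth, cdna = tr$cdna, counts = cnt,
         concatemers = conc)
  })
}
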