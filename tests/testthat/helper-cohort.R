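# Shared fixture builders. Everything is generated in code at test time.

# A small two-group cohort reused across files (memoised per test run).
small_cohort <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      cfg <- sim_config(groups = c(AFR = 2, EUR = 2), n_genes = 6,
                        variants_per_gene = 30, pop_size_range = c(20L, 22L),
                        seed = 101)
      memo <<- simulate_cohort(cfg)
    }
    memo
  }
})

# Residualized (batch + sex) log2 expression for a simulated cohort.
residualized_log2 <- function(cohort) {
  fm <- cohort$expression
  log_fm <- feature_matrix(fm$features, log2(fm$values), fm$samples,
                           kind = "normalized")
  mm <- stats::model.matrix(~ batch + sex, data = cohort$samples)[, -1, drop = FALSE]
  residualize(log_fm, mm)
}

# Hand-built single/multi-variant cohort on the package containers: dosages
# drawn at exact MAF, expression built from the multiplicative aFC model.
make_afc_cohort <- function(n, mafs, deltas, sigma, baseline = 8, seed = 1) {
  set.seed(seed)
  k <- length(mafs)
  dos <- t(vapply(mafs, function(m) rbinom(n, 2, m), numeric(n)))
  variants <- tibble::tibble(chrom = "chr1", pos = 1000L + seq_len(k),
                             id = paste0("v", seq_len(k)), ref = "A", alt = "G")
  ids <- sprintf("I%03d", seq_len(n))
  geno <- genotype_matrix(variants, ids, dos)
  log2e <- rep(baseline, n)
  for (q in seq_len(k)) {
    log2e <- log2e + log2(((2 - dos[q, ]) + dos[q, ] * 2^deltas[q]) / 2)
  }
  log2e <- log2e + rnorm(n, 0, sigma)
  fm <- feature_matrix(
    tibble::tibble(feature_id = "G1", chrom = "chr1", anchor = 1000L,
                   gene_id = "G1"),
    matrix(2^log2e, 1, n), ids, kind = "raw-count")
  list(genotypes = geno, expression = fm)
}

# Independent transcription of the Weir & Cockerham (1984) two-population
# variance components, written from the published definitions (r symbolic,
# frequency/heterozygosity averages first) as the oracle for the estimator.
wc_oracle_theta <- function(geno1, geno2) {
  counts <- function(g) {
    g <- g[!is.na(g)]
    c(n = length(g), p = sum(g) / (2 * length(g)), h = mean(g == 1))
  }
  x <- counts(geno1); y <- counts(geno2)
  r <- 2
  n_bar <- (x["n"] + y["n"]) / r
  n_c <- (r * n_bar - (x["n"]^2 + y["n"]^2) / (r * n_bar)) / (r - 1)
  p_bar <- (x["n"] * x["p"] + y["n"] * y["p"]) / (r * n_bar)
  h_bar <- (x["n"] * x["h"] + y["n"] * y["h"]) / (r * n_bar)
  s2 <- (x["n"] * (x["p"] - p_bar)^2 + y["n"] * (y["p"] - p_bar)^2) /
    ((r - 1) * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 -
       ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  cc <- h_bar / 2
  unname(a / (a + b + cc))
}
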