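# Property-based evaluation experiments shared by the acceptance test file
# and scripts/acceptance.R (which sources this file from the repository root).
# Each function runs the installed package on freshly generated data and
# returns the measured quantities.

# --- Weir-Cockerham estimator vs the independent formula transcription ------
criterion_fst_oracle <- function(seed, n_toys = 100) {
  set.seed(seed)
  diffs <- c()
  while (length(diffs) < n_toys) {
    d1 <- rbinom(20, 2, runif(1, 0.05, 0.95))
    d2 <- rbinom(20, 2, runif(1, 0.05, 0.95))
    if (sum(d1) + sum(d2) %in% c(0, 80)) next
    ids <- paste0("S", 1:40)
    geno <- genotype_matrix(
      tibble::tibble(chrom = "chr1", pos = 100L, id = "v1",
                     ref = "A", alt = "G"),
      ids, matrix(c(d1, d2), 1))
    st <- tibble::tibble(sample_id = ids,
                         population = rep(c("P1", "P2"), each = 20),
                         group = rep(c("G1", "G2"), each = 20),
                         sex = "F", batch = "B1")
    fst <- weir_cockerham_fst(geno, st, "G1")
    diffs <- c(diffs, abs(fst$theta - wc_oracle_theta(d1, d2)))
  }
  list(max_abs_diff = max(diffs), n = n_toys)
}

# --- FST calibration under Balding-Nichols differentiation ------------------
criterion_fst_calibration <- function(seed) {
  # 1000 independent variants (block size 1: no shared drift between variants)
  cfg <- sim_config(groups = c(G1 = 1, G2 = 1), pop_size_range = c(200L, 200L),
                    f_group = 0.1, f_pop = 1e-4, n_genes = 20,
                    variants_per_gene = 50, ld_rho = 0, ld_block_size = 1,
                    seed = seed)
  g <- simulate_genotypes(cfg)
  fst <- weir_cockerham_fst(g$genotypes, g$samples, "G1")
  list(mean_theta = fst_overall(fst)$theta_overall, n = nrow(fst))
}

# --- residualization used by the calibration experiments --------------------
criterion_residualize <- function(co, n_geno_pcs = 5) {
  lfm <- feature_matrix(co$expression$features, log2(co$expression$values),
                        co$expression$samples, kind = "normalized")
  cov <- suppressWarnings(compute_covariates(
    co$genotypes, inverse_normal_transform(lfm), co$samples,
    n_geno_pcs = n_geno_pcs, n_pheno_pcs = 0))
  residualize(lfm, cov)
}

# --- fine-mapping calibration: coverage and two-signal detection ------------
criterion_finemap_single <- function(seed, n_genes = 200) {
  cfg <- sim_config(n_genes = n_genes, variants_per_gene = 60, ld_rho = 0.9,
                    n_causal_probs = c(0, 1, 0, 0, 0, 0), seed = seed)
  co <- simulate_cohort(cfg, splicing = FALSE)
  rs <- criterion_residualize(co)
  sets <- suppressWarnings(
    finemap_features(co$genotypes, rs, rs$features$feature_id))
  tru <- co$truth$expression_genes
  keys <- unique(paste(sets$feature_id, sets$cs_id))
  hit <- vapply(keys, function(k) {
    parts <- strsplit(k, " ")[[1]]
    members <- sets$variant_id[sets$feature_id == parts[1] &
                                 sets$cs_id == as.integer(parts[2])]
    any(unlist(tru$causal[tru$gene_id == parts[1]]) %in% members)
  }, logical(1))
  list(coverage = mean(hit), n_sets = length(hit), n_genes = n_genes)
}

criterion_finemap_two_causal <- function(seed, n_genes = 50) {
  cfg <- sim_config(n_genes = n_genes, variants_per_gene = 60, ld_rho = 0.9,
                    n_causal_probs = c(0, 0, 1, 0, 0, 0), afc_fixed = 0.5,
                    causal_separate_blocks = TRUE, seed = seed)
  co <- simulate_cohort(cfg, splicing = FALSE)
  rs <- criterion_residualize(co)
  sets <- suppressWarnings(
    finemap_features(co$genotypes, rs, rs$features$feature_id))
  tru <- co$truth$expression_genes
  ok <- vapply(seq_len(nrow(tru)), function(j) {
    ss <- sets[sets$feature_id == tru$gene_id[j], ]
    length(unique(ss$cs_id)) >= 2 &&
      all(unlist(tru$causal[j]) %in% ss$variant_id)
  }, logical(1))
  list(detection_rate = mean(ok), n = n_genes)
}

# --- conditional aFC estimation: exactness and noisy-grid accuracy ----------
afc_synthetic_cohort <- function(n, mafs, deltas, sigma, seed) {
  set.seed(seed)
  k <- length(mafs)
  dos <- t(vapply(mafs, function(m) rbinom(n, 2, m), numeric(n)))
  ids <- sprintf("I%04d", seq_len(n))
  geno <- genotype_matrix(
    tibble::tibble(chrom = "chr1", pos = 1000L + seq_len(k),
                   id = paste0("v", seq_len(k)), ref = "A", alt = "G"),
    ids, dos)
  log2e <- rep(8, n)
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

criterion_afc_noiseless <- function(seed) {
  deltas <- c(1.0, -0.5)
  co <- afc_synthetic_cohort(731, mafs = c(0.3, 0.4), deltas = deltas,
                             sigma = 0, seed = seed)
  est <- estimate_afc(co$expression, co$genotypes,
                      tibble::tibble(gene_id = "G1",
                                     variant_id = c("v1", "v2")), n_boot = 0)
  list(max_abs_error = max(abs(est$log2_afc - deltas)), n = 731)
}

criterion_afc_grid <- function(seed, n = 731, sigma = 0.5, n_rep = 20) {
  grid <- expand.grid(maf = c(0.2, 0.5), delta = c(0.25, 0.5, 1, 2))
  errs <- c()
  for (r in seq_len(n_rep)) {
    for (i in seq_len(nrow(grid))) {
      co <- afc_synthetic_cohort(n, grid$maf[i], grid$delta[i], sigma,
                                 seed = seed + 1000 * r + i)
      est <- estimate_afc(co$expression, co$genotypes,
                          tibble::tibble(gene_id = "G1", variant_id = "v1"),
                          n_boot = 0)
      errs <- c(errs, abs(est$log2_afc - grid$delta[i]))
    }
  }
  list(mean_abs_error = mean(errs), n = length(errs))
}

# --- permutation machinery: null uniformity, eGene FDR and power ------------
criterion_perm_null <- function(seed, n_rep = 10) {
  ks <- vapply(seq_len(n_rep), function(r) {
    cfg <- sim_config(groups = c(AFR = 2, AMR = 1, EAS = 1, EUR = 2, SAS = 1),
                      n_genes = 40, variants_per_gene = 30,
                      n_causal_probs = c(1, 0, 0, 0, 0, 0),
                      group_shift_frac = 0, seed = seed + r)
    co <- simulate_cohort(cfg, splicing = FALSE)
    rs <- criterion_residualize(co)
    pp <- permutation_pass(co$genotypes, rs, n_perm = 500, seed = seed + r)
    ks.test(pp$p_effective, "punif")$p.value
  }, numeric(1))
  list(mean_ks_p = mean(ks), n = n_rep)
}

criterion_perm_fdr <- function(seed, n_rep = 20) {
  fdrs <- c(); pows <- c()
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(groups = c(AFR = 4, AMR = 3, EAS = 3, EUR = 4, SAS = 3),
                      n_genes = 100, variants_per_gene = 40,
                      n_causal_probs = c(0.7, 0.3, 0, 0, 0, 0),
                      afc_fixed = 1, maf_min_causal = 0.25, seed = seed + r)
    co <- simulate_cohort(cfg, splicing = FALSE)
    rs <- criterion_residualize(co)
    pp <- permutation_pass(co$genotypes, rs, n_perm = 1000, seed = seed + r)
    call <- call_significant(pp, fdr = 0.05)
    tru <- co$truth$expression_genes
    true_genes <- tru$gene_id[tru$n_causal > 0]
    called <- call$features$feature_id[call$features$significant]
    fdrs <- c(fdrs, if (length(called)) mean(!(called %in% true_genes)) else 0)
    pows <- c(pows, mean(true_genes %in% called))
  }
  list(fdr = mean(fdrs), power = mean(pows), n = n_rep)
}

# --- genotype-by-group interaction: rescue and type-I calibration -----------
criterion_interaction_rescue <- function(seed, n_genes = 200) {
  cfg <- sim_config(n_genes = n_genes, variants_per_gene = 40, f_group = 0.15,
                    ld_rho_group = c(AFR = 0.4, AMR = 0.95, EAS = 0.95,
                                     EUR = 0.95, SAS = 0.95),
                    n_causal_probs = c(0, 0, 1, 0, 0, 0), afc_fixed = 1,
                    causal_same_block = TRUE, group_shift_frac = 0,
                    seed = seed)
  co <- simulate_cohort(cfg, splicing = FALSE)
  lfm <- feature_matrix(co$expression$features, log2(co$expression$values),
                        co$expression$samples, kind = "normalized")
  mm <- stats::model.matrix(~ batch + sex, data = co$samples)[, -1, drop = FALSE]
  rs <- residualize(lfm, mm)
  tru <- co$truth$expression_genes
  leads <- tibble::tibble(gene_id = rep(tru$gene_id, times = tru$n_causal),
                          variant_id = unlist(tru$causal))
  lead1 <- leads[!duplicated(leads$gene_id), ]
  single <- interaction_scan(co$genotypes, rs, co$samples, leads,
                             mode = "single")
  joint <- interaction_scan(co$genotypes, rs, co$samples, leads,
                            mode = "joint")
  key <- paste(lead1$gene_id, lead1$variant_id)
  s1 <- single[match(key, paste(single$gene_id, single$variant_id)), ]
  j1 <- joint[match(key, paste(joint$gene_id, joint$variant_id)), ]
  hits <- which(s1$significant)
  list(rescue_fraction = if (length(hits)) mean(!j1$significant[hits]) else NA,
       n_hits = length(hits), n_tested = sum(s1$tested))
}

criterion_interaction_type1 <- function(seed, n_genes = 1000, alpha = 0.05) {
  cfg <- sim_config(n_genes = n_genes, variants_per_gene = 10,
                    n_causal_probs = c(0, 1, 0, 0, 0, 0), afc_fixed = 0.25,
                    group_shift_frac = 0, seed = seed)
  co <- simulate_cohort(cfg, splicing = FALSE)
  lfm <- feature_matrix(co$expression$features, log2(co$expression$values),
                        co$expression$samples, kind = "normalized")
  mm <- stats::model.matrix(~ batch + sex, data = co$samples)[, -1, drop = FALSE]
  rs <- residualize(lfm, mm)
  tru <- co$truth$expression_genes
  one <- tru$n_causal == 1
  leads <- tibble::tibble(gene_id = tru$gene_id[one],
                          variant_id = vapply(tru$causal[one], `[`, "", 1))
  single <- interaction_scan(co$genotypes, rs, co$samples, leads,
                             mode = "single", alpha = alpha)
  rate <- mean(single$p_interaction[single$tested] < alpha)
  list(type1_rate = rate, n = sum(single$tested))
}

# --- variance partitioning recovery and the permutation-p floor -------------
criterion_variance_partition <- function(seed, n_genes = 200, n_perm = 999) {
  cfg <- sim_config(n_genes = n_genes, variants_per_gene = 10,
                    n_causal_probs = c(1, 0, 0, 0, 0, 0),
                    group_var_frac = 0.10, seed = seed)
  co <- simulate_cohort(cfg, splicing = FALSE)
  lfm <- feature_matrix(co$expression$features, log2(co$expression$values),
                        co$expression$samples, kind = "normalized")
  mm <- stats::model.matrix(~ batch + sex, data = co$samples)[, -1, drop = FALSE]
  rs <- residualize(lfm, mm)
  vp <- partition_variance(rs, co$samples, "group", n_perm = n_perm,
                           seed = seed)
  list(mean_proportion = vp$mean_proportion, p_perm = vp$p_perm,
       p_floor = 1 / (n_perm + 1), n = n_genes)
}

# --- enrichment: exact-test oracle and planted placement preference ---------
criterion_fisher_oracle <- function() {
  # 2x2 table 30/70 vs 10/90 built from synthetic coordinates
  leads <- tibble::tibble(chrom = "chr1", pos = seq_len(100) * 1000,
                          id = paste0("l", 1:100), maf = 0.2, distance = 100)
  leads$pos[1:30] <- round(seq(101, 199, length.out = 30))
  bg <- tibble::tibble(chrom = "chr1", pos = seq_len(100) * 1000 + 7,
                       id = paste0("b", 1:100), maf = 0.2, distance = 100)
  bg$pos[1:10] <- round(seq(102, 198, length.out = 10))
  ann <- tibble::tibble(name = "p", chrom = "chr1", start = 100L, end = 200L)
  res <- enrichment_test(leads, bg, ann, match = FALSE)
  probs <- stats::dhyper(0:40, 40, 160, 100)
  p_oracle <- sum(probs[probs <= stats::dhyper(30, 40, 160, 100) * (1 + 1e-7)])
  list(abs_diff = abs(res$p - p_oracle), n = 200)
}

regulatory_patches <- function(genes, seed, name, k = 8, w = 10000) {
  set.seed(seed)
  dplyr::bind_rows(lapply(seq_len(nrow(genes)), function(j) {
    st <- sort(sample.int(1.8e6 - w, k)) - 9e5 + genes$tss[j]
    tibble::tibble(name = name, chrom = genes$chrom[j],
                   start = as.integer(st), end = as.integer(st + w))
  }))
}

criterion_enrichment_planted <- function(seed, n_rep = 25) {
  det <- c(); dummy_folds <- c()
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(groups = c(AFR = 1, AMR = 1, EAS = 1, EUR = 1, SAS = 1),
                      pop_size_range = c(25L, 28L), n_genes = 100,
                      variants_per_gene = 40,
                      n_causal_probs = c(0, 1, 0, 0, 0, 0), seed = seed + r)
    g0 <- simulate_genotypes(cfg)
    ann_reg <- regulatory_patches(g0$truth$genes, seed + r, "regulatory")
    cfg$causal_bias <- list(intervals = ann_reg, odds = 5)
    e <- simulate_expression(g0$genotypes, g0$samples, cfg, g0$truth)
    tru <- e$truth$expression_genes
    freq <- variant_frequencies(g0$genotypes)
    vmeta <- dplyr::left_join(e$truth$variant_layout,
                              e$truth$genes[, c("gene_id", "tss")],
                              by = "gene_id")
    vmeta$distance <- vmeta$pos - vmeta$tss
    vmeta$maf <- freq$maf[match(vmeta$id, freq$id)]
    causal <- unlist(tru$causal)
    leads <- vmeta[match(causal, vmeta$id), ]
    bg <- vmeta[!(vmeta$id %in% causal) & vmeta$maf >= 0.05, ]
    dummy <- regulatory_patches(g0$truth$genes, seed + 10000 + r, "dummy")
    enr <- suppressWarnings(
      enrichment_test(leads, bg, dplyr::bind_rows(ann_reg, dummy),
                      seed = seed + r))
    pr <- enr[enr$annotation == "regulatory", ]
    det <- c(det, pr$fold > 1 && pr$p_bonferroni < 0.05)
    dummy_folds <- c(dummy_folds, enr$fold[enr$annotation == "dummy"])
  }
  list(detection_rate = mean(det),
       dummy_mean_fold = mean(dummy_folds, na.rm = TRUE), n = n_rep)
}
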