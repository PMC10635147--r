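test_that("Balding-Nichols group frequencies have variance F * p0 * (1 - p0)", {
  cfg <- sim_config(groups = c(AFR = 1, AMR = 1, EAS = 1, EUR = 1, SAS = 1),
                    pop_size_range = c(5L, 6L), n_genes = 200,
                    variants_per_gene = 50, f_group = 0.1, seed = 77)
  g <- simulate_genotypes(cfg)
  ratio <- apply(g$truth$p_group, 1, var) / (g$truth$p0 * (1 - g$truth$p0))
  expect_equal(mean(ratio), 0.1, tolerance = 0.1)
  expect_lt(abs(mean(ratio) - 0.1), 0.01)
})

test_that("invalid differentiation and LD parameters are rejected", {
  expect_error(sim_config(f_group = 0), "F parameters")
  expect_error(sim_config(f_group = 1.2), "F parameters")
  expect_error(sim_config(ld_rho = 1), "ld_rho")
  expect_error(sim_config(n_genes = 0), "positive")
})

test_that("LD blocks induce strong adjacent-dosage correlation", {
  cfg <- sim_config(n_genes = 5, variants_per_gene = 30, ld_block_size = 10,
                    ld_rho = 0.95, seed = 13)
  g <- simulate_genotypes(cfg)
  lay <- g$truth$variant_layout
  rs <- c()
  for (b in unique(lay$block)) {
    ix <- match(lay$id[lay$block == b], rownames(g$genotypes$dosage))
    for (k in seq_len(length(ix) - 1)) {
      rs <- c(rs, abs(cor(g$genotypes$dosage[ix[k], ], g$genotypes$dosage[ix[k + 1], ])))
    }
  }
  expect_gt(mean(rs, na.rm = TRUE), 0.7)
})

test_that("expression follows the multiplicative aFC model exactly at sigma = 0", {
  cfg <- sim_config(groups = c(AFR = 1, EUR = 1), pop_size_range = c(60L, 60L),
                    n_genes = 8, variants_per_gene = 20, noise_sd = 0,
                    batch_sd = 0, sex_effect_sd = 0, group_shift_frac = 0,
                    n_causal_probs = c(0, 1, 0, 0, 0, 0), seed = 19)
  co <- simulate_cohort(cfg, splicing = FALSE)
  tru <- co$truth$expression_genes
  for (j in which(tru$n_causal == 1)) {
    d <- co$genotypes$dosage[tru$causal[[j]][1], ]
    if (!any(d == 2) || !any(d == 0)) next
    e <- co$expression$values[j, ]
    ratio <- mean(e[d == 2]) / mean(e[d == 0])
    expect_equal(ratio, 2^tru$delta[[j]][1], tolerance = 1e-9)
  }
})

test_that("without causal or group effects, labels carry no expression signal", {
  cfg <- sim_config(groups = c(AFR = 2, EUR = 2), pop_size_range = c(25L, 25L),
                    n_genes = 20, variants_per_gene = 10,
                    n_causal_probs = c(1, 0, 0, 0, 0, 0), group_shift_frac = 0,
                    batch_sd = 0, sex_effect_sd = 0, seed = 23)
  co <- simulate_cohort(cfg, splicing = FALSE)
  lfm <- feature_matrix(co$expression$features, log2(co$expression$values),
                        co$expression$samples, kind = "normalized")
  vp <- partition_variance(residualize(lfm, NULL), co$samples, "group",
                           n_perm = 99, seed = 1)
  expect_lt(vp$mean_proportion, 0.05)
})

test_that("noiseless cohorts are exactly identifiable by the aFC estimator", {
  cfg <- sim_config(groups = c(AFR = 2, EUR = 2), pop_size_range = c(50L, 50L),
                    n_genes = 10, variants_per_gene = 20, noise_sd = 0,
                    batch_sd = 0, sex_effect_sd = 0, group_shift_frac = 0,
                    n_causal_probs = c(0, 0.5, 0.5, 0, 0, 0), seed = 29)
  co <- simulate_cohort(cfg, splicing = FALSE)
  tru <- co$truth$expression_genes
  leads <- tidyr::unnest(tru[tru$n_causal > 0, c("gene_id", "causal")],
                         "causal")
  names(leads)[2] <- "variant_id"
  afc <- estimate_afc(co$expression, co$genotypes, leads, n_boot = 0)
  truth_delta <- unlist(tru$delta[tru$n_causal > 0])
  expect_equal(afc$log2_afc, truth_delta, tolerance = 1e-6)
})

test_that("splicing ratios sum to one and respond monotonically to dosage", {
  cfg <- sim_config(groups = c(AFR = 2, EUR = 2), pop_size_range = c(40L, 40L),
                    n_genes = 20, variants_per_gene = 20,
                    cluster_causal_prob = 1, seed = 37)
  co <- simulate_cohort(cfg)
  sp <- co$splicing
  sums <- tapply(seq_len(nrow(sp$values)), sp$features$cluster_id,
                 function(ix) colSums(sp$values[ix, , drop = FALSE]))
  for (s in sums) expect_equal(unname(s), rep(1, ncol(sp$values)), tolerance = 1e-12)

  clu <- co$truth$splicing_clusters
  checked <- 0
  for (i in seq_len(nrow(clu))) {
    if (is.na(clu$causal_variant[i]) || abs(clu$logit_effect[i]) < 0.5) next
    d <- co$genotypes$dosage[clu$causal_variant[i], ]
    if (sum(d == 2) < 5 || sum(d == 0) < 5) next
    fid <- paste0(clu$cluster_id[i], ":intron", clu$target_intron[i])
    ratio <- sp$values[fid, ]
    diff <- mean(ratio[d == 2]) - mean(ratio[d == 0])
    expect_equal(sign(diff), sign(clu$logit_effect[i]))
    checked <- checked + 1
  }
  expect_gt(checked, 3)
})

test_that("clusters need at least two introns", {
  cfg <- sim_config(seed = 1)
  cfg$introns_range <- c(1L, 1L)
  g <- simulate_genotypes(sim_config(groups = c(AFR = 1), n_genes = 2,
                                     pop_size_range = c(10L, 10L), seed = 2))
  expect_error(simulate_splicing(g$genotypes, g$samples, cfg, g$truth),
               "at least 2 introns")
})

test_that("fixtures round-trip and are byte-deterministic given the seed", {
  cfg <- sim_config(groups = c(AFR = 1, EUR = 1), pop_size_range = c(10L, 12L),
                    n_genes = 5, variants_per_gene = 10, seed = 41)
  co <- simulate_cohort(cfg)
  d1 <- file.path(tempfile(), "fx1")
  paths <- write_fixture(d1, co)
  expect_length(paths, 5)
  expect_error(write_fixture(d1, co), "overwrite")

  back_g <- read_genotypes(file.path(d1, "genotypes.vcf"))
  expect_equal(unname(back_g$dosage), unname(co$genotypes$dosage))
  back_e <- read_phenotype_bed(file.path(d1, "expression.bed"), kind = "raw-count")
  expect_equal(back_e$values, co$expression$values, tolerance = 1e-12)
  back_s <- read_sample_table(file.path(d1, "samples.tsv"))
  expect_equal(back_s$population, co$samples$population)

  co2 <- simulate_cohort(cfg)
  d2 <- file.path(tempfile(), "fx2")
  write_fixture(d2, co2)
  for (f in basename(paths)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  cfg3 <- cfg; cfg3$seed <- 42L
  co3 <- simulate_cohort(cfg3)
  expect_false(identical(co3$genotypes$dosage, co$genotypes$dosage))
})
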