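two_group_geno <- function(d1, d2) {
  n1 <- length(d1); n2 <- length(d2)
  ids <- c(paste0("A", seq_len(n1)), paste0("B", seq_len(n2)))
  geno <- genotype_matrix(
    tibble::tibble(chrom = "chr1", pos = 100L, id = "v1", ref = "A", alt = "G"),
    ids, matrix(c(d1, d2), 1))
  samples <- tibble::tibble(
    sample_id = ids, population = rep(c("P1", "P2"), c(n1, n2)),
    group = rep(c("G1", "G2"), c(n1, n2)), sex = "F", batch = "B1")
  list(geno = geno, samples = samples)
}

test_that("a fixed allelic difference gives theta of one", {
  tg <- two_group_geno(rep(2, 20), rep(0, 20))
  fst <- weir_cockerham_fst(tg$geno, tg$samples, "G1")
  expect_equal(fst$theta, 1)
})

test_that("identical genotype counts in both groups give non-positive theta", {
  set.seed(4)
  d <- rbinom(25, 2, 0.4)
  tg <- two_group_geno(d, d)
  fst <- weir_cockerham_fst(tg$geno, tg$samples, "G1")
  expect_lte(fst$theta, 0)
})

test_that("theta matches an independent transcription of the 1984 formulas", {
  set.seed(12)
  for (i in 1:25) {
    d1 <- rbinom(20, 2, runif(1, 0.05, 0.95))
    d2 <- rbinom(20, 2, runif(1, 0.05, 0.95))
    if (sum(d1) + sum(d2) == 0 || sum(d1) + sum(d2) == 80) next
    tg <- two_group_geno(d1, d2)
    fst <- weir_cockerham_fst(tg$geno, tg$samples, "G1")
    expect_equal(fst$theta, wc_oracle_theta(d1, d2), tolerance = 1e-12)
  }
})

test_that("theta is invariant to swapping ref and alt coding", {
  set.seed(13)
  d1 <- rbinom(30, 2, 0.3); d2 <- rbinom(30, 2, 0.6)
  tg <- two_group_geno(d1, d2)
  tg_flip <- two_group_geno(2 - d1, 2 - d2)
  f1 <- weir_cockerham_fst(tg$geno, tg$samples, "G1")
  f2 <- weir_cockerham_fst(tg_flip$geno, tg_flip$samples, "G1")
  expect_equal(f1$theta, f2$theta, tolerance = 1e-12)
})

test_that("monomorphic-everywhere variants are undefined, absent ones an error", {
  tg <- two_group_geno(rep(0, 10), rep(0, 10))
  fst <- weir_cockerham_fst(tg$geno, tg$samples, "G1")
  expect_true(is.na(fst$theta))
  expect_error(weir_cockerham_fst(tg$geno, tg$samples, "G1", variants = "nope"),
               "nope")
  expect_error(weir_cockerham_fst(tg$geno, tg$samples, "G9"), "focal")
})

test_that("mean theta averages the pairwise focal-versus-other estimates", {
  set.seed(14)
  ids <- paste0("S", 1:60)
  geno <- genotype_matrix(
    tibble::tibble(chrom = "chr1", pos = 100L, id = "v1", ref = "A", alt = "G"),
    ids, matrix(rbinom(60, 2, 0.4), 1))
  samples <- tibble::tibble(sample_id = ids,
                            population = rep(c("P1", "P2", "P3"), each = 20),
                            group = rep(c("G1", "G2", "G3"), each = 20),
                            sex = "F", batch = "B1")
  fst <- weir_cockerham_fst(geno, samples, "G1")
  expect_equal(nrow(fst), 2)
  expect_equal(unique(fst$mean_theta), mean(fst$theta))
})

test_that("the multi-locus estimator is the ratio of summed components", {
  set.seed(15)
  ids <- paste0("S", 1:80)
  geno <- genotype_matrix(
    tibble::tibble(chrom = "chr1", pos = 100L + 1:20, id = paste0("v", 1:20),
                   ref = "A", alt = "G"),
    ids, matrix(rbinom(20 * 80, 2, 0.4), 20))
  st <- tibble::tibble(sample_id = ids,
                       population = rep(c("P1", "P2"), each = 40),
                       group = rep(c("G1", "G2"), each = 40),
                       sex = "F", batch = "B1")
  fst <- weir_cockerham_fst(geno, st, "G1")
  ov <- fst_overall(fst)
  expect_equal(ov$theta_overall,
               sum(fst$a) / sum(fst$a + fst$b + fst$c))
  expect_equal(ov$n_variants, 20)
})

test_that("geographic frequency classes follow the stated rule order", {
  freqs <- tibble::tibble(
    variant_id = c("v1", "v2", "v3", "v4"),
    AFR = c(0.2, 0.12, 0, 0.04),
    AMR = c(0.3, 0.2, 0.1, 0.2),
    EAS = c(0.1, 0.3, 0.2, 0.3),
    EUR = c(0.08, 0, 0, 0.06),
    SAS = c(0.15, 0.1, 0.1, 0.01))
  cls <- classify_frequency_distribution(freqs)
  expect_equal(cls$class, c("globally_common", "absent_EUR", "absent_EUR_AFR",
                            "other"))
  expect_error(classify_frequency_distribution(
    tibble::tibble(variant_id = "v", AFR = 0, EUR = 0, AMR = 0, EAS = 0,
                   SAS = 0)), "monomorphic")
  expect_error(classify_frequency_distribution(
    tibble::tibble(variant_id = "v", AFR = 1.2, EUR = 0.1)), "\\[0, 1\\]")
})

test_that("per-stratum allele frequencies are exact", {
  tg <- two_group_geno(c(rep(2, 5), rep(0, 5)), rep(1, 10))
  af <- allele_frequency_by(tg$geno, tg$samples, "group")
  expect_equal(af$af[af$stratum == "G1"], 0.5)
  expect_equal(af$af[af$stratum == "G2"], 0.5)
  expect_equal(af$n, c(10, 10))
})

test_that("differential expression matches the two-sample t-test oracle", {
  set.seed(31)
  n <- 60
  ids <- paste0("S", 1:n)
  grp <- rep(c("AFR", "EUR", "EAS"), each = 20)
  vals <- matrix(rnorm(8 * n), 8, n)
  vals[3, grp == "AFR"] <- vals[3, grp == "AFR"] + 1  # planted shift
  fm <- feature_matrix(
    tibble::tibble(feature_id = paste0("G", 1:8), chrom = "chr1",
                   anchor = 1000L, gene_id = paste0("G", 1:8)),
    vals, ids, kind = "normalized")
  samples <- tibble::tibble(sample_id = ids, population = grp, group = grp,
                            sex = "F", batch = "B1")
  de <- differential_expression_by_group(fm, samples, "AFR")
  for (i in 1:8) {
    tt <- t.test(vals[i, grp == "AFR"], vals[i, grp != "AFR"],
                 var.equal = TRUE)
    expect_equal(de$p[i], tt$p.value, tolerance = 1e-10)
    expect_equal(de$estimate[i], unname(diff(rev(tt$estimate))),
                 tolerance = 1e-10)
  }
  expect_error(differential_expression_by_group(fm, samples, "OCE"), "focal")
})

test_that("a strongly shifted gene lands in the top DE decile", {
  set.seed(32)
  n <- 750
  grp <- rep(c("AFR", "EUR"), c(150, 600))
  vals <- matrix(rnorm(20 * n), 20, n)
  vals[7, grp == "AFR"] <- vals[7, grp == "AFR"] + 1
  fm <- feature_matrix(
    tibble::tibble(feature_id = paste0("G", 1:20), chrom = "chr1",
                   anchor = 1L, gene_id = paste0("G", 1:20)),
    vals, paste0("S", 1:n), kind = "normalized")
  samples <- tibble::tibble(sample_id = paste0("S", 1:n), population = grp,
                            group = grp, sex = "F", batch = "B1")
  de <- differential_expression_by_group(fm, samples, "AFR")
  expect_equal(de$decile[7], 10L)
})

test_that("fst_de_association validates its join and binning", {
  fst <- tibble::tibble(gene_id = paste0("G", 1:20),
                        mean_theta = runif(20, 0, 0.3))
  de <- tibble::tibble(gene_id = paste0("G", 1:20), p = runif(20),
                       q = runif(20), decile = rep(5L, 20))
  expect_error(fst_de_association(fst, de), "degenerate")
  de$decile <- rep(1:10, 2)
  out <- fst_de_association(fst, de)
  expect_equal(nrow(out$decile_means), 10)
  expect_error(fst_de_association(fst, dplyr::mutate(de, gene_id = paste0("H", 1:20))),
               "no genes shared")
})

test_that("interaction scan applies the group-MAF filter with a reason", {
  set.seed(41)
  n_per <- 40
  grp <- rep(c("AFR", "AMR", "EAS", "EUR", "SAS"), each = n_per)
  ids <- paste0("S", seq_along(grp))
  # variant present only in AFR
  d <- ifelse(grp == "AFR", rbinom(length(grp), 2, 0.3), 0)
  d2 <- rbinom(length(grp), 2, 0.4)
  geno <- genotype_matrix(
    tibble::tibble(chrom = "chr1", pos = c(100L, 200L), id = c("v1", "v2"),
                   ref = "A", alt = "G"),
    ids, rbind(d, d2))
  fm <- feature_matrix(
    tibble::tibble(feature_id = "G1", chrom = "chr1", anchor = 150L,
                   gene_id = "G1"),
    matrix(rnorm(length(grp)), 1), ids, kind = "normalized")
  samples <- tibble::tibble(sample_id = ids, population = grp, group = grp,
                            sex = "F", batch = "B1")
  res <- interaction_scan(geno, fm, samples,
                          tibble::tibble(gene_id = "G1",
                                         variant_id = c("v1", "v2")))
  expect_false(res$tested[res$variant_id == "v1"])
  expect_equal(res$skip_reason[res$variant_id == "v1"], "MAF filter")
  expect_true(res$tested[res$variant_id == "v2"])
  expect_equal(unique(res$n_tested), 1)
  expect_error(interaction_scan(geno, fm, samples,
                                tibble::tibble(gene_id = character(0),
                                               variant_id = character(0))),
               "empty")
})

test_that("conditioning on the co-causal variant removes apparent interaction", {
  set.seed(43)
  n_per <- 150
  grp <- rep(c("AFR", "EUR"), each = n_per)
  ids <- paste0("S", seq_along(grp))
  # v2 is correlated with v1 much more strongly in AFR than in EUR
  v1 <- rbinom(2 * n_per, 2, 0.5)
  sw <- ifelse(grp == "AFR", runif(2 * n_per) < 0.05, runif(2 * n_per) < 0.9)
  v2 <- ifelse(sw, rbinom(2 * n_per, 2, 0.5), v1)
  y <- 0.8 * v1 + 0.8 * v2 + rnorm(2 * n_per, 0, 0.6)
  geno <- genotype_matrix(
    tibble::tibble(chrom = "chr1", pos = c(100L, 200L), id = c("v1", "v2"),
                   ref = "A", alt = "G"), ids, rbind(v1, v2))
  fm <- feature_matrix(
    tibble::tibble(feature_id = "G1", chrom = "chr1", anchor = 150L,
                   gene_id = "G1"), matrix(y, 1), ids, kind = "normalized")
  samples <- tibble::tibble(sample_id = ids, population = grp, group = grp,
                            sex = "F", batch = "B1")
  leads <- tibble::tibble(gene_id = "G1", variant_id = c("v1", "v2"))
  single <- interaction_scan(geno, fm, samples, leads, mode = "single")
  joint <- interaction_scan(geno, fm, samples, leads, mode = "joint")
  expect_lt(single$p_interaction[1], 0.01)
  expect_gt(joint$p_interaction[1], single$p_interaction[1])
})

test_that("quasi-Poisson and Poisson point estimates coincide", {
  set.seed(51)
  genes <- tibble::tibble(gene_id = paste0("G", 1:200),
                          score = runif(200))
  top <- genes$score >= quantile(genes$score, 0.9)
  nsets <- rpois(200, ifelse(top, 0.6, 1.2))
  qp <- glm(nsets ~ top, family = quasipoisson())
  pois <- glm(nsets ~ top, family = poisson())
  expect_equal(coef(qp), coef(pois), tolerance = 1e-12)
})

test_that("constraint associations detect planted architecture differences", {
  set.seed(52)
  n_genes <- 400
  genes <- paste0("G", seq_len(n_genes))
  score <- runif(n_genes)
  top <- score >= quantile(score, 0.9)
  egene <- runif(n_genes) < ifelse(top, 0.4, 0.7)
  nsets <- ifelse(egene, rpois(n_genes, ifelse(top, 0.7, 1.4)) + 1L, 0L)
  afc <- tibble::tibble(
    gene_id = rep(genes, nsets),
    log2_afc = rnorm(sum(nsets), 0, ifelse(rep(top, nsets), 0.2, 0.55)))
  cs <- constraint_associations(
    tibble::tibble(gene_id = genes, score = score),
    tibble::tibble(gene_id = genes, egene = egene),
    tibble::tibble(gene_id = genes, n_sets = nsets), afc)
  tests <- cs$tests
  expect_lt(tests$statistic[tests$test == "nsets_quasipoisson_top_decile"], 0)
  expect_lt(tests$p[tests$test == "nsets_quasipoisson_top_decile"], 0.05)
  expect_lt(tests$p[tests$test == "abs_afc_top_decile_vs_other"], 0.05)
  expect_error(constraint_associations(
    tibble::tibble(gene_id = genes[1:12], score = score[1:12]),
    tibble::tibble(gene_id = genes[1:12], egene = rep(c(TRUE, FALSE), 6)),
    tibble::tibble(gene_id = genes[1:12], n_sets = nsets[1:12]), afc),
    "stratum")
})

test_that("replication status is overlap with the study-B union per gene", {
  sets_a <- tibble::tibble(
    gene_id = c("g1", "g1", "g2", "g3"),
    cs_id = c(1, 1, 1, 1),
    variant_id = c("v1", "v2", "v1", "v5"))
  b <- list(g1 = c("v2", "v9"), g2 = c("v9"))
  out <- replication_compare(sets_a, b)
  expect_equal(out$status, c("replicated", "not_replicated", "gene_absent_in_B"))
  expect_equal(as.integer(attr(out, "status_counts")), c(1L, 1L, 1L))
})
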