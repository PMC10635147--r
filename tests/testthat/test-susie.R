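indep_geno <- function(n, p, maf = 0.3, seed = 1) {
  set.seed(seed)
  matrix(rbinom(n * p, 2, maf), n, p,
         dimnames = list(NULL, paste0("v", seq_len(p))))
}

test_that("a lone causal variant without LD is found exactly", {
  X <- indep_geno(300, 20, seed = 5)
  y <- X[, 7] * 1.0
  fit <- susie_fit(X, y, L = 10)
  expect_equal(length(unique(fit$sets$cs_id)), 1)
  expect_equal(fit$sets$variant_id, "v7")
  expect_gt(fit$pip["v7"], 0.95)
  expect_true(fit$sets$lead)
})

test_that("single-effect inclusion weights match the analytic Bayes-factor softmax", {
  X <- indep_geno(150, 12, seed = 9)
  set.seed(10)
  y <- X[, 3] * 0.4 + rnorm(150)
  fit <- susie_fit(X, y, L = 1, tol = 1e-10, max_iter = 200)
  # closed-form single-effect regression at the fitted prior/residual variance
  Xs <- scale(X); yc <- y - mean(y)
  d <- colSums(Xs^2)
  bhat <- as.vector(crossprod(Xs, yc)) / d
  shat2 <- fit$sigma2 / d
  v <- fit$V[1]
  lbf <- 0.5 * log(shat2 / (shat2 + v)) + 0.5 * bhat^2 / shat2 * v / (v + shat2)
  alpha_oracle <- exp(lbf - max(lbf)) / sum(exp(lbf - max(lbf)))
  expect_equal(unname(fit$alpha[1, ]), unname(alpha_oracle), tolerance = 1e-6)
})

test_that("the ELBO is monotone non-decreasing", {
  for (s in 1:4) {
    X <- indep_geno(120, 25, seed = s)
    set.seed(s + 100)
    y <- X[, 1] * 0.5 + X[, 10] * 0.3 + rnorm(120)
    fit <- susie_fit(X, y, L = 5, tol = 1e-8, max_iter = 60)
    expect_true(all(diff(fit$elbo) >= -1e-8))
  }
})

test_that("set count respects L and purity filtering is enforced", {
  set.seed(55)
  n <- 200
  base <- rbinom(n, 2, 0.5)
  # a loose block: moderately correlated copies of one signal variant
  X <- sapply(1:12, function(j) {
    sw <- runif(n) < 0.35
    ifelse(sw, rbinom(n, 2, 0.5), base)
  })
  colnames(X) <- paste0("v", 1:12)
  y <- base * 0.4 + rnorm(n, 0, 1)
  strict <- susie_fit(X, y, L = 3, purity_min = 0.99)
  loose <- susie_fit(X, y, L = 3, purity_min = 0)
  expect_gt(nrow(loose$sets), 0)
  expect_lte(length(unique(loose$sets$cs_id)), 3)
  if (nrow(strict$sets)) expect_true(all(strict$sets$purity >= 0.99))
  expect_lte(length(unique(strict$sets$cs_id)),
             length(unique(loose$sets$cs_id)))
  # the discarded sets are exactly those below the purity threshold
  expect_setequal(unique(strict$sets$purity),
                  unique(loose$sets$purity[loose$sets$purity >= 0.99]))
})

test_that("zero-variance phenotypes are rejected", {
  X <- indep_geno(50, 5)
  expect_error(susie_fit(X, rep(1, 50)), "zero-variance")
})

test_that("credible sets shrink as LD weakens", {
  sizes <- sapply(c(0.99, 0.1), function(rho) {
    cfg <- sim_config(groups = c(AFR = 1, EUR = 1), pop_size_range = c(50L, 50L),
                      n_genes = 25, variants_per_gene = 40, ld_rho = rho,
                      n_causal_probs = c(0, 1, 0, 0, 0, 0), afc_sd = 0.6,
                      seed = 301)
    co <- simulate_cohort(cfg, splicing = FALSE)
    rs <- residualized_log2(co)
    sets <- suppressWarnings(
      finemap_features(co$genotypes, rs, rs$features$feature_id, L = 5))
    if (nrow(sets) == 0) return(NA_real_)
    median(table(paste(sets$feature_id, sets$cs_id)))
  })
  expect_gt(sizes[1], sizes[2])
})

test_that("intron credible sets merge by transitive variant sharing", {
  mk <- function(feature, cs, vars, incl = seq(0.9, by = -0.2,
                                               length.out = length(vars))) {
    tibble::tibble(gene_id = "G", feature_id = feature, cs_id = cs,
                   variant_id = vars, inclusion = incl)
  }
  two <- dplyr::bind_rows(mk("i1", 1, c("A", "B")), mk("i2", 1, c("B", "C")))
  m <- merge_intron_credible_sets(two)
  expect_equal(length(unique(m$cs_id)), 1)
  expect_setequal(m$variant_id, c("A", "B", "C"))
  expect_true(all(m$source_introns == "i1,i2"))

  disj <- dplyr::bind_rows(mk("i1", 1, "A"), mk("i2", 1, "C"))
  m2 <- merge_intron_credible_sets(disj)
  expect_equal(length(unique(m2$cs_id)), 2)

  chain <- list(mk("i1", 1, c("A", "B")), mk("i2", 1, c("B", "C")),
                mk("i3", 1, c("C", "D")))
  perms <- list(1:3, c(2, 1, 3), c(3, 2, 1), c(2, 3, 1), c(3, 1, 2), c(1, 3, 2))
  outs <- lapply(perms, function(p)
    merge_intron_credible_sets(dplyr::bind_rows(chain[p])))
  for (o in outs[-1]) expect_equal(o, outs[[1]])
  expect_setequal(outs[[1]]$variant_id, c("A", "B", "C", "D"))
  expect_equal(length(unique(outs[[1]]$cs_id)), 1)

  mixed <- dplyr::bind_rows(mk("i1", 1, "A"),
                            dplyr::mutate(mk("i2", 1, "B"), gene_id = "H"))
  expect_error(merge_intron_credible_sets(mixed), "different genes")
})

test_that("merged sets keep the maximum inclusion across sources", {
  a <- tibble::tibble(gene_id = "G", feature_id = "i1", cs_id = 1,
                      variant_id = c("A", "B"), inclusion = c(0.5, 0.4))
  b <- tibble::tibble(gene_id = "G", feature_id = "i2", cs_id = 1,
                      variant_id = c("B", "C"), inclusion = c(0.9, 0.05))
  m <- merge_intron_credible_sets(dplyr::bind_rows(a, b))
  expect_equal(m$inclusion[m$variant_id == "B"], 0.9)
  expect_equal(m$variant_id[m$lead], "B")
})

test_that("intron-level fine-mapping merges into gene-level splicing signals", {
  cfg <- sim_config(groups = c(AFR = 2, EUR = 2), pop_size_range = c(50L, 50L),
                    n_genes = 6, variants_per_gene = 30,
                    cluster_causal_prob = 1, sqtl_effect_sd = 3,
                    logit_noise_sd = 0.3, seed = 71)
  co <- simulate_cohort(cfg)
  sp <- suppressMessages(filter_features(co$splicing, min_value = 0,
                                         min_fraction = 0))
  rs <- residualize(inverse_normal_transform(sp), NULL)
  clu <- co$truth$splicing_clusters
  merged_all <- list()
  for (g in unique(rs$features$gene_id)) {
    introns <- rs$features$feature_id[rs$features$gene_id == g]
    sets <- suppressWarnings(
      finemap_features(co$genotypes, rs, introns, L = 3))
    if (nrow(sets) == 0) next
    freq <- variant_frequencies(co$genotypes)
    vi <- tibble::tibble(id = co$genotypes$variants$id, maf = freq$maf,
                         pos = co$genotypes$variants$pos)
    merged <- merge_intron_credible_sets(
      dplyr::select(sets, "gene_id", "feature_id", "cs_id", "variant_id",
                    "inclusion"), vi)
    merged_all[[g]] <- merged
    expect_true(all(table(merged$cs_id[merged$lead]) == 1))
  }
  merged_all <- dplyr::bind_rows(merged_all)
  expect_gt(nrow(merged_all), 0)
  # at least half of the merged gene-level signals pinpoint the true sVariant
  hits <- vapply(unique(merged_all$gene_id), function(g) {
    truth_v <- clu$causal_variant[clu$gene_id == g]
    any(merged_all$variant_id[merged_all$gene_id == g] %in% truth_v)
  }, logical(1))
  expect_gte(mean(hits), 0.5)
})

test_that("lead selection is deterministic with the stated tie rules", {
  set1 <- tibble::tibble(variant_id = c("a", "b", "c"),
                         inclusion = c(0.7, 0.2, 0.1))
  expect_equal(select_lead(set1), "a")
  vi <- tibble::tibble(id = c("a", "b"), maf = c(0.1, 0.3), pos = c(5L, 9L))
  set2 <- tibble::tibble(variant_id = c("a", "b"), inclusion = c(0.5, 0.5))
  expect_equal(select_lead(set2, vi), "b")
  vi3 <- tibble::tibble(id = c("a", "b"), maf = c(0.3, 0.3), pos = c(9L, 5L))
  expect_equal(select_lead(set2, vi3), "b")
  expect_error(select_lead(set1[0, ]), "empty")
})
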