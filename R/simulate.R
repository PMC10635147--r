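#' Configuration for the synthetic cohort generator
#'
#' The defaults emulate the structure of a globally diverse LCL cohort:
#' 26 populations nested in 5 continental groups with 27-30 individuals per
#' population (~731 samples), Balding-Nichols allele-frequency differentiation
#' at the group and population level, blockwise LD, and multi-causal cis
#' regulation acting multiplicatively on expression under the allelic
#' fold change (aFC) model. Every dimension scales down for tests.
#'
#' @param groups Named integer vector: populations per continental group.
#' @param pop_size_range Integer range of individuals per population.
#' @param f_group,f_pop Balding-Nichols differentiation parameters in (0,1)
#'   at the continental-group and population level.
#' @param n_genes Number of genes (one cis window each).
#' @param variants_per_gene Variants simulated per cis window.
#' @param ld_block_size,ld_rho LD block length (variants) and latent
#'   within-block correlation in `[0,1)`.
#' @param ld_rho_group Optional named vector of per-continental-group latent
#'   within-block correlations, overriding `ld_rho` (LD strength differs
#'   between human ancestry groups, African-ancestry groups having the least;
#'   this is the mechanism behind apparent cross-group effect-size
#'   heterogeneity of tag variants).
#' @param n_causal_probs Probabilities of 0..5 causal variants per gene.
#' @param maf_min_causal Minimum cohort MAF for a variant to be eligible as
#'   causal (monomorphic picks are thereby excluded by construction).
#' @param afc_sd,afc_cap Causal effects are log2 aFC values drawn from
#'   `Normal(0, afc_sd^2)` truncated at `±afc_cap`.
#' @param noise_sd Residual sd of log2 expression.
#' @param baseline_log2 Mean log2 expression of a reference-homozygote sample.
#' @param n_batches,batch_sd,sex_effect_sd Technical covariate structure:
#'   batches are assigned stratified across populations; per-gene batch and
#'   sex effects are drawn with these sds (log2 scale).
#' @param group_shift_frac,group_shift_sd Fraction of genes receiving
#'   continental-group expression shifts and their sd (log2 scale).
#' @param group_var_frac If non-`NULL`, overrides `group_shift_frac`: every
#'   gene receives group shifts scaled so the between-group share of log2
#'   expression variance equals this fraction exactly (given `noise_sd`).
#' @param group_noise_mult Optional named multipliers of `noise_sd` per group
#'   (models e.g. a diversity gradient across groups).
#' @param afc_fixed Optional numeric vector of fixed log2 aFC values; when
#'   set, a gene with k causal variants receives the first k entries
#'   (recycled) instead of random draws.
#' @param causal_same_block If `TRUE`, all causal variants of a gene are drawn
#'   from a single LD block (the effect-size-heterogeneity study condition).
#' @param causal_separate_blocks If `TRUE`, each causal variant of a gene is
#'   drawn from a different LD block (independent-signal study condition).
#' @param causal_bias Optional `list(intervals = tibble(chrom,start,end),
#'   odds = )`: variants inside the intervals get `odds`-fold higher weight
#'   when causal variants are sampled.
#' @param introns_range,cluster_causal_prob,sqtl_effect_sd,logit_noise_sd
#'   Splicing generator: introns per cluster, probability a cluster carries a
#'   causal sQTL, logit-scale effect sd, and logit-scale noise sd.
#' @param seed Integer seed; the generator is fully reproducible given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(groups = c(AFR = 7, AMR = 4, EAS = 5, EUR = 5, SAS = 5),
                       pop_size_range = c(27L, 30L),
                       f_group = 0.1, f_pop = 0.02,
                       n_genes = 50, variants_per_gene = 60,
                       ld_block_size = 10, ld_rho = 0.9, ld_rho_group = NULL,
                       n_causal_probs = c(0.25, 0.40, 0.20, 0.09, 0.04, 0.02),
                       maf_min_causal = 0.05,
                       afc_sd = 0.5, afc_cap = log2(100),
                       noise_sd = 0.5, baseline_log2 = 8,
                       n_batches = 4, batch_sd = 0.2, sex_effect_sd = 0.1,
                       group_shift_frac = 0.2, group_shift_sd = 0.25,
                       group_var_frac = NULL, group_noise_mult = NULL,
                       afc_fixed = NULL,
                       causal_same_block = FALSE, causal_separate_blocks = FALSE,
                       causal_bias = NULL,
                       introns_range = c(2L, 4L), cluster_causal_prob = 0.5,
                       sqtl_effect_sd = 1.5, logit_noise_sd = 0.5,
                       seed = 1L) {
  if (f_group <= 0 || f_group >= 1 || f_pop <= 0 || f_pop >= 1) {
    abort("Balding-Nichols F parameters must lie in (0, 1)")
  }
  if (ld_rho < 0 || ld_rho >= 1) abort("ld_rho must lie in [0, 1)")
  if (n_genes < 1 || variants_per_gene < 1 || any(groups < 1)) {
    abort("sizes must be positive")
  }
  cfg <- as.list(environment())
  cfg$n_causal_probs <- n_causal_probs / sum(n_causal_probs)
  structure(cfg, class = "sim_config")
}

#' Draw Balding-Nichols frequencies around a base frequency
#' @noRd
bn_draw <- function(p, f) {
  a <- p * (1 - f) / f
  b <- (1 - p) * (1 - f) / f
  rbeta(length(p), a, b)
}

#' Simulate genotypes under a two-level Balding-Nichols model with LD blocks
#'
#' Group frequencies are Beta-distributed around an ancestral frequency with
#' parameter `f_group`; population frequencies are drawn analogously around
#' their group frequency with `f_pop`. Haplotypes are drawn per population
#' under Hardy-Weinberg; LD is induced by thresholding latent Gaussian vectors
#' with exchangeable within-block correlation `ld_rho` at frequency-matched
#' quantiles.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return `list(genotypes, samples, truth)` where `truth` holds ancestral and
#'   drawn frequencies plus the gene/variant layout.
#' @export
simulate_genotypes <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)

  pops <- unlist(lapply(names(config$groups), function(g)
    paste0(g, seq_len(config$groups[[g]]))))
  pop_group <- rep(names(config$groups), config$groups)
  pop_sizes <- sample_safe(seq(config$pop_size_range[1], config$pop_size_range[2]),
                           length(pops), replace = TRUE)
  n <- sum(pop_sizes)
  samples <- tibble::tibble(
    sample_id = sprintf("S%04d", seq_len(n)),
    population = rep(pops, pop_sizes),
    group = rep(pop_group, pop_sizes),
    sex = sample(c("F", "M"), n, replace = TRUE),
    batch = as.character(NA)
  )
  # stratify batches across populations: round-robin within population
  batch <- character(n)
  for (p in pops) {
    ix <- which(samples$population == p)
    batch[ix] <- paste0("B", 1 + (seq_along(ix) - 1) %% config$n_batches)
  }
  samples$batch <- batch

  m_per <- config$variants_per_gene
  # genes round-robin across 22 autosomes so positions stay in integer range
  gj <- seq_len(config$n_genes)
  genes <- tibble::tibble(
    gene_id = sprintf("GENE%04d", gj),
    chrom = paste0("chr", (gj - 1L) %% 22L + 1L),
    tss = as.integer(1e6 + ((gj - 1L) %/% 22L) * 2.2e6)
  )
  variants <- dplyr::bind_rows(lapply(seq_len(config$n_genes), function(j) {
    pos <- sort(sample.int(1.8e6, m_per) - 9e5 + genes$tss[j])
    tibble::tibble(
      chrom = genes$chrom[j], pos = pos,
      id = sprintf("var_%04d_%03d", j, seq_len(m_per)),
      ref = "A", alt = "G", gene_id = genes$gene_id[j],
      block = paste0(genes$gene_id[j], "_b",
                     ceiling(seq_len(m_per) / config$ld_block_size))
    )
  }))
  m <- nrow(variants)

  # Variants in a tight LD block segregate on shared haplotypes: their
  # frequencies are nearly identical and their drift is shared. The ancestral
  # frequency is therefore drawn per block (small per-variant jitter), and the
  # Balding-Nichols Beta draws use one uniform quantile per (block, group) and
  # per (block, population) - a comonotone copula that leaves every variant's
  # marginal exactly Beta (so Var = F * p0 * (1 - p0) holds variant-wise)
  # while letting block-mates drift together.
  blocks <- match(variants$block, unique(variants$block))
  n_blocks <- max(blocks)
  p0_block <- runif(n_blocks, 0.1, 0.9)
  p0 <- pmin(pmax(p0_block[blocks] + runif(m, -0.05, 0.05), 0.05), 0.95)
  grp_names <- names(config$groups)
  qbn <- function(u, p, f) {
    p <- pmin(pmax(p, 1e-5), 1 - 1e-5)   # guard degenerate Beta shapes
    suppressWarnings(stats::qbeta(u, p * (1 - f) / f, (1 - p) * (1 - f) / f))
  }
  u_grp <- matrix(runif(n_blocks * length(grp_names)), n_blocks)
  p_grp <- vapply(seq_along(grp_names), function(g)
    qbn(u_grp[blocks, g], p0, config$f_group), numeric(m))
  colnames(p_grp) <- grp_names
  u_pop <- matrix(runif(n_blocks * length(pops)), n_blocks)
  p_pop <- vapply(seq_along(pops), function(k)
    qbn(u_pop[blocks, k], p_grp[, pop_group[k]], config$f_pop), numeric(m))
  colnames(p_pop) <- pops
  rho <- config$ld_rho

  dosage <- matrix(0, nrow = m, ncol = n,
                   dimnames = list(variants$id, samples$sample_id))
  draw_haplotypes <- function(nh, thr, rho_k) {
    u <- matrix(rnorm(nh * n_blocks), nh, n_blocks)
    z <- sqrt(rho_k) * u[, blocks, drop = FALSE] +
      sqrt(1 - rho_k) * matrix(rnorm(nh * m), nh, m)
    # allele = 1 when latent falls below the frequency-matched quantile
    t(z) < thr
  }
  for (k in seq_along(pops)) {
    ix <- which(samples$population == pops[k])
    thr <- qnorm(p_pop[, k])
    rho_k <- if (is.null(config$ld_rho_group)) rho else
      unname(config$ld_rho_group[pop_group[k]])
    h1 <- draw_haplotypes(length(ix), thr, rho_k)
    h2 <- draw_haplotypes(length(ix), thr, rho_k)
    dosage[, ix] <- h1 + h2
  }

  geno <- genotype_matrix(
    variants[, c("chrom", "pos", "id", "ref", "alt")],
    samples$sample_id, dosage)
  truth <- structure(list(
    config = config, genes = genes,
    variant_layout = variants[, c("id", "gene_id", "chrom", "pos", "block")],
    p0 = setNames(p0, variants$id), p_group = p_grp, p_pop = p_pop
  ), class = "sim_truth")
  list(genotypes = geno, samples = validate_sample_table(samples), truth = truth)
}

#' Truncated normal draw for log2 aFC effects
#' @noRd
draw_afc <- function(k, sd, cap) {
  d <- rnorm(k, 0, sd)
  while (any(bad <- abs(d) > cap)) d[bad] <- rnorm(sum(bad), 0, sd)
  d
}

#' Simulate expression under the multiplicative aFC model
#'
#' For sample i and gene g with causal set K, expression is
#' `b_g * prod_k ((2 - d_ik) + d_ik * 2^delta_k) / 2 * 2^(covariate, group
#' and noise terms)`: the generative inverse of the aFC effect-size
#' definition, so generator and estimator form a consistent pair.
#'
#' @inheritParams simulate_genotypes
#' @param genotypes,samples Output of [simulate_genotypes()].
#' @param truth The `sim_truth` from [simulate_genotypes()] (gene layout).
#' @return `list(expression, truth)`; `truth$expression_genes` records causal
#'   ids, log2 aFC values, group shifts and covariate effects per gene.
#' @export
simulate_expression <- function(genotypes, samples, config,
                                truth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- truth$genes
  layout <- truth$variant_layout
  n <- nrow(samples)
  freqs <- variant_frequencies(genotypes)
  eligible <- freqs$id[freqs$maf >= config$maf_min_causal]

  bias_w <- rep(1, nrow(layout))
  if (!is.null(config$causal_bias)) {
    iv <- config$causal_bias$intervals
    if (is.null(iv$chrom)) iv$chrom <- layout$chrom[1]
    inside <- rep(FALSE, nrow(layout))
    for (r in seq_len(nrow(iv))) {
      inside <- inside | (layout$chrom == iv$chrom[r] &
                            layout$pos >= iv$start[r] & layout$pos <= iv$end[r])
    }
    bias_w[inside] <- config$causal_bias$odds
  }
  names(bias_w) <- layout$id

  grp_names <- names(config$groups)
  grp_of_sample <- samples$group
  batch_levels <- sort(unique(samples$batch))
  sigma <- rep(config$noise_sd, n)
  if (!is.null(config$group_noise_mult)) {
    sigma <- sigma * unname(config$group_noise_mult[grp_of_sample])
  }

  vals <- matrix(0, nrow(genes), n,
                 dimnames = list(genes$gene_id, samples$sample_id))
  gene_truth <- vector("list", nrow(genes))
  for (j in seq_len(nrow(genes))) {
    g <- genes$gene_id[j]
    cand <- intersect(layout$id[layout$gene_id == g], eligible)
    if (isTRUE(config$causal_same_block)) {
      blk <- layout$block[match(cand, layout$id)]
      tab <- table(blk)
      pick_blk <- sample(names(tab)[tab == max(tab)], 1)
      cand <- cand[blk == pick_blk]
    }
    k <- sample(0:5, 1, prob = config$n_causal_probs)
    k <- min(k, length(cand))
    causal <- if (k == 0) {
      character(0)
    } else if (isTRUE(config$causal_separate_blocks)) {
      blk <- layout$block[match(cand, layout$id)]
      k <- min(k, length(unique(blk)))
      picked_blocks <- sample_safe(unique(blk), k)
      vapply(picked_blocks, function(b)
        sample_safe(cand[blk == b], 1, prob = bias_w[cand[blk == b]]), "")
    } else {
      sample_safe(cand, k, prob = bias_w[cand])
    }
    delta <- if (!is.null(config$afc_fixed)) {
      rep_len(config$afc_fixed, max(k, 1))[seq_len(k)]
    } else {
      draw_afc(k, config$afc_sd, config$afc_cap)
    }

    log2e <- rep(config$baseline_log2, n)
    if (k > 0) {
      d <- genotypes$dosage[causal, , drop = FALSE]
      for (q in seq_len(k)) {
        log2e <- log2e + log2(((2 - d[q, ]) + d[q, ] * 2^delta[q]) / 2)
      }
    }
    if (!is.null(config$group_var_frac)) {
      e <- rnorm(length(grp_names))
      s <- e[match(grp_of_sample, grp_names)]
      s <- s - mean(s)
      v <- mean(s^2)
      target <- config$noise_sd^2 * config$group_var_frac / (1 - config$group_var_frac)
      shift <- if (v > 0) s * sqrt(target / v) else s
      gshift <- setNames(tapply(shift, grp_of_sample, mean)[grp_names], grp_names)
    } else if (runif(1) < config$group_shift_frac) {
      gshift <- setNames(rnorm(length(grp_names), 0, config$group_shift_sd), grp_names)
      shift <- gshift[grp_of_sample]
    } else {
      gshift <- setNames(rep(0, length(grp_names)), grp_names)
      shift <- rep(0, n)
    }
    beff <- setNames(rnorm(length(batch_levels), 0, config$batch_sd), batch_levels)
    seff <- rnorm(1, 0, config$sex_effect_sd)
    log2e <- log2e + shift + beff[samples$batch] + seff * (samples$sex == "F") +
      rnorm(n, 0, sigma)
    vals[j, ] <- 2^log2e
    gene_truth[[j]] <- tibble::tibble(
      gene_id = g, n_causal = k,
      causal = list(causal), delta = list(delta),
      group_shift = list(gshift), sex_effect = seff)
  }
  fm <- feature_matrix(
    tibble::tibble(feature_id = genes$gene_id, chrom = genes$chrom,
                   anchor = genes$tss, strand = "+", gene_id = genes$gene_id,
                   cluster_id = NA_character_),
    vals, samples$sample_id, kind = "raw-count")
  truth$expression_genes <- dplyr::bind_rows(gene_truth)
  list(expression = fm, truth = truth)
}

#' Simulate intron-excision ratios with cis splicing effects
#'
#' One splicing cluster per gene; intron usage proportions follow a
#' logistic-normal whose logits shift additively with the dosage of a causal
#' variant. Per-sample ratios sum to 1 within each cluster.
#'
#' @inheritParams simulate_expression
#' @return `list(splicing, truth)`; `truth$splicing_clusters` records the
#'   causal variant, target intron and logit effect per cluster.
#' @export
simulate_splicing <- function(genotypes, samples, config, truth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (config$introns_range[1] < 2) abort("clusters need at least 2 introns")
  genes <- truth$genes
  layout <- truth$variant_layout
  n <- nrow(samples)
  freqs <- variant_frequencies(genotypes)
  eligible <- freqs$id[freqs$maf >= config$maf_min_causal]

  feats <- list(); vals <- list(); clu_truth <- list()
  for (j in seq_len(nrow(genes))) {
    g <- genes$gene_id[j]
    clu <- paste0(g, ":clu", j)
    ni <- sample_safe(seq(config$introns_range[1], config$introns_range[2]), 1)
    base <- rnorm(ni, 0, 1)
    cand <- intersect(layout$id[layout$gene_id == g], eligible)
    has_effect <- length(cand) > 0 && runif(1) < config$cluster_causal_prob
    causal <- if (has_effect) sample(cand, 1) else NA_character_
    target <- if (has_effect) sample.int(ni, 1) else NA_integer_
    eff <- if (has_effect) {
      e <- 0
      while (abs(e) < 0.25) e <- rnorm(1, 0, config$sqtl_effect_sd)
      e
    } else 0
    logits <- matrix(base, ni, n) + matrix(rnorm(ni * n, 0, config$logit_noise_sd), ni, n)
    if (has_effect) {
      logits[target, ] <- logits[target, ] + eff * genotypes$dosage[causal, ]
    }
    expl <- exp(logits)
    ratio <- sweep(expl, 2, colSums(expl), "/")
    ids <- paste0(clu, ":intron", seq_len(ni))
    feats[[j]] <- tibble::tibble(
      feature_id = ids, chrom = genes$chrom[j],
      anchor = genes$tss[j] + 100L * seq_len(ni), strand = "+",
      gene_id = g, cluster_id = clu)
    vals[[j]] <- ratio
    clu_truth[[j]] <- tibble::tibble(
      cluster_id = clu, gene_id = g, n_introns = ni,
      causal_variant = causal, target_intron = target, logit_effect = eff)
  }
  fm <- feature_matrix(dplyr::bind_rows(feats), do.call(rbind, vals),
                       samples$sample_id, kind = "excision-ratio")
  truth$splicing_clusters <- dplyr::bind_rows(clu_truth)
  list(splicing = fm, truth = truth)
}

#' Simulate a complete cohort
#'
#' Runs [simulate_genotypes()], [simulate_expression()] and (optionally)
#' [simulate_splicing()] under a single seed.
#'
#' @param config A [sim_config()].
#' @param splicing Include intron-excision phenotypes?
#' @return `list(genotypes, samples, expression, splicing, truth)`.
#' @export
simulate_cohort <- function(config, splicing = TRUE) {
  g <- simulate_genotypes(config)
  e <- simulate_expression(g$genotypes, g$samples, config, g$truth)
  out <- list(genotypes = g$genotypes, samples = g$samples,
              expression = e$expression, splicing = NULL, truth = e$truth)
  if (splicing) {
    s <- simulate_splicing(g$genotypes, g$samples, config, e$truth)
    out$splicing <- s$splicing
    out$truth <- s$truth
  }
  out
}

#' Write a simulated cohort to disk as standard-format fixtures
#'
#' Emits `genotypes.vcf`, `expression.bed`, `splicing.bed` (when present),
#' `samples.tsv` and `truth.json`, re-readable by the package's readers.
#' Output is deterministic given the generator seed.
#'
#' @param dir Output directory.
#' @param cohort Output of [simulate_cohort()].
#' @param overwrite Overwrite an existing fixture set?
#' @return Character vector of written paths.
#' @export
write_fixture <- function(dir, cohort, overwrite = FALSE) {
  marker <- file.path(dir, "truth.json")
  if (file.exists(marker) && !overwrite) {
    abort(paste("fixture already exists in", dir, "(use overwrite = TRUE)"))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    write_genotypes(cohort$genotypes, file.path(dir, "genotypes.vcf")),
    write_phenotype_bed(cohort$expression, file.path(dir, "expression.bed")),
    write_sample_table(cohort$samples, file.path(dir, "samples.tsv"))
  )
  if (!is.null(cohort$splicing)) {
    paths <- c(paths, write_phenotype_bed(cohort$splicing, file.path(dir, "splicing.bed")))
  }
  tr <- cohort$truth
  json <- list(
    config = unclass(tr$config)[!vapply(unclass(tr$config), is.null, TRUE)],
    genes = tr$genes,
    expression_genes = if (!is.null(tr$expression_genes)) {
      dplyr::mutate(tr$expression_genes,
                    causal = vapply(.data$causal, paste, "", collapse = ","),
                    delta = vapply(.data$delta, paste, "", collapse = ","),
                    group_shift = vapply(.data$group_shift,
                                         function(x) paste(signif(x, 10), collapse = ","), ""))
    },
    splicing_clusters = tr$splicing_clusters,
    p0 = tr$p0
  )
  jsonlite::write_json(json, marker, auto_unbox = TRUE, digits = NA, null = "null")
  c(paths, marker)
}
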