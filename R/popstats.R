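#' Weir & Cockerham (1984) variance components for two groups at one variant
#' @noRd
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  c(a = a, b = b, c = c)
}

#' Weir-Cockerham FST of variants between a focal group and each other group
#'
#' The diploid variance-components estimator of Weir & Cockerham (1984):
#' `theta_hat = a / (a + b + c)` computed from allele frequencies, observed
#' heterozygosities and sample sizes of each (focal, other) group pair.
#' Pairs monomorphic in both groups are flagged undefined rather than zero,
#' and negative estimates are retained (the estimator is noisy around zero
#' under the null; truncation would bias averages).
#'
#' @param genotypes A [genotype_matrix()].
#' @param samples Sample tibble (aligned with `genotypes`).
#' @param focal Focal continental group label.
#' @param variants Variant ids to evaluate (default: all).
#' @return Tibble with one row per (variant, other group): variance
#'   components `a`, `b`, `c`, `theta`, plus the per-variant
#'   `mean_theta` across defined pairs.
#' @export
weir_cockerham_fst <- function(genotypes, samples, focal,
                               variants = genotypes$variants$id) {
  groups <- unique(samples$group)
  if (!(focal %in% groups)) abort(paste("focal group absent:", focal))
  if (length(groups) < 2) abort("need at least 2 groups")
  vix <- match(variants, genotypes$variants$id)
  if (anyNA(vix)) {
    abort(paste("variant(s) missing from genotypes:",
                toString(variants[is.na(vix)])))
  }
  others <- setdiff(groups, focal)
  group_stats <- function(g) {
    dos <- genotypes$dosage[vix, samples$group == g, drop = FALSE]
    n <- rowSums(!is.na(dos))
    if (any(n < 2)) abort("every group needs >= 2 genotyped samples per variant")
    list(n = n, p = rowMeans(dos, na.rm = TRUE) / 2,
         h = rowMeans(dos == 1, na.rm = TRUE))
  }
  fs <- group_stats(focal)
  out <- list()
  for (g in others) {
    gs <- group_stats(g)
    comp <- t(vapply(seq_along(vix), function(i)
      wc_components(fs$n[i], fs$p[i], fs$h[i], gs$n[i], gs$p[i], gs$h[i]),
      numeric(3)))
    denom <- rowSums(comp)
    theta <- ifelse(abs(denom) < 1e-300, NA_real_, comp[, 1] / denom)
    out[[g]] <- tibble::tibble(
      variant_id = variants, focal = focal, other = g,
      a = unname(comp[, 1]), b = unname(comp[, 2]), c = unname(comp[, 3]),
      theta = unname(theta))
  }
  res <- dplyr::bind_rows(out)
  means <- res |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(mean_theta = mean(.data$theta, na.rm = TRUE),
                     .groups = "drop")
  dplyr::left_join(res, means, by = "variant_id")
}

#' Multi-locus FST as the ratio of summed variance components
#'
#' Weir & Cockerham's recommended combined estimator over a set of variants:
#' `sum(a) / sum(a + b + c)` per (focal, other) pair. Averaging per-variant
#' ratios instead is biased downward; the ratio of sums is the standard
#' genome-wide summary.
#'
#' @param fst Output of [weir_cockerham_fst()].
#' @return Tibble with one row per (focal, other) pair: `theta_overall`,
#'   `n_variants`, plus the grand ratio over all pairs in the
#'   `"theta_overall_all_pairs"` attribute.
#' @export
fst_overall <- function(fst) {
  out <- fst |>
    dplyr::group_by(.data$focal, .data$other) |>
    dplyr::summarise(
      theta_overall = sum(.data$a, na.rm = TRUE) /
        sum(.data$a + .data$b + .data$c, na.rm = TRUE),
      n_variants = dplyr::n_distinct(.data$variant_id), .groups = "drop")
  attr(out, "theta_overall_all_pairs") <-
    sum(fst$a, na.rm = TRUE) / sum(fst$a + fst$b + fst$c, na.rm = TRUE)
  out
}

#' Alternate-allele frequency per sample stratum
#'
#' @param genotypes A [genotype_matrix()].
#' @param samples Sample tibble.
#' @param by Stratifying column of `samples` (`"group"` or `"population"`).
#' @param variants Variant ids (default all).
#' @return Tibble `variant_id`, stratum, `af`, `n`.
#' @export
allele_frequency_by <- function(genotypes, samples, by = "group",
                                variants = genotypes$variants$id) {
  vix <- match(variants, genotypes$variants$id)
  if (anyNA(vix)) abort("variant(s) missing from genotypes")
  strata <- unique(samples[[by]])
  dplyr::bind_rows(lapply(strata, function(s) {
    dos <- genotypes$dosage[vix, samples[[by]] == s, drop = FALSE]
    tibble::tibble(variant_id = variants, stratum = s,
                   af = unname(rowMeans(dos, na.rm = TRUE) / 2),
                   n = unname(rowSums(!is.na(dos))))
  }))
}

#' Classify the geographic frequency distribution of variants
#'
#' Mutually exclusive classes evaluated in order: `absent_EUR_AFR` (allele
#' frequency 0 in both the European and African group but positive elsewhere),
#' `absent_EUR` (0 in the European group, positive in at least one other),
#' `globally_common` (frequency above `common_threshold` in every group),
#' else `other`.
#'
#' @param freqs Tibble with `variant_id` and one allele-frequency column per
#'   continental group (wide), or the long output of [allele_frequency_by()].
#' @param common_threshold Global commonness threshold (default 0.05).
#' @param eur,afr Column names of the European and African groups.
#' @return Tibble `variant_id`, `class`, plus the per-group frequencies; the
#'   `"class_counts"` attribute tabulates classes.
#' @export
classify_frequency_distribution <- function(freqs, common_threshold = 0.05,
                                            eur = "EUR", afr = "AFR") {
  if (all(c("stratum", "af") %in% names(freqs))) {
    freqs <- tidyr::pivot_wider(freqs[, c("variant_id", "stratum", "af")],
                                names_from = "stratum", values_from = "af")
  }
  gcols <- setdiff(names(freqs), "variant_id")
  af <- as.matrix(freqs[, gcols])
  if (any(af < 0 | af > 1, na.rm = TRUE)) abort("allele frequencies must lie in [0, 1]")
  if (any(rowSums(af) == 0)) {
    abort("variant monomorphic in all groups cannot be classified")
  }
  has_eur <- eur %in% gcols; has_afr <- afr %in% gcols
  cls <- rep("other", nrow(af))
  common <- rowSums(af > common_threshold) == ncol(af)
  cls[common] <- "globally_common"
  if (has_eur) {
    a_eur <- af[, eur] == 0 & rowSums(af > 0) >= 1
    cls[a_eur] <- "absent_EUR"
    if (has_afr) {
      a_both <- af[, eur] == 0 & af[, afr] == 0 & rowSums(af > 0) >= 1
      cls[a_both] <- "absent_EUR_AFR"
    }
  }
  out <- dplyr::mutate(freqs, class = cls, .after = "variant_id")
  attr(out, "class_counts") <- table(cls)
  out
}

#' Differential expression between a focal group and all other samples
#'
#' Per gene, a two-sample linear contrast (focal vs rest) on the residualized
#' expression; genes are ranked by p-value and binned into deciles, the 10th
#' decile holding the smallest p-values (strongest differential expression).
#'
#' @inheritParams partition_variance
#' @param focal Focal continental group.
#' @return Tibble: `gene_id`, `estimate` (focal minus rest), `tstat`, `p`,
#'   `q` (BH), `decile`.
#' @export
differential_expression_by_group <- function(fm, samples, focal) {
  grp <- samples$group == focal
  if (!any(grp)) abort(paste("focal group absent:", focal))
  n1 <- sum(grp); n2 <- sum(!grp); n <- n1 + n2
  m1 <- rowMeans(fm$values[, grp, drop = FALSE])
  m2 <- rowMeans(fm$values[, !grp, drop = FALSE])
  ss <- rowSums((fm$values[, grp, drop = FALSE] - m1)^2) +
    rowSums((fm$values[, !grp, drop = FALSE] - m2)^2)
  se <- sqrt(ss / (n - 2) * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  p <- 2 * pt(abs(t), n - 2, lower.tail = FALSE)
  dec <- as.integer(cut(rank(-p, ties.method = "first"),
                        breaks = quantile(rank(-p, ties.method = "first"),
                                          probs = seq(0, 1, 0.1)),
                        include.lowest = TRUE, labels = FALSE))
  tibble::tibble(gene_id = fm$features$gene_id, estimate = unname(m1 - m2),
                 tstat = unname(t), p = unname(p),
                 q = unname(p.adjust(p, "BH")), decile = dec)
}

#' Association between lead-eQTL FST and differential expression
#'
#' Mean lead-eQTL FST per DE decile, a rank-sum (Mann-Whitney) test of FST
#' for differentially expressed eGenes (`q <= de_fdr`) versus non-DE eGenes,
#' and the rank-biserial effect size with a bootstrap interval.
#'
#' @param fst Tibble keyed by `gene_id` with a `mean_theta` column (lead-eQTL
#'   FST per gene).
#' @param de Output of [differential_expression_by_group()].
#' @param de_fdr DE significance cutoff on `q` (default 0.05).
#' @param n_boot Bootstrap resamples for the effect-size interval.
#' @param seed Bootstrap seed.
#' @return `list(decile_means, test)`.
#' @export
fst_de_association <- function(fst, de, de_fdr = 0.05, n_boot = 200, seed = 1) {
  dat <- dplyr::inner_join(fst, de, by = "gene_id")
  if (nrow(dat) == 0) abort("no genes shared between FST and DE tables")
  if (length(unique(dat$decile)) < 2) abort("degenerate decile binning")
  decile_means <- dat |>
    dplyr::group_by(.data$decile) |>
    dplyr::summarise(mean_fst = mean(.data$mean_theta, na.rm = TRUE),
                     n = dplyr::n(), .groups = "drop")
  is_de <- dat$q <= de_fdr
  test <- NULL
  if (any(is_de) && any(!is_de)) {
    wt <- wilcox.test(dat$mean_theta[is_de], dat$mean_theta[!is_de])
    n1 <- sum(is_de); n2 <- sum(!is_de)
    rb <- function(flag, theta) {
      u <- wilcox.test(theta[flag], theta[!flag], exact = FALSE)$statistic
      2 * u / (sum(flag) * sum(!flag)) - 1
    }
    set.seed(seed)
    boot <- vapply(seq_len(n_boot), function(b) {
      ix <- sample.int(nrow(dat), replace = TRUE)
      if (length(unique(is_de[ix])) < 2) return(NA_real_)
      rb(is_de[ix], dat$mean_theta[ix])
    }, numeric(1))
    test <- tibble::tibble(
      statistic = unname(wt$statistic), p = wt$p.value,
      rank_biserial = rb(is_de, dat$mean_theta),
      rb_lo = quantile(boot, 0.025, na.rm = TRUE),
      rb_hi = quantile(boot, 0.975, na.rm = TRUE),
      n_de = n1, n_non_de = n2)
  }
  list(decile_means = decile_means, test = test)
}

#' Genotype-by-continental-group interaction scan over lead eQTLs
#'
#' For each lead variant, compares the additive association model to one with
#' a genotype-by-group interaction term (omnibus F-test over group levels).
#' In `"single"` mode the models are `y ~ g + group` vs `y ~ g * group`; in
#' `"joint"` mode both additionally include additive dosage terms for every
#' other lead of the same gene, so apparent heterogeneity caused by unmodelled
#' additive signals is controlled for. Leads are tested only when their MAF is
#' at least `maf_group_min` in two or more groups; groups smaller than
#' `min_group_n` samples cause a skip. Bonferroni correction is over the
#' number of tested leads.
#'
#' @inheritParams nominal_pass
#' @param samples Sample tibble (aligned).
#' @param leads Tibble `gene_id`, `variant_id` of lead eQTLs (all leads of a
#'   gene are used as conditioning terms in joint mode).
#' @param mode `"single"` or `"joint"`.
#' @param alpha Family-wise level for the Bonferroni threshold (default 0.05).
#' @param maf_group_min Per-group MAF filter (default 0.05).
#' @param min_group_n Minimum samples per group (default 10).
#' @return Tibble: per lead, `p_interaction`, `f_stat`, `tested`,
#'   `skip_reason`, `significant` (Bonferroni), `n_tested`, `mode`.
#' @export
interaction_scan <- function(genotypes, fm, samples, leads,
                             mode = c("single", "joint"), alpha = 0.05,
                             maf_group_min = 0.05, min_group_n = 10) {
  mode <- match.arg(mode)
  if (nrow(leads) == 0) abort("empty leads list")
  stopifnot(identical(genotypes$samples, fm$samples))
  groups <- factor(samples$group)
  gtab <- table(groups)
  dos <- impute_dosage(genotypes$dosage)
  res <- list()
  for (i in seq_len(nrow(leads))) {
    g <- leads$gene_id[i]; v <- leads$variant_id[i]
    vix <- match(v, genotypes$variants$id)
    gi <- match(g, fm$features$gene_id)
    if (is.na(vix) || is.na(gi)) {
      abort(paste("lead not found in cohort:", g, v))
    }
    skip <- NA_character_
    if (any(gtab < min_group_n)) {
      skip <- sprintf("group with < %d samples", min_group_n)
    } else {
      gmaf <- vapply(levels(groups), function(G) {
        a <- mean(dos[vix, groups == G]) / 2
        min(a, 1 - a)
      }, numeric(1))
      if (sum(gmaf >= maf_group_min) < 2) skip <- "MAF filter"
    }
    if (!is.na(skip)) {
      res[[i]] <- tibble::tibble(gene_id = g, variant_id = v, mode = mode,
                                 tested = FALSE, skip_reason = skip,
                                 f_stat = NA_real_, p_interaction = NA_real_)
      next
    }
    y <- fm$values[gi, ]
    gdos <- dos[vix, ]
    dat <- data.frame(y = y, g = gdos, grp = groups)
    if (mode == "joint") {
      others <- setdiff(leads$variant_id[leads$gene_id == g], v)
      for (k in seq_along(others)) {
        dat[[paste0("o", k)]] <- dos[match(others[k], genotypes$variants$id), ]
      }
      base_terms <- c("g", "grp",
                      if (length(others)) paste0("o", seq_along(others)))
    } else {
      base_terms <- c("g", "grp")
    }
    f0 <- lm(as.formula(paste("y ~", paste(base_terms, collapse = " + "))), data = dat)
    f1 <- lm(as.formula(paste("y ~", paste(c(base_terms, "g:grp"), collapse = " + "))),
             data = dat)
    av <- anova(f0, f1)
    res[[i]] <- tibble::tibble(gene_id = g, variant_id = v, mode = mode,
                               tested = TRUE, skip_reason = NA_character_,
                               f_stat = av$F[2], p_interaction = av$`Pr(>F)`[2])
  }
  out <- dplyr::bind_rows(res)
  n_tested <- sum(out$tested)
  out$n_tested <- n_tested
  out$bonferroni_threshold <- if (n_tested > 0) alpha / n_tested else NA_real_
  out$significant <- out$tested & !is.na(out$p_interaction) &
    out$p_interaction <= out$bonferroni_threshold
  out
}

#' Constraint-score associations of eGenes, credible-set counts and effects
#'
#' Three tests linking gene-level mutational constraint (e.g. pLI) to eQTL
#' architecture: a rank-sum test of constraint score for eGenes versus
#' non-eGenes; a quasi-Poisson GLM of the number of credible sets on a
#' top-decile-constraint indicator; and a rank-sum test of lead-eQTL
#' `|log2 aFC|` for top-decile versus other genes. The top-decile indicator
#' is derived from the empirical score distribution of the tested genes.
#'
#' @param constraint Tibble `gene_id`, `score`.
#' @param egene_flags Tibble `gene_id`, `egene` (logical).
#' @param n_sets Tibble `gene_id`, `n_sets` (credible sets per gene; 0 for
#'   none).
#' @param afc Tibble `gene_id`, `log2_afc` per lead (output of
#'   [estimate_afc()]).
#' @param min_stratum Minimum genes per compared stratum (default 10).
#' @return A `constraint_stats` object: `$tests` tibble plus the merged
#'   per-gene table in `$genes`.
#' @export
constraint_associations <- function(constraint, egene_flags, n_sets, afc,
                                    min_stratum = 10) {
  genes <- constraint |>
    dplyr::inner_join(egene_flags, by = "gene_id") |>
    dplyr::left_join(n_sets, by = "gene_id") |>
    dplyr::mutate(n_sets = dplyr::coalesce(.data$n_sets, 0L))
  aefs <- afc |>
    dplyr::filter(!is.na(.data$log2_afc)) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(mean_abs_afc = mean(abs(.data$log2_afc)), .groups = "drop")
  genes <- dplyr::left_join(genes, aefs, by = "gene_id")
  genes$top_decile <- genes$score >= quantile(genes$score, 0.9, na.rm = TRUE)
  if (sum(genes$egene) < min_stratum || sum(!genes$egene) < min_stratum ||
      sum(genes$top_decile) < min_stratum || sum(!genes$top_decile) < min_stratum) {
    abort(sprintf("fewer than %d genes in a compared stratum", min_stratum))
  }
  w1 <- wilcox.test(score ~ egene, data = genes)
  qp <- glm(n_sets ~ top_decile, data = genes, family = quasipoisson())
  afc_dat <- genes[!is.na(genes$mean_abs_afc), ]
  w2 <- if (sum(afc_dat$top_decile) >= 2 && sum(!afc_dat$top_decile) >= 2) {
    wilcox.test(mean_abs_afc ~ top_decile, data = afc_dat)
  } else NULL
  tests <- tibble::tibble(
    test = c("score_egene_vs_non", "nsets_quasipoisson_top_decile",
             "abs_afc_top_decile_vs_other"),
    statistic = c(unname(w1$statistic), coef(qp)["top_decileTRUE"],
                  if (is.null(w2)) NA_real_ else unname(w2$statistic)),
    p = c(w1$p.value, summary(qp)$coefficients["top_decileTRUE", 4],
          if (is.null(w2)) NA_real_ else w2$p.value))
  structure(list(tests = tests, genes = genes, glm = qp),
            class = "constraint_stats")
}

#' @export
print.constraint_stats <- function(x, ...) {
  cat("<constraint_stats>\n")
  print(x$tests)
  invisible(x)
}

#' Compare credible sets between two studies by membership overlap
#'
#' A study-A credible set replicates in study B when its membership
#' intersects the union of study-B credible-set variants for the same gene;
#' genes without any study-B set are reported as `gene_absent_in_B`.
#'
#' @param sets_a Tibble `gene_id`, `cs_id`, `variant_id` (study A sets).
#' @param sets_b_by_gene Named list: gene id -> character vector of study-B
#'   credible-set variant ids (union across sets/tissues).
#' @return Tibble `gene_id`, `cs_id`, `status`; the `"status_counts"`
#'   attribute tabulates statuses.
#' @export
replication_compare <- function(sets_a, sets_b_by_gene) {
  res <- sets_a |>
    dplyr::group_by(.data$gene_id, .data$cs_id) |>
    dplyr::summarise(members = list(.data$variant_id), .groups = "drop")
  res$status <- vapply(seq_len(nrow(res)), function(i) {
    b <- sets_b_by_gene[[res$gene_id[i]]]
    if (is.null(b) || length(b) == 0) return("gene_absent_in_B")
    if (length(intersect(res$members[[i]], b))) "replicated" else "not_replicated"
  }, character(1))
  out <- res[, c("gene_id", "cs_id", "status")]
  attr(out, "status_counts") <- table(out$status)
  out
}
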