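#' Two-sided p-value from a Pearson correlation
#' @noRd
p_from_r <- function(r, n) {
  r2 <- pmin(r^2, 1 - 1e-15)
  t <- abs(r) * sqrt((n - 2) / (1 - r2))
  2 * pt(t, n - 2, lower.tail = FALSE)
}

#' Index cis variants for one feature
#' @noRd
cis_variants <- function(geno, anchor, chrom, window, maf, maf_min) {
  which(geno$variants$chrom == chrom &
          abs(geno$variants$pos - anchor) <= window &
          maf >= maf_min & maf > 0)
}

#' Nominal cis association pass
#'
#' For each feature, simple linear regression of the residualized phenotype on
#' alternate-allele dosage for every variant within `window` bp of the feature
#' anchor with cohort MAF at least `maf_min`. Missing dosages are mean-imputed
#' per variant. Two-sided t-test p-values.
#'
#' @param genotypes A [genotype_matrix()] (sample-aligned with `fm`).
#' @param fm Residualized [feature_matrix()].
#' @param window cis window in bp around the feature anchor (default 1 Mb).
#' @param maf_min Minimum cohort MAF (default 0.01).
#' @return Tibble with one row per feature-variant pair: `feature_id`,
#'   `variant_id`, `slope`, `se`, `tstat`, `p`, `maf`, `distance`.
#'   Features with no testable cis variant are recorded in the
#'   `"skipped_features"` attribute, not dropped silently.
#' @export
nominal_pass <- function(genotypes, fm, window = 1e6, maf_min = 0.01) {
  if (window <= 0) abort("window must be positive")
  stopifnot(identical(genotypes$samples, fm$samples))
  n <- length(fm$samples)
  dos <- impute_dosage(genotypes$dosage)
  maf <- variant_frequencies(genotypes)$maf
  out <- vector("list", nrow(fm$values))
  skipped <- character(0)
  for (i in seq_len(nrow(fm$values))) {
    idx <- cis_variants(genotypes, fm$features$anchor[i], fm$features$chrom[i],
                        window, maf, maf_min)
    if (length(idx)) {
      sds <- apply(dos[idx, , drop = FALSE], 1, sd)
      idx <- idx[sds > 0]
    }
    if (!length(idx)) {
      skipped <- c(skipped, fm$features$feature_id[i])
      next
    }
    y <- fm$values[i, ]
    g <- dos[idx, , drop = FALSE]
    gy <- as.vector(g %*% y) - rowSums(g) * mean(y)
    gg <- rowSums(g^2) - rowSums(g)^2 / n
    yy <- sum(y^2) - n * mean(y)^2
    slope <- gy / gg
    r <- gy / sqrt(gg * yy)
    sse <- yy * (1 - pmin(r^2, 1))
    se <- sqrt(sse / (n - 2) / gg)
    out[[i]] <- tibble::tibble(
      feature_id = fm$features$feature_id[i],
      variant_id = genotypes$variants$id[idx],
      slope = unname(slope), se = unname(se), tstat = unname(slope / se),
      p = unname(p_from_r(r, n)), maf = maf[idx],
      distance = genotypes$variants$pos[idx] - fm$features$anchor[i])
  }
  res <- dplyr::bind_rows(out)
  attr(res, "skipped_features") <- skipped
  res
}

#' Maximum-likelihood beta fit to permutation minimum p-values
#' @noRd
fit_beta_ml <- function(x) {
  x <- pmin(pmax(x, 1e-300), 1 - 1e-16)
  mu <- mean(x); v <- var(x)
  k <- max(mu * (1 - mu) / max(v, 1e-12) - 1, 0.1)
  par0 <- log(c(max(mu * k, 0.05), max((1 - mu) * k, 0.05)))
  nll <- function(lp) -sum(dbeta(x, exp(lp[1]), exp(lp[2]), log = TRUE))
  fit <- optim(par0, nll, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-10))
  exp(fit$par)
}

#' Permutation pass with beta-approximated gene-level p-values
#'
#' Per feature (or per group of features, e.g. the introns of one gene), the
#' phenotype's sample labels are permuted `n_perm` times; the per-permutation
#' best nominal p-value is recorded; a beta distribution is fitted to the
#' permuted minima by maximum likelihood; the effective gene-level p-value is
#' `BetaCDF(observed best p; alpha, beta)`. The empirical permutation p-value
#' is reported alongside for auditing. In grouped mode the minimum is taken
#' over member features inside each permutation, giving a gene-level null over
#' correlated introns.
#'
#' @inheritParams nominal_pass
#' @param n_perm Number of permutations (default 1000; < 100 warns, < 10
#'   errors).
#' @param seed Permutation seed.
#' @param grouping Optional named character vector mapping `feature_id` to a
#'   group id (e.g. intron to gene).
#' @return Tibble with one row per feature/group: best nominal p, best
#'   variant, beta shape parameters, effective and empirical p, `n_perm`,
#'   `n_variants`.
#' @export
permutation_pass <- function(genotypes, fm, window = 1e6, n_perm = 1000,
                             seed = 1, grouping = NULL, maf_min = 0.01) {
  if (n_perm < 10) abort("n_perm < 10 is not interpretable")
  if (n_perm < 100) warn("n_perm < 100 gives unstable beta fits")
  stopifnot(identical(genotypes$samples, fm$samples))
  n <- length(fm$samples)
  dos <- impute_dosage(genotypes$dosage)
  maf <- variant_frequencies(genotypes)$maf
  gsd <- apply(dos, 1, sd)

  feat_group <- if (is.null(grouping)) {
    setNames(fm$features$feature_id, fm$features$feature_id)
  } else {
    grouping[fm$features$feature_id]
  }
  groups <- unique(feat_group)
  set.seed(seed)
  perms <- replicate(n_perm, sample.int(n))

  res <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    members <- which(feat_group == groups[gi])
    best_obs <- 1; best_var <- NA_character_
    perm_best <- rep(1, n_perm)
    n_var <- 0L
    for (i in members) {
      idx <- cis_variants(genotypes, fm$features$anchor[i], fm$features$chrom[i],
                          window, maf, maf_min)
      idx <- idx[gsd[idx] > 0]
      if (!length(idx)) next
      n_var <- max(n_var, length(idx))
      g <- t(scale(t(dos[idx, , drop = FALSE])))
      y <- as.vector(scale(fm$values[i, ]))
      r_obs <- as.vector(g %*% y) / (n - 1)
      p_obs <- p_from_r(r_obs, n)
      if (min(p_obs) < best_obs) {
        best_obs <- min(p_obs)
        best_var <- genotypes$variants$id[idx][which.min(p_obs)]
      }
      yperm <- matrix(y[perms], nrow = n)
      rp <- crossprod(yperm, t(g)) / (n - 1)
      pmin_i <- p_from_r(apply(abs(rp), 1, max), n)
      perm_best <- pmin(perm_best, pmin_i)
    }
    if (is.na(best_var)) next
    shape <- fit_beta_ml(perm_best)
    res[[gi]] <- tibble::tibble(
      feature_id = groups[gi], best_p = best_obs, best_variant = best_var,
      beta_shape1 = shape[1], beta_shape2 = shape[2],
      p_effective = pmax(pbeta(best_obs, shape[1], shape[2]), 1e-300),
      p_empirical = (1 + sum(perm_best <= best_obs)) / (n_perm + 1),
      n_perm = n_perm, n_variants = n_var)
  }
  dplyr::bind_rows(res)
}

#' Call significant features at a cohort FDR
#'
#' Benjamini-Hochberg q-values on the beta-approximated effective p-values;
#' a feature is an eGene/sGene when `q <= fdr`. The per-feature nominal
#' threshold is `BetaQuantile(p_t; alpha, beta)` where `p_t` is the effective
#' p-value at the q = fdr boundary, interpolated between the last significant
#' and first non-significant feature. When a nominal association table is
#' supplied, all pairs below their feature's threshold are returned.
#'
#' @param perm_results Output of [permutation_pass()].
#' @param fdr FDR level (default 0.05).
#' @param nominal Optional output of [nominal_pass()] to extract significant
#'   feature-variant pairs.
#' @return A `significance_call` object with `$features` (q-values, flags,
#'   per-feature nominal thresholds) and `$pairs`.
#' @export
call_significant <- function(perm_results, fdr = 0.05, nominal = NULL) {
  if (is.null(perm_results) || nrow(perm_results) == 0) {
    abort("empty permutation results")
  }
  q <- p.adjust(perm_results$p_effective, method = "BH")
  sig <- q <= fdr
  p_sorted <- sort(perm_results$p_effective)
  if (any(sig)) {
    p_hi <- max(perm_results$p_effective[sig])
    p_lo_candidates <- p_sorted[p_sorted > p_hi]
    p_t <- if (length(p_lo_candidates)) (p_hi + min(p_lo_candidates)) / 2 else p_hi
  } else {
    p_t <- NA_real_
  }
  features <- perm_results |>
    dplyr::mutate(
      q_value = q, significant = sig,
      nominal_threshold = if (is.na(p_t)) NA_real_ else
        qbeta(p_t, .data$beta_shape1, .data$beta_shape2)) |>
    dplyr::select("feature_id", "best_p", "best_variant", "p_effective",
                  "p_empirical", "q_value", "significant", "nominal_threshold")
  pairs <- NULL
  if (!is.null(nominal) && any(sig)) {
    thr <- setNames(features$nominal_threshold, features$feature_id)
    keep_f <- features$feature_id[features$significant]
    pairs <- nominal |>
      dplyr::filter(.data$feature_id %in% keep_f,
                    .data$p <= thr[.data$feature_id]) |>
      dplyr::arrange(.data$feature_id, .data$p)
  }
  structure(list(features = features, pairs = pairs, fdr = fdr,
                 p_threshold = p_t, n_significant = sum(sig)),
            class = "significance_call")
}

#' @export
print.significance_call <- function(x, ...) {
  cat(sprintf("<significance_call> %d/%d features significant at FDR %.2f\n",
              x$n_significant, nrow(x$features), x$fdr))
  invisible(x)
}
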