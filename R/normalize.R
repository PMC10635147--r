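#' Filter lowly-quantified features
#'
#' Keeps features whose value is at least `min_value` in at least
#' `min_fraction` of samples. For excision-ratio matrices additionally drops
#' zero-variance introns and clusters reduced below two introns.
#'
#' @param fm A [feature_matrix()] on the raw scale.
#' @param min_value,min_fraction Expression thresholds (defaults 1 and 0.2).
#' @return The filtered [feature_matrix()]; counts of removed features are
#'   reported with a message.
#' @export
filter_features <- function(fm, min_value = 1, min_fraction = 0.2) {
  frac <- rowMeans(fm$values >= min_value)
  keep <- frac >= min_fraction
  if (fm$kind == "excision-ratio") {
    keep <- keep & apply(fm$values, 1, stats::var) > 0
    cl <- fm$features$cluster_id
    tab <- table(cl[keep])
    keep <- keep & cl %in% names(tab)[tab >= 2]
  }
  if (!any(keep)) abort("all features removed by filtering")
  inform(sprintf(
    "filter_features: kept %d/%d features (min_value=%g, min_fraction=%g)",
    sum(keep), length(keep), min_value, min_fraction))
  feature_matrix(fm$features[keep, , drop = FALSE],
                 fm$values[keep, , drop = FALSE], fm$samples, kind = fm$kind)
}

#' Rank-based inverse normal transform
#'
#' Per feature, values are replaced by `qnorm((rank - 0.5) / n)` with average
#' ranks for ties, giving bounded standard-normal quantiles with mean ~0.
#'
#' @param fm A [feature_matrix()].
#' @return A [feature_matrix()] of kind `"normalized"`.
#' @export
inverse_normal_transform <- function(fm) {
  n <- ncol(fm$values)
  const <- apply(fm$values, 1, function(x) diff(range(x)) == 0)
  if (any(const)) {
    abort(paste("constant feature(s) cannot be transformed:",
                toString(head(fm$features$feature_id[const], 5))))
  }
  out <- t(apply(fm$values, 1, function(x) qnorm((rank(x, ties.method = "average") - 0.5) / n)))
  feature_matrix(fm$features, out, fm$samples, kind = "normalized")
}

#' Greedy LD pruning of variants
#' @noRd
ld_prune <- function(dosage, r2_max = 0.2, window = 50) {
  m <- nrow(dosage)
  keep <- logical(m)
  sds <- apply(dosage, 1, sd)
  last_kept <- integer(0)
  for (i in seq_len(m)) {
    if (sds[i] == 0) next
    recent <- last_kept[last_kept > i - window]
    ok <- TRUE
    if (length(recent)) {
      r <- suppressWarnings(cor(dosage[i, ], t(dosage[recent, , drop = FALSE])))
      ok <- all(r^2 < r2_max, na.rm = TRUE)
    }
    if (ok) {
      keep[i] <- TRUE
      last_kept <- c(last_kept, i)
    }
  }
  keep
}

#' Build the covariate matrix for association testing
#'
#' Genotype principal components are computed from LD-pruned standardised
#' dosages, phenotype PCs from the (transformed) feature matrix; batch
#' indicators (reference level dropped) and a sex indicator are appended.
#' Collinear columns are dropped with a warning.
#'
#' @param genotypes A [genotype_matrix()].
#' @param fm The transformed [feature_matrix()].
#' @param samples Sample tibble (aligned).
#' @param n_geno_pcs,n_pheno_pcs Numbers of PCs (defaults 5 and 15).
#' @return Numeric matrix, samples in rows (rownames = sample ids), full
#'   column rank.
#' @export
compute_covariates <- function(genotypes, fm, samples,
                               n_geno_pcs = 5, n_pheno_pcs = 15) {
  n <- length(genotypes$samples)
  if (n_geno_pcs >= n || n_pheno_pcs >= n) abort("more PCs requested than samples")
  gpc <- NULL
  if (n_geno_pcs > 0) {
    dos <- impute_dosage(genotypes$dosage)
    dos <- dos[ld_prune(dos), , drop = FALSE]
    gx <- t(scale(t(dos)))
    gx <- gx[stats::complete.cases(gx), , drop = FALSE]
    gpc <- svd(t(gx), nu = n_geno_pcs, nv = 0)$u[, seq_len(n_geno_pcs), drop = FALSE]
    colnames(gpc) <- paste0("geno_PC", seq_len(n_geno_pcs))
  }

  ppc <- NULL
  n_pheno_pcs <- min(n_pheno_pcs, nrow(fm$values) - 1)
  if (n_pheno_pcs > 0) {
    px <- t(scale(t(fm$values)))
    px <- px[stats::complete.cases(px), , drop = FALSE]
    ppc <- svd(t(px), nu = n_pheno_pcs, nv = 0)$u[, seq_len(n_pheno_pcs), drop = FALSE]
    colnames(ppc) <- paste0("pheno_PC", seq_len(n_pheno_pcs))
  }

  batch <- factor(samples$batch)
  bmat <- if (nlevels(batch) > 1) {
    mm <- model.matrix(~batch)[, -1, drop = FALSE]
    colnames(mm) <- sub("^batch", "batch_", colnames(mm))
    mm
  } else NULL
  sex <- if (length(unique(samples$sex)) > 1) {
    cbind(sex = as.numeric(samples$sex == samples$sex[1]))
  } else NULL

  cov <- do.call(cbind, Filter(Negate(is.null), list(gpc, ppc, bmat, sex)))
  rownames(cov) <- samples$sample_id
  q <- qr(cbind(1, cov))
  if (q$rank < ncol(cov) + 1) {
    drop_idx <- q$pivot[-seq_len(q$rank)] - 1L
    warn(paste("dropping collinear covariate(s):",
               toString(colnames(cov)[drop_idx])))
    cov <- cov[, -drop_idx, drop = FALSE]
  }
  cov
}

#' Residualize a feature matrix against covariates
#'
#' Per feature, ordinary-least-squares residuals against the covariates plus
#' an intercept; residuals are orthogonal to every covariate column.
#' Residualizing twice equals residualizing once.
#'
#' @param fm A [feature_matrix()].
#' @param covariates Numeric matrix, samples in rows, matching `fm` sample
#'   order, or `NULL` for intercept-only (mean centring).
#' @return A [feature_matrix()] of kind `"normalized"` holding residuals.
#' @export
residualize <- function(fm, covariates = NULL) {
  x <- cbind(intercept = rep(1, ncol(fm$values)), covariates)
  q <- qr(x)
  if (q$rank < ncol(x)) abort("covariate matrix is rank-deficient")
  res <- t(qr.resid(q, t(fm$values)))
  feature_matrix(fm$features, res, fm$samples, kind = "normalized")
}
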