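#' One-way ANOVA R-squared per feature, vectorised
#' @noRd
anova_r2 <- function(values, labels) {
  f <- factor(labels)
  ind <- model.matrix(~ f - 1)
  ns <- colSums(ind)
  gm <- sweep(values %*% ind, 2, ns, "/")
  mu <- rowMeans(values)
  ssb <- as.vector(gm^2 %*% ns) - sum(ns) * mu^2
  sst <- rowSums(values^2) - sum(ns) * mu^2
  r2 <- ifelse(sst > 0, ssb / sst, NA_real_)
  unname(pmin(pmax(r2, 0), 1))
}

#' Partition phenotype variance across population labels
#'
#' Per feature, the proportion of variance in the residualized phenotype
#' explained by the label factor (one-way ANOVA R-squared), at the
#' continental-group or population level. The cohort mean proportion is
#' tested against a permutation null in which labels are permuted jointly
#' across samples (one shared permutation per replicate for all features,
#' preserving inter-feature correlation);
#' `p = (1 + #[perm mean >= observed mean]) / (n_perm + 1)`.
#'
#' @param fm Residualized [feature_matrix()].
#' @param samples Sample tibble (aligned).
#' @param level `"group"` or `"population"`.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Seed for the permutations.
#' @param collapse If `"cluster"`, per-intron proportions are averaged within
#'   splicing cluster for the per-feature report.
#' @return A `variance_partition` object: `tidy()` gives per-feature
#'   proportions, `glance()` the cohort summary.
#' @export
partition_variance <- function(fm, samples, level = c("group", "population"),
                               n_perm = 999, seed = 1,
                               collapse = c("none", "cluster")) {
  level <- match.arg(level)
  collapse <- match.arg(collapse)
  if (n_perm < 1) abort("n_perm must be >= 1")
  labels <- if (level == "group") samples$group else samples$population
  tab <- table(labels)
  if (length(tab) < 2) abort("need at least 2 labels")
  if (any(tab < 2)) abort("every label needs at least 2 samples")

  r2 <- anova_r2(fm$values, labels)
  obs_mean <- mean(r2, na.rm = TRUE)
  set.seed(seed)
  perm_means <- vapply(seq_len(n_perm), function(b) {
    mean(anova_r2(fm$values, sample(labels)), na.rm = TRUE)
  }, numeric(1))
  p <- (1 + sum(perm_means >= obs_mean)) / (n_perm + 1)

  per_feature <- tibble::tibble(
    feature_id = fm$features$feature_id,
    cluster_id = fm$features$cluster_id,
    proportion = r2, level = level)
  if (collapse == "cluster") {
    per_feature <- per_feature |>
      dplyr::group_by(.data$cluster_id) |>
      dplyr::summarise(proportion = mean(.data$proportion, na.rm = TRUE),
                       .groups = "drop") |>
      dplyr::mutate(feature_id = .data$cluster_id, level = .env$level) |>
      dplyr::select("feature_id", "cluster_id", "proportion", "level")
  }
  structure(list(per_feature = per_feature, level = level,
                 mean_proportion = obs_mean, p_perm = p, n_perm = n_perm,
                 perm_means = perm_means),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat(sprintf(
    "<variance_partition> level=%s: mean proportion %.4f (permutation p %s, %d perms)\n",
    x$level, x$mean_proportion,
    format.pval(x$p_perm, digits = 3), x$n_perm))
  invisible(x)
}

#' Test whether within-group phenotype variance differs among groups
#'
#' Computes the per-feature, per-group sample variance of the residualized
#' phenotype and fits a gamma GLM with log link of variance on group factor
#' (observations are feature-by-group pairs, pooled over features). Reports
#' the analysis-of-deviance chi-square with `df = n_groups - 1` and the
#' per-group mean variances.
#'
#' @inheritParams partition_variance
#' @return A `group_variance_test` object (`tidy()`: per-group means;
#'   `glance()`: statistic, df, p).
#' @export
within_group_variance_test <- function(fm, samples) {
  groups <- factor(samples$group)
  tab <- table(groups)
  if (any(tab < 3)) abort("every group needs at least 3 samples")
  vmat <- vapply(levels(groups), function(g)
    apply(fm$values[, groups == g, drop = FALSE], 1, stats::var),
    numeric(nrow(fm$values)))
  dat <- tibble::tibble(
    variance = as.vector(vmat),
    group = factor(rep(levels(groups), each = nrow(fm$values)), levels(groups)))
  pos <- dat$variance > 0
  n_dropped <- sum(!pos)
  if (n_dropped > 0) {
    inform(sprintf("within_group_variance_test: dropped %d zero-variance cell(s)",
                   n_dropped))
  }
  dat <- dat[pos, ]
  fit <- glm(variance ~ group, data = dat, family = Gamma(link = "log"))
  av <- anova(fit, test = "Chisq")
  stat <- av$Deviance[2] / summary(fit)$dispersion
  df <- av$Df[2]
  p <- pchisq(stat, df, lower.tail = FALSE)
  structure(list(
    per_group = tibble::tibble(
      group = levels(groups),
      mean_variance = unname(colMeans(vmat)),
      n_features = unname(colSums(vmat > 0))),
    statistic = stat, df = df, p_value = p, n_obs = nrow(dat),
    family = "Gamma(log)"), class = "group_variance_test")
}

#' @export
print.group_variance_test <- function(x, ...) {
  cat(sprintf(
    "<group_variance_test> analysis of deviance: chi2[%d, N = %d] = %.1f, p = %s\n",
    x$df, x$n_obs, x$statistic, format.pval(x$p_value, digits = 3)))
  invisible(x)
}
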