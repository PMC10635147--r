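#' In-memory cohort containers
#'
#' `genotype_matrix()` and `feature_matrix()` are the two matrix-backed
#' containers the pipeline passes between stages. Variant / feature metadata
#' live in tibbles; the numeric payload is a base matrix so linear algebra
#' stays fast. All user-facing analysis functions return plain tibbles.
#'
#' @param variants Tibble with columns `chrom`, `pos` (1-based), `id`,
#'   `ref`, `alt`; one row per biallelic variant.
#' @param samples Character vector of unique sample ids.
#' @param dosage Numeric matrix of alternate-allele counts, variants in rows,
#'   samples in columns. Entries must be 0, 1, 2 or `NA` (missing).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(variants, samples, dosage) {
  variants <- tibble::as_tibble(variants)
  stopifnot(all(c("chrom", "pos", "id", "ref", "alt") %in% names(variants)))
  if (any(variants$pos < 1)) abort("variant positions must be >= 1")
  if (any(variants$ref == variants$alt)) abort("ref and alt alleles must differ")
  if (anyDuplicated(samples)) abort("sample ids must be unique")
  dosage <- as.matrix(dosage)
  if (!all(dim(dosage) == c(nrow(variants), length(samples)))) {
    abort("dosage dimensions must be (n_variants, n_samples)")
  }
  ok <- dosage %in% c(0, 1, 2) | is.na(dosage)
  if (!all(ok)) abort("dosages must be 0, 1, 2 or NA")
  dimnames(dosage) <- list(variants$id, samples)
  structure(
    list(variants = variants, samples = as.character(samples), dosage = dosage),
    class = "genotype_matrix"
  )
}

#' @param features Tibble with columns `feature_id`, `chrom`, `anchor`
#'   (1-based anchor position: TSS or intron start), and optionally `strand`,
#'   `gene_id`, `cluster_id`.
#' @param values Numeric matrix, features in rows, samples in columns.
#' @param kind One of `"raw-count"`, `"normalized"`, `"excision-ratio"`.
#' @rdname genotype_matrix
#' @export
feature_matrix <- function(features, values, samples,
                           kind = c("raw-count", "normalized", "excision-ratio")) {
  kind <- match.arg(kind)
  features <- tibble::as_tibble(features)
  stopifnot(all(c("feature_id", "chrom", "anchor") %in% names(features)))
  if (anyDuplicated(features$feature_id)) abort("duplicate feature ids")
  if (!"strand" %in% names(features)) features$strand <- "+"
  if (!"gene_id" %in% names(features)) features$gene_id <- features$feature_id
  if (!"cluster_id" %in% names(features)) features$cluster_id <- NA_character_
  values <- as.matrix(values)
  if (!all(dim(values) == c(nrow(features), length(samples)))) {
    abort("values dimensions must be (n_features, n_samples)")
  }
  if (kind == "excision-ratio" &&
      any(values < -1e-9 | values > 1 + 1e-9, na.rm = TRUE)) {
    abort("excision ratios must lie in [0, 1]")
  }
  dimnames(values) <- list(features$feature_id, samples)
  structure(
    list(features = features, values = values, samples = as.character(samples),
         kind = kind),
    class = "feature_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d variants x %d samples (%d missing calls)\n",
              nrow(x$dosage), ncol(x$dosage), sum(is.na(x$dosage))))
  invisible(x)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d features x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$kind))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Validate a sample metadata table
#'
#' Checks the invariants the pipeline relies on: unique sample ids and a
#' population label that maps to exactly one continental group.
#'
#' @param samples Tibble with columns `sample_id`, `population`, `group`,
#'   `sex`, `batch`.
#' @return The table, invisibly standardised (character columns).
#' @export
validate_sample_table <- function(samples) {
  samples <- tibble::as_tibble(samples)
  need <- c("sample_id", "population", "group", "sex", "batch")
  miss <- setdiff(need, names(samples))
  if (length(miss)) abort(paste("sample table missing columns:", toString(miss)))
  if (anyDuplicated(samples$sample_id)) abort("duplicate sample ids")
  map <- unique(samples[, c("population", "group")])
  if (anyDuplicated(map$population)) {
    abort("a population maps to more than one continental group")
  }
  dplyr::mutate(samples, dplyr::across(dplyr::all_of(need), as.character))
}

#' Subset helpers used by the cis stages
#' @noRd
subset_geno_samples <- function(geno, ids) {
  idx <- match(ids, geno$samples)
  if (anyNA(idx)) abort("requested samples absent from genotypes")
  genotype_matrix(geno$variants, geno$samples[idx], geno$dosage[, idx, drop = FALSE])
}

#' @noRd
subset_feat_samples <- function(fm, ids) {
  idx <- match(ids, fm$samples)
  if (anyNA(idx)) abort("requested samples absent from phenotype matrix")
  feature_matrix(fm$features, fm$values[, idx, drop = FALSE], fm$samples[idx],
                 kind = fm$kind)
}

#' Allele frequency and MAF per variant
#'
#' Frequencies are computed from non-missing dosages; `maf` folds the
#' alternate-allele frequency at 0.5.
#'
#' @param geno A [genotype_matrix()].
#' @return Tibble with `id`, `af`, `maf`, `n_called`.
#' @export
variant_frequencies <- function(geno) {
  n_called <- rowSums(!is.na(geno$dosage))
  af <- rowMeans(geno$dosage, na.rm = TRUE) / 2
  tibble::tibble(id = geno$variants$id, af = af, maf = pmin(af, 1 - af),
                 n_called = n_called)
}

#' Sample from a vector without the length-1 integer surprise
#' @noRd
sample_safe <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

#' Mean-impute missing dosages (per variant)
#' @noRd
impute_dosage <- function(dos) {
  miss <- is.na(dos)
  if (!any(miss)) return(dos)
  mu <- rowMeans(dos, na.rm = TRUE)
  dos[miss] <- mu[row(dos)[miss]]
  dos
}
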