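#' Read genotypes from a VCF file
#'
#' Parses GT fields into alternate-allele dosages (0/1/2, `NA` for missing).
#' Multi-allelic records are rejected with a warning count by default, or
#' split into one biallelic record per alternate allele.
#'
#' Internal coordinates are 1-based throughout the package; VCF positions are
#' used as-is.
#'
#' @param vcf_path Path to a VCF (optionally gzipped) with GT fields.
#' @param region Optional `list(chrom =, start =, end =)` restricting variants
#'   (1-based, inclusive).
#' @param sample_subset Optional character vector of sample ids to keep; an
#'   absent id is an error listing the missing ids.
#' @param multiallelic `"reject"` (default) or `"split"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(vcf_path, region = NULL, sample_subset = NULL,
                           multiallelic = c("reject", "split")) {
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(vcf_path)) abort(paste("no such VCF:", vcf_path))
  v <- tryCatch(vcfR::read.vcfR(vcf_path, verbose = FALSE),
                error = function(e) abort(paste0("malformed VCF '", vcf_path,
                                                 "': ", conditionMessage(e))))
  fix_raw <- vcfR::getFIX(v)
  if (is.null(dim(fix_raw))) fix_raw <- t(fix_raw)   # single-record VCF
  fix <- tibble::as_tibble(as.data.frame(fix_raw, stringsAsFactors = FALSE))
  if (nrow(fix) == 0) abort("VCF contains no variant records")
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt_raw)) abort("VCF has no GT field")
  if (is.null(dim(gt_raw))) gt_raw <- t(gt_raw)
  gt_raw <- matrix(as.character(gt_raw), nrow = nrow(fix),
                   dimnames = list(NULL, colnames(gt_raw)))
  samples <- colnames(gt_raw)

  chrom <- fix$CHROM
  pos <- as.integer(fix$POS)
  id <- fix$ID
  id[is.na(id) | id == "."] <- paste0(chrom, ":", pos)[is.na(id) | id == "."]
  ref <- fix$REF
  alt <- fix$ALT

  multi <- grepl(",", alt, fixed = TRUE)
  alt_list <- strsplit(alt, ",", fixed = TRUE)
  keep <- !multi
  if (any(multi) && multiallelic == "reject") {
    warn(sprintf("rejected %d multi-allelic record(s)", sum(multi)))
  }

  # fast path: biallelic GT alleles are single characters (0, 1 or .)
  a1 <- substr(gt_raw, 1, 1)
  a2 <- substr(gt_raw, 3, 3)
  diploid <- nchar(gt_raw) >= 3 & !is.na(gt_raw)
  count_allele <- function(k) {
    d <- (a1 == k) + ifelse(diploid, a2 == k, 0)
    d[is.na(gt_raw) | a1 == "." | (diploid & a2 == ".")] <- NA_real_
    matrix(as.numeric(d), nrow = nrow(gt_raw))
  }
  dos1 <- count_allele("1")

  rows <- list(); dmat <- list()
  for (i in seq_len(nrow(fix))) {
    alts_i <- alt_list[[i]]
    if (!multi[i]) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        chrom = chrom[i], pos = pos[i], id = id[i], ref = ref[i], alt = alts_i[1])
      dmat[[length(dmat) + 1L]] <- dos1[i, ]
    } else if (multiallelic == "split") {
      parts <- strsplit(gt_raw[i, ], "[/|]")
      for (k in seq_along(alts_i)) {
        dos <- vapply(parts, function(p) {
          if (length(p) == 0 || anyNA(p) || any(p == ".")) return(NA_real_)
          sum(p == as.character(k))
        }, numeric(1))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          chrom = chrom[i], pos = pos[i], id = paste0(id[i], "_", alts_i[k]),
          ref = ref[i], alt = alts_i[k])
        dmat[[length(dmat) + 1L]] <- dos
      }
    }
  }
  if (!length(rows)) abort("no biallelic records retained from VCF")
  variants <- dplyr::bind_rows(rows)
  dosage <- do.call(rbind, dmat)
  colnames(dosage) <- samples

  if (!is.null(region)) {
    keep_r <- variants$chrom == region$chrom &
      variants$pos >= region$start & variants$pos <= region$end
    variants <- variants[keep_r, , drop = FALSE]
    dosage <- dosage[keep_r, , drop = FALSE]
  }
  if (!is.null(sample_subset)) {
    missing_ids <- setdiff(sample_subset, samples)
    if (length(missing_ids)) {
      abort(paste("samples absent from VCF:", toString(missing_ids)))
    }
    dosage <- dosage[, sample_subset, drop = FALSE]
    samples <- sample_subset
  }
  genotype_matrix(variants, samples, dosage)
}

#' Write genotypes as a plain-text VCF
#'
#' Dosages are emitted as unphased GT calls (0/0, 0/1, 1/1, ./.); the package
#' stores dosage-level information only, so phase is not preserved.
#'
#' @param geno A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", geno$samples), collapse = "\t"))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow = nrow(geno$dosage), ncol = ncol(geno$dosage))
  ok <- !is.na(geno$dosage)
  gt[ok] <- gt_code[as.character(geno$dosage[ok])]
  body <- paste(geno$variants$chrom, geno$variants$pos, geno$variants$id,
                geno$variants$ref, geno$variants$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a phenotype BED file
#'
#' tensorQTL-style layout: four anchor columns (`chrom`, `start`, `end`,
#' `feature id`) then one column per sample; the header row carries the sample
#' ids. BED starts are 0-based and converted to the package's 1-based internal
#' anchor (`anchor = start + 1`).
#'
#' Feature ids of the form `gene:cluster:intron` (the splicing writer's
#' convention) are split into `gene_id` and `cluster_id`.
#'
#' @param path Path to the tab-separated file.
#' @param kind Value kind of the matrix (see [feature_matrix()]).
#' @return A [feature_matrix()].
#' @export
read_phenotype_bed <- function(path, kind = "normalized") {
  if (!file.exists(path)) abort(paste("no such file:", path))
  nf <- utils::count.fields(path, sep = "\t", comment.char = "")
  if (length(unique(nf)) != 1) {
    bad <- which(nf != nf[1])[1]
    abort(sprintf("ragged phenotype BED: row %d has %d fields, expected %d",
                  bad, nf[bad], nf[1]))
  }
  hdr <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  hdr[1] <- sub("^#", "", hdr[1])
  dat <- readr::read_tsv(path, skip = 1, col_names = hdr,
                         col_types = readr::cols(.default = readr::col_guess()),
                         progress = FALSE, show_col_types = FALSE)
  if (ncol(dat) < 5) abort("phenotype BED needs 4 anchor columns plus samples")
  samples <- hdr[-(1:4)]
  ids <- as.character(dat[[4]])
  if (anyDuplicated(ids)) {
    abort(paste("duplicate feature ids:", toString(unique(ids[duplicated(ids)]))))
  }
  vals <- as.matrix(dat[, -(1:4), drop = FALSE])
  if (anyNA(vals) || !is.numeric(vals)) {
    w <- which(is.na(vals) | !is.finite(vals), arr.ind = TRUE)[1, ]
    abort(sprintf("empty or non-numeric value for feature '%s', sample '%s'",
                  ids[w[1]], samples[w[2]]))
  }
  parts <- strsplit(ids, ":", fixed = TRUE)
  three <- lengths(parts) == 3
  features <- tibble::tibble(
    feature_id = ids,
    chrom = as.character(dat[[1]]),
    anchor = as.integer(dat[[2]]) + 1L,
    strand = "+",
    gene_id = ifelse(three, vapply(parts, `[`, "", 1), ids),
    cluster_id = ifelse(three,
                        vapply(parts, function(p) paste(p[1:2], collapse = ":"), ""),
                        NA_character_)
  )
  feature_matrix(features, vals, samples, kind = kind)
}

#' Write a feature matrix as a phenotype BED
#'
#' Inverse of [read_phenotype_bed()]: internal 1-based anchors are written as
#' 0-based BED starts.
#'
#' @inheritParams write_genotypes
#' @param fm A [feature_matrix()].
#' @export
write_phenotype_bed <- function(fm, path) {
  hdr <- paste(c("#chr", "start", "end", "feature_id", fm$samples), collapse = "\t")
  body <- paste(fm$features$chrom, fm$features$anchor - 1L, fm$features$anchor,
                fm$features$feature_id,
                apply(fm$values, 1, function(r)
                  paste(formatC(r, format = "g", digits = 15), collapse = "\t")),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write sample metadata TSV
#'
#' Columns: `sample_id`, `population`, `group`, `sex`, `batch`.
#' @param path Path to the TSV.
#' @return A validated sample tibble.
#' @export
read_sample_table <- function(path) {
  validate_sample_table(readr::read_tsv(path, show_col_types = FALSE,
                                        progress = FALSE))
}

#' @rdname read_sample_table
#' @param samples Sample tibble.
#' @export
write_sample_table <- function(samples, path) {
  readr::write_tsv(validate_sample_table(samples), path)
  invisible(path)
}

#' Align genotypes, phenotypes and metadata on shared samples
#'
#' Restricts all three objects to the intersection of sample ids and imposes a
#' single sample order (that of the genotype object). The number of dropped
#' samples is reported with a message.
#'
#' @param genotypes A [genotype_matrix()].
#' @param phenotypes A [feature_matrix()].
#' @param samples A sample tibble.
#' @return `list(genotypes =, phenotypes =, samples =)`, sample-aligned.
#' @export
align_cohort <- function(genotypes, phenotypes, samples) {
  samples <- validate_sample_table(samples)
  shared <- intersect(intersect(genotypes$samples, phenotypes$samples),
                      samples$sample_id)
  if (!length(shared)) abort("no shared samples across genotypes, phenotypes and metadata")
  ord <- genotypes$samples[genotypes$samples %in% shared]
  dropped <- length(unique(c(genotypes$samples, phenotypes$samples,
                             samples$sample_id))) - length(ord)
  if (dropped > 0) inform(sprintf("align_cohort: dropped %d unshared sample(s)", dropped))
  list(
    genotypes = subset_geno_samples(genotypes, ord),
    phenotypes = subset_feat_samples(phenotypes, ord),
    samples = samples[match(ord, samples$sample_id), , drop = FALSE]
  )
}

#' Read annotation intervals from a BED file
#'
#' BED intervals are 0-based half-open; they are converted to internal 1-based
#' closed intervals (`start + 1 .. end`). The 4th column names the annotation.
#'
#' @param path Path to the BED file.
#' @return Tibble with `name`, `chrom`, `start`, `end` (1-based closed),
#'   sorted within annotation.
#' @export
read_annotation_bed <- function(path) {
  dat <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE, comment = "#")
  if (ncol(dat) < 4) abort("annotation BED needs 4 columns (chrom,start,end,name)")
  ann <- tibble::tibble(name = as.character(dat[[4]]),
                        chrom = as.character(dat[[1]]),
                        start = as.integer(dat[[2]]) + 1L,
                        end = as.integer(dat[[3]]))
  if (any(ann$end < ann$start)) abort("annotation interval with negative length")
  dplyr::arrange(ann, .data$name, .data$chrom, .data$start)
}

#' Read a two-column gene constraint score TSV (e.g. pLI)
#' @param path Path to a TSV with columns gene id and score.
#' @return Tibble with `gene_id`, `score`.
#' @export
read_constraint_scores <- function(path) {
  dat <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  tibble::tibble(gene_id = as.character(dat[[1]]), score = as.numeric(dat[[2]]))
}

#' Read / write a covariate matrix TSV (covariates x samples, tensorQTL dialect)
#' @param path Path to the TSV.
#' @return Numeric matrix, samples in rows, covariates in columns.
#' @export
read_covariates_tsv <- function(path) {
  dat <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- t(as.matrix(dat[, -1, drop = FALSE]))
  colnames(m) <- dat[[1]]
  m
}

#' @rdname read_covariates_tsv
#' @param covariates Matrix, samples in rows (rownames = sample ids).
#' @export
write_covariates_tsv <- function(covariates, path) {
  dat <- tibble::as_tibble(t(covariates), rownames = "covariate")
  readr::write_tsv(dat, path)
  invisible(path)
}
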