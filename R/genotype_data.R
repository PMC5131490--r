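# Core containers shared by every pipeline stage. All user-facing
# coordinates are 1-based inclusive (PED/MAP and VCF convention).
#
# Dosage coding: 0 = homozygous reference, 1 = heterozygous,
# 2 = homozygous alternate, NA = missing. Haplotype allele coding:
# 0 = reference allele, 1 = alternate allele (never missing).

#' Construct an ordered marker map
#'
#' Holds the ordered SNP loci (chromosome, base-pair position, id and the
#' two allele codes) that define all window and segment coordinates in the
#' pipeline. Loci must be grouped by chromosome with strictly increasing
#' positions within each chromosome, ids must be unique, and every locus is
#' biallelic with single-character allele codes.
#'
#' @param chrom chromosome label per locus.
#' @param pos_bp 1-based base-pair position per locus.
#' @param snp_id unique SNP identifier per locus.
#' @param ref_allele,alt_allele single-character allele codes; the dosage of
#'   a genotype is the count of `alt_allele` copies.
#' @return a data frame of class `marker_map`.
#' @export
marker_map <- function(chrom, pos_bp, snp_id, ref_allele, alt_allele) {
  df <- data.frame(
    chrom = as.character(chrom),
    pos_bp = as.integer(pos_bp),
    snp_id = as.character(snp_id),
    ref_allele = as.character(ref_allele),
    alt_allele = as.character(alt_allele),
    stringsAsFactors = FALSE
  )
  validate_marker_map(df)
  class(df) <- c("marker_map", "data.frame")
  df
}

validate_marker_map <- function(df) {
  n <- nrow(df)
  if (n == 0L) return(invisible(df))
  if (anyNA(df$pos_bp) || any(df$pos_bp < 1L)) {
    stop("marker positions must be positive integers")
  }
  if (anyDuplicated(df$snp_id)) stop("snp ids must be unique")
  blocks <- rle(df$chrom)$values
  if (anyDuplicated(blocks)) {
    stop("loci of one chromosome must form a contiguous block")
  }
  ok <- tapply(df$pos_bp, factor(df$chrom, levels = blocks),
               function(p) all(diff(p) > 0))
  if (!all(ok)) {
    stop("positions must be strictly increasing within each chromosome")
  }
  if (any(nchar(df$ref_allele) != 1L) || any(nchar(df$alt_allele) != 1L)) {
    stop("allele codes must be single characters")
  }
  if (any(df$ref_allele == df$alt_allele)) {
    stop("every locus must have two distinct alleles")
  }
  invisible(df)
}

#' Construct a genotype matrix
#'
#' Samples-by-loci matrix of alternate-allele dosage (0, 1, 2 or `NA` for
#' missing), tied to the [marker_map()] that defines its columns.
#'
#' @param dosage integer matrix, samples in rows, loci in columns; values
#'   restricted to 0/1/2/`NA`.
#' @param map the [marker_map()] describing the columns.
#' @param sample_ids sample identifiers; defaults to `rownames(dosage)`.
#' @return an object of class `genotype_matrix` with elements `dosage`
#'   (dimnamed integer matrix) and `map`.
#' @export
genotype_matrix <- function(dosage, map, sample_ids = rownames(dosage)) {
  stopifnot(is.matrix(dosage), inherits(map, "marker_map"))
  if (ncol(dosage) != nrow(map)) {
    stop("genotype matrix has ", ncol(dosage), " columns but the map has ",
         nrow(map), " loci")
  }
  if (is.null(sample_ids)) {
    sample_ids <- if (nrow(dosage)) paste0("s", seq_len(nrow(dosage))) else character(0)
  }
  if (length(sample_ids) != nrow(dosage)) stop("one sample id per row required")
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  storage.mode(dosage) <- "integer"
  bad <- !is.na(dosage) & !(dosage %in% 0:2)
  if (any(bad)) stop("dosage values must be 0, 1, 2 or NA")
  dimnames(dosage) <- list(as.character(sample_ids), map$snp_id)
  structure(list(dosage = dosage, map = map), class = "genotype_matrix")
}

#' Construct a phased haplotype matrix
#'
#' Two haplotypes per sample over the loci of a [marker_map()]. Alleles are
#' coded 0 (reference) / 1 (alternate) with no missing entries; sample `i`
#' occupies rows `2i - 1` and `2i`. Row `2i - 1` is the paternally
#' transmitted haplotype for simulated pedigrees.
#'
#' @param alleles integer matrix of 0/1 allele codes, `2 * n_samples` rows.
#' @param sample_ids sample identifiers (length `nrow(alleles) / 2`).
#' @param map the [marker_map()] describing the columns.
#' @return an object of class `haplotype_matrix`.
#' @export
haplotype_matrix <- function(alleles, sample_ids, map) {
  stopifnot(is.matrix(alleles), inherits(map, "marker_map"))
  if (ncol(alleles) != nrow(map)) {
    stop("haplotype matrix has ", ncol(alleles), " columns but the map has ",
         nrow(map), " loci")
  }
  if (nrow(alleles) != 2L * length(sample_ids)) {
    stop("haplotype matrix must have exactly two rows per sample")
  }
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  storage.mode(alleles) <- "integer"
  if (anyNA(alleles) || !all(alleles %in% 0:1)) {
    stop("haplotype alleles must be 0 or 1 with no missing entries")
  }
  sample_ids <- as.character(sample_ids)
  rn <- if (length(sample_ids)) {
    paste0(rep(sample_ids, each = 2L), c(".1", ".2"))
  } else character(0)
  dimnames(alleles) <- list(rn, map$snp_id)
  structure(list(alleles = alleles, sample_ids = sample_ids, map = map),
            class = "haplotype_matrix")
}

#' Collapse phased haplotypes to dosages
#'
#' @param hap a [haplotype_matrix()].
#' @return a [genotype_matrix()] with no missing entries, where each dosage
#'   is the sum of the sample's two phased alleles.
#' @export
haplotypes_to_dosage <- function(hap) {
  stopifnot(inherits(hap, "haplotype_matrix"))
  n <- length(hap$sample_ids)
  a <- hap$alleles
  d <- a[seq(1L, by = 2L, length.out = n), , drop = FALSE] +
    a[seq(2L, by = 2L, length.out = n), , drop = FALSE]
  genotype_matrix(d, hap$map, hap$sample_ids)
}

#' Check dosage/haplotype consistency
#'
#' Verifies the core phasing invariant: wherever the genotype dosage is
#' non-missing it equals the sum of the sample's two phased alleles.
#'
#' @param hap a [haplotype_matrix()].
#' @param geno a [genotype_matrix()] over the same samples and loci.
#' @return `TRUE` invisibly; errors when the invariant is violated.
#' @export
check_hap_consistency <- function(hap, geno) {
  stopifnot(inherits(hap, "haplotype_matrix"), inherits(geno, "genotype_matrix"))
  if (!identical(hap$sample_ids, rownames(geno$dosage))) {
    stop("sample ids of haplotype and genotype matrices differ")
  }
  if (!identical(hap$map$snp_id, geno$map$snp_id)) {
    stop("marker maps of haplotype and genotype matrices differ")
  }
  d <- haplotypes_to_dosage(hap)$dosage
  obs <- !is.na(geno$dosage)
  if (!all(d[obs] == geno$dosage[obs])) {
    stop("phased alleles do not sum to the observed dosage at every call")
  }
  invisible(TRUE)
}

#' Valid sample statuses
#' @export
SAMPLE_STATUSES <- c("affected", "obligate_carrier", "control", "panel_healthy")

#' Construct a sample table
#'
#' The sample table is the single source of disease-status truth for the
#' pipeline: it drives the 2/1/0 response coding of the association scan and
#' the case/carrier/panel role assignment of the variant-filter cascade.
#'
#' @param sample_id unique sample identifiers.
#' @param status one of `"affected"`, `"obligate_carrier"`, `"control"`,
#'   `"panel_healthy"` per sample.
#' @param sire_id,dam_id optional parent identifiers (`NA` when unknown).
#' @return a data frame of class `sample_table`.
#' @export
sample_table <- function(sample_id, status, sire_id = NA_character_,
                         dam_id = NA_character_) {
  df <- data.frame(
    sample_id = as.character(sample_id),
    status = as.character(status),
    sire_id = as.character(sire_id),
    dam_id = as.character(dam_id),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$sample_id)) stop("sample ids must be unique")
  bad <- !df$status %in% SAMPLE_STATUSES
  if (any(bad)) {
    stop("unknown status: ", paste(unique(df$status[bad]), collapse = ", "),
         " (allowed: ", paste(SAMPLE_STATUSES, collapse = ", "), ")")
  }
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Genotype state codes for sequence-level variants
#'
#' Variant genotype states are stored as integers: 0 = `hom_ref`,
#' 1 = `het`, 2 = `hom_alt`, `NA` = missing.
#' @export
GENOTYPE_STATES <- c(hom_ref = 0L, het = 1L, hom_alt = 2L)

#' Construct a table of sequence-level variant records
#'
#' @param info data frame with one row per variant and columns `variant_id`,
#'   `chrom`, `pos_bp`, `ref`, `alt`, `csq_class` (consequence-class label,
#'   `NA` allowed until a class filter is applied).
#' @param geno integer matrix of genotype states (see [GENOTYPE_STATES]),
#'   samples in rows, variants in columns.
#' @return an object of class `variant_table`.
#' @export
variant_table <- function(info, geno) {
  need <- c("variant_id", "chrom", "pos_bp", "ref", "alt", "csq_class")
  if (!all(need %in% names(info))) {
    stop("variant info must have columns: ", paste(need, collapse = ", "))
  }
  info <- as.data.frame(info)[need]
  info$variant_id <- as.character(info$variant_id)
  info$chrom <- as.character(info$chrom)
  info$pos_bp <- as.integer(info$pos_bp)
  info$csq_class <- as.character(info$csq_class)
  if (anyDuplicated(info$variant_id)) stop("variant ids must be unique")
  stopifnot(is.matrix(geno))
  if (ncol(geno) != nrow(info)) {
    stop("genotype state matrix must have one column per variant")
  }
  storage.mode(geno) <- "integer"
  bad <- !is.na(geno) & !(geno %in% 0:2)
  if (any(bad)) stop("genotype states must be 0 (hom_ref), 1 (het), 2 (hom_alt) or NA")
  if (is.null(rownames(geno))) stop("genotype state matrix needs sample ids as rownames")
  colnames(geno) <- info$variant_id
  structure(list(info = info, geno = geno), class = "variant_table")
}

#' Number of variants in a variant table
#' @param x a [variant_table()].
#' @export
n_variants <- function(x) {
  stopifnot(inherits(x, "variant_table"))
  nrow(x$info)
}

#' Subset pipeline objects by locus or sample
#'
#' `subset_loci()` keeps the loci at the given (global) map row indices;
#' `subset_samples()` keeps the named samples, in the order given. Both
#' preserve all container invariants.
#'
#' @param x a [genotype_matrix()] or [haplotype_matrix()].
#' @param idx integer vector of map row indices to keep (increasing).
#' @param ids character vector of sample ids to keep.
#' @return an object of the same class as `x`.
#' @export
subset_loci <- function(x, idx) UseMethod("subset_loci")

#' @export
subset_loci.genotype_matrix <- function(x, idx) {
  idx <- as.integer(idx)
  map <- x$map[idx, , drop = FALSE]
  class(map) <- c("marker_map", "data.frame")
  validate_marker_map(map)
  genotype_matrix(x$dosage[, idx, drop = FALSE], map, rownames(x$dosage))
}

#' @export
subset_loci.haplotype_matrix <- function(x, idx) {
  idx <- as.integer(idx)
  map <- x$map[idx, , drop = FALSE]
  class(map) <- c("marker_map", "data.frame")
  validate_marker_map(map)
  haplotype_matrix(x$alleles[, idx, drop = FALSE], x$sample_ids, map)
}

#' @rdname subset_loci
#' @export
subset_samples <- function(x, ids) UseMethod("subset_samples")

#' @export
subset_samples.genotype_matrix <- function(x, ids) {
  ids <- as.character(ids)
  miss <- setdiff(ids, rownames(x$dosage))
  if (length(miss)) stop("unknown sample ids: ", paste(miss, collapse = ", "))
  genotype_matrix(x$dosage[ids, , drop = FALSE], x$map, ids)
}

#' @export
subset_samples.haplotype_matrix <- function(x, ids) {
  ids <- as.character(ids)
  pos <- match(ids, x$sample_ids)
  if (anyNA(pos)) {
    stop("unknown sample ids: ", paste(ids[is.na(pos)], collapse = ", "))
  }
  rows <- as.vector(rbind(2L * pos - 1L, 2L * pos))
  haplotype_matrix(x$alleles[rows, , drop = FALSE], ids, x$map)
}

#' Extract the phased haplotype pair of one sample
#'
#' @param hap a [haplotype_matrix()].
#' @param id a sample id.
#' @return a 2-by-loci integer matrix of 0/1 allele codes.
#' @export
hap_pair <- function(hap, id) {
  stopifnot(inherits(hap, "haplotype_matrix"))
  i <- match(id, hap$sample_ids)
  if (is.na(i)) stop("unknown sample id: ", id)
  hap$alleles[c(2L * i - 1L, 2L * i), , drop = FALSE]
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "samples x", ncol(x$dosage), "loci;",
      sum(is.na(x$dosage)), "missing calls\n")
  invisible(x)
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat("haplotype_matrix:", length(x$sample_ids), "samples (",
      nrow(x$alleles), "haplotypes ) x", ncol(x$alleles), "loci\n")
  invisible(x)
}

#' @export
print.variant_table <- function(x, ...) {
  cat("variant_table:", nrow(x$info), "variants x", nrow(x$geno), "samples\n")
  if (nrow(x$info)) {
    cat("  span:", x$info$chrom[1], ":", min(x$info$pos_bp), "-",
        max(x$info$pos_bp), "\n", sep = "")
  }
  invisible(x)
}
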