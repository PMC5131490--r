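# File formats touched by the pipeline: PLINK-dialect PED/MAP, a phased
# haplotype table, the sample table, and region VCFs (read via vcfR,
# written by a minimal VCFv4.2 text writer).

split_ws <- function(lines) strsplit(trimws(lines), "[ \t]+")

#' Read genotypes from a PLINK-dialect PED/MAP file pair
#'
#' The native MAP dialect carries six whitespace-delimited columns
#' (chromosome, snp id, cM, bp position, ref allele, alt allele), i.e. the
#' `.bim` layout, so that dosage is always collapsed relative to a declared
#' reference allele. A plain 4-column MAP (chromosome, snp id, cM, bp) is
#' also accepted; the alleles are then inferred from the PED with the
#' lexicographically smaller observed allele as reference (an error is
#' raised for loci where fewer than two alleles are observed). Allele codes
#' in the PED that match neither declared allele are a hard error — no
#' strand auto-flipping is attempted.
#'
#' PED rows have 6 metadata columns (family, individual, sire, dam, sex,
#' phenotype) followed by two allele columns per locus; any `0` allele makes
#' the call missing. The phenotype column is ignored: disease status lives
#' in the [sample_table()].
#'
#' @param ped_path,map_path paths to the PED and MAP files.
#' @return a list with elements `geno` (a [genotype_matrix()]) and `map`
#'   (its [marker_map()]).
#' @export
read_ped_map <- function(ped_path, map_path) {
  stopifnot(file.exists(ped_path), file.exists(map_path))
  map_rows <- split_ws(readLines(map_path))
  map_rows <- map_rows[lengths(map_rows) > 0L]
  ncols <- unique(lengths(map_rows))
  if (length(ncols) > 1L || !ncols %in% c(4L, 6L)) {
    stop("MAP file must have 4 or 6 whitespace-delimited columns throughout")
  }
  m <- length(map_rows)
  mm <- do.call(rbind, map_rows)

  ped_rows <- split_ws(readLines(ped_path))
  ped_rows <- ped_rows[lengths(ped_rows) > 0L]
  n <- length(ped_rows)
  expected <- 6L + 2L * m
  for (i in seq_len(n)) {
    if (length(ped_rows[[i]]) != expected) {
      stop(sprintf(
        "PED line %d has %d fields; expected %d (6 metadata + 2 alleles for each of %d loci)",
        i, length(ped_rows[[i]]), expected, m))
    }
  }
  ids <- vapply(ped_rows, `[`, character(1), 2L)
  a1 <- a2 <- matrix("0", n, m)
  for (i in seq_len(n)) {
    al <- ped_rows[[i]][-(1:6)]
    a1[i, ] <- al[seq(1L, by = 2L, length.out = m)]
    a2[i, ] <- al[seq(2L, by = 2L, length.out = m)]
  }

  if (ncols == 6L) {
    ref <- mm[, 5L]; alt <- mm[, 6L]
  } else {
    ref <- alt <- character(m)
    for (j in seq_len(m)) {
      obs <- sort(unique(setdiff(c(a1[, j], a2[, j]), "0")))
      if (length(obs) != 2L) {
        stop(sprintf(
          "cannot infer ref/alt for locus %s from a 4-column MAP: %d allele(s) observed; use the 6-column dialect",
          mm[j, 2L], length(obs)))
      }
      ref[j] <- obs[1L]; alt[j] <- obs[2L]
    }
  }
  map <- marker_map(mm[, 1L], as.integer(mm[, 4L]), mm[, 2L], ref, alt)

  dosage <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    known <- c("0", map$ref_allele[j], map$alt_allele[j])
    bad <- !(x1 %in% known) | !(x2 %in% known)
    if (any(bad)) {
      stop(sprintf(
        "PED line %d carries allele '%s' at locus %s; declared alleles are %s/%s",
        which(bad)[1L],
        setdiff(c(x1[bad], x2[bad]), known)[1L],
        map$snp_id[j], map$ref_allele[j], map$alt_allele[j]))
    }
    miss <- x1 == "0" | x2 == "0"
    d <- (x1 == map$alt_allele[j]) + (x2 == map$alt_allele[j])
    d[miss] <- NA_integer_
    dosage[, j] <- as.integer(d)
  }
  rownames(dosage) <- ids
  list(geno = genotype_matrix(dosage, map, ids), map = map)
}

#' Write genotypes as a PLINK-dialect PED/MAP file pair
#'
#' Emits the 6-column MAP dialect (chromosome, id, cM = 0, bp, ref, alt)
#' and a PED with family/individual ids both set to the sample id, unknown
#' parents/sex and phenotype `-9`. Missing dosages become `0 0`. The output
#' round-trips bit-identically through [read_ped_map()] followed by
#' `write_ped_map()`.
#'
#' @param geno a [genotype_matrix()].
#' @param out_prefix path prefix; `<prefix>.ped` and `<prefix>.map` are
#'   written.
#' @return the two file paths, invisibly.
#' @export
write_ped_map <- function(geno, out_prefix) {
  stopifnot(inherits(geno, "genotype_matrix"))
  map <- geno$map
  if (anyNA(map$ref_allele) || anyNA(map$alt_allele)) {
    stop("ref/alt allele codes are required to write a PED")
  }
  map_path <- paste0(out_prefix, ".map")
  ped_path <- paste0(out_prefix, ".ped")
  writeLines(paste(map$chrom, map$snp_id, 0L, map$pos_bp,
                   map$ref_allele, map$alt_allele), map_path)

  d <- geno$dosage
  n <- nrow(d); m <- ncol(d)
  lines <- character(n)
  for (i in seq_len(n)) {
    a1 <- ifelse(is.na(d[i, ]), "0",
                 ifelse(d[i, ] >= 1L, map$alt_allele, map$ref_allele))
    a2 <- ifelse(is.na(d[i, ]), "0",
                 ifelse(d[i, ] == 2L, map$alt_allele, map$ref_allele))
    lines[i] <- paste(c(rownames(d)[i], rownames(d)[i], "0", "0", "0", "-9",
                        as.vector(rbind(a1, a2))), collapse = " ")
  }
  writeLines(lines, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read and write the phased-haplotype table
#'
#' Tab-separated matrix with two rows per sample: columns `sample_id`,
#' `hap` (1 or 2), then one 0/1 allele column per locus named by snp id.
#'
#' @param path file path.
#' @param map the [marker_map()] the table columns must match.
#' @return `read_haplotypes()` returns a [haplotype_matrix()].
#' @export
read_haplotypes <- function(path, map) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(colnames(df)[-(1:2)], map$snp_id)) {
    stop("haplotype table columns do not match the marker map")
  }
  ids <- unique(df$sample_id)
  a <- as.matrix(df[, -(1:2), drop = FALSE])
  haplotype_matrix(a, ids, map)
}

#' @rdname read_haplotypes
#' @param hap a [haplotype_matrix()] to write.
#' @export
write_haplotypes <- function(hap, path) {
  stopifnot(inherits(hap, "haplotype_matrix"))
  df <- data.frame(
    sample_id = rep(hap$sample_ids, each = 2L),
    hap = rep(1:2, length(hap$sample_ids)),
    hap$alleles, check.names = FALSE
  )
  colnames(df)[-(1:2)] <- hap$map$snp_id
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write the sample table
#'
#' Tab-separated file with header `sample_id status sire_id dam_id`.
#'
#' @param path file path.
#' @return `read_sample_table()` returns a [sample_table()].
#' @export
read_sample_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA")
  sample_table(df$sample_id, df$status, df$sire_id, df$dam_id)
}

#' @rdname read_sample_table
#' @param samples a [sample_table()] to write.
#' @export
write_sample_table <- function(samples, path) {
  stopifnot(inherits(samples, "sample_table"))
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

parse_region <- function(region) {
  if (is.list(region)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(region)))
    return(list(chrom = as.character(region$chrom),
                start = as.numeric(region$start),
                end = as.numeric(region$end)))
  }
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4L) stop("region must be 'chrom:start-end' (1-based inclusive)")
  list(chrom = m[2], start = as.numeric(m[3]), end = as.numeric(m[4]))
}

#' Read biallelic variant records from a region of a VCF
#'
#' Parses the VCF with \pkg{vcfR} and keeps the biallelic records whose
#' position falls inside `region` (1-based inclusive). Multi-allelic
#' records are skipped with a warning and counted in the
#' `n_multiallelic_skipped` attribute of the result — they are never split.
#' GT fields are mapped to genotype states (`0/0` → hom_ref, `0/1`/`1/0` →
#' het, `1/1` → hom_alt, any `.` → missing); phased separators are
#' accepted. A consequence-class label is read from the INFO key
#' `CSQ_CLASS` when present.
#'
#' @param vcf_path path to a VCF v4.2 file with GT for all samples.
#' @param region `"chrom:start-end"` or `list(chrom=, start=, end=)`.
#' @return a [variant_table()] with attribute `n_multiallelic_skipped`.
#' @export
read_region_vcf <- function(vcf_path, region) {
  stopifnot(file.exists(vcf_path))
  reg <- parse_region(region)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    geno <- matrix(integer(0), nrow = 0, ncol = 0)
    rownames(geno) <- character(0)
    return(empty_variant_table())
  }
  fix$POS <- as.numeric(fix$POS)
  in_region <- fix$CHROM == reg$chrom & fix$POS >= reg$start & fix$POS <= reg$end
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  n_skip <- sum(in_region & multi)
  if (n_skip > 0L) {
    warning(n_skip, " multi-allelic record(s) in region skipped")
  }
  keep <- which(in_region & !multi)
  csq <- vcfR::extract.info(vcf, "CSQ_CLASS")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(csq)) csq <- rep(NA_character_, nrow(fix))

  state_of <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(NA_integer_, length(g))
    out[g %in% "0/0"] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g %in% "1/1"] <- 2L
    out
  }
  ids <- fix$ID[keep]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0("var_", fix$CHROM[keep][no_id], "_", fix$POS[keep][no_id])
  info <- data.frame(
    variant_id = ids, chrom = fix$CHROM[keep], pos_bp = fix$POS[keep],
    ref = fix$REF[keep], alt = fix$ALT[keep],
    csq_class = csq[keep], stringsAsFactors = FALSE
  )
  geno <- apply(gt[keep, , drop = FALSE], 1L, state_of)
  if (is.null(dim(geno))) geno <- matrix(geno, ncol = length(keep))
  rownames(geno) <- colnames(gt)
  out <- variant_table(info, geno)
  attr(out, "n_multiallelic_skipped") <- n_skip
  out
}

empty_variant_table <- function(sample_ids = character(0)) {
  info <- data.frame(variant_id = character(0), chrom = character(0),
                     pos_bp = integer(0), ref = character(0),
                     alt = character(0), csq_class = character(0),
                     stringsAsFactors = FALSE)
  geno <- matrix(integer(0), nrow = length(sample_ids), ncol = 0)
  rownames(geno) <- sample_ids
  out <- variant_table(info, geno)
  attr(out, "n_multiallelic_skipped") <- 0L
  out
}

#' Write a variant table as a minimal VCF v4.2 text file
#'
#' Emits one biallelic record per variant with the consequence class in the
#' INFO key `CSQ_CLASS` and GT as the only FORMAT field. Output is plain
#' text and round-trips through [read_region_vcf()] at state level.
#'
#' @param vt a [variant_table()].
#' @param path output path.
#' @export
write_region_vcf <- function(vt, path) {
  stopifnot(inherits(vt, "variant_table"))
  samples <- rownames(vt$geno)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CSQ_CLASS,Number=1,Type=String,Description=\"Consequence class label\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  gt_str <- c("0/0", "0/1", "1/1")
  recs <- vapply(seq_len(nrow(vt$info)), function(j) {
    g <- vt$geno[, j]
    gs <- ifelse(is.na(g), "./.", gt_str[g + 1L])
    info <- if (is.na(vt$info$csq_class[j])) "." else
      paste0("CSQ_CLASS=", vt$info$csq_class[j])
    paste(c(vt$info$chrom[j], vt$info$pos_bp[j], vt$info$variant_id[j],
            vt$info$ref[j], vt$info$alt[j], ".", "PASS", info, "GT", gs),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, recs), path)
  invisible(path)
}
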