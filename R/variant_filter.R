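# Recessive-compatibility candidate-variant cascade with per-step
# accounting, consequence-class filtering, allele-frequency estimation and
# haplotype-variant concordance.
#
# Role asymmetry: a missing genotype in a case or obligate carrier makes a
# variant incompatible (conservative — the evidence for compatibility is
# absent), whereas a missing panel genotype never excludes a variant (the
# panel can only exclude through an observed homozygous-alternate call).

#' Default consequence classes kept by the coding/splice filter
#' @export
CODING_CLASSES <- c("stop_gained", "splice_site", "missense", "synonymous")

variant_geno_rows <- function(vt, ids, role) {
  miss <- setdiff(ids, rownames(vt$geno))
  if (length(miss)) {
    stop("unknown ", role, " id(s): ", paste(miss, collapse = ", "))
  }
  vt$geno[ids, , drop = FALSE]
}

#' Recessive-inheritance compatibility of variants
#'
#' A variant is compatible with recessive inheritance when every case is
#' homozygous for the alternate allele and every obligate carrier is
#' heterozygous. Any missing genotype among these roles makes the variant
#' incompatible.
#'
#' @param vt a [variant_table()].
#' @param case_ids,carrier_ids sample ids filling the two roles; all must
#'   be present in the table.
#' @return named logical vector, one entry per variant.
#' @export
recessive_compatible <- function(vt, case_ids, carrier_ids) {
  stopifnot(inherits(vt, "variant_table"),
            length(case_ids) >= 1L, length(carrier_ids) >= 0L)
  gc <- variant_geno_rows(vt, case_ids, "case")
  gk <- variant_geno_rows(vt, carrier_ids, "carrier")
  cases_ok <- colSums(is.na(gc) | gc != 2L) == 0L
  carriers_ok <- colSums(is.na(gk) | gk != 1L) == 0L
  setNames(cases_ok & carriers_ok, vt$info$variant_id)
}

subset_variants <- function(vt, keep) {
  out <- variant_table(vt$info[keep, , drop = FALSE],
                       vt$geno[, keep, drop = FALSE])
  out
}

#' Exclude variants homozygous-alternate in a healthy panel
#'
#' Drops any variant observed homozygous for the alternate allele in at
#' least one panel sample. Heterozygous panel carriers are tolerated;
#' missing panel genotypes never exclude.
#'
#' @param vt a [variant_table()].
#' @param panel_ids panel sample ids (present in the table).
#' @return list with `variants` (the survivors) and `n_excluded`.
#' @export
exclude_hom_alt_in_panel <- function(vt, panel_ids) {
  stopifnot(inherits(vt, "variant_table"))
  gp <- variant_geno_rows(vt, panel_ids, "panel")
  hom_alt_seen <- colSums(gp == 2L, na.rm = TRUE) > 0L
  list(variants = subset_variants(vt, !hom_alt_seen),
       n_excluded = sum(hom_alt_seen))
}

#' Filter variants by consequence class
#'
#' Retains variants whose consequence-class label is in `allowed_classes`
#' (default: coding and splice classes, [CODING_CLASSES]). Labels are a
#' hard input contract — an unlabelled variant is an error, since
#' annotation is upstream of this pipeline.
#'
#' @param vt a [variant_table()].
#' @param allowed_classes character vector of retained class labels.
#' @return the filtered [variant_table()].
#' @export
consequence_filter <- function(vt, allowed_classes = CODING_CLASSES) {
  stopifnot(inherits(vt, "variant_table"))
  if (anyNA(vt$info$csq_class)) {
    stop("unlabelled variant(s): ",
         paste(utils::head(vt$info$variant_id[is.na(vt$info$csq_class)], 5),
               collapse = ", "))
  }
  subset_variants(vt, vt$info$csq_class %in% allowed_classes)
}

restrict_to_region <- function(vt, reg) {
  keep <- vt$info$chrom == reg$chrom &
    vt$info$pos_bp >= reg$start & vt$info$pos_bp <= reg$end
  subset_variants(vt, keep)
}

#' Run the recessive-compatibility filter cascade
#'
#' Steps, in order: restrict to the candidate region; keep variants
#' compatible with recessive inheritance (hom-alt in every case, het in
#' every obligate carrier); exclude variants homozygous-alternate in any
#' healthy-panel sample; keep coding/splice consequence classes. The
#' report carries the surviving count after every step.
#'
#' @param vt a [variant_table()].
#' @param region `"chrom:start-end"` or `list(chrom=, start=, end=)`.
#' @param samples a [sample_table()]; cases are the `affected` samples,
#'   carriers the `obligate_carrier` samples. Both groups must be
#'   non-empty.
#' @param panel_ids panel sample ids; defaults to the `panel_healthy`
#'   samples of `samples`. Must be non-empty.
#' @param allowed_classes consequence classes kept by the final step.
#' @return list with `candidates` (the surviving [variant_table()]) and
#'   `report` (class `cascade_report`).
#' @export
run_cascade <- function(vt, region, samples, panel_ids = NULL,
                        allowed_classes = CODING_CLASSES) {
  stopifnot(inherits(vt, "variant_table"), inherits(samples, "sample_table"))
  reg <- parse_region(region)
  case_ids <- samples$sample_id[samples$status == "affected"]
  carrier_ids <- samples$sample_id[samples$status == "obligate_carrier"]
  if (is.null(panel_ids)) {
    panel_ids <- samples$sample_id[samples$status == "panel_healthy"]
  }
  if (length(case_ids) == 0L) stop("no affected samples: case role is empty")
  if (length(carrier_ids) == 0L) stop("no obligate carriers: carrier role is empty")
  if (length(panel_ids) == 0L) stop("healthy panel is empty")

  v1 <- restrict_to_region(vt, reg)
  compat <- recessive_compatible(v1, case_ids, carrier_ids)
  v2 <- subset_variants(v1, compat)
  panel_step <- exclude_hom_alt_in_panel(v2, panel_ids)
  v3 <- panel_step$variants
  v4 <- consequence_filter(v3, allowed_classes)

  report <- structure(list(
    steps = data.frame(
      step = c("input", "region", "recessive_compatible",
               "not_hom_alt_in_panel", "coding_or_splice"),
      surviving = c(n_variants(vt), n_variants(v1), n_variants(v2),
                    n_variants(v3), n_variants(v4)),
      stringsAsFactors = FALSE
    ),
    region = sprintf("%s:%d-%d", reg$chrom, as.integer(reg$start),
                     as.integer(reg$end)),
    roles = list(cases = case_ids, carriers = carrier_ids,
                 panel = panel_ids),
    allowed_classes = allowed_classes
  ), class = "cascade_report")
  list(candidates = v4, report = report)
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("Recessive-compatibility cascade (", x$region, ")\n", sep = "")
  cat(sprintf("  roles: %d case(s), %d carrier(s), %d panel sample(s)\n",
              length(x$roles$cases), length(x$roles$carriers),
              length(x$roles$panel)))
  for (i in seq_len(nrow(x$steps))) {
    cat(sprintf("  %-22s %d\n", x$steps$step[i], x$steps$surviving[i]))
  }
  invisible(x)
}

#' Serialise a cascade report to JSON
#' @param report a `cascade_report`.
#' @param path output path.
#' @export
write_cascade_report <- function(report, path) {
  stopifnot(inherits(report, "cascade_report"))
  jsonlite::write_json(list(steps = report$steps, region = report$region,
                            roles = report$roles,
                            allowed_classes = report$allowed_classes),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Alternate-allele frequency from genotype counts
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts (total at least 1).
#' @return `(n_het + 2 n_hom_alt) / (2 total)`.
#' @export
allele_frequency <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  total <- n_hom_ref + n_het + n_hom_alt
  if (total < 1) stop("at least one genotype required")
  (n_het + 2 * n_hom_alt) / (2 * total)
}

#' Round a proportion to integer percent, half up
#'
#' Reported allele frequencies are conventionally stated as integer
#' percentages with halves rounding up.
#'
#' @param x a proportion in `[0, 1]`.
#' @return integer percent.
#' @export
percent_round <- function(x) {
  as.integer(floor(x * 100 + 0.5))
}

#' Concordance between haplotype carrier state and a variant's genotypes
#'
#' Cross-tabulates the per-sample carrier haplotype copy count (0/1/2)
#' against the variant genotype state (hom_ref/het/hom_alt). Concordance
#' is "complete" — the variant is in complete linkage disequilibrium with
#' the haplotype — exactly when every off-diagonal cell (copy 0 with
#' anything but hom_ref, copy 1 with anything but het, copy 2 with
#' anything but hom_alt) is zero. Missing genotypes are excluded from the
#' table and counted separately.
#'
#' @param copy_counts integer vector of carrier copy counts (0/1/2).
#' @param states integer vector of genotype states (0/1/2/NA, see
#'   [GENOTYPE_STATES]), aligned with `copy_counts`.
#' @return an object of class `concordance`: list with `table` (3x3),
#'   `complete`, `n_discordant`, `n_missing`.
#' @export
haplotype_variant_concordance <- function(copy_counts, states) {
  stopifnot(length(copy_counts) == length(states),
            all(copy_counts %in% 0:2))
  obs <- !is.na(states)
  tab <- table(
    copy_count = factor(copy_counts[obs], levels = 0:2),
    genotype = factor(states[obs], levels = 0:2,
                      labels = c("hom_ref", "het", "hom_alt"))
  )
  n_disc <- sum(tab) - sum(diag(tab))
  structure(list(table = tab, complete = n_disc == 0L,
                 n_discordant = as.integer(n_disc),
                 n_missing = sum(!obs)),
            class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat("Haplotype-variant concordance:",
      if (x$complete) "complete" else
        sprintf("incomplete (%d discordant)", x$n_discordant), "\n")
  print(x$table)
  if (x$n_missing) cat("  missing genotypes:", x$n_missing, "\n")
  invisible(x)
}
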