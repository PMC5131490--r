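# Marker and sample quality control: call-rate, minor-allele-frequency and
# exact Hardy-Weinberg filters, with per-step accounting.

#' Quality-control thresholds
#'
#' All thresholds are strict inequalities, matching how such filters are
#' conventionally stated: a marker is retained when its MAF is *above*
#' `min_maf`, its HWE p-value *above* `hwe_p_floor`, and call rates are
#' *higher than* the minima.
#'
#' @param min_maf minimum minor allele frequency (exclusive), default 0.005.
#' @param hwe_p_floor Hardy-Weinberg exact-test p-value floor (exclusive),
#'   default 1e-4.
#' @param min_snp_callrate,min_sample_callrate call-rate minima (exclusive),
#'   default 0.95.
#' @return an object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_maf = 0.005, hwe_p_floor = 1e-4,
                          min_snp_callrate = 0.95,
                          min_sample_callrate = 0.95) {
  th <- list(min_maf = min_maf, hwe_p_floor = hwe_p_floor,
             min_snp_callrate = min_snp_callrate,
             min_sample_callrate = min_sample_callrate)
  stopifnot(all(unlist(th) >= 0), all(unlist(th) <= 1))
  structure(th, class = "qc_thresholds")
}

#' Minor allele frequency of a dosage column
#'
#' `min(p, 1 - p)` where `p` is the alternate-allele frequency over
#' non-missing calls.
#'
#' @param dosage_column integer vector of dosages (0/1/2/NA).
#' @return the minor allele frequency.
#' @export
compute_maf <- function(dosage_column) {
  obs <- dosage_column[!is.na(dosage_column)]
  if (length(obs) == 0L) stop("all genotypes missing: MAF undefined")
  p <- sum(obs) / (2 * length(obs))
  min(p, 1 - p)
}

# log probability of nAa heterozygotes given n genotypes and nA copies of
# the rarer allele: multinomial genotype count over the hypergeometric-like
# allele-arrangement denominator.
hwe_log_prob <- function(n_het, n, nA) {
  n_hom_a <- (nA - n_het) / 2
  n_hom_b <- n - n_het - n_hom_a
  lgamma(n + 1) - lgamma(n_hom_a + 1) - lgamma(n_het + 1) -
    lgamma(n_hom_b + 1) + n_het * log(2) +
    lgamma(nA + 1) + lgamma(2 * n - nA + 1) - lgamma(2 * n + 1)
}

#' Exact test for Hardy-Weinberg equilibrium
#'
#' Two-sided exact test: all heterozygote counts consistent with the
#' observed allele counts are enumerated and the probabilities of
#' configurations no more likely than the observed one are summed.
#' Monomorphic input returns p = 1 (not an error).
#'
#' @param n_hom_ref,n_het,n_hom_alt observed genotype counts.
#' @return the exact p-value.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n < 1L) stop("at least one genotype required")
  nA <- 2 * min(n_hom_ref, n_hom_alt) + n_het  # rarer allele count
  if (nA == 0) return(1.0)
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  logp <- hwe_log_prob(hets, n, nA)
  logp <- logp - max(logp)
  pr <- exp(logp) / sum(exp(logp))
  p_obs <- pr[match(n_het, hets)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

#' Apply marker and sample quality control
#'
#' Filters are applied in a fixed, logged order: per-sample call rate
#' first, then per-SNP call rate, minor allele frequency and the exact
#' Hardy-Weinberg test, each recomputed on what the previous step retained.
#' The operation is idempotent. The report records what each step removed;
#' totals change if the order changes, which is why the order is fixed.
#'
#' @param geno a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return a list with elements `genotypes` (the filtered
#'   [genotype_matrix()]) and `report` (class `qc_report`, carrying
#'   per-step removal counts, removed sample ids, per-sample call rates,
#'   and the retained sample ids / global locus indices `kept_samples` /
#'   `kept_loci` for aligning companion matrices).
#' @export
apply_qc <- function(geno, thresholds = qc_thresholds()) {
  stopifnot(inherits(geno, "genotype_matrix"),
            inherits(thresholds, "qc_thresholds"))
  d <- geno$dosage
  if (nrow(d) == 0L || ncol(d) == 0L) stop("non-empty genotype matrix required")

  sample_cr <- rowMeans(!is.na(d))
  keep_s <- sample_cr > thresholds$min_sample_callrate
  d1 <- d[keep_s, , drop = FALSE]

  snp_cr <- colMeans(!is.na(d1))
  keep_cr <- snp_cr > thresholds$min_snp_callrate
  n_rm_cr <- sum(!keep_cr)

  maf <- rep(0, ncol(d1))
  has_call <- colSums(!is.na(d1)) > 0L
  maf[has_call] <- apply(d1[, has_call, drop = FALSE], 2L, compute_maf)
  keep_maf <- keep_cr & has_call & maf > thresholds$min_maf
  n_rm_maf <- sum(keep_cr & !keep_maf)

  hwe_p <- rep(1, ncol(d1))
  for (j in which(keep_maf)) {
    x <- d1[, j]
    hwe_p[j] <- hwe_exact_test(sum(x == 0L, na.rm = TRUE),
                               sum(x == 1L, na.rm = TRUE),
                               sum(x == 2L, na.rm = TRUE))
  }
  keep_hwe <- keep_maf & hwe_p > thresholds$hwe_p_floor
  n_rm_hwe <- sum(keep_maf & !keep_hwe)

  kept_loci <- unname(which(keep_hwe))
  out <- subset_loci(genotype_matrix(d1, geno$map, rownames(d1)), kept_loci)

  report <- structure(list(
    steps = data.frame(
      step = c("sample_callrate", "snp_callrate", "maf", "hwe"),
      removed = c(sum(!keep_s), n_rm_cr, n_rm_maf, n_rm_hwe),
      stringsAsFactors = FALSE
    ),
    samples_removed = rownames(d)[!keep_s],
    sample_call_rates = setNames(sample_cr, rownames(d)),
    n_samples_in = nrow(d), n_loci_in = ncol(d),
    n_samples_retained = sum(keep_s), n_loci_retained = length(kept_loci),
    kept_samples = rownames(d)[keep_s],
    kept_loci = kept_loci,
    thresholds = thresholds
  ), class = "qc_report")
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Quality control report\n")
  cat(sprintf("  samples: %d in, %d retained (%d removed by call rate)\n",
              x$n_samples_in, x$n_samples_retained,
              length(x$samples_removed)))
  cat(sprintf("  loci:    %d in, %d retained\n", x$n_loci_in,
              x$n_loci_retained))
  for (i in seq_len(nrow(x$steps))) {
    cat(sprintf("    %-16s removed %d\n", x$steps$step[i], x$steps$removed[i]))
  }
  invisible(x)
}

#' Serialise a QC report to JSON
#' @param report a `qc_report`.
#' @param path output path.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  jsonlite::write_json(list(
    steps = report$steps,
    samples_removed = report$samples_removed,
    n_samples_in = report$n_samples_in, n_loci_in = report$n_loci_in,
    n_samples_retained = report$n_samples_retained,
    n_loci_retained = report$n_loci_retained
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
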