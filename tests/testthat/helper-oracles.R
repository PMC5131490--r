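# Independent reference implementations ("oracles") used to validate the
# package's optimised routines, plus small fixture builders. Every oracle
# deliberately takes a different computational route from the code it
# checks.

# Exact HWE p-value by the recurrence over heterozygote counts
# (relative probabilities built multiplicatively, then normalised) —
# independent of the log-gamma closed form in the package.
oracle_hwe <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  nA <- 2 * min(n_hom_ref, n_hom_alt) + n_het
  if (nA == 0) return(1.0)
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  rel <- numeric(length(hets))
  rel[1] <- 1
  for (i in seq_along(hets)[-1]) {
    h <- hets[i]  # P(h)/P(h-2) = 4 * nhomA(h-2) * nhomB(h-2) / (h (h-1))
    ha <- (nA - (h - 2)) / 2
    hb <- n - (h - 2) - ha
    rel[i] <- rel[i - 1] * 4 * ha * hb / (h * (h - 1))
  }
  pr <- rel / sum(rel)
  p_obs <- pr[match(n_het, hets)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

# OLS via explicit normal equations solved with solve() — independent of
# the QR path in test_haplotype().
oracle_ols <- function(y, X_cov, dosage) {
  X <- cbind(1, X_cov, dosage)
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * solve(XtX)[ncol(X), ncol(X)])
  t <- beta[ncol(X)] / se
  list(beta = beta[ncol(X)], se = se, p = 2 * pt(-abs(t), df))
}

# Exhaustive ROH scanner: enumerates every interval with homozygous
# endpoints and het count within budget, keeps those with enough
# homozygous SNPs, and retains only maximal ones (no one-hom-step
# extension on either side stays within budget; farther extensions add at
# least as many hets, so one-step checks suffice).
oracle_roh <- function(d, pos, min_snps, max_het) {
  n <- length(d)
  is_hom <- !is.na(d) & d != 1L
  is_het <- !is.na(d) & d == 1L
  ch <- cumsum(is_het); chom <- cumsum(is_hom)
  hets_in <- function(i, j) ch[j] - if (i > 1) ch[i - 1] else 0
  homs_in <- function(i, j) chom[j] - if (i > 1) chom[i - 1] else 0
  homs <- which(is_hom)
  cand <- list()
  for (ii in seq_along(homs)) {
    for (jj in ii:length(homs)) {
      i <- homs[ii]; j <- homs[jj]
      if (hets_in(i, j) > max_het) break
      if (homs_in(i, j) < min_snps) next
      ext_l <- ii > 1 && hets_in(homs[ii - 1], j) <= max_het
      ext_r <- jj < length(homs) && hets_in(i, homs[jj + 1]) <= max_het
      if (!ext_l && !ext_r) {
        cand[[length(cand) + 1L]] <- c(start = pos[i], end = pos[j])
      }
    }
  }
  if (!length(cand)) return(NULL)
  out <- unique(do.call(rbind, cand))
  out[order(out[, "start"]), , drop = FALSE]
}

# Exhaustive shared-autozygosity scanner over a small dosage matrix:
# candidate intervals have informative endpoints (all samples observed,
# homozygous, identical), zero conflicting loci inside, enough informative
# loci, and are maximal.
oracle_shared <- function(D, pos, min_snps) {
  n <- ncol(D)
  locus_ok <- vapply(seq_len(n), function(j) {
    x <- D[, j]; x <- x[!is.na(x)]
    if (any(x == 1L)) return(FALSE)
    !(any(x == 0L) && any(x == 2L))
  }, logical(1))
  informative <- vapply(seq_len(n), function(j) {
    x <- D[, j]
    !anyNA(x) && locus_ok[j] && length(unique(x)) == 1L && x[1] != 1L
  }, logical(1))
  cbad <- cumsum(!locus_ok); cinf <- cumsum(informative)
  bad_in <- function(i, j) cbad[j] - if (i > 1) cbad[i - 1] else 0
  inf_in <- function(i, j) cinf[j] - if (i > 1) cinf[i - 1] else 0
  infs <- which(informative)
  cand <- list()
  for (ii in seq_along(infs)) {
    for (jj in ii:length(infs)) {
      i <- infs[ii]; j <- infs[jj]
      if (bad_in(i, j) > 0) break
      if (inf_in(i, j) < min_snps) next
      ext_l <- ii > 1 && bad_in(infs[ii - 1], j) == 0
      ext_r <- jj < length(infs) && bad_in(i, infs[jj + 1]) == 0
      if (!ext_l && !ext_r) {
        cand[[length(cand) + 1L]] <- c(start = pos[i], end = pos[j])
      }
    }
  }
  if (!length(cand)) return(NULL)
  out <- unique(do.call(rbind, cand))
  out[order(out[, "start"]), , drop = FALSE]
}

# --- fixture builders --------------------------------------------------------

mk_map <- function(m, chrom = "1", spacing = 1000L) {
  marker_map(chrom = rep(chrom, m), pos_bp = seq_len(m) * spacing,
             snp_id = sprintf("s%s_%03d", chrom, seq_len(m)),
             ref_allele = rep("A", m), alt_allele = rep("G", m))
}

mk_geno <- function(dosage, map = NULL, chrom = "1") {
  if (is.null(map)) map <- mk_map(ncol(dosage), chrom)
  genotype_matrix(dosage, map)
}

# A small but full-featured simulated population shared by module tests.
small_config <- function(seed = 7, ...) {
  args <- list(n_chromosomes = 2L, snps_per_chromosome = 250L,
               chromosome_length_bp = 25e6, n_founders = 150L,
               carrier_haplotype_chromosome = "2",
               carrier_region_bp = c(8e6, 16e6),
               n_panel_healthy = 40L, n_region_variants = 120L,
               seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

small_pop <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_population(small_config())
    cache
  }
})
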