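# Pedigree-structured genotype simulator with full ground truth.
#
# The design emulates a livestock mapping study: a single crossbred founder
# sire carries one copy of a distinguishable disease haplotype; his carrier
# descendants are mated to each other (a half-sib design mirroring heavy AI
# sire usage), producing affected offspring whose parents are the obligate
# carriers; controls and a healthy panel descend from unrelated founders and
# carry zero copies by construction. Gene dropping uses Poisson-count
# crossovers with uniform positions and no interference. Haplotypes are
# represented internally as mosaics of founder-haplotype segments, so
# identity by descent is known exactly and region variants added later are
# phase-consistent without perturbing the SNP genotypes.

#' Simulation configuration
#'
#' Defaults reproduce the study conditions the pipeline is validated
#' against: 2 affected, 14 obligate carriers (the parents of affected
#' offspring) and 27 controls genotyped at 5 chromosomes x 600 SNPs, one
#' carrier founder whose disease haplotype spans a 10 Mb region, a healthy
#' panel (scaled down to 150 animals), and ~500 sequence-level variants in
#' the candidate region of which exactly one — a stop-gained variant — rides
#' the carrier haplotype.
#'
#' @param n_chromosomes number of autosomes simulated.
#' @param snps_per_chromosome array SNPs per chromosome.
#' @param chromosome_length_bp physical chromosome length.
#' @param n_founders size of the unrelated founder pool that supplies dams
#'   and control/panel parents (the carrier sire is extra).
#' @param n_generations pedigree depth; 3 = founders, carriers, affecteds.
#'   Values above 3 insert extra carrier-descent meioses before the carrier
#'   matings.
#' @param n_affected,n_obligate_carriers,n_controls,n_panel_healthy sample
#'   counts per status; `n_obligate_carriers` must be even (carriers are
#'   mated pairwise) and `n_affected` cannot exceed the number of matings.
#' @param carrier_haplotype_chromosome chromosome label bearing the disease
#'   haplotype.
#' @param carrier_region_bp length-2 interval (bp, 1-based inclusive) the
#'   disease haplotype spans; must lie within the chromosome.
#' @param recombination_rate expected crossovers per chromosome per meiosis.
#' @param genotyping_missing_rate per-call missingness applied to the
#'   genotype matrix only (haplotypes stay complete).
#' @param founder_allele_freq_distribution named vector
#'   `c(shape1=, shape2=, min_maf=)`: per-locus alternate-allele frequencies
#'   are Beta(shape1, shape2) draws resampled until within
#'   `[min_maf, 1 - min_maf]`.
#' @param n_region_variants sequence-level variants simulated in the
#'   carrier region (including the causal one).
#' @param retry_budget attempts allowed per carrier/affected breeding step.
#' @param seed integer seed governing one hierarchical random stream;
#'   per-stage sub-streams are derived deterministically so that adding
#'   region variants never perturbs the SNP genotypes.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 5L,
                       snps_per_chromosome = 600L,
                       chromosome_length_bp = 60e6,
                       n_founders = 400L,
                       n_generations = 3L,
                       n_affected = 2L,
                       n_obligate_carriers = 14L,
                       n_controls = 27L,
                       n_panel_healthy = 150L,
                       carrier_haplotype_chromosome = "3",
                       carrier_region_bp = c(40e6, 50e6),
                       recombination_rate = 1.0,
                       genotyping_missing_rate = 0.01,
                       founder_allele_freq_distribution =
                         c(shape1 = 2, shape2 = 2, min_maf = 0.05),
                       n_region_variants = 500L,
                       retry_budget = 100L,
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    snps_per_chromosome = as.integer(snps_per_chromosome),
    chromosome_length_bp = as.numeric(chromosome_length_bp),
    n_founders = as.integer(n_founders),
    n_generations = as.integer(n_generations),
    n_affected = as.integer(n_affected),
    n_obligate_carriers = as.integer(n_obligate_carriers),
    n_controls = as.integer(n_controls),
    n_panel_healthy = as.integer(n_panel_healthy),
    carrier_haplotype_chromosome = as.character(carrier_haplotype_chromosome),
    carrier_region_bp = as.numeric(carrier_region_bp),
    recombination_rate = as.numeric(recombination_rate),
    genotyping_missing_rate = as.numeric(genotyping_missing_rate),
    founder_allele_freq_distribution = founder_allele_freq_distribution,
    n_region_variants = as.integer(n_region_variants),
    retry_budget = as.integer(retry_budget),
    seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(n_chromosomes >= 1L, snps_per_chromosome >= 1L,
              chromosome_length_bp >= 1, n_founders >= 2L,
              n_generations >= 3L, n_affected >= 1L,
              n_obligate_carriers >= 2L, n_controls >= 0L,
              n_panel_healthy >= 0L, n_region_variants >= 1L,
              retry_budget >= 1L)
    stopifnot(recombination_rate >= 0, genotyping_missing_rate >= 0,
              genotyping_missing_rate <= 1)
    if (n_obligate_carriers %% 2L != 0L) {
      stop("n_obligate_carriers must be even (carriers are mated pairwise)")
    }
    if (length(carrier_region_bp) != 2L ||
        carrier_region_bp[1] < 1 ||
        carrier_region_bp[2] > chromosome_length_bp ||
        carrier_region_bp[1] >= carrier_region_bp[2]) {
      stop("carrier_region_bp must be an increasing interval within the chromosome")
    }
    fd <- founder_allele_freq_distribution
    stopifnot(all(c("shape1", "shape2", "min_maf") %in% names(fd)),
              fd[["min_maf"]] >= 0, fd[["min_maf"]] < 0.5)
  })
  structure(cfg, class = "sim_config")
}

# Deterministic per-stage sub-seed derived from the master seed, kept
# within 32-bit integer range.
sub_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629 + 1)
}

draw_founder_freqs <- function(m, fd) {
  lo <- fd[["min_maf"]]; hi <- 1 - lo
  p <- rbeta(m, fd[["shape1"]], fd[["shape2"]])
  bad <- p < lo | p > hi
  while (any(bad)) {
    p[bad] <- rbeta(sum(bad), fd[["shape1"]], fd[["shape2"]])
    bad <- p < lo | p > hi
  }
  p
}

# --- segment-mosaic gene dropping -------------------------------------------
# A haplotype on one chromosome is a matrix with columns (start, end, hap):
# closed intervals that tile [1, L] and reference founder haplotype rows.

clip_segs <- function(segs, a, b) {
  s <- segs[segs[, "end"] >= a & segs[, "start"] <= b, , drop = FALSE]
  if (nrow(s)) {
    s[, "start"] <- pmax(s[, "start"], a)
    s[, "end"] <- pmin(s[, "end"], b)
  }
  s
}

gamete_one <- function(h1, h2, L, rate) {
  nx <- rpois(1L, rate)
  cuts <- if (nx > 0L) sort(runif(nx, 1, L)) else numeric(0)
  src <- sample.int(2L, 1L)
  bounds <- c(1, cuts, L + 1)
  out <- NULL
  for (i in seq_len(length(bounds) - 1L)) {
    a <- bounds[i]
    b <- bounds[i + 1L] - 1e-6  # cuts are non-integer, SNPs sit at integers
    par <- if (src == 1L) h1 else h2
    out <- rbind(out, clip_segs(par, a, b))
    src <- 3L - src
  }
  out
}

#' Simulate a pedigree-structured population with a recessive disease
#' haplotype
#'
#' Gene-drops phased genotypes through the half-sib pedigree described in
#' [sim_config()]. Exactly the configured numbers of affected (two carrier
#' haplotype copies across the whole carrier region), obligate-carrier
#' (parents of affected offspring, one copy each), control and
#' panel-healthy (zero copies) samples are emitted, together with complete
#' ground truth. Missingness is applied to the genotype matrix only; output
#' is fully reproducible from the seed.
#'
#' @param config a [sim_config()].
#' @return an object of class `sim_population`: a list with elements
#'   `haplotypes` ([haplotype_matrix()]), `genotypes`
#'   ([genotype_matrix()] with missing calls), `map`, `samples`
#'   ([sample_table()]) and `truth` (class `sim_truth`, holding the causal
#'   variant id and position, the carrier haplotype allele string over the
#'   carrier region, the per-sample true carrier copy count, and internal
#'   descent bookkeeping used by [simulate_region_variants()]).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  chroms <- as.character(seq_len(config$n_chromosomes))
  cc <- config$carrier_haplotype_chromosome
  if (!cc %in% chroms) {
    stop("carrier_haplotype_chromosome must be one of ",
         paste(chroms, collapse = ", "))
  }
  m <- config$snps_per_chromosome
  L <- config$chromosome_length_bp
  r1 <- config$carrier_region_bp[1]; r2 <- config$carrier_region_bp[2]
  nh <- 2L * (config$n_founders + 1L)  # founder pool + the carrier sire

  # -- founder haplotypes ----------------------------------------------------
  set.seed(sub_seed(config$seed, "founders"))
  pos <- fall <- setNames(vector("list", length(chroms)), chroms)
  for (ch in chroms) {
    pos[[ch]] <- sort(sample.int(L, m))
    p <- draw_founder_freqs(m, config$founder_allele_freq_distribution)
    fall[[ch]] <- matrix(rbinom(nh * m, 1L, rep(p, each = nh)), nrow = nh)
  }
  tot <- m * length(chroms)
  al <- vapply(seq_len(tot), function(i) sample(c("A", "C", "G", "T"), 2L),
               character(2))
  map <- marker_map(
    chrom = rep(chroms, each = m),
    pos_bp = unlist(pos, use.names = FALSE),
    snp_id = sprintf("snp_%s_%04d", rep(chroms, each = m),
                     rep(seq_len(m), times = length(chroms))),
    ref_allele = al[1L, ], alt_allele = al[2L, ]
  )
  region_cols <- which(pos[[cc]] >= r1 & pos[[cc]] <= r2)
  carrier_string <- paste0(fall[[cc]][1L, region_cols], collapse = "")

  # -- pedigree --------------------------------------------------------------
  set.seed(sub_seed(config$seed, "pedigree"))
  founder_counter <- 0L
  new_founder <- function() {
    founder_counter <<- founder_counter %% config$n_founders + 1L
    founder_counter
  }
  founder_ind <- function(k) {  # k = 0 is the carrier sire (haps 1, 2)
    haps <- c(2L * k + 1L, 2L * k + 2L)
    lapply(setNames(chroms, chroms), function(ch) list(
      h1 = cbind(start = 1, end = L, hap = haps[1L]),
      h2 = cbind(start = 1, end = L, hap = haps[2L])
    ))
  }
  child_of <- function(pa, ma) {
    lapply(setNames(chroms, chroms), function(ch) list(
      h1 = gamete_one(pa[[ch]]$h1, pa[[ch]]$h2, L, config$recombination_rate),
      h2 = gamete_one(ma[[ch]]$h1, ma[[ch]]$h2, L, config$recombination_rate)
    ))
  }
  hap_is_carrier <- function(segs) {
    o <- segs[segs[, "end"] >= r1 & segs[, "start"] <= r2, "hap"]
    length(o) > 0L && all(o == 1)
  }
  carrier_copies <- function(ind) {
    hap_is_carrier(ind[[cc]]$h1) + hap_is_carrier(ind[[cc]]$h2)
  }
  sire <- founder_ind(0L)
  depth <- config$n_generations - 2L

  make_carrier <- function(label) {
    cur <- sire; cur_id <- "S"
    sire_id <- dam_id <- NA_character_
    for (d in seq_len(depth)) {
      fid <- new_founder()
      dam <- founder_ind(fid)
      found <- FALSE
      for (t in seq_len(config$retry_budget)) {
        ch <- child_of(cur, dam)
        if (carrier_copies(ch) >= 1L) { found <- TRUE; break }
      }
      if (!found) {
        stop(sprintf(
          "could not breed a carrier descendant within the retry budget of %d attempts",
          config$retry_budget))
      }
      sire_id <- cur_id; dam_id <- sprintf("f%03d", fid)
      cur <- ch; cur_id <- sprintf("%s_g%d", label, d)
    }
    list(ind = cur, sire_id = sire_id, dam_id = dam_id)
  }

  n_mat <- config$n_obligate_carriers %/% 2L
  if (config$n_affected > n_mat) {
    stop(sprintf(
      paste0("config demands %d affected offspring but only %d carrier matings ",
             "are available within the retry budget of %d attempts"),
      config$n_affected, n_mat, config$retry_budget))
  }
  carriers <- lapply(seq_len(config$n_obligate_carriers), function(i) {
    make_carrier(sprintf("car_%02d", i))
  })
  car_ids <- sprintf("car_%02d", seq_len(config$n_obligate_carriers))

  affected <- vector("list", n_mat)
  for (k in seq_len(n_mat)) {
    pa <- carriers[[2L * k - 1L]]$ind
    ma <- carriers[[2L * k]]$ind
    found <- FALSE
    for (t in seq_len(config$retry_budget)) {
      ch <- child_of(pa, ma)
      if (carrier_copies(ch) == 2L) { found <- TRUE; break }
    }
    if (!found) {
      stop(sprintf(
        "could not produce an affected offspring within the retry budget of %d attempts",
        config$retry_budget))
    }
    affected[[k]] <- ch
  }

  unrelated_child <- function() {
    child_of(founder_ind(new_founder()), founder_ind(new_founder()))
  }
  controls <- replicate(config$n_controls, unrelated_child(), simplify = FALSE)
  panel <- replicate(config$n_panel_healthy, unrelated_child(), simplify = FALSE)

  # -- assemble samples ------------------------------------------------------
  aff_ids <- sprintf("aff_%d", seq_len(config$n_affected))
  ctl_ids <- sprintf("ctl_%02d", seq_len(config$n_controls))
  pan_ids <- sprintf("pan_%03d", seq_len(config$n_panel_healthy))
  ids <- c(aff_ids, car_ids, ctl_ids, pan_ids)
  inds <- c(affected[seq_len(config$n_affected)],
            lapply(carriers, `[[`, "ind"), controls, panel)
  names(inds) <- ids
  status <- c(rep("affected", config$n_affected),
              rep("obligate_carrier", config$n_obligate_carriers),
              rep("control", config$n_controls),
              rep("panel_healthy", config$n_panel_healthy))
  sire_id <- c(car_ids[2L * seq_len(config$n_affected) - 1L],
               vapply(carriers, `[[`, character(1), "sire_id"),
               rep(NA_character_, config$n_controls + config$n_panel_healthy))
  dam_id <- c(car_ids[2L * seq_len(config$n_affected)],
              vapply(carriers, `[[`, character(1), "dam_id"),
              rep(NA_character_, config$n_controls + config$n_panel_healthy))
  samples <- sample_table(ids, status, sire_id, dam_id)

  # -- haplotype alleles -----------------------------------------------------
  n <- length(ids)
  alleles <- matrix(0L, nrow = 2L * n, ncol = tot)
  offset <- setNames((seq_along(chroms) - 1L) * m, chroms)
  hap_alleles <- function(segs, ch) {
    v <- integer(m)
    for (i in seq_len(nrow(segs))) {
      idx <- which(pos[[ch]] >= segs[i, "start"] & pos[[ch]] <= segs[i, "end"])
      if (length(idx)) v[idx] <- fall[[ch]][segs[i, "hap"], idx]
    }
    v
  }
  for (s in seq_len(n)) {
    for (ch in chroms) {
      cols <- offset[[ch]] + seq_len(m)
      alleles[2L * s - 1L, cols] <- hap_alleles(inds[[s]][[ch]]$h1, ch)
      alleles[2L * s, cols] <- hap_alleles(inds[[s]][[ch]]$h2, ch)
    }
  }
  hap <- haplotype_matrix(alleles, ids, map)

  copy_count <- vapply(inds, carrier_copies, integer(1))
  region_origins <- lapply(inds, function(ind) list(
    h1 = clip_segs(ind[[cc]]$h1, r1, r2),
    h2 = clip_segs(ind[[cc]]$h2, r1, r2)
  ))

  # -- genotype matrix with missingness --------------------------------------
  geno <- haplotypes_to_dosage(hap)
  set.seed(sub_seed(config$seed, "missingness"))
  if (config$genotyping_missing_rate > 0) {
    d <- geno$dosage
    d[runif(length(d)) < config$genotyping_missing_rate] <- NA_integer_
    geno <- genotype_matrix(d, map, ids)
  }

  # -- causal variant placement ----------------------------------------------
  set.seed(sub_seed(config$seed, "causal"))
  causal_pos <- floor(runif(1, r1, r2 + 1))
  truth <- structure(list(
    causal_variant_id = sprintf("var_%s_%d", cc, causal_pos),
    causal_pos_bp = causal_pos,
    carrier_chrom = cc,
    carrier_region_bp = c(r1, r2),
    carrier_haplotype = carrier_string,
    copy_count = copy_count,
    region_snp_count = length(region_cols),
    region_snp_idx = offset[[cc]] + region_cols,
    region_origins = region_origins,
    n_founder_haps = nh,
    founder_snp_alleles = fall
  ), class = "sim_truth")

  structure(list(haplotypes = hap, genotypes = geno, map = map,
                 samples = samples, truth = truth),
            class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  tab <- table(x$samples$status)
  cat("sim_population:", length(x$haplotypes$sample_ids), "samples x",
      nrow(x$map), "SNPs\n  ")
  cat(paste(names(tab), tab, sep = " = ", collapse = ", "), "\n")
  cat("  carrier region: chr", x$truth$carrier_chrom, ":",
      x$truth$carrier_region_bp[1], "-", x$truth$carrier_region_bp[2],
      " (", x$truth$region_snp_count, " SNPs)\n", sep = "")
  invisible(x)
}

#' Simulate sequence-level variants in the carrier region
#'
#' Places `n_region_variants` biallelic variants in the carrier region.
#' Exactly one — the causal variant, at the position recorded in the truth
#' and labelled `stop_gained` — is carried by the carrier founder haplotype
#' and by no other founder haplotype, so it is in complete linkage
#' disequilibrium with the disease haplotype. All other variants receive
#' random founder-haplotype assignments and descend through the recorded
#' segment mosaics, so every genotype is phase-consistent with the SNP
#' haplotypes. Each variant carries a consequence-class label drawn from
#' \{stop_gained, splice_site, missense, synonymous, intergenic\}.
#'
#' @param config the [sim_config()] used for the population.
#' @param truth the `sim_truth` from [simulate_population()].
#' @param samples the [sample_table()] from the same run.
#' @param vcf_path optional path; when given, the variants are also written
#'   as a VCF via [write_region_vcf()].
#' @return a [variant_table()] over all samples.
#' @export
simulate_region_variants <- function(config, truth, samples, vcf_path = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  if (truth$region_snp_count == 0L) {
    stop("carrier region contains no SNP support")
  }
  set.seed(sub_seed(config$seed, "variants"))
  r <- truth$carrier_region_bp
  cc <- truth$carrier_chrom
  nv <- config$n_region_variants
  nh <- truth$n_founder_haps

  if (nv > 1L) {
    bg_pos <- sample.int(r[2] - r[1] + 1L, nv - 1L) + r[1] - 1L
    while (any(bg_pos == truth$causal_pos_bp)) {
      k <- bg_pos == truth$causal_pos_bp
      bg_pos[k] <- sample.int(r[2] - r[1] + 1L, sum(k)) + r[1] - 1L
    }
  } else bg_pos <- numeric(0)
  vpos <- sort(c(truth$causal_pos_bp, bg_pos))
  causal_idx <- match(truth$causal_pos_bp, vpos)

  fvar <- matrix(0L, nh, nv)
  bfreq <- runif(nv, 0.05, 0.5)
  for (j in seq_len(nv)) fvar[, j] <- rbinom(nh, 1L, bfreq[j])
  fvar[, causal_idx] <- 0L
  fvar[1L, causal_idx] <- 1L  # only the carrier founder haplotype

  ids <- samples$sample_id
  geno <- matrix(0L, length(ids), nv, dimnames = list(ids, NULL))
  for (s in ids) {
    for (h in c("h1", "h2")) {
      segs <- truth$region_origins[[s]][[h]]
      seg_i <- findInterval(vpos, segs[, "start"])
      hap_ids <- segs[seg_i, "hap"]
      geno[s, ] <- geno[s, ] + fvar[cbind(hap_ids, seq_len(nv))]
    }
  }

  alv <- vapply(seq_len(nv), function(i) sample(c("A", "C", "G", "T"), 2L),
                character(2))
  cls <- sample(c("intergenic", "synonymous", "missense",
                  "splice_site", "stop_gained"),
                nv, replace = TRUE, prob = c(0.80, 0.10, 0.07, 0.015, 0.015))
  cls[causal_idx] <- "stop_gained"
  info <- data.frame(
    variant_id = sprintf("var_%s_%d", cc, vpos),
    chrom = cc, pos_bp = vpos, ref = alv[1L, ], alt = alv[2L, ],
    csq_class = cls, stringsAsFactors = FALSE
  )
  vt <- variant_table(info, geno)
  if (!is.null(vcf_path)) write_region_vcf(vt, vcf_path)
  vt
}

#' Write a complete simulated fixture set to a directory
#'
#' Emits PED/MAP, the phased-haplotype table, the sample table TSV, the
#' region VCF and the ground truth as JSON.
#'
#' @param pop a `sim_population` from [simulate_population()].
#' @param config its [sim_config()].
#' @param dir output directory (created if absent).
#' @return the directory path, invisibly.
#' @export
write_fixture_set <- function(pop, config, dir) {
  stopifnot(inherits(pop, "sim_population"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_ped_map(pop$genotypes, file.path(dir, "genotypes"))
  write_haplotypes(pop$haplotypes, file.path(dir, "haplotypes.tsv"))
  write_sample_table(pop$samples, file.path(dir, "samples.tsv"))
  vt <- simulate_region_variants(config, pop$truth, pop$samples,
                                 vcf_path = file.path(dir, "region.vcf"))
  tr <- pop$truth
  jsonlite::write_json(list(
    causal_variant_id = tr$causal_variant_id,
    causal_pos_bp = tr$causal_pos_bp,
    carrier_chrom = tr$carrier_chrom,
    carrier_region_bp = tr$carrier_region_bp,
    carrier_haplotype = tr$carrier_haplotype,
    copy_count = as.list(tr$copy_count)
  ), file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
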