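# Runs of homozygosity, shared autozygosity, control exclusion and segment
# length reporting.

test_that("an all-homozygous chromosome yields one run spanning first to last SNP", {
  map <- mk_map(100)
  d <- rep(c(0L, 2L), 50)
  got <- find_roh(d, map)
  expect_identical(nrow(got), 1L)
  expect_identical(got$start_bp, 1000L)
  expect_identical(got$end_bp, 100000L)
  expect_identical(got$n_snps, 100L)
})

test_that("alternating het/hom genotypes yield no run at max_het 0", {
  map <- mk_map(100)
  d <- rep(c(0L, 1L), 50)
  expect_identical(nrow(find_roh(d, map)), 0L)
})

test_that("missing calls are neutral: they neither break runs nor count", {
  map <- mk_map(50)
  d <- rep(2L, 50)
  d[c(10, 11, 30)] <- NA_integer_
  got <- find_roh(d, map, min_snps = 40)
  expect_identical(nrow(got), 1L)
  expect_identical(got$n_snps, 47L)
  # but 47 homozygous SNPs fail a floor of 48
  expect_identical(nrow(find_roh(d, map, min_snps = 48)), 0L)
})

test_that("ROH equals the exhaustive interval scanner on seeded vectors", {
  for (s in 1:4) {
    set.seed(700 + s)
    m <- 500
    map <- mk_map(m)
    # long homozygous stretches with sparse hets and some missing
    d <- ifelse(runif(m) < 0.08, 1L, ifelse(runif(m) < 0.5, 0L, 2L))
    d[sample(m, 25)] <- NA_integer_
    for (mh in 0:1) {
      got <- find_roh(d, map, min_snps = 20, max_het = mh)
      ref <- oracle_roh(d, map$pos_bp, min_snps = 20, max_het = mh)
      if (is.null(ref)) {
        expect_identical(nrow(got), 0L)
      } else {
        expect_identical(cbind(start = got$start_bp, end = got$end_bp),
                         ref)
      }
    }
  }
})

test_that("two identical fully homozygous samples share one chromosome-spanning segment", {
  map <- mk_map(60)
  d <- matrix(rep(c(0L, 2L), 30), nrow = 2, ncol = 60, byrow = TRUE)
  rownames(d) <- c("a1", "a2")
  got <- shared_autozygosity(d, map)
  expect_identical(nrow(got), 1L)
  expect_identical(got$start_bp, 1000L)
  expect_identical(got$end_bp, 60000L)
  expect_identical(got$n_snps, 60L)
  expect_error(shared_autozygosity(d[1, , drop = FALSE], map), "two samples")
})

test_that("opposite homozygotes at one internal SNP split the shared segment", {
  map <- mk_map(50)
  d <- matrix(0L, 2, 50)
  d[1, 25] <- 0L; d[2, 25] <- 2L
  rownames(d) <- c("a1", "a2")
  got <- shared_autozygosity(d, map, min_snps = 10)
  expect_identical(nrow(got), 2L)
  expect_identical(got$end_idx[1], 24L)
  expect_identical(got$start_idx[2], 26L)
})

test_that("shared autozygosity equals the exhaustive scanner on seeded matrices", {
  for (s in 1:3) {
    set.seed(810 + s)
    m <- 400; k <- 3
    D <- matrix(ifelse(runif(m * k) < 0.06, 1L,
                       ifelse(runif(m * k) < 0.85, 0L, 2L)), nrow = k)
    D[sample(length(D), 30)] <- NA_integer_
    rownames(D) <- paste0("a", 1:k)
    map <- mk_map(m)
    got <- shared_autozygosity(D, map, min_snps = 15)
    ref <- oracle_shared(D, map$pos_bp, min_snps = 15)
    if (is.null(ref)) {
      expect_identical(nrow(got), 0L)
    } else {
      expect_identical(cbind(start = got$start_bp, end = got$end_bp), ref)
    }
  }
})

test_that("shared segments are contained in each member's ROH and shrink monotonically", {
  pop <- small_pop()
  aff <- pop$samples$sample_id[pop$samples$status == "affected"]
  car <- pop$samples$sample_id[pop$samples$status == "obligate_carrier"][1]
  D <- pop$genotypes$dosage[c(aff, car), , drop = FALSE]
  segs2 <- shared_autozygosity(D[1:2, ], pop$map, min_snps = 10)
  segs3 <- shared_autozygosity(D, pop$map, min_snps = 10)
  # containment in each member's ROH (same floor, since every informative
  # shared SNP is a homozygous call of the member)
  for (id in aff) {
    roh <- find_roh(pop$genotypes$dosage[id, ], pop$map, min_snps = 10)
    for (i in seq_len(nrow(segs2))) {
      hit <- roh$chrom == segs2$chrom[i] &
        roh$start_bp <= segs2$start_bp[i] & roh$end_bp >= segs2$end_bp[i]
      expect_true(any(hit))
    }
  }
  # adding a sample never lengthens a segment
  for (i in seq_len(nrow(segs3))) {
    cover <- segs2$chrom == segs3$chrom[i] &
      segs2$start_bp <= segs3$start_bp[i] & segs2$end_bp >= segs3$end_bp[i]
    expect_true(any(cover))
  }
})

test_that("the affecteds' shared segment covers the carrier region (truth check)", {
  pop <- small_pop()
  tr <- pop$truth
  aff <- pop$samples$sample_id[pop$samples$status == "affected"]
  D <- pop$genotypes$dosage[aff, , drop = FALSE]
  segs <- shared_autozygosity(D, pop$map)
  on_cc <- segs[segs$chrom == tr$carrier_chrom, ]
  hit <- on_cc$start_bp <= tr$carrier_region_bp[1] + 1e6 &
    on_cc$end_bp >= tr$carrier_region_bp[2] - 1e6
  expect_true(any(on_cc$start_bp <= tr$causal_pos_bp &
                    on_cc$end_bp >= tr$causal_pos_bp))
  expect_true(any(hit))
})

test_that("control exclusion drops matched segments, keeps the rest, and matches a direct scan", {
  map <- mk_map(60)
  cases <- matrix(2L, 2, 60, dimnames = list(c("a1", "a2"), NULL))
  segs <- shared_autozygosity(cases, map)
  expect_identical(nrow(segs), 1L)

  # a control identical to the cases removes the segment
  ctl_same <- matrix(2L, 1, 60, dimnames = list("c1", NULL))
  expect_identical(nrow(exclude_control_homozygotes(segs, ctl_same, map)), 0L)

  # a control het everywhere leaves it untouched
  ctl_het <- matrix(1L, 1, 60, dimnames = list("c2", NULL))
  expect_equal(exclude_control_homozygotes(segs, ctl_het, map), segs)

  # homozygous for the other allele does not match either
  ctl_opp <- matrix(0L, 1, 60, dimnames = list("c3", NULL))
  expect_identical(nrow(exclude_control_homozygotes(segs, ctl_opp, map)), 1L)

  # seeded fixture: survivors equal a direct per-control per-segment scan
  set.seed(99)
  pop <- small_pop()
  aff <- pop$samples$sample_id[pop$samples$status == "affected"]
  ctl <- pop$samples$sample_id[pop$samples$status == "control"]
  D <- pop$genotypes$dosage[aff, , drop = FALSE]
  C <- pop$genotypes$dosage[ctl, , drop = FALSE]
  segs <- shared_autozygosity(D, pop$map, min_snps = 10)
  got <- exclude_control_homozygotes(segs, C, pop$map)
  keep <- logical(nrow(segs))
  for (i in seq_len(nrow(segs))) {
    idx <- segs$start_idx[i]:segs$end_idx[i]
    ch <- strsplit(segs$allele_string[i], "")[[1]]
    inf <- ch != "."
    target <- ifelse(ch[inf] == pop$map$ref_allele[idx][inf], 0L, 2L)
    matched <- FALSE
    for (c in seq_len(nrow(C))) {
      v <- C[c, idx][inf]
      if (any(!is.na(v) & v == target) && all(v[!is.na(v)] == target[!is.na(v)])) {
        matched <- TRUE; break
      }
    }
    keep[i] <- !matched
  }
  expect_identical(got$start_bp, segs$start_bp[keep])
  expect_identical(got$end_bp, segs$end_bp[keep])
})

test_that("trim mode removes control-covered loci and re-extracts runs", {
  map <- mk_map(60)
  cases <- matrix(2L, 2, 60, dimnames = list(c("a1", "a2"), NULL))
  segs <- shared_autozygosity(cases, map)
  ctl <- matrix(1L, 1, 60, dimnames = list("c1", NULL))
  ctl[1, 1:25] <- 2L  # control homozygous over the left half only
  got <- exclude_control_homozygotes(segs, ctl, map, mode = "trim",
                                     min_snps = 20)
  expect_identical(nrow(got), 1L)
  expect_identical(got$start_idx, 26L)
  expect_identical(got$end_idx, 60L)
  expect_identical(got$n_snps, 35L)
})

test_that("segment lengths in Mb reproduce reported values", {
  expect_identical(segment_length_mb(40113694, 61378199), 21.26)
  expect_identical(segment_length_mb(5, 5), 0)
  expect_identical(segment_length_mb(1000000, 9720000), 8.72)
  expect_error(segment_length_mb(10, 5), "end")
})

test_that("cross-group shared haplotypes behave at the degenerate ends", {
  map <- mk_map(40)
  a <- matrix(2L, 1, 40, dimnames = list("vwd1", NULL))
  b <- matrix(0L, 1, 40, dimnames = list("rhv1", NULL))
  expect_identical(nrow(cross_group_shared_haplotype(a, b, map, 10)), 0L)

  # a single sample shared by both groups reduces to its own ROH set
  d <- matrix(rep(c(2L, 2L, 2L, 1L), 10), 1, 40,
              dimnames = list("x", NULL))
  got <- cross_group_shared_haplotype(d, d, map, min_snps = 3)
  roh <- find_roh(d[1, ], map, min_snps = 3, max_het = 0)
  expect_identical(got$start_bp, roh$start_bp)
  expect_identical(got$end_bp, roh$end_bp)
})

test_that("two groups seeded with the same founder haplotype share a segment containing the causal position", {
  cfg_a <- small_config(seed = 31)
  cfg_b <- small_config(seed = 31)  # same founder stream = same haplotype
  pop_a <- simulate_population(cfg_a)
  pop_b <- simulate_population(sim_config(
    n_chromosomes = 2L, snps_per_chromosome = 250L,
    chromosome_length_bp = 25e6, n_founders = 150L,
    carrier_haplotype_chromosome = "2", carrier_region_bp = c(8e6, 16e6),
    n_panel_healthy = 40L, n_region_variants = 120L, seed = 31,
    n_controls = 5L))
  # identical founder sub-stream -> identical carrier haplotype "breeds"
  expect_identical(pop_a$truth$carrier_haplotype, pop_b$truth$carrier_haplotype)
  aff_a <- pop_a$samples$sample_id[pop_a$samples$status == "affected"]
  aff_b <- pop_b$samples$sample_id[pop_b$samples$status == "affected"]
  A <- pop_a$genotypes$dosage[aff_a, , drop = FALSE]
  rownames(A) <- paste0("a_", rownames(A))
  B <- pop_b$genotypes$dosage[aff_b, , drop = FALSE]
  rownames(B) <- paste0("b_", rownames(B))
  got <- cross_group_shared_haplotype(A, B, pop_a$map, min_snps = 10)
  pos <- pop_a$truth$causal_pos_bp
  hit <- got$chrom == pop_a$truth$carrier_chrom &
    got$start_bp <= pos & got$end_bp >= pos
  expect_true(any(hit))
})
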