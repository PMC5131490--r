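# PED/MAP and VCF readers/writers and the core container invariants.

test_that("dosage collapses against the declared alt allele, with PLINK missing convention", {
  dir <- withr::local_tempdir()
  writeLines(c("1 s1 0 100 C A",
               "1 s2 0 200 T G"), file.path(dir, "x.map"))
  writeLines(c("ind1 ind1 0 0 0 -9 A A G G",
               "ind2 ind2 0 0 0 -9 A C 0 0",
               "ind3 ind3 0 0 0 -9 C C G T"),
             file.path(dir, "x.ped"))
  got <- read_ped_map(file.path(dir, "x.ped"), file.path(dir, "x.map"))
  expect_identical(got$geno$dosage["ind1", ], c(s1 = 2L, s2 = 2L))
  expect_identical(got$geno$dosage["ind2", ], c(s1 = 1L, s2 = NA_integer_))
  expect_identical(got$geno$dosage["ind3", ], c(s1 = 0L, s2 = 1L))
  expect_identical(got$map$alt_allele, c("A", "G"))
})

test_that("PED/MAP round-trips bit-identically and at value level", {
  map <- marker_map(chrom = c("1", "1", "2", "2"),
                    pos_bp = c(100L, 250L, 90L, 400L),
                    snp_id = paste0("rs", 1:4),
                    ref_allele = c("A", "C", "G", "T"),
                    alt_allele = c("G", "T", "A", "C"))
  d <- matrix(c(0L, 1L, 2L, NA,
                2L, 2L, 0L, 1L,
                NA, 0L, 1L, 2L), nrow = 3, byrow = TRUE)
  rownames(d) <- c("a", "b", "c")
  g <- genotype_matrix(d, map)
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "one")
  write_ped_map(g, p1)
  back <- read_ped_map(paste0(p1, ".ped"), paste0(p1, ".map"))
  expect_identical(back$geno$dosage, g$dosage)
  expect_identical(as.data.frame(back$map), as.data.frame(map))
  # writing what was read reproduces the files byte for byte
  p2 <- file.path(dir, "two")
  write_ped_map(back$geno, p2)
  expect_identical(readLines(paste0(p2, ".ped")), readLines(paste0(p1, ".ped")))
  expect_identical(readLines(paste0(p2, ".map")), readLines(paste0(p1, ".map")))
})

test_that("an empty genotype matrix writes a valid empty PED with a full MAP", {
  map <- mk_map(4)
  g <- genotype_matrix(matrix(integer(0), nrow = 0, ncol = 4), map)
  dir <- withr::local_tempdir()
  write_ped_map(g, file.path(dir, "empty"))
  expect_length(readLines(file.path(dir, "empty.ped")), 0)
  back <- read_ped_map(file.path(dir, "empty.ped"), file.path(dir, "empty.map"))
  expect_identical(nrow(back$geno$dosage), 0L)
  expect_identical(back$map$snp_id, map$snp_id)
})

test_that("PED rows with the wrong field count are rejected naming the line", {
  dir <- withr::local_tempdir()
  writeLines("1 s1 0 100 A G", file.path(dir, "x.map"))
  writeLines(c("i1 i1 0 0 0 -9 A A",
               "i2 i2 0 0 0 -9 A"), file.path(dir, "x.ped"))
  expect_error(read_ped_map(file.path(dir, "x.ped"), file.path(dir, "x.map")),
               "PED line 2")
})

test_that("undeclared alleles in the PED are a hard error (no auto-flip)", {
  dir <- withr::local_tempdir()
  writeLines("1 s1 0 100 A G", file.path(dir, "x.map"))
  writeLines("i1 i1 0 0 0 -9 A T", file.path(dir, "x.ped"))
  expect_error(read_ped_map(file.path(dir, "x.ped"), file.path(dir, "x.map")),
               "declared alleles")
})

test_that("marker map invariants are enforced", {
  expect_error(marker_map("1", c(10L, 10L), c("a", "b"), c("A", "A"),
                          c("G", "G")),
               "strictly increasing")
  expect_error(marker_map("1", c(10L, 20L), c("a", "a"), c("A", "A"),
                          c("G", "G")), "unique")
  expect_error(marker_map("1", 10L, "a", "A", "A"), "distinct")
  expect_error(marker_map(c("1", "2", "1"), c(1L, 1L, 2L), letters[1:3],
                          rep("A", 3), rep("G", 3)), "contiguous")
})

test_that("haplotype/dosage consistency is enforced and verified", {
  map <- mk_map(3)
  a <- matrix(c(0L, 1L, 1L,
                1L, 0L, 1L), nrow = 2, byrow = TRUE)
  hap <- haplotype_matrix(a, "s1", map)
  g_ok <- genotype_matrix(matrix(c(1L, NA, 2L), 1), map, "s1")
  expect_true(check_hap_consistency(hap, g_ok))
  g_bad <- genotype_matrix(matrix(c(2L, 1L, 2L), 1), map, "s1")
  expect_error(check_hap_consistency(hap, g_bad), "do not sum")
  expect_error(haplotype_matrix(matrix(c(0L, NA, 1L, 1L, 0L, 1L), 2, byrow = TRUE),
                                "s1", map), "missing")
})

test_that("region VCF reading filters by region, maps GT states and skips multi-allelics", {
  set.seed(41)
  n_rec <- 50
  pos <- sort(sample.int(100000, n_rec))
  gts <- c("0/0", "0/1", "1/1", "./.")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CSQ_CLASS,Number=1,Type=String,Description=\"x\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "sA", "sB", "sC"), collapse = "\t")
  )
  g_truth <- matrix(sample(0:3, n_rec * 3, replace = TRUE), ncol = 3)
  for (i in seq_len(n_rec)) {
    lines <- c(lines, paste(c("22", pos[i], paste0("v", i), "A", "T", ".",
                              "PASS", "CSQ_CLASS=missense", "GT",
                              gts[g_truth[i, ] + 1]), collapse = "\t"))
  }
  # one multi-allelic record inside the region
  lines <- c(lines, paste(c("22", 500, "multi", "A", "T,C", ".", "PASS",
                            ".", "GT", "0/0", "0/1", "0/2"), collapse = "\t"))
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "region.vcf")
  writeLines(lines, vcf)

  region <- list(chrom = "22", start = 1, end = 50000)
  expected_n <- sum(pos <= 50000)
  expect_warning(vt <- read_region_vcf(vcf, region), "multi-allelic")
  expect_identical(n_variants(vt), expected_n)
  expect_identical(attr(vt, "n_multiallelic_skipped"), 1L)
  keep <- which(pos <= 50000)
  expected_states <- t(g_truth[keep, , drop = FALSE])
  expected_states[expected_states == 3L] <- NA_integer_
  rownames(expected_states) <- c("sA", "sB", "sC")
  colnames(expected_states) <- paste0("v", keep)
  expect_identical(vt$geno, expected_states)
  expect_identical(unique(vt$info$csq_class), "missense")
})

test_that("VCF writing round-trips genotype states through the vcfR-based reader", {
  pop <- small_pop()
  cfg <- small_config()
  vt <- simulate_region_variants(cfg, pop$truth, pop$samples)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "sim.vcf")
  write_region_vcf(vt, path)
  r <- pop$truth$carrier_region_bp
  back <- read_region_vcf(path, list(chrom = pop$truth$carrier_chrom,
                                     start = r[1], end = r[2]))
  expect_identical(back$geno, vt$geno)
  expect_identical(back$info$csq_class, vt$info$csq_class)
  expect_identical(back$info$pos_bp, vt$info$pos_bp)
})

test_that("sample table and haplotype table round-trip through TSV", {
  pop <- small_pop()
  dir <- withr::local_tempdir()
  sp <- file.path(dir, "samples.tsv")
  write_sample_table(pop$samples, sp)
  back <- read_sample_table(sp)
  expect_identical(as.data.frame(back), as.data.frame(pop$samples))

  hp <- file.path(dir, "haps.tsv")
  sub <- subset_samples(pop$haplotypes, pop$samples$sample_id[1:5])
  write_haplotypes(sub, hp)
  hback <- read_haplotypes(hp, sub$map)
  expect_identical(hback$alleles, sub$alleles)
  expect_identical(hback$sample_ids, sub$sample_ids)
})

test_that("sample table rejects unknown statuses and duplicate ids", {
  expect_error(sample_table("a", "sick"), "unknown status")
  expect_error(sample_table(c("a", "a"), c("control", "control")), "unique")
})
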