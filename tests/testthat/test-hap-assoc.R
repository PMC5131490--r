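# Sliding-window enumeration, haplotype cataloguing/dosage, the OLS test,
# and the genome-wide calibration helpers.

test_that("window enumeration drops partial trailing windows", {
  expect_identical(nrow(enumerate_windows(mk_map(20))), 1L)
  expect_identical(nrow(enumerate_windows(mk_map(19))), 0L)
  w25 <- enumerate_windows(mk_map(25))
  expect_identical(nrow(w25), 2L)
  expect_identical(w25$start_idx, c(1L, 6L))
  expect_identical(w25$end_idx, c(20L, 25L))
  expect_identical(w25$start_bp, c(1000L, 6000L))
  expect_error(enumerate_windows(mk_map(25), window_size = 1), "at least 2")

  # windows never span chromosomes
  map2 <- marker_map(chrom = rep(c("1", "2"), c(22, 23)),
                     pos_bp = c(seq_len(22), seq_len(23)) * 100L,
                     snp_id = paste0("m", 1:45),
                     ref_allele = rep("A", 45), alt_allele = rep("C", 45))
  w <- enumerate_windows(map2)
  expect_identical(nrow(w), 2L)
  expect_identical(w$chrom, c("1", "2"))
  expect_identical(w$start_idx, c(1L, 23L))
})

test_that("haplotype cataloguing counts strings and applies the strict 5% floor", {
  map <- mk_map(20)
  # 43 samples = 86 haplotypes: one haplotype class on 4 chromosomes
  # (freq 0.0465 < 0.05, excluded), the rest split 50/30/2 among three
  # other classes
  base <- list(rep(0L, 20), rep(1L, 20), rep(c(0L, 1L), 10), rep(c(1L, 0L), 10))
  counts <- c(50, 30, 2, 4)
  rows <- do.call(rbind, mapply(function(b, k) {
    matrix(rep(unlist(b), k), nrow = k, byrow = TRUE)
  }, base, counts, SIMPLIFY = FALSE))
  hap <- haplotype_matrix(rows, paste0("s", 1:43), map)
  w <- enumerate_windows(map)[1, ]
  cat0 <- catalogue_haplotypes(w, hap, min_freq = 0)
  expect_identical(sum(cat0$count), 86L)
  cat5 <- catalogue_haplotypes(w, hap)
  expect_identical(nrow(cat5), 2L)  # 4/86 and 2/86 both excluded
  expect_equal(sort(cat5$freq, decreasing = TRUE), c(50, 30) / 86)

  # single shared haplotype -> one entry at frequency 1
  hap1 <- haplotype_matrix(matrix(0L, 10, 20), paste0("t", 1:5), map)
  c1 <- catalogue_haplotypes(w, hap1)
  expect_identical(nrow(c1), 1L)
  expect_identical(c1$freq, 1)
})

test_that("three haplotype classes at 0.5/0.3/0.2 are counted exactly", {
  map <- mk_map(20)
  base <- list(rep(0L, 20), rep(1L, 20), rep(c(0L, 1L), 10))
  counts <- c(10, 6, 4)
  rows <- do.call(rbind, mapply(function(b, k) {
    matrix(rep(unlist(b), k), nrow = k, byrow = TRUE)
  }, base, counts, SIMPLIFY = FALSE))
  hap <- haplotype_matrix(rows, paste0("s", 1:10), map)
  got <- catalogue_haplotypes(enumerate_windows(map)[1, ], hap)
  expect_identical(nrow(got), 3L)
  expect_equal(got$freq, c(0.5, 0.3, 0.2))
})

test_that("haplotype dosage counts exact string matches and partitions to 2", {
  map <- mk_map(4)
  hap <- haplotype_matrix(matrix(c(0L, 0L, 1L, 1L,
                                   0L, 0L, 1L, 1L,
                                   1L, 1L, 0L, 0L,
                                   0L, 0L, 1L, 1L), 4, byrow = TRUE),
                          c("x", "y"), map)
  expect_identical(haplotype_dosage(hap_pair(hap, "x"), "0011"), 2L)
  expect_identical(haplotype_dosage(hap_pair(hap, "x"), "1100"), 0L)
  expect_identical(haplotype_dosage(hap_pair(hap, "y"), "0011"), 1L)

  # partition identity on simulated data: with min_freq = 0 the dosages of
  # all catalogued haplotypes sum to 2 for every sample
  pop <- small_pop()
  hap_s <- subset_samples(pop$haplotypes, pop$samples$sample_id[1:20])
  w <- enumerate_windows(hap_s$map)
  set.seed(8)
  for (wi in sample(nrow(w), 5)) {
    cat0 <- catalogue_haplotypes(w[wi, ], hap_s, min_freq = 0)
    tot <- rep(0L, 20)
    for (h in cat0$hap_string) {
      for (s in seq_len(20)) {
        pair <- hap_pair(hap_s, hap_s$sample_ids[s])[, w$start_idx[wi]:w$end_idx[wi]]
        tot[s] <- tot[s] + haplotype_dosage(pair, h)
      }
    }
    expect_true(all(tot == 2L))
  }
})

test_that("the OLS haplotype test matches the normal-equations oracle to 1e-8", {
  set.seed(202)
  n <- 43
  status <- rep(c(2, 1, 0), c(2, 14, 27))
  pcs_mat <- matrix(rnorm(n * 10), n)
  dimnames(pcs_mat) <- list(paste0("s", 1:n), paste0("PC", 1:10))
  pcs <- structure(list(scores = pcs_mat, eigenvalues = rep(1, n), k = 10L),
                   class = "pc_set")
  for (i in 1:20) {
    ht <- rbinom(n, 2, 0.2)
    if (var(ht) == 0) next
    y <- status + rnorm(n, 0, 0.3)
    got <- test_haplotype(y, pcs, ht)
    ref <- oracle_ols(y, pcs_mat, ht)
    expect_equal(got$beta, ref$beta, tolerance = 1e-8)
    expect_equal(got$se, ref$se, tolerance = 1e-8)
    expect_equal(got$p, ref$p, tolerance = 1e-8)
    expect_identical(got$df, 43L - 10L - 2L)
  }
})

test_that("a dosage identical to the response gives beta 1 and the floor p-value", {
  y <- rep(c(2, 1, 0), c(2, 5, 10))
  got <- test_haplotype(y, NULL, y)
  expect_equal(got$beta, 1, tolerance = 1e-12)
  # numerically perfect fit: p collapses to (or near) the double floor
  expect_gt(got$p, 0)
  expect_lt(got$p, 1e-200)
  # constant dosage is untestable, not an error
  expect_true(test_haplotype(y, NULL, rep(1, length(y)))$untestable)
})

test_that("p-values are calibrated under the null (KS vs uniform)", {
  set.seed(42)
  n <- 40
  ht <- rbinom(n, 2, 0.3)
  pv <- replicate(1000, test_haplotype(rnorm(n), NULL, ht)$p)
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
})

test_that("genomic inflation behaves at the null median, under uniform p, and under scaling", {
  expect_equal(genomic_inflation(rep(0.5, 7)), 1, tolerance = 1e-12)
  set.seed(13)
  p <- runif(1e5)
  expect_equal(genomic_inflation(p), 1, tolerance = 0.02)
  chi2 <- qchisq(p, 1, lower.tail = FALSE) * 2
  p2 <- pchisq(chi2, 1, lower.tail = FALSE)
  expect_equal(genomic_inflation(p2), 2, tolerance = 0.04)
  expect_error(genomic_inflation(numeric(0)), "at least one")
})

test_that("the Bonferroni threshold reproduces the genome-wide cutoff", {
  expect_identical(signif(bonferroni_threshold(57837), 2), 8.6e-7)
  expect_identical(bonferroni_threshold(1), 0.05)
  expect_identical(bonferroni_threshold(100), 5e-4)
})

test_that("the scan counts tests per window and rejects misaligned PCs", {
  pop <- small_pop()
  ids <- pop$samples$sample_id[pop$samples$status != "panel_healthy"]
  hap <- subset_samples(pop$haplotypes, ids)
  # single-window input: n_tests equals the catalogue size
  w1 <- subset_loci(hap, 1:20)
  scan1 <- run_association_scan(w1, pop$samples, NULL)
  cat1 <- catalogue_haplotypes(enumerate_windows(w1$map)[1, ], w1)
  expect_identical(scan1$summary$n_tests, nrow(cat1))
  expect_identical(scan1$summary$n_windows, 1L)

  g <- build_grm(subset_samples(pop$genotypes, ids))
  pcs <- top_principal_components(g, 10)
  bad <- pcs
  rownames(bad$scores) <- rev(rownames(bad$scores))
  expect_error(run_association_scan(hap, pop$samples, bad), "misaligned")
})

test_that("response coding follows the sample table and excludes the panel", {
  s <- sample_table(c("a", "c", "k", "p"),
                    c("affected", "control", "obligate_carrier",
                      "panel_healthy"))
  y <- response_vector(s)
  expect_identical(y, c(a = 2, c = 0, k = 1))
})
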