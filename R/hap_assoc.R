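# Sliding-window haplotype association scan with carrier-informed response
# coding, PC stratification correction and genome-wide calibration
# (genomic-control inflation factor, Bonferroni threshold, QQ data).
#
# Model per catalogued haplotype (one-vs-rest):
#   y = mu + sum_j a_j PC_j + b * HT + e
# where y is 2/1/0 for affected / obligate carrier / control, HT is the
# 0/1/2 haplotype dosage, and e is a normal residual. Ordinary least
# squares; the p-value for b uses a t reference with n - k - 2 degrees of
# freedom (intercept + k PCs + haplotype).

#' Enumerate sliding windows over a marker map
#'
#' Per chromosome, windows start at the 1st, `1 + step`-th, ... SNP while a
#' full `window_size`-SNP window fits; partial trailing windows are
#' dropped, so chromosome ends have reduced coverage.
#'
#' @param map a [marker_map()].
#' @param window_size SNPs per window (default 20; must be at least 2).
#' @param step SNPs between successive window starts (default 5).
#' @return a data frame of class `window_set` with columns `window_id`,
#'   `chrom`, `start_idx`, `end_idx` (global map row indices), `start_bp`,
#'   `end_bp`.
#' @export
enumerate_windows <- function(map, window_size = 20L, step = 5L) {
  stopifnot(inherits(map, "marker_map"), nrow(map) > 0L)
  window_size <- as.integer(window_size); step <- as.integer(step)
  if (window_size < 2L) stop("window_size must be at least 2")
  if (step < 1L) stop("step must be positive")
  blocks <- rle(map$chrom)
  offs <- cumsum(c(0L, blocks$lengths))
  rows <- list()
  for (b in seq_along(blocks$values)) {
    nc <- blocks$lengths[b]
    if (nc < window_size) next
    starts <- seq(1L, nc - window_size + 1L, by = step)
    rows[[b]] <- data.frame(
      chrom = blocks$values[b],
      start_idx = offs[b] + starts,
      end_idx = offs[b] + starts + window_size - 1L,
      stringsAsFactors = FALSE
    )
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start_idx = integer(0),
               end_idx = integer(0))
  df$start_bp <- map$pos_bp[df$start_idx]
  df$end_bp <- map$pos_bp[df$end_idx]
  df <- df[, c("chrom", "start_idx", "end_idx", "start_bp", "end_bp")]
  df <- cbind(window_id = sprintf("w%05d", seq_len(nrow(df))), df,
              stringsAsFactors = FALSE)
  class(df) <- c("window_set", "data.frame")
  df
}

window_strings <- function(hap, start_idx, end_idx) {
  sub <- hap$alleles[, start_idx:end_idx, drop = FALSE]
  do.call(paste0, as.data.frame(sub))
}

#' Catalogue the haplotype alleles of a window
#'
#' Distinct allele strings over the window's loci with population frequency
#' strictly above `min_freq` among the `2n` sample haplotypes.
#'
#' @param window one row of an [enumerate_windows()] result (or any list
#'   with `start_idx`/`end_idx`).
#' @param hap a [haplotype_matrix()].
#' @param min_freq frequency floor (exclusive), default 0.05.
#' @return data frame with columns `hap_string`, `count`, `freq`, ordered
#'   by decreasing frequency. May be empty.
#' @export
catalogue_haplotypes <- function(window, hap, min_freq = 0.05) {
  stopifnot(inherits(hap, "haplotype_matrix"))
  s <- window_strings(hap, window$start_idx, window$end_idx)
  tab <- sort(table(s), decreasing = TRUE)
  freq <- as.numeric(tab) / length(s)
  keep <- freq > min_freq
  data.frame(hap_string = names(tab)[keep], count = as.integer(tab)[keep],
             freq = freq[keep], stringsAsFactors = FALSE)
}

#' Haplotype dosage of one sample
#'
#' Number of the sample's two phased haplotypes exactly matching the
#' catalogued allele string.
#'
#' @param pair 2-row 0/1 allele matrix over the window's loci (see
#'   [hap_pair()]) or a length-2 character vector of allele strings.
#' @param hap_string the catalogued allele string.
#' @return 0, 1 or 2.
#' @export
haplotype_dosage <- function(pair, hap_string) {
  s <- if (is.character(pair)) pair else apply(pair, 1L, paste0, collapse = "")
  stopifnot(length(s) == 2L)
  sum(s == hap_string)
}

#' Test one haplotype dosage vector against the carrier-informed response
#'
#' Ordinary least squares of `y` on an intercept, the `k` principal
#' components and the haplotype dosage; two-sided p-value for the haplotype
#' coefficient from the t-distribution with `n - k - 2` degrees of freedom.
#' A constant (or collinear) dosage vector is flagged untestable rather
#' than raising an error. A perfect fit would give p = 0; p is clamped to
#' the smallest positive double so it stays in (0, 1].
#'
#' @param y numeric response (2/1/0 coding; see [response_vector()]).
#' @param pcs a [top_principal_components()] result, or `NULL` for no
#'   covariates.
#' @param dosages numeric haplotype dosage vector aligned with `y`.
#' @return a list with `beta`, `se`, `intercept`, `covariate_effects`,
#'   `df`, `p` and `untestable`.
#' @export
test_haplotype <- function(y, pcs, dosages) {
  n <- length(y)
  stopifnot(length(dosages) == n)
  S <- if (is.null(pcs)) matrix(0, n, 0) else pcs$scores
  stopifnot(nrow(S) == n)
  k <- ncol(S)
  if (n <= k + 2L) stop("need more samples than model parameters")
  untest <- list(beta = NA_real_, se = NA_real_, intercept = NA_real_,
                 covariate_effects = rep(NA_real_, k), df = n - k - 2L,
                 p = NA_real_, untestable = TRUE)
  if (var(dosages) == 0) return(untest)
  X <- cbind(1, S, dosages)
  qx <- qr(X)
  if (qx$rank < ncol(X)) return(untest)
  coefs <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  df <- n - ncol(X)
  sigma2 <- sum(res^2) / df
  R <- qr.R(qx)
  XtXinv <- chol2inv(R)
  se <- sqrt(sigma2 * XtXinv[ncol(X), ncol(X)])
  b <- coefs[length(coefs)]
  p <- if (se == 0) 0 else 2 * pt(-abs(b / se), df)
  list(beta = unname(b), se = se, intercept = unname(coefs[1]),
       covariate_effects = unname(coefs[seq_len(k) + 1L]),
       df = df, p = max(p, .Machine$double.xmin), untestable = FALSE)
}

#' Genomic-control inflation factor
#'
#' Median of the 1-df chi-square statistics implied by the p-values,
#' divided by the null chi-square median (0.4549364...). Values near 1
#' indicate adequate confounding control.
#'
#' @param p_values p-values in (0, 1].
#' @return lambda.
#' @export
genomic_inflation <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  if (length(p) == 0L) stop("at least one p-value required")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  chi <- qchisq(p, df = 1, lower.tail = FALSE)
  median(chi) / qchisq(0.5, df = 1)
}

#' Bonferroni family-wise significance threshold
#'
#' @param n_tests number of tests performed.
#' @param alpha family-wise error rate, default 0.05.
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  stopifnot(n_tests >= 1)
  alpha / n_tests
}

#' Carrier-informed response coding
#'
#' Codes disease status as a quantitative response: 2 for affected, 1 for
#' obligate carriers, 0 for controls. Panel-healthy samples take no part in
#' the scan and are rejected here.
#'
#' @param samples a [sample_table()].
#' @return named numeric vector over the scan samples, in table order.
#' @export
response_vector <- function(samples) {
  stopifnot(inherits(samples, "sample_table"))
  sc <- samples[samples$status != "panel_healthy", ]
  code <- c(affected = 2, obligate_carrier = 1, control = 0)
  setNames(unname(code[sc$status]), sc$sample_id)
}

#' Run the genome-wide sliding-window haplotype association scan
#'
#' Catalogues the haplotypes of every window, computes each sample's
#' haplotype dosage, and tests every catalogued haplotype one-vs-rest with
#' [test_haplotype()]. Scan samples are those with status affected /
#' obligate_carrier / control, in sample-table order; the haplotype matrix
#' and PC scores must cover them (PC score rows must match exactly — a
#' misalignment is an error before any testing).
#'
#' @param hap a [haplotype_matrix()] (may contain extra samples).
#' @param samples a [sample_table()].
#' @param pcs a [top_principal_components()] result over the scan samples,
#'   or `NULL` to fit without covariates.
#' @param window_size,step,min_freq see [enumerate_windows()] and
#'   [catalogue_haplotypes()].
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @return an object of class `hap_scan`: `results` (one row per tested
#'   haplotype, sorted by p-value), `qq` (expected vs observed -log10 p),
#'   and a `summary` list with `n_windows`, `n_tests`, `lambda`,
#'   `bonferroni`, `n_significant` and the top hit.
#' @export
run_association_scan <- function(hap, samples, pcs,
                                 window_size = 20L, step = 5L,
                                 min_freq = 0.05, alpha = 0.05) {
  stopifnot(inherits(hap, "haplotype_matrix"),
            inherits(samples, "sample_table"))
  y <- response_vector(samples)
  ids <- names(y)
  if (!all(ids %in% hap$sample_ids)) {
    stop("haplotype matrix is missing scan samples: ",
         paste(setdiff(ids, hap$sample_ids), collapse = ", "))
  }
  hap <- subset_samples(hap, ids)
  if (!is.null(pcs)) {
    if (!identical(rownames(pcs$scores), ids)) {
      stop("PC score rows are misaligned with the scan samples")
    }
  }
  n <- length(ids)
  windows <- enumerate_windows(hap$map, window_size, step)
  res <- vector("list", nrow(windows))
  for (w in seq_len(nrow(windows))) {
    s <- window_strings(hap, windows$start_idx[w], windows$end_idx[w])
    cat_w <- catalogue_haplotypes(windows[w, ], hap, min_freq)
    if (nrow(cat_w) == 0L) next
    h1 <- s[seq(1L, by = 2L, length.out = n)]
    h2 <- s[seq(2L, by = 2L, length.out = n)]
    rows <- vector("list", nrow(cat_w))
    for (i in seq_len(nrow(cat_w))) {
      ht <- (h1 == cat_w$hap_string[i]) + (h2 == cat_w$hap_string[i])
      fit <- test_haplotype(y, pcs, ht)
      rows[[i]] <- data.frame(
        window_id = windows$window_id[w], chrom = windows$chrom[w],
        start_bp = windows$start_bp[w], end_bp = windows$end_bp[w],
        hap_string = cat_w$hap_string[i], freq = cat_w$freq[i],
        beta = fit$beta, se = fit$se, p = fit$p,
        untestable = fit$untestable, stringsAsFactors = FALSE
      )
    }
    res[[w]] <- do.call(rbind, rows)
  }
  results <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(results)) stop("no haplotype passed the frequency floor in any window")
  results <- results[order(results$p, na.last = TRUE), ]
  rownames(results) <- NULL

  pv <- results$p[!is.na(results$p)]
  n_tests <- nrow(results)
  lambda <- genomic_inflation(pv)
  thr <- bonferroni_threshold(n_tests, alpha)
  qq <- data.frame(
    expected = -log10((seq_along(pv) - 0.5) / length(pv)),
    observed = -log10(sort(pv))
  )
  structure(list(
    results = results, qq = qq,
    summary = list(
      n_samples = n, n_windows = nrow(windows), n_tests = n_tests,
      n_untestable = sum(results$untestable), lambda = lambda,
      alpha = alpha, bonferroni = thr,
      n_significant = sum(pv < thr),
      top = results[1L, , drop = FALSE]
    ),
    params = list(window_size = window_size, step = step,
                  min_freq = min_freq, k = if (is.null(pcs)) 0L else pcs$k)
  ), class = "hap_scan")
}

#' @export
print.hap_scan <- function(x, ...) {
  s <- x$summary
  cat("Haplotype association scan\n")
  cat(sprintf("  %d samples, %d windows, %d haplotype tests (%d untestable)\n",
              s$n_samples, s$n_windows, s$n_tests, s$n_untestable))
  cat(sprintf("  inflation factor lambda = %.2f\n", s$lambda))
  cat(sprintf("  Bonferroni threshold (alpha = %g): %.3g\n", s$alpha,
              s$bonferroni))
  cat(sprintf("  significant haplotypes: %d\n", s$n_significant))
  t <- s$top
  cat(sprintf("  top hit: %s %s:%d-%d  freq %.3f  beta %.3f  p %.3g\n",
              t$window_id, t$chrom, t$start_bp, t$end_bp, t$freq, t$beta,
              t$p))
  invisible(x)
}

#' @export
summary.hap_scan <- function(object, ...) object$summary

#' Manhattan and QQ plot of a haplotype scan
#'
#' @param x a `hap_scan`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.hap_scan <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  r <- x$results[!is.na(x$results$p), ]
  chroms <- unique(r$chrom)
  span <- tapply(r$end_bp, r$chrom, max)[chroms]
  off <- setNames(cumsum(c(0, as.numeric(span)))[seq_along(chroms)], chroms)
  xpos <- off[r$chrom] + (r$start_bp + r$end_bp) / 2
  col <- (match(r$chrom, chroms) %% 2L) + 1L
  plot(xpos, -log10(r$p), pch = 20, cex = 0.5, col = c("grey40", "steelblue")[col],
       xlab = "genome position", ylab = expression(-log[10](p)),
       main = "haplotype scan", xaxt = "n", ...)
  axis(1, at = off + as.numeric(span) / 2, labels = chroms)
  abline(h = -log10(x$summary$bonferroni), col = "red", lty = 2)
  plot(x$qq$expected, x$qq$observed, pch = 20, cex = 0.5,
       xlab = expression(expected ~ -log[10](p)),
       ylab = expression(observed ~ -log[10](p)), main = "QQ")
  abline(0, 1, col = "red")
  invisible(x)
}

#' Write scan results and QQ table as TSV
#' @param scan a `hap_scan`.
#' @param results_path,qq_path output paths (`NULL` to skip either).
#' @export
write_scan <- function(scan, results_path = NULL, qq_path = NULL) {
  stopifnot(inherits(scan, "hap_scan"))
  if (!is.null(results_path)) {
    utils::write.table(scan$results, results_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(qq_path)) {
    utils::write.table(scan$qq, qq_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(scan)
}
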