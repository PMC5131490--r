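# Runs of homozygosity, shared autozygosity across affected samples, and
# control-based exclusion — the homozygosity-mapping stage.
#
# ROH are defined on array-density genotypes by SNP count, not bp length.
# Missing calls are neutral: they neither break a run nor count toward
# min_snps. Segment bp bounds are the positions of the first and last
# homozygous SNP of the run (1-based inclusive), never midpoints to
# flanking SNPs.

# Maximal intervals (in index space of `st`, a 0/1/2 status vector with 1 =
# het) containing at most max_het hets. Returns a 2-column matrix of
# inclusive index bounds; intervals may overlap when max_het > 0.
max_het_intervals <- function(is_het, max_het) {
  t <- sum(is_het)
  n <- length(is_het)
  if (t <= max_het) return(matrix(c(1L, n), ncol = 2))
  hets <- which(is_het)
  k <- max_het
  lo <- c(1L, hets + 1L)[seq_len(t - k + 1L)]
  hi <- c(hets - 1L, n)[seq_len(t - k + 1L) + k]
  cbind(lo, hi)[lo <= hi, , drop = FALSE]
}

roh_one_chrom <- function(d, pos, min_snps, max_het) {
  obs <- unname(which(!is.na(d)))
  if (length(obs) == 0L) return(NULL)
  st <- d[obs]
  iv <- max_het_intervals(st == 1L, max_het)
  segs <- list()
  for (i in seq_len(nrow(iv))) {
    hom <- which(st[iv[i, 1]:iv[i, 2]] != 1L) + iv[i, 1] - 1L
    if (length(hom) < min_snps) next
    segs[[length(segs) + 1L]] <- c(
      first = obs[hom[1L]], last = obs[hom[length(hom)]],
      n_snps = length(hom),
      n_het = sum(st[hom[1L]:hom[length(hom)]][
        !is.na(st[hom[1L]:hom[length(hom)]])] == 1L)
    )
  }
  if (length(segs) == 0L) return(NULL)
  out <- unique(do.call(rbind, segs))
  # with max_het > 0, trimming can nest one budget window's run inside
  # another's; keep only maximal runs
  if (nrow(out) > 1L) {
    contained <- vapply(seq_len(nrow(out)), function(i) {
      any(out[-i, "first"] <= out[i, "first"] &
            out[-i, "last"] >= out[i, "last"])
    }, logical(1))
    out <- out[!contained, , drop = FALSE]
  }
  out[order(out[, "first"]), , drop = FALSE]
}

run_allele_string <- function(d, map, from, to) {
  idx <- from:to
  ch <- rep(".", length(idx))
  ch[!is.na(d[idx]) & d[idx] == 0L] <- map$ref_allele[idx][
    !is.na(d[idx]) & d[idx] == 0L]
  ch[!is.na(d[idx]) & d[idx] == 2L] <- map$alt_allele[idx][
    !is.na(d[idx]) & d[idx] == 2L]
  paste0(ch, collapse = "")
}

#' Find runs of homozygosity in one sample
#'
#' Maximal runs of homozygous calls (dosage 0 or 2) containing at most
#' `max_het` heterozygous calls and any number of missing calls, with at
#' least `min_snps` homozygous SNPs. Runs are reported in coordinate
#' order; with `max_het > 0` maximal runs may overlap.
#'
#' @param sample_dosages dosage vector (0/1/2/NA) aligned with `map`.
#' @param map a [marker_map()].
#' @param min_snps minimum homozygous SNPs per run (default 20).
#' @param max_het heterozygous calls tolerated per run (default 0).
#' @param sample_id optional id recorded in the output.
#' @return data frame of class `roh_segments`: `sample_id`, `chrom`,
#'   `start_bp`, `end_bp`, `start_idx`, `end_idx` (global map rows),
#'   `n_snps` (homozygous count), `n_het`, `allele_string` (allele
#'   character at homozygous SNPs, `.` elsewhere).
#' @export
find_roh <- function(sample_dosages, map, min_snps = 20L, max_het = 0L,
                     sample_id = NA_character_) {
  stopifnot(inherits(map, "marker_map"),
            length(sample_dosages) == nrow(map))
  blocks <- rle(map$chrom)
  offs <- cumsum(c(0L, blocks$lengths))
  rows <- list()
  for (b in seq_along(blocks$values)) {
    idx <- offs[b] + seq_len(blocks$lengths[b])
    segs <- roh_one_chrom(sample_dosages[idx], map$pos_bp[idx],
                          min_snps, max_het)
    if (is.null(segs)) next
    for (i in seq_len(nrow(segs))) {
      gi <- offs[b] + c(segs[i, "first"], segs[i, "last"])
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample_id, chrom = blocks$values[b],
        start_bp = map$pos_bp[gi[1]], end_bp = map$pos_bp[gi[2]],
        start_idx = gi[1], end_idx = gi[2],
        n_snps = unname(segs[i, "n_snps"]), n_het = unname(segs[i, "n_het"]),
        allele_string = run_allele_string(sample_dosages, map, gi[1], gi[2]),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    sample_id = character(0), chrom = character(0), start_bp = integer(0),
    end_bp = integer(0), start_idx = integer(0), end_idx = integer(0),
    n_snps = integer(0), n_het = integer(0), allele_string = character(0),
    stringsAsFactors = FALSE
  )
  class(out) <- c("roh_segments", "data.frame")
  out
}

# Per-locus shared-autozygosity status for a dosage matrix (samples x loci):
#  2 = conflict (any het, or homozygotes for opposite alleles)
#  1 = informative (all samples observed, homozygous, identical)
#  0 = neutral (no conflict, but at least one missing call)
shared_locus_status <- function(D) {
  n_obs <- colSums(!is.na(D))
  any_het <- colSums(D == 1L, na.rm = TRUE) > 0L
  any_ref <- colSums(D == 0L, na.rm = TRUE) > 0L
  any_alt <- colSums(D == 2L, na.rm = TRUE) > 0L
  conflict <- any_het | (any_ref & any_alt)
  informative <- !conflict & n_obs == nrow(D)
  ifelse(conflict, 2L, ifelse(informative, 1L, 0L))
}

#' Shared autozygosity segments across samples
#'
#' Maximal intervals where every listed sample is homozygous for the
#' identical allele at every SNP; missing calls are tolerated (they do not
#' break a segment and do not count toward `min_snps`). Segment bounds are
#' trimmed to the first and last fully informative SNP, and at least
#' `min_snps` informative SNPs are required.
#'
#' @param dosages samples-by-loci dosage matrix (rownames = sample ids), at
#'   least two rows.
#' @param map a [marker_map()].
#' @param min_snps minimum informative SNPs per segment (default 20).
#' @return data frame of class `shared_segments`: `chrom`, `start_bp`,
#'   `end_bp`, `start_idx`, `end_idx`, `n_snps` (informative count),
#'   `n_neutral`, `members` (comma-separated sample ids),
#'   `allele_string` (shared allele at informative SNPs, `.` elsewhere).
#' @export
shared_autozygosity <- function(dosages, map, min_snps = 20L) {
  stopifnot(is.matrix(dosages), inherits(map, "marker_map"),
            ncol(dosages) == nrow(map))
  if (nrow(dosages) < 2L) stop("at least two samples required")
  members <- paste(rownames(dosages), collapse = ",")
  status <- shared_locus_status(dosages)
  blocks <- rle(map$chrom)
  offs <- cumsum(c(0L, blocks$lengths))
  rows <- list()
  for (b in seq_along(blocks$values)) {
    idx <- offs[b] + seq_len(blocks$lengths[b])
    st <- status[idx]
    iv <- max_het_intervals(st == 2L, 0L)  # intervals free of conflicts
    for (i in seq_len(nrow(iv))) {
      inf <- which(st[iv[i, 1]:iv[i, 2]] == 1L) + iv[i, 1] - 1L
      if (length(inf) < min_snps) next
      gi <- offs[b] + c(inf[1L], inf[length(inf)])
      # shared allele string: derive from the first sample (all agree)
      d1 <- dosages[1L, gi[1]:gi[2]]
      sub_status <- st[inf[1L]:inf[length(inf)]]
      ch <- rep(".", gi[2] - gi[1] + 1L)
      ok <- sub_status == 1L
      ch[ok & d1 == 0L] <- map$ref_allele[gi[1]:gi[2]][ok & d1 == 0L]
      ch[ok & d1 == 2L] <- map$alt_allele[gi[1]:gi[2]][ok & d1 == 2L]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = blocks$values[b],
        start_bp = map$pos_bp[gi[1]], end_bp = map$pos_bp[gi[2]],
        start_idx = gi[1], end_idx = gi[2],
        n_snps = length(inf),
        n_neutral = sum(sub_status == 0L),
        members = members,
        allele_string = paste0(ch, collapse = ""),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    chrom = character(0), start_bp = integer(0), end_bp = integer(0),
    start_idx = integer(0), end_idx = integer(0), n_snps = integer(0),
    n_neutral = integer(0), members = character(0),
    allele_string = character(0), stringsAsFactors = FALSE
  )
  class(out) <- c("shared_segments", "data.frame")
  out
}

# Does a control's dosage vector match a segment's shared homozygous allele
# at every informative SNP (missing tolerated, at least one observed match)?
control_matches_segment <- function(ctl_dosage, seg, map) {
  idx <- seg$start_idx:seg$end_idx
  ch <- strsplit(seg$allele_string, "")[[1]]
  inf <- ch != "."
  target <- ifelse(ch[inf] == map$ref_allele[idx][inf], 0L, 2L)
  v <- ctl_dosage[idx][inf]
  obs <- !is.na(v)
  any(obs & v == target) && all(v[obs] == target[obs])
}

#' Exclude segments homozygous in controls
#'
#' Drops (default) or trims segments for which any control sample is
#' homozygous for the shared allele. A control "matches" a segment when,
#' at every informative SNP, it is homozygous for the shared allele or
#' missing (with at least one observed match). In trim mode, informative
#' SNPs at which any control is homozygous for the shared allele are
#' removed and the remaining stretches re-extracted at `min_snps`.
#'
#' @param segments a [shared_autozygosity()] result.
#' @param control_dosages controls-by-loci dosage matrix aligned with
#'   `map`.
#' @param map the [marker_map()] the segments were built on.
#' @param mode `"drop"` (default) or `"trim"`.
#' @param min_snps minimum informative SNPs when re-extracting in trim
#'   mode.
#' @return the filtered `shared_segments` data frame.
#' @export
exclude_control_homozygotes <- function(segments, control_dosages, map,
                                        mode = c("drop", "trim"),
                                        min_snps = 20L) {
  mode <- match.arg(mode)
  stopifnot(inherits(segments, "shared_segments"), is.matrix(control_dosages))
  if (nrow(segments) == 0L || nrow(control_dosages) == 0L) return(segments)
  if (mode == "drop") {
    keep <- vapply(seq_len(nrow(segments)), function(i) {
      seg <- segments[i, ]
      !any(vapply(seq_len(nrow(control_dosages)), function(c) {
        control_matches_segment(control_dosages[c, ], seg, map)
      }, logical(1)))
    }, logical(1))
    out <- segments[keep, , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("shared_segments", "data.frame")
    return(out)
  }
  # trim mode
  rows <- list()
  for (i in seq_len(nrow(segments))) {
    seg <- segments[i, ]
    idx <- seg$start_idx:seg$end_idx
    ch <- strsplit(seg$allele_string, "")[[1]]
    inf <- which(ch != ".")
    target <- ifelse(ch[inf] == map$ref_allele[idx][inf], 0L, 2L)
    covered <- rep(FALSE, length(inf))
    for (c in seq_len(nrow(control_dosages))) {
      v <- control_dosages[c, idx][inf]
      covered <- covered | (!is.na(v) & v == target)
    }
    keep_inf <- inf[!covered]
    if (length(keep_inf) == 0L) next
    gaps <- c(0L, which(diff(which(!covered)) > 1L), sum(!covered))
    runs <- cbind(head(gaps, -1L) + 1L, gaps[-1L])
    for (r in seq_len(nrow(runs))) {
      sub <- keep_inf[runs[r, 1]:runs[r, 2]]
      if (length(sub) < min_snps) next
      gi <- seg$start_idx - 1L + c(sub[1L], sub[length(sub)])
      new_ch <- ch[sub[1L]:sub[length(sub)]]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = seg$chrom, start_bp = map$pos_bp[gi[1]],
        end_bp = map$pos_bp[gi[2]], start_idx = gi[1], end_idx = gi[2],
        n_snps = length(sub), n_neutral = sum(new_ch == "."),
        members = seg$members,
        allele_string = paste0(new_ch, collapse = ""),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else segments[0, ]
  rownames(out) <- NULL
  class(out) <- c("shared_segments", "data.frame")
  out
}

#' Segment length in megabases
#'
#' `(end - start) / 1e6`, rounded to two decimals for reporting (the
#' unrounded value is `(end_bp - start_bp) / 1e6`).
#'
#' @param start_bp,end_bp segment bounds, `end_bp >= start_bp`.
#' @return length in Mb, rounded to 2 decimals.
#' @export
segment_length_mb <- function(start_bp, end_bp) {
  stopifnot(all(end_bp >= start_bp))
  round((end_bp - start_bp) / 1e6, 2)
}

#' Shared haplotype across two groups of affected samples
#'
#' Runs [shared_autozygosity()] over the union of both groups' samples and
#' annotates group membership — the cross-population comparison that asks
#' whether affected individuals from two breeds inherited the same
#' haplotype from a common ancestor.
#'
#' @param dosages_a,dosages_b samples-by-loci dosage matrices (rownames =
#'   sample ids) for the two groups, aligned with `map`. Each group needs
#'   at least one sample. A sample appearing in both groups is used once.
#' @param map a [marker_map()].
#' @param min_snps minimum informative SNPs per segment.
#' @return a `shared_segments` data frame whose `members` column is
#'   annotated as `a:<ids>;b:<ids>`.
#' @export
cross_group_shared_haplotype <- function(dosages_a, dosages_b, map,
                                         min_snps = 20L) {
  stopifnot(is.matrix(dosages_a), is.matrix(dosages_b),
            nrow(dosages_a) >= 1L, nrow(dosages_b) >= 1L,
            ncol(dosages_a) == nrow(map), ncol(dosages_b) == nrow(map))
  ids_a <- rownames(dosages_a); ids_b <- rownames(dosages_b)
  D <- rbind(dosages_a, dosages_b[!(ids_b %in% ids_a), , drop = FALSE])
  if (nrow(D) < 2L) D <- rbind(D, D)  # single shared sample: its own ROH set
  segs <- shared_autozygosity(D, map, min_snps)
  if (nrow(segs)) {
    segs$members <- paste0("a:", paste(ids_a, collapse = ","), ";b:",
                           paste(ids_b, collapse = ","))
  }
  segs
}

#' Write ROH or shared segments as BED-style TSV
#'
#' Tab-separated with a header line flagging the 1-based inclusive
#' coordinate convention.
#'
#' @param segments a `roh_segments` or `shared_segments` data frame.
#' @param path output path.
#' @export
write_segments <- function(segments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates are 1-based inclusive SNP positions", con)
  utils::write.table(segments, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
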