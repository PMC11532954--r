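# Gene-regulatory feature derivation and interval intersection.

#' Construct a gene-model table
#'
#' Transcript-level gene models in the refFlat/genePred sense: 0-based
#' half-open transcript and CDS bounds plus parallel sorted exon boundary
#' lists. `cds_start == cds_end` marks a noncoding transcript. Multiple
#' transcripts may share a `gene_id`; feature derivation unions them.
#'
#' @param gene_id,transcript_id,chrom,strand Character vectors.
#' @param tx_start,tx_end,cds_start,cds_end Integer vectors (0-based
#'   half-open).
#' @param exon_starts,exon_ends Lists of integer vectors (parallel, sorted).
#' @return Data frame of class `gene_models` with list columns for exons.
#' @export
gene_models <- function(gene_id, transcript_id = gene_id, chrom, strand,
                        tx_start, tx_end, cds_start = tx_start,
                        cds_end = tx_start, exon_starts, exon_ends) {
  m <- data.frame(gene_id = as.character(gene_id),
                  transcript_id = as.character(transcript_id),
                  chrom = as.character(chrom),
                  strand = as.character(strand),
                  tx_start = as.integer(tx_start),
                  tx_end = as.integer(tx_end),
                  cds_start = as.integer(cds_start),
                  cds_end = as.integer(cds_end),
                  stringsAsFactors = FALSE)
  m$exon_starts <- lapply(exon_starts, as.integer)
  m$exon_ends <- lapply(exon_ends, as.integer)
  validate_gene_models(m)
  class(m) <- c("gene_models", "data.frame")
  m
}

validate_gene_models <- function(m) {
  for (i in seq_len(nrow(m))) {
    id <- m$gene_id[i]
    es <- m$exon_starts[[i]]; ee <- m$exon_ends[[i]]
    if (!m$strand[i] %in% c("+", "-")) {
      stop("gene ", id, ": strand must be '+' or '-'")
    }
    if (m$tx_start[i] >= m$tx_end[i]) {
      stop("gene ", id, ": tx_start must be < tx_end")
    }
    if (length(es) != length(ee) || !length(es)) {
      stop("gene ", id, ": exon_starts/exon_ends must be non-empty and parallel")
    }
    if (any(es >= ee) || is.unsorted(es, strictly = TRUE) ||
        any(es[-1L] < ee[-length(ee)])) {
      stop("gene ", id, ": exons must be sorted and non-overlapping")
    }
    if (es[1L] < m$tx_start[i] || ee[length(ee)] > m$tx_end[i]) {
      stop("gene ", id, ": exons must lie within the transcript bounds")
    }
    if (m$cds_start[i] > m$cds_end[i] || m$cds_start[i] < m$tx_start[i] ||
        m$cds_end[i] > m$tx_end[i]) {
      stop("gene ", id, ": CDS bounds must lie within the transcript bounds")
    }
  }
  invisible(m)
}

# restrict sorted interval lists (a_starts,a_ends) to window [lo, hi)
clip_intervals <- function(starts, ends, lo, hi) {
  keep <- ends > lo & starts < hi
  data.frame(start = pmax(starts[keep], lo), end = pmin(ends[keep], hi))
}

merge_gene_intervals <- function(df) {
  if (!nrow(df)) return(df)
  out <- lapply(split(df, list(df$gene_id, df$chrom), drop = TRUE),
                function(d) {
    r <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
    data.frame(gene_id = d$gene_id[1L], chrom = d$chrom[1L],
               start = IRanges::start(r) - 1L, end = IRanges::end(r),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Derive regulatory features from gene models
#'
#' Strand-aware derivation of the classical regulatory loci: TSS (the
#' transcript 5' end), the single position `tss_upstream` bases upstream of
#' the TSS in transcript orientation (TSS-45 by default), 5'/3' UTR
#' intervals (from CDS bounds; noncoding transcripts contribute none),
#' exons, introns (gaps between consecutive exons) and 5'/3' splice-site
#' points. When several transcripts share a `gene_id`, interval features
#' are the per-gene union and point features the per-gene distinct set.
#'
#' Splice-site convention (0-based): for an intron `[a, b)` of a + strand
#' gene the 5' (donor) site is the base at `a` and the 3' (acceptor) site
#' the base at `b`; on the minus strand the donor is `b - 1` and the
#' acceptor `a - 1`, i.e. always the first base downstream of the junction
#' in transcript orientation.
#'
#' @param models A [gene_models()] frame.
#' @param tss_upstream Distance upstream of the TSS for the promoter-point
#'   feature (default 45).
#' @return A `feature_set` list with elements `tss`, `tss45` (point frames:
#'   `gene_id`, `chrom`, `pos`, `strand`), `utr5`, `utr3`, `exon`, `intron`
#'   (interval frames: `gene_id`, `chrom`, `start`, `end`) and `splice5`,
#'   `splice3` (point frames with `strand`).
#' @export
derive_features <- function(models, tss_upstream = 45L) {
  validate_gene_models(models)
  n <- nrow(models)
  pt <- function() data.frame(gene_id = character(0), chrom = character(0),
                              pos = integer(0), strand = character(0),
                              stringsAsFactors = FALSE)
  iv <- function() data.frame(gene_id = character(0), chrom = character(0),
                              start = integer(0), end = integer(0),
                              stringsAsFactors = FALSE)
  tss <- pt(); tss45 <- pt(); splice5 <- pt(); splice3 <- pt()
  utr5 <- iv(); utr3 <- iv(); exon <- iv(); intron <- iv()
  for (i in seq_len(n)) {
    id <- models$gene_id[i]; chr <- models$chrom[i]
    std <- models$strand[i]
    es <- models$exon_starts[[i]]; ee <- models$exon_ends[[i]]
    tss_pos <- if (std == "+") models$tx_start[i] else models$tx_end[i] - 1L
    t45 <- if (std == "+") tss_pos - tss_upstream else tss_pos + tss_upstream
    tss <- rbind(tss, data.frame(gene_id = id, chrom = chr, pos = tss_pos,
                                 strand = std))
    tss45 <- rbind(tss45, data.frame(gene_id = id, chrom = chr, pos = t45,
                                     strand = std))
    exon <- rbind(exon, data.frame(gene_id = id, chrom = chr,
                                   start = es, end = ee))
    if (length(es) > 1L) {
      ia <- ee[-length(ee)]; ib <- es[-1L]
      intron <- rbind(intron, data.frame(gene_id = id, chrom = chr,
                                         start = ia, end = ib))
      if (std == "+") {
        s5 <- ia; s3 <- ib
      } else {
        s5 <- ib - 1L; s3 <- ia - 1L
      }
      splice5 <- rbind(splice5, data.frame(gene_id = id, chrom = chr,
                                           pos = s5, strand = std))
      splice3 <- rbind(splice3, data.frame(gene_id = id, chrom = chr,
                                           pos = s3, strand = std))
    }
    cs <- models$cds_start[i]; ce <- models$cds_end[i]
    if (cs < ce) {
      left <- clip_intervals(es, ee, models$tx_start[i], cs)
      right <- clip_intervals(es, ee, ce, models$tx_end[i])
      u5 <- if (std == "+") left else right
      u3 <- if (std == "+") right else left
      if (nrow(u5)) utr5 <- rbind(utr5, cbind(gene_id = id, chrom = chr, u5))
      if (nrow(u3)) utr3 <- rbind(utr3, cbind(gene_id = id, chrom = chr, u3))
    }
  }
  dedupe_pts <- function(p) unique(p)
  structure(list(tss = dedupe_pts(tss), tss45 = dedupe_pts(tss45),
                 utr5 = merge_gene_intervals(utr5),
                 utr3 = merge_gene_intervals(utr3),
                 exon = merge_gene_intervals(exon),
                 intron = merge_gene_intervals(intron),
                 splice5 = dedupe_pts(splice5),
                 splice3 = dedupe_pts(splice3),
                 tss_upstream = as.integer(tss_upstream)),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat("pG4 feature set:\n")
  for (f in c("tss", "tss45", "utr5", "utr3", "exon", "intron",
              "splice5", "splice3")) {
    cat(sprintf("  %-8s %5d records\n", f, nrow(x[[f]])))
  }
  invisible(x)
}

feature_name_map <- c("TSS" = "tss", "TSS-45" = "tss45", "5UTR" = "utr5",
                      "3UTR" = "utr3", "exon" = "exon", "intron" = "intron")

#' Feature intervals by name
#'
#' Returns the intervals of a named feature as a 0-based half-open frame;
#' point features (TSS, TSS-45) become width-1 intervals.
#' @param features A [derive_features()] result.
#' @param feature One of `TSS`, `TSS-45`, `5UTR`, `3UTR`, `exon`, `intron`.
#' @return Data frame `gene_id`, `chrom`, `start`, `end`.
#' @export
feature_intervals <- function(features, feature) {
  key <- feature_name_map[feature]
  if (is.na(key)) {
    stop("unknown feature '", feature, "'; expected one of ",
         paste(names(feature_name_map), collapse = ", "))
  }
  f <- features[[key]]
  if (key %in% c("tss", "tss45")) {
    data.frame(gene_id = f$gene_id, chrom = f$chrom, start = f$pos,
               end = f$pos + 1L, stringsAsFactors = FALSE)
  } else {
    f
  }
}

#' Intersect two sorted interval sets
#'
#' Reports every pair of intervals from `a` and `b` sharing at least one
#' base, with the overlap length — standard `intersect` semantics on
#' 0-based half-open intervals (abutting intervals do not overlap). Inputs
#' are expected sorted by (chrom, start); unsorted input is sorted
#' internally with a message.
#'
#' @param a,b Data frames with `chrom`, `start`, `end`.
#' @return Data frame `a_idx`, `b_idx` (row indices into the inputs as
#'   given) and `overlap` (bases shared), sorted by (`a_idx`, `b_idx`).
#' @export
intersect_ranges <- function(a, b) {
  check_sorted <- function(d, nm) {
    if (nrow(d) > 1L) {
      o <- order(d$chrom, d$start)
      if (!identical(o, seq_len(nrow(d)))) {
        message("intersect_ranges: input '", nm, "' not sorted; sorting")
      }
    }
  }
  check_sorted(a, "a"); check_sorted(b, "b")
  out <- data.frame(a_idx = integer(0), b_idx = integer(0),
                    overlap = integer(0))
  for (chr in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == chr); ib <- which(b$chrom == chr)
    ra <- IRanges::IRanges(a$start[ia] + 1L, a$end[ia])
    rb <- IRanges::IRanges(b$start[ib] + 1L, b$end[ib])
    ov <- IRanges::findOverlaps(ra, rb)
    if (!length(ov)) next
    w <- IRanges::width(IRanges::pintersect(ra[S4Vectors::queryHits(ov)],
                                            rb[S4Vectors::subjectHits(ov)]))
    out <- rbind(out, data.frame(a_idx = ia[S4Vectors::queryHits(ov)],
                                 b_idx = ib[S4Vectors::subjectHits(ov)],
                                 overlap = w))
  }
  out <- out[order(out$a_idx, out$b_idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition genes by pG4 presence at a feature
#'
#' A gene is "with pG4" iff any hit (either strand; strands are merged for
#' all feature-overlap calls) covers at least one base of that gene's
#' feature intervals — for point features, contains the point. The
#' partition is exhaustive and disjoint over the genes that possess the
#' feature.
#'
#' @param models [gene_models()] frame.
#' @param hits Hits from [scan_genome()].
#' @param feature Feature name (see [feature_intervals()]).
#' @param tss_upstream Upstream distance for the TSS-45-style feature.
#' @return List with character vectors `with` and `without`.
#' @export
partition_genes <- function(models, hits, feature, tss_upstream = 45L) {
  fs <- derive_features(models, tss_upstream = tss_upstream)
  iv <- feature_intervals(fs, feature)
  all_genes <- unique(iv$gene_id)
  if (!nrow(hits) || !nrow(iv)) {
    return(list(with = character(0), without = all_genes))
  }
  merged <- merged_hits_frame(hits)
  ov <- intersect_ranges(iv[order(iv$chrom, iv$start), , drop = FALSE],
                         merged)
  ordered_iv <- iv[order(iv$chrom, iv$start), , drop = FALSE]
  with_genes <- unique(ordered_iv$gene_id[ov$a_idx])
  list(with = sort(with_genes),
       without = sort(setdiff(all_genes, with_genes)))
}

# strand-merged hits as a sorted 0-based frame
merged_hits_frame <- function(hits) {
  rng <- merged_pg4_ranges(hits)
  if (!length(rng)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  }
  out <- do.call(rbind, lapply(names(rng), function(chr) {
    data.frame(chrom = chr, start = IRanges::start(rng[[chr]]) - 1L,
               end = IRanges::end(rng[[chr]]), stringsAsFactors = FALSE)
  }))
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Count EST start sites falling inside pG4 intervals
#'
#' An EST counts when its strand-aware 5' start position lies inside any
#' strand-merged pG4 interval (half-open containment; pG4 strand ignored).
#'
#' @param ests Data frame with `chrom`, `strand`, `start_site` (0-based).
#' @param hits Hits from [scan_genome()].
#' @return List `n_in_pg4`, `n_total`.
#' @export
est_tss_overlap <- function(ests, hits) {
  n_total <- nrow(ests)
  rng <- merged_pg4_ranges(hits)
  n_in <- 0L
  for (chr in names(rng)) {
    p <- ests$start_site[ests$chrom == chr]
    if (!length(p)) next
    n_in <- n_in + sum(IRanges::countOverlaps(
      IRanges::IRanges(p + 1L, p + 1L), rng[[chr]]) > 0L)
  }
  list(n_in_pg4 = n_in, n_total = n_total)
}

profile_side <- function(sites, rng, window) {
  counts <- integer(2L * window + 1L)
  if (!nrow(sites)) return(counts)
  for (chr in unique(sites$chrom)) {
    red <- rng[[chr]]
    if (is.null(red) || !length(red)) next
    sc <- sites[sites$chrom == chr, , drop = FALSE]
    win <- IRanges::IRanges(sc$pos - window + 1L, sc$pos + window + 1L)
    ov <- IRanges::findOverlaps(win, red)
    if (!length(ov)) next
    pint <- IRanges::pintersect(win[S4Vectors::queryHits(ov)],
                                red[S4Vectors::subjectHits(ov)])
    qs <- S4Vectors::queryHits(ov)
    for (k in seq_along(qs)) {
      pos0 <- (IRanges::start(pint)[k] - 1L):(IRanges::end(pint)[k] - 1L)
      off <- if (sc$strand[qs[k]] == "+") pos0 - sc$pos[qs[k]]
             else sc$pos[qs[k]] - pos0
      idx <- off + window + 1L
      counts[idx] <- counts[idx] + 1L
    }
  }
  counts
}

#' Per-offset pG4 coverage around splice sites
#'
#' For every 5' and 3' splice site, each genomic base covered by a
#' strand-merged pG4 interval and lying within `window` bases of the site
#' contributes one count at its signed offset in transcript orientation
#' (negative = upstream of the site, i.e. "before"; minus-strand genes are
#' mirrored). Motifs are counted per covered base, not per motif.
#'
#' @param models [gene_models()] frame (needs at least one intron; a
#'   zero-filled profile with a warning is returned otherwise).
#' @param hits Hits from [scan_genome()].
#' @param window Half-window in bases (default 2500).
#' @return A `splice_profile` object: `window`, `offsets`
#'   (-window..window), `counts_5p`, `counts_3p`, `n_sites_5p`,
#'   `n_sites_3p`.
#' @export
splice_profile <- function(models, hits, window = 2500L) {
  window <- as.integer(window)
  fs <- derive_features(models)
  s5 <- fs$splice5; s3 <- fs$splice3
  s5 <- unique(s5[, c("chrom", "pos", "strand")])
  s3 <- unique(s3[, c("chrom", "pos", "strand")])
  if (!nrow(s5) && !nrow(s3)) {
    warning("no introns in the gene models; returning a zero profile")
  }
  rng <- merged_pg4_ranges(hits)
  structure(list(window = window, offsets = seq(-window, window),
                 counts_5p = profile_side(s5, rng, window),
                 counts_3p = profile_side(s3, rng, window),
                 n_sites_5p = nrow(s5), n_sites_3p = nrow(s3)),
            class = "splice_profile")
}

#' @export
print.splice_profile <- function(x, ...) {
  cat(sprintf("splice-site pG4 profile, window +/-%d bp\n", x$window))
  cat(sprintf("  5' sites: %d, total pG4 bp in window: %d\n",
              x$n_sites_5p, sum(x$counts_5p)))
  cat(sprintf("  3' sites: %d, total pG4 bp in window: %d\n",
              x$n_sites_3p, sum(x$counts_3p)))
  invisible(x)
}

#' Per-offset fold enrichment of a splice profile
#'
#' Fold at each offset is the count divided by the mean count over all
#' offsets of that side; the argmax offset is reported per side (ties go to
#' the most upstream offset).
#'
#' @param profile A [splice_profile()] object.
#' @return List with `fold_5p`, `fold_3p` (vectors over `offsets`),
#'   `peak_5p`, `peak_3p` (argmax offsets, NA for an all-zero side),
#'   `peak_fold_5p`, `peak_fold_3p` and `offsets`.
#' @export
profile_enrichment <- function(profile) {
  side <- function(counts) {
    mu <- mean(counts)
    if (mu == 0) {
      warning("all-zero profile side; fold values undefined")
      return(list(fold = rep(NA_real_, length(counts)), peak = NA_integer_,
                  peak_fold = NA_real_))
    }
    fold <- counts / mu
    peak <- profile$offsets[which.max(counts)]
    list(fold = fold, peak = peak, peak_fold = max(fold))
  }
  f5 <- side(profile$counts_5p)
  f3 <- side(profile$counts_3p)
  list(fold_5p = f5$fold, fold_3p = f3$fold,
       peak_5p = f5$peak, peak_3p = f3$peak,
       peak_fold_5p = f5$peak_fold, peak_fold_3p = f3$peak_fold,
       offsets = profile$offsets)
}
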