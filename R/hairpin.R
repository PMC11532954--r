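# 500-bp genome binning, per-bin hairpin folding free energy via a
# pluggable adapter, deltaG histograms and hotspot localization.

#' Folding result container
#'
#' A per-sequence set of predicted secondary structures, each with a free
#' energy (kcal/mol) and a melting temperature (degC). Adapters wrapping
#' external engines should return this; downstream code summarizes it as
#' (min deltaG, max Tm, structure count).
#'
#' @param dg,tm Numeric vectors of equal length (possibly empty).
#' @param engine,parameters Provenance strings recorded with the result.
#' @return Object of class `folding_result`.
#' @export
folding_result <- function(dg, tm, engine = "unknown", parameters = "") {
  stopifnot(length(dg) == length(tm))
  structure(list(structures = data.frame(dg = as.numeric(dg),
                                         tm = as.numeric(tm)),
                 engine = engine, parameters = parameters),
            class = "folding_result")
}

#' @export
print.folding_result <- function(x, ...) {
  n <- nrow(x$structures)
  if (n) {
    cat(sprintf("folding result (%s): %d structures, min dG %.2f, max Tm %.1f\n",
                x$engine, n, min(x$structures$dg), max(x$structures$tm)))
  } else {
    cat(sprintf("folding result (%s): no structures\n", x$engine))
  }
  invisible(x)
}

#' Naive deterministic hairpin folder
#'
#' An intentionally simple in-repo folding adapter so that the deltaG
#' landscape machinery is testable offline: it enumerates maximal
#' complementary hairpin stems (Watson-Crick pairs only, minimum loop 3)
#' along every anti-diagonal of the sequence-versus-reverse-complement
#' comparison, scores each stem with fixed pair energies (G:C -3, A:T -2
#' kcal/mol) plus a +3 kcal/mol loop initiation penalty, and assigns a
#' Wallace-rule melting temperature (4 degC per G:C pair, 2 per A:T).
#' It makes no claim to match a thermodynamic engine; real analyses plug
#' in an external folder via the same adapter interface.
#'
#' @param seq Nucleotide string.
#' @param min_stem Minimum stem pairs to report a structure (default 3).
#' @param loop_min Minimum loop length between the stem halves (default 3).
#' @param max_structures Cap on reported structures (most stable kept).
#' @return A [folding_result()].
#' @export
naive_fold <- function(seq, min_stem = 3L, loop_min = 3L,
                       max_structures = 20L) {
  s <- strsplit(toupper(seq), "")[[1L]]
  n <- length(s)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pair_e <- c(A = 2, C = 3, G = 3, T = 2)   # magnitude of pair energy
  dgs <- numeric(0); tms <- numeric(0)
  if (n >= 2L * min_stem + loop_min) {
    valid <- s %in% names(comp)
    for (csum in seq(3L, 2L * n - 1L)) {
      i <- seq.int(max(1L, csum - n), floor((csum - 1L) / 2L))
      if (!length(i)) next
      j <- csum - i
      ok <- valid[i] & valid[j] & comp[s[i]] == s[j] & (j - i) > loop_min
      r <- rle(ok)
      ends <- cumsum(r$lengths)
      for (k in which(r$values & r$lengths >= min_stem)) {
        idx <- i[(ends[k] - r$lengths[k] + 1L):ends[k]]
        e <- sum(pair_e[s[idx]])
        gc <- sum(s[idx] %in% c("G", "C"))
        at <- length(idx) - gc
        dgs <- c(dgs, 3 - e)
        tms <- c(tms, 4 * gc + 2 * at)
      }
    }
  }
  if (length(dgs) > max_structures) {
    keep <- order(dgs)[seq_len(max_structures)]
    dgs <- dgs[keep]; tms <- tms[keep]
  }
  folding_result(dgs, tms, engine = "naive_hairpin",
                 parameters = sprintf("min_stem=%d loop_min=%d", min_stem,
                                      loop_min))
}

#' Divide a genome into fixed-size bins
#'
#' Contiguous, non-overlapping bins per chromosome. A bin containing any N
#' is flagged `has_gap`; a shorter terminal bin is flagged `terminal`.
#' Gap and terminal bins are skipped by [score_bins()] and excluded from
#' histograms.
#'
#' @inheritParams scan_genome
#' @param bin_size Bin width in bases (default 500).
#' @return Data frame `chrom`, `start`, `end` (0-based half-open),
#'   `has_gap`, `terminal`.
#' @export
bin_genome <- function(genome, bin_size = 500L) {
  genome <- as_genome(genome)
  bin_size <- as.integer(bin_size)
  out <- lapply(names(genome), function(chr) {
    L <- nchar(genome[[chr]])
    starts <- seq.int(0L, L - 1L, by = bin_size)
    ends <- pmin(starts + bin_size, L)
    npos <- gregexpr("N", toupper(genome[[chr]]), fixed = TRUE)[[1L]]
    has_gap <- rep(FALSE, length(starts))
    if (npos[1L] != -1L) {
      gap_bins <- unique((as.integer(npos) - 1L) %/% bin_size) + 1L
      has_gap[gap_bins] <- TRUE
    }
    data.frame(chrom = chr, start = starts, end = ends,
               has_gap = has_gap, terminal = (ends - starts) < bin_size,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Score bins with a folding adapter
#'
#' Sets `dg` to the minimum free energy the adapter reports for each
#' eligible bin's sequence; gap and terminal bins are skipped, and adapter
#' failures leave `dg` absent (NA) with a message.
#'
#' @param bins Output of [bin_genome()].
#' @param genome The genome the bins refer to.
#' @param adapter Folding adapter, e.g. [naive_fold()] or an external-
#'   engine wrapper.
#' @return `bins` with an added numeric `dg` column.
#' @export
score_bins <- function(bins, genome, adapter = naive_fold) {
  genome <- as_genome(genome)
  bins$dg <- NA_real_
  idx <- which(!bins$has_gap & !bins$terminal)
  n_fail <- 0L
  for (i in idx) {
    seq_i <- substr(genome[[bins$chrom[i]]], bins$start[i] + 1L, bins$end[i])
    bins$dg[i] <- tryCatch(summarize_folding(adapter(seq_i))$dg,
                           error = function(e) {
                             n_fail <<- n_fail + 1L
                             NA_real_
                           })
  }
  if (n_fail) message("score_bins: adapter failed on ", n_fail, " bins")
  bins
}

#' Histogram of bin folding free energies
#'
#' Left-closed 5 kcal/mol bins spanning -272.5 to 7.5 by default (a value
#' exactly on an edge belongs to the bin starting there); values outside
#' the range accumulate into the clamped end bins and are counted in
#' `n_clamped`. Summary statistics (mode-bin center, mean, SD, median) are
#' computed on the raw values.
#'
#' @param scored Output of [score_bins()] (or a numeric vector of dg
#'   values).
#' @param lo,hi,width Histogram range and bin width (defaults -272.5, 7.5,
#'   5 kcal/mol).
#' @return Object of class `dg_histogram`: `edges` (frame `edge_lo`,
#'   `edge_hi`, `count`), `summary` (mode_center, mean, sd, median, n),
#'   `n_clamped`.
#' @export
dg_histogram <- function(scored, lo = -272.5, hi = 7.5, width = 5) {
  dg <- if (is.data.frame(scored)) scored$dg else scored
  dg <- dg[is.finite(dg)]
  if (!length(dg)) stop("no scored bins to histogram")
  edges_lo <- seq(lo, hi - width, by = width)
  nb <- length(edges_lo)
  idx <- floor((dg - lo) / width) + 1
  n_clamped <- sum(idx < 1 | idx > nb)
  idx <- pmin(pmax(idx, 1), nb)
  counts <- tabulate(idx, nbins = nb)
  structure(list(
    edges = data.frame(edge_lo = edges_lo, edge_hi = edges_lo + width,
                       count = counts),
    summary = list(mode_center = edges_lo[which.max(counts)] + width / 2,
                   mean = mean(dg), sd = stats::sd(dg),
                   median = stats::median(dg), n = length(dg)),
    n_clamped = n_clamped), class = "dg_histogram")
}

#' @export
print.dg_histogram <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("deltaG histogram of %d bins: mode %.1f, ",
                     "mean %.1f +/- %.1f, median %.1f kcal/mol"),
              s$n, s$mode_center, s$mean, s$sd, s$median))
  if (x$n_clamped) cat(sprintf(" (%d values clamped)", x$n_clamped))
  cat("\n")
  invisible(x)
}

#' Locate an interval in the deltaG landscape
#'
#' Returns the scored bin containing the interval (the bin of its midpoint
#' when it spans a boundary), the bin's deltaG, and the bin's percentile
#' among all scored bins — the fraction of scored bins at least as stable
#' (dg <= the bin's dg), so the single most stable bin scores 1/n.
#'
#' @param chrom,start,end Interval coordinates (0-based half-open).
#' @param scored Output of [score_bins()].
#' @return List `bin` (one-row frame), `dg`, `percentile`.
#' @export
locate_hotspot <- function(chrom, start, end, scored) {
  mid <- (start + end) %/% 2
  i <- which(scored$chrom == chrom & scored$start <= mid & scored$end > mid)
  if (!length(i)) stop("interval midpoint not covered by any bin")
  i <- i[1L]
  if (!is.finite(scored$dg[i])) {
    stop("interval falls in an unscored (gap/terminal) bin")
  }
  all_dg <- scored$dg[is.finite(scored$dg)]
  list(bin = scored[i, , drop = FALSE], dg = scored$dg[i],
       percentile = mean(all_dg <= scored$dg[i]))
}

#' Extract a pG4 sequence extended by flanks for folding
#'
#' Forward-strand sequence of `[start - flank, end + flank)`, clipped at
#' the chromosome ends (with a message); for minus-strand hits the reverse
#' complement is returned, so the result always reads in motif
#' orientation.
#'
#' @param hit One-row hits frame (or list) with `chrom`, `start`, `end`,
#'   `strand`.
#' @param genome The genome the hit refers to.
#' @param flank Flank width on each side (default 20).
#' @return Character sequence.
#' @export
extend_for_folding <- function(hit, genome, flank = 20L) {
  genome <- as_genome(genome)
  L <- nchar(genome[[hit$chrom]])
  lo <- hit$start - flank
  hi <- hit$end + flank
  if (lo < 0L || hi > L) {
    message("extend_for_folding: flank clipped at chromosome boundary")
    lo <- max(0L, lo); hi <- min(L, hi)
  }
  s <- substr(genome[[hit$chrom]], lo + 1L, hi)
  if (identical(hit$strand, "-")) s <- revcomp(s)
  s
}
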