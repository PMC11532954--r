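# Independent oracles and small fixture builders used across the suite.

random_seq <- function(n, seed = NULL, alphabet = c("A", "C", "G", "T")) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# per-base bitmap oracle for covered base pairs
bitmap_covered_bp <- function(hits, chrom_lengths) {
  total <- 0L
  for (chr in names(chrom_lengths)) {
    mask <- logical(chrom_lengths[[chr]])
    h <- hits[hits$chrom == chr, , drop = FALSE]
    for (i in seq_len(nrow(h))) {
      mask[(h$start[i] + 1L):h$end[i]] <- TRUE
    }
    total <- total + sum(mask)
  }
  total
}

# quadratic all-vs-all interval intersection oracle (0-based half-open)
brute_intersect <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov >= 1L) out[[length(out) + 1L]] <- c(i, j, ov)
    }
  }
  if (!length(out)) {
    return(data.frame(a_idx = integer(0), b_idx = integer(0),
                      overlap = integer(0)))
  }
  m <- do.call(rbind, out)
  d <- data.frame(a_idx = m[, 1L], b_idx = m[, 2L], overlap = m[, 3L])
  d[order(d$a_idx, d$b_idx), , drop = FALSE]
}

# exact two-sided rank-sum p by enumeration of all assignments
enumerate_ranksum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  obs <- sum(rank(pooled)[seq_len(nx)])
  combos <- utils::combn(nx + ny, nx)
  stats_all <- apply(combos, 2L, function(idx) sum(rank(pooled)[idx]))
  mu <- nx * (nx + ny + 1) / 2
  mean(abs(stats_all - mu) >= abs(obs - mu) - 1e-9)
}

# one-exon / multi-exon model builders
make_model <- function(gene_id = "g1", chrom = "c1", strand = "+",
                       exon_starts, exon_ends,
                       cds_start = exon_starts[1],
                       cds_end = exon_starts[1]) {
  gene_models(gene_id = gene_id, chrom = chrom, strand = strand,
              tx_start = exon_starts[1], tx_end = exon_ends[length(exon_ends)],
              cds_start = cds_start, cds_end = cds_end,
              exon_starts = list(exon_starts), exon_ends = list(exon_ends))
}

hits_frame <- function(chrom, start, end, strand = "+", q_score = NA_real_) {
  n <- max(length(chrom), length(start))
  data.frame(chrom = chrom, start = start, end = end,
             strand = rep_len(strand, n), n_runs = rep_len(4L, n),
             sequence = rep_len("", n), q_score = rep_len(q_score, n),
             stringsAsFactors = FALSE)
}
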