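# pG4 motif scanner: maximal G-run detection + leftmost-greedy run chaining.
# Coordinates are 0-based half-open (BED convention) throughout the package.

#' Scanner parameters for the pG4 motif
#'
#' The canonical putative G-quadruplex (pG4) motif is at least four runs of
#' at least three guanines, with consecutive runs separated by loops of 1 to
#' 7 bases. All four dimensions are tunable.
#'
#' @param min_run_length Minimum guanines per run (>= 2). Default 3.
#' @param min_runs Minimum number of G runs in a motif (>= 2). Default 4.
#' @param loop_min,loop_max Allowed loop length range (bases between
#'   consecutive runs). Defaults 1 and 7; loops longer than 7 bp are excluded
#'   because the corresponding structures are predicted to be unstable.
#' @return An object of class `scan_params`.
#' @examples
#' scan_params()
#' scan_params(loop_max = 12)
#' @export
scan_params <- function(min_run_length = 3L, min_runs = 4L,
                        loop_min = 1L, loop_max = 7L) {
  min_run_length <- as.integer(min_run_length)
  min_runs <- as.integer(min_runs)
  loop_min <- as.integer(loop_min)
  loop_max <- as.integer(loop_max)
  if (min_run_length < 2L) stop("min_run_length must be >= 2")
  if (min_runs < 2L) stop("min_runs must be >= 2")
  if (loop_min < 1L) stop("loop_min must be >= 1")
  if (loop_min > loop_max) stop("loop_min must be <= loop_max")
  structure(list(min_run_length = min_run_length, min_runs = min_runs,
                 loop_min = loop_min, loop_max = loop_max),
            class = "scan_params")
}

#' @export
print.scan_params <- function(x, ...) {
  cat(sprintf("pG4 scan parameters: >=%d runs of G{%d,}, loops %d-%d bp\n",
              x$min_runs, x$min_run_length, x$loop_min, x$loop_max))
  invisible(x)
}

#' PCRE pattern equivalent to the scanner's motif definition
#'
#' Builds the regular expression `G{r,}+(?:[ACGT]{lmin,lmax}G{r,}+){k-1,}+`.
#' Possessive quantifiers on the G runs encode the convention that a maximal
#' run of guanines is consumed whole as a single run and is never split into
#' run + loop + run. Used as an independent reference route (e.g. by the
#' synthetic generator to annotate ground truth); the scanner itself is a
#' run-chaining algorithm that does not use this pattern.
#'
#' @param params A [scan_params()] object.
#' @return A single PCRE pattern string (use with `perl = TRUE`).
#' @export
pg4_regex <- function(params = scan_params()) {
  sprintf("G{%d,}+(?:[ACGT]{%d,%d}G{%d,}+){%d,}+",
          params$min_run_length, params$loop_min, params$loop_max,
          params$min_run_length, params$min_runs - 1L)
}

empty_hits <- function(with_chrom = TRUE) {
  h <- data.frame(start = integer(0), end = integer(0),
                  strand = character(0), n_runs = integer(0),
                  sequence = character(0), q_score = numeric(0),
                  stringsAsFactors = FALSE)
  if (with_chrom) h <- cbind(data.frame(chrom = character(0)), h)
  h
}

#' Scan one strand of a sequence for pG4 motifs
#'
#' Finds leftmost-maximal, non-overlapping pG4 matches: maximal runs of
#' `min_run_length` or more guanines are chained greedily while consecutive
#' runs are separated by a loop of length `loop_min..loop_max` containing
#' only A/C/G/T (a motif never spans an ambiguous N base). A chain of at
#' least `min_runs` runs is emitted as one hit and scanning resumes after
#' its end.
#'
#' @param seq A single nucleotide string over A/C/G/T/N (case-insensitive;
#'   soft-masked lowercase is treated as uppercase unless `mask_lower`).
#' @param params A [scan_params()] object.
#' @param mask_lower If `TRUE`, lowercase (soft-masked) bases are treated as
#'   N and therefore excluded from motifs.
#' @return A data frame with columns `start`, `end` (0-based half-open
#'   offsets into `seq`), `strand` (always "+"), `n_runs`, `sequence`
#'   (motif bases) and `q_score` (NA; stability scores are external input).
#' @examples
#' scan_strand("GGGTGGGTGGGTGGG")
#' @export
scan_strand <- function(seq, params = scan_params(), mask_lower = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  s <- if (mask_lower) chartr("acgtn", "NNNNN", seq) else seq
  s <- toupper(s)
  bad <- regexpr("[^ACGTN]", s)[1L]
  if (bad != -1L) {
    stop(sprintf("non-nucleotide character '%s' at offset %d",
                 substr(s, bad, bad), bad - 1L))
  }
  m <- gregexpr(sprintf("G{%d,}", params$min_run_length), s)[[1L]]
  if (m[1L] == -1L) return(empty_hits(with_chrom = FALSE))
  run_start <- as.integer(m) - 1L                       # 0-based
  run_end <- run_start + attr(m, "match.length")        # exclusive
  n <- length(run_start)

  # loop between run j and j+1 is chainable if its length is within bounds
  # and it contains no N
  if (n > 1L) {
    gap_len <- run_start[-1L] - run_end[-n]
    gap_seq <- substring(s, run_end[-n] + 1L, run_start[-1L])
    chainable <- gap_len >= params$loop_min & gap_len <= params$loop_max &
      !grepl("N", gap_seq, fixed = TRUE)
  } else {
    chainable <- logical(0)
  }

  starts <- integer(0); ends <- integer(0); nruns <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && chainable[j]) j <- j + 1L
    if (j - i + 1L >= params$min_runs) {
      starts <- c(starts, run_start[i])
      ends <- c(ends, run_end[j])
      nruns <- c(nruns, j - i + 1L)
    }
    i <- j + 1L
  }
  if (!length(starts)) return(empty_hits(with_chrom = FALSE))
  data.frame(start = starts, end = ends, strand = "+", n_runs = nruns,
             sequence = substring(s, starts + 1L, ends),
             q_score = NA_real_, stringsAsFactors = FALSE)
}

#' Reference regex route for pG4 matching
#'
#' Leftmost, non-overlapping matches of [pg4_regex()] on the uppercased
#' sequence. Kept deliberately separate from [scan_strand()] so the two
#' routes can be compared; the synthetic-data generator uses this route to
#' annotate ground truth.
#'
#' @inheritParams scan_strand
#' @return Data frame with `start`, `end` (0-based half-open).
#' @export
scan_strand_regex <- function(seq, params = scan_params()) {
  s <- toupper(seq)
  m <- gregexpr(pg4_regex(params), s, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = as.integer(m) - 1L,
             end = as.integer(m) - 1L + attr(m, "match.length"))
}

as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) genome <- as.character(genome)
  stopifnot(is.character(genome))
  if (length(genome) && (is.null(names(genome)) || anyNA(names(genome)) ||
                         any(names(genome) == ""))) {
    stop("genome sequences must be named by chromosome")
  }
  genome
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Scan a genome on both strands for pG4 motifs
#'
#' Plus-strand hits come from [scan_strand()] on each sequence; minus-strand
#' hits from scanning the reverse complement, with coordinates mapped back
#' onto the forward axis. Hits are ordered by (chrom, start, strand).
#'
#' @param genome Named character vector of chromosome sequences (or a
#'   `Biostrings::DNAStringSet`), e.g. from [read_fasta()].
#' @inheritParams scan_strand
#' @return Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open genomic), `strand`, `n_runs`, `sequence` (bases on the
#'   matched strand), `q_score`.
#' @examples
#' scan_genome(c(c1 = "CCCACCCACCCACCC"))  # minus-strand minimal motif
#' @export
scan_genome <- function(genome, params = scan_params(), mask_lower = FALSE) {
  genome <- as_genome(genome)
  if (!length(genome)) return(empty_hits())
  out <- vector("list", 2L * length(genome))
  k <- 0L
  for (chr in names(genome)) {
    plus <- scan_strand(genome[[chr]], params, mask_lower)
    if (nrow(plus)) {
      plus$chrom <- chr
      k <- k + 1L; out[[k]] <- plus
    }
    minus <- scan_strand(revcomp(genome[[chr]]), params, mask_lower)
    if (nrow(minus)) {
      L <- nchar(genome[[chr]])
      new_start <- L - minus$end
      minus$end <- L - minus$start
      minus$start <- new_start
      minus$strand <- "-"
      minus$chrom <- chr
      k <- k + 1L; out[[k]] <- minus
    }
  }
  if (!k) return(empty_hits())
  hits <- do.call(rbind, out[seq_len(k)])
  hits <- hits[, c("chrom", "start", "end", "strand", "n_runs",
                   "sequence", "q_score")]
  hits <- hits[order(hits$chrom, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# per-chromosome list of strand-merged IRanges (1-based, closed, as IRanges
# convention) from a 0-based half-open hits frame
merged_pg4_ranges <- function(hits) {
  stopifnot(is.data.frame(hits))
  if (!nrow(hits)) return(list())
  sp <- split(seq_len(nrow(hits)), hits$chrom)
  lapply(sp, function(idx) {
    IRanges::reduce(IRanges::IRanges(start = hits$start[idx] + 1L,
                                     end = hits$end[idx]))
  })
}

#' Base pairs covered by pG4 hits (strand union)
#'
#' Size of the union of all hit intervals projected onto the forward genomic
#' axis, with the two strands merged — the convention used when a single
#' genomic "pG4 bp" figure is reported per assembly.
#'
#' @param hits Hits data frame from [scan_genome()] (or any frame with
#'   `chrom`, `start`, `end`).
#' @return Integer number of covered base pairs.
#' @export
merged_pg4_bp <- function(hits) {
  rng <- merged_pg4_ranges(hits)
  if (!length(rng)) return(0L)
  sum(vapply(rng, function(r) sum(IRanges::width(r)), numeric(1)))
}

#' Percentage helper for pG4 coverage
#'
#' `100 * pg4_bp / total_bp`, rounded to `digits` decimals. Exposed
#' separately from [pg4_fraction()] so published counts can be fed in
#' directly.
#'
#' @param pg4_bp Covered base pairs (strand-merged).
#' @param total_bp Ungapped genome length (excluding N bases).
#' @param digits Decimals to round to (default 2).
#' @return Percentage.
#' @examples
#' pg4_percentage(10002935, 2948583725)  # 0.34
#' @export
pg4_percentage <- function(pg4_bp, total_bp, digits = 2) {
  if (!is.finite(total_bp) || total_bp <= 0) {
    stop("total_bp must be positive")
  }
  round(100 * pg4_bp / total_bp, digits)
}

#' Ungapped length of a genome
#'
#' Total number of non-N bases across all sequences.
#' @inheritParams scan_genome
#' @return Numeric base count.
#' @export
ungapped_length <- function(genome) {
  genome <- as_genome(genome)
  if (!length(genome)) return(0)
  set <- Biostrings::DNAStringSet(toupper(unname(genome)))
  sum(nchar(genome)) - sum(Biostrings::letterFrequency(set, "N")[, 1L])
}

#' Fraction of a genome covered by pG4 motifs
#'
#' `100 * merged_pg4_bp(hits) / ungapped_length(genome)`, the per-assembly
#' "percentage with pG4" statistic.
#'
#' @inheritParams scan_genome
#' @param hits Hits from [scan_genome()].
#' @param digits Decimals to round to (default 2).
#' @return Percentage of ungapped bases covered.
#' @export
pg4_fraction <- function(genome, hits, digits = 2) {
  pg4_percentage(merged_pg4_bp(hits), ungapped_length(genome), digits)
}
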