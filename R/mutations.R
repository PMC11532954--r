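# Mutation-catalog intersection, stability stratification, hotspot ranking
# and per-substitution secondary-structure impact calls.

mutation_span <- function(muts) {
  w <- ifelse(muts$mut_type %in% c("substitution", "deletion"),
              nchar(muts$ref), 1L)
  if (any(muts$mut_type %in% c("substitution", "deletion") &
          (is.na(muts$ref) | muts$ref == ""))) {
    stop("ref must be non-empty for substitutions and deletions")
  }
  data.frame(start = muts$pos, end = muts$pos + w)
}

#' Annotate mutations with the pG4 hit they overlap
#'
#' A mutation overlaps a pG4 when any affected reference base lies within
#' the hit interval: the substituted base(s) for substitutions, the deleted
#' span for deletions, the insertion point for insertions and duplications.
#' When a mutation touches several hits the first by coordinate is
#' recorded.
#'
#' @param muts Mutation data frame (`chrom`, `pos` 0-based, `ref`, `alt`,
#'   `mut_type`, `source`, `label`, `sample_id`).
#' @param hits Hits from [scan_genome()].
#' @return `muts` with an added integer column `pg4_id` (row index into
#'   `hits`, NA when outside every hit).
#' @export
intersect_mutations <- function(muts, hits) {
  muts$pg4_id <- NA_integer_
  if (!nrow(muts) || !nrow(hits)) return(muts)
  span <- mutation_span(muts)
  for (chr in intersect(unique(muts$chrom), unique(hits$chrom))) {
    im <- which(muts$chrom == chr); ih <- which(hits$chrom == chr)
    rm_ <- IRanges::IRanges(span$start[im] + 1L, span$end[im])
    rh <- IRanges::IRanges(hits$start[ih] + 1L, hits$end[ih])
    ov_all <- IRanges::findOverlaps(rm_, rh)
    if (length(ov_all)) {
      q <- S4Vectors::queryHits(ov_all); s <- S4Vectors::subjectHits(ov_all)
      first_by_coord <- tapply(ih[s], q, function(v) v[which.min(hits$start[v])])
      muts$pg4_id[im[as.integer(names(first_by_coord))]] <-
        as.integer(first_by_coord)
    }
  }
  muts
}

#' Deduplication key for a mutation record
#'
#' Germline records are unique by genomic change (chrom, pos, ref, alt);
#' somatic records additionally by sample, so the same variant seen in two
#' tumour samples counts twice.
#'
#' @param muts Mutation data frame with a `source` column.
#' @return Character vector of keys, one per row.
#' @export
uniqueness_key <- function(muts) {
  base <- paste(muts$chrom, muts$pos, muts$ref, muts$alt, sep = ":")
  som <- muts$source == "somatic"
  if (any(som & (is.na(muts$sample_id) | muts$sample_id == ""))) {
    stop("somatic records require a sample_id")
  }
  ifelse(som, paste(base, muts$sample_id, sep = ":"), base)
}

#' Stratify pG4 hits by stability score
#'
#' Splits hits into stable (Q-score >= threshold) and unstable sets.
#' Q-scores are consumed as input (BED score column or `q_score` column);
#' hits without a score are excluded and counted.
#'
#' @param hits Hits with a `q_score` column.
#' @param threshold Stability threshold (default 19; boundary inclusive).
#' @return List `stable`, `unstable` (hit frames), `stable_fraction`,
#'   `n_missing`.
#' @export
stability_stratify <- function(hits, threshold = 19) {
  q <- hits$q_score
  if (is.null(q)) q <- rep(NA_real_, nrow(hits))
  miss <- !is.finite(q)
  if (all(miss)) {
    warning("no Q-scores present; empty stratification")
    return(list(stable = hits[0, , drop = FALSE],
                unstable = hits[0, , drop = FALSE],
                stable_fraction = NA_real_, n_missing = sum(miss)))
  }
  scored <- hits[!miss, , drop = FALSE]
  stable <- scored[scored$q_score >= threshold, , drop = FALSE]
  unstable <- scored[scored$q_score < threshold, , drop = FALSE]
  list(stable = stable, unstable = unstable,
       stable_fraction = nrow(stable) / nrow(scored),
       n_missing = sum(miss))
}

#' Rank pG4 hotspots by unique mutation load
#'
#' Counts unique mutations (per [uniqueness_key()]) per overlapped pG4 and
#' ranks descending, ties broken by coordinate. Also tabulates per-site
#' recurrence of short indels (deletions/insertions/duplications), the
#' route used to survey recurrent small-indel hotspots.
#'
#' @param annotated Mutations annotated by [intersect_mutations()].
#' @param hits The hits frame the annotation refers to.
#' @return List `pg4_ranking` (frame `pg4_id`, `chrom`, `start`, `end`,
#'   `n_unique`) and `indel_recurrence` (frame `chrom`, `pos`, `mut_type`,
#'   `n_unique`).
#' @export
hotspot_rank <- function(annotated, hits) {
  inpg4 <- annotated[!is.na(annotated$pg4_id), , drop = FALSE]
  if (nrow(inpg4)) {
    keys <- uniqueness_key(inpg4)
    per <- tapply(keys, inpg4$pg4_id, function(k) length(unique(k)))
    ids <- as.integer(names(per))
    rank <- data.frame(pg4_id = ids, chrom = hits$chrom[ids],
                       start = hits$start[ids], end = hits$end[ids],
                       n_unique = as.integer(per))
    rank <- rank[order(-rank$n_unique, rank$chrom, rank$start), ,
                 drop = FALSE]
    rownames(rank) <- NULL
  } else {
    rank <- data.frame(pg4_id = integer(0), chrom = character(0),
                       start = integer(0), end = integer(0),
                       n_unique = integer(0))
  }
  ind <- annotated[annotated$mut_type %in%
                     c("deletion", "insertion", "duplication"), ,
                   drop = FALSE]
  if (nrow(ind)) {
    key <- paste(ind$chrom, ind$pos, ind$mut_type, sep = "\r")
    per <- tapply(uniqueness_key(ind), key, function(k) length(unique(k)))
    parts <- strsplit(names(per), "\r", fixed = TRUE)
    rec <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                      pos = as.integer(vapply(parts, `[`, "", 2L)),
                      mut_type = vapply(parts, `[`, "", 3L),
                      n_unique = as.integer(per))
    rec <- rec[order(-rec$n_unique, rec$chrom, rec$pos), , drop = FALSE]
    rownames(rec) <- NULL
  } else {
    rec <- data.frame(chrom = character(0), pos = integer(0),
                      mut_type = character(0), n_unique = integer(0))
  }
  list(pg4_ranking = rank, indel_recurrence = rec)
}

summarize_folding <- function(fr) {
  if (is.null(fr) || !nrow(fr$structures)) {
    return(list(dg = 0, tm = 0, n = 0L))
  }
  list(dg = min(fr$structures$dg), tm = max(fr$structures$tm),
       n = nrow(fr$structures))
}

arrow <- function(delta, eps) {
  if (delta > eps) "up" else if (delta < -eps) "down" else "equal"
}

#' Classify a substitution's effect on predicted secondary structure
#'
#' Folds the wild-type sequence (a pG4 extended by flanks) and the mutant
#' through a folding adapter, summarizes each as (minimum free energy
#' deltaG, maximum melting temperature, number of structures), and calls a
#' direction arrow per metric. The Tm and structure-count arrows follow the
#' raw metric direction; the deltaG arrow is expressed as G4/structure
#' *stability* direction, i.e. "down" when the mutant deltaG is weaker
#' (less negative by more than `eps_dg`).
#'
#' @param wt_seq Wild-type sequence (pG4 plus flanks, motif-strand bases).
#' @param pos 0-based offset of the substituted base within `wt_seq`.
#' @param ref,alt Single reference/alternative bases; `ref` must match the
#'   sequence.
#' @param adapter Folding adapter: function(sequence) returning a
#'   [folding_result()] (e.g. [naive_fold()], or a wrapper re-ingesting an
#'   external engine's output).
#' @param eps_dg,eps_tm Equality tolerances: 0.01 kcal/mol and 0.1 degC by
#'   default (the metric precision of typical folding engines); the
#'   structure count compares exactly.
#' @return Object of class `impact_call`: `stability`, `tm`, `n` arrows
#'   (down/equal/up), metric deltas, and the wild-type/mutant summaries.
#' @export
substitution_impact <- function(wt_seq, pos, ref, alt, adapter,
                                eps_dg = 0.01, eps_tm = 0.1) {
  wt_seq <- toupper(wt_seq)
  ref <- toupper(ref); alt <- toupper(alt)
  have <- substr(wt_seq, pos + 1L, pos + 1L)
  if (have != ref) {
    stop(sprintf("ref mismatch at offset %d: sequence has '%s', record '%s'",
                 pos, have, ref))
  }
  mut_seq <- wt_seq
  substr(mut_seq, pos + 1L, pos + 1L) <- alt
  wt <- summarize_folding(adapter(wt_seq))
  mu <- summarize_folding(adapter(mut_seq))
  d_dg <- mu$dg - wt$dg
  d_tm <- mu$tm - wt$tm
  d_n <- mu$n - wt$n
  structure(list(
    # deltaG up (less negative) = weaker structure = stability down
    stability = c(up = "down", down = "up", equal = "equal")[[arrow(d_dg, eps_dg)]],
    tm = arrow(d_tm, eps_tm),
    n = arrow(d_n, 0),
    delta_dg = d_dg, delta_tm = d_tm, delta_n = d_n,
    wt = wt, mut = mu), class = "impact_call")
}

#' @export
print.impact_call <- function(x, ...) {
  cat(sprintf("impact: stability %s (ddG %+.2f), Tm %s (%+.1f), N %s (%+d)\n",
              x$stability, x$delta_dg, x$tm, x$delta_tm, x$n, x$delta_n))
  invisible(x)
}

as_arrow_frame <- function(calls) {
  if (is.data.frame(calls)) {
    stopifnot(all(c("stability", "tm", "n") %in% names(calls)))
    return(calls[, c("stability", "tm", "n")])
  }
  data.frame(stability = vapply(calls, `[[`, "", "stability"),
             tm = vapply(calls, `[[`, "", "tm"),
             n = vapply(calls, `[[`, "", "n"))
}

#' Tally impact calls
#'
#' Counts of substitutions decreasing structure stability, decreasing
#' melting temperature, decreasing structure count, and altering at least
#' one of the three metrics.
#'
#' @param calls A list of [substitution_impact()] calls, or a data frame
#'   with arrow columns `stability`, `tm`, `n` (values down/equal/up).
#' @return Named integer vector: `stability_down`, `tm_down`, `n_down`,
#'   `any_changed`.
#' @export
tally_impacts <- function(calls) {
  a <- as_arrow_frame(calls)
  bad <- !unlist(a) %in% c("down", "equal", "up")
  if (any(bad)) stop("arrows must be one of down/equal/up")
  c(stability_down = sum(a$stability == "down"),
    tm_down = sum(a$tm == "down"),
    n_down = sum(a$n == "down"),
    any_changed = sum(a$stability != "equal" | a$tm != "equal" |
                        a$n != "equal"))
}

#' Read a table of published substitution impact arrows
#'
#' Parses a TSV with one row per substitution and raw metric-direction
#' columns `dg_dir`, `tm_dir`, `n_dir` (up/down/equal as printed for
#' minimum deltaG, maximum melting temperature, structure count). The raw
#' deltaG direction is converted into a stability arrow (deltaG up = less
#' negative = stability down) so the result feeds [tally_impacts()]
#' directly.
#'
#' @param path TSV path with header.
#' @return Data frame with the original columns plus `stability`, `tm`,
#'   `n` arrow columns.
#' @export
read_impact_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("dg_dir", "tm_dir", "n_dir")
  if (!all(need %in% names(tab))) {
    stop("impact table needs columns: ", paste(need, collapse = ", "))
  }
  flip <- c(up = "down", down = "up", equal = "equal")
  tab$stability <- unname(flip[tab$dg_dir])
  tab$tm <- tab$tm_dir
  tab$n <- tab$n_dir
  tab
}
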