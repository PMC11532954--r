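# Seeded synthetic-data generators with planted ground truth for every
# downstream stage: genome + pG4 motifs, gene models + EST starts, paired
# tumor/normal expression, mutation catalogs with hotspots.

#' Simulation configuration
#'
#' One root `seed` streams per-component sub-seeds (genome, annotation,
#' expression, mutations) so components can be regenerated independently
#' and every output is byte-reproducible. The defaults emulate the
#' statistical structure of the real inputs: pG4 motif density 0.34% of
#' bases (the human genome-wide figure), an EST start-site pG4 overlap
#' fraction of 0.63%, paired tumor/normal log-normal expression with a
#' higher-expressed / lower-CV pG4 gene set (target indiv-CV 30% versus
#' 60%), and uniform background mutations with a configurable pG4
#' enrichment fold and plantable recurrent hotspots.
#'
#' @param seed Root integer seed.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param gc_content Background G+C fraction in (0, 1).
#' @param pg4_density Target fraction of bases covered by pG4 motifs.
#' @param scan [scan_params()] defining the planted motif family.
#' @param n_genes,exons_per_gene,exon_length,intron_length,intergenic Gene
#'   model geometry: gene count, exon-count choices, and ranges (min, max)
#'   for exon/intron/intergenic lengths.
#' @param n_ests Number of EST start records.
#' @param est_pg4_overlap Fraction of EST starts planted inside pG4
#'   intervals (each EST independently).
#' @param expression List: `n_genes_per_set`, `n_patients`, `mean_fpkm`
#'   (named: pg4, non_pg4), `between_gene_sd` (log-scale SD of gene means
#'   within each set; smaller for the pG4 set so its g-CV is lower),
#'   `cv_pct` (target per-gene CV across patients), `tumor_log2_shift`
#'   (mean, sd of the per-gene tumor shift in log2 units),
#'   `tumor_dispersion` (multiplier on within-gene SD in tumors),
#'   `tumor_between_shrink` (named: pg4, non_pg4; shrinkage of each
#'   gene's total tumor deviation from the set center, baseline plus
#'   tumor-specific shift — < 1 plants a tumor g-CV reduction).
#' @param mutation List: `n`, `pg4_fold` (per-base rate ratio inside pG4),
#'   `source`, `hotspot` (NULL or list(chrom, pos, recurrence, mut_type)).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 100000L),
                       gc_content = 0.41,
                       pg4_density = 0.0034,
                       scan = scan_params(),
                       n_genes = 30L,
                       exons_per_gene = 2:6,
                       exon_length = c(100L, 250L),
                       intron_length = c(150L, 600L),
                       intergenic = c(200L, 800L),
                       n_ests = 5000L,
                       est_pg4_overlap = 0.0063,
                       expression = list(),
                       mutation = list()) {
  expr_default <- list(n_genes_per_set = 200L, n_patients = 200L,
                       mean_fpkm = c(pg4 = 50, non_pg4 = 20),
                       between_gene_sd = c(pg4 = 0.5, non_pg4 = 1.0),
                       cv_pct = c(pg4 = 30, non_pg4 = 60),
                       tumor_log2_shift = c(mean = 0.5, sd = 0.25),
                       tumor_dispersion = 1.1,
                       tumor_between_shrink = c(pg4 = 0.8, non_pg4 = 1.0))
  mut_default <- list(n = 5000L, pg4_fold = 1, source = "somatic",
                      hotspot = NULL)
  expression <- utils::modifyList(expr_default, expression)
  mutation <- utils::modifyList(mut_default, mutation,
                                keep.null = TRUE)
  stopifnot(gc_content > 0, gc_content < 1,
            pg4_density >= 0, pg4_density <= 1,
            est_pg4_overlap >= 0, est_pg4_overlap <= 1,
            all(chrom_lengths > 0))
  if (any(expression$cv_pct < 0)) stop("invalid CV target: must be >= 0")
  structure(list(seed = as.integer(seed),
                 chrom_lengths = chrom_lengths, gc_content = gc_content,
                 pg4_density = pg4_density, scan = scan,
                 n_genes = as.integer(n_genes),
                 exons_per_gene = exons_per_gene,
                 exon_length = exon_length, intron_length = intron_length,
                 intergenic = intergenic, n_ests = as.integer(n_ests),
                 est_pg4_overlap = est_pg4_overlap,
                 expression = expression, mutation = mutation),
            class = "sim_config")
}

derive_seeds <- function(seed) {
  set.seed(seed)
  s <- sample.int(2147483646L, 4L)
  names(s) <- c("genome", "annotation", "expression", "mutation")
  s
}

# both-strand regex reference scan, mapped to forward coordinates
regex_genome_scan <- function(genome, params) {
  out <- lapply(names(genome), function(chr) {
    plus <- scan_strand_regex(genome[[chr]], params)
    minus <- scan_strand_regex(revcomp(genome[[chr]]), params)
    L <- nchar(genome[[chr]])
    res <- rbind(
      if (nrow(plus)) cbind(plus, strand = "+") else NULL,
      if (nrow(minus)) data.frame(start = L - minus$end,
                                  end = L - minus$start, strand = "-")
      else NULL)
    if (is.null(res) || !nrow(res)) return(NULL)
    cbind(chrom = chr, res)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0))
  }
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

sample_motif <- function(params, minimal = FALSE) {
  k <- params$min_runs
  run <- strrep("G", params$min_run_length)
  loop_len <- if (minimal) rep(params$loop_min, k - 1L) else
    sample(seq(params$loop_min, params$loop_max), k - 1L, replace = TRUE)
  loops <- vapply(loop_len, function(l) {
    paste(sample(c("A", "C", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
  paste0(run, paste0(loops, run, collapse = ""))
}

#' Generate a genome with planted pG4 motifs
#'
#' Draws i.i.d. background sequence at the configured GC content, then
#' plants canonical motifs (loop bases drawn from A/C/T so runs cannot
#' extend) at non-overlapping positions until the target covered-base
#' density is reached, counting spurious background motifs toward the
#' target. A guard zone of `loop_max + 1` A/T bases on each side of every
#' planted motif prevents run extension or chaining into the flanks, so
#' planted motifs are recoverable at exact coordinates. The truth set is
#' annotated post hoc with the reference regex on both strands, so
#' legitimate spurious background motifs are part of the truth.
#'
#' @param cfg A [sim_config()].
#' @param seed Sub-seed (defaults to the genome stream of `cfg$seed`).
#' @return List `genome` (named character), `truth` (frame `chrom`,
#'   `start`, `end`, `strand` of all motifs), `planted` (frame of planted
#'   motifs only), `config`.
#' @export
gen_genome <- function(cfg, seed = derive_seeds(cfg$seed)[["genome"]]) {
  set.seed(seed)
  params <- cfg$scan
  guard <- params$loop_max + 1L
  min_len <- cfg$scan$min_runs * cfg$scan$min_run_length +
    (cfg$scan$min_runs - 1L) * cfg$scan$loop_min
  probs <- c((1 - cfg$gc_content) / 2, cfg$gc_content / 2,
             cfg$gc_content / 2, (1 - cfg$gc_content) / 2)
  genome <- character(0)
  planted <- list()
  for (chr in names(cfg$chrom_lengths)) {
    L <- cfg$chrom_lengths[[chr]]
    target_bp <- round(cfg$pg4_density * L)
    if (target_bp > 0.3 * L) {
      stop("pg4_density infeasible for chromosome length")
    }
    x <- sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = probs)
    spur <- regex_genome_scan(stats::setNames(paste(x, collapse = ""), chr),
                              params)
    occupied <- logical(L)
    if (nrow(spur)) {
      for (i in seq_len(nrow(spur))) {
        lo <- max(1L, spur$start[i] + 1L - guard)
        hi <- min(L, spur$end[i] + guard)
        occupied[lo:hi] <- TRUE
      }
    }
    existing_bp <- merged_pg4_bp(spur)
    remaining <- target_bp - existing_bp
    tries <- 0L
    while (remaining > 0) {
      motif <- sample_motif(params, minimal = remaining < min_len + 2L)
      len <- nchar(motif)
      if (L - len - 2L * guard < 1L) stop("chromosome too short to plant")
      pos <- sample.int(L - len - 2L * guard, 1L) + guard  # 0-based start
      window <- (pos - guard + 1L):(pos + len + guard)     # 1-based
      if (any(occupied[window])) {
        tries <- tries + 1L
        if (tries > 20000L) stop("pg4_density infeasible: no room to plant")
        next
      }
      strand <- sample(c("+", "-"), 1L)
      ins <- if (strand == "-") revcomp(motif) else motif
      x[(pos + 1L):(pos + len)] <- strsplit(ins, "")[[1L]]
      gl <- (pos - guard + 1L):pos
      gr <- (pos + len + 1L):(pos + len + guard)
      x[c(gl, gr)] <- sample(c("A", "T"), 2L * guard, replace = TRUE)
      occupied[window] <- TRUE
      planted[[length(planted) + 1L]] <-
        data.frame(chrom = chr, start = pos, end = pos + len,
                   strand = strand, stringsAsFactors = FALSE)
      remaining <- remaining - len
    }
    genome[chr] <- paste(x, collapse = "")
  }
  planted <- if (length(planted)) do.call(rbind, planted) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0))
  planted <- planted[order(planted$chrom, planted$start), , drop = FALSE]
  rownames(planted) <- NULL
  list(genome = genome, truth = regex_genome_scan(genome, params),
       planted = planted, config = cfg)
}

pg4_position_pool <- function(truth) {
  merged <- merged_hits_frame(truth)
  if (!nrow(merged)) {
    return(data.frame(chrom = character(0), pos = integer(0)))
  }
  do.call(rbind, lapply(seq_len(nrow(merged)), function(i) {
    data.frame(chrom = merged$chrom[i],
               pos = seq.int(merged$start[i], merged$end[i] - 1L),
               stringsAsFactors = FALSE)
  }))
}

sample_background_positions <- function(n, chrom_lengths, pg4_mask) {
  chroms <- names(chrom_lengths)
  pr <- chrom_lengths / sum(chrom_lengths)
  chrom <- sample(chroms, n, replace = TRUE, prob = pr)
  pos <- integer(n)
  for (i in seq_len(n)) {
    repeat {
      p <- sample.int(chrom_lengths[[chrom[i]]], 1L) - 1L
      if (!pg4_mask[[chrom[i]]][p + 1L]) break
    }
    pos[i] <- p
  }
  data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

pg4_masks <- function(truth, chrom_lengths) {
  masks <- lapply(chrom_lengths, function(L) logical(L))
  merged <- merged_hits_frame(truth)
  for (i in seq_len(nrow(merged))) {
    masks[[merged$chrom[i]]][(merged$start[i] + 1L):merged$end[i]] <- TRUE
  }
  masks
}

#' Generate gene models and EST start records
#'
#' Places non-overlapping multi-exon gene models along the chromosomes
#' (alternating random strand, CDS inside the terminal exons) and draws
#' EST start sites such that a fraction `est_pg4_overlap` of them
#' (independently per EST) fall inside true pG4 intervals, the rest
#' uniformly over non-pG4 bases.
#'
#' @param cfg A [sim_config()].
#' @param gen Output of [gen_genome()].
#' @param seed Sub-seed (defaults to the annotation stream).
#' @return List `models` ([gene_models()]), `ests` (frame `chrom`,
#'   `strand`, `start_site`, `in_pg4`).
#' @export
gen_annotation <- function(cfg, gen,
                           seed = derive_seeds(cfg$seed)[["annotation"]]) {
  set.seed(seed)
  rint <- function(rng) sample(seq(rng[1L], rng[2L]), 1L)
  rows <- list()
  gid <- 0L
  for (chr in names(cfg$chrom_lengths)) {
    L <- cfg$chrom_lengths[[chr]]
    pos <- rint(cfg$intergenic)
    while (gid < cfg$n_genes) {
      n_ex <- sample(cfg$exons_per_gene, 1L)
      ex_len <- vapply(seq_len(n_ex), function(i) rint(cfg$exon_length),
                       integer(1))
      in_len <- if (n_ex > 1L) {
        vapply(seq_len(n_ex - 1L), function(i) rint(cfg$intron_length),
               integer(1))
      } else integer(0)
      span <- sum(ex_len) + sum(in_len)
      if (pos + span >= L) break
      es <- pos + cumsum(c(0L, utils::head(ex_len, -1L) + in_len))
      ee <- es + ex_len
      cds_start <- es[1L] + ex_len[1L] %/% 3L
      cds_end <- ee[n_ex] - ex_len[n_ex] %/% 3L
      if (cds_start >= cds_end) { cds_start <- es[1L]; cds_end <- es[1L] }
      gid <- gid + 1L
      rows[[gid]] <- list(gene_id = sprintf("g%03d", gid), chrom = chr,
                          strand = sample(c("+", "-"), 1L),
                          tx_start = pos, tx_end = pos + span,
                          cds_start = cds_start, cds_end = cds_end,
                          exon_starts = es, exon_ends = ee)
      pos <- pos + span + rint(cfg$intergenic)
    }
    if (gid >= cfg$n_genes) break
  }
  if (gid < cfg$n_genes) {
    stop("too many genes for genome length: placed ", gid, " of ",
         cfg$n_genes)
  }
  models <- gene_models(
    gene_id = vapply(rows, `[[`, "", "gene_id"),
    chrom = vapply(rows, `[[`, "", "chrom"),
    strand = vapply(rows, `[[`, "", "strand"),
    tx_start = vapply(rows, `[[`, 0L, "tx_start"),
    tx_end = vapply(rows, `[[`, 0L, "tx_end"),
    cds_start = vapply(rows, `[[`, 0L, "cds_start"),
    cds_end = vapply(rows, `[[`, 0L, "cds_end"),
    exon_starts = lapply(rows, `[[`, "exon_starts"),
    exon_ends = lapply(rows, `[[`, "exon_ends"))

  pool <- pg4_position_pool(gen$truth)
  if (cfg$est_pg4_overlap > 0 && !nrow(pool)) {
    stop("no pG4 intervals to place EST starts in")
  }
  masks <- pg4_masks(gen$truth, cfg$chrom_lengths)
  n <- cfg$n_ests
  in_pg4 <- stats::rbinom(n, 1L, cfg$est_pg4_overlap) == 1L
  ests <- data.frame(chrom = character(n), strand = character(n),
                     start_site = integer(n), in_pg4 = in_pg4,
                     stringsAsFactors = FALSE)
  n_in <- sum(in_pg4)
  if (n_in) {
    take <- sample.int(nrow(pool), n_in, replace = TRUE)
    ests$chrom[in_pg4] <- pool$chrom[take]
    ests$start_site[in_pg4] <- pool$pos[take]
  }
  if (n - n_in) {
    bg <- sample_background_positions(n - n_in, cfg$chrom_lengths, masks)
    ests$chrom[!in_pg4] <- bg$chrom
    ests$start_site[!in_pg4] <- bg$pos
  }
  ests$strand <- sample(c("+", "-"), n, replace = TRUE)
  list(models = models, ests = ests)
}

#' Generate a paired tumor/normal expression matrix
#'
#' Log-normal fpkm values. Gene means (log scale) are drawn per set around
#' the set's mean fpkm with a set-specific between-gene SD; within-gene
#' (across-patient) SD is set from the target CV via
#' `sigma = sqrt(log(1 + (cv/100)^2))`, so the linear-scale CV of each
#' gene equals its target in expectation. Tumor samples add a per-gene
#' log2 shift, multiply the within-gene SD by `tumor_dispersion`, and
#' shrink the between-gene spread by `tumor_between_shrink` (per set),
#' which plants the tumor g-CV reduction for the pG4 set.
#'
#' @param cfg A [sim_config()].
#' @param pg4_genes,non_pg4_genes Disjoint gene-id vectors; defaults are
#'   synthesized from `cfg$expression$n_genes_per_set`.
#' @param seed Sub-seed (defaults to the expression stream).
#' @return An [expression_matrix()] with attributes `pg4_genes`,
#'   `non_pg4_genes`.
#' @export
gen_expression <- function(cfg, pg4_genes = NULL, non_pg4_genes = NULL,
                           seed = derive_seeds(cfg$seed)[["expression"]]) {
  set.seed(seed)
  e <- cfg$expression
  if (any(e$cv_pct < 0)) stop("invalid CV target: must be >= 0")
  if (is.null(pg4_genes)) {
    pg4_genes <- sprintf("pg4_g%04d", seq_len(e$n_genes_per_set))
  }
  if (is.null(non_pg4_genes)) {
    non_pg4_genes <- sprintf("bg_g%04d", seq_len(e$n_genes_per_set))
  }
  if (length(intersect(pg4_genes, non_pg4_genes))) {
    stop("gene sets must be disjoint")
  }
  genes <- c(pg4_genes, non_pg4_genes)
  grp <- rep(c("pg4", "non_pg4"), c(length(pg4_genes),
                                    length(non_pg4_genes)))
  ng <- length(genes); np <- e$n_patients
  center <- log(e$mean_fpkm[grp])
  mu_g <- center + stats::rnorm(ng, 0, e$between_gene_sd[grp])
  sigma_w <- sqrt(log1p((e$cv_pct[grp] / 100)^2))
  normal <- exp(matrix(mu_g, ng, np) +
                  matrix(stats::rnorm(ng * np), ng, np) * sigma_w)
  # the tumor's gene-level deviation (baseline deviation + tumor-specific
  # shift) is shrunk as a whole, so a shrink < 1 plants a between-gene
  # spread (g-CV) reduction that the per-gene shifts cannot undo
  shift_dev <- stats::rnorm(ng, 0, e$tumor_log2_shift[["sd"]]) * log(2)
  mu_t <- center + e$tumor_log2_shift[["mean"]] * log(2) +
    e$tumor_between_shrink[grp] * (mu_g - center + shift_dev)
  sigma_t <- sigma_w * e$tumor_dispersion
  tumor <- exp(matrix(mu_t, ng, np) +
                 matrix(stats::rnorm(ng * np), ng, np) * sigma_t)
  values <- cbind(normal, tumor)
  patients <- sprintf("P%03d", seq_len(np))
  colnames(values) <- c(paste0(patients, "_N"), paste0(patients, "_T"))
  rownames(values) <- genes
  meta <- data.frame(sample = colnames(values), tissue = "synthetic",
                     condition = rep(c("normal", "tumor"), each = np),
                     patient = rep(patients, 2L),
                     stringsAsFactors = FALSE)
  m <- expression_matrix(values, meta)
  attr(m, "pg4_genes") <- pg4_genes
  attr(m, "non_pg4_genes") <- non_pg4_genes
  m
}

#' Generate a mutation catalog with pG4 enrichment and hotspots
#'
#' Background substitutions fall uniformly over non-pG4 bases; the pG4
#' per-base rate is inflated by `pg4_fold`, so the probability that a
#' mutation lands inside pG4 is `f q / (f q + 1 - q)` with `q` the pG4
#' base fraction. An optional hotspot plants exact recurrences of one
#' indel at one site with distinct sample ids.
#'
#' @param cfg A [sim_config()].
#' @param gen Output of [gen_genome()].
#' @param seed Sub-seed (defaults to the mutation stream).
#' @return Mutation data frame (see [read_mutations_tsv()] for columns).
#' @export
gen_mutations <- function(cfg, gen,
                          seed = derive_seeds(cfg$seed)[["mutation"]]) {
  set.seed(seed)
  mcfg <- cfg$mutation
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      mut_type = character(0), source = character(0),
                      label = character(0), sample_id = character(0),
                      stringsAsFactors = FALSE)
  out <- empty
  n <- mcfg$n
  if (n > 0) {
    pool <- pg4_position_pool(gen$truth)
    masks <- pg4_masks(gen$truth, cfg$chrom_lengths)
    L_total <- sum(cfg$chrom_lengths)
    q <- nrow(pool) / L_total
    f <- mcfg$pg4_fold
    p_in <- f * q / (f * q + (1 - q))
    in_flag <- stats::rbinom(n, 1L, p_in) == 1L
    chrom <- character(n); pos <- integer(n)
    if (any(in_flag)) {
      take <- sample.int(nrow(pool), sum(in_flag), replace = TRUE)
      chrom[in_flag] <- pool$chrom[take]
      pos[in_flag] <- pool$pos[take]
    }
    if (any(!in_flag)) {
      bg <- sample_background_positions(sum(!in_flag), cfg$chrom_lengths,
                                        masks)
      chrom[!in_flag] <- bg$chrom
      pos[!in_flag] <- bg$pos
    }
    ref <- vapply(seq_len(n), function(i) {
      substr(gen$genome[[chrom[i]]], pos[i] + 1L, pos[i] + 1L)
    }, character(1))
    alt <- vapply(ref, function(r) {
      sample(setdiff(c("A", "C", "G", "T"), r), 1L)
    }, character(1))
    out <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                      mut_type = "substitution", source = mcfg$source,
                      label = sample(c("large_intestine", "skin", "stomach",
                                       "liver", "breast"), n,
                                     replace = TRUE),
                      sample_id = if (mcfg$source == "somatic") {
                        sprintf("S%05d", seq_len(n))
                      } else NA_character_,
                      stringsAsFactors = FALSE)
  }
  hs <- mcfg$hotspot
  if (!is.null(hs)) {
    if (!hs$chrom %in% names(cfg$chrom_lengths) ||
        hs$pos < 0 || hs$pos >= cfg$chrom_lengths[[hs$chrom]]) {
      stop("hotspot outside the genome")
    }
    type <- if (is.null(hs$mut_type)) "deletion" else hs$mut_type
    ref <- substr(gen$genome[[hs$chrom]], hs$pos + 1L, hs$pos + 2L)
    rows <- data.frame(chrom = hs$chrom, pos = hs$pos, ref = ref,
                       alt = "", mut_type = type, source = mcfg$source,
                       label = "hotspot",
                       sample_id = if (mcfg$source == "somatic") {
                         sprintf("H%04d", seq_len(hs$recurrence))
                       } else NA_character_,
                       stringsAsFactors = FALSE)
    out <- rbind(out, rows)
  }
  rownames(out) <- NULL
  out
}

#' Run every generator under one configuration
#'
#' Streams the root seed into the four component generators, partitions
#' the annotated genes by pG4 overlap of the transcript span, and builds
#' the expression matrix over synthetic gene sets sized per the
#' configuration.
#'
#' @param cfg A [sim_config()].
#' @return List `genome`, `truth`, `planted`, `models`, `ests`, `expr`,
#'   `muts`, `pg4_genes`, `non_pg4_genes`, `config`, `seeds`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  seeds <- derive_seeds(cfg$seed)
  gen <- gen_genome(cfg, seeds[["genome"]])
  ann <- gen_annotation(cfg, gen, seeds[["annotation"]])
  tx <- data.frame(chrom = ann$models$chrom, start = ann$models$tx_start,
                   end = ann$models$tx_end)
  tx_sorted <- order(tx$chrom, tx$start)
  ov <- intersect_ranges(tx[tx_sorted, , drop = FALSE],
                         merged_hits_frame(gen$truth))
  with_genes <- unique(ann$models$gene_id[tx_sorted][ov$a_idx])
  expr <- gen_expression(cfg, seed = seeds[["expression"]])
  muts <- gen_mutations(cfg, gen, seeds[["mutation"]])
  list(genome = gen$genome, truth = gen$truth, planted = gen$planted,
       models = ann$models, ests = ann$ests, expr = expr, muts = muts,
       pg4_genes = sort(with_genes),
       non_pg4_genes = sort(setdiff(unique(ann$models$gene_id),
                                    with_genes)),
       config = cfg, seeds = seeds)
}
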