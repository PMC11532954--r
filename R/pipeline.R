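# End-to-end driver: simulate -> scan -> genome stats -> features ->
# splice profile -> expression -> mutations -> hairpin context.

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis on synthetic data
#'
#' Executes the stages in dependency order on a freshly simulated dataset:
#' pG4 scan, genome-level statistics (covered bp, genome fraction, EST
#' start overlap with Fisher test and enrichment factor), per-feature gene
#' partitions, the splice-site profile with its fold-enrichment peaks,
#' expression statistics (level contrast, tumor/normal log2 fold change,
#' indiv-CV, g-CV with the paired tumor/normal test), mutation overlap
#' with hotspot ranking, and the binned deltaG landscape via the naive
#' folding adapter. When `out_dir` is given, per-stage TSV/JSON reports
#' and a run manifest (parameters, seed, file checksums, version,
#' timestamp) are written there.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Optional output directory (created if missing).
#' @param splice_window Half-window for the splice profile (default 500,
#'   sized for synthetic intron lengths).
#' @return A list of per-stage reports (invisibly returns the same list
#'   after writing when `out_dir` is set).
#' @export
run_pipeline <- function(cfg = sim_config(), out_dir = NULL,
                         splice_window = 500L) {
  sim <- run_stage("simulate", simulate_study(cfg))
  hits <- run_stage("scan", scan_genome(sim$genome, cfg$scan))

  genome_stats <- run_stage("genome_stats", {
    bp <- merged_pg4_bp(hits)
    ung <- ungapped_length(sim$genome)
    frac <- pg4_percentage(bp, ung)
    est <- est_tss_overlap(sim$ests, hits)
    est_pct <- round(100 * est$n_in_pg4 / est$n_total, 2)
    fisher_p <- fisher_2x2(est$n_in_pg4, est$n_total - est$n_in_pg4,
                           bp, ung - bp)
    list(pg4_bp = bp, ungapped_bp = ung, pg4_pct = frac,
         n_hits = nrow(hits), est_in_pg4 = est$n_in_pg4,
         est_total = est$n_total, est_pct = est_pct,
         est_fisher_p = fisher_p,
         est_enrichment_factor = enrichment_factor(est_pct, frac))
  })

  features <- run_stage("features", {
    out <- lapply(names(feature_name_map), function(f) {
      part <- partition_genes(sim$models, hits, f)
      data.frame(feature = f, n_with = length(part$with),
                 n_without = length(part$without))
    })
    do.call(rbind, out)
  })

  splice <- run_stage("splice_profile", {
    prof <- splice_profile(sim$models, hits, window = splice_window)
    enr <- profile_enrichment(prof)
    list(profile = prof, peak_5p = enr$peak_5p, peak_3p = enr$peak_3p,
         peak_fold_5p = enr$peak_fold_5p, peak_fold_3p = enr$peak_fold_3p)
  })

  expression <- run_stage("expression", {
    m <- sim$expr
    pg4 <- attr(m, "pg4_genes"); non <- attr(m, "non_pg4_genes")
    lev_n <- log_mean_expression(m, condition = "normal")
    cmp <- group_compare(lev_n[pg4], lev_n[non])
    fc <- tumor_normal_log2fc(m, pg4, non)
    cv_n <- indiv_cv(m, "normal")
    gcv_n_pg4 <- g_cv(m, pg4, "normal")
    gcv_t_pg4 <- g_cv(m, pg4, "tumor")
    names(gcv_n_pg4$cv) <- m$meta$patient[match(names(gcv_n_pg4$cv),
                                                m$meta$sample)]
    names(gcv_t_pg4$cv) <- m$meta$patient[match(names(gcv_t_pg4$cv),
                                                m$meta$sample)]
    paired <- paired_condition_test(gcv_n_pg4$cv, gcv_t_pg4$cv)
    list(level_median_pg4 = cmp$median_with,
         level_median_non = cmp$median_without, level_p = cmp$p,
         log2fc_contrast_p = fc$contrast$p,
         indiv_cv_median = stats::median(cv_n$cv),
         gcv_paired_p = paired$p, gcv_direction = paired$direction)
  })

  mutations <- run_stage("mutations", {
    ann <- intersect_mutations(sim$muts, hits)
    n_in <- sum(!is.na(ann$pg4_id))
    enr <- overlap_enrichment(n_in, nrow(ann),
                              genome_stats$pg4_bp,
                              genome_stats$ungapped_bp)
    ranks <- hotspot_rank(ann, hits)
    list(n_mutations = nrow(ann), n_in_pg4 = n_in, fold = enr$fold,
         p = enr$p, top_hotspots = utils::head(ranks$pg4_ranking, 5L))
  })

  hairpin <- run_stage("hairpin", {
    bins <- score_bins(bin_genome(sim$genome), sim$genome, naive_fold)
    hist <- dg_histogram(bins)
    top <- if (nrow(mutations$top_hotspots)) {
      h <- mutations$top_hotspots[1L, ]
      tryCatch(locate_hotspot(h$chrom, h$start, h$end, bins),
               error = function(e) NULL)
    } else NULL
    list(n_scored = sum(is.finite(bins$dg)), histogram = hist,
         hotspot_context = top)
  })

  report <- list(config = cfg, genome_stats = genome_stats,
                 features = features, splice = splice,
                 expression = expression, mutations = mutations,
                 hairpin = hairpin)
  if (!is.null(out_dir)) {
    write_pipeline_reports(report, sim, hits, out_dir)
  }
  report
}

numeric_report <- function(report) {
  flat <- c(report$genome_stats[c("pg4_bp", "ungapped_bp", "pg4_pct",
                                  "n_hits", "est_in_pg4", "est_total",
                                  "est_pct", "est_fisher_p",
                                  "est_enrichment_factor")],
            list(splice_peak_5p = report$splice$peak_5p,
                 splice_peak_3p = report$splice$peak_3p),
            report$expression[c("level_median_pg4", "level_median_non",
                                "level_p", "indiv_cv_median",
                                "gcv_paired_p")],
            report$mutations[c("n_mutations", "n_in_pg4", "fold", "p")],
            list(dg_mode = report$hairpin$histogram$summary$mode_center,
                 dg_mean = report$hairpin$histogram$summary$mean,
                 dg_median = report$hairpin$histogram$summary$median))
  flat[!vapply(flat, is.null, logical(1))]
}

write_pipeline_reports <- function(report, sim, hits, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(out_dir, "genome.fa"),
    hits = file.path(out_dir, "hits.bed"),
    truth = file.path(out_dir, "truth.bed"),
    genes = file.path(out_dir, "genes.refflat"),
    features = file.path(out_dir, "feature_partitions.tsv"),
    profile = file.path(out_dir, "splice_profile.tsv"),
    histogram = file.path(out_dir, "dg_histogram.tsv"),
    summary = file.path(out_dir, "summary.json"))
  write_fasta(sim$genome, paths[["fasta"]])
  write_hits_bed(hits, paths[["hits"]])
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_refflat(sim$models, paths[["genes"]])
  utils::write.table(report$features, paths[["features"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  prof <- report$splice$profile
  utils::write.table(data.frame(offset = prof$offsets,
                                count_5p = prof$counts_5p,
                                count_3p = prof$counts_3p),
                     paths[["profile"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(report$hairpin$histogram$edges, paths[["histogram"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(numeric_report(report), paths[["summary"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    command = "run_pipeline",
    tool_version = as.character(utils::packageVersion("g4scape")),
    seed = report$config$seed,
    parameters = list(chrom_lengths = as.list(report$config$chrom_lengths),
                      gc_content = report$config$gc_content,
                      pg4_density = report$config$pg4_density),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    checksums = {
      sums <- tools::md5sum(unname(paths[names(paths) != "summary"]))
      names(sums) <- basename(names(sums))
      as.list(sums)
    })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
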