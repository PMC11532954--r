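test_that("genome generation is deterministic and respects density", {
  cfg <- sim_config(seed = 1, chrom_lengths = c(chr1 = 30000L))
  g1 <- gen_genome(cfg)
  g2 <- gen_genome(cfg)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$truth, g2$truth)

  none <- gen_genome(sim_config(seed = 2, pg4_density = 0,
                                chrom_lengths = c(chr1 = 5000L)))
  expect_equal(nrow(none$planted), 0L)

  expect_error(gen_genome(sim_config(seed = 3, pg4_density = 0.5,
                                     chrom_lengths = c(chr1 = 5000L))),
               "infeasible")
})

test_that("planted motifs are recovered exactly by the scanner", {
  cfg <- sim_config(seed = 1)
  gen <- gen_genome(cfg)
  hits <- scan_genome(gen$genome, cfg$scan)
  key <- function(d) paste(d$chrom, d$start, d$end, d$strand)
  expect_true(all(key(gen$planted) %in% key(hits)))
  # scanner and truth annotation agree on the whole genome
  expect_identical(key(hits), key(gen$truth))
  target <- cfg$pg4_density * sum(cfg$chrom_lengths)
  expect_lt(abs(merged_pg4_bp(hits) - target) / target, 0.1)
})

test_that("EST overlap fraction is plantable across its whole range", {
  cfg0 <- sim_config(seed = 7, chrom_lengths = c(chr1 = 30000L),
                     n_genes = 8L, n_ests = 300L, est_pg4_overlap = 0)
  gen <- gen_genome(cfg0)
  ann0 <- gen_annotation(cfg0, gen)
  hits <- scan_genome(gen$genome)
  expect_equal(est_tss_overlap(ann0$ests, hits)$n_in_pg4, 0L)

  cfg1 <- sim_config(seed = 7, chrom_lengths = c(chr1 = 30000L),
                     n_genes = 8L, n_ests = 300L, est_pg4_overlap = 1)
  ann1 <- gen_annotation(cfg1, gen)
  ov1 <- est_tss_overlap(ann1$ests, hits)
  expect_equal(ov1$n_in_pg4, 300L)

  cfgf <- sim_config(seed = 7, n_ests = 10000L, est_pg4_overlap = 0.2)
  genf <- gen_genome(cfgf)
  annf <- gen_annotation(cfgf, genf)
  ovf <- est_tss_overlap(annf$ests, scan_genome(genf$genome))
  f_hat <- ovf$n_in_pg4 / ovf$n_total
  expect_lt(abs(f_hat - 0.2), 3 * sqrt(0.2 * 0.8 / 10000))
})

test_that("gene placement errors when the genome is too short", {
  expect_error(gen_annotation(
    sim_config(seed = 2, chrom_lengths = c(chr1 = 3000L), n_genes = 50L),
    gen_genome(sim_config(seed = 2, chrom_lengths = c(chr1 = 3000L),
                          n_genes = 50L))),
    "too many genes")
})

test_that("expression generator hits planted targets and edge cases", {
  cfg <- sim_config(seed = 4, expression = list(cv_pct = c(pg4 = 0,
                                                           non_pg4 = 0),
                                                n_genes_per_set = 20L,
                                                n_patients = 10L))
  m0 <- gen_expression(cfg)
  cv0 <- indiv_cv(m0, "normal")
  expect_true(all(cv0$cv == 0))

  expect_error(sim_config(seed = 4,
                          expression = list(cv_pct = c(pg4 = -5,
                                                       non_pg4 = 30))),
               "invalid CV")
  expect_error(gen_expression(sim_config(seed = 4), pg4_genes = c("a", "b"),
                              non_pg4_genes = c("b", "c")), "disjoint")

  # no tumor shift and no extra dispersion: median log2FC near zero
  cfg_null <- sim_config(seed = 4, expression = list(
    tumor_log2_shift = c(mean = 0, sd = 0), tumor_dispersion = 1,
    tumor_between_shrink = c(pg4 = 1, non_pg4 = 1)))
  mnull <- gen_expression(cfg_null)
  fc <- tumor_normal_log2fc(mnull)
  expect_lt(abs(stats::median(fc$log2fc)), 0.05)
})

test_that("null mutation catalogs show no artificial pG4 enrichment", {
  cfg <- sim_config(seed = 11)
  gen <- gen_genome(cfg)
  muts <- gen_mutations(cfg, gen)
  hits <- scan_genome(gen$genome)
  ann <- intersect_mutations(muts, hits)
  bp <- merged_pg4_bp(hits); L <- ungapped_length(gen$genome)
  res <- overlap_enrichment(sum(!is.na(ann$pg4_id)), nrow(ann), bp, L)
  q <- bp / L
  se_fold <- sqrt(q * (1 - q) / nrow(ann)) / q
  expect_lt(abs(res$fold - 1), 3 * se_fold)
})

test_that("simulate_study wires components together deterministically", {
  cfg <- sim_config(seed = 5, chrom_lengths = c(chr1 = 40000L),
                    n_genes = 10L, n_ests = 200L,
                    expression = list(n_genes_per_set = 30L,
                                      n_patients = 20L),
                    mutation = list(n = 200L))
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$muts, s2$muts)
  expect_identical(s1$expr$values, s2$expr$values)
  expect_setequal(c(s1$pg4_genes, s1$non_pg4_genes), s1$models$gene_id)
  expect_length(intersect(s1$pg4_genes, s1$non_pg4_genes), 0L)
})
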