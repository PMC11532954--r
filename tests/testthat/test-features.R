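test_that("feature derivation is strand-aware", {
  m <- make_model(exon_starts = 100L, exon_ends = 200L)
  fs <- derive_features(m)
  expect_equal(fs$tss$pos, 100L)
  expect_equal(fs$tss45$pos, 55L)
  expect_equal(nrow(fs$intron), 0L)
  expect_equal(nrow(fs$utr5), 0L)  # noncoding: no UTRs

  mm <- make_model(strand = "-", exon_starts = 100L, exon_ends = 200L)
  fsm <- derive_features(mm)
  expect_equal(fsm$tss$pos, 199L)
  expect_equal(fsm$tss45$pos, 244L)

  m2 <- make_model(exon_starts = c(100L, 180L), exon_ends = c(150L, 200L))
  fs2 <- derive_features(m2)
  expect_equal(fs2$intron[, c("start", "end")],
               data.frame(start = 150L, end = 180L), ignore_attr = TRUE)
  expect_equal(fs2$splice5$pos, 150L)
  expect_equal(fs2$splice3$pos, 180L)
})

test_that("UTRs come from CDS bounds and transcripts union per gene", {
  m <- make_model(exon_starts = c(0L, 60L), exon_ends = c(40L, 100L),
                  cds_start = 20L, cds_end = 80L)
  fs <- derive_features(m)
  expect_equal(fs$utr5[, c("start", "end")],
               data.frame(start = 0L, end = 20L), ignore_attr = TRUE)
  expect_equal(fs$utr3[, c("start", "end")],
               data.frame(start = 80L, end = 100L), ignore_attr = TRUE)

  # two transcripts of one gene: exon union merges overlapping intervals
  mm <- gene_models(gene_id = c("g1", "g1"), transcript_id = c("t1", "t2"),
                    chrom = "c1", strand = "+",
                    tx_start = c(0L, 50L), tx_end = c(100L, 150L),
                    exon_starts = list(0L, 50L), exon_ends = list(100L, 150L))
  fs2 <- derive_features(mm)
  expect_equal(fs2$exon[, c("start", "end")],
               data.frame(start = 0L, end = 150L), ignore_attr = TRUE)
  expect_equal(nrow(fs2$tss), 2L)  # distinct TSS points are kept
})

test_that("malformed exon lists are reported by gene id", {
  expect_error(make_model(gene_id = "bad1", exon_starts = c(100L, 90L),
                          exon_ends = c(150L, 200L)), "bad1")
  expect_error(make_model(gene_id = "bad2", exon_starts = c(100L, 140L),
                          exon_ends = c(150L, 200L)), "bad2")
})

test_that("intersect_ranges equals the quadratic oracle", {
  a <- data.frame(chrom = "c1", start = 0L, end = 10L)
  b <- data.frame(chrom = "c1", start = 5L, end = 15L)
  got <- intersect_ranges(a, b)
  expect_equal(got$overlap, 5L)
  # half-open abutment does not overlap
  expect_equal(nrow(intersect_ranges(
    a, data.frame(chrom = "c1", start = 10L, end = 20L))), 0L)

  set.seed(7)
  n <- 300L
  mk <- function() {
    st <- sample.int(2000L, n) - 1L
    d <- data.frame(chrom = sample(c("c1", "c2"), n, TRUE), start = st,
                    end = st + sample.int(40L, n, TRUE))
    d[order(d$chrom, d$start), , drop = FALSE]
  }
  a <- mk(); b <- mk()
  rownames(a) <- rownames(b) <- NULL
  got <- intersect_ranges(a, b)
  ref <- brute_intersect(a, b)
  expect_equal(got, ref, ignore_attr = TRUE)
  # overlap lengths are symmetric
  swapped <- intersect_ranges(b, a)
  expect_equal(sort(got$overlap), sort(swapped$overlap))
})

test_that("gene partition is exhaustive, disjoint, and matches planted truth", {
  models <- gene_models(
    gene_id = c("gA", "gB", "gC"), chrom = "c1", strand = "+",
    tx_start = c(0L, 500L, 1000L), tx_end = c(300L, 800L, 1300L),
    exon_starts = list(c(0L, 200L), c(500L, 700L), c(1000L, 1200L)),
    exon_ends = list(c(100L, 300L), c(600L, 800L), c(1100L, 1300L)))
  # pG4 inside gA's intron only
  hits <- hits_frame("c1", 150L, 165L)
  part <- partition_genes(models, hits, "intron")
  expect_equal(part$with, "gA")
  expect_equal(part$without, c("gB", "gC"))
  expect_length(intersect(part$with, part$without), 0L)

  # point feature containment
  tss_hit <- hits_frame("c1", 495L, 510L)
  expect_equal(partition_genes(models, tss_hit, "TSS")$with, "gB")
  expect_equal(partition_genes(models, empty <- hits_frame(character(0),
                                                           integer(0),
                                                           integer(0)),
                               "TSS")$with, character(0))
  expect_error(partition_genes(models, hits, "promoter"), "unknown feature")
})

test_that("EST start containment is half-open on merged intervals", {
  hits <- hits_frame("c1", 0L, 15L)
  ests <- data.frame(chrom = "c1", strand = "+", start_site = c(7L, 15L, 0L))
  ov <- est_tss_overlap(ests, hits)
  expect_equal(ov$n_in_pg4, 2L)  # 7 and 0 inside, 15 excluded
  expect_equal(ov$n_total, 3L)
})

test_that("splice profile counts per covered base at signed offsets", {
  m <- make_model(exon_starts = c(0L, 1500L), exon_ends = c(1000L, 2000L))
  prof <- splice_profile(m, hits_frame("c1", 940L, 955L), window = 100L)
  expected <- integer(201L)
  expected[(-60:-46) + 101L] <- 1L
  expect_equal(prof$counts_5p, expected)
  expect_equal(sum(prof$counts_3p), 0L)

  # all-zero profile without hits
  z <- splice_profile(m, hits_frame(character(0), integer(0), integer(0)),
                      window = 50L)
  expect_true(all(z$counts_5p == 0L) && all(z$counts_3p == 0L))

  # conservation: total counts equal total overlap bp with the windows
  set.seed(3)
  st <- sort(sample.int(1800L, 30L)) - 1L
  hits <- hits_frame("c1", st, st + 15L)
  p <- splice_profile(m, hits, window = 200L)
  merged <- g4scape:::merged_hits_frame(hits)
  win5 <- data.frame(chrom = "c1", start = 1000L - 200L, end = 1000L + 201L)
  ov <- intersect_ranges(win5, merged)
  expect_equal(sum(p$counts_5p), sum(ov$overlap))
})

test_that("profiles are translation invariant and mirror on minus strand", {
  m <- make_model(exon_starts = c(0L, 1500L), exon_ends = c(1000L, 2000L))
  hits <- hits_frame("c1", 940L, 955L)
  shift <- 5000L
  m2 <- make_model(exon_starts = c(0L, 1500L) + shift,
                   exon_ends = c(1000L, 2000L) + shift)
  p1 <- splice_profile(m, hits, window = 100L)
  p2 <- splice_profile(m2, hits_frame("c1", 940L + shift, 955L + shift),
                       window = 100L)
  expect_equal(p1$counts_5p, p2$counts_5p)

  # minus-strand gene: the same physical motif upstream of the donor in
  # transcript orientation sits downstream on the forward axis
  mneg <- make_model(strand = "-", exon_starts = c(0L, 1500L),
                     exon_ends = c(1000L, 2000L))
  # donor at 1499 (transcript runs right to left); upstream = larger coords
  pneg <- splice_profile(mneg, hits_frame("c1", 1545L, 1560L),
                         window = 100L)
  expect_equal(which(pneg$counts_5p == 1L) - 101L,
               -60:-46)
})

test_that("profile enrichment folds and argmax behave analytically", {
  prof <- structure(list(window = 2L, offsets = -2:2,
                         counts_5p = c(0L, 0L, 4L, 0L, 0L),
                         counts_3p = rep(2L, 5L),
                         n_sites_5p = 1L, n_sites_3p = 1L),
                    class = "splice_profile")
  enr <- profile_enrichment(prof)
  expect_equal(enr$fold_5p, c(0, 0, 5, 0, 0))
  expect_equal(enr$peak_5p, 0L)
  expect_equal(enr$fold_3p, rep(1, 5))
  zero <- prof
  zero$counts_5p <- integer(5L)
  expect_warning(profile_enrichment(zero), "all-zero")
})
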