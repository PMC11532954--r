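mut_row <- function(chrom = "c1", pos, ref = "G", alt = "A",
                    mut_type = "substitution", source = "germline",
                    label = "d", sample_id = NA_character_) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             mut_type = mut_type, source = source, label = label,
             sample_id = sample_id, stringsAsFactors = FALSE)
}

test_that("mutation overlap uses the affected reference span", {
  hits <- hits_frame("c1", 0L, 15L)
  expect_false(is.na(intersect_mutations(mut_row(pos = 7L), hits)$pg4_id))
  # deletion [14,16) shares one base with [0,15)
  del <- mut_row(pos = 14L, ref = "GG", alt = "", mut_type = "deletion")
  expect_false(is.na(intersect_mutations(del, hits)$pg4_id))
  # insertion point at 15 is outside the half-open hit
  ins <- mut_row(pos = 15L, ref = "G", alt = "GT", mut_type = "insertion")
  expect_true(is.na(intersect_mutations(ins, hits)$pg4_id))
})

test_that("mutation overlap matches a per-base bitmap oracle", {
  set.seed(13)
  L <- 5000L
  st <- sort(sample.int(L - 60L, 40L)) - 1L
  hits <- hits_frame("c1", st, st + sample(10:30, 40L, TRUE))
  muts <- mut_row(pos = sample.int(L - 2L, 400L) - 1L)
  ann <- intersect_mutations(muts, hits)
  mask <- logical(L)
  for (i in seq_len(nrow(hits))) mask[(hits$start[i] + 1L):hits$end[i]] <- TRUE
  expect_equal(!is.na(ann$pg4_id), mask[muts$pos + 1L])
})

test_that("uniqueness keys depend on source semantics", {
  g2 <- rbind(mut_row(pos = 5L), mut_row(pos = 5L))
  expect_equal(length(unique(uniqueness_key(g2))), 1L)
  s2 <- rbind(mut_row(pos = 5L, source = "somatic", sample_id = "s1"),
              mut_row(pos = 5L, source = "somatic", sample_id = "s2"))
  expect_equal(length(unique(uniqueness_key(s2))), 2L)
  expect_error(uniqueness_key(mut_row(pos = 5L, source = "somatic")),
               "sample_id")
  # order invariance
  set.seed(1)
  cat1 <- rbind(g2, s2)
  expect_equal(length(unique(uniqueness_key(cat1))),
               length(unique(uniqueness_key(cat1[sample(4L), ]))))
})

test_that("stability stratification is boundary-inclusive and counts missing", {
  hits <- hits_frame("c1", c(0L, 20L, 40L, 60L), c(15L, 35L, 55L, 75L),
                     q_score = c(18.9, 19.0, 25, NA))
  s <- stability_stratify(hits)
  expect_equal(nrow(s$stable), 2L)
  expect_equal(nrow(s$unstable), 1L)
  expect_equal(s$stable_fraction, 2 / 3)
  expect_equal(s$n_missing, 1L)
  expect_warning(stability_stratify(hits_frame("c1", 0L, 15L)), "no Q-scores")

  set.seed(2)
  hq <- hits_frame("c1", seq(0L, by = 100L, length.out = 10000L),
                   seq(15L, by = 100L, length.out = 10000L),
                   q_score = rnorm(10000L, 19, 5))
  frac <- stability_stratify(hq)$stable_fraction
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("hotspot ranking orders by unique count with coordinate ties", {
  hits <- hits_frame("c1", c(0L, 100L, 200L), c(15L, 115L, 215L))
  muts <- rbind(mut_row(pos = c(1L, 2L, 3L)),          # 3 in pG4 1
                mut_row(pos = 101L),                    # 1 in pG4 2
                mut_row(pos = 201L))                    # 1 in pG4 3
  ann <- intersect_mutations(muts, hits)
  rk <- hotspot_rank(ann, hits)$pg4_ranking
  expect_equal(rk$n_unique, c(3L, 1L, 1L))
  expect_equal(rk$start, c(0L, 100L, 200L))  # tie broken by coordinate

  # permutation invariance of the ranking
  ann2 <- ann[sample(nrow(ann)), ]
  expect_equal(hotspot_rank(ann2, hits)$pg4_ranking, rk)
})

test_that("planted recurrent hotspot tops the indel recurrence table", {
  cfg <- sim_config(seed = 6, mutation = list(
    n = 500L, hotspot = list(chrom = "chr1", pos = 5000L,
                             recurrence = 50L)))
  gen <- gen_genome(cfg)
  muts <- gen_mutations(cfg, gen)
  rec <- hotspot_rank(intersect_mutations(muts, scan_genome(gen$genome)),
                      scan_genome(gen$genome))$indel_recurrence
  expect_equal(rec$n_unique[1L], 50L)
  expect_equal(rec$pos[1L], 5000L)
  expect_error(gen_mutations(sim_config(seed = 6, mutation = list(
    n = 0L, hotspot = list(chrom = "chrX", pos = 10L, recurrence = 2L))),
    gen), "outside")
  expect_equal(nrow(gen_mutations(sim_config(seed = 6,
                                             mutation = list(n = 0L)),
                                  gen)), 0L)
})

test_that("substitution impact arrows follow the metric conventions", {
  mock <- function(wt, mut) {
    function(seq) if (seq == "ATGA") wt else mut
  }
  fr <- function(dg, tm) folding_result(dg, tm, engine = "mock")
  call1 <- substitution_impact("ATGA", 1L, "T", "C",
                               mock(fr(c(-10, -5), c(60, 50)),
                                    fr(-8, 55)))
  expect_equal(call1$stability, "down")  # dG weaker (up) = stability down
  expect_equal(call1$tm, "down")
  expect_equal(call1$n, "down")

  call2 <- substitution_impact("ATGA", 1L, "T", "C",
                               mock(fr(-10, 60), fr(-10, 60)))
  expect_equal(unlist(call2[c("stability", "tm", "n")]),
               c(stability = "equal", tm = "equal", n = "equal"))

  # within-epsilon dG difference is equal
  call3 <- substitution_impact("ATGA", 1L, "T", "C",
                               mock(fr(-10.0, 60), fr(-10.005, 60)))
  expect_equal(call3$stability, "equal")

  expect_error(substitution_impact("ATGA", 1L, "G", "C",
                                   mock(fr(-1, 1), fr(-1, 1))),
               "ref mismatch")
})

test_that("impact tallies count arrow directions and any change", {
  expect_equal(unname(tally_impacts(data.frame(
    stability = "down", tm = "down", n = "down"))), c(1L, 1L, 1L, 1L))
  alleq <- data.frame(stability = rep("equal", 3), tm = "equal",
                      n = "equal")
  expect_equal(unname(tally_impacts(alleq)), c(0L, 0L, 0L, 0L))

  # any_changed complements the all-equal rows on random arrow sets
  set.seed(9)
  for (i in 1:10) {
    a <- data.frame(stability = sample(c("down", "equal", "up"), 30, TRUE),
                    tm = sample(c("down", "equal", "up"), 30, TRUE),
                    n = sample(c("down", "equal", "up"), 30, TRUE))
    tl <- tally_impacts(a)
    n_alleq <- sum(a$stability == "equal" & a$tm == "equal" &
                     a$n == "equal")
    expect_equal(unname(tl["any_changed"]), 30L - n_alleq)
  }
  expect_error(tally_impacts(data.frame(stability = "sideways",
                                        tm = "down", n = "down")), "arrows")
})
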