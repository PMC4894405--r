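test_that("extract_promoter slices by strand and refuses short context", {
  chrom <- seq_record("c1", "AAAACGT")
  expect_equal(extract_promoter(chrom, 4, "+", W = 4)$sequence, "AAAA")
  # minus strand: reverse complement of the 4 bases right of the TSS
  expect_equal(extract_promoter(chrom, 2, "-", W = 4)$sequence, "ACGT")
  expect_error(extract_promoter(chrom, 2, "+", W = 4), "short by 2")
  expect_error(extract_promoter(chrom, 4, "-", W = 4), "minus strand")
  expect_error(extract_promoter(chrom, 99, "+", W = 4), "outside")
  p <- extract_promoter(chrom, 4, "+", W = 4, promoter_id = "p1",
                        species = "gg", gene_label = "NAT")
  expect_equal(p$W, 4L)
  expect_equal(p$gene_label, "NAT")
})

test_that("find_cpg_islands matches hand-counted dinucleotide cases", {
  expect_equal(nrow(find_cpg_islands(strrep("A", 1000))), 0L)

  isl <- find_cpg_islands(strrep("CG", 100))
  expect_equal(nrow(isl), 1L)
  expect_equal(isl$start, 0L)
  expect_equal(isl$end, 200L)
  expect_equal(isl$gc_fraction, 1.0)
  # 100 CpG dinucleotides: obs/exp = 100*200 / (100*100)
  expect_equal(isl$obs_exp_cpg, 2.0)

  # GC-rich but CpG-poor: one CG dinucleotide, obs/exp = 200/10000
  expect_equal(nrow(find_cpg_islands(
    paste0(strrep("C", 100), strrep("G", 100)))), 0L)

  # island embedded in AT background is found and merged maximally
  s <- paste0(strrep("AT", 200), strrep("CG", 150), strrep("TA", 200))
  isl2 <- find_cpg_islands(s)
  expect_equal(nrow(isl2), 1L)
  expect_true(isl2$start <= 400 && isl2$end >= 700)
})

test_that("assign_segment partitions the promoter exactly", {
  expect_equal(assign_segment(2499), 1L)   # position -1
  expect_equal(assign_segment(2000), 1L)   # position -500
  expect_equal(assign_segment(1999), 2L)   # position -501
  expect_equal(assign_segment(0), 5L)      # position -2500
  k <- assign_segment(0:2499)
  expect_true(all(k %in% 1:5))
  expect_equal(as.integer(table(k)), rep(500L, 5L))   # exact partition
  expect_error(assign_segment(2500), "outside")
  expect_error(assign_segment(-1), "outside")
  # non-default geometry
  expect_equal(assign_segment(0, W = 1000, L = 250), 4L)
})

make_promoter <- function(sp, seqstr, label = "NAT") {
  structure(list(promoter_id = paste0(sp, "_", label), species = sp,
                 gene_label = label, sequence = seqstr, alphabet = "dna",
                 W = nchar(seqstr)), class = c("promoter", "seq_record"))
}

test_that("lineage_conserved_elements keeps only pan-lineage elements", {
  mats <- scenario_matrices()
  params <- scan_params()
  # singleton lineage: every observed (matrix, segment) pair is conserved
  one <- simulate_promoter_set("solo", mats,
                               list(list(matrix_id = "MA0056.1",
                                         segment = 2)), seed = 5)
  lin1 <- lineage_set("one", one$promoters, "solo")
  hits1 <- scan_promoters(mats, one$promoters, params)
  ce1 <- lineage_conserved_elements(lin1, hits1)
  seen <- unique(data.frame(matrix_id = hits1$matrix_id,
                            segment = assign_segment(hits1$start)))
  expect_equal(nrow(ce1), nrow(seen))

  # 4 species, consensus site planted in segment 2 of all
  sp4 <- paste0("sp", 1:4)
  all4 <- simulate_promoter_set(sp4, mats,
                                list(list(matrix_id = "MA0152.1",
                                          segment = 2)), seed = 8)
  lin4 <- lineage_set("avian", all4$promoters, "sp1")
  hits4 <- scan_promoters(mats, all4$promoters, params)
  ce4 <- lineage_conserved_elements(lin4, hits4)
  expect_true(any(ce4$matrix_id == "MA0152.1" & ce4$segment == 2L))

  # same but the site omitted in one species
  miss <- simulate_promoter_set(sp4, mats,
                                list(list(matrix_id = "MA0152.1",
                                          segment = 2,
                                          species = sp4[1:3])), seed = 8)
  linm <- lineage_set("avian", miss$promoters, "sp1")
  hitsm <- scan_promoters(mats, miss$promoters, params)
  cem <- lineage_conserved_elements(linm, hitsm)
  expect_false(any(cem$matrix_id == "MA0152.1" & cem$segment == 2L))

  # a species in hits but not the lineage is an error
  stray <- hits4
  stray$species[1L] <- "intruder"
  expect_error(lineage_conserved_elements(lin4, stray), "intruder")
})

ce_stub <- function(df, hits = NULL, ref = "refsp", W = 2500L) {
  if (is.null(hits))
    hits <- data.frame(matrix_id = character(0), segment = integer(0),
                       species = character(0), start = integer(0))
  structure(df, hits = hits, lineage = "stub",
            species = unique(c(hits$species, ref)), W = W, L = 500L,
            reference_species = ref,
            class = c("conserved_elements", "data.frame"))
}

test_that("shared_elements intersects on (matrix, segment)", {
  a <- data.frame(matrix_id = c("M1", "M2"), name = c("x", "y"),
                  segment = c(1L, 3L))
  n <- data.frame(matrix_id = "M1", name = "x", segment = 1L)
  d <- data.frame(matrix_id = c("M1", "M2"), name = c("x", "y"),
                  segment = c(1L, 3L))
  rep0 <- shared_elements(ce_stub(a), ce_stub(n), ce_stub(d))
  expect_equal(rep0$shared_with_NAT$matrix_id, "M1")
  expect_equal(rep0$shared_with_DAT$matrix_id, c("M1", "M2"))
  # element in all three appears in both lists
  expect_true("M1" %in% rep0$shared_with_NAT$matrix_id &&
                "M1" %in% rep0$shared_with_DAT$matrix_id)
  # disjoint matrix sets: both empty
  z <- data.frame(matrix_id = "M9", name = "z", segment = 1L)
  rep1 <- shared_elements(ce_stub(z), ce_stub(n), ce_stub(d))
  expect_equal(nrow(rep1$shared_with_NAT), 0L)
  expect_equal(nrow(rep1$shared_with_DAT), 0L)
  # segment tolerance widens the match
  b <- data.frame(matrix_id = "M2", name = "y", segment = 4L)
  expect_equal(nrow(shared_elements(ce_stub(a), ce_stub(b),
                                    ce_stub(z))$shared_with_NAT), 0L)
  expect_equal(
    shared_elements(ce_stub(a), ce_stub(b), ce_stub(z),
                    segment_tolerance = 1L)$shared_with_NAT$matrix_id, "M2")
})

test_that("shared_elements recovers a planted avian/DAT-only element", {
  mats <- scenario_matrices()
  params <- scan_params()
  plant_foxc1 <- list(list(matrix_id = "MA0032.1", segment = 3),
                      list(matrix_id = "MA0004.1", offset = 2380))
  plant_anchor <- list(list(matrix_id = "MA0004.1", offset = 2380))
  av <- simulate_promoter_set(paste0("a", 1:3), mats, plant_foxc1,
                              seed = 21)
  mn <- simulate_promoter_set(paste0("n", 1:3), mats, plant_anchor,
                              seed = 22)
  md <- simulate_promoter_set(paste0("d", 1:3), mats, plant_foxc1,
                              seed = 23)
  ce <- function(sim, ref) lineage_conserved_elements(
    lineage_set("lin", sim$promoters, ref),
    scan_promoters(mats, sim$promoters, params))
  rep <- shared_elements(ce(av, "a1"), ce(mn, "n1"), ce(md, "d1"))
  expect_true(any(rep$shared_with_DAT$matrix_id == "MA0032.1" &
                    rep$shared_with_DAT$segment == 3L))
  expect_false(any(rep$shared_with_NAT$matrix_id == "MA0032.1"))
})

test_that("anchor_positions maps elements relative to the proximal anchor", {
  W <- 2500L
  # avian: anchor hits at u=120 and u=480 (most proximal chosen), one
  # shared element at u=620
  mk_hits <- function(sp, us, mids, segs) data.frame(
    matrix_id = mids, segment = segs, species = sp, start = W - us,
    stringsAsFactors = FALSE)
  a_df <- data.frame(matrix_id = c("ANC", "EL"), name = c("anchor", "el"),
                     segment = c(1L, 2L))
  a_hits <- mk_hits("zf", c(120, 480, 620), c("ANC", "ANC", "EL"),
                    c(1L, 1L, 2L))
  n_df <- data.frame(matrix_id = c("ANC", "EL"), name = c("anchor", "el"),
                     segment = c(1L, 2L))
  n_hits <- mk_hits("mm", c(100, 600), c("ANC", "EL"), c(1L, 2L))
  d_df <- data.frame(matrix_id = "ANC", name = "anchor", segment = 1L)
  d_hits <- mk_hits("mm", 150, "ANC", 1L)
  conserved <- list(avian = ce_stub(a_df, a_hits, "zf"),
                    mammalian_nat = ce_stub(n_df, n_hits, "mm"),
                    mammalian_dat = ce_stub(d_df, d_hits, "mm"))
  rep <- shared_elements(conserved$avian, conserved$mammalian_nat,
                         conserved$mammalian_dat)
  anc <- anchor_positions(rep, conserved, "ANC")
  expect_true(anc$anchored)
  expect_equal(anc$anchors$avian$u_anchor, 120)   # most proximal of 120/480
  el <- anc$shared_with_NAT[anc$shared_with_NAT$matrix_id == "EL", ]
  expect_equal(el$anchored_pos, 120 - 620)        # -500, upstream negative
  expect_equal(el$anchored_pos_other, 100 - 600)
  anch_self <- anc$shared_with_NAT[anc$shared_with_NAT$matrix_id == "ANC", ]
  expect_equal(anch_self$anchored_pos, 0)         # element at the anchor

  # anchor absent from one lineage: flagged, not an error
  conserved2 <- conserved
  conserved2$mammalian_dat <- ce_stub(
    data.frame(matrix_id = "EL", name = "el", segment = 2L),
    mk_hits("mm", 600, "EL", 2L), "mm")
  anc2 <- anchor_positions(rep, conserved2, "ANC")
  expect_false(anc2$anchored)
  expect_equal(attr(anc2, "anchor_missing_in"), "mammalian_dat")
})
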