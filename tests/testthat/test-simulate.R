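test_that("promoter simulation is deterministic and overlap-safe", {
  mats <- scenario_matrices()
  plants <- list(list(matrix_id = "MA0004.1", offset = 2380),
                 list(matrix_id = "MA0056.1", segment = 3))
  s1 <- simulate_promoter_set(c("x", "y"), mats, plants, seed = 91)
  s2 <- simulate_promoter_set(c("x", "y"), mats, plants, seed = 91)
  expect_identical(lapply(s1$promoters, `[[`, "sequence"),
                   lapply(s2$promoters, `[[`, "sequence"))
  s3 <- simulate_promoter_set(c("x", "y"), mats, plants, seed = 92)
  expect_false(identical(s1$promoters$x$sequence, s3$promoters$x$sequence))
  # fasta round-trip is byte-identical under the same seed
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(lapply(s1$promoters, function(p)
    seq_record(p$promoter_id, p$sequence, "dna", species = p$species)), f1)
  write_fasta(lapply(s2$promoters, function(p)
    seq_record(p$promoter_id, p$sequence, "dna", species = p$species)), f2)
  expect_identical(readLines(f1), readLines(f2))
  # overlapping plants are an error, not silent clobbering
  clash <- list(list(matrix_id = "MA0004.1", offset = 100),
                list(matrix_id = "MA0056.1", offset = 104))
  expect_error(simulate_promoter_set("x", mats, clash, seed = 1),
               "overlap")
  # truth records the planted site at relative score 1
  pw <- build_pwm(mats[[1L]], scan_params())
  site <- s1$truth$motifs$site[s1$truth$motifs$matrix_id == "MA0004.1"][1L]
  expect_equal(relative_score(pw, site), 1.0)
})

test_that("a plant-free promoter has no hits at threshold 1", {
  mats <- scenario_matrices()
  s <- simulate_promoter_set("x", mats, list(), seed = 93)
  hits <- scan_promoters(mats, s$promoters, scan_params(threshold = 1.0))
  expect_equal(nrow(hits), 0L)
})

test_that("ortholog simulation matches its analytic identity expectation", {
  tr2 <- ape::read.tree(text = "(a:1,b:1);")
  # q = 0: tips identical
  s0 <- simulate_ortholog_proteins(tr2, root_length = 200L, q = 0,
                                   seed = 101)
  expect_identical(s0$records[[1L]]$sequence, s0$records[[2L]]$sequence)
  expect_equal(s0$truth$expected_identity$expected_identity, 1.0)
  # q = 0.1, length 1000: measured identity inside the central 99%
  # binomial band around (1-q)^2 + q^2/19
  q <- 0.1
  n <- 1000L
  s1 <- simulate_ortholog_proteins(tr2, root_length = n, q = q, seed = 102)
  p_exp <- (1 - q)^2 + q^2 / 19
  expect_equal(s1$truth$expected_identity$expected_identity, p_exp)
  a <- strsplit(s1$records[[1L]]$sequence, "", fixed = TRUE)[[1L]]
  b <- strsplit(s1$records[[2L]]$sequence, "", fixed = TRUE)[[1L]]
  matches <- sum(a == b)
  expect_gte(matches, qbinom(0.005, n, p_exp))
  expect_lte(matches, qbinom(0.995, n, p_exp))
  # determinism
  s1b <- simulate_ortholog_proteins(tr2, root_length = n, q = q, seed = 102)
  expect_identical(s1$records, s1b$records)
})

test_that("star-tree tips are exchangeable in expectation", {
  star <- ape::read.tree(text = "(a,b,c,d);")
  s <- simulate_ortholog_proteins(star, root_length = 400L, q = 0.08,
                                  seed = 103)
  expect_equal(length(unique(s$truth$expected_identity$expected_identity)),
               1L)
  # measured identities all within the shared 99.9% band
  p <- s$truth$expected_identity$expected_identity[1L]
  seqs <- lapply(s$records, function(r)
    strsplit(r$sequence, "", fixed = TRUE)[[1L]])
  for (i in 1:3) for (j in (i + 1):4) {
    m <- sum(seqs[[i]] == seqs[[j]])
    expect_gte(m, qbinom(0.0005, 400L, p))
    expect_lte(m, qbinom(0.9995, 400L, p))
  }
})

test_that("reverse_translate emits the fixed stop-free coding sequence", {
  dna <- reverse_translate("MKTW")
  expect_equal(nchar(dna), 12L)
  expect_equal(as.character(Biostrings::translate(Biostrings::DNAString(dna))),
               "MKTW")
  expect_error(reverse_translate("MKX"), "X")
  # whole-alphabet round trip
  aa <- "ARNDCQEGHILKMFPSTWYV"
  expect_equal(as.character(Biostrings::translate(
    Biostrings::DNAString(reverse_translate(aa)))), aa)
})

test_that("locus simulation plants genes, decoys and gaps where recorded", {
  panel <- simulate_paralog_panel(seed = 7)
  loc <- simulate_locus("spA", panel, gene_present = TRUE, decoys = "NAT",
                        n_gap_runs = c(120L, 60L), seed = 111)
  tr <- loc$truth
  expect_true(tr$gene_present)
  # the planted gene lies inside the flanked interval
  expect_gte(tr$gene_span[1L], tr$interval[1L])
  expect_lte(tr$gene_span[2L], tr$interval[2L])
  # the recorded gene span decodes back to the panel protein
  gene_dna <- substr(loc$genome$sequence, tr$gene_span[1L] + 1L,
                     tr$gene_span[2L])
  expect_equal(as.character(Biostrings::translate(
    Biostrings::DNAString(gene_dna))), panel$DAT$sequence)
  # decoys land outside the interval
  expect_true(all(tr$decoys$start >= tr$interval[2L]))
  # gap census agrees with the N runs planted
  gr <- assess_assembly(substr(loc$genome$sequence, tr$interval[1L] + 1L,
                               tr$interval[2L]))
  expect_equal(gr$n_runs, 2L)
  expect_equal(gr$longest_run, 120L)
  # determinism
  loc2 <- simulate_locus("spA", panel, gene_present = TRUE, decoys = "NAT",
                         n_gap_runs = c(120L, 60L), seed = 111)
  expect_identical(loc$genome$sequence, loc2$genome$sequence)
  expect_identical(loc$hits, loc2$hits)
  # a gene longer than the intergenic span is rejected
  expect_error(simulate_locus("spB", panel, intergenic_length = 500L,
                              seed = 1), "too long")
})

test_that("the internal translated search hits the planted gene in place", {
  panel <- simulate_paralog_panel(seed = 7)
  loc <- simulate_locus("spC", panel, gene_present = TRUE, seed = 112)
  hits <- loc$hits
  expect_gt(nrow(hits), 0L)
  top <- hits[1L, ]   # sorted by score
  expect_equal(top$query_id, "DAT")
  expect_equal(top$subject_id, "spC_chr1")
  # top hit covers the recorded gene span
  expect_lte(abs(top$s_start0 - loc$truth$gene_span[1L]), 3)
  expect_lte(abs(top$s_end0 - loc$truth$gene_span[2L]), 3)
  expect_gt(top$percent_identity, 99)
  # the emitted table is valid for the 12-column writer/reader pair
  f <- withr::local_tempfile()
  write_hit_table(hits, f)
  back <- read_hit_table(f)
  expect_equal(back$s_start0, hits$s_start0)
  expect_equal(back$s_strand, hits$s_strand)
})

test_that("minus-strand placements map back to plus-strand coordinates", {
  panel <- simulate_paralog_panel(length = 80L, seed = 21)
  gene_dna <- reverse_translate(panel$DAT)
  flank <- strrep("AT", 150)
  genome <- seq_record("g", paste0(flank, revcomp_str(gene_dna), flank),
                       "dna")
  hits <- align_panel_to_genome(panel$DAT, genome)
  expect_gt(nrow(hits), 0L)
  expect_equal(hits$s_strand[1L], "-")
  expect_equal(hits$s_start0[1L], 300)
  expect_equal(hits$s_end0[1L], 300 + nchar(gene_dna))
})
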