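test_that("build_pwm reproduces hand-evaluated log-odds weights", {
  p <- pfm("M1", "T", matrix(c(4, 0, 0, 0), 4L))
  w <- build_pwm(p, scan_params())
  # (4 + 0.8*0.25) / (4 + 0.8) / 0.25 = 3.5 ; (0 + 0.2) / 4.8 / 0.25
  expect_equal(unname(w$weights["A", 1L]), log2(3.5), tolerance = 1e-12)
  expect_equal(unname(w$weights["C", 1L]), log2(0.2 / 4.8 / 0.25),
               tolerance = 1e-12)
  expect_equal(unname(w$weights["C", 1L]), -2.585, tolerance = 1e-3)
  expect_equal(unname(w$weights["A", 1L]), 1.807, tolerance = 1e-3)
  expect_equal(w$s_min, sum(apply(w$weights, 2L, min)))
  expect_equal(w$s_max, sum(apply(w$weights, 2L, max)))
})

test_that("a uniform column is weightless and collapses the score range", {
  p <- pfm("M1", "T", matrix(c(3, 3, 3, 3), 4L))
  for (pc in c(0.1, 0.8, 5)) {
    w <- build_pwm(p, scan_params(pseudocount = pc))
    expect_equal(unname(w$weights[, 1L]), rep(0, 4L), tolerance = 1e-12)
    expect_equal(w$s_min, w$s_max)
  }
  expect_equal(relative_score(build_pwm(p, scan_params()), "G"), 1.0)
})

test_that("pseudocount dilution shrinks as counts scale up", {
  p1 <- pfm("M1", "T", matrix(c(7, 2, 1, 0), 4L))
  p2 <- pfm("M1", "T", matrix(2 * c(7, 2, 1, 0), 4L))
  params <- scan_params(pseudocount = 0.8)
  w1 <- build_pwm(p1, params)
  w2 <- build_pwm(p2, params)
  # nonzero-count bases barely move; direct evaluation bounds the shift
  expect_lt(max(abs(w1$weights[1:3, 1L] - w2$weights[1:3, 1L])), 0.08)
  # p -> 0 limit for the nonzero-count bases; doubling must move toward it
  lim <- log2((c(7, 2, 1) / 10) / 0.25)
  d1 <- abs(unname(w1$weights[1:3, 1L]) - lim)
  d2 <- abs(unname(w2$weights[1:3, 1L]) - lim)
  expect_true(all(d2 < d1))
  # the zero-count base approaches its -Inf limit monotonically instead
  expect_lt(unname(w2$weights[4L, 1L]), unname(w1$weights[4L, 1L]))
})

test_that("relative_score hits its extremes at consensus and anti-consensus", {
  set.seed(7)
  for (rep in 1:10) {
    p <- random_pfm("M", sample(2:8, 1L))
    w <- build_pwm(p, scan_params())
    cons <- paste(c("A", "C", "G", "T")[apply(w$weights, 2L, which.max)],
                  collapse = "")
    anti <- paste(c("A", "C", "G", "T")[apply(w$weights, 2L, which.min)],
                  collapse = "")
    expect_equal(relative_score(w, cons), 1.0)
    expect_equal(relative_score(w, anti), 0.0)
  }
})

test_that("relative_score equals independent re-summation on random windows", {
  set.seed(11)
  p <- random_pfm("M", 6L)
  w <- build_pwm(p, scan_params())
  for (rep in 1:25) {
    win <- random_dna_str(6L)
    idx <- match(strsplit(win, "", fixed = TRUE)[[1L]],
                 c("A", "C", "G", "T"))
    raw <- sum(vapply(1:6, function(j) w$weights[idx[j], j], numeric(1L)))
    expect_equal(relative_score(w, win),
                 (raw - w$s_min) / (w$s_max - w$s_min), tolerance = 1e-12)
  }
  expect_true(is.na(relative_score(w, "ACGTNN")))
  expect_error(relative_score(w, "ACGT"), "length")
})

test_that("scan_sequence finds a planted consensus and respects strictness", {
  p <- make_pfm("M", "X", "ACGTTACA")   # not palindromic
  w <- build_pwm(p, scan_params())
  s <- seq_record("s", "ACGTTACA")
  hits <- scan_sequence(w, s, scan_params(threshold = 0.90))
  fwd <- hits[hits$strand == "+", ]
  expect_equal(nrow(fwd), 1L)
  expect_equal(fwd$start, 0L)
  expect_equal(fwd$end, 8L)
  expect_equal(fwd$relative_score, 1.0)
  # strict ">" at threshold 1.0 excludes even the consensus
  expect_equal(nrow(scan_sequence(w, s, scan_params(threshold = 1.0))), 0L)
  expect_gt(nrow(scan_sequence(
    w, s, scan_params(threshold = 1.0, comparison = "ge"))), 0L)
  # shorter than the matrix: empty, not an error
  expect_equal(nrow(scan_sequence(w, seq_record("t", "ACG"),
                                  scan_params())), 0L)
})

test_that("scan_sequence equals exhaustive enumeration on random inputs", {
  set.seed(23)
  params <- scan_params(threshold = 0.75)
  for (rep in 1:30) {
    p <- random_pfm("M", sample(2:8, 1L))
    w <- build_pwm(p, params)
    s <- random_dna_str(sample(20:200, 1L), c("A", "C", "G", "T", "N"))
    got <- scan_sequence(w, seq_record("s", s), params)
    want <- brute_scan(w, s, threshold = 0.75)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, want$start)
      expect_equal(got$strand, want$strand)
      expect_equal(got$score, want$score, tolerance = 1e-12)
      expect_equal(got$relative_score, want$relative_score,
                   tolerance = 1e-12)
    }
  }
})

test_that("scanning is strand-symmetric under reverse complement", {
  set.seed(31)
  params <- scan_params(threshold = 0.7)
  for (rep in 1:10) {
    p <- random_pfm("M", sample(3:7, 1L))
    w <- build_pwm(p, params)
    L <- ncol(w$weights)
    s <- random_dna_str(80L)
    n <- nchar(s)
    h1 <- scan_sequence(w, seq_record("s", s), params)
    h2 <- scan_sequence(w, seq_record("s", revcomp_str(s)), params)
    # mirror h2 back onto s coordinates with swapped strand labels
    mirrored <- data.frame(start = n - h2$end, strand = ifelse(
      h2$strand == "+", "-", "+"), score = h2$score)
    mirrored <- mirrored[order(mirrored$start, mirrored$strand), ]
    expect_equal(h1$start, mirrored$start)
    expect_equal(h1$strand, mirrored$strand)
    expect_equal(h1$score, mirrored$score, tolerance = 1e-12)
  }
})

test_that("relative scores stay in [0,1] and increase with raw score", {
  set.seed(37)
  p <- random_pfm("M", 5L)
  w <- build_pwm(p, scan_params())
  s <- random_dna_str(300L)
  hits <- scan_sequence(w, seq_record("s", s), scan_params(threshold = 1e-9))
  expect_true(all(hits$relative_score >= 0 & hits$relative_score <= 1))
  # monotone in raw score (up to floating-point ties)
  expect_true(all(diff(hits$relative_score[order(hits$score)]) >= -1e-12))
})

test_that("motif hit writers emit BED and TSV", {
  p <- make_pfm("M", "X", "ACGTAC")
  w <- build_pwm(p, scan_params())
  hits <- scan_sequence(w, seq_record("s", "ACGTACGTACGT"),
                        scan_params(threshold = 0.5))
  bed <- withr::local_tempfile()
  tsv <- withr::local_tempfile()
  write_motif_hits(hits, bed, tsv)
  expect_equal(length(readLines(bed)), nrow(hits))
  back <- read.delim(tsv)
  expect_equal(back$start, hits$start)
  expect_equal(back$relative_score, hits$relative_score)
})
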