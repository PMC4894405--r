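# Independent oracles and fixture builders shared across the suite.

# -- fixture builders ---------------------------------------------------------

# strong-count pfm whose consensus is `cons` (count 20 vs 1 elsewhere)
make_pfm <- function(id, name, cons) {
  m <- matrix(1, 4, nchar(cons), dimnames = list(c("A", "C", "G", "T"), NULL))
  idx <- match(strsplit(cons, "", fixed = TRUE)[[1L]], c("A", "C", "G", "T"))
  for (j in seq_along(idx)) m[idx[j], j] <- 20
  pfm(id, name, m)
}

random_pfm <- function(id, L) {
  m <- matrix(sample(0:12, 4L * L, replace = TRUE), 4L, L)
  zero <- colSums(m) == 0
  m[1L, zero] <- 1
  pfm(id, paste0("RND", L), m)
}

random_dna_str <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# the six matrices used by planted promoter scenarios (distinct, specific)
scenario_matrices <- function() {
  list(make_pfm("MA0004.1", "ARNT", "CACGTGCA"),
       make_pfm("MA0152.1", "NFATC2", "TTTTCCAG"),
       make_pfm("MA0056.1", "MZF1", "TGGGGAGG"),
       make_pfm("MA0130.1", "ZNF354C", "CTCCACCT"),
       make_pfm("MA0032.1", "FOXC1", "GTAAACAA"),
       make_pfm("MA0099.1", "HOXA5", "CATTAATG"))
}

revcomp_str <- function(s) {
  paste(rev(chartr("ACGT", "TGCA",
                   strsplit(s, "", fixed = TRUE)[[1L]])), collapse = "")
}

# hand-build a hit table row set (1-based inclusive coords, strand via
# s_start > s_end) without touching the reader
make_hits <- function(q_start, q_end, s_start, s_end, subject_id = "chr",
                      pid = 90, evalue = NA_real_) {
  n <- length(q_start)
  df <- data.frame(
    query_id = rep("q", n), subject_id = rep(subject_id, length.out = n),
    percent_identity = rep(pid, length.out = n),
    aln_length = q_end - q_start + 1,
    mismatches = 0, gap_opens = 0,
    q_start = q_start, q_end = q_end, s_start = s_start, s_end = s_end,
    e_value = rep(evalue, length.out = n), bit_score = 100,
    stringsAsFactors = FALSE)
  df$s_strand <- ifelse(df$s_start > df$s_end, "-", "+")
  df$s_start0 <- ifelse(df$s_strand == "+", df$s_start - 1, df$s_end - 1)
  df$s_end0 <- ifelse(df$s_strand == "+", df$s_end, df$s_start)
  class(df) <- c("hit_table", "data.frame")
  df
}

# -- oracle: exhaustive PWM window enumeration --------------------------------

# scores every window on both strands by per-position re-summation,
# independent of the vectorised scanner
brute_scan <- function(pwm, sequence, threshold = 0.9, strands = "both",
                       comparison = "gt") {
  L <- ncol(pwm$weights)
  n <- nchar(sequence)
  bases <- c("A", "C", "G", "T")
  denom <- pwm$s_max - pwm$s_min
  hits <- list()
  score_window <- function(w) {
    total <- 0
    for (j in seq_len(L)) {
      b <- match(substr(w, j, j), bases)
      if (is.na(b)) return(NA_real_)
      total <- total + pwm$weights[b, j]
    }
    total
  }
  if (n >= L) {
    for (start0 in 0:(n - L)) {
      w <- substr(sequence, start0 + 1L, start0 + L)
      raw <- score_window(w)
      if (!is.na(raw)) {
        rel <- if (denom > 0) (raw - pwm$s_min) / denom else 1.0
        if (if (comparison == "gt") rel > threshold else rel >= threshold)
          hits[[length(hits) + 1L]] <- data.frame(
            start = start0, strand = "+", score = raw, relative_score = rel)
      }
      if (strands == "both") {
        raw_m <- score_window(revcomp_str(w))
        if (!is.na(raw_m)) {
          rel_m <- if (denom > 0) (raw_m - pwm$s_min) / denom else 1.0
          if (if (comparison == "gt") rel_m > threshold else
              rel_m >= threshold)
            hits[[length(hits) + 1L]] <- data.frame(
              start = start0, strand = "-", score = raw_m,
              relative_score = rel_m)
        }
      }
    }
  }
  if (!length(hits))
    return(data.frame(start = integer(0), strand = character(0),
                      score = numeric(0), relative_score = numeric(0)))
  df <- do.call(rbind, hits)
  df <- df[order(df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# -- oracle: exhaustive global-alignment enumeration --------------------------

# maximal score over every global alignment of a and b under affine gaps
# (gap of length k costs open + k * ext), by recursive path enumeration
brute_align_score <- function(a, b, submat, open = 10, ext = 0.5) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  best <- -Inf
  # state: i residues of a and j of b consumed; last move for gap-run logic
  rec <- function(i, j, score, last) {
    if (i == length(ca) && j == length(cb)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i < length(ca) && j < length(cb))
      rec(i + 1L, j + 1L, score + submat[ca[i + 1L], cb[j + 1L]], "d")
    if (i < length(ca))   # gap in b
      rec(i + 1L, j, score - ext - if (last == "gb") 0 else open, "gb")
    if (j < length(cb))   # gap in a
      rec(i, j + 1L, score - ext - if (last == "ga") 0 else open, "ga")
  }
  rec(0L, 0L, 0, "start")
  best
}

# -- oracle: Dollo minimum by ancestral-state enumeration ---------------------

# minimal number of 1->0 edges over every internal-state assignment with at
# most one origin (root being present, or a 0->1 edge)
brute_dollo_losses <- function(tree, states) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  tip_present <- as.integer(states[tree$tip.label] == "present")
  if (!any(tip_present == 1L)) return(0L)
  K <- tree$Nnode
  grid <- as.matrix(expand.grid(rep(list(0:1), K)))
  S <- matrix(0L, nrow(grid), nnode)
  S[, seq_len(ntip)] <- matrix(tip_present, nrow(grid), ntip, byrow = TRUE)
  S[, ntip + seq_len(K)] <- grid
  ps <- S[, tree$edge[, 1L], drop = FALSE]
  cs <- S[, tree$edge[, 2L], drop = FALSE]
  origins <- rowSums(ps == 0L & cs == 1L) + S[, ntip + 1L]
  losses <- rowSums(ps == 1L & cs == 0L)
  min(losses[origins <= 1L])
}

random_rooted_tree <- function(ntip) ape::rtree(ntip, rooted = TRUE)
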