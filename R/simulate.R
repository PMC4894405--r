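AA20 <- PROTEIN_ALPHABET[PROTEIN_ALPHABET != "X"]

# fixed codon per residue for reverse translation: reproducible, and free of
# stop codons by construction
CODON_OF <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
              Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
              L = "CTT", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
              S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

# evaluate code under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

random_dna <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Consensus site of a frequency matrix
#'
#' Per-column argmax base (ties resolved in A,C,G,T order). A consensus
#' window always attains relative profile score 1.
#'
#' @param pfm A [pfm()] object.
#' @return DNA string of the matrix length.
#' @export
consensus_site <- function(pfm) {
  paste(rownames(pfm$counts)[apply(pfm$counts, 2L, which.max)],
        collapse = "")
}

sampled_site <- function(pfm) {
  paste(apply(pfm$counts, 2L, function(col)
    sample(c("A", "C", "G", "T"), 1L, prob = col / sum(col))),
    collapse = "")
}

#' Reverse-translate a protein with a fixed codon table
#'
#' One fixed codon per residue (no randomness), so the DNA of a planted
#' gene is reproducible and stop-free.
#'
#' @param protein Protein string or [seq_record()] (X not allowed).
#' @return DNA string of length `3 * nchar(protein)`.
#' @export
reverse_translate <- function(protein) {
  s <- protein_string(protein, "protein")
  if (grepl("X", s, fixed = TRUE))
    stop("cannot reverse-translate ambiguous residue X")
  paste(CODON_OF[strsplit(s, "", fixed = TRUE)[[1L]]], collapse = "")
}

#' Simulate a promoter set with planted motif sites
#'
#' Generates one W-bp promoter per species as i.i.d. background at a given
#' GC content, then overwrites planted motif sites at recorded positions.
#' A `consensus`-mode site has relative profile score exactly 1; a
#' `sampled` site is drawn from the matrix column frequencies. A plant
#' targeted at segment `k` is placed uniformly at random fully inside that
#' segment; an explicit `offset` (0-based promoter start) is honoured
#' as-is. Overlapping plants within a species are an error (no silent
#' clobbering). The same seed reproduces the output exactly.
#'
#' @param species Character vector of species labels.
#' @param matrices List of [pfm()] objects (names ignored; matched by
#'   `matrix_id`).
#' @param plants List of plant specs: each a list with `matrix_id`, one of
#'   `segment` (1-based index) or `offset`, optional `species` (subset;
#'   default all), `mode` (`"consensus"`/`"sampled"`), `strand`
#'   (`"+"`/`"-"`, site written as its reverse complement for `"-"`).
#' @param W Promoter width (default 2500).
#' @param gc Background GC fraction (default 0.4).
#' @param L Segment length (default 500).
#' @param gene_label Label attached to the promoters (e.g. `"NAT"`).
#' @param seed Integer seed.
#' @return List with `promoters` (list of `promoter` objects, ids
#'   `<species>_<gene_label>`) and `truth` (seed, parameters, and a
#'   `motifs` data frame: matrix_id, species, segment, start, strand,
#'   site).
#' @export
simulate_promoter_set <- function(species, matrices, plants = list(),
                                  W = 2500L, gc = 0.4, L = 500L,
                                  gene_label = "", seed = 1L) {
  mat_ids <- vapply(matrices, function(m) m$matrix_id, character(1L))
  names(matrices) <- mat_ids
  with_seed(seed, {
    proms <- list()
    truth_rows <- list()
    for (sp in species) {
      seq_chars <- strsplit(random_dna(W, gc), "", fixed = TRUE)[[1L]]
      occupied <- integer(0)
      for (pl in plants) {
        target_sp <- if (is.null(pl$species)) species else pl$species
        if (!(sp %in% target_sp)) next
        if (!pl$matrix_id %in% mat_ids)
          stop("plant refers to unknown matrix '", pl$matrix_id, "'")
        m <- matrices[[pl$matrix_id]]
        Lm <- ncol(m$counts)
        mode <- if (is.null(pl$mode)) "consensus" else pl$mode
        strand <- if (is.null(pl$strand)) "+" else pl$strand
        site <- if (mode == "consensus") consensus_site(m) else
          sampled_site(m)
        if (!is.null(pl$offset)) {
          s0 <- pl$offset
          if (s0 < 0 || s0 + Lm > W)
            stop("plant offset ", s0, " does not fit in promoter")
        } else {
          k <- pl$segment
          lo <- W - k * L
          hi <- W - (k - 1L) * L - Lm
          if (lo < 0 || hi < lo)
            stop("site of length ", Lm, " does not fit in segment ", k)
          s0 <- if (hi == lo) lo else sample(lo:hi, 1L)
        }
        span <- (s0 + 1L):(s0 + Lm)
        if (length(intersect(span, occupied)))
          stop("overlapping plants in species '", sp, "' at offset ", s0)
        occupied <- c(occupied, span)
        written <- if (strand == "-") revcomp(site) else site
        seq_chars[span] <- strsplit(written, "", fixed = TRUE)[[1L]]
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          matrix_id = pl$matrix_id, species = sp,
          segment = assign_segment(s0, W = W, L = L), start = s0,
          strand = strand, site = site, mode = mode,
          stringsAsFactors = FALSE)
      }
      proms[[sp]] <- structure(
        list(promoter_id = paste0(sp, if (nzchar(gene_label))
          paste0("_", gene_label) else ""),
          species = sp, gene_label = gene_label,
          sequence = paste(seq_chars, collapse = ""), alphabet = "dna",
          W = as.integer(W)),
        class = c("promoter", "seq_record"))
    }
    motifs <- if (length(truth_rows)) do.call(rbind, truth_rows) else
      data.frame(matrix_id = character(0), species = character(0),
                 segment = integer(0), start = integer(0),
                 strand = character(0), site = character(0),
                 mode = character(0), stringsAsFactors = FALSE)
    list(promoters = proms,
         truth = list(kind = "promoter_set", seed = seed, W = W, L = L,
                      gc = gc, gene_label = gene_label, motifs = motifs))
  })
}

# probability that a tip residue equals its ancestor's residue after a path
# of per-branch substitution probabilities q (uniform replacement over the
# other 19 residues)
path_retention <- function(qs) {
  p <- 1
  for (q in qs) p <- p * (1 - q) + (1 - p) * q / 19
  p
}

#' Simulate ortholog proteins diverged along a tree
#'
#' A uniformly random root protein evolves down a rooted tree; on each
#' branch every site substitutes independently with probability `q`, the
#' replacement drawn uniformly from the other 19 residues (no indels).
#' This intentionally non-biological model gives closed-form expected
#' identities: for two tips whose paths from their common ancestor retain
#' the ancestral residue with probabilities `a` and `b`, expected identity
#' is `a*b + (1-a)*(1-b)/19` (for one branch of probability `q` each side,
#' `(1-q)^2 + q^2/19`). These expectations are recorded in the truth.
#'
#' @param tree Rooted `phylo` tree.
#' @param root_length Protein length (default 600).
#' @param q Per-branch substitution probability in `[0, 1)`; scalar or one
#'   value per edge of `tree` (edge order of `tree$edge`).
#' @param seed Integer seed.
#' @return List with `records` (protein [seq_record()]s, one per tip) and
#'   `truth` (seed, q, root_length, and `expected_identity`: per tip pair
#'   the analytic expected fraction identical).
#' @export
simulate_ortholog_proteins <- function(tree, root_length = 600L, q,
                                       seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  nedge <- nrow(tree$edge)
  if (length(q) == 1L) q <- rep(q, nedge)
  if (length(q) != nedge) stop("q must be scalar or one value per edge")
  if (any(q < 0 | q >= 1)) stop("q must lie in [0, 1)")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  with_seed(seed, {
    seqs <- vector("list", ntip + tree$Nnode)
    seqs[[root]] <- sample(AA20, root_length, replace = TRUE)
    pre <- ape::reorder.phylo(tree, "cladewise")
    edge_q <- q[match(paste(pre$edge[, 1L], pre$edge[, 2L]),
                      paste(tree$edge[, 1L], tree$edge[, 2L]))]
    for (i in seq_len(nedge)) {
      parent <- pre$edge[i, 1L]; child <- pre$edge[i, 2L]
      s <- seqs[[parent]]
      mut <- which(runif(root_length) < edge_q[i])
      if (length(mut))
        s[mut] <- vapply(s[mut], function(r)
          sample(setdiff(AA20, r), 1L), character(1L))
      seqs[[child]] <- s
    }
    records <- lapply(seq_len(ntip), function(i)
      seq_record(tree$tip.label[i],
                 paste(seqs[[i]], collapse = ""), "protein",
                 species = tree$tip.label[i]))
    # analytic expectations per pair
    pairs <- if (ntip >= 2L) t(utils::combn(ntip, 2L)) else
      matrix(integer(0), ncol = 2L)
    exp_rows <- lapply(seq_len(nrow(pairs)), function(r) {
      i <- pairs[r, 1L]; j <- pairs[r, 2L]
      anc <- ape::getMRCA(tree, c(tree$tip.label[i], tree$tip.label[j]))
      path_q <- function(tip) {
        nodes <- ape::nodepath(tree, anc, tip)
        qs <- numeric(0)
        for (e in seq_len(length(nodes) - 1L))
          qs <- c(qs, q[tree$edge[, 1L] == nodes[e] &
                          tree$edge[, 2L] == nodes[e + 1L]])
        qs
      }
      a <- path_retention(path_q(i))
      b <- path_retention(path_q(j))
      data.frame(tip_a = tree$tip.label[i], tip_b = tree$tip.label[j],
                 expected_identity = a * b + (1 - a) * (1 - b) / 19,
                 stringsAsFactors = FALSE)
    })
    expected <- if (length(exp_rows)) do.call(rbind, exp_rows) else
      data.frame(tip_a = character(0), tip_b = character(0),
                 expected_identity = numeric(0))
    list(records = records,
         truth = list(kind = "ortholog_proteins", seed = seed,
                      root_length = root_length, q = q,
                      expected_identity = expected))
  })
}

#' Simulate a four-member monoamine-transporter-like paralog panel
#'
#' Four related proteins (`DAT`, `NAT`, `SERT_A`, `SERT_B`) diverged from
#' one ancestor on a fixed topology `((DAT,NAT),(SERT_A,SERT_B))`, for use
#' as a paralog-disambiguation panel in locus simulations.
#'
#' @param length Protein length (default 300).
#' @param q Per-branch substitution probability (default 0.10).
#' @param seed Integer seed.
#' @return Named list of protein [seq_record()]s.
#' @export
simulate_paralog_panel <- function(length = 300L, q = 0.10, seed = 1L) {
  tree <- ape::read.tree(text = "((DAT,NAT),(SERT_A,SERT_B));")
  sim <- simulate_ortholog_proteins(tree, root_length = length, q = q,
                                    seed = seed)
  panel <- sim$records
  names(panel) <- vapply(panel, `[[`, character(1L), "id")
  panel[c("DAT", "NAT", "SERT_A", "SERT_B")]
}

#' Toy translated search of a protein against a genome
#'
#' The package's own aligner, so no external search tool is needed: the
#' genome is translated in all six frames, split into stop-free segments,
#' and each segment of at least `min_aa` residues is aligned locally
#' (Smith-Waterman via Biostrings) against the query. Alignments scoring
#' at least `min_score` are emitted as 12-column hit rows with subject
#' coordinates mapped back to the plus strand (minus-strand hits encoded
#' `s_start > s_end`). Raw scores are converted to bit scores and
#' Karlin-Altschul e-values with the standard gapped BLOSUM62 parameters
#' (lambda = 0.267, K = 0.041), so weak chance alignments carry honest
#' significance estimates and the downstream e-value filter behaves as it
#' would on a real search.
#'
#' @param query Protein [seq_record()].
#' @param genome DNA [seq_record()].
#' @param min_aa Minimum translated segment length (default 25).
#' @param min_score Minimum local alignment raw score (default 60).
#' @param matrix Substitution matrix (default BLOSUM62).
#' @return A `hit_table` (possibly zero rows).
#' @export
align_panel_to_genome <- function(query, genome, min_aa = 25L,
                                  min_score = 60, matrix = "BLOSUM62") {
  ka_lambda <- 0.267
  ka_k <- 0.041
  stopifnot(inherits(query, "seq_record"), query$alphabet == "protein",
            inherits(genome, "seq_record"), genome$alphabet == "dna")
  submat <- get_sub_matrix(matrix)
  qlen <- nchar(query$sequence)
  n <- nchar(genome$sequence)
  # collect every stop-free segment of at least min_aa residues over all
  # six frames, then align them against the query in one batched call
  seg_seq <- character(0)
  seg_meta <- list()
  for (strand in c("+", "-")) {
    dna <- if (strand == "+") genome$sequence else revcomp(genome$sequence)
    dna_noN <- gsub("N", "A", dna, fixed = TRUE)
    for (f in 0:2) {
      naa <- (n - f) %/% 3L
      if (naa < min_aa) next
      sub <- substr(dna_noN, f + 1L, f + naa * 3L)
      aa <- as.character(Biostrings::translate(Biostrings::DNAString(sub)))
      segs <- strsplit(aa, "*", fixed = TRUE)[[1L]]
      offs <- cumsum(c(0L, nchar(segs[-length(segs)]) + 1L))
      keep <- which(nchar(segs) >= min_aa)
      for (si in keep) {
        seg_seq <- c(seg_seq, segs[si])
        seg_meta[[length(seg_meta) + 1L]] <- list(strand = strand, f = f,
                                                  a0 = offs[si])
      }
    }
  }
  rows <- list()
  if (length(seg_seq)) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(seg_seq),
      Biostrings::AAString(query$sequence),
      substitutionMatrix = submat, gapOpening = 10, gapExtension = 0.5,
      type = "local")
    scores <- Biostrings::score(pa)
    for (si in which(scores >= min_score)) {
      sc <- scores[si]
      meta <- seg_meta[[si]]
      sa <- unname(as.character(Biostrings::alignedPattern(pa[si])))
      qa <- unname(as.character(Biostrings::alignedSubject(pa[si])))
      ca <- strsplit(qa, "", fixed = TRUE)[[1L]]
      cb <- strsplit(sa, "", fixed = TRUE)[[1L]]
      both <- ca != "-" & cb != "-"
      ident <- sum(both & ca == cb)
      gap_opens <- count_gap_opens(ca) + count_gap_opens(cb)
      q1 <- Biostrings::start(Biostrings::subject(pa))[si]
      q2 <- Biostrings::end(Biostrings::subject(pa))[si]
      p1 <- Biostrings::start(Biostrings::pattern(pa))[si]  # aa in segment
      p2 <- Biostrings::end(Biostrings::pattern(pa))[si]
      d_start0 <- meta$f + 3L * (meta$a0 + p1 - 1L)
      d_end0 <- meta$f + 3L * (meta$a0 + p2)
      if (meta$strand == "+") {
        s_start <- d_start0 + 1L; s_end <- d_end0
      } else {
        s_start <- n - d_start0       # = plus-strand end, 1-based
        s_end <- n - d_end0 + 1L      # = plus-strand start + 1
      }
      bit <- (ka_lambda * sc - log(ka_k)) / log(2)
      evalue <- ka_k * qlen * n * exp(-ka_lambda * sc)
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = query$id, subject_id = genome$id,
        percent_identity = 100 * ident / sum(both),
        aln_length = length(ca), mismatches = sum(both) - ident,
        gap_opens = gap_opens, q_start = q1, q_end = q2,
        s_start = s_start, s_end = s_end, e_value = evalue,
        bit_score = bit, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_hit_table())
  df <- do.call(rbind, rows)
  df$s_strand <- ifelse(df$s_start > df$s_end, "-", "+")
  df$s_start0 <- ifelse(df$s_strand == "+", df$s_start - 1, df$s_end - 1)
  df$s_end0 <- ifelse(df$s_strand == "+", df$s_end, df$s_start)
  df <- df[order(-df$bit_score), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("hit_table", "data.frame")
  df
}

count_gap_opens <- function(chars) {
  r <- rle(chars == "-")
  sum(r$values)
}

#' Simulate a gene locus with flank genes, optional middle gene, decoys
#' and assembly gaps
#'
#' Builds a toy chromosome `flank_a | intergenic | flank_b | decoy region`
#' where the intergenic span optionally carries the reverse-translated
#' target gene, plus optional N-gap runs, and decoy paralog genes placed
#' outside the flanked interval. The accompanying hit table is produced by
#' the package's own translated search ([align_panel_to_genome()]) of the
#' target protein against the simulated chromosome.
#'
#' @param species Species label.
#' @param panel Named paralog panel (see [simulate_paralog_panel()]); must
#'   contain `target`.
#' @param target Panel name of the gene under test (default `"DAT"`).
#' @param gene_present Logical: plant the target gene in the interval?
#' @param decoys Character vector of panel names planted outside the
#'   interval (e.g. `"NAT"`).
#' @param flank_length Two flank gene lengths in bp (default 1000, 1000).
#' @param intergenic_length Width of the flanked interval (default 4000).
#' @param n_gap_runs Integer vector of N-run lengths inserted into the
#'   interval (empty for a clean assembly).
#' @param gc Background GC (default 0.4).
#' @param seed Integer seed.
#' @return List: `genome` (dna [seq_record()]), `flanks` (BED-style
#'   [gene_interval()] rows), `interval` ([syntenic_interval()]), `hits`
#'   (`hit_table` of target vs genome), `panel`, and `truth` (planted
#'   presence, spans of gene/decoys/gaps, seed).
#' @export
simulate_locus <- function(species, panel, target = "DAT",
                           gene_present = TRUE, decoys = character(0),
                           flank_length = c(1000L, 1000L),
                           intergenic_length = 4000L,
                           n_gap_runs = integer(0), gc = 0.4, seed = 1L) {
  if (!target %in% names(panel)) stop("target '", target, "' not in panel")
  if (length(setdiff(decoys, names(panel))))
    stop("decoy(s) not in panel: ",
         paste(setdiff(decoys, names(panel)), collapse = ", "))
  gene_dna <- reverse_translate(panel[[target]])
  if (gene_present && nchar(gene_dna) + 20L > intergenic_length)
    stop("gene (", nchar(gene_dna), " bp) too long for intergenic span (",
         intergenic_length, " bp)")
  with_seed(seed, {
    inter <- strsplit(random_dna(intergenic_length, gc), "",
                      fixed = TRUE)[[1L]]
    gene_span <- NULL
    if (gene_present) {
      g0 <- (intergenic_length - nchar(gene_dna)) %/% 2L
      inter[(g0 + 1L):(g0 + nchar(gene_dna))] <-
        strsplit(gene_dna, "", fixed = TRUE)[[1L]]
      gene_span <- c(g0, g0 + nchar(gene_dna))   # interval-local, half-open
    }
    gap_spans <- list()
    if (length(n_gap_runs)) {
      avail_end <- if (gene_present) gene_span[1L] - 10L else
        intergenic_length - 10L
      pos <- 10L
      for (run in n_gap_runs) {
        if (pos + run > avail_end)
          stop("N-gap runs do not fit in the interval")
        inter[(pos + 1L):(pos + run)] <- "N"
        gap_spans[[length(gap_spans) + 1L]] <- c(pos, pos + run)
        pos <- pos + run + 10L
      }
    }
    # decoy paralogs are distinct loci elsewhere in the genome: space them
    # beyond the intron-chaining allowance so hits to different genes are
    # never merged into one chain (real paralogs sit megabases apart)
    decoy_spacing <- 11000L
    decoy_parts <- character(0)
    decoy_rows <- list()
    offset_tail <- 0L
    for (d in decoys) {
      spacer <- random_dna(decoy_spacing, gc)
      d_dna <- reverse_translate(panel[[d]])
      decoy_rows[[length(decoy_rows) + 1L]] <-
        data.frame(decoy = d, offset_in_tail = offset_tail + decoy_spacing,
                   length = nchar(d_dna), stringsAsFactors = FALSE)
      decoy_parts <- c(decoy_parts, spacer, d_dna)
      offset_tail <- offset_tail + decoy_spacing + nchar(d_dna)
    }
    chrom_seq <- paste0(random_dna(flank_length[1L], gc),
                        paste(inter, collapse = ""),
                        random_dna(flank_length[2L], gc),
                        paste(decoy_parts, collapse = ""),
                        random_dna(300L, gc))
    chrom_id <- paste0(species, "_chr1")
    genome <- seq_record(chrom_id, chrom_seq, "dna", species = species)
    fa <- gene_interval(species, chrom_id, 0L, flank_length[1L], "+",
                        "flankA")
    fb_start <- flank_length[1L] + intergenic_length
    fb <- gene_interval(species, chrom_id, fb_start,
                        fb_start + flank_length[2L], "+", "flankB")
    interval <- syntenic_interval(fa, fb)
    hits <- align_panel_to_genome(panel[[target]], genome)
    flanks <- rbind(fa, fb)
    class(flanks) <- c("gene_interval", "data.frame")
    tail_origin <- fb_start + flank_length[2L]
    decoy_df <- if (length(decoy_rows)) {
      dd <- do.call(rbind, decoy_rows)
      dd$start <- tail_origin + dd$offset_in_tail
      dd$end <- dd$start + dd$length
      dd
    } else data.frame(decoy = character(0), offset_in_tail = integer(0),
                      length = integer(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
    gaps_df <- if (length(gap_spans)) {
      gm <- do.call(rbind, gap_spans)
      data.frame(start = flank_length[1L] + gm[, 1L],
                 end = flank_length[1L] + gm[, 2L])
    } else data.frame(start = integer(0), end = integer(0))
    list(genome = genome, flanks = flanks, interval = interval,
         hits = hits, panel = panel,
         truth = list(kind = "locus", seed = seed, species = species,
                      target = target, gene_present = gene_present,
                      gene_span = if (gene_present)
                        gene_span + flank_length[1L] else NULL,
                      decoys = decoy_df, gaps = gaps_df,
                      interval = c(interval$start, interval$end)))
  })
}
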