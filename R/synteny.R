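#' Presence-call parameters
#'
#' Thresholds governing when alignment-hit chains count as evidence that a
#' gene is present, and when a locus is clean enough to call the gene
#' absent. The published analysis applied these judgments manually; here
#' they are explicit, configurable, and echoed into every call.
#'
#' @param min_identity Minimum chain mean percent identity (default 35).
#' @param min_query_coverage Minimum fraction of the query protein covered
#'   by a chain (default 0.40).
#' @param max_evalue Maximum e-value (default 1e-5); rows with a missing
#'   e-value (`"."`) are not filtered on it.
#' @param chain_gap Maximum subject-side gap (bp) merged into one chain —
#'   an intron allowance (default 10000).
#' @param gap_max Maximum assembly-gap (N) fraction of the syntenic
#'   interval for an `absent` call (default 0.10).
#' @return An object of class `call_params`.
#' @export
call_params <- function(min_identity = 35, min_query_coverage = 0.40,
                        max_evalue = 1e-5, chain_gap = 10000,
                        gap_max = 0.10) {
  if (min_identity < 0 || min_identity > 100)
    stop("min_identity must be in [0,100]")
  if (min_query_coverage < 0 || min_query_coverage > 1)
    stop("min_query_coverage must be in [0,1]")
  if (max_evalue <= 0) stop("max_evalue must be positive")
  if (chain_gap < 0) stop("chain_gap must be non-negative")
  if (gap_max < 0 || gap_max > 1) stop("gap_max must be in [0,1]")
  structure(list(min_identity = min_identity,
                 min_query_coverage = min_query_coverage,
                 max_evalue = max_evalue, chain_gap = chain_gap,
                 gap_max = gap_max),
            class = "call_params")
}

#' The syntenic interval between two flank genes
#'
#' The span strictly between two marker genes (e.g. the CLPTM1L-LPCAT1
#' pair that brackets the locus of interest), where the middle gene is
#' expected to sit. Order of the flanks on the chromosome is irrelevant.
#'
#' @param flank_a,flank_b One-row [gene_interval()]s on the same species
#'   and chromosome; must not overlap.
#' @return An object of class `syntenic_interval` with `species`, `chrom`,
#'   `start`, `end` (0-based half-open) and the two flanks.
#' @export
syntenic_interval <- function(flank_a, flank_b) {
  stopifnot(inherits(flank_a, "gene_interval"),
            inherits(flank_b, "gene_interval"),
            nrow(flank_a) == 1L, nrow(flank_b) == 1L)
  if (flank_a$species != flank_b$species)
    stop("flanks from different species")
  if (flank_a$chrom != flank_b$chrom)
    stop("synteny broken: flanks on different chromosomes (",
         flank_a$chrom, " vs ", flank_b$chrom, ")")
  if (flank_a$start < flank_b$end && flank_b$start < flank_a$end)
    stop("flank genes overlap; no interval between them")
  start <- min(flank_a$end, flank_b$end)
  end <- max(flank_a$start, flank_b$start)
  structure(list(species = flank_a$species, chrom = flank_a$chrom,
                 start = start, end = end,
                 flank_a = flank_a, flank_b = flank_b),
            class = "syntenic_interval")
}

#' @export
print.syntenic_interval <- function(x, ...) {
  cat(sprintf("<syntenic_interval> %s %s:[%d,%d) (%d bp) between %s and %s\n",
              x$species, x$chrom, x$start, x$end, x$end - x$start,
              x$flank_a$gene_name, x$flank_b$gene_name))
  invisible(x)
}

#' Assembly-gap census of an interval
#'
#' Exact run-length census of N characters, used to decide whether an
#' absence call could instead be an assembly artifact.
#'
#' @param interval_seq DNA string or [seq_record()] of the interval.
#' @return An object of class `gap_report`: `n_runs`, `n_fraction`,
#'   `longest_run`, `length`.
#' @export
assess_assembly <- function(interval_seq) {
  s <- if (is.list(interval_seq)) interval_seq$sequence else interval_seq
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
  r <- rle(ch == "N")
  n_runs <- sum(r$values)
  longest <- if (n_runs) max(r$lengths[r$values]) else 0L
  structure(list(n_runs = n_runs,
                 n_fraction = sum(ch == "N") / length(ch),
                 longest_run = longest, length = length(ch)),
            class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  cat(sprintf("<gap_report> %d N runs, fraction %.3f, longest %d of %d bp\n",
              x$n_runs, x$n_fraction, x$longest_run, x$length))
  invisible(x)
}

#' Chain co-linear alignment hits and measure query coverage
#'
#' Local hits of one query protein against one genome (typically one hit
#' per exon) are grouped by subject sequence and strand, merged whenever
#' the subject-side gap between consecutive hits is at most `chain_gap`,
#' and each chain's query coverage is computed as the length of the union
#' of its query spans divided by the query length.
#'
#' @param hits A `hit_table` for one query (see [read_hit_table()]).
#' @param query_length Query protein length (residues).
#' @param params A [call_params()] (supplies `chain_gap`).
#' @return List of chains sorted by decreasing coverage; each chain is a
#'   list with `subject_id`, `strand`, `s_start0`, `s_end0`, `coverage`,
#'   `mean_identity` (alignment-length weighted), `min_evalue` (`NA` when
#'   absent on all rows), and the member `hits`.
#' @export
chain_hits <- function(hits, query_length, params = call_params()) {
  stopifnot(query_length > 0)
  if (!nrow(hits)) return(list())
  chains <- list()
  for (sid in unique(hits$subject_id)) {
    for (str in unique(hits$s_strand[hits$subject_id == sid])) {
      h <- hits[hits$subject_id == sid & hits$s_strand == str, ,
                drop = FALSE]
      h <- h[order(h$s_start0), , drop = FALSE]
      grp <- cumsum(c(1, (h$s_start0[-1L] >
                            cummax_end(h) + params$chain_gap)[seq_len(nrow(h) - 1L)]))
      for (g in unique(grp)) {
        hg <- h[grp == g, , drop = FALSE]
        cov <- union_len(hg$q_start, hg$q_end) / query_length
        chains[[length(chains) + 1L]] <- list(
          subject_id = sid, strand = str,
          s_start0 = min(hg$s_start0), s_end0 = max(hg$s_end0),
          coverage = cov,
          mean_identity = sum(hg$percent_identity * hg$aln_length) /
            sum(hg$aln_length),
          min_evalue = if (all(is.na(hg$e_value))) NA_real_
                       else min(hg$e_value, na.rm = TRUE),
          hits = hg)
      }
    }
  }
  chains[order(-vapply(chains, `[[`, numeric(1L), "coverage"))]
}

# running maximum of subject end for gap computation against the chain so far
cummax_end <- function(h) cummax(h$s_end0)[-nrow(h)]

# total length of the union of 1-based inclusive intervals
union_len <- function(starts, ends) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  tot <- 0; cur_s <- starts[1L]; cur_e <- ends[1L]
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] <= cur_e + 1) cur_e <- max(cur_e, ends[i])
    else { tot <- tot + cur_e - cur_s + 1; cur_s <- starts[i]; cur_e <- ends[i] }
  }
  tot + cur_e - cur_s + 1
}

#' Assign a candidate region to its best-matching paralog
#'
#' High-scoring hits at a monoamine-transporter locus are frequently to a
#' closely related family member (NAT or SERT) rather than the gene under
#' test; this disambiguates by global alignment of the region's protein
#' against a reference panel. Ties are broken by higher identity, then by
#' panel order, and flagged.
#'
#' @param region_protein Protein string or [seq_record()] for the region.
#' @param panel Named list of reference protein [seq_record()]s (e.g.
#'   `DAT`, `NAT`, `SERT_A`, `SERT_B`); non-empty.
#' @param matrix Substitution matrix (default BLOSUM62).
#' @return List: `paralog` (panel name), `score`, `margin` (score gap to
#'   the runner-up; `Inf` for a singleton panel), `tie` (logical),
#'   `scores` (named vector).
#' @export
classify_hit_paralog <- function(region_protein, panel,
                                 matrix = "BLOSUM62") {
  if (!length(panel)) stop("empty paralog panel")
  if (is.null(names(panel)) || any(!nzchar(names(panel))))
    names(panel) <- vapply(panel, function(p) p$id, character(1L))
  scores <- numeric(length(panel))
  idents <- numeric(length(panel))
  for (i in seq_along(panel)) {
    aln <- global_align(region_protein, panel[[i]], matrix = matrix)
    scores[i] <- aln$score
    idents[i] <- identity_similarity(aln)$identity_pct
  }
  names(scores) <- names(panel)
  best_score <- max(scores)
  cand <- which(scores == best_score)
  tie <- FALSE
  if (length(cand) > 1L) {
    best_id <- max(idents[cand])
    cand2 <- cand[idents[cand] == best_id]
    tie <- length(cand2) > 1L
    cand <- cand2[1L]   # declared order: panel order breaks exact ties
  }
  margin <- if (length(panel) == 1L) Inf
            else best_score - max(scores[-cand[1L]])
  list(paralog = names(panel)[cand[1L]], score = best_score,
       margin = margin, tie = tie, scores = scores)
}

# best translated protein segment of a genomic region (six frames on the
# reported strand's two frames set: three frames of the given strand),
# segments split at stop codons
translate_region_segments <- function(dna, min_aa = 25L) {
  out <- character(0)
  n <- nchar(dna)
  for (f in 0:2) {
    if (n - f < 3L) next
    sub <- substr(dna, f + 1L, f + ((n - f) %/% 3L) * 3L)
    aa <- suppressWarnings(as.character(Biostrings::translate(
      Biostrings::DNAString(gsub("N", "A", sub)),
      if.fuzzy.codon = "solve")))
    segs <- strsplit(aa, "*", fixed = TRUE)[[1L]]
    out <- c(out, segs[nchar(segs) >= min_aa])
  }
  out
}

#' Call gene presence/absence for one species
#'
#' Combines chained alignment evidence, the flank-defined syntenic
#' interval, and assembly quality into a per-species verdict. A chain
#' qualifies as evidence of the target gene when its query coverage,
#' identity and (when available) e-value pass [call_params()] thresholds
#' and its translated region classifies to the target in the paralog
#' panel. Verdicts: `present_syntenic` (qualifying chain overlapping the
#' interval), `present_elsewhere` (qualifying chain anywhere else — a
#' translocated gene is not "lost"), `absent` (no qualifying chain, both
#' flanks located, interval N-fraction at most `gap_max`), otherwise
#' `indeterminate` with the reason recorded.
#'
#' @param hits `hit_table` of the target-gene query vs this genome.
#' @param query_length Length of the query protein (residues).
#' @param interval A [syntenic_interval()], or `NULL` when the flanks
#'   could not be located.
#' @param gap_report An [assess_assembly()] report for the interval (or
#'   `NULL` when no interval).
#' @param panel Paralog reference panel (see [classify_hit_paralog()]).
#' @param target Panel name of the gene under test (e.g. `"DAT"`).
#' @param genome Optional dna [seq_record()] list/named list keyed by
#'   subject id, used to translate chain regions for paralog
#'   classification; without it the paralog filter cannot run and chains
#'   are classified as the target by alignment statistics alone.
#' @param params A [call_params()].
#' @param species,gene Labels on the call (default from the interval).
#' @return An object of class `presence_call`: `species`, `gene`,
#'   `verdict`, `reason`, `evidence` (chain summary data frame, gap
#'   report, parameter echo).
#' @export
call_presence <- function(hits, query_length, interval, gap_report, panel,
                          target, genome = NULL, params = call_params(),
                          species = NULL, gene = target) {
  if (is.null(species))
    species <- if (!is.null(interval)) interval$species else ""
  chains <- chain_hits(hits, query_length, params)
  summ <- data.frame(subject_id = character(0), strand = character(0),
                     s_start0 = numeric(0), s_end0 = numeric(0),
                     coverage = numeric(0), mean_identity = numeric(0),
                     min_evalue = numeric(0), paralog = character(0),
                     qualifying = logical(0), in_interval = logical(0),
                     stringsAsFactors = FALSE)
  genome_list <- NULL
  if (!is.null(genome)) {
    if (inherits(genome, "seq_record")) genome <- list(genome)
    genome_list <- stats::setNames(genome, vapply(genome, `[[`, character(1L),
                                                  "id"))
  }
  for (ch in chains) {
    stats_ok <- ch$coverage >= params$min_query_coverage &&
      ch$mean_identity >= params$min_identity &&
      (is.na(ch$min_evalue) || ch$min_evalue <= params$max_evalue)
    paralog <- NA_character_
    if (stats_ok && !is.null(genome_list) &&
        ch$subject_id %in% names(genome_list)) {
      region <- substr(genome_list[[ch$subject_id]]$sequence,
                       ch$s_start0 + 1L, ch$s_end0)
      if (ch$strand == "-") region <- revcomp(region)
      segs <- translate_region_segments(region)
      if (length(segs)) {
        # the longest stop-free segment is the candidate coding frame
        paralog <- classify_hit_paralog(segs[which.max(nchar(segs))],
                                        panel)$paralog
      }
    } else if (stats_ok && is.null(genome_list)) {
      paralog <- target   # no sequence context: statistics alone decide
    }
    qual <- stats_ok && identical(paralog, target)
    in_int <- !is.null(interval) && ch$subject_id == interval$chrom &&
      ch$s_start0 < interval$end && ch$s_end0 > interval$start
    summ <- rbind(summ, data.frame(
      subject_id = ch$subject_id, strand = ch$strand,
      s_start0 = ch$s_start0, s_end0 = ch$s_end0, coverage = ch$coverage,
      mean_identity = ch$mean_identity, min_evalue = ch$min_evalue,
      paralog = paralog, qualifying = qual, in_interval = in_int,
      stringsAsFactors = FALSE))
  }
  flanks_located <- !is.null(interval)
  if (any(summ$qualifying & summ$in_interval)) {
    verdict <- "present_syntenic"; reason <- "qualifying chain in syntenic interval"
  } else if (any(summ$qualifying)) {
    verdict <- "present_elsewhere"
    reason <- "qualifying chain outside syntenic interval"
  } else if (flanks_located && !is.null(gap_report) &&
             gap_report$n_fraction <= params$gap_max) {
    verdict <- "absent"
    reason <- sprintf("no qualifying chain; interval N fraction %.3f <= %.3f",
                      gap_report$n_fraction, params$gap_max)
  } else {
    verdict <- "indeterminate"
    reason <- if (!flanks_located) "flank genes not located"
      else if (is.null(gap_report)) "no assembly-gap assessment available"
      else sprintf("interval N fraction %.3f exceeds gap_max %.3f",
                   gap_report$n_fraction, params$gap_max)
  }
  structure(list(species = species, gene = gene, verdict = verdict,
                 reason = reason,
                 evidence = list(chains = summ, gap_report = gap_report,
                                 params = unclass(params))),
            class = "presence_call")
}

#' @export
print.presence_call <- function(x, ...) {
  cat(sprintf("<presence_call> %s %s: %s (%s)\n", x$species, x$gene,
              x$verdict, x$reason))
  invisible(x)
}
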