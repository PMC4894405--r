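#' Extract a promoter window upstream of a TSS
#'
#' Returns the W bases immediately upstream of a transcription start site,
#' 5'->3' on the coding strand. The promoter convention used throughout the
#' package: index `W - 1` is position -1 (the base immediately upstream of
#' the TSS) and index 0 is position `-W`; the upstream offset of index `i`
#' is `u(i) = W - i`. For a minus-strand gene the reverse complement of the
#' `W` bases to the right of the TSS is taken. Fewer than `W` available
#' bases is an error (no silent truncation).
#'
#' @param chrom_seq A dna [seq_record()] holding the chromosome/scaffold.
#' @param tss 0-based position of the transcription start site.
#' @param strand `"+"` or `"-"` (gene orientation).
#' @param W Promoter width in bp (default 2500).
#' @param promoter_id,species,gene_label Labels carried on the result.
#' @return A `promoter` object: a dna record with `promoter_id`,
#'   `gene_label` and `W` fields.
#' @export
extract_promoter <- function(chrom_seq, tss, strand = c("+", "-"), W = 2500L,
                             promoter_id = NULL, species = NULL,
                             gene_label = "") {
  strand <- match.arg(strand)
  stopifnot(inherits(chrom_seq, "seq_record"), chrom_seq$alphabet == "dna")
  n <- nchar(chrom_seq$sequence)
  if (W < 1L) stop("W must be >= 1")
  if (tss < 0 || tss >= n) stop("tss ", tss, " outside [0, ", n, ")")
  if (strand == "+") {
    if (tss - W < 0)
      stop("only ", tss, " bases upstream of tss; need W = ", W,
           " (short by ", W - tss, ")")
    seq <- substr(chrom_seq$sequence, tss - W + 1L, tss)
  } else {
    if (tss + 1L + W > n)
      stop("only ", n - tss - 1L, " bases upstream of tss (minus strand); ",
           "need W = ", W, " (short by ", tss + 1L + W - n, ")")
    seq <- revcomp(substr(chrom_seq$sequence, tss + 2L, tss + 1L + W))
  }
  if (is.null(promoter_id)) promoter_id <- paste0(chrom_seq$id, ":tss", tss)
  if (is.null(species)) species <- chrom_seq$species
  structure(list(promoter_id = promoter_id, species = species,
                 gene_label = gene_label, sequence = seq, alphabet = "dna",
                 W = W),
            class = c("promoter", "seq_record"))
}

#' @export
print.promoter <- function(x, ...) {
  cat(sprintf("<promoter> %s (%s, %s), W=%d\n", x$promoter_id, x$species,
              x$gene_label, x$W))
  invisible(x)
}

#' Detect CpG islands
#'
#' Classical criteria: every `min_length`-bp window (1-bp slide) with GC
#' fraction >= `gc_min` and observed/expected CpG ratio
#' `(#CG * length) / (#C * #G)` >= `oe_min` qualifies; overlapping
#' qualifying windows are merged into maximal regions, whose statistics are
#' reported. Used to sanity-check TSS placement (distance from island to
#' TSS); it never relocates a TSS.
#'
#' @param seq A dna [seq_record()] or plain DNA string.
#' @param min_length Minimum island length (default 200).
#' @param gc_min Minimum GC fraction (default 0.5).
#' @param oe_min Minimum observed/expected CpG (default 0.6).
#' @return `data.frame` with columns `start`, `end` (0-based half-open),
#'   `gc_fraction`, `obs_exp_cpg`; zero rows when nothing qualifies.
#' @export
find_cpg_islands <- function(seq, min_length = 200L, gc_min = 0.5,
                             oe_min = 0.6) {
  s <- if (is.list(seq)) seq$sequence else seq
  n <- nchar(s)
  empty <- data.frame(start = integer(0), end = integer(0),
                      gc_fraction = numeric(0), obs_exp_cpg = numeric(0))
  if (n < min_length) return(empty)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  is_c <- as.integer(ch == "C")
  is_g <- as.integer(ch == "G")
  is_cg <- as.integer(ch[-n] == "C" & ch[-1L] == "G")
  cum_c <- c(0L, cumsum(is_c))
  cum_g <- c(0L, cumsum(is_g))
  cum_cg <- c(0L, cumsum(is_cg))
  win_stats <- function(start, end) {   # 0-based half-open, vectorised
    len <- end - start
    nc <- cum_c[end + 1L] - cum_c[start + 1L]
    ng <- cum_g[end + 1L] - cum_g[start + 1L]
    # CpG dinucleotides fully inside the window: positions start..end-2
    ncg <- cum_cg[pmax(end - 1L, start) + 1L] - cum_cg[start + 1L]
    gc <- (nc + ng) / len
    oe <- ifelse(nc > 0 & ng > 0, ncg * len / (nc * ng), 0)
    list(gc = gc, oe = oe)
  }
  starts <- 0:(n - min_length)
  st <- win_stats(starts, starts + min_length)
  ok <- st$gc >= gc_min & st$oe >= oe_min
  if (!any(ok)) return(empty)
  # merge overlapping qualifying windows into maximal regions
  runs <- rle(ok)
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1L
  keep <- which(runs$values)
  out <- lapply(keep, function(r) {
    a <- starts[idx_start[r]]
    b <- starts[idx_end[r]] + min_length
    stx <- win_stats(a, b)
    data.frame(start = a, end = b, gc_fraction = stx$gc, obs_exp_cpg = stx$oe)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assign a promoter hit to its upstream 500-bp segment
#'
#' Promoters are divided into consecutive segments of `L` bp starting at
#' the TSS: segment 1 covers positions -1 .. -L, segment 2 covers
#' -(L+1) .. -2L, and so on. A hit is assigned by its leftmost base: with
#' upstream offset `u = W - start`, the segment is
#' `k = floor((u - 1) / L) + 1`.
#'
#' @param start Hit start (0-based promoter coordinate); vectorised.
#' @param W Promoter width (default 2500).
#' @param L Segment length (default 500).
#' @return Integer segment indices (1..W/L for in-bounds hits).
#' @export
assign_segment <- function(start, W = 2500L, L = 500L) {
  if (any(start < 0 | start >= W))
    stop("hit start outside promoter [0, ", W, ")")
  u <- W - start
  as.integer(floor((u - 1) / L) + 1L)
}

#' Group promoters of one lineage
#'
#' @param lineage_name Label, e.g. `"avian_NAT"`.
#' @param promoters List of [extract_promoter()] objects (or dna records of
#'   equal length), one per species; species must be unique.
#' @param reference_species The species whose promoter coordinates anchor
#'   reporting (e.g. zebra finch for avian NAT, mouse for the mammalian
#'   sets); must be among the promoters.
#' @return An object of class `lineage_set`.
#' @export
lineage_set <- function(lineage_name, promoters, reference_species) {
  if (!length(promoters)) stop("lineage '", lineage_name, "': no promoters")
  sp <- vapply(promoters, function(p) p$species, character(1L))
  if (anyDuplicated(sp))
    stop("lineage '", lineage_name, "': duplicate species ",
         sp[duplicated(sp)][1L])
  if (!(reference_species %in% sp))
    stop("reference species '", reference_species, "' not in lineage '",
         lineage_name, "'")
  Ws <- vapply(promoters, function(p)
    if (!is.null(p$W)) p$W else nchar(p$sequence), numeric(1L))
  if (length(unique(Ws)) != 1L)
    stop("lineage '", lineage_name, "': promoters of unequal width")
  names(promoters) <- sp
  structure(list(lineage_name = lineage_name, promoters = promoters,
                 species = sp, reference_species = reference_species,
                 W = as.integer(Ws[1L])),
            class = "lineage_set")
}

#' @export
print.lineage_set <- function(x, ...) {
  cat(sprintf("<lineage_set> %s: %d species (%s), reference=%s, W=%d\n",
              x$lineage_name, length(x$species),
              paste(x$species, collapse = ", "), x$reference_species, x$W))
  invisible(x)
}

#' Lineage-conserved promoter elements
#'
#' A (matrix, segment) pair counts as conserved within a lineage only when
#' every species of the lineage has at least one hit of that matrix whose
#' leftmost base falls in that segment; all non-conserved sites are dropped.
#' Each (matrix, segment) pair is treated independently, so a matrix can be
#' conserved in several segments.
#'
#' @param lineage A [lineage_set()].
#' @param hits A `motif_hits` data frame over the lineage's promoters (from
#'   [scan_promoters()]); a species in `hits` absent from the lineage is an
#'   error.
#' @param L Segment length (default 500).
#' @return `data.frame` of class `conserved_elements` with columns
#'   `matrix_id`, `name`, `segment`, ordered by (matrix_id, segment), plus
#'   a `"hits"` attribute holding the supporting hits (with `segment` and
#'   `element` key columns) and `"lineage"`, `"species"`, `"W"`, `"L"`
#'   attributes.
#' @export
lineage_conserved_elements <- function(lineage, hits, L = 500L) {
  stopifnot(inherits(lineage, "lineage_set"))
  extra <- setdiff(unique(hits$species), lineage$species)
  if (length(extra))
    stop("hits contain species not in lineage '", lineage$lineage_name,
         "': ", paste(extra, collapse = ", "))
  W <- lineage$W
  out <- data.frame(matrix_id = character(0), name = character(0),
                    segment = integer(0), stringsAsFactors = FALSE)
  sup <- hits[0, , drop = FALSE]
  if (nrow(hits)) {
    hits$segment <- assign_segment(hits$start, W = W, L = L)
    hits$element <- paste(hits$matrix_id, hits$segment, sep = "|")
    tab <- unique(hits[, c("matrix_id", "name", "segment", "species",
                           "element")])
    n_sp <- tapply(tab$species, tab$element, function(x) length(unique(x)))
    conserved <- names(n_sp)[n_sp == length(lineage$species)]
    if (length(conserved)) {
      el <- unique(tab[tab$element %in% conserved,
                       c("matrix_id", "name", "segment", "element")])
      el <- el[order(el$matrix_id, el$segment), , drop = FALSE]
      out <- el[, c("matrix_id", "name", "segment")]
      rownames(out) <- NULL
      sup <- hits[hits$element %in% conserved, , drop = FALSE]
      rownames(sup) <- NULL
    }
  }
  structure(out,
            hits = sup, lineage = lineage$lineage_name,
            species = lineage$species, W = W, L = L,
            reference_species = lineage$reference_species,
            class = c("conserved_elements", "data.frame"))
}

element_keys <- function(ce) {
  if (!nrow(ce)) character(0) else paste(ce$matrix_id, ce$segment, sep = "|")
}

#' Elements shared between the avian NAT lineage and each mammalian lineage
#'
#' Intersects the lineage-conserved element sets: an avian element is
#' shared with a mammalian set when the same matrix is conserved in the
#' same segment (optionally within +/- `segment_tolerance` segments).
#'
#' @param avian Conserved elements of the avian NAT lineage
#'   ([lineage_conserved_elements()]).
#' @param mammalian_nat,mammalian_dat Conserved elements of the mammalian
#'   NAT and DAT lineages.
#' @param segment_tolerance Allowed segment-index difference (default 0,
#'   i.e. same segment).
#' @return An object of class `shared_element_report` with data frames
#'   `shared_with_NAT` and `shared_with_DAT` (columns `matrix_id`, `name`,
#'   `segment` (avian), `segment_other`); an element may appear in both.
#' @export
shared_elements <- function(avian, mammalian_nat, mammalian_dat,
                            segment_tolerance = 0L) {
  match_sets <- function(a, b) {
    rows <- list()
    for (i in seq_len(nrow(a))) {
      j <- which(b$matrix_id == a$matrix_id[i] &
                   abs(b$segment - a$segment[i]) <= segment_tolerance)
      if (length(j)) {
        jj <- j[which.min(abs(b$segment[j] - a$segment[i]))]
        rows[[length(rows) + 1L]] <-
          data.frame(matrix_id = a$matrix_id[i], name = a$name[i],
                     segment = a$segment[i], segment_other = b$segment[jj],
                     stringsAsFactors = FALSE)
      }
    }
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(matrix_id = character(0), name = character(0),
                 segment = integer(0), segment_other = integer(0),
                 stringsAsFactors = FALSE)
    out[order(out$matrix_id, out$segment), , drop = FALSE]
  }
  structure(list(shared_with_NAT = match_sets(avian, mammalian_nat),
                 shared_with_DAT = match_sets(avian, mammalian_dat),
                 segment_tolerance = segment_tolerance,
                 anchored = FALSE, anchor_matrix_id = NA_character_,
                 anchors = NULL),
            class = "shared_element_report")
}

#' @export
print.shared_element_report <- function(x, ...) {
  cat(sprintf("<shared_element_report> %d shared with mammalian NAT, %d with mammalian DAT%s\n",
              nrow(x$shared_with_NAT), nrow(x$shared_with_DAT),
              if (x$anchored) paste0("; anchored on ", x$anchor_matrix_id)
              else " (not anchored)"))
  invisible(x)
}

# most TSS-proximal supporting hit of one element for one species:
# smallest upstream offset u = W - start
proximal_hit_u <- function(ce, matrix_id, segment, species) {
  h <- attr(ce, "hits")
  W <- attr(ce, "W")
  h <- h[h$matrix_id == matrix_id & h$segment == segment &
           h$species == species, , drop = FALSE]
  if (!nrow(h)) return(NA_real_)
  min(W - h$start)
}

#' Anchor shared elements on a common proximal motif
#'
#' Promoter maps from different lineages are aligned on a motif (by default
#' an ARNT matrix) conserved in the proximal segment of every lineage: in
#' each lineage's reference species the most TSS-proximal conserved anchor
#' hit defines position 0, and every shared element is reported at offset
#' `u_anchor - u_element` (elements further upstream are negative). If the
#' anchor is not conserved in segment 1 of every lineage the report is
#' returned un-anchored with a flag, not an error.
#'
#' @param report A [shared_elements()] report.
#' @param conserved Named list of the three
#'   [lineage_conserved_elements()] results, names `avian`,
#'   `mammalian_nat`, `mammalian_dat`.
#' @param anchor_matrix_id Matrix id of the anchor motif.
#' @return The report with `anchored = TRUE`, per-lineage anchor offsets in
#'   `anchors` (including the anchored TSS position `u_anchor`), and
#'   columns `anchored_pos` (avian reference) and `anchored_pos_other`
#'   added to both shared tables; or the input flagged un-anchored.
#' @export
anchor_positions <- function(report, conserved, anchor_matrix_id) {
  stopifnot(inherits(report, "shared_element_report"))
  need <- c("avian", "mammalian_nat", "mammalian_dat")
  if (!all(need %in% names(conserved)))
    stop("'conserved' must have elements ", paste(need, collapse = ", "))
  anchors <- list()
  for (nm in need) {
    ce <- conserved[[nm]]
    if (!any(ce$matrix_id == anchor_matrix_id & ce$segment == 1L)) {
      report$anchored <- FALSE
      report$anchor_matrix_id <- anchor_matrix_id
      attr(report, "anchor_missing_in") <- nm
      return(report)
    }
    ref <- attr(ce, "reference_species")
    anchors[[nm]] <- list(reference_species = ref,
                          u_anchor = proximal_hit_u(ce, anchor_matrix_id,
                                                    1L, ref))
  }
  annotate <- function(df, other_nm) {
    if (!nrow(df)) {
      df$anchored_pos <- numeric(0)
      df$anchored_pos_other <- numeric(0)
      return(df)
    }
    ce_a <- conserved$avian
    ce_b <- conserved[[other_nm]]
    ref_a <- attr(ce_a, "reference_species")
    ref_b <- attr(ce_b, "reference_species")
    df$anchored_pos <- vapply(seq_len(nrow(df)), function(i)
      anchors$avian$u_anchor -
        proximal_hit_u(ce_a, df$matrix_id[i], df$segment[i], ref_a),
      numeric(1L))
    df$anchored_pos_other <- vapply(seq_len(nrow(df)), function(i)
      anchors[[other_nm]]$u_anchor -
        proximal_hit_u(ce_b, df$matrix_id[i], df$segment_other[i], ref_b),
      numeric(1L))
    df
  }
  report$shared_with_NAT <- annotate(report$shared_with_NAT, "mammalian_nat")
  report$shared_with_DAT <- annotate(report$shared_with_DAT, "mammalian_dat")
  report$anchored <- TRUE
  report$anchor_matrix_id <- anchor_matrix_id
  report$anchors <- anchors
  report
}
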