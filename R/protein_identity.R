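.submat_cache <- new.env(parent = emptyenv())

get_sub_matrix <- function(matrix_name) {
  if (!matrix_name %in% c("BLOSUM62", "BLOSUM45"))
    stop("substitution matrix must be BLOSUM62 or BLOSUM45")
  if (is.null(.submat_cache[[matrix_name]])) {
    env <- new.env()
    utils::data(list = matrix_name, package = "Biostrings", envir = env)
    .submat_cache[[matrix_name]] <- get(matrix_name, envir = env)
  }
  .submat_cache[[matrix_name]]
}

protein_string <- function(x, arg = "sequence") {
  s <- if (is.list(x)) x$sequence else x
  if (!is.character(s) || length(s) != 1L || !nzchar(s))
    stop(arg, " must be a non-empty protein sequence")
  s <- toupper(s)
  bad <- validate_residues(s, "protein")
  if (length(bad))
    stop("illegal protein residue(s) in ", arg, ": ",
         paste(bad, collapse = ","))
  s
}

#' Optimal global protein alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh global alignment under an affine gap model: a gap
#' of length k costs `gap_open + k * gap_extend`. BLOSUM62 is the default
#' scoring matrix; BLOSUM45 is selectable for highly divergent sequences.
#' The dynamic programming engine is Biostrings' `pairwiseAlignment`
#' (deterministic among co-optimal alignments).
#'
#' @param a,b Protein sequences ([seq_record()] or strings); the 20
#'   standard residues plus X.
#' @param matrix `"BLOSUM62"` (default) or `"BLOSUM45"`.
#' @param gap_open Gap opening penalty (default 10).
#' @param gap_extend Per-residue gap extension penalty (default 0.5).
#' @return An object of class `alignment_result`: `aligned_a`, `aligned_b`
#'   (equal-length gapped strings; removing `-` restores the inputs),
#'   `score`, `matrix_name`, `gap_open`, `gap_extend`.
#' @export
global_align <- function(a, b, matrix = "BLOSUM62", gap_open = 10,
                         gap_extend = 0.5) {
  sa <- protein_string(a, "a")
  sb <- protein_string(b, "b")
  submat <- get_sub_matrix(matrix)
  # align in canonical order so that swapping the inputs yields the
  # mirrored alignment (identity/similarity are then symmetric even when
  # several alignments are co-optimal)
  swap <- sa > sb
  p1 <- if (swap) sb else sa
  p2 <- if (swap) sa else sb
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(p1), Biostrings::AAString(p2),
    substitutionMatrix = submat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  g1 <- unname(as.character(Biostrings::alignedPattern(pa)))
  g2 <- unname(as.character(Biostrings::alignedSubject(pa)))
  res <- structure(list(aligned_a = if (swap) g2 else g1,
                        aligned_b = if (swap) g1 else g2,
                        score = Biostrings::score(pa),
                        matrix_name = matrix, gap_open = gap_open,
                        gap_extend = gap_extend),
                   class = "alignment_result")
  stopifnot(nchar(res$aligned_a) == nchar(res$aligned_b))
  res
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> %d columns, score %.1f (%s, open %g / extend %g)\n",
              nchar(x$aligned_a), x$score, x$matrix_name, x$gap_open,
              x$gap_extend))
  invisible(x)
}

#' Gap-excluded identity and similarity percentages
#'
#' Identity/similarity in the SIAS style: gap columns are not taken into
#' account by default, i.e. the denominator counts only columns with a
#' residue in both sequences. A column is "similar" when its substitution
#' score is positive (identities included). Alternative denominators —
#' shorter ungapped sequence length, or full alignment length — are
#' selectable since published percentages do not always disambiguate.
#'
#' @param aln An [global_align()] result.
#' @param denominator_mode One of `"aligned_columns"` (default),
#'   `"shorter_sequence_length"`, `"alignment_length"`.
#' @param matrix Substitution matrix for the similarity call; defaults to
#'   the alignment's matrix.
#' @return An object of class `identity_stats`: `identity_pct`,
#'   `similarity_pct`, `aligned_columns`, `identical`, `similar`,
#'   `denominator`, `denominator_mode`.
#' @export
identity_similarity <- function(aln,
                                denominator_mode = c("aligned_columns",
                                                     "shorter_sequence_length",
                                                     "alignment_length"),
                                matrix = NULL) {
  stopifnot(inherits(aln, "alignment_result"))
  denominator_mode <- match.arg(denominator_mode)
  if (is.null(matrix)) matrix <- aln$matrix_name
  submat <- get_sub_matrix(matrix)
  ca <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1L]]
  both <- ca != "-" & cb != "-"
  aligned_columns <- sum(both)
  identical_n <- sum(both & ca == cb)
  similar_n <- 0L
  if (aligned_columns)
    similar_n <- sum(submat[cbind(ca[both], cb[both])] > 0)
  D <- switch(denominator_mode,
              aligned_columns = aligned_columns,
              shorter_sequence_length = min(sum(ca != "-"), sum(cb != "-")),
              alignment_length = length(ca))
  if (D == 0) stop("identity denominator is zero (no aligned columns)")
  structure(list(identity_pct = 100 * identical_n / D,
                 similarity_pct = 100 * similar_n / D,
                 aligned_columns = aligned_columns,
                 identical = identical_n, similar = similar_n,
                 denominator = D, denominator_mode = denominator_mode),
            class = "identity_stats")
}

#' @export
print.identity_stats <- function(x, ...) {
  cat(sprintf("<identity_stats> identity %.1f%%, similarity %.1f%% (D=%d, %s)\n",
              x$identity_pct, x$similarity_pct, x$denominator,
              x$denominator_mode))
  invisible(x)
}

#' Restrict a protein to a set of residue ranges
#'
#' Concatenates the listed 1-based inclusive residue ranges (e.g. a
#' TM1-TM12 transmembrane span) before alignment.
#'
#' @param record A protein [seq_record()] or string.
#' @param ranges Two-column matrix/data.frame of 1-based inclusive
#'   `start`,`end` residue ranges; `NULL` returns the input unchanged.
#' @return A protein string (or updated record if a record was given).
#' @export
mask_region <- function(record, ranges = NULL) {
  s <- protein_string(record, "record")
  if (is.null(ranges)) return(if (is.list(record)) record else s)
  ranges <- as.matrix(ranges)
  if (ncol(ranges) != 2L) stop("ranges must have two columns (start, end)")
  n <- nchar(s)
  if (any(ranges[, 1L] < 1 | ranges[, 2L] > n | ranges[, 1L] > ranges[, 2L]))
    stop("range outside sequence [1, ", n, "]")
  masked <- paste(substring(s, ranges[, 1L], ranges[, 2L]), collapse = "")
  if (is.list(record)) {
    record$sequence <- masked
    record
  } else masked
}

#' Pairwise identity/similarity table for a set of proteins
#'
#' Aligns every requested pair globally and tabulates gap-excluded
#' identity and similarity percentages; ready to write as TSV.
#'
#' @param records List of protein [seq_record()]s.
#' @param pairs Two-column matrix/data.frame of record ids to compare;
#'   `NULL` compares all unordered pairs.
#' @param mask Optional residue-range mask ([mask_region()]) applied to
#'   every sequence before alignment.
#' @inheritParams global_align
#' @inheritParams identity_similarity
#' @return `data.frame` with columns `id_a`, `id_b`, `identity_pct`,
#'   `similarity_pct`, `aligned_columns`, `score`.
#' @export
identity_table <- function(records, pairs = NULL, mask = NULL,
                           matrix = "BLOSUM62", gap_open = 10,
                           gap_extend = 0.5,
                           denominator_mode = "aligned_columns") {
  ids <- vapply(records, function(r) r$id, character(1L))
  names(records) <- ids
  if (is.null(pairs)) {
    if (length(ids) < 2L) stop("need at least two records")
    pairs <- t(utils::combn(ids, 2L))
  }
  pairs <- as.matrix(pairs)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    ra <- records[[pairs[i, 1L]]]
    rb <- records[[pairs[i, 2L]]]
    if (is.null(ra) || is.null(rb))
      stop("unknown record id in pairs row ", i)
    sa <- mask_region(ra$sequence, mask)
    sb <- mask_region(rb$sequence, mask)
    aln <- global_align(sa, sb, matrix = matrix, gap_open = gap_open,
                        gap_extend = gap_extend)
    st <- identity_similarity(aln, denominator_mode = denominator_mode)
    data.frame(id_a = pairs[i, 1L], id_b = pairs[i, 2L],
               identity_pct = st$identity_pct,
               similarity_pct = st$similarity_pct,
               aligned_columns = st$aligned_columns, score = aln$score,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
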