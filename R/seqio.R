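#' @importFrom stats setNames rbinom runif qbinom
#' @importFrom utils read.delim write.table head tail
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
PROTEIN_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                      "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")

#' Construct a sequence record
#'
#' The elementary sequence container used throughout the package: an id, an
#' optional species label, the residue string (stored uppercase) and an
#' alphabet tag. DNA records may contain only A, C, G, T, N; protein records
#' the 20 standard residues plus X.
#'
#' @param id Text identifier (non-empty).
#' @param sequence Residue string (non-empty; validated against `alphabet`).
#' @param alphabet `"dna"` or `"protein"`.
#' @param species Optional species label (default `""`).
#' @return An object of class `seq_record`: a list with elements `id`,
#'   `species`, `sequence`, `alphabet`.
#' @export
seq_record <- function(id, sequence, alphabet = c("dna", "protein"),
                       species = "") {
  alphabet <- match.arg(alphabet)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("'id' must be a non-empty string")
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a non-empty string (record '", id, "')")
  sequence <- toupper(sequence)
  bad <- validate_residues(sequence, alphabet)
  if (length(bad))
    stop("illegal ", alphabet, " residue(s) ", paste(bad, collapse = ","),
         " in record '", id, "'")
  structure(list(id = id, species = species, sequence = sequence,
                 alphabet = alphabet),
            class = "seq_record")
}

# returns the distinct illegal characters, character(0) if clean
validate_residues <- function(sequence, alphabet) {
  allowed <- if (alphabet == "dna") DNA_ALPHABET else PROTEIN_ALPHABET
  chars <- unique(strsplit(sequence, "", fixed = TRUE)[[1L]])
  setdiff(chars, allowed)
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s [%s]%s, %d residues\n", x$id, x$alphabet,
              if (nzchar(x$species)) paste0(" species=", x$species) else "",
              nchar(x$sequence)))
  invisible(x)
}

#' Read a FASTA file
#'
#' Strict FASTA reader: rejects (rather than coerces) empty files, duplicate
#' ids, records without sequence, and residues outside the declared alphabet,
#' reporting the offending line number. The species label is parsed from the
#' header token following the first `|` when `species_from = "pipe"`, or
#' supplied via a named `species_map`; it is never guessed from free text.
#'
#' @param path FASTA file.
#' @param alphabet `"dna"` or `"protein"`.
#' @param species_from `"pipe"` (token after the first `|` in the header) or
#'   `"none"`.
#' @param species_map Optional named character vector mapping record id to
#'   species; overrides `species_from`.
#' @return List of [seq_record()] in file order.
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein"),
                       species_from = c("pipe", "none"),
                       species_map = NULL) {
  alphabet <- match.arg(alphabet)
  species_from <- match.arg(species_from)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) stop("empty FASTA file: ", path)
  hdr <- grep("^>", lines)
  if (!length(hdr) || nonblank[1L] < hdr[1L])
    stop("malformed FASTA (line ", nonblank[1L], "): expected '>' header")
  records <- vector("list", length(hdr))
  ids <- character(length(hdr))
  bounds <- c(hdr, length(lines) + 1L)
  for (i in seq_along(hdr)) {
    header <- sub("^>", "", lines[hdr[i]])
    id <- strsplit(trimws(header), "[ |]")[[1L]][1L]
    if (is.na(id) || !nzchar(id))
      stop("empty header id (line ", hdr[i], ")")
    if (id %in% ids[seq_len(i - 1L)])
      stop("duplicate id '", id, "' (line ", hdr[i], ")")
    ids[i] <- id
    body_lines <- seq(hdr[i] + 1L, bounds[i + 1L] - 1L)
    body_lines <- body_lines[body_lines <= length(lines)]
    if (bounds[i + 1L] <= hdr[i] + 1L)
      stop("record '", id, "' has no sequence (line ", hdr[i], ")")
    seq_parts <- toupper(trimws(lines[body_lines]))
    for (k in seq_along(seq_parts)) {
      bad <- validate_residues(seq_parts[k], alphabet)
      if (length(bad))
        stop("illegal ", alphabet, " residue(s) ",
             paste(bad, collapse = ","), " in record '", id,
             "' (line ", body_lines[k], ")")
    }
    sequence <- paste(seq_parts, collapse = "")
    if (!nzchar(sequence))
      stop("record '", id, "' has no sequence (line ", hdr[i], ")")
    species <- ""
    if (!is.null(species_map)) {
      if (id %in% names(species_map)) species <- unname(species_map[[id]])
    } else if (species_from == "pipe" && grepl("|", header, fixed = TRUE)) {
      species <- trimws(strsplit(header, "|", fixed = TRUE)[[1L]][2L])
      if (is.na(species)) species <- ""
    }
    records[[i]] <- seq_record(id, sequence, alphabet, species = species)
  }
  records
}

#' Write sequence records as FASTA
#'
#' Inverse of [read_fasta()]: `read_fasta(write_fasta(x, p), ...)` recovers
#' the records. A non-empty species label is written as `id|species`.
#'
#' @param records List of [seq_record()].
#' @param path Output file.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "seq_record")) records <- list(records)
  out <- character(0)
  for (rec in records) {
    stopifnot(inherits(rec, "seq_record"))
    hdr <- if (nzchar(rec$species)) paste0(rec$id, "|", rec$species) else rec$id
    body <- wrap_seq(rec$sequence, width)
    out <- c(out, paste0(">", hdr), body)
  }
  writeLines(out, path)
  invisible(path)
}

wrap_seq <- function(s, width) {
  n <- nchar(s)
  starts <- seq(1L, n, by = width)
  substring(s, starts, pmin(starts + width - 1L, n))
}

#' Read JASPAR-format position frequency matrices
#'
#' Parses JASPAR 2016-style text: a `>ID NAME` header followed by four count
#' rows in base order A, C, G, T, each optionally prefixed by the base letter
#' and bracketed (`A [ 4 0 12 ]`). Counts are preserved exactly; files may
#' hold several matrices.
#'
#' @param path Matrix file.
#' @return List of `pfm` objects (fields `matrix_id`, `name`, `counts`: a
#'   4 x L numeric matrix with rownames A,C,G,T) in file order.
#' @export
read_jaspar_pfm <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no '>' records in ", path)
  out <- vector("list", length(hdr))
  for (i in seq_along(hdr)) {
    header <- trimws(sub("^>", "", lines[hdr[i]]))
    toks <- strsplit(header, "[ \t]+")[[1L]]
    matrix_id <- toks[1L]
    name <- if (length(toks) >= 2L) paste(toks[-1L], collapse = " ") else ""
    row_idx <- hdr[i] + 1:4
    if (max(row_idx) > length(lines) ||
        (i < length(hdr) && max(row_idx) >= hdr[i + 1L]))
      stop("matrix '", matrix_id, "': expected 4 count rows (A,C,G,T)")
    counts <- vector("list", 4L)
    for (b in 1:4) {
      row <- lines[row_idx[b]]
      base_letter <- c("A", "C", "G", "T")[b]
      # strip optional leading base letter and brackets
      row <- sub(paste0("^\\s*", base_letter, "\\s*"), "", row,
                 ignore.case = TRUE)
      row <- gsub("\\[|\\]", " ", row)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(row), "\\s+")[[1L]]))
      if (!length(vals) || anyNA(vals))
        stop("matrix '", matrix_id, "': unparseable ", base_letter, " row")
      counts[[b]] <- vals
    }
    lens <- lengths(counts)
    if (length(unique(lens)) != 1L)
      stop("matrix '", matrix_id, "': rows of unequal length (",
           paste(lens, collapse = ","), ")")
    m <- do.call(rbind, counts)
    rownames(m) <- c("A", "C", "G", "T")
    out[[i]] <- pfm(matrix_id, name, m)
  }
  out
}

#' Construct a position frequency matrix
#'
#' @param matrix_id Matrix identifier (e.g. `"MA0004.1"`).
#' @param name Factor name (e.g. `"ARNT"`).
#' @param counts 4 x L non-negative numeric matrix, rows A, C, G, T; every
#'   column total must be positive.
#' @return A `pfm` object.
#' @export
pfm <- function(matrix_id, name, counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("counts must have 4 rows (A,C,G,T)")
  if (ncol(counts) < 1L) stop("matrix '", matrix_id, "': zero columns")
  if (any(counts < 0)) stop("matrix '", matrix_id, "': negative counts")
  if (any(colSums(counts) <= 0))
    stop("matrix '", matrix_id, "': column with zero total")
  rownames(counts) <- c("A", "C", "G", "T")
  structure(list(matrix_id = matrix_id, name = name, counts = counts),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("<pfm> %s %s (L=%d)\n", x$matrix_id, x$name, ncol(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Read a 12-column tabular alignment hit file
#'
#' The standard tab-separated local-alignment dialect: query id, subject id,
#' percent identity, alignment length, mismatches, gap opens, query
#' start/end (1-based inclusive), subject start/end (1-based inclusive;
#' start > end encodes a minus-strand hit), e-value, bit score. E-value and
#' bit score may be `"."` (missing); a missing e-value disables the e-value
#' filter for that row downstream. Subject coordinates are additionally
#' exposed 0-based half-open on the plus strand (`s_start0`, `s_end0`) with
#' an explicit `s_strand` column, the package-internal convention.
#'
#' @param path Hit file; an empty file yields a zero-row table.
#' @return A `data.frame` of class `hit_table`.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) return(empty_hit_table())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols != 12L)) {
    bad <- which(ncols != 12L)[1L]
    stop("row ", bad, ": expected 12 tab-separated columns, got ", ncols[bad])
  }
  m <- do.call(rbind, parts)
  num <- function(j, what, allow_missing = FALSE) {
    v <- m[, j]
    if (allow_missing) v[v == "."] <- NA_character_
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out) & (if (allow_missing) !is.na(v) else TRUE))
    if (length(bad))
      stop("row ", bad[1L], ": non-numeric ", what, " '", m[bad[1L], j], "'")
    out
  }
  df <- data.frame(
    query_id = m[, 1L], subject_id = m[, 2L],
    percent_identity = num(3L, "percent identity"),
    aln_length = num(4L, "alignment length"),
    mismatches = num(5L, "mismatch count"),
    gap_opens = num(6L, "gap-open count"),
    q_start = num(7L, "query start"), q_end = num(8L, "query end"),
    s_start = num(9L, "subject start"), s_end = num(10L, "subject end"),
    e_value = num(11L, "e-value", allow_missing = TRUE),
    bit_score = num(12L, "bit score", allow_missing = TRUE),
    stringsAsFactors = FALSE)
  if (any(df$percent_identity < 0 | df$percent_identity > 100)) {
    bad <- which(df$percent_identity < 0 | df$percent_identity > 100)[1L]
    stop("row ", bad, ": percent identity outside [0,100]")
  }
  if (any(df$q_start > df$q_end)) {
    bad <- which(df$q_start > df$q_end)[1L]
    stop("row ", bad, ": query start > end (queries are unstranded)")
  }
  df$s_strand <- ifelse(df$s_start > df$s_end, "-", "+")
  df$s_start0 <- ifelse(df$s_strand == "+", df$s_start - 1, df$s_end - 1)
  df$s_end0 <- ifelse(df$s_strand == "+", df$s_end, df$s_start)
  class(df) <- c("hit_table", "data.frame")
  df
}

empty_hit_table <- function() {
  df <- data.frame(query_id = character(0), subject_id = character(0),
                   percent_identity = numeric(0), aln_length = numeric(0),
                   mismatches = numeric(0), gap_opens = numeric(0),
                   q_start = numeric(0), q_end = numeric(0),
                   s_start = numeric(0), s_end = numeric(0),
                   e_value = numeric(0), bit_score = numeric(0),
                   s_strand = character(0), s_start0 = numeric(0),
                   s_end0 = numeric(0), stringsAsFactors = FALSE)
  class(df) <- c("hit_table", "data.frame")
  df
}

#' Write a hit table in the 12-column tabular dialect
#'
#' @param hits A `hit_table` (see [read_hit_table()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  cols <- c("query_id", "subject_id", "percent_identity", "aln_length",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start",
            "s_end", "e_value", "bit_score")
  m <- hits[, cols, drop = FALSE]
  fmt <- vapply(seq_len(nrow(m)), function(i) {
    v <- unlist(lapply(m[i, ], function(x)
      if (is.na(x)) "." else format(x, scientific = FALSE, trim = TRUE,
                                    digits = 15)))
    paste(v, collapse = "\t")
  }, character(1L))
  writeLines(fmt, path)
  invisible(path)
}

#' Construct a gene interval
#'
#' Intervals are 0-based half-open on the plus strand with an explicit
#' strand, the convention used everywhere inside the package; 1-based
#' inclusive coordinates appear only at file-format boundaries.
#'
#' @param species Species label.
#' @param chrom Chromosome/scaffold name.
#' @param start,end 0-based half-open span; requires `0 <= start < end`.
#' @param strand `"+"` or `"-"`.
#' @param gene_name Gene symbol.
#' @return A one-row `data.frame` of class `gene_interval`.
#' @export
gene_interval <- function(species, chrom, start, end, strand = "+",
                          gene_name = "") {
  if (!(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (start < 0 || start >= end)
    stop("need 0 <= start < end (got [", start, ",", end, "))")
  df <- data.frame(species = species, chrom = chrom, start = start,
                   end = end, strand = strand, gene_name = gene_name,
                   stringsAsFactors = FALSE)
  class(df) <- c("gene_interval", "data.frame")
  df
}

#' Read BED-style gene annotations
#'
#' Six-column BED (chrom, start, end, name, score, strand), 0-based
#' half-open as in the BED standard — which is also the package-internal
#' convention, so no shifting occurs.
#'
#' @param path BED file.
#' @param species Species label attached to every interval.
#' @return A `gene_interval` data frame (possibly zero rows).
#' @export
read_bed <- function(path, species = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines)) {
    df <- gene_interval(species, "x", 0, 1)[0, ]
    return(df)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 6L)) {
    bad <- which(lengths(parts) < 6L)[1L]
    stop("row ", bad, ": expected >= 6 BED columns")
  }
  m <- do.call(rbind, lapply(parts, `[`, 1:6))
  start <- suppressWarnings(as.numeric(m[, 2L]))
  end <- suppressWarnings(as.numeric(m[, 3L]))
  if (anyNA(start) || anyNA(end)) stop("non-numeric BED coordinates")
  if (any(!m[, 6L] %in% c("+", "-"))) stop("BED strand must be '+' or '-'")
  if (any(start < 0 | start >= end)) {
    bad <- which(start < 0 | start >= end)[1L]
    stop("row ", bad, ": need 0 <= start < end")
  }
  df <- data.frame(species = species, chrom = m[, 1L], start = start,
                   end = end, strand = m[, 6L], gene_name = m[, 4L],
                   stringsAsFactors = FALSE)
  class(df) <- c("gene_interval", "data.frame")
  df
}

#' Write gene intervals as six-column BED
#'
#' @param intervals A `gene_interval` data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", intervals$chrom,
                   as.integer(intervals$start), as.integer(intervals$end),
                   intervals$gene_name, intervals$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a rooted newick tree
#'
#' Thin wrapper over [ape::read.tree()] that insists on a rooted tree, the
#' precondition for Dollo loss inference.
#'
#' @param path Newick file.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("unparseable newick in ", path)
  if (!ape::is.rooted(tree)) stop("tree in ", path, " is not rooted")
  tree
}

# reverse complement of an uppercase ACGTN string
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
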