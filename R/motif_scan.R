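#' Scanning parameters
#'
#' Controls PWM construction and scanning. The relative-score cutoff
#' defaults to 0.90 with a strict `>` comparison, i.e. a hit must exceed
#' 90% of the matrix's attainable score range. The pseudocount (0.8,
#' distributed by background frequency) and the uniform 0.25 background
#' follow the convention of the JASPAR-associated scanner family; both are
#' exposed here rather than hard-wired.
#'
#' @param threshold Relative profile score cutoff, in (0, 1].
#' @param strands `"both"` or `"forward"`.
#' @param pseudocount Non-negative pseudocount mass added per column.
#' @param background Length-4 base probabilities (A,C,G,T); must sum to 1.
#' @param comparison `"gt"` (strict, default) or `"ge"`.
#' @return An object of class `scan_params`.
#' @export
scan_params <- function(threshold = 0.90, strands = c("both", "forward"),
                        pseudocount = 0.8,
                        background = c(0.25, 0.25, 0.25, 0.25),
                        comparison = c("gt", "ge")) {
  strands <- match.arg(strands)
  comparison <- match.arg(comparison)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-9)
    stop("background must be 4 positive probabilities summing to 1")
  structure(list(threshold = threshold, strands = strands,
                 pseudocount = pseudocount,
                 background = setNames(as.numeric(background),
                                       c("A", "C", "G", "T")),
                 comparison = comparison),
            class = "scan_params")
}

#' @export
print.scan_params <- function(x, ...) {
  cat(sprintf(paste0("<scan_params> threshold %s %.3f, strands=%s, ",
                     "pseudocount=%.3g, background=%s\n"),
              if (x$comparison == "gt") ">" else ">=", x$threshold,
              x$strands, x$pseudocount,
              paste(format(x$background), collapse = "/")))
  invisible(x)
}

#' Build a log-odds position weight matrix from count data
#'
#' Converts a position frequency matrix to log2-odds weights against the
#' background:
#' `w[b, j] = log2( (counts[b, j] + p * bg[b]) / (N_j + p) / bg[b] )`
#' with `N_j` the column-`j` count total and `p` the pseudocount. Per-column
#' minima/maxima and their sums (the attainable score range) are cached for
#' relative-score normalisation.
#'
#' @param pfm A [pfm()] object.
#' @param params A [scan_params()] object (supplies pseudocount and
#'   background).
#' @return An object of class `pwm` with fields `matrix_id`, `name`,
#'   `weights` (4 x L, bits), `background`, `pseudocount`, `col_min`,
#'   `col_max`, `s_min`, `s_max`.
#' @export
build_pwm <- function(pfm, params = scan_params()) {
  stopifnot(inherits(pfm, "pfm"), inherits(params, "scan_params"))
  p <- params$pseudocount
  bg <- params$background
  counts <- pfm$counts
  n_j <- colSums(counts)
  freq <- sweep(counts + p * bg, 2L, n_j + p, "/")
  w <- log2(freq / bg)
  if (any(!is.finite(w)))
    stop("matrix '", pfm$matrix_id,
         "': non-finite weights; use a positive pseudocount for 0 counts")
  col_min <- apply(w, 2L, min)
  col_max <- apply(w, 2L, max)
  structure(list(matrix_id = pfm$matrix_id, name = pfm$name, weights = w,
                 background = bg, pseudocount = p,
                 col_min = col_min, col_max = col_max,
                 s_min = sum(col_min), s_max = sum(col_max)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s %s (L=%d), score range [%.3f, %.3f] bits\n",
              x$matrix_id, x$name, ncol(x$weights), x$s_min, x$s_max))
  invisible(x)
}

# integer-encode ACGT (N and anything else -> NA)
encode_dna <- function(s) {
  match(strsplit(s, "", fixed = TRUE)[[1L]], c("A", "C", "G", "T"))
}

#' Relative profile score of a single window
#'
#' Maps the raw log-odds sum of an L-length window onto the unit interval:
#' `(score - s_min) / (s_max - s_min)`, where `s_min`/`s_max` are the
#' minimal/maximal attainable sums. A degenerate matrix (`s_max == s_min`)
#' scores 1. A window containing characters outside ACGT is unscorable and
#' returns `NA` (distinct from any low score).
#'
#' @param pwm A [build_pwm()] object.
#' @param window DNA string of exactly the matrix length.
#' @return A number in `[0, 1]`, or `NA_real_` for an unscorable window.
#' @export
relative_score <- function(pwm, window) {
  stopifnot(inherits(pwm, "pwm"))
  L <- ncol(pwm$weights)
  if (nchar(window) != L)
    stop("window length ", nchar(window), " != matrix length ", L)
  idx <- encode_dna(toupper(window))
  if (anyNA(idx)) return(NA_real_)
  raw <- sum(pwm$weights[cbind(idx, seq_len(L))])
  if (pwm$s_max == pwm$s_min) return(1.0)
  (raw - pwm$s_min) / (pwm$s_max - pwm$s_min)
}

# score every window of an encoded sequence; NA where a window covers an N
window_scores <- function(weights, code) {
  L <- ncol(weights)
  n <- length(code)
  nwin <- n - L + 1L
  if (nwin < 1L) return(numeric(0))
  sc <- numeric(nwin)
  for (j in seq_len(L)) sc <- sc + weights[code[j:(j + nwin - 1L)], j]
  sc
}

#' Scan a DNA sequence for PWM hits above the relative-score threshold
#'
#' Slides the matrix over every window of the sequence (both strands by
#' default); windows whose relative profile score exceeds the threshold are
#' reported. Minus-strand windows are scored on the reverse complement but
#' reported in plus-strand coordinates (0-based half-open). Windows
#' containing N are skipped. A sequence shorter than the matrix yields an
#' empty hit set.
#'
#' @param pwm A [build_pwm()] object.
#' @param seq A dna [seq_record()] (or promoter).
#' @param params A [scan_params()] object.
#' @return A `data.frame` of class `motif_hits` with columns `matrix_id`,
#'   `name`, `promoter_id`, `species`, `start`, `end`, `strand`, `score`
#'   (bits), `relative_score`; sorted by `start` then strand (`+` first).
#' @export
scan_sequence <- function(pwm, seq, params = scan_params()) {
  stopifnot(inherits(pwm, "pwm"), inherits(params, "scan_params"))
  sequence <- if (is.list(seq)) seq$sequence else seq
  seq_id <- if (is.list(seq) && !is.null(seq$promoter_id)) seq$promoter_id
            else if (is.list(seq)) seq$id else ""
  species <- if (is.list(seq) && !is.null(seq$species)) seq$species else ""
  if (is.list(seq) && !is.null(seq$alphabet) && seq$alphabet != "dna")
    stop("scan_sequence requires a dna record")
  L <- ncol(pwm$weights)
  n <- nchar(sequence)
  hits <- empty_motif_hits()
  if (n >= L) {
    denom <- pwm$s_max - pwm$s_min
    rel <- function(raw) if (denom > 0) (raw - pwm$s_min) / denom else
      rep(1.0, length(raw))
    keep <- function(r) if (params$comparison == "gt")
      r > params$threshold else r >= params$threshold
    code <- encode_dna(sequence)
    fwd_raw <- window_scores(pwm$weights, code)
    fwd_rel <- rel(fwd_raw)
    fi <- which(!is.na(fwd_rel) & keep(fwd_rel))
    rows <- list()
    if (length(fi))
      rows[[1L]] <- data.frame(start = fi - 1L, strand = "+",
                               score = fwd_raw[fi],
                               relative_score = fwd_rel[fi])
    if (params$strands == "both") {
      rc_code <- encode_dna(revcomp(sequence))
      rev_raw <- window_scores(pwm$weights, rc_code)
      rev_rel <- rel(rev_raw)
      ri <- which(!is.na(rev_rel) & keep(rev_rel))
      if (length(ri))
        # window starting at i (0-based) on the reverse complement occupies
        # plus-strand span [n - i - L, n - i)
        rows[[length(rows) + 1L]] <-
          data.frame(start = n - (ri - 1L) - L, strand = "-",
                     score = rev_raw[ri], relative_score = rev_rel[ri])
    }
    if (length(rows)) {
      df <- do.call(rbind, rows)
      df <- data.frame(matrix_id = pwm$matrix_id, name = pwm$name,
                       promoter_id = seq_id, species = species,
                       start = df$start, end = df$start + L,
                       strand = df$strand, score = df$score,
                       relative_score = df$relative_score,
                       stringsAsFactors = FALSE)
      df <- df[order(df$start, df$strand), , drop = FALSE]
      rownames(df) <- NULL
      class(df) <- c("motif_hits", "data.frame")
      hits <- df
    }
  }
  hits
}

empty_motif_hits <- function() {
  df <- data.frame(matrix_id = character(0), name = character(0),
                   promoter_id = character(0), species = character(0),
                   start = integer(0), end = integer(0),
                   strand = character(0), score = numeric(0),
                   relative_score = numeric(0), stringsAsFactors = FALSE)
  class(df) <- c("motif_hits", "data.frame")
  df
}

#' Scan a set of promoters with a set of matrices
#'
#' Convenience loop over [scan_sequence()]; one combined hit table out.
#'
#' @param pwms List of [build_pwm()] objects (or [pfm()] objects, which are
#'   converted using `params`).
#' @param seqs List of dna [seq_record()]s / promoters.
#' @param params A [scan_params()] object.
#' @return A `motif_hits` data frame.
#' @export
scan_promoters <- function(pwms, seqs, params = scan_params()) {
  if (!length(pwms)) return(empty_motif_hits())
  pwms <- lapply(pwms, function(m)
    if (inherits(m, "pfm")) build_pwm(m, params) else m)
  out <- lapply(pwms, function(m)
    lapply(seqs, function(s) scan_sequence(m, s, params)))
  df <- do.call(rbind, unlist(out, recursive = FALSE))
  if (is.null(df)) return(empty_motif_hits())
  rownames(df) <- NULL
  df
}

#' Write motif hits as BED-with-score and companion TSV
#'
#' @param hits A `motif_hits` data frame.
#' @param bed_path,tsv_path Output files (either may be `NULL` to skip).
#' @return Invisibly, a character vector of the files written.
#' @export
write_motif_hits <- function(hits, bed_path = NULL, tsv_path = NULL) {
  written <- character(0)
  if (!is.null(bed_path)) {
    lines <- sprintf("%s\t%d\t%d\t%s\t%.4f\t%s", hits$promoter_id,
                     as.integer(hits$start), as.integer(hits$end),
                     hits$matrix_id, hits$relative_score, hits$strand)
    writeLines(lines, bed_path)
    written <- c(written, bed_path)
  }
  if (!is.null(tsv_path)) {
    cols <- c("matrix_id", "name", "promoter_id", "species", "start",
              "end", "strand", "score", "relative_score")
    write.table(hits[, cols], tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    written <- c(written, tsv_path)
  }
  invisible(written)
}
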