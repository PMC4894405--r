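known_config_keys <- list(
  promoter = c("matrices", "lineages", "scan", "L", "segment_tolerance",
               "anchor_matrix_id", "out_dir"),
  loss = c("species_data", "tree", "panel", "target", "params", "out_dir"))

pipe_log <- function(...) message("[orthotrace] ", sprintf(...))

check_keys <- function(config, stage) {
  unknown <- setdiff(names(config), known_config_keys[[stage]])
  if (length(unknown))
    stop("unknown config key(s) for ", stage, " pipeline: ",
         paste(unknown, collapse = ", "))
}

as_scan_params <- function(x) {
  if (inherits(x, "scan_params")) x
  else if (is.null(x)) scan_params()
  else do.call(scan_params, x)
}

as_call_params <- function(x) {
  if (inherits(x, "call_params")) x
  else if (is.null(x)) call_params()
  else do.call(call_params, x)
}

load_matrices <- function(m) {
  if (is.character(m)) read_jaspar_pfm(m)
  else if (is.list(m)) m
  else stop("'matrices' must be a JASPAR file path or a list of pfm objects")
}

load_lineage <- function(name, spec) {
  proms <- spec$promoters
  if (is.character(proms)) {
    sidecar <- read.delim(spec$sidecar, stringsAsFactors = FALSE)
    recs <- read_fasta(proms, alphabet = "dna",
                       species_map = setNames(sidecar$species, sidecar$id))
    proms <- lapply(recs, function(r) {
      i <- match(r$id, sidecar$id)
      structure(list(promoter_id = r$id, species = sidecar$species[i],
                     gene_label = sidecar$gene_label[i],
                     sequence = r$sequence, alphabet = "dna",
                     W = nchar(r$sequence)),
                class = c("promoter", "seq_record"))
    })
  }
  lineage_set(name, proms, spec$reference_species)
}

#' Run the comparative promoter analysis end to end
#'
#' scan -> segment -> lineage-conserve -> share -> anchor. Promoters of
#' three lineages (avian NAT, mammalian NAT, mammalian DAT) are scanned
#' with every matrix under the relative-score threshold; per lineage, only
#' (matrix, segment) pairs hit in every species survive; the avian set is
#' intersected with each mammalian set; shared elements are mapped
#' relative to the proximal anchor motif in each lineage's reference
#' species. Every tunable is echoed into the report.
#'
#' @param config A list (or YAML file path, see
#'   [read_pipeline_config()]) with keys: `lineages` (named list
#'   `avian`, `mammalian_nat`, `mammalian_dat`, each with `promoters`
#'   — a list of `promoter` objects, or a FASTA path plus `sidecar`
#'   table — and `reference_species`), `matrices` (list of [pfm()] or a
#'   JASPAR file), `scan` ([scan_params()] or argument list), `L`
#'   (segment length, default 500), `segment_tolerance` (default 0),
#'   `anchor_matrix_id`, and optional `out_dir` for TSV/JSON reports.
#' @return Invisibly, a list with `hits` (per lineage), `conserved` (per
#'   lineage), `report` (anchored [shared_elements()] report), `params`
#'   (full echo) and `files` written.
#' @export
run_promoter_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  check_keys(config, "promoter")
  need <- c("avian", "mammalian_nat", "mammalian_dat")
  if (!all(need %in% names(config$lineages)))
    stop("config$lineages must define: ", paste(need, collapse = ", "))
  params <- as_scan_params(config$scan)
  L <- if (is.null(config$L)) 500L else as.integer(config$L)
  tol <- if (is.null(config$segment_tolerance)) 0L else
    as.integer(config$segment_tolerance)
  matrices <- load_matrices(config$matrices)
  if (!length(matrices)) {
    warning("empty matrix set: report will be empty")
  }
  pwms <- lapply(matrices, build_pwm, params = params)

  lineages <- lapply(need, function(nm)
    tryCatch(load_lineage(nm, config$lineages[[nm]]),
             error = function(e) stop("stage lineage-load (", nm, "): ",
                                      conditionMessage(e))))
  names(lineages) <- need

  hits <- lapply(need, function(nm) {
    h <- tryCatch(scan_promoters(pwms, lineages[[nm]]$promoters, params),
                  error = function(e) stop("stage scan (", nm, "): ",
                                           conditionMessage(e)))
    pipe_log("scan %s: %d hits over %d promoters", nm, nrow(h),
             length(lineages[[nm]]$promoters))
    h
  })
  names(hits) <- need

  conserved <- lapply(need, function(nm) {
    ce <- tryCatch(lineage_conserved_elements(lineages[[nm]], hits[[nm]],
                                              L = L),
                   error = function(e) stop("stage conserve (", nm, "): ",
                                            conditionMessage(e)))
    pipe_log("conserve %s: %d lineage-conserved elements", nm, nrow(ce))
    ce
  })
  names(conserved) <- need

  report <- shared_elements(conserved$avian, conserved$mammalian_nat,
                            conserved$mammalian_dat,
                            segment_tolerance = tol)
  pipe_log("share: %d with mammalian NAT, %d with mammalian DAT",
           nrow(report$shared_with_NAT), nrow(report$shared_with_DAT))
  if (!is.null(config$anchor_matrix_id)) {
    report <- anchor_positions(report, conserved, config$anchor_matrix_id)
    pipe_log("anchor (%s): %s", config$anchor_matrix_id,
             if (report$anchored) "anchored" else "anchor not conserved")
  }

  echo <- list(threshold = params$threshold, comparison = params$comparison,
               strands = params$strands, pseudocount = params$pseudocount,
               background = as.list(params$background), L = L,
               segment_tolerance = tol,
               anchor_matrix_id = config$anchor_matrix_id,
               W = lineages$avian$W,
               lineage_species = lapply(lineages, `[[`, "species"),
               reference_species = lapply(lineages, `[[`,
                                          "reference_species"),
               n_matrices = length(matrices))
  files <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- write_promoter_reports(config$out_dir, conserved, report, echo)
  }
  invisible(list(hits = hits, conserved = conserved, report = report,
                 params = echo, files = files))
}

write_promoter_reports <- function(out_dir, conserved, report, echo) {
  ce_all <- do.call(rbind, lapply(names(conserved), function(nm) {
    df <- as.data.frame(conserved[[nm]])
    if (nrow(df)) df$lineage <- nm else df$lineage <- character(0)
    df
  }))
  f1 <- file.path(out_dir, "conserved_elements.tsv")
  write.table(ce_all, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  sh <- rbind(
    cbind(shared_with = "mammalian_NAT", report$shared_with_NAT),
    cbind(shared_with = "mammalian_DAT", report$shared_with_DAT))
  f2 <- file.path(out_dir, "shared_elements.tsv")
  write.table(sh, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  f3 <- file.path(out_dir, "promoter_report.json")
  jsonlite::write_json(
    list(parameters = echo,
         anchored = report$anchored,
         anchor_matrix_id = report$anchor_matrix_id,
         anchors = report$anchors,
         shared_with_NAT = report$shared_with_NAT,
         shared_with_DAT = report$shared_with_DAT,
         n_conserved = lapply(conserved, nrow)),
    f3, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  c(f1, f2, f3)
}

#' Run the synteny-based gene-loss analysis end to end
#'
#' Per species: flank location -> syntenic interval -> assembly-gap census
#' -> hit chaining, paralog disambiguation and presence call; then Dollo
#' loss inference over the species tree. A species present in the tree but
#' lacking data (or whose flanks cannot be located) is marked
#' indeterminate and excluded from the Dollo step; the pipeline continues.
#'
#' @param config A list (or YAML path) with keys: `species_data` (named
#'   per-species list: `hits` — `hit_table` or path, `genome` —
#'   [seq_record()] or FASTA path, `flanks` — [gene_interval()] rows or
#'   BED path), `tree` (`phylo` or newick path), `panel` (named protein
#'   records or FASTA path), `target` (panel name under test), `params`
#'   ([call_params()] or argument list), optional `out_dir`.
#' @return Invisibly, a list with `calls` (per-species
#'   [call_presence()]), `presence` (species x verdict data frame),
#'   `dollo` ([dollo_losses()] result, `NULL` if no callable species),
#'   `excluded` (species left out of Dollo), `params`, `files`.
#' @export
run_loss_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  check_keys(config, "loss")
  params <- as_call_params(config$params)
  tree <- config$tree
  if (is.character(tree)) tree <- read_newick(tree)
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  panel <- config$panel
  if (is.character(panel)) {
    recs <- read_fasta(panel, alphabet = "protein")
    panel <- setNames(recs, vapply(recs, `[[`, character(1L), "id"))
  }
  target <- config$target
  if (is.null(target) || !target %in% names(panel))
    stop("config$target must name a panel member")
  qlen <- nchar(panel[[target]]$sequence)

  calls <- list()
  for (sp in tree$tip.label) {
    sd <- config$species_data[[sp]]
    if (is.null(sd)) {
      calls[[sp]] <- structure(
        list(species = sp, gene = target, verdict = "indeterminate",
             reason = "no data for species",
             evidence = list(chains = NULL, gap_report = NULL,
                             params = unclass(params))),
        class = "presence_call")
      pipe_log("call %s: indeterminate (no data)", sp)
      next
    }
    hits <- if (is.character(sd$hits)) read_hit_table(sd$hits) else sd$hits
    genome <- if (is.character(sd$genome))
      read_fasta(sd$genome, alphabet = "dna")[[1L]] else sd$genome
    flanks <- if (is.character(sd$flanks)) read_bed(sd$flanks, species = sp)
      else sd$flanks
    interval <- NULL
    gap_report <- NULL
    if (!is.null(flanks) && nrow(flanks) >= 2L) {
      interval <- tryCatch(
        syntenic_interval(flanks[1L, , drop = FALSE],
                          flanks[2L, , drop = FALSE]),
        error = function(e) {
          pipe_log("call %s: %s", sp, conditionMessage(e))
          NULL
        })
      if (!is.null(interval) && !is.null(genome) &&
          interval$chrom == genome$id)
        gap_report <- assess_assembly(substr(genome$sequence,
                                             interval$start + 1L,
                                             interval$end))
    }
    calls[[sp]] <- call_presence(hits, qlen, interval, gap_report, panel,
                                 target, genome = genome, params = params,
                                 species = sp)
    pipe_log("call %s: %s", sp, calls[[sp]]$verdict)
  }

  presence <- data.frame(
    species = names(calls),
    verdict = vapply(calls, `[[`, character(1L), "verdict"),
    reason = vapply(calls, `[[`, character(1L), "reason"),
    stringsAsFactors = FALSE, row.names = NULL)
  callable <- presence$species[presence$verdict != "indeterminate"]
  excluded <- setdiff(tree$tip.label, callable)
  dollo <- NULL
  if (length(callable) >= 2L) {
    sub <- if (length(excluded)) ape::drop.tip(tree, excluded) else tree
    states <- ifelse(presence$verdict[match(sub$tip.label,
                                            presence$species)] ==
                       "absent", "absent", "present")
    names(states) <- sub$tip.label
    dollo <- dollo_losses(sub, states)
    pipe_log("dollo: %d loss(es)%s", dollo$n_losses,
             if (length(excluded))
               paste0(" (excluded: ", paste(excluded, collapse = ", "), ")")
             else "")
  }

  echo <- c(unclass(params), list(target = target,
                                  panel = names(panel),
                                  n_species = length(tree$tip.label),
                                  excluded_from_dollo = excluded))
  files <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    f1 <- file.path(config$out_dir, "presence_matrix.tsv")
    write.table(presence, f1, sep = "\t", quote = FALSE, row.names = FALSE)
    f2 <- file.path(config$out_dir, "loss_report.json")
    jsonlite::write_json(
      list(parameters = echo, presence = presence,
           n_losses = if (is.null(dollo)) NA else dollo$n_losses,
           loss_clades = if (is.null(dollo)) list() else
             as.list(dollo$losses$clade),
           never_present = if (is.null(dollo)) NA else dollo$never_present,
           evidence = lapply(calls, function(cl)
             list(verdict = cl$verdict, reason = cl$reason,
                  chains = cl$evidence$chains))),
      f2, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(f1, f2)
  }
  invisible(list(calls = calls, presence = presence, dollo = dollo,
                 excluded = excluded, params = echo, files = files))
}

#' Read a pipeline configuration from YAML
#'
#' File-based front end for the two pipelines; values reference input
#' files (FASTA/BED/JASPAR/newick/hit tables) by path. Keys are validated
#' by the pipeline entry points; unknown keys are rejected.
#'
#' @param path YAML file.
#' @return A named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}
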