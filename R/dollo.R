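#' Dollo-parsimony loss inference on a presence/absence character
#'
#' Under Dollo parsimony a character (here: a gene) is gained exactly once
#' and may be lost any number of times. The single gain is placed at the
#' most recent common ancestor of the tips where the gene is present, so
#' an absent outgroup is "never gained" rather than "lost". Within that
#' ancestor's subtree the minimal loss set is the set of maximal clades in
#' which every tip lacks the gene; one loss is charged to the stem branch
#' of each such clade. This reconstruction is minimal by construction and
#' deterministic.
#'
#' @param tree A rooted `phylo` tree (see [read_newick()]).
#' @param states Named character (`"present"`/`"absent"`) or logical
#'   (`TRUE` = present) vector covering every tip label.
#' @return An object of class `dollo_result`: `n_losses`, `losses` (data
#'   frame with the crown node of each lost clade and the tip labels it
#'   covers), `gain_node` (`NA` when no tip is present),
#'   `never_present` flag, and the `states` used.
#' @export
dollo_losses <- function(tree, states) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  ntip <- length(tree$tip.label)
  if (is.logical(states))
    states <- ifelse(states, "present", "absent")
  if (is.null(names(states))) {
    if (length(states) != ntip)
      stop("unnamed states must match the number of tips")
    names(states) <- tree$tip.label
  }
  missing_tips <- setdiff(tree$tip.label, names(states))
  if (length(missing_tips))
    stop("no state for tip(s): ", paste(missing_tips, collapse = ", "))
  bad <- setdiff(unique(states[tree$tip.label]), c("present", "absent"))
  if (length(bad))
    stop("states must be 'present'/'absent' (got ",
         paste(bad, collapse = ","), ")")
  present <- states[tree$tip.label] == "present"

  if (!any(present))
    return(structure(list(n_losses = 0L,
                          losses = data.frame(node = integer(0),
                                              clade = character(0),
                                              stringsAsFactors = FALSE),
                          gain_node = NA_integer_, never_present = TRUE,
                          states = states),
                     class = "dollo_result"))

  present_tips <- tree$tip.label[present]
  gain_node <- if (length(present_tips) == 1L)
    match(present_tips, tree$tip.label)
  else ape::getMRCA(tree, present_tips)

  nnode <- ntip + tree$Nnode
  # all_absent[v]: every tip below v (v itself if a tip) is absent;
  # postorder guarantees children are finalised before their parent
  all_absent <- logical(nnode)
  all_absent[seq_len(ntip)] <- !present
  po <- ape::reorder.phylo(tree, "postorder")
  for (parent in unique(po$edge[, 1L])) {
    children <- po$edge[po$edge[, 1L] == parent, 2L]
    all_absent[parent] <- all(all_absent[children])
  }

  # nodes inside the gain subtree
  in_subtree <- logical(nnode)
  in_subtree[gain_node] <- TRUE
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(pre$edge)))
    if (in_subtree[pre$edge[i, 1L]]) in_subtree[pre$edge[i, 2L]] <- TRUE

  parent_of <- integer(nnode)
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
  loss_nodes <- which(in_subtree & all_absent &
                        seq_len(nnode) != gain_node &
                        !all_absent[pmax(parent_of, 1L)])
  # the parent of any node inside the subtree is inside it too, and the
  # gain node itself is never all-absent, so parent_of is always valid here
  clade_tips <- vapply(loss_nodes, function(v) {
    tips <- if (v <= ntip) tree$tip.label[v]
            else ape::extract.clade(tree, v)$tip.label
    paste(tips, collapse = ",")
  }, character(1L))
  losses <- data.frame(node = loss_nodes, clade = clade_tips,
                       stringsAsFactors = FALSE)
  losses <- losses[order(losses$node), , drop = FALSE]
  rownames(losses) <- NULL
  structure(list(n_losses = nrow(losses), losses = losses,
                 gain_node = gain_node, never_present = FALSE,
                 states = states),
            class = "dollo_result")
}

#' @export
print.dollo_result <- function(x, ...) {
  if (x$never_present) {
    cat("<dollo_result> character never present; 0 losses\n")
  } else {
    cat(sprintf("<dollo_result> gain at node %d, %d loss(es)\n",
                x$gain_node, x$n_losses))
    if (x$n_losses)
      cat(paste0("  loss on stem of {", x$losses$clade, "}\n"), sep = "")
  }
  invisible(x)
}
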