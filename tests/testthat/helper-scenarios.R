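# End-to-end planted scenarios shared by the pipeline tests and the
# acceptance suite.

# Three-lineage promoter scenario: an ARNT-like proximal anchor everywhere,
# NAT-shared elements planted in avian + mammalian NAT, and the
# avian-NAT/mammalian-DAT-only elements (NFATC2/MZF1/ZNF354C/FOXC1-like).
promoter_scenario <- function(seed, out_dir = NULL) {
  mats <- scenario_matrices()
  avian_sp <- c("zebra_finch", "budgerigar", "chicken", "turkey")
  mam_nat_sp <- c("mouse", "rat", "opossum", "platypus")
  mam_dat_sp <- c("mouse", "rat", "opossum")
  # explicit offsets: plants can never collide and anchored positions are
  # exactly computable from the recorded truth (u = W - offset)
  anchor <- list(matrix_id = "MA0004.1", offset = 2380)   # u = 120, seg 1
  nat_shared <- list(list(matrix_id = "MA0099.1", offset = 2200))  # seg 1
  dat_shared <- list(list(matrix_id = "MA0152.1", offset = 1300),  # seg 3
                     list(matrix_id = "MA0056.1", offset = 1700),  # seg 2
                     list(matrix_id = "MA0130.1", offset = 700),   # seg 4
                     list(matrix_id = "MA0032.1", offset = 1100))  # seg 3
  av <- simulate_promoter_set(avian_sp, mats,
                              c(list(anchor), nat_shared, dat_shared),
                              gene_label = "NAT", seed = seed)
  mn <- simulate_promoter_set(mam_nat_sp, mats, c(list(anchor), nat_shared),
                              gene_label = "NAT", seed = seed + 1L)
  md <- simulate_promoter_set(mam_dat_sp, mats, c(list(anchor), dat_shared),
                              gene_label = "DAT", seed = seed + 2L)
  config <- list(
    matrices = mats,
    lineages = list(
      avian = list(promoters = av$promoters,
                   reference_species = "zebra_finch"),
      mammalian_nat = list(promoters = mn$promoters,
                           reference_species = "mouse"),
      mammalian_dat = list(promoters = md$promoters,
                           reference_species = "mouse")),
    scan = list(threshold = 0.90),
    anchor_matrix_id = "MA0004.1",
    out_dir = out_dir)
  planted_nat <- data.frame(matrix_id = "MA0099.1", segment = 1L)
  planted_dat <- data.frame(
    matrix_id = c("MA0032.1", "MA0056.1", "MA0130.1", "MA0152.1"),
    segment = c(3L, 2L, 4L, 3L))
  list(config = config, matrices = mats,
       truth = list(avian = av$truth, mammalian_nat = mn$truth,
                    mammalian_dat = md$truth),
       planted_nat = planted_nat, planted_dat = planted_dat,
       anchor_u = 120)
}

# expected anchored position of a planted element in a reference species,
# straight from the simulation truth (u = W - start; anchor at u = 120)
truth_anchored_pos <- function(truth, matrix_id, ref_species, anchor_u,
                               W = 2500) {
  m <- truth$motifs
  row <- m[m$matrix_id == matrix_id & m$species == ref_species, ]
  anchor_u - (W - row$start[1L])
}

# 8-taxon amniote locus scenario: the four sauropsid genomes planted absent
# (with a NAT decoy), the rest planted present
loss_scenario <- function(seed, out_dir = NULL, n_gap_species = character(0)) {
  tree <- ape::read.tree(text = paste0(
    "((((chicken,zebra_finch),(lizard,turtle)),(mouse,opossum)),",
    "(frog,fish));"))
  panel <- simulate_paralog_panel(seed = seed)
  absent_sp <- c("chicken", "zebra_finch", "lizard", "turtle")
  species_data <- list()
  for (i in seq_along(tree$tip.label)) {
    sp <- tree$tip.label[i]
    gaps <- if (sp %in% n_gap_species) 2400L else integer(0)
    loc <- simulate_locus(sp, panel,
                          gene_present = !(sp %in% absent_sp),
                          decoys = if (sp %in% absent_sp) "NAT"
                                   else character(0),
                          n_gap_runs = gaps, seed = seed + i)
    species_data[[sp]] <- list(hits = loc$hits, genome = loc$genome,
                               flanks = loc$flanks)
  }
  list(config = list(species_data = species_data, tree = tree,
                     panel = panel, target = "DAT", out_dir = out_dir),
       absent_species = absent_sp, tree = tree, panel = panel)
}
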