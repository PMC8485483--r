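#' Simulate a set of strain genomes with known phylogeny and recombination
#'
#' Generates `n_species * n_strains_per_species` genomes: a random ancestral
#' genome is mutated under the Jukes-Cantor model to species ancestors, each
#' species ancestor is evolved along a (Yule) strain tree rescaled to a
#' root-to-tip depth of `within_species_divergence / 2`, and Poisson-distributed
#' homologous-recombination imports overwrite contiguous tracts on tree
#' branches. The full ground truth (trees, per-strain mutations, recombination
#' tracts) is returned alongside the genomes.
#'
#' All coordinates in the truth tables are 0-based, half-open.
#'
#' @param params a [sim_params()] object.
#' @param strain_tree optional `phylo` (or newick string) used as the strain
#'   tree for every species in place of a random Yule tree; its tip labels are
#'   ignored and its depth is rescaled.
#' @return a list with `genomes` (named character vector of sequences) and
#'   `truth`, a `sim_truth` list carrying `species_tree`, `strain_trees`,
#'   `species` (genome -> species label), `mutations` (strain, position,
#'   ref_base, alt_base relative to the species ancestor) and `recomb_tracts`
#'   (strain, start, end, donor).
#' @export
simulate_strain_set <- function(params, strain_tree = NULL) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  L <- params$genome_length
  nsp <- params$n_species
  nst <- params$n_strains_per_species

  if (is.character(strain_tree)) strain_tree <- ape::read.tree(text = strain_tree)
  if (!is.null(strain_tree)) {
    if (!inherits(strain_tree, "phylo")) stop("'strain_tree' must be a phylo or newick string")
    if (ape::Ntip(strain_tree) != nst)
      stop("'strain_tree' must have n_strains_per_species tips")
  }

  ancestor <- random_seq_vec(L, params$gc_content)
  species_names <- sprintf("sp%d", seq_len(nsp))
  species_roots <- lapply(species_names, function(s)
    evolve_jc(ancestor, params$between_species_divergence / 2))
  names(species_roots) <- species_names

  species_tree <- if (nsp >= 2) {
    ape::read.tree(text = paste0("(", paste(sprintf("%s:%g", species_names,
      params$between_species_divergence / 2), collapse = ","), ");"))
  } else NULL

  genomes <- character(0)
  species_of <- character(0)
  strain_trees <- list()
  mutations <- list()
  tracts <- list()

  for (sp in species_names) {
    root_seq <- species_roots[[sp]]
    labels <- sprintf("%s_st%d", sp, seq_len(nst))
    if (nst == 1L) {
      leaf_seqs <- list(root_seq)
      names(leaf_seqs) <- labels
      tree <- NULL
    } else {
      tree <- if (is.null(strain_tree)) ape::rphylo(nst, birth = 1, death = 0) else strain_tree
      depth <- max(ape::node.depth.edgelength(tree))
      if (depth > 0 && params$within_species_divergence > 0) {
        tree$edge.length <- tree$edge.length / depth * (params$within_species_divergence / 2)
      } else {
        tree$edge.length <- tree$edge.length * 0
      }
      tree$tip.label <- labels
      ev <- evolve_tree(tree, root_seq, params)
      leaf_seqs <- ev$leaf_seqs
      for (tr in ev$tracts) {
        tracts[[length(tracts) + 1L]] <- tr
      }
    }
    strain_trees[[sp]] <- tree
    for (lab in names(leaf_seqs)) {
      v <- leaf_seqs[[lab]]
      diff <- which(v != root_seq)
      if (length(diff)) {
        mutations[[length(mutations) + 1L]] <- data.frame(
          strain = lab, position = diff - 1L,
          ref_base = root_seq[diff], alt_base = v[diff],
          stringsAsFactors = FALSE)
      }
      genomes[lab] <- vec_to_seq(v)
      species_of[lab] <- sp
    }
  }

  truth <- structure(list(
    species_tree = species_tree,
    strain_trees = strain_trees,
    species = species_of,
    mutations = if (length(mutations)) do.call(rbind, mutations) else
      data.frame(strain = character(0), position = integer(0),
                 ref_base = character(0), alt_base = character(0)),
    recomb_tracts = if (length(tracts)) do.call(rbind, tracts) else
      data.frame(strain = character(0), start = integer(0), end = integer(0),
                 donor = character(0)),
    params = params
  ), class = "sim_truth")
  list(genomes = genomes, truth = truth)
}

# evolve a root sequence down a strain tree with recombination imports;
# returns leaf sequences and per-leaf recombination tracts
evolve_tree <- function(tree, root_seq, params) {
  L <- length(root_seq)
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  root <- ntip + 1L
  edges <- ape::reorder.phylo(tree, "cladewise")$edge  # preorder edge walk
  elens <- ape::reorder.phylo(tree, "cladewise")$edge.length

  # clonal pass: substitutions only
  node_seq <- vector("list", ntip + nnode)
  node_seq[[root]] <- root_seq
  for (k in seq_len(nrow(edges))) {
    node_seq[[edges[k, 2L]]] <- evolve_jc(node_seq[[edges[k, 1L]]], elens[k])
  }

  tips_below <- descendant_tips(tree)
  leaf_seqs <- node_seq[seq_len(ntip)]
  names(leaf_seqs) <- tree$tip.label

  tracts <- list()
  if (params$recomb_rate_per_branch > 0) {
    for (k in seq_len(nrow(edges))) {
      child <- edges[k, 2L]
      n_imp <- rpois(1L, params$recomb_rate_per_branch)
      if (n_imp == 0L) next
      desc <- tips_below[[child]]
      for (i in seq_len(n_imp)) {
        start <- sample.int(L, 1L) - 1L
        len <- 1L + rgeom(1L, prob = 1 / params$mean_tract_length)
        end <- min(L, start + len)
        idx <- (start + 1L):end
        if (params$donor_model == "within") {
          others <- setdiff(seq_len(ntip), desc)
          if (length(others)) {
            don <- others[sample.int(length(others), 1L)]
            donor_tract <- node_seq[[don]][idx]
            donor_id <- tree$tip.label[don]
          } else {
            donor_tract <- node_seq[[child]][idx]
            donor_id <- "external"
          }
        } else {
          donor_tract <- node_seq[[child]][idx]
          donor_id <- "external"
        }
        donor_tract <- evolve_jc(donor_tract, params$tract_divergence)
        for (tp in desc) {
          leaf_seqs[[tree$tip.label[tp]]][idx] <- donor_tract
          tracts[[length(tracts) + 1L]] <- data.frame(
            strain = tree$tip.label[tp], start = start, end = end,
            donor = donor_id, stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(leaf_seqs = leaf_seqs, tracts = tracts)
}

# tips below each node (including the node itself for tips)
descendant_tips <- function(tree) {
  ntip <- ape::Ntip(tree)
  res <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) res[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(po))) {
    res[[po[k, 1L]]] <- c(res[[po[k, 1L]]], res[[po[k, 2L]]])
  }
  res
}

#' Overwrite a genomic tract with sequence copied from a donor genome
#'
#' Splices a homologous-recombination import into one genome of a strain set:
#' the recipient's `[start, end)` tract (0-based, half-open) is replaced by the
#' donor's tract, optionally carrying extra divergence, and the event is
#' appended to the truth's `recomb_tracts`. Useful for constructing controlled
#' recombination scenarios on top of a clonal simulation.
#'
#' @param genomes named character vector of genome sequences.
#' @param truth the `sim_truth` from [simulate_strain_set()].
#' @param recipient,donor genome ids in `genomes`.
#' @param start,end 0-based half-open tract bounds.
#' @param tract_divergence extra substitutions/site applied to the donor copy.
#' @return list with updated `genomes` and `truth`.
#' @export
inject_recombination <- function(genomes, truth, recipient, donor, start, end,
                                 tract_divergence = 0) {
  stopifnot(recipient %in% names(genomes), donor %in% names(genomes),
            start >= 0, end > start, end <= nchar(genomes[[recipient]]))
  rv <- seq_to_vec(genomes[[recipient]])
  dv <- seq_to_vec(genomes[[donor]])
  idx <- (start + 1L):end
  rv[idx] <- evolve_jc(dv[idx], tract_divergence)
  genomes[[recipient]] <- vec_to_seq(rv)
  truth$recomb_tracts <- rbind(truth$recomb_tracts, data.frame(
    strain = recipient, start = as.integer(start), end = as.integer(end),
    donor = donor, stringsAsFactors = FALSE))
  list(genomes = genomes, truth = truth)
}
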