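#' Simulate gene families with controlled per-species occupancy
#'
#' Draws `n_families` unrelated family sequences and, for every genome, lets
#' the genome carry a mutated copy of each family with its species' occupancy
#' probability. The carriage truth matrix is returned for recovery tests of
#' the pangenome rules.
#'
#' @param n_families number of gene families.
#' @param occupancy carriage probability per family and species: a single
#'   fraction, a named per-species vector, or an `n_families x n_species`
#'   matrix with species column names.
#' @param genome_species named character vector mapping genome id -> species
#'   label (e.g. `truth$species` from [simulate_strain_set()]).
#' @param mutation_rate substitutions/site between a carried copy and the
#'   family ancestor (pairwise member divergence is about twice this).
#' @param length_range integer range the family lengths are drawn from.
#' @param gc_content GC fraction of family sequences.
#' @param seed integer seed.
#' @return list with `genes` (data.frame: genome_id, gene_id, family,
#'   sequence) and `truth_matrix` (logical families x genomes matrix with a
#'   `species` attribute).
#' @export
simulate_gene_families <- function(n_families, occupancy, genome_species,
                                   mutation_rate = 0.02,
                                   length_range = c(300L, 900L),
                                   gc_content = 0.4, seed = 1L) {
  assert_positive(n_families, "n_families")
  if (is.null(names(genome_species)))
    stop("'genome_species' must be a named vector (genome id -> species)")
  species <- sort(unique(genome_species))
  occ <- occupancy_matrix(occupancy, n_families, species)
  set.seed(seed)

  genomes <- names(genome_species)
  fam_ids <- sprintf("fam%04d", seq_len(n_families))
  truth <- matrix(FALSE, n_families, length(genomes),
                  dimnames = list(fam_ids, genomes))
  rows <- vector("list", n_families)
  for (f in seq_len(n_families)) {
    len <- sample(length_range[1]:length_range[2], 1L)
    base <- random_seq_vec(len, gc_content)
    carried <- runif(length(genomes)) < occ[f, genome_species[genomes]]
    truth[f, ] <- carried
    if (!any(carried)) next
    gs <- genomes[carried]
    rows[[f]] <- data.frame(
      genome_id = gs,
      gene_id = sprintf("%s|%s", gs, fam_ids[f]),
      family = fam_ids[f],
      sequence = vapply(gs, function(g) vec_to_seq(evolve_jc(base, mutation_rate)),
                        character(1)),
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(genes) <- NULL
  attr(truth, "species") <- genome_species
  list(genes = genes, truth_matrix = truth)
}

occupancy_matrix <- function(occupancy, n_families, species) {
  if (is.matrix(occupancy)) {
    if (nrow(occupancy) != n_families || !all(species %in% colnames(occupancy)))
      stop("occupancy matrix must be n_families x species with species column names")
    occ <- occupancy[, species, drop = FALSE]
  } else if (!is.null(names(occupancy))) {
    if (!all(species %in% names(occupancy)))
      stop("named occupancy must cover every species")
    occ <- matrix(rep(occupancy[species], each = n_families), n_families,
                  dimnames = list(NULL, species))
  } else {
    assert_fraction(occupancy, "occupancy")
    occ <- matrix(occupancy, n_families, length(species),
                  dimnames = list(NULL, species))
  }
  if (any(occ < 0 | occ > 1)) stop("occupancy fractions must lie in [0, 1]")
  occ
}
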