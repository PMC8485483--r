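#' Simulation parameters for the synthetic ancient-metagenome generator
#'
#' Bundles every knob of the generator: the strain/species divergence
#' structure, homologous-recombination imports, ancient-DNA fragmentation and
#' terminal deamination damage, and sequencing depth/error. Divergence
#' parameters are *expected pairwise* substitutions per site: strain trees are
#' rescaled so the maximum root-to-tip depth is `within_species_divergence / 2`
#' and species ancestors sit `between_species_divergence / 2` from their common
#' ancestor, so the deepest within-species pair diverges by
#' `within_species_divergence` and between-species pairs by
#' `between_species_divergence` (plus their within-species depths).
#'
#' @param genome_length genome size in bp; must be at least
#'   `10 * mean_tract_length` so recombination tracts stay small relative to
#'   the clonal frame.
#' @param gc_content GC fraction of the ancestral genome (default 0.30,
#'   typical of oral *Methanobrevibacter*).
#' @param n_species,n_strains_per_species number of species and of sampled
#'   strains per species.
#' @param between_species_divergence,within_species_divergence expected
#'   pairwise substitutions/site between species ancestors and between the
#'   deepest strain pair within a species.
#' @param recomb_rate_per_branch expected recombination imports per branch of
#'   the strain tree (analogous to R/theta).
#' @param mean_tract_length mean imported tract length in bp (geometric;
#'   delta analog).
#' @param tract_divergence extra substitutions/site carried by an imported
#'   tract relative to its donor (nu analog).
#' @param donor_model `"external"` (default): the donor is an independently
#'   mutated copy of the recipient's clonal frame, i.e. an import from outside
#'   the sample. `"within"`: the donor tract is copied from another sampled
#'   lineage of the same species (host-to-host transfer), which is the model
#'   that can distort tree topology.
#' @param mean_fragment_length,min_fragment_length,fragment_sdlog ancient-DNA
#'   fragment length model: log-normal with the given mean and log-sd,
#'   truncated below at `min_fragment_length` (>= 25 bp, the usual
#'   post-merging floor).
#' @param damage_rate_5p probability of C->T misincorporation at the first
#'   5' position of a read; decays as `exp(-damage_decay * (pos - 1))` along
#'   the read, with symmetric G->A damage from the 3' end.
#' @param damage_decay per-position exponential decay constant of the damage.
#' @param seq_error independent per-base sequencing error probability.
#' @param depth_per_strain target fold coverage per simulated sample.
#' @param coverage_mode `"uniform"` (default) places fragments uniformly at
#'   random; `"tiling"` lays `round(depth_per_strain)` staggered end-to-end
#'   passes so every site is covered at least `round(depth_per_strain)` times
#'   (used for controlled-truth tests where full breadth is required).
#' @param seed integer master seed; identical parameters give byte-identical
#'   output.
#'
#' @return an object of class `sim_params` (a validated list).
#' @export
sim_params <- function(genome_length = 50000L,
                       gc_content = 0.30,
                       n_species = 3L,
                       between_species_divergence = 0.15,
                       n_strains_per_species = 4L,
                       within_species_divergence = 0.01,
                       recomb_rate_per_branch = 0,
                       mean_tract_length = 2000,
                       tract_divergence = 0.05,
                       donor_model = c("external", "within"),
                       mean_fragment_length = 60,
                       min_fragment_length = 25L,
                       fragment_sdlog = 0.25,
                       damage_rate_5p = 0.3,
                       damage_decay = 0.5,
                       seq_error = 0.001,
                       depth_per_strain = 20,
                       coverage_mode = c("uniform", "tiling"),
                       seed = 1L) {
  donor_model <- match.arg(donor_model)
  coverage_mode <- match.arg(coverage_mode)
  assert_positive(genome_length, "genome_length")
  assert_fraction(gc_content, "gc_content")
  assert_positive(n_species, "n_species")
  assert_positive(n_strains_per_species, "n_strains_per_species")
  assert_positive(between_species_divergence + 1e-12, "between_species_divergence")
  if (within_species_divergence < 0) stop("'within_species_divergence' must be >= 0", call. = FALSE)
  if (recomb_rate_per_branch < 0) stop("'recomb_rate_per_branch' must be >= 0", call. = FALSE)
  assert_positive(mean_tract_length, "mean_tract_length")
  if (tract_divergence < 0) stop("'tract_divergence' must be >= 0", call. = FALSE)
  assert_positive(mean_fragment_length, "mean_fragment_length")
  if (min_fragment_length < 25) stop("'min_fragment_length' must be >= 25", call. = FALSE)
  assert_positive(fragment_sdlog, "fragment_sdlog")
  assert_fraction(damage_rate_5p, "damage_rate_5p")
  if (damage_decay < 0) stop("'damage_decay' must be >= 0", call. = FALSE)
  assert_fraction(seq_error, "seq_error")
  if (!is.numeric(depth_per_strain) || depth_per_strain <= 0)
    stop("'depth_per_strain' must be > 0", call. = FALSE)
  if (genome_length < 10 * mean_tract_length)
    stop("'genome_length' must be >= 10 * mean_tract_length", call. = FALSE)
  if (mean_fragment_length < min_fragment_length)
    stop("'mean_fragment_length' must be >= min_fragment_length", call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  structure(list(
    genome_length = as.integer(genome_length), gc_content = gc_content,
    n_species = as.integer(n_species),
    between_species_divergence = between_species_divergence,
    n_strains_per_species = as.integer(n_strains_per_species),
    within_species_divergence = within_species_divergence,
    recomb_rate_per_branch = recomb_rate_per_branch,
    mean_tract_length = mean_tract_length,
    tract_divergence = tract_divergence,
    donor_model = donor_model,
    mean_fragment_length = mean_fragment_length,
    min_fragment_length = as.integer(min_fragment_length),
    fragment_sdlog = fragment_sdlog,
    damage_rate_5p = damage_rate_5p, damage_decay = damage_decay,
    seq_error = seq_error, depth_per_strain = depth_per_strain,
    coverage_mode = coverage_mode,
    seed = as.integer(seed)
  ), class = "sim_params")
}
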