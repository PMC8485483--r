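#' Pipeline configuration
#'
#' Collects every stage toggle and threshold of the strain-phylogenomics
#' pipeline with its canonical default, validates ranges, and rejects unknown
#' keys. The effective configuration is echoed into every run directory.
#'
#' @param ... named overrides of the defaults listed below.
#' @return a `pipeline_config` list.
#' @details Defaults: read gate `min_mq = 30`, `min_read_length = 30`,
#'   `min_read_identity = 0.97`; consensus `min_depth = 3`,
#'   `min_dominant_freq = 0.80`; presence screen `breadth_threshold = 0.50`;
#'   hit filter `min_hit_length = 500`, `min_hit_identity = 0.95`; cleaning
#'   `max_row_gap_frac = 0.50`, `max_col_missing_frac = 0.10`; phylogeny
#'   `n_bootstrap = 100`; recombination `recomb_window = 1000`,
#'   `recomb_step = 100`, `recomb_alpha = 0.05`, `max_mask_iter = 20`;
#'   damage `damage_window = 25`, `min_terminal_rate = 0.05`,
#'   `min_fold_over_baseline = 2`; ANI `ani_fragment_length = 1000`,
#'   `ani_cut = 0.05`; pangenome `cluster_identity = 0.85`,
#'   `core_frac = 0.90`, `specific_frac = 0.90`; stage toggles `run_damage`,
#'   `run_screen`, `run_phylo`, `run_ani`, `run_bootstrap`; `seed = 1`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    min_mq = 30, min_read_length = 30, min_read_identity = 0.97,
    min_depth = 3, min_dominant_freq = 0.80,
    breadth_threshold = 0.50,
    min_hit_length = 500, min_hit_identity = 0.95,
    max_row_gap_frac = 0.50, max_col_missing_frac = 0.10,
    n_bootstrap = 100,
    recomb_window = 1000, recomb_step = 100, recomb_alpha = 0.05,
    max_mask_iter = 20,
    damage_window = 25, min_terminal_rate = 0.05, min_fold_over_baseline = 2,
    ani_fragment_length = 1000, ani_cut = 0.05,
    cluster_identity = 0.85, core_frac = 0.90, specific_frac = 0.90,
    run_damage = TRUE, run_screen = TRUE, run_phylo = TRUE,
    run_ani = FALSE, run_bootstrap = FALSE,
    seed = 1
  )
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1L]]) && is.null(names(over)[1L]))
    over <- over[[1L]]
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg <- defaults
  cfg[names(over)] <- over
  for (nm in c("min_read_identity", "min_dominant_freq", "breadth_threshold",
               "min_hit_identity", "max_row_gap_frac", "max_col_missing_frac",
               "recomb_alpha", "ani_cut", "cluster_identity", "core_frac",
               "specific_frac"))
    assert_fraction(cfg[[nm]], nm)
  for (nm in c("min_mq", "min_read_length", "min_depth", "min_hit_length",
               "n_bootstrap", "recomb_window", "recomb_step", "max_mask_iter",
               "damage_window", "ani_fragment_length"))
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] < 0)
      stop(sprintf("'%s' must be a non-negative number", nm))
  structure(cfg, class = "pipeline_config")
}

#' Save / load a pipeline configuration (JSON round-trip)
#'
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   validated `pipeline_config` (unknown keys are rejected).
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  pipeline_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Run the strain-level phylogenomics pipeline
#'
#' Executes the stages in order on a set of per-sample read alignments against
#' one reference: damage profiling and authentication, gated consensus
#' reconstruction, breadth-of-coverage presence screen, reference-anchored MSA
#' assembly and cleaning, and the iterative recombination-masking phylogeny.
#' All intermediates and a machine-readable JSON summary are persisted in
#' `out_dir`; a rerun with the same inputs and config reproduces them.
#'
#' @param samples named list of `read_alignments` data.frames (or paths to SAM
#'   files), one per sample.
#' @param reference reference genome sequence.
#' @param ref_id reference name.
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created).
#' @param extra_rows optional named list of additional MSA sources
#'   (`consensus_genome` or filtered `local_hits`), e.g. MAG-derived rows.
#' @return (invisibly) a list with per-sample `breadth`, `presence`,
#'   `authentic`, the retained sample ids, the cleaned `msa`, the final
#'   `tree`, the `tract_history`, and `paths` of persisted artifacts.
#' @export
run_strain_pipeline <- function(samples, reference, ref_id, config,
                                out_dir, extra_rows = list()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!length(samples)) stop("empty sample list: nothing to run")
  if (is.null(names(samples)) || any(names(samples) == ""))
    stop("samples must be named")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_config(config, file.path(out_dir, "config.json"))
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  logf("effective config: %s",
       jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA))

  breadth <- numeric(0); presence <- logical(0); authentic <- logical(0)
  consensi <- list()
  for (s in names(samples)) {
    aln <- samples[[s]]
    if (is.character(aln)) aln <- read_sam(aln, sample = s)
    if (isTRUE(config$run_damage)) {
      prof <- misincorporation_profile(aln, reference,
                                       window = config$damage_window)
      auth <- authenticate(prof, config$min_terminal_rate,
                           config$min_fold_over_baseline)
      write_damage_profile(prof, file.path(out_dir, paste0(s, ".damage.tsv")))
      authentic[s] <- isTRUE(auth$authentic)
      logf("sample %s: damage ct_5p[1]=%.4f baseline=%.5f authentic=%s",
           s, prof$ct_5p[1], prof$interior_ct_baseline, auth$authentic)
    }
    pu <- tryCatch(
      build_pileup(aln, reference, ref_id = NULL,
                   min_mq = config$min_mq, min_len = config$min_read_length,
                   min_identity = config$min_read_identity),
      error = function(e) stop("stage consensus failed for sample '", s,
                               "': ", conditionMessage(e), call. = FALSE))
    cons <- call_consensus(pu, config$min_depth, config$min_dominant_freq)
    cons$ref_id <- ref_id   # pileups are anchored to the pipeline reference
    breadth[s] <- breadth_of_coverage(pu, config$min_depth)
    presence[s] <- detect_presence(breadth[s], config$breadth_threshold)
    consensi[[s]] <- cons
    logf("sample %s: breadth=%.3f present=%s", s, breadth[s], presence[s])
  }
  write_tsv(data.frame(sample = names(samples), breadth = unname(breadth),
                       present = unname(presence)),
            file.path(out_dir, "breadth.tsv"))
  write_fasta(vapply(consensi, function(cg) cg$sequence, character(1)),
              file.path(out_dir, "consensus.fasta"))

  keep <- if (isTRUE(config$run_screen)) names(samples)[presence] else names(samples)
  logf("presence screen retained %d/%d samples", length(keep), length(samples))

  sources <- c(consensi[keep], extra_rows)
  msa <- build_ref_msa(sources, reference, ref_id = ref_id,
                       include_reference = TRUE)
  msa <- clean_msa(msa, config$max_row_gap_frac, config$max_col_missing_frac,
                   mode = "strain")
  write_msa(msa, file.path(out_dir, "msa.fasta"))

  tree <- NULL; history <- NULL; masked <- NULL
  if (isTRUE(config$run_phylo)) {
    if (length(msa$rows) < 3L)
      stop("stage phylogeny failed: fewer than 3 rows after screening/cleaning")
    res <- iterative_mask_phylogeny(
      msa,
      detector = function(m) detect_recombination(
        m, window = config$recomb_window, step = config$recomb_step,
        alpha = config$recomb_alpha),
      max_iter = config$max_mask_iter)
    tree <- res$tree; history <- res$tract_history; masked <- res$msa
    if (isTRUE(config$run_bootstrap) && length(masked$rows) >= 4L)
      tree <- bootstrap_support(masked, n_reps = config$n_bootstrap,
                                seed = config$seed)
    write_newick(tree, file.path(out_dir, "tree.nwk"))
    write_tracts(history, file.path(out_dir, "tracts.tsv"))
    write_msa(masked, file.path(out_dir, "msa_masked.fasta"))
    logf("phylogeny: %d masking iterations, %d tracts",
         res$n_iter, nrow(history))
  }

  summary <- list(samples = names(samples), breadth = as.list(breadth),
                  presence = as.list(presence),
                  authentic = if (length(authentic)) as.list(authentic) else NULL,
                  retained = keep,
                  msa_rows = length(msa$rows), msa_cols = length(msa$column_coords),
                  n_tracts = if (is.null(history)) NA else nrow(history))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(breadth = breadth, presence = presence,
                 authentic = authentic, retained = keep,
                 consensus = consensi, msa = msa, masked_msa = masked,
                 tree = tree, tract_history = history, out_dir = out_dir))
}

#' Compare a pipeline run against the simulation ground truth
#'
#' Tabulates parameter-recovery metrics: per-sample consensus error (mismatch
#' rate at non-gap sites against the true source genome), breadth, damage
#' recovery (when profiles were computed), tract overlap (best Jaccard of
#' detected vs true tracts per recombinant strain), and tree accuracy
#' (Robinson-Foulds distance of the final tree to the true strain tree over
#' the retained taxa, when both have >= 4 shared tips).
#'
#' @param run result of [run_strain_pipeline()].
#' @param truth the `sim_truth` for the genomes the samples came from.
#' @param genomes the true genome sequences.
#' @return a list with `consensus` (per-sample data.frame), `rf_distance`,
#'   `tract_jaccard` (per true tract) — elements are NULL when not applicable.
#' @export
recovery_report <- function(run, truth, genomes) {
  stopifnot(inherits(truth, "sim_truth"))
  rows <- lapply(names(run$consensus), function(s) {
    if (!s %in% names(genomes)) stop("no truth genome for sample '", s, "'")
    cons <- seq_to_vec(run$consensus[[s]]$sequence)
    tru <- seq_to_vec(genomes[[s]])
    called <- cons != "-"
    data.frame(sample = s, called_sites = sum(called),
               errors = sum(cons[called] != tru[called]),
               error_rate = ifelse(sum(called) > 0,
                                   sum(cons[called] != tru[called]) / sum(called), NA),
               breadth = run$breadth[[s]], stringsAsFactors = FALSE)
  })
  consensus <- do.call(rbind, rows)

  rf <- NULL
  sp_of <- truth$species[run$retained]
  sp_tab <- table(sp_of)
  if (length(sp_tab)) {
    sp <- names(sp_tab)[which.max(sp_tab)]
    tt <- truth$strain_trees[[sp]]
    if (!is.null(tt) && !is.null(run$tree)) {
      shared <- intersect(run$tree$tip.label, tt$tip.label)
      if (length(shared) >= 4L) {
        t1 <- ape::keep.tip(run$tree, shared)
        t2 <- ape::keep.tip(tt, shared)
        rf <- rf_distance(t1, t2)
      }
    }
  }

  tj <- NULL
  if (nrow(truth$recomb_tracts) && !is.null(run$tract_history)) {
    tj <- truth$recomb_tracts
    tj$jaccard <- vapply(seq_len(nrow(tj)), function(k) {
      det <- run$tract_history[run$tract_history$row_id == tj$strain[k], , drop = FALSE]
      if (!nrow(det)) return(0)
      max(vapply(seq_len(nrow(det)), function(q)
        interval_jaccard(tj$start[k], tj$end[k], det$start[q], det$end[q]),
        numeric(1)))
    }, numeric(1))
  }
  list(consensus = consensus, rf_distance = rf, tract_jaccard = tj)
}

# unrooted Robinson-Foulds distance via canonical bipartition sets
rf_distance <- function(t1, t2) {
  b1 <- tree_bipartitions(t1); b2 <- tree_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' One-command synthetic demonstration run
#'
#' Simulates a three-species strain set with damaged reads, runs ANI species
#' delimitation on the genomes, runs the full read-based pipeline for the
#' first species against one of its strains as reference, and reports
#' parameter recovery. The strain tree topology is fixed (balanced) so the
#' truth comparison is determinate; mutations, fragments and damage are drawn
#' from `seed`.
#'
#' @param out_dir run directory.
#' @param seed master seed.
#' @param genome_length simulated genome size (default 25000 bp).
#' @param depth_per_strain fold coverage per sample (default 20).
#' @return list with `run` (pipeline result), `report` (recovery report),
#'   `ani_clusters`, `species_truth`, and `summary` (named numeric vector of
#'   headline metrics, also written to `<out_dir>/demo_summary.json`).
#' @export
run_demo <- function(out_dir, seed = 1L, genome_length = 25000L,
                     depth_per_strain = 20) {
  params <- sim_params(genome_length = genome_length, n_species = 3L,
                       n_strains_per_species = 4L,
                       between_species_divergence = 0.15,
                       within_species_divergence = 0.01,
                       depth_per_strain = depth_per_strain,
                       damage_rate_5p = 0.3, damage_decay = 0.5,
                       seq_error = 0.001, seed = as.integer(seed))
  bal <- ape::read.tree(text = "((a:0.7,b:0.7):0.3,(c:0.7,d:0.7):0.3);")
  ss <- simulate_strain_set(params, strain_tree = bal)
  sim <- simulate_reads(ss$genomes, ss$truth, params)
  truth <- sim$truth

  # species delimitation on the genome sequences (the MAG surrogate)
  am <- ani_matrix(ss$genomes)
  clusters <- delimit_species(am, max_intra_distance = 0.05)

  # read-based strain phylogeny for species 1, first strain as reference;
  # the reference MSA row gets a distinct id so it never collides with the
  # consensus row reconstructed from that same strain's reads
  sp1 <- names(truth$species)[truth$species == "sp1"]
  ref_id <- paste0(sp1[1L], "|ref")
  reference <- ss$genomes[[sp1[1L]]]
  samples <- split(sim$alignments, sim$alignments$sample)
  class_fix <- function(df) { class(df) <- c("read_alignments", "data.frame"); df }
  samples <- lapply(samples, class_fix)
  cfg <- pipeline_config(seed = as.integer(seed))
  run <- run_strain_pipeline(samples, reference, ref_id, cfg, out_dir)
  rep <- recovery_report(run, truth, ss$genomes)

  ari <- adjusted_rand(clusters[names(truth$species)],
                       as.integer(factor(truth$species)))
  summary <- c(
    consensus_error_rate = max(rep$consensus$error_rate[rep$consensus$sample %in% sp1]),
    mean_breadth_sp1 = mean(rep$consensus$breadth[rep$consensus$sample %in% sp1]),
    n_retained = length(run$retained),
    n_species_clusters = length(unique(clusters)),
    species_ari = ari,
    tree_rf = if (is.null(rep$rf_distance)) NA_real_ else rep$rf_distance)
  write_sim_truth(truth, file.path(out_dir, "truth"))
  jsonlite::write_json(as.list(summary), file.path(out_dir, "demo_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(run = run, report = rep, ani_clusters = clusters,
       species_truth = truth$species, summary = summary)
}

# adjusted Rand index between two label vectors
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}
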