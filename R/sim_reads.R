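#' Simulate damaged ancient-DNA reads with their true alignments
#'
#' For every genome of a strain set, draws fragments from a truncated
#' log-normal length distribution, applies terminal cytosine-deamination
#' damage (C->T from the 5' end, G->A from the 3' end, both decaying
#' exponentially along the read) and independent sequencing error, and emits
#' the reads together with their *true* placements: no aligner is run, the
#' alignment records are the simulation truth. Each genome becomes one
#' "sample" whose sample id equals the genome id.
#'
#' Reads are reported in sequencing (read) orientation; alignment records
#' store the read in reference orientation. Simulated genomes are colinear
#' (substitution-only), so the true coordinates are valid against any genome
#' of the set used as a mapping reference.
#'
#' @param genomes named character vector from [simulate_strain_set()].
#' @param truth the matching `sim_truth`; `read_truth` is added to it.
#' @param params the [sim_params()] used for the simulation.
#' @return list with `reads` (data.frame: read_id, sample, seq, qual),
#'   `alignments` (a `read_alignments` data.frame: read_id, sample, ref_id,
#'   ref_start 0-based, strand, mapq, cigar, seq in reference orientation)
#'   and `truth` with a `read_truth` table (read_id, strain, ref_start,
#'   ref_end, strand, damaged_positions in read coordinates, n_errors).
#' @export
simulate_reads <- function(genomes, truth, params) {
  stopifnot(inherits(params, "sim_params"))
  if (params$depth_per_strain <= 0) stop("'depth_per_strain' must be > 0", call. = FALSE)
  set.seed(params$seed + 10007L)
  L <- params$genome_length
  reads_l <- list(); aln_l <- list(); rt_l <- list()

  for (g in names(genomes)) {
    gv <- seq_to_vec(genomes[[g]])
    frag <- draw_fragments(L, params)
    n <- length(frag$start)
    if (n == 0L) next
    strand <- sample(c("+", "-"), n, replace = TRUE)
    read_id <- sprintf("%s_r%06d", g, seq_len(n))

    seqs_read <- character(n); seqs_ref <- character(n)
    dmg_pos <- character(n); n_err <- integer(n)
    for (i in seq_len(n)) {
      s <- frag$start[i]; len <- frag$len[i]
      slice <- gv[(s + 1L):(s + len)]
      rv <- if (strand[i] == "+") slice else revcomp_vec(slice)
      d <- apply_damage(rv, params)
      rv <- d$read
      e <- apply_seq_error(rv, params$seq_error)
      rv <- e$read
      seqs_read[i] <- vec_to_seq(rv)
      seqs_ref[i] <- if (strand[i] == "+") seqs_read[i] else revcomp(seqs_read[i])
      dmg_pos[i] <- paste(d$positions, collapse = ",")
      n_err[i] <- e$n
    }
    reads_l[[g]] <- data.frame(read_id = read_id, sample = g, seq = seqs_read,
                               qual = strrep("I", frag$len), stringsAsFactors = FALSE)
    aln_l[[g]] <- data.frame(read_id = read_id, sample = g, ref_id = g,
                             ref_start = frag$start, strand = strand,
                             mapq = 60L, cigar = sprintf("%dM", frag$len),
                             seq = seqs_ref, stringsAsFactors = FALSE)
    rt_l[[g]] <- data.frame(read_id = read_id, strain = g,
                            ref_start = frag$start,
                            ref_end = frag$start + frag$len,
                            strand = strand, damaged_positions = dmg_pos,
                            n_errors = n_err, stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, reads_l); rownames(reads) <- NULL
  alignments <- do.call(rbind, aln_l); rownames(alignments) <- NULL
  class(alignments) <- c("read_alignments", "data.frame")
  truth$read_truth <- do.call(rbind, rt_l); rownames(truth$read_truth) <- NULL
  list(reads = reads, alignments = alignments, truth = truth)
}

# fragment starts/lengths for one genome under the configured coverage mode
draw_fragments <- function(L, params) {
  meanlog <- log(params$mean_fragment_length) - params$fragment_sdlog^2 / 2
  draw_len <- function(n) {
    out <- integer(0)
    while (length(out) < n) {
      x <- as.integer(round(rlnorm(n, meanlog, params$fragment_sdlog)))
      x <- x[x >= params$min_fragment_length]   # truncation by rejection
      out <- c(out, x)
    }
    pmin(out[seq_len(n)], L)
  }
  if (params$coverage_mode == "tiling") {
    n_pass <- max(1L, as.integer(round(params$depth_per_strain)))
    starts <- integer(0); lens <- integer(0)
    for (p in seq_len(n_pass)) {
      pos <- -as.integer(round((p - 1) * params$mean_fragment_length / n_pass))
      while (pos < L) {
        len <- draw_len(1L)
        st <- min(max(pos, 0L), L - len)
        starts <- c(starts, st); lens <- c(lens, len)
        nxt <- st + len
        if (nxt >= L) break
        pos <- nxt
      }
    }
    list(start = starts, len = lens)
  } else {
    target <- params$depth_per_strain * L
    starts <- integer(0); lens <- integer(0); tot <- 0
    chunk <- max(16L, as.integer(ceiling(target / params$mean_fragment_length / 4)))
    while (tot < target) {
      len <- draw_len(chunk)
      keep <- cumsum(len) <= (target - tot) + max(len)
      len <- len[keep]
      st <- vapply(len, function(l) sample.int(L - l + 1L, 1L) - 1L, integer(1))
      need <- which(cumsum(len) + tot >= target)
      if (length(need)) { len <- len[seq_len(need[1])]; st <- st[seq_len(need[1])] }
      starts <- c(starts, st); lens <- c(lens, len); tot <- tot + sum(len)
    }
    list(start = starts, len = lens)
  }
}

# terminal deamination in read orientation; returns damaged read and the
# 1-based read positions where a damage substitution was applied
apply_damage <- function(rv, params) {
  len <- length(rv)
  pos <- integer(0)
  if (params$damage_rate_5p > 0) {
    p5 <- params$damage_rate_5p * exp(-params$damage_decay * (seq_len(len) - 1))
    hit5 <- which(rv == "C" & runif(len) < p5)
    d3 <- rev(seq_len(len)) - 1L
    p3 <- params$damage_rate_5p * exp(-params$damage_decay * d3)
    hit3 <- which(rv == "G" & runif(len) < p3)
    if (length(hit5)) rv[hit5] <- "T"
    if (length(hit3)) rv[hit3] <- "A"
    pos <- sort(c(hit5, hit3))
  }
  list(read = rv, positions = pos)
}

apply_seq_error <- function(rv, rate) {
  if (rate <= 0) return(list(read = rv, n = 0L))
  hit <- which(runif(length(rv)) < rate)
  if (length(hit)) {
    shift <- sample.int(3L, length(hit), replace = TRUE)
    code <- match(rv[hit], BASES)
    rv[hit] <- BASES[((code - 1L + shift) %% 4L) + 1L]
  }
  list(read = rv, n = length(hit))
}
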