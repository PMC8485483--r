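#' Detect recombination tracts as clustered substitutions
#'
#' A simplified windowed surrogate for a clonal-frame detector: per row, a
#' substitution is a column where the row differs from the column-wise
#' majority allele (gaps excluded; ties broken lexicographically A<C<G<T).
#' Sliding windows whose substitution count exceeds the Bonferroni-corrected
#' Poisson critical value — with rate lambda = (row substitution density) x
#' (comparable sites in the window) — are merged into tracts. Under clonal
#' evolution substitutions are scattered, so windows stay below the critical
#' value at the configured family-wise rate; an imported tract concentrates
#' substitutions and lights up its windows.
#'
#' @param msa a `ref_msa` with >= 3 rows.
#' @param window window width in columns (default 1000).
#' @param step window step in columns (default 100).
#' @param alpha family-wise false-positive rate across all row-windows
#'   (Bonferroni; default 0.05).
#' @return a data.frame of tracts: `row_id`, `start`, `end` (0-based half-open
#'   column coordinates), `score` (max window substitution count) and
#'   `p_value` (Poisson upper tail of that count).
#' @export
detect_recombination <- function(msa, window = 1000L, step = 100L,
                                 alpha = 0.05) {
  im <- msa_int(msa)
  if (nrow(im) < 3L) stop("need >= 3 rows to call a column majority")
  n <- nrow(im); L <- ncol(im)
  window <- min(as.integer(window), L)
  step <- as.integer(step)

  # column-wise majority over A,C,G,T with lexicographic tie-break
  tab <- vapply(1:4, function(b) colSums(im == b), numeric(L))
  if (L == 1L) tab <- matrix(tab, nrow = 1L)
  maj <- max.col(tab, ties.method = "first")   # first = smallest base index

  starts <- seq.int(0L, max(0L, L - window), by = step)
  if (!length(starts)) starts <- 0L
  n_tests <- n * length(starts)
  alpha_adj <- alpha / n_tests

  out <- list()
  for (i in seq_len(n)) {
    present <- im[i, ] > 0L
    sub <- present & im[i, ] != maj
    ncomp <- sum(present)
    if (ncomp == 0L) next
    dens <- sum(sub) / ncomp
    cs_sub <- c(0L, cumsum(sub))
    cs_prs <- c(0L, cumsum(present))
    wc <- cs_sub[pmin(starts + window, L) + 1L] - cs_sub[starts + 1L]
    wn <- cs_prs[pmin(starts + window, L) + 1L] - cs_prs[starts + 1L]
    lam <- dens * wn
    crit <- qpois(1 - alpha_adj, lam)
    sig <- which(wc > crit & wn > 0L)
    if (!length(sig)) next
    # merge overlapping significant windows into tracts
    ws <- starts[sig]; we <- pmin(starts[sig] + window, L)
    o <- order(ws)
    ws <- ws[o]; we <- we[o]; cnt <- wc[sig][o]; lamo <- lam[sig][o]
    ts <- ws[1L]; te <- we[1L]; best <- cnt[1L]; bl <- lamo[1L]
    for (k in seq_along(ws)[-1L]) {
      if (ws[k] <= te) {
        te <- max(te, we[k])
        if (cnt[k] > best) { best <- cnt[k]; bl <- lamo[k] }
      } else {
        out[[length(out) + 1L]] <- data.frame(
          row_id = rownames(im)[i], start = ts, end = te, score = best,
          p_value = ppois(best - 1L, bl, lower.tail = FALSE),
          stringsAsFactors = FALSE)
        ts <- ws[k]; te <- we[k]; best <- cnt[k]; bl <- lamo[k]
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      row_id = rownames(im)[i], start = ts, end = te, score = best,
      p_value = ppois(best - 1L, bl, lower.tail = FALSE),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(row_id = character(0), start = integer(0),
                      end = integer(0), score = integer(0),
                      p_value = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# replace tract cells with '-' in a ref_msa; returns list(msa, n_new_cells)
mask_tracts <- function(msa, tracts) {
  m <- msa_matrix(msa)
  n_new <- 0L
  for (k in seq_len(nrow(tracts))) {
    i <- match(tracts$row_id[k], rownames(m))
    if (is.na(i)) next
    idx <- (tracts$start[k] + 1L):tracts$end[k]
    n_new <- n_new + sum(m[i, idx] != "-")
    m[i, idx] <- "-"
  }
  list(msa = msa_from_matrix(m, msa$ref_id, msa$column_coords),
       n_new_cells = n_new)
}

#' Iterative recombination masking and tree rebuilding
#'
#' Runs the detect -> mask -> rebuild loop: recombination tracts are replaced
#' by gaps and the tree is re-estimated, iterating until the detector returns
#' no tracts (or no tract adds a newly masked cell) or `max_iter` is reached.
#' Masked cells accumulate strictly across iterations, which guarantees
#' termination.
#'
#' @param msa a `ref_msa`.
#' @param detector function(msa) returning a tract data.frame with columns
#'   `row_id`, `start`, `end` (the adapter contract; default
#'   [detect_recombination()]).
#' @param builder function(msa) returning a `phylo` (default: neighbor
#'   joining on Jukes-Cantor distances).
#' @param max_iter iteration cap (default 20); reaching it with detections
#'   still pending sets `converged = FALSE` and warns rather than failing.
#' @return list with `tree` (final `phylo`), `msa` (final masked alignment),
#'   `tract_history` (tracts with an `iteration` column), `n_iter`,
#'   `masked_cells` (cumulative count) and `converged`.
#' @export
iterative_mask_phylogeny <- function(msa,
                                     detector = detect_recombination,
                                     builder = function(m)
                                       neighbor_joining(jc_distance_matrix(m)),
                                     max_iter = 20L) {
  stopifnot(inherits(msa, "ref_msa"))
  history <- list()
  masked <- 0L
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    tracts <- detector(msa)
    if (!nrow(tracts)) { converged <- TRUE; break }
    mk <- mask_tracts(msa, tracts)
    tracts$iteration <- iter
    history[[iter]] <- tracts
    if (mk$n_new_cells == 0L) { converged <- TRUE; break }
    masked <- masked + mk$n_new_cells
    msa <- mk$msa
    if (iter >= max_iter) break
  }
  if (!converged)
    warning("max_iter reached with recombination detections still pending")
  tree <- builder(msa)
  list(tree = tree, msa = msa,
       tract_history = if (length(history)) do.call(rbind, history) else
         data.frame(row_id = character(0), start = integer(0),
                    end = integer(0), score = integer(0),
                    p_value = numeric(0), iteration = integer(0)),
       n_iter = iter, masked_cells = masked, converged = converged)
}

#' Write recombination tracts as a BED-like TSV
#'
#' @param tracts tract data.frame (e.g. `tract_history`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tracts <- function(tracts, path) {
  write_tsv(tracts, path)
}
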