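#' Normalize a raw fiber-count connectome
#'
#' Turns raw streamline counts into the dimensionless normalized weights
#' the propagation model expects, in three steps:
#' 1. scale by target-region volume, `w_tilde[i, j] = counts[i, j] / V_i`,
#'    so entries represent fiber density in the receiving region;
#' 2. for each (anterior, posterior) hippocampus pair, increment both
#'    directed entries between the two parts by the 98th percentile of the
#'    volume-scaled matrix — tractography misses the strong gray-matter
#'    connection between them;
#' 3. divide by the maximal ingoing sum, `w = w_tilde / max_i sum_j
#'    w_tilde[i, j]`, so the maximal ingoing weight sum is exactly 1.
#'
#' The result is invariant to a global rescaling of the counts.
#'
#' @param counts square nonnegative matrix of streamline counts
#'   (`counts[i, j]` = fibers from region `j` to region `i`).
#' @param volumes positive region volumes (mm^3), one per region.
#' @param hippocampus_pairs optional list of length-2 vectors of region ids
#'   (anterior, posterior), one per hemisphere.
#' @param region_ids region labels; defaults to dimnames of `counts`.
#' @param percentile_nonzero_only if `TRUE`, compute the hippocampus
#'   correction percentile over nonzero entries only (default `FALSE`:
#'   all entries, linear-interpolation percentile).
#' @return A [connectome()].
#' @export
normalize_connectome <- function(counts, volumes, hippocampus_pairs = list(),
                                 region_ids = NULL,
                                 percentile_nonzero_only = FALSE) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  if (ncol(counts) != n) stop("counts matrix must be square")
  if (any(counts < 0)) stop("fiber counts must be nonnegative")
  if (all(counts == 0)) stop("all-zero count matrix")
  if (length(volumes) != n) stop("length(volumes) must equal nrow(counts)")
  if (any(volumes <= 0)) stop("region volumes must be positive")
  if (is.null(region_ids)) {
    region_ids <- rownames(counts)
    if (is.null(region_ids)) region_ids <- paste0("R", seq_len(n))
  }
  diag(counts) <- 0
  w <- sweep(counts, 1, volumes, "/")
  if (length(hippocampus_pairs)) {
    vals <- if (percentile_nonzero_only) w[w > 0] else as.vector(w)
    p98 <- stats::quantile(vals, 0.98, names = FALSE, type = 7)
    for (pair in hippocampus_pairs) {
      idx <- match(pair, region_ids)
      if (any(is.na(idx)) || length(idx) != 2L)
        stop("hippocampus pair not found among region ids: ",
             paste(pair, collapse = ", "))
      w[idx[1], idx[2]] <- w[idx[1], idx[2]] + p98
      w[idx[2], idx[1]] <- w[idx[2], idx[1]] + p98
    }
  }
  w <- w / max(rowSums(w))
  connectome(w, region_ids)
}
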