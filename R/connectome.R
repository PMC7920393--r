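#' Connectome container
#'
#' A weighted, directed structural brain network. Entry `weights[i, j]` is
#' the (dimensionless) connection strength from region `j` to region `i`.
#' A valid connectome is nonnegative, zero on the diagonal, and normalized
#' so that the maximal ingoing weight sum `max_i sum_j w_ij` is at most 1
#' (exactly 1 after [normalize_connectome()]; resections can only lower it).
#' The normalization guarantees that the weighted seizing input of every
#' region stays in `[0, 1]`, the domain of the excitation function.
#'
#' @param weights square numeric matrix of nonnegative weights.
#' @param region_ids character vector of region labels; defaults to the
#'   matrix dimnames or `"R1"..."Rn"`.
#' @return An object of class `"connectome"`: the weight matrix with region
#'   ids as dimnames.
#' @export
connectome <- function(weights, region_ids = NULL) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (ncol(weights) != n) stop("connectome matrix must be square")
  if (!is.numeric(weights) || any(!is.finite(weights)))
    stop("connectome weights must be finite numerics")
  if (any(weights < 0)) stop("connectome weights must be nonnegative")
  if (any(diag(weights) != 0)) stop("connectome diagonal must be zero")
  if (n > 0 && max(rowSums(weights)) > 1 + 1e-8)
    stop("max ingoing weight sum exceeds 1; normalize the connectome first")
  if (is.null(region_ids)) {
    region_ids <- rownames(weights)
    if (is.null(region_ids)) region_ids <- paste0("R", seq_len(n))
  }
  if (length(region_ids) != n) stop("length(region_ids) must equal nrow")
  if (anyDuplicated(region_ids)) stop("region ids must be unique")
  dimnames(weights) <- list(region_ids, region_ids)
  structure(weights, class = c("connectome", "matrix", "array"))
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("Connectome: %d regions, %d nonzero connections,\n",
              nrow(x), sum(x > 0)))
  cat(sprintf("  max ingoing weight sum %.6g\n", max(rowSums(x))))
  invisible(x)
}

#' @rdname connectome
#' @param x object to test.
#' @export
is_connectome <- function(x) inherits(x, "connectome")

region_ids <- function(W) rownames(W)

#' Read / write a connectome
#'
#' Dense CSV (or TSV) with a header row of region ids; the matrix is read
#' as directed (no symmetry is assumed or imposed).
#'
#' @param path file path.
#' @param sep field separator, `","` or `"\t"`.
#' @return `read_connectome()` returns a [connectome()];
#'   `write_connectome()` returns `path` invisibly.
#' @export
read_connectome <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  m <- as.matrix(df)
  rownames(m) <- colnames(m)
  connectome(m)
}

#' @rdname read_connectome
#' @param W a [connectome()].
#' @export
write_connectome <- function(W, path, sep = ",") {
  utils::write.table(as.data.frame(unclass(W)), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Remove resected regions from a connectome
#'
#' Returns the sub-network on the surviving regions: rows and columns of
#' all resected regions are dropped. Ingoing weight sums can only decrease,
#' so the normalization invariant (`<= 1`) is preserved.
#'
#' @param W a [connectome()].
#' @param resected character vector of region ids (or integer indices) to
#'   remove; must all be present in `W`.
#' @return A [connectome()] on the surviving regions.
#' @export
apply_resection <- function(W, resected) {
  stopifnot(is_connectome(W))
  ids <- region_ids(W)
  if (is.numeric(resected)) {
    if (any(resected < 1 | resected > length(ids)))
      stop("resected index out of range")
    resected <- ids[resected]
  }
  unknown <- setdiff(resected, ids)
  if (length(unknown))
    stop("unknown region id(s): ", paste(unknown, collapse = ", "))
  keep <- setdiff(ids, resected)
  connectome(unclass(W)[keep, keep, drop = FALSE], keep)
}
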