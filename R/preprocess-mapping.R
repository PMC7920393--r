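#' Brain parcellation (voxel representation)
#'
#' @param region_ids character vector of region labels.
#' @param voxel_coords list (one element per region) of numeric matrices
#'   with 3 columns: voxel center coordinates in mm, scanner space.
#' @return Object of class `"parcellation"`.
#' @export
parcellation <- function(region_ids, voxel_coords) {
  stopifnot(length(region_ids) == length(voxel_coords))
  voxel_coords <- lapply(voxel_coords, function(v) {
    v <- as.matrix(v)
    if (ncol(v) != 3 || nrow(v) == 0)
      stop("each region needs a nonempty n x 3 voxel coordinate matrix")
    v
  })
  structure(list(region_ids = region_ids, voxel_coords = voxel_coords),
            class = "parcellation")
}

#' Assign an SEEG contact midpoint to a brain region
#'
#' Distance to a region is the minimum Euclidean distance from the contact
#' midpoint to the region's voxel centers (0 inside the region). If the two
#' nearest regions are at similar distance — `d2 / (d1 + 0.5 mm) < 2`,
#' where `d1`, `d2` are the nearest and second-nearest distances — the
#' observation is ambiguous and stays unassigned. There is no upper
#' distance cap, but a warning is emitted for midpoints more than 5 mm
#' from the nearest gray matter.
#'
#' @param midpoint length-3 numeric, mm.
#' @param parc a [parcellation()] with at least two regions.
#' @return Region id (character) or `NA_character_` if unassigned.
#' @export
assign_channel_to_region <- function(midpoint, parc) {
  stopifnot(inherits(parc, "parcellation"), length(midpoint) == 3)
  if (length(parc$region_ids) < 2)
    stop("parcellation must contain at least two regions")
  d <- vapply(parc$voxel_coords, function(v) {
    sqrt(min(colSums((t(v) - midpoint)^2)))
  }, numeric(1))
  ord <- order(d)
  d1 <- d[ord[1]]; d2 <- d[ord[2]]
  if (d1 > 5)
    warning(sprintf("contact midpoint %.2f mm from nearest gray matter", d1))
  if (d2 / (d1 + 0.5) < 2) return(NA_character_)
  parc$region_ids[ord[1]]
}

# lower-interpolation median: element at 1-based index floor((k + 1) / 2)
# of the sorted values (Inf sentinels participate in the ordering)
median_lower <- function(x) sort(x)[(length(x) + 1L) %/% 2L]

#' Aggregate channel observations into a region observation
#'
#' Channels assigned to the same region are combined by taking the median
#' of their onset times with lower interpolation for even counts;
#' non-seizing channels enter the multiset with onset `Inf`. The region is
#' seizing iff the resulting median is finite — this coincides with the
#' channel majority rule, with an even split resolved to the seizing side.
#'
#' @param onsets numeric vector of per-channel onsets (seconds; `Inf` for
#'   non-seizing channels); at least one channel.
#' @return List with `status` (`"seizing"`/`"non-seizing"`), `onset_s`
#'   (`Inf` when non-seizing), and `n_channels`.
#' @export
aggregate_region_observation <- function(onsets) {
  stopifnot(is.numeric(onsets), length(onsets) >= 1, !anyNA(onsets))
  m <- median_lower(onsets)
  list(status = if (is.finite(m)) "seizing" else "non-seizing",
       onset_s = m, n_channels = length(onsets))
}

#' Partially observed seizure
#'
#' The region-level observation of one seizure: every region of the
#' network is hidden (no assigned channel), seizing (with a finite onset
#' time), or non-seizing.
#'
#' @param region_ids all region ids of the network, in connectome order.
#' @param status character vector in `{"hidden", "seizing", "non-seizing"}`.
#' @param onset_s numeric vector: finite onset (s) for seizing regions,
#'   `Inf` for non-seizing, `NA` for hidden.
#' @return Object of class `"seizure_observation"`.
#' @export
seizure_observation <- function(region_ids, status, onset_s) {
  n <- length(region_ids)
  stopifnot(length(status) == n, length(onset_s) == n,
            all(status %in% c("hidden", "seizing", "non-seizing")))
  sz <- status == "seizing"
  if (!all(is.finite(onset_s[sz])))
    stop("seizing regions must have finite onset times")
  if (!all(is.infinite(onset_s[status == "non-seizing"])))
    stop("non-seizing regions must have onset Inf")
  onset_s[status == "hidden"] <- NA_real_
  structure(list(region_ids = region_ids, status = status,
                 onset_s = onset_s),
            class = "seizure_observation")
}

#' @export
print.seizure_observation <- function(x, ...) {
  cat(sprintf(
    "Seizure observation: %d regions (%d seizing, %d non-seizing, %d hidden)\n",
    length(x$region_ids), sum(x$status == "seizing"),
    sum(x$status == "non-seizing"), sum(x$status == "hidden")))
  invisible(x)
}

#' Align and truncate region observations into a model-ready seizure
#'
#' Shifts all finite onsets so the earliest one falls at `t1` (30 s),
#' reclassifies regions whose shifted onset exceeds `t_lim` (90 s) as
#' non-seizing, and marks unobserved regions hidden. A seizure with no
#' seizing region after mapping is excluded (returns `NULL`).
#'
#' @param onsets named numeric vector of region onsets for the observed
#'   regions (`Inf` for observed non-seizing regions); names are region
#'   ids.
#' @param region_ids all region ids of the network.
#' @param t1 alignment time (s) of the first region onset.
#' @param t_lim seizure time limit (s).
#' @return A [seizure_observation()], or `NULL` if the seizure is
#'   excluded.
#' @export
finalize_seizure <- function(onsets, region_ids, t1 = 30, t_lim = 90) {
  stopifnot(!is.null(names(onsets)), all(names(onsets) %in% region_ids))
  if (!any(is.finite(onsets))) return(NULL)
  shifted <- onsets + (t1 - min(onsets[is.finite(onsets)]))
  shifted[shifted > t_lim] <- Inf
  status <- rep("hidden", length(region_ids))
  onset_s <- rep(NA_real_, length(region_ids))
  idx <- match(names(onsets), region_ids)
  status[idx] <- ifelse(is.finite(shifted), "seizing", "non-seizing")
  onset_s[idx] <- shifted
  seizure_observation(region_ids, status, onset_s)
}

#' Seizure inclusion by duration
#'
#' Only seizures strictly longer than 30 s are included; shorter ones
#' break the assumption that every recruited region keeps seizing until
#' the time limit too severely.
#'
#' @param duration_s seizure duration in seconds.
#' @return Logical.
#' @export
seizure_duration_filter <- function(duration_s) {
  stopifnot(is.numeric(duration_s))
  duration_s > 30
}

#' Seizure-observation I/O
#'
#' Three-column CSV `(region_id, status, onset_s)` with `"inf"` for
#' non-seizing and empty onset for hidden regions.
#'
#' @param obs a [seizure_observation()].
#' @param path file path.
#' @return `read_seizure_observation()` returns a
#'   [seizure_observation()]; the writer returns `path` invisibly.
#' @export
write_seizure_observation <- function(obs, path) {
  stopifnot(inherits(obs, "seizure_observation"))
  onset <- ifelse(obs$status == "seizing",
                  format(obs$onset_s, digits = 17),
                  ifelse(obs$status == "non-seizing", "inf", ""))
  utils::write.csv(data.frame(region_id = obs$region_ids,
                              status = obs$status, onset_s = onset),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_seizure_observation
#' @export
read_seizure_observation <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(onset_s = "character"))
  onset <- suppressWarnings(as.numeric(df$onset_s))
  onset[tolower(trimws(df$onset_s)) == "inf"] <- Inf
  seizure_observation(df$region_id, df$status, onset)
}
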