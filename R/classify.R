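## Classification of detected plaques into the study's categories:
## pre-existing vs new, new-in-vicinity, flower clusters, multicore,
## and merged-vs-separate core fate.

lookup_label <- function(det, x_px, y_px) {
  # label value at the pixel containing a 0-based point coordinate
  r <- pmin(pmax(floor(y_px), 0), nrow(det$labels) - 1L) + 1L
  c <- pmin(pmax(floor(x_px), 0), ncol(det$labels) - 1L) + 1L
  det$labels[cbind(r, c)]
}

#' Assign dense cores to antibody plaques
#'
#' Each core-channel (MX) region is assigned to the antibody (AB) region
#' whose mask contains its centroid; cores whose centroid falls in no AB
#' mask are reported as orphans. A plaque's `n_cores` is the number of
#' distinct MX components assigned to it ("clearly separate" cores).
#'
#' @param ab_det,mx_det `plaque_regions` for the antibody and core channels
#'   of the same calibrated image (equal pixel grids required).
#' @return A `plaque_records` data.frame: the AB regions with columns
#'   `plaque_id`, `x_um`, `y_um`, `area_px`, `area_um2`, `n_cores`, plus
#'   attributes `assignments` (data.frame `mx_id`, `ab_id`), `orphans`
#'   (MX ids unassigned), `mx_centroids`, `pixel_size_um`.
#' @export
pair_channels <- function(ab_det, mx_det) {
  stopifnot(inherits(ab_det, "plaque_regions"),
            inherits(mx_det, "plaque_regions"))
  if (!isTRUE(all.equal(ab_det$pixel_size_um, mx_det$pixel_size_um)) ||
      !identical(dim(ab_det$labels), dim(mx_det$labels)))
    stop("AB and MX detections come from different pixel grids")
  mx <- mx_det$regions
  ab_id <- if (nrow(mx) > 0) lookup_label(ab_det, mx$x_px, mx$y_px)
           else integer(0)
  assignments <- data.frame(mx_id = mx$id, ab_id = ab_id)
  orphans <- mx$id[ab_id == 0L]
  if (length(orphans) > 0)
    warning(length(orphans),
            " core region(s) fall outside every antibody plaque (orphans)")
  rec <- ab_det$regions
  names(rec)[names(rec) == "id"] <- "plaque_id"
  rec$n_cores <- as.integer(tabulate(ab_id[ab_id > 0L], nbins = nrow(rec)))
  structure(rec,
            assignments = assignments, orphans = orphans,
            mx_centroids = mx[, c("id", "x_um", "y_um", "x_px", "y_px",
                                  "area_px")],
            pixel_size_um = ab_det$pixel_size_um,
            class = c("plaque_records", "data.frame"))
}

#' Flag new plaques
#'
#' A plaque is "new" when it is antibody positive but contains no dense-core
#' (MX) component: `is_new = (n_cores == 0)`.
#'
#' @param records a `plaque_records` data.frame from [pair_channels()].
#' @return The records with an `is_new` logical column.
#' @export
classify_new <- function(records) {
  stopifnot("n_cores" %in% names(records))
  records$is_new <- records$n_cores == 0L
  records
}

#' Reference centres of pre-existing plaques
#'
#' Distances are measured core-to-core, so the reference centre of a
#' pre-existing plaque defaults to the centroid of its largest assigned MX
#' core; the antibody-mask centroid is available as an alternative.
#'
#' @param records a `plaque_records` data.frame (after [classify_new()]).
#' @param method `"mx_core"` (default) or `"ab_centroid"`.
#' @return data.frame `plaque_id`, `x_um`, `y_um` for non-new plaques.
#' @export
pre_plaque_centers <- function(records, method = c("mx_core", "ab_centroid")) {
  method <- match.arg(method)
  pre <- records[!records$is_new, , drop = FALSE]
  if (method == "ab_centroid" || nrow(pre) == 0)
    return(data.frame(plaque_id = pre$plaque_id, x_um = pre$x_um,
                      y_um = pre$y_um))
  asg <- attr(records, "assignments")
  mx <- attr(records, "mx_centroids")
  out <- pre[, c("plaque_id", "x_um", "y_um")]
  for (i in seq_len(nrow(out))) {
    ids <- asg$mx_id[asg$ab_id == out$plaque_id[i]]
    if (length(ids) > 0) {
      sub <- mx[mx$id %in% ids, , drop = FALSE]
      main <- which.max(sub$area_px)
      out$x_um[i] <- sub$x_um[main]; out$y_um[i] <- sub$y_um[main]
    }
  }
  rownames(out) <- NULL
  out
}

#' Vicinity classification of new plaques
#'
#' Computes each new plaque's Euclidean centre-to-centre distance to the
#' nearest pre-existing plaque and flags it "in the vicinity" when that
#' distance is strictly less than `radius_um` (40 um by default).
#'
#' @param records a `plaque_records` data.frame with `is_new` set.
#' @param pre_centers optional data.frame/matrix of pre-existing centres
#'   (`x_um`, `y_um`); defaults to [pre_plaque_centers()] of the records.
#' @param radius_um vicinity radius in micrometres.
#' @return Records with `nearest_pre_um` (NA for pre-existing plaques, and
#'   for new plaques when no pre-existing plaque is present) and
#'   `in_vicinity` columns.
#' @export
vicinity_classify <- function(records, pre_centers = NULL, radius_um = 40) {
  stopifnot("is_new" %in% names(records))
  if (is.null(pre_centers)) pre_centers <- pre_plaque_centers(records)
  pc <- as.matrix(as.data.frame(pre_centers)[, c("x_um", "y_um")])
  records$nearest_pre_um <- NA_real_
  records$in_vicinity <- FALSE
  idx <- which(records$is_new)
  if (length(idx) > 0 && nrow(pc) > 0) {
    d <- nearest_dist(records[idx, c("x_um", "y_um")], pc)
    records$nearest_pre_um[idx] <- d
    records$in_vicinity[idx] <- d < radius_um
  }
  records
}

#' Find flower clusters
#'
#' A flower plaque is a pre-existing plaque with two or more new plaques
#' ("petals") whose centres lie strictly within `radius_um` of its centre.
#' A new plaque within range of several pre-existing plaques appears in each
#' of those clusters; `flower_parent_id` on the records is the nearest one.
#'
#' @inheritParams vicinity_classify
#' @return list with `flowers` (data.frame `parent_id`, `petal_id`,
#'   `distance_um`; one row per membership) and `records` (with
#'   `flower_parent_id` set to the nearest parent or NA).
#' @export
find_flowers <- function(records, pre_centers = NULL, radius_um = 40) {
  stopifnot(all(c("is_new", "in_vicinity") %in% names(records)))
  if (is.null(pre_centers)) pre_centers <- pre_plaque_centers(records)
  pre_centers <- as.data.frame(pre_centers)
  newp <- records[records$is_new, , drop = FALSE]
  memb <- data.frame(parent_id = integer(0), petal_id = integer(0),
                     distance_um = numeric(0))
  records$flower_parent_id <- NA_integer_
  if (nrow(newp) > 0 && nrow(pre_centers) > 0) {
    for (i in seq_len(nrow(pre_centers))) {
      d <- sqrt((newp$x_um - pre_centers$x_um[i])^2 +
                  (newp$y_um - pre_centers$y_um[i])^2)
      hit <- which(d < radius_um)
      if (length(hit) >= 2) {
        memb <- rbind(memb, data.frame(
          parent_id = pre_centers$plaque_id[i],
          petal_id = newp$plaque_id[hit], distance_um = d[hit]))
      }
    }
    if (nrow(memb) > 0) {
      # nearest flower parent per petal
      best <- memb[order(memb$petal_id, memb$distance_um), ]
      best <- best[!duplicated(best$petal_id), ]
      records$flower_parent_id[match(best$petal_id, records$plaque_id)] <-
        best$parent_id
    }
  }
  rownames(memb) <- NULL
  list(flowers = memb, records = records)
}

#' Flag multicore and large plaques
#'
#' A multicore plaque bears two or more clearly separate dense cores within
#' the boundary of a single antibody plaque; a large plaque exceeds
#' `large_threshold_um2` (300 um^2 by default).
#'
#' @param records a `plaque_records` data.frame from [pair_channels()].
#' @param large_threshold_um2 area threshold in um^2 (strict `>`).
#' @return Records with `is_multicore` and `is_large` columns.
#' @export
classify_multicore <- function(records, large_threshold_um2 = 300) {
  stopifnot("n_cores" %in% names(records))
  records$is_multicore <- records$n_cores >= 2L
  records$is_large <- records$area_um2 > large_threshold_um2
  records
}

#' Classify the fate of multicore plaques
#'
#' With a dense-core counterstain (TR) channel, a multicore plaque's cores
#' are "merged" when at least two of its MX core centroids fall inside one
#' TR connected region, and "separate" otherwise. Without a TR channel the
#' fate is "not_applicable".
#'
#' @param records a `plaque_records` data.frame with `is_multicore` set.
#' @param tr_det `plaque_regions` of the counterstain channel, or NULL.
#' @return Records with a `core_fate` column
#'   (`"merged"`/`"separate"`/`"not_applicable"`).
#' @export
classify_core_fate <- function(records, tr_det = NULL) {
  stopifnot("is_multicore" %in% names(records))
  records$core_fate <- "not_applicable"
  if (is.null(tr_det)) return(records)
  stopifnot(inherits(tr_det, "plaque_regions"))
  asg <- attr(records, "assignments")
  mx <- attr(records, "mx_centroids")
  for (i in which(records$is_multicore)) {
    ids <- asg$mx_id[asg$ab_id == records$plaque_id[i]]
    sub <- mx[mx$id %in% ids, , drop = FALSE]
    tr_id <- lookup_label(tr_det, sub$x_px, sub$y_px)
    tr_id <- tr_id[tr_id > 0L]
    records$core_fate[i] <-
      if (length(tr_id) >= 2 && any(table(tr_id) >= 2)) "merged"
      else "separate"
  }
  records
}

#' Classify all plaques of one image
#'
#' Convenience wrapper running [pair_channels()], [classify_new()],
#' [vicinity_classify()], [find_flowers()], [classify_multicore()] and
#' [classify_core_fate()] in order.
#'
#' @param ab_det,mx_det,tr_det `plaque_regions` per channel (`tr_det`
#'   optional).
#' @param radius_um vicinity radius (default 40 um).
#' @param large_threshold_um2 large-plaque threshold (default 300 um^2).
#' @param pre_center_method `"mx_core"` or `"ab_centroid"`, see
#'   [pre_plaque_centers()].
#' @return list with `records` (fully annotated `plaque_records`), `flowers`
#'   membership table, `pre_centers`.
#' @export
classify_image <- function(ab_det, mx_det, tr_det = NULL, radius_um = 40,
                           large_threshold_um2 = 300,
                           pre_center_method = "mx_core") {
  rec <- pair_channels(ab_det, mx_det)
  rec <- classify_new(rec)
  centers <- pre_plaque_centers(rec, method = pre_center_method)
  rec <- vicinity_classify(rec, centers, radius_um)
  fl <- find_flowers(rec, centers, radius_um)
  rec <- classify_multicore(fl$records, large_threshold_um2)
  rec <- classify_core_fate(rec, tr_det)
  list(records = rec, flowers = fl$flowers, pre_centers = centers)
}
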