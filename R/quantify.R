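#' Collect coral patches from annotated retained frames
#'
#' A patch is a coral aggregation within a single frame; its area is the
#' annotated coral-covered area and its abundance the referenced coral
#' count. One annotation row yields at most one patch (aggregations inside
#' a frame are not subdivided). Only retained (non-overlapping) frames may
#' be annotated here; an annotation referencing an excluded or unknown
#' frame is an error.
#'
#' @param annotations Annotation tibble: `frame_id`, `analysed_area_m2`,
#'   `available_substrate_m2`, `coral_covered_m2`, `coral_count`.
#' @param geoframes Geoframe tibble with `retained` flags
#'   (see [exclude_overlaps()]).
#' @return Patch tibble: `patch_id`, `frame_id`, `area_m2`, `coral_count`.
#' @export
collect_patches <- function(annotations, geoframes) {
  stop_not_df(annotations, "annotations")
  stop_not_df(geoframes, "geoframes")
  require_cols(annotations, c("frame_id", "analysed_area_m2",
                              "available_substrate_m2", "coral_covered_m2",
                              "coral_count"), "annotations")
  require_cols(geoframes, c("frame_id", "retained"), "geoframes")
  retained_ids <- geoframes$frame_id[geoframes$retained %in% TRUE]
  bad <- setdiff(annotations$frame_id, retained_ids)
  if (length(bad) > 0) {
    abort(sprintf(
      "Annotation(s) reference excluded or unknown frame(s): %s%s.",
      paste(head(bad, 5), collapse = ", "),
      if (length(bad) > 5) sprintf(" (+%d more)", length(bad) - 5) else ""))
  }
  check_annotation_invariants(annotations)
  with_coral <- annotations[annotations$coral_covered_m2 > 0, , drop = FALSE]
  tibble::tibble(
    patch_id = sprintf("P%05d", seq_len(nrow(with_coral))),
    frame_id = with_coral$frame_id,
    area_m2 = with_coral$coral_covered_m2,
    coral_count = with_coral$coral_count
  )
}

check_annotation_invariants <- function(annotations) {
  bad <- annotations$coral_covered_m2 > annotations$available_substrate_m2 +
    1e-9 |
    annotations$available_substrate_m2 > annotations$analysed_area_m2 + 1e-9
  if (any(bad)) {
    abort(sprintf(
      "Annotation area invariant violated (coral <= available <= analysed) for frame(s): %s.",
      paste(head(annotations$frame_id[bad], 5), collapse = ", ")))
  }
  inc <- annotations$coral_covered_m2 > 0 & annotations$coral_count < 1
  if (any(inc)) {
    abort(sprintf(
      "Coral cover without a coral count for frame(s): %s.",
      paste(head(annotations$frame_id[inc], 5), collapse = ", ")))
  }
  invisible(annotations)
}

#' Detect coral banks as runs of patch-bearing frames
#'
#' Aggregations extending over at least three consecutive retained frames
#' of a transect lane form a coral bank. Adjacency is positional: frames
#' are consecutive in acquisition order within their lane after overlap
#' exclusion; a single coral-free frame interrupts (does not bridge) a run.
#'
#' @param patches Patch tibble from [collect_patches()].
#' @param geoframes Geoframe tibble with `retained` flags.
#' @param min_frames Minimum run length for a bank (default 3).
#' @return Bank tibble: `bank_id`, `site`, `transect`, `n_frames`,
#'   `member_frame_ids` (list column, in order), `depth_min_m`,
#'   `depth_max_m`.
#' @export
detect_banks <- function(patches, geoframes, min_frames = 3) {
  stop_not_df(patches, "patches")
  stop_not_df(geoframes, "geoframes")
  require_cols(geoframes, c("frame_id", "site", "transect", "lane", "y_m",
                            "retained"), "geoframes")
  ret <- geoframes[geoframes$retained %in% TRUE, , drop = FALSE]
  ord_key <- if ("timestamp_s" %in% names(ret)) ret$timestamp_s else
    seq_len(nrow(ret))
  banks <- list()
  for (ln in unique(ret$lane)) {
    rows <- which(ret$lane == ln)
    rows <- rows[order(ord_key[rows])]
    has_patch <- ret$frame_id[rows] %in% patches$frame_id
    r <- rle(has_patch)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values & r$lengths >= min_frames)) {
      idx <- rows[starts[k]:ends[k]]
      banks[[length(banks) + 1]] <- tibble::tibble(
        site = ret$site[idx[1]], transect = ret$transect[idx[1]],
        n_frames = length(idx),
        member_frame_ids = list(ret$frame_id[idx]),
        depth_min_m = min(ret$y_m[idx]), depth_max_m = max(ret$y_m[idx]))
    }
  }
  if (length(banks) == 0) {
    return(tibble::tibble(bank_id = character(), site = character(),
                          transect = character(), n_frames = integer(),
                          member_frame_ids = list(),
                          depth_min_m = numeric(), depth_max_m = numeric()))
  }
  out <- dplyr::bind_rows(banks)
  dplyr::mutate(out, bank_id = sprintf("B%03d", dplyr::row_number()),
                .before = 1)
}

#' Length/width shape metrics of measured corals
#'
#' Each adequately oriented coral contributes one shape value, the ratio of
#' its length to its mid-length width. Corals counted but not measurable
#' (oblique view, hidden) carry no shape and are unaffected here. Shapes
#' above 5 are classified long and thin, below 3 short and thick.
#'
#' @param measurements Tibble with `frame_id`, `length_m`, `width_m` (one
#'   row per measured coral).
#' @return Tibble with the inputs plus `shape` and `shape_class`
#'   (`"long_thin"`, `"intermediate"`, `"short_thick"`).
#' @export
shape_metrics <- function(measurements) {
  stop_not_df(measurements, "measurements")
  require_cols(measurements, c("frame_id", "length_m", "width_m"),
               "measurements")
  bad <- measurements$length_m <= 0 | measurements$width_m <= 0
  if (any(bad)) {
    abort(sprintf("Non-positive coral dimension(s) in frame(s): %s.",
                  paste(unique(head(measurements$frame_id[bad], 5)),
                        collapse = ", ")))
  }
  dplyr::mutate(
    tibble::as_tibble(measurements),
    shape = .data$length_m / .data$width_m,
    shape_class = dplyr::case_when(
      .data$shape > 5 ~ "long_thin",
      .data$shape < 3 ~ "short_thick",
      TRUE ~ "intermediate"))
}
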