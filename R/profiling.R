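#' Aggregate single-cell features to well-level profiles
#'
#' Computes the mean of every feature across all cells within a well,
#' producing one vector representation per well, together with the cell
#' count. If a layout is supplied, wells present in the layout but absent
#' from the cell table (zero imaged cells) are kept as rows flagged
#' `missing = TRUE` with `NA` features — they carry no profile and are
#' excluded from control statistics and enrichment downstream.
#'
#' @param cells cell-level feature table; must carry `plate_id` and
#'   `well_id`; every numeric column that is not an annotation is treated
#'   as a feature.
#' @param layout optional [generate_plate_layout()] table used to annotate
#'   wells and to flag unimaged ones.
#' @return A `well_profiles` data frame: keys, annotations (when a layout
#'   is given), `cell_count`, `missing`, and per-feature well means. The
#'   feature column names are stored in `attr(, "feature_cols")`.
#' @export
aggregate_well <- function(cells, layout = NULL) {
  stopifnot(all(c("plate_id", "well_id") %in% names(cells)))
  fcols <- .feature_cols(cells)
  if (!length(fcols)) stop("no feature columns found in the cell table")
  key <- well_key(cells$plate_id, cells$well_id)
  keys <- unique(key)
  idx <- split(seq_len(nrow(cells)), factor(key, levels = keys))

  prof <- do.call(rbind, lapply(idx, function(i) {
    colMeans(as.matrix(cells[i, fcols, drop = FALSE]))
  }))
  first <- vapply(idx, `[`, integer(1), 1)
  out <- data.frame(
    plate_id = cells$plate_id[first], well_id = cells$well_id[first],
    cell_count = lengths(idx), missing = FALSE,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(prof))
  rownames(out) <- NULL

  ann_cols <- c("role", "compound_id", "concentration_index", "moa_label",
                "coculture_id")
  if (!is.null(layout)) {
    validate_plate_layout(layout)
    lkey <- well_key(layout$plate_id, layout$well_id)
    absent <- !(lkey %in% keys)
    if (any(absent)) {
      blank <- out[rep(NA_integer_, sum(absent)), ]
      blank$plate_id <- layout$plate_id[absent]
      blank$well_id <- layout$well_id[absent]
      blank$cell_count <- 0L
      blank$missing <- TRUE
      out <- rbind(out, blank)
    }
    keep <- intersect(ann_cols, names(layout))
    m <- match(well_key(out$plate_id, out$well_id), lkey)
    for (cl in keep) out[[cl]] <- layout[[cl]][m]
  } else {
    # carry per-well annotations through from the cell table when present
    for (cl in intersect(ann_cols, names(cells)))
      out[[cl]] <- cells[[cl]][first][match(well_key(out$plate_id, out$well_id),
                                            keys)]
  }
  out <- out[order(out$plate_id, out$well_id), ]
  rownames(out) <- NULL
  attr(out, "feature_cols") <- fcols
  class(out) <- c("well_profiles", "data.frame")
  out
}

#' Robust per-plate normalization against negative controls
#'
#' Applies the screening-standard robust transform per plate and feature:
#' `(value - median of negative controls) / MAD of negative controls`,
#' with the median and MAD computed from that plate's DMSO wells only.
#' After normalization every plate's negative-control median is exactly 0
#' per feature.
#'
#' The MAD is the raw median absolute deviation by default (no 1.4826
#' consistency factor), matching the plain formula; set `mad_scale = TRUE`
#' for the normal-consistent version. Features whose control MAD is 0 on a
#' plate carry no robust scale there: they are dropped on that plate
#' (values set `NA`, with a warning); set `mad_epsilon` to floor the MAD
#' instead.
#'
#' @param profiles a [aggregate_well()] result carrying a `role` column.
#' @param layout optional layout used to attach `role` when the profiles
#'   were aggregated without one.
#' @param mad_scale logical; multiply the MAD by 1.4826.
#' @param mad_epsilon optional positive floor for the MAD; overrides the
#'   drop policy.
#' @param min_controls minimum number of non-missing negative-control
#'   wells required per plate (default 2).
#' @return The normalized `well_profiles` frame; dropped (plate, feature)
#'   pairs are recorded in `attr(, "dropped")`.
#' @export
robust_normalize <- function(profiles, layout = NULL, mad_scale = FALSE,
                             mad_epsilon = NULL, min_controls = 2) {
  if (!"role" %in% names(profiles)) {
    if (is.null(layout))
      stop("profiles must carry a 'role' column (aggregate with a layout)")
    m <- match(well_key(profiles$plate_id, profiles$well_id),
               well_key(layout$plate_id, layout$well_id))
    profiles$role <- layout$role[m]
  }
  if (!"missing" %in% names(profiles)) profiles$missing <- FALSE
  fcols <- attr(profiles, "feature_cols")
  if (is.null(fcols)) fcols <- .feature_cols(profiles)
  const <- if (mad_scale) 1.4826 else 1
  out <- profiles
  dropped <- data.frame(plate_id = character(0), feature = character(0))

  for (p in unique(profiles$plate_id)) {
    on_plate <- profiles$plate_id == p
    ctrl <- on_plate & profiles$role == "negative_control" & !profiles$missing
    if (sum(ctrl) < min_controls)
      stop("plate ", p, " has ", sum(ctrl), " usable negative-control wells; ",
           min_controls, " required")
    for (fc in fcols) {
      x <- profiles[[fc]][ctrl]
      med <- stats::median(x)
      mad <- stats::median(abs(x - med)) * const
      if (mad == 0) {
        if (!is.null(mad_epsilon)) {
          mad <- mad_epsilon
        } else {
          dropped <- rbind(dropped, data.frame(plate_id = p, feature = fc))
          out[[fc]][on_plate] <- NA_real_
          next
        }
      }
      out[[fc]][on_plate] <- (profiles[[fc]][on_plate] - med) / mad
    }
  }
  if (nrow(dropped))
    warning("features with zero control MAD dropped on some plates: ",
            paste(unique(dropped$feature), collapse = ", "))
  attr(out, "feature_cols") <- fcols
  attr(out, "dropped") <- dropped
  out
}

#' Z-prime plate-quality factor
#'
#' `Z' = 1 - 3 * (sd_pos + sd_neg) / |mean_pos - mean_neg|`, the standard
#' separation statistic between positive and negative control readouts;
#' values above 0.5 indicate adequate assay separation.
#'
#' @param positive_values,negative_values control readouts (>= 2 each).
#' @return The Z' value (at most 1). Equal arm means give `-Inf` with a
#'   warning.
#' @export
zprime <- function(positive_values, negative_values) {
  stopifnot(length(positive_values) >= 2, length(negative_values) >= 2)
  dmu <- abs(mean(positive_values) - mean(negative_values))
  if (dmu == 0) {
    warning("control means are equal; Z' is undefined (-Inf)")
    return(-Inf)
  }
  1 - 3 * (stats::sd(positive_values) + stats::sd(negative_values)) / dmu
}

#' Per-plate Z-prime quality report
#'
#' Evaluates plate quality using the per-well cancer-cell count as the
#' assay readout (positive controls kill cells, so the count separates the
#' arms), as is common when a cytotoxic positive control is used.
#'
#' @param profiles [aggregate_well()] output with `role` and `cell_count`.
#' @param threshold pass threshold (default 0.5).
#' @param readout column to use as the readout (default `"cell_count"`).
#' @return Data frame: `plate_id`, `zprime`, `pass`.
#' @export
plate_quality <- function(profiles, threshold = 0.5, readout = "cell_count") {
  stopifnot(all(c("role", readout) %in% names(profiles)))
  plates <- unique(profiles$plate_id)
  z <- vapply(plates, function(p) {
    sel <- profiles$plate_id == p & !profiles$missing
    pos <- profiles[[readout]][sel & profiles$role == "positive_control"]
    neg <- profiles[[readout]][sel & profiles$role == "negative_control"]
    zprime(pos, neg)
  }, numeric(1))
  data.frame(plate_id = plates, zprime = z, pass = z > threshold,
             row.names = NULL)
}
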