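#' Generate a synthetic plate layout
#'
#' Builds the annotation table for one assay plate of a co-culture drug
#' screen: every compound is placed at every concentration exactly once, and
#' a fixed number of negative (DMSO, vehicle) and positive (benzethonium
#' chloride, cell-killing) control wells are interspersed. Well positions
#' are drawn at random but are a pure function of `seed`.
#'
#' @param n_compounds number of treated compounds on the plate.
#' @param n_conc number of concentrations per compound (concentration_index
#'   runs 1..`n_conc`, 1 = lowest dose).
#' @param moa_assignment named character vector mapping every compound id to
#'   its mechanism-of-action label; its names define the compound set.
#' @param controls_per_role number of wells for each control role
#'   (default 12 DMSO + 12 BzCl, the usual 384-well QC design).
#' @param plate_id plate identifier.
#' @param coculture_id co-culture combination label (cancer line +
#'   fibroblast line, e.g. `"KB"`).
#' @param plate_rows,plate_cols physical plate dimensions (default 16 x 24 =
#'   384 wells).
#' @param seed integer seed; the layout is deterministic given the seed.
#' @return A `plate_layout` data frame with one row per annotated well and
#'   columns `plate_id`, `well_id`, `row`, `col`, `role`
#'   (`negative_control` / `positive_control` / `treated`), `compound_id`,
#'   `concentration_index`, `moa_label`, `coculture_id`.
#' @examples
#' moa <- setNames(rep(c("PARP", "MEK1/2"), 2), paste0("C", 1:4))
#' lay <- generate_plate_layout(4, 5, moa, seed = 1)
#' table(lay$role)
#' @export
generate_plate_layout <- function(n_compounds, n_conc = 5, moa_assignment,
                                  controls_per_role = 12,
                                  plate_id = "P1", coculture_id = "KB",
                                  plate_rows = 16, plate_cols = 24,
                                  seed = 1) {
  stopifnot(.is_count(n_compounds), .is_count(n_conc), n_conc >= 1,
            .is_count(controls_per_role), controls_per_role >= 0)
  compounds <- names(moa_assignment)
  if (is.null(compounds) || anyNA(moa_assignment))
    stop("'moa_assignment' must be a named character vector with no NA")
  if (length(compounds) < n_compounds)
    stop("'moa_assignment' must cover all ", n_compounds, " compounds")
  compounds <- compounds[seq_len(n_compounds)]

  n_wells <- n_compounds * n_conc + 2L * controls_per_role
  capacity <- plate_rows * plate_cols
  if (n_wells > capacity)
    stop("plate capacity exceeded: ", n_wells, " wells requested but the plate has ",
         capacity, " (", plate_rows, " x ", plate_cols, ")")

  roles <- c(rep("negative_control", controls_per_role),
             rep("positive_control", controls_per_role),
             rep("treated", n_compounds * n_conc))
  compound <- c(rep("DMSO", controls_per_role),
                rep("BzCl", controls_per_role),
                rep(compounds, each = n_conc))
  conc <- c(rep(NA_integer_, 2L * controls_per_role),
            rep(seq_len(n_conc), times = n_compounds))
  moa <- c(rep(NA_character_, 2L * controls_per_role),
           rep(unname(moa_assignment[compounds]), each = n_conc))

  withr::with_seed(seed, {
    pos <- sample.int(capacity, n_wells)
  })
  r <- (pos - 1L) %/% plate_cols + 1L
  c <- (pos - 1L) %% plate_cols + 1L
  wid <- sprintf("%s%02d", LETTERS[(r - 1L) %% 26L + 1L], c)

  out <- data.frame(
    plate_id = plate_id, well_id = wid, row = r, col = c,
    role = roles, compound_id = compound,
    concentration_index = conc, moa_label = moa,
    coculture_id = coculture_id,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$row, out$col), ]
  rownames(out) <- NULL
  class(out) <- c("plate_layout", "data.frame")
  out
}

#' Generate a multi-plate screen layout
#'
#' Partitions a compound library across several plates (each compound is
#' screened once, at all concentrations, on exactly one plate) and attaches
#' identical control sets to each plate.
#'
#' @param n_plates number of plates.
#' @param n_compounds_per_plate treated compounds per plate.
#' @param n_moa number of mechanism-of-action classes; compounds are
#'   assigned round-robin so every class has compounds on every plate.
#' @param n_conc,controls_per_role,coculture_id,seed see
#'   [generate_plate_layout()].
#' @return A `plate_layout` data frame spanning all plates.
#' @export
generate_screen_layout <- function(n_plates = 2, n_compounds_per_plate = 20,
                                   n_moa = 4, n_conc = 5,
                                   controls_per_role = 12,
                                   coculture_id = "KB", seed = 1) {
  stopifnot(.is_count(n_plates), n_plates >= 1, .is_count(n_moa), n_moa >= 1)
  n_total <- n_plates * n_compounds_per_plate
  compounds <- sprintf("C%03d", seq_len(n_total))
  moas <- sprintf("MOA_%02d", seq_len(n_moa))
  assignment <- setNames(rep(moas, length.out = n_total), compounds)

  plates <- lapply(seq_len(n_plates), function(p) {
    idx <- seq.int((p - 1L) * n_compounds_per_plate + 1L,
                   p * n_compounds_per_plate)
    generate_plate_layout(
      n_compounds_per_plate, n_conc, assignment[idx],
      controls_per_role = controls_per_role,
      plate_id = sprintf("P%02d", p), coculture_id = coculture_id,
      seed = derive_seed(seed, sprintf("layout/P%02d", p))
    )
  })
  out <- do.call(rbind, plates)
  rownames(out) <- NULL
  class(out) <- c("plate_layout", "data.frame")
  out
}

#' Validate a plate layout
#'
#' Checks the structural invariants of a layout table: required columns,
#' unique well coordinates within a plate, complete treated-well annotation,
#' and concentration indices within range.
#'
#' @param layout a `plate_layout` data frame (or plain data frame with the
#'   same columns).
#' @return `layout`, invisibly; errors describe the first violation found.
#' @export
validate_plate_layout <- function(layout) {
  req <- c("plate_id", "well_id", "role", "compound_id",
           "concentration_index", "moa_label")
  miss <- setdiff(req, names(layout))
  if (length(miss))
    stop("layout is missing required columns: ", paste(miss, collapse = ", "))
  key <- well_key(layout$plate_id, layout$well_id)
  if (anyDuplicated(key))
    stop("well coordinates are not unique within plates: ",
         key[duplicated(key)][1])
  tr <- layout[layout$role == "treated", ]
  if (nrow(tr)) {
    if (anyNA(tr$compound_id) || anyNA(tr$moa_label))
      stop("every treated well must have compound_id and moa_label")
    if (anyNA(tr$concentration_index) || any(tr$concentration_index < 1))
      stop("every treated well must have concentration_index >= 1")
  }
  invisible(layout)
}
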