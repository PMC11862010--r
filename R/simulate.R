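#' Mechanism-of-action effect model for synthetic screens
#'
#' Defines how treatment shifts cell-level morphological features in the
#' synthetic screen: each MOA class gets one direction in feature space
#' (drawn once from a seeded standard normal and scaled to a given L2
#' norm), modulated by a non-negative concentration curve, on top of
#' per-plate batch offsets and per-cell Gaussian noise. Negative-control
#' (DMSO) wells receive zero effect by construction.
#'
#' @param moa_labels character vector of MOA class labels.
#' @param n_features feature-space dimension (>= 2).
#' @param effect_size L2 norm of the feature shift per MOA at concentration
#'   multiplier 1; scalar or one value per MOA. 0 gives a null screen.
#' @param conc_curve non-negative multiplier per concentration index
#'   (index 1 = lowest dose). The default rises with dose, mirroring the
#'   expectation that low doses induce subtle or no morphological change.
#' @param cell_noise_sd standard deviation of per-cell feature noise.
#' @param plate_sd standard deviation of per-plate, per-feature batch
#'   offsets (motivates per-plate normalization downstream).
#' @param seed integer seed fixing the effect directions.
#' @return An `effect_model` list with elements `effects` (matrix, one row
#'   per MOA), `conc_curve`, `cell_noise_sd`, `plate_sd`, `seed`.
#' @export
effect_model <- function(moa_labels, n_features = 8, effect_size = 0,
                         conc_curve = c(0.1, 0.3, 0.6, 0.85, 1),
                         cell_noise_sd = 1, plate_sd = 0.25, seed = 1) {
  stopifnot(.is_count(n_features), n_features >= 2,
            is.numeric(conc_curve), all(is.finite(conc_curve)),
            cell_noise_sd >= 0, plate_sd >= 0)
  if (any(conc_curve < 0))
    stop("concentration multipliers must be non-negative")
  moa_labels <- unique(as.character(moa_labels))
  effect_size <- rep_len(effect_size, length(moa_labels))

  eff <- withr::with_seed(seed, {
    m <- matrix(stats::rnorm(length(moa_labels) * n_features),
                nrow = length(moa_labels))
    nrm <- sqrt(rowSums(m^2))
    m / ifelse(nrm > 0, nrm, 1) * effect_size
  })
  rownames(eff) <- moa_labels
  colnames(eff) <- sprintf("f_%d", seq_len(n_features) - 1L)
  structure(
    list(effects = eff, conc_curve = conc_curve,
         cell_noise_sd = cell_noise_sd, plate_sd = plate_sd, seed = seed),
    class = "effect_model"
  )
}

#' Simulate a single-cell feature table for a plate layout
#'
#' Statistical stand-in for the screen's segmented-cell feature data: for
#' every well the cell count is drawn (controlled seeding, ~10% CV; the
#' cytotoxic positive control kills most cells), and each cell's feature
#' vector is `MOA effect x concentration multiplier + plate offset +
#' N(0, cell_noise_sd)`. DMSO wells get the plate offset and noise only.
#'
#' @param layout a [generate_plate_layout()]-style layout.
#' @param effects an [effect_model()].
#' @param cells_per_well list with `mean` (expected cells in a healthy
#'   well), `cv` (coefficient of variation of seeding), and
#'   `positive_survival` (surviving fraction in positive-control wells).
#' @param seed integer master seed; the table is deterministic given it.
#' @return Data frame with one row per cell: layout annotations, `cell_id`,
#'   and feature columns `f_0 ... f_{d-1}`.
#' @export
simulate_feature_table <- function(layout, effects,
                                   cells_per_well = list(
                                     mean = 50, cv = 0.1,
                                     positive_survival = 0.05),
                                   seed = 1) {
  validate_plate_layout(layout)
  stopifnot(inherits(effects, "effect_model"))
  if (!"coculture_id" %in% names(layout)) layout$coculture_id <- NA_character_
  d <- ncol(effects$effects)
  fn <- colnames(effects$effects)
  plates <- unique(layout$plate_id)

  withr::with_seed(seed, {
    plate_off <- matrix(stats::rnorm(length(plates) * d, sd = effects$plate_sd),
                        nrow = length(plates),
                        dimnames = list(plates, fn))
    per_well <- lapply(seq_len(nrow(layout)), function(i) {
      w <- layout[i, ]
      mu_n <- if (identical(w$role, "positive_control"))
        cells_per_well$mean * cells_per_well$positive_survival
      else cells_per_well$mean
      n <- max(0L, as.integer(round(stats::rnorm(1, mu_n, cells_per_well$cv * mu_n))))
      if (n == 0L) return(NULL)
      shift <- numeric(d)
      if (identical(w$role, "treated")) {
        k <- min(w$concentration_index, length(effects$conc_curve))
        shift <- effects$effects[w$moa_label, ] * effects$conc_curve[k]
      }
      feats <- matrix(stats::rnorm(n * d, sd = effects$cell_noise_sd),
                      nrow = n, byrow = TRUE)
      feats <- sweep(feats, 2, shift + plate_off[w$plate_id, ], "+")
      colnames(feats) <- fn
      cbind(
        w[rep(1L, n), c("plate_id", "well_id", "role", "compound_id",
                        "concentration_index", "moa_label", "coculture_id"),
          drop = FALSE],
        data.frame(cell_id = seq_len(n)),
        as.data.frame(feats)
      )
    })
  })
  out <- do.call(rbind, per_well)
  rownames(out) <- NULL
  out
}
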