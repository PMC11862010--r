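#' @keywords internal
"_PACKAGE"

# Annotation columns shared by layouts, cell tables and well profiles.
# Everything else numeric is treated as a feature column.
.annotation_cols <- c(
  "plate_id", "well_id", "row", "col", "role", "compound_id",
  "concentration_index", "moa_label", "coculture_id", "cell_id",
  "cell_count", "missing", "well_key"
)

#' Well key
#'
#' Wells are identified across plates by the string `"<plate_id>:<well_id>"`.
#'
#' @param plate_id,well_id character vectors of equal length.
#' @return Character vector of keys.
#' @export
well_key <- function(plate_id, well_id) paste(plate_id, well_id, sep = ":")

# Deterministic 32-bit string hash (polynomial rolling hash mod a Mersenne
# prime). Used to derive per-query child seeds from one master seed so that
# permutation p-values are reproducible per well regardless of scan order.
.hash32 <- function(x) {
  h <- 0
  for (b in utf8ToInt(x)) h <- (h * 31 + b) %% 2147483647
  h
}

#' Derive a child seed from a master seed and a string key
#'
#' All randomness in the package flows from one master seed; stage- and
#' query-level seeds are derived deterministically so results do not depend
#' on evaluation order.
#'
#' @param seed master seed (integer).
#' @param key character scalar naming the consumer (e.g. a well key).
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(key))
  as.integer((abs(seed) + .hash32(key)) %% 2147483647)
}

.feature_cols <- function(df) {
  cand <- setdiff(names(df), .annotation_cols)
  cand[vapply(df[cand], is.numeric, logical(1))]
}

.is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x == round(x)

# Hex digest of a string (two independent rolling hashes); used for the run
# manifest so a config change is visible as a different hash.
.hexdigest <- function(x) {
  h1 <- 0; h2 <- 0
  for (b in utf8ToInt(x)) {
    h1 <- (h1 * 31 + b) %% 2147483647
    h2 <- (h2 * 131 + b) %% 2147483629
  }
  sprintf("%08x%08x", h1, h2)
}
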