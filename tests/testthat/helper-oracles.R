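# Independent oracles for the enrichment statistic, written as plain loops
# so they share no code path with the package implementation.

# brute-force prefix-max running sum, kept exact on the integer scale
# (+n_miss per hit, -n_hit per miss) so permutation ties are unambiguous
oracle_es <- function(labels, category) {
  nh <- sum(labels == category)
  nm <- sum(labels != category)
  running <- 0
  best <- -Inf
  for (l in labels) {
    running <- running + (if (l == category) nm else -nh)
    if (running > best) best <- running
  }
  best / (nh * nm)
}

# exact permutation p by enumerating every placement of the shuffled hits
# (uniform label shuffles weight each hit-position subset equally)
oracle_p_exact <- function(labels, category, fix_first = TRUE) {
  obs <- oracle_es(labels, category)
  n <- length(labels)
  hit <- labels == category
  free <- if (fix_first) 2:n else 1:n
  k <- sum(hit[free])
  placements <- if (k == 0 || k == length(free)) {
    matrix(which(hit[free]), ncol = 1)
  } else {
    utils::combn(length(free), k)
  }
  exceed <- 0
  total <- ncol(placements)
  for (j in seq_len(total)) {
    lab <- rep("miss", n)
    if (fix_first && hit[1]) lab[1] <- category
    lab[free[placements[, j]]] <- category
    es <- oracle_es(lab, category)
    if (es > obs) exceed <- exceed + 1
  }
  exceed / total
}

# all label sequences of length n over {A, B} with >= 1 A and >= 1 B
all_two_label_sequences <- function(n) {
  out <- list()
  for (i in 1:(2^n - 2)) {
    bits <- as.integer(intToBits(i))[1:n]
    out[[length(out) + 1]] <- ifelse(bits == 1, "A", "B")
  }
  out
}

# small well-profile frame for ranking tests: one row per well, explicit
# feature values, all treated unless stated
make_profiles <- function(features, plate_id = "P1", role = "treated",
                          moa = NULL, compound = NULL, conc = NULL) {
  n <- nrow(features)
  df <- data.frame(
    plate_id = plate_id, well_id = sprintf("W%02d", seq_len(n)),
    cell_count = 10L, missing = FALSE,
    role = rep_len(role, n),
    compound_id = if (is.null(compound)) sprintf("C%02d", seq_len(n)) else compound,
    concentration_index = if (is.null(conc)) 1L else conc,
    moa_label = if (is.null(moa)) "M1" else moa,
    coculture_id = "KB",
    stringsAsFactors = FALSE
  )
  colnames(features) <- sprintf("f_%d", seq_len(ncol(features)) - 1)
  out <- cbind(df, as.data.frame(features))
  attr(out, "feature_cols") <- colnames(features)
  class(out) <- c("well_profiles", "data.frame")
  out
}
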