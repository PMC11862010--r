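# Mechanism-of-action enrichment over correlation-ranked well profiles.
#
# For a query well, all eligible wells are ranked by the correlation of
# their normalized morphological profiles with the query's. A running sum
# walks down the ranking, stepping up at wells sharing the query's MOA and
# down otherwise (unweighted Kolmogorov-Smirnov increments +1/N_hit,
# -1/N_miss, so the curve ends at exactly 0 and the enrichment score — the
# curve's maximum — lives in [0, 1]). Significance comes from shuffling
# the MOA labels below rank 1 and recomputing the score; the p-value is
# the strictly-greater proportion of shuffled scores.

#' Rank wells by profile correlation with a query well
#'
#' @param query_key well key (`"plate:well"`) of the query; must be among
#'   the eligible wells unless explicitly excluded.
#' @param profiles normalized [well_profiles][aggregate_well()] frame with
#'   `role` and `moa_label` columns.
#' @param metric `"pearson"` or `"spearman"`.
#' @param exclusions character vector of well keys to remove before
#'   ranking (e.g. sibling concentrations of the query compound).
#' @param include_controls logical; by default only treated wells enter
#'   the ranked list.
#' @return A `ranked_list` data frame sorted by decreasing correlation
#'   (stable; ties broken by well key; the query well, correlation 1 with
#'   itself, is ranked first): `rank`, `well_key`, `correlation`,
#'   `moa_label`, `compound_id`, `concentration_index`. The query key and
#'   MOA are attached as attributes.
#' @details Feature columns containing `NA` among the eligible wells
#'   (e.g. dropped on one plate by the zero-MAD policy) are excluded from
#'   the correlation with a message; wells with zero profile variance are
#'   dropped with a warning (their correlation is undefined).
#' @export
correlation_ranking <- function(query_key, profiles,
                                metric = c("pearson", "spearman"),
                                exclusions = character(0),
                                include_controls = FALSE) {
  metric <- match.arg(metric)
  stopifnot(all(c("moa_label") %in% names(profiles)))
  fcols <- attr(profiles, "feature_cols")
  if (is.null(fcols)) fcols <- .feature_cols(profiles)
  key <- well_key(profiles$plate_id, profiles$well_id)

  qrow <- match(query_key, key)
  if (is.na(qrow)) stop("query well ", query_key, " not found in profiles")

  elig <- !(key %in% exclusions)
  if ("missing" %in% names(profiles)) elig <- elig & !profiles$missing
  if (!include_controls && "role" %in% names(profiles))
    elig <- elig & profiles$role == "treated"
  if (sum(elig) < 2) stop("fewer than 2 eligible wells after exclusions")

  use_rows <- union(qrow, which(elig))
  Xall <- as.matrix(profiles[use_rows, fcols, drop = FALSE])
  bad <- colSums(is.na(Xall)) > 0
  if (any(bad)) {
    message("excluding ", sum(bad), " feature(s) with NA among eligible wells")
    fcols <- fcols[!bad]
  }
  if (length(fcols) < 2) stop("fewer than 2 usable features for correlation")

  elig_idx <- which(elig)
  X <- as.matrix(profiles[elig_idx, fcols, drop = FALSE])
  qvec <- as.numeric(profiles[qrow, fcols])
  if (metric == "spearman") {
    X <- t(apply(X, 1, rank))
    qvec <- rank(qvec)
  }
  if (stats::sd(qvec) == 0)
    stop("query profile has zero variance; correlation undefined")
  v <- apply(X, 1, stats::sd)
  if (any(v == 0)) {
    keep <- v > 0 | elig_idx == qrow
    warning(sum(!keep), " well(s) with zero profile variance dropped")
    X <- X[keep, , drop = FALSE]
    elig_idx <- elig_idx[keep]
  }
  ekey <- key[elig_idx]

  corr <- as.numeric(stats::cor(t(X), qvec))
  qi <- match(query_key, ekey)        # NA when the query was excluded
  ord <- if (is.na(qi)) {
    order(-corr, ekey)
  } else {
    corr[qi] <- 1                     # exact self-correlation
    others <- setdiff(seq_along(ekey), qi)
    c(qi, others[order(-corr[others], ekey[others])])
  }

  src <- profiles[elig_idx[ord], , drop = FALSE]
  out <- data.frame(
    rank = seq_along(ord), well_key = ekey[ord], correlation = corr[ord],
    moa_label = src$moa_label, stringsAsFactors = FALSE
  )
  for (cl in c("compound_id", "concentration_index"))
    if (cl %in% names(src)) out[[cl]] <- src[[cl]]
  attr(out, "query_key") <- query_key
  attr(out, "query_moa") <- profiles$moa_label[match(query_key, key)]
  class(out) <- c("ranked_list", "data.frame")
  out
}

.ranked_labels <- function(ranked) {
  if (is.data.frame(ranked)) as.character(ranked$moa_label)
  else as.character(ranked)
}

#' Running MOA enrichment score
#'
#' Walks the ranked list computing a running sum with unweighted KS
#' increments: `+1/N_hit` at wells whose MOA matches `category`,
#' `-1/N_miss` otherwise. The increments sum to zero, so the curve always
#' ends at 0; the enrichment score is the maximum of the running sum and
#' lies in `[0, 1]`.
#'
#' @param ranked a [correlation_ranking()] result, or simply a character
#'   vector of MOA labels in rank order.
#' @param category the MOA label scored as a "hit".
#' @return List with `es` (the maximum of the running sum) and
#'   `running_curve` (one value per rank).
#' @export
running_enrichment_score <- function(ranked, category) {
  labels <- .ranked_labels(ranked)
  if (!length(labels)) stop("ranked list is empty")
  hit <- labels == category
  nh <- sum(hit); nm <- sum(!hit)
  if (nh == 0) stop("category '", category, "' absent from the ranked list")
  if (nm == 0) stop("category '", category, "' is universal; score undefined")
  # integer increments (+nm per hit, -nh per miss) keep the running sum
  # exact, so permutation ties compare exactly; divide once at the end
  curve <- cumsum(ifelse(hit, nm, -nh)) / (nh * nm)
  list(es = max(curve), running_curve = curve)
}

# es for hit positions on the integer scale (hit +nm, miss -nh); exact, so
# strict-greater tie handling in the permutation test is unambiguous.
.es_from_hits <- function(hit_pos, N, nh, nm) {
  inc <- rep.int(-nh, N)
  inc[hit_pos] <- nm
  max(cumsum(inc))
}

#' Permutation p-value for an enrichment score
#'
#' Shuffles the MOA labels uniformly at random `n_perm` times — keeping
#' the rank-1 label fixed when `fix_first` (the first sample is the query
#' itself) — recomputes the enrichment score for each shuffle, and returns
#' the proportion of shuffled scores strictly greater than the observed
#' one. No add-one smoothing by default, so `p = 0` is attainable; set
#' `smooth = TRUE` for the conservative `(k + 1) / (B + 1)` estimate.
#'
#' @inheritParams running_enrichment_score
#' @param n_perm number of shuffles (>= 1).
#' @param fix_first keep the rank-1 label out of the shuffle.
#' @param seed integer seed; the p-value is deterministic given it.
#' @param smooth use `(k + 1) / (B + 1)` instead of `k / B`.
#' @return The p-value in `[0, 1]`, with attributes `es_obs` and `n_perm`.
#' @export
permutation_pvalue <- function(ranked, category, n_perm = 1000,
                               fix_first = TRUE, seed = 1, smooth = FALSE) {
  stopifnot(.is_count(n_perm), n_perm >= 1)
  labels <- .ranked_labels(ranked)
  obs <- running_enrichment_score(labels, category)$es
  hit <- labels == category
  N <- length(labels)
  nh <- sum(hit); nm <- N - nh
  obs_int <- .es_from_hits(which(hit), N, nh, nm)   # exact integer scale

  first_hit <- fix_first && hit[1]
  n_free <- if (fix_first) N - 1L else N
  n_free_hits <- nh - (if (fix_first) hit[1] else 0)
  offset <- if (fix_first) 1L else 0L

  k <- withr::with_seed(seed, {
    exceed <- 0L
    fixed_pos <- if (first_hit) 1L else integer(0)
    for (b in seq_len(n_perm)) {
      pos <- offset + sample.int(n_free, n_free_hits)
      es_b <- .es_from_hits(c(fixed_pos, pos), N, nh, nm)
      if (es_b > obs_int) exceed <- exceed + 1L
    }
    exceed
  })
  p <- if (smooth) (k + 1) / (n_perm + 1) else k / n_perm
  structure(p, es_obs = obs, n_perm = n_perm)
}

#' Scan every treated well for enrichment of its own MOA
#'
#' For each treated query well: rank all eligible treated wells by profile
#' correlation with the query, score the query's own MOA with the running
#' sum, and attach a permutation p-value. With `leave_compound_out`, all
#' other wells of the query's compound (its sibling concentrations) are
#' removed from the ranked list before scoring, so enrichment cannot be
#' driven by the compound matching itself.
#'
#' @param profiles normalized well profiles (see [robust_normalize()]).
#' @param layout optional layout to (re-)attach annotations.
#' @param alpha significance level for the `enriched` flag.
#' @param n_perm permutations per query.
#' @param leave_compound_out exclude the query compound's other wells.
#' @param metric correlation metric, `"pearson"` (default) or
#'   `"spearman"`.
#' @param seed master seed; each query gets a child seed derived from
#'   `(seed, well key)` so results do not depend on scan order.
#' @return A `moa_enrichment` object: `results` data frame (one row per
#'   treated query well: keys, compound, concentration, `moa`, `es`,
#'   `p_value`, `enriched`, `computable`, `n_perm`, `seed`) plus the scan
#'   parameters. Queries whose MOA has fewer than 2 eligible wells (or no
#'   non-match) are flagged `computable = FALSE`.
#' @export
moa_enrichment_scan <- function(profiles, layout = NULL, alpha = 0.05,
                                n_perm = 1000, leave_compound_out = FALSE,
                                metric = "pearson", seed = 1) {
  stopifnot(alpha > 0, alpha < 1, .is_count(n_perm), n_perm >= 1)
  if (!is.null(layout)) {
    m <- match(well_key(profiles$plate_id, profiles$well_id),
               well_key(layout$plate_id, layout$well_id))
    for (cl in c("role", "compound_id", "concentration_index", "moa_label",
                 "coculture_id"))
      if (cl %in% names(layout)) profiles[[cl]] <- layout[[cl]][m]
  }
  need <- c("role", "compound_id", "moa_label")
  if (!all(need %in% names(profiles)))
    stop("profiles must carry role, compound_id and moa_label ",
         "(supply a layout)")
  if (!"missing" %in% names(profiles)) profiles$missing <- FALSE
  key <- well_key(profiles$plate_id, profiles$well_id)
  queries <- which(profiles$role == "treated" & !profiles$missing &
                     !is.na(profiles$moa_label))

  rows <- lapply(queries, function(i) {
    qkey <- key[i]
    excl <- character(0)
    if (leave_compound_out) {
      sib <- profiles$role == "treated" &
        profiles$compound_id == profiles$compound_id[i] & key != qkey
      excl <- key[sib]
    }
    res <- data.frame(
      well_key = qkey, plate_id = profiles$plate_id[i],
      well_id = profiles$well_id[i],
      compound_id = profiles$compound_id[i],
      concentration_index = profiles$concentration_index[i],
      moa = profiles$moa_label[i],
      coculture_id = if ("coculture_id" %in% names(profiles))
        profiles$coculture_id[i] else NA_character_,
      es = NA_real_, p_value = NA_real_, enriched = NA,
      computable = FALSE, n_perm = n_perm,
      seed = derive_seed(seed, qkey),
      stringsAsFactors = FALSE
    )
    ranked <- correlation_ranking(qkey, profiles, metric = metric,
                                  exclusions = excl)
    labels <- ranked$moa_label
    nh <- sum(labels == res$moa)
    if (nh < 2 || nh >= length(labels)) return(res)   # not computable
    sc <- running_enrichment_score(labels, res$moa)
    p <- permutation_pvalue(labels, res$moa, n_perm = n_perm,
                            fix_first = TRUE, seed = res$seed)
    res$es <- sc$es
    res$p_value <- as.numeric(p)
    res$enriched <- res$p_value < alpha
    res$computable <- TRUE
    res
  })
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  structure(
    list(results = results, alpha = alpha, n_perm = n_perm, metric = metric,
         leave_compound_out = leave_compound_out, seed = seed,
         profiles = profiles),
    class = "moa_enrichment"
  )
}

#' Percent-enriched summary per MOA
#'
#' `percent_enriched = 100 * n_enriched / n_total` per group, where
#' `n_total` counts the computable query profiles of that MOA (per
#' co-culture by default) and `n_enriched` those reaching `p < alpha`.
#'
#' @param results a [moa_enrichment_scan()] object or its `results` frame.
#' @param by grouping columns (default co-culture and MOA).
#' @return A `moa_summary` data frame: grouping columns, `n_enriched`,
#'   `n_total`, `percent_enriched`. Groups with zero total are omitted.
#' @export
percent_enriched <- function(results, by = c("coculture_id", "moa")) {
  df <- if (inherits(results, "moa_enrichment")) results$results else results
  if (!nrow(df)) stop("no enrichment results to summarise")
  df <- df[df$computable, , drop = FALSE]
  by <- intersect(by, names(df))
  g <- interaction(df[by], drop = TRUE, sep = "\r")
  agg <- do.call(rbind, lapply(split(df, g), function(d) {
    cbind(d[1, by, drop = FALSE],
          data.frame(n_enriched = sum(d$enriched),
                     n_total = nrow(d),
                     percent_enriched = 100 * mean(d$enriched)))
  }))
  agg <- agg[order(agg[[by[1]]], if (length(by) > 1) agg[[by[2]]]), ,
             drop = FALSE]
  rownames(agg) <- NULL
  class(agg) <- c("moa_summary", "data.frame")
  agg
}

#' @export
print.moa_enrichment <- function(x, ...) {
  r <- x$results
  cat("MOA enrichment scan (", x$metric, " correlation, ",
      x$n_perm, " permutations",
      if (x$leave_compound_out) ", leave-compound-out", ")\n", sep = "")
  cat("  queries: ", nrow(r), " (", sum(!r$computable), " not computable)\n",
      sep = "")
  ok <- r[r$computable, ]
  if (nrow(ok))
    cat("  enriched at alpha = ", x$alpha, ": ", sum(ok$enriched), "/",
        nrow(ok), " (", round(100 * mean(ok$enriched), 1), "%)\n", sep = "")
  invisible(x)
}

#' @export
summary.moa_enrichment <- function(object, ...) {
  percent_enriched(object)
}

#' Plot the running enrichment curve for one query well
#'
#' @param x a [moa_enrichment_scan()] object.
#' @param well_key query well key; defaults to the computable query with
#'   the largest enrichment score.
#' @param ... passed to [graphics::plot()].
#' @export
plot.moa_enrichment <- function(x, well_key = NULL, ...) {
  r <- x$results[x$results$computable, ]
  if (!nrow(r)) stop("no computable queries to plot")
  if (is.null(well_key)) well_key <- r$well_key[which.max(r$es)]
  row <- r[r$well_key == well_key, ]
  if (!nrow(row)) stop("unknown query well ", well_key)
  excl <- character(0)
  if (x$leave_compound_out) {
    key <- with(x$profiles, paste(plate_id, well_id, sep = ":"))
    sib <- x$profiles$role == "treated" &
      x$profiles$compound_id == row$compound_id & key != well_key
    excl <- key[sib]
  }
  ranked <- correlation_ranking(well_key, x$profiles, metric = x$metric,
                                exclusions = excl)
  sc <- running_enrichment_score(ranked, row$moa)
  graphics::plot(seq_along(sc$running_curve), sc$running_curve, type = "l",
                 xlab = "rank", ylab = "running enrichment",
                 main = sprintf("%s  MOA %s  es = %.2f  p = %.3g",
                                well_key, row$moa, row$es, row$p_value), ...)
  graphics::abline(h = 0, lty = 3)
  hits <- which(ranked$moa_label == row$moa)
  graphics::rug(hits)
  invisible(sc)
}
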