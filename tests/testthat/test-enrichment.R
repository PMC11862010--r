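test_that("correlation ranking puts self first, negation last, and matches a hand oracle", {
  withr::with_seed(61, {
    feats <- matrix(rnorm(5 * 6), 5)
  })
  feats[2, ] <- -feats[1, ]          # exact negation of the query
  prof <- make_profiles(feats, moa = c("M1", "M2", "M1", "M2", "M1"))
  q <- "P1:W01"
  rk <- correlation_ranking(q, prof)
  expect_equal(rk$well_key[1], q)
  expect_equal(rk$correlation[1], 1)
  expect_equal(rk$well_key[5], "P1:W02")
  expect_equal(rk$correlation[5], -1)
  expect_true(all(diff(rk$correlation) <= 1e-12))
  # brute-force Pearson via covariance / sd products
  for (i in 2:5) {
    x <- feats[1, ]; y <- feats[match(rk$well_key[i], sprintf("P1:W%02d", 1:5)), ]
    r_hand <- sum((x - mean(x)) * (y - mean(y))) / (length(x) - 1) / (sd(x) * sd(y))
    expect_equal(rk$correlation[i], r_hand, tolerance = 1e-12)
  }
  # exclusions drop wells from the ranked list
  rk2 <- correlation_ranking(q, prof, exclusions = "P1:W03")
  expect_false("P1:W03" %in% rk2$well_key)
  # zero-variance wells are dropped with a warning
  feats3 <- feats; feats3[4, ] <- 2
  prof3 <- make_profiles(feats3)
  expect_warning(rk3 <- correlation_ranking(q, prof3), "zero profile variance")
  expect_false("P1:W04" %in% rk3$well_key)
})

test_that("running enrichment score reproduces hand-computed cases", {
  r1 <- running_enrichment_score(c("A", "A", "B", "B"), "A")
  expect_equal(r1$running_curve, c(0.5, 1, 0.5, 0))
  expect_equal(r1$es, 1)
  r2 <- running_enrichment_score(c("B", "B", "A", "A"), "A")
  expect_equal(r2$running_curve, c(-0.5, -1, -0.5, 0))
  expect_equal(r2$es, 0)
  expect_equal(running_enrichment_score(c("A", "B", "A", "B"), "A")$es, 0.5)
  expect_error(running_enrichment_score(c("B", "B"), "A"), "absent")
  expect_error(running_enrichment_score(c("A", "A"), "A"), "universal")
})

test_that("running curve ends at zero, es lies in [0, 1], and depends only on label order", {
  withr::with_seed(62, {
    for (i in 1:25) {
      n <- sample(4:40, 1)
      labels <- sample(c("A", "B"), n, replace = TRUE)
      if (!any(labels == "A")) labels[1] <- "A"
      if (!any(labels == "B")) labels[2] <- "B"
      r <- running_enrichment_score(labels, "A")
      expect_equal(r$running_curve[n], 0, tolerance = 1e-12)
      expect_gte(r$es, 0)
      expect_lte(r$es, 1)
      expect_equal(r$es, oracle_es(labels, "A"), tolerance = 1e-12)
    }
  })
})

test_that("es agrees with the brute-force oracle for every short two-label list", {
  for (n in 2:7) {
    for (labels in all_two_label_sequences(n)) {
      expect_equal(running_enrichment_score(labels, "A")$es,
                   oracle_es(labels, "A"), tolerance = 1e-12)
    }
  }
})

test_that("permutation p follows the spec's worked example and degenerate case", {
  # ranked [A, A, B]: shuffling ranks 2-3 yields es in {1, 0.5}; observed 1
  ps <- permutation_pvalue(c("A", "A", "B"), "A", n_perm = 50, seed = 1)
  expect_equal(as.numeric(ps), 0)
  perm_es <- sapply(list(c("A", "A", "B"), c("A", "B", "A")),
                    oracle_es, category = "A")
  expect_setequal(round(perm_es, 10), c(1, 0.5))
  # all non-first labels identical: every shuffle reproduces the list
  p2 <- permutation_pvalue(c("A", "B", "B", "B"), "A", n_perm = 20, seed = 2)
  expect_equal(as.numeric(p2), 0)
  # determinism
  labels <- c("A", "B", "A", "B", "B", "A", "B", "B")
  expect_identical(permutation_pvalue(labels, "A", n_perm = 200, seed = 7),
                   permutation_pvalue(labels, "A", n_perm = 200, seed = 7))
  # smoothed variant is (k + 1) / (B + 1)
  p_raw <- permutation_pvalue(labels, "A", n_perm = 200, seed = 7)
  p_sm <- permutation_pvalue(labels, "A", n_perm = 200, seed = 7, smooth = TRUE)
  expect_equal(as.numeric(p_sm), (as.numeric(p_raw) * 200 + 1) / 201)
})

test_that("Monte-Carlo p matches exhaustive enumeration within binomial error", {
  # deeper version of the check in test-acceptance: a spread of list shapes
  cases <- list(c("A", "A", "B", "B", "B"),
                c("B", "A", "B", "A", "B", "A", "B"),
                c("A", "B", "B", "A", "A", "B"),
                c("B", "B", "A", "A", "B", "A", "A"))
  for (labels in cases) {
    p_ex <- oracle_p_exact(labels, "A", fix_first = TRUE)
    p_mc <- as.numeric(permutation_pvalue(labels, "A", n_perm = 2000,
                                          fix_first = TRUE,
                                          seed = derive_seed(77, paste(labels, collapse = ""))))
    se <- sqrt(p_ex * (1 - p_ex) / 2000)
    expect_lte(abs(p_mc - p_ex), max(3 * se, 1e-12))
  }
})

test_that("es is invariant under monotone transforms of the correlations", {
  withr::with_seed(63, {
    feats <- matrix(rnorm(12 * 8), 12)
  })
  prof <- make_profiles(feats, moa = rep(c("M1", "M2", "M3"), 4))
  rk <- correlation_ranking("P1:W01", prof)
  es1 <- running_enrichment_score(rk, "M1")$es
  # squash correlations monotonically: ranking (and hence es) is unchanged
  rk2 <- rk; rk2$correlation <- tanh(3 * rk$correlation)
  expect_equal(running_enrichment_score(rk2, "M1")$es, es1)
})

test_that("the enrichment scan annotates queries, honours exclusions and flags degenerates", {
  lay <- generate_screen_layout(n_plates = 1, n_compounds_per_plate = 6,
                                n_moa = 3, n_conc = 5, controls_per_role = 3,
                                seed = 71)
  eff <- effect_model(sort(unique(na.omit(lay$moa_label))), 6,
                      effect_size = 2, seed = 72)
  cells <- simulate_feature_table(lay, eff, seed = 73)
  norm <- robust_normalize(aggregate_well(cells, lay), min_controls = 2)
  scan <- moa_enrichment_scan(norm, n_perm = 100, seed = 74)
  r <- scan$results
  expect_equal(nrow(r), sum(lay$role == "treated"))
  expect_true(all(r$computable))
  expect_true(all(r$es >= 0 & r$es <= 1))
  expect_true(all(r$p_value >= 0 & r$p_value <= 1))
  expect_equal(r$enriched, r$p_value < 0.05)

  # leave-compound-out removes exactly (n_conc - 1) sibling wells
  q <- r$well_key[1]
  full <- correlation_ranking(q, norm)
  sib <- well_key(lay$plate_id, lay$well_id)[
    lay$role == "treated" & lay$compound_id == r$compound_id[1]]
  lco <- correlation_ranking(q, norm, exclusions = setdiff(sib, q))
  expect_equal(nrow(full) - nrow(lco), 4)
  expect_true(q %in% lco$well_key)

  # scans are reproducible and order-independent via per-query child seeds
  scan2 <- moa_enrichment_scan(norm, n_perm = 100, seed = 74)
  expect_identical(scan$results, scan2$results)

  # an MOA with a single eligible well is flagged not computable
  withr::with_seed(76, {
    feats <- matrix(rnorm(6 * 5), 6)
  })
  prof_lone <- make_profiles(feats, moa = c("M_rare", rep("M_common", 5)))
  scan3 <- moa_enrichment_scan(prof_lone, n_perm = 50, seed = 75)
  lonely <- scan3$results[scan3$results$moa == "M_rare", ]
  expect_false(lonely$computable)
  expect_true(is.na(lonely$es))
  # the universal MOA of the remaining queries is equally undefined
  expect_true(all(scan3$results$computable[scan3$results$moa == "M_common"]))
})

test_that("percent_enriched implements the percentage formula and partitions results", {
  df <- data.frame(
    well_key = sprintf("P1:W%02d", 1:10), coculture_id = "KB",
    moa = rep(c("M1", "M2"), c(5, 5)),
    enriched = c(TRUE, TRUE, TRUE, FALSE, FALSE,
                 rep(FALSE, 5)),
    computable = TRUE, stringsAsFactors = FALSE
  )
  s <- percent_enriched(df)
  expect_equal(s$percent_enriched[s$moa == "M1"], 60)   # 3 of 5
  expect_equal(s$percent_enriched[s$moa == "M2"], 0)
  expect_equal(sum(s$n_total), sum(df$computable))
  df$enriched <- TRUE
  expect_true(all(percent_enriched(df)$percent_enriched == 100))
})
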