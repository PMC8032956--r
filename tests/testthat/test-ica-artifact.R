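test_that("spatial ICA recovers well-separated planted sources", {
  ph <- generate_phantom(phantom_spec(dim = c(16, 16, 6), n_frames = 150,
                                      n_networks = 3, network_amp = 3,
                                      noise_sigma = 0.3, global_amp = 0,
                                      resp_amp = 0, n_roi_per_hemi = 4,
                                      seed = 7))
  cs <- spatial_ica(ph$series, ph$mask, n_components = 10, seed = 11)
  expect_equal(cs$n_components, 10)
  idx <- which(ph$mask$voxels)
  matched <- vapply(1:3, function(k) {
    truth <- as.numeric(ph$truth$maps[[k]])[idx]
    max(abs(vapply(1:10, function(j)
      cor(truth, as.numeric(cs$maps[[j]])[idx]), numeric(1))))
  }, numeric(1))
  expect_true(all(matched > 0.95))
  # unit-variance courses, z-scored maps, non-negative skewness
  expect_equal(apply(cs$courses, 2, sd), rep(1, 10), tolerance = 1e-8)
  for (j in 1:10) {
    v <- as.numeric(cs$maps[[j]])[idx]
    expect_equal(sd(v), 1, tolerance = 1e-8)
    expect_gte(mean((v - mean(v))^3), -1e-8)
  }
  expect_true(cs$explained_variance > 0 && cs$explained_variance <= 1)
})

test_that("spatial ICA is deterministic and enforces the model-order bound", {
  ph <- test_phantom(seed = 13, n_networks = 2, noise_sigma = 0.5)
  a <- spatial_ica(ph$series, ph$mask, n_components = 5, seed = 3)
  b <- spatial_ica(ph$series, ph$mask, n_components = 5, seed = 3)
  expect_identical(a$courses, b$courses)
  expect_identical(a$maps, b$maps)
  expect_error(spatial_ica(ph$series, ph$mask,
                           n_components = ph$series$n_frames, seed = 1),
               "below n_frames")
})

test_that("component features measure clusters, rim, slices and spectra", {
  d <- c(12, 12, 6)
  g <- tiny_grid(d)
  mask <- brain_mask(array(TRUE, dim = d), g)
  nt <- 200
  mk_cs <- function(map, course) component_set(list(map), cbind(course),
                                               mask, 1)
  # one compact suprathreshold cube
  m1 <- array(0, dim = d); m1[5:7, 5:7, 3:4] <- 5
  f1 <- extract_features(mk_cs(m1, rnorm(nt)), mask)
  expect_equal(f1$n_clusters, 1L)
  expect_equal(f1$largest_cluster_frac, 1)

  # 50 isolated voxels: a 26-disconnected speckle pattern
  set.seed(5)
  m2 <- array(0, dim = d)
  co <- as.matrix(expand.grid(x = seq(1, 11, by = 3), y = seq(1, 11, by = 3),
                              z = seq(1, 5, by = 2)))
  pick <- co[sample(nrow(co), 30), ]
  m2[cbind(pick)] <- 6
  f2 <- extract_features(mk_cs(m2, rnorm(nt)), mask)
  expect_equal(f2$n_clusters, 30L)
  expect_equal(f2$largest_cluster_frac, 1 / 30)

  # single-slice sheet concentrates on one slice
  m3 <- array(0, dim = d); m3[, , 2] <- 4
  f3 <- extract_features(mk_cs(m3, rnorm(nt)), mask)
  expect_equal(f3$slice_conc, 1)

  # pure 0.2 Hz tone: peak at 0.2, negligible low-band power
  tvec <- (0:(nt - 1)) * 1.6
  f4 <- extract_features(mk_cs(m1, sin(2 * pi * 0.2 * tvec)), mask,
                         tr_vol = 1.6)
  expect_equal(f4$peak_freq, 0.2, tolerance = 0.01)
  expect_lt(f4$low_band_frac, 0.05)

  # empty suprathreshold set is flagged, not an error
  f5 <- extract_features(mk_cs(array(0.1, dim = d), rnorm(nt)), mask)
  expect_true(f5$empty_map)
  expect_equal(f5$n_clusters, 0L)
  expect_error(extract_features(mk_cs(m1, rnorm(nt)), mask,
                                z_threshold = 0), "> 0")
})

test_that("26-connectivity merges diagonal neighbours into one cluster", {
  d <- c(6, 6, 3)
  m <- array(FALSE, dim = d)
  m[2, 2, 1] <- m[3, 3, 2] <- m[4, 4, 3] <- TRUE   # touching only diagonally
  expect_equal(ratfc:::cluster_sizes_26(m), 3L)
  m[6, 6, 1] <- TRUE
  expect_equal(ratfc:::cluster_sizes_26(m), c(3L, 1L))
})

test_that("cleaning regresses artifact courses out and keeps signal", {
  d <- c(8, 8, 2); nt <- 300
  g <- tiny_grid(d)
  mask <- brain_mask(array(TRUE, dim = d), g)
  set.seed(23)
  tvec <- (0:(nt - 1)) * 1.6
  s_course <- sin(2 * pi * 0.03 * tvec)
  a_course <- cos(2 * pi * 0.11 * tvec)        # orthogonal-by-frequency
  dat <- array(0, c(d, nt))
  for (x in 1:8) for (y in 1:8) for (z in 1:2)
    dat[x, y, z, ] <- s_course + 3 * a_course + 100
  series <- bold_series(dat, g, 1.6)
  maps <- list(array(1, dim = d), array(1, dim = d))
  courses <- cbind(s_course / sd(s_course), a_course / sd(a_course))
  cs <- component_set(maps, courses, mask, 1)

  # empty artifact list: bit-exact identity
  expect_identical(clean_series(series, cs, integer(0))$data, series$data)

  cleaned <- clean_series(series, cs, 2, mode = "aggressive")
  v <- cleaned$data[1, 1, 1, ]
  expect_lt(abs(cor(v, a_course)), 0.02)
  expect_gt(cor(v, s_course), 0.99)
  # residual orthogonal to the removed course
  expect_lt(abs(sum((v - mean(v)) * (a_course - mean(a_course)))), 1e-6)

  soft <- clean_series(series, cs, 2, mode = "soft")
  expect_lt(abs(cor(soft$data[1, 1, 1, ], a_course)), 0.02)
  expect_gt(cor(soft$data[1, 1, 1, ], s_course), 0.99)

  # removing every component leaves (approximately) the temporal mean
  all_removed <- clean_series(series, cs, 1:2, mode = "aggressive")
  expect_lt(sd(all_removed$data[1, 1, 1, ]), 1e-8)
  expect_equal(mean(all_removed$data[1, 1, 1, ]), 100, tolerance = 1e-8)

  expect_error(clean_series(series, cs, 3), "out of range")
})

test_that("classifier separates a synthetic corpus with high recall/precision", {
  corpus <- generate_labeled_components(100, 100, seed = 5)
  hold <- c(1:30, 101:130)
  train <- setdiff(1:200, hold)
  clf <- train_classifier(corpus$features[train, ], corpus$labels[train],
                          seed = 9)
  expect_gte(clf$cv_recall, 0.85)
  expect_gte(clf$cv_precision, 0.85)
  truth <- which(corpus$labels[hold] == "artifact")
  cl <- classify_components(clf, corpus$features[hold, ], threshold = 50)
  ev <- evaluate_classification(cl$artifact_idx, truth, length(hold))
  expect_gte(ev$recall, 0.85)
  expect_gte(ev$precision, 0.85)
  # determinism
  clf2 <- train_classifier(corpus$features[train, ], corpus$labels[train],
                           seed = 9)
  expect_equal(artifact_scores(clf, corpus$features[hold, ]),
               artifact_scores(clf2, corpus$features[hold, ]))
  expect_error(train_classifier(corpus$features[1:20, ],
                                factor(rep("artifact", 20),
                                       levels = c("signal", "artifact")),
                                seed = 1), "both")
})

test_that("threshold semantics: boundaries, nesting, monotone trade-off", {
  corpus <- generate_labeled_components(60, 60, seed = 15)
  clf <- train_classifier(corpus$features, corpus$labels, seed = 2)
  feats <- generate_labeled_components(40, 40, seed = 16)$features
  truth <- which(generate_labeled_components(40, 40, seed = 16)$labels ==
                   "artifact")

  c0 <- classify_components(clf, feats, 0)
  s <- c0$scores
  expect_setequal(c0$artifact_idx, which(s == 100))
  c100 <- classify_components(clf, feats, 100)
  expect_setequal(c100$artifact_idx, seq_len(nrow(feats)))
  expect_error(classify_components(clf, feats, 101), "0, 100")

  thresholds <- c(20, 30, 40, 45, 50, 60, 70)
  sets <- lapply(thresholds, function(t)
    classify_components(clf, feats, t)$artifact_idx)
  for (i in seq_along(thresholds)[-1]) {
    expect_true(all(sets[[i - 1]] %in% sets[[i]]))   # nesting
  }
  ev <- lapply(sets, evaluate_classification, truth = truth,
               universe_size = nrow(feats))
  recalls <- vapply(ev, `[[`, numeric(1), "recall")
  expect_true(all(diff(recalls) >= 0))               # recall non-decreasing
  precisions <- vapply(ev, `[[`, numeric(1), "precision")
  expect_true(all(diff(precisions) <= 1e-12))        # precision non-increasing
})

test_that("dual-threshold review is the symmetric difference of artifact lists", {
  corpus <- generate_labeled_components(60, 60, seed = 25)
  clf <- train_classifier(corpus$features, corpus$labels, seed = 2)
  feats <- generate_labeled_components(30, 30, seed = 26)$features
  dt <- dual_threshold_review(clf, feats, 20, 70)
  lo <- dt$low$artifact_idx; hi <- dt$high$artifact_idx
  expect_setequal(dt$review, union(setdiff(lo, hi), setdiff(hi, lo)))
  expect_setequal(dt$auto_artifact, intersect(lo, hi))
  expect_setequal(union(union(dt$auto_artifact, dt$auto_signal), dt$review),
                  seq_len(nrow(feats)))
  expect_error(dual_threshold_review(clf, feats, 70, 20), "below")

  # narrower threshold pair reviews a subset of the wide pair
  dt_narrow <- dual_threshold_review(clf, feats, 40, 50)
  expect_true(all(dt_narrow$review %in% dt$review))
})

test_that("recall/precision arithmetic and degenerate flags", {
  ev <- evaluate_classification(c(1, 2, 3), c(1, 2, 3), 10)
  expect_equal(ev$recall, 1); expect_equal(ev$precision, 1)
  ev2 <- evaluate_classification(c(1, 2, 5), 1:4, 10)
  expect_equal(ev2$recall, 0.5)
  expect_equal(ev2$precision, 2 / 3, tolerance = 1e-12)
  ev3 <- evaluate_classification(integer(0), 1:4, 10)
  expect_false(ev3$precision_defined)
  expect_true(is.na(ev3$precision))
  ev4 <- evaluate_classification(1:2, integer(0), 10)
  expect_false(ev4$recall_defined)
  expect_error(evaluate_classification(11, 1:2, 10), "universe")
})
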