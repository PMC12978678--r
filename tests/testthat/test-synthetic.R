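# toy atlas, lesion growth, connectome simulation, behavior generation

test_that("atlas construction yields mirrored parcels and trajectories", {
  at <- make_atlas(c(20, 24, 20), K = 4, seed = 2)
  expect_identical(length(at$parcel_names), 8L)
  # 6 left intra-hemispheric + 4 homotopic trajectories
  expect_identical(nrow(at$edges), 10L)
  expect_identical(length(at$trajectories), 10L)
  # every voxel belongs to exactly one parcel
  expect_true(all(at$labels >= 1 & at$labels <= 8))
  # left parcels live strictly in the left half
  left_vox <- arrayInd(which(at$labels <= 4), at$shape)
  expect_true(all(left_vox[, 1] <= at$left_max))
  # trajectories stay inside the grid and end at the parcel centroids
  lin <- function(ijk) as.integer(ijk[1] + (ijk[2] - 1) * 20 +
                                    (ijk[3] - 1) * 480)
  for (e in seq_len(10)) {
    tr <- at$trajectories[[e]]
    expect_true(all(tr >= 1 & tr <= prod(at$shape)))
    pa <- match(at$edges$parcel_a[e], at$parcel_names)
    pb <- match(at$edges$parcel_b[e], at$parcel_names)
    expect_identical(tr[1], lin(at$centroids[pa, ]))
    expect_identical(tr[length(tr)], lin(at$centroids[pb, ]))
  }
  # determinism
  at2 <- make_atlas(c(20, 24, 20), K = 4, seed = 2)
  expect_identical(at$labels, at2$labels)
  expect_error(make_atlas(c(8, 8, 8), 4), ">= 12")
  expect_error(make_atlas(c(12, 12, 12), 100), "infeasible")
})

test_that("lesions are left-lateralized single 26-connected components", {
  at <- make_atlas(seed = 3)
  masks <- simulate_lesions(12, at, seed = 3)
  for (m in masks) {
    vox <- which(m$grid == 1)
    expect_gt(length(vox), 0)
    ijk <- arrayInd(vox, dim(m$grid))
    expect_true(all(ijk[, 1] <= at$left_max))
    lab <- label_clusters(m$grid, 26)
    expect_identical(max(lab), 1L) # one connected component
  }
  # exact target volume when no clipping occurs
  expect_true(all(vapply(masks, function(m) sum(m$grid), 0) >= 1))
})

test_that("territory bias 1 confines lesion seeds to the territory", {
  at <- make_atlas(seed = 5)
  masks <- simulate_lesions(10, at, territory_bias = 1, seed = 5)
  for (m in masks)
    expect_true(attr(m, "seed_voxel") %in% attr(m, "territory"))
})

test_that("lesion volumes track the lognormal target distribution", {
  at <- make_atlas(seed = 7)
  masks <- simulate_lesions(64, at, seed = 7)
  vols <- vapply(masks, function(m) sum(m$grid), 0)
  target_mean <- exp(5.93 + 0.75^2 / 2)
  expect_lt(abs(mean(vols) - target_mean) / target_mean, 0.25)
})

test_that("patient edges are zeroed exactly when the lesion cuts the tract", {
  at <- make_atlas(seed = 9)
  # lesion covering one full trajectory
  tr1 <- at$trajectories[[1]]
  g <- array(0L, at$shape); g[tr1] <- 1L
  m_cut <- lesion_mask(g, diag(c(2, 2, 2, 1)), "cut")
  # lesion disjoint from all trajectories
  alltr <- unique(unlist(at$trajectories))
  free <- setdiff(which(slice.index(array(0, at$shape), 1) <= at$left_max),
                  alltr)[1]
  g2 <- array(0L, at$shape); g2[free] <- 1L
  m_free <- lesion_mask(g2, diag(c(2, 2, 2, 1)), "free")

  sim <- simulate_connectomes(at, list(m_cut, m_free), n_controls = 5,
                              unreliable_edge_fraction = 0, seed = 9)
  wA <- sim$patients[[1]]$weights
  a1 <- match(at$edges$parcel_a[1], at$parcel_names)
  b1 <- match(at$edges$parcel_b[1], at$parcel_names)
  expect_identical(wA[a1, b1], 0)
  expect_true(1 %in% sim$patient_cut[[1]])
  # the disjoint lesion zeroes nothing
  expect_length(sim$patient_cut[[2]], 0L)
  expect_true(all(sim$patients[[2]]$weights[cbind(
    match(at$edges$parcel_a, at$parcel_names),
    match(at$edges$parcel_b, at$parcel_names))] > 0))
})

test_that("unreliable edges surface as non-analyzable after binarization", {
  at <- make_atlas(seed = 11)
  masks <- simulate_lesions(10, at, seed = 11)
  sim <- simulate_connectomes(at, masks, n_controls = 40,
                              unreliable_edge_fraction = 0.2, seed = 11)
  d <- binarize_disconnection(sim$patients[[1]], sim$controls)
  ei <- cbind(match(at$edges$parcel_a, at$parcel_names),
              match(at$edges$parcel_b, at$parcel_names))
  an <- d$analyzable[ei]
  # with 40 controls at 30% dropout, every designated unreliable edge is
  # absent somewhere, and only those edges become non-analyzable
  expect_identical(which(an == 0L), sim$unreliable_edges)
})

test_that("every zeroed analyzable edge traces back to a lesion-tract hit", {
  sc <- simulate_cohort(seed = 13, n_patients = 12, n_controls = 10)
  at <- sc$atlas
  for (i in seq_along(sc$connectomes$patients)) {
    les <- which(sc$masks[[i]]$grid == 1L)
    cut_expect <- which(vapply(at$trajectories, function(tr)
      any(tr %in% les), TRUE))
    expect_identical(sc$truth$patient_cut[[i]], cut_expect)
  }
})

test_that("behavior follows the logistic generating model", {
  params <- behavior_params()
  subjects <- data.frame(subject_id = c("a", "b"), group = "patient",
                         age = c(61.6, 61.6), education = c(16.5, 16.5))
  truth0 <- list(effect_weights = c(real_word = 0, PW0M = 0, PW1M = 0,
                                    PWMM = 0),
                 edge_weights = c(real_word = 0, PW0M = 0, PW1M = 0,
                                  PWMM = 0))
  # zero damage at covariate means: accuracy concentrates at the baseline
  set.seed(1)
  reps <- replicate(300, {
    co <- simulate_behavior(subjects, truth0, c(0, 0), c(0, 0),
                            seed = sample.int(1e6, 1))
    co$PW0M_correct / co$PW0M_n
  })
  expect_lt(abs(mean(reps) - 0.897), 0.02)
  # full damage with a large weight pins accuracy near the shifted floor
  truth4 <- truth0; truth4$effect_weights[c("PW0M", "PW1M", "PWMM")] <- 4
  reps4 <- replicate(300, {
    co <- simulate_behavior(subjects, truth4, c(1, 1), c(0, 0),
                            seed = sample.int(1e6, 1))
    co$PW0M_correct / co$PW0M_n
  })
  expect_lt(abs(mean(reps4) - plogis(qlogis(0.897) - 4)), 0.03)
  # trial counts: 200 real words, 20 per pseudoword class; durations capped
  co <- simulate_behavior(subjects, truth0, c(0, 0), c(0, 0), seed = 1)
  expect_identical(co$real_word_n, c(200L, 200L))
  expect_identical(co$PW1M_n, c(20L, 20L))
  expect_true(all(co$real_word_correct <= co$real_word_n))
  expect_true(all(unlist(co[grep("_duration", names(co))]) > 0))
  expect_true(all(unlist(co[grep("_duration", names(co))]) <= 10))
})

test_that("the real-pseudoword accuracy gap matches the analytic prediction", {
  # with a pseudoword-only weight, the population mean gap among damaged
  # subjects equals the logistic-difference prediction
  n <- 1000
  subjects <- data.frame(subject_id = sprintf("s%04d", 1:n),
                         group = "patient", age = 61.6, education = 16.5)
  truth <- list(effect_weights = c(real_word = 0, PW0M = 2, PW1M = 2,
                                   PWMM = 2),
                edge_weights = c(real_word = 0, PW0M = 0, PW1M = 0,
                                 PWMM = 0))
  co <- simulate_behavior(subjects, truth, damage_frac = rep(1, n),
                          edges_cut = rep(0L, n), seed = 3)
  gap <- mean(co$real_word_correct / 200) -
    mean(score_accuracy(co, c("PW0M", "PW1M", "PWMM")))
  p <- behavior_params()
  pred <- plogis(p$baseline_logit[["real_word"]]) -
    mean(plogis(p$baseline_logit[c("PW0M", "PW1M", "PWMM")] - 2))
  expect_lt(abs(gap - pred), 0.02)
})

test_that("cohort regeneration from the same seed is bitwise identical", {
  a <- simulate_cohort(seed = 17, n_patients = 12, n_controls = 8)
  b <- simulate_cohort(seed = 17, n_patients = 12, n_controls = 8)
  expect_identical(a$cohort, b$cohort)
  expect_identical(lapply(a$masks, `[[`, "grid"),
                   lapply(b$masks, `[[`, "grid"))
  expect_identical(lapply(a$connectomes$patients, `[[`, "weights"),
                   lapply(b$connectomes$patients, `[[`, "weights"))
  expect_identical(a$truth[names(a$truth) != "seed"],
                   b$truth[names(b$truth) != "seed"])
})

test_that("null cohorts decouple behavior from lesion anatomy", {
  sc <- simulate_cohort(seed = 19, n_patients = 40, n_controls = 10)
  des <- build_voxel_design(sc$masks, 0.2)
  pat <- sc$cohort[sc$cohort$group == "patient", ]
  acc <- score_accuracy(pat, c("PW0M", "PW1M", "PWMM"))
  r <- apply(des$X, 2, function(x) stats::cor(x, acc))
  expect_lt(abs(mean(r)), 3 / sqrt(nrow(des$X)))
})

test_that("recovery metrics implement dice and centroid distance", {
  expect_equal(recovery_metrics(1:100, 1:100, dim = c(10, 10, 10))$dice, 1)
  expect_equal(recovery_metrics(1:100, 1:100,
                                dim = c(10, 10, 10))$centroid_distance, 0)
  expect_equal(recovery_metrics(1:100, 101:200, dim = c(10, 10, 10))$dice, 0)
  expect_equal(recovery_metrics(1:100, 51:150, dim = c(10, 10, 10))$dice, 0.5)
  expect_message(z <- recovery_metrics(integer(0), integer(0)), "both sets empty")
  expect_equal(z$dice, 0)
  # edge sets by key
  r <- recovery_metrics(c("A|B", "B|C"), "A|B")
  expect_equal(r$dice, 2 * 1 / 3)
  expect_true(r$hit)
})

test_that("synthetic cohorts round-trip to disk", {
  sc <- simulate_cohort(seed = 23, n_patients = 10, n_controls = 5)
  dir <- withr::local_tempdir()
  write_synthetic_cohort(sc, dir)
  masks <- read_lesion_masks(file.path(dir, "masks",
                                       paste0(sc$cohort$subject_id[1:10],
                                              ".nii.gz")))
  expect_identical(masks[[1]]$grid, sc$masks[[1]]$grid)
  cn <- read_connectome(file.path(dir, "connectomes", "ctl001.tsv"),
                        file.path(dir, "connectomes", "labels.tsv"))
  expect_equal(cn$weights, sc$connectomes$controls[[1]]$weights,
               tolerance = 1e-9)
  co <- read_cohort_table(file.path(dir, "cohort.tsv"))
  expect_identical(nrow(co), 15L)
  expect_true(file.exists(file.path(dir, "truth.json")))
})
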