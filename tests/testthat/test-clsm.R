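# disconnectome binarization, edge filtering, edge/parcel inference

make_ctl <- function(w, labels, id) connectome(w, labels, id)

test_that("binarization implements absent-in-patient AND present-in-all-controls", {
  labels <- c("A", "B", "C")
  base <- matrix(5, 3, 3); diag(base) <- 0
  # patient edge A-B absent; all controls have it -> disconnected
  wp <- base; wp[1, 2] <- wp[2, 1] <- 0
  pat <- connectome(wp, labels, "p1")
  ctls <- list(make_ctl(base, labels, "c1"), make_ctl(base, labels, "c2"))
  d <- binarize_disconnection(pat, ctls)
  expect_identical(d$D[1, 2], 1L)
  expect_identical(d$analyzable[1, 2], 1L)
  # patient weight > 0 -> never disconnected, whatever the controls
  expect_identical(d$D[1, 3], 0L)
  # one control missing the edge -> not analyzable, not disconnected
  w2 <- base; w2[2, 3] <- w2[3, 2] <- 0
  ctls2 <- list(make_ctl(base, labels, "c1"), make_ctl(w2, labels, "c2"))
  d2 <- binarize_disconnection(pat, ctls2)
  expect_identical(d2$analyzable[2, 3], 0L)
  expect_identical(d2$D[2, 3], 0L)
  # label mismatch
  bad <- connectome(base, c("A", "B", "X"))
  expect_error(binarize_disconnection(pat, list(ctls[[1]], bad)), "labels")
})

test_that("binarization equals a brute-force triple-loop oracle", {
  set.seed(33)
  labels <- paste0("P", 1:5)
  for (rep in 1:50) {
    wp <- toy_weights(5, seed = rep, p_zero = 0.3)
    pat <- connectome(wp, labels, "p")
    ctls <- lapply(1:3, function(c)
      connectome(toy_weights(5, seed = 1000 + rep * 10 + c, p_zero = 0.2),
                 labels, paste0("c", c)))
    d <- binarize_disconnection(pat, ctls)
    for (a in 1:5) for (b in 1:5) {
      present_all <- TRUE
      for (ctl in ctls) if (ctl$weights[a, b] == 0) present_all <- FALSE
      expD <- as.integer(a != b && present_all && pat$weights[a, b] == 0)
      expA <- as.integer(a != b && present_all)
      expect_identical(d$D[a, b], expD)
      expect_identical(d$analyzable[a, b], expA)
    }
    # symmetry and zero diagonal after every operation
    expect_identical(d$D, t(d$D))
    expect_identical(d$analyzable, t(d$analyzable))
    expect_true(all(diag(d$D) == 0L) && all(diag(d$analyzable) == 0L))
  }
})

test_that("edge filter applies the strict > 10% rule (64-patient arithmetic)", {
  labels <- c("A", "B", "C", "D")
  base <- matrix(5, 4, 4); diag(base) <- 0
  ctls <- lapply(1:3, function(c) make_ctl(base, labels, paste0("c", c)))
  n <- 64
  # edge A-B cut in 7/64 (> 0.10, retained); A-C in 6/64 (dropped);
  # A-D cut in all (retained)
  disconn <- lapply(seq_len(n), function(i) {
    w <- base
    if (i <= 7) w[1, 2] <- w[2, 1] <- 0
    if (i <= 6) w[1, 3] <- w[3, 1] <- 0
    w[1, 4] <- w[4, 1] <- 0
    binarize_disconnection(connectome(w, labels, sprintf("p%02d", i)), ctls)
  })
  des <- build_edge_design(disconn, min_fraction = 0.10)
  keys <- edge_key(des$edges$parcel_a, des$edges$parcel_b)
  expect_true("A|B" %in% keys)
  expect_false("A|C" %in% keys)
  expect_true("A|D" %in% keys)
  expect_true(all(des$fraction > 0.10))
  expect_true(all(des$X %in% c(0, 1)))
})

test_that("edges not analyzable are dropped however often they are absent", {
  labels <- c("A", "B", "C")
  base <- matrix(5, 3, 3); diag(base) <- 0
  wc <- base; wc[1, 2] <- wc[2, 1] <- 0 # control lacks A-B
  ctls <- list(make_ctl(base, labels, "c1"), make_ctl(wc, labels, "c2"))
  disconn <- lapply(1:12, function(i) {
    w <- base
    w[1, 2] <- w[2, 1] <- 0              # all patients lack A-B too
    if (i <= 6) w[1, 3] <- w[3, 1] <- 0  # A-C cut in half the patients
    binarize_disconnection(connectome(w, labels, sprintf("p%02d", i)), ctls)
  })
  des <- build_edge_design(disconn)
  keys <- edge_key(des$edges$parcel_a, des$edges$parcel_b)
  expect_false("A|B" %in% keys)
  expect_true("A|C" %in% keys)
})

test_that("retained edge count is non-increasing in the filter threshold", {
  sc <- simulate_cohort(seed = 41, n_patients = 16, n_controls = 8)
  disconn <- lapply(sc$connectomes$patients, binarize_disconnection,
                    controls = sc$connectomes$controls)
  n_at <- vapply(c(0, 0.1, 0.3, 0.6), function(t) {
    d <- tryCatch(build_edge_design(disconn, t), error = function(e) NULL)
    if (is.null(d)) 0L else ncol(d$X)
  }, 0L)
  expect_true(all(diff(n_at) <= 0))
})

test_that("edge inference is invariant to subject relabeling", {
  sc <- simulate_cohort(seed = 43, n_patients = 20, n_controls = 10,
                        edge_effect = 3)
  sch <- perm_scheme(120, seed = 5)
  f1 <- svr_clsm(sc$connectomes$patients, sc$connectomes$controls, sc$cohort,
                 "pseudoword_lexicality", scheme = sch)
  # permute patient order in inputs; cohort table untouched (alignment is by id)
  ord <- rev(seq_along(sc$connectomes$patients))
  f2 <- svr_clsm(sc$connectomes$patients[ord], sc$connectomes$controls,
                 sc$cohort, "pseudoword_lexicality", scheme = sch)
  expect_equal(f1$edges$beta, f2$edges$beta, tolerance = 1e-12)
  expect_identical(f1$edges$significant, f2$edges$significant)
})

test_that("parcel statistics aggregate incident retained edges", {
  # toy 3-parcel chain where all signal sits on edge (A,B): parcels A and B
  # carry equal statistics, parcel C gets the remaining edge's share only
  beta <- c(-2, 0) # edges: A-B, B-C
  incidence <- matrix(c(1, 0, # A on edge A-B only
                        1, 1, # B on both
                        0, 1), # C on B-C only
                      nrow = 2, dimnames = list(NULL, c("A", "B", "C")))
  s <- strokemap:::.parcel_stat(beta, incidence)
  expect_equal(unname(s), c(2, 2, 0))
  # permutation matrix form used for the null
  B <- rbind(c(-1, -1), c(0.5, -0.2))
  S <- strokemap:::.parcel_stat(B, incidence)
  expect_equal(unname(S), rbind(c(1, 2, 1), c(0, 0.2, 0.2)))
})

test_that("parcels with no retained incident edges are not analyzable", {
  sc <- simulate_cohort(seed = 47, n_patients = 20, n_controls = 10)
  f <- svr_clsm(sc$connectomes$patients, sc$connectomes$controls, sc$cohort,
                "pseudoword_lexicality", scheme = perm_scheme(100, seed = 3))
  # right-hemisphere parcels have only homotopic edges, often filtered out;
  # whatever the split, the flags must be consistent
  not_an <- !f$parcels$analyzable
  expect_true(all(is.na(f$parcels$p_fwer[not_an])))
  expect_true(all(!f$parcels$significant[not_an]))
  an <- f$parcels$analyzable
  expect_true(all(f$parcels$p_fwer[an] > 0 & f$parcels$p_fwer[an] <= 1))
  expect_identical(f$parcels$significant,
                   !is.na(f$parcels$p_fwer) &
                     f$parcels$p_fwer < f$scheme$alpha)
  # the permutation-stream nulls are deterministic given the seed
  f2 <- svr_clsm(sc$connectomes$patients, sc$connectomes$controls, sc$cohort,
                 "pseudoword_lexicality", scheme = perm_scheme(100, seed = 3))
  expect_identical(f$null_min_beta, f2$null_min_beta)
  expect_identical(f$null_max_parcel, f2$null_max_parcel)
})

test_that("CLSM results write to disk with the documented columns", {
  sc <- simulate_cohort(seed = 49, n_patients = 16, n_controls = 8)
  disconn <- lapply(sc$connectomes$patients, binarize_disconnection,
                    controls = sc$connectomes$controls)
  f <- svr_clsm(disconn, cohort = sc$cohort,
                contrast = "pseudoword_lexicality",
                scheme = perm_scheme(100, seed = 1))
  dir <- withr::local_tempdir()
  write_clsm_results(f, dir, disconn = disconn[1:2])
  back <- read_edge_table(file.path(dir, "edges.tsv"))
  expect_identical(nrow(back), nrow(f$edges))
  expect_equal(back$beta, f$edges$beta, tolerance = 1e-12)
  expect_true(file.exists(file.path(dir, "parcels.tsv")))
  expect_true(file.exists(file.path(dir, "disconnectome_pat001.tsv")))
})
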