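# fixture builders shared across test files (all generated in code)

# a small mask with given lesioned linear indices
toy_mask <- function(idx, dim = c(6, 6, 6), voxel_mm = 1, id = "s1") {
  g <- array(0, dim)
  g[idx] <- 1
  lesion_mask(g, diag(c(voxel_mm, voxel_mm, voxel_mm, 1)), id)
}

# a minimal patient cohort table with per-class trial counts
toy_cohort <- function(n = 12, seed = 42) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    data.frame(
      subject_id = sprintf("pat%03d", seq_len(n)),
      group = "patient",
      age = round(runif(n, 40, 80)),
      education = round(runif(n, 12, 20)),
      lesion_volume_cm3 = round(runif(n, 1, 20), 3),
      real_word_n = 200L, real_word_correct = rbinom(n, 200, 0.9),
      PW0M_n = 20L, PW0M_correct = rbinom(n, 20, 0.7),
      PW1M_n = 20L, PW1M_correct = rbinom(n, 20, 0.8),
      PWMM_n = 20L, PWMM_correct = rbinom(n, 20, 0.75))
  })
}

# random symmetric non-negative connectome weights
toy_weights <- function(K = 5, seed = 1, p_zero = 0.2) {
  set.seed(seed)
  w <- matrix(runif(K * K, 1, 10), K, K)
  w[runif(K * K) < p_zero] <- 0
  w <- (w + t(w)) / 2
  diag(w) <- 0
  w
}

# independent flood-fill labeling oracle built on igraph
igraph_label_oracle <- function(mask, connectivity) {
  d <- dim(mask)
  fg <- which(mask > 0)
  if (!length(fg)) return(array(0L, d))
  coords <- arrayInd(fg, d)
  lim <- switch(as.character(connectivity), "6" = 1, "18" = 2, "26" = 3)
  edges <- integer(0)
  if (length(fg) > 1) {
    for (a in seq_along(fg)) for (b in seq_along(fg)) {
      if (b <= a) next
      dd <- abs(coords[a, ] - coords[b, ])
      if (max(dd) <= 1 && sum(dd) <= lim && sum(dd) > 0)
        edges <- c(edges, a, b)
    }
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  lab <- array(0L, d)
  lab[fg] <- comp
  lab
}
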