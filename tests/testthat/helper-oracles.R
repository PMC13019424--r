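# Independent oracles and small fixture builders used across the suite.

# Rand index between two flat partitions
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

# Naive median-linkage oracle: clusters carry explicit midpoint
# representatives; merge the closest pair of representatives, the merged
# representative is their midpoint. Independent of Lance-Williams updates.
median_linkage_oracle <- function(points) {
  reps <- lapply(seq_len(nrow(points)), function(i) points[i, ])
  members <- lapply(seq_len(nrow(points)), function(i) i)
  heights <- numeric(0)
  merged_sets <- list()
  while (length(reps) > 1L) {
    m <- length(reps)
    best <- Inf; bi <- 0L; bj <- 0L
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      v <- sqrt(sum((reps[[i]] - reps[[j]])^2))
      if (v < best) { best <- v; bi <- i; bj <- j }
    }
    heights <- c(heights, best)
    new_members <- sort(c(members[[bi]], members[[bj]]))
    merged_sets[[length(merged_sets) + 1L]] <- new_members
    reps[[bi]] <- (reps[[bi]] + reps[[bj]]) / 2
    members[[bi]] <- new_members
    reps <- reps[-bj]; members <- members[-bj]
  }
  list(heights = heights, merged_sets = merged_sets)
}

# leaf index sets produced at each merge of a linkage_tree
tree_merge_sets <- function(tree) {
  out <- vector("list", nrow(tree$merge))
  for (m in seq_len(nrow(tree$merge))) {
    grab <- function(code) if (code < 0) -code else out[[code]]
    out[[m]] <- sort(c(grab(tree$merge[m, 1L]), grab(tree$merge[m, 2L])))
  }
  out
}

# dense grid-search NNLS oracle for a two-active-component subproblem:
# minimizes ||K c - s||^2 over the nonnegative grid at `step` resolution
nnls_grid_oracle <- function(K, s, upper = 3, step = 1e-3) {
  stopifnot(ncol(K) == 2L)
  G <- crossprod(K); b <- drop(crossprod(K, s))
  c1 <- seq(0, upper, by = step); c2 <- seq(0, upper, by = step)
  # f(c) = c'Gc - 2 b'c (+ const), evaluated separably on the grid
  f <- outer(G[1, 1] * c1^2 - 2 * b[1] * c1, G[2, 2] * c2^2 - 2 * b[2] * c2, "+") +
    2 * G[1, 2] * outer(c1, c2)
  k <- arrayInd(which.min(f), dim(f))
  c(c1[k[1]], c2[k[2]])
}

# small noiseless synthetic mixture fixture on the default grid
make_raw_mixtures <- function(n = 12, seed = 42, ester_form = "FAME") {
  comps <- render_pure_components(ester_form)
  fr <- with_test_seed(seed, {
    g <- matrix(stats::rgamma(n * 5, shape = 1), n)
    100 * g / rowSums(g)
  })
  colnames(fr) <- acyl_species()
  spectra <- lapply(seq_len(n), function(k)
    mix_spectrum(fr[k, ], comps, NULL, id = sprintf("mix_%02d", k)))
  list(set = bind_spectra(spectra), fractions = fr, components = comps)
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a
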