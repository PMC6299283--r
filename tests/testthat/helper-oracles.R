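# Independent oracles and small fixtures used across the suite.

# Naive Ward agglomeration recomputed from point coordinates: at each step
# merge the pair of clusters whose union minimizes the increase in
# within-cluster sum of squares (computed from scratch, O(n^3) overall).
# ward2 heights on Euclidean distances are sqrt(2 * deltaSS); ward1 heights
# on squared Euclidean distances are 2 * deltaSS.
naive_ward_points <- function(pts, variant = "ward2") {
  n <- nrow(pts)
  ss <- function(ix) {
    if (length(ix) == 1L) return(0)
    m <- colMeans(pts[ix, , drop = FALSE])
    sum(sweep(pts[ix, , drop = FALSE], 2L, m)^2)
  }
  clusters <- as.list(seq_len(n))
  ids <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    best <- Inf
    bi <- bj <- NA_integer_
    nc <- length(clusters)
    for (i in seq_len(nc - 1L)) {
      for (j in (i + 1L):nc) {
        cost <- ss(c(clusters[[i]], clusters[[j]])) -
          ss(clusters[[i]]) - ss(clusters[[j]])
        if (cost < best - 1e-12) {
          best <- cost
          bi <- i
          bj <- j
        }
      }
    }
    merge[step, ] <- c(ids[bi], ids[bj])
    height[step] <- if (variant == "ward2") sqrt(2 * best) else 2 * best
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
    ids[bi] <- step
    ids <- ids[-bj]
  }
  list(merge = merge, height = height)
}

# naive clade check: root at an outgroup taxon and test monophyly with ape
naive_has_clade <- function(tree, taxa) {
  out <- setdiff(tree$tip.label, taxa)
  rooted <- ape::root(tree, outgroup = out[1L], resolve.root = TRUE)
  ape::is.monophyletic(rooted, taxa)
}

rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  agree <- (same_a == same_b)
  (sum(agree[upper.tri(agree)])) / choose(n, 2)
}

# two-sided 99% binomial interval for an observed frequency
binom_ci99 <- function(p, n) {
  c(stats::qbinom(0.005, n, p), stats::qbinom(0.995, n, p)) / n
}

# canonical split-key set of a tree
split_keys <- function(tree) {
  sort(vapply(tree_bipartitions(tree), split_key, ""))
}

two_group_spec <- function() {
  data.frame(group = c("g1", "g2"), n_species = c(5L, 5L),
             retention = c(0.9, 0.1))
}

# connected components of a non-negative weight matrix (BFS, no igraph)
igraph_free_components <- function(w) {
  n <- nrow(w)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      nb <- which(w[v, ] > 0 & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  names(comp) <- rownames(w)
  comp
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
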