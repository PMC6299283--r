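#' Frequency of a clade across a tree sample
#'
#' The support of a clade is the fraction of trees in which the bipartition
#' (clade | universe \ clade) appears as an internal edge — the
#' bootstrap-proportion semantics of ultrafast-bootstrap files.  Only exact
#' split presence counts; no partial or compatibility credit is given.
#'
#' @param sample a [tree_sample()].
#' @param taxa character vector of taxon labels whose monophyly is
#'   interrogated (or a [bipartition()]).
#' @return support in `[0, 1]`.  Trivial queries (single taxon, all taxa or
#'   all-but-one) are present in every unrooted tree and return 1 with a
#'   warning.
#' @export
clade_frequency <- function(sample, taxa) {
  stopifnot(inherits(sample, "tree_sample"))
  if (inherits(taxa, "bipartition")) {
    if (!identical(taxa$universe, sample$taxa))
      stop("bipartition universe does not match the sample's taxa")
    taxa <- taxa$side
  }
  taxa <- unique(as.character(taxa))
  unknown <- setdiff(taxa, sample$taxa)
  if (length(unknown))
    stop("query taxa not in the sample: ", paste(unknown, collapse = ", "))
  n <- length(sample$taxa)
  k <- length(taxa)
  if (k == 0L) stop("empty clade query")
  if (k == 1L || k >= n - 1L) {
    warning("trivial split (|taxa| = ", k, " of ", n,
            "); support is 1 by definition")
    return(1)
  }
  bip <- bipartition(taxa, sample$taxa)
  hits <- vapply(sample$trees, .has_split, TRUE, side = bip$side)
  mean(hits)
}

# Does `tree` contain the non-trivial split (side | rest)?  Single postorder
# accumulation of clade size and in-query count per node; the split is
# present iff some node's clade equals the query side or its complement.
# Root suppression is unnecessary: the multiset of edge splits is unchanged
# by (un)rooting.
.has_split <- function(tree, side) {
  tl <- tree$tip.label
  n <- length(tl)
  q <- tl %in% side
  k <- sum(q)
  tree <- stats::reorder(tree, "postorder")
  e <- tree$edge
  m <- n + tree$Nnode
  size <- c(rep.int(1L, n), integer(tree$Nnode))
  inq <- c(as.integer(q), integer(tree$Nnode))
  for (r in seq_len(nrow(e))) {
    p <- e[r, 1L]
    ch <- e[r, 2L]
    size[p] <- size[p] + size[ch]
    inq[p] <- inq[p] + inq[ch]
  }
  idx <- (n + 1L):m
  any((size[idx] == k & inq[idx] == k) |
        (size[idx] == n - k & inq[idx] == 0L))
}

#' Majority-rule consensus tree
#'
#' Retains exactly the non-trivial splits whose frequency across the sample
#' is strictly greater than `threshold` (the CONSENSE majority-rule
#' convention; strict ">" guarantees pairwise compatibility for
#' `threshold >= 0.5`).  Retained edges are labelled with their frequency.
#'
#' @param sample a [tree_sample()].
#' @param threshold frequency cutoff (default 0.5).
#' @return a `phylo` with split frequencies as internal node labels.
#' @export
majority_consensus <- function(sample, threshold = 0.5) {
  stopifnot(inherits(sample, "tree_sample"))
  if (threshold < 0.5 || threshold >= 1)
    stop("threshold must be in [0.5, 1)")
  counts <- new.env(parent = emptyenv())
  for (tr in sample$trees) {
    for (key in .tree_split_keys(tr, sample$taxa)) {
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
    }
  }
  keys <- ls(counts)
  freq <- vapply(keys, function(k) counts[[k]], 0L) / length(sample$trees)
  keep <- freq > threshold
  bips <- lapply(strsplit(keys[keep], "\r", fixed = TRUE), function(s)
    structure(list(side = s, universe = sample$taxa),
              class = "bipartition"))
  tree_from_bipartitions(bips, universe = sample$taxa,
                         labels = format(round(freq[keep], 6)))
}

#' Support-versus-removal curve
#'
#' Assembles the slow-fast support curve: for each (fraction removed, tree
#' sample) pair, the frequency of the focal clade, ordered by fraction.
#' `n_trees` is reported per point so binomial error bars can be computed
#' downstream.
#'
#' @param samples list of `(fraction, sample)` pairs: either a named list
#'   `list(list(fraction =, sample =), ...)` or a list of [tree_sample()]
#'   with a numeric `fractions` vector.
#' @param taxa clade query as in [clade_frequency()].
#' @param fractions numeric vector of fractions when `samples` is a plain
#'   list of tree samples.
#' @return data.frame of class `support_curve`: columns `fraction`,
#'   `support`, `n_trees`, sorted by strictly increasing fraction.
#' @export
support_curve <- function(samples, taxa, fractions = NULL) {
  if (is.null(fractions)) {
    fractions <- vapply(samples, function(p) p$fraction, 0)
    samples <- lapply(samples, `[[`, "sample")
  }
  if (length(fractions) != length(samples))
    stop("one fraction per sample required")
  if (anyDuplicated(fractions))
    stop("duplicate fractions in curve input")
  u <- samples[[1L]]$taxa
  for (s in samples) {
    if (!identical(s$taxa, u))
      stop("tree samples do not share a common taxon set")
  }
  o <- order(fractions)
  out <- data.frame(
    fraction = fractions[o],
    support = vapply(samples[o], clade_frequency, 0, taxa = taxa),
    n_trees = vapply(samples[o], length, 0L))
  class(out) <- c("support_curve", "data.frame")
  out
}

#' Uncorrected pairwise distances of an alignment
#'
#' Proportion of differing columns (p-distance) between every pair of
#' sequences; columns where either sequence has a gap (`-`) or `X` are
#' excluded for that pair.
#'
#' @param aln an [alignment()].
#' @return symmetric numeric matrix with taxon dimnames.
#' @export
p_distance <- function(aln) {
  m <- alignment_matrix(aln)
  n <- nrow(m)
  ok <- !(m == "-" | m == "X" | m == "x")
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      use <- ok[i, ] & ok[j, ]
      nu <- sum(use)
      d[i, j] <- d[j, i] <-
        if (nu == 0L) 0 else sum(m[i, use] != m[j, use]) / nu
    }
  }
  d
}

#' Bootstrap sample of neighbour-joining distance trees
#'
#' A lightweight stand-in for maximum-likelihood bootstrap inference, used
#' to regenerate tree samples per stripped alignment subset: columns are
#' resampled with replacement, p-distances computed, and a neighbour-joining
#' tree built per replicate.
#'
#' @param aln an [alignment()] with at least 4 sequences.
#' @param n_replicates number of bootstrap trees (default 100).
#' @param seed integer seed; the sample is deterministic per seed.
#' @return a [tree_sample()].
#' @export
distance_bootstrap <- function(aln, n_replicates = 100, seed = 1) {
  stopifnot(inherits(aln, "aa_alignment"), aln$n_seq >= 4L)
  m <- alignment_matrix(aln)
  trees <- with_seed(seed, {
    lapply(seq_len(n_replicates), function(b) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      mb <- m[, cols, drop = FALSE]
      n <- nrow(mb)
      d <- matrix(0, n, n, dimnames = list(rownames(mb), rownames(mb)))
      for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
          d[i, j] <- d[j, i] <- mean(mb[i, ] != mb[j, ])
        }
      }
      ape::nj(d)
    })
  })
  tree_sample(trees)
}
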