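#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the base RNG seeded to `seed`, then restores the
#' previous RNG state, so generators are deterministic per seed without
#' clobbering the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  code
}

#' Simulate a random binary unrooted tree
#'
#' Labels are `t001..tN`; branch lengths are exponential with mean
#' `br_mean` (0.15 expected substitutions/site by default, a typical
#' phylogenomic scale).
#'
#' @param n_taxa number of leaves (>= 4).
#' @param seed integer seed (same seed, same tree).
#' @param br_mean mean branch length.
#' @return an unrooted binary `phylo`.
#' @export
simulate_tree <- function(n_taxa, seed = 1, br_mean = 0.15) {
  if (n_taxa < 4L) stop("n_taxa must be >= 4")
  with_seed(seed, {
    tr <- ape::rtree(n_taxa, rooted = FALSE,
                     br = function(k) stats::rexp(k, rate = 1 / br_mean))
    tr$tip.label <- sprintf("t%03d",
                            as.integer(sub("^t", "", tr$tip.label)))
    tr
  })
}

.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "", fixed = TRUE)[[1L]]

# simulate `length(rates)` independent sites on `tree` under a 20-state
# equal-exchangeability (Poisson-style) process; `rates` are per-site
# branch-length multipliers.  Returns an integer matrix tips x sites.
.simulate_sites <- function(tree, rates) {
  if (is.null(tree$edge.length))
    stop("tree must have branch lengths to simulate sequences")
  ns <- length(rates)
  n <- length(tree$tip.label)
  tree <- stats::reorder(tree, "cladewise")   # parents before children
  nnode <- n + tree$Nnode
  states <- matrix(0L, nnode, ns)
  root <- tree$edge[1L, 1L]
  states[root, ] <- sample.int(20L, ns, replace = TRUE)
  for (r in seq_len(nrow(tree$edge))) {
    p <- tree$edge[r, 1L]
    ch <- tree$edge[r, 2L]
    d <- tree$edge.length[r] * rates
    p_same <- 1 / 20 + 19 / 20 * exp(-20 / 19 * d)
    stay <- stats::runif(ns) < p_same
    jump <- sample.int(19L, ns, replace = TRUE)
    st <- states[p, ]
    st[!stay] <- ((st[!stay] - 1L + jump[!stay]) %% 20L) + 1L
    states[ch, ] <- st
  }
  states[seq_len(n), , drop = FALSE]
}

#' Simulate an alignment with heterogeneous site rates
#'
#' Sites evolve on `tree` under an equal-exchangeability amino-acid process
#' with per-site rate multipliers drawn from a gamma distribution with
#' shape `gamma_shape` and mean 1.  Optionally, the `conflict_fraction`
#' of sites with the *highest* rate multipliers are instead simulated on an
#' NNI rearrangement of the tree across `conflict_split`, planting a
#' conflicting phylogenetic signal concentrated in the fastest sites — the
#' situation progressive fast-site removal is designed to expose.
#'
#' @param tree a binary unrooted `phylo` with branch lengths.
#' @param length number of columns (>= 20).
#' @param gamma_shape gamma shape alpha for among-site rate heterogeneity.
#' @param conflict_fraction fraction of fastest sites carrying the
#'   conflicting topology, in `[0, 1]`.
#' @param seed integer seed.
#' @param conflict_split the [bipartition()] (or taxon vector) across whose
#'   edge the conflicting NNI is applied; default: the first non-trivial
#'   split of `tree`.
#' @return list: `alignment`, `rates` (true multipliers, a [site_rates()]),
#'   `conflict_sites` (sorted column indices, empty when fraction is 0)
#'   and `conflict_tree` (the rearranged topology, `NULL` when unused).
#' @export
simulate_alignment_with_rates <- function(tree, length, gamma_shape = 1,
                                          conflict_fraction = 0, seed = 1,
                                          conflict_split = NULL) {
  stopifnot(inherits(tree, "phylo"))
  n_sites <- as.integer(length)
  length <- NULL  # the argument shadows base::length; use n_sites below
  if (n_sites < 20L) stop("length must be >= 20")
  if (conflict_fraction < 0 || conflict_fraction > 1)
    stop("conflict_fraction must be in [0, 1]")
  with_seed(seed, {
    rates <- stats::rgamma(n_sites, shape = gamma_shape, rate = gamma_shape)
    k <- .round_half_up(conflict_fraction * n_sites)
    conflict <- if (k > 0L) sort(rank_sites_by_rate(rates)[seq_len(k)])
    else integer(0)
    alt <- NULL
    states <- .simulate_sites(tree, rates)
    if (k > 0L) {
      alt <- nni_rearrange(tree, conflict_split)
      alt_states <- .simulate_sites(alt, rates[conflict])
      states[, conflict] <- alt_states[match(tree$tip.label,
                                             alt$tip.label), ,
                                       drop = FALSE]
    }
    seqs <- apply(states, 1L, function(s)
      paste(.aa_alphabet[s], collapse = ""))
    list(alignment = alignment(tree$tip.label, seqs),
         rates = site_rates(rates),
         conflict_sites = conflict,
         conflict_tree = alt)
  })
}

# ---- NNI via split surgery -------------------------------------------------
#
# For a binary unrooted tree, a nearest-neighbour interchange across an
# internal edge replaces exactly one split: if the edge's side S has child
# clades A and B and its parent-side sibling clade is T, the rearranged
# tree's split set swaps S = A|B for A|T (or B|T).  Operating on the clade
# family avoids any rooted-tree surgery.

# maximal clades (or singleton tips) composing `s` within laminar family
.clade_children <- function(s, clades) {
  inside <- clades[vapply(clades, function(cl)
    length(cl) < length(s) && all(cl %in% s), TRUE)]
  keep <- rep(TRUE, length(inside))
  for (i in seq_along(inside)) {
    for (j in seq_along(inside)) {
      if (i != j && keep[j] &&
          length(inside[[i]]) < length(inside[[j]]) &&
          all(inside[[i]] %in% inside[[j]])) keep[i] <- FALSE
    }
  }
  maximal <- inside[keep]
  covered <- unlist(maximal)
  children <- c(maximal, as.list(setdiff(s, covered)))
  children[order(vapply(children, min, ""))]
}

#' Nearest-neighbour interchange across a split
#'
#' Returns the tree obtained by one NNI across the internal edge defined by
#' `split`.  Of the two possible interchanges, `which` selects the child
#' clade of the split side that is swapped with the parent-side sibling.
#' Branch lengths are dropped (the result is a topology).
#'
#' @param tree a binary unrooted `phylo` (>= 4 leaves).
#' @param split a [bipartition()] of the tree, or a taxon vector for one
#'   side; default: the tree's first non-trivial split.
#' @param which 1 or 2.
#' @return a `phylo` topology.
#' @export
nni_rearrange <- function(tree, split = NULL, which = 1) {
  bips <- tree_bipartitions(tree)
  if (length(bips) == 0L) stop("tree has no internal edge to rearrange")
  universe <- bips[[1L]]$universe
  if (is.null(split)) {
    focal <- bips[[1L]]
  } else {
    focal <- if (inherits(split, "bipartition")) split
    else bipartition(split, universe)
  }
  keys <- vapply(bips, split_key, "")
  if (!split_key(focal) %in% keys)
    stop("the given split is not an edge of the tree")
  clades <- lapply(bips, `[[`, "side")
  s <- focal$side
  children <- .clade_children(s, clades)
  if (length(children) != 2L)
    stop("NNI requires a binary tree (split side has ",
         length(children), " children)")
  above <- clades[vapply(clades, function(cl)
    length(cl) > length(s) && all(s %in% cl), TRUE)]
  parent <- if (length(above)) {
    above[[which.min(vapply(above, length, 0L))]]
  } else {
    setdiff(universe, universe[1L])   # edge abuts the reference taxon
  }
  sibling <- setdiff(parent, s)
  a <- children[[if (which == 1) 1L else 2L]]
  new_side <- sort(c(a, sibling))
  clades[[match(split_key(focal), keys)]] <- new_side
  out <- .tree_from_clades(clades, universe)
  if (!is.null(tree$edge.length))
    out <- .transfer_edge_lengths(tree, out, split_key(focal))
  out
}

# canonical-side key of every edge's split (trivial tip splits included)
.edge_split_keys <- function(tree) {
  tl <- sort(tree$tip.label)
  n <- length(tl)
  tree <- stats::reorder(tree, "postorder")
  sets <- c(as.list(tree$tip.label), vector("list", tree$Nnode))
  for (r in seq_len(nrow(tree$edge))) {
    p <- tree$edge[r, 1L]
    ch <- tree$edge[r, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  keys <- vapply(seq_len(nrow(tree$edge)), function(r) {
    s <- sets[[tree$edge[r, 2L]]]
    if (tl[1L] %in% s) s <- setdiff(tl, s)
    paste(sort(s), collapse = "\r")
  }, "")
  list(tree = tree, keys = keys)
}

# give `to` (an NNI rearrangement of `from`) branch lengths by split
# identity; the new focal edge inherits the replaced edge's length
.transfer_edge_lengths <- function(from, to, focal_key) {
  src <- .edge_split_keys(from)
  lengths <- stats::setNames(src$tree$edge.length, src$keys)
  dst <- .edge_split_keys(to)
  len <- lengths[dst$keys]
  len[is.na(len)] <- lengths[[focal_key]]
  out <- dst$tree
  out$edge.length <- unname(len)
  out
}

#' Extreme internal split of a tree
#'
#' The split of the internal edge with the smallest (most contested) or
#' largest (best supported) branch length — the usual focal edges whose
#' support a fast-site-removal analysis interrogates.
#'
#' @param tree a `phylo` with branch lengths.
#' @param which `"shortest"` or `"longest"`.
#' @return a [bipartition()].
#' @export
internal_split <- function(tree, which = c("shortest", "longest")) {
  which <- match.arg(which)
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  es <- .edge_split_keys(tree)
  n <- ape::Ntip(es$tree)
  sizes <- lengths(strsplit(es$keys, "\r", fixed = TRUE))
  internal <- sizes >= 2L & sizes <= n - 2L
  if (!any(internal)) stop("tree has no internal edge")
  len <- es$tree$edge.length[internal]
  pick <- if (which == "shortest") which.min(len) else which.max(len)
  key <- es$keys[internal][pick]
  bipartition(strsplit(key, "\r", fixed = TRUE)[[1L]],
              sort(tree$tip.label))
}

#' Simulate a bootstrap-style tree sample with a planted clade frequency
#'
#' Each replicate independently keeps the focal edge of `base_tree` with
#' probability `p`; otherwise one NNI (chosen at random between the two
#' possible interchanges) is applied across it.  The realized focal-clade
#' frequency is therefore Binomial(`n_trees`, `p`) / `n_trees`.
#'
#' @param base_tree a binary unrooted `phylo`.
#' @param focal a [bipartition()] of `base_tree` (or a taxon vector).
#' @param p planted frequency in `[0, 1]`.
#' @param n_trees number of replicates.
#' @param seed integer seed.
#' @return a [tree_sample()].
#' @export
simulate_tree_sample <- function(base_tree, focal, p, n_trees = 1000,
                                 seed = 1) {
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  if (n_trees < 1L) stop("n_trees must be >= 1")
  alt1 <- nni_rearrange(base_tree, focal, which = 1)
  alt2 <- nni_rearrange(base_tree, focal, which = 2)
  with_seed(seed, {
    keep <- stats::runif(n_trees) < p
    coin <- stats::runif(n_trees) < 0.5
    trees <- lapply(seq_len(n_trees), function(i) {
      if (keep[i]) base_tree else if (coin[i]) alt1 else alt2
    })
    tree_sample(trees)
  })
}

#' Simulate species x ortholog count profiles with planted groups
#'
#' Two-level generator emulating the coherent gene-repertoire structure of
#' real presence/absence matrices: each (group, ortholog) pair first draws
#' a retention probability from a Beta distribution whose mean is the
#' group's retention (`concentration` = a + b; the default 0.5 is strongly
#' U-shaped, so most orthologs are coherently present or coherently absent
#' within a group), then each species draws presence Bernoulli with its
#' group's per-ortholog probability.  The marginal presence probability of
#' every cell equals the group retention; retention 0 or 1 is degenerate
#' (all-absent / all-present).  Present orthologs are duplicated (count 2)
#' with probability `dup_prob` so downstream binarization is exercised.
#'
#' Without the ortholog-level layer (i.e. independent Bernoulli draws at
#' the group retention), species rows would be pairwise independent and
#' Pearson similarity would carry no group signal at all; the hierarchy is
#' what makes the correlation-based comparative stage recover the planted
#' groups.
#'
#' @param group_spec data.frame with columns `group`, `n_species`,
#'   `retention` (>= 2 groups, each >= 2 species, retention in `[0, 1]`).
#' @param n_orthologs number of ortholog columns.
#' @param seed integer seed.
#' @param concentration Beta concentration of the per-ortholog retention
#'   (default 0.5); larger values shrink ortholog-level variation.
#' @param dup_prob probability that a present ortholog has count 2
#'   (default 0.2).
#' @return list: `counts` (integer matrix in {0,1,2}, species x orthologs),
#'   `groups` (named character vector, species -> group) and `retention`
#'   (group x ortholog matrix of the latent per-ortholog probabilities).
#' @export
simulate_profiles <- function(group_spec, n_orthologs, seed = 1,
                              concentration = 0.5, dup_prob = 0.2) {
  gs <- as.data.frame(group_spec)
  if (!all(c("group", "n_species", "retention") %in% names(gs)))
    stop("group_spec needs columns group, n_species, retention")
  if (nrow(gs) < 2L) stop("need at least 2 groups")
  if (any(gs$n_species < 2L)) stop("each group needs at least 2 species")
  if (any(gs$retention < 0 | gs$retention > 1))
    stop("retention probabilities must be in [0, 1]")
  species <- unlist(lapply(seq_len(nrow(gs)), function(i)
    sprintf("%s_sp%02d", gs$group[i], seq_len(gs$n_species[i]))))
  groups <- rep(as.character(gs$group), gs$n_species)
  names(groups) <- species
  with_seed(seed, {
    ret <- t(vapply(gs$retention, function(m) {
      if (m <= 0 || m >= 1) return(rep(m, n_orthologs))
      stats::rbeta(n_orthologs, m * concentration,
                   (1 - m) * concentration)
    }, numeric(n_orthologs)))
    rownames(ret) <- as.character(gs$group)
    prob <- ret[groups, , drop = FALSE]
    present <- matrix(stats::rbinom(length(prob), 1L, prob),
                      nrow = length(species))
    dup <- matrix(stats::rbinom(length(prob), 1L, dup_prob),
                  nrow = length(species))
    counts <- present * (1L + dup)
    dimnames(counts) <- list(species,
                             sprintf("OG%04d", seq_len(n_orthologs)))
    colnames(ret) <- colnames(counts)
    list(counts = counts, groups = groups, retention = ret)
  })
}

#' Simulate a homology hit table with planted query classes
#'
#' Generates a ranked hit table whose queries fall into five planted
#' classes, chosen so each decontamination rule engine fires on exactly its
#' class: `target` (clean eukaryotic, kept), `prokaryote` (bestsum taxon
#' bacterial/archaeal/viral, removed by the cellular-origin screen),
#' `host_first` (rank-1 stramenopile below the e-value cutoff, removed by
#' the first-hit screen), `no_hit` (no rows, removed) and `host_identity`
#' (best stramenopile identity > 95%, removed by the identity screen).
#' Bit scores decrease with rank and reported e-values are <= 1e-10.
#'
#' @param composition named integer vector with (a subset of) the five
#'   class names above; total >= 1.
#' @param seed integer seed.
#' @return list: `hits` (validated hit data.frame) and `truth` (data.frame
#'   qseqid, class).
#' @export
simulate_hit_table <- function(composition, seed = 1) {
  classes <- c("target", "prokaryote", "host_first", "no_hit",
               "host_identity")
  comp <- stats::setNames(rep(0L, 5L), classes)
  unknown <- setdiff(names(composition), classes)
  if (length(unknown))
    stop("unknown classes: ", paste(unknown, collapse = ", "))
  comp[names(composition)] <- as.integer(composition)
  if (any(comp < 0)) stop("counts must be non-negative")
  total <- sum(comp)
  if (total < 1L) stop("at least one query required")

  fungi <- c("Spizellomyces punctatus", "Batrachochytrium dendrobatidis",
             "Agaricus bisporus", "Cryptococcus neoformans",
             "Allomyces macrogynus")
  stram <- c("Nannochloropsis gaditana", "Phytophthora sojae",
             "Aureococcus anophagefferens", "Aphanomyces invadans")
  proks <- data.frame(
    species = c("Escherichia coli", "Bacillus subtilis",
                "Sulfolobus solfataricus", "Haloferax volcanii",
                "Acanthamoeba polyphaga mimivirus"),
    superkingdom = c("Bacteria", "Bacteria", "Archaea", "Archaea",
                     "Viruses"), stringsAsFactors = FALSE)

  with_seed(seed, {
    labels <- sample(rep(classes, comp))   # shuffle query order
    qids <- sprintf("q%04d", seq_len(total))
    rows <- vector("list", total)
    for (i in seq_len(total)) {
      cls <- labels[i]
      if (cls == "no_hit") next
      n_hits <- sample(3:12, 1L)
      bit <- round(stats::runif(1L, 180, 320) -
                     cumsum(c(0, stats::runif(n_hits - 1L, 1, 15))), 1)
      ev <- 10^-stats::runif(n_hits, 11, 60)
      if (cls == "prokaryote") {
        pick <- sample.int(nrow(proks), n_hits, replace = TRUE)
        sp <- proks$species[pick]
        sk <- proks$superkingdom[pick]
        fl <- "prokaryote"
        pid <- round(stats::runif(n_hits, 30, 90), 1)
      } else {
        sp <- sample(fungi, n_hits, replace = TRUE)
        sk <- rep("Eukaryota", n_hits)
        fl <- rep("fungi", n_hits)
        pid <- round(stats::runif(n_hits, 30, 90), 1)
        if (cls == "host_first") {
          sp[1L] <- sample(stram, 1L)
          fl <- c("stramenopile", fl[-1L])
          pid[1L] <- round(stats::runif(1L, 40, 95), 1)
        } else if (cls == "host_identity") {
          # last-ranked (lowest-scoring) hit is the near-identical host
          # protein, so the bestsum winner stays fungal
          sp[n_hits] <- sample(stram, 1L)
          fl[n_hits] <- "stramenopile"
          pid[n_hits] <- round(stats::runif(1L, 95.1, 100), 1)
        }
      }
      rows[[i]] <- data.frame(
        qseqid = qids[i], sseqid = sprintf("s%05d", sample.int(9e4, n_hits)),
        rank = seq_len(n_hits), pident = pid, evalue = ev, bitscore = bit,
        superkingdom = sk, lineage_flags = fl, species = sp,
        stringsAsFactors = FALSE)
    }
    hits <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    if (is.null(hits)) {
      hits <- data.frame(qseqid = character(), sseqid = character(),
                         rank = integer(), pident = numeric(),
                         evalue = numeric(), bitscore = numeric(),
                         superkingdom = character(),
                         lineage_flags = character(),
                         species = character(), stringsAsFactors = FALSE)
    }
    list(hits = validate_hits(hits),
         truth = data.frame(qseqid = qids, class = labels,
                            stringsAsFactors = FALSE))
  })
}
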