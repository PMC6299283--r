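#' Parse a newick string into a tree
#'
#' Trees are represented as `ape` `phylo` objects and treated as unrooted for
#' all split operations.  Internal node labels are preserved and interpreted
#' as support values when numeric (the ultrafast-bootstrap convention).
#'
#' @param text a single newick string terminated by `;`.
#' @return a `phylo` object.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty newick string")
  # cheap pre-check so parse errors carry a character position
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("unbalanced ')' at position ", i, " in newick string")
    }
  }
  if (depth != 0L)
    stop("unbalanced '(' in newick string (", depth, " unclosed)")
  if (!endsWith(text, ";"))
    stop("newick string must end with ';'")
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("newick parse error: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("newick parse error: unreadable tree")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup))
    stop("duplicate leaf labels: ", paste(unique(dup), collapse = ", "))
  tree
}

#' Serialize a tree to newick
#'
#' @param tree a `phylo` object.
#' @return a newick string ending in `;`.  Re-parsing it yields an identical
#'   leaf set and bipartition set.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree)
}

#' Bipartition (unrooted split) of a taxon set
#'
#' A bipartition is stored canonically by the side that does **not** contain
#' the lexicographically smallest taxon of the universe, which makes equality
#' order-independent and hashable.
#'
#' @param side character vector of taxa on one side of the split.
#' @param universe character vector of all taxa.
#' @return an object of class `bipartition` with sorted `side` and
#'   `universe` fields.
#' @export
bipartition <- function(side, universe) {
  universe <- sort(unique(as.character(universe)))
  side <- unique(as.character(side))
  if (!all(side %in% universe))
    stop("side contains taxa outside the universe: ",
         paste(setdiff(side, universe), collapse = ", "))
  if (length(side) == 0L || length(side) == length(universe))
    stop("side must be a proper non-empty subset of the universe")
  if (universe[1L] %in% side) side <- setdiff(universe, side)
  structure(list(side = sort(side), universe = universe),
            class = "bipartition")
}

#' @export
print.bipartition <- function(x, ...) {
  cat("Bipartition: {", paste(x$side, collapse = ","), "} | {",
      paste(setdiff(x$universe, x$side), collapse = ","), "}\n", sep = "")
  invisible(x)
}

#' @rdname bipartition
#' @param bip a `bipartition`.
#' @return `split_key()`: a single string identifying the canonical side,
#'   usable as a hash key.
#' @export
split_key <- function(bip) {
  paste(bip$side, collapse = "\r")
}

#' @export
`==.bipartition` <- function(e1, e2) {
  identical(e1$universe, e2$universe) && identical(e1$side, e2$side)
}

# Clade (tip set) of every internal node, for the unrooted form of `tree`.
# Returns a list of character vectors; may include trivial n-1 sets when the
# pseudo-root is attached next to a leaf.
.internal_clades <- function(tree) {
  tree <- ape::collapse.singles(tree)
  if (!ape::is.rooted(tree) || ape::Ntip(tree) < 3L) {
    utree <- tree
  } else {
    utree <- ape::unroot(tree)
  }
  n <- ape::Ntip(utree)
  if (n < 4L || utree$Nnode < 2L) return(list())
  utree <- stats::reorder(utree, "postorder")
  sets <- vector("list", n + utree$Nnode)
  for (i in seq_len(n)) sets[[i]] <- utree$tip.label[i]
  for (k in seq_len(nrow(utree$edge))) {
    p <- utree$edge[k, 1L]
    ch <- utree$edge[k, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  root <- n + 1L
  internal <- setdiff(unique(utree$edge[, 1L]), root)
  lab <- if (!is.null(utree$node.label)) utree$node.label else NULL
  out <- lapply(internal, function(v) sets[[v]])
  attr(out, "support") <- if (!is.null(lab)) lab[internal - n] else NULL
  out
}

#' Extract the bipartitions of a tree
#'
#' One bipartition per internal edge of the unrooted tree, canonicalized.
#' Polytomies simply yield fewer splits; a fully resolved (binary) unrooted
#' tree with n leaves has exactly n - 3 non-trivial splits.
#'
#' @param tree a `phylo` object.
#' @param include_trivial if `TRUE`, also return the n single-leaf splits.
#' @return list of [bipartition()] objects (possibly empty).
#' @export
tree_bipartitions <- function(tree, include_trivial = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  taxa <- sort(tree$tip.label)
  n <- length(taxa)
  clades <- .internal_clades(tree)
  sides <- lapply(clades, function(s) {
    if (taxa[1L] %in% s) setdiff(taxa, s) else sort(s)
  })
  keep <- vapply(sides, function(s) {
    k <- length(s)
    k >= 2L && k <= n - 2L
  }, TRUE)
  sides <- unique(sides[keep])
  bips <- lapply(sides, function(s)
    structure(list(side = s, universe = taxa), class = "bipartition"))
  if (include_trivial) {
    triv <- lapply(taxa[-1L], function(t)
      structure(list(side = t, universe = taxa), class = "bipartition"))
    compl <- structure(list(side = sort(taxa[-1L]), universe = taxa),
                       class = "bipartition")
    bips <- c(bips, triv, list(compl))
  }
  bips
}

# Canonical split keys of a tree (fast path used by clade_frequency).
.tree_split_keys <- function(tree, taxa) {
  clades <- .internal_clades(tree)
  n <- length(taxa)
  keys <- vapply(clades, function(s) {
    if (taxa[1L] %in% s) s <- setdiff(taxa, s) else s <- sort(s)
    if (length(s) < 2L || length(s) > n - 2L) return(NA_character_)
    paste(s, collapse = "\r")
  }, "")
  unique(keys[!is.na(keys)])
}

#' Bootstrap-style tree sample
#'
#' An ordered collection of equally weighted trees over a common leaf set,
#' e.g. the replicate trees of an ultrafast-bootstrap run (one newick per
#' line).
#'
#' @param trees list of `phylo` objects (or a `multiPhylo`).
#' @return object of class `tree_sample` with fields `trees` and `taxa`
#'   (sorted common leaf set).
#' @export
tree_sample <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (inherits(trees, "multiPhylo")) {
    # [[ decompresses shared tip labels of compact multiPhylo objects
    trees <- lapply(seq_along(trees), function(i) trees[[i]])
  }
  trees <- unclass(trees)
  if (length(trees) == 0L) stop("empty tree sample")
  taxa <- sort(trees[[1L]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), taxa))
      stop("tree ", i, " has a different leaf set than tree 1")
  }
  structure(list(trees = trees, taxa = taxa), class = "tree_sample")
}

#' @export
print.tree_sample <- function(x, ...) {
  cat("Tree sample: ", length(x$trees), " trees over ", length(x$taxa),
      " taxa\n", sep = "")
  invisible(x)
}

#' @export
length.tree_sample <- function(x) length(x$trees)

#' Read a tree sample (one newick per line)
#'
#' @param path file with one newick tree per non-empty line (UFBOOT dialect).
#' @return a [tree_sample()]; file order preserved, `taxa` taken from the
#'   first tree.  Any tree whose leaf set differs triggers an error naming
#'   the offending line.
#' @export
read_tree_sample <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("no trees in ", path)
  trees <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    trees[[i]] <- tryCatch(parse_newick(lines[i]), error = function(e)
      stop("line ", lineno[i], ": ", conditionMessage(e)))
  }
  taxa <- sort(trees[[1L]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), taxa))
      stop("line ", lineno[i], ": leaf set differs from first tree")
  }
  structure(list(trees = trees, taxa = taxa), class = "tree_sample")
}

#' Write a tree sample (one newick per line)
#'
#' @param sample a [tree_sample()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tree_sample <- function(sample, path) {
  stopifnot(inherits(sample, "tree_sample"))
  writeLines(vapply(sample$trees, write_newick, ""), path)
  invisible(path)
}

# ---- building trees from compatible splits --------------------------------
#
# A laminar family of clades (each excluding the reference taxon, i.e. the
# lexicographically smallest one) determines an unrooted topology; used by
# the majority-rule consensus and by NNI rearrangement via split surgery.

# newick for the subtree spanned by `members`, nesting the clades of
# `clades` that fall inside it; `labels[[key]]` gives an optional node label.
.nest_newick <- function(members, clades, labels) {
  inside <- clades[vapply(clades, function(cl)
    length(cl) < length(members) && all(cl %in% members), TRUE)]
  covered <- character(0)
  parts <- character(0)
  if (length(inside)) {
    sizes <- vapply(inside, length, 0L)
    ord <- order(-sizes, vapply(inside, `[`, "", 1L))
    for (i in ord) {
      cl <- inside[[i]]
      if (any(cl %in% covered)) next  # nested under an earlier maximal clade
      key <- paste(sort(cl), collapse = "\r")
      lab <- if (!is.null(labels) && !is.null(labels[[key]]))
        labels[[key]] else ""
      parts <- c(parts,
                 paste0(.nest_newick(cl, inside, labels), lab))
      covered <- c(covered, cl)
    }
  }
  singles <- setdiff(members, covered)
  paste0("(", paste(c(parts, sort(singles)), collapse = ","), ")")
}

# clades: list of character vectors, all excluding `ref`; universe includes
# ref.  Returns a phylo whose non-trivial splits are exactly `clades`
# (restricted to sizes 2..n-2).
.tree_from_clades <- function(clades, universe, labels = NULL) {
  universe <- sort(universe)
  ref <- universe[1L]
  rest <- setdiff(universe, ref)
  clades <- lapply(clades, sort)
  body <- .nest_newick(rest, clades, labels)
  # splice ref into the top-level multifurcation
  nwk <- paste0("(", ref, ",", substr(body, 2L, nchar(body)), ";")
  parse_newick(nwk)
}

#' Build a tree from a set of compatible bipartitions
#'
#' Reconstructs the (possibly multifurcating) unrooted topology containing
#' exactly the given non-trivial splits.  The splits must form a laminar
#' (pairwise compatible) family, as majority-rule consensus splits do.
#'
#' @param bips list of [bipartition()] over a common universe (may be empty,
#'   yielding a star tree).
#' @param universe taxon set; required when `bips` is empty.
#' @param labels optional character vector, one label per bipartition,
#'   attached as internal node labels.
#' @return a `phylo` object.
#' @export
tree_from_bipartitions <- function(bips, universe = NULL, labels = NULL) {
  if (length(bips)) {
    u <- bips[[1L]]$universe
    if (!is.null(universe) && !identical(sort(universe), u))
      stop("universe does not match the bipartitions")
    universe <- u
  }
  if (is.null(universe)) stop("universe required for an empty split set")
  labmap <- NULL
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(bips))
    labmap <- as.list(as.character(labels))
    names(labmap) <- vapply(bips, split_key, "")
  }
  .tree_from_clades(lapply(bips, `[[`, "side"), universe, labmap)
}
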