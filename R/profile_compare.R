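#' Build a binary ortholog presence/absence profile
#'
#' Species-wise ortholog counts are binarized (presence = count >= 1).  By
#' default, orthologs absent from every species are removed — they carry no
#' comparative signal — and their ids recorded.
#'
#' @param counts numeric matrix or data.frame of non-negative integer
#'   counts; rows = species, columns = ortholog ids (dimnames required).
#' @param drop_empty drop all-zero columns (default `TRUE`).
#' @return 0/1 integer matrix of class `binary_profile`; attribute
#'   `dropped` lists removed ortholog ids.
#' @export
build_binary_profile <- function(counts, drop_empty = TRUE) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have species row names and ortholog column names")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("species and ortholog labels must be unique")
  if (!is.numeric(counts) || anyNA(counts))
    stop("counts must be numeric and complete")
  if (any(counts < 0))
    stop("negative counts at ",
         paste(head(which(counts < 0)), collapse = ", "))
  profile <- matrix(as.integer(counts >= 1), nrow(counts), ncol(counts),
                    dimnames = dimnames(counts))
  dropped <- character(0)
  if (drop_empty) {
    empty <- colSums(profile) == 0L
    dropped <- colnames(profile)[empty]
    profile <- profile[, !empty, drop = FALSE]
  }
  structure(profile, class = c("binary_profile", class(profile)),
            dropped = dropped)
}

#' Pearson similarity between species profiles
#'
#' Pairwise Pearson correlation of the 0/1 rows (on binary vectors this is
#' the phi coefficient).  A species whose profile is constant (all 0 or all
#' 1) has no defined correlation and is reported as an error rather than
#' silently coerced, since that would distort the ordination.
#'
#' @param profile a [build_binary_profile()] matrix (rows = species).
#' @return symmetric species x species matrix of r in `[-1, 1]`, unit
#'   diagonal, class `similarity_matrix`.
#' @export
pearson_similarity <- function(profile) {
  m <- unclass(profile)
  if (nrow(m) < 2L) stop("need at least 2 species")
  v <- apply(m, 1L, stats::var)
  if (any(v == 0))
    stop("constant profile (r undefined) for species: ",
         paste(rownames(m)[v == 0], collapse = ", "))
  r <- stats::cor(t(m))
  diag(r) <- 1
  structure(r, class = c("similarity_matrix", "matrix", "array"))
}

#' Dissimilarity D = 1 - r
#'
#' The complementary species distance matrix: elementwise `1 - r`, zero
#' diagonal, entries in `[0, 2]`.  Note that `1 - r` need not satisfy the
#' triangle inequality, so PCoA on it may produce negative eigenvalues.
#'
#' @param sim a [pearson_similarity()] matrix.
#' @return symmetric matrix of class `dissimilarity_matrix`.
#' @export
to_dissimilarity <- function(sim) {
  d <- 1 - unclass(sim)
  diag(d) <- 0
  structure(d, class = c("dissimilarity_matrix", "matrix", "array"))
}

#' Principal coordinate analysis
#'
#' Classical (metric) multidimensional scaling: Gower double-centering of
#' `-D^2 / 2` followed by eigendecomposition.  Coordinates are eigenvectors
#' scaled by the square root of their (positive) eigenvalues.  Negative
#' eigenvalues — expected when D is non-Euclidean, as `1 - r` on binary
#' profiles generally is — are reported but not corrected; explained
#' fractions are normalized over the positive part of the spectrum only.
#'
#' @param d square symmetric non-negative matrix with zero diagonal.
#' @param k number of axes to return (default 2).
#' @return list of class `pcoa_result`: `coordinates` (n x k'), `eigenvalues`
#'   (full spectrum, descending), `explained` (fraction per positive axis),
#'   `broken_stick` (expectation per positive axis), `n_positive`.
#' @export
pcoa <- function(d, k = 2) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n != ncol(d) || max(abs(d - t(d))) > 1e-8)
    stop("d must be square and symmetric")
  if (any(d < 0)) stop("d must be non-negative")
  if (any(abs(diag(d)) > 1e-12)) stop("d must have a zero diagonal")
  a <- -0.5 * d^2
  centred <- sweep(sweep(a, 1L, rowMeans(a)), 2L, colMeans(a)) + mean(a)
  eig <- eigen((centred + t(centred)) / 2, symmetric = TRUE)
  lambda <- eig$values
  tol <- 1e-9 * max(abs(lambda), 1e-300)
  pos <- which(lambda > tol)
  n_pos <- length(pos)
  k_eff <- min(k, n_pos)
  if (k_eff < k)
    warning("only ", n_pos, " positive eigenvalue(s); returning ", k_eff,
            " axis/axes")
  if (k_eff == 0L) {
    coords <- matrix(0, n, 0, dimnames = list(rownames(d), NULL))
  } else {
    coords <- eig$vectors[, seq_len(k_eff), drop = FALSE] %*%
      diag(sqrt(lambda[seq_len(k_eff)]), k_eff)
    dimnames(coords) <- list(rownames(d),
                             paste0("Axis", seq_len(k_eff)))
  }
  explained <- if (n_pos) lambda[pos] / sum(lambda[pos]) else numeric(0)
  structure(list(coordinates = coords,
                 eigenvalues = lambda,
                 explained = explained,
                 broken_stick = broken_stick(max(n_pos, 1L)),
                 n_positive = n_pos),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("PCoA: ", nrow(x$coordinates), " objects, ", ncol(x$coordinates),
      " axes returned, ", x$n_positive, " positive eigenvalues\n", sep = "")
  if (length(x$explained))
    cat("explained (first axes): ",
        paste(round(utils::head(x$explained, 4), 4), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Broken-stick expectations
#'
#' Null expectation for the fraction of variance on each ordination axis
#' when total variance is split at random: `E_i = (1/n) * sum_{j=i..n} 1/j`.
#' Decreasing in `i` and summing to 1.
#'
#' @param n_axes number of axes (>= 1).
#' @return numeric vector `E_1..E_n`.
#' @export
broken_stick <- function(n_axes) {
  n_axes <- as.integer(n_axes)
  if (is.na(n_axes) || n_axes < 1L) stop("n_axes must be >= 1")
  rev(cumsum(1 / rev(seq_len(n_axes)))) / n_axes
}

#' Compare explained variance to the broken-stick expectation
#'
#' The axis-retention criterion: an axis is meaningful when its explained
#' fraction strictly exceeds the broken-stick expectation for its rank.
#'
#' @param pcoa_result a [pcoa()] result.
#' @param n_axes number of leading axes to assess (default 2).
#' @return data.frame (axis, explained, expected, exceeds).
#' @export
compare_axes_to_broken_stick <- function(pcoa_result, n_axes = 2) {
  stopifnot(inherits(pcoa_result, "pcoa_result"))
  if (pcoa_result$n_positive < n_axes)
    stop("only ", pcoa_result$n_positive, " positive axes; cannot assess ",
         n_axes)
  expd <- pcoa_result$explained[seq_len(n_axes)]
  expc <- broken_stick(pcoa_result$n_positive)[seq_len(n_axes)]
  data.frame(axis = seq_len(n_axes), explained = expd, expected = expc,
             exceeds = expd > expc)
}

#' Ward hierarchical clustering
#'
#' Agglomerative clustering through the Lance-Williams recurrence.  The
#' default `ward2` dialect is Ward's criterion on the distances themselves
#' (squares internally, square-roots the merge heights — the `ward.D2`
#' convention); `ward1` applies the plain recurrence to the matrix as given
#' (the historical `ward.D`, appropriate when the input is already squared).
#' Ties are broken by the smallest (row, col) pair in label order and the
#' plotting leaf order is a left-before-right traversal, so results are
#' fully deterministic.
#'
#' @param d symmetric dissimilarity matrix with labels (or a `dist`).
#' @param variant `"ward2"` (default) or `"ward1"`.
#' @return object of class `ward_linkage`: `merge` (hclust-style matrix),
#'   `height`, `labels`, `order` (leaf order), `sizes`, `variant`.
#' @export
ward_cluster <- function(d, variant = c("ward2", "ward1")) {
  variant <- match.arg(variant)
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 objects to cluster")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("o", 1:n)
  labels <- rownames(d)
  work <- if (variant == "ward2") d^2 else d
  size <- rep.int(1L, n)
  id <- -(1:n)                # hclust convention: negative = singleton
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  members <- as.list(1:n)     # original object indices per active cluster
  for (step in seq_len(n - 1L)) {
    act <- which(active)
    best <- c(NA_integer_, NA_integer_)
    bestval <- Inf
    for (ii in seq_len(length(act) - 1L)) {
      i <- act[ii]
      js <- act[(ii + 1L):length(act)]
      vals <- work[i, js]
      jmin <- js[which.min(vals)]       # which.min: first minimum = tie rule
      if (min(vals) < bestval) {
        bestval <- min(vals)
        best <- c(i, jmin)
      }
    }
    i <- best[1L]; j <- best[2L]
    merge[step, ] <- c(id[i], id[j])
    height[step] <- if (variant == "ward2") sqrt(bestval) else bestval
    ni <- size[i]; nj <- size[j]
    for (kk in act) {
      if (kk == i || kk == j) next
      nk <- size[kk]
      newd <- ((ni + nk) * work[i, kk] + (nj + nk) * work[j, kk] -
                 nk * bestval) / (ni + nj + nk)
      work[i, kk] <- work[kk, i] <- newd
    }
    size[i] <- ni + nj
    id[i] <- step
    active[j] <- FALSE
    members[[i]] <- c(members[[i]], members[[j]])
  }
  order <- .linkage_leaf_order(merge, n)
  structure(list(merge = merge, height = height, labels = labels,
                 order = order, sizes = NULL, variant = variant),
            class = "ward_linkage")
}

# left-before-right recursive traversal of the merge history
.linkage_leaf_order <- function(merge, n) {
  walk <- function(node) {
    if (node < 0L) return(-node)
    c(walk(merge[node, 1L]), walk(merge[node, 2L]))
  }
  walk(nrow(merge))
}

#' @export
print.ward_linkage <- function(x, ...) {
  cat("Ward linkage (", x$variant, "): ", length(x$labels),
      " leaves, heights ", round(min(x$height), 4), "..",
      round(max(x$height), 4), "\n", sep = "")
  invisible(x)
}

#' @export
as.hclust.ward_linkage <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = x$variant,
                 call = match.call(), dist.method = "user"),
            class = "hclust")
}

#' Cut a Ward linkage into k clusters
#'
#' @param linkage a [ward_cluster()] result.
#' @param k number of clusters.
#' @return integer cluster membership named by labels.
#' @export
cut_linkage <- function(linkage, k) {
  stopifnot(inherits(linkage, "ward_linkage"))
  stats::cutree(as.hclust(linkage), k = k)
}

#' Order a matrix by clustering leaf orders for heatmap display
#'
#' Rows are ordered by the species linkage's leaf order and columns by the
#' ortholog linkage's leaf order; values are never mutated.  For similarity
#' heatmaps the conventional display clamps r to `[0, 1]`; the clamp range
#' is returned as metadata (`clamp` attribute) rather than applied to the
#' data.
#'
#' @param m matrix with row and column dimnames (binary profile or
#'   similarity matrix).
#' @param row_linkage [ward_cluster()] over the row labels (or `NULL` to
#'   keep row order).
#' @param col_linkage [ward_cluster()] over the column labels (or `NULL`).
#' @param clamp optional numeric length-2 display range recorded as
#'   metadata, e.g. `c(0, 1)` for similarity heatmaps.
#' @return the reordered matrix with attributes `row_order`, `col_order`
#'   and (optionally) `clamp`.
#' @export
heatmap_layout <- function(m, row_linkage = NULL, col_linkage = NULL,
                           clamp = NULL) {
  m <- as.matrix(unclass(m))
  ro <- seq_len(nrow(m))
  co <- seq_len(ncol(m))
  if (!is.null(row_linkage)) {
    if (!setequal(row_linkage$labels, rownames(m)))
      stop("row linkage labels do not match matrix rows")
    ro <- match(row_linkage$labels[row_linkage$order], rownames(m))
  }
  if (!is.null(col_linkage)) {
    if (!setequal(col_linkage$labels, colnames(m)))
      stop("column linkage labels do not match matrix columns")
    co <- match(col_linkage$labels[col_linkage$order], colnames(m))
  }
  out <- m[ro, co, drop = FALSE]
  attr(out, "row_order") <- rownames(m)[ro]
  attr(out, "col_order") <- colnames(m)[co]
  if (!is.null(clamp)) attr(out, "clamp") <- sort(as.numeric(clamp))
  out
}
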