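counts_mat <- function(values, species, orthologs) {
  matrix(values, nrow = length(species), byrow = TRUE,
         dimnames = list(species, orthologs))
}

test_that("binarization and empty-column filtering", {
  m <- counts_mat(c(0, 2, 1, 0), c("s1", "s2"), c("o1", "o2"))
  bp <- build_binary_profile(m)
  expect_equal(unclass(bp)[, ], counts_mat(c(0, 1, 1, 0),
                                           c("s1", "s2"), c("o1", "o2"))[, ])

  m2 <- counts_mat(c(1, 0, 3, 2, 0, 1), c("s1", "s2"),
                   c("o1", "o2", "o3"))
  bp2 <- build_binary_profile(m2)
  expect_equal(colnames(bp2), c("o1", "o3"))
  expect_equal(attr(bp2, "dropped"), "o2")
  bp2k <- build_binary_profile(m2, drop_empty = FALSE)
  expect_equal(ncol(bp2k), 3L)

  ones <- counts_mat(rep(1, 6), c("s1", "s2"), c("o1", "o2", "o3"))
  expect_true(all(build_binary_profile(ones) == 1L))
  expect_equal(attr(build_binary_profile(ones), "dropped"), character(0))

  m2[1, 1] <- -1
  expect_error(build_binary_profile(m2), "negative")
})

test_that("pearson similarity on binary rows is the phi coefficient", {
  p <- counts_mat(c(1, 0, 1, 0,
                    0, 1, 0, 1,
                    1, 1, 0, 0,
                    1, 0, 1, 1), paste0("s", 1:4), paste0("o", 1:4))
  bp <- build_binary_profile(p)
  r <- pearson_similarity(bp)
  expect_equal(unname(diag(r)), rep(1, 4))
  expect_equal(r, t(r))
  expect_equal(r["s1", "s2"], -1)            # complements
  expect_equal(r["s3", "s1"], 0)             # 1100 vs 1010
  twin <- rbind(p, s1b = p[1, ])             # an identical extra row
  expect_equal(pearson_similarity(build_binary_profile(
    twin))["s1", "s1b"], 1)
  const <- counts_mat(c(1, 1, 1, 1, 1, 0, 1, 0), c("flat", "ok"),
                      paste0("o", 1:4))
  expect_error(pearson_similarity(build_binary_profile(const)), "flat")
})

test_that("dissimilarity is 1 - r with zero diagonal", {
  r <- structure(matrix(c(1, 0.25, 0.25, 1), 2, 2,
                        dimnames = list(c("a", "b"), c("a", "b"))),
                 class = c("similarity_matrix", "matrix", "array"))
  d <- to_dissimilarity(r)
  expect_equal(d["a", "b"], 0.75)
  expect_equal(unname(diag(d)), c(0, 0))
  r[1, 2] <- r[2, 1] <- -1
  expect_equal(to_dissimilarity(r)["a", "b"], 2)
  r[1, 2] <- r[2, 1] <- 1
  expect_equal(to_dissimilarity(r)["a", "b"], 0)
})

test_that("PCoA reconstructs Euclidean configurations", {
  set.seed(11)
  pts <- matrix(stats::rnorm(6), 3, 2)
  d <- as.matrix(stats::dist(pts))
  res <- pcoa(d, k = 2)
  expect_equal(as.matrix(stats::dist(res$coordinates)), d,
               tolerance = 1e-8, ignore_attr = TRUE)
  # Euclidean input: no meaningful negative eigenvalues
  expect_true(min(res$eigenvalues) > -1e-9 * max(res$eigenvalues))

  # closed form for two objects at distance 1
  d2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"),
                                                    c("a", "b")))
  expect_warning(res2 <- pcoa(d2, k = 2), "positive")
  expect_equal(res2$n_positive, 1L)
  expect_equal(sort(res2$coordinates[, 1]), c(-0.5, 0.5),
               ignore_attr = TRUE)

  # identical objects sit at identical coordinates
  d3 <- as.matrix(stats::dist(pts[c(1, 1, 2, 3), ]))
  res3 <- pcoa(d3, k = 2)
  expect_equal(res3$coordinates[1, ], res3$coordinates[2, ],
               tolerance = 1e-8, ignore_attr = TRUE)

  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  dneg <- d2; dneg[1, 2] <- dneg[2, 1] <- -1
  expect_error(pcoa(dneg), "non-negative")
})

test_that("broken-stick fractions match closed forms and normalize", {
  expect_equal(broken_stick(1), 1)
  expect_equal(broken_stick(3), c(11, 5, 2) / 18)
  expect_equal(sum(broken_stick(50)), 1)
  expect_true(all(diff(broken_stick(20)) < 0))
  expect_error(broken_stick(0), ">= 1")
})

test_that("axis verdicts compare explained variance to broken stick", {
  fake <- structure(list(coordinates = matrix(0, 5, 2),
                         eigenvalues = c(6, 3, 0.6, 0.3, 0.1) - 0,
                         explained = c(0.6, 0.3, 0.06, 0.03, 0.01),
                         broken_stick = broken_stick(5), n_positive = 5L),
                    class = "pcoa_result")
  v <- compare_axes_to_broken_stick(fake, 2)
  expect_equal(v$expected, c(0.4566667, 0.2566667), tolerance = 1e-6)
  expect_true(all(v$exceeds))

  fake$explained <- broken_stick(5)        # equality is not enough
  expect_false(any(compare_axes_to_broken_stick(fake, 2)$exceeds))

  fake$n_positive <- 1L
  expect_error(compare_axes_to_broken_stick(fake, 2), "only 1")
})

test_that("ward linkage matches the naive sum-of-squares oracle", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(4:9, 1)
    pts <- matrix(stats::rnorm(2 * n), n, 2)
    d <- as.matrix(stats::dist(pts))
    dimnames(d) <- list(paste0("p", 1:n), paste0("p", 1:n))
    for (variant in c("ward2", "ward1")) {
      got <- ward_cluster(if (variant == "ward2") d else d^2,
                          variant = variant)
      want <- naive_ward_points(pts, variant)
      expect_equal(got$merge, want$merge, info = variant)
      expect_equal(got$height, want$height, tolerance = 1e-8,
                   info = variant)
      expect_true(all(diff(got$height) > -1e-10))
    }
  }
})

test_that("ward handles the smallest case and planted blocks", {
  d <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("a", "b"),
                                                   c("a", "b")))
  w <- ward_cluster(d)
  expect_equal(nrow(w$merge), 1L)
  expect_equal(w$height, 3)
  expect_error(ward_cluster(d[1, 1, drop = FALSE]), "at least 2")

  # two planted blocks of near-identical profiles
  set.seed(5)
  p <- rbind(matrix(rep(c(rep(1, 20), rep(0, 20)), 4), 4, byrow = TRUE),
             matrix(rep(c(rep(0, 20), rep(1, 20)), 4), 4, byrow = TRUE))
  noise <- matrix(rbinom(length(p), 1, 0.05), nrow(p))
  p <- abs(p - noise)
  dimnames(p) <- list(paste0("s", 1:8), paste0("o", 1:40))
  d2 <- to_dissimilarity(pearson_similarity(
    build_binary_profile(p)))
  cut <- cut_linkage(ward_cluster(d2), 2)
  expect_equal(rand_index(cut, rep(1:2, each = 4)), 1.0)
})

test_that("heatmap layout orders by leaf order without mutating values", {
  m <- counts_mat(c(1, 0, 1, 0, 1, 0,
                    1, 1, 0, 0, 1, 0,
                    0, 1, 0, 1, 0, 1,
                    0, 1, 1, 1, 0, 1), paste0("s", 1:4), paste0("o", 1:6))
  bp <- build_binary_profile(m)
  d <- to_dissimilarity(pearson_similarity(bp))
  sl <- ward_cluster(d)
  ol <- ward_cluster(as.matrix(stats::dist(t(unclass(bp)))))
  lay <- heatmap_layout(bp, sl, ol, clamp = c(0, 1))
  expect_equal(sort(attr(lay, "row_order")), sort(rownames(m)))
  expect_equal(attr(lay, "clamp"), c(0, 1))
  expect_equal(sort(as.vector(lay)), sort(as.vector(unclass(bp))))
  # values at reordered positions are the original values
  expect_equal(lay[attr(lay, "row_order")[1], attr(lay, "col_order")[1]],
               unclass(bp)[attr(lay, "row_order")[1],
                           attr(lay, "col_order")[1]])
  # identity: no linkages given
  expect_equal(as.vector(heatmap_layout(bp)), as.vector(unclass(bp)))
  bad <- ward_cluster(d)
  bad$labels <- paste0("x", 1:4)
  expect_error(heatmap_layout(bp, bad), "row linkage")
})

test_that("planted two-block profiles yield contiguous heatmap blocks", {
  p <- simulate_profiles(two_group_spec(), 120, seed = 9)
  bp <- build_binary_profile(p$counts)
  d <- to_dissimilarity(pearson_similarity(bp))
  lay <- heatmap_layout(bp, ward_cluster(d), NULL)
  ord_groups <- p$groups[attr(lay, "row_order")]
  expect_equal(length(rle(ord_groups)$lengths), 2L)  # contiguous blocks
})
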