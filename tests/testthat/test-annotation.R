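hit_row <- function(q, sp, bit, rank = 1, sk = "Eukaryota",
                    flags = "fungi", ev = 1e-20, pid = 50) {
  data.frame(qseqid = q, sseqid = paste0("s", rank), rank = rank,
             pident = pid, evalue = ev, bitscore = bit,
             superkingdom = sk, lineage_flags = flags, species = sp,
             stringsAsFactors = FALSE)
}

test_that("bestsum sums bitscores per species over the first 10 hits", {
  one <- hit_row("q1", "X", 80)
  expect_equal(assign_taxon_bestsum(one)$species, "X")

  # A: 50 + 60 = 110 beats B: 100
  h <- rbind(hit_row("q1", "B", 100, 1), hit_row("q1", "A", 60, 2),
             hit_row("q1", "A", 50, 3))
  a <- assign_taxon_bestsum(h)
  expect_equal(a$species, "A")
  expect_equal(a$score, 110)

  # an 11th hit is ignored no matter its (rank-consistent) score
  h11 <- do.call(rbind, lapply(1:11, function(r)
    hit_row("q1", if (r <= 10) paste0("sp", r) else "C", 120 - r, r)))
  a11 <- assign_taxon_bestsum(h11)
  expect_equal(a11$species, "sp1")
  # with top_n = 11 the same table can answer differently
  h11b <- h11
  h11b$species[2:11] <- "C"
  expect_equal(assign_taxon_bestsum(h11b)$species, "C")     # 9 hits of C
  expect_equal(assign_taxon_bestsum(h11b, top_n = 1)$species, "sp1")

  # hit-less queries are NO_HIT
  nh <- assign_taxon_bestsum(h, queries = c("q1", "q2"))
  expect_equal(nh$species[nh$qseqid == "q2"], "NO_HIT")
})

test_that("bestsum ties break by best single hit then label", {
  h <- rbind(hit_row("q1", "B", 70, 1), hit_row("q1", "A", 40, 2),
             hit_row("q1", "A", 30, 3))       # both sum to 70
  expect_equal(assign_taxon_bestsum(h)$species, "B")
  h2 <- rbind(hit_row("q1", "B", 50, 1), hit_row("q1", "A", 50, 2))
  expect_equal(assign_taxon_bestsum(h2)$species, "A")  # label order
})

test_that("hit tables are validated", {
  bad <- rbind(hit_row("q1", "A", 50, 1), hit_row("q1", "B", 90, 2))
  expect_error(validate_hits(bad), "increase with rank")
  dup <- rbind(hit_row("q1", "A", 50, 1), hit_row("q1", "B", 40, 1))
  expect_error(validate_hits(dup), "duplicate hit ranks")
  expect_error(validate_hits(hit_row("q1", "A", 50, pid = 150)),
               "identity")
})

test_that("cellular-origin screen keeps only eukaryotic assignments", {
  asg <- data.frame(
    qseqid = paste0("q", 1:4),
    species = c("E. coli", "NO_HIT", "Fungus x", "Virus y"),
    superkingdom = c("Bacteria", NA, "Eukaryota", "Viruses"),
    score = c(10, 0, 20, 30), stringsAsFactors = FALSE)
  out <- screen_cellular_origin(asg)
  expect_equal(out$keep, c(FALSE, FALSE, TRUE, FALSE))
  asg$superkingdom[1] <- "Monera"
  expect_error(screen_cellular_origin(asg), "unknown superkingdom")
})

test_that("host screen discards only stramenopile first hits below cutoff", {
  h1 <- rbind(hit_row("q1", "Phyto", 90, 1, flags = "stramenopile",
                      ev = 1e-20))
  expect_false(screen_host_first_hit(h1)$keep)

  h2 <- rbind(hit_row("q2", "Fungus", 90, 1),
              hit_row("q2", "Phyto", 80, 2, flags = "stramenopile"))
  expect_true(screen_host_first_hit(h2)$keep)

  # only hit is above the cutoff: no qualifying hit, keep
  h3 <- hit_row("q3", "Phyto", 90, 1, flags = "stramenopile", ev = 1e-5)
  expect_true(screen_host_first_hit(h3)$keep)
  # but the rank-2 qualifying hit decides if rank-1 fails the cutoff
  h4 <- rbind(hit_row("q4", "Fungus", 90, 1, ev = 1e-5),
              hit_row("q4", "Phyto", 80, 2, flags = "stramenopile",
                      ev = 1e-15))
  expect_false(screen_host_first_hit(h4)$keep)
})

test_that("host identity rule is 100% or strictly greater than 95%", {
  expect_equal(screen_host_identity(c(100, 96.2, 95.0, 94.9, NA)),
               c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_error(screen_host_identity(101), "outside")
})

test_that("deduplication collapses exact duplicates and substrings", {
  p <- c(a = "MKV", b = "MKVLL", c = "MKV", d = "AAAA")
  res <- dedup_identical(p)
  expect_equal(sort(names(res$retained)), c("b", "d"))
  expect_equal(res$clusters[["a"]], "b")    # substring of longer
  expect_equal(res$clusters[["c"]], "b")
  expect_equal(dedup_identical(c(x = "AB", y = "CD", z = "EF"))$clusters,
               character(0))
  # exact-only mode keeps substrings
  res2 <- dedup_identical(p, exact_only = TRUE)
  expect_true("a" %in% names(res2$retained) ||
                "c" %in% names(res2$retained))
  expect_false(all(c("a", "c") %in% names(res2$retained)))
  # ties by id: identical sequences keep the smallest id
  res3 <- dedup_identical(c(z = "QQQ", a = "QQQ"))
  expect_equal(names(res3$retained), "a")
  expect_error(dedup_identical(character(0)), "empty")
})

test_that("MCL separates components and weak bridges", {
  tri2 <- matrix(0, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  for (ix in list(1:3, 4:6))
    for (i in ix) for (j in ix) if (i != j) tri2[i, j] <- 1
  cl <- mcl_cluster(tri2)
  expect_equal(cl, list(c("a", "b", "c"), c("d", "e", "f")))

  edge <- data.frame(from = "a", to = "b", weight = 1)
  expect_equal(mcl_cluster(edge), list(c("a", "b")))

  barbell <- matrix(0, 8, 8, dimnames = list(letters[1:8], letters[1:8]))
  for (ix in list(1:4, 5:8))
    for (i in ix) for (j in ix) if (i != j) barbell[i, j] <- 1
  barbell[4, 5] <- barbell[5, 4] <- 0.05
  expect_equal(mcl_cluster(barbell),
               list(letters[1:4], letters[5:8]))

  expect_error(mcl_cluster(data.frame(from = "a", to = "b",
                                      weight = -1)), "positive")
})

test_that("MCL clusters form a partition and respect components", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    w <- matrix(0, n, n, dimnames = list(paste0("n", 1:n),
                                         paste0("n", 1:n)))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (stats::runif(1) < 0.35) w[i, j] <- w[j, i] <- stats::runif(1)
    }
    cl <- mcl_cluster(w)
    expect_equal(sort(unlist(cl)), sort(rownames(w)))  # partition
    comp <- igraph_free_components(w)
    for (cluster in cl)
      expect_length(unique(comp[cluster]), 1L)  # never spans components
  }
})

test_that("cluster retention counts distinct organisms", {
  clusters <- list(c("p1", "p2", "p3"), c("p4", "p5", "p6", "p7", "p8"))
  orgs <- c(p1 = "a", p2 = "b", p3 = "c",
            p4 = "a", p5 = "a", p6 = "b", p7 = "b", p8 = "a")
  expect_equal(filter_clusters_by_organisms(clusters, orgs), clusters[1])
  expect_equal(filter_clusters_by_organisms(clusters, orgs,
                                            min_organisms = 1), clusters)
  # monotonicity: raising min_organisms never retains more
  for (k in 1:4) {
    n_k <- length(filter_clusters_by_organisms(clusters, orgs, k))
    n_k1 <- length(filter_clusters_by_organisms(clusters, orgs, k + 1))
    expect_lte(n_k1, n_k)
  }
  expect_error(filter_clusters_by_organisms(clusters, orgs[-1]),
               "without an organism")
})

test_that("KEGG transfer is >= 80% with existing-ID precedence", {
  fam <- data.frame(
    family = paste0("f", 1:4),
    uniprot_best_bit = c(100, 100, 100, 100),
    kegg_best_bit = c(80, 79.9, 200, NA),
    existing_kegg_id = c(NA, NA, "K00001", NA),
    candidate_kegg_id = c("K11111", "K22222", "K33333", "K44444"),
    stringsAsFactors = FALSE)
  res <- transfer_kegg_ids(fam)
  expect_equal(res$transfer, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(res$assigned_kegg_id,
               c("K11111", NA, "K00001", NA))
  fam$uniprot_best_bit[1] <- NA
  expect_error(transfer_kegg_ids(fam), "uniprot_best_bit required")
})

test_that("presence calls require both e-value thresholds", {
  hits <- data.frame(
    genome = c("g1", "g1", "g2", "g2"),
    protein = paste0("p", 1:4),
    hmm = c("H1", "H2", "H1", "H1"),
    full_evalue = c(1e-6, 1e-4, 1e-8, 1e-9),
    domain_evalue = c(1e-5, 1e-9, 1e-3, 1e-6),
    stringsAsFactors = FALSE)
  map <- c(H1 = "K001", H2 = "K002", H3 = "K003")
  m <- build_presence_matrix(hits, map)
  expect_equal(m["g1", "K001"], 1L)   # both thresholds pass
  expect_equal(m["g1", "K002"], 0L)   # full fails
  expect_equal(m["g2", "K001"], 1L)   # one of two proteins qualifies
  expect_equal(unname(colSums(m)["K003"]), 0)

  # idempotent presence: two qualifying proteins, same cell stays 1
  hits2 <- rbind(hits, data.frame(genome = "g1", protein = "p5",
                                  hmm = "H1", full_evalue = 1e-9,
                                  domain_evalue = 1e-9))
  expect_equal(build_presence_matrix(hits2, map)["g1", "K001"], 1L)

  # monotonicity: tightening thresholds never creates presence
  m_tight <- build_presence_matrix(hits, map, full_cutoff = 1e-8,
                                   domain_cutoff = 1e-5)
  expect_true(all(m_tight <= m))
  hits$full_evalue[1] <- -1
  expect_error(build_presence_matrix(hits, map), "non-negative")
})

test_that("the decontamination pipeline is input-order invariant", {
  ht <- simulate_hit_table(c(target = 8, prokaryote = 5, host_first = 4,
                             no_hit = 3, host_identity = 4), seed = 77)
  res1 <- decontaminate(ht$hits, queries = ht$truth$qseqid)
  shuffled <- ht$hits[sample.int(nrow(ht$hits)), ]
  res2 <- decontaminate(shuffled, queries = ht$truth$qseqid)
  expect_equal(res1$kept, res2$kept)
  expect_equal(res1$stages, res2$stages)
})

test_that("rule engines recover planted hit-table classes exactly", {
  ht <- simulate_hit_table(c(target = 10, prokaryote = 6, host_first = 5,
                             no_hit = 4, host_identity = 5), seed = 13)
  res <- decontaminate(ht$hits, queries = ht$truth$qseqid)
  got <- table(factor(res$detail$removed_at,
                      levels = c("cellular_origin", "host_first_hit",
                                 "host_identity")), useNA = "no")
  expect_equal(unname(got["cellular_origin"]), 10L)  # prokaryote + no_hit
  expect_equal(unname(got["host_first_hit"]), 5L)
  expect_equal(unname(got["host_identity"]), 5L)
  expect_equal(sort(res$kept),
               sort(ht$truth$qseqid[ht$truth$class == "target"]))
})
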