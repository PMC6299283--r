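#' Validate a homology hit table
#'
#' Hit tables are BLAST outfmt-6-like data.frames extended with taxonomy:
#' columns `qseqid`, `sseqid`, `rank`, `pident`, `evalue`, `bitscore`,
#' `superkingdom` (Bacteria/Archaea/Eukaryota/Viruses), `lineage_flags`
#' (semicolon-separated labels such as `stramenopile`) and `species`.
#' Within a query, ranks must be unique and bitscores non-increasing with
#' rank.
#'
#' @param hits data.frame of hit records.
#' @return the validated data.frame, rows ordered by (qseqid, rank).
#' @export
validate_hits <- function(hits) {
  req <- c("qseqid", "sseqid", "rank", "pident", "evalue", "bitscore",
           "superkingdom", "lineage_flags", "species")
  missing <- setdiff(req, names(hits))
  if (length(missing))
    stop("hit table lacks columns: ", paste(missing, collapse = ", "))
  if (nrow(hits) == 0L) return(hits)
  if (any(hits$bitscore < 0) || any(hits$evalue < 0))
    stop("bitscores and e-values must be non-negative")
  if (any(hits$pident < 0 | hits$pident > 100))
    stop("percent identity must lie in [0, 100]")
  hits <- hits[order(hits$qseqid, hits$rank), , drop = FALSE]
  for (q in unique(hits$qseqid)) {
    h <- hits[hits$qseqid == q, ]
    if (anyDuplicated(h$rank))
      stop("duplicate hit ranks for query ", q)
    if (is.unsorted(-h$bitscore))
      stop("bitscores increase with rank for query ", q)
  }
  rownames(hits) <- NULL
  hits
}

#' Read / write a hit table
#'
#' @param path TSV file with the columns documented in [validate_hits()].
#' @return a validated hit data.frame.
#' @export
read_hits <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  validate_hits(utils::read.table(path, header = TRUE, sep = "\t",
                                  quote = "", stringsAsFactors = FALSE))
}

#' @rdname read_hits
#' @param hits a hit data.frame.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.valid_superkingdoms <- c("Bacteria", "Archaea", "Eukaryota", "Viruses")

#' Bestsum taxonomic assignment
#'
#' Assigns each query to the species with the largest bitscore sum over its
#' first `top_n` hits (the "bestsum" tax rule).  Ties on the summed score
#' are broken by the species owning the single highest-scoring hit, then by
#' lexicographic species label.  Queries without hits are assigned `NO_HIT`.
#'
#' @param hits a validated hit table (possibly several queries).
#' @param queries optional character vector of query ids to report (so
#'   hit-less queries appear as `NO_HIT` rows); default: queries present in
#'   `hits`.
#' @param top_n number of top-ranked hits considered (default 10).
#' @return data.frame (qseqid, species, superkingdom, score); `NO_HIT` rows
#'   carry `NA` superkingdom and zero score.
#' @export
assign_taxon_bestsum <- function(hits, queries = NULL, top_n = 10) {
  hits <- validate_hits(hits)
  if (is.null(queries)) queries <- unique(hits$qseqid)
  res <- lapply(queries, function(q) {
    h <- hits[hits$qseqid == q & hits$rank <= top_n, , drop = FALSE]
    if (nrow(h) == 0L)
      return(data.frame(qseqid = q, species = "NO_HIT",
                        superkingdom = NA_character_, score = 0,
                        stringsAsFactors = FALSE))
    sums <- tapply(h$bitscore, h$species, sum)
    best_single <- tapply(h$bitscore, h$species, max)
    ord <- order(-sums, -best_single[names(sums)], names(sums))
    sp <- names(sums)[ord[1L]]
    data.frame(qseqid = q, species = sp,
               superkingdom = h$superkingdom[h$species == sp][1L],
               score = unname(sums[ord[1L]]), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Cellular-origin screen
#'
#' Removes queries with no hit at all and queries whose bestsum assignment
#' is bacterial, archaeal or viral; only eukaryotic assignments are kept.
#'
#' @param assignments output of [assign_taxon_bestsum()].
#' @return the assignments with a logical `keep` column.
#' @export
screen_cellular_origin <- function(assignments) {
  sk <- assignments$superkingdom
  known <- is.na(sk) | sk %in% .valid_superkingdoms
  if (!all(known))
    stop("unknown superkingdom label(s): ",
         paste(unique(sk[!known]), collapse = ", "))
  assignments$keep <- !is.na(sk) & sk == "Eukaryota" &
    assignments$species != "NO_HIT"
  assignments
}

#' Host first-hit screen
#'
#' Against the mixed fungal/stramenopile reference, a query is discarded iff
#' its rank-1 hit passing the e-value cutoff is flagged as a stramenopile
#' (potential host origin).  Queries with no qualifying hit are kept.
#'
#' @param hits validated hit table.
#' @param queries optional query ids to report.
#' @param evalue_cutoff significance cutoff (default 1e-10).
#' @return data.frame (qseqid, keep).
#' @export
screen_host_first_hit <- function(hits, queries = NULL,
                                  evalue_cutoff = 1e-10) {
  hits <- validate_hits(hits)
  if (is.null(queries)) queries <- unique(hits$qseqid)
  keep <- vapply(queries, function(q) {
    h <- hits[hits$qseqid == q & hits$evalue <= evalue_cutoff, ,
              drop = FALSE]
    if (nrow(h) == 0L) return(TRUE)
    first <- h[which.min(h$rank), ]
    !.has_flag(first$lineage_flags, "stramenopile")
  }, TRUE)
  data.frame(qseqid = queries, keep = unname(keep),
             stringsAsFactors = FALSE)
}

.has_flag <- function(flags, what) {
  what %in% strsplit(as.character(flags), ";", fixed = TRUE)[[1L]]
}

#' Host-identity exclusion
#'
#' Drops a protein iff its best identity against the host proteome is 100%
#' or strictly greater than 95% (95.0 exactly is kept); proteins with no
#' host hit (`NA`) are kept.  The 100% clause is logically redundant but
#' kept to mirror the two-stage screen it reproduces.
#'
#' @param identity numeric vector of best percent identities in `[0, 100]`,
#'   `NA` where absent.
#' @return logical `keep` vector of the same length.
#' @export
screen_host_identity <- function(identity) {
  identity <- as.numeric(identity)
  bad <- !is.na(identity) & (identity < 0 | identity > 100)
  if (any(bad))
    stop("identity outside [0, 100]: ",
         paste(identity[bad], collapse = ", "))
  is.na(identity) | !(identity == 100 | identity > 95)
}

#' Best host identity per query from a hit table
#'
#' Convenience for the identity screen: the maximum percent identity over a
#' query's stramenopile-flagged hits, `NA` when it has none.
#'
#' @param hits validated hit table.
#' @param queries optional query ids to report.
#' @return named numeric vector.
#' @export
host_best_identity <- function(hits, queries = NULL) {
  hits <- validate_hits(hits)
  if (is.null(queries)) queries <- unique(hits$qseqid)
  host <- vapply(seq_len(nrow(hits)), function(i)
    .has_flag(hits$lineage_flags[i], "stramenopile"), TRUE)
  out <- vapply(queries, function(q) {
    v <- hits$pident[hits$qseqid == q & host]
    if (length(v)) max(v) else NA_real_
  }, 0)
  names(out) <- queries
  out
}

#' Deduplicate peptides at 100% identity
#'
#' Removes exact duplicates and sequences that are exact substrings of a
#' retained longer sequence (the global-identity behaviour of 100%-identity
#' clustering).  The longest sequence is retained; ties are broken by the
#' lexicographically smallest id.
#'
#' @param peptides named character vector (names = ids, values = residues).
#' @param exact_only if `TRUE`, only full-length duplicates are collapsed.
#' @return list with `retained` (named character vector) and `clusters`
#'   (named character vector mapping each dropped id to its representative).
#' @export
dedup_identical <- function(peptides, exact_only = FALSE) {
  if (length(peptides) == 0L) stop("empty peptide set")
  if (is.null(names(peptides)) || any(!nzchar(names(peptides))))
    stop("peptides must be named by id")
  ids <- names(peptides)
  o <- order(-nchar(peptides), ids)
  retained <- character(0)
  rep_of <- character(0)
  for (i in o) {
    s <- peptides[[i]]
    host <- NA_character_
    for (r in names(retained)) {
      hit <- if (exact_only) identical(retained[[r]], s)
      else grepl(s, retained[[r]], fixed = TRUE)
      if (hit) { host <- r; break }
    }
    if (is.na(host)) {
      retained[ids[i]] <- s
    } else {
      rep_of[ids[i]] <- host
    }
  }
  list(retained = retained, clusters = rep_of)
}

#' Markov clustering (MCL) of a weighted similarity graph
#'
#' Column-stochastic flow simulation with self-loops: alternate expansion
#' (matrix squaring) and inflation (elementwise power `inflation`, column
#' renormalization), pruning entries below `prune`, until the largest entry
#' change drops below `tol` or `max_iter` is reached.  Clusters are the
#' connected components of the attractor structure of the limit matrix;
#' nodes attracted by several components are resolved to the
#' highest-weight attractor, ties to the smallest attractor index.
#'
#' @param graph either a symmetric non-negative weight matrix with labels,
#'   or a data.frame of edges (`from`, `to`, `weight`).
#' @param inflation inflation parameter (default 2.0).
#' @param prune entries below this are zeroed each iteration (default 1e-8).
#' @param tol convergence tolerance on the max entry change (default 1e-6).
#' @param max_iter iteration cap (default 100).
#' @return list of character vectors (disjoint clusters covering all
#'   nodes), ordered by smallest member node index.
#' @export
mcl_cluster <- function(graph, inflation = 2.0, prune = 1e-8, tol = 1e-6,
                        max_iter = 100) {
  w <- .as_weight_matrix(graph)
  n <- nrow(w)
  nodes <- rownames(w)
  if (n == 1L) return(list(nodes))
  diag(w) <- pmax(diag(w), apply(w, 2L, max))  # self-loops
  diag(w)[diag(w) == 0] <- 1                   # isolated nodes
  m <- sweep(w, 2L, colSums(w), "/")
  for (it in seq_len(max_iter)) {
    m2 <- m %*% m                       # expansion
    m2 <- m2^inflation                  # inflation
    m2[m2 < prune] <- 0
    cs <- colSums(m2)
    cs[cs == 0] <- 1
    m2 <- sweep(m2, 2L, cs, "/")
    delta <- max(abs(m2 - m))
    m <- m2
    if (delta < tol) break
  }
  # attractors: rows with mass on their own diagonal
  attractors <- which(diag(m) > prune)
  if (length(attractors) == 0L) attractors <- seq_len(n)
  # merge attractors that share any attracted node
  comp <- seq_along(attractors)
  supp <- lapply(attractors, function(a) which(m[a, ] > prune))
  for (i in seq_along(attractors)) {
    for (j in seq_len(i - 1L)) {
      if (length(intersect(supp[[i]], supp[[j]])) ||
          m[attractors[i], attractors[j]] > prune ||
          m[attractors[j], attractors[i]] > prune) {
        comp[comp == comp[i]] <- comp[j]
      }
    }
  }
  # assign every node to the attractor group with the largest incoming mass
  groups <- sort(unique(comp))
  assign <- integer(n)
  for (v in seq_len(n)) {
    wts <- vapply(groups, function(g)
      max(m[attractors[comp == g], v], 0), 0)
    if (max(wts) <= 0) {
      # isolated under pruning: fall back to strongest original neighbour
      wts <- vapply(groups, function(g)
        max(w[attractors[comp == g], v], 0), 0)
    }
    assign[v] <- groups[which.max(wts)]
  }
  out <- lapply(split(seq_len(n), assign), function(ix) nodes[sort(ix)])
  names(out) <- NULL
  out[order(vapply(out, function(cl) min(match(cl, nodes)), 0L))]
}

.as_weight_matrix <- function(graph) {
  if (is.matrix(graph)) {
    if (is.null(rownames(graph)))
      rownames(graph) <- colnames(graph) <- paste0("n", seq_len(nrow(graph)))
    if (any(graph < 0)) stop("edge weights must be non-negative")
    if (max(abs(graph - t(graph))) > 1e-12)
      stop("weight matrix must be symmetric")
    return(graph)
  }
  ed <- as.data.frame(graph)
  if (!all(c("from", "to", "weight") %in% names(ed)))
    stop("edge list needs columns from, to, weight")
  if (any(ed$weight <= 0)) stop("edge weights must be positive")
  nodes <- sort(unique(c(as.character(ed$from), as.character(ed$to))))
  w <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(ed))) {
    a <- as.character(ed$from[i]); b <- as.character(ed$to[i])
    if (a == b) next
    w[a, b] <- w[b, a] <- max(w[a, b], ed$weight[i])
  }
  w
}

#' Retain clusters spanning enough organisms
#'
#' Keeps clusters whose members come from at least `min_organisms` distinct
#' organisms, filtering out lineage-specific families.
#'
#' @param clusters list of character vectors of protein ids.
#' @param organisms named character vector mapping every protein id to its
#'   organism.
#' @param min_organisms minimum distinct organisms (default 3).
#' @return the retained subset of `clusters`.
#' @export
filter_clusters_by_organisms <- function(clusters, organisms,
                                         min_organisms = 3) {
  unmapped <- setdiff(unlist(clusters), names(organisms))
  if (length(unmapped))
    stop("proteins without an organism mapping: ",
         paste(utils::head(unmapped, 5L), collapse = ", "))
  keep <- vapply(clusters, function(cl)
    length(unique(organisms[cl])) >= min_organisms, TRUE)
  clusters[keep]
}

#' KEGG-ortholog identifier transfer rule
#'
#' A KEGG ortholog id is transferred to a family iff the best KEGG-protein
#' bit score is at least 80% of the best UniProt-protein bit score *and* no
#' KEGG id is already associated ("at least" = inclusive `>=`).
#'
#' @param families data.frame with columns `family`, `uniprot_best_bit`,
#'   `kegg_best_bit` (`NA` when no KEGG candidate), `existing_kegg_id`
#'   (`NA`/`""` when absent) and `candidate_kegg_id`.
#' @param min_ratio score ratio threshold (default 0.8).
#' @return the input with logical `transfer` and `assigned_kegg_id` columns.
#' @export
transfer_kegg_ids <- function(families, min_ratio = 0.8) {
  req <- c("family", "uniprot_best_bit", "kegg_best_bit",
           "existing_kegg_id", "candidate_kegg_id")
  missing <- setdiff(req, names(families))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "))
  has_candidate <- !is.na(families$kegg_best_bit)
  if (any(has_candidate & is.na(families$uniprot_best_bit)))
    stop("uniprot_best_bit required wherever a KEGG candidate is scored")
  has_existing <- !is.na(families$existing_kegg_id) &
    nzchar(families$existing_kegg_id)
  families$transfer <- has_candidate & !has_existing &
    families$kegg_best_bit >= min_ratio * families$uniprot_best_bit
  families$assigned_kegg_id <- ifelse(
    has_existing, families$existing_kegg_id,
    ifelse(families$transfer, families$candidate_kegg_id, NA_character_))
  families
}

#' Thresholded KEGG presence/absence matrix
#'
#' A best-HMM hit qualifies iff its full-sequence e-value and best single
#' domain e-value both pass their thresholds; a genome x KEGG cell is 1 iff
#' at least one qualifying protein of that genome maps to that KEGG id.
#'
#' @param best_hits data.frame with columns `genome`, `protein`, `hmm`,
#'   `full_evalue`, `domain_evalue` (one best-hit row per protein; proteins
#'   with no hit simply have no row).
#' @param hmm_to_kegg named character vector mapping HMM ids to KEGG
#'   ortholog ids (`NA`/missing = no KEGG id).
#' @param full_cutoff full-sequence e-value threshold (default 1e-5).
#' @param domain_cutoff single-domain e-value threshold (default 1e-4).
#' @return 0/1 integer matrix, genomes x KEGG ids (sorted labels).
#' @export
build_presence_matrix <- function(best_hits, hmm_to_kegg,
                                  full_cutoff = 1e-5,
                                  domain_cutoff = 1e-4) {
  req <- c("genome", "protein", "hmm", "full_evalue", "domain_evalue")
  missing <- setdiff(req, names(best_hits))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "))
  if (any(best_hits$full_evalue < 0) || any(best_hits$domain_evalue < 0))
    stop("e-values must be non-negative")
  qual <- best_hits$full_evalue <= full_cutoff &
    best_hits$domain_evalue <= domain_cutoff
  kegg <- hmm_to_kegg[best_hits$hmm]
  ok <- qual & !is.na(kegg) & nzchar(kegg)
  genomes <- sort(unique(best_hits$genome))
  kos <- sort(unique(stats::na.omit(unname(hmm_to_kegg))))
  kos <- kos[nzchar(kos)]
  m <- matrix(0L, length(genomes), length(kos),
              dimnames = list(genomes, kos))
  if (any(ok))
    m[cbind(match(best_hits$genome[ok], genomes),
            match(kegg[ok], kos))] <- 1L
  m
}

#' Full decontamination pipeline
#'
#' Chains the rule engines in the published order: bestsum taxon assignment
#' with the cellular-origin screen (remove no-hit, bacterial, archaeal and
#' viral queries), the host first-hit screen, and the host-identity
#' exclusion.  Each stage only sees the survivors of the previous one.
#'
#' @param hits validated hit table against the general reference (taxonomy
#'   columns populated).
#' @param queries character vector of all query ids (so hit-less queries
#'   are counted); default: queries present in `hits`.
#' @param top_n bestsum depth (default 10).
#' @param evalue_cutoff host first-hit e-value cutoff (default 1e-10).
#' @return list with `kept` (character vector), `stages` (per-stage
#'   retained/removed counts) and `detail` (per-query data.frame with the
#'   stage at which each query was removed, `NA` if kept).
#' @export
decontaminate <- function(hits, queries = NULL, top_n = 10,
                          evalue_cutoff = 1e-10) {
  hits <- validate_hits(hits)
  if (is.null(queries)) queries <- unique(hits$qseqid)
  asg <- screen_cellular_origin(
    assign_taxon_bestsum(hits, queries = queries, top_n = top_n))
  removed_at <- stats::setNames(rep(NA_character_, length(queries)), queries)
  removed_at[asg$qseqid[!asg$keep]] <- "cellular_origin"
  surv1 <- asg$qseqid[asg$keep]
  s2 <- screen_host_first_hit(hits, queries = surv1,
                              evalue_cutoff = evalue_cutoff)
  removed_at[s2$qseqid[!s2$keep]] <- "host_first_hit"
  surv2 <- s2$qseqid[s2$keep]
  ident <- host_best_identity(hits, queries = surv2)
  keep3 <- screen_host_identity(ident)
  removed_at[surv2[!keep3]] <- "host_identity"
  kept <- surv2[keep3]
  stages <- data.frame(
    stage = c("input", "cellular_origin", "host_first_hit",
              "host_identity"),
    retained = c(length(queries), length(surv1), length(surv2),
                 length(kept)))
  stages$removed <- c(0L, -diff(stages$retained))
  list(kept = kept, stages = stages,
       detail = data.frame(qseqid = queries,
                           removed_at = unname(removed_at),
                           stringsAsFactors = FALSE))
}
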