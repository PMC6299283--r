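#' Amino-acid alignment container
#'
#' An `aa_alignment` is a light container for a multiple sequence alignment:
#' a character vector of residue strings (one per sequence) plus the sequence
#' ids.  All sequences must have the same number of columns and ids must be
#' unique, non-empty and free of internal whitespace.
#'
#' @param ids character vector of sequence labels.
#' @param seqs character vector of residue strings, same length as `ids`.
#'   The expected alphabet is the 20 amino acids plus `X`, `-` and `*`;
#'   residues are stored verbatim.
#' @return An object of class `aa_alignment` with fields `ids`, `seqs`,
#'   `n_seq` and `length` (number of columns).
#' @examples
#' aln <- alignment(c("A", "B"), c("MKVL", "MK-L"))
#' aln$length
#' @export
alignment <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- as.character(seqs)
  if (length(ids) != length(seqs))
    stop("`ids` and `seqs` must have the same length")
  if (length(ids) == 0L)
    stop("alignment must contain at least one sequence")
  if (anyNA(ids) || any(!nzchar(ids)))
    stop("sequence ids must be non-empty")
  if (any(grepl("[[:space:]]", ids)))
    stop("sequence ids must not contain whitespace: ",
         paste(ids[grepl("[[:space:]]", ids)], collapse = ", "))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sequence ids: ", paste(unique(dup), collapse = ", "))
  len <- nchar(seqs)
  if (any(len == 0L))
    stop("empty sequence for id ", ids[which(len == 0L)[1L]])
  if (length(unique(len)) != 1L) {
    bad <- ids[len != len[1L]][1L]
    stop("unequal sequence lengths: '", bad, "' has ", len[ids == bad][1L],
         " columns, expected ", len[1L])
  }
  structure(list(ids = ids, seqs = seqs, n_seq = length(ids),
                 length = len[1L]),
            class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("Amino-acid alignment: ", x$n_seq, " sequences x ", x$length,
      " columns\n", sep = "")
  invisible(x)
}

#' Alignment as a character matrix
#'
#' @param aln an [alignment()].
#' @return character matrix, rows = sequences (named by id), one column per
#'   alignment column.
#' @export
alignment_matrix <- function(aln) {
  stopifnot(inherits(aln, "aa_alignment"))
  m <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  rownames(m) <- aln$ids
  m
}

#' Subset alignment columns
#'
#' @param aln an [alignment()].
#' @param columns integer vector of 1-based column indices to keep, in the
#'   order given.
#' @return an [alignment()] restricted to `columns`.
#' @export
alignment_columns <- function(aln, columns) {
  stopifnot(inherits(aln, "aa_alignment"))
  columns <- as.integer(columns)
  if (length(columns) == 0L)
    stop("cannot build an alignment with zero columns")
  if (any(columns < 1L | columns > aln$length))
    stop("column index out of range [1, ", aln$length, "]")
  m <- alignment_matrix(aln)[, columns, drop = FALSE]
  alignment(aln$ids, apply(m, 1L, paste, collapse = ""))
}

#' Read a multiple alignment
#'
#' Reads an amino-acid alignment from FASTA or relaxed (single-header)
#' PHYLIP.  FASTA ids are the first whitespace-delimited token of the header
#' line; relaxed PHYLIP expects a "ntax nchar" header followed by one
#' `id sequence` record per line (sequences may be split over several
#' whitespace-separated chunks on the same line).
#'
#' @param path file to read.
#' @param format `"fasta"` or `"phylip-relaxed"`.
#' @return an [alignment()]; sequence order as in the file, gaps preserved.
#' @export
read_alignment <- function(path, format = c("fasta", "phylip-relaxed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta") {
    bin <- ape::read.FASTA(path, type = "AA")
    if (length(bin) == 0L) stop("no sequences in ", path)
    ids <- vapply(strsplit(names(bin), "[[:space:]]+"), `[`, "", 1L)
    seqs <- vapply(as.character(bin),
                   function(s) paste(s, collapse = ""), "")
    return(alignment(ids, unname(seqs)))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not a PHYLIP file: ", path)
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1L]),
                                              "[[:space:]]+")[[1L]]))
  if (length(hdr) != 2L || anyNA(hdr))
    stop("malformed PHYLIP header: '", lines[1L], "'")
  body <- lines[-1L]
  if (length(body) != hdr[1L])
    stop("PHYLIP header declares ", hdr[1L], " sequences, found ",
         length(body))
  toks <- strsplit(trimws(body), "[[:space:]]+")
  ids <- vapply(toks, `[`, "", 1L)
  seqs <- vapply(toks, function(t) paste(t[-1L], collapse = ""), "")
  aln <- alignment(ids, seqs)
  if (aln$length != hdr[2L])
    stop("PHYLIP header declares ", hdr[2L], " columns, found ", aln$length)
  aln
}

#' Write a multiple alignment
#'
#' The FASTA writer wraps residues at 60 columns; the relaxed PHYLIP writer
#' emits a single "ntax nchar" header and one record per line.  A written
#' alignment re-read with [read_alignment()] reproduces ids, order and
#' residues exactly.
#'
#' @param aln an [alignment()].
#' @param path output file.
#' @param format `"fasta"` or `"phylip-relaxed"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip-relaxed")) {
  format <- match.arg(format)
  if (!inherits(aln, "aa_alignment"))
    stop("`aln` must be an aa_alignment")
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "fasta") {
    wrap <- function(s) {
      starts <- seq(1L, nchar(s), by = 60L)
      substring(s, starts, pmin(starts + 59L, nchar(s)))
    }
    for (i in seq_len(aln$n_seq)) {
      writeLines(c(paste0(">", aln$ids[i]), wrap(aln$seqs[i])), con)
    }
  } else {
    writeLines(paste(aln$n_seq, aln$length), con)
    writeLines(paste(format(aln$ids, width = max(nchar(aln$ids)) + 2L),
                     aln$seqs), con)
  }
  invisible(path)
}

#' Concatenate marker alignments into a partitioned supermatrix
#'
#' Builds the standard phylogenomic supermatrix: rows are the union of taxa
#' across markers (by first appearance, or an explicit `taxa` order), columns
#' are the markers laid end to end, and taxa absent from a marker are filled
#' with gap characters (`-`) across that marker's columns.
#'
#' @param markers named list of [alignment()] objects; names are marker
#'   labels (unnamed lists get `marker1..markerK`).
#' @param taxa optional character vector fixing the row set and order; must
#'   contain every taxon present in any marker.
#' @return a `supermatrix`: list with `alignment` (the concatenation) and
#'   `partitions`, a data.frame of (marker, start, end) 0-based half-open
#'   column intervals tiling `[0, length)`.
#' @seealso [write_partitions()] for the RAxML-style partition table.
#' @export
concatenate_markers <- function(markers, taxa = NULL) {
  if (length(markers) == 0L) stop("no markers to concatenate")
  if (!all(vapply(markers, inherits, TRUE, "aa_alignment")))
    stop("all markers must be aa_alignment objects")
  nm <- names(markers)
  if (is.null(nm) || any(!nzchar(nm)))
    nm <- paste0("marker", seq_along(markers))
  if (anyDuplicated(nm)) stop("duplicate marker names")
  seen <- unique(unlist(lapply(markers, `[[`, "ids")))
  if (is.null(taxa)) {
    taxa <- seen
  } else {
    missing <- setdiff(seen, taxa)
    if (length(missing))
      stop("taxa list is missing marker taxa: ",
           paste(missing, collapse = ", "))
  }
  lens <- vapply(markers, `[[`, 0L, "length")
  rows <- vapply(seq_along(markers), function(i) {
    m <- markers[[i]]
    filled <- rep(strrep("-", lens[i]), length(taxa))
    hit <- match(m$ids, taxa)
    filled[hit] <- m$seqs
    filled
  }, character(length(taxa)))
  if (is.null(dim(rows))) rows <- matrix(rows, nrow = length(taxa))
  seqs <- apply(rows, 1L, paste, collapse = "")
  ends <- cumsum(lens)
  parts <- data.frame(marker = nm, start = ends - lens, end = ends,
                      stringsAsFactors = FALSE)
  structure(list(alignment = alignment(taxa, seqs), partitions = parts),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("Partitioned supermatrix: ", x$alignment$n_seq, " taxa x ",
      x$alignment$length, " columns, ", nrow(x$partitions),
      " partitions\n", sep = "")
  invisible(x)
}

#' Write a RAxML-style partition table
#'
#' Internal partition intervals are 0-based half-open; the emitted table uses
#' the conventional 1-based inclusive coordinates, one `marker = start-end`
#' line per partition.
#'
#' @param sm a `supermatrix` from [concatenate_markers()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_partitions <- function(sm, path) {
  stopifnot(inherits(sm, "supermatrix"))
  p <- sm$partitions
  writeLines(sprintf("%s = %d-%d", p$marker, p$start + 1L, p$end), path)
  invisible(path)
}
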