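#' Read per-site evolutionary rates
#'
#' Parses the tab-separated per-site rate table produced by maximum
#' likelihood software (the IQ-TREE `-wsr` dialect): a header line, optional
#' `#` comment lines, a 1-based site-index column and a rate column
#' (an optional third rate-category column is ignored).
#'
#' @param path TSV file.
#' @return numeric vector of relative rates ordered by site index (class
#'   `site_rates`).
#' @export
read_site_rates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(trimws(lines), "#")]
  if (length(lines) < 2L) stop("no data rows in ", path)
  tab <- utils::read.table(text = lines, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("rate table needs at least a site and a rate column")
  site <- suppressWarnings(as.integer(tab[[1L]]))
  rate <- suppressWarnings(as.numeric(tab[[2L]]))
  if (anyNA(site))
    stop("non-integer site index at data line ", which(is.na(site))[1L])
  if (anyNA(rate))
    stop("non-numeric rate at data line ", which(is.na(rate))[1L])
  if (anyDuplicated(site))
    stop("duplicate site index at data line ",
         which(duplicated(site))[1L], " (site ",
         site[duplicated(site)][1L], ")")
  o <- order(site)
  site <- site[o]
  rate <- rate[o]
  if (!identical(site, seq_along(site)))
    stop("site indices must cover 1..", length(site), " without gaps; ",
         "first missing site: ", setdiff(seq_len(max(site)), site)[1L])
  site_rates(rate)
}

#' @rdname read_site_rates
#' @param rates numeric vector of non-negative finite relative rates (one
#'   per alignment column, mean approximately 1).
#' @export
site_rates <- function(rates) {
  rates <- as.numeric(rates)
  if (length(rates) == 0L) stop("empty rate vector")
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("rates must be finite and non-negative")
  structure(rates, class = "site_rates")
}

#' Write a per-site rate table
#'
#' @param rates a [site_rates()] vector.
#' @param path output TSV (columns `Site`, `Rate`).
#' @return `path`, invisibly.
#' @export
write_site_rates <- function(rates, path) {
  utils::write.table(data.frame(Site = seq_along(rates),
                                Rate = as.numeric(rates)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rank alignment columns fastest first
#'
#' Stable ordering: descending rate, ties broken by ascending column index,
#' so results are identical across platforms.
#'
#' @param rates a [site_rates()] (or plain numeric) vector.
#' @return integer permutation of `1..L`, fastest column first.
#' @export
rank_sites_by_rate <- function(rates) {
  rates <- as.numeric(rates)
  order(-rates, seq_along(rates))
}

# round-half-up with a guard against binary representation error
# (e.g. 0.15 * 10 = 1.4999999999999998 must still round to 2)
.round_half_up <- function(x) as.integer(floor(x + 0.5 + 1e-9))

#' Remove the fastest-evolving fraction of sites
#'
#' Removes the `k = round_half_up(fraction * L)` top-ranked columns of the
#' alignment; the retained columns keep their original relative order.  This
#' is the single step of the slow-fast (progressive fast-site removal)
#' analysis used to diagnose long-branch attraction.
#'
#' @param aln an [alignment()].
#' @param rates per-column rates, length equal to `aln$length`.
#' @param fraction fraction of sites to remove, in `[0, 1)`.
#' @return an [alignment()] with `L - k` columns.
#' @export
strip_fastest <- function(aln, rates, fraction) {
  stopifnot(inherits(aln, "aa_alignment"))
  rates <- as.numeric(rates)
  if (length(rates) != aln$length)
    stop("rates length (", length(rates), ") does not match alignment ",
         "length (", aln$length, ")")
  if (fraction < 0 || fraction >= 1)
    stop("fraction must be in [0, 1)")
  k <- .round_half_up(fraction * aln$length)
  if (k == 0L) return(aln)
  if (k >= aln$length)
    stop("fraction ", fraction, " would remove every column")
  drop <- rank_sites_by_rate(rates)[seq_len(k)]
  alignment_columns(aln, sort(setdiff(seq_len(aln$length), drop)))
}

#' Progressive stripping plan
#'
#' Fractions `{step, 2*step, ...}` up to and including `max_fraction`.  The
#' default plan (5% steps to 95%) yields 19 nested subsets.
#'
#' @param step fraction removed per increment (default 0.05).
#' @param max_fraction last fraction (default 0.95); `0 < step <=
#'   max_fraction < 1`.
#' @return object of class `strip_plan` with field `fractions`.
#' @export
strip_plan <- function(step = 0.05, max_fraction = 0.95) {
  if (!(step > 0 && step <= max_fraction && max_fraction < 1))
    stop("need 0 < step <= max_fraction < 1")
  n <- floor(max_fraction / step + 1e-9)
  structure(list(step = step, max_fraction = max_fraction,
                 fractions = step * seq_len(n)),
            class = "strip_plan")
}

#' @export
print.strip_plan <- function(x, ...) {
  cat("Strip plan: step ", x$step, ", up to ", x$max_fraction, " (",
      length(x$fractions), " subsets)\n", sep = "")
  invisible(x)
}

#' Progressively strip the fastest sites
#'
#' Emits one stripped alignment per fraction of the plan, all computed from
#' the fixed original rate ranking, so the retained column sets are nested
#' along the plan (the standard cumulative slow-fast construction).
#'
#' @param aln an [alignment()].
#' @param rates per-column rates.
#' @param plan a [strip_plan()].
#' @return named list of [alignment()] (names = fractions); attribute
#'   `manifest` is a data.frame (fraction, k_removed, length).
#' @export
progressive_strip <- function(aln, rates, plan = strip_plan()) {
  stopifnot(inherits(plan, "strip_plan"))
  out <- lapply(plan$fractions, function(f) strip_fastest(aln, rates, f))
  names(out) <- format(plan$fractions)
  k <- vapply(out, function(a) aln$length - a$length, 0L)
  attr(out, "manifest") <- data.frame(fraction = plan$fractions,
                                      k_removed = as.integer(k),
                                      length = aln$length - as.integer(k))
  out
}
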