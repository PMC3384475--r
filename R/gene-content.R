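#' Core genome of a strain set
#'
#' The core is the set of genes called present in every strain; a gene
#' with "no data" in any strain is excluded from the core but still counts
#' in the denominator, so the fraction is conservative.
#'
#' @param matrix A [presence_matrix].
#' @return List with `genes` (core locus tags), `n` (core size) and
#'   `fraction_pct` (percent of all probes, one decimal half-up).
#' @export
core_set <- function(matrix) {
  stopifnot(inherits(matrix, "presence_matrix"))
  m <- matrix$calls
  if (ncol(m) < 1L || nrow(m) < 1L) stopf("empty presence matrix")
  in_core <- rowSums(m) == ncol(m)       # NA in a row propagates to NA
  in_core[is.na(in_core)] <- FALSE
  list(genes = rownames(m)[in_core], n = sum(in_core),
       fraction_pct = round_half_up(100 * sum(in_core) / nrow(m), 1))
}

#' Pairwise shared-gene counts and percentages
#'
#' For every strain pair, the number of genes called present in both, and
#' that count as a percentage of the smaller of the two strains'
#' detectable-gene totals (so a strain whose present set contains the
#' other's scores 100). The diagonal holds each strain's detectable total.
#' Genes with no data in a strain do not count as present there.
#'
#' @param matrix A [presence_matrix] with >= 2 strains.
#' @param pct One of `"min"` (percent of the smaller detectable set,
#'   default) or `"mean"` (percent of the average of the two).
#' @return List of class `shared_gene_matrix`: `count` (integer matrix,
#'   diagonal = detectable totals), `percent` (one-decimal matrix, diagonal
#'   100), `detectable` (named vector).
#' @export
pairwise_overlap <- function(matrix, pct = c("min", "mean")) {
  stopifnot(inherits(matrix, "presence_matrix"))
  pct <- match.arg(pct)
  m <- matrix$calls
  if (ncol(m) < 2L) stopf("need >= 2 strains")
  p <- m
  p[is.na(p)] <- FALSE
  counts <- crossprod(p * 1L)
  det <- diag(counts)
  lo <- if (pct == "min") outer(det, det, pmin) else outer(det, det, "+") / 2
  percent <- round_half_up(100 * counts / lo, 1)
  percent[lo == 0] <- NA_real_
  structure(list(count = counts, percent = percent, detectable = det),
            class = "shared_gene_matrix")
}

#' @export
print.shared_gene_matrix <- function(x, ...) {
  cat(sprintf("shared_gene_matrix over %d strains (detectable %d-%d genes)\n",
              length(x$detectable), min(x$detectable), max(x$detectable)))
  invisible(x)
}

#' Occupancy of named regions and gene sets
#'
#' For each selected gene set and strain: the percentage of the set's
#' informative members (members with a call, present or absent) that are
#' called present — the "relative occurrence" of an island, plasmid or
#' gene cluster in that strain. Members with no data are removed from both
#' numerator and denominator.
#'
#' @param matrix A [presence_matrix].
#' @param table A [gene_table] whose sets contain the regions of interest.
#' @param sets Character vector of set names (default: all sets in
#'   `table`).
#' @return List of class `occupancy_table`: `percent` (sets x strains,
#'   unrounded; round at report time), `informative` (denominator counts)
#'   and `members_present` (list matrix of present member tags per cell).
#' @export
region_occupancy <- function(matrix, table, sets = names(table$sets)) {
  stopifnot(inherits(matrix, "presence_matrix"), inherits(table, "gene_table"))
  if (!length(sets)) stopf("no gene sets selected")
  unknown <- setdiff(sets, names(table$sets))
  if (length(unknown)) stopf("unknown gene set '%s'", unknown[1])
  m <- matrix$calls
  pct <- matrix(NA_real_, length(sets), ncol(m),
                dimnames = list(sets, colnames(m)))
  info <- pct
  detail <- matrix(vector("list", length(pct)), length(sets), ncol(m),
                   dimnames = dimnames(pct))
  for (s in sets) {
    members <- table$sets[[s]]
    if (!length(members)) stopf("gene set '%s' is empty", s)
    at <- match(members, rownames(m))
    if (anyNA(at)) stopf("set '%s' member '%s' absent from matrix", s,
                         members[which(is.na(at))[1]])
    sub <- m[at, , drop = FALSE]
    for (j in seq_len(ncol(m))) {
      ok <- !is.na(sub[, j])
      info[s, j] <- sum(ok)
      pct[s, j] <- if (any(ok)) 100 * sum(sub[ok, j]) / sum(ok) else NA_real_
      detail[[s, j]] <- members[ok][sub[ok, j]]
    }
  }
  structure(list(percent = pct, informative = info,
                 members_present = detail),
            class = "occupancy_table")
}

#' @export
print.occupancy_table <- function(x, ...) {
  cat(sprintf("occupancy_table: %d set(s) x %d strain(s)\n",
              nrow(x$percent), ncol(x$percent)))
  print(round_half_up(x$percent, 1))
  invisible(x)
}
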