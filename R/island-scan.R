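#' Classify genes by presence variability
#'
#' A gene is `conserved` when absent in no strain, `variable` when absent
#' in at least `min_absent` strains and present in at least `min_present`
#' (the signature of a horizontally mobile element across a strain panel),
#' and `uninformative` otherwise. Strains with no data for a gene are
#' ignored; a gene with no informative call at all is uninformative.
#'
#' @param matrix A [presence_matrix].
#' @param min_absent Minimum absent strains for "variable" (default 4).
#' @param min_present Minimum present strains for "variable" (default 1).
#' @return Named factor with levels conserved / variable / uninformative.
#' @export
gene_variability <- function(matrix, min_absent = 4L, min_present = 1L) {
  stopifnot(inherits(matrix, "presence_matrix"))
  m <- matrix$calls
  if (ncol(m) < min_absent + min_present)
    stopf("need >= %d strains for these thresholds", min_absent + min_present)
  n_pres <- rowSums(m, na.rm = TRUE)
  n_abs <- rowSums(!m, na.rm = TRUE)
  cls <- ifelse(n_pres + n_abs == 0, "uninformative",
         ifelse(n_abs == 0, "conserved",
         ifelse(n_abs >= min_absent & n_pres >= min_present,
                "variable", "uninformative")))
  factor(setNames(cls, rownames(m)),
         levels = c("conserved", "variable", "uninformative"))
}

#' A detected genomic-island candidate
#'
#' @param name Island name.
#' @param replicon Replicon the island lies on.
#' @param first,last 1-based indices of the first/last member locus in the
#'   replicon's locus order.
#' @param start,end 1-based inclusive bp coordinates (start of first locus
#'   to end of last).
#' @param n_genes Number of member loci.
#' @param size_kb Size in kb (one decimal); defaults to
#'   [island_size_kb()] of the coordinates.
#' @param score Fraction of member loci classified variable.
#' @param profile Named per-strain mean presence over member loci.
#' @param concordance Pearson correlation of `profile` with a two-group
#'   indicator, when a strain partition is supplied.
#' @return An object of class `island_call`.
#' @export
island_call <- function(name, replicon, first, last, start, end, n_genes,
                        size_kb = island_size_kb(start, end), score = NA_real_,
                        profile = NULL, concordance = NA_real_) {
  if (n_genes > 0 && start > end) stopf("island start > end")
  structure(list(name = name, replicon = replicon, first = first,
                 last = last, start = start, end = end,
                 n_genes = as.integer(n_genes), size_kb = size_kb,
                 score = score, profile = profile,
                 concordance = concordance),
            class = "island_call")
}

#' @export
print.island_call <- function(x, ...) {
  cat(sprintf("island_call %s: %s:%d-%d, %d genes, %.1f kb, score %.2f\n",
              x$name, x$replicon, x$start, x$end, x$n_genes, x$size_kb,
              x$score))
  invisible(x)
}

#' Island size in kb
#'
#' 1-based inclusive interval length in kb, rounded half-up to one
#' decimal — the convention of printed genomic-island tables.
#'
#' @param start,end 1-based inclusive coordinates, `1 <= start <= end`.
#' @return Size in kb.
#' @examples
#' island_size_kb(1217667, 1358908)  # 141.2
#' @export
island_size_kb <- function(start, end) {
  if (any(start < 1) || any(start > end)) stopf("need 1 <= start <= end")
  round_half_up((end - start + 1) / 1000, 1)
}

#' @noRd
qualifying_windows <- function(v, min_genes, max_gap, min_frac) {
  n <- length(v)
  out <- NULL
  # segments separated by runs of > max_gap non-variable loci; no
  # qualifying window can span such a run (its interior gaps would exceed
  # max_gap), so each segment is handled independently
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  breaks <- which(!r$values & r$lengths > max_gap)
  seg_bounds <- cbind(c(1L, ends[breaks] + 1L), c(starts[breaks] - 1L, n))
  for (s in seq_len(nrow(seg_bounds))) {
    a <- seg_bounds[s, 1]; b <- seg_bounds[s, 2]
    if (a > b) next
    vs <- which(v[a:b]) + a - 1L
    if (!length(vs)) next
    a <- vs[1]; b <- vs[length(vs)]
    len <- b - a + 1L
    if (len < min_genes) next
    cs <- cumsum(v)
    frac <- function(i, j) (cs[j] - cs[i] + 1L) / (j - i + 1L)  # v[i] true
    if (frac(a, b) >= min_frac) {
      # the full segment qualifies; every other window is contained in it
      out <- rbind(out, c(a, b))
      next
    }
    # enumerate windows with variable endpoints; interior gap runs are
    # automatically <= max_gap inside a segment
    cand <- NULL
    for (ii in seq_along(vs)) {
      i <- vs[ii]
      jj <- vs[vs - i + 1L >= min_genes]
      if (!length(jj)) next
      q <- jj[(cs[jj] - cs[i] + 1L) / (jj - i + 1L) >= min_frac]
      if (length(q)) cand <- rbind(cand, cbind(i, q))
    }
    if (is.null(cand)) next
    # keep windows not strictly contained in another qualifying window
    keep <- rep(TRUE, nrow(cand))
    for (k in seq_len(nrow(cand))) {
      contained <- cand[, 1] <= cand[k, 1] & cand[, 2] >= cand[k, 2]
      contained[k] <- FALSE
      if (any(contained)) keep[k] <- FALSE
    }
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  if (is.null(out)) return(matrix(integer(0), 0, 2))
  # overlap resolution: keep the maximal (longest) run first
  lens <- out[, 2] - out[, 1]
  ord <- order(-lens, out[, 1])
  out <- out[ord, , drop = FALSE]
  kept <- matrix(integer(0), 0, 2)
  for (k in seq_len(nrow(out))) {
    if (!nrow(kept) ||
        all(out[k, 2] < kept[, 1] | out[k, 1] > kept[, 2]))
      kept <- rbind(kept, out[k, ])
  }
  kept[order(kept[, 1]), , drop = FALSE]
}

#' Scan replicons for candidate genomic islands
#'
#' Formalizes pattern scanning of strain presence maps: a candidate island
#' is a maximal run of consecutive loci that starts and ends on a variable
#' gene, contains at least `min_genes` loci of which a fraction of at
#' least `min_variable_frac` are variable, and never has more than
#' `max_gap` consecutive non-variable loci inside. Runs never cross
#' replicon boundaries; overlapping candidates are resolved by keeping the
#' maximal run.
#'
#' @param matrix A [presence_matrix] covering the loci of `table`.
#' @param table A [gene_table]; loci must be sorted by start within each
#'   replicon.
#' @param min_genes Minimum run length (default 5).
#' @param max_gap Maximum internal run of non-variable loci (default 2).
#' @param min_variable_frac Minimum variable fraction (default 0.8).
#' @param groups Optional two-group strain partition (list with `I`, `II`)
#'   for the group-concordance score.
#' @param min_absent,min_present Passed to [gene_variability()].
#' @return List of [island_call] objects, ordered by replicon and start.
#' @export
scan_islands <- function(matrix, table, min_genes = 5L, max_gap = 2L,
                         min_variable_frac = 0.8, groups = NULL,
                         min_absent = 4L, min_present = 1L) {
  stopifnot(inherits(matrix, "presence_matrix"), inherits(table, "gene_table"))
  genes <- table$genes
  cls <- gene_variability(matrix, min_absent, min_present)
  at <- match(genes$locus_tag, names(cls))
  if (anyNA(at)) stopf("locus '%s' missing from presence matrix",
                       genes$locus_tag[which(is.na(at))[1]])
  calls <- matrix$calls[at, , drop = FALSE]
  variable <- cls[at] == "variable"
  ind <- NULL
  if (!is.null(groups))
    ind <- setNames(colnames(calls) %in% groups$I, colnames(calls)) * 1
  out <- list()
  for (rep_name in unique(genes$replicon)) {
    ri <- which(genes$replicon == rep_name)
    if (is.unsorted(genes$start[ri]))
      stopf("annotation not sorted by start on replicon '%s'", rep_name)
    win <- qualifying_windows(variable[ri], min_genes, max_gap,
                              min_variable_frac)
    for (k in seq_len(nrow(win))) {
      i <- win[k, 1]; j <- win[k, 2]
      rows <- ri[i:j]
      prof <- colMeans(calls[rows, , drop = FALSE], na.rm = TRUE)
      conc <- if (!is.null(ind) && stats::sd(prof) > 0 && stats::sd(ind) > 0)
        stats::cor(prof, ind[names(prof)]) else NA_real_
      out[[length(out) + 1L]] <- island_call(
        name = sprintf("%s-isl%02d", rep_name, k), replicon = rep_name,
        first = i, last = j,
        start = genes$start[rows[1]], end = genes$end[rows[length(rows)]],
        n_genes = j - i + 1L, score = mean(variable[rows]),
        profile = prof, concordance = conc)
    }
  }
  out
}

#' Merge two parts of an inversion-split island
#'
#' An island split in two by a chromosomal inversion is reported as the
#' union of its parts: sizes and gene counts are summed (not the spanning
#' interval), the per-strain profile is the gene-count-weighted mean, and
#' the name joins both parts. Merging with a zero-length placeholder
#' (0 genes, 0 kb) is the identity; overlapping inputs are an error.
#'
#' @param a,b [island_call] objects on the same replicon.
#' @return The merged `island_call`.
#' @export
merge_split_island <- function(a, b) {
  stopifnot(inherits(a, "island_call"), inherits(b, "island_call"))
  if (b$n_genes == 0L && b$size_kb == 0) return(a)
  if (a$n_genes == 0L && a$size_kb == 0) return(b)
  if (!identical(a$replicon, b$replicon))
    stopf("cannot merge islands on different replicons")
  if (a$start > b$start) { tmp <- a; a <- b; b <- tmp }
  if (b$start <= a$end) stopf("cannot merge overlapping islands")
  ng <- a$n_genes + b$n_genes
  prof <- if (!is.null(a$profile) && !is.null(b$profile))
    (a$profile * a$n_genes + b$profile * b$n_genes) / ng else NULL
  score <- if (is.na(a$score) || is.na(b$score)) NA_real_ else
    (a$score * a$n_genes + b$score * b$n_genes) / ng
  island_call(name = paste(a$name, b$name, sep = "+"), replicon = a$replicon,
              first = a$first, last = b$last, start = a$start, end = b$end,
              n_genes = ng, size_kb = a$size_kb + b$size_kb, score = score,
              profile = prof)
}
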