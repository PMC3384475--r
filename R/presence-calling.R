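#' Fold change over background
#'
#' Per spot, the ratio of the background-corrected test-channel intensity
#' to a background reference level: the spot's own measured background
#' (`per-spot` mode, default) or the array-wide fitted background mean
#' (`array-background` mode). The offset in the denominator matches the
#' offset added by the correction, so the ratio is defined for every spot.
#' The ratio deliberately uses the normexp-corrected (not loess-adjusted)
#' intensity: loess re-centres log-ratios locally in A and would absorb
#' the very absent-gene signal the ratio is meant to detect.
#'
#' @param norm A [normalize_scan()] result.
#' @param mode `"per-spot"` or `"array-background"`.
#' @return Data frame of class `fold_change_vector` with columns
#'   `probe_id`, `fold`, `valid` (FALSE for flagged spots, whose fold is
#'   `NA`).
#' @export
fold_change <- function(norm, mode = c("per-spot", "array-background")) {
  stopifnot(inherits(norm, "normalized_scan"))
  mode <- match.arg(mode)
  tab <- norm$table
  denom <- if (mode == "per-spot") tab$bg_test + norm$offset else
    norm$params_test$mu + norm$offset
  if (any(denom <= 0)) stopf("non-positive background denominator")
  fold <- tab$corr_test / denom
  fold[tab$flagged] <- NA_real_
  structure(data.frame(probe_id = tab$probe_id, fold = fold,
                       valid = !tab$flagged, stringsAsFactors = FALSE),
            class = c("fold_change_vector", "data.frame"))
}

#' Call gene presence from fold changes
#'
#' A gene is called present when its fold change is at or above `cutoff`
#' (inclusive). Flagged spots yield "no data" (`NA`), never absence. With a
#' probe-to-gene map, multi-probe genes are collapsed by majority vote over
#' their valid probes; ties give `NA`.
#'
#' @param folds A [fold_change] result.
#' @param cutoff Fold-change cutoff (default 20, the calibrated value used
#'   for the final strain comparisons).
#' @param probe_map Optional data frame (`probe_id`, `locus_tag`); when
#'   `NULL` each probe is one gene named by its probe id.
#' @return Named logical vector (`TRUE` present, `FALSE` absent, `NA` no
#'   data), one element per gene.
#' @export
call_presence <- function(folds, cutoff = 20, probe_map = NULL) {
  stopifnot(inherits(folds, "fold_change_vector"))
  if (!is.numeric(cutoff) || cutoff <= 0) stopf("'cutoff' must be > 0")
  call <- folds$fold >= cutoff
  call[!folds$valid] <- NA
  names(call) <- folds$probe_id
  if (is.null(probe_map)) return(call)
  stopifnot(all(c("probe_id", "locus_tag") %in% names(probe_map)))
  idx <- match(probe_map$probe_id, folds$probe_id)
  if (anyNA(idx)) stopf("probe_map references unknown probe '%s'",
                        probe_map$probe_id[which(is.na(idx))[1]])
  per_gene <- tapply(call[idx], probe_map$locus_tag, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA)
    n_yes <- sum(v)
    if (2L * n_yes == length(v)) NA else n_yes > length(v) / 2
  })
  out <- as.logical(per_gene)
  names(out) <- names(per_gene)
  out[unique(probe_map$locus_tag)]
}

#' Calibrate the presence cutoff on strains of known content
#'
#' Evaluates a grid of candidate cutoffs against one or more validation
#' hybridizations whose true gene content is known (e.g. plasmid-cured
#' derivatives of the reference): `fp(c)` counts known-absent genes called
#' present and `fn(c)` known-present genes called absent at cutoff `c`.
#' The chosen cutoff is the smallest grid value minimizing `fp + fn`
#' (deterministic, and conservative toward sensitivity).
#'
#' @param derivative_scans List; each element a list with `folds` (a
#'   [fold_change] result) and `truth` (named logical vector of true
#'   presence, by probe id). At least 20 informative genes in total are
#'   required; with fewer than 10 in either truth class the calibration
#'   is one-sided and a warning is raised.
#' @param grid Candidate cutoffs (default 1 to 100 in steps of 0.5).
#' @return List of class `cutoff_calibration`: `grid`, `fp`, `fn`,
#'   `cutoff`.
#' @export
calibrate_cutoff <- function(derivative_scans, grid = seq(1, 100, by = 0.5)) {
  if (!length(derivative_scans)) stopf("need at least one validation scan")
  if (!length(grid) || any(grid <= 0)) stopf("'grid' must be positive")
  grid <- sort(grid)
  pres <- abs_ <- numeric(0)
  for (ds in derivative_scans) {
    f <- ds$folds
    truth <- ds$truth
    stopifnot(inherits(f, "fold_change_vector"), is.logical(truth))
    at <- match(names(truth), f$probe_id)
    if (anyNA(at)) stopf("truth references unknown probe '%s'",
                         names(truth)[which(is.na(at))[1]])
    ok <- f$valid[at] & !is.na(truth)
    pres <- c(pres, f$fold[at][ok & truth])
    abs_ <- c(abs_, f$fold[at][ok & !truth])
  }
  if (length(pres) + length(abs_) < 20L)
    stopf("truth must cover >= 20 informative genes")
  if (length(pres) < 10L || length(abs_) < 10L)
    warning("fewer than 10 known genes in one truth class; ",
            "calibration is one-sided", call. = FALSE)
  fp <- vapply(grid, function(ct) sum(abs_ >= ct), numeric(1))
  fn <- vapply(grid, function(ct) sum(pres < ct), numeric(1))
  structure(list(grid = grid, fp = fp, fn = fn,
                 cutoff = grid[which.min(fp + fn)],
                 n_present = length(pres), n_absent = length(abs_)),
            class = "cutoff_calibration")
}

#' @export
print.cutoff_calibration <- function(x, ...) {
  at <- which(x$grid == x$cutoff)
  cat(sprintf(paste0("cutoff_calibration: c* = %g (fp = %d, fn = %d over ",
                     "%d absent / %d present genes)\n"),
              x$cutoff, x$fp[at], x$fn[at], x$n_absent, x$n_present))
  invisible(x)
}

#' Genes-by-strains presence matrix
#'
#' @param calls Logical matrix, genes in rows (named), strains in columns
#'   (named); `NA` means no data.
#' @param fold Optional numeric matrix of fold changes, same dimnames.
#' @return An object of class `presence_matrix`.
#' @export
presence_matrix <- function(calls, fold = NULL) {
  if (!is.matrix(calls) || !is.logical(calls))
    stopf("'calls' must be a logical matrix")
  if ((nrow(calls) > 0 && is.null(rownames(calls))) ||
      (ncol(calls) > 0 && is.null(colnames(calls))))
    stopf("'calls' must have gene rownames and strain colnames")
  if (!is.null(fold) && !identical(dim(fold), dim(calls)))
    stopf("'fold' dimensions must match 'calls'")
  structure(list(calls = calls, fold = fold), class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("presence_matrix: %d genes x %d strains (%.1f%% present, %.1f%% no data)\n",
              nrow(x$calls), ncol(x$calls),
              100 * mean(x$calls, na.rm = TRUE),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Assemble a presence matrix from per-strain calls
#'
#' @param call_list Named list (by strain) of named logical call vectors,
#'   as produced by [call_presence()]; all must cover the same genes.
#' @param fold_list Optional named list of fold-change vectors aligned the
#'   same way.
#' @return A [presence_matrix].
#' @export
build_presence_matrix <- function(call_list, fold_list = NULL) {
  if (!length(call_list) || is.null(names(call_list)))
    stopf("'call_list' must be a non-empty named list")
  genes <- names(call_list[[1]])
  m <- vapply(call_list, function(v) {
    if (!identical(names(v), genes)) stopf("call vectors cover different genes")
    v
  }, logical(length(genes)))
  rownames(m) <- genes
  fm <- NULL
  if (!is.null(fold_list)) {
    fm <- vapply(fold_list, function(f) f$fold[match(genes, f$probe_id)],
                 numeric(length(genes)))
    dimnames(fm) <- dimnames(m)
  }
  presence_matrix(m, fm)
}
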