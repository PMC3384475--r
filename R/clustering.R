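#' Correlation distance between strain profiles
#'
#' d(i, j) = 1 - Pearson correlation of the two strains' profile vectors
#' (e.g. their rows of the shared-gene percentage matrix, or per-island
#' conservation percentages). Ranges over [0, 2].
#'
#' @param profiles Numeric matrix, one row per strain (named), columns are
#'   profile entries (>= 2).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
profile_distance <- function(profiles) {
  if (!is.matrix(profiles) || nrow(profiles) < 2L || ncol(profiles) < 2L)
    stopf("'profiles' must be a matrix with >= 2 strains and >= 2 entries")
  v <- apply(profiles, 1, stats::var)
  if (any(v == 0))
    stopf("zero-variance profile for strain '%s'",
          rownames(profiles)[which(v == 0)[1]])
  d <- 1 - stats::cor(t(profiles))
  diag(d) <- 0
  d
}

#' Complete-linkage strain dendrogram
#'
#' Agglomerative clustering where the distance between two clusters is the
#' maximum pairwise member distance, so merge heights are non-decreasing
#' from leaves to root.
#'
#' @param dist Symmetric distance matrix (zero diagonal) or `dist` object.
#' @return List of class `strain_dendrogram` with elements `hclust` and
#'   `support` (`NULL` until [bootstrap_support()] is run).
#' @export
complete_linkage <- function(dist) {
  if (is.matrix(dist)) {
    if (!isSymmetric(unname(dist), tol = 1e-8))
      stopf("distance matrix must be symmetric")
    dist <- stats::as.dist(dist)
  }
  hc <- stats::hclust(dist, method = "complete")
  structure(list(hclust = hc, support = NULL), class = "strain_dendrogram")
}

#' @export
print.strain_dendrogram <- function(x, ...) {
  cat(sprintf("strain_dendrogram: %d strains%s\n", length(x$hclust$labels),
              if (is.null(x$support)) "" else
                sprintf(", bootstrap supports %g-%g%%",
                        min(x$support), max(x$support))))
  invisible(x)
}

#' Member sets of every internal node
#'
#' @param hc An `hclust` object.
#' @return Named list: for each internal node, the sorted member labels;
#'   names are the members pasted with `|` (clade keys).
#' @export
clade_sets <- function(hc) {
  n <- length(hc$labels)
  members <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    take <- function(x) if (x < 0) hc$labels[-x] else members[[x]]
    members[[k]] <- sort(c(take(hc$merge[k, 1]), take(hc$merge[k, 2])))
  }
  names(members) <- vapply(members, paste, "", collapse = "|")
  members
}

#' Shared-gene percentage profiles
#'
#' Each strain's profile is its row of the pairwise shared-gene percentage
#' matrix — the clustering input used for the strain comparison figures.
#' Percentages here are taken relative to the *mean* of the two strains'
#' detectable totals: when one strain's gene content nearly contains
#' another's (a strain panel where one group carries almost all mobile
#' elements), min-based percentages saturate at 100 across groups and
#' carry no grouping signal, while mean-based percentages still reflect
#' content size differences.
#'
#' @param matrix A [presence_matrix].
#' @return Numeric matrix, strains x strains.
#' @export
overlap_profiles <- function(matrix) {
  pairwise_overlap(matrix, pct = "mean")$percent
}

#' Bootstrap supports by gene resampling
#'
#' Resamples genes (matrix rows) with replacement `n_boot` times; each
#' replicate is taken through profiles, correlation distance and
#' complete linkage. The support of an internal node of the original tree
#' is the percentage of replicate trees containing that node's exact
#' strain set as a clade (ordinary bootstrap probability).
#'
#' @param matrix A [presence_matrix] (>= 2 genes).
#' @param n_boot Number of resamples (default 1000).
#' @param seed Integer seed; fixes supports exactly.
#' @param profile_fun Function mapping a `presence_matrix` to a profile
#'   matrix (default [overlap_profiles()]).
#' @return A `strain_dendrogram` (the tree of the full data) with
#'   `support`: named percent vector keyed by clade (members pasted with
#'   `|`).
#' @export
bootstrap_support <- function(matrix, n_boot = 1000L, seed = 1L,
                              profile_fun = overlap_profiles) {
  stopifnot(inherits(matrix, "presence_matrix"))
  if (n_boot < 1L) stopf("'n_boot' must be >= 1")
  n_genes <- nrow(matrix$calls)
  if (n_genes < 2L) stopf("need >= 2 genes to resample")
  tree <- complete_linkage(profile_distance(profile_fun(matrix)))
  orig <- clade_sets(tree$hclust)
  hits <- setNames(numeric(length(orig)), names(orig))
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n_genes, replace = TRUE)
      pm_b <- presence_matrix(matrix$calls[idx, , drop = FALSE])
      keys <- tryCatch({
        hc_b <- complete_linkage(profile_distance(profile_fun(pm_b)))$hclust
        names(clade_sets(hc_b))
      }, error = function(e) character(0))
      at <- names(hits) %in% keys
      hits[at] <- hits[at] + 1
    }
  })
  tree$support <- 100 * hits / n_boot
  tree
}

#' Cut a dendrogram into the two main strain groups
#'
#' Removes the root merge and returns the two resulting strain sets,
#' labelled I and II by decreasing mean island occupancy when supplied,
#' otherwise by decreasing size.
#'
#' @param tree A `strain_dendrogram`.
#' @param island_occupancy Optional named numeric: per-strain mean island
#'   occupancy percent.
#' @return List with character vectors `I` and `II`.
#' @export
cut_two_groups <- function(tree, island_occupancy = NULL) {
  stopifnot(inherits(tree, "strain_dendrogram"))
  hc <- tree$hclust
  if (length(hc$labels) < 2L) stopf("need >= 2 strains")
  cl <- stats::cutree(hc, k = 2)
  g1 <- names(cl)[cl == 1]
  g2 <- names(cl)[cl == 2]
  swap <- if (!is.null(island_occupancy)) {
    mean(island_occupancy[g1], na.rm = TRUE) <
      mean(island_occupancy[g2], na.rm = TRUE)
  } else length(g1) < length(g2)
  if (swap) list(I = g2, II = g1) else list(I = g1, II = g2)
}
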