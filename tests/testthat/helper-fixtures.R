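# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code; oracles deliberately avoid the package's
# own code paths for the quantity they check.

# -- small study fixtures ----------------------------------------------------

tiny_genome <- function(n_loci = 300L, n_islands = 3L, seed = 1L,
                        island_genes = c(5L, 20L)) {
  cfg <- genome_config(
    replicons = data.frame(name = c("CHR1", "pSML"),
                           length_bp = c(n_loci * 1000L, 40L * 1000L),
                           n_loci = c(n_loci, 40L), stringsAsFactors = FALSE),
    islands = c(CHR1 = n_islands), island_genes = island_genes)
  build_genome_model(cfg, seed)
}

tiny_noise <- function(...) {
  args <- list(...)
  defaults <- list(n_controls = 60L)
  do.call(noise_model, utils::modifyList(defaults, args))
}

# presence matrix straight from generator truth (no scans)
truth_matrix <- function(model, contents) {
  m <- vapply(contents, function(ct) model$loci$locus_tag %in% ct$present,
              logical(nrow(model$loci)))
  dimnames(m) <- list(model$loci$locus_tag,
                      vapply(contents, `[[`, "", "strain_id"))
  presence_matrix(m)
}

random_presence <- function(n_genes, n_strains, p = 0.5, na_rate = 0,
                            seed = 1L) {
  set.seed(seed)
  m <- matrix(stats::runif(n_genes * n_strains) < p, n_genes, n_strains,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_strains))))
  if (na_rate > 0) m[stats::runif(length(m)) < na_rate] <- NA
  presence_matrix(m)
}

rand_index <- function(a, b) {
  n <- length(a)
  agree <- 0L
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n))
    agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
  agree / choose(n, 2)
}

# supports attached to the two children of the root merge
root_children_supports <- function(tree) {
  hc <- tree$hclust
  sets <- clade_sets(hc)
  top <- hc$merge[nrow(hc$merge), ]
  keys <- vapply(top[top > 0], function(k) names(sets)[k], "")
  unname(tree$support[keys])
}

# -- independent bootstrap oracle --------------------------------------------
# resample-recluster loop written against base R only: manual shared-percent
# profiles, cor, hclust, and clade extraction via cutree at each merge height

manual_profiles <- function(calls) {
  ns <- ncol(calls)
  det <- colSums(calls, na.rm = TRUE)
  p <- matrix(0, ns, ns, dimnames = list(colnames(calls), colnames(calls)))
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    sh <- sum(calls[, i] & calls[, j], na.rm = TRUE)
    p[i, j] <- round_half_up(100 * sh / ((det[i] + det[j]) / 2), 1)
  }
  p
}

manual_clades <- function(calls) {
  hc <- stats::hclust(stats::as.dist(1 - stats::cor(t(manual_profiles(calls)))),
                      method = "complete")
  lab <- hc$labels
  unlist(lapply(seq_len(length(lab) - 1L), function(k) {
    cl <- stats::cutree(hc, h = hc$height[k] + 1e-12)
    keys <- vapply(split(lab, cl), function(v)
      paste(sort(v), collapse = "|"), "")
    unname(keys[lengths(split(lab, cl)) > 1])
  }))
}

independent_bootstrap_supports <- function(pm, clade_keys, n_boot, seed) {
  hits <- setNames(numeric(length(clade_keys)), clade_keys)
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(pm$calls), replace = TRUE)
    prof <- manual_profiles(pm$calls[idx, , drop = FALSE])
    # degenerate replicate (empty or constant profile): contributes nothing,
    # mirroring the error-and-skip path of the implementation
    if (anyNA(prof) || any(apply(prof, 1, stats::var) == 0)) next
    keys <- unique(manual_clades(pm$calls[idx, , drop = FALSE]))
    at <- clade_keys %in% keys
    hits[at] <- hits[at] + 1
  }
  100 * hits / n_boot
}

# -- normexp oracles ---------------------------------------------------------

# analytic density of X = Normal(mu, sigma^2) + Exponential(mean alpha)
dnormexp_log <- function(x, mu, sigma, alpha) {
  -log(alpha) + (mu - x) / alpha + sigma^2 / (2 * alpha^2) +
    stats::pnorm((x - mu) / sigma - sigma / alpha, log.p = TRUE)
}

# posterior mean E[S | X = x] by direct numerical integration over s.
# The integrand is rescaled by its peak value (otherwise a narrow normal
# kernel deep inside a wide interval underflows or is missed) and the
# integral is split at the peak so quadrature always sees it.
numint_posterior_mean <- function(x, mu, sigma, alpha) {
  logf <- function(s) stats::dnorm(x - s, mu, sigma, log = TRUE) - s / alpha
  s_peak <- min(max(x - mu, 0), max(x - mu - sigma^2 / alpha, 0))
  M <- logf(s_peak)
  f0 <- function(s) exp(logf(s) - M)
  f1 <- function(s) s * f0(s)
  upper <- max(x - mu, 0) + 15 * sigma + 15 * alpha
  pieces <- sort(unique(pmin(pmax(
    c(0, s_peak + sigma * c(-40, -10, 0, 10, 40), upper), 0), upper)))
  int <- function(f) sum(vapply(seq_len(length(pieces) - 1L), function(k)
    stats::integrate(f, pieces[k], pieces[k + 1L], rel.tol = 1e-12,
                     abs.tol = 0)$value, numeric(1)))
  int(f1) / int(f0)
}

# -- island-scanner oracle ---------------------------------------------------

# exhaustive enumeration of all maximal qualifying windows + overlap
# resolution, straight from the definition
brute_force_windows <- function(v, min_genes, max_gap, min_frac) {
  n <- length(v)
  qual <- NULL
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j - i + 1 < min_genes || !v[i] || !v[j]) next
    runs <- rle(v[i:j])
    gaps <- runs$lengths[!runs$values]
    if (length(gaps) && max(gaps) > max_gap) next
    if (mean(v[i:j]) < min_frac) next
    qual <- rbind(qual, c(i, j))
  }
  if (is.null(qual)) return(matrix(integer(0), 0, 2))
  maximal <- qual[vapply(seq_len(nrow(qual)), function(k) {
    inside <- qual[, 1] <= qual[k, 1] & qual[, 2] >= qual[k, 2]
    inside[k] <- FALSE
    !any(inside)
  }, logical(1)), , drop = FALSE]
  ord <- order(-(maximal[, 2] - maximal[, 1]), maximal[, 1])
  maximal <- maximal[ord, , drop = FALSE]
  kept <- matrix(integer(0), 0, 2)
  for (k in seq_len(nrow(maximal))) {
    if (!nrow(kept) ||
        all(maximal[k, 2] < kept[, 1] | maximal[k, 1] > kept[, 2]))
      kept <- rbind(kept, maximal[k, ])
  }
  kept[order(kept[, 1]), , drop = FALSE]
}

# gene table with one locus per index on one replicon
index_gene_table <- function(n, replicon = "CHR1", sets = list()) {
  gene_table(data.frame(
    locus_tag = sprintf("L%03d", seq_len(n)), replicon = replicon,
    start = seq_len(n) * 1000L - 999L, end = seq_len(n) * 1000L - 100L,
    strand = "+", probe_id = sprintf("P%03d", seq_len(n)),
    stringsAsFactors = FALSE), sets)
}

# hand-built normalized_scan for calling tests
fake_norm <- function(corr_test, bg_test,
                      flagged = rep(FALSE, length(corr_test)),
                      mu = 0, offset = 50) {
  n <- length(corr_test)
  structure(list(
    strain_id = "X",
    params_test = normexp_params(mu, 1, 100),
    params_ref = normexp_params(0, 1, 100),
    offset = offset,
    table = data.frame(probe_id = sprintf("P%02d", seq_len(n)), block = 1L,
                       flagged = flagged, bg_test = bg_test,
                       corr_test = corr_test, corr_ref = 1000, A = 10, M = 0,
                       test_norm = corr_test, stringsAsFactors = FALSE)),
    class = "normalized_scan")
}
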