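#' Spot-level two-channel scan
#'
#' Container for one strain's hybridization: an ordered spot table with
#' print-tip coordinates, foreground/background median intensities for the
#' test (query strain) and reference channels, and a quality flag. Any
#' negative flag marks the spot as unusable (scanner software convention).
#'
#' @param strain_id Strain identifier.
#' @param spots Data frame with columns `probe_id`, `block`, `row`,
#'   `column`, `fg_test`, `bg_test`, `fg_ref`, `bg_ref`, `flag`.
#' @return An object of class `array_scan`.
#' @export
array_scan <- function(strain_id, spots) {
  req <- c("probe_id", "block", "row", "column",
           "fg_test", "bg_test", "fg_ref", "bg_ref", "flag")
  miss <- setdiff(req, names(spots))
  if (length(miss)) stopf("spot table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  spots <- spots[, req]
  if (anyDuplicated(spots$probe_id))
    stopf("duplicate probe_id: '%s'",
          spots$probe_id[duplicated(spots$probe_id)][1])
  num <- c("block", "row", "column", "fg_test", "bg_test", "fg_ref", "bg_ref")
  for (cn in num) {
    v <- spots[[cn]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
      stopf("column '%s' must be finite numeric", cn)
  }
  if (any(spots$block < 1 | spots$row < 1 | spots$column < 1))
    stopf("block/row/column must be positive")
  if (any(spots[c("fg_test", "bg_test", "fg_ref", "bg_ref")] < 0))
    stopf("intensities must be >= 0")
  structure(list(strain_id = as.character(strain_id), spots = spots),
            class = "array_scan")
}

#' @export
print.array_scan <- function(x, ...) {
  cat(sprintf("array_scan '%s': %d spots, %d flagged\n", x$strain_id,
              nrow(x$spots), sum(x$spots$flag < 0)))
  invisible(x)
}

#' Write a spot table
#'
#' Tab-delimited UTF-8 with `#`-prefixed metadata lines (`# strain_id=...`)
#' followed by a header row and one row per spot.
#'
#' @param scan An [array_scan].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spot_table <- function(scan, path) {
  stopifnot(inherits(scan, "array_scan"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# strain_id=", scan$strain_id), con)
  utils::write.table(scan$spots, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a spot table
#'
#' Inverse of [write_spot_table()]. Rows with unparseable numeric fields are
#' rejected with the offending file line number; missing columns and
#' duplicate probe ids are format errors.
#'
#' @param path Spot-table file.
#' @return An [array_scan].
#' @export
read_spot_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta <- grep("^#", lines, value = TRUE)
  body_at <- grep("^#", lines, invert = TRUE)
  if (length(body_at) < 1L) stopf("'%s': no header line found", path)
  strain_id <- sub("^#\\s*strain_id=", "",
                   grep("strain_id=", meta, value = TRUE)[1])
  if (is.na(strain_id)) strain_id <- "unknown"
  header <- strsplit(lines[body_at[1]], "\t", fixed = TRUE)[[1]]
  req <- c("probe_id", "block", "row", "column",
           "fg_test", "bg_test", "fg_ref", "bg_ref", "flag")
  miss <- setdiff(req, header)
  if (length(miss)) stopf("'%s': missing column(s): %s", path,
                          paste(miss, collapse = ", "))
  rows_at <- body_at[-1]
  fields <- strsplit(lines[rows_at], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(header)))
    stopf("'%s' line %d: expected %d fields, found %d", path,
          rows_at[which(nf != length(header))[1]], length(header),
          nf[which(nf != length(header))[1]])
  tab <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(tab) <- header
  for (cn in setdiff(req, "probe_id")) {
    v <- suppressWarnings(as.numeric(tab[[cn]]))
    if (anyNA(v))
      stopf("'%s' line %d: non-numeric value '%s' in column '%s'", path,
            rows_at[which(is.na(v))[1]], tab[[cn]][which(is.na(v))[1]], cn)
    tab[[cn]] <- v
  }
  for (cn in c("block", "row", "column", "flag")) tab[[cn]] <- as.integer(tab[[cn]])
  array_scan(strain_id, tab)
}

#' Probe/gene annotation with named gene sets
#'
#' @param genes Data frame with columns `locus_tag`, `replicon`, `start`,
#'   `end`, `strand`, `probe_id`; coordinates are 1-based inclusive.
#' @param sets Named list mapping set name to a character vector of member
#'   locus tags (genomic islands, plasmids, resistance clusters, ...).
#' @return An object of class `gene_table`.
#' @export
gene_table <- function(genes, sets = list()) {
  req <- c("locus_tag", "replicon", "start", "end", "strand", "probe_id")
  miss <- setdiff(req, names(genes))
  if (length(miss)) stopf("annotation lacks column(s): %s",
                          paste(miss, collapse = ", "))
  genes <- genes[, req]
  if (anyDuplicated(genes$locus_tag))
    stopf("duplicate locus_tag: '%s'",
          genes$locus_tag[duplicated(genes$locus_tag)][1])
  if (any(genes$start > genes$end))
    stopf("start > end for locus '%s'",
          genes$locus_tag[which(genes$start > genes$end)[1]])
  if (any(genes$start < 1)) stopf("coordinates are 1-based; start must be >= 1")
  for (s in names(sets)) {
    unknown <- setdiff(sets[[s]], genes$locus_tag)
    if (length(unknown))
      stopf("gene set '%s' references unknown locus '%s'", s, unknown[1])
  }
  structure(list(genes = genes, sets = sets), class = "gene_table")
}

#' @export
print.gene_table <- function(x, ...) {
  cat(sprintf("gene_table: %d loci on %d replicon(s), %d gene set(s)\n",
              nrow(x$genes), length(unique(x$genes$replicon)),
              length(x$sets)))
  invisible(x)
}

#' Read gene annotation and optional gene sets
#'
#' @param annotation_path TSV with header `locus_tag replicon start end
#'   strand probe_id` (1-based inclusive coordinates).
#' @param genesets_path Optional headerless two-column TSV
#'   (`set_name`, `locus_tag`).
#' @return A [gene_table].
#' @export
read_gene_table <- function(annotation_path, genesets_path = NULL) {
  genes <- utils::read.delim(annotation_path, stringsAsFactors = FALSE,
                             colClasses = c(start = "integer", end = "integer"))
  sets <- list()
  if (!is.null(genesets_path)) {
    gs <- utils::read.delim(genesets_path, header = FALSE,
                            stringsAsFactors = FALSE,
                            col.names = c("set_name", "locus_tag"))
    sets <- split(gs$locus_tag, gs$set_name)
  }
  gene_table(genes, sets)
}

#' @noRd
write_gene_table <- function(table, annotation_path, genesets_path = NULL) {
  utils::write.table(table$genes, annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(genesets_path)) {
    gs <- data.frame(
      set_name = rep(names(table$sets), lengths(table$sets)),
      locus_tag = unlist(table$sets, use.names = FALSE))
    utils::write.table(gs, genesets_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(annotation_path)
}

#' Write / read a presence matrix as TSV
#'
#' Genes in rows, strains in columns; cells are `1` (present), `0`
#' (absent) or `NA` (flagged / no data — never conflated with absence).
#'
#' @param matrix A [presence_matrix].
#' @param path TSV file.
#' @return `path` invisibly (writer); a `presence_matrix` (reader). The
#'   fold-change layer is not round-tripped.
#' @export
write_presence_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "presence_matrix"))
  m <- matrix$calls + 0L
  df <- data.frame(locus_tag = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_presence_tsv
#' @export
read_presence_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE]) == 1L
  rownames(m) <- df[[1]]
  presence_matrix(m)
}

#' Write an occupancy table as TSV
#'
#' One row per region/gene set, one column per strain, percents printed to
#' one decimal (half-up).
#'
#' @param occupancy An [occupancy_table][region_occupancy].
#' @param path TSV file.
#' @export
write_occupancy_tsv <- function(occupancy, path) {
  stopifnot(inherits(occupancy, "occupancy_table"))
  m <- occupancy$percent
  fmt <- matrix(ifelse(is.na(m), "NA", sprintf("%.1f", round_half_up(m, 1))),
                nrow = nrow(m), dimnames = dimnames(m))
  out <- data.frame(set = rownames(m), fmt,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write island calls as BED and as a 1-based report
#'
#' The BED file uses 0-based half-open coordinates
#' (`start - 1`, `end`); the companion report keeps the 1-based inclusive
#' convention of genome-annotation tables, with sizes in kb at one decimal.
#'
#' @param islands List of [island_call] objects (may be empty).
#' @param bed_path,report_path Output files; either may be `NULL` to skip.
#' @export
write_islands <- function(islands, bed_path = NULL, report_path = NULL) {
  if (!is.null(bed_path)) {
    con <- file(bed_path, "w")
    writeLines("#replicon\tstart\tend\tname\tscore\tn_genes", con)
    for (isl in islands)
      writeLines(sprintf("%s\t%d\t%d\t%s\t%.3f\t%d", isl$replicon,
                         isl$start - 1L, isl$end, isl$name, isl$score,
                         isl$n_genes), con)
    close(con)
  }
  if (!is.null(report_path)) {
    df <- if (length(islands)) do.call(rbind, lapply(islands, function(isl)
      data.frame(name = isl$name, replicon = isl$replicon,
                 size_kb = sprintf("%.1f", isl$size_kb),
                 coordinates = sprintf("%d-%d", isl$start, isl$end),
                 n_genes = isl$n_genes, score = round(isl$score, 3),
                 stringsAsFactors = FALSE)))
    else data.frame(name = character(), replicon = character(),
                    size_kb = character(), coordinates = character(),
                    n_genes = integer(), score = numeric())
    utils::write.table(df, report_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(bed_path)
}

#' Write a strain dendrogram as newick
#'
#' Bootstrap supports (percent), when present, become internal node labels.
#'
#' @param dendrogram A [strain_dendrogram][complete_linkage], optionally
#'   with supports attached by [bootstrap_support()].
#' @param path Newick file.
#' @export
write_newick <- function(dendrogram, path) {
  stopifnot(inherits(dendrogram, "strain_dendrogram"))
  phy <- ape::as.phylo(dendrogram$hclust)
  if (!is.null(dendrogram$support)) {
    labs <- character(phy$Nnode)
    clades <- ape::prop.part(phy)
    for (k in seq_len(phy$Nnode)) {
      members <- sort(attr(clades, "labels")[clades[[k]]])
      key <- paste(members, collapse = "|")
      if (key %in% names(dendrogram$support))
        labs[k] <- sprintf("%g", dendrogram$support[[key]])
    }
    phy$node.label <- labs
  }
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Write the full result bundle of a run
#'
#' @param matrix A [presence_matrix].
#' @param occupancy An occupancy table, or `NULL`.
#' @param islands List of island calls.
#' @param dendrogram A strain dendrogram, or `NULL`.
#' @param outdir Output directory (created if needed).
#' @return Named character vector of written paths (the manifest).
#' @export
write_outputs <- function(matrix, occupancy, islands, dendrogram, outdir) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create output directory '%s'", outdir)
  manifest <- c(presence = file.path(outdir, "presence_matrix.tsv"),
                islands_bed = file.path(outdir, "islands.bed"),
                islands_report = file.path(outdir, "islands_report.tsv"))
  write_presence_tsv(matrix, manifest[["presence"]])
  write_islands(islands, manifest[["islands_bed"]], manifest[["islands_report"]])
  if (!is.null(occupancy)) {
    manifest[["occupancy"]] <- file.path(outdir, "occupancy.tsv")
    write_occupancy_tsv(occupancy, manifest[["occupancy"]])
  }
  if (!is.null(dendrogram)) {
    manifest[["tree"]] <- file.path(outdir, "strains.nwk")
    write_newick(dendrogram, manifest[["tree"]])
  }
  manifest
}
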