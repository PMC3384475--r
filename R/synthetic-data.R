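#' Generator settings for a reference-like genome
#'
#' Describes the replicon layout, probe (locus) counts and planted-region
#' structure of a synthetic reference genome. The defaults emulate a
#' four-replicon metal-resistant beta-proteobacterium: two chromosomes and
#' two megaplasmids carrying 6205 CDS probes in total, with 13 genomic
#' islands planted on chromosome 1 and 5 on chromosome 2. Each plasmid is
#' additionally planted as a single "plasmid-backbone" region so that
#' plasmid-cured validation derivatives can be generated.
#'
#' @param replicons Data frame with columns `name`, `length_bp`, `n_loci`.
#' @param islands Named integer vector: number of islands to plant per
#'   (chromosomal) replicon.
#' @param island_genes Length-2 integer vector, minimum and maximum island
#'   length in genes.
#' @param gene_bp Nominal gene footprint in bp (genes are laid out
#'   non-overlapping on a regular grid within each replicon).
#' @return A list of class `genome_config`.
#' @export
genome_config <- function(replicons = data.frame(
                            name = c("CHR1", "CHR2", "pMOL28", "pMOL30"),
                            length_bp = c(3928089L, 2580084L, 171459L, 233720L),
                            n_loci = c(3533L, 2331L, 125L, 216L),
                            stringsAsFactors = FALSE),
                          islands = c(CHR1 = 13L, CHR2 = 5L),
                          island_genes = c(5L, 150L),
                          gene_bp = 900L) {
  stopifnot(is.data.frame(replicons),
            all(c("name", "length_bp", "n_loci") %in% names(replicons)))
  if (any(replicons$n_loci < 1L) || any(replicons$length_bp < replicons$n_loci))
    stopf("each replicon needs >= 1 locus and >= 1 bp per locus")
  if (length(island_genes) != 2L || island_genes[1] > island_genes[2] ||
      island_genes[1] < 1L)
    stopf("'island_genes' must be c(min, max) with 1 <= min <= max")
  if (length(islands) && !all(names(islands) %in% replicons$name))
    stopf("islands requested on unknown replicon(s): %s",
          paste(setdiff(names(islands), replicons$name), collapse = ", "))
  structure(list(replicons = replicons, islands = islands,
                 island_genes = as.integer(island_genes),
                 gene_bp = as.integer(gene_bp)),
            class = "genome_config")
}

#' Build a synthetic genome model with planted regions
#'
#' Lays out loci on each replicon (non-overlapping, sorted by start) and
#' plants the configured genomic islands as contiguous locus runs. Island
#' positions and lengths are drawn from `seed`; each island is recorded in
#' the truth table (`$regions`) together with the plasmid-backbone regions.
#'
#' Islands are placed one per equal-width bin of the replicon's locus index
#' so that planted regions are always separated by conserved backbone; a
#' configuration whose maximum island length does not fit in a bin (plus a
#' 5-locus margin on each side) is rejected.
#'
#' @param config A [genome_config()].
#' @param seed Integer seed; fixes the model exactly.
#' @return A list of class `genome_model` with elements `replicons`,
#'   `loci` (locus_tag, replicon, start, end, strand, probe_id, ordered by
#'   replicon then start) and `regions` (name, class, replicon, first, last
#'   — global row indices into `loci`).
#' @export
build_genome_model <- function(config = genome_config(), seed = 1L) {
  stopifnot(inherits(config, "genome_config"))
  rep_tab <- config$replicons

  loci <- do.call(rbind, lapply(seq_len(nrow(rep_tab)), function(r) {
    n <- rep_tab$n_loci[r]
    spacing <- rep_tab$length_bp[r] %/% n
    glen <- max(1L, min(config$gene_bp, spacing - 50L))
    start <- (seq_len(n) - 1L) * spacing + 1L
    data.frame(locus_tag = sprintf("%s_%04d", rep_tab$name[r], seq_len(n)),
               replicon = rep_tab$name[r],
               start = start, end = start + glen - 1L,
               strand = "+", stringsAsFactors = FALSE)
  }))
  loci$probe_id <- sprintf("P%05d", seq_len(nrow(loci)))
  rownames(loci) <- NULL

  regions <- with_seed(seed, {
    out <- list()
    for (rep_name in names(config$islands)) {
      n_isl <- config$islands[[rep_name]]
      if (n_isl < 1L) next
      idx <- which(loci$replicon == rep_name)
      bin <- length(idx) %/% n_isl
      if (config$island_genes[2] + 10L > bin)
        stopf("replicon %s cannot hold %d islands of up to %d genes",
              rep_name, n_isl, config$island_genes[2])
      pre <- if (rep_name == "CHR1") "CMGI-" else "CMGI-2-"
      for (k in seq_len(n_isl)) {
        len <- sample(seq(config$island_genes[1], config$island_genes[2]), 1L)
        lo <- (k - 1L) * bin + 5L
        first <- lo + sample.int(bin - len - 9L, 1L)
        out[[length(out) + 1L]] <- data.frame(
          name = paste0(pre, k), class = "island", replicon = rep_name,
          first = idx[first], last = idx[first + len - 1L],
          stringsAsFactors = FALSE)
      }
    }
    # plasmid replicons (lowercase-p prefix, bacterial naming convention)
    # become one whole-replicon backbone region (cured-derivative targets)
    plasmids <- rep_tab$name[grepl("^p", rep_tab$name)]
    for (rep_name in setdiff(plasmids, names(config$islands))) {
      idx <- which(loci$replicon == rep_name)
      out[[length(out) + 1L]] <- data.frame(
        name = rep_name, class = "plasmid-backbone", replicon = rep_name,
        first = idx[1], last = idx[length(idx)], stringsAsFactors = FALSE)
    }
    if (length(out)) do.call(rbind, out) else
      data.frame(name = character(), class = character(),
                 replicon = character(), first = integer(), last = integer(),
                 stringsAsFactors = FALSE)
  })
  rownames(regions) <- NULL

  structure(list(replicons = rep_tab, loci = loci, regions = regions),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d loci on %d replicon(s), %d planted region(s)\n",
              nrow(x$loci), nrow(x$replicons), nrow(x$regions)))
  invisible(x)
}

#' @noRd
region_loci <- function(model, region_name) {
  r <- model$regions[model$regions$name == region_name, , drop = FALSE]
  if (nrow(r) == 0L) stopf("unknown region '%s'", region_name)
  model$loci$locus_tag[seq(r$first, r$last)]
}

#' Assign gene content to synthetic strains
#'
#' Backbone loci (outside every planted region) are present in every strain.
#' Each planted region is inherited as a block: a strain carries the whole
#' region with its group's probability, after which individual loci may be
#' dropped with probability `dropout` (emulating diverged or missing genes
#' inside a carried element).
#'
#' @param model A [build_genome_model()] result.
#' @param n_groupI,n_groupII Number of strains in each content group.
#' @param island_presence Named probabilities `c(I = , II = )` that a strain
#'   of each group carries any given island.
#' @param plasmid_presence Same, for plasmid-backbone regions.
#' @param dropout Per-locus dropout probability within a carried region.
#' @param seed Integer seed.
#' @return List of `strain_content` objects (`strain_id`, `group`,
#'   `present` — character vector of locus tags).
#' @export
assign_strain_content <- function(model, n_groupI = 7L, n_groupII = 9L,
                                  island_presence = c(I = 0.9, II = 0.2),
                                  plasmid_presence = c(I = 1.0, II = 0.7),
                                  dropout = 0.02, seed = 1L) {
  stopifnot(inherits(model, "genome_model"))
  if (n_groupI + n_groupII == 0L) stopf("need at least one strain")
  if (any(island_presence < 0) || any(island_presence > 1) ||
      any(plasmid_presence < 0) || any(plasmid_presence > 1))
    stopf("presence probabilities must lie in [0, 1]")
  if (!all(c("I", "II") %in% names(island_presence)))
    stopf("'island_presence' must have elements named I and II")

  groups <- rep(c("I", "II"), c(n_groupI, n_groupII))
  ids <- sprintf("S%02d", seq_along(groups))
  reg <- model$regions
  in_region <- rep(FALSE, nrow(model$loci))
  for (k in seq_len(nrow(reg))) in_region[seq(reg$first[k], reg$last[k])] <- TRUE
  backbone <- model$loci$locus_tag[!in_region]

  with_seed(seed, lapply(seq_along(ids), function(i) {
    g <- groups[i]
    present <- backbone
    for (k in seq_len(nrow(reg))) {
      p <- if (reg$class[k] == "island") island_presence[[g]] else
        plasmid_presence[[g]]
      if (stats::runif(1) <= p) {
        tags <- model$loci$locus_tag[seq(reg$first[k], reg$last[k])]
        keep <- stats::runif(length(tags)) >= dropout
        present <- c(present, tags[keep])
      }
    }
    structure(list(strain_id = ids[i], group = g,
                   present = sort(present)),
              class = "strain_content")
  }))
}

#' @export
print.strain_content <- function(x, ...) {
  cat(sprintf("strain_content %s (group %s): %d loci present\n",
              x$strain_id, x$group, length(x$present)))
  invisible(x)
}

#' Derive a validation strain of known content
#'
#' Returns a copy of `reference` with every locus of one planted region
#' removed — the in-silico analogue of a plasmid-cured or island-deleted
#' derivative whose true gene content is known, used to calibrate the
#' presence-calling cutoff. The operation is idempotent.
#'
#' @param reference A `strain_content`.
#' @param region_name Name of a planted region in `model`.
#' @param model The `genome_model` the reference was drawn from.
#' @return A `strain_content` with `group = "derivative"`.
#' @export
make_validation_derivative <- function(reference, region_name, model) {
  stopifnot(inherits(reference, "strain_content"),
            inherits(model, "genome_model"))
  drop_tags <- region_loci(model, region_name)
  suffix <- paste0("-d", region_name)
  id <- if (endsWith(reference$strain_id, suffix)) reference$strain_id else
    paste0(reference$strain_id, suffix)
  structure(list(strain_id = id, group = "derivative",
                 present = setdiff(reference$present, drop_tags)),
            class = "strain_content")
}

#' Two-channel array noise model
#'
#' Parameters of the simulated scanner output. The background of each
#' channel is Normal(`mu_b`, `sigma_b`^2); a hybridizing (present) spot
#' adds a signal of mean `alpha_s` on a 16-bit-like intensity scale, drawn
#' as a detection floor (`signal_floor_frac * alpha_s`, the weakest signal
#' a truly hybridizing probe produces) plus an exponential spread above it
#' with mean `alpha_s * (1 - signal_floor_frac)`. Print-tip bias multiplies
#' the test channel by `2^(tip_bias_amplitude * u)` with `u` spread over
#' [-1, 1] across blocks, and a dye trend multiplies it by
#' `2^(dye_intercept + dye_slope * (A - mean(A)))` where A is the mean
#' log2 intensity.
#'
#' @param mu_b,sigma_b Background mean and sd (intensity units).
#' @param alpha_s Mean present-spot signal (intensity units).
#' @param signal_floor_frac Detection floor as a fraction of `alpha_s`
#'   (in [0, 1)).
#' @param tip_bias_amplitude Print-tip bias amplitude (log2 units).
#' @param dye_intercept,dye_slope Dye-trend coefficients (log2 units,
#'   intercept and slope versus centred A).
#' @param flag_rate Fraction of spots flagged bad (flag -100).
#' @param blocks Print-tip grid as c(rows, cols) of blocks.
#' @param n_controls Number of blank buffer spots spread over the array.
#'   They carry no probe, so both channels read pure background; as on
#'   real spotted slides they anchor the background component of the
#'   intensity model even when nearly every gene probe hybridizes.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(mu_b = 100, sigma_b = 15, alpha_s = 20000,
                        signal_floor_frac = 0.25, tip_bias_amplitude = 0.3,
                        dye_intercept = 0, dye_slope = 0.15,
                        flag_rate = 0.02, blocks = c(4L, 4L),
                        n_controls = 600L) {
  if (mu_b <= 0 || sigma_b < 0 || alpha_s <= 0)
    stopf("mu_b and alpha_s must be > 0; sigma_b must be >= 0")
  if (signal_floor_frac < 0 || signal_floor_frac >= 1)
    stopf("'signal_floor_frac' must be in [0, 1)")
  if (flag_rate < 0 || flag_rate >= 1) stopf("'flag_rate' must be in [0, 1)")
  structure(list(mu_b = mu_b, sigma_b = sigma_b, alpha_s = alpha_s,
                 signal_floor_frac = signal_floor_frac,
                 tip_bias_amplitude = tip_bias_amplitude,
                 dye_intercept = dye_intercept, dye_slope = dye_slope,
                 flag_rate = flag_rate, blocks = as.integer(blocks),
                 n_controls = as.integer(n_controls)),
            class = "noise_model")
}

#' Simulate a two-channel hybridization scan
#'
#' One spot per locus plus the configured blank control spots, assigned
#' row-major to the print-tip grid with the controls spread over the
#' slide. The reference channel always carries signal on gene probes (the
#' reference strain carries every probe); the test channel carries signal
#' only for loci present in `content`; controls (`probe_id` starting with
#' `CTRL`) read background in both channels. Intensities are rounded to
#' integers as a median-intensity scanner would report them.
#'
#' @param model A `genome_model`.
#' @param content A `strain_content` for the test strain.
#' @param noise A [noise_model()].
#' @param seed Integer seed; fixes the scan exactly.
#' @return An [array_scan] object.
#' @export
simulate_scan <- function(model, content, noise = noise_model(), seed = 1L) {
  stopifnot(inherits(model, "genome_model"),
            inherits(content, "strain_content"),
            inherits(noise, "noise_model"))
  bad <- setdiff(content$present, model$loci$locus_tag)
  if (length(bad))
    stopf("content has loci outside the model (e.g. '%s')", bad[1])
  n_gene <- nrow(model$loci)
  n <- n_gene + noise$n_controls
  nb <- prod(noise$blocks)
  per_block <- ceiling(n / nb)
  ncol_b <- ceiling(sqrt(per_block))
  i0 <- seq_len(n) - 1L
  block <- i0 %/% per_block + 1L
  within <- i0 %% per_block
  row <- within %/% ncol_b + 1L
  col <- within %% ncol_b + 1L
  # controls interleaved evenly over the slide
  if (noise$n_controls >= n_gene)
    stopf("more control spots than gene probes")
  is_ctrl <- rep(FALSE, n)
  if (noise$n_controls > 0L)
    is_ctrl[floor(seq(0, n - 1, length.out = noise$n_controls)) + 1L] <- TRUE
  probe_id <- character(n)
  probe_id[!is_ctrl] <- model$loci$probe_id
  probe_id[is_ctrl] <- sprintf("CTRL%04d", seq_len(sum(is_ctrl)))
  present <- logical(n)
  present[!is_ctrl] <- model$loci$locus_tag %in% content$present
  probed <- !is_ctrl

  with_seed(seed, {
    rbg <- function() pmax(1, stats::rnorm(n, noise$mu_b, noise$sigma_b))
    floor_s <- noise$signal_floor_frac * noise$alpha_s
    sig <- function() floor_s + stats::rexp(n, 1 / (noise$alpha_s - floor_s))
    fg_test <- rbg() + sig() * present
    fg_ref  <- rbg() + sig() * probed
    bg_test <- rbg()
    bg_ref  <- rbg()
    # print-tip and dye biases act on the test channel, so they show up in M
    u <- if (nb > 1L) seq(-1, 1, length.out = nb) else 0
    fg_test <- fg_test * 2^(noise$tip_bias_amplitude * u[block])
    a0 <- 0.5 * (log2(fg_test) + log2(fg_ref))
    fg_test <- fg_test *
      2^(noise$dye_intercept + noise$dye_slope * (a0 - mean(a0)))
    flag <- rep(0L, n)
    n_bad <- round(noise$flag_rate * n)
    if (n_bad > 0L) flag[sample.int(n, n_bad)] <- -100L

    array_scan(content$strain_id, data.frame(
      probe_id = probe_id,
      block = block, row = row, column = col,
      fg_test = round(fg_test), bg_test = round(bg_test),
      fg_ref = round(fg_ref), bg_ref = round(bg_ref),
      flag = flag, stringsAsFactors = FALSE))
  })
}

#' Per-strain presence truth table
#'
#' @param model A `genome_model`.
#' @param contents List of `strain_content`.
#' @return Data frame (strain, locus, present) covering every locus of the
#'   model for every strain.
#' @export
content_truth <- function(model, contents) {
  do.call(rbind, lapply(contents, function(ct) {
    data.frame(strain = ct$strain_id, locus = model$loci$locus_tag,
               present = as.integer(model$loci$locus_tag %in% ct$present),
               stringsAsFactors = FALSE)
  }))
}

#' Gene table view of a genome model
#'
#' Exposes the model's loci as a [gene_table], with every planted region as
#' a named gene set (so occupancy can be computed against generator truth).
#'
#' @param model A `genome_model`.
#' @return A `gene_table`.
#' @export
as_gene_table <- function(model) {
  stopifnot(inherits(model, "genome_model"))
  sets <- lapply(seq_len(nrow(model$regions)), function(k)
    model$loci$locus_tag[seq(model$regions$first[k], model$regions$last[k])])
  names(sets) <- model$regions$name
  gene_table(model$loci, sets)
}
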