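test_that("genome model lays out sorted, non-overlapping loci and plants regions", {
  # degenerate: one replicon, no regions
  cfg <- genome_config(replicons = data.frame(name = "CHR1",
                                              length_bp = 120000L,
                                              n_loci = 100L),
                       islands = c())
  m <- build_genome_model(cfg, seed = 3)
  expect_equal(nrow(m$loci), 100L)
  expect_equal(nrow(m$regions), 0L)
  expect_false(is.unsorted(m$loci$start))
  expect_true(all(utils::head(m$loci$end, -1) < utils::tail(m$loci$start, -1)))

  # default configuration: 13 + 5 islands plus two plasmid backbones
  md <- build_genome_model(genome_config(), seed = 3)
  expect_equal(sum(md$regions$class == "island"), 18L)
  expect_equal(sum(md$regions$class == "plasmid-backbone"), 2L)
  expect_equal(nrow(md$loci), 6205L)
  for (k in seq_len(nrow(md$regions))) {
    idx <- seq(md$regions$first[k], md$regions$last[k])
    # contiguity and containment: one replicon, consecutive locus rows
    expect_equal(unique(md$loci$replicon[idx]), md$regions$replicon[k])
    expect_equal(idx, md$regions$first[k]:md$regions$last[k])
  }
  # islands are pairwise disjoint
  isl <- md$regions[md$regions$class == "island", ]
  isl <- isl[order(isl$first), ]
  expect_true(all(utils::head(isl$last, -1) < utils::tail(isl$first, -1) |
                  utils::head(isl$replicon, -1) != utils::tail(isl$replicon, -1)))
})

test_that("genome model generation is deterministic and validates capacity", {
  expect_identical(build_genome_model(genome_config(), 11),
                   build_genome_model(genome_config(), 11))
  cfg <- genome_config(replicons = data.frame(name = "CHR1",
                                              length_bp = 60000L,
                                              n_loci = 50L),
                       islands = c(CHR1 = 2L), island_genes = c(20L, 40L))
  expect_error(build_genome_model(cfg, 1), "cannot hold")
})

test_that("strain content inherits islands as blocks at group probabilities", {
  m <- tiny_genome(n_islands = 3, seed = 2)

  # extremes: group I everything, group II nothing
  cts <- assign_strain_content(m, 2, 2, island_presence = c(I = 1, II = 0),
                               plasmid_presence = c(I = 1, II = 0),
                               dropout = 0, seed = 5)
  isl_tags <- unlist(lapply(which(m$regions$class == "island"), function(k)
    m$loci$locus_tag[seq(m$regions$first[k], m$regions$last[k])]))
  expect_true(all(isl_tags %in% cts[[1]]$present))
  expect_true(all(isl_tags %in% cts[[2]]$present))
  expect_false(any(isl_tags %in% cts[[3]]$present))
  # backbone loci present in every strain
  backbone <- setdiff(m$loci$locus_tag,
                      unlist(lapply(seq_len(nrow(m$regions)), function(k)
                        m$loci$locus_tag[seq(m$regions$first[k],
                                             m$regions$last[k])])))
  for (ct in cts) expect_true(all(backbone %in% ct$present))

  # single strain at probability 1 carries all loci
  ct1 <- assign_strain_content(m, 1, 0, island_presence = c(I = 1, II = 1),
                               plasmid_presence = c(I = 1, II = 1),
                               dropout = 0, seed = 1)[[1]]
  expect_setequal(ct1$present, m$loci$locus_tag)

  expect_error(assign_strain_content(m, 0, 0), "at least one strain")
})

test_that("empirical island carriage tracks the group probabilities", {
  md <- build_genome_model(genome_config(), seed = 4)
  cts <- assign_strain_content(md, 7, 9, island_presence = c(I = 0.9, II = 0.2),
                               dropout = 0, seed = 6)
  reg <- md$regions[md$regions$class == "island", ]
  carried <- vapply(cts, function(ct) {
    mean(vapply(seq_len(nrow(reg)), function(k) {
      tags <- md$loci$locus_tag[seq(reg$first[k], reg$last[k])]
      all(tags %in% ct$present)
    }, logical(1)))
  }, numeric(1))
  grp <- vapply(cts, `[[`, "", "group")
  expect_lt(abs(mean(carried[grp == "I"]) - 0.9), 0.15)
  expect_lt(abs(mean(carried[grp == "II"]) - 0.2), 0.15)
})

test_that("validation derivatives lose exactly one region and are idempotent", {
  m <- tiny_genome(seed = 9)
  ref <- assign_strain_content(m, 1, 0, island_presence = c(I = 1, II = 1),
                               plasmid_presence = c(I = 1, II = 1),
                               dropout = 0, seed = 1)[[1]]
  n_plasmid <- sum(m$loci$replicon == "pSML")
  d <- make_validation_derivative(ref, "pSML", m)
  expect_equal(d$group, "derivative")
  expect_length(setdiff(ref$present, d$present), n_plasmid)
  expect_true(all(startsWith(setdiff(ref$present, d$present), "pSML")))
  d2 <- make_validation_derivative(d, "pSML", m)
  expect_identical(d2$present, d$present)
  expect_identical(d2$strain_id, d$strain_id)
  expect_error(make_validation_derivative(ref, "nope", m), "unknown region")
})

test_that("simulated scans honour the noise model in the noise-free limit", {
  m <- tiny_genome(seed = 1)
  cts <- assign_strain_content(m, 1, 1, island_presence = c(I = 1, II = 0),
                               plasmid_presence = c(I = 1, II = 0),
                               dropout = 0, seed = 2)
  nz <- tiny_noise(mu_b = 100, sigma_b = 1e-9, alpha_s = 4000,
                   tip_bias_amplitude = 0, dye_slope = 0, flag_rate = 0)
  sc <- simulate_scan(m, cts[[2]], nz, seed = 3)   # group II: islands absent
  sp <- sc$spots
  present <- m$loci$locus_tag[m$loci$locus_tag %in% cts[[2]]$present]
  at <- match(m$loci$probe_id[match(present, m$loci$locus_tag)], sp$probe_id)
  absent_at <- match(m$loci$probe_id[!(m$loci$locus_tag %in% present)],
                     sp$probe_id)
  expect_lt(max(abs(sp$fg_test[absent_at] - 100)), 1)
  expect_lt(abs(mean(sp$fg_test[at]) - (100 + 4000)), 250)
})

test_that("present spots clear a 20-fold ratio over background at default noise", {
  m <- tiny_genome(n_loci = 1000, seed = 5)
  ct <- assign_strain_content(m, 1, 0, seed = 2)[[1]]
  sc <- simulate_scan(m, ct, tiny_noise(), seed = 7)
  sp <- sc$spots
  gene_at <- match(m$loci$probe_id, sp$probe_id)
  present <- m$loci$locus_tag %in% ct$present
  ratio <- sp$fg_test[gene_at] / sp$bg_test[gene_at]
  expect_gt(mean(ratio[present] >= 20), 0.99)
  expect_true(all(ratio[!present] < 20))
})

test_that("scan generation is deterministic and validates content", {
  m <- tiny_genome(seed = 1)
  ct <- assign_strain_content(m, 1, 0, seed = 2)[[1]]
  s1 <- simulate_scan(m, ct, tiny_noise(), seed = 42)
  s2 <- simulate_scan(m, ct, tiny_noise(), seed = 42)
  expect_identical(s1, s2)
  expect_equal(nrow(s1$spots), nrow(m$loci) + 60L)
  expect_equal(sum(s1$spots$flag < 0), round(0.02 * nrow(s1$spots)))
  bad <- ct
  bad$present <- c(bad$present, "NOT_A_LOCUS")
  expect_error(simulate_scan(m, bad, tiny_noise(), 1), "outside the model")
})

test_that("group profiles separate more between groups than within (truth)", {
  md <- build_genome_model(genome_config(), seed = 8)
  cts <- assign_strain_content(md, 5, 5, island_presence = c(I = 0.9, II = 0.2),
                               seed = 9)
  jaccard <- function(a, b)
    1 - length(intersect(a, b)) / length(union(a, b))
  grp <- vapply(cts, `[[`, "", "group")
  sets <- lapply(cts, `[[`, "present")
  meanI <- Reduce(intersect, sets[grp == "I"])
  d_within <- mean(utils::combn(which(grp == "I"), 2, function(ij)
    jaccard(sets[[ij[1]]], sets[[ij[2]]])))
  d_between <- mean(outer(which(grp == "I"), which(grp == "II"),
                          Vectorize(function(i, j)
                            jaccard(sets[[i]], sets[[j]]))))
  expect_gt(d_between, d_within)
})
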