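test_that("gene variability classes follow the absent/present thresholds", {
  m <- matrix(TRUE, 3, 16, dimnames = list(c("all", "split", "rare"),
                                           sprintf("s%02d", 1:16)))
  m["split", 1:9] <- FALSE   # absent 9, present 7
  m["rare", 1:3] <- FALSE    # absent 3 (below min_absent)
  cls <- gene_variability(presence_matrix(m))
  expect_equal(as.character(cls[c("all", "split", "rare")]),
               c("conserved", "variable", "uninformative"))

  # brute force on a random panel
  pm <- random_presence(50, 16, na_rate = 0.05, seed = 77)
  cls2 <- gene_variability(pm, min_absent = 4, min_present = 1)
  for (g in rownames(pm$calls)) {
    v <- pm$calls[g, ]
    na <- sum(!v, na.rm = TRUE); np <- sum(v, na.rm = TRUE)
    want <- if (na + np == 0) "uninformative" else if (na == 0) "conserved"
      else if (na >= 4 && np >= 1) "variable" else "uninformative"
    expect_equal(as.character(cls2[[g]]), want)
  }
  # all no-data is uninformative, not conserved
  m_na <- matrix(NA, 1, 16, dimnames = list("g", sprintf("s%02d", 1:16)))
  expect_equal(as.character(gene_variability(presence_matrix(m_na))),
               "uninformative")
})

make_pattern_matrix <- function(variable, n_strains = 8) {
  # variable genes: absent in half the strains; conserved: present in all
  n <- length(variable)
  m <- matrix(TRUE, n, n_strains,
              dimnames = list(sprintf("L%03d", seq_len(n)),
                              sprintf("s%d", seq_len(n_strains))))
  m[variable, seq_len(floor(n_strains / 2))] <- FALSE
  presence_matrix(m)
}

test_that("island scan finds planted runs and respects gaps", {
  gt <- index_gene_table(40)
  # all conserved: nothing to find
  expect_length(scan_islands(make_pattern_matrix(rep(FALSE, 40)), gt,
                             min_absent = 4, min_present = 1), 0)

  # one run of 10 variable loci flanked by conserved loci
  v <- rep(FALSE, 40); v[11:20] <- TRUE
  calls <- scan_islands(make_pattern_matrix(v), gt, min_absent = 4)
  expect_length(calls, 1)
  expect_equal(c(calls[[1]]$first, calls[[1]]$last), c(11, 20))
  expect_equal(calls[[1]]$n_genes, 10L)
  expect_equal(calls[[1]]$start, gt$genes$start[11])
  expect_equal(calls[[1]]$end, gt$genes$end[20])

  # two runs separated by max_gap + 1 conserved loci stay two calls
  v2 <- rep(FALSE, 40); v2[5:12] <- TRUE; v2[16:23] <- TRUE   # gap of 3
  calls2 <- scan_islands(make_pattern_matrix(v2), gt, max_gap = 2,
                         min_absent = 4)
  expect_length(calls2, 2)
  expect_equal(vapply(calls2, `[[`, 0, "first"), c(5, 16))

  # the same runs separated by max_gap conserved loci fuse into one call
  v3 <- rep(FALSE, 40); v3[5:12] <- TRUE; v3[15:22] <- TRUE   # gap of 2
  calls3 <- scan_islands(make_pattern_matrix(v3), gt, max_gap = 2,
                         min_absent = 4)
  expect_length(calls3, 1)
  expect_equal(c(calls3[[1]]$first, calls3[[1]]$last), c(5, 22))
})

test_that("island scan equals exhaustive window enumeration", {
  for (s in 1:40) {
    set.seed(s)
    n <- sample(10:50, 1)
    # blocky variability patterns plus noise exercise gap/fraction logic
    v <- rep(FALSE, n)
    for (k in seq_len(sample(1:3, 1))) {
      a <- sample(n, 1); b <- min(n, a + sample(3:12, 1))
      v[a:b] <- TRUE
    }
    flip <- runif(n) < 0.1
    v[flip] <- !v[flip]
    min_genes <- sample(3:6, 1); max_gap <- sample(1:3, 1)
    min_frac <- sample(c(0.6, 0.8, 0.9), 1)

    pm <- make_pattern_matrix(v)
    gt <- index_gene_table(n)
    got <- scan_islands(pm, gt, min_genes = min_genes, max_gap = max_gap,
                        min_variable_frac = min_frac, min_absent = 4)
    got_win <- if (length(got))
      t(vapply(got, function(x) c(x$first, x$last), numeric(2)))
      else matrix(integer(0), 0, 2)
    want <- brute_force_windows(v, min_genes, max_gap, min_frac)
    expect_equal(unname(got_win), unname(want), info = paste("seed", s))
  }
})

test_that("island calls never cross replicons and stay disjoint", {
  gt2 <- gene_table(rbind(
    within(index_gene_table(30)$genes, replicon <- "CHR1"),
    within(index_gene_table(30)$genes, {
      replicon <- "CHR2"
      locus_tag <- sub("L", "M", locus_tag)
      probe_id <- sub("P", "Q", probe_id)
    })))
  v <- rep(FALSE, 60); v[26:35] <- TRUE   # straddles the replicon boundary
  m <- matrix(TRUE, 60, 8, dimnames = list(gt2$genes$locus_tag,
                                           sprintf("s%d", 1:8)))
  m[v, 1:4] <- FALSE
  calls <- scan_islands(presence_matrix(m), gt2, min_absent = 4)
  expect_true(all(vapply(calls, `[[`, "", "replicon") %in% c("CHR1", "CHR2")))
  for (rep_name in c("CHR1", "CHR2")) {
    on_rep <- Filter(function(x) x$replicon == rep_name, calls)
    expect_length(on_rep, 1)  # 5 loci on each side of the boundary
    expect_equal(on_rep[[1]]$n_genes, 5L)
  }
})

test_that("island sizes reproduce the published coordinate arithmetic", {
  expect_equal(island_size_kb(2895950, 2905048), 9.1)
  expect_equal(island_size_kb(813173, 900292), 87.1)
  expect_equal(island_size_kb(1075185, 1094655), 19.5)
  expect_equal(island_size_kb(1217667, 1358908), 141.2)
  expect_equal(island_size_kb(2202142, 2322293), 120.2)
  expect_equal(island_size_kb(1, 1000), 1.0)
  expect_error(island_size_kb(10, 5), "start")
})

test_that("merging split islands sums sizes and is commutative", {
  b <- island_call("CMGI-B", "CHR2", 1, 21, 1075185, 1094655, 21,
                   score = 0.9, profile = c(s1 = 1, s2 = 0))
  d <- island_call("CMGI-D", "CHR2", 30, 170, 1217667, 1358908, 141,
                   score = 0.8, profile = c(s1 = 1, s2 = 0.5))
  merged <- merge_split_island(b, d)
  expect_equal(merged$size_kb, 160.7)
  expect_equal(merged$n_genes, 162L)
  expect_equal(merged$name, "CMGI-B+CMGI-D")
  expect_equal(merged$profile[["s2"]], (0 * 21 + 0.5 * 141) / 162)
  expect_equal(merge_split_island(d, b)[c("size_kb", "n_genes", "start", "end")],
               merged[c("size_kb", "n_genes", "start", "end")])

  empty <- island_call("none", "CHR2", 0, 0, 1, 0, 0, size_kb = 0)
  expect_identical(merge_split_island(b, empty), b)
  expect_identical(merge_split_island(empty, d), d)

  overlap <- island_call("X", "CHR2", 1, 50, 1080000, 1200000, 50)
  expect_error(merge_split_island(b, overlap), "overlapping")
  other <- island_call("Y", "CHR1", 1, 5, 10, 5000, 5)
  expect_error(merge_split_island(b, other), "replicon")
})

test_that("group concordance tracks the planted two-group signal", {
  v <- rep(FALSE, 30); v[10:19] <- TRUE
  pm <- make_pattern_matrix(v)     # variable genes absent in s1..s4
  gt <- index_gene_table(30)
  calls <- scan_islands(pm, gt, min_absent = 4,
                        groups = list(I = c("s5", "s6", "s7", "s8"),
                                      II = c("s1", "s2", "s3", "s4")))
  expect_length(calls, 1)
  expect_equal(calls[[1]]$concordance, 1.0)
  expect_equal(unname(calls[[1]]$profile[c("s1", "s5")]), c(0, 1))
})
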