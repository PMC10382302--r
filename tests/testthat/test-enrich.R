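test_that("hypergeometric enrichment reproduces reference tables and enumeration", {
  # domain-domain interaction tables for two cell lines; the reference
  # values are printed truncated, so compare with sub-percent tolerance
  expect_equal(signif(hypergeom_enrichment(131, 61, 598, 718), 3), 2.17e-9)
  expect_equal(hypergeom_enrichment(79, 24, 369, 517), 7.65e-12,
               tolerance = 2e-3)
  # physical-interaction enrichment among attracting vs avoiding pairs
  expect_equal(hypergeom_enrichment(92, 40, 447, 483), 1.98e-6,
               tolerance = 4e-3)
  # tiny table checked by direct enumeration: C(2,2) C(2,0) / C(4,2) = 1/6
  expect_equal(hypergeom_enrichment(2, 0, 0, 2), 1 / 6)
  # matrix input, zero margin
  expect_equal(hypergeom_enrichment(matrix(c(3, 1, 2, 4), 2, 2)),
               hypergeom_enrichment(3, 2, 1, 4))
  expect_warning(p <- hypergeom_enrichment(0, 0, 3, 4), "zero margin")
  expect_equal(p, 1)
})

test_that("upper and lower hypergeometric tails overlap at the observed value", {
  for (seed in 1:5) {
    set.seed(seed)
    cells <- rpois(4, 20) + 1
    a <- cells[1]; b <- cells[2]; cc <- cells[3]; d <- cells[4]
    up <- hypergeom_enrichment(a, b, cc, d)
    lo <- hypergeom_enrichment(b, a, d, cc)  # column swap = lower tail
    expect_gte(up + lo, 1)
  }
})

test_that("call-by-interaction tables are filled by pair membership", {
  # 539 attracting / 523 avoiding pairs, 92 and 40 of them interacting
  facs <- sprintf("F%04d", 1:1100)
  n_att <- 539; n_av <- 523
  stats <- data.frame(factor_i = facs[1:(n_att + n_av)],
                      factor_j = facs[2:(n_att + n_av + 1)],
                      call = c(rep("attract", n_att), rep("repel", n_av)))
  interacting <- stats[c(1:92, n_att + (1:40)), c("factor_i", "factor_j")]
  out <- pair_interaction_table(stats, interacting)
  expect_equal(as.vector(out$table), c(92, 447, 40, 483))
  expect_equal(out$p, 1.98e-6, tolerance = 4e-3)
  # empty interaction list
  out0 <- suppressWarnings(
    pair_interaction_table(stats, interacting[0, ]))
  expect_equal(as.vector(out0$table), c(0, 539, 0, 523))
  expect_equal(out0$p, 1)
  # random small instance against brute-force membership counting
  set.seed(44)
  st <- data.frame(factor_i = sample(LETTERS[1:8], 20, TRUE),
                   factor_j = sample(LETTERS[9:16], 20, TRUE),
                   call = sample(c("attract", "repel", "neutral"), 20, TRUE))
  il <- data.frame(factor_i = sample(LETTERS[1:8], 10, TRUE),
                   factor_j = sample(LETTERS[9:16], 10, TRUE))
  out <- suppressWarnings(pair_interaction_table(st, il))
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  member <- key(st$factor_i, st$factor_j) %in% key(il$factor_i, il$factor_j)
  expect_equal(out$table["interacting", "attracting"],
               sum(st$call == "attract" & member))
  expect_equal(out$table["not_interacting", "avoiding"],
               sum(st$call == "repel" & !member))
})

test_that("domain composition induces potentially interacting pairs", {
  fd <- data.frame(factor = c("A", "A", "B", "C"),
                   domain = c("d1", "d2", "d3", "d4"))
  dp <- data.frame(domain_i = "d2", domain_j = "d3")
  out <- potential_interactions(fd, dp)
  expect_equal(nrow(out), 1L)
  expect_setequal(c(out$factor_i, out$factor_j), c("A", "B"))
})

test_that("target genes follow the >=5 / <=3 group rule", {
  # gene TSS next to region 1; region 1 has an edge to region 6
  net <- toy_net()
  tss <- data.frame(chrom = "chrT", start = net$regions$end[1] + 500L,
                    gene = "G1")
  groups <- stats::setNames(c(rep(1, 6), rep(2, 4)), paste0("F", 1:10))
  # 5 group-1 factors bind region 1, 2 group-2 factors bind region 6
  # (spatially linked to region 1)
  bound <- c(lapply(1:5, function(i) 1L), list(integer(0)),
             lapply(1:2, function(i) 6L), list(integer(0)), list(integer(0)))
  names(bound) <- paste0("F", 1:10)
  bm <- toy_binding(bound, 10L)
  out <- assign_target_genes(bm, net, tss, groups)
  expect_equal(out$count_group1, 5L)
  expect_equal(out$count_group2, 2L)
  expect_equal(out$assigned_group, 1L)
  # 5 vs 4 -> unassigned
  bound2 <- bound
  bound2$F9 <- 6L; bound2$F10 <- 6L
  out2 <- assign_target_genes(toy_binding(bound2, 10L), net, tss, groups)
  expect_equal(out2$count_group2, 4L)
  expect_true(is.na(out2$assigned_group))
  # stricter alternate rule: 3 from one group, 0 from the other
  out3 <- assign_target_genes(toy_binding(bound2, 10L), net, tss, groups,
                              min_in = 3L, max_out = 0L)
  expect_true(is.na(out3$assigned_group))
  bound3 <- bound; bound3$F7 <- integer(0); bound3$F8 <- integer(0)
  out4 <- assign_target_genes(toy_binding(bound3, 10L), net, tss, groups,
                              min_in = 3L, max_out = 0L)
  expect_equal(out4$assigned_group, 1L)
  # monotonicity: adding a binding site never removes a target relation
  out5 <- assign_target_genes(toy_binding(c(bound[-6],
                                            list(F6 = 1L))[names(bound)],
                                          10L), net, tss, groups)
  expect_equal(out5$assigned_group, 1L)
  expect_gte(out5$count_group1, out$count_group1)
})

test_that("gene-set enrichment handles disjoint and extreme tables", {
  expect_warning(
    out <- gene_set_enrichment(c("g1", "g2"), c("g3"), c("x1", "x2")),
    "zero margin")
  expect_equal(out$p, 1)
  out <- gene_set_enrichment(paste0("a", 1:10), paste0("b", 1:10),
                             paste0("a", 1:10))
  expect_equal(out$p, 1 / choose(20, 10))
  expect_error(gene_set_enrichment(character(), "g", "g"), "empty")
  # small random instance against the enumeration identity
  set.seed(3)
  t1 <- paste0("g", 1:6); t2 <- paste0("h", 1:5)
  ref <- c(sample(t1, 3), sample(t2, 2))
  out <- gene_set_enrichment(t1, t2, ref)
  expect_equal(out$p, stats::phyper(2, 5, 6, 6, lower.tail = FALSE))
})

test_that("target gene lists are emitted per group with a background", {
  targets <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                        count_group1 = c(6L, 0L, 2L, 5L),
                        count_group2 = c(1L, 6L, 2L, 5L),
                        assigned_group = c(1L, 2L, NA, NA))
  dir <- withr::local_tempdir()
  paths <- write_target_gene_lists(targets, dir)
  expect_equal(readLines(paths[["group1"]]), "g1")
  expect_equal(readLines(paths[["group2"]]), "g2")
  expect_equal(readLines(paths[["background"]]), targets$gene)
})

test_that("TSS distances use midpoints and match a brute-force nearest scan", {
  tss <- data.frame(chrom = "c1", start = c(1000L, 9000L))
  peaks <- list(F1 = data.frame(chrom = "c1",
                                start = c(990L, 1990L, 8990L),
                                end = c(1010L, 2010L, 9010L)))
  out <- tss_distance_cdf(peaks, tss)
  expect_equal(out$distance, c(0, 0, 1000))
  # brute force on random data
  set.seed(15)
  tss2 <- data.frame(chrom = "c1", start = sample.int(50000L, 20))
  pk <- data.frame(chrom = "c1", start = sample.int(50000L, 30))
  pk$end <- pk$start + 200L
  out2 <- tss_distance_cdf(list(F = pk), tss2)
  mids <- pk$start + 100L
  bf <- sort(vapply(mids, function(m) min(abs(m - tss2$start)), 0))
  expect_equal(out2$distance, bf)
  # peaks on a chromosome without TSS are excluded
  pk2 <- rbind(pk, data.frame(chrom = "c9", start = 5L, end = 105L))
  expect_message(out3 <- tss_distance_cdf(list(F = pk2), tss2), "excluded")
  expect_equal(nrow(out3), 30L)
})

test_that("internal nodes on shortest PPI paths are counted per category", {
  ppi <- data.frame(node_i = c("A", "X", "A", "Y", "P", "Q"),
                    node_j = c("X", "B", "Y", "B", "Q", "R"))
  pairs <- data.frame(factor_i = c("A", "A"), factor_j = c("B", "X"),
                      category = c("group1", "group1"))
  out <- shortest_path_internal_tfs(ppi, pairs,
                                    annotated_tfs = c("X", "Y", "A", "B"))
  # two equal-length paths A-X-B and A-Y-B: both internal nodes counted once
  expect_equal(sort(out$tf), c("X", "Y"))
  expect_equal(out$count, c(1L, 1L))
  # a direct edge has no internal nodes; disconnected pairs are skipped
  pairs2 <- data.frame(factor_i = c("A", "A"), factor_j = c("X", "P"),
                       category = "g")
  expect_message(out2 <- shortest_path_internal_tfs(ppi, pairs2, "X"),
                 "skipped")
  expect_equal(nrow(out2), 0L)
  # invariant to PPI edge-list ordering
  out3 <- shortest_path_internal_tfs(ppi[sample(nrow(ppi)), ], pairs,
                                     annotated_tfs = c("X", "Y", "A", "B"))
  expect_equal(out3[order(out3$tf), ], out[order(out$tf), ],
               ignore_attr = TRUE)
  # only annotated TFs are counted
  out4 <- shortest_path_internal_tfs(ppi, pairs, annotated_tfs = "Y")
  expect_equal(out4$tf, "Y")
})
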