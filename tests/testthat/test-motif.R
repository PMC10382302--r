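uniform_pwm <- function(name = "U", L = 4L)
  make_pwm(name, matrix(0.25, L, 4L))

deterministic_pwm <- function(name = "D", consensus = "ACG") {
  codes <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  W <- matrix(0, length(codes), 4L)
  W[cbind(seq_along(codes), codes)] <- 1
  make_pwm(name, W)
}

test_that("information score spans 0 to 2L with the closed-form cases", {
  expect_equal(information_score(uniform_pwm(L = 5L)), 0)
  expect_equal(information_score(deterministic_pwm(consensus = "ACG")), 6)
  # a half-half column contributes exactly 1 bit
  W <- rbind(c(0.5, 0.5, 0, 0))
  expect_equal(information_score(make_pwm("H", W)), 1)
  p <- make_pwm("X", rbind(c(0.4, 0.3, 0.2, 0.1), c(0.25, 0.25, 0.25, 0.25)))
  expect_gte(information_score(p), 0)
  expect_lte(information_score(p), 4)
})

test_that("representative selection maximizes information with name tie-breaks", {
  u <- uniform_pwm(); d <- deterministic_pwm()
  expect_equal(select_representative(list(u))$name, "U")
  expect_equal(select_representative(list(u, d))$name, "D")
  # hand-computed: I(a) = 2, I(b) = 6, I(c) = 0 for these matrices
  a <- make_pwm("a", rbind(c(1, 0, 0, 0), c(0.25, 0.25, 0.25, 0.25),
                           c(0.25, 0.25, 0.25, 0.25)))
  b <- deterministic_pwm("b", "TTT")
  cc <- uniform_pwm("c", 3L)
  expect_equal(select_representative(list(cc, a, b))$name, "b")
  # exact tie broken lexicographically
  t1 <- deterministic_pwm("zeta", "AC")
  t2 <- deterministic_pwm("alpha", "GT")
  expect_equal(select_representative(list(t1, t2))$name, "alpha")
  expect_error(select_representative(list()), "empty")
})

test_that("LLR scoring reproduces closed forms and a naive recomputation", {
  d <- deterministic_pwm(consensus = "ACGT")
  expect_equal(llr_score("ACGT", d), 8, tolerance = 1e-2)
  # PWM equal to background scores 0 everywhere
  u <- uniform_pwm(L = 6L)
  expect_equal(llr_score("ACGTAC", u), 0)
  # naive per-position recomputation on a random PWM
  set.seed(4)
  W <- matrix(rgamma(4 * 4, 1), 4L); W <- W / rowSums(W)
  p <- make_pwm("R", W)
  win <- "GATC"
  codes <- match(strsplit(win, "")[[1]], c("A", "C", "G", "T"))
  W2 <- (W + 1e-4) / rowSums(W + 1e-4)
  naive <- sum(log2(W2[cbind(1:4, codes)] / 0.25))
  expect_equal(llr_score(win, p), naive)
  expect_warning(expect_true(is.na(llr_score("ACNT", p))), "ambiguous")
  expect_error(llr_score("ACG", p), "length")
})

test_that("peak scores are strand-symmetric maxima over windows", {
  d <- deterministic_pwm(consensus = "ACGTT")
  s <- "GGGGACGTTGGGG"
  expect_equal(peak_motif_score(s, d), 10, tolerance = 1e-2)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_equal(peak_motif_score(rc, d), peak_motif_score(s, d))
  # brute-force max over both strands on random input
  set.seed(9)
  W <- matrix(rgamma(12, 1), 3L); W <- W / rowSums(W)
  p <- make_pwm("R", W)
  sq <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
  sqrc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sq)))
  wins <- c(substring(sq, 1:48, 3:50), substring(sqrc, 1:48, 3:50))
  expect_equal(peak_motif_score(sq, p),
               max(vapply(wins, llr_score, 0, pwm = p)))
  expect_warning(expect_true(is.na(peak_motif_score("AC", p))), "shorter")
})

test_that("the score distribution matches exhaustive enumeration", {
  set.seed(2)
  for (L in c(1L, 4L, 6L)) {
    W <- matrix(rgamma(4 * L, 1), L); W <- W / rowSums(W)
    p <- make_pwm("R", W)
    dist <- score_distribution(p, bins = 2000L)
    expect_equal(sum(dist$pmf), 1, tolerance = 1e-9)
    if (L == 1L) expect_lte(sum(dist$pmf > 0), 4L)
    # survival function agrees with enumeration of all 4^L windows scored
    # on the same discretization grid (the DP is a pure convolution)
    grid <- as.matrix(expand.grid(rep(list(1:4), L)))
    ints <- rowSums(matrix(dist$qmatrix[cbind(rep(seq_len(L),
                                                  each = nrow(grid)),
                                              as.vector(grid))],
                           nrow(grid), L))
    probs <- apply(grid, 1L, function(cc) prod(0.25^L))
    for (q in c(0.5, 0.1, 1e-2, 1e-3, 1e-4)) {
      thr <- score_threshold(dist, q)
      if (!is.finite(thr)) next
      k <- round(thr / dist$delta)
      expect_equal(score_pvalue(dist, k, integer = TRUE),
                   sum(probs[ints >= k]), tolerance = 1e-3)
    }
    # and brackets the exact-score enumeration within one grid step per
    # position (the discretization error bound)
    oracle <- bf_survival(p)
    slack <- L * dist$delta / 2 + 1e-9
    thr <- score_threshold(dist, 1e-2)
    expect_lte(oracle$sf(thr + slack) - 1e-9, score_pvalue(dist, thr))
    expect_gte(oracle$sf(thr - slack) + 1e-9, score_pvalue(dist, thr))
    # p(max score) is at least the consensus probability under background
    cons_prob <- 0.25^L
    expect_gte(score_pvalue(dist, max(dist$scores[dist$pmf > 0])) + 1e-12,
               cons_prob)
  }
})

test_that("region scanning finds a planted consensus site exactly", {
  pwm <- consensus_pwm("M", "ACGTTGCA")
  set.seed(6)
  ds <- simulate_motif_dataset(n_isolated = 2L, n_interacting = 2L,
                               peak_length = 120L, pwm = pwm,
                               p_iso = 0, p_int = 0, seed = 6)
  # plant one consensus occurrence at a known offset of region 1
  chars <- strsplit(as.character(ds$genome[[1]]), "")[[1]]
  off <- 37L
  at <- ds$network$regions$start[1] + off
  chars[(at + 1):(at + 8)] <- strsplit("ACGTTGCA", "")[[1]]
  genome <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(genome) <- names(ds$genome)
  hits <- scan_regions(genome, ds$network, pwm)
  h1 <- hits[hits$region == 1L, ]
  expect_true(any(h1$offset == off & h1$strand == "+"))
  # every reported hit clears the p-value threshold
  expect_true(all(hits$pvalue <= 1e-4))
  bm <- motif_binding_map(hits, ds$network)
  expect_true(1L %in% bm$bound$M)
})

test_that("all-ambiguous sequence yields no hits", {
  pwm <- consensus_pwm("M", "ACGT")
  net <- toy_net(n = 2L, edges = cbind(1L, 2L))
  genome <- Biostrings::DNAStringSet(paste(rep("N", 20000), collapse = ""))
  names(genome) <- "chrT"
  expect_equal(nrow(scan_regions(genome, net, pwm)), 0L)
})

test_that("scanning agrees with an exhaustive LLR oracle", {
  pwm <- consensus_pwm("M", "ACGTAC", p = 0.7)
  set.seed(12)
  seqchars <- sample(c("A", "C", "G", "T"), 1000, TRUE)
  # plant exact and near-exact sites
  seqchars[101:106] <- strsplit("ACGTAC", "")[[1]]
  seqchars[501:506] <- strsplit("ACGGAC", "")[[1]]
  genome <- Biostrings::DNAStringSet(paste(seqchars, collapse = ""))
  names(genome) <- "chrQ"
  net <- chromcooc:::new_interaction_network(
    data.frame(chrom = "chrQ", start = 0L, end = 1000L),
    matrix(integer(), ncol = 2))
  hits <- scan_regions(genome, net, pwm, p_threshold = 1e-3)
  expect_true(100L %in% hits$offset)  # 0-based offset of the planted site
  # reported LLRs equal the independent single-window computation
  for (k in seq_len(nrow(hits))) {
    s <- if (hits$strand[k] == "+") {
      paste(seqchars[(hits$offset[k] + 1):(hits$offset[k] + 6)],
            collapse = "")
    } else {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(
        paste(seqchars[(hits$offset[k] + 1):(hits$offset[k] + 6)],
              collapse = ""))))
    }
    expect_equal(hits$llr[k], llr_score(s, pwm))
  }
  # enumeration oracle: every window clearly above threshold is reported
  oracle <- bf_survival(pwm)
  dist <- score_distribution(pwm)
  thr <- score_threshold(dist, 1e-3)
  fwd <- vapply(1:995, function(i)
    llr_score(paste(seqchars[i:(i + 5)], collapse = ""), pwm), 0)
  clear <- which(fwd > thr + 0.05) - 1L
  expect_true(all(clear %in% hits$offset[hits$strand == "+"]))
})

test_that("MEME minimal files round-trip and clusters pick representatives", {
  pwms <- list(consensus_pwm("MA0001.1", "ACGTA"),
               uniform_pwm("MA0002.1", 4L),
               deterministic_pwm("MA0003.1", "TTGA"))
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme(pwms, path)
  back <- read_meme(path)
  expect_equal(names(back), c("MA0001.1", "MA0002.1", "MA0003.1"))
  expect_equal(back[["MA0001.1"]]$matrix, pwms[[1]]$matrix,
               tolerance = 1e-4)
  expect_equal(attr(back, "background"), uniform_background(),
               ignore_attr = TRUE)
  cl <- data.frame(cluster = c("c1", "c1", "c2"),
                   motif = c("MA0001.1", "MA0002.1", "MA0003.1"))
  reps <- cluster_representatives(back, cl)
  expect_equal(reps$c1$name, "MA0001.1")
  expect_equal(reps$c2$name, "MA0003.1")
})

test_that("FIMO TSV import maps hits onto network regions", {
  net <- toy_net()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste("motif_id", "motif_alt_id", "sequence_name", "start",
                     "stop", "strand", "score", "p-value", "q-value",
                     "matched_sequence", sep = "\t"),
               paste("M1", "m", "chrT", 101, 108, "+", 12.3, 2e-5, 0.01,
                     "ACGTACGT", sep = "\t")), path)
  fimo <- read_fimo(path)
  expect_equal(fimo$start, 100L)
  bm <- fimo_binding_map(fimo, net)
  expect_equal(bm$bound$M1, 1L)
})

test_that("strong-motif partition applies the top-decile rule per factor", {
  net <- toy_net(n = 10L, edges = cbind(1:2, 3:4))  # regions 5-10 isolated
  ps <- data.frame(factor = "F1", score = 1:10,
                   region = c(1:4, 5:10))
  out <- strong_motif_partition(ps, net)
  # only the score-10 peak reaches the 90th percentile (type-7 quantile 9.1)
  expect_equal(out$frac_strong_isolated, 1 / 6)
  expect_equal(out$frac_strong_interacting, 0)
  # fewer than 10 scored peaks is flagged
  expect_warning(strong_motif_partition(ps[1:5, ], net),
                 "quantile unstable")
  # all peaks isolated -> interacting fraction NA
  ps2 <- data.frame(factor = rep("F1", 12), score = 1:12, region = NA)
  out2 <- strong_motif_partition(ps2, net)
  expect_true(is.na(out2$frac_strong_interacting))
  expect_equal(out2$n_isolated, 12L)
})

test_that("same-factor neighbour refinement splits interacting peaks", {
  net <- toy_net(n = 6L, edges = cbind(c(1L, 3L), c(2L, 4L)))
  ps <- data.frame(factor = "F1", score = c(10, 1, 5, 2),
                   region = c(1L, 2L, 3L, 4L))
  # F1 binds region 2 (neighbour of 1) but not 4 (neighbour of 3)
  bm <- toy_binding(list(F1 = c(1L, 2L)), 6L)
  out <- suppressWarnings(same_tf_refinement(ps, net, bm))
  expect_equal(out$n_same_tf, 2L)   # peaks in regions 1 and 2
  expect_equal(out$n_other, 2L)     # peaks in regions 3 and 4
})
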