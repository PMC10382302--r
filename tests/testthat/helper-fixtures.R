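# Fixtures and independent brute-force oracles used across the test files.
# All fixtures are built in code; randomness is always seeded by the caller.

# A small deterministic interaction network. `edges` indexes regions laid
# consecutively on one synthetic chromosome (gap 5000, length 1000).
toy_net <- function(n = 10L, edges = cbind(1:5, 6:10)) {
  regions <- data.frame(chrom = "chrT",
                        start = seq(0L, by = 6000L, length.out = n),
                        end = seq(0L, by = 6000L, length.out = n) + 1000L)
  chromcooc:::new_interaction_network(regions, edges)
}

toy_binding <- function(bound, n_regions) {
  chromcooc:::new_binding_map(bound, n_regions)
}

random_intervals <- function(n, max_pos = 20000L, chroms = c("c1", "c2")) {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE), start = start,
             end = start + sample.int(500L, n, replace = TRUE))
}

# O(n^2) transitive-closure interval merger via union-find (oracle for
# merge_intervals)
bf_merge <- function(df, gap) {
  n <- nrow(df)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j || df$chrom[i] != df$chrom[j]) next
    sep <- max(df$start[i], df$start[j]) - min(df$end[i], df$end[j])
    if (sep <= gap) parent[find(j)] <- find(i)
  }
  root <- vapply(seq_len(n), find, 1L)
  out <- do.call(rbind, lapply(split(seq_len(n), root), function(ii)
    data.frame(chrom = df$chrom[ii[1L]], start = min(df$start[ii]),
               end = max(df$end[ii]))))
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

# brute-force spatial co-occurrence: per edge, ordered endpoint assignments
# (homotypic pairs once per edge)
bf_spatial <- function(net, binding) {
  facs <- binding$factors
  C <- matrix(0L, length(facs), length(facs), dimnames = list(facs, facs))
  bound <- lapply(binding$bound, function(ids)
    seq_len(net_n(net)) %in% ids)
  for (k in seq_len(nrow(net$edges))) {
    u <- net$edges[k, 1L]; v <- net$edges[k, 2L]
    for (i in seq_along(facs)) for (j in seq_along(facs)) {
      if (i == j) {
        C[i, i] <- C[i, i] + (bound[[i]][u] && bound[[i]][v])
      } else if (bound[[i]][u] && bound[[j]][v]) {
        # one ordered assignment; the (j, i) loop pass adds the other
        C[i, j] <- C[i, j] + 1L
        C[j, i] <- C[j, i] + 1L
      }
    }
  }
  C
}

net_n <- function(net) nrow(net$regions)

# brute-force sequential co-occurrence
bf_sequential <- function(net, binding) {
  facs <- binding$factors
  C <- matrix(0L, length(facs), length(facs), dimnames = list(facs, facs))
  for (i in seq_along(facs)) for (j in seq_along(facs)) {
    C[i, j] <- if (i == j) length(binding$bound[[i]])
               else length(intersect(binding$bound[[i]], binding$bound[[j]]))
  }
  C
}

# random binding map over a network
random_binding <- function(net, factors = c("A", "B", "C"), p = 0.3) {
  n <- net_n(net)
  bound <- lapply(factors, function(f) which(stats::runif(n) < p))
  names(bound) <- factors
  toy_binding(bound, n)
}

# a near-deterministic PWM with the given consensus string
consensus_pwm <- function(name, consensus, p = 0.97) {
  codes <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  W <- matrix((1 - p) / 3, length(codes), 4L)
  W[cbind(seq_along(codes), codes)] <- p
  make_pwm(name, W)
}

# enumeration oracle: exact survival function of window LLR over all 4^L
# windows under the background
bf_survival <- function(pwm, background = uniform_background(),
                        pseudocount = 1e-4) {
  M <- chromcooc:::pwm_llr_matrix(pwm, background, pseudocount)
  L <- nrow(M)
  grid <- as.matrix(expand.grid(rep(list(1:4), L)))
  scores <- rowSums(matrix(M[cbind(rep(seq_len(L), each = nrow(grid)),
                                   as.vector(grid))], nrow(grid), L))
  probs <- apply(grid, 1L, function(cc) prod(background[cc]))
  list(scores = scores, probs = probs,
       sf = function(s) sum(probs[scores >= s - 1e-12]))
}
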