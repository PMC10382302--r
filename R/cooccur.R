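# Pairwise TF co-occurrence counting, empirical significance against the
# randomization ensemble, attract/repel calls, cross-mode comparison, and
# the consensus network.
#
# All per-pair vectors follow the fixed upper-triangle-with-diagonal order
# of pair_index(); homotypic (diagonal) pairs are included by default.

# factors x factors adjacency-weighted counts; `e` is the edge matrix
spatial_counts_matrix <- function(B, e, count = "ordered") {
  nf <- nrow(B)
  if (!nrow(e)) {
    C <- matrix(0, nf, nf, dimnames = list(rownames(B), rownames(B)))
    return(C)
  }
  Bu <- B[, e[, 1L], drop = FALSE]
  Bv <- B[, e[, 2L], drop = FALSE]
  X <- as.matrix(Bu %*% Matrix::t(Bv))   # ordered assignments i@u, j@v
  C <- X + t(X)
  diag(C) <- diag(C) / 2                 # homotypic: once per edge
  if (count == "presence") {
    TT <- Bu * Bv                         # factor binds both endpoints
    M <- as.matrix(TT %*% Matrix::t(TT))
    C <- X + t(X) - M
    diag(C) <- Matrix::rowSums(TT)
  }
  dimnames(C) <- list(rownames(B), rownames(B))
  C
}

#' Spatial co-occurrence counts across interaction edges
#'
#' `count(i, j)` sums, over every interaction edge, the ordered assignments
#' of factors i and j to the two endpoints (0, 1 or 2 per edge); a homotypic
#' pair on both endpoints of an edge counts once. With `count = "presence"`
#' each edge contributes at most 1.
#'
#' @param network An `interaction_network`.
#' @param binding A `binding_map`.
#' @param count `"ordered"` (default) or `"presence"`.
#' @return Symmetric factors-by-factors integer matrix with attribute
#'   `mode = "spatial"`.
#' @export
spatial_cooccurrence <- function(network, binding,
                                 count = c("ordered", "presence")) {
  count <- match.arg(count)
  C <- spatial_counts_matrix(binding_matrix(binding), network$edges, count)
  structure(C, mode = "spatial")
}

#' Sequential co-occurrence counts within regions
#'
#' `count(i, j)` is the number of regions bound by both factors; the
#' diagonal holds the number of regions each factor binds.
#'
#' @inheritParams spatial_cooccurrence
#' @return Symmetric factors-by-factors integer matrix with attribute
#'   `mode = "sequential"`.
#' @export
sequential_cooccurrence <- function(network, binding) {
  B <- binding_matrix(binding)
  C <- as.matrix(B %*% Matrix::t(B))
  dimnames(C) <- list(binding$factors, binding$factors)
  structure(C, mode = "sequential")
}

#' Empirical two-tailed p-values against an ensemble of null counts
#'
#' For each pair, `p_attract` is the fraction of null replicates with count
#' greater than or equal to the observed count, and `p_repel` the fraction
#' with count less than or equal to it (both tails include equality, so
#' `p_attract + p_repel >= 1`). The default raw fraction can be exactly 0;
#' `pseudocount = TRUE` switches to the permutation estimator
#' `(k + 1) / (R + 1)`, which is bounded below by `1/(R+1)`.
#'
#' @param observed Numeric vector of observed per-pair counts.
#' @param nulls Numeric matrix of null counts, one row per replicate, one
#'   column per pair (same order as `observed`).
#' @param pseudocount Use the `(k+1)/(R+1)` estimator (default `FALSE`).
#' @return List with numeric vectors `p_attract` and `p_repel`.
#' @export
empirical_pvalues <- function(observed, nulls, pseudocount = FALSE) {
  nulls <- as.matrix(nulls)
  R <- nrow(nulls)
  if (R == 0L) stop("ensemble has zero replicates")
  stopifnot(length(observed) == ncol(nulls))
  ge <- colSums(nulls >= matrix(observed, R, length(observed), byrow = TRUE))
  le <- colSums(nulls <= matrix(observed, R, length(observed), byrow = TRUE))
  pc <- if (pseudocount) 1 else 0
  list(p_attract = (ge + pc) / (R + pc), p_repel = (le + pc) / (R + pc))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH over the full p-value list, returned in input order. Applied
#' separately to the attract-tail and repel-tail lists by the callers.
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return Numeric vector of q-values.
#' @export
bh_qvalues <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

call_from_q <- function(q_attract, q_repel, alpha = 0.05) {
  both <- q_attract <= alpha & q_repel <= alpha
  if (any(both))
    warning(sum(both), " pair(s) significant in both tails; set to neutral")
  ifelse(both, "neutral",
         ifelse(q_attract <= alpha, "attract",
                ifelse(q_repel <= alpha, "repel", "neutral")))
}

#' Classify pairs as attracting, repelling or neutral
#'
#' A pair attracts when `q_attract <= alpha`, repels when
#' `q_repel <= alpha`; the (degenerate) case of both tails significant is
#' set to neutral with a warning.
#'
#' @param stats A pair-stats data frame with columns `q_attract`, `q_repel`.
#' @param alpha FDR threshold (default 0.05).
#' @return `stats` with its `call` column (re)computed.
#' @export
classify_pairs <- function(stats, alpha = 0.05) {
  stopifnot(all(c("q_attract", "q_repel") %in% names(stats)))
  stats$call <- call_from_q(stats$q_attract, stats$q_repel, alpha)
  stats
}

# Assemble the per-pair stats table from observed counts + null count
# matrix; `px` is a (possibly filtered) pair_index() data frame
make_pair_stats <- function(px, observed_vec, nulls, alpha, pseudocount) {
  pv <- empirical_pvalues(observed_vec, nulls, pseudocount)
  stats <- data.frame(
    factor_i = px$factor_i, factor_j = px$factor_j,
    observed = observed_vec,
    mean_null = colMeans(nulls),
    p_attract = pv$p_attract, p_repel = pv$p_repel,
    stringsAsFactors = FALSE
  )
  stats$q_attract <- bh_qvalues(stats$p_attract)
  stats$q_repel <- bh_qvalues(stats$p_repel)
  stats$call <- call_from_q(stats$q_attract, stats$q_repel, alpha)
  rownames(stats) <- NULL
  stats
}

#' Randomization test for TF-pair co-occurrence
#'
#' Counts observed co-occurrences, generates `replicates` degree-class-
#' preserving randomizations of the binding network, and reports empirical
#' two-tailed p-values, BH q-values (each tail corrected over the full pair
#' list) and attract/repel/neutral calls. With `mode = "both"` the same
#' ensemble of randomized binding maps is scored in both the spatial and the
#' sequential sense.
#'
#' @param network An `interaction_network`.
#' @param binding A `binding_map`.
#' @param mode `"spatial"`, `"sequential"`, or `"both"`.
#' @param replicates Ensemble size R (default 1000).
#' @param rule A [degree_class_rule()].
#' @param seed Master seed for the ensemble.
#' @param alpha FDR threshold for calls (default 0.05).
#' @param count Spatial counting unit, see [spatial_cooccurrence()].
#' @param pseudocount Use the `(k+1)/(R+1)` permutation p-value estimator
#'   (default `TRUE`; see [empirical_pvalues()]).
#' @param include_homotypic Keep homotypic (diagonal) pairs in the table and
#'   in the BH correction (default `TRUE`).
#' @return A `pair_stats` data frame (columns `factor_i, factor_j, observed,
#'   mean_null, p_attract, p_repel, q_attract, q_repel, call`) with
#'   attributes `mode`, `alpha`, `replicates`, `seed`; for `mode = "both"`,
#'   a named list of two such tables.
#' @export
cooccurrence_test <- function(network, binding,
                              mode = c("spatial", "sequential", "both"),
                              replicates = 1000L,
                              rule = degree_class_rule(), seed = NULL,
                              alpha = 0.05,
                              count = c("ordered", "presence"),
                              pseudocount = TRUE,
                              include_homotypic = TRUE) {
  mode <- match.arg(mode)
  count <- match.arg(count)
  modes <- if (mode == "both") c("spatial", "sequential") else mode
  ens <- generate_ensemble(network, binding, replicates, rule, seed)

  count_one <- function(bm) {
    B <- binding_matrix(bm)
    out <- list()
    if ("spatial" %in% modes)
      out$spatial <- pair_vector(spatial_counts_matrix(B, network$edges,
                                                       count))
    if ("sequential" %in% modes)
      out$sequential <- pair_vector(as.matrix(B %*% Matrix::t(B)))
    out
  }

  obs <- count_one(binding)
  P <- length(obs[[1L]])
  nulls <- lapply(modes, function(m) matrix(0, replicates, P))
  names(nulls) <- modes
  for (r in seq_len(replicates)) {
    cnt <- count_one(ensemble_replicate(ens, r, network, binding))
    for (m in modes) nulls[[m]][r, ] <- cnt[[m]]
  }

  px <- pair_index(binding$factors)
  keep <- if (include_homotypic) rep(TRUE, P) else px$i != px$j
  res <- lapply(modes, function(m) {
    stats <- make_pair_stats(px[keep, , drop = FALSE], obs[[m]][keep],
                             nulls[[m]][, keep, drop = FALSE],
                             alpha, pseudocount)
    structure(stats, mode = m, alpha = alpha, replicates = replicates,
              seed = ens$seed, class = c("pair_stats", "data.frame"))
  })
  names(res) <- modes
  if (mode == "both") res else res[[1L]]
}

#' Random-as-real negative control
#'
#' Treats one randomized replicate as the observed network and compares it
#' against the remaining replicates; on a well-calibrated null this yields
#' approximately uniform p-values and no significant pairs.
#'
#' @inheritParams cooccurrence_test
#' @param replicates Number of null replicates the pseudo-observed replicate
#'   is compared against (default 500).
#' @return A `pair_stats` data frame (see [cooccurrence_test()]).
#' @export
negative_control <- function(network, binding,
                             mode = c("spatial", "sequential"),
                             replicates = 500L,
                             rule = degree_class_rule(), seed = NULL,
                             alpha = 0.05, count = c("ordered", "presence"),
                             pseudocount = TRUE) {
  mode <- match.arg(mode)
  count <- match.arg(count)
  ens <- generate_ensemble(network, binding, replicates + 1L, rule, seed)
  count_one <- function(bm) {
    B <- binding_matrix(bm)
    if (mode == "spatial")
      pair_vector(spatial_counts_matrix(B, network$edges, count))
    else pair_vector(as.matrix(B %*% Matrix::t(B)))
  }
  obs <- count_one(ensemble_replicate(ens, 1L, network, binding))
  nulls <- matrix(0, replicates, length(obs))
  for (r in seq_len(replicates))
    nulls[r, ] <- count_one(ensemble_replicate(ens, r + 1L, network, binding))
  stats <- make_pair_stats(pair_index(binding$factors), obs, nulls, alpha,
                           pseudocount)
  structure(stats, mode = paste0(mode, "-control"), alpha = alpha,
            replicates = replicates, seed = ens$seed,
            class = c("pair_stats", "data.frame"))
}

#' Compare attract/repel calls from two analyses
#'
#' @param calls_a,calls_b Pair-stats data frames (or any data frames with
#'   `factor_i`, `factor_j`, `call`) over the same factor universe.
#' @return Data frame with `factor_i`, `factor_j`, `call_a`, `call_b` and
#'   `category` in `agree` (both significant, identical), `disagree` (both
#'   significant, opposite) or `insignificant` (one or both neutral).
#' @export
compare_calls <- function(calls_a, calls_b) {
  key <- function(x) paste(x$factor_i, x$factor_j, sep = "\r")
  if (!setequal(key(calls_a), key(calls_b)))
    stop("call tables cover different factor pairs")
  b <- calls_b$call[match(key(calls_a), key(calls_b))]
  a <- calls_a$call
  category <- ifelse(a == "neutral" | b == "neutral", "insignificant",
                     ifelse(a == b, "agree", "disagree"))
  data.frame(factor_i = calls_a$factor_i, factor_j = calls_a$factor_j,
             call_a = a, call_b = b, category = category,
             stringsAsFactors = FALSE)
}

#' Consensus network of repeatedly attracting pairs
#'
#' Keeps every factor pair called `attract` in at least `min_support` of the
#' supplied analyses (typically spatial/sequential x binding/motif). Pairs
#' absent from a table count as non-attracting there.
#'
#' @param call_sets Named list of pair-stats (or call) data frames.
#' @param min_support Minimum number of supporting attract calls
#'   (default 2).
#' @return Data frame with `factor_i`, `factor_j`, `n_support` and a
#'   comma-separated `supports` column naming the supporting analyses.
#' @export
consensus_network <- function(call_sets, min_support = 2L) {
  stopifnot(is.list(call_sets), length(call_sets) >= 1L)
  if (is.null(names(call_sets)))
    names(call_sets) <- paste0("set", seq_along(call_sets))
  longs <- lapply(names(call_sets), function(nm) {
    x <- call_sets[[nm]]
    x <- x[x$call == "attract", c("factor_i", "factor_j"), drop = FALSE]
    if (nrow(x)) x$support <- nm
    x
  })
  long <- do.call(rbind, longs[vapply(longs, nrow, 1L) > 0])
  if (is.null(long) || !nrow(long))
    return(data.frame(factor_i = character(), factor_j = character(),
                      n_support = integer(), supports = character(),
                      stringsAsFactors = FALSE))
  # canonical unordered pair key
  fi <- pmin(long$factor_i, long$factor_j)
  fj <- pmax(long$factor_i, long$factor_j)
  key <- paste(fi, fj, sep = "\r")
  agg <- tapply(long$support, key, function(s) sort(unique(s)))
  n_support <- lengths(agg)
  keys <- names(agg)[n_support >= min_support]
  parts <- strsplit(keys, "\r", fixed = TRUE)
  data.frame(
    factor_i = vapply(parts, `[`, "", 1L),
    factor_j = vapply(parts, `[`, "", 2L),
    n_support = as.integer(n_support[n_support >= min_support]),
    supports = vapply(agg[keys], paste, "", collapse = ","),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Signed q-value matrix for heatmap display
#'
#' Encodes attraction as `-q_attract` and repulsion as `+(1 - q_repel)`
#' (so strong attraction is most negative, strong repulsion closest to 1),
#' neutral pairs as 0. Rows/columns are ordered by average-linkage
#' hierarchical clustering of the matrix.
#'
#' @param stats A `pair_stats` data frame.
#' @return Symmetric numeric matrix with attribute `order` (the clustering
#'   order of factor names).
#' @export
heatmap_matrix <- function(stats) {
  factors <- sort(unique(c(stats$factor_i, stats$factor_j)))
  H <- matrix(0, length(factors), length(factors),
              dimnames = list(factors, factors))
  for (k in seq_len(nrow(stats))) {
    v <- switch(stats$call[k],
                attract = -stats$q_attract[k],
                repel = 1 - stats$q_repel[k],
                0)
    H[stats$factor_i[k], stats$factor_j[k]] <- v
    H[stats$factor_j[k], stats$factor_i[k]] <- v
  }
  ord <- seq_along(factors)
  if (length(factors) > 2L)
    ord <- stats::hclust(stats::dist(H), method = "average")$order
  attr(H, "order") <- factors[ord]
  H
}

#' Plot the signed q-value heatmap
#'
#' Renders [heatmap_matrix()] with attraction in green and repulsion in
#' red, rows/columns in clustering order. Requires the `pheatmap` package.
#'
#' @param stats A `pair_stats` data frame.
#' @param filename Optional output file (PNG by extension); default plots
#'   to the active device.
#' @return The `pheatmap` object, invisibly.
#' @export
plot_cooccurrence_heatmap <- function(stats, filename = NA) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("plot_cooccurrence_heatmap requires the pheatmap package")
  H <- heatmap_matrix(stats)
  ord <- attr(H, "order")
  pal <- grDevices::colorRampPalette(c("darkgreen", "green", "black",
                                       "red", "darkred"))(101)
  ph <- pheatmap::pheatmap(H[ord, ord], cluster_rows = FALSE,
                           cluster_cols = FALSE, color = pal,
                           breaks = seq(-1, 1, length.out = 102),
                           filename = filename)
  invisible(ph)
}

#' Restrict network edges to a compartment class
#'
#' Assigns each region to the compartment (e.g. A/B) with which it overlaps
#' most, then keeps only edges whose two endpoints share one compartment
#' class (optionally a specific class). Regions are retained; degrees are
#' recomputed.
#'
#' @param network An `interaction_network`.
#' @param compartments Data frame `chrom`, `start`, `end`, `name`
#'   (compartment class label), e.g. from [read_bed()].
#' @param class Optional single class label to keep (default: any shared
#'   class).
#' @return The edge-filtered `interaction_network`.
#' @export
restrict_to_compartments <- function(network, compartments, class = NULL) {
  stopifnot(inherits(network, "interaction_network"),
            "name" %in% names(compartments))
  validate_intervals(compartments, "compartment")
  hits <- GenomicRanges::findOverlaps(as_granges0(network$regions),
                                      as_granges0(compartments))
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(as_granges0(network$regions))[S4Vectors::queryHits(hits)],
    IRanges::ranges(as_granges0(compartments))[S4Vectors::subjectHits(hits)]))
  assign_class <- rep(NA_character_, nrow(network$regions))
  if (length(hits)) {
    df <- data.frame(r = S4Vectors::queryHits(hits),
                     cls = compartments$name[S4Vectors::subjectHits(hits)],
                     ov = ov)
    df <- df[order(df$r, -df$ov), ]
    df <- df[!duplicated(df$r), ]
    assign_class[df$r] <- df$cls
  }
  e <- network$edges
  c1 <- assign_class[e[, 1L]]; c2 <- assign_class[e[, 2L]]
  keep <- !is.na(c1) & !is.na(c2) & c1 == c2
  if (!is.null(class)) keep <- keep & c1 == class
  out <- network
  out$edges <- e[keep, , drop = FALSE]
  out$regions$degree <- region_degrees(nrow(out$regions), out$edges)
  out
}
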