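# Downstream statistics: hypergeometric 2x2 enrichment, target-gene
# assignment by the >=5 / <=3 group rule, TSS-distance distributions, and
# internal-node frequencies on shortest PPI paths.

#' One-sided hypergeometric enrichment test on a 2x2 table
#'
#' For counts `a` (attracting & interacting), `b` (avoiding & interacting),
#' `c` (attracting & not), `d` (avoiding & not), computes the exact upper
#' tail `P(X >= a)` with `X` hypergeometric on population `a+b+c+d`,
#' successes `a+b`, draws `a+c` (no continuity correction).
#'
#' @param a,b,c,d Non-negative cell counts, or a 2x2 matrix/table as `a`
#'   (first column = attracting, first row = interacting).
#' @return One-sided p-value; 1 with a warning for a zero-margin table.
#' @examples
#' hypergeom_enrichment(131, 61, 598, 718)   # 2.17e-09
#' @export
hypergeom_enrichment <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a) || is.table(a)) {
    stopifnot(all(dim(a) == 2L))
    m <- as.matrix(a)
    b <- m[1L, 2L]; c <- m[2L, 1L]; d <- m[2L, 2L]; a <- m[1L, 1L]
  }
  cells <- c(a, b, c, d)
  stopifnot(length(cells) == 4L, all(cells >= 0))
  if ((a + b) == 0L || (a + c) == 0L || (b + d) == 0L || (c + d) == 0L) {
    warning("zero margin in contingency table; p = 1 by convention")
    return(1)
  }
  stats::phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
}

#' Build the attract/avoid x interacting 2x2 table
#'
#' Crosses the attract/repel calls of a pair-stats table with membership in
#' a supplied set of (physically or potentially) interacting factor pairs.
#' Neutral pairs and homotypic pairs are excluded.
#'
#' @param stats A `pair_stats` data frame (column `call`).
#' @param interacting Data frame with columns `factor_i`, `factor_j`
#'   listing interacting pairs (unordered).
#' @return List with `table` (2x2 matrix: rows interacting yes/no, columns
#'   attracting/avoiding) and `p` from [hypergeom_enrichment()].
#' @export
pair_interaction_table <- function(stats, interacting) {
  x <- stats[stats$call != "neutral" & stats$factor_i != stats$factor_j, ]
  key <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = "\r")
  int_keys <- unique(key(interacting$factor_i, interacting$factor_j))
  is_int <- key(x$factor_i, x$factor_j) %in% int_keys
  attract <- x$call == "attract"
  tab <- matrix(c(sum(attract & is_int), sum(!attract & is_int),
                  sum(attract & !is_int), sum(!attract & !is_int)),
                2L, 2L, byrow = TRUE,
                dimnames = list(c("interacting", "not_interacting"),
                                c("attracting", "avoiding")))
  list(table = tab, p = hypergeom_enrichment(tab))
}

#' Potentially interacting factor pairs from domain-domain interactions
#'
#' A factor pair is "potentially interacting" when any protein domain of
#' one factor is listed as interacting with any domain of the other.
#'
#' @param factor_domains Data frame `factor`, `domain` (factor domain
#'   composition).
#' @param domain_pairs Data frame `domain_i`, `domain_j` of interacting
#'   domain pairs (unordered).
#' @return Data frame `factor_i`, `factor_j` of potentially interacting
#'   pairs.
#' @export
potential_interactions <- function(factor_domains, domain_pairs) {
  dkey <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = "\r")
  dp <- unique(dkey(domain_pairs$domain_i, domain_pairs$domain_j))
  facs <- sort(unique(factor_domains$factor))
  doms <- split(factor_domains$domain, factor_domains$factor)
  out <- list()
  for (i in seq_along(facs)) for (j in seq_len(i)) {
    combos <- expand.grid(di = doms[[facs[i]]], dj = doms[[facs[j]]],
                          stringsAsFactors = FALSE)
    if (any(dkey(combos$di, combos$dj) %in% dp))
      out[[length(out) + 1L]] <- c(facs[j], facs[i])
  }
  if (!length(out))
    return(data.frame(factor_i = character(), factor_j = character(),
                      stringsAsFactors = FALSE))
  m <- do.call(rbind, out)
  data.frame(factor_i = m[, 1L], factor_j = m[, 2L],
             stringsAsFactors = FALSE)
}

# factor -> genes targeted: a factor targets a gene when it binds a region
# within `window` bp of the gene TSS, or a region with an interaction edge
# to such a region
factor_gene_links <- function(binding, network, tss, window = 2000L) {
  stopifnot(all(c("chrom", "start", "gene") %in% names(tss)))
  tss_gr <- GenomicRanges::GRanges(tss$chrom,
                                   IRanges::IRanges(tss$start + 1L,
                                                    tss$start + 1L))
  reg_gr <- as_granges0(network$regions)
  hits <- GenomicRanges::findOverlaps(reg_gr, tss_gr, maxgap = window)
  prox <- data.frame(region = S4Vectors::queryHits(hits),
                     gene = tss$gene[S4Vectors::subjectHits(hits)],
                     stringsAsFactors = FALSE)
  e <- network$edges
  nbrs <- vector("list", nrow(network$regions))
  if (nrow(e)) {
    nb <- split(c(e[, 2L], e[, 1L]), c(e[, 1L], e[, 2L]))
    nbrs[as.integer(names(nb))] <- nb
  }
  genes_by_region <- split(prox$gene, prox$region)
  lapply(binding$bound, function(ids) {
    direct <- unlist(genes_by_region[as.character(ids)], use.names = FALSE)
    spatial_regions <- unique(unlist(nbrs[ids], use.names = FALSE))
    spatial <- unlist(genes_by_region[as.character(spatial_regions)],
                      use.names = FALSE)
    unique(c(direct, spatial))
  })
}

#' Assign target genes to factor groups
#'
#' A factor targets a gene when one of its bound regions lies within
#' `window` bp of the gene's TSS, either sequentially or via one spatial
#' interaction edge. A gene is then a group-1 (group-2) target when it is
#' targeted by at least `min_in` distinct factors of that group and at most
#' `max_out` factors of the other.
#'
#' @param binding A `binding_map`.
#' @param network An `interaction_network`.
#' @param tss Data frame `chrom`, `start`, `gene` (TSS positions, 0-based;
#'   a BED `name` column is accepted as `gene`).
#' @param groups Named vector mapping factor names to group 1 or 2; factors
#'   missing from it are ignored.
#' @param window Distance window in bp (default 2000).
#' @param min_in Minimum own-group factor count (default 5).
#' @param max_out Maximum other-group factor count (default 3).
#' @return Data frame per gene: `count_group1`, `count_group2`,
#'   `assigned_group` (1, 2 or NA).
#' @export
assign_target_genes <- function(binding, network, tss, groups,
                                window = 2000L, min_in = 5L, max_out = 3L) {
  if (is.null(tss$gene) && !is.null(tss$name)) tss$gene <- tss$name
  links <- factor_gene_links(binding, network, tss, window)
  g1 <- names(groups)[groups == 1]
  g2 <- names(groups)[groups == 2]
  genes <- sort(unique(tss$gene))
  count_in <- function(fset) {
    tab <- table(unlist(links[intersect(fset, names(links))],
                        use.names = FALSE))
    out <- stats::setNames(integer(length(genes)), genes)
    out[names(tab)] <- as.integer(tab)
    out
  }
  c1 <- count_in(g1); c2 <- count_in(g2)
  assigned <- ifelse(c1 >= min_in & c2 <= max_out, 1L,
                     ifelse(c2 >= min_in & c1 <= max_out, 2L, NA_integer_))
  data.frame(gene = genes, count_group1 = as.integer(c1),
             count_group2 = as.integer(c2), assigned_group = assigned,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Gene-set enrichment of group-1 over group-2 targets
#'
#' Crosses group membership of target genes with membership in a reference
#' gene set (e.g. housekeeping genes) and applies the one-sided
#' hypergeometric test (upper tail for group 1).
#'
#' @param targets_group1,targets_group2 Character vectors of target genes.
#' @param reference Character vector, the reference gene set.
#' @return List with the 2x2 `table` and the `p` value.
#' @export
gene_set_enrichment <- function(targets_group1, targets_group2, reference) {
  if (!length(targets_group1) || !length(targets_group2))
    stop("empty target gene set")
  a <- sum(targets_group1 %in% reference)
  b <- sum(targets_group2 %in% reference)
  cc <- sum(!targets_group1 %in% reference)
  d <- sum(!targets_group2 %in% reference)
  tab <- matrix(c(a, b, cc, d), 2L, 2L, byrow = TRUE,
                dimnames = list(c("in_reference", "not_in_reference"),
                                c("group1", "group2")))
  list(table = tab, p = hypergeom_enrichment(tab))
}

#' Write per-group target-gene lists for external enrichment tools
#'
#' Term-database-dependent analyses (GO, trait catalogs) are left to
#' external services; this writes the inputs they need: one gene list per
#' group plus the background list of all genes considered.
#'
#' @param targets Data frame from [assign_target_genes()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_target_gene_lists <- function(targets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(group1 = file.path(dir, "targets_group1.txt"),
             group2 = file.path(dir, "targets_group2.txt"),
             background = file.path(dir, "background_genes.txt"))
  writeLines(targets$gene[!is.na(targets$assigned_group) &
                            targets$assigned_group == 1L], paths[["group1"]])
  writeLines(targets$gene[!is.na(targets$assigned_group) &
                            targets$assigned_group == 2L], paths[["group2"]])
  writeLines(targets$gene, paths[["background"]])
  invisible(paths)
}

#' Distances from peaks to the nearest TSS, with empirical CDF
#'
#' Distance is measured from the peak midpoint (or nearest edge) to the
#' nearest TSS on the same chromosome. Peaks on chromosomes without any TSS
#' are excluded with a message.
#'
#' @param peaks_by_factor Named list of peak data frames
#'   (`chrom`,`start`,`end`).
#' @param tss Data frame `chrom`, `start` (TSS positions, 0-based).
#' @param mode `"midpoint"` (default) or `"edge"`.
#' @return Data frame `factor`, `distance` (bp), sorted within factor; use
#'   `stats::ecdf` on a factor's (or pooled group's) distances for the CDF.
#' @export
tss_distance_cdf <- function(peaks_by_factor, tss,
                             mode = c("midpoint", "edge")) {
  mode <- match.arg(mode)
  stopifnot(length(tss$start) > 0)
  tss_by_chrom <- lapply(split(tss$start, tss$chrom), sort)
  # |position - nearest TSS| via a sorted-insertion scan
  nearest_dist <- function(pos, ts) {
    i <- findInterval(pos, ts)
    left <- ifelse(i >= 1L, pos - ts[pmax(i, 1L)], Inf)
    right <- ifelse(i < length(ts), ts[pmin(i + 1L, length(ts))] - pos, Inf)
    pmin(left, right)
  }
  res <- lapply(names(peaks_by_factor), function(f) {
    pk <- peaks_by_factor[[f]]
    if (!nrow(pk)) return(NULL)
    keep <- pk$chrom %in% names(tss_by_chrom)
    if (any(!keep))
      message(sum(!keep), " peak(s) of ", f,
              " on chromosomes without a TSS excluded")
    pk <- pk[keep, , drop = FALSE]
    d <- unlist(lapply(split(seq_len(nrow(pk)), pk$chrom), function(ii) {
      ts <- tss_by_chrom[[pk$chrom[ii[1L]]]]
      if (mode == "midpoint") {
        mid <- pk$start[ii] + (pk$end[ii] - pk$start[ii]) %/% 2L
        nearest_dist(mid, ts)
      } else {
        # distance from the interval: 0 when a TSS falls inside
        dl <- nearest_dist(pk$start[ii], ts)
        dr <- nearest_dist(pk$end[ii] - 1L, ts)
        inside <- findInterval(pk$end[ii] - 1L, ts) -
          findInterval(pk$start[ii] - 1L, ts) > 0L
        ifelse(inside, 0, pmin(dl, dr))
      }
    }), use.names = FALSE)
    data.frame(factor = f, distance = sort(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(factor = character(), distance = numeric())
  rownames(out) <- NULL
  out
}

#' Internal-node frequencies on shortest PPI paths between factor pairs
#'
#' For each factor pair, finds the shortest-path distance in the (undirected,
#' unweighted) PPI graph and collects the union of internal nodes lying on
#' any shortest path between the pair; only nodes in `annotated_tfs` are
#' counted, once per pair, and frequencies are aggregated per pair category.
#'
#' @param ppi Data frame `node_i`, `node_j` of undirected PPI edges.
#' @param pairs Data frame `factor_i`, `factor_j`, `category` (e.g.
#'   group1/group2/cross).
#' @param annotated_tfs Character vector of annotated TF names.
#' @return Data frame `tf`, `category`, `count`. Disconnected or absent
#'   pairs contribute nothing (with a message).
#' @export
shortest_path_internal_tfs <- function(ppi, pairs, annotated_tfs) {
  g <- igraph::graph_from_data_frame(ppi[, c("node_i", "node_j")],
                                     directed = FALSE)
  g <- igraph::simplify(g)
  vnames <- igraph::V(g)$name
  counts <- list()
  skipped <- 0L
  for (k in seq_len(nrow(pairs))) {
    a <- pairs$factor_i[k]; b <- pairs$factor_j[k]
    if (!(a %in% vnames) || !(b %in% vnames)) { skipped <- skipped + 1L; next }
    da <- as.vector(igraph::distances(g, v = a))
    db <- as.vector(igraph::distances(g, v = b))
    dab <- da[match(b, vnames)]
    if (!is.finite(dab)) { skipped <- skipped + 1L; next }
    # node w is internal to some shortest path iff d(a,w) + d(w,b) = d(a,b)
    internal <- vnames[is.finite(da) & is.finite(db) & da + db == dab]
    internal <- setdiff(internal, c(a, b))
    internal <- intersect(internal, annotated_tfs)
    for (tf in internal) {
      kk <- paste(tf, pairs$category[k], sep = "\r")
      counts[[kk]] <- (counts[[kk]] %||% 0L) + 1L
    }
  }
  if (skipped) message(skipped, " disconnected/absent pair(s) skipped")
  if (!length(counts))
    return(data.frame(tf = character(), category = character(),
                      count = integer(), stringsAsFactors = FALSE))
  parts <- strsplit(names(counts), "\r", fixed = TRUE)
  out <- data.frame(tf = vapply(parts, `[`, "", 1L),
                    category = vapply(parts, `[`, "", 2L),
                    count = as.integer(unlist(counts)),
                    stringsAsFactors = FALSE)
  out[order(out$category, -out$count, out$tf), , drop = FALSE]
}
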