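# Region-region interaction network and bipartite TF-binding map.
#
# An `interaction_network` is a list with
#   regions: data.frame(id, chrom, start, end, degree)  -- id = row position
#   edges:   integer matrix, 2 columns, id1 < id2, unique, no self edges
# A `binding_map` is a list with
#   factors:   character vector of factor names
#   bound:     named list, per factor a sorted integer vector of region ids
#   n_regions: region count of the companion network

new_interaction_network <- function(regions, edges) {
  regions$id <- seq_len(nrow(regions))
  edges <- unique_edges(edges)
  if (is.null(regions$degree))
    regions$degree <- region_degrees(nrow(regions), edges)
  regions <- regions[, c("id", "chrom", "start", "end", "degree")]
  rownames(regions) <- NULL
  structure(list(regions = regions, edges = edges),
            class = "interaction_network")
}

# canonicalize: id1 < id2, drop self edges and duplicates
unique_edges <- function(edges) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges)) {
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                   pmax(edges[, 1L], edges[, 2L]))
    edges <- edges[edges[, 1L] != edges[, 2L], , drop = FALSE]
    edges <- edges[!duplicated(edges), , drop = FALSE]
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  colnames(edges) <- c("id1", "id2")
  edges
}

region_degrees <- function(n, edges) {
  tabulate(c(edges[, 1L], edges[, 2L]), nbins = n)
}

#' Build the region-region interaction network
#'
#' Merges interaction anchors (gap `merge_gap`), maps each anchor pair to its
#' merged regions, drops self edges (both anchors in one merged region) and
#' short-range pairs (regions on one chromosome separated by at most
#' `min_span` bp), deduplicates edges, and finally removes regions with
#' unrealistically high degree (> `max_degree`) or length (> `max_length`)
#' together with their incident edges. Regions that merely lose edges are
#' retained with degree 0.
#'
#' @param pairs Data frame of anchor pairs with columns
#'   `chrom1,start1,end1,chrom2,start2,end2` (0-based half-open), e.g. from
#'   [read_interactions()].
#' @param merge_gap Anchor-merge gap in bp (default 2000).
#' @param min_span Minimum same-chromosome separation in bp for an edge to
#'   count as long-range (default 2000).
#' @param max_degree Maximum allowed region degree (default 20).
#' @param max_length Maximum allowed region length in bp (default 30000).
#' @param iterate_filter Re-apply the degree/length filter until stable
#'   instead of the default single pass.
#' @param intra_chromosomal_only Drop inter-chromosomal edges (default keeps
#'   them).
#' @return An `interaction_network` object.
#' @export
build_interaction_network <- function(pairs, merge_gap = 2000L,
                                      min_span = 2000L, max_degree = 20L,
                                      max_length = 30000L,
                                      iterate_filter = FALSE,
                                      intra_chromosomal_only = FALSE) {
  stopifnot(merge_gap >= 0, min_span >= 0, max_degree > 0, max_length > 0)
  need <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  stopifnot(all(need %in% names(pairs)))
  a1 <- data.frame(chrom = pairs$chrom1, start = pairs$start1,
                   end = pairs$end1, stringsAsFactors = FALSE)
  a2 <- data.frame(chrom = pairs$chrom2, start = pairs$start2,
                   end = pairs$end2, stringsAsFactors = FALSE)
  validate_intervals(a1, "anchor 1"); validate_intervals(a2, "anchor 2")

  if (nrow(pairs) == 0L) {
    return(new_interaction_network(
      data.frame(id = integer(), chrom = character(), start = integer(),
                 end = integer(), degree = integer(),
                 stringsAsFactors = FALSE),
      matrix(integer(), ncol = 2L)))
  }

  regions <- merge_intervals(rbind(a1, a2), gap = merge_gap)
  rgr <- as_granges0(regions)
  locate <- function(anchors) {
    hits <- GenomicRanges::findOverlaps(as_granges0(anchors), rgr,
                                        select = "first")
    if (anyNA(hits))
      stop("internal error: anchor overlaps no merged region")
    hits
  }
  e <- cbind(locate(a1), locate(a2))
  e <- unique_edges(e)                      # self edges + duplicates gone

  if (nrow(e)) {
    same <- regions$chrom[e[, 1L]] == regions$chrom[e[, 2L]]
    if (intra_chromosomal_only) e <- e[same, , drop = FALSE]
  }
  if (nrow(e)) {
    same <- regions$chrom[e[, 1L]] == regions$chrom[e[, 2L]]
    # region ids are sorted by coordinate, so id1 < id2 implies id1 upstream
    gap <- regions$start[e[, 2L]] - regions$end[e[, 1L]]
    short <- same & gap <= min_span
    e <- e[!short, , drop = FALSE]
  }

  regions$degree <- region_degrees(nrow(regions), e)
  repeat {
    len <- regions$end - regions$start
    bad <- which(regions$degree > max_degree | len > max_length)
    if (!length(bad)) break
    keep <- setdiff(seq_len(nrow(regions)), bad)
    remap <- integer(nrow(regions)); remap[keep] <- seq_along(keep)
    e <- e[e[, 1L] %in% keep & e[, 2L] %in% keep, , drop = FALSE]
    e <- cbind(remap[e[, 1L]], remap[e[, 2L]])
    colnames(e) <- c("id1", "id2")
    regions <- regions[keep, , drop = FALSE]
    regions$degree <- region_degrees(nrow(regions), e)
    if (!iterate_filter) {
      # degrees only decrease on removal, so one pass suffices; assert it
      stopifnot(all(regions$degree <= max_degree))
      break
    }
  }
  rownames(regions) <- NULL
  new_interaction_network(regions[, c("chrom", "start", "end", "degree")], e)
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf(
    "interaction_network: %d regions, %d edges (max degree %s, %d chromosomes)\n",
    nrow(x$regions), nrow(x$edges),
    if (nrow(x$regions)) max(x$regions$degree) else "NA",
    length(unique(x$regions$chrom))))
  invisible(x)
}

new_binding_map <- function(bound, n_regions) {
  bound <- lapply(bound, function(v) sort(unique(as.integer(v))))
  structure(list(factors = names(bound), bound = bound,
                 n_regions = as.integer(n_regions)),
            class = "binding_map")
}

#' @export
print.binding_map <- function(x, ...) {
  cat(sprintf("binding_map: %d factors over %d regions (%d links)\n",
              length(x$factors), x$n_regions,
              sum(lengths(x$bound))))
  invisible(x)
}

#' Map ChIP-seq peaks onto network regions
#'
#' Links factor `f` to region `r` when some peak of `f` overlaps `r`'s
#' interval by at least `min_overlap` bp (half-open coordinates: an abutting
#' peak does not overlap). Multiple peaks in one region yield a single link.
#'
#' @param network An `interaction_network`.
#' @param peaks_by_factor Named list of peak data frames
#'   (`chrom`,`start`,`end`), one per factor.
#' @param min_overlap Minimum overlap in bp (default 1).
#' @param mode `"overlap"` (default) or `"midpoint"` (peak midpoint must lie
#'   inside the region).
#' @return A `binding_map`. Factors with zero mapped regions are kept with an
#'   empty set and a warning.
#' @export
map_bindings <- function(network, peaks_by_factor, min_overlap = 1L,
                         mode = c("overlap", "midpoint")) {
  mode <- match.arg(mode)
  stopifnot(inherits(network, "interaction_network"),
            is.list(peaks_by_factor), !is.null(names(peaks_by_factor)),
            min_overlap >= 1L)
  rgr <- as_granges0(network$regions)
  bound <- lapply(names(peaks_by_factor), function(f) {
    pk <- peaks_by_factor[[f]]
    validate_intervals(pk, paste("peak for", f))
    if (nrow(pk) == 0L) return(integer())
    if (mode == "midpoint") {
      mid <- pk$start + (pk$end - pk$start) %/% 2L
      pk <- data.frame(chrom = pk$chrom, start = mid, end = mid + 1L)
    }
    hits <- GenomicRanges::findOverlaps(as_granges0(pk), rgr,
                                        minoverlap = min_overlap)
    sort(unique(S4Vectors::subjectHits(hits)))
  })
  names(bound) <- names(peaks_by_factor)
  empty <- names(bound)[lengths(bound) == 0L]
  if (length(empty))
    warning("factor(s) with zero mapped regions: ",
            paste(empty, collapse = ", "))
  new_binding_map(bound, nrow(network$regions))
}

# factors x regions sparse 0/1 matrix view of a binding map
binding_matrix <- function(binding) {
  Matrix::sparseMatrix(
    i = rep.int(seq_along(binding$factors), lengths(binding$bound)),
    j = unlist(binding$bound, use.names = FALSE),
    x = 1,
    dims = c(length(binding$factors), binding$n_regions),
    dimnames = list(binding$factors, NULL)
  )
}

#' Convert an interaction network to an igraph graph
#'
#' @param network An `interaction_network`.
#' @return An undirected `igraph` graph whose vertices carry the region
#'   coordinates as attributes.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  g <- igraph::make_empty_graph(n = nrow(network$regions), directed = FALSE)
  g <- igraph::add_edges(g, t(network$edges))
  igraph::vertex_attr(g, "chrom") <- network$regions$chrom
  igraph::vertex_attr(g, "start") <- network$regions$start
  igraph::vertex_attr(g, "end") <- network$regions$end
  g
}

#' Write / read an interaction network as TSV
#'
#' Nodes TSV: `id, chrom, start, end, degree`; edges TSV: `id1, id2`.
#'
#' @param network An `interaction_network`.
#' @param nodes_path,edges_path Output (or input) file paths.
#' @return `write_network` returns the paths invisibly; `read_network`
#'   returns an `interaction_network`.
#' @export
write_network <- function(network, nodes_path, edges_path) {
  utils::write.table(network$regions, nodes_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(network$edges, edges_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(nodes_path, edges_path))
}

#' @rdname write_network
#' @export
read_network <- function(nodes_path, edges_path) {
  nodes <- utils::read.table(nodes_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  edges <- utils::read.table(edges_path, sep = "\t", header = TRUE)
  new_interaction_network(nodes[, c("chrom", "start", "end")],
                          as.matrix(edges[, c("id1", "id2")]))
}
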