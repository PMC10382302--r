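# Degree-class-preserving randomization of the bipartite binding network.
#
# Every TF-region link is reassigned to a region whose region-region
# interaction degree lies in the same degree class as the original target:
# exact degree for d <= 5, a +/-2 window for 6 <= d <= 10, and the open
# class {11, ..., max degree} above that. Per-factor out-degrees are
# conserved exactly (links are drawn without replacement per factor).

#' Degree-class rule for the binding-network randomization
#'
#' @param exact_max Largest degree matched exactly (default 5).
#' @param window_lo,window_hi Degree range matched within
#'   `+/- window_halfwidth` (defaults 6 and 10).
#' @param window_halfwidth Half-width of the windowed class (default 2).
#' @return A `degree_class_rule` object.
#' @export
degree_class_rule <- function(exact_max = 5L, window_lo = 6L,
                              window_hi = 10L, window_halfwidth = 2L) {
  stopifnot(exact_max < window_lo, window_lo <= window_hi,
            window_halfwidth >= 0)
  structure(list(exact_max = as.integer(exact_max),
                 window_lo = as.integer(window_lo),
                 window_hi = as.integer(window_hi),
                 window_halfwidth = as.integer(window_halfwidth)),
            class = "degree_class_rule")
}

#' Candidate replacement degrees for an original target degree
#'
#' @param d Original region-region degree (>= 0).
#' @param rule A [degree_class_rule()].
#' @param max_degree Largest degree present in the network (caps the open
#'   top class; default 20, the network construction cap).
#' @return Integer vector of admissible replacement degrees.
#' @examples
#' candidate_degrees(3)                    # exact: 3
#' candidate_degrees(6)                    # windowed: 4..8
#' candidate_degrees(15, max_degree = 20)  # open top class: 11..20
#' @export
candidate_degrees <- function(d, rule = degree_class_rule(),
                              max_degree = 20L) {
  stopifnot(d >= 0)
  d <- as.integer(d)
  if (d <= rule$exact_max) return(d)
  if (d <= rule$window_hi)
    return(seq.int(max(0L, d - rule$window_halfwidth),
                   d + rule$window_halfwidth))
  seq.int(rule$window_hi + 1L, max(max_degree, d))
}

# Precompute, per distinct target degree, the pool of candidate region ids.
# Reused across all replicates of an ensemble.
randomization_scheme <- function(network, binding, rule = degree_class_rule()) {
  deg <- network$regions$degree
  max_deg <- if (length(deg)) max(deg) else 0L
  links_by_deg <- lapply(binding$bound, function(ids) {
    if (!length(ids)) return(list())
    split(ids, deg[ids])
  })
  need <- unique(unlist(lapply(links_by_deg, names), use.names = FALSE))
  pools <- lapply(need, function(ds) {
    which(deg %in% candidate_degrees(as.integer(ds), rule, max_deg))
  })
  names(pools) <- need
  list(links_by_deg = links_by_deg, pools = pools,
       n_regions = binding$n_regions)
}

#' Randomize a binding map preserving degree classes
#'
#' Produces one randomized replicate of the bipartite binding network: each
#' factor keeps its out-degree exactly, and each link originally pointing at
#' a region of degree `d` is reassigned (uniformly, without replacement per
#' factor) to a region with degree in [candidate_degrees()] of `d`. The
#' original region is itself a candidate ("possibly the same region"). If a
#' factor's demand exhausts a candidate pool, the surplus links keep their
#' original regions and a warning is emitted.
#'
#' @param network An `interaction_network`.
#' @param binding A `binding_map` consistent with `network`.
#' @param rule A [degree_class_rule()].
#' @param seed Optional integer seed (deterministic output when set).
#' @param scheme Internal precomputed pools; leave `NULL`.
#' @param keep_assignment Attach a per-link `orig -> new` assignment table
#'   (attribute `"assignment"`) for auditing.
#' @return A randomized `binding_map`.
#' @export
randomize_bindings <- function(network, binding, rule = degree_class_rule(),
                               seed = NULL, scheme = NULL,
                               keep_assignment = FALSE) {
  if (is.null(scheme)) scheme <- randomization_scheme(network, binding, rule)
  maybe_set_seed(seed)
  assignment <- if (keep_assignment) vector("list", length(scheme$links_by_deg))
  bound <- vector("list", length(scheme$links_by_deg))
  names(bound) <- names(scheme$links_by_deg)
  for (f in seq_along(bound)) {
    by_deg <- scheme$links_by_deg[[f]]
    chosen <- integer(0)
    orig_all <- integer(0)
    # scarcest candidate pools first, so overlapping windowed classes do
    # not starve the rare top-class regions
    class_order <- names(by_deg)[order(lengths(scheme$pools[names(by_deg)]))]
    for (ds in class_order) {
      orig <- by_deg[[ds]]
      k <- length(orig)
      avail <- setdiff(scheme$pools[[ds]], chosen)
      if (length(avail) >= k) {
        new <- if (length(avail) == 1L) avail else sample(avail, k)
      } else {
        # pool exhausted: take every unused candidate; surplus links keep
        # their original regions where possible, and as a last resort move
        # to any unused region (out-degree conservation takes precedence
        # over the degree class)
        warning("candidate pool for degree ", ds,
                " exhausted; surplus links keep their original regions")
        new <- c(avail, setdiff(orig, c(avail, chosen)))
        if (length(new) < k) {
          pool_rest <- setdiff(seq_len(scheme$n_regions), c(chosen, new))
          extra <- if (length(pool_rest) == 1L) pool_rest
                   else sample(pool_rest, k - length(new))
          new <- c(new, extra)
        }
        new <- new[seq_len(k)]
      }
      chosen <- c(chosen, new)
      orig_all <- c(orig_all, orig[seq_along(new)])
    }
    bound[[f]] <- chosen
    if (keep_assignment)
      assignment[[f]] <- data.frame(orig = orig_all, new = chosen)
  }
  out <- new_binding_map(bound, scheme$n_regions)
  if (keep_assignment) {
    names(assignment) <- names(bound)
    attr(out, "assignment") <- assignment
  }
  out
}

#' Generate an ensemble of randomized binding networks
#'
#' Replicate seeds are derived reproducibly from the master seed by index,
#' so replicate `i` does not depend on how many replicates precede it.
#'
#' @param network An `interaction_network`.
#' @param binding A `binding_map`.
#' @param replicates Number of replicates R (default 1000).
#' @param rule A [degree_class_rule()].
#' @param seed Master seed.
#' @param materialize Keep all replicate binding maps in memory
#'   (default `FALSE`: the ensemble stores only seeds and replicates are
#'   regenerated on demand by [ensemble_replicate()]).
#' @return A `randomization_ensemble` object.
#' @export
generate_ensemble <- function(network, binding, replicates = 1000L,
                              rule = degree_class_rule(), seed = NULL,
                              materialize = FALSE) {
  if (replicates < 1L) stop("replicates must be >= 1")
  seed <- seed %||% sample.int(2147483646L, 1L)
  scheme <- randomization_scheme(network, binding, rule)
  rep_seeds <- replicate_seeds(seed, replicates)
  maps <- NULL
  if (materialize)
    maps <- lapply(rep_seeds, function(s)
      randomize_bindings(network, binding, rule, seed = s, scheme = scheme))
  structure(list(replicates = as.integer(replicates), seed = seed,
                 rep_seeds = rep_seeds, rule = rule, scheme = scheme,
                 maps = maps),
            class = "randomization_ensemble")
}

#' Materialize one replicate of an ensemble
#'
#' @param ensemble A `randomization_ensemble`.
#' @param i Replicate index in `1:replicates`.
#' @param network,binding The network and binding map the ensemble was
#'   built from.
#' @return The i-th randomized `binding_map`.
#' @export
ensemble_replicate <- function(ensemble, i, network, binding) {
  stopifnot(i >= 1L, i <= ensemble$replicates)
  if (!is.null(ensemble$maps)) return(ensemble$maps[[i]])
  randomize_bindings(network, binding, ensemble$rule,
                     seed = ensemble$rep_seeds[[i]],
                     scheme = ensemble$scheme)
}

#' Audit degree-class conservation across an ensemble
#'
#' Checks, for every replicate: per-factor out-degree conserved exactly;
#' every link's replacement degree inside the candidate class of its
#' original degree; and the per-factor multiset of target degrees conserved
#' exactly over the exact class (original degree <= `exact_max`). Note the
#' windowed class can legally exchange links across the exact-class boundary
#' (an original degree-6 link may land on a degree-4 region), so the
#' exact-class multiset check is guaranteed only on networks whose windowed
#' degree classes do not bleed below `exact_max + 1`.
#'
#' @inheritParams generate_ensemble
#' @return Data frame with one row per replicate and logical columns
#'   `outdegree_ok`, `link_class_ok`, `exact_class_ok`.
#' @export
randomization_audit <- function(network, binding, replicates = 500L,
                                rule = degree_class_rule(), seed = NULL) {
  deg <- network$regions$degree
  max_deg <- if (length(deg)) max(deg) else 0L
  scheme <- randomization_scheme(network, binding, rule)
  rep_seeds <- replicate_seeds(seed %||% sample.int(2147483646L, 1L),
                               replicates)
  orig_sizes <- lengths(binding$bound)
  orig_exact <- lapply(binding$bound, function(ids)
    sort(deg[ids][deg[ids] <= rule$exact_max]))
  res <- vapply(seq_len(replicates), function(i) {
    bm <- randomize_bindings(network, binding, rule, seed = rep_seeds[[i]],
                             scheme = scheme, keep_assignment = TRUE)
    asn <- attr(bm, "assignment")
    link_ok <- all(vapply(asn, function(a) {
      if (!nrow(a)) return(TRUE)
      all(mapply(function(o, n) deg[n] %in% candidate_degrees(deg[o], rule,
                                                              max_deg),
                 a$orig, a$new))
    }, logical(1)))
    exact <- lapply(bm$bound, function(ids)
      sort(deg[ids][deg[ids] <= rule$exact_max]))
    c(all(lengths(bm$bound) == orig_sizes),
      link_ok,
      all(mapply(identical, exact, orig_exact)))
  }, logical(3))
  data.frame(replicate = seq_len(replicates),
             outdegree_ok = res[1, ], link_class_ok = res[2, ],
             exact_class_ok = res[3, ])
}
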