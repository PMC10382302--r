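# Synthetic interaction networks, bindings, motifs and sequences with
# planted attraction/repulsion structure. The generators emit the same
# objects (and, via the writers, the same file formats) the analysis
# pipeline consumes, so every stage is testable without external data.

#' Configuration for the synthetic-data generator
#'
#' Defaults describe the reference simulation condition used throughout the
#' package's tests: 2000 regions with Poisson(3) interaction degrees, 20
#' factors in two groups of 8 plus 4 ungrouped factors, baseline binding
#' probability 0.10 per factor-region, co-binding odds boosted 8-fold for
#' same-group pairs across an edge and damped 8-fold for cross-group pairs.
#'
#' @param n_regions Number of regions (default 2000).
#' @param degree_law One of `list(type = "poisson", lambda = )`,
#'   `list(type = "fixed", k = )`, or `list(type = "empirical", degrees = )`.
#' @param n_factors Number of factors (default 20).
#' @param group_of Integer vector of length `n_factors` with values 1, 2 or
#'   `NA` (ungrouped). Default: 40% group 1, 40% group 2, rest ungrouped.
#' @param attract_boost Multiplicative odds boost (>= 1) for same-group
#'   co-binding across an edge (default 8).
#' @param repel_damp Multiplicative odds damping (<= 1) for cross-group
#'   co-binding (default 1/8).
#' @param base_bind_prob Baseline per-factor per-region binding probability
#'   (default 0.10).
#' @param max_degree Degree cap so the generated network passes the
#'   construction filters untouched (default 20).
#' @param seed Master seed; network, binding and motif stages use seeds
#'   derived from it by index.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_regions = 2000L,
                         degree_law = list(type = "poisson", lambda = 3),
                         n_factors = 20L, group_of = NULL,
                         attract_boost = 8, repel_damp = 1 / 8,
                         base_bind_prob = 0.10, max_degree = 20L,
                         seed = NULL) {
  stopifnot(n_regions >= 2L, n_factors >= 1L, attract_boost >= 1,
            repel_damp <= 1, repel_damp > 0,
            base_bind_prob > 0, base_bind_prob < 1)
  if (is.null(group_of)) {
    k <- floor(0.4 * n_factors)
    group_of <- rep(NA_integer_, n_factors)
    if (k >= 1L) {
      group_of[seq_len(k)] <- 1L
      group_of[k + seq_len(k)] <- 2L
    }
  }
  stopifnot(length(group_of) == n_factors,
            all(is.na(group_of) | group_of %in% 1:2))
  seed <- seed %||% sample.int(2147483646L, 1L)
  structure(list(n_regions = as.integer(n_regions), degree_law = degree_law,
                 n_factors = as.integer(n_factors),
                 group_of = as.integer(group_of),
                 attract_boost = attract_boost, repel_damp = repel_damp,
                 base_bind_prob = base_bind_prob,
                 max_degree = as.integer(max_degree),
                 seed = as.integer(seed)),
            class = "synth_config")
}

synth_stage_seed <- function(config, stage) {
  replicate_seeds(config$seed, 3L)[match(stage,
                                         c("network", "binding", "motif"))]
}

draw_degrees <- function(config) {
  law <- config$degree_law
  d <- switch(law$type,
              poisson = stats::rpois(config$n_regions, law$lambda),
              fixed = rep(as.integer(law$k), config$n_regions),
              empirical = sample(as.integer(law$degrees), config$n_regions,
                                 replace = TRUE),
              stop("unknown degree law: ", law$type))
  d <- pmin(d, config$max_degree)
  if (sum(d) %% 2L == 1L) {
    i <- which(d < config$max_degree)[1L]
    d[i] <- d[i] + 1L
  }
  d
}

# region intervals on a synthetic chromosome: lengths < 30 kbp and gaps
# wide enough (> 2 x merge gap) that the construction filters are no-ops
synth_region_table <- function(n, min_len = 500L, max_len = 1500L,
                               gap = 5000L, chrom = "chrS") {
  len <- if (min_len == max_len) rep(min_len, n)
         else sample(seq.int(min_len, max_len), n, replace = TRUE)
  start <- cumsum(c(gap, utils::head(len, -1L) + gap))
  data.frame(chrom = chrom, start = start, end = start + len,
             stringsAsFactors = FALSE)
}

#' Simulate an interaction network
#'
#' Draws a degree sequence from the configured law, realizes a simple graph
#' with exactly those degrees (configuration-model style, no self or
#' duplicate edges), and lays the regions on a synthetic chromosome with
#' lengths and gaps chosen so that the standard construction filters leave
#' the network untouched.
#'
#' @param config A [synth_config()].
#' @return An `interaction_network`.
#' @export
simulate_network <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  maybe_set_seed(synth_stage_seed(config, "network"))
  d <- draw_degrees(config)
  g <- tryCatch(
    igraph::sample_degseq(d, method = "fast.heur.simple"),
    error = function(e) stop("infeasible degree sequence: ",
                             conditionMessage(e)))
  edges <- igraph::as_edgelist(g)
  regions <- synth_region_table(config$n_regions)
  net <- new_interaction_network(regions, edges)
  stopifnot(all(net$regions$degree == d))
  net
}

synth_factor_names <- function(n) sprintf("TF%02d", seq_len(n))

#' Simulate factor bindings with planted attraction/repulsion
#'
#' Binding indicators are drawn from a pairwise Markov random field over the
#' interaction network: relative to independent baseline binding at
#' `base_bind_prob`, the joint odds of two factors co-binding the two
#' endpoints of an interaction edge are multiplied by `attract_boost` for
#' same-group pairs and by `repel_damp` for cross-group pairs (ungrouped
#' factors carry no tilt and bind independently). Sampling uses block Gibbs
#' sweeps (one factor's bindings are conditionally independent given all
#' other factors, since homotypic pairs carry no tilt), and at every update
#' the factor's intercept is calibrated so its expected marginal binding
#' rate stays at `base_bind_prob`; realized per-factor rates therefore
#' fluctuate only by binomial noise around the design value.
#'
#' @param network An `interaction_network` from [simulate_network()].
#' @param config The same [synth_config()].
#' @param sweeps Gibbs sweeps (default 30).
#' @return List with `binding` (a `binding_map`) and `truth` (data frame
#'   `factor_i`, `factor_j`, `relation` in attract/repel/null for every
#'   heterotypic pair).
#' @export
simulate_bindings <- function(network, config, sweeps = 30L) {
  stopifnot(inherits(config, "synth_config"))
  maybe_set_seed(synth_stage_seed(config, "binding"))
  n <- config$n_regions
  nf <- config$n_factors
  p <- config$base_bind_prob
  factors <- synth_factor_names(nf)
  grp <- config$group_of

  px <- pair_index(factors)
  px <- px[px$i != px$j, ]
  relation <- ifelse(is.na(grp[px$i]) | is.na(grp[px$j]), "null",
                     ifelse(grp[px$i] == grp[px$j], "attract", "repel"))
  truth <- data.frame(factor_i = px$factor_i, factor_j = px$factor_j,
                      relation = relation, stringsAsFactors = FALSE)

  # pairwise log-odds tilt matrix (0 for homotypic, ungrouped and
  # null-relation pairs)
  logtilt <- matrix(0, nf, nf)
  for (k in seq_len(nrow(px))) {
    v <- switch(relation[k], attract = log(config$attract_boost),
                repel = log(config$repel_damp), 0)
    logtilt[px$i[k], px$j[k]] <- v
    logtilt[px$j[k], px$i[k]] <- v
  }

  e <- network$edges
  A <- Matrix::sparseMatrix(i = c(e[, 1L], e[, 2L]),
                            j = c(e[, 2L], e[, 1L]), x = 1,
                            dims = c(n, n))
  B <- matrix(stats::runif(nf * n) < p, nf, n,
              dimnames = list(factors, NULL))
  tilted <- which(rowSums(logtilt != 0) > 0)
  if (length(tilted) && nrow(e)) {
    for (s in seq_len(sweeps)) {
      for (f in tilted) {
        # neighbour-bound counts per partner factor, then the pairwise field
        NBf <- as.vector(logtilt[f, ] %*% (B %*% A))
        # intercept calibrated so the expected marginal rate equals p
        a <- tryCatch(stats::uniroot(function(a)
          mean(stats::plogis(a + NBf)) - p,
          lower = stats::qlogis(p) - 40, upper = stats::qlogis(p) + 40,
          tol = 1e-8)$root,
          error = function(e) stats::qlogis(p))
        B[f, ] <- stats::runif(n) < stats::plogis(a + NBf)
      }
    }
  }
  bound <- apply(B, 1L, which, simplify = FALSE)
  list(binding = new_binding_map(bound, n), truth = truth)
}

#' Simulate a motif-scanning dataset with degree-dependent motif strength
#'
#' Generates a synthetic genome with isolated (degree-0) and interacting
#' (degree-1, pairwise-linked) regions; each region's sequence is i.i.d.
#' uniform background, and an exact consensus occurrence of the motif is
#' inserted with probability `p_iso` in isolated regions and `p_int` in
#' interacting regions. `p_iso > p_int` emulates the observation that
#' spatially isolated binding sites carry stronger motifs.
#'
#' @param n_isolated,n_interacting Region counts (defaults 200 each;
#'   `n_interacting` is rounded down to an even number for pairing).
#' @param peak_length Region/peak length in bp (default 300).
#' @param pwm A `pwm` object; default is a generated 8-mer with 0.85
#'   dominant-base probability per position.
#' @param p_iso,p_int Consensus planting probabilities (defaults 0.6, 0.2).
#' @param seed Integer seed.
#' @return List with `network`, `genome` (a [Biostrings::DNAStringSet] of
#'   one synthetic chromosome), `peaks` (data frame, one peak per region),
#'   `pwm`, and `planted` (logical per region).
#' @export
simulate_motif_dataset <- function(n_isolated = 200L, n_interacting = 200L,
                                   peak_length = 300L, pwm = NULL,
                                   p_iso = 0.6, p_int = 0.2, seed = NULL) {
  maybe_set_seed(seed)
  n_interacting <- 2L * (n_interacting %/% 2L)
  n <- n_isolated + n_interacting
  stopifnot(n >= 1L, p_iso >= 0, p_iso <= 1, p_int >= 0, p_int <= 1)
  if (is.null(pwm)) {
    L <- 8L
    W <- matrix(0.05, L, 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
    cons <- sample.int(4L, L, replace = TRUE)
    W[cbind(seq_len(L), cons)] <- 0.85
    pwm <- make_pwm("synthTF", W)
  }
  L <- nrow(pwm$matrix)
  stopifnot(peak_length >= L)

  regions <- synth_region_table(n, min_len = peak_length,
                                max_len = peak_length)
  interacting <- sample.int(n, n_interacting)
  e <- matrix(interacting, ncol = 2L)
  net <- new_interaction_network(regions, e)

  chrom_len <- max(regions$end) + 1000L
  genome_chars <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
  is_int <- net$regions$degree > 0L
  planted <- stats::runif(n) < ifelse(is_int, p_int, p_iso)
  cons_chars <- strsplit(consensus_string(pwm), "")[[1L]]
  for (r in which(planted)) {
    off <- sample.int(peak_length - L + 1L, 1L) - 1L
    at <- net$regions$start[r] + off   # 0-based genome offset
    genome_chars[(at + 1L):(at + L)] <- cons_chars
  }
  genome <- Biostrings::DNAStringSet(paste(genome_chars, collapse = ""))
  names(genome) <- net$regions$chrom[1L]

  peaks <- data.frame(chrom = net$regions$chrom, start = net$regions$start,
                      end = net$regions$end, factor = pwm$name,
                      region = net$regions$id, stringsAsFactors = FALSE)
  list(network = net, genome = genome, peaks = peaks, pwm = pwm,
       planted = planted)
}

#' Write a simulated dataset in the pipeline's input formats
#'
#' Emits the interaction pairs TSV, one BED peak file per factor, and the
#' planted-relation truth TSV; with a motif dataset also the genome FASTA
#' and the motif in MEME minimal format.
#'
#' @param dir Output directory (created if needed).
#' @param network An `interaction_network`.
#' @param binding Optional `binding_map`.
#' @param truth Optional truth data frame from [simulate_bindings()].
#' @param genome Optional `DNAStringSet`.
#' @param pwm Optional `pwm`.
#' @return Named character vector of written paths, invisibly.
#' @export
write_synth_dataset <- function(dir, network, binding = NULL, truth = NULL,
                                genome = NULL, pwm = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(interactions = file.path(dir, "interactions.tsv"))
  r <- network$regions
  e <- network$edges
  pairs <- data.frame(chrom1 = r$chrom[e[, 1L]], start1 = r$start[e[, 1L]],
                      end1 = r$end[e[, 1L]], chrom2 = r$chrom[e[, 2L]],
                      start2 = r$start[e[, 2L]], end2 = r$end[e[, 2L]])
  utils::write.table(pairs, paths[["interactions"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(binding)) {
    for (f in binding$factors) {
      path <- file.path(dir, paste0("peaks_", f, ".bed"))
      paths[[paste0("peaks_", f)]] <- path
      ids <- binding$bound[[f]]
      utils::write.table(r[ids, c("chrom", "start", "end")], path,
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
    }
  }
  if (!is.null(truth)) {
    paths[["truth"]] <- file.path(dir, "truth.tsv")
    utils::write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(genome)) {
    paths[["genome"]] <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(genome, paths[["genome"]])
  }
  if (!is.null(pwm)) {
    paths[["motif"]] <- file.path(dir, "motif.meme")
    write_meme(list(pwm), paths[["motif"]])
  }
  invisible(paths)
}
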