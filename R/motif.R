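# Position weight matrices: information content, representative selection,
# log2 likelihood-ratio scoring, an exact (discretized) score distribution
# under the background model for FIMO-style p-value thresholds, region
# scanning, and the strong-motif / spatial-isolation analysis.

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' @param name Motif name.
#' @param matrix Numeric L x 4 matrix of per-position base probabilities,
#'   columns A, C, G, T; each row must sum to 1 within 1e-6.
#' @return A `pwm` object.
#' @export
make_pwm <- function(name, matrix) {
  matrix <- as.matrix(matrix)
  stopifnot(ncol(matrix) == 4L, nrow(matrix) >= 1L, all(matrix >= 0),
            all(abs(rowSums(matrix) - 1) < 1e-6))
  colnames(matrix) <- DNA_BASES
  structure(list(name = as.character(name), matrix = matrix),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s: length %d, information %.2f bits, consensus %s\n",
              x$name, nrow(x$matrix), information_score(x),
              consensus_string(x)))
  invisible(x)
}

#' Consensus sequence of a PWM (most probable base per position)
#' @param pwm A `pwm` object.
#' @return Character string of length L.
#' @export
consensus_string <- function(pwm) {
  paste(DNA_BASES[max.col(pwm$matrix, ties.method = "first")], collapse = "")
}

#' Uniform background distribution over A, C, G, T
#' @return Named numeric vector summing to 1.
#' @export
uniform_background <- function() {
  stats::setNames(rep(0.25, 4L), DNA_BASES)
}

#' Motif information score in bits
#'
#' `I = sum_n (2 + sum_b W[n,b] log2 W[n,b])`, with `0 log 0 = 0`; ranges
#' from 0 (all positions uniform) to 2L (deterministic PWM). Computed on the
#' raw probabilities (no pseudocount).
#'
#' @param pwm A `pwm` object.
#' @return Information content in bits.
#' @export
information_score <- function(pwm) {
  W <- pwm$matrix
  plogp <- ifelse(W > 0, W * log2(W), 0)
  sum(2 + rowSums(plogp))
}

#' Select the most informative PWM as a cluster representative
#'
#' @param pwms Non-empty list of `pwm` objects (one similarity cluster).
#' @return The `pwm` with the highest [information_score()]; ties broken by
#'   name, lexicographically.
#' @export
select_representative <- function(pwms) {
  if (!length(pwms)) stop("empty motif cluster")
  info <- vapply(pwms, information_score, numeric(1))
  nms <- vapply(pwms, function(p) p$name, character(1))
  best <- which(info == max(info))
  pwms[[best[order(nms[best])][1L]]]
}

#' Pick one representative per motif cluster
#'
#' @param pwms Named or unnamed list of `pwm` objects.
#' @param clusters Data frame with columns `cluster` and `motif` (e.g. from
#'   a two-column TSV read with [read_motif_clusters()]).
#' @return Named list of representative `pwm`s, one per cluster.
#' @export
cluster_representatives <- function(pwms, clusters) {
  stopifnot(all(c("cluster", "motif") %in% names(clusters)))
  nms <- vapply(pwms, function(p) p$name, character(1))
  lapply(split(clusters$motif, clusters$cluster), function(members) {
    hit <- nms %in% members
    if (!any(hit)) stop("cluster members not found among supplied PWMs")
    select_representative(pwms[hit])
  })
}

#' @rdname cluster_representatives
#' @param path Two-column TSV `cluster<TAB>motif`, no header.
#' @export
read_motif_clusters <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  stats::setNames(x[, 1:2], c("cluster", "motif"))
}

#' Read motifs in MEME minimal format
#'
#' Parses the `MOTIF` / `letter-probability matrix:` blocks of a MEME
#' minimal file (the format JASPAR motifs are distributed in with the MEME
#' suite). Only the ACGT alphabet is supported.
#'
#' @param path Path to the MEME file.
#' @return List of `pwm` objects; the file's background letter frequencies,
#'   when present, are attached as attribute `"background"`.
#' @export
read_meme <- function(path) {
  lines <- readLines(path, warn = FALSE)
  bg <- NULL
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(trimws(lines[bg_at[1L] + 1L]), "\\s+")[[1L]]
    vals <- suppressWarnings(as.numeric(toks))
    bases <- toks[is.na(vals)]
    bg <- stats::setNames(vals[!is.na(vals)], bases)[DNA_BASES]
  }
  starts <- grep("^MOTIF\\s", lines)
  if (!length(starts)) stop("no MOTIF blocks found in ", path)
  pwms <- lapply(starts, function(s) {
    name <- strsplit(trimws(sub("^MOTIF\\s+", "", lines[s])), "\\s+")[[1L]][1L]
    hdr <- s + grep("^letter-probability matrix:",
                    lines[(s + 1L):length(lines)])[1L]
    if (is.na(hdr)) stop("motif ", name, ": no letter-probability matrix")
    w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1L):(hdr + w)]
    W <- do.call(rbind, lapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1L]][1:4])))
    # tolerate the small rounding slack typical of published matrices
    W <- W / rowSums(W)
    make_pwm(name, W)
  })
  names(pwms) <- vapply(pwms, function(p) p$name, character(1))
  if (!is.null(bg)) attr(pwms, "background") <- bg
  pwms
}

#' Write motifs in MEME minimal format
#'
#' @param pwms List of `pwm` objects.
#' @param path Output path.
#' @param background Background probabilities (default uniform).
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwms, path, background = uniform_background()) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "", "Background letter frequencies",
               paste(DNA_BASES, sprintf("%.5f", background),
                     collapse = " "), ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$name), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      nrow(p$matrix)), con)
    writeLines(apply(p$matrix, 1L, function(r)
      paste(sprintf("%.6f", r), collapse = "  ")), con)
    writeLines("", con)
  }
  invisible(path)
}

# log2 likelihood-ratio score matrix; a small pseudocount keeps zero
# entries finite (the raw matrix is used for information_score only)
pwm_llr_matrix <- function(pwm, background = uniform_background(),
                           pseudocount = 1e-4) {
  W <- (pwm$matrix + pseudocount)
  W <- W / rowSums(W)
  log2(sweep(W, 2L, background, "/"))
}

# A/C/G/T -> 1..4, anything else NA
seq_codes <- function(s) {
  if (length(s) == 1L && nchar(s[1L]) > 1L) s <- strsplit(s, "")[[1L]]
  match(toupper(s), DNA_BASES)
}

# scores of all windows of length L = nrow(M); NA where a window contains
# an ambiguous base
window_scores <- function(codes, M) {
  L <- nrow(M)
  nw <- length(codes) - L + 1L
  if (nw < 1L) return(numeric(0))
  sc <- M[1L, ][codes[seq_len(nw)]]
  if (L > 1L) for (n in 2L:L)
    sc <- sc + M[n, ][codes[n:(nw + n - 1L)]]
  sc
}

# reverse-complement view of a score matrix (scan + strand of the sequence
# with this matrix == scan - strand with the original)
revcomp_matrix <- function(M) M[rev(seq_len(nrow(M))), 4:1, drop = FALSE]

#' Log-likelihood-ratio score of a sequence window under a PWM
#'
#' `LLR = sum_n log2(W[n, S_n] / B[S_n])` for a window S of the PWM's
#' length. Zero PWM entries are floored via a pseudocount (default 1e-4,
#' rows renormalized) so the score is always finite.
#'
#' @param window Character string (or character vector of single bases) of
#'   the PWM's length, over A/C/G/T.
#' @param pwm A `pwm` object.
#' @param background Background base probabilities (default uniform 0.25).
#' @param pseudocount PWM pseudocount (default 1e-4).
#' @return Score in bits (log2 units); `NA` with a warning if the window
#'   contains an ambiguous base.
#' @export
llr_score <- function(window, pwm, background = uniform_background(),
                      pseudocount = 1e-4) {
  codes <- seq_codes(window)
  L <- nrow(pwm$matrix)
  if (length(codes) != L)
    stop("window length ", length(codes), " != motif length ", L)
  if (anyNA(codes)) {
    warning("window contains ambiguous base; skipped")
    return(NA_real_)
  }
  M <- pwm_llr_matrix(pwm, background, pseudocount)
  sum(M[cbind(seq_len(L), codes)])
}

#' Maximum-window motif score of a peak sequence
#'
#' The motif score of a peak is the maximum LLR over all windows of the
#' sequence, on both strands.
#'
#' @param sequence Character string or [Biostrings::DNAString].
#' @inheritParams llr_score
#' @return Maximum score in bits; `NA` with a warning when the sequence is
#'   shorter than the motif or contains no unambiguous window.
#' @export
peak_motif_score <- function(sequence, pwm,
                             background = uniform_background(),
                             pseudocount = 1e-4) {
  codes <- seq_codes(as.character(sequence))
  L <- nrow(pwm$matrix)
  if (length(codes) < L) {
    warning("sequence shorter than motif; peak excluded")
    return(NA_real_)
  }
  M <- pwm_llr_matrix(pwm, background, pseudocount)
  sc <- c(window_scores(codes, M), window_scores(codes, revcomp_matrix(M)))
  if (all(is.na(sc))) {
    warning("no unambiguous window in sequence")
    return(NA_real_)
  }
  max(sc, na.rm = TRUE)
}

#' Exact (discretized) distribution of window LLR scores under background
#'
#' Position-wise dynamic-programming convolution of the per-position score
#' contributions, discretized onto `bins` equal-width score bins. The
#' survival function gives FIMO-style p-values `P(score >= s)` for windows
#' drawn from the background model.
#'
#' @inheritParams llr_score
#' @param bins Number of discretization bins (default 1000).
#' @return A `score_distribution` object: support `scores`, probabilities
#'   `pmf`, survival function values `sf`, bin width `delta`, and the
#'   integer score matrix used for exact lookups during scanning.
#' @export
score_distribution <- function(pwm, background = uniform_background(),
                               bins = 1000L, pseudocount = 1e-4) {
  stopifnot(bins >= 1L)
  M <- pwm_llr_matrix(pwm, background, pseudocount)
  L <- nrow(M)
  lo <- sum(apply(M, 1L, min)); hi <- sum(apply(M, 1L, max))
  delta <- if (hi > lo) (hi - lo) / bins else 1
  qm <- round(M / delta)
  kmin <- sum(apply(qm, 1L, min)); kmax <- sum(apply(qm, 1L, max))
  pmf <- numeric(kmax - kmin + 1L)   # index k - kmin + 1
  # DP over positions
  cur <- 1; cmin <- 0L
  for (n in seq_len(L)) {
    qs <- qm[n, ]
    nmin <- cmin + min(qs); nmax <- cmin + length(cur) - 1L + max(qs)
    nxt <- numeric(nmax - nmin + 1L)
    for (b in 1:4) {
      at <- (cmin + qs[b] - nmin + 1L):(cmin + qs[b] - nmin + length(cur))
      nxt[at] <- nxt[at] + cur * background[b]
    }
    cur <- nxt; cmin <- nmin
  }
  pmf[(cmin - kmin + 1L):(cmin - kmin + length(cur))] <- cur
  sf <- rev(cumsum(rev(pmf)))
  structure(list(delta = delta, qmatrix = qm, kmin = kmin,
                 scores = (kmin:kmax) * delta, pmf = pmf, sf = sf),
            class = "score_distribution")
}

#' P-value of a score under a score distribution
#'
#' @param dist A [score_distribution()].
#' @param score Numeric score(s) in bits, or integer score(s) on the
#'   distribution's grid when `integer = TRUE`.
#' @param integer Interpret `score` as grid units.
#' @return `P(window score >= score)` under the background model.
#' @export
score_pvalue <- function(dist, score, integer = FALSE) {
  k <- if (integer) score else round(score / dist$delta)
  idx <- pmin(pmax(k - dist$kmin + 1L, 1L), length(dist$sf))
  out <- dist$sf[idx]
  out[k > dist$kmin + length(dist$sf) - 1L] <- 0
  out
}

#' Smallest score whose background p-value is at most `p`
#'
#' @param dist A [score_distribution()].
#' @param p Target p-value (default 1e-4, the FIMO default threshold).
#' @return Score in bits, or `Inf` when no score attains `p`.
#' @export
score_threshold <- function(dist, p = 1e-4) {
  i <- which(dist$sf <= p)
  if (!length(i)) return(Inf)
  dist$scores[min(i)]
}

region_sequences <- function(genome, regions) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  stopifnot(methods::is(genome, "DNAStringSet"))
  names(genome) <- sub("\\s.*", "", names(genome))
  chrlen <- stats::setNames(Biostrings::width(genome), names(genome))
  missing <- setdiff(unique(regions$chrom), names(genome))
  if (length(missing))
    stop("chromosome(s) absent from genome: ", paste(missing, collapse = ", "))
  end <- pmin(regions$end, chrlen[regions$chrom])
  if (any(end < regions$end))
    warning("region(s) beyond chromosome end clipped")
  lapply(seq_len(nrow(regions)), function(i)
    as.character(Biostrings::subseq(genome[[regions$chrom[i]]],
                                    start = regions$start[i] + 1L,
                                    end = end[i])))
}

#' Scan network regions for motif occurrences
#'
#' Reports every window (both strands) whose score p-value under the
#' background [score_distribution()] is at most `p_threshold` (FIMO default
#' 1e-4).
#'
#' @param genome A [Biostrings::DNAStringSet] or FASTA path.
#' @param network An `interaction_network` (its regions are scanned).
#' @param pwm A `pwm` object.
#' @param p_threshold Hit p-value threshold (default 1e-4).
#' @inheritParams llr_score
#' @param bins Discretization bins for the score distribution.
#' @return Data frame of hits: `motif`, `region` (region id), `offset`
#'   (0-based, on the + strand of the region), `strand`, `llr`, `pvalue`.
#' @export
scan_regions <- function(genome, network, pwm, p_threshold = 1e-4,
                         background = uniform_background(),
                         pseudocount = 1e-4, bins = 1000L) {
  dist <- score_distribution(pwm, background, bins, pseudocount)
  M <- pwm_llr_matrix(pwm, background, pseudocount)
  Mrc <- revcomp_matrix(M)
  qrc <- revcomp_matrix(dist$qmatrix)
  seqs <- region_sequences(genome, network$regions)
  hits <- lapply(seq_along(seqs), function(i) {
    codes <- seq_codes(seqs[[i]])
    if (length(codes) < nrow(M)) return(NULL)
    out <- lapply(c("+", "-"), function(strand) {
      mm <- if (strand == "+") M else Mrc
      qq <- if (strand == "+") dist$qmatrix else qrc
      ints <- window_scores(codes, qq)
      pv <- score_pvalue(dist, ints, integer = TRUE)
      keep <- which(!is.na(ints) & pv <= p_threshold)
      if (!length(keep)) return(NULL)
      sc <- window_scores(codes, mm)
      data.frame(motif = pwm$name, region = network$regions$id[i],
                 offset = keep - 1L, strand = strand, llr = sc[keep],
                 pvalue = pv[keep], stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits))
    hits <- data.frame(motif = character(), region = integer(),
                       offset = integer(), strand = character(),
                       llr = numeric(), pvalue = numeric(),
                       stringsAsFactors = FALSE)
  rownames(hits) <- NULL
  hits
}

#' Binding map from motif hits
#'
#' Links each motif (treated as a factor) to every network region holding at
#' least one hit.
#'
#' @param hits Hit data frame with columns `motif` and `region` (from
#'   [scan_regions()] or [read_fimo()] + region mapping).
#' @param network The companion `interaction_network`.
#' @return A `binding_map` whose factors are the motif names.
#' @export
motif_binding_map <- function(hits, network) {
  stopifnot(all(c("motif", "region") %in% names(hits)))
  bound <- lapply(split(hits$region, hits$motif), unique)
  new_binding_map(bound, nrow(network$regions))
}

#' Read FIMO TSV output
#'
#' Accepts the standard FIMO TSV (columns `motif_id`, `sequence_name`,
#' `start`, `stop`, `strand`, `score`, `p-value`; 1-based inclusive
#' coordinates) and returns genome-interval hits; map them onto a network
#' with [fimo_binding_map()].
#'
#' @param path Path to `fimo.tsv`.
#' @return Data frame `motif`, `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `score`, `pvalue`.
#' @export
read_fimo <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         comment.char = "#", check.names = FALSE,
                         stringsAsFactors = FALSE)
  need <- c("motif_id", "sequence_name", "start", "stop", "strand", "score",
            "p-value")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("FIMO TSV missing column(s): ",
                         paste(miss, collapse = ", "))
  data.frame(motif = x$motif_id, chrom = x$sequence_name,
             start = x$start - 1L, end = x$stop, strand = x$strand,
             score = x$score, pvalue = x[["p-value"]],
             stringsAsFactors = FALSE)
}

#' @rdname read_fimo
#' @param fimo Data frame from `read_fimo`.
#' @param network An `interaction_network`.
#' @export
fimo_binding_map <- function(fimo, network) {
  hits <- GenomicRanges::findOverlaps(as_granges0(fimo),
                                      as_granges0(network$regions))
  df <- data.frame(motif = fimo$motif[S4Vectors::queryHits(hits)],
                   region = S4Vectors::subjectHits(hits))
  motif_binding_map(df, network)
}

#' Score peaks by their maximum-window motif score
#'
#' @param genome A [Biostrings::DNAStringSet] or FASTA path.
#' @param peaks Data frame `chrom`, `start`, `end`, and optionally `factor`.
#' @param pwm A `pwm` object.
#' @inheritParams llr_score
#' @return `peaks` with a `score` column (max-window LLR in bits; `NA` for
#'   peaks shorter than the motif).
#' @export
score_peaks <- function(genome, peaks, pwm,
                        background = uniform_background(),
                        pseudocount = 1e-4) {
  M <- pwm_llr_matrix(pwm, background, pseudocount)
  Mrc <- revcomp_matrix(M)
  seqs <- region_sequences(genome, peaks)
  peaks$score <- vapply(seqs, function(s) {
    codes <- seq_codes(s)
    if (length(codes) < nrow(M)) return(NA_real_)
    sc <- c(window_scores(codes, M), window_scores(codes, Mrc))
    if (all(is.na(sc))) NA_real_ else max(sc, na.rm = TRUE)
  }, numeric(1))
  if (is.null(peaks$factor)) peaks$factor <- pwm$name
  peaks
}

assign_peaks_to_regions <- function(peaks, network) {
  GenomicRanges::findOverlaps(as_granges0(peaks),
                              as_granges0(network$regions),
                              select = "first")
}

#' Strong-motif fraction in isolated versus interacting peaks
#'
#' A peak is "strong" when its motif score reaches its factor's
#' `strong_quantile` score quantile (default top 10%, ties included);
#' "isolated" when it overlaps no network region or a region of degree 0.
#' Reports the fraction of strong peaks in each group, per factor.
#'
#' @param peak_scores Data frame with columns `factor`, `score` and either
#'   `region` (network region id, `NA` when unassigned) or `chrom`, `start`,
#'   `end` for on-the-fly assignment.
#' @param network An `interaction_network`.
#' @param strong_quantile Quantile defining "strong" (default 0.90).
#' @return Data frame per factor: `n_isolated`, `n_interacting`,
#'   `frac_strong_isolated`, `frac_strong_interacting` (NA when a group is
#'   empty). Factors with fewer than 10 scored peaks are flagged with a
#'   warning.
#' @export
strong_motif_partition <- function(peak_scores, network,
                                   strong_quantile = 0.90) {
  ps <- peak_scores[!is.na(peak_scores$score), , drop = FALSE]
  if (is.null(ps$region))
    ps$region <- assign_peaks_to_regions(ps, network)
  deg <- network$regions$degree
  isolated <- is.na(ps$region) | deg[ps$region] == 0L
  few <- names(which(table(ps$factor) < 10L))
  if (length(few))
    warning("factor(s) with < 10 scored peaks, quantile unstable: ",
            paste(few, collapse = ", "))
  res <- lapply(split(seq_len(nrow(ps)), ps$factor), function(ii) {
    thr <- stats::quantile(ps$score[ii], strong_quantile, names = FALSE)
    strong <- ps$score[ii] >= thr
    iso <- isolated[ii]
    data.frame(n_isolated = sum(iso), n_interacting = sum(!iso),
               frac_strong_isolated =
                 if (any(iso)) mean(strong[iso]) else NA_real_,
               frac_strong_interacting =
                 if (any(!iso)) mean(strong[!iso]) else NA_real_)
  })
  out <- do.call(rbind, res)
  out <- cbind(data.frame(factor = names(res), stringsAsFactors = FALSE),
               out)
  rownames(out) <- NULL
  out
}

#' Strong-motif fractions split by same-factor binding on neighbours
#'
#' Refines the interacting group of [strong_motif_partition()]: peaks in
#' interacting regions are split by whether at least one spatially
#' interacting neighbour region is bound by the same factor.
#'
#' @inheritParams strong_motif_partition
#' @param binding A `binding_map` giving each factor's bound regions.
#' @return Data frame per factor: `frac_strong_same_tf`,
#'   `frac_strong_other` with the corresponding peak counts.
#' @export
same_tf_refinement <- function(peak_scores, network, binding,
                               strong_quantile = 0.90) {
  ps <- peak_scores[!is.na(peak_scores$score), , drop = FALSE]
  if (is.null(ps$region))
    ps$region <- assign_peaks_to_regions(ps, network)
  deg <- network$regions$degree
  e <- network$edges
  nbrs <- vector("list", nrow(network$regions))
  if (nrow(e)) {
    nb <- split(c(e[, 2L], e[, 1L]), c(e[, 1L], e[, 2L]))
    nbrs[as.integer(names(nb))] <- nb
  }
  res <- lapply(split(seq_len(nrow(ps)), ps$factor), function(ii) {
    f <- ps$factor[ii[1L]]
    bound_f <- logical(nrow(network$regions))
    if (f %in% binding$factors) bound_f[binding$bound[[f]]] <- TRUE
    thr <- stats::quantile(ps$score[ii], strong_quantile, names = FALSE)
    strong <- ps$score[ii] >= thr
    interacting <- !is.na(ps$region[ii]) & deg[ps$region[ii]] > 0L
    same <- vapply(ps$region[ii], function(r) {
      if (is.na(r) || !length(nbrs[[r]])) return(FALSE)
      any(bound_f[nbrs[[r]]])
    }, logical(1))
    grp_same <- interacting & same
    grp_other <- interacting & !same
    data.frame(
      n_same_tf = sum(grp_same), n_other = sum(grp_other),
      frac_strong_same_tf =
        if (any(grp_same)) mean(strong[grp_same]) else NA_real_,
      frac_strong_other =
        if (any(grp_other)) mean(strong[grp_other]) else NA_real_)
  })
  out <- do.call(rbind, res)
  out <- cbind(data.frame(factor = names(res), stringsAsFactors = FALSE),
               out)
  rownames(out) <- NULL
  out
}
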