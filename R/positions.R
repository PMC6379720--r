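# Positional analysis: where focal codon pairs occur within ORFs, how their
# conserved occurrences are distributed along the coding sequence, and
# whether a focal set is enriched among model outliers.

#' Collect occurrences of focal codon pairs
#'
#' Scans each alignment's reference for occurrences of the focal pairs and
#' records the 1-based start codon index, the reference ORF length, the
#' relative position (start / length, in (0, 1]) and whether the occurrence
#' is conserved (both codon columns conserved across all species, with no
#' insertion column between them).
#'
#' @param alignments List of `codon_alignment` objects.
#' @param focal_pairs Character vector of `"XXX-YYY"` pair ids.
#' @param conserved_only Keep only conserved occurrences (default `FALSE`).
#' @return Data frame `orf_id`, `pair`, `start_codon_index`,
#'   `orf_length_codons`, `relative_position`, `conserved`.
#' @export
collect_occurrences <- function(alignments, focal_pairs,
                                conserved_only = FALSE) {
  focal_pairs <- normalize_pair(focal_pairs)
  rows <- lapply(alignments, function(aln) {
    core <- aln_core(aln)
    n <- length(core$ref_codons)
    if (n < 2L) return(NULL)
    i <- seq_len(n - 1L)
    pid <- paste(core$ref_codons[i], core$ref_codons[i + 1L], sep = "-")
    hit <- pid %in% focal_pairs
    if (!any(hit)) return(NULL)
    pcons <- core$conserved[i] & core$conserved[i + 1L] & core$adjacent
    data.frame(orf_id = core$orf_id, pair = pid[hit],
               start_codon_index = i[hit], orf_length_codons = n,
               relative_position = i[hit] / n,
               conserved = pcons[hit], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(orf_id = character(0), pair = character(0),
                      start_codon_index = integer(0),
                      orf_length_codons = integer(0),
                      relative_position = numeric(0),
                      conserved = logical(0), stringsAsFactors = FALSE)
  }
  if (conserved_only) out <- out[out$conserved, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Positional null distribution from random codon-pair sets
#'
#' Draws `n_sets` random sets of `set_size` codon pairs (uniformly, without
#' replacement within a set, from `universe` minus `exclude`), pools the
#' (optionally conserved-only) occurrence positions of each set and takes
#' the set's median relative position. A sampled set with zero occurrences
#' is redrawn and the event counted. Deterministic for a fixed seed.
#'
#' @param occurrences Occurrence data frame from [collect_occurrences()]
#'   run over the pair universe of interest.
#' @param n_sets Number of random sets (e.g. 100).
#' @param set_size Pairs per set (e.g. 9).
#' @param seed Integer seed; required, no hidden RNG state.
#' @param universe Pair ids to draw from. Default: all pairs present in
#'   `occurrences`.
#' @param exclude Pair ids never drawn (e.g. the focal set).
#' @param conserved_only Use conserved occurrences only (default `TRUE`).
#' @return An object of class `simulation_summary`: `n_sets`, `set_size`,
#'   `seed`, `medians` (per-set median positions), `mean_of_medians`,
#'   `sd_of_medians`, `n_resampled`.
#' @export
simulate_random_sets <- function(occurrences, n_sets, set_size, seed,
                                 universe = NULL, exclude = character(0),
                                 conserved_only = TRUE) {
  stopifnot(n_sets >= 1L, set_size >= 1L, is.numeric(seed))
  occ <- occurrences
  if (conserved_only) occ <- occ[occ$conserved, , drop = FALSE]
  if (is.null(universe)) universe <- unique(occurrences$pair)
  universe <- setdiff(universe, exclude)
  if (length(universe) < set_size) {
    stop("pair universe (", length(universe),
         ") smaller than set_size (", set_size, ")")
  }
  pos_by_pair <- split(occ$relative_position, occ$pair)
  set.seed(as.integer(seed))
  medians <- numeric(n_sets)
  n_resampled <- 0L
  for (s in seq_len(n_sets)) {
    repeat {
      pairs <- sample(universe, set_size)
      pos <- unlist(pos_by_pair[pairs], use.names = FALSE)
      if (length(pos) > 0L) break
      n_resampled <- n_resampled + 1L
      if (n_resampled > 1000L * n_sets) {
        stop("could not draw a set with occurrences")
      }
    }
    medians[s] <- stats::median(pos)
  }
  if (n_resampled > 0L) {
    message("simulate_random_sets: redrew ", n_resampled,
            " empty set(s)")
  }
  structure(list(n_sets = n_sets, set_size = set_size,
                 seed = as.integer(seed), medians = medians,
                 mean_of_medians = mean(medians),
                 sd_of_medians = stats::sd(medians),
                 n_resampled = n_resampled),
            class = "simulation_summary")
}

#' @export
print.simulation_summary <- function(x, ...) {
  cat("Random-set position simulation: ", x$n_sets, " sets of ",
      x$set_size, " pairs; mean of medians ",
      signif(x$mean_of_medians, 4), " (sd ", signif(x$sd_of_medians, 4),
      ")\n", sep = "")
  invisible(x)
}

#' One-tailed Fisher enrichment test
#'
#' Exact hypergeometric tail probability for a 2x2 table, evaluated by
#' log-space summation of the hypergeometric terms. With
#' `alternative = "greater"` the p-value is `P(X >= in_set_hits)` where X is
#' the number of in-set items among the hits under random assortment — the
#' probability that at least this many focal pairs would land among the
#' outliers by chance.
#'
#' @param in_set_hits,in_set_misses Counts for the focal set (e.g. focal
#'   pairs that are / are not outliers).
#' @param out_set_hits,out_set_misses Counts for the complement.
#' @param alternative `"greater"` (enrichment, default) or `"less"`.
#' @return The p-value. An all-zero table yields 1 with a warning.
#' @examples
#' fisher_enrichment(9, 8, 31, 3673)  # ~1.7e-14
#' @export
fisher_enrichment <- function(in_set_hits, in_set_misses, out_set_hits,
                              out_set_misses,
                              alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  a <- in_set_hits; b <- in_set_misses
  c_ <- out_set_hits; d <- out_set_misses
  stopifnot(a >= 0, b >= 0, c_ >= 0, d >= 0)
  N <- a + b + c_ + d
  if (N == 0) {
    warning("all-zero table; p = 1")
    return(1)
  }
  n1 <- a + b        # size of the focal set (draws)
  K <- a + c_        # total hits
  lo <- max(0, n1 + K - N)
  hi <- min(n1, K)
  ks <- if (alternative == "greater") seq.int(a, hi) else seq.int(lo, a)
  lp <- lchoose(K, ks) + lchoose(N - K, n1 - ks) - lchoose(N, n1)
  m <- max(lp)
  min(1, exp(m + log(sum(exp(lp - m)))))
}

#' Summaries of relative positions of occurrences
#'
#' @param occurrences Data frame from [collect_occurrences()] or a numeric
#'   vector of relative positions.
#' @return List with `median`, `ecdf` (data frame of sorted unique
#'   `position` and cumulative `fraction`, right-continuous, ending at 1)
#'   and `first_third` (fraction of occurrences with position <= 1/3).
#' @export
positional_summary <- function(occurrences) {
  pos <- if (is.data.frame(occurrences)) {
    occurrences$relative_position
  } else {
    as.numeric(occurrences)
  }
  if (length(pos) == 0L) stop("no occurrences")
  sp <- sort(unique(pos))
  frac <- vapply(sp, function(q) mean(pos <= q), 0)
  list(median = stats::median(pos),
       ecdf = data.frame(position = sp, fraction = frac),
       first_third = mean(pos <= 1 / 3))
}
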