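# Gene-property comparisons between ORF sets defined by conserved focal
# pairs: two-sample Kolmogorov-Smirnov tests on numeric properties and a
# chi-squared test on categorical (polysome) composition.

#' Define ORF sets by conserved focal and control pairs
#'
#' An ORF joins the focal (or control) set when it contains at least one
#' occurrence of a focal (control) pair that is identical in sequence and
#' aligned location in at least `min_species` of the species present,
#' counting the reference itself; the occurrence's two codon columns must be
#' consecutive in the alignment. ORFs qualifying for both sets are assigned
#' to the focal set and reported in `overlap`; all remaining analyzed ORFs
#' form the third set.
#'
#' @param alignments List of `codon_alignment` objects.
#' @param focal_pairs,control_pairs Character vectors of `"XXX-YYY"` ids.
#' @param min_species Minimum number of species carrying the pair at the
#'   same aligned location (default 4, as in a five-species comparison
#'   requiring conservation in at least four).
#' @return List with `focal`, `control`, `other` (ORF id vectors that
#'   partition the analyzed ORFs), `overlap`, and `min_species`.
#' @export
define_orf_sets <- function(alignments, focal_pairs, control_pairs,
                            min_species = 4L) {
  focal_pairs <- normalize_pair(focal_pairs)
  control_pairs <- normalize_pair(control_pairs)
  in_focal <- in_control <- logical(length(alignments))
  orf_ids <- character(length(alignments))
  for (g in seq_along(alignments)) {
    aln <- alignments[[g]]
    if (min_species > nrow(aln$codons)) {
      stop("min_species (", min_species, ") exceeds species count (",
           nrow(aln$codons), ") in group ", aln$group_id)
    }
    core <- aln_core(aln)
    orf_ids[g] <- core$orf_id
    n <- length(core$ref_codons)
    if (n < 2L) next
    i <- seq_len(n - 1L)
    pid <- paste(core$ref_codons[i], core$ref_codons[i + 1L], sep = "-")
    hit <- which(pid %in% c(focal_pairs, control_pairs) & core$adjacent)
    if (length(hit) == 0L) next
    m <- aln$codons[, core$anchors, drop = FALSE]
    for (h in hit) {
      n_match <- sum(m[, h] == core$ref_codons[h] &
                       m[, h + 1L] == core$ref_codons[h + 1L])
      if (n_match >= min_species) {
        if (pid[h] %in% focal_pairs) in_focal[g] <- TRUE
        if (pid[h] %in% control_pairs) in_control[g] <- TRUE
      }
    }
  }
  overlap <- orf_ids[in_focal & in_control]
  list(focal = orf_ids[in_focal],
       control = orf_ids[in_control & !in_focal],
       other = orf_ids[!in_focal & !in_control],
       overlap = overlap, min_species = as.integer(min_species))
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Two-sided two-sample KS test of the null that two property distributions
#' are the same. The p-value is exact when `n * m <= 10^4` (and the data are
#' tie-free), asymptotic otherwise. Missing values are dropped.
#'
#' @param sample_a,sample_b Numeric vectors (size >= 1 after NA removal).
#' @param exact Force exact (`TRUE`) or asymptotic (`FALSE`); default
#'   chooses by sample size.
#' @return List with `statistic` (D), `p.value`, `n`, `m`.
#' @export
ks_compare <- function(sample_a, sample_b, exact = NULL) {
  a <- sample_a[!is.na(sample_a)]
  b <- sample_b[!is.na(sample_b)]
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  if (is.null(exact)) exact <- length(a) * length(b) <= 1e4
  res <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  list(statistic = unname(res$statistic), p.value = res$p.value,
       n = length(a), m = length(b))
}

#' Chi-squared test on set-by-category counts
#'
#' Pearson chi-squared test (no continuity correction) that ORF sets share
#' one category distribution, e.g. over the five polysome-association
#' categories. Rows or columns whose margin is zero are dropped with a
#' warning.
#'
#' @param counts Matrix of counts, sets in rows, categories in columns.
#' @return List with `statistic`, `df`, `p.value` and `expected`.
#' @export
chisq_categories <- function(counts) {
  counts <- as.matrix(counts)
  rz <- rowSums(counts) == 0
  cz <- colSums(counts) == 0
  if (any(rz) || any(cz)) {
    warning("dropping ", sum(rz), " zero row(s) and ", sum(cz),
            " zero column(s)")
    counts <- counts[!rz, !cz, drop = FALSE]
  }
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    stop("need at least 2 non-empty rows and columns")
  }
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p.value = res$p.value, expected = res$expected)
}

#' Property summaries and pairwise KS tests per ORF set
#'
#' For every numeric property, reports per-set n, median and mean, and the
#' pairwise two-sample KS p-values between the sets. ORFs missing from the
#' property table, and missing values, are excluded per test with counts in
#' the output.
#'
#' @param properties Data frame with an `orf_id` column and numeric property
#'   columns (non-numeric columns other than `orf_id` are ignored here; use
#'   [chisq_categories()] for categorical composition).
#' @param sets Named list of ORF id vectors (e.g. from [define_orf_sets()],
#'   pass `sets[c("focal","control","other")]`).
#' @return List with `summary` (property, set, n, n_missing, median, mean)
#'   and `ks` (property, set_a, set_b, D, p.value).
#' @export
summarize_sets <- function(properties, sets) {
  stopifnot(is.data.frame(properties), "orf_id" %in% names(properties),
            is.list(sets), !is.null(names(sets)))
  num_cols <- names(properties)[vapply(properties, is.numeric, TRUE)]
  values <- function(set_ids, prop) {
    v <- properties[[prop]][match(set_ids, properties$orf_id)]
    v
  }
  summ <- list(); ks <- list()
  for (prop in num_cols) {
    for (sname in names(sets)) {
      v <- values(sets[[sname]], prop)
      ok <- !is.na(v)
      summ[[length(summ) + 1L]] <- data.frame(
        property = prop, set = sname, n = sum(ok),
        n_missing = sum(!ok),
        median = if (any(ok)) stats::median(v[ok]) else NA_real_,
        mean = if (any(ok)) mean(v[ok]) else NA_real_,
        stringsAsFactors = FALSE)
    }
    sn <- names(sets)
    for (i in seq_len(length(sn) - 1L)) {
      for (j in seq.int(i + 1L, length(sn))) {
        va <- values(sets[[sn[i]]], prop); va <- va[!is.na(va)]
        vb <- values(sets[[sn[j]]], prop); vb <- vb[!is.na(vb)]
        row <- data.frame(property = prop, set_a = sn[i], set_b = sn[j],
                          D = NA_real_, p.value = NA_real_,
                          stringsAsFactors = FALSE)
        if (length(va) > 0L && length(vb) > 0L) {
          k <- ks_compare(va, vb)
          row$D <- k$statistic
          row$p.value <- k$p.value
        }
        ks[[length(ks) + 1L]] <- row
      }
    }
  }
  list(summary = do.call(rbind, summ), ks = do.call(rbind, ks))
}
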