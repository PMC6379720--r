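# Origin-constrained pair model: codon pair conservation rate (y) regressed
# on the product of the constituent codon conservation rates (x) with the
# intercept fixed at zero. Outliers are pairs whose residual exceeds k
# residual standard deviations; the positive direction means more conserved
# than the constituent codons predict.

#' Fit the origin-constrained line to pair vs codon-product conservation
#'
#' Least squares through the origin: slope = sum(x*y) / sum(x^2), with
#' x the product of the two constituent codon conservation rates and y the
#' pair conservation rate. Pairs with undefined rates (zero totals for the
#' pair or either codon) are excluded and counted.
#'
#' @param table A frame-0 `conservation_table`.
#' @param weighted Weight pairs by their reference occurrence totals
#'   (default `FALSE`, matching an unweighted fit).
#' @return An object of class `pair_fit`: `slope`, `residual_sigma` (sample
#'   standard deviation of residuals), `pairs` data frame (`pair`, `codon1`,
#'   `codon2`, `x`, `y`, `residual`, `deviation_sigma`), `n_excluded`.
#' @export
fit_origin_line <- function(table, weighted = FALSE) {
  stopifnot(inherits(table, "conservation_table"))
  crate <- stats::setNames(table$codons$rate, table$codons$codon)
  p <- table$pairs
  x <- unname(crate[p$codon1] * crate[p$codon2])
  y <- p$rate
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) stop("fewer than 2 pairs with defined rates")
  xs <- x[ok]; ys <- y[ok]
  w <- if (weighted) p$total[ok] else rep(1, sum(ok))
  if (all(xs == 0)) stop("degenerate design: all codon-product rates are zero")
  slope <- sum(w * xs * ys) / sum(w * xs^2)
  resid <- ys - slope * xs
  sigma <- stats::sd(resid)
  df <- data.frame(pair = p$pair[ok], codon1 = p$codon1[ok],
                   codon2 = p$codon2[ok], total = p$total[ok],
                   x = xs, y = ys, residual = resid,
                   deviation_sigma = if (sigma > 0) resid / sigma else
                     rep(0, length(resid)),
                   stringsAsFactors = FALSE)
  structure(list(slope = slope, residual_sigma = sigma, pairs = df,
                 n_excluded = sum(!ok), weighted = weighted,
                 reference = table$reference),
            class = "pair_fit")
}

#' @export
print.pair_fit <- function(x, ...) {
  cat("Origin-constrained pair fit: slope ", signif(x$slope, 4),
      ", residual sigma ", signif(x$residual_sigma, 4), ", ",
      nrow(x$pairs), " pairs (", x$n_excluded, " excluded)\n", sep = "")
  invisible(x)
}

#' Call sigma outliers of the pair fit
#'
#' @param fit A `pair_fit`.
#' @param k_sigma Threshold in residual standard deviations (default 3).
#' @return List with `above` (pairs with deviation > k) and `below`
#'   (deviation < -k), as character vectors of pair ids. With a degenerate
#'   fit (`residual_sigma == 0`) both sets are empty with a warning.
#' @export
call_outliers <- function(fit, k_sigma = 3) {
  stopifnot(inherits(fit, "pair_fit"))
  if (fit$residual_sigma == 0) {
    warning("residual sigma is zero; no outliers can be called")
    return(list(above = character(0), below = character(0)))
  }
  d <- fit$pairs$deviation_sigma
  list(above = fit$pairs$pair[d > k_sigma],
       below = fit$pairs$pair[d < -k_sigma])
}

#' Pseudocounted normalized conservation scores
#'
#' For each pair, `(pair_rate + p) / ((codon1_rate + p) * (codon2_rate + p))`
#' where `p` is a pseudocount. With `pseudocount = "auto"` the pseudocount is
#' the reciprocal of the total sense codon count in the reference coding
#' region — the smallest conservation-rate difference observable in the
#' alignments. With `p = 0`, pairs whose codon rates are zero are undefined.
#'
#' @param table A `conservation_table`.
#' @param pseudocount `"auto"` or a non-negative number.
#' @return An object of class `normalized_scores`: `pseudocount` and
#'   `scores`, a data frame (`pair`, `codon1`, `codon2`, `pair_rate`,
#'   `codon1_rate`, `codon2_rate`, `score`).
#' @export
normalized_scores <- function(table, pseudocount = "auto") {
  stopifnot(inherits(table, "conservation_table"))
  p <- if (identical(pseudocount, "auto")) {
    if (table$n_ref_codons == 0L) stop("empty table: cannot derive pseudocount")
    1 / table$n_ref_codons
  } else {
    stopifnot(is.numeric(pseudocount), pseudocount >= 0)
    as.numeric(pseudocount)
  }
  crate <- stats::setNames(table$codons$rate, table$codons$codon)
  pr <- table$pairs
  c1 <- unname(crate[pr$codon1])
  c2 <- unname(crate[pr$codon2])
  denom <- (c1 + p) * (c2 + p)
  score <- ifelse(!is.na(pr$rate) & !is.na(denom) & denom > 0,
                  (pr$rate + p) / denom, NA_real_)
  structure(list(pseudocount = p,
                 reference = table$reference,
                 frame_offset = table$frame_offset,
                 scores = data.frame(pair = pr$pair, codon1 = pr$codon1,
                                     codon2 = pr$codon2, pair_rate = pr$rate,
                                     codon1_rate = c1, codon2_rate = c2,
                                     score = score, stringsAsFactors = FALSE)),
            class = "normalized_scores")
}

# shared z-score machinery: log-transform scores, standardize within families
family_zscores <- function(pairs, scores, family) {
  ok <- !is.na(scores) & scores > 0
  X <- ifelse(ok, log(scores), NA_real_)
  mu <- stats::ave(X, family, FUN = function(v) mean(v, na.rm = TRUE))
  sg <- stats::ave(X, family, FUN = function(v) {
    if (sum(!is.na(v)) < 2L) 0 else stats::sd(v, na.rm = TRUE)
  })
  degenerate <- !is.na(X) & sg == 0
  z <- ifelse(is.na(X), NA_real_, ifelse(sg > 0, (X - mu) / sg, 0))
  data.frame(pair = pairs, dipeptide = family, X = X, mu = mu, sigma = sg,
             z = z, degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Dipeptide-family z-scores of normalized conservation scores
#'
#' Log-transforms the normalized conservation scores and standardizes them
#' within each dipeptide family (all sense pairs encoding the same ordered
#' amino acid pair under `code`): `z = (X - mu) / sigma` with the family
#' mean and sample standard deviation. Families with a single member or zero
#' spread (e.g. Met-Trp) get `z = 0` and are flagged `degenerate`. The log
#' base only rescales X and the family statistics jointly, so z is
#' base-invariant.
#'
#' @param scores A `normalized_scores` object (pseudocount applied, scores
#'   positive).
#' @param code A `genetic_code`.
#' @return An object of class `dipeptide_z` with a data frame `z_table`
#'   (`pair`, `dipeptide`, `X`, `mu`, `sigma`, `z`, `degenerate`).
#' @export
dipeptide_zscores <- function(scores, code) {
  stopifnot(inherits(scores, "normalized_scores"),
            inherits(code, "genetic_code"))
  s <- scores$scores
  fam <- paste0(code$codon_to_aa[s$codon1], code$codon_to_aa[s$codon2])
  structure(list(pseudocount = scores$pseudocount,
                 frame_offset = scores$frame_offset,
                 z_table = family_zscores(s$pair, s$score, fam)),
            class = "dipeptide_z")
}

#' Rank codon pairs within their dipeptide family
#'
#' Ranks each pair among the sense pairs encoding the same dipeptide, by raw
#' pair conservation rate or by normalized conservation score. Rank 1 is the
#' most conserved; ties share the smallest rank ("min" ranks, so a family
#' with values 0.9, 0.5, 0.5, 0.1 ranks 1, 2, 2, 4).
#'
#' @param x A `conservation_table` (for `by = "raw_rate"`) or a
#'   `normalized_scores` object (for `by = "normalized"`).
#' @param code A `genetic_code`.
#' @param by `"raw_rate"` or `"normalized"`.
#' @return Data frame `pair`, `dipeptide`, `value`, `rank` (NA for pairs
#'   with undefined values).
#' @export
rank_within_dipeptide <- function(x, code, by = c("raw_rate", "normalized")) {
  by <- match.arg(by)
  if (by == "raw_rate") {
    stopifnot(inherits(x, "conservation_table"))
    pairs <- x$pairs$pair
    value <- x$pairs$rate
    fam <- paste0(code$codon_to_aa[x$pairs$codon1],
                  code$codon_to_aa[x$pairs$codon2])
  } else {
    stopifnot(inherits(x, "normalized_scores"))
    pairs <- x$scores$pair
    value <- x$scores$score
    fam <- paste0(code$codon_to_aa[x$scores$codon1],
                  code$codon_to_aa[x$scores$codon2])
  }
  rk <- stats::ave(value, fam, FUN = function(v) {
    r <- rep(NA_integer_, length(v))
    ok <- !is.na(v)
    r[ok] <- rank(-v[ok], ties.method = "min")
    r
  })
  data.frame(pair = pairs, dipeptide = fam, value = value, rank = rk,
             stringsAsFactors = FALSE)
}

#' Consistency of outlier deviations across comparisons
#'
#' Collects each pair's signed deviation (in residual sigmas) from several
#' pairwise-comparison fits and flags pairs exceeding each threshold in
#' every comparison in which the pair has defined rates. Pairs missing from
#' any comparison are marked `incomplete`.
#'
#' @param fits Named list of `pair_fit` objects, one per comparison.
#' @param thresholds Numeric thresholds (default `c(2, 3)`).
#' @return Data frame with one row per pair: per-comparison deviation
#'   columns `sigma_<comparison>`, `incomplete`, and a logical
#'   `above_<k>sigma` column per threshold.
#' @export
cross_comparison_consistency <- function(fits, thresholds = c(2, 3)) {
  stopifnot(length(fits) >= 1L, !is.null(names(fits)))
  all_pairs <- sort(unique(unlist(lapply(fits, function(f) f$pairs$pair))))
  dev <- sapply(fits, function(f) {
    f$pairs$deviation_sigma[match(all_pairs, f$pairs$pair)]
  })
  dev <- matrix(dev, nrow = length(all_pairs),
                dimnames = list(NULL, names(fits)))
  out <- data.frame(pair = all_pairs, stringsAsFactors = FALSE)
  for (cmp in names(fits)) out[[paste0("sigma_", cmp)]] <- dev[, cmp]
  out$incomplete <- rowSums(is.na(dev)) > 0L
  for (k in thresholds) {
    flag <- apply(dev, 1L, function(v) {
      v <- v[!is.na(v)]
      length(v) > 0L && all(v > k)
    })
    out[[paste0("above_", gsub("\\.", "_", format(k)), "sigma")]] <- flag
  }
  out
}

#' Frame-shift control for focal codon pairs
#'
#' Tests whether the high relative conservation of focal pairs is a property
#' of the reading frame rather than of the underlying hexamer: for each
#' focal pair, the six-nucleotide sequence is scored as a shifted
#' tri-nucleotide unit pair in the +1 and +2 frame tables, with the
#' normalized score and a z-score within the family of unit pairs sharing
#' the same translated unit pair (stops translate to `*`). At frame 0 this
#' reduces to the dipeptide z-score of the pair itself.
#'
#' @param tables List of `conservation_table`s covering frame offsets 0, 1
#'   and 2 (matched by their `frame_offset` field).
#' @param focal_pairs Character vector of `"XXX-YYY"` pair ids.
#' @param code A `genetic_code` (families of the translated units).
#' @param pseudocount `"auto"` or a number, per table.
#' @return Data frame `pair`, `frame`, `score`, `z`, `absent`, `degenerate`.
#' @export
frame_shift_control <- function(tables, focal_pairs, code,
                                pseudocount = "auto") {
  focal_pairs <- normalize_pair(focal_pairs)
  offsets <- vapply(tables, function(t) t$frame_offset, 0L)
  if (!all(c(0L, 1L, 2L) %in% offsets)) {
    stop("tables for frame offsets 0, 1 and 2 are required; got ",
         paste(offsets, collapse = ", "))
  }
  out <- list()
  for (f in c(0L, 1L, 2L)) {
    tab <- tables[[which(offsets == f)[1L]]]
    ns <- normalized_scores(tab, pseudocount)
    s <- ns$scores
    fam <- paste0(code$codon_to_aa[s$codon1], code$codon_to_aa[s$codon2])
    zt <- family_zscores(s$pair, s$score, fam)
    idx <- match(focal_pairs, zt$pair)
    total <- tab$pairs$total[match(focal_pairs, tab$pairs$pair)]
    absent <- is.na(idx) | is.na(total) | total == 0L
    out[[length(out) + 1L]] <- data.frame(
      pair = focal_pairs, frame = f,
      score = ifelse(absent, NA_real_, s$score[idx]),
      z = ifelse(absent, NA_real_, zt$z[idx]),
      absent = absent,
      degenerate = ifelse(is.na(idx), NA, zt$degenerate[idx]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
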