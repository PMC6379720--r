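# Conservation counting. A reference codon is conserved when every species'
# entry in its alignment column is non-gap and string-identical to it. A
# reference codon pair (two consecutive reference codons) always counts
# toward the pair's total; it is conserved only when both member columns are
# conserved and the columns are consecutive in the alignment (an insertion
# column from any species between them breaks positional identity).

# per-alignment core: reference-anchored columns and conservation indicators
aln_core <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  ref <- aln$codons[aln$reference, ]
  anchors <- which(ref != GAP_CODON)
  ref_codons <- ref[anchors]
  m <- aln$codons[, anchors, drop = FALSE]
  cons <- colSums(m == matrix(ref_codons, nrow(m), length(anchors),
                              byrow = TRUE)) == nrow(m)
  list(ref_codons = ref_codons, conserved = unname(cons), anchors = anchors,
       adjacent = diff(anchors) == 1L,
       orf_id = ref_orf_id(aln), n_species = nrow(m))
}

ref_orf_id <- function(aln) {
  if (!is.null(aln$orf_ids) && aln$reference %in% names(aln$orf_ids)) {
    aln$orf_ids[[aln$reference]]
  } else {
    aln$group_id
  }
}

#' Is an alignment column conserved?
#'
#' A column is conserved when every species carries the reference codon
#' (non-gap and identical). The column must be reference-anchored.
#'
#' @param aln A `codon_alignment`.
#' @param column Column index (1-based).
#' @return List with `conserved` (logical) and `codon` (the reference codon).
#' @export
is_conserved_column <- function(aln, column) {
  stopifnot(inherits(aln, "codon_alignment"),
            column >= 1L, column <= aln$n_columns)
  ref <- aln$codons[aln$reference, column]
  if (ref == GAP_CODON) {
    stop("reference row is a gap at column ", column)
  }
  list(conserved = all(aln$codons[, column] == ref), codon = unname(ref))
}

new_conservation_table <- function(reference, species_set, frame_offset,
                                   codon_df, pair_df, n_ref_codons,
                                   n_stop_codons = 0L, n_stop_pairs = 0L) {
  structure(list(reference = reference, species_set = species_set,
                 frame_offset = frame_offset, codons = codon_df,
                 pairs = pair_df, n_ref_codons = n_ref_codons,
                 n_stop_codons = n_stop_codons, n_stop_pairs = n_stop_pairs),
            class = "conservation_table")
}

#' @export
print.conservation_table <- function(x, ...) {
  cat("Conservation table (frame ", x$frame_offset, ", reference ",
      x$reference, ")\n", sep = "")
  cat(" ", nrow(x$codons), " unit types over ", x$n_ref_codons,
      " reference units; ", nrow(x$pairs), " pair types\n", sep = "")
  invisible(x)
}

tabulate_units <- function(units, conserved, universe) {
  idx <- match(units, universe)
  keep <- !is.na(idx)
  total <- tabulate(idx[keep], nbins = length(universe))
  cons <- tabulate(idx[keep & conserved], nbins = length(universe))
  list(total = total, conserved = cons, n_dropped = sum(!keep))
}

#' Accumulate codon and codon-pair conservation (reading frame 0)
#'
#' Counts, over a collection of codon alignments sharing one reference
#' species, how many times each sense codon and each ordered adjacent sense
#' codon pair occurs in the reference and how many of those occurrences are
#' conserved across all species of their alignment. Rates are
#' conserved/total, reported as `NA` (undefined) when the total is zero.
#' Codons and pairs involving stop codons are excluded.
#'
#' @param alignments List of `codon_alignment` objects with a common
#'   reference species.
#' @param code A `genetic_code` (defines the 61 sense codons / 3721 pairs).
#' @return A `conservation_table` with data frames `codons`
#'   (codon, total, conserved, rate) and `pairs`
#'   (codon1, codon2, pair, total, conserved, rate), plus `n_ref_codons`,
#'   the total sense codon count in the reference (the "auto" pseudocount
#'   denominator).
#' @export
accumulate_conservation <- function(alignments, code) {
  stopifnot(length(alignments) >= 1L, inherits(code, "genetic_code"))
  refs <- unique(vapply(alignments, function(a) a$reference, ""))
  if (length(refs) != 1L) {
    stop("alignments have mixed reference species: ",
         paste(refs, collapse = ", "))
  }
  sc <- sense_codons(code)
  cod_u <- cod_c <- integer(length(sc))
  pair_u <- pair_c <- integer(length(sc)^2)
  species <- character(0)
  n_stop_codons <- 0L
  n_stop_pairs <- 0L
  for (aln in alignments) {
    core <- aln_core(aln)
    species <- union(species, rownames(aln$codons))
    rc <- core$ref_codons
    n <- length(rc)
    if (n == 0L) next
    sense <- rc %in% sc
    n_stop_codons <- n_stop_codons + sum(!sense)
    ci <- match(rc[sense], sc)
    cod_u <- cod_u + tabulate(ci, nbins = length(sc))
    cod_c <- cod_c + tabulate(ci[core$conserved[sense]], nbins = length(sc))
    if (n >= 2L) {
      i <- seq_len(n - 1L)
      psense <- sense[i] & sense[i + 1L]
      n_stop_pairs <- n_stop_pairs + sum(!psense)
      pcons <- core$conserved[i] & core$conserved[i + 1L] & core$adjacent
      pidx <- (match(rc[i], sc) - 1L) * length(sc) + match(rc[i + 1L], sc)
      pidx <- pidx[psense]
      pcons <- pcons[psense]
      pair_u <- pair_u + tabulate(pidx, nbins = length(pair_u))
      pair_c <- pair_c + tabulate(pidx[pcons], nbins = length(pair_u))
    }
  }
  codon_df <- data.frame(codon = sc, total = cod_u, conserved = cod_c,
                         rate = ifelse(cod_u > 0L, cod_c / cod_u, NA_real_),
                         stringsAsFactors = FALSE)
  c1 <- rep(sc, each = length(sc))
  c2 <- rep(sc, times = length(sc))
  pair_df <- data.frame(codon1 = c1, codon2 = c2,
                        pair = paste(c1, c2, sep = "-"),
                        total = pair_u, conserved = pair_c,
                        rate = ifelse(pair_u > 0L, pair_c / pair_u, NA_real_),
                        stringsAsFactors = FALSE)
  new_conservation_table(refs, sort(species), 0L, codon_df, pair_df,
                         n_ref_codons = sum(cod_u),
                         n_stop_codons = n_stop_codons,
                         n_stop_pairs = n_stop_pairs)
}

# per-alignment nucleotide-level conservation, used by the frame-shift
# control: for each reference nucleotide, whether all species carry the
# identical base in a non-gap column.
aln_nt_core <- function(aln) {
  ref <- aln$codons[aln$reference, ]
  anchors <- which(ref != GAP_CODON)
  n <- length(anchors)
  if (n == 0L) {
    return(list(nt = character(0), cons = logical(0), col = integer(0),
                aidx = integer(0)))
  }
  m <- aln$codons[, anchors, drop = FALSE]
  # species x (3n) character matrix of bases ("-" within gap codons)
  chm <- do.call(rbind, lapply(seq_len(nrow(m)), function(r) {
    strsplit(paste(m[r, ], collapse = ""), "")[[1L]]
  }))
  refnt <- chm[match(aln$reference, rownames(m)), ]
  cons <- colSums(chm == matrix(refnt, nrow(chm), ncol(chm), byrow = TRUE)) ==
    nrow(chm)
  list(nt = refnt, cons = unname(cons),
       col = rep(anchors, each = 3L), aidx = rep(seq_len(n), each = 3L),
       orf_id = ref_orf_id(aln))
}

#' Conservation of frame-shifted tri-nucleotide units
#'
#' Re-tokenizes each alignment's reference nucleotide sequence into
#' tri-nucleotide units starting at an offset of +1 or +2 from the reading
#' frame, and counts unit and adjacent-unit-pair conservation. A unit is
#' conserved when its three nucleotide positions sit in alignment columns
#' that are non-gap and identical across all species, with no insertion
#' column interrupting it; unit pairs additionally require the whole
#' six-nucleotide span to be uninterrupted. All 64 unit types can occur,
#' since frame-shifted units are not codons and stops are not excluded.
#'
#' @param alignments List of `codon_alignment` objects sharing a reference.
#' @param offset 1 or 2.
#' @return A `conservation_table` with `frame_offset` set to `offset`; the
#'   `codons` data frame holds the 64 unit types and `pairs` the 4096 unit
#'   pairs.
#' @export
shifted_frame_conservation <- function(alignments, offset) {
  stopifnot(length(alignments) >= 1L, offset %in% c(1L, 2L))
  refs <- unique(vapply(alignments, function(a) a$reference, ""))
  if (length(refs) != 1L) {
    stop("alignments have mixed reference species: ",
         paste(refs, collapse = ", "))
  }
  bases <- c("A", "C", "G", "T")
  units <- as.vector(outer(bases, outer(bases, bases, paste0),
                           paste0))
  units <- sort(units)
  unit_u <- unit_c <- integer(64L)
  pair_u <- pair_c <- integer(64L^2)
  species <- character(0)
  for (aln in alignments) {
    species <- union(species, rownames(aln$codons))
    core <- aln_nt_core(aln)
    nnt <- length(core$nt)
    if (nnt < offset + 3L) next
    s <- seq.int(offset + 1L, nnt - 2L, by = 3L)
    u <- paste0(core$nt[s], core$nt[s + 1L], core$nt[s + 2L])
    ucons <- core$cons[s] & core$cons[s + 1L] & core$cons[s + 2L] &
      (core$col[s + 2L] - core$col[s]) == (core$aidx[s + 2L] - core$aidx[s])
    ui <- match(u, units)
    unit_u <- unit_u + tabulate(ui, nbins = 64L)
    unit_c <- unit_c + tabulate(ui[ucons], nbins = 64L)
    nu <- length(s)
    if (nu >= 2L) {
      i <- seq_len(nu - 1L)
      span_ok <- (core$col[s[i] + 5L] - core$col[s[i]]) ==
        (core$aidx[s[i] + 5L] - core$aidx[s[i]])
      pcons <- ucons[i] & ucons[i + 1L] & span_ok
      pidx <- (ui[i] - 1L) * 64L + ui[i + 1L]
      pair_u <- pair_u + tabulate(pidx, nbins = length(pair_u))
      pair_c <- pair_c + tabulate(pidx[pcons], nbins = length(pair_u))
    }
  }
  codon_df <- data.frame(codon = units, total = unit_u, conserved = unit_c,
                         rate = ifelse(unit_u > 0L, unit_c / unit_u, NA_real_),
                         stringsAsFactors = FALSE)
  c1 <- rep(units, each = 64L)
  c2 <- rep(units, times = 64L)
  pair_df <- data.frame(codon1 = c1, codon2 = c2,
                        pair = paste(c1, c2, sep = "-"),
                        total = pair_u, conserved = pair_c,
                        rate = ifelse(pair_u > 0L, pair_c / pair_u, NA_real_),
                        stringsAsFactors = FALSE)
  new_conservation_table(refs, sort(species), as.integer(offset), codon_df,
                         pair_df, n_ref_codons = sum(unit_u))
}

#' Per-ORF codon conservation rates
#'
#' For each alignment, the fraction of reference codons conserved across all
#' species: conserved codon count over reference ORF length in codons.
#'
#' @param alignments List of `codon_alignment` objects.
#' @return Data frame with `orf_id`, `length_codons`, `conserved_codons`,
#'   `rate`. Zero-length ORFs are excluded with a warning. The median and
#'   mean rate are attached as attributes `median_rate` and `mean_rate`.
#' @export
orf_conservation_rates <- function(alignments) {
  rows <- lapply(alignments, function(aln) {
    core <- aln_core(aln)
    data.frame(orf_id = core$orf_id,
               length_codons = length(core$ref_codons),
               conserved_codons = sum(core$conserved),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  zero <- df$length_codons == 0L
  if (any(zero)) {
    warning("excluding ", sum(zero), " zero-length ORF(s)")
    df <- df[!zero, , drop = FALSE]
  }
  df$rate <- df$conserved_codons / df$length_codons
  attr(df, "median_rate") <- stats::median(df$rate)
  attr(df, "mean_rate") <- mean(df$rate)
  df
}

#' Windowed local conservation profile
#'
#' Sliding-window mean of the per-codon conserved indicator along the
#' reference of one alignment. Window `w` at position `i` covers reference
#' codons `i .. min(i + w - 1, L)` (truncated at the ORF end); when the
#' window is at least the ORF length a single full-ORF value (the per-ORF
#' conservation rate) is returned.
#'
#' @param aln A `codon_alignment`.
#' @param window Window size in codons (>= 1).
#' @return Numeric vector of windowed conservation fractions.
#' @export
local_conservation_profile <- function(aln, window = 10L) {
  stopifnot(window >= 1L)
  core <- aln_core(aln)
  x <- as.numeric(core$conserved)
  L <- length(x)
  if (L == 0L) return(numeric(0))
  if (window >= L) return(mean(x))
  cs <- cumsum(c(0, x))
  ends <- pmin(seq_len(L) + window - 1L, L)
  (cs[ends + 1L] - cs[seq_len(L)]) / (ends - seq_len(L) + 1L)
}
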