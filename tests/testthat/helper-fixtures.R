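# Fixture builders and independent oracles used across the suite. Oracles
# are deliberately naive (nested loops over nucleotide columns, explicit
# enumeration) and never call the code paths they check.

CODE1 <- load_genetic_code(1)
CODE12 <- load_genetic_code(12)

tmpfile <- function(lines, ext = ".txt") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}

# random small codon alignment, optionally with gap codons in any row
random_alignment <- function(n_species = 3, n_cols = 12, n_codon_types = 4,
                             gap_prob = 0.15, group_id = "g") {
  pool <- c("GCA", "GCC", "CGA", "CGG", "ATG", "TGG", "TTT", "CCG")[
    seq_len(n_codon_types)]
  m <- matrix(sample(pool, n_species * n_cols, replace = TRUE),
              nrow = n_species)
  gaps <- matrix(runif(length(m)) < gap_prob, nrow = n_species)
  m[gaps] <- "---"
  rownames(m) <- paste0("sp", seq_len(n_species))
  codon_alignment(m, reference = "sp1", group_id = group_id)
}

# ---- nucleotide-level conservation oracle ------------------------------
# Works directly on the codon matrix, expanding it to per-base columns and
# comparing bases, ignoring the package's codon abstraction. Returns totals
# and conserved counts keyed by unit / unit pair for one frame offset.
oracle_conservation <- function(alignments, offset = 0) {
  unit_tot <- list(); unit_con <- list()
  pair_tot <- list(); pair_con <- list()
  bump <- function(env, key) {
    env[[key]] <- (if (is.null(env[[key]])) 0L else env[[key]]) + 1L
  }
  ut <- new.env(); uc <- new.env(); pt <- new.env(); pc <- new.env()
  for (aln in alignments) {
    m <- aln$codons
    nsp <- nrow(m)
    # per-base matrix: nsp x (3 * n_columns); "-" inside gap codons
    base <- do.call(rbind, lapply(seq_len(nsp), function(r) {
      unlist(strsplit(m[r, ], ""), use.names = FALSE)
    }))
    ref_r <- match(aln$reference, rownames(m))
    # reference nucleotide positions: base columns where ref is not a gap
    nt_cols <- which(base[ref_r, ] != "-")
    refnt <- base[ref_r, nt_cols]
    n_nt <- length(nt_cols)
    nt_ok <- vapply(seq_len(n_nt), function(i) {
      col <- nt_cols[i]
      all(base[, col] == refnt[i])
    }, TRUE)
    starts <- seq.int(offset + 1L, n_nt - 2L, by = 3L)
    starts <- starts[starts + 2L <= n_nt]
    if (length(starts) == 0L) next
    ucons <- logical(length(starts))
    for (k in seq_along(starts)) {
      s <- starts[k]
      unit <- paste(refnt[s:(s + 2L)], collapse = "")
      contiguous <- nt_cols[s + 2L] - nt_cols[s] == 2L
      ucons[k] <- contiguous && all(nt_ok[s:(s + 2L)])
      bump(ut, unit)
      if (ucons[k]) bump(uc, unit)
    }
    if (length(starts) >= 2L) {
      for (k in seq_len(length(starts) - 1L)) {
        s1 <- starts[k]; s2 <- starts[k + 1L]
        pairkey <- paste(paste(refnt[s1:(s1 + 2L)], collapse = ""),
                         paste(refnt[s2:(s2 + 2L)], collapse = ""),
                         sep = "-")
        span_ok <- nt_cols[s2 + 2L] - nt_cols[s1] == 5L
        bump(pt, pairkey)
        if (ucons[k] && ucons[k + 1L] && span_ok) bump(pc, pairkey)
      }
    }
  }
  grab <- function(env) unlist(as.list(env))
  list(unit_total = grab(ut), unit_conserved = grab(uc),
       pair_total = grab(pt), pair_conserved = grab(pc))
}

# compare a conservation_table against the oracle on the same alignments
expect_matches_oracle <- function(tab, alignments, offset, code = NULL) {
  orc <- oracle_conservation(alignments, offset)
  keep_units <- if (offset == 0) sense_codons(code) else tab$codons$codon
  for (u in keep_units) {
    expect_identical(tab$codons$total[tab$codons$codon == u],
                     as.integer(orc$unit_total[u] %||% 0L),
                     info = paste("unit total", u, "frame", offset))
    expect_identical(tab$codons$conserved[tab$codons$codon == u],
                     as.integer(orc$unit_conserved[u] %||% 0L),
                     info = paste("unit conserved", u, "frame", offset))
  }
  keep_pairs <- tab$pairs$pair[tab$pairs$total > 0 |
                                 tab$pairs$pair %in% names(orc$pair_total)]
  for (p in keep_pairs) {
    expect_identical(tab$pairs$total[tab$pairs$pair == p],
                     as.integer(orc$pair_total[p] %||% 0L),
                     info = paste("pair total", p, "frame", offset))
    expect_identical(tab$pairs$conserved[tab$pairs$pair == p],
                     as.integer(orc$pair_conserved[p] %||% 0L),
                     info = paste("pair conserved", p, "frame", offset))
  }
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

# ---- brute-force global alignment score oracle -------------------------
# Enumerates every monotone alignment path of two short sequences and
# scores it with affine gap costs (each maximal run of one gap type costs
# open + ext * run length; a U run abutting an L run is two gaps).
oracle_align_score <- function(x, y, S, gap_open, gap_ext) {
  xa <- strsplit(x, "")[[1L]]; ya <- strsplit(y, "")[[1L]]
  best <- -Inf
  score_moves <- function(moves) {
    score <- 0; mi <- 1L; mj <- 1L
    prev <- ""
    for (mv in moves) {
      if (mv == "D") {
        score <- score + S[xa[mi], ya[mj]]
        mi <- mi + 1L; mj <- mj + 1L
      } else {
        if (mv != prev) score <- score - gap_open
        score <- score - gap_ext
        if (mv == "U") mi <- mi + 1L else mj <- mj + 1L
      }
      prev <- mv
    }
    score
  }
  rec <- function(i, j, moves) {
    if (i > length(xa) && j > length(ya)) {
      best <<- max(best, score_moves(moves))
      return(invisible())
    }
    if (i <= length(xa) && j <= length(ya)) rec(i + 1L, j + 1L, c(moves, "D"))
    if (i <= length(xa)) rec(i + 1L, j, c(moves, "U"))
    if (j <= length(ya)) rec(i, j + 1L, c(moves, "L"))
  }
  rec(1L, 1L, character(0))
  best
}

# ---- Fisher enumeration oracle -----------------------------------------
# Enumerates tables with the observed margins; the weight of a table is the
# number of ways to choose which focal items and which background items are
# hits. Upper-tail p = weight(k >= a) / total weight.
oracle_fisher_greater <- function(a, b, c_, d) {
  n1 <- a + b; n2 <- c_ + d; K <- a + c_
  ks <- max(0, K - n2):min(n1, K)
  w <- choose(n1, ks) * choose(n2, K - ks)
  sum(w[ks >= a]) / sum(w)
}

# ---- KS permutation enumeration oracle ---------------------------------
ks_D <- function(a, b) {
  pooled <- sort(unique(c(a, b)))
  Fa <- vapply(pooled, function(q) mean(a <= q), 0)
  Fb <- vapply(pooled, function(q) mean(b <= q), 0)
  max(abs(Fa - Fb))
}

oracle_ks_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  d_obs <- ks_D(a, b)
  idx <- utils::combn(length(pooled), n)
  ds <- apply(idx, 2L, function(ii) ks_D(pooled[ii], pooled[-ii]))
  mean(ds >= d_obs - 1e-12)
}

# minimal conservation_table for model-level unit tests: set codon rates
# and pair rates directly
fake_table <- function(codon_rates, pair_rates, n_ref_codons = 1000L) {
  code <- CODE1
  sc <- sense_codons(code)
  tot <- ifelse(sc %in% names(codon_rates), 100L, 0L)
  rate <- rep(NA_real_, length(sc))
  rate[match(names(codon_rates), sc)] <- unname(codon_rates)
  codon_df <- data.frame(codon = sc, total = tot,
                         conserved = ifelse(is.na(rate), 0L,
                                            as.integer(round(rate * 100))),
                         rate = rate, stringsAsFactors = FALSE)
  c1 <- rep(sc, each = length(sc)); c2 <- rep(sc, times = length(sc))
  pid <- paste(c1, c2, sep = "-")
  ptot <- ifelse(pid %in% names(pair_rates), 100L, 0L)
  prate <- rep(NA_real_, length(pid))
  prate[match(names(pair_rates), pid)] <- unname(pair_rates)
  pair_df <- data.frame(codon1 = c1, codon2 = c2, pair = pid, total = ptot,
                        conserved = ifelse(is.na(prate), 0L,
                                           as.integer(round(prate * 100))),
                        rate = prate, stringsAsFactors = FALSE)
  structure(list(reference = "sp1", species_set = c("sp1", "sp2"),
                 frame_offset = 0L, codons = codon_df, pairs = pair_df,
                 n_ref_codons = n_ref_codons, n_stop_codons = 0L,
                 n_stop_pairs = 0L),
            class = "conservation_table")
}
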