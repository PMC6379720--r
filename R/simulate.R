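# Synthetic multi-species ortholog generator. Divergence is star-shaped:
# the reference species is the ancestor and every other species is derived
# from it independently, so per-codon conservation under a per-branch
# substitution probability s is (1 - s)^(n_species - 1) and adjacent codons
# evolve independently — the expected pair/codon-product coupling for
# unplanted pairs is 1. Planted codon pairs are written into the ancestor at
# random non-overlapping positions; a configurable fraction of each pair's
# planted occurrences is "locked": copied verbatim into every species and
# shielded from indels, which is what position-specific selection on a codon
# pair looks like to the downstream statistics.

#' Default planted codon pairs
#'
#' Nine rare-codon pairs (CGA-, CCG-, GCG-heavy, the composition typical of
#' translationally inhibitory pairs in yeast) chosen so that each encodes a
#' distinct ordered dipeptide — one planted pair per dipeptide family.
#'
#' @return Character vector of nine `"XXX-YYY"` pair ids.
#' @export
default_planted_pairs <- function() {
  c("CGA-ATA", "CGA-CCG", "CGA-CGA", "CGA-GCG", "CTC-CCG",
    "GTA-CGA", "ATA-CGG", "CTG-GCG", "CCG-CGA")
}

#' Specification of a synthetic ortholog set
#'
#' @param n_species Number of species including the reference (2-5).
#' @param n_genes Number of orthologous genes.
#' @param gene_length_range Codon length range `c(min, max)`, drawn
#'   uniformly.
#' @param codon_frequencies `"uniform"` or a named probability vector over
#'   the 61 sense codons (sums to 1).
#' @param sub_prob Per-branch per-codon synonymous substitution probability.
#' @param nonsyn_prob Per-branch per-codon nonsynonymous substitution
#'   probability.
#' @param indel_prob Per-branch per-codon probability of a codon-level
#'   insertion or deletion.
#' @param planted_pairs Data frame with columns `pair`, `lock_fraction`,
#'   `occurrences`; or a character vector of pair ids (then `lock_fraction`
#'   and `occurrences` defaults apply); or `NULL` for a neutral genome.
#' @param lock_fraction,occurrences Defaults used when `planted_pairs` is a
#'   character vector: fraction of planted occurrences locked (0.4) and
#'   planted occurrences per pair (50).
#' @param code_table Genetic code table id (1 or 12).
#' @param seed Integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_species = 5L, n_genes = 500L,
                           gene_length_range = c(100L, 600L),
                           codon_frequencies = "uniform",
                           sub_prob = 0.3, nonsyn_prob = 0,
                           indel_prob = 0,
                           planted_pairs = default_planted_pairs(),
                           lock_fraction = 0.4, occurrences = 50L,
                           code_table = 1L, seed = 1L) {
  stopifnot(n_species >= 2L, n_species <= 5L, n_genes >= 1L,
            length(gene_length_range) == 2L,
            gene_length_range[1L] >= 2L,
            gene_length_range[1L] <= gene_length_range[2L],
            sub_prob >= 0, sub_prob <= 1, nonsyn_prob >= 0,
            nonsyn_prob <= 1, indel_prob >= 0, indel_prob <= 1)
  code <- load_genetic_code(code_table)
  sc <- sense_codons(code)
  if (identical(codon_frequencies, "uniform")) {
    freq <- stats::setNames(rep(1 / length(sc), length(sc)), sc)
  } else {
    stopifnot(is.numeric(codon_frequencies),
              length(codon_frequencies) == length(sc),
              all(names(codon_frequencies) %in% sc),
              abs(sum(codon_frequencies) - 1) < 1e-9)
    freq <- codon_frequencies[sc]
  }
  if (is.character(planted_pairs)) {
    planted_pairs <- data.frame(pair = normalize_pair(planted_pairs),
                                lock_fraction = lock_fraction,
                                occurrences = as.integer(occurrences),
                                stringsAsFactors = FALSE)
  }
  if (!is.null(planted_pairs)) {
    stopifnot(is.data.frame(planted_pairs),
              all(c("pair", "lock_fraction", "occurrences") %in%
                    names(planted_pairs)))
    planted_pairs$pair <- normalize_pair(planted_pairs$pair)
    cods <- c(substr(planted_pairs$pair, 1L, 3L),
              substr(planted_pairs$pair, 5L, 7L))
    if (!all(cods %in% sc)) {
      stop("planted pair contains a stop codon under table ", code_table)
    }
    stopifnot(all(planted_pairs$lock_fraction >= 0),
              all(planted_pairs$lock_fraction <= 1),
              all(planted_pairs$occurrences >= 0))
  }
  structure(list(n_species = as.integer(n_species),
                 n_genes = as.integer(n_genes),
                 gene_length_range = as.integer(gene_length_range),
                 codon_frequencies = freq, sub_prob = sub_prob,
                 nonsyn_prob = nonsyn_prob, indel_prob = indel_prob,
                 planted_pairs = planted_pairs,
                 code_table = as.integer(code_table),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic multi-species ortholog set
#'
#' Draws ancestral genes codon-wise from the spec's codon frequencies,
#' writes the planted pair occurrences into them at uniform random
#' non-overlapping positions, then derives each non-reference species
#' independently from the ancestor by per-codon synonymous substitution
#' (uniform over the codon's other synonymous codons; single-codon families
#' never change), optional nonsynonymous substitution and codon-level
#' indels. Locked planted occurrences are copied verbatim into every
#' species: never substituted, never deleted, and no insertion is placed
#' between their two codons. Deterministic for a fixed seed.
#'
#' @param spec A `synthetic_spec`.
#' @return An object of class `synthetic_orthologs`: `spec`, `species`
#'   (reference first), `reference`, `seqs` (species -> named list of codon
#'   vectors per ORF), `ortholog_table` (data frame, one column per
#'   species), and `truth` (list with `occurrences` — data frame `pair`,
#'   `orf_id`, `start_codon_index`, `locked` —, `per_orf` conserved-codon
#'   ground truth computed by direct sequence comparison when no indels are
#'   simulated, and `neutral_coupling = 1`).
#' @export
generate_orthologs <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  code <- load_genetic_code(spec$code_table)
  sc <- names(spec$codon_frequencies)
  aa <- code$codon_to_aa[sc]
  syn_class <- split(sc, aa)  # synonymous codons per amino acid
  species <- paste0("sp", seq_len(spec$n_species))
  reference <- species[1L]

  lens <- sample.int(spec$gene_length_range[2L] - spec$gene_length_range[1L] + 1L,
                     spec$n_genes, replace = TRUE) +
    spec$gene_length_range[1L] - 1L
  orf_of <- function(sp, g) sprintf("%s_g%04d", sp, g)

  ancestor <- lapply(lens, function(L) sample(sc, L, replace = TRUE,
                                              prob = spec$codon_frequencies))
  occupied <- lapply(lens, function(L) logical(L))
  occ_rows <- list()
  if (!is.null(spec$planted_pairs)) {
    for (r in seq_len(nrow(spec$planted_pairs))) {
      pr <- spec$planted_pairs[r, ]
      k <- pr$occurrences
      if (k == 0L) next
      n_locked <- round(pr$lock_fraction * k)
      placed <- 0L
      attempts <- 0L
      while (placed < k) {
        attempts <- attempts + 1L
        if (attempts > 200L * k) {
          stop("cannot place ", k, " occurrences of ", pr$pair,
               ": genome capacity exhausted")
        }
        g <- sample.int(spec$n_genes, 1L)
        pos <- sample.int(lens[g] - 1L, 1L)
        if (occupied[[g]][pos] || occupied[[g]][pos + 1L]) next
        ancestor[[g]][pos] <- substr(pr$pair, 1L, 3L)
        ancestor[[g]][pos + 1L] <- substr(pr$pair, 5L, 7L)
        occupied[[g]][pos] <- occupied[[g]][pos + 1L] <- TRUE
        placed <- placed + 1L
        occ_rows[[length(occ_rows) + 1L]] <- data.frame(
          pair = pr$pair, orf_id = orf_of(reference, g), gene = g,
          start_codon_index = pos, locked = placed <= n_locked,
          stringsAsFactors = FALSE)
      }
    }
  }
  occurrences <- if (length(occ_rows) > 0L) {
    do.call(rbind, occ_rows)
  } else {
    data.frame(pair = character(0), orf_id = character(0),
               gene = integer(0), start_codon_index = integer(0),
               locked = logical(0), stringsAsFactors = FALSE)
  }

  # per-gene locked position masks
  locked_pos <- lapply(lens, function(L) logical(L))
  locked_start <- lapply(lens, function(L) logical(L))
  if (nrow(occurrences) > 0L) {
    for (r in which(occurrences$locked)) {
      g <- occurrences$gene[r]; p <- occurrences$start_codon_index[r]
      locked_pos[[g]][p] <- locked_pos[[g]][p + 1L] <- TRUE
      locked_start[[g]][p] <- TRUE
    }
  }

  # flat representation of alternatives per codon, for vectorized draws
  syn_alternatives <- lapply(stats::setNames(sc, sc), function(cd) {
    setdiff(syn_class[[code$codon_to_aa[[cd]]]], cd)
  })
  syn_flat <- unlist(syn_alternatives, use.names = FALSE)
  syn_len <- lengths(syn_alternatives)
  syn_off <- cumsum(c(0L, syn_len[-length(syn_len)]))
  names(syn_len) <- names(syn_off) <- sc
  nonsyn_alternatives <- lapply(stats::setNames(sc, sc), function(cd) {
    sc[aa != code$codon_to_aa[[cd]]]
  })
  ns_flat <- unlist(nonsyn_alternatives, use.names = FALSE)
  ns_len <- lengths(nonsyn_alternatives)
  ns_off <- cumsum(c(0L, ns_len[-length(ns_len)]))
  names(ns_len) <- names(ns_off) <- sc

  gene_of <- rep.int(seq_len(spec$n_genes), lens)
  anc_flat <- unlist(ancestor, use.names = FALSE)
  locked_flat <- unlist(locked_pos, use.names = FALSE)
  lstart_flat <- unlist(locked_start, use.names = FALSE)
  ntot <- length(anc_flat)

  seqs <- stats::setNames(vector("list", spec$n_species), species)
  seqs[[reference]] <- stats::setNames(ancestor,
                                       vapply(seq_len(spec$n_genes),
                                              function(g) orf_of(reference, g), ""))
  for (sp in species[-1L]) {
    cods <- anc_flat
    free <- !locked_flat
    if (spec$sub_prob > 0) {
      hit <- which(free & stats::runif(ntot) < spec$sub_prob)
      if (length(hit) > 0L) {
        len <- syn_len[cods[hit]]
        pick <- syn_off[cods[hit]] + ceiling(stats::runif(length(hit)) * len)
        repl <- syn_flat[pick]
        keep <- len > 0L  # single-codon families cannot change
        cods[hit[keep]] <- repl[keep]
      }
    }
    if (spec$nonsyn_prob > 0) {
      hit <- which(free & stats::runif(ntot) < spec$nonsyn_prob)
      if (length(hit) > 0L) {
        len <- ns_len[cods[hit]]
        cods[hit] <- ns_flat[ns_off[cods[hit]] +
                               ceiling(stats::runif(length(hit)) * len)]
      }
    }
    genes <- split(cods, gene_of)
    # codon-level indels (deletion of a free codon, or insertion after a
    # position that is not a locked pair's first codon)
    if (spec$indel_prob > 0) {
      for (g in seq_len(spec$n_genes)) {
        cg <- genes[[g]]
        hit <- which(stats::runif(length(cg)) < spec$indel_prob)
        for (i in rev(hit)) {
          if (stats::runif(1L) < 0.5) {
            if (!locked_pos[[g]][i] && length(cg) > 2L) cg <- cg[-i]
          } else if (!locked_start[[g]][i]) {
            ins <- sample(sc, 1L, prob = spec$codon_frequencies)
            cg <- append(cg, ins, after = i)
          }
        }
        genes[[g]] <- cg
      }
    }
    names(genes) <- vapply(seq_len(spec$n_genes),
                           function(g) orf_of(sp, g), "")
    seqs[[sp]] <- genes
  }

  tab <- as.data.frame(lapply(stats::setNames(species, species), function(sp) {
    vapply(seq_len(spec$n_genes), function(g) orf_of(sp, g), "")
  }), stringsAsFactors = FALSE)

  per_orf <- NULL
  if (spec$indel_prob == 0) {
    cons <- vapply(seq_len(spec$n_genes), function(g) {
      eq <- rep(TRUE, lens[g])
      for (sp in species[-1L]) eq <- eq & seqs[[sp]][[g]] == ancestor[[g]]
      sum(eq)
    }, 0L)
    per_orf <- data.frame(orf_id = names(seqs[[reference]]),
                          length_codons = lens, conserved_codons = cons,
                          rate = cons / lens, stringsAsFactors = FALSE)
  }

  structure(list(spec = spec, species = species, reference = reference,
                 seqs = seqs, ortholog_table = tab,
                 truth = list(occurrences = occurrences, per_orf = per_orf,
                              neutral_coupling = 1)),
            class = "synthetic_orthologs")
}

#' Codon alignments of a synthetic ortholog set
#'
#' `method = "truth"` builds the generator's own homology alignment
#' directly (valid only for indel-free simulations, where every species has
#' the ancestor's codon coordinates and the true alignment is gap-free) —
#' this isolates the conservation statistics from aligner behaviour.
#' `method = "align"` runs the full translate-align-backtranslate path via
#' [align_group()].
#'
#' @param sim A `synthetic_orthologs` object.
#' @param method `"truth"` or `"align"`.
#' @param params See [alignment_params()] (used by `"align"`).
#' @return List of `codon_alignment` objects, one per gene.
#' @export
as_codon_alignments <- function(sim, method = c("truth", "align"),
                                params = alignment_params()) {
  stopifnot(inherits(sim, "synthetic_orthologs"))
  method <- match.arg(method)
  code <- load_genetic_code(sim$spec$code_table)
  n <- sim$spec$n_genes
  out <- vector("list", n)
  for (g in seq_len(n)) {
    orf_ids <- vapply(sim$species, function(sp) names(sim$seqs[[sp]])[g], "")
    if (method == "truth") {
      if (sim$spec$indel_prob > 0) {
        stop("truth alignments are only defined for indel-free simulations")
      }
      rows <- lapply(sim$species, function(sp) sim$seqs[[sp]][[g]])
      names(rows) <- sim$species
      out[[g]] <- codon_alignment(rows, reference = sim$reference,
                                  group_id = orf_ids[[sim$reference]],
                                  orf_ids = orf_ids)
    } else {
      members <- lapply(sim$species, function(sp) {
        list(orf_id = names(sim$seqs[[sp]])[g],
             sequence = paste(sim$seqs[[sp]][[g]], collapse = ""))
      })
      names(members) <- sim$species
      grp <- list(group_id = orf_ids[[sim$reference]], members = members)
      out[[g]] <- align_group(grp, code, reference = sim$reference,
                              params = params)
    }
  }
  out
}

#' Write a synthetic ortholog set to disk
#'
#' Writes one ORF FASTA per species, the ortholog table as TSV and the
#' truth record as JSON.
#'
#' @param sim A `synthetic_orthologs` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_synthetic <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_orthologs"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (sp in sim$species) {
    p <- file.path(dir, paste0(sp, "_orfs.fasta"))
    write_fasta(vapply(sim$seqs[[sp]], paste, "", collapse = ""), p)
    paths <- c(paths, p)
  }
  # Pillars-style: no header row, one column per species in species order
  tsv <- file.path(dir, "orthologs.tsv")
  utils::write.table(sim$ortholog_table, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  truth <- file.path(dir, "truth.json")
  jsonlite::write_json(sim$truth, truth, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, tsv, truth))
}

#' Synthetic per-gene property table
#'
#' Emits lognormal numeric properties (CAI, protein abundance, mRNA
#' half-life), the true gene length in codons, and a five-level polysome
#' category, for every reference ORF of a simulation. Configured log-scale
#' offsets are applied to the focal set (ORFs containing a locked planted
#' occurrence), so property shifts of known size can be planted for testing
#' the gene-property statistics.
#'
#' @param sim A `synthetic_orthologs` object.
#' @param shifts Named numeric vector of log-scale offsets applied to focal
#'   ORFs, by property name (subset of `cai`, `abundance`, `half_life`);
#'   e.g. `c(abundance = -1)`. Default: no shift.
#' @param seed Integer seed.
#' @param polysome_probs_focal Optional length-5 probability vector for the
#'   focal set's polysome categories (default: same as background).
#' @return Data frame `orf_id`, `cai`, `length`, `abundance`, `half_life`,
#'   `polysome`, `focal`.
#' @export
emit_property_table <- function(sim, shifts = NULL, seed = 1L,
                                polysome_probs_focal = NULL) {
  stopifnot(inherits(sim, "synthetic_orthologs"))
  set.seed(as.integer(seed))
  orfs <- names(sim$seqs[[sim$reference]])
  n <- length(orfs)
  focal <- orfs %in% sim$truth$occurrences$orf_id[sim$truth$occurrences$locked]
  off <- function(prop) {
    o <- rep(0, n)
    if (!is.null(shifts) && prop %in% names(shifts)) o[focal] <- shifts[[prop]]
    o
  }
  cats <- c("orf_lt_590", "monosome", "no_enrichment", "polysome",
            "polysome_top300")
  base_probs <- c(0.15, 0.15, 0.2, 0.35, 0.15)
  pol <- character(n)
  for (i in seq_len(n)) {
    pr <- if (focal[i] && !is.null(polysome_probs_focal)) {
      polysome_probs_focal
    } else {
      base_probs
    }
    pol[i] <- sample(cats, 1L, prob = pr)
  }
  data.frame(orf_id = orfs,
             cai = pmin(1, exp(stats::rnorm(n, log(0.15) + off("cai"), 0.25))),
             length = lengths(sim$seqs[[sim$reference]]),
             abundance = exp(stats::rnorm(n, log(3000) + off("abundance"), 1.5)),
             half_life = exp(stats::rnorm(n, log(10) + off("half_life"), 0.5)),
             polysome = pol, focal = focal, stringsAsFactors = FALSE)
}
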