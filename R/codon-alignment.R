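#' Codon alignment container
#'
#' A codon alignment holds, for each species, a row of codon-width columns:
#' each column entry is either a 3-letter DNA codon or the gap token `"---"`.
#' One species is the designated reference; deleting gap tokens from any row
#' reproduces that species' input codon sequence exactly.
#'
#' @param rows Named list (species -> character vector of codons/gaps) or a
#'   character matrix with species rownames.
#' @param reference Reference species id (must be a row).
#' @param group_id Orthogroup identifier.
#' @param orf_ids Optional named character vector of per-species ORF ids.
#' @return An object of class `codon_alignment` with elements `group_id`,
#'   `reference`, `codons` (species x columns character matrix), `n_columns`
#'   and `orf_ids`.
#' @export
codon_alignment <- function(rows, reference, group_id = "group",
                            orf_ids = NULL) {
  if (is.list(rows)) {
    lens <- lengths(rows)
    if (length(unique(lens)) != 1L) {
      stop("alignment rows differ in column count: ",
           paste(lens, collapse = ", "))
    }
    m <- do.call(rbind, rows)
    rownames(m) <- names(rows)
  } else {
    m <- rows
  }
  stopifnot(is.matrix(m), is.character(m), !is.null(rownames(m)))
  if (!reference %in% rownames(m)) {
    stop("reference species '", reference, "' not present in alignment")
  }
  ok <- m == GAP_CODON | grepl("^[ACGT]{3}$", m)
  if (!all(ok)) {
    stop("invalid alignment entry '", m[!ok][1L],
         "' (expected a DNA codon or '---')")
  }
  structure(list(group_id = group_id, reference = reference, codons = m,
                 n_columns = ncol(m), orf_ids = orf_ids),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("Codon alignment '", x$group_id, "': ", nrow(x$codons), " species x ",
      x$n_columns, " columns (reference ", x$reference, ")\n", sep = "")
  invisible(x)
}

#' Remove gaps from one row of a codon alignment
#'
#' @param aln A `codon_alignment`.
#' @param species Species id.
#' @return The species' ungapped DNA sequence.
#' @export
ungap_row <- function(aln, species) {
  stopifnot(inherits(aln, "codon_alignment"))
  row <- aln$codons[species, ]
  paste(row[row != GAP_CODON], collapse = "")
}

#' Back-translate an amino acid alignment to a codon alignment
#'
#' Replaces each aligned amino acid by the codon it came from, and each gap
#' by the gap token. For every species, the translation of its nucleotide
#' sequence (after trailing-stop stripping) must equal its ungapped aligned
#' amino acids; a mismatch is an error naming the species and column.
#'
#' @param aa_alignment Named character vector of equal-length aligned amino
#'   acid strings.
#' @param nt_seqs Named character vector of the species' coding sequences.
#' @param code A `genetic_code`, or a named list of codes per species.
#' @param reference Reference species id.
#' @param group_id Orthogroup identifier.
#' @param orf_ids Optional named character vector of per-species ORF ids.
#' @return A `codon_alignment`.
#' @export
backtranslate <- function(aa_alignment, nt_seqs, code, reference,
                          group_id = "group", orf_ids = NULL) {
  stopifnot(is.character(aa_alignment), !is.null(names(aa_alignment)),
            all(names(aa_alignment) %in% names(nt_seqs)))
  codes <- per_species_codes(names(aa_alignment), code)
  widths <- nchar(aa_alignment)
  if (length(unique(widths)) != 1L) stop("aligned lengths differ")
  rows <- list()
  for (sp in names(aa_alignment)) {
    nt <- strip_trailing_stop(nt_seqs[[sp]], codes[[sp]])
    aa_cols <- strsplit(aa_alignment[[sp]], "")[[1L]]
    n_res <- sum(aa_cols != "-")
    if (nchar(nt) != 3L * n_res) {
      stop("species ", sp, ": nucleotide length ", nchar(nt),
           " does not match ", n_res, " aligned residues")
    }
    cods <- codons_of(nt)
    aa_nt <- unname(codes[[sp]]$codon_to_aa[cods])
    mism <- which(aa_nt != aa_cols[aa_cols != "-"])
    if (length(mism) > 0L) {
      col <- which(aa_cols != "-")[mism[1L]]
      stop("species ", sp, ": translation mismatch at alignment column ", col)
    }
    row <- rep(GAP_CODON, length(aa_cols))
    row[aa_cols != "-"] <- cods
    rows[[sp]] <- row
  }
  codon_alignment(rows, reference = reference, group_id = group_id,
                  orf_ids = orf_ids)
}

#' Align an orthogroup into a codon alignment
#'
#' Translate-align-backtranslate: member ORFs are translated under their
#' genetic code, the amino acid sequences aligned with [align_proteins()]
#' and the alignment mapped back onto codons. When all member proteins are
#' identical the gap-free alignment is returned directly (it is the optimal
#' global alignment and needs no dynamic programming).
#'
#' @param group An `ortholog_group` from [build_ortholog_groups()] (or any
#'   list with `group_id` and `members` of `list(orf_id=, sequence=)`).
#' @param code A `genetic_code` or named per-species list of codes.
#' @param reference Reference species id (must be a member).
#' @param params See [alignment_params()].
#' @return A `codon_alignment`.
#' @export
align_group <- function(group, code, reference, params = alignment_params()) {
  members <- group$members
  if (!reference %in% names(members)) {
    stop("group ", group$group_id, ": reference species '", reference,
         "' is not a member")
  }
  codes <- per_species_codes(names(members), code)
  nt <- vapply(members, function(m) m$sequence, "")
  orf_ids <- vapply(members, function(m) m$orf_id, "")
  aa <- vapply(names(members), function(sp) translate_orf(nt[[sp]], codes[[sp]]),
               "")
  if (length(unique(aa)) == 1L) {
    rows <- lapply(nt, function(s) codons_of(strip_trailing_stop(s, codes[[1L]])))
    return(codon_alignment(rows, reference = reference,
                           group_id = group$group_id, orf_ids = orf_ids))
  }
  aln <- align_proteins(aa, params)
  backtranslate(aln, nt, code, reference = reference,
                group_id = group$group_id, orf_ids = orf_ids)
}

#' Read a pre-aligned codon FASTA
#'
#' Ingests an aligned FASTA produced by an external codon-aware aligner. All
#' records must have the same length, a multiple of 3, and gaps must occur
#' only as whole in-frame codon-width runs; otherwise the alignment is not
#' codon-aware and an error is raised.
#'
#' @param path Aligned FASTA path.
#' @param reference Reference species id (a record name).
#' @param group_id Orthogroup identifier (default: file name).
#' @return A `codon_alignment`.
#' @export
read_codon_alignment <- function(path, reference,
                                 group_id = sub("\\.[^.]*$", "", basename(path))) {
  seqs <- read_fasta(path)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("aligned records differ in length: ", paste(unique(lens), collapse = ", "))
  }
  if (lens[1L] %% 3L != 0L) {
    stop("alignment length ", lens[1L], " is not a multiple of 3")
  }
  rows <- lapply(seqs, function(s) {
    cods <- codons_of(s)
    partial <- grepl("-", cods) & cods != GAP_CODON
    if (any(partial)) {
      stop("alignment not codon-aware: gap run out of frame at codon column ",
           which(partial)[1L])
    }
    cods
  })
  codon_alignment(rows, reference = reference, group_id = group_id)
}

#' Write a codon alignment as aligned FASTA
#'
#' @param aln A `codon_alignment`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_codon_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "codon_alignment"))
  seqs <- apply(aln$codons, 1L, paste, collapse = "")
  write_fasta(seqs, path)
}
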