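#' Load a genetic code table
#'
#' Returns the codon-to-amino-acid mapping for NCBI translation table 1 (the
#' standard code) or table 12 (the alternative yeast nuclear code used by
#' *Candida albicans* and relatives, in which CTG encodes serine rather than
#' leucine). The two tables are otherwise identical and share the three
#' universal stop codons TAA, TAG and TGA.
#'
#' @param table_id Integer, 1 or 12.
#' @return An object of class `genetic_code`: a list with elements
#'   `table_id` and `codon_to_aa`, a named character vector mapping each of
#'   the 64 DNA codons to a one-letter amino acid or `"*"` for stop.
#' @examples
#' gc1 <- load_genetic_code(1)
#' gc1$codon_to_aa[["CTG"]]  # "L"
#' load_genetic_code(12)$codon_to_aa[["CTG"]]  # "S"
#' @export
load_genetic_code <- function(table_id) {
  if (!is.numeric(table_id) || length(table_id) != 1L || !table_id %in% c(1L, 12L)) {
    stop("unsupported genetic code table '", paste(table_id, collapse = ","),
         "'; supported tables: 1 (standard), 12 (alternative yeast nuclear)")
  }
  map <- Biostrings::getGeneticCode(as.character(as.integer(table_id)))
  map <- map[order(names(map))]
  structure(list(table_id = as.integer(table_id), codon_to_aa = map),
            class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code table", x$table_id,
      if (x$table_id == 12L) "(alternative yeast nuclear; CTG -> S)"
      else "(standard)", "\n")
  cat(" ", sum(x$codon_to_aa != "*"), "sense codons,",
      sum(x$codon_to_aa == "*"), "stops\n")
  invisible(x)
}

#' Sense codons and sense codon pairs of a genetic code
#'
#' @param code A `genetic_code`.
#' @return `sense_codons()`: character vector of the 61 non-stop codons in
#'   alphabetical order. `sense_pairs()`: character vector of the 3721
#'   ordered sense codon pairs as `"XXX-YYY"` identifiers.
#' @export
sense_codons <- function(code) {
  stopifnot(inherits(code, "genetic_code"))
  names(code$codon_to_aa)[code$codon_to_aa != "*"]
}

#' @rdname sense_codons
#' @export
sense_pairs <- function(code) {
  sc <- sense_codons(code)
  as.vector(outer(sc, sc, function(a, b) paste(a, b, sep = "-")))
}

#' Dipeptide encoded by a codon pair
#'
#' Maps pair identifiers (`"CGA-CGA"`) to the two-letter amino acid string of
#' their translation under `code`. Stop codons translate to `"*"`, which only
#' arises for frame-shifted tri-nucleotide units, never for sense pairs.
#'
#' @param pairs Character vector of `"XXX-YYY"` pair identifiers (DNA or RNA
#'   spelling; `U` is accepted and converted to `T`).
#' @param code A `genetic_code`.
#' @return Character vector of dipeptides.
#' @export
pair_dipeptide <- function(pairs, code) {
  stopifnot(inherits(code, "genetic_code"))
  pairs <- normalize_pair(pairs)
  c1 <- substr(pairs, 1L, 3L)
  c2 <- substr(pairs, 5L, 7L)
  paste0(code$codon_to_aa[c1], code$codon_to_aa[c2])
}

#' Normalize codon-pair identifiers
#'
#' Uppercases, converts RNA spelling (U) to DNA (T) and accepts either
#' `"XXXYYY"` hexamers or `"XXX-YYY"`.
#' @param pairs Character vector.
#' @return Character vector of `"XXX-YYY"` identifiers.
#' @export
normalize_pair <- function(pairs) {
  p <- chartr("uU", "tT", pairs)
  p <- toupper(gsub("[^A-Za-z]", "", p))
  bad <- nchar(p) != 6L
  if (any(bad)) {
    stop("malformed codon pair identifier(s): ",
         paste(utils::head(pairs[bad], 3L), collapse = ", "))
  }
  paste(substr(p, 1L, 3L), substr(p, 4L, 6L), sep = "-")
}

# split a nucleotide string into codons; assumes length %% 3 == 0
codons_of <- function(sequence) {
  n <- nchar(sequence)
  if (n == 0L) return(character(0))
  substring(sequence, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Translate a coding sequence
#'
#' Translates an ORF codon by codon under the given genetic code. A trailing
#' stop codon is stripped; an internal stop is an error that names the codon
#' index, since the pipeline's inputs are spliced coding sequences by
#' contract.
#'
#' @param sequence A DNA string (length a multiple of 3).
#' @param code A `genetic_code`.
#' @return One-letter amino acid string, one letter per non-terminating codon.
#' @examples
#' translate_orf("ATGGCTTAA", load_genetic_code(1))  # "MA"
#' @export
translate_orf <- function(sequence, code) {
  stopifnot(inherits(code, "genetic_code"), is.character(sequence),
            length(sequence) == 1L)
  sequence <- chartr("uU", "tT", toupper(sequence))
  if (nchar(sequence) %% 3L != 0L) {
    stop("sequence length ", nchar(sequence), " is not a multiple of 3")
  }
  cods <- codons_of(sequence)
  aa <- unname(code$codon_to_aa[cods])
  if (anyNA(aa)) {
    stop("non-DNA codon at position ", which(is.na(aa))[1L], ": ",
         cods[which(is.na(aa))[1L]])
  }
  n <- length(aa)
  if (n > 0L && aa[n] == "*") {
    aa <- aa[-n]
    cods <- cods[-n]
    n <- n - 1L
  }
  if (any(aa == "*")) {
    stop("internal stop codon at codon ", which(aa == "*")[1L], " (",
         cods[which(aa == "*")[1L]], ")")
  }
  paste(aa, collapse = "")
}

# strip one trailing stop codon if present; returns the sequence unchanged
# otherwise
strip_trailing_stop <- function(sequence, code) {
  sequence <- chartr("uU", "tT", toupper(sequence))
  n <- nchar(sequence)
  if (n >= 3L && n %% 3L == 0L) {
    last <- substr(sequence, n - 2L, n)
    aa <- code$codon_to_aa[last]
    if (!is.na(aa) && aa == "*") return(substr(sequence, 1L, n - 3L))
  }
  sequence
}
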