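#' Read a FASTA file of coding sequences
#'
#' Sequence identifiers are the first whitespace-delimited token of each
#' header line. Sequences are uppercased and RNA spelling (`U`) is converted
#' to DNA (`T`); record order is preserved. Gap characters (`-`) are kept, so
#' the same reader serves aligned FASTA.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  first <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), ";"))[1L]
  if (!is.na(first) && !startsWith(trimws(lines[first]), ">")) {
    stop("malformed FASTA in ", path, ": sequence before header at line ", first)
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(chartr("uU", "tT", as.character(set)))
  names(seqs) <- vapply(strsplit(names(set), "[ \t]+"), `[`, "", 1L)
  seqs
}

#' Write sequences as FASTA
#'
#' Writes a named character vector of sequences wrapped at 60 columns.
#' `write_fasta()` followed by [read_fasta()] is the identity on normalized
#' (uppercase DNA) sequences.
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read an ortholog table
#'
#' Parses a tab-separated ortholog table with one row per orthogroup and one
#' column per species position (the layout of the yeast gene order browser
#' "Pillars"-style files). Missing members are marked with a placeholder
#' token. Rows with fewer than two non-placeholder entries among the
#' requested species are dropped.
#'
#' @param path Path to the TSV file. Lines starting with `#` are ignored.
#' @param species_order Character vector naming the species of each column,
#'   in column order.
#' @param placeholder Token marking a missing ortholog (default `"---"`).
#' @param reference Optional reference species; when given, the group id is
#'   that species' ORF id (falling back to the first member present).
#' @return List of orthogroup skeletons; each is a list with `group_id` and
#'   `members`, a named character vector mapping species to ORF id.
#' @export
read_ortholog_table <- function(path, species_order, placeholder = "---",
                                reference = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  stopifnot(is.character(species_order), length(species_order) >= 2L)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  rownum <- which(keep)
  groups <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) != length(species_order)) {
      stop("ortholog table row ", rownum[i], " has ", length(f),
           " columns; expected ", length(species_order))
    }
    names(f) <- species_order
    f <- f[nzchar(f) & f != placeholder]
    if (length(f) < 2L) next
    gid <- if (!is.null(reference) && reference %in% names(f)) {
      f[[reference]]
    } else {
      f[[1L]]
    }
    groups[[i]] <- list(group_id = gid, members = f)
  }
  groups[!vapply(groups, is.null, TRUE)]
}

#' ORF exclusion filter
#'
#' A set of ORF identifiers (e.g. dubious ORFs and pseudogenes) to be removed
#' from the analysis. Exclusion is keyed on the reference species' ORF id,
#' because exclusion lists come from one annotation database.
#'
#' @param excluded_ids Character vector of ORF ids, or a path given to
#'   [read_orf_filter()] (one id per line, `#` comments allowed).
#' @return An object of class `orf_filter`.
#' @export
orf_filter <- function(excluded_ids = character(0)) {
  structure(list(excluded_ids = unique(as.character(excluded_ids))),
            class = "orf_filter")
}

#' @rdname orf_filter
#' @param path File with one excluded id per line.
#' @export
read_orf_filter <- function(path) {
  ids <- trimws(readLines(path, warn = FALSE))
  orf_filter(ids[nzchar(ids) & !startsWith(ids, "#")])
}

#' Apply an ORF filter to orthogroups
#'
#' Removes groups whose reference-species ORF id is excluded. Filtering is
#' idempotent and never removes a group because of a non-reference member's
#' id.
#'
#' @param groups List of orthogroups (skeletons from [read_ortholog_table()]
#'   or sequence-bearing groups from [build_ortholog_groups()]).
#' @param filter An `orf_filter`.
#' @param reference Reference species id.
#' @return The filtered list; the number of removals is reported as a
#'   message.
#' @export
apply_orf_filter <- function(groups, filter, reference) {
  stopifnot(inherits(filter, "orf_filter"))
  if (length(filter$excluded_ids) == 0L) return(groups)
  ref_id <- vapply(groups, function(g) {
    m <- g$members[[reference]]
    if (is.null(m)) NA_character_ else if (is.list(m)) m$orf_id else m
  }, "")
  drop <- !is.na(ref_id) & ref_id %in% filter$excluded_ids
  if (any(drop)) {
    message("apply_orf_filter: removed ", sum(drop), " of ", length(groups),
            " groups")
  }
  groups[!drop]
}

#' Attach sequences to orthogroup skeletons
#'
#' Combines the id-only skeletons of [read_ortholog_table()] with per-species
#' sequence collections. Trailing stop codons are stripped. Groups with a
#' member whose sequence is missing, or whose stripped length is not a
#' multiple of 3, or with fewer than two members left, are dropped and
#' reported.
#'
#' @param skeletons List from [read_ortholog_table()].
#' @param seqs_by_species Named list: species id -> named character vector of
#'   ORF sequences (as from [read_fasta()]).
#' @param code A `genetic_code` used to recognize trailing stops (a single
#'   code, or a named list of codes per species).
#' @return List of `ortholog_group` objects: `group_id` plus `members`, a
#'   named list of `list(orf_id=, sequence=)` per species.
#' @export
build_ortholog_groups <- function(skeletons, seqs_by_species, code) {
  codes <- per_species_codes(names(seqs_by_species), code)
  n_bad <- 0L
  out <- lapply(skeletons, function(sk) {
    members <- list()
    for (sp in names(sk$members)) {
      pool <- seqs_by_species[[sp]]
      id <- sk$members[[sp]]
      if (is.null(pool) || !id %in% names(pool)) next
      s <- strip_trailing_stop(pool[[id]], codes[[sp]])
      if (nchar(s) == 0L || nchar(s) %% 3L != 0L) {
        return(structure(list(), bad = TRUE))
      }
      members[[sp]] <- list(orf_id = id, sequence = s)
    }
    if (length(members) < 2L) return(structure(list(), bad = TRUE))
    structure(list(group_id = sk$group_id, members = members),
              class = "ortholog_group")
  })
  bad <- vapply(out, function(g) isTRUE(attr(g, "bad")) || length(g) == 0L, TRUE)
  if (any(bad)) {
    message("build_ortholog_groups: dropped ", sum(bad),
            " groups (missing member, empty or out-of-frame sequence)")
  }
  out[!bad]
}

# expand a single code or named list of codes to one code per species
per_species_codes <- function(species, code) {
  if (inherits(code, "genetic_code")) {
    return(stats::setNames(rep(list(code), length(species)), species))
  }
  stopifnot(is.list(code), all(species %in% names(code)))
  code[species]
}
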