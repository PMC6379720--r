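test_that("generation is deterministic for a fixed seed", {
  spec <- synthetic_spec(n_species = 3, n_genes = 10,
                         gene_length_range = c(20L, 40L), occurrences = 3L,
                         seed = 12)
  a <- generate_orthologs(spec)
  b <- generate_orthologs(spec)
  expect_identical(a$seqs, b$seqs)
  expect_identical(a$truth$occurrences, b$truth$occurrences)
})

test_that("zero substitution and indel rates give identical species", {
  sim <- generate_orthologs(synthetic_spec(n_species = 4, n_genes = 8,
                                           gene_length_range = c(20L, 30L),
                                           sub_prob = 0, occurrences = 2L,
                                           seed = 2))
  for (sp in sim$species[-1]) {
    for (g in seq_along(sim$seqs$sp1)) {
      expect_identical(sim$seqs[[sp]][[g]], sim$seqs$sp1[[g]])
    }
  }
  tab <- accumulate_conservation(as_codon_alignments(sim), CODE1)
  expect_true(all(tab$codons$rate[tab$codons$total > 0] == 1))
})

test_that("locked occurrences are identical across species in the output", {
  sim <- generate_orthologs(synthetic_spec(n_species = 5, n_genes = 40,
                                           gene_length_range = c(50L, 80L),
                                           occurrences = 10L, seed = 3))
  occ <- sim$truth$occurrences
  locked <- occ[occ$locked, ]
  expect_gt(nrow(locked), 0)
  for (r in seq_len(nrow(locked))) {
    g <- locked$gene[r]; p <- locked$start_codon_index[r]
    want <- c(substr(locked$pair[r], 1, 3), substr(locked$pair[r], 5, 7))
    for (sp in sim$species) {
      expect_identical(sim$seqs[[sp]][[g]][p:(p + 1)], want)
    }
  }
})

test_that("truth occurrences match the emitted reference sequence", {
  sim <- generate_orthologs(synthetic_spec(n_species = 2, n_genes = 20,
                                           gene_length_range = c(40L, 60L),
                                           occurrences = 6L, seed = 9))
  occ <- sim$truth$occurrences
  for (r in seq_len(nrow(occ))) {
    g <- occ$gene[r]; p <- occ$start_codon_index[r]
    expect_identical(paste(sim$seqs$sp1[[g]][p:(p + 1)], collapse = "-"),
                     occ$pair[r])
  }
  # planted occurrences never overlap
  by_gene <- split(occ$start_codon_index, occ$gene)
  for (pos in by_gene) {
    pos <- sort(pos)
    if (length(pos) > 1) expect_true(all(diff(pos) >= 2))
  }
})

test_that("fully locked pairs with excluded background are perfectly conserved", {
  sc <- sense_codons(CODE1)
  freq <- setNames(ifelse(sc %in% c("CGA"), 0, 1), sc)
  freq <- freq / sum(freq)
  sim <- generate_orthologs(synthetic_spec(
    n_species = 3, n_genes = 20, gene_length_range = c(40L, 60L),
    codon_frequencies = freq, sub_prob = 0.5,
    planted_pairs = data.frame(pair = "CGA-CGA", lock_fraction = 1,
                               occurrences = 12L), seed = 10))
  tab <- accumulate_conservation(as_codon_alignments(sim), CODE1)
  row <- tab$pairs[tab$pairs$pair == "CGA-CGA", ]
  # every reference CGA-CGA is a locked planting (or spans two adjacent
  # lockings), so conservation is total
  expect_gte(row$total, 12L)
  expect_identical(row$conserved, row$total)
})

test_that("realized codon frequencies match the spec at large n", {
  sim <- generate_orthologs(synthetic_spec(n_species = 2, n_genes = 300,
                                           gene_length_range = c(300L, 400L),
                                           planted_pairs = NULL, seed = 20))
  cods <- unlist(sim$seqs$sp1, use.names = FALSE)
  n <- length(cods)
  expect_gt(n, 1e5)
  freq <- table(factor(cods, levels = sense_codons(CODE1))) / n
  p <- 1 / 61
  tol <- 5 * sqrt(p * (1 - p) / n)  # multinomial error
  expect_true(all(abs(freq - p) < tol))
})

test_that("impossible planting requests fail loudly", {
  expect_error(generate_orthologs(synthetic_spec(
    n_species = 2, n_genes = 1, gene_length_range = c(10L, 10L),
    planted_pairs = data.frame(pair = "CGA-CGA", lock_fraction = 0,
                               occurrences = 50L), seed = 1)),
    "capacity")
})

test_that("property tables are seeded and shift only the focal set", {
  sim <- generate_orthologs(synthetic_spec(n_species = 3, n_genes = 30,
                                           gene_length_range = c(30L, 50L),
                                           occurrences = 5L, seed = 4))
  a <- emit_property_table(sim, seed = 5)
  b <- emit_property_table(sim, seed = 5)
  expect_identical(a, b)
  shifted <- emit_property_table(sim, shifts = c(half_life = 3), seed = 5)
  expect_identical(shifted$half_life[!shifted$focal],
                   a$half_life[!a$focal])
  expect_true(all(shifted$half_life[shifted$focal] >
                    a$half_life[a$focal]))
})

test_that("synthetic sets round-trip through the disk format", {
  sim <- generate_orthologs(synthetic_spec(n_species = 2, n_genes = 5,
                                           gene_length_range = c(10L, 20L),
                                           occurrences = 2L, seed = 14))
  dir <- tempfile()
  write_synthetic(sim, dir)
  fa <- read_fasta(file.path(dir, "sp1_orfs.fasta"))
  expect_identical(unname(fa[1]), paste(sim$seqs$sp1[[1]], collapse = ""))
  tab <- read.delim(file.path(dir, "orthologs.tsv"), header = FALSE,
                    stringsAsFactors = FALSE)
  expect_identical(nrow(tab), 5L)
  expect_true(file.exists(file.path(dir, "truth.json")))
})
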