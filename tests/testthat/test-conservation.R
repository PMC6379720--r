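# toy three-species group: reference codons ATG GCA CGA; sp2 differs at
# column 2 (GCC instead of GCA)
toy_alignment <- function() {
  codon_alignment(list(sp1 = c("ATG", "GCA", "CGA"),
                       sp2 = c("ATG", "GCC", "CGA"),
                       sp3 = c("ATG", "GCA", "CGA")),
                  reference = "sp1", group_id = "toy")
}

test_that("column conservation is strict identity across species", {
  aln <- toy_alignment()
  expect_true(is_conserved_column(aln, 1)$conserved)
  expect_false(is_conserved_column(aln, 2)$conserved)
  expect_identical(is_conserved_column(aln, 2)$codon, "GCA")
  gapped <- codon_alignment(list(sp1 = c("CGA", "GCA"),
                                 sp2 = c("CGA", "---")),
                            reference = "sp1")
  expect_false(is_conserved_column(gapped, 2)$conserved)
  refgap <- codon_alignment(list(sp1 = c("---", "GCA"),
                                 sp2 = c("CGA", "GCA")), "sp1")
  expect_error(is_conserved_column(refgap, 1), "gap")
})

test_that("toy group rates match hand counts", {
  tab <- accumulate_conservation(list(toy_alignment()), CODE1)
  get <- function(codon) tab$codons[tab$codons$codon == codon, ]
  expect_identical(get("ATG")$total, 1L)
  expect_identical(get("ATG")$conserved, 1L)
  expect_identical(get("GCA")$conserved, 0L)
  expect_identical(get("CGA")$conserved, 1L)
  pget <- function(p) tab$pairs[tab$pairs$pair == p, ]
  expect_identical(pget("ATG-GCA")$total, 1L)
  expect_identical(pget("ATG-GCA")$conserved, 0L)
  expect_identical(pget("GCA-CGA")$conserved, 0L)

  orf <- orf_conservation_rates(list(toy_alignment()))
  expect_equal(orf$rate, 2 / 3)
})

test_that("fully identical alignments give rate 1 everywhere defined", {
  aln <- codon_alignment(list(sp1 = c("GCA", "CGA", "GCA"),
                              sp2 = c("GCA", "CGA", "GCA")), "sp1")
  tab <- accumulate_conservation(list(aln), CODE1)
  expect_true(all(tab$codons$rate[tab$codons$total > 0] == 1))
  expect_true(all(tab$pairs$rate[tab$pairs$total > 0] == 1))
  expect_equal(orf_conservation_rates(list(aln))$rate, 1)
})

test_that("counting matches the nucleotide-column oracle on random fixtures", {
  set.seed(5)
  for (rep in 1:6) {
    alns <- lapply(1:3, function(i) {
      random_alignment(n_species = sample(2:4, 1), n_cols = sample(4:15, 1),
                       group_id = paste0("g", i))
    })
    tab0 <- accumulate_conservation(alns, CODE1)
    expect_matches_oracle(tab0, alns, 0, CODE1)
    for (off in 1:2) {
      expect_matches_oracle(shifted_frame_conservation(alns, off), alns, off)
    }
  }
})

test_that("adding a divergent species never increases conserved counts", {
  set.seed(9)
  for (rep in 1:5) {
    aln <- random_alignment(n_species = 3, n_cols = 12, gap_prob = 0.1)
    extra <- matrix(sample(c("GCA", "TTT", "---"), aln$n_columns,
                           replace = TRUE), nrow = 1,
                    dimnames = list("sp9"))
    bigger <- codon_alignment(rbind(aln$codons, extra), "sp1")
    t1 <- accumulate_conservation(list(aln), CODE1)
    t2 <- accumulate_conservation(list(bigger), CODE1)
    expect_true(all(t2$codons$conserved <= t1$codons$conserved))
    expect_true(all(t2$pairs$conserved <= t1$pairs$conserved))
    expect_identical(t2$codons$total, t1$codons$total)
  }
})

test_that("a conserved pair implies both member codons conserved", {
  set.seed(13)
  for (rep in 1:5) {
    alns <- list(random_alignment(n_cols = 20))
    tab <- accumulate_conservation(alns, CODE1)
    cons <- setNames(tab$codons$conserved > 0, tab$codons$codon)
    with_pairs <- tab$pairs[tab$pairs$conserved > 0, ]
    if (nrow(with_pairs) > 0) {
      expect_true(all(cons[with_pairs$codon1]))
      expect_true(all(cons[with_pairs$codon2]))
    }
  }
})

test_that("insertion columns between reference codons break pair conservation", {
  # sp2 carries an insertion between the two reference codons
  aln <- codon_alignment(list(sp1 = c("GCA", "---", "CGA"),
                              sp2 = c("GCA", "TTT", "CGA")), "sp1")
  tab <- accumulate_conservation(list(aln), CODE1)
  p <- tab$pairs[tab$pairs$pair == "GCA-CGA", ]
  expect_identical(p$total, 1L)     # still a countable reference pair
  expect_identical(p$conserved, 0L) # but not co-located
  expect_identical(tab$codons$conserved[tab$codons$codon == "GCA"], 1L)
  expect_identical(tab$codons$conserved[tab$codons$codon == "CGA"], 1L)
})

test_that("frame-shifted tokenization follows the stated offsets", {
  aln <- codon_alignment(list(sp1 = c("ATG", "GCA", "CGA"),
                              sp2 = c("ATG", "GCA", "CGA")), "sp1")
  t1 <- shifted_frame_conservation(list(aln), 1)
  expect_setequal(t1$codons$codon[t1$codons$total > 0], c("TGG", "CAC"))
  t2 <- shifted_frame_conservation(list(aln), 2)
  expect_setequal(t2$codons$codon[t2$codons$total > 0], c("GGC", "ACG"))
  expect_true(all(t1$codons$rate[t1$codons$total > 0] == 1))
})

test_that("counts over a generated genome equal the truth record", {
  sim <- generate_orthologs(synthetic_spec(n_species = 3, n_genes = 30,
                                           gene_length_range = c(30L, 60L),
                                           seed = 77, occurrences = 5L))
  alns <- as_codon_alignments(sim)
  orf <- orf_conservation_rates(alns)
  truth <- sim$truth$per_orf
  expect_identical(orf$conserved_codons,
                   truth$conserved_codons[match(orf$orf_id, truth$orf_id)])
  expect_equal(orf$rate, truth$rate[match(orf$orf_id, truth$orf_id)])
  # total sense codons equals summed reference gene lengths
  tab <- accumulate_conservation(alns, CODE1)
  expect_identical(tab$n_ref_codons, as.integer(sum(truth$length_codons)))
  expect_identical(sum(tab$pairs$total) + tab$n_stop_pairs,
                   as.integer(sum(truth$length_codons - 1L)))
})

test_that("local conservation profile windows behave at edges", {
  mk <- function(flags) {
    cods <- ifelse(flags, "CGA", "GCA")
    other <- ifelse(flags, "CGA", "GCC")
    codon_alignment(list(sp1 = cods, sp2 = other), "sp1")
  }
  allc <- mk(rep(TRUE, 6))
  expect_equal(local_conservation_profile(allc, 3), rep(1, 6))
  alt <- mk(rep(c(TRUE, FALSE), 4))
  prof <- local_conservation_profile(alt, 2)
  expect_true(all(prof %in% c(0.5, 1, 0)))
  aln <- mk(c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(local_conservation_profile(aln, 4), 3 / 4)   # window = length
  expect_equal(local_conservation_profile(aln, 99), 3 / 4)  # window > length
  expect_equal(local_conservation_profile(aln, 1),
               c(1, 1, 0, 1))
})
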