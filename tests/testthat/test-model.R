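test_that("origin-constrained slope equals its closed form", {
  # hand example: points (x, y) = (0.25, 1) and (1, 0.5)
  tab <- fake_table(c(GCA = 0.5, GCC = 0.5, CGA = 1, CGG = 1),
                    c("GCA-GCC" = 1, "CGA-CGG" = 0.5))
  fit <- fit_origin_line(tab)
  expect_equal(fit$slope, (0.25 * 1 + 1 * 0.5) / (0.25^2 + 1^2))
  expect_equal(fit$pairs$residual,
               fit$pairs$y - fit$slope * fit$pairs$x)
  expect_equal(fit$residual_sigma, sd(fit$pairs$residual))
  expect_equal(fit$pairs$deviation_sigma,
               fit$pairs$residual / fit$residual_sigma, tolerance = 1e-12)

  # random tables: machine-precision agreement with sum(xy)/sum(x^2)
  set.seed(3)
  sc <- sense_codons(CODE1)
  cr <- setNames(runif(20, 0.05, 0.9), sample(sc, 20))
  pn <- as.vector(outer(names(cr)[1:5], names(cr)[6:10],
                        function(a, b) paste(a, b, sep = "-")))
  pr <- setNames(runif(length(pn)), pn)
  fit2 <- fit_origin_line(fake_table(cr, pr))
  expect_equal(fit2$slope,
               sum(fit2$pairs$x * fit2$pairs$y) / sum(fit2$pairs$x^2),
               tolerance = 1e-12)
})

test_that("undefined rates are excluded from the fit and counted", {
  tab <- fake_table(c(GCA = 0.5, CGA = 0.4), c("GCA-CGA" = 0.3,
                                               "GCA-GCA" = 0.2))
  # pair GCA-TTT has no totals anywhere: excluded silently; also a pair
  # whose codon rate is undefined
  fit <- fit_origin_line(tab)
  expect_identical(nrow(fit$pairs), 2L)
  expect_identical(fit$n_excluded, 3721L - 2L)
})

test_that("outlier calls are symmetric, disjoint and guard degenerate fits", {
  tab <- fake_table(c(GCA = 0.5, GCC = 0.5, CGA = 1, CGG = 1),
                    c("GCA-GCC" = 1, "CGA-CGG" = 0.5))
  fit <- fit_origin_line(tab)
  o <- call_outliers(fit, 3)
  expect_length(o$above, 0L)  # n = 2: residuals are within ~1 sigma
  expect_length(intersect(o$above, o$below), 0L)

  # perfectly collinear input (dyadic rates, so y = 2x holds exactly in
  # floating point): sigma 0, warning, empty sets
  col <- fake_table(c(GCA = 0.25, GCC = 0.5, CGA = 0.75),
                    c("GCA-GCC" = 0.25, "GCA-CGA" = 0.375, "GCC-CGA" = 0.75))
  cfit <- fit_origin_line(col)
  expect_equal(cfit$slope, 2)
  expect_equal(cfit$residual_sigma, 0)
  expect_warning(oc <- call_outliers(cfit), "zero")
  expect_length(oc$above, 0L)
})

test_that("normalized scores follow the pseudocounted ratio", {
  tab <- fake_table(c(GCA = 0.5, GCC = 0.5, CGA = 0.1, CGG = 0.1),
                    c("GCA-GCC" = 0.25, "CGA-CGG" = 0))
  s0 <- normalized_scores(tab, 0)
  expect_equal(s0$scores$score[s0$scores$pair == "GCA-GCC"], 1)
  s1 <- normalized_scores(tab, 0.01)
  expect_equal(s1$scores$score[s1$scores$pair == "GCA-GCC"], 0.26 / 0.2601)
  s2 <- normalized_scores(tab, 0.001)
  expect_equal(s2$scores$score[s2$scores$pair == "CGA-CGG"], 0.001 / 0.101^2)
  # p = 0 with a zero codon rate: undefined
  z <- fake_table(c(GCA = 0, GCC = 0.5), c("GCA-GCC" = 0))
  expect_true(is.na(normalized_scores(z, 0)$scores$score[
    normalized_scores(z, 0)$scores$pair == "GCA-GCC"]))
})

test_that("scores converge monotonically to the unpseudocounted ratio", {
  tab <- fake_table(c(GCA = 0.5, GCC = 0.4), c("GCA-GCC" = 0.3))
  lim <- 0.3 / (0.5 * 0.4)
  err <- vapply(c(1e-3, 1e-6, 1e-9), function(p) {
    s <- normalized_scores(tab, p)
    abs(s$scores$score[s$scores$pair == "GCA-GCC"] - lim)
  }, 0)
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 1e-7)
})

test_that("auto pseudocount is the reciprocal reference codon count", {
  tab <- fake_table(c(GCA = 0.5, GCC = 0.4), c("GCA-GCC" = 0.3),
                    n_ref_codons = 2500L)
  expect_equal(normalized_scores(tab)$pseudocount, 1 / 2500)
})

test_that("dipeptide z-scores standardize each family", {
  # family "KK" (AAA/AAG): scores e, e, e^3 for three of its pairs
  pr <- c("AAA-AAA" = exp(1), "AAA-AAG" = exp(1), "AAG-AAA" = exp(3))
  tab <- fake_table(c(AAA = 1, AAG = 1), pr)
  ns <- normalized_scores(tab, 0)
  # normalized score = rate here because codon rates are 1
  zt <- dipeptide_zscores(ns, CODE1)
  kk <- zt$z_table[zt$z_table$dipeptide == "KK" & !is.na(zt$z_table$X), ]
  expect_equal(sort(kk$X), c(1, 1, 3))
  expect_equal(unique(kk$mu), 5 / 3)
  expect_equal(unique(kk$sigma), sd(c(1, 1, 3)))
  expect_equal(sort(kk$z), sort((c(1, 1, 3) - 5 / 3) / sd(c(1, 1, 3))))
  expect_equal(mean(kk$z), 0, tolerance = 1e-9)
  expect_equal(sd(kk$z), 1, tolerance = 1e-9)
})

test_that("single-member and zero-spread families get z = 0 with a flag", {
  pr <- c("ATG-TGG" = 2, "GCA-GCA" = 3, "GCA-GCC" = 3, "GCC-GCA" = 3)
  tab <- fake_table(c(ATG = 1, TGG = 1, GCA = 1, GCC = 1), pr)
  zt <- dipeptide_zscores(normalized_scores(tab, 0), CODE1)
  mw <- zt$z_table[zt$z_table$pair == "ATG-TGG", ]
  expect_equal(mw$z, 0)
  expect_true(mw$degenerate)
  aa <- zt$z_table[zt$z_table$pair == "GCA-GCC", ]
  expect_equal(aa$z, 0)
  expect_true(aa$degenerate)
})

test_that("z-scores are invariant to the log base", {
  # changing log base multiplies X by a constant; squaring every score
  # doubles natural-log X, so z must not change
  pr <- c("AAA-AAA" = 1.5, "AAA-AAG" = 0.7, "AAG-AAA" = 2.2, "AAG-AAG" = 1.1)
  t1 <- fake_table(c(AAA = 1, AAG = 1), pr)
  t2 <- fake_table(c(AAA = 1, AAG = 1), pr^2)
  z1 <- dipeptide_zscores(normalized_scores(t1, 0), CODE1)$z_table
  z2 <- dipeptide_zscores(normalized_scores(t2, 0), CODE1)$z_table
  keep <- !is.na(z1$X)
  expect_equal(z1$z[keep], z2$z[keep], tolerance = 1e-12)
})

test_that("within-family ranking uses shared min ranks", {
  pr <- c("AAA-AAA" = 0.9, "AAA-AAG" = 0.5, "AAG-AAA" = 0.5,
          "AAG-AAG" = 0.1)
  tab <- fake_table(c(AAA = 1, AAG = 1), pr)
  rk <- rank_within_dipeptide(tab, CODE1, by = "raw_rate")
  got <- rk$rank[match(names(pr), rk$pair)]
  expect_equal(got, c(1, 2, 2, 4))
  # single-member family ranks first
  one <- fake_table(c(ATG = 1, TGG = 1), c("ATG-TGG" = 0.5))
  r1 <- rank_within_dipeptide(one, CODE1, by = "raw_rate")
  expect_equal(r1$rank[r1$pair == "ATG-TGG"], 1)
})

test_that("cross-comparison flags require exceedance in every defined comparison", {
  mk_fit <- function(devs) {
    structure(list(slope = 1, residual_sigma = 1,
                   pairs = data.frame(pair = names(devs), x = 1, y = 1,
                                      residual = unname(devs),
                                      deviation_sigma = unname(devs),
                                      stringsAsFactors = FALSE),
                   n_excluded = 0L), class = "pair_fit")
  }
  one <- cross_comparison_consistency(list(c1 = mk_fit(c("CGA-CGA" = 3.5))))
  expect_true(one$above_2sigma[one$pair == "CGA-CGA"])
  expect_true(one$above_3sigma[one$pair == "CGA-CGA"])

  two <- cross_comparison_consistency(
    list(c1 = mk_fit(c("CGA-CGA" = 3.5, "GCA-GCA" = 0.2)),
         c2 = mk_fit(c("CGA-CGA" = 2.5, "GCA-GCA" = 4))))
  r <- two[two$pair == "CGA-CGA", ]
  expect_true(r$above_2sigma)
  expect_false(r$above_3sigma)
  expect_false(r$incomplete)

  # a pair absent from one comparison is incomplete; flags use defined ones
  inc <- cross_comparison_consistency(
    list(c1 = mk_fit(c("CGA-CGA" = 3.5, "TTT-TTC" = 4)),
         c2 = mk_fit(c("CGA-CGA" = 3.2))))
  r2 <- inc[inc$pair == "TTT-TTC", ]
  expect_true(r2$incomplete)
  expect_true(r2$above_3sigma)
})

test_that("frame-shift control flags absent hexamers and zeroes identical data", {
  aln <- codon_alignment(list(sp1 = c("CGA", "CGA", "GCA", "TTT"),
                              sp2 = c("CGA", "CGA", "GCA", "TTT")), "sp1")
  tabs <- list(accumulate_conservation(list(aln), CODE1),
               shifted_frame_conservation(list(aln), 1),
               shifted_frame_conservation(list(aln), 2))
  fsc <- frame_shift_control(tabs, c("CGA-CGA", "ATG-TGG"), CODE1,
                             pseudocount = 0.01)
  cga <- fsc[fsc$pair == "CGA-CGA", ]
  expect_false(cga$absent[cga$frame == 0])
  expect_true(all(fsc$absent[fsc$pair == "ATG-TGG"]))
  # everything identical: all defined z are 0 (degenerate families)
  expect_true(all(fsc$z[!fsc$absent] == 0 | is.na(fsc$z)))
})
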