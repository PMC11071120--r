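# Histograms use hit midpoints; with NULL pwms the offset itself is the
# midpoint, which keeps the bin arithmetic transparent in these fixtures.

test_that("positional weights equal the excess-density formula", {
  # 4 hits in bin 0 plus one hit in each of bins 1..96: d_obs(0) = 0.04,
  # analytic d_rnd = 0.01 -> weight (0.04-0.01)/0.04 = 0.75
  hits <- tibble::tibble(
    motif_id = "M1", region_id = "G1",
    offset = c(rep(10L, 4), seq(100L, 9600L, by = 100L) + 10L),
    strand = "+", match_score = 1)
  h <- build_positional_histograms(hits, pwms = NULL)
  expect_equal(h$d_obs[h$bin == 0], 0.04)
  expect_equal(h$weight[h$bin == 0], 0.75)
  # occupied bins at exactly the random density get weight 0
  expect_equal(h$weight[h$bin == 1], 0)
  expect_true(all(h$weight >= 0 & h$weight < 1))
  expect_equal(sum(h$d_obs), 1)
  expect_equal(sum(h$d_rnd), 1)

  # perfectly uniform occupancy: D_obs = D_rnd everywhere -> all weights 0
  unif <- tibble::tibble(motif_id = "M1", region_id = "G1",
                         offset = seq(0L, 9900L, by = 100L) + 50L,
                         strand = "+", match_score = 1)
  hu <- build_positional_histograms(unif, pwms = NULL)
  expect_true(all(hu$weight == 0))
})

test_that("motifs without promoter hits are flagged", {
  hits <- tibble::tibble(motif_id = "M1", region_id = "G1", offset = 10L,
                         strand = "+", match_score = 1)
  pwms <- list(toy_pwm("M1"), toy_pwm("M2"))
  names(pwms) <- c("M1", "M2")
  expect_warning(build_positional_histograms(hits, pwms), "M2")
})

manual_histogram <- function(weights_by_bin) {
  h <- tibble::tibble(motif_id = "M1", bin = as.integer(names(weights_by_bin)),
                      d_obs = 0.5, d_rnd = 0.1,
                      weight = unname(weights_by_bin))
  attr(h, "bin_width") <- 100
  h
}

test_that("promoter TFBS score is the L-weighted TF expression sum", {
  # two hits in bins with L = 0.5 and 0.25; binding TFs at TPM 99 and 9:
  # score = (0.5 + 0.25) * (log10(100) + log10(10)) = 0.75 * 3 = 2.25
  hist <- manual_histogram(c(`0` = 0.5, `1` = 0.25))
  hits <- tibble::tibble(motif_id = "M1", region_id = "G1",
                         offset = c(50L, 150L), strand = "+", match_score = 1)
  pwm <- toy_pwm("M1", tfs = c("TFA", "TFB"))
  sc <- score_prm_tfbs(hits, hist, c(TFA = 99, TFB = 9), pwm)
  expect_equal(sc$score, 2.25)

  # no hits for a gene -> that gene simply has no score row
  expect_equal(nrow(score_prm_tfbs(hits[0, ], hist, c(TFA = 99), pwm)), 0)

  # a TF missing from the expression table counts as TPM 0, with warning
  expect_warning(
    sc0 <- score_prm_tfbs(hits, hist, c(TFA = 99), pwm),
    "TPM 0")
  expect_equal(sc0$score, 0.75 * 2)
})

test_that("the prmTFBS double sum factorizes exactly", {
  st <- generate_study(n_genes = 60, n_motifs = 6, n_prm_informative = 3,
                       n_lrc_informative = 2, seed = 9)
  tf_term <- regdom:::tf_expression_term(st$pwms, st$truth$tf_expression)
  lens <- regdom:::motif_lengths(st$pwms)
  bw <- attr(st$histograms, "bin_width")
  wtab <- st$histograms
  for (i in seq_len(nrow(st$prm_scores))) {
    g <- st$prm_scores$gene_id[i]
    m <- st$prm_scores$motif_id[i]
    hh <- st$prm_hits[st$prm_hits$region_id == g & st$prm_hits$motif_id == m, ]
    mids <- hh$offset + lens[m] %/% 2L
    L <- wtab$weight[match(paste(m, mids %/% bw), paste(wtab$motif_id, wtab$bin))]
    # direct double sum: sum_k (L_ik * sum_n log10(TPM+1))
    direct <- sum(vapply(L, function(l) l * tf_term[m], numeric(1)))
    expect_equal(st$prm_scores$score[i], unname(direct), tolerance = 1e-12)
  }
})

test_that("the lrcTFBS triple sum matches hand evaluation", {
  lrcs <- tibble::tibble(region_id = c("L1", "L2"), gene_id = "G1",
                         chrom = "chr1", start = 0L, end = 5000L,
                         center = 2500L, ct = 1, hm = 1,
                         activity = c(0.75, 0.25))
  hits <- tibble::tibble(motif_id = "M1",
                         region_id = c("L1", "L2", "L2"),
                         offset = c(0L, 100L, 200L), strand = "+",
                         match_score = c(1.0, 0.9, 0.8))
  pwm <- toy_pwm("M1", tfs = "TFA")
  # tf term = log10(9 + 1) = 1; 0.75*1.0 + 0.25*(0.9+0.8) = 1.175
  sc <- score_lrc_tfbs(hits, lrcs, c(TFA = 9), pwm)
  expect_equal(sc$score, 1.175, tolerance = 1e-12)

  # one LRC with activity 1, single hit M = 0.8, TF at TPM 99 -> 1.6
  solo_hit <- tibble::tibble(motif_id = "M1", region_id = "L1", offset = 0L,
                             strand = "+", match_score = 0.8)
  sc2 <- score_lrc_tfbs(solo_hit, dplyr::mutate(lrcs, activity = c(1, 0)),
                        c(TFA = 99), pwm)
  expect_equal(sc2$score, 0.8 * 2, tolerance = 1e-12)

  expect_error(
    score_lrc_tfbs(dplyr::mutate(hits, region_id = "nope"), lrcs,
                   c(TFA = 9), pwm),
    "unknown LRC")
})

test_that("scores are monotone in TF expression and order-invariant", {
  hist <- manual_histogram(c(`0` = 0.5, `1` = 0.25))
  hits <- tibble::tibble(motif_id = "M1", region_id = "G1",
                         offset = c(50L, 150L), strand = "+", match_score = 1)
  pwm <- toy_pwm("M1", tfs = c("TFA", "TFB"))
  base <- score_prm_tfbs(hits, hist, c(TFA = 10, TFB = 5), pwm)$score
  for (up in list(c(TFA = 20, TFB = 5), c(TFA = 10, TFB = 50))) {
    expect_gte(score_prm_tfbs(hits, hist, up, pwm)$score, base)
  }
  shuffled <- score_prm_tfbs(hits[2:1, ], hist, c(TFA = 10, TFB = 5), pwm)
  expect_equal(shuffled$score, base)
})

test_that("feature matrices assemble the right nested column sets", {
  st <- generate_study(n_genes = 60, n_motifs = 6, n_prm_informative = 3,
                       n_lrc_informative = 2, seed = 5)
  mats <- study_matrices(st)
  expect_equal(ncol(mats$B$S), 6)
  expect_equal(ncol(mats$BH$S), 6 + 6)
  expect_equal(ncol(mats$BL$S), 6 + 6)
  expect_equal(ncol(mats$BHL$S), 18)
  expect_setequal(colnames(mats$BHL$S),
                  union(colnames(mats$BH$S), colnames(mats$BL$S)))
  expect_equal(unname(mats$BHL$y),
               unname(log10(tpm_vector(st$genes, "c1")[mats$BHL$gene_ids] + 1)))

  # randomized twins are deterministic in their seed and permute columns
  r1 <- study_matrices(st, "BHL", randomize = TRUE, seed = 3)[[1]]
  r2 <- study_matrices(st, "BHL", randomize = TRUE, seed = 3)[[1]]
  expect_identical(r1$S, r2$S)
  expect_equal(sort(unname(r1$S[, 1])), sort(unname(mats$BHL$S[, 1])))
  expect_false(identical(r1$S, mats$BHL$S))
})
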