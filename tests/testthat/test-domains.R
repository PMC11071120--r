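test_that("promoter windows are strand-aware and clip at zero", {
  g <- tibble::tibble(gene_id = c("A", "B", "C"), chrom = "chr1",
                      tss = c(50000L, 50000L, 4000L), tes = NA_integer_,
                      strand = c("+", "-", "+"))
  p <- define_promoters(g)
  expect_equal(unlist(p[1, c("prox_start", "prox_end")], use.names = FALSE),
               c(40000L, 50000L))
  expect_equal(unlist(p[1, c("core_start", "core_end")], use.names = FALSE),
               c(47500L, 50500L))
  # minus strand mirrors about the TSS
  expect_equal(unlist(p[2, c("core_start", "core_end")], use.names = FALSE),
               c(49500L, 52500L))
  expect_equal(unlist(p[2, c("prox_start", "prox_end")], use.names = FALSE),
               c(50000L, 60000L))
  # clipped proximal window
  expect_equal(unlist(p[3, c("prox_start", "prox_end")], use.names = FALSE),
               c(0L, 4000L))
  expect_true(p$clipped[3])
  expect_false(any(p$clipped[1:2]))

  expect_error(define_promoters(g, chrom_lengths = c(chr1 = 10000)),
               "beyond chromosome")
})

test_that("VC normalization conserves mass and downweights hubs", {
  # single pair: rescaling restores the raw count
  one <- tibble::tibble(chrom = "chr1", start_a = 0L, end_a = 1000L,
                        start_b = 50000L, end_b = 51000L, raw_count = 7)
  expect_equal(vc_normalize(one)$norm_count, 7)

  # symmetric triangle: equal counts stay equal
  tri <- tibble::tibble(chrom = "chr1",
                        start_a = c(0L, 0L, 10000L),
                        end_a = c(1000L, 1000L, 11000L),
                        start_b = c(10000L, 20000L, 20000L),
                        end_b = c(11000L, 21000L, 21000L),
                        raw_count = c(2, 2, 2))
  nt <- vc_normalize(tri)
  expect_equal(nt$norm_count, rep(2, 3))

  # star: hub H contacts A (8), B (4), C (4).
  # cov(H)=16, cov(A)=8, cov(B)=4, cov(C)=4, so raw/(cov*cov) is equal for
  # all three pairs: the hub-heavy pair drops from 1/2 of the raw mass to
  # 1/3 of the normalized mass.
  star <- tibble::tibble(chrom = "chr1",
                         start_a = 0L, end_a = 1000L,
                         start_b = c(10000L, 20000L, 30000L),
                         end_b = c(11000L, 21000L, 31000L),
                         raw_count = c(8, 4, 4))
  ns <- vc_normalize(star)
  expect_equal(sum(ns$norm_count), sum(star$raw_count), tolerance = 1e-9)
  share <- ns$norm_count / sum(ns$norm_count)
  expect_equal(share, rep(1 / 3, 3), tolerance = 1e-12)
  expect_lt(share[1], star$raw_count[1] / sum(star$raw_count))
})

make_lrc_toy <- function(partner_centers, extra_genes = NULL) {
  g <- tibble::tibble(gene_id = "A", chrom = "chr1", tss = 50000L,
                      tes = 58000L, strand = "+", tpm_c1 = 10)
  if (!is.null(extra_genes)) g <- dplyr::bind_rows(g, extra_genes)
  cc <- tibble::tibble(chrom = "chr1",
                       start_a = 49500L, end_a = 50500L,
                       start_b = as.integer(partner_centers - 500L),
                       end_b = as.integer(partner_centers + 500L),
                       raw_count = 5)
  p <- define_promoters(g)
  list(genes = g, promoters = p, contacts = vc_normalize(cc))
}

test_that("LRC derivation enforces the >10 kb intergenic rule", {
  # core promoter of A is [47500, 50500); 56000 is ~6 kb away -> excluded,
  # 90000 is ~40 kb away -> kept
  toy <- make_lrc_toy(c(56000L, 90000L))
  lrcs <- derive_lrc_regions(toy$contacts, toy$promoters, toy$genes)
  expect_equal(nrow(lrcs), 1)
  expect_equal(lrcs$center, 90000L)
  expect_equal(lrcs$end - lrcs$start, 5000L)

  # a partner center inside another gene's body is not intergenic
  blocker <- tibble::tibble(gene_id = "B", chrom = "chr1", tss = 85000L,
                            tes = 95000L, strand = "+", tpm_c1 = 1)
  toy2 <- make_lrc_toy(90000L, extra_genes = blocker)
  lrcs2 <- derive_lrc_regions(toy2$contacts, toy2$promoters, toy2$genes)
  expect_equal(nrow(lrcs2), 0)

  expect_error(
    derive_lrc_regions(toy$contacts, toy$promoters,
                       dplyr::mutate(toy$genes, tes = NA_integer_)),
    "tes")
})

test_that("overlapping anchors merge into one 5-kb window with summed ct", {
  # two 1-kb anchors overlapping by 200 bp
  toy <- make_lrc_toy(c(90000L, 90800L))
  lrcs <- derive_lrc_regions(toy$contacts, toy$promoters, toy$genes)
  expect_equal(nrow(lrcs), 1)
  expect_equal(lrcs$end - lrcs$start, 5000L)
  expect_equal(lrcs$ct, sum(toy$contacts$norm_count), tolerance = 1e-9)
  # union is [89500, 91300), center at its midpoint
  expect_equal(lrcs$center, (89500L + 91300L) %/% 2L)
})

test_that("an anchor contacting two core promoters yields one LRC per gene", {
  g <- tibble::tibble(gene_id = c("A", "B"), chrom = "chr1",
                      tss = c(50000L, 52000L), tes = c(58000L, 44000L),
                      strand = c("+", "-"), tpm_c1 = c(10, 10))
  # anchor [49500,50500) overlaps A's core [47500,50500) and B's core
  # [51500,54500)? no - use an anchor spanning both cores
  cc <- vc_normalize(tibble::tibble(
    chrom = "chr1", start_a = 49500L, end_a = 52000L,
    start_b = 89500L, end_b = 90500L, raw_count = 3))
  p <- define_promoters(g)
  lrcs <- derive_lrc_regions(cc, p, g)
  expect_setequal(lrcs$gene_id, c("A", "B"))
  expect_equal(unique(lrcs$center), 90000L)
})

test_that("LRC derivation is deterministic and order-independent", {
  toy <- make_lrc_toy(c(90000L, 75000L, 110000L))
  a <- derive_lrc_regions(toy$contacts, toy$promoters, toy$genes)
  b <- derive_lrc_regions(toy$contacts[c(3, 1, 2), ], toy$promoters, toy$genes)
  expect_equal(a, b)
})

test_that("activities follow the activity-by-contact normalization", {
  lrcs <- tibble::tibble(
    region_id = c("A:lrc1", "A:lrc2", "B:lrc1"),
    gene_id = c("A", "A", "B"), chrom = "chr1",
    start = c(87500L, 107500L, 207500L), end = c(92500L, 112500L, 212500L),
    center = c(90000L, 110000L, 210000L), ct = c(1, 1, 2))
  peaks <- tibble::tibble(
    chrom = "chr1",
    start = c(89000L, 89400L, 109000L),
    end = c(89400L, 89800L, 109400L),
    mark = c("H3K27ac", "H3K4me1", "H3K27ac"),
    fold_enrichment = c(8, 8, 2), qvalue = 0.001)
  out <- attach_activity(lrcs, peaks)
  # hm: A:lrc1 mean(log2 8, log2 8) = 3; A:lrc2 log2 2 = 1; B none -> 0
  expect_equal(out$hm, c(3, 1, 0))
  # activities: hm*ct = {3, 1} -> {0.75, 0.25}; gene B all-zero
  expect_equal(out$activity, c(0.75, 0.25, 0))

  # single active LRC gets activity exactly 1
  solo <- attach_activity(lrcs[1, ], peaks)
  expect_equal(solo$activity, 1)

  expect_error(
    attach_activity(lrcs, dplyr::mutate(peaks, fold_enrichment = -1)),
    "log2")
})

test_that("per-gene activities always sum to exactly 0 or 1", {
  st <- generate_study(n_genes = 80, n_motifs = 8, n_prm_informative = 4,
                       n_lrc_informative = 2, seed = 3)
  sums <- tapply(st$lrcs$activity, st$lrcs$gene_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12 | abs(sums) < 1e-12))
  # and every window center respects the distance rule
  p <- st$promoters[match(st$lrcs$gene_id, st$promoters$gene_id), ]
  d <- pmax(p$core_start - st$lrcs$center, st$lrcs$center - (p$core_end - 1L))
  expect_true(all(d > 10000))
})

test_that("promoter histone features average log2 fold-enrichment", {
  g <- tibble::tibble(gene_id = "A", chrom = "chr1", tss = 50000L,
                      tes = 58000L, strand = "+")
  p <- define_promoters(g)
  peaks <- tibble::tibble(chrom = "chr1", start = c(41000L, 43000L),
                          end = c(41500L, 43500L), mark = "H3K4me3",
                          fold_enrichment = c(4, 16), qvalue = 0.001)
  hf <- promoter_histone_features(p, peaks, marks = c("H3K4me3", "H3K9me3"))
  expect_equal(hf$hist_H3K4me3, 3) # mean(2, 4)
  expect_equal(hf$hist_H3K9me3, 0) # no peak
})
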