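net_fixture_genes <- function() {
  tibble::tibble(
    gene_id = c("G1", "G2", "G3", "TFA", "TFB", "CF1", "CF2"),
    chrom = "chr1", tss = 1000L * (1:7), tes = 1000L * (1:7) + 500L,
    strand = "+", deg_label = c("up", "up", "up", rep("none", 4)),
    tpm_c1 = c(10, 10, 10, 50, 2, 20, 1),
    tpm_c2 = c(10, 10, 10, 40, 2, 25, 2),
    tpm_c3 = c(10, 10, 10, 30, 2, 15, 1)
  )
}

test_that("TF-gene edges require significance, binding, hits and expression", {
  genes <- net_fixture_genes()
  pwms <- list(M1 = toy_pwm("M1", tfs = c("TFA", "TFB")))
  prm_hits <- tibble::tibble(motif_id = "M1", region_id = c("G1", "G2", "G3"),
                             offset = 0L, strand = "+", match_score = 1)
  ens <- toy_ensemble("prm_M1", "prm", 0.4)
  net <- build_tf_gene_network(ens, prm_hits, pwms = pwms, genes = genes)
  # TFB is at 2 TPM everywhere -> filtered; TFA connects to all 3 targets
  expect_equal(nrow(net$edges), 3)
  expect_setequal(net$vertices$type, c("prmTF", "gene"))
  expect_equal(sum(net$vertices$type == "prmTF"), 1)

  # nothing significant -> empty network
  ens0 <- toy_ensemble("prm_M1", "prm", 0.4, significant = FALSE)
  expect_equal(nrow(build_tf_gene_network(ens0, prm_hits, pwms = pwms,
                                          genes = genes)$edges), 0)
})

test_that("a motif significant in both compartments yields two typed TF vertices", {
  genes <- net_fixture_genes()
  pwms <- list(M1 = toy_pwm("M1", tfs = "TFA"))
  prm_hits <- tibble::tibble(motif_id = "M1", region_id = "G1",
                             offset = 0L, strand = "+", match_score = 1)
  lrcs <- tibble::tibble(region_id = "G2:lrc1", gene_id = "G2", chrom = "chr1",
                         start = 0L, end = 5000L, center = 2500L,
                         ct = 1, hm = 1, activity = 1)
  lrc_hits <- tibble::tibble(motif_id = "M1", region_id = "G2:lrc1",
                             offset = 0L, strand = "+", match_score = 0.9)
  ens <- toy_ensemble(c("prm_M1", "lrc_M1"), c("prm", "lrc"), c(0.4, -0.2))
  net <- build_tf_gene_network(ens, prm_hits, lrc_hits, lrcs, pwms, genes)
  expect_setequal(net$vertices$id[net$vertices$name == "TFA"],
                  c("prmTF:TFA", "lrcTF:TFA"))
  expect_equal(nrow(net$edges), 2)
})

test_that("cofactor extension applies strict PPI and expression thresholds", {
  genes <- net_fixture_genes()
  pwms <- list(M1 = toy_pwm("M1", tfs = "TFA"))
  prm_hits <- tibble::tibble(motif_id = "M1", region_id = c("G1", "G2"),
                             offset = 0L, strand = "+", match_score = 1)
  net <- build_tf_gene_network(toy_ensemble("prm_M1", "prm", 0.4),
                               prm_hits, pwms = pwms, genes = genes)
  ppi <- tibble::tibble(
    protein_a = c("TFA", "TFA", "TFA", "NOPE"),
    protein_b = c("CF1", "CF2", "CF1", "CF1"),
    score = c(0.4, 0.9, 0.8, 0.9)) # 0.4 exactly fails the strict filter
  ext <- extend_with_cofactors(net, ppi, genes)
  cof <- ext$vertices[ext$vertices$type == "cofactor", ]
  # CF2 is sub-threshold (max 2 TPM); only CF1 via the 0.8 edge remains
  expect_equal(cof$name, "CF1")
  expect_equal(sum(ext$edges$provenance == "ppi"), 1)

  # a cofactor interacting with 2 network TFs gets 1 vertex, 2 edges
  genes2 <- dplyr::mutate(genes, tpm_c1 = replace(tpm_c1, gene_id == "TFB", 30))
  pwms2 <- list(M1 = toy_pwm("M1", tfs = c("TFA", "TFB")))
  net2 <- build_tf_gene_network(toy_ensemble("prm_M1", "prm", 0.4),
                                prm_hits, pwms = pwms2, genes = genes2)
  ppi2 <- tibble::tibble(protein_a = c("TFA", "TFB"), protein_b = "CF1",
                         score = 0.9)
  ext2 <- extend_with_cofactors(net2, ppi2, genes2)
  expect_equal(sum(ext2$vertices$type == "cofactor"), 1)
  expect_equal(sum(ext2$edges$provenance == "ppi"), 2)
})

test_that("depth-2 reconstruction adds exactly the 2-hop closures", {
  # path A-B-C: the only 2-hop pair is A-C
  p <- path_network(list(c("gene:A", "gene:B"), c("gene:B", "gene:C")))
  d <- reconstruct_depth2(p)
  expect_equal(nrow(d$edges), 3)
  expect_true(any(d$edges$from == "gene:A" & d$edges$to == "gene:C"))

  # complete graph: unchanged
  k4 <- t(utils::combn(paste0("gene:", LETTERS[1:4]), 2))
  full <- path_network(list(k4[, 1], k4[, 2]))
  expect_equal(nrow(reconstruct_depth2(full)$edges), 6)

  # star with 5 leaves: all 10 leaf-leaf pairs get closed
  star <- path_network(list(rep("gene:H", 5), paste0("gene:L", 1:5)))
  ds <- reconstruct_depth2(star)
  expect_equal(nrow(ds$edges), 5 + 10)
  # and the result is stable under a second pass (now a complete graph)
  expect_equal(nrow(reconstruct_depth2(ds)$edges), 15)

  # the degree cap limits how many closures a vertex accepts
  capped <- reconstruct_depth2(star, max_added_per_vertex = 6L)
  expect_true(all(table(c(capped$edges$from, capped$edges$to)) <= 6))
})

test_that("network construction is order-independent", {
  genes <- net_fixture_genes()
  pwms <- list(M1 = toy_pwm("M1", tfs = "TFA"), M2 = toy_pwm("M2", tfs = "TFA"))
  prm_hits <- tibble::tibble(motif_id = c("M1", "M2", "M1"),
                             region_id = c("G1", "G2", "G3"),
                             offset = 0L, strand = "+", match_score = 1)
  ens <- toy_ensemble(c("prm_M1", "prm_M2"), "prm", c(0.4, 0.2))
  a <- build_tf_gene_network(ens, prm_hits, pwms = pwms, genes = genes)
  b <- build_tf_gene_network(ens[2:1, ], prm_hits[c(3, 1, 2), ],
                             pwms = pwms, genes = genes)
  expect_setequal(paste(a$edges$from, a$edges$to),
                  paste(b$edges$from, b$edges$to))
})
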