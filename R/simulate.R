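# Self-contained synthetic studies with planted ground truth. The
# generative model is exactly the model the pipeline fits: feature scores
# are computed by the package's own scoring functions on the planted hits,
# domains and peaks, and the log-scale response is a planted linear
# combination of those scores plus Gaussian noise. Parameter recovery is
# therefore a well-posed test of the selector, not of the generator.

DNA <- c("A", "C", "G", "T")

consensus_seq <- function(pfm) paste(DNA[apply(pfm, 2, which.max)], collapse = "")

# All single-mismatch variants of a PFM consensus with their exact
# min-max-normalized scores.
variant_table <- function(pfm) {
  prof <- match_profile(pfm)
  w <- prof$w[1:4, , drop = FALSE]
  L <- ncol(pfm)
  cons <- apply(pfm, 2, which.max)
  base_raw <- sum(w[cbind(cons, seq_len(L))])
  out <- list(tibble(seq = paste(DNA[cons], collapse = ""), score = 1.0))
  for (p in seq_len(L)) {
    for (b in setdiff(1:4, cons[p])) {
      v <- cons
      v[p] <- b
      raw <- base_raw - w[cons[p], p] + w[b, p]
      out[[length(out) + 1L]] <- tibble(
        seq = paste(DNA[v], collapse = ""),
        score = unname((raw - prof$s_min) / (prof$s_max - prof$s_min))
      )
    }
  }
  bind_rows(out)
}

make_pfm <- function(L, strength = 85L) {
  cons <- sample(1:4, L, replace = TRUE)
  m <- matrix(5, nrow = 4, ncol = L, dimnames = list(DNA, NULL))
  m[cbind(cons, seq_len(L))] <- strength
  m
}

random_dna <- function(n) paste(sample(DNA, n, replace = TRUE), collapse = "")

#' Generate a complete synthetic study with planted ground truth
#'
#' Emulates every input of the pipeline: gene models with per-condition
#' TPM, intrachromosomal Hi-C contact pairs, histone peaks, PFMs with a
#' motif-to-TF map, PPI edges, motif-hit tables and (optionally) promoter /
#' LRC sequences with the motif instances planted at the hit offsets.
#' Target-gene expression is generated as
#' `TPM = 10^(b0 + sum_j w_j S_ij + e) - 1`, `e ~ N(0, noise_sd)`, where
#' `S` is the BHL design computed by the package's own scoring functions on
#' the planted data, and `b0` shifts the response to be non-negative so the
#' log transform round-trips exactly.
#'
#' @param n_genes Number of target (modeled) genes.
#' @param n_motifs Number of motifs; each yields one promoter and one LRC
#'   feature, so the design has `2 * n_motifs` TFBS columns plus 6 histone
#'   columns.
#' @param n_lrc_per_gene LRC windows per gene.
#' @param n_prm_informative,n_lrc_informative How many promoter / LRC
#'   features carry planted effects.
#' @param effect_size Absolute planted coefficient (signs alternate).
#' @param histone_effects Named vector of planted coefficients on promoter
#'   histone features (on the log2 fold-enrichment scale).
#' @param noise_sd Standard deviation of the log10-scale expression noise.
#' @param seed RNG seed; the whole bundle is a deterministic function of it.
#' @param sequences Also build promoter/LRC sequences with planted
#'   instances (slower; off by default for large studies).
#' @return A list (class `regdom_study`) with tibbles `genes`, `contacts`,
#'   `peaks`, `ppi`, `prm_hits`, `lrc_hits`, the `pwms` list, derived
#'   `promoters` and `lrcs`, `histograms`, `features` (the BHL
#'   `regdom_features`), optional `promoter_sequences`/`lrc_sequences`, and
#'   `truth` (planted coefficients, intercept, noise draws, seed).
#' @export
generate_study <- function(n_genes = 1000L, n_motifs = 40L,
                           n_lrc_per_gene = 3L,
                           n_prm_informative = 20L, n_lrc_informative = 10L,
                           effect_size = 0.5,
                           histone_effects = c(H3K27ac = 0.3, H3K27me3 = -0.3),
                           noise_sd = 0.3, seed = 1L,
                           sequences = FALSE) {
  if (n_genes < 50) abort("n_genes must be >= 50")
  if (!is.finite(effect_size)) abort("effect size must be finite")
  if (n_prm_informative > n_motifs || n_lrc_informative > n_motifs) {
    abort("informative feature counts cannot exceed n_motifs")
  }
  withr::with_seed(seed, {
    generate_study_impl(n_genes, n_motifs, n_lrc_per_gene,
                        n_prm_informative, n_lrc_informative, effect_size,
                        histone_effects, noise_sd, seed, sequences)
  })
}

generate_study_impl <- function(n_genes, n_motifs, n_lrc_per_gene,
                                n_prm_informative, n_lrc_informative,
                                effect_size, histone_effects, noise_sd,
                                seed, sequences) {
  L <- 10L
  six_marks <- c("H3K27ac", "H3K4me1", "H3K4me3", "H3K27me3", "H3K36me3",
                 "H3K9me3")
  ## -- gene layout: targets spaced 120 kb, alternating strand ------------
  per_chrom <- 25L
  gidx <- seq_len(n_genes)
  chrom <- paste0("chr", (gidx - 1L) %/% per_chrom + 1L)
  slot <- (gidx - 1L) %% per_chrom
  tss <- 60000L + slot * 120000L
  strand <- ifelse(gidx %% 2L == 1L, "+", "-")
  tes <- ifelse(strand == "+", tss + 8000L, tss - 8000L)
  gene_id <- sprintf("G%04d", gidx)
  targets <- tibble(gene_id = gene_id, chrom = chrom, tss = tss,
                    tes = as.integer(tes), strand = strand,
                    deg_label = "up")

  ## -- TF and cofactor genes on their own chromosomes -------------------
  n_tfs_extra <- max(0L, n_motifs %/% 4L) # motifs mapped to 2 TFs
  tf_ids <- sprintf("TF%03d", seq_len(n_motifs + n_tfs_extra))
  tf_tpm <- round(10^runif(length(tf_ids), 0.5, 1.5), 3) # 3..30 TPM
  tf_tab <- tibble(gene_id = tf_ids, chrom = "chrTF",
                   tss = 50000L + (seq_along(tf_ids) - 1L) * 50000L,
                   tes = 50000L + (seq_along(tf_ids) - 1L) * 50000L + 5000L,
                   strand = "+", deg_label = "none")
  n_cof <- 30L
  cof_ids <- sprintf("CF%03d", seq_len(n_cof))
  cof_tpm <- round(10^runif(n_cof, 0.4, 1.8), 3)
  cof_tpm[seq_len(5)] <- round(runif(5, 0.1, 2.9), 3) # below 3-TPM filter
  cof_tab <- tibble(gene_id = cof_ids, chrom = "chrCF",
                    tss = 50000L + (seq_len(n_cof) - 1L) * 50000L,
                    tes = 50000L + (seq_len(n_cof) - 1L) * 50000L + 5000L,
                    strand = "+", deg_label = "none")

  ## -- motifs and TF map -------------------------------------------------
  pwms <- vector("list", n_motifs)
  extra <- 0L
  for (j in seq_len(n_motifs)) {
    tfs <- tf_ids[j]
    if (j %% 4L == 0L && extra < n_tfs_extra) {
      extra <- extra + 1L
      tfs <- c(tfs, tf_ids[n_motifs + extra])
    }
    pwms[[j]] <- list(motif_id = sprintf("M%03d", j), matrix = make_pfm(L),
                      binding_tfs = tfs)
  }
  names(pwms) <- purrr::map_chr(pwms, "motif_id")
  motif_ids <- names(pwms)
  variants <- purrr::map(pwms, ~ {
    vt <- variant_table(.x$matrix)
    vt[vt$score >= 0.72 | vt$score == 1, , drop = FALSE]
  })

  ## -- Hi-C contacts and LRC peaks --------------------------------------
  lrc_centers <- purrr::map(seq_len(n_genes), function(g) {
    dir <- if (targets$strand[g] == "+") 1L else -1L
    targets$tss[g] + dir * (20000L + (seq_len(n_lrc_per_gene) - 1L) * 7000L)
  })
  contact_rows <- purrr::map_dfr(seq_len(n_genes), function(g) {
    t <- targets$tss[g]
    ctr <- lrc_centers[[g]]
    tibble(chrom_a = targets$chrom[g],
           start_a = t - 500L, end_a = t + 500L,
           start_b = ctr - 500L, end_b = ctr + 500L,
           raw_count = round(10^runif(n_lrc_per_gene, 0.3, 1.8)))
  })
  # background anchor-anchor rows diversify VC coverage
  bg <- contact_rows |>
    group_by(.data$chrom_a) |>
    dplyr::slice_sample(prop = 0.3) |>
    ungroup()
  if (nrow(bg) > 1) {
    sh <- c(nrow(bg), seq_len(nrow(bg) - 1L)) # pair each with the previous
    bg2 <- tibble(chrom_a = bg$chrom_a,
                  start_a = bg$start_b, end_a = bg$end_b,
                  start_b = bg$start_b[sh], end_b = bg$end_b[sh],
                  raw_count = round(10^runif(nrow(bg), 0.2, 1.0)))
    bg2 <- bg2[bg2$chrom_a == bg$chrom_a[sh] & bg2$start_a != bg2$start_b, ]
    contact_rows <- bind_rows(contact_rows, bg2)
  }
  contacts <- tibble(chrom = contact_rows$chrom_a,
                     start_a = contact_rows$start_a, end_a = contact_rows$end_a,
                     start_b = contact_rows$start_b, end_b = contact_rows$end_b,
                     raw_count = pmax(contact_rows$raw_count, 1))

  # enhancer marks: ~80% of windows carry both marks
  lrc_peak_rows <- purrr::map_dfr(seq_len(n_genes), function(g) {
    ctr <- lrc_centers[[g]]
    active <- runif(length(ctr)) < 0.8
    if (!any(active)) active[1] <- TRUE
    purrr::map_dfr(which(active), function(c_i) {
      tibble(chrom = targets$chrom[g],
             start = ctr[c_i] - 250L, end = ctr[c_i] + 250L,
             mark = c("H3K27ac", "H3K4me1"),
             fold_enrichment = 2^runif(2, 1, 4),
             qvalue = 0.001)
    })
  })
  # promoter marks: one peak per gene per mark inside the proximal window
  hist_log2 <- matrix(rnorm(n_genes * 6L, mean = 2, sd = 0.6),
                      nrow = n_genes, dimnames = list(gene_id, six_marks))
  prom_peak_rows <- purrr::map_dfr(seq_along(six_marks), function(m) {
    mid <- ifelse(targets$strand == "+", targets$tss - 5000L,
                  targets$tss + 5000L)
    tibble(chrom = targets$chrom, start = mid - 400L, end = mid + 400L,
           mark = six_marks[m], fold_enrichment = unname(2^hist_log2[, m]),
           qvalue = 0.001)
  })
  peaks <- bind_rows(lrc_peak_rows, prom_peak_rows)

  ## -- derive domains with the pipeline itself ---------------------------
  all_genes <- bind_rows(targets, tf_tab, cof_tab)
  promoters <- define_promoters(all_genes)
  contacts_n <- vc_normalize(contacts)
  lrcs <- derive_lrc_regions(contacts_n,
                             promoters[promoters$gene_id %in% gene_id, ],
                             all_genes)
  lrcs <- attach_activity(lrcs, peaks)

  ## -- planted hits -------------------------------------------------------
  B <- 100L
  pref_bins <- purrr::map(motif_ids, ~ sample(0:(B - 1L), 8L))
  names(pref_bins) <- motif_ids
  prm_info <- motif_ids[seq_len(n_prm_informative)]
  lrc_info <- motif_ids[seq_len(n_lrc_informative)]

  draw_variant <- function(motif, k) {
    vt <- variants[[motif]]
    idx <- sample.int(nrow(vt), k, replace = TRUE)
    vt[idx, , drop = FALSE]
  }
  prm_hits <- purrr::map_dfr(motif_ids, function(mj) {
    lam <- if (mj %in% prm_info) 1.0 else 0.7
    k <- rpois(n_genes, lam)
    gi <- rep(seq_len(n_genes), k)
    if (length(gi) == 0) return(NULL)
    bins <- if (mj %in% prm_info) {
      sample(pref_bins[[mj]], length(gi), replace = TRUE)
    } else {
      sample(0:(B - 1L), length(gi), replace = TRUE)
    }
    mid <- bins * 100L + sample(5:94, length(gi), replace = TRUE)
    vt <- draw_variant(mj, length(gi))
    tibble(motif_id = mj, region_id = gene_id[gi],
           offset = as.integer(mid - L %/% 2L), strand = "+",
           match_score = vt$score, planted_seq = vt$seq)
  })
  # de-overlap within a promoter (keep first of any colliding pair)
  prm_hits <- prm_hits |>
    arrange(.data$region_id, .data$offset) |>
    group_by(.data$region_id) |>
    filter(c(TRUE, diff(.data$offset) >= L)) |>
    ungroup()

  lrc_hits <- purrr::map_dfr(motif_ids, function(mj) {
    lam <- if (mj %in% lrc_info) 1.0 else 0.7
    k <- rpois(n_genes, lam)
    gi <- rep(seq_len(n_genes), k)
    if (length(gi) == 0) return(NULL)
    rid <- purrr::map_chr(gi, function(g) {
      rs <- lrcs$region_id[lrcs$gene_id == gene_id[g]]
      rs[sample.int(length(rs), 1L)]
    })
    vt <- draw_variant(mj, length(gi))
    tibble(motif_id = mj, region_id = rid,
           offset = sample(0:(5000L - L), length(gi), replace = TRUE),
           strand = "+", match_score = vt$score, planted_seq = vt$seq)
  })
  lrc_hits <- lrc_hits |>
    arrange(.data$region_id, .data$offset) |>
    group_by(.data$region_id) |>
    filter(c(TRUE, diff(.data$offset) >= L)) |>
    ungroup()

  ## -- PPI edges ----------------------------------------------------------
  ppi <- purrr::map_dfr(cof_ids, function(cf) {
    k <- sample(1:3, 1)
    tibble(protein_a = sample(tf_ids[seq_len(n_motifs)], k),
           protein_b = cf,
           score = round(runif(k, 0.45, 0.99), 3))
  })
  ppi <- bind_rows(
    ppi,
    tibble(protein_a = sample(tf_ids, 5), protein_b = sprintf("XX%02d", 1:5),
           score = round(runif(5, 0.5, 0.9), 3)),
    tibble(protein_a = sample(tf_ids, 5), protein_b = sample(cof_ids, 5),
           score = round(runif(5, 0.05, 0.4), 3))
  )

  ## -- feature scores and the planted response ---------------------------
  tf_expression <- setNames(tf_tpm, tf_ids)
  histograms <- build_positional_histograms(prm_hits, pwms)
  prm_scores <- score_prm_tfbs(prm_hits, histograms, tf_expression, pwms)
  lrc_scores <- score_lrc_tfbs(lrc_hits, lrcs, tf_expression, pwms)
  hist_feat <- tibble(gene_id = gene_id)
  for (m in six_marks) hist_feat[[paste0("hist_", m)]] <- unname(hist_log2[, m])

  S_prm <- matrix(0, n_genes, n_motifs, dimnames = list(gene_id, motif_ids))
  S_prm[cbind(prm_scores$gene_id, prm_scores$motif_id)] <- prm_scores$score
  S_lrc <- matrix(0, n_genes, n_motifs, dimnames = list(gene_id, motif_ids))
  S_lrc[cbind(lrc_scores$gene_id, lrc_scores$motif_id)] <- lrc_scores$score

  w <- c(
    setNames(effect_size * (-1)^(seq_len(n_prm_informative) - 1L),
             paste0("prm_", prm_info)),
    setNames(effect_size * (-1)^(seq_len(n_lrc_informative)),
             paste0("lrc_", lrc_info))
  )
  lin <- drop(S_prm[, prm_info, drop = FALSE] %*%
                w[paste0("prm_", prm_info)]) +
    drop(S_lrc[, lrc_info, drop = FALSE] %*% w[paste0("lrc_", lrc_info)])
  if (length(histone_effects) > 0) {
    hw <- setNames(as.numeric(histone_effects),
                   paste0("hist_", names(histone_effects)))
    lin <- lin + drop(hist_log2[, names(histone_effects), drop = FALSE] %*%
                        as.numeric(histone_effects))
    w <- c(w, hw)
  }
  eps <- rnorm(n_genes, 0, noise_sd)
  b0 <- 0.05 - min(lin + eps)
  y <- unname(b0 + lin + eps)
  tpm_c1 <- 10^y - 1

  genes <- bind_rows(
    targets |>
      mutate(tpm_c1 = tpm_c1,
             tpm_c2 = tpm_c1 * 2^rnorm(n_genes, 0, 0.2),
             tpm_c3 = tpm_c1 * 2^rnorm(n_genes, 0, 0.2)),
    bind_rows(tf_tab, cof_tab) |>
      mutate(tpm_c1 = c(tf_tpm, cof_tpm),
             tpm_c2 = .data$tpm_c1 * 2^rnorm(length(tf_ids) + n_cof, 0, 0.1),
             tpm_c3 = .data$tpm_c1 * 2^rnorm(length(tf_ids) + n_cof, 0, 0.1))
  )

  seqs <- NULL
  if (sequences) {
    seqs <- plant_sequences(prm_hits, gene_id, PROXIMAL_LEN, L)
    lrc_seqs <- plant_sequences(lrc_hits, lrcs$region_id, 5000L, L)
    seqs <- list(promoters = seqs, lrcs = lrc_seqs)
  }

  structure(
    list(genes = genes, contacts = contacts, peaks = peaks, ppi = ppi,
         prm_hits = select(prm_hits, -"planted_seq"),
         lrc_hits = select(lrc_hits, -"planted_seq"),
         pwms = pwms, promoters = promoters, lrcs = lrcs,
         histograms = histograms,
         prm_scores = prm_scores, lrc_scores = lrc_scores,
         histone_features = hist_feat,
         sequences = seqs,
         planted_hits = list(prm = prm_hits, lrc = lrc_hits),
         truth = list(planted_coefficients = w, intercept = b0,
                      noise = eps, noise_sd = noise_sd, seed = seed,
                      preferred_bins = pref_bins,
                      target_ids = gene_id, tf_expression = tf_expression)),
    class = "regdom_study"
  )
}

# Random backgrounds with planted instances written at hit offsets.
plant_sequences <- function(hits, region_ids, region_len, L) {
  seqs <- setNames(vapply(region_ids, function(x) random_dna(region_len),
                          character(1)), region_ids)
  for (i in seq_len(nrow(hits))) {
    rid <- hits$region_id[i]
    off <- hits$offset[i]
    s <- seqs[[rid]]
    substr(s, off + 1L, off + L) <- hits$planted_seq[i]
    seqs[[rid]] <- s
  }
  seqs
}

#' @export
print.regdom_study <- function(x, ...) {
  cat(sprintf("<regdom_study> %d target genes, %d motifs, %d LRC windows | seed %d\n",
              length(x$truth$target_ids), length(x$pwms), nrow(x$lrcs),
              x$truth$seed))
  invisible(x)
}

#' Assemble the model matrices of a synthetic study
#'
#' @param study A `regdom_study`.
#' @param kinds Model kinds to build.
#' @param randomize,seed Build randomized control twins instead.
#' @return Named list of `regdom_features`.
#' @export
study_matrices <- function(study, kinds = c("B", "BH", "BL", "BHL"),
                           randomize = FALSE, seed = 1L) {
  setNames(purrr::map(kinds, function(k) {
    assemble_feature_matrix(
      study$genes, "c1", study$prm_scores, study$lrc_scores,
      study$histone_features, model_kind = k,
      gene_ids = study$truth$target_ids,
      randomize = randomize, seed = seed
    )
  }), kinds)
}

#' Write a synthetic study to disk
#'
#' Emits `genes.tsv`, `contacts.tsv`, one narrowPeak file per mark under
#' `peaks/`, `pfm.txt`, `tf_map.tsv`, `ppi.tsv`, `prm_hits.tsv`,
#' `lrc_hits.tsv` and, when sequences were generated, FASTA files of the
#' promoter and LRC windows.
#'
#' @param study A `regdom_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_files <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  write_table(study$genes, file.path(dir, "genes.tsv"))
  ct <- study$contacts
  readr::write_tsv(
    tibble(chrom_a = ct$chrom, start_a = ct$start_a, end_a = ct$end_a,
           chrom_b = ct$chrom, start_b = ct$start_b, end_b = ct$end_b,
           count = ct$raw_count),
    file.path(dir, "contacts.tsv"), progress = FALSE
  )
  for (m in unique(study$peaks$mark)) {
    pk <- study$peaks[study$peaks$mark == m, ]
    np <- tibble(chrom = pk$chrom, start = pk$start, end = pk$end,
                 name = ".", score = 0L, strand = ".",
                 signalValue = pk$fold_enrichment,
                 pValue = -1, qValue = -log10(pk$qvalue), peak = -1L)
    readr::write_tsv(np, file.path(dir, "peaks", paste0(m, ".narrowPeak")),
                     col_names = FALSE, progress = FALSE)
  }
  pfm_lines <- unlist(purrr::map(study$pwms, function(p) {
    c(paste0(">", p$motif_id),
      apply(p$matrix, 1, function(r) paste(r, collapse = "\t")))
  }))
  writeLines(pfm_lines, file.path(dir, "pfm.txt"))
  tf_map <- purrr::map_dfr(study$pwms, function(p) {
    tibble(motif_id = p$motif_id, tf_gene_id = p$binding_tfs)
  })
  write_table(tf_map, file.path(dir, "tf_map.tsv"))
  write_table(study$ppi, file.path(dir, "ppi.tsv"))
  write_table(study$prm_hits, file.path(dir, "prm_hits.tsv"))
  write_table(study$lrc_hits, file.path(dir, "lrc_hits.tsv"))
  if (!is.null(study$sequences)) {
    writeLines(paste0(">", names(study$sequences$promoters), "\n",
                      study$sequences$promoters),
               file.path(dir, "promoters.fasta"))
    writeLines(paste0(">", names(study$sequences$lrcs), "\n",
                      study$sequences$lrcs),
               file.path(dir, "lrc_windows.fasta"))
  }
  invisible(dir)
}

#' Generate a stochastic block model network with typed vertices
#'
#' Vertices are split into `n_blocks` blocks of `size_per_block`; each
#' within-block pair is connected with probability `p_in`, each
#' between-block pair with `p_out`. Vertex types cycle through cofactor /
#' TF / gene to mimic the tripartite regulatory network shape.
#'
#' @param n_blocks,size_per_block Block structure.
#' @param p_in,p_out Connection probabilities, `0 <= p_out < p_in <= 1`.
#' @param seed RNG seed.
#' @return List with `network` (a `regdom_network`) and `truth` (tibble
#'   `id`, `block`).
#' @export
generate_block_network <- function(n_blocks = 2L, size_per_block = 30L,
                                   p_in = 0.3, p_out = 0.01, seed = 1L) {
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    abort("need 0 <= p_out < p_in <= 1")
  }
  withr::with_seed(seed, {
    n <- n_blocks * size_per_block
    block <- rep(seq_len(n_blocks), each = size_per_block)
    type <- rep_len(c("cofactor", "prmTF", "gene"), n)
    ids <- sprintf("%s:v%03d", type, seq_len(n))
    pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
    p <- ifelse(block[pairs[, 1]] == block[pairs[, 2]], p_in, p_out)
    keep <- runif(nrow(pairs)) < p
    net <- empty_network()
    net <- add_edges(net, ids[pairs[keep, 1]], ids[pairs[keep, 2]],
                     provenance = "sbm")
    net <- rebuild_vertices(net)
    # isolated vertices still belong to the network
    missing <- setdiff(ids, net$vertices$id)
    if (length(missing) > 0) {
      net$vertices <- bind_rows(
        net$vertices,
        tibble(id = missing, type = sub(":.*$", "", missing),
               name = sub("^[^:]*:", "", missing))
      ) |> arrange(.data$id)
    }
    list(network = net, truth = tibble(id = ids, block = block))
  })
}
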