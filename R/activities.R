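# Post-selection summaries: TFBS/TF activities, per-gene effect partitions
# and module expression correlation.

#' Activities of significant TFBS features and their TFs
#'
#' A TFBS feature's activity is its mean RC multiplied by the total TPM of
#' its binding TF genes; a TF's activity score is the feature's mean RC
#' multiplied by that TF gene's own TPM. Signs therefore follow the mean RC
#' (activator-like positive, repressor-like negative).
#'
#' @param ensembles Tested ensemble tibble; only significant rows are used.
#' @param tf_expression Named vector, TF gene id -> TPM ([tpm_vector()]).
#' @param pwms PWM list (binding TFs per motif).
#' @param log_tpm Use `log10(TPM + 1)` instead of raw TPM.
#' @return Tibble `name`, `level` (`"tfbs"` or `"tf"`), `location`,
#'   `mean_rc`, `activity`.
#' @export
compute_activities <- function(ensembles, tf_expression, pwms,
                               log_tpm = FALSE) {
  sig <- ensembles[ensembles$significant & ensembles$location %in% c("prm", "lrc"), ]
  xf <- if (log_tpm) function(x) log10(x + 1) else identity
  rows <- purrr::pmap(
    list(sig$feature, sig$location, sig$mean_rc),
    function(feature, location, mean_rc) {
      motif <- sub("^(prm|lrc)_", "", feature)
      tfs <- pwms[[motif]]$binding_tfs
      tpm <- tf_expression[tfs]
      tpm[is.na(tpm)] <- 0
      bind_rows(
        tibble(name = feature, level = "tfbs", location = location,
               mean_rc = mean_rc, activity = mean_rc * sum(xf(tpm))),
        tibble(name = paste0(location, "_", tfs), level = "tf",
               location = location, mean_rc = mean_rc,
               activity = mean_rc * xf(unname(tpm)))
      )
    }
  )
  bind_rows(rows)
}

#' Partition per-gene regulatory effects
#'
#' For each modeled gene, the contribution of a significant TFBS feature is
#' `mean_rc * S_ij`. Contributions are split into four classes by feature
#' location and contribution sign, and each class's summed absolute
#' contribution is divided by the gene's total absolute contribution. Genes
#' with no contribution get all-zero proportions and `degenerate = TRUE`.
#'
#' @param fm The `regdom_features` design the ensemble was fitted on.
#' @param ensembles Tested ensemble tibble (significant rows used).
#' @return Tibble `gene_id`, `prm_pos`, `prm_neg`, `lrc_pos`, `lrc_neg`,
#'   `degenerate`.
#' @export
partition_effects <- function(fm, ensembles) {
  sig <- ensembles[ensembles$significant & ensembles$location %in% c("prm", "lrc"), ]
  out <- tibble(gene_id = fm$gene_ids, prm_pos = 0, prm_neg = 0,
                lrc_pos = 0, lrc_neg = 0, degenerate = TRUE)
  if (nrow(sig) == 0) return(out)
  contrib <- sweep(fm$S[, sig$feature, drop = FALSE], 2, sig$mean_rc, "*")
  cls <- function(loc, sgn) {
    sel <- sig$location == loc
    m <- contrib[, sel, drop = FALSE]
    m[sign(m) != sgn] <- 0
    rowSums(abs(m))
  }
  sums <- cbind(prm_pos = cls("prm", 1), prm_neg = cls("prm", -1),
                lrc_pos = cls("lrc", 1), lrc_neg = cls("lrc", -1))
  tot <- rowSums(sums)
  ok <- tot > 0
  sums[ok, ] <- sums[ok, , drop = FALSE] / tot[ok]
  sums[!ok, ] <- 0
  tibble(gene_id = fm$gene_ids,
         prm_pos = unname(sums[, "prm_pos"]),
         prm_neg = unname(sums[, "prm_neg"]),
         lrc_pos = unname(sums[, "lrc_pos"]),
         lrc_neg = unname(sums[, "lrc_neg"]),
         degenerate = !ok)
}

#' Correlation of mean expression profiles between gene sets
#'
#' For every pair of labeled gene sets (e.g. a cluster's cofactors, TFs and
#' target genes), the Pearson correlation of the sets' mean-TPM profiles
#' across conditions.
#'
#' @param gene_sets Named list of gene-id vectors (each non-empty).
#' @param genes Gene tibble with at least three `tpm_` condition columns.
#' @return Tibble `set_a`, `set_b`, `pcc` (upper-triangle pairs; NA with a
#'   warning when a profile is constant).
#' @export
module_expression_correlation <- function(gene_sets, genes) {
  tpm_cols <- grep("^tpm_", names(genes), value = TRUE)
  if (length(tpm_cols) < 3) abort("need at least 3 conditions")
  if (any(lengths(gene_sets) < 1)) abort("every gene set needs >= 1 gene")
  profiles <- purrr::map(gene_sets, function(ids) {
    unknown <- setdiff(ids, genes$gene_id)
    if (length(unknown) > 0) {
      abort(paste0("unknown gene id(s): ", paste(head(unknown, 5), collapse = ", ")))
    }
    colMeans(as.matrix(genes[match(ids, genes$gene_id), tpm_cols, drop = FALSE]))
  })
  labels <- names(gene_sets)
  pairs <- which(upper.tri(diag(length(labels))), arr.ind = TRUE)
  out <- purrr::map_dfr(seq_len(nrow(pairs)), function(r) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    pa <- profiles[[a]]; pb <- profiles[[b]]
    pcc <- if (sd(pa) == 0 || sd(pb) == 0) NA_real_ else cor(pa, pb)
    tibble(set_a = labels[a], set_b = labels[b], pcc = pcc)
  })
  if (anyNA(out$pcc)) warn("constant mean-TPM profile: correlation undefined")
  out
}
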