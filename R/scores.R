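# From motif hits to the regression design matrix.
#
# Promoter hits are weighted purely by position: L(b) compares the observed
# density of a motif's hit midpoints across all promoters (D_obs) with a
# random placement density (D_rnd) in 100-bp bins,
#   L(b) = 0                          if D_obs(b) <= D_rnd(b)
#        = (D_obs(b) - D_rnd(b)) / D_obs(b)   otherwise,
# so L in [0, 1). LRC hits are weighted by the region's activity A and the
# hit's MATCH score M instead; neither weighting uses the other's term.

#' Build positional weight histograms for promoter hits
#'
#' Pools each motif's hit midpoints over all promoters into `bin_width` bins
#' (bin 0 farthest upstream, sequences being 5'->3' oriented), normalizes to
#' the observed density `d_obs`, pairs it with a random density `d_rnd`
#' (analytic uniform by default, or a seeded empirical shuffle), and derives
#' the excess-density weight per bin.
#'
#' @param hits Promoter hit tibble ([scan_motifs()] output; `region_id` must
#'   be the promoter's gene id).
#' @param pwms PWM list; used for motif lengths (hit midpoint = offset +
#'   length/2) and to warn about motifs with no promoter hits. When `NULL`,
#'   offsets are used as midpoints.
#' @param promoter_length Promoter window length in bp.
#' @param bin_width Bin width in bp.
#' @param mode `"uniform"` for the analytic random density `1/B`;
#'   `"shuffle"` to resample as many positions uniformly at random.
#' @param seed Seed for `mode = "shuffle"`.
#' @return A tibble (class `regdom_histograms`) with one row per motif x
#'   bin: `motif_id`, `bin`, `d_obs`, `d_rnd`, `weight`.
#' @export
build_positional_histograms <- function(hits, pwms = NULL,
                                        promoter_length = 10000,
                                        bin_width = 100,
                                        mode = c("uniform", "shuffle"),
                                        seed = 1L) {
  mode <- match.arg(mode)
  B <- as.integer(ceiling(promoter_length / bin_width))
  lens <- motif_lengths(pwms)
  if (!is.null(pwms)) {
    missed <- setdiff(names(lens), unique(hits$motif_id))
    if (length(missed) > 0) {
      warn(paste0("no promoter hits for motif(s): ",
                  paste(missed, collapse = ", "), "; histogram omitted"))
    }
  }
  mids <- hit_midpoints(hits, lens)
  bins <- pmin(pmax(mids %/% bin_width, 0L), B - 1L)
  out <- purrr::map(split(bins, hits$motif_id), function(b) {
    obs <- tabulate(b + 1L, nbins = B)
    d_obs <- obs / sum(obs)
    if (mode == "uniform") {
      d_rnd <- rep(1 / B, B)
    } else {
      d_rnd <- withr::with_seed(seed, {
        r <- sample.int(promoter_length, length(b), replace = TRUE) - 1L
        tabulate(r %/% bin_width + 1L, nbins = B) / length(b)
      })
    }
    tibble(bin = 0:(B - 1L), d_obs = d_obs, d_rnd = d_rnd,
           weight = positional_weight(d_obs, d_rnd))
  })
  res <- bind_rows(out, .id = "motif_id")
  attr(res, "bin_width") <- bin_width
  attr(res, "promoter_length") <- promoter_length
  class(res) <- c("regdom_histograms", class(res))
  res
}

positional_weight <- function(d_obs, d_rnd) {
  ifelse(d_obs > d_rnd, (d_obs - d_rnd) / d_obs, 0)
}

motif_lengths <- function(pwms) {
  if (is.null(pwms)) return(NULL)
  if (!is.null(pwms$motif_id)) pwms <- list(pwms)
  setNames(purrr::map_int(pwms, ~ ncol(.x$matrix)),
           purrr::map_chr(pwms, "motif_id"))
}

hit_midpoints <- function(hits, lens = NULL) {
  if (is.null(lens)) return(hits$offset)
  L <- unname(lens[hits$motif_id])
  L[is.na(L)] <- 0L
  as.integer(hits$offset + L %/% 2L)
}

# sum_n log10(TPM_n + 1) over a motif's binding TFs; missing TFs count as
# TPM 0 with a warning.
tf_expression_term <- function(pwms, tf_expression, pseudocount = 1) {
  if (!is.null(pwms$motif_id)) pwms <- list(pwms)
  all_tfs <- unique(unlist(purrr::map(pwms, "binding_tfs")))
  missing <- setdiff(all_tfs, names(tf_expression))
  if (length(missing) > 0) {
    warn(paste0("TF(s) absent from expression table, treated as TPM 0: ",
                paste(missing, collapse = ", ")))
  }
  vapply(pwms, function(p) {
    tpm <- tf_expression[p$binding_tfs]
    tpm[is.na(tpm)] <- 0
    sum(log10(tpm + pseudocount))
  }, numeric(1)) |>
    setNames(purrr::map_chr(pwms, "motif_id"))
}

#' Score promoter TFBS features
#'
#' For gene `i` and motif `j` found `K` times in the promoter, the score is
#' `sum_k ( L_ik * sum_n log10(TPM_jn + 1) )`, `L_ik` being the positional
#' weight of the bin containing the k-th hit midpoint and `n` indexing the
#' motif's binding TFs. The sum factorizes as
#' `(sum_k L_ik) * (sum_n log10(TPM_jn + 1))`.
#'
#' @param hits Promoter hit tibble; `region_id` is the gene id.
#' @param histograms Output of [build_positional_histograms()].
#' @param tf_expression Named vector, TF gene id -> TPM in the modeled
#'   condition (see [tpm_vector()]).
#' @param pwms PWM list (binding TFs and motif lengths).
#' @param pseudocount Added to TPM before log10 (default 1).
#' @return Tibble `gene_id`, `motif_id`, `score` (genes with hits only).
#' @export
score_prm_tfbs <- function(hits, histograms, tf_expression, pwms,
                           pseudocount = 1) {
  if (nrow(hits) == 0) {
    return(tibble(gene_id = character(), motif_id = character(),
                  score = double()))
  }
  bin_width <- attr(histograms, "bin_width") %||% 100
  tf_term <- tf_expression_term(pwms, tf_expression, pseudocount)
  mids <- hit_midpoints(hits, motif_lengths(pwms))
  h <- hits |>
    mutate(bin = pmin(pmax(mids %/% bin_width, 0L),
                      max(histograms$bin))) |>
    left_join(as_tibble(histograms)[, c("motif_id", "bin", "weight")],
              by = c("motif_id", "bin"))
  h$weight[is.na(h$weight)] <- 0
  h |>
    group_by(gene_id = .data$region_id, .data$motif_id) |>
    summarise(score = sum(.data$weight), .groups = "drop") |>
    mutate(score = .data$score * unname(tf_term[.data$motif_id]))
}

#' Score LRC TFBS features
#'
#' For gene `i` and motif `j` found across the gene's `C` LRC regions, the
#' score is `sum_c sum_k ( A_ic * M_ick * sum_n log10(TPM_jn + 1) )` with
#' `A_ic` the LRC activity and `M_ick` the hit's MATCH score.
#'
#' @param hits LRC hit tibble; `region_id` references `lrcs$region_id`.
#' @param lrcs LRC tibble with `activity` ([attach_activity()]).
#' @param tf_expression Named vector, TF gene id -> TPM.
#' @param pwms PWM list.
#' @param pseudocount Added to TPM before log10.
#' @return Tibble `gene_id`, `motif_id`, `score`.
#' @export
score_lrc_tfbs <- function(hits, lrcs, tf_expression, pwms, pseudocount = 1) {
  if (nrow(hits) == 0) {
    return(tibble(gene_id = character(), motif_id = character(),
                  score = double()))
  }
  unknown <- setdiff(unique(hits$region_id), lrcs$region_id)
  if (length(unknown) > 0) {
    abort(paste0("hit(s) reference unknown LRC region(s): ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  tf_term <- tf_expression_term(pwms, tf_expression, pseudocount)
  hits |>
    inner_join(lrcs[, c("region_id", "gene_id", "activity")], by = "region_id") |>
    group_by(.data$gene_id, .data$motif_id) |>
    summarise(score = sum(.data$activity * .data$match_score),
              .groups = "drop") |>
    mutate(score = .data$score * unname(tf_term[.data$motif_id]))
}

#' Extract one condition's TPM as a named vector
#'
#' @param genes Gene tibble with `tpm_<condition>` columns.
#' @param condition Condition name (with or without the `tpm_` prefix).
#' @return Named numeric vector gene_id -> TPM.
#' @export
tpm_vector <- function(genes, condition) {
  col <- if (condition %in% names(genes)) condition else paste0("tpm_", condition)
  if (!col %in% names(genes)) {
    abort(paste0("no TPM column for condition '", condition, "'"))
  }
  setNames(genes[[col]], genes$gene_id)
}

#' Assemble the regression feature matrix
#'
#' Builds the genes x features design for one of the nested model kinds:
#' `B` (promoter TFBS scores only), `BH` (B + per-mark promoter histone
#' features), `BL` (B + LRC TFBS scores), `BHL` (all). The response is
#' `log10(TPM + 1)` in the modeled condition. `randomize = TRUE` permutes
#' every feature column independently across genes (seeded), producing the
#' randomized control twin of a model.
#'
#' @param genes Gene tibble.
#' @param condition Condition whose TPM is the response.
#' @param prm_scores Tibble from [score_prm_tfbs()].
#' @param lrc_scores Tibble from [score_lrc_tfbs()] (required for BL/BHL).
#' @param histone_features Tibble from [promoter_histone_features()]
#'   (required for BH/BHL).
#' @param model_kind One of `"B"`, `"BH"`, `"BL"`, `"BHL"`.
#' @param gene_ids Genes to model; defaults to genes with a `deg_label` when
#'   any is set, otherwise all genes.
#' @param randomize Permute feature columns (randomized control)?
#' @param seed Seed for `randomize`.
#' @return A `regdom_features` object: list with `gene_ids`,
#'   `feature_names`, `location` (`prm`/`lrc`/`histone` per feature), design
#'   matrix `S`, response `y`, `model_kind`.
#' @export
assemble_feature_matrix <- function(genes, condition, prm_scores,
                                    lrc_scores = NULL,
                                    histone_features = NULL,
                                    model_kind = c("BHL", "B", "BH", "BL"),
                                    gene_ids = NULL,
                                    randomize = FALSE, seed = NULL) {
  model_kind <- match.arg(model_kind)
  if (is.null(gene_ids)) {
    lab <- genes$deg_label
    gene_ids <- if (!all(is.na(lab)) && any(lab %in% c("up", "down"), na.rm = TRUE)) {
      genes$gene_id[!is.na(lab) & lab %in% c("up", "down")]
    } else {
      genes$gene_id
    }
  }
  tpm <- tpm_vector(genes, condition)[gene_ids]
  drop <- is.na(tpm)
  if (any(drop)) {
    inform(sprintf("assemble_feature_matrix: %d gene(s) lack a response, excluded",
                   sum(drop)))
    gene_ids <- gene_ids[!drop]
    tpm <- tpm[!drop]
  }
  y <- log10(tpm + 1)

  wide <- function(scores, prefix) {
    m <- matrix(0, nrow = length(gene_ids),
                ncol = length(unique(scores$motif_id)),
                dimnames = list(gene_ids,
                                paste0(prefix, sort(unique(scores$motif_id)))))
    sc <- scores[scores$gene_id %in% gene_ids, , drop = FALSE]
    if (nrow(sc) > 0) {
      m[cbind(sc$gene_id, paste0(prefix, sc$motif_id))] <- sc$score
    }
    m
  }

  blocks <- list(prm = wide(prm_scores, "prm_"))
  if (model_kind %in% c("BH", "BHL")) {
    if (is.null(histone_features)) {
      abort(paste0(model_kind, " model needs histone_features"))
    }
    hf <- histone_features[match(gene_ids, histone_features$gene_id), , drop = FALSE]
    hm <- as.matrix(hf[, setdiff(names(hf), "gene_id"), drop = FALSE])
    rownames(hm) <- gene_ids
    hm[is.na(hm)] <- 0
    blocks$histone <- hm
  }
  if (model_kind %in% c("BL", "BHL")) {
    if (is.null(lrc_scores)) abort(paste0(model_kind, " model needs lrc_scores"))
    blocks$lrc <- wide(lrc_scores, "lrc_")
  }

  S <- do.call(cbind, unname(blocks))
  location <- rep(names(blocks), vapply(blocks, ncol, integer(1)))
  location[location == "histone"] <- "histone"
  if (anyDuplicated(colnames(S))) abort("duplicate feature names")

  if (randomize) {
    if (is.null(seed)) abort("randomize = TRUE requires a seed")
    S <- withr::with_seed(seed, {
      apply(S, 2, function(col) col[sample.int(length(col))])
    })
    rownames(S) <- gene_ids
  }

  structure(
    list(gene_ids = gene_ids, feature_names = colnames(S),
         location = setNames(location, colnames(S)),
         S = S, y = setNames(y, gene_ids),
         model_kind = model_kind, condition = condition,
         randomized = randomize),
    class = "regdom_features"
  )
}

#' @export
print.regdom_features <- function(x, ...) {
  cat(sprintf("<regdom_features> %s model%s: %d genes x %d features (%s)\n",
              x$model_kind, if (x$randomized) " [randomized]" else "",
              length(x$gene_ids), length(x$feature_names),
              paste(sprintf("%s: %d", names(table(x$location)),
                            table(x$location)), collapse = ", ")))
  invisible(x)
}

#' @export
as_tibble.regdom_features <- function(x, ...) {
  bind_cols(tibble(gene_id = x$gene_ids, y = unname(x$y)),
            as_tibble(x$S, .name_repair = "minimal"))
}
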