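# A gene's 3D transcriptional domain: the 10-kb proximal promoter, the core
# promoter (-2500..+500 around the TSS), and the distal 5-kb long-range
# contact (LRC) windows reached through Hi-C anchor pairs.

PROXIMAL_LEN <- 10000L
CORE_UP <- 2500L
CORE_DOWN <- 500L
LRC_HALF <- 2500L
LRC_MIN_DIST <- 10000L

#' Define promoter windows for a gene set
#'
#' For a `+` gene with TSS `t` the proximal promoter is `[t-10000, t)` and
#' the core promoter `[t-2500, t+500)`; for a `-` gene both intervals are
#' reflected about the TSS. Windows running past coordinate 0 are clipped
#' and flagged.
#'
#' @param genes Gene tibble from [read_gene_models()] or [generate_study()].
#' @param chrom_lengths Optional named vector of chromosome lengths; when
#'   given, a TSS beyond its chromosome is an error.
#' @return Tibble `gene_id`, `chrom`, `strand`, `tss`, `prox_start`,
#'   `prox_end`, `core_start`, `core_end`, `clipped`.
#' @export
define_promoters <- function(genes, chrom_lengths = NULL) {
  if (!is.null(chrom_lengths)) {
    len <- unname(chrom_lengths[genes$chrom])
    bad <- !is.na(len) & genes$tss >= len
    if (any(bad)) {
      abort(sprintf("TSS beyond chromosome length for gene(s): %s",
                    paste(genes$gene_id[bad], collapse = ", ")))
    }
  }
  plus <- genes$strand == "+"
  t <- genes$tss
  prox_start <- ifelse(plus, t - PROXIMAL_LEN, t)
  prox_end <- ifelse(plus, t, t + PROXIMAL_LEN)
  core_start <- ifelse(plus, t - CORE_UP, t - CORE_DOWN)
  core_end <- ifelse(plus, t + CORE_DOWN, t + CORE_UP)
  clipped <- prox_start < 0 | core_start < 0
  tibble(
    gene_id = genes$gene_id, chrom = genes$chrom, strand = genes$strand,
    tss = t,
    prox_start = as.integer(pmax(prox_start, 0L)),
    prox_end = as.integer(prox_end),
    core_start = as.integer(pmax(core_start, 0L)),
    core_end = as.integer(core_end),
    clipped = clipped
  )
}

#' Vanilla-Coverage normalization of Hi-C contacts
#'
#' Per chromosome, each pair's count is divided by the product of the
#' coverages of its two anchors (coverage of an anchor = sum of raw counts
#' over all pairs touching it), then the result is rescaled so the total
#' normalized mass equals the total raw mass. `method = "sqrt-vc"` divides
#' by the square root of the coverage product instead.
#'
#' @param contacts Tibble from [read_contacts()].
#' @param method `"vc"` (default) or `"sqrt-vc"`.
#' @return `contacts` with a `norm_count` column.
#' @export
vc_normalize <- function(contacts, method = c("vc", "sqrt-vc")) {
  method <- match.arg(method)
  if (any(contacts$raw_count <= 0)) abort("raw_count must be > 0")
  out <- contacts
  out$norm_count <- NA_real_
  for (ch in unique(contacts$chrom)) {
    idx <- which(contacts$chrom == ch)
    sub <- contacts[idx, , drop = FALSE]
    key_a <- paste(sub$start_a, sub$end_a)
    key_b <- paste(sub$start_b, sub$end_b)
    keys <- c(key_a, key_b)
    cov <- tapply(rep(sub$raw_count, 2L), keys, sum)
    denom <- unname(cov[key_a]) * unname(cov[key_b])
    if (method == "sqrt-vc") denom <- sqrt(denom)
    nc <- sub$raw_count / denom
    nc <- nc * sum(sub$raw_count) / sum(nc)
    out$norm_count[idx] <- nc
  }
  out
}

#' Derive long-range contact (LRC) regions
#'
#' Keeps contact pairs in which one 1-kb anchor overlaps a gene's core
#' promoter while the partner anchor's center lies in intergenic space
#' (outside every gene body and proximal promoter window) more than 10 kb
#' from that core promoter (center to nearest core edge). Overlapping
#' partner anchors targeting the same gene are merged by interval union;
#' each merged anchor's center is stretched bidirectionally to a 5-kb
#' window. The window's contact weight `ct` is the sum of the normalized
#' counts of its constituent pairs.
#'
#' @param contacts VC-normalized contacts (must carry `norm_count`).
#' @param promoters Output of [define_promoters()].
#' @param genes Gene tibble carrying `tes` gene-body ends (required for the
#'   intergenic mask).
#' @return Tibble `region_id`, `gene_id`, `chrom`, `start`, `end`, `center`,
#'   `ct` (one row per merged 5-kb LRC window per target gene).
#' @export
derive_lrc_regions <- function(contacts, promoters, genes) {
  if (!"norm_count" %in% names(contacts)) {
    abort("contacts must be VC-normalized first (missing norm_count)")
  }
  if (all(is.na(genes$tes))) {
    abort("gene table lacks tes gene-body ends; cannot build intergenic mask")
  }
  with_body <- genes[!is.na(genes$tes), , drop = FALSE]
  body_start <- pmin(with_body$tss, with_body$tes)
  body_end <- pmax(with_body$tss, with_body$tes)
  mask <- tibble(
    chrom = c(with_body$chrom, promoters$chrom),
    start = c(body_start, promoters$prox_start),
    end = c(body_end, promoters$prox_end)
  )

  res <- list()
  for (ch in unique(contacts$chrom)) {
    cc <- contacts[contacts$chrom == ch, , drop = FALSE]
    pp <- promoters[promoters$chrom == ch, , drop = FALSE]
    mm <- mask[mask$chrom == ch, , drop = FALSE]
    if (nrow(cc) == 0 || nrow(pp) == 0) next
    mask_ir <- IRanges::IRanges(mm$start + 1L, mm$end)
    core_ir <- IRanges::IRanges(pp$core_start + 1L, pp$core_end)
    for (side in c("a", "b")) {
      s <- cc[[paste0("start_", side)]]
      e <- cc[[paste0("end_", side)]]
      os <- cc[[paste0("start_", if (side == "a") "b" else "a")]]
      oe <- cc[[paste0("end_", if (side == "a") "b" else "a")]]
      hit <- IRanges::findOverlaps(IRanges::IRanges(s + 1L, e), core_ir)
      if (length(hit) == 0) next
      qi <- S4Vectors::queryHits(hit)
      gi <- S4Vectors::subjectHits(hit)
      center <- (os[qi] + oe[qi]) %/% 2L
      # intergenic: center not inside any gene body / proximal window
      cir <- IRanges::IRanges(center + 1L, center + 1L)
      in_mask <- IRanges::overlapsAny(cir, mask_ir)
      dist <- pmax(pp$core_start[gi] - center, center - (pp$core_end[gi] - 1L), 0L)
      keep <- !in_mask & dist > LRC_MIN_DIST
      if (!any(keep)) next
      res[[length(res) + 1L]] <- tibble(
        gene_id = pp$gene_id[gi][keep], chrom = ch,
        a_start = os[qi][keep], a_end = oe[qi][keep],
        norm_count = cc$norm_count[qi][keep]
      )
    }
  }
  if (length(res) == 0) {
    return(tibble(region_id = character(), gene_id = character(),
                  chrom = character(), start = integer(), end = integer(),
                  center = integer(), ct = double()))
  }
  hits <- bind_rows(res)

  merged <- hits |>
    group_by(.data$gene_id, .data$chrom) |>
    dplyr::group_modify(function(d, key) {
      ir <- IRanges::IRanges(d$a_start + 1L, d$a_end)
      red <- IRanges::reduce(ir)
      grp <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, red))
      tibble(
        u_start = IRanges::start(red)[seq_along(red)] - 1L,
        u_end = IRanges::end(red)[seq_along(red)],
        ct = as.numeric(tapply(d$norm_count, grp, sum))
      )
    }) |>
    ungroup()

  merged |>
    mutate(center = (.data$u_start + .data$u_end) %/% 2L,
           start = .data$center - LRC_HALF,
           end = .data$center + LRC_HALF) |>
    group_by(.data$gene_id) |>
    mutate(region_id = paste0(.data$gene_id, ":lrc", row_number())) |>
    ungroup() |>
    select("region_id", "gene_id", "chrom", "start", "end", "center", "ct") |>
    arrange(.data$gene_id, .data$start)
}

#' Attach histone scores and activities to LRC regions
#'
#' `hm` is the mean of log2 fold-enrichment over all H3K27ac / H3K4me1 peaks
#' overlapping the 5-kb window (0 when none overlap). The activity of LRC
#' `c` for gene `i` follows the activity-by-contact form
#' `A_ic = (hm_ic * ct_ic) / sum_m (hm_im * ct_im)` over the gene's LRC
#' regions; when the denominator is 0 all of the gene's activities are 0.
#'
#' @param lrcs Tibble from [derive_lrc_regions()].
#' @param peaks Peak tibble carrying `mark` and `fold_enrichment`.
#' @param marks Histone marks that define enhancer activity.
#' @return `lrcs` with `hm` and `activity` columns.
#' @export
attach_activity <- function(lrcs, peaks, marks = c("H3K27ac", "H3K4me1")) {
  pk <- peaks[peaks$mark %in% marks, , drop = FALSE]
  if (nrow(pk) > 0 && any(pk$fold_enrichment <= 0)) {
    abort("fold_enrichment must be > 0 (log2 undefined)")
  }
  lrcs$hm <- mean_log2_fe_overlap(lrcs, pk)
  lrcs |>
    group_by(.data$gene_id) |>
    mutate(activity = {
      w <- .data$hm * .data$ct
      tot <- sum(w)
      if (tot > 0) w / tot else rep(0, length(w))
    }) |>
    ungroup()
}

# mean log2(fold_enrichment) of peaks overlapping each window row; 0 if none
mean_log2_fe_overlap <- function(windows, peaks) {
  out <- numeric(nrow(windows))
  if (nrow(peaks) == 0 || nrow(windows) == 0) return(out)
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    pk <- peaks[peaks$chrom == ch, , drop = FALSE]
    if (nrow(pk) == 0) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(windows$start[wi] + 1L, windows$end[wi]),
      IRanges::IRanges(pk$start + 1L, pk$end)
    )
    if (length(ov) == 0) next
    qh <- S4Vectors::queryHits(ov)
    vals <- log2(pk$fold_enrichment[S4Vectors::subjectHits(ov)])
    m <- tapply(vals, qh, mean)
    out[wi[as.integer(names(m))]] <- as.numeric(m)
  }
  out
}

#' Per-gene promoter histone features
#'
#' For each gene and requested mark, the mean log2 fold-enrichment of peaks
#' overlapping the promoter window (the 10-kb proximal window by default,
#' switchable to the core promoter); genes with no overlapping peak score 0.
#'
#' @param promoters Output of [define_promoters()].
#' @param peaks Peak tibble (`chrom`, `start`, `end`, `mark`,
#'   `fold_enrichment`).
#' @param marks Marks to compute, one feature column each.
#' @param window `"proximal"` (default) or `"core"`.
#' @return Tibble with `gene_id` and one `hist_<mark>` column per mark.
#' @export
promoter_histone_features <- function(promoters, peaks,
                                      marks = c("H3K27ac", "H3K4me1", "H3K4me3",
                                                "H3K27me3", "H3K36me3", "H3K9me3"),
                                      window = c("proximal", "core")) {
  window <- match.arg(window)
  win <- tibble(
    gene_id = promoters$gene_id, chrom = promoters$chrom,
    start = if (window == "proximal") promoters$prox_start else promoters$core_start,
    end = if (window == "proximal") promoters$prox_end else promoters$core_end
  )
  out <- tibble(gene_id = promoters$gene_id)
  for (mk in marks) {
    out[[paste0("hist_", mk)]] <-
      mean_log2_fe_overlap(win, peaks[peaks$mark == mk, , drop = FALSE])
  }
  out
}
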