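# Small fixtures built in code, plus independent oracles.

toy_pwm <- function(id = "M1", mat, tfs = "TFX") {
  if (missing(mat)) {
    # strong 6-bp motif, consensus ACGTAC
    mat <- matrix(2, nrow = 4, ncol = 6, dimnames = list(c("A", "C", "G", "T"), NULL))
    cons <- c(1, 2, 3, 4, 1, 2)
    mat[cbind(cons, 1:6)] <- 30
  }
  list(motif_id = id, matrix = mat, binding_tfs = tfs)
}

pwm_consensus <- function(pwm) {
  paste(c("A", "C", "G", "T")[apply(pwm$matrix, 2, which.max)], collapse = "")
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# Independent brute-force scanner: per-window loops, no shared code with
# scan_motifs beyond base R.
brute_scan <- function(sequences, pwm, threshold = 0.7) {
  counts <- pwm$matrix
  f <- counts
  for (j in seq_len(ncol(counts))) f[, j] <- counts[, j] / sum(counts[, j])
  info <- numeric(ncol(f))
  for (j in seq_len(ncol(f))) {
    for (b in 1:4) {
      if (f[b, j] > 0) info[j] <- info[j] + f[b, j] * log(4 * f[b, j])
    }
  }
  smin <- 0; smax <- 0
  for (j in seq_len(ncol(f))) {
    smin <- smin + min(info[j] * f[, j])
    smax <- smax + max(info[j] * f[, j])
  }
  score_window <- function(win) {
    s <- 0
    for (j in seq_along(win)) {
      b <- match(win[j], c("A", "C", "G", "T"))
      if (is.na(b)) return(NA_real_)
      s <- s + info[j] * f[b, j]
    }
    (s - smin) / (smax - smin)
  }
  L <- ncol(counts)
  out <- list()
  for (rid in names(sequences)) {
    chars <- strsplit(sequences[[rid]], "")[[1]]
    n <- length(chars)
    if (n < L) next
    for (off in 0:(n - L)) {
      win <- chars[(off + 1):(off + L)]
      sc <- score_window(win)
      if (!is.na(sc) && sc >= threshold) {
        out[[length(out) + 1]] <- data.frame(
          motif_id = pwm$motif_id, region_id = rid, offset = off,
          strand = "+", match_score = sc, stringsAsFactors = FALSE)
      }
      win_rc <- chartr("ACGTN", "TGCAN", rev(win))
      sc <- score_window(win_rc)
      if (!is.na(sc) && sc >= threshold) {
        out[[length(out) + 1]] <- data.frame(
          motif_id = pwm$motif_id, region_id = rid, offset = off,
          strand = "-", match_score = sc, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(motif_id = character(), region_id = character(),
                      offset = integer(), strand = character(),
                      match_score = double()))
  }
  df <- do.call(rbind, out)
  df[order(df$motif_id, df$region_id, df$offset, df$strand), ]
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

toy_genes <- function() {
  tibble::tibble(
    gene_id = c("G1", "G2", "G3"),
    chrom = "chr1",
    tss = c(50000L, 250000L, 450000L),
    tes = c(58000L, 242000L, 458000L),
    strand = c("+", "-", "+"),
    deg_label = "up",
    tpm_c1 = c(10, 5, 0), tpm_c2 = c(8, 6, 1), tpm_c3 = c(12, 4, 0.5)
  )
}

# A hand-buildable ensemble tibble accepted by downstream functions.
toy_ensemble <- function(feature, location, mean_rc, significant = TRUE,
                         rcs = NULL, n_runs = 10L) {
  tb <- tibble::tibble(
    feature = feature, location = location, mean_rc = mean_rc,
    n_selected = n_runs,
    rcs = rcs %||% lapply(mean_rc, function(m) rep(m, n_runs)),
    significant = significant
  )
  attr(tb, "n_runs") <- n_runs
  tb
}

`%||%` <- function(a, b) if (is.null(a)) b else a

path_network <- function(edges) {
  net <- regdom:::empty_network()
  net <- regdom:::add_edges(net, edges[[1]], edges[[2]], provenance = "test")
  regdom:::rebuild_vertices(net)
}
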