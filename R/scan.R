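# MATCH-style PWM scanning. A hit's score is the min-max normalized,
# information-weighted similarity between a sequence window and the motif:
#   score = (S_raw - S_min) / (S_max - S_min),
# S_raw = sum_p I(p) * f(p, base_p), I(p) = sum_b f(p,b) * ln(4 f(p,b)),
# S_min/S_max the minimal/maximal attainable sums. Scores live in [0, 1];
# reported hits are those at or above the threshold (0.7 by default, the
# conventional floor for a confident match).

#' Extract region sequences from a genome
#'
#' Pulls the sequence of each region from a FASTA genome (path or
#' `DNAStringSet`), reverse-complementing regions on the `-` strand so that
#' offset 0 is always the region's 5' end.
#'
#' @param genome FASTA path or a `Biostrings::DNAStringSet` named by
#'   chromosome.
#' @param regions Tibble with `region_id`, `chrom`, `start`, `end`
#'   (0-based half-open) and optionally `strand`.
#' @return Named character vector of uppercase sequences.
#' @export
get_region_sequences <- function(genome, regions) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  missing <- setdiff(unique(regions$chrom), names(genome))
  if (length(missing) > 0) {
    abort(paste0("chromosome(s) absent from genome: ",
                 paste(missing, collapse = ", ")))
  }
  strand <- regions$strand %||% rep("+", nrow(regions))
  if (is.null(regions$strand)) strand <- rep("+", nrow(regions))
  out <- character(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    s <- Biostrings::subseq(genome[[regions$chrom[i]]],
                            start = regions$start[i] + 1L,
                            end = regions$end[i])
    if (strand[i] == "-") s <- Biostrings::reverseComplement(s)
    out[i] <- toupper(as.character(s))
  }
  names(out) <- regions$region_id
  out
}

# Information-weighted score matrix W (4+N rows x L), S_min, S_max for a PFM.
match_profile <- function(pfm) {
  f <- sweep(pfm, 2, colSums(pfm), "/")
  info <- colSums(ifelse(f > 0, f * log(4 * f), 0))
  w <- sweep(f, 2, info, "*")
  list(
    w = rbind(w, N = NA_real_), # row 5 poisons windows containing N
    s_min = sum(apply(w, 2, min)),
    s_max = sum(apply(w, 2, max))
  )
}

#' Scan sequences for motif hits
#'
#' Scans both strands of each sequence with every PWM, scoring windows with
#' the min-max normalized information-weighted similarity described above.
#' Windows containing `N` are skipped. For `-` strand hits the reported
#' offset is the window's start on the forward (as-supplied) sequence.
#'
#' @param sequences Named character vector (region_id -> uppercase ACGTN).
#' @param pwms PWM list from [read_pwms()] (or a single record).
#' @param threshold Minimum score to report, in (0, 1]; defaults to 0.7.
#' @return Tibble `motif_id`, `region_id`, `offset`, `strand`, `match_score`.
#' @export
scan_motifs <- function(sequences, pwms, threshold = 0.7) {
  if (!is.null(pwms$motif_id)) pwms <- list(pwms)
  if (threshold <= 0 || threshold > 1) abort("threshold must be in (0, 1]")
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    abort(paste0("invalid characters in sequence(s): ",
                 paste(names(sequences)[bad], collapse = ", ")))
  }
  base_code <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 5L)
  enc <- lapply(sequences, function(s) {
    unname(base_code[strsplit(s, "", fixed = TRUE)[[1]]])
  })
  comp <- c(4L, 3L, 2L, 1L, 5L) # A<->T, C<->G, N->N

  out <- vector("list", 0)
  for (pwm in pwms) {
    prof <- match_profile(pwm$matrix)
    L <- ncol(pwm$matrix)
    rng <- prof$s_max - prof$s_min
    for (rid in names(enc)) {
      x <- enc[[rid]]
      n <- length(x)
      if (n < L) next
      nw <- n - L + 1L
      fwd <- numeric(nw)
      rev <- numeric(nw)
      xr <- comp[rev(x)]
      for (p in seq_len(L)) {
        fwd <- fwd + prof$w[cbind(x[p:(p + nw - 1L)], p)]
        rev <- rev + prof$w[cbind(xr[p:(p + nw - 1L)], p)]
      }
      sc_f <- (fwd - prof$s_min) / rng
      sc_r <- (rev - prof$s_min) / rng
      # reverse-strand window j (on reversed seq) starts at n - L - j + 2 fwd
      keep_f <- which(!is.na(sc_f) & sc_f >= threshold)
      keep_r <- which(!is.na(sc_r) & sc_r >= threshold)
      if (length(keep_f) + length(keep_r) == 0) next
      out[[length(out) + 1L]] <- tibble(
        motif_id = pwm$motif_id,
        region_id = rid,
        offset = c(keep_f - 1L, n - L + 1L - keep_r),
        strand = rep(c("+", "-"), c(length(keep_f), length(keep_r))),
        match_score = c(sc_f[keep_f], sc_r[keep_r])
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(motif_id = character(), region_id = character(),
                  offset = integer(), strand = character(),
                  match_score = double()))
  }
  bind_rows(out) |> arrange(.data$motif_id, .data$region_id, .data$offset)
}
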