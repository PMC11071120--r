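# Readers/writers for the external file dialects the pipeline touches.
# All genomic intervals are 0-based half-open throughout the package,
# regardless of source dialect; a TSS is a single 0-based position.

#' Read gene models
#'
#' Parses a tab-separated gene table with columns `gene_id`, `chrom`, `tss`,
#' `tes`, `strand`, optionally `deg_label`, followed by one TPM column per
#' condition. `tss`/`tes` are 0-based; `tes` (transcript end site) bounds the
#' gene body used for the intergenic mask.
#'
#' @param path Path to a TSV file with a header row.
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `tss`, `tes`,
#'   `strand`, `deg_label` (`NA` when absent) and one numeric `tpm_<cond>`
#'   column per condition.
#' @export
read_gene_models <- function(path) {
  df <- read_tsv_strict(path)
  required <- c("gene_id", "chrom", "tss", "strand")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0("gene table ", path, " lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  meta_cols <- intersect(c("gene_id", "chrom", "tss", "tes", "strand", "deg_label"),
                         names(df))
  tpm_cols <- setdiff(names(df), meta_cols)
  if (!"tes" %in% names(df)) df$tes <- NA_integer_
  if (!"deg_label" %in% names(df)) df$deg_label <- NA_character_
  df <- validate_gene_models(df, tpm_cols, path)
  # canonical column order; TPM columns prefixed tpm_ if not already
  plain <- !startsWith(tpm_cols, "tpm_")
  names(df)[match(tpm_cols[plain], names(df))] <- paste0("tpm_", tpm_cols[plain])
  tpm_cols[plain] <- paste0("tpm_", tpm_cols[plain])
  select(df, "gene_id", "chrom", "tss", "tes", "strand", "deg_label",
         dplyr::all_of(tpm_cols))
}

validate_gene_models <- function(df, tpm_cols, path = "<genes>") {
  bad_row <- function(i, why) {
    abort(sprintf("%s line %d: %s", path, i + 1L, why)) # +1 for header
  }
  if (anyDuplicated(df$gene_id)) {
    dup <- df$gene_id[duplicated(df$gene_id)][1]
    abort(sprintf("%s: duplicated gene_id '%s'", path, dup))
  }
  df$tss <- parse_int_col(df$tss, "tss", path)
  df$tes <- suppressWarnings(as.integer(df$tes)) # optional, NA allowed
  if (any(df$tss < 0)) bad_row(which(df$tss < 0)[1], "negative tss")
  if (!all(df$strand %in% c("+", "-"))) {
    bad_row(which(!df$strand %in% c("+", "-"))[1], "strand must be + or -")
  }
  for (cc in tpm_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v)) bad_row(which(is.na(v))[1], paste0("non-numeric TPM in ", cc))
    if (any(v < 0)) bad_row(which(v < 0)[1], paste0("negative TPM in ", cc))
    df[[cc]] <- v
  }
  df
}

#' Read ENCODE narrowPeak files
#'
#' Reads the BED6+4 narrowPeak dialect: `chrom start end name score strand
#' signalValue pValue qValue peak`, where `signalValue` is fold-enrichment
#' and `qValue` is -log10 of the q-value. Coordinates stay 0-based half-open.
#'
#' @param path Path to a narrowPeak file (no header).
#' @param mark Histone mark label to attach (e.g. `"H3K27ac"`); defaults to
#'   the file name stem.
#' @param filter If `TRUE`, keep only peaks with q-value < 0.05 and
#'   fold-enrichment > 2 (both strict, as conventional for ChIP-seq peak
#'   retention).
#' @param blacklist Optional tibble of BED intervals (`chrom`, `start`,
#'   `end`); peaks overlapping any blacklisted interval are dropped.
#' @return Tibble with `chrom`, `start`, `end`, `mark`, `fold_enrichment`,
#'   `qvalue` (the linear-scale q-value).
#' @export
read_narrowpeak <- function(path, mark = NULL, filter = FALSE, blacklist = NULL) {
  cols <- c("chrom", "start", "end", "name", "score", "strand",
            "signalValue", "pValue", "qValue", "peak")
  df <- suppressWarnings(readr::read_tsv(
    path, col_names = cols, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  ))
  if (nrow(df) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  mark = character(), fold_enrichment = double(),
                  qvalue = double()))
  }
  if (ncol(df) < 10 || anyNA(df$peak)) {
    abort(paste0(path, ": narrowPeak requires 10 columns (BED6+4)"))
  }
  mark <- mark %||% sub("\\.[^.]*$", "", basename(path))
  out <- tibble(
    chrom = df$chrom,
    start = parse_int_col(df$start, "start", path),
    end = parse_int_col(df$end, "end", path),
    mark = mark,
    fold_enrichment = as.numeric(df$signalValue),
    neglog10_q = as.numeric(df$qValue)
  )
  if (any(out$start >= out$end)) abort(paste0(path, ": start must be < end"))
  if (any(out$fold_enrichment <= 0)) {
    abort(paste0(path, ": fold_enrichment (signalValue) must be > 0"))
  }
  out$qvalue <- 10^(-out$neglog10_q)
  out$neglog10_q <- NULL
  if (filter) {
    # q < 0.05 via -log10 q > -log10(0.05); ties at exactly 0.05 excluded
    out <- filter(out, -log10(.data$qvalue) > -log10(0.05),
                  .data$fold_enrichment > 2)
  }
  if (!is.null(blacklist)) {
    out <- subtract_blacklist(out, blacklist)
  }
  out
}

subtract_blacklist <- function(peaks, blacklist) {
  if (nrow(peaks) == 0 || nrow(blacklist) == 0) return(peaks)
  keep <- rep(TRUE, nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    bl <- blacklist[blacklist$chrom == ch, , drop = FALSE]
    if (nrow(bl) == 0) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(peaks$start[pi] + 1L, peaks$end[pi]),
      IRanges::IRanges(bl$start + 1L, bl$end)
    )
    keep[pi[unique(S4Vectors::queryHits(ov))]] <- FALSE
  }
  peaks[keep, , drop = FALSE]
}

#' Read a BED file (3+ columns) as a blacklist / mask
#'
#' @param path Path to a BED file (no header, 0-based half-open).
#' @return Tibble `chrom`, `start`, `end`.
#' @export
read_bed_mask <- function(path) {
  df <- suppressWarnings(readr::read_tsv(
    path, col_names = FALSE, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  ))
  if (ncol(df) < 3) abort(paste0(path, ": BED needs at least 3 columns"))
  tibble(chrom = df[[1]],
         start = parse_int_col(df[[2]], "start", path),
         end = parse_int_col(df[[3]], "end", path))
}

#' Read Hi-C contact pairs (BEDPE-like)
#'
#' Expects tab-separated columns `chrom_a start_a end_a chrom_b start_b
#' end_b count` (header optional and auto-detected). Interchromosomal rows
#' are dropped with a message; duplicate pairs are retained (aggregation is
#' downstream).
#'
#' @param path Path to the contact table.
#' @return Tibble `chrom`, `start_a`, `end_a`, `start_b`, `end_b`,
#'   `raw_count` of intrachromosomal pairs.
#' @export
read_contacts <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("chrom", first, ignore.case = TRUE)
  cols <- c("chrom_a", "start_a", "end_a", "chrom_b", "start_b", "end_b", "count")
  df <- suppressWarnings(readr::read_tsv(
    path, col_names = if (has_header) TRUE else cols, skip = 0,
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  ))
  if (has_header) names(df)[seq_along(cols)] <- cols
  if (ncol(df) < 7) abort(paste0(path, ": contact table needs 7 columns"))
  n0 <- nrow(df)
  inter <- df$chrom_a != df$chrom_b
  if (any(inter)) {
    inform(sprintf("read_contacts: dropped %d interchromosomal pair(s)",
                   sum(inter)))
    df <- df[!inter, , drop = FALSE]
  }
  out <- tibble(
    chrom = df$chrom_a,
    start_a = parse_int_col(df$start_a, "start_a", path),
    end_a = parse_int_col(df$end_a, "end_a", path),
    start_b = parse_int_col(df$start_b, "start_b", path),
    end_b = parse_int_col(df$end_b, "end_b", path),
    raw_count = as.numeric(df$count)
  )
  if (anyNA(out$raw_count)) abort(paste0(path, ": non-numeric contact count"))
  if (any(out$raw_count <= 0)) {
    abort(paste0(path, ": contact counts must be > 0"))
  }
  out
}

#' Read position frequency matrices (JASPAR PFM text) with a TF map
#'
#' PFM blocks start with `>motif_id` and carry four rows of counts in
#' A, C, G, T order; rows may be bare numbers or the JASPAR
#' `A [ 1 2 3 ]` style. The TF map is a two-column TSV
#' `motif_id<TAB>tf_gene_id` (many-to-many). Motifs without any mapped TF
#' are dropped with a warning, since a TFBS with no binding TF cannot be
#' scored.
#'
#' @param path_pfm Path to the PFM text file.
#' @param path_tf_map Path to the motif-to-TF map TSV (header optional).
#' @return A named list of PWM records, each a list with `motif_id`,
#'   `matrix` (4 x L count matrix, rows A/C/G/T) and `binding_tfs`
#'   (character vector).
#' @export
read_pwms <- function(path_pfm, path_tf_map) {
  lines <- readLines(path_pfm)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0) abort(paste0(path_pfm, ": no '>' motif headers"))
  ends <- c(starts[-1] - 1L, length(lines))
  pwms <- purrr::map2(starts, ends, function(s, e) {
    motif_id <- sub("^>\\s*", "", lines[s])
    motif_id <- strsplit(motif_id, "\\s+")[[1]][1]
    body <- lines[(s + 1L):e]
    if (length(body) != 4) {
      abort(sprintf("%s: motif %s needs exactly 4 count rows", path_pfm, motif_id))
    }
    rows <- lapply(body, parse_pfm_row, path = path_pfm)
    if (length(unique(lengths(rows))) != 1) {
      abort(sprintf("%s: motif %s has ragged count rows", path_pfm, motif_id))
    }
    mat <- do.call(rbind, rows)
    rownames(mat) <- c("A", "C", "G", "T")
    if (ncol(mat) < 4) {
      abort(sprintf("%s: motif %s shorter than 4 positions", path_pfm, motif_id))
    }
    if (any(mat < 0)) abort(sprintf("%s: negative count in %s", path_pfm, motif_id))
    if (any(colSums(mat) == 0)) {
      abort(sprintf("%s: motif %s has a zero-sum column", path_pfm, motif_id))
    }
    list(motif_id = motif_id, matrix = mat, binding_tfs = character())
  })
  names(pwms) <- purrr::map_chr(pwms, "motif_id")

  map <- read_tf_map(path_tf_map)
  for (i in seq_along(pwms)) {
    pwms[[i]]$binding_tfs <-
      unique(map$tf_gene_id[map$motif_id == pwms[[i]]$motif_id])
  }
  unmapped <- purrr::map_int(pwms, ~ length(.x$binding_tfs)) == 0
  if (any(unmapped)) {
    warn(sprintf("read_pwms: dropping %d motif(s) with no mapped TF: %s",
                 sum(unmapped), paste(names(pwms)[unmapped], collapse = ", ")))
    pwms <- pwms[!unmapped]
  }
  pwms
}

parse_pfm_row <- function(line, path) {
  line <- sub("^\\s*[ACGTacgt]\\s*", "", line)
  line <- gsub("[\\[\\]]", " ", line, perl = TRUE)
  toks <- strsplit(trimws(line), "\\s+")[[1]]
  vals <- suppressWarnings(as.numeric(toks))
  if (anyNA(vals)) abort(paste0(path, ": non-numeric PFM entry '", line, "'"))
  vals
}

read_tf_map <- function(path) {
  df <- suppressWarnings(readr::read_tsv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  ))
  if (!all(c("motif_id", "tf_gene_id") %in% names(df))) {
    # headerless two-column form
    df <- suppressWarnings(readr::read_tsv(
      path, col_names = c("motif_id", "tf_gene_id"),
      show_col_types = FALSE, progress = FALSE,
      col_types = readr::cols(.default = readr::col_character())
    ))
  }
  df[, c("motif_id", "tf_gene_id")]
}

#' Read protein-protein interaction edges
#'
#' Expects TSV columns `protein_a`, `protein_b`, `score` (header optional).
#' Scores must lie in \[0, 1\] (STRING-style confidence scaled to 1);
#' self-interactions are rejected.
#'
#' @param path Path to the PPI edge table.
#' @return Tibble `protein_a`, `protein_b`, `score`.
#' @export
read_ppi <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("protein", first, ignore.case = TRUE)
  df <- suppressWarnings(readr::read_tsv(
    path, col_names = if (has_header) TRUE else c("protein_a", "protein_b", "score"),
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  ))
  out <- tibble(protein_a = df[[1]], protein_b = df[[2]],
                score = as.numeric(df[[3]]))
  if (anyNA(out$score) || any(out$score < 0 | out$score > 1)) {
    abort(paste0(path, ": PPI scores must be numeric in [0, 1]"))
  }
  if (any(out$protein_a == out$protein_b)) {
    abort(paste0(path, ": self-interaction edges are not allowed"))
  }
  out
}

#' Read a precomputed motif-hit table
#'
#' The scanner ([scan_motifs()]) writes/consumes hits as TSV with columns
#' `motif_id`, `region_id`, `offset` (0-based, region-local), `strand`,
#' `match_score`.
#'
#' @param path Path to the hits TSV.
#' @return Tibble of hits.
#' @export
read_hits <- function(path) {
  df <- read_tsv_strict(path)
  need <- c("motif_id", "region_id", "offset", "strand", "match_score")
  if (!all(need %in% names(df))) {
    abort(paste0(path, ": hits table needs columns ",
                 paste(need, collapse = ", ")))
  }
  tibble(motif_id = as.character(df$motif_id),
         region_id = as.character(df$region_id),
         offset = parse_int_col(df$offset, "offset", path),
         strand = as.character(df$strand),
         match_score = as.numeric(df$match_score))
}

#' Write a tibble as TSV
#'
#' Thin wrapper used for all tabular outputs so that round-tripping through
#' disk reproduces collections field-for-field.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(x)
}

# -- shared low-level helpers -------------------------------------------------

read_tsv_strict <- function(path) {
  df <- suppressWarnings(readr::read_tsv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  ))
  as_tibble(df)
}

parse_int_col <- function(x, what, path) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v)) {
    abort(sprintf("%s line %d: non-numeric %s", path,
                  which(is.na(v))[1] + 1L, what))
  }
  if (any(v != floor(v))) {
    abort(sprintf("%s: %s must be integer-valued", path, what))
  }
  as.integer(v)
}
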