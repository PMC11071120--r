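# Cofactor-TF-gene networks. Vertices are typed: target genes ("gene"),
# TFs binding significant promoter features ("prmTF"), TFs binding
# significant LRC features ("lrcTF") and PPI cofactors ("cofactor"). A TF
# gene active in both compartments contributes two typed vertices. Edges
# are binary, undirected, with no self-loops.

vertex_id <- function(type, name) paste(type, name, sep = ":")

empty_network <- function() {
  structure(
    list(vertices = tibble(id = character(), type = character(),
                           name = character()),
         edges = tibble(from = character(), to = character(),
                        weight = double(), provenance = character())),
    class = "regdom_network"
  )
}

#' @export
print.regdom_network <- function(x, ...) {
  tt <- table(x$vertices$type)
  cat(sprintf("<regdom_network> %d vertices (%s), %d edges\n",
              nrow(x$vertices),
              paste(sprintf("%s: %d", names(tt), tt), collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}

add_edges <- function(net, from, to, provenance, weight = 1) {
  keep <- from != to
  lo <- pmin(from[keep], to[keep])
  hi <- pmax(from[keep], to[keep])
  e <- tibble(from = lo, to = hi, weight = weight, provenance = provenance)
  net$edges <- distinct(bind_rows(net$edges, e),
                        .data$from, .data$to, .keep_all = TRUE)
  net
}

rebuild_vertices <- function(net) {
  ids <- sort(unique(c(net$edges$from, net$edges$to)))
  net$vertices <- tibble(
    id = ids,
    type = sub(":.*$", "", ids),
    name = sub("^[^:]*:", "", ids)
  )
  net
}

#' Build the TF-gene network from significant features
#'
#' For every Bonferroni-significant TFBS feature, connects each TF that
#' binds the motif (and is expressed above `tpm_threshold` in at least one
#' condition) to every modeled gene whose promoter (for `prm` features) or
#' LRC windows (for `lrc` features) contain a hit of that motif.
#'
#' @param ensembles Tested ensemble ([test_rc_significance()]).
#' @param prm_hits,lrc_hits Hit tibbles used to build the features.
#' @param lrcs LRC tibble mapping LRC region ids to genes.
#' @param pwms PWM list (binding TFs).
#' @param genes Gene tibble with `tpm_` columns (TF expression filter).
#' @param gene_ids Genes eligible as targets (default: the modeled genes in
#'   `prm_hits`/`lrcs`).
#' @param tpm_threshold TF expression threshold (TPM, strict >).
#' @return A `regdom_network`.
#' @export
build_tf_gene_network <- function(ensembles, prm_hits, lrc_hits = NULL,
                                  lrcs = NULL, pwms, genes,
                                  gene_ids = NULL, tpm_threshold = 3) {
  sig <- ensembles[ensembles$significant & ensembles$location %in% c("prm", "lrc"), ]
  net <- empty_network()
  if (nrow(sig) == 0) return(net)
  tpm_cols <- grep("^tpm_", names(genes), value = TRUE)
  max_tpm <- apply(as.matrix(genes[, tpm_cols, drop = FALSE]), 1, max)
  expressed <- setNames(max_tpm > tpm_threshold, genes$gene_id)

  lrc_gene <- if (!is.null(lrcs)) setNames(lrcs$gene_id, lrcs$region_id) else NULL
  for (i in seq_len(nrow(sig))) {
    loc <- sig$location[i]
    motif <- sub("^(prm|lrc)_", "", sig$feature[i])
    tfs <- pwms[[motif]]$binding_tfs
    tfs <- tfs[!is.na(expressed[tfs]) & expressed[tfs]]
    if (length(tfs) == 0) {
      warn(paste0("significant feature ", sig$feature[i],
                  " has no expressed binding TF"))
      next
    }
    if (loc == "prm") {
      targets <- unique(prm_hits$region_id[prm_hits$motif_id == motif])
    } else {
      if (is.null(lrc_hits) || is.null(lrc_gene)) next
      rids <- lrc_hits$region_id[lrc_hits$motif_id == motif]
      targets <- unique(unname(lrc_gene[rids]))
    }
    if (!is.null(gene_ids)) targets <- intersect(targets, gene_ids)
    if (length(targets) == 0) next
    grid <- tidyr::expand_grid(tf = tfs, gene = targets)
    grid <- grid[grid$tf != grid$gene, , drop = FALSE]
    if (nrow(grid) == 0) next
    net <- add_edges(net,
                     vertex_id(paste0(loc, "TF"), grid$tf),
                     vertex_id("gene", grid$gene),
                     provenance = paste0(loc, "-binding"))
  }
  rebuild_vertices(net)
}

#' Extend a TF-gene network with PPI cofactors
#'
#' Adds a cofactor vertex for every protein that physically interacts
#' (PPI score strictly above `ppi_threshold`) with a TF already in the
#' network and is expressed above `tpm_threshold` in at least one
#' condition. Cofactors connect only to TF vertices, never to genes;
#' proteins already present as network TFs are not duplicated as cofactors.
#'
#' @param network A `regdom_network` with TF vertices.
#' @param ppi PPI tibble ([read_ppi()]).
#' @param genes Gene tibble with `tpm_` columns.
#' @param ppi_threshold Confidence threshold (strict >), default 0.4.
#' @param tpm_threshold Expression threshold (strict >), default 3 TPM.
#' @return The extended `regdom_network`.
#' @export
extend_with_cofactors <- function(network, ppi, genes, ppi_threshold = 0.4,
                                  tpm_threshold = 3) {
  tf_rows <- network$vertices[network$vertices$type %in% c("prmTF", "lrcTF"), ]
  if (nrow(tf_rows) == 0) abort("network has no TF vertices")
  tpm_cols <- grep("^tpm_", names(genes), value = TRUE)
  max_tpm <- setNames(apply(as.matrix(genes[, tpm_cols, drop = FALSE]), 1, max),
                      genes$gene_id)
  tf_names <- unique(tf_rows$name)
  pp <- ppi[ppi$score > ppi_threshold, , drop = FALSE]
  # orient so that protein_a is the network TF
  both <- bind_rows(pp, rename(pp, protein_a = "protein_b", protein_b = "protein_a"))
  both <- both[both$protein_a %in% tf_names, , drop = FALSE]
  both <- both[!both$protein_b %in% tf_names, , drop = FALSE]
  ok <- !is.na(max_tpm[both$protein_b]) & max_tpm[both$protein_b] > tpm_threshold
  both <- both[ok, , drop = FALSE]
  if (nrow(both) == 0) return(network)
  links <- inner_join(both, tf_rows[, c("id", "name")],
                      by = c(protein_a = "name"), relationship = "many-to-many")
  net <- add_edges(network, links$id,
                   vertex_id("cofactor", links$protein_b),
                   provenance = "ppi")
  rebuild_vertices(net)
}

#' Densify a network with 2-hop neighbor edges
#'
#' For each vertex (in lexicographic order), adds unit-weight edges to its
#' 2-hop neighbors, most-shared-neighbors first (ties broken by vertex id),
#' stopping when the vertex's degree reaches `max_added_per_vertex`.
#' Original edges are never modified.
#'
#' @param network A `regdom_network`.
#' @param max_added_per_vertex Degree cap while densifying (default 1000).
#' @return The densified `regdom_network` (new edges have provenance
#'   `"depth2"`).
#' @export
reconstruct_depth2 <- function(network, max_added_per_vertex = 1000L) {
  ids <- network$vertices$id
  adj <- lapply(setNames(ids, ids), function(v) character(0))
  for (i in seq_len(nrow(network$edges))) {
    f <- network$edges$from[i]; t <- network$edges$to[i]
    adj[[f]] <- c(adj[[f]], t)
    adj[[t]] <- c(adj[[t]], f)
  }
  deg <- lengths(adj)
  new_from <- character(0); new_to <- character(0)
  for (v in sort(ids)) {
    if (deg[[v]] >= max_added_per_vertex) next
    nb <- adj[[v]]
    two <- unlist(adj[nb], use.names = FALSE)
    two <- two[two != v & !two %in% nb]
    if (length(two) == 0) next
    shared <- sort(table(two), decreasing = TRUE)
    cand <- names(shared)[order(-as.integer(shared), names(shared))]
    for (u in cand) {
      if (deg[[v]] >= max_added_per_vertex) break
      if (deg[[u]] >= max_added_per_vertex) next
      new_from <- c(new_from, v); new_to <- c(new_to, u)
      adj[[v]] <- c(adj[[v]], u); adj[[u]] <- c(adj[[u]], v)
      deg[[v]] <- deg[[v]] + 1L; deg[[u]] <- deg[[u]] + 1L
    }
  }
  if (length(new_from) > 0) {
    network <- add_edges(network, new_from, new_to, provenance = "depth2")
  }
  rebuild_vertices(network)
}

#' Convert a network to an igraph object
#'
#' @param network A `regdom_network`.
#' @return An undirected `igraph` graph with a `type` vertex attribute.
#' @export
as_igraph <- function(network) {
  g <- igraph::graph_from_data_frame(
    network$edges[, c("from", "to", "weight")],
    directed = FALSE, vertices = network$vertices
  )
  g
}
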