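#' Extract an aligned window of read sequences
#'
#' Returns the window-restricted sequences (on the contig strand) of every
#' read whose gapless alignment fully spans `[start, start + length)` on
#' `contig_id`.  These equal-length sequences are the haplotype sample the
#' ancestry network is built from.
#'
#' @param alignments A `read_alignments` object.
#' @param contig_id Contig to window.
#' @param start 0-based window start.
#' @param length Window length.
#' @return Named character vector of window sequences (>= 3 required).
#' @export
extract_window <- function(alignments, contig_id, start, length) {
  a <- alignments[alignments$contig_id == contig_id, , drop = FALSE]
  span <- a$offset <= start &
    (a$offset + nchar(a$oriented)) >= (start + length)
  a <- a[span, , drop = FALSE]
  if (nrow(a) < 3L)
    stop("fewer than 3 reads span the window [", start, ", ",
         start + length, ") on ", contig_id)
  out <- substr(a$oriented, start - a$offset + 1L, start - a$offset + length)
  names(out) <- a$read_id
  out
}

#' Highest-depth window of a contig
#'
#' Default window choice for the ancestry network: the `length`-base
#' window with maximal summed pileup depth (leftmost on ties).
#'
#' @param columns Pileup columns of one contig.
#' @param length Window length.
#' @return 0-based start position.
#' @export
highest_depth_window <- function(columns, length = 100L) {
  depth <- columns$depth[order(columns$pos)]
  L <- base::length(depth)
  if (L < length) stop("contig shorter than window")
  cs <- cumsum(depth)
  win <- cs[length:L] - c(0, cs[seq_len(L - length)])
  which.max(win) - 1L
}

#' Collapse identical sequences into haplotypes
#'
#' @param sequences Equal-length character vector.
#' @return data.frame of class `haplotypes` with `sequence` and
#'   `multiplicity`, ordered by descending multiplicity then sequence;
#'   multiplicities sum to the input count.
#' @export
collapse_identical <- function(sequences) {
  if (length(unique(nchar(sequences))) > 1L)
    stop("sequences must have equal length")
  tab <- table(sequences)
  out <- data.frame(sequence = names(tab), multiplicity = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$multiplicity, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("haplotypes", "data.frame")
  out
}

# Pairwise Hamming distances between equal-length sequences.
hamming_matrix <- function(seqs) {
  n <- length(seqs)
  chars <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  d <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- sum(chars[i, ] != chars[j, ])
    }
  }
  d
}

#' Build the ancestor-descendant network of a haplotype sample
#'
#' A transparent, deterministic surrogate for Bayesian ancestral-network
#' inference: haplotypes are connected by a minimum spanning tree on
#' pairwise Hamming distances, rooted at the multiplicity-weighted medoid
#' (the haplotype minimizing the sum of distances to all copies of all
#' others; ties to highest multiplicity, then lexicographic sequence), and
#' edges are directed away from the root as ancestor -> descendant.  The
#' total edge weight is minimal over all spanning trees.  This reproduces
#' the qualitative star-versus-chain readout of ancestral expansion
#' networks; it is *not* a posterior inference.
#'
#' @param haplotypes A [collapse_identical()] result (>= 2 haplotypes,
#'   no duplicates).
#' @return Object of class `ancestry_network`: list with `nodes`
#'   (data.frame `id`, `sequence`, `multiplicity`), `root` (node id) and
#'   `edges` (data.frame `parent`, `child`, `distance`,
#'   `child_multiplicity`).
#' @export
build_arborescence <- function(haplotypes) {
  stopifnot(inherits(haplotypes, "data.frame"),
            all(c("sequence", "multiplicity") %in% names(haplotypes)))
  if (anyDuplicated(haplotypes$sequence))
    stop("duplicate haplotypes; collapse_identical() them first")
  n <- nrow(haplotypes)
  if (n < 2L) stop("need at least 2 haplotypes")
  # canonical node order makes the result invariant to input order
  h <- haplotypes[order(-haplotypes$multiplicity, haplotypes$sequence), ,
                  drop = FALSE]
  d <- hamming_matrix(h$sequence)
  wsum <- as.vector(d %*% h$multiplicity)
  root <- which.min(wsum)  # first minimum = highest mult, then lexicographic
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  mst <- igraph::mst(g, weights = igraph::E(g)$weight, algorithm = "prim")
  # direct edges away from the root
  bfs <- igraph::bfs(mst, root = root, father = TRUE)
  father <- as.integer(bfs$father)
  ids <- sprintf("h%d", seq_len(n))
  child <- setdiff(seq_len(n), root)
  edges <- data.frame(parent = ids[father[child]], child = ids[child],
                      distance = d[cbind(father[child], child)],
                      child_multiplicity = h$multiplicity[child],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$parent, edges$child), , drop = FALSE]
  rownames(edges) <- NULL
  net <- structure(list(
    nodes = data.frame(id = ids, sequence = h$sequence,
                       multiplicity = h$multiplicity, stringsAsFactors = FALSE),
    root = ids[root], edges = edges), class = "ancestry_network")
  validate_arborescence(net)
  net
}

# Invariants every emitted network must satisfy.
validate_arborescence <- function(net) {
  n <- nrow(net$nodes)
  stopifnot(nrow(net$edges) == n - 1L,
            all(net$edges$distance >= 1L),
            !net$root %in% net$edges$child,
            !anyDuplicated(net$edges$child))
  # root-reachability: walk parents back from every node
  parent_of <- setNames(net$edges$parent, net$edges$child)
  for (id in net$nodes$id) {
    seen <- character(0)
    cur <- id
    while (cur != net$root) {
      if (cur %in% seen || !cur %in% names(parent_of))
        stop("network is not an arborescence rooted at ", net$root)
      seen <- c(seen, cur)
      cur <- parent_of[[cur]]
    }
  }
  invisible(net)
}

#' Expansion signature of an ancestry network
#'
#' A recent population expansion leaves one ancestral haplotype spawning
#' many descendants: the network is a star.  `star_score` is the maximum
#' out-degree over `(nodes - 1)`; 1 is a perfect star, values near 0 a
#' chain.
#'
#' @param network A [build_arborescence()] result.
#' @return list with `max_out_degree` and `star_score`.
#' @export
expansion_score <- function(network) {
  stopifnot(inherits(network, "ancestry_network"))
  n <- nrow(network$nodes)
  out_deg <- table(factor(network$edges$parent, levels = network$nodes$id))
  mx <- max(as.integer(out_deg))
  list(max_out_degree = mx, star_score = mx / (n - 1L))
}

#' Write an ancestry network to edge-list TSV (and optional GraphML)
#'
#' @param network A [build_arborescence()] result.
#' @param path TSV output path.
#' @param graphml Optional GraphML output path.
#' @return Invisibly, the paths written.
#' @export
write_ancestry_network <- function(network, path, graphml = NULL) {
  write.table(network$edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(graphml)) {
    g <- igraph::graph_from_data_frame(network$edges, directed = TRUE,
                                       vertices = network$nodes)
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(c(path, graphml))
}
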