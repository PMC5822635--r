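#' @section Read containers:
#' Reads move through the pipeline as [Biostrings::DNAStringSet] /
#' [Biostrings::QualityScaledDNAStringSet] objects; internal kernels work
#' on plain named character vectors.
#' @noRd
as_read_seqs <- function(reads) {
  if (is.character(reads)) {
    if (is.null(names(reads)))
      names(reads) <- sprintf("read%06d", seq_along(reads))
    return(reads)
  }
  s <- as.character(reads)
  if (is.null(names(s))) names(s) <- sprintf("read%06d", seq_along(s))
  s
}

#' Quality-filter shotgun reads
#'
#' Trims the trailing (3') run of bases with Phred quality below
#' `q_threshold` from each read and drops reads whose trimmed length falls
#' below `min_length`.  FASTA input (reads without qualities) passes
#' through unfiltered with a warning, mirroring the pass-through contract
#' for quality-less data.
#'
#' @param reads A [Biostrings::QualityScaledDNAStringSet] (FASTQ) or
#'   [Biostrings::DNAStringSet] (FASTA).
#' @param q_threshold Phred threshold below which 3' bases are trimmed.
#' @param min_length Minimum surviving read length.
#' @return Filtered reads of the same class, with attributes `n_kept` and
#'   `n_dropped`.
#' @export
quality_filter <- function(reads, q_threshold = 30L, min_length = 80L) {
  if (!methods::is(reads, "QualityScaledXStringSet")) {
    warning("input has no base qualities (FASTA); passing reads through unfiltered")
    attr(reads, "n_kept") <- length(reads)
    attr(reads, "n_dropped") <- 0L
    return(reads)
  }
  qints <- methods::as(Biostrings::quality(reads), "IntegerList")
  keep_len <- vapply(qints, function(q) {
    ok <- which(q >= q_threshold)
    if (length(ok)) max(ok) else 0L
  }, integer(1L))
  keep <- keep_len >= min_length
  out <- IRanges::narrow(reads[keep], start = 1L, end = keep_len[keep])
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  message(sum(keep), " reads kept, ", sum(!keep), " dropped by quality filter")
  out
}

#' Subsample reads to a target genome coverage
#'
#' Retains a uniform random subset whose total base count approximates
#' `target_coverage * genome_size` (the largest prefix of a random
#' permutation whose cumulative bases do not exceed the target).
#'
#' @param reads Read set (any container accepted by the pipeline).
#' @param genome_size Genome size in bases (> 0).
#' @param target_coverage Fold coverage to retain.
#' @param seed Optional integer seed.
#' @return Subset of `reads`; all reads (with a warning) if the request
#'   exceeds what is available.
#' @export
subsample <- function(reads, genome_size, target_coverage = 1, seed = NULL) {
  stopifnot_scalar_num(genome_size, "genome_size", min = 0, strict = TRUE)
  widths <- if (is.character(reads)) nchar(reads) else Biostrings::width(reads)
  target <- target_coverage * genome_size
  if (sum(widths) <= target) {
    warning("requested coverage exceeds available reads; returning all reads")
    return(reads)
  }
  with_seed_if(seed, {
    ord <- sample.int(length(reads))
    n_take <- findInterval(target, cumsum(widths[ord]) - 1e-9)
    reads[sort(ord[seq_len(n_take)])]
  })
}

#' Best local-alignment similarity between two reads
#'
#' Exact Smith-Waterman local alignment (match +1, mismatch -1, gap open
#' -5, gap extend -2) of `a` against both orientations of `b`; similarity
#' is matches over aligned columns, and `orientation` records the winning
#' strand ("forward" on ties).
#'
#' @param a,b Character scalars or `DNAString`s.
#' @return list with `similarity` (in `[0, 1]`), `overlap_length` (aligned
#'   columns) and `orientation` ("forward"/"reverse").
#' @export
pairwise_similarity <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  stopifnot(nzchar(a), nzchar(b))
  fwd <- local_alignment(a, b)
  rev <- local_alignment(a, revcomp(b))
  if (rev$score > fwd$score) {
    list(similarity = rev$identity, overlap_length = rev$length,
         orientation = "reverse")
  } else {
    list(similarity = fwd$identity, overlap_length = fwd$length,
         orientation = "forward")
  }
}

local_alignment <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = 5, gapExtension = 2)
  # alignment length including gap columns
  len <- nchar(as.character(Biostrings::alignedPattern(aln)))
  list(score = Biostrings::score(aln),
       identity = if (len > 0) Biostrings::nmatch(aln) / len else 0,
       length = len)
}

#' Build the all-to-all read similarity graph
#'
#' An undirected edge joins two reads when their best gapless (default) or
#' Smith-Waterman (`method = "exact"`) alignment over either orientation
#' reaches `min_similarity` identity over at least `min_overlap_fraction`
#' of the shorter read.  The default path seeds candidate pairs with shared
#' `seed_kmer`-mers and evaluates the most k-mer-supported diagonals, which
#' is exact for substitution-only differences and a documented heuristic
#' otherwise; `method = "exact"` performs all-pairs local alignment.
#' Reads with more than `max_n_fraction` ambiguous bases are dropped first.
#'
#' @param reads Read set.
#' @param min_similarity Minimum alignment identity for an edge.
#' @param min_overlap_fraction Minimum overlap as a fraction of the shorter
#'   read.
#' @param seed_kmer Seed k-mer length for the default path.
#' @param method "kmer" (default) or "exact".
#' @param max_n_fraction Drop reads with more than this fraction of N.
#' @return Object of class `similarity_graph`: list with `nodes` (read
#'   ids) and `edges` (data.frame `from`, `to`, `similarity`, `overlap`,
#'   `orientation`).
#' @export
build_graph <- function(reads, min_similarity = 0.90,
                        min_overlap_fraction = 0.55, seed_kmer = 13L,
                        method = c("kmer", "exact"), max_n_fraction = 0.10) {
  method <- match.arg(method)
  seqs <- as_read_seqs(reads)
  if (length(seqs) < 2L) stop("need at least 2 reads to build a graph")
  n_frac <- vapply(gregexpr("[^ACGT]", seqs), function(m)
    if (m[1L] == -1L) 0L else length(m), integer(1L)) / nchar(seqs)
  seqs <- seqs[n_frac <= max_n_fraction]

  if (method == "kmer") {
    e <- cpp_similarity_edges(unname(seqs), as.integer(seed_kmer),
                              min_similarity, min_overlap_fraction)
    edges <- data.frame(from = names(seqs)[e$j], to = names(seqs)[e$i],
                        similarity = e$similarity, overlap = e$overlap,
                        orientation = ifelse(e$orientation == "F",
                                             "forward", "reverse"),
                        stringsAsFactors = FALSE)
  } else {
    pairs <- combn(length(seqs), 2L)
    rows <- vector("list", ncol(pairs))
    for (c_i in seq_len(ncol(pairs))) {
      i <- pairs[1L, c_i]; j <- pairs[2L, c_i]
      ps <- pairwise_similarity(seqs[[i]], seqs[[j]])
      need <- min_overlap_fraction * min(nchar(seqs[[i]]), nchar(seqs[[j]]))
      if (ps$similarity >= min_similarity && ps$overlap_length >= need) {
        rows[[c_i]] <- data.frame(from = names(seqs)[i], to = names(seqs)[j],
                                  similarity = ps$similarity,
                                  overlap = ps$overlap_length,
                                  orientation = ps$orientation,
                                  stringsAsFactors = FALSE)
      }
    }
    rows <- rows[!vapply(rows, is.null, logical(1L))]
    edges <- if (length(rows)) do.call(rbind, rows) else
      data.frame(from = character(0), to = character(0),
                 similarity = numeric(0), overlap = integer(0),
                 orientation = character(0), stringsAsFactors = FALSE)
  }
  structure(list(nodes = names(seqs), edges = edges,
                 params = list(min_similarity = min_similarity,
                               min_overlap_fraction = min_overlap_fraction,
                               seed_kmer = seed_kmer, method = method)),
            class = "similarity_graph")
}

as_igraph <- function(graph) {
  stopifnot(inherits(graph, "similarity_graph"))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(graph$nodes), name = graph$nodes)
  if (nrow(graph$edges)) {
    g <- igraph::add_edges(g, rbind(graph$edges$from, graph$edges$to),
                           weight = graph$edges$similarity)
  }
  g
}

#' Cluster reads into repeat families
#'
#' Connected components of the similarity graph become repeat clusters;
#' singleton components are reported separately as unclustered.  Cluster
#' ids (`CL1`, `CL2`, ...) are assigned by descending size, with ties
#' broken by smallest member read id.
#'
#' @param graph A [build_graph()] result.
#' @return Object of class `read_clusters`: list with `clusters` (named
#'   list of read-id vectors), `unclustered` (read ids) and `membership`
#'   (data.frame `read_id`, `cluster_id`).
#' @export
cluster_reads <- function(graph) {
  g <- as_igraph(graph)
  comp <- igraph::components(g)
  ids <- split(graph$nodes, comp$membership)
  sizes <- lengths(ids)
  singles <- unlist(ids[sizes == 1L], use.names = FALSE)
  multi <- ids[sizes > 1L]
  if (length(multi)) {
    first_id <- vapply(multi, function(x) min(x), character(1L))
    ord <- order(-lengths(multi), first_id)
    multi <- lapply(multi[ord], function(x) sort(x))
    names(multi) <- sprintf("CL%d", seq_along(multi))
  } else multi <- setNames(list(), character(0))
  membership <- data.frame(
    read_id = c(unlist(multi, use.names = FALSE), singles),
    cluster_id = c(rep(names(multi), lengths(multi)),
                   rep(NA_character_, length(singles))),
    stringsAsFactors = FALSE)
  structure(list(clusters = multi, unclustered = sort(singles %||% character(0)),
                 membership = membership),
            class = "read_clusters")
}

#' Graph-topology metrics of a repeat cluster
#'
#' Density is `2|E| / (|V|(|V|-1))`; the diameter estimate is the maximum
#' eccentricity over breadth-first searches from up to `max_bfs` seed nodes
#' (exact when the cluster has no more nodes than seeds).  The topology
#' class follows the qualitative shapes repeat graphs take: globular
#' high-density clusters ("dense-circularizable", density >= `D_hi`),
#' sparse long-diameter clusters of simple/low-complexity repeats
#' ("diffuse", density <= `D_lo` and diameter >= `L_hi`), and thread-like
#' structures otherwise ("linear-thread").
#'
#' @param read_ids Members of one cluster (>= 2).
#' @param graph The [build_graph()] result they came from.
#' @param D_hi,D_lo,L_hi Classification thresholds.
#' @param max_bfs Number of BFS seed nodes for the diameter estimate.
#' @return list with `density`, `diameter_estimate`, `topology_class`,
#'   `size`.
#' @export
topology_metrics <- function(read_ids, graph, D_hi = 0.30, D_lo = 0.05,
                             L_hi = 10L, max_bfs = 50L) {
  if (length(read_ids) < 2L) stop("topology metrics undefined for singleton cluster")
  g <- igraph::induced_subgraph(as_igraph(graph), read_ids)
  v <- igraph::vcount(g); e <- igraph::ecount(g)
  density <- 2 * e / (v * (v - 1))
  seeds <- sort(igraph::V(g)$name)[seq_len(min(v, max_bfs))]
  d <- igraph::distances(g, v = seeds, weights = NA)
  diam <- max(d[is.finite(d)])
  cls <- if (density >= D_hi) "dense-circularizable"
  else if (density <= D_lo && diam >= L_hi) "diffuse"
  else "linear-thread"
  list(density = density, diameter_estimate = as.integer(diam),
       topology_class = cls, size = v)
}

# Majority-vote consensus from a 4 x L count matrix; ties resolved to the
# alphabetically first base among the tied maxima (which.max on A,C,G,T
# rows).  Zero-depth columns become N.
consensus_call <- function(counts) {
  depth <- colSums(counts)
  call <- BASES[apply(counts, 2L, which.max)]
  call[depth == 0L] <- "N"
  paste(call, collapse = "")
}

#' Assemble consensus contigs from a read cluster
#'
#' Greedy seed-and-extend assembly: the highest-degree read seeds a
#' consensus; all cluster reads are then repeatedly mapped to the growing
#' consensus (both orientations, gapless), overhangs extend it, and every
#' column is called by per-base majority vote (ties to the alphabetically
#' first base) until the sequence stabilizes.  Unplaced reads seed further
#' contigs.  Contig ends are trimmed to columns with depth >=
#' `min_end_depth`, and contigs shorter than `min_contig_length` are
#' discarded (count retained in the `n_discarded` attribute).
#'
#' @param reads Read set (the full set; only `read_ids` are used).
#' @param read_ids Members of the cluster to assemble (>= 2).
#' @param graph Optional [build_graph()] result; node degree orders seed
#'   choice (read length is used otherwise).
#' @param min_contig_length Minimum reported contig length.
#' @param min_identity Identity required to place a read on the consensus.
#' @param min_anchor Minimum overlapping bases required to place a read.
#' @param seed_kmer Seed k-mer length.
#' @param max_rounds Mapping/realign rounds per contig.
#' @param min_end_depth Depth required to retain consensus end columns.
#' @param min_end_agreement Majority-base fraction required to retain
#'   consensus end columns (private flanking sequence of individual copies
#'   piles up at element boundaries with no majority base).
#' @return Named character vector of contig sequences (`<cluster>c1`, ...)
#'   with attribute `n_discarded`.
#' @export
assemble_consensus <- function(reads, read_ids, graph = NULL,
                               min_contig_length = 500L, min_identity = 0.85,
                               min_anchor = 30L, seed_kmer = 13L,
                               max_rounds = 30L, min_end_depth = 2L,
                               min_end_agreement = 0.6) {
  seqs <- as_read_seqs(reads)[read_ids]
  if (length(seqs) < 2L) stop("need at least 2 reads to assemble")
  if (!is.null(graph)) {
    g <- as_igraph(graph)
    deg <- igraph::degree(g)[read_ids]
    deg[is.na(deg)] <- 0L
  } else deg <- nchar(seqs)
  pool <- names(seqs)[order(-deg, names(seqs))]

  contigs <- character(0)
  n_discarded <- 0L
  while (length(pool) > 0L) {
    seed_id <- pool[1L]
    consensus <- unname(seqs[[seed_id]])
    members <- seed_id
    cl_seqs <- seqs[pool]
    for (round in seq_len(max_rounds)) {
      m <- cpp_map_reads(unname(cl_seqs), consensus, as.integer(seed_kmer),
                         min_identity, as.integer(min_anchor))
      placed <- which(!is.na(m$contig))
      if (!(match(seed_id, names(cl_seqs)) %in% placed)) {
        # degenerate: seed no longer maps to its own consensus
        placed <- unique(c(placed, match(seed_id, names(cl_seqs))))
        m$offset[match(seed_id, names(cl_seqs))] <- 0L
        m$strand[match(seed_id, names(cl_seqs))] <- "F"
      }
      if (length(placed) == 0L) break
      oriented <- unname(cl_seqs[placed])
      rev <- which(m$strand[placed] == "R")
      if (length(rev)) oriented[rev] <- revcomp(oriented[rev])
      offs <- m$offset[placed]
      lo <- min(offs)
      hi <- max(offs + nchar(oriented))
      counts <- cpp_pileup(rep(1L, length(placed)), offs - lo, oriented,
                           hi - lo)[[1L]]
      new_consensus <- consensus_call(counts)
      members <- names(cl_seqs)[placed]
      if (identical(new_consensus, consensus)) { consensus <- new_consensus; break }
      consensus <- new_consensus
    }
    # final trim to well-supported columns
    m <- cpp_map_reads(unname(cl_seqs), consensus, as.integer(seed_kmer),
                       min_identity, as.integer(min_anchor))
    placed <- which(!is.na(m$contig))
    if (length(placed)) {
      oriented <- unname(cl_seqs[placed])
      rev <- which(m$strand[placed] == "R")
      if (length(rev)) oriented[rev] <- revcomp(oriented[rev])
      counts <- cpp_pileup(rep(1L, length(placed)), m$offset[placed], oriented,
                           nchar(consensus))[[1L]]
      depth <- colSums(counts)
      maj <- apply(counts, 2L, max) / pmax(depth, 1L)
      # repeat copies carry private flanking sequence: columns beyond the
      # element boundary are supported by one copy's reads only, so trim end
      # columns whose depth falls far below the contig median or that lack a
      # majority base
      need_depth <- max(min_end_depth, 0.25 * stats::median(depth))
      ok <- which(depth >= need_depth & maj >= min_end_agreement)
      if (length(ok)) {
        consensus <- substr(consensus, min(ok), max(ok))
      }
      members <- names(cl_seqs)[placed]
    }
    if (nchar(consensus) >= min_contig_length) {
      contigs <- c(contigs, consensus)
    } else {
      n_discarded <- n_discarded + 1L
    }
    pool <- setdiff(pool, unique(c(members, seed_id)))
  }
  if (length(contigs)) names(contigs) <- sprintf("c%d", seq_along(contigs))
  attr(contigs, "n_discarded") <- n_discarded
  contigs
}

#' Estimate the repetitive fraction of the genome
#'
#' Fraction of reads that belong to clusters of size at least
#' `min_cluster_fraction * total_reads`; at ~1x sampling this approximates
#' the fraction of the genome in medium/high copy number repeats.  The
#' estimate is monotone non-increasing in `min_cluster_fraction`.
#'
#' @param clusters A [cluster_reads()] result.
#' @param total_reads Total number of reads that entered clustering (> 0).
#' @param min_cluster_fraction Minimum cluster size, as a fraction of
#'   `total_reads`, for a cluster to count as repetitive.
#' @return Proportion in `[0, 1]`.
#' @export
repeat_fraction <- function(clusters, total_reads,
                            min_cluster_fraction = 1e-4) {
  if (total_reads <= 0) stop("total_reads must be positive")
  sizes <- lengths(clusters$clusters)
  big <- sizes >= min_cluster_fraction * total_reads
  sum(sizes[big]) / total_reads
}
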