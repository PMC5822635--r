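#' Align reads back to consensus contigs
#'
#' Gapless seed-and-extend alignment of each read against both strands of
#' every contig: shared `seed_kmer`-mers vote for candidate diagonals and
#' the best-supported diagonals are evaluated by direct comparison.  Each
#' read receives at most one placement -- the one with the most matching
#' columns, ties broken by leftmost contig, then leftmost position, then
#' forward strand.  Reads below `min_identity` over the overlap, or
#' overlapping by fewer than `min_overlap` bases, stay unaligned.
#'
#' Alignments produced externally (e.g. by a gapped aligner) can be
#' ingested with [read_sam_alignments()] instead.
#'
#' @param reads Read set.
#' @param contigs Named character vector of contig sequences.
#' @param min_identity Minimum identity over the overlapping columns.
#' @param seed_kmer Seed k-mer length.
#' @param min_overlap Minimum overlapping bases.
#' @return Object of class `read_alignments`: data.frame with `read_id`,
#'   `contig_id`, `offset` (0-based, may be negative when the read
#'   overhangs the contig start), `strand`, `matches`, `aln_len`,
#'   `identity` and `oriented` (read sequence on the contig strand);
#'   unaligned reads are omitted.  Contig names/lengths travel in
#'   attributes.
#' @export
align_reads <- function(reads, contigs, min_identity = 0.85, seed_kmer = 13L,
                        min_overlap = 30L) {
  if (length(contigs) == 0L) stop("contigs must be non-empty")
  seqs <- as_read_seqs(reads)
  m <- cpp_map_reads(unname(seqs), unname(contigs), as.integer(seed_kmer),
                     min_identity, as.integer(min_overlap))
  hit <- which(!is.na(m$contig))
  oriented <- unname(seqs[hit])
  rev <- which(m$strand[hit] == "R")
  if (length(rev)) oriented[rev] <- revcomp(oriented[rev])
  out <- data.frame(
    read_id = names(seqs)[hit],
    contig_id = (names(contigs) %||% sprintf("c%d", seq_along(contigs)))[m$contig[hit]],
    offset = m$offset[hit],
    strand = ifelse(m$strand[hit] == "F", "forward", "reverse"),
    matches = m$matches[hit],
    aln_len = m$aln_len[hit],
    identity = m$matches[hit] / m$aln_len[hit],
    oriented = oriented,
    stringsAsFactors = FALSE)
  attr(out, "contig_names") <- names(contigs) %||% sprintf("c%d", seq_along(contigs))
  attr(out, "contig_lengths") <- setNames(nchar(contigs), names(contigs))
  attr(out, "n_unaligned") <- length(seqs) - length(hit)
  class(out) <- c("read_alignments", "data.frame")
  out
}

#' Ingest gapless alignments from a SAM file
#'
#' Minimal ingestion path for externally produced alignments: parses SAM
#' text records whose CIGAR consists of a single match run (`<n>M`,
#' optionally soft-clipped at either end) into the same alignment table
#' produced by [align_reads()].  Records with indels are skipped with a
#' warning (the pileup-based estimators here are substitution-only).
#'
#' @param path SAM file.
#' @param contigs Named character vector of the reference contigs.
#' @return A `read_alignments` object.
#' @export
read_sam_alignments <- function(path, contigs) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  rows <- list(); skipped <- 0L
  for (f in fields) {
    if (length(f) < 11L) next
    flag <- as.integer(f[2L])
    if (bitwAnd(flag, 4L) > 0L) next  # unmapped
    cig <- f[6L]
    mm <- regmatches(cig, gregexpr("[0-9]+[MIDNSHP=X]", cig))[[1L]]
    ops <- substr(mm, nchar(mm), nchar(mm))
    len <- as.integer(substr(mm, 1L, nchar(mm) - 1L))
    if (any(ops %in% c("I", "D", "N"))) { skipped <- skipped + 1L; next }
    m_len <- sum(len[ops %in% c("M", "=", "X")])
    lead_clip <- if (ops[1L] == "S") len[1L] else 0L
    seq <- f[10L]
    core <- substr(seq, lead_clip + 1L, lead_clip + m_len)
    contig_id <- f[3L]
    if (!contig_id %in% names(contigs)) next
    off <- as.integer(f[4L]) - 1L
    ref <- substr(contigs[[contig_id]], off + 1L, off + m_len)
    matches <- sum(strsplit(core, "")[[1L]] == strsplit(ref, "")[[1L]])
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = f[1L], contig_id = contig_id, offset = off,
      strand = if (bitwAnd(flag, 16L) > 0L) "reverse" else "forward",
      matches = matches, aln_len = m_len, identity = matches / m_len,
      oriented = core, stringsAsFactors = FALSE)
  }
  if (skipped > 0L)
    warning(skipped, " SAM records with indels skipped (substitution-only pileup)")
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(read_id = character(0), contig_id = character(0),
               offset = integer(0), strand = character(0),
               matches = integer(0), aln_len = integer(0),
               identity = numeric(0), oriented = character(0),
               stringsAsFactors = FALSE)
  attr(out, "contig_names") <- names(contigs)
  attr(out, "contig_lengths") <- setNames(nchar(contigs), names(contigs))
  class(out) <- c("read_alignments", "data.frame")
  out
}

#' Build per-position pileup columns
#'
#' Counts bases per contig position from the aligned reads (reverse-strand
#' reads already complemented in the alignment table).  Overhanging read
#' bases outside the contig are clipped; an alignment lying entirely
#' outside its contig is an error.  Zero-depth positions are included with
#' depth 0.
#'
#' @param alignments A `read_alignments` object.
#' @param contigs Named character vector of contigs.
#' @return data.frame with `contig_id`, `pos` (0-based), `A`, `C`, `G`,
#'   `T`, `depth`.
#' @export
pileup <- function(alignments, contigs) {
  stopifnot(inherits(alignments, "read_alignments"))
  nm <- names(contigs) %||% sprintf("c%d", seq_along(contigs))
  lens <- nchar(contigs)
  idx <- match(alignments$contig_id, nm)
  if (anyNA(idx)) stop("alignment references unknown contig")
  bad <- alignments$offset >= lens[idx] |
    (alignments$offset + nchar(alignments$oriented)) <= 0L
  if (any(bad)) stop("alignment beyond contig bounds: ",
                     alignments$read_id[which(bad)[1L]])
  mats <- cpp_pileup(idx, alignments$offset, alignments$oriented,
                     as.integer(lens))
  do.call(rbind, lapply(seq_along(contigs), function(j) {
    m <- mats[[j]]
    data.frame(contig_id = nm[j], pos = seq_len(ncol(m)) - 1L,
               A = m[1L, ], C = m[2L, ], G = m[3L, ], T = m[4L, ],
               depth = colSums(m), stringsAsFactors = FALSE)
  }))
}

# per-site unbiased pairwise diversity from allele counts:
# pi = (n/(n-1)) * (1 - sum_b (c_b/n)^2), identical to
# (# differing pairs) / choose(n, 2).
pi_site <- function(counts) {
  n <- sum(counts)
  if (n < 2L) return(NA_real_)
  (n / (n - 1)) * (1 - sum((counts / n)^2))
}

#' Average pairwise nucleotide diversity of a contig
#'
#' Per qualifying site (depth >= `min_depth`), computes the unbiased
#' pairwise diversity `(n/(n-1)) * (1 - sum_b (c_b/n)^2)` -- exactly the
#' number of differing read pairs over `choose(n, 2)` -- and averages over
#' sites.  This is the divergence/age proxy of a repeat family: reads
#' sampled from many genomic copies pile onto one consensus, so their
#' per-site diversity reflects between-copy divergence.
#'
#' @param columns Pileup columns of one contig (data.frame with `A`, `C`,
#'   `G`, `T`).
#' @param min_depth Minimum depth for a site to qualify.
#' @param min_covered_fraction If fewer than this fraction of positions
#'   qualify, the estimate is flagged low-coverage.
#' @return list with `theta_pi`, `n_sites_used`, `low_coverage`.
#' @export
theta_pi <- function(columns, min_depth = 4L, min_covered_fraction = 0.6) {
  counts <- as.matrix(columns[, c("A", "C", "G", "T")])
  depth <- rowSums(counts)
  qual <- which(depth >= min_depth)
  if (length(qual) == 0L) stop("insufficient coverage: no site reaches min_depth")
  pis <- apply(counts[qual, , drop = FALSE], 1L, pi_site)
  list(theta_pi = mean(pis), n_sites_used = length(qual),
       low_coverage = length(qual) < min_covered_fraction * nrow(counts))
}

#' Copy number from mean pileup depth
#'
#' Mean depth over all contig positions (zero-depth positions included)
#' divided by the depth expected of a single-copy locus (the sampling
#' coverage; at 1x, raw depth is copy number).
#'
#' @param columns Pileup columns of one contig (data.frame with `depth`).
#' @param single_copy_depth Depth of a single-copy region (> 0).
#' @return list with `copy_number` and `mean_depth`.
#' @export
copy_number <- function(columns, single_copy_depth = 1) {
  stopifnot_scalar_num(single_copy_depth, "single_copy_depth", min = 0,
                       strict = TRUE)
  mean_depth <- mean(columns$depth)
  list(copy_number = mean_depth / single_copy_depth, mean_depth = mean_depth)
}

#' Per-contig divergence records (the divergence-vs-copy-number table)
#'
#' Combines [theta_pi()] and [copy_number()] per contig into one record
#' per contig -- one point in the divergence / copy-number plane on which
#' the half-life regression runs.
#'
#' @param columns Pileup columns for all contigs (from [pileup()]).
#' @param classes Optional data.frame `contig_id`, `class_label` (from
#'   [classify_contigs()]).
#' @param single_copy_depth Depth of a single-copy region.
#' @inheritParams theta_pi
#' @return data.frame with `contig_id`, `class_label`, `theta_pi`,
#'   `mean_depth`, `copy_number`, `n_sites_used`, `low_coverage`.
#' @export
divergence_records <- function(columns, classes = NULL, single_copy_depth = 1,
                               min_depth = 4L, min_covered_fraction = 0.6) {
  ids <- unique(columns$contig_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    cc <- columns[columns$contig_id == id, , drop = FALSE]
    tp <- theta_pi(cc, min_depth, min_covered_fraction)
    cn <- copy_number(cc, single_copy_depth)
    data.frame(contig_id = id, class_label = NA_character_,
               theta_pi = tp$theta_pi, mean_depth = cn$mean_depth,
               copy_number = cn$copy_number, n_sites_used = tp$n_sites_used,
               low_coverage = tp$low_coverage, stringsAsFactors = FALSE)
  }))
  if (!is.null(classes)) {
    out$class_label <- classes$class_label[match(out$contig_id, classes$contig_id)]
  }
  out
}

#' Per-read divergence from the consensus
#'
#' Mismatch fraction of each aligned read over its aligned columns; an
#' estimate of the divergence of the genomic copy the read came from
#' (plus sequencing error, which shifts all reads equally).
#'
#' @param alignments A `read_alignments` object.
#' @return data.frame with `read_id`, `contig_id`, `divergence`,
#'   `aln_len`.
#' @export
read_divergences <- function(alignments) {
  data.frame(read_id = alignments$read_id, contig_id = alignments$contig_id,
             divergence = 1 - alignments$identity,
             aln_len = alignments$aln_len, stringsAsFactors = FALSE)
}

#' Copy number binned by divergence
#'
#' Bins copies (or reads) of one family by divergence and returns the copy
#' number per bin -- the within-family analogue of the per-contig
#' divergence/copy-number table, used to fit a half-life from a single
#' large family.  With per-copy divergences, weights of 1 give copy counts
#' per bin.  With per-read divergences, set `weights = aln_len /
#' (contig_length * single_copy_depth)` so each bin's weight sum is the
#' copy number its reads represent.
#'
#' @param divergences Numeric vector of divergences.
#' @param weights Per-observation copy-number weight (default 1 each).
#' @param bin_width Divergence bin width.
#' @param max_divergence Optional right truncation (bins beyond are
#'   dropped, e.g. near an aligner identity cutoff).
#' @return data.frame with `theta_pi` (bin midpoint), `copy_number`,
#'   `n` (observations per bin); empty bins are omitted.
#' @export
binned_copy_profile <- function(divergences, weights = NULL,
                                bin_width = 0.02, max_divergence = NULL) {
  if (is.null(weights)) weights <- rep(1, length(divergences))
  stopifnot(length(weights) == length(divergences))
  bin <- floor(divergences / bin_width)
  if (!is.null(max_divergence)) {
    # keep only complete bins: a bin truncated by the cutoff would bias the
    # regression slope downward
    keep <- (bin + 1) * bin_width <= max_divergence + 1e-12
    bin <- bin[keep]; weights <- weights[keep]
  }
  if (!length(bin)) stop("no observations below max_divergence")
  agg <- rowsum(cbind(w = weights, n = 1), group = bin)
  mids <- (as.numeric(rownames(agg)) + 0.5) * bin_width
  data.frame(theta_pi = mids, copy_number = agg[, "w"], n = as.integer(agg[, "n"]))
}
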