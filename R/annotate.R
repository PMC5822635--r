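#' Read a repeat reference library
#'
#' Parses a FASTA repeat library with RepeatMasker-style headers
#' (`name#Class/Subclass`).  Entries without a `#` get class "Unknown".
#'
#' @param path FASTA file path.
#' @return Object of class `repeat_library`: data.frame with `name`,
#'   `class_label`, `sequence`.
#' @export
read_repeat_library <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  repeat_library(setNames(as.character(x), names(x)))
}

#' Construct a repeat library from named sequences
#'
#' @param seqs Named character vector; names follow the
#'   `name#Class/Subclass` convention.
#' @return Object of class `repeat_library`.
#' @export
repeat_library <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  hdr <- sub("\\s.*$", "", names(seqs))
  has_class <- grepl("#", hdr, fixed = TRUE)
  name <- ifelse(has_class, sub("#.*$", "", hdr), hdr)
  class_label <- ifelse(has_class, sub("^[^#]*#", "", hdr), "Unknown")
  if (anyDuplicated(name)) stop("duplicate entry names in repeat library")
  structure(data.frame(name = name, class_label = class_label,
                       sequence = unname(seqs), stringsAsFactors = FALSE),
            class = c("repeat_library", "data.frame"))
}

# Best local alignment of `query` (both strands) against one subject.
best_hit_identity <- function(query, subject) {
  f <- local_alignment(query, subject)
  r <- local_alignment(revcomp(query), subject)
  if (r$score > f$score) r else f
}

#' Classify a consensus contig against a repeat library
#'
#' Scores the contig against every library entry by best local alignment
#' over both strands and assigns the class of the best entry whose hit
#' reaches `min_identity` over at least `min_alignment` aligned columns.
#' Ties (equal identity) are broken by longer alignment, then lexicographic
#' entry name.  With no passing hit the contig is "Unclassified".
#'
#' @param contig Character scalar (or `DNAString`).
#' @param library A [repeat_library()].
#' @param min_identity Minimum alignment identity.
#' @param min_alignment Minimum aligned columns.
#' @return Class label (character scalar) with attributes `name`,
#'   `identity` and `aln_len` of the best hit (when one passes).
#' @export
classify_contig <- function(contig, library, min_identity = 0.80,
                            min_alignment = 80L) {
  stopifnot(inherits(library, "repeat_library"))
  if (nrow(library) == 0L) stop("empty repeat library")
  contig <- as.character(contig)
  hits <- lapply(library$sequence, function(s) best_hit_identity(contig, s))
  identity <- vapply(hits, `[[`, numeric(1L), "identity")
  len <- vapply(hits, `[[`, numeric(1L), "length")
  pass <- identity >= min_identity & len >= min_alignment
  if (!any(pass)) return("Unclassified")
  ord <- order(-identity, -len, library$name)
  best <- ord[pass[ord]][1L]
  structure(library$class_label[best], name = library$name[best],
            identity = identity[best], aln_len = as.integer(len[best]))
}

#' Classify many contigs
#'
#' Vector wrapper around [classify_contig()].
#'
#' @inheritParams classify_contig
#' @param contigs Named character vector of contig sequences.
#' @return data.frame with `contig_id`, `class_label`, `best_entry`,
#'   `identity`, `aln_len`.
#' @export
classify_contigs <- function(contigs, library, min_identity = 0.80,
                             min_alignment = 80L) {
  res <- lapply(contigs, classify_contig, library = library,
                min_identity = min_identity, min_alignment = min_alignment)
  data.frame(
    contig_id = names(contigs) %||% sprintf("c%d", seq_along(contigs)),
    class_label = vapply(res, as.character, character(1L)),
    best_entry = vapply(res, function(r) attr(r, "name") %||% NA_character_,
                        character(1L)),
    identity = vapply(res, function(r) attr(r, "identity") %||% NA_real_,
                      numeric(1L)),
    aln_len = vapply(res, function(r) attr(r, "aln_len") %||% NA_integer_,
                     integer(1L)),
    stringsAsFactors = FALSE)
}

#' Drop contaminant sequences from a contig set
#'
#' Classifies contigs against a user-supplied contaminant library (e.g.
#' plastid or viral sequences) and removes those with a passing hit.
#'
#' @param contigs Named character vector.
#' @param contaminants A [repeat_library()] of contaminant sequences.
#' @inheritParams classify_contig
#' @return The retained contigs, with attribute `n_removed`.
#' @export
filter_contaminants <- function(contigs, contaminants, min_identity = 0.80,
                                min_alignment = 80L) {
  cls <- classify_contigs(contigs, contaminants, min_identity, min_alignment)
  keep <- cls$class_label == "Unclassified"
  out <- contigs[keep]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Cross-genome repeat-library similarity table
#'
#' For every repeat class present in `libA`, finds reciprocal-best-hit
#' (RBH) pairs between the class members of the two libraries by percent
#' identity of the best local alignment (both strands) and reports the
#' mean percent similarity over RBH pairs.  Classes absent from `libB`
#' yield a missing (`NA`) row, mirroring how cross-species repeat tables
#' mark families absent from one genome's library.
#'
#' @param libA,libB [repeat_library()] objects.
#' @return data.frame of class `cross_species_table` with `repeat_class`,
#'   `mean_percent_similarity` and `n_pairs` (NA for missing classes).
#' @export
cross_species_similarity <- function(libA, libB) {
  stopifnot(inherits(libA, "repeat_library"), inherits(libB, "repeat_library"))
  classes <- unique(libA$class_label)
  rows <- lapply(classes, function(cl) {
    a <- libA[libA$class_label == cl, , drop = FALSE]
    b <- libB[libB$class_label == cl, , drop = FALSE]
    if (nrow(b) == 0L) {
      return(data.frame(repeat_class = cl, mean_percent_similarity = NA_real_,
                        n_pairs = NA_integer_, stringsAsFactors = FALSE))
    }
    pid <- matrix(0, nrow(a), nrow(b), dimnames = list(a$name, b$name))
    for (i in seq_len(nrow(a))) {
      for (j in seq_len(nrow(b))) {
        pid[i, j] <- 100 * best_hit_identity(a$sequence[i], b$sequence[j])$identity
      }
    }
    # reciprocal best hits, deterministic tie-break by entry name order
    best_ab <- apply(pid, 1L, which.max)
    best_ba <- apply(pid, 2L, which.max)
    rbh <- which(best_ba[best_ab] == seq_len(nrow(a)))
    if (length(rbh) == 0L) {
      return(data.frame(repeat_class = cl, mean_percent_similarity = NA_real_,
                        n_pairs = 0L, stringsAsFactors = FALSE))
    }
    sims <- pid[cbind(rbh, best_ab[rbh])]
    data.frame(repeat_class = cl, mean_percent_similarity = mean(sims),
               n_pairs = length(rbh), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cross_species_table", "data.frame")
  out
}
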