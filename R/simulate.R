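#' Parameters of a steady-state birth-death repeat family
#'
#' A repeat family is modelled as a linear birth-death process on insertion
#' count: every live copy triggers a new insertion at rate `birth_rate` and
#' is lost at rate `death_rate`.  Each new insertion is a copy of the
#' conserved ancestral (master) element and thereafter accumulates private
#' substitutions at `mutation_rate` per site per time unit (Jukes-Cantor
#' style: a random site is replaced by a uniformly chosen different base;
#' no indels).  Divergence from the family ancestor therefore measures the
#' age of each insertion, and at the steady state (`birth_rate ==
#' death_rate`) surviving-copy divergences are exponentially distributed
#' with rate `death_rate / mutation_rate`.
#'
#' The family half-life -- the divergence by which half of all insertions
#' have been lost -- is `log(2) * mutation_rate / death_rate`, recorded in
#' the `true_half_life` field (`NA` when `death_rate == 0`: with no loss
#' process the half-life is undefined).
#'
#' @param family_id Character label for the family.
#' @param element_length Element length in bases (>= 100).
#' @param birth_rate,death_rate Per-copy insertion and loss rates (events
#'   per element per time unit).
#' @param mutation_rate Substitution rate per site per time unit.
#' @param duration Total simulated time `T` (> 0).
#' @param n_initial Number of copies present at time 0 (default 1, a single
#'   ancestral insertion).  Larger values start the process at its
#'   stationary size, which a critical process cannot reach from one copy.
#' @param copy_cap Abort if the live copy count exceeds this (guards
#'   against supercritical explosions).
#' @param seed Optional integer seed making the family reproducible.
#' @return An object of class `family_params`.
#' @export
family_params <- function(family_id, element_length = 1000, birth_rate,
                          death_rate, mutation_rate, duration,
                          n_initial = 1L, copy_cap = 10000L, seed = NULL) {
  stopifnot_scalar_num(element_length, "element_length", min = 100)
  stopifnot_scalar_num(birth_rate, "birth_rate", min = 0)
  stopifnot_scalar_num(death_rate, "death_rate", min = 0)
  stopifnot_scalar_num(mutation_rate, "mutation_rate", min = 0)
  stopifnot_scalar_num(duration, "duration", min = 0, strict = TRUE)
  stopifnot_scalar_num(n_initial, "n_initial", min = 1)
  structure(list(
    family_id = as.character(family_id),
    element_length = as.integer(element_length),
    birth_rate = birth_rate, death_rate = death_rate,
    mutation_rate = mutation_rate, duration = duration,
    n_initial = as.integer(n_initial), copy_cap = as.integer(copy_cap),
    seed = seed,
    true_half_life = if (death_rate > 0) log(2) * mutation_rate / death_rate else NA_real_
  ), class = "family_params")
}

# Apply `n_events` substitution events to a character-vector sequence.
# Events hit uniform random sites; each replaces the current base by one of
# the other three.  Multiple hits at a site are applied sequentially, so
# reversions can occur, exactly as in the underlying mutation process.
mutate_chars <- function(chars, n_events) {
  if (n_events == 0L) return(chars)
  pos <- sample.int(length(chars), n_events, replace = TRUE)
  for (p in pos) {
    chars[p] <- sample(setdiff(BASES, chars[p]), 1L)
  }
  chars
}

#' Simulate one repeat family under the steady-state birth-death model
#'
#' Runs the continuous-time birth-death process of [family_params()] by
#' Gillespie simulation and returns the surviving copy sequences at time
#' `duration` together with exact ground truth.  `per_copy_divergence`
#' records the *counted* number of substitution events per site applied to
#' each surviving copy (its expected divergence from the family ancestor);
#' realized Hamming divergence can differ slightly through multiple hits
#' and is recoverable from the returned sequences.
#'
#' Extinction before `duration` is not an error: the family is returned
#' with zero copies (callers decide whether to resample).
#'
#' @param params A [family_params()] object.
#' @return A list of class `family_sim` with elements `copies` (character
#'   vector of surviving sequences), `ancestor` (the master element), and
#'   `truth` (list: `family_id`, `surviving_copies`, `per_copy_divergence`,
#'   `true_half_life`).
#' @export
simulate_family <- function(params) {
  stopifnot(inherits(params, "family_params"))
  with_seed_if(params$seed, {
    L <- params$element_length
    ancestor <- random_dna(L)
    b <- params$birth_rate; d <- params$death_rate; T <- params$duration
    birth_time <- rep(0, params$n_initial)
    t <- 0
    if (b + d > 0) {
      repeat {
        n <- length(birth_time)
        if (n == 0L) break
        t <- t + rexp(1L, (b + d) * n)
        if (t > T) break
        if (runif(1L) < b / (b + d)) {
          if (n + 1L > params$copy_cap)
            stop("copy number exceeded copy_cap (", params$copy_cap,
                 "); the process is supercritical at this scale")
          birth_time <- c(birth_time, t)
        } else {
          birth_time <- birth_time[-sample.int(n, 1L)]
        }
      }
    }
    ages <- T - birth_time
    n_sub <- if (length(ages)) rpois(length(ages), params$mutation_rate * L * ages) else integer(0)
    anc_chars <- strsplit(ancestor, "", fixed = TRUE)[[1L]]
    copies <- vapply(n_sub, function(k) {
      paste(mutate_chars(anc_chars, k), collapse = "")
    }, character(1L))
    structure(list(
      copies = copies,
      ancestor = ancestor,
      ages = ages,
      truth = list(
        family_id = params$family_id,
        surviving_copies = length(copies),
        per_copy_divergence = n_sub / L,
        true_half_life = params$true_half_life
      )
    ), class = "family_sim")
  })
}

#' Configuration for a synthetic genome
#'
#' Assembles the component specification consumed by [simulate_genome()]:
#' birth-death transposable-element families, an optional concertedly
#' evolving tandem rDNA array (high copy number, near-zero divergence), an
#' optional high-divergence simple-repeat fraction, and i.i.d. single-copy
#' background.
#'
#' Concerted evolution of the rDNA array is modelled by its observable
#' signature only: every unit is the array master plus `Poisson(divergence
#' * unit_length)` private substitutions, with `divergence` small (default
#' 0.003), rather than by an explicit gene-conversion process.  Simple
#' repeats are tandem k-mers (motif length drawn from 2..10) mutated at a
#' per-stretch divergence.
#'
#' @param families List of [family_params()] objects.
#' @param rdna `NULL` or list with `unit_length`, `n_copies`, and optional
#'   `divergence` (default 0.003) and `family_id` (default "rDNA").
#' @param simple `NULL` or list with `n_stretches`, `stretch_length`, and
#'   optional `divergence` (default 0.15) and `family_id` (default
#'   "simple").
#' @param background_length Bases of single-copy background sequence.
#' @param seed Optional integer seed.
#' @return A list of class `genome_config`.
#' @export
genome_config <- function(families = list(), rdna = NULL, simple = NULL,
                          background_length = 0L, seed = NULL) {
  stopifnot(all(vapply(families, inherits, logical(1L), "family_params")))
  stopifnot_scalar_num(background_length, "background_length", min = 0)
  if (!is.null(rdna)) {
    rdna$divergence <- rdna$divergence %||% 0.003
    rdna$family_id <- rdna$family_id %||% "rDNA"
    stopifnot(!is.null(rdna$unit_length), !is.null(rdna$n_copies))
  }
  if (!is.null(simple)) {
    simple$divergence <- simple$divergence %||% 0.15
    simple$family_id <- simple$family_id %||% "simple"
    stopifnot(!is.null(simple$n_stretches), !is.null(simple$stretch_length))
  }
  structure(list(families = families, rdna = rdna, simple = simple,
                 background_length = as.integer(background_length),
                 seed = seed),
            class = "genome_config")
}

mutate_string <- function(s, n_events) {
  paste(mutate_chars(strsplit(s, "", fixed = TRUE)[[1L]], n_events), collapse = "")
}

#' Simulate a genome with planted repeat families
#'
#' Simulates every family in the configuration, then concatenates the
#' shuffled family copies, the tandem rDNA array (kept contiguous),
#' simple-repeat stretches and single-copy background into one sequence.
#' Strands are assigned uniformly per piece.  Returns the sequence together
#' with an exact feature table (0-based half-open coordinates) and per
#' family ground truth, so that every read simulated from the genome can be
#' traced to its true origin.
#'
#' @param config A [genome_config()] object.
#' @return A list of class `synthetic_genome` with elements `sequence`,
#'   `length`, `features` (data.frame: `family_id`, `start`, `end`,
#'   `strand`), `truths`, `ancestors`, `single_copy_fraction` and
#'   `repetitive_fraction`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "genome_config"))
  with_seed_if(config$seed, {
    pieces <- list()     # each: list(seq, features = data.frame(rel_start, rel_end, family_id))
    ancestors <- list()
    truths <- list()

    for (fp in config$families) {
      sim <- simulate_family(fp)
      truths[[fp$family_id]] <- sim$truth
      ancestors[[fp$family_id]] <- sim$ancestor
      for (cp in sim$copies) {
        pieces[[length(pieces) + 1L]] <- list(
          seq = cp,
          features = data.frame(rel_start = 0L, rel_end = nchar(cp),
                                family_id = fp$family_id,
                                stringsAsFactors = FALSE))
      }
    }

    if (!is.null(config$rdna)) {
      rd <- config$rdna
      master <- random_dna(rd$unit_length)
      units <- vapply(seq_len(rd$n_copies), function(i) {
        mutate_string(master, rpois(1L, rd$divergence * rd$unit_length))
      }, character(1L))
      ancestors[[rd$family_id]] <- master
      truths[[rd$family_id]] <- list(
        family_id = rd$family_id, surviving_copies = rd$n_copies,
        per_copy_divergence = rep(rd$divergence, rd$n_copies),
        true_half_life = NA_real_)
      starts <- cumsum(c(0L, nchar(units)[-length(units)]))
      pieces[[length(pieces) + 1L]] <- list(
        seq = paste(units, collapse = ""),
        features = data.frame(rel_start = starts,
                              rel_end = starts + nchar(units),
                              family_id = rd$family_id,
                              stringsAsFactors = FALSE))
    }

    if (!is.null(config$simple)) {
      sp <- config$simple
      for (i in seq_len(sp$n_stretches)) {
        motif <- random_dna(sample(2:10, 1L))
        reps <- ceiling(sp$stretch_length / nchar(motif))
        s <- substr(strrep(motif, reps), 1L, sp$stretch_length)
        s <- mutate_string(s, rpois(1L, sp$divergence * nchar(s)))
        pieces[[length(pieces) + 1L]] <- list(
          seq = s,
          features = data.frame(rel_start = 0L, rel_end = nchar(s),
                                family_id = sp$family_id,
                                stringsAsFactors = FALSE))
      }
    }

    if (length(pieces)) pieces <- pieces[sample.int(length(pieces))]

    # background split into len(pieces)+1 chunks interleaved between pieces
    n_gap <- length(pieces) + 1L
    bg_total <- config$background_length
    if (bg_total > 0L) {
      cuts <- sort(sample.int(bg_total + 1L, n_gap - 1L, replace = TRUE) - 1L)
      gap_len <- diff(c(0L, cuts, bg_total))
    } else gap_len <- rep(0L, n_gap)

    seq_parts <- character(0)
    feats <- list()
    pos <- 0L
    for (idx in seq_along(pieces)) {
      g <- gap_len[idx]
      if (g > 0L) { seq_parts <- c(seq_parts, random_dna(g)); pos <- pos + g }
      p <- pieces[[idx]]
      strand <- sample(c("+", "-"), 1L)
      s <- p$seq
      f <- p$features
      if (strand == "-") {
        s <- revcomp(s)
        w <- nchar(p$seq)
        new_start <- w - f$rel_end
        f$rel_end <- w - f$rel_start
        f$rel_start <- new_start
      }
      f$start <- pos + f$rel_start
      f$end <- pos + f$rel_end
      f$strand <- strand
      feats[[length(feats) + 1L]] <- f[, c("family_id", "start", "end", "strand")]
      seq_parts <- c(seq_parts, s)
      pos <- pos + nchar(s)
    }
    g <- gap_len[n_gap]
    if (g > 0L) { seq_parts <- c(seq_parts, random_dna(g)); pos <- pos + g }

    features <- if (length(feats)) do.call(rbind, feats) else
      data.frame(family_id = character(0), start = integer(0),
                 end = integer(0), strand = character(0),
                 stringsAsFactors = FALSE)
    features <- features[order(features$start), , drop = FALSE]
    rownames(features) <- NULL
    genome_seq <- paste(seq_parts, collapse = "")
    stopifnot(nchar(genome_seq) == pos)
    rep_frac <- if (pos > 0L) sum(features$end - features$start) / pos else 0
    structure(list(
      sequence = genome_seq, length = pos, features = features,
      truths = truths, ancestors = ancestors,
      repetitive_fraction = rep_frac,
      single_copy_fraction = 1 - rep_frac
    ), class = "synthetic_genome")
  })
}

# Label a read by the feature containing its midpoint ("background" if none).
origin_labels <- function(features, starts, read_length) {
  mid <- starts + read_length %/% 2L
  lab <- rep("background", length(starts))
  if (nrow(features) == 0L) return(lab)
  idx <- findInterval(mid, features$start)
  hit <- idx >= 1L
  hit[hit] <- mid[hit] < features$end[idx[hit]]
  lab[hit] <- features$family_id[idx[hit]]
  lab
}

#' Simulate shotgun reads from a synthetic genome
#'
#' Draws `round(coverage * G / read_length)` reads uniformly from both
#' strands, adds per-base substitution errors at `error_rate`, and attaches
#' constant Phred qualities consistent with the error rate
#' (`-10*log10(error_rate)`, capped at Q40).  Read names encode the true
#' origin as `read|family|start|strand`, where `family` is the planted
#' feature containing the read midpoint (or "background").
#'
#' @param genome A [simulate_genome()] result.
#' @param coverage Target fold coverage (> 0).
#' @param read_length Read length in bases (<= genome length).
#' @param error_rate Per-base substitution error probability.
#' @param seed Optional integer seed.
#' @return A [Biostrings::QualityScaledDNAStringSet] with origin-encoded
#'   names.
#' @export
shotgun_reads <- function(genome, coverage = 1, read_length = 100L,
                          error_rate = 0, seed = NULL) {
  stopifnot(inherits(genome, "synthetic_genome"))
  stopifnot_scalar_num(coverage, "coverage", min = 0, strict = TRUE)
  if (read_length > genome$length)
    stop("read_length exceeds genome length")
  with_seed_if(seed, {
    G <- genome$length
    n <- round(coverage * G / read_length)
    starts <- sample.int(G - read_length + 1L, n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    seqs <- substring(genome$sequence, starts, starts + read_length - 1L)
    seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
    if (error_rate > 0) {
      n_err <- rbinom(n, read_length, error_rate)
      for (i in which(n_err > 0L)) {
        seqs[i] <- mutate_string(seqs[i], n_err[i])
      }
    }
    q <- if (error_rate > 0) min(40L, round(-10 * log10(error_rate))) else 40L
    lab <- origin_labels(genome$features, starts, read_length)
    ids <- sprintf("r%06d|%s|%d|%s", seq_len(n), lab, starts - 1L, strand)
    reads <- Biostrings::DNAStringSet(seqs)
    names(reads) <- ids
    qual <- Biostrings::PhredQuality(strrep(intToUtf8(q + 33L), read_length))
    Biostrings::QualityScaledDNAStringSet(
      reads, Biostrings::PhredQuality(rep(as.character(qual), n)))
  })
}

#' Decode planted-truth origin labels from simulated read names
#'
#' @param ids Character vector of read names produced by [shotgun_reads()].
#' @return data.frame with `read_id`, `origin` (family id or "background"),
#'   `start` (0-based genome position) and `strand`.
#' @export
read_origin <- function(ids) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  stopifnot(all(lengths(parts) == 4L))
  data.frame(read_id = ids,
             origin = vapply(parts, `[`, character(1L), 2L),
             start = as.integer(vapply(parts, `[`, character(1L), 3L)),
             strand = vapply(parts, `[`, character(1L), 4L),
             stringsAsFactors = FALSE)
}

#' Write simulator outputs to disk
#'
#' Emits the genome FASTA, the feature table as BED (0-based half-open),
#' and the ground-truth table as TSV (`family_id`, `copies`,
#' `true_half_life`, comma-separated `divergences`).
#'
#' @param genome A [simulate_genome()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fasta")
  dna <- Biostrings::DNAStringSet(genome$sequence)
  names(dna) <- "synthetic_genome"
  Biostrings::writeXStringSet(dna, fa)
  bed <- file.path(dir, "features.bed")
  write.table(
    data.frame(chrom = "synthetic_genome", start = genome$features$start,
               end = genome$features$end, name = genome$features$family_id,
               score = 0L, strand = genome$features$strand),
    bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  tsv <- file.path(dir, "truth.tsv")
  tr <- do.call(rbind, lapply(genome$truths, function(t) {
    data.frame(family_id = t$family_id, copies = t$surviving_copies,
               true_half_life = t$true_half_life,
               divergences = paste(signif(t$per_copy_divergence, 6),
                                   collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(tr)) tr <- data.frame(family_id = character(0))
  write.table(tr, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fa, bed, tsv))
}
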