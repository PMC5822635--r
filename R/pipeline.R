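#' Read shotgun reads from FASTQ or FASTA
#'
#' @param path Input file; `.fastq`/`.fq` files load with qualities.
#' @return A [Biostrings::QualityScaledDNAStringSet] (FASTQ) or
#'   [Biostrings::DNAStringSet] (FASTA).
#' @export
read_reads <- function(path) {
  if (grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE)) {
    Biostrings::readQualityScaledDNAStringSet(path)
  } else {
    Biostrings::readDNAStringSet(path)
  }
}

#' Write shotgun reads to FASTQ (Phred+33)
#'
#' @param reads A [Biostrings::QualityScaledDNAStringSet].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_reads <- function(reads, path) {
  Biostrings::writeQualityScaledXStringSet(reads, path)
  invisible(path)
}

pipeline_defaults <- function() {
  list(
    seed = NULL,
    simulate = NULL,
    reads = NULL,
    genome_size = NULL,
    filter = list(q_threshold = 30L, min_length = 80L),
    subsample = list(target_coverage = NULL),
    graph = list(min_similarity = 0.90, min_overlap_fraction = 0.55,
                 seed_kmer = 13L, method = "kmer"),
    cluster = list(min_cluster_reads = 10L,
                   min_cluster_fraction = 1e-4),
    assembly = list(min_contig_length = 500L, min_identity = 0.85,
                    min_anchor = 30L),
    annotate = list(library = NULL, min_identity = 0.80, min_alignment = 80L),
    divergence = list(min_identity = 0.85, min_depth = 4L,
                      min_covered_fraction = 0.6, single_copy_depth = NULL,
                      min_overlap = 30L),
    halflife = list(tol = 1e-6, min_records = 3L),
    network = list(window_length = 100L, enabled = TRUE)
  )
}

merge_config <- function(defaults, user, path = "config") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown ", path, " key(s): ", paste(unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]]) &&
        !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, "$", k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

build_sim_config <- function(sim) {
  fam_fields <- setdiff(names(sim), c("rdna", "simple", "background_length",
                                      "coverage", "read_length", "error_rate",
                                      "families"))
  if (length(fam_fields))
    stop("unknown simulate key(s): ", paste(fam_fields, collapse = ", "))
  fams <- lapply(sim$families %||% list(), function(f) do.call(family_params, f))
  genome_config(families = fams, rdna = sim$rdna, simple = sim$simple,
                background_length = sim$background_length %||% 0L)
}

#' Run the repeat-landscape pipeline end to end
#'
#' Chains the full analysis: obtain reads (simulate a genome or load
#' FASTQ/FASTA), quality-filter, optionally subsample to a target
#' coverage, build the similarity graph, cluster, assemble consensus
#' contigs per cluster, annotate against a repeat library (when given),
#' align reads back, compute per-contig divergence and copy number, fit
#' half-lives per repeat class, and build an ancestry network per cluster.
#' Stage outputs are written as plain-text interchange files under
#' `out_dir` along with a manifest echoing every parameter and seed; runs
#' are byte-identical under a fixed seed.
#'
#' @param config Named list (or path to a YAML file) of pipeline
#'   parameters; unknown keys are rejected.  Must contain either a
#'   `simulate` block or a `reads` path.
#' @param out_dir Output directory (created; pass `NULL` to skip writing).
#' @return A list of class `pipeline_run` with all stage results.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- merge_config(pipeline_defaults(), config)
  if (is.null(cfg$simulate) && is.null(cfg$reads))
    stop("config must provide either a 'simulate' block or a 'reads' path")

  run <- list(config = cfg)
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    gcfg <- build_sim_config(sim)
    gcfg$seed <- cfg$seed
    genome <- simulate_genome(gcfg)
    reads <- shotgun_reads(genome, coverage = sim$coverage %||% 1,
                           read_length = sim$read_length %||% 100L,
                           error_rate = sim$error_rate %||% 0,
                           seed = if (is.null(cfg$seed)) NULL else cfg$seed + 1L)
    run$genome <- genome
    genome_size <- genome$length
  } else {
    reads <- read_reads(cfg$reads)
    genome_size <- cfg$genome_size
    if (is.null(genome_size)) stop("genome_size required with external reads")
  }

  reads <- quality_filter(reads, cfg$filter$q_threshold, cfg$filter$min_length)
  if (!is.null(cfg$subsample$target_coverage)) {
    reads <- subsample(reads, genome_size, cfg$subsample$target_coverage,
                       seed = if (is.null(cfg$seed)) NULL else cfg$seed + 2L)
  }
  run$n_reads <- length(reads)
  seqs <- as_read_seqs(reads)

  graph <- build_graph(seqs, cfg$graph$min_similarity,
                       cfg$graph$min_overlap_fraction, cfg$graph$seed_kmer,
                       method = cfg$graph$method)
  clusters <- cluster_reads(graph)
  run$graph <- graph
  run$clusters <- clusters
  run$repeat_fraction <- repeat_fraction(clusters, length(seqs),
                                         cfg$cluster$min_cluster_fraction)

  big <- clusters$clusters[lengths(clusters$clusters) >=
                             cfg$cluster$min_cluster_reads]
  run$metrics <- do.call(rbind, lapply(names(big), function(cl) {
    tm <- topology_metrics(big[[cl]], graph)
    data.frame(cluster_id = cl, size = tm$size, density = tm$density,
               diameter_estimate = tm$diameter_estimate,
               topology_class = tm$topology_class, stringsAsFactors = FALSE)
  }))

  contigs <- character(0)
  contig_cluster <- character(0)
  for (cl in names(big)) {
    ct <- assemble_consensus(seqs, big[[cl]], graph,
                             min_contig_length = cfg$assembly$min_contig_length,
                             min_identity = cfg$assembly$min_identity,
                             min_anchor = cfg$assembly$min_anchor,
                             seed_kmer = cfg$graph$seed_kmer)
    if (length(ct)) {
      names(ct) <- paste0(cl, names(ct))
      contigs <- c(contigs, ct)
      contig_cluster <- c(contig_cluster, setNames(rep(cl, length(ct)), names(ct)))
    }
  }
  run$contigs <- contigs
  run$contig_cluster <- contig_cluster
  if (length(contigs) == 0L) {
    run$records <- NULL
    if (!is.null(out_dir)) write_pipeline_outputs(run, out_dir)
    class(run) <- "pipeline_run"
    return(run)
  }

  if (!is.null(cfg$annotate$library)) {
    lib <- if (inherits(cfg$annotate$library, "repeat_library"))
      cfg$annotate$library else read_repeat_library(cfg$annotate$library)
    run$classification <- classify_contigs(contigs, lib,
                                           cfg$annotate$min_identity,
                                           cfg$annotate$min_alignment)
  }

  aln <- align_reads(seqs, contigs, cfg$divergence$min_identity,
                     cfg$graph$seed_kmer, cfg$divergence$min_overlap)
  cols <- pileup(aln, contigs)
  scd <- cfg$divergence$single_copy_depth %||%
    (sum(nchar(seqs)) / genome_size)
  run$single_copy_depth <- scd
  run$alignments <- aln
  run$pileup <- cols
  run$records <- divergence_records(cols, run$classification, scd,
                                    cfg$divergence$min_depth,
                                    cfg$divergence$min_covered_fraction)

  if (!is.null(run$classification)) {
    cls_counts <- table(run$records$class_label)
    fit_classes <- names(cls_counts)[cls_counts >= cfg$halflife$min_records]
    run$fits <- lapply(setNames(fit_classes, fit_classes), function(cl) {
      fit_halflife(run$records[run$records$class_label %in% cl, , drop = FALSE],
                   group_id = cl, tol = cfg$halflife$tol)
    })
  }

  if (isTRUE(cfg$network$enabled)) {
    run$networks <- list()
    # reads must fully span the window: cap it below the read length
    wl <- min(cfg$network$window_length,
              floor(0.7 * stats::median(nchar(seqs))))
    for (cid in names(contigs)) {
      net <- tryCatch({
        cc <- cols[cols$contig_id == cid, , drop = FALSE]
        w0 <- highest_depth_window(cc, wl)
        win <- extract_window(aln, cid, w0, wl)
        hap <- collapse_identical(win)
        if (nrow(hap) < 2L) NULL else {
          nw <- build_arborescence(hap)
          list(network = nw, score = expansion_score(nw), window_start = w0)
        }
      }, error = function(e) NULL)
      if (!is.null(net)) run$networks[[cid]] <- net
    }
  }

  class(run) <- "pipeline_run"
  if (!is.null(out_dir)) write_pipeline_outputs(run, out_dir)
  run
}

write_pipeline_outputs <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) if (!is.null(df) && nrow(df))
    write.table(df, file.path(out_dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  w(run$clusters$membership, "clusters.tsv")
  w(run$metrics, "metrics.tsv")
  w(run$graph$edges, "graph_edges.tsv")
  if (length(run$contigs)) {
    ct <- Biostrings::DNAStringSet(run$contigs)
    Biostrings::writeXStringSet(ct, file.path(out_dir, "contigs.fasta"))
  }
  w(run$classification, "classification.tsv")
  w(run$records, "divergence_records.tsv")
  if (!is.null(run$fits)) {
    fits <- do.call(rbind, lapply(run$fits, function(f)
      data.frame(group = f$group_id, slope = f$slope, intercept = f$intercept,
                 r_squared = f$r_squared, n_points = f$n_points,
                 half_life = f$half_life,
                 half_life_percent = f$half_life_percent,
                 dynamics = f$dynamics, stringsAsFactors = FALSE)))
    w(fits, "halflife_fits.tsv")
  }
  if (!is.null(run$networks) && length(run$networks)) {
    ns <- do.call(rbind, lapply(names(run$networks), function(cid) {
      x <- run$networks[[cid]]
      data.frame(contig_id = cid, root = x$network$root,
                 n_nodes = nrow(x$network$nodes),
                 max_out_degree = x$score$max_out_degree,
                 star_score = x$score$star_score,
                 window_start = x$window_start, stringsAsFactors = FALSE)
    }))
    w(ns, "networks.tsv")
    for (cid in names(run$networks)) {
      write_ancestry_network(run$networks[[cid]]$network,
                             file.path(out_dir, paste0("network_", cid, ".tsv")))
    }
  }
  summ <- summarize_run(run)
  w(summ, "summary.tsv")
  manifest <- list(package_version = as.character(utils::packageVersion("repeatscape")),
                   seed = run$config$seed,
                   parameters = run$config[setdiff(names(run$config),
                                                   c("simulate", "reads"))],
                   n_reads = run$n_reads,
                   repeat_fraction = run$repeat_fraction)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' Summary table of a pipeline run
#'
#' Per-class genome percentages (reads in clusters annotated to each
#' class over total reads), the unclustered/background remainder, and
#' per-class half-life and expansion summaries.  Percentages plus the
#' remainder sum to 100.
#'
#' @param run A [run_pipeline()] result.
#' @return data.frame with `category`, `percent_of_reads`, `n_reads`.
#' @export
summarize_run <- function(run) {
  stopifnot(inherits(run, "pipeline_run") || is.list(run))
  total <- run$n_reads
  memb <- run$clusters$membership
  cluster_class <- NULL
  if (!is.null(run$classification) && length(run$contig_cluster)) {
    cc <- data.frame(cluster_id = unname(run$contig_cluster),
                     contig_id = names(run$contig_cluster),
                     stringsAsFactors = FALSE)
    cc$class <- run$classification$class_label[
      match(cc$contig_id, run$classification$contig_id)]
    # one class per cluster: the class of its first contig
    cluster_class <- tapply(cc$class, cc$cluster_id, function(x) x[1L])
  }
  cl_of_read <- memb$cluster_id
  cls <- rep("Unclustered", nrow(memb))
  in_cluster <- !is.na(cl_of_read)
  cls[in_cluster] <- "Unclassified"
  if (!is.null(cluster_class)) {
    known <- cl_of_read %in% names(cluster_class)
    cls[known] <- cluster_class[cl_of_read[known]]
  }
  tab <- table(cls)
  out <- data.frame(category = names(tab),
                    percent_of_reads = 100 * as.integer(tab) / total,
                    n_reads = as.integer(tab), stringsAsFactors = FALSE)
  out[order(-out$percent_of_reads), , drop = FALSE]
}
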