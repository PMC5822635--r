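test_that("quality filter trims 3' tails and drops short reads", {
  set.seed(1)
  s100 <- rand_seq(100)
  reads <- make_fastq_reads(
    list(s100, rand_seq(100), rand_seq(100)),
    list(rep(40L, 100),                  # pristine: kept unchanged
         c(rep(40L, 79), rep(2L, 21)),   # trims to 79: dropped
         c(rep(40L, 80), rep(2L, 20))))  # trims to 80: kept
  out <- suppressMessages(quality_filter(reads, q_threshold = 30, min_length = 80))
  expect_equal(length(out), 2L)
  expect_identical(as.character(out[[1]]), s100)
  expect_equal(Biostrings::width(out)[2], 80L)
  expect_equal(attr(out, "n_dropped"), 1L)
})

test_that("FASTA input passes through the quality filter with a warning", {
  reads <- Biostrings::DNAStringSet(replicate(10, rand_seq(60)))
  expect_warning(out <- quality_filter(reads), "FASTA")
  expect_equal(length(out), 10L)
})

test_that("subsampling hits the target coverage and is seed-deterministic", {
  reads <- setNames(replicate(200, rand_seq(100)), sprintf("r%03d", 1:200))
  sub <- subsample(reads, genome_size = 10000, target_coverage = 1, seed = 5)
  expect_length(sub, 100)
  sub2 <- subsample(reads, genome_size = 10000, target_coverage = 1, seed = 5)
  expect_identical(sub, sub2)
  expect_warning(all_back <- subsample(reads, 10000, target_coverage = 5),
                 "exceeds")
  expect_length(all_back, 200)
})

test_that("pairwise similarity handles identity, reverse complement and mismatches", {
  set.seed(2)
  a <- rand_seq(100)
  ps <- pairwise_similarity(a, a)
  expect_equal(ps$similarity, 1.0)
  expect_equal(ps$overlap_length, 100L)
  expect_identical(ps$orientation, "forward")

  ps_rc <- pairwise_similarity(a, rc(a))
  expect_equal(ps_rc$similarity, 1.0)
  expect_equal(ps_rc$overlap_length, 100L)
  expect_identical(ps_rc$orientation, "reverse")

  ps_mm <- pairwise_similarity("ACGTACGTAC", "ACGTTCGTAC")
  expect_equal(ps_mm$similarity, 0.9)
  expect_equal(ps_mm$overlap_length, 10L)
})

test_that("graph edges obey the admission thresholds on constructed triples", {
  set.seed(3)
  a <- rand_seq(100)
  reads <- c(a = a, b = a, c = rand_seq(100))
  for (m in c("kmer", "exact")) {
    g <- build_graph(reads, method = m)
    expect_equal(nrow(g$edges), 1L)
    expect_setequal(unlist(g$edges[, c("from", "to")]), c("a", "b"))
    expect_length(g$nodes, 3L)
  }
})

test_that("five identical reads give the complete graph K5", {
  set.seed(4)
  a <- rand_seq(120)
  reads <- setNames(rep(a, 5), letters[1:5])
  g <- build_graph(reads)
  expect_equal(nrow(g$edges), 10L)
  expect_true(all(g$edges$similarity == 1))
})

test_that("graph and clustering are invariant to reverse-complementing reads", {
  set.seed(5)
  template <- rand_seq(400)
  reads <- tile_reads(template, c(1, 41, 81, 131, 201, 241), 100)
  reads <- c(reads, x1 = rand_seq(100))
  g1 <- build_graph(reads)
  flip <- c(2, 4, 7)
  reads2 <- reads
  reads2[flip] <- vapply(reads[flip], rc, character(1))
  g2 <- build_graph(reads2)
  canon <- function(g) {
    e <- g$edges
    key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
    e[order(key), c("similarity", "overlap")]
  }
  expect_equal(canon(g1)$overlap, canon(g2)$overlap)
  c1 <- cluster_reads(g1); c2 <- cluster_reads(g2)
  expect_identical(c1$clusters, c2$clusters)
  expect_identical(c1$unclustered, c2$unclustered)
})

test_that("every admitted edge satisfies the thresholds", {
  g <- planted_two_family_genome(n_copies = 10, element_length = 1000,
                                 background = 10000, seed = 2)
  reads <- shotgun_reads(g, coverage = 2, read_length = 100,
                         error_rate = 0.005, seed = 3)
  seqs <- setNames(as.character(reads), names(reads))
  gr <- build_graph(seqs)
  expect_gt(nrow(gr$edges), 0)
  expect_true(all(gr$edges$similarity >= 0.90))
  w <- nchar(seqs)
  expect_true(all(gr$edges$overlap >=
                    0.55 * pmin(w[gr$edges$from], w[gr$edges$to]) - 1e-9))
  # clusters plus unclustered reads exactly partition the input
  cl <- cluster_reads(gr)
  all_ids <- c(unlist(cl$clusters, use.names = FALSE), cl$unclustered)
  expect_setequal(all_ids, gr$nodes)
  expect_equal(length(all_ids), length(gr$nodes))
})

test_that("connected components become clusters and singletons stay out", {
  set.seed(7)
  template <- rand_seq(200)
  reads <- c(a = substr(template, 1, 100), b = substr(template, 41, 140),
             c = substr(template, 81, 180), d = rand_seq(100))
  g <- build_graph(reads)
  cl <- cluster_reads(g)
  expect_length(cl$clusters, 1L)
  expect_setequal(cl$clusters[[1]], c("a", "b", "c"))
  expect_identical(cl$unclustered, "d")

  # no edges at all: everything unclustered
  g0 <- build_graph(c(x = rand_seq(80), y = rand_seq(80), z = rand_seq(80)))
  cl0 <- cluster_reads(g0)
  expect_length(cl0$clusters, 0L)
  expect_length(cl0$unclustered, 3L)
})

test_that("topology metrics match hand-computed graphs", {
  set.seed(8)
  a <- rand_seq(100)
  k4 <- build_graph(setNames(rep(a, 4), letters[1:4]))
  tm <- topology_metrics(letters[1:4], k4)
  expect_equal(tm$density, 1.0)
  expect_equal(tm$diameter_estimate, 1L)
  expect_identical(tm$topology_class, "dense-circularizable")

  # path of 4 nodes: density 3/6, diameter 3
  template <- rand_seq(220)
  p4 <- tile_reads(template, c(1, 41, 81, 121), 100)
  gp <- build_graph(p4)
  expect_equal(nrow(gp$edges), 3L)
  tmp <- topology_metrics(names(p4), gp)
  expect_equal(tmp$density, 0.5)
  expect_equal(tmp$diameter_estimate, 3L)

  # 6-cycle on a circular template: density 6/15 = 0.4, diameter 3
  circ <- rand_seq(270)
  wrap <- paste0(circ, substr(circ, 1, 99))
  c6 <- tile_reads(wrap, c(1, 46, 91, 136, 181, 226), 100)
  gc <- build_graph(c6)
  expect_equal(nrow(gc$edges), 6L)
  tmc <- topology_metrics(names(c6), gc)
  expect_equal(tmc$density, 0.4)
  expect_equal(tmc$diameter_estimate, 3L)

  expect_error(topology_metrics("a", k4), "singleton")
})

test_that("three error-free tiling reads reassemble their template exactly", {
  set.seed(9)
  template <- rand_seq(200)
  reads <- tile_reads(template, c(1, 51, 101), 100)
  ct <- assemble_consensus(reads, names(reads), min_contig_length = 150,
                           min_end_depth = 1)
  expect_length(ct, 1L)
  expect_identical(unname(ct[1]), template)
})

test_that("majority vote resolves columns with alphabetical tie-break", {
  counts <- matrix(0L, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  counts["A", 1] <- 2L; counts["C", 1] <- 1L   # A,A,C -> A
  counts["A", 2] <- 1L; counts["C", 2] <- 1L   # tie A/C -> A
  counts["G", 3] <- 3L
  expect_identical(repeatscape:::consensus_call(counts), "AAG")
})

test_that("contigs below the minimum length are discarded", {
  set.seed(10)
  a <- rand_seq(400)
  reads <- tile_reads(a, c(1, 101, 201), 200)
  ct <- assemble_consensus(reads, names(reads), min_contig_length = 500,
                           min_end_depth = 1)
  expect_length(ct, 0L)
  expect_equal(attr(ct, "n_discarded"), 1L)
})

test_that("repeat fraction follows cluster sizes and its threshold monotonically", {
  fake <- structure(list(
    clusters = list(CL1 = sprintf("a%d", 1:600), CL2 = sprintf("b%d", 1:300)),
    unclustered = sprintf("u%d", 1:100)), class = "read_clusters")
  expect_equal(repeat_fraction(fake, 1000, min_cluster_fraction = 0.01), 0.9)
  expect_equal(repeat_fraction(fake, 1000, min_cluster_fraction = 0.7), 0)
  expect_equal(repeat_fraction(fake, 1000, min_cluster_fraction = 0.35), 0.6)
  th <- c(1e-4, 0.01, 0.1, 0.31, 0.61)
  fr <- vapply(th, function(t) repeat_fraction(fake, 1000, t), numeric(1))
  expect_true(all(diff(fr) <= 0))
  expect_error(repeat_fraction(fake, 0), "positive")
})
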