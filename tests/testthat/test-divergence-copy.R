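make_contig <- function(n = 300) setNames(rand_seq(n), "ctg1")

test_that("reads place at their true positions on either strand", {
  set.seed(21)
  ct <- make_contig(300)
  reads <- c(fwd = substr(ct[[1]], 11, 110),
             rev = rc(substr(ct[[1]], 1, 100)),
             junk = rand_seq(100))
  aln <- align_reads(reads, ct)
  expect_setequal(aln$read_id, c("fwd", "rev"))
  expect_equal(aln$offset[aln$read_id == "fwd"], 10L)
  expect_identical(aln$strand[aln$read_id == "fwd"], "forward")
  expect_equal(aln$offset[aln$read_id == "rev"], 0L)
  expect_identical(aln$strand[aln$read_id == "rev"], "reverse")
  expect_equal(attr(aln, "n_unaligned"), 1L)
  expect_error(align_reads(reads, character(0)), "non-empty")
})

test_that("pileup counts bases with strand-complement bookkeeping", {
  set.seed(22)
  ct <- make_contig(40)
  reads <- c(f1 = substr(ct[[1]], 1, 5))
  aln <- align_reads(reads, ct, min_overlap = 5, seed_kmer = 5)
  cols <- pileup(aln, ct)
  expect_equal(nrow(cols), 40L)
  expect_equal(sum(cols$depth), 5L)
  first5 <- cols[cols$pos < 5, ]
  bases <- strsplit(substr(ct[[1]], 1, 5), "")[[1]]
  for (i in 1:5) expect_equal(first5[i, bases[i]], 1)

  # two identical stacked reads, plus the same locus on the reverse strand
  reads2 <- c(f1 = substr(ct[[1]], 1, 30), f2 = substr(ct[[1]], 1, 30),
              r1 = rc(substr(ct[[1]], 1, 30)))
  cols2 <- pileup(align_reads(reads2, ct), ct)
  expect_true(all(cols2$depth[cols2$pos < 30] == 3))
  counts <- as.matrix(cols2[cols2$pos < 30, c("A", "C", "G", "T")])
  expect_true(all(apply(counts, 1, max) == 3))  # all three reads agree
})

test_that("total pileup bases equal total aligned read bases", {
  g <- planted_two_family_genome(n_copies = 15, element_length = 800,
                                 background = 8000, seed = 5)
  reads <- shotgun_reads(g, coverage = 2, read_length = 100,
                         error_rate = 0.002, seed = 6)
  ct <- setNames(g$ancestors$famA, "famA")
  aln <- align_reads(setNames(as.character(reads), names(reads)), ct)
  # clip overhanging bases the way the pileup will
  lens <- pmin(aln$offset + nchar(aln$oriented), nchar(ct)) - pmax(aln$offset, 0L)
  cols <- pileup(aln, ct)
  expect_equal(sum(cols$depth), sum(lens))
})

test_that("per-site diversity matches the worked examples", {
  col <- function(A = 0, C = 0, G = 0, T = 0)
    data.frame(A = A, C = C, G = G, T = T)
  expect_equal(theta_pi(col(A = 6), min_depth = 4)$theta_pi, 0)
  expect_equal(theta_pi(col(A = 2, C = 2), min_depth = 4)$theta_pi, 2 / 3,
               tolerance = 1e-12)
  expect_equal(theta_pi(col(A = 3, G = 1), min_depth = 4)$theta_pi, 0.5,
               tolerance = 1e-12)
  expect_error(theta_pi(col(A = 2), min_depth = 4), "insufficient coverage")
})

test_that("closed-form per-site pi equals brute-force pair counting", {
  set.seed(23)
  for (i in 1:200) {
    n <- sample(2:20, 1)
    counts <- as.vector(stats::rmultinom(1, n, prob = runif(4, 0.05, 1)))
    expect_equal(repeatscape:::pi_site(counts), pi_site_bruteforce(counts),
                 tolerance = 1e-12)
  }
})

test_that("copy number is mean depth over single-copy depth", {
  cols <- data.frame(A = rep(50L, 20), C = 0L, G = 0L, T = 0L,
                     depth = rep(50L, 20))
  expect_equal(copy_number(cols, 1)$copy_number, 50)
  expect_equal(copy_number(cols, 2)$copy_number, 25)
  # zero-depth positions count toward the mean
  cols2 <- rbind(cols, data.frame(A = 0L, C = 0L, G = 0L, T = 0L,
                                  depth = rep(0L, 20)))
  expect_equal(copy_number(cols2, 1)$copy_number, 25)
})

test_that("a planted 40-copy family is recovered near its copy number", {
  fp <- family_params("famA", element_length = 1000, birth_rate = 0,
                      death_rate = 0, mutation_rate = 0, duration = 1,
                      n_initial = 40, seed = 31)
  g <- simulate_genome(genome_config(families = list(fp),
                                     background_length = 40000, seed = 32))
  reads <- shotgun_reads(g, coverage = 1, read_length = 100,
                         error_rate = 0, seed = 33)
  ct <- setNames(g$ancestors$famA, "famA")
  aln <- align_reads(setNames(as.character(reads), names(reads)), ct)
  cols <- pileup(aln, ct)
  cn <- copy_number(cols, single_copy_depth = 1)$copy_number
  expect_lt(abs(cn - 40) / 40, 0.15)
  # error-free identical copies: zero diversity
  tp <- theta_pi(cols)
  expect_equal(tp$theta_pi, 0)
})

test_that("theta-pi grows monotonically with simulated family divergence", {
  tps <- vapply(c(0.005, 0.02, 0.05), function(mu) {
    fp <- family_params("f", element_length = 800, birth_rate = 0,
                        death_rate = 0, mutation_rate = mu, duration = 1,
                        n_initial = 30, seed = round(1000 * mu))
    g <- simulate_genome(genome_config(families = list(fp),
                                       background_length = 5000, seed = 35))
    reads <- shotgun_reads(g, coverage = 2, read_length = 100,
                           error_rate = 0, seed = 36)
    ct <- setNames(g$ancestors$f, "f")
    aln <- align_reads(setNames(as.character(reads), names(reads)), ct,
                       min_identity = 0.8)
    theta_pi(pileup(aln, ct))$theta_pi
  }, numeric(1))
  expect_true(all(diff(tps) > 0))
})

test_that("gapless SAM records ingest into the same alignment table", {
  set.seed(24)
  ct <- make_contig(200)
  r1 <- substr(ct[[1]], 21, 120)
  sam <- c(
    "@HD\tVN:1.6",
    "@SQ\tSN:ctg1\tLN:200",
    paste("q1", 0, "ctg1", 21, 60, "100M", "*", 0, 0, r1,
          strrep("I", 100), sep = "\t"),
    paste("q2", 16, "ctg1", 1, 60, "5S95M", "*", 0, 0,
          paste0("NNNNN", substr(ct[[1]], 1, 95)), strrep("I", 100), sep = "\t"),
    paste("q3", 0, "ctg1", 50, 60, "40M2D60M", "*", 0, 0,
          rand_seq(100), strrep("I", 100), sep = "\t"))
  f <- withr::local_tempfile(fileext = ".sam")
  writeLines(sam, f)
  expect_warning(aln <- read_sam_alignments(f, ct), "indels")
  expect_equal(nrow(aln), 2L)
  expect_equal(aln$offset, c(20L, 0L))
  expect_equal(aln$identity, c(1, 1))
  cols <- pileup(aln, ct)
  expect_equal(sum(cols$depth), 195L)
})

test_that("divergence records combine diversity and depth per contig", {
  set.seed(25)
  g <- planted_two_family_genome(n_copies = 20, element_length = 800,
                                 background = 5000, seed = 9)
  reads <- shotgun_reads(g, coverage = 2, read_length = 100,
                         error_rate = 0.001, seed = 10)
  cts <- c(famA = g$ancestors$famA, famB = g$ancestors$famB)
  aln <- align_reads(setNames(as.character(reads), names(reads)), cts,
                     min_identity = 0.8)
  cols <- pileup(aln, cts)
  cls <- data.frame(contig_id = c("famA", "famB"),
                    class_label = c("LTR/Copia", "LTR/Gypsy"))
  rec <- divergence_records(cols, cls, single_copy_depth = 2)
  expect_equal(nrow(rec), 2L)
  expect_identical(rec$class_label, cls$class_label)
  expect_true(all(rec$theta_pi > 0 & rec$theta_pi < 1))
  expect_true(all(abs(rec$copy_number - 20) / 20 < 0.25))
})
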