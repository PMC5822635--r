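test_that("no mutation yields copies identical to the ancestor", {
  fp <- family_params("f", element_length = 500, birth_rate = 2, death_rate = 1,
                      mutation_rate = 0, duration = 1, n_initial = 5, seed = 3)
  sim <- simulate_family(fp)
  expect_gt(sim$truth$surviving_copies, 0)
  expect_true(all(sim$copies == sim$ancestor))
  expect_true(all(sim$truth$per_copy_divergence == 0))
})

test_that("zero death rate leaves the half-life undefined", {
  fp <- family_params("f", element_length = 200, birth_rate = 1, death_rate = 0,
                      mutation_rate = 0.01, duration = 1, seed = 1)
  expect_true(is.na(fp$true_half_life))
  fp2 <- family_params("f", element_length = 200, birth_rate = 1,
                       death_rate = 4, mutation_rate = 0.02, duration = 1)
  expect_equal(fp2$true_half_life, log(2) * 0.02 / 4)
})

test_that("extinction returns zero copies with truth recorded", {
  fp <- family_params("f", element_length = 200, birth_rate = 0,
                      death_rate = 50, mutation_rate = 0.01, duration = 2,
                      n_initial = 1, seed = 9)
  sim <- simulate_family(fp)
  expect_identical(sim$truth$surviving_copies, 0L)
  expect_length(sim$copies, 0)
})

test_that("copy explosion above the cap aborts with a clear error", {
  fp <- family_params("f", element_length = 100, birth_rate = 40,
                      death_rate = 0, mutation_rate = 0, duration = 2,
                      n_initial = 10, copy_cap = 50, seed = 2)
  expect_error(simulate_family(fp), "copy_cap")
})

test_that("family parameter validation rejects bad inputs", {
  expect_error(family_params("f", element_length = 50, birth_rate = 1,
                             death_rate = 1, mutation_rate = 0.1, duration = 1),
               "element_length")
  expect_error(family_params("f", birth_rate = -1, death_rate = 1,
                             mutation_rate = 0.1, duration = 1), "birth_rate")
  expect_error(family_params("f", birth_rate = 1, death_rate = 1,
                             mutation_rate = 0.1, duration = 0), "duration")
})

test_that("steady-state divergences follow the exponential law", {
  # at birth_rate == death_rate the surviving-copy age distribution is
  # exponential with the death rate; divergence maps through mutation_rate
  fp <- family_params("f", element_length = 1000, birth_rate = 5,
                      death_rate = 5, mutation_rate = 5 / 13.8629,
                      duration = 1, n_initial = 700, seed = 17)
  sim <- simulate_family(fp)
  expect_gte(sim$truth$surviving_copies, 500)
  ks <- suppressWarnings(
    stats::ks.test(sim$truth$per_copy_divergence, "pexp", 13.8629))
  expect_gt(ks$p.value, 0.01)
})

test_that("a planted family of identical copies gives the stated genome fraction", {
  fp <- family_params("fam1", element_length = 1000, birth_rate = 0,
                      death_rate = 0, mutation_rate = 0, duration = 1,
                      n_initial = 10, seed = 4)
  g <- simulate_genome(genome_config(families = list(fp),
                                     background_length = 10000, seed = 5))
  expect_equal(nrow(g$features), 10)
  expect_equal(g$length, 20000)
  expect_equal(g$repetitive_fraction, 0.5)
  expect_equal(sum(g$features$end - g$features$start), 10000)
  # features lie in bounds and the planted copies occupy their coordinates
  expect_true(all(g$features$start >= 0 & g$features$end <= g$length))
  f1 <- g$features[1, ]
  planted <- substr(g$sequence, f1$start + 1, f1$end)
  if (f1$strand == "-") planted <- rc(planted)
  expect_identical(planted, g$ancestors$fam1)
})

test_that("an empty family list gives pure background", {
  g <- simulate_genome(genome_config(background_length = 5000, seed = 8))
  expect_equal(g$length, 5000)
  expect_equal(g$repetitive_fraction, 0)
  expect_equal(nrow(g$features), 0)
})

test_that("genome simulation is byte-identical under a fixed seed", {
  cfg <- genome_config(
    families = list(family_params("f", element_length = 500, birth_rate = 1,
                                  death_rate = 1, mutation_rate = 0.1,
                                  duration = 1, n_initial = 5, seed = 6)),
    rdna = list(unit_length = 600, n_copies = 5),
    simple = list(n_stretches = 2, stretch_length = 800),
    background_length = 5000, seed = 7)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(g1$features, g2$features)
  r1 <- shotgun_reads(g1, coverage = 2, read_length = 80, error_rate = 0.01,
                      seed = 11)
  r2 <- shotgun_reads(g1, coverage = 2, read_length = 80, error_rate = 0.01,
                      seed = 11)
  expect_identical(as.character(r1), as.character(r2))
})

test_that("read count follows coverage * genome / read_length", {
  g <- simulate_genome(genome_config(background_length = 10000, seed = 2))
  r1 <- shotgun_reads(g, coverage = 1, read_length = 100, seed = 3)
  expect_length(r1, 100)
  r5 <- shotgun_reads(g, coverage = 5, read_length = 100, seed = 3)
  expect_length(r5, 500)
})

test_that("error-free reads are exact genome substrings on either strand", {
  g <- simulate_genome(genome_config(background_length = 4000, seed = 21))
  r <- shotgun_reads(g, coverage = 1, read_length = 60, error_rate = 0, seed = 22)
  org <- read_origin(names(r))
  for (i in seq_len(length(r))) {
    s <- as.character(r[[i]])
    piece <- substr(g$sequence, org$start[i] + 1, org$start[i] + 60)
    expect_identical(s, if (org$strand[i] == "+") piece else rc(piece))
  }
})

test_that("read origin labels track the planted repetitive fraction", {
  g <- planted_two_family_genome(n_copies = 20, element_length = 1000,
                                 background = 20000, seed = 3)
  r <- shotgun_reads(g, coverage = 2, read_length = 100, seed = 13)
  org <- read_origin(names(r))
  expect_setequal(unique(org$origin), c("famA", "famB", "background"))
  frac <- mean(org$origin != "background")
  expect_lt(abs(frac - g$repetitive_fraction), 0.05)
})

test_that("phred qualities encode the error rate", {
  g <- simulate_genome(genome_config(background_length = 3000, seed = 2))
  r <- shotgun_reads(g, coverage = 1, read_length = 50, error_rate = 0.01,
                     seed = 4)
  q <- methods::as(Biostrings::quality(r), "IntegerList")[[1]]
  expect_true(all(q == 20L))
})

test_that("simulator outputs round-trip to disk as plain text", {
  g <- planted_two_family_genome(n_copies = 5, element_length = 1000,
                                 background = 3000, seed = 6)
  dir <- withr::local_tempdir()
  paths <- write_genome(g, dir)
  expect_true(all(file.exists(paths)))
  fa <- Biostrings::readDNAStringSet(file.path(dir, "genome.fasta"))
  expect_identical(as.character(fa[[1]]), g$sequence)
  bed <- read.table(file.path(dir, "features.bed"), sep = "\t")
  expect_equal(nrow(bed), nrow(g$features))
  r <- shotgun_reads(g, coverage = 1, read_length = 80, error_rate = 0.01,
                     seed = 2)
  fq <- file.path(dir, "reads.fastq")
  write_reads(r, fq)
  back <- suppressWarnings(read_reads(fq))  # Biostrings drops mcols on load
  expect_identical(as.character(back), setNames(as.character(r), names(r)))
})
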