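# Shared fixtures and independent oracles, built in code at test time.

BASES4 <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(BASES4, n, replace = TRUE), collapse = "")

rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

# Substitute exactly `k` distinct positions (no multiple hits): divergence
# bookkeeping in tests is exact by construction.
sub_k <- function(s, k, positions = NULL) {
  ch <- strsplit(s, "")[[1]]
  if (is.null(positions)) positions <- sample(length(ch), k)
  for (p in positions) ch[p] <- sample(setdiff(BASES4, ch[p]), 1)
  paste(ch, collapse = "")
}

# FASTQ-style read set with explicit per-base integer qualities.
make_fastq_reads <- function(seqs, quals_int) {
  s <- Biostrings::DNAStringSet(unlist(seqs))
  names(s) <- sprintf("r%03d", seq_along(seqs))
  q <- vapply(quals_int, function(qq) intToUtf8(qq + 33L), character(1))
  Biostrings::QualityScaledDNAStringSet(s, Biostrings::PhredQuality(q))
}

# Reads tiling a template at given 1-based start positions.
tile_reads <- function(template, starts, len) {
  out <- substring(template, starts, starts + len - 1L)
  names(out) <- sprintf("t%03d", seq_along(out))
  out
}

# Brute-force per-site pairwise diversity: differing pairs / choose(n, 2).
pi_site_bruteforce <- function(counts) {
  reads <- rep(seq_along(counts), counts)
  n <- length(reads)
  if (n < 2) return(NA_real_)
  diff_pairs <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) if (reads[i] != reads[j]) diff_pairs <- diff_pairs + 1L
  }
  diff_pairs / choose(n, 2)
}

# Exact two-sided Mann-Whitney p-value by exhaustive enumeration of all
# choose(n1 + n2, n1) group assignments (no ties assumed).
mw_exact_p <- function(x, y) {
  nx <- length(x)
  N <- nx + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * (N - nx) / 2
  combs <- utils::combn(N, nx)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Minimum spanning-tree weight by exhaustive enumeration of all n^(n-2)
# labeled spanning trees (Pruefer sequences) of the complete graph.
min_spanning_weight_exhaustive <- function(d) {
  n <- nrow(d)
  if (n == 2) return(d[1, 2])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- Inf
  for (row in seq_len(nrow(seqs))) {
    pr <- seqs[row, ]
    avail <- rep(1L, n)
    for (v in pr) avail[v] <- avail[v] + 1L
    w <- 0
    for (k in seq_len(n - 2)) {
      leaf <- which(avail == 1L)[1]
      v <- pr[k]
      w <- w + d[leaf, v]
      avail[leaf] <- 0L
      avail[v] <- avail[v] - 1L
    }
    last <- which(avail == 1L)
    w <- w + d[last[1], last[2]]
    if (w < best) best <- w
  }
  best
}

# Total weight of an emitted ancestry network.
network_weight <- function(net) sum(net$edges$distance)

# Simple planted two-family genome used by several tests.
planted_two_family_genome <- function(n_copies = 100L, element_length = 1000L,
                                      mu = 0.03, background = 200000L,
                                      seed = 1L) {
  fa <- family_params("famA", element_length = element_length, birth_rate = 0,
                      death_rate = 0, mutation_rate = mu, duration = 1,
                      n_initial = n_copies, seed = seed * 101L)
  fb <- family_params("famB", element_length = element_length, birth_rate = 0,
                      death_rate = 0, mutation_rate = mu, duration = 1,
                      n_initial = n_copies, seed = seed * 101L + 1L)
  simulate_genome(genome_config(families = list(fa, fb),
                                background_length = background,
                                seed = seed * 101L + 2L))
}
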