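#' Fit a repeat half-life from copy number vs divergence
#'
#' Under a steady-state birth-death model, the number of surviving
#' insertions decays exponentially with their divergence from the active
#' element, so `ln(copy_number)` is linear in divergence.  This fits the
#' ordinary least-squares regression `ln(copy_number) = a + b * theta_pi`
#' and converts the slope to the family half-life -- the divergence at
#' which half of all insertions have been lost -- as `ln(2) / (-b)`.
#'
#' Dynamics follow the slope sign: negative slopes are the neutral decay
#' the steady-state model predicts; positive slopes indicate copies that
#' proliferated after diverging (recent expansion, or directional
#' selection); near-zero slopes (within `tol`) are flat.  The half-life is
#' finite and positive only for decay; it is `Inf` for flat fits and `NA`
#' for expansion.
#'
#' @param records data.frame with columns `theta_pi` and `copy_number`
#'   (e.g. from [divergence_records()] or [binned_copy_profile()]).
#' @param group_id Label carried into the result.
#' @param tol Slope magnitude below which dynamics are "flat".
#' @param log10 Use base-10 logs for the fit; the half-life is rescaled
#'   consistently and is identical either way.
#' @return Object of class `halflife_fit`: list with `group_id`, `slope`,
#'   `intercept`, `r_squared`, `n_points`, `half_life`, `half_life_percent`
#'   and `dynamics` ("decay" / "expansion" / "flat").
#' @export
fit_halflife <- function(records, group_id = "group", tol = 1e-6,
                         log10 = FALSE) {
  stopifnot(all(c("theta_pi", "copy_number") %in% names(records)))
  bad <- records$copy_number <= 0
  if (any(bad)) {
    warning(sum(bad), " record(s) with copy_number <= 0 excluded from fit")
    records <- records[!bad, , drop = FALSE]
  }
  if (nrow(records) < 3L)
    stop("need at least 3 records with positive copy number to fit a half-life")
  y <- if (log10) log10(records$copy_number) else log(records$copy_number)
  fit <- lm(y ~ records$theta_pi)
  b <- unname(coef(fit)[2L]); a <- unname(coef(fit)[1L])
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else NA_real_
  # slope in natural-log units regardless of display base
  b_nat <- if (log10) b * log(10) else b
  if (b_nat < -tol) {
    dynamics <- "decay"; hl <- log(2) / (-b_nat)
  } else if (b_nat > tol) {
    dynamics <- "expansion"; hl <- NA_real_
  } else {
    dynamics <- "flat"; hl <- Inf
  }
  structure(list(group_id = group_id, slope = b, intercept = a,
                 r_squared = r2, n_points = nrow(records),
                 half_life = hl, half_life_percent = 100 * hl,
                 dynamics = dynamics, log10 = log10),
            class = "halflife_fit")
}

#' @export
print.halflife_fit <- function(x, ...) {
  cat(sprintf("Half-life fit for '%s' (%d points)\n", x$group_id, x$n_points))
  cat(sprintf("  slope %.4f%s  intercept %.4f  r^2 %.4f\n", x$slope,
              if (x$log10) " (log10)" else "", x$intercept, x$r_squared))
  cat(sprintf("  dynamics: %s; half-life: %s\n", x$dynamics,
              if (is.na(x$half_life)) "undefined (expanding)"
              else if (is.infinite(x$half_life)) "infinite (flat)"
              else sprintf("%.4f (%.2f%% divergence)", x$half_life,
                           x$half_life_percent)))
  invisible(x)
}

#' Interpret the dynamics of a half-life fit
#'
#' Maps the fitted slope sign to its evolutionary reading: decay reflects
#' neutral turnover (insertions accumulate mutations and are gradually
#' lost), a positive slope signals a recent population expansion or
#' possible directional selection (copies proliferated after diverging),
#' and a flat profile is a steady state.
#'
#' @param fit A [fit_halflife()] result.
#' @return Character label.
#' @export
classify_dynamics <- function(fit) {
  stopifnot(inherits(fit, "halflife_fit"))
  switch(fit$dynamics,
         decay = "neutral turnover",
         expansion = "recent population expansion / possible directional selection",
         flat = "steady state")
}

#' Compare half-life distributions between genomes
#'
#' Per-genome median and standard deviation of finite half-lives, all
#' pairwise two-sided Mann-Whitney (Wilcoxon rank-sum) tests -- exact for
#' group sizes up to 20 without ties, normal approximation with tie
#' correction otherwise -- plus one-way ANOVA and Kruskal-Wallis omnibus
#' tests on the same values.  No multiplicity correction by default.
#'
#' @param half_lives_by_genome Named list of numeric half-life vectors.
#' @param p_adjust Method passed to [stats::p.adjust()] ("none" default).
#' @return Object of class `group_comparison`: list with `summary`
#'   (data.frame genome, n, median, sd), `pairwise` (data.frame genome1,
#'   genome2, statistic, p_value, p_adjusted), `anova` (F, p) and
#'   `kruskal` (statistic, p).
#' @export
group_compare <- function(half_lives_by_genome, p_adjust = "none") {
  vals <- lapply(half_lives_by_genome, function(x) x[is.finite(x)])
  small <- vapply(vals, length, integer(1L)) < 2L
  if (any(small)) {
    warning("excluding group(s) with < 2 finite half-lives: ",
            paste(names(vals)[small], collapse = ", "))
    vals <- vals[!small]
  }
  if (length(vals) < 2L) stop("need at least 2 usable genomes to compare")
  summ <- data.frame(genome = names(vals),
                     n = vapply(vals, length, integer(1L)),
                     median = vapply(vals, median, numeric(1L)),
                     sd = vapply(vals, sd, numeric(1L)),
                     stringsAsFactors = FALSE)
  prs <- combn(names(vals), 2L)
  pw <- do.call(rbind, lapply(seq_len(ncol(prs)), function(k) {
    g1 <- prs[1L, k]; g2 <- prs[2L, k]
    x <- vals[[g1]]; y <- vals[[g2]]
    exact <- length(x) <= 20L && length(y) <= 20L && !anyDuplicated(c(x, y))
    wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact))
    data.frame(genome1 = g1, genome2 = g2, statistic = unname(wt$statistic),
               p_value = wt$p.value, exact = exact, stringsAsFactors = FALSE)
  }))
  pw$p_adjusted <- stats::p.adjust(pw$p_value, method = p_adjust)
  all_v <- unlist(vals, use.names = FALSE)
  grp <- factor(rep(names(vals), lengths(vals)))
  an <- anova(lm(all_v ~ grp))
  kw <- kruskal.test(all_v, grp)
  structure(list(summary = summ, pairwise = pw,
                 anova = list(F = an$`F value`[1L], p = an$`Pr(>F)`[1L]),
                 kruskal = list(statistic = unname(kw$statistic),
                                p = kw$p.value)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Half-life comparison across genomes\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("ANOVA F = %.3f, p = %.4g; Kruskal-Wallis chi^2 = %.3f, p = %.4g\n",
              x$anova$F, x$anova$p, x$kruskal$statistic, x$kruskal$p))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Jukes-Cantor distance correction
#'
#' Converts an observed mismatch proportion into the expected number of
#' substitution events per site under the Jukes-Cantor model,
#' `-3/4 * log(1 - 4 d / 3)`, undoing multiple-hit saturation.
#'
#' @param d Observed proportion(s) of differing sites (< 0.75).
#' @return Corrected divergence(s).
#' @export
jc_correct <- function(d) {
  stopifnot(all(d < 0.75))
  -0.75 * log(1 - 4 * d / 3)
}

#' Estimate a single family's half-life from reads and its consensus
#'
#' The within-family analogue of the per-contig half-life regression:
#' aligns the reads to the family consensus, takes each read's
#' (Jukes-Cantor corrected) divergence as the age proxy of the copy it
#' came from, bins reads by divergence, converts per-bin aligned bases to
#' copy number, and fits [fit_halflife()] on the binned profile.  Bins are
#' truncated at `max_divergence` (complete bins only), well below the
#' aligner identity cutoff so late bins are not depleted.
#'
#' @param reads Read set.
#' @param contig Consensus sequence of the family (length-1 named
#'   character).
#' @param single_copy_depth Depth of a single-copy region (sampling
#'   coverage).
#' @param min_identity Alignment identity cutoff (loose by default so that
#'   old, diverged copies still align).
#' @param min_aln_len Reads aligned over fewer bases are dropped (their
#'   divergence estimate is too noisy).
#' @param bin_width,max_divergence Binning of the divergence axis.
#' @param jukes_cantor Apply [jc_correct()] to per-read divergences.
#' @param seed_kmer Alignment seed k-mer.
#' @return A [fit_halflife()] result with the binned profile attached as
#'   attribute `profile`.
#' @export
estimate_family_halflife <- function(reads, contig, single_copy_depth = 1,
                                     min_identity = 0.80, min_aln_len = 100L,
                                     bin_width = 0.02, max_divergence = 0.14,
                                     jukes_cantor = TRUE, seed_kmer = 13L) {
  stopifnot(length(contig) == 1L)
  aln <- align_reads(reads, contig, min_identity = min_identity,
                     seed_kmer = seed_kmer)
  rdv <- read_divergences(aln)
  rdv <- rdv[rdv$aln_len >= min_aln_len, , drop = FALSE]
  d <- if (jukes_cantor) jc_correct(rdv$divergence) else rdv$divergence
  prof <- binned_copy_profile(
    d, weights = rdv$aln_len / (nchar(contig[[1L]]) * single_copy_depth),
    bin_width = bin_width, max_divergence = max_divergence)
  fit <- fit_halflife(prof, group_id = names(contig) %||% "family")
  attr(fit, "profile") <- prof
  fit
}
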