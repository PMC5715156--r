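# Genetic diversity statistics (Na, rarefied allelic richness, Ho, He, FIS)
# and temporal effective population size from heterozygosity decline.

#' Expected heterozygosity from allele counts
#'
#' The plain gene-diversity estimator `He = 1 - sum(p^2)` with sample allele
#' frequencies `p` (the GenAlEx default). The small-sample unbiased form
#' `N/(N-1) * He` (N = gene copies) is available via `unbiased = TRUE`.
#'
#' @param counts integer vector of allele copy counts at one locus.
#' @param unbiased apply the `N/(N-1)` correction.
#' @return Expected heterozygosity in `[0, 1)`; `NA` if no alleles scored.
#' @export
expected_het_counts <- function(counts, unbiased = FALSE) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (N == 0) return(NA_real_)
  he <- 1 - sum((counts / N)^2)
  if (unbiased && N > 1) he <- he * N / (N - 1)
  he
}

#' Per-locus and mean expected heterozygosity of a genotype table
#'
#' @param gt a [genotype_table()].
#' @param unbiased see [expected_het_counts()].
#' @return List with `per_locus` (named vector; `NA` for loci with no data,
#'   which are flagged and excluded from the mean) and `mean`.
#' @export
expected_heterozygosity <- function(gt, unbiased = FALSE) {
  per <- vapply(allele_counts(gt), expected_het_counts,
                numeric(1), unbiased = unbiased)
  list(per_locus = per, mean = mean(per, na.rm = TRUE))
}

#' Observed heterozygosity
#'
#' Fraction of non-missing genotypes that are heterozygous, per locus,
#' averaged over loci with data.
#'
#' @param gt a [genotype_table()].
#' @return List with `per_locus` and `mean`.
#' @export
observed_heterozygosity <- function(gt) {
  per <- vapply(seq_along(gt$loci), function(l) {
    ok <- !is.na(gt$a1[, l])
    if (!any(ok)) return(NA_real_)
    mean(gt$a1[ok, l] != gt$a2[ok, l])
  }, numeric(1))
  names(per) <- gt$loci
  list(per_locus = per, mean = mean(per, na.rm = TRUE))
}

#' Rarefied allelic richness at one locus
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies drawn without replacement from the `N` sampled copies:
#' `Ar = sum_a [1 - choose(N - N_a, g) / choose(N, g)]`.
#'
#' @param counts integer vector of allele copy counts.
#' @param g rarefaction size in gene copies, `1 <= g <= N`.
#' @return Rarefied allelic richness (>= 1 for any locus with data).
#' @export
allelic_richness_counts <- function(counts, g) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (g < 1) stop("rarefaction size g must be >= 1")
  if (N == 0) return(NA_real_)
  if (g > N) stop("rarefaction size g exceeds sampled gene copies (", N, ")")
  # exp(lchoose) handles choose(N - Na, g) = 0 when N - Na < g
  sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
}

#' Mean rarefied allelic richness of a genotype table
#'
#' @param gt a [genotype_table()].
#' @param g rarefaction size in gene copies; default: smallest per-locus gene
#'   count in the table (the FSTAT convention applies the smallest count
#'   across all compared samples — pass that `g` explicitly when comparing
#'   year samples).
#' @return List with `per_locus`, `mean` and the `g` used.
#' @export
allelic_richness <- function(gt, g = NULL) {
  cnts <- allele_counts(gt)
  Ns <- vapply(cnts, sum, numeric(1))
  if (is.null(g)) g <- min(Ns[Ns > 0])
  per <- vapply(cnts, function(cc) {
    if (sum(cc) == 0) return(NA_real_)
    allelic_richness_counts(cc, g)
  }, numeric(1))
  list(per_locus = per, mean = mean(per, na.rm = TRUE), g = g)
}

#' Inbreeding coefficient FIS
#'
#' Primary output is the Weir & Cockerham single-sample estimator `f`
#' (variance-components form, summed over alleles and loci); the simple
#' multilocus `1 - mean(Ho)/mean(He)` is reported alongside. Undefined when
#' every locus is monomorphic (returned as `NaN`, not 0).
#'
#' @param gt a [genotype_table()] with at least 2 individuals.
#' @return List with `fis` (Weir-Cockerham f), `fis_simple`, and per-locus
#'   components.
#' @export
inbreeding_coefficient <- function(gt) {
  if (length(gt$ids) < 2L) stop("FIS needs at least 2 individuals")
  num <- 0; den <- 0
  per_locus <- rep(NA_real_, length(gt$loci))
  for (l in seq_along(gt$loci)) {
    ok <- !is.na(gt$a1[, l])
    n <- sum(ok)
    if (n < 2L) next
    g1 <- gt$a1[ok, l]; g2 <- gt$a2[ok, l]
    alleles <- unique(c(g1, g2))
    if (length(alleles) < 2L) next
    lb <- 0; lc <- 0
    for (a in alleles) {
      p <- (sum(g1 == a) + sum(g2 == a)) / (2 * n)
      h <- mean((g1 == a) != (g2 == a))  # heterozygotes carrying one copy of a
      b <- n / (n - 1) * (p * (1 - p) - (2 * n - 1) / (4 * n) * h)
      lb <- lb + b
      lc <- lc + h / 2
    }
    num <- num + lc; den <- den + lb + lc
    if (lb + lc != 0) per_locus[l] <- 1 - lc / (lb + lc)
  }
  names(per_locus) <- gt$loci
  ho <- observed_heterozygosity(gt)$mean
  he <- expected_heterozygosity(gt)$mean
  list(fis = if (den == 0) NaN else 1 - num / den,
       fis_simple = if (he == 0) NaN else 1 - ho / he,
       per_locus = per_locus)
}

#' Per-year diversity report
#'
#' Mirrors the standard temporal diversity table: for each (population, year)
#' group, sample size `n`, mean alleles per locus `Na`, mean rarefied allelic
#' richness `Ar` at a common rarefaction size, mean observed and expected
#' heterozygosity and FIS. Loci with no data in a group are excluded from
#' that group's means and flagged in the per-locus detail.
#'
#' @param gt a [genotype_table()] with `pop` and `year` metadata.
#' @param g rarefaction size in gene copies; default: the smallest per-locus
#'   gene count across all groups, the FSTAT convention.
#' @return Data frame with columns `pop`, `year`, `n`, `Na`, `Ar`, `Ho`,
#'   `He`, `Fis`; per-locus detail in attribute `"per_locus"`.
#' @export
diversity_report <- function(gt, g = NULL) {
  yr <- ifelse(is.na(gt$meta$year), "NA", gt$meta$year)
  key <- interaction(gt$meta$pop, yr, drop = TRUE)
  groups <- levels(key)
  subs <- lapply(groups, function(k) gt_subset(gt, which(key == k)))
  if (is.null(g)) {
    g <- min(unlist(lapply(subs, function(s) {
      Ns <- vapply(allele_counts(s), sum, numeric(1))
      Ns[Ns > 0]
    })))
  }
  per_locus <- list()
  rows <- lapply(seq_along(groups), function(i) {
    s <- subs[[i]]
    cnts <- allele_counts(s)
    na_per <- vapply(cnts, function(cc) {
      if (sum(cc) == 0) NA_real_ else sum(cc > 0)
    }, numeric(1))
    ar <- allelic_richness(s, g = min(g, min(vapply(cnts, sum, numeric(1))
                                             [vapply(cnts, sum, numeric(1)) > 0])))
    he <- expected_heterozygosity(s)
    ho <- observed_heterozygosity(s)
    fis <- inbreeding_coefficient(s)
    per_locus[[groups[i]]] <<- data.frame(
      locus = s$loci, Na = na_per, Ar = ar$per_locus,
      Ho = ho$per_locus, He = he$per_locus, row.names = NULL)
    data.frame(pop = s$meta$pop[1L], year = s$meta$year[1L],
               n = length(s$ids),
               Na = mean(na_per, na.rm = TRUE), Ar = ar$mean,
               Ho = ho$mean, He = he$mean, Fis = fis$fis,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$pop, out$year), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "per_locus") <- per_locus
  attr(out, "g") <- g
  out
}

#' Temporal effective population size from heterozygosity decline
#'
#' Inverts the drift expectation `H_t = H_0 (1 - 1/(2 Ne))^t` with
#' `t = years / gen_time` generations:
#' `Ne = 1 / (2 * (1 - (H_t/H_0)^(1/t)))`.
#' When `H_t >= H_0` there is no drift signal and `Ne` is reported as `+Inf`
#' with a warning.
#'
#' @param H0,Ht expected heterozygosity at the start and end of the interval.
#' @param years elapsed calendar years (> 0).
#' @param gen_time generation time in years (> 0); default 1.54, the value
#'   appropriate to a short-lived marsupial with mostly annual male turnover.
#' @return Object of class `ne_estimate`: `point`, `ci_low`, `ci_high`
#'   (`NA` unless estimated from tables, see [ne_from_tables()]), `H0`, `Ht`,
#'   `years`, `gen_time`, `t`.
#' @export
ne_from_het_decline <- function(H0, Ht, years, gen_time = 1.54) {
  if (H0 <= 0) stop("H0 must be positive")
  if (years <= 0 || gen_time <= 0) stop("years and gen_time must be positive")
  if (Ht < 0) stop("Ht must be non-negative")
  t <- years / gen_time
  if (Ht >= H0) {
    warning("Ht >= H0: no heterozygosity decline, Ne reported as +Inf")
    point <- Inf
  } else {
    point <- 1 / (2 * (1 - (Ht / H0)^(1 / t)))
  }
  structure(list(point = point, ci_low = NA_real_, ci_high = NA_real_,
                 H0 = H0, Ht = Ht, years = years, gen_time = gen_time, t = t),
            class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat(sprintf("Ne = %.2f (t = %.2f generations, H0 = %.3f -> Ht = %.3f)\n",
              x$point, x$t, x$H0, x$Ht))
  if (!is.na(x$ci_low)) {
    cat(sprintf("  95%% locus-bootstrap CI: %.2f - %.2f (B = %d)\n",
                x$ci_low, x$ci_high, x$B))
  }
  invisible(x)
}

#' Ne from two genotype tables with a locus bootstrap CI
#'
#' Computes mean expected heterozygosity over the shared loci at the two time
#' points, the point estimate via [ne_from_het_decline()], and a percentile
#' confidence interval by resampling loci with replacement and recomputing
#' `H0`, `Ht` and `Ne` on each replicate.
#'
#' @param gt0,gt1 genotype tables at the start and end of the interval
#'   (shared loci are used).
#' @param years elapsed calendar years.
#' @param gen_time generation time in years.
#' @param B bootstrap replicates.
#' @param level confidence level.
#' @param seed RNG seed.
#' @return An `ne_estimate` with `ci_low`/`ci_high` filled in (replicates
#'   with no decline enter as `+Inf`, so upper bounds may be infinite).
#' @export
ne_from_tables <- function(gt0, gt1, years, gen_time = 1.54, B = 1000L,
                           level = 0.95, seed = 1L) {
  shared <- intersect(gt0$loci, gt1$loci)
  if (!length(shared)) stop("no shared loci between the two tables")
  h0 <- expected_heterozygosity(gt0)$per_locus[shared]
  h1 <- expected_heterozygosity(gt1)$per_locus[shared]
  ok <- !is.na(h0) & !is.na(h1)
  h0 <- h0[ok]; h1 <- h1[ok]
  if (!length(h0)) stop("no shared loci with data at both time points")
  est <- ne_from_het_decline(mean(h0), mean(h1), years, gen_time)
  t <- est$t
  ne_of <- function(H0, Ht) {
    if (H0 <= 0 || Ht >= H0) Inf else 1 / (2 * (1 - (Ht / H0)^(1 / t)))
  }
  reps <- with_seed(seed, vapply(seq_len(B), function(b) {
    i <- sample.int(length(h0), replace = TRUE)
    ne_of(mean(h0[i]), mean(h1[i]))
  }, numeric(1)))
  a <- (1 - level) / 2
  ci <- percentile_nearest_rank(reps, c(a, 1 - a))
  est$ci_low <- ci[1L]; est$ci_high <- ci[2L]; est$B <- as.integer(B)
  est
}
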