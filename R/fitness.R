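# Hybrid relative fitness per annual cohort: expected counts under the
# sire-pool and random-mating models, bootstrap confidence intervals, and
# exact significance tests.

#' Expected F1 counts under the sire-pool model
#'
#' Apportions the new adults of the first post-translocation cohort by sire
#' origin: with `m_i` introduced and `m_r` resident males in the breeding
#' pool, each new adult is an F1 with probability `m_i / (m_i + m_r)` under
#' equal sire fitness.
#'
#' @param n_new_adults new first-year adults in the cohort.
#' @param n_introduced_males introduced males that survived to breed.
#' @param n_resident_males resident males in the breeding pool.
#' @return Numeric `c(exp_hybrid =, exp_nonhybrid =)` summing to
#'   `n_new_adults`.
#' @export
expected_f1_counts <- function(n_new_adults, n_introduced_males,
                               n_resident_males) {
  stopifnot(n_new_adults >= 0, n_introduced_males >= 0, n_resident_males >= 0)
  tot <- n_introduced_males + n_resident_males
  if (tot == 0) stop("sire pool is empty")
  eh <- n_new_adults * n_introduced_males / tot
  c(exp_hybrid = eh, exp_nonhybrid = n_new_adults - eh)
}

#' Expected hybrid counts in the following cohort under random mating
#'
#' An offspring carries introduced alleles unless *both* parents are
#' non-hybrid. With parents drawn at random from the previous year's adult
#' pool (hybrids and non-hybrids pooled across sexes by default), the
#' non-hybrid parental frequency is `q = n_nonhybrid / (n_hybrid +
#' n_nonhybrid)` and the expected hybrid count is `n_new * (1 - q^2)`.
#' Sex-specific frequencies can be supplied instead via `q_female` /
#' `q_male`, giving `n_new * (1 - q_f * q_m)`.
#'
#' @param n_new_adults new adults in the cohort.
#' @param n_hybrid_prev,n_nonhybrid_prev hybrid / non-hybrid adults in the
#'   previous year's pool.
#' @param q_female,q_male optional sex-specific non-hybrid frequencies
#'   (both must be given to take effect).
#' @return Numeric `c(exp_hybrid =, exp_nonhybrid =)`.
#' @export
expected_next_cohort_hybrids <- function(n_new_adults, n_hybrid_prev,
                                         n_nonhybrid_prev,
                                         q_female = NULL, q_male = NULL) {
  if (is.null(q_female) != is.null(q_male)) {
    stop("supply both q_female and q_male, or neither")
  }
  if (is.null(q_female)) {
    tot <- n_hybrid_prev + n_nonhybrid_prev
    if (tot <= 0) stop("previous adult pool is empty")
    q2 <- (n_nonhybrid_prev / tot)^2
  } else {
    stopifnot(q_female >= 0, q_female <= 1, q_male >= 0, q_male <= 1)
    q2 <- q_female * q_male
  }
  eh <- n_new_adults * (1 - q2)
  c(exp_hybrid = eh, exp_nonhybrid = n_new_adults - eh)
}

#' Hybrid relative fitness
#'
#' The double ratio `w = (obs_h / exp_h) / (obs_n / exp_n)`: the observed-
#' to-expected representation of hybrids relative to that of non-hybrids.
#' Scale-invariant in all four arguments.
#'
#' @param obs_h,obs_n observed hybrid / non-hybrid counts.
#' @param exp_h,exp_n expected counts (both > 0).
#' @return The fitness ratio; `+Inf` (with a warning) when `obs_n = 0`.
#' @export
relative_fitness <- function(obs_h, obs_n, exp_h, exp_n) {
  stopifnot(obs_h >= 0, obs_n >= 0, exp_h > 0, exp_n > 0)
  if (obs_n == 0) {
    warning("no non-hybrids observed: relative fitness is infinite")
    return(Inf)
  }
  (obs_h / exp_h) / (obs_n / exp_n)
}

#' Bootstrap percentile CI for relative fitness
#'
#' Resamples the `n = obs_h + obs_n` observed ancestry labels with
#' replacement (equivalently, draws the hybrid count from
#' `Binomial(n, obs_h/n)`), recomputes the fitness ratio against the *fixed*
#' expectations, and returns equal-tailed percentile bounds of the `B`
#' replicate values. Because the resampled ratio takes at most `n + 1`
#' distinct values, bounds are chosen by *closest achieved tail mass*: each
#' bound is the replicate value whose strictly-outside tail probability is
#' nearest `(1 - level)/2`, the equal-tailed interval with coverage closest
#' to nominal on a discrete distribution (a nearest-rank cut systematically
#' overshoots the tail here). Replicates with zero non-hybrids contribute
#' `w = +Inf` and sort above all finite values, so upper bounds remain
#' well defined.
#'
#' @param obs_h,obs_n observed counts (`obs_h + obs_n >= 2`).
#' @param exp_h,exp_n fixed expected counts.
#' @param B bootstrap replicates (warning below 100).
#' @param seed RNG seed.
#' @param level confidence level.
#' @return List `ci_low`, `ci_high`, `B`, `seed`, `degenerate` (TRUE when
#'   the observed sample is all one class, making the CI a point mass).
#' @export
bootstrap_rf_ci <- function(obs_h, obs_n, exp_h, exp_n, B = 1000L, seed = 1L,
                            level = 0.95) {
  n <- obs_h + obs_n
  stopifnot(n >= 2, exp_h > 0, exp_n > 0)
  if (B < 100L) warning("B < 100 gives unstable percentile bounds")
  h <- with_seed(seed, stats::rbinom(B, n, obs_h / n))
  w <- ifelse(h == n, Inf, (h / exp_h) / ((n - h) / exp_n))
  ci <- tail_match_bounds(w, level = level)
  list(ci_low = ci[1L], ci_high = ci[2L], B = as.integer(B),
       seed = as.integer(seed),
       degenerate = obs_h == 0L || obs_n == 0L)
}

#' Exact resampling distribution of the fitness ratio
#'
#' The no-sampling oracle behind [bootstrap_rf_ci()]: enumerates all `n + 1`
#' possible resampled hybrid counts, their exact `Binomial(n, obs_h/n)`
#' probabilities, and the corresponding fitness ratios.
#'
#' @inheritParams bootstrap_rf_ci
#' @return Data frame `h`, `prob`, `w`, sorted by `h`.
#' @export
rf_resampling_distribution <- function(obs_h, obs_n, exp_h, exp_n) {
  n <- obs_h + obs_n
  h <- 0:n
  w <- ifelse(h == n, Inf, (h / exp_h) / ((n - h) / exp_n))
  data.frame(h = h, prob = stats::dbinom(h, n, obs_h / n), w = w)
}

#' Chi-squared goodness of fit for a two-class cohort
#'
#' `X^2 = sum (obs - exp)^2 / exp` on the hybrid / non-hybrid split, df = 1,
#' upper-tail p-value.
#'
#' @param obs length-2 observed counts.
#' @param exp length-2 expected counts (> 0).
#' @return List `statistic`, `p`.
#' @export
chi2_gof <- function(obs, exp) {
  stopifnot(length(obs) == 2L, length(exp) == 2L, all(exp > 0))
  x2 <- sum((obs - exp)^2 / exp)
  list(statistic = x2, p = stats::pchisq(x2, df = 1, lower.tail = FALSE))
}

#' One-tailed Fisher's exact test for a 2x2 table
#'
#' Hypergeometric tail probability with all margins fixed: the sum of
#' probabilities of tables at least as extreme as observed in the stated
#' direction for the top-left cell `a` (`"greater"`: enrichment of `a`,
#' `"less"`: depletion). Implemented by direct enumeration of the
#' hypergeometric support.
#'
#' @param a,b,c,d cell counts (rows = group, columns = outcome).
#' @param direction `"greater"` or `"less"` for cell `a`.
#' @return The exact one-tailed p-value.
#' @export
fisher_exact_one_tailed <- function(a, b, c, d,
                                    direction = c("greater", "less")) {
  direction <- match.arg(direction)
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0, a + b + c + d > 0)
  r1 <- a + b; col1 <- a + c; n <- a + b + c + d
  lo <- max(0L, r1 - (n - col1)); hi <- min(r1, col1)
  support <- lo:hi
  probs <- stats::dhyper(support, col1, n - col1, r1)
  keep <- if (direction == "greater") support >= a else support <= a
  sum(probs[keep])
}

#' Exact upper-tail binomial test for a hybrid count
#'
#' `P(X >= obs_h)` for `X ~ Binomial(n, p0)`: the exact one-sample test of
#' whether the observed hybrid count exceeds the neutral cohort expectation
#' `p0` (e.g. the sire-pool proportion).
#'
#' @param obs_h observed hybrid count, `0 <= obs_h <= n`.
#' @param n cohort size.
#' @param p0 null per-individual hybrid probability, in (0, 1).
#' @return The exact p-value.
#' @export
binomial_exact_upper <- function(obs_h, n, p0) {
  stopifnot(obs_h >= 0, obs_h <= n, p0 > 0, p0 < 1)
  stats::pbinom(obs_h - 1, n, p0, lower.tail = FALSE)
}

#' Assemble a cohort fitness row
#'
#' Bundles observed and expected counts, relative fitness, bootstrap CI and
#' both significance tests (chi-squared goodness of fit as the primary,
#' matching how the printed cohort significance values arise; the exact
#' binomial upper-tail test alongside) into one record.
#'
#' @param year cohort year label.
#' @param obs_h,obs_n observed hybrid / non-hybrid new adults.
#' @param exp_h,exp_n expected counts.
#' @param B bootstrap replicates.
#' @param seed bootstrap seed.
#' @return Object of class `cohort_fitness` (a one-row data frame with
#'   columns `year`, `obs_hybrid`, `obs_nonhybrid`, `exp_hybrid`,
#'   `exp_nonhybrid`, `relative_fitness`, `ci_low`, `ci_high`, `p_chi2`,
#'   `p_exact`, `B`, `seed`).
#' @export
cohort_fitness <- function(year, obs_h, obs_n, exp_h, exp_n,
                           B = 1000L, seed = 1L) {
  w <- relative_fitness(obs_h, obs_n, exp_h, exp_n)
  ci <- bootstrap_rf_ci(obs_h, obs_n, exp_h, exp_n, B = B, seed = seed)
  gof <- chi2_gof(c(obs_h, obs_n), c(exp_h, exp_n))
  pe <- binomial_exact_upper(obs_h, obs_h + obs_n, exp_h / (exp_h + exp_n))
  out <- data.frame(year = year, obs_hybrid = obs_h, obs_nonhybrid = obs_n,
                    exp_hybrid = exp_h, exp_nonhybrid = exp_n,
                    relative_fitness = w, ci_low = ci$ci_low,
                    ci_high = ci$ci_high, p_chi2 = gof$p, p_exact = pe,
                    B = ci$B, seed = ci$seed, stringsAsFactors = FALSE)
  class(out) <- c("cohort_fitness", "data.frame")
  out
}

#' Longevity and census-survival summary by ancestry class
#'
#' Longevity counts calendar years inclusively: an animal seen only in its
#' first adult year has longevity 1. Returns per-class mean longevity and
#' the 2x2 alive-at-census table (class x alive) with its one-tailed
#' Fisher p-value (direction: hybrids enriched among survivors).
#'
#' @param records individual records (see [read_individuals_csv()]).
#' @param calls ancestry calls from [classify_ancestry()] (joined on `id`).
#' @param census_year census year for the survival table.
#' @param hybrid_classes classes counted as hybrid.
#' @return List `longevity` (data frame class / n / mean_longevity),
#'   `survival_table` (2x2 matrix), `p_survival`.
#' @export
longevity_summary <- function(records, calls, census_year,
                              hybrid_classes = c("F1", "F2", "backcross")) {
  df <- merge(records, calls[c("id", "class")], by = "id")
  if (!nrow(df)) stop("no overlap between records and ancestry calls")
  if (census_year < min(df$year_first_adult)) {
    stop("census_year precedes the first cohort")
  }
  df$longevity <- df$last_seen_year - df$year_first_adult + 1L
  df$group <- ifelse(df$class %in% hybrid_classes, "hybrid", "nonhybrid")
  lng <- aggregate(longevity ~ group, df, mean)
  names(lng) <- c("class", "mean_longevity")
  lng$n <- as.integer(table(df$group)[lng$class])
  df$alive <- df$last_seen_year >= census_year
  tab <- matrix(c(sum(df$group == "hybrid" & df$alive),
                  sum(df$group == "hybrid" & !df$alive),
                  sum(df$group == "nonhybrid" & df$alive),
                  sum(df$group == "nonhybrid" & !df$alive)),
                2, 2, byrow = TRUE,
                dimnames = list(c("hybrid", "nonhybrid"),
                                c("alive", "dead")))
  p <- fisher_exact_one_tailed(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2],
                               direction = "greater")
  list(longevity = lng[c("class", "n", "mean_longevity")],
       survival_table = tab, p_survival = p)
}
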