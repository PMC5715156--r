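# Forward-time Mendelian simulator: two diverged populations, a male-only
# translocation, offspring cohorts with a configurable hybrid fitness
# advantage, and imperfect annual trapping.

#' Simulation configuration
#'
#' Defaults emulate the monitored system: a 24-locus microsatellite panel, a
#' low-diversity recipient population (He target 0.14) and a high-diversity
#' source (He target 0.55), 8 loci with source-private diagnostic alleles,
#' 21 resident sires against 5 surviving translocated males, and a composite
#' hybrid fitness advantage of 2.6 applied as a sire-sampling weight (mating
#' success and juvenile survival are not separable in cohort counts, so the
#' simulator collapses them into one weight by design).
#'
#' @param n_loci number of microsatellite loci.
#' @param recipient_He_target,source_He_target mean expected heterozygosity
#'   each pool is tuned to (0 = monomorphic).
#' @param n_diagnostic_loci loci whose source alleles are private (absent
#'   from the recipient); must be `<= n_loci`.
#' @param n_alleles_recipient,n_alleles_source alleles segregating per locus
#'   in each pool; with `k` alleles the reachable mean He is below `1 - 1/k`.
#' @param n_resident_males,n_resident_females resident breeding adults.
#' @param n_translocated_males introduced sires surviving to the breeding
#'   season.
#' @param hybrid_fitness_w sire-sampling weight (>= 0) for sires carrying
#'   introduced ancestry, relative to resident sires.
#' @param offspring_per_female litter size per dam per season (capped at 4,
#'   the full pouch-young complement).
#' @param juvenile_survival probability a pouch young is recruited as a
#'   first-year adult the following spring.
#' @param survival_f,survival_m annual adult survival by sex (females
#'   markedly longer-lived than males in this system).
#' @param capture_p per-secondary-occasion detection probability.
#' @param n_secondary secondary trapping occasions per annual session.
#' @param seed master seed; every stochastic stage derives its own sub-seed
#'   from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_loci = 24L,
                       recipient_He_target = 0.14,
                       source_He_target = 0.55,
                       n_diagnostic_loci = 8L,
                       n_alleles_recipient = 2L,
                       n_alleles_source = 6L,
                       n_resident_males = 21L,
                       n_resident_females = 20L,
                       n_translocated_males = 5L,
                       hybrid_fitness_w = 2.6,
                       offspring_per_female = 4L,
                       juvenile_survival = 0.4,
                       survival_f = 0.6,
                       survival_m = 0.1,
                       capture_p = 0.3,
                       n_secondary = 6L,
                       seed = 1L) {
  cfg <- list(
    n_loci = as.integer(n_loci),
    recipient_He_target = recipient_He_target,
    source_He_target = source_He_target,
    n_diagnostic_loci = as.integer(n_diagnostic_loci),
    n_alleles_recipient = as.integer(n_alleles_recipient),
    n_alleles_source = as.integer(n_alleles_source),
    n_resident_males = as.integer(n_resident_males),
    n_resident_females = as.integer(n_resident_females),
    n_translocated_males = as.integer(n_translocated_males),
    hybrid_fitness_w = hybrid_fitness_w,
    offspring_per_female = as.integer(offspring_per_female),
    juvenile_survival = juvenile_survival,
    survival_f = survival_f,
    survival_m = survival_m,
    capture_p = capture_p,
    n_secondary = as.integer(n_secondary),
    seed = as.integer(seed)
  )
  probs <- c("juvenile_survival", "survival_f", "survival_m", "capture_p")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]")
  }
  for (t in c("recipient_He_target", "source_He_target")) {
    if (cfg[[t]] < 0 || cfg[[t]] >= 1) stop(t, " must be in [0, 1)")
  }
  if (cfg$hybrid_fitness_w < 0) stop("hybrid_fitness_w must be >= 0")
  if (cfg$n_diagnostic_loci > cfg$n_loci) {
    stop("n_diagnostic_loci cannot exceed n_loci")
  }
  if (cfg$offspring_per_female < 0L || cfg$offspring_per_female > 4L) {
    stop("offspring_per_female must be in 0..4 (full pouch complement is 4)")
  }
  if (cfg$n_loci < 1L) stop("need at least one locus")
  # He target must be reachable with the allele count cap: max E[He] = 1 - 1/k.
  dirichlet_alpha(cfg$recipient_He_target, cfg$n_alleles_recipient,
                  "recipient_He_target")
  dirichlet_alpha(cfg$source_He_target, cfg$n_alleles_source,
                  "source_He_target")
  structure(cfg, class = "sim_config")
}

# Symmetric Dirichlet concentration giving E[1 - sum p^2] = target with k
# alleles: alpha = target / ((1 - target) * k - 1). Errors when the target
# is not reachable for that allele count.
dirichlet_alpha <- function(target, k, what = "He target") {
  if (target == 0) return(0)
  denom <- (1 - target) * k - 1
  if (denom <= 0) {
    stop(sprintf("%s = %.3f is unreachable with %d alleles per locus (max %.3f)",
                 what, target, k, 1 - 1 / k), call. = FALSE)
  }
  target / denom
}

r_dirichlet_sym <- function(k, alpha) {
  g <- stats::rgamma(k, shape = alpha)
  if (all(g == 0)) g[sample.int(k, 1L)] <- 1
  g / sum(g)
}

# Allele-frequency spectra for both pools. Non-diagnostic loci share one
# allele ladder (recipient alleles are a subset of the source's); diagnostic
# loci give the source a fully non-overlapping ladder, emulating markers with
# fixed differences between the regions.
pool_frequencies <- function(cfg, seed) {
  with_seed(seed, {
    a_rec <- dirichlet_alpha(cfg$recipient_He_target, cfg$n_alleles_recipient)
    a_src <- dirichlet_alpha(cfg$source_He_target, cfg$n_alleles_source)
    diag_loci <- seq_len(cfg$n_diagnostic_loci)
    lapply(seq_len(cfg$n_loci), function(l) {
      rec_alleles <- 100L + 2L * seq_len(cfg$n_alleles_recipient) # 102, 104, ...
      src_alleles <- if (l %in% diag_loci) {
        150L + 2L * seq_len(cfg$n_alleles_source)                 # private range
      } else {
        100L + 2L * seq_len(cfg$n_alleles_source)                 # superset range
      }
      p_rec <- if (cfg$recipient_He_target == 0) {
        c(1, rep(0, cfg$n_alleles_recipient - 1L))
      } else {
        r_dirichlet_sym(cfg$n_alleles_recipient, a_rec)
      }
      p_src <- if (cfg$source_He_target == 0) {
        c(1, rep(0, cfg$n_alleles_source - 1L))
      } else {
        r_dirichlet_sym(cfg$n_alleles_source, a_src)
      }
      list(recipient = stats::setNames(p_rec, rec_alleles),
           source = stats::setNames(p_src, src_alleles),
           diagnostic = l %in% diag_loci)
    })
  })
}

sample_pool <- function(freqs, which_pool, n, ids, pop, seed) {
  n_loci <- length(freqs)
  a1 <- matrix(NA_integer_, n, n_loci)
  a2 <- matrix(NA_integer_, n, n_loci)
  with_seed(seed, {
    for (l in seq_len(n_loci)) {
      p <- freqs[[l]][[which_pool]]
      alle <- as.integer(names(p))
      a1[, l] <- sample(alle, n, replace = TRUE, prob = p)
      a2[, l] <- sample(alle, n, replace = TRUE, prob = p)
    }
  })
  genotype_table(ids, paste0("L", seq_len(n_loci)), a1, a2, pop = pop)
}

#' Simulate the recipient and source populations
#'
#' Draws per-locus allele frequencies from symmetric Dirichlet distributions
#' whose concentration is tuned so the mean expected heterozygosity matches
#' each pool's target, then samples Hardy-Weinberg genotypes. Diagnostic loci
#' carry source alleles at frequency zero in the recipient pool by
#' construction.
#'
#' @param config a [sim_config()].
#' @param seed seed (default: derived from `config$seed`).
#' @param n_recipient,n_source individuals sampled per pool.
#' @return A [genotype_table()] with populations `"recipient"` and
#'   `"source"`; the drawn frequency spectra are attached as attribute
#'   `"freqs"` for downstream breeding.
#' @export
simulate_source_pools <- function(config, seed = NULL,
                                  n_recipient = NULL, n_source = 100L) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% sub_seed(config$seed, 1L)
  n_recipient <- n_recipient %||%
    (config$n_resident_males + config$n_resident_females)
  freqs <- pool_frequencies(config, sub_seed(seed, 1L))
  rec <- sample_pool(freqs, "recipient", n_recipient,
                     sprintf("R%03d", seq_len(n_recipient)), "recipient",
                     sub_seed(seed, 2L))
  src <- sample_pool(freqs, "source", n_source,
                     sprintf("S%03d", seq_len(n_source)), "source",
                     sub_seed(seed, 3L))
  out <- gt_bind(rec, src)
  attr(out, "freqs") <- freqs
  out
}

# Ancestry class of an offspring from its parents' classes. Hybrid classes
# are collapsed the way diagnostic alleles see them: introduced x resident
# is F1; any hybrid-or-introduced x resident is a backcross; two parents both
# carrying introduced ancestry give an F2-type offspring.
offspring_class <- function(c1, c2) {
  hyb <- c("introduced", "F1", "F2", "backcross")
  h1 <- c1 %in% hyb; h2 <- c2 %in% hyb
  if (!h1 && !h2) return("resident")
  if (xor(h1, h2)) {
    solo <- if (h1) c1 else c2
    return(if (solo == "introduced") "F1" else "backcross")
  }
  "F2"
}

#' Breed one offspring cohort
#'
#' Each offspring draws a dam uniformly from the female pool and a sire from
#' the male pool with sampling weight `config$hybrid_fitness_w` for sires
#' carrying introduced ancestry (resident sires have weight 1), then inherits
#' one random allele per parent per locus. Each dam produces
#' `config$offspring_per_female` young.
#'
#' @param parents list with elements `dams` and `sires` (two
#'   [genotype_table()]s on one locus panel) and `dam_class` / `sire_class`
#'   (character ancestry class per parent, from
#'   `c("resident","introduced","F1","F2","backcross")`).
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @param year cohort year label attached to the offspring table.
#' @param id_prefix prefix for generated offspring ids.
#' @return List with `genotypes` (a [genotype_table()]) and `truth` (a data
#'   frame `id`, `class`, `sire`, `dam`, `sex`).
#' @export
breed_cohort <- function(parents, config, seed = NULL, year = NA_integer_,
                         id_prefix = "O") {
  stopifnot(inherits(config, "sim_config"))
  dams <- parents$dams; sires <- parents$sires
  if (!length(dams$ids)) stop("no dams in parent pool")
  if (!length(sires$ids)) stop("no sires in parent pool")
  if (!identical(dams$loci, sires$loci)) stop("dam and sire locus panels differ")
  dam_class <- rep_len(parents$dam_class %||% "resident", length(dams$ids))
  sire_class <- rep_len(parents$sire_class %||% "resident", length(sires$ids))
  seed <- seed %||% sub_seed(config$seed, 2L)

  w <- ifelse(sire_class == "resident", 1, config$hybrid_fitness_w)
  if (all(w == 0)) stop("all sire weights are zero; no matings possible")
  n_off <- length(dams$ids) * config$offspring_per_female
  L <- length(dams$loci)
  with_seed(seed, {
    dam_i <- rep(seq_along(dams$ids), each = config$offspring_per_female)
    sire_i <- sample(seq_along(sires$ids), n_off, replace = TRUE, prob = w)
    pick <- function(tab, idx) {
      # one random allele per parent per locus (Mendelian segregation)
      takes <- matrix(stats::runif(length(idx) * L) < 0.5, length(idx), L)
      ifelse(takes, tab$a1[idx, , drop = FALSE], tab$a2[idx, , drop = FALSE])
    }
    a1 <- pick(dams, dam_i)
    a2 <- pick(sires, sire_i)
    sex <- ifelse(stats::runif(n_off) < 0.5, "F", "M")
  })
  ids <- sprintf("%s%04d", id_prefix, seq_len(max(n_off, 1L))[seq_len(n_off)])
  cls <- vapply(seq_len(n_off), function(i) {
    offspring_class(dam_class[dam_i[i]], sire_class[sire_i[i]])
  }, character(1))
  gt <- genotype_table(ids, dams$loci, a1, a2, pop = "recipient",
                       year = year, sex = sex)
  truth <- data.frame(id = ids, class = cls,
                      sire = sires$ids[sire_i], dam = dams$ids[dam_i],
                      sex = sex, stringsAsFactors = FALSE)
  list(genotypes = gt, truth = truth)
}

#' Simulate annual trapping with imperfect detection
#'
#' Every alive individual is detected independently with probability
#' `config$capture_p` on each of `config$n_secondary` occasions; individuals
#' never detected that year are dropped from the output (they produce no
#' capture history) but remain in the caller's truth records.
#'
#' @param individuals data frame with columns `id` and `year` (one row per
#'   alive individual-year).
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return A `capture_histories` object (see [read_capture_csv()]).
#' @export
simulate_trapping <- function(individuals, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$capture_p <= 0) stop("capture_p must be positive to trap anything")
  seed <- seed %||% sub_seed(config$seed, 3L)
  k <- config$n_secondary
  n <- nrow(individuals)
  det <- with_seed(seed,
    matrix(stats::rbinom(n * k, 1L, config$capture_p), n, k))
  seen <- rowSums(det) > 0
  if (!any(seen)) stop("no individuals detected; raise capture_p or n_secondary")
  df <- data.frame(id = individuals$id[seen], year = individuals$year[seen],
                   stringsAsFactors = FALSE)
  det <- det[seen, , drop = FALSE]
  colnames(det) <- paste0("occ_", seq_len(k))
  validate_capture_histories(cbind(df, as.data.frame(det)))
}

#' Simulate the full study
#'
#' End-to-end generator: draws the two pools, translocates
#' `n_translocated_males` source males into the recipient population, breeds
#' two offspring cohorts (the second from the mixed pool of survivors and
#' recruited first-cohort adults), thins juveniles to first-year adults, and
#' runs annual trapping over the alive population. Years are labelled with
#' calendar analogues of the study: baseline `year0`, first hybrid cohort
#' `year0 + 2`, second cohort `year0 + 3`.
#'
#' @param config a [sim_config()].
#' @param year0 baseline calendar year label.
#' @return List with elements `pools` (baseline two-population table),
#'   `panel_baseline` (recipient-only pre-translocation table), `adults`
#'   (genotype table of all recipient-side adults across years, with
#'   year-first-adult labels), `truth` (per-individual class, parents,
#'   alive-by-year flags), `records` (individual life-history records),
#'   `histories` (capture histories), and `config`.
#' @export
simulate_study <- function(config, year0 = 2010L) {
  stopifnot(inherits(config, "sim_config"))
  pools <- simulate_source_pools(config)
  rec <- gt_subset(pools, which(pools$meta$pop == "recipient"))
  src <- gt_subset(pools, which(pools$meta$pop == "source"))

  nm <- config$n_resident_males; nf <- config$n_resident_females
  res_sex <- c(rep("M", nm), rep("F", nf))
  rec$meta$sex <- res_sex
  rec$meta$year <- year0
  res_m <- gt_subset(rec, which(res_sex == "M"))
  res_f <- gt_subset(rec, which(res_sex == "F"))

  # translocated males get recipient-side ids distinct from the source pool
  intro <- gt_subset(src, seq_len(config$n_translocated_males))
  intro <- genotype_table(sprintf("T%02d", seq_along(intro$ids)), intro$loci,
                          intro$a1, intro$a2, pop = "recipient",
                          year = year0 + 1L, sex = "M")

  y1 <- year0 + 2L; y2 <- year0 + 3L

  # Season 1: resident dams; sires = resident males + introduced males.
  sires1 <- gt_bind(res_m, intro)
  b1 <- breed_cohort(
    list(dams = res_f, sires = sires1,
         dam_class = "resident",
         sire_class = c(rep("resident", nm),
                        rep("introduced", config$n_translocated_males))),
    config, seed = sub_seed(config$seed, 11L), year = y1, id_prefix = "A")
  co1 <- recruit(b1, config, sub_seed(config$seed, 12L))

  # Season 2: survivors of the residents plus the recruited first cohort;
  # introduced males are gone (in the study all but one died after season 1,
  # and the survivor did not breed that season).
  surv_res <- survive(rec$ids, rec$meta$sex, config, sub_seed(config$seed, 13L))
  pool2_gt <- gt_bind(gt_subset(rec, surv_res), co1$genotypes)
  pool2_class <- c(rep("resident", sum(surv_res)), co1$truth$class)
  pool2_sex <- pool2_gt$meta$sex
  b2 <- breed_cohort(
    list(dams = gt_subset(pool2_gt, which(pool2_sex == "F")),
         sires = gt_subset(pool2_gt, which(pool2_sex == "M")),
         dam_class = pool2_class[pool2_sex == "F"],
         sire_class = pool2_class[pool2_sex == "M"]),
    config, seed = sub_seed(config$seed, 14L), year = y2, id_prefix = "B")
  co2 <- recruit(b2, config, sub_seed(config$seed, 15L))

  adults <- gt_bind(rec, intro, co1$genotypes, co2$genotypes)
  classes <- c(rep("resident", length(rec$ids)),
               rep("introduced", length(intro$ids)),
               co1$truth$class, co2$truth$class)
  truth <- data.frame(
    id = adults$ids, class = classes, sex = adults$meta$sex,
    year_first_adult = adults$meta$year, stringsAsFactors = FALSE)
  truth$sire <- NA_character_; truth$dam <- NA_character_
  for (co in list(co1, co2)) {
    i <- match(co$truth$id, truth$id)
    truth$sire[i] <- co$truth$sire
    truth$dam[i] <- co$truth$dam
  }

  # Alive-by-year flags and last-seen years from sex-specific survival.
  years <- year0:(y2 + 1L)
  alive <- matrix(FALSE, nrow(truth), length(years),
                  dimnames = list(truth$id, years))
  last <- truth$year_first_adult
  with_seed(sub_seed(config$seed, 16L), {
    for (i in seq_len(nrow(truth))) {
      yr <- truth$year_first_adult[i]
      s <- if (truth$sex[i] == "F") config$survival_f else config$survival_m
      alive[i, match(yr, years)] <- TRUE
      y <- yr
      while (y < max(years) && stats::runif(1) < s) {
        y <- y + 1L
        alive[i, match(y, years)] <- TRUE
      }
      last[i] <- y
    }
  })
  truth$last_seen_year <- last

  records <- data.frame(
    id = truth$id, sex = truth$sex,
    year_first_adult = truth$year_first_adult,
    pouch_young = ifelse(truth$sex == "F", 4L, NA_integer_),
    last_seen_year = truth$last_seen_year, stringsAsFactors = FALSE)

  alive_df <- do.call(rbind, lapply(seq_along(years), function(j) {
    ids <- truth$id[alive[, j] & truth$class != "introduced"]
    if (!length(ids)) return(NULL)
    data.frame(id = ids, year = years[j], stringsAsFactors = FALSE)
  }))
  histories <- simulate_trapping(alive_df, config,
                                 seed = sub_seed(config$seed, 17L))

  list(pools = pools, panel_baseline = rec, adults = adults, truth = truth,
       records = records, histories = histories, alive = alive,
       config = config, years = list(baseline = year0, cohort1 = y1,
                                     cohort2 = y2))
}

# Thin a litter cohort to recruited first-year adults.
recruit <- function(brood, config, seed) {
  keep <- with_seed(seed,
    stats::runif(nrow(brood$truth)) < config$juvenile_survival)
  if (!any(keep)) keep[1L] <- TRUE  # keep the cohort non-empty
  list(genotypes = gt_subset(brood$genotypes, keep),
       truth = brood$truth[keep, , drop = FALSE])
}

survive <- function(ids, sex, config, seed) {
  p <- ifelse(sex == "F", config$survival_f, config$survival_m)
  with_seed(seed, stats::runif(length(ids)) < p)
}
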