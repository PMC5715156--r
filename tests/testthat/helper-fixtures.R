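# Shared fixtures and independent brute-force oracles.

simple_gt <- function(a1, a2, ...) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  genotype_table(sprintf("I%02d", seq_len(nrow(a1))),
                 paste0("L", seq_len(ncol(a1))), a1, a2, ...)
}

# resample individuals (with replacement allowed) under fresh unique ids
resample_gt <- function(gt, idx, prefix = "X") {
  genotype_table(paste0(prefix, seq_along(idx)), gt$loci,
                 gt$a1[idx, , drop = FALSE], gt$a2[idx, , drop = FALSE],
                 pop = gt$meta$pop[idx], year = gt$meta$year[idx],
                 sex = gt$meta$sex[idx])
}

# rarefied allelic richness by exhaustive enumeration of all g-subsamples
ar_brute <- function(counts, g) {
  genes <- rep(seq_along(counts), counts)
  combs <- utils::combn(length(genes), g)
  mean(apply(combs, 2, function(i) length(unique(genes[i]))))
}

# one-tailed Fisher p by enumerating every table with the observed margins
fisher_brute <- function(a, b, c, d, direction = "greater") {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, r1 - (n - c1)); hi <- min(r1, c1)
  xs <- lo:hi
  num <- vapply(xs, function(x) choose(c1, x) * choose(n - c1, r1 - x),
                numeric(1))
  keep <- if (direction == "greater") xs >= a else xs <= a
  sum(num[keep]) / sum(num)
}

# breed exactly n offspring of a given cross type from simulated pools;
# pass the same `pools` used to build the diagnostic panel
breed_type <- function(cfg, n, type = c("F1", "F2", "backcross"), seed,
                       pools = NULL) {
  type <- match.arg(type)
  if (is.null(pools)) {
    pools <- simulate_source_pools(cfg, seed = seed, n_source = 60L)
  }
  res <- gt_subset(pools, which(pools$meta$pop == "recipient"))
  src <- gt_subset(pools, which(pools$meta$pop == "source"))
  cfg1 <- cfg; cfg1$offspring_per_female <- 1L
  n_res <- length(res$ids)
  dams0 <- resample_gt(res, ((seq_len(n) - 1L) %% n_res) + 1L, "D")
  if (type == "F1") {
    b <- breed_cohort(list(dams = dams0, sires = src,
                           dam_class = "resident", sire_class = "introduced"),
                      cfg1, seed = seed + 1L)
    return(b)
  }
  f1 <- breed_cohort(list(dams = dams0, sires = src,
                          dam_class = "resident", sire_class = "introduced"),
                     cfg1, seed = seed + 1L)$genotypes
  f1d <- resample_gt(f1, seq_len(n), "H")
  if (type == "F2") {
    sires <- resample_gt(f1, seq_len(min(n, length(f1$ids))), "S")
    breed_cohort(list(dams = f1d, sires = sires,
                      dam_class = "F1", sire_class = "F1"),
                 cfg1, seed = seed + 2L)
  } else {
    breed_cohort(list(dams = f1d, sires = res,
                      dam_class = "F1", sire_class = "resident"),
                 cfg1, seed = seed + 2L)
  }
}

# discrete Wright-Fisher drift of allele counts at one locus (2N genes)
wf_drift <- function(p0, two_n, t) {
  p <- p0
  for (i in seq_len(t)) {
    p <- as.numeric(stats::rmultinom(1, two_n, p)) / two_n
  }
  p
}
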