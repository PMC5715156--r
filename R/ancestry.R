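# Ancestry classification from diagnostic alleles private to the source
# population, and random-mating class expectations.

#' Build a diagnostic-allele panel
#'
#' An allele is *central-diagnostic* iff it is present in the source
#' population and absent from the recipient baseline (pre-translocation
#' sample). Only loci whose source and recipient allele sets are fully
#' disjoint (fixed differences / non-overlapping allele ranges) enter the
#' panel: at a locus with any shared allele, a resident-range allele in a
#' hybrid is uninformative about which parent transmitted it, so such loci
#' would bias the per-locus homozygosity patterns the classifier relies on.
#'
#' @param source_table [genotype_table()] of the source population.
#' @param recipient_table [genotype_table()] of the recipient baseline
#'   (sampled before any introduced ancestry entered the population).
#' @return Object of class `diagnostic_panel`: a named list (one element per
#'   panel locus) of `list(central = <source-private alleles>,
#'   southern = <recipient alleles>)`.
#' @export
build_panel <- function(source_table, recipient_table) {
  shared <- intersect(source_table$loci, recipient_table$loci)
  if (!length(shared)) stop("source and recipient tables share no loci")
  src_cnt <- allele_counts(source_table)
  rec_cnt <- allele_counts(recipient_table)
  panel <- list()
  for (l in shared) {
    src_alleles <- as.integer(names(src_cnt[[l]]))
    rec_alleles <- as.integer(names(rec_cnt[[l]]))
    if (length(src_alleles) && length(rec_alleles) &&
        !length(intersect(src_alleles, rec_alleles))) {
      panel[[l]] <- list(central = sort(src_alleles),
                         southern = sort(rec_alleles))
    }
  }
  if (!length(panel)) {
    stop("no diagnostic loci found: every locus shares alleles between ",
         "source and recipient baseline; genotype more loci")
  }
  structure(panel, class = "diagnostic_panel")
}

#' @export
print.diagnostic_panel <- function(x, ...) {
  cat(sprintf("diagnostic_panel: %d loci with source-private alleles\n",
              length(x)))
  invisible(x)
}

# Per-individual central-allele score matrix over panel loci:
# number of central alleles (0/1/2) or NA when the call is missing.
central_dose <- function(gt, panel) {
  loci <- intersect(names(panel), gt$loci)
  if (!length(loci)) stop("genotype table shares no loci with the panel")
  dose <- matrix(NA_integer_, length(gt$ids), length(loci),
                 dimnames = list(gt$ids, loci))
  for (l in loci) {
    j <- match(l, gt$loci)
    cen <- panel[[l]]$central
    dose[, l] <- (gt$a1[, j] %in% cen) + (gt$a2[, j] %in% cen)
    dose[is.na(gt$a1[, j]), l] <- NA_integer_
  }
  dose
}

#' Hybrid index from diagnostic alleles
#'
#' Fraction of scored diagnostic-locus alleles that are of central (source)
#' origin: `(# central alleles) / (2 x scored panel loci)`. A quantitative
#' companion to the categorical calls: 0 for residents, 0.5 for F1s at fully
#' diagnostic loci, about 0.25 for first-generation backcrosses.
#'
#' @param gt a [genotype_table()].
#' @param panel a [build_panel()] result.
#' @return Named numeric vector in `[0, 1]`; `NaN` when no panel locus is
#'   scored for an individual.
#' @export
hybrid_index <- function(gt, panel) {
  dose <- central_dose(gt, panel)
  scored <- rowSums(!is.na(dose))
  idx <- rowSums(dose, na.rm = TRUE) / (2 * scored)
  idx[scored == 0] <- NaN
  idx
}

#' Classify ancestry from diagnostic alleles
#'
#' Rule table applied to the scored panel loci of each individual:
#' \itemize{
#'   \item no central allele at any locus: `resident`;
#'   \item heterozygous central/resident at *every* scored locus: `F1`
#'     (up to `max_inconsistent_loci` homozygous loci are tolerated, for
#'     genotyping error);
#'   \item central alleles present, no locus homozygous central, at least one
#'     locus homozygous resident: `backcross`;
#'   \item central alleles present with at least one locus homozygous central
#'     (including mixtures of homozygous central and homozygous resident):
#'     `F2`;
#'   \item id listed in `introduced_ids`: `introduced` (overrides the rules);
#'   \item no scorable panel locus: `ambiguous`.
#' }
#' Note the Mendelian caveat: an F2 heterozygous at all `L` scored loci is
#' indistinguishable from an F1 (probability `(1/2)^L`); see
#' [classification_ambiguity()].
#'
#' @param gt a [genotype_table()].
#' @param panel a [build_panel()] result.
#' @param max_inconsistent_loci homozygous loci tolerated in an otherwise
#'   all-heterozygous (F1-like) pattern; default 0 (strict).
#' @param introduced_ids ids of translocated individuals.
#' @return Data frame (one row per individual): `id`, `class`,
#'   `hybrid_index`, `n_loci_scored`, `n_het`, `n_hom_central`,
#'   `n_hom_resident`.
#' @export
classify_ancestry <- function(gt, panel, max_inconsistent_loci = 0L,
                              introduced_ids = NULL) {
  dose <- central_dose(gt, panel)
  scored <- rowSums(!is.na(dose))
  n_het <- rowSums(dose == 1L, na.rm = TRUE)
  n_homc <- rowSums(dose == 2L, na.rm = TRUE)
  n_homr <- rowSums(dose == 0L, na.rm = TRUE)
  idx <- rowSums(dose, na.rm = TRUE) / (2 * scored)
  idx[scored == 0] <- NaN

  cls <- character(length(gt$ids))
  for (i in seq_along(gt$ids)) {
    cls[i] <- if (scored[i] == 0) {
      "ambiguous"
    } else if (n_het[i] + n_homc[i] == 0) {
      "resident"
    } else if (n_homc[i] + n_homr[i] <= max_inconsistent_loci && n_het[i] > 0) {
      "F1"
    } else if (n_homc[i] >= 1L) {
      "F2"
    } else if (n_homr[i] >= 1L) {
      "backcross"
    } else {
      "ambiguous"
    }
  }
  if (!is.null(introduced_ids)) cls[gt$ids %in% introduced_ids] <- "introduced"
  data.frame(id = gt$ids, class = cls, hybrid_index = idx,
             n_loci_scored = scored, n_het = n_het,
             n_hom_central = n_homc, n_hom_resident = n_homr,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Mendelian misclassification rates of the rule table
#'
#' Closed-form probabilities, under fully diagnostic loci and no genotyping
#' error, that a true F2 or first-generation backcross produces a genotype
#' the rule table assigns to another class. With `L` scored loci a true F2
#' is called F1 with probability `(1/2)^L`, called backcross when it carries
#' central alleles but no homozygous-central locus and at least one
#' homozygous-resident locus, and called resident with probability
#' `(1/4)^L`; a true backcross is called resident with probability
#' `(1/2)^L` and can never be called F2.
#'
#' @param L number of scored diagnostic loci.
#' @return Data frame of true class vs called class probabilities.
#' @export
classification_ambiguity <- function(L) {
  stopifnot(L >= 1)
  # F2: per-locus dose ~ {0: 1/4, 1: 1/2, 2: 1/4}
  f2_f1 <- (1 / 2)^L
  f2_res <- (1 / 4)^L
  f2_bc <- (3 / 4)^L - (1 / 2)^L - (1 / 4)^L + 0
  # P(no homC) = (3/4)^L; minus all-het (F1 call) and all-homR (resident);
  # remainder has >=1 homR and >=1 het -> backcross call.
  f2_f2 <- 1 - f2_f1 - f2_res - f2_bc
  # backcross: dose ~ {0: 1/2, 1: 1/2}
  bc_res <- (1 / 2)^L
  bc_f1 <- (1 / 2)^L            # all loci het
  bc_bc <- 1 - bc_res - bc_f1
  data.frame(
    true = c(rep("F2", 4), rep("backcross", 3)),
    called = c("F1", "resident", "backcross", "F2", "resident", "F1", "backcross"),
    prob = c(f2_f1, f2_res, f2_bc, f2_f2, bc_res, bc_f1, bc_bc),
    stringsAsFactors = FALSE)
}

#' Random-mating expectations for hybrid classes
#'
#' Given the hybrid frequency among breeding females and males, the expected
#' class composition of the next cohort under random mating: an F2 requires
#' two hybrid parents, a backcross exactly one, a non-hybrid none.
#'
#' @param p_female_hybrid,p_male_hybrid hybrid frequency among breeding
#'   females / males, in `[0, 1]`.
#' @return Named numeric vector `c(F2 =, backcross =, nonhybrid =)`, summing
#'   to 1.
#' @export
random_mating_expectations <- function(p_female_hybrid, p_male_hybrid) {
  stopifnot(p_female_hybrid >= 0, p_female_hybrid <= 1,
            p_male_hybrid >= 0, p_male_hybrid <= 1)
  pf <- p_female_hybrid; pm <- p_male_hybrid
  c(F2 = pf * pm,
    backcross = pf * (1 - pm) + (1 - pf) * pm,
    nonhybrid = (1 - pf) * (1 - pm))
}
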