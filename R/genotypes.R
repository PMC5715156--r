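#' Construct a multilocus genotype table
#'
#' A `genotype_table` holds diploid codominant calls (microsatellite fragment
#' lengths) for a set of individuals at a shared locus panel, together with a
#' population label and optional year / sex metadata per individual.
#' Genotypes are unordered allele pairs; homozygotes are stored as a repeated
#' allele. A missing call is encoded as `NA` in *both* allele slots — partial
#' calls are rejected so that missing data can never masquerade as a
#' homozygote.
#'
#' @param ids character vector of unique individual identifiers.
#' @param loci character vector of unique locus names.
#' @param a1,a2 integer matrices (`length(ids)` x `length(loci)`) of allele
#'   fragment lengths; `NA` in both marks a missing call.
#' @param pop population label(s), recycled to one per individual.
#' @param year integer year label(s) (e.g. year first caught as adult),
#'   recycled; `NA` allowed.
#' @param sex `"F"`/`"M"` per individual, recycled; `NA` allowed.
#' @return An object of class `genotype_table`: a list with elements `ids`,
#'   `loci`, `a1`, `a2` and a `meta` data frame (`id`, `pop`, `year`, `sex`).
#' @export
genotype_table <- function(ids, loci, a1, a2, pop = "pop1",
                           year = NA_integer_, sex = NA_character_) {
  ids <- as.character(ids)
  loci <- as.character(loci)
  if (anyDuplicated(ids)) stop("duplicate individual ids")
  if (anyDuplicated(loci)) stop("duplicate locus names")
  a1 <- matrix(as.integer(a1), nrow = length(ids), ncol = length(loci))
  a2 <- matrix(as.integer(a2), nrow = length(ids), ncol = length(loci))
  if (any(xor(is.na(a1), is.na(a2)))) {
    stop("half-missing genotype call: both alleles must be NA or neither")
  }
  ok <- !is.na(a1)
  if (any(a1[ok] <= 0L) || any(a2[ok] <= 0L)) {
    stop("allele lengths must be positive integers")
  }
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  meta <- data.frame(
    id = ids,
    pop = rep_len(as.character(pop), length(ids)),
    year = rep_len(as.integer(year), length(ids)),
    sex = rep_len(as.character(sex), length(ids)),
    stringsAsFactors = FALSE
  )
  structure(list(ids = ids, loci = loci, a1 = a1, a2 = a2, meta = meta),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d individuals x %d loci, %d population(s)\n",
              length(x$ids), length(x$loci),
              length(unique(x$meta$pop))))
  miss <- mean(is.na(x$a1))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Subset a genotype table by individual
#'
#' @param gt a [genotype_table()].
#' @param i logical, integer or character index into the individuals.
#' @return A `genotype_table` with the selected individuals.
#' @export
gt_subset <- function(gt, i) {
  if (is.character(i)) i <- match(i, gt$ids)
  genotype_table(gt$ids[i], gt$loci,
                 gt$a1[i, , drop = FALSE], gt$a2[i, , drop = FALSE],
                 pop = gt$meta$pop[i], year = gt$meta$year[i],
                 sex = gt$meta$sex[i])
}

#' Row-bind genotype tables sharing one locus panel
#'
#' @param ... `genotype_table` objects with identical `loci`.
#' @return A combined `genotype_table`.
#' @export
gt_bind <- function(...) {
  tabs <- list(...)
  stopifnot(length(tabs) >= 1L)
  loci <- tabs[[1L]]$loci
  for (t in tabs) {
    if (!identical(t$loci, loci)) stop("locus panels differ; cannot bind")
  }
  genotype_table(
    ids = unlist(lapply(tabs, `[[`, "ids")),
    loci = loci,
    a1 = do.call(rbind, lapply(tabs, `[[`, "a1")),
    a2 = do.call(rbind, lapply(tabs, `[[`, "a2")),
    pop = unlist(lapply(tabs, function(t) t$meta$pop)),
    year = unlist(lapply(tabs, function(t) t$meta$year)),
    sex = unlist(lapply(tabs, function(t) t$meta$sex))
  )
}

#' Per-locus allele counts
#'
#' Tabulates allele copies at each locus over the non-missing genotypes.
#'
#' @param gt a [genotype_table()].
#' @return Named list, one integer table per locus (allele length -> count);
#'   loci with no scored genotypes yield a zero-length table.
#' @export
allele_counts <- function(gt) {
  out <- lapply(seq_along(gt$loci), function(l) {
    al <- c(gt$a1[, l], gt$a2[, l])
    table(al[!is.na(al)])
  })
  names(out) <- gt$loci
  out
}
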