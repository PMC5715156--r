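# Readers and writers: Genepop, columnar genotype CSV, individual records,
# capture histories. All writers are bit-stable for a fixed input order.

#' Read a Genepop file
#'
#' Parses the classic Genepop text format (title line; locus names, one per
#' line or comma-separated on one line; `pop` separators; one individual per
#' line as `name , g1 g2 ...`). Both the 4-digit (2-digit alleles) and the
#' 6-digit (3-digit alleles) dialects are accepted; `0000` / `000000` — or any
#' call with a zero allele — is mapped to a missing call.
#'
#' Population labelling dialect: if the name field before the comma contains
#' whitespace, its first token is taken as the population label and the
#' remainder as the individual id (this is what [write_genepop()] emits);
#' otherwise the whole field is the id and blocks are labelled
#' `pop1, pop2, ...`.
#'
#' @param path path to a Genepop `.gen` file.
#' @return A [genotype_table()] (year and sex metadata are `NA`; Genepop does
#'   not carry them).
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop_parse(path, length(lines), "truncated Genepop file")
  is_pop <- grepl("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  first_pop <- which(is_pop)[1L]
  if (is.na(first_pop) || first_pop < 3L) {
    stop_parse(path, 1L, "no 'pop' separator found after locus names")
  }
  locus_lines <- trimws(lines[2:(first_pop - 1L)])
  locus_lines <- locus_lines[nzchar(locus_lines)]
  if (length(locus_lines) == 1L && grepl(",", locus_lines)) {
    loci <- trimws(strsplit(locus_lines, ",")[[1L]])
  } else {
    loci <- locus_lines
    if (any(grepl(",", loci))) {
      stop_parse(path, 2L, "mixed one-per-line and comma-separated locus names")
    }
  }
  if (!length(loci) || anyDuplicated(loci)) {
    stop_parse(path, 2L, "empty or duplicated locus names")
  }

  ids <- character(); pops <- character()
  a1 <- NULL; a2 <- NULL
  block <- 0L
  digits <- NA_integer_
  for (ln in seq(first_pop, length(lines))) {
    txt <- trimws(lines[ln])
    if (!nzchar(txt)) next
    if (grepl("^pop$", txt, ignore.case = TRUE)) {
      block <- block + 1L
      next
    }
    parts <- strsplit(txt, ",", fixed = TRUE)[[1L]]
    if (length(parts) < 2L) stop_parse(path, ln, "expected 'name , genotypes'")
    name <- trimws(parts[1L])
    if (grepl("\\s", name)) {
      toks <- strsplit(name, "\\s+")[[1L]]
      pop_lab <- toks[1L]
      id <- paste(toks[-1L], collapse = " ")
    } else {
      pop_lab <- paste0("pop", block)
      id <- name
    }
    gts <- strsplit(trimws(paste(parts[-1L], collapse = ",")), "\\s+")[[1L]]
    if (length(gts) != length(loci)) {
      stop_parse(path, ln, sprintf("expected %d genotypes, found %d",
                                   length(loci), length(gts)))
    }
    w <- unique(nchar(gts))
    if (length(w) != 1L || !(w %in% c(4L, 6L)) || any(!grepl("^[0-9]+$", gts))) {
      stop_parse(path, ln, "genotypes must be uniform 4- or 6-digit numeric codes")
    }
    if (is.na(digits)) digits <- w %/% 2L
    if (w %/% 2L != digits) stop_parse(path, ln, "mixed allele code widths")
    x1 <- as.integer(substr(gts, 1L, digits))
    x2 <- as.integer(substr(gts, digits + 1L, 2L * digits))
    miss <- x1 == 0L | x2 == 0L
    x1[miss] <- NA_integer_; x2[miss] <- NA_integer_
    ids <- c(ids, id); pops <- c(pops, pop_lab)
    a1 <- rbind(a1, x1); a2 <- rbind(a2, x2)
  }
  if (!length(ids)) stop_parse(path, length(lines), "no individuals found")
  genotype_table(ids, loci, a1, a2, pop = pops)
}

#' Write a Genepop file
#'
#' Inverse of [read_genepop()] for the population-label dialect documented
#' there: individuals are written as `<pop> <id> ,  g1 g2 ...`, grouped into
#' `pop` blocks in order of first appearance of each population label.
#' Allele code width is chosen automatically (2 digits if every allele is
#' below 100, else 3) unless forced.
#'
#' @param gt a [genotype_table()].
#' @param path output path.
#' @param title title line (first line of the file).
#' @param digits allele code width, 2 or 3; default auto.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(gt, path, title = "generescue export", digits = NULL) {
  mx <- suppressWarnings(max(gt$a1, gt$a2, na.rm = TRUE))
  if (!is.finite(mx)) mx <- 1L
  if (is.null(digits)) digits <- if (mx < 100L) 2L else 3L
  stopifnot(digits %in% c(2L, 3L))
  if (mx >= 10^digits) stop("allele length ", mx, " does not fit in ", digits, " digits")
  fmt <- function(x) {
    x[is.na(x)] <- 0L
    formatC(x, width = digits, flag = "0")
  }
  out <- c(title, gt$loci)
  for (p in unique(gt$meta$pop)) {
    out <- c(out, "pop")
    for (i in which(gt$meta$pop == p)) {
      codes <- paste0(fmt(gt$a1[i, ]), fmt(gt$a2[i, ]))
      out <- c(out, paste0(p, " ", gt$ids[i], " ,  ", paste(codes, collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read / write genotype tables as columnar CSV
#'
#' The CSV dialect carries the full metadata Genepop cannot: columns `id`,
#' `pop`, `year`, `sex`, then `<locus>.1` and `<locus>.2` allele-length pairs
#' for each locus (empty cells = missing call). UTF-8, comma separated,
#' header required.
#'
#' @param gt a [genotype_table()].
#' @param path file path.
#' @return `read_genotype_csv()` returns a [genotype_table()];
#'   `write_genotype_csv()` returns `path` invisibly.
#' @export
write_genotype_csv <- function(gt, path) {
  df <- gt$meta
  for (l in seq_along(gt$loci)) {
    df[[paste0(gt$loci[l], ".1")]] <- gt$a1[, l]
    df[[paste0(gt$loci[l], ".2")]] <- gt$a2[, l]
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_genotype_csv
#' @export
read_genotype_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "pop", "year", "sex")
  if (!all(need %in% names(df))) {
    stop("genotype CSV must have columns ", paste(need, collapse = ", "))
  }
  acols <- setdiff(names(df), need)
  l1 <- grep("\\.1$", acols, value = TRUE)
  loci <- sub("\\.1$", "", l1)
  if (!length(loci) || !all(paste0(loci, ".2") %in% acols)) {
    stop("genotype CSV needs paired <locus>.1 / <locus>.2 columns")
  }
  a1 <- as.matrix(df[paste0(loci, ".1")])
  a2 <- as.matrix(df[paste0(loci, ".2")])
  genotype_table(df$id, loci, a1, a2, pop = df$pop, year = df$year, sex = df$sex)
}

#' Read / write individual life-history records
#'
#' Columns: `id`, `sex` (`F`/`M`), `year_first_adult`, `pouch_young`
#' (0-4, empty for males / unknown), `last_seen_year`, and optional
#' morphometric columns (`weight_g`, `tail_mm`, `head_mm`, `body_mm`).
#'
#' @param records a data frame with the columns above.
#' @param path file path.
#' @return `read_individuals_csv()` returns the validated data frame.
#' @export
read_individuals_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_individuals(df)
}

#' @rdname read_individuals_csv
#' @export
write_individuals_csv <- function(records, path) {
  validate_individuals(records)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

validate_individuals <- function(df) {
  need <- c("id", "sex", "year_first_adult", "last_seen_year")
  if (!all(need %in% names(df))) {
    stop("individual records need columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$id)) stop("duplicate individual ids in records")
  if (!all(df$sex %in% c("F", "M", NA))) stop("sex must be F or M")
  if (any(df$last_seen_year < df$year_first_adult, na.rm = TRUE)) {
    stop("last_seen_year before year_first_adult")
  }
  if ("pouch_young" %in% names(df)) {
    py <- df$pouch_young
    if (any(py < 0 | py > 4, na.rm = TRUE)) stop("pouch_young must be in 0..4")
  }
  df
}

#' Read capture histories from CSV
#'
#' Expected columns: `id`, `year`, then `occ_1 ... occ_k` binary detection
#' columns for the secondary occasions within each primary year. The number
#' of secondary occasions may vary between years: cells for occasions not run
#' in a given year are left empty, and all rows of one year must use the same
#' occasion set. All-zero histories are rejected — an individual never
#' detected within a year cannot appear in the data.
#'
#' @param path CSV path.
#' @return An object of class `capture_histories`: a data frame with columns
#'   `id`, `year` and the `occ_*` detection columns (`NA` = occasion not run
#'   that year).
#' @export
read_capture_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_capture_histories(df)
}

#' @rdname read_capture_csv
#' @param ch a `capture_histories` object.
#' @export
write_capture_csv <- function(ch, path) {
  utils::write.csv(as.data.frame(ch), path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

validate_capture_histories <- function(df) {
  occ <- grep("^occ_\\d+$", names(df), value = TRUE)
  if (!all(c("id", "year") %in% names(df)) || !length(occ)) {
    stop("capture CSV needs columns id, year, occ_1..occ_k")
  }
  occ <- occ[order(as.integer(sub("occ_", "", occ)))]
  df <- df[c("id", "year", occ)]
  m <- as.matrix(df[occ])
  if (!all(m %in% c(0, 1, NA))) stop("capture cells must be 0, 1 or empty")
  if (anyDuplicated(df[c("id", "year")])) stop("duplicate (id, year) rows")
  live <- rowSums(m == 1, na.rm = TRUE)
  if (any(live == 0)) {
    stop("all-zero capture history for id(s): ",
         paste(df$id[live == 0], collapse = ", "))
  }
  for (y in unique(df$year)) {
    sub <- m[df$year == y, , drop = FALSE]
    pat <- !is.na(sub)
    if (nrow(sub) > 1L && any(colSums(pat) %% nrow(sub) != 0)) {
      stop("inconsistent occasion set within year ", y)
    }
  }
  structure(df, class = c("capture_histories", "data.frame"))
}

# Detection matrix (individuals x occasions) for one primary year.
year_matrix <- function(ch, year) {
  sub <- ch[ch$year == year, , drop = FALSE]
  occ <- grep("^occ_", names(sub), value = TRUE)
  m <- as.matrix(sub[occ])
  keep <- colSums(!is.na(m)) > 0
  m <- m[, keep, drop = FALSE]
  rownames(m) <- sub$id
  storage.mode(m) <- "integer"
  m
}

#' Export capture histories in MARK encounter-history (.inp) format
#'
#' One line per individual per primary year: the concatenated 0/1 history
#' followed by a frequency of 1 and a terminating semicolon, for
#' cross-checking single-year closed models against external software.
#'
#' @param ch a `capture_histories` object.
#' @param path output path.
#' @param year primary year to export.
#' @return `path`, invisibly.
#' @export
write_mark_inp <- function(ch, path, year) {
  m <- year_matrix(ch, year)
  if (!nrow(m)) stop("no histories for year ", year)
  lines <- paste0("/* ", rownames(m), " */ ",
                  apply(m, 1, paste, collapse = ""), " 1;")
  writeLines(lines, path)
  invisible(path)
}
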