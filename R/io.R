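#' Reconstruct integer haplotype counts from printed percentage frequencies
#'
#' Published frequency tables usually print haplotype or allele frequencies as
#' percentages rounded to one decimal place.  When the number of gene copies
#' (2N) is known, the underlying integer counts can often be recovered
#' exactly: a count `k` is admissible for a printed value `f` only if
#' `|100 k / gene_copies - f| <= 0.05`, and the admissible counts must sum to
#' `gene_copies`.  The solution is found by exhaustive enumeration over the
#' admissible range of every entry; if no integer vector is consistent, or if
#' more than one is, the function fails rather than guessing.
#'
#' @param freq_percent numeric vector of printed percentages in \[0, 100\].
#' @param gene_copies total number of gene copies (2N), a positive integer.
#' @param tol half-width of the rounding band on the percentage scale
#'   (default 0.05, i.e. printed values rounded to one decimal).
#' @return Integer vector of counts, same length and names as `freq_percent`,
#'   summing to `gene_copies`.
#' @examples
#' reconstruct_counts(c(6.3, 43.8, 25.0, 12.5, 12.5, 0, 0), 16)
#' @export
reconstruct_counts <- function(freq_percent, gene_copies, tol = 0.05) {
  stopifnot(is.numeric(freq_percent), length(freq_percent) >= 1L,
            all(is.finite(freq_percent)),
            all(freq_percent >= 0), all(freq_percent <= 100),
            length(gene_copies) == 1L, gene_copies > 0,
            gene_copies == round(gene_copies))
  n <- as.integer(gene_copies)
  cand <- lapply(freq_percent, function(f) {
    lo <- max(0L, floor((f - tol) * n / 100))
    hi <- min(n, ceiling((f + tol) * n / 100))
    ks <- lo:hi
    ks[abs(100 * ks / n - f) <= tol + 1e-9]
  })
  empty <- which(vapply(cand, length, 1L) == 0L)
  if (length(empty))
    stop(sprintf(
      "no integer count matches printed frequency at entr%s %s (2N = %d)",
      if (length(empty) > 1) "ies" else "y",
      paste(empty, collapse = ", "), n))
  lo <- vapply(cand, min, 1L)
  hi <- vapply(cand, max, 1L)
  k <- length(cand)
  # depth-first enumeration with sum bounds; keep up to two solutions
  sols <- list()
  lo_tail <- rev(cumsum(rev(lo)))
  hi_tail <- rev(cumsum(rev(hi)))
  recurse <- function(i, acc, s) {
    if (length(sols) >= 2L) return()
    if (i > k) {
      if (s == n) sols[[length(sols) + 1L]] <<- acc
      return()
    }
    rest_lo <- if (i < k) lo_tail[i + 1L] else 0L
    rest_hi <- if (i < k) hi_tail[i + 1L] else 0L
    for (v in cand[[i]]) {
      if (s + v + rest_lo <= n && s + v + rest_hi >= n)
        recurse(i + 1L, c(acc, v), s + v)
    }
  }
  recurse(1L, integer(0), 0L)
  if (length(sols) == 0L)
    stop(sprintf("printed frequencies are inconsistent with 2N = %d: %s",
                 n, paste(sprintf("%.1f", freq_percent), collapse = ", ")))
  if (length(sols) > 1L)
    stop(sprintf("count reconstruction ambiguous for 2N = %d: at least %s and %s",
                 n, paste(sols[[1]], collapse = ","),
                 paste(sols[[2]], collapse = ",")))
  out <- sols[[1]]
  names(out) <- names(freq_percent)
  out
}

#' Validate a population-by-haplotype count table
#'
#' @param counts integer matrix, populations in rows, haplotype/allele classes
#'   in columns, non-negative entries.  Row sums are the per-population gene
#'   copy numbers (2N).
#' @return `counts`, invisibly, after validation.
#' @export
validate_count_table <- function(counts) {
  stopifnot(is.matrix(counts), is.numeric(counts))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("count table must contain non-negative integers")
  if (any(rowSums(counts) == 0))
    stop("population(s) with zero gene copies: ",
         paste(rownames(counts)[rowSums(counts) == 0], collapse = ", "))
  invisible(counts)
}

# -- genotype / pedigree / genepop readers ---------------------------------

.parse_allele_pair <- function(x, line, what) {
  if (is.na(x) || x == "NA" || x == "") return(c(NA_character_, NA_character_))
  parts <- strsplit(x, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop(sprintf("line %d: malformed %s genotype '%s' (expected a1/a2)",
                 line, what, x))
  parts
}

#' Read an individual genotype table
#'
#' Tab-separated, one row per individual.  Required columns: `id`,
#' `population`, `dab`, `uaa`; genotypes are unordered allele pairs written
#' `a1/a2` (e.g. `*02/*03`), missing as `NA`.  Any further columns are
#' treated as microsatellite loci with integer allele lengths (`101/103`,
#' or 6-digit Genepop coding `101103`; `NA` or `000000` missing).
#'
#' @param path file path.
#' @param catalog haplotype catalog used to validate MHC allele labels.
#' @return A data frame of class `"haplopop_genotypes"`: columns `id`,
#'   `population`, `dab`, `uaa` (strings `a1/a2`), plus one column per
#'   microsatellite locus.  Attribute `"msat_loci"` lists the locus names.
#' @export
read_genotype_table <- function(path, catalog = mhc_haplotype_catalog()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("id", "population", "dab", "uaa")
  if (!all(need %in% names(df)))
    stop("genotype table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$id))
    stop("duplicate individual id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  msat <- setdiff(names(df), need)
  for (i in seq_len(nrow(df))) {
    ln <- i + 1L  # header is line 1
    for (locus in c("dab", "uaa")) {
      pair <- .parse_allele_pair(df[[locus]][i], ln, toupper(locus))
      if (anyNA(pair)) next
      valid <- unique(catalog[[locus]])
      bad <- setdiff(pair, valid)
      if (length(bad))
        stop(sprintf("line %d: unknown %s allele '%s'",
                     ln, toupper(locus), bad[1]))
    }
    for (locus in msat) {
      x <- df[[locus]][i]
      if (is.na(x) || x %in% c("NA", "", "000000", "0000")) {
        df[[locus]][i] <- NA_character_
        next
      }
      if (grepl("^[0-9]{6}$", x)) {          # Genepop 3-digit coding
        a <- c(substr(x, 1, 3), substr(x, 4, 6))
        if (any(a == "000")) { df[[locus]][i] <- NA_character_; next }
        df[[locus]][i] <- paste(as.integer(a), collapse = "/")
        next
      }
      pair <- .parse_allele_pair(x, ln, locus)
      if (anyNA(suppressWarnings(as.integer(pair))))
        stop(sprintf("line %d: microsatellite alleles at %s must be integer lengths, got '%s'",
                     ln, locus, x))
    }
  }
  attr(df, "msat_loci") <- msat
  class(df) <- c("haplopop_genotypes", class(df))
  df
}

#' Read a pedigree table
#'
#' Tab-separated with columns `id`, `sire`, `dam` and optionally
#' `candidate_sires`, `candidate_dams` (comma-separated label sets, e.g. cage
#' co-occupants).  Unknown parents are `NA`.  The pedigree must be acyclic.
#'
#' @param path file path.
#' @return Data frame with columns `id`, `sire`, `dam`, `candidate_sires`,
#'   `candidate_dams` (the last two as list columns of character vectors).
#' @export
read_pedigree <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(df)))
    stop("pedigree must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$id))
    stop("duplicate pedigree id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  df$sire[df$sire %in% c("", "NA")] <- NA_character_
  df$dam[df$dam %in% c("", "NA")] <- NA_character_
  split_set <- function(col) {
    if (!col %in% names(df)) return(rep(list(character(0)), nrow(df)))
    lapply(df[[col]], function(x)
      if (is.na(x) || x %in% c("", "NA")) character(0)
      else trimws(strsplit(x, ",", fixed = TRUE)[[1]]))
  }
  out <- data.frame(id = df$id, sire = df$sire, dam = df$dam,
                    stringsAsFactors = FALSE)
  out$candidate_sires <- split_set("candidate_sires")
  out$candidate_dams <- split_set("candidate_dams")
  .check_acyclic(out)
  out
}

.check_acyclic <- function(ped) {
  # DFS over child -> parent edges restricted to ids in the table
  parents <- stats::setNames(
    lapply(seq_len(nrow(ped)), function(i)
      ped$id[match(c(ped$sire[i], ped$dam[i]), ped$id, nomatch = 0L)]),
    ped$id)
  state <- stats::setNames(integer(length(parents)), names(parents))
  visit <- function(v) {
    if (state[[v]] == 1L) stop("pedigree cycle involving individual ", v)
    if (state[[v]] == 2L) return()
    state[[v]] <<- 1L
    for (p in parents[[v]]) visit(p)
    state[[v]] <<- 2L
  }
  for (v in names(parents)) visit(v)
  invisible(TRUE)
}

#' Read a Genepop microsatellite file
#'
#' Supports the standard dialect: a title line, one locus name per line (or a
#' single comma-separated line), `Pop` separators, and individual lines
#' `name ,  090090 092094 ...` with 2- or 3-digit allele coding.  All-zero
#' genotypes are missing.  Population labels are taken from the name of each
#' population's last individual when it looks like `pop_ind`, otherwise
#' `pop1`, `pop2`, ...
#'
#' @param path file path.
#' @return Data frame with columns `id`, `population` and one column per
#'   locus (allele lengths as `a1/a2` strings, `NA` when missing), with
#'   attribute `"msat_loci"`.
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not a Genepop file: ", path)
  body <- lines[-1L]
  pop_at <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (length(pop_at) == 0L) stop("Genepop file has no 'Pop' line: ", path)
  loci <- body[seq_len(pop_at[1] - 1L)]
  if (length(loci) == 1L && grepl(",", loci))
    loci <- trimws(strsplit(loci, ",", fixed = TRUE)[[1]])
  else loci <- trimws(loci)
  rows <- list()
  pop_i <- 0L
  for (k in seq(pop_at[1], length(body))) {
    ln <- body[k]
    if (grepl("^\\s*pop\\s*$", ln, ignore.case = TRUE)) {
      pop_i <- pop_i + 1L
      next
    }
    parts <- strsplit(ln, ",", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop(sprintf("Genepop parse error at line %d: '%s'",
                   which(lines == ln)[1], ln))
    nm <- trimws(parts[1])
    gts <- strsplit(trimws(parts[2]), "\\s+")[[1]]
    if (length(gts) != length(loci))
      stop(sprintf("Genepop line for '%s': %d genotypes, expected %d loci",
                   nm, length(gts), length(loci)))
    d <- nchar(gts[1]) / 2L
    if (!d %in% c(2L, 3L))
      stop("Genepop genotypes must use 2- or 3-digit allele coding")
    pair <- vapply(gts, function(g) {
      a <- c(substr(g, 1L, d), substr(g, d + 1L, 2L * d))
      if (any(as.integer(a) == 0L)) NA_character_
      else paste(as.integer(a), collapse = "/")
    }, character(1), USE.NAMES = FALSE)
    rows[[length(rows) + 1L]] <-
      c(list(id = nm, population = paste0("pop", pop_i)), as.list(pair))
  }
  df <- do.call(rbind.data.frame,
                c(rows, list(stringsAsFactors = FALSE, make.row.names = FALSE)))
  names(df) <- c("id", "population", loci)
  # prefer embedded population labels "pop_ind"
  lab <- sub("_[^_]*$", "", df$id)
  if (!anyDuplicated(unique(cbind(df$population, lab))[, 1]) &&
      all(grepl("_", df$id)))
    df$population <- lab
  attr(df, "msat_loci") <- loci
  df
}

#' Write microsatellite genotypes in Genepop format
#'
#' @param genotypes data frame as returned by [read_genotype_table()] or
#'   [read_genepop()] (columns `id`, `population`, loci as `a1/a2`).
#' @param path output file.
#' @param title title line.
#' @param digits allele field width (2 or 3).
#' @return `path`, invisibly.
#' @export
write_genepop <- function(genotypes, path, title = "haplopop export",
                          digits = 3L) {
  loci <- attr(genotypes, "msat_loci")
  if (is.null(loci))
    loci <- setdiff(names(genotypes), c("id", "population", "dab", "uaa"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(title, loci), con)
  fmt <- function(x) {
    if (is.na(x)) return(strrep("0", 2L * digits))
    a <- as.integer(strsplit(x, "/", fixed = TRUE)[[1]])
    paste0(formatC(a, width = digits, flag = "0"), collapse = "")
  }
  for (pop in unique(genotypes$population)) {
    writeLines("Pop", con)
    sub <- genotypes[genotypes$population == pop, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      gts <- vapply(loci, function(l) fmt(sub[[l]][i]), character(1))
      writeLines(paste0(pop, "_", sub$id[i], " ,  ",
                        paste(gts, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Write analysis results to TSV or JSON
#'
#' Tabular results (data frames) round-trip through TSV; arbitrary nested
#' results (e.g. an AMOVA fit) are serialized to JSON, and to TSV only via a
#' flat component table when one is available (`x$table`).
#'
#' @param x a data frame or list.
#' @param path output file.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  } else {
    tab <- if (is.data.frame(x)) x
           else if (!is.null(x$table) && is.data.frame(x$table)) x$table
           else stop("no tabular representation for TSV output; use json")
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read results written by [write_results()]
#'
#' @param path file path; format inferred from the extension.
#' @return A data frame (TSV) or list (JSON).
#' @export
read_results <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    utils::read.delim(path, stringsAsFactors = FALSE)
}
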