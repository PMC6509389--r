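#' Read genotypes from GenePop or CSV
#'
#' The CSV dialect is one row per individual with columns `id`, `site`, then
#' two columns per locus named `<locus>.a1` and `<locus>.a2`; missing alleles
#' are coded 0. GenePop files are accepted with 2- or 3-digit allele coding;
#' `00`/`000` codes a missing call. The site label of each POP block is taken
#' from the last comma-separated token of the first individual line in the
#' block (a common convention for carrying site ids in GenePop names).
#'
#' @param path path to an existing file.
#' @param format `"csv"` or `"genepop"`.
#' @return a validated [genotype_table()].
#' @seealso [write_genotypes()]
#' @export
read_genotypes <- function(path, format = c("csv", "genepop")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
    csv = read_genotypes_csv(path),
    genepop = read_genotypes_genepop(path)
  )
}

read_genotypes_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("id", "site") %in% names(df))) {
    stop("CSV must have 'id' and 'site' columns: ", path)
  }
  acols <- setdiff(names(df), c("id", "site"))
  is_a1 <- grepl("\\.a1$", acols)
  is_a2 <- grepl("\\.a2$", acols)
  if (!all(is_a1 | is_a2)) {
    stop("locus columns must be named <locus>.a1 / <locus>.a2")
  }
  loci <- sub("\\.a1$", "", acols[is_a1])
  loci2 <- sub("\\.a2$", "", acols[is_a2])
  if (!identical(loci, loci2)) stop("mismatched .a1/.a2 locus columns")
  a1 <- as.matrix(df[, paste0(loci, ".a1"), drop = FALSE])
  a2 <- as.matrix(df[, paste0(loci, ".a2"), drop = FALSE])
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  a1[a1 == 0L] <- NA_integer_
  a2[a2 == 0L] <- NA_integer_
  # half-missing calls are a validation error, not silently dropped
  genotype_table(df$id, df$site, loci, a1, a2)
}

parse_genepop_alleles <- function(code, line_no) {
  w <- nchar(code)
  if (!w %in% c(4L, 6L)) {
    stop(sprintf("line %d: genotype '%s' is not 2- or 3-digit coded",
                 line_no, code))
  }
  half <- w %/% 2L
  a <- suppressWarnings(as.integer(substr(code, 1L, half)))
  b <- suppressWarnings(as.integer(substr(code, half + 1L, w)))
  if (is.na(a) || is.na(b)) {
    stop(sprintf("line %d: non-numeric genotype '%s'", line_no, code))
  }
  if (a == 0L) a <- NA_integer_
  if (b == 0L) b <- NA_integer_
  if (xor(is.na(a), is.na(b))) {
    stop(sprintf("line %d: half-missing genotype '%s'", line_no, code))
  }
  c(a, b)
}

read_genotypes_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines_trim <- trimws(lines)
  if (length(lines_trim) < 3) stop("GenePop file too short: ", path)
  is_pop <- toupper(lines_trim) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("no POP keyword found in ", path)
  header <- lines_trim[2:(first_pop - 1)]
  loci <- trimws(unlist(strsplit(header, ",")))
  loci <- loci[nzchar(loci)]
  if (!length(loci)) stop("no locus names found in ", path)

  id <- character(); site <- character()
  rows1 <- list(); rows2 <- list()
  cur_site <- NA_character_
  pop_i <- 0L
  for (k in seq(first_pop, length(lines_trim))) {
    ln <- lines_trim[k]
    if (!nzchar(ln)) next
    if (toupper(ln) == "POP") {
      pop_i <- pop_i + 1L
      cur_site <- NA_character_
      next
    }
    if (pop_i == 0L) next
    toks <- strsplit(ln, ",")[[1]]
    if (length(toks) < 2) {
      stop(sprintf("line %d: expected '<name>, <genotypes>'", k))
    }
    gts <- strsplit(trimws(toks[length(toks)]), "[[:space:]]+")[[1]]
    idtoks <- trimws(toks[-length(toks)])
    if (is.na(cur_site)) {
      cur_site <- idtoks[length(idtoks)]
      if (!nzchar(cur_site)) cur_site <- sprintf("pop%02d", pop_i)
    }
    if (length(gts) != length(loci)) {
      stop(sprintf("line %d: %d genotypes for %d loci",
                   k, length(gts), length(loci)))
    }
    al <- vapply(seq_along(gts),
                 function(j) parse_genepop_alleles(gts[j], k),
                 integer(2))
    id <- c(id, idtoks[1])
    site <- c(site, cur_site)
    rows1[[length(rows1) + 1L]] <- al[1, ]
    rows2[[length(rows2) + 1L]] <- al[2, ]
  }
  if (!length(id)) stop("no individuals found in ", path)
  genotype_table(id, site, loci,
                 do.call(rbind, rows1), do.call(rbind, rows2))
}

#' Write genotypes to GenePop or CSV
#'
#' CSV uses the dialect documented in [read_genotypes()]. GenePop output is
#' 3-digit coded with one POP block per site (sites in order of first
#' appearance) and individual lines `"<id> ,<site>, <genotypes>"`, so the
#' site label round-trips through the last name token.
#'
#' @param x a `genotype_table`.
#' @param path output path.
#' @param format `"csv"` or `"genepop"`.
#' @param title title line for GenePop output.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(x, path, format = c("csv", "genepop"),
                            title = "ibrsamp genotype export") {
  format <- match.arg(format)
  validate_genotype_table(x)
  if (format == "csv") {
    a1 <- x$a1; a2 <- x$a2
    a1[is.na(a1)] <- 0L; a2[is.na(a2)] <- 0L
    out <- data.frame(id = x$id, site = x$site, check.names = FALSE)
    for (j in seq_along(x$loci)) {
      out[[paste0(x$loci[j], ".a1")]] <- a1[, j]
      out[[paste0(x$loci[j], ".a2")]] <- a2[, j]
    }
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  if (any(c(x$a1, x$a2) > 999L, na.rm = TRUE)) {
    stop("allele codes above 999 cannot be written as 3-digit GenePop")
  }
  fmt3 <- function(a) ifelse(is.na(a), "000", sprintf("%03d", a))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(paste(x$loci, collapse = ", "), con)
  for (s in unique(x$site)) {
    writeLines("POP", con)
    rows <- which(x$site == s)
    for (i in rows) {
      gts <- paste0(fmt3(x$a1[i, ]), fmt3(x$a2[i, ]), collapse = " ")
      writeLines(sprintf("%s ,%s, %s", x$id[i], s, gts), con)
    }
  }
  invisible(path)
}

#' Classify sites by sample size
#'
#' Partitions sites into population-level samples (at least `min_pop_size`
#' individuals) and below-threshold sites. The default threshold of 11
#' follows the empirical cut commonly used for pond-breeding amphibian
#' surveys where per-site catch is uneven.
#'
#' @param x a `genotype_table`.
#' @param min_pop_size minimum individuals for a population-level site.
#' @return a list with `population` and `below` (character vectors of site
#'   labels) and `counts` (named integer vector for all sites).
#' @export
classify_sites <- function(x, min_pop_size = 11) {
  stopifnot(min_pop_size >= 1)
  counts <- site_counts(x)
  list(
    population = names(counts)[counts >= min_pop_size],
    below = names(counts)[counts < min_pop_size],
    counts = counts
  )
}

#' Per-locus allele frequencies
#'
#' Frequencies are computed over observed (non-missing) gene copies; each
#' diploid call contributes two copies.
#'
#' @param x a `genotype_table`.
#' @param group `"pooled"` for all individuals, or a character vector of site
#'   labels defining the group.
#' @return a list with one element per locus, each a list with `freq` (named
#'   numeric vector summing to 1, empty if no data) and `n_genes` (observed
#'   gene-copy count).
#' @export
allele_frequencies <- function(x, group = "pooled") {
  if (identical(group, "pooled")) {
    sel <- seq_along(x$id)
  } else {
    sel <- which(x$site %in% group)
    if (!length(sel)) stop("group contains no individuals")
  }
  out <- lapply(seq_along(x$loci), function(j) {
    genes <- c(x$a1[sel, j], x$a2[sel, j])
    genes <- genes[!is.na(genes)]
    if (!length(genes)) {
      return(list(freq = numeric(0), n_genes = 0L))
    }
    tab <- table(genes)
    list(
      freq = stats::setNames(as.numeric(tab) / length(genes), names(tab)),
      n_genes = length(genes)
    )
  })
  names(out) <- x$loci
  out
}

#' Per-locus allele gene-copy counts
#'
#' @inheritParams allele_frequencies
#' @return named list per locus of named integer count vectors.
#' @export
allele_counts <- function(x, group = "pooled") {
  fr <- allele_frequencies(x, group)
  lapply(fr, function(f) {
    stats::setNames(as.integer(round(f$freq * f$n_genes)), names(f$freq))
  })
}
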