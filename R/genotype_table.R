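#' Diploid genotype tables
#'
#' A `genotype_table` holds diploid multilocus genotypes for a set of
#' individuals, each assigned to exactly one sampling site. Allele calls are
#' stored as two integer matrices (`a1`, `a2`, individuals x loci); a missing
#' call is `NA` in both matrices at that cell (a locus call is either complete
#' or wholly missing).
#'
#' @param id character vector of unique individual ids.
#' @param site character vector, same length as `id`: site label per
#'   individual.
#' @param loci character vector of locus names.
#' @param a1,a2 integer matrices (`length(id)` x `length(loci)`) of allele
#'   codes; positive integers, `NA` for missing. `a1[i, l]` and `a2[i, l]`
#'   must be both present or both `NA`.
#'
#' @return An object of class `genotype_table` with elements `id`, `site`,
#'   `loci`, `a1`, `a2`.
#' @examples
#' gt <- genotype_table(
#'   id = c("i1", "i2"), site = c("s1", "s2"), loci = c("L1", "L2"),
#'   a1 = matrix(c(1L, 1L, 2L, 3L), 2), a2 = matrix(c(1L, 2L, 2L, 3L), 2)
#' )
#' n_individuals(gt)
#' @export
genotype_table <- function(id, site, loci, a1, a2) {
  id <- as.character(id)
  site <- as.character(site)
  loci <- as.character(loci)
  a1 <- as.matrix(a1); storage.mode(a1) <- "integer"
  a2 <- as.matrix(a2); storage.mode(a2) <- "integer"
  dimnames(a1) <- dimnames(a2) <- list(id, loci)
  obj <- structure(
    list(id = id, site = site, loci = loci, a1 = a1, a2 = a2),
    class = "genotype_table"
  )
  validate_genotype_table(obj)
}

#' Validate a genotype table
#'
#' Checks the structural invariants: unique ids, one site per individual,
#' positive integer allele codes, and per-call completeness (both alleles
#' present or both missing).
#'
#' @param x a `genotype_table`.
#' @return `x`, invisibly unchanged, or an error describing the violation.
#' @export
validate_genotype_table <- function(x) {
  stopifnot(inherits(x, "genotype_table"))
  n <- length(x$id)
  L <- length(x$loci)
  if (L < 1) stop("genotype table must have at least one locus")
  if (n < 1) stop("genotype table must have at least one individual")
  if (anyDuplicated(x$id)) stop("individual ids must be unique")
  if (length(x$site) != n) stop("every individual needs exactly one site")
  if (any(is.na(x$site)) || any(!nzchar(x$site))) {
    stop("site labels must be non-empty")
  }
  if (!all(dim(x$a1) == c(n, L)) || !all(dim(x$a2) == c(n, L))) {
    stop("allele matrices must be individuals x loci")
  }
  if (any(xor(is.na(x$a1), is.na(x$a2)))) {
    stop("a locus call must have both alleles present or be wholly missing")
  }
  ok1 <- x$a1[!is.na(x$a1)]; ok2 <- x$a2[!is.na(x$a2)]
  if (any(ok1 <= 0L) || any(ok2 <= 0L)) {
    stop("allele codes must be positive integers")
  }
  x
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf(
    "<genotype_table> %d individuals, %d loci, %d sites\n",
    length(x$id), length(x$loci), length(unique(x$site))
  ))
  invisible(x)
}

#' Number of individuals / loci / per-site counts
#'
#' @param x a `genotype_table`.
#' @return `n_individuals` and `n_loci` return counts; `site_counts` returns
#'   a named integer vector of individuals per site.
#' @export
n_individuals <- function(x) length(x$id)

#' @rdname n_individuals
#' @export
n_loci <- function(x) length(x$loci)

#' @rdname n_individuals
#' @export
site_counts <- function(x) {
  tab <- table(x$site)
  stats::setNames(as.integer(tab), names(tab))
}

#' Subset a genotype table by individuals or sites
#'
#' @param x a `genotype_table`.
#' @param individuals character vector of individual ids to keep, or `NULL`.
#' @param sites character vector of site labels to keep, or `NULL`.
#' @return a `genotype_table` restricted to the selection (intersection when
#'   both are given).
#' @export
subset_genotypes <- function(x, individuals = NULL, sites = NULL) {
  keep <- rep(TRUE, length(x$id))
  if (!is.null(individuals)) {
    missing_ids <- setdiff(individuals, x$id)
    if (length(missing_ids)) {
      stop("unknown individual ids: ", paste(missing_ids, collapse = ", "))
    }
    keep <- keep & x$id %in% individuals
  }
  if (!is.null(sites)) keep <- keep & x$site %in% sites
  if (!any(keep)) stop("selection leaves no individuals")
  genotype_table(
    id = x$id[keep], site = x$site[keep], loci = x$loci,
    a1 = x$a1[keep, , drop = FALSE], a2 = x$a2[keep, , drop = FALSE]
  )
}
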