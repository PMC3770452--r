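#' Genotype count table for a biallelic locus
#'
#' Constructs the basic data object of the package: a 2x3 table of genotype
#' counts for a case group and a control group at a biallelic locus with
#' genotypes AA, AB and BB (A is the reference allele).
#'
#' @param case integer vector of length 3: counts of AA, AB, BB in the case
#'   group.
#' @param control integer vector of length 3: counts of AA, AB, BB in the
#'   control group.
#' @return An object of class `genotype_table`: a list with components
#'   `case` and `control` (named integer 3-vectors), `n` (case total) and
#'   `m` (control total). Totals are always recomputed from the counts.
#' @examples
#' gt <- genotype_table(c(55, 83, 50), c(24, 42, 39))
#' gt
#' allele_table(gt)
#' @seealso [read_genotype_table()], [allele_table()]
#' @export
genotype_table <- function(case, control) {
  case <- check_counts3(case, "case")
  control <- check_counts3(control, "control")
  n <- sum(case)
  m <- sum(control)
  if (n < 1L) stop("case row is empty (n = 0)", call. = FALSE)
  if (m < 1L) stop("control row is empty (m = 0)", call. = FALSE)
  structure(
    list(case = case, control = control, n = n, m = m),
    class = "genotype_table"
  )
}

GENO <- c("AA", "AB", "BB")

check_counts3 <- function(x, group) {
  if (length(x) != 3L || !is.numeric(x)) {
    stop(sprintf("%s counts must be a numeric vector of length 3 (AA, AB, BB)",
                 group), call. = FALSE)
  }
  if (anyNA(x)) stop(sprintf("%s counts contain NA", group), call. = FALSE)
  bad <- which(x < 0 | x != round(x))
  if (length(bad)) {
    stop(sprintf("%s count for %s is %s; counts must be non-negative integers",
                 group, GENO[bad[1L]], format(x[bad[1L]])), call. = FALSE)
  }
  stats::setNames(as.integer(round(x)), GENO)
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("Genotype counts (biallelic locus)\n")
  tab <- rbind(Case = c(x$case, Total = x$n),
               Control = c(x$control, Total = x$m))
  print(tab)
  invisible(x)
}

#' @export
as.matrix.genotype_table <- function(x, ...) {
  rbind(case = x$case, control = x$control)
}

#' Read a genotype table from a delimited file
#'
#' Reads a TSV or CSV file with a header row `Group, AA, AB, BB` (an optional
#' trailing `Total` column is accepted) and exactly two data rows, the first
#' for the case group and the second for the control group. Row totals in the
#' file are advisory only: totals are recomputed from the counts and a
#' mismatch is an error, guarding against transcription mistakes.
#'
#' @param path path to a TSV or CSV file. The delimiter is taken from the
#'   file extension (`.csv` is comma, anything else tab) unless `sep` is
#'   given.
#' @param sep optional field separator overriding the extension heuristic.
#' @return A [genotype_table()].
#' @export
read_genotype_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  names(df) <- trimws(names(df))
  need <- c("AA", "AB", "BB")
  hit <- match(tolower(need), tolower(names(df)))
  if (anyNA(hit)) {
    stop("malformed header: expected columns AA, AB, BB (got: ",
         paste(names(df), collapse = ", "), ")", call. = FALSE)
  }
  if (nrow(df) != 2L) {
    stop("expected exactly two data rows (case then control), found ",
         nrow(df), call. = FALSE)
  }
  counts <- df[, hit]
  for (j in seq_along(counts)) {
    if (!is.numeric(counts[[j]])) {
      stop(sprintf("non-numeric value '%s' in column %s",
                   format(counts[[1L, j]]), need[j]), call. = FALSE)
    }
  }
  gt <- genotype_table(as.numeric(counts[1L, ]), as.numeric(counts[2L, ]))
  tot <- match("total", tolower(names(df)))
  if (!is.na(tot) && is.numeric(df[[tot]])) {
    stated <- df[[tot]]
    if (!isTRUE(all.equal(stated, c(gt$n, gt$m)))) {
      stop(sprintf(
        "Total column (%s) disagrees with recomputed row sums (%s)",
        paste(stated, collapse = ", "),
        paste(c(gt$n, gt$m), collapse = ", ")), call. = FALSE)
    }
  }
  gt
}

#' Write a genotype table to a delimited file
#'
#' Writes the dialect accepted by [read_genotype_table()], including the
#' recomputed `Total` column, so that a write/read cycle round-trips exactly.
#'
#' @param x a [genotype_table()].
#' @param path output file path; `.csv` selects comma, otherwise tab.
#' @param sep optional separator override.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(x, path, sep = NULL) {
  stopifnot(inherits(x, "genotype_table"))
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- data.frame(Group = c("Case", "Control"),
                   AA = c(x$case[["AA"]], x$control[["AA"]]),
                   AB = c(x$case[["AB"]], x$control[["AB"]]),
                   BB = c(x$case[["BB"]], x$control[["BB"]]),
                   Total = c(x$n, x$m))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Allele count table derived from genotype counts
#'
#' Collapses a genotype table to the 2x2 allele-count table: each AA
#' individual contributes two A alleles, each heterozygote one of each, so
#' `x_A = 2 x_AA + x_AB` and `x_B = 2 x_BB + x_AB` (likewise for controls).
#' The allele table has `2n` and `2m` "observations" -- twice as many as
#' there are individuals -- which is exactly why the traditional chi-square
#' test on it is only valid under Hardy-Weinberg equilibrium.
#'
#' @param x a [genotype_table()].
#' @return An object of class `allele_table`: list with `case` and `control`
#'   (named counts of A and B alleles) and totals `two_n`, `two_m`.
#' @export
allele_table <- function(x) {
  stopifnot(inherits(x, "genotype_table"))
  ca <- c(A = unname(2L * x$case[["AA"]] + x$case[["AB"]]),
          B = unname(2L * x$case[["BB"]] + x$case[["AB"]]))
  co <- c(A = unname(2L * x$control[["AA"]] + x$control[["AB"]]),
          B = unname(2L * x$control[["BB"]] + x$control[["AB"]]))
  structure(list(case = ca, control = co,
                 two_n = 2L * x$n, two_m = 2L * x$m),
            class = "allele_table")
}

#' @export
print.allele_table <- function(x, ...) {
  cat("Allele counts (2 per individual)\n")
  print(rbind(Case = c(x$case, Total = x$two_n),
              Control = c(x$control, Total = x$two_m)))
  invisible(x)
}

#' Hypothesis descriptors
#'
#' Identifies one of the four sharp hypotheses handled by the package and
#' records the dimensions used by the chi-square reference distribution and
#' the e-value/p-value calibration: the ambient parameter dimension `d` and
#' the dimension of the null set.
#'
#' * `"genotypic"`: the two genotype frequency vectors are identical
#'   (d = 4, null dimension 2).
#' * `"allelic"`: the allele-A frequencies agree,
#'   `gamma_AA + gamma_AB/2 = Pi_AA + Pi_AB/2` (d = 4, null dimension 3).
#' * `"hwe_case"`, `"hwe_control"`: the group's genotype frequencies lie on
#'   the Hardy-Weinberg curve (p^2, 2p(1-p), (1-p)^2) in that group's own
#'   2-simplex (d = 2, null dimension 1).
#'
#' @param kind one of `"genotypic"`, `"allelic"`, `"hwe_case"`,
#'   `"hwe_control"`.
#' @return A list with `kind`, `d` and `null_dim`.
#' @export
hypothesis_spec <- function(kind = c("genotypic", "allelic",
                                     "hwe_case", "hwe_control")) {
  kind <- match.arg(kind)
  dims <- switch(kind,
    genotypic = c(d = 4L, null_dim = 2L),
    allelic = c(d = 4L, null_dim = 3L),
    hwe_case = ,
    hwe_control = c(d = 2L, null_dim = 1L))
  list(kind = kind, d = unname(dims[["d"]]),
       null_dim = unname(dims[["null_dim"]]))
}

# Validate a pair of probability 3-vectors (gamma, pi); tolerance on the
# simplex constraint is 1e-12 before renormalisation.
check_prob3 <- function(p, what) {
  if (length(p) != 3L || !is.numeric(p) || anyNA(p)) {
    stop(what, " must be a numeric probability 3-vector", call. = FALSE)
  }
  if (any(p < -1e-12) || any(p > 1 + 1e-12)) {
    stop(what, " has components outside [0, 1]", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-8) {
    stop(what, " does not sum to 1 (sum = ", format(sum(p)), ")",
         call. = FALSE)
  }
  stats::setNames(pmin(pmax(p, 0), 1), GENO)
}
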