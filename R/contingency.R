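#' Build a 2x2 contingency table from an annotated cohort
#'
#' Evaluates two logical predicates over the rows of an annotated cohort
#' and cross-tabulates them. Records for which either predicate evaluates
#' to `NA` are dropped listwise and counted in the exclusion tally, so
#' denominators reflect tumors with available data.
#'
#' @param data Data.frame (typically from [annotate_cohort()]).
#' @param row,col One-sided formulas whose right-hand sides evaluate to
#'   logical vectors in the context of `data`, e.g.
#'   `~ braf_class == "class3"`.
#' @param row_labels,col_labels Optional length-2 character labels for the
#'   TRUE/FALSE levels; defaults are derived from the formulas.
#' @return An object of class `"contingency_2x2"`: a list with `counts`
#'   (2x2 integer matrix, TRUE level first), `row_labels`, `col_labels`
#'   and `n_excluded`.
#' @examples
#' cohort <- data.frame(braf_class = c("class3", "class3", "class1"),
#'                      additional_ras = c(TRUE, FALSE, FALSE))
#' build_table(cohort, ~ braf_class == "class3", ~ additional_ras)
#' @export
build_table <- function(data, row, col, row_labels = NULL, col_labels = NULL) {
  eval_pred <- function(f) {
    stopifnot(inherits(f, "formula"), length(f) == 2)
    v <- eval(f[[2]], data, environment(f))
    if (!is.logical(v)) stop("predicate must evaluate to logical", call. = FALSE)
    rep_len(v, nrow(data))
  }
  r <- eval_pred(row)
  c_ <- eval_pred(col)
  keep <- !is.na(r) & !is.na(c_)
  n_excluded <- sum(!keep)
  r <- r[keep]
  c_ <- c_[keep]
  if (length(r) == 0) stop("no records left after exclusions", call. = FALSE)
  counts <- matrix(
    c(sum(r & c_), sum(r & !c_), sum(!r & c_), sum(!r & !c_)),
    nrow = 2, byrow = TRUE
  )
  lab <- function(f, labels) {
    if (!is.null(labels)) labels else {
      p <- deparse(f[[2]])
      c(p, paste0("!(", p, ")"))
    }
  }
  structure(
    list(counts = counts,
         row_labels = lab(row, row_labels),
         col_labels = lab(col, col_labels),
         n_excluded = n_excluded),
    class = "contingency_2x2"
  )
}

#' Construct a 2x2 contingency table from counts
#'
#' @param counts 2x2 matrix (or length-4 vector, filled by row) of
#'   non-negative integers.
#' @param row_labels,col_labels Optional length-2 character labels.
#' @return A `"contingency_2x2"` object (see [build_table()]).
#' @examples
#' contingency_table(c(13, 5, 12, 27))
#' @export
contingency_table <- function(counts, row_labels = c("row1", "row2"),
                              col_labels = c("col1", "col2")) {
  counts <- matrix(as.integer(round(counts)), nrow = 2, byrow = !is.matrix(counts))
  if (any(counts < 0) || anyNA(counts)) {
    stop("contingency counts must be non-negative integers", call. = FALSE)
  }
  structure(
    list(counts = counts, row_labels = row_labels, col_labels = col_labels,
         n_excluded = 0L),
    class = "contingency_2x2"
  )
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- x$counts
  dimnames(m) <- list(x$row_labels, x$col_labels)
  print(m)
  if (x$n_excluded > 0) {
    cat("(", x$n_excluded, " records excluded for missing data)\n", sep = "")
  }
  invisible(x)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Computes the two-sided p-value by the minimum-likelihood rule: the sum
#' of hypergeometric point probabilities, over all tables with the
#' observed margins, that do not exceed the probability of the observed
#' table (with the conventional `1 + 1e-7` relative fence against
#' floating-point ties). The sample odds ratio `(a*d)/(b*c)` is reported.
#'
#' A table with a zero margin carries no information about association;
#' by convention `p = 1` is returned with a warning.
#'
#' @param table A `"contingency_2x2"` object, 2x2 matrix, or length-4
#'   vector (filled by row).
#' @return A list of class `"fisher_exact"`: `p_two_sided`, `odds_ratio`
#'   (`Inf` when `b*c = 0` and `a*d > 0`; `NaN` when both products are 0),
#'   and `table`.
#' @examples
#' fisher_exact_2x2(c(13, 5, 12, 27))$p_two_sided  # ~0.005
#' @export
fisher_exact_2x2 <- function(table) {
  if (!inherits(table, "contingency_2x2")) table <- contingency_table(table)
  m <- table$counts
  a <- m[1, 1]; b <- m[1, 2]; c_ <- m[2, 1]; d <- m[2, 2]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; n <- r1 + r2
  if (n < 1) stop("table total must be >= 1", call. = FALSE)

  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) {
    warning("zero margin: association is undefined; returning p = 1")
    p <- 1
  } else {
    support <- max(0, c1 - r2):min(r1, c1)
    probs <- stats::dhyper(support, r1, r2, c1)
    p_obs <- stats::dhyper(a, r1, r2, c1)
    p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }
  or <- if (b * c_ > 0) (a * d) / (b * c_) else if (a * d > 0) Inf else NaN
  structure(
    list(p_two_sided = p, odds_ratio = or, table = table),
    class = "fisher_exact"
  )
}

#' @export
print.fisher_exact <- function(x, ...) {
  cat("Fisher exact test (two-sided, minimum-likelihood rule)\n")
  print(x$table)
  cat(sprintf("odds ratio = %.4g, p = %.4g\n", x$odds_ratio, x$p_two_sided))
  invisible(x)
}

pct <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)

#' Summarize an annotated cohort by BRAF class
#'
#' Produces a class-stratified clinicopathologic and molecular summary:
#' per-class tumor counts, the share of all profiled tumors and of
#' BRAF-mutant tumors, the proportion carrying an additional pathogenic
#' KRAS/NRAS/NF1 mutation, the atypical share among those, and MSI,
#' location and sex breakdowns. Percentages are computed over tumors with
#' non-missing data for each variable.
#'
#' Tumors whose only BRAF mutations are unclassified are kept in the
#' totals under their own row but excluded from class rows; a tumor with
#' BRAF mutations of more than one class is counted once under
#' `"multiple"`.
#'
#' @param cohort Data.frame from [annotate_cohort()] (or equivalent).
#' @return Data.frame of class `"cohort_summary"`, one row per BRAF class
#'   (`class1`, `class2`, `class3`, `unclassified`, `multiple`,
#'   `wild_type`) with count and percentage columns.
#' @export
cohort_summary <- function(cohort) {
  stopifnot(all(c("braf_class", "additional_ras") %in% names(cohort)))
  n_total <- nrow(cohort)
  n_braf <- sum(cohort$braf_class != "wild_type")
  levels_ <- c("class1", "class2", "class3", "unclassified", "multiple",
               "wild_type")
  rows <- lapply(levels_, function(cl) {
    g <- cohort[cohort$braf_class == cl, , drop = FALSE]
    n <- nrow(g)
    n_ras <- sum(g$additional_ras, na.rm = TRUE)
    n_atyp <- sum(g$additional_ras_atypical, na.rm = TRUE)
    msi_known <- if ("msi_status" %in% names(g)) {
      g$msi_status[!is.na(g$msi_status) & g$msi_status != "unknown"]
    } else character(0)
    loc_known <- if ("location" %in% names(g)) {
      g$location[!is.na(g$location) & g$location != "unknown"]
    } else character(0)
    sex_known <- if ("sex" %in% names(g)) g$sex[!is.na(g$sex)] else character(0)
    data.frame(
      braf_class = cl,
      n = n,
      pct_of_profiled = pct(n, n_total),
      pct_of_braf_mutant = if (cl == "wild_type") 0 else pct(n, n_braf),
      n_additional_ras = n_ras,
      pct_additional_ras = pct(n_ras, n),
      n_atypical_ras = n_atyp,
      pct_atypical_among_ras = pct(n_atyp, n_ras),
      n_msi_known = length(msi_known),
      pct_msi = pct(sum(msi_known == "MSI"), length(msi_known)),
      n_location_known = length(loc_known),
      pct_distal = pct(sum(loc_known == "distal"), length(loc_known)),
      n_sex_known = length(sex_known),
      pct_male = pct(sum(sex_known == "male"), length(sex_known)),
      mean_age = if ("age" %in% names(g)) mean(g$age, na.rm = TRUE) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_summary", "data.frame")
  out
}
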