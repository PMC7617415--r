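#' Expected variant allele frequency under the purity--copy-number model
#'
#' For a clonal mutation carried on `n_mut` of a cancer cell's alleles,
#' with `n_wt_cancer` wild-type alleles per cancer cell, two wild-type
#' alleles per contaminating normal cell and tumor purity `purity`, the
#' expected fraction of mutant reads is
#'
#' \deqn{VAF = \frac{purity \cdot N_{mut}}
#'   {purity (N_{mut} + N_{wt,can}) + 2 (1 - purity)}}
#'
#' The diploid heterozygote reduces to `VAF = purity / 2`.
#'
#' @param purity Tumor purity in (0, 1].
#' @param n_mut Mutant allele copies per cancer cell (non-negative integer).
#' @param n_wt_cancer Wild-type allele copies per cancer cell.
#' @return Expected VAF in \[0, 1\] (0 when `n_mut = 0`).
#' @examples
#' expected_vaf(1, 1, 1)    # 0.5
#' expected_vaf(0.6, 2, 1)  # 0.4615...
#' @export
expected_vaf <- function(purity, n_mut, n_wt_cancer) {
  if (any(is.na(purity)) || any(purity <= 0) || any(purity > 1)) {
    stop("purity must lie in (0, 1]", call. = FALSE)
  }
  if (any(n_mut < 0) || any(n_wt_cancer < 0)) {
    stop("allele copy numbers must be non-negative", call. = FALSE)
  }
  purity * n_mut / (purity * (n_mut + n_wt_cancer) + 2 * (1 - purity))
}

#' Solve the purity--VAF--copy-number relation for purity
#'
#' Inverts [expected_vaf()]: given an observed VAF and a putative
#' assignment of mutant and wild-type allele copy numbers, returns the
#' tumor purity the assignment would imply,
#' `purity = 2 / (n_mut/vaf - n_mut - n_wt_cancer + 2)`.
#' Substituting each allele-specific copy number as `n_mut` in turn
#' generally leaves only one assignment whose implied purity is
#' consistent with the sample's estimated purity.
#'
#' @param vaf Observed variant allele frequency in (0, 1].
#' @param n_mut,n_wt_cancer Putative mutant / wild-type allele copies per
#'   cancer cell (`n_mut >= 1`).
#' @param epsilon Slack above 1 tolerated before flagging the solution
#'   invalid (absorbs sampling noise near purity 1).
#' @return Data.frame with columns `purity` (implied purity; `NaN` when
#'   the relation has no positive solution) and `valid` (`TRUE` when the
#'   implied purity lies in (0, 1 + epsilon\]).
#' @examples
#' solve_purity(0.5, 1, 1)       # purity 1, valid
#' solve_purity(0.9, 1, 1)       # purity 1.8, flagged invalid
#' @export
solve_purity <- function(vaf, n_mut, n_wt_cancer, epsilon = 0.05) {
  n <- max(length(vaf), length(n_mut), length(n_wt_cancer))
  vaf <- rep_len(vaf, n)
  n_mut <- rep_len(n_mut, n)
  n_wt_cancer <- rep_len(n_wt_cancer, n)
  if (any(n_mut < 1)) stop("n_mut must be >= 1", call. = FALSE)
  if (any(vaf < 0 | vaf > 1, na.rm = TRUE)) {
    stop("vaf must lie in [0, 1]", call. = FALSE)
  }
  denom <- n_mut / vaf - n_mut - n_wt_cancer + 2
  p <- ifelse(vaf == 0 | denom == 0, NaN, 2 / denom)
  p[!is.na(p) & p <= 0] <- NaN
  valid <- !is.na(p) & is.finite(p) & p > 0 & p <= 1 + epsilon
  data.frame(purity = p, valid = valid)
}

#' Assign mutant and wild-type allele copy numbers
#'
#' Allele-specific copy-number callers report a segment's two allele copy
#' numbers without saying which carries the mutation. Both assignments are
#' evaluated through [solve_purity()]; the one whose implied purity falls
#' closest to the sample's estimated purity (and within `tol`) is
#' returned. When both assignments fit equally well the call is
#' `"ambiguous"`; when neither fits, `"no_fit"` (a subclonality signal).
#'
#' @param vaf Observed VAF of the mutation.
#' @param purity Sample purity estimate.
#' @param cn_a,cn_b The segment's two allele copy numbers (non-negative
#'   integers, e.g. major and minor).
#' @param tol Maximum `|implied - estimated|` purity difference accepted.
#' @param epsilon Passed to [solve_purity()].
#' @return Data.frame with columns `n_mut`, `n_wt_cancer`,
#'   `implied_purity`, `residual` (winning assignment), `residual_other`,
#'   and `status` (`"assigned"`, `"ambiguous"` or `"no_fit"`).
#' @examples
#' assign_mutant_copy_number(0.4, 0.5, 2, 1)
#' @export
assign_mutant_copy_number <- function(vaf, purity, cn_a, cn_b, tol = 0.1,
                                      epsilon = 0.05) {
  one <- function(vaf, purity, a, b) {
    cand <- data.frame(n_mut = c(a, b), n_wt = c(b, a))
    cand <- cand[cand$n_mut >= 1, , drop = FALSE]
    cand <- unique(cand)
    if (nrow(cand) == 0) {
      return(data.frame(n_mut = NA_integer_, n_wt_cancer = NA_integer_,
                        implied_purity = NA_real_, residual = NA_real_,
                        residual_other = NA_real_, status = "no_fit"))
    }
    sol <- solve_purity(vaf, cand$n_mut, cand$n_wt, epsilon = epsilon)
    res <- abs(sol$purity - purity)
    res[!sol$valid] <- Inf
    ord <- order(res)
    best <- ord[1]
    other <- if (nrow(cand) > 1) ord[2] else NA_integer_
    status <- if (!is.finite(res[best]) || res[best] > tol) {
      "no_fit"
    } else if (!is.na(other) && is.finite(res[other]) && res[other] <= tol &&
               abs(res[other] - res[best]) < 1e-9) {
      "ambiguous"
    } else {
      "assigned"
    }
    data.frame(
      n_mut = cand$n_mut[best], n_wt_cancer = cand$n_wt[best],
      implied_purity = sol$purity[best],
      residual = res[best],
      residual_other = if (is.na(other)) NA_real_ else res[other],
      status = status, stringsAsFactors = FALSE
    )
  }
  n <- max(length(vaf), length(purity), length(cn_a), length(cn_b))
  args <- data.frame(vaf = rep_len(vaf, n), purity = rep_len(purity, n),
                     a = rep_len(cn_a, n), b = rep_len(cn_b, n))
  do.call(rbind, lapply(seq_len(n), function(i) {
    one(args$vaf[i], args$purity[i], args$a[i], args$b[i])
  }))
}

#' Corrected allele fraction (cancer cell fraction scale)
#'
#' The implied fraction of tumor cells carrying the mutation: the purity
#' implied by the observed VAF under the assigned allele copy numbers,
#' divided by the sample purity, capped at `1 + epsilon`. A value of 1
#' means clonal; values well below 1 indicate subclonality. Contexts
#' whose copy-number assignment failed propagate `NA`.
#'
#' @inheritParams solve_purity
#' @param purity Sample purity estimate.
#' @return Numeric vector of corrected allele fractions (`NA` where the
#'   implied purity is not a valid solution).
#' @examples
#' corrected_allele_fraction(0.2, 0.8, 1, 1)  # ~0.5: subclonal
#' @export
corrected_allele_fraction <- function(vaf, purity, n_mut, n_wt_cancer,
                                      epsilon = 0.05) {
  sol <- solve_purity(vaf, n_mut, n_wt_cancer, epsilon = 1)  # cap applied below
  frac <- sol$purity / purity
  frac[!is.finite(frac)] <- NA_real_
  pmin(frac, 1 + epsilon)
}

#' Allele copy context for one mutation
#'
#' Bundles the quantities the clonality tests need for a single mutation:
#' read counts, sample purity and the assigned allele copy numbers.
#'
#' @param mutant_reads,total_reads Non-negative integers,
#'   `mutant_reads <= total_reads`.
#' @param purity Sample purity in (0, 1].
#' @param n_mut,n_wt_cancer Assigned allele copy numbers (`n_mut >= 1`).
#' @param id Optional mutation identifier.
#' @return A list of class `"allele_copy_context"` with the above fields
#'   plus `vaf = mutant_reads / total_reads`.
#' @export
allele_copy_context <- function(mutant_reads, total_reads, purity,
                                n_mut = 1, n_wt_cancer = 1, id = NA_character_) {
  stopifnot(length(mutant_reads) == 1, length(total_reads) == 1)
  if (is.na(total_reads) || total_reads < 1) {
    stop("total_reads must be >= 1", call. = FALSE)
  }
  if (mutant_reads < 0 || mutant_reads > total_reads) {
    stop("mutant_reads must lie in [0, total_reads]", call. = FALSE)
  }
  if (purity <= 0 || purity > 1) stop("purity must lie in (0, 1]", call. = FALSE)
  if (n_mut + n_wt_cancer < 1) {
    stop("a mutated locus needs at least one allele copy", call. = FALSE)
  }
  structure(
    list(id = id, mutant_reads = as.integer(mutant_reads),
         total_reads = as.integer(total_reads),
         vaf = mutant_reads / total_reads,
         purity = purity, n_mut = as.integer(n_mut),
         n_wt_cancer = as.integer(n_wt_cancer)),
    class = "allele_copy_context"
  )
}

#' Test whether two mutations co-occur in the same clone
#'
#' Two components, reported separately:
#'
#' 1. *Per-variant clonal consistency*: an exact binomial test of the
#'    mutant read count against the VAF expected if the mutation were
#'    clonal at the sample's purity and assigned copy numbers
#'    ([expected_vaf()]). A variant "passes" when the two-sided p-value
#'    is at least `alpha`, i.e. its counts do not differ significantly
#'    from the clonal expectation.
#' 2. *Pairwise independence*: a Pearson chi-squared test on the 2x2
#'    table of copy-number-corrected mutant and reference read counts of
#'    the two variants (mutant counts scaled to per-allele-copy units);
#'    the raw-count version is reported alongside.
#'
#' Call logic: `co_clonal` when both variants pass (1); `nested` when
#' exactly one passes and the other is significantly *below* its clonal
#' expectation; `distinct` when both fail and their corrected allele
#' fractions sum to at most 1 (compatible with disjoint subclones);
#' `ambiguous` otherwise. Because the co-clonality decision combines two
#' per-variant tests, each is compared at the Sidak-adjusted level
#' `1 - sqrt(1 - alpha)`, so the pair-level decision has size `alpha`
#' (the nominal level at which counts are tested against purity).
#'
#' @param ctx_a,ctx_b [allele_copy_context()] objects.
#' @param alpha Pair-level significance for the co-clonality decision;
#'   also the level of the pairwise chi-squared test.
#' @return A list of class `"clonality_call"`: `call`, per-variant
#'   binomial p-values (`p_binom_a`, `p_binom_b`), expected VAFs,
#'   corrected allele fractions (`ccf_a`, `ccf_b`), implied purities, and
#'   the chi-squared statistic/p-value on corrected (`chisq_stat`,
#'   `p_chisq`) and raw (`chisq_stat_raw`, `p_chisq_raw`) counts.
#' @examples
#' a <- allele_copy_context(400, 1000, purity = 0.8)
#' b <- allele_copy_context(395, 1000, purity = 0.8)
#' test_pair_clonality(a, b)$call  # "co_clonal"
#' @export
test_pair_clonality <- function(ctx_a, ctx_b, alpha = 0.05) {
  stopifnot(inherits(ctx_a, "allele_copy_context"),
            inherits(ctx_b, "allele_copy_context"))
  comp <- function(ctx) {
    ev <- expected_vaf(ctx$purity, ctx$n_mut, ctx$n_wt_cancer)
    bt <- stats::binom.test(ctx$mutant_reads, ctx$total_reads, p = ev)
    lt <- stats::binom.test(ctx$mutant_reads, ctx$total_reads, p = ev,
                            alternative = "less")
    ccf <- corrected_allele_fraction(ctx$vaf, ctx$purity, ctx$n_mut,
                                     ctx$n_wt_cancer)
    imp <- solve_purity(ctx$vaf, ctx$n_mut, ctx$n_wt_cancer)
    list(expected_vaf = ev, p = bt$p.value, p_less = lt$p.value,
         ccf = ccf, implied_purity = imp$purity)
  }
  a <- comp(ctx_a)
  b <- comp(ctx_b)

  chisq2 <- function(ma, ra, mb, rb) {
    tab <- rbind(c(ma, ra), c(mb, rb))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      return(list(statistic = NA_real_, p.value = NA_real_))
    }
    suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  }
  corr <- chisq2(round(ctx_a$mutant_reads / ctx_a$n_mut),
                 ctx_a$total_reads - ctx_a$mutant_reads,
                 round(ctx_b$mutant_reads / ctx_b$n_mut),
                 ctx_b$total_reads - ctx_b$mutant_reads)
  raw <- chisq2(ctx_a$mutant_reads, ctx_a$total_reads - ctx_a$mutant_reads,
                ctx_b$mutant_reads, ctx_b$total_reads - ctx_b$mutant_reads)

  alpha_var <- 1 - sqrt(1 - alpha)  # Sidak: pair-level size = alpha
  pass_a <- a$p >= alpha_var
  pass_b <- b$p >= alpha_var
  call <- if (pass_a && pass_b) {
    "co_clonal"
  } else if (xor(pass_a, pass_b)) {
    failed <- if (pass_a) b else a
    if (failed$p_less < alpha_var) "nested" else "ambiguous"
  } else if (!pass_a && !pass_b &&
             isTRUE(a$ccf + b$ccf <= 1)) {
    "distinct"
  } else {
    "ambiguous"
  }

  structure(
    list(ids = c(ctx_a$id, ctx_b$id), call = call,
         p_binom_a = a$p, p_binom_b = b$p,
         expected_vaf_a = a$expected_vaf, expected_vaf_b = b$expected_vaf,
         ccf_a = a$ccf, ccf_b = b$ccf,
         implied_purity_a = a$implied_purity, implied_purity_b = b$implied_purity,
         chisq_stat = unname(corr$statistic), p_chisq = corr$p.value,
         chisq_stat_raw = unname(raw$statistic), p_chisq_raw = raw$p.value,
         alpha = alpha),
    class = "clonality_call"
  )
}

#' @export
print.clonality_call <- function(x, ...) {
  cat("pair clonality call:", x$call, "\n")
  cat(sprintf("  binomial consistency p: A = %.3g, B = %.3g (alpha = %g)\n",
              x$p_binom_a, x$p_binom_b, x$alpha))
  cat(sprintf("  corrected allele fractions: A = %.3f, B = %.3f\n",
              x$ccf_a, x$ccf_b))
  cat(sprintf("  chi-squared independence (corrected counts): X2 = %.3f, p = %.3g\n",
              x$chisq_stat, x$p_chisq))
  invisible(x)
}
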