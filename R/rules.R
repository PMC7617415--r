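#' Driver classification rule tables
#'
#' Codon sets used to classify BRAF mutations into kinase-activity classes
#' 1, 2 and 3 and positional domains A, B and C, and KRAS/NRAS/NF1 variants
#' into typical vs. atypical pathogenic Ras-pathway drivers.
#'
#' Defaults: BRAF class 1 = codon 600 (V600E); class 2 = codons 464, 469,
#' 597, 601 (Ras-independent active dimers); class 3 = codons 466, 581,
#' 594, 595, 596 (kinase-impaired, Ras-dependent). Domain A = codon 600;
#' domain B = codons 581--601 excluding 600; domain C = the ATP-binding-site
#' codons 464, 466, 469. Typical KRAS = substitutions at codons 12, 13, 61;
#' atypical KRAS = codons 14, 19, 22, 33, 34, 59, 60, 68, 117, 146, 147.
#' All pathogenic NRAS substitutions (codons 12/13/61) and protein-truncating
#' NF1 mutations count as atypical Ras-pathway drivers, reflecting their low
#' frequency in colorectal cancer.
#'
#' @param config Optional path to a YAML file overriding any of the default
#'   sets (same structure as `inst/extdata/classification_rules.yaml`).
#' @return A list of class `"ras_rules"` with components `braf`
#'   (`class1`, `class2`, `class3`, `domain_A`, `domain_B`, `domain_C`),
#'   `kras` (`typical`, `atypical`), `nras` (`pathogenic`) and `nf1`
#'   (`truncating_consequences`).
#' @examples
#' r <- ras_rules()
#' r$braf$class3
#' @export
ras_rules <- function(config = NULL) {
  rules <- list(
    braf = list(
      class1 = 600L,
      class2 = c(464L, 469L, 597L, 601L),
      class3 = c(466L, 581L, 594L, 595L, 596L),
      domain_A = 600L,
      domain_B = setdiff(581:601, 600L),
      domain_C = c(464L, 466L, 469L)
    ),
    kras = list(
      typical = c(12L, 13L, 61L),
      atypical = c(14L, 19L, 22L, 33L, 34L, 59L, 60L, 68L, 117L, 146L, 147L)
    ),
    nras = list(pathogenic = c(12L, 13L, 61L)),
    # whether NF1 splice variants count as protein-truncating is not settled;
    # included by default, editable here
    nf1 = list(truncating_consequences = c("nonsense", "frameshift", "splice"))
  )
  if (!is.null(config)) {
    user <- yaml::read_yaml(config)
    for (top in names(user)) {
      if (!top %in% names(rules)) {
        stop("unknown rules section: ", top, call. = FALSE)
      }
      for (key in names(user[[top]])) {
        if (!key %in% names(rules[[top]])) {
          stop("unknown rules key: ", top, "$", key, call. = FALSE)
        }
        val <- user[[top]][[key]]
        rules[[top]][[key]] <- if (is.numeric(val)) as.integer(val) else as.character(val)
      }
    }
  }
  validate_rules(rules)
  structure(rules, class = "ras_rules")
}

validate_rules <- function(rules) {
  cls <- rules$braf[c("class1", "class2", "class3")]
  if (any(duplicated(unlist(cls)))) {
    stop("BRAF class codon sets must be pairwise disjoint", call. = FALSE)
  }
  dom <- rules$braf[c("domain_A", "domain_B", "domain_C")]
  if (any(duplicated(unlist(dom)))) {
    stop("BRAF domain codon sets must be pairwise disjoint", call. = FALSE)
  }
  if (length(intersect(rules$kras$typical, rules$kras$atypical)) > 0) {
    stop("KRAS typical and atypical codon sets must be disjoint", call. = FALSE)
  }
  invisible(rules)
}
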