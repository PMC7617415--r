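#' Classify BRAF mutations into kinase-activity classes 1/2/3
#'
#' Missense substitutions at the listed hotspot codons are assigned their
#' class; missense changes at any other codon, and all non-missense
#' consequences, are `"unclassified"` and treated as presumed passengers in
#' class-based analyses.
#'
#' @param codon Integer vector of affected codons.
#' @param consequence Character vector of consequences
#'   (`missense`, `nonsense`, `frameshift`, `splice`, `synonymous`, `other`).
#' @param rules A [ras_rules()] object.
#' @return Character vector: `"class1"`, `"class2"`, `"class3"` or
#'   `"unclassified"`.
#' @examples
#' classify_braf(c(600, 594, 469, 250), rep("missense", 4))
#' @export
classify_braf <- function(codon, consequence = "missense", rules = ras_rules()) {
  codon <- as.integer(codon)
  consequence <- rep_len(as.character(consequence), length(codon))
  out <- rep("unclassified", length(codon))
  miss <- !is.na(consequence) & consequence == "missense" & !is.na(codon)
  out[miss & codon %in% rules$braf$class1] <- "class1"
  out[miss & codon %in% rules$braf$class2] <- "class2"
  out[miss & codon %in% rules$braf$class3] <- "class3"
  out
}

#' Classify BRAF missense mutations into positional domains A/B/C
#'
#' A simpler, positional alternative to the 1-2-3 functional scheme:
#' A = codon 600; B = codons flanking 600 (581--601, excluding 600);
#' C = the ATP-binding-site codons (464, 466, 469). Everything else is
#' `"unassigned"`.
#'
#' @inheritParams classify_braf
#' @return Character vector: `"A"`, `"B"`, `"C"` or `"unassigned"`.
#' @examples
#' classify_braf_domain(c(600, 594, 466))
#' @export
classify_braf_domain <- function(codon, consequence = "missense",
                                 rules = ras_rules()) {
  codon <- as.integer(codon)
  consequence <- rep_len(as.character(consequence), length(codon))
  out <- rep("unassigned", length(codon))
  miss <- !is.na(consequence) & consequence == "missense" & !is.na(codon)
  out[miss & codon %in% rules$braf$domain_A] <- "A"
  out[miss & codon %in% rules$braf$domain_B] <- "B"
  out[miss & codon %in% rules$braf$domain_C] <- "C"
  out
}

#' Classify KRAS/NRAS/NF1 variants as typical or atypical Ras drivers
#'
#' KRAS substitutions at the canonical hotspots (codons 12/13/61) are
#' `"kras_typical"`; KRAS substitutions at the prespecified non-hotspot
#' pathogenic codons, all pathogenic NRAS substitutions (codons 12/13/61)
#' and protein-truncating NF1 mutations are `"atypical_ras"`. Everything
#' else (including synonymous changes and NF1 missense) is `"non_driver"`.
#'
#' @param gene Character vector of gene symbols (case-insensitive); must be
#'   KRAS, NRAS or NF1.
#' @inheritParams classify_braf
#' @return Character vector: `"kras_typical"`, `"atypical_ras"` or
#'   `"non_driver"`.
#' @examples
#' classify_ras_pathway(c("KRAS", "KRAS", "NRAS", "NF1"),
#'                      c(12, 19, 12, 1000),
#'                      c("missense", "missense", "missense", "nonsense"))
#' @export
classify_ras_pathway <- function(gene, codon, consequence = "missense",
                                 rules = ras_rules()) {
  gene <- toupper(as.character(gene))
  if (!all(gene %in% c("KRAS", "NRAS", "NF1"))) {
    stop("classify_ras_pathway() handles KRAS, NRAS and NF1 only; got: ",
         paste(unique(setdiff(gene, c("KRAS", "NRAS", "NF1"))), collapse = ", "),
         call. = FALSE)
  }
  codon <- as.integer(rep_len(codon, length(gene)))
  consequence <- rep_len(as.character(consequence), length(gene))
  out <- rep("non_driver", length(gene))
  miss <- !is.na(consequence) & consequence == "missense" & !is.na(codon)
  out[gene == "KRAS" & miss & codon %in% rules$kras$typical] <- "kras_typical"
  out[gene == "KRAS" & miss & codon %in% rules$kras$atypical] <- "atypical_ras"
  out[gene == "NRAS" & miss & codon %in% rules$nras$pathogenic] <- "atypical_ras"
  out[gene == "NF1" & consequence %in% rules$nf1$truncating_consequences] <-
    "atypical_ras"
  out
}

# derive codon/consequence columns for a mutation table, parsing the
# protein change where they are absent
complete_variants <- function(variants) {
  required <- c("sample_id", "gene", "protein_change")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols)) {
    stop("mutation table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  need <- !all(c("codon", "consequence") %in% names(variants)) ||
    anyNA(variants$codon) || anyNA(variants$consequence)
  if (need) {
    parsed <- parse_protein_change(variants$protein_change)
    if (!"codon" %in% names(variants)) variants$codon <- parsed$codon
    if (!"consequence" %in% names(variants)) {
      variants$consequence <- parsed$consequence
    }
    fill <- is.na(variants$codon)
    variants$codon[fill] <- parsed$codon[fill]
    fill <- is.na(variants$consequence)
    variants$consequence[fill] <- parsed$consequence[fill]
  }
  variants$gene <- toupper(variants$gene)
  variants
}

#' Roll variant calls up to a per-tumor annotation
#'
#' Aggregates one sample's variant calls into a single tumor record:
#' the BRAF class (with the full multi-class list retained when a tumor
#' carries mutations of more than one class), the positional domain, and
#' flags for additional pathogenic Ras-pathway mutations and whether any
#' of them is atypical.
#'
#' Tumors carrying BRAF mutations of two or more distinct classes are
#' labelled `"multiple"` so that single-label summaries can exclude them
#' from per-class denominators without double counting.
#'
#' @param variants Data.frame of one sample's mutations with columns
#'   `sample_id`, `gene`, `protein_change` (optional `codon`,
#'   `consequence`).
#' @param clinical Optional one-row data.frame (or list) with any of
#'   `msi_status`, `location`, `age`, `sex`, `stage`.
#' @param rules A [ras_rules()] object.
#' @return One-row data.frame with columns `sample_id`, `braf_class`,
#'   `braf_classes` (comma-separated multi-class list), `braf_domain`,
#'   `additional_ras`, `additional_ras_atypical`, `msi_status`, `location`,
#'   `age`, `sex`, `stage`.
#' @examples
#' v <- data.frame(sample_id = "t1",
#'                 gene = c("BRAF", "KRAS"),
#'                 protein_change = c("G466V", "L19F"))
#' annotate_tumor(v)
#' @export
annotate_tumor <- function(variants, clinical = NULL, rules = ras_rules()) {
  variants <- complete_variants(variants)
  sid <- unique(variants$sample_id)
  if (length(sid) != 1) {
    stop("annotate_tumor() expects variants from a single sample; got: ",
         paste(sid, collapse = ", "), call. = FALSE)
  }

  is_braf <- variants$gene == "BRAF"
  braf_cls <- classify_braf(variants$codon[is_braf],
                            variants$consequence[is_braf], rules)
  braf_dom <- classify_braf_domain(variants$codon[is_braf],
                                   variants$consequence[is_braf], rules)
  classes <- sort(unique(braf_cls[braf_cls != "unclassified"]))
  braf_class <- if (!any(is_braf)) {
    "wild_type"
  } else if (length(classes) == 0) {
    "unclassified"
  } else if (length(classes) > 1) {
    "multiple"
  } else {
    classes
  }
  doms <- unique(braf_dom[braf_dom != "unassigned"])
  braf_domain <- if (length(doms) == 1) doms else
    if (length(doms) > 1) "multiple" else "unassigned"

  is_ras <- variants$gene %in% c("KRAS", "NRAS", "NF1")
  ras_cls <- if (any(is_ras)) {
    classify_ras_pathway(variants$gene[is_ras], variants$codon[is_ras],
                         variants$consequence[is_ras], rules)
  } else {
    character(0)
  }
  additional_ras <- any(ras_cls %in% c("kras_typical", "atypical_ras"))
  additional_ras_atypical <- any(ras_cls == "atypical_ras")

  clin <- function(field, default = NA) {
    if (!is.null(clinical) && field %in% names(clinical)) {
      clinical[[field]][1]
    } else {
      default
    }
  }
  data.frame(
    sample_id = sid,
    braf_class = braf_class,
    braf_classes = paste(classes, collapse = ","),
    braf_domain = braf_domain,
    additional_ras = additional_ras,
    additional_ras_atypical = additional_ras_atypical,
    msi_status = as.character(clin("msi_status")),
    location = as.character(clin("location")),
    age = as.numeric(clin("age")),
    sex = as.character(clin("sex")),
    stage = as.character(clin("stage")),
    stringsAsFactors = FALSE
  )
}

#' Annotate a whole cohort of tumors
#'
#' Applies [annotate_tumor()] to every sample in a mutation table, joining
#' clinical fields by `sample_id`. Samples present only in the clinical
#' table (no somatic mutation in the profiled genes) are included as BRAF
#' wild-type records, so cohort-level denominators cover all profiled
#' tumors.
#'
#' @param mutations Data.frame with columns `sample_id`, `gene`,
#'   `protein_change` (optional `codon`, `consequence`).
#' @param clinical Optional data.frame keyed by `sample_id` with any of
#'   `msi_status`, `location`, `age`, `sex`, `stage`.
#' @param rules A [ras_rules()] object.
#' @return Data.frame with one row per tumor (see [annotate_tumor()]).
#' @export
annotate_cohort <- function(mutations, clinical = NULL, rules = ras_rules()) {
  mutations <- complete_variants(mutations)
  ids <- unique(c(mutations$sample_id,
                  if (!is.null(clinical)) clinical$sample_id))
  rows <- lapply(ids, function(sid) {
    v <- mutations[mutations$sample_id == sid, , drop = FALSE]
    cl <- if (!is.null(clinical)) {
      clinical[clinical$sample_id == sid, , drop = FALSE]
    }
    if (nrow(v) == 0) {
      v <- data.frame(sample_id = sid, gene = "NONE",
                      protein_change = "A1A", codon = 1L,
                      consequence = "synonymous",
                      stringsAsFactors = FALSE)
    }
    annotate_tumor(v, clinical = cl, rules = rules)
  })
  do.call(rbind, rows)
}
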