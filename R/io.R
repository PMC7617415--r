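# TSV interchange: every stage reads and writes plain tab-separated text
# with a header, so intermediate results stay inspectable.

read_tsv_checked <- function(path, required, optional = character(0)) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("file '", path, "' lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read a MAF-like somatic mutation table
#'
#' @param path TSV with required columns `sample_id`, `gene`,
#'   `protein_change` and optional `codon`, `consequence`, `context`,
#'   `ref`, `alt`, `mutant_reads`, `total_reads`.
#' @return Data.frame.
#' @export
read_mutation_table <- function(path) {
  read_tsv_checked(path, c("sample_id", "gene", "protein_change"))
}

#' Read a per-sample clinical table
#'
#' @param path TSV with required column `sample_id` and any of
#'   `msi_status`, `location`, `age`, `sex`, `stage`.
#' @return Data.frame.
#' @export
read_clinical_table <- function(path) {
  read_tsv_checked(path, "sample_id")
}

#' Read per-mutation read counts
#'
#' @param path TSV with columns `sample_id`, `mutation_id`,
#'   `mutant_reads`, `total_reads`.
#' @return Data.frame.
#' @export
read_reads_table <- function(path) {
  read_tsv_checked(path, c("sample_id", "mutation_id", "mutant_reads",
                           "total_reads"))
}

#' Read per-sample purity estimates
#'
#' @param path TSV with columns `sample_id`, `purity`.
#' @return Data.frame.
#' @export
read_purity_table <- function(path) {
  read_tsv_checked(path, c("sample_id", "purity"))
}

#' Read allele-specific copy-number segments
#'
#' @param path TSV with columns `sample_id`, `chromosome`, `start`, `end`
#'   (half-open, 0-based), `major_cn`, `minor_cn`.
#' @return Data.frame.
#' @export
read_cn_segments <- function(path) {
  read_tsv_checked(path, c("sample_id", "chromosome", "start", "end",
                           "major_cn", "minor_cn"))
}

#' Look up the copy-number segment covering each mutation
#'
#' Joins mutations to allele-specific copy-number segments by sample,
#' chromosome and position, treating segments as half-open 0-based
#' intervals `[start, end)`.
#'
#' @param mutations Data.frame with columns `sample_id`, `chromosome`,
#'   `position` (1-based coordinate of the mutated base).
#' @param segments Data.frame as read by [read_cn_segments()].
#' @return `mutations` with `major_cn`, `minor_cn` columns appended
#'   (`NA` where no segment covers the site).
#' @export
join_cn_segments <- function(mutations, segments) {
  stopifnot(all(c("sample_id", "chromosome", "position") %in% names(mutations)),
            all(c("sample_id", "chromosome", "start", "end", "major_cn",
                  "minor_cn") %in% names(segments)))
  mutations$major_cn <- NA_integer_
  mutations$minor_cn <- NA_integer_
  key <- paste(segments$sample_id, segments$chromosome)
  mkey <- paste(mutations$sample_id, mutations$chromosome)
  for (k in unique(mkey)) {
    seg <- segments[key == k, , drop = FALSE]
    if (nrow(seg) == 0) next
    seg <- seg[order(seg$start), , drop = FALSE]
    idx <- which(mkey == k)
    pos0 <- mutations$position[idx] - 1L  # to 0-based
    hit <- findInterval(pos0, seg$start)
    ok <- hit >= 1 & pos0 < seg$end[pmax(hit, 1)]
    mutations$major_cn[idx[ok]] <- seg$major_cn[hit[ok]]
    mutations$minor_cn[idx[ok]] <- seg$minor_cn[hit[ok]]
  }
  mutations
}

#' Read a mutation catalog for spectrum building
#'
#' @param path TSV with columns `sample_id`, `context`, `ref`, `alt`.
#' @return Data.frame.
#' @export
read_catalog <- function(path) {
  read_tsv_checked(path, c("sample_id", "context", "ref", "alt"))
}

#' Read somatic mutations from a VCF
#'
#' Optional VCF ingest (requires the `vcfR` package): extracts one record
#' per variant with the protein change taken from a named INFO field
#' (e.g. an annotation like `PCHANGE=V600E`) and the gene from another.
#'
#' @param path VCF 4.x file.
#' @param protein_change_field Name of the INFO field holding the HGVS p.
#'   short form.
#' @param gene_field Name of the INFO field holding the gene symbol.
#' @param sample_id Sample identifier to assign to all records.
#' @return Data.frame with columns `sample_id`, `gene`, `protein_change`.
#' @export
read_vcf_mutations <- function(path, protein_change_field = "PCHANGE",
                               gene_field = "GENE", sample_id = "sample1") {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("VCF ingest requires the 'vcfR' package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gene <- vcfR::extract.info(v, gene_field)
  pc <- vcfR::extract.info(v, protein_change_field)
  keep <- !is.na(gene) & !is.na(pc)
  data.frame(sample_id = sample_id, gene = gene[keep],
             protein_change = pc[keep], stringsAsFactors = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
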