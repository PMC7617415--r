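AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His", "Ile",
         "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp", "Tyr", "Val")

# normalize a 3-letter amino-acid token (or Ter) to 1-letter; NA if unknown
aa3_to_1 <- function(x) {
  x <- paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, 3)))
  out <- AA1[match(x, AA3)]
  out[x == "Ter"] <- "*"
  out
}

#' Parse an HGVS p. short-form protein change
#'
#' Accepts one-letter short forms (`"V600E"`, `"Q61*"`, `"K117fs"`) and
#' three-letter forms (`"Val600Glu"`, `"Gln61Ter"`), with or without a
#' leading `"p."`. The consequence is derived from the alternate token:
#' a different amino acid gives `missense`, the same amino acid
#' `synonymous`, `*`/`Ter` `nonsense`, and an `fs` suffix `frameshift`.
#'
#' @param protein_change Character vector of protein changes.
#' @return A data.frame with columns `protein_change`, `codon` (integer),
#'   `ref_aa`, `alt_aa` (one-letter; `"*"` for a stop, `NA` for frameshift)
#'   and `consequence`.
#' @examples
#' parse_protein_change(c("V600E", "p.Asp594Gly", "Q61*", "K117fs"))
#' @export
parse_protein_change <- function(protein_change) {
  stopifnot(is.character(protein_change), length(protein_change) > 0)
  x <- sub("^p\\.", "", trimws(protein_change))
  x <- sub("^\\((.*)\\)$", "\\1", x)

  n <- length(x)
  ref <- alt <- rep(NA_character_, n)
  codon <- rep(NA_integer_, n)
  cons <- rep(NA_character_, n)

  # three-letter to one-letter normalization first
  m3 <- regexec("^([A-Za-z]{3})([0-9]+)([A-Za-z]{3}|\\*)(fs.*)?$", x)
  r3 <- regmatches(x, m3)
  # one-letter form
  m1 <- regexec("^([A-Z])([0-9]+)(\\*|[A-Z])?(fs.*|=)?$", x)
  r1 <- regmatches(x, m1)

  for (i in seq_len(n)) {
    p <- r1[[i]]
    if (length(p)) {
      ref[i] <- p[2]
      codon[i] <- as.integer(p[3])
      alt[i] <- if (nzchar(p[4])) p[4] else NA_character_
      if (nzchar(p[5]) && startsWith(p[5], "fs")) {
        cons[i] <- "frameshift"
        alt[i] <- NA_character_
      } else if (identical(p[5], "=")) {
        cons[i] <- "synonymous"
        alt[i] <- ref[i]
      }
    } else {
      p <- r3[[i]]
      if (length(p)) {
        ref[i] <- aa3_to_1(p[2])
        codon[i] <- as.integer(p[3])
        alt[i] <- if (identical(p[4], "*")) "*" else aa3_to_1(p[4])
        if (nzchar(p[5])) {
          cons[i] <- "frameshift"
          alt[i] <- NA_character_
        }
      }
    }
    if (is.na(cons[i])) {
      if (is.na(ref[i]) || is.na(codon[i])) {
        # fall through to the validity check below
      } else if (is.na(alt[i])) {
        cons[i] <- NA_character_
      } else if (alt[i] == "*") {
        cons[i] <- "nonsense"
      } else if (alt[i] == ref[i]) {
        cons[i] <- "synonymous"
      } else {
        cons[i] <- "missense"
      }
    }
    bad <- is.na(ref[i]) || is.na(codon[i]) ||
      !(ref[i] %in% c(AA1, "*")) ||
      (!is.na(alt[i]) && !(alt[i] %in% c(AA1, "*"))) ||
      is.na(cons[i])
    if (bad) {
      stop("cannot parse protein change: '", protein_change[i], "'",
           call. = FALSE)
    }
  }

  data.frame(
    protein_change = protein_change,
    codon = codon,
    ref_aa = ref,
    alt_aa = alt,
    consequence = cons,
    stringsAsFactors = FALSE
  )
}
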