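BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

revcomp3 <- function(ctx) {
  vapply(strsplit(ctx, ""), function(b) {
    paste(rev(unname(COMPLEMENT[b])), collapse = "")
  }, character(1))
}

#' The 96 single-base-substitution channels
#'
#' Canonical channel labels in the conventional order: substitution types
#' C>A, C>G, C>T, T>A, T>C, T>G (pyrimidine strand), each expanded over
#' the 16 flanking-base combinations with the left flank varying slowest.
#'
#' @return Character vector of 96 labels of the form `"A[C>A]A"`.
#' @export
sbs_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- character(0)
  for (s in subs) {
    ref <- substr(s, 1, 1)
    for (l in BASES) {
      for (r in BASES) {
        out <- c(out, paste0(l, "[", s, "]", r))
      }
    }
  }
  out
}

#' Collapse a mutation to its pyrimidine-strand channel
#'
#' Single-base substitutions are reported from the pyrimidine strand: when
#' the reference base is a purine, the trinucleotide context is
#' reverse-complemented and the reference/alternate bases complemented
#' before labeling, so a mutation and its reverse-strand representation
#' map to the same channel.
#'
#' @param context Character vector of 3-mers on the reference strand with
#'   the mutated base central.
#' @param ref,alt Single reference/alternate bases on the reference strand.
#' @return Character vector of channel labels (see [sbs_channels()]).
#' @examples
#' collapse_to_pyrimidine("GTG", "T", "A")  # "G[T>A]G"
#' collapse_to_pyrimidine("CAC", "A", "T")  # same channel, other strand
#' @export
collapse_to_pyrimidine <- function(context, ref, alt) {
  n <- max(length(context), length(ref), length(alt))
  context <- toupper(rep_len(context, n))
  ref <- toupper(rep_len(ref, n))
  alt <- toupper(rep_len(alt, n))
  ok <- nchar(context) == 3 &
    !grepl("[^ACGT]", context) &
    ref %in% BASES & alt %in% BASES &
    substr(context, 2, 2) == ref & ref != alt
  if (!all(ok)) {
    bad <- which(!ok)[1]
    stop("malformed mutation: context='", context[bad], "' ref='", ref[bad],
         "' alt='", alt[bad], "'", call. = FALSE)
  }
  pur <- ref %in% c("A", "G")
  context[pur] <- revcomp3(context[pur])
  ref[pur] <- unname(COMPLEMENT[ref[pur]])
  alt[pur] <- unname(COMPLEMENT[alt[pur]])
  paste0(substr(context, 1, 1), "[", ref, ">", alt, "]",
         substr(context, 3, 3))
}

#' Build normalized 96-channel mutation spectra
#'
#' Tabulates a catalog of single-base substitutions into per-sample raw
#' channel counts and normalizes each sample's counts to proportional
#' activity (weights summing to one), allowing comparison between samples
#' with different mutation burdens.
#'
#' @param catalog Data.frame with columns `sample_id`, `context`, `ref`,
#'   `alt` (reference-strand representation; strand collapse is applied).
#' @return A list of class `"spectrum_profiles"` with `counts` and
#'   `weights` (samples x 96 matrices, columns in [sbs_channels()] order)
#'   and `empty` (logical vector flagging samples with zero mutations).
#' @export
build_spectrum <- function(catalog) {
  required <- c("sample_id", "context", "ref", "alt")
  if (!all(required %in% names(catalog))) {
    stop("catalog lacks column(s): ",
         paste(setdiff(required, names(catalog)), collapse = ", "),
         call. = FALSE)
  }
  channels <- sbs_channels()
  samples <- unique(as.character(catalog$sample_id))
  counts <- matrix(0L, nrow = length(samples), ncol = 96,
                   dimnames = list(samples, channels))
  if (nrow(catalog) > 0) {
    ch <- collapse_to_pyrimidine(catalog$context, catalog$ref, catalog$alt)
    tab <- table(factor(as.character(catalog$sample_id), levels = samples),
                 factor(ch, levels = channels))
    counts[] <- as.integer(tab)
  }
  totals <- rowSums(counts)
  weights <- counts / ifelse(totals > 0, totals, 1)
  empty <- totals == 0
  if (any(empty)) {
    warning("sample(s) with empty catalog produce a zero profile: ",
            paste(samples[empty], collapse = ", "))
  }
  structure(list(counts = counts, weights = weights, empty = empty),
            class = "spectrum_profiles")
}

#' Proportion of a sample's mutations in a causal channel set
#'
#' The causal-channel proportion of a sample is the summed normalized
#' weight over the channels capable of generating a given driver
#' substitution — e.g. `G[T>A]G` for the class 1 (V600E) change. It is
#' additive over disjoint channel sets and equals 1 over all 96 channels.
#'
#' @param spectra A `"spectrum_profiles"` object from [build_spectrum()].
#' @param channels Character vector of channel labels (a causal set; see
#'   [braf_causal_channels()]).
#' @return Named numeric vector, one proportion in \[0, 1\] per sample.
#' @export
causal_channel_proportion <- function(spectra, channels) {
  stopifnot(inherits(spectra, "spectrum_profiles"))
  unknown <- setdiff(channels, sbs_channels())
  if (length(unknown)) {
    stop("unknown channel label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  rowSums(spectra$weights[, unique(channels), drop = FALSE])
}

#' Causal trinucleotide channels for BRAF mutation classes
#'
#' Returns the channel set whose mutations generate the BRAF driver
#' substitutions of a class: the single class 1 channel `G[T>A]G`
#' (the V600E change, GTG>GAG on the coding strand), or the 16 channels
#' generating the prespecified class 2 and 3 substitutions. The mapping
#' from coding change to pyrimidine-strand channel ships as an editable
#' audit table (`inst/extdata/braf_causal_channels.tsv`), derived from the
#' BRAF coding-strand trinucleotide context of each substitution.
#'
#' @param set `"class1"`, `"class2_3"`, or the path to a custom TSV with a
#'   `channel` column (and optionally a `class` column filtered by
#'   `label`).
#' @param label Optional value of the `class` column to filter a custom
#'   table by.
#' @return Character vector of channel labels.
#' @examples
#' braf_causal_channels("class1")         # "G[T>A]G"
#' length(braf_causal_channels("class2_3"))  # 16
#' @export
braf_causal_channels <- function(set = c("class1", "class2_3"), label = NULL) {
  if (file.exists(set[1])) {
    tab <- utils::read.delim(set[1], stringsAsFactors = FALSE)
  } else {
    set <- match.arg(set)
    tab <- braf_channel_table()
    label <- switch(set, class1 = "class1", class2_3 = c("class2", "class3"))
  }
  if (!"channel" %in% names(tab)) {
    stop("channel table needs a 'channel' column", call. = FALSE)
  }
  if (!is.null(label) && "class" %in% names(tab)) {
    tab <- tab[tab$class %in% label, , drop = FALSE]
  }
  sort(unique(tab$channel))
}

#' Audit table mapping BRAF driver substitutions to channels
#'
#' One row per prespecified BRAF driver substitution, with its class, the
#' coding-strand trinucleotide context around the mutated base, the
#' coding-strand base change, and the pyrimidine-collapsed channel
#' (recomputed from the context at load time, so edits stay consistent).
#'
#' @return Data.frame with columns `class`, `protein_change`,
#'   `coding_context`, `coding_ref`, `coding_alt`, `channel`.
#' @export
braf_channel_table <- function() {
  path <- system.file("extdata", "braf_causal_channels.tsv", package = "rasco")
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  recomputed <- collapse_to_pyrimidine(tab$coding_context, tab$coding_ref,
                                       tab$coding_alt)
  if (!identical(recomputed, tab$channel)) {
    stop("braf_causal_channels.tsv channels are inconsistent with contexts",
         call. = FALSE)
  }
  tab
}

#' Logistic model of driver presence on causal-channel activity
#'
#' Fits, by maximum likelihood, a logistic regression of the presence of
#' a BRAF mutation on the sample's causal-channel proportion, adjusting
#' for tumor location (distal = 1), MSI status (MSS = 1), age at
#' diagnosis and sex (male = 1). Complete separation is detected and
#' flagged rather than silently reported.
#'
#' @param data Data.frame with columns `presence` (0/1), `channel_proportion`,
#'   `location` (`"proximal"`/`"distal"`), `msi` (`"MSI"`/`"MSS"`), `age`,
#'   `sex` (`"female"`/`"male"`). Already-numeric covariates are used as is.
#' @return A list of class `"presence_fit"`: `coefficients` (data.frame
#'   with `estimate`, `se`, `z`, `p` per term), `separation` (logical),
#'   `model` (the underlying `glm` object), and `coding` describing the
#'   covariate coding.
#' @export
fit_presence_logistic <- function(data) {
  required <- c("presence", "channel_proportion", "location", "msi", "age", "sex")
  if (!all(required %in% names(data))) {
    stop("data lacks column(s): ",
         paste(setdiff(required, names(data)), collapse = ", "), call. = FALSE)
  }
  y <- as.numeric(data$presence)
  if (!all(y %in% c(0, 1))) stop("presence must be 0/1", call. = FALSE)
  if (sum(y) == 0 || sum(y) == length(y)) {
    stop("need at least one case and one control", call. = FALSE)
  }
  num <- function(x, one) if (is.numeric(x)) x else as.numeric(x == one)
  df <- data.frame(
    presence = y,
    channel_proportion = data$channel_proportion,
    location_distal = num(data$location, "distal"),
    mss = num(data$msi, "MSS"),
    age = data$age,
    sex_male = num(data$sex, "male")
  )
  fit <- stats::glm(presence ~ channel_proportion + location_distal + mss +
                      age + sex_male,
                    family = stats::binomial(), data = df)
  eps <- 1e-8
  mu <- stats::fitted(fit)
  separation <- !fit$converged || any(mu < eps | mu > 1 - eps)
  if (separation) {
    warning("possible complete separation: estimates may be unstable")
  }
  sm <- summary(fit)$coefficients
  coefs <- data.frame(
    term = rownames(sm),
    estimate = sm[, 1], se = sm[, 2], z = sm[, 3], p = sm[, 4],
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(coefficients = coefs, separation = separation, model = fit,
         coding = c(location = "distal = 1", msi = "MSS = 1", sex = "male = 1")),
    class = "presence_fit"
  )
}

#' @export
print.presence_fit <- function(x, ...) {
  cat("logistic model of mutation presence on channel activity\n")
  cat("covariate coding:", paste(names(x$coding), x$coding, sep = ": ",
                                 collapse = "; "), "\n")
  if (x$separation) cat("WARNING: possible complete separation\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}
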