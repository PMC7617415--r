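#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the class-stratified structure of the combined
#' 6,605-tumor colorectal cancer dataset: per-class cohort frequencies
#' (class 1 10.7%, class 2 0.47%, class 3 1.22%; the remainder BRAF
#' wild-type), per-class probabilities of an additional pathogenic
#' KRAS/NRAS/NF1 mutation (2.4% / 29% / 45.7%; wild-type 53.2%), the
#' atypical fraction among those, per-class MSI probability (class 2/3
#' tumors are microsatellite stable) and distal-location probability.
#' Variant spellings are drawn from pools of observed driver mutations.
#'
#' @param class_freq Named numeric: cohort frequency of each BRAF class.
#' @param p_additional_ras Named numeric: probability of an additional
#'   Ras-pathway driver, per class (including `wild_type`).
#' @param p_atypical_given_ras Named numeric: atypical fraction among
#'   additional Ras drivers, per class.
#' @param p_msi Named numeric: MSI probability per class.
#' @param p_distal Named numeric: distal-location probability per class.
#' @param age_mean,age_sd Normal age distribution (years).
#' @param p_male Probability of male sex.
#' @param stage_probs Named numeric over stages I--IV (summing to 1).
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(
    class_freq = c(class1 = 0.107, class2 = 0.0047, class3 = 0.0122),
    p_additional_ras = c(class1 = 0.024, class2 = 0.29, class3 = 0.457,
                         wild_type = 0.532),
    p_atypical_given_ras = c(class1 = 0.765, class2 = 0.556, class3 = 0.784,
                             wild_type = 0.192),
    p_msi = c(class1 = 0.524, class2 = 0, class3 = 0, wild_type = 0.395),
    p_distal = c(class1 = 0.163, class2 = 0.625, class3 = 0.561,
                 wild_type = 0.657),
    age_mean = 68, age_sd = 10, p_male = 0.55,
    stage_probs = c(I = 0.17, II = 0.31, III = 0.36, IV = 0.16)) {
  probs <- c(class_freq, p_additional_ras, p_atypical_given_ras, p_msi,
             p_distal, p_male, stage_probs)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (sum(class_freq) > 1) {
    stop("class frequencies must sum to at most 1", call. = FALSE)
  }
  if (abs(sum(stage_probs) - 1) > 1e-8) {
    stop("stage probabilities must sum to 1", call. = FALSE)
  }
  structure(
    list(class_freq = class_freq, p_additional_ras = p_additional_ras,
         p_atypical_given_ras = p_atypical_given_ras, p_msi = p_msi,
         p_distal = p_distal, age_mean = age_mean, age_sd = age_sd,
         p_male = p_male, stage_probs = stage_probs),
    class = "cohort_config"
  )
}

# observed driver spellings per category; NF1 truncating spellings are
# synthetic placeholders (nonsense/frameshift)
VARIANT_POOLS <- list(
  braf_class1 = "V600E",
  braf_class2 = c("G469V", "K601E", "L597V"),
  braf_class3 = c("D594G", "G466V", "G596R"),
  kras_typical = c("G12D", "G13D", "Q61H"),
  kras_atypical = c("L19F", "A146T", "V14I", "V14L", "D33E", "P34L",
                    "G60D", "K117Q", "A146V", "A59T"),
  nras = c("G12D", "G12V"),
  nf1_truncating = c("R100*", "Q200*", "K300fs")
)

#' Generate a synthetic annotated cohort
#'
#' Draws, per tumor: a BRAF status/class, a concrete BRAF protein change,
#' additional Ras-pathway variants (typical KRAS vs. atypical KRAS/NRAS/
#' NF1), MSI status, location, age, sex and stage. The output is a
#' mutation table and a clinical table in the exact dialects the
#' annotation stage reads, so the full pipeline can run end to end on
#' synthetic data. Deterministic given the seed.
#'
#' @param n_tumors Number of tumors.
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return List with `mutations` (`sample_id`, `gene`, `protein_change`),
#'   `clinical` (`sample_id`, `msi_status`, `location`, `age`, `sex`,
#'   `stage`) and `truth` (`sample_id`, `braf_class`, `additional_ras`,
#'   `additional_ras_atypical`).
#' @export
simulate_cohort <- function(n_tumors, config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"), n_tumors >= 1)
  set.seed(seed)
  classes <- c(names(config$class_freq), "wild_type")
  p <- c(config$class_freq, wild_type = 1 - sum(config$class_freq))
  cls <- sample(classes, n_tumors, replace = TRUE, prob = p)
  sid <- sprintf("sim_%06d", seq_len(n_tumors))

  add_ras <- stats::rbinom(n_tumors, 1, config$p_additional_ras[cls]) == 1
  atyp <- add_ras &
    stats::rbinom(n_tumors, 1, config$p_atypical_given_ras[cls]) == 1

  mut_rows <- vector("list", n_tumors)
  for (i in seq_len(n_tumors)) {
    rows <- NULL
    if (cls[i] != "wild_type") {
      pool <- VARIANT_POOLS[[paste0("braf_", cls[i])]]
      rows <- data.frame(sample_id = sid[i], gene = "BRAF",
                         protein_change = sample(pool, 1),
                         stringsAsFactors = FALSE)
    }
    if (add_ras[i]) {
      if (atyp[i]) {
        src <- sample(c("kras_atypical", "nras", "nf1_truncating"), 1,
                      prob = c(0.6, 0.25, 0.15))
        gene <- switch(src, kras_atypical = "KRAS", nras = "NRAS",
                       nf1_truncating = "NF1")
        pc <- sample(VARIANT_POOLS[[src]], 1)
      } else {
        gene <- "KRAS"
        pc <- sample(VARIANT_POOLS$kras_typical, 1)
      }
      rows <- rbind(rows, data.frame(sample_id = sid[i], gene = gene,
                                     protein_change = pc,
                                     stringsAsFactors = FALSE))
    }
    mut_rows[[i]] <- rows
  }
  mutations <- do.call(rbind, mut_rows)
  if (is.null(mutations)) {
    mutations <- data.frame(sample_id = character(0), gene = character(0),
                            protein_change = character(0))
  }

  clinical <- data.frame(
    sample_id = sid,
    msi_status = ifelse(stats::rbinom(n_tumors, 1, config$p_msi[cls]) == 1,
                        "MSI", "MSS"),
    location = ifelse(stats::rbinom(n_tumors, 1, config$p_distal[cls]) == 1,
                      "distal", "proximal"),
    age = round(stats::rnorm(n_tumors, config$age_mean, config$age_sd), 1),
    sex = ifelse(stats::rbinom(n_tumors, 1, config$p_male) == 1,
                 "male", "female"),
    stage = sample(names(config$stage_probs), n_tumors, replace = TRUE,
                   prob = config$stage_probs),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(sample_id = sid, braf_class = cls,
                      additional_ras = add_ras,
                      additional_ras_atypical = atyp,
                      stringsAsFactors = FALSE)
  list(mutations = mutations, clinical = clinical, truth = truth)
}

#' Simulate sequencing read counts under the purity--CN--clonality model
#'
#' For each mutation in the truth table, draws
#' `mutant_reads ~ Binomial(depth, cell_fraction * expected_vaf)` where
#' the expected VAF comes from [expected_vaf()] at the tumor's purity and
#' the mutation's allele copy numbers. The truth table is retained so
#' recovery tests can compare inferred against generating values.
#'
#' @param truth Data.frame with columns `mutation_id`, `purity`, `n_mut`,
#'   `n_wt_cancer`, `cell_fraction`, `depth` (optional `sample_id`).
#' @param seed Integer seed.
#' @return List with `reads` (`mutation_id`, `mutant_reads`,
#'   `total_reads`) and `truth` (input plus `expected_vaf`).
#' @export
simulate_read_counts <- function(truth, seed = 1) {
  required <- c("mutation_id", "purity", "n_mut", "n_wt_cancer",
                "cell_fraction", "depth")
  if (!all(required %in% names(truth))) {
    stop("truth table lacks column(s): ",
         paste(setdiff(required, names(truth)), collapse = ", "),
         call. = FALSE)
  }
  if (any(truth$depth < 1)) stop("depths must be >= 1", call. = FALSE)
  if (any(truth$cell_fraction < 0 | truth$cell_fraction > 1)) {
    stop("cell fractions must lie in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  ev <- expected_vaf(truth$purity, truth$n_mut, truth$n_wt_cancer) *
    truth$cell_fraction
  reads <- data.frame(
    mutation_id = truth$mutation_id,
    mutant_reads = stats::rbinom(nrow(truth), truth$depth, ev),
    total_reads = as.integer(truth$depth),
    stringsAsFactors = FALSE
  )
  truth$expected_vaf <- ev
  list(reads = reads, truth = truth)
}

#' Channel probability vector with configured causal-channel mass
#'
#' Builds a 96-channel probability vector placing a configured total mass
#' on the class 1 causal channel and on the 16 class 2/3 causal channels
#' (split evenly within the set), with the remaining mass spread flat over
#' the other channels. Defaults calibrate the generator to the mean
#' proportional activities observed in whole-genome colorectal cancer
#' spectra: 0.69% for the class 1 (V600E) channel `G[T>A]G` and a summed
#' 12.9% for the class 2/3 channels.
#'
#' @param class1_mass Total probability on the class 1 channel.
#' @param class2_3_mass Total probability on the class 2/3 channel set.
#' @return Named numeric vector of 96 probabilities summing to 1, in
#'   [sbs_channels()] order.
#' @export
default_channel_probs <- function(class1_mass = 0.0069,
                                  class2_3_mass = 0.129) {
  channels <- sbs_channels()
  c1 <- braf_causal_channels("class1")
  c23 <- setdiff(braf_causal_channels("class2_3"), c1)
  p <- stats::setNames(rep(0, 96), channels)
  p[c1] <- class1_mass / length(c1)
  p[c23] <- class2_3_mass / length(c23)
  rest <- setdiff(channels, c(c1, c23))
  p[rest] <- (1 - class1_mass - class2_3_mass) / length(rest)
  p
}

#' Simulate a mutation catalog over the 96 channels
#'
#' Draws each sample's mutations from a multinomial over the 96
#' pyrimidine-strand channels and emits every mutation on a random strand
#' (half on the reference representation, half reverse-complemented), so
#' downstream strand collapse is exercised.
#'
#' @param n_samples Number of samples.
#' @param mutations_per_sample Mutations per sample (scalar or vector).
#' @param channel_probs Numeric vector of 96 channel probabilities
#'   (summing to 1), in [sbs_channels()] order. Default: uniform.
#' @param seed Integer seed.
#' @return Data.frame catalog (`sample_id`, `context`, `ref`, `alt`) plus
#'   a `"channel_probs"` attribute.
#' @export
simulate_catalog <- function(n_samples, mutations_per_sample,
                             channel_probs = rep(1 / 96, 96), seed = 1) {
  if (length(channel_probs) != 96 || abs(sum(channel_probs) - 1) > 1e-8) {
    stop("channel_probs must be 96 probabilities summing to 1", call. = FALSE)
  }
  set.seed(seed)
  channels <- sbs_channels()
  m <- rep_len(mutations_per_sample, n_samples)
  sid <- rep(sprintf("spl_%04d", seq_len(n_samples)), m)
  ch <- sample(channels, sum(m), replace = TRUE, prob = channel_probs)
  left <- substr(ch, 1, 1)
  ref <- substr(ch, 3, 3)
  alt <- substr(ch, 5, 5)
  right <- substr(ch, 7, 7)
  context <- paste0(left, ref, right)
  flip <- stats::runif(length(ch)) < 0.5
  context[flip] <- revcomp3(context[flip])
  ref[flip] <- unname(COMPLEMENT[ref[flip]])
  alt[flip] <- unname(COMPLEMENT[alt[flip]])
  out <- data.frame(sample_id = sid, context = context, ref = ref, alt = alt,
                    stringsAsFactors = FALSE)
  attr(out, "channel_probs") <- stats::setNames(channel_probs, channels)
  out
}
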