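PIPELINE_SCHEMA <- list(
  seed = "integer",
  stages = "character",
  inputs = c("mutations", "clinical", "reads", "purity", "cn_segments",
             "pairs", "catalog"),
  contrasts = NULL,  # list of {name, row, col}
  channels = "character",
  simulate = c("n_tumors")
)

validate_pipeline_config <- function(config) {
  unknown <- setdiff(names(config), names(PIPELINE_SCHEMA))
  if (length(unknown)) {
    stop("unknown config key: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(config$inputs)) {
    unknown <- setdiff(names(config$inputs), PIPELINE_SCHEMA$inputs)
    if (length(unknown)) {
      stop("unknown config key: inputs$",
           paste(unknown, collapse = ", inputs$"), call. = FALSE)
    }
  }
  known_stages <- c("simulate", "annotate", "cooccur", "clonality", "spectrum")
  if (!is.null(config$stages)) {
    unknown <- setdiff(config$stages, known_stages)
    if (length(unknown)) {
      stop("unknown stage: ", paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  invisible(config)
}

stage_log <- function(manifest, stage, n_in, n_out, outputs) {
  message(sprintf("[%s] rows in: %d, rows out: %d, outputs: %s",
                  stage, n_in, n_out, paste(basename(outputs), collapse = ", ")))
  manifest$stages[[stage]] <- list(
    rows_in = n_in, rows_out = n_out,
    outputs = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                      basename(outputs)))
  )
  manifest
}

#' Run the analysis pipeline end to end
#'
#' Executes the configured stages in dependency order — `simulate`
#' (optional synthetic inputs), `annotate`, `cooccur`, `clonality`,
#' `spectrum` — exchanging plain TSV files, and writes a reproducibility
#' manifest (`manifest.json`) listing the package version, config and
#' input checksums, seed, per-stage row counts and output checksums.
#' Reruns with identical config and inputs are byte-identical for the
#' deterministic stages (the manifest's timestamp aside).
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#'   Recognized keys: `seed`, `stages`, `inputs` (`mutations`, `clinical`,
#'   `reads`, `purity`, `cn_segments`, `pairs`, `catalog`), `contrasts`
#'   (list of `name`/`row`/`col` predicate strings), `channels`
#'   (`class1`, `class2_3` or a TSV path), `simulate` (`n_tumors`).
#'   Unknown keys are rejected by name.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config, out_dir) {
  config_path <- NULL
  if (is.character(config)) {
    config_path <- config
    config <- yaml::read_yaml(config)
  }
  validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  stages <- config$stages %||%
    c("annotate", "cooccur", "clonality", "spectrum")
  inputs <- config$inputs %||% list()

  manifest <- list(
    tool = paste0("rasco ", as.character(utils::packageVersion("rasco"))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config_checksum = if (!is.null(config_path)) {
      unname(tools::md5sum(config_path))
    },
    input_checksums = as.list(vapply(inputs, function(p) {
      unname(tools::md5sum(p))
    }, character(1))),
    stages = list()
  )

  if ("simulate" %in% stages) {
    n <- config$simulate$n_tumors %||% 1000L
    sim <- simulate_cohort(n, seed = seed)
    f_mut <- file.path(out_dir, "simulated_mutations.tsv")
    f_cln <- file.path(out_dir, "simulated_clinical.tsv")
    write_tsv(sim$mutations, f_mut)
    write_tsv(sim$clinical, f_cln)
    inputs$mutations <- f_mut
    inputs$clinical <- f_cln
    manifest <- stage_log(manifest, "simulate", n,
                          nrow(sim$mutations), c(f_mut, f_cln))
  }

  annotated <- NULL
  if ("annotate" %in% stages) {
    if (is.null(inputs$mutations)) {
      stop("annotate stage needs inputs$mutations", call. = FALSE)
    }
    mut <- read_mutation_table(inputs$mutations)
    cln <- if (!is.null(inputs$clinical)) read_clinical_table(inputs$clinical)
    annotated <- annotate_cohort(mut, cln)
    f <- file.path(out_dir, "annotated.tsv")
    write_tsv(annotated, f)
    manifest <- stage_log(manifest, "annotate", nrow(mut), nrow(annotated), f)
  }

  if ("cooccur" %in% stages) {
    if (is.null(annotated)) stop("cooccur stage needs annotate", call. = FALSE)
    contrasts <- config$contrasts %||% list(
      list(name = "class3_vs_class1_additional_ras",
           row = 'braf_class == "class3"',
           col = "additional_ras",
           subset = 'braf_class %in% c("class1", "class3")')
    )
    rows <- lapply(contrasts, function(ct) {
      data_ <- annotated
      if (!is.null(ct$subset)) {
        keep <- eval(parse(text = ct$subset), data_)
        data_ <- data_[keep & !is.na(keep), , drop = FALSE]
      }
      tab <- build_table(data_,
                         stats::as.formula(paste("~", ct$row)),
                         stats::as.formula(paste("~", ct$col)))
      fe <- fisher_exact_2x2(tab)
      data.frame(contrast = ct$name,
                 a = tab$counts[1, 1], b = tab$counts[1, 2],
                 c = tab$counts[2, 1], d = tab$counts[2, 2],
                 odds_ratio = fe$odds_ratio, p_two_sided = fe$p_two_sided,
                 n_excluded = tab$n_excluded, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    f <- file.path(out_dir, "cooccurrence.tsv")
    write_tsv(res, f)
    manifest <- stage_log(manifest, "cooccur", nrow(annotated), nrow(res), f)
  }

  if ("clonality" %in% stages) {
    for (need in c("reads", "purity", "pairs")) {
      if (is.null(inputs[[need]])) {
        stop("clonality stage needs inputs$", need, call. = FALSE)
      }
    }
    reads <- read_reads_table(inputs$reads)
    purity <- read_purity_table(inputs$purity)
    pairs <- read_tsv_checked(inputs$pairs,
                              c("sample_id", "mutation_a", "mutation_b"))
    cn <- if (!is.null(inputs$cn_segments)) {
      read_tsv_checked(inputs$cn_segments,
                       c("mutation_id", "major_cn", "minor_cn"))
    }
    res <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      pr <- pairs[i, ]
      pur <- purity$purity[purity$sample_id == pr$sample_id][1]
      ctx <- lapply(c(pr$mutation_a, pr$mutation_b), function(mid) {
        rr <- reads[reads$mutation_id == mid, ][1, ]
        nm <- 1L; nw <- 1L; status <- "diploid_default"
        if (!is.null(cn) && mid %in% cn$mutation_id) {
          cc <- cn[cn$mutation_id == mid, ][1, ]
          asg <- assign_mutant_copy_number(rr$mutant_reads / rr$total_reads,
                                           pur, cc$major_cn, cc$minor_cn)
          if (asg$status == "assigned") {
            nm <- asg$n_mut; nw <- asg$n_wt_cancer
          }
          status <- asg$status
        }
        list(ctx = allele_copy_context(rr$mutant_reads, rr$total_reads, pur,
                                       nm, nw, id = mid),
             status = status)
      })
      cl <- test_pair_clonality(ctx[[1]]$ctx, ctx[[2]]$ctx)
      data.frame(sample_id = pr$sample_id,
                 mutation_a = pr$mutation_a, mutation_b = pr$mutation_b,
                 cn_status_a = ctx[[1]]$status, cn_status_b = ctx[[2]]$status,
                 n_mut_a = ctx[[1]]$ctx$n_mut, n_mut_b = ctx[[2]]$ctx$n_mut,
                 ccf_a = cl$ccf_a, ccf_b = cl$ccf_b,
                 p_binom_a = cl$p_binom_a, p_binom_b = cl$p_binom_b,
                 chisq_stat = cl$chisq_stat, p_chisq = cl$p_chisq,
                 p_chisq_raw = cl$p_chisq_raw,
                 call = cl$call, stringsAsFactors = FALSE)
    }))
    f <- file.path(out_dir, "clonality.tsv")
    write_tsv(res, f)
    manifest <- stage_log(manifest, "clonality", nrow(pairs), nrow(res), f)
  }

  if ("spectrum" %in% stages) {
    if (is.null(inputs$catalog)) {
      stop("spectrum stage needs inputs$catalog", call. = FALSE)
    }
    catalog <- read_catalog(inputs$catalog)
    sp <- build_spectrum(catalog)
    out <- data.frame(sample_id = rownames(sp$weights), sp$weights,
                      check.names = FALSE, stringsAsFactors = FALSE)
    f <- file.path(out_dir, "spectra.tsv")
    write_tsv(out, f)
    fp <- NULL
    if (!is.null(config$channels)) {
      chans <- braf_causal_channels(config$channels)
      prop <- causal_channel_proportion(sp, chans)
      fp <- file.path(out_dir, "channel_proportions.tsv")
      write_tsv(data.frame(sample_id = names(prop),
                           channel_proportion = unname(prop)), fp)
    }
    manifest <- stage_log(manifest, "spectrum", nrow(catalog),
                          nrow(out), c(f, fp))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
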