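random_mutations <- function(n, seed) {
  set.seed(seed)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  context <- paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), ref,
                    sample(c("A", "C", "G", "T"), n, replace = TRUE))
  data.frame(context = context, ref = ref, alt = unname(alt),
             stringsAsFactors = FALSE)
}

revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(strsplit(x, ""), function(b) paste(rev(comp[b]), collapse = ""),
         character(1))
}

test_that("pyrimidine collapse reproduces canonical channel labels", {
  expect_equal(collapse_to_pyrimidine("GTG", "T", "A"), "G[T>A]G")
  expect_equal(collapse_to_pyrimidine("AGC", "G", "A"), "G[C>T]T")
  # the reverse-strand representation of GTG>GAG is CAC>CTC
  expect_equal(collapse_to_pyrimidine("CAC", "A", "T"), "G[T>A]G")
  expect_error(collapse_to_pyrimidine("GT", "T", "A"), "malformed")
  expect_error(collapse_to_pyrimidine("GAG", "T", "A"), "malformed")
  expect_error(collapse_to_pyrimidine("GTG", "T", "T"), "malformed")
})

test_that("channel collapse is strand-invariant on 1,000 random mutations", {
  mut <- random_mutations(1000, seed = 51)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  fwd <- collapse_to_pyrimidine(mut$context, mut$ref, mut$alt)
  rev_ <- collapse_to_pyrimidine(revcomp(mut$context),
                                 unname(comp[mut$ref]), unname(comp[mut$alt]))
  expect_equal(fwd, rev_)
  # every label is one of the 96 channels, and all 96 are reachable
  expect_true(all(fwd %in% sbs_channels()))
  expect_equal(length(unique(sbs_channels())), 96L)
})

test_that("spectra normalize to one and raw counts add over catalogs", {
  cat1 <- data.frame(sample_id = "s1",
                     context = rep("GTG", 4), ref = "T", alt = "A")
  sp <- build_spectrum(cat1)
  expect_equal(unname(sp$weights["s1", "G[T>A]G"]), 1.0)
  expect_equal(sum(sp$weights), 1.0)

  mut <- random_mutations(500, seed = 52)
  mut$sample_id <- rep(c("a", "b"), length.out = 500)
  sp_all <- build_spectrum(mut)
  expect_equal(unname(rowSums(sp_all$weights)), c(1, 1), tolerance = 1e-12)
  sp_a <- build_spectrum(mut[mut$sample_id == "a", ])
  sp_b <- build_spectrum(mut[mut$sample_id == "b", ])
  expect_equal(sp_all$counts["a", ], sp_a$counts["a", ])
  expect_equal(sp_all$counts["a", ] + sp_all$counts["b", ],
               sp_a$counts["a", ] + sp_b$counts["b", ])

  # weights are scale-free: duplicating the catalog changes nothing
  sp_dup <- build_spectrum(rbind(cat1, cat1))
  expect_equal(sp_dup$weights, sp$weights)

  # empty catalog yields an empty profile set without error
  empty <- data.frame(sample_id = character(0), context = character(0),
                      ref = character(0), alt = character(0))
  sp0 <- build_spectrum(empty)
  expect_equal(nrow(sp0$weights), 0L)
})

test_that("causal channel proportions are additive and bounded", {
  mut <- random_mutations(2000, seed = 53)
  mut$sample_id <- "s"
  sp <- build_spectrum(mut)
  all96 <- sbs_channels()
  expect_equal(unname(causal_channel_proportion(sp, all96)), 1.0)
  # disjoint partition sums to 1
  parts <- split(all96, rep(1:4, each = 24))
  total <- Reduce(`+`, lapply(parts, function(p) {
    causal_channel_proportion(sp, p)
  }))
  expect_equal(unname(total), 1.0)
  p1 <- causal_channel_proportion(sp, braf_causal_channels("class1"))
  expect_equal(unname(p1), unname(sp$weights["s", "G[T>A]G"]))
  expect_error(causal_channel_proportion(sp, "Z[C>A]A"), "unknown channel")
})

test_that("the causal channel table is consistent and has the right shape", {
  tab <- braf_channel_table()
  expect_equal(braf_causal_channels("class1"), "G[T>A]G")
  c23 <- braf_causal_channels("class2_3")
  expect_length(c23, 16L)
  expect_true(all(c23 %in% sbs_channels()))
  # every listed substitution collapses to its recorded channel
  expect_equal(collapse_to_pyrimidine(tab$coding_context, tab$coding_ref,
                                      tab$coding_alt),
               tab$channel)
})

test_that("the logistic fit matches the IRLS oracle to 1e-6", {
  d <- make_presence_data(50, beta_channel = 1, seed = 61)
  fit <- fit_presence_logistic(d)
  X <- cbind(1, d$channel_proportion, as.numeric(d$location == "distal"),
             as.numeric(d$msi == "MSS"), d$age,
             as.numeric(d$sex == "male"))
  beta <- irls_logistic(X, d$presence)
  expect_equal(unname(fit$coefficients$estimate), unname(beta),
               tolerance = 1e-6)
})

test_that("degenerate presence data errors; separation is flagged", {
  d <- make_presence_data(40, beta_channel = 0, seed = 62)
  d$presence <- 0
  expect_error(fit_presence_logistic(d), "case and.*control")
  # perfectly separating covariate
  d2 <- make_presence_data(40, beta_channel = 0, seed = 63)
  d2$presence <- as.numeric(d2$channel_proportion > 0.5)
  w <- capture_warnings(fit2 <- fit_presence_logistic(d2))
  expect_true(any(grepl("separation", w)))
  expect_true(fit2$separation)
})

test_that("null and non-null channel effects are recovered across replicates", {
  null_ok <- vapply(1:30, function(i) {
    d <- make_presence_data(2000, beta_channel = 0, seed = 700 + i)
    cf <- fit_presence_logistic(d)$coefficients
    row <- cf[cf$term == "channel_proportion", ]
    abs(row$estimate) < 2 * row$se
  }, logical(1))
  expect_gte(mean(null_ok), 0.9)
  est_ok <- vapply(1:30, function(i) {
    d <- make_presence_data(2000, beta_channel = 1.5, seed = 800 + i)
    cf <- fit_presence_logistic(d)$coefficients
    abs(cf$estimate[cf$term == "channel_proportion"] - 1.5) < 0.3
  }, logical(1))
  expect_gte(mean(est_ok), 0.9)
})
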