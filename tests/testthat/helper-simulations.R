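# Shared simulation harnesses and independent oracles for the test suite.

# Simulate n_pairs tumor pairs at the given purity: variant A clonal
# (cell fraction 1), variant B at cf_b; diploid heterozygous loci,
# depths uniform on 200-1000. Returns the vector of clonality calls.
sim_clonality_calls <- function(n_pairs, cf_b, seed, purity = 0.7) {
  set.seed(seed)
  depths <- sample(200:1000, 2 * n_pairs, replace = TRUE)
  truth <- data.frame(
    mutation_id = sprintf("m%05d", seq_len(2 * n_pairs)),
    purity = purity, n_mut = 1L, n_wt_cancer = 1L,
    cell_fraction = rep(c(1, cf_b), n_pairs),
    depth = depths
  )
  rc <- simulate_read_counts(truth, seed = seed)
  vapply(seq_len(n_pairs), function(i) {
    ia <- 2 * i - 1; ib <- 2 * i
    ctx_a <- allele_copy_context(rc$reads$mutant_reads[ia],
                                 rc$reads$total_reads[ia], purity, 1, 1)
    ctx_b <- allele_copy_context(rc$reads$mutant_reads[ib],
                                 rc$reads$total_reads[ib], purity, 1, 1)
    test_pair_clonality(ctx_a, ctx_b)$call
  }, character(1))
}

# Simulate clonal mutations on random allele-specific copy-number states
# and score how often assign_mutant_copy_number() recovers the generating
# (n_mut, n_wt) among unambiguously assigned cases. depth >= 500.
sim_cn_recovery <- function(n, seed) {
  set.seed(seed)
  states <- matrix(c(2, 1, 3, 1, 2, 0, 3, 2, 4, 2), ncol = 2, byrow = TRUE)
  idx <- sample(nrow(states), n, replace = TRUE)
  major <- states[idx, 1]; minor <- states[idx, 2]
  pick_major <- sample(c(TRUE, FALSE), n, replace = TRUE)
  n_mut <- ifelse(pick_major | minor == 0, major, minor)
  n_wt <- major + minor - n_mut
  purity <- round(stats::runif(n, 0.4, 0.9), 3)
  truth <- data.frame(
    mutation_id = sprintf("cn%05d", seq_len(n)),
    purity = purity, n_mut = n_mut, n_wt_cancer = n_wt,
    cell_fraction = 1,
    depth = sample(500:2000, n, replace = TRUE)
  )
  rc <- simulate_read_counts(truth, seed = seed)
  vaf <- rc$reads$mutant_reads / rc$reads$total_reads
  asg <- assign_mutant_copy_number(vaf, purity, major, minor)
  assigned <- asg$status == "assigned"
  list(
    n_assigned = sum(assigned),
    recovery = mean(asg$n_mut[assigned] == n_mut[assigned] &
                      asg$n_wt_cancer[assigned] == n_wt[assigned])
  )
}

# Independent iteratively-reweighted least-squares logistic fit: the
# oracle the glm-based implementation is checked against.
irls_logistic <- function(X, y, tol = 1e-12, max_iter = 200) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- drop(solve(crossprod(X, w * X), crossprod(X, w * z)))
    if (max(abs(beta_new - beta)) < tol) return(beta_new)
    beta <- beta_new
  }
  beta
}

# Cohort for the presence-on-channel-activity model: channel proportions
# drawn from Beta(0.5, 0.5) for spread, independent covariates, presence
# from the logistic model with slope beta_channel.
make_presence_data <- function(n, beta_channel, seed, beta0 = -0.5 * beta_channel) {
  set.seed(seed)
  x <- stats::rbeta(n, 0.5, 0.5)
  loc <- sample(c("proximal", "distal"), n, replace = TRUE)
  msi <- sample(c("MSI", "MSS"), n, replace = TRUE, prob = c(0.2, 0.8))
  age <- stats::rnorm(n, 68, 10)
  sex <- sample(c("female", "male"), n, replace = TRUE)
  eta <- beta0 + beta_channel * x + 0.2 * (loc == "distal") -
    0.1 * (msi == "MSS") + 0.005 * (age - 68) + 0.1 * (sex == "male")
  presence <- stats::rbinom(n, 1, 1 / (1 + exp(-eta)))
  data.frame(presence = presence, channel_proportion = x, location = loc,
             msi = msi, age = age, sex = sex, stringsAsFactors = FALSE)
}

# Independent brute-force 2x2 tally used against build_table().
brute_tally <- function(r, c_) {
  keep <- !is.na(r) & !is.na(c_)
  r <- r[keep]; c_ <- c_[keep]
  matrix(c(sum(r & c_), sum(r & !c_), sum(!r & c_), sum(!r & !c_)),
         nrow = 2, byrow = TRUE)
}

# Two-sided Fisher p by explicit enumeration with binomial coefficients
# (independent of dhyper): minimum-likelihood rule.
fisher_enum_p <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, support) * choose(r2, c1 - support) / choose(n, c1)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}
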