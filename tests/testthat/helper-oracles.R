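# Independent brute-force oracles used across the suite.

# AUC by exhaustive positive-negative pair counting, ties = 1/2
auc_pair_count <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# two-sided Fisher exact p by enumeration of the hypergeometric support
fisher_p_enum <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# a small labeled instance with ties, for rank-based checks
tied_instance <- function(seed, n = 16) {
  set.seed(seed)
  list(scores = sample(seq(-30, 50, by = 10), n, replace = TRUE),
       labels = sample(c(0L, 1L), n, replace = TRUE, prob = c(0.4, 0.6)))
}

# every attainable PASS factor combination (288 rows)
all_factor_records <- function() {
  g <- expand.grid(
    severity = c("severe", "non_severe"),
    acuity = c("acute", "chronic"),
    age_ge60 = c(TRUE, FALSE),
    red_flags = c(TRUE, FALSE),
    aa_condition = c(TRUE, FALSE),
    somatic = c("present", "absent", "unknown"),
    tl_lt_1st = c("short", "not_short", "unknown"),
    stringsAsFactors = FALSE
  )
  g$patient_id <- sprintf("G%03d", seq_len(nrow(g)))
  g
}
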