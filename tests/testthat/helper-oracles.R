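# Brute-force path-enumeration oracle for the forward likelihood and the
# Viterbi decoding: sums/maximizes over every state path with the first
# record fixed in S_NOADA (probability one), independent of the recursion
# under test.
enum_paths <- function(records, em, tp) {
  E <- exp(adamhmm:::.emission_logmat(records$y_pkres, records$y_ada, em))
  P <- transition_probs(tp)
  n <- nrow(E)
  if (n == 1) {
    return(list(loglik = log(E[1, 1]), best_logprob = log(E[1, 1]),
                best_path = 1L))
  }
  grid <- as.matrix(expand.grid(rep(list(1:2), n - 1)))
  total <- 0
  best <- -Inf
  best_path <- NULL
  for (k in seq_len(nrow(grid))) {
    s <- c(1L, grid[k, ])
    pr <- E[1, 1]
    for (t in 2:n) pr <- pr * P[s[t - 1], s[t]] * E[t, s[t]]
    total <- total + pr
    if (log(pr) > best) {
      best <- log(pr)
      best_path <- s
    }
  }
  list(loglik = log(total), best_logprob = best, best_path = unname(best_path))
}

# small deterministic record table used by several tests
toy_records <- function(n, seed = 1, p_missing = 0) {
  set.seed(seed)
  y1 <- round(stats::rnorm(n, 0, 1.2), 3)
  y2 <- round(stats::rnorm(n, 1.2, 1.1), 3)
  if (p_missing > 0) {
    y1[stats::runif(n) < p_missing] <- NA
    y2[stats::runif(n) < p_missing] <- NA
    both <- is.na(y1) & is.na(y2)
    y2[both] <- 0.9
  }
  data.frame(time = 14 * seq_len(n), y_pkres = y1, y_ada = y2)
}

table3_em <- function() czp_example_params()$em
table3_tp <- function() czp_example_params()$tp

`%||%` <- function(a, b) if (is.null(a)) b else a
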