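# Shared fixtures and independent oracles. The oracles here are written
# brute-force (full enumeration / O(n^2) loops) and never call the package
# code paths they check.

tiny_cohort_df <- function() {
  data.frame(
    id = c("a", "b", "c", "d", "e", "f"),
    resp = c(1, 0, 1, 0, 0, 1),
    os_time = c(5, 3, 9, 2, 7, 11),
    os_event = c(1, 1, 0, 1, 1, 0),
    tmb = c(10, 2, 8, 1, 3, 12),
    gep = c(0.2, 1.5, 0.4, 2.0, 1.1, 0.3)
  )
}

tiny_cohort <- function() {
  cohort(tiny_cohort_df(), sample_id = "id", response = "resp",
         time = "os_time", event = "os_event",
         markers = c("tmb", "gep"), response_coding = "1")
}

sim_both <- function(n = 150, seed = 11, ...) {
  simulate_cohort(sim_config(n = n, seed = seed, b1 = 0.8, b2 = -0.6,
                             g1 = -0.5, g2 = 0.4, ...))
}

# Mann-Whitney AUC by explicit pair counting (ties count 1/2)
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Gonen-Heller CPE by explicit double loop
brute_cpe <- function(eta) {
  n <- length(eta); s <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    s <- s + 1 / (1 + exp(-abs(eta[i] - eta[j])))
    np <- np + 1
  }
  s / np
}

# exact two-sided rank-sum p by enumerating all group assignments
enum_wilcoxon_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  r <- rank(pooled)
  obs <- sum(r[seq_len(na)])
  idx <- utils::combn(length(pooled), na)
  ws <- apply(idx, 2, function(ii) sum(r[ii]))
  ew <- mean(ws)
  mean(abs(ws - ew) >= abs(obs - ew) - 1e-9)
}

# two-sided Fisher p by enumerating all tables with the observed margins
enum_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# k=2 log-rank chi-square from first principles (risk-set tabulation)
enum_logrank_chi2 <- function(times, events, groups) {
  g <- as.integer(factor(groups))
  ts <- sort(unique(times[events == 1]))
  o1 <- e1 <- v <- 0
  for (t in ts) {
    at <- times >= t
    n <- sum(at); n1 <- sum(at & g == 1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g == 1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o1 - e1)^2 / v
}
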