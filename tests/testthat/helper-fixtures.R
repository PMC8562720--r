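# Shared in-code fixtures and independent oracles.

make_profile <- function(means, genes = NULL, types = NULL) {
  means <- as.matrix(means)
  if (is.null(genes)) genes <- rownames(means)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(means)))
  if (is.null(types)) types <- colnames(means)
  if (is.null(types)) types <- paste0("ct", seq_len(ncol(means)))
  dimnames(means) <- list(genes, types)
  structure(list(genes = genes, cell_types = types, means = means),
            class = "cell_type_profile")
}

small_config <- function(...) {
  args <- utils::modifyList(
    list(n_cell_types = 4L, replicates_per_type = 4L,
         n_tumor_lines = 10L, n_genes = 200L,
         n_specific_per_type = 3L, n_prognostic = 4L,
         n_patients = 120L),
    list(...))
  do.call(sim_config, args)
}

# Brute-force Benjamini-Hochberg step-up: adj_i = min over k with
# p_(k) >= p_(i) of p_(k) * m / k, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(pmin(ranked[i:m] * m / (i:m), 1))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Two-group log-rank statistic from hand-built 2x2 risk tables at each
# distinct event time (no variance shortcuts; hypergeometric variance).
logrank_oracle <- function(time, event, group) {
  g <- as.integer(factor(group))
  stopifnot(length(unique(g)) == 2L)
  times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (tk in times) {
    at_risk <- time >= tk
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1L)
    d <- sum(time == tk & event == 1)
    d1 <- sum(time == tk & event == 1 & g == 1L)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- (O - E)^2 / V
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# Product-limit estimator written directly from its definition.
km_oracle <- function(time, event) {
  times <- sort(unique(time))
  s <- 1
  out <- numeric(length(times))
  for (i in seq_along(times)) {
    tk <- times[i]
    n_risk <- sum(time >= tk)
    d <- sum(time == tk & event == 1)
    s <- s * (1 - d / n_risk)
    out[i] <- s
  }
  data.frame(time = times, estimate = out)
}

# Fisher two-sided p by full enumeration of tables with fixed margins.
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0L, r1 + c1 - n)
  hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
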