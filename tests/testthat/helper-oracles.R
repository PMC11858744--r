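# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the error function is evaluated via its pnorm
# identity, likelihoods by explicit per-row summation, rank-test reference
# values by exhaustive enumeration.

erf_ref <- function(x) 2 * pnorm(x * sqrt(2)) - 1

`%||%` <- function(a, b) if (is.null(a)) b else a

# psychometric curve written exactly as the model definition, term by term
psy_ref <- function(eta, w, p) {
  0.5 + 0.5 * erf_ref(log(eta / p) / (sqrt(2) * log(w + 1)))
}

# direct-summation negative log-likelihood (clipped like the implementation)
brute_nll <- function(tab, w, p) {
  total <- 0
  for (i in seq_len(nrow(tab))) {
    f <- psy_ref(tab$eta_cp[i], w, p)
    f <- min(max(f, 1e-9), 1 - 1e-9)
    total <- total - tab$k_thicker[i] * log(f) -
      (tab$n_total[i] - tab$k_thicker[i]) * log(1 - f)
  }
  total
}

make_table <- function(eta, k, n, p_true = NULL, group = "X") {
  tab <- data.frame(eta_cp = eta, k_thicker = as.integer(k),
                    n_total = as.integer(rep(n, length.out = length(eta))))
  attr(tab, "reference_viscosity_cp") <- p_true
  attr(tab, "group_label") <- group
  tab
}

# exhaustive two-sided Mann-Whitney p over all group relabelings
exact_u_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  mu <- n1 * (n - n1) / 2
  idx <- utils::combn(n, n1)
  us <- apply(idx, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# U of x by its pair-counting definition (independent of the rank formula)
count_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# exhaustive two-sided signed-rank p over all 2^n sign assignments
exact_w_p <- function(values, baseline = 50) {
  d <- values - baseline
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% r)
  w_min <- pmin(ws, sum(r) - ws)
  mean(w_min <= w_obs + 1e-12)
}

# signed-rank statistic from its definition
count_w <- function(values, baseline = 50) {
  d <- values - baseline
  d <- d[d != 0]
  r <- rank(abs(d))
  min(sum(r[d > 0]), sum(r[d < 0]))
}

# single-group design helper (7 pairs incl. the equal-viscosity catch pair)
one_group_design <- function(group = "C", appearance = "transparent",
                             task_id = "test") {
  groups <- build_group_designs(silicone_stimuli(),
                                reference_appearance = appearance)
  enumerate_pairs(groups[group], include_equal_pair = TRUE,
                  dedup = "within_appearance", task_id = task_id)
}
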