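# Independent brute-force oracle for the signed-rank test: enumerate all
# 2^n sign assignments of the nonzero differences and count assignments at
# least as extreme (two-sided, symmetric about the mean rank sum).
bf_signed_rank <- function(before, after) {
  d <- after - before
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(list(statistic = 0, p_value = 1))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.numeric(signs %*% r)
  mu <- sum(r) / 2
  p <- mean(abs(Ws - mu) >= abs(W - mu) - 1e-9)
  list(statistic = W, p_value = p)
}

# random paired data with a controllable amount of ties and zero differences
random_paired <- function(n, tie_prob = 0.3, zero_prob = 0.1) {
  before <- sample(0:5, n, replace = TRUE)
  d <- sample(c(-3, -2, -1, 1, 2, 3), n, replace = TRUE)
  if (tie_prob > 0) d <- ifelse(runif(n) < tie_prob, sign(d), d)
  d[runif(n) < zero_prob] <- 0
  list(before = before, after = before + d)
}
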