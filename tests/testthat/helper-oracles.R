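# Independent brute-force oracles: direct loops over the definitions,
# sharing no code with the package internals.

rmssd_bf <- function(a) {
  n <- length(a)
  if (n < 2) return(NA_real_)
  s <- 0
  for (i in 1:(n - 1)) s <- s + (a[i + 1] - a[i])^2
  sqrt(s / (n - 1))
}

lookahead_bf <- function(dur, kind, i, k) {
  ys <- numeric(0)
  j <- i + 1
  while (j <= length(dur) && length(ys) < k) {
    if (kind[j] == "use") ys <- c(ys, dur[j])
    j <- j + 1
  }
  if (length(ys) == k) ys else NULL
}

si_bf <- function(dur, kind, k = 3, denominator = "all_diffs") {
  diffs <- numeric(0)
  tmeans <- numeric(0)
  for (i in seq_along(dur)) {
    if (kind[i] != "nonuse") next
    ys <- lookahead_bf(dur, kind, i, k)
    if (is.null(ys)) next
    d <- abs(dur[i] - ys)
    diffs <- c(diffs, d)
    tmeans <- c(tmeans, mean(d))
  }
  if (length(diffs) == 0) return(NA_real_)
  if (denominator == "all_diffs") mean(diffs) else mean(tmeans)
}

ci_bf <- function(dur, kind, k = 3) {
  out <- numeric(0)
  for (i in seq_along(dur)) {
    if (kind[i] != "nonuse") next
    ys <- lookahead_bf(dur, kind, i, k)
    if (is.null(ys)) next
    out <- c(out, abs(dur[i] - sum(ys)))
  }
  if (length(out) == 0) NA_real_ else mean(out)
}

pearson_bf <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  r <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  n <- length(x)
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# random strictly alternating use/nonuse duration sequence
random_alternating <- function(n, start_use = TRUE) {
  kind <- rep(c("use", "nonuse"), length.out = n)
  if (!start_use && n > 0) kind <- rev(rep(c("use", "nonuse"), length.out = n))
  list(dur = round(stats::rlnorm(n, log(300), 1), 3), kind = kind)
}
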