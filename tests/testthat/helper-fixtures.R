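# Analytic curve fixtures used across the geometry tests.

straight_segment <- function(len = 100, n = 101) {
  boundary_curve(seq(0, len, length.out = n), rep(0, n))
}

circle_arc <- function(r = 10, angle_deg = 180, n = 361, closed = FALSE) {
  th <- seq(0, angle_deg * pi / 180, length.out = n)
  if (closed) th <- th[-n]
  boundary_curve(r * cos(th), r * sin(th), closed = closed)
}

# Independent two-group Mantel-Cox oracle: brute per-event-time 2x2
# accumulation, (sum(O - E))^2 / sum(V).
logrank_oracle_2g <- function(time, event, group) {
  g1 <- unique(group)[1]
  u <- 0
  v <- 0
  for (t0 in sort(unique(time[event == 1]))) {
    at <- time >= t0
    n <- sum(at)
    n1 <- sum(at & group == g1)
    d <- sum(time == t0 & event == 1)
    d1 <- sum(time == t0 & event == 1 & group == g1)
    u <- u + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  u^2 / v
}

# Independent Harrell C oracle: O(n^2) pair enumeration.
harrell_oracle <- function(time, event, scores) {
  num <- 0
  den <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      comp <- (time[i] < time[j] && event[i] == 1) ||
        (time[i] == time[j] && event[i] == 1 && event[j] == 0)
      if (comp) {
        den <- den + 1
        num <- num + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
      }
    }
  }
  if (den == 0) NA_real_ else num / den
}

# Closed-form 2x2 Pearson chi-square.
chi2_closed_form <- function(tab) {
  tab <- matrix(as.numeric(tab), 2, 2)
  a <- tab[1, 1]
  b <- tab[1, 2]
  c_ <- tab[2, 1]
  d <- tab[2, 2]
  n <- a + b + c_ + d
  n * (a * d - b * c_)^2 / ((a + b) * (c_ + d) * (a + c_) * (b + d))
}
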