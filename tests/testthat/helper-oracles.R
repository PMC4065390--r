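`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent oracles used across the suite. These deliberately use naive
# algorithms (explicit summation, enumeration, pair counting) so that they
# share no code path with the implementation they check.

# Day of week by Zeller's congruence (proleptic Gregorian), ISO numbering.
zeller_iso_weekday <- function(date) {
  lt <- as.POSIXlt(date)
  y <- lt$year + 1900L
  m <- lt$mon + 1L
  d <- lt$mday
  y <- ifelse(m < 3, y - 1L, y)
  m <- ifelse(m < 3, m + 12L, m)
  K <- y %% 100L
  J <- y %/% 100L
  h <- (d + (13L * (m + 1L)) %/% 5L + K + K %/% 4L + J %/% 4L + 5L * J) %% 7L
  # Zeller: 0 = Saturday ... 6 = Friday -> ISO 1 = Monday ... 7 = Sunday
  ((h + 5L) %% 7L) + 1L
}

# Brute-force Poisson upper tail by explicit summation of at least `terms`
# terms past n (plus enough to cover the bulk of the distribution).
oracle_poisson_tail <- function(n, lam, terms = 200) {
  if (lam == 0) return(as.numeric(n == 0))
  kmax <- n + max(terms, ceiling(lam + 40 * sqrt(lam) + 50))
  k <- n:kmax
  sum(exp(k * log(lam) - lam - lgamma(k + 1)))
}

# Smallest k with CDF(k) >= p by a linear scan over the mass function.
oracle_poisson_quantile <- function(p, lam) {
  k <- 0
  acc <- exp(-lam)
  while (acc < p) {
    k <- k + 1
    acc <- acc + exp(k * log(lam) - lam - lgamma(k + 1))
    if (k > 1e6) stop("scan overflow")
  }
  k
}

# Naive re-computation of the sliding-window median/MAD detector.
oracle_mad_flags <- function(x, half_width, multiplier) {
  n <- length(x)
  flags <- logical(n)
  for (i in seq_len(n)) {
    win <- if (is.finite(half_width)) {
      setdiff(max(1, i - half_width):min(n, i + half_width), i)
    } else setdiff(seq_len(n), i)
    m <- median(x[win])
    s <- median(abs(x[win] - m))
    dev <- abs(x[i] - m)
    flags[i] <- if (s > 0) dev > multiplier * s else dev > 0
  }
  flags
}

# AUC by O(n^2) pair counting with half credit for ties.
oracle_auc <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Loop-based confusion tally.
oracle_confusion <- function(flags, truth) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(flags)) {
    if (flags[i] && truth[i]) tp <- tp + 1L
    else if (flags[i]) fp <- fp + 1L
    else if (truth[i]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}
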