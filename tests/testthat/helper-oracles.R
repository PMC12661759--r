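# Brute-force oracles, deliberately independent of the package internals.

# exact two-sided signed-rank p by enumerating every sign vector
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  W_all <- as.matrix(signs) %*% r
  p_lo <- mean(W_all <= W_obs)
  p_hi <- mean(W_all >= W_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# exact two-sided rank-sum p by enumerating every labeling of the pooled data
oracle_rank_sum_p <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  U_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(length(pooled), nx)
  U_all <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  min(1, 2 * min(mean(U_all <= U_obs), mean(U_all >= U_obs)))
}

# two-sided Fisher p: enumerate all tables with the observed margins via
# choose(), sum the probabilities not exceeding the observed table's
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c; N <- m + n2
  xs <- max(0, k - n2):min(k, m)
  prob <- choose(m, xs) * choose(n2, k - xs) / choose(N, k)
  obs <- prob[xs == a]
  sum(prob[prob <= obs * (1 + 1e-7)])
}

# hand step-up BH
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# digest oracle: test every contiguous substring for being a valid product
oracle_digest <- function(sequence, max_missed, proline_rule) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  is_cut <- function(i) {               # cleavable boundary after position i
    i >= 1 && i < n && chars[i] %in% c("K", "R") &&
      !(proline_rule && chars[i + 1] == "P")
  }
  out <- character()
  for (s in 1:n) {
    for (e in s:n) {
      starts_ok <- s == 1 || is_cut(s - 1)
      ends_ok <- e == n || is_cut(e)
      if (!starts_ok || !ends_ok) next
      internal <- if (e > s) sum(vapply(s:(e - 1), is_cut, TRUE)) else 0
      if (internal <= max_missed) out <- c(out, paste(chars[s:e], collapse = ""))
    }
  }
  out
}

# overlap-aware sequon scan via lookahead regex
oracle_sequons <- function(seq) {
  hits <- gregexpr("N(?=[^P][STC])", seq, perl = TRUE)[[1]]
  if (hits[1] == -1) integer() else as.integer(hits)
}

# per-feature exclusive-region classification for membership sets
oracle_regions <- function(universes) {
  feats <- unique(unlist(universes))
  key <- vapply(feats, function(f) {
    paste(names(universes)[vapply(universes, function(u) f %in% u, TRUE)],
          collapse = "&")
  }, "")
  table(key)
}

random_peptide <- function(len,
                           alphabet = c("A", "C", "D", "E", "F", "G", "H",
                                        "I", "K", "L", "M", "N", "P", "Q",
                                        "R", "S", "T", "V", "W", "Y")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
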