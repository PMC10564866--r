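# Independent reference implementations used as test oracles. These are
# deliberately naive (quadratic scans, explicit enumeration) and share no
# code with the package internals they check.

# Best local alignment score under match +1, mismatch -2, gap of length k
# costing 5 + 2k. Three-state affine DP, score only.
oracle_local_score <- function(q, s) {
  qc <- strsplit(q, "")[[1]]; sc <- strsplit(s, "")[[1]]
  n <- length(qc); m <- length(sc)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i - 1, j] - 7, E[i - 1, j] - 2)
      F[i, j] <- max(H[i, j - 1] - 7, F[i, j - 1] - 2)
      sub <- if (qc[i - 1] == sc[j - 1] && qc[i - 1] != "N") 1 else -2
      H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Global-alignment identity (match +1, mismatch -1, gap -2), matches and
# alignment length from a diagonal-preferring traceback.
oracle_global_identity <- function(a, b) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- -2 * (0:n); S[1, ] <- -2 * (0:m)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    S[i, j] <- max(S[i - 1, j - 1] + if (ac[i - 1] == bc[j - 1]) 1 else -1,
                   S[i - 1, j] - 2, S[i, j - 1] - 2)
  }
  i <- n + 1; j <- m + 1; matches <- 0; len <- 0
  while (i > 1 || j > 1) {
    if (i > 1 && j > 1 &&
        S[i, j] == S[i - 1, j - 1] + (if (ac[i - 1] == bc[j - 1]) 1 else -1)) {
      if (ac[i - 1] == bc[j - 1]) matches <- matches + 1
      i <- i - 1; j <- j - 1
    } else if (i > 1 && S[i, j] == S[i - 1, j] - 2) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    len <- len + 1
  }
  matches / len
}

# Two-sided Fisher p by explicit enumeration of all tables with the
# observed margins, exact factorial arithmetic.
oracle_fisher <- function(a, b, c, d) {
  if (a + b + c + d == 0) return(1)
  m <- a + b; n <- c + d; k <- a + c
  tab_prob <- function(x) {
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
  }
  support <- max(0, k - n):min(k, m)
  probs <- vapply(support, tab_prob, numeric(1))
  obs <- tab_prob(a)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Welch statistic from the closed-form definition.
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# All-pairs Hamming-distance-1 edge list (brute force).
oracle_hamming1 <- function(seqs) {
  n <- length(seqs)
  out <- NULL
  if (n < 2) return(matrix(integer(0), 0, 2))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- strsplit(seqs[i], "")[[1]]; b <- strsplit(seqs[j], "")[[1]]
    if (length(a) == length(b) && sum(a != b) == 1) {
      out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

# Greedy "assign to first seed at >= threshold identity" dereplication in
# the package's processing order, with identity from the naive global DP.
oracle_derep <- function(records, threshold = 0.99) {
  idcol <- if ("sequence_id" %in% names(records)) "sequence_id" else "id"
  if (!"duplicate_count" %in% names(records)) records$duplicate_count <- 1L
  ord <- order(-records$duplicate_count, -nchar(records$sequence),
               records[[idcol]])
  records <- records[ord, ]
  seeds <- integer(0); assign_to <- integer(nrow(records))
  for (i in seq_len(nrow(records))) {
    hit <- 0
    for (ci in seq_along(seeds)) {
      if (oracle_global_identity(records$sequence[i],
                                 records$sequence[seeds[ci]]) >= threshold) {
        hit <- ci; break
      }
    }
    if (hit == 0) { seeds <- c(seeds, i); hit <- length(seeds) }
    assign_to[i] <- hit
  }
  split(records[[idcol]], assign_to)
}

# Adjusted Rand index between two label vectors.
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  total <- choose(sum(tab), 2)
  expected <- sum_a * sum_b / total
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}
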