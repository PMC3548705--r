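# Independent oracles the implementation is checked against. These stay
# deliberately naive: double loops, brute-force enumeration, no shared code
# with the package internals.

# textbook chi-square: explicit double loop over cells
chisq_oracle <- function(counts) {
  n <- sum(counts)
  rt <- rowSums(counts)
  ct <- colSums(counts)
  chi2 <- 0
  for (p in seq_len(nrow(counts))) {
    for (q in seq_len(ncol(counts))) {
      e <- rt[p] * ct[q] / n
      chi2 <- chi2 + (counts[p, q] - e)^2 / e
    }
  }
  unname(chi2)
}

cramers_v_oracle <- function(a, b) {
  counts <- unclass(table(a, b))
  P <- nrow(counts)
  Q <- ncol(counts)
  unname(sqrt(chisq_oracle(counts) / (length(a) * min(P - 1, Q - 1))))
}

# Hubert-Arabie ARI from brute-force enumeration of all object pairs
ari_pairs_oracle <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (!sa && !sb) n00 <- n00 + 1
      else if (sa && !sb) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  num <- 2 * (n11 * n00 - n10 * n01)
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) 1 else num / den
}

# all permutations of a vector (small k only)
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# accuracy by exhaustive search over label permutations
accuracy_perm_oracle <- function(labels, reference) {
  k <- length(unique(labels))
  best <- 0
  for (perm in all_perms(seq_len(k))) {
    best <- max(best, mean(perm[labels] == reference))
  }
  best
}

# minimum within-cluster SSQ over every assignment of n points to k
# nonempty clusters (prototypes at cluster means)
best_partition_wss_oracle <- function(x, k) {
  n <- nrow(x)
  best <- Inf
  assignment <- rep(1L, n)
  repeat {
    if (length(unique(assignment)) == k) {
      w <- 0
      for (c in seq_len(k)) {
        rows <- x[assignment == c, , drop = FALSE]
        w <- w + sum(sweep(rows, 2, colMeans(rows))^2)
      }
      best <- min(best, w)
    }
    # increment the base-k counter
    i <- 1L
    while (i <= n && assignment[i] == k) {
      assignment[i] <- 1L
      i <- i + 1L
    }
    if (i > n) break
    assignment[i] <- assignment[i] + 1L
  }
  best
}

# two well-separated Gaussian blobs in d dimensions
make_blobs <- function(n_per = 20, centers = rbind(c(0, 0), c(8, 8)),
                       sd = 0.4, seed = 1) {
  withr::with_seed(seed, {
    x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
      matrix(rnorm(n_per * ncol(centers), sd = sd), ncol = ncol(centers)) +
        rep(centers[i, ], each = n_per)
    }))
    list(data = x, labels = rep(seq_len(nrow(centers)), each = n_per))
  })
}

random_labels <- function(n, k, seed) {
  withr::with_seed(seed, {
    # ensure all k labels appear
    l <- c(seq_len(k), sample.int(k, n - k, replace = TRUE))
    sample(l)
  })
}
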