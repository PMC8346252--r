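# Independent oracles used to cross-check package operations. Each is a
# deliberately different code path from the implementation it verifies.

# Step-up Benjamini-Hochberg, written from the definition: order p, compute
# p_(i) * m / i, take cumulative minima from the largest rank down.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Triad scoring by direct window enumeration with a set-equality check.
oracle_alternation <- function(entries) {
  n <- length(entries)
  if (n < 3) return(NA_real_)
  triads <- 0
  for (i in 1:(n - 2)) {
    w <- entries[i:(i + 2)]
    if (identical(sort(w), c("A", "B", "C"))) triads <- triads + 1
  }
  100 * triads / (n - 2)
}

# All arm-entry sequences of length n without immediate re-entries.
all_valid_sequences <- function(n, arms = c("A", "B", "C")) {
  seqs <- as.list(arms)
  for (i in seq_len(n - 1)) {
    seqs <- unlist(lapply(seqs, function(s) {
      lapply(setdiff(arms, s[length(s)]), function(a) c(s, a))
    }), recursive = FALSE)
  }
  seqs
}

# Train assembly by explicit enumeration: walk the spike list, growing the
# current train while each consecutive gap lies in the ISI window; close the
# train otherwise; afterwards repeatedly fuse neighboring trains whose
# boundary gap is below the join interval; finally filter.
oracle_trains <- function(times, params) {
  if (!length(times)) return(list())
  trains <- list(times[1])
  for (t in times[-1]) {
    last <- trains[[length(trains)]]
    gap <- t - last[length(last)]
    if (gap >= params$inter_spike_interval_s[1] &&
        gap <= params$inter_spike_interval_s[2]) {
      trains[[length(trains)]] <- c(last, t)
    } else {
      trains[[length(trains) + 1]] <- t
    }
  }
  repeat {
    fused <- FALSE
    if (length(trains) > 1) {
      for (i in seq_len(length(trains) - 1)) {
        a <- trains[[i]]; b <- trains[[i + 1]]
        if (b[1] - a[length(a)] < params$join_interval_s) {
          trains[[i]] <- c(a, b)
          trains[[i + 1]] <- NULL
          fused <- TRUE
          break
        }
      }
    }
    if (!fused) break
  }
  Filter(function(tr) {
    length(tr) >= params$min_spikes &&
      (tr[length(tr)] - tr[1]) >= params$train_min_duration_s
  }, trains)
}

# Classical two-way fixed-effects sum-of-squares decomposition on a balanced
# design, computed from cell/marginal means.
oracle_anova2 <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  a <- nlevels(A); b <- nlevels(B)
  n <- length(y) / (a * b)
  gm <- mean(y)
  mA <- tapply(y, A, mean)
  mB <- tapply(y, B, mean)
  mAB <- tapply(y, interaction(A, B), mean)
  ss_a <- b * n * sum((mA - gm)^2)
  ss_b <- a * n * sum((mB - gm)^2)
  cellA <- rep(levels(A), times = b)
  cellB <- rep(levels(B), each = a)
  ss_ab <- n * sum((mAB - mA[cellA] - mB[cellB] + gm)^2)
  ss_e <- sum((y - mAB[interaction(A, B)])^2)
  df_a <- a - 1; df_b <- b - 1; df_ab <- df_a * df_b
  df_e <- length(y) - a * b
  F_a <- (ss_a / df_a) / (ss_e / df_e)
  F_b <- (ss_b / df_b) / (ss_e / df_e)
  F_ab <- (ss_ab / df_ab) / (ss_e / df_e)
  list(F = c(genotype = F_a, age = F_b, interaction = F_ab),
       p = c(genotype = pf(F_a, df_a, df_e, lower.tail = FALSE),
             age = pf(F_b, df_b, df_e, lower.tail = FALSE),
             interaction = pf(F_ab, df_ab, df_e, lower.tail = FALSE)))
}

# Ordinary least squares via the normal equations, one gene at a time.
oracle_ols <- function(y, X) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}
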