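# Independent oracles shared across test files. These deliberately avoid
# the package's own code paths.

# Hubert-Arabie adjusted Rand index
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  (sum(choose(tab, 2)) - expected) / ((si + sj) / 2 - expected)
}

# scalar pCASL kinetic-model oracle (times in seconds)
asl_oracle <- function(dm, m0, lambda, alpha, t1a, pld, dur) {
  6000 * lambda * dm * exp(pld / t1a) /
    (2 * alpha * m0 * t1a * (1 - exp(-dur / t1a)))
}

# brute-force profile search for a single breakpoint
grid_psi_oracle <- function(x, y, step = 0.05) {
  grid <- seq(min(x) + step, max(x) - step, by = step)
  grid <- grid[vapply(grid, function(p)
    sum(x <= p) >= 3 && sum(x > p) >= 3, logical(1))]
  rss <- vapply(grid, function(p) {
    X <- cbind(1, x, pmax(x - p, 0))
    sum(stats::lm.fit(X, y)$residuals^2)
  }, numeric(1))
  grid[which.min(rss)]
}

# textbook validity-index oracles written independently of the package
db_oracle <- function(features, labels) {
  labs <- sort(unique(labels))
  K <- length(labs)
  cent <- lapply(labs, function(l) colMeans(features[labels == l, , drop = FALSE]))
  s <- vapply(seq_len(K), function(i) {
    pts <- features[labels == labs[i], , drop = FALSE]
    mean(sqrt(colSums((t(pts) - cent[[i]])^2)))
  }, numeric(1))
  total <- 0
  for (i in seq_len(K)) {
    worst <- -Inf
    for (j in seq_len(K)) {
      if (i == j) next
      d <- sqrt(sum((cent[[i]] - cent[[j]])^2))
      worst <- max(worst, (s[i] + s[j]) / d)
    }
    total <- total + worst
  }
  total / K
}

ch_oracle <- function(features, labels) {
  labs <- sort(unique(labels))
  K <- length(labs)
  N <- nrow(features)
  grand <- colMeans(features)
  ssb <- 0; ssw <- 0
  for (l in labs) {
    pts <- features[labels == l, , drop = FALSE]
    cen <- colMeans(pts)
    ssb <- ssb + nrow(pts) * sum((cen - grand)^2)
    ssw <- ssw + sum((t(pts) - cen)^2)
  }
  (ssb / (K - 1)) / (ssw / (N - K))
}

# recursive flood fill over a logical 3D array (26-connectivity)
floodfill_oracle <- function(supra) {
  dims <- dim(supra)
  lab <- array(0L, dims)
  cur <- 0L
  idx <- which(supra)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      v <- stack[1]; stack <- stack[-1]
      ai <- arrayInd(v, dims)
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        p <- ai + c(dx, dy, dz)
        if (any(p < 1) || any(p > dims)) next
        l <- p[1] + (p[2] - 1) * dims[1] + (p[3] - 1) * dims[1] * dims[2]
        if (supra[l] && lab[l] == 0L) { lab[l] <- cur; stack <- c(stack, l) }
      }
    }
  }
  lab
}

small_cohort <- function(seed = 1, n = 40) {
  generate_cohort(generator_config(n_subjects = n,
                                   grid_shape = c(12, 14, 12),
                                   seed = seed))
}
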