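# Independent oracles used across the suite. Each is a deliberately naive
# reimplementation, kept separate from the package's own code paths.

# Medcouple by literal enumeration of the kernel definition: all pairs
# (xi <= m, xj >= m), special -1/0/+1 kernel for pairs tied at the median.
mc_enumeration_oracle <- function(x) {
  x <- sort(x)
  m <- median(x)
  left <- x[x <= m]
  right <- x[x >= m]
  k <- sum(x == m)
  hs <- c()
  for (a in seq_along(left)) {
    for (b in seq_along(right)) {
      lo <- left[a]; hi <- right[b]
      if (hi != lo) {
        hs <- c(hs, ((hi - m) - (m - lo)) / (hi - lo))
      } else {
        i <- a - (length(left) - k)
        j <- b
        hs <- c(hs, if (i + j - 1 < k) -1 else if (i + j - 1 == k) 0 else 1)
      }
    }
  }
  median(hs)
}

# PCA eigenvalues of population-standardized data by brute-force
# eigendecomposition of the divisor-n covariance matrix.
pca_pop_oracle <- function(X) {
  Z <- apply(X, 2, function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2)))
  eigen(crossprod(Z) / nrow(Z), symmetric = TRUE)$values
}

# Bounded (uniform-marginal) mixed table with 2 latent dimensions: no value
# can fall outside the adjusted fences of a uniform distribution, so the
# only univariate outliers are ones injected explicitly.
bounded_cohort <- function(n = 150, seed = 1) {
  set.seed(seed)
  L <- matrix(rnorm(n * 2), n, 2)
  B <- rbind(c(1, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, 1), c(0, -1), c(0.3, 0.3))
  X <- L %*% t(B) + matrix(rnorm(n * 7, sd = 0.45), n, 7)
  U <- apply(X, 2, function(v) pnorm(v, sd = sd(v)))
  df <- as.data.frame(U)
  names(df) <- paste0("v", 1:7)
  df$g1 <- factor(ifelse(runif(n) < plogis(L[, 1]), "yes", "no"))
  df$g2 <- factor(ifelse(runif(n) < plogis(L[, 2]), "yes", "no"))
  df$donor_id <- sprintf("B%03d", seq_len(n))
  df
}
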