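# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# per-label masked means by explicit looping over voxels
oracle_regional_means <- function(values, labels, k) {
  out <- rep(NA_real_, k)
  for (lab in seq_len(k)) {
    acc <- c()
    for (i in seq_along(labels)) {
      if (labels[i] == lab && !is.na(values[i])) acc <- c(acc, values[i])
    }
    if (length(acc)) out[lab] <- sum(acc) / length(acc)
  }
  out
}

# two-pass voxelwise mean and population/sample SD over a list of arrays
oracle_mean_sd <- function(arrays, population = TRUE) {
  n <- length(arrays)
  mu <- Reduce(`+`, arrays) / n
  ss <- Reduce(`+`, lapply(arrays, function(a) (a - mu)^2))
  list(mean = mu, sd = sqrt(ss / if (population) n else n - 1))
}

# exhaustive BH step-up: adjusted p_i = min over j >= rank(i) of p_(j)*m/j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    cand <- sorted[i:m] * m / (i:m)
    adj[o[i]] <- min(1, min(cand))
  }
  adj
}

# pooled-variance two-sample t from first principles
oracle_pooled_t <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / (n1 + n2 - 2)
  (mean(x2) - mean(x1)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# discrete 1-D Gaussian kernel weights used by the closed-form smoothing
# oracle (same definition as the mathematical spec of the operation)
oracle_gaussian_weights <- function(sigma_vox) {
  radius <- max(1L, ceiling(4 * sigma_vox))
  w <- exp(-(-radius:radius)^2 / (2 * sigma_vox^2))
  w / sum(w)
}

rand_volume <- function(dims = c(8, 8, 8), voxel = 2, modality = "gm",
                        fun = stats::runif) {
  volume_grid(array(fun(prod(dims)), dim = dims), voxel, modality)
}

# small fully latent cohort frame for statistics tests
tiny_frame <- function(seed = 1, n = 12) {
  set.seed(seed)
  ids <- sprintf("S%02d", 1:n)
  grp <- rep(c("intervention", "control"), each = n / 2)
  pre <- rnorm(n, 100, 4)
  post <- pre + rnorm(n, 0.3, 1.5)
  rbind(data.frame(participant = ids, group = grp, time = "pre",
                   measure = "m", value = pre),
        data.frame(participant = ids, group = grp, time = "post",
                   measure = "m", value = post))
}
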