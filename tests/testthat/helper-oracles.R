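# Independent oracles used by the test suite.  Each is written from first
# principles on a different code path from the implementation it checks.

# Exact HWE p-value by enumeration over heterozygote counts using the
# downward probability recurrence (the implementation uses log-factorials).
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  rare <- min(2 * n_hom_alt + n_het, 2 * n_hom_ref + n_het)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(hets))
  probs[length(hets)] <- 1
  for (i in rev(seq_along(hets))[-1]) {
    h <- hets[i + 1]
    n_rare_hom <- (rare - h) / 2
    n_comm_hom <- n - (rare + h) / 2
    probs[i] <- probs[i + 1] * h * (h - 1) /
      (4 * (n_rare_hom + 1) * (n_comm_hom + 1))
  }
  probs <- probs / sum(probs)
  obs <- which(hets == n_het)
  sum(probs[probs <= probs[obs] * (1 + 1e-12)])
}

# Brute-force profiled REML over a heritability grid, dense linear algebra
# with explicit inverses and determinants.
grid_reml_oracle <- function(y, x, a_mat, step = 0.001) {
  n <- length(y)
  cc <- ncol(x)
  h2s <- seq(0, 1, by = step)
  lls <- vapply(h2s, function(h2) tryCatch({
    v0 <- h2 * a_mat + (1 - h2) * diag(n)
    vi <- solve(v0)
    xtvix <- t(x) %*% vi %*% x
    p0 <- vi - vi %*% x %*% solve(xtvix) %*% t(x) %*% vi
    q <- drop(t(y) %*% p0 %*% y)
    shat <- q / (n - cc)
    ld <- as.numeric(determinant(v0, logarithm = TRUE)$modulus)
    ldb <- as.numeric(determinant(xtvix, logarithm = TRUE)$modulus)
    -0.5 * (ld + ldb + (n - cc) * log(shat) + (n - cc))
  }, error = function(e) -Inf),         # singular V0: outside the PD region
  numeric(1))
  best <- which.max(lls)
  structure(list(h2 = h2s[best], ll = lls[best]), lls = lls)
}

# Direct dense 3D Gaussian convolution with reflect boundary (edge repeated):
# out-of-range position p maps to 1 - p below, 2n + 1 - p above.
reflect_idx <- function(p, n) {
  while (any(p < 1) || any(p > n)) {
    p <- ifelse(p < 1, 1 - p, p)
    p <- ifelse(p > n, 2 * n + 1 - p, p)
  }
  p
}

smooth_oracle <- function(vol, sigma = 0.5, truncate = 4) {
  r <- as.integer(truncate * sigma + 0.5)
  t1 <- seq(-r, r)
  w1 <- exp(-t1^2 / (2 * sigma^2))
  w1 <- w1 / sum(w1)
  k3 <- outer(outer(w1, w1), w1)
  dims <- dim(vol)
  out <- array(0, dims)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) {
    for (k in seq_len(dims[3])) {
      acc <- 0
      for (a in seq_along(t1)) for (b in seq_along(t1)) {
        for (d3 in seq_along(t1)) {
          acc <- acc + k3[a, b, d3] *
            vol[reflect_idx(i + t1[a], dims[1]),
                reflect_idx(j + t1[b], dims[2]),
                reflect_idx(k + t1[d3], dims[3])]
        }
      }
      out[i, j, k] <- acc
    }
  }
  out
}

# Breadth-first flood fill labeling of a binary 3D array.
flood_fill_oracle <- function(vol, connectivity = 26) {
  dims <- dim(vol)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  ord <- switch(as.character(connectivity), "6" = 1, "18" = 2, "26" = 3)
  offs <- offs[rowSums(abs(offs)) <= ord, , drop = FALSE]
  labels <- array(0L, dims)
  nxt <- 0L
  idx <- which(vol != 0)
  coords <- arrayInd(idx, dims)
  scan <- coords[order(coords[, 1], coords[, 2], coords[, 3]), , drop = FALSE]
  for (s in seq_len(nrow(scan))) {
    start <- scan[s, ]
    if (labels[start[1], start[2], start[3]] != 0) next
    nxt <- nxt + 1L
    queue <- matrix(start, ncol = 3)
    head <- 1L
    labels[start[1], start[2], start[3]] <- nxt
    while (head <= nrow(queue)) {
      cur <- queue[head, ]
      head <- head + 1L
      for (o in seq_len(nrow(offs))) {
        nb <- cur + offs[o, ]
        if (any(nb < 1) || any(nb > dims)) next
        if (vol[nb[1], nb[2], nb[3]] != 0 &&
            labels[nb[1], nb[2], nb[3]] == 0L) {
          labels[nb[1], nb[2], nb[3]] <- nxt
          queue <- rbind(queue, nb)
        }
      }
    }
  }
  labels
}

# canonical partition signature: sorted list of sorted member index sets
partition_signature <- function(labels) {
  idx <- which(labels != 0)
  sets <- split(idx, labels[idx])
  unname(sets[order(vapply(sets, min, numeric(1)))])
}

# small random fixture: genotypes + GRM + covariates + simulated phenotype
make_reml_fixture <- function(n = 40, m = 200, h2 = 0.5, seed = 1) {
  d <- simulation_design(n_samples = n, n_variants = m,
                         n_blocks = max(1L, n %/% 8L), block_size = 8L,
                         seed = seed)
  g <- qc_filter(simulate_genotypes(d))$genotypes
  a <- compute_grm(g)
  nn <- length(a$samples)
  set.seed(seed + 1000)
  covs <- data.frame(sample_id = a$samples,
                     age = rnorm(nn, 77, 7), sex = rbinom(nn, 1, 0.5))
  x <- build_covariates(covs)
  es <- eigen(a$values, symmetric = TRUE)
  l <- es$vectors %*% diag(sqrt(pmax(es$values, 0)))
  u <- drop(l %*% rnorm(nn)); u <- (u - mean(u)) / sd(u)
  e <- rnorm(nn); e <- (e - mean(e)) / sd(e)
  y <- sqrt(h2) * u + sqrt(1 - h2) * e + 0.01 * covs$age
  list(y = y, x = x, a = a, g = g)
}
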