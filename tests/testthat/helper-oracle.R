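# Exhaustive transmission-vector oracle for nuclear families.
#
# Enumerates every equiprobable combination of (paternal allele, maternal
# allele) choices per offspring per variant and returns exact conditional
# moments of the (weighted) offspring pseudo-count X and of the family
# score u = sum_j T_j (X_j - E[X_j]).  Independent of the package's moment
# formulas: it only uses the Mendelian transmission law.
enumerate_family <- function(father, mother, traits,
                             weights = rep(1, length(father))) {
  M <- length(father)
  n <- length(traits)
  stopifnot(length(mother) == M, length(weights) == M, 4^(n * M) <= 2^20)
  al <- function(cnt) switch(cnt + 1L, c(0L, 0L), c(0L, 1L), c(1L, 1L))
  # the 4 equiprobable transmitted counts for variant k
  cell <- lapply(seq_len(M), function(k) {
    as.vector(outer(al(father[k]), al(mother[k]), "+"))
  })
  grid <- as.matrix(expand.grid(rep(list(1:4), n * M)))
  X <- matrix(0, nrow(grid), n)
  for (j in seq_len(n)) {
    for (k in seq_len(M)) {
      X[, j] <- X[, j] + weights[k] * cell[[k]][grid[, (j - 1L) * M + k]]
    }
  }
  ex <- mean(X[, 1L])
  varx <- mean(X[, 1L]^2) - ex^2
  u <- as.vector(X %*% traits) - sum(traits) * ex
  list(expected_x = ex, var_x = varx,
       e_u = mean(u), var_u = mean(u^2) - mean(u)^2,
       outcomes_x = X, outcomes_u = u)
}
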