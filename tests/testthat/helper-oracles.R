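# Independent oracles, deliberately implemented differently from the
# package internals.

# Brute-force coancestry (kinship) by recursive ancestor-path expansion
# with memoisation; A = 2 * Theta.
kinship_oracle_matrix <- function(ped) {
  n <- nrow(ped)
  s <- ped$sire_idx
  d <- ped$dam_idx
  memo <- new.env(parent = emptyenv())
  kin <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    key <- paste(min(i, j), max(i, j))
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- if (i == j) {
      0.5 * (1 + kin(s[i], d[i]))
    } else if (i > j) {
      0.5 * (kin(s[i], j) + kin(d[i], j))
    } else {
      0.5 * (kin(s[j], i) + kin(d[j], i))
    }
    memo[[key]] <- val
    val
  }
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(i)) {
    A[i, j] <- A[j, i] <- 2 * kin(i, j)
  }
  dimnames(A) <- list(ped$animal, ped$animal)
  A
}

# Dense-V restricted log-likelihood: independent of the sparse MME path.
dense_reml_loglik <- function(design, ped, s2a, s2pe, s2e) {
  A <- relationship_matrix(ped)
  Z <- as.matrix(design$Tm[, design$p + design$ql + seq_len(design$qa)])
  W <- as.matrix(design$Tm[, design$p + seq_len(design$ql)])
  X <- design$X
  y <- design$y
  n <- design$n
  p <- design$p
  V <- s2a * Z %*% A %*% t(Z) + s2pe * tcrossprod(W) + s2e * diag(n)
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  b <- solve(XVX, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  -0.5 * ((n - p) * log(2 * pi) + determinant(V)$modulus[1] +
            determinant(XVX)$modulus[1] + drop(t(r) %*% Vi %*% y))
}

# random but valid pedigree: founders then generations of random matings
random_pedigree <- function(n_animals, n_founders = 12L, seed = 1L) {
  set.seed(seed)
  animal <- sprintf("A%03d", seq_len(n_animals))
  sire <- dam <- rep(NA_character_, n_animals)
  for (i in seq((n_founders + 1L), n_animals)) {
    pool <- seq_len(i - 1L)
    pick <- sample(pool, 2L)
    sire[i] <- animal[pick[1]]
    dam[i] <- animal[pick[2]]
  }
  validate_pedigree(animal, sire, dam)
}
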