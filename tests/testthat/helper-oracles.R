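# Independent reference implementations used to cross-check the package.
# These deliberately take the slow, obvious route.

# Horn's quaternion characteristic-polynomial method: optimal superposition
# RMSD from the largest eigenvalue of the 4x4 key matrix. Independent of the
# SVD route used by superpose().
quaternion_rmsd <- function(mobile, reference) {
  a <- sweep(mobile, 2, colMeans(mobile))
  b <- sweep(reference, 2, colMeans(reference))
  s <- t(a) %*% b
  sxx <- s[1, 1]; sxy <- s[1, 2]; sxz <- s[1, 3]
  syx <- s[2, 1]; syy <- s[2, 2]; syz <- s[2, 3]
  szx <- s[3, 1]; szy <- s[3, 2]; szz <- s[3, 3]
  k <- matrix(c(
    sxx + syy + szz, syz - szy, szx - sxz, sxy - syx,
    syz - szy, sxx - syy - szz, sxy + syx, szx + sxz,
    szx - sxz, sxy + syx, -sxx + syy - szz, syz + szy,
    sxy - syx, szx + sxz, syz + szy, -sxx - syy + szz
  ), 4, 4, byrow = TRUE)
  lambda <- max(eigen(k, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(a^2) + sum(b^2) - 2 * lambda) / nrow(a)
  sqrt(max(msd, 0))
}

# Exhaustive enumeration of every monotone warping path (steps (1,0), (0,1),
# (1,1), fixed endpoints, band |i-j| <= window); returns the minimal total
# |a_i - b_j| cost. Only feasible for short series.
dtw_enumerate_cost <- function(a, b, window) {
  n <- length(a); m <- length(b)
  best <- Inf
  recurse <- function(i, j, acc) {
    if (window > 0 && abs(i - j) > window) return(invisible())
    acc <- acc + abs(a[i] - b[j])
    if (acc >= best) return(invisible())
    if (i == n && j == m) {
      best <<- acc
      return(invisible())
    }
    if (i < n && j < m) recurse(i + 1, j + 1, acc)
    if (i < n) recurse(i + 1, j, acc)
    if (j < m) recurse(i, j + 1, acc)
  }
  recurse(1, 1, 0)
  best
}

# Memoised top-down recursion for the same minimum; independent of the
# bottom-up banded C++ kernel, usable up to ~20 frames.
dtw_recursive_cost <- function(a, b, window) {
  n <- length(a); m <- length(b)
  memo <- matrix(NA_real_, n, m)
  visit <- function(i, j) {
    if (i < 1 || j < 1) return(Inf)
    if (window > 0 && abs(i - j) > window) return(Inf)
    if (!is.na(memo[i, j])) return(memo[i, j])
    cost <- abs(a[i] - b[j])
    val <- if (i == 1 && j == 1) {
      cost
    } else {
      cost + min(visit(i - 1, j - 1), visit(i - 1, j), visit(i, j - 1))
    }
    memo[i, j] <<- val
    val
  }
  visit(n, m)
}

# Plugin mutual information (bits) straight from the contingency table.
mi_from_table <- function(residues, labels) {
  keep <- residues != "-"
  tab <- table(residues[keep], labels[keep])
  n <- sum(tab)
  mi <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      if (tab[i, j] > 0) {
        pij <- tab[i, j] / n
        mi <- mi + pij * log2(pij / (sum(tab[i, ]) / n * sum(tab[, j]) / n))
      }
    }
  }
  mi
}

# small rigid helpers -------------------------------------------------------

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

rigid_move <- function(coords, rot, shift) {
  sweep(coords %*% rot, 2, shift, `+`)
}

# tiny toy protein topology with a few titratable residues
toy_topology <- function() {
  tibble::tibble(
    chain = c("A", "A", "A", "B", "B", "B", "B"),
    resno = c(1L, 2L, 3L, 1L, 2L, 3L, 4L),
    resname = c("ASP", "GLY", "LYS", "SER", "GLU", "HIS", "ALA"),
    atom = "CA", element = "C"
  )
}
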