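# Independent oracles used to cross-check the implementation.

# Optimal superposition RMSD via the quaternion characteristic matrix
# (Horn's method): the largest eigenvalue of the 4x4 key matrix gives the
# best proper rotation without ever constructing it, so this shares no code
# path with the SVD-based Kabsch fit it checks.
oracle_rmsd_quaternion <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  S <- crossprod(Qc, Pc) # S[a, b] = sum_i q_ia * p_ib
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  e0 <- sum(Pc^2) + sum(Qc^2)
  sqrt(max(0, e0 - 2 * lam) / nrow(P))
}

# All-pairs O(n^2) clash finder: the reference for the grid-based
# clash_report. Returns sorted "i-j" pair keys.
oracle_clash_pairs <- function(model, cutoff) {
  a <- model$atoms
  X <- as.matrix(a[, c("x", "y", "z")])
  d <- as.matrix(dist(X))
  hit <- which(d < cutoff, arr.ind = TRUE)
  hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  keep <- !(a$chain_id[hit[, 1]] == a$chain_id[hit[, 2]] &
              abs(a$residue_number[hit[, 1]] - a$residue_number[hit[, 2]]) < 3)
  hit <- hit[keep, , drop = FALSE]
  sort(paste(hit[, 1], hit[, 2], sep = "-"))
}

# Direct window-sum hydropathy (loop form), independent of the cumsum
# implementation.
oracle_hydropathy <- function(seq, window) {
  l <- strsplit(seq, "")[[1]]
  h <- unname(kd_scale()[l])
  h[l == "X"] <- 0
  n <- length(h)
  half <- (window - 1) / 2
  out <- rep(NA_real_, n)
  for (i in (half + 1):(n - half)) out[i] <- mean(h[(i - half):(i + half)])
  out
}

# rotation by `angle` radians about z
rot_z <- function(angle) {
  matrix(c(cos(angle), -sin(angle), 0,
           sin(angle),  cos(angle), 0,
           0,           0,          1), 3, 3, byrow = TRUE)
}

random_proper_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}
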