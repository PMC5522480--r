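# Independent oracles used by the tests. Deliberately written with
# different algorithms from the package code paths they check.

# Horn quaternion superposition RMSD (vs the package's Kabsch/SVD route)
quaternion_rmsd <- function(A, B) {
  stopifnot(nrow(A) == nrow(B))
  n <- nrow(A)
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  S <- t(Ac) %*% Bc
  K <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(Ac^2) + sum(Bc^2) - 2 * lam) / n
  sqrt(max(msd, 0))
}

# brute-force enumeration of geometric backbone-backbone H-bonds: all
# (N-H of residue i, O of residue j) pairs, plain loops, no bookkeeping
brute_force_bb_hbonds <- function(conf, dist_cutoff = 0.35,
                                  angle_cutoff = 30) {
  at <- conf$model$atoms
  xyz <- conf$xyz
  n <- conf$model$n_residues
  found <- NULL
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      Ni <- xyz[at$residue == i & at$name == "N", ]
      Hi <- xyz[at$residue == i & at$name == "H", ]
      Oj <- xyz[at$residue == j & at$name == "O", ]
      d <- sqrt(sum((Ni - Oj)^2))
      v1 <- Hi - Ni; v2 <- Oj - Ni
      ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      if (d <= dist_cutoff && ang <= angle_cutoff)
        found <- rbind(found, c(donor_res = i, acceptor_res = j))
    }
  }
  found
}

# rigid rotation about a random axis plus translation (seeded)
random_rigid_motion <- function(xyz, seed) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, 2 * pi)
  Kx <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * Kx + (1 - cos(th)) * Kx %*% Kx
  sweep(xyz %*% t(R), 2, rnorm(3), `+`)
}
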