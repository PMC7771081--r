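# Shared fixtures, all built in code.

# Minimal PDB writer for hand-built test structures.
pdb_atom_line <- function(serial, name, res, chain, resno, x, y, z,
                          occ = 1, alt = "") {
  sprintf("ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %1s",
          serial, name, alt, res, chain, resno, x, y, z, occ, 0,
          substr(name, 1, 1))
}

write_toy_pdb <- function(path, lines) {
  writeLines(c(lines, "END"), path)
  path
}

# A proper rotation about z by theta plus translation.
rigid_motion <- function(X, theta = 0.7, shift = c(5, -2, 7)) {
  R <- matrix(c(cos(theta), sin(theta), 0,
                -sin(theta), cos(theta), 0,
                0, 0, 1), 3, 3)
  sweep(X %*% t(R), 2, shift, "+")
}

random_probability_matrix <- function(LT, LQ) {
  matrix(stats::runif(LT * LQ, 0.001, 0.999), LT, LQ)
}

# Independent eigen-pair feature oracle: explicit loops over k, i, j with
# its own dense eigendecomposition and |lambda|-descending selection.
eigen_pair_oracle <- function(MT, MQ, K) {
  sel <- function(M) {
    e <- eigen(M, symmetric = TRUE)
    ord <- order(-abs(e$values), -e$values)
    k_eff <- min(K, nrow(M))
    lam <- numeric(K); vec <- matrix(0, K, nrow(M))
    for (k in seq_len(k_eff)) {
      lam[k] <- e$values[ord[k]]
      vec[k, ] <- e$vectors[, ord[k]]
    }
    list(lam = lam, vec = vec)
  }
  eT <- sel(MT); eQ <- sel(MQ)
  out <- array(0, dim = c(nrow(MT), nrow(MQ), K))
  for (k in seq_len(K))
    for (i in seq_len(nrow(MT)))
      for (j in seq_len(nrow(MQ)))
        out[i, j, k] <- sqrt(abs(eT$lam[k] * eQ$lam[k])) *
          abs(eT$vec[k, i]) * abs(eQ$vec[k, j])
  out
}
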