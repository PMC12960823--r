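# Independent oracles and small builders shared across the test files.

# Quaternion (Horn) optimal superposition: an implementation independent of
# the SVD-based Kabsch path. Returns the minimal RMSD of a onto b over all
# proper rotations + translations.
quaternion_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  ac <- sweep(a, 2L, colMeans(a)); bc <- sweep(b, 2L, colMeans(b))
  m <- crossprod(ac, bc)   # sum over points of a_i b_i^T
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  k <- matrix(c(
    sxx + syy + szz, syz - szy,       szx - sxz,       sxy - syx,
    syz - szy,       sxx - syy - szz, sxy + syx,       szx + sxz,
    szx - sxz,       sxy + syx,       -sxx + syy - szz, syz + szy,
    sxy - syx,       szx + sxz,       syz + szy,       -sxx - syy + szz),
    4L, 4L, byrow = TRUE)
  lam <- max(eigen(k, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(ac^2) + sum(bc^2) - 2 * lam) / nrow(a)
  sqrt(max(msd, 0))
}

# Random non-degenerate C-alpha model.
random_model <- function(n, seed = 1, chains = "A", scale = 10) {
  set.seed(seed)
  calpha_model(matrix(stats::rnorm(3 * n, sd = scale), n, 3L),
               chain = rep(chains, length.out = n),
               resno = seq_len(n))
}

# Minimal PDB text builder. `rows` is a data.frame with columns
# resno, x, y, z and optional chain, alt, occ, type, resid.
pdb_text <- function(rows) {
  n <- nrow(rows)
  ch <- if (is.null(rows$chain)) rep("A", n) else rows$chain
  alt <- if (is.null(rows$alt)) rep(" ", n) else rows$alt
  occ <- if (is.null(rows$occ)) rep(1, n) else rows$occ
  typ <- if (is.null(rows$type)) rep("ATOM", n) else rows$type
  aa <- if (is.null(rows$resid)) rep("ALA", n) else rows$resid
  c(sprintf("%-6s%5d  CA %1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f  0.00           C",
            typ, seq_len(n), alt, aa, ch, rows$resno,
            rows$x, rows$y, rows$z, occ),
    "END")
}

write_pdb_text <- function(rows, path = tempfile(fileext = ".pdb")) {
  writeLines(pdb_text(rows), path)
  path
}

# Random proper rotation + translation of row coordinates.
rotate_random <- function(xyz) {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, 2 * pi)
  k <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  r <- diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
  sweep(xyz %*% r, 2L, stats::rnorm(3, sd = 20), "+")
}

# All-pairs harmonic force oracle: plain double loop, no pair list.
brute_force_forces <- function(topology, xyz) {
  f <- matrix(0, nrow(xyz), 3L)
  p <- topology$pairs
  for (r in seq_len(nrow(p))) {
    i <- p$i[r]; j <- p$j[r]
    dv <- xyz[j, ] - xyz[i, ]
    d <- sqrt(sum(dv^2))
    fm <- p$k[r] * (d - p$d0[r]) / d
    f[i, ] <- f[i, ] + fm * dv
    f[j, ] <- f[j, ] - fm * dv
  }
  f
}

# Central-difference gradient of the potential energy.
numeric_gradient <- function(topology, xyz, h = 1e-6) {
  g <- matrix(0, nrow(xyz), 3L)
  for (i in seq_len(nrow(xyz))) for (c in 1:3) {
    xp <- xyz; xp[i, c] <- xp[i, c] + h
    xm <- xyz; xm[i, c] <- xm[i, c] - h
    g[i, c] <- (potential_energy(topology, xp) -
                potential_energy(topology, xm)) / (2 * h)
  }
  g
}
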