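# Hinge amplitude (degrees) of the canonical 60-residue benchmark fixture;
# set so the superposed end-state RMSD is ~8 Angstrom.
HINGE_STUDY_AMPLITUDE <- 61

#' Synthetic two-state C-alpha fixtures
#'
#' Generates idealized two-state coarse-grained systems with known ground
#' truth, emulating the classic motion taxonomy (hinge bending, rotor
#' twisting, breathing, plus two displacement fields used to calibrate the
#' collectivity measure). Chains are compact helical coils (or, optionally,
#' gently curved extended strands) with exact `spacing` between consecutive
#' beads in both end states (except for the deliberately local
#' `single_residue` motion, which displaces one bead). All motions are
#' rigid transformations of whole segments, so ground-truth displacement
#' fields are exact.
#'
#' Motions:
#' * `hinge`: rotate the distal half of each chain about an axis through its
#'   midpoint bead; `amplitude` in degrees.
#' * `rotor`: rotate the last chain (or the whole model when there is a
#'   single chain) about the global z axis; `amplitude` in degrees.
#' * `breathing`: translate every chain radially away from the z axis;
#'   `amplitude` in Angstrom; needs >= 2 chains.
#' * `uniform_translation`: translate everything by `(amplitude, 0, 0)`.
#' * `single_residue`: displace the last bead by `amplitude` Angstrom.
#'
#' @param n_residues beads per chain.
#' @param chains number of chains (labelled A, B, ...).
#' @param motion one of the motions above.
#' @param amplitude degrees (rotations) or Angstrom (translations).
#' @param spacing consecutive C-alpha spacing, Angstrom (default 3.8).
#' @param geometry chain geometry: `"helix"` (default) is a compact
#'   alpha-helix-like coil whose dense local contacts and strong chirality
#'   mimic real secondary structure; `"extended"` is a gently curved open
#'   strand with sparse contacts.
#' @param turn_deg in-plane curvature of the `"extended"` strand, degrees
#'   per residue (default 2; keeps the chain non-collinear).
#' @return list with `start` and `target` ([calpha_model()]s sharing residue
#'   keys), ground-truth `rmsd` and `kappa` of the as-constructed
#'   displacement field (no superposition), and the motion parameters.
#' @export
make_two_state <- function(n_residues = 60L, chains = 1L,
                           motion = c("hinge", "rotor", "breathing",
                                      "uniform_translation",
                                      "single_residue"),
                           amplitude = 30, spacing = 3.8,
                           geometry = c("helix", "extended"),
                           turn_deg = 2) {
  motion <- match.arg(motion)
  geometry <- match.arg(geometry)
  if (spacing <= 0) stop("spacing must be > 0", call. = FALSE)
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  start <- fixture_base(n_residues, chains, spacing, turn_deg, geometry)
  xyz <- start$xyz

  tgt <- xyz
  if (motion == "hinge") {
    for (ch in unique(start$chain)) {
      idx <- which(start$chain == ch)
      hinge <- idx[max(2L, ceiling(length(idx) / 2))]
      distal <- idx[idx > hinge]
      tang <- xyz[hinge, ] - xyz[hinge - 1L, ]
      axis <- normalize3(cross3(tang, c(0, 0, 1)))
      tgt[distal, ] <- rotate_about(xyz[distal, , drop = FALSE],
                                    xyz[hinge, ], axis, amplitude)
    }
  } else if (motion == "rotor") {
    idx <- if (chains == 1L) seq_len(nrow(xyz))
           else which(start$chain == utils::tail(unique(start$chain), 1L))
    center <- if (chains == 1L) colMeans(xyz[idx, , drop = FALSE])
              else c(0, 0, 0)
    center[3L] <- 0
    tgt[idx, ] <- rotate_about(xyz[idx, , drop = FALSE], center,
                               c(0, 0, 1), amplitude)
  } else if (motion == "breathing") {
    if (chains < 2L)
      stop("breathing needs at least 2 chains", call. = FALSE)
    for (ch in unique(start$chain)) {
      idx <- which(start$chain == ch)
      cen <- colMeans(xyz[idx, , drop = FALSE])
      dir <- normalize3(c(cen[1L], cen[2L], 0))
      tgt[idx, ] <- sweep(xyz[idx, , drop = FALSE], 2L, amplitude * dir, "+")
    }
  } else if (motion == "uniform_translation") {
    tgt <- sweep(xyz, 2L, c(amplitude, 0, 0), "+")
  } else if (motion == "single_residue") {
    last <- nrow(xyz)
    tang <- xyz[last, ] - xyz[last - 1L, ]
    dir <- normalize3(cross3(tang, c(0, 0, 1)))
    tgt[last, ] <- xyz[last, ] + amplitude * dir
  }

  check_self_intersection(tgt, start$chain, start$resno)
  target <- set_coords(start, tgt)
  disp <- sqrt(rowSums((tgt - xyz)^2))
  gt_rmsd <- sqrt(mean(disp^2))
  gt_kappa <- if (sum(disp) > 0) {
    f <- disp / sum(disp); f <- f[f > 0]
    exp(-sum(f * log(f))) / length(disp)
  } else NA_real_
  list(start = start, target = target, rmsd = gt_rmsd, kappa = gt_kappa,
       motion = motion, amplitude = amplitude, spacing = spacing)
}

# Single-chain geometry built from unit tangents, so consecutive spacing is
# exactly `spacing`; multiple chains are rigid copies arranged around the
# z axis at a fixed radius.
#
# "helix": ~95 deg of twist per residue with a constant rise, a compact
# alpha-helix-like coil. Its dense short-range contacts give the elastic
# network the local rigidity of real secondary structure, and its strong
# chirality keeps the mirror-image solution of the pairwise-distance
# constraints far away, as it is for real folds (a near-planar chain lets a
# distance-driven sampler descend into the enantiomer basin).
# "extended": gently curved open strand, in-plane turn `turn_deg` with a
# small out-of-plane pitch; sparse contacts, never self-overlapping.
fixture_base <- function(n_residues, chains, spacing, turn_deg,
                         geometry = "helix") {
  n <- as.integer(n_residues)
  if (n < 2L) stop("n_residues must be >= 2", call. = FALSE)
  if (geometry == "helix") {
    phi <- (seq_len(n - 1L) - 1L) * 95 * pi / 180
    psi <- 0.41 + 0.03 * sin(0.25 * seq_len(n - 1L))
  } else {
    phi <- (seq_len(n - 1L) - 1L) * turn_deg * pi / 180
    psi <- 0.30 + 0.08 * sin(0.25 * seq_len(n - 1L))
  }
  tang <- cbind(cos(phi) * cos(psi), sin(phi) * cos(psi), sin(psi))
  base <- rbind(c(0, 0, 0), apply(tang * spacing, 2L, cumsum))
  base <- sweep(base, 2L, colMeans(base))
  chains <- as.integer(chains)
  if (chains < 1L) stop("chains must be >= 1", call. = FALSE)
  radius <- if (chains == 1L) 0
            else if (geometry == "helix") max(12, 3 * spacing)
            else max(12, spacing * n / 8)
  xyz <- NULL; ch <- character(0)
  for (c in seq_len(chains)) {
    ang <- 360 * (c - 1L) / chains
    placed <- sweep(base, 2L, c(radius, 0, 0), "+")
    placed <- rotate_about(placed, c(0, 0, 0), c(0, 0, 1), ang)
    xyz <- rbind(xyz, placed)
    ch <- c(ch, rep(LETTERS[c], n))
  }
  calpha_model(xyz, ch, rep(seq_len(n), chains))
}

normalize3 <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) return(c(1, 0, 0))
  v / nv
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Rodrigues rotation of row coordinates about an axis through `center`.
rotate_about <- function(xyz, center, axis, angle_deg) {
  u <- normalize3(axis)
  th <- angle_deg * pi / 180
  kmat <- matrix(c(0, -u[3L], u[2L], u[3L], 0, -u[1L], -u[2L], u[1L], 0),
                 3L, 3L, byrow = TRUE)
  rot <- diag(3L) + sin(th) * kmat + (1 - cos(th)) * (kmat %*% kmat)
  sweep(sweep(xyz, 2L, center) %*% t(rot), 2L, center, "+")
}

check_self_intersection <- function(xyz, chain, resno, min_dist = 2) {
  cp <- cpp_pairs_within_cutoff(as.matrix(xyz), min_dist)
  if (length(cp$i) == 0L) return(invisible(TRUE))
  adjacent <- chain[cp$i] == chain[cp$j] &
    abs(resno[cp$j] - resno[cp$i]) <= 1L
  if (any(!adjacent))
    stop("amplitude incompatible with geometry: beads closer than ",
         min_dist, " Angstrom after the motion", call. = FALSE)
  invisible(TRUE)
}

#' The 60-residue hinge benchmark fixture
#'
#' The canonical single-chain hinge system used throughout the package's
#' validation: a 60-residue helical coil at exact 3.8 Angstrom spacing whose
#' distal half rotates by the amplitude that puts the superposed end-state
#' RMSD at ~8 Angstrom.
#'
#' @return as [make_two_state()].
#' @export
hinge_study_fixture <- function() {
  make_two_state(n_residues = 60L, chains = 1L, motion = "hinge",
                 amplitude = HINGE_STUDY_AMPLITUDE)
}

#' Synthetic ensemble with known modes
#'
#' Members are `base + sum_m a_m u_m + noise`, with orthonormal random mode
#' vectors `u_m`, normal amplitudes `a_m ~ N(0, mode_sd_m^2)` and optional
#' isotropic Gaussian coordinate noise -- the parameter-recovery ground truth
#' for ensemble PCA. Reproducible from the seed.
#'
#' @param base a [calpha_model()].
#' @param n_members number of conformations (>= 2).
#' @param mode_sd standard deviations of the mode amplitudes (one per mode).
#' @param noise_sigma per-coordinate noise SD in Angstrom (default 0).
#' @param seed RNG seed.
#' @param modes optional 3N x M matrix of mode vectors (orthonormalized
#'   random directions when NULL).
#' @return list with `models` (list of [calpha_model()]s), `modes` (3N x M,
#'   orthonormal), `amplitudes` (n x M).
#' @export
make_ensemble <- function(base, n_members, mode_sd = c(2, 1),
                          noise_sigma = 0, seed = 1, modes = NULL) {
  if (n_members < 2L) stop("n_members must be >= 2", call. = FALSE)
  set.seed(as.integer(seed))
  n3 <- 3L * n_beads(base)
  m <- length(mode_sd)
  if (is.null(modes)) {
    modes <- qr.Q(qr(matrix(rnorm(n3 * m), n3, m)))
    for (c in seq_len(m)) {
      mi <- which.max(abs(modes[, c]))
      if (modes[mi, c] < 0) modes[, c] <- -modes[, c]
    }
  } else {
    modes <- as.matrix(modes)
    if (nrow(modes) != n3 || ncol(modes) != m)
      stop("modes must be a 3N x length(mode_sd) matrix", call. = FALSE)
  }
  amps <- matrix(rnorm(n_members * m), n_members, m)
  amps <- sweep(amps, 2L, mode_sd, "*")
  x0 <- flatten_xyz(base)
  models <- lapply(seq_len(n_members), function(i) {
    x <- x0 + as.vector(modes %*% amps[i, ])
    if (noise_sigma > 0) x <- x + rnorm(n3, sd = noise_sigma)
    set_coords(base, unflatten_xyz(x))
  })
  list(models = models, modes = modes, amplitudes = amps)
}

#' Remove residues from a model
#'
#' Emulates structures with missing residues or absent chains; used to test
#' transitions between end states of differing composition.
#'
#' @param model a [calpha_model()].
#' @param drop_keys residue keys (or `"chain:resno"` prefixes) to remove.
#' @param drop_frac additionally drop this random fraction of the remaining
#'   residues.
#' @param seed RNG seed for the random fraction.
#' @return a [calpha_model()].
#' @export
degrade_model <- function(model, drop_keys = NULL, drop_frac = 0, seed = 1) {
  keys <- residue_keys(model)
  keep <- rep(TRUE, length(keys))
  if (!is.null(drop_keys)) {
    norm <- vapply(drop_keys, function(k) {
      if (length(strsplit(k, ":", fixed = TRUE)[[1L]]) == 2L)
        paste0(k, ":") else k
    }, character(1L))
    keep <- keep & !(keys %in% norm) & !(model$chain %in% drop_keys)
  }
  if (drop_frac > 0) {
    set.seed(as.integer(seed))
    cand <- which(keep)
    kill <- sample(cand, size = floor(drop_frac * length(cand)))
    keep[kill] <- FALSE
  }
  if (sum(keep) < 2L)
    stop("cannot drop (almost) all residues", call. = FALSE)
  subset_model(model, which(keep))
}
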