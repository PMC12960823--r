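#' Root-mean-square deviation between two models
#'
#' `sqrt(mean |r_b - r_a|^2)` over corresponding beads, optionally after
#' optimal superposition ([kabsch_superpose()]). The two models must share
#' identical residue keys unless an explicit correspondence map is given.
#'
#' @param a,b [calpha_model()]s.
#' @param superpose superpose `b` onto `a` first (default TRUE, the
#'   convention for quantifying conformational change amplitude).
#' @param map optional [match_residues()] result; required when keys differ.
#' @return RMSD in Angstrom.
#' @export
ca_rmsd <- function(a, b, superpose = TRUE, map = NULL) {
  pair <- displacement_pair(a, b, map)
  xa <- pair$xa; xb <- pair$xb
  if (superpose) {
    fit <- kabsch_superpose(xb, xa)
    xb <- fit$xyz
  }
  sqrt(mean(rowSums((xb - xa)^2)))
}

displacement_pair <- function(a, b, map = NULL) {
  if (is.null(map)) {
    if (!identical(residue_keys(a), residue_keys(b)))
      stop("models have different residue keys; pass a correspondence map",
           call. = FALSE)
    list(xa = a$xyz, xb = b$xyz)
  } else {
    mp <- map$matched_pairs
    if (nrow(mp) == 0L) stop("correspondence map is empty", call. = FALSE)
    list(xa = a$xyz[mp[, 1L], , drop = FALSE],
         xb = b$xyz[mp[, 2L], , drop = FALSE])
  }
}

#' Collectivity degree of a conformational change
#'
#' Entropy-based measure of how many residues participate in the displacement
#' field between two conformations:
#' `kappa = (1/N) exp(-sum f_i log f_i)` with
#' `f_i = |dr_i| / sum_j |dr_j|` the normalized per-bead displacement
#' magnitudes. Ranges from `1/N` (one residue moves) to 1 (all residues move
#' by the same amount); invariant to a global rescaling of the displacements.
#'
#' The displacement field is taken between the coordinates as given
#' (`superpose = FALSE` default), so rigid-body offsets count as uniform
#' motion; superpose first to measure internal change only.
#'
#' @inheritParams ca_rmsd
#' @param superpose superpose `b` onto `a` before taking displacements.
#' @return kappa, dimensionless in `[1/N, 1]`.
#' @export
collectivity <- function(a, b, superpose = FALSE, map = NULL) {
  pair <- displacement_pair(a, b, map)
  xb <- pair$xb
  if (superpose) xb <- kabsch_superpose(xb, pair$xa)$xyz
  mag <- sqrt(rowSums((xb - pair$xa)^2))
  tot <- sum(mag)
  if (tot == 0)
    stop("all displacements are zero; collectivity is undefined",
         call. = FALSE)
  f <- mag / tot
  nz <- f > 0
  exp(-sum(f[nz] * log(f[nz]))) / length(f)
}

#' Distances between consecutive C-alpha beads
#'
#' Distances between sequence-adjacent residues within each chain. Two beads
#' are consecutive when their residue numbers differ by one, or are equal
#' with differing insertion codes. Larger residue-number gaps are chain
#' breaks: no distance is computed and the break is reported.
#'
#' @param frame a [calpha_model()].
#' @return list with `distances` (data.frame: `chain`, `key_i`, `key_j`,
#'   `distance`) and `breaks` (data.frame: `chain`, `key_i`, `key_j`,
#'   `gap`).
#' @export
consecutive_ca_distances <- function(frame) {
  keys <- residue_keys(frame)
  n <- n_beads(frame)
  i <- seq_len(n - 1L); j <- i + 1L
  same_chain <- frame$chain[i] == frame$chain[j]
  dres <- frame$resno[j] - frame$resno[i]
  consec <- same_chain &
    (dres == 1L | (dres == 0L & frame$insert[i] != frame$insert[j]))
  broken <- same_chain & !consec
  d <- pair_distances(frame$xyz, i[consec], j[consec])
  list(
    distances = data.frame(chain = frame$chain[i][consec],
                           key_i = keys[i][consec], key_j = keys[j][consec],
                           distance = d, stringsAsFactors = FALSE),
    breaks = data.frame(chain = frame$chain[i][broken],
                        key_i = keys[i][broken], key_j = keys[j][broken],
                        gap = dres[broken], stringsAsFactors = FALSE))
}

#' Summary statistics of consecutive C-alpha distances
#'
#' Min/median/max plus boxplot-rule outliers (outside 1.5 x IQR beyond the
#' quartiles).
#'
#' @param frame a [calpha_model()].
#' @return list `min`, `median`, `max`, `n`, `outliers` (numeric values).
#' @export
ca_distance_stats <- function(frame) {
  d <- consecutive_ca_distances(frame)$distances$distance
  if (length(d) == 0L)
    return(list(min = NA_real_, median = NA_real_, max = NA_real_,
                n = 0L, outliers = numeric(0)))
  q <- stats::quantile(d, c(0.25, 0.75), names = FALSE)
  iqr <- q[2L] - q[1L]
  # the 1e-9 slack stops numerically identical distances (idealized
  # geometries) from registering as outliers through round-off
  out <- d[d < q[1L] - 1.5 * iqr - 1e-9 | d > q[2L] + 1.5 * iqr + 1e-9]
  list(min = min(d), median = stats::median(d), max = max(d),
       n = length(d), outliers = out)
}

#' Overlap between two direction vectors
#'
#' Absolute normalized inner product `|v . w| / (|v| |w|)`, in `[0, 1]`.
#'
#' @param v,w numeric vectors of equal length.
#' @return scalar overlap.
#' @export
subspace_overlap <- function(v, w) {
  if (length(v) != length(w))
    stop("vectors must have equal length", call. = FALSE)
  nv <- sqrt(sum(v^2)); nw <- sqrt(sum(w^2))
  if (nv == 0 || nw == 0) stop("zero vector has no direction", call. = FALSE)
  abs(sum(v * w)) / (nv * nw)
}

#' Root mean square inner product between two subspaces
#'
#' `RMSIP = sqrt( (1/k) sum_i sum_j (a_i . b_j)^2 )` over the top `k x k`
#' block of inner products between the two (orthonormal) vector sets; 1 when
#' the spanned subspaces coincide, regardless of vector order within them.
#'
#' @param basis_a,basis_b `ca_pca` objects, or matrices with unit-norm
#'   columns.
#' @param k number of leading vectors from each set.
#' @return RMSIP in `[0, 1]`.
#' @export
rmsip <- function(basis_a, basis_b, k) {
  ua <- if (inherits(basis_a, "ca_pca")) basis_a$U else as.matrix(basis_a)
  ub <- if (inherits(basis_b, "ca_pca")) basis_b$U else as.matrix(basis_b)
  if (nrow(ua) != nrow(ub))
    stop("bases have different dimensionality", call. = FALSE)
  if (k < 1L || k > ncol(ua) || k > ncol(ub))
    stop("k exceeds the number of available vectors", call. = FALSE)
  ua <- ua[, seq_len(k), drop = FALSE]
  ub <- ub[, seq_len(k), drop = FALSE]
  ua <- sweep(ua, 2L, sqrt(colSums(ua^2)), "/")
  ub <- sweep(ub, 2L, sqrt(colSums(ub^2)), "/")
  sqrt(sum(crossprod(ua, ub)^2) / k)
}

#' Angle defined by three residues
#'
#' The angle at the middle residue (vertex) of the triplet, in degrees, in
#' `[0, 180]`. Residues are addressed by key (`"chain:resno"` or
#' `"chain:resno:insert"`).
#'
#' @param frame a [calpha_model()].
#' @param key_i,key_j,key_k residue keys; `key_j` is the vertex.
#' @return angle in degrees.
#' @export
three_point_angle <- function(frame, key_i, key_j, key_k) {
  idx <- vapply(c(key_i, key_j, key_k), function(k) {
    if (length(strsplit(k, ":", fixed = TRUE)[[1L]]) == 2L)
      k <- paste0(k, ":")
    hit <- match(k, residue_keys(frame))
    if (is.na(hit)) stop("residue key not found: ", k, call. = FALSE)
    hit
  }, integer(1L))
  v1 <- frame$xyz[idx[1L], ] - frame$xyz[idx[2L], ]
  v2 <- frame$xyz[idx[3L], ] - frame$xyz[idx[2L], ]
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0)
    stop("coincident points; angle is undefined", call. = FALSE)
  cosang <- sum(v1 * v2) / (n1 * n2)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Per-frame metrics report for a trajectory
#'
#' For each frame: RMSD to the target, collectivity of the displacement from
#' the first frame, and consecutive C-alpha distance statistics. Optional
#' three-point angles are evaluated per frame.
#'
#' @param frames a `transition_path` or list of [calpha_model()]s.
#' @param target optional [calpha_model()] for per-frame RMSD.
#' @param angles optional named list of key triplets
#'   (`list(theta = c(i, j, k))`).
#' @return data.frame, one row per frame.
#' @export
path_metrics <- function(frames, target = NULL, angles = NULL) {
  if (inherits(frames, "transition_path")) frames <- frames$frames
  start <- frames[[1L]]
  tmap <- if (!is.null(target)) match_residues(start, target)
  rows <- lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    st <- ca_distance_stats(f)
    row <- data.frame(
      frame = i,
      rmsd_to_target = if (is.null(target)) NA_real_
                       else ca_rmsd(f, target, superpose = TRUE, map = tmap),
      kappa_vs_start = if (i == 1L) NA_real_
                       else tryCatch(collectivity(start, f),
                                     error = function(e) NA_real_),
      ca_min = st$min, ca_median = st$median, ca_max = st$max,
      ca_outliers = length(st$outliers))
    if (!is.null(angles))
      for (nm in names(angles))
        row[[nm]] <- three_point_angle(f, angles[[nm]][1L],
                                       angles[[nm]][2L], angles[[nm]][3L])
    row
  })
  do.call(rbind, rows)
}
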