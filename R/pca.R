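#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation plus translation minimizing the RMSD of the
#' masked beads of `mobile` onto `reference` (reflections are never
#' returned), and applies it to *all* beads of `mobile`.
#'
#' @param mobile,reference [calpha_model()]s or N x 3 matrices with equal N.
#' @param mask optional logical vector or integer indices selecting the beads
#'   used for the fit (default: all). At least 3 non-collinear beads are
#'   required.
#' @return list with `xyz` (transformed mobile coordinates; a `calpha_model`
#'   when `mobile` was one), `rmsd` (over the masked beads), `rotation`
#'   (3 x 3), `translation` (length 3); the transform acts as
#'   `x %*% rotation + translation` on row coordinates.
#' @export
kabsch_superpose <- function(mobile, reference, mask = NULL) {
  was_model <- inherits(mobile, "calpha_model")
  a <- if (was_model) mobile$xyz else as.matrix(mobile)
  b <- if (inherits(reference, "calpha_model")) reference$xyz
       else as.matrix(reference)
  if (nrow(a) != nrow(b))
    stop("mobile and reference must have the same number of beads",
         call. = FALSE)
  idx <- if (is.null(mask)) seq_len(nrow(a))
         else if (is.logical(mask)) which(mask) else as.integer(mask)
  if (length(idx) < 3L)
    stop("superposition needs at least 3 masked beads", call. = FALSE)
  am <- a[idx, , drop = FALSE]; bm <- b[idx, , drop = FALSE]
  ca <- colMeans(am); cb <- colMeans(bm)
  ac <- sweep(am, 2L, ca); bc <- sweep(bm, 2L, cb)
  sv_a <- svd(ac)
  if (sv_a$d[2L] < 1e-8 * max(sv_a$d[1L], 1e-8))
    stop("masked beads are collinear; superposition is ill-defined",
         call. = FALSE)
  h <- crossprod(ac, bc)                     # 3 x 3
  sv <- svd(h)
  s <- sign(det(sv$u) * det(sv$v))
  rot <- sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
  trans <- cb - as.vector(ca %*% rot)
  new_xyz <- sweep(a %*% rot, 2L, trans, "+")
  rmsd <- sqrt(mean(rowSums((new_xyz[idx, , drop = FALSE] - bm)^2)))
  out_xyz <- if (was_model) set_coords(mobile, new_xyz) else new_xyz
  list(xyz = out_xyz, rmsd = rmsd, rotation = rot, translation = trans)
}

#' Principal component analysis of a superposed ensemble
#'
#' Computes the 3N x 3N positional covariance about the ensemble mean (the
#' average over the n conformations) and its eigendecomposition, via SVD of
#' the centered coordinate matrix. Eigenvalues (variances, Angstrom^2) are
#' sorted descending; values numerically indistinguishable from zero are
#' clamped to zero, so at most `min(n - 1, 3N)` are positive. Each
#' eigenvector's sign is fixed so its largest-magnitude component is
#' positive, and within numerically degenerate eigenvalue blocks vectors are
#' ordered by the index of that component, making the basis reproducible.
#'
#' Note the deliberate asymmetry of this toolkit: the covariance is taken
#' about the ensemble *mean*, while projections ([pc_project()]) are anchored
#' at the *reference* structure.
#'
#' @param ensemble a `ca_ensemble`, already superposed onto its reference
#'   (see [superpose_ensemble()]).
#' @return an object of class `ca_pca`: `U` (3N x r orthonormal columns),
#'   `lambda` (length r), `mean`, `ref` (reference coordinates, 3N),
#'   `keys`, `template`.
#' @export
ensemble_pca <- function(ensemble) {
  x <- ensemble$X
  if (nrow(x) < 2L)
    stop("ensemble PCA needs at least 2 conformations", call. = FALSE)
  n <- nrow(x)
  xm <- colMeans(x)
  xc <- sweep(x, 2L, xm)
  sv <- svd(xc, nu = 0L)
  lambda <- sv$d^2 / n
  if (max(lambda) > 0)
    lambda[lambda < max(lambda) * 1e-12] <- 0
  r <- min(n, ncol(x))
  lambda <- lambda[seq_len(r)]
  u <- sv$v[, seq_len(r), drop = FALSE]
  # sign convention
  for (m in seq_len(ncol(u))) {
    mi <- which.max(abs(u[, m]))
    if (u[mi, m] < 0) u[, m] <- -u[, m]
  }
  # deterministic order inside degenerate blocks
  if (r > 1L) {
    tol <- max(lambda, 1e-300) * 1e-9
    grp <- cumsum(c(TRUE, diff(lambda) < -tol))
    for (g in unique(grp)) {
      members <- which(grp == g)
      if (length(members) > 1L) {
        key <- vapply(members, function(m) which.max(abs(u[, m])), integer(1))
        u[, members] <- u[, members[order(key)], drop = FALSE]
      }
    }
  }
  structure(
    list(U = u, lambda = lambda, mean = xm,
         ref = x[ensemble$reference_index, ],
         keys = ensemble$keys, template = ensemble$template),
    class = "ca_pca")
}

#' @export
print.ca_pca <- function(x, ...) {
  tot <- sum(x$lambda)
  cat("ca_pca:", length(x$lambda), "components over",
      length(x$keys), "residues\n")
  if (tot > 0)
    cat(sprintf("  PC1 %.1f%%, PC2 %.1f%% of total variance %.2f A^2\n",
                100 * x$lambda[1L] / tot,
                if (length(x$lambda) > 1L) 100 * x$lambda[2L] / tot else 0,
                tot))
  invisible(x)
}

#' Scree plot of a PCA basis
#' @param x a `ca_pca`.
#' @param n_show number of leading eigenvalues to draw.
#' @param ... ignored.
#' @export
plot.ca_pca <- function(x, n_show = 10L, ...) {
  n_show <- min(n_show, length(x$lambda))
  graphics::barplot(x$lambda[seq_len(n_show)],
                    names.arg = paste0("PC", seq_len(n_show)),
                    ylab = "eigenvalue (A^2)")
  invisible(x)
}

#' Project a conformation onto principal components
#'
#' Reference-anchored projection: `p = (x - x_ref) . PC_m / |PC_m|`, in
#' Angstrom. The conformation must already be superposed onto the same
#' reference used for the basis.
#'
#' @param conformation a [calpha_model()] over the basis residues, or a
#'   3N coordinate vector.
#' @param basis a `ca_pca`.
#' @param m component index (scalar or vector; default all components).
#' @return numeric vector of projections, one per requested component.
#' @export
pc_project <- function(conformation, basis, m = NULL) {
  x <- if (inherits(conformation, "calpha_model")) flatten_xyz(conformation)
       else as.numeric(conformation)
  if (length(x) != length(basis$ref))
    stop("conformation has ", length(x) / 3, " residues; basis expects ",
         length(basis$ref) / 3, call. = FALSE)
  if (is.null(m)) m <- seq_len(ncol(basis$U))
  if (any(m < 1L | m > ncol(basis$U)))
    stop("component index out of range (1..", ncol(basis$U), ")",
         call. = FALSE)
  dx <- x - basis$ref
  vapply(m, function(mm) {
    u <- basis$U[, mm]
    sum(dx * u) / sqrt(sum(u^2))
  }, numeric(1L))
}

#' Project the frames of a transition path
#'
#' Reduces each frame to the basis residues, superposes it onto the basis
#' reference, and projects it.
#'
#' @param path a `transition_path` (or list of [calpha_model()]s).
#' @param basis a `ca_pca`.
#' @param m component indices (default first two).
#' @return data.frame with one row per frame, columns `frame`, `PC<m>`.
#' @export
project_path <- function(path, basis, m = 1:2) {
  frames <- if (inherits(path, "transition_path")) path$frames else path
  ref_xyz <- unflatten_xyz(basis$ref)
  proj <- vapply(frames, function(f) {
    idx <- match(basis$keys, residue_keys(f))
    if (anyNA(idx))
      stop("frame lacks residues required by the PCA basis", call. = FALSE)
    sub <- f$xyz[idx, , drop = FALSE]
    fit <- kabsch_superpose(sub, ref_xyz)
    pc_project(flatten_xyz(fit$xyz), basis, m)
  }, numeric(length(m)))
  proj <- if (is.matrix(proj)) t(proj) else matrix(proj, ncol = 1L)
  out <- data.frame(frame = seq_along(frames))
  for (c in seq_along(m)) out[[paste0("PC", m[c])]] <- proj[, c]
  out
}

#' Fraction of variance captured by the leading components
#'
#' @param basis a `ca_pca`.
#' @param top_k number of leading components (>= 1).
#' @return fraction in `[0, 1]`; exactly 1 when `top_k` reaches the rank.
#' @export
variance_fraction <- function(basis, top_k) {
  if (top_k < 1L) stop("top_k must be >= 1", call. = FALSE)
  tot <- sum(basis$lambda)
  if (tot <= 0) stop("ensemble has zero total variance", call. = FALSE)
  sum(basis$lambda[seq_len(min(top_k, length(basis$lambda)))]) / tot
}
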