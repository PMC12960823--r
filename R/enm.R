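#' Elastic-network parameters
#'
#' Parameters of the coarse-grained elastic network. Springs come in three
#' kinds: *bonded* springs between sequence neighbours (residue-number
#' separation up to `sequence_span` within a chain), *Cartesian* springs
#' between any pair closer than `cutoff` in the conformation the network was
#' built from, and *rigid-block* springs connecting every pair inside a
#' user-declared rigid block regardless of distance. Stiffness rules follow
#' the MD-calibrated essential-dynamics ENM family: an inverse-power law in
#' sequence separation for bonded pairs and an inverse-power law in distance
#' for Cartesian pairs. The stiffness scales and exponents are deliberately
#' exposed -- they are configurable, not hard-wired.
#'
#' @param cutoff pair-list cutoff r_c in Angstrom (default 8).
#' @param sequence_span residue separations treated as bonded (default 3).
#' @param sequence_constant bonded stiffness scale, kcal/mol/A^2 (default 60).
#' @param sequence_exponent bonded inverse-power exponent (default 2).
#' @param cartesian_constant Cartesian stiffness scale, kcal/mol/A^2
#'   (default 6).
#' @param cartesian_exponent Cartesian inverse-power exponent (default 6).
#' @param reference_length distance in Angstrom at which a Cartesian spring
#'   has stiffness `cartesian_constant` (default 3.8, the ideal consecutive
#'   C-alpha spacing).
#' @param rigid_spring_constant stiffness of intra-rigid-block springs,
#'   kcal/mol/A^2 (default 1).
#' @return a list of class `enm_params`.
#' @export
enm_params <- function(cutoff = 8, sequence_span = 3,
                       sequence_constant = 60, sequence_exponent = 2,
                       cartesian_constant = 6, cartesian_exponent = 6,
                       reference_length = 3.8, rigid_spring_constant = 1) {
  p <- list(cutoff = cutoff, sequence_span = as.integer(sequence_span),
            sequence_constant = sequence_constant,
            sequence_exponent = sequence_exponent,
            cartesian_constant = cartesian_constant,
            cartesian_exponent = cartesian_exponent,
            reference_length = reference_length,
            rigid_spring_constant = rigid_spring_constant)
  pos <- c("cutoff", "sequence_constant", "cartesian_constant",
           "reference_length", "rigid_spring_constant")
  for (nm in pos)
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] <= 0)
      stop("enm parameter `", nm, "` must be a positive number",
           call. = FALSE)
  if (p$sequence_span < 0L)
    stop("sequence_span must be >= 0", call. = FALSE)
  structure(p, class = "enm_params")
}

#' Spring stiffness rule
#'
#' Bonded pairs (sequence separation between 1 and `sequence_span` on the
#' same chain) get `sequence_constant / separation^sequence_exponent`;
#' all other pairs get
#' `cartesian_constant * (reference_length / d0)^cartesian_exponent`,
#' which is monotonically non-increasing in the rest length `d0`.
#'
#' @param sequence_separation integer vector; use `NA` for pairs on different
#'   chains.
#' @param d0 rest length(s) in Angstrom, > 0.
#' @param params an [enm_params()].
#' @return numeric stiffness in kcal/mol/A^2 (vectorized).
#' @export
spring_constant <- function(sequence_separation, d0, params = enm_params()) {
  if (any(d0 <= 0))
    stop("rest length d0 must be > 0", call. = FALSE)
  sep <- sequence_separation
  bonded <- !is.na(sep) & sep >= 1L & sep <= params$sequence_span
  k <- params$cartesian_constant *
    (params$reference_length / d0)^params$cartesian_exponent
  if (any(bonded))
    k[bonded] <- params$sequence_constant /
      abs(sep[bonded])^params$sequence_exponent
  k
}

#' Build the spring topology of a model
#'
#' Constructs the pair list L from the given conformation: all bonded
#' sequence neighbours, all pairs with distance strictly below the cutoff,
#' and all pairs inside each rigid block (the cutoff is removed for rigid
#' blocks, and every intra-block spring has stiffness
#' `rigid_spring_constant`). Rest lengths are the distances in the source
#' conformation.
#'
#' @param model a [calpha_model()].
#' @param params an [enm_params()].
#' @param rigid_blocks list of integer bead-index vectors, each a rigid
#'   block; blocks must be disjoint. See [read_rigid_blocks()].
#' @return an object of class `spring_topology`: `pairs` (data.frame with
#'   columns `i`, `j`, `kind`, `sep`, `k`, `d0`), `rigid_blocks`,
#'   `params`, `source_xyz`.
#' @export
build_topology <- function(model, params = enm_params(),
                           rigid_blocks = NULL) {
  n <- n_beads(model)
  if (n < 2L) stop("need at least 2 beads", call. = FALSE)
  rigid_blocks <- validate_rigid_blocks(rigid_blocks, n)
  pr <- enumerate_pairs(model, model$xyz, params, rigid_blocks)
  d0 <- pair_distances(model$xyz, pr$i, pr$j)
  if (any(d0 == 0))
    stop("coincident beads in pair(s): ",
         paste(sprintf("(%d,%d)", pr$i[d0 == 0], pr$j[d0 == 0]),
               collapse = " "), call. = FALSE)
  k <- ifelse(pr$kind == "rigid", params$rigid_spring_constant,
              spring_constant(ifelse(pr$kind == "bonded", pr$sep, NA),
                              d0, params))
  structure(
    list(pairs = data.frame(i = pr$i, j = pr$j, kind = pr$kind,
                            sep = pr$sep, k = k, d0 = d0,
                            stringsAsFactors = FALSE),
         rigid_blocks = rigid_blocks, params = params,
         source_xyz = model$xyz, chain = model$chain, resno = model$resno),
    class = "spring_topology")
}

#' @export
print.spring_topology <- function(x, ...) {
  cat("spring_topology:", nrow(x$pairs), "springs over",
      nrow(x$source_xyz), "beads (",
      sum(x$pairs$kind == "bonded"), "bonded,",
      sum(x$pairs$kind == "cartesian"), "cartesian,",
      sum(x$pairs$kind == "rigid"), "rigid )\n")
  invisible(x)
}

validate_rigid_blocks <- function(rigid_blocks, n) {
  if (is.null(rigid_blocks) || length(rigid_blocks) == 0L) return(list())
  rigid_blocks <- lapply(rigid_blocks, function(b) sort(unique(as.integer(b))))
  all_idx <- unlist(rigid_blocks)
  if (any(all_idx < 1L | all_idx > n))
    stop("rigid block indices out of range", call. = FALSE)
  if (anyDuplicated(all_idx))
    stop("rigid blocks overlap", call. = FALSE)
  rigid_blocks
}

# Enumerate the pair set (i < j) with kind classification.
# Priority: rigid > bonded > cartesian.
enumerate_pairs <- function(model, xyz, params, rigid_blocks) {
  cp <- cpp_pairs_within_cutoff(xyz, params$cutoff)
  pi <- cp$i; pj <- cp$j
  # bonded: same chain, residue-number separation in [1, span]
  if (params$sequence_span >= 1L) {
    bl <- bonded_pairs(model$chain, model$resno, params$sequence_span)
    pi <- c(pi, bl$i); pj <- c(pj, bl$j)
  }
  for (b in rigid_blocks) {
    if (length(b) >= 2L) {
      cmb <- utils::combn(b, 2L)
      pi <- c(pi, cmb[1L, ]); pj <- c(pj, cmb[2L, ])
    }
  }
  key <- (pi - 1) * nrow(xyz) + pj
  keep <- !duplicated(key)
  pi <- pi[keep]; pj <- pj[keep]
  o <- order(pi, pj)
  pi <- pi[o]; pj <- pj[o]
  rigid_id <- integer(nrow(xyz))
  for (bi in seq_along(rigid_blocks)) rigid_id[rigid_blocks[[bi]]] <- bi
  same_block <- rigid_id[pi] > 0L & rigid_id[pi] == rigid_id[pj]
  sep <- ifelse(model$chain[pi] == model$chain[pj],
                abs(model$resno[pj] - model$resno[pi]), NA_integer_)
  bonded <- !is.na(sep) & sep >= 1L & sep <= params$sequence_span
  kind <- ifelse(same_block, "rigid", ifelse(bonded, "bonded", "cartesian"))
  list(i = pi, j = pj, kind = kind, sep = sep)
}

bonded_pairs <- function(chain, resno, span) {
  i <- integer(0); j <- integer(0)
  for (ch in unique(chain)) {
    idx <- which(chain == ch)
    if (length(idx) < 2L) next
    rn <- resno[idx]
    for (s in seq_len(span)) {
      hit <- match(rn + s, rn)
      ok <- which(!is.na(hit))
      if (length(ok)) {
        i <- c(i, idx[ok]); j <- c(j, idx[hit[ok]])
      }
    }
  }
  if (length(i) == 0L) return(list(i = integer(0), j = integer(0)))
  ii <- pmin(i, j); jj <- pmax(i, j)
  list(i = ii, j = jj)
}

pair_distances <- function(xyz, i, j) {
  sqrt((xyz[i, 1L] - xyz[j, 1L])^2 + (xyz[i, 2L] - xyz[j, 2L])^2 +
       (xyz[i, 3L] - xyz[j, 3L])^2)
}

#' Harmonic forces of a spring topology
#'
#' For each pair, a harmonic force of magnitude `k_ij * (d_ij - d0_ij)`
#' directed along the pair axis, accumulated with Newton's-third-law
#' antisymmetry; the total force over all beads is the zero vector.
#'
#' @param topology a `spring_topology`.
#' @param xyz N x 3 coordinate matrix (defaults to the topology source).
#' @return N x 3 matrix of forces in kcal/mol/A.
#' @export
compute_forces <- function(topology, xyz = topology$source_xyz) {
  p <- topology$pairs
  n <- nrow(xyz)
  if (n != nrow(topology$source_xyz))
    stop("positions do not match topology size", call. = FALSE)
  d <- pair_distances(xyz, p$i, p$j)
  if (any(d == 0))
    stop("coincident beads in pair(s): ",
         paste(sprintf("(%d,%d)", p$i[d == 0], p$j[d == 0]), collapse = " "),
         call. = FALSE)
  fmag <- p$k * (d - p$d0) / d          # >0 pulls i toward j
  dvec <- xyz[p$j, , drop = FALSE] - xyz[p$i, , drop = FALSE]
  contrib <- dvec * fmag
  f <- matrix(0, n, 3L)
  for (c in 1:3) {
    acc_i <- rowsum(contrib[, c], p$i)
    acc_j <- rowsum(contrib[, c], p$j)
    f[as.integer(rownames(acc_i)), c] <-
      f[as.integer(rownames(acc_i)), c] + acc_i[, 1L]
    f[as.integer(rownames(acc_j)), c] <-
      f[as.integer(rownames(acc_j)), c] - acc_j[, 1L]
  }
  f
}

#' Harmonic potential energy of a spring topology
#'
#' Sum over springs of `1/2 k (d - d0)^2`; zero exactly at the conformation
#' the network was built from. Forces are its exact negative gradient.
#'
#' @inheritParams compute_forces
#' @return scalar energy in kcal/mol.
#' @export
potential_energy <- function(topology, xyz = topology$source_xyz) {
  p <- topology$pairs
  d <- pair_distances(xyz, p$i, p$j)
  sum(0.5 * p$k * (d - p$d0)^2)
}

#' Rebuild the pair list from current positions
#'
#' Re-applies the [build_topology()] rule at the given positions: pairs that
#' left the cutoff are dropped and newly proximal pairs are admitted. The
#' network is adaptive where the conformation is soft and conservative where
#' it is stiff: Cartesian springs and bonded springs at sequence separation
#' >= 2 (pseudo-bond-angle terms) re-derive rest length -- and, for Cartesian
#' springs, stiffness -- from the *current* positions, so the network minimum
#' tracks the deforming structure instead of pulling it back toward the
#' conformation it started from; nearest-neighbour bonded springs (separation
#' 1, the pseudo-bonds) and rigid-block springs always keep their original
#' rest lengths, anchoring the chain's local scale and the block's internal
#' geometry. Bonded and rigid pairs are retained regardless of distance.
#'
#' @param topology a `spring_topology`.
#' @param xyz current N x 3 positions.
#' @return a new `spring_topology` whose `source_xyz` is `xyz`.
#' @export
rebuild_pair_list <- function(topology, xyz) {
  params <- topology$params
  n <- nrow(xyz)
  model_like <- list(chain = topology$chain, resno = topology$resno,
                     xyz = xyz)
  pr <- enumerate_pairs(model_like, xyz, params, topology$rigid_blocks)
  key_new <- (pr$i - 1) * n + pr$j
  old <- topology$pairs
  key_old <- (old$i - 1) * n + old$j
  hit <- match(key_new, key_old)
  d_now <- pair_distances(xyz, pr$i, pr$j)
  if (any(d_now == 0))
    stop("coincident beads in pair(s): ",
         paste(sprintf("(%d,%d)", pr$i[d_now == 0], pr$j[d_now == 0]),
               collapse = " "), call. = FALSE)
  inherit <- !is.na(hit) &
    (pr$kind == "rigid" | (pr$kind == "bonded" & pr$sep == 1L))
  d0 <- ifelse(inherit, old$d0[hit], d_now)
  k <- ifelse(pr$kind == "rigid", params$rigid_spring_constant,
              spring_constant(ifelse(pr$kind == "bonded", pr$sep, NA),
                              d0, params))
  structure(
    list(pairs = data.frame(i = pr$i, j = pr$j, kind = pr$kind,
                            sep = pr$sep, k = k, d0 = d0,
                            stringsAsFactors = FALSE),
         rigid_blocks = topology$rigid_blocks, params = params,
         source_xyz = xyz, chain = topology$chain, resno = topology$resno),
    class = "spring_topology")
}

#' Parse a rigid-block definition file
#'
#' Plain text, one block per line. A line is either a chain identifier
#' (`C`: the whole chain) or a residue span (`C:start-end`). Blank lines and
#' `#` comments are ignored.
#'
#' @param path file path.
#' @param model the [calpha_model()] the indices refer to.
#' @return list of integer bead-index vectors.
#' @export
read_rigid_blocks <- function(path, model) {
  if (!file.exists(path))
    stop("cannot read rigid-block file: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, function(ln) rigid_block_indices(ln, model))
}

#' Resolve a rigid-block selector to bead indices
#' @param selector `"C"` (whole chain) or `"C:start-end"` (residue span).
#' @param model the [calpha_model()].
#' @return integer bead indices.
#' @export
rigid_block_indices <- function(selector, model) {
  parts <- strsplit(selector, ":", fixed = TRUE)[[1L]]
  ch <- parts[1L]
  idx <- which(model$chain == ch)
  if (length(idx) == 0L)
    stop("rigid-block selector `", selector, "` matches no residues",
         call. = FALSE)
  if (length(parts) == 2L) {
    span <- as.integer(strsplit(parts[2L], "-", fixed = TRUE)[[1L]])
    if (length(span) != 2L || anyNA(span))
      stop("malformed rigid-block selector: ", selector, call. = FALSE)
    idx <- idx[model$resno[idx] >= span[1L] & model$resno[idx] <= span[2L]]
    if (length(idx) == 0L)
      stop("rigid-block selector `", selector, "` matches no residues",
           call. = FALSE)
  }
  idx
}
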