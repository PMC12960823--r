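#' One-bead-per-residue C-alpha model
#'
#' A `calpha_model` holds the coarse-grained representation used throughout the
#' package: one bead per residue at the position of its C-alpha atom, together
#' with the residue identity needed to match residues across structures
#' (chain identifier, residue number and insertion code, exactly as found in
#' the source file -- no renumbering is ever performed).
#'
#' @param xyz numeric N x 3 matrix of coordinates in Angstrom.
#' @param chain character vector of chain identifiers, length N.
#' @param resno integer vector of residue numbers, length N.
#' @param insert character vector of insertion codes (`""` when absent).
#' @param aa optional character vector of residue names (3-letter codes).
#'
#' @return An object of class `calpha_model`.
#' @export
calpha_model <- function(xyz, chain, resno, insert = NULL, aa = NULL) {
  xyz <- as.matrix(xyz)
  if (!is.numeric(xyz) || ncol(xyz) != 3L)
    stop("`xyz` must be a numeric N x 3 matrix", call. = FALSE)
  n <- nrow(xyz)
  if (n < 2L)
    stop("a calpha_model needs at least 2 residues, got ", n, call. = FALSE)
  if (!all(is.finite(xyz)))
    stop("all coordinates must be finite", call. = FALSE)
  if (is.null(insert)) insert <- rep("", n)
  insert[is.na(insert)] <- ""
  chain <- as.character(chain)
  resno <- as.integer(resno)
  insert <- as.character(insert)
  if (length(chain) != n || length(resno) != n || length(insert) != n)
    stop("chain/resno/insert must have one entry per bead", call. = FALSE)
  keys <- paste(chain, resno, insert, sep = ":")
  if (anyDuplicated(keys)) {
    dup <- unique(keys[duplicated(keys)])
    stop("duplicate residue key(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  dimnames(xyz) <- NULL
  structure(
    list(xyz = xyz, chain = chain, resno = resno, insert = insert, aa = aa),
    class = "calpha_model")
}

#' @export
print.calpha_model <- function(x, ...) {
  cat("calpha_model:", nrow(x$xyz), "residues,",
      length(unique(x$chain)), "chain(s) [",
      paste(unique(x$chain), collapse = " "), "]\n")
  invisible(x)
}

#' Residue keys of a model
#'
#' Keys are `chain:resno:insert` strings; they identify residues when matching
#' two end states.
#'
#' @param model a `calpha_model`.
#' @return character vector of length N.
#' @export
residue_keys <- function(model) {
  paste(model$chain, model$resno, model$insert, sep = ":")
}

#' Number of beads in a model
#' @param model a `calpha_model`.
#' @return integer.
#' @export
n_beads <- function(model) nrow(model$xyz)

#' Flatten model coordinates to a 3N vector
#'
#' Layout is `x1, y1, z1, x2, y2, z2, ...`, the convention used for ensemble
#' rows and PCA eigenvectors.
#'
#' @param model a `calpha_model` or an N x 3 matrix.
#' @return numeric vector of length 3N.
#' @export
flatten_xyz <- function(model) {
  m <- if (inherits(model, "calpha_model")) model$xyz else as.matrix(model)
  as.vector(t(m))
}

#' Rebuild an N x 3 coordinate matrix from a flat 3N vector
#' @param v numeric vector of length 3N in `x1, y1, z1, ...` layout.
#' @return N x 3 matrix.
#' @export
unflatten_xyz <- function(v) {
  matrix(as.numeric(v), ncol = 3L, byrow = TRUE)
}

#' Replace the coordinates of a model
#' @param model a `calpha_model`.
#' @param xyz N x 3 matrix with the same N.
#' @return a `calpha_model`.
#' @export
set_coords <- function(model, xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != n_beads(model))
    stop("replacement coordinates have wrong number of beads", call. = FALSE)
  calpha_model(xyz, model$chain, model$resno, model$insert, model$aa)
}

#' Subset a model by bead indices
#' @param model a `calpha_model`.
#' @param idx integer indices of beads to keep (in the given order).
#' @return a `calpha_model`.
#' @export
subset_model <- function(model, idx) {
  if (length(idx) < 2L)
    stop("cannot subset a model below 2 residues", call. = FALSE)
  calpha_model(model$xyz[idx, , drop = FALSE], model$chain[idx],
               model$resno[idx], model$insert[idx],
               if (!is.null(model$aa)) model$aa[idx])
}
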