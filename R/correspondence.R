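#' Establish residue correspondence between two models
#'
#' Residues are matched by identical key (chain identifier, residue number,
#' insertion code), the convention that lets end states with differing residue
#' counts or chain compositions be paired without sequence alignment. Zero
#' overlap is not an error: callers decide how to treat it.
#'
#' @param model_a,model_b [calpha_model()]s.
#' @return a list of class `correspondence_map` with `matched_pairs`
#'   (two-column integer matrix: index in A, index in B, in A's order),
#'   `unmatched_a` and `unmatched_b` (integer index vectors).
#' @export
match_residues <- function(model_a, model_b) {
  ka <- residue_keys(model_a)
  kb <- residue_keys(model_b)
  j <- match(ka, kb)
  ia <- which(!is.na(j))
  pairs <- cbind(a = ia, b = j[ia])
  structure(
    list(matched_pairs = pairs,
         unmatched_a = which(is.na(j)),
         unmatched_b = setdiff(seq_along(kb), j[ia])),
    class = "correspondence_map")
}

#' @export
print.correspondence_map <- function(x, ...) {
  cat("correspondence_map:", nrow(x$matched_pairs), "matched,",
      length(x$unmatched_a), "unmatched in A,",
      length(x$unmatched_b), "unmatched in B\n")
  invisible(x)
}

#' Correspondence report as a data frame
#'
#' One row per residue of either model, suitable for CSV export.
#'
#' @param map a `correspondence_map` from [match_residues()].
#' @param model_a,model_b the models it was computed from.
#' @return data.frame with columns `key`, `index_a`, `index_b`, `status`.
#' @export
correspondence_table <- function(map, model_a, model_b) {
  ka <- residue_keys(model_a)
  kb <- residue_keys(model_b)
  mp <- map$matched_pairs
  block <- function(key, ia, ib, status) {
    n <- length(key)
    data.frame(key = key, index_a = rep_len(ia, n),
               index_b = rep_len(ib, n),
               status = rep_len(status, n), stringsAsFactors = FALSE)
  }
  rbind(
    block(ka[mp[, 1L]], mp[, 1L], mp[, 2L], "matched"),
    block(ka[map$unmatched_a], map$unmatched_a, NA_integer_, "only_in_a"),
    block(kb[map$unmatched_b], NA_integer_, map$unmatched_b, "only_in_b"))
}

#' Assemble a common-residue ensemble from several models
#'
#' Keeps exactly the residues present in every model (regions missing in at
#' least one conformation are removed), ordered as in the reference model, and
#' stacks the flattened coordinates into an n x 3N matrix -- the input
#' expected by [ensemble_pca()] after superposition.
#'
#' @param models list of at least two [calpha_model()]s.
#' @param reference_index which model defines residue order and serves as the
#'   PCA reference (default 1).
#' @param member_ids optional character labels, one per model.
#' @return an object of class `ca_ensemble`: `X` (n x 3N coordinate matrix),
#'   `reference_index`, `member_ids`, `keys` (common residue keys, length N),
#'   and `template` (a model carrying the common-residue identity).
#' @export
reduce_to_common <- function(models, reference_index = 1L,
                             member_ids = NULL) {
  if (!is.list(models) || length(models) < 2L)
    stop("need at least 2 models to build an ensemble", call. = FALSE)
  if (reference_index < 1L || reference_index > length(models))
    stop("reference_index out of range", call. = FALSE)
  keysets <- lapply(models, residue_keys)
  common <- Reduce(intersect, keysets)
  if (length(common) == 0L)
    stop("no residues are common to all models", call. = FALSE)
  ref_keys <- keysets[[reference_index]]
  common <- ref_keys[ref_keys %in% common]   # reference order
  rows <- t(vapply(seq_along(models), function(i) {
    idx <- match(common, keysets[[i]])
    flatten_xyz(models[[i]]$xyz[idx, , drop = FALSE])
  }, numeric(3L * length(common))))
  if (is.null(member_ids))
    member_ids <- sprintf("model_%d", seq_along(models))
  ref_idx0 <- match(common, ref_keys)
  template <- subset_model(models[[reference_index]], ref_idx0)
  structure(
    list(X = rows, reference_index = as.integer(reference_index),
         member_ids = member_ids, keys = common, template = template),
    class = "ca_ensemble")
}

#' @export
print.ca_ensemble <- function(x, ...) {
  cat("ca_ensemble:", nrow(x$X), "conformations x",
      length(x$keys), "common residues (reference:",
      x$member_ids[x$reference_index], ")\n")
  invisible(x)
}

#' Extract one ensemble member as a model
#' @param ensemble a `ca_ensemble`.
#' @param i member index.
#' @return a [calpha_model()].
#' @export
ensemble_member <- function(ensemble, i) {
  set_coords(ensemble$template, unflatten_xyz(ensemble$X[i, ]))
}

#' Superpose every ensemble member onto the reference
#'
#' Applies the optimal rigid-body (Kabsch) transform of each row onto the
#' reference row, the global structural alignment step that precedes ensemble
#' PCA.
#'
#' @param ensemble a `ca_ensemble`.
#' @param mask optional logical/integer residue mask used for the fit
#'   (default: all common residues).
#' @return the ensemble with aligned coordinate rows.
#' @export
superpose_ensemble <- function(ensemble, mask = NULL) {
  ref <- unflatten_xyz(ensemble$X[ensemble$reference_index, ])
  for (i in seq_len(nrow(ensemble$X))) {
    if (i == ensemble$reference_index) next
    fit <- kabsch_superpose(unflatten_xyz(ensemble$X[i, ]), ref, mask)
    ensemble$X[i, ] <- flatten_xyz(fit$xyz)
  }
  ensemble
}
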