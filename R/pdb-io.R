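#' Read a PDB file as a C-alpha model
#'
#' Parses ATOM records (via [bio3d::read.pdb()]), keeps one C-alpha bead per
#' residue and discards everything else (HETATM, non-CA atoms, waters). When
#' the file contains multiple MODEL blocks, only the first is used; see
#' [read_calpha_trajectory()] for multi-model trajectories. Alternate
#' locations are resolved deterministically: the highest-occupancy altloc
#' wins, ties are broken by alphabetical altloc identifier.
#'
#' @param path path to a PDB file.
#' @return a [calpha_model()].
#' @export
read_calpha_model <- function(path) {
  frames <- read_calpha_trajectory(path, first_only = TRUE)
  frames[[1L]]
}

#' Read a (multi-model) PDB file as a list of C-alpha models
#'
#' All MODEL blocks are read; residue identity is taken from the first block
#' (PDB trajectories share one topology across models).
#'
#' @param path path to a PDB file.
#' @param first_only read only the first MODEL block.
#' @return a list of [calpha_model()] objects, one per MODEL block.
#' @export
read_calpha_trajectory <- function(path, first_only = FALSE) {
  if (!file.exists(path))
    stop("cannot read PDB file: ", path, call. = FALSE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = !first_only,
                                     rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  atom <- pdb$atom
  ca <- which(atom$type == "ATOM" & atom$elety == "CA")
  if (length(ca) == 0L)
    stop("no C-alpha ATOM records found in ", path, call. = FALSE)

  chain <- atom$chain[ca]
  chain[is.na(chain)] <- ""
  insert <- atom$insert[ca]
  insert[is.na(insert)] <- ""
  resno <- atom$resno[ca]
  alt <- atom$alt[ca]
  alt[is.na(alt)] <- ""
  occ <- atom$o[ca]
  occ[is.na(occ)] <- 1

  keys <- paste(chain, resno, insert, sep = ":")
  keep <- resolve_altlocs(keys, alt, occ, path)
  ca <- ca[keep]
  if (length(ca) < 2L)
    stop("fewer than 2 C-alpha residues in ", path, call. = FALSE)

  xyz_cols <- bio3d::atom2xyz(ca)
  xyz_all <- pdb$xyz
  if (is.null(dim(xyz_all))) xyz_all <- matrix(xyz_all, nrow = 1L)
  n_models <- if (first_only) 1L else nrow(xyz_all)

  lapply(seq_len(n_models), function(m) {
    calpha_model(unflatten_xyz(unname(xyz_all[m, xyz_cols])),
                 chain[keep], resno[keep], insert[keep],
                 aa = atom$resid[ca])
  })
}

# Pick, per residue key, the surviving row among altloc duplicates.
# Returns indices into `keys`. Errors on genuine duplicates (same key, same
# altloc code twice).
resolve_altlocs <- function(keys, alt, occ, path) {
  idx <- seq_along(keys)
  picked <- vapply(split(idx, factor(keys, levels = unique(keys))),
    function(g) {
      if (length(g) == 1L) return(g)
      if (anyDuplicated(alt[g]))
        stop("duplicate residue key after altloc resolution in ", path, ": ",
             keys[g[1L]], call. = FALSE)
      g[order(-occ[g], alt[g])][1L]
    }, integer(1L))
  sort(unname(picked))
}

#' Write C-alpha frames as a multi-model PDB trajectory
#'
#' Writes standard MODEL/ENDMDL blocks numbered from 1, one CA ATOM record per
#' bead (element C), coordinates at 3 decimals. The output round-trips through
#' [read_calpha_trajectory()] to within formatting precision (1e-3 Angstrom).
#'
#' @param frames a list of [calpha_model()]s sharing identical residue keys,
#'   or a single model.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_multimodel_pdb <- function(frames, path) {
  if (inherits(frames, "calpha_model")) frames <- list(frames)
  if (length(frames) == 0L)
    stop("no frames to write", call. = FALSE)
  keys0 <- residue_keys(frames[[1L]])
  for (f in frames)
    if (!identical(residue_keys(f), keys0))
      stop("all frames must share identical residue keys", call. = FALSE)

  ref <- frames[[1L]]
  n <- n_beads(ref)
  aa <- if (is.null(ref$aa)) rep("ALA", n) else ref$aa
  ch <- ifelse(ref$chain == "", " ", substr(ref$chain, 1L, 1L))
  ins <- ifelse(ref$insert == "", " ", substr(ref$insert, 1L, 1L))

  con <- file(path, open = "wt")
  on.exit(close(con))
  for (m in seq_along(frames)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- frames[[m]]$xyz
    writeLines(sprintf(
      "ATOM  %5d  CA  %3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(n), aa, ch, ref$resno, ins,
      xyz[, 1L], xyz[, 2L], xyz[, 3L]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
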