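# Alignment-guided rigid-body superposition: residue correspondence comes
# from the group alignment, the fit is a least-squares Kabsch (SVD)
# rotation + translation over CA atoms, and the resulting transform is
# applied to the member's full structure (all chains and ligands).

#' Residue correspondence between two aligned members
#'
#' Pairs of sequence positions that share an alignment column, restricted
#' to an optional column range and to residues modeled in both structures.
#'
#' @param ga The group alignment.
#' @param ref_member,target_member Member uids (both present in `ga`).
#' @param ref_structure,target_structure Their `structure_model`s.
#' @param entities Named list of entities (for sequence lengths).
#' @param column_range Optional `c(begin, end)` restriction in alignment
#'   columns.
#' @return `data.frame` with columns `column`, `ref_seq_pos`,
#'   `target_seq_pos`. Fewer than 3 pairs is an error (no rigid fit is
#'   possible).
#' @export
correspondence <- function(ga, ref_member, target_member,
                           ref_structure, target_structure, entities,
                           column_range = NULL) {
  col_of <- function(uid, structure) {
    ent <- entities[[uid]]
    map <- .member_col_map(ga, uid, nchar(ent$sequence))
    inst <- .instance_for_member(structure, uid)
    has_ca <- inst$atoms$seq_pos[inst$atoms$atom_name == "CA"]
    ok <- !is.na(map) & inst$residues$modeled &
      inst$residues$seq_pos %in% has_ca
    setNames(inst$residues$seq_pos[ok], map[ok])
  }
  ref_map <- col_of(ref_member, ref_structure)
  tgt_map <- col_of(target_member, target_structure)
  cols <- intersect(as.integer(names(ref_map)), as.integer(names(tgt_map)))
  if (!is.null(column_range)) {
    cols <- cols[cols >= column_range[1] & cols <= column_range[2]]
  }
  cols <- sort(cols)
  if (length(cols) < 3L) {
    stop("fewer than 3 corresponding residues; cannot superpose",
         call. = FALSE)
  }
  data.frame(column = cols,
             ref_seq_pos = unname(ref_map[as.character(cols)]),
             target_seq_pos = unname(tgt_map[as.character(cols)]))
}

#' Kabsch rigid-body superposition
#'
#' Least-squares optimal rotation and translation mapping `target_coords`
#' onto `ref_coords` (SVD solution with reflection correction), with the
#' RMSD evaluated after transformation. Applying the result means
#' `x' = R x + t`.
#'
#' @param ref_coords,target_coords Equal-size `n x 3` matrices, `n >= 3`,
#'   not all collinear.
#' @return An object of class `superposition_result`: `rotation` (3x3,
#'   proper orthonormal), `translation` (length 3, Angstrom), `n_pairs`,
#'   `rmsd`, `column_range` (filled in by [superpose_members()]).
#' @export
kabsch <- function(ref_coords, target_coords) {
  ref_coords <- as.matrix(ref_coords)
  target_coords <- as.matrix(target_coords)
  n <- nrow(ref_coords)
  if (n < 3L || nrow(target_coords) != n) {
    stop("need two equal-length coordinate sets with at least 3 points",
         call. = FALSE)
  }
  cr <- colMeans(ref_coords)
  ct <- colMeans(target_coords)
  A <- sweep(ref_coords, 2, cr)
  B <- sweep(target_coords, 2, ct)
  if (min(svd(B)$d) < 1e-9 && min(svd(A)$d) < 1e-9) {
    stop("degenerate (collinear) geometry; rotation is not determined",
         call. = FALSE)
  }
  H <- t(B) %*% A          # covariance of target against reference
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- cr - as.vector(R %*% ct)
  moved <- sweep(target_coords %*% t(R), 2, t_vec, "+")
  rmsd <- sqrt(mean(rowSums((moved - ref_coords)^2)))
  structure(list(rotation = R, translation = t_vec, n_pairs = n,
                 rmsd = rmsd, column_range = NULL),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat("<superposition_result> n_pairs = ", x$n_pairs,
      ", rmsd = ", format(x$rmsd, digits = 4), " A",
      if (!is.null(x$column_range)) paste0(", columns ", x$column_range[1],
                                           "-", x$column_range[2]),
      "\n", sep = "")
  invisible(x)
}

#' @noRd
.ca_coords_at <- function(structure, member_uid, seq_pos) {
  inst <- .instance_for_member(structure, member_uid)
  ca <- inst$atoms[inst$atoms$atom_name == "CA", , drop = FALSE]
  as.matrix(ca[match(seq_pos, ca$seq_pos), c("x", "y", "z")])
}

#' @noRd
.transform_structure <- function(structure, rotation, translation) {
  structure$chains <- lapply(structure$chains, function(ch) {
    if (nrow(ch$atoms) > 0L) {
      xyz <- as.matrix(ch$atoms[, c("x", "y", "z")])
      ch$atoms[, c("x", "y", "z")] <-
        sweep(xyz %*% t(rotation), 2, translation, "+")
    }
    ch
  })
  if (nrow(structure$ligands) > 0L) {
    xyz <- as.matrix(structure$ligands[, c("x", "y", "z")])
    structure$ligands[, c("x", "y", "z")] <-
      sweep(xyz %*% t(rotation), 2, translation, "+")
  }
  structure
}

#' Superpose group members onto a reference
#'
#' For each target member, residue correspondence with the reference is
#' taken from the group alignment (optionally restricted to a column
#' range), a Kabsch fit is computed over the corresponding CA atoms, and
#' the whole target structure (all chains and ligands) is transformed.
#' RMSD can additionally be evaluated over a separate column range
#' (`eval_range`), e.g. to measure how far a mobile domain sits after
#' fitting on a fixed domain.
#'
#' @param group A `structure_group`.
#' @param ga The group alignment.
#' @param structures Named list of `structure_model` by entry id.
#' @param entities Named list of entities.
#' @param ref_member Reference member uid (default: first member with a
#'   structure).
#' @param targets Target member uids (default: all other members with
#'   structures).
#' @param column_range Optional fitting restriction `c(begin, end)`.
#' @param eval_range Optional evaluation range; when given, `eval_rmsd` is
#'   reported over the correspondences inside it.
#' @return Named list per target: `result` (a `superposition_result`, with
#'   `eval_rmsd` when requested) and `structure` (the transformed model).
#'   Members whose correspondence fails are skipped with a warning.
#' @export
superpose_members <- function(group, ga, structures, entities,
                              ref_member = NULL, targets = NULL,
                              column_range = NULL, eval_range = NULL) {
  entry_of <- function(uid) entities[[uid]]$entry_id
  with_structure <- Filter(function(uid) {
    !is.null(entities[[uid]]) && entry_of(uid) %in% names(structures)
  }, intersect(group$member_uids, names(ga$members)))
  if (is.null(ref_member)) ref_member <- with_structure[1]
  if (is.null(targets)) targets <- setdiff(with_structure, ref_member)
  ref_structure <- structures[[entry_of(ref_member)]]
  out <- list()
  for (uid in targets) {
    tgt_structure <- structures[[entry_of(uid)]]
    corr <- tryCatch(
      correspondence(ga, ref_member, uid, ref_structure, tgt_structure,
                     entities, column_range),
      error = function(e) e)
    if (inherits(corr, "error")) {
      warning("skipping ", uid, ": ", conditionMessage(corr), call. = FALSE)
      next
    }
    ref_xyz <- .ca_coords_at(ref_structure, ref_member, corr$ref_seq_pos)
    tgt_xyz <- .ca_coords_at(tgt_structure, uid, corr$target_seq_pos)
    fit <- kabsch(ref_xyz, tgt_xyz)
    fit$column_range <- column_range
    moved <- .transform_structure(tgt_structure, fit$rotation, fit$translation)
    if (!is.null(eval_range)) {
      ecorr <- correspondence(ga, ref_member, uid, ref_structure,
                              tgt_structure, entities, eval_range)
      e_ref <- .ca_coords_at(ref_structure, ref_member, ecorr$ref_seq_pos)
      e_tgt <- .ca_coords_at(moved, uid, ecorr$target_seq_pos)
      fit$eval_rmsd <- sqrt(mean(rowSums((e_tgt - e_ref)^2)))
      fit$eval_range <- eval_range
    }
    out[[uid]] <- list(result = fit, structure = moved)
  }
  out
}

#' Write a superposition RMSD report (TSV)
#'
#' @param superposition Result of [superpose_members()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_superposition_report <- function(superposition, path) {
  rows <- lapply(names(superposition), function(uid) {
    r <- superposition[[uid]]$result
    data.frame(member_uid = uid, n_pairs = r$n_pairs,
               rmsd = round(r$rmsd, 6),
               column_range = if (is.null(r$column_range)) "full"
               else paste0(r$column_range[1], ":", r$column_range[2]),
               eval_rmsd = if (is.null(r$eval_rmsd)) NA_real_
               else round(r$eval_rmsd, 6),
               stringsAsFactors = FALSE)
  })
  .write_tsv(do.call(rbind, rows), path)
}
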