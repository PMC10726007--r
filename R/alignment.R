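# Reference-anchored (star) group alignment and its summary tracks.
#
# Columns are the positions 1..L of the reference sequence (the accession
# reference for accession groups, the cluster representative for identity
# groups). Each member is aligned pairwise to the reference; member
# insertions relative to the reference are recorded but occupy no column.

#' Build the group alignment
#'
#' Reference-anchored star alignment of a group's members. For
#' reference-accession groups the anchor is the group's reference sequence;
#' for sequence-identity groups the anchor is the cluster representative
#' (the group's first member). Deposition groups have no sequence-level
#' alignment.
#'
#' @param group A `structure_group` (see [build_groups()]).
#' @param entities Named list of [polymer_entity()] covering the members.
#' @param config A [clustering_config()] (matrix and gap penalties).
#' @return An object of class `group_alignment` with fields `group_id`,
#'   `n_columns`, `reference_uid`, `reference_sequence`, `members` (named
#'   list of aligned-region `data.frame`s with columns `member_begin`,
#'   `member_end`, `column_begin`, `column_end`), `insertions` (named list
#'   of `data.frame`s with `member_pos`, `after_column`) and `depth`
#'   (per-column member count).
#' @export
build_group_alignment <- function(group, entities,
                                  config = clustering_config()) {
  stopifnot(inherits(group, "structure_group"))
  if (group$provenance == "deposition") {
    stop("deposition groups aggregate entries, not sequences; ",
         "no group alignment is defined for them", call. = FALSE)
  }
  if (group$provenance == "reference_accession") {
    ref_seq <- group$reference_sequence
    ref_uid <- group$accession %||% group$group_id
  } else {
    ref_uid <- group$reference_uid %||% group$member_uids[1]
    ent <- entities[[ref_uid]]
    if (is.null(ent)) stop("reference member ", ref_uid,
                           " missing from entities", call. = FALSE)
    ref_seq <- ent$sequence
  }
  n_col <- nchar(ref_seq)
  members <- list()
  insertions <- list()
  depth <- integer(n_col)
  for (uid in group$member_uids) {
    ent <- entities[[uid]]
    if (is.null(ent)) {
      warning("member ", uid, " has no sequence; skipped", call. = FALSE)
      next
    }
    aln <- align_pair_global(ref_seq, ent$sequence, config)
    p <- aln$aligned_pairs
    if (nrow(p) == 0L) {
      warning("member ", uid, " failed to align; skipped", call. = FALSE)
      next
    }
    brk <- c(TRUE, diff(p[, 1]) != 1L | diff(p[, 2]) != 1L)
    run <- cumsum(brk)
    regions <- do.call(rbind, lapply(split(seq_len(nrow(p)), run), function(ix) {
      data.frame(member_begin = p[ix[1], 2], member_end = p[ix[length(ix)], 2],
                 column_begin = p[ix[1], 1], column_end = p[ix[length(ix)], 1])
    }))
    rownames(regions) <- NULL
    members[[uid]] <- regions
    ins_pos <- setdiff(seq_len(nchar(ent$sequence)), p[, 2])
    if (length(ins_pos) > 0L) {
      after <- vapply(ins_pos, function(mp) {
        prior <- p[p[, 2] < mp, 1]
        if (length(prior) == 0L) 0L else as.integer(max(prior))
      }, integer(1))
      insertions[[uid]] <- data.frame(member_pos = ins_pos, after_column = after)
    }
    cols <- p[, 1]
    depth[cols] <- depth[cols] + 1L
  }
  structure(list(group_id = group$group_id, n_columns = n_col,
                 reference_uid = ref_uid, reference_sequence = ref_seq,
                 members = members, insertions = insertions, depth = depth),
            class = "group_alignment")
}

#' @export
print.group_alignment <- function(x, ...) {
  cat("<group_alignment> ", x$group_id, ": ", length(x$members),
      " member(s) over ", x$n_columns, " columns (reference ",
      x$reference_uid, ")\n", sep = "")
  invisible(x)
}

# member position -> column map (integer vector over 1..member length,
# NA where the position is an insertion relative to the reference)
#' @noRd
.member_col_map <- function(ga, uid, member_length) {
  reg <- ga$members[[uid]]
  if (is.null(reg)) stop("member ", uid, " is not in the group alignment",
                         call. = FALSE)
  map <- rep(NA_integer_, member_length)
  for (k in seq_len(nrow(reg))) {
    map[reg$member_begin[k]:reg$member_end[k]] <-
      reg$column_begin[k]:reg$column_end[k]
  }
  map
}

# per-column symbol for one member: the residue where aligned, "-" where the
# member's alignment spans the column but skips it (deletion), NA outside
# the member's first..last aligned column (terminal truncation).
#' @noRd
.column_symbols <- function(ga, uid, sequence) {
  reg <- ga$members[[uid]]
  sym <- rep(NA_character_, ga$n_columns)
  if (is.null(reg)) return(sym)
  span <- seq(min(reg$column_begin), max(reg$column_end))
  sym[span] <- "-"
  chars <- strsplit(sequence, "")[[1]]
  for (k in seq_len(nrow(reg))) {
    sym[reg$column_begin[k]:reg$column_end[k]] <-
      chars[reg$member_begin[k]:reg$member_end[k]]
  }
  sym
}

#' @noRd
.alignment_symbol_matrix <- function(ga, entities) {
  uids <- names(ga$members)
  mat <- matrix(NA_character_, nrow = length(uids), ncol = ga$n_columns,
                dimnames = list(uids, NULL))
  for (uid in uids) {
    mat[uid, ] <- .column_symbols(ga, uid, entities[[uid]]$sequence)
  }
  mat
}

#' Consensus sequence track
#'
#' Per column, the most frequent symbol over members, counting a gap
#' (deletion relative to the reference) as a symbol. Members whose aligned
#' span does not reach the column are excluded from that column. Ties break
#' residue-over-gap, then alphabetically.
#'
#' @param ga A [build_group_alignment()] result.
#' @param entities Named list of entities providing member sequences.
#' @return A symbol [positional_track()]; columns no member spans are `NA`.
#' @export
consensus_track <- function(ga, entities) {
  mat <- .alignment_symbol_matrix(ga, entities)
  values <- vapply(seq_len(ga$n_columns), function(cc) {
    col <- mat[, cc]
    col <- col[!is.na(col)]
    if (length(col) == 0L) return(NA_character_)
    tab <- table(col)
    best <- max(tab)
    cand <- sort(names(tab)[tab == best])
    residues <- setdiff(cand, "-")
    if (length(residues) > 0L) residues[1] else "-"
  }, character(1))
  positional_track("consensus", ga$group_id, "symbol", values,
                   "modal symbol per alignment column (gap counts as a symbol)")
}

#' Sequence variation track
#'
#' Per column, `1 - modal residue count / members with a residue there`;
#' 0 means perfectly conserved. Columns where no member has a residue are
#' `NA`. Values are invariant under member reordering.
#'
#' @inheritParams consensus_track
#' @return A fraction [positional_track()].
#' @export
variation_track <- function(ga, entities) {
  mat <- .alignment_symbol_matrix(ga, entities)
  values <- vapply(seq_len(ga$n_columns), function(cc) {
    col <- mat[, cc]
    col <- col[!is.na(col) & col != "-"]
    if (length(col) == 0L) return(NA_real_)
    1 - max(table(col)) / length(col)
  }, numeric(1))
  positional_track("variation", ga$group_id, "fraction", values,
                   "1 - modal residue frequency among members with a residue")
}

#' Paginate group-alignment members
#'
#' Members are presented in blocks (50 by default, matching the display
#' convention for large groups), ordered by the supplied ranking or by
#' alignment order.
#'
#' @param ga A `group_alignment`.
#' @param page 1-based page index.
#' @param page_size Members per page.
#' @param ranking Optional character vector giving the member order.
#' @return Character vector of member uids on the page (empty when `page`
#'   is beyond the last page).
#' @export
paginate <- function(ga, page, page_size = 50L, ranking = NULL) {
  if (page < 1L) stop("page must be >= 1", call. = FALSE)
  uids <- ranking %||% names(ga$members)
  from <- (page - 1L) * page_size + 1L
  if (from > length(uids)) return(character())
  uids[from:min(length(uids), from + page_size - 1L)]
}
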