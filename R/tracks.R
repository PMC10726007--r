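# Positional tracks: per-alignment-column values derived from member
# structures and annotations. Three distinct denominators are used, one per
# track family:
#   * structural-feature frequencies: members with a MODELED residue at the
#     column;
#   * per-ligand binding frequencies: members contacting that ligand
#     ANYWHERE (so a ligand seen in one member still shows frequency 1.0 at
#     its contact columns, instead of a near-zero group-wide rate);
#   * the global binding histogram: raw (member, ligand) contact events.

.TRACK_KINDS <- c("symbol", "fraction", "count", "region", "score")

#' Construct a positional track
#'
#' @param track_id Track name (e.g. `"consensus"`, `"helix"`).
#' @param group_id Owning group.
#' @param kind One of `symbol`, `fraction`, `count`, `region`, `score`.
#' @param values Per-column vector, or for `region` tracks a `data.frame`
#'   with `column_begin`, `column_end`, `label` (sorted, non-overlapping).
#' @param provenance_note Free-text description of how values were derived.
#' @return An object of class `positional_track`.
#' @export
positional_track <- function(track_id, group_id, kind, values,
                             provenance_note = "") {
  kind <- match.arg(kind, .TRACK_KINDS)
  if (kind == "fraction") {
    v <- values[!is.na(values)]
    if (any(v < 0 | v > 1)) stop("fraction track values must lie in [0,1]",
                                 call. = FALSE)
  }
  if (kind == "count" && any(values[!is.na(values)] < 0)) {
    stop("count track values must be non-negative", call. = FALSE)
  }
  if (kind == "region") {
    stopifnot(is.data.frame(values),
              all(c("column_begin", "column_end", "label") %in% names(values)))
    if (nrow(values) > 1L) {
      o <- order(values$column_begin)
      values <- values[o, , drop = FALSE]
      if (any(values$column_begin[-1] <= values$column_end[-nrow(values)])) {
        stop("region track regions must be non-overlapping", call. = FALSE)
      }
    }
    rownames(values) <- NULL
  }
  structure(list(track_id = track_id, group_id = group_id, kind = kind,
                 values = values, provenance_note = provenance_note),
            class = "positional_track")
}

#' @export
print.positional_track <- function(x, ...) {
  cat("<positional_track> ", x$track_id, " (", x$kind, ")\n", sep = "")
  invisible(x)
}

#' @noRd
.runs_to_regions <- function(cols, label) {
  if (length(cols) == 0L) return(NULL)
  cols <- sort(cols)
  brk <- c(TRUE, diff(cols) != 1L)
  run <- cumsum(brk)
  do.call(rbind, lapply(split(cols, run), function(cc) {
    data.frame(column_begin = cc[1], column_end = cc[length(cc)],
               label = label, stringsAsFactors = FALSE)
  }))
}

#' @noRd
.instance_for_member <- function(structure, member_uid) {
  uids <- vapply(structure$chains, function(ch) ch$entity_uid, character(1))
  hit <- match(member_uid, uids)
  if (is.na(hit)) stop("no chain of ", structure$entry_id,
                       " realizes entity ", member_uid, call. = FALSE)
  structure$chains[[hit]]
}

#' Modeled / unmodeled regions of one member in column coordinates
#'
#' Partitions the member's aligned columns into `modeled` regions (atomic
#' coordinates present) and `unmodeled` regions.
#'
#' @param member_uid Entity uid of the member.
#' @param structure The member's `structure_model`.
#' @param ga The group alignment.
#' @return A region [positional_track()].
#' @export
modeled_track <- function(member_uid, structure, ga) {
  inst <- .instance_for_member(structure, member_uid)
  L <- nrow(inst$residues)
  map <- .member_col_map(ga, member_uid, L)
  modeled_cols <- map[inst$residues$modeled & !is.na(map)]
  unmodeled_cols <- map[!inst$residues$modeled & !is.na(map)]
  regions <- rbind(.runs_to_regions(modeled_cols, "modeled"),
                   .runs_to_regions(unmodeled_cols, "unmodeled"))
  positional_track(paste0("modeled:", member_uid), ga$group_id, "region",
                   regions, "aligned columns with/without atomic coordinates")
}

.PLDDT_BINS <- c("very-low", "low", "confident", "very-high")

#' @noRd
.plddt_bin <- function(v) {
  ifelse(is.na(v), NA_character_,
         ifelse(v >= 90, "very-high",
                ifelse(v >= 70, "confident",
                       ifelse(v >= 50, "low", "very-low"))))
}

#' Per-column pLDDT of a computed member
#'
#' The per-residue prediction confidence mapped to alignment columns, plus
#' a companion categorical track with the conventional confidence bins:
#' very-high >= 90, confident [70, 90), low [50, 70), very-low < 50
#' (half-open on the lower side).
#'
#' @inheritParams modeled_track
#' @return List with `score` and `category` [positional_track()]s.
#' @export
plddt_track <- function(member_uid, structure, ga) {
  if (structure$provenance != "computed") {
    stop("pLDDT tracks are defined for computed models only", call. = FALSE)
  }
  inst <- .instance_for_member(structure, member_uid)
  L <- nrow(inst$residues)
  map <- .member_col_map(ga, member_uid, L)
  scores <- rep(NA_real_, ga$n_columns)
  ok <- !is.na(map)
  scores[map[ok]] <- inst$residues$confidence[ok]
  list(score = positional_track(paste0("plddt:", member_uid), ga$group_id,
                                "score", scores, "per-residue pLDDT"),
       category = positional_track(paste0("plddt_bin:", member_uid),
                                   ga$group_id, "symbol", .plddt_bin(scores),
                                   "pLDDT confidence bins (90/70/50)"))
}

# ---------------------------------------------------------------------------
# CA-geometry secondary structure (P-SEA-style)

# Published CA-geometry windows: helix d3 = 5.3 +/- 0.5 A, d4 = 6.4 +/- 0.6 A,
# CA angle 89 +/- 12 deg, CA dihedral 50 +/- 20 deg; strand d2 = 6.7 +/- 0.6,
# d3 = 9.9 +/- 0.9, d4 = 12.4 +/- 1.1, angle 124 +/- 14, |dihedral| in
# [145, 180]. Helix needs 5 consecutive strict hits, strand 4; each region
# may be extended by one residue per side under the relaxed criteria.

#' @noRd
.sse_for_ca_run <- function(xyz) {
  n <- nrow(xyz)
  out <- rep("C", n)
  if (n < 5L) return(out)
  d2 <- d3 <- d4 <- r <- a <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i >= 2L && i + 1L <= n) {
      d2[i] <- .vnorm(xyz[i + 1L, ] - xyz[i - 1L, ])
      r[i] <- .vangle(xyz[i - 1L, ], xyz[i, ], xyz[i + 1L, ]) * 180 / pi
    }
    if (i >= 2L && i + 2L <= n) {
      d3[i] <- .vnorm(xyz[i + 2L, ] - xyz[i - 1L, ])
      a[i] <- .vdihedral(xyz[i - 1L, ], xyz[i, ], xyz[i + 1L, ],
                         xyz[i + 2L, ]) * 180 / pi
    }
    if (i >= 2L && i + 3L <= n) d4[i] <- .vnorm(xyz[i + 3L, ] - xyz[i - 1L, ])
  }
  inw <- function(x, lo, hi) !is.na(x) & x >= lo & x <= hi
  relaxed_h <- inw(d3, 4.8, 5.8) | inw(r, 77, 101)
  strict_h <- (inw(d3, 4.8, 5.8) & inw(d4, 5.8, 7.0)) |
    (inw(r, 77, 101) & inw(a, 30, 70))
  relaxed_s <- inw(d3, 9.0, 10.8)
  strict_s <- (inw(d2, 6.1, 7.3) & inw(d3, 9.0, 10.8) & inw(d4, 11.3, 13.5)) |
    (inw(r, 110, 138) & (inw(a, -180, -125) | inw(a, 145, 180)))
  mask_consecutive <- function(mask, k) {
    res <- rep(FALSE, length(mask))
    run <- rle(mask)
    pos <- cumsum(c(1L, run$lengths))
    for (j in seq_along(run$lengths)) {
      if (run$values[j] && run$lengths[j] >= k) {
        res[pos[j]:(pos[j] + run$lengths[j] - 1L)] <- TRUE
      }
    }
    res
  }
  extend <- function(base, relaxed) {
    left <- c(base[-1], FALSE) & !base
    right <- c(FALSE, base[-length(base)]) & !base
    base | ((left | right) & relaxed)
  }
  helix <- extend(mask_consecutive(strict_h, 5L), relaxed_h)
  strand <- extend(mask_consecutive(strict_s, 4L), relaxed_s)
  out[helix] <- "H"
  out[strand] <- "E"
  out
}

#' Assign secondary structure from CA geometry
#'
#' Per-residue H (helix) / E (strand) / C (coil) labels from CA-only
#' distance, angle and dihedral windows. Chains (or contiguous modeled
#' segments) shorter than 5 residues are labelled all-C; unmodeled residues
#' are labelled C.
#'
#' @param structure A `structure_model`.
#' @return Named list, chain id to character vector of labels over the
#'   chain's residues (in `seq_pos` order).
#' @export
assign_secondary_structure <- function(structure) {
  out <- list()
  for (ch in structure$chains) {
    res <- ch$residues
    labels <- rep("C", nrow(res))
    ca <- ch$atoms[ch$atoms$atom_name == "CA", , drop = FALSE]
    pos <- res$seq_pos[res$modeled]
    pos <- pos[pos %in% ca$seq_pos]
    if (length(pos) > 0L) {
      brk <- c(TRUE, diff(pos) != 1L)
      for (seg in split(pos, cumsum(brk))) {
        xyz <- as.matrix(ca[match(seg, ca$seq_pos), c("x", "y", "z")])
        labels[match(seg, res$seq_pos)] <- .sse_for_ca_run(xyz)
      }
    }
    out[[ch$chain_id]] <- labels
  }
  out
}

#' Structural-feature frequency track
#'
#' Per column, the fraction of members whose residue at that column carries
#' the feature, over members with a modeled residue there. `NA` where no
#' member has a modeled residue.
#'
#' @param group A `structure_group`.
#' @param ga The group alignment.
#' @param entities Named list of entities.
#' @param structures Named list of `structure_model` by entry id (needed
#'   for `helix` / `strand`).
#' @param feature `"helix"`, `"strand"`, or
#'   `list(source = "PFAM", id = "PF0001")` for a domain feature (`id`
#'   optional: any domain of the source then counts).
#' @return A fraction [positional_track()].
#' @export
feature_frequency_track <- function(group, ga, entities, structures = NULL,
                                    feature) {
  numer <- integer(ga$n_columns)
  denom <- integer(ga$n_columns)
  is_domain <- is.list(feature)
  if (is_domain && !(feature$source %in% .DOMAIN_SOURCES)) {
    stop("unknown domain source '", feature$source, "'", call. = FALSE)
  }
  for (uid in names(ga$members)) {
    ent <- entities[[uid]]
    L <- nchar(ent$sequence)
    map <- .member_col_map(ga, uid, L)
    struct <- if (!is.null(structures)) structures[[ent$entry_id]] else NULL
    if (is.null(struct)) next
    inst <- .instance_for_member(struct, uid)
    has_feature <- rep(FALSE, L)
    if (is_domain) {
      da <- ent$domain_annotations
      da <- da[da$source == feature$source, , drop = FALSE]
      if (!is.null(feature$id)) da <- da[da$domain_id == feature$id, , drop = FALSE]
      for (k in seq_len(nrow(da))) {
        has_feature[da$begin[k]:da$end[k]] <- TRUE
      }
    } else {
      labels <- assign_secondary_structure(struct)[[inst$chain_id]]
      want <- if (feature == "helix") "H" else if (feature == "strand") "E"
      else stop("unknown feature '", feature, "'", call. = FALSE)
      has_feature <- labels == want
    }
    modeled <- inst$residues$modeled
    ok <- !is.na(map) & modeled
    denom[map[ok]] <- denom[map[ok]] + 1L
    hit <- ok & has_feature
    numer[map[hit]] <- numer[map[hit]] + 1L
  }
  values <- ifelse(denom == 0L, NA_real_, numer / denom)
  name <- if (is_domain) paste0("domain:", feature$source,
                                if (!is.null(feature$id)) paste0(":", feature$id))
  else feature
  positional_track(name, ga$group_id, "fraction", values,
                   "feature frequency over members modeled at each column")
}

# ---------------------------------------------------------------------------
# ligand contacts and binding tracks

#' Detect protein-ligand contacts
#'
#' A residue is in contact with a ligand component when any of its heavy
#' (non-hydrogen) atoms lies within `cutoff` Angstrom of any heavy ligand
#' atom. Waters are excluded by construction ([structure_model()] rejects
#' them as ligands).
#'
#' @param structure A `structure_model` with at least the ligand table.
#' @param cutoff Heavy-atom distance cutoff in Angstrom (default 4.5).
#' @return `data.frame` with columns `member_uid`, `chain_id`, `seq_pos`,
#'   `comp_id`, `min_distance` (one row per residue-ligand pair in
#'   contact).
#' @export
detect_contacts <- function(structure, cutoff = 4.5) {
  empty <- data.frame(member_uid = character(), chain_id = character(),
                      seq_pos = integer(), comp_id = character(),
                      min_distance = numeric(), stringsAsFactors = FALSE)
  lg <- structure$ligands
  lg <- lg[lg$element != "H", , drop = FALSE]
  if (nrow(lg) == 0L) return(empty)
  out <- list()
  for (ch in structure$chains) {
    at <- ch$atoms[ch$atoms$element != "H", , drop = FALSE]
    if (nrow(at) == 0L) next
    pxyz <- as.matrix(at[, c("x", "y", "z")])
    for (comp in unique(lg$comp_id)) {
      lxyz <- as.matrix(lg[lg$comp_id == comp, c("x", "y", "z"), drop = FALSE])
      # all-pairs distances (desk-scale structures; no spatial index needed)
      d2 <- outer(rowSums(pxyz^2), rowSums(lxyz^2), "+") -
        2 * pxyz %*% t(lxyz)
      mind <- sqrt(pmax(0, apply(d2, 1, min)))
      per_res <- tapply(mind, at$seq_pos, min)
      hit <- per_res <= cutoff
      if (any(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          member_uid = ch$entity_uid, chain_id = ch$chain_id,
          seq_pos = as.integer(names(per_res))[hit], comp_id = comp,
          min_distance = unname(per_res[hit]), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Binding-site tracks
#'
#' Two track families from per-member contact tables:
#' \itemize{
#'   \item `global`: a count per column of (member, ligand-component)
#'     contact events observed there;
#'   \item `per_ligand`: for each component, the fraction of members
#'     contacting it at the column, relative to the members contacting it
#'     anywhere (a ligand bound by a single member therefore reaches 1.0 at
#'     its contact columns rather than being diluted by the group size).
#' }
#'
#' @param group A `structure_group`.
#' @param ga The group alignment.
#' @param contacts `data.frame` as returned by [detect_contacts()]
#'   (rows from several members may be concatenated).
#' @param entities Named list of entities (for sequence lengths).
#' @return List with `global` (count track) and `per_ligand` (named list of
#'   fraction tracks; components with zero contacting members are omitted).
#' @export
binding_tracks <- function(group, ga, contacts, entities) {
  global <- integer(ga$n_columns)
  events <- list()  # comp_id -> list(member -> columns)
  members <- intersect(unique(contacts$member_uid), names(ga$members))
  for (uid in members) {
    ent <- entities[[uid]]
    map <- .member_col_map(ga, uid, nchar(ent$sequence))
    rows <- contacts[contacts$member_uid == uid, , drop = FALSE]
    for (comp in unique(rows$comp_id)) {
      pos <- rows$seq_pos[rows$comp_id == comp]
      cols <- unique(map[pos])
      cols <- cols[!is.na(cols)]
      if (length(cols) == 0L) next
      global[cols] <- global[cols] + 1L
      if (is.null(events[[comp]])) events[[comp]] <- list()
      events[[comp]][[uid]] <- cols
    }
  }
  per_ligand <- list()
  for (comp in names(events)) {
    n_members <- length(events[[comp]])
    counts <- integer(ga$n_columns)
    for (cols in events[[comp]]) counts[cols] <- counts[cols] + 1L
    per_ligand[[comp]] <- positional_track(
      paste0("binding:", comp), ga$group_id, "fraction", counts / n_members,
      sprintf("fraction of the %d member(s) contacting %s", n_members, comp))
  }
  list(global = positional_track("global_binding", ga$group_id, "count",
                                 global, "(member, ligand) contact events per column"),
       per_ligand = per_ligand)
}

#' Mutation-marker columns of a member
#'
#' Columns where the member residue differs from the reference residue
#' (defined for reference-accession groups; gaps are not markers). A single
#' substitution at reference position p yields the marker set `{p}`.
#'
#' @param member_uid Member entity uid.
#' @param ga The group alignment (anchored on the reference sequence).
#' @param entities Named list of entities.
#' @return Sorted integer vector of marker columns.
#' @export
mutation_markers <- function(member_uid, ga, entities) {
  ent <- entities[[member_uid]]
  sym <- .column_symbols(ga, member_uid, ent$sequence)
  ref <- strsplit(ga$reference_sequence, "")[[1]]
  which(!is.na(sym) & sym != "-" & sym != ref)
}

#' Export tracks as a BED-like TSV
#'
#' One row per region or per run of equal value: `group_id`, `track_id`,
#' `column_begin`, `column_end`, `value`.
#'
#' @param tracks List of [positional_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracks_tsv <- function(tracks, path) {
  rows <- list()
  for (tr in tracks) {
    if (tr$kind == "region") {
      v <- tr$values
      rows[[length(rows) + 1L]] <- data.frame(
        group_id = tr$group_id, track_id = tr$track_id,
        column_begin = v$column_begin, column_end = v$column_end,
        value = v$label, stringsAsFactors = FALSE)
    } else {
      vals <- as.character(tr$values)
      vals[is.na(vals)] <- "."
      brk <- c(TRUE, vals[-1] != vals[-length(vals)])
      run <- cumsum(brk)
      begin <- which(brk)
      end <- c(begin[-1] - 1L, length(vals))
      rows[[length(rows) + 1L]] <- data.frame(
        group_id = tr$group_id, track_id = tr$track_id,
        column_begin = begin, column_end = end, value = vals[begin],
        stringsAsFactors = FALSE)
    }
  }
  .write_tsv(do.call(rbind, rows), path)
}
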