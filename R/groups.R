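# Group assembly under three provenance methods, member ranking, and the
# group-summary histograms with stacked subgroup filtering.
#
# Granularity: deposition groups aggregate entries (whole structures);
# reference-accession and sequence-identity groups aggregate entities
# (individual polymer sequences).

.GROUP_PROVENANCE <- c("deposition", "reference_accession", "sequence_identity")
.SUMMARY_ATTRIBUTES <- c("organism", "release_year",
                         "determination_methodology", "domain_source")

#' @noRd
.new_group <- function(group_id, provenance, member_uids, title,
                       threshold = NULL, reference_sequence = NULL,
                       accession = NULL, reference_uid = NULL) {
  if (length(member_uids) < 1L) stop("a group needs at least one member",
                                     call. = FALSE)
  if ((provenance == "sequence_identity") != !is.null(threshold)) {
    stop("threshold is present iff provenance is sequence_identity",
         call. = FALSE)
  }
  if ((provenance == "reference_accession") != !is.null(reference_sequence)) {
    stop("reference_sequence is present iff provenance is reference_accession",
         call. = FALSE)
  }
  structure(list(group_id = group_id, provenance = provenance,
                 threshold = threshold, member_uids = member_uids,
                 reference_sequence = reference_sequence,
                 accession = accession, reference_uid = reference_uid,
                 title = title),
            class = "structure_group")
}

#' @export
print.structure_group <- function(x, ...) {
  cat("<structure_group> ", x$group_id, " (", x$provenance, "): ",
      length(x$member_uids), " member(s)\n", sep = "")
  invisible(x)
}

#' Assemble groups of entities or entries
#'
#' Three provenance methods:
#' \describe{
#'   \item{deposition}{entries deposited together; members are entry ids,
#'     keyed on `deposition_group_id`.}
#'   \item{reference_accession}{entities sharing a reference-database
#'     accession; entities without an accession belong to no group. The
#'     group's reference sequence is taken from `reference_sequences`
#'     (named by accession) when supplied, else from the longest member
#'     (ties by uid).}
#'   \item{sequence_identity}{sequence clusters (see
#'     [cluster_sequences()]) relabelled as groups; the cluster
#'     representative becomes the alignment reference.}
#' }
#'
#' @param entities Named list of [polymer_entity()].
#' @param clusters List of `seq_cluster` (required for
#'   `sequence_identity`; all at one threshold).
#' @param method One of `"deposition"`, `"reference_accession"`,
#'   `"sequence_identity"`.
#' @param reference_sequences Optional named character vector/list mapping
#'   accession to its reference sequence.
#' @return List of `structure_group`.
#' @export
build_groups <- function(entities, clusters = NULL,
                         method = c("deposition", "reference_accession",
                                    "sequence_identity"),
                         reference_sequences = NULL) {
  method <- match.arg(method)
  if (method == "deposition") {
    dep <- unname(vapply(entities,
                         function(e) e$deposition_group_id %||% NA_character_,
                         character(1)))
    entry <- unname(vapply(entities, function(e) e$entry_id, character(1)))
    keys <- sort(unique(dep[!is.na(dep)]))
    return(lapply(keys, function(k) {
      members <- sort(unique(entry[!is.na(dep) & dep == k]))
      .new_group(paste0("dep_", k), "deposition", members,
                 title = paste("Deposition group", k))
    }))
  }
  if (method == "reference_accession") {
    acc <- unname(vapply(entities, function(e) e$accession %||% NA_character_,
                         character(1)))
    uids <- unname(vapply(entities, function(e) e$entity_uid, character(1)))
    keys <- sort(unique(acc[!is.na(acc)]))
    return(lapply(keys, function(k) {
      members <- uids[!is.na(acc) & acc == k]
      ref <- if (!is.null(reference_sequences) &&
                 !is.null(reference_sequences[[k]])) {
        reference_sequences[[k]]
      } else {
        seqs <- unname(vapply(entities[members], function(e) e$sequence,
                              character(1)))
        seqs[order(-nchar(seqs), members)][1]
      }
      .new_group(paste0("uni_", k), "reference_accession", members,
                 title = paste("Reference accession group", k),
                 reference_sequence = ref, accession = k)
    }))
  }
  # sequence_identity
  if (is.null(clusters) || length(clusters) == 0L) {
    stop("sequence_identity grouping requires clusters", call. = FALSE)
  }
  thr <- unique(vapply(clusters, function(cl) cl$threshold, numeric(1)))
  if (length(thr) != 1L) {
    stop("clusters mix thresholds: ", paste(thr, collapse = ", "),
         call. = FALSE)
  }
  pct <- as.integer(round(thr * 100))
  lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    .new_group(sprintf("seqid%d_%04d", pct, i), "sequence_identity",
               cl$member_uids,
               title = sprintf("Sequence identity group (%d%%) %04d", pct, i),
               threshold = thr, reference_uid = cl$representative_uid)
  })
}

#' @noRd
.group_entities <- function(group, entities) {
  if (group$provenance == "deposition") {
    entries <- vapply(entities, function(e) e$entry_id, character(1))
    entities[entries %in% group$member_uids]
  } else {
    entities[intersect(group$member_uids, names(entities))]
  }
}

#' Rank group members
#'
#' For reference-accession groups, members are ordered by reference
#' coverage (fraction of reference positions aligned to a member residue)
#' descending, with ties broken by release date ascending, then uid
#' ascending. Other provenances keep the input order.
#'
#' @param group A `structure_group`.
#' @param entities Named list of entities.
#' @param ga The group alignment (required for accession groups; build it
#'   first with [build_group_alignment()]).
#' @return Permutation of `group$member_uids`.
#' @export
rank_members <- function(group, entities, ga = NULL) {
  if (group$provenance != "reference_accession") return(group$member_uids)
  if (is.null(ga)) {
    stop("ranking an accession group needs its alignment; ",
         "call build_group_alignment() first", call. = FALSE)
  }
  L <- nchar(group$reference_sequence)
  coverage <- vapply(group$member_uids, function(uid) {
    reg <- ga$members[[uid]]
    if (is.null(reg)) return(0)
    sum(reg$column_end - reg$column_begin + 1L) / L
  }, numeric(1))
  dates <- vapply(group$member_uids, function(uid) {
    entities[[uid]]$release_date %||% "9999-12-31"
  }, character(1))
  unname(group$member_uids[order(-coverage, dates, group$member_uids)])
}

#' @noRd
.attribute_values <- function(group, entities, attribute) {
  ents <- .group_entities(group, entities)
  unset <- function(v) is.null(v) || is.na(v) || !nzchar(v)
  if (attribute == "organism") {
    vapply(ents, function(e) {
      if (unset(e$organism)) "unknown" else e$organism
    }, character(1))
  } else if (attribute == "release_year") {
    vapply(ents, function(e) {
      if (unset(e$release_date)) "unknown" else substr(e$release_date, 1, 4)
    }, character(1))
  } else if (attribute == "determination_methodology") {
    vapply(ents, function(e) e$provenance, character(1))
  } else if (attribute == "domain_source") {
    vapply(ents, function(e) {
      src <- unique(e$domain_annotations$source)
      if (length(src) == 0L) "unknown" else paste(sort(src), collapse = "+")
    }, character(1))
  } else {
    stop("unknown attribute '", attribute, "'; supported: ",
         paste(.SUMMARY_ATTRIBUTES, collapse = ", "), call. = FALSE)
  }
}

#' Summarize a group attribute as a histogram
#'
#' Bin counts of one member attribute over the group; members with the
#' attribute unset fall into an `"unknown"` bin. Without a filter the
#' nonmatching counts are all zero.
#'
#' @param group A `structure_group`.
#' @param entities Named list of entities.
#' @param attribute One of `organism`, `release_year`,
#'   `determination_methodology`, `domain_source`.
#' @param subset Optional member uid subset counted as "matching" (used by
#'   [filter_subgroup()]).
#' @return A `histogram_summary`: list with `attribute` and `bins`
#'   (`data.frame` with `label`, `matching_count`, `nonmatching_count`).
#' @export
summarize_group <- function(group, entities, attribute, subset = NULL) {
  values <- .attribute_values(group, entities, attribute)
  uids <- names(values)
  labels <- sort(unique(values))
  if (is.null(subset)) subset <- uids
  bins <- do.call(rbind, lapply(labels, function(lb) {
    in_bin <- values == lb
    data.frame(label = lb,
               matching_count = sum(in_bin & uids %in% subset),
               nonmatching_count = sum(in_bin & !(uids %in% subset)),
               stringsAsFactors = FALSE)
  }))
  structure(list(attribute = attribute, bins = bins),
            class = "histogram_summary")
}

#' @export
print.histogram_summary <- function(x, ...) {
  cat("<histogram_summary> ", x$attribute, "\n", sep = "")
  print(x$bins)
  invisible(x)
}

#' Select a subgroup and recompute all histograms as stacked counts
#'
#' Mirrors clicking one histogram bar: the members in the selected bin form
#' the subgroup, and every summary histogram is recomputed with stacked
#' matching / nonmatching counts (which always sum to the unfiltered
#' counts).
#'
#' @param group A `structure_group`.
#' @param entities Named list of entities.
#' @param attribute Attribute the filter applies to.
#' @param value Bin label to select.
#' @return List with `members` (uids in the subgroup, in group order) and
#'   `summaries` (named list of `histogram_summary` over all supported
#'   attributes).
#' @export
filter_subgroup <- function(group, entities, attribute, value) {
  values <- .attribute_values(group, entities, attribute)
  if (!(value %in% values)) {
    warning("no member falls in bin '", value, "' of ", attribute,
            call. = FALSE)
  }
  keep <- names(values)[values == value]
  ents <- .group_entities(group, entities)
  members_in_order <- if (group$provenance == "deposition") {
    intersect(names(ents), keep)
  } else {
    intersect(group$member_uids, keep)
  }
  summaries <- lapply(.SUMMARY_ATTRIBUTES, function(attr) {
    summarize_group(group, entities, attr, subset = keep)
  })
  names(summaries) <- .SUMMARY_ATTRIBUTES
  list(members = members_in_order, summaries = summaries)
}
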