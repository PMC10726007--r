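# JSON serialization of group documents (provenance, alignment,
# annotations), schema validation, and import for round-tripping.
#
# Field names follow the group-API vocabulary (group_provenance, aligned
# regions, ranking) without claiming wire compatibility with any live
# service. Arrays that must stay arrays are built as R lists so that
# export -> import -> export is byte-stable.

#' Group provenance record
#'
#' Metadata describing a grouping methodology: aggregation granularity
#' (entry for deposition groups, entity otherwise), software name,
#' description and version.
#'
#' @param method Grouping method.
#' @return Named list (serializable as JSON).
#' @export
group_provenance_record <- function(method = c("deposition",
                                               "reference_accession",
                                               "sequence_identity")) {
  method <- match.arg(method)
  descriptions <- c(
    deposition = "structures deposited together as one batch",
    reference_accession = "entities sharing a reference-database accession",
    sequence_identity = "greedy centroid sequence-identity clustering")
  list(method = method,
       granularity = if (method == "deposition") "entry" else "entity",
       software_name = "structgroups",
       description = unname(descriptions[method]),
       version = as.character(utils::packageVersion("structgroups")))
}

#' @noRd
.regions_as_list <- function(regions) {
  lapply(seq_len(nrow(regions)), function(k) {
    list(member_begin = regions$member_begin[k],
         member_end = regions$member_end[k],
         column_begin = regions$column_begin[k],
         column_end = regions$column_end[k])
  })
}

#' @noRd
.subset_alignment <- function(ga, member_filter) {
  unknown <- setdiff(member_filter, names(ga$members))
  if (length(unknown) > 0L) {
    stop("member filter names unknown members: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  ga$members <- ga$members[member_filter]
  ga$insertions <- ga$insertions[intersect(names(ga$insertions), member_filter)]
  depth <- integer(ga$n_columns)
  for (reg in ga$members) {
    for (k in seq_len(nrow(reg))) {
      cols <- reg$column_begin[k]:reg$column_end[k]
      depth[cols] <- depth[cols] + 1L
    }
  }
  ga$depth <- depth
  ga
}

#' Export a group alignment document
#'
#' Serializes the group MSA: reference, per-member aligned regions, and
#' (optionally) the consensus and variation summary tracks. A member
#' filter restricts the emitted members and recomputes the summaries over
#' the subset, mirroring subgroup selection.
#'
#' @param group A `structure_group`.
#' @param ga The group alignment.
#' @param entities Named list of entities.
#' @param include_summary Include consensus/variation tracks?
#' @param member_filter Optional member uid subset.
#' @param path Optional output file; when given the document is written as
#'   pretty JSON.
#' @return The document (named list), invisibly when written.
#' @export
export_group_alignment <- function(group, ga, entities,
                                   include_summary = TRUE,
                                   member_filter = NULL, path = NULL) {
  if (!is.null(member_filter)) ga <- .subset_alignment(ga, member_filter)
  doc <- list(
    group_id = ga$group_id,
    group_provenance = group_provenance_record(group$provenance),
    reference = list(id = ga$reference_uid,
                     sequence = ga$reference_sequence,
                     n_columns = ga$n_columns),
    members = lapply(names(ga$members), function(uid) {
      list(member_uid = uid,
           aligned_regions = .regions_as_list(ga$members[[uid]]))
    }))
  if (include_summary) {
    doc$consensus <- as.list(consensus_track(ga, entities)$values)
    doc$variation <- as.list(variation_track(ga, entities)$values)
  }
  validate_document(doc, "group_alignment")
  if (!is.null(path)) {
    .write_json(doc, path)
    return(invisible(doc))
  }
  doc
}

#' Import a group alignment document
#'
#' @param path JSON path written by [export_group_alignment()].
#' @return The document as nested lists (schema-validated).
#' @export
import_group_alignment <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  validate_document(doc, "group_alignment")
  doc
}

#' Export a group annotations document
#'
#' With `histogram_flag = TRUE` the document carries aggregated positional
#' tracks (feature frequencies, binding histograms); with `FALSE` it
#' carries per-member feature lists in member coordinates together with
#' each member's column mapping.
#'
#' @param group A `structure_group`.
#' @param tracks List of [positional_track()] (histogram mode).
#' @param ga The group alignment (needed for per-member mode).
#' @param member_features Named list (uid to `data.frame` with columns
#'   `feature`, `member_begin`, `member_end`) for per-member mode.
#' @param histogram_flag Boolean selecting the document mode.
#' @param path Optional output file.
#' @return The document (named list).
#' @export
export_group_annotations <- function(group, tracks = NULL, ga = NULL,
                                     member_features = NULL,
                                     histogram_flag = TRUE, path = NULL) {
  if (histogram_flag) {
    annotations <- lapply(tracks %||% list(), function(tr) {
      values <- if (tr$kind == "region") {
        lapply(seq_len(nrow(tr$values)), function(k) {
          list(column_begin = tr$values$column_begin[k],
               column_end = tr$values$column_end[k],
               label = tr$values$label[k])
        })
      } else as.list(tr$values)
      list(track_id = tr$track_id, kind = tr$kind, values = values)
    })
    doc <- list(group_id = group$group_id, mode = "histogram",
                annotations = annotations)
  } else {
    if (is.null(ga)) stop("per-member annotations need the group alignment",
                          call. = FALSE)
    annotations <- lapply(names(member_features %||% list()), function(uid) {
      ft <- member_features[[uid]]
      list(member_uid = uid,
           features = lapply(seq_len(nrow(ft)), function(k) {
             list(feature = ft$feature[k], member_begin = ft$member_begin[k],
                  member_end = ft$member_end[k])
           }),
           aligned_regions = .regions_as_list(ga$members[[uid]]))
    })
    doc <- list(group_id = group$group_id, mode = "per_member",
                annotations = annotations)
  }
  validate_document(doc, "group_annotations")
  if (!is.null(path)) {
    .write_json(doc, path)
    return(invisible(doc))
  }
  doc
}

#' @noRd
.write_json <- function(doc, path) {
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# schema validation (structural subset of JSON Schema: type, required,
# properties, items, enum)

#' @noRd
.schema_cache <- new.env(parent = emptyenv())

#' @noRd
.load_schema <- function(name) {
  if (!exists(name, envir = .schema_cache)) {
    path <- system.file("schemas", paste0(name, ".schema.json"),
                        package = "structgroups")
    if (!nzchar(path)) stop("no schema named '", name, "'", call. = FALSE)
    assign(name, jsonlite::read_json(path, simplifyVector = FALSE),
           envir = .schema_cache)
  }
  get(name, envir = .schema_cache)
}

#' @noRd
.json_type <- function(x) {
  if (is.null(x)) "null"
  else if (is.list(x)) { if (!is.null(names(x)) && length(x) > 0) "object" else "array" }
  else if (is.character(x)) "string"
  else if (is.logical(x)) "boolean"
  else if (is.numeric(x)) { if (is.integer(x) || isTRUE(all.equal(x, round(x)))) "integer" else "number" }
  else "unknown"
}

#' @noRd
.check_schema <- function(x, schema, where) {
  types <- schema$type
  if (!is.null(types)) {
    types <- unlist(types)
    actual <- .json_type(x)
    ok <- actual %in% types ||
      (actual == "integer" && "number" %in% types) ||
      (actual == "array" && "object" %in% types && length(x) == 0L) ||
      (actual == "object" && "array" %in% types)
    if (!ok) stop("schema violation at ", where, ": expected ",
                  paste(types, collapse = "|"), ", got ", actual,
                  call. = FALSE)
  }
  if (!is.null(schema$enum) && !is.null(x)) {
    if (!(x %in% unlist(schema$enum))) {
      stop("schema violation at ", where, ": '", x, "' not in enum",
           call. = FALSE)
    }
  }
  if (!is.null(schema$required)) {
    missing <- setdiff(unlist(schema$required), names(x))
    if (length(missing) > 0L) {
      stop("schema violation at ", where, ": missing required field(s) ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(schema$properties) && is.list(x)) {
    for (nm in intersect(names(schema$properties), names(x))) {
      .check_schema(x[[nm]], schema$properties[[nm]],
                    paste0(where, ".", nm))
    }
  }
  if (!is.null(schema$items) && is.list(x) && is.null(names(x))) {
    for (k in seq_along(x)) {
      .check_schema(x[[k]], schema$items, paste0(where, "[", k, "]"))
    }
  }
  invisible(TRUE)
}

#' Validate a document against a shipped schema
#'
#' Structural validation (types, required fields, enums) against the JSON
#' schemas shipped under `inst/schemas/`.
#'
#' @param doc Document as nested lists.
#' @param schema_name `"group_alignment"`, `"group_annotations"` or
#'   `"group_provenance"`.
#' @return `TRUE` invisibly; errors name the offending path.
#' @export
validate_document <- function(doc, schema_name) {
  .check_schema(doc, .load_schema(schema_name), schema_name)
}
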