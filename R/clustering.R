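# Multi-threshold sequence-identity clustering with incremental update
# semantics. The algorithm is a transparent greedy centroid pass
# (longest-first, CD-HIT style): deterministic, exactly testable, and with
# an import path for externally computed cluster files.

#' Alignment / clustering configuration
#'
#' @param thresholds Identity thresholds as fractions in `(0, 1]`; the
#'   default set matches the standard 30/50/70/90/95/100% ladder.
#' @param substitution_matrix Substitution matrix name (a Biostrings data
#'   set; default BLOSUM62).
#' @param gap_open,gap_extend Affine gap penalties; a gap of length k costs
#'   `gap_open + k * gap_extend`.
#' @return An object of class `clustering_config`.
#' @export
clustering_config <- function(thresholds = c(0.30, 0.50, 0.70, 0.90, 0.95, 1.00),
                              substitution_matrix = "BLOSUM62",
                              gap_open = 11, gap_extend = 1) {
  if (any(thresholds <= 0 | thresholds > 1)) {
    stop("thresholds must lie in (0, 1]", call. = FALSE)
  }
  structure(list(thresholds = thresholds,
                 substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "clustering_config")
}

.submat_cache <- new.env(parent = emptyenv())

#' @noRd
.get_submat <- function(name) {
  if (!exists(name, envir = .submat_cache)) {
    env <- new.env()
    utils::data(list = name, package = "Biostrings", envir = env)
    assign(name, get(name, envir = env), envir = .submat_cache)
  }
  get(name, envir = .submat_cache)
}

#' @noRd
.encode_seq <- function(sequence, alphabet) {
  idx <- match(strsplit(sequence, "")[[1]], alphabet)
  if (anyNA(idx)) {
    stop("sequence contains letters outside the substitution matrix alphabet",
         call. = FALSE)
  }
  idx - 1L
}

#' Global pairwise alignment (Needleman-Wunsch, affine gaps)
#'
#' Optimal global alignment under the configured substitution matrix and
#' affine gap penalties, with deterministic traceback (prefer diagonal,
#' then up, then left on score ties).
#'
#' @param seq_a,seq_b Non-empty one-letter amino-acid strings.
#' @param config A [clustering_config()].
#' @return List with `score` and `aligned_pairs`, a two-column integer
#'   matrix of 1-based positions `(pos_a, pos_b)`, strictly increasing in
#'   both coordinates.
#' @export
align_pair_global <- function(seq_a, seq_b, config = clustering_config()) {
  assert_sequence(seq_a, "seq_a")
  assert_sequence(seq_b, "seq_b")
  mat <- .get_submat(config$substitution_matrix)
  res <- .align_global_cpp(.encode_seq(seq_a, colnames(mat)),
                           .encode_seq(seq_b, colnames(mat)),
                           mat, config$gap_open, config$gap_extend)
  pairs <- res$pairs
  colnames(pairs) <- c("pos_a", "pos_b")
  list(score = res$score, aligned_pairs = pairs)
}

#' Pairwise sequence identity
#'
#' Identity of the optimal global alignment, normalized by the shorter
#' sequence length: `matches / min(len_a, len_b)`. With this normalization
#' a full-length chain and its exact fragment score 1.0, so they co-cluster
#' at the 100% threshold.
#'
#' @inheritParams align_pair_global
#' @return Fraction in `[0, 1]`; symmetric in its arguments.
#' @export
pairwise_identity <- function(seq_a, seq_b, config = clustering_config()) {
  aln <- align_pair_global(seq_a, seq_b, config)
  p <- aln$aligned_pairs
  if (nrow(p) == 0L) return(0)
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  matches <- sum(a[p[, 1]] == b[p[, 2]])
  matches / min(nchar(seq_a), nchar(seq_b))
}

#' @noRd
.cluster_id <- function(threshold, ordinal) {
  sprintf("%d_%04d", as.integer(round(threshold * 100)), ordinal)
}

#' @noRd
.new_cluster <- function(threshold, ordinal, representative_uid) {
  structure(list(cluster_id = .cluster_id(threshold, ordinal),
                 threshold = threshold,
                 representative_uid = representative_uid,
                 member_uids = representative_uid),
            class = "seq_cluster")
}

#' Greedy sequence-identity clustering at one threshold
#'
#' Entities are visited longest-first (ties by `entity_uid` ascending);
#' each joins the earliest-founded cluster whose representative it matches
#' at `>= threshold` identity, else founds a new cluster. The result is a
#' partition of the input and is fully deterministic.
#'
#' @param entities List of [polymer_entity()] (or any objects with
#'   `entity_uid` and `sequence` fields).
#' @param threshold Identity threshold in `(0, 1]`.
#' @param config A [clustering_config()].
#' @return List of `seq_cluster` objects (representative first in
#'   `member_uids`).
#' @export
cluster_sequences <- function(entities, threshold,
                              config = clustering_config()) {
  if (length(entities) == 0L) stop("no entities to cluster", call. = FALSE)
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]", call. = FALSE)
  }
  uids <- unname(vapply(entities, function(e) e$entity_uid, character(1)))
  seqs <- unname(vapply(entities, function(e) e$sequence, character(1)))
  ord <- order(-nchar(seqs), uids)
  clusters <- list()
  reps <- character()
  rep_seqs <- character()
  for (k in ord) {
    assigned <- FALSE
    for (ci in seq_along(clusters)) {
      if (pairwise_identity(seqs[k], rep_seqs[ci], config) >= threshold) {
        clusters[[ci]]$member_uids <- c(clusters[[ci]]$member_uids, uids[k])
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      clusters[[length(clusters) + 1L]] <-
        .new_cluster(threshold, length(clusters) + 1L, uids[k])
      reps <- c(reps, uids[k])
      rep_seqs <- c(rep_seqs, seqs[k])
    }
  }
  clusters
}

#' Incrementally extend an existing clustering
#'
#' New entities are assigned to the first existing representative (scanned
#' in `cluster_id` order) meeting the threshold; unmatched entities found
#' new clusters appended with the next ordinal. Existing memberships never
#' change, mirroring a weekly incremental update.
#'
#' @param existing List of `seq_cluster` at a single threshold (may be
#'   empty, in which case the result equals [cluster_sequences()]).
#' @param new_entities Entities to place.
#' @param config A [clustering_config()].
#' @param threshold Required when `existing` is empty.
#' @return Updated list of clusters.
#' @export
update_clusters <- function(existing, new_entities,
                            config = clustering_config(), threshold = NULL) {
  if (length(existing) == 0L) {
    if (is.null(threshold)) {
      stop("threshold is required when no prior clusters exist", call. = FALSE)
    }
    return(cluster_sequences(new_entities, threshold, config))
  }
  thr <- unique(vapply(existing, function(cl) cl$threshold, numeric(1)))
  if (length(thr) != 1L) {
    stop("existing clusters mix thresholds: ",
         paste(thr, collapse = ", "), call. = FALSE)
  }
  ids <- vapply(existing, function(cl) cl$cluster_id, character(1))
  existing <- existing[order(ids)]
  # representative sequences must be resolvable from new_entities or carried
  # clusters; callers pass the full entity set
  uids <- unname(vapply(new_entities, function(e) e$entity_uid, character(1)))
  seqs <- unname(vapply(new_entities, function(e) e$sequence, character(1)))
  all_members <- unlist(lapply(existing, function(cl) cl$member_uids))
  fresh <- which(!(uids %in% all_members))
  ord <- fresh[order(-nchar(seqs[fresh]), uids[fresh])]
  rep_uids <- vapply(existing, function(cl) cl$representative_uid, character(1))
  rep_seqs <- unname(vapply(rep_uids, function(u) {
    hit <- match(u, uids)
    if (!is.na(hit)) seqs[hit] else NA_character_
  }, character(1)))
  for (k in ord) {
    assigned <- FALSE
    for (ci in seq_along(existing)) {
      if (is.na(rep_seqs[ci])) next
      if (pairwise_identity(seqs[k], rep_seqs[ci], config) >= thr) {
        existing[[ci]]$member_uids <- c(existing[[ci]]$member_uids, uids[k])
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      existing[[length(existing) + 1L]] <-
        .new_cluster(thr, length(existing) + 1L, uids[k])
      rep_seqs <- c(rep_seqs, seqs[k])
    }
  }
  existing
}

#' Write clusters to a cluster file
#'
#' One cluster per line, member uids whitespace-separated, representative
#' first. The conventional file name for threshold `t` is
#' `clusters-by-entity-<100 t>.txt`.
#'
#' @param clusters List of `seq_cluster` at a single threshold.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_file <- function(clusters, path) {
  thr <- unique(vapply(clusters, function(cl) cl$threshold, numeric(1)))
  if (length(thr) != 1L) {
    stop("one cluster file holds a single threshold", call. = FALSE)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(vapply(clusters, function(cl) {
    paste(cl$member_uids, collapse = " ")
  }, character(1)), con, sep = "\n")
  invisible(path)
}

#' Read a cluster file
#'
#' @param path Cluster file path (format of [write_cluster_file()]).
#' @param threshold Identity threshold the file was computed at.
#' @return List of `seq_cluster`.
#' @export
read_cluster_file <- function(path, threshold) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    members <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(members) == 0L || any(!nzchar(members))) {
      stop("malformed cluster file line ", i, " in ", path, call. = FALSE)
    }
    cl <- .new_cluster(threshold, i, members[1])
    cl$member_uids <- members
    cl
  })
}

#' Conventional cluster file name for a threshold
#' @param threshold Identity threshold in `(0, 1]`.
#' @return E.g. `"clusters-by-entity-100.txt"` for 1.0.
#' @export
cluster_file_name <- function(threshold) {
  sprintf("clusters-by-entity-%d.txt", as.integer(round(threshold * 100)))
}

#' Check the partition property of a clustering
#' @param clusters List of `seq_cluster`.
#' @param entity_uids Character vector the clusters should partition.
#' @return `TRUE` (invisibly) or an error.
#' @export
validate_partition <- function(clusters, entity_uids) {
  members <- unlist(lapply(clusters, function(cl) cl$member_uids))
  if (anyDuplicated(members)) {
    stop("clusters overlap: ", paste(members[duplicated(members)],
                                     collapse = ", "), call. = FALSE)
  }
  if (!setequal(members, entity_uids)) {
    stop("clusters do not cover the entity set", call. = FALSE)
  }
  reps <- vapply(clusters, function(cl) cl$representative_uid, character(1))
  in_own <- vapply(seq_along(clusters), function(i) {
    reps[i] %in% clusters[[i]]$member_uids
  }, logical(1))
  if (!all(in_own)) stop("a representative is missing from its own cluster",
                         call. = FALSE)
  invisible(TRUE)
}
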