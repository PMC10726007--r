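# End-to-end orchestration: fixtures/inputs -> clustering -> grouping ->
# alignment -> tracks -> superposition -> export, driven by a JSON config.
# Every stage logs its parameters to stderr; outputs are deterministic
# under a fixed seed (no timestamps), so a rerun with the same config is
# byte-identical.

#' Run the full group-analysis pipeline
#'
#' Config (JSON file or equivalent list) fields:
#' \describe{
#'   \item{seed}{integer; seeds the fixture generator.}
#'   \item{fixtures}{arguments for [fixture_spec()] (synthetic corpus), or}
#'   \item{inputs}{`structure_dir`, `fasta`, `entity_sidecar`,
#'     `domain_sidecar` for an on-disk corpus. `structure_dir` may be
#'     omitted, in which case the track and superposition stages are
#'     skipped.}
#'   \item{thresholds}{identity thresholds to cluster at (default the
#'     30/50/70/90/95/100% ladder).}
#'   \item{import_clusters}{optional named list threshold-percent to
#'     cluster-file path; bypasses internal clustering at those
#'     thresholds.}
#'   \item{superpose_columns}{optional `[begin, end]` fit restriction.}
#'   \item{contact_cutoff}{heavy-atom contact cutoff (default 4.5).}
#' }
#'
#' Artifacts under `out_dir`: `clusters/clusters-by-entity-<t>.txt`,
#' `groups/<id>.summary.json`, `alignments/<id>.alignment.json`,
#' `annotations/<id>.annotations.json`, `tracks/<id>.tracks.tsv`,
#' `superposition/<id>.report.tsv` plus transformed mmCIF files, and
#' `provenance.json` (software version, config hash, seed).
#'
#' Any stage failure aborts with a stage-named error and leaves a
#' `FAILED.<stage>` marker in `out_dir`.
#'
#' @param config Path to a JSON config file, or a named list.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the entities, groups and written file
#'   paths.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    config_path <- config
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  } else {
    config_path <- NULL
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  stage <- function(name, code) {
    message("[structgroups] stage ", name)
    tryCatch(code, error = function(e) {
      marker <- file.path(out_dir, paste0("FAILED.", name))
      writeLines(conditionMessage(e), marker)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  # --- inputs -------------------------------------------------------------
  corpus <- stage("inputs", {
    if (!is.null(config$fixtures)) {
      fx_args <- config$fixtures
      fx_args$seed <- fx_args$seed %||% config$seed %||% 1L
      if (!is.null(fx_args$ligand_sites) && is.data.frame(fx_args$ligand_sites)) {
        fx_args$ligand_sites <- lapply(seq_len(nrow(fx_args$ligand_sites)),
                                       function(k) as.list(fx_args$ligand_sites[k, ]))
      }
      spec <- do.call(fixture_spec, fx_args)
      message("  generating fixture corpus (seed ", spec$seed, ", ",
              spec$n_entities, " entities)")
      fx <- make_group_fixture(spec, out_dir = file.path(out_dir, "fixtures"))
      list(entities = fx$entities, structures = fx$structures,
           reference_sequences = setNames(list(fx$ancestor_sequence),
                                          fx$accession))
    } else if (!is.null(config$inputs)) {
      inp <- config$inputs
      seqs <- read_fasta(inp$fasta)
      meta <- if (!is.null(inp$entity_sidecar)) {
        read_entity_sidecar(inp$entity_sidecar, known_uids = names(seqs))
      } else NULL
      doms <- if (!is.null(inp$domain_sidecar)) {
        read_domain_sidecar(inp$domain_sidecar, known_uids = names(seqs))
      } else NULL
      structures <- list()
      entities <- list()
      if (!is.null(inp$structure_dir)) {
        files <- sort(list.files(inp$structure_dir,
                                 pattern = "\\.(cif|pdb|ent)$",
                                 full.names = TRUE))
        for (f in files) {
          m <- read_structure(f)
          structures[[m$entry_id]] <- m
          entities <- c(entities, extract_entities(m, meta, doms))
        }
        # sidecar provenance overrides may retag a model
        for (id in names(structures)) {
          uids <- vapply(structures[[id]]$chains,
                         function(ch) ch$entity_uid, character(1))
          pv <- unique(vapply(entities[uids], function(e) e$provenance,
                              character(1)))
          if (length(pv) == 1L) structures[[id]]$provenance <- pv
        }
      } else {
        for (uid in names(seqs)) {
          row <- if (!is.null(meta)) meta[meta$entity_uid == uid, , drop = FALSE]
          else NULL
          args <- list(entity_uid = uid,
                       entry_id = sub("_[0-9]+$", "", uid),
                       sequence = seqs[[uid]], provenance = "experimental")
          if (!is.null(row) && nrow(row) == 1L) {
            for (f in c("accession", "organism", "release_date",
                        "deposition_group_id", "provenance")) {
              v <- row[[f]]
              if (!is.null(v) && !is.na(v) && nzchar(v)) args[[f]] <- v
            }
          }
          entities[[uid]] <- do.call(polymer_entity, args)
        }
      }
      list(entities = entities, structures = structures,
           reference_sequences = NULL)
    } else {
      stop("config needs either 'fixtures' or 'inputs'")
    }
  })
  entities <- corpus$entities
  structures <- corpus$structures
  have_structures <- length(structures) > 0L

  cfg <- clustering_config(
    thresholds = config$thresholds %||% c(0.30, 0.50, 0.70, 0.90, 0.95, 1.00))

  # --- clustering ---------------------------------------------------------
  clusters_by_threshold <- stage("cluster", {
    dir.create(file.path(out_dir, "clusters"), showWarnings = FALSE)
    out <- list()
    for (thr in cfg$thresholds) {
      pct <- as.character(as.integer(round(thr * 100)))
      imported <- config$import_clusters[[pct]]
      cls <- if (!is.null(imported)) {
        message("  importing clusters at ", pct, "% from ", imported)
        read_cluster_file(imported, thr)
      } else {
        cluster_sequences(entities, thr, cfg)
      }
      validate_partition(cls, vapply(entities, function(e) e$entity_uid,
                                     character(1)))
      path <- file.path(out_dir, "clusters", cluster_file_name(thr))
      write_cluster_file(cls, path)
      written <- c(written, path)
      message("  ", pct, "%: ", length(cls), " cluster(s)")
      out[[pct]] <- cls
    }
    out
  })

  # --- grouping + summaries ----------------------------------------------
  groups <- stage("group", {
    dir.create(file.path(out_dir, "groups"), showWarnings = FALSE)
    gid_pct <- as.character(as.integer(round(
      (config$identity_threshold %||% 1.0) * 100)))
    out <- c(build_groups(entities, method = "deposition"),
             build_groups(entities, method = "reference_accession",
                          reference_sequences = corpus$reference_sequences),
             build_groups(entities,
                          clusters = clusters_by_threshold[[gid_pct]],
                          method = "sequence_identity"))
    for (g in out) {
      summaries <- lapply(.SUMMARY_ATTRIBUTES, function(a) {
        s <- summarize_group(g, entities, a)
        list(attribute = a,
             bins = lapply(seq_len(nrow(s$bins)), function(k) {
               list(label = s$bins$label[k],
                    matching_count = s$bins$matching_count[k],
                    nonmatching_count = s$bins$nonmatching_count[k])
             }))
      })
      doc <- list(group_id = g$group_id,
                  group_provenance = group_provenance_record(g$provenance),
                  title = g$title,
                  n_members = length(g$member_uids),
                  members = as.list(g$member_uids),
                  summaries = summaries)
      path <- file.path(out_dir, "groups", paste0(g$group_id, ".summary.json"))
      .write_json(doc, path)
    }
    message("  ", length(out), " group(s)")
    out
  })

  seq_groups <- Filter(function(g) g$provenance == "reference_accession",
                       groups)

  # --- alignment + export -------------------------------------------------
  alignments <- stage("align", {
    dir.create(file.path(out_dir, "alignments"), showWarnings = FALSE)
    out <- list()
    for (g in seq_groups) {
      ga <- build_group_alignment(g, entities, cfg)
      export_group_alignment(g, ga, entities, include_summary = TRUE,
                             path = file.path(out_dir, "alignments",
                                              paste0(g$group_id,
                                                     ".alignment.json")))
      out[[g$group_id]] <- ga
    }
    out
  })

  # --- tracks -------------------------------------------------------------
  stage("tracks", if (!have_structures) {
    message("  skipped: no coordinates")
    writeLines("skipped: no coordinates",
               file.path(out_dir, "tracks.skipped"))
  } else {
    dir.create(file.path(out_dir, "annotations"), showWarnings = FALSE)
    dir.create(file.path(out_dir, "tracks"), showWarnings = FALSE)
    cutoff <- config$contact_cutoff %||% 4.5
    for (g in seq_groups) {
      ga <- alignments[[g$group_id]]
      contacts <- do.call(rbind, lapply(names(ga$members), function(uid) {
        st <- structures[[entities[[uid]]$entry_id]]
        if (is.null(st)) NULL else detect_contacts(st, cutoff)
      }))
      track_list <- list(consensus_track(ga, entities),
                         variation_track(ga, entities),
                         feature_frequency_track(g, ga, entities, structures,
                                                 "helix"),
                         feature_frequency_track(g, ga, entities, structures,
                                                 "strand"))
      if (!is.null(contacts) && nrow(contacts) > 0L) {
        bt <- binding_tracks(g, ga, contacts, entities)
        track_list <- c(track_list, list(bt$global), bt$per_ligand)
      }
      export_group_annotations(g, tracks = track_list, histogram_flag = TRUE,
                               path = file.path(out_dir, "annotations",
                                                paste0(g$group_id,
                                                       ".annotations.json")))
      write_tracks_tsv(track_list,
                       file.path(out_dir, "tracks",
                                 paste0(g$group_id, ".tracks.tsv")))
    }
  })

  # --- superposition ------------------------------------------------------
  stage("superpose", if (!have_structures) {
    message("  skipped: no coordinates")
    writeLines("skipped: no coordinates",
               file.path(out_dir, "superpose.skipped"))
  } else {
    dir.create(file.path(out_dir, "superposition"), showWarnings = FALSE)
    colr <- config$superpose_columns
    if (!is.null(colr)) colr <- as.integer(colr)
    for (g in seq_groups) {
      ga <- alignments[[g$group_id]]
      sp <- superpose_members(g, ga, structures, entities,
                              column_range = colr)
      if (length(sp) == 0L) next
      write_superposition_report(
        sp, file.path(out_dir, "superposition",
                      paste0(g$group_id, ".report.tsv")))
      for (uid in names(sp)) {
        write_structure(sp[[uid]]$structure,
                        file.path(out_dir, "superposition",
                                  paste0(g$group_id, ".",
                                         gsub("[^A-Za-z0-9_]", "_", uid),
                                         ".cif")))
      }
    }
  })

  # --- provenance ---------------------------------------------------------
  stage("export", {
    config_hash <- if (!is.null(config_path)) {
      unname(tools::md5sum(config_path))
    } else {
      tmp <- tempfile(fileext = ".json")
      .write_json(config, tmp)
      h <- unname(tools::md5sum(tmp))
      unlink(tmp)
      h
    }
    .write_json(list(software_name = "structgroups",
                     version = as.character(
                       utils::packageVersion("structgroups")),
                     seed = config$seed %||% NA,
                     config_hash = config_hash),
                file.path(out_dir, "provenance.json"))
  })

  invisible(list(entities = entities, structures = structures,
                 groups = groups, alignments = alignments,
                 out_dir = out_dir))
}
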