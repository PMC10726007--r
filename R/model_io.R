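# Structure and sequence I/O, and projection of structure files onto the
# entry / entity / instance hierarchy used throughout the package.
#
# Conventions (used by every downstream module):
#   * sequence positions are 1-based and inclusive (mmCIF label_seq_id);
#   * provenance ("experimental" | "computed") is declared metadata, never
#     inferred from B-factor ranges;
#   * water ("HOH") and the standard amino acids are never ligands; every
#     other non-polymer component is.

.PROVENANCE <- c("experimental", "computed")
.DOMAIN_SOURCES <- c("SCOP", "CATH", "PFAM", "ECOD")

#' Construct a polymer entity record
#'
#' A polymer entity is one distinct polymer sequence with its provenance and
#' optional metadata; it is the unit of clustering and of reference-accession
#' and sequence-identity grouping.
#'
#' @param entity_uid Globally unique identifier. By convention
#'   `"<entry_id>_<entity_id>"` for experimental entities and the model
#'   identifier itself for computed structure models.
#' @param entry_id Identifier of the entry the entity belongs to.
#' @param sequence One-letter amino-acid string over the 20 standard codes
#'   plus `"X"` (used for modified or unknown residues).
#' @param provenance `"experimental"` or `"computed"`.
#' @param accession,description,organism,release_date,deposition_group_id
#'   Optional metadata; `release_date` is an ISO `"YYYY-MM-DD"` string.
#' @param domain_annotations `data.frame` with columns `source` (one of
#'   SCOP, CATH, PFAM, ECOD), `domain_id`, `begin`, `end` (1-based,
#'   inclusive sequence positions).
#' @return An object of class `polymer_entity`.
#' @export
polymer_entity <- function(entity_uid, entry_id, sequence,
                           provenance = c("experimental", "computed"),
                           accession = NULL, description = NULL,
                           organism = NULL, release_date = NULL,
                           deposition_group_id = NULL,
                           domain_annotations = NULL) {
  provenance <- match.arg(provenance)
  assert_sequence(sequence)
  if (is.null(domain_annotations)) {
    domain_annotations <- data.frame(source = character(), domain_id = character(),
                                     begin = integer(), end = integer(),
                                     stringsAsFactors = FALSE)
  }
  stopifnot(all(c("source", "domain_id", "begin", "end") %in%
                  names(domain_annotations)))
  if (nrow(domain_annotations) > 0L) {
    if (!all(domain_annotations$source %in% .DOMAIN_SOURCES)) {
      stop("domain sources must be one of ",
           paste(.DOMAIN_SOURCES, collapse = ", "), call. = FALSE)
    }
    ok <- domain_annotations$begin >= 1L &
      domain_annotations$begin <= domain_annotations$end &
      domain_annotations$end <= nchar(sequence)
    if (!all(ok)) stop("domain annotation ranges must satisfy 1 <= begin <= end <= sequence length",
                       call. = FALSE)
  }
  structure(list(entity_uid = entity_uid, entry_id = entry_id,
                 sequence = sequence, provenance = provenance,
                 accession = accession, description = description,
                 organism = organism, release_date = release_date,
                 deposition_group_id = deposition_group_id,
                 domain_annotations = domain_annotations),
            class = "polymer_entity")
}

#' @export
print.polymer_entity <- function(x, ...) {
  cat("<polymer_entity> ", x$entity_uid, " (", x$provenance, ", ",
      nchar(x$sequence), " aa)\n", sep = "")
  invisible(x)
}

#' Construct a structure model
#'
#' Parsed 3D coordinates of one entry: polymer chains (instances), ligands,
#' and provenance. Each chain is built with [polymer_instance()].
#'
#' @param entry_id Entry identifier.
#' @param chains List of `polymer_instance` objects (at least one).
#' @param ligands `data.frame` with columns `comp_id`, `chain_id`,
#'   `atom_name`, `element`, `x`, `y`, `z` (Angstrom). Water and standard
#'   amino-acid components are rejected.
#' @param provenance `"experimental"` or `"computed"`.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(entry_id, chains, ligands = NULL,
                            provenance = c("experimental", "computed")) {
  provenance <- match.arg(provenance)
  if (length(chains) < 1L) stop("a structure model needs at least one chain", call. = FALSE)
  stopifnot(all(vapply(chains, inherits, logical(1), "polymer_instance")))
  if (is.null(ligands)) {
    ligands <- data.frame(comp_id = character(), chain_id = character(),
                          atom_name = character(), element = character(),
                          x = numeric(), y = numeric(), z = numeric(),
                          stringsAsFactors = FALSE)
  }
  bad <- ligands$comp_id %in% c("HOH", names(.AA_3TO1))
  if (any(bad)) stop("water and standard amino acids cannot be ligands: ",
                     paste(unique(ligands$comp_id[bad]), collapse = ", "),
                     call. = FALSE)
  structure(list(entry_id = entry_id, provenance = provenance,
                 chains = chains, ligands = ligands),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("<structure_model> ", x$entry_id, " (", x$provenance, "): ",
      length(x$chains), " chain(s), ",
      length(unique(x$ligands$comp_id)), " ligand component(s)\n", sep = "")
  invisible(x)
}

#' Construct a polymer instance (one chain)
#'
#' @param chain_id Chain identifier within the entry.
#' @param entity_uid Identifier of the entity this chain realizes.
#' @param residues `data.frame` with columns `seq_pos` (1-based, strictly
#'   increasing), `aa` (one-letter code), `modeled` (logical), `confidence`
#'   (pLDDT in `[0,100]` or `NA`; present only for computed models).
#' @param atoms `data.frame` with columns `seq_pos`, `atom_name`, `element`,
#'   `x`, `y`, `z`. Residues flagged `modeled = FALSE` must have no atoms.
#' @return An object of class `polymer_instance`.
#' @export
polymer_instance <- function(chain_id, entity_uid, residues, atoms = NULL) {
  stopifnot(all(c("seq_pos", "aa", "modeled") %in% names(residues)))
  if (is.null(residues$confidence)) residues$confidence <- NA_real_
  if (is.unsorted(residues$seq_pos, strictly = TRUE)) {
    stop("residue sequence positions must be strictly increasing", call. = FALSE)
  }
  if (is.null(atoms)) {
    atoms <- data.frame(seq_pos = integer(), atom_name = character(),
                        element = character(), x = numeric(), y = numeric(),
                        z = numeric(), stringsAsFactors = FALSE)
  }
  unmodeled <- residues$seq_pos[!residues$modeled]
  if (any(atoms$seq_pos %in% unmodeled)) {
    stop("unmodeled residues cannot carry atoms", call. = FALSE)
  }
  modeled_without_atoms <- setdiff(residues$seq_pos[residues$modeled], atoms$seq_pos)
  if (length(modeled_without_atoms) > 0L) {
    stop("modeled residues without atoms: ",
         paste(head(modeled_without_atoms), collapse = ", "), call. = FALSE)
  }
  conf <- residues$confidence
  if (any(!is.na(conf) & (conf < 0 | conf > 100))) {
    stop("confidence (pLDDT) values must lie in [0, 100]", call. = FALSE)
  }
  structure(list(chain_id = chain_id, entity_uid = entity_uid,
                 residues = residues, atoms = atoms),
            class = "polymer_instance")
}

#' Sequence of a polymer instance
#' @param instance A `polymer_instance`.
#' @return One-letter string over all residues (modeled or not).
#' @export
instance_sequence <- function(instance) {
  paste(instance$residues$aa, collapse = "")
}

# ---------------------------------------------------------------------------
# residue-name tables

.AA_3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
              GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
              LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
              SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
.AA_1TO3 <- setNames(names(.AA_3TO1), unname(.AA_3TO1))

#' @noRd
aa3_to_1 <- function(resname) {
  out <- unname(.AA_3TO1[resname])
  unknown <- is.na(out)
  if (any(unknown)) {
    warning("unknown residue name(s) mapped to 'X': ",
            paste(unique(resname[unknown]), collapse = ", "), call. = FALSE)
    out[unknown] <- "X"
  }
  out
}

#' @noRd
aa1_to_3 <- function(aa) {
  out <- unname(.AA_1TO3[aa])
  out[is.na(out)] <- "UNK"
  out
}

# ---------------------------------------------------------------------------
# mmCIF (PDBx subset)

# Tokenize one CIF line, honouring single and double quotes.
.cif_tokens <- function(line) {
  out <- character()
  i <- 1L
  n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (grepl("^[ \t]$", ch)) { i <- i + 1L; next }
    if (ch == "'" || ch == '"') {
      j <- i + 1L
      while (j <= n && substr(line, j, j) != ch) j <- j + 1L
      out <- c(out, substr(line, i + 1L, j - 1L))
      i <- j + 1L
    } else {
      j <- i
      while (j <= n && !grepl("^[ \t]$", substr(line, j, j))) j <- j + 1L
      out <- c(out, substr(line, i, j - 1L))
      i <- j
    }
  }
  out
}

# Parse a PDBx/mmCIF file into named items and loop tables.
# Supports: data_ block, simple `_cat.item value` pairs (including multi-line
# `;`-delimited values), and loop_ tables with quoted tokens.
.parse_mmcif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  items <- list()
  loops <- list()
  i <- 1L
  n <- length(lines)
  read_value_block <- function(start) {
    # multi-line ;...; value beginning at `start`
    j <- start + 1L
    val <- character()
    while (j <= n && !startsWith(lines[j], ";")) {
      val <- c(val, lines[j]); j <- j + 1L
    }
    if (j > n) stop("unterminated ';' value block at line ", start,
                    " of ", path, call. = FALSE)
    list(value = paste(val, collapse = ""), next_line = j + 1L)
  }
  while (i <= n) {
    line <- sub("#.*$", "", lines[i])
    trimmed <- trimws(line)
    if (trimmed == "" || startsWith(trimmed, "data_")) { i <- i + 1L; next }
    if (trimmed == "loop_") {
      i <- i + 1L
      fields <- character()
      while (i <= n && startsWith(trimws(lines[i]), "_")) {
        fields <- c(fields, trimws(lines[i])); i <- i + 1L
      }
      rows <- list()
      buf <- character()
      while (i <= n) {
        t2 <- trimws(sub("#.*$", "", lines[i]))
        if (t2 == "" || t2 == "loop_" || startsWith(t2, "_") ||
            startsWith(t2, "data_")) break
        if (startsWith(lines[i], ";")) {
          vb <- read_value_block(i)
          buf <- c(buf, vb$value)
          i <- vb$next_line
        } else {
          buf <- c(buf, .cif_tokens(t2))
          i <- i + 1L
        }
        while (length(buf) >= length(fields)) {
          rows[[length(rows) + 1L]] <- buf[seq_along(fields)]
          buf <- buf[-seq_along(fields)]
        }
      }
      if (length(buf) > 0L) {
        stop("malformed loop_ (", length(buf), " dangling token(s)) near line ",
             i, " of ", path, call. = FALSE)
      }
      cat_name <- sub("\\..*$", "", fields[1])
      tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
      names(tab) <- sub("^_[^.]+\\.", "", fields)
      loops[[cat_name]] <- tab
    } else if (startsWith(trimmed, "_")) {
      toks <- .cif_tokens(trimmed)
      key <- toks[1]
      if (length(toks) >= 2L) {
        items[[key]] <- toks[2]
        i <- i + 1L
      } else if (i + 1L <= n && startsWith(lines[i + 1L], ";")) {
        vb <- read_value_block(i + 1L)
        items[[key]] <- vb$value
        i <- vb$next_line
      } else {
        items[[key]] <- trimws(lines[i + 1L])
        i <- i + 2L
      }
    } else {
      stop("unparseable mmCIF content at line ", i, " of ", path, ": ",
           trimmed, call. = FALSE)
    }
  }
  list(items = items, loops = loops)
}

#' Read a structure file
#'
#' Parses a PDBx/mmCIF or legacy PDB file into a [structure_model()]. The
#' full polymer sequence is taken from the entity description in the file
#' (`_entity_poly` / SEQRES) when present; residues present in the sequence
#' but absent from the coordinates appear with `modeled = FALSE`. For
#' computed models the isotropic B-factor column is copied into the
#' per-residue `confidence` (pLDDT).
#'
#' Legacy PDB chains with insertion codes are renumbered sequentially after
#' parsing (a mapping message is emitted) so that downstream tracks see a
#' single integer coordinate system.
#'
#' @param path File path.
#' @param format `"mmcif"`, `"pdb"`, or `"auto"` (by file extension).
#' @param provenance `"experimental"` or `"computed"`; for mmCIF the
#'   `_struct.pdbx_structure_determination_methodology` item, when present,
#'   takes precedence. Provenance is declared, never inferred from B-factors.
#' @return A `structure_model`.
#' @export
read_structure <- function(path, format = c("auto", "mmcif", "pdb"),
                           provenance = c("experimental", "computed")) {
  format <- match.arg(format)
  provenance <- match.arg(provenance)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif"
    else if (ext %in% c("pdb", "ent")) "pdb"
    else stop("cannot infer format from extension '", ext, "'; pass `format`",
              call. = FALSE)
  }
  if (format == "mmcif") .read_mmcif_structure(path, provenance)
  else .read_pdb_structure(path, provenance)
}

.read_mmcif_structure <- function(path, provenance) {
  parsed <- .parse_mmcif(path)
  entry_id <- parsed$items[["_entry.id"]] %||% sub("\\.[^.]*$", "", basename(path))
  meth <- parsed$items[["_struct.pdbx_structure_determination_methodology"]]
  if (!is.null(meth)) {
    provenance <- if (identical(meth, "computational")) "computed" else "experimental"
  }
  atoms <- parsed$loops[["_atom_site"]]
  if (is.null(atoms)) stop("no _atom_site loop in ", path, call. = FALSE)
  num <- function(x) as.numeric(x)
  atoms$Cartn_x <- num(atoms$Cartn_x)
  atoms$Cartn_y <- num(atoms$Cartn_y)
  atoms$Cartn_z <- num(atoms$Cartn_z)
  atoms$B_iso_or_equiv <- if ("B_iso_or_equiv" %in% names(atoms))
    num(atoms$B_iso_or_equiv) else NA_real_

  # entity sequences from _entity_poly (one-letter) when present
  seqs <- list()
  ep <- parsed$loops[["_entity_poly"]]
  if (is.null(ep) && !is.null(parsed$items[["_entity_poly.entity_id"]])) {
    ep <- data.frame(entity_id = parsed$items[["_entity_poly.entity_id"]],
                     pdbx_seq_one_letter_code =
                       parsed$items[["_entity_poly.pdbx_seq_one_letter_code"]],
                     stringsAsFactors = FALSE)
  }
  if (!is.null(ep)) {
    for (k in seq_len(nrow(ep))) {
      seqs[[ep$entity_id[k]]] <- gsub("[^A-Za-z]", "", ep$pdbx_seq_one_letter_code[k])
    }
  }

  is_poly <- atoms$group_PDB == "ATOM"
  poly <- atoms[is_poly, , drop = FALSE]
  het <- atoms[!is_poly, , drop = FALSE]
  het <- het[het$label_comp_id != "HOH", , drop = FALSE]

  chains <- list()
  for (ch in unique(poly$label_asym_id)) {
    ca <- poly[poly$label_asym_id == ch, , drop = FALSE]
    entity_id <- unique(ca$label_entity_id)[1]
    seq_pos <- as.integer(ca$label_seq_id)
    full_seq <- seqs[[entity_id]]
    obs <- !duplicated(seq_pos)
    obs_pos <- seq_pos[obs]
    obs_aa <- aa3_to_1(ca$label_comp_id[obs])
    if (is.null(full_seq)) {
      L <- max(obs_pos)
      aa_full <- rep("X", L)
      aa_full[obs_pos] <- obs_aa
    } else {
      L <- nchar(full_seq)
      aa_full <- strsplit(full_seq, "")[[1]]
    }
    modeled <- seq_len(L) %in% obs_pos
    confidence <- rep(NA_real_, L)
    if (provenance == "computed") {
      b_per_res <- tapply(ca$B_iso_or_equiv, seq_pos, function(v) v[1])
      confidence[as.integer(names(b_per_res))] <- unname(b_per_res)
    }
    residues <- data.frame(seq_pos = seq_len(L), aa = aa_full,
                           modeled = modeled, confidence = confidence,
                           stringsAsFactors = FALSE)
    atoms_df <- data.frame(seq_pos = seq_pos, atom_name = ca$label_atom_id,
                           element = ca$type_symbol,
                           x = ca$Cartn_x, y = ca$Cartn_y, z = ca$Cartn_z,
                           stringsAsFactors = FALSE)
    uid <- if (provenance == "computed") entry_id
    else paste0(entry_id, "_", entity_id)
    chains[[length(chains) + 1L]] <-
      polymer_instance(ch, uid, residues, atoms_df)
  }

  ligands <- if (nrow(het) > 0L) {
    data.frame(comp_id = het$label_comp_id, chain_id = het$label_asym_id,
               atom_name = het$label_atom_id, element = het$type_symbol,
               x = het$Cartn_x, y = het$Cartn_y, z = het$Cartn_z,
               stringsAsFactors = FALSE)
  } else NULL
  structure_model(entry_id, chains, ligands, provenance)
}

.read_pdb_structure <- function(path, provenance) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  entry_id <- toupper(sub("\\.[^.]*$", "", basename(path)))
  at <- pdb$atom
  poly <- at[at$type == "ATOM", , drop = FALSE]
  het <- at[at$type == "HETATM" & at$resid != "HOH", , drop = FALSE]

  seqres <- pdb$seqres  # named by chain, 3-letter codes

  chains <- list()
  chain_seqs <- character()
  for (ch in unique(poly$chain)) {
    ca <- poly[poly$chain == ch, , drop = FALSE]
    # renumber insertion-coded residues sequentially
    key <- paste(ca$resno, ifelse(is.na(ca$insert), "", ca$insert))
    ukey <- unique(key)
    new_pos <- match(key, ukey)
    if (any(!is.na(ca$insert) & ca$insert != "")) {
      message("chain ", ch, ": insertion-coded residues renumbered 1..",
              length(ukey))
    }
    first <- !duplicated(new_pos)
    obs_pos <- new_pos[first]
    obs_aa <- aa3_to_1(ca$resid[first])
    if (!is.null(seqres) && ch %in% names(seqres)) {
      full_aa <- aa3_to_1(unname(seqres[names(seqres) == ch]))
      L <- length(full_aa)
      # map observed residues onto SEQRES positions by original numbering
      # when consistent, else sequentially
      if (max(obs_pos) <= L) {
        resno1 <- ca$resno[first]
        if (min(resno1) >= 1 && max(resno1) <= L &&
            !anyDuplicated(resno1) && all(diff(resno1) > 0)) {
          obs_pos <- resno1
          new_pos <- ca$resno
        }
      }
      modeled <- seq_len(L) %in% obs_pos
      aa_full <- full_aa
    } else {
      L <- max(obs_pos)
      aa_full <- rep("X", L)
      aa_full[obs_pos] <- obs_aa
      modeled <- seq_len(L) %in% obs_pos
    }
    confidence <- rep(NA_real_, L)
    if (provenance == "computed") {
      b_first <- ca$b[first]
      confidence[obs_pos] <- b_first
    }
    residues <- data.frame(seq_pos = seq_len(L), aa = aa_full,
                           modeled = modeled, confidence = confidence,
                           stringsAsFactors = FALSE)
    atoms_df <- data.frame(seq_pos = as.integer(new_pos),
                           atom_name = ca$elety,
                           element = ifelse(is.na(ca$elesy) | ca$elesy == "",
                                            substr(ca$elety, 1, 1), ca$elesy),
                           x = ca$x, y = ca$y, z = ca$z,
                           stringsAsFactors = FALSE)
    chain_seqs[ch] <- paste(aa_full, collapse = "")
    chains[[length(chains) + 1L]] <- list(chain_id = ch, residues = residues,
                                          atoms = atoms_df)
  }
  # entity assignment: chains with identical sequences share an entity
  useq <- unique(unname(chain_seqs))
  instances <- lapply(chains, function(chn) {
    ent_id <- match(chain_seqs[[chn$chain_id]], useq)
    uid <- if (provenance == "computed") entry_id else paste0(entry_id, "_", ent_id)
    polymer_instance(chn$chain_id, uid, chn$residues, chn$atoms)
  })
  ligands <- if (nrow(het) > 0L) {
    data.frame(comp_id = het$resid, chain_id = het$chain,
               atom_name = het$elety,
               element = ifelse(is.na(het$elesy) | het$elesy == "",
                                substr(het$elety, 1, 1), het$elesy),
               x = het$x, y = het$y, z = het$z, stringsAsFactors = FALSE)
  } else NULL
  structure_model(entry_id, instances, ligands, provenance)
}

#' Write a structure as PDBx/mmCIF
#'
#' Emits `_entry`, `_struct.pdbx_structure_determination_methodology`,
#' `_entity_poly` (one-letter sequences) and an `_atom_site` loop. Computed
#' models carry per-residue confidence in `B_iso_or_equiv`.
#'
#' @param model A `structure_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  con <- file(path, "wb")  # "wb": identical bytes on every platform
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con, sep = "\n")
  w("data_", model$entry_id)
  w("_entry.id ", model$entry_id)
  w("_struct.pdbx_structure_determination_methodology ",
    if (model$provenance == "computed") "computational" else "experimental")
  ents <- unique(vapply(model$chains, function(ch) ch$entity_uid, character(1)))
  ent_ids <- vapply(model$chains, function(ch) {
    as.character(match(ch$entity_uid, ents))
  }, character(1))
  w("loop_")
  w("_entity_poly.entity_id")
  w("_entity_poly.pdbx_seq_one_letter_code")
  for (k in seq_along(ents)) {
    ch <- model$chains[[match(ents[k], vapply(model$chains,
                                              function(c) c$entity_uid,
                                              character(1)))]]
    w(k, " ", instance_sequence(ch))
  }
  w("loop_")
  for (f in c("group_PDB", "id", "type_symbol", "label_atom_id",
              "label_comp_id", "label_asym_id", "label_entity_id",
              "label_seq_id", "Cartn_x", "Cartn_y", "Cartn_z",
              "occupancy", "B_iso_or_equiv")) {
    w("_atom_site.", f)
  }
  fmt <- function(v) formatC(v, format = "f", digits = 3)
  id <- 0L
  for (ci in seq_along(model$chains)) {
    ch <- model$chains[[ci]]
    res <- ch$residues
    conf <- setNames(res$confidence, res$seq_pos)
    aa <- setNames(res$aa, res$seq_pos)
    a <- ch$atoms
    for (k in seq_len(nrow(a))) {
      id <- id + 1L
      p <- as.character(a$seq_pos[k])
      b <- conf[[p]]
      w("ATOM ", id, " ", a$element[k], " ", a$atom_name[k], " ",
        aa1_to_3(aa[[p]]), " ", ch$chain_id, " ", ent_ids[ci], " ", p, " ",
        fmt(a$x[k]), " ", fmt(a$y[k]), " ", fmt(a$z[k]), " 1.00 ",
        if (is.na(b)) "0.00" else fmt(b))
    }
  }
  lg <- model$ligands
  for (k in seq_len(nrow(lg))) {
    id <- id + 1L
    w("HETATM ", id, " ", lg$element[k], " ", lg$atom_name[k], " ",
      lg$comp_id[k], " ", lg$chain_id[k], " . . ",
      fmt(lg$x[k]), " ", fmt(lg$y[k]), " ", fmt(lg$z[k]), " 1.00 0.00")
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# entities

#' Derive polymer entities from a structure
#'
#' One entity is produced per distinct (sequence, entity identifier) pair;
#' chains sharing an entity map to the same `entity_uid`. Optional sidecar
#' metadata (see [read_entity_sidecar()]) is merged by `entity_uid`; sidecar
#' rows naming unknown entities are dropped with a warning.
#'
#' @param structure A `structure_model`.
#' @param metadata Optional sidecar `data.frame` (columns `entity_uid`,
#'   `accession`, `organism`, `release_date`, `deposition_group_id`,
#'   `provenance`).
#' @param domains Optional domain sidecar `data.frame` (columns `entity_uid`,
#'   `source`, `domain_id`, `begin`, `end`).
#' @return List of `polymer_entity`, named by `entity_uid`.
#' @export
extract_entities <- function(structure, metadata = NULL, domains = NULL) {
  uids <- vapply(structure$chains, function(ch) ch$entity_uid, character(1))
  out <- list()
  for (uid in unique(uids)) {
    ch <- structure$chains[[match(uid, uids)]]
    args <- list(entity_uid = uid, entry_id = structure$entry_id,
                 sequence = instance_sequence(ch),
                 provenance = structure$provenance)
    if (!is.null(metadata)) {
      row <- metadata[metadata$entity_uid == uid, , drop = FALSE]
      if (nrow(row) >= 1L) {
        row <- row[1L, ]
        blank_to_null <- function(v) {
          if (is.null(v) || is.na(v) || !nzchar(as.character(v))) NULL
          else as.character(v)
        }
        args$accession <- blank_to_null(row$accession)
        args$organism <- blank_to_null(row$organism)
        args$release_date <- blank_to_null(row$release_date)
        args$deposition_group_id <- blank_to_null(row$deposition_group_id)
        pv <- blank_to_null(row$provenance)
        if (!is.null(pv)) args$provenance <- pv
      }
    }
    if (!is.null(domains)) {
      dd <- domains[domains$entity_uid == uid, c("source", "domain_id",
                                                 "begin", "end"), drop = FALSE]
      if (nrow(dd) > 0L) {
        dd$begin <- as.integer(dd$begin); dd$end <- as.integer(dd$end)
        rownames(dd) <- NULL
        args$domain_annotations <- dd
      }
    }
    out[[uid]] <- do.call(polymer_entity, args)
  }
  out
}

#' Read the entity metadata sidecar (TSV)
#'
#' Tab-separated with header; columns `entity_uid`, `accession`, `organism`,
#' `release_date`, `deposition_group_id`, `provenance`. Rows naming entities
#' absent from `known_uids` (when supplied) are dropped with a warning.
#'
#' @param path TSV path.
#' @param known_uids Optional character vector of valid entity uids.
#' @return A `data.frame`.
#' @export
read_entity_sidecar <- function(path, known_uids = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!"entity_uid" %in% names(tab)) {
    stop("sidecar must have an entity_uid column", call. = FALSE)
  }
  if (!is.null(known_uids)) {
    bad <- !(tab$entity_uid %in% known_uids)
    if (any(bad)) {
      warning("ignoring sidecar rows with unknown entity_uid: ",
              paste(tab$entity_uid[bad], collapse = ", "), call. = FALSE)
      tab <- tab[!bad, , drop = FALSE]
    }
  }
  tab
}

#' Read the domain annotation sidecar (TSV)
#'
#' Tab-separated with header; columns `entity_uid`, `source`, `domain_id`,
#' `begin`, `end`.
#'
#' @inheritParams read_entity_sidecar
#' @return A `data.frame`.
#' @export
read_domain_sidecar <- function(path, known_uids = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("entity_uid", "source", "domain_id", "begin", "end")
  if (!all(need %in% names(tab))) {
    stop("domain sidecar needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(known_uids)) {
    bad <- !(tab$entity_uid %in% known_uids)
    if (any(bad)) {
      warning("ignoring domain rows with unknown entity_uid: ",
              paste(unique(tab$entity_uid[bad]), collapse = ", "),
              call. = FALSE)
      tab <- tab[!bad, , drop = FALSE]
    }
  }
  tab
}

# ---------------------------------------------------------------------------
# FASTA

#' Write entities as FASTA
#'
#' One record per entity, header = `entity_uid`.
#'
#' @param entities List of `polymer_entity`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(entities, path) {
  if (length(entities) == 0L) stop("no entities to write", call. = FALSE)
  seqs <- Biostrings::AAStringSet(vapply(entities, function(e) e$sequence,
                                         character(1)))
  names(seqs) <- vapply(entities, function(e) e$entity_uid, character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a FASTA file of entity sequences
#'
#' @param path FASTA path.
#' @return Named character vector (names = record ids, values = sequences).
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
}
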