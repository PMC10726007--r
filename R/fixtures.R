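# Synthetic structure/sequence/metadata generator. Everything downstream is
# tested against corpora built here: ideal secondary-structure backbones,
# hinge motions, geometric ligand placements, unmodeled gaps, pLDDT
# profiles, and mutated sequence variants -- all deterministic under a seed.

# Ideal backbone geometry (lengths in Angstrom, angles in degrees).
.BOND_N_CA <- 1.458
.BOND_CA_C <- 1.525
.BOND_C_N <- 1.329
.BOND_C_O <- 1.231
.ANGLE_N_CA_C <- 111.2
.ANGLE_CA_C_N <- 116.2
.ANGLE_C_N_CA <- 121.7
.ANGLE_CA_C_O <- 120.8
.OMEGA_TRANS <- 180

.IDEAL_TORSIONS <- list(helix = c(phi = -57, psi = -47),
                        strand = c(phi = -139, psi = 135))

#' @noRd
.normalize_layout <- function(ss_layout) {
  if (is.data.frame(ss_layout)) {
    stopifnot(all(c("element", "length") %in% names(ss_layout)))
    lay <- ss_layout
  } else {
    lay <- do.call(rbind, lapply(ss_layout, function(el) {
      data.frame(element = as.character(el[[1]]),
                 length = as.integer(el[[2]]), stringsAsFactors = FALSE)
    }))
  }
  if (is.null(lay) || nrow(lay) == 0L || sum(lay$length) == 0L) {
    stop("secondary-structure layout is empty", call. = FALSE)
  }
  stopifnot(all(lay$element %in% c("helix", "strand", "coil")))
  lay
}

#' Run code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
.with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Build a backbone with ideal secondary-structure geometry
#'
#' Constructs N, CA, C, O backbone atoms from ideal torsion angles
#' (helix phi = -57, psi = -47; strand phi = -139, psi = +135; coil torsions
#' drawn uniformly from (-180, 180] under the seed) with standard bond
#' lengths and angles, using the natural-extension-of-reference-frame
#' construction.
#'
#' @param ss_layout Secondary-structure layout: a `data.frame` with columns
#'   `element` (`"helix"`, `"strand"`, `"coil"`) and `length`, or a list of
#'   `(element, length)` pairs. Lengths must sum to `nchar(sequence)`.
#' @param sequence One-letter amino-acid sequence.
#' @param seed Seed for coil torsions.
#' @param entry_id,chain_id,provenance Passed through to the model.
#' @return A fully modeled single-chain [structure_model()].
#' @export
build_ideal_chain <- function(ss_layout, sequence, seed = 1L,
                              entry_id = "CHAIN", chain_id = "A",
                              provenance = "experimental") {
  assert_sequence(sequence)
  lay <- .normalize_layout(ss_layout)
  L <- nchar(sequence)
  if (sum(lay$length) != L) {
    stop("layout lengths sum to ", sum(lay$length),
         " but the sequence has ", L, " residues", call. = FALSE)
  }
  element_per_res <- rep(lay$element, lay$length)
  torsions <- .with_seed(seed, {
    t(vapply(element_per_res, function(el) {
      if (el == "coil") c(phi = runif(1, -180, 180), psi = runif(1, -180, 180))
      else .IDEAL_TORSIONS[[el]]
    }, c(phi = 0, psi = 0)))
  })

  n_xyz <- ca_xyz <- c_xyz <- o_xyz <- matrix(NA_real_, L, 3)
  n_xyz[1, ] <- c(0, 0, 0)
  ca_xyz[1, ] <- c(.BOND_N_CA, 0, 0)
  a1 <- (180 - .ANGLE_N_CA_C) * pi / 180
  c_xyz[1, ] <- ca_xyz[1, ] + .BOND_CA_C * c(cos(a1), sin(a1), 0)
  for (i in seq_len(L)) {
    if (i > 1L) {
      n_xyz[i, ] <- .place_atom(n_xyz[i - 1, ], ca_xyz[i - 1, ], c_xyz[i - 1, ],
                                .BOND_C_N, .ANGLE_CA_C_N, torsions[i - 1, "psi"])
      ca_xyz[i, ] <- .place_atom(ca_xyz[i - 1, ], c_xyz[i - 1, ], n_xyz[i, ],
                                 .BOND_N_CA, .ANGLE_C_N_CA, .OMEGA_TRANS)
      c_xyz[i, ] <- .place_atom(c_xyz[i - 1, ], n_xyz[i, ], ca_xyz[i, ],
                                .BOND_CA_C, .ANGLE_N_CA_C, torsions[i, "phi"])
    }
    o_xyz[i, ] <- .place_atom(n_xyz[i, ], ca_xyz[i, ], c_xyz[i, ],
                              .BOND_C_O, .ANGLE_CA_C_O, torsions[i, "psi"] + 180)
  }

  atoms <- data.frame(
    seq_pos = rep(seq_len(L), each = 4L),
    atom_name = rep(c("N", "CA", "C", "O"), L),
    element = rep(c("N", "C", "C", "O"), L),
    x = as.vector(rbind(n_xyz[, 1], ca_xyz[, 1], c_xyz[, 1], o_xyz[, 1])),
    y = as.vector(rbind(n_xyz[, 2], ca_xyz[, 2], c_xyz[, 2], o_xyz[, 2])),
    z = as.vector(rbind(n_xyz[, 3], ca_xyz[, 3], c_xyz[, 3], o_xyz[, 3])),
    stringsAsFactors = FALSE)
  residues <- data.frame(seq_pos = seq_len(L),
                         aa = strsplit(sequence, "")[[1]],
                         modeled = TRUE, confidence = NA_real_,
                         stringsAsFactors = FALSE)
  uid <- if (provenance == "computed") entry_id else paste0(entry_id, "_1")
  structure_model(entry_id,
                  list(polymer_instance(chain_id, uid, residues, atoms)),
                  provenance = provenance)
}

#' Create a hinge-motion copy of a structure
#'
#' Residues at or beyond the pivot are rigidly rotated by `rotation_deg`
#' about an axis through the pivot CA; residues before the pivot (and the
#' pivot CA itself) are untouched. The default axis is computed from the
#' fixed domain only (perpendicular to the vector from the first CA to the
#' pivot CA), so repeated applications compose: applying 30 degrees twice
#' equals applying 60 degrees once.
#'
#' @param base A single-chain `structure_model`.
#' @param pivot_seq_pos Hinge pivot (must be an interior, modeled residue).
#' @param rotation_deg Rotation angle in degrees.
#' @param axis Optional explicit rotation axis (length-3 vector).
#' @return A `structure_model` with entry id `"<base>_H"`.
#' @export
make_hinge_pair <- function(base, pivot_seq_pos, rotation_deg, axis = NULL) {
  ch <- base$chains[[1]]
  L <- max(ch$residues$seq_pos)
  if (pivot_seq_pos <= 1L || pivot_seq_pos >= L) {
    stop("hinge pivot must be strictly inside the chain", call. = FALSE)
  }
  ca <- ch$atoms[ch$atoms$atom_name == "CA", , drop = FALSE]
  pivot_ca <- unlist(ca[match(pivot_seq_pos, ca$seq_pos), c("x", "y", "z")])
  if (anyNA(pivot_ca)) stop("pivot residue has no CA atom", call. = FALSE)
  if (is.null(axis)) {
    first_ca <- unlist(ca[1, c("x", "y", "z")])
    v <- pivot_ca - first_ca
    axis <- .vcross(v, c(0, 0, 1))
    if (.vnorm(axis) < 1e-6) axis <- .vcross(v, c(0, 1, 0))
  }
  R <- rotation_about_axis(axis, rotation_deg)
  moving <- ch$atoms$seq_pos >= pivot_seq_pos
  xyz <- as.matrix(ch$atoms[moving, c("x", "y", "z")])
  xyz <- sweep(sweep(xyz, 2, pivot_ca) %*% t(R), 2, pivot_ca, "+")
  atoms <- ch$atoms
  atoms[moving, c("x", "y", "z")] <- xyz
  inst <- polymer_instance(ch$chain_id, ch$entity_uid, ch$residues, atoms)
  structure_model(paste0(base$entry_id, "_H"), list(inst), base$ligands,
                  base$provenance)
}

#' Specification of a synthetic group fixture
#'
#' Defaults describe a small but realistic group: 20 variants of one
#' ancestral sequence of 80-120 residues, 5% point mutations per position,
#' a fifth of the members emitted as computed models with pLDDT around 85,
#' and a 10% chance per experimental member of one unmodeled gap.
#'
#' @param seed Integer seed; fixes every random draw.
#' @param n_entities Number of sequence variants.
#' @param length_range `(min, max)` for the ancestral sequence length.
#' @param mutation_rate Per-position mutation probability in `[0,1]`. A
#'   mutated position is redrawn uniformly over the 20 standard residues, so
#'   the expected variant-vs-ancestor identity is
#'   `1 - mutation_rate * 19/20`.
#' @param unmodeled_gap_prob Probability that an experimental member carries
#'   one unmodeled gap (5-15 residues).
#' @param ss_layout Optional secondary-structure layout (see
#'   [build_ideal_chain()]); by default helix / coil / strand / coil / helix
#'   blocks spanning the sequence.
#' @param hinge Optional `list(pivot_seq_pos, rotation_deg)`; every second
#'   member is emitted in the hinged ("open") conformation.
#' @param ligand_sites List of `list(comp_id, anchor_seq_pos, offset,
#'   members = NULL)`; a single-atom ligand is placed `offset` Angstrom from
#'   the anchor CA, pointing away from the chain centroid, in the named
#'   members (default: all experimental members).
#' @param plddt_profile `list(mean, sd)` for computed-model confidence.
#' @param n_computed Number of members emitted as computed models (the last
#'   `n_computed` variants).
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed, n_entities = 20L, length_range = c(80L, 120L),
                         mutation_rate = 0.05, unmodeled_gap_prob = 0.1,
                         ss_layout = NULL, hinge = NULL,
                         ligand_sites = list(),
                         plddt_profile = list(mean = 85, sd = 8),
                         n_computed = max(0L, round(n_entities / 5))) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            mutation_rate >= 0, mutation_rate <= 1,
            unmodeled_gap_prob >= 0, unmodeled_gap_prob <= 1,
            n_computed >= 0, n_computed <= n_entities)
  structure(list(seed = as.integer(seed), n_entities = as.integer(n_entities),
                 length_range = as.integer(length_range),
                 mutation_rate = mutation_rate,
                 unmodeled_gap_prob = unmodeled_gap_prob,
                 ss_layout = ss_layout, hinge = hinge,
                 ligand_sites = ligand_sites, plddt_profile = plddt_profile,
                 n_computed = as.integer(n_computed)),
            class = "fixture_spec")
}

#' @noRd
.default_layout <- function(L) {
  h1 <- max(5L, floor(L * 0.30)); c1 <- max(2L, floor(L * 0.10))
  s1 <- max(5L, floor(L * 0.20)); c2 <- max(2L, floor(L * 0.10))
  h2 <- L - h1 - c1 - s1 - c2
  if (h2 < 5L) stop("sequence too short for the default layout", call. = FALSE)
  data.frame(element = c("helix", "coil", "strand", "coil", "helix"),
             length = c(h1, c1, s1, c2, h2), stringsAsFactors = FALSE)
}

#' Generate a synthetic group corpus
#'
#' Builds `n_entities` variants of a seeded ancestral sequence, one
#' structure per variant on a shared ideal-geometry backbone (optionally
#' with a hinge motion in every second member), with ligands, unmodeled
#' gaps and pLDDT profiles per the spec. All experimental members share one
#' accession (they are variants of the same protein) and one deposition
#' group; organisms and release years cycle through a small set so that
#' summary histograms have several bins.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Optional directory; when given, writes
#'   `structures/<id>.cif`, `sequences.fasta`, `entities.tsv` and
#'   `domains.tsv` (byte-identical for identical specs).
#' @return List with `entities` (named list of [polymer_entity()]),
#'   `structures` (named by entry id), `ancestor_sequence`, `accession`,
#'   and `spec`.
#' @export
make_group_fixture <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  .with_seed(spec$seed, {
    L <- if (spec$length_range[1] == spec$length_range[2]) spec$length_range[1]
    else sample(seq(spec$length_range[1], spec$length_range[2]), 1L)
    ancestor <- paste(sample(.AA20, L, replace = TRUE), collapse = "")
    lay <- if (is.null(spec$ss_layout)) .default_layout(L)
    else .normalize_layout(spec$ss_layout)

    n <- spec$n_entities
    computed <- seq_len(n) > (n - spec$n_computed)
    organisms <- c("Homo sapiens", "Mus musculus", "Escherichia coli")
    years <- 2016:2023
    accession <- "P00001"

    entities <- list()
    structures <- list()
    meta_rows <- list()
    domain_rows <- list()
    anc_chars <- strsplit(ancestor, "")[[1]]

    for (i in seq_len(n)) {
      chars <- anc_chars
      mut <- runif(L) < spec$mutation_rate
      if (any(mut)) chars[mut] <- sample(.AA20, sum(mut), replace = TRUE)
      seqi <- paste(chars, collapse = "")

      prov <- if (computed[i]) "computed" else "experimental"
      entry_id <- if (computed[i]) sprintf("CSM%04d", i) else sprintf("E%04d", i)
      uid <- if (computed[i]) entry_id else paste0(entry_id, "_1")

      model <- build_ideal_chain(lay, seqi, seed = spec$seed + i,
                                 entry_id = entry_id, provenance = prov)
      if (!is.null(spec$hinge) && i %% 2L == 0L) {
        model <- make_hinge_pair(model, spec$hinge$pivot_seq_pos,
                                 spec$hinge$rotation_deg)
        model$entry_id <- entry_id  # keep the id stable across conformations
      }
      ch <- model$chains[[1]]
      ch$entity_uid <- uid
      model$chains[[1]] <- ch

      # pLDDT for computed members
      if (computed[i]) {
        conf <- rnorm(L, spec$plddt_profile$mean, spec$plddt_profile$sd)
        conf <- round(pmin(100, pmax(0, conf)), 2)
        model$chains[[1]]$residues$confidence <- conf
      }

      # one unmodeled gap for experimental members
      if (!computed[i] && runif(1) < spec$unmodeled_gap_prob) {
        glen <- sample(5:15, 1L)
        gstart <- sample(seq(2L, L - glen), 1L)
        gap <- seq(gstart, gstart + glen - 1L)
        inst <- model$chains[[1]]
        inst$residues$modeled[gap] <- FALSE
        inst$atoms <- inst$atoms[!(inst$atoms$seq_pos %in% gap), , drop = FALSE]
        model$chains[[1]] <- inst
      }

      # ligand placement
      for (site in spec$ligand_sites) {
        wanted <- site$members %||% which(!computed)
        hit <- if (is.numeric(wanted)) i %in% wanted else uid %in% wanted
        if (!hit) next
        inst <- model$chains[[1]]
        ca <- inst$atoms[inst$atoms$atom_name == "CA", , drop = FALSE]
        anchor <- ca[match(site$anchor_seq_pos, ca$seq_pos), c("x", "y", "z")]
        if (anyNA(anchor)) next  # anchor fell in an unmodeled gap
        centroid <- colMeans(ca[, c("x", "y", "z")])
        dir <- .vunit(unlist(anchor) - centroid)
        pos <- unlist(anchor) + site$offset * dir
        model$ligands <- rbind(model$ligands, data.frame(
          comp_id = site$comp_id, chain_id = "L", atom_name = "C1",
          element = "C", x = pos[1], y = pos[2], z = pos[3],
          stringsAsFactors = FALSE))
      }

      ent <- polymer_entity(
        entity_uid = uid, entry_id = entry_id, sequence = seqi,
        provenance = prov, accession = accession,
        organism = organisms[(i - 1L) %% length(organisms) + 1L],
        release_date = sprintf("%d-06-01", years[(i - 1L) %% length(years) + 1L]),
        deposition_group_id = if (computed[i]) NULL else "DEP0001",
        domain_annotations = .fixture_domains(L, spec$hinge))
      entities[[uid]] <- ent
      structures[[entry_id]] <- model

      meta_rows[[i]] <- data.frame(
        entity_uid = uid, accession = accession,
        organism = ent$organism, release_date = ent$release_date,
        deposition_group_id = ent$deposition_group_id %||% "",
        provenance = prov, stringsAsFactors = FALSE)
      dd <- ent$domain_annotations
      dd$entity_uid <- uid
      domain_rows[[i]] <- dd[, c("entity_uid", "source", "domain_id",
                                 "begin", "end")]
    }

    out <- list(entities = entities, structures = structures,
                ancestor_sequence = ancestor, accession = accession,
                spec = spec)
    if (!is.null(out_dir)) {
      dir.create(file.path(out_dir, "structures"), recursive = TRUE,
                 showWarnings = FALSE)
      for (id in names(structures)) {
        write_structure(structures[[id]],
                        file.path(out_dir, "structures", paste0(id, ".cif")))
      }
      write_fasta(entities, file.path(out_dir, "sequences.fasta"))
      .write_tsv(do.call(rbind, meta_rows), file.path(out_dir, "entities.tsv"))
      .write_tsv(do.call(rbind, domain_rows), file.path(out_dir, "domains.tsv"))
      out$out_dir <- out_dir
    }
    out
  })
}

#' @noRd
.fixture_domains <- function(L, hinge) {
  split_at <- if (is.null(hinge)) floor(L / 2) else hinge$pivot_seq_pos - 1L
  data.frame(source = c("PFAM", "PFAM"),
             domain_id = c("PF0001", "PF0002"),
             begin = c(1L, split_at + 1L),
             end = c(split_at, L), stringsAsFactors = FALSE)
}

#' @noRd
.write_tsv <- function(df, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}
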