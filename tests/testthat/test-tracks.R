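# Positional tracks: modeled regions, pLDDT, secondary structure,
# feature/binding frequencies, mutation markers.

# a 1-member structure-bearing group anchored on its own sequence
one_member_group <- function(model, uid = model$chains[[1]]$entity_uid) {
  seqi <- instance_sequence(model$chains[[1]])
  ents <- tiny_entities(setNames(seqi, uid), accession = "P1")
  ents[[uid]]$entry_id <- model$entry_id
  ents[[uid]]$provenance <- model$provenance
  g <- build_groups(ents, method = "reference_accession",
                    reference_sequences = list(P1 = seqi))[[1]]
  list(entities = ents, group = g, ga = build_group_alignment(g, ents))
}

test_that("modeled and unmodeled columns partition the aligned span", {
  m <- build_ideal_chain(data.frame(element = "helix", length = 100),
                         strrep("A", 100), entry_id = "MD")
  inst <- m$chains[[1]]
  drop <- c(1:9, 91:100)
  inst$residues$modeled[drop] <- FALSE
  inst$atoms <- inst$atoms[!(inst$atoms$seq_pos %in% drop), ]
  m$chains[[1]] <- inst
  w <- one_member_group(m)
  tr <- modeled_track("MD_1", m, w$ga)
  reg <- tr$values
  expect_equal(reg$column_begin[reg$label == "modeled"], 10)
  expect_equal(reg$column_end[reg$label == "modeled"], 90)
  expect_equal(reg$column_begin[reg$label == "unmodeled"], c(1, 91))
  covered <- unlist(apply(reg, 1, function(r) {
    as.integer(r[["column_begin"]]):as.integer(r[["column_end"]])
  }))
  expect_setequal(covered, 1:100)     # partition: covering
  expect_false(anyDuplicated(covered) > 0)  # and disjoint
  # fully modeled member: a single modeled region
  m2 <- build_ideal_chain(data.frame(element = "helix", length = 30),
                          strrep("A", 30), entry_id = "FM")
  w2 <- one_member_group(m2)
  tr2 <- modeled_track("FM_1", m2, w2$ga)
  expect_equal(nrow(tr2$values), 1)
  expect_equal(tr2$values$label, "modeled")
})

test_that("pLDDT maps to columns and bins at 90/70/50 half-open edges", {
  m <- build_ideal_chain(data.frame(element = "helix", length = 8),
                         strrep("A", 8), entry_id = "CM",
                         provenance = "computed")
  conf <- c(95, 90, 89.9, 70, 69.9, 50, 49.9, 10)
  m$chains[[1]]$residues$confidence <- conf
  w <- one_member_group(m, uid = "CM")
  tr <- plddt_track("CM", m, w$ga)
  expect_equal(tr$score$values, conf)
  expect_equal(tr$category$values,
               c("very-high", "very-high", "confident", "confident",
                 "low", "low", "very-low", "very-low"))
  exp_m <- m; exp_m$provenance <- "experimental"
  expect_error(plddt_track("CM", exp_m, w$ga), "computed models only")
})

test_that("ideal fixtures earn their secondary-structure labels", {
  h <- build_ideal_chain(data.frame(element = "helix", length = 20),
                         strrep("A", 20))
  lab_h <- assign_secondary_structure(h)$A
  expect_gte(sum(lab_h[3:18] == "H"), 16 * 0.8)
  s <- build_ideal_chain(data.frame(element = "strand", length = 20),
                         strrep("A", 20))
  lab_s <- assign_secondary_structure(s)$A
  expect_gte(sum(lab_s == "E"), 20 - 4)
  # short chains are all coil
  tiny <- build_ideal_chain(data.frame(element = "helix", length = 4),
                            strrep("A", 4))
  expect_equal(assign_secondary_structure(tiny)$A, rep("C", 4))
})

test_that("feature frequencies use the modeled-member denominator", {
  # 4 members on the same backbone; one strand-member at the helix columns
  mk <- function(id, el) {
    m <- build_ideal_chain(data.frame(element = el, length = 30),
                           strrep("A", 30), entry_id = id)
    m
  }
  models <- list(H1 = mk("H1", "helix"), H2 = mk("H2", "helix"),
                 H3 = mk("H3", "helix"), S1 = mk("S1", "strand"))
  ents <- tiny_entities(setNames(rep(strrep("A", 30), 4),
                                 c("H1_1", "H2_1", "H3_1", "S1_1")),
                        accession = rep("P1", 4))
  for (uid in names(ents)) ents[[uid]]$entry_id <- sub("_1$", "", uid)
  g <- build_groups(ents, method = "reference_accession",
                    reference_sequences = list(P1 = strrep("A", 30)))[[1]]
  ga <- build_group_alignment(g, ents)
  tr <- feature_frequency_track(g, ga, ents, models, "helix")
  # interior helix columns: 3 of 4 members helical
  expect_equal(tr$values[10], 3 / 4)
  tr_s <- feature_frequency_track(g, ga, ents, models, "strand")
  expect_equal(tr_s$values[10], 1 / 4)
  # all-members feature: domain spanning 5..20 on every member
  for (uid in names(ents)) {
    ents[[uid]]$domain_annotations <- data.frame(
      source = "PFAM", domain_id = "PFX", begin = 5L, end = 20L)
  }
  dom <- feature_frequency_track(g, ga, ents, models,
                                 list(source = "PFAM", id = "PFX"))
  expect_equal(dom$values[5:20], rep(1, 16))
  expect_equal(dom$values[c(1:4, 21:30)], rep(0, 14))
  expect_error(feature_frequency_track(g, ga, ents, models,
                                       list(source = "NOPE")),
               "unknown domain source")
})

test_that("contact detection agrees with the brute-force oracle", {
  fx <- make_group_fixture(fixture_spec(
    seed = 23, n_entities = 3, length_range = c(50L, 50L), n_computed = 0,
    unmodeled_gap_prob = 0,
    ligand_sites = list(list(comp_id = "GTP", anchor_seq_pos = 25,
                             offset = 3.5))))
  for (st in fx$structures) {
    got <- detect_contacts(st)
    want <- oracle_contacts(st)
    expect_equal(got$seq_pos, want$seq_pos)
    expect_equal(got$min_distance, want$min_distance, tolerance = 1e-9)
  }
  # distant ligand: no contacts
  st <- fx$structures[[1]]
  st$ligands$x <- st$ligands$x + 500
  expect_equal(nrow(detect_contacts(st)), 0L)
  # rigid invariance: translate everything
  st2 <- fx$structures[[1]]
  for (i in seq_along(st2$chains)) {
    st2$chains[[i]]$atoms[, c("x", "y", "z")] <-
      st2$chains[[i]]$atoms[, c("x", "y", "z")] + 17.3
  }
  st2$ligands[, c("x", "y", "z")] <- st2$ligands[, c("x", "y", "z")] + 17.3
  moved <- detect_contacts(st2)
  orig <- detect_contacts(fx$structures[[1]])
  expect_equal(moved$seq_pos, orig$seq_pos)
  expect_equal(moved$min_distance, orig$min_distance, tolerance = 1e-9)
})

test_that("per-ligand binding normalizes by contacting members", {
  # group of 4; GTP contacts columns 10-12 in exactly one member
  seqs <- setNames(rep(strrep("A", 30), 4), sprintf("b%d_1", 1:4))
  ents <- tiny_entities(seqs, accession = rep("P1", 4))
  g <- build_groups(ents, method = "reference_accession",
                    reference_sequences = list(P1 = strrep("A", 30)))[[1]]
  ga <- build_group_alignment(g, ents)
  contacts <- data.frame(member_uid = "b1_1", chain_id = "A",
                         seq_pos = 10:12, comp_id = "GTP",
                         min_distance = 3.0, stringsAsFactors = FALSE)
  bt <- binding_tracks(g, ga, contacts, ents)
  expect_equal(bt$per_ligand$GTP$values[10:12], rep(1.0, 3))
  expect_equal(bt$per_ligand$GTP$values[c(1:9, 13:30)], rep(0, 27))
  expect_equal(bt$global$values[10:12], rep(1L, 3))
  # two members contact GTP, one of them also at column 11
  contacts2 <- rbind(contacts,
                     data.frame(member_uid = "b2_1", chain_id = "A",
                                seq_pos = 10:11, comp_id = "GTP",
                                min_distance = 3.0))
  bt2 <- binding_tracks(g, ga, contacts2, ents)
  expect_equal(bt2$per_ligand$GTP$values[10], 1.0)
  expect_equal(bt2$per_ligand$GTP$values[11], 1.0)
  expect_equal(bt2$per_ligand$GTP$values[12], 0.5)
  # global sums to total events
  expect_equal(sum(bt2$global$values), 3 + 2)
})

test_that("mutation markers flag substituted columns only", {
  w <- worked_group()
  expect_equal(mutation_markers("m1", w$ga, w$entities), integer())
  expect_equal(mutation_markers("m2", w$ga, w$entities), 10L)
  # deletion is not a marker
  expect_equal(mutation_markers("m3", w$ga, w$entities), integer())
  # marker count equals the Hamming distance over aligned non-gap columns
  ref <- "ACDEFGHIKL"
  mut <- "ACDAFGHIKA"
  ents <- tiny_entities(c(r_1 = ref, m_1 = mut), accession = c("P1", "P1"))
  g <- build_groups(ents, method = "reference_accession",
                    reference_sequences = list(P1 = ref))[[1]]
  ga <- build_group_alignment(g, ents)
  expect_equal(mutation_markers("m_1", ga, ents), c(4L, 10L))
})

test_that("a substitution at reference position 76 is marked at column 76", {
  set.seed(76)
  ref <- random_aa_seq(120)
  chars <- strsplit(ref, "")[[1]]
  chars[76] <- if (chars[76] == "A") "E" else "A"
  mut <- paste(chars, collapse = "")
  ents <- tiny_entities(c(wt_1 = ref, mu_1 = mut), accession = c("P1", "P1"))
  g <- build_groups(ents, method = "reference_accession",
                    reference_sequences = list(P1 = ref))[[1]]
  ga <- build_group_alignment(g, ents)
  expect_equal(mutation_markers("mu_1", ga, ents), 76L)
  expect_equal(mutation_markers("wt_1", ga, ents), integer())
})

test_that("track constructors enforce range invariants", {
  expect_error(positional_track("t", "g", "fraction", c(0.5, 1.2)),
               "\\[0,1\\]")
  expect_error(positional_track("t", "g", "count", c(1, -2)),
               "non-negative")
  expect_error(positional_track("t", "g", "region",
                                data.frame(column_begin = c(1, 3),
                                           column_end = c(4, 6),
                                           label = "x")),
               "non-overlapping")
})
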