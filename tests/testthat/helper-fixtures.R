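# Shared in-code fixtures for the test suite.

# A tiny entity list built directly (no structures).
tiny_entities <- function(seqs, provenance = NULL, accession = NULL,
                          organism = NULL, release_date = NULL) {
  opt <- function(v, i) {
    if (is.null(v) || is.na(v[i])) NULL else unname(v[i])
  }
  out <- lapply(seq_along(seqs), function(i) {
    polymer_entity(
      entity_uid = names(seqs)[i],
      entry_id = sub("_[0-9]+$", "", names(seqs)[i]),
      sequence = seqs[[i]],
      provenance = if (is.null(provenance)) "experimental" else provenance[i],
      accession = opt(accession, i),
      organism = opt(organism, i),
      release_date = opt(release_date, i))
  })
  names(out) <- names(seqs)
  out
}

# The 4-member worked group used for hand-computed track arithmetic.
# Reference = member m1; m2 has one substitution; m3 has an internal
# deletion; m4 is identical to m1.
#   ref:  ACDEFGHIKL (10 columns)
#   m1 =  ACDEFGHIKL
#   m2 =  ACDEFGHIKV      (substitution at position 10)
#   m3 =  ACDEGHIKL       (F5 deleted)
#   m4 =  ACDEFGHIKL
worked_group <- function() {
  seqs <- c(m1 = "ACDEFGHIKL", m2 = "ACDEFGHIKV",
            m3 = "ACDEGHIKL", m4 = "ACDEFGHIKL")
  entities <- tiny_entities(seqs, accession = rep("P99999", 4))
  group <- build_groups(entities, method = "reference_accession",
                        reference_sequences = list(P99999 = "ACDEFGHIKL"))[[1]]
  ga <- build_group_alignment(group, entities)
  list(entities = entities, group = group, ga = ga)
}

# An all-helix chain plus a structure-bearing group for track tests.
helix_model <- function(L = 30, seed = 1, entry_id = "HX", ...) {
  build_ideal_chain(data.frame(element = "helix", length = L),
                    strrep("A", L), seed = seed, entry_id = entry_id, ...)
}
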