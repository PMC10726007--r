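# Global alignment against independent oracles; star alignment; summary
# tracks; pagination.

test_that("identical sequences align fully with the diagonal score", {
  seq <- "MKTAYIAKQR"
  aln <- align_pair_global(seq, seq)
  expect_equal(nrow(aln$aligned_pairs), nchar(seq))
  expect_equal(aln$aligned_pairs[, 1], aln$aligned_pairs[, 2])
  env <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = env)
  chars <- strsplit(seq, "")[[1]]
  expect_equal(aln$score,
               sum(vapply(chars, function(ch) env$BLOSUM62[ch, ch], numeric(1))))
})

test_that("alignment scores equal the DP oracle on seeded random pairs", {
  set.seed(101)
  for (k in 1:50) {
    a <- random_aa_seq(sample(1:40, 1))
    b <- random_aa_seq(sample(1:40, 1))
    aln <- align_pair_global(a, b)
    expect_equal(aln$score, oracle_nw_score(a, b),
                 info = paste(a, b, sep = " / "))
    # aligned pairs strictly increasing in both coordinates
    p <- aln$aligned_pairs
    if (nrow(p) > 1) {
      expect_true(all(diff(p[, 1]) > 0))
      expect_true(all(diff(p[, 2]) > 0))
    }
  }
})

test_that("the classic worked pair scores as the oracle says", {
  expect_equal(align_pair_global("HEAGAWGHEE", "PAWHEAE")$score,
               oracle_nw_score("HEAGAWGHEE", "PAWHEAE"))
})

test_that("alignment score agrees with an independent library implementation", {
  env <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = env)
  set.seed(77)
  for (k in 1:10) {
    a <- random_aa_seq(sample(5:30, 1))
    b <- random_aa_seq(sample(5:30, 1))
    ref <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                         substitutionMatrix = env$BLOSUM62,
                                         gapOpening = 11, gapExtension = 1)
    expect_equal(align_pair_global(a, b)$score, Biostrings::score(ref))
  }
})

test_that("length-1 sequences align per exhaustive enumeration", {
  # vs "A": either one aligned pair (score s(x, A)) or none (two gaps,
  # score -(11+1)*2); the best of those is optimal
  env <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = env)
  for (x in c("A", "W", "C")) {
    aln <- align_pair_global(x, "A")
    best <- max(env$BLOSUM62[x, "A"], -2 * 12)
    expect_equal(aln$score, best)
    expect_equal(nrow(aln$aligned_pairs), if (best == -24) 0L else 1L)
  }
})

test_that("star alignment anchors columns on the reference", {
  w <- worked_group()
  ga <- w$ga
  expect_equal(ga$n_columns, 10)
  # member identical to the reference: one region spanning everything
  expect_equal(nrow(ga$members[["m1"]]), 1)
  expect_equal(unlist(ga$members[["m1"]][1, ]),
               c(member_begin = 1, member_end = 10,
                 column_begin = 1, column_end = 10))
  # internal deletion: two regions around the deleted column
  m3 <- ga$members[["m3"]]
  expect_equal(nrow(m3), 2)
  expect_equal(m3$column_begin, c(1, 6))
  expect_equal(m3$column_end, c(4, 10))
  expect_equal(m3$member_begin, c(1, 5))
  expect_equal(m3$member_end, c(4, 9))
  # depth: column 5 misses m3 only
  expect_equal(ga$depth, c(4, 4, 4, 4, 3, 4, 4, 4, 4, 4))
})

test_that("a member deleting an internal block yields flanking regions", {
  ref <- random_aa_seq(80)
  member <- paste0(substr(ref, 1, 39), substr(ref, 61, 80))
  ents <- tiny_entities(c(r_1 = ref, m_1 = member),
                        accession = c("P1", "P1"))
  g <- build_groups(ents, method = "reference_accession",
                    reference_sequences = list(P1 = ref))[[1]]
  ga <- build_group_alignment(g, ents)
  reg <- ga$members[["m_1"]]
  expect_equal(nrow(reg), 2)
  expect_equal(reg$column_begin, c(1, 61))
  expect_equal(reg$column_end, c(39, 80))
})

test_that("member-to-column maps are injective and order-preserving", {
  set.seed(5)
  ref <- random_aa_seq(50)
  for (k in 1:10) {
    # random edit: delete a block or substitute a few positions
    s <- strsplit(ref, "")[[1]]
    if (k %% 2 == 0) s <- s[-(10:14)] else s[sample(50, 3)] <- "W"
    member <- paste(s, collapse = "")
    ents <- tiny_entities(c(r_1 = ref, m_1 = member),
                          accession = c("P1", "P1"))
    g <- build_groups(ents, method = "reference_accession",
                      reference_sequences = list(P1 = ref))[[1]]
    ga <- build_group_alignment(g, ents)
    map <- structgroups:::.member_col_map(ga, "m_1", nchar(member))
    cols <- map[!is.na(map)]
    expect_false(anyDuplicated(cols) > 0)
    expect_true(all(diff(cols) > 0))
  }
})

test_that("consensus takes the modal symbol with stated tie-breaks", {
  w <- worked_group()
  cons <- consensus_track(w$ga, w$entities)
  # all columns modal from {m1,m2,m4} = reference residues
  expect_equal(paste(cons$values, collapse = ""), "ACDEFGHIKL")
  # tie residue-over-gap, then alphabetical: build a 2-member group with a
  # deletion in one member -> column 5 sees one residue, one gap
  ents <- tiny_entities(c(r_1 = "ACDEFGHIKL", d_1 = "ACDEGHIKL"),
                        accession = c("P1", "P1"))
  g <- build_groups(ents, method = "reference_accession",
                    reference_sequences = list(P1 = "ACDEFGHIKL"))[[1]]
  ga <- build_group_alignment(g, ents)
  cons2 <- consensus_track(ga, ents)
  expect_equal(cons2$values[5], "F")  # residue beats gap on a 1-1 tie
})

test_that("gap majority wins the consensus when most members delete", {
  ents <- tiny_entities(c(r_1 = "ACDEFGHIKL", d_1 = "ACDEGHIKL",
                          e_1 = "ACDEGHIKL"),
                        accession = rep("P1", 3))
  g <- build_groups(ents, method = "reference_accession",
                    reference_sequences = list(P1 = "ACDEFGHIKL"))[[1]]
  ga <- build_group_alignment(g, ents)
  cons <- consensus_track(ga, ents)
  expect_equal(cons$values[5], "-")
})

test_that("variation reflects residue diversity and ignores ordering", {
  w <- worked_group()
  v <- variation_track(w$ga, w$entities)$values
  expect_equal(v[1:9], rep(0, 9))       # conserved columns
  expect_equal(v[10], 1 - 3 / 4)        # L,L,L,V
  # reorder members
  w2 <- w
  w2$ga$members <- rev(w2$ga$members)
  expect_equal(variation_track(w2$ga, w2$entities)$values, v)
  # identical members: zero everywhere
  ents <- tiny_entities(c(a_1 = "ACDEF", b_1 = "ACDEF"),
                        accession = c("P1", "P1"))
  g <- build_groups(ents, method = "reference_accession",
                    reference_sequences = list(P1 = "ACDEF"))[[1]]
  ga <- build_group_alignment(g, ents)
  expect_equal(variation_track(ga, ents)$values, rep(0, 5))
})

test_that("pagination slices members into blocks without loss", {
  seqs <- setNames(rep("ACDEFGHIKL", 120), sprintf("m%03d_1", 1:120))
  ents <- tiny_entities(seqs, accession = rep("P1", 120))
  g <- build_groups(ents, method = "reference_accession",
                    reference_sequences = list(P1 = "ACDEFGHIKL"))[[1]]
  ga <- build_group_alignment(g, ents)
  pages <- lapply(1:3, function(p) paginate(ga, p))
  expect_equal(lengths(pages), c(50, 50, 20))
  expect_equal(sort(unlist(pages)), sort(names(ga$members)))
  expect_equal(paginate(ga, 4), character())
  small <- paginate(ga, 1, page_size = 200)
  expect_length(small, 120)
  expect_error(paginate(ga, 0), ">= 1")
})
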