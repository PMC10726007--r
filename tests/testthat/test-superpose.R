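# Alignment-guided rigid-body superposition.

test_that("self and translated superposition recover the identity motion", {
  set.seed(2)
  A <- matrix(rnorm(30), 10, 3)
  f <- kabsch(A, A)
  expect_equal(f$rmsd, 0, tolerance = 1e-9)
  expect_equal(f$rotation, diag(3), tolerance = 1e-9)
  expect_equal(f$translation, c(0, 0, 0), tolerance = 1e-9)
  B <- sweep(A, 2, c(1, 2, 3), "+")
  f2 <- kabsch(A, B)
  expect_equal(f2$rmsd, 0, tolerance = 1e-9)
  expect_equal(f2$translation, c(-1, -2, -3), tolerance = 1e-9)
})

test_that("kabsch inverts any proper rigid motion (seeded property)", {
  set.seed(31)
  for (k in 1:25) {
    A <- matrix(rnorm(3 * sample(4:20, 1)), ncol = 3)
    R <- rotation_about_axis(rnorm(3), runif(1, -180, 180))
    t <- rnorm(3, sd = 10)
    B <- sweep(A %*% t(R), 2, t, "+")
    f <- kabsch(A, B)
    expect_lt(f$rmsd, 1e-9)
    expect_equal(det(f$rotation), 1, tolerance = 1e-9)
    expect_equal(t(f$rotation) %*% f$rotation, diag(3), tolerance = 1e-9)
  }
})

test_that("kabsch RMSD matches the quaternion oracle on noisy clouds", {
  set.seed(11)
  for (k in 1:25) {
    A <- matrix(rnorm(30), 10, 3)
    R <- rotation_about_axis(rnorm(3), runif(1, -180, 180))
    B <- sweep(A %*% t(R), 2, rnorm(3, sd = 5), "+") +
      matrix(rnorm(30, sd = 0.5), 10, 3)
    expect_equal(kabsch(A, B)$rmsd, oracle_quaternion_rmsd(A, B),
                 tolerance = 1e-9)
  }
})

test_that("rmsd is invariant under a common rigid motion of both sets", {
  set.seed(4)
  A <- matrix(rnorm(24), 8, 3)
  B <- A + matrix(rnorm(24, sd = 1), 8, 3)
  base <- kabsch(A, B)$rmsd
  R <- rotation_about_axis(c(1, 1, 0), 73)
  t <- c(5, -3, 2)
  A2 <- sweep(A %*% t(R), 2, t, "+")
  B2 <- sweep(B %*% t(R), 2, t, "+")
  expect_equal(kabsch(A2, B2)$rmsd, base, tolerance = 1e-9)
})

test_that("larger noise never decreases expected rmsd", {
  set.seed(8)
  A <- matrix(rnorm(60), 20, 3)
  mean_rmsd <- vapply(c(0.1, 0.5, 2.0), function(sd) {
    mean(vapply(1:20, function(k) {
      kabsch(A, A + matrix(rnorm(60, sd = sd), 20, 3))$rmsd
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_rmsd) > 0))
})

test_that("degenerate and undersized inputs are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch(line, line), "degenerate|collinear")
  A <- matrix(rnorm(6), 2, 3)
  expect_error(kabsch(A, A), "at least 3")
})

test_that("correspondence respects column ranges and modeled residues", {
  m <- build_ideal_chain(data.frame(element = "helix", length = 200),
                         strrep("A", 200), entry_id = "CR")
  seqi <- strrep("A", 200)
  ents <- tiny_entities(c(CR_1 = seqi, CR2_1 = seqi),
                        accession = c("P1", "P1"))
  ents$CR_1$entry_id <- "CR"; ents$CR2_1$entry_id <- "CR2"
  m2 <- m; m2$entry_id <- "CR2"
  m2$chains[[1]]$entity_uid <- "CR2_1"
  g <- build_groups(ents, method = "reference_accession",
                    reference_sequences = list(P1 = seqi))[[1]]
  ga <- build_group_alignment(g, ents)
  full <- correspondence(ga, "CR_1", "CR2_1", m, m2, ents)
  expect_equal(nrow(full), 200)
  lim <- correspondence(ga, "CR_1", "CR2_1", m, m2, ents,
                        column_range = c(1, 100))
  expect_true(all(lim$column <= 100))
  # unmodeled block in the target drops those columns
  inst <- m2$chains[[1]]
  inst$residues$modeled[40:60] <- FALSE
  inst$atoms <- inst$atoms[!(inst$atoms$seq_pos %in% 40:60), ]
  m2$chains[[1]] <- inst
  part <- correspondence(ga, "CR_1", "CR2_1", m, m2, ents)
  expect_false(any(part$column %in% 40:60))
  expect_error(correspondence(ga, "CR_1", "CR2_1", m, m2, ents,
                              column_range = c(1, 2)),
               "fewer than 3")
})

test_that("domain-restricted superposition separates hinge conformations", {
  base <- build_ideal_chain(data.frame(element = "helix", length = 100),
                            strrep("A", 100), entry_id = "OP")
  open <- make_hinge_pair(base, 50, 30)
  open$entry_id <- "CL"
  open$chains[[1]]$entity_uid <- "CL_1"
  seqi <- strrep("A", 100)
  ents <- tiny_entities(c(OP_1 = seqi, CL_1 = seqi),
                        accession = c("P1", "P1"))
  ents$OP_1$entry_id <- "OP"; ents$CL_1$entry_id <- "CL"
  structures <- list(OP = base, CL = open)
  g <- build_groups(ents, method = "reference_accession",
                    reference_sequences = list(P1 = seqi))[[1]]
  ga <- build_group_alignment(g, ents)

  fixed <- superpose_members(g, ga, structures, ents, ref_member = "OP_1",
                             targets = "CL_1", column_range = c(1, 49),
                             eval_range = c(50, 100))
  r <- fixed$CL_1$result
  expect_lte(r$rmsd, 0.01)
  expect_gt(r$eval_rmsd, 5)
  full <- superpose_members(g, ga, structures, ents, ref_member = "OP_1",
                            targets = "CL_1")
  expect_gt(full$CL_1$result$rmsd, r$rmsd)
  expect_lt(full$CL_1$result$rmsd, r$eval_rmsd)
  # self-superposition: identity transform
  self <- superpose_members(g, ga, structures, ents, ref_member = "OP_1",
                            targets = "OP_1")
  expect_equal(self$OP_1$result$rmsd, 0, tolerance = 1e-9)
  expect_equal(self$OP_1$result$rotation, diag(3), tolerance = 1e-9)
})

test_that("transformed CA coordinates reproduce the reported rmsd", {
  set.seed(14)
  base <- build_ideal_chain(data.frame(element = "helix", length = 60),
                            strrep("A", 60), entry_id = "RP")
  moved_model <- base
  moved_model$entry_id <- "RQ"
  moved_model$chains[[1]]$entity_uid <- "RQ_1"
  R <- rotation_about_axis(c(0, 1, 1), 25)
  inst <- moved_model$chains[[1]]
  xyz <- as.matrix(inst$atoms[, c("x", "y", "z")])
  inst$atoms[, c("x", "y", "z")] <-
    sweep(xyz %*% t(R), 2, c(3, 1, -2), "+") +
    matrix(rnorm(nrow(xyz) * 3, sd = 0.3), ncol = 3)
  moved_model$chains[[1]] <- inst
  seqi <- strrep("A", 60)
  ents <- tiny_entities(c(RP_1 = seqi, RQ_1 = seqi),
                        accession = c("P1", "P1"))
  ents$RP_1$entry_id <- "RP"; ents$RQ_1$entry_id <- "RQ"
  g <- build_groups(ents, method = "reference_accession",
                    reference_sequences = list(P1 = seqi))[[1]]
  ga <- build_group_alignment(g, ents)
  sp <- superpose_members(g, ga, list(RP = base, RQ = moved_model), ents,
                          ref_member = "RP_1", targets = "RQ_1")
  r <- sp$RQ_1$result
  tr <- sp$RQ_1$structure
  ca_ref <- base$chains[[1]]$atoms
  ca_ref <- as.matrix(ca_ref[ca_ref$atom_name == "CA", c("x", "y", "z")])
  ca_new <- tr$chains[[1]]$atoms
  ca_new <- as.matrix(ca_new[ca_new$atom_name == "CA", c("x", "y", "z")])
  naive <- sqrt(mean(rowSums((ca_new - ca_ref)^2)))
  expect_equal(naive, r$rmsd, tolerance = 1e-9)
})
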