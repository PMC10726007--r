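# Independent oracles used to cross-check the implementation. These are
# deliberately written with different algorithms/styles than the package
# code (scoring-only DP in plain R, quaternion superposition, naive
# distance scans) and must stay independent of the paths they check.

.oracle_blosum62 <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
})

# Affine-gap global alignment score by straightforward dynamic programming
# (three-state Gotoh recurrence, score only). Gap of length k costs
# open + k * extend.
oracle_nw_score <- function(a, b, mat = .oracle_blosum62,
                            open = 11, extend = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- X <- Y <- matrix(-Inf, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * extend)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * extend)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[av[i], bv[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                             X[i, j + 1] - extend,
                             Y[i, j + 1] - open - extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                             Y[i + 1, j] - extend,
                             X[i + 1, j] - open - extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Horn's closed-form quaternion solution for the optimal rotation; returns
# the RMSD after superposing target onto ref.
oracle_quaternion_rmsd <- function(ref, target) {
  A <- sweep(ref, 2, colMeans(ref))
  B <- sweep(target, 2, colMeans(target))
  S <- t(B) %*% A
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  ev <- eigen(K, symmetric = TRUE)
  q <- ev$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  moved <- B %*% t(R)
  sqrt(mean(rowSums((moved - A)^2)))
}

# Naive all-pairs contact scan (double loop over atoms; no vectorized
# shortcuts) over a structure_model.
oracle_contacts <- function(structure, cutoff = 4.5) {
  out <- list()
  lg <- structure$ligands
  lg <- lg[lg$element != "H", , drop = FALSE]
  for (ch in structure$chains) {
    at <- ch$atoms[ch$atoms$element != "H", , drop = FALSE]
    for (comp in unique(lg$comp_id)) {
      lgc <- lg[lg$comp_id == comp, , drop = FALSE]
      for (sp in unique(at$seq_pos)) {
        res_at <- at[at$seq_pos == sp, , drop = FALSE]
        best <- Inf
        for (i in seq_len(nrow(res_at))) {
          for (j in seq_len(nrow(lgc))) {
            d <- sqrt((res_at$x[i] - lgc$x[j])^2 +
                        (res_at$y[i] - lgc$y[j])^2 +
                        (res_at$z[i] - lgc$z[j])^2)
            if (d < best) best <- d
          }
        }
        if (best <= cutoff) {
          out[[length(out) + 1L]] <- data.frame(
            member_uid = ch$entity_uid, seq_pos = sp, comp_id = comp,
            min_distance = best, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

random_aa_seq <- function(n) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), n, replace = TRUE),
        collapse = "")
}
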