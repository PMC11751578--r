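# Shared fixtures (generated in code, cached per session) and independent
# oracles used to cross-check the package implementations.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

fx_helix <- function(n = 30) {
  cached(paste0("helix", n),
         suppressMessages(attach_sidechains(make_backbone(n, "helix"))))
}

fx_strand <- function(n = 30) {
  cached(paste0("strand", n),
         suppressMessages(attach_sidechains(make_backbone(n, "strand"))))
}

fx_globule <- function(n = 100, seed = 1) {
  cached(sprintf("globule%d_%d", n, seed),
         suppressMessages(make_globule(n, seed = seed)))
}

fx_mixed_allatom <- function(n = 150, seed = 5) {
  cached(sprintf("mixed%d_%d", n, seed),
         suppressMessages(attach_sidechains(
           make_backbone(n, "mixed", seed = seed))))
}

random_rotation_matrix <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

rigid_move <- function(s, R, t) {
  xyz <- cbind(s$x, s$y, s$z) %*% t(R)
  s$x <- xyz[, 1] + t[1]; s$y <- xyz[, 2] + t[2]; s$z <- xyz[, 3] + t[3]
  s
}

# --- independent affine-gap global alignment oracle (Gotoh) -------------
# Full-matrix DP; gap of length k costs open + k * extend (the convention
# of the alignment backend under test). Returns the optimal score only.
oracle_nw_score <- function(a, b, mat, open = 10, extend = 0.5) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- Ix <- Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -(open + extend * i)
  for (j in seq_len(m)) Iy[1, j + 1] <- -(open + extend * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- mat[av[i], bv[j]]
      M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + sub
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                              Ix[i, j + 1] - extend)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                              Iy[i + 1, j] - extend)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

blosum62_test_matrix <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  mat <- env$BLOSUM62
  mat["X", ] <- 0L
  mat[, "X"] <- 0L
  mat
}

random_aa_seq <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# --- brute-force TM objective oracle ------------------------------------
# Dense multi-start optimization of the TM objective over rigid motions;
# independent of the fragment-seeded search in the package.
oracle_tm <- function(ref_ca, mod_ca, l_ref) {
  d0 <- max(if (l_ref > 15) 1.24 * (l_ref - 15)^(1 / 3) - 1.8 else 0.5, 0.5)
  obj <- function(p) {
    th <- sqrt(sum(p[1:3]^2))
    R <- if (th < 1e-12) diag(3) else {
      k <- p[1:3] / th
      K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
      diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
    }
    fitted <- mod_ca %*% t(R)
    fitted <- sweep(fitted, 2, -p[4:6])
    d2 <- rowSums((fitted - ref_ca)^2)
    -sum(1 / (1 + d2 / d0^2)) / l_ref
  }
  best <- Inf
  for (k in 1:150) {
    ax <- stats::rnorm(3)
    ax <- ax / sqrt(sum(ax^2)) * stats::runif(1, 0, pi)
    t0 <- colMeans(ref_ca) - colMeans(mod_ca) + stats::rnorm(3, 0, 1)
    o <- stats::optim(c(ax, t0), obj, method = "Nelder-Mead",
                      control = list(maxit = 800, reltol = 1e-12))
    if (o$value < best) best <- o$value
  }
  -best
}

# numeric minimizer oracle for the optimal-superposition RMSD
oracle_min_rmsd <- function(ref, mov) {
  obj <- function(p) {
    th <- sqrt(sum(p[1:3]^2))
    R <- if (th < 1e-12) diag(3) else {
      k <- p[1:3] / th
      K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
      diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
    }
    fitted <- sweep(mov %*% t(R), 2, -p[4:6])
    sqrt(mean(rowSums((fitted - ref)^2)))
  }
  best <- Inf
  for (k in 1:60) {
    p0 <- c(stats::rnorm(3, 0, 1), colMeans(ref) - colMeans(mov))
    o <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 1000, reltol = 1e-14))
    if (o$value < best) best <- o$value
  }
  best
}

# minimal hand-written PDB fixture text
minimal_pdb_lines <- function() {
  c("ATOM      1  N   ALA A   1      -0.525   1.363   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       1.525   0.000   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       2.153   0.530   0.920  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1      -0.526  -0.774  -1.209  1.00  0.00           C",
    "TER", "END")
}
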