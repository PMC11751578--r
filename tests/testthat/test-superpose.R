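# Kabsch superposition, rectified C-alpha RMSD, TM-score, all-atom RMSD.

test_that("kabsch exactly recovers rigid copies with a proper rotation", {
  s <- fx_helix(12)
  ref <- coords(s)
  set.seed(3)
  R <- random_rotation_matrix(); tr <- c(5, -2, 1)
  mov <- sweep(ref %*% t(R), 2, -tr)
  sup <- kabsch(ref, mov)
  expect_lt(sup$rmsd, 1e-9)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
})

test_that("reflections are disallowed: mirrored chiral sets keep rmsd > 0", {
  set.seed(8)
  ref <- matrix(rnorm(12), 4, 3)
  mir <- ref %*% diag(c(-1, 1, 1))
  sup <- kabsch(ref, mir)
  expect_gt(sup$rmsd, 0.05)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
  # an unconstrained numeric minimizer over proper rotations agrees
  set.seed(9)
  expect_equal(sup$rmsd, oracle_min_rmsd(ref, mir), tolerance = 1e-6)
})

test_that("kabsch minimum matches a numeric minimizer on a 3-point toy", {
  ref <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  mov <- rbind(c(0, 0, 0), c(1.1, 0, 0), c(0, 1, 0))
  sup <- kabsch(ref, mov)
  set.seed(1)
  expect_equal(sup$rmsd, oracle_min_rmsd(ref, mov), tolerance = 1e-6)
})

test_that("kabsch validates its inputs", {
  expect_error(kabsch(matrix(0, 4, 3), matrix(0, 5, 3)), "differ in length")
  expect_error(kabsch(matrix(0, 2, 3), matrix(0, 2, 3)), "underdetermined")
})

test_that("alpha-RMSD is zero on identity, capped, and monotone in the cap", {
  s <- fx_globule(100, 1)
  n <- nrow(residue_table(s))
  m <- identity_mapping(n)
  expect_equal(alpha_rmsd(s, s, m), 0)
  # displace one residue far away: rectification caps its contribution
  mod <- tibble::as_tibble(s)
  sel <- atom_res_idx(s) == 50
  mod$x[sel] <- mod$x[sel] + 100
  mod <- new_structure(mod)
  capped <- alpha_rmsd(s, mod, m, cap = 5)
  # accounting identity against a direct recomputation from the Kabsch fit
  ca_r <- coords(s[s$atom == "CA", ])
  ca_m <- coords(mod[mod$atom == "CA", ])
  sup <- kabsch(ca_r, ca_m)
  fitted <- sweep(ca_m %*% t(sup$rotation), 2, -sup$translation)
  d <- sqrt(rowSums((fitted - ca_r)^2))
  expect_equal(capped, sqrt(mean(pmin(d, 5)^2)), tolerance = 1e-9)
  expect_lte(capped, 5)
  plain_ca <- alpha_rmsd(s, mod, m, cap = Inf)
  expect_gt(plain_ca, capped)
  caps <- c(1, 2, 5, 10, Inf)
  vals <- vapply(caps, function(cc) alpha_rmsd(s, mod, m, cap = cc), 0)
  expect_true(all(diff(vals) >= -1e-12))
})

test_that("uncapped alpha-RMSD equals the plain Kabsch CA RMSD", {
  s <- fx_globule(100, 1)
  p <- gaussian_noise(s, 0.8, seed = 2)
  m <- identity_mapping(nrow(residue_table(s)))
  ca_r <- coords(s[s$atom == "CA", ])
  ca_m <- coords(p[p$atom == "CA", ])
  expect_equal(alpha_rmsd(s, p, m, cap = Inf), kabsch(ca_r, ca_m)$rmsd,
               tolerance = 1e-9)
})

test_that("TM-score is 1 on identity and d0-distance pairs score 0.5", {
  s <- fx_globule(100, 1)
  m <- identity_mapping(100)
  expect_equal(as.numeric(tm_score(s, s, m)), 1, tolerance = 1e-9)
  expect_equal(tm_d0(100), 1.24 * 85^(1 / 3) - 1.8)
  expect_equal(tm_d0(10), 0.5)
  # all CA displaced by exactly d0 along x in a fixed frame: per-pair 0.5
  d0 <- tm_d0(100)
  mod <- tibble::as_tibble(s)
  mod$x <- mod$x + d0
  sc <- tm_score(s, new_structure(mod), m)
  # the search must find at least the obvious superposition of score 1
  expect_gte(as.numeric(sc), 0.999)
  # without re-superposition the displaced frame scores exactly 0.5:
  ca <- coords(s[s$atom == "CA", ])
  shifted <- sweep(ca, 2, c(-d0, 0, 0))
  terms <- 1 / (1 + rowSums((shifted - ca)^2) / d0^2)
  expect_equal(mean(terms), 0.5, tolerance = 1e-12)
})

test_that("TM-score matches a brute-force objective oracle on small toys", {
  set.seed(14)
  for (k in 1:3) {
    toy <- make_backbone(8, "mixed", seed = k)
    pert <- gaussian_noise(toy, 0.6, seed = 100 + k)
    m <- identity_mapping(8)
    mine <- as.numeric(tm_score(toy, pert, m))
    ora <- oracle_tm(coords(toy[toy$atom == "CA", ]),
                     coords(pert[pert$atom == "CA", ]), 8)
    expect_equal(mine, ora, tolerance = 1e-3)
  }
})

test_that("the TM search never loses to the single full-mapping Kabsch fit", {
  set.seed(2)
  for (k in 1:4) {
    s <- fx_globule(100, 1)
    p <- gaussian_noise(s, k, seed = 30 + k)
    m <- identity_mapping(100)
    ca_r <- coords(s[s$atom == "CA", ])
    ca_m <- coords(p[p$atom == "CA", ])
    sup <- kabsch(ca_r, ca_m)
    fitted <- sweep(ca_m %*% t(sup$rotation), 2, -sup$translation)
    d0 <- tm_d0(100)
    kab_tm <- mean(1 / (1 + rowSums((fitted - ca_r)^2) / d0^2))
    expect_gte(as.numeric(tm_score(s, p, m)) + 1e-9, kab_tm)
  }
})

test_that("TM-score and alpha-RMSD are rigid-motion invariant", {
  s <- fx_globule(100, 1)
  p <- gaussian_noise(s, 1, seed = 5)
  m <- identity_mapping(100)
  tm0 <- as.numeric(tm_score(s, p, m))
  ar0 <- alpha_rmsd(s, p, m)
  set.seed(77)
  R <- random_rotation_matrix(); tr <- rnorm(3, 0, 20)
  p2 <- rigid_move(p, R, tr)
  expect_equal(as.numeric(tm_score(s, p2, m)), tm0, tolerance = 1e-6)
  expect_equal(alpha_rmsd(s, p2, m), ar0, tolerance = 1e-6)
})

test_that("TM-score requires at least 5 mapped pairs", {
  s <- fx_helix(4)
  expect_error(tm_score(s, s, identity_mapping(4)), "fewer than 5")
})

test_that("all-atom RMSD pairs by name, fits on backbone, counts skips", {
  s <- fx_helix(20)
  m <- identity_mapping(20)
  expect_equal(as.numeric(all_atom_rmsd(s, s, m)), 0, tolerance = 1e-9)
  # translate every side-chain atom +1 A along x; backbone fit unaffected
  mod <- tibble::as_tibble(s)
  side <- !(mod$atom %in% c("N", "CA", "C", "O"))
  mod$x[side] <- mod$x[side] + 1
  r <- all_atom_rmsd(s, new_structure(mod), m, "sidechain")
  expect_equal(as.numeric(r), 1, tolerance = 1e-9)
  expect_equal(attr(r, "n_skipped"), 0L)
  # removing atoms from the model counts them as skipped
  stripped <- new_structure(mod[!(mod$atom %in% c("OG", "OG1", "SG")), ])
  r2 <- all_atom_rmsd(s, stripped, m, "all")
  expect_equal(attr(r2, "n_skipped"),
               sum(s$atom %in% c("OG", "OG1", "SG")))
})
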