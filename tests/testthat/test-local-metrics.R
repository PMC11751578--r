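# lDDT, stereochemistry check, chi angles / MAE, burial.

test_that("lDDT is 1 on identity, globally and per residue", {
  s <- fx_globule(100, 1)
  r <- lddt(s, s, identity_mapping(100))
  expect_equal(r$global, 1)
  expect_true(all(r$per_residue$lddt[r$per_residue$n_pairs > 0] == 1))
  expect_true(r$global >= 0 && r$global <= 1)
})

test_that("a uniform 3 A distance error scores exactly 0.25", {
  # two single-atom residues: one candidate pair with |dm - dr| = 3
  mk <- function(d) new_structure(tibble::tibble(
    chain = "A", resno = 1:2, resname = "GLY", atom = "CA",
    x = c(0, d), y = 0, z = 0))
  r <- lddt(mk(5), mk(8), identity_mapping(2))
  expect_equal(r$global, 0.25)
  expect_equal(r$n_pairs, 1L)
  # and a 0.7 A error passes 1, 2 and 4 A thresholds: 0.75
  expect_equal(lddt(mk(5), mk(5.7), identity_mapping(2))$global, 0.75)
})

test_that("lDDT is superposition-free: rigid motions change nothing", {
  s <- fx_globule(100, 1)
  p <- gaussian_noise(s, 1, seed = 3)
  m <- identity_mapping(100)
  base <- lddt(s, p, m)
  set.seed(13)
  R <- random_rotation_matrix(); tr <- rnorm(3, 0, 30)
  moved <- rigid_move(p, R, tr)
  r2 <- lddt(s, moved, m)
  expect_lt(abs(r2$global - base$global), 1e-9)
  expect_lt(max(abs(r2$per_residue$lddt - base$per_residue$lddt),
                na.rm = TRUE), 1e-9)
})

test_that("global lDDT decreases monotonically with noise level", {
  s <- fx_mixed_allatom(100, 3)
  m <- identity_mapping(100)
  sigmas <- c(0, 0.5, 1, 2, 4)
  means <- vapply(sigmas, function(sg) {
    mean(vapply(1:10, function(rep) {
      lddt(s, gaussian_noise(s, sg, seed = 1000 * sg + rep), m)$global
    }, 0))
  }, 0)
  expect_equal(means[1], 1)
  expect_true(all(diff(means) < 0))
})

test_that("sigma = 1 noise reproduces the analytic large-separation lDDT", {
  s <- fx_mixed_allatom(150, 5)
  p <- gaussian_noise(s, 1, seed = 21)
  analytic <- mean(pnorm(c(0.5, 1, 2, 4) / sqrt(2)) -
                     pnorm(-c(0.5, 1, 2, 4) / sqrt(2)))
  r <- lddt(s, p, identity_mapping(150))
  expect_lt(abs(r$global - analytic), 0.02)
})

test_that("missing model atoms count as non-conserved", {
  s <- fx_helix(20)
  m <- identity_mapping(20)
  bbonly <- new_structure(tibble::as_tibble(
    s[s$atom %in% c("N", "CA", "C", "O"), ]))
  full <- lddt(s, s, m)$global
  partial <- lddt(s, bbonly, m)$global
  expect_lt(partial, full)
  # with side chains excluded from the reference too, the score recovers
  bb_ref <- lddt(s, bbonly, m, include_sidechains = FALSE)$global
  expect_equal(bb_ref, 1)
})

test_that("terminal-symmetry naming is resolved in the model's favor", {
  s <- fx_helix(20)
  m <- identity_mapping(20)
  # swap OD1/OD2 on every ASP in the model: chemically the same structure
  mod <- tibble::as_tibble(s)
  asp <- mod$resname == "ASP"
  od1 <- asp & mod$atom == "OD1"; od2 <- asp & mod$atom == "OD2"
  mod$atom[od1] <- "OD2"; mod$atom[od2] <- "OD1"
  mod <- new_structure(mod)
  with_sym <- lddt(s, mod, m, symmetry_resolution = TRUE)$global
  without <- lddt(s, mod, m, symmetry_resolution = FALSE)$global
  expect_equal(with_sym, 1)
  expect_lt(without, 1)
})

test_that("stereochemistry checks flag engineered defects precisely", {
  s <- fx_helix(20)
  expect_equal(nrow(stereochemistry_check(s)), 0L)
  # stretch one CA-C bond to 2.5 A
  mod <- tibble::as_tibble(s)
  r5 <- atom_res_idx(s) == 5
  crow <- r5 & mod$atom == "C"
  carow <- r5 & mod$atom == "CA"
  dir <- unlist(mod[crow, c("x", "y", "z")]) - unlist(mod[carow, c("x", "y", "z")])
  dir <- dir / sqrt(sum(dir^2))
  shift <- (2.5 - 1.525) * dir
  mod$x[crow] <- mod$x[crow] + shift[1]
  mod$y[crow] <- mod$y[crow] + shift[2]
  mod$z[crow] <- mod$z[crow] + shift[3]
  v <- stereochemistry_check(new_structure(mod))
  expect_true(5L %in% v$res_idx)
  expect_true(any(v$type == "bond" & v$detail == "CA-C" & v$res_idx == 5))
})

test_that("sigma = 1 noise leaves a majority of residues flagged", {
  s <- fx_mixed_allatom(100, 3)
  p <- gaussian_noise(s, 1, seed = 8)
  v <- stereochemistry_check(p)
  expect_gt(length(unique(v$res_idx)) / 100, 0.5)
})

test_that("stereo-gated lDDT drops flagged side chains from the model", {
  s <- fx_helix(30)
  m <- identity_mapping(30)
  # corrupt one side chain badly (bond geometry) but keep global distances
  mod <- tibble::as_tibble(s)
  leu_cd1 <- mod$resname == "LEU" & mod$atom == "CD1"
  mod$x[leu_cd1] <- mod$x[leu_cd1] + 3
  mod <- new_structure(mod)
  gated <- lddt(s, mod, m, stereo_checks = TRUE)$global
  ungated <- lddt(s, mod, m, stereo_checks = FALSE)$global
  expect_false(isTRUE(all.equal(gated, ungated)))
})

test_that("chi angles follow their definitions and truncate when atoms vanish", {
  s <- fx_helix(25)
  ridx <- atom_res_idx(s)
  ala <- s[ridx == 1, ]
  expect_length(chi_angles(ala), 0)          # ALA: no chi
  gly <- s[s$resname == "GLY", ]
  expect_length(chi_angles(gly), 0)
  lys <- s[s$resname == "LYS", ]
  expect_length(chi_angles(lys), 4)
  # removing CG truncates LYS at chi1
  lys2 <- lys[lys$atom != "CG", ]
  expect_length(chi_angles(lys2), 0)
  # removing CD truncates after chi1
  lys3 <- lys[lys$atom != "CD", ]
  expect_length(chi_angles(lys3), 1)
})

test_that("chi-MAE wraps, averages per index, and honors ring symmetry", {
  s <- fx_helix(40)
  m <- identity_mapping(40)
  r <- chi_mae(s, s, m)
  expect_equal(r$overall, 0)
  expect_true(all(r$per_chi$mae == 0))
  # shift every chi1 by +10 degrees
  shift_list <- list()
  for (rn in c("SER","CYS","THR","VAL","ILE","LEU","MET","ASP","ASN",
               "GLU","GLN","LYS","ARG","HIS","PHE","TYR","TRP","PRO")) {
    v <- templateprobe:::IDEAL_CHI[[rn]]
    v[1] <- v[1] + 10
    shift_list[[rn]] <- v
  }
  mod <- suppressMessages(attach_sidechains(make_backbone(40, "helix"),
                                            chi = shift_list))
  r2 <- chi_mae(s, mod, m)
  expect_equal(r2$per_chi$mae[r2$per_chi$chi == 1], 10, tolerance = 1e-6)
  expect_lt(max(r2$per_chi$mae[r2$per_chi$chi > 1]), 1e-6)
  # PHE chi2 flipped by 180 degrees contributes zero (ring symmetry)
  phe_flip <- list(PHE = templateprobe:::IDEAL_CHI$PHE + c(0, 180))
  mod2 <- suppressMessages(attach_sidechains(make_backbone(40, "helix"),
                                             chi = phe_flip))
  r3 <- chi_mae(s, mod2, m)
  expect_lt(r3$overall, 1e-6)
  # adding 360 to stored angles changes nothing
  tyr_wrap <- list(TYR = templateprobe:::IDEAL_CHI$TYR + c(360, 0))
  mod3 <- suppressMessages(attach_sidechains(make_backbone(40, "helix"),
                                             chi = tyr_wrap))
  expect_lt(chi_mae(s, mod3, m)$overall, 1e-6)
})

test_that("asparagine amide flips are NOT treated as symmetric", {
  s <- fx_helix(40)
  asn_flip <- list(ASN = templateprobe:::IDEAL_CHI$ASN + c(0, 180))
  mod <- suppressMessages(attach_sidechains(make_backbone(40, "helix"),
                                            chi = asn_flip))
  r <- chi_mae(s, mod, identity_mapping(40))
  expect_gt(r$per_chi$mae[r$per_chi$chi == 2], 10)
})

test_that("burial counts neighbors and orders interior above surface", {
  s <- fx_strand(20)
  b <- burial(s)
  expect_equal(nrow(b), 20L)
  # extended strand: terminal residues are least buried
  expect_equal(min(b$burial), min(b$burial[c(1, 20)]))
  g <- fx_globule(150, 2)
  bg <- burial(g)
  ca <- coords(g[g$atom == "CA", ])
  cen <- colMeans(ca)
  dist_cen <- sqrt(rowSums(sweep(ca, 2, cen)^2))
  interior <- bg$burial[dist_cen <= quantile(dist_cen, 0.2)]
  surface <- bg$burial[dist_cen >= quantile(dist_cen, 0.8)]
  expect_gte(min(interior), median(surface))
  # single-residue structure has zero burial
  one <- new_structure(tibble::tibble(chain = "A", resno = 1,
                                      resname = "GLY", atom = "CA",
                                      x = 0, y = 0, z = 0))
  expect_equal(burial(one)$burial, 0L)
})
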