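# Template perturbations: Gaussian noise, PCA projection, side-chain
# stripping, glycine-CB templates, hit filtering.

test_that("zero-sigma noise is the identity and seeds reproduce draws", {
  s <- fx_helix(10)
  expect_identical(coords(gaussian_noise(s, 0, seed = 1)), coords(s))
  a <- gaussian_noise(s, 1, seed = 7)
  b <- gaussian_noise(s, 1, seed = 7)
  expect_identical(coords(a), coords(b))
  expect_false(identical(coords(a), coords(gaussian_noise(s, 1, seed = 8))))
})

test_that("noise displacement statistics match sigma at large atom counts", {
  big <- cached("bigchain", suppressMessages(
    attach_sidechains(make_backbone(1300, "helix"))))
  expect_gte(nrow(big), 1e4)
  p <- gaussian_noise(big, 1, seed = 11)
  delta <- coords(p) - coords(big)
  # unsuperposed all-atom RMSD converges to sqrt(3) * sigma
  rmsd <- sqrt(mean(rowSums(delta^2)))
  expect_lt(abs(rmsd - sqrt(3)) / sqrt(3), 0.02)
  # per-component variance converges to sigma^2
  expect_lt(abs(var(as.vector(delta)) - 1), 0.05)
})

test_that("perturbations preserve residue count, order and chains", {
  s <- fx_helix(20)
  rt <- residue_table(s)
  for (out in list(gaussian_noise(s, 1, seed = 1), pca_project(s, 2),
                   suppressMessages(strip_sidechains(s, "heuristic")),
                   glycine_cb_template(s))) {
    rt2 <- residue_table(out)
    expect_equal(rt2$resno, rt$resno)
    expect_equal(rt2$chain, rt$chain)
  }
})

test_that("PCA projection yields exact low-rank coordinates", {
  s <- fx_globule(100, 1)
  p2 <- pca_project(s, 2)
  Xc <- sweep(coords(p2), 2, colMeans(coords(p2)))
  sv <- svd(Xc)$d
  expect_lt(sv[3], 1e-8 * sv[1])
  p1 <- pca_project(s, 1)
  Xc1 <- sweep(coords(p1), 2, colMeans(coords(p1)))
  expect_lt(svd(Xc1)$d[2], 1e-8 * svd(Xc1)$d[1])
  # planar input is a fixed point of the 2-component projection
  p2b <- pca_project(p2, 2)
  expect_lt(max(abs(coords(p2b) - coords(p2))), 1e-6)
})

test_that("1-PC projection captures exactly the leading eigenvalue variance", {
  s <- fx_helix(40)
  X <- coords(s)
  ev <- eigen(cov(X), symmetric = TRUE)$values
  p1 <- pca_project(s, 1)
  captured <- sum(diag(cov(coords(p1)))) / sum(ev)
  expect_equal(captured, ev[1] / sum(ev), tolerance = 1e-9)
  # projected points are collinear
  Xc <- sweep(coords(p1), 2, colMeans(coords(p1)))
  expect_lt(svd(Xc)$d[2], 1e-8 * svd(Xc)$d[1])
})

test_that("side-chain stripping implements all four C-beta policies", {
  s <- fx_helix(20)
  ab <- strip_sidechains(s, "absent")
  expect_setequal(unique(ab$atom), c("N", "CA", "C", "O"))
  or <- strip_sidechains(s, "origin")
  cb <- or[or$atom == "CB", ]
  expect_equal(nrow(cb), nrow(residue_table(s)))  # glycine included
  expect_true(all(cb$x == 0.1 & cb$y == 0.1 & cb$z == 0.1))
  he <- strip_sidechains(s, "heuristic")
  expect_equal(sum(he$atom == "CB"), nrow(residue_table(s)))
  tm <- strip_sidechains(s, "template")
  # original CB positions kept bitwise; glycine has none to copy
  orig_cb <- s[s$atom == "CB", ]
  kept_cb <- tm[tm$atom == "CB", ]
  expect_equal(nrow(kept_cb), nrow(orig_cb))
  expect_identical(coords(kept_cb), coords(orig_cb))
  expect_false("CB" %in% tm$atom[tm$resname == "GLY"])
})

test_that("the heuristic C-beta has tetrahedral geometry and is equivariant", {
  n <- c(-0.525, 1.363, 0); ca <- c(0, 0, 0); c_ <- c(1.526, 0, 0)
  cb <- heuristic_cbeta(n, ca, c_)
  expect_lt(abs(sqrt(sum((cb - ca)^2)) - 1.53), 0.02)
  ang <- acos(sum((n - ca) * (cb - ca)) /
                (sqrt(sum((n - ca)^2)) * sqrt(sum((cb - ca)^2)))) * 180 / pi
  expect_lt(abs(ang - 110), 2)
  set.seed(42)
  for (k in 1:5) {
    R <- random_rotation_matrix(); t <- rnorm(3, 0, 10)
    cb2 <- heuristic_cbeta(R %*% n + t, R %*% ca + t, R %*% c_ + t)
    expect_lt(max(abs(cb2 - (R %*% cb + t))), 1e-9)
  }
  expect_error(heuristic_cbeta(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), "collinear")
})

test_that("the heuristic C-beta reproduces ideal C-beta positions", {
  s <- fx_helix(40)
  ridx <- atom_res_idx(s)
  for (r in residue_table(s)$res_idx) {
    at <- s[ridx == r, ]
    if (!"CB" %in% at$atom || at$resname[1] == "PRO") next
    hcb <- heuristic_cbeta(unlist(at[at$atom == "N", c("x", "y", "z")]),
                           unlist(at[at$atom == "CA", c("x", "y", "z")]),
                           unlist(at[at$atom == "C", c("x", "y", "z")]))
    icb <- unlist(at[at$atom == "CB", c("x", "y", "z")])
    expect_lt(sqrt(sum((hcb - icb)^2)), 0.1)
  }
})

test_that("glycine-CB templates erase identity but not geometry", {
  s <- fx_helix(15)
  g <- glycine_cb_template(s)
  expect_true(all(g$resname == "GLY"))
  expect_equal(as.integer(table(atom_res_idx(g))), rep(5L, 15))
  expect_equal(extract_sequence(g)$sequence, strrep("G", 15))
  # backbone coordinates bitwise unchanged
  for (a in c("N", "CA", "C", "O")) {
    expect_identical(coords(g[g$atom == a, ]), coords(s[s$atom == a, ]))
  }
  # idempotent
  g2 <- glycine_cb_template(g)
  expect_identical(tibble::as_tibble(g2), tibble::as_tibble(g))
})

test_that("hit filtering applies the identity window and coverage floor", {
  hits <- tibble::tibble(
    qseqid = c("q1", "q1", "q1", "q2", "q3", "q3"),
    sseqid = c("tA", "tB", "tC", "tD", "tE", "tF"),
    pident = c(50, 75, 50, 45, 60, 60),
    alnlen = 90, mismatch = 0, gapopen = 0,
    qstart = c(1, 1, 1, 1, 1, 1),
    qend = c(90, 90, 79, 85, 90, 90),
    sstart = 1, send = 90,
    evalue = c(1e-30, 1e-50, 1e-40, 1e-10, 1e-20, 1e-25),
    bits = 200, qlen = 100
  )
  kept <- filter_template_hits(hits)
  # q1: 75% identity rejected, 79% coverage rejected -> tA survives
  expect_equal(kept$sseqid[kept$qseqid == "q1"], "tA")
  # q2: pident 45, coverage 0.85 -> kept
  expect_true("q2" %in% kept$qseqid)
  # q3: best e-value wins among equal-identity survivors
  expect_equal(kept$sseqid[kept$qseqid == "q3"], "tF")
  expect_lte(nrow(kept), length(unique(hits$qseqid)))
  # deterministic subset of the input
  expect_identical(kept, filter_template_hits(hits))
  expect_true(all(kept$sseqid %in% hits$sseqid))
})

test_that("hit tables read from disk and take qlen from a companion source", {
  f <- withr::local_tempfile(fileext = ".m8")
  writeLines(c(
    "q1\tt1\t55.0\t90\t40\t1\t1\t90\t5\t94\t1e-30\t200",
    "q1\tt2\t95.0\t90\t40\t1\t1\t90\t5\t94\t1e-60\t300"), f)
  hits <- read_hits_m8(f)
  expect_equal(nrow(hits), 2L)
  expect_error(filter_template_hits(hits), "qlen")
  kept <- filter_template_hits(hits, qlen = c(q1 = 100))
  expect_equal(kept$sseqid, "t1")
  expect_warning(filter_template_hits(hits, qlen = c(zz = 10)), "unknown length")
})
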