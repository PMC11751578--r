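# Synthetic all-atom structure generator. Backbones are built by
# internal-coordinate chain extension with ideal bond lengths and angles;
# side chains are placed from ideal internal coordinates at chosen chi
# angles. A biased, confined self-avoiding growth yields compact globular
# chains so that superposition-based metrics behave as on real folds.

DEFAULT_SEQ_CYCLE <- "ACDEFGHIKLMNPQRSTVWY"

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

preset_torsions <- function(length, preset, seed = NULL) {
  switch(preset,
    helix = data.frame(phi = rep(-57, length), psi = rep(-47, length),
                       omega = rep(180, length)),
    strand = data.frame(phi = rep(-120, length), psi = rep(120, length),
                        omega = rep(180, length)),
    coil = with_seed(seed, {
      basins <- matrix(c(-70, 140, -60, -45, -120, 130, -90, 0),
                       ncol = 2, byrow = TRUE)
      pick <- sample.int(nrow(basins), length, replace = TRUE)
      data.frame(phi = basins[pick, 1] + stats::rnorm(length, 0, 10),
                 psi = basins[pick, 2] + stats::rnorm(length, 0, 10),
                 omega = rep(180, length))
    }),
    mixed = with_seed(seed, {
      phi <- numeric(0); psi <- numeric(0)
      kinds <- c("helix", "strand", "coil")
      k <- 1L
      while (length(phi) < length) {
        kind <- kinds[(k - 1L) %% 3L + 1L]
        n <- switch(kind, helix = sample(8:15, 1), strand = sample(5:10, 1),
                    coil = sample(3:6, 1))
        tp <- switch(kind,
          helix = cbind(rep(-57, n), rep(-47, n)),
          strand = cbind(rep(-120, n), rep(120, n)),
          coil = {
            basins <- matrix(c(-70, 140, -60, -45, -90, 0),
                             ncol = 2, byrow = TRUE)
            pick <- sample.int(nrow(basins), n, replace = TRUE)
            cbind(basins[pick, 1] + stats::rnorm(n, 0, 10),
                  basins[pick, 2] + stats::rnorm(n, 0, 10))
          })
        phi <- c(phi, tp[, 1]); psi <- c(psi, tp[, 2])
        k <- k + 1L
      }
      data.frame(phi = phi[seq_len(length)], psi = psi[seq_len(length)],
                 omega = rep(180, length))
    }),
    stop("unknown torsion preset: ", preset, call. = FALSE)
  )
}

# Backbone N/CA/C coordinates from per-residue (phi, psi, omega).
# Returns a list of L x 3 matrices.
backbone_from_torsions <- function(phi, psi, omega = rep(180, length(phi))) {
  L <- length(phi)
  g <- BB_GEOM
  N <- CA <- C <- matrix(NA_real_, L, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  ang <- (180 - g$a_n_ca_c) * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(cos(ang), sin(ang), 0)
  for (i in seq_len(L - 1)) {
    N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ], g$b_c_n, g$a_ca_c_n, psi[i])
    CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ], g$b_n_ca, g$a_c_n_ca, omega[i])
    C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], g$b_ca_c, g$a_n_ca_c, phi[i + 1])
  }
  list(N = N, CA = CA, C = C)
}

# Carbonyl O for every residue: anti to the next N in the sp2 plane, i.e.
# dihedral N-CA-C-O = psi + 180.
backbone_oxygens <- function(bb, psi) {
  L <- nrow(bb$N)
  O <- matrix(NA_real_, L, 3)
  for (i in seq_len(L)) {
    O[i, ] <- place_atom(bb$N[i, ], bb$CA[i, ], bb$C[i, ],
                         BB_GEOM$b_c_o, BB_GEOM$a_ca_c_o, psi[i] + 180)
  }
  O
}

default_sequence <- function(length) {
  letters1 <- strsplit(DEFAULT_SEQ_CYCLE, "")[[1]]
  unname(AA3_FROM_1[rep_len(letters1, length)])
}

backbone_tibble <- function(bb, O, resnames, source) {
  L <- nrow(bb$N)
  rows <- vector("list", L)
  for (i in seq_len(L)) {
    xyz <- rbind(bb$N[i, ], bb$CA[i, ], bb$C[i, ], O[i, ])
    rows[[i]] <- data.frame(
      chain = "A", resno = i, resname = resnames[i],
      atom = c("N", "CA", "C", "O"),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      stringsAsFactors = FALSE
    )
  }
  new_structure(do.call(rbind, rows), source = source)
}

#' Generate an idealized backbone
#'
#' Builds an N-CA-C-O backbone by internal-coordinate chain extension with
#' ideal bond lengths (N-CA 1.458, CA-C 1.525, C-N 1.329, C-O 1.231
#' Angstrom) and ideal angles. Torsions come from a named preset
#' (`helix`: phi = -57, psi = -47; `strand`: phi = -120, psi = +120;
#' `coil`/`mixed`: seeded sampling from allowed basins; omega = 180
#' throughout) or an explicit per-residue data frame with columns
#' `phi`, `psi` and optionally `omega`.
#'
#' @param length residue count (at least 3).
#' @param torsions preset name (`"helix"`, `"strand"`, `"coil"`, `"mixed"`)
#'   or a data frame of per-residue torsions in degrees.
#' @param sequence optional 1-letter sequence string; defaults to a
#'   repeating cycle over all 20 amino acids so every residue type is
#'   exercised.
#' @param seed RNG seed for the sampled presets; the generator is a pure
#'   function of its arguments.
#' @return A `struct_tbl` backbone (no side chains).
#' @export
make_backbone <- function(length, torsions = "helix", sequence = NULL,
                          seed = NULL) {
  if (length < 3) stop("backbone length must be at least 3", call. = FALSE)
  if (is.character(torsions)) {
    torsions <- preset_torsions(length, match.arg(torsions,
      c("helix", "strand", "coil", "mixed")), seed = seed)
  }
  stopifnot(nrow(torsions) == length)
  if (is.null(torsions$omega)) torsions$omega <- rep(180, length)
  bb <- backbone_from_torsions(torsions$phi, torsions$psi, torsions$omega)
  O <- backbone_oxygens(bb, torsions$psi)
  resnames <- if (is.null(sequence)) default_sequence(length)
              else unname(AA3_FROM_1[strsplit(sequence, "")[[1]]])
  stopifnot(length(resnames) == length, !anyNA(resnames))
  backbone_tibble(bb, O, resnames, source = sprintf("make_backbone(%d)", length))
}

# chi angles for one residue under a rotamer mode. `overrides` is a named
# list (by residue type) of explicit chi vectors.
chi_for_residue <- function(resname, mode, overrides = NULL) {
  ideal <- IDEAL_CHI[[resname]]
  if (is.null(ideal)) return(numeric(0))
  if (!is.null(overrides) && !is.null(overrides[[resname]])) {
    chis <- overrides[[resname]]
    stopifnot(length(chis) == length(ideal))
    return(chis)
  }
  if (mode == "ideal_single") return(ideal)
  # proline's chi values are ring-closure constraints, not free rotamers
  if (resname == "PRO") return(ideal)
  vapply(seq_along(ideal), function(k) {
    menu <- ROTAMER_LIBRARY[[min(k, length(ROTAMER_LIBRARY))]]
    menu[sample.int(length(menu), 1)]
  }, numeric(1))
}

# Build side-chain heavy atoms (including CB) for one residue from the
# ideal topology at the given chi angles. `bbpos` is a named list with N,
# CA, C coordinates. Returns a matrix with rownames = atom names.
build_sidechain <- function(resname, bbpos, chis) {
  if (resname == "GLY") return(NULL)
  pos <- list(N = bbpos$N, CA = bbpos$CA, C = bbpos$C)
  cbg <- if (resname == "PRO") PRO_CB_GEOM else CB_GEOM
  pos$CB <- place_atom(pos$C, pos$N, pos$CA, cbg$bond, cbg$angle, cbg$torsion)
  tp <- SIDECHAIN_TOPO[[resname]]
  if (!is.null(tp)) {
    for (j in seq_len(nrow(tp))) {
      row <- tp[j, ]
      tors <- if (is.na(row$chi)) row$offset else chis[row$chi] + row$offset
      pos[[row$atom]] <- place_atom(pos[[row$r1]], pos[[row$r2]], pos[[row$r3]],
                                    row$bond, row$angle, tors)
    }
  }
  out <- do.call(rbind, pos[-(1:3)])
  rownames(out) <- names(pos)[-(1:3)]
  out
}

#' Attach ideal side chains to a backbone
#'
#' Every non-glycine residue gains its full heavy-atom side chain built
#' from ideal internal coordinates at the chi angles dictated by the
#' rotamer mode; the C-beta sits at the ideal tetrahedral position.
#' Existing side-chain atoms are rebuilt; backbone atoms are never moved.
#' Residues with incomplete backbones are left backbone-only with a
#' message.
#'
#' @param s structure tibble with complete N/CA/C backbones.
#' @param mode `"ideal_single"` (one fixed chi set per residue type) or
#'   `"random_library"` (seeded draws from a small rotamer menu).
#' @param seed RNG seed for `random_library`.
#' @param chi optional named list (by 3-letter residue type) of explicit
#'   chi vectors overriding the mode.
#' @return A `struct_tbl` with side chains.
#' @export
attach_sidechains <- function(s, mode = c("ideal_single", "random_library"),
                              seed = NULL, chi = NULL) {
  mode <- match.arg(mode)
  with_seed(seed, {
    rt <- residue_table(s)
    ridx <- atom_res_idx(s)
    rows <- vector("list", nrow(rt))
    skipped <- 0L
    for (i in seq_len(nrow(rt))) {
      at <- s[ridx == i, , drop = FALSE]
      bb <- at[at$atom %in% BACKBONE_ATOMS, , drop = FALSE]
      keep <- tibble::as_tibble(bb)
      resname <- rt$resname[i]
      if (!all(c("N", "CA", "C") %in% bb$atom) || !(resname %in% AA3)) {
        skipped <- skipped + 1L
        rows[[i]] <- tibble::as_tibble(at)
        next
      }
      bbpos <- list(N = unlist(bb[bb$atom == "N", c("x", "y", "z")]),
                    CA = unlist(bb[bb$atom == "CA", c("x", "y", "z")]),
                    C = unlist(bb[bb$atom == "C", c("x", "y", "z")]))
      sc <- build_sidechain(resname, bbpos,
                            chi_for_residue(resname, mode, chi))
      if (!is.null(sc)) {
        scrows <- keep[rep(1L, nrow(sc)), , drop = FALSE]
        scrows$atom <- rownames(sc)
        scrows$element <- element_of(rownames(sc))
        scrows$x <- sc[, 1]; scrows$y <- sc[, 2]; scrows$z <- sc[, 3]
        keep <- dplyr::bind_rows(keep, scrows)
      }
      rows[[i]] <- keep
    }
    if (skipped > 0) {
      message(skipped, " residue(s) left backbone-only (incomplete backbone)")
    }
    as_structure(dplyr::bind_rows(rows), s)
  })
}

# Inter-residue heavy-atom pairs closer than `floor_A`, excluding the
# peptide C(i)-N(i+1) bond. Returns a two-column matrix of atom row indices.
clash_pairs <- function(s, floor_A = 1.5) {
  xyz <- coords(s)
  n <- nrow(xyz)
  D <- as.matrix(stats::dist(xyz))
  ridx <- atom_res_idx(s)
  close <- which(D < floor_A & upper.tri(D), arr.ind = TRUE)
  if (nrow(close) == 0) return(close)
  keep <- ridx[close[, 1]] != ridx[close[, 2]]
  close <- close[keep, , drop = FALSE]
  if (nrow(close) == 0) return(close)
  # drop the peptide bond: C of residue r with N of residue r+1, same chain
  a <- close[, 1]; b <- close[, 2]
  pep <- (s$atom[a] == "C" & s$atom[b] == "N" &
            ridx[b] == ridx[a] + 1L & s$chain[a] == s$chain[b]) |
         (s$atom[b] == "C" & s$atom[a] == "N" &
            ridx[a] == ridx[b] + 1L & s$chain[a] == s$chain[b])
  # proline ring atoms reach the preceding carbonyl through the ring
  # nitrogen (1-3 / 1-4 interactions), so those contacts are covalent
  # geometry, not non-bonded clashes
  pro_ring <- (s$resname[b] == "PRO" & s$atom[b] %in% c("CG", "CD") &
                 ridx[a] == ridx[b] - 1L & s$atom[a] %in% c("C", "O") &
                 s$chain[a] == s$chain[b]) |
              (s$resname[a] == "PRO" & s$atom[a] %in% c("CG", "CD") &
                 ridx[b] == ridx[a] - 1L & s$atom[b] %in% c("C", "O") &
                 s$chain[a] == s$chain[b])
  close[!(pep | pro_ring), , drop = FALSE]
}

# Greedy clash repair: re-pick chi angles of clashing residues from a small
# menu; residues that cannot be resolved are truncated to backbone + CB.
repair_clashes <- function(s, floor_A = 1.6, max_pass = 5) {
  for (pass in seq_len(max_pass)) {
    cp <- clash_pairs(s, floor_A)
    if (nrow(cp) == 0) return(s)
    ridx <- atom_res_idx(s)
    bad <- sort(unique(c(ridx[cp[, 1]], ridx[cp[, 2]])))
    rt <- residue_table(s)
    for (i in bad) {
      resname <- rt$resname[i]
      nchi <- length(IDEAL_CHI[[resname]])
      if (resname == "GLY" || nchi == 0) next
      at <- s[ridx == i, , drop = FALSE]
      bb <- at[at$atom %in% BACKBONE_ATOMS, , drop = FALSE]
      if (!all(c("N", "CA", "C") %in% bb$atom)) next
      bbpos <- list(N = unlist(bb[bb$atom == "N", c("x", "y", "z")]),
                    CA = unlist(bb[bb$atom == "CA", c("x", "y", "z")]),
                    C = unlist(bb[bb$atom == "C", c("x", "y", "z")]))
      others <- coords(s[ridx != i, , drop = FALSE])
      cand1 <- c(IDEAL_CHI[[resname]][1], -65, 180, 62, 100, -150)
      cand2 <- if (nchi >= 2) c(IDEAL_CHI[[resname]][2], 180, 65, -90) else 0
      best <- NULL; best_score <- c(Inf, -Inf)
      for (c1 in cand1) for (c2 in cand2) {
        chis <- IDEAL_CHI[[resname]]
        chis[1] <- c1
        if (nchi >= 2) chis[2] <- c2
        sc <- build_sidechain(resname, bbpos, chis)
        dd <- sqrt(pmax(outer(rowSums(sc^2), rowSums(others^2), "+") -
                          2 * sc %*% t(others), 0))
        nclash <- sum(dd < floor_A)
        mind <- min(dd)
        if (nclash < best_score[1] ||
            (nclash == best_score[1] && mind > best_score[2])) {
          best_score <- c(nclash, mind)
          best <- sc
        }
        if (best_score[1] == 0) break
      }
      # replace side-chain rows
      keepbb <- tibble::as_tibble(bb)
      scrows <- keepbb[rep(1L, nrow(best)), , drop = FALSE]
      scrows$atom <- rownames(best)
      scrows$element <- element_of(rownames(best))
      scrows$x <- best[, 1]; scrows$y <- best[, 2]; scrows$z <- best[, 3]
      s <- as_structure(
        dplyr::bind_rows(s[ridx < i, , drop = FALSE], keepbb, scrows,
                         s[ridx > i, , drop = FALSE]), s)
      ridx <- atom_res_idx(s)
    }
  }
  cp <- clash_pairs(s, floor_A)
  if (nrow(cp) > 0) {
    ridx <- atom_res_idx(s)
    bad <- sort(unique(c(ridx[cp[, 1]], ridx[cp[, 2]])))
    message("truncating ", length(bad),
            " residue(s) to backbone + CB after clash repair")
    keep <- !(ridx %in% bad) | s$atom %in% c(BACKBONE_ATOMS, "CB")
    s <- as_structure(s[keep, , drop = FALSE], s)
  }
  s
}

#' Generate a compact globular all-atom chain
#'
#' Grows a self-avoiding backbone in torsion space inside a confining
#' sphere (biased towards compactness), so that the radius of gyration
#' approximately follows the globular scaling 2.2 * length^(1/3) Angstrom,
#' then attaches ideal side chains and greedily resolves severe steric
#' overlaps by re-picking chi angles.
#'
#' @param length residue count (at least 20).
#' @param seed RNG seed; the result is a pure function of
#'   `(length, seed)`.
#' @param max_attempts restart budget for the self-avoiding growth; a
#'   generation error reports the attempt count if exceeded.
#' @return A `struct_tbl` all-atom globule.
#' @export
make_globule <- function(length, seed = 1, max_attempts = 25) {
  if (length < 20) stop("globule length must be at least 20", call. = FALSE)
  with_seed(seed, {
    target_rg <- 2.2 * length^(1 / 3)
    # soft harmonic confinement radius, calibrated so the realized CA
    # radius of gyration lands near the globular scaling target
    r_core <- 1.08 * target_rg
    g <- BB_GEOM
    basins <- matrix(c(-57, -47, -120, 120, -70, 140, -60, -30, -90, 0, 60, 40),
                     ncol = 2, byrow = TRUE)
    n_cand <- 30L
    for (attempt in seq_len(max_attempts)) {
      N <- CA <- C <- matrix(NA_real_, length, 3)
      phi <- psi <- rep(NA_real_, length)
      N[1, ] <- c(0, 0, 0); CA[1, ] <- c(g$b_n_ca, 0, 0)
      ang <- (180 - g$a_n_ca_c) * pi / 180
      C[1, ] <- CA[1, ] + g$b_ca_c * c(cos(ang), sin(ang), 0)
      phi[1] <- -70
      i <- 1L
      fails <- 0L
      ok <- TRUE
      # all backbone heavy atoms placed so far (residues 1..i-1), used to
      # keep non-bonded backbone separations realistic
      bb_seen <- matrix(NA_real_, 5L * length, 3)
      bb_sq <- numeric(5L * length)   # cached squared norms of bb_seen rows
      ca_sq <- numeric(length)        # cached squared norms of CA rows
      ca_sq[1] <- sum(CA[1, ]^2)
      bb_n <- 0L
      push_bb <- function(res) {
        # store residue `res` once its psi (hence O) is known; CB included
        # because its position is fixed by the backbone and cannot be
        # repaired later by chi re-picking
        O_r <- place_atom(N[res, ], CA[res, ], C[res, ],
                          g$b_c_o, g$a_ca_c_o, psi[res] + 180)
        CB_r <- place_atom(C[res, ], N[res, ], CA[res, ],
                           CB_GEOM$bond, CB_GEOM$angle, CB_GEOM$torsion)
        new_rows <- rbind(N[res, ], CA[res, ], C[res, ], O_r, CB_r)
        bb_seen[bb_n + 1:5, ] <<- new_rows
        bb_sq[bb_n + 1:5] <<- rowSums(new_rows^2)
        bb_n <<- bb_n + 5L
      }
      while (i < length) {
        pick <- sample.int(nrow(basins), n_cand, replace = TRUE)
        cand <- cbind(basins[pick, 1] + stats::rnorm(n_cand, 0, 15),
                      basins[pick, 2] + stats::rnorm(n_cand, 0, 15))
        valid <- vector("list", n_cand)
        energy <- rep(NA_real_, n_cand)
        for (k in seq_len(n_cand)) {
          N2 <- place_atom(N[i, ], CA[i, ], C[i, ], g$b_c_n, g$a_ca_c_n, cand[k, 2])
          CA2 <- place_atom(CA[i, ], C[i, ], N2, g$b_n_ca, g$a_c_n_ca, 180)
          C2 <- place_atom(C[i, ], N2, CA2, g$b_ca_c, g$a_n_ca_c, cand[k, 1])
          if (i >= 2) {
            ii <- seq_len(i - 1)
            dd2 <- ca_sq[ii] + sum(CA2^2) -
              2 * drop(CA[ii, , drop = FALSE] %*% CA2)
            if (min(dd2) < 3.55^2) next
            # backbone + CB atoms of residues 1..i-1 (residue i itself is
            # covalently linked) must stay outside contact range; the CB
            # floor is looser (it only needs severe-overlap clearance)
            CB2 <- place_atom(C2, N2, CA2,
                              CB_GEOM$bond, CB_GEOM$angle, CB_GEOM$torsion)
            # the psi candidate also fixes the carbonyl O of residue i
            O1 <- place_atom(N[i, ], CA[i, ], C[i, ],
                             g$b_c_o, g$a_ca_c_o, cand[k, 2] + 180)
            Q <- rbind(N2, CA2, C2, O1, CB2)
            jj <- seq_len(bb_n)
            d2m <- outer(bb_sq[jj], rowSums(Q^2), "+") -
              2 * bb_seen[jj, , drop = FALSE] %*% t(Q)
            if (min(d2m[, 1:3]) < 2.2^2 || min(d2m[, 4:5]) < 1.7^2) next
          }
          # two-step lookahead: the phi candidate only bends the chain one
          # residue later, so confinement must look past the next CA
          N3 <- place_atom(N2, CA2, C2, g$b_c_n, g$a_ca_c_n, -47)
          CA3 <- place_atom(CA2, C2, N3, g$b_n_ca, g$a_c_n_ca, 180)
          valid[[k]] <- list(N2, CA2, C2)
          energy[k] <- 4 * (max(0, vnorm(CA2) - r_core)^2 +
                              max(0, vnorm(CA3) - r_core)^2)
          if (sum(!is.na(energy)) >= 6L) break
        }
        kk <- which(!is.na(energy))
        if (length(kk) > 0) {
          k <- kk[sample.int(length(kk), 1,
                             prob = exp(-(energy[kk] - min(energy[kk]))))]
          psi[i] <- cand[k, 2]; phi[i + 1] <- cand[k, 1]
          N[i + 1, ] <- valid[[k]][[1]]
          CA[i + 1, ] <- valid[[k]][[2]]
          C[i + 1, ] <- valid[[k]][[3]]
          ca_sq[i + 1] <- sum(CA[i + 1, ]^2)
          push_bb(i)
          i <- i + 1L
        } else {
          fails <- fails + 1L
          if (fails > 5L * length) { ok <- FALSE; break }
          back <- min(i - 1L, 4L)
          i <- i - back  # backtrack a few residues and regrow
          bb_n <- max(0L, bb_n - 5L * back)
        }
      }
      if (!ok) next
      # acceptance gate on compactness: the realized CA radius of gyration
      # must track the globular scaling target; otherwise adjust the
      # confinement radius and regrow (still a pure function of the seed)
      rg <- sqrt(mean(rowSums(sweep(CA, 2, colMeans(CA))^2)))
      ratio <- rg / target_rg
      if (ratio > 1.23) { r_core <- r_core * 0.94; next }
      if (ratio < 0.80) { r_core <- r_core * 1.06; next }
      # pick a final-residue psi whose carbonyl O stays clear of the chain
      psi[length] <- -47
      best_d <- -Inf
      for (pcand in c(-47, 120, 180, -30, 60, 0, -120)) {
        O_l <- place_atom(N[length, ], CA[length, ], C[length, ],
                          g$b_c_o, g$a_ca_c_o, pcand + 180)
        dmin <- min(outer(bb_sq[seq_len(bb_n)], sum(O_l^2), "+") -
                      2 * bb_seen[seq_len(bb_n), , drop = FALSE] %*% O_l)
        if (dmin > best_d) { best_d <- dmin; psi[length] <- pcand }
        if (best_d > 2.4^2) break
      }
      bb <- list(N = N, CA = CA, C = C)
      O <- backbone_oxygens(bb, psi)
      s <- backbone_tibble(bb, O, default_sequence(length),
                           source = sprintf("make_globule(%d, seed = %s)",
                                            length, format(seed)))
      s <- attach_sidechains(s, mode = "ideal_single")
      s <- suppressMessages(repair_clashes(s))
      attr(s, "source") <- sprintf("make_globule(%d, seed = %s)", length,
                                   format(seed))
      return(s)
    }
    stop("globule generation failed after ", max_attempts, " attempts",
         call. = FALSE)
  })
}

#' Write a set of synthetic fixtures with a manifest
#'
#' Generates globular all-atom fixtures and writes them as PDB files plus a
#' JSON manifest recording lengths and seeds.
#'
#' @param dir output directory (created if needed).
#' @param lengths integer vector of residue counts.
#' @param seed base RNG seed; fixture i uses `seed + i`.
#' @return Tibble manifest (paths, lengths, seeds), invisibly.
#' @export
write_fixture_set <- function(dir, lengths = c(150, 200, 250), seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- tibble::tibble(
    path = file.path(dir, sprintf("fixture_%03d.pdb", seq_along(lengths))),
    length = as.integer(lengths),
    seed = seed + seq_along(lengths)
  )
  for (i in seq_len(nrow(manifest))) {
    s <- make_globule(manifest$length[i], seed = manifest$seed[i])
    write_structure(s, manifest$path[i], format = "pdb")
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
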