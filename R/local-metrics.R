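# Superposition-free local metrics: the local distance difference test
# (lDDT, global and per-residue), a stereochemistry check with an
# ideal-geometry reference table, side-chain chi angles and their mean
# absolute error, and a neighbor-count burial proxy.

LDDT_THRESHOLDS <- c(0.5, 1, 2, 4)
LDDT_RADIUS <- 15

# fraction of thresholds conserved per candidate pair; missing model atoms
# (NA distances) count as non-conserved at every threshold
pair_fraction <- function(d_ref, d_model, thresholds) {
  dd <- abs(d_model - d_ref)
  out <- numeric(length(d_ref))
  okmask <- !is.na(dd)
  if (any(okmask)) {
    acc <- rep(0, sum(okmask))
    for (t in thresholds) acc <- acc + (dd[okmask] < t)
    out[okmask] <- acc / length(thresholds)
  }
  out
}

#' Local distance difference test (lDDT)
#'
#' Superposition-free model quality in [0, 1]. Candidate pairs are
#' heavy-atom pairs in the *reference* closer than the inclusion radius
#' and belonging to different residues. A pair is conserved at tolerance
#' `t` iff both atoms exist in the model (paired by mapped residue and
#' identical atom name) and the model reproduces the reference distance
#' within `t`; the per-pair score is the fraction of thresholds conserved.
#' The global score averages over all candidate pairs; per-residue scores
#' average over the pairs touching each residue's atoms. Pairs with an
#' atom missing from the model count as non-conserved, penalizing
#' incomplete models.
#'
#' With `symmetry_resolution` (default on), residues whose terminal atoms
#' have ambiguous names (ASP, GLU, PHE, TYR, ARG) may have their model
#' naming swapped, one residue at a time, whichever choice maximizes that
#' residue's score. With `stereo_checks` (default off, since perturbed
#' templates violate stereochemistry wholesale) the side chains of model
#' residues flagged by [stereochemistry_check()] are excluded before
#' scoring.
#'
#' @param ref,model structure tibbles.
#' @param mapping a `residue_mapping` (defaults to [map_residues()]).
#' @param inclusion_radius candidate-pair radius in Angstrom (default 15).
#' @param thresholds ordered positive tolerances in Angstrom (default
#'   0.5, 1, 2, 4).
#' @param include_sidechains use all heavy atoms (default) or backbone
#'   (N, CA, C, O) only.
#' @param stereo_checks exclude side chains of stereochemically invalid
#'   model residues.
#' @param symmetry_resolution resolve ambiguous terminal atom naming.
#' @return An `lddt_result` list: `global` score, `per_residue` tibble
#'   (`res_idx`, `chain`, `resno`, `resname`, `lddt`, `n_pairs`) and
#'   `n_pairs`.
#' @export
lddt <- function(ref, model, mapping = NULL,
                 inclusion_radius = LDDT_RADIUS,
                 thresholds = LDDT_THRESHOLDS,
                 include_sidechains = TRUE,
                 stereo_checks = FALSE,
                 symmetry_resolution = TRUE) {
  stopifnot(all(thresholds > 0), !is.unsorted(thresholds))
  if (is.null(mapping)) mapping <- map_residues(ref, model)
  if (nrow(mapping) == 0) stop("empty residue mapping: lDDT undefined",
                               call. = FALSE)
  if (!include_sidechains) {
    ref <- as_structure(ref[ref$atom %in% BACKBONE_ATOMS, ], ref)
    model <- as_structure(model[model$atom %in% BACKBONE_ATOMS, ], model)
  }
  if (stereo_checks) {
    viol <- stereochemistry_check(model)
    if (nrow(viol) > 0) {
      bad <- unique(viol$res_idx)
      keep <- !(atom_res_idx(model) %in% bad) |
        model$atom %in% BACKBONE_ATOMS
      model <- as_structure(model[keep, ], model)
    }
  }

  rt_ref <- residue_table(ref)
  rref <- atom_res_idx(ref)
  rmod <- atom_res_idx(model)
  map_vec <- rep(NA_integer_, nrow(rt_ref))
  map_vec[mapping$ref_idx] <- mapping$model_idx

  # matched model coordinates per reference atom (NA if absent)
  mod_res_of_ref_atom <- map_vec[rref]
  key_ref <- paste(mod_res_of_ref_atom, ref$atom)
  key_mod <- paste(rmod, model$atom)
  mrow <- match(key_ref, key_mod)
  M <- coords(model)[mrow, , drop = FALSE]
  M[is.na(mrow), ] <- NA_real_

  X <- coords(ref)
  D <- as.matrix(stats::dist(X))
  sel <- which(D < inclusion_radius & upper.tri(D), arr.ind = TRUE)
  diffres <- rref[sel[, 1]] != rref[sel[, 2]]
  pi_ <- sel[diffres, 1]
  pj <- sel[diffres, 2]
  if (length(pi_) == 0) stop("no candidate pairs within the inclusion radius",
                             call. = FALSE)
  d_ref <- D[cbind(pi_, pj)]
  d_model_of <- function(M) sqrt(rowSums((M[pi_, , drop = FALSE] -
                                            M[pj, , drop = FALSE])^2))
  frac <- pair_fraction(d_ref, d_model_of(M), thresholds)

  if (symmetry_resolution) {
    amb <- which(rt_ref$resname %in% names(AMBIGUOUS_ATOM_SWAPS) &
                   !is.na(map_vec))
    for (r in amb) {
      groups <- AMBIGUOUS_ATOM_SWAPS[[rt_ref$resname[r]]]
      ref_rows <- which(rref == r)
      touch <- which(rref[pi_] == r | rref[pj] == r)
      if (length(touch) == 0) next
      M2 <- M
      swapped <- FALSE
      for (g in groups) {
        a1 <- ref_rows[ref$atom[ref_rows] == g[1]]
        a2 <- ref_rows[ref$atom[ref_rows] == g[2]]
        if (length(a1) == 1 && length(a2) == 1 &&
            !anyNA(M[a1, ]) && !anyNA(M[a2, ])) {
          M2[c(a1, a2), ] <- M[c(a2, a1), , drop = FALSE]
          swapped <- TRUE
        }
      }
      if (!swapped) next
      dm_alt <- sqrt(rowSums((M2[pi_[touch], , drop = FALSE] -
                                M2[pj[touch], , drop = FALSE])^2))
      frac_alt <- pair_fraction(d_ref[touch], dm_alt, thresholds)
      if (sum(frac_alt) > sum(frac[touch])) {
        M <- M2
        frac[touch] <- frac_alt
        # pairs touching this residue with both ends elsewhere unaffected
      }
    }
  }

  global <- mean(frac)
  sums <- counts <- numeric(nrow(rt_ref))
  ti <- rref[pi_]; tj <- rref[pj]
  for (side in list(ti, tj)) {
    agg <- rowsum(frac, side)
    cnt <- rowsum(rep(1, length(frac)), side)
    idx <- as.integer(rownames(agg))
    sums[idx] <- sums[idx] + agg[, 1]
    counts[idx] <- counts[idx] + cnt[, 1]
  }
  per_res <- tibble::tibble(
    res_idx = rt_ref$res_idx, chain = rt_ref$chain, resno = rt_ref$resno,
    resname = rt_ref$resname,
    lddt = ifelse(counts > 0, sums / counts, NA_real_),
    n_pairs = as.integer(counts)
  )
  structure(list(global = global, per_residue = per_res,
                 n_pairs = length(frac)),
            class = "lddt_result")
}

#' @export
print.lddt_result <- function(x, ...) {
  cat(sprintf("# lDDT: global %.4f over %d candidate pairs, %d residue(s)\n",
              x$global, x$n_pairs, nrow(x$per_residue)))
  invisible(x)
}

# Ideal-geometry standard deviations used by the stereochemistry check.
STEREO_SIGMA <- list(bond = 0.02, angle = 3.0)

#' Stereochemistry check
#'
#' Flags residues whose bond lengths or bond angles deviate from the ideal
#' reference geometry (the same constant table the synthetic generator
#' builds from) by more than `tolerance_sigmas` standard deviations, and
#' residues involved in non-bonded inter-residue heavy-atom contacts
#' closer than `clash_floor`. Ring-closure bonds are implied by the
#' placement tree and are not checked.
#'
#' @param s structure tibble.
#' @param tolerance_sigmas allowed deviation in standard deviations
#'   (default 4).
#' @param clash_floor inter-residue contact floor in Angstrom (default
#'   1.5); the peptide bond is exempt.
#' @return Tibble of violations (`res_idx`, `chain`, `resno`, `resname`,
#'   `type`, `detail`, `value`, `expected`); zero rows means a clean
#'   structure.
#' @export
stereochemistry_check <- function(s, tolerance_sigmas = 4, clash_floor = 1.5) {
  rt <- residue_table(s)
  ridx <- atom_res_idx(s)
  pos_of <- function(rows, name) {
    i <- rows[s$atom[rows] == name]
    if (length(i) == 1) c(s$x[i], s$y[i], s$z[i]) else NULL
  }
  viol <- list()
  add <- function(r, type, detail, value, expected) {
    viol[[length(viol) + 1]] <<- tibble::tibble(
      res_idx = r, chain = rt$chain[r], resno = rt$resno[r],
      resname = rt$resname[r], type = type, detail = detail,
      value = value, expected = expected)
  }
  check_bond <- function(r, p1, p2, detail, expected) {
    if (is.null(p1) || is.null(p2)) return()
    v <- vnorm(p1 - p2)
    if (abs(v - expected) > tolerance_sigmas * STEREO_SIGMA$bond)
      add(r, "bond", detail, v, expected)
  }
  check_angle <- function(r, p1, p2, p3, detail, expected) {
    if (is.null(p1) || is.null(p2) || is.null(p3)) return()
    v <- angle3(p1, p2, p3)
    if (abs(v - expected) > tolerance_sigmas * STEREO_SIGMA$angle)
      add(r, "angle", detail, v, expected)
  }
  rows_by_res <- split(seq_len(nrow(s)), ridx)
  g <- BB_GEOM
  for (r in seq_len(nrow(rt))) {
    rows <- rows_by_res[[as.character(r)]]
    N <- pos_of(rows, "N"); CA <- pos_of(rows, "CA")
    C <- pos_of(rows, "C"); O <- pos_of(rows, "O"); CB <- pos_of(rows, "CB")
    check_bond(r, N, CA, "N-CA", g$b_n_ca)
    check_bond(r, CA, C, "CA-C", g$b_ca_c)
    check_bond(r, C, O, "C-O", g$b_c_o)
    check_angle(r, N, CA, C, "N-CA-C", g$a_n_ca_c)
    check_angle(r, CA, C, O, "CA-C-O", g$a_ca_c_o)
    if (!is.null(CB)) {
      cbg <- if (rt$resname[r] == "PRO") PRO_CB_GEOM else CB_GEOM
      check_bond(r, CA, CB, "CA-CB", cbg$bond)
      check_angle(r, N, CA, CB, "N-CA-CB", cbg$angle)
    }
    # peptide link to the following residue in the same chain
    if (r < nrow(rt) && rt$chain[r + 1] == rt$chain[r] &&
        rt$resno[r + 1] == rt$resno[r] + 1L) {
      N2 <- pos_of(rows_by_res[[as.character(r + 1)]], "N")
      check_bond(r, C, N2, "C-N(+1)", g$b_c_n)
      check_angle(r, CA, C, N2, "CA-C-N(+1)", g$a_ca_c_n)
    }
    # side-chain geometry from the ideal topology
    tp <- SIDECHAIN_TOPO[[rt$resname[r]]]
    if (!is.null(tp)) {
      for (j in seq_len(nrow(tp))) {
        pd <- pos_of(rows, tp$atom[j])
        p3 <- pos_of(rows, tp$r3[j]); p2 <- pos_of(rows, tp$r2[j])
        check_bond(r, pd, p3, paste0(tp$r3[j], "-", tp$atom[j]), tp$bond[j])
        check_angle(r, p2, p3, pd,
                    paste(tp$r2[j], tp$r3[j], tp$atom[j], sep = "-"),
                    tp$angle[j])
      }
    }
  }
  cp <- clash_pairs(s, clash_floor)
  if (nrow(cp) > 0) {
    for (k in seq_len(nrow(cp))) {
      a <- cp[k, 1]; b <- cp[k, 2]
      d <- vnorm(c(s$x[a] - s$x[b], s$y[a] - s$y[b], s$z[a] - s$z[b]))
      for (r in unique(c(ridx[a], ridx[b]))) {
        add(r, "clash", paste0(s$atom[a], "..", s$atom[b]), d, clash_floor)
      }
    }
  }
  if (length(viol) == 0) {
    return(tibble::tibble(res_idx = integer(), chain = character(),
                          resno = integer(), resname = character(),
                          type = character(), detail = character(),
                          value = numeric(), expected = numeric()))
  }
  dplyr::bind_rows(viol)
}

#' Side-chain chi angles of one residue
#'
#' Computes the signed dihedrals chi1..chi4 (as defined by [chi_table()])
#' in (-180, 180]. A missing atom, or a degenerate (collinear) quadruple,
#' truncates the list at the first incomputable angle.
#'
#' @param residue a structure tibble slice holding one residue.
#' @param table chi definition table from [chi_table()].
#' @return Numeric vector of up to 4 angles in degrees (length 0 for
#'   ALA/GLY).
#' @export
chi_angles <- function(residue, table = chi_table()) {
  resname <- residue$resname[1]
  defs <- table$angles[[resname]]
  if (is.null(defs)) return(numeric(0))
  out <- numeric(0)
  for (quad in defs) {
    rows <- match(quad, residue$atom)
    if (anyNA(rows)) break
    p <- coords(residue)[rows, , drop = FALSE]
    ang <- dihedral4(p[1, ], p[2, ], p[3, ], p[4, ])
    if (is.na(ang)) break
    out <- c(out, ang)
  }
  out
}

wrap_angle_diff <- function(delta) {
  d <- abs(delta) %% 360
  pmin(d, 360 - d)
}

#' Side-chain chi-angle mean absolute error
#'
#' Per chi index, the wrapped absolute difference between reference and
#' model angles, minimized over symmetry-equivalent values for terminal
#' groups with 2-fold symmetry (ASP chi2, GLU chi3, PHE chi2, TYR chi2:
#' chi and chi + 180 are equivalent). Residues are paired via the mapping
#' and an angle is compared only when computable on both sides.
#'
#' @param ref,model structure tibbles.
#' @param mapping a `residue_mapping` (defaults to [map_residues()]).
#' @param table chi definition table from [chi_table()].
#' @return List with `overall` MAE (degrees) and `per_chi` tibble
#'   (`chi`, `mae`, `n`).
#' @export
chi_mae <- function(ref, model, mapping = NULL, table = chi_table()) {
  if (is.null(mapping)) mapping <- map_residues(ref, model)
  rref <- atom_res_idx(ref)
  rmod <- atom_res_idx(model)
  rt <- residue_table(ref)
  errs <- vector("list", nrow(mapping))
  for (k in seq_len(nrow(mapping))) {
    ra <- ref[rref == mapping$ref_idx[k], , drop = FALSE]
    ma <- model[rmod == mapping$model_idx[k], , drop = FALSE]
    ca <- chi_angles(ra, table)
    cm <- chi_angles(ma, table)
    n <- min(length(ca), length(cm))
    if (n == 0) next
    resname <- ra$resname[1]
    e <- numeric(n)
    for (j in seq_len(n)) {
      d <- wrap_angle_diff(ca[j] - cm[j])
      sym <- any(table$symmetric$resname == resname &
                   table$symmetric$chi == j)
      if (sym) d <- min(d, wrap_angle_diff(ca[j] - cm[j] - 180))
      e[j] <- d
    }
    errs[[k]] <- tibble::tibble(chi = seq_len(n), err = e)
  }
  all <- dplyr::bind_rows(errs)
  if (nrow(all) == 0) stop("no comparable chi angles: metric undefined",
                           call. = FALSE)
  per_chi <- dplyr::summarise(dplyr::group_by(all, .data$chi),
                              mae = mean(.data$err), n = dplyr::n(),
                              .groups = "drop")
  list(overall = mean(all$err), per_chi = per_chi)
}

#' Neighbor-count burial proxy
#'
#' Burial of each residue as the number of other residues whose CB (CA for
#' glycine or CB-less residues) lies within `radius` of this residue's
#' CB/CA; higher counts mean more buried. Quantile bins support
#' burial-stratified metric reporting.
#'
#' @param ref structure tibble.
#' @param radius neighbor radius in Angstrom (default 10).
#' @param bins number of quantile bins (default 4, i.e. quartiles).
#' @return Tibble (`res_idx`, `chain`, `resno`, `resname`, `burial`,
#'   `burial_bin`; bin 1 = most exposed).
#' @export
burial <- function(ref, radius = 10, bins = 4) {
  rt <- residue_table(ref)
  ridx <- atom_res_idx(ref)
  P <- matrix(NA_real_, nrow(rt), 3)
  for (r in seq_len(nrow(rt))) {
    rows <- which(ridx == r)
    i <- rows[ref$atom[rows] == "CB"]
    if (length(i) == 0) i <- rows[ref$atom[rows] == "CA"]
    if (length(i) >= 1) P[r, ] <- c(ref$x[i[1]], ref$y[i[1]], ref$z[i[1]])
  }
  n <- nrow(P)
  counts <- integer(n)
  if (n > 1) {
    D <- as.matrix(stats::dist(P))
    counts <- as.integer(rowSums(D < radius, na.rm = TRUE) - 1L)
  }
  tibble::tibble(
    res_idx = rt$res_idx, chain = rt$chain, resno = rt$resno,
    resname = rt$resname, burial = counts,
    burial_bin = if (n >= bins) dplyr::ntile(counts, bins) else
      rep(1L, n)
  )
}
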