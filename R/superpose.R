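# Global backbone metrics: Kabsch optimal superposition, all-atom RMSD,
# rectified C-alpha RMSD and the TM-score with its fragment-seeded
# superposition search.

#' Kabsch optimal rigid superposition
#'
#' Finds the proper rotation `R` and translation `t` minimizing
#' `RMSD(ref, R * mov + t)`. Reflections are forbidden: the smallest
#' singular direction is sign-corrected so `det(R) = +1`.
#'
#' @param ref_points,mov_points n x 3 coordinate matrices (equal n,
#'   n >= 3).
#' @return A `superposition` list with `rotation` (3 x 3), `translation`
#'   (length 3) and `rmsd` over the fitted set.
#' @export
kabsch <- function(ref_points, mov_points) {
  ref_points <- as.matrix(ref_points)
  mov_points <- as.matrix(mov_points)
  if (nrow(ref_points) != nrow(mov_points)) {
    stop("point sets differ in length: ", nrow(ref_points), " vs ",
         nrow(mov_points), call. = FALSE)
  }
  if (nrow(ref_points) < 3) {
    stop("superposition is underdetermined with fewer than 3 points",
         call. = FALSE)
  }
  cr <- colMeans(ref_points)
  cm <- colMeans(mov_points)
  P <- sweep(mov_points, 2, cm)
  Q <- sweep(ref_points, 2, cr)
  H <- crossprod(P, Q)            # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cr - as.vector(R %*% cm)
  fitted <- apply_rigid(mov_points, R, t)
  rmsd <- sqrt(mean(rowSums((fitted - ref_points)^2)))
  structure(list(rotation = R, translation = t, rmsd = rmsd),
            class = "superposition")
}

# Mapped C-alpha coordinate pairs (both present); rows follow the mapping.
mapped_ca <- function(ref, model, mapping) {
  rref <- atom_res_idx(ref)
  rmod <- atom_res_idx(model)
  ca_ref <- ref[ref$atom == "CA", , drop = FALSE]
  ca_mod <- model[model$atom == "CA", , drop = FALSE]
  i <- match(mapping$ref_idx, rref[ref$atom == "CA"])
  j <- match(mapping$model_idx, rmod[model$atom == "CA"])
  ok <- !is.na(i) & !is.na(j)
  list(ref = coords(ca_ref)[i[ok], , drop = FALSE],
       model = coords(ca_mod)[j[ok], , drop = FALSE])
}

#' Rectified C-alpha RMSD
#'
#' Superposes the mapped C-alpha sets with [kabsch()], rectifies each
#' per-residue deviation to `min(d_i, cap)` before squaring, and returns
#' the root mean square. The cap bounds the influence of outlier residues;
#' `cap = Inf` recovers the plain C-alpha RMSD.
#'
#' @param ref,model structure tibbles.
#' @param mapping a `residue_mapping` (defaults to [map_residues()]).
#' @param cap rectification cap in Angstrom (default 5).
#' @return RMSD in Angstrom.
#' @export
alpha_rmsd <- function(ref, model, mapping = NULL, cap = 5) {
  if (is.null(mapping)) mapping <- map_residues(ref, model)
  pts <- mapped_ca(ref, model, mapping)
  if (nrow(pts$ref) == 0) stop("no mapped C-alpha pairs: metric undefined",
                               call. = FALSE)
  sup <- kabsch(pts$ref, pts$model)
  fitted <- apply_rigid(pts$model, sup$rotation, sup$translation)
  d <- sqrt(rowSums((fitted - pts$ref)^2))
  sqrt(mean(pmin(d, cap)^2))
}

#' TM-score distance normalization
#'
#' `d0(L) = max(1.24 * (L - 15)^(1/3) - 1.8, 0.5)` Angstrom, the published
#' TM-score convention, normalized by the reference length.
#'
#' @param l_ref reference residue count.
#' @return d0 in Angstrom.
#' @export
tm_d0 <- function(l_ref) {
  if (l_ref > 15) max(1.24 * (l_ref - 15)^(1 / 3) - 1.8, 0.5) else 0.5
}

tm_objective <- function(ref, fitted, d0, l_ref) {
  d2 <- rowSums((fitted - ref)^2)
  sum(1 / (1 + d2 / d0^2)) / l_ref
}

#' TM-score with fragment-seeded superposition search
#'
#' Length-normalized structural similarity in (0, 1]:
#' `TM = max over superpositions of (1/L_ref) * sum_i 1 / (1 + (d_i/d0)^2)`
#' over the mapped C-alpha pairs, with `L_ref` the reference residue count
#' and `d0` from [tm_d0()]. The search seeds superpositions from gapless
#' mapped fragments of lengths L, L/2, L/4, ... (>= 4) at half-length
#' offsets, refines each by iteratively re-superposing on the pairs within
#' a d0-based cutoff until the included set is stable, and finally polishes
#' the best transform by direct local optimization of the TM objective
#' over the six rigid-motion parameters. The result can therefore only
#' improve on any single Kabsch superposition of the full mapping.
#'
#' @param ref,model structure tibbles.
#' @param mapping a `residue_mapping` of at least 5 pairs (defaults to
#'   [map_residues()]).
#' @return TM-score in (0, 1], with the optimal transform attached as the
#'   `"superposition"` attribute.
#' @export
tm_score <- function(ref, model, mapping = NULL) {
  if (is.null(mapping)) mapping <- map_residues(ref, model)
  pts <- mapped_ca(ref, model, mapping)
  n <- nrow(pts$ref)
  if (n < 5) stop("TM-score undefined with fewer than 5 mapped pairs",
                  call. = FALSE)
  l_ref <- nrow(residue_table(ref))
  d0 <- tm_d0(l_ref)
  d_cut <- max(d0, 2.0)

  best <- list(score = -Inf, R = diag(3), t = c(0, 0, 0))
  consider <- function(R, t) {
    sc <- tm_objective(pts$ref, apply_rigid(pts$model, R, t), d0, l_ref)
    if (sc > best$score) best <<- list(score = sc, R = R, t = t)
  }
  refine <- function(R, t) {
    sel_prev <- integer(0)
    for (iter in 1:20) {
      d <- sqrt(rowSums((apply_rigid(pts$model, R, t) - pts$ref)^2))
      cut <- d_cut
      sel <- which(d < cut)
      while (length(sel) < 3) {
        cut <- cut + 0.5
        sel <- which(d < cut)
      }
      if (identical(sel, sel_prev)) break
      sel_prev <- sel
      sup <- kabsch(pts$ref[sel, , drop = FALSE], pts$model[sel, , drop = FALSE])
      R <- sup$rotation; t <- sup$translation
      consider(R, t)
    }
  }

  obj <- function(p) {
    -tm_objective(pts$ref,
                  apply_rigid(pts$model, rotvec_to_mat(p[1:3]), p[4:6]),
                  d0, l_ref)
  }
  polish <- function(R, t) {
    opt <- stats::optim(c(mat_to_rotvec(R), t), obj, method = "Nelder-Mead",
                        control = list(maxit = 600, reltol = 1e-10))
    if (-opt$value > best$score) {
      best <<- list(score = -opt$value, R = rotvec_to_mat(opt$par[1:3]),
                    t = opt$par[4:6])
    }
  }

  len <- n
  while (len >= 4) {
    offs <- seq(1L, n - len + 1L, by = max(1L, len %/% 2L))
    for (o in offs) {
      idx <- o:(o + len - 1L)
      sup <- try(kabsch(pts$ref[idx, , drop = FALSE],
                        pts$model[idx, , drop = FALSE]), silent = TRUE)
      if (inherits(sup, "try-error")) next
      consider(sup$rotation, sup$translation)
      refine(sup$rotation, sup$translation)
    }
    if (len == 4L) break
    len <- max(len %/% 2L, 4L)
  }

  # short chains have few fragment seeds and a multi-modal objective:
  # add a deterministic set of rotation starts, each locally polished
  if (n <= 50) {
    cr <- colMeans(pts$ref)
    cm <- colMeans(pts$model)
    n_starts <- if (n <= 12) 150L else 40L
    starts <- with_seed(20240801L,
                        lapply(seq_len(n_starts), function(k) random_rotation()))
    for (R0 in starts) {
      t0 <- cr - as.vector(R0 %*% cm)
      refine(R0, t0)
      polish(R0, t0)
    }
  }

  # very short chains: basin-hop around the incumbent, since the optimum
  # may superpose a non-contiguous subset no fragment seed captures
  if (n <= 12) {
    with_seed(20240802L, {
      for (round in 1:3) {
        R0 <- best$R; t0 <- best$t
        for (k in 1:60) {
          Rp <- rotvec_to_mat(mat_to_rotvec(R0) + stats::rnorm(3, 0, 0.15))
          tp <- t0 + stats::rnorm(3, 0, 0.5)
          polish(Rp, tp)
        }
      }
    })
  }

  # local polish of the best transform in rigid-motion parameters
  polish(best$R, best$t)
  structure(best$score,
            superposition = structure(
              list(rotation = best$R, translation = best$t, rmsd = NA_real_),
              class = "superposition"))
}

#' All-atom / side-chain RMSD after backbone superposition
#'
#' Atoms are paired by (mapped residue, identical atom name). The
#' superposition is fitted on the backbone atoms (N, CA, C, O) of the
#' mapped residues; the RMSD is then computed over `atom_set`: all matched
#' heavy atoms, or side-chain (non-backbone) heavy atoms only. Atoms
#' present in only one partner are skipped and counted in the
#' `"n_skipped"` attribute.
#'
#' @param ref,model structure tibbles.
#' @param mapping a `residue_mapping` (defaults to [map_residues()]).
#' @param atom_set `"all"` or `"sidechain"`.
#' @return RMSD in Angstrom with attribute `n_skipped`.
#' @export
all_atom_rmsd <- function(ref, model, mapping = NULL,
                          atom_set = c("all", "sidechain")) {
  atom_set <- match.arg(atom_set)
  if (is.null(mapping)) mapping <- map_residues(ref, model)
  rref <- atom_res_idx(ref)
  rmod <- atom_res_idx(model)
  pair_ref <- list(); pair_mod <- list(); pair_name <- list()
  n_skipped <- 0L
  for (k in seq_len(nrow(mapping))) {
    ra <- ref[rref == mapping$ref_idx[k], , drop = FALSE]
    ma <- model[rmod == mapping$model_idx[k], , drop = FALSE]
    common <- intersect(ra$atom, ma$atom)
    n_skipped <- n_skipped + sum(!(ra$atom %in% common)) +
      sum(!(ma$atom %in% common))
    if (length(common) == 0) next
    pair_ref[[k]] <- coords(ra)[match(common, ra$atom), , drop = FALSE]
    pair_mod[[k]] <- coords(ma)[match(common, ma$atom), , drop = FALSE]
    pair_name[[k]] <- common
  }
  A <- do.call(rbind, pair_ref)
  B <- do.call(rbind, pair_mod)
  nm <- unlist(pair_name)
  if (is.null(A) || nrow(A) == 0) {
    stop("no atom pairs shared between mapped residues: metric undefined",
         call. = FALSE)
  }
  bb <- nm %in% BACKBONE_ATOMS
  fit_idx <- if (sum(bb) >= 3) which(bb) else seq_len(nrow(A))
  sup <- kabsch(A[fit_idx, , drop = FALSE], B[fit_idx, , drop = FALSE])
  fitted <- apply_rigid(B, sup$rotation, sup$translation)
  eval_idx <- switch(atom_set, all = seq_len(nrow(A)), sidechain = which(!bb))
  if (length(eval_idx) == 0) {
    stop("no atoms in the requested atom set: metric undefined", call. = FALSE)
  }
  out <- sqrt(mean(rowSums((fitted[eval_idx, , drop = FALSE] -
                              A[eval_idx, , drop = FALSE])^2)))
  structure(out, n_skipped = n_skipped)
}
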