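# Template mutilation and perturbation protocols: per-coordinate Gaussian
# noise, projection onto leading principal components, side-chain stripping
# with three C-beta placement policies, and the glycine-C-beta template that
# removes amino-acid identity while keeping geometry.

# Fixed "next to the origin" C-beta used by the non-informative placement;
# slightly off zero to avoid exact-coincidence degeneracies.
ORIGIN_CB <- c(0.1, 0.1, 0.1)

#' Add independent Gaussian noise to every coordinate
#'
#' Each atomic coordinate component receives an independent draw from
#' Normal(0, sigma^2); the topology (atoms, residues, chains) is unchanged.
#' Atoms are visited in file order, components x then y then z, from a
#' single seeded generator, so the output is reproducible.
#'
#' @param s structure tibble.
#' @param sigma noise standard deviation in Angstrom (default 1.0).
#' @param seed RNG seed.
#' @return Perturbed `struct_tbl`.
#' @export
gaussian_noise <- function(s, sigma = 1.0, seed = NULL) {
  stopifnot(nrow(s) > 0, sigma >= 0)
  if (sigma == 0) return(s)
  with_seed(seed, {
    n <- nrow(s)
    noise <- matrix(stats::rnorm(3L * n, 0, sigma), ncol = 3, byrow = TRUE)
    set_coords(s, coords(s) + noise)
  })
}

#' Project a structure onto its leading principal components
#'
#' Coordinates are mean-centered, the principal axes are computed from the
#' structure's own atom coordinates, each atom is reconstructed keeping
#' only the top `n_components` (discarded components set to zero), and the
#' mean is added back. The output remains a valid 3D structure whose
#' points lie in an `n_components`-dimensional affine subspace.
#'
#' Eigenvectors are oriented so their largest-magnitude component is
#' positive and eigenvalue ties are broken by original axis order, making
#' the projection deterministic. By default all heavy atoms enter the PCA
#' fit; `atoms = "CA"` restricts the fit (and projection) to C-alpha.
#'
#' @param s structure tibble (at least 4 atoms, not all identical).
#' @param n_components 1 or 2.
#' @param atoms `"all"` or `"CA"`: the coordinate set defining the axes.
#' @return Projected `struct_tbl`.
#' @export
pca_project <- function(s, n_components = 2, atoms = c("all", "CA")) {
  atoms <- match.arg(atoms)
  stopifnot(n_components %in% c(1L, 2L))
  fit_rows <- if (atoms == "CA") which(s$atom == "CA") else seq_len(nrow(s))
  if (length(fit_rows) < 4) stop("need at least 4 atoms for PCA projection",
                                 call. = FALSE)
  X <- coords(s)[fit_rows, , drop = FALSE]
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  if (max(abs(Xc)) < 1e-9) stop("degenerate input: all coordinates identical",
                                call. = FALSE)
  cv <- crossprod(Xc) / (nrow(Xc) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  V <- eg$vectors
  # deterministic sign: largest-magnitude component of each axis positive
  for (j in 1:3) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  if (n_components == 2L && eg$values[2] < 1e-12 * max(eg$values[1], 1e-300)) {
    message("collinear input: second principal axis is arbitrary within the null space")
  }
  P <- V[, seq_len(n_components), drop = FALSE]
  Yc <- sweep(coords(s), 2, mu)
  proj <- Yc %*% P %*% t(P)
  out <- set_coords(s, sweep(proj, 2, -mu))
  attr(out, "pca") <- list(values = eg$values, vectors = V, center = mu,
                           n_components = n_components, atoms = atoms)
  out
}

#' Backbone-based heuristic C-beta position
#'
#' Reconstructs an ideal tetrahedral C-beta from the backbone N, CA and C
#' positions as the fixed linear combination
#' `CB = CA + wa * (b x c) + wb * b + wc * c` with `b = CA - N`,
#' `c = C - CA` and the published constant weights
#' (-0.58273431, 0.56802827, -0.54067466). The construction is local, so
#' it is exactly equivariant under rigid motions.
#'
#' @param n,ca,c backbone coordinates (3-vectors).
#' @return 3-vector with the C-beta coordinate.
#' @export
heuristic_cbeta <- function(n, ca, c) {
  stopifnot(length(n) == 3, length(ca) == 3, length(c) == 3,
            all(is.finite(c(n, ca, c))))
  b <- ca - n
  cc <- c - ca
  a <- cross3(b, cc)
  if (vnorm(a) < 1e-9) stop("collinear backbone atoms: C-beta is undefined",
                            call. = FALSE)
  ca + CB_HEURISTIC_W[["a"]] * a + CB_HEURISTIC_W[["b"]] * b +
    CB_HEURISTIC_W[["c"]] * cc
}

#' Strip side chains, with a choice of C-beta placements
#'
#' Removes all side-chain atoms so each residue retains exactly N, CA, C
#' and O, then handles the C-beta according to `cbeta_mode`:
#' \describe{
#'   \item{`absent`}{no CB at all.}
#'   \item{`origin`}{a non-informative CB at the fixed point
#'     (0.1, 0.1, 0.1) Angstrom for every residue.}
#'   \item{`heuristic`}{CB rebuilt from the backbone via
#'     [heuristic_cbeta()].}
#'   \item{`template`}{the original CB kept where present.}
#' }
#' Glycine has no CB to copy, so it stays CB-less in modes `template` and
#' `absent`; in modes `heuristic` and `origin` glycine also receives a CB
#' (set `gly_cb = FALSE` to suppress), mirroring glycine-extension
#' semantics. Residues missing backbone atoms needed by the heuristic are
#' emitted without CB with a message.
#'
#' @param s structure tibble.
#' @param cbeta_mode one of `"absent"`, `"origin"`, `"heuristic"`,
#'   `"template"`.
#' @param gly_cb should glycine receive a CB in modes `origin`/`heuristic`?
#' @return Stripped `struct_tbl`.
#' @export
strip_sidechains <- function(s, cbeta_mode = c("absent", "origin", "heuristic",
                                               "template"),
                             gly_cb = TRUE) {
  cbeta_mode <- match.arg(cbeta_mode)
  ridx <- atom_res_idx(s)
  keep_names <- if (cbeta_mode == "template") c(BACKBONE_ATOMS, "CB")
                else BACKBONE_ATOMS
  base <- s[s$atom %in% keep_names, , drop = FALSE]
  if (cbeta_mode %in% c("origin", "heuristic")) {
    rt <- residue_table(s)
    bidx <- atom_res_idx(base)
    rows <- vector("list", nrow(rt))
    n_missing <- 0L
    for (i in seq_len(nrow(rt))) {
      at <- tibble::as_tibble(base[bidx == i, , drop = FALSE])
      want_cb <- gly_cb || rt$resname[i] != "GLY"
      if (want_cb) {
        cb <- if (cbeta_mode == "origin") ORIGIN_CB else {
          if (all(c("N", "CA", "C") %in% at$atom)) {
            heuristic_cbeta(unlist(at[at$atom == "N", c("x", "y", "z")]),
                            unlist(at[at$atom == "CA", c("x", "y", "z")]),
                            unlist(at[at$atom == "C", c("x", "y", "z")]))
          } else {
            n_missing <- n_missing + 1L
            NULL
          }
        }
        if (!is.null(cb)) {
          row <- at[1L, ]
          row$atom <- "CB"; row$element <- "C"
          row$x <- cb[1]; row$y <- cb[2]; row$z <- cb[3]
          at <- dplyr::bind_rows(at, row)
        }
      }
      rows[[i]] <- at
    }
    if (n_missing > 0) {
      message(n_missing, " residue(s) missing backbone atoms: no CB placed")
    }
    base <- dplyr::bind_rows(rows)
  }
  as_structure(base, s)
}

#' Glycine-C-beta template construction
#'
#' Removes all amino-acid identity from a template: every residue is
#' renamed `GLY`, atoms are reduced to N, CA, C, O plus a C-beta, and the
#' extracted sequence of the result is all-glycine. With
#' `cbeta_source = "template"` the original CB is kept where present and
#' rebuilt heuristically otherwise; with `"heuristic"` every CB is rebuilt
#' from the backbone. Backbone coordinates are unchanged and the operation
#' is idempotent.
#'
#' @param s structure tibble with complete backbones.
#' @param cbeta_source `"template"` or `"heuristic"`.
#' @return Glycine-reduced `struct_tbl`.
#' @export
glycine_cb_template <- function(s, cbeta_source = c("template", "heuristic")) {
  cbeta_source <- match.arg(cbeta_source)
  kept <- s[s$atom %in% c(BACKBONE_ATOMS, "CB"), , drop = FALSE]
  rt <- residue_table(kept)
  ridx <- atom_res_idx(kept)
  rows <- vector("list", nrow(rt))
  for (i in seq_len(nrow(rt))) {
    at <- tibble::as_tibble(kept[ridx == i, , drop = FALSE])
    has_cb <- "CB" %in% at$atom
    rebuild <- cbeta_source == "heuristic" || !has_cb
    if (rebuild && all(c("N", "CA", "C") %in% at$atom)) {
      cb <- heuristic_cbeta(unlist(at[at$atom == "N", c("x", "y", "z")]),
                            unlist(at[at$atom == "CA", c("x", "y", "z")]),
                            unlist(at[at$atom == "C", c("x", "y", "z")]))
      at <- at[at$atom != "CB", , drop = FALSE]
      row <- at[1L, ]
      row$atom <- "CB"; row$element <- "C"
      row$x <- cb[1]; row$y <- cb[2]; row$z <- cb[3]
      at <- dplyr::bind_rows(at, row)
    }
    at$resname <- "GLY"
    rows[[i]] <- at
  }
  as_structure(dplyr::bind_rows(rows), s)
}

#' Describe a perturbation for pipeline runs
#'
#' @param kind one of `"identity"`, `"gaussian"`, `"pca_project"`,
#'   `"strip_sidechains"`, `"glycine_cb"`.
#' @param sigma Gaussian noise level in Angstrom.
#' @param n_components 1 or 2 principal components.
#' @param cbeta_mode C-beta placement for `strip_sidechains`.
#' @param seed RNG seed (Gaussian noise only).
#' @param label optional label used in reports; defaults to a compact
#'   description.
#' @return A `perturbation_spec` list.
#' @export
perturbation_spec <- function(kind = c("identity", "gaussian", "pca_project",
                                       "strip_sidechains", "glycine_cb"),
                              sigma = 1.0, n_components = 2,
                              cbeta_mode = "heuristic", seed = NULL,
                              label = NULL) {
  kind <- match.arg(kind)
  if (kind == "gaussian") stopifnot(sigma > 0)
  if (is.null(label)) {
    label <- switch(kind,
      identity = "identity",
      gaussian = sprintf("gaussian(sigma=%g)", sigma),
      pca_project = sprintf("pca(%dPC)", n_components),
      strip_sidechains = sprintf("strip(cb=%s)", cbeta_mode),
      glycine_cb = "glycine_cb")
  }
  structure(list(kind = kind, sigma = sigma, n_components = n_components,
                 cbeta_mode = cbeta_mode, seed = seed, label = label),
            class = "perturbation_spec")
}

#' Apply a perturbation spec to a structure
#'
#' @param s structure tibble.
#' @param spec a [perturbation_spec()].
#' @param seed overriding RNG seed (wins over `spec$seed`).
#' @return Perturbed `struct_tbl`.
#' @export
perturb_structure <- function(s, spec, seed = NULL) {
  stopifnot(inherits(spec, "perturbation_spec"))
  seed <- if (!is.null(seed)) seed else spec$seed
  switch(spec$kind,
    identity = s,
    gaussian = gaussian_noise(s, sigma = spec$sigma, seed = seed),
    pca_project = pca_project(s, n_components = spec$n_components),
    strip_sidechains = strip_sidechains(s, cbeta_mode = spec$cbeta_mode),
    glycine_cb = glycine_cb_template(s)
  )
}
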