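# Shared structural data model: a structure is a tibble with one row per
# heavy atom, carrying chain / residue / atom identity and coordinates.
# Everything downstream (generator, perturbations, metrics) operates on this
# tabular representation, so results chain naturally with dplyr verbs.

STRUCT_COLS <- c("chain", "resno", "icode", "resname", "atom", "element",
                 "x", "y", "z", "occ", "bfactor", "altloc")

#' Construct a structure tibble
#'
#' Builds the atom-level tibble used throughout the package. One row per
#' atom with columns `chain`, `resno`, `icode`, `resname`, `atom` (PDB-style
#' atom name), `element`, `x`, `y`, `z` (Angstrom), `occ`, `bfactor` and
#' `altloc`. Missing optional columns are filled with defaults.
#'
#' @param df data frame with at least `chain`, `resno`, `resname`, `atom`,
#'   `x`, `y`, `z`.
#' @param source provenance note (file path or generator tag) stored as an
#'   attribute.
#' @return A `struct_tbl` tibble.
#' @export
new_structure <- function(df, source = "r") {
  df <- tibble::as_tibble(df)
  required <- c("chain", "resno", "resname", "atom", "x", "y", "z")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("structure is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"icode" %in% names(df)) df$icode <- ""
  if (!"element" %in% names(df)) df$element <- element_of(df$atom)
  if (!"occ" %in% names(df)) df$occ <- 1
  if (!"bfactor" %in% names(df)) df$bfactor <- 0
  if (!"altloc" %in% names(df)) df$altloc <- ""
  df$icode[is.na(df$icode)] <- ""
  df$altloc[is.na(df$altloc)] <- ""
  df$resno <- as.integer(df$resno)
  df$chain <- as.character(df$chain)
  df <- df[, STRUCT_COLS]
  stopifnot(all(is.finite(df$x)), all(is.finite(df$y)), all(is.finite(df$z)))
  structure(df, class = c("struct_tbl", class(tibble::tibble())),
            source = source)
}

#' @export
print.struct_tbl <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("# protein structure: %d chain(s), %d residue(s), %d atom(s)\n",
              length(unique(x$chain)), nrow(rt), nrow(x)))
  src <- attr(x, "source")
  if (!is.null(src)) cat(sprintf("# source: %s\n", src))
  NextMethod()
}

is_structure <- function(x) inherits(x, "struct_tbl")

# Restore struct_tbl class/attributes after dplyr operations.
as_structure <- function(df, template) {
  structure(tibble::as_tibble(df),
            class = c("struct_tbl", class(tibble::tibble())),
            source = attr(template, "source"))
}

#' Residue-level view of a structure
#'
#' @param s structure tibble.
#' @return Tibble with one row per residue (`chain`, `resno`, `icode`,
#'   `resname`) plus a global residue index `res_idx` in chain order.
#' @export
residue_table <- function(s) {
  rt <- dplyr::distinct(tibble::as_tibble(s)[, c("chain", "resno", "icode", "resname")])
  rt$res_idx <- seq_len(nrow(rt))
  tibble::as_tibble(rt)
}

# Global residue index (matching residue_table) for every atom row.
atom_res_idx <- function(s) {
  key <- paste(s$chain, s$resno, s$icode, sep = "\r")
  match(key, unique(key))
}

# n x 3 coordinate matrix.
coords <- function(s) {
  m <- cbind(x = s$x, y = s$y, z = s$z)
  rownames(m) <- NULL
  m
}

set_coords <- function(s, xyz) {
  stopifnot(nrow(xyz) == nrow(s))
  s$x <- xyz[, 1L]
  s$y <- xyz[, 2L]
  s$z <- xyz[, 3L]
  s
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pdb", "ent")) return("pdb")
  if (ext %in% c("cif", "mmcif")) return("mmcif")
  stop("cannot infer structure format from extension '.", ext,
       "'; pass format = \"pdb\" or \"mmcif\"", call. = FALSE)
}

#' Read a protein structure from PDB or mmCIF
#'
#' Parses the file, keeps the first model only, and excludes hetero
#' molecules and waters. `HETATM` records whose residue name has a standard
#' mapping (e.g. selenomethionine `MSE`) are retained so that
#' [standardize_structure()] can map them.
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by extension).
#' @return A `struct_tbl` tibble.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") format <- guess_format(path)
  parsed <- withCallingHandlers(
    tryCatch(
      if (format == "pdb") bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
      else bio3d::read.cif(path, verbose = FALSE),
      error = function(e) {
        stop("failed to parse ", format, " file '", path, "': ",
             conditionMessage(e), call. = FALSE)
      }
    ),
    warning = function(w) {
      if (grepl("beta version|helix/sheet|PDB records", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }
  )
  at <- parsed$atom
  keep <- at$type == "ATOM" |
    (at$type == "HETATM" & at$resid %in% c(AA3, names(NONSTANDARD_MAP)))
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) {
    stop("no protein residues in '", path,
         "' (hetero molecules and waters are excluded)", call. = FALSE)
  }
  chain <- ifelse(is.na(at$chain), "A", at$chain)
  new_structure(
    data.frame(
      chain = chain, resno = at$resno,
      icode = ifelse(is.na(at$insert), "", at$insert),
      resname = at$resid, atom = at$elety,
      element = ifelse(is.na(at$elesy) | at$elesy == "",
                       element_of(at$elety), at$elesy),
      x = at$x, y = at$y, z = at$z,
      occ = ifelse(is.na(at$o), 1, at$o),
      bfactor = ifelse(is.na(at$b), 0, at$b),
      altloc = ifelse(is.na(at$alt), "", at$alt),
      stringsAsFactors = FALSE
    ),
    source = path
  )
}

format_pdb_atom_name <- function(name) {
  # Names of up to 3 characters start in column 14; 4-character names use
  # the full field.
  ifelse(nchar(name) >= 4, substr(name, 1, 4), sprintf(" %-3s", name))
}

#' Write a structure to PDB or mmCIF
#'
#' PDB output uses fixed-width `ATOM` records with `TER` separators between
#' chains; coordinates outside the fixed-width capacity of the PDB format
#' (at most 9999.999, at least -999.999) raise an error advising mmCIF.
#'
#' @param s structure tibble.
#' @param path output path.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (nrow(s) == 0) stop("refusing to write an empty structure", call. = FALSE)
  if (format == "pdb") {
    xyz <- coords(s)
    if (any(xyz > 9999.999) || any(xyz < -999.999)) {
      stop("coordinates exceed the fixed-width PDB field capacity; ",
           "write mmCIF instead (format = \"mmcif\")", call. = FALSE)
    }
    lines <- character(0)
    serial <- 0L
    for (ch in unique(s$chain)) {
      cs <- s[s$chain == ch, , drop = FALSE]
      rec <- sprintf(
        "ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial + seq_len(nrow(cs)),
        format_pdb_atom_name(cs$atom),
        ifelse(cs$altloc == "", " ", cs$altloc),
        cs$resname, ch, cs$resno,
        ifelse(cs$icode == "", " ", cs$icode),
        cs$x, cs$y, cs$z, cs$occ, cs$bfactor, cs$element
      )
      serial <- serial + nrow(cs)
      last <- cs[nrow(cs), ]
      ter <- sprintf("TER   %5d      %3s %1s%4d%1s",
                     serial + 1L, last$resname, ch, last$resno,
                     ifelse(last$icode == "", " ", last$icode))
      serial <- serial + 1L
      lines <- c(lines, rec, ter)
    }
    writeLines(c(lines, "END"), path)
  } else {
    rt <- residue_table(s)
    ridx <- atom_res_idx(s)
    hdr <- c(
      "data_structure", "#", "loop_",
      paste0("_atom_site.",
             c("group_PDB", "id", "type_symbol", "label_atom_id",
               "label_alt_id", "label_comp_id", "label_asym_id",
               "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
               "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
               "B_iso_or_equiv", "auth_seq_id", "auth_comp_id",
               "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num"))
    )
    rows <- sprintf(
      "ATOM %d %s %s %s %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f %d %s %s %s 1",
      seq_len(nrow(s)), s$element, s$atom,
      ifelse(s$altloc == "", ".", s$altloc),
      s$resname, s$chain, ridx,
      ifelse(s$icode == "", "?", s$icode),
      s$x, s$y, s$z, s$occ, s$bfactor,
      s$resno, s$resname, s$chain, s$atom
    )
    writeLines(c(hdr, rows, "#"), path)
  }
  invisible(path)
}

#' Standardize a parsed structure
#'
#' Applies the fixed normalization used before any perturbation or metric:
#' hydrogens (and deuterium) are removed; for atoms with alternate
#' locations, the highest-occupancy altloc is kept (ties broken towards the
#' lexicographically first altloc, blank first); non-standard residues are
#' mapped through a fixed table (e.g. `MSE` to `MET`, renaming `SE` to
#' `SD`), and unmappable residues are dropped with a message. Residues are
#' re-ordered strictly by (chain, resno, icode). The operation is
#' idempotent.
#'
#' @param s structure tibble.
#' @return Standardized `struct_tbl`.
#' @export
standardize_structure <- function(s) {
  df <- tibble::as_tibble(s)
  df <- df[!(df$element %in% c("H", "D")), , drop = FALSE]
  # altloc resolution: per atom site keep max occupancy, ties -> first altloc
  ord <- order(df$chain, df$resno, df$icode, df$atom, -df$occ, df$altloc)
  df <- df[ord, , drop = FALSE]
  key <- paste(df$chain, df$resno, df$icode, df$atom, sep = "\r")
  df <- df[!duplicated(key), , drop = FALSE]
  df$altloc <- ""
  # non-standard residue mapping
  mapped <- df$resname %in% names(NONSTANDARD_MAP)
  if (any(mapped)) {
    for (old in unique(df$resname[mapped])) {
      sel <- df$resname == old
      ren <- NONSTANDARD_ATOM_MAP[[old]]
      if (!is.null(ren)) {
        hit <- sel & df$atom %in% names(ren)
        df$atom[hit] <- unname(ren[df$atom[hit]])
        df$element[hit] <- element_of(df$atom[hit])
      }
      df$resname[sel] <- NONSTANDARD_MAP[[old]]
    }
  }
  bad <- !(df$resname %in% AA3)
  if (any(bad)) {
    dropped <- unique(df$resname[bad])
    message("dropping unmappable residue type(s): ",
            paste(dropped, collapse = ", "))
    df <- df[!bad, , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no standard residues left after standardization",
                          call. = FALSE)
  # strict residue ordering; atoms within a residue in canonical order
  # (backbone first, then side chain alphabetically)
  rank <- match(df$atom, c("N", "CA", "C", "O", "CB"))
  rank[is.na(rank)] <- 6L
  df <- df[order(df$chain, df$resno, df$icode, rank, df$atom), , drop = FALSE]
  as_structure(df, s)
}

#' Extract one-letter sequences per chain
#'
#' One letter per resolved residue in chain order. Gaps in the author
#' numbering do not introduce gap characters: the sequence is gapless.
#' Unknown residue types emit `'X'` with a warning.
#'
#' @param s structure tibble.
#' @return Tibble with columns `id` (chain) and `sequence`.
#' @export
extract_sequence <- function(s) {
  rt <- residue_table(s)
  letter <- unname(AA1[rt$resname])
  if (anyNA(letter)) {
    warning("unknown residue type(s) emitted as 'X': ",
            paste(unique(rt$resname[is.na(letter)]), collapse = ", "))
    letter[is.na(letter)] <- "X"
  }
  rt$letter <- letter
  chains <- unique(rt$chain)
  tibble::tibble(
    id = chains,
    sequence = vapply(chains, function(ch) {
      paste(rt$letter[rt$chain == ch], collapse = "")
    }, character(1), USE.NAMES = FALSE)
  )
}

#' Write sequences as FASTA
#'
#' @param seqs tibble with `id` and `sequence` columns (as returned by
#'   [extract_sequence()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::AAStringSet(stats::setNames(seqs$sequence, seqs$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
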