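# Orchestration: score a model against a reference with the full metric
# suite, run target x perturbation experiment grids, and talk to external
# structure predictors through a minimal adapter contract.

metric_or_na <- function(expr) {
  tryCatch(suppressMessages(expr), error = function(e) NA_real_)
}

#' Score a model against a reference with the full metric suite
#'
#' Computes TM-score, all-atom and side-chain RMSD, rectified C-alpha
#' RMSD, global lDDT, chi-angle MAEs, the skipped-atom count and the
#' fraction of model residues with stereochemistry violations. Metrics
#' that are undefined for the given pair (e.g. side-chain RMSD of a
#' backbone-only model) are reported as `NA`, never as zero.
#'
#' @param ref,model structure tibbles.
#' @param mapping a `residue_mapping`; defaults to [map_residues()]
#'   (diagonal for identical sequences, Needleman-Wunsch otherwise).
#' @param alpha_cap rectification cap for [alpha_rmsd()] (Angstrom).
#' @param lddt_args list of extra arguments forwarded to [lddt()].
#' @return A one-row `struct_eval` tibble.
#' @export
evaluate_structures <- function(ref, model, mapping = NULL, alpha_cap = 5,
                                lddt_args = list()) {
  if (is.null(mapping)) mapping <- map_residues(ref, model)
  rmsd_all <- metric_or_na(all_atom_rmsd(ref, model, mapping, "all"))
  n_skipped <- if (is.na(rmsd_all)) NA_integer_ else
    as.integer(attr(rmsd_all, "n_skipped"))
  lddt_res <- tryCatch(
    suppressMessages(do.call(lddt, c(list(ref, model, mapping), lddt_args))),
    error = function(e) NULL)
  chi <- tryCatch(suppressMessages(chi_mae(ref, model, mapping)),
                  error = function(e) NULL)
  chi_by_idx <- rep(NA_real_, 4)
  if (!is.null(chi)) chi_by_idx[chi$per_chi$chi] <- chi$per_chi$mae
  viol <- tryCatch(suppressMessages(stereochemistry_check(model)),
                   error = function(e) NULL)
  n_res_model <- nrow(residue_table(model))
  out <- tibble::tibble(
    tm = metric_or_na(as.numeric(tm_score(ref, model, mapping))),
    rmsd_all = as.numeric(rmsd_all),
    rmsd_sidechain = metric_or_na(
      as.numeric(all_atom_rmsd(ref, model, mapping, "sidechain"))),
    alpha_rmsd = metric_or_na(alpha_rmsd(ref, model, mapping, cap = alpha_cap)),
    lddt_global = if (is.null(lddt_res)) NA_real_ else lddt_res$global,
    chi_mae_overall = if (is.null(chi)) NA_real_ else chi$overall,
    chi_mae_1 = chi_by_idx[1], chi_mae_2 = chi_by_idx[2],
    chi_mae_3 = chi_by_idx[3], chi_mae_4 = chi_by_idx[4],
    n_skipped_atoms = n_skipped,
    stereo_violation_fraction = if (is.null(viol)) NA_real_ else
      length(unique(viol$res_idx)) / n_res_model
  )
  class(out) <- c("struct_eval", class(out))
  out
}

#' Configure an experiment run
#'
#' @param targets a character vector of structure file paths, a list of
#'   structure tibbles, or an integer vector of residue counts (fixtures
#'   generated with [make_globule()]). Paths are validated up front.
#' @param perturbations list of [perturbation_spec()] objects.
#' @param predictor optional external-predictor adapter: a command
#'   template with `{template}`, `{sequence}` and `{workdir}`
#'   placeholders (see [predictor_adapter()]).
#' @param output_dir where perturbed/refined structures and tables are
#'   written; `NULL` keeps everything in memory.
#' @param seed global RNG seed; every random draw in the run derives from
#'   it together with the target and perturbation indices.
#' @param alpha_cap,lddt_args metric options forwarded to
#'   [evaluate_structures()].
#' @param predictor_timeout adapter timeout in seconds.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(targets, perturbations, predictor = NULL,
                              output_dir = NULL, seed = 1, alpha_cap = 5,
                              lddt_args = list(), predictor_timeout = 300) {
  if (is.character(targets)) {
    missing <- targets[!file.exists(targets)]
    if (length(missing) > 0) {
      stop("target file(s) not found: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  if (inherits(perturbations, "perturbation_spec")) {
    perturbations <- list(perturbations)
  }
  stopifnot(all(vapply(perturbations, inherits, TRUE, "perturbation_spec")))
  structure(list(targets = targets, perturbations = perturbations,
                 predictor = predictor, output_dir = output_dir,
                 seed = seed, alpha_cap = alpha_cap, lddt_args = lddt_args,
                 predictor_timeout = predictor_timeout),
            class = "experiment_config")
}

load_target <- function(targets, i, seed) {
  t <- if (is.list(targets)) targets[[i]] else targets[i]
  if (is_structure(t)) return(list(s = t, id = paste0("target_", i)))
  if (is.character(t)) {
    return(list(s = standardize_structure(read_structure(t)),
                id = sub("\\.[^.]*$", "", basename(t))))
  }
  if (is.numeric(t)) {
    return(list(s = make_globule(as.integer(t), seed = seed),
                id = sprintf("fixture_L%d", as.integer(t))))
  }
  stop("unsupported target specification", call. = FALSE)
}

#' Run a target x perturbation experiment grid
#'
#' For every target and perturbation: applies the perturbation, evaluates
#' the perturbed template against the original (stage `"perturbed"`), and,
#' if a predictor adapter is configured, invokes it on the perturbed
#' template and evaluates its output (stage `"refined"`). Adapter
#' failures mark the row `status = "failed"` with the adapter's message
#' and the run continues. Given the same config (including `seed`) the
#' report is identical between runs.
#'
#' @param config an [experiment_config()].
#' @return A `probe_report` tibble: one row per (target, perturbation,
#'   stage) with metric columns and `status`/`message`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  out_dir <- config$output_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  n_t <- if (is.list(config$targets)) length(config$targets)
         else length(config$targets)
  rows <- list()
  for (i in seq_len(n_t)) {
    tgt_seed <- (config$seed * 10007L + i * 101L) %% 2147483647L
    tgt <- load_target(config$targets, i, tgt_seed)
    for (j in seq_along(config$perturbations)) {
      spec <- config$perturbations[[j]]
      pseed <- (tgt_seed + j * 131L) %% 2147483647L
      pert <- perturb_structure(tgt$s, spec, seed = pseed)
      if (!is.null(out_dir)) {
        write_structure(pert, file.path(out_dir,
          sprintf("%s__%s.pdb", tgt$id, gsub("[^A-Za-z0-9_.-]", "_",
                                             spec$label))), "pdb")
      }
      # perturbations preserve residue correspondence, so the perturbed
      # stage is scored under the identity mapping (sequence alignment
      # would be meaningless for identity-erasing templates)
      ev <- evaluate_structures(tgt$s, pert,
                                mapping = identity_mapping(
                                  nrow(residue_table(tgt$s))),
                                alpha_cap = config$alpha_cap,
                                lddt_args = config$lddt_args)
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(target = tgt$id, perturbation = spec$label,
                       stage = "perturbed", status = "ok", message = ""),
        tibble::as_tibble(ev))
      if (!is.null(config$predictor)) {
        wd <- file.path(if (is.null(out_dir)) tempdir() else out_dir,
                        sprintf("adapter_%d_%d", i, j))
        refined <- tryCatch({
          dir.create(wd, showWarnings = FALSE, recursive = TRUE)
          tpath <- file.path(wd, "template.pdb")
          spath <- file.path(wd, "sequence.fasta")
          write_structure(pert, tpath, "pdb")
          write_fasta(extract_sequence(tgt$s), spath)
          mpath <- predictor_adapter(config$predictor, tpath, spath, wd,
                                     timeout = config$predictor_timeout)
          m <- standardize_structure(read_structure(mpath))
          cov <- nrow(residue_table(m)) / nrow(residue_table(pert))
          if (cov < 0.5) {
            stop("predictor output covers only ",
                 sprintf("%.0f%%", 100 * cov), " of the template residues")
          }
          m
        }, error = function(e) e)
        if (inherits(refined, "error")) {
          na_ev <- evaluate_structures(tgt$s, tgt$s)
          na_ev[1, ] <- lapply(na_ev, function(x) x[NA_integer_])
          rows[[length(rows) + 1]] <- dplyr::bind_cols(
            tibble::tibble(target = tgt$id, perturbation = spec$label,
                           stage = "refined", status = "failed",
                           message = conditionMessage(refined)),
            tibble::as_tibble(na_ev))
        } else {
          ev2 <- evaluate_structures(tgt$s, refined,
                                     alpha_cap = config$alpha_cap,
                                     lddt_args = config$lddt_args)
          rows[[length(rows) + 1]] <- dplyr::bind_cols(
            tibble::tibble(target = tgt$id, perturbation = spec$label,
                           stage = "refined", status = "ok", message = ""),
            tibble::as_tibble(ev2))
        }
      }
    }
  }
  report <- dplyr::bind_rows(rows)
  class(report) <- c("probe_report", class(report))
  attr(report, "config") <- config
  if (!is.null(out_dir)) {
    utils::write.csv(report, file.path(out_dir, "report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summarize_experiment(report),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  report
}

#' Aggregate an experiment report
#'
#' Mean and standard deviation of every metric per (perturbation, stage),
#' over rows with `status == "ok"`.
#'
#' @param report a `probe_report` from [run_experiment()].
#' @return Long-format tibble (`perturbation`, `stage`, `metric`, `mean`,
#'   `sd`, `n`).
#' @export
summarize_experiment <- function(report) {
  metrics <- c("tm", "rmsd_all", "rmsd_sidechain", "alpha_rmsd",
               "lddt_global", "chi_mae_overall", "chi_mae_1", "chi_mae_2",
               "chi_mae_3", "chi_mae_4", "stereo_violation_fraction")
  ok <- dplyr::filter(tibble::as_tibble(report), .data$status == "ok")
  long <- tidyr::pivot_longer(
    ok[, c("perturbation", "stage", metrics)],
    dplyr::all_of(metrics), names_to = "metric", values_to = "value")
  dplyr::summarise(
    dplyr::group_by(long, .data$perturbation, .data$stage, .data$metric),
    mean = mean(.data$value, na.rm = TRUE),
    sd = stats::sd(.data$value, na.rm = TRUE),
    n = sum(!is.na(.data$value)), .groups = "drop")
}

#' Invoke an external structure predictor through a shell adapter
#'
#' The adapter contract: `command` is a shell command template containing
#' the placeholders `{template}`, `{sequence}` and `{workdir}`. The
#' command must exit 0 and deposit exactly one structure file (`*.pdb` or
#' `*.cif`) under `workdir`; that file's path is returned. Everything a
#' specific predictor needs (model selection, recycling, relaxation
#' settings) lives inside the adapter script, not in this package.
#'
#' @param command adapter command template.
#' @param template_path,sequence_path,workdir substituted into the
#'   template.
#' @param timeout seconds before the adapter is abandoned.
#' @return Path to the deposited structure file.
#' @export
predictor_adapter <- function(command, template_path, sequence_path, workdir,
                              timeout = 300) {
  cmd <- gsub("{template}", template_path, command, fixed = TRUE)
  cmd <- gsub("{sequence}", sequence_path, cmd, fixed = TRUE)
  cmd <- gsub("{workdir}", workdir, cmd, fixed = TRUE)
  before <- list.files(workdir, pattern = "\\.(pdb|cif)$", full.names = TRUE)
  status <- system(cmd, timeout = timeout)
  if (status != 0) {
    stop("predictor adapter exited with status ", status, call. = FALSE)
  }
  after <- list.files(workdir, pattern = "\\.(pdb|cif)$", full.names = TRUE)
  produced <- setdiff(after, before)
  if (length(produced) != 1) {
    stop("predictor adapter must deposit exactly one structure file, found ",
         length(produced), call. = FALSE)
  }
  info <- file.info(produced)
  if (is.na(info$size) || info$size == 0) {
    stop("predictor adapter produced an empty structure file", call. = FALSE)
  }
  produced
}
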