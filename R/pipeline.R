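#' Per-domain stability comparison of two models
#'
#' The end-to-end trajectory-comparison stage: for every domain of the
#' partition it computes per-replicate RMSD series (backbone atoms,
#' reference = frame 1), summarises each model's RMSD over the trailing
#' analysis window, and runs the smoothing + DTW + delta-RMSD/f protocol
#' over all ordered replicate pairs (model 1 as MD1, model 2 as MD2). Rows
#' with `f` at or below the configured significance threshold are flagged:
#' for a destabilised model 2 the aligned series run higher and f collapses
#' towards 0.
#'
#' @param model_1,model_2 Lists of [trajectory()] replicates, or character
#'   vectors of multi-model PDB paths (all paths are checked before any
#'   computation starts).
#' @param partition A [domain_partition()] naming the domains to analyse.
#' @param config A [ts_compare_config()].
#' @param atoms Atom-name set measured (default [backbone_atoms]).
#' @param fit `"local"` (fit each domain onto itself; isolates internal
#'   deformation) or `"global"` (fit the whole structure, measure the
#'   domain; also captures rigid displacement of the domain).
#' @param model_names Length-2 labels used in the output.
#' @return Tibble of class `phstab_stability`, one row per domain:
#'   `domain`, `n_res`, `rmsd_1`, `rmsd_1_sd`, `rmsd_2`, `rmsd_2_sd`,
#'   `delta_rmsd`, `delta_sd`, `f`, `significant`.
#' @export
run_stability <- function(model_1, model_2, partition,
                          config = ts_compare_config(),
                          atoms = backbone_atoms,
                          fit = c("local", "global"),
                          model_names = c("model_1", "model_2")) {
  fit <- match.arg(fit)
  load_set <- function(x) {
    if (is.character(x)) {
      missing_files <- x[!file.exists(x)]
      if (length(missing_files) > 0) {
        abort(paste0(
          "replicate file(s) not found: ",
          paste(missing_files, collapse = ", ")
        ))
      }
      lapply(x, read_multimodel_pdb)
    } else {
      stopifnot(all(vapply(x, inherits, logical(1), "phstab_traj")))
      x
    }
  }
  set1 <- load_set(model_1)
  set2 <- load_set(model_2)

  domain_rows <- function(dname) {
    ranges <- partition[partition$domain == dname, , drop = FALSE]
    sel_of <- function(traj) {
      m <- select_atoms(traj$topology, residues = ranges, atoms = atoms)
      f <- if (fit == "local") {
        m
      } else {
        select_atoms(traj$topology, residues = partition, atoms = atoms)
      }
      list(measure = m, fit = f)
    }
    series_of <- function(trajs) {
      lapply(trajs, function(tr) {
        s <- sel_of(tr)
        rmsd_series(tr, measure = s$measure, fit = s$fit)
      })
    }
    s1 <- series_of(set1)
    s2 <- series_of(set2)
    window_vals <- function(slist) {
      unlist(lapply(slist, function(s) tail(s$rmsd, config$expected_length)))
    }
    v1 <- window_vals(s1)
    v2 <- window_vals(s2)
    cmp <- compare_models(s1, s2, config)
    tibble::tibble(
      domain = dname,
      n_res = domain_residue_count(partition, dname),
      rmsd_1 = mean(v1), rmsd_1_sd = stats::sd(v1),
      rmsd_2 = mean(v2), rmsd_2_sd = stats::sd(v2),
      delta_rmsd = cmp$delta_rmsd, delta_sd = cmp$delta_sd, f = cmp$f,
      significant = cmp$f <= config$significance_f
    )
  }
  out <- purrr::map_dfr(unique(partition$domain), domain_rows)
  attr(out, "model_names") <- model_names
  attr(out, "config") <- config
  class(out) <- c("phstab_stability", class(out))
  out
}

#' Consolidated text report over completed stages
#'
#' Formats any combination of stage outputs (stability table, SSP ranking,
#' NAC summaries, kinetic fits) into a plain-text report; every table is
#' echoed as parseable CSV lines so numbers trace to the stage outputs
#' without recomputation.
#'
#' @param stages Named list of stage outputs (data frames or fitted
#'   objects). Must be non-empty.
#' @param file Optional path; when given the report is also written there.
#' @param seed Optional seed to echo in the header.
#' @return Character vector of report lines, invisibly when `file` is set.
#' @export
run_report <- function(stages, file = NULL, seed = NULL) {
  if (length(stages) == 0) abort("nothing to report")
  if (is.null(names(stages)) || any(names(stages) == "")) {
    abort("every stage must be named")
  }
  fmt_stage <- function(x, nm) {
    header <- sprintf("== %s ==", nm)
    body <- if (inherits(x, "phstab_infit") || inherits(x, "phstab_mmfit")) {
      df <- tidy(x)
      c(
        paste(names(df), collapse = ","),
        apply(df, 1, paste, collapse = ",")
      )
    } else if (is.data.frame(x)) {
      c(
        paste(names(x), collapse = ","),
        apply(x, 1, function(r) paste(trimws(format(r)), collapse = ","))
      )
    } else {
      utils::capture.output(print(x))
    }
    c(header, body, "")
  }
  lines <- c(
    "phstab stage report",
    if (!is.null(seed)) sprintf("seed: %d", seed),
    "",
    unlist(purrr::imap(stages, fmt_stage))
  )
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
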