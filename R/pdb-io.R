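#' Read a multi-model PDB file as a trajectory
#'
#' Parses MODEL/ENDMDL blocks of a standard PDB file into a [trajectory()].
#' ATOM and HETATM records are both kept, so crystallographic waters and
#' ions survive the round trip. A file without MODEL records yields a
#' one-frame trajectory. Every model must present the same atom roster
#' (same names, residues and chains in the same order); the first model
#' that deviates is named in the error.
#'
#' @param path Path to a PDB file.
#' @param frame_interval Time between models, ps (default 5, the usual MD
#'   snapshot spacing).
#' @return A [trajectory()].
#' @export
read_multimodel_pdb <- function(path, frame_interval = 5) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- which(trimws(rec) == "MODEL")

  if (length(model_starts) == 0) {
    blocks <- list(which(is_atom))
  } else {
    model_ends <- which(trimws(rec) == "ENDMDL")
    if (length(model_ends) < length(model_starts)) {
      model_ends <- c(model_ends, length(lines))
    }
    blocks <- purrr::map2(model_starts, model_ends, function(s, e) {
      w <- which(is_atom)
      w[w > s & w < e]
    })
  }
  if (length(blocks) == 0 || length(blocks[[1]]) == 0) {
    abort("no ATOM/HETATM records found")
  }

  parse_block <- function(idx) {
    ln <- lines[idx]
    xyz <- cbind(
      suppressWarnings(as.numeric(substr(ln, 31, 38))),
      suppressWarnings(as.numeric(substr(ln, 39, 46))),
      suppressWarnings(as.numeric(substr(ln, 47, 54)))
    )
    bad <- which(!stats::complete.cases(xyz))
    if (length(bad) > 0) {
      abort(sprintf("unparseable coordinate at line %d", idx[bad[1]]))
    }
    list(
      roster = paste(
        trimws(substr(ln, 13, 16)), trimws(substr(ln, 18, 20)),
        trimws(substr(ln, 22, 22)), trimws(substr(ln, 23, 26))
      ),
      topology = tibble::tibble(
        chain = trimws(substr(ln, 22, 22)),
        resno = as.integer(trimws(substr(ln, 23, 26))),
        resname = trimws(substr(ln, 18, 20)),
        atom = trimws(substr(ln, 13, 16)),
        element = trimws(substr(ln, 77, 78))
      ),
      xyz = xyz
    )
  }

  first <- parse_block(blocks[[1]])
  frames <- vector("list", length(blocks))
  frames[[1]] <- first$xyz
  if (length(blocks) > 1) {
    for (m in 2:length(blocks)) {
      b <- parse_block(blocks[[m]])
      if (!identical(b$roster, first$roster)) {
        abort(sprintf("atom roster of model %d does not match model 1", m))
      }
      frames[[m]] <- b$xyz
    }
  }
  top <- first$topology
  if (all(top$element == "")) {
    top$element <- guess_element(top$atom)
  }
  trajectory(top, frames, frame_interval = frame_interval)
}

# element symbol from a PDB atom name (strip digits/primes, take leading letter;
# two-letter names like CA-the-ion are resolved by the residue name upstream)
guess_element <- function(atom_names) {
  stripped <- gsub("[0-9']", "", atom_names)
  toupper(substr(stripped, 1, 1))
}

#' Write a trajectory as a multi-model PDB file
#'
#' Emits one MODEL/ENDMDL block per frame with standard fixed columns
#' (coordinates at 0.001 Angstrom precision). Waters and ions in the
#' topology are written as HETATM records.
#'
#' @param traj A [trajectory()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_multimodel_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "phstab_traj"))
  if (length(traj$frames) == 0) abort("no frames")
  top <- traj$topology
  het <- top$resname %in% c("HOH", "WAT", "CA", "MG", "ZN", "NA", "CL", "K")
  record <- ifelse(het, "HETATM", "ATOM  ")
  # names shorter than 4 characters start in column 14
  name_fmt <- ifelse(nchar(top$atom) < 4, paste0(" ", top$atom), top$atom)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(traj$frames)) {
    fr <- traj$frames[[m]]
    writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(sprintf(
      "%s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      record, seq_len(nrow(top)), name_fmt, top$resname, top$chain,
      top$resno, fr[, 1], fr[, 2], fr[, 3], 1, 0, top$element
    ), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
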