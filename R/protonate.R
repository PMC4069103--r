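#' Protonation-state assignment at a target pH
#'
#' Fixed-protonation MD treats pH by freezing each titratable group's state
#' at the start of the simulation: a residue is protonated iff its predicted
#' pKa is strictly higher than the target pH. Manual overrides take
#' precedence over the rule (buried carboxylates in carboxyl-carboxylate
#' pairs and catalytic N-termini are the classic cases that need one) and
#' every decision records whether it came from the rule or an override.
#'
#' The proton lands on the conventional heavy atom of each residue type:
#' OD for Asp, OE for Glu, NZ for Lys, NE for Arg, NE2 (or ND1) for His,
#' N for the N-terminus and O for the C-terminus.
#'
#' @param pka_table Tibble with columns `chain`, `resno`, `resname`, `pka`
#'   (see [read_pka_table()] / [default_model_pkas()]).
#' @param target_ph Target pH (finite scalar).
#' @param overrides Optional tibble with columns `chain`, `resno`, `resname`,
#'   `state` ("protonated"/"deprotonated") and `ph` (numeric, or NA/"any"
#'   for pH-independent overrides).
#'
#' @return Tibble with one row per titratable residue: the key columns,
#'   `pka`, `state`, `proton_target_atom`, `source` ("rule" or "override").
#' @export
#' @examples
#' tab <- tibble::tibble(chain = "B", resno = 482, resname = "GLU", pka = 13.8)
#' assign_protonation(tab, target_ph = 7.5)
assign_protonation <- function(pka_table, target_ph, overrides = NULL) {
  stopifnot(is.finite(target_ph))
  tab <- tibble::as_tibble(pka_table)
  # rule: protonated iff pKa strictly greater than the target pH
  out <- dplyr::mutate(tab,
    state = ifelse(.data$pka > target_ph, "protonated", "deprotonated"),
    proton_target_atom = proton_target(.data$resname),
    source = "rule"
  )
  if (!is.null(overrides) && nrow(overrides) > 0) {
    ov <- tibble::as_tibble(overrides)
    if (!"ph" %in% names(ov)) ov$ph <- NA
    ov$ph_any <- is.na(suppressWarnings(as.numeric(ov$ph))) |
      tolower(as.character(ov$ph)) == "any"
    ov_num <- suppressWarnings(as.numeric(ov$ph))
    applies <- ov$ph_any | (!is.na(ov_num) & ov_num == target_ph)
    ov <- ov[applies, , drop = FALSE]
    for (r in seq_len(nrow(ov))) {
      hit <- which(out$chain == ov$chain[r] & out$resno == ov$resno[r] &
        out$resname == ov$resname[r])
      if (length(hit) == 0) {
        abort(sprintf(
          "override refers to absent residue %s/%d/%s",
          ov$chain[r], ov$resno[r], ov$resname[r]
        ))
      }
      out$state[hit] <- ov$state[r]
      out$source[hit] <- "override"
    }
  }
  out
}

# conventional protonation target atom per residue type; neutral His default
# tautomer is NE2-protonated
proton_target <- function(resname) {
  map <- c(
    ASP = "OD", GLU = "OE", LYS = "NZ", ARG = "NE", HIS = "NE2",
    CYS = "SG", TYR = "OH", NTERM = "N", CTERM = "O"
  )
  unname(map[resname])
}

#' Model pKa table from a topology
#'
#' A fallback pKa table built from textbook model values per residue type
#' (Asp 3.8, Glu 4.2, His 6.0, Lys 10.5, Arg 12.5, Cys 8.3, Tyr 10.1,
#' N-terminus 8.0, C-terminus 3.5), for use when no structure-aware pKa
#' prediction is supplied. Non-titratable residues are omitted.
#'
#' @param topology Topology tibble (or [trajectory()]).
#' @return pKa tibble (`chain`, `resno`, `resname`, `pka`).
#' @export
default_model_pkas <- function(topology) {
  if (inherits(topology, "phstab_traj")) topology <- topology$topology
  model <- c(
    ASP = 3.8, GLU = 4.2, HIS = 6.0, LYS = 10.5, ARG = 12.5,
    CYS = 8.3, TYR = 10.1, NTERM = 8.0, CTERM = 3.5
  )
  res <- dplyr::distinct(topology, .data$chain, .data$resno, .data$resname)
  res <- res[res$resname %in% names(model), , drop = FALSE]
  dplyr::mutate(res, pka = unname(model[.data$resname]))
}

#' Read a whitespace-delimited pKa table
#'
#' Expected columns: chain, residue number, residue name, pKa — the format
#' any pKa predictor's output is trivially converted to. Lines starting
#' with `#` are ignored.
#'
#' @param path File path.
#' @return pKa tibble.
#' @export
read_pka_table <- function(path) {
  df <- utils::read.table(path,
    col.names = c("chain", "resno", "resname", "pka"),
    colClasses = c("character", "integer", "character", "numeric"),
    comment.char = "#"
  )
  tibble::as_tibble(df)
}
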