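#' Near-attack-conformation criteria
#'
#' A substrate pose is productive (near to attack) when three active-site
#' distances are all at most their cutoffs: the catalytic serine's
#' gamma-oxygen to the substrate carbonyl carbon, and the substrate carbonyl
#' oxygen to each of the two oxyanion-hole nitrogens (a backbone amide N and
#' a side-chain amide N). Residues are fixed by the enzyme; substrate atom
#' names vary by compound and are supplied here.
#'
#' @param ser_og,sub_c,sub_o,oxy_backbone_n,oxy_sidechain_n Atom specs,
#'   each `list(chain=, resno=, atom=)`. Defaults name the penicillin
#'   acylase active site (Ser beta-1 OG, Ala beta-69 N, Asn beta-241 ND2)
#'   with a substrate residue on chain "S".
#' @param max_distance Distance cutoff in Angstrom applied to all three
#'   measures (default 3.5, inclusive).
#' @return List of class `phstab_nac_criteria`.
#' @export
nac_criteria <- function(ser_og = list(chain = "B", resno = 1, atom = "OG"),
                         sub_c = list(chain = "S", resno = 1, atom = "C7"),
                         sub_o = list(chain = "S", resno = 1, atom = "O7"),
                         oxy_backbone_n = list(chain = "B", resno = 69, atom = "N"),
                         oxy_sidechain_n = list(chain = "B", resno = 241, atom = "ND2"),
                         max_distance = 3.5) {
  stopifnot(max_distance > 0)
  structure(
    list(
      ser_og = ser_og, sub_c = sub_c, sub_o = sub_o,
      oxy_backbone_n = oxy_backbone_n, oxy_sidechain_n = oxy_sidechain_n,
      max_distance = max_distance
    ),
    class = "phstab_nac_criteria"
  )
}

resolve_atom <- function(topology, spec) {
  i <- which(topology$chain == spec$chain & topology$resno == spec$resno &
    topology$atom == spec$atom)
  if (length(i) != 1) {
    abort(sprintf(
      "atom %s/%s/%s missing or ambiguous in topology",
      spec$chain, spec$resno, spec$atom
    ))
  }
  i
}

#' Is a frame in a near-attack conformation?
#'
#' @param frame_coords Coordinates of one frame.
#' @param topology Topology tibble.
#' @param criteria [nac_criteria()].
#' @return TRUE iff all three distances are <= the cutoff (inclusive).
#' @export
nac_check <- function(frame_coords, topology, criteria = nac_criteria()) {
  at <- lapply(
    criteria[c("ser_og", "sub_c", "sub_o", "oxy_backbone_n", "oxy_sidechain_n")],
    resolve_atom,
    topology = topology
  )
  d <- function(i, j) sqrt(sum((frame_coords[i, ] - frame_coords[j, ])^2))
  d(at$ser_og, at$sub_c) <= criteria$max_distance &&
    d(at$sub_o, at$oxy_backbone_n) <= criteria$max_distance &&
    d(at$sub_o, at$oxy_sidechain_n) <= criteria$max_distance
}

#' Percentage of productive frames in a trajectory window
#'
#' Evaluates [nac_check()] over a trailing window (default: the last 1000
#' frames, 5 ns at 5 ps per frame) and reports the productive percentage.
#'
#' @param traj A [trajectory()].
#' @param criteria [nac_criteria()].
#' @param window_frames Trailing window length (default `min(1000, n)`).
#' @return Percentage in \[0, 100\].
#' @export
nac_fraction <- function(traj, criteria = nac_criteria(), window_frames = NULL) {
  stopifnot(inherits(traj, "phstab_traj"))
  n <- length(traj$frames)
  window_frames <- window_frames %||% min(1000L, n)
  if (window_frames < 1 || window_frames > n) abort("invalid frame window")
  idx <- seq.int(n - window_frames + 1L, n)
  hits <- vapply(idx, function(k) {
    nac_check(traj$frames[[k]], traj$topology, criteria)
  }, logical(1))
  100 * mean(hits)
}

#' Summarise NAC fractions over independent replicates
#'
#' Mean and sample standard deviation (n - 1) over per-replicate productive
#' percentages, the form in which replicate MD runs are reported.
#'
#' @param fractions Numeric vector of per-replicate percentages (>= 2).
#' @return One-row tibble: `mean`, `sd`, `n`.
#' @export
nac_replicate_summary <- function(fractions) {
  if (length(fractions) < 2) {
    abort("at least 2 replicates required (SD undefined otherwise)")
  }
  if (any(fractions < 0 | fractions > 100)) abort("fractions must be in [0, 100]")
  tibble::tibble(
    mean = mean(fractions),
    sd = stats::sd(fractions),
    n = length(fractions)
  )
}
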