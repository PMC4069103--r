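#' Geometric hydrogen-bond acceptance criteria
#'
#' A donor-H...acceptor triple is accepted when the donor-acceptor distance
#' is at most `max_distance` and the donor-hydrogen-acceptor angle lies in
#' `angle_range` (boundaries inclusive).
#'
#' @param max_distance Donor-acceptor distance cutoff, Angstrom (default 3.5).
#' @param angle_range Donor-H-acceptor angle window, degrees
#'   (default `c(145, 180)`).
#' @return List of class `phstab_hbond_criteria`.
#' @export
hbond_criteria <- function(max_distance = 3.5, angle_range = c(145, 180)) {
  stopifnot(
    max_distance > 0,
    length(angle_range) == 2,
    angle_range[1] >= 0, angle_range[1] <= angle_range[2], angle_range[2] <= 180
  )
  structure(
    list(max_distance = max_distance, angle_range = angle_range),
    class = "phstab_hbond_criteria"
  )
}

# donor/acceptor chemistry roster: N and O heavy atoms act as acceptors; an
# N or O with a covalently attached hydrogen (within 1.25 A) acts as a donor.
# Water oxygens are both. Sulfur is excluded.
polar_heavy <- function(topology) {
  el <- topology$element
  el[el == "" | is.na(el)] <- guess_element(topology$atom[el == "" | is.na(el)])
  which(el %in% c("N", "O"))
}

hydrogen_idx <- function(topology) {
  el <- topology$element
  el[el == "" | is.na(el)] <- guess_element(topology$atom[el == "" | is.na(el)])
  which(el == "H")
}

#' Detect hydrogen bonds in a single frame
#'
#' Enumerates all donor-hydrogen-acceptor triples that pass both geometric
#' criteria. Donors are N/O atoms with an attached hydrogen (attachment =
#' covalent distance below 1.25 Angstrom in this frame); acceptors are all
#' N/O atoms; water oxygens act as both. When the topology carries no
#' hydrogens, strict mode refuses and points to the heavy-atom fallback
#' (`mode = "heavy"`), which accepts on donor-acceptor distance alone — the
#' appropriate screen for crystal structures that have not been protonated —
#' and marks every hit with `angle = NA`.
#'
#' @param frame_coords `n x 3` coordinate matrix for one frame.
#' @param topology Topology tibble.
#' @param criteria [hbond_criteria()].
#' @param donors,acceptors Optional integer index vectors restricting the
#'   donor / acceptor rosters.
#' @param mode `"strict"` (require hydrogens) or `"heavy"` (distance-only
#'   fallback).
#' @return Tibble with one row per bond: donor/hydrogen/acceptor atom keys,
#'   `distance` (D-A, Angstrom) and `angle` (D-H-A, degrees; NA in heavy
#'   mode).
#' @export
detect_hbonds <- function(frame_coords, topology, criteria = hbond_criteria(),
                          donors = NULL, acceptors = NULL,
                          mode = c("strict", "heavy")) {
  mode <- match.arg(mode)
  polar <- polar_heavy(topology)
  hyd <- hydrogen_idx(topology)
  donors <- donors %||% polar
  acceptors <- acceptors %||% polar
  donors <- intersect(donors, polar)
  acceptors <- intersect(acceptors, polar)

  empty <- tibble::tibble(
    donor_chain = character(), donor_resno = integer(),
    donor_resname = character(), donor_atom = character(),
    hydrogen = character(),
    acceptor_chain = character(), acceptor_resno = integer(),
    acceptor_resname = character(), acceptor_atom = character(),
    distance = numeric(), angle = numeric()
  )
  if (length(donors) == 0 || length(acceptors) == 0) {
    return(empty)
  }

  if (mode == "strict") {
    if (length(hyd) == 0) {
      abort(paste(
        "topology contains no hydrogens; use mode = 'heavy' for the",
        "distance-only fallback on unprotonated structures"
      ))
    }
    # attach each hydrogen to its nearest polar heavy atom within 1.25 A
    rows <- purrr::map_dfr(hyd, function(h) {
      dv <- sweep(frame_coords[donors, , drop = FALSE], 2, frame_coords[h, ])
      dd <- sqrt(rowSums(dv^2))
      j <- which.min(dd)
      if (dd[j] > 1.25) {
        return(NULL)
      }
      d <- donors[j]
      av <- sweep(frame_coords[acceptors, , drop = FALSE], 2, frame_coords[d, ])
      da <- sqrt(rowSums(av^2))
      cand <- which(acceptors != d & da <= criteria$max_distance)
      if (length(cand) == 0) {
        return(NULL)
      }
      ang <- vapply(acceptors[cand], function(a) {
        v1 <- frame_coords[d, ] - frame_coords[h, ]
        v2 <- frame_coords[a, ] - frame_coords[h, ]
        cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      }, numeric(1))
      ok <- ang >= criteria$angle_range[1] & ang <= criteria$angle_range[2]
      if (!any(ok)) {
        return(NULL)
      }
      acc <- acceptors[cand][ok]
      tibble::tibble(
        donor_chain = topology$chain[d], donor_resno = topology$resno[d],
        donor_resname = topology$resname[d], donor_atom = topology$atom[d],
        hydrogen = topology$atom[h],
        acceptor_chain = topology$chain[acc],
        acceptor_resno = topology$resno[acc],
        acceptor_resname = topology$resname[acc],
        acceptor_atom = topology$atom[acc],
        distance = da[cand][ok], angle = ang[ok]
      )
    })
  } else {
    pairs <- expand.grid(d = donors, a = acceptors)
    pairs <- pairs[pairs$d != pairs$a, , drop = FALSE]
    # same-residue pairs are covalent neighbours, not hydrogen bonds
    same_res <- topology$chain[pairs$d] == topology$chain[pairs$a] &
      topology$resno[pairs$d] == topology$resno[pairs$a]
    pairs <- pairs[!same_res, , drop = FALSE]
    dd <- sqrt(rowSums((frame_coords[pairs$d, , drop = FALSE] -
      frame_coords[pairs$a, , drop = FALSE])^2))
    keep <- dd <= criteria$max_distance
    pairs <- pairs[keep, , drop = FALSE]
    rows <- tibble::tibble(
      donor_chain = topology$chain[pairs$d], donor_resno = topology$resno[pairs$d],
      donor_resname = topology$resname[pairs$d], donor_atom = topology$atom[pairs$d],
      hydrogen = NA_character_,
      acceptor_chain = topology$chain[pairs$a],
      acceptor_resno = topology$resno[pairs$a],
      acceptor_resname = topology$resname[pairs$a],
      acceptor_atom = topology$atom[pairs$a],
      distance = dd[keep], angle = NA_real_
    )
    attr(rows, "heavy_atom_mode") <- TRUE
  }
  if (nrow(rows) == 0) empty else rows
}

#' Fraction of frames in which a residue pair is hydrogen bonded
#'
#' A pair counts as bonded in a frame when at least one qualifying
#' donor-H-acceptor triple exists between the two residues (donor side
#' first). This is the per-pair persistence used to summarise how reliably
#' an interaction such as a buried carboxyl-carboxylate bond survives a
#' simulation.
#'
#' @param traj A [trajectory()].
#' @param donor_residue,acceptor_residue Lists `list(chain=, resno=)`.
#' @param criteria [hbond_criteria()].
#' @param frames Optional integer vector of frame indices (default: all).
#' @param mode Passed to [detect_hbonds()].
#' @return Fraction in \[0, 1\].
#' @export
hbond_persistence <- function(traj, donor_residue, acceptor_residue,
                              criteria = hbond_criteria(), frames = NULL,
                              mode = "strict") {
  stopifnot(inherits(traj, "phstab_traj"))
  frames <- frames %||% seq_along(traj$frames)
  top <- traj$topology
  d_idx <- which(top$chain == donor_residue$chain & top$resno == donor_residue$resno)
  a_idx <- which(top$chain == acceptor_residue$chain & top$resno == acceptor_residue$resno)
  if (length(d_idx) == 0 || length(a_idx) == 0) abort("pair atoms absent from topology")
  hits <- vapply(frames, function(k) {
    hb <- detect_hbonds(traj$frames[[k]], top, criteria,
      donors = d_idx, acceptors = a_idx, mode = mode
    )
    nrow(hb) > 0
  }, logical(1))
  mean(hits)
}

#' Extract the hydrogen-bond network around seed residues
#'
#' Collects all hydrogen bonds incident to the seed residues, pulling in
#' their direct partners, and (optionally) bridging waters: a water bonded
#' to a seed contributes its remaining bonds too, so water-mediated links
#' one hop away are visible in the network.
#'
#' @param frame_coords Coordinates of one frame.
#' @param topology Topology tibble.
#' @param criteria [hbond_criteria()].
#' @param seed_residues Tibble/data frame with columns `chain`, `resno`.
#' @param include_waters Follow one water hop (default TRUE).
#' @param mode Passed to [detect_hbonds()].
#' @return List of class `phstab_hbnet` with elements `nodes` (tibble of
#'   residue keys) and `edges` (bond tibble).
#' @export
extract_network <- function(frame_coords, topology, criteria = hbond_criteria(),
                            seed_residues, include_waters = TRUE,
                            mode = "strict") {
  all_bonds <- detect_hbonds(frame_coords, topology, criteria, mode = mode)
  seed_key <- paste(seed_residues$chain, seed_residues$resno)
  dkey <- paste(all_bonds$donor_chain, all_bonds$donor_resno)
  akey <- paste(all_bonds$acceptor_chain, all_bonds$acceptor_resno)
  touches_seed <- dkey %in% seed_key | akey %in% seed_key
  edges <- all_bonds[touches_seed, , drop = FALSE]
  if (include_waters) {
    water <- c("HOH", "WAT")
    bridge <- unique(c(
      dkey[touches_seed][all_bonds$donor_resname[touches_seed] %in% water],
      akey[touches_seed][all_bonds$acceptor_resname[touches_seed] %in% water]
    ))
    via_water <- (dkey %in% bridge & all_bonds$donor_resname %in% water) |
      (akey %in% bridge & all_bonds$acceptor_resname %in% water)
    edges <- dplyr::distinct(rbind(edges, all_bonds[via_water, , drop = FALSE]))
  }
  nodes <- dplyr::distinct(dplyr::bind_rows(
    tibble::tibble(
      chain = edges$donor_chain, resno = edges$donor_resno,
      resname = edges$donor_resname
    ),
    tibble::tibble(
      chain = edges$acceptor_chain, resno = edges$acceptor_resno,
      resname = edges$acceptor_resname
    )
  ))
  if (nrow(nodes) == 0) {
    # isolated seeds still appear as nodes
    nodes <- dplyr::distinct(tibble::tibble(
      chain = seed_residues$chain, resno = as.integer(seed_residues$resno),
      resname = NA_character_
    ))
  }
  structure(list(nodes = nodes, edges = edges), class = "phstab_hbnet")
}

#' @export
print.phstab_hbnet <- function(x, ...) {
  cat(sprintf(
    "<phstab_hbnet> %d node(s), %d edge(s)\n",
    nrow(x$nodes), nrow(x$edges)
  ))
  invisible(x)
}

net_pair_keys <- function(net) {
  e <- net$edges
  if (nrow(e) == 0) {
    return(character(0))
  }
  a <- paste(e$donor_chain, e$donor_resno)
  b <- paste(e$acceptor_chain, e$acceptor_resno)
  # undirected residue-pair key
  unique(ifelse(a < b, paste(a, "--", b), paste(b, "--", a)))
}

#' Compare two hydrogen-bond networks
#'
#' Set-difference report keyed by unordered residue pair: which
#' interactions are shared, lost (in `net_a` only) and gained (in `net_b`
#' only). This is how a network's collapse between two conditions is
#' quantified.
#'
#' @param net_a,net_b Networks from [extract_network()].
#' @return List with character vectors `shared`, `lost`, `gained`.
#' @export
diff_networks <- function(net_a, net_b) {
  ka <- net_pair_keys(net_a)
  kb <- net_pair_keys(net_b)
  list(
    shared = intersect(ka, kb),
    lost = setdiff(ka, kb),
    gained = setdiff(kb, ka)
  )
}
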