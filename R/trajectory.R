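#' Trajectory objects
#'
#' A trajectory couples a fixed atom topology with an ordered stack of
#' coordinate frames, the object every structural statistic in this package
#' consumes. The topology is a tibble with one row per atom (columns
#' `chain`, `resno`, `resname`, `atom`, `element`); each frame is an
#' `n_atoms x 3` matrix of coordinates in Angstrom. `frame_interval` is the
#' time between consecutive frames in picoseconds (MD snapshots are
#' typically saved every 5 ps).
#'
#' @param topology Tibble describing the atoms (see Details).
#' @param frames List of `n_atoms x 3` numeric matrices, one per frame.
#' @param frame_interval Time between frames, ps. Must be positive.
#'
#' @return An object of class `phstab_traj`.
#' @export
#' @examples
#' top <- tibble::tibble(
#'   chain = "A", resno = 1:3, resname = "GLY",
#'   atom = "CA", element = "C"
#' )
#' xyz <- matrix(rnorm(9), 3, 3)
#' trajectory(top, list(xyz, xyz + 1))
trajectory <- function(topology, frames, frame_interval = 5) {
  stopifnot(is.data.frame(topology), is.list(frames))
  required <- c("chain", "resno", "resname", "atom", "element")
  missing_cols <- setdiff(required, names(topology))
  if (length(missing_cols) > 0) {
    abort(paste0("topology lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (any(topology$resno < 1)) abort("residue numbers must be >= 1")
  if (length(frames) < 1) abort("no frames")
  n <- nrow(topology)
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    if (!is.matrix(fr) || nrow(fr) != n || ncol(fr) != 3) {
      abort(sprintf("frame %d does not have one 3-D position per topology atom", k))
    }
    if (!all(is.finite(fr))) abort(sprintf("frame %d contains non-finite coordinates", k))
  }
  if (!is.numeric(frame_interval) || frame_interval <= 0) {
    abort("frame_interval must be > 0")
  }
  structure(
    list(
      topology = tibble::as_tibble(topology),
      frames = frames,
      frame_interval = frame_interval
    ),
    class = "phstab_traj"
  )
}

#' @export
print.phstab_traj <- function(x, ...) {
  cat(sprintf(
    "<phstab_traj> %d atoms, %d frame(s), %.3g ps/frame\n",
    nrow(x$topology), length(x$frames), x$frame_interval
  ))
  chains <- unique(x$topology$chain)
  cat("  chains:", paste(chains, collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.phstab_traj <- function(x) length(x$frames)

#' Frame times of a trajectory
#' @param traj A [trajectory()].
#' @return Numeric vector of frame times in ps (frame 1 at t = 0).
#' @export
frame_times <- function(traj) {
  stopifnot(inherits(traj, "phstab_traj"))
  (seq_along(traj$frames) - 1) * traj$frame_interval
}

#' @describeIn trajectory Long tabular view: one row per atom per frame with
#'   columns `frame`, `time_ps`, the topology columns and `x`, `y`, `z`.
#' @param x A `phstab_traj`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.phstab_traj <- function(x, ...) {
  times <- frame_times(x)
  purrr::map2_dfr(x$frames, seq_along(x$frames), function(fr, k) {
    dplyr::mutate(x$topology,
      frame = k, time_ps = times[k],
      x = fr[, 1], y = fr[, 2], z = fr[, 3],
      .before = 1
    )
  })
}

# ---- atom selection ---------------------------------------------------------

#' Backbone and C-alpha atom-name sets
#'
#' The "protein backbone" convention used throughout is {N, CA, C, O}
#' (amide nitrogen, alpha carbon, carbonyl carbon and carbonyl oxygen).
#' @export
backbone_atoms <- c("N", "CA", "C", "O")

#' Select atoms from a topology
#'
#' Resolves a chain / residue-range / atom-name filter against a topology to
#' a deterministic, order-preserving vector of atom row indices.
#'
#' @param topology Topology tibble (or a [trajectory()], whose topology is used).
#' @param chain Optional chain label(s) to keep.
#' @param residues Optional residue filter: either a numeric vector of
#'   residue numbers or a data frame of inclusive ranges with columns
#'   `chain`, `start`, `end` (as produced by [domain_partition()]).
#' @param atoms Optional atom-name set, e.g. [backbone_atoms] or `"CA"`.
#'
#' @return Integer vector of atom indices (possibly empty).
#' @export
select_atoms <- function(topology, chain = NULL, residues = NULL, atoms = NULL) {
  if (inherits(topology, "phstab_traj")) topology <- topology$topology
  keep <- rep(TRUE, nrow(topology))
  if (!is.null(chain)) keep <- keep & topology$chain %in% chain
  if (!is.null(residues)) {
    if (is.data.frame(residues)) {
      in_range <- rep(FALSE, nrow(topology))
      for (r in seq_len(nrow(residues))) {
        in_range <- in_range |
          (topology$chain == residues$chain[r] &
            topology$resno >= residues$start[r] &
            topology$resno <= residues$end[r])
      }
      keep <- keep & in_range
    } else {
      keep <- keep & topology$resno %in% residues
    }
  }
  if (!is.null(atoms)) keep <- keep & topology$atom %in% atoms
  which(keep)
}

# ---- domain partitions ------------------------------------------------------

#' Domain partitions
#'
#' A domain partition names structural domains as lists of inclusive
#' per-chain residue ranges. Ranges belonging to one domain may be
#' discontinuous in sequence (the Ntn-hydrolase alpha-beta-beta-alpha core
#' domain, for instance, is assembled from three separate stretches of the
#' beta chain).
#'
#' @param ... Named arguments, one per domain. Each value is a list of
#'   ranges, each range a vector/list `list("B", 1, 72)` meaning chain "B",
#'   residues 1 to 72 inclusive.
#'
#' @return A tibble with columns `domain`, `chain`, `start`, `end`, of class
#'   `phstab_domains`.
#' @export
#' @examples
#' domain_partition(B2 = list(list("B", 73, 145)))
domain_partition <- function(...) {
  doms <- list(...)
  if (length(doms) == 0 || is.null(names(doms)) || any(names(doms) == "")) {
    abort("every domain must be named")
  }
  rows <- purrr::imap_dfr(doms, function(ranges, nm) {
    purrr::map_dfr(ranges, function(r) {
      tibble::tibble(
        domain = nm,
        chain = as.character(r[[1]]),
        start = as.integer(r[[2]]),
        end = as.integer(r[[3]])
      )
    })
  })
  if (any(rows$start > rows$end)) abort("range start must be <= end")
  # ranges within one domain must not overlap
  by_dom <- split(rows, paste(rows$domain, rows$chain))
  for (d in by_dom) {
    if (nrow(d) > 1) {
      d <- d[order(d$start), ]
      if (any(d$start[-1] <= d$end[-nrow(d)])) {
        abort(sprintf("overlapping ranges in domain %s", d$domain[1]))
      }
    }
  }
  structure(rows, class = c("phstab_domains", class(rows)))
}

#' Number of residues in a domain
#'
#' Sums `end - start + 1` over a domain's ranges.
#'
#' @param partition A [domain_partition()].
#' @param domain_name Name of the domain.
#' @return Integer residue count.
#' @export
domain_residue_count <- function(partition, domain_name) {
  rows <- partition[partition$domain == domain_name, , drop = FALSE]
  if (nrow(rows) == 0) abort(sprintf("unknown domain '%s'", domain_name))
  sum(rows$end - rows$start + 1L)
}

#' Structural domains of E. coli penicillin acylase
#'
#' The CATH-derived five-domain partition of the penicillin acylase
#' heterodimer (alpha chain = "A", beta chain = "B"): the mainly-helical A1
#' and A2 domains of the alpha chain, the catalytic
#' alpha-beta-beta-alpha-core B1 assembled from three discontinuous beta-chain
#' stretches, the mainly-beta B2 and the mainly-helical B3. The `Total` entry
#' covers the complete heterodimer (209 + 557 residues).
#'
#' @return A [domain_partition()].
#' @export
#' @examples
#' domain_residue_count(ecpa_domains(), "B1") # 302
ecpa_domains <- function() {
  domain_partition(
    Total = list(list("A", 1, 209), list("B", 1, 557)),
    A1 = list(list("A", 3, 149)),
    A2 = list(list("A", 150, 179)),
    B1 = list(list("B", 1, 72), list("B", 146, 290), list("B", 452, 536)),
    B2 = list(list("B", 73, 145)),
    B3 = list(list("B", 291, 451))
  )
}

# ---- superposition ----------------------------------------------------------

#' Least-squares rigid-body superposition
#'
#' Finds the proper rotation and translation minimising the RMSD between two
#' paired coordinate sets (the Kabsch algorithm via singular value
#' decomposition; reflections are excluded).
#'
#' @param mobile,reference `n x 3` matrices of paired coordinates, n >= 3.
#' @return List with elements `rotation` (3x3, det +1), `translation`
#'   (length-3), and `rmsd` (Angstrom). The transform maps mobile
#'   coordinates onto the reference: `x %*% rotation + translation`.
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3) {
    abort("mobile and reference must be paired n x 3 matrices")
  }
  n <- nrow(mobile)
  if (n < 3) abort("superposition needs at least 3 atoms")
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  xm <- sweep(mobile, 2, cm)
  xr <- sweep(reference, 2, cr)
  h <- crossprod(xm, xr) # covariance
  sv <- svd(h)
  if (sv$d[2] < 1e-12) abort("degenerate (collinear) geometry")
  d <- sign(det(sv$v %*% t(sv$u)))
  corr <- diag(c(1, 1, d))
  rot <- sv$u %*% corr %*% t(sv$v)
  trans <- cr - drop(cm %*% rot)
  fitted <- xm %*% rot
  rmsd <- sqrt(mean(rowSums((fitted - xr)^2)))
  list(rotation = rot, translation = trans, rmsd = rmsd)
}

apply_transform <- function(coords, fit) {
  sweep(coords %*% fit$rotation, 2, fit$translation, `+`)
}

# ---- RMSD / RMSF ------------------------------------------------------------

#' Per-frame RMSD series of a trajectory
#'
#' For every frame, superposes `fit` atoms onto the reference frame and
#' reports the RMSD of the `measure` atoms after applying that transform.
#' Fitting and measuring on the same selection (the default) isolates a
#' domain's internal deformation; fitting on a larger (e.g. whole-protein)
#' selection also captures rigid displacement of the measured region
#' relative to the rest of the structure.
#'
#' @param traj A [trajectory()].
#' @param measure Integer atom indices (see [select_atoms()]) whose RMSD is
#'   reported.
#' @param fit Atom indices used for the superposition; defaults to `measure`.
#' @param reference_frame Frame index used as the reference structure
#'   (default 1, the start of the production run).
#' @param label Optional series label carried into the output.
#'
#' @return Tibble with columns `frame`, `time_ps`, `rmsd` (and `label` if
#'   given). RMSD in Angstrom.
#' @export
rmsd_series <- function(traj, measure, fit = measure, reference_frame = 1,
                        label = NULL) {
  stopifnot(inherits(traj, "phstab_traj"))
  if (length(measure) == 0 || length(fit) < 3) {
    abort("empty selection (fit needs >= 3 atoms)")
  }
  ref <- traj$frames[[reference_frame]]
  times <- frame_times(traj)
  vals <- vapply(seq_along(traj$frames), function(k) {
    fr <- traj$frames[[k]]
    sp <- superpose(fr[fit, , drop = FALSE], ref[fit, , drop = FALSE])
    moved <- apply_transform(fr[measure, , drop = FALSE], sp)
    sqrt(mean(rowSums((moved - ref[measure, , drop = FALSE])^2)))
  }, numeric(1))
  out <- tibble::tibble(frame = seq_along(vals), time_ps = times, rmsd = vals)
  if (!is.null(label)) out$label <- label
  out
}

#' Per-residue RMSF profile
#'
#' Root mean square fluctuation of selected atoms about their mean position
#' over a trailing window of frames. Frames in the window are first aligned
#' to the window's first frame on the same selection, then the time-average
#' structure is computed and `RMSF_i = sqrt(mean_t |x_i(t) - <x_i>|^2)`.
#'
#' @param traj A [trajectory()].
#' @param selection Atom indices (conventionally C-alpha atoms).
#' @param window_frames Number of trailing frames to analyse; defaults to
#'   `min(2000, n_frames)` (10 ns at 5 ps/frame).
#' @param align Superpose frames before averaging (default TRUE). Disable
#'   only for constructed test geometries.
#'
#' @return Tibble with columns `chain`, `resno`, `resname`, `atom`, `rmsf`.
#' @export
rmsf_profile <- function(traj, selection, window_frames = NULL, align = TRUE) {
  stopifnot(inherits(traj, "phstab_traj"))
  n <- length(traj$frames)
  window_frames <- window_frames %||% min(2000L, n)
  if (window_frames > n) abort("window larger than trajectory")
  if (length(selection) == 0) abort("empty selection")
  idx <- seq.int(n - window_frames + 1L, n)
  ref <- traj$frames[[idx[1]]][selection, , drop = FALSE]
  stack <- lapply(idx, function(k) {
    fr <- traj$frames[[k]][selection, , drop = FALSE]
    if (align) {
      sp <- superpose(fr, ref)
      fr <- apply_transform(fr, sp)
    }
    fr
  })
  mean_xyz <- Reduce(`+`, stack) / length(stack)
  sq <- Reduce(`+`, lapply(stack, function(fr) rowSums((fr - mean_xyz)^2)))
  rmsf <- sqrt(sq / length(stack))
  dplyr::mutate(
    traj$topology[selection, c("chain", "resno", "resname", "atom")],
    rmsf = rmsf
  )
}

#' Distance between two named atoms in a frame
#'
#' Convenience for measurements such as the carboxyl-carboxylate O-O
#' separation of an acidic pair.
#'
#' @param traj A [trajectory()].
#' @param atom_a,atom_b Lists `list(chain=, resno=, atom=)` naming the atoms.
#' @param frame Frame index (default 1).
#' @return Distance in Angstrom.
#' @export
atom_distance <- function(traj, atom_a, atom_b, frame = 1) {
  find1 <- function(a) {
    i <- select_atoms(traj$topology, chain = a$chain, residues = a$resno, atoms = a$atom)
    if (length(i) != 1) {
      abort(sprintf("atom %s/%s/%s not uniquely resolvable", a$chain, a$resno, a$atom))
    }
    i
  }
  fr <- traj$frames[[frame]]
  sqrt(sum((fr[find1(atom_a), ] - fr[find1(atom_b), ])^2))
}
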