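# Seeded generators for every input class the pipeline consumes. All are
# pure functions of their arguments plus the seed (RNG state is restored
# afterwards), and their outputs validate against the consuming module's
# container invariants.

#' Generate a synthetic multi-domain trajectory
#'
#' Builds a pseudo-protein of one chain per domain (one CA pseudo-atom per
#' residue on a deterministic lattice, domains 30 Angstrom apart) and a
#' frame stack in which every atom fluctuates i.i.d. Gaussian about its
#' reference position while drifting domains additionally translate
#' coherently along +x by `drift` Angstrom per frame. Frame 1 carries no
#' drift, so with `sigma = 0` the RMSD of a drifting domain against frame 1
#' under an external fit is exactly `drift * (t - 1)` at frame `t` — the
#' "ascending RMSD trend" signature of a destabilised domain with an
#' analytically known magnitude.
#'
#' @param domains Named list, one entry per domain:
#'   `list(n_atoms =, sigma =, drift =)` with `sigma` the per-coordinate
#'   fluctuation SD (Angstrom) and `drift` the coherent translation rate
#'   (Angstrom/frame, 0 = stationary).
#' @param n_frames Number of frames (>= 2; default 2000, i.e. 10 ns at
#'   5 ps/frame).
#' @param frame_interval ps per frame (default 5).
#' @param seed RNG seed (mandatory).
#' @return A [trajectory()]; the domain partition is attached as attribute
#'   `"domains"` and chain labels are "A", "B", ... in domain order.
#' @export
gen_trajectory <- function(domains = list(
                             stable = list(n_atoms = 30, sigma = 0.3, drift = 0),
                             drifting = list(n_atoms = 30, sigma = 0.3, drift = 0.001)
                           ),
                           n_frames = 2000, frame_interval = 5, seed) {
  if (missing(seed)) abort("seed is mandatory")
  stopifnot(n_frames >= 2, length(domains) >= 1, !is.null(names(domains)))
  chains <- LETTERS[seq_along(domains)]

  # deterministic reference lattice: CA spacing 3.8 A, domains offset in y
  ref_list <- purrr::imap(domains, function(d, nm) {
    k <- which(names(domains) == nm)
    i <- seq_len(d$n_atoms) - 1
    cbind(
      3.8 * (i %% 10),
      30 * (k - 1) + 3.8 * (i %/% 10),
      rep(0, d$n_atoms)
    )
  })
  ref <- do.call(rbind, ref_list)
  top <- purrr::imap_dfr(domains, function(d, nm) {
    k <- which(names(domains) == nm)
    tibble::tibble(
      chain = chains[k], resno = seq_len(d$n_atoms),
      resname = "GLY", atom = "CA", element = "C"
    )
  })
  sigma_atom <- unlist(purrr::map2(
    domains, seq_along(domains),
    function(d, k) rep(d$sigma, d$n_atoms)
  ))
  drift_atom <- unlist(purrr::map2(
    domains, seq_along(domains),
    function(d, k) rep(d$drift %||% 0, d$n_atoms)
  ))
  n_atoms <- nrow(ref)

  frames <- withr::with_seed(seed, {
    lapply(seq_len(n_frames), function(t) {
      noise <- matrix(stats::rnorm(n_atoms * 3), n_atoms, 3) * sigma_atom
      shift <- cbind(drift_atom * (t - 1), 0, 0)
      ref + noise + shift
    })
  })
  traj <- trajectory(top, frames, frame_interval = frame_interval)
  part <- do.call(domain_partition, setNames(
    purrr::map(seq_along(domains), function(k) {
      list(list(chains[k], 1, domains[[k]]$n_atoms))
    }),
    names(domains)
  ))
  attr(traj, "domains") <- part
  traj
}

#' Generate a labelled alignment with planted subfamily-specific columns
#'
#' Background columns share one consensus residue across all subfamilies;
#' each sequence carries the consensus with probability
#' `background_conservation`, otherwise a random other residue. Planted
#' columns instead have a distinct consensus residue per subfamily, kept
#' with probability `1 - noise`. Gap-free; labels "S1", "S2", ...; the
#' template is the first sequence of subfamily 1.
#'
#' @param seqs_per_subfamily Integer vector, one entry per subfamily
#'   (default `c(20, 10, 10, 4)`, mirroring the sizes of the four
#'   penicillin-acylase subfamilies).
#' @param n_columns Alignment length (default 60).
#' @param n_planted Number of planted specificity columns (default 3).
#' @param background_conservation Background consensus retention rate
#'   (default 0.9).
#' @param noise Substitution rate at planted columns (default 0.1).
#' @param seed RNG seed (mandatory).
#' @return A [labeled_msa()]; planted column indices in attribute
#'   `"planted_columns"`.
#' @export
gen_labeled_msa <- function(seqs_per_subfamily = c(20, 10, 10, 4),
                            n_columns = 60, n_planted = 3,
                            background_conservation = 0.9, noise = 0.1,
                            seed) {
  if (missing(seed)) abort("seed is mandatory")
  stopifnot(
    n_planted < n_columns, length(seqs_per_subfamily) >= 2,
    background_conservation >= 0, background_conservation <= 1,
    noise >= 0, noise <= 1
  )
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  n_sub <- length(seqs_per_subfamily)
  labels <- rep(paste0("S", seq_len(n_sub)), seqs_per_subfamily)
  n_seq <- length(labels)

  withr::with_seed(seed, {
    planted <- sort(sample(n_columns, n_planted))
    bg_consensus <- sample(aa, n_columns, replace = TRUE)
    # distinct per-subfamily consensus at planted columns
    planted_consensus <- t(vapply(planted, function(j) sample(aa, n_sub),
      character(n_sub)
    ))
    m <- matrix("", n_seq, n_columns)
    for (s in seq_len(n_seq)) {
      sub_k <- match(labels[s], paste0("S", seq_len(n_sub)))
      for (j in seq_len(n_columns)) {
        pk <- match(j, planted)
        if (!is.na(pk)) {
          cons <- planted_consensus[pk, sub_k]
          keep_p <- 1 - noise
        } else {
          cons <- bg_consensus[j]
          keep_p <- background_conservation
        }
        m[s, j] <- if (stats::runif(1) < keep_p) {
          cons
        } else {
          sample(setdiff(aa, cons), 1)
        }
      }
    }
    seqs <- setNames(apply(m, 1, paste, collapse = ""), paste0("seq", seq_len(n_seq)))
    msa <- labeled_msa(seqs, labels, template = "seq1")
    attr(msa, "planted_columns") <- planted
    msa
  })
}

#' Generate exponential activity-decay data
#'
#' Model curve `A_0 * exp(-k_in * t)` plus homoscedastic Gaussian noise of
#' SD `noise_sd * A_0`; negative draws are truncated at 0.
#'
#' @param k_in True inactivation constant, min^-1 (default 0.0026).
#' @param A_0 Initial activity (default 100).
#' @param times Sampling times in minutes (default every 25 min to 600).
#' @param noise_sd Noise SD as a fraction of `A_0` (default 0.02).
#' @param seed RNG seed (mandatory).
#' @return Tibble (`time`, `activity`) with the true parameters as
#'   attribute `"truth"`.
#' @export
gen_decay <- function(k_in = 0.0026, A_0 = 100, times = seq(0, 600, by = 25),
                      noise_sd = 0.02, seed) {
  if (missing(seed)) abort("seed is mandatory")
  stopifnot(noise_sd >= 0)
  withr::with_seed(seed, {
    mu <- A_0 * exp(-k_in * times)
    act <- pmax(mu + stats::rnorm(length(times), sd = noise_sd * A_0), 0)
    out <- tibble::tibble(time = times, activity = act)
    attr(out, "truth") <- c(k_in = k_in, A_0 = A_0)
    out
  })
}

#' Generate Michaelis-Menten initial-rate data
#'
#' Model curve `k_cat * E_0 * S / (K_M + S)` plus Gaussian noise whose SD
#' is `noise_sd` times the signal at each point (relative measurement
#' error, the usual behaviour of initial-rate assays); negative draws are
#' truncated at 0.
#'
#' @param k_cat True turnover number, s^-1 (default 25.0).
#' @param K_M True Michaelis constant, uM (default 25.0).
#' @param enzyme_conc `E_0` in uM (default 1).
#' @param substrate Substrate grid in uM (default 12 points spanning
#'   0.5-50, the usual assay range).
#' @param noise_sd Noise SD as a fraction of the per-point signal
#'   (default 0.02).
#' @param seed RNG seed (mandatory).
#' @return Tibble (`substrate`, `rate`) with truth attribute.
#' @export
gen_mm <- function(k_cat = 25.0, K_M = 25.0, enzyme_conc = 1,
                   substrate = c(0.5, 1, 2, 3.5, 5, 7.5, 10, 15, 20, 30, 40, 50),
                   noise_sd = 0.02, seed) {
  if (missing(seed)) abort("seed is mandatory")
  stopifnot(noise_sd >= 0, all(substrate > 0))
  withr::with_seed(seed, {
    vmax <- k_cat * enzyme_conc
    mu <- vmax * substrate / (K_M + substrate)
    rate <- pmax(mu + stats::rnorm(length(substrate), sd = noise_sd * mu), 0)
    out <- tibble::tibble(substrate = substrate, rate = rate)
    attr(out, "truth") <- c(k_cat = k_cat, K_M = K_M)
    out
  })
}

#' Generate a minimal donor-H-acceptor trajectory
#'
#' A three-atom triad whose geometry satisfies the hydrogen-bond criteria
#' in a Bernoulli(`p_bonded`) subset of frames: conforming frames place the
#' acceptor at a 2.9 Angstrom donor-acceptor distance and a 165 degree
#' donor-H-acceptor angle; non-conforming frames stretch the distance to
#' 4.5 Angstrom at the same angle.
#'
#' @param p_bonded Probability a frame is bonded.
#' @param n_frames Number of frames.
#' @param seed RNG seed (mandatory).
#' @param frame_interval ps per frame (default 5).
#' @return A [trajectory()] (donor residue 1 "DON", acceptor residue 2
#'   "ACC", chain "X"); the per-frame bond indicator is attribute
#'   `"bonded"`.
#' @export
gen_hbond_frames <- function(p_bonded, n_frames, seed, frame_interval = 5) {
  if (missing(seed)) abort("seed is mandatory")
  stopifnot(p_bonded >= 0, p_bonded <= 1, n_frames >= 1)
  top <- tibble::tibble(
    chain = "X", resno = c(1L, 1L, 2L), resname = c("DON", "DON", "ACC"),
    atom = c("N", "H", "O"), element = c("N", "H", "O")
  )
  triad <- function(da_dist) {
    # N at origin, H on +x; acceptor set so the D-H-A angle is 165 degrees
    # and |N-O| equals da_dist
    ang <- 15 * pi / 180
    cc <- cos(ang)
    r <- -cc + sqrt(cc^2 + (da_dist^2 - 1))
    rbind(
      c(0, 0, 0),
      c(1, 0, 0),
      c(1 + r * cc, r * sin(ang), 0)
    )
  }
  on_frame <- triad(2.9)
  off_frame <- triad(4.5)
  withr::with_seed(seed, {
    bonded <- stats::runif(n_frames) < p_bonded
    frames <- lapply(bonded, function(b) if (b) on_frame else off_frame)
    traj <- trajectory(top, frames, frame_interval = frame_interval)
    attr(traj, "bonded") <- bonded
    traj
  })
}
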