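#' Labelled multiple sequence alignment
#'
#' Aligned sequences plus a subfamily label per sequence, the substrate of
#' subfamily-specific-position analysis. One sequence is the designated
#' template: positions are ultimately reported as residue numbers of that
#' protein.
#'
#' @param sequences Named character vector of equal-length aligned
#'   sequences (gap = "-").
#' @param labels Character vector of subfamily labels, one per sequence
#'   (recycled names are matched by position).
#' @param template Id (name) of the template sequence.
#' @param template_chain Chain label attached to reported template
#'   positions (default "B").
#' @return Tibble (`id`, `seq`, `subfamily`) of class `phstab_msa` with the
#'   template id as an attribute.
#' @export
labeled_msa <- function(sequences, labels, template = names(sequences)[1],
                        template_chain = "B") {
  stopifnot(length(sequences) == length(labels), length(sequences) >= 2)
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1) abort("aligned sequences must share one length")
  if (!template %in% names(sequences)) abort("template id not among sequences")
  if (any(is.na(labels) | labels == "")) abort("every sequence must be labelled")
  if (!grepl("[^-]", sequences[[template]])) {
    abort("template must contain at least one non-gap column")
  }
  out <- tibble::tibble(
    id = names(sequences),
    seq = toupper(unname(sequences)),
    subfamily = as.character(labels)
  )
  structure(out,
    class = c("phstab_msa", class(out)),
    template = template, template_chain = template_chain
  )
}

msa_template <- function(msa) attr(msa, "template")

msa_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(msa$seq, ""))
  rownames(m) <- msa$id
  m
}

#' Pairwise identity of two aligned rows
#'
#' Matches divided by the number of columns where at least one row is
#' non-gap (columns gapped in both rows are ignored; a gap against a
#' residue counts as a mismatch).
#'
#' @param seq_a,seq_b Equal-length aligned strings.
#' @return Fraction in \[0, 1\].
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  if (length(a) != length(b)) abort("aligned rows must have equal length")
  informative <- !(a == "-" & b == "-")
  if (!any(informative)) {
    return(0)
  }
  sum(a == b & a != "-") / sum(informative)
}

#' Remove redundant sequences
#'
#' Greedy single-linkage clustering at pairwise identity strictly above
#' `threshold`; one representative is kept per cluster — the first sequence
#' in input order, except that the template is always retained (and
#' represents its own cluster).
#'
#' @param msa A [labeled_msa()].
#' @param threshold Identity threshold (default 0.95).
#' @return Filtered `phstab_msa`.
#' @export
filter_redundant <- function(msa, threshold = 0.95) {
  n <- nrow(msa)
  idm <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) idm[i, j] <- idm[j, i] <- pairwise_identity(msa$seq[i], msa$seq[j])
    }
  }
  adj <- idm > threshold
  # connected components = single-linkage clusters
  cluster <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(cluster[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      if (!is.na(cluster[v])) next
      cluster[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(cluster)))
    }
  }
  tmpl_row <- which(msa$id == msa_template(msa))
  keep <- vapply(unique(cluster), function(cl) {
    members <- which(cluster == cl)
    if (tmpl_row %in% members) tmpl_row else members[1]
  }, integer(1))
  out <- msa[sort(keep), , drop = FALSE]
  structure(out,
    class = class(msa),
    template = msa_template(msa), template_chain = attr(msa, "template_chain")
  )
}

# gapped Karlin-Altschul constants for BLOSUM62 with gap open 11 / extend 1
.ka_lambda <- 0.267
.ka_k <- 0.041

#' Alignment bit score per column against a template
#'
#' Globally aligns the (degapped) sequence to the (degapped) template with
#' BLOSUM62 (gap open 11, extend 1), converts the raw score to bits with
#' the standard gapped Karlin-Altschul constants, and divides by the number
#' of alignment columns. Used as a relatedness filter: sequences scoring
#' below a bits-per-column threshold are too distant to assume the
#' template's function. The discard rule is strict "less than", so a value
#' exactly at the threshold is retained.
#'
#' @param seq,template_seq Amino-acid strings (gaps tolerated, stripped).
#' @return Bits per alignment column.
#' @export
bits_per_column <- function(seq, template_seq) {
  s <- gsub("-", "", seq)
  t <- gsub("-", "", template_seq)
  if (nchar(s) == 0 || nchar(t) == 0) abort("empty sequence")
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(s), Biostrings::AAString(t),
    substitutionMatrix = data_env$BLOSUM62,
    gapOpening = 11, gapExtension = 1, type = "global"
  )
  raw <- Biostrings::score(aln)
  bits <- (.ka_lambda * raw - log(.ka_k)) / log(2)
  ncols <- Biostrings::nchar(Biostrings::alignedPattern(aln))
  bits / ncols
}

#' Drop sequences too distant from the template
#'
#' Applies the [bits_per_column()] relatedness filter: sequences sharing
#' strictly less than `threshold` bits per column with the template are
#' discarded. The template is always retained.
#'
#' @param msa A [labeled_msa()].
#' @param threshold Bits-per-column cutoff (default 0.25).
#' @return Filtered `phstab_msa`.
#' @export
filter_low_scoring <- function(msa, threshold = 0.25) {
  tmpl <- msa$seq[msa$id == msa_template(msa)]
  bits <- vapply(msa$seq, bits_per_column, numeric(1), template_seq = tmpl)
  keep <- bits >= threshold | msa$id == msa_template(msa)
  out <- msa[keep, , drop = FALSE]
  structure(out,
    class = class(msa),
    template = msa_template(msa), template_chain = attr(msa, "template_chain")
  )
}

# mutual information (bits) between residue identity and subfamily label
# over the non-gap entries of one column, optionally with the Miller-Madow
# small-sample bias correction applied to each entropy term
column_mi <- function(residues, labels, correction = c("miller-madow", "none")) {
  correction <- match.arg(correction)
  keep <- residues != "-"
  r <- residues[keep]
  l <- labels[keep]
  n <- length(r)
  if (n == 0) {
    return(0)
  }
  tab <- table(r, l)
  p <- tab / n
  px <- rowSums(p)
  py <- colSums(p)
  h <- function(pv) {
    pv <- pv[pv > 0]
    -sum(pv * log2(pv))
  }
  mi <- h(px) + h(py) - h(as.vector(p))
  if (correction == "miller-madow") {
    mx <- sum(px > 0)
    my <- sum(py > 0)
    mxy <- sum(p > 0)
    mi <- mi + ((mx - 1) + (my - 1) - (mxy - 1)) / (2 * n * log(2))
  }
  max(mi, 0)
}

#' Specificity score of an alignment column
#'
#' Measures how subfamily-specific a column is: the mutual information (in
#' bits) between residue identity and subfamily label over the column's
#' non-gap entries. A column perfectly conserved within each subfamily but
#' different between subfamilies scores highly; a column whose residue
#' distribution is independent of the labels scores 0. The Miller-Madow
#' small-sample correction is applied by default; `correction = "none"`
#' gives the plugin estimate (exactly 1 bit for two equal-size subfamilies
#' with two distinct fixed residues).
#'
#' @param column_residues Character vector of residues (one per sequence,
#'   gap = "-").
#' @param labels Subfamily labels, same length.
#' @param correction `"miller-madow"` (default) or `"none"`.
#' @return Non-negative score in bits.
#' @export
specificity_score <- function(column_residues, labels,
                              correction = c("miller-madow", "none")) {
  stopifnot(length(column_residues) == length(labels))
  nongap <- column_residues != "-"
  per_sub <- table(labels[nongap])
  if (length(per_sub) < 2 || any(per_sub < 2)) {
    abort("need >= 2 subfamilies with >= 2 non-gap residues each")
  }
  column_mi(column_residues, labels, match.arg(correction))
}

#' Per-subfamily residue frequencies of a column
#'
#' @param column_residues Character vector of residues (gap = "-").
#' @param labels Subfamily labels, same length.
#' @return Tibble (`subfamily`, `residue`, `pct`) sorted by descending
#'   frequency within subfamily; percentages are integer-rounded and gaps
#'   excluded.
#' @export
frequency_table <- function(column_residues, labels) {
  df <- tibble::tibble(residue = column_residues, subfamily = as.character(labels))
  df <- df[df$residue != "-", , drop = FALSE]
  out <- dplyr::count(df, .data$subfamily, .data$residue)
  out <- dplyr::mutate(dplyr::group_by(out, .data$subfamily),
    pct = as.integer(round(100 * .data$n / sum(.data$n)))
  )
  out <- dplyr::arrange(dplyr::ungroup(out), .data$subfamily, dplyr::desc(.data$n), .data$residue)
  out[, c("subfamily", "residue", "pct")]
}

#' Format a frequency table as "N(50%) D(50%)" strings
#'
#' @param freq Output of [frequency_table()].
#' @return Named character vector, one string per subfamily.
#' @export
format_frequencies <- function(freq) {
  sp <- split(freq, freq$subfamily)
  vapply(sp, function(d) {
    paste(sprintf("%s(%d%%)", d$residue, d$pct), collapse = " ")
  }, character(1))
}

#' Map an alignment column to a template residue number
#'
#' Counts non-gap template positions up to the column. A column gapped in
#' the template is unmapped (NA).
#'
#' @param msa A [labeled_msa()].
#' @param column_index Column number (1-based).
#' @return One-row tibble: `column`, `chain`, `resno` (NA if unmapped).
#' @export
map_column_to_template <- function(msa, column_index) {
  tmpl <- strsplit(msa$seq[msa$id == msa_template(msa)], "")[[1]]
  stopifnot(column_index >= 1, column_index <= length(tmpl))
  resno <- if (tmpl[column_index] == "-") {
    NA_integer_
  } else {
    sum(tmpl[seq_len(column_index)] != "-")
  }
  tibble::tibble(
    column = as.integer(column_index),
    chain = attr(msa, "template_chain") %||% "B",
    resno = resno
  )
}

#' Configuration for subfamily-specific-position analysis
#'
#' @param identity_threshold Redundancy filter threshold (default 0.95).
#' @param bits_threshold Relatedness filter, bits per column (default 0.25).
#' @param max_gap_fraction Columns with a higher gap fraction are skipped
#'   and flagged (default 0.5).
#' @param n_permutations Label permutations for the significance null
#'   (default 1000, minimum 100).
#' @param seed Mandatory RNG seed for the permutations.
#' @param correction Entropy bias correction for the score (see
#'   [specificity_score()]).
#' @return List of class `phstab_sspcfg`.
#' @export
ssp_config <- function(identity_threshold = 0.95, bits_threshold = 0.25,
                       max_gap_fraction = 0.5, n_permutations = 1000,
                       seed, correction = "miller-madow") {
  if (missing(seed)) abort("a permutation seed is mandatory")
  stopifnot(
    identity_threshold > 0, identity_threshold <= 1,
    max_gap_fraction >= 0, max_gap_fraction <= 1,
    n_permutations >= 100
  )
  structure(
    list(
      identity_threshold = identity_threshold,
      bits_threshold = bits_threshold,
      max_gap_fraction = max_gap_fraction,
      n_permutations = as.integer(n_permutations),
      seed = as.integer(seed),
      correction = correction
    ),
    class = "phstab_sspcfg"
  )
}

#' Rank subfamily-specific positions in a labelled alignment
#'
#' Scores every alignment column with [specificity_score()], attaches a
#' permutation p-value and Z-score (subfamily labels shuffled across
#' sequences, one shuffle shared by all columns per permutation, seeded),
#' maps columns to template residue numbers, formats per-subfamily residue
#' frequencies, and sorts by descending score. Columns exceeding the
#' configured gap fraction are excluded and flagged in the
#' `"skipped_columns"` attribute. The p-value uses the add-one estimator
#' `(1 + #(null >= observed)) / (1 + n_permutations)`.
#'
#' @param msa A [labeled_msa()] (already filtered; see [filter_redundant()]
#'   and [filter_low_scoring()]).
#' @param config An [ssp_config()].
#' @return Tibble sorted by descending score: `column`, `chain`, `resno`,
#'   `score`, `p_value`, `z`, plus one `freq_<subfamily>` string column per
#'   subfamily.
#' @export
rank_ssp <- function(msa, config) {
  stopifnot(inherits(config, "phstab_sspcfg"))
  if (length(unique(msa$subfamily)) < 2) abort("need at least 2 subfamilies")
  m <- msa_matrix(msa)
  labels <- msa$subfamily
  n_col <- ncol(m)
  gap_frac <- colMeans(m == "-")
  usable <- which(gap_frac <= config$max_gap_fraction)
  skipped <- setdiff(seq_len(n_col), usable)

  obs <- vapply(usable, function(j) {
    column_mi(m[, j], labels, config$correction)
  }, numeric(1))

  null_mat <- withr::with_seed(config$seed, {
    vapply(seq_len(config$n_permutations), function(p) {
      perm <- sample(labels)
      vapply(usable, function(j) column_mi(m[, j], perm, config$correction),
        numeric(1)
      )
    }, numeric(length(usable)))
  })
  null_mat <- matrix(null_mat, nrow = length(usable))
  p_val <- vapply(seq_along(usable), function(k) {
    (1 + sum(null_mat[k, ] >= obs[k])) / (1 + config$n_permutations)
  }, numeric(1))
  null_sd <- apply(null_mat, 1, stats::sd)
  z <- ifelse(null_sd > 0, (obs - rowMeans(null_mat)) / null_sd, NA_real_)

  mapping <- purrr::map_dfr(usable, map_column_to_template, msa = msa)
  freqs <- purrr::map_dfr(usable, function(j) {
    fmt <- format_frequencies(frequency_table(m[, j], labels))
    tibble::as_tibble(as.list(setNames(fmt, paste0("freq_", names(fmt)))))
  })
  out <- dplyr::bind_cols(
    mapping,
    tibble::tibble(score = obs, p_value = p_val, z = z),
    freqs
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$score))
  attr(out, "skipped_columns") <- skipped
  out
}
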