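#' Rank residues by fractional solvent accessibility
#'
#' Sorts residues ascending by fractional SASA (most buried first), breaking
#' ties by ascending residue number, and assigns consecutive ranks 1..N.
#' This burial axis is what variant-type counts are smoothed along.
#'
#' @param residues Residue tibble from [residue_sasa()] / [compute_sasa()]
#'   (columns `resnum` — or equivalently `position` — plus `restype` and
#'   `frac_sasa`).
#' @return A tibble with columns `rank`, `position`, `restype`, `frac_sasa`.
#' @export
rank_by_burial <- function(residues) {
  if (!"resnum" %in% names(residues) && "position" %in% names(residues)) {
    residues <- residues %>% rename(resnum = "position")
  }
  assert_columns(residues, c("resnum", "restype", "frac_sasa"), "`residues`")
  if (nrow(residues) == 0) stop_ardscan("empty_input", "no residues to rank")
  if (!all(is.finite(residues$frac_sasa))) {
    stop_ardscan("bad_coordinates", "fractional SASA values must be finite")
  }
  residues %>%
    arrange(.data$frac_sasa, .data$resnum) %>%
    mutate(rank = row_number()) %>%
    select("rank", position = "resnum", "restype", "frac_sasa")
}

#' Centered moving mean along the rank axis
#'
#' Smooths a series with a centered moving mean of the given window width.
#' At the edges the window is truncated and the divisor is the number of
#' in-window points, so a constant series is preserved exactly and every
#' output lies between the input's min and max. `window = 1` is the
#' identity. With the default width 20, an interior unit impulse smooths
#' to 1/20 = 0.05.
#'
#' @param counts Numeric vector ordered by rank.
#' @param window Integer window width (>= 1, default 20).
#' @return Numeric vector of the same length.
#' @export
smooth_counts <- function(counts, window = 20L) {
  if (length(counts) == 0) stop_ardscan("empty_input", "cannot smooth an empty series")
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop_ardscan("bad_window", "`window` must be >= 1")
  n <- length(counts)
  left <- (window - 1L) %/% 2L
  right <- window %/% 2L
  cs <- cumsum(c(0, counts))
  i <- seq_len(n)
  lo <- pmax(i - left, 1L)
  hi <- pmin(i + right, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Build a burial profile from SASA ranks and variant-type counts
#'
#' Joins per-position variant-type counts onto the burial ranking (positions
#' without any observed variant get 0 types), and smooths the counts along
#' the rank axis with [smooth_counts()]. Positions present in the spectra
#' but absent from the structure have no SASA and are dropped with a
#' warning.
#'
#' @param residues Residue tibble (see [rank_by_burial()]).
#' @param type_counts Per-position counts from [variant_type_count()]
#'   (columns `position`, `n_types`).
#' @param window Smoothing window width (default 20 ranks).
#' @return A tibble of class `burial_profile` with columns `rank`,
#'   `position`, `restype`, `frac_sasa`, `n_types`, `smoothed`.
#' @export
burial_profile <- function(residues, type_counts, window = 20L) {
  skeleton <- rank_by_burial(residues)
  assert_columns(type_counts, c("position", "n_types"), "`type_counts`")
  lost <- setdiff(type_counts$position, skeleton$position)
  if (length(lost) > 0) {
    warn(sprintf("%d variant position(s) absent from the structure, dropped: %s",
                 length(lost), paste(utils::head(lost, 10), collapse = ", ")))
  }
  out <- skeleton %>%
    left_join(type_counts %>% select("position", "n_types"), by = "position") %>%
    mutate(
      n_types = tidyr::replace_na(.data$n_types, 0L),
      smoothed = smooth_counts(.data$n_types, window = window)
    )
  class(out) <- c("burial_profile", class(out))
  attr(out, "window") <- as.integer(window)
  out
}

#' Score burial/variability discordance by permutation
#'
#' The discordance raw score of a residue is its observed variant-type count
#' minus the smoothed local expectation at its burial rank — large positive
#' scores mark buried residues with unexpectedly many variant types (the
#' formal counterpart of reading a buried outlier such as TRPV1 M308 off a
#' burial-vs-variability plot). Significance is assessed by permuting the
#' type counts across ranks (the exchangeable null "variant counts carry no
#' burial information"): for each residue the permuted profile is
#' re-smoothed and the residue's p-value is
#' `(1 + #{permutations with permuted raw score at this rank >= observed})
#' / (n_permutations + 1)`. These are marginal per-residue p-values —
#' exactly uniform at any fixed rank under the null — and are unadjusted;
#' apply [stats::p.adjust()] before declaring discoveries across a whole
#' profile.
#'
#' @param profile A [burial_profile()].
#' @param n_permutations Number of permutations (>= 99; default 999).
#' @param seed Integer seed for the permutation stream.
#' @return The profile with added columns `discordance` (raw score) and
#'   `p_value`.
#' @export
discordance <- function(profile, n_permutations = 999L, seed = 1L) {
  assert_columns(profile, c("rank", "n_types", "smoothed", "frac_sasa"), "`profile`")
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 99L) stop_ardscan("bad_permutations", "`n_permutations` must be >= 99")
  window <- attr(profile, "window") %||% 20L
  prof <- profile %>% arrange(.data$rank)
  obs <- prof$n_types - prof$smoothed
  n <- nrow(prof)
  exceed <- integer(n)
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(n_permutations)) {
      perm <- sample(prof$n_types)
      raw <- perm - smooth_counts(perm, window = window)
      exceed <- exceed + (raw >= obs)
    }
  })
  p <- (1 + exceed) / (n_permutations + 1)
  out <- prof %>% mutate(discordance = obs, p_value = p)
  class(out) <- class(profile)
  attr(out, "window") <- window
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Conservation of the alignment column holding a reference position
#'
#' Locates, in an aligned FASTA, the column that carries a given residue of
#' a reference sequence (counting that sequence's non-gap letters from its
#' stated first residue number), and reports the column letters and the
#' identity fraction: the fraction of sequences with a non-gap letter in the
#' column whose letter matches the reference's.
#'
#' @param alignment Path to an aligned FASTA file, or a named character
#'   vector of equal-length aligned sequences.
#' @param ref_id Name (or unique prefix) of the reference sequence.
#' @param position Residue number in the reference sequence's own numbering.
#' @param ref_start Residue number of the reference's first non-gap letter.
#' @return A list with `column` (1-based alignment column), `ref_letter`,
#'   `letters` (named character vector per sequence, gaps as `"-"`), and
#'   `identity` (fraction in [0, 1]).
#' @export
column_identity <- function(alignment, ref_id, position, ref_start = 1L) {
  seqs <- read_alignment(alignment)
  hit <- which(names(seqs) == ref_id)
  if (length(hit) == 0) hit <- which(startsWith(names(seqs), ref_id))
  if (length(hit) != 1) {
    stop_ardscan("id_not_found",
                 sprintf("reference id '%s' matches %d sequence(s)", ref_id, length(hit)))
  }
  ref <- strsplit(seqs[[hit]], "")[[1]]
  nongap <- ref != "-" & ref != "."
  idx <- position - ref_start + 1L
  if (idx < 1 || idx > sum(nongap)) {
    stop_ardscan("position_out_of_range",
                 sprintf("position %d beyond reference sequence (has %d residues from %d)",
                         position, sum(nongap), ref_start))
  }
  col <- which(nongap)[idx]
  letters_col <- vapply(seqs, function(s) substr(s, col, col), character(1))
  letters_col[letters_col == "."] <- "-"
  present <- letters_col != "-"
  identity <- mean(toupper(letters_col[present]) == toupper(ref[col]))
  list(
    column = col,
    ref_letter = ref[col],
    letters = letters_col,
    identity = identity
  )
}

# aligned FASTA -> named character vector; Biostrings when available,
# so the standard parser handles wrapped lines and descriptions
read_alignment <- function(alignment) {
  if (is.character(alignment) && length(alignment) == 1 && file.exists(alignment)) {
    if (requireNamespace("Biostrings", quietly = TRUE)) {
      aln <- Biostrings::readAAStringSet(alignment)
      seqs <- as.character(aln)
      names(seqs) <- sub("\\s.*$", "", names(aln))
    } else {
      lines <- readLines(alignment)
      hdr <- grepl("^>", lines)
      id <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
      grp <- cumsum(hdr)
      seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste0, character(1), collapse = "")
      names(seqs) <- id
    }
  } else if (is.character(alignment) && !is.null(names(alignment))) {
    seqs <- alignment
  } else {
    stop_ardscan("unreadable_file", "`alignment` must be a FASTA path or a named character vector")
  }
  if (length(unique(nchar(seqs))) != 1) {
    stop_ardscan("ragged_alignment", "aligned sequences must have equal length")
  }
  seqs
}
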