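#' Parse HGVS protein consequences into missense changes
#'
#' Splits gnomAD-style protein consequence strings such as `"p.Met309Val"`
#' into reference amino acid, position and alternate amino acid (one-letter
#' codes). Only true missense changes are accepted: synonymous, nonsense
#' (`Ter`) and frameshift (`fs`) consequences are rejected with a distinct
#' error for each cause, so upstream readers can count skip reasons.
#'
#' @param hgvs_p Character vector of protein consequences in HGVS p. notation.
#' @return A tibble with one row per input and columns `ref_aa`, `position`,
#'   `alt_aa`.
#' @export
#' @examples
#' parse_protein_consequence(c("p.Met309Val", "p.Ala256Thr"))
parse_protein_consequence <- function(hgvs_p) {
  if (!is.character(hgvs_p) || length(hgvs_p) == 0) {
    stop_ardscan("malformed_hgvs", "`hgvs_p` must be a non-empty character vector")
  }
  m <- stringr::str_match(hgvs_p, "^p\\.\\(?([A-Z][a-z]{2})(\\d+)([A-Z][a-z]{2}|Ter|\\*|=|fs.*|del.*|dup.*)\\)?$")
  bad <- is.na(m[, 1])
  if (any(bad)) {
    stop_ardscan(
      "malformed_hgvs",
      sprintf("not valid HGVS p. missense notation: %s",
              paste(utils::head(hgvs_p[bad], 5), collapse = ", "))
    )
  }
  ref3 <- m[, 2]
  pos <- as.integer(m[, 3])
  alt3 <- m[, 4]

  nonsense <- alt3 %in% c("Ter", "*") | startsWith(alt3, "fs") |
    startsWith(alt3, "del") | startsWith(alt3, "dup")
  if (any(nonsense)) {
    stop_ardscan(
      "nonsense_not_missense",
      sprintf("not a missense change (nonsense/frameshift/indel): %s",
              paste(utils::head(hgvs_p[nonsense], 5), collapse = ", "))
    )
  }
  unknown <- !(ref3 %in% AA_THREE) | !(alt3 %in% c(AA_THREE, "="))
  if (any(unknown)) {
    stop_ardscan(
      "unknown_code",
      sprintf("unknown amino-acid code in: %s",
              paste(utils::head(hgvs_p[unknown], 5), collapse = ", "))
    )
  }
  syn <- alt3 == "=" | ref3 == alt3
  if (any(syn)) {
    stop_ardscan(
      "synonymous_not_missense",
      sprintf("synonymous, not missense: %s",
              paste(utils::head(hgvs_p[syn], 5), collapse = ", "))
    )
  }
  tibble(
    ref_aa = unname(AA_ONE[ref3]),
    position = pos,
    alt_aa = unname(AA_ONE[alt3])
  )
}

#' Format a missense change back into HGVS p. notation
#'
#' Inverse of [parse_protein_consequence()]; round-tripping is the identity
#' on all canonical amino acids.
#'
#' @param ref_aa,alt_aa One-letter amino-acid codes.
#' @param position Integer residue position.
#' @return Character vector of `"p.<Ref3><pos><Alt3>"` strings.
#' @export
format_protein_consequence <- function(ref_aa, position, alt_aa) {
  if (!all(ref_aa %in% names(AA_THREE)) || !all(alt_aa %in% names(AA_THREE))) {
    stop_ardscan("unknown_code", "amino acids must be canonical one-letter codes")
  }
  paste0("p.", AA_THREE[ref_aa], position, AA_THREE[alt_aa])
}

#' Residue numbering maps between ortholog conventions
#'
#' A constant-offset map between two residue numbering conventions, e.g.
#' human TRPV1 M309 versus rat TRPV1 M308 (offset -1). Applying and then
#' inverting the offset is the identity.
#'
#' @param offset Signed integer added to source positions to obtain
#'   reference positions.
#' @param source_label,reference_label Free-text labels for the two
#'   conventions.
#' @return An object of class `numbering_map`.
#' @export
#' @examples
#' human_to_rat <- numbering_map(-1, "human TRPV1", "rat TRPV1")
#' map_numbering(309, human_to_rat)
numbering_map <- function(offset = 0L, source_label = "source", reference_label = "reference") {
  offset <- as.integer(offset)
  if (length(offset) != 1 || is.na(offset)) {
    stop_ardscan("malformed_map", "`offset` must be a single integer")
  }
  structure(
    list(offset = offset, source_label = source_label, reference_label = reference_label),
    class = "numbering_map"
  )
}

#' @export
print.numbering_map <- function(x, ...) {
  cat(sprintf("<numbering_map> %s -> %s (offset %+d)\n",
              x$source_label, x$reference_label, x$offset))
  invisible(x)
}

#' Map residue positions between numbering conventions
#'
#' @param position Integer vector of positions in the source numbering.
#' @param map A [numbering_map()].
#' @return Integer vector of positions in the reference numbering.
#' @export
map_numbering <- function(position, map = numbering_map(0L)) {
  stopifnot(inherits(map, "numbering_map"))
  out <- as.integer(position) + map$offset
  if (any(out < 1L, na.rm = TRUE)) {
    stop_ardscan("out_of_range",
                 sprintf("mapped position(s) below 1: %s",
                         paste(position[out < 1L], collapse = ", ")))
  }
  out
}

#' Read a gnomAD-style missense variant export
#'
#' Reads a CSV with one row per variant, parses the HGVS protein consequence
#' of each row, and returns a tidy table of missense variants. Rows whose
#' consequence is not a parseable missense change (nonsense, frameshift,
#' synonymous, malformed) are skipped; the number skipped per cause is
#' reported in a warning and attached as the `"skipped"` attribute. Rows
#' with a missing allele count default to 1 with a warning, since an
#' observed variant implies at least one allele.
#'
#' @param path Path to the CSV file (any reader-compatible connection).
#' @param consequence_col,allele_count_col Column names holding the HGVS p.
#'   consequence and the allele count.
#' @param source_release Optional free-text provenance label stored in the
#'   `source_release` column (e.g. `"gnomAD 4.1"`).
#' @return A tibble with columns `ref_aa`, `position`, `alt_aa`,
#'   `allele_count`, `source_release`.
#' @export
read_variant_csv <- function(path,
                             consequence_col = "protein_consequence",
                             allele_count_col = "allele_count",
                             source_release = NA_character_) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  assert_columns(raw, c(consequence_col, allele_count_col), "variant export")

  parsed_one <- function(s) {
    tryCatch(
      cbind(parse_protein_consequence(s), cause = NA_character_),
      ardscan_error = function(e) {
        tibble(ref_aa = NA_character_, position = NA_integer_,
               alt_aa = NA_character_, cause = class(e)[[1]])
      }
    )
  }
  parsed <- purrr::map(raw[[consequence_col]], parsed_one) %>% bind_rows()

  skipped <- table(parsed$cause[!is.na(parsed$cause)])
  if (length(skipped) > 0) {
    warn(sprintf(
      "skipped %d unparseable row(s): %s",
      sum(skipped),
      paste(sprintf("%s=%d", sub("^ardscan_", "", names(skipped)), skipped), collapse = ", ")
    ))
  }

  ac <- suppressWarnings(as.numeric(raw[[allele_count_col]]))
  if (anyNA(ac[is.na(parsed$cause)])) {
    warn("rows lacking an allele count default to 1")
    ac[is.na(ac)] <- 1
  }

  out <- parsed %>%
    mutate(allele_count = as.integer(ac), source_release = source_release) %>%
    filter(is.na(.data$cause)) %>%
    select(-"cause")
  attr(out, "skipped") <- as.list(skipped)
  out
}

#' Aggregate missense variants into per-position spectra
#'
#' Sums allele counts over identical (position, alternate amino acid) pairs
#' after mapping positions into the reference numbering, yielding one row
#' per observed alternate amino acid per position — the per-residue variant
#' spectrum. Duplicate rows are summed, never deduplicated, because exports
#' may split one amino-acid change across several nucleotide variants.
#' Zero-count alleles are dropped.
#'
#' @param variants Tibble with columns `ref_aa`, `position`, `alt_aa`,
#'   `allele_count` (as from [read_variant_csv()] or
#'   [parse_protein_consequence()]).
#' @param map A [numbering_map()] applied to `position` (default: identity).
#' @return A tibble with columns `position` (reference numbering), `ref_aa`,
#'   `alt_aa`, `allele_count`, sorted by position then decreasing count.
#' @export
#' @examples
#' v <- tibble::tibble(
#'   ref_aa = "M", position = 309L, alt_aa = c("V", "V", "T"),
#'   allele_count = c(100L, 21L, 8L)
#' )
#' build_spectra(v, numbering_map(-1))
build_spectra <- function(variants, map = numbering_map(0L)) {
  assert_columns(variants, c("ref_aa", "position", "alt_aa", "allele_count"),
                 "`variants`")
  if (nrow(variants) == 0) {
    return(tibble(position = integer(), ref_aa = character(),
                  alt_aa = character(), allele_count = integer()))
  }
  if (any(variants$allele_count < 0)) {
    stop_ardscan("negative_count", "allele counts must be non-negative")
  }
  if (any(variants$ref_aa == variants$alt_aa)) {
    stop_ardscan("synonymous_not_missense", "ref_aa must differ from alt_aa")
  }
  out <- variants %>%
    mutate(position = map_numbering(.data$position, map)) %>%
    group_by(.data$position, .data$ref_aa, .data$alt_aa) %>%
    summarise(allele_count = as.integer(sum(.data$allele_count)), .groups = "drop")

  conflict <- out %>%
    distinct(.data$position, .data$ref_aa) %>%
    count(.data$position) %>%
    filter(n > 1)
  if (nrow(conflict) > 0) {
    stop_ardscan(
      "reference_mismatch",
      sprintf("conflicting reference amino acids at mapped position(s): %s",
              paste(conflict$position, collapse = ", "))
    )
  }
  out %>%
    filter(.data$allele_count >= 1) %>%
    arrange(.data$position, dplyr::desc(.data$allele_count), .data$alt_aa)
}

#' Count distinct variant types per position
#'
#' A variant type is a distinct alternate amino acid observed at a position,
#' regardless of allele abundance or underlying nucleotide change. At TRPV1
#' M308 the gnomAD 4.1 spectrum (Val:121, Thr:8, Ile:2, Arg:2) has 4 types.
#'
#' @param spectra Spectrum tibble from [build_spectra()].
#' @return A tibble with columns `position`, `ref_aa`, `n_types`,
#'   `total_alleles`.
#' @export
variant_type_count <- function(spectra) {
  assert_columns(spectra, c("position", "ref_aa", "alt_aa", "allele_count"),
                 "`spectra`")
  spectra %>%
    filter(.data$allele_count >= 1) %>%
    group_by(.data$position, .data$ref_aa) %>%
    summarise(
      n_types = n_distinct(.data$alt_aa),
      total_alleles = as.integer(sum(.data$allele_count)),
      .groups = "drop"
    )
}

#' Normalize a variant spectrum to its most common allele
#'
#' Divides each alternate amino acid's allele count by the position's maximum
#' count, so the most common missense amino acid maps to exactly 1.0 (ties
#' all map to 1.0).
#'
#' @param spectra Spectrum tibble from [build_spectra()]; must be non-empty.
#' @return The input with an added `fraction` column in (0, 1].
#' @export
normalized_spectrum <- function(spectra) {
  assert_columns(spectra, c("position", "alt_aa", "allele_count"), "`spectra`")
  if (nrow(spectra) == 0) {
    stop_ardscan("empty_spectrum", "cannot normalize an empty spectrum")
  }
  spectra %>%
    group_by(.data$position) %>%
    mutate(fraction = .data$allele_count / max(.data$allele_count)) %>%
    ungroup()
}

#' Aggregate the spectra of one residue class over a sequence range
#'
#' Finds every position in `range` whose sequence letter equals
#' `residue_class` (e.g. all Met residues of an ankyrin repeat domain) and
#' sums their variant spectra into a single aggregate spectrum keyed by
#' alternate amino acid — the comparison used to contrast TRPV1 M308 against
#' the methionines of the TRPA1 ARD.
#'
#' @param spectra Spectrum tibble from [build_spectra()].
#' @param sequence Amino-acid string (one-letter) covering the range.
#' @param start Residue number of the first letter of `sequence`.
#' @param residue_class One-letter amino acid defining the class.
#' @param range Integer vector `c(lo, hi)`; must lie within the sequence.
#' @return A list with `positions` (integer vector of class positions) and
#'   `spectrum` (tibble `alt_aa`, `allele_count`, `fraction` normalized to
#'   the most common alternate amino acid; empty if the class is absent).
#' @export
residue_class_spectrum <- function(spectra, sequence, start = 1L, residue_class, range) {
  letters_vec <- strsplit(sequence, "")[[1]]
  lo <- as.integer(range[[1]]); hi <- as.integer(range[[2]])
  seq_end <- start + length(letters_vec) - 1L
  if (lo < start || hi > seq_end || lo > hi) {
    stop_ardscan("out_of_range",
                 sprintf("range [%d, %d] outside sequence span [%d, %d]",
                         lo, hi, start, seq_end))
  }
  pos_all <- seq.int(lo, hi)
  positions <- pos_all[letters_vec[pos_all - start + 1L] == residue_class]
  agg <- spectra %>%
    filter(.data$position %in% positions) %>%
    group_by(.data$alt_aa) %>%
    summarise(allele_count = as.integer(sum(.data$allele_count)), .groups = "drop") %>%
    arrange(dplyr::desc(.data$allele_count))
  if (nrow(agg) > 0) {
    agg <- agg %>% mutate(fraction = .data$allele_count / max(.data$allele_count))
  } else {
    agg <- tibble(alt_aa = character(), allele_count = integer(), fraction = numeric())
  }
  list(positions = positions, spectrum = agg)
}
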