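#' Read a protein structure into an atom table
#'
#' Reads a PDB (`.pdb`) or mmCIF (`.cif`) file and returns one row per heavy
#' atom. Hydrogens (and deuterium) and all hetero/water records are excluded;
#' where alternate locations exist, only the highest-occupancy conformer of
#' each atom is kept; records are sorted by (chain, residue number).
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @param chains Optional character vector of chain ids to keep (default:
#'   all chains present).
#' @param range Optional `c(lo, hi)` residue-number range (author numbering,
#'   as deposited) to keep.
#' @return A tibble with columns `chain`, `resnum`, `insert`, `resid`
#'   (three-letter residue name), `atom` (atom name), `x`, `y`, `z` (A),
#'   `element`, `occupancy`.
#' @export
read_structure <- function(path, chains = NULL, range = NULL) {
  if (!file.exists(path)) {
    stop_ardscan("unreadable_file", sprintf("no such structure file: %s", path))
  }
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop_ardscan("missing_dependency", "package 'bio3d' is required to read structures")
  }
  ext <- tolower(tools::file_ext(path))
  pdb <- tryCatch(
    switch(ext,
      pdb = bio3d::read.pdb(path, verbose = FALSE),
      cif = suppressWarnings(bio3d::read.cif(path, verbose = FALSE)),
      stop_ardscan("unreadable_file",
                   sprintf("unsupported structure format '.%s' (need .pdb or .cif)", ext))
    ),
    error = function(e) {
      if (inherits(e, "ardscan_error")) stop(e)
      stop_ardscan("unreadable_file", sprintf("could not parse %s: %s", path, conditionMessage(e)))
    }
  )

  at <- as_tibble(pdb$atom)
  at$o <- suppressWarnings(as.numeric(at$o))
  at$o[is.na(at$o)] <- 1

  element <- toupper(trimws(as.character(at$elesy)))
  fallback <- is.na(element) | element == ""
  if (any(fallback)) {
    # derive from the atom name: strip digits/primes, take leading letters
    nm <- gsub("[^A-Za-z]", "", as.character(at$elety[fallback]))
    element[fallback] <- toupper(substr(nm, 1, 1))
  }

  atoms <- tibble(
    record = as.character(at$type),
    chain = as.character(at$chain),
    resnum = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", as.character(at$insert)),
    resid = as.character(at$resid),
    atom = as.character(at$elety),
    alt = ifelse(is.na(at$alt), "", as.character(at$alt)),
    x = as.numeric(at$x), y = as.numeric(at$y), z = as.numeric(at$z),
    element = element,
    occupancy = at$o
  ) %>%
    filter(.data$record == "ATOM",
           !(.data$element %in% c("H", "D")),
           !(.data$resid %in% c("HOH", "WAT", "DOD")))

  if (!is.null(chains)) atoms <- atoms %>% filter(.data$chain %in% chains)
  if (!is.null(range)) {
    atoms <- atoms %>% filter(.data$resnum >= range[[1]], .data$resnum <= range[[2]])
  }
  if (nrow(atoms) == 0) {
    stop_ardscan("empty_selection", "no atoms left after chain/range filtering")
  }

  atoms %>%
    # highest-occupancy conformer per (chain, residue, atom name)
    arrange(.data$chain, .data$resnum, .data$insert, .data$atom,
            dplyr::desc(.data$occupancy), .data$alt) %>%
    distinct(.data$chain, .data$resnum, .data$insert, .data$atom, .keep_all = TRUE) %>%
    arrange(.data$chain, .data$resnum, .data$insert) %>%
    select("chain", "resnum", "insert", "resid", "atom",
           "x", "y", "z", "element", "occupancy")
}

#' Deterministic unit-sphere test points (golden spiral)
#'
#' The seedless point set used by [shrake_rupley()]: points are spaced on a
#' Fibonacci (golden-angle) spiral, giving near-uniform coverage of the
#' sphere that is identical across runs and platforms.
#'
#' @param n Number of points.
#' @return An `n x 3` matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Shrake-Rupley per-atom solvent-accessible surface area
#'
#' Rolls a solvent probe over the structure numerically: each atom's
#' solvent-expanded sphere (radius = vdW radius + probe) is sampled at a
#' deterministic golden-spiral point set, and its SASA is
#' `4*pi*(r+p)^2 * (accessible points / n_points)`, where a point is
#' accessible if it lies outside every neighbour's solvent-expanded sphere.
#' Deterministic given its inputs; no random state is consumed.
#'
#' @param atoms Atom tibble from [read_structure()] (or any tibble with
#'   `x`, `y`, `z` and `element` columns).
#' @param probe_radius Solvent probe radius in A (water: 1.4).
#' @param n_points Number of test points per atom (>= 96; default 960, at
#'   which the isolated-sphere closed form is matched within 1%).
#' @return The input tibble with an added `atom_sasa` column (A^2).
#' @export
shrake_rupley <- function(atoms, probe_radius = 1.4, n_points = 960) {
  assert_columns(atoms, c("x", "y", "z", "element"), "`atoms`")
  if (probe_radius <= 0) stop_ardscan("bad_probe", "`probe_radius` must be > 0")
  if (n_points < 96) stop_ardscan("bad_points", "`n_points` must be >= 96")
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  if (!all(is.finite(xyz))) stop_ardscan("bad_coordinates", "coordinates must be finite")
  radii <- vdw_radius(atoms$element)
  pts <- sphere_points(n_points)
  sasa <- tryCatch(
    .sasa_cpp(xyz, radii, probe_radius, pts),
    error = function(e) {
      if (grepl("degenerate_geometry", conditionMessage(e))) {
        stop_ardscan("degenerate_geometry", "coincident atoms at identical coordinates")
      }
      stop(e)
    }
  )
  atoms %>% mutate(atom_sasa = as.numeric(sasa))
}

#' Per-residue absolute and fractional solvent accessibility
#'
#' Sums per-atom SASA within each residue and divides by the residue type's
#' theoretical maximum ASA (see [amino_acid_properties()]) to obtain
#' fractional SASA (relative solvent accessibility, ~0 = buried). Fractional
#' values may exceed 1 for highly exposed residues and are reported as-is,
#' with a warning above 1.2.
#'
#' @param atoms Atom tibble with an `atom_sasa` column, from
#'   [shrake_rupley()].
#' @return A tibble with columns `chain`, `resnum`, `restype` (one-letter),
#'   `abs_sasa` (A^2) and `frac_sasa`.
#' @export
residue_sasa <- function(atoms) {
  assert_columns(atoms, c("chain", "resnum", "resid", "atom_sasa"), "`atoms`")
  res <- atoms %>%
    group_by(.data$chain, .data$resnum, .data$resid) %>%
    summarise(abs_sasa = sum(.data$atom_sasa), .groups = "drop")
  unknown <- setdiff(toupper(unique(res$resid)), names(AA_ONE_UPPER))
  if (length(unknown) > 0) {
    stop_ardscan("unknown_residue",
                 sprintf("residue type(s) absent from the reference max-ASA table: %s",
                         paste(unknown, collapse = ", ")))
  }
  out <- res %>%
    mutate(
      restype = unname(AA_ONE_UPPER[toupper(.data$resid)]),
      frac_sasa = .data$abs_sasa / unname(MAX_ASA[.data$restype])
    ) %>%
    select("chain", "resnum", "restype", "abs_sasa", "frac_sasa") %>%
    arrange(.data$chain, .data$resnum)
  if (any(out$frac_sasa > 1.2)) {
    warn(sprintf("%d residue(s) with fractional SASA > 1.2 (reported as-is)",
                 sum(out$frac_sasa > 1.2)))
  }
  out
}

#' Compute per-residue SASA for a structure file
#'
#' Convenience wrapper chaining [read_structure()], [shrake_rupley()] and
#' [residue_sasa()]. SASA is computed in the context of all atoms selected
#' by `chains` (e.g. the full tetramer, so burial reflects the assembly) and
#' then reported for `report_chain` restricted to `range`.
#'
#' @inheritParams read_structure
#' @inheritParams shrake_rupley
#' @param report_chain Chain id to report (default: first chain in context).
#' @param range Optional residue-number range to report.
#' @return A residue-level tibble as from [residue_sasa()].
#' @export
compute_sasa <- function(path, chains = NULL, report_chain = NULL, range = NULL,
                         probe_radius = 1.4, n_points = 960) {
  atoms <- read_structure(path, chains = chains)
  res <- shrake_rupley(atoms, probe_radius = probe_radius, n_points = n_points) %>%
    residue_sasa()
  if (is.null(report_chain)) report_chain <- res$chain[[1]]
  out <- res %>% filter(.data$chain == report_chain)
  if (nrow(out) == 0) {
    stop_ardscan("empty_selection",
                 sprintf("report chain '%s' not present", report_chain))
  }
  if (!is.null(range)) {
    out <- out %>% filter(.data$resnum >= range[[1]], .data$resnum <= range[[2]])
    if (nrow(out) == 0) stop_ardscan("empty_selection", "no residues in requested range")
  }
  out
}
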