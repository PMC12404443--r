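# Ideal alpha-helix builder: a small, valid PDB generator used to exercise
# the structure reader and the SASA code without any deposited structure.

# place atom D given three prior atoms A-B-C, bond |CD|, angle B-C-D and
# torsion A-B-C-D (natural extension reference frame)
place_atom <- function(a, b, cc, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- torsion_deg * pi / 180
  bc <- cc - b
  bc_u <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma_cross(ab, bc_u)
  n_u <- n / sqrt(sum(n^2))
  m_u <- pracma_cross(n_u, bc_u)
  d_local <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  cc + d_local[1] * bc_u + d_local[2] * m_u + d_local[3] * n_u
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Generate an ideal alpha-helix structure as PDB text
#'
#' Builds an ideal alpha-helical backbone (phi = -57, psi = -47, omega =
#' 180 degrees; standard bond lengths and angles) with carbonyl oxygens and
#' beta carbons for the given sequence, and returns valid PDB `ATOM`
#' records parseable by [read_structure()]. Terminal residues of the helix
#' are more solvent-exposed than central ones, which makes the output a
#' convenient self-contained fixture for SASA code.
#'
#' @param sequence One-letter amino-acid string, 3 to 500 residues.
#' @param path Optional file path; when given the PDB text is written there.
#' @param chain Chain identifier (default `"A"`).
#' @param start Residue number of the first residue (default 1).
#' @param phi,psi Backbone dihedrals in degrees (defaults -57/-47, the ideal
#'   alpha-helix; -139/135 gives an extended beta conformation, useful for
#'   maximally exposed reference fixtures).
#' @return The PDB text as a character vector of lines (invisibly when
#'   `path` is given).
#' @export
#' @examples
#' pdb <- generate_helix_structure("MKTAYIAKQR")
generate_helix_structure <- function(sequence, path = NULL, chain = "A", start = 1L,
                                     phi = -57, psi = -47) {
  letters_vec <- strsplit(sequence, "")[[1]]
  n_res <- length(letters_vec)
  if (n_res < 3 || n_res > 500) {
    stop_ardscan("bad_length", "sequence must have 3 to 500 residues")
  }
  if (!all(letters_vec %in% names(AA_THREE))) {
    stop_ardscan("unknown_code",
                 sprintf("unsupported residue letter(s): %s",
                         paste(setdiff(letters_vec, names(AA_THREE)), collapse = ", ")))
  }

  omega <- 180
  b_n_ca <- 1.458; b_ca_c <- 1.525; b_c_n <- 1.329; b_c_o <- 1.231; b_ca_cb <- 1.530
  a_n_ca_c <- 111.0; a_ca_c_n <- 116.2; a_c_n_ca <- 121.7; a_ca_c_o <- 120.8

  N <- matrix(NA_real_, n_res, 3)
  CA <- matrix(NA_real_, n_res, 3)
  C <- matrix(NA_real_, n_res, 3)
  O <- matrix(NA_real_, n_res, 3)
  CB <- matrix(NA_real_, n_res, 3)

  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(b_n_ca, 0, 0)
  ang <- a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + b_ca_c * c(-cos(ang), sin(ang), 0)

  for (k in seq_len(n_res)) {
    if (k > 1) {
      N[k, ] <- place_atom(N[k - 1, ], CA[k - 1, ], C[k - 1, ], b_c_n, a_ca_c_n, psi)
      CA[k, ] <- place_atom(CA[k - 1, ], C[k - 1, ], N[k, ], b_n_ca, a_c_n_ca, omega)
      C[k, ] <- place_atom(C[k - 1, ], N[k, ], CA[k, ], b_ca_c, a_n_ca_c, phi)
    }
    # carbonyl oxygen: torsion N-CA-C-O = psi + 180
    O[k, ] <- place_atom(N[k, ], CA[k, ], C[k, ], b_c_o, a_ca_c_o, psi + 180)
    # beta carbon: tetrahedral off CA, L-configuration
    if (letters_vec[k] != "G") {
      u1 <- N[k, ] - CA[k, ]; u1 <- u1 / sqrt(sum(u1^2))
      u2 <- C[k, ] - CA[k, ]; u2 <- u2 / sqrt(sum(u2^2))
      bis <- u1 + u2; bis <- bis / sqrt(sum(bis^2))
      nrm <- pracma_cross(u2, u1); nrm <- nrm / sqrt(sum(nrm^2))
      dir <- -0.619 * bis + 0.786 * nrm
      dir <- dir / sqrt(sum(dir^2))
      CB[k, ] <- CA[k, ] + b_ca_cb * dir
    }
  }

  fmt <- function(serial, name, res3, resno, xyz, element) {
    name_field <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
    sprintf("ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, name_field, res3, chain, resno,
            xyz[1], xyz[2], xyz[3], 1.00, 0.00, element)
  }
  lines <- character(0)
  serial <- 0L
  for (k in seq_len(n_res)) {
    res3 <- toupper(AA_THREE[[letters_vec[k]]])
    resno <- start + k - 1L
    for (entry in list(list("N", N[k, ], "N"), list("CA", CA[k, ], "C"),
                       list("C", C[k, ], "C"), list("O", O[k, ], "O"),
                       if (letters_vec[k] != "G") list("CB", CB[k, ], "C"))) {
      if (is.null(entry)) next
      serial <- serial + 1L
      lines <- c(lines, fmt(serial, entry[[1]], res3, resno, entry[[2]], entry[[3]]))
    }
  }
  lines <- c(lines, "TER", "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
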