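# Shared fixture builders; everything is generated in code at test time.

# the gnomAD 4.1 spectrum printed for rat TRPV1 M308 (human M309):
# Val:121, Thr:8, Ile:2, Arg:2
m308_spectrum <- function() {
  tibble::tibble(
    position = 308L,
    ref_aa = "M",
    alt_aa = c("V", "T", "I", "R"),
    allele_count = c(121L, 8L, 2L, 2L)
  )
}

# tiny PDB with an altloc pair (A occ 0.60 / B occ 0.40), a hydrogen and a
# water, to exercise the reader's filtering rules
altloc_pdb <- function(path) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.458   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA BALA A   1       1.500   0.100   0.000  0.40  0.00           C",
    "ATOM      4  C   ALA A   1       2.004   1.423   0.000  1.00  0.00           C",
    "ATOM      5  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      6  H   ALA A   1       0.500   0.500   0.500  1.00  0.00           H",
    "HETATM    7  O   HOH A 101       8.000   8.000   8.000  1.00  0.00           O",
    "END"
  )
  writeLines(lines, path)
  path
}

# minimal mmCIF holding the same four heavy atoms as the PDB above
mini_cif <- function(path) {
  hdr <- c(
    "data_synthetic", "#", "loop_",
    paste0("_atom_site.", c(
      "group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
      "label_comp_id", "label_asym_id", "label_entity_id", "label_seq_id",
      "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
      "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id", "auth_comp_id",
      "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num"
    ))
  )
  rows <- c(
    "ATOM 1 N N . ALA A 1 1 ? 0.000 0.000 0.000 1.00 0.00 ? 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 1.458 0.000 0.000 1.00 0.00 ? 1 ALA A CA 1",
    "ATOM 3 C C . ALA A 1 1 ? 2.004 1.423 0.000 1.00 0.00 ? 1 ALA A C 1",
    "ATOM 4 O O . ALA A 1 1 ? 1.251 2.390 0.000 1.00 0.00 ? 1 ALA A O 1"
  )
  writeLines(c(hdr, rows, "#"), path)
  path
}

# exchangeable-null burial profile: uniform SASA, iid Poisson type counts
null_profile <- function(seed, n = 100, lambda = 1) {
  withr::with_seed(seed, {
    resid <- tibble::tibble(
      position = seq_len(n), restype = "A", frac_sasa = sort(runif(n))
    )
    nt <- tibble::tibble(position = seq_len(n), n_types = rpois(n, lambda))
  })
  burial_profile(resid, nt)
}

# square-wave single-channel trace at 50% duty cycle
square_wave_trace <- function(i = 1, n_cycles = 500, fs = 1000) {
  n <- 2 * n_cycles
  tibble::tibble(
    time_s = (seq_len(n) - 1) / fs,
    current_pA = rep(c(0, i), n_cycles)
  )
}
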