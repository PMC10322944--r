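# fixtures are built in code; no binary files

# minimal two-atom PDB text
minimal_pdb_lines <- function() {
  c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1       2.000   2.500   3.000  1.00 10.00           C",
    "END"
  )
}

# the same content in mmCIF dialect
minimal_cif_lines <- function() {
  c(
    "data_TOY",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . ALA A 1 1 ? 1.000 2.000 3.000 1.00 10.00 ? 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 2.000 2.500 3.000 1.00 10.00 ? 1 ALA A CA 1",
    "#"
  )
}

# one polymer-atom row in read_structure() layout
protein_atom <- function(name, resname, resno, chain, xyz, serial = 1L,
                         element = substr(name, 1, 1)) {
  tibble::tibble(
    atom_serial = as.integer(serial), atom_name = name, element = element,
    x = xyz[1], y = xyz[2], z = xyz[3],
    residue_name = resname, residue_number = as.integer(resno),
    chain_id = chain, record = "ATOM",
    is_hydrogen = element %in% c("H", "D"), is_polymer = TRUE
  )
}

# a short decoy host chain: a covalent-attachment cysteine right next to the
# bilin's ring A (so the chain wins nearest-host assignment and the b82 site
# is inferred), a second distal cysteine, and a short CA trace
decoy_chain <- function(chain, origin, n_res = 4) {
  dplyr::bind_rows(
    protein_atom("SG", "CYS", 84, chain, origin + c(0, 2.97, 0), serial = 1L,
                 element = "S"),
    protein_atom("SG", "CYS", 153, chain, origin + c(0, 30, 0), serial = 2L,
                 element = "S"),
    dplyr::bind_rows(lapply(seq_len(n_res), function(i) {
      protein_atom("CA", "ALA", i, chain, origin + c(0, 6 + i, 0),
                   serial = i + 2L)
    }))
  )
}

# single "arginine" marker: a CZ atom at a prescribed position
arg_atom <- function(chain, resno, xyz, serial = 1L) {
  protein_atom("CZ", "ARG", resno, chain, xyz, serial = serial, element = "C")
}

# toy rod: three b82-like bilins plus a linker chain whose arginine contacts
# mirror the membrane-side linker signature (bilin 1: high-numbered ARGs,
# bilin 2: none, bilin 3: lower-numbered ARGs)
toy_labeled_structure <- function(cutoff_contact = 3) {
  b1 <- make_tetrapyrrole(30, 9, 21, chain_id = "U", residue_number = 301L,
                          origin = c(0, 0, 0))
  b2 <- make_tetrapyrrole(26, 7, 8, chain_id = "V", residue_number = 301L,
                          origin = c(0, 0, 40))
  b3 <- make_tetrapyrrole(28, 8, 25, chain_id = "W", residue_number = 301L,
                          origin = c(0, 0, 80))
  hosts <- dplyr::bind_rows(
    decoy_chain("A", c(0, 0, 0)), decoy_chain("B", c(0, 0, 40)),
    decoy_chain("C", c(0, 0, 80))
  )
  near <- function(bilin, k) as.numeric(bilin[1, c("x", "y", "z")]) + c(0, 0, k)
  linker <- dplyr::bind_rows(
    arg_atom("L", 112, near(b1, 2.5), serial = 1L),
    arg_atom("L", 178, near(b1, -2.5), serial = 2L),
    arg_atom("L", 181, near(b1, 3.0), serial = 3L),
    arg_atom("L", 16, near(b3, 2.5), serial = 4L),
    arg_atom("L", 163, near(b3, -2.5), serial = 5L),
    arg_atom("L", 169, near(b3, 3.0), serial = 6L),
    protein_atom("CA", "GLY", 50, "L", c(20, 20, 20), serial = 7L)
  )
  atoms <- dplyr::bind_rows(hosts, linker, b1, b2, b3)
  atoms$atom_serial <- seq_len(nrow(atoms))
  atoms
}

# random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# brute-force plane normal: minimize squared orthogonal distance over a
# 1-degree grid on the unit hemisphere
grid_search_normal <- function(points) {
  centered <- sweep(points, 2, colMeans(points))
  th <- (0:90) * pi / 180
  ph <- (0:359) * pi / 180
  grid <- cbind(
    rep(sin(th), each = length(ph)) * cos(ph),
    rep(sin(th), each = length(ph)) * sin(ph),
    rep(cos(th), each = length(ph))
  )
  ss <- colSums((centered %*% t(grid))^2)
  grid[which.min(ss), ]
}

# sequential three-compartment scheme with distinct, well-separated rates
sequential_scheme3 <- function(taus = c(A = 5, B = 60, C = 700)) {
  kinetic_scheme(
    names(taus),
    transfers = data.frame(from = names(taus)[1:2], to = names(taus)[2:3],
                           rate = 1 / taus[1:2]),
    loss = stats::setNames(1 / taus[3], names(taus)[3])
  )
}

# location of optional deposited coordinate files (not shipped; the analyses
# that reproduce published structural numbers need them on disk)
deposited_file <- function(name) {
  candidates <- c(
    system.file("extdata", "deposited", name, package = "bilindyn"),
    file.path("deposited", name),
    file.path("..", "..", "deposited", name)
  )
  candidates <- candidates[nzchar(candidates)]
  hit <- candidates[file.exists(candidates)]
  if (length(hit)) hit[1] else NA_character_
}
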