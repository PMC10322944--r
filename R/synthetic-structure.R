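# Synthetic structural fixtures: idealized tetrapyrroles with prescribed
# inter-ring plane angles, used for round-trip testing of the geometry code.

#' Generate an idealized tetrapyrrole with prescribed inter-ring angles
#'
#' Builds four planar five-atom pyrrole rings (N + 4 C, regular pentagons)
#' whose centres lie on a common axis; ring i+1 is rotated about that axis
#' by the prescribed inter-plane angle relative to ring i. Because the
#' rotation axis lies in every ring plane, the angle between fitted
#' least-squares planes of adjacent rings equals the construction angle
#' exactly at zero jitter — that round-trip identity is the generator's
#' contract. Atom names follow the phycocyanobilin chemical component
#' (`NA, C1A..C4A`, ..., `ND, C1D..C4D`) so the result flows through
#' [extract_bilins()] and [bilin_conformation()] unchanged.
#'
#' @param theta_ab,theta_bc,theta_cd Prescribed adjacent inter-ring plane
#'   angles, degrees, each in \[0, 90\].
#' @param ring_radius Pentagon circumradius, Angstrom (default 1.17,
#'   approximating a pyrrole ring).
#' @param ring_spacing Distance between adjacent ring centres along the
#'   construction axis, Angstrom (default 3.6).
#' @param jitter_sigma Isotropic Gaussian coordinate noise, Angstrom.
#' @param seed Integer seed for the jitter (ignored at `jitter_sigma = 0`).
#' @param chain_id,residue_number,residue_name Identity of the emitted
#'   residue (defaults `"X"`, 201, `"CYC"`).
#' @param origin 3-vector added to all coordinates.
#' @return Atom tibble in [read_structure()] layout (20 HETATM rows).
#' @examples
#' toy <- make_tetrapyrrole(26, 7, 8)
#' bilin_conformation(toy)
#' @export
make_tetrapyrrole <- function(theta_ab = 0, theta_bc = 0, theta_cd = 0,
                              ring_radius = 1.17, ring_spacing = 3.6,
                              jitter_sigma = 0, seed = 1L,
                              chain_id = "X", residue_number = 201L,
                              residue_name = "CYC", origin = c(0, 0, 0)) {
  th <- c(theta_ab, theta_bc, theta_cd)
  stopifnot(all(th >= 0), all(th <= 90), ring_radius > 0, ring_spacing > 0,
            jitter_sigma >= 0)
  cum <- c(0, cumsum(th)) * pi / 180
  ring_ids <- c("A", "B", "C", "D")
  # base pentagon in the xy plane, first vertex (the nitrogen) on +y
  phi <- 2 * pi * (0:4) / 5 + pi / 2
  base <- cbind(ring_radius * cos(phi), ring_radius * sin(phi), 0)
  rows <- vector("list", 4)
  for (i in 1:4) {
    a <- cum[i]
    rot <- rbind(c(1, 0, 0),
                 c(0, cos(a), -sin(a)),
                 c(0, sin(a), cos(a)))      # rotation about the x axis
    pts <- base %*% t(rot)
    pts[, 1] <- pts[, 1] + (i - 1) * ring_spacing
    nm <- c(paste0("N", ring_ids[i]), paste0("C", 1:4, ring_ids[i]))
    rows[[i]] <- tibble::tibble(
      atom_name = nm,
      element = c("N", "C", "C", "C", "C"),
      x = pts[, 1], y = pts[, 2], z = pts[, 3]
    )
  }
  atoms <- dplyr::bind_rows(rows)
  if (jitter_sigma > 0) {
    atoms[, c("x", "y", "z")] <- with_local_seed(seed, {
      atoms[, c("x", "y", "z")] +
        matrix(stats::rnorm(3 * nrow(atoms), sd = jitter_sigma), ncol = 3)
    })
  }
  atoms$x <- atoms$x + origin[1]
  atoms$y <- atoms$y + origin[2]
  atoms$z <- atoms$z + origin[3]
  tibble::tibble(
    atom_serial = seq_len(nrow(atoms)),
    atom_name = atoms$atom_name,
    element = atoms$element,
    x = atoms$x, y = atoms$y, z = atoms$z,
    residue_name = residue_name,
    residue_number = as.integer(residue_number),
    chain_id = chain_id,
    record = "HETATM",
    is_hydrogen = FALSE,
    is_polymer = FALSE
  )
}

# evaluate expr under a fixed RNG state, restoring the caller's state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Wrap loose bilin atoms as a one-row bilin table
#'
#' Convenience for feeding a [make_tetrapyrrole()] atom tibble straight into
#' [bilin_conformation()] / [contact_map()] without a full structure parse.
#'
#' @param atoms Atom tibble of a single bilin residue.
#' @param label Bilin label (default from chain and residue number).
#' @return One-row bilin tibble in [extract_bilins()] layout.
#' @export
as_bilin_table <- function(atoms, label = NULL) {
  stopifnot(nrow(atoms) > 0)
  if (is.null(label)) {
    label <- sprintf("%s-%d", atoms$chain_id[1], atoms$residue_number[1])
  }
  tibble::tibble(
    chain_id = atoms$chain_id[1],
    residue_number = atoms$residue_number[1],
    residue_name = atoms$residue_name[1],
    host_chain_id = NA_character_,
    n_atoms = nrow(atoms),
    atoms = list(atoms),
    label = label
  )
}
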