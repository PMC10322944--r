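#' Read a macromolecular structure into an atom table
#'
#' Parses a coordinate file (PDB or mmCIF) and returns one row per atom.
#' Multi-model files are reduced to the first model. Coordinates are in
#' Angstrom. Chains are classified as polymer when they contain at least one
#' `ATOM` record; purely `HETATM` chains (ligands, waters) are non-polymer.
#'
#' @param path Path to a coordinate file.
#' @param format One of `"auto"` (extension-based), `"pdb"`, `"mmcif"`.
#' @param accession_label Free-text label stored as the `accession_label`
#'   attribute of the returned table; defaults to the file name.
#' @return A tibble with columns `atom_serial`, `atom_name`, `element`,
#'   `x`, `y`, `z`, `residue_name`, `residue_number`, `chain_id`, `record`,
#'   `is_hydrogen`, `is_polymer`.
#' @examples
#' toy <- make_tetrapyrrole(theta_ab = 26, theta_bc = 7, theta_cd = 8)
#' f <- tempfile(fileext = ".pdb")
#' write_structure_pdb(toy, f)
#' atoms <- read_structure(f)
#' nrow(atoms)
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           accession_label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("structure file not found: ", path, call. = FALSE)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      pdb = "pdb", ent = "pdb",
      cif = "mmcif", mmcif = "mmcif",
      stop("cannot infer format from extension '.", ext,
           "'; pass format = \"pdb\" or \"mmcif\"", call. = FALSE)
    )
  }
  parsed <- tryCatch(
    if (format == "pdb") {
      suppressWarnings(bio3d::read.pdb(path, multi = FALSE))
    } else {
      suppressWarnings(bio3d::read.cif(path))
    },
    error = function(e) {
      stop("failed to parse ", path, " as ", format, ": ",
           conditionMessage(e), call. = FALSE)
    }
  )
  at <- parsed$atom
  # first model only: bio3d already restricts coordinates to model 1 for
  # multi = FALSE; mmCIF tables may carry all models, keep the first
  if (format == "mmcif" && nrow(at) > 0 && "eleno" %in% names(at)) {
    dup <- duplicated(at$eleno)
    if (any(dup)) at <- at[!dup, , drop = FALSE]
  }
  elem <- as.character(at$elesy)
  missing_elem <- is.na(elem) | elem == ""
  if (any(missing_elem)) {
    elem[missing_elem] <- guess_element(at$elety[missing_elem])
  }
  chain <- as.character(at$chain)
  chain[is.na(chain) | chain == ""] <- "_"
  atoms <- tibble::tibble(
    atom_serial = as.integer(at$eleno),
    atom_name = as.character(at$elety),
    element = toupper(elem),
    x = as.numeric(at$x), y = as.numeric(at$y), z = as.numeric(at$z),
    residue_name = as.character(at$resid),
    residue_number = as.integer(at$resno),
    chain_id = chain,
    record = as.character(at$type)
  )
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite coordinates in ", path, call. = FALSE)
  }
  atoms$is_hydrogen <- atoms$element %in% c("H", "D")
  polymer_chains <- unique(atoms$chain_id[atoms$record == "ATOM"])
  atoms$is_polymer <- atoms$record == "ATOM" & atoms$chain_id %in% polymer_chains
  attr(atoms, "accession_label") <-
    if (is.null(accession_label)) basename(path) else accession_label
  atoms
}

# element symbol from a PDB atom name (first alphabetic character, with the
# standard exception that names like "1HB2" are hydrogens)
guess_element <- function(atom_name) {
  nm <- gsub("[^A-Za-z]", "", as.character(atom_name))
  vapply(nm, function(s) {
    if (nchar(s) == 0) return("X")
    toupper(substr(s, 1, 1))
  }, character(1), USE.NAMES = FALSE)
}

#' Write an atom table as a PDB file
#'
#' Counterpart to [read_structure()] used by the synthetic generators and for
#' round-trip testing. Coordinates are written at the standard 3-decimal PDB
#' precision.
#'
#' @param atoms Atom tibble as returned by [read_structure()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(atoms, path) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0)
  xyz <- as.vector(t(as.matrix(atoms[, c("x", "y", "z")])))
  rec <- if ("record" %in% names(atoms)) atoms$record else rep("ATOM", nrow(atoms))
  suppressWarnings(bio3d::write.pdb(
    file = path,
    xyz = xyz,
    type = rec,
    resno = atoms$residue_number,
    resid = atoms$residue_name,
    eleno = if ("atom_serial" %in% names(atoms)) atoms$atom_serial else seq_len(nrow(atoms)),
    elety = atoms$atom_name,
    chain = atoms$chain_id,
    elesy = if ("element" %in% names(atoms)) atoms$element else guess_element(atoms$atom_name)
  ))
  invisible(path)
}

#' Count polymer chains in an atom table
#'
#' A chain counts as polymer when it carries at least one `ATOM` record.
#'
#' @param atoms Atom tibble from [read_structure()].
#' @return Integer number of polymer chains.
#' @export
polymer_chain_count <- function(atoms) {
  length(unique(atoms$chain_id[atoms$is_polymer]))
}

#' Default bilin residue codes
#'
#' `CYC` is the wwPDB chemical-component code for phycocyanobilin; some
#' depositions use `PCB`. Both are matched by default.
#' @return Character vector of 3-letter codes.
#' @export
bilin_residue_codes <- function() c("CYC", "PCB")

#' Extract bilin chromophores from an atom table
#'
#' Finds every non-polymer residue whose name matches `residue_codes` and
#' returns one row per bilin with its atoms as a nested tibble. The host
#' chain (the subunit the bilin is covalently attached to) is assigned as the
#' polymer chain with the smallest heavy-atom distance to the bilin; LINK
#' records are deliberately not used because they are unreliable across
#' depositions.
#'
#' @param atoms Atom tibble from [read_structure()].
#' @param residue_codes 3-letter residue codes identifying bilins.
#' @return A tibble with columns `chain_id`, `residue_number`, `residue_name`,
#'   `host_chain_id`, `n_atoms`, and the list-column `atoms`. Zero matches
#'   give an empty tibble with a warning.
#' @export
extract_bilins <- function(atoms, residue_codes = bilin_residue_codes()) {
  stopifnot(length(residue_codes) > 0)
  hits <- atoms[!atoms$is_polymer & atoms$residue_name %in% residue_codes, , drop = FALSE]
  if (nrow(hits) == 0) {
    warning("no residues matching codes {", paste(residue_codes, collapse = ", "),
            "} found", call. = FALSE)
    return(tibble::tibble(
      chain_id = character(), residue_number = integer(),
      residue_name = character(), host_chain_id = character(),
      n_atoms = integer(), atoms = list()
    ))
  }
  poly <- atoms[atoms$is_polymer & !atoms$is_hydrogen, , drop = FALSE]
  out <- hits |>
    tidyr::nest(atoms = !c("chain_id", "residue_number", "residue_name")) |>
    dplyr::arrange(.data$chain_id, .data$residue_number)
  out$host_chain_id <- vapply(out$atoms, function(ba) {
    nearest_polymer_chain(ba, poly)
  }, character(1))
  out$n_atoms <- vapply(out$atoms, nrow, integer(1))
  out[, c("chain_id", "residue_number", "residue_name",
          "host_chain_id", "n_atoms", "atoms")]
}

nearest_polymer_chain <- function(bilin_atoms, polymer_atoms) {
  if (nrow(polymer_atoms) == 0) return(NA_character_)
  ba <- bilin_atoms[!bilin_atoms$is_hydrogen, c("x", "y", "z"), drop = FALSE]
  d2min <- tapply(seq_len(nrow(polymer_atoms)), polymer_atoms$chain_id, function(i) {
    pa <- polymer_atoms[i, c("x", "y", "z"), drop = FALSE]
    min(pairwise_sqdist(as.matrix(ba), as.matrix(pa)))
  })
  names(which.min(d2min))
}

# squared distances between rows of two n x 3 matrices
pairwise_sqdist <- function(a, b) {
  outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
}

#' Assign rod-nomenclature labels to bilins
#'
#' Builds a label for every bilin of the form
#' `<hexamer><layer>-<site>-<index>` (for example `1I-b82-2`): the hexamer
#' index (1 = membrane-proximal, counting up the rod), the trimer layer
#' within the hexamer (I = bottom, II = top), the attachment site (`a84`,
#' `b82`, or `b155`), and, for the beta-82 bilins of the bottom trimer, a
#' monomer index 1-3 determined by their arginine-contact signature with the
#' membrane-side linker: the bilin with no arginine contact within `cutoff`
#' gets index 2 (a distinguishing feature of the flattened, red-shifted
#' bilin), and the remaining two are ordered by the highest-numbered arginine
#' that contacts them (descending), giving indices 1 and 3. Elsewhere the
#' index follows chain order.
#'
#' @param bilins Bilin tibble from [extract_bilins()].
#' @param atoms Full atom tibble (for contacts and geometry).
#' @param linker_chains Named character vector mapping linker roles to chain
#'   ids, e.g. `c(CpcL = "K", CpcC1 = "L")`. The chain named `CpcL` (or the
#'   first entry) is used for the arginine-signature test. `NULL` disables
#'   signature-based indexing.
#' @param cutoff Heavy-atom contact cutoff in Angstrom (default 4).
#' @return `bilins` with added columns `site`, `hexamer`, `layer`,
#'   `monomer_index`, `label`.
#' @export
assign_bilin_labels <- function(bilins, atoms, linker_chains = NULL, cutoff = 4) {
  n <- nrow(bilins)
  if (n == 0) return(dplyr::mutate(bilins, site = character(0),
                                   hexamer = integer(0), layer = character(0),
                                   monomer_index = integer(0), label = character(0)))
  bilins$site <- vapply(seq_len(n), function(i) {
    infer_attachment_site(bilins$atoms[[i]], bilins$host_chain_id[i], atoms)
  }, character(1))

  # stack position along the rod axis: project bilin centroids on the first
  # principal axis of all polymer CA/heavy atoms, bin into trimer layers
  cent <- t(vapply(bilins$atoms, function(a) {
    colMeans(as.matrix(a[!a$is_hydrogen, c("x", "y", "z")]))
  }, numeric(3)))
  poly <- as.matrix(atoms[atoms$is_polymer & !atoms$is_hydrogen, c("x", "y", "z")])
  # a rod trimer carries 9 bilins (3 monomers x 3 sites); when the bilin
  # count is a whole number of trimers, bin centroid positions along the rod
  # axis into trimer layers, else treat everything as one layer
  n_layers <- if (n %% 9 == 0 && n >= 18) n %/% 9 else 1L
  if (nrow(poly) >= 3 && n_layers > 1) {
    ax <- stats::prcomp(poly)$rotation[, 1]
    proj <- drop(cent %*% ax)
    # orient axis so the linker-bearing (membrane-proximal) end is low
    if (!is.null(linker_chains)) {
      lk <- as.matrix(atoms[atoms$chain_id == linker_chains[[1]] & !atoms$is_hydrogen,
                            c("x", "y", "z")])
      if (nrow(lk) > 0 && mean(lk %*% ax) > mean(poly %*% ax)) {
        proj <- -proj
      }
    }
    bilins$layer_rank <- cut(rank(proj, ties.method = "first"),
                             breaks = seq(0, n, length.out = n_layers + 1),
                             labels = FALSE)
  } else {
    bilins$layer_rank <- 1L
  }
  bilins$hexamer <- as.integer((bilins$layer_rank - 1L) %/% 2L + 1L)
  bilins$layer <- c("I", "II")[(bilins$layer_rank - 1L) %% 2L + 1L]
  bilins$layer_rank <- NULL

  bilins$monomer_index <- stats::ave(
    seq_len(n), bilins$hexamer, bilins$layer, bilins$site,
    FUN = function(i) seq_along(i)
  )

  # arginine-signature indexing of the bottom-trimer b82 bilins
  if (!is.null(linker_chains)) {
    lchain <- if ("CpcL" %in% names(linker_chains)) linker_chains[["CpcL"]] else linker_chains[[1]]
    bottom <- which(bilins$hexamer == 1L & bilins$layer == "I" & bilins$site == "b82")
    if (length(bottom) == 3) {
      sig <- lapply(bottom, function(i) {
        cc <- contact_map(atoms, bilins[i, , drop = FALSE], cutoff = cutoff)
        arg <- cc[cc$partner_chain_id == lchain & cc$partner_residue_name == "ARG", ]
        sort(unique(arg$partner_residue_number))
      })
      narg <- vapply(sig, length, integer(1))
      if (sum(narg == 0) == 1) {
        idx2 <- bottom[narg == 0]
        others <- bottom[narg > 0]
        maxarg <- vapply(sig[narg > 0], max, numeric(1))
        if (length(others) == 2 && maxarg[1] != maxarg[2]) {
          ord <- others[order(maxarg, decreasing = TRUE)]
          bilins$monomer_index[ord[1]] <- 1L
          bilins$monomer_index[idx2] <- 2L
          bilins$monomer_index[ord[2]] <- 3L
        } else {
          stop("ambiguous arginine-contact signature among bottom-trimer b82 ",
               "bilins: candidates ",
               paste(bilins$chain_id[others], bilins$residue_number[others],
                     collapse = "; "), call. = FALSE)
        }
      } else if (all(narg == 0)) {
        # no linker contacts at all: keep chain-order indices
      } else {
        stop("ambiguous arginine-contact signature: expected exactly one ",
             "bottom-trimer b82 bilin without arginine contacts, found ",
             sum(narg == 0), call. = FALSE)
      }
    }
  }
  bilins$label <- sprintf("%d%s-%s-%d", bilins$hexamer, bilins$layer,
                          bilins$site, bilins$monomer_index)
  bilins
}

# attachment site from the residue number of the nearest cysteine SG in the
# host chain (covalent attachment is at ring A to a Cys); falls back on "b82"
infer_attachment_site <- function(bilin_atoms, host_chain, atoms) {
  sg <- atoms[atoms$is_polymer & atoms$chain_id %in% host_chain &
                atoms$residue_name == "CYS" & atoms$atom_name == "SG", , drop = FALSE]
  if (is.na(host_chain) || nrow(sg) == 0) return("b82")
  ba <- as.matrix(bilin_atoms[!bilin_atoms$is_hydrogen, c("x", "y", "z")])
  d2 <- pairwise_sqdist(ba, as.matrix(sg[, c("x", "y", "z")]))
  resno <- sg$residue_number[which.min(apply(d2, 2, min))]
  # attachment cysteines: alpha-84 on the alpha subunit; beta-82 and
  # beta-153/155 on the beta subunit. Residue number alone separates the
  # beta sites; alpha vs beta-82 (both near 84) is resolved by whether the
  # host chain has a second attachment cysteine above residue 140.
  if (resno > 140) return("b155")
  has_high_cys <- any(sg$residue_number > 140)
  if (has_high_cys) "b82" else "a84"
}

#' Guess the membrane-proximal linker chain of a rod structure
#'
#' Operational heuristic for rod models whose chain roles are not annotated:
#' phycocyanin subunit chains are identified as the two most common chain
#' lengths; the remaining polymer chains are linker candidates. The shortest
#' candidate (the CpcD-like domain) marks the distal end of the rod, and the
#' candidate farthest from it along the rod's principal axis is returned as
#' the membrane-proximal linker (CpcL in a CpcL-rod). With a single
#' candidate, that candidate is returned.
#'
#' @param atoms Atom tibble from [read_structure()].
#' @return A chain id, or `NA` when no linker candidate exists.
#' @export
guess_membrane_linker_chain <- function(atoms) {
  poly <- atoms[atoms$is_polymer & !atoms$is_hydrogen, , drop = FALSE]
  if (nrow(poly) == 0) return(NA_character_)
  len <- vapply(split(poly$residue_number, poly$chain_id),
                function(r) length(unique(r)), integer(1))
  tab <- sort(table(len), decreasing = TRUE)
  pc_lengths <- as.integer(names(tab)[tab >= 4][seq_len(min(2, sum(tab >= 4)))])
  cand <- names(len)[!len %in% pc_lengths]
  if (length(cand) == 0) return(NA_character_)
  if (length(cand) == 1) return(cand)
  centroid <- function(ch) {
    m <- poly[poly$chain_id == ch, c("x", "y", "z")]
    colMeans(as.matrix(m))
  }
  ax <- stats::prcomp(as.matrix(poly[, c("x", "y", "z")]))$rotation[, 1]
  proj <- vapply(cand, function(ch) sum(centroid(ch) * ax), numeric(1))
  distal <- cand[which.min(len[cand])]
  cand[which.max(abs(proj - proj[distal]))]
}

#' Write a bilin inventory as TSV
#'
#' @param bilins Bilin tibble, ideally after [assign_bilin_labels()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_bilin_inventory <- function(bilins, path) {
  cols <- intersect(c("label", "residue_name", "chain_id", "residue_number",
                      "host_chain_id", "n_atoms"), names(bilins))
  utils::write.table(as.data.frame(bilins[, cols]), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
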