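#' Map protein contacts of bilin chromophores
#'
#' Every heavy-atom pair (bilin atom, non-bilin atom) at distance <= `cutoff`
#' yields one contact record; an atom exactly at the cutoff is included.
#' This is a plain distance criterion — no hydrogen-bond geometry test —
#' matching how bilin-protein interactions are usually reported (e.g.
#' "residues within 4 Angstrom of the bilin").
#'
#' @param atoms Full atom tibble from [read_structure()].
#' @param bilins Bilin tibble from [extract_bilins()] (one or more rows).
#' @param cutoff Distance cutoff in Angstrom, > 0. Default 4.
#' @param exclude_hydrogens Drop hydrogens from both sides (default TRUE).
#' @return Tibble sorted by distance within each bilin: `bilin_label`,
#'   `partner_chain_id`, `partner_residue_name`, `partner_residue_number`,
#'   `partner_atom`, `bilin_atom`, `distance`.
#' @export
contact_map <- function(atoms, bilins, cutoff = 4, exclude_hydrogens = TRUE) {
  stopifnot(cutoff > 0)
  empty <- tibble::tibble(
    bilin_label = character(), partner_chain_id = character(),
    partner_residue_name = character(), partner_residue_number = integer(),
    partner_atom = character(), bilin_atom = character(), distance = numeric()
  )
  if (nrow(bilins) == 0) return(empty)
  labs <- if ("label" %in% names(bilins)) bilins$label else
    sprintf("%s-%d", bilins$chain_id, bilins$residue_number)
  res <- purrr::map(seq_len(nrow(bilins)), function(i) {
    ba <- bilins$atoms[[i]]
    if (exclude_hydrogens) ba <- ba[!ba$is_hydrogen, , drop = FALSE]
    # environment = everything that is not this bilin residue
    env <- atoms[!(atoms$chain_id == bilins$chain_id[i] &
                     atoms$residue_number == bilins$residue_number[i] &
                     atoms$residue_name == bilins$residue_name[i]), , drop = FALSE]
    if (exclude_hydrogens) env <- env[!env$is_hydrogen, , drop = FALSE]
    if (nrow(env) == 0 || nrow(ba) == 0) return(empty)
    d2 <- pairwise_sqdist(as.matrix(ba[, c("x", "y", "z")]),
                          as.matrix(env[, c("x", "y", "z")]))
    hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
    if (nrow(hit) == 0) return(empty)
    out <- tibble::tibble(
      bilin_label = labs[i],
      partner_chain_id = env$chain_id[hit[, 2]],
      partner_residue_name = env$residue_name[hit[, 2]],
      partner_residue_number = env$residue_number[hit[, 2]],
      partner_atom = env$atom_name[hit[, 2]],
      bilin_atom = ba$atom_name[hit[, 1]],
      distance = sqrt(d2[hit])
    )
    dplyr::arrange(out, .data$distance)
  })
  dplyr::bind_rows(res)
}
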