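#' Fit a least-squares plane to a set of points
#'
#' Total-least-squares plane through `points`: the plane minimizing the sum
#' of squared orthogonal distances, obtained from the eigen-decomposition of
#' the centered second-moment matrix. The normal is the eigenvector of the
#' smallest eigenvalue; its sign can be fixed with `orient_towards` (the
#' normal is flipped to have positive dot product with the vector from the
#' centroid to that point). Angles computed downstream use `|n1 . n2|`, so
#' the sign convention affects reporting only.
#'
#' @param points Numeric matrix (n x 3) or data frame with columns x, y, z;
#'   n >= 3 and not collinear.
#' @param orient_towards Optional 3-vector; see above.
#' @return An object of class `ring_plane`: list with `centroid` (3-vector,
#'   Angstrom), `normal` (unit 3-vector), `planarity_rms` (Angstrom, RMS
#'   out-of-plane deviation).
#' @export
fit_plane <- function(points, orient_towards = NULL) {
  pts <- as_xyz_matrix(points)
  if (nrow(pts) < 3) {
    stop("plane fit needs >= 3 points, got ", nrow(pts), call. = FALSE)
  }
  centroid <- colMeans(pts)
  centered <- sweep(pts, 2, centroid)
  mom <- crossprod(centered)
  ev <- eigen(mom, symmetric = TRUE)
  # collinearity: the two smallest eigenvalues both (near) zero relative to
  # the spread of the points
  scale2 <- max(ev$values[1], .Machine$double.eps)
  if (ev$values[2] / scale2 < 1e-12) {
    stop("degenerate geometry: points are collinear (or coincident), ",
         "no unique plane", call. = FALSE)
  }
  normal <- ev$vectors[, 3]
  normal <- normal / sqrt(sum(normal^2))
  if (!is.null(orient_towards)) {
    v <- as.numeric(orient_towards) - centroid
    if (sum(v * normal) < 0) normal <- -normal
  }
  structure(
    list(
      centroid = centroid,
      normal = normal,
      planarity_rms = sqrt(max(ev$values[3], 0) / nrow(pts))
    ),
    class = "ring_plane"
  )
}

as_xyz_matrix <- function(points) {
  if (is.data.frame(points)) {
    stopifnot(all(c("x", "y", "z") %in% names(points)))
    points <- as.matrix(points[, c("x", "y", "z")])
  }
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  stopifnot(ncol(points) == 3, all(is.finite(points)))
  points
}

#' Acute angle between two ring planes
#'
#' `acos(|n1 . n2|)` in degrees, in \[0, 90\]. Symmetric in its arguments and
#' invariant to flipping either normal.
#'
#' @param p1,p2 `ring_plane` objects (or unit 3-vectors).
#' @return Angle in degrees.
#' @export
inter_ring_angle <- function(p1, p2) {
  n1 <- if (inherits(p1, "ring_plane")) p1$normal else as.numeric(p1)
  n2 <- if (inherits(p2, "ring_plane")) p2$normal else as.numeric(p2)
  stopifnot(abs(sum(n1^2) - 1) < 1e-6, abs(sum(n2^2) - 1) < 1e-6)
  d <- abs(sum(n1 * n2))
  acos(min(1, d)) * 180 / pi
}

#' Pyrrole ring atom definitions
#'
#' The default follows the wwPDB chemical component for phycocyanobilin:
#' each pyrrole ring is its five-membered ring proper (one nitrogen plus four
#' ring carbons); exocyclic substituents (methyls, vinyls, propionates, the
#' carbonyl oxygens of rings A and D) are excluded. The convention is
#' configurable so its influence on the inter-ring angles can be probed.
#'
#' @return Named list with entries `A`, `B`, `C`, `D`, each a character
#'   vector of five atom names.
#' @export
ring_definitions <- function() {
  list(
    A = c("NA", "C1A", "C2A", "C3A", "C4A"),
    B = c("NB", "C1B", "C2B", "C3B", "C4B"),
    C = c("NC", "C1C", "C2C", "C3C", "C4C"),
    D = c("ND", "C1D", "C2D", "C3D", "C4D")
  )
}

# resolve the four ring planes of one bilin atom table
bilin_ring_planes <- function(bilin_atoms, rings = ring_definitions()) {
  stopifnot(all(c("A", "B", "C", "D") %in% names(rings)))
  found <- lapply(rings, function(names_i) {
    sel <- bilin_atoms[match(names_i, bilin_atoms$atom_name), , drop = FALSE]
    if (anyNA(sel$x)) {
      missing <- names_i[is.na(match(names_i, bilin_atoms$atom_name))]
      stop("bilin is missing ring atoms: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    sel
  })
  centroids <- lapply(found, function(s) colMeans(as.matrix(s[, c("x", "y", "z")])))
  planes <- vector("list", 4)
  names(planes) <- names(rings)[1:4]
  ring_order <- c("A", "B", "C", "D")
  for (i in seq_along(ring_order)) {
    rl <- ring_order[i]
    nxt <- if (i < 4) centroids[[ring_order[i + 1]]] else centroids[[ring_order[3]]]
    planes[[rl]] <- fit_plane(found[[rl]], orient_towards = nxt)
  }
  planes
}

#' Inter-ring angles and planarity of bilins
#'
#' For every bilin, fits the four pyrrole ring planes and computes the three
#' adjacent inter-ring angles theta_AB, theta_BC, theta_CD (degrees). Smaller
#' angles mean a flatter, more conjugated, more red-shifted chromophore. The
#' `planarity_score` is `-(theta_AB + theta_BC + theta_CD)` so that higher
#' scores mean flatter bilins; it is a simple monotone aggregate reported
#' alongside the raw angles.
#'
#' @param bilins Bilin tibble from [extract_bilins()] (optionally labelled),
#'   or a single bilin atom tibble.
#' @param rings Ring atom definitions, see [ring_definitions()].
#' @return A tibble with one row per bilin: `label` (when present),
#'   `theta_ab`, `theta_bc`, `theta_cd`, `planarity_score`, and
#'   `max_ring_rms` (largest within-ring RMS deviation, Angstrom).
#' @export
bilin_conformation <- function(bilins, rings = ring_definitions()) {
  if (is.data.frame(bilins) && "atoms" %in% names(bilins)) {
    rows <- purrr::map(bilins$atoms, one_conformation, rings = rings)
    out <- dplyr::bind_rows(rows)
    lab <- if ("label" %in% names(bilins)) bilins$label else
      sprintf("%s-%d", bilins$chain_id, bilins$residue_number)
    dplyr::bind_cols(tibble::tibble(label = lab), out)
  } else {
    dplyr::bind_cols(tibble::tibble(label = "bilin"),
                     one_conformation(bilins, rings))
  }
}

one_conformation <- function(bilin_atoms, rings) {
  pl <- bilin_ring_planes(bilin_atoms, rings)
  th <- c(
    inter_ring_angle(pl$A, pl$B),
    inter_ring_angle(pl$B, pl$C),
    inter_ring_angle(pl$C, pl$D)
  )
  tibble::tibble(
    theta_ab = th[1], theta_bc = th[2], theta_cd = th[3],
    planarity_score = -sum(th),
    max_ring_rms = max(vapply(pl, function(p) p$planarity_rms, numeric(1)))
  )
}

#' Rank bilins as red-shifted terminal-emitter candidates
#'
#' Orders bilins by `planarity_score` (flattest first) with the number of
#' linker contacts as the secondary key. The top-ranked bilin is flagged as
#' the red-PCB candidate. Ties on both keys are reported, never broken
#' silently.
#'
#' @param conformations Tibble from [bilin_conformation()].
#' @param contacts Contact tibble from [contact_map()] (may cover several
#'   bilins), or `NULL` for geometry-only ranking.
#' @param linker_chain_ids Chains counted as linker contacts; default all
#'   partner chains in `contacts`.
#' @return `conformations` with added `linker_contacts`, `rank`,
#'   `red_candidate`, `tied` columns, sorted by rank.
#' @export
rank_red_candidates <- function(conformations, contacts = NULL,
                                linker_chain_ids = NULL) {
  stopifnot(nrow(conformations) >= 1)
  cf <- conformations
  cf$linker_contacts <- 0L
  if (!is.null(contacts) && nrow(contacts) > 0) {
    keep <- if (is.null(linker_chain_ids)) rep(TRUE, nrow(contacts)) else
      contacts$partner_chain_id %in% linker_chain_ids
    cnt <- table(contacts$bilin_label[keep])
    idx <- match(cf$label, names(cnt))
    cf$linker_contacts <- ifelse(is.na(idx), 0L, as.integer(cnt[idx]))
  }
  ord <- order(-cf$planarity_score, -cf$linker_contacts)
  cf <- cf[ord, , drop = FALSE]
  key <- paste(signif(cf$planarity_score, 10), cf$linker_contacts)
  cf$rank <- seq_len(nrow(cf))
  cf$tied <- duplicated(key) | duplicated(key, fromLast = TRUE)
  cf$red_candidate <- cf$rank == 1L
  if (cf$tied[1]) {
    warning("top-ranked red-PCB candidate is tied with ",
            sum(key == key[1]) - 1L, " other bilin(s); ranking is ambiguous",
            call. = FALSE)
  }
  tibble::as_tibble(cf)
}
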