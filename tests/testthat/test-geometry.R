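test_that("fit_plane recovers exact planes and rejects degenerate input", {
  pts <- cbind(c(0, 1, 2, 0.5, 1.5), c(0, 0.2, 1, 2, 1.3), 0)
  pl <- fit_plane(pts)
  expect_equal(abs(pl$normal[3]), 1, tolerance = 1e-12)
  expect_equal(pl$planarity_rms, 0, tolerance = 1e-12)

  expect_error(fit_plane(pts[1:2, ]), ">= 3 points")
  collinear <- cbind(0:4, 0:4, 0:4)
  expect_error(fit_plane(collinear), "collinear")
})

test_that("fit_plane matches a 1-degree grid-search minimizer on perturbed points", {
  set.seed(42)
  for (rep in 1:3) {
    base <- cbind(stats::runif(5, -2, 2), stats::runif(5, -2, 2), 0)
    rot <- random_rotation()
    pts <- (base + matrix(stats::rnorm(15, sd = 0.05), 5)) %*% t(rot)
    pl <- fit_plane(pts)
    gn <- grid_search_normal(pts)
    ang <- acos(min(1, abs(sum(pl$normal * gn)))) * 180 / pi
    expect_lt(ang, 2)
  }
})

test_that("inter_ring_angle follows the acute absolute-value convention", {
  z <- structure(list(normal = c(0, 0, 1)), class = "ring_plane")
  x <- structure(list(normal = c(1, 0, 0)), class = "ring_plane")
  zneg <- structure(list(normal = c(0, 0, -1)), class = "ring_plane")
  expect_equal(inter_ring_angle(z, z), 0)
  expect_equal(inter_ring_angle(z, x), 90)
  expect_equal(inter_ring_angle(z, zneg), 0)
  expect_equal(inter_ring_angle(z, x), inter_ring_angle(x, z))
})

test_that("plane fits and angles are invariant under rigid motion", {
  set.seed(7)
  toy <- make_tetrapyrrole(26, 7, 8)
  before <- bilin_conformation(toy)
  rot <- random_rotation()
  shift <- c(11, -3, 5)
  moved <- toy
  xyz <- as.matrix(toy[, c("x", "y", "z")]) %*% t(rot)
  moved$x <- xyz[, 1] + shift[1]
  moved$y <- xyz[, 2] + shift[2]
  moved$z <- xyz[, 3] + shift[3]
  after <- bilin_conformation(moved)
  expect_equal(
    unlist(after[, c("theta_ab", "theta_bc", "theta_cd")]),
    unlist(before[, c("theta_ab", "theta_bc", "theta_cd")]),
    tolerance = 1e-9
  )
})

test_that("bilin_conformation flags missing ring atoms by name", {
  toy <- make_tetrapyrrole(10, 10, 10)
  broken <- toy[toy$atom_name != "C2C", ]
  expect_error(bilin_conformation(broken), "C2C")
})

test_that("fully planar and prescribed-angle tetrapyrroles round-trip", {
  flat <- bilin_conformation(make_tetrapyrrole(0, 0, 0))
  expect_equal(unlist(flat[, c("theta_ab", "theta_bc", "theta_cd")]),
               c(theta_ab = 0, theta_bc = 0, theta_cd = 0), tolerance = 1e-9)
  bent <- bilin_conformation(make_tetrapyrrole(26, 7, 8))
  expect_equal(unlist(bent[, c("theta_ab", "theta_bc", "theta_cd")]),
               c(theta_ab = 26, theta_bc = 7, theta_cd = 8), tolerance = 1e-6)
})

test_that("red-candidate ranking uses planarity first, contacts second, and reports ties", {
  conf <- bilin_conformation(
    dplyr::bind_rows(
      as_bilin_table(make_tetrapyrrole(26, 7, 8), label = "flat"),
      as_bilin_table(make_tetrapyrrole(28, 9, 38,
                                       chain_id = "Y"), label = "bent")
    )
  )
  rk <- rank_red_candidates(conf)
  expect_equal(rk$label[rk$red_candidate], "flat")
  expect_false(any(rk$tied))

  # equal conformations: explicit tie report
  conf_eq <- conf
  conf_eq[2, c("theta_ab", "theta_bc", "theta_cd", "planarity_score")] <-
    conf_eq[1, c("theta_ab", "theta_bc", "theta_cd", "planarity_score")]
  expect_warning(rk_eq <- rank_red_candidates(conf_eq), "tied")
  expect_true(all(rk_eq$tied))

  # contacts break planarity ties
  contacts <- tibble::tibble(bilin_label = c("bent", "bent"),
                             partner_chain_id = "L",
                             partner_residue_name = "ARG",
                             partner_residue_number = c(1L, 2L),
                             partner_atom = "CZ", bilin_atom = "NA",
                             distance = c(3, 3.5))
  rk_c <- rank_red_candidates(conf_eq, contacts)
  expect_equal(rk_c$label[rk_c$red_candidate], "bent")
  expect_false(rk_c$tied[1])
})
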