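make_two_exp_surface <- function(noise = 0, seed = 1) {
  sch <- kinetic_scheme(c("A", "B"),
                        transfers = data.frame(from = "A", to = "B", rate = 1 / 5),
                        loss = c(B = 1 / 200))
  make_surface(sch,
               times = c(seq(0, 20, by = 0.25),
                         exp(seq(log(21), log(1500), length.out = 60))),
               wavelengths = seq(580, 700, by = 3),
               band_centers = c(620, 665), band_widths = 12,
               noise_sigma = noise, seed = seed)
}

test_that("noiseless two-exponential lifetimes are recovered within 0.1%", {
  surf <- make_two_exp_surface()
  fit <- global_fit_das(surf, 2)
  expect_true(fit$converged)
  expect_equal(fit$lifetimes, c(5, 200), tolerance = 1e-3)
  expect_lt(fit$fit_residual_rms, 1e-8)
  expect_false(is.unsorted(fit$lifetimes))
})

test_that("a single-component fit returns the generating band up to scale", {
  sch <- kinetic_scheme("A", loss = c(A = 1 / 50))
  wl <- seq(600, 700, by = 2)
  surf <- make_surface(sch, times = seq(0, 400, by = 2), wavelengths = wl,
                       band_centers = 650, band_widths = 12,
                       noise_sigma = 0.01, seed = 4)
  fit <- global_fit_das(surf, 1)
  truth <- attr(surf, "truth")$bands[1, ]
  amp <- fit$amplitude_spectra[1, ]
  scale <- sum(amp * truth) / sum(truth^2)
  expect_gt(abs(stats::cor(amp, truth)), 0.999)
  expect_lt(max(abs(amp - scale * truth)), 0.05 * max(abs(truth)))
  # residual sits at the injected noise level
  expect_lt(fit$fit_residual_rms, 2 * 0.01 * max(abs(surf$signal)))
})

test_that("noisy four-component lifetimes are recovered within 10%", {
  sch <- kinetic_scheme(c("A", "B", "C", "D"),
    transfers = data.frame(from = c("A", "B", "C"), to = c("B", "C", "D"),
                           rate = 1 / c(5, 50, 400)),
    loss = c(D = 1 / 2000))
  surf <- make_surface(sch,
                       times = c(seq(-1, 2, by = 0.1),
                                 exp(seq(log(2.4), log(8000), length.out = 80))),
                       wavelengths = seq(550, 700, by = 2),
                       band_centers = c(600, 630, 660, 690), band_widths = 12,
                       irf = irf_model(0.1), noise_sigma = 0.01, seed = 12)
  fit <- global_fit_das(surf, 4, irf = irf_model(0.1))
  expect_true(fit$converged)
  expect_equal(fit$lifetimes, c(5, 50, 400, 2000), tolerance = 0.1)
})

test_that("DAS lifetimes equal -1/eigenvalues of the generating scheme", {
  s <- sequential_scheme3()
  surf <- make_surface(s,
                       times = c(seq(0, 20, by = 0.5),
                                 exp(seq(log(21), log(5000), length.out = 70))),
                       wavelengths = seq(580, 700, by = 3),
                       band_centers = c(615, 650, 685), band_widths = 11,
                       noise_sigma = 0, seed = 1)
  fit <- global_fit_das(surf, 3)
  expect_equal(fit$lifetimes, scheme_lifetimes(s), tolerance = 1e-4)
})

test_that("residual rms never increases with more components", {
  surf <- make_two_exp_surface(noise = 0.02, seed = 6)
  rms <- vapply(1:4, function(k) {
    suppressWarnings(global_fit_das(surf, k)$fit_residual_rms)
  }, numeric(1))
  expect_true(all(diff(rms) <= 1e-10))
})

test_that("das_to_sas identities: single compartment and parallel schemes", {
  # single compartment: SAS identical to DAS
  sch1 <- kinetic_scheme("A", loss = c(A = 1 / 50))
  surf1 <- make_surface(sch1, times = seq(0, 400, by = 2),
                        wavelengths = seq(600, 700, by = 5),
                        band_centers = 650, band_widths = 12)
  das1 <- global_fit_das(surf1, 1)
  sas1 <- das_to_sas(das1, sch1)
  expect_equal(unname(sas1$species_spectra), unname(das1$amplitude_spectra),
               tolerance = 1e-8)

  # parallel (diagonal K) scheme: SAS proportional to DAS componentwise
  schp <- kinetic_scheme(c("A", "B"), loss = c(A = 1 / 5, B = 1 / 200),
                         initial = c(A = 0.5, B = 0.5))
  surfp <- make_surface(schp,
                        times = c(seq(0, 20, by = 0.25),
                                  exp(seq(log(21), log(1500), length.out = 60))),
                        wavelengths = seq(580, 700, by = 3),
                        band_centers = c(620, 665), band_widths = 12)
  dasp <- global_fit_das(surfp, 2)
  sasp <- das_to_sas(dasp, schp)
  for (i in 1:2) {
    cr <- stats::cor(sasp$species_spectra[i, ], dasp$amplitude_spectra[i, ])
    expect_equal(abs(cr), 1, tolerance = 1e-6)
  }
})

test_that("sequential-scheme SAS recovers the generating bands within 1%", {
  s <- sequential_scheme3()
  truth_bands <- NULL
  surf <- make_surface(s,
                       times = c(seq(0, 20, by = 0.5),
                                 exp(seq(log(21), log(5000), length.out = 70))),
                       wavelengths = seq(580, 700, by = 3),
                       band_centers = c(615, 650, 685), band_widths = 11,
                       noise_sigma = 0, seed = 1)
  truth_bands <- attr(surf, "truth")$bands
  das <- global_fit_das(surf, 3)
  sas <- das_to_sas(das, s)
  expect_lt(max(abs(sas$species_spectra - truth_bands)),
            0.01 * max(abs(truth_bands)))
  # reconstruction identity against the DAS reconstruction
  expect_lt(max(abs(sas_reconstruction(sas) - das_reconstruction(das))), 1e-10)
})

test_that("das_to_sas rejects mismatched component counts and lifetimes", {
  s <- sequential_scheme3()
  surf <- make_two_exp_surface()
  das2 <- global_fit_das(surf, 2)
  expect_error(das_to_sas(das2, s), "must match")
  wrong <- kinetic_scheme(c("A", "B"),
                          transfers = data.frame(from = "A", to = "B",
                                                 rate = 1 / 17),
                          loss = c(B = 1 / 900))
  expect_error(das_to_sas(das2, wrong), "model inconsistency")
})

test_that("target fit recovers rates directly from the surface", {
  # one compartment on 1-exponential data: rate = 1/tau
  sch <- kinetic_scheme("A", loss = c(A = 1 / 50))
  surf <- make_surface(sch, times = seq(0, 400, by = 2),
                       wavelengths = seq(600, 700, by = 5),
                       band_centers = 650, band_widths = 12)
  tf1 <- fit_target(surf, function(tau) kinetic_scheme("A", loss = c(A = 1 / tau[["A"]])),
                    init_lifetimes = c(A = 20))
  expect_equal(unname(tf1$lifetimes), 50, tolerance = 1e-6)

  # noiseless sequential two-compartment surface: rates within 0.1%
  surf2 <- make_two_exp_surface()
  builder2 <- function(tau) {
    kinetic_scheme(c("A", "B"),
                   transfers = data.frame(from = "A", to = "B",
                                          rate = 1 / tau[["A"]]),
                   loss = c(B = 1 / tau[["B"]]))
  }
  tf2 <- fit_target(surf2, builder2, init_lifetimes = c(A = 8, B = 120))
  expect_equal(unname(tf2$lifetimes), c(5, 200), tolerance = 1e-3)
  expect_true(tf2$converged)
  # equivalent to das_to_sas on noiseless data
  das2 <- global_fit_das(surf2, 2)
  sas2 <- das_to_sas(das2, builder2(c(A = 5, B = 200)))
  expect_equal(unname(tf2$sas$species_spectra), unname(sas2$species_spectra),
               tolerance = 1e-4)
})

test_that("component annotation maps kinetics onto structural classes", {
  toy <- toy_labeled_structure()
  bil <- assign_bilin_labels(extract_bilins(toy), toy,
                             linker_chains = c(CpcL = "L"))
  conf <- bilin_conformation(bil)
  contacts <- contact_map(toy, bil, cutoff = 4)
  ranking <- rank_red_candidates(conf, contacts, linker_chain_ids = "L")
  expect_equal(ranking$label[ranking$red_candidate], "1I-b82-2")
  # add a bulk-antenna class (no linker contacts) the fastest component maps to
  ranking <- dplyr::bind_rows(
    ranking,
    dplyr::mutate(ranking[1, ], label = "2I-a84-1", planarity_score = -70,
                  linker_contacts = 0L, rank = 4L, red_candidate = FALSE,
                  tied = FALSE))

  surf <- make_surface_preset("cpcl_ta", noise_sigma = 0.01, seed = 2)
  fit <- suppressWarnings(global_fit_das(surf, 4, irf = irf_model(0.1)))
  ann <- annotate_components(fit, ranking)
  expect_equal(ann$assigned_bilins[[1]], "2I-a84-1")
  expect_equal(nrow(ann), 4)
  # slowest component lands on the flattened, linker-engaged bilin
  expect_equal(ann$assigned_bilins[[4]], "1I-b82-2")

  # one component + one bilin: trivially paired
  one <- ranking[ranking$red_candidate, ]
  sch <- kinetic_scheme("A", loss = c(A = 1 / 50))
  surf1 <- make_surface(sch, times = seq(0, 300, by = 5),
                        wavelengths = seq(600, 700, by = 10),
                        band_centers = 650, band_widths = 12)
  ann1 <- annotate_components(global_fit_das(surf1, 1), one)
  expect_equal(ann1$assigned_bilins[[1]], one$label)

  # more components than structural classes: warning and partial map
  expect_warning(
    ann5 <- annotate_components(
      suppressWarnings(global_fit_das(surf, 5, irf = irf_model(0.1))),
      ranking),
    "fewer structural classes")
  expect_true(any(vapply(ann5$assigned_bilins, length, integer(1)) == 0))
})
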