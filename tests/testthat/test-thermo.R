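# Thermodynamic derivations: free energy <-> Kd, membrane partition
# correction, copy-number -> molarity. Frozen expected values were computed
# independently by hand/scalar arithmetic with R = 1.9872e-3 kcal/(mol K),
# T = 310 K before the implementation was written.

test_that("affinity_to_kd reproduces printed and derived conversions", {
  # docked ATP affinity: -7.0 kcal/mol prints as 11.6 uM
  expect_equal(affinity_to_kd(-7.0, td_ctx), 11.6e-6, tolerance = 0.005)
  # 1 M standard state
  expect_identical(affinity_to_kd(0, td_ctx), 1)
  # frozen scalar-arithmetic oracle: exp(-11.1 / (1.9872e-3 * 310))
  expect_equal(affinity_to_kd(-11.1, td_ctx), 1.495015e-8, tolerance = 1e-6)
  expect_error(affinity_to_kd(NaN), "finite")
  expect_error(affinity_to_kd(Inf), "finite")
})

test_that("kd_to_affinity inverts affinity_to_kd to 1e-12", {
  set.seed(42)
  dg <- stats::runif(50, -15, 2)
  expect_equal(kd_to_affinity(affinity_to_kd(dg, td_ctx), td_ctx), dg,
               tolerance = 1e-12)
  expect_error(kd_to_affinity(0), "positive")
  expect_error(kd_to_affinity(-1), "positive")
})

test_that("membrane affinities reproduce every printed table row", {
  rows <- list(list(-11.1, 25704, -4.85),   # nilotinib
               list(-10.3, 23988, -4.09),   # imatinib
               list(-8.8, 6606, -3.38),     # dasatinib
               list(-10.9, 3467, -5.88))    # paclitaxel
  for (r in rows) {
    expect_equal(membrane_affinity(r[[1]], r[[2]], td_ctx), r[[3]],
                 tolerance = 0.011)
  }
  # pc = 1 leaves the affinity unchanged
  expect_identical(membrane_affinity(-5.0, 1, td_ctx), -5.0)
  expect_error(membrane_affinity(-5, 0), "positive")
  expect_error(membrane_affinity(-5, -2), "positive")
})

test_that("copy-number conversion reproduces the printed pump molarities", {
  geom <- cell_geometry()
  # printed values are rounded; +-2%
  expect_equal(copies_to_membrane_molarity(300000, geom), 100e-6,
               tolerance = 0.02)
  expect_equal(copies_to_membrane_molarity(300, geom), 0.1e-6,
               tolerance = 0.02)
  expect_identical(copies_to_membrane_molarity(0, geom), 0)
  expect_error(copies_to_membrane_molarity(-1, geom), "non-negative")
  # exact linearity
  set.seed(7)
  n <- stats::runif(10, 1, 1e6)
  expect_identical(copies_to_membrane_molarity(2 * n, geom),
                   2 * copies_to_membrane_molarity(n, geom))
})

test_that("cytosol volume matches the sphere-volume oracle", {
  # frozen hand calculation: (4/3) pi (7e-6 - 8e-9)^3 m^3 -> liters
  expect_equal(cytosol_volume(cell_geometry()), 1.431835e-12,
               tolerance = 1e-6)
  # unit-sphere scaling: r = 1 m, t -> 0
  expect_equal(cytosol_volume(cell_geometry(1, 1e-12)), (4 / 3) * pi * 1000,
               tolerance = 1e-8)
  # monotone in radius
  r <- seq(1e-6, 1e-5, length.out = 6)
  v <- vapply(r, function(ri) cytosol_volume(cell_geometry(ri, 8e-9)),
              numeric(1))
  expect_true(all(diff(v) > 0))
  expect_error(cell_geometry(1e-9, 8e-9), "radius")
})

test_that("drug_params derives the membrane-basis SBD Kd consistently", {
  d <- drug_params("nilotinib", -11.1, 25704, Kd_nbd = 2e-9, ctx = td_ctx)
  expect_equal(d$Kd_sbd_membrane, 3.842787e-4, tolerance = 1e-6)
  expect_equal(
    d$Kd_sbd_membrane,
    affinity_to_kd(membrane_affinity(-11.1, 25704, td_ctx), td_ctx))
  expect_error(drug_params("x", -5, 0, 1e-9), "positive")
  expect_error(drug_params("x", -5, 10, Kd_nbd = -1), "Kd_nbd")
})

test_that("the bundled drug table carries the published parameter set", {
  expect_setequal(names(td_drugs),
                  c("nilotinib", "imatinib", "dasatinib", "paclitaxel"))
  expect_equal(td_drugs$nilotinib$Kd_nbd, 2e-9)
  expect_equal(td_drugs$imatinib$Kd_nbd, 2e-7)
  expect_equal(td_drugs$dasatinib$Kd_nbd, 2.5e-7)
  expect_identical(td_drugs$paclitaxel$Kd_nbd, Inf)
  expect_equal(attr(td_drugs, "Kd_atp"), 1.16e-5)
  # membrane Kds equal exp(dG_mem / RT) row by row
  for (d in td_drugs) {
    expect_equal(d$Kd_sbd_membrane,
                 affinity_to_kd(
                   membrane_affinity(d$dG_sbd_aqueous,
                                     d$partition_coefficient, td_ctx),
                   td_ctx))
  }
})

test_that("read_drug_table rejects malformed tables", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines("name,partition_coefficient\nfoo,10", p)
  expect_error(read_drug_table(p), "missing columns")
  expect_error(read_drug_table("/nonexistent/file.csv"), "not found")
})
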