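# Scenario machinery. These tests run on deliberately coarse dose/ATP grids
# to stay fast; the full published sweeps live in test-acceptance.R.

test_that("scenario validates its fields", {
  expect_error(scenario(mechanism = "BAD"), "arg")
  expect_error(scenario(sweep = list(axis = "tki_ext", values = c(2, 1))),
               "sorted")
  expect_error(scenario(sweep = list(axis = "nope", values = 1)), "arg")
  expect_error(scenario(improvement = list(parameter = "Kd_nbd", fold = -1)),
               "fold")
  s <- scenario(sweep = list(axis = "atp", values = c(1e-4, 1e-3)))
  expect_s3_class(s, "pgp_scenario")
})

test_that("without the pump the readout is the passive equilibrium", {
  s <- scenario(tki = "nilotinib", pgp_total = 0, tki_ext = 1e-6)
  res <- run_scenario(s, td_params, td_drugs)
  # extracellular clamped at 3 uM: the aqueous phases equalise there
  expect_equal(res$readout, 3e-6, tolerance = 1e-6)
  expect_equal(res$readout, no_pump_reference(scenario(), td_params, td_drugs),
               tolerance = 1e-8)
})

test_that("unknown drug names are a configuration error", {
  expect_error(run_scenario(scenario(tki = "gefitinib"), td_params, td_drugs),
               "unknown drug")
})

test_that("a TKI that cannot bind anywhere does not act", {
  doses <- c(1e-7, 1e-5)
  drugs2 <- td_drugs
  drugs2$inert <- inert_tki
  s_inert <- scenario(tki = "inert", pgp_total = 1e-6,
                      sweep = list(axis = "tki_ext", values = doses))
  r_inert <- run_scenario(s_inert, td_params, drugs2)
  # oracle: direct simulation with no TKI at all
  s_none <- scenario(tki = "nilotinib", pgp_total = 1e-6, tki_ext = 0)
  r_none <- run_scenario(s_none, td_params, td_drugs)
  expect_equal(r_inert$readout, rep(r_none$readout, 2), tolerance = 1e-6)
})

test_that("NBD_ONLY knockout of a TKI with no NBD binding equals no TKI", {
  # knocking out the SBD of a TKI that (already) cannot bind the NBD leaves
  # a drug that binds nothing
  drugs2 <- td_drugs
  drugs2$sbdonly <- drug_params("sbdonly", partition_coefficient = 1000,
                                Kd_nbd = Inf, Kd_sbd_membrane = 1e-5)
  s <- scenario(tki = "sbdonly", pgp_total = 1e-6, tki_ext = 1e-5,
                mechanism = "NBD_ONLY")
  r <- run_scenario(s, td_params, drugs2)
  r0 <- run_scenario(scenario(tki = "sbdonly", pgp_total = 1e-6, tki_ext = 0),
                     td_params, drugs2)
  expect_equal(r$readout, r0$readout, tolerance = 1e-6)
})

test_that("dose-response is monotone in dose and in pump level", {
  doses <- c(3e-7, 3e-6, 3e-5)
  dr <- dose_response("imatinib", doses, pgp_levels = c(1e-6, 1e-5),
                      base = scenario(), params = td_params, drugs = td_drugs)
  for (lev in dr) {
    expect_true(all(diff(lev$readout) >= -1e-9 * max(lev$readout)))
  }
  # at fixed dose, accumulation non-increasing in pump level
  expect_true(all(dr[[2]]$readout <= dr[[1]]$readout * (1 + 1e-9)))
})

test_that("mechanism decomposition: NBD binding on top of SBD never hurts", {
  # One-sided composition bound. Adding NBD binding to an SBD-binding TKI
  # can only slow the pump (it does not deplete cytosolic TKI), so
  # BOTH >= SBD_ONLY everywhere. The converse bound does NOT hold: enabling
  # SBD binding makes the TKI a transported substrate, lowers its cytosolic
  # level and can weaken NBD inhibition dramatically (the excretion effect
  # discussed in the source analysis) — asserted below as a regression.
  atps <- c(1e-4, 1e-3)
  readout <- function(tki, mech) {
    s <- scenario(tki = tki, tki_ext = 1e-6, pgp_total = 1e-5,
                  mechanism = mech, sweep = list(axis = "atp", values = atps))
    run_scenario(s, td_params, td_drugs)$readout
  }
  for (tki in c("nilotinib", "imatinib")) {
    rb <- readout(tki, "BOTH")
    rs <- readout(tki, "SBD_ONLY")
    expect_true(all(rb >= rs * (1 - 1e-6)))
  }
  # excretion effect: for nilotinib (strong NBD binder, strong substrate)
  # the full model accumulates far less paclitaxel than the NBD-only ideal
  rn <- readout("nilotinib", "NBD_ONLY")
  rb <- readout("nilotinib", "BOTH")
  expect_true(all(rb < rn))
})

test_that("transition_point flags degenerate identical curves", {
  drugs2 <- td_drugs
  drugs2$inert <- inert_tki
  tp <- transition_point("inert", atp_range = c(1e-4, 1e-3),
                         base = scenario(tki_ext = 1e-6, pgp_total = 1e-6),
                         n_grid = 4, params = td_params, drugs = drugs2)
  expect_true(tp$ambiguous)
})

test_that("transition_point brackets a genuine crossing", {
  tp <- transition_point("imatinib", atp_range = c(1e-5, 1e-2),
                         base = scenario(tki_ext = 1e-6, pgp_total = 1e-5),
                         n_grid = 7, params = td_params, drugs = td_drugs)
  expect_false(is.na(tp$transition))
  expect_equal(tp$n_crossings, 1L)
  # the readout difference changes sign across the returned value
  d <- tp$grid$nbd_only - tp$grid$sbd_only
  below <- max(which(tp$grid$atp < tp$transition))
  expect_lt(d[below] * d[below + 1L], 0)
})

test_that("improvement with fold = 1 reproduces the baseline exactly", {
  s <- scenario(tki = "dasatinib", pgp_total = 1e-6,
                sweep = list(axis = "tki_ext", values = c(1e-6, 1e-5)))
  scr <- improvement_screen("dasatinib", base = s, fold = 1,
                            params = td_params, drugs = td_drugs)
  for (p in c("Kd_nbd", "Kd_sbd", "PC")) {
    expect_equal(scr[[p]]$readout, scr$baseline$readout, tolerance = 1e-9)
  }
})

test_that("improving the NBD affinity never decreases accumulation", {
  s <- scenario(tki = "dasatinib", pgp_total = 1e-6,
                sweep = list(axis = "tki_ext", values = c(1e-6, 3e-6, 1e-5)))
  scr <- improvement_screen("dasatinib", base = s, fold = 10,
                            params = td_params, drugs = td_drugs)
  expect_true(all(scr$Kd_nbd$readout >=
                    scr$baseline$readout * (1 - 1e-6)))
})

test_that("steady state is idempotent under further integration", {
  s <- scenario(tki = "nilotinib", tki_ext = 1e-6, pgp_total = 1e-5)
  m <- pgp_model(td_drugs$paclitaxel, td_drugs$nilotinib, td_params)
  ss <- pgp_steady_state(m, initial_state(m, sub_ext = 3e-6, tki_ext = 1e-6,
                                          atp = 3e-3, pgp_total = 1e-5))
  expect_true(ss$converged)
  tr <- simulate_trajectory(m, ss$y, c(0, 1e4))
  drift <- abs(tr[2, "sub_cyt"] - ss$y[["sub_cyt"]]) / ss$y[["sub_cyt"]]
  expect_lt(drift, 1e-3)
})

test_that("sweep results serialise to tidy CSV", {
  s <- scenario(tki = "nilotinib", pgp_total = 0,
                sweep = list(axis = "tki_ext", values = c(1e-7, 1e-6)))
  res <- run_scenario(s, td_params, td_drugs)
  p <- withr::local_tempfile(fileext = ".csv")
  write_sweep_csv(res, p)
  tab <- read.csv(p)
  expect_setequal(names(tab), c("axis", "sweep_value", "variable", "value_M"))
  expect_equal(nrow(tab), 2L * 16L)  # two sweep values x 16 state variables
})
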