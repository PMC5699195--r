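# The pump-cycle ODE core: state enumeration, mass/pump conservation,
# clamping, equilibrium structure.

test_that("the pump lattice enumerates its states in the documented order", {
  st <- pgp_states()
  expect_equal(nrow(st), 9L)
  expect_equal(st$sbd[1], "EMPTY")
  expect_equal(st$nbd[1], "EMPTY")
  expect_false(any(duplicated(paste(st$sbd, st$nbd))))
  # row-major in SBD: first three rows share SBD = EMPTY
  expect_equal(st$sbd[1:3], rep("EMPTY", 3))
  st12 <- pgp_states("noncompetitive")
  expect_equal(nrow(st12), 12L)
  expect_true("BOTH" %in% st12$sbd)
})

test_that("rhs is zero for the empty resting system", {
  m <- pgp_model(td_drugs$paclitaxel, td_drugs$nilotinib, td_params)
  y <- initial_state(m, sub_ext = 0, tki_ext = 0, atp = 0, pgp_total = 1e-5)
  expect_identical(unname(pgp_rhs(y, m)), rep(0, m$n))
})

test_that("pump mass is conserved by construction, for random states", {
  set.seed(101)
  for (scheme in c("competitive", "noncompetitive")) {
    m <- pgp_model(td_drugs$paclitaxel, td_drugs$imatinib, td_params,
                   scheme = scheme)
    for (rep in 1:10) {
      dy <- pgp_rhs(random_state(m), m)
      expect_lt(abs(sum(dy[m$pump_idx])),
                1e-12 * max(abs(dy[m$pump_idx]), 1e-300))
    }
  }
})

test_that("drug moles are conserved when turnover is off and clamps open", {
  set.seed(202)
  par0 <- kinetic_parameters(k_cat = 0, extracellular_clamped = FALSE,
                             atp_clamped = FALSE)
  for (scheme in c("competitive", "noncompetitive")) {
    m <- pgp_model(td_drugs$paclitaxel, td_drugs$dasatinib, par0,
                   scheme = scheme)
    st <- m$states
    sub_bound <- which(st$sbd %in% c("SUBSTRATE", "BOTH"))
    tki_bound_counts <- (st$sbd %in% c("TKI", "BOTH")) + (st$nbd == "TKI")
    p <- m$params
    for (rep in 1:10) {
      dy <- pgp_rhs(random_state(m), m)
      sub_terms <- c(dy[["sub_ext"]] * p$V_ext, dy[["sub_mem"]] * p$V_mem,
                     dy[["sub_cyt"]] * p$V_cyt,
                     p$V_mem * dy[m$pump_idx][sub_bound])
      tki_terms <- c(dy[["tki_ext"]] * p$V_ext, dy[["tki_mem"]] * p$V_mem,
                     dy[["tki_cyt"]] * p$V_cyt,
                     p$V_mem * dy[m$pump_idx] * tki_bound_counts)
      expect_lt(abs(sum(sub_terms)), 1e-10 * max(abs(sub_terms), 1e-300))
      expect_lt(abs(sum(tki_terms)), 1e-10 * max(abs(tki_terms), 1e-300))
    }
  }
})

test_that("rhs validates its input", {
  m <- pgp_model(td_drugs$paclitaxel, td_drugs$nilotinib, td_params)
  y <- initial_state(m, sub_ext = 1e-6)
  expect_error(pgp_rhs(y[-1], m), "entries")
  y[1] <- -1e-9
  expect_error(pgp_rhs(y, m), "negative")
})

test_that("pump conservation and clamping hold along trajectories", {
  m <- pgp_model(td_drugs$paclitaxel, td_drugs$nilotinib, td_params)
  y0 <- initial_state(m, sub_ext = 3e-6, tki_ext = 1e-6, atp = 3e-3,
                      pgp_total = 1e-5)
  tr <- simulate_trajectory(m, y0, c(0, 0.1, 1, 10, 100))
  pump_tot <- rowSums(tr[, 1 + m$pump_idx])
  expect_equal(pump_tot, rep(1e-5, nrow(tr)), tolerance = 1e-8)
  # clamped variables are bit-identical to their initial values
  expect_identical(unname(tr[, "sub_ext"]), rep(3e-6, nrow(tr)))
  expect_identical(unname(tr[, "tki_ext"]), rep(1e-6, nrow(tr)))
  expect_identical(unname(tr[, "atp_cyt"]), rep(3e-3, nrow(tr)))
  # no state dips below -atol
  expect_gt(min(tr[, -1]), -td_params$atol)
})

test_that("the 9- and 12-state lattices relax to the closed-form occupancy", {
  par0 <- kinetic_parameters(k_cat = 0)
  for (scheme in c("competitive", "noncompetitive")) {
    m <- pgp_model(td_drugs$paclitaxel, td_drugs$nilotinib, par0,
                   scheme = scheme)
    ss <- pgp_steady_state(
      m, initial_state(m, sub_ext = 3e-6, tki_ext = 1e-6, atp = 3e-3,
                       pgp_total = 1e-5))
    expect_true(ss$converged)
    occ <- equilibrium_occupancy(
      m, list(sub_mem = ss$y[["sub_mem"]], tki_mem = ss$y[["tki_mem"]],
              atp_cyt = ss$y[["atp_cyt"]], tki_cyt = ss$y[["tki_cyt"]]))
    expect_equal(sum(occ), 1, tolerance = 1e-12)
    frac <- ss$y[m$pump_idx] / sum(ss$y[m$pump_idx])
    expect_equal(unname(frac), unname(occ), tolerance = 1e-6)
  }
})

test_that("occupancy closed form has the textbook half-saturation point", {
  par0 <- kinetic_parameters(k_cat = 0)
  m <- pgp_model(td_drugs$paclitaxel, inert_tki, par0)
  occ <- equilibrium_occupancy(
    m, list(sub_mem = td_drugs$paclitaxel$Kd_sbd_membrane))
  sbd_sub <- sum(occ[m$states$sbd == "SUBSTRATE"])
  expect_equal(sbd_sub, 0.5, tolerance = 1e-12)
  # no ligands at all: everything in the apo state
  occ0 <- equilibrium_occupancy(m, list())
  expect_identical(unname(occ0[1]), 1)
  # misuse guard
  m1 <- pgp_model(td_drugs$paclitaxel, inert_tki, td_params)
  expect_error(equilibrium_occupancy(m1, list()), "k_cat")
})

test_that("without the pump each drug equilibrates to its partition coefficient", {
  par0 <- kinetic_parameters(extracellular_clamped = FALSE,
                             atp_clamped = FALSE)
  m <- pgp_model(td_drugs$paclitaxel, td_drugs$dasatinib, par0)
  ss <- pgp_steady_state(
    m, initial_state(m, sub_ext = 1e-6, tki_ext = 1e-6, atp = 0,
                     pgp_total = 0))
  expect_true(ss$converged)
  expect_equal(ss$y[["sub_mem"]] / ss$y[["sub_cyt"]],
               td_drugs$paclitaxel$partition_coefficient, tolerance = 1e-6)
  expect_equal(ss$y[["sub_mem"]] / ss$y[["sub_ext"]],
               td_drugs$paclitaxel$partition_coefficient, tolerance = 1e-6)
  expect_equal(ss$y[["tki_mem"]] / ss$y[["tki_cyt"]],
               td_drugs$dasatinib$partition_coefficient, tolerance = 1e-6)
})

test_that("drug_moles audits the trajectory when nothing is consumed", {
  par0 <- kinetic_parameters(k_cat = 0, extracellular_clamped = FALSE,
                             atp_clamped = FALSE)
  m <- pgp_model(td_drugs$paclitaxel, td_drugs$nilotinib, par0)
  y0 <- initial_state(m, sub_ext = 3e-6, tki_ext = 1e-6, atp = 3e-3,
                      pgp_total = 1e-5)
  tr <- simulate_trajectory(m, y0, c(0, 1, 50))
  m0 <- drug_moles(y0, m, "substrate")
  for (i in seq_len(nrow(tr))) {
    yi <- tr[i, -1]
    expect_equal(drug_moles(yi, m, "substrate"), m0, tolerance = 1e-6)
  }
})
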