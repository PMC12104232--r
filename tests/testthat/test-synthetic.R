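test_that("the phantom is deterministic, sized as designed, and disjoint", {
  g <- small_phantom_grid()
  s1 <- make_phantom(g, seed = 5)
  s2 <- make_phantom(g, seed = 5)
  for (lb in names(s1$masks))
    expect_identical(s1$masks[[lb]]$occupancy, s2$masks[[lb]]$occupancy)
  s3 <- make_phantom(g, seed = 6)
  expect_false(identical(s1$masks$GTVnx$occupancy, s3$masks$GTVnx$occupancy))

  # target volume within 10% of the analytic ellipsoid volume
  v_analytic <- 4 / 3 * pi * 22 * 18 * 18 / 1000
  expect_lt(abs(volume_cc(s1$masks$GTVnx) - v_analytic) / v_analytic, 0.10)

  expect_false(any(s1$masks$GTVnx$occupancy & s1$masks$SpinalCord$occupancy))
  expect_setequal(names(s1$masks),
                  c("GTVnx", "SpinalCord", "Parotid_L", "Parotid_R",
                    "OpticNerve_L", "OpticNerve_R"))
  expect_error(make_phantom(voxel_grid(c(10, 10, 10), c(1, 1, 1))),
               "too small")
})

test_that("a zero-perturbation observer reproduces the standard exactly", {
  g <- small_phantom_grid()
  std <- make_phantom(g, seed = 5)
  obs <- simulate_observer(std, observer_model("null", 0, 0, 0, seed = 9))
  for (lb in names(std$masks)) {
    expect_identical(obs$masks[[lb]]$occupancy, std$masks[[lb]]$occupancy)
    expect_equal(dsc(obs$masks[[lb]], std$masks[[lb]]), 1)
  }
})

test_that("negative volume bias shrinks every structure", {
  g <- small_phantom_grid()
  std <- make_phantom(g, seed = 5)
  obs <- simulate_observer(std, observer_model("eroder", -2, 0, 0, seed = 9))
  for (lb in names(std$masks)) {
    dv <- delta_v(volume_cc(obs$masks[[lb]]), volume_cc(std$masks[[lb]]))
    # voxel quantization and the thin-organ erosion floor can leave a
    # sub-voxel organ unchanged, but erosion never grows anything
    expect_lte(dv, 0)
  }
  for (lb in c("GTVnx", "SpinalCord", "Parotid_L", "Parotid_R")) {
    expect_lt(delta_v(volume_cc(obs$masks[[lb]]),
                      volume_cc(std$masks[[lb]])), 0)
  }
  # systematic erosion never annihilates even the smallest organs
  obs4 <- simulate_observer(std, observer_model("hard", -4, 1.5, 0.5, seed = 9))
  expect_true(all(vapply(obs4$masks, function(m) any(m$occupancy), logical(1))))
})

test_that("simulated observers are deterministic given their seed", {
  g <- small_phantom_grid()
  std <- make_phantom(g, seed = 5)
  m <- observer_model("A", -1, 1.5, 0.5, seed = 33)
  o1 <- simulate_observer(std, m)
  o2 <- simulate_observer(std, m)
  for (lb in names(std$masks))
    expect_identical(o1$masks[[lb]]$occupancy, o2$masks[[lb]]$occupancy)
})

test_that("more surface noise lowers the mean Dice against the standard", {
  g <- small_phantom_grid()
  std <- make_phantom(g, seed = 5)
  mean_dsc <- function(noise) {
    mean(vapply(1:10, function(s) {
      o <- simulate_observer(std, observer_model("n", 0, noise, 0, seed = s))
      dsc(o$masks$GTVnx, std$masks$GTVnx)
    }, double(1)))
  }
  d <- vapply(c(0.5, 2, 4), mean_dsc, double(1))
  expect_true(all(diff(d) < 0))
})

test_that("dose surrogate fully covers the planning target and falls off outside", {
  g <- small_phantom_grid()
  std <- make_phantom(g, seed = 5)
  ptv <- expand_margin(std$masks$GTVnx, 3); ptv$label <- "PTVnx"
  dm <- dose_model(penumbra_sigma_mm = 3)
  dose <- synthesize_dose(structure_set(list(ptv), "std"), dm)
  expect_equal(pdc(dose, ptv, 70), 100)

  # a plan conformal to a strict superset still covers the standard target
  grown <- expand_margin(ptv, 4); grown$label <- "PTVnx"
  dose_big <- synthesize_dose(structure_set(list(grown), "big"), dm)
  expect_equal(pdc(dose_big, ptv, 70), 100)
  expect_error(synthesize_dose(structure_set(list(std$masks$GTVnx), "x"), dm),
               "target labels")
})

test_that("under-contoured plans leave cold spots on the standard target", {
  g <- small_phantom_grid()
  std <- make_phantom(g, seed = 5)
  ptv <- expand_margin(std$masks$GTVnx, 3); ptv$label <- "PTVnx"
  obs <- simulate_observer(std, observer_model("under", -4, 0, 0, seed = 2))
  optv <- expand_margin(obs$masks$GTVnx, 3); optv$label <- "PTVnx"
  dose <- synthesize_dose(structure_set(list(optv), "under"),
                          dose_model(penumbra_sigma_mm = 3))
  expect_lt(pdc(dose, ptv, 70), 100)
  e <- eud(compute_dvh(dose, ptv)$voxel_doses_gy, a_exponent = -8)
  expect_lt(e, 70)
})

test_that("generated cohorts regenerate identically and write a full bundle", {
  g <- small_phantom_grid()
  observers <- list(observer_model("A", -2), observer_model("B", 2))
  c1 <- generate_cohort(2, observers, dose_model(), seed = 3, grid = g)
  c2 <- generate_cohort(2, observers, dose_model(), seed = 3, grid = g)
  expect_identical(
    c1$patients[[2]]$sets$A$masks$GTVnx$occupancy,
    c2$patients[[2]]$sets$A$masks$GTVnx$occupancy)
  expect_identical(c1$patients[[1]]$doses$B$dose_gy,
                   c2$patients[[1]]$doses$B$dose_gy)
  expect_equal(length(c1$patients), 2)
  expect_setequal(names(c1$patients[[1]]$sets), c("A", "B"))

  dir <- file.path(tempdir(), "cohort_test")
  write_cohort(c1, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  # per patient: 7 standard masks (6 organs + PTV), dose, and per observer
  # 7 masks + dose
  p1 <- file.path(dir, "patient_001")
  expect_equal(length(list.files(file.path(p1, "standard"))), 7)
  expect_equal(length(list.files(file.path(p1, "A"))), 7)
  expect_true(file.exists(file.path(p1, "dose_A.nii.gz")))
  # round trip: a re-read mask equals the in-memory one
  m <- read_mask(file.path(p1, "standard", "GTVnx.nii.gz"))
  expect_identical(m$occupancy, c1$patients[[1]]$standard$masks$GTVnx$occupancy)
  unlink(dir, recursive = TRUE)
})
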