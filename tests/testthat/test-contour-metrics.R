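test_that("delta_v is the signed observer-minus-standard volume difference", {
  expect_equal(delta_v(30, 30), 0)
  # reconstructed observer volume = standard + reported difference
  expect_equal(delta_v(29.93 + 22.54, 29.93), 22.54)
  expect_equal(delta_v(10, 25), -15)  # under-contouring is negative
  expect_error(delta_v(-1, 5))
})

test_that("mmr is max over min with sane guards", {
  expect_equal(mmr(c(4, 4, 4)), 1)
  expect_equal(mmr(c(4, 6)), 1.5)
  expect_equal(mmr(c(1.1, 2.0, 3.3, 5.5)), 5)
  expect_error(mmr(c(3)), "at least 2")
  expect_error(mmr(c(0, 2)), "non-positive")
})

test_that("cv uses the sample SD and is scale invariant", {
  expect_equal(cv_volumes(c(5, 5, 5, 5)), 0)
  expect_equal(cv_volumes(c(4, 6)), sqrt(2) / 5)  # sample SD sqrt(2), mean 5
  set.seed(2)
  v <- runif(6, 1, 50)
  expect_equal(cv_volumes(v * 3.7), cv_volumes(v))
  expect_equal(mmr(v * 3.7), mmr(v))
  expect_gte(mmr(v), 1)
  expect_gte(cv_volumes(v), 0)
})

test_that("dsc counts overlap voxels symmetrically", {
  g <- voxel_grid(c(8, 8, 8), c(1, 1, 1))
  a <- cube_mask(g, c(1, 1, 1), c(2, 2, 2))   # 8 voxels
  b <- cube_mask(g, c(2, 1, 1), c(3, 2, 2))   # 8 voxels, 4 shared
  expect_equal(dsc(a, b), 0.5)
  expect_equal(dsc(b, a), dsc(a, b))
  expect_equal(dsc(a, a), 1)
  disj <- cube_mask(g, c(6, 6, 6), c(7, 7, 7))
  expect_equal(dsc(a, disj), 0)
  empty <- structure_mask(array(FALSE, c(8, 8, 8)), g)
  expect_error(dsc(empty, empty), "empty")
})

test_that("dsc decreases monotonically as a nested mask erodes", {
  g <- voxel_grid(c(20, 20, 16), c(1, 1, 1.5))
  outer_m <- cube_mask(g, c(3, 3, 3), c(17, 17, 13))
  vals <- vapply(0:5, function(s) {
    inner <- cube_mask(g, c(3 + s, 3 + s, 3 + s), c(17 - s, 17 - s, 13 - s))
    dsc(outer_m, inner)
  }, double(1))
  expect_true(all(diff(vals) < 0))
})

test_that("hd95 reproduces simple closed-form distances", {
  g <- voxel_grid(c(6, 6, 12), c(1, 1, 2))
  a <- cube_mask(g, c(3, 3, 3), c(3, 3, 3))
  b <- cube_mask(g, c(3, 3, 8), c(3, 3, 8))   # 5 slices apart, 2 mm slices
  expect_equal(as.numeric(hd95(a, b)), 10)
  expect_equal(as.numeric(hd95(a, a)), 0)
  expect_equal(as.numeric(hd95(b, a)), as.numeric(hd95(a, b)))
  empty <- structure_mask(array(FALSE, g$shape), g)
  expect_error(hd95(a, empty), "empty")
})

test_that("hd95 equals the all-pairs boundary oracle on random masks", {
  set.seed(31)
  for (rep in 1:25) {
    shp <- sample(5:14, 3, replace = TRUE)
    sp <- c(runif(1, 0.7, 1.5), runif(1, 0.7, 1.5), runif(1, 1.5, 3))
    g <- voxel_grid(shp, sp)
    a <- random_blob(g)
    b <- random_blob(g)
    got <- hd95(structure_mask(a, g, "a"), structure_mask(b, g, "b"))
    expect_equal(as.numeric(got), brute_hd95(a, b, sp), tolerance = 1e-12)
  }
})

test_that("identical observers give back their mask as STAPLE consensus", {
  g <- voxel_grid(c(8, 8, 8), c(1, 1, 1))
  m <- cube_mask(g, c(2, 2, 2), c(6, 6, 5))
  res <- staple(list(m, m, m))
  expect_identical(res$consensus$occupancy, m$occupancy)
  expect_true(all(res$sensitivity > 0.99))
  expect_true(all(res$specificity > 0.99))
})

test_that("the STAPLE E-step posterior matches a hand-computed pass", {
  # 4-voxel line, 3 observers of equal initial reliability p = q = 0.99,
  # prior 0.5; vote counts per voxel: 3, 2, 1, 0.
  g <- voxel_grid(c(4, 1, 1), c(1, 1, 1))
  mk <- function(v) structure_mask(array(as.logical(v), c(4, 1, 1)), g)
  masks <- list(mk(c(1, 1, 1, 0)), mk(c(1, 1, 0, 0)), mk(c(1, 0, 0, 0)))
  res <- staple(masks, max_iter = 0, prior = 0.5)
  p <- 0.99
  # posterior odds = (p/(1-p))^m * ((1-p)/p)^(3-m) for m of 3 votes, prior 0.5
  w_hand <- vapply(c(3, 2, 1, 0), function(m) {
    odds <- (p / (1 - p))^m * ((1 - p) / p)^(3 - m)
    odds / (1 + odds)
  }, double(1))
  expect_equal(as.vector(res$posterior), w_hand, tolerance = 1e-12)
  # the 2-of-3 voxel is in the consensus, the 1-of-3 voxel is not
  expect_identical(as.vector(res$consensus$occupancy),
                   c(TRUE, TRUE, FALSE, FALSE))
})

test_that("STAPLE consensus is invariant to observer ordering", {
  g <- voxel_grid(c(6, 6, 4), c(1, 1, 2))
  set.seed(17)
  masks <- lapply(1:4, function(i) structure_mask(random_blob(g), g))
  r1 <- staple(masks)
  r2 <- staple(masks[c(3, 1, 4, 2)])
  expect_identical(r1$consensus$occupancy, r2$consensus$occupancy)
  expect_equal(sort(r1$sensitivity), sort(r2$sensitivity))
})

test_that("equally-reliable STAPLE with uniform prior is the majority vote", {
  g <- voxel_grid(c(2, 2, 2), c(1, 1, 1))
  rotl8 <- function(x, s) bitwAnd(bitwOr(bitwShiftL(x, s), bitwShiftR(x, 8 - s)), 255L)
  for (idx in 0:255) {
    masks <- lapply(0:2, function(j) {
      bits <- as.integer(intToBits(rotl8(idx, j)))[1:8]
      structure_mask(array(as.logical(bits), c(2, 2, 2)), g)
    })
    res <- staple(masks, prior = 0.5, shared = TRUE)
    votes <- Reduce(`+`, lapply(masks, function(m) m$occupancy))
    expect_identical(res$consensus$occupancy, votes >= 2,
                     info = paste("pattern", idx))
  }
})

test_that("an all-empty observer triggers the degenerate-rate warning", {
  g <- voxel_grid(c(4, 4, 4), c(1, 1, 1))
  m <- cube_mask(g, c(2, 2, 2), c(3, 3, 3))
  empty <- structure_mask(array(FALSE, c(4, 4, 4)), g)
  expect_warning(res <- staple(list(m, m, empty)), "all-empty")
  expect_true(all(res$sensitivity >= 1e-6 & res$sensitivity <= 1 - 1e-6))
})

test_that("group_report emits the expected per-observer and group rows", {
  g <- voxel_grid(c(12, 12, 10), c(1, 1, 2))
  ref <- cube_mask(g, c(4, 4, 4), c(9, 9, 7), "GTVnx")
  same <- lapply(1:4, function(i) ref)
  rep1 <- group_report(same, ref, paste0("obs", 1:4), "p1")
  expect_equal(nrow(rep1), 3 * 4 + 2)
  expect_true(all(rep1$value[rep1$metric_name == "dV_cc"] == 0))
  expect_true(all(rep1$value[rep1$metric_name == "DSC"] == 1))
  expect_true(all(rep1$value[rep1$metric_name == "HD95_mm"] == 0))
  expect_equal(rep1$value[rep1$metric_name == "MMR"], 1)
  expect_equal(rep1$value[rep1$metric_name == "CV"], 0)

  eroded <- cube_mask(g, c(5, 5, 4), c(9, 9, 7), "GTVnx")
  rep2 <- group_report(list(ref, eroded, ref), ref, paste0("obs", 1:3), "p1")
  dv <- rep2$value[rep2$metric_name == "dV_cc"]
  expect_equal(sum(dv < 0), 1)
  # the report's HD95 is the same symmetric statistic hd95() computes
  expect_equal(rep2$value[rep2$metric_name == "HD95_mm" &
                            rep2$observer_id == "obs2"],
               as.numeric(hd95(eroded, ref)))
})
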