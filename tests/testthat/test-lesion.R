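grid3 <- function(d = c(4, 5, 3), fill = 0) array(fill, dim = d)

test_that("binarisation is strict at the threshold and preserves metadata", {
  a <- grid3()
  a[1, 1, 1] <- 0.5      # exactly at threshold -> 0
  a[2, 1, 1] <- 0.500001
  a[3, 1, 1] <- 1
  vg <- volume_grid(a, voxel_dims = c(2, 2, 2), space = "MNI")
  bm <- binarize_mask(vg)
  expect_equal(bm$data[1, 1, 1], 0)
  expect_equal(bm$data[2, 1, 1], 1)
  expect_equal(bm$data[3, 1, 1], 1)
  expect_equal(bm$voxel_dims, c(2, 2, 2))
  expect_equal(binarize_mask(volume_grid(grid3()))$data, grid3())
  expect_error(binarize_mask(volume_grid(grid3(fill = 1.1))), "outside")
  # elementwise oracle on a random volume
  set.seed(3)
  r <- array(runif(60), dim = c(4, 5, 3))
  bm2 <- binarize_mask(volume_grid(r))
  for (i in seq_along(r)) expect_equal(bm2$data[i], as.numeric(r[i] > 0.5))
})

test_that("max-probability atlas takes rater fractions and honours ties", {
  d <- c(4, 4, 2)
  mk <- function(vox) {
    a <- array(0, d); a[vox] <- 1
    binary_mask(a)
  }
  # one rater per ROI, disjoint boxes -> union, probabilities in {0,1}
  res <- build_max_prob_atlas(list(A = list(mk(1:4)), B = list(mk(9:12))))
  expect_equal(sort(unique(as.vector(res$atlas$labels))), c(0L, 1L, 2L))
  expect_true(all(res$prob_maps$A$data %in% c(0, 1)))
  expect_equal(which(res$atlas$labels == res$atlas$legend[["A"]]), 1:4)

  # 2 raters, voxel marked by 1 of 2 for A only -> probability 0.5, label A
  res2 <- build_max_prob_atlas(list(A = list(mk(1), mk(c(1, 2))),
                                    B = list(mk(5), mk(5))))
  expect_equal(res2$prob_maps$A$data[2], 0.5)
  expect_equal(res2$atlas$labels[2], res2$atlas$legend[["A"]])

  # tie 0.5 vs 0.5 -> tie code
  res3 <- build_max_prob_atlas(list(A = list(mk(1), mk(2)),
                                    B = list(mk(1), mk(3))))
  expect_equal(res3$prob_maps$A$data[1], 0.5)
  expect_equal(res3$prob_maps$B$data[1], 0.5)
  expect_equal(res3$atlas$labels[1], 0L)
  res3b <- build_max_prob_atlas(list(A = list(mk(1), mk(2)),
                                     B = list(mk(1), mk(3))), tie_code = 9L)
  expect_equal(res3b$atlas$labels[1], 9L)
  expect_equal(res3b$atlas$legend[["undefined"]], 9L)

  # probability values live on the 1/n rater grid
  res4 <- build_max_prob_atlas(list(A = list(mk(1), mk(1:2), mk(1:3))))
  expect_true(all(res4$prob_maps$A$data * 3 ==
                    round(res4$prob_maps$A$data * 3)))

  # order independence away from ties
  resAB <- build_max_prob_atlas(list(A = list(mk(1:4)), B = list(mk(9:12))))
  resBA <- build_max_prob_atlas(list(B = list(mk(9:12)), A = list(mk(1:4))))
  labA <- resAB$atlas$labels == resAB$atlas$legend[["A"]]
  labA2 <- resBA$atlas$labels == resBA$atlas$legend[["A"]]
  expect_equal(labA, labA2)

  expect_error(build_max_prob_atlas(list()), "named list")
  expect_error(build_max_prob_atlas(list(A = list())), "at least one rater")
  bad <- binary_mask(array(0, c(2, 2, 2)))
  expect_error(build_max_prob_atlas(list(A = list(mk(1)), B = list(bad))),
               "grid")
})

test_that("posterior truncation restricts ROIs to the reference extent", {
  d <- c(3, 31, 3)
  lab <- array(0L, d)
  lab[2, 11:21, 2] <- 1L   # reference spans slices 11..21 on the anterior axis
  lab[1, 1:31, 2] <- 2L    # ITG-like ROI spanning everything
  atl <- roi_atlas(lab, c(PRc = 1L, ITG = 2L))
  tr <- truncate_posterior(atl, "ITG", "PRc")
  itg_slices <- which(apply(tr$labels == 2L, 2, any))
  expect_equal(min(itg_slices), 11L)
  expect_equal(max(itg_slices), 31L)
  # untouched ROI list -> unchanged; reference covering everything -> unchanged
  expect_identical(truncate_posterior(atl, character(), "PRc"), atl)
  lab2 <- lab; lab2[3, 1:31, 1] <- 0L
  atl2 <- roi_atlas(lab, c(PRc = 1L, ITG = 2L))
  full <- atl2; full$labels[2, 1:31, 2] <- 1L
  expect_equal(truncate_posterior(full, "ITG", "PRc")$labels, full$labels)
  expect_error(truncate_posterior(atl, "ITG", "Missing"), "unknown ROI")
  empty <- atl; empty$labels[empty$labels == 1L] <- 0L
  expect_error(truncate_posterior(empty, "ITG", "PRc"), "empty")
})

test_that("damage proportions and volumes match counting oracles", {
  d <- c(4, 4, 2)
  lab <- array(0L, d); lab[1:8] <- 1L; lab[9:16] <- 2L
  atl <- roi_atlas(lab, c(A = 1L, B = 2L))
  les <- array(0, d); les[1:4] <- 1
  bm <- binary_mask(les)
  dp <- roi_damage_profile(bm, atl, "p1")
  expect_equal(dp$damage[["A"]], 0.5)   # half of the 8-voxel ROI
  expect_equal(dp$damage[["B"]], 0)
  expect_equal(dp$lesion_volume_cm3, 4 * 1 / 1000)
  # full lesion -> all damage 1
  full <- binary_mask(array(1, d))
  expect_true(all(roi_damage_profile(full, atl)$damage == 1))
  # random lesion matches the voxel-loop oracle
  set.seed(8)
  rl <- binary_mask(array(rbinom(prod(d), 1, 0.4), d))
  dp2 <- roi_damage_profile(rl, atl)
  expect_equal(dp2$damage, oracle_roi_damage(rl$data, lab, c(A = 1L, B = 2L)),
               tolerance = 1e-12)
  # joint permutation invariance
  perm <- sample(prod(d))
  lab_p <- array(lab[perm], d); les_p <- array(rl$data[perm], d)
  dp3 <- roi_damage_profile(binary_mask(les_p), roi_atlas(lab_p, c(A = 1L, B = 2L)))
  expect_equal(dp3$damage, dp2$damage)
  # conservation: sum over ROIs of count x damage = lesioned voxels in ROIs
  counts <- c(A = sum(lab == 1L), B = sum(lab == 2L))
  expect_equal(sum(counts * dp2$damage), sum(rl$data[lab > 0]))
  # empty ROI is missing, not zero
  atl3 <- roi_atlas(lab, c(A = 1L, B = 2L, C = 3L))
  expect_true(is.na(roi_damage_profile(rl, atl3)$damage[["C"]]))
  # grid mismatch
  expect_error(roi_damage_profile(binary_mask(array(0, c(2, 2, 2))), atl),
               "do not match")
})

test_that("1 mm isotropic mask with 12900 damaged voxels is 12.9 cm^3", {
  d <- c(30, 30, 20)
  les <- array(0, d); les[seq_len(12900)] <- 1
  expect_equal(lesion_volume_cm3(binary_mask(les, voxel_dims = c(1, 1, 1))),
               12.9)
})

test_that("hemisphere-labelled ROIs pool by name unless kept separate", {
  d <- c(4, 4, 2)
  lab <- array(0L, d); lab[1:4] <- 1L; lab[5:8] <- 2L
  atl <- roi_atlas(lab, c(L_PRc = 1L, R_PRc = 2L))
  les <- array(0, d); les[1:4] <- 1
  merged <- roi_damage_profile(binary_mask(les), atl)
  expect_equal(names(merged$damage), "PRc")
  expect_equal(merged$damage[["PRc"]], 0.5)
  split <- roi_damage_profile(binary_mask(les), atl, merge_hemispheres = FALSE)
  expect_equal(split$damage[["L_PRc"]], 1)
  expect_equal(split$damage[["R_PRc"]], 0)
})

test_that("damage intercorrelations match pairwise Pearson oracles", {
  mk_prof <- function(id, v)
    structure(list(patient = id,
                   damage = setNames(v, c("A", "B", "C")),
                   lesion_volume_cm3 = 0), class = "damage_profile")
  profs <- list(mk_prof("p1", c(0, 0, 0.2)), mk_prof("p2", c(1, 1, 0.1)),
                mk_prof("p3", c(2, 2, 0.9)), mk_prof("p4", c(3, 3, 0.4)))
  ic <- damage_intercorrelations(profs)
  expect_equal(ic$r["A", "B"], 1.0)
  # anti-correlated vectors
  profs2 <- lapply(1:4, function(i) mk_prof(i, c(i - 1, 4 - i, runif(1))))
  expect_equal(damage_intercorrelations(profs2)$r["A", "B"], -1.0)
  # random profiles vs oracle
  set.seed(11)
  profs3 <- lapply(1:6, function(i) mk_prof(i, runif(3)))
  ic3 <- damage_intercorrelations(profs3)
  m <- do.call(rbind, lapply(profs3, function(p) p$damage))
  for (a in 1:2) for (b in (a + 1):3) {
    o <- oracle_pearson(m[, a], m[, b])
    expect_equal(ic3$r[a, b], o$r, tolerance = 1e-12)
    expect_equal(ic3$p[a, b], o$p, tolerance = 1e-12)
  }
  # zero-variance ROI flagged undefined
  profs4 <- lapply(1:4, function(i) mk_prof(i, c(0.5, runif(2))))
  ic4 <- damage_intercorrelations(profs4)
  expect_true(all(is.na(ic4$p["A", c("B", "C")])))
  expect_error(damage_intercorrelations(profs4[1:2]), "at least 3")
})
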