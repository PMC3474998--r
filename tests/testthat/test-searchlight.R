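# brute-force offset oracle over the full cube
brute_offsets <- function(r) {
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  g <- g[g$dx^2 + g$dy^2 + g$dz^2 <= r^2, ]
  nrow(g)
}

test_that("sphere offsets match brute-force enumeration", {
  expect_equal(nrow(sphere_offsets(0)), 1L)
  expect_equal(nrow(sphere_offsets(1)), 7L)
  for (r in 0:4) expect_equal(nrow(sphere_offsets(r)), brute_offsets(r))
  expect_true(any(apply(sphere_offsets(3), 1, function(v) all(v == 0))))
  expect_error(sphere_offsets(-1), "non-negative")
})

test_that("neighborhoods are restricted to the mask and shrink at borders", {
  # solid box mask: interior centers see the full 123-voxel sphere
  vol <- array(0L, dim = c(13, 13, 13)); vol[3:11, 3:11, 3:11] <- 1L
  mask <- roi_mask(vol)
  spec <- searchlight_spec(mask, 3)
  interior <- searchlight_neighborhood(c(7, 7, 7), spec)
  expect_equal(nrow(interior), 123L)
  face <- searchlight_neighborhood(c(3, 7, 7), spec)
  expect_lt(nrow(face), 123L)
  # containment for every center of an irregular mask
  m2 <- test_mask(n_vox = 50, seed = 4)
  sp2 <- searchlight_spec(m2, 3)
  for (ctr in sample(which(m2$data != 0), 10)) {
    co <- which(m2$data != 0, arr.ind = TRUE)
    cc <- co[match(ctr, which(m2$data != 0)), ]
    nb <- searchlight_neighborhood(cc, sp2)
    expect_true(all(m2$data[nb] != 0))
  }
  # single-voxel mask: neighborhood is just the center
  one <- array(0L, dim = c(7, 7, 7)); one[4, 4, 4] <- 1L
  nb1 <- searchlight_neighborhood(c(4, 4, 4), searchlight_spec(roi_mask(one), 3))
  expect_equal(nrow(nb1), 1L)
  expect_error(searchlight_neighborhood(c(1, 1, 1), sp2), "outside")
})

test_that("searchlight scores are 1 on a separable toy and near chance on noise", {
  # hand-traceable toy: 1 voxel, 2 trials/class, values well separated;
  # every LOO fold keeps both classes and classifies by sign
  vol <- array(0L, dim = c(3, 3, 3)); vol[2, 2, 2] <- 1L
  mask <- roi_mask(vol)
  bs <- beta_series(matrix(c(-2, -1, 1, 2), ncol = 1),
                    which(vol != 0, arr.ind = TRUE) - 1L)
  sc <- searchlight_scores(bs, c("B", "B", "A", "A"), searchlight_spec(mask, 3))
  expect_equal(as.numeric(sc), 1)

  # duplicating every trial never hurts the separable score
  bs2 <- beta_series(matrix(rep(c(-2, -1, 1, 2), 2), ncol = 1),
                     which(vol != 0, arr.ind = TRUE) - 1L)
  sc2 <- searchlight_scores(bs2, rep(c("B", "B", "A", "A"), 2),
                            searchlight_spec(mask, 3))
  expect_gte(as.numeric(sc2), as.numeric(sc) - 1e-12)

  # pure noise with i.i.d. labels: mean score across centers near 0.5
  m2 <- test_mask(n_vox = 40, seed = 6)
  bsn <- noise_betas(m2, 40, seed = 8)
  lab <- coin_labels(40, seed = 9)
  scn <- searchlight_scores(bsn, lab, searchlight_spec(m2, 2))
  expect_lt(abs(mean(scn) - 0.5), 0.12)

  expect_error(searchlight_scores(bsn, rep("A", 40), searchlight_spec(m2, 2)),
               "class")
})

test_that("feature selection obeys the documented ranking and tie-break rules", {
  m <- test_mask(n_vox = 40, seed = 5)
  spec <- searchlight_spec(m, 2)
  nv <- roi_voxel_count(m)
  nb <- hippmvpa:::build_neighborhoods(spec)

  # all scores tied, single-best: lexicographically first center wins
  sel <- select_features(rep(0.5, nv), spec, rule = "single_best")
  co <- which(m$data != 0, arr.ind = TRUE)
  first <- order(co[, 1], co[, 2], co[, 3])[1]
  expect_identical(sel, sort(nb[[first]]))

  # a unique winner: exactly its neighborhood
  sc <- rep(0, nv); sc[17] <- 1
  expect_identical(select_features(sc, spec, rule = "single_best"),
                   sort(nb[[17]]))

  # union rule reaches the target fraction of the ROI
  set.seed(1)
  sel_u <- select_features(runif(nv), spec, target_fraction = 0.6)
  expect_gte(length(sel_u), ceiling(0.6 * nv))
  expect_true(all(sel_u %in% seq_len(nv)))
  expect_error(select_features(numeric(0), spec), "empty")
})

test_that("default union rule on a CA1-sized ROI selects a voxel count in the reported band", {
  masks <- make_subfield_masks(c(40, 40, 24), seed = 13)
  ca1 <- masks$CA1_L
  nv <- roi_voxel_count(ca1)
  spec <- searchlight_spec(ca1, 3)
  coords <- which(ca1$data != 0, arr.ind = TRUE) - 1L
  for (i in 1:3) {
    set.seed(40 + i)
    n <- 24
    lab <- rep(c("A", "B"), each = n / 2)
    # weak distributed signal gives a realistic, spatially smooth score map
    sig <- rnorm(nv)
    X <- matrix(rnorm(n * nv), n) + 0.4 * outer(ifelse(lab == "A", 1, -1), sig)
    sel <- select_features(searchlight_scores(beta_series(X, coords), lab, spec),
                           spec)
    expect_gte(length(sel), 140L)
    expect_lte(length(sel), 190L)
  }
})
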