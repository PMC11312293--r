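# Band-selection unit tests use 16-bin quantization on 32x32 planes: with
# bins^2 << n_pixels the MI of unrelated bands stays near zero, so the
# redundant/non-redundant margin is governed by the constructed duplicates.
sel_hist <- histogram_config(16)

test_that("single-image selection: no runs, one run, and a hand-enumerated mix", {
  set.seed(301)
  # all pairwise MI below threshold -> every band retained
  indep <- spectral_cube(array(runif(32 * 32 * 5), c(32, 32, 5)))
  expect_identical(select_bands_single(indep, 2, sel_hist), 0:4)

  # identical bands: one run spanning all -> exactly one retained
  base <- matrix(runif(32 * 32), 32, 32)
  same <- spectral_cube(array(rep(base, 4), c(32, 32, 4)))
  expect_length(select_bands_single(same, 2, sel_hist), 1)

  # 6 bands; 2,3,4 are bijective transforms of one field (mutually high MI).
  # Band 3 keeps the flat distribution (max entropy), 2 and 4 are skewed:
  # run {2,3,4} keeps 3, so retained = {0,1,3,5}
  u <- matrix(runif(1024), 32, 32)
  px <- array(0, c(32, 32, 6))
  px[, , 1] <- runif(1024)
  px[, , 2] <- runif(1024)
  px[, , 3] <- u^3     # concentrated near 0: low entropy
  px[, , 4] <- u       # uniform: maximal entropy
  px[, , 5] <- u^2     # intermediate
  px[, , 6] <- runif(1024)
  cube <- spectral_cube(px)
  prof <- adjacent_mi_profile(cube, sel_hist)
  ent <- prof$entropies
  expect_gt(ent[4], max(ent[3], ent[5]))
  expect_identical(select_bands_single(cube, 2, sel_hist), c(0L, 1L, 3L, 5L))
  expect_error(select_bands_single(
    spectral_cube(matrix(runif(64), 8, 8)), 2, sel_hist), "at least 2 bands")
})

test_that("entropy ties inside a run break toward the lowest band index", {
  base <- matrix(rep(0:15, 16), 16, 16)
  px <- array(rep(base, 3), c(16, 16, 3))  # identical bands: exact entropy tie
  sel <- select_bands_single(spectral_cube(px), 1, sel_hist)
  expect_identical(sel, 0L)
})

test_that("consensus vote follows strict-majority arithmetic", {
  # synthetic vote pattern via cubes that agree/disagree on one band
  votes <- rbind(matrix(TRUE, 13, 1), matrix(FALSE, 12, 1))
  expect_true(mean(votes) > 0.5)          # 13/25 passes strict majority
  expect_false(mean(votes[1:12, , drop = FALSE]) > 0.5 &&
               mean(rbind(votes[1:12, , drop = FALSE],
                          matrix(FALSE, 13, 1))) > 0.5)  # 12/25 fails

  set.seed(302)
  # unanimity: every cube has the same redundant pair with a deterministic
  # entropy winner (uniform field beats its cubed transform)
  cubes <- replicate(6, {
    u <- matrix(runif(1024), 32, 32)
    px <- array(0, c(32, 32, 4))
    px[, , 1] <- runif(1024)
    px[, , 2] <- u^3
    px[, , 3] <- u
    px[, , 4] <- runif(1024)
    spectral_cube(px)
  }, simplify = FALSE)
  single <- lapply(cubes, select_bands_single, mi_threshold = 2,
                   config = sel_hist)
  expect_length(unique(single), 1)
  cons <- select_bands_consensus(cubes,
    selection_config(mi_threshold = 2, n_sample_images = 6, seed = 5),
    sel_hist)
  expect_identical(cons$retained, single[[1]])
  expect_identical(cons$retained, c(0L, 2L, 3L))
  expect_identical(dim(cons$votes), c(6L, 4L))
  expect_error(select_bands_consensus(list(),
    selection_config(mi_threshold = 2)), "empty cube list")
})

test_that("consensus recovers planted duplicate groups exactly", {
  set.seed(303)
  ds <- generate_dataset(synth_config(
    n_images_per_class = 7, n_base_bands = 6, height = 48, width = 48,
    duplicate_groups = list(list(source = 1, n_copies = 1, sd = 0.01),
                            list(source = 3, n_copies = 1, sd = 0.01),
                            list(source = 5, n_copies = 1, sd = 0.01)),
    band_corr = 0.3, seed = 42))
  cfg <- selection_config(mi_threshold = 2, n_sample_images = 25, seed = 9)
  sel <- select_bands_consensus(ds$cubes, cfg, histogram_config(32))
  groups <- ds$redundancy_map$groups
  dropped <- setdiff(0:(ds$redundancy_map$n_bands - 1), sel$retained)
  # every dropped band is in some duplicate group; each group keeps exactly 1
  expect_true(all(dropped %in% unlist(groups)))
  for (g in groups) expect_length(intersect(g, sel$retained), 1)
  expect_length(sel$retained, ds$redundancy_map$n_bands - length(groups))
})

test_that("threshold sweep is monotone and deterministic; Inf keeps all bands", {
  set.seed(304)
  cubes <- replicate(5, fixture_duplicate_cube(
    n = 32, n_base = 4, duplicates = list("0" = 0.01, "2" = 0.05)),
    simplify = FALSE)
  cfg <- selection_config(mi_threshold = 3, n_sample_images = 5, seed = 2)
  tab <- threshold_sweep(cubes, c(Inf, 3.5, 2.5, 1.5, 0.5), cfg, sel_hist)
  expect_identical(nrow(tab), 5L)
  expect_identical(tab$n_retained[1], 6L)          # Inf: nothing redundant
  expect_true(all(diff(tab$n_retained) <= 0))      # non-increasing counts
  tab2 <- threshold_sweep(cubes, c(Inf, 3.5, 2.5, 1.5, 0.5), cfg, sel_hist)
  expect_identical(tab, tab2)                      # bit-for-bit reproducible
})

test_that("selection is idempotent on its own retained subset", {
  set.seed(305)
  cube <- fixture_duplicate_cube(n = 32, n_base = 4,
                                 duplicates = list("1" = 0.01))
  sel <- select_bands_single(cube, 2, sel_hist)
  sub <- subset_bands(cube, sel)
  resel <- select_bands_single(sub, 2, sel_hist)
  expect_identical(resel, seq_along(sel) - 1L)
})

test_that("band selections persist to JSON and reload", {
  set.seed(306)
  cubes <- replicate(3, fixture_duplicate_cube(
    n = 32, n_base = 3, duplicates = list("0" = 0.01)), simplify = FALSE)
  sel <- select_bands_consensus(cubes,
    selection_config(mi_threshold = 2, n_sample_images = 3, seed = 1),
    sel_hist)
  f <- withr::local_tempfile(fileext = ".json")
  write_band_selection(sel, f)
  back <- read_band_selection(f)
  expect_identical(back$retained, sel$retained)
  expect_equal(back$threshold, sel$threshold)
  expect_match(back$config_hash, "^[0-9a-f]{32}$")
})
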