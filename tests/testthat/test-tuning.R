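# tuning_analysis module: bulk tunings, crossings, opponency, groups,
# crossing histograms, randomization controls

test_that("bulk_tuning is linear and proportional to single-cone tunings", {
  cones <- default_cones()
  W <- matrix(0, 4, 4, dimnames = dimnames(rand_weights()))
  W["red", "Lsus"] <- -1.7
  cv <- bulk_tuning(W, cones)
  expect_equal(cor(cv, cones$tuning[, "red"]), -1)     # proportional
  expect_equal(bulk_tuning(W * 0, cones), rep(0, 251))
  # normalization rescales the curve but never moves its crossings
  Wg <- matrix(0, 4, 4, dimnames = dimnames(W)); Wg["green", ] <- -0.4
  c1 <- bulk_tuning(Wg, cones)
  c2 <- bulk_tuning(normalize_weights(Wg), cones)
  expect_equal(find_zero_crossings(c1, cones$wavelength_nm),
               find_zero_crossings(c2, cones$wavelength_nm))
  # green-only weights cross at the green template crossing
  expect_equal(find_zero_crossings(c1, cones$wavelength_nm),
               cone_crossings(cones)$green, tolerance = 2)
})

test_that("find_zero_crossings locates interpolated sign changes", {
  wl <- 360:610
  expect_equal(find_zero_crossings(wl - 500, wl), 500)
  expect_length(find_zero_crossings(rep(2, 251), wl), 0)
  # sine crossing at 450 and 520, recovered within one grid step
  cur <- sin(2 * pi * (wl - 450) / 140)
  cr <- find_zero_crossings(cur, wl)
  expect_true(any(abs(cr - 450) <= 1))
  expect_true(any(abs(cr - 520) <= 1))
})

test_that("classify_opponency applies an inclusive 10% threshold", {
  wl <- 360:610
  lobe <- function(c0, w) exp(-0.5 * ((wl - c0) / w)^2)
  mono <- -lobe(550, 40)
  expect_false(classify_opponency(mono, wl)$is_opponent)
  expect_length(classify_opponency(mono, wl)$crossings, 0)
  # compact-support lobes so the opposite peak is *exactly* frac
  two_lobe <- function(frac) {
    ifelse(wl < 450, frac * lobe(420, 20), 0) -
      ifelse(wl >= 450, lobe(550, 30), 0)
  }
  for (frac in c(0.10, 0.05, 0.2)) {
    res <- classify_opponency(two_lobe(frac), wl)
    expect_equal(res$is_opponent, frac >= 0.10)
  }
  # invariant to positive rescaling
  cur <- -lobe(550, 30) + 0.3 * lobe(420, 25)
  expect_equal(classify_opponency(cur * 7.3, wl)$is_opponent,
               classify_opponency(cur, wl)$is_opponent)
  expect_error(classify_opponency(rep(0, 251), wl), "zero curve")
})

test_that("assign_spectral_group follows the crossing bands and template
          similarity", {
  cones <- default_cones()
  wl <- cones$wavelength_nm
  lobe <- function(c0, w) exp(-0.5 * ((wl - c0) / w)^2)
  # crossing at 448, short-On/long-Off profile -> UV:R/G/B
  cur_uv <- lobe(400, 30) - 0.8 * lobe(550, 50)
  cr <- find_zero_crossings(cur_uv, wl)
  expect_true(any(cr > 430 & cr < 470))
  expect_equal(assign_spectral_group(cur_uv, cones), "uv_rgb_opponent")
  # crossing at ~497 -> blue-opponent
  cur_b <- -lobe(440, 35) + 0.9 * lobe(560, 40)
  expect_equal(assign_spectral_group(cur_b, cones), "blue_opponent")
  # flat negative curve -> broad
  expect_equal(assign_spectral_group(rep(-1, length(wl)), cones), "broad")
  # archetype curves map back to their generating groups
  arch <- spectral_archetypes()
  for (nm in names(arch))
    expect_equal(assign_spectral_group(bulk_tuning(arch[[nm]], cones),
                                       cones), nm)
})

test_that("zero-crossing histogram weights clusters by ROI abundance", {
  cones <- default_cones(); wl <- cones$wavelength_nm
  Wg <- matrix(0, 4, 4, dimnames = dimnames(rand_weights()))
  Wg["green", ] <- -1
  cv <- bulk_tuning(Wg, cones)
  h <- zero_crossing_histogram(list(cv), 100, wl)
  expect_equal(h$total_mass, 100)
  expect_equal(sum(h$counts[h$mids > 515 & h$mids < 530]), 100)
  # non-opponent clusters contribute nothing
  Wr <- matrix(0, 4, 4, dimnames = dimnames(Wg)); Wr["red", ] <- -1
  h2 <- zero_crossing_histogram(list(cv, bulk_tuning(Wr, cones)),
                                c(40, 60), wl)
  expect_equal(h2$total_mass, 40)
})

test_that("3-archetype populations give a trimodal crossing histogram that
          collapses under cone shuffling", {
  cones <- default_cones()
  arch <- spectral_archetypes()[c("green_opponent", "blue_opponent",
                                  "uv_rgb_opponent")]
  set.seed(61)
  wlist <- lapply(rep(names(arch), each = 10), function(nm)
    arch[[nm]] + matrix(rnorm(16, 0, 0.05), 4, 4))
  counts <- rpois(30, 50) + 1
  curves <- lapply(wlist, bulk_tuning, cone_set = cones)
  h <- zero_crossing_histogram(curves, counts, cones$wavelength_nm)
  # modes within +/- 10 nm of 450 / 483 / 523
  for (target in c(450, 483, 523)) {
    near <- h$mids >= target - 10 & h$mids <= target + 10
    expect_gt(sum(h$counts[near]), 0.8 * sum(counts) / 3 * 0.5)
  }
  real_score <- trimodality_score(h)
  null <- randomization_controls(wlist, cones, counts,
                                 mode = "shuffle_across_cones",
                                 n_iter = 30, seed = 2)
  expect_gt(real_score, mean(null$scores))
  # fixed seed -> identical null draws
  null2 <- randomization_controls(wlist, cones, counts,
                                  mode = "shuffle_across_cones",
                                  n_iter = 30, seed = 2)
  expect_identical(null$mean_counts, null2$mean_counts)
})

test_that("cone shuffling with identical cone tunings changes nothing", {
  cones <- default_cones()
  same <- cones
  same$tuning[, ] <- cones$tuning[, "green"]
  set.seed(62)
  wlist <- replicate(8, rand_weights(), simplify = FALSE)
  counts <- rep(10, 8)
  h_real <- zero_crossing_histogram(lapply(wlist, bulk_tuning,
                                           cone_set = same),
                                    counts, same$wavelength_nm)
  null <- randomization_controls(wlist, same, counts,
                                 mode = "shuffle_across_cones",
                                 n_iter = 5, seed = 3)
  for (hh in null$histograms) expect_equal(hh$counts, h_real$counts)
})

test_that("per-component crossing histogram mode works", {
  cones <- default_cones()
  Wg <- matrix(0, 4, 4, dimnames = dimnames(rand_weights()))
  Wg["green", ] <- -1
  pc <- bulk_tuning(Wg, cones, per_component = TRUE)$per_component_curves
  h <- zero_crossing_histogram(list(pc), 10, cones$wavelength_nm,
                               mode = "per_component")
  expect_equal(h$total_mass, 40)          # 4 opponent component curves
})
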