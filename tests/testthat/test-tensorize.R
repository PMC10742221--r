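test_that("the azimuthal equidistant projection is centred, distance-true, injective", {
  mon <- fixture_montage()
  proj <- project_montage(mon, 16)
  expect_equal(unname(proj$coords[1, ]), c(7.5, 7.5)) # vertex at grid centre
  # equal polar angle -> equal radius from centre
  th <- acos(mon$positions[, 3])
  r <- sqrt(rowSums(sweep(proj$coords, 2, c(7.5, 7.5))^2))
  ring <- which(abs(th - 92 * pi / 180) < 1e-9)
  expect_lt(diff(range(r[ring])), 1e-9)
  # 32 distinct rounded cells
  cells <- paste(round(proj$coords[, 1]), round(proj$coords[, 2]))
  expect_equal(length(unique(cells)), 32)
  expect_true(all(proj$coords >= 0 & proj$coords <= 15))

  antipode <- eeg_montage(c("a", "b"), rbind(c(0, 0, 1), c(0, 0, -1)))
  expect_error(project_montage(antipode), "antipode")
})

test_that("biharmonic frames are exact at electrodes and match a dense oracle", {
  mon <- fixture_montage()
  proj <- project_montage(mon, 16)
  set.seed(5)
  v <- rnorm(32)
  expect_lt(max(abs(interpolate_at(v, proj, proj$coords) - v)), 1e-6)
  f_const <- interpolate_frame(rep(4.2, 32), proj)
  expect_lt(max(abs(f_const[proj$mask] - 4.2)), 1e-9)
  expect_true(all(f_const[!proj$mask] == 0))

  # 8-electrode toy layout vs the helper's independent dense solve
  pts <- cbind(c(3, 12, 7, 4, 10, 13, 6, 9), c(3, 4, 8, 12, 11, 7, 5, 13))
  vals <- rnorm(8)
  toy <- structure(list(coords = pts, grid = 16,
                        mask = matrix(TRUE, 16, 16), operator = NULL),
                   class = "grid_projection")
  tg <- cbind(runif(10, 3, 13), runif(10, 3, 13))
  expect_lt(max(abs(interpolate_at(vals, toy, tg) - biharm_oracle(pts, vals, tg))),
            1e-9)

  dup <- structure(list(coords = pts[c(1, 1, 2), ], grid = 16,
                        mask = matrix(TRUE, 16, 16), operator = NULL),
                   class = "grid_projection")
  expect_error(interpolate_at(vals[1:3], dup, tg), "duplicate")
})

test_that("window counts follow floor(S - 3) + 1 and degenerate inputs warn", {
  counts <- function(S) length(window_segments(matrix(0, round(S * 120), 1), 120))
  for (S in c(3, 4.5, 5, 7, 30, 182)) {
    expect_equal(counts(S), floor(S - 3) + 1)
    # brute-force enumeration oracle
    brute <- 0; s <- 0
    while (s + 3 <= S + 1e-9) { brute <- brute + 1; s <- s + 1 }
    expect_equal(counts(S), brute)
  }
  expect_warning(empty <- window_segments(matrix(0, 200, 2), 120), "shorter")
  expect_length(empty, 0)
})

test_that("tensor datasets are linear in the signal and exact at electrode cells", {
  mon <- fixture_montage()
  spec <- simulation_spec(n_experts = 1, n_novices = 1, trials_per_subject = 1,
                          task_s = 8, rest_s = 5, pre_trigger_s = 31,
                          snr_db = Inf, seed = 4)
  rec <- resample_recording(simulate_subject(spec, "expert"), 250)
  ep <- extract_task_epochs(rec, onset_s = -2, duration_s = 8,
                            subject = "E1", trial = 1, group = "expert")
  ds <- build_tensor_dataset(list(ep), mon)
  expect_equal(dim(ds$tensors), c(6, 16, 16, 360)) # 8 s span -> 6 windows
  expect_identical(ds$info$label, rep("expert", 6))
  expect_false(anyNA(ds$tensors))

  ep2 <- ep; ep2$epochs[[1]] <- -1.5 * ep$epochs[[1]]
  ds2 <- build_tensor_dataset(list(ep2), mon)
  expect_equal(ds2$tensors, -1.5 * ds$tensors, tolerance = 1e-12)

  # the interpolant evaluated at each electrode's continuous coordinate
  # reproduces the (resampled) channel series sample by sample
  X120 <- apply(ep$epochs[[1]], 2, eegskill:::resample_poly, p = 12, q = 25)
  seg1 <- window_segments(X120, 120)[[1]]
  for (t in c(1, 100, 360)) {
    expect_lt(max(abs(interpolate_at(seg1[t, ], ds$proj, ds$proj$coords) -
                        seg1[t, ])), 1e-6)
  }

  empty <- build_tensor_dataset(list(), mon)
  expect_equal(dim(empty$tensors)[1], 0)
})

test_that("tensor dataset subsetting keeps annotations aligned", {
  ds <- simulate_tensor_dataset(n_per_class = 4, seed = 9)
  sub <- tensor_subset(ds, c(2, 7))
  expect_equal(dim(sub$tensors)[1], 2)
  expect_identical(sub$info$label, ds$info$label[c(2, 7)])
  expect_equal(sub$tensors[1, , , ], ds$tensors[2, , , ])
})
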