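# shared fixture: an unstimulated movie at the canonical 20-min sampling,
# evaluated at the truth level so tracking is tested in isolation
localRun <- local({
  sc <- sceneParams(n_cells = 80L, field_size = c(900L, 900L), n_frames = 25L,
                    frame_interval = 20, rng_seed = 17)
  truth <- simulateDynamics(generatePopulation(sc),
                            motion = motionParams(cell_cycle_mean = 12,
                                                  cell_cycle_sd = 2))
  meas <- truthMeasurements(truth)
  list(truth = truth, meas = meas,
       tracks = linkTracks(meas, pixel_size = 0.8))
})

test_that("static cells give whole-movie tracks with constant centroids", {
  sc <- smallScene(n_cells = 10L, n_frames = 8L)
  truth <- simulateDynamics(generatePopulation(sc),
                            motion = motionParams(mean_speed = 0,
                                                  cell_cycle_mean = 400))
  tk <- linkTracks(truthMeasurements(truth))
  spans <- tapply(tk$frame, tk$track_id, function(f) length(f))
  expect_true(all(spans == 8L))
  drift <- tapply(tk$centroid_row, tk$track_id, function(x) diff(range(x)))
  expect_true(all(drift == 0))
})

test_that("nearest-centroid linking reproduces the true lineage at nominal motility", {
  tk <- localRun$tracks
  acc <- linkAccuracy(tk, tk$cell_id, localRun$truth)
  expect_gte(acc, 0.99)
})

test_that("links are one-to-one within every frame pair", {
  tk <- localRun$tracks
  for (f in sort(unique(tk$frame))) {
    ids <- tk$track_id[tk$frame == f]
    expect_false(anyDuplicated(ids) > 0)
  }
})

test_that("a cell leaving the field terminates its track at the gate", {
  m <- data.frame(frame = rep(1:4, each = 1), cell_id = 1L,
                  centroid_row = c(10, 13, 16, 300),  # jump beyond any gate
                  centroid_col = 10, area = 100, border = FALSE,
                  total_red = 1000)
  tk <- linkTracks(m, max_displacement = 9, pixel_size = 1)
  expect_equal(length(unique(tk$track_id)), 2L)
  expect_equal(tk$track_id[tk$frame == 3], tk$track_id[tk$frame == 1])
  expect_false(tk$track_id[tk$frame == 4] == tk$track_id[tk$frame == 3])
})

test_that("tracking is deterministic", {
  a <- linkTracks(localRun$meas)
  b <- linkTracks(localRun$meas)
  expect_identical(a, b)
})

test_that("an exact twofold drop with a co-appearing sibling is a division", {
  m <- data.frame(frame = c(1, 2, 3, 3, 4, 4),
                  cell_id = c(1, 1, 1, 2, 1, 2),
                  centroid_row = c(50, 50, 45, 58, 45, 60),
                  centroid_col = 50, area = 300, border = FALSE,
                  total_red = c(1000, 1000, 500, 500, 505, 495))
  tk <- linkTracks(m, max_displacement = 20, pixel_size = 1)
  dv <- detectDivisions(tk, drop_factor = 0.6)
  expect_equal(nrow(dv$divisions), 1L)
  expect_equal(dv$divisions$frame, 3)
  daughters <- c(dv$divisions$daughter1, dv$divisions$daughter2)
  expect_setequal(unique(dv$tracks$track_id[dv$tracks$frame >= 3]), daughters)
  expect_true(all(dv$tracks$parent_track[dv$tracks$frame >= 3] ==
                    dv$divisions$parent_track))
})

test_that("slow photobleaching-scale decay never triggers division calls", {
  # 3% loss over 40 frames, far above the twofold-drop threshold
  decay <- 0.97^((0:39) / 39)
  m <- data.frame(frame = rep(1:40, times = 2),
                  cell_id = rep(1:2, each = 40),
                  centroid_row = rep(c(30, 80), each = 40),
                  centroid_col = 50, area = 300, border = FALSE,
                  total_red = rep(1000 * decay, 2))
  tk <- linkTracks(m, max_displacement = 9, pixel_size = 1)
  dv <- detectDivisions(tk)
  expect_equal(nrow(dv$divisions), 0L)
})

test_that("division detection recovers generator divisions on tracked truth", {
  truth <- localRun$truth
  dv <- detectDivisions(localRun$tracks)
  true_div <- truth@params$divisions
  expect_gt(nrow(true_div), 10)
  # recall: a true division matched by a detected one at the same frame
  # with the detected daughters near the true ones
  cells <- truthCells(truth)
  matched <- vapply(seq_len(nrow(true_div)), function(i) {
    cand <- dv$divisions[abs(dv$divisions$frame - true_div$frame[i]) <= 1, ,
                         drop = FALSE]
    if (!nrow(cand)) return(FALSE)
    d1 <- cells[cells$cell_id == true_div$daughter1[i] &
                  cells$frame == true_div$frame[i], ]
    near <- vapply(seq_len(nrow(cand)), function(j) {
      rows <- dv$tracks[dv$tracks$track_id %in%
                          c(cand$daughter1[j], cand$daughter2[j]) &
                          dv$tracks$frame == cand$frame[j], ]
      any(sqrt((rows$centroid_row - d1$row)^2 +
                 (rows$centroid_col - d1$col)^2) < 40)
    }, logical(1))
    any(near)
  }, logical(1))
  expect_gte(mean(matched), 0.95)
  # false positives: detected events with no true division nearby in time
  fp <- vapply(seq_len(nrow(dv$divisions)), function(j) {
    !any(abs(true_div$frame - dv$divisions$frame[j]) <= 1)
  }, logical(1))
  expect_lte(sum(fp) / length(unique(localRun$tracks$track_id)), 0.02)
})

test_that("track count balances initial cells, divisions and departures", {
  # zero motion: no departures, so end-of-movie tracks = initial + divisions
  sc <- sceneParams(n_cells = 40L, field_size = c(700L, 700L), n_frames = 20L,
                    frame_interval = 60, rng_seed = 23)
  truth <- simulateDynamics(generatePopulation(sc),
                            motion = motionParams(mean_speed = 0,
                                                  cell_cycle_mean = 15,
                                                  cell_cycle_sd = 2))
  tk <- linkTracks(truthMeasurements(truth))
  dv <- detectDivisions(tk)
  endTracks <- unique(dv$tracks$track_id[dv$tracks$frame == 20L])
  expect_equal(length(endTracks), 40L + nrow(truth@params$divisions))
})

test_that("motility estimates match construction and generator setting", {
  static <- data.frame(frame = 1:5, centroid_row = 7, centroid_col = 9)
  expect_equal(trackMotility(static, 0.8, 20), 0)
  line <- data.frame(frame = 1:4, centroid_row = (0:3) * 3.5,
                     centroid_col = 0)
  expect_equal(trackMotility(line, 0.8, 20), 8.4)  # 2.8 um / 20 min
  expect_warning(v <- trackMotility(static[1, ], 0.8, 20), "single-frame")
  expect_true(is.na(v))
  # population mean over the random-walk movie: definition-matched recovery
  tk <- localRun$tracks
  sp <- vapply(split(tk, tk$track_id), function(t)
    if (nrow(t) >= 2) trackMotility(t, 0.8, 20) else NA_real_, numeric(1))
  expect_lt(abs(mean(sp, na.rm = TRUE) - 8.5) / 8.5, 0.15)
})

test_that("synchronization aligns traces on the chosen event", {
  tk <- localRun$tracks
  # mode none: identity alignment, time 0 at the first movie frame
  s0 <- synchronizeTracks(tk, "none", measure = "total", channel = "red",
                          frame_interval = 20)
  expect_equal(min(alignedTime(s0)), 0)
  expect_equal(nrow(alignedTraces(s0)), length(unique(tk$track_id)))
  # drug mode: common event frame
  sd <- synchronizeTracks(tk, "drug", drug_frame = 10L, frame_interval = 20)
  expect_equal(alignedTime(sd)[which(colnames(alignedTraces(sd)) == "0")], 0)
  # division mode: each daughter starts at aligned time 0
  dv <- detectDivisions(tk)
  expect_message(
    sv <- synchronizeTracks(dv$tracks, "division", measure = "total",
                            channel = "red", frame_interval = 20),
    "excluded")
  tr <- alignedTraces(sv)
  t0 <- which(abs(alignedTime(sv)) < 1e-9)
  expect_true(all(!is.na(tr[, t0])))
  expect_true(all(is.na(tr[, 1])) || min(alignedTime(sv)) == 0)
  # no event anywhere fails
  expect_error(synchronizeTracks(localRun$tracks, "division",
                                 measure = "total", channel = "red"),
               "no track")
})

test_that("division-aligned spans reproduce the drawn cell-cycle lengths", {
  sc <- sceneParams(n_cells = 50L, field_size = c(800L, 800L), n_frames = 40L,
                    frame_interval = 60, rng_seed = 29)
  truth <- simulateDynamics(generatePopulation(sc),
                            motion = motionParams(cell_cycle_mean = 16,
                                                  cell_cycle_sd = 2))
  cells <- truthCells(truth)
  div <- truth@params$divisions
  # daughters that divide again: observed birth-to-division interval should
  # equal their drawn cycle length within one frame
  kids <- div[div$parent_id %in% c(div$daughter1, div$daughter2), ,
              drop = FALSE]
  expect_gt(nrow(kids), 3)
  for (i in seq_len(nrow(kids))) {
    birth <- min(cells$frame[cells$cell_id == kids$parent_id[i]])
    drawn <- cells$cycle_h[cells$cell_id == kids$parent_id[i]][1]
    observed_h <- (kids$frame[i] - birth) * 1      # 60-min frames
    expect_lt(abs(observed_h - drawn), 1 + 1e-9)
  }
})
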