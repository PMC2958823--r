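#' @include AllClasses.R synthetic-movie.R segmentation.R tracking.R dynamics-stats.R
NULL

## nearest-truth-centroid assignment of measured cells, per frame
matchMeasurementsToTruth <- function(measurements, truth, max_dist_px = 12) {
  cells <- truth@cells
  out <- rep(NA_integer_, nrow(measurements))
  for (f in unique(measurements$frame)) {
    mi <- which(measurements$frame == f)
    tf <- cells[cells$frame == f & cells$visible, , drop = FALSE]
    if (!nrow(tf)) next
    d2 <- outer(measurements$centroid_row[mi], tf$row, "-")^2 +
      outer(measurements$centroid_col[mi], tf$col, "-")^2
    j <- apply(d2, 1, which.min)
    hit <- d2[cbind(seq_along(mi), j)] <= max_dist_px^2
    out[mi[hit]] <- tf$cell_id[j[hit]]
  }
  out
}

## mean best-match Jaccard of true cell masks vs a segmented label map
truthJaccard <- function(truth, frame, cell_labels, min_area = 50) {
  tl <- groundTruthMasks(truth, frame)@cellLabels
  ids <- setdiff(unique(as.integer(tl)), 0L)
  js <- vapply(ids, function(id) {
    tm <- tl == id
    if (sum(tm) < min_area) return(NA_real_)
    cand <- as.integer(cell_labels[tm])
    cand <- cand[cand > 0L]
    if (!length(cand)) return(0)
    best <- as.integer(names(which.max(table(cand))))
    pred <- cell_labels == best
    sum(tm & pred) / sum(tm | pred)
  }, numeric(1))
  mean(js, na.rm = TRUE)
}

#' Ground-truth benchmark of the full quantification pipeline
#'
#' Simulates one drug-response movie under the generator's default study
#' conditions (expression CV 0.41/0.44, rank correlation 0.64, nuclear
#' fractions 0.43/0.39, nuclear folds 1.78/1.95 at 25 h, motility 8.5 um/h,
#' 28 +/- 4 h cell cycle, <= 3% bleaching), renders it with flat field,
#' background, shot and read noise, runs the complete analysis --
#' correction, seeded segmentation, measurement, tracking, division
#' detection, response statistics -- and scores every stage against the
#' ground truth.
#'
#' @param seed integer seed driving all randomness.
#' @param n_cells cells at frame 1.
#' @param n_frames movie length in frames.
#' @param frame_interval minutes between frames; the default 30 min makes a
#'   60-frame movie span 30 h, leaving a full 25-h analysis window after
#'   drug addition at frame 10.
#' @param drug_frame frame of drug addition.
#' @param field_size field size in pixels.
#' @param jaccard_frames frames at which segmentation accuracy is scored.
#' @param verbose print progress.
#' @return named list: \code{mean_cell_jaccard}, \code{link_accuracy},
#'   \code{division_recall}, \code{division_fp_per_track},
#'   \code{cv_total_cyan}, \code{cv_total_yellow}, \code{rank_correlation}
#'   (plus its nuclear and enrichment counterparts),
#'   \code{nuclear_fold_25h_cyan}, \code{nuclear_fold_25h_yellow},
#'   \code{t50_error_h}, \code{mean_t50_h}, \code{tau50_enrichment_h},
#'   \code{tau50_total_h}, \code{n_cells_tracked}, plus the generator
#'   settings under \code{settings}.
#' @export
pipelineBenchmark <- function(seed = 1L, n_cells = 200L, n_frames = 60L,
                              frame_interval = 30, drug_frame = 10L,
                              field_size = c(1000L, 1000L),
                              jaccard_frames = NULL,
                              verbose = FALSE) {
  if (is.null(jaccard_frames))
    jaccard_frames <- unique(c(1L, n_frames %/% 2L, n_frames))
  scene <- sceneParams(n_cells = n_cells, field_size = field_size,
                       pixel_size = 0.8, frame_interval = frame_interval,
                       n_frames = n_frames, drug_frame = drug_frame,
                       rng_seed = seed)
  expr <- expressionParams()
  response <- responseParams()
  motion <- motionParams()
  dt_h <- frame_interval / 60

  if (verbose) message("simulating ground truth ...")
  truth <- simulateDynamics(generatePopulation(scene, expr), response, motion)
  if (verbose) message("rendering ", n_frames, " frames ...")
  stack <- renderFrames(truth, opticsParams())

  if (verbose) message("segmenting and measuring ...")
  meas <- quantifyMovie(stack, flat_field = stack@metadata$flatField,
                        dark_offset = "estimate", verbose = verbose)

  tk <- linkTracks(meas, pixel_size = scene$pixel_size)
  dv <- detectDivisions(tk)
  tracks <- dv$tracks

  trueIds <- matchMeasurementsToTruth(tracks, truth)

  ## segmentation accuracy
  jac <- vapply(jaccard_frames, function(f) {
    red <- flatFieldCorrect(getFrame(stack, f, "red"),
                            stack@metadata$flatField,
                            estimateBackground(getFrame(stack, f, "red")))
    truthJaccard(truth, f, segmentFrame(red)@cellLabels)
  }, numeric(1))

  ## tracking accuracy vs true lineage
  div_true <- truth@params$divisions
  ord <- order(tracks$track_id, tracks$frame)
  tid <- tracks$track_id[ord]; fr <- tracks$frame[ord]; ti <- trueIds[ord]
  same <- tid[-1] == tid[-length(tid)] & diff(fr) == 1L & !is.na(ti[-1]) &
    !is.na(ti[-length(ti)])
  a <- ti[-length(ti)][same]; b <- ti[-1][same]
  link_ok <- a == b |
    paste(a, b) %in% c(paste(div_true$parent_id, div_true$daughter1),
                       paste(div_true$parent_id, div_true$daughter2))
  link_accuracy <- mean(link_ok)

  ## division detection vs true events
  cells <- truth@cells
  recall <- NA_real_; fp_rate <- NA_real_
  if (nrow(div_true)) {
    matched <- vapply(seq_len(nrow(div_true)), function(i) {
      cand <- dv$divisions[abs(dv$divisions$frame - div_true$frame[i]) <= 1, ,
                           drop = FALSE]
      if (!nrow(cand)) return(FALSE)
      d1 <- cells[cells$cell_id == div_true$daughter1[i] &
                    cells$frame == div_true$frame[i], ]
      any(vapply(seq_len(nrow(cand)), function(j) {
        rows <- tracks[tracks$track_id %in% c(cand$daughter1[j],
                                              cand$daughter2[j]) &
                         tracks$frame == cand$frame[j], ]
        any(sqrt((rows$centroid_row - d1$row)^2 +
                   (rows$centroid_col - d1$col)^2) < 40)
      }, logical(1)))
    }, logical(1))
    recall <- mean(matched)
    fp <- vapply(seq_len(nrow(dv$divisions)), function(j)
      !any(abs(div_true$frame - dv$divisions$frame[j]) <= 1), logical(1))
    fp_rate <- sum(fp) / length(unique(tracks$track_id))
  }

  ## population statistics at the first frame (basal state, pre-division)
  f1 <- tracks[tracks$frame == 1L & !tracks$border, , drop = FALSE]
  cv_c <- populationCV(f1$total_cyan)
  cv_y <- populationCV(f1$total_yellow)
  rank_r <- suppressWarnings(
    stats::cor(f1$total_cyan, f1$total_yellow, method = "spearman"))
  rank_r_nuc <- suppressWarnings(
    stats::cor(f1$nuclear_cyan, f1$nuclear_yellow, method = "spearman"))
  rank_r_enr <- suppressWarnings(
    stats::cor(f1$enrich_cyan, f1$enrich_yellow, method = "spearman"))

  ## drug response: normalized nuclear level 25 h after addition
  time_h <- (seq_len(n_frames) - drug_frame) * dt_h
  foldAt25 <- function(channel) {
    tr <- traceMatrix(tracks, "nuclear", channel,
                      frames = seq_len(n_frames))
    norm <- suppressMessages(normalizeToBaseline(tr, time_h, 0))
    i25 <- which(abs(time_h - 25) < 1e-9)
    mean(norm[, i25], na.rm = TRUE)
  }
  fold_c <- foldAt25("cyan")
  fold_y <- foldAt25("yellow")

  ## per-cell T50 vs the analytic ground-truth crossing time
  trc <- traceMatrix(tracks, "nuclear", "cyan", frames = seq_len(n_frames))
  rm_meas <- suppressMessages(responseMetrics(trc, time_h, 0, 25))
  tgt <- truth@params$response_targets
  d25 <- exp(-25 / response$response_timescale)
  n25 <- tgt$t_cyan + (tgt$n0_cyan - tgt$t_cyan) * d25
  half <- (tgt$n0_cyan + n25) / 2
  t50_true <- -response$response_timescale *
    log((tgt$t_cyan - half) / (tgt$t_cyan - tgt$n0_cyan))
  # restrict both to the tracked cells that the measured metric covers
  row_tid <- as.integer(rm_meas$track_id)
  tid2true <- tapply(trueIds, tracks$track_id, function(x)
    x[which(!is.na(x))[1]])
  true_of_row <- tid2true[as.character(row_tid)]
  keep <- !is.na(true_of_row) & !rm_meas$censored & !rm_meas$degenerate
  t50_pairs <- data.frame(meas = rm_meas$T50[keep],
                          true = t50_true[match(true_of_row[keep],
                                                tgt$cell_id)])
  t50_pairs <- t50_pairs[stats::complete.cases(t50_pairs), , drop = FALSE]
  t50_err <- abs(mean(t50_pairs$meas) - mean(t50_pairs$true))

  ## co-dynamics of the stimulated movie
  post <- which(time_h >= 0)
  enr_c <- traceMatrix(tracks, "enrich", "cyan", frames = seq_len(n_frames))
  enr_y <- traceMatrix(tracks, "enrich", "yellow", frames = seq_len(n_frames))
  tot_c <- traceMatrix(tracks, "total", "cyan", frames = seq_len(n_frames))
  tot_y <- traceMatrix(tracks, "total", "yellow", frames = seq_len(n_frames))
  tau_e <- tau50(crossCorrelation(enr_c[, post], enr_y[, post],
                                  time_h[post], max_lag = 12,
                                  measure = "enrichment"))
  tau_t <- tau50(crossCorrelation(tot_c[, post], tot_y[, post],
                                  time_h[post], max_lag = 12,
                                  measure = "total"))

  list(mean_cell_jaccard = mean(jac),
       link_accuracy = link_accuracy,
       division_recall = recall,
       division_fp_per_track = fp_rate,
       n_true_divisions = nrow(div_true),
       cv_total_cyan = cv_c,
       cv_total_yellow = cv_y,
       rank_correlation = rank_r,
       rank_correlation_nuclear = rank_r_nuc,
       rank_correlation_enrichment = rank_r_enr,
       nuclear_fold_25h_cyan = fold_c,
       nuclear_fold_25h_yellow = fold_y,
       t50_error_h = t50_err,
       mean_t50_h = mean(t50_pairs$meas),
       tau50_enrichment_h = as.numeric(tau_e),
       tau50_total_h = as.numeric(tau_t),
       n_cells_tracked = length(unique(tracks$track_id)),
       settings = list(seed = seed, n_cells = n_cells, n_frames = n_frames,
                       frame_interval = frame_interval,
                       drug_frame = drug_frame,
                       cv_total = expr$cv_total,
                       rank_correlation = expr$rank_correlation,
                       fold_nuclear_25h = response$fold_nuclear_25h,
                       frame_interval_h = dt_h))
}
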