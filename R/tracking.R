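#' @include AllClasses.R
NULL

#' Link per-frame cell measurements into single-cell tracks
#'
#' Tracks are built by scanning the movie from its last frame to its first
#' and linking each segmented cell to the cell in the previous frame with
#' the closest centroid, the classic nearest-centroid scheme. Matching
#' within a frame pair is one-to-one and greedy by ascending distance, with
#' ties broken by the lower cell label pair, so the result is deterministic.
#' Links farther than \code{max_displacement} are refused: cells without a
#' predecessor start a track (birth or field entry) and cells without a
#' successor end one (death or field exit).
#'
#' @param measurements data.frame from \code{\link{measureCells}} /
#'   \code{\link{quantifyMovie}} (needs \code{frame, cell_id, centroid_row,
#'   centroid_col}).
#' @param max_displacement gate in micrometres. The default covers both the
#'   per-frame migration step (~2.8 um at 8.5 um/h and 20-min frames) and
#'   the centroid jump from a mother to her daughters at division (about
#'   one cell radius), while staying far below typical neighbour spacing.
#' @param pixel_size micrometres per pixel, used to convert the gate.
#' @return the measurement table with a \code{track_id} column added and a
#'   \code{parent_track} column initialized to NA (filled by
#'   \code{\link{detectDivisions}}).
#' @export
linkTracks <- function(measurements, max_displacement = 15, pixel_size = 0.8) {
  m <- measurements[order(measurements$frame, measurements$cell_id), ,
                    drop = FALSE]
  if (!nrow(m)) {
    m$track_id <- integer(0); m$parent_track <- integer(0)
    return(m)
  }
  gate_px2 <- (max_displacement / pixel_size)^2
  frames <- sort(unique(m$frame))
  m$track_id <- NA_integer_
  m$parent_track <- NA_integer_
  rowsOf <- split(seq_len(nrow(m)), m$frame)

  last <- as.character(frames[length(frames)])
  m$track_id[rowsOf[[last]]] <- seq_along(rowsOf[[last]])
  next_track <- length(rowsOf[[last]]) + 1L

  for (i in rev(seq_along(frames))[-length(frames)]) {
    cur <- rowsOf[[as.character(frames[i])]]      # frame t (has track ids)
    prev <- rowsOf[[as.character(frames[i - 1])]] # frame t-1 (to assign)
    if (length(prev) == 0L) next
    if (length(cur) == 0L) {
      m$track_id[prev] <- seq(next_track, length.out = length(prev))
      next_track <- next_track + length(prev)
      next
    }
    d2 <- outer(m$centroid_row[cur], m$centroid_row[prev], "-")^2 +
      outer(m$centroid_col[cur], m$centroid_col[prev], "-")^2
    cand <- which(d2 <= gate_px2, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(d2[cand], m$cell_id[cur][cand[, 1]],
                   m$cell_id[prev][cand[, 2]])
      cand <- cand[ord, , drop = FALSE]
      usedCur <- logical(length(cur)); usedPrev <- logical(length(prev))
      for (k in seq_len(nrow(cand))) {
        a <- cand[k, 1]; b <- cand[k, 2]
        if (usedCur[a] || usedPrev[b]) next
        usedCur[a] <- TRUE; usedPrev[b] <- TRUE
        m$track_id[prev[b]] <- m$track_id[cur[a]]
      }
    }
    un <- prev[is.na(m$track_id[prev])]
    if (length(un)) {
      m$track_id[un] <- seq(next_track, length.out = length(un))
      next_track <- next_track + length(un)
    }
  }
  m
}

#' Detect division events along tracks and split them into daughters
#'
#' A division is flagged at frame t of a track when its total fluorescence
#' (red channel by default, since the red marker is expressed by every cell)
#' drops to at most \code{drop_factor} times the value at t-1 -- the sharp
#' twofold drop of a mother's content splitting between daughters -- and a
#' sibling track is born at t nearby. Requiring the co-appearing sibling
#' protects against segmentation failures that also halve the measured
#' intensity. Each flagged frame splits the track: frames before t keep the
#' mother's id, frames from t on become one daughter and the newborn sibling
#' track the other, both recording the mother in \code{parent_track}.
#'
#' @param tracks data.frame from \code{\link{linkTracks}}.
#' @param drop_factor division threshold on the frame-to-frame intensity
#'   ratio; 0.6 targets the nominal twofold drop with noise margin.
#' @param channel channel whose total fluorescence is monitored.
#' @param sibling_radius maximum centroid distance (pixels) of the newborn
#'   sibling; default 2 cell diameters estimated from the median area.
#' @return list with \code{tracks} (ids rewritten so each daughter is its
#'   own track, \code{parent_track} filled) and \code{divisions} (one row
#'   per event: \code{parent_track, frame, daughter1, daughter2}).
#' @export
detectDivisions <- function(tracks, drop_factor = 0.6, channel = "red",
                            sibling_radius = NULL) {
  m <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  col <- paste0("total_", channel)
  if (!col %in% names(m)) stop("column ", col, " not found in tracks")
  if (is.null(sibling_radius)) {
    med_area <- stats::median(m$area)
    sibling_radius <- 4 * sqrt(med_area / pi)   # 2 diameters
  }
  if (!nrow(m)) {
    return(list(tracks = m,
                divisions = data.frame(parent_track = integer(0),
                                       frame = integer(0),
                                       daughter1 = integer(0),
                                       daughter2 = integer(0))))
  }
  div <- data.frame(parent_track = integer(0), frame = integer(0),
                    daughter1 = integer(0), daughter2 = integer(0))
  out <- detectDivisionsScan(m, div, drop_factor, col, sibling_radius)
  rownames(out$tracks) <- NULL
  out
}

## scan for intensity-drop + co-appearing-sibling events, splitting one
## track per iteration until stable (a lineage can divide more than once
## inside one movie, and a split daughter must be re-examined)
detectDivisionsScan <- function(m, div, drop_factor, col, sibling_radius) {
  repeat {
    next_track <- max(m$track_id) + 1L
    births <- vapply(split(seq_len(nrow(m)), m$track_id),
                     function(ix) ix[which.min(m$frame[ix])], integer(1))
    birthRow <- data.frame(track_id = m$track_id[births],
                           frame = m$frame[births], row = births)
    found <- FALSE
    for (tid in unique(m$track_id)) {
      ix <- which(m$track_id == tid)
      ix <- ix[order(m$frame[ix])]
      if (length(ix) < 2L) next
      v <- m[[col]][ix]; fr <- m$frame[ix]
      consec <- c(FALSE, diff(fr) == 1L)
      dropped <- c(FALSE, v[-1] <= drop_factor * v[-length(v)]) & consec
      jumped <- c(FALSE, v[-1] >= 1.3 * v[-length(v)]) & consec
      onEdge <- if ("border" %in% names(m)) m$border[ix] else
        rep(FALSE, length(ix))
      bf <- min(fr)
      for (k in which(dropped)) {
        f <- fr[k]
        if (f <= bf) next
        # partially imaged cells lose intensity as they slide off the
        # field; their fading is not a division
        if (onEdge[k] || onEdge[k - 1L]) next
        # the halving must persist: a transient one-frame dip is a
        # segmentation artifact (merge/split flicker), not a division
        if (k < length(v) && consec[k + 1] && v[k + 1] > 0.8 * v[k - 1]) next
        # an upward jump shortly before the drop marks a merge with a
        # neighbour whose later separation halves the intensity; mothers
        # only grow smoothly (a few percent per frame), so a recent jump
        # disqualifies the drop as a division
        jprev <- which(jumped[seq_len(k - 1L)])
        if (length(jprev) && f - fr[max(jprev)] <= 6L) next
        # the sibling normally appears at the division frame; allow one
        # frame of grace for a daughter that is briefly pooled with a
        # touching neighbour before segmentation resolves it
        sib <- birthRow[(birthRow$frame == f | birthRow$frame == f + 1L) &
                          birthRow$track_id != tid, , drop = FALSE]
        if (!nrow(sib)) next
        d <- sqrt((m$centroid_row[sib$row] - m$centroid_row[ix[k]])^2 +
                    (m$centroid_col[sib$row] - m$centroid_col[ix[k]])^2)
        ok <- which(d <= sibling_radius)
        ok <- ok[is.na(m$parent_track[sib$row[ok]])]
        if (!length(ok)) next
        sib_tid <- sib$track_id[ok[which.min(d[ok])]]
        tail_ix <- ix[fr >= f]
        d1 <- next_track; next_track <- next_track + 1L
        m$track_id[tail_ix] <- d1
        m$parent_track[tail_ix] <- tid
        m$parent_track[m$track_id == sib_tid] <- tid
        div <- rbind(div, data.frame(parent_track = tid, frame = f,
                                     daughter1 = d1, daughter2 = sib_tid))
        found <- TRUE
        break
      }
      if (found) break
    }
    if (!found) break
  }
  list(tracks = m, divisions = div)
}

#' Mean centre-of-mass speed of a track
#'
#' @param track data.frame rows of one track (needs \code{frame,
#'   centroid_row, centroid_col}).
#' @param pixel_size micrometres per pixel.
#' @param frame_interval minutes between frames.
#' @return mean speed in micrometres per hour over consecutive frame pairs;
#'   NA with a warning for a single-frame track.
#' @export
trackMotility <- function(track, pixel_size = 0.8, frame_interval = 20) {
  t <- track[order(track$frame), , drop = FALSE]
  if (nrow(t) < 2L) {
    warning("motility undefined for a single-frame track")
    return(NA_real_)
  }
  steps <- sqrt(diff(t$centroid_row)^2 + diff(t$centroid_col)^2) * pixel_size
  dth <- diff(t$frame) * frame_interval / 60
  mean(steps / dth)
}

#' Align single-cell traces on a common event
#'
#' Re-indexes each track's trace of one measure to hours relative to an
#' alignment event: the drug-addition frame (\code{mode = "drug"}), the
#' track's own birth-by-division (\code{mode = "division"}, the in-silico
#' synchronization that replaces chemical synchronization), or no alignment
#' (\code{mode = "none"}, absolute movie time). Tracks lacking the event are
#' excluded and counted in a message.
#'
#' @param tracks data.frame from \code{\link{linkTracks}} (after
#'   \code{\link{detectDivisions}} when division alignment is wanted).
#' @param mode "drug", "division" or "none".
#' @param measure,channel which trace to extract, forming the column
#'   \code{<measure>_<channel>} (e.g. \code{nuclear_cyan}).
#' @param drug_frame 1-based frame of drug addition (mode "drug").
#' @param frame_interval minutes between frames.
#' @param min_pre_frames drop tracks with fewer pre-event frames (mode
#'   "drug").
#' @return an \linkS4class{AlignedTraceSet}.
#' @export
synchronizeTracks <- function(tracks, mode = c("drug", "division", "none"),
                              measure = "nuclear", channel = "cyan",
                              drug_frame = NULL, frame_interval = 20,
                              min_pre_frames = 0L) {
  mode <- match.arg(mode)
  col <- paste0(measure, "_", channel)
  if (!col %in% names(tracks)) stop("column ", col, " not found in tracks")
  ids <- sort(unique(tracks$track_id))
  eventFrame <- switch(mode,
    none = stats::setNames(rep(min(tracks$frame), length(ids)), ids),
    drug = {
      if (is.null(drug_frame)) stop("drug_frame required for mode 'drug'")
      stats::setNames(rep(drug_frame, length(ids)), ids)
    },
    division = {
      bf <- tapply(tracks$frame, tracks$track_id, min)
      pt <- tapply(tracks$parent_track, tracks$track_id,
                   function(x) x[1])
      ev <- ifelse(is.na(pt), NA_integer_, bf)
      stats::setNames(ev[as.character(ids)], ids)
    })
  keep <- !is.na(eventFrame)
  if (mode == "drug" && min_pre_frames > 0L) {
    first <- tapply(tracks$frame, tracks$track_id, min)[as.character(ids)]
    keep <- keep & (drug_frame - first >= min_pre_frames)
  }
  dropped <- sum(!keep)
  if (dropped) message(dropped, " track(s) lack the alignment event and were",
                       " excluded")
  ids <- ids[keep]
  if (!length(ids)) stop("no track carries the requested alignment event")
  eventFrame <- eventFrame[as.character(ids)]
  rel <- tracks$frame[tracks$track_id %in% ids] -
    eventFrame[as.character(tracks$track_id[tracks$track_id %in% ids])]
  grid <- seq(min(rel), max(rel))
  tr <- matrix(NA_real_, length(ids), length(grid),
               dimnames = list(ids, grid))
  sub <- tracks[tracks$track_id %in% ids, , drop = FALSE]
  ri <- match(sub$track_id, ids)
  ci <- match(sub$frame - eventFrame[as.character(sub$track_id)], grid)
  tr[cbind(ri, ci)] <- sub[[col]]
  new("AlignedTraceSet", traces = tr, time = grid * frame_interval / 60,
      alignment = mode, trackIds = as.integer(ids))
}
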