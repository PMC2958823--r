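#' @include AllClasses.R
NULL

#' Extract a track-by-frame trace matrix from a track table
#'
#' @param tracks data.frame with \code{track_id, frame} and measurement
#'   columns.
#' @param measure one of "total", "nuclear", "cyto", "enrich".
#' @param channel channel name.
#' @param frames frame grid to cover (default: full observed range).
#' @return numeric matrix, rows = tracks (rownames are track ids), columns =
#'   frames; NA where a track is not observed.
#' @export
traceMatrix <- function(tracks, measure = "nuclear", channel = "cyan",
                        frames = NULL) {
  col <- paste0(measure, "_", channel)
  if (!col %in% names(tracks)) stop("column ", col, " not found")
  if (is.null(frames)) frames <- seq(min(tracks$frame), max(tracks$frame))
  ids <- sort(unique(tracks$track_id))
  out <- matrix(NA_real_, length(ids), length(frames),
                dimnames = list(ids, frames))
  ri <- match(tracks$track_id, ids)
  ci <- match(tracks$frame, frames)
  ok <- !is.na(ci)
  out[cbind(ri[ok], ci[ok])] <- tracks[[col]][ok]
  out
}

#' Normalize traces to their pre-event baseline
#'
#' Divides every cell's trace by the mean of its last \code{n_baseline}
#' values at or before the event time, the "normalized to initial level
#' prior to drug addition" convention. Cells whose baseline is missing, zero
#' or negative are excluded with a message.
#'
#' @param traces matrix (cells x time), e.g. from \code{\link{traceMatrix}}
#'   or \code{alignedTraces}.
#' @param time numeric vector of times (hours) for the columns.
#' @param event_time time of the event (hours) on the same axis.
#' @param n_baseline number of frames at or before the event to average.
#' @return the normalized trace matrix (excluded rows dropped).
#' @export
normalizeToBaseline <- function(traces, time, event_time = 0,
                                n_baseline = 1L) {
  stopifnot(ncol(traces) == length(time), n_baseline >= 1L)
  pre <- which(time <= event_time + 1e-9)
  if (!length(pre)) stop("no time points at or before event_time")
  use <- utils::tail(pre, n_baseline)
  base <- rowMeans(traces[, use, drop = FALSE], na.rm = TRUE)
  bad <- !is.finite(base) | base <= 0
  if (any(bad))
    message(sum(bad), " cell(s) with missing or non-positive baseline ",
            "excluded from normalization")
  traces[!bad, , drop = FALSE] / base[!bad]
}

#' Coefficient of variation across cells
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#'
#' @param values numeric vector; NAs are dropped.
#' @return CV, or NA (with a warning) for fewer than 2 values or zero mean.
#' @export
populationCV <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2L) { warning("CV undefined for n < 2"); return(NA_real_) }
  m <- mean(v)
  if (m == 0) { warning("CV undefined for zero mean"); return(NA_real_) }
  stats::sd(v) / m
}

#' 90:10 percentile ratio across cells
#'
#' Ratio of the 90th to the 10th percentile of per-cell values, the spread
#' measure robust to the long right tail of expression distributions.
#' Percentiles use the linear-interpolation (type 7) convention.
#'
#' @param values numeric vector; NAs are dropped.
#' @return the ratio, or NA (with a warning) for fewer than 10 values or a
#'   non-positive 10th percentile.
#' @export
ratio9010 <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 10L) {
    warning("90:10 ratio undefined for n < 10"); return(NA_real_)
  }
  q <- stats::quantile(v, c(0.1, 0.9), names = FALSE, type = 7)
  if (q[1] <= 0) {
    warning("90:10 ratio undefined: non-positive 10th percentile")
    return(NA_real_)
  }
  q[2] / q[1]
}

#' Correlation between two channels across cells, with bootstrap CI
#'
#' Spearman rank correlation (default) with its test p-value, plus a
#' percentile bootstrap confidence interval over cells to report the
#' robustness of the estimate.
#'
#' @param x,y paired per-cell values; pairs with NA are dropped.
#' @param method passed to \code{stats::cor.test}.
#' @param n_boot bootstrap resamples (0 skips the CI).
#' @param conf confidence level of the percentile interval.
#' @return list with \code{estimate}, \code{p_value}, \code{ci} (length 2 or
#'   NULL), \code{n}.
#' @export
correlateChannels <- function(x, y, method = "spearman", n_boot = 1000L,
                              conf = 0.95) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10L) stop("need at least 10 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  ci <- NULL
  if (n_boot > 0L) {
    bs <- vapply(seq_len(n_boot), function(i) {
      ix <- sample.int(n, n, replace = TRUE)
      suppressWarnings(stats::cor(x[ix], y[ix], method = method))
    }, numeric(1))
    alpha <- (1 - conf) / 2
    ci <- stats::quantile(bs, c(alpha, 1 - alpha), names = FALSE, na.rm = TRUE)
  }
  list(estimate = unname(ct$estimate), p_value = ct$p.value, ci = ci, n = n)
}

#' Per-cell response metrics of drug-induced nuclear accumulation
#'
#' For each cell's nuclear trace: \code{Fi}, the level at drug addition
#' (averaged over \code{n_baseline} frames up to the drug time);
#' \code{Fmax}, the maximum within the analysis window after the drug;
#' their difference and ratio; \code{F_end}, the level at the window end;
#' and \code{T50}, the time (hours after the drug) at which the trace first
#' reaches halfway between Fi and the level at the window end -- "half of
#' the nuclear level observed 25 h after drug addition" -- found by linear
#' interpolation between frames. Cells whose trace never reaches the half
#' level get NA with the \code{censored} flag; flat traces reach it at time
#' 0 and are flagged \code{degenerate}.
#'
#' @param traces matrix (cells x time) of nuclear levels.
#' @param time numeric vector of times in hours for the columns.
#' @param drug_time time of drug addition (hours) on the same axis.
#' @param window analysis window length in hours (default 25).
#' @param n_baseline frames averaged for Fi.
#' @return data.frame with one row per cell: \code{Fi, Fmax, dF, fold,
#'   F_end, T50, censored, degenerate}. Cells not covering the window are
#'   dropped with a message.
#' @export
responseMetrics <- function(traces, time, drug_time = 0, window = 25,
                            n_baseline = 1L) {
  stopifnot(ncol(traces) == length(time))
  i0 <- which(time <= drug_time + 1e-9)
  if (!length(i0)) stop("trace does not cover the drug time")
  iw <- which(time > drug_time + 1e-9 & time <= drug_time + window + 1e-9)
  if (!length(iw)) stop("trace does not cover the analysis window")
  iend <- iw[length(iw)]
  covered <- rowSums(is.na(traces[, c(utils::tail(i0, 1), iw), drop = FALSE])) == 0
  if (any(!covered))
    message(sum(!covered), " cell(s) not covering the analysis window were",
            " dropped")
  tr <- traces[covered, , drop = FALSE]
  use0 <- utils::tail(i0, n_baseline)
  Fi <- rowMeans(tr[, use0, drop = FALSE], na.rm = TRUE)
  Fmax <- apply(tr[, iw, drop = FALSE], 1, max)
  Fend <- tr[, iend]
  half <- (Fi + Fend) / 2
  n <- nrow(tr)
  T50 <- rep(NA_real_, n)
  censored <- rep(FALSE, n)
  degenerate <- abs(Fend - Fi) < 1e-12 * pmax(abs(Fi), 1)
  tt <- time[c(utils::tail(i0, 1), iw)] - drug_time
  for (i in seq_len(n)) {
    y <- tr[i, c(utils::tail(i0, 1), iw)]
    if (degenerate[i]) { T50[i] <- 0; next }
    hit <- if (Fend[i] >= Fi[i]) which(y >= half[i]) else which(y <= half[i])
    if (!length(hit)) { censored[i] <- TRUE; next }
    k <- hit[1]
    if (k == 1L) { T50[i] <- 0; next }
    # linear interpolation between frames k-1 and k
    frac <- (half[i] - y[k - 1]) / (y[k] - y[k - 1])
    T50[i] <- tt[k - 1] + frac * (tt[k] - tt[k - 1])
  }
  data.frame(track_id = rownames(tr) %||% seq_len(n),
             Fi = Fi, Fmax = pmax(Fmax, Fi), dF = pmax(Fmax, Fi) - Fi,
             fold = pmax(Fmax, Fi) / Fi, F_end = Fend, T50 = T50,
             censored = censored, degenerate = degenerate,
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-correlation function of two channels' single-cell dynamics
#'
#' For traces c(t) and y(t) of the two tagged channels in the same cells on
#' a shared time grid, computes for each lag tau the cross-cell,
#' cross-time correlation of the deviations from the per-time-point
#' population means c-bar(t), y-bar(t):
#' \deqn{R(\tau) = \frac{\langle (c(t) - \bar c(t))\,(y(t+\tau) - \bar y(t+\tau)) \rangle}
#'   {\sqrt{\langle (c(t) - \bar c(t))^2 \rangle \langle (y(t+\tau) - \bar y(t+\tau))^2 \rangle}}}
#' where the averages run over cells and over all valid time pairs at that
#' lag. The Pearson-style normalization over the matched samples bounds
#' |R| by 1 (Cauchy-Schwarz) and gives R(0) = 1 for identical traces; the
#' unnormalized cross-covariance is also returned.
#'
#' @param traces_c,traces_y matrices (cells x time) on the same grid, same
#'   row order.
#' @param time numeric vector of times in hours.
#' @param max_lag largest |tau| in hours.
#' @param measure label stored in the result (e.g. "total" or "enrichment").
#' @return a \linkS4class{CrossCorrResult}; lags with fewer than 2 valid
#'   pairs get NA.
#' @export
crossCorrelation <- function(traces_c, traces_y, time, max_lag = 12,
                             measure = "total") {
  stopifnot(identical(dim(traces_c), dim(traces_y)),
            ncol(traces_c) == length(time), nrow(traces_c) >= 2L)
  dt <- unique(round(diff(time), 10))
  if (length(dt) != 1L) stop("time grid must be uniform")
  K <- floor(max_lag / dt)
  nT <- length(time)
  cbar <- colMeans(traces_c, na.rm = TRUE)
  ybar <- colMeans(traces_y, na.rm = TRUE)
  A <- sweep(traces_c, 2, cbar)
  B <- sweep(traces_y, 2, ybar)
  lags <- (-K):K
  R <- cov <- rep(NA_real_, length(lags))
  nP <- integer(length(lags))
  for (j in seq_along(lags)) {
    k <- lags[j]
    t1 <- seq_len(nT)
    t2 <- t1 + k
    ok <- t2 >= 1L & t2 <= nT
    a <- A[, t1[ok], drop = FALSE]
    b <- B[, t2[ok], drop = FALSE]
    valid <- !is.na(a) & !is.na(b)
    nP[j] <- sum(valid)
    if (nP[j] < 2L) next
    av <- a[valid]; bv <- b[valid]
    num <- mean(av * bv)
    den <- sqrt(mean(av^2) * mean(bv^2))
    cov[j] <- num
    R[j] <- if (den > 0) num / den else NA_real_
  }
  new("CrossCorrResult", lag = lags * dt, R = R, cov = cov, nPairs = nP,
      nCells = nrow(traces_c), measure = measure)
}

#' Decorrelation time of a cross-correlation function
#'
#' The smallest positive lag at which R(tau) has decayed to half of R(0),
#' by linear interpolation between grid lags; longer decorrelation times
#' mean more strongly coupled dynamics. With \code{symmetric = TRUE} the
#' positive and negative branches are averaged. If R never reaches half
#' within the lag range the result is censored: Inf is returned with
#' attribute \code{censored_at} set to the largest available lag.
#'
#' @param result a \linkS4class{CrossCorrResult}.
#' @param symmetric average the two branches.
#' @return tau50 in hours (possibly Inf, censored).
#' @export
tau50 <- function(result, symmetric = FALSE) {
  stopifnot(is(result, "CrossCorrResult"))
  i0 <- which.min(abs(result@lag))
  R0 <- result@R[i0]
  if (is.na(R0) || R0 <= 0)
    stop("tau50 undefined: R(0) missing or non-positive")
  half <- R0 / 2
  branch <- function(idx) {
    lag <- abs(result@lag[idx]); R <- result@R[idx]
    ord <- order(lag)
    lag <- lag[ord]; R <- R[ord]
    below <- which(!is.na(R) & R <= half)
    if (!length(below)) {
      out <- Inf
      attr(out, "censored_at") <- max(lag)
      return(out)
    }
    k <- below[1]
    if (k == 1L) return(lag[1])
    frac <- (R[k - 1] - half) / (R[k - 1] - R[k])
    lag[k - 1] + frac * (lag[k] - lag[k - 1])
  }
  pos <- branch(which(result@lag >= 0))
  if (!symmetric) return(pos)
  neg <- branch(which(result@lag <= 0))
  if (is.infinite(pos) || is.infinite(neg)) {
    out <- Inf
    attr(out, "censored_at") <- max(abs(result@lag))
    return(out)
  }
  (pos + neg) / 2
}

#' Population statistics over time
#'
#' Assembles per-time-point summaries of the tracked population: mean, sd,
#' CV, 90:10 ratio and n for each requested measure and channel, plus the
#' between-channel Spearman correlation per time point. Border-flagged
#' cells are excluded by default since partially imaged cells bias totals.
#'
#' @param tracks data.frame from the tracking stage.
#' @param measures measures to summarize.
#' @param channels the two channels to summarize and correlate.
#' @param exclude_border drop border-flagged cells.
#' @param frame_interval minutes between frames (for the hours column).
#' @return data.frame with one row per (frame, measure): summary columns
#'   per channel and the between-channel correlation \code{spearman_R}
#'   (NA when fewer than 10 cells).
#' @export
populationReport <- function(tracks,
                             measures = c("total", "nuclear", "cyto", "enrich"),
                             channels = c("cyan", "yellow"),
                             exclude_border = TRUE, frame_interval = 20) {
  m <- tracks
  if (exclude_border && "border" %in% names(m)) m <- m[!m$border, , drop = FALSE]
  frames <- sort(unique(m$frame))
  rows <- list()
  for (f in frames) {
    mf <- m[m$frame == f, , drop = FALSE]
    for (meas in measures) {
      row <- list(frame = f, hours = (f - 1) * frame_interval / 60,
                  measure = meas, n_cells = nrow(mf))
      vals <- list()
      for (ch in channels) {
        v <- mf[[paste0(meas, "_", ch)]]
        vals[[ch]] <- v
        row[[paste0("mean_", ch)]] <- mean(v, na.rm = TRUE)
        row[[paste0("sd_", ch)]] <- stats::sd(v, na.rm = TRUE)
        row[[paste0("cv_", ch)]] <- if (nrow(mf) >= 2)
          suppressWarnings(populationCV(v)) else NA_real_
        row[[paste0("ratio9010_", ch)]] <- suppressWarnings(ratio9010(v))
      }
      row$spearman_R <- if (nrow(mf) >= 10 &&
                            stats::sd(vals[[1]], na.rm = TRUE) > 0 &&
                            stats::sd(vals[[2]], na.rm = TRUE) > 0)
        suppressWarnings(stats::cor(vals[[1]], vals[[2]], method = "spearman",
                                    use = "complete.obs")) else NA_real_
      rows[[length(rows) + 1L]] <- as.data.frame(row)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
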