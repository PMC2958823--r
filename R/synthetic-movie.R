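#' @include AllClasses.R synthetic-params.R
NULL

## Pearson correlation of the Gaussian copula that yields a requested
## Spearman correlation under monotone (here lognormal / logit-normal)
## marginals.
copulaRho <- function(rank_correlation) 2 * sin(pi * rank_correlation / 6)

## Correlated standard-normal pair, n draws, Pearson correlation rho.
rnorm2 <- function(n, rho) {
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n)
  cbind(z1, z2)
}

## Lognormal with a given mean and CV; cv = 0 degenerates to the mean.
rlnormMeanCV <- function(n, mean, cv, z = stats::rnorm(n)) {
  sdlog <- sqrt(log1p(cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  exp(meanlog + sdlog * z)
}

truthColumns <- c("frame", "cell_id", "parent_id", "birth_frame",
                  "row", "col", "a", "b", "theta", "nuc_a", "nuc_b",
                  "visible", "age_h", "cycle_h",
                  "total_red", "nuc_red", "total_cyan", "nuc_cyan",
                  "total_yellow", "nuc_yellow")

emptyTruthCells <- function() {
  out <- as.data.frame(lapply(truthColumns, function(x) numeric(0)))
  names(out) <- truthColumns
  out
}

#' Generate the initial cell population of a synthetic field
#'
#' Places non-overlapping elliptical cells (each with a concentric nuclear
#' sub-ellipse) uniformly in the field and draws their fluorescence state:
#' total levels of the two tagged channels from lognormal marginals joined by
#' a Gaussian copula with the requested rank correlation, per-cell nuclear
#' fractions from a correlated logit-normal around the channel baselines, and
#' a near-uniform red segmentation channel whose nuclear signal follows the
#' configured nucleus:cytoplasm contrast and the cell's realized geometry.
#'
#' @param scene scene parameters from \code{\link{sceneParams}}; its
#'   \code{rng_seed}, when non-NULL, seeds the generator.
#' @param expr expression parameters from \code{\link{expressionParams}}.
#' @return a \linkS4class{GroundTruth} holding frame 1 only.
#' @export
generatePopulation <- function(scene = sceneParams(),
                               expr = expressionParams()) {
  if (!is.null(scene$rng_seed)) set.seed(scene$rng_seed)
  n <- scene$n_cells
  if (n == 0L) {
    return(new("GroundTruth", cells = emptyTruthCells(), scene = scene,
               params = list(expr = expr),
               bleachFactor = rep(1, scene$n_frames)))
  }

  r_px <- scene$cell_radius / scene$pixel_size
  nr <- scene$field_size[1]; nc <- scene$field_size[2]
  min_d2 <- (scene$spacing_factor * r_px)^2

  rows <- numeric(n); cols <- numeric(n)
  placed <- 0L; attempts <- 0L; max_attempts <- 500L * n
  margin <- min(r_px, min(nr, nc) / 4)
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("cannot place ", n, " cells at this density; enlarge field_size ",
           "or reduce n_cells / spacing_factor (placed ", placed, ")")
    pr <- stats::runif(1, 1 + margin, nr - margin)
    pc <- stats::runif(1, 1 + margin, nc - margin)
    if (placed == 0L ||
        min((rows[seq_len(placed)] - pr)^2 + (cols[seq_len(placed)] - pc)^2) >= min_d2) {
      placed <- placed + 1L
      rows[placed] <- pr; cols[placed] <- pc
    }
  }

  a <- r_px * exp(stats::rnorm(n, 0, scene$radius_jitter) - scene$radius_jitter^2 / 2)
  b <- a * stats::runif(n, 0.8, 1)
  theta <- stats::runif(n, 0, pi)
  nuc_a <- scene$nucleus_fraction * a
  nuc_b <- scene$nucleus_fraction * b

  z_tot <- rnorm2(n, copulaRho(expr$rank_correlation))
  total_cyan   <- rlnormMeanCV(n, expr$mean_level, expr$cv_total[1], z_tot[, 1])
  total_yellow <- rlnormMeanCV(n, expr$mean_level, expr$cv_total[2], z_tot[, 2])
  total_red    <- rlnormMeanCV(n, expr$mean_level, expr$red_cv)

  z_eta <- rnorm2(n, copulaRho(expr$enrichment_correlation))
  f_cyan   <- stats::plogis(stats::qlogis(expr$baseline_nuclear_fraction[1]) +
                              expr$nuclear_fraction_sd * z_eta[, 1])
  f_yellow <- stats::plogis(stats::qlogis(expr$baseline_nuclear_fraction[2]) +
                              expr$nuclear_fraction_sd * z_eta[, 2])

  # red nuclear fraction implied by the nucleus:cytoplasm contrast and the
  # realized ellipse areas
  area_n <- pi * nuc_a * nuc_b
  area_c <- pi * a * b
  f_red <- expr$red_contrast * area_n /
    (expr$red_contrast * area_n + (area_c - area_n))

  cells <- data.frame(
    frame = 1L, cell_id = seq_len(n), parent_id = NA_integer_,
    birth_frame = 1L, row = rows, col = cols, a = a, b = b, theta = theta,
    nuc_a = nuc_a, nuc_b = nuc_b, visible = TRUE,
    age_h = NA_real_, cycle_h = NA_real_,
    total_red = total_red, nuc_red = f_red * total_red,
    total_cyan = total_cyan, nuc_cyan = f_cyan * total_cyan,
    total_yellow = total_yellow, nuc_yellow = f_yellow * total_yellow
  )
  new("GroundTruth", cells = cells, scene = scene,
      params = list(expr = expr), bleachFactor = rep(1, scene$n_frames))
}

## cell-cycle draw: truncated normal, floor at 6 h
drawCycles <- function(n, mean, sd) {
  out <- stats::rnorm(n, mean, sd)
  bad <- out < 6
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- out < 6
  }
  out
}

#' Simulate cell motion, growth, division and drug response over all frames
#'
#' Propagates the frame-1 ground truth through the movie. Cells perform a
#' random walk at the configured speed, their fluorescent content doubles
#' exponentially over one cell cycle, and at the end of their (per-cell,
#' once-drawn) cycle they divide: area shrinks and every channel's signal is
#' split between the two daughters, conserving the parent's total exactly.
#' From the drug frame onward, division and growth arrest (as under a
#' DNA-damaging drug) and the nuclear signal of each tagged channel relaxes
#' as a saturating exponential from its level at drug addition toward a
#' per-cell target, while total signal stays constant, so the cytoplasmic
#' signal falls correspondingly. Targets are calibrated on the realized
#' population at the drug frame so that the mean per-cell nuclear fold change
#' at \code{reference_hours} equals \code{fold_nuclear_25h} in expectation.
#' Photobleaching is recorded as a per-frame global multiplicative factor and
#' applied at render time.
#'
#' @param truth a frame-1 \linkS4class{GroundTruth} from
#'   \code{\link{generatePopulation}}.
#' @param response response parameters from \code{\link{responseParams}}.
#' @param motion motion parameters from \code{\link{motionParams}}.
#' @param seed optional integer seed for the dynamics draws.
#' @return a \linkS4class{GroundTruth} covering all frames; its
#'   \code{params} list gains \code{divisions} (parent_id, frame, daughter
#'   ids) and, for stimulated movies, \code{response_targets}.
#' @export
simulateDynamics <- function(truth, response = responseParams(),
                             motion = motionParams(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  scene <- truth@scene
  st <- truth@cells[truth@cells$frame == 1L, , drop = FALSE]
  n_frames <- scene$n_frames
  dt_h <- scene$frame_interval / 60
  step_px <- motion$mean_speed * dt_h / scene$pixel_size
  drug <- scene$drug_frame
  nr <- scene$field_size[1]; nc <- scene$field_size[2]

  if (nrow(st)) {
    st$cycle_h <- drawCycles(nrow(st), motion$cell_cycle_mean, motion$cell_cycle_sd)
    st$age_h <- stats::runif(nrow(st), 0, st$cycle_h)
    st$heading <- stats::runif(nrow(st), 0, 2 * pi)
  }
  turn_sd <- motion$turning_rate * sqrt(dt_h)
  st$f_cyan <- st$nuc_cyan / st$total_cyan
  st$f_yellow <- st$nuc_yellow / st$total_yellow
  st$f_red <- st$nuc_red / st$total_red

  next_id <- if (nrow(st)) max(st$cell_id) + 1L else 1L
  divisions <- list()
  targets <- NULL
  sig_cols <- c("total_red", "nuc_red", "total_cyan", "nuc_cyan",
                "total_yellow", "nuc_yellow")

  snapshot <- function(state, f) {
    if (!nrow(state)) return(NULL)
    out <- state[, truthColumns[-1], drop = FALSE]
    out <- cbind(frame = f, out)
    out
  }
  frames <- list(snapshot(st, 1L))

  for (f in seq_len(n_frames)[-1]) {
    if (nrow(st) == 0L) next
    pre_drug <- is.null(drug) || f < drug

    dividing <- rep(FALSE, nrow(st))
    if (pre_drug) {
      st$age_h <- st$age_h + dt_h
      dividing <- st$age_h >= st$cycle_h
    }

    # motion: fixed step length along a persistent heading; cells entering
    # mitosis round up and pause migration for that frame
    if (step_px > 0 && any(!dividing)) {
      st$heading[!dividing] <- st$heading[!dividing] +
        stats::rnorm(sum(!dividing), 0, turn_sd)
      st$row[!dividing] <- st$row[!dividing] +
        step_px * cos(st$heading[!dividing])
      st$col[!dividing] <- st$col[!dividing] +
        step_px * sin(st$heading[!dividing])
      st <- repelOverlaps(st)
    }

    if (pre_drug) {
      growth <- 2^(dt_h / st$cycle_h)
      keep <- st[!dividing, , drop = FALSE]
      if (nrow(keep))
        keep[, sig_cols] <- keep[, sig_cols] * growth[!dividing]
      daughters <- NULL
      if (any(dividing)) {
        for (i in which(dividing)) {
          p <- st[i, , drop = FALSE]
          q <- stats::runif(1, 0.45, 0.55)
          ang <- stats::runif(1, 0, 2 * pi)
          off <- 0.7 * p$a    # shrunken daughters sit roughly in contact
          d <- p[c(1L, 1L), , drop = FALSE]
          d$cell_id <- c(next_id, next_id + 1L)
          d$parent_id <- p$cell_id
          d$birth_frame <- f
          d$age_h <- 0
          d$cycle_h <- drawCycles(2L, motion$cell_cycle_mean, motion$cell_cycle_sd)
          d$row <- p$row + c(off * cos(ang), -off * cos(ang))
          d$col <- p$col + c(off * sin(ang), -off * sin(ang))
          # cytokinesis pushes the sisters apart: opposite headings
          d$heading <- c(ang, ang + pi)
          shrink <- 0.75
          d[, c("a", "b", "nuc_a", "nuc_b")] <- p[, c("a", "b", "nuc_a", "nuc_b")][rep(1, 2), ] * shrink
          d[, sig_cols] <- p[rep(1, 2), sig_cols] * c(q, 1 - q)
          divisions[[length(divisions) + 1L]] <-
            data.frame(parent_id = p$cell_id, frame = f,
                       daughter1 = next_id, daughter2 = next_id + 1L)
          next_id <- next_id + 2L
          daughters <- rbind(daughters, d)
        }
      }
      st <- rbind(keep, daughters)
    } else {
      # drug present: division and growth arrested; nuclear response active
      if (is.null(targets)) {
        targets <- computeTargets(st, response)
        st$t_cyan <- targets$t_cyan; st$t_yellow <- targets$t_yellow
        st$n0_cyan <- st$nuc_cyan; st$n0_yellow <- st$nuc_yellow
        st$t_drug_h <- (drug - 1) * dt_h
      }
      dt_since <- (f - 1) * dt_h - st$t_drug_h
      decay <- exp(-dt_since / response$response_timescale)
      st$nuc_cyan <- st$t_cyan + (st$n0_cyan - st$t_cyan) * decay
      st$nuc_yellow <- st$t_yellow + (st$n0_yellow - st$t_yellow) * decay
    }

    # nuclear signal tracks the (growing) total at its per-cell fraction
    # while unstimulated
    if (pre_drug) {
      st$nuc_cyan <- st$f_cyan * st$total_cyan
      st$nuc_yellow <- st$f_yellow * st$total_yellow
    }
    st$nuc_red <- st$f_red * st$total_red

    m <- pmax(st$a, st$b)
    st$visible <- st$row >= 1 - m & st$row <= nr + m &
      st$col >= 1 - m & st$col <= nc + m
    frames[[f]] <- snapshot(st, f)
  }

  keep_frames <- frames[!vapply(frames, is.null, logical(1))]
  cells <- if (length(keep_frames)) do.call(rbind, keep_frames) else
    emptyTruthCells()
  rownames(cells) <- NULL
  params <- truth@params
  params$response <- response
  params$motion <- motion
  params$divisions <- if (length(divisions)) do.call(rbind, divisions) else
    data.frame(parent_id = integer(0), frame = integer(0),
               daughter1 = integer(0), daughter2 = integer(0))
  if (!is.null(targets)) params$response_targets <- targets
  bleach <- (1 - motion$bleaching_total)^((seq_len(n_frames) - 1) /
                                            max(n_frames - 1, 1))
  new("GroundTruth", cells = cells, scene = scene, params = params,
      bleachFactor = bleach)
}

## Soft volume exclusion: cells whose centres come closer than a fraction of
## their summed radii are pushed apart symmetrically along the line of
## centres. A couple of relaxation passes per frame keeps neighbours from
## drifting into full overlap, as contact inhibition does in a monolayer.
repelOverlaps <- function(st, min_frac = 0.85, passes = 2L) {
  n <- nrow(st)
  if (n < 2L) return(st)
  for (p in seq_len(passes)) {
    d2 <- (outer(st$row, st$row, "-"))^2 + (outer(st$col, st$col, "-"))^2
    lim <- min_frac * outer(st$a, st$a, "+")
    bad <- which(d2 < lim^2 & upper.tri(d2), arr.ind = TRUE)
    if (!nrow(bad)) break
    for (k in seq_len(nrow(bad))) {
      i <- bad[k, 1]; j <- bad[k, 2]
      dr <- st$row[j] - st$row[i]; dc <- st$col[j] - st$col[i]
      d <- sqrt(dr^2 + dc^2)
      if (d < 1e-6) { dr <- 1; dc <- 0; d <- 1 }
      need <- (min_frac * (st$a[i] + st$a[j]) - d) / 2
      if (need <= 0) next
      st$row[i] <- st$row[i] - need * dr / d
      st$col[i] <- st$col[i] - need * dc / d
      st$row[j] <- st$row[j] + need * dr / d
      st$col[j] <- st$col[j] + need * dc / d
    }
  }
  st
}

## Per-cell nuclear target levels at drug addition; calibrated so the mean
## per-cell fold at reference_hours equals the requested fold.
computeTargets <- function(st, response) {
  n <- nrow(st)
  d <- exp(-response$reference_hours / response$response_timescale)
  one <- function(n0, total, fold) {
    g <- exp(stats::rnorm(n, 0, response$fold_dispersion) -
               response$fold_dispersion^2 / 2)
    ratio <- (fold - d) / (1 - d)          # required mean target/initial
    base <- if (response$response_mode == "fold_change") n0 * g else g
    cap <- 0.95 * total
    # nuclear signal cannot exceed the (constant) total, so targets are
    # capped; calibrate the common scale under the cap so the realized
    # population still delivers the requested mean fold
    achievable <- mean(cap / n0)
    if (ratio >= achievable) {
      warning("requested nuclear fold is not attainable within total ",
              "signal; targets saturate at 95% of total")
      return(cap)
    }
    h <- function(s) mean(pmin(s * base, cap) / n0) - ratio
    s_hi <- ratio / mean(base / n0) + 1
    while (h(s_hi) < 0) s_hi <- s_hi * 2
    s <- stats::uniroot(h, c(0, s_hi), tol = 1e-10)$root
    pmin(s * base, cap)
  }
  data.frame(cell_id = st$cell_id,
             t_cyan = one(st$nuc_cyan, st$total_cyan,
                          response$fold_nuclear_25h[1]),
             t_yellow = one(st$nuc_yellow, st$total_yellow,
                            response$fold_nuclear_25h[2]),
             n0_cyan = st$nuc_cyan, n0_yellow = st$nuc_yellow)
}

## The smooth multiplicative illumination profile used by the renderer:
## parabolic vignette, normalized to mean 1.
makeFlatField <- function(nr, nc, strength) {
  r <- (seq_len(nr) - (nr + 1) / 2) / (nr / 2)
  c <- (seq_len(nc) - (nc + 1) / 2) / (nc / 2)
  d2 <- outer(r^2, c^2, "+") / 2
  v <- 1 - strength * d2
  v / mean(v)
}

## Elliptical cell + nucleus membership over the cell's bounding box.
## Returns NULL when the cell does not intersect the field; otherwise the
## in-field index rows/cols, logical masks and full (unclipped) areas.
cellMasks <- function(row, col, a, b, theta, nuc_a, nuc_b, nr, nc) {
  m <- max(a, b)
  r0 <- floor(row - m); r1 <- ceiling(row + m)
  c0 <- floor(col - m); c1 <- ceiling(col + m)
  rr <- r0:r1; cc <- c0:c1
  dx <- rr - row; dy <- cc - col
  ct <- cos(theta); stn <- sin(theta)
  DX <- matrix(dx, length(rr), length(cc))
  DY <- matrix(dy, length(rr), length(cc), byrow = TRUE)
  u <- DX * ct + DY * stn
  w <- -DX * stn + DY * ct
  cellM <- (u / a)^2 + (w / b)^2 <= 1
  nucM <- if (nuc_a > 0 && nuc_b > 0)
    (u / nuc_a)^2 + (w / nuc_b)^2 <= 1 else cellM & FALSE
  inR <- rr >= 1 & rr <= nr
  inC <- cc >= 1 & cc <= nc
  if (!any(inR) || !any(inC)) return(NULL)
  list(rows = rr[inR], cols = cc[inC],
       cellM = cellM[inR, inC, drop = FALSE],
       nucM = nucM[inR, inC, drop = FALSE],
       cellArea = sum(cellM), nucArea = sum(nucM))
}

#' Render a ground-truth field into a multi-channel movie
#'
#' Paints every visible cell as a uniform elliptical cytoplasm with a
#' uniform concentric nuclear region, at densities chosen so that the
#' integral of each channel over the cell's full (discretized) mask equals
#' the cell's true signal. Per frame the signal is scaled by the global
#' photobleaching factor and the smooth multiplicative flat field, a
#' constant background offset is added, Poisson shot noise and Gaussian read
#' noise are applied, and pixels are quantized to integer camera counts
#' (clipping at the sensor bit depth, with a warning if clipping occurs).
#' The true flat field and background are stored in the movie metadata so
#' correction can be verified against them.
#'
#' @param truth a \linkS4class{GroundTruth} covering the frames to render.
#' @param optics optics parameters from \code{\link{opticsParams}}.
#' @param channels which channels to render, a subset of
#'   \code{c("phase", "red", "yellow", "cyan")}.
#' @param seed optional integer seed for the noise draws.
#' @return a \linkS4class{MovieStack}; its metadata holds \code{flatField},
#'   \code{background} and \code{optics}.
#' @export
renderFrames <- function(truth, optics = opticsParams(),
                         channels = c("red", "yellow", "cyan"),
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(channels %in% c("phase", "red", "yellow", "cyan")))
  scene <- truth@scene
  nr <- scene$field_size[1]; nc <- scene$field_size[2]
  cells <- truth@cells
  n_frames <- scene$n_frames
  V <- makeFlatField(nr, nc, optics$flat_field_strength)
  maxval <- 2^optics$bit_depth - 1
  arr <- array(0, dim = c(nr, nc, length(channels), n_frames))
  clipped <- FALSE
  sigcol <- c(red = "total_red", cyan = "total_cyan", yellow = "total_yellow")
  nuccol <- c(red = "nuc_red", cyan = "nuc_cyan", yellow = "nuc_yellow")

  for (f in seq_len(n_frames)) {
    cf <- cells[cells$frame == f & cells$visible, , drop = FALSE]
    canv <- lapply(channels, function(ch) matrix(0, nr, nc))
    names(canv) <- channels
    for (i in seq_len(nrow(cf))) {
      mk <- cellMasks(cf$row[i], cf$col[i], cf$a[i], cf$b[i], cf$theta[i],
                      cf$nuc_a[i], cf$nuc_b[i], nr, nc)
      if (is.null(mk) || mk$cellArea == 0) next
      cytoArea <- mk$cellArea - mk$nucArea
      for (ch in channels) {
        if (ch == "phase") {
          dens_c <- optics$phase_level
          dens_n <- optics$phase_level
        } else {
          tot <- cf[[sigcol[[ch]]]][i]
          nuc <- cf[[nuccol[[ch]]]][i]
          if (cytoArea > 0) {
            dens_c <- (tot - nuc) / cytoArea
            dens_n <- if (mk$nucArea > 0) nuc / mk$nucArea else 0
          } else {
            dens_c <- 0
            dens_n <- tot / mk$nucArea
          }
        }
        sub <- canv[[ch]][mk$rows, mk$cols, drop = FALSE]
        sub[mk$cellM] <- sub[mk$cellM] + dens_c
        if (mk$nucArea > 0)
          sub[mk$nucM] <- sub[mk$nucM] + (dens_n - dens_c)
        canv[[ch]][mk$rows, mk$cols] <- sub
      }
    }
    for (k in seq_along(channels)) {
      img <- canv[[channels[k]]] * truth@bleachFactor[f] * V + optics$background
      if (optics$shot_noise)
        img <- matrix(stats::rpois(length(img), pmax(img, 0)), nr, nc)
      if (optics$read_noise_sd > 0)
        img <- img + stats::rnorm(length(img), 0, optics$read_noise_sd)
      img <- pmax(img, 0)
      if (any(img > maxval)) { clipped <- TRUE; img <- pmin(img, maxval) }
      if (optics$quantize) img <- round(img)
      arr[, , k, f] <- img
    }
  }
  if (clipped)
    warning("pixel values exceeded the ", optics$bit_depth,
            "-bit range and were clipped")
  new("MovieStack", pixels = arr, channels = channels,
      frameInterval = scene$frame_interval, pixelSize = scene$pixel_size,
      metadata = list(flatField = V, background = optics$background,
                      optics = optics))
}

#' Ground-truth label maps for one frame
#'
#' Rasterizes the true cell and nucleus ellipses of one frame into integer
#' label maps (labels = cell ids). Where two cells overlap, the earlier id
#' keeps the pixel.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param frame 1-based frame index.
#' @return a \linkS4class{SegmentedFrame}.
#' @export
groundTruthMasks <- function(truth, frame) {
  scene <- truth@scene
  nr <- scene$field_size[1]; nc <- scene$field_size[2]
  cf <- truth@cells[truth@cells$frame == frame & truth@cells$visible, ,
                    drop = FALSE]
  cl <- matrix(0L, nr, nc)
  nl <- matrix(0L, nr, nc)
  for (i in seq_len(nrow(cf))) {
    mk <- cellMasks(cf$row[i], cf$col[i], cf$a[i], cf$b[i], cf$theta[i],
                    cf$nuc_a[i], cf$nuc_b[i], nr, nc)
    if (is.null(mk)) next
    sub <- cl[mk$rows, mk$cols, drop = FALSE]
    put <- mk$cellM & sub == 0L
    sub[put] <- cf$cell_id[i]
    cl[mk$rows, mk$cols] <- sub
    subn <- nl[mk$rows, mk$cols, drop = FALSE]
    putn <- mk$nucM & put
    subn[putn] <- cf$cell_id[i]
    nl[mk$rows, mk$cols] <- subn
  }
  new("SegmentedFrame", cellLabels = cl, nucleusLabels = nl,
      frame = as.integer(frame))
}

#' One-call synthetic movie
#'
#' Convenience wrapper chaining \code{\link{generatePopulation}},
#' \code{\link{simulateDynamics}} and \code{\link{renderFrames}}.
#'
#' @inheritParams generatePopulation
#' @inheritParams simulateDynamics
#' @inheritParams renderFrames
#' @return list with elements \code{truth} (\linkS4class{GroundTruth}) and
#'   \code{stack} (\linkS4class{MovieStack}).
#' @export
simulateMovie <- function(scene = sceneParams(), expr = expressionParams(),
                          response = responseParams(), motion = motionParams(),
                          optics = opticsParams(),
                          channels = c("red", "yellow", "cyan")) {
  truth <- generatePopulation(scene, expr)
  truth <- simulateDynamics(truth, response, motion)
  stack <- renderFrames(truth, optics, channels)
  list(truth = truth, stack = stack)
}

#' Write the ground truth of a synthetic movie to plain-text files
#'
#' Writes the per-cell per-frame truth table as CSV and every generator
#' parameter (including the seed) as a YAML sidecar.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
writeGroundTruth <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cells_path <- file.path(dir, "truth_cells.csv")
  utils::write.csv(truth@cells, cells_path, row.names = FALSE)
  meta <- list(scene = truth@scene,
               params = lapply(truth@params[c("expr", "response", "motion")],
                               function(p) p),
               bleach_factor = truth@bleachFactor)
  meta$params <- meta$params[!vapply(meta$params, is.null, logical(1))]
  yaml_path <- file.path(dir, "truth_params.yaml")
  yaml::write_yaml(meta, yaml_path)
  invisible(c(cells_path, yaml_path))
}
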