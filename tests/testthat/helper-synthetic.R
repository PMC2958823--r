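# Shared fixtures: small synthetic scenes and mask-comparison utilities.

# noise-free optics: exact signal conservation, uniform illumination
noiselessOptics <- function(background = 0) {
  opticsParams(flat_field_strength = 0, background = background,
               shot_noise = FALSE, read_noise_sd = 0, quantize = FALSE)
}

# a small well-separated field, cheap enough for per-test rendering
smallScene <- function(n_cells = 12L, n_frames = 3L, seed = 42L, ...) {
  sceneParams(n_cells = n_cells, field_size = c(256L, 256L),
              pixel_size = 0.8, n_frames = n_frames,
              spacing_factor = 3.5, rng_seed = seed, ...)
}

# Jaccard index of one label against another label map
jaccardOf <- function(maskA, maskB) {
  inter <- sum(maskA & maskB)
  union <- sum(maskA | maskB)
  if (union == 0) return(NA_real_)
  inter / union
}

# mean best-match Jaccard of true cells vs a segmented label map
meanCellJaccard <- function(truthSeg, cellLab, min_area = 50) {
  tl <- cellLabels(truthSeg)
  ids <- setdiff(unique(as.integer(tl)), 0L)
  js <- vapply(ids, function(id) {
    tm <- tl == id
    if (sum(tm) < min_area) return(NA_real_)  # barely-visible border slivers
    cand <- as.integer(cellLab[tm])
    cand <- cand[cand > 0L]
    if (!length(cand)) return(0)
    best <- as.integer(names(which.max(table(cand))))
    jaccardOf(tm, cellLab == best)
  }, numeric(1))
  mean(js, na.rm = TRUE)
}

# map measurement rows to ground-truth cell ids by nearest true centroid
matchToTruth <- function(measurements, truth, max_dist_px = 12) {
  cells <- truthCells(truth)
  out <- rep(NA_integer_, nrow(measurements))
  for (f in unique(measurements$frame)) {
    mi <- which(measurements$frame == f)
    tf <- cells[cells$frame == f & cells$visible, , drop = FALSE]
    if (!nrow(tf)) next
    d2 <- outer(measurements$centroid_row[mi], tf$row, "-")^2 +
      outer(measurements$centroid_col[mi], tf$col, "-")^2
    j <- apply(d2, 1, which.min)
    dmin <- d2[cbind(seq_along(mi), j)]
    hit <- dmin <= max_dist_px^2
    out[mi[hit]] <- tf$cell_id[j[hit]]
  }
  out
}

# a synthetic frame of painted rectangles for arithmetic-level tests
paintedFrame <- function(nr = 60, nc = 60) {
  cl <- matrix(0L, nr, nc)
  nl <- matrix(0L, nr, nc)
  cl[11:20, 11:20] <- 1L            # 100-pixel cell
  nl[13:16, 13:20] <- 1L            # 32-pixel nucleus calc by caller
  list(cellLabels = cl, nucleusLabels = nl)
}

# turn a GroundTruth directly into a measurement table (skips rendering);
# per-frame labels are the true cell ids, which makes lineage evaluation exact
truthMeasurements <- function(truth) {
  cells <- truthCells(truth)
  cells <- cells[cells$visible, , drop = FALSE]
  data.frame(frame = cells$frame, cell_id = cells$cell_id,
             centroid_row = cells$row, centroid_col = cells$col,
             area = round(pi * cells$a * cells$b), border = FALSE,
             total_red = cells$total_red, nuclear_red = cells$nuc_red,
             cyto_red = cells$total_red - cells$nuc_red,
             enrich_red = cells$nuc_red / cells$total_red,
             total_cyan = cells$total_cyan, nuclear_cyan = cells$nuc_cyan,
             cyto_cyan = cells$total_cyan - cells$nuc_cyan,
             enrich_cyan = cells$nuc_cyan / cells$total_cyan,
             total_yellow = cells$total_yellow,
             nuclear_yellow = cells$nuc_yellow,
             cyto_yellow = cells$total_yellow - cells$nuc_yellow,
             enrich_yellow = cells$nuc_yellow / cells$total_yellow)
}

# fraction of measured frame-to-frame links that agree with true lineage
linkAccuracy <- function(tracks, trueIds, truth) {
  div <- truth@params$divisions
  ord <- order(tracks$track_id, tracks$frame)
  tid <- tracks$track_id[ord]; fr <- tracks$frame[ord]; ti <- trueIds[ord]
  same <- tid[-1] == tid[-length(tid)] & diff(fr) == 1L
  a <- ti[-length(ti)][same]; b <- ti[-1][same]
  okDirect <- a == b
  okDiv <- paste(a, b) %in% c(paste(div$parent_id, div$daughter1),
                              paste(div$parent_id, div$daughter2))
  mean(okDirect | okDiv)
}
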