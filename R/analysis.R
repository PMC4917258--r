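#' Activation map from a frame stack
#'
#' Per-node time of the first rising crossing of `threshold` after `t0`.
#' Nodes that never activate are NA.
#'
#' @param rec an `nram_recording` with frames, or a 3D array (nx, ny, nt).
#' @param threshold activation threshold, mV (default -20, rising).
#' @param t0 reference time, ms; activation times are reported relative to
#'   it (only frames at or after `t0` are considered).
#' @param times frame times (taken from the recording when omitted).
#' @param isochrone isochrone interval attached as an attribute, ms.
#' @return Matrix (nx x ny) of class `nram_activation_map` with activation
#'   times in ms after `t0`.
#' @export
activation_map <- function(rec, threshold = -20, t0 = 0, times = NULL,
                           isochrone = 6) {
  fr <- if (is.list(rec)) rec$frames else rec
  if (is.null(fr)) stop("recording has no frames")
  if (is.null(times)) times <- if (is.list(rec)) rec$frame_time else
    seq_len(dim(fr)[3]) - 1
  keep <- which(times >= t0)
  fr <- fr[, , keep, drop = FALSE]
  times <- times[keep]
  nx <- dim(fr)[1]; ny <- dim(fr)[2]; nt <- dim(fr)[3]
  m <- matrix(fr, nx * ny, nt)
  above <- !is.na(m) & m >= threshold
  # first frame that is above threshold with the previous frame below
  rising <- above & cbind(FALSE, !above[, -nt, drop = FALSE])
  rising[, 1] <- above[, 1]
  first <- apply(rising, 1, function(z) { i <- which(z)[1]; i })
  out <- matrix(times[first] - t0, nx, ny)
  out[is.na(matrix(m[, 1], nx, ny))] <- NA
  attr(out, "isochrone") <- isochrone
  attr(out, "threshold") <- threshold
  class(out) <- c("nram_activation_map", class(out))
  out
}

#' Conduction velocity from an activation map
#'
#' Fits activation time against distance along the propagation axis by
#' least squares over the central region (a stated margin near the
#' stimulus site and the far boundary is excluded) and returns the inverse
#' slope. For a synthetic map with a uniform time gradient g per node the
#' estimate equals dx/g exactly.
#'
#' @param map activation-time matrix (ms), NA outside the tissue.
#' @param dx space step, cm.
#' @param axis propagation axis: `"x"` (rows) or `"y"` (columns).
#' @param margin fraction of the extent excluded at each end.
#' @return Conduction velocity in cm/s.
#' @export
conduction_velocity <- function(map, dx, axis = c("x", "y"), margin = 0.2) {
  axis <- match.arg(axis)
  if (axis == "y") map <- t(map)
  prof <- rowMeans(map, na.rm = TRUE)
  n <- length(prof)
  idx <- seq(max(1, ceiling(n * margin)), min(n, floor(n * (1 - margin))))
  idx <- idx[is.finite(prof[idx])]
  if (length(idx) < 3) stop("too few activated nodes to estimate CV")
  fit <- stats::lm.fit(cbind(1, idx * dx), prof[idx])
  slope <- unname(fit$coefficients[2])  # ms per cm
  if (!is.finite(slope) || slope <= 0) stop("no forward propagation along axis")
  1000 / slope  # cm/s
}

#' APD80 map and dispersion from a frame stack
#'
#' Computes per-node action-potential metrics from each node's voltage
#' trace at frame resolution and returns the APD80 map together with its
#' dispersion (max - min over in-mask nodes).
#'
#' @param rec an `nram_recording` with frames, or a 3D array.
#' @param stim_time onset of the analysed beat, ms.
#' @param times frame times.
#' @param level repolarization level (0.8 for APD80).
#' @return List with `apd` (matrix, ms), `rmp` (matrix, mV), `dispersion`
#'   (ms, max - min of `apd`).
#' @export
apd_map <- function(rec, stim_time, times = NULL, level = 0.8) {
  fr <- if (is.list(rec)) rec$frames else rec
  if (is.null(fr)) stop("recording has no frames")
  if (is.null(times)) times <- if (is.list(rec)) rec$frame_time else
    seq_len(dim(fr)[3]) - 1
  nx <- dim(fr)[1]; ny <- dim(fr)[2]; nt <- dim(fr)[3]
  m <- matrix(fr, nx * ny, nt)
  pre <- which(times < stim_time)
  if (!length(pre)) stop("stim_time precedes the first frame")
  after <- which(times >= stim_time)
  rmp <- m[, pre[length(pre)]]
  seg <- m[, after, drop = FALSE]
  tseg <- times[after]
  ipk <- max.col(replace(seg, is.na(seg), -Inf), ties.method = "first")
  peak <- seg[cbind(seq_len(nrow(seg)), ipk)]
  amp <- peak - rmp
  lvl <- peak - level * amp
  apd <- rep(NA_real_, nrow(seg))
  # upstroke: first crossing of -20 mV; APD measured from there to the
  # repolarization crossing (frame resolution)
  for (k in seq_len(nrow(seg))) {
    if (is.na(amp[k]) || amp[k] < 40) next
    up <- which(seg[k, ] >= -20)[1]
    if (is.na(up)) next
    rp <- which(seg[k, ] <= lvl[k] & seq_len(ncol(seg)) > ipk[k])[1]
    if (is.na(rp)) next
    # linear interpolation of the crossing instant
    if (rp > 1 && seg[k, rp - 1] > lvl[k]) {
      tcross <- tseg[rp - 1] + (tseg[rp] - tseg[rp - 1]) *
        (seg[k, rp - 1] - lvl[k]) / (seg[k, rp - 1] - seg[k, rp])
    } else tcross <- tseg[rp]
    apd[k] <- tcross - tseg[up]
  }
  apdm <- matrix(apd, nx, ny)
  rmpm <- matrix(rmp, nx, ny)
  vals <- apdm[is.finite(apdm)]
  list(apd = apdm, rmp = rmpm,
       dispersion = if (length(vals)) max(vals) - min(vals) else NA_real_)
}

#' Spiral-tip trajectory by isoline intersection
#'
#' Detects the spiral-wave tip in each frame as the intersection of the
#' voltage isoline V = `iso` with the zero contour of dV/dt (computed from
#' consecutive frames), using bilinear marching-squares segments per grid
#' cell. Points are linked across frames; frames with no tip leave a gap.
#'
#' @param rec an `nram_recording` with frames, or a 3D array.
#' @param iso tip isoline, mV (default -30).
#' @param times frame times.
#' @param dx space step in cm (for mm coordinates); taken from the
#'   recording's grid when available.
#' @return data.frame of class `nram_tip_trajectory`: `t` (ms), `x`, `y`
#'   (node coordinates), `x_mm`, `y_mm`.
#' @export
tip_trajectory <- function(rec, iso = -30, times = NULL, dx = NULL) {
  fr <- if (is.list(rec)) rec$frames else rec
  if (is.null(fr)) stop("recording has no frames")
  if (is.null(times)) times <- if (is.list(rec)) rec$frame_time else
    seq_len(dim(fr)[3]) - 1
  if (is.null(dx)) dx <- if (is.list(rec)) rec$grid$dx else NA_real_
  nt <- dim(fr)[3]
  out <- vector("list", nt - 1)
  last <- c(dim(fr)[1] / 2, dim(fr)[2] / 2)  # start looking near the centre
  for (k in seq_len(nt - 1)) {
    A <- fr[, , k] - iso
    B <- fr[, , k + 1] - fr[, , k]
    pts <- .isoline_intersections(A, B)
    if (is.null(pts)) next
    d2 <- (pts[, 1] - last[1])^2 + (pts[, 2] - last[2])^2
    pt <- pts[which.min(d2), ]
    last <- pt
    out[[k]] <- data.frame(t = times[k], x = pt[1], y = pt[2])
  }
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) out <- data.frame(t = numeric(0), x = numeric(0),
                                      y = numeric(0))
  out$x_mm <- (out$x - 1) * dx * 10
  out$y_mm <- (out$y - 1) * dx * 10
  class(out) <- c("nram_tip_trajectory", "data.frame")
  out
}

# all intersections of the zero-level sets of fields A and B (matrices);
# marching-squares chords intersected within each 2x2 cell
.isoline_intersections <- function(A, B) {
  nx <- nrow(A); ny <- ncol(A)
  okA <- is.finite(A); okB <- is.finite(B)
  a00 <- A[-nx, -ny]; a10 <- A[-1, -ny]; a01 <- A[-nx, -1]; a11 <- A[-1, -1]
  b00 <- B[-nx, -ny]; b10 <- B[-1, -ny]; b01 <- B[-nx, -1]; b11 <- B[-1, -1]
  fin <- okA[-nx, -ny] & okA[-1, -ny] & okA[-nx, -1] & okA[-1, -1] &
         okB[-nx, -ny] & okB[-1, -ny] & okB[-nx, -1] & okB[-1, -1]
  sgnA <- (pmin(a00, a10, a01, a11) < 0) & (pmax(a00, a10, a01, a11) > 0)
  sgnB <- (pmin(b00, b10, b01, b11) < 0) & (pmax(b00, b10, b01, b11) > 0)
  cand <- which(fin & sgnA & sgnB, arr.ind = TRUE)
  if (!nrow(cand)) return(NULL)
  hits <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    segA <- .ms_segment(A[i, j], A[i + 1, j], A[i, j + 1], A[i + 1, j + 1])
    segB <- .ms_segment(B[i, j], B[i + 1, j], B[i, j + 1], B[i + 1, j + 1])
    if (is.null(segA) || is.null(segB)) next
    pt <- .seg_intersect(segA, segB)
    if (!is.null(pt)) hits[[length(hits) + 1]] <- c(i + pt[1], j + pt[2])
  }
  if (!length(hits)) return(NULL)
  do.call(rbind, hits)
}

# zero-crossing chord of a bilinear cell with corner values
# f(0,0)=f00, f(1,0)=f10, f(0,1)=f01, f(1,1)=f11; returns matrix 2x2
# (two endpoints in unit-cell coordinates) or NULL
.ms_segment <- function(f00, f10, f01, f11) {
  pts <- NULL
  edge <- function(v1, v2, p1, p2) {
    if (is.na(v1) || is.na(v2) || v1 * v2 > 0) return(NULL)
    if (v1 == v2) return(NULL)
    s <- v1 / (v1 - v2)
    p1 + s * (p2 - p1)
  }
  e <- list(edge(f00, f10, c(0, 0), c(1, 0)),
            edge(f01, f11, c(0, 1), c(1, 1)),
            edge(f00, f01, c(0, 0), c(0, 1)),
            edge(f10, f11, c(1, 0), c(1, 1)))
  e <- e[!vapply(e, is.null, TRUE)]
  if (length(e) < 2) return(NULL)
  rbind(e[[1]], e[[2]])
}

# intersection of two segments given as 2x2 matrices (rows = endpoints)
.seg_intersect <- function(s1, s2) {
  p <- s1[1, ]; r <- s1[2, ] - s1[1, ]
  q <- s2[1, ]; s <- s2[2, ] - s2[1, ]
  den <- r[1] * s[2] - r[2] * s[1]
  if (abs(den) < 1e-12) return(NULL)
  tt <- ((q[1] - p[1]) * s[2] - (q[2] - p[2]) * s[1]) / den
  uu <- ((q[1] - p[1]) * r[2] - (q[2] - p[2]) * r[1]) / den
  if (tt < -0.05 || tt > 1.05 || uu < -0.05 || uu > 1.05) return(NULL)
  p + tt * r
}

#' Core size of a tip trajectory
#'
#' Maximum pairwise extent of the trajectory points over one meander cycle
#' (or the whole trajectory when `cycle_ms` is NULL), in mm.
#'
#' @param traj an `nram_tip_trajectory`.
#' @param cycle_ms window length defining one meander cycle, ms.
#' @return Core size in mm.
#' @export
core_size <- function(traj, cycle_ms = NULL) {
  if (!nrow(traj)) return(NA_real_)
  tt <- traj
  if (!is.null(cycle_ms)) tt <- traj[traj$t >= max(traj$t) - cycle_ms, ]
  if (nrow(tt) < 2) return(0)
  d <- as.matrix(stats::dist(cbind(tt$x_mm, tt$y_mm)))
  max(d)
}

#' Dominant period of a voltage signal
#'
#' Detrends the trace (mean removal and linear trend), applies a Hann
#' window, and returns the period of the spectral peak together with the
#' spectral resolution.
#'
#' @param v voltage samples.
#' @param dt sampling interval, ms.
#' @return List with `period_ms`, `frequency_hz`, `resolution_hz`.
#' @export
dominant_period <- function(v, dt) {
  n <- length(v)
  if (n < 8) stop("trace too short for a spectrum")
  x <- stats::residuals(stats::lm.fit(cbind(1, seq_len(n)), v))
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  X <- stats::fft(x * w)
  half <- 2:floor(n / 2)
  pow <- Mod(X[half])^2
  fs <- 1000 / dt                       # Hz
  freqs <- (half - 1) * fs / n
  fpk <- freqs[which.max(pow)]
  list(period_ms = 1000 / fpk, frequency_hz = fpk, resolution_hz = fs / n)
}

#' Reentry wavelength
#'
#' Product of conduction velocity and APD80 during reentry, in cm.
#'
#' @param cv conduction velocity, cm/s.
#' @param apd80_reentry APD80 during reentry, ms.
#' @return Wavelength in cm.
#' @examples
#' wavelength(22.2, 40)  # 0.888 cm
#' @export
wavelength <- function(cv, apd80_reentry) cv * apd80_reentry / 1000
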