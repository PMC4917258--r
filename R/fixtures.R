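#' Deterministic synthetic fixtures for testing and demonstrations
#'
#' Generates small, fully synthetic inputs whose properties are known by
#' construction: a rigidly rotating spiral movie with a prescribed tip
#' circle, an action-potential-like trace with prescribed APDs, APD maps
#' with prescribed dispersion, and a small monolayer grid.
#'
#' Kinds:
#' \describe{
#'   \item{`rotor`}{list(frames, times, centre, radius_nodes): a rotating
#'     depolarization front on an `n` x `n` grid that pivots about a point
#'     orbiting the grid centre on a circle of radius `radius_nodes`. The
#'     pivot is analytically the unique intersection of the V = -30 mV
#'     isoline with the dV/dt = 0 contour, so the detected tip path is a
#'     circle of known radius.}
#'   \item{`plane_wave`}{list(frames, times): a travelling plane wave with
#'     no phase singularity.}
#'   \item{`ap_trace`}{data.frame(time, V): triangular AP with RMP -80 mV,
#'     peak +40 mV and linear repolarization over 100 ms, so APD50 = 50 ms
#'     and APD80 = 80 ms from the upstroke.}
#'   \item{`apd_map_uniform` / `apd_map_gradient` / `apd_map_step`}{APD80
#'     matrices with dispersion 0 / `spread` (smooth) / `spread` (two
#'     sharp domains).}
#'   \item{`grid32`}{a 32 x 32 monolayer disc via [build_monolayer()].}
#' }
#'
#' @param kind fixture kind (see Details).
#' @param seed integer seed (placement randomness of `grid32`).
#' @param n linear grid size for movies/maps.
#' @param radius_nodes tip-circle radius of the rotor, in nodes.
#' @param spread APD spread of gradient/step maps, ms.
#' @param duration movie length, ms.
#' @param period rotation (or wave) period, ms.
#' @return The fixture object (see Details).
#' @export
make_fixture <- function(kind = c("rotor", "plane_wave", "ap_trace",
                                  "apd_map_uniform", "apd_map_gradient",
                                  "apd_map_step", "grid32"),
                         seed = 1, n = 64, radius_nodes = 6, spread = 19,
                         duration = 100, period = 50) {
  kind <- match.arg(kind)
  switch(kind,
    rotor = {
      times <- seq(0, duration, by = 1)
      cx0 <- (n + 1) / 2; cy0 <- (n + 1) / 2
      fr <- array(NA_real_, c(n, n, length(times)))
      om <- 2 * pi / period
      for (k in seq_along(times)) {
        t <- times[k]
        # pivot orbits the grid centre; front direction locked to the orbit
        # phase so the pivot's translation is parallel to the front (the
        # unique V=iso, dV/dt=0 intersection then sits exactly on the pivot)
        cx <- cx0 + radius_nodes * cos(om * t)
        cy <- cy0 + radius_nodes * sin(om * t)
        X <- matrix(seq_len(n), n, n) - cx
        Y <- matrix(seq_len(n), n, n, byrow = TRUE) - cy
        u <- cos(om * t) * X + sin(om * t) * Y
        fr[, , k] <- -30 + 50 * tanh(u / 4)
      }
      list(frames = fr, times = times, centre = c(cx0, cy0),
           radius_nodes = radius_nodes, period = period)
    },
    plane_wave = {
      times <- seq(0, duration, by = 1)
      fr <- array(NA_real_, c(n, n, length(times)))
      for (k in seq_along(times)) {
        X <- matrix(seq_len(n), n, n)
        fr[, , k] <- -30 + 50 * cos(2 * pi * (X / n - times[k] / period))
      }
      list(frames = fr, times = times)
    },
    ap_trace = {
      time <- seq(0, 200, by = 0.1)
      V <- rep(-80, length(time))
      V[time >= 20 & time < 21] <- -80 + (time[time >= 20 & time < 21] - 20) * 120
      rep_ph <- time >= 21 & time < 121
      V[rep_ph] <- 40 - (time[rep_ph] - 21) * 1.2
      data.frame(time = time, V = V)
    },
    apd_map_uniform = matrix(50, n, n),
    apd_map_gradient = {
      g <- matrix(seq(50, 50 + spread, length.out = n), n, n)
      g
    },
    apd_map_step = {
      m <- matrix(50, n, n)
      m[seq_len(floor(n / 2)), ] <- 50 + spread
      m
    },
    grid32 = build_monolayer(nx = 32, ny = 32, dx = 0.00625, diameter = 0.19,
                             fib_fraction = 0.17, variability = c(50, 150),
                             seed = seed)
  )
}
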