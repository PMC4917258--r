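#' The 19 conductances and fluxes subject to intercellular variability
#'
#' Enumerates the maximal conductances and Ca2+-flux rates that receive one
#' independent random multiplier per cell when building a heterogeneous
#' monolayer. The composite inward rectifier contributes two entries
#' (rectifier part and K+ leak part), and the NSR-to-JSR transfer rate is
#' scaled through its inverse time constant.
#'
#' @return Character vector of length 19.
#' @export
variability_targets <- function() {
  c("G_Na", "G_CaL", "G_CaT", "G_to", "G_Kur", "G_Kr", "G_Ks", "G_f",
    "G_Nab", "G_Cab", "gK1_scale", "g_Kleak", "g_KACh", "I_NaK_max",
    "k_NCX", "V_max_up", "k_s_rel", "k_leak", "k_tr")
}

#' Random conductance multipliers for intercellular variability
#'
#' Draws one independent uniform factor in \[X1/100, X2/100\] for each of
#' the 19 designated conductances/fluxes ([variability_targets()]) and each
#' of `n` cells. The published variability settings are 50-150%, 75-125%
#' and 90-110%; the degenerate range (100, 100) yields factors exactly 1.
#'
#' @param n number of cells.
#' @param variability length-2 vector (X1, X2) in percent, 0 < X1 <= X2.
#' @param seed integer seed (the draw is reproducible and does not disturb
#'   the global RNG stream).
#' @return n x 19 matrix of multipliers with named columns.
#' @export
variability_multipliers <- function(n, variability = c(100, 100), seed = 1) {
  x1 <- variability[1]; x2 <- variability[2]
  if (!(x1 > 0 && x1 <= x2)) stop("variability must satisfy 0 < X1 <= X2")
  m <- matrix(.with_seed(seed, stats::runif(n * 19, 0.01 * x1, 0.01 * x2)),
              nrow = n, ncol = 19)
  colnames(m) <- variability_targets()
  m
}

# run code under a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Construct a virtual monolayer
#'
#' Builds a 2D lattice with a circular culture mask, random myofibroblast
#' placement and per-cell conductance variability. With the default grid
#' (256 x 256, dx = 0.00625 cm, i.e. a 16 mm square) the 15.6 mm culture
#' disc is inscribed; nodes outside the disc are no-flux. Exactly
#' `round(fib_fraction * N_masked)` nodes become passive myofibroblasts,
#' placed uniformly at random. The same seed yields a bit-identical grid.
#'
#' @param nx,ny grid points.
#' @param dx space step, cm.
#' @param diameter culture-disc diameter, cm (default 1.56 = 15.6 mm).
#' @param fib_fraction myofibroblast fraction of masked nodes (0 <= f < 1).
#' @param variability (X1, X2) percent range of intercellular variability.
#' @param seed integer seed governing placement and multipliers.
#' @param D diffusion coefficient, cm^2/ms.
#' @param shape `"disc"` (circular mask) or `"square"` (whole rectangle, as
#'   used for homogeneous spiral-wave characterisation) or `"strip"` (full
#'   rectangle; alias of square).
#' @return Object of class `nram_grid`: list with `nx`, `ny`, `dx`, `D`,
#'   `type` (integer matrix: 0 outside, 1 myocyte, 2 myofibroblast),
#'   `mult` (n_nodes x 19 multiplier matrix), `seed`, `fib_fraction`,
#'   `variability`.
#' @export
build_monolayer <- function(nx = 256, ny = 256, dx = 0.00625,
                            diameter = 1.56, fib_fraction = 0,
                            variability = c(100, 100), seed = 1,
                            D = 0.00012, shape = c("disc", "square", "strip")) {
  shape <- match.arg(shape)
  if (fib_fraction < 0 || fib_fraction >= 1)
    stop("fib_fraction must lie in [0, 1)")
  if (shape == "disc" && (nx * dx < diameter || ny * dx < diameter))
    stop("grid too small to inscribe the culture disc")
  type <- matrix(0L, nx, ny)
  if (shape == "disc") {
    cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
    r2 <- (diameter / (2 * dx))^2
    ix <- matrix(seq_len(nx), nx, ny)
    iy <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
    type[(ix - cx)^2 + (iy - cy)^2 <= r2] <- 1L
  } else {
    type[] <- 1L
  }
  masked <- which(type == 1L)
  nfib <- round(fib_fraction * length(masked))
  if (nfib > 0) {
    fib <- .with_seed(seed, sample(masked, nfib))
    type[fib] <- 2L
  }
  mult <- matrix(1, nx * ny, 19)
  colnames(mult) <- variability_targets()
  myo <- which(type == 1L)
  mult[myo, ] <- variability_multipliers(length(myo), variability,
                                         seed = seed + 1L)
  g <- list(nx = nx, ny = ny, dx = dx, D = D, diameter = diameter,
            type = type, mult = mult, seed = seed,
            fib_fraction = fib_fraction, variability = variability,
            shape = shape)
  class(g) <- "nram_grid"
  g
}

#' @export
print.nram_grid <- function(x, ...) {
  n_m <- sum(x$type == 1L); n_f <- sum(x$type == 2L)
  cat(sprintf("NRAM monolayer grid %d x %d (dx = %g cm, %s)\n",
              x$nx, x$ny, x$dx, x$shape))
  cat(sprintf("  %d myocytes, %d myofibroblasts (%.1f%%), variability %g-%g%%, seed %d\n",
              n_m, n_f, 100 * n_f / (n_m + n_f), x$variability[1],
              x$variability[2], x$seed))
  invisible(x)
}

#' Quality control of a monolayer APD map
#'
#' Applies the acceptance rule used for simulated monolayers: the map is
#' rejected if the APD80 dispersion (max - min over masked myocyte nodes,
#' after discarding a boundary margin) exceeds `max_dispersion` (20 ms), or
#' if the distribution is non-uniform in the sense of containing contiguous
#' APD domains with sharp borders (more than `jump_fraction` of adjacent
#' node pairs differing by over `jump_threshold`). A smooth gradient below
#' the dispersion limit is accepted, as are isolated frame-quantisation
#' outliers.
#'
#' @param apd80_map numeric matrix of APD80 (ms), NA outside the mask.
#' @param max_dispersion rejection threshold on max - min, ms.
#' @param jump_threshold APD difference between adjacent nodes counted as a
#'   domain border, ms.
#' @param jump_fraction tolerated share of adjacent pairs above the jump
#'   threshold.
#' @param margin number of boundary node layers discarded before judging.
#' @return list with `accept` (logical), `reason` (`NA`, `"dispersion"` or
#'   `"non-uniform"`), `dispersion` (ms).
#' @export
qc_monolayer <- function(apd80_map, max_dispersion = 20, jump_threshold = 10,
                         jump_fraction = 0.005, margin = 2) {
  m <- apd80_map
  # erode the mask by `margin` layers to drop boundary artefacts
  for (k in seq_len(margin)) {
    inner <- !is.na(m)
    shrink <- inner
    shrink[-1, ] <- shrink[-1, ] & inner[-nrow(m), ]
    shrink[-nrow(m), ] <- shrink[-nrow(m), ] & inner[-1, ]
    shrink[, -1] <- shrink[, -1] & inner[, -ncol(m)]
    shrink[, -ncol(m)] <- shrink[, -ncol(m)] & inner[, -1]
    m[!shrink] <- NA
  }
  vals <- m[!is.na(m)]
  if (!length(vals)) stop("APD map empty after margin erosion")
  disp <- max(vals) - min(vals)
  if (disp > max_dispersion)
    return(list(accept = FALSE, reason = "dispersion", dispersion = disp))
  dx1 <- abs(m[-1, ] - m[-nrow(m), ])
  dy1 <- abs(m[, -1] - m[, -ncol(m)])
  jumps <- c(dx1[!is.na(dx1)], dy1[!is.na(dy1)])
  if (length(jumps) && mean(jumps > jump_threshold) > jump_fraction)
    return(list(accept = FALSE, reason = "non-uniform", dispersion = disp))
  list(accept = TRUE, reason = NA_character_, dispersion = disp)
}
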