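#' Read and write parameter sets as plain text
#'
#' Parameter files are `key = value` lines (one per key; `#` comments and
#' blank lines ignored). Block fractions are keyed `block.<current>`.
#' Unknown keys are rejected. A round trip restores the parameter set
#' exactly.
#'
#' @param params an `nram_params` object.
#' @param path file path.
#' @return `read_params()` returns a validated `nram_params`;
#'   `write_params()` returns `path` invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "nram_params"))
  scal <- params[setdiff(names(params), "block")]
  lines <- c("# NRAM ionic-model parameter set",
             sprintf("%s = %.17g", names(scal), unlist(scal)),
             sprintf("block.%s = %.17g", names(params$block), params$block))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.+)$", lines))
  bad <- lines[vapply(kv, length, 0L) != 3]
  if (length(bad)) stop("malformed parameter line: ", bad[1])
  keys <- vapply(kv, `[`, "", 2)
  vals <- as.numeric(vapply(kv, `[`, "", 3))
  if (anyNA(vals)) stop("non-numeric parameter value for ",
                        keys[which(is.na(vals))[1]])
  p <- .default_params()
  isblk <- startsWith(keys, "block.")
  for (i in which(!isblk)) {
    if (!keys[i] %in% names(p)) stop("unknown parameter key: ", keys[i])
    p[[keys[i]]] <- vals[i]
  }
  for (i in which(isblk)) {
    cur <- sub("^block\\.", "", keys[i])
    if (!cur %in% block_currents()) stop("unknown blockable current: ", cur)
    p$block[[cur]] <- vals[i]
  }
  validate_params(p)
}

#' Write a single-cell trace as CSV
#'
#' Columns `time_ms`, `V_mV`, `Ca_i_mM`, `Ca_NSR_mM`, `Ca_JSR_mM`, plus
#' per-current columns when the trace carries them.
#'
#' @param trace an `nram_trace`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(time_ms = trace$time, V_mV = trace$V,
                   Ca_i_mM = trace$Ca_i, Ca_NSR_mM = trace$Ca_NSR,
                   Ca_JSR_mM = trace$Ca_JSR)
  cur <- attr(trace, "currents")
  if (!is.null(cur)) df <- cbind(df, as.data.frame(cur))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write and read voltage frame stacks
#'
#' Binary container: a JSON header line (nx, ny, dx_cm, frame times) then
#' raw little-endian doubles, one frame after another (column-major). A
#' CSV/JSON sidecar is embedded as the header, so one file round-trips the
#' stack.
#'
#' @param frames 3D array (nx, ny, nt).
#' @param times frame times, ms.
#' @param dx space step, cm.
#' @param path output file.
#' @return `write_frames()` returns `path` invisibly; `read_frames()`
#'   returns list(frames, times, dx).
#' @export
write_frames <- function(frames, times, dx, path) {
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] == length(times))
  hdr <- jsonlite::toJSON(list(nx = dim(frames)[1], ny = dim(frames)[2],
                               dx_cm = dx, times = times),
                          auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(hdr, "\n")), con)
  writeBin(as.numeric(frames), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- raw(0)
  repeat {
    b <- readBin(con, "raw", 1)
    if (!length(b) || b == charToRaw("\n")) break
    hdr_raw <- c(hdr_raw, b)
  }
  hdr <- jsonlite::fromJSON(rawToChar(hdr_raw))
  n <- hdr$nx * hdr$ny * length(hdr$times)
  x <- readBin(con, "numeric", n, size = 8, endian = "little")
  list(frames = array(x, c(hdr$nx, hdr$ny, length(hdr$times))),
       times = hdr$times, dx = hdr$dx_cm)
}

#' Serialize a monolayer grid
#'
#' Writes the cell-type map as CSV (integer codes: 0 outside, 1 myocyte,
#' 2 myofibroblast), the multiplier matrix as CSV, and a JSON manifest
#' (seed, fractions, variability range, geometry) alongside.
#'
#' @param grid an `nram_grid`.
#' @param prefix output path prefix; writes `<prefix>_type.csv`,
#'   `<prefix>_mult.csv`, `<prefix>_manifest.json`.
#' @return The three paths, invisibly.
#' @export
write_grid <- function(grid, prefix) {
  tpath <- paste0(prefix, "_type.csv")
  mpath <- paste0(prefix, "_mult.csv")
  jpath <- paste0(prefix, "_manifest.json")
  utils::write.table(grid$type, tpath, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(grid$mult, mpath, sep = ",", row.names = FALSE,
                     col.names = TRUE)
  jsonlite::write_json(list(nx = grid$nx, ny = grid$ny, dx = grid$dx,
                            D = grid$D, diameter = grid$diameter,
                            seed = grid$seed,
                            fib_fraction = grid$fib_fraction,
                            variability = grid$variability,
                            shape = grid$shape),
                       jpath, auto_unbox = TRUE, digits = NA)
  invisible(c(tpath, mpath, jpath))
}

#' @rdname write_grid
#' @export
read_grid <- function(prefix) {
  man <- jsonlite::fromJSON(paste0(prefix, "_manifest.json"))
  type <- as.matrix(utils::read.table(paste0(prefix, "_type.csv"), sep = ","))
  dimnames(type) <- NULL
  mult <- as.matrix(utils::read.csv(paste0(prefix, "_mult.csv"), check.names = FALSE))
  g <- list(nx = man$nx, ny = man$ny, dx = man$dx, D = man$D,
            diameter = man$diameter, type = matrix(as.integer(type), man$nx),
            mult = mult, seed = man$seed, fib_fraction = man$fib_fraction,
            variability = man$variability, shape = man$shape)
  class(g) <- "nram_grid"
  g
}
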