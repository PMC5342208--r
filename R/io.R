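# Trajectory and reference-curve serialization: plain delimited text with
# a '#'-prefixed metadata header, comma-separated, '.' decimal separator.

#' Write / read a trajectory as tidy CSV
#'
#' The file holds one row per (time, series, species) with the per-cell
#' series labelled by cell id and the lattice-wide sums labelled
#' `"global"`; run metadata (parameters, seed, scenario, step size) is
#' preserved in a `#`-prefixed header block, so `read_trajectory()`
#' restores densities and metadata exactly as stored.
#'
#' @param traj An `fp_trajectory`.
#' @param path Output file path.
#' @return `write_trajectory()`: the path, invisibly;
#'   `read_trajectory()`: an `fp_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "fp_trajectory"))
  p <- traj$params
  meta <- c(
    "# fockpop trajectory v1",
    sprintf("# scenario: %s", traj$scenario),
    sprintf("# seed: %s", traj$seed),
    sprintf("# dt: %.17g", traj$dt),
    sprintf("# method: %s", traj$method),
    sprintf("# status: %s", traj$status),
    sprintf("# n_cells: %d", ncol(traj$n_a)),
    sprintf("# params: sigma=%.17g tau=%.17g mu=%.17g p=%.17g K_total=%.17g jitter=%.17g eps_density=%.17g",
            p$sigma, p$tau, p$mu, p$p, p$K_total, p$jitter, p$eps_density),
    sprintf("# norm: %s", paste(sprintf("%.17g", traj$norm), collapse = " ")))
  df <- as.data.frame(traj)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(format(df, digits = 17, scientific = FALSE,
                            trim = TRUE),
                     con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  if (!length(hdr) || !grepl("fockpop trajectory", hdr[1L]))
    stop("not a fockpop trajectory file: ", path, call. = FALSE)
  get_meta <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, ":"))]
    if (!length(ln)) return(NA_character_)
    trimws(sub(paste0("^# ", key, ":"), "", ln[1L]))
  }
  df <- utils::read.csv(text = lines[!startsWith(lines, "#")],
                        stringsAsFactors = FALSE)
  pv <- get_meta("params")
  kv <- strsplit(strsplit(pv, " +")[[1L]], "=")
  pl <- stats::setNames(lapply(kv, function(x) as.numeric(x[2L])),
                        vapply(kv, `[`, "", 1L))
  params <- model_params(sigma = pl$sigma, tau = pl$tau, mu = pl$mu,
                         p = pl$p, K_total = pl$K_total, jitter = pl$jitter,
                         eps_density = pl$eps_density)
  M <- as.integer(get_meta("n_cells"))
  times <- sort(unique(df$time))
  nt <- length(times)
  n_a <- matrix(NA_real_, nt, M); n_b <- matrix(NA_real_, nt, M)
  for (sp in c("a", "b")) {
    sub <- df[df$species == sp & df$cell_id != "global", ]
    m <- matrix(NA_real_, nt, M)
    m[cbind(match(sub$time, times), as.integer(sub$cell_id))] <- sub$density
    if (sp == "a") n_a <- m else n_b <- m
  }
  norm <- as.numeric(strsplit(get_meta("norm"), " +")[[1L]])
  lat_info <- list(L = NA_integer_, n_cells = M, n_modes = 2L * M,
                   dim = NA_real_, neighbors = NA_character_,
                   boundary = NA_character_)
  seed <- suppressWarnings(as.integer(get_meta("seed")))
  new_trajectory(time = times, n_a = n_a, n_b = n_b, norm = norm,
                 params = params, lattice_info = lat_info,
                 dt = as.numeric(get_meta("dt")),
                 method = get_meta("method"),
                 scenario = get_meta("scenario"), seed = seed,
                 status = get_meta("status"))
}

#' Synthetic reference demographic curve
#'
#' Generates an irregular oscillating time series around a carrying
#' capacity `K_ref` whose minimum and maximum, as ratios to `K_ref`, equal
#' the requested values exactly at the generated resolution. It stands in
#' for external demographic reconstructions in the comparison statistics
#' and in tests; curves written to disk are plainly labelled synthetic.
#'
#' The waveform is a seeded sum of incommensurate sinusoids, affinely
#' rescaled so its extremes hit the requested band exactly.
#'
#' @param K_ref Carrying capacity of the reference curve.
#' @param min_ratio,max_ratio Requested extremes relative to `K_ref`;
#'   `0 < min_ratio <= 1 <= max_ratio`.
#' @param n_periods Approximate number of main oscillation periods.
#' @param n_points Number of samples.
#' @param seed Integer seed for the random phases.
#' @param path Optional path; when given, the curve is written as
#'   two-column CSV (`time,value`) with a metadata header.
#' @return A data frame with columns `time`, `value` and attribute
#'   `K_ref`; written to `path` when requested.
#' @export
make_reference_fixture <- function(K_ref = 0.185, min_ratio = 0.70,
                                   max_ratio = 1.57, n_periods = 5,
                                   n_points = 500, seed = 1L,
                                   path = NULL) {
  if (!(min_ratio > 0 && min_ratio <= 1 && max_ratio >= 1))
    stop("need 0 < min_ratio <= 1 <= max_ratio", call. = FALSE)
  stopifnot(n_points >= 2L, n_periods >= 1)
  tm <- seq(0, n_periods, length.out = n_points)
  if (min_ratio == max_ratio) {
    w <- rep(0, n_points)
  } else {
    w <- with_seed(seed, {
      ph <- stats::runif(3L, 0, 2 * pi)
      am <- stats::runif(3L, 0.3, 1)
      base <- am[1L] * sin(2 * pi * tm + ph[1L]) +
        am[2L] * 0.45 * sin(2 * pi * exp(1) / 2 * tm + ph[2L]) +
        am[3L] * 0.25 * sin(2 * pi * sqrt(5) * tm + ph[3L])
      2 * (base - min(base)) / (max(base) - min(base)) - 1  # extremes +/-1
    })
  }
  mid <- (min_ratio + max_ratio) / 2
  half <- (max_ratio - min_ratio) / 2
  value <- K_ref * (mid + half * w)
  out <- data.frame(time = tm, value = value)
  attr(out, "K_ref") <- K_ref
  if (!is.null(path)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# fockpop synthetic reference curve v1",
                 sprintf("# K_ref: %.17g", K_ref),
                 sprintf("# seed: %d", as.integer(seed))), con)
    utils::write.table(format(out, digits = 17, scientific = FALSE,
                              trim = TRUE),
                       con, sep = ",", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Read a reference curve from delimited text
#'
#' Accepts two-column (time, value) text with optional header line and
#' optional `#` comment lines; comma, semicolon, tab or whitespace
#' delimited. A `# K_ref:` header, if present, is attached as the `K_ref`
#' attribute.
#'
#' @param path File path.
#' @return Data frame with columns `time`, `value` (and possibly a
#'   `K_ref` attribute).
#' @export
read_reference <- function(path) {
  lines <- readLines(path)
  kline <- lines[grepl("^#\\s*K_ref:", lines)]
  body <- lines[!startsWith(trimws(lines), "#")]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L)
    stop("reference file has fewer than 2 data rows", call. = FALSE)
  delim <- if (grepl(",", body[[1]])) "," else
           if (grepl(";", body[[1]])) ";" else
           if (grepl("\t", body[[1]])) "\t" else ""
  has_header <- !grepl("^[-+0-9.eE \t,;]+$", body[[1]])
  df <- utils::read.table(text = body, sep = delim, header = has_header,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("reference file needs two columns", call. = FALSE)
  out <- data.frame(time = as.numeric(df[[1L]]), value = as.numeric(df[[2L]]))
  if (anyNA(out$time) || anyNA(out$value))
    stop("non-numeric entries in reference file", call. = FALSE)
  if (length(kline))
    attr(out, "K_ref") <- as.numeric(sub("^#\\s*K_ref:\\s*", "", kline[1L]))
  out
}
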