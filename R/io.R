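# Readers and writers for the delimited text formats: detections,
# receiver/beacon tables, localization tables, run configuration. Times
# are serialized as decimal seconds with picosecond precision (12 dp):
# fixed-point, so round trips do not drift, and fine enough that the
# ~0.3 mm quantization is negligible against any ToA error.

fmt_s <- function(x) sprintf("%.12f", x)

#' Read a detection table
#'
#' Delimited text with header columns `packet_id, emitter_id, receiver_id,
#' toa_s, sigma_s, snr_db, timestamp_s` (CSV), or a JSON-lines file with
#' the same fields (detected by a `.jsonl`/`.json` extension).
#'
#' @param path file path.
#' @return a detection data.frame.
#' @export
read_detections <- function(path) {
  d <- if (grepl("\\.jsonl?$", path)) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    do.call(rbind, lapply(lines, function(l)
      as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(packet_id = "character",
                                   emitter_id = "character",
                                   receiver_id = "character"))
  }
  validate_detections(d)
  d
}

#' Write a detection table as CSV
#' @param detections detection data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path) {
  d <- detections
  for (col in c("toa_s", "timestamp_s"))
    if (!is.null(d[[col]])) d[[col]] <- fmt_s(d[[col]])
  # sigmas span nanoseconds to picoseconds: scientific notation
  if (!is.null(d$sigma_s)) d$sigma_s <- sprintf("%.6e", d$sigma_s)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a receiver/beacon table
#'
#' CSV with columns `id, x_m, y_m, z_m, is_beacon`. Rows with
#' `is_beacon = TRUE` describe beacon transmitters (id = emitter id,
#' position = the beacon's known true position); the rest are receivers.
#'
#' @param path file path.
#' @return list with `receivers` (receiver table) and `beacons`
#'   (data.frame `id, x, y, z`).
#' @export
read_receivers <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(id = "character"))
  need <- c("id", "x_m", "y_m", "z_m")
  if (!all(need %in% names(d)))
    stop("receiver table needs columns ", paste(need, collapse = ", "))
  if (is.null(d$is_beacon)) d$is_beacon <- FALSE
  b <- d[as.logical(d$is_beacon), , drop = FALSE]
  r <- d[!as.logical(d$is_beacon), , drop = FALSE]
  list(receivers = receiver_table(r$id, r$x_m, r$y_m, r$z_m),
       beacons = data.frame(id = b$id, x = b$x_m, y = b$y_m, z = b$z_m,
                            stringsAsFactors = FALSE))
}

#' Write a receiver/beacon table
#' @param receivers receiver table.
#' @param beacons data.frame `id, x, y, z` (may be empty).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_receivers <- function(receivers, beacons, path) {
  d <- rbind(data.frame(id = receivers$id, x_m = receivers$x,
                        y_m = receivers$y, z_m = receivers$z,
                        is_beacon = FALSE),
             if (nrow(beacons)) data.frame(id = beacons$id,
                                           x_m = beacons$x,
                                           y_m = beacons$y,
                                           z_m = beacons$z,
                                           is_beacon = TRUE))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# short deterministic fingerprint of a config for provenance headers
config_hash <- function(config) {
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

#' Write a localization table
#'
#' CSV with a provenance header line (`# toatrack ...` with the config
#' hash and seed, enabling exact reruns) and columns `packet_id,
#' emitter_id, time_s, x_m, y_m, z_m, cov_xx, cov_xy, cov_yy, std_m, nbs,
#' ambiguous, variant`.
#'
#' @param estimates list of `toa_estimate`s.
#' @param path output path.
#' @param config the `toa_config` used (for the provenance header).
#' @return `path`, invisibly.
#' @export
write_localizations <- function(estimates, path, config = toa_config()) {
  rows <- lapply(estimates, function(e) {
    cv <- e$covariance
    data.frame(packet_id = e$packet_id, emitter_id = e$emitter_id,
               time_s = fmt_s(e$time),
               x_m = sprintf("%.6f", e$location[1]),
               y_m = sprintf("%.6f", e$location[2]),
               z_m = sprintf("%.6f", e$location[3]),
               cov_xx = sprintf("%.6g", cv[1, 1]),
               cov_xy = sprintf("%.6g", cv[1, 2]),
               cov_yy = sprintf("%.6g", cv[2, 2]),
               std_m = sprintf("%.6f", e$std), nbs = e$nbs,
               ambiguous = e$ambiguous,
               variant = e$diagnostics$variant,
               stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(packet_id = character(), emitter_id = character(),
               time_s = character(), x_m = character(),
               y_m = character(), z_m = character(),
               cov_xx = character(), cov_xy = character(),
               cov_yy = character(), std_m = character(),
               nbs = integer(), ambiguous = logical(),
               variant = character())
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# toatrack %s; config_hash=%s; seed=%s",
    as.character(utils::packageVersion("toatrack")),
    config_hash(config),
    if (is.null(config$seed)) "NA" else config$seed), con)
  utils::write.csv(tab, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a localization table
#' @param path file written by [write_localizations()].
#' @return data.frame with numeric columns restored.
#' @export
read_localizations <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                  colClasses = c(packet_id = "character",
                                 emitter_id = "character"))
}

#' Read a run configuration file
#'
#' YAML (or JSON) key-value file; keys must be arguments of
#' [toa_config()], unknown keys are rejected.
#'
#' @param path file path.
#' @return a `toa_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(toa_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(toa_config, vals)
}
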