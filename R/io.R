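#' Write a recording to a plain-text container directory
#'
#' One directory per recording: each trace as a two-column TSV
#' (`time_s`, `value`) written to full floating precision, plus a JSON
#' sidecar `recording.json` carrying rate, units, mode, holding, cell
#' metadata, epochs and solution compositions. [read_recording()] inverts
#' this bit-exactly for metadata and to full double precision for samples.
#'
#' @param rec an [recording()].
#' @param path directory to create (must not already contain a sidecar
#'   unless `overwrite = TRUE`).
#' @param overwrite replace an existing container.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, overwrite = FALSE) {
  stopifnot(inherits(rec, "hc_recording"))
  sidecar <- file.path(path, "recording.json")
  if (file.exists(sidecar) && !overwrite)
    stop("container already exists at ", path, " (use overwrite = TRUE)")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  tr_meta <- list()
  for (nm in names(rec$traces)) {
    tr <- rec$traces[[nm]]
    fn <- paste0("trace-", nm, ".tsv")
    tt <- trace_times(tr)
    con <- file(file.path(path, fn), "w")
    writeLines("time_s\tvalue", con)
    writeLines(paste(sprintf("%.17g", tt), sprintf("%.17g", tr$samples),
                     sep = "\t"), con)
    close(con)
    tr_meta[[nm]] <- list(file = fn, rate_hz = tr$rate, units = tr$units,
                          t0 = tr$t0, n = length(tr$samples))
  }
  side <- list(
    format = "hairclamp-recording-v1",
    mode = rec$mode,
    holding = rec$holding,
    meta = unclass(rec$meta),
    traces = tr_meta,
    epochs = lapply(rec$epochs, unclass),
    solutions = lapply(rec$solutions, function(s)
      list(label = s$label, ions = as.list(s$ions),
           blockers = as.list(s$blockers)))
  )
  # digits = I(17): full significant digits so doubles round-trip exactly
  jsonlite::write_json(side, sidecar, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a recording container
#'
#' @param path directory written by [write_recording()].
#' @return an [recording()].
#' @export
read_recording <- function(path) {
  sidecar <- file.path(path, "recording.json")
  if (!file.exists(sidecar))
    stop("no recording.json sidecar found in ", path)
  side <- jsonlite::read_json(sidecar, simplifyVector = FALSE)
  if (!identical(side$format, "hairclamp-recording-v1"))
    stop("malformed sidecar: unknown or missing format tag in ", sidecar)
  need <- c("mode", "holding", "meta", "traces", "epochs")
  miss <- setdiff(need, names(side))
  if (length(miss))
    stop("malformed sidecar: missing field(s) ", paste(miss, collapse = ", "),
         " in ", sidecar)
  traces <- list()
  for (nm in names(side$traces)) {
    tm <- side$traces[[nm]]
    f <- file.path(path, tm$file)
    if (!file.exists(f)) stop("trace file missing: ", f)
    tab <- utils::read.table(f, header = TRUE, sep = "\t",
                             colClasses = "numeric")
    if (!identical(names(tab), c("time_s", "value")))
      stop("malformed trace table ", f, ": expected columns time_s, value")
    if (nrow(tab) != tm$n)
      stop(sprintf("trace '%s': sidecar declares %d samples, file has %d",
                   nm, tm$n, nrow(tab)))
    traces[[nm]] <- trace(tab$value, tm$rate_hz, tm$units, tm$t0)
  }
  epochs <- lapply(seq_along(side$epochs), function(i) {
    e <- side$epochs[[i]]
    ok <- all(c("label", "t_start", "t_end", "track") %in% names(e))
    if (!ok) stop("malformed sidecar: epoch #", i, " lacks required fields")
    epoch(e$label, e$t_start, e$t_end, e$track)
  })
  m <- side$meta
  meta <- cell_meta(m$genotype, m$age, m$cell_type, m$position,
                    m$bundle_intact)
  solutions <- lapply(side$solutions, function(s)
    do.call(solution_spec, c(list(label = s$label), s$ions, s$blockers)))
  recording(traces, epochs, meta, side$mode, side$holding, solutions)
}
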