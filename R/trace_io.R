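# On-disk sweep-bundle formats.
#
# Canonical container: a directory per cell holding manifest.json (cell and
# per-sweep metadata, with explicit units) plus one diffable CSV per sweep
# (columns voltage,current at 9 significant digits). An HDF5 layout
# (/sweeps/<id>/{voltage,current} with attributes) is read/written through
# rhdf5 when that package is installed. NWB import is not supported in this
# build (no NWB reader in the dependency stack).

ACCEPTED_UNITS <- list(
  voltage = c(mV = 1, V = 1000),
  current = c(pA = 1, nA = 1000),
  sample_rate = c(kHz = 1, Hz = 1e-3))

# scale factor that brings a declared unit to canonical mV/pA/kHz
unit_factor <- function(quantity, unit, sweep_id) {
  if (is.null(unit) || is.na(unit) || !nzchar(unit))
    stopf("sweep %s: missing units for %s", sweep_id, quantity)
  f <- ACCEPTED_UNITS[[quantity]][unit]
  if (is.na(f)) stopf("sweep %s: unknown %s unit '%s'", sweep_id, quantity, unit)
  unname(f)
}

sweep_meta <- function(s, file) {
  list(sweep_id = s$sweep_id, clamp_mode = s$clamp_mode,
       sample_rate = s$sample_rate, n_samples = length(s$voltage),
       units = list(voltage = "mV", current = "pA", sample_rate = "kHz"),
       protocol = list(kind = s$protocol$kind, amplitude = s$protocol$amplitude,
                       frequency = s$protocol$frequency,
                       duration_ms = s$protocol$duration_ms,
                       onset_ms = s$protocol$onset_ms,
                       holding = s$protocol$holding),
       baseline_window = s$baseline_window, file = file)
}

#' Write a cell record to disk
#'
#' @param record a [cell_record()].
#' @param path target directory (csv_json) or `.h5` file (hdf5); created or
#'   overwritten.
#' @param format `"csv_json"` (canonical, diffable) or `"hdf5"` (requires the
#'   rhdf5 package).
#' @return `path`, invisibly.
#' @seealso [read_cell_bundle()]
#' @export
write_cell_bundle <- function(record, path, format = c("csv_json", "hdf5")) {
  format <- match.arg(format)
  if (!is_cell_record(record)) stopf("record must be a gc_cell_record")
  if (format == "hdf5") return(write_bundle_hdf5(record, path))
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
    stopf("cannot create bundle directory %s", path)
  dir.create(file.path(path, "sweeps"), showWarnings = FALSE)
  files <- sprintf("sweeps/%s.csv", vapply(record$sweeps, `[[`, character(1),
                                           "sweep_id"))
  for (i in seq_along(record$sweeps)) {
    s <- record$sweeps[[i]]
    con <- file(file.path(path, files[i]), "wb")
    writeLines(c("voltage,current",
                 paste(fmt_series(s$voltage), fmt_series(s$current), sep = ",")),
               con)
    close(con)
  }
  manifest <- list(
    container = "gcio-bundle", version = "1",
    cell = list(cell_id = record$cell_id, animal_id = record$animal_id,
                age_days = record$age_days, labeled = record$labeled,
                notes = record$notes),
    sweeps = unname(Map(sweep_meta, record$sweeps, files)))
  json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, null = "null")
  con <- file(file.path(path, "manifest.json"), "wb")
  writeLines(json, con)
  close(con)
  invisible(path)
}

#' Read a cell record from disk
#'
#' Units are normalized to mV/pA/kHz; protocol descriptors and record
#' invariants are re-validated on read, so a malformed bundle (missing units,
#' unknown protocol kind, off-grid sinusoid frequency, truncated series) is a
#' hard error naming the offending sweep.
#'
#' @param path bundle directory (csv_json) or `.h5` file (hdf5).
#' @param format `"csv_json"`, `"hdf5"`, or `"nwb"` (not supported; errors).
#' @return a [cell_record()].
#' @export
read_cell_bundle <- function(path, format = c("csv_json", "hdf5", "nwb")) {
  format <- match.arg(format)
  if (format == "nwb")
    stopf("NWB import is not supported in this build; convert to the csv_json bundle dialect")
  if (format == "hdf5") return(read_bundle_hdf5(path))
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stopf("no manifest.json under %s", path)
  manifest <- jsonlite::fromJSON(mf, simplifyVector = FALSE)
  cellm <- manifest$cell
  sweeps <- lapply(manifest$sweeps, function(m) {
    id <- m$sweep_id %||% "<unnamed>"
    if (is.null(m$protocol$kind) || !(m$protocol$kind %in% PROTOCOL_KINDS))
      stopf("sweep %s: unknown protocol kind '%s'", id,
            m$protocol$kind %||% "<missing>")
    fv <- unit_factor("voltage", m$units$voltage, id)
    fc <- unit_factor("current", m$units$current, id)
    fr <- unit_factor("sample_rate", m$units$sample_rate, id)
    tab <- utils::read.csv(file.path(path, m$file), colClasses = "numeric")
    if (!is.null(m$n_samples) && nrow(tab) != m$n_samples)
      stopf("sweep %s: truncated series (%d samples on disk, %d declared)",
            id, nrow(tab), m$n_samples)
    proto <- protocol_descriptor(m$protocol$kind, m$protocol$amplitude,
                                 frequency = m$protocol$frequency,
                                 duration_ms = m$protocol$duration_ms,
                                 onset_ms = m$protocol$onset_ms,
                                 holding = m$protocol$holding %||% 0)
    new_sweep(id, m$clamp_mode, m$sample_rate * fr, tab$voltage * fv,
              tab$current * fc, proto,
              baseline_window = as.numeric(unlist(m$baseline_window)))
  })
  cell_record(cellm$cell_id, cellm$animal_id %||% NA_character_,
              age_days = cellm$age_days %||% NA, labeled = isTRUE(cellm$labeled),
              sweeps = sweeps, notes = cellm$notes %||% "")
}

write_bundle_hdf5 <- function(record, path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stopf("format 'hdf5' requires the rhdf5 package; use format 'csv_json'")
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  h5meta <- list(cell_id = record$cell_id, animal_id = record$animal_id,
                 age_days = record$age_days, labeled = as.integer(record$labeled),
                 notes = record$notes)
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  for (nm in names(h5meta))
    if (!is.na(h5meta[[nm]])) rhdf5::h5writeAttribute(h5meta[[nm]], fid, nm)
  rhdf5::H5Gclose(rhdf5::H5Gcreate(fid, "sweeps"))
  for (s in record$sweeps) {
    g <- sprintf("sweeps/%s", s$sweep_id)
    gid <- rhdf5::H5Gcreate(fid, g)
    rhdf5::h5writeDataset(s$voltage, gid, "voltage")
    rhdf5::h5writeDataset(s$current, gid, "current")
    meta <- sweep_meta(s, NULL)
    att <- c(meta[c("clamp_mode", "sample_rate")], meta$protocol,
             list(units_voltage = "mV", units_current = "pA",
                  units_sample_rate = "kHz",
                  baseline_from = s$baseline_window[1],
                  baseline_to = s$baseline_window[2]))
    for (nm in names(att))
      if (!is.null(att[[nm]])) rhdf5::h5writeAttribute(att[[nm]], gid, nm)
    rhdf5::H5Gclose(gid)
  }
  invisible(path)
}

read_bundle_hdf5 <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stopf("format 'hdf5' requires the rhdf5 package")
  if (!file.exists(path)) stopf("no such file: %s", path)
  drop_dims <- function(a) lapply(a, function(x) if (is.array(x)) as.vector(x) else x)
  top <- drop_dims(rhdf5::h5readAttributes(path, "/"))
  ids <- rhdf5::h5ls(path, recursive = 2)
  ids <- ids$name[ids$group == "/sweeps" & ids$otype == "H5I_GROUP"]
  sweeps <- lapply(ids, function(id) {
    g <- sprintf("/sweeps/%s", id)
    a <- drop_dims(rhdf5::h5readAttributes(path, g))
    fv <- unit_factor("voltage", a$units_voltage, id)
    fc <- unit_factor("current", a$units_current, id)
    fr <- unit_factor("sample_rate", a$units_sample_rate, id)
    if (is.null(a$kind) || !(a$kind %in% PROTOCOL_KINDS))
      stopf("sweep %s: unknown protocol kind '%s'", id, a$kind %||% "<missing>")
    proto <- protocol_descriptor(a$kind, a$amplitude,
                                 frequency = a$frequency,
                                 duration_ms = a$duration_ms,
                                 onset_ms = a$onset_ms, holding = a$holding %||% 0)
    new_sweep(id, a$clamp_mode, a$sample_rate * fr,
              as.numeric(rhdf5::h5read(path, paste0(g, "/voltage"))) * fv,
              as.numeric(rhdf5::h5read(path, paste0(g, "/current"))) * fc,
              proto, baseline_window = c(a$baseline_from, a$baseline_to))
  })
  cell_record(top$cell_id, top$animal_id %||% NA_character_,
              age_days = top$age_days %||% NA,
              labeled = isTRUE(top$labeled == 1L), sweeps = sweeps,
              notes = top$notes %||% "")
}
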