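# CSV history schema: one file per quantity, first line a '# units: si'
# comment, then a fixed column layout. A JSON run manifest accompanies the
# CSVs. Outputs are bit-stable for identical inputs.

write_csv_units <- function(df, path, units = "si") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# units: %s", units), con)
  utils::write.csv(df, con, row.names = FALSE)
}

read_csv_units <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Write run histories and manifest to a directory
#'
#' Emits `stress.csv`, `strain.csv` (time, element, 6 Voigt components),
#' `volume.csv`, `nodes.csv` (displacements/velocities/internal forces),
#' `contact.csv`, `energy.csv`, `elements.csv` (id, part, label, side,
#' reference volume) and `manifest.json` (time step policy, cycles, added
#' mass absolute and percent, termination status, seed, unit system).
#' Error-terminated runs still write their partial histories.
#'
#' @param run An `fe_run`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_histories <- function(run, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    ff_stop("foamfem_io_error", "cannot create directory '%s'", dir)
  }
  nf <- length(run$time); E <- dim(run$element$stress)[2]
  idx <- expand.grid(frame = seq_len(nf), element = seq_len(E))
  voigt <- c("xx", "yy", "zz", "xy", "yz", "zx")
  flat <- function(a, prefix) {
    m <- matrix(a, nf * E, 6L)
    colnames(m) <- paste0(prefix, "_", voigt)
    data.frame(time = run$time[idx$frame], element = idx$element, m)
  }
  write_csv_units(flat(run$element$stress, "s"), file.path(dir, "stress.csv"))
  write_csv_units(flat(run$element$strain, "e"), file.path(dir, "strain.csv"))
  write_csv_units(data.frame(time = run$time[idx$frame], element = idx$element,
                             volume = as.vector(run$element$volume)),
                  file.path(dir, "volume.csv"))
  N <- dim(run$node$u)[2]
  nidx <- expand.grid(frame = seq_len(nf), node = seq_len(N))
  nd <- data.frame(time = run$time[nidx$frame], node = nidx$node)
  for (q in c("u", "v", "f_int")) {
    m <- matrix(run$node[[q]], nf * N, 3L)
    colnames(m) <- paste0(q, c("x", "y", "z"))
    nd <- cbind(nd, m)
  }
  write_csv_units(nd, file.path(dir, "nodes.csv"))
  write_csv_units(run$contact, file.path(dir, "contact.csv"))
  write_csv_units(run$energy, file.path(dir, "energy.csv"))
  mesh <- run$mesh; meta <- run$model$part_meta
  lbl <- meta$label[match(mesh$part, meta$part)]
  sde <- meta$side[match(mesh$part, meta$part)]
  write_csv_units(data.frame(element = seq_len(E), part = mesh$part,
                             label = ifelse(is.na(lbl), "other", lbl),
                             side = ifelse(is.na(sde), "center", sde),
                             volume = mesh$volumes),
                  file.path(dir, "elements.csv"))
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(dir)
}

#' Read element histories back from a history directory
#'
#' @param dir Directory written by [write_histories()] (or externally
#'   supplied files following the same schema).
#' @return List of [element_history()] objects; attribute `"contact"`
#'   holds the contact data frame if present.
#' @export
read_histories <- function(dir) {
  stress <- read_csv_units(file.path(dir, "stress.csv"))
  strain <- read_csv_units(file.path(dir, "strain.csv"))
  vols <- read_csv_units(file.path(dir, "elements.csv"))
  hs <- lapply(vols$element, function(e) {
    si <- stress[stress$element == e, , drop = FALSE]
    ei <- strain[strain$element == e, , drop = FALSE]
    element_history(id = e, time = si$time,
                    stress = as.matrix(si[, 3:8]),
                    strain = as.matrix(ei[, 3:8]),
                    volume = vols$volume[vols$element == e],
                    part = vols$part[vols$element == e],
                    label = vols$label[vols$element == e],
                    side = vols$side[vols$element == e])
  })
  cpath <- file.path(dir, "contact.csv")
  if (file.exists(cpath)) attr(hs, "contact") <- read_csv_units(cpath)
  hs
}

#' Read a risk curve from a 2-column CSV (force, probability)
#'
#' @param path CSV path; a header line is expected.
#' @param label Curve label.
#' @return A [risk_curve()].
#' @export
read_risk_curve <- function(path, label = basename(path)) {
  df <- utils::read.csv(path, comment.char = "#")
  risk_curve(df[[1]], df[[2]], label = label)
}

#' Read a load curve from a 2-column CSV (strain, stress)
#'
#' @param path CSV path.
#' @param sfo Ordinate scale factor.
#' @param stress_unit Multiplier applied to the stress column to reach Pa.
#' @return A [load_curve()].
#' @export
read_load_curve <- function(path, sfo = 1, stress_unit = 1) {
  df <- utils::read.csv(path, comment.char = "#")
  load_curve(df[[1]], df[[2]] * stress_unit, sfo = sfo)
}
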