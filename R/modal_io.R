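## ModalSolution persistence --------------------------------------------------

#' Write a modal solution to HDF5
#'
#' Datasets `frequencies_hz`, `shapes` (3N x k), `omega2`, `residuals`,
#' `free_dofs`; provenance entries become root attributes.
#'
#' @param solution a [solve_modes()] result.
#' @param path output `.h5` file (overwritten).
#' @return `path`, invisibly.
#' @export
write_modal_h5 <- function(solution, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(solution$frequencies_hz, path, "frequencies_hz")
  rhdf5::h5write(solution$shapes, path, "shapes")
  rhdf5::h5write(solution$omega2, path, "omega2")
  rhdf5::h5write(solution$residuals, path, "residuals")
  rhdf5::h5write(solution$free_dofs, path, "free_dofs")
  rhdf5::h5write(solution$n_nodes, path, "n_nodes")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid))
  prov <- solution$provenance
  for (nm in names(prov)) {
    val <- prov[[nm]]
    if (is.atomic(val) && length(val) == 1L && !is.logical(val))
      rhdf5::h5writeAttribute(val, fid, nm)
    else rhdf5::h5writeAttribute(
      as.character(jsonlite::toJSON(val, auto_unbox = TRUE, force = TRUE)),
      fid, nm)
  }
  rhdf5::h5writeAttribute(solution$ortho_error, fid, "ortho_error")
  invisible(path)
}

#' Read a modal solution from HDF5
#'
#' @param path file written by [write_modal_h5()].
#' @return a `modal_solution`.
#' @export
read_modal_h5 <- function(path) {
  if (!file.exists(path)) stop2("file not found: %s", path)
  freqs <- as.numeric(rhdf5::h5read(path, "frequencies_hz"))
  shapes <- rhdf5::h5read(path, "shapes")
  omega2 <- as.numeric(rhdf5::h5read(path, "omega2"))
  resid <- as.numeric(rhdf5::h5read(path, "residuals"))
  free <- as.integer(rhdf5::h5read(path, "free_dofs"))
  nn <- as.integer(rhdf5::h5read(path, "n_nodes"))
  fid <- rhdf5::H5Fopen(path)
  attrs <- rhdf5::h5readAttributes(fid, "/")
  rhdf5::H5Fclose(fid)
  ortho <- attrs$ortho_error %||% NA_real_
  attrs$ortho_error <- NULL
  prov <- lapply(attrs, function(a) {
    if (is.array(a)) a <- as.vector(a)
    if (is.character(a) && length(a) == 1L && grepl("^[\\[{]", a))
      jsonlite::fromJSON(a) else a
  })
  structure(list(frequencies_hz = freqs, shapes = shapes, omega2 = omega2,
                 residuals = resid, ortho_error = as.numeric(ortho),
                 free_dofs = free, n_nodes = nn, provenance = prov),
            class = "modal_solution")
}

#' Write the frequencies-only CSV of one or more solutions
#'
#' Columns: solution, mode_index, frequency_hz, scale, plus one column per
#' material-region tag (density/E) when present in the provenance.
#'
#' @param solutions a `modal_solution` or list of them.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_frequencies_csv <- function(solutions, path) {
  if (inherits(solutions, "modal_solution")) solutions <- list(solutions)
  rows <- lapply(seq_along(solutions), function(i) {
    s <- solutions[[i]]
    d <- data.frame(solution = i,
                    mode_index = seq_along(s$frequencies_hz),
                    frequency_hz = s$frequencies_hz,
                    scale = s$provenance$scale %||% 1)
    mats <- s$provenance$materials
    if (!is.null(mats)) {
      for (r in names(mats)) {
        d[[paste0(r, "_rho")]] <- mats[[r]]$density
        d[[paste0(r, "_E")]] <- mats[[r]]$young_modulus
      }
    }
    d
  })
  # align columns across solutions
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(d) {
    for (c_ in setdiff(cols, names(d))) d[[c_]] <- NA
    d[, cols]
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write a mode-match report to CSV and JSON
#'
#' @param report a [match_modes()] result.
#' @param path_csv,path_json output files (either may be NULL).
#' @return invisibly, the report.
#' @export
write_match_report <- function(report, path_csv = NULL, path_json = NULL) {
  if (!is.null(path_csv))
    utils::write.csv(report$matches, path_csv, row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(
      list(matches = report$matches,
           unmatched_peaks_hz = report$unmatched_peaks_hz,
           tolerance_pct = report$tolerance_pct),
      path_json, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(report)
}
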