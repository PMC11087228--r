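#' @title Plain-text input/output
#' @name doepath-io
#' @description Designs and strain libraries travel as CSV files with a JSON
#'   sidecar recording provenance (generators, seeds, noise specification);
#'   kinetic parameter sets travel as a long-format CSV
#'   (reaction_id, parameter, value, units). All readers accept files written
#'   by the corresponding writer.
NULL

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write / read a design
#'
#' @param design A `doe_design`.
#' @param path CSV destination; a `.json` sidecar with the provenance is
#'   written next to it.
#' @return `read_design` returns a `doe_design`.
#' @export
write_design <- function(design, path) {
  utils::write.csv(as.data.frame(design_matrix(design)), path,
                   row.names = FALSE)
  jsonlite::write_json(design$provenance, sidecar_path(path), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  m <- as.matrix(utils::read.csv(path, check.names = FALSE))
  prov <- if (file.exists(sidecar_path(path)))
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  else list(type = "imported")
  new_design(m, colnames(m), prov)
}

#' Write / read a strain library
#'
#' CSV columns: one per factor (coded -1/+1), `truth_mM`, then `rep_1..rep_n`;
#' the noise specification and seed go to the JSON sidecar.
#'
#' @param library A `strain_library`.
#' @param path CSV destination.
#' @return `read_library` returns a `strain_library`.
#' @export
write_library <- function(library, path) {
  reps <- library$replicates
  colnames(reps) <- paste0("rep_", seq_len(ncol(reps)))
  df <- cbind(as.data.frame(library$strains),
              data.frame(truth_mM = library$truth), as.data.frame(reps))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(sigma = library$noise$sigma,
                            n_reps = library$noise$n_reps,
                            distribution = library$noise$distribution,
                            seed = library$seed),
                       sidecar_path(path), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  fac <- names(df)[!grepl("^(truth_mM|rep_)", names(df))]
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  structure(list(strains = as.matrix(df[fac]),
                 truth = df$truth_mM,
                 replicates = as.matrix(df[grepl("^rep_", names(df))]),
                 noise = noise_spec(side$sigma, side$n_reps),
                 seed = if (is.null(side$seed)) NA_integer_ else
                   as.integer(side$seed)),
            class = "strain_library")
}

#' Write / read kinetic parameters
#'
#' Long-format CSV: `reaction_id` (the prefix before the first dot of the
#' parameter name, e.g. `FCS` for `FCS.Km.CUA`), `parameter` (full name),
#' `value`, `units`.
#'
#' @param params Named numeric vector as in [default_kinetic_parameters()].
#' @param path CSV destination.
#' @return `read_kinetic_parameters` returns the named numeric vector, ready
#'   for [build_default_model()].
#' @export
write_kinetic_parameters <- function(params, path) {
  units <- function(nm) {
    if (grepl("\\.Km\\.|Km\\.", nm)) "mM"
    else if (grepl("kcat", nm)) "1/h"
    else if (nm == "C3H.k") "1/(mM*h)"
    else if (nm == "sim.horizon") "h"
    else "mM"
  }
  df <- data.frame(reaction_id = sub("\\..*$", "", names(params)),
                   parameter = names(params),
                   value = as.numeric(params),
                   units = vapply(names(params), units, ""))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinetic_parameters
#' @export
read_kinetic_parameters <- function(path) {
  df <- utils::read.csv(path)
  stats::setNames(df$value, df$parameter)
}

#' Write a frequency table
#'
#' @param freq A `frequency_table`.
#' @param path CSV destination.
#' @export
write_frequency_table <- function(freq, path) {
  utils::write.csv(as.data.frame(freq), path, row.names = FALSE)
  invisible(path)
}
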