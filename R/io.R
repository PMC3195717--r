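#' Write an energy trace as delimited text
#'
#' Layout: leading `#meta` comment lines carrying the metadata block as
#' JSON, then a header row `residue` + frame times in fs, then one row
#' per residue (index followed by its energies in kcal/mol).
#'
#' @param trace an `energy_trace`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_trace <- function(trace, path) {
  meta <- jsonlite::toJSON(trace$metadata, auto_unbox = TRUE,
                           digits = NA, null = "null")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#meta ", meta), con)
  writeLines(paste(c("residue", format(trace$times, trim = TRUE,
                                       scientific = FALSE)),
                   collapse = "\t"), con)
  m <- cbind(seq_len(nrow(trace$energies)), trace$energies)
  utils::write.table(m, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an energy trace written by [write_trace()]
#' @param path input file.
#' @return an `energy_trace`.
#' @export
read_trace <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#meta ", lines)
  metadata <- if (length(meta_lines)) {
    jsonlite::fromJSON(sub("^#meta ", "", lines[meta_lines[1]]),
                       simplifyVector = TRUE)
  } else list()
  body <- lines[!startsWith(lines, "#")]
  ed_assert(length(body) >= 2, "enerdiss_format_error",
            "trace file has no data rows")
  times <- as.numeric(strsplit(body[1], "\t", fixed = TRUE)[[1]][-1])
  dat <- utils::read.table(text = body[-1], sep = "\t")
  energy_trace(times, as.matrix(dat[, -1, drop = FALSE]),
               metadata = metadata)
}

#' Write a response profile (residue index, response time)
#'
#' Two-column tab-separated text; nonresponsive residues get "NA".
#' @param profile a `response_profile`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_profile <- function(profile, path) {
  policy <- attr(profile, "policy")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#meta ", jsonlite::toJSON(
    list(perturbed = attr(profile, "perturbed"),
         policy = if (!is.null(policy)) unclass(policy)),
    auto_unbox = TRUE, digits = NA, null = "null")), con)
  writeLines("residue\tresponse_time_fs", con)
  utils::write.table(
    data.frame(seq_along(profile), as.numeric(profile)),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a two-column curve (dissipation or difference)
#' @param curve a `dissipation_curve` or `difference_curve`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_curve <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a two-column curve
#' @param path input file with a header row naming the columns
#'   (`t` plus `NR` or `dNR`).
#' @return a `dissipation_curve` or `difference_curve` depending on the
#'   second column's name.
#' @export
read_curve <- function(path) {
  dat <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#")
  ed_assert(ncol(dat) >= 2, "enerdiss_format_error",
            "curve file needs two columns")
  if ("dNR" %in% names(dat)) {
    structure(data.frame(t = dat$t, dNR = dat$dNR),
              class = c("difference_curve", "data.frame"))
  } else {
    structure(data.frame(t = dat[[1]], NR = dat[[2]]),
              class = c("dissipation_curve", "data.frame"))
  }
}

#' Write a module-region table in wide layout
#' @param tab a `module_region_table` (or plain matrix).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_module_table <- function(tab, path) {
  df <- data.frame(region = rownames(tab), unclass(tab)[, , drop = FALSE],
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
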