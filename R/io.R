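detect_sep <- function(path) {
  first <- readLines(path, n = 50)
  first <- first[!startsWith(first, "#")][1]
  if (grepl(",", first) && !grepl("\t", first)) "," else "\t"
}

read_table_checked <- function(path, required, what) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                          comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("%s (%s): missing column(s) %s", what, path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  df
}

header_value <- function(path, key) {
  hdr <- grep("^#", readLines(path, n = 50), value = TRUE)
  hit <- grep(paste0("^#\\s*", key, "\\s"), hdr, value = TRUE)
  if (length(hit) == 0L) return(NULL)
  as.numeric(strsplit(trimws(sub(paste0("^#\\s*", key), "", hit[1])),
                      "\\s+")[[1]][1])
}

#' Read / write a calorimetric enthalpy curve
#'
#' TSV/CSV dialect with a header row containing `temperature_K` and
#' `delta_H_kJ_per_mol` (optionally `sigma`); `#` lines are comments.
#'
#' @param path File path.
#' @return `read_itc_curve`: an [itc_curve()]. `write_itc_curve`: `path`,
#'   invisibly.
#' @export
read_itc_curve <- function(path) {
  df <- read_table_checked(path, c("temperature_K", "delta_H_kJ_per_mol"),
                           "ITC curve")
  itc_curve(df$temperature_K, df$delta_H_kJ_per_mol,
            sigma = if ("sigma" %in% names(df)) df$sigma else NULL)
}

#' @rdname read_itc_curve
#' @param curve An [itc_curve()].
#' @export
write_itc_curve <- function(curve, path) {
  df <- data.frame(temperature_K = curve$temperature,
                   delta_H_kJ_per_mol = curve$delta_h)
  if ("sigma" %in% names(curve)) df$sigma <- curve$sigma
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a chemical depolymerisation curve
#'
#' TSV/CSV with header columns `denaturant_M` and `fraction_monomer`.  The
#' total protein concentration and temperature are taken from `#`-comment
#' header lines (`# total_conc_M <value>`, `# temperature_K <value>`) or
#' from the arguments, which take precedence.
#'
#' @param path File path.
#' @param total_conc Total protein concentration, M (overrides the header).
#' @param temperature Temperature, K (overrides the header).
#' @return `read_depoly_curve`: a [depoly_curve()]. `write_depoly_curve`:
#'   `path`, invisibly.
#' @export
read_depoly_curve <- function(path, total_conc = NULL, temperature = NULL) {
  df <- read_table_checked(path, c("denaturant_M", "fraction_monomer"),
                           "depolymerisation curve")
  mt <- total_conc %||% header_value(path, "total_conc_M")
  if (is.null(mt))
    stop("total protein concentration not given (argument or header line ",
         "'# total_conc_M <value>')", call. = FALSE)
  temp <- temperature %||% header_value(path, "temperature_K") %||% 298.15
  depoly_curve(df$denaturant_M, df$fraction_monomer, mt, temp)
}

#' @rdname read_depoly_curve
#' @param curve A [depoly_curve()].
#' @export
write_depoly_curve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# total_conc_M %.8g", attr(curve, "total_conc")),
               sprintf("# temperature_K %.8g", attr(curve, "temperature")),
               "denaturant_M\tfraction_monomer"), con)
  writeLines(sprintf("%.10g\t%.10g", curve$denaturant,
                     curve$fraction_monomer), con)
  invisible(path)
}

#' Write sampled trajectories as TSV
#'
#' @param run An `mc_samples` object.
#' @param path Output file; a `#` header records the seed and parameters.
#' @return `path`, invisibly.
#' @export
write_samples <- function(run, path) {
  stopifnot(inherits(run, "mc_samples"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# fibrilMC samples: seed %d, alpha %g, T0 %g, sweeps %d",
    run$config$rng_seed, run$hparams$alpha, run$hparams$t0,
    run$config$sweeps), con)
  utils::write.table(run$samples, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
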