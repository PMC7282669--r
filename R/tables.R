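#' Interaction tables of the lattice Hamiltonian
#'
#' Bundles the pairwise amino-acid contact energies, the per-residue solvent
#' interaction energies, the hydrogen-bond strength, the beta-strand
#' propensity and the side-chain steric penalty.  Hydrophobic residues are,
#' by definition of the model, exactly those with a positive solvent
#' interaction energy.
#'
#' @param pair Symmetric 20 x 20 numeric matrix of contact energies
#'   (reduced units per contact), rows/columns named by the one-letter codes
#'   `ACDEFGHIKLMNPQRSTVWY`.
#' @param solvent Named numeric vector of length 20: `epsilon_{a,solv}`,
#'   positive for the nine hydrophobic residue types.
#' @param eps_hb Energy per hydrogen bond (`<= 0` for favourable bonds).
#' @param n_beta Beta-strand propensity `N_beta >= 1`; each residue in the
#'   beta state pays the temperature-independent entropy penalty
#'   `log(n_beta)`.
#' @param steric_penalty Energy added for each pair of side chains pointing
#'   at the same lattice site.
#' @return An object of class `interaction_tables`.
#' @export
interaction_tables <- function(pair, solvent, eps_hb = -1,
                               n_beta = exp(1), steric_penalty = 2) {
  stopifnot(is.matrix(pair), dim(pair) == c(20L, 20L),
            length(solvent) == 20L, n_beta >= 1, is.numeric(steric_penalty))
  if (max(abs(pair - t(pair))) > 1e-12)
    stop("pair-energy table must be symmetric", call. = FALSE)
  if (is.null(rownames(pair))) rownames(pair) <- colnames(pair) <- AA_ALPHABET
  if (is.null(names(solvent))) names(solvent) <- AA_ALPHABET
  pair <- pair[AA_ALPHABET, AA_ALPHABET]
  solvent <- solvent[AA_ALPHABET]
  bad <- HYDROPHOBIC_SET[solvent[HYDROPHOBIC_SET] <= 0]
  if (length(bad))
    stop("hydrophobic residue(s) with non-positive solvent energy: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(pair = pair, solvent = solvent, eps_hb = eps_hb,
                 n_beta = n_beta, steric_penalty = steric_penalty),
            class = "interaction_tables")
}

#' @export
print.interaction_tables <- function(x, ...) {
  cat(sprintf(
    "Interaction tables: eps_hb = %g, N_beta = %g, steric penalty = %g\n",
    x$eps_hb, x$n_beta, x$steric_penalty))
  cat(sprintf("  eps_FF = %g, eps_LL = %g, eps_F,solv = %g\n",
              x$pair["F", "F"], x$pair["L", "L"], x$solvent["F"]))
  invisible(x)
}

#' Default interaction tables shipped with the package
#'
#' Reads the plain-text parameter files under `inst/extdata`: a 20 x 20
#' contact-energy matrix derived from an octanol-water side-chain transfer
#' hydrophobicity scale (so that `eps_FF < eps_LL < 0`), a 20-entry solvent
#' vector positive exactly for the nine hydrophobic residue types, and the
#' scalar parameters.  The scale factors were calibrated once so that the
#' default TFTFTFT fibril is stable over an intermediate temperature window
#' with heat denaturation near reduced `T ~ 0.4` when the hydrophobic
#' temperature dependence is switched off; the files are editable and can be
#' overridden per argument.
#'
#' @param pair_file,solvent_file,params_file Optional overriding file paths;
#'   defaults to the shipped files.
#' @return An [interaction_tables()] object.
#' @export
default_tables <- function(pair_file = NULL, solvent_file = NULL,
                           params_file = NULL) {
  pf <- pair_file %||% system.file("extdata", "pair_energies.tsv",
                                   package = "fibrilMC", mustWork = TRUE)
  sf <- solvent_file %||% system.file("extdata", "solvent_energies.tsv",
                                      package = "fibrilMC", mustWork = TRUE)
  kf <- params_file %||% system.file("extdata", "default_params.txt",
                                     package = "fibrilMC", mustWork = TRUE)
  pair <- as.matrix(utils::read.table(pf, header = TRUE, row.names = 1,
                                      comment.char = "#", check.names = FALSE))
  sv <- utils::read.table(sf, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  solvent <- stats::setNames(sv$epsilon_solv, sv$residue)
  kv <- read_params(kf)
  interaction_tables(pair, solvent,
                     eps_hb = kv$eps_hb, n_beta = kv$n_beta,
                     steric_penalty = kv$steric_penalty)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a flat key-value parameter file
#'
#' Lines of the form `key value` (whitespace separated); `#` starts a
#' comment.  Values are converted to numeric where possible.
#'
#' @param path Path to the parameter file.
#' @return A named list.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "[ \t]+")[[1]]
    if (length(parts) < 2L)
      stop(sprintf("%s: malformed parameter line %d: '%s'", path, i,
                   lines[i]), call. = FALSE)
    val <- suppressWarnings(as.numeric(parts[2]))
    out[[parts[1]]] <- if (is.na(val)) parts[2] else val
  }
  out
}
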