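DIR_LABELS <- c("+x", "-x", "+y", "-y", "+z", "-z")
DIR_VECS <- rbind(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
                  c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L))

new_chain <- function(pos, dir, beta, frozen) {
  storage.mode(pos) <- "integer"
  list(pos = pos, dir = as.integer(dir), beta = as.logical(beta),
       frozen = isTRUE(frozen))
}

#' Assemble a lattice system from explicit chains
#'
#' Low-level constructor used by [build_seed()] and by tests that need toy
#' systems.  Every chain shares the same sequence; coordinates are 0-based
#' integers inside a hard-wall cubic box.
#'
#' @param sequence A [peptide_sequence()] shared by all chains.
#' @param chains List of chains, each a list with `pos` (n x 3 integer matrix),
#'   `dir` (integer side-chain directions, 0..5 meaning +x,-x,+y,-y,+z,-z),
#'   `beta` (logical beta-strand flags) and `frozen` (logical scalar).
#' @param box Edge length of the cubic box (sites per edge).
#' @param native_max Number of in-register contacts in the fully docked
#'   reference, used to normalise the native fraction (`NA` if undefined).
#' @return An object of class `lattice_system`.
#' @export
lattice_system <- function(sequence, chains, box, native_max = NA_real_) {
  stopifnot(inherits(sequence, "peptide_sequence"), box >= 3)
  sys <- structure(list(sequence = sequence, chains = chains,
                        box = as.integer(box), native_max = native_max),
                   class = "lattice_system")
  validate_system(sys)
  sys
}

#' @export
print.lattice_system <- function(x, ...) {
  nf <- sum(!vapply(x$chains, `[[`, logical(1), "frozen"))
  cat(sprintf(
    "Lattice system: %d chains (%d frozen seed, %d free), sequence %s, box %d^3\n",
    length(x$chains), length(x$chains) - nf, nf,
    paste(x$sequence$residues, collapse = ""), x$box))
  op <- order_params(x)
  cat(sprintf("  C_ext = %d, native contacts = %d, exposed hydrophobic = %d\n",
              op$c_ext, op$native_contacts, op$c_h_exposed))
  invisible(x)
}

sys_arrays <- function(system) {
  L <- length(system$sequence)
  nch <- length(system$chains)
  pos <- do.call(rbind, lapply(system$chains, `[[`, "pos"))
  list(pos = pos,
       dir = unlist(lapply(system$chains, `[[`, "dir")),
       beta = unlist(lapply(system$chains, `[[`, "beta")),
       chain = rep(seq_len(nch) - 1L, each = L),
       frozen = vapply(system$chains, `[[`, logical(1), "frozen"),
       aa = rep(aa_index0(system$sequence$residues), nch),
       box = system$box)
}

#' Validate the geometric invariants of a lattice system
#'
#' Checks chain connectivity (consecutive residues on adjacent sites), global
#' self-avoidance, box containment and side-chain direction codes; stops with
#' a descriptive error on the first violation.
#'
#' @param system A [lattice_system()].
#' @return `TRUE`, invisibly.
#' @export
validate_system <- function(system) {
  stopifnot(inherits(system, "lattice_system"))
  L <- length(system$sequence)
  all_pos <- NULL
  for (ci in seq_along(system$chains)) {
    ch <- system$chains[[ci]]
    if (nrow(ch$pos) != L || length(ch$dir) != L || length(ch$beta) != L)
      stop(sprintf("chain %d does not match the sequence length", ci),
           call. = FALSE)
    if (any(ch$pos < 0L) || any(ch$pos >= system$box))
      stop(sprintf("chain %d leaves the simulation box", ci), call. = FALSE)
    if (any(ch$dir < 0L | ch$dir > 5L))
      stop(sprintf("chain %d has an invalid side-chain direction", ci),
           call. = FALSE)
    if (L > 1L) {
      steps <- abs(diff(ch$pos))
      if (any(rowSums(steps) != 1L))
        stop(sprintf("chain %d breaks backbone connectivity", ci),
             call. = FALSE)
    }
    all_pos <- rbind(all_pos, ch$pos)
  }
  key <- all_pos[, 1] + system$box * (all_pos[, 2] + system$box * all_pos[, 3])
  if (anyDuplicated(key))
    stop("two residues occupy the same lattice site", call. = FALSE)
  invisible(TRUE)
}

#' Build a pre-formed fibril seed with two free monomers
#'
#' Constructs the standard simulation setup: a frozen seed of `2 * n_layers`
#' peptides arranged as a double beta-sheet (each layer is two in-register,
#' anti-facing strands whose hydrophobic side chains point into the
#' inter-sheet core; layers stack along the fibril axis), plus two free
#' chains placed in the dissociated monomeric arrangement.  For the default
#' seven-residue peptide and `n_layers = 4` this reproduces the printed
#' order-parameter constants: a fully docked extra layer makes `C_ext = 21`
#' in-register contacts, and docking buries 6 hydrophobic side chains.
#'
#' @param sequence A [peptide_sequence()] (default geometry assumes length 7).
#' @param n_layers Number of seed layers (two chains per layer), `>= 1`.
#' @param box Box edge length; must be large enough to hold seed and
#'   separated free chains.
#' @return A `lattice_system` with `2 * n_layers` frozen chains and 2 free
#'   chains.
#' @examples
#' sys <- build_seed(peptide_sequence("TFTFTFT"))
#' order_params(sys)$c_ext   # 0: free chains start monomeric
#' @export
build_seed <- function(sequence, n_layers = 4, box = 20) {
  stopifnot(inherits(sequence, "peptide_sequence"), n_layers >= 1)
  L <- length(sequence)
  box <- as.integer(box)
  if (box < max(L + 4L, n_layers + 6L))
    stop(sprintf("box edge %d too small to hold the seed and free chains",
                 box), call. = FALSE)
  ox <- (box - L) %/% 2L
  oy <- box %/% 2L - 1L
  z0 <- (box - n_layers - 1L) %/% 2L
  chains <- list()
  for (k in seq_len(n_layers) - 1L) {
    for (j in 0:1) {
      pos <- cbind(ox + seq_len(L) - 1L, oy + j, z0 + k)
      dirs <- rep(if (j == 0L) 2L else 3L, L)  # point into the core
      chains[[length(chains) + 1L]] <-
        new_chain(pos, dirs, rep(TRUE, L), frozen = TRUE)
    }
  }
  # dissociated free chains in opposite corners, side chains exposed
  chains[[length(chains) + 1L]] <-
    new_chain(cbind(1L + seq_len(L) - 1L, 1L, 1L), rep(4L, L),
              rep(FALSE, L), frozen = FALSE)
  chains[[length(chains) + 1L]] <-
    new_chain(cbind(1L + seq_len(L) - 1L, box - 2L, box - 3L), rep(4L, L),
              rep(FALSE, L), frozen = FALSE)
  sys <- lattice_system(sequence, chains, box, native_max = 3 * L)
  if (order_params(sys)$c_ext != 0L)
    stop("box too small: free chains touch the seed in the monomeric layout",
         call. = FALSE)
  sys
}

free_chain_ids <- function(system)
  which(!vapply(system$chains, `[[`, logical(1), "frozen"))

seed_chain_ids <- function(system)
  which(vapply(system$chains, `[[`, logical(1), "frozen"))

#' Reference fibrillar state: both free chains fully docked
#'
#' Places the two free chains as the next in-register layer on top of the
#' seed (along the fibril axis), side chains pointing into the hydrophobic
#' core, beta flags on.  In this configuration the free layer makes 21
#' external contacts (7 to each other + 7 each to the seed layer below) and
#' exposes no hydrophobic side chain.
#'
#' @param system A system from [build_seed()] (seed in constructed
#'   orientation).
#' @return The system with free chains docked; `native fraction = 1`.
#' @export
reference_fibrillar_state <- function(system) {
  stopifnot(inherits(system, "lattice_system"))
  fids <- free_chain_ids(system)
  sids <- seed_chain_ids(system)
  if (length(fids) != 2L || length(sids) < 2L)
    stop("reference docking needs 2 free chains and a seed", call. = FALSE)
  L <- length(system$sequence)
  seed_pos <- do.call(rbind, lapply(system$chains[sids], `[[`, "pos"))
  zmax <- max(seed_pos[, 3])
  top <- seed_pos[seed_pos[, 3] == zmax, , drop = FALSE]
  ys <- sort(unique(top[, 2]))
  ox <- min(top[, 1])
  for (j in 1:2) {
    pos <- cbind(ox + seq_len(L) - 1L, ys[j], zmax + 1L)
    dirs <- rep(if (j == 1L) 2L else 3L, L)
    system$chains[[fids[j]]] <- new_chain(pos, dirs, rep(TRUE, L),
                                          frozen = FALSE)
  }
  validate_system(system)
  system
}

#' Reference monomeric state: free chains dissociated and fully exposed
#'
#' Places both free chains extended, mutually non-contacting and away from
#' the seed, with all side chains pointing at empty sites: `C_ext = 0` and
#' every hydrophobic side chain is solvent exposed.
#'
#' @param system A system from [build_seed()].
#' @return The system with free chains dissociated.
#' @export
reference_monomeric_state <- function(system) {
  stopifnot(inherits(system, "lattice_system"))
  fids <- free_chain_ids(system)
  L <- length(system$sequence)
  box <- system$box
  anchors <- list(c(1L, 1L, 1L), c(1L, box - 2L, box - 3L),
                  c(1L, 1L, box - 3L), c(1L, box - 2L, 1L))
  for (j in seq_along(fids)) {
    a <- anchors[[j]]
    pos <- cbind(a[1] + seq_len(L) - 1L, a[2], a[3])
    system$chains[[fids[j]]] <- new_chain(pos, rep(4L, L), rep(FALSE, L),
                                          frozen = FALSE)
  }
  validate_system(system)
  if (order_params(system)$c_ext != 0L)
    stop("box too small to separate the free chains", call. = FALSE)
  system
}

# solvent-sign vector used only to flag hydrophobic residues in order
# parameters: +1 for the nine hydrophobic types, 0 otherwise
h_flag_vector <- function() as.numeric(AA_ALPHABET %in% HYDROPHOBIC_SET)

#' Order parameters of a configuration
#'
#' * `c_ext`: inter-molecular nearest-neighbour residue contacts involving at
#'   least one free chain;
#' * `native_contacts`: the subset of those that are in-register (equal
#'   residue index), the contacts present in the fully docked layer;
#' * `native_fraction`: `native_contacts` normalised by the system's docked
#'   reference count (21 for the default geometry; `NA` if undefined);
#' * `c_h_exposed`: free-chain hydrophobic side chains pointing at an
#'   unoccupied site.
#'
#' @param system A [lattice_system()].
#' @return A list with components `c_ext`, `native_contacts`,
#'   `native_fraction`, `c_h_exposed`.
#' @export
order_params <- function(system) {
  a <- sys_arrays(system)
  op <- cpp_order_params(a$pos, a$dir, a$beta, a$chain, a$frozen, a$aa,
                         a$box, h_flag_vector())
  op$native_fraction <- if (is.na(system$native_max)) NA_real_
                        else op$native_contacts / system$native_max
  op
}

#' Count external contacts
#'
#' @param system A [lattice_system()].
#' @return Integer count of unordered unit-distance residue pairs belonging
#'   to different molecules, at least one in a free chain.
#' @export
count_external_contacts <- function(system) order_params(system)$c_ext

#' Count solvent-exposed hydrophobic side chains of the free chains
#'
#' @param system A [lattice_system()].
#' @return Integer count of free-chain residues with a hydrophobic side chain
#'   pointing at an unoccupied lattice site.
#' @export
count_exposed_hydrophobic <- function(system) order_params(system)$c_h_exposed

#' Write / read a configuration snapshot
#'
#' Plain-text trajectory format, one residue per line:
#' `chain  index  x  y  z  side_dir  beta  frozen`, with `side_dir` one of
#' `+x -x +y -y +z -z`, preceded by `#`-comment header lines recording the
#' box size and sequence.
#'
#' @param system A [lattice_system()].
#' @param path Output file.
#' @return `write_trajectory`: `path`, invisibly. `read_trajectory`: the
#'   reconstructed `lattice_system`.
#' @export
write_trajectory <- function(system, path) {
  stopifnot(inherits(system, "lattice_system"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fibrilMC configuration"),
               sprintf("# box %d", system$box),
               sprintf("# sequence %s",
                       paste(system$sequence$residues, collapse = "")),
               sprintf("# native_max %g", system$native_max),
               "chain\tindex\tx\ty\tz\tside_dir\tbeta\tfrozen"), con)
  for (ci in seq_along(system$chains)) {
    ch <- system$chains[[ci]]
    for (i in seq_len(nrow(ch$pos)))
      writeLines(sprintf("%d\t%d\t%d\t%d\t%d\t%s\t%d\t%d", ci, i,
                         ch$pos[i, 1], ch$pos[i, 2], ch$pos[i, 3],
                         DIR_LABELS[ch$dir[i] + 1L], as.integer(ch$beta[i]),
                         as.integer(ch$frozen)), con)
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  box <- as.integer(sub("# box ", "", hdr[startsWith(hdr, "# box")]))
  seq_str <- sub("# sequence ", "", hdr[startsWith(hdr, "# sequence")])
  nm <- suppressWarnings(
    as.numeric(sub("# native_max ", "", hdr[startsWith(hdr, "# native_max")])))
  if (length(nm) == 0L) nm <- NA_real_
  df <- utils::read.table(text = lines[!startsWith(lines, "#")], header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  need <- c("chain", "index", "x", "y", "z", "side_dir", "beta", "frozen")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trajectory file misses column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  sequence <- peptide_sequence(seq_str)
  chains <- lapply(split(df, df$chain), function(d) {
    d <- d[order(d$index), ]
    new_chain(cbind(d$x, d$y, d$z), match(d$side_dir, DIR_LABELS) - 1L,
              d$beta == 1, frozen = d$frozen[1] == 1)
  })
  lattice_system(sequence, unname(chains), box, native_max = nm)
}
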