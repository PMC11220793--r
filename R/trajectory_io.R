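# Trajectory container and readers/writers for multi-frame PDB and
# (extended) XYZ, plus the sidecar selection config naming the analysis
# atoms. PDB parsing is delegated to bio3d; XYZ has no installed reader so
# the format is handled here.

ATOMIC_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974, F = 18.998, Cl = 35.45,
                   Br = 79.904, I = 126.904)

element_from_name <- function(name) {
  # strip digits, take leading one- or two-letter element symbol
  sym <- gsub("[^A-Za-z]", "", name)
  two <- paste0(toupper(substr(sym, 1, 1)), tolower(substr(sym, 2, 2)))
  ifelse(two %in% names(ATOMIC_MASSES), two, toupper(substr(sym, 1, 1)))
}

masses_from_elements <- function(elements) {
  m <- ATOMIC_MASSES[elements]
  m[is.na(m)] <- 12.011 # unknown atoms treated as carbon
  unname(m)
}

#' Construct a trajectory object
#'
#' A lightweight multi-frame container: per-frame coordinate matrices plus
#' atom names, masses and named atom selections (0-based indices).
#'
#' @param coordinates List of n_atoms x 3 matrices (angstrom), one per
#'   frame.
#' @param atom_names Character vector of atom names, length n_atoms.
#' @param masses Atomic masses, amu; derived from the atom names when
#'   omitted.
#' @param selections Named list of 0-based integer index vectors (e.g.
#'   `phenyl_dihedral`, `imhb_donor`, `imhb_hydrogen`, `imhb_acceptor`,
#'   `reference_map`).
#' @return A list of class `"trajectory"`.
#' @export
trajectory <- function(coordinates, atom_names, masses = NULL,
                       selections = list()) {
  if (!length(coordinates)) stop_domain("trajectory needs >= 1 frame")
  n_atoms <- nrow(coordinates[[1]])
  ok <- vapply(coordinates, function(f)
    is.matrix(f) && nrow(f) == n_atoms && ncol(f) == 3, logical(1))
  if (!all(ok)) stop_domain("all frames must be n_atoms x 3 matrices")
  if (length(atom_names) != n_atoms)
    stop_domain("atom_names must match the atom count")
  if (is.null(masses))
    masses <- masses_from_elements(element_from_name(atom_names))
  if (length(masses) != n_atoms || any(masses <= 0))
    stop_domain("masses must be positive, one per atom")
  for (nm in names(selections)) {
    idx <- selections[[nm]]
    if (any(idx < 0) || any(idx >= n_atoms))
      stop_domain("selection '%s' has out-of-range indices", nm)
  }
  if (!is.null(selections$phenyl_dihedral) &&
      length(unique(selections$phenyl_dihedral)) != 4)
    stop_domain("phenyl_dihedral must name 4 distinct atoms")
  structure(list(n_frames = length(coordinates), n_atoms = n_atoms,
                 coordinates = coordinates, atom_names = atom_names,
                 masses = masses, selections = selections),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", x$n_frames, "frames x", x$n_atoms, "atoms;",
      "selections:", paste(names(x$selections), collapse = ", "), "\n")
  invisible(x)
}

#' Read a multi-frame trajectory from PDB or XYZ
#'
#' Multi-model PDB files (MODEL/ENDMDL records) are parsed with
#' `bio3d::read.pdb`; `.xyz` files are parsed as concatenated (extended)
#' XYZ frames, each `n` line + comment line + `n` atom lines of
#' `element x y z`.
#'
#' @param path Path to a `.pdb` or `.xyz` file.
#' @param selections Named list of 0-based selections, or a path passed to
#'   [read_selections()].
#' @return A `"trajectory"` object.
#' @export
read_trajectory <- function(path, selections = list()) {
  if (is.character(selections) && length(selections) == 1)
    selections <- read_selections(selections)
  ext <- tolower(tools::file_ext(path))
  if (ext == "xyz") return(read_xyz(path, selections))
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz # n_frames x 3*n_atoms
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_atoms <- ncol(xyz) / 3
  coords <- lapply(seq_len(nrow(xyz)), function(i)
    matrix(xyz[i, ], ncol = 3, byrow = TRUE))
  names_vec <- pdb$atom$elety[seq_len(n_atoms)]
  elements <- pdb$atom$elesy[seq_len(n_atoms)]
  if (is.null(elements) || all(is.na(elements)) || all(elements == ""))
    elements <- element_from_name(names_vec)
  trajectory(coords, names_vec,
             masses = masses_from_elements(elements),
             selections = selections)
}

read_xyz <- function(path, selections = list()) {
  lines <- readLines(path)
  coords <- list(); names_vec <- NULL
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop_domain("malformed XYZ: expected atom count at line %d", i)
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(block), "\\s+")
    frame_names <- vapply(parts, `[`, character(1), 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (is.null(names_vec)) names_vec <- frame_names
    coords[[length(coords) + 1]] <- xyz
    i <- i + 2 + n
  }
  trajectory(coords, names_vec, selections = selections)
}

#' Write a trajectory as concatenated XYZ frames
#'
#' @param traj A `"trajectory"` object.
#' @param path Output path.
#' @param comment Comment written on each frame's second line.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path, comment = "frame") {
  stopifnot(inherits(traj, "trajectory"))
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(traj$n_frames)) {
    fr <- traj$coordinates[[i]]
    writeLines(as.character(traj$n_atoms), con)
    writeLines(sprintf("%s %d", comment, i), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", traj$atom_names,
                       fr[, 1], fr[, 2], fr[, 3]), con)
  }
  invisible(path)
}

#' Read an atom-selection config
#'
#' Plain-text sidecar with one selection per line, `name: i j k ...`,
#' indices 0-based; `#` starts a comment. Recognised names include
#' `phenyl_dihedral` (4 atoms), `imhb_donor`, `imhb_hydrogen`,
#' `imhb_acceptor` (1 atom each) and `reference_map`.
#'
#' @param path Path to the selection file.
#' @return Named list of 0-based integer vectors.
#' @export
read_selections <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop_domain("malformed selection line: '%s'", ln)
    idx <- suppressWarnings(as.integer(strsplit(trimws(kv[2]), "\\s+")[[1]]))
    if (any(is.na(idx)))
      stop_domain("non-integer index in selection '%s'", trimws(kv[1]))
    out[[trimws(kv[1])]] <- idx
  }
  out
}

#' Write an atom-selection config
#'
#' @param selections Named list of 0-based integer vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selections <- function(selections, path) {
  lines <- c("# atom selections (0-based indices)",
             vapply(names(selections), function(nm)
               paste0(nm, ": ", paste(selections[[nm]], collapse = " ")),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}
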