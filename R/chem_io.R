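# molecule input, cube/JSON output, run configuration

#' Create a molecule specification
#'
#' The basic unit of input: element symbols, Cartesian coordinates in
#' Angstrom, total charge and spin multiplicity.
#'
#' @param atoms character vector of element symbols
#' @param coords numeric matrix (n_atoms x 3) of coordinates in Angstrom
#' @param charge integer total charge
#' @param spin_multiplicity integer >= 1 (2S + 1)
#' @param label free-text label
#' @return an object of class `coox_molecule`
#' @export
molecule_spec <- function(atoms, coords, charge = 0L, spin_multiplicity = 1L,
                          label = "") {
  coords <- as.matrix(coords)
  if (is.vector(coords)) coords <- matrix(coords, ncol = 3, byrow = TRUE)
  if (nrow(coords) != length(atoms) || ncol(coords) != 3) {
    stop(errorCondition(
      sprintf("coordinate block (%d x %d) does not match %d atoms",
              nrow(coords), ncol(coords), length(atoms)),
      class = c("coox_count_mismatch", "coox_error")
    ))
  }
  z <- element_number(atoms)
  nelec <- sum(z) - charge
  if (nelec < 0) {
    stop(errorCondition("negative electron count",
                        class = c("coox_bad_charge", "coox_error")))
  }
  if (spin_multiplicity < 1 ||
      (nelec - (spin_multiplicity - 1)) %% 2 != 0) {
    stop(errorCondition(
      sprintf("electron count %d inconsistent with multiplicity %d",
              nelec, spin_multiplicity),
      class = c("coox_bad_multiplicity", "coox_error")
    ))
  }
  structure(
    list(atoms = atoms, coords = coords, charge = as.integer(charge),
         spin_multiplicity = as.integer(spin_multiplicity), label = label,
         atomic_numbers = z, n_electrons = nelec),
    class = "coox_molecule"
  )
}

#' @export
print.coox_molecule <- function(x, ...) {
  cat(sprintf("<molecule '%s': %d atoms, charge %d, multiplicity %d>\n",
              x$label, length(x$atoms), x$charge, x$spin_multiplicity))
  invisible(x)
}

#' Read a molecule from a standard XYZ file
#'
#' @param path file in XYZ layout: atom-count line, comment line, then
#'   `element x y z` rows in Angstrom
#' @param charge,spin_multiplicity electronic state assigned to the geometry
#'   (XYZ itself carries neither)
#' @return a [molecule_spec()]
#' @export
read_xyz <- function(path, charge = 0L, spin_multiplicity = 1L) {
  lines <- readLines(path)
  if (length(lines) < 2) {
    stop(errorCondition("XYZ file has fewer than two lines",
                        class = c("coox_xyz_malformed", "coox_error")))
  }
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) {
    stop(errorCondition(
      sprintf("malformed atom-count line: '%s'", lines[1]),
      class = c("coox_xyz_count", "coox_error")
    ))
  }
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n) {
    stop(errorCondition(
      sprintf("count line promises %d atoms but %d rows follow", n, length(body)),
      class = c("coox_count_mismatch", "coox_error")
    ))
  }
  body <- body[seq_len(n)]
  toks <- strsplit(trimws(body), "[[:space:]]+")
  atoms <- character(n)
  coords <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    tk <- toks[[i]]
    if (length(tk) < 4) {
      stop(errorCondition(
        sprintf("atom row %d has %d fields, expected 4", i, length(tk)),
        class = c("coox_xyz_malformed", "coox_error")
      ))
    }
    atoms[i] <- tk[1]
    xyz <- suppressWarnings(as.numeric(tk[2:4]))
    if (anyNA(xyz)) {
      stop(errorCondition(
        sprintf("cannot parse coordinates on atom row %d: '%s'", i, body[i]),
        class = c("coox_xyz_coord", "coox_error")
      ))
    }
    coords[i, ] <- xyz
  }
  molecule_spec(atoms, coords, charge = charge,
                spin_multiplicity = spin_multiplicity,
                label = trimws(lines[2]))
}

#' Write a molecule (or trajectory frame) in XYZ layout
#'
#' @param molecule a [molecule_spec()]
#' @param path output file; opened in append mode if `append = TRUE`
#' @param comment comment line
#' @param append append as an extra frame (multi-frame XYZ)
#' @export
write_xyz <- function(molecule, path, comment = molecule$label, append = FALSE) {
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(as.character(length(molecule$atoms)), con)
  writeLines(comment, con)
  writeLines(sprintf("%-3s %18.10f %18.10f %18.10f", molecule$atoms,
                     molecule$coords[, 1], molecule$coords[, 2],
                     molecule$coords[, 3]), con)
  invisible(NULL)
}

#' Define a rectilinear volumetric grid
#'
#' @param origin grid origin (Bohr)
#' @param axes 3 x 3 matrix whose rows are the step vectors (Bohr)
#' @param counts integer point counts along the three axes
#' @export
grid_spec <- function(origin, axes, counts) {
  axes <- as.matrix(axes)
  stopifnot(length(origin) == 3, all(dim(axes) == c(3, 3)), length(counts) == 3)
  structure(list(origin = as.numeric(origin), axes = axes,
                 counts = as.integer(counts)),
            class = "coox_grid")
}

#' Default cube-export grid around a molecule
#'
#' @param molecule a [molecule_spec()]
#' @param n points per axis
#' @param margin margin around the nuclei, Bohr
#' @export
default_grid <- function(molecule, n = 80L, margin = 4) {
  xyz <- molecule$coords * BOHR_PER_ANGSTROM
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  step <- (hi - lo) / (n - 1)
  grid_spec(lo, diag(step), rep(as.integer(n), 3))
}

# all grid points, x-outer / z-inner ordering (cube data order)
grid_points <- function(grid) {
  n <- grid$counts
  idx <- as.matrix(expand.grid(k = seq_len(n[3]) - 1, j = seq_len(n[2]) - 1,
                               i = seq_len(n[1]) - 1))
  pts <- cbind(idx[, "i"], idx[, "j"], idx[, "k"]) %*% grid$axes
  sweep(pts, 2, grid$origin, "+")
}

#' Write a scalar field as a Gaussian cube file
#'
#' Coordinates are written in Bohr; the data block runs z fastest.
#'
#' @param field numeric vector, length `prod(grid$counts)`, in cube data order
#' @param molecule a [molecule_spec()]
#' @param grid a [grid_spec()]
#' @param path output path
#' @param comment two header comment lines
#' @export
write_cube <- function(field, molecule, grid, path,
                       comment = c("cooxr volumetric data", "")) {
  if (length(field) != prod(grid$counts)) {
    stop(errorCondition(
      sprintf("field length %d does not match grid (%s)", length(field),
              paste(grid$counts, collapse = "x")),
      class = c("coox_count_mismatch", "coox_error")
    ))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comment[1:2], con)
  nat <- length(molecule$atoms)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", nat,
                     grid$origin[1], grid$origin[2], grid$origin[3]), con)
  for (d in 1:3) {
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f", grid$counts[d],
                       grid$axes[d, 1], grid$axes[d, 2], grid$axes[d, 3]), con)
  }
  xyz <- molecule$coords * BOHR_PER_ANGSTROM
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f",
                     molecule$atomic_numbers, as.numeric(molecule$atomic_numbers),
                     xyz[, 1], xyz[, 2], xyz[, 3]), con)
  # z fastest: emit per (x, y) scanline, 6 values per line
  n <- grid$counts
  arr <- array(field, dim = c(n[3], n[2], n[1]))  # filled z, y, x
  for (i in seq_len(n[1])) {
    for (j in seq_len(n[2])) {
      vals <- arr[, j, i]
      for (s in seq(1, length(vals), by = 6)) {
        chunk <- vals[s:min(s + 5, length(vals))]
        writeLines(paste(sprintf("%13.5E", chunk), collapse = ""), con)
      }
    }
  }
  invisible(NULL)
}

#' Read a Gaussian cube file written by [write_cube()]
#'
#' @param path cube file
#' @return list with `field`, `grid`, atom numbers and positions (Bohr)
#' @export
read_cube <- function(path) {
  lines <- readLines(path)
  num <- function(s) as.numeric(strsplit(trimws(s), "[[:space:]]+")[[1]])
  h <- num(lines[3])
  nat <- as.integer(h[1])
  origin <- h[2:4]
  axes <- matrix(0, 3, 3)
  counts <- integer(3)
  for (d in 1:3) {
    v <- num(lines[3 + d])
    counts[d] <- as.integer(v[1])
    axes[d, ] <- v[2:4]
  }
  atoms <- t(vapply(seq_len(nat), function(i) num(lines[6 + i]), numeric(5)))
  data <- as.numeric(unlist(strsplit(trimws(lines[-(1:(6 + nat))]),
                                     "[[:space:]]+")))
  # stored x-outer, z-fastest; return in the same order write_cube consumes
  list(field = data, grid = grid_spec(origin, axes, counts),
       atomic_numbers = as.integer(atoms[, 1]), positions = atoms[, 3:5])
}

#' Run configuration
#'
#' Bundles the knobs of an excited-state calculation.  The electronic
#' temperature controls the Fermi smearing of the constrained SCF; the
#' commutator norm of `[F, P]` is the SCF convergence measure.
#'
#' @param functional functional label; the built-in backend implements `"hf"`
#' @param basis basis label (built in: `"sto-3g"`)
#' @param temperature electronic temperature in Kelvin
#' @param method one of `"coox"`, `"coox_scaled"`, `"coox_auto"`, `"xcdft"`,
#'   `"tcdft"`
#' @param state_index 1-based target excitation
#' @param spin_channel `"singlet_restricted"`, `"singlet_unrestricted_alpha"`
#'   or `"triplet"`
#' @param tcdft_threshold amplitude cutoff for t-cDFT constraint retention
#' @param scf_conv convergence threshold on the commutator norm
#' @param auto_switch_tol deviation of the excited-electron count from 1 above
#'   which `coox_auto` switches to the scaled constraint
#' @param n_states number of linear-response states to solve for
#' @param seed seed for any stochastic initial guess
#' @param max_iter maximum macro iterations
#' @param verbose emit per-iteration log lines on standard error
#' @return an object of class `coox_config`
#' @export
run_config <- function(functional = "hf", basis = "sto-3g", temperature = 1000,
                       method = c("coox_auto", "coox", "coox_scaled", "xcdft",
                                  "tcdft"),
                       state_index = 1L,
                       spin_channel = c("singlet_restricted",
                                        "singlet_unrestricted_alpha",
                                        "triplet"),
                       tcdft_threshold = 0.1, scf_conv = 1e-7,
                       auto_switch_tol = 0.20, n_states = NULL, seed = 1L,
                       max_iter = 200L, verbose = FALSE) {
  method <- match.arg(method)
  spin_channel <- match.arg(spin_channel)
  if (temperature <= 0) {
    stop(errorCondition("electronic temperature must be positive",
                        class = c("coox_bad_config", "coox_error")))
  }
  if (auto_switch_tol <= 0 || auto_switch_tol >= 1) {
    stop(errorCondition("auto_switch_tol must lie in (0, 1)",
                        class = c("coox_bad_config", "coox_error")))
  }
  if (tcdft_threshold <= 0 || tcdft_threshold > 1) {
    stop(errorCondition("tcdft_threshold must lie in (0, 1]",
                        class = c("coox_bad_config", "coox_error")))
  }
  structure(
    list(functional = functional, basis = basis, temperature = temperature,
         method = method, state_index = as.integer(state_index),
         spin_channel = spin_channel, tcdft_threshold = tcdft_threshold,
         scf_conv = scf_conv, auto_switch_tol = auto_switch_tol,
         n_states = n_states, seed = as.integer(seed),
         max_iter = as.integer(max_iter), verbose = isTRUE(verbose)),
    class = "coox_config"
  )
}

#' Read a run configuration from YAML
#'
#' Field names mirror the arguments of [run_config()].
#'
#' @param path YAML file
#' @param overrides named list taking precedence over the file (CLI flags)
#' @export
read_config_yaml <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

REPORT_SCHEMA_VERSION <- "1"
.report_required <- c("schema_version", "delta_e_ev", "lambda_c", "n_exc",
                      "pct_t1", "pct_t2", "method", "functional", "basis",
                      "spin_type", "scaled_used", "residual",
                      "commutator_norm", "macro_iterations", "converged")

#' Serialize an excitation report to JSON
#'
#' @param report an excitation report (see [excitation_report()])
#' @param path output file
#' @export
report_json <- function(report, path) {
  miss <- setdiff(.report_required, names(report))
  if (length(miss) > 0) {
    stop(errorCondition(
      sprintf("report is missing field(s): %s", paste(miss, collapse = ", ")),
      class = c("coox_report_schema", "coox_error")
    ))
  }
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(NULL)
}

#' Read back a JSON excitation report
#'
#' @param path JSON file written by [report_json()]
#' @export
read_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  miss <- setdiff(.report_required, names(rep))
  if (length(miss) > 0) {
    stop(errorCondition(
      sprintf("report is missing field(s): %s", paste(miss, collapse = ", ")),
      class = c("coox_report_schema", "coox_error")
    ))
  }
  structure(rep, class = "coox_report")
}

#' Path of a shipped fixture geometry
#'
#' The shipped geometries are documented literature structures for small
#' closed-shell molecules; they are handy, reproducible inputs, not the
#' benchmark geometries of any published excitation data set.
#'
#' @param name one of `"h2"`, `"h2o"`, `"ch2o"`, `"c2h4"`, `"benzene"`
#' @export
fixture_path <- function(name) {
  f <- system.file("extdata", paste0(name, ".xyz"), package = "cooxr")
  if (!nzchar(f)) {
    stop(errorCondition(sprintf("no fixture named '%s'", name),
                        class = c("coox_error")))
  }
  f
}

#' Regular H6 ring, an engineered degenerate-frontier-orbital toy
#'
#' A hydrogen hexagon has, like benzene, a doubly degenerate highest occupied
#' and lowest unoccupied level, and exposes the restricted-constraint
#' double-excitation pathology at minimal cost.
#'
#' @param r ring radius in Angstrom
#' @export
molecule_h6_ring <- function(r = 1.0) {
  ang <- 2 * pi * (0:5) / 6
  molecule_spec(rep("H", 6), cbind(r * cos(ang), r * sin(ang), 0),
                label = sprintf("H6 ring r=%.3f A", r))
}
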