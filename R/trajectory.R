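#' Spin trajectory container
#'
#' A `spin_trajectory` holds time-ordered positions of hydrogen nuclei
#' together with the per-nucleus metadata every downstream stage needs:
#' pool membership (water pool "WP" vs macromolecule pool "MP"), molecule
#' grouping, species, and the periodic box if any. Positions are in nm and
#' the sampling interval `dt` in ps; the main magnetic field defines the
#' z-axis of the coordinate frame.
#'
#' @param coords numeric array `n_frames x n_atoms x 3`, positions in nm.
#' @param dt sampling interval in ps (> 0).
#' @param species character vector, one entry per atom (molecule species
#'   tag, e.g. `"SOL"`, `"CHL"`).
#' @param molecule_id integer vector, one entry per atom.
#' @param pool optional character vector per atom, `"WP"`/`"MP"` or `NA`.
#' @param box optional numeric length-3 vector of orthorhombic box edge
#'   lengths in nm; `NULL` for non-periodic trajectories.
#' @param metadata list of free-form metadata (generators record their
#'   ground-truth motional parameters here).
#' @return object of class `spin_trajectory`.
#' @export
spin_trajectory <- function(coords, dt, species = NULL, molecule_id = NULL,
                            pool = NULL, box = NULL, metadata = list()) {
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("coords must be an n_frames x n_atoms x 3 array")
  n_atoms <- dim(coords)[2]
  if (!all(is.finite(coords)))
    stop("coordinates must be finite")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a single positive number (ps)")
  if (is.null(species)) species <- rep("MOL", n_atoms)
  if (is.null(molecule_id)) molecule_id <- seq_len(n_atoms)
  if (is.null(pool)) pool <- rep(NA_character_, n_atoms)
  if (length(species) != n_atoms || length(molecule_id) != n_atoms ||
      length(pool) != n_atoms)
    stop("species, molecule_id and pool must have one entry per atom")
  if (!is.null(box)) {
    if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
      stop("box must be three positive edge lengths (nm)")
    box <- as.numeric(box)
  }
  structure(list(coords = coords, dt = dt,
                 species = as.character(species),
                 molecule_id = as.integer(molecule_id),
                 pool = as.character(pool),
                 box = box, metadata = metadata),
            class = "spin_trajectory")
}

#' @export
print.spin_trajectory <- function(x, ...) {
  cat(sprintf(
    "spin_trajectory: %d frames x %d nuclei, dt = %g ps (%.4g ns total)\n",
    n_frames(x), n_atoms(x), x$dt, duration_ps(x) / 1e3))
  cnt <- pool_counts(x)
  cat(sprintf("  pools: WP = %d, MP = %d, unassigned = %d\n",
              cnt[["WP"]], cnt[["MP"]], cnt[["unassigned"]]))
  if (!is.null(x$box))
    cat(sprintf("  periodic box: %g x %g x %g nm\n",
                x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' @rdname spin_trajectory
#' @param traj a `spin_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @rdname spin_trajectory
#' @export
n_atoms <- function(traj) dim(traj$coords)[2]

#' @rdname spin_trajectory
#' @export
duration_ps <- function(traj) (n_frames(traj) - 1) * traj$dt

#' Pool occupation counts
#'
#' @param traj a `spin_trajectory`.
#' @return named integer vector with elements `WP`, `MP`, `unassigned`.
#' @export
pool_counts <- function(traj) {
  c(WP = sum(traj$pool == "WP", na.rm = TRUE),
    MP = sum(traj$pool == "MP", na.rm = TRUE),
    unassigned = sum(is.na(traj$pool)))
}

#' Assign hydrogen nuclei to relaxation pools
#'
#' Every hydrogen nucleus belongs to exactly one of two pools: the water
#' pool (WP) or the macromolecule pool (MP). Assignment is by molecule
#' species through a named rule, e.g. `c(SOL = "WP", CHL = "MP")`.
#'
#' @param traj a `spin_trajectory`.
#' @param rule named character vector mapping species to `"WP"` or `"MP"`.
#' @return the trajectory with `pool` populated; the counts are available
#'   via [pool_counts()].
#' @export
assign_pools <- function(traj, rule) {
  stopifnot(inherits(traj, "spin_trajectory"))
  if (is.null(names(rule)) || !all(rule %in% c("WP", "MP")))
    stop("rule must be a named character vector with values 'WP' or 'MP'")
  if (n_atoms(traj) == 0L) return(traj)
  unknown <- setdiff(unique(traj$species), names(rule))
  if (length(unknown))
    stop("no pool rule for species: ", paste(unknown, collapse = ", "))
  traj$pool <- unname(rule[traj$species])
  traj
}

#' Make molecules whole across periodic boundaries
#'
#' Atoms of one molecule that were wrapped to opposite sides of the
#' periodic box are shifted by integer box vectors so that each molecule is
#' spatially contiguous, frame by frame. Every atom is imaged relative to
#' the first atom of its molecule. Inter-nuclear distances computed under
#' the minimum-image convention are unchanged by this operation, and
#' applying it twice equals applying it once.
#'
#' @param traj a `spin_trajectory`; returned unchanged when non-periodic.
#' @return recomposed `spin_trajectory`.
#' @export
recompose_molecules <- function(traj) {
  stopifnot(inherits(traj, "spin_trajectory"))
  if (is.null(traj$box)) return(traj)
  L <- traj$box
  co <- traj$coords
  for (mol in unique(traj$molecule_id)) {
    idx <- which(traj$molecule_id == mol)
    if (length(idx) < 2L) next
    anchor <- idx[1]
    for (ax in 1:3) {
      ref <- co[, anchor, ax]
      for (a in idx[-1]) {
        d <- co[, a, ax] - ref
        co[, a, ax] <- co[, a, ax] - L[ax] * round(d / L[ax])
      }
    }
  }
  # ambiguity check: a molecule wider than half the box cannot be
  # recomposed uniquely
  ext <- 0
  for (mol in unique(traj$molecule_id)) {
    idx <- which(traj$molecule_id == mol)
    if (length(idx) < 2L) next
    for (ax in 1:3)
      ext <- max(ext, max(co[1, idx, ax]) - min(co[1, idx, ax]))
  }
  if (ext * 2 > min(L))
    warning("molecular extent exceeds half the box; recomposition ambiguous")
  traj$coords <- co
  traj
}

#' Water mass fraction of a lipid/water composition
#'
#' Computes the water mass fraction m_water / m_total from per-species
#' molecule counts and molecular formulas. Used to characterise how much of
#' the hydrogen signal sits in the water compartment of a membrane system.
#'
#' @param species data.frame with columns `formula` (e.g. `"C27H46O"`) and
#'   `count` for the non-water species (lipids, ions).
#' @param waters number of water molecules.
#' @return list with `water_mass_fraction`, `m_water`, `m_other` (g/mol
#'   totals).
#' @export
#' @examples
#' mass_composition_report(myelin_composition(), waters = 4699)
mass_composition_report <- function(species, waters) {
  m_water <- waters * formula_mass("H2O")
  m_other <- 0
  if (nrow(species))
    m_other <- sum(vapply(species$formula, formula_mass, 0) * species$count)
  total <- m_water + m_other
  list(water_mass_fraction = if (total > 0) m_water / total else 0,
       m_water = m_water, m_other = m_other)
}

## monoisotopic-free standard atomic weights for the elements occurring in
## membrane lipids and counter ions
.atomic_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                  P = 30.974, S = 32.06, Na = 22.990)

#' Molecular mass from a Hill-style formula string
#'
#' @param formula e.g. `"C40H80NO8P"`.
#' @return mass in g/mol.
#' @export
formula_mass <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  if (!length(parts) || sum(attr(m, "match.length")) != nchar(formula))
    stop("cannot parse formula: ", formula)
  total <- 0
  for (p in parts) {
    el <- sub("[0-9]*$", "", p)
    n <- sub("^[A-Za-z]+", "", p)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% names(.atomic_mass))
      stop("unknown element '", el, "' in formula ", formula)
    total <- total + .atomic_mass[[el]] * n
  }
  total
}

#' Number of hydrogens in a formula
#' @param formula formula string.
#' @return integer hydrogen count.
#' @export
formula_hydrogens <- function(formula) {
  m <- regmatches(formula, regexpr("H[0-9]*", formula))
  if (!length(m)) return(0L)
  n <- sub("^H", "", m)
  if (nzchar(n)) as.integer(n) else 1L
}

#' Myelin membrane model composition
#'
#' Two-leaflet lipid composition of a myelin-like membrane patch: per
#' leaflet 27 cholesterol, 23 DPPC, 23 POPE, 23 galactocerebroside and 4
#' sulfatide molecules, plus 8 sodium counter ions. With 4699 water
#' molecules in the inter-leaflet space this corresponds to a water mass
#' fraction of about 40% and 13810 membrane (MP) hydrogens against 9398
#' water (WP) hydrogens.
#'
#' @return data.frame with columns `species`, `formula`, `count` (both
#'   leaflets combined; ions included).
#' @export
myelin_composition <- function() {
  data.frame(
    species = c("CHL", "DPPC", "POPE", "GalC", "GalS", "NA+"),
    formula = c("C27H46O", "C40H80NO8P", "C39H76NO8P",
                "C40H77NO7", "C40H76NO11S", "Na"),
    count = c(2L * 27L, 2L * 23L, 2L * 23L, 2L * 23L, 2L * 4L, 8L),
    stringsAsFactors = FALSE)
}
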