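#' Write a trajectory to disk
#'
#' Two formats are supported. The internal columnar format is a
#' self-describing plain-text container (header, per-atom table, per-frame
#' coordinate blocks) that round-trips coordinates bit-exactly via
#' `%.17g`; it is the native format of the synthetic generators. GRO is a
#' fixed-width interoperability format (3 decimal places, i.e. 1 pm
#' resolution) with one concatenated frame block per time step and the
#' frame time in the title line.
#'
#' @param traj a [spin_trajectory()].
#' @param path output file path.
#' @param format `"internal"` or `"gro"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("internal", "gro")) {
  format <- match.arg(format)
  stopifnot(inherits(traj, "spin_trajectory"))
  if (format == "internal") .write_internal(traj, path) else .write_gro(traj, path)
  invisible(path)
}

#' Read a trajectory from disk
#'
#' Reads hydrogen nuclei only (GRO: atoms whose name starts with "H"),
#' preserving molecule grouping. The sampling interval is taken from the
#' header (internal format) or inferred from the frame times and verified
#' constant (GRO); a non-uniform time grid is an error naming the
#' offending frame.
#'
#' @param path file path.
#' @param format `"internal"` or `"gro"`.
#' @param hydrogen_pattern regex applied to GRO atom names to select
#'   hydrogens; default `"^H"`.
#' @return a [spin_trajectory()].
#' @export
read_trajectory <- function(path, format = c("internal", "gro"),
                            hydrogen_pattern = "^H") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "internal") .read_internal(path) else
    .read_gro(path, hydrogen_pattern)
}

## ---- internal columnar format ------------------------------------------

.write_internal <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nf <- n_frames(traj); na <- n_atoms(traj)
  writeLines(c("#spintraj 1",
               sprintf("n_atoms %d", na),
               sprintf("n_frames %d", nf),
               sprintf("dt_ps %.17g", traj$dt),
               if (is.null(traj$box)) "box_nm none" else
                 sprintf("box_nm %.17g %.17g %.17g",
                         traj$box[1], traj$box[2], traj$box[3]),
               "atoms"), con)
  writeLines(sprintf("%d %s %d %s", seq_len(na), traj$species,
                     traj$molecule_id,
                     ifelse(is.na(traj$pool), "NA", traj$pool)), con)
  writeLines("frames", con)
  for (f in seq_len(nf)) {
    writeLines(sprintf("frame %d", f), con)
    writeLines(sprintf("%.17g %.17g %.17g",
                       traj$coords[f, , 1], traj$coords[f, , 2],
                       traj$coords[f, , 3]), con)
  }
}

.read_internal <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#spintraj"))
    stop("not an internal trajectory file: ", path)
  hdr <- function(key) {
    ln <- grep(paste0("^", key, " "), lines, value = TRUE)[1]
    if (is.na(ln)) stop("missing header field '", key, "' in ", path)
    sub(paste0("^", key, " "), "", ln)
  }
  na <- as.integer(hdr("n_atoms"))
  nf <- as.integer(hdr("n_frames"))
  dt <- as.numeric(hdr("dt_ps"))
  boxs <- hdr("box_nm")
  box <- if (identical(boxs, "none")) NULL else
    as.numeric(strsplit(boxs, " +")[[1]])
  ai <- which(lines == "atoms")[1]
  fi <- which(lines == "frames")[1]
  if (is.na(ai) || is.na(fi)) stop("malformed internal trajectory: ", path)
  at <- do.call(rbind, strsplit(lines[(ai + 1):(ai + na)], " +"))
  species <- at[, 2]
  molecule_id <- as.integer(at[, 3])
  pool <- ifelse(at[, 4] == "NA", NA_character_, at[, 4])
  coords <- array(NA_real_, c(nf, na, 3))
  pos <- fi + 1
  for (f in seq_len(nf)) {
    if (pos > length(lines) || !startsWith(lines[pos], "frame "))
      stop("frame ", f, " missing or truncated in ", path)
    block <- lines[(pos + 1):(pos + na)]
    if (length(block) != na || anyNA(block) || any(startsWith(block, "frame")))
      stop("frame ", f, " does not contain ", na, " nuclei in ", path)
    xyz <- matrix(as.numeric(unlist(strsplit(block, " +"))),
                  ncol = 3, byrow = TRUE)
    if (nrow(xyz) != na || anyNA(xyz))
      stop("frame ", f, " does not contain ", na, " nuclei in ", path)
    coords[f, , ] <- xyz
    pos <- pos + na + 1
  }
  spin_trajectory(coords, dt, species = species, molecule_id = molecule_id,
                  pool = pool, box = box)
}

## ---- GRO interoperability format ---------------------------------------

.write_gro <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  na <- n_atoms(traj)
  box <- if (is.null(traj$box)) c(0, 0, 0) else traj$box
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("spinrelax t= %.4f", (f - 1) * traj$dt), con)
    writeLines(sprintf("%5d", na), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       traj$molecule_id %% 100000L, traj$species,
                       sprintf("H%d", seq_len(na) %% 10000L),
                       seq_len(na) %% 100000L,
                       traj$coords[f, , 1], traj$coords[f, , 2],
                       traj$coords[f, , 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]), con)
  }
}

.read_gro <- function(path, hydrogen_pattern) {
  lines <- readLines(path)
  pos <- 1L
  times <- numeric(0)
  frames <- list()
  species <- molecule_id <- name <- NULL
  box <- NULL
  f <- 0L
  while (pos + 1L <= length(lines)) {
    f <- f + 1L
    title <- lines[pos]
    tm <- regmatches(title, regexpr("t= *[-0-9.eE+]+", title))
    times <- c(times, if (length(tm)) as.numeric(sub("t= *", "", tm)) else NA)
    na <- as.integer(trimws(lines[pos + 1L]))
    if (is.na(na) || pos + 1L + na + 1L > length(lines))
      stop("truncated GRO frame ", f, " in ", path)
    block <- lines[(pos + 2L):(pos + 1L + na)]
    if (f == 1L) {
      molecule_id <- as.integer(substr(block, 1, 5))
      species <- trimws(substr(block, 6, 10))
      name <- trimws(substr(block, 11, 15))
    } else if (length(block) != length(name)) {
      stop("frame ", f, " has a different atom count in ", path)
    }
    xyz <- cbind(as.numeric(substr(block, 21, 28)),
                 as.numeric(substr(block, 29, 36)),
                 as.numeric(substr(block, 37, 44)))
    frames[[f]] <- xyz
    box <- as.numeric(strsplit(trimws(lines[pos + 2L + na]), " +")[[1]])[1:3]
    pos <- pos + 3L + na
  }
  if (!f) stop("no frames in ", path)
  if (f > 1L) {
    dts <- diff(times)
    if (anyNA(dts)) stop("GRO frames without 't=' timestamps in ", path)
    bad <- which(abs(dts - dts[1]) > 1e-6 * max(dts[1], 1))
    if (length(bad))
      stop("inconsistent frame timestamps at frame ", bad[1] + 1L,
           " in ", path)
    dt <- dts[1]
  } else dt <- 1
  keep <- grepl(hydrogen_pattern, name)
  if (!any(keep)) stop("no hydrogen atoms matched in ", path)
  coords <- array(NA_real_, c(f, sum(keep), 3))
  for (i in seq_len(f)) coords[i, , ] <- frames[[i]][keep, , drop = FALSE]
  if (!is.null(box) && all(box == 0)) box <- NULL
  spin_trajectory(coords, dt, species = species[keep],
                  molecule_id = molecule_id[keep], box = box)
}
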