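#' Read a multi-frame XYZ file
#'
#' Parses the standard multi-frame XYZ layout: an atom-count line, a
#' comment line, then one line per atom with an element symbol and three
#' Cartesian coordinates (Angstrom).  Energy labels are recovered from
#' \code{key=value} tokens in the comment line; \code{E_low} and
#' \code{E_high} (kcal/mol) are recognized.
#'
#' @param path file path
#' @param full_z use full nuclear charges instead of valence counts
#' @return a list of \code{conformer} objects
#' @export
read_xyz <- function(path, full_z = FALSE) {
  lines <- readLines(path)
  confs <- list()
  i <- 1L
  frame <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat <= 0L) {
      stop("line ", i, ": expected a positive atom count, got '",
           trimws(lines[i]), "'")
    }
    if (i + 1L + nat > length(lines)) {
      stop("line ", i, ": frame declares ", nat,
           " atoms but the file ends after ",
           length(lines) - i - 1L, " atom lines")
    }
    comment <- lines[i + 1L]
    frame <- frame + 1L
    species <- character(nat)
    coords <- matrix(NA_real_, nat, 3L)
    for (a in seq_len(nat)) {
      ln <- i + 1L + a
      tok <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
      if (length(tok) < 4L) {
        stop("line ", ln, ": expected 'symbol x y z', got '",
             trimws(lines[ln]), "'")
      }
      xyz <- suppressWarnings(as.numeric(tok[2:4]))
      if (anyNA(xyz)) stop("line ", ln, ": non-numeric coordinate")
      species[a] <- tok[1]
      coords[a, ] <- xyz
    }
    en <- .parse_energy_comment(comment)
    label <- sub("\\s*(E_low|E_high)=.*$", "", comment)
    confs[[frame]] <- conformer(species, coords,
                                label = trimws(label),
                                energy = en, full_z = full_z)
    i <- i + 2L + nat
  }
  confs
}

.parse_energy_comment <- function(comment) {
  en <- list()
  for (key in c("E_low", "E_high")) {
    m <- regmatches(comment,
                    regexpr(paste0(key, "=[-+0-9.eE]+"), comment))
    if (length(m) == 1L) {
      en[[key]] <- as.numeric(sub(paste0(key, "="), "", m))
    }
  }
  if (length(en) == 0L) NULL else en
}

#' Write conformers to a multi-frame XYZ file
#'
#' Energies attached to a conformer are serialized into the comment
#' line as \code{E_low=...} / \code{E_high=...} so that
#' \code{read_xyz(write_xyz(x))} round-trips both geometry and labels.
#'
#' @param conformers a list of \code{conformer} objects (non-empty)
#' @param path output file path
#' @param digits coordinate precision
#' @return invisibly, \code{path}
#' @export
write_xyz <- function(conformers, path, digits = 10) {
  if (inherits(conformers, "conformer")) conformers <- list(conformers)
  if (length(conformers) == 0L) stop("no conformers to write")
  out <- character(0)
  for (conf in conformers) {
    comment <- conf$label
    if (!is.null(conf$energy)) {
      if (!is.null(conf$energy$E_low)) {
        comment <- paste(comment,
                         sprintf("E_low=%.*g", digits, conf$energy$E_low))
      }
      if (!is.null(conf$energy$E_high)) {
        comment <- paste(comment,
                         sprintf("E_high=%.*g", digits, conf$energy$E_high))
      }
    }
    fmt <- function(x) formatC(x, format = "f", digits = digits,
                               width = digits + 6)
    atom_lines <- paste(formatC(conf$species, width = -2),
                        fmt(conf$coords[, 1]), fmt(conf$coords[, 2]),
                        fmt(conf$coords[, 3]))
    out <- c(out, as.character(length(conf$species)), trimws(comment),
             atom_lines)
  }
  writeLines(out, path)
  invisible(path)
}
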