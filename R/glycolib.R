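# Glycoform nomenclature, subclass backbones, and the theoretical
# glycopeptide mass library.

# Monoisotopic masses in Da.  Glycan residue masses are the dehydrated
# (incorporated) residues; water is added once per peptide.
.mono <- list(
  water  = 18.010565,
  proton = 1.00728,
  hex    = 162.05282,
  hexnac = 203.07937,
  fuc    = 146.05791,
  neuac  = 291.09542
)

.aa_mono <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#' Tryptic Fc peptide backbones of the IgG subclasses
#'
#' The Asn297 tryptic glycopeptide moieties differ between subclasses only
#' by Tyr/Phe substitutions.  IgG3 (EEQYNSTFR) and IgG4 (EEQFNSTYR) are
#' sequence isomers with identical mass and are treated as a single
#' `"IgG3/4"` class throughout.
#'
#' @return A data frame with columns `subclass`, `sequence` and
#'   `residue_mass_sum` (monoisotopic sum of amino-acid residue masses, Da,
#'   excluding water).
#' @export
#' @examples
#' igg_backbones()
igg_backbones <- function() {
  seqs <- c("IgG1" = "EEQYNSTYR", "IgG2" = "EEQFNSTFR", "IgG3/4" = "EEQYNSTFR")
  data.frame(
    subclass = names(seqs),
    sequence = unname(seqs),
    residue_mass_sum = vapply(
      seqs, function(s) sum(.aa_mono[strsplit(s, "")[[1]]]), numeric(1),
      USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

#' The 22-name glycoform vocabulary
#'
#' Shorthand names follow the usual IgG Fc convention: the digit counts
#' galactoses on the biantennary core (`G0`/`G1`/`G2`), `N` marks a
#' bisecting GlcNAc, `-N` the loss of one antennary GlcNAc, `F` core
#' fucose, and `S`/`S2` one or two N-acetylneuraminic acids.
#'
#' @return Character vector of the 22 glycoform names grouped by
#'   galactosylation.
#' @export
default_glycoforms <- function() {
  c("G0", "G0F", "G0N", "G0NF", "G0-NF",
    "G1", "G1F", "G1FS", "G1-N", "G1N", "G1NF", "G1-NF", "G1NFS", "G1S",
    "G2", "G2F", "G2FS", "G2N", "G2NF", "G2NFS", "G2S", "G2S2")
}

#' Parse a glycoform shorthand name into a monosaccharide composition
#'
#' Accepts names of the grammar `G<0|1|2> [-N|N] [F] [S|S2]`.  The core
#' biantennary scaffold contributes 3 hexoses and 4 HexNAc; the galactose
#' digit adds hexoses, `N` adds a (bisecting) HexNAc, `-N` removes one
#' antennary HexNAc, `F` adds a core fucose and `S`/`S2` add sialic acids.
#'
#' @param name A single glycoform name, e.g. `"G0-NF"` or `"G2S2"`.
#' @return An object of class `glycan_composition`: a list with integer
#'   fields `hex`, `hexnac`, `fuc`, `neuac` and the `name`.
#' @export
#' @examples
#' parse_glycoform_name("G0F")
#' parse_glycoform_name("G1NFS")
parse_glycoform_name <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name))
    glyco_stop("glycoform name must be a single string", "glycomig_parse_error")
  m <- regmatches(name, regexec("^G([0-9])(-N|N)?(F)?(S2|S)?$", name))[[1]]
  if (length(m) == 0L) {
    # name the offending token: strip the pieces we do understand
    rest <- sub("^G[0-9]", "", name)
    rest <- sub("^(-N|N)", "", rest)
    rest <- sub("^F", "", rest)
    rest <- sub("^(S2|S)", "", rest)
    tok <- if (nzchar(rest)) rest else name
    glyco_stop(sprintf("cannot parse glycoform name '%s': unknown token '%s'",
                       name, tok), "glycomig_parse_error")
  }
  gal <- as.integer(m[2])
  if (gal > 2L)
    glyco_stop(sprintf("cannot parse '%s': galactose digit %d > 2", name, gal),
               "glycomig_parse_error")
  bis <- m[3]
  out <- list(
    hex    = 3L + gal,
    hexnac = 4L + (bis == "N") - (bis == "-N"),
    fuc    = as.integer(m[4] == "F"),
    neuac  = switch(m[5], "S" = 1L, "S2" = 2L, 0L),
    name   = name
  )
  class(out) <- "glycan_composition"
  out
}

#' Format a glycan composition back to its shorthand name
#'
#' Inverse of [parse_glycoform_name()]; `format(parse(x)) == x` for every
#' vocabulary name.
#'
#' @param comp A `glycan_composition`.
#' @return The shorthand name string.
#' @export
format_glycoform <- function(comp) {
  stopifnot(inherits(comp, "glycan_composition"))
  paste0(
    "G", comp$hex - 3L,
    c("-N", "", "N")[comp$hexnac - 2L],
    if (comp$fuc == 1L) "F" else "",
    c("", "S", "S2")[comp$neuac + 1L]
  )
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat(sprintf("<glycan %s> Hex%d HexNAc%d Fuc%d NeuAc%d\n",
              x$name, x$hex, x$hexnac, x$fuc, x$neuac))
  invisible(x)
}

#' Theoretical glycopeptide m/z
#'
#' Monoisotopic `[M+H]+` mass of a subclass Fc peptide backbone carrying a
#' glycan composition: amino-acid residue masses + one water + glycan
#' residue masses + one proton.
#'
#' @param backbone Subclass name (`"IgG1"`, `"IgG2"`, `"IgG3/4"`) or a row
#'   of [igg_backbones()].
#' @param glycan A `glycan_composition` (from [parse_glycoform_name()]) or
#'   a glycoform name string.
#' @return Theoretical m/z in Da.
#' @export
#' @examples
#' glycopeptide_mz("IgG2", "G0F")  # 2602.1, a repeatability QC mass
glycopeptide_mz <- function(backbone, glycan) {
  bb <- igg_backbones()
  if (is.character(backbone)) {
    if (!backbone %in% bb$subclass)
      glyco_stop(sprintf("unknown subclass '%s'", backbone), "glycomig_parse_error")
    pep <- bb$residue_mass_sum[bb$subclass == backbone]
  } else {
    pep <- backbone$residue_mass_sum
  }
  if (is.character(glycan)) glycan <- parse_glycoform_name(glycan)
  with(.mono,
       pep + water +
         glycan$hex * hex + glycan$hexnac * hexnac +
         glycan$fuc * fuc + glycan$neuac * neuac +
         proton)
}

#' Build the annotated theoretical glycopeptide library
#'
#' One entry per (subclass, glycoform) pair.  Because IgG3/4 is isomeric
#' with neither IgG1 nor IgG2 but a hexose-for-fucose swap almost exactly
#' compensates the one-oxygen backbone difference, several IgG3/4 species
#' coincide in mass with IgG1/IgG2 species; such IgG3/4 entries are flagged
#' `overlapped` and ignored downstream.
#'
#' @param glycoforms Character vector of glycoform names
#'   (default [default_glycoforms()]).
#' @param subclasses Character vector of subclass classes.
#' @param overlap_tol Da; an IgG3/4 entry within this distance of any
#'   IgG1/IgG2 entry is flagged. Default 1.0 (linear-mode peaks are broad).
#' @return A `glyco_library` data frame with columns `subclass`,
#'   `glycoform`, `hex`, `hexnac`, `fuc`, `neuac`, `mz`, `overlapped`,
#'   sorted by `mz`.
#' @export
build_library <- function(glycoforms = default_glycoforms(),
                          subclasses = c("IgG1", "IgG2", "IgG3/4"),
                          overlap_tol = 1.0) {
  grid <- expand.grid(subclass = subclasses, glycoform = glycoforms,
                      stringsAsFactors = FALSE)
  if (anyDuplicated(grid))
    glyco_stop("duplicate (subclass, glycoform) pairs", "glycomig_parse_error")
  comps <- lapply(grid$glycoform, parse_glycoform_name)
  lib <- data.frame(
    subclass  = grid$subclass,
    glycoform = grid$glycoform,
    hex    = vapply(comps, `[[`, integer(1), "hex"),
    hexnac = vapply(comps, `[[`, integer(1), "hexnac"),
    fuc    = vapply(comps, `[[`, integer(1), "fuc"),
    neuac  = vapply(comps, `[[`, integer(1), "neuac"),
    stringsAsFactors = FALSE
  )
  lib$mz <- mapply(function(s, g) glycopeptide_mz(s, g),
                   lib$subclass, lib$glycoform, USE.NAMES = FALSE)
  is34 <- lib$subclass == "IgG3/4"
  lib$overlapped <- FALSE
  if (any(is34) && any(!is34)) {
    main_mz <- lib$mz[!is34]
    lib$overlapped[is34] <- vapply(
      lib$mz[is34], function(m) any(abs(main_mz - m) <= overlap_tol),
      logical(1))
  }
  lib <- lib[order(lib$mz), , drop = FALSE]
  rownames(lib) <- NULL
  attr(lib, "overlap_tol") <- overlap_tol
  class(lib) <- c("glyco_library", "data.frame")
  lib
}

#' @export
print.glyco_library <- function(x, ...) {
  cat(sprintf("<glyco_library> %d entries (%d overlap-flagged), m/z %.1f-%.1f\n",
              nrow(x), sum(x$overlapped), min(x$mz), max(x$mz)))
  print.data.frame(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat("...\n")
  invisible(x)
}

# Look up theoretical m/z of specific (subclass, glycoform) pairs.
library_mz <- function(library, subclass, glycoform) {
  idx <- match(paste(subclass, glycoform), paste(library$subclass, library$glycoform))
  if (anyNA(idx))
    glyco_stop("entry not present in library", "glycomig_parse_error")
  library$mz[idx]
}

#' Internal calibrant masses
#'
#' The four glycopeptides used for internal calibration (nominal m/z
#' 2602.1, 2796.1, 2958.2, 3217.3): IgG2 G0F, IgG1 G1F, IgG1 G2F and
#' IgG2 G2FS.
#'
#' @param library Optional `glyco_library`; defaults to [build_library()].
#' @return Named numeric vector of theoretical m/z.
#' @export
calibrant_masses <- function(library = build_library()) {
  sub <- c("IgG2", "IgG1", "IgG1", "IgG2")
  gf  <- c("G0F",  "G1F",  "G2F",  "G2FS")
  setNames(library_mz(library, sub, gf), paste(sub, gf))
}

#' Repeatability QC masses
#'
#' The six minor components used for replicate RSD quality control
#' (nominal m/z 2602.1, 2634.0, 2764.1, 2796.1, 2926.2, 2958.2).
#'
#' @param library Optional `glyco_library`; defaults to [build_library()].
#' @return Named numeric vector of theoretical m/z.
#' @export
qc_masses <- function(library = build_library()) {
  sub <- c("IgG2", "IgG1", "IgG2", "IgG1", "IgG2", "IgG1")
  gf  <- c("G0F",  "G0F",  "G1F",  "G1F",  "G2F",  "G2F")
  setNames(library_mz(library, sub, gf), paste(sub, gf))
}

#' Write / read a glycopeptide library as a tabular text file
#'
#' @param library A `glyco_library`.
#' @param path File path (CSV).
#' @return `read_library` returns the `glyco_library`.
#' @export
write_library <- function(library, path) {
  write.csv(as.data.frame(library), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  lib <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subclass", "glycoform", "hex", "hexnac", "fuc", "neuac",
            "mz", "overlapped")
  if (!all(need %in% names(lib)))
    glyco_stop("library file lacks required columns", "glycomig_format_error")
  lib <- lib[order(lib$mz), , drop = FALSE]
  rownames(lib) <- NULL
  class(lib) <- c("glyco_library", "data.frame")
  lib
}
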