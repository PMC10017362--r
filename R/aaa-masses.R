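# Residue mass tables and peptide mass bookkeeping.
#
# Two conventions are always carried side by side: monoisotopic (lightest
# isotopes only; what MALDI-TOF reports for small peptides) and average
# (isotope-abundance weighted; what older "MW" figures usually quote).
# Published product tables mix the two conventions freely, so every species
# in this package reports both.

#' Standard amino-acid residue masses
#'
#' Monoisotopic and average masses, in Da, of the 20 standard amino-acid
#' residues as they occur inside a peptide chain (i.e. minus one water
#' relative to the free amino acid).
#'
#' @format A named numeric vector of length 20 (one-letter codes).
#' @name residue_masses
NULL

.MONO_RESIDUE <- c(
  G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276,
  V =  99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
  I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
  K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
  F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

.AVG_RESIDUE <- c(
  G =  57.0519, A =  71.0788, S =  87.0782, P =  97.1167,
  V =  99.1326, T = 101.1051, C = 103.1388, L = 113.1594,
  I = 113.1594, N = 114.1038, D = 115.0886, Q = 128.1307,
  K = 128.1741, E = 129.1155, M = 131.1926, H = 137.1411,
  F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

.WATER_MONO <- 18.010565
.WATER_AVG  <- 18.0153
.H_MONO     <- 1.0078250319
.H_AVG      <- 1.00794

.AA20 <- names(.MONO_RESIDUE)

#' Round half away from zero
#'
#' Mass comparisons against printed integer MWs use round-half-away-from-
#' zero (base \code{round()} is round-half-even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 0).
#' @return Rounded values.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Construct a peptide
#'
#' A peptide is a one-letter sequence with a topology (\code{"linear"} or
#' \code{"cyclic"}) and an explicit disulfide count. Cysteines default to
#' reduced; each declared disulfide removes two hydrogens from the mass.
#'
#' @param sequence One-letter amino-acid string (20 standard codes only).
#' @param topology \code{"linear"} or \code{"cyclic"}.
#' @param disulfide_count Number of disulfide bonds (default 0, i.e. all
#'   cysteines reduced). Must not exceed \code{floor(nCys / 2)}.
#' @param name Optional label carried through product tables.
#' @param min_ring Minimum ring size permitted for cyclic topology
#'   (default 5 residues; smaller backbone macrocycles are chemically
#'   implausible).
#' @return An object of class \code{"peptide"}.
#' @examples
#' peptide("GISYKPAYLNGL", name = "GN10-GL")
#' peptide("GISYKPAYLN", topology = "cyclic", name = "cGN10")
#' @export
peptide <- function(sequence, topology = c("linear", "cyclic"),
                    disulfide_count = 0L, name = NULL, min_ring = 5L) {
  topology <- match.arg(topology)
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% .AA20)
  if (length(bad))
    stop("nonstandard residue '", chars[bad[1L]], "' at position ", bad[1L],
         call. = FALSE)
  if (topology == "cyclic" && length(chars) < min_ring)
    stop("cyclic peptide of length ", length(chars),
         " is below the minimum ring size of ", min_ring, call. = FALSE)
  ncys <- sum(chars == "C")
  disulfide_count <- as.integer(disulfide_count)
  if (disulfide_count < 0L || disulfide_count > ncys %/% 2L)
    stop("disulfide_count must be between 0 and floor(#Cys/2) = ",
         ncys %/% 2L, call. = FALSE)
  structure(
    list(sequence = sequence, topology = topology,
         disulfide_count = disulfide_count, name = name),
    class = "peptide")
}

#' @export
print.peptide <- function(x, ...) {
  m <- peptide_mass(x)
  cat(sprintf("<peptide%s> %s (%s, %d S-S)\n  mono %.4f Da | avg %.4f Da\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              x$sequence, x$topology, x$disulfide_count,
              m[["mono_mass"]], m[["avg_mass"]]))
  invisible(x)
}

#' Peptide mass in both conventions
#'
#' Linear mass is the sum of residue masses plus one water; head-to-tail
#' cyclization removes that water (one condensation closes the backbone).
#' Each disulfide bond subtracts two hydrogens.
#'
#' @param p A \code{\link{peptide}} (a plain string is accepted and treated
#'   as a linear reduced peptide).
#' @return Named numeric vector with \code{mono_mass} and \code{avg_mass}
#'   in Da.
#' @examples
#' peptide_mass(peptide("GISYKPAYLNGL"))            # ~1294.69 mono
#' peptide_mass(peptide("GISYKPAYLN", "cyclic"))    # ~1106.58 mono
#' @export
peptide_mass <- function(p) {
  if (is.character(p)) p <- peptide(p)
  stopifnot(inherits(p, "peptide"))
  chars <- strsplit(p$sequence, "", fixed = TRUE)[[1L]]
  mono <- sum(.MONO_RESIDUE[chars])
  avg  <- sum(.AVG_RESIDUE[chars])
  if (p$topology == "linear") {
    mono <- mono + .WATER_MONO
    avg  <- avg + .WATER_AVG
  }
  if (p$disulfide_count > 0L) {
    mono <- mono - 2 * .H_MONO * p$disulfide_count
    avg  <- avg - 2 * .H_AVG * p$disulfide_count
  }
  c(mono_mass = mono, avg_mass = avg)
}
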