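# Asx-specific reaction modelling: recognition sites, hydrolysis,
# head-to-tail cyclization, intermolecular ligation and the
# cap-removal/splice cascade, with exact mass bookkeeping per product.
#
# Legumain-family enzymes act C-terminal to Asn/Asp (the P1 residue, in
# Schechter-Berger nomenclature). Ligase-favourable substrates carry an
# Asx-Xaa-Yaa C-terminal motif: Xaa (P1') any residue except Pro, Yaa (P2')
# hydrophobic. For the incoming nucleophile, Gly is favoured at P1'' and
# hydrophobics at P2''. Motif violations are reported as warnings, never
# refusals: such substrates still react, just less efficiently.

.HYDROPHOBIC_DEFAULT <- c("F", "I", "L", "M", "V", "A", "W", "Y")

#' Find Asx (P1) recognition sites in a peptide
#'
#' Reports every Asn/Asp position together with the surrounding P2, P1' and
#' P2' residues and whether the site satisfies the Asx-Xaa-Yaa motif
#' (P1' not Pro and P2' hydrophobic). For cyclic peptides positions wrap
#' around the ring.
#'
#' @param p A \code{\link{peptide}} or plain sequence string.
#' @param hydrophobic Residue set accepted at P2' (default
#'   \code{c("F","I","L","M","V","A","W","Y")}).
#' @return A data frame with one row per site: \code{p1_position},
#'   \code{p1_residue}, \code{p2}, \code{p1prime}, \code{p2prime},
#'   \code{motif_ok} (NA when P1'/P2' do not exist, i.e. at a linear chain
#'   end).
#' @examples
#' find_p1_sites("GISYKPAYLNGL")     # one Asn site at 10, motif OK
#' find_p1_sites("AINGLRRGYSGSDALEG") # Asn at 3 and Asp at 13
#' @export
find_p1_sites <- function(p, hydrophobic = .HYDROPHOBIC_DEFAULT) {
  if (is.character(p)) p <- peptide(p)
  chars <- strsplit(p$sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  pos <- which(chars %in% c("N", "D"))
  at <- function(i) {
    if (p$topology == "cyclic") chars[(i - 1L) %% n + 1L]
    else if (i >= 1L && i <= n) chars[i] else NA_character_
  }
  out <- data.frame(
    p1_position = pos,
    p1_residue  = chars[pos],
    p2          = vapply(pos - 1L, at, character(1L)),
    p1prime     = vapply(pos + 1L, at, character(1L)),
    p2prime     = vapply(pos + 2L, at, character(1L)),
    stringsAsFactors = FALSE)
  out$motif_ok <- ifelse(
    is.na(out$p1prime) | is.na(out$p2prime), NA,
    out$p1prime != "P" & out$p2prime %in% hydrophobic)
  out[order(out$p1_position), , drop = FALSE]
}

# resolve a site argument (row of find_p1_sites output, or bare position)
.resolve_site <- function(p, site) {
  chars <- strsplit(p$sequence, "", fixed = TRUE)[[1L]]
  pos <- if (is.data.frame(site)) {
    stopifnot(nrow(site) == 1L)
    site$p1_position
  } else as.integer(site)
  if (pos < 1L || pos > length(chars))
    stop("site position ", pos, " outside peptide of length ", length(chars),
         call. = FALSE)
  if (!chars[pos] %in% c("N", "D"))
    stop("residue at position ", pos, " is '", chars[pos],
         "', not Asn/Asp", call. = FALSE)
  pos
}

.product_row <- function(name, kind, pep, warnings = "") {
  m <- peptide_mass(pep)
  data.frame(name = name, kind = kind, sequence = pep$sequence,
             topology = pep$topology,
             mono_mass = unname(m[["mono_mass"]]),
             avg_mass = unname(m[["avg_mass"]]),
             warnings = warnings, stringsAsFactors = FALSE)
}

.product_set <- function(rows) {
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("product_set", "data.frame")
  out
}

#' @export
print.product_set <- function(x, ...) {
  cat("<product_set> ", nrow(x), " species\n", sep = "")
  df <- as.data.frame(x)
  df$mono_mass <- sprintf("%.4f", df$mono_mass)
  df$avg_mass <- sprintf("%.4f", df$avg_mass)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Predict Asx-specific hydrolysis products
#'
#' Cleaves the peptide bond C-terminal to the P1 Asn/Asp, yielding a linear
#' N-terminal fragment (through P1) and a linear C-terminal fragment. One
#' water is consumed, so
#' \code{mass(substrate) + water = mass(N-fragment) + mass(C-fragment)}.
#' Cyclic substrates are ring-opened at the site (one linear product).
#'
#' @param p Substrate \code{\link{peptide}} (or string).
#' @param site A row of \code{\link{find_p1_sites}} output, or a P1
#'   position.
#' @return A \code{product_set} data frame.
#' @examples
#' predict_cleavage("GISYKPAYLNGL", 10)  # GN10 (1125 mono) + GL
#' @export
predict_cleavage <- function(p, site) {
  if (is.character(p)) p <- peptide(p)
  pos <- .resolve_site(p, site)
  n <- nchar(p$sequence)
  if (p$topology == "cyclic") {
    # ring opening: linearize so the ring's P1 becomes the new C-terminus
    chars <- strsplit(p$sequence, "", fixed = TRUE)[[1L]]
    lin <- paste(chars[c(seq_len(n)[-seq_len(pos)], seq_len(pos))],
                 collapse = "")
    return(.product_set(list(
      .product_row(paste0(p$name %||% "substrate", "_opened"),
                   "hydrolysis_n_fragment", peptide(lin)))))
  }
  if (pos >= n)
    stop("cleavage at the last residue leaves an empty C-fragment",
         call. = FALSE)
  nfrag <- peptide(substr(p$sequence, 1L, pos))
  cfrag <- peptide(substr(p$sequence, pos + 1L, n))
  .product_set(list(
    .product_row("N_fragment", "hydrolysis_n_fragment", nfrag),
    .product_row("C_fragment", "hydrolysis_c_fragment", cfrag)))
}

#' Predict head-to-tail cyclization products
#'
#' Transpeptidation at the P1 Asx: the substrate's N-terminus attacks the
#' acyl-enzyme, closing a backbone macrocycle over residues 1..P1 and
#' releasing the C-terminal leaving group. Mass balance:
#' \code{mass(cyclic) + mass(leaving) = mass(substrate)} exactly (the
#' condensation water lost on cyclization equals the water gained by the
#' released leaving group).
#'
#' @inheritParams predict_cleavage
#' @param min_ring Minimum ring size (default 5).
#' @return A \code{product_set} with the cyclic product and the leaving
#'   group.
#' @examples
#' predict_cyclization("GISYKPAYLNGL", 10)  # cGN10 (1107 mono) + GL
#' @export
predict_cyclization <- function(p, site, min_ring = 5L) {
  if (is.character(p)) p <- peptide(p)
  if (p$topology != "linear")
    stop("cyclization requires a linear substrate", call. = FALSE)
  pos <- .resolve_site(p, site)
  n <- nchar(p$sequence)
  if (pos >= n)
    stop("no leaving group: P1 at the C-terminus cannot transpeptidate",
         call. = FALSE)
  if (pos < min_ring)
    stop("ring of ", pos, " residues is below the minimum ring size of ",
         min_ring, call. = FALSE)
  cyc <- peptide(substr(p$sequence, 1L, pos), topology = "cyclic",
                 min_ring = min_ring)
  lv <- peptide(substr(p$sequence, pos + 1L, n))
  .product_set(list(
    .product_row("cyclic_product", "cyclic", cyc),
    .product_row("leaving_group", "leaving_group", lv)))
}

#' Predict intermolecular ligation products
#'
#' The donor is cleaved at its P1 Asx and the acceptor peptide's N-terminus
#' is ligated onto the donor's P1 carbonyl, displacing the donor's leaving
#' group. Mass balance:
#' \code{mass(ligated) = mass(donor prefix) + mass(acceptor) - water}.
#' Unfavourable nucleophiles (P1'' not Gly, P2'' not hydrophobic) yield
#' warnings.
#'
#' @param donor Donor \code{\link{peptide}} (or string), linear, with a
#'   non-empty leaving group after P1.
#' @param donor_site P1 site in the donor.
#' @param acceptor Acceptor (incoming nucleophile) peptide or string;
#'   linear, non-empty.
#' @param hydrophobic Residue set accepted at P2''.
#' @return A \code{product_set} with the ligated product and the leaving
#'   group.
#' @examples
#' predict_ligation("GFSYKPAYSNGL", 10, "GI")  # GFSYKPAYSNGI, 1303.44 avg
#' @export
predict_ligation <- function(donor, donor_site, acceptor,
                             hydrophobic = .HYDROPHOBIC_DEFAULT) {
  if (is.character(donor)) donor <- peptide(donor)
  if (is.character(acceptor)) {
    if (!nzchar(acceptor)) stop("acceptor must be non-empty", call. = FALSE)
    acceptor <- peptide(acceptor)
  }
  if (donor$topology != "linear" || acceptor$topology != "linear")
    stop("ligation requires linear donor and acceptor", call. = FALSE)
  pos <- .resolve_site(donor, donor_site)
  n <- nchar(donor$sequence)
  if (pos >= n)
    stop("no leaving group: donor P1 at the C-terminus", call. = FALSE)
  warn <- character(0)
  p1pp <- substr(acceptor$sequence, 1L, 1L)
  p2pp <- if (nchar(acceptor$sequence) >= 2L)
    substr(acceptor$sequence, 2L, 2L) else NA_character_
  if (p1pp != "G")
    warn <- c(warn, paste0("P1'' is ", p1pp, ", not the favoured Gly"))
  if (!is.na(p2pp) && !p2pp %in% hydrophobic)
    warn <- c(warn, paste0("P2'' ", p2pp, " outside hydrophobic set"))
  lig <- peptide(paste0(substr(donor$sequence, 1L, pos), acceptor$sequence))
  lv <- peptide(substr(donor$sequence, pos + 1L, n))
  .product_set(list(
    .product_row("ligated_product", "ligated", lig,
                 warnings = paste(warn, collapse = "; ")),
    .product_row("leaving_group", "leaving_group", lv)))
}

#' Predict the cap-removal / splice cascade
#'
#' Two sequential Asx events, as in cyclotide-precursor maturation: first an
#' Asn-specific hydrolysis removes the N-terminal cap (prefix through the
#' cap Asn), then an Asp-specific transpeptidation cyclizes the intermediate,
#' releasing the suffix after the cyclization Asp. With \code{cap_site =
#' NULL} (cap length 0) this reduces to \code{\link{predict_cyclization}}.
#'
#' @param p Linear substrate \code{\link{peptide}} (or string).
#' @param cap_site Asn P1 site of the cap cleavage (or NULL for no cap).
#' @param cyc_site Asx P1 site of the downstream cyclization; must follow
#'   \code{cap_site}.
#' @param min_ring Minimum ring size for the cyclic product.
#' @return A \code{product_set} with cap, linear intermediate, cyclic
#'   product and leaving group.
#' @examples
#' predict_splice_cascade("AINGLRRGYSGSDALEG", 3, 13)
#' @export
predict_splice_cascade <- function(p, cap_site, cyc_site, min_ring = 5L) {
  if (is.character(p)) p <- peptide(p)
  if (p$topology != "linear")
    stop("splice cascade requires a linear substrate", call. = FALSE)
  if (is.null(cap_site))
    return(predict_cyclization(p, cyc_site, min_ring = min_ring))
  cap_pos <- .resolve_site(p, cap_site)
  cyc_pos <- .resolve_site(p, cyc_site)
  if (cap_pos >= cyc_pos)
    stop("cap site (", cap_pos, ") must precede the cyclization site (",
         cyc_pos, ")", call. = FALSE)
  if (cyc_pos - cap_pos < min_ring)
    stop("segment between cap and cyclization sites (", cyc_pos - cap_pos,
         " residues) is below the minimum ring size of ", min_ring,
         call. = FALSE)
  n <- nchar(p$sequence)
  if (cyc_pos >= n)
    stop("no leaving group after the cyclization site", call. = FALSE)
  cap <- peptide(substr(p$sequence, 1L, cap_pos))
  inter <- peptide(substr(p$sequence, cap_pos + 1L, n))
  cyc <- peptide(substr(p$sequence, cap_pos + 1L, cyc_pos),
                 topology = "cyclic", min_ring = min_ring)
  lv <- peptide(substr(p$sequence, cyc_pos + 1L, n))
  .product_set(list(
    .product_row("cap", "cap", cap),
    .product_row("intermediate", "intermediate", inter),
    .product_row("cyclic_product", "cyclic", cyc),
    .product_row("leaving_group", "leaving_group", lv)))
}

#' Write a product set to a delimited file
#'
#' @param ps A \code{product_set}.
#' @param path Output path (tab-separated).
#' @return \code{path}, invisibly.
#' @export
write_product_set <- function(ps, path) {
  utils::write.table(as.data.frame(ps), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
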