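# Ligase-activity determinant (LAD) engineering.
#
# Two conserved Gly residues flanking the S1 Asx-binding pocket steer
# legumain activity: Gly at both (AEP-like) favours hydrolysis, while the
# hydrophobic substitutions found in natural ligases (Val at LAD1 as in
# butelase-1, Ala at LAD2 as in VyPAL2) favour transpeptidation. The
# standard panel from an AEP-like parent is: LAD1->V, LAD2->A, and the
# double mutant.

.AEP_STATE_DEFAULT <- "G"
.PAL_STATE_DEFAULT <- c("V", "I", "L", "A", "F", "M")

#' Locate the LAD sites in a subject sequence
#'
#' LAD positions are supplied in reference numbering and resolved through a
#' reference map (positions whose column was trimmed from the consensus
#' resolve to NA and are rejected, never silently shifted). Pass
#' \code{ref_map = NULL} for an identity map (positions already in subject
#' coordinates).
#'
#' @param subject Subject protein sequence (plain string, consensus
#'   coordinates).
#' @param lad_positions Named or unnamed vector of reference positions;
#'   names default to \code{LAD1}, \code{LAD2}, ...
#' @param ref_map Optional \code{\link{map_to_reference}} result (with
#'   consensus lookup) translating reference numbers to subject positions.
#' @param aep_state,pal_state Residue sets defining the AEP-like and
#'   PAL-like states (defaults \code{"G"} and hydrophobics
#'   \code{c("V","I","L","A","F","M")}).
#' @return A data frame of class \code{"lad_sites"}: \code{name},
#'   \code{position} (subject coordinates), \code{observed_residue}, plus
#'   the state sets as attributes.
#' @export
locate_lad_sites <- function(subject, lad_positions, ref_map = NULL,
                             aep_state = .AEP_STATE_DEFAULT,
                             pal_state = .PAL_STATE_DEFAULT) {
  stopifnot(is.character(subject), length(subject) == 1L)
  nm <- names(lad_positions)
  if (is.null(nm)) nm <- paste0("LAD", seq_along(lad_positions))
  pos <- if (is.null(ref_map)) as.integer(lad_positions)
  else reference_to_consensus(ref_map, lad_positions)
  for (i in seq_along(pos)) {
    if (is.na(pos[i]))
      stop("site ", nm[i], ": reference position ", lad_positions[i],
           " maps to a trimmed/gapped column", call. = FALSE)
    if (pos[i] < 1L || pos[i] > nchar(subject))
      stop("site ", nm[i], ": position ", pos[i],
           " outside subject of length ", nchar(subject), call. = FALSE)
  }
  out <- data.frame(name = nm, position = pos,
                    observed_residue = substring(subject, pos, pos),
                    stringsAsFactors = FALSE)
  attr(out, "aep_state") <- aep_state
  attr(out, "pal_state") <- pal_state
  class(out) <- c("lad_sites", "data.frame")
  out
}

#' Classify a legumain as AEP-like or PAL-like from its LAD residues
#'
#' All sites in the AEP state set yield \code{"AEP-like"}; otherwise at
#' least one site in the PAL state set yields \code{"PAL-like"}; anything
#' else is \code{"ambiguous"} (a first-class outcome, never coerced).
#'
#' @param sites A \code{\link{locate_lad_sites}} result.
#' @param aep_state,pal_state Override the state sets stored on
#'   \code{sites}.
#' @return One of \code{"AEP-like"}, \code{"PAL-like"},
#'   \code{"ambiguous"}.
#' @export
classify_activity <- function(sites,
                              aep_state = attr(sites, "aep_state"),
                              pal_state = attr(sites, "pal_state")) {
  if (is.null(aep_state)) aep_state <- .AEP_STATE_DEFAULT
  if (is.null(pal_state)) pal_state <- .PAL_STATE_DEFAULT
  obs <- sites$observed_residue
  if (all(obs %in% aep_state)) return("AEP-like")
  if (any(obs %in% pal_state)) return("PAL-like")
  "ambiguous"
}

#' Create an enzyme variant record
#'
#' @param name Variant name.
#' @param sequence Protein sequence.
#' @param lad_sites A \code{\link{locate_lad_sites}} result for this
#'   sequence (re-derived when omitted and \code{lad_positions} given).
#' @param lineage Optional list(parent = name, plan = mutation plan).
#' @return An object of class \code{"enzyme_variant"} with the LAD
#'   classification filled in.
#' @export
enzyme_variant <- function(name, sequence, lad_sites, lineage = NULL) {
  stopifnot(inherits(lad_sites, "lad_sites"))
  # refresh observed residues from this sequence
  lad_sites$observed_residue <-
    substring(sequence, lad_sites$position, lad_sites$position)
  structure(list(name = name, sequence = sequence, lad_sites = lad_sites,
                 classification = classify_activity(lad_sites),
                 lineage = lineage),
            class = "enzyme_variant")
}

#' @export
print.enzyme_variant <- function(x, ...) {
  cat("<enzyme_variant> ", x$name, " (", x$classification, "), ",
      nchar(x$sequence), " aa\n  LAD: ",
      paste(sprintf("%s=%s@%d", x$lad_sites$name,
                    x$lad_sites$observed_residue, x$lad_sites$position),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Build a mutation plan
#'
#' @param position Subject positions (distinct).
#' @param from_residue,to_residue Residues before/after at each position.
#' @param label Variant name for the resulting child.
#' @return A data frame of class \code{"mutation_plan"}.
#' @export
mutation_plan <- function(position, from_residue, to_residue, label) {
  stopifnot(length(position) == length(from_residue),
            length(position) == length(to_residue),
            !anyDuplicated(position))
  structure(data.frame(position = as.integer(position),
                       from_residue = from_residue,
                       to_residue = to_residue, stringsAsFactors = FALSE),
            label = label, class = c("mutation_plan", "data.frame"))
}

#' Invert a mutation plan
#'
#' @param plan A \code{\link{mutation_plan}}.
#' @param label Label for the inverse plan.
#' @return The plan with from/to swapped.
#' @export
invert_plan <- function(plan, label = paste0(attr(plan, "label"), "_rev")) {
  mutation_plan(plan$position, plan$to_residue, plan$from_residue, label)
}

#' Apply a mutation plan to an enzyme variant
#'
#' Each substitution is checked against the parent sequence (a mismatch
#' between the plan's from-residue and the observed residue rejects the
#' plan, naming the position). Lineage is recorded and the LAD
#' classification recomputed.
#'
#' @param parent An \code{\link{enzyme_variant}}.
#' @param plan A \code{\link{mutation_plan}}.
#' @return The child \code{enzyme_variant}.
#' @export
apply_mutations <- function(parent, plan) {
  stopifnot(inherits(parent, "enzyme_variant"),
            inherits(plan, "mutation_plan"))
  seq <- parent$sequence
  for (i in seq_len(nrow(plan))) {
    pos <- plan$position[i]
    obs <- substring(seq, pos, pos)
    if (obs != plan$from_residue[i])
      stop("plan expects ", plan$from_residue[i], " at position ", pos,
           " but the parent has ", obs, call. = FALSE)
    substring(seq, pos, pos) <- plan$to_residue[i]
  }
  enzyme_variant(attr(plan, "label"), seq, parent$lad_sites,
                 lineage = list(parent = parent$name, plan = plan))
}

#' Design the PAL mutant panel from an AEP-like parent
#'
#' Emits the three canonical variants: LAD1 Gly to Val (butelase-1-like),
#' LAD2 Gly to Ala (VyPAL2-like), and the double mutant; all classify
#' PAL-like. The parent must carry Gly at both LAD sites.
#'
#' @param parent An AEP-like \code{\link{enzyme_variant}} with two LAD
#'   sites.
#' @param suffixes Name suffixes for the three variants (default 1:3).
#' @return A named list of three \code{enzyme_variant} objects.
#' @export
design_pal_panel <- function(parent, suffixes = 1:3) {
  stopifnot(inherits(parent, "enzyme_variant"),
            nrow(parent$lad_sites) == 2L)
  if (parent$classification != "AEP-like" ||
      !all(parent$lad_sites$observed_residue == "G"))
    stop("panel requires an AEP-like parent with Gly at both LAD sites ",
         "(got ", paste(parent$lad_sites$observed_residue, collapse = "/"),
         ")", call. = FALSE)
  p1 <- parent$lad_sites$position[parent$lad_sites$name == "LAD1"]
  p2 <- parent$lad_sites$position[parent$lad_sites$name == "LAD2"]
  base <- sub("LEG", "PAL", parent$name, fixed = TRUE)
  if (base == parent$name) base <- paste0(parent$name, "_PAL")
  plans <- list(
    mutation_plan(p1, "G", "V", paste0(base, suffixes[1L])),
    mutation_plan(p2, "G", "A", paste0(base, suffixes[2L])),
    mutation_plan(c(p2, p1), c("G", "G"), c("A", "V"),
                  paste0(base, suffixes[3L])))
  out <- lapply(plans, function(pl) apply_mutations(parent, pl))
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Write enzyme variants as FASTA with lineage in the description
#'
#' @param variants List of \code{\link{enzyme_variant}} objects.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_variants <- function(variants, path) {
  desc <- vapply(variants, function(v) {
    lin <- if (is.null(v$lineage)) "de-novo" else
      paste0("parent=", v$lineage$parent, " plan=",
             paste(sprintf("%s%d%s", v$lineage$plan$from_residue,
                           v$lineage$plan$position,
                           v$lineage$plan$to_residue), collapse = ","))
    paste0(v$name, " ", v$classification, " ", lin)
  }, character(1))
  ss <- Biostrings::AAStringSet(vapply(variants, `[[`, character(1),
                                       "sequence"))
  names(ss) <- desc
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
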