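# Consensus design from an aligned legumain family: per-column occupancy
# and conservation profiling, occupancy-threshold trimming, reference
# numbering maps, and assembly of the tagged expression construct.
#
# Coordinate systems are kept strictly apart: alignment columns (1-based
# over the MSA), consensus positions (1-based over kept columns) and
# reference residue numbers (1-based over the ungapped reference sequence).

.GAPS <- c("-", ".")
.EXTENDED <- c("X", "B", "Z", "U")  # count toward occupancy, never designable
.ALPHABET <- c(.AA20, .EXTENDED)
# deterministic consensus tie-break order; extended codes last so they can
# only win a column containing nothing else
.TIE_ORDER <- c(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1L]], .EXTENDED)

#' Construct an aligned protein family
#'
#' @param ids Character vector of sequence identifiers.
#' @param seqs Character vector of gapped sequences (equal lengths; gaps
#'   \code{-} or \code{.}, the latter normalized to \code{-}; lowercase
#'   uppercased).
#' @return An object of class \code{"aligned_family"} with elements
#'   \code{ids}, \code{seqs} and \code{alignment_length}.
#' @export
aligned_family <- function(ids, seqs) {
  stopifnot(is.character(ids), is.character(seqs),
            length(ids) == length(seqs), length(ids) >= 1L)
  seqs <- chartr(".", "-", toupper(seqs))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    off <- which(lens != lens[1L])[1L]
    stop("record ", off, " ('", ids[off], "') has length ", lens[off],
         ", expected ", lens[1L], call. = FALSE)
  }
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    bad <- which(!chars %in% c(.ALPHABET, "-"))
    if (length(bad))
      stop("illegal symbol '", chars[bad[1L]], "' in record '", ids[i],
           "' at column ", bad[1L], call. = FALSE)
  }
  structure(list(ids = ids, seqs = unname(seqs),
                 alignment_length = lens[1L]),
            class = "aligned_family")
}

#' @export
print.aligned_family <- function(x, ...) {
  cat("<aligned_family> ", length(x$ids), " sequences x ",
      x$alignment_length, " columns\n", sep = "")
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Ragged alignments and symbols outside the 20 standard codes plus
#' X/B/Z/U and gap characters are rejected with the offending record named.
#'
#' @param path Path to an aligned FASTA file.
#' @return An \code{\link{aligned_family}}.
#' @export
parse_alignment <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  aligned_family(names(ss), as.character(ss))
}

#' Write an aligned family as FASTA
#'
#' @param family An \code{\link{aligned_family}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_alignment <- function(family, path) {
  ss <- Biostrings::BStringSet(family$seqs)
  names(ss) <- family$ids
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# alignment as a character matrix (rows = sequences)
.family_matrix <- function(family) {
  matrix(unlist(strsplit(family$seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(family$seqs), byrow = TRUE)
}

#' Per-column occupancy/conservation profiles
#'
#' Occupancy is the non-gap fraction of a column; conservation is the modal
#' fraction among non-gap symbols; the consensus residue is the most common
#' designable residue (ties broken by a fixed order; X/B/Z/U count toward
#' occupancy but can only become consensus in a column containing nothing
#' else; an all-gap column has consensus \code{NA}).
#'
#' @param family An \code{\link{aligned_family}}.
#' @return A data frame with one row per alignment column: \code{column},
#'   \code{occupancy}, \code{conservation}, \code{consensus}, and a
#'   list-column \code{counts} of named residue-count vectors.
#' @export
compute_column_profiles <- function(family) {
  stopifnot(inherits(family, "aligned_family"))
  mat <- .family_matrix(family)
  nseq <- nrow(mat)
  prof <- lapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    res <- col[col != "-"]
    occ <- length(res) / nseq
    if (!length(res))
      return(list(occupancy = 0, conservation = NA_real_,
                  consensus = NA_character_, counts = integer(0)))
    counts <- table(factor(res, levels = .TIE_ORDER))
    counts <- counts[counts > 0L]
    eligible <- counts[!names(counts) %in% .EXTENDED]
    pool <- if (length(eligible)) eligible else counts
    # which.max on a table ordered by .TIE_ORDER gives the tie-break for free
    cons <- names(pool)[which.max(pool)]
    list(occupancy = occ,
         conservation = max(counts) / length(res),
         consensus = cons,
         counts = c(counts))
  })
  out <- data.frame(
    column = seq_len(family$alignment_length),
    occupancy = vapply(prof, `[[`, numeric(1), "occupancy"),
    conservation = vapply(prof, `[[`, numeric(1), "conservation"),
    consensus = vapply(prof, `[[`, character(1), "consensus"),
    stringsAsFactors = FALSE)
  out$counts <- lapply(prof, `[[`, "counts")
  out
}

#' Build the occupancy-trimmed consensus
#'
#' Keeps exactly the columns whose occupancy is at or above the threshold
#' (strictly-below-threshold columns are removed: at the default 0.10,
#' a column at exactly 10\% occupancy is kept) and concatenates their
#' consensus residues.
#'
#' @param profiles Output of \code{\link{compute_column_profiles}}.
#' @param threshold Occupancy threshold in (0, 1]; default 0.10.
#' @return An object of class \code{"consensus_result"}: \code{profiles},
#'   \code{occupancy_threshold}, \code{consensus_sequence},
#'   \code{kept_columns} and \code{column_to_position} (named integer map
#'   from alignment column to 1-based consensus position).
#' @export
build_consensus <- function(profiles, threshold = 0.10) {
  stopifnot(is.data.frame(profiles),
            all(c("column", "occupancy", "consensus") %in% names(profiles)))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]", call. = FALSE)
  keep <- profiles$occupancy >= threshold & !is.na(profiles$consensus)
  kept <- profiles$column[keep]
  cons <- paste(profiles$consensus[keep], collapse = "")
  map <- seq_along(kept)
  names(map) <- kept
  structure(list(profiles = profiles, occupancy_threshold = threshold,
                 consensus_sequence = cons, kept_columns = kept,
                 column_to_position = map),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("<consensus_result> ", nchar(x$consensus_sequence), " residues kept of ",
      nrow(x$profiles), " columns (occupancy >= ", x$occupancy_threshold,
      ")\n", sep = "")
  invisible(x)
}

#' Map alignment columns to a reference sequence's numbering
#'
#' Every column where the reference member is non-gap is paired with the
#' reference's 1-based ungapped residue number. When a consensus is
#' supplied, a consensus-position to reference-number lookup restricted to
#' kept columns is included (columns where the reference is gapped resolve
#' to NA, not an error).
#'
#' @param family An \code{\link{aligned_family}} containing the reference.
#' @param reference_id Identifier of the reference member.
#' @param consensus Optional \code{\link{consensus_result}} from the same
#'   family.
#' @return An object of class \code{"reference_map"}: \code{reference_id},
#'   \code{pairs} (data frame: column, ref_number, ref_residue) and, when a
#'   consensus is given, \code{consensus_to_reference} (data frame:
#'   consensus_position, ref_number — NA where the reference is gapped).
#' @export
map_to_reference <- function(family, reference_id, consensus = NULL) {
  stopifnot(inherits(family, "aligned_family"))
  idx <- match(reference_id, family$ids)
  if (is.na(idx))
    stop("reference '", reference_id, "' not found in the family",
         call. = FALSE)
  chars <- strsplit(family$seqs[idx], "", fixed = TRUE)[[1L]]
  nongap <- chars != "-"
  pairs <- data.frame(column = which(nongap),
                      ref_number = seq_len(sum(nongap)),
                      ref_residue = chars[nongap],
                      stringsAsFactors = FALSE)
  out <- list(reference_id = reference_id, pairs = pairs)
  if (!is.null(consensus)) {
    stopifnot(inherits(consensus, "consensus_result"))
    ref_at_col <- rep(NA_integer_, family$alignment_length)
    ref_at_col[pairs$column] <- pairs$ref_number
    out$consensus_to_reference <- data.frame(
      consensus_position = seq_along(consensus$kept_columns),
      ref_number = ref_at_col[consensus$kept_columns])
  }
  structure(out, class = "reference_map")
}

#' Look up the consensus position of a reference residue number
#'
#' @param map A \code{\link{map_to_reference}} result built with a
#'   consensus.
#' @param ref_number Reference residue number(s).
#' @return Integer consensus position(s); NA where the reference residue
#'   falls in a trimmed column.
#' @export
reference_to_consensus <- function(map, ref_number) {
  stopifnot(inherits(map, "reference_map"),
            !is.null(map$consensus_to_reference))
  ctr <- map$consensus_to_reference
  ctr$consensus_position[match(ref_number, ctr$ref_number)]
}

#' Region annotations over consensus coordinates
#'
#' @param name Character vector of region names, each one of
#'   \code{signal_peptide}, \code{prodomain_nonconserved},
#'   \code{prodomain_conserved}, \code{core}, \code{cap},
#'   \code{c_terminal_tail}.
#' @param start,end 1-based inclusive consensus-position bounds.
#' @return A validated data frame of regions (non-overlapping, ordered).
#' @export
region_annotation <- function(name, start, end) {
  valid <- c("signal_peptide", "prodomain_nonconserved",
             "prodomain_conserved", "core", "cap", "c_terminal_tail")
  bad <- setdiff(name, valid)
  if (length(bad)) stop("unknown region name(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  df <- data.frame(name = name, start = as.integer(start),
                   end = as.integer(end), stringsAsFactors = FALSE)
  if (any(df$end < df$start)) stop("region end before start", call. = FALSE)
  df <- df[order(df$start), , drop = FALSE]
  if (nrow(df) > 1L && any(df$start[-1L] <= df$end[-nrow(df)])) {
    i <- which(df$start[-1L] <= df$end[-nrow(df)])[1L]
    stop("regions overlap: '", df$name[i], "' and '", df$name[i + 1L], "'",
         call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Assemble the tagged expression construct
#'
#' Replaces the signal peptide plus nonconserved prodomain with an
#' N-terminal tag, and the tail after the designated conserved position
#' (the start of the \code{c_terminal_tail} region minus one) with a
#' C-terminal tag:
#' \code{construct = n_tag + consensus[keep_start..keep_end] + c_tag} where
#' \code{keep_start} is the start of \code{prodomain_conserved} (1 if that
#' region is absent) and \code{keep_end} is \code{c_terminal_tail$start - 1}
#' (the consensus end if absent). The edit log replays exactly.
#'
#' @param consensus A \code{\link{consensus_result}} or plain sequence.
#' @param regions A \code{\link{region_annotation}} data frame (may be
#'   empty).
#' @param n_tag,c_tag Tag sequences (default His6, \code{"HHHHHH"}).
#' @return An object of class \code{"construct_design"}: \code{sequence},
#'   \code{edits} (ordered data frame of operation, start, end, inserted),
#'   \code{n_tag}, \code{c_tag}, \code{source_sequence}.
#' @export
assemble_construct <- function(consensus, regions = NULL,
                               n_tag = "HHHHHH", c_tag = "HHHHHH") {
  src <- if (inherits(consensus, "consensus_result"))
    consensus$consensus_sequence else consensus
  stopifnot(is.character(src), length(src) == 1L)
  n <- nchar(src)
  if (is.null(regions))
    regions <- data.frame(name = character(0), start = integer(0),
                          end = integer(0))
  if (nrow(regions) && any(regions$end > n | regions$start < 1L)) {
    i <- which(regions$end > n | regions$start < 1L)[1L]
    stop("region '", regions$name[i], "' out of bounds for consensus of ",
         n, " residues", call. = FALSE)
  }
  keep_start <- if ("prodomain_conserved" %in% regions$name)
    regions$start[regions$name == "prodomain_conserved"] else 1L
  keep_end <- if ("c_terminal_tail" %in% regions$name)
    regions$start[regions$name == "c_terminal_tail"] - 1L else n
  if (keep_end < keep_start)
    stop("kept span is empty: conserved prodomain starts at ", keep_start,
         " but the C-terminal tail starts at ", keep_end + 1L,
         call. = FALSE)
  edits <- data.frame(operation = character(0), start = integer(0),
                      end = integer(0), inserted = character(0),
                      stringsAsFactors = FALSE)
  seq <- src
  # C-terminal replacement first: spans before it keep their coordinates
  if (keep_end < n || nzchar(c_tag)) {
    seq <- paste0(substr(seq, 1L, keep_end), c_tag)
    edits <- rbind(edits, data.frame(
      operation = "replace_c_terminus", start = keep_end + 1L,
      end = n, inserted = c_tag, stringsAsFactors = FALSE))
  }
  if (keep_start > 1L || nzchar(n_tag)) {
    seq <- paste0(n_tag, substr(seq, keep_start, nchar(seq)))
    edits <- rbind(edits, data.frame(
      operation = "replace_n_terminus", start = 1L,
      end = keep_start - 1L, inserted = n_tag, stringsAsFactors = FALSE))
  }
  structure(list(sequence = seq, edits = edits, n_tag = n_tag,
                 c_tag = c_tag, source_sequence = src),
            class = "construct_design")
}

#' Replay a construct's edit log on its source sequence
#'
#' @param design A \code{\link{assemble_construct}} result.
#' @param source Source sequence (defaults to the one stored in the
#'   design).
#' @return The reconstructed construct sequence.
#' @export
replay_edits <- function(design, source = design$source_sequence) {
  seq <- source
  ed <- design$edits
  for (i in seq_len(nrow(ed))) {
    pre <- if (ed$start[i] > 1L) substr(seq, 1L, ed$start[i] - 1L) else ""
    post <- if (ed$end[i] < nchar(seq))
      substr(seq, ed$end[i] + 1L, nchar(seq)) else ""
    seq <- paste0(pre, ed$inserted[i], post)
  }
  seq
}

#' Write per-column profiles as a delimited table
#'
#' @param profiles Output of \code{\link{compute_column_profiles}}.
#' @param path Output path (tab-separated; counts serialized as
#'   \code{res:count} pairs).
#' @return \code{path}, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  df <- profiles
  df$counts <- vapply(df$counts, function(ct)
    paste(sprintf("%s:%d", names(ct), ct), collapse = ","), character(1))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
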