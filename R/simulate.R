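# Synthetic-data generators with known ground truth.
#
# The real 1500-member legumain family behind the consensus design is not
# deposited, so every input class the pipeline consumes can be simulated
# here: aligned families with a truth consensus, high-occupancy conserved
# cores and sparse insert columns; LAD-labelled variant sets; noisy
# Michaelis-Menten rate tables; and pH-dependent product profiles. All
# randomness flows from one explicit seed per call; the caller's RNG state
# is untouched.

# evaluate code under a local RNG seeded with `seed`
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Specify a synthetic aligned family
#'
#' @param truth_consensus Truth consensus sequence (20 standard codes).
#' @param n_sequences Number of family members.
#' @param per_column_conservation Probability, per truth column, that a
#'   member carries the truth residue (otherwise uniform over the other
#'   19). Scalar or one value per column.
#' @param insert_blocks List of \code{list(anchor, length, carrier_fraction)}:
#'   an insert of \code{length} columns placed after truth column
#'   \code{anchor}, carried (non-gap, random residues) by approximately
#'   \code{carrier_fraction} of members and gapped in the rest.
#' @param seed Integer seed.
#' @return A validated list of class \code{"family_spec"}.
#' @export
family_spec <- function(truth_consensus, n_sequences,
                        per_column_conservation = 0.9,
                        insert_blocks = list(), seed = 1L) {
  chars <- strsplit(toupper(truth_consensus), "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% .AA20)
  if (length(bad))
    stop("truth_consensus has nonstandard residue at position ", bad[1L],
         call. = FALSE)
  n_col <- length(chars)
  cons <- rep_len(per_column_conservation, n_col)
  stopifnot(all(cons >= 0 & cons <= 1), n_sequences >= 1L)
  for (b in insert_blocks) {
    stopifnot(all(c("anchor", "length", "carrier_fraction") %in% names(b)))
    if (b$anchor < 0L || b$anchor > n_col)
      stop("insert block anchored at column ", b$anchor,
           " falls outside the ", n_col, "-column truth sequence",
           call. = FALSE)
    stopifnot(b$length >= 1L, b$carrier_fraction >= 0,
              b$carrier_fraction < 1)
  }
  structure(list(truth_consensus = paste(chars, collapse = ""),
                 n_sequences = as.integer(n_sequences),
                 per_column_conservation = cons,
                 insert_blocks = insert_blocks, seed = as.integer(seed)),
            class = "family_spec")
}

#' Generate an aligned family with known truth
#'
#' Core columns carry the truth residue with the stated per-column
#' conservation; insert-block columns are random residues in carrier rows
#' and gaps elsewhere. Deterministic for a fixed seed.
#'
#' @param spec A \code{\link{family_spec}}.
#' @return A list: \code{family} (an \code{\link{aligned_family}}) and
#'   \code{truth} with \code{consensus}, per-alignment-column
#'   \code{occupancy} (realized non-gap fraction), \code{is_insert}
#'   (logical per column) and \code{core_columns} (alignment columns of
#'   the truth residues, in order).
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  with_seed(spec$seed, {
    truth <- strsplit(spec$truth_consensus, "", fixed = TRUE)[[1L]]
    n_core <- length(truth)
    n <- spec$n_sequences
    # column plan in final alignment order: truth column index, or an
    # insert block id (blocks placed after their anchor, stably by anchor)
    blocks <- spec$insert_blocks
    anchors <- vapply(blocks, function(b) as.integer(b$anchor), integer(1))
    plan <- data.frame(kind = rep("core", n_core),
                       which = seq_len(n_core))
    for (k in order(anchors, decreasing = TRUE)) {
      at <- anchors[k]  # truth column after which the block sits
      pos <- if (at == 0L) 0L else which(plan$kind == "core" &
                                           plan$which == at)
      ins <- data.frame(kind = rep("insert", blocks[[k]]$length),
                        which = k)
      top <- plan[seq_len(pos), , drop = FALSE]
      bot <- if (pos < nrow(plan))
        plan[(pos + 1L):nrow(plan), , drop = FALSE] else plan[0L, ]
      plan <- rbind(top, ins, bot)
    }
    # carrier rows per block (one Bernoulli draw per row per block)
    carriers <- lapply(blocks, function(b)
      stats::runif(n) < b$carrier_fraction)
    mat <- matrix("-", nrow = n, ncol = nrow(plan))
    for (j in seq_len(nrow(plan))) {
      if (plan$kind[j] == "core") {
        tj <- plan$which[j]
        hit <- stats::runif(n) < spec$per_column_conservation[tj]
        col <- rep(truth[tj], n)
        if (any(!hit))
          col[!hit] <- sample(setdiff(.AA20, truth[tj]), sum(!hit),
                              replace = TRUE)
        mat[, j] <- col
      } else {
        cr <- carriers[[plan$which[j]]]
        if (any(cr))
          mat[cr, j] <- sample(.AA20, sum(cr), replace = TRUE)
      }
    }
    is_insert <- plan$kind == "insert"
    occupancy <- colMeans(mat != "-")
    fam <- aligned_family(sprintf("syn%04d", seq_len(n)),
                          apply(mat, 1L, paste, collapse = ""))
    list(family = fam,
         truth = list(consensus = spec$truth_consensus,
                      occupancy = occupancy,
                      is_insert = is_insert,
                      core_columns = which(!is_insert)))
  })
}

#' Generate LAD-labelled variant sequences
#'
#' Emits \code{n_per_class} AEP-like sequences (Gly retained at both LAD
#' positions) and \code{n_per_class} PAL-like sequences (LAD mutations
#' cycling through double, LAD1-only and LAD2-only patterns, so a single
#' PAL variant is the double mutant). Neutral background substitutions at
#' \code{background_rate} per residue never touch the LAD positions or any
#' \code{protected} positions, so the labels stay valid.
#'
#' @param base Base protein sequence with Gly at both LAD positions.
#' @param lad_positions Two positions (subject coordinates), LAD1 then
#'   LAD2.
#' @param n_per_class Variants per class (0 gives an empty set).
#' @param seed Integer seed.
#' @param background_rate Per-residue background substitution probability
#'   (default 0.01).
#' @param protected Additional positions never mutated (e.g. the catalytic
#'   triad).
#' @return A data frame: \code{name}, \code{label} (\code{"AEP-like"} /
#'   \code{"PAL-like"}), \code{sequence}, \code{lad1}, \code{lad2}
#'   (residues at the LAD positions).
#' @export
generate_lad_variants <- function(base, lad_positions, n_per_class,
                                  seed = 1L, background_rate = 0.01,
                                  protected = integer(0)) {
  stopifnot(length(lad_positions) == 2L, n_per_class >= 0L)
  base <- toupper(base)
  for (i in 1:2)
    if (substring(base, lad_positions[i], lad_positions[i]) != "G")
      stop("base lacks Gly at LAD position ", lad_positions[i],
           " (found '",
           substring(base, lad_positions[i], lad_positions[i]), "')",
           call. = FALSE)
  if (n_per_class == 0L)
    return(data.frame(name = character(0), label = character(0),
                      sequence = character(0), lad1 = character(0),
                      lad2 = character(0), stringsAsFactors = FALSE))
  with_seed(seed, {
    untouchable <- c(lad_positions, protected)
    mutate_background <- function(seq) {
      chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
      hit <- which(stats::runif(length(chars)) < background_rate)
      hit <- setdiff(hit, untouchable)
      for (i in hit)
        chars[i] <- sample(setdiff(.AA20, chars[i]), 1L)
      paste(chars, collapse = "")
    }
    pal_patterns <- c("both", "lad1", "lad2")
    rows <- list()
    for (k in seq_len(n_per_class)) {
      rows[[length(rows) + 1L]] <-
        c(sprintf("AEP_%03d", k), "AEP-like", mutate_background(base))
    }
    for (k in seq_len(n_per_class)) {
      seq <- base
      pat <- pal_patterns[(k - 1L) %% 3L + 1L]
      if (pat %in% c("both", "lad1"))
        substring(seq, lad_positions[1L], lad_positions[1L]) <- "V"
      if (pat %in% c("both", "lad2"))
        substring(seq, lad_positions[2L], lad_positions[2L]) <- "A"
      rows[[length(rows) + 1L]] <-
        c(sprintf("PAL_%03d", k), "PAL-like", mutate_background(seq))
    }
    out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(out) <- c("name", "label", "sequence")
    out$lad1 <- substring(out$sequence, lad_positions[1L],
                          lad_positions[1L])
    out$lad2 <- substring(out$sequence, lad_positions[2L],
                          lad_positions[2L])
    out
  })
}

#' Specify a simulated rate experiment
#'
#' @param kcat_true Turnover number, 1/s.
#' @param km_true Michaelis constant, uM.
#' @param enzyme_conc Enzyme concentration, molar (default 10 nM as in
#'   standard kinetic assays here).
#' @param substrate_concs Substrate series, uM (default
#'   \code{c(1, 2, 5, 10, 20, 40, 70, 100)}, spanning 1-100 uM).
#' @param noise_cv Coefficient of variation of the multiplicative Gaussian
#'   rate noise (default 0.02).
#' @param seed Integer seed.
#' @return A validated list of class \code{"rate_spec"}.
#' @export
rate_spec <- function(kcat_true, km_true, enzyme_conc = 10e-9,
                      substrate_concs = c(1, 2, 5, 10, 20, 40, 70, 100),
                      noise_cv = 0.02, seed = 1L) {
  stopifnot(kcat_true > 0, km_true > 0, enzyme_conc > 0,
            all(substrate_concs > 0), noise_cv >= 0)
  structure(list(kcat_true = kcat_true, km_true = km_true,
                 enzyme_conc = enzyme_conc,
                 substrate_concs = substrate_concs,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "rate_spec")
}

#' Generate a noisy Michaelis-Menten rate table
#'
#' \code{v = kcat * E0 * S / (KM + S)} times multiplicative Gaussian noise
#' with the stated CV, truncated at zero. Deterministic for a fixed seed.
#'
#' @param spec A \code{\link{rate_spec}}.
#' @return Data frame with columns \code{substrate_uM} and
#'   \code{rate_uM_per_s}.
#' @export
generate_rate_data <- function(spec) {
  stopifnot(inherits(spec, "rate_spec"))
  with_seed(spec$seed, {
    e0_uM <- spec$enzyme_conc * 1e6
    s <- spec$substrate_concs
    v <- spec$kcat_true * e0_uM * s / (spec$km_true + s)
    if (spec$noise_cv > 0)
      v <- pmax(0, v * (1 + stats::rnorm(length(v), 0, spec$noise_cv)))
    data.frame(substrate_uM = s, rate_uM_per_s = v)
  })
}

#' Generate pH-dependent product-distribution profiles
#'
#' The C/H ratio follows a logistic curve in pH,
#' \code{r(pH) = r_max / (1 + exp(-slope * (pH - midpoint)))}, mirroring
#' the empirical rise of cyclization over hydrolysis with pH; a slope of 0
#' gives the same ratio everywhere. A fixed converted fraction is split
#' between cyclized and hydrolyzed according to the ratio, so percentages
#' sum exactly to 100 and round-trip through
#' \code{\link{quantify_products}}.
#'
#' @param ph_grid pH values.
#' @param ch_midpoint_ph Midpoint of the logistic (default 6.5).
#' @param ch_slope Logistic slope per pH unit (default 2).
#' @param ch_max Asymptotic C/H ratio (default 25).
#' @param converted_fraction Fraction of substrate converted at each pH
#'   (default 0.45).
#' @param seed Integer seed (reserved; the profile itself is
#'   deterministic).
#' @return Data frame: \code{pH}, \code{percent_hydrolyzed},
#'   \code{percent_cyclized}, \code{percent_remaining}, \code{ch_ratio}.
#' @export
generate_product_profiles <- function(ph_grid, ch_midpoint_ph = 6.5,
                                      ch_slope = 2, ch_max = 25,
                                      converted_fraction = 0.45,
                                      seed = 1L) {
  stopifnot(all(ph_grid > 0), ch_max > 0,
            converted_fraction >= 0, converted_fraction <= 1)
  r <- ch_max / (1 + exp(-ch_slope * (ph_grid - ch_midpoint_ph)))
  conv <- 100 * converted_fraction
  data.frame(pH = ph_grid,
             percent_hydrolyzed = conv / (1 + r),
             percent_cyclized = conv * r / (1 + r),
             percent_remaining = 100 - conv,
             ch_ratio = r)
}

#' Write a rate table as delimited text
#'
#' @param rates Output of \code{\link{generate_rate_data}}.
#' @param path Output path (comma-separated with header
#'   \code{substrate_uM,rate_uM_per_s}).
#' @return \code{path}, invisibly.
#' @export
write_rate_table <- function(rates, path) {
  utils::write.csv(rates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write family truth metadata as a sidecar table
#'
#' @param truth Truth record from \code{\link{generate_family}}.
#' @param path Output path (tab-separated: column, occupancy, is_insert).
#' @return \code{path}, invisibly.
#' @export
write_family_truth <- function(truth, path) {
  utils::write.table(
    data.frame(column = seq_along(truth$occupancy),
               occupancy = truth$occupancy,
               is_insert = truth$is_insert),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
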