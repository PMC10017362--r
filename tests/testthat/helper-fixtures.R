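# Shared fixtures and independent oracles for the test suite.

AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1L]]

random_sequence <- function(len) paste(sample(AA20, len, replace = TRUE),
                                       collapse = "")

# random gapped family for oracle-equivalence checks
random_family <- function(n_seq, n_col, gap_prob = 0.2) {
  seqs <- vapply(seq_len(n_seq), function(i) {
    chars <- sample(AA20, n_col, replace = TRUE)
    chars[runif(n_col) < gap_prob] <- "-"
    paste(chars, collapse = "")
  }, character(1))
  aligned_family(sprintf("s%03d", seq_len(n_seq)), seqs)
}

# Brute-force per-column profile oracle: counts characters one cell at a
# time via substring, independent of the package's matrix path.
oracle_profiles <- function(family) {
  n_seq <- length(family$seqs)
  lapply(seq_len(family$alignment_length), function(j) {
    col <- vapply(family$seqs, substring, character(1), j, j,
                  USE.NAMES = FALSE)
    res <- col[col != "-"]
    if (!length(res))
      return(list(occupancy = 0, conservation = NA_real_,
                  consensus = NA_character_))
    tab <- table(res)
    top <- names(tab)[tab == max(tab)]
    tie_order <- c(AA20, c("X", "B", "Z", "U"))
    designable <- setdiff(top, c("X", "B", "Z", "U"))
    pool <- if (length(setdiff(names(tab), c("X", "B", "Z", "U")))) {
      dtab <- tab[setdiff(names(tab), c("X", "B", "Z", "U"))]
      names(dtab)[dtab == max(dtab)]
    } else top
    list(occupancy = length(res) / n_seq,
         conservation = max(tab) / length(res),
         consensus = pool[order(match(pool, tie_order))][1L])
  })
}

# independent residue-mass oracle (summed per character, different tables
# object from the package internals)
ORACLE_MONO <- c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
                 V = 99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
                 I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
                 K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
                 F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

oracle_mono_linear <- function(seq)
  sum(ORACLE_MONO[strsplit(seq, "")[[1L]]]) + 18.010565
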