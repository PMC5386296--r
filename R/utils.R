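#' Residue class alphabet
#'
#' The 23 residue classes over which interface pair-potentials are defined:
#' the 20 standard amino acids (one-letter codes) plus the phosphorylated
#' forms pS, pT and pY.
#'
#' @return Character vector of length 23.
#' @export
residue_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
    "F", "P", "S", "T", "W", "Y", "V", "pS", "pT", "pY")
}

#' Map an amino acid and phospho flag to a residue class
#'
#' @param aa One-letter amino acid code(s).
#' @param phospho Logical flag(s); `TRUE` folds S/T/Y into pS/pT/pY.
#' @return Character vector of residue classes.
#' @export
residue_class <- function(aa, phospho = FALSE) {
  aa <- as.character(aa)
  phospho <- rep_len(as.logical(phospho), length(aa))
  bad <- !(aa %in% residue_alphabet()[1:20])
  if (any(bad)) {
    stop("unknown residue class: ", paste(unique(aa[bad]), collapse = ", "))
  }
  if (any(phospho & !(aa %in% c("S", "T", "Y")))) {
    stop("phospho flag is only valid for S, T or Y residues")
  }
  ifelse(phospho, paste0("p", aa), aa)
}

#' Default configuration for the switch-prediction pipeline
#'
#' All tunable constants in one place.  `contact_cutoff` is the maximum
#' heavy-atom distance (\eqn{\le}, in Angstrom) defining a residue-residue
#' interface contact; `asa_buried_cutoff` the side-chain accessible surface
#' area (Angstrom^2) below which (strictly) a residue is called buried;
#' `disorder_window`/`disorder_cutoff` define the sliding-window mean rule
#' for intrinsic disorder; `gap_fraction_cutoff` excludes poorly aligned
#' sequences from redundancy grouping; `switch_threshold` is the |S_switch|
#' at or beyond which a site is called enabling/disabling; `target_fpr` the
#' false-positive-rate bound used for benchmark threshold selection;
#' `n_shuffles` the number of shuffled negatives generated per positive;
#' `cv_folds`/`cv_reps` control the cross-validated logistic regression;
#' `pseudocount` is the per-pair count added before pair-potential
#' estimation; `homolog_interface_rule` gives the (identity, coverage,
#' shared-interface) fractions for homologous-interface matching.
#'
#' @param ... Named overrides of any default.
#' @return A named list of class `"phosphoswitch_config"`.
#' @export
switch_config <- function(...) {
  cfg <- list(
    contact_cutoff = 5.0,
    asa_buried_cutoff = 5.0,
    disorder_window = 11L,
    disorder_cutoff = 0.5,
    gap_fraction_cutoff = 0.09,
    switch_threshold = 1.7,
    target_fpr = 0.05,
    n_shuffles = 10L,
    cv_folds = 5L,
    cv_reps = 100L,
    pseudocount = 1,
    homolog_interface_rule = c(identity = 0.5, coverage = 0.5, shared = 0.5),
    master_seed = 1L
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  stopifnot(cfg$contact_cutoff > 0, cfg$asa_buried_cutoff > 0,
            cfg$disorder_window >= 1, cfg$switch_threshold > 0,
            cfg$target_fpr >= 0, cfg$target_fpr <= 1,
            cfg$gap_fraction_cutoff >= 0, cfg$gap_fraction_cutoff <= 1,
            cfg$pseudocount >= 0)
  class(cfg) <- "phosphoswitch_config"
  cfg
}

#' Read an aligned FASTA file
#'
#' @param path File path.
#' @return Named character vector of gapped sequences (all equal length).
#' @export
read_alignment <- function(path) {
  x <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  if (length(unique(nchar(seqs))) > 1) {
    stop("sequences in ", path, " have unequal aligned lengths")
  }
  seqs
}

#' Write an aligned FASTA file
#'
#' @param seqs Named character vector of gapped sequences.
#' @param path File path.
#' @export
write_alignment <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

# Column index in a gapped sequence of its `pos`-th ungapped residue,
# or NA if pos exceeds the ungapped length.
.ungapped_to_column <- function(gapped, pos) {
  chars <- strsplit(gapped, "")[[1]]
  idx <- which(chars != "-" & chars != ".")
  if (pos < 1 || pos > length(idx)) return(NA_integer_)
  idx[pos]
}

.read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
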