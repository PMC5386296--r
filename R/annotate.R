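#' Map a sequence site onto a template chain through a pairwise alignment
#'
#' Positional information is transferred through the alignment even when
#' the aligned amino acids differ; a site aligned to a template gap maps to
#' nothing.
#'
#' @param pos 1-based position of the site in the (ungapped) query
#'   sequence.
#' @param alignment List with gapped strings `query` and `template`.
#' @param template_positions Optional vector of author residue numbers for
#'   the template chain (1-based ungapped order); defaults to 1..n.
#' @return List with `template_pos` (author number), `template_aa`, and
#'   `identical` (query and template amino acid agree), or `NULL` when the
#'   site falls on a template gap.
#' @export
map_site_to_template <- function(pos, alignment, template_positions = NULL) {
  q <- strsplit(toupper(alignment$query), "")[[1]]
  t <- strsplit(toupper(alignment$template), "")[[1]]
  if (length(q) != length(t)) stop("alignment rows differ in length")
  gap <- c("-", ".")
  qlen <- sum(!(q %in% gap))
  if (pos < 1 || pos > qlen) {
    stop("site position ", pos, " outside the aligned query (length ",
         qlen, ")")
  }
  col <- .ungapped_to_column(alignment$query, pos)
  if (t[col] %in% gap) return(NULL)
  tpos <- sum(!(t[seq_len(col)] %in% gap))
  if (!is.null(template_positions)) tpos <- template_positions[tpos]
  list(template_pos = tpos, template_aa = t[col],
       identical = identical(q[col], t[col]))
}

#' Minimum fraction of identical residues against the structural template
#'
#' For each interacting protein, the fraction of identical residues over
#' the aligned (gap-free) columns of its alignment with its template chain;
#' f_ID is the minimum of the two.  For a homodimer the two alignments
#' coincide and one may be supplied.
#'
#' @param aln_chain1,aln_chain2 Pairwise alignments (lists with gapped
#'   `query` and `template`); `aln_chain2` may be omitted for homodimers.
#' @return f_ID in \[0, 1\].
#' @export
fraction_identity <- function(aln_chain1, aln_chain2 = NULL) {
  one <- function(aln) {
    s <- .aln_stats(aln$query, aln$template)
    if (s$n_aligned == 0) stop("alignment has no aligned columns")
    s$identity
  }
  if (is.null(aln_chain2)) one(aln_chain1)
  else min(one(aln_chain1), one(aln_chain2))
}

#' Orthologue conservation fraction at a site
#'
#' f_Cons is the fraction of sequences in the orthologue-group alignment
#' that carry the site's amino acid, or Aspartate or Glutamate (the
#' phosphomimetic residues), at the site's alignment column.  Sequences
#' gapped at the column count in the denominator only.  When the protein is
#' not covered by any group alignment the species-average f_Cons over all
#' S/T/Y sites is used instead (`fallback_used = TRUE`).
#'
#' @param group_alignment Named character vector of gapped sequences (an
#'   orthologue group alignment), or `NULL` when no group covers the
#'   protein.
#' @param protein_acc Identifier of the query protein within the alignment.
#' @param pos 1-based ungapped position of the site in the query protein.
#' @param wild_aa Site amino acid (S, T or Y).
#' @param species_average Fallback f_Cons when the protein is in no group.
#' @return List of class `"orthology_profile"`: `n_sequences`, `column`
#'   (residue composition), `f_Cons`, `fallback_used`.
#' @export
conservation_fraction <- function(group_alignment, protein_acc, pos,
                                  wild_aa, species_average = NA_real_) {
  if (is.null(group_alignment) || !(protein_acc %in% names(group_alignment))) {
    if (is.na(species_average)) {
      stop("protein ", protein_acc,
           " not in any group alignment and no species average supplied")
    }
    return(structure(list(group_id = NA_character_, n_sequences = 0L,
                          column = character(), f_Cons = species_average,
                          fallback_used = TRUE),
                     class = "orthology_profile"))
  }
  col <- .ungapped_to_column(group_alignment[[protein_acc]], pos)
  if (is.na(col)) {
    stop("position ", pos, " beyond the ungapped length of ", protein_acc)
  }
  column <- toupper(substr(group_alignment, col, col))
  n <- length(group_alignment)
  f <- sum(column %in% c(wild_aa, "D", "E")) / n
  structure(list(group_id = attr(group_alignment, "group_id") %||%
                   NA_character_,
                 n_sequences = n, column = column, f_Cons = f,
                 fallback_used = FALSE),
            class = "orthology_profile")
}

#' Classify a residue as intrinsically disordered
#'
#' A site is disordered when the mean per-residue disorder score over a
#' sliding window centred on the site (default 11 residues, truncated at
#' the termini) is at least the cutoff (inclusive).
#'
#' @param scores Numeric vector of per-residue disorder propensities in
#'   \[0, 1\] covering the protein (index = sequence position).
#' @param pos Site position.
#' @param window Window width in residues (odd).
#' @param cutoff Mean-score cutoff.
#' @return `TRUE`/`FALSE`, or `NA` when scores in the window are missing.
#' @export
classify_disorder <- function(scores, pos, window = 11L, cutoff = 0.5) {
  stopifnot(window >= 1, pos >= 1, pos <= length(scores))
  half <- (window - 1L) %/% 2L
  win <- scores[max(1L, pos - half):min(length(scores), pos + half)]
  if (anyNA(win)) return(NA)
  mean(win) >= cutoff
}

#' Classify surface exposure from side-chain accessible surface area
#'
#' Buried when the side-chain ASA is strictly below the cutoff
#' (5 Angstrom^2 by default); exposed otherwise.
#'
#' @param asa Side-chain accessible surface area (Angstrom^2).
#' @param cutoff Burial cutoff.
#' @return `"buried"` or `"exposed"`; `NA` for unset ASA.
#' @export
classify_exposure <- function(asa, cutoff = 5.0) {
  ifelse(is.na(asa), NA_character_,
         ifelse(asa < cutoff, "buried", "exposed"))
}

#' Collapse redundant sites across homologous proteins
#'
#' Sites (phosphosites and background) are grouped by their column in a
#' sequence-group alignment (e.g. UniRef50 groups), so equivalents in close
#' homologues count once.  A member sequence whose gap fraction (gaps
#' divided by its ungapped residue count) is at or above
#' `max_gap_fraction` is too poorly aligned to group and its sites stand
#' alone.  Background sites sharing a non-redundant key with any
#' phosphosite are relabelled `ambiguous` and excluded from the counts.
#' Proteins in no group alignment form singleton groups.
#'
#' @param sites Data frame with columns `protein_acc`, `pos` and `status`
#'   (`"phospho"` or `"background"`).
#' @param group_alignments Named list of group alignments (named character
#'   vectors of gapped sequences, names = protein accessions).  When a
#'   protein occurs in several groups the first by sorted group name wins.
#' @param max_gap_fraction Exclusion cutoff for poorly aligned members.
#' @return List with `sites` (input plus `nr_group_id` and updated
#'   `status`) and `counts` (non-redundant phospho, background, ambiguous).
#' @export
group_redundant_sites <- function(sites, group_alignments = list(),
                                  max_gap_fraction = 0.09) {
  stopifnot(all(c("protein_acc", "pos", "status") %in% names(sites)))
  group_ids <- sort(names(group_alignments))
  # first (sorted) group containing each protein, unless too gapped there
  lookup <- function(acc) {
    for (g in group_ids) {
      aln <- group_alignments[[g]]
      if (acc %in% names(aln)) {
        gapped <- aln[[acc]]
        n_gap <- sum(strsplit(gapped, "")[[1]] %in% c("-", "."))
        len <- nchar(gapped) - n_gap
        if (len == 0 || n_gap / len >= max_gap_fraction) return(NULL)
        return(list(group = g, gapped = gapped))
      }
    }
    NULL
  }
  nr_key <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    hit <- lookup(sites$protein_acc[i])
    nr_key[i] <- if (is.null(hit)) {
      paste0("singleton:", sites$protein_acc[i], ":", sites$pos[i])
    } else {
      col <- .ungapped_to_column(hit$gapped, sites$pos[i])
      if (is.na(col)) paste0("singleton:", sites$protein_acc[i], ":",
                             sites$pos[i])
      else paste0(hit$group, ":", col)
    }
  }
  sites$nr_group_id <- nr_key
  phospho_keys <- unique(nr_key[sites$status == "phospho"])
  amb <- sites$status == "background" & nr_key %in% phospho_keys
  sites$status[amb] <- "ambiguous"
  counts <- c(
    phospho = length(unique(nr_key[sites$status == "phospho"])),
    background = length(unique(nr_key[sites$status == "background"])),
    ambiguous = sum(amb)
  )
  list(sites = sites, counts = counts)
}
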