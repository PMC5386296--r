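#' Interaction Effect of phosphorylating a site in an interface
#'
#' IE is the sum, over the site residue's inter-chain contacts, of the
#' change in residue pair-potential when the site is phosphorylated.  In a
#' homodimeric interface both copies of the protein are taken as
#' phosphorylated: the mirrored copy of the site contributes its own
#' contact sum (doubling symmetric contributions), and a contact between
#' the two copies of the site itself is scored once as the
#' phospho-phospho versus unmodified-unmodified difference.
#'
#' @param model An `interface_model`, or its contacts data frame.
#' @param site_chain,site_pos Chain and author residue number of the site
#'   within the interface.
#' @param matrix A `pair_potential`.
#' @param homodimer Treat the interface as homodimeric; defaults to the
#'   model's own flag.  The mirrored copy is the residue at the same
#'   position (same amino acid) in the partner chain.
#' @param site_aa Site amino acid; inferred from the contacts when omitted.
#' @return IE (dimensionless).  A mapped site with no inter-chain contacts
#'   has IE = 0.
#' @export
interaction_effect <- function(model, site_chain, site_pos, matrix,
                               homodimer = NULL, site_aa = NULL) {
  if (inherits(model, "interface_model")) {
    if (is.null(homodimer)) homodimer <- model$homodimer
    edges <- model$contacts
  } else {
    edges <- model
    if (is.null(homodimer)) homodimer <- FALSE
  }
  if (nrow(edges) == 0) return(0)

  side_of <- function(chain, pos) {
    a <- edges$chain_a == chain & edges$pos_a == pos
    b <- edges$chain_b == chain & edges$pos_b == pos
    list(a = which(a), b = which(b))
  }
  sel <- side_of(site_chain, site_pos)
  if (is.null(site_aa)) {
    site_aa <- c(edges$aa_a[sel$a], edges$aa_b[sel$b])[1]
    if (is.na(site_aa)) return(0)   # site has no inter-chain contacts
  }
  if (!site_aa %in% c("S", "T", "Y")) {
    stop("site residue must be S, T or Y; got ", site_aa)
  }

  other_chain <- setdiff(unique(c(edges$chain_a, edges$chain_b)), site_chain)
  copies <- list(list(chain = site_chain, pos = site_pos))
  if (homodimer && length(other_chain) == 1) {
    copies <- c(copies, list(list(chain = other_chain, pos = site_pos)))
  }
  ie <- 0
  seen <- character()
  for (cp in copies) {
    sel <- side_of(cp$chain, cp$pos)
    for (i in sel$a) {
      key <- paste(i, "e")
      if (key %in% seen) next
      seen <- c(seen, key)
      self_pair <- homodimer && edges$aa_b[i] == site_aa &&
        edges$pos_b[i] == site_pos && edges$chain_b[i] != cp$chain
      partner <- residue_class(edges$aa_b[i], edges$phospho_b[i])
      ie <- ie + delta_on_phosphorylation(matrix, site_aa, partner,
                                          self_pair = self_pair)
    }
    for (i in sel$b) {
      key <- paste(i, "e")
      if (key %in% seen) next
      seen <- c(seen, key)
      self_pair <- homodimer && edges$aa_a[i] == site_aa &&
        edges$pos_a[i] == site_pos && edges$chain_a[i] != cp$chain
      partner <- residue_class(edges$aa_a[i], edges$phospho_a[i])
      ie <- ie + delta_on_phosphorylation(matrix, site_aa, partner,
                                          self_pair = self_pair)
    }
  }
  ie
}

#' The switch score
#'
#' S_switch = IE x f_ID x f_Cons: the Interaction Effect weighted by the
#' sequence identity to the structural template and by the conservation of
#' the site across orthologues.  High positive values indicate enabling
#' candidates, high negative values disabling ones.
#'
#' @param IE Interaction Effect.
#' @param f_ID Fraction of identical residues to the template, in \[0, 1\].
#' @param f_Cons Orthologue conservation fraction, in \[0, 1\].
#' @return S_switch (unrounded).
#' @export
s_switch <- function(IE, f_ID, f_Cons) {
  if (any(f_ID < 0 | f_ID > 1, na.rm = TRUE) ||
      any(f_Cons < 0 | f_Cons > 1, na.rm = TRUE)) {
    stop("f_ID and f_Cons must lie in [0, 1]")
  }
  IE * f_ID * f_Cons
}

#' Call a site enabling, disabling or neutral
#'
#' @param S S_switch value(s).
#' @param threshold Positive threshold tau; `S >= tau` is enabling,
#'   `S <= -tau` disabling (both inclusive), anything else neutral.
#' @return Character vector of labels.
#' @export
classify_switch <- function(S, threshold = 1.7) {
  stopifnot(threshold > 0)
  ifelse(S >= threshold, "enabling",
         ifelse(S <= -threshold, "disabling", "neutral"))
}

#' Aggregate scores over alternative templates
#'
#' When several templates cover the same site at the same interface the
#' most significant score is kept: maximum |S_switch|, ties broken by
#' larger |IE|, then enabling (positive) over disabling, then
#' lexicographically smallest template identifier, giving a deterministic
#' result.
#'
#' @param scores Data frame with one row per template and columns
#'   `S_switch`, `IE` and `template`.
#' @return The selected row.
#' @export
aggregate_templates <- function(scores) {
  if (is.null(nrow(scores)) || nrow(scores) == 0) {
    stop("no template scores to aggregate")
  }
  ord <- order(-abs(scores$S_switch), -abs(scores$IE),
               -sign(scores$S_switch), as.character(scores$template))
  scores[ord[1], , drop = FALSE]
}
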