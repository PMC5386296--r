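#' Construct a pair-potential matrix with planted scores
#'
#' Builds a symmetric `pair_potential` with every entry 0 except the
#' planted ones; useful as a sampling target and for worked examples.
#'
#' @param alphabet Residue class alphabet.
#' @param scores Named list of planted entries, each `list(a, b, value)`.
#' @return A `pair_potential`.
#' @export
make_planted_potential <- function(alphabet = residue_alphabet(),
                                   scores = list()) {
  m <- matrix(0, length(alphabet), length(alphabet),
              dimnames = list(alphabet, alphabet))
  for (sc in scores) {
    a <- sc[[1]]; b <- sc[[2]]; v <- as.numeric(sc[[3]])
    if (!a %in% alphabet || !b %in% alphabet) {
      stop("planted class outside alphabet: ", a, "/", b)
    }
    m[a, b] <- v
    m[b, a] <- v
  }
  structure(m, pseudocount = NA_real_, provenance = "planted",
            class = c("pair_potential", "matrix"))
}

.class_to_aa <- function(cl) {
  phospho <- startsWith(cl, "p")
  list(aa = ifelse(phospho, substr(cl, 2, 2), cl), phospho = phospho)
}

# target unordered-pair distribution p(a,b) proportional to
# e(a,b) * exp(s(a,b)) with e from fixed marginals g0 (uniform default);
# both the symmetric-matrix form and its marginals are returned
.pair_target <- function(s, marginals = NULL) {
  alphabet <- rownames(s)
  g0 <- if (is.null(marginals)) {
    stats::setNames(rep(1 / length(alphabet), length(alphabet)), alphabet)
  } else marginals[alphabet] / sum(marginals[alphabet])
  e <- 2 * outer(g0, g0)
  diag(e) <- g0^2
  w <- e * exp(s)
  tot <- sum(w[upper.tri(w, diag = TRUE)])
  p <- w / tot
  g <- (rowSums(p) + diag(p)) / 2   # marginals of the target
  list(p = p, g = g, g0 = g0)
}

#' Implied log-odds potential of a sampling target
#'
#' The contact sampler draws pairs from
#' \eqn{p(a,b) \propto e_0(a,b)\exp(s(a,b))} with \eqn{e_0} built from
#' fixed marginals.  The estimator, however, normalises against the
#' independence model of the *sampled* marginals, so what it converges to
#' is \eqn{s^*(a,b) = \ln(p(a,b)/e_g(a,b))} with \eqn{e_g} from the
#' marginals of \eqn{p} itself.  This function computes that implied
#' potential in closed form; it is the ground truth for round-trip
#' recovery of a planted matrix.
#'
#' @param matrix A `pair_potential` (the raw planted scores).
#' @param marginals Marginal class frequencies of the sampler (default
#'   uniform).
#' @return A `pair_potential` of implied scores.
#' @export
calibrate_potential <- function(matrix, marginals = NULL) {
  tgt <- .pair_target(unclass(matrix), marginals)
  e <- 2 * outer(tgt$g, tgt$g)
  diag(e) <- tgt$g^2
  structure(log(tgt$p / e), pseudocount = NA_real_,
            provenance = "implied sampling-target log-odds",
            class = c("pair_potential", "matrix"))
}

#' Sample contacting residue-class pairs from a planted potential
#'
#' Unordered class pairs are drawn i.i.d. with probability proportional to
#' \eqn{e(a,b) \exp(s(a,b))}, where the independence expectation
#' \eqn{e(a,b)} comes from the supplied marginal class frequencies
#' (uniform by default).  Sampling then re-estimating the potential
#' recovers the planted matrix's implied self-normalised scores (see
#' [calibrate_potential()]), making this the round-trip oracle for
#' [estimate_pair_potential()].
#'
#' @param matrix A finite `pair_potential` (the sampling target).
#' @param n_pairs Number of contact pairs to draw.
#' @param seed Integer seed (deterministic output).
#' @param marginals Named vector of class frequencies; default uniform.
#' @return Contact-edge data frame (chain A/B, sequential positions, aa
#'   and phospho columns) consumable by [count_contact_pairs()].
#' @export
sample_contact_graph <- function(matrix, n_pairs, seed = 1L,
                                 marginals = NULL) {
  alphabet <- rownames(matrix)
  if (any(!is.finite(matrix))) stop("planted matrix must be finite")
  tgt <- .pair_target(unclass(matrix), marginals)
  ut <- upper.tri(tgt$p, diag = TRUE)
  pairs <- which(ut, arr.ind = TRUE)
  p <- tgt$p[ut]
  if (!all(is.finite(p)) || sum(p) <= 0) {
    stop("sampling target is not normalisable")
  }
  .with_seed(seed, {
    draw <- sample.int(nrow(pairs), n_pairs, replace = TRUE, prob = p)
    ca <- .class_to_aa(alphabet[pairs[draw, 1]])
    cb <- .class_to_aa(alphabet[pairs[draw, 2]])
    data.frame(
      struct_id = "synthetic", assembly = NA,
      chain_a = "A", pos_a = seq_len(n_pairs), icode_a = "",
      aa_a = ca$aa, phospho_a = ca$phospho,
      chain_b = "B", pos_b = seq_len(n_pairs), icode_b = "",
      aa_b = cb$aa, phospho_b = cb$phospho,
      min_dist = NA_real_, stringsAsFactors = FALSE
    )
  })
}

#' Write a two-chain toy complex with prescribed contacts
#'
#' Builds PDB-format text for two chains of idealised pseudo-residues
#' (backbone N, CA, C, O plus a single CB side-chain atom; glycine has no
#' CB), placed so that exactly the requested inter-chain residue pairs
#' fall within 5 Angstrom of each other.  S/T/Y residues can be planted as
#' phosphoresidues (written as SEP/TPO/PTR).  The output is parseable by
#' [read_structure()].
#'
#' @param n_per_chain Residues per chain (>= 1).
#' @param contact_pairs List of integer pairs `c(pos_a, pos_b)` to place in
#'   contact; each chain-B residue may appear in at most one pair.
#' @param sequence_a,sequence_b One-letter sequences (default poly-Ala);
#'   identical sequences make the complex a homodimer downstream.
#' @param phospho Data frame (`chain`, `pos`) of residues to emit as
#'   SEP/TPO/PTR; they must be S/T/Y in the sequence.
#' @param path Optional output file; the PDB text is returned invisibly
#'   either way.
#' @return Character scalar of PDB text.
#' @export
make_toy_complex <- function(n_per_chain, contact_pairs = list(),
                             sequence_a = NULL, sequence_b = NULL,
                             phospho = NULL, path = NULL) {
  if (n_per_chain < 1) stop("n_per_chain must be at least 1")
  if (is.null(sequence_a)) sequence_a <- strrep("A", n_per_chain)
  if (is.null(sequence_b)) sequence_b <- sequence_a
  stopifnot(nchar(sequence_a) == n_per_chain,
            nchar(sequence_b) == n_per_chain)
  bpos <- vapply(contact_pairs, function(p) p[2], numeric(1))
  if (anyDuplicated(bpos)) {
    stop("unsatisfiable contact request: a chain-B residue can be placed ",
         "near only one chain-A residue")
  }
  for (p in contact_pairs) {
    if (p[1] < 1 || p[1] > n_per_chain || p[2] < 1 || p[2] > n_per_chain) {
      stop("contact pair (", p[1], ",", p[2], ") outside 1..", n_per_chain)
    }
  }
  contact_of_b <- stats::setNames(
    vapply(contact_pairs, function(p) p[1], numeric(1)),
    as.character(bpos))

  is_phospho <- function(chain, pos) {
    !is.null(phospho) &&
      any(phospho$chain == chain & phospho$pos == pos)
  }
  resname <- function(chain, pos, aa) {
    if (is_phospho(chain, pos)) {
      if (!aa %in% c("S", "T", "Y")) {
        stop("cannot phosphorylate ", aa, " at ", chain, ":", pos)
      }
      c(S = "SEP", T = "TPO", Y = "PTR")[[aa]]
    } else .aa1to3[[aa]]
  }

  lines <- character()
  serial <- 0L
  emit <- function(name, res3, chain, pos, x, y, z) {
    serial <<- serial + 1L
    elem <- substr(name, 1, 1)
    sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            serial, paste0(" ", name), res3, chain, pos, x, y, z, elem)
  }
  residue_atoms <- function(aa, chain, pos, ca) {
    res3 <- resname(chain, pos, aa)
    out <- c(
      emit("N", res3, chain, pos, ca[1] - 1.2, ca[2] + 0.8, ca[3]),
      emit("CA", res3, chain, pos, ca[1], ca[2], ca[3]),
      emit("C", res3, chain, pos, ca[1] + 1.2, ca[2] + 0.8, ca[3]),
      emit("O", res3, chain, pos, ca[1] + 1.8, ca[2] + 1.9, ca[3])
    )
    if (aa != "G") {
      # side chain points towards the partner chain for chain B contacts
      dir <- if (chain == "A") -1 else -1
      out <- c(out, emit("CB", res3, chain, pos,
                         ca[1], ca[2] + dir * 1.5, ca[3]))
    }
    out
  }
  sa <- strsplit(sequence_a, "")[[1]]
  sb <- strsplit(sequence_b, "")[[1]]
  for (i in seq_len(n_per_chain)) {
    lines <- c(lines, residue_atoms(sa[i], "A", i, c(10 * i, 0, 0)))
  }
  lines <- c(lines, "TER")
  n_at_target <- integer(0)
  for (j in seq_len(n_per_chain)) {
    tgt <- if (as.character(j) %in% names(contact_of_b)) {
      contact_of_b[[as.character(j)]]
    } else NULL
    ca <- if (!is.null(tgt)) {
      # several B residues contacting the same A residue fan out along z
      k <- as.character(tgt)
      n_at_target[k] <- (if (k %in% names(n_at_target))
        n_at_target[[k]] else 0L) + 1L
      c(10 * tgt, 4.5, 3 * (n_at_target[[k]] - 1L))
    } else c(10 * j, 40, 0)
    lines <- c(lines, residue_atoms(sb[j], "B", j, ca))
  }
  lines <- c(lines, "TER", "END")
  txt <- paste(c(lines, ""), collapse = "\n")
  if (!is.null(path)) writeLines(lines, path)
  invisible(txt)
}

#' Simulate an orthologue-group alignment with tunable conservation
#'
#' All sequences are identical outside the site column.  At the site
#' column each sequence independently carries the wild-type amino acid
#' with probability `c`, Asp or Glu with probability `de_fraction`, a gap
#' with probability `gap_fraction`, and some other residue otherwise, so
#' the expected conservation fraction is `c + de_fraction`.  The site
#' column index is attached as attribute `"site_column"`.
#'
#' @param wild_aa Site amino acid (S, T or Y).
#' @param n_seq Number of sequences.
#' @param c Probability of the wild-type residue at the site column.
#' @param de_fraction Probability of Asp/Glu at the site column.
#' @param gap_fraction Probability of a gap at the site column.
#' @param seed Integer seed.
#' @param length Alignment length (site column at the middle).
#' @return Named character vector of gapped sequences (`seq1`..`seqN`)
#'   with attributes `site_column` and `group_id`.
#' @export
make_ortholog_alignment <- function(wild_aa, n_seq, c, de_fraction = 0,
                                    gap_fraction = 0, seed = 1L,
                                    length = 21L) {
  stopifnot(c >= 0, de_fraction >= 0, gap_fraction >= 0,
            c + de_fraction + gap_fraction <= 1, n_seq >= 1, length >= 1)
  site_col <- (length + 1L) %/% 2L
  other <- setdiff(residue_alphabet()[1:20], c(wild_aa, "D", "E"))
  .with_seed(seed, {
    backbone <- sample(residue_alphabet()[1:20], length, replace = TRUE)
    u <- stats::runif(n_seq)
    site <- ifelse(u < c, wild_aa,
                   ifelse(u < c + de_fraction,
                          sample(c("D", "E"), n_seq, replace = TRUE),
                          ifelse(u < c + de_fraction + gap_fraction, "-",
                                 sample(other, n_seq, replace = TRUE))))
    seqs <- vapply(seq_len(n_seq), function(i) {
      s <- backbone
      s[site_col] <- site[i]
      paste(s, collapse = "")
    }, character(1))
    names(seqs) <- paste0("seq", seq_len(n_seq))
    attr(seqs, "site_column") <- site_col
    attr(seqs, "group_id") <- "synthetic_group"
    seqs
  })
}

#' Ungapped position of the site column for one alignment member
#'
#' @param aln Alignment from [make_ortholog_alignment()].
#' @param seq_name Member name.
#' @return 1-based ungapped position, or `NA` if the member is gapped at
#'   the site column.
#' @export
site_position_in <- function(aln, seq_name) {
  col <- attr(aln, "site_column")
  chars <- strsplit(aln[[seq_name]], "")[[1]]
  if (chars[col] %in% c("-", ".")) return(NA_integer_)
  sum(!(chars[seq_len(col)] %in% c("-", ".")))
}

#' Simulate a labelled switch benchmark with a planted effect
#'
#' Positives receive an Interaction Effect drawn from a unit-variance
#' normal centred at `effect_size` with the sign of the planted effect
#' direction (enabling positive, disabling negative); negatives are
#' centred at zero.  Template identity f_ID ~ Beta(8, 2) and conservation
#' f_Cons ~ Beta(5, 2) emulate the predominance of close templates and
#' moderately conserved sites; S_switch is their product with IE.  The
#' columns `IE_signed` and `S_switch_signed` carry the effect-signed
#' encodings used for ROC ranking.
#'
#' @param n_pos,n_neg Numbers of positive and negative entries.
#' @param effect_size Planted |mean IE| of the positives (0 = null).
#' @param seed Integer seed.
#' @param path Optional TSV output path (benchmark-table dialect).
#' @return Benchmark data frame with ground-truth `effect` labels.
#' @export
make_synthetic_benchmark <- function(n_pos = 200L, n_neg = 200L,
                                     effect_size = 3, seed = 1L,
                                     path = NULL) {
  stopifnot(effect_size >= 0, n_pos >= 1, n_neg >= 1)
  .with_seed(seed, {
    n <- n_pos + n_neg
    set <- rep(c("positive", "negative"), c(n_pos, n_neg))
    effect <- sample(c("enabling", "disabling"), n, replace = TRUE)
    sign <- ifelse(effect == "enabling", 1, -1)
    ie <- ifelse(set == "positive",
                 stats::rnorm(n, mean = sign * effect_size, sd = 1),
                 stats::rnorm(n, mean = 0, sd = 1))
    f_id <- stats::rbeta(n, 8, 2)
    f_cons <- stats::rbeta(n, 5, 2)
    ss <- s_switch(ie, f_id, f_cons)
    df <- data.frame(
      set = set,
      protein = sprintf("SYNP%04d", seq_len(n)),
      site = paste0(sample(c("S", "T", "Y"), n, replace = TRUE), " ",
                    sample(500, n, replace = TRUE), "-p"),
      interactor = sprintf("SYNI%04d", sample(100, n, replace = TRUE)),
      effect = effect,
      IE = ie, f_ID = f_id, f_Cons = f_cons, S_switch = ss,
      IE_signed = ie * sign, S_switch_signed = ss * sign,
      kinase = FALSE,
      stringsAsFactors = FALSE
    )
    if (!is.null(path)) .write_tsv(df, path)
    df
  })
}
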