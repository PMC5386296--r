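#' Tally contacting residue-class pairs
#'
#' Each inter-chain contact increments one unordered pair of residue
#' classes; phosphorylated S/T/Y fold into the pS/pT/pY classes.
#'
#' @param edges Contact data frame as produced by
#'   [find_interface_contacts()] (columns aa_a, phospho_a, aa_b, phospho_b),
#'   or an `interface_model`.
#' @param alphabet Residue class alphabet (default [residue_alphabet()]).
#' @return Object of class `"pair_count_table"`: symmetric integer matrix
#'   of counts with `total_pairs` (sum over unordered pairs) attached.
#' @export
count_contact_pairs <- function(edges, alphabet = residue_alphabet()) {
  if (inherits(edges, "interface_model")) edges <- edges$contacts
  n <- length(alphabet)
  counts <- matrix(0L, n, n, dimnames = list(alphabet, alphabet))
  if (nrow(edges) > 0) {
    # fold the phospho flag into the class label; validate against the
    # supplied alphabet so toy alphabets work too
    ca <- ifelse(edges$phospho_a, paste0("p", edges$aa_a), edges$aa_a)
    cb <- ifelse(edges$phospho_b, paste0("p", edges$aa_b), edges$aa_b)
    bad <- !(ca %in% alphabet) | !(cb %in% alphabet)
    if (any(bad)) stop("residue class outside alphabet: ",
                       paste(unique(c(ca[bad], cb[bad])), collapse = ", "))
    # canonical unordered order, then tabulate
    lo <- pmin(match(ca, alphabet), match(cb, alphabet))
    hi <- pmax(match(ca, alphabet), match(cb, alphabet))
    tab <- table(paste(lo, hi))
    for (k in names(tab)) {
      ij <- as.integer(strsplit(k, " ")[[1]])
      counts[ij[1], ij[2]] <- counts[ij[1], ij[2]] + as.integer(tab[[k]])
    }
    counts[lower.tri(counts)] <- t(counts)[lower.tri(counts)]
  }
  structure(counts, total_pairs = sum(counts[upper.tri(counts, diag = TRUE)]),
            class = c("pair_count_table", "matrix"))
}

#' Estimate an interface pair-potential matrix from contact counts
#'
#' Quasi-chemical log-odds estimation against an independence random model.
#' With pseudocounted counts \eqn{n'(a,b) = n(a,b) + \alpha} over unordered
#' class pairs and \eqn{N' = \sum n'}, the observed pair frequency is
#' \eqn{f(a,b) = n'(a,b)/N'}, the marginal class frequency is
#' \eqn{g(a) = \sum_b n'(a,b)(1+[a=b]) / (2N')}, the expected frequency
#' under independence is \eqn{e(a,b) = 2 g(a) g(b)} for \eqn{a \ne b} and
#' \eqn{g(a)^2} on the diagonal, and the score is
#' \eqn{s(a,b) = \ln(f/e)} (natural log, dimensionless).
#'
#' @param counts A `pair_count_table` (or symmetric count matrix).
#' @param pseudocount Pseudocount \eqn{\alpha \ge 0} added to every
#'   unordered pair.  With `pseudocount = 0` an unobserved pair scores
#'   `-Inf` and a warning is raised.
#' @return Object of class `"pair_potential"`: symmetric numeric matrix of
#'   scores with attributes `pseudocount` and `provenance`.
#' @export
estimate_pair_potential <- function(counts, pseudocount = 1) {
  stopifnot(pseudocount >= 0)
  m <- unclass(counts)
  if (!isSymmetric(unname(m))) stop("count matrix must be symmetric")
  alphabet <- rownames(m)
  np <- m + pseudocount
  Nprime <- sum(np[upper.tri(np, diag = TRUE)])
  if (Nprime <= 0) stop("no counts and no pseudocount mass")
  f_obs <- np / Nprime            # off-diagonal cells appear twice; the
  f_obs[row(np) == col(np)] <- diag(np) / Nprime  # unordered f is read per pair
  g <- (rowSums(np) + diag(np)) / (2 * Nprime)
  e <- 2 * outer(g, g)
  diag(e) <- g^2
  s <- log(f_obs / e)
  if (any(!is.finite(s))) {
    warning("unobserved pair(s) with pseudocount 0 give -Inf scores; ",
            "use pseudocount > 0 for downstream scoring")
  }
  structure(s, pseudocount = pseudocount,
            provenance = paste0("estimated from ",
                                attr(counts, "total_pairs") %||% sum(m) ,
                                " contact pairs"),
            class = c("pair_potential", "matrix"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pair_potential <- function(x, ...) {
  cat("pair_potential over", nrow(x), "classes (",
      attr(x, "provenance") %||% "unknown provenance", ")\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Change in pair-potential upon phosphorylation
#'
#' For a site residue `aa` (S, T or Y) in contact with `partner`, returns
#' \eqn{s(p\mbox{-}aa, partner') - s(aa, partner)}.  Normally
#' `partner' = partner`; when the partner is the mirrored copy of the site
#' itself across a homodimeric interface both copies are taken as
#' phosphorylated, so the modified-state partner is the phosphorylated
#' class too (`self_pair = TRUE`).
#'
#' @param matrix A `pair_potential`.
#' @param aa Site amino acid, one of S, T, Y.
#' @param partner Partner residue class (one-letter code, or pS/pT/pY).
#' @param self_pair Is the partner the mirrored copy of the site in a
#'   homodimer (both copies phosphorylated)?
#' @return Score difference (dimensionless).
#' @export
delta_on_phosphorylation <- function(matrix, aa, partner,
                                     self_pair = FALSE) {
  if (!aa %in% c("S", "T", "Y")) {
    stop("phosphorylatable residues are S, T and Y; got ", aa)
  }
  p_aa <- paste0("p", aa)
  partner_mod <- if (self_pair) p_aa else partner
  for (cl in unique(c(aa, p_aa, partner, partner_mod))) {
    if (!cl %in% rownames(matrix)) {
      stop("residue class missing from matrix: ", cl)
    }
  }
  unname(matrix[p_aa, partner_mod] - matrix[aa, partner])
}

#' Read or write a pair-potential matrix TSV
#'
#' The file dialect has class labels as the first row and first column
#' (one-letter amino acids plus pS/pT/pY) and numeric score cells.  Writing
#' then reading reproduces the matrix to 6 decimals; an asymmetric file
#' (beyond 1e-6) is rejected.
#'
#' @param x A `pair_potential` (write only).
#' @param path File path.
#' @return For `read_pair_potential`, a `pair_potential`.
#' @export
write_pair_potential <- function(x, path) {
  stopifnot(inherits(x, "pair_potential"))
  df <- data.frame(class = rownames(x),
                   formatC(unclass(x), format = "f", digits = 6),
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' @rdname write_pair_potential
#' @export
read_pair_potential <- function(path) {
  df <- .read_tsv(path)
  labels <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(labels, colnames(m))) {
    stop("matrix file row and column labels disagree")
  }
  if (!is.numeric(m) || anyNA(suppressWarnings(m * 1))) {
    stop("non-numeric cell in pair-potential file")
  }
  storage.mode(m) <- "double"
  dimnames(m) <- list(labels, labels)
  if (max(abs(m - t(m))) > 1e-6) {
    stop("pair-potential file is not symmetric (tolerance 1e-6)")
  }
  m <- (m + t(m)) / 2
  structure(m, pseudocount = NA_real_, provenance = paste("read from", path),
            class = c("pair_potential", "matrix"))
}
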