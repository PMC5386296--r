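# Independent oracles and fixture builders used across the test files.

# -- pair-potential oracle: direct evaluation of the log-odds formula from
#    a plain list of unordered pair counts (independent of the matrix code)
oracle_pair_potential <- function(pair_counts, alphabet, alpha) {
  # pair_counts: named list "A|B" -> count (unordered keys, A <= B)
  key <- function(a, b) paste(sort(c(a, b)), collapse = "|")
  np <- function(a, b) {
    k <- key(a, b)
    (if (k %in% names(pair_counts)) pair_counts[[k]] else 0) + alpha
  }
  N <- 0
  for (i in seq_along(alphabet)) for (j in i:length(alphabet)) {
    N <- N + np(alphabet[i], alphabet[j])
  }
  g <- sapply(alphabet, function(a) {
    tot <- 0
    for (b in alphabet) tot <- tot + np(a, b) * (1 + (a == b))
    tot / (2 * N)
  })
  s <- matrix(NA_real_, length(alphabet), length(alphabet),
              dimnames = list(alphabet, alphabet))
  for (a in alphabet) for (b in alphabet) {
    f <- np(a, b) / N
    e <- if (a == b) g[[a]]^2 else 2 * g[[a]] * g[[b]]
    s[a, b] <- log(f / e)
  }
  s
}

# -- AUC oracle: exhaustive concordant-pair enumeration (rank statistic)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  conc <- 0
  for (p in pos) for (n in neg) {
    conc <- conc + (p > n) + 0.5 * (p == n)
  }
  conc / (length(pos) * length(neg))
}

# -- threshold oracle: exhaustive search over all observed cutpoints for
#    the most permissive threshold with FPR <= bound
oracle_threshold_at_fpr <- function(scores, labels, max_fpr) {
  cands <- c(Inf, sort(unique(scores), decreasing = TRUE))
  nn <- sum(!labels)
  np <- sum(labels)
  best <- NULL
  for (t in cands) {
    fp <- sum(scores >= t & !labels)
    if (fp / nn <= max_fpr) {
      best <- list(threshold = t, fpr = fp / nn,
                   tpr = sum(scores >= t & labels) / np)
    }
  }
  best
}

# -- Fisher oracle: full enumeration of 2x2 tables with fixed margins
oracle_fisher_two_sided <- function(tp, fp, fn, tn) {
  r1 <- tp + fp
  c1 <- tp + fn
  n <- tp + fp + fn + tn
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(ks, c1, n - c1, r1)
  p_obs <- dhyper(tp, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# -- analytic sphere areas for ASA checks (probe-expanded radii)
sphere_area <- function(r_vdw, probe = 1.4) 4 * pi * (r_vdw + probe)^2
# accessible area of one of two equal spheres of radius R at distance d
two_sphere_exposed <- function(R, d) 2 * pi * R * (R + d / 2)

# -- minimal hand-written PDB records for exact-geometry tests
pdb_atom_line <- function(serial, name, res3, chain, resno, x, y, z,
                          elem = substr(name, 1, 1)) {
  sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, paste0(" ", name), res3, chain, resno, x, y, z, elem)
}

write_mini_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# two single-CB residues on different chains at an exact CB-CB distance
two_residue_pdb <- function(d, res3 = c("ALA", "ALA")) {
  write_mini_pdb(c(
    pdb_atom_line(1, "CA", res3[1], "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CB", res3[1], "A", 1, 0, 1.5, 0),
    "TER",
    pdb_atom_line(3, "CA", res3[2], "B", 1, 0, 1.5 + d + 1.5, 0),
    pdb_atom_line(4, "CB", res3[2], "B", 1, 0, 1.5 + d, 0),
    "TER"
  ))
}

# -- fixture: worked disabling-site corpus (site with two acidic contacts,
#    identity template, poorly conserved orthologue column)
worked_example_fixture <- function(dir = tempfile("fx")) {
  dir.create(file.path(dir, "structures"), recursive = TRUE)
  dir.create(file.path(dir, "alignments"))
  seq_a <- "AAAATAAA"
  seq_b <- "AEEAAAAA"
  make_toy_complex(8, list(c(5, 2), c(5, 3)),
                   sequence_a = seq_a, sequence_b = seq_b,
                   path = file.path(dir, "structures", "tmpl1.pdb"))
  pot <- make_planted_potential(scores = list(list("pT", "E", -3.37)))
  write_pair_potential(pot, file.path(dir, "matrix.tsv"))
  write_alignment(c(query = seq_a, template = seq_a),
                  file.path(dir, "alignments", "QPROT__tmpl1_A.afa"))
  write_alignment(c(query = seq_b, template = seq_b),
                  file.path(dir, "alignments", "QPART__tmpl1_B.afa"))
  grp <- c(QPROT = seq_a,
           setNames(rep(gsub("T", "G", seq_a), 9), paste0("orth", 1:9)))
  write_alignment(grp, file.path(dir, "alignments", "group_g1.afa"))
  sites <- data.frame(protein = "QPROT", species = "hs", wild_aa = "T",
                      pos = 5, status = "phospho", interactor = "QPART",
                      template = "tmpl1:A:B", stringsAsFactors = FALSE)
  list(dir = dir, sites = sites,
       structures = file.path(dir, "structures"),
       alignments = file.path(dir, "alignments"),
       matrix = file.path(dir, "matrix.tsv"))
}
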