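#' Read a protein structure and extract residue records
#'
#' Parses a PDB or mmCIF file (via \pkg{bio3d}), keeps the 20 standard amino
#' acids plus the phosphoresidues SEP (phosphoserine), TPO (phosphothreonine)
#' and PTR (phosphotyrosine), and returns one residue record per residue
#' together with the heavy-atom coordinates needed for contact and
#' accessible-surface-area computation.  Other non-standard residues
#' (ligands, water, modified residues without a standard parent here) are
#' skipped with a warning.  Where alternate locations are present only the
#' highest-occupancy conformer of each atom is kept.
#'
#' @param path Path to a structure file.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @param struct_id Structure identifier; defaults to the file base name.
#' @return An object of class `"switch_structure"`: a list with `atom`
#'   (heavy-atom data frame: chain, resno, insert, resid, elety, elesym,
#'   x, y, z) and `residues` (struct_id, chain_id, seq_pos, icode, aa,
#'   phospho, sidechain_asa — ASA unset until [sidechain_asa()] is run).
#' @seealso [detect_phospho_residues()], [find_interface_contacts()],
#'   [sidechain_asa()]
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           struct_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  if (is.null(struct_id)) {
    struct_id <- sub("\\.(pdb|ent|cif|mmcif)$", "", basename(path),
                     ignore.case = TRUE)
  }
  pdb <- tryCatch(
    suppressWarnings(
      if (format == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path)
    ),
    error = function(e) stop("unreadable structure file ", path, ": ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("empty structure: ", path)
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  if (is.null(at$elesym) || all(is.na(at$elesym))) {
    at$elesym <- sub("^[0-9]*", "", substr(trimws(at$elety), 1, 1))
  }
  at$elesym <- toupper(trimws(at$elesym))

  skip <- !(at$resid %in% names(.aa3to1))
  if (any(skip)) {
    warning("skipping non-standard residue(s): ",
            paste(sort(unique(at$resid[skip])), collapse = ", "))
    at <- at[!skip, , drop = FALSE]
  }
  if (nrow(at) == 0) stop("empty structure (no polymer residues): ", path)

  # highest-occupancy altloc conformer per atom
  if (any(nzchar(at$alt))) {
    occ <- at$o
    occ[is.na(occ)] <- 1
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
    ord <- order(key, -occ)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                               sep = "\r")), , drop = FALSE]
  }
  at <- at[at$elesym != "H" & at$elesym != "D", , drop = FALSE]
  if (nrow(at) == 0) stop("empty structure (no heavy atoms): ", path)

  atom <- data.frame(
    chain = as.character(at$chain), resno = as.integer(at$resno),
    insert = as.character(at$insert), resid = as.character(at$resid),
    elety = trimws(as.character(at$elety)),
    elesym = as.character(at$elesym),
    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE
  )
  atom <- atom[order(atom$chain, atom$resno, atom$insert), , drop = FALSE]
  rownames(atom) <- NULL

  rk <- !duplicated(paste(atom$chain, atom$resno, atom$insert, sep = "\r"))
  res <- atom[rk, c("chain", "resno", "insert", "resid")]
  residues <- data.frame(
    struct_id = struct_id,
    chain_id = res$chain,
    seq_pos = res$resno,
    icode = res$insert,
    aa = unname(.aa3to1[res$resid]),
    phospho = res$resid %in% names(.phospho_resnames),
    sidechain_asa = NA_real_,
    stringsAsFactors = FALSE
  )
  rownames(residues) <- NULL
  structure(list(struct_id = struct_id, atom = atom, residues = residues),
            class = "switch_structure")
}

#' @export
print.switch_structure <- function(x, ...) {
  cat("switch_structure", x$struct_id, "-",
      nrow(x$residues), "residues,",
      length(unique(x$residues$chain_id)), "chain(s),",
      sum(x$residues$phospho), "phosphoresidue(s)\n")
  invisible(x)
}

#' Subset a structure to selected chains
#'
#' Used e.g. to recompute accessible surface area with a partner chain
#' removed.
#'
#' @param x A `switch_structure`.
#' @param chains Chain identifiers to keep.
#' @return A `switch_structure` restricted to `chains`.
#' @export
subset_chains <- function(x, chains) {
  stopifnot(inherits(x, "switch_structure"))
  missing <- setdiff(chains, unique(x$atom$chain))
  if (length(missing)) stop("chain(s) not in structure: ",
                            paste(missing, collapse = ", "))
  x$atom <- x$atom[x$atom$chain %in% chains, , drop = FALSE]
  x$residues <- x$residues[x$residues$chain_id %in% chains, , drop = FALSE]
  rownames(x$atom) <- rownames(x$residues) <- NULL
  x
}

#' Phosphoresidues of a structure
#'
#' @param residues A residue data frame (as in `switch_structure$residues`)
#'   or a `switch_structure`.
#' @return The subset of residue records with `phospho = TRUE` (residues
#'   read as SEP, TPO or PTR).
#' @export
detect_phospho_residues <- function(residues) {
  if (inherits(residues, "switch_structure")) residues <- residues$residues
  residues[residues$phospho, , drop = FALSE]
}

.chain_sequence <- function(struct, chain) {
  r <- struct$residues[struct$residues$chain_id == chain, , drop = FALSE]
  paste(r$aa, collapse = "")
}

#' Extract inter-chain residue contacts as an interface model
#'
#' A contact is a pair of residues in the two chains whose minimum
#' heavy-atom distance is at most `cutoff` Angstrom.  Each residue pair is
#' recorded once, with the minimum distance, ordered by (pos_a, pos_b).
#' The interface is flagged as homodimeric when the two chains carry an
#' identical residue sequence.
#'
#' @param struct A `switch_structure`.
#' @param chain_a,chain_b Chain identifiers forming the interface.
#' @param cutoff Contact distance cutoff in Angstrom (inclusive).
#' @param assembly,model Optional biological-assembly and model tags carried
#'   into the interface identifier.
#' @return An object of class `"interface_model"`: interface_id, `contacts`
#'   data frame (struct_id, assembly, chain_a, pos_a, icode_a, aa_a,
#'   phospho_a, chain_b, pos_b, icode_b, aa_b, phospho_b, min_dist),
#'   per-chain residue tables, and the `homodimer` flag.
#' @export
find_interface_contacts <- function(struct, chain_a, chain_b, cutoff = 5.0,
                                    assembly = NA, model = NA) {
  stopifnot(inherits(struct, "switch_structure"), cutoff > 0)
  for (ch in c(chain_a, chain_b)) {
    if (!ch %in% struct$atom$chain) stop("chain not in structure: ", ch)
  }
  aa_at <- struct$atom[struct$atom$chain == chain_a, , drop = FALSE]
  bb_at <- struct$atom[struct$atom$chain == chain_b, , drop = FALSE]
  ra <- struct$residues[struct$residues$chain_id == chain_a, , drop = FALSE]
  rb <- struct$residues[struct$residues$chain_id == chain_b, , drop = FALSE]

  xb <- as.matrix(bb_at[, c("x", "y", "z")])
  keyb <- paste(bb_at$resno, bb_at$insert, sep = "\r")
  keyb_res <- paste(rb$seq_pos, rb$icode, sep = "\r")
  out <- list()
  for (i in seq_len(nrow(ra))) {
    sel <- aa_at$resno == ra$seq_pos[i] & aa_at$insert == ra$icode[i]
    xa <- as.matrix(aa_at[sel, c("x", "y", "z"), drop = FALSE])
    # squared distance of every B atom to its nearest atom of residue i
    d2 <- rep(Inf, nrow(xb))
    for (k in seq_len(nrow(xa))) {
      dk <- (xb[, 1] - xa[k, 1])^2 + (xb[, 2] - xa[k, 2])^2 +
        (xb[, 3] - xa[k, 3])^2
      d2 <- pmin(d2, dk)
    }
    dmin <- sqrt(tapply(d2, factor(keyb, levels = keyb_res), min))
    hit <- which(dmin <= cutoff)
    if (length(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        struct_id = struct$struct_id, assembly = assembly,
        chain_a = chain_a, pos_a = ra$seq_pos[i], icode_a = ra$icode[i],
        aa_a = ra$aa[i], phospho_a = ra$phospho[i],
        chain_b = chain_b, pos_b = rb$seq_pos[hit], icode_b = rb$icode[hit],
        aa_b = rb$aa[hit], phospho_b = rb$phospho[hit],
        min_dist = unname(dmin[hit]), stringsAsFactors = FALSE
      )
    }
  }
  contacts <- if (length(out)) do.call(rbind, out) else data.frame(
    struct_id = character(), assembly = character(), chain_a = character(),
    pos_a = integer(), icode_a = character(), aa_a = character(),
    phospho_a = logical(), chain_b = character(), pos_b = integer(),
    icode_b = character(), aa_b = character(), phospho_b = logical(),
    min_dist = numeric(), stringsAsFactors = FALSE
  )
  contacts <- contacts[order(contacts$pos_a, contacts$icode_a,
                             contacts$pos_b, contacts$icode_b), ,
                       drop = FALSE]
  rownames(contacts) <- NULL
  structure(list(
    interface_id = list(struct_id = struct$struct_id, assembly = assembly,
                        model = model, chain_a = chain_a, chain_b = chain_b),
    contacts = contacts,
    residues = list(a = ra, b = rb),
    homodimer = identical(.chain_sequence(struct, chain_a),
                          .chain_sequence(struct, chain_b)),
    cutoff = cutoff
  ), class = "interface_model")
}

#' @export
print.interface_model <- function(x, ...) {
  id <- x$interface_id
  cat("interface_model", id$struct_id, paste0(id$chain_a, ":", id$chain_b),
      "-", nrow(x$contacts), "contact(s),",
      if (x$homodimer) "homodimer" else "heterodimer", "\n")
  invisible(x)
}

#' Write interface contacts to TSV
#'
#' @param model An `interface_model`.
#' @param path Output file.
#' @export
write_contacts_tsv <- function(model, path) {
  stopifnot(inherits(model, "interface_model"))
  .write_tsv(model$contacts, path)
}

# van der Waals radii (Angstrom) by element; 1.70 for unknown elements
.vdw_radius <- function(elesym) {
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90,
         F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
  out <- unname(r[elesym])
  out[is.na(out)] <- 1.70
  out
}

# deterministic near-uniform points on the unit sphere (golden spiral)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

.backbone_atoms <- c("N", "CA", "C", "O", "OXT", "OT1", "OT2")

#' Side-chain accessible surface area
#'
#' Shrake-Rupley accessible surface area with a 1.4 Angstrom probe and a
#' deterministic spiral point set, summed over side-chain atoms (CB and
#' beyond; backbone N, CA, C, O and terminal oxygens excluded).  Glycine has
#' no side-chain atoms and its side-chain ASA is defined as 0.  A
#' non-glycine residue whose side-chain atoms are all missing from the file
#' gets `NA` (unset), never a silent 0.
#'
#' @param struct A `switch_structure`.
#' @param probe Probe radius in Angstrom.
#' @param n_points Number of sphere sample points per atom (>= 960
#'   recommended).
#' @return The structure's residue data frame with `sidechain_asa` filled in
#'   (Angstrom^2).
#' @export
sidechain_asa <- function(struct, probe = 1.4, n_points = 960L) {
  stopifnot(inherits(struct, "switch_structure"), n_points >= 12)
  at <- struct$atom
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rad <- .vdw_radius(at$elesym) + probe
  sp <- .sphere_points(n_points)
  n <- nrow(at)
  area <- numeric(n)
  for (i in seq_len(n)) {
    di <- sqrt((xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
               (xyz[, 3] - xyz[i, 3])^2)
    nb <- which(di < rad[i] + rad & seq_len(n) != i)
    pts <- sweep(sp * rad[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      acc <- acc & d2 > rad[j]^2
      if (!any(acc)) break
    }
    area[i] <- 4 * pi * rad[i]^2 * sum(acc) / n_points
  }
  res <- struct$residues
  rkey <- paste(res$chain_id, res$seq_pos, res$icode, sep = "\r")
  akey <- paste(at$chain, at$resno, at$insert, sep = "\r")
  side <- !(at$elety %in% .backbone_atoms)
  for (i in seq_len(nrow(res))) {
    if (res$aa[i] == "G") {
      res$sidechain_asa[i] <- 0
      next
    }
    sel <- akey == rkey[i] & side
    res$sidechain_asa[i] <- if (any(sel)) sum(area[sel]) else NA_real_
  }
  res
}

# query position -> template position map from one pairwise gapped alignment
.aln_map <- function(query_gapped, template_gapped) {
  q <- strsplit(query_gapped, "")[[1]]
  t <- strsplit(template_gapped, "")[[1]]
  if (length(q) != length(t)) stop("pairwise alignment rows differ in length")
  gap <- c("-", ".")
  qpos <- cumsum(!(q %in% gap))
  tpos <- cumsum(!(t %in% gap))
  keep <- !(q %in% gap)
  map <- ifelse(t[keep] %in% gap, NA_integer_, tpos[keep])
  names(map) <- qpos[keep]
  map
}

.aln_stats <- function(query_gapped, template_gapped) {
  q <- strsplit(toupper(query_gapped), "")[[1]]
  t <- strsplit(toupper(template_gapped), "")[[1]]
  gap <- c("-", ".")
  aligned <- !(q %in% gap) & !(t %in% gap)
  qlen <- sum(!(q %in% gap))
  n_aligned <- sum(aligned)
  identity <- if (n_aligned > 0) sum(q[aligned] == t[aligned]) / n_aligned
              else NA_real_
  list(identity = identity, coverage = n_aligned / qlen,
       n_aligned = n_aligned)
}

.interface_residues <- function(model, side = c("a", "b")) {
  side <- match.arg(side)
  cc <- model$contacts
  unique(cc[[paste0("pos_", side)]])
}

#' Match an interface against candidate homologous interfaces
#'
#' A candidate interface matches the query when, for both chains, the
#' pairwise alignment of query chain to candidate chain has at least the
#' required fraction of identical residues, at least the required coverage
#' of the query sequence, and the two interfaces share at least the
#' required fraction of interface residues after alignment.  Used to pair
#' interfaces carrying a phosphoresidue with unphosphorylated homologues.
#'
#' @param query An `interface_model`.
#' @param candidates Named list of `interface_model`s.
#' @param alignments Named list (one element per candidate) of two pairwise
#'   alignments, `a` and `b`, each a list with gapped strings `query` and
#'   `template` aligning the query chain to the candidate chain.  A
#'   candidate with no alignment entry is skipped with a warning.
#' @param rule Numeric vector `(identity, coverage, shared)` of minimum
#'   fractions; default `c(0.5, 0.5, 0.5)`.
#' @return Data frame of candidates with their identity, coverage and
#'   shared-interface fractions and a `match` flag.
#' @export
find_homologous_interfaces <- function(query, candidates, alignments,
                                       rule = c(identity = 0.5,
                                                coverage = 0.5,
                                                shared = 0.5)) {
  stopifnot(inherits(query, "interface_model"))
  out <- list()
  for (id in names(candidates)) {
    cand <- candidates[[id]]
    aln <- alignments[[id]]
    if (is.null(aln) || is.null(aln$a) || is.null(aln$b)) {
      warning("no alignment for candidate ", id, "; skipped")
      next
    }
    sa <- .aln_stats(aln$a$query, aln$a$template)
    sb <- .aln_stats(aln$b$query, aln$b$template)
    identity <- min(sa$identity, sb$identity)
    coverage <- min(sa$coverage, sb$coverage)
    shared <- local({
      hits <- 0L; tot <- 0L
      for (side in c("a", "b")) {
        qres <- .interface_residues(query, side)
        map <- .aln_map(alignments[[id]][[side]]$query,
                        alignments[[id]][[side]]$template)
        cres <- .interface_residues(cand, side)
        # alignments are over 1-based ungapped positions; author numbering
        # is translated through each chain's residue order
        qresseq <- query$residues[[side]]$seq_pos
        cresseq <- cand$residues[[side]]$seq_pos
        for (p in qres) {
          tot <- tot + 1L
          qi <- match(p, qresseq)
          tp <- if (is.na(qi)) NA_integer_ else map[as.character(qi)]
          if (!is.na(tp) && tp <= length(cresseq) &&
              cresseq[tp] %in% cres) hits <- hits + 1L
        }
      }
      if (tot == 0) 0 else hits / tot
    })
    out[[id]] <- data.frame(
      candidate = id, identity = identity, coverage = coverage,
      shared_interface = shared,
      match = identity >= rule[[1]] && coverage >= rule[[2]] &&
        shared >= rule[[3]],
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(candidate = character(), identity = numeric(),
                      coverage = numeric(), shared_interface = numeric(),
                      match = logical(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
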