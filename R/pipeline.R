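#' Score a table of phosphosites against structural templates
#'
#' End-to-end pipeline: for every input row (site x interactor x template)
#' the site is mapped onto its template chain through the pairwise
#' alignment, annotated with disorder and surface exposure, scored for the
#' Interaction Effect against the pair-potential matrix, weighted by f_ID
#' and f_Cons into S_switch, and classified.  Rows for the same site and
#' interactor are then aggregated to the most significant template.
#' Every input row appears in the full output with a status:
#' `scored`, `unmapped` (site falls on a template gap or has no
#' alignment), or `no-interface` (mapped residue has no inter-chain
#' contact; IE = 0).
#'
#' File contracts: `sites` is a TSV with columns `protein`, `species`,
#' `wild_aa`, `pos`, `status`, `interactor`, `template`
#' (`"<struct>:<chain_a>:<chain_b>"`, the site protein on `chain_a`) and
#' optional `source`, `pubmed`, `throughput`.  Structures live in
#' `structures_dir` as `<struct>.pdb` or `.cif`.  Pairwise alignments live
#' in `alignments_dir` as `<protein>__<struct>_<chain>.afa` (query first
#' record, template chain second); orthologue groups as `group_*.afa`.
#' `disorder` is a TSV (`protein`, `pos`, `score`).
#'
#' @param sites Sites TSV path or data frame.
#' @param structures_dir Directory of template structures.
#' @param alignments_dir Directory of aligned FASTA files.
#' @param matrix A `pair_potential` or the path of its TSV.
#' @param disorder Optional disorder TSV path or data frame.
#' @param config A [switch_config()].
#' @param out Optional path for the full per-template results TSV (scores
#'   written at 4 decimals); the aggregated table goes to
#'   `<out>.aggregated.tsv`.
#' @return List with `full` and `aggregated` data frames (unrounded).
#' @export
score_sites_pipeline <- function(sites, structures_dir, alignments_dir,
                                 matrix, disorder = NULL,
                                 config = switch_config(), out = NULL) {
  if (is.character(sites)) sites <- .read_tsv(sites)
  if (is.character(matrix)) matrix <- read_pair_potential(matrix)
  if (is.character(disorder)) disorder <- .read_tsv(disorder)
  need <- c("protein", "wild_aa", "pos", "interactor", "template")
  miss <- setdiff(need, names(sites))
  if (length(miss)) stop("sites table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"species" %in% names(sites)) sites$species <- NA_character_

  group_files <- if (dir.exists(alignments_dir)) {
    sort(list.files(alignments_dir, pattern = "^group_.*\\.afa$",
                    full.names = TRUE))
  } else character()
  groups <- lapply(group_files, read_alignment)
  names(groups) <- sub("\\.afa$", "", basename(group_files))

  struct_cache <- new.env(parent = emptyenv())
  get_struct <- function(id) {
    if (!is.null(struct_cache[[id]])) return(struct_cache[[id]])
    for (ext in c(".pdb", ".cif")) {
      f <- file.path(structures_dir, paste0(id, ext))
      if (file.exists(f)) {
        s <- suppressWarnings(read_structure(f, struct_id = id))
        struct_cache[[id]] <- list(struct = s, asa = sidechain_asa(s),
                                   ifaces = list())
        return(struct_cache[[id]])
      }
    }
    NULL
  }
  get_iface <- function(id, ca, cb) {
    entry <- get_struct(id)
    if (is.null(entry)) return(NULL)
    key <- paste(ca, cb, sep = ":")
    if (is.null(entry$ifaces[[key]])) {
      entry$ifaces[[key]] <- find_interface_contacts(
        entry$struct, ca, cb, cutoff = config$contact_cutoff)
      struct_cache[[id]] <- entry
    }
    entry$ifaces[[key]]
  }
  get_aln <- function(protein, struct, chain) {
    f <- file.path(alignments_dir,
                   paste0(protein, "__", struct, "_", chain, ".afa"))
    if (!file.exists(f)) return(NULL)
    a <- read_alignment(f)
    list(query = a[[1]], template = a[[2]])
  }
  disorder_flag <- function(protein, pos) {
    if (is.null(disorder)) return(NA)
    sc <- disorder[disorder$protein == protein, , drop = FALSE]
    if (!nrow(sc)) return(NA)
    v <- rep(NA_real_, max(sc$pos))
    v[sc$pos] <- sc$score
    if (pos > length(v)) return(NA)
    classify_disorder(v, pos, window = config$disorder_window,
                      cutoff = config$disorder_cutoff)
  }
  cons_for <- function(protein, pos, wild_aa) {
    for (g in sort(names(groups))) {
      if (protein %in% names(groups[[g]])) {
        pr <- conservation_fraction(groups[[g]], protein, pos, wild_aa)
        return(c(pr$f_Cons, 0))
      }
    }
    c(NA_real_, 1)   # fallback needed; filled with the species average
  }

  n <- nrow(sites)
  res <- data.frame(
    protein = sites$protein, species = sites$species,
    site = paste(sites$wild_aa, sites$pos, sep = " "),
    interactor = sites$interactor, template = sites$template,
    pdbres = rep(NA_character_, n), status = rep("scored", n),
    disordered = rep(NA, n), exposure = rep(NA_character_, n),
    IE = rep(NA_real_, n), f_ID = rep(NA_real_, n),
    f_Cons = rep(NA_real_, n), S_switch = rep(NA_real_, n),
    label = rep(NA_character_, n), fallback_f_Cons = rep(FALSE, n),
    stringsAsFactors = FALSE
  )
  if ("throughput" %in% names(sites)) res$throughput <- sites$throughput

  for (i in seq_len(n)) {
    row <- sites[i, ]
    res$disordered[i] <- disorder_flag(row$protein, row$pos)
    tpl <- strsplit(row$template, ":")[[1]]
    if (length(tpl) != 3) {
      res$status[i] <- "unmapped"
      next
    }
    sid <- tpl[1]; ca <- tpl[2]; cb <- tpl[3]
    entry <- get_struct(sid)
    aln_a <- get_aln(row$protein, sid, ca)
    if (is.null(entry) || is.null(aln_a)) {
      res$status[i] <- "unmapped"
      next
    }
    chain_res <- entry$asa[entry$asa$chain_id == ca, , drop = FALSE]
    m <- map_site_to_template(row$pos, aln_a,
                              template_positions = chain_res$seq_pos)
    if (is.null(m)) {
      res$status[i] <- "unmapped"
      next
    }
    tr <- chain_res[chain_res$seq_pos == m$template_pos, , drop = FALSE][1, ]
    res$pdbres[i] <- paste0(ca, m$template_pos,
                            if (nzchar(tr$icode)) tr$icode else "", " ",
                            tr$aa)
    res$exposure[i] <- classify_exposure(tr$sidechain_asa,
                                         cutoff = config$asa_buried_cutoff)
    aln_b <- get_aln(row$interactor, sid, cb)
    res$f_ID[i] <- tryCatch(
      if (is.null(aln_b)) fraction_identity(aln_a)
      else fraction_identity(aln_a, aln_b),
      error = function(e) NA_real_)
    fc <- cons_for(row$protein, row$pos, row$wild_aa)
    res$f_Cons[i] <- fc[1]
    res$fallback_f_Cons[i] <- fc[2] == 1
    iface <- get_iface(sid, ca, cb)
    if (is.null(iface)) {
      res$status[i] <- "unmapped"
      next
    }
    has_contact <- any(iface$contacts$pos_a == m$template_pos)
    ie <- tryCatch(
      interaction_effect(iface, ca, m$template_pos, matrix,
                         site_aa = row$wild_aa),
      error = function(e) NA_real_)
    if (!has_contact) res$status[i] <- "no-interface"
    res$IE[i] <- ie
  }
  # species-average f_Cons fallback, computed from the scored corpus
  for (sp in unique(res$species)) {
    sel <- (is.na(res$species) & is.na(sp)) |
      (!is.na(res$species) & !is.na(sp) & res$species == sp)
    have <- sel & !res$fallback_f_Cons & !is.na(res$f_Cons)
    avg <- if (any(have)) mean(res$f_Cons[have]) else NA_real_
    res$f_Cons[sel & res$fallback_f_Cons] <- avg
  }
  ok <- !is.na(res$IE) & !is.na(res$f_ID) & !is.na(res$f_Cons)
  res$S_switch[ok] <- s_switch(res$IE[ok], res$f_ID[ok], res$f_Cons[ok])
  res$label[ok] <- classify_switch(res$S_switch[ok],
                                   threshold = config$switch_threshold)

  scored <- res[!is.na(res$S_switch), , drop = FALSE]
  agg <- if (nrow(scored)) {
    keys <- unique(scored[, c("protein", "site", "interactor")])
    do.call(rbind, lapply(seq_len(nrow(keys)), function(k) {
      sub <- scored[scored$protein == keys$protein[k] &
                      scored$site == keys$site[k] &
                      scored$interactor == keys$interactor[k], ,
                    drop = FALSE]
      aggregate_templates(sub)
    }))
  } else res[0, , drop = FALSE]
  rownames(agg) <- NULL

  if (!is.null(out)) {
    fmt <- function(df) {
      for (cl in c("IE", "f_ID", "f_Cons", "S_switch")) {
        df[[cl]] <- ifelse(is.na(df[[cl]]), NA,
                           formatC(df[[cl]], format = "f", digits = 4))
      }
      df
    }
    .write_tsv(fmt(res), out)
    .write_tsv(fmt(agg), paste0(out, ".aggregated.tsv"))
  }
  list(full = res, aggregated = agg)
}

#' Fig-1b-style category counts for a scored corpus
#'
#' Counts sites by pipeline category: total, ordered (not disordered),
#' matched to a template, surface exposed, in an interface (at least one
#' inter-chain contact), and predicted enabling/disabling.
#'
#' @param full The `full` data frame from [score_sites_pipeline()].
#' @return Named integer vector of per-site counts.
#' @export
pipeline_category_counts <- function(full) {
  key <- paste(full$protein, full$site)
  per_site <- function(flag) length(unique(key[flag]))
  c(
    total = length(unique(key)),
    ordered = per_site(!is.na(full$disordered) & !full$disordered),
    matched = per_site(full$status != "unmapped"),
    exposed = per_site(!is.na(full$exposure) & full$exposure == "exposed"),
    interface = per_site(full$status == "scored"),
    enabling = per_site(!is.na(full$label) & full$label == "enabling"),
    disabling = per_site(!is.na(full$label) & full$label == "disabling")
  )
}
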