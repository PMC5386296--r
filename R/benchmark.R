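# run expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Load a benchmark table of labelled site-interactor pairs
#'
#' Tab-separated with at least the columns `set` (`positive`/`negative`),
#' `protein`, `site`, `interactor` and `effect` (`enabling`, `disabling`
#' or `unknown`); the feature columns `IE`, `f_ID`, `f_Cons`, `S_switch`,
#' an optional pass-through `ddG` column and a 0/1 `kinase` flag are
#' carried when present.  Unknown effects are kept but flagged.
#'
#' @param path TSV file path.
#' @return Data frame of benchmark entries (with logical `kinase` and
#'   `effect_known` columns).
#' @export
load_benchmark_table <- function(path) {
  df <- .read_tsv(path)
  mandatory <- c("set", "protein", "site", "interactor", "effect")
  miss <- setdiff(mandatory, names(df))
  if (length(miss)) stop("benchmark table missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- !(df$set %in% c("positive", "negative"))
  if (any(bad)) stop("invalid set value(s): ",
                     paste(unique(df$set[bad]), collapse = ", "))
  if ("kinase" %in% names(df)) {
    df$kinase <- df$kinase %in% c("1", 1, TRUE, "TRUE", "yes")
  }
  df$effect_known <- df$effect %in% c("enabling", "disabling")
  df
}

#' Build an exposure-matched shuffled negative set
#'
#' For each positive site, `n_shuffles` serine/threonine/tyrosine positions
#' are drawn without replacement from the same protein, restricted to
#' positions in the same surface-exposure class (buried/exposed) as the
#' positive so that the exposure distribution of the positives is
#' preserved; the interactor and the annotated effect are copied to each
#' shuffled position.  When no same-class position exists any S/T/Y is
#' used (logged); a protein with no alternative S/T/Y at all skips the
#' positive with a warning.  Deterministic for a fixed seed.
#'
#' @param positives Data frame with columns `protein`, `pos`, `interactor`,
#'   `effect` (and optionally `kinase`).
#' @param protein_sequences Named character vector of protein sequences.
#' @param exposure Data frame (`protein`, `pos`, `exposure` in
#'   buried/exposed) covering candidate S/T/Y positions; positions absent
#'   from it are treated as exposure-unknown and only used by the
#'   fallback.
#' @param n_shuffles Negatives drawn per positive.
#' @param seed Integer seed.
#' @return Data frame of negative entries (`set = "negative"`, shuffled
#'   `pos`/`wild_aa`, `source_pos` of the originating positive).
#' @export
build_negative_set <- function(positives, protein_sequences, exposure,
                               n_shuffles = 10L, seed = 1L) {
  stopifnot(all(c("protein", "pos", "interactor", "effect") %in%
                  names(positives)))
  exp_key <- paste(exposure$protein, exposure$pos)
  exposure_of <- function(protein, pos) {
    i <- match(paste(protein, pos), exp_key)
    if (is.na(i)) NA_character_ else exposure$exposure[i]
  }
  .with_seed(seed, {
    out <- list()
    for (i in seq_len(nrow(positives))) {
      p <- positives[i, , drop = FALSE]
      seqstr <- protein_sequences[[p$protein]]
      if (is.null(seqstr)) {
        warning("no sequence for ", p$protein, "; positive skipped")
        next
      }
      chars <- strsplit(seqstr, "")[[1]]
      sty <- setdiff(which(chars %in% c("S", "T", "Y")), p$pos)
      if (!length(sty)) {
        warning("no alternative S/T/Y in ", p$protein, "; positive skipped")
        next
      }
      cls <- exposure_of(p$protein, p$pos)
      cand_cls <- vapply(sty, function(q) exposure_of(p$protein, q),
                         character(1))
      cand <- if (!is.na(cls)) sty[!is.na(cand_cls) & cand_cls == cls]
              else integer()
      if (!length(cand)) {
        message("no exposure-matched S/T/Y for ", p$protein, " pos ",
                p$pos, "; falling back to any S/T/Y")
        cand <- sty
      }
      take <- sample(cand, min(n_shuffles, length(cand)))
      if (length(take) < n_shuffles) {
        message("only ", length(take), " of ", n_shuffles,
                " negatives available for ", p$protein, " pos ", p$pos)
      }
      out[[length(out) + 1L]] <- data.frame(
        set = "negative", protein = p$protein, pos = take,
        wild_aa = chars[take], interactor = p$interactor,
        effect = p$effect, source_pos = p$pos,
        kinase = if ("kinase" %in% names(p)) p$kinase else NA,
        stringsAsFactors = FALSE
      )
    }
    if (!length(out)) {
      return(data.frame(set = character(), protein = character(),
                        pos = integer(), wild_aa = character(),
                        interactor = character(), effect = character(),
                        source_pos = integer(), kinase = logical(),
                        stringsAsFactors = FALSE))
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Effect-signed predictor scores
#'
#' Encodes the ground truth for signed ROC evaluation: an enabling effect
#' should give a high positive score and a disabling effect a high
#' negative one, so disabling entries have their score sign flipped before
#' ranking.
#'
#' @param entries Benchmark data frame (columns `effect` and `score_col`).
#' @param score_col Name of the score column (default `"S_switch"`).
#' @return Numeric vector of signed scores.
#' @export
effect_signed_scores <- function(entries, score_col = "S_switch") {
  s <- entries[[score_col]]
  ifelse(entries$effect == "disabling", -s, s)
}

#' ROC and precision-recall curves
#'
#' Threshold sweep over the observed scores (predicted positive when
#' score >= threshold), with trapezoidal AUC.  `direction = "absolute"`
#' ranks by |score|, for detecting switches irrespective of the direction
#' of the effect.
#'
#' @param scores Numeric scores.
#' @param labels Logical (or `"positive"`/`"negative"`) true labels.
#' @param direction `"high_positive"` or `"absolute"`.
#' @return Object of class `"roc_curve"`: data frame of curve points
#'   (threshold, tp, fp, fn, tn, fpr, tpr, precision, recall), `auc`, and
#'   the scores/labels used.
#' @export
roc_pr_curves <- function(scores, labels,
                          direction = c("high_positive", "absolute")) {
  direction <- match.arg(direction)
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels) == "positive"
  }
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(labels))
  if (!any(labels) || all(labels)) {
    stop("ROC needs at least one positive and one negative")
  }
  s <- if (direction == "absolute") abs(scores) else scores
  np <- sum(labels)
  nn <- sum(!labels)
  thr <- c(Inf, sort(unique(s), decreasing = TRUE))
  pts <- do.call(rbind, lapply(thr, function(t) {
    pred <- s >= t
    tp <- sum(pred & labels); fp <- sum(pred & !labels)
    data.frame(threshold = t, tp = tp, fp = fp, fn = np - tp,
               tn = nn - fp, fpr = fp / nn, tpr = tp / np,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = tp / np)
  }))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc, scores = s, labels = labels,
                 direction = direction),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("roc_curve:", sum(x$labels), "positives,", sum(!x$labels),
      "negatives, AUC =", round(x$auc, 4), "\n")
  invisible(x)
}

#' Operating point at a bounded false positive rate
#'
#' Selects the smallest (most permissive) score threshold whose false
#' positive rate does not exceed `max_fpr`, and reports the confusion
#' statistics and the two-sided Fisher's exact p-value of the resulting
#' 2x2 table.
#'
#' @param curve A `roc_curve`.
#' @param max_fpr FPR bound (default 0.05).
#' @return List of class `"roc_summary"`: auc, threshold, fpr, tpr, tnr,
#'   accuracy, ppv, p_value, and the confusion counts.
#' @export
threshold_at_fpr <- function(curve, max_fpr = 0.05) {
  stopifnot(inherits(curve, "roc_curve"))
  pts <- curve$points
  ok <- pts[pts$fpr <= max_fpr, , drop = FALSE]
  best <- ok[which.min(ok$threshold), , drop = FALSE]
  p <- if (best$tp + best$fp + best$fn + best$tn > 0 &&
           (best$tp + best$fp) * (best$fn + best$tn) +
           (best$tp + best$fn) * (best$fp + best$tn) > 0) {
    fisher_exact_p(best$tp, best$fp, best$fn, best$tn)
  } else NA_real_
  structure(list(
    auc = curve$auc, threshold = best$threshold, fpr = best$fpr,
    tpr = best$tpr, tnr = 1 - best$fpr,
    accuracy = (best$tp + best$tn) / (best$tp + best$fp + best$fn + best$tn),
    ppv = best$precision, p_value = p,
    counts = c(tp = best$tp, fp = best$fp, fn = best$fn, tn = best$tn)
  ), class = "roc_summary")
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf(
    "roc_summary: AUC %.3f | cut %.4g | fpr %.3f tpr %.3f acc %.3f ppv %s | p %.3g\n",
    x$auc, x$threshold, x$fpr, x$tpr, x$accuracy,
    ifelse(is.na(x$ppv), "NA", sprintf("%.3f", x$ppv)), x$p_value))
  invisible(x)
}

#' Two-sided Fisher's exact test on a 2x2 confusion table
#'
#' @param tp,fp,fn,tn Non-negative cell counts.
#' @return Two-sided p-value (sum of hypergeometric probabilities no
#'   larger than that of the observed table).
#' @export
fisher_exact_p <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  if (tp + fp + fn + tn == 0) stop("all-zero table")
  stats::fisher.test(matrix(c(tp, fn, fp, tn), 2))$p.value
}

#' Filter benchmark entries
#'
#' Sub-benchmarks used to probe robustness: dropping kinase interactors
#' (to control for kinase-substrate bias), requiring near-identical
#' structural templates (`min_f_ID`), or keeping one effect direction.
#'
#' @param entries Benchmark data frame.
#' @param exclude_kinase Drop entries whose interactor is a kinase.
#' @param min_f_ID Keep entries with `f_ID >=` this value (NA = no filter).
#' @param effect Keep only this effect (`"enabling"`/`"disabling"`; NA =
#'   no filter).
#' @return Filtered data frame.
#' @export
filter_benchmark <- function(entries, exclude_kinase = FALSE,
                             min_f_ID = NA, effect = NA) {
  keep <- rep(TRUE, nrow(entries))
  if (exclude_kinase) {
    stopifnot("kinase" %in% names(entries))
    keep <- keep & !entries$kinase
  }
  if (!is.na(min_f_ID)) keep <- keep & entries$f_ID >= min_f_ID
  if (!is.na(effect)) keep <- keep & entries$effect == effect
  entries[keep, , drop = FALSE]
}

#' @rdname filter_benchmark
#' @export
filter_kinase_interactors <- function(entries) {
  filter_benchmark(entries, exclude_kinase = TRUE)
}

#' Cross-validated logistic regression over benchmark features
#'
#' Balances the benchmark by undersampling the negative set to the number
#' of positives, runs k-fold cross-validation, and repeats; per repeat the
#' held-out predicted probabilities are pooled into one ROC, the operating
#' point at `max_fpr` is taken, and means and standard deviations of AUC,
#' threshold, FPR, TPR, TNR, accuracy and PPV are reported over repeats,
#' together with per-fold coefficient summaries.  A final unbalanced fit
#' on the full data is returned as well.  Deterministic for a fixed seed.
#'
#' @param entries Benchmark data frame (`set` plus feature columns).
#' @param features Feature column names (default IE, f_ID, f_Cons).
#' @param folds Cross-validation folds.
#' @param reps Repeats of balanced undersampling + CV.
#' @param seed Integer master seed; per-repeat substreams are derived from
#'   it.
#' @param max_fpr FPR bound for the operating point.
#' @return List of class `"logistic_cv"`: `stat_means`, `stat_sds`,
#'   `coef_means`, `coef_sds`, `per_rep` (data frame), `final_fit` (glm on
#'   the full set) and `final_roc`.
#' @export
logistic_cv <- function(entries, features = c("IE", "f_ID", "f_Cons"),
                        folds = 5L, reps = 100L, seed = 1L,
                        max_fpr = 0.05) {
  stopifnot(all(features %in% names(entries)), "set" %in% names(entries))
  y <- entries$set == "positive"
  pos_idx <- which(y)
  neg_idx <- which(!y)
  n_pos <- length(pos_idx)
  if (n_pos < folds || length(neg_idx) < folds) {
    stop("need at least `folds` positives and negatives")
  }
  X <- entries[, features, drop = FALSE]
  form <- stats::as.formula(paste("y ~", paste(features, collapse = " + ")))

  rep_stats <- vector("list", reps)
  rep_coefs <- vector("list", reps)
  for (r in seq_len(reps)) {
    .with_seed(seed + r, {
      neg_take <- sample(neg_idx, n_pos)
      idx <- c(pos_idx, neg_take)
      yy <- y[idx]
      dd <- cbind(data.frame(y = yy), X[idx, , drop = FALSE])
      # fold assignment; re-drawn if a training fold would be single-class
      for (attempt in 1:20) {
        fold <- sample(rep_len(seq_len(folds), length(idx)))
        ok <- all(vapply(seq_len(folds), function(k) {
          tr <- dd$y[fold != k]
          any(tr) && !all(tr)
        }, logical(1)))
        if (ok) break
        message("single-class fold; resampling fold assignment")
      }
      prob <- rep(NA_real_, length(idx))
      cf <- matrix(NA_real_, folds, length(features) + 1L)
      for (k in seq_len(folds)) {
        fit <- suppressWarnings(
          stats::glm(form, family = stats::binomial(),
                     data = dd[fold != k, , drop = FALSE],
                     control = stats::glm.control(epsilon = 1e-8,
                                                  maxit = 100))
        )
        prob[fold == k] <- suppressWarnings(
          stats::predict(fit, newdata = dd[fold == k, , drop = FALSE],
                         type = "response"))
        cf[k, ] <- stats::coef(fit)
      }
      colnames(cf) <- c("(Intercept)", features)
      curve <- roc_pr_curves(prob, yy)
      op <- threshold_at_fpr(curve, max_fpr)
      rep_stats[[r]] <- data.frame(
        rep = r, auc = curve$auc, threshold = op$threshold, fpr = op$fpr,
        tpr = op$tpr, tnr = op$tnr, accuracy = op$accuracy, ppv = op$ppv,
        n_pos = sum(yy), n_neg = sum(!yy)
      )
      rep_coefs[[r]] <- cf
    })
  }
  per_rep <- do.call(rbind, rep_stats)
  all_cf <- do.call(rbind, rep_coefs)
  stat_cols <- c("auc", "threshold", "fpr", "tpr", "tnr", "accuracy", "ppv")
  final_fit <- suppressWarnings(
    stats::glm(form, family = stats::binomial(),
               data = cbind(data.frame(y = y), X),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  )
  final_prob <- stats::fitted(final_fit)
  structure(list(
    stat_means = colMeans(per_rep[, stat_cols], na.rm = TRUE),
    stat_sds = apply(per_rep[, stat_cols], 2, stats::sd, na.rm = TRUE),
    coef_means = colMeans(all_cf),
    coef_sds = apply(all_cf, 2, stats::sd),
    per_rep = per_rep,
    final_fit = final_fit,
    final_roc = roc_pr_curves(final_prob, y)
  ), class = "logistic_cv")
}

#' @export
print.logistic_cv <- function(x, ...) {
  cat("logistic_cv over", nrow(x$per_rep), "repeats\n")
  cat("  mean AUC", round(x$stat_means[["auc"]], 4),
      "| mean accuracy", round(x$stat_means[["accuracy"]], 4), "\n")
  cat("  coefficients:",
      paste(names(x$coef_means), round(x$coef_means, 3), collapse = ", "),
      "\n")
  invisible(x)
}

#' Compare a site property between two groups
#'
#' Continuous properties (accessible surface area, conservation fractions)
#' are compared with the Wilcoxon-Mann-Whitney rank-sum test; binary
#' classifications with a 2x2 chi-square test (no continuity correction)
#' on the category counts.
#'
#' @param values_a,values_b The two groups: numeric vectors (continuous)
#'   or logical/0-1 vectors (binary).
#' @param kind `"continuous"` or `"binary"`.
#' @return List with `statistic` and `p_value`.
#' @export
compare_site_properties <- function(values_a, values_b,
                                    kind = c("continuous", "binary")) {
  kind <- match.arg(kind)
  if (!length(values_a) || !length(values_b)) stop("empty group")
  if (kind == "continuous") {
    ht <- suppressWarnings(stats::wilcox.test(values_a, values_b))
    list(statistic = unname(ht$statistic), p_value = ht$p.value)
  } else {
    m <- rbind(a = c(sum(values_a %in% c(1, TRUE)),
                     sum(!values_a %in% c(1, TRUE))),
               b = c(sum(values_b %in% c(1, TRUE)),
                     sum(!values_b %in% c(1, TRUE))))
    ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    list(statistic = unname(ht$statistic), p_value = ht$p.value)
  }
}
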