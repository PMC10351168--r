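# Cohort-level immunogenomic statistics: recurrence, self-dissimilarity,
# intratumor heterogeneity, immunoediting odds ratios, the covariate-adjusted
# logistic depletion model, and neoantigen burden metrics.

#' Neoantigenic rate
#'
#' Number of neoantigens generated per mutation. Undefined (NA) when there
#' are no mutations.
#'
#' @param n_neoantigens,n_mutations Non-negative counts.
#' @return Numeric rate, or `NA` when `n_mutations == 0`.
#' @export
neoantigenic_rate <- function(n_neoantigens, n_mutations) {
  if (n_neoantigens < 0 || n_mutations < 0) stop("counts must be non-negative")
  if (n_mutations == 0) return(NA_real_)
  n_neoantigens / n_mutations
}

#' Shared-neoantigen occurrence across a cohort
#'
#' Counts, for every peptide sequence, the number of distinct patients in
#' which it was called; a peptide is recurrent when seen in more than two
#' patients. Within-patient duplicates do not inflate counts.
#'
#' @param records data.frame with columns `patient` and `sequence` (or
#'   `peptide`).
#' @return data.frame with `sequence`, `n_patients`, `recurrent`, sorted by
#'   descending count then sequence.
#' @export
shared_occurrence <- function(records) {
  if (!is.null(records$peptide) && is.null(records$sequence)) {
    records$sequence <- records$peptide
  }
  if (!nrow(records)) {
    return(data.frame(sequence = character(0), n_patients = integer(0),
                      recurrent = logical(0)))
  }
  u <- unique(records[, c("sequence", "patient")])
  tab <- table(u$sequence)
  out <- data.frame(sequence = names(tab), n_patients = as.integer(tab))
  out$recurrent <- out$n_patients > 2L
  out <- out[order(-out$n_patients, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' k-mer x allele binding interaction map
#'
#' For a mutated neo-peptide segment, enumerates all 8-11-mers, predicts
#' their binding against an allele set, and counts the interactions (calls
#' passing the neoantigen thresholds) per k-mer. Counts are also reported on
#' a log10(n+1) scale for heatmap export.
#'
#' @param neo_peptide Amino-acid string of the mutated segment (length >= 8).
#' @param alleles Character vector of MHC-I alleles.
#' @param backend A `BindingBackend`.
#' @param ic50_threshold,rank_threshold Neoantigen thresholds.
#' @return data.frame with `kmer`, `k`, `offset`, `n_interactions`,
#'   `log10_interactions`; total interaction count as
#'   `attr(, "total_interactions")`.
#' @export
kmer_allele_interactions <- function(neo_peptide, alleles, backend,
                                     ic50_threshold = 500,
                                     rank_threshold = 2.0) {
  stopifnot(nchar(neo_peptide) >= 8)
  L <- nchar(neo_peptide)
  rows <- list()
  for (k in 8:11) {
    if (L < k) next
    for (start in 0:(L - k)) {
      rows[[length(rows) + 1L]] <- data.frame(
        kmer = substr(neo_peptide, start + 1L, start + k),
        k = k, offset = start)
    }
  }
  km <- do.call(rbind, rows)
  calls <- predict_binding(unique(km$kmer), alleles, backend)
  pass <- calls[calls$ic50 < ic50_threshold & calls$rank < rank_threshold, ,
                drop = FALSE]
  n_pass <- table(factor(pass$peptide, levels = unique(km$kmer)))
  km$n_interactions <- as.integer(n_pass[km$kmer])
  km$log10_interactions <- log10(km$n_interactions + 1)
  attr(km, "total_interactions") <- sum(km$n_interactions)
  km
}

#' Build the wild-type peptidome for self-dissimilarity
#'
#' Cleaves every proteome protein into its 8-11-mers.
#'
#' @param proteome Named character vector of protein sequences.
#' @return Character vector of unique 8-11-mer peptides.
#' @export
peptidome_kmers <- function(proteome) {
  out <- character(0)
  for (p in proteome) {
    L <- nchar(p)
    for (k in 8:11) {
      if (L < k) next
      starts <- 1:(L - k + 1)
      out <- c(out, substring(p, starts, starts + k - 1L))
    }
  }
  unique(out)
}

#' Self-dissimilarity of a neoantigen peptide
#'
#' Finds the most similar wild-type counterpart in the peptidome by local
#' (Smith-Waterman) alignment under BLOSUM62 with gap open 11 / extend 1,
#' and classifies the peptide HIGH-similarity when the best raw score
#' strictly exceeds the threshold (default 35). The peptidome may be held
#' either as full proteins (default; local alignment maxima against short
#' queries are identical) or as the explicit 8-11-mer set.
#'
#' @param peptide Amino-acid string (standard alphabet).
#' @param peptidome Character vector: full proteins (`mode = "protein"`) or
#'   8-11-mers (`mode = "kmer"`, e.g. from [peptidome_kmers()]).
#' @param mode `"protein"` or `"kmer"`.
#' @param threshold Raw-score threshold for the HIGH class (strict `>`).
#' @param gap_open,gap_extend Gap penalties (positive costs).
#' @return List with `score` (best raw score; `NA` on an empty peptidome)
#'   and `class` (`"HIGH"` or `"LOW"`).
#' @export
self_dissimilarity <- function(peptide, peptidome,
                               mode = c("protein", "kmer"),
                               threshold = 35, gap_open = 11, gap_extend = 1) {
  mode <- match.arg(mode)
  peptidome <- peptidome[nzchar(peptidome)]
  if (!length(peptidome)) return(list(score = NA_real_, class = "LOW"))
  data("BLOSUM62", package = "Biostrings", envir = environment())
  scores <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(rep(peptide, length(peptidome))),
    subject = Biostrings::AAStringSet(peptidome),
    type = "local", substitutionMatrix = BLOSUM62,
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE)
  best <- max(scores)
  list(score = best, class = if (best > threshold) "HIGH" else "LOW")
}

#' Fraction of subclonal neoantigens (intratumor heterogeneity)
#'
#' @param clonality Character vector of per-neoantigen clonality labels;
#'   `"UNKNOWN"` entries are excluded.
#' @return Fraction subclonal in \[0, 1\], or `NA` when no labelled
#'   neoantigens remain.
#' @export
ith_fraction <- function(clonality) {
  lab <- clonality[clonality %in% c("CLONAL", "SUBCLONAL")]
  if (!length(lab)) return(NA_real_)
  mean(lab == "SUBCLONAL")
}

#' Odds ratio with the Haldane-Anscombe correction
#'
#' OR = (a d) / (b c) on a 2x2 table (rows = group, columns = outcome). If
#' any cell is zero, 0.5 is added to all four cells before computing, which
#' keeps the ratio finite. A table with an all-zero row or column is flagged
#' degenerate.
#'
#' @param tab 2x2 numeric matrix (or length-4 vector `a, b, c, d` filled
#'   by row).
#' @return List with `or`, `corrected` (logical), `degenerate` (logical).
#' @export
odds_ratio_haldane <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(tab, nrow = 2, byrow = TRUE)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  corrected <- any(tab == 0)
  t2 <- if (corrected) tab + 0.5 else tab
  list(or = (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1]),
       corrected = corrected, degenerate = degenerate)
}

#' Odds ratio from two proportions
#'
#' Ratio of the odds implied by two proportions, e.g. the neoantigenic
#' proportions of oncogenic versus passenger SVs.
#'
#' @param p1,p2 Proportions in (0, 1).
#' @return Numeric odds ratio (odds(p1) / odds(p2)).
#' @export
odds_ratio_from_proportions <- function(p1, p2) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1)
  (p1 / (1 - p1)) / (p2 / (1 - p2))
}

#' Per-patient clonal vs subclonal neoantigen-generation odds ratios
#'
#' For every patient with at least one clonal and one subclonal SV, builds
#' the 2x2 table (rows subclonal/clonal, columns neoantigenic/not) and
#' computes the Haldane-Anscombe odds ratio; OR > 1 means neoantigen-
#' generating SVs are enriched among subclonal SVs. The cohort-level
#' one-sample test locates the median log-OR against 0 by the Wilcoxon
#' signed-rank procedure (exact below n = 25, normal approximation above).
#'
#' @param sv_table data.frame with columns `patient`, `clonality`
#'   (CLONAL/SUBCLONAL; other labels excluded), and `neoantigenic`
#'   (logical).
#' @return List with `per_patient` (data.frame patient/or/log_or), `skipped`
#'   (data.frame patient/reason), `median_or`, and `p_value`.
#' @export
clonal_subclonal_or <- function(sv_table) {
  sv_table <- sv_table[sv_table$clonality %in% c("CLONAL", "SUBCLONAL"), ,
                       drop = FALSE]
  pats <- unique(sv_table$patient)
  res <- list(); skipped <- list()
  for (p in pats) {
    sub <- sv_table[sv_table$patient == p, , drop = FALSE]
    if (!any(sub$clonality == "CLONAL") || !any(sub$clonality == "SUBCLONAL")) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(patient = p, reason = "needs >=1 clonal and >=1 subclonal SV")
      next
    }
    a <- sum(sub$clonality == "SUBCLONAL" & sub$neoantigenic)
    b <- sum(sub$clonality == "SUBCLONAL" & !sub$neoantigenic)
    c_ <- sum(sub$clonality == "CLONAL" & sub$neoantigenic)
    d <- sum(sub$clonality == "CLONAL" & !sub$neoantigenic)
    or <- odds_ratio_haldane(matrix(c(a, b, c_, d), 2, byrow = TRUE))$or
    res[[length(res) + 1L]] <- data.frame(patient = p, or = or,
                                          log_or = log(or))
  }
  per_patient <- if (length(res)) do.call(rbind, res)
                 else data.frame(patient = character(0), or = numeric(0),
                                 log_or = numeric(0))
  skipped <- if (length(skipped)) do.call(rbind, skipped)
             else data.frame(patient = character(0), reason = character(0))
  p_value <- if (nrow(per_patient) >= 3) {
    stats::wilcox.test(per_patient$log_or, mu = 0,
                       exact = nrow(per_patient) < 25)$p.value
  } else NA_real_
  list(per_patient = per_patient, skipped = skipped,
       median_or = if (nrow(per_patient)) stats::median(per_patient$or)
                   else NA_real_,
       p_value = p_value)
}

#' Covariate-adjusted logistic depletion model
#'
#' Fits logit(P) = b0 + b1 X1 + b2 X2 + b3 X3, where P is the probability
#' of an SV generating a neoantigen, X1 indicates an oncogenic SV, X2 is the
#' number of affected amino acids, and X3 indicates a frameshift SV.
#' Maximum likelihood by iteratively reweighted least squares (convergence
#' tolerance 1e-8, at most 100 iterations); standard errors come from the
#' observed information. Non-varying covariates are dropped from the fit and
#' reported with coefficient 0. Perfect separation marks the fit
#' non-converged and the coefficients unreliable.
#'
#' @param design data.frame with columns `X1`, `X2`, `X3`, and binary `y`
#'   (at least 10 rows).
#' @return A `LogisticFit`: list with `coefficients` (named b0, b1, b2, b3),
#'   `se`, `converged`, `iterations`, `wald_z`, `wald_p` (test of b1 = 0).
#' @export
depletion_logistic <- function(design) {
  stopifnot(all(c("X1", "X2", "X3", "y") %in% names(design)),
            nrow(design) >= 10)
  stopifnot(all(design$y %in% c(0, 1)))
  vars <- c("X1", "X2", "X3")
  varying <- vars[vapply(vars, function(v) length(unique(design[[v]])) > 1,
                         logical(1))]
  f <- if (length(varying))
    stats::as.formula(paste("y ~", paste(varying, collapse = " + ")))
  else stats::as.formula("y ~ 1")
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(f, family = stats::binomial(), data = design,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- stats::coef(summary(fit))
  nm <- c("b0" = "(Intercept)", "b1" = "X1", "b2" = "X2", "b3" = "X3")
  coefs <- stats::setNames(rep(0, 4), names(nm))
  ses <- stats::setNames(rep(NA_real_, 4), names(nm))
  for (i in seq_along(nm)) {
    if (nm[i] %in% rownames(co)) {
      coefs[i] <- co[nm[i], "Estimate"]
      ses[i] <- co[nm[i], "Std. Error"]
    }
  }
  # separation also shows up as runaway coefficient magnitudes
  if (any(abs(stats::coef(fit)) > 15)) separated <- TRUE
  converged <- fit$converged && !separated
  z <- if (!is.na(ses["b1"]) && ses["b1"] > 0) coefs["b1"] / ses["b1"] else NA_real_
  structure(list(coefficients = coefs, se = ses, converged = converged,
                 iterations = fit$iter,
                 wald_z = unname(z),
                 wald_p = if (is.na(z)) NA_real_ else
                   2 * stats::pnorm(-abs(unname(z)))),
            class = "LogisticFit")
}

#' @export
#' @method print LogisticFit
print.LogisticFit <- function(x, ...) {
  cat("Logistic depletion model",
      if (x$converged) "(converged)" else "(NOT converged; unreliable)", "\n")
  print(data.frame(coef = x$coefficients, se = x$se))
  cat(sprintf("Wald test of b1 = 0: z = %.3f, p = %.3g\n", x$wald_z, x$wald_p))
  invisible(x)
}

#' Neoantigen burden metrics
#'
#' TNB (tumor neoantigen burden) counts SNV+indel neoantigens, SVNB the
#' SV-derived ones, and GANB (genomic alteration-related neoantigen burden)
#' their sum. Classification uses the exome-scale high-burden threshold
#' (default > 323 neoantigens); a patient is "rescued" when TNB is below the
#' threshold but GANB exceeds it.
#'
#' @param snv_neo,indel_neo,sv_neo Non-negative neoantigen counts.
#' @param threshold High-burden cutoff (strict `>`, default 323).
#' @return A `BurdenRecord`: list with `TNB`, `SVNB`, `GANB`, `TNB_high`,
#'   `GANB_high`, `rescued`.
#' @export
burdens <- function(snv_neo, indel_neo, sv_neo, threshold = 323) {
  stopifnot(snv_neo >= 0, indel_neo >= 0, sv_neo >= 0)
  tnb <- snv_neo + indel_neo
  ganb <- tnb + sv_neo
  structure(list(TNB = tnb, SVNB = sv_neo, GANB = ganb,
                 TNB_high = tnb > threshold, GANB_high = ganb > threshold,
                 rescued = (tnb <= threshold) && (ganb > threshold),
                 threshold = threshold),
            class = "BurdenRecord")
}

#' @export
#' @method print BurdenRecord
print.BurdenRecord <- function(x, ...) {
  cat(sprintf("TNB %s, SVNB %s, GANB %s (threshold %s): %s\n",
              x$TNB, x$SVNB, x$GANB, x$threshold,
              if (x$rescued) "rescued by SV neoantigens"
              else if (x$GANB_high) "high burden" else "low burden"))
  invisible(x)
}
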