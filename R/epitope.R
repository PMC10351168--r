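# Peptide windowing, self filtering, and binding-threshold neoantigen calls.

#' Window a neo-protein into candidate peptides
#'
#' Enumerates every k-mer (k in `[k_min, k_max]`) of the neo-protein that
#' overlaps the mutated span by at least one residue. Windows containing X
#' (ambiguous-codon residues) are excluded.
#'
#' @param np A `NeoProtein` with `mutated_span` computed, or a list with
#'   `sequence` and `mutated_span`.
#' @param k_min,k_max Window size bounds (defaults 8 and 11).
#' @return data.frame with columns `sequence`, `k`, `protein_offset`
#'   (0-based start in the neo-protein), and `mutated_positions`
#'   (comma-separated 0-based indices within the peptide).
#' @export
window_peptides <- function(np, k_min = 8L, k_max = 11L) {
  stopifnot(k_min >= 1, k_min <= k_max)
  empty <- data.frame(sequence = character(0), k = integer(0),
                      protein_offset = integer(0),
                      mutated_positions = character(0))
  span <- np$mutated_span
  if (is.null(span) || span[2] <= span[1]) return(empty)
  s <- np$sequence
  L <- nchar(s)
  rows <- list()
  for (k in seq(k_min, k_max)) {
    if (L < k) next
    for (start in 0:(L - k)) {
      if (start >= span[2] || start + k <= span[1]) next   # no overlap
      pep <- substr(s, start + 1L, start + k)
      if (grepl("X", pep, fixed = TRUE)) next
      mut <- seq.int(max(span[1], start), min(span[2], start + k) - 1L) - start
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = pep, k = k, protein_offset = start,
        mutated_positions = paste(mut, collapse = ","))
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Remove self peptides
#'
#' Drops every candidate peptide whose sequence occurs as an exact substring
#' of any wild-type protein. With `mode = "parents"` only the proteins named
#' in each peptide's `donor_gene`/`acceptor_gene` columns are searched;
#' the default screens the whole annotation proteome. Duplicate rows (same
#' patient and sequence) are collapsed with their SV provenance merged.
#' The operation is idempotent and its output is disjoint from the proteome
#' substring set.
#'
#' @param peptides data.frame from [window_peptides()] (plus optional
#'   provenance columns `patient`, `sv_id`, `donor_gene`, `acceptor_gene`).
#' @param proteome Named character vector of wild-type protein sequences
#'   (names are gene ids), e.g. from [txdb_proteome()].
#' @param mode `"proteome"` (default) or `"parents"`.
#' @return The filtered data.frame, input order preserved.
#' @export
filter_self <- function(peptides, proteome, mode = c("proteome", "parents")) {
  mode <- match.arg(mode)
  if (!nrow(peptides)) return(peptides)
  is_self <- vapply(seq_len(nrow(peptides)), function(i) {
    pep <- peptides$sequence[i]
    targets <- proteome
    if (mode == "parents") {
      keep <- names(proteome) %in% c(peptides$donor_gene[i],
                                     peptides$acceptor_gene[i])
      targets <- proteome[keep]
    }
    any(vapply(targets, function(p) grepl(pep, p, fixed = TRUE), logical(1)))
  }, logical(1))
  out <- peptides[!is_self, , drop = FALSE]
  if (!nrow(out)) { rownames(out) <- NULL; return(out) }
  # collapse per-patient duplicates, merging provenance
  patient <- if (!is.null(out$patient)) out$patient else ""
  key <- paste(patient, out$sequence, sep = "\r")
  if (anyDuplicated(key)) {
    first <- !duplicated(key)
    if (!is.null(out$sv_id)) {
      merged <- vapply(split(out$sv_id, key), function(v)
        paste(unique(v), collapse = ";"), character(1))
      out$sv_id[first] <- merged[key[first]]
    }
    out <- out[first, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Predict MHC binding for peptide x allele pairs
#'
#' Dispatches to a `BindingBackend` and enforces the totality contract:
#' exactly one call per peptide x allele pair must come back.
#'
#' @param peptides Character vector (or data.frame with a `sequence`
#'   column) of peptides.
#' @param alleles Character vector of MHC-I allele names.
#' @param backend A `BindingBackend` (see [mock_backend()],
#'   [netmhcpan_backend()]).
#' @return data.frame with columns peptide, allele, ic50, rank.
#' @export
predict_binding <- function(peptides, alleles, backend) {
  stopifnot(inherits(backend, "BindingBackend"))
  if (is.data.frame(peptides)) peptides <- peptides$sequence
  peptides <- unique(peptides)
  calls <- backend$predict(peptides, alleles)
  expected <- length(peptides) * length(alleles)
  if (nrow(calls) != expected) {
    stop("backend ", backend$name, " returned ", nrow(calls),
         " calls for ", expected, " peptide x allele pairs")
  }
  calls
}

#' Call neoantigens from binding predictions
#'
#' A peptide becomes a neoantigen iff at least one call has
#' `ic50 < ic50_threshold` AND `rank < rank_threshold` (both strict). All
#' passing allele calls are attached; the best allele is the one with the
#' minimum IC50.
#'
#' @param peptides data.frame of candidate peptides (column `sequence` plus
#'   provenance).
#' @param calls data.frame from [predict_binding()].
#' @param ic50_threshold IC50 cutoff in nM (default 500).
#' @param rank_threshold Percentile-rank cutoff (default 2.0).
#' @return data.frame of neoantigen records, one row per peptide, with
#'   `best_allele`, `best_ic50`, `best_rank`, `n_alleles`,
#'   `passing_alleles`; the full passing-call table is attached as
#'   `attr(, "calls")`.
#' @export
call_neoantigens <- function(peptides, calls, ic50_threshold = 500,
                             rank_threshold = 2.0) {
  stopifnot(ic50_threshold > 0, rank_threshold >= 0)
  pass <- calls[calls$ic50 < ic50_threshold & calls$rank < rank_threshold, ,
                drop = FALSE]
  keep <- peptides$sequence %in% pass$peptide
  out <- peptides[keep, , drop = FALSE]
  if (nrow(out)) {
    best <- lapply(out$sequence, function(s) {
      sub <- pass[pass$peptide == s, , drop = FALSE]
      sub <- sub[order(sub$ic50, sub$allele), , drop = FALSE]
      data.frame(best_allele = sub$allele[1], best_ic50 = sub$ic50[1],
                 best_rank = sub$rank[1], n_alleles = nrow(sub),
                 passing_alleles = paste(sub$allele, collapse = ";"))
    })
    out <- cbind(out, do.call(rbind, best))
  } else {
    out$best_allele <- character(0); out$best_ic50 <- numeric(0)
    out$best_rank <- numeric(0); out$n_alleles <- integer(0)
    out$passing_alleles <- character(0)
  }
  rownames(out) <- NULL
  attr(out, "calls") <- pass[pass$peptide %in% out$sequence, , drop = FALSE]
  out
}

#' Hydrophobic residue fraction of a peptide
#'
#' Fraction of residues in the hydrophobic set \{V, I, L, F, M, W, C\}.
#'
#' @param peptide Amino-acid string.
#' @return Numeric in \[0, 1\].
#' @export
hydrophobic_fraction <- function(peptide) {
  if (!nzchar(peptide)) stop("empty peptide")
  res <- strsplit(peptide, "")[[1]]
  mean(res %in% c("V", "I", "L", "F", "M", "W", "C"))
}

#' Read an HLA allele list
#'
#' One allele per line (e.g. `HLA-A*02:01`); blank lines and `#` comments
#' are ignored.
#'
#' @param path Path to a text file.
#' @return Character vector of allele names.
#' @export
read_alleles <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
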