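# End-to-end orchestration: VCF -> annotation/filters -> neo-ORF assembly
# and translation -> peptide windowing and self filtering -> binding
# prediction -> neoantigen calls, with a stage-by-stage funnel report.

#' Run configuration for the prediction pipeline
#'
#' Defaults mirror the method's standard operating point: 8-11-mer windows,
#' IC50 < 500 nM and rank < 2.0 (both strict).
#'
#' @param vcf,gtf,fasta,alleles Input paths (`alleles` may also be a
#'   character vector of allele names).
#' @param outdir Optional output directory.
#' @param backend A `BindingBackend`, or one of `"mock"`, `"always"`,
#'   `"never"`, `"netmhcpan"`.
#' @param seed Seed for the mock backend.
#' @param ic50_threshold,rank_threshold,k_min,k_max Calling parameters.
#' @param sample Patient label used when the VCF carries none.
#' @param self_filter_mode `"proteome"` or `"parents"` (see
#'   [filter_self()]).
#' @param allow_one_intergenic,start_rescue,include_start_rescued Flags; see
#'   [annotate_sv()], [assemble_neo_transcript()], [translate_neo()].
#' @return A `RunConfig` list.
#' @export
run_config <- function(vcf, gtf, fasta, alleles, outdir = NULL,
                       backend = "mock", seed = 1L,
                       ic50_threshold = 500, rank_threshold = 2.0,
                       k_min = 8L, k_max = 11L, sample = NULL,
                       self_filter_mode = "proteome",
                       allow_one_intergenic = FALSE,
                       start_rescue = FALSE,
                       include_start_rescued = FALSE) {
  stopifnot(ic50_threshold > 0, rank_threshold >= 0, k_min <= k_max)
  structure(as.list(environment()), class = "RunConfig")
}

.resolve_backend <- function(backend, seed) {
  if (inherits(backend, "BindingBackend")) return(backend)
  switch(backend,
         mock = mock_backend(seed = seed, mode = "hash"),
         always = mock_backend(seed = seed, mode = "always"),
         never = mock_backend(seed = seed, mode = "never"),
         netmhcpan = netmhcpan_backend(),
         stop("unknown backend: ", backend))
}

#' Run the SV neoantigen prediction pipeline
#'
#' Executes all stages on one sample and reports a funnel: parsed SVs,
#' feasible junctions, assembled/translated neo-proteins, candidate
#' peptides, and neoantigen calls, with every drop attributed to a reason.
#' At each stage survivors plus per-reason drops equal the stage input.
#' With a deterministic backend, re-running an identical configuration
#' produces identical outputs.
#'
#' @param cfg A `RunConfig` from [run_config()].
#' @return A `PipelineRun` list: `summary` (stage counts), `drops`
#'   (reason table), `junctions`, `annotations`, `proteins`, `peptides`,
#'   `neoantigens` (data.frames), and `files` when `outdir` was set.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  for (p in c(cfg$vcf, cfg$gtf, cfg$fasta)) {
    if (!file.exists(p)) stop("input not readable: ", p)
  }
  alleles <- if (length(cfg$alleles) == 1 && file.exists(cfg$alleles))
    read_alleles(cfg$alleles) else cfg$alleles
  backend <- .resolve_backend(cfg$backend, cfg$seed)
  genome <- load_genome(cfg$fasta)
  txdb <- load_annotation(cfg$gtf)
  proteome <- txdb_proteome(txdb, genome)

  parsed <- parse_sv_vcf(cfg$vcf, sample = cfg$sample, genome = genome)
  drops <- list()
  drop <- function(stage, id, reason) {
    drops[[length(drops) + 1L]] <<- data.frame(stage = stage, id = id,
                                               reason = reason)
  }
  for (i in seq_len(nrow(parsed$rejects))) {
    drop("parse", parsed$rejects$id[i], parsed$rejects$reason[i])
  }

  anns <- lapply(parsed$pairs, annotate_sv, txdb = txdb,
                 allow_one_intergenic = cfg$allow_one_intergenic)
  feasible <- list()
  for (a in anns) {
    if (a$feasible) feasible[[length(feasible) + 1L]] <- a
    else drop("filter", a$pair$id, a$reject_reason)
  }

  proteins <- list()
  for (a in feasible) {
    nt <- assemble_neo_transcript(a, txdb, genome,
                                  start_rescue = cfg$start_rescue)
    if (is.character(nt)) { drop("assembly", a$pair$id, nt); next }
    wt <- wt_protein(a$ends[[a$donor_end]]$transcript, genome)
    np <- translate_neo(nt, wt = wt)
    if (is.character(np)) { drop("translation", a$pair$id, np); next }
    np$sv_id <- a$pair$id
    np$patient <- a$pair$patient
    np$clonality <- a$pair$clonality
    np$sv_class <- a$sv_class
    np$gene_context <- a$gene_context
    proteins[[length(proteins) + 1L]] <- np
  }

  pep_rows <- list()
  for (np in proteins) {
    if (np$start_rescued && !cfg$include_start_rescued) {
      drop("windowing", np$sv_id, "START_RESCUED_EXCLUDED")
      next
    }
    w <- window_peptides(np, k_min = cfg$k_min, k_max = cfg$k_max)
    if (!nrow(w)) { drop("windowing", np$sv_id, "EMPTY_MUTATED_SPAN"); next }
    w$sv_id <- np$sv_id; w$patient <- np$patient
    w$clonality <- np$clonality
    w$donor_gene <- np$donor_gene; w$acceptor_gene <- np$acceptor_gene
    w$sv_class <- np$sv_class; w$frameshift <- np$frameshift
    w$termination <- np$termination; w$gene_context <- np$gene_context
    pep_rows[[length(pep_rows) + 1L]] <- w
  }
  peptides_all <- if (length(pep_rows)) do.call(rbind, pep_rows)
                  else data.frame(sequence = character(0), k = integer(0),
                                  protein_offset = integer(0),
                                  mutated_positions = character(0),
                                  sv_id = character(0), patient = character(0))
  peptides <- filter_self(peptides_all, proteome,
                          mode = cfg$self_filter_mode)

  if (nrow(peptides) && length(alleles)) {
    calls <- predict_binding(peptides$sequence, alleles, backend)
    neoantigens <- call_neoantigens(peptides, calls,
                                    ic50_threshold = cfg$ic50_threshold,
                                    rank_threshold = cfg$rank_threshold)
  } else {
    calls <- data.frame(peptide = character(0), allele = character(0),
                        ic50 = numeric(0), rank = numeric(0))
    neoantigens <- call_neoantigens(peptides, calls,
                                    ic50_threshold = cfg$ic50_threshold,
                                    rank_threshold = cfg$rank_threshold)
  }

  drops_df <- if (length(drops)) do.call(rbind, drops)
              else data.frame(stage = character(0), id = character(0),
                              reason = character(0))
  protein_df <- if (length(proteins)) do.call(rbind, lapply(proteins,
    function(np) data.frame(
      sv_id = np$sv_id, patient = np$patient, donor_gene = np$donor_gene,
      acceptor_gene = np$acceptor_gene, sv_class = np$sv_class,
      gene_context = np$gene_context, frameshift = np$frameshift,
      termination = np$termination, start_rescued = np$start_rescued,
      junction_aa = np$junction_aa, mutated_start = np$mutated_span[1],
      mutated_end = np$mutated_span[2], sequence = np$sequence)))
    else data.frame(sv_id = character(0), sequence = character(0))
  summary <- c(parsed = length(parsed$pairs) + nrow(parsed$rejects),
               canonical = length(parsed$pairs),
               feasible = length(feasible),
               proteins = length(proteins),
               peptides = nrow(peptides),
               neoantigens = nrow(neoantigens))
  run <- structure(list(summary = summary, drops = drops_df,
                        junctions = pairs_to_table(parsed$pairs),
                        annotations = annotations_to_table(anns),
                        proteins = protein_df, peptides = peptides,
                        neoantigens = neoantigens, calls = calls,
                        config = cfg),
                   class = "PipelineRun")
  if (!is.null(cfg$outdir)) run$files <- write_run(run, cfg$outdir)
  run
}

#' @export
#' @method print PipelineRun
print.PipelineRun <- function(x, ...) {
  cat("svneo pipeline run\n")
  s <- x$summary
  cat(sprintf("  records parsed     %d\n", s["parsed"]))
  cat(sprintf("  canonical junctions %d\n", s["canonical"]))
  cat(sprintf("  feasible junctions %d\n", s["feasible"]))
  cat(sprintf("  neo-proteins       %d\n", s["proteins"]))
  cat(sprintf("  candidate peptides %d\n", s["peptides"]))
  cat(sprintf("  neoantigens        %d\n", s["neoantigens"]))
  if (nrow(x$drops)) {
    cat("  drops by stage/reason:\n")
    tab <- stats::aggregate(id ~ stage + reason, x$drops, length)
    for (i in seq_len(nrow(tab))) {
      cat(sprintf("    %-11s %-24s %d\n", tab$stage[i], tab$reason[i],
                  tab$id[i]))
    }
  }
  invisible(x)
}

#' Write pipeline outputs
#'
#' Emits the junction/annotation/protein/peptide/neoantigen tables as TSV,
#' the neo-protein and peptide FASTAs, and a machine-readable run report
#' (JSON). Files are written atomically (temp file + rename).
#'
#' @param run A `PipelineRun`.
#' @param outdir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- c()
  wtsv <- function(df, name) {
    path <- file.path(outdir, name)
    tmp <- paste0(path, ".tmp")
    utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
    file.rename(tmp, path)
    files[name] <<- path
  }
  wtsv(run$junctions, "junctions.tsv")
  wtsv(run$annotations, "annotations.tsv")
  wtsv(run$proteins, "neo_orfs.tsv")
  wtsv(run$peptides, "peptides.tsv")
  wtsv(run$neoantigens, "neoantigens.tsv")
  wtsv(run$drops, "drops.tsv")
  # neo-protein FASTA: sv_id|donor|acceptor|frameshift|termination
  fa <- file.path(outdir, "neo_proteins.fa")
  tmp <- paste0(fa, ".tmp")
  con <- file(tmp, "w")
  for (i in seq_len(nrow(run$proteins))) {
    p <- run$proteins[i, ]
    writeLines(c(sprintf(">%s|%s|%s|%s|%s", p$sv_id, p$donor_gene,
                         p$acceptor_gene, p$frameshift, p$termination),
                 p$sequence), con)
  }
  close(con)
  file.rename(tmp, fa)
  files["neo_proteins.fa"] <- fa
  pf <- file.path(outdir, "peptides.fa")
  tmp <- paste0(pf, ".tmp")
  con <- file(tmp, "w")
  for (i in seq_len(nrow(run$peptides))) {
    writeLines(c(sprintf(">%s_%d", run$peptides$sv_id[i],
                         run$peptides$protein_offset[i]),
                 run$peptides$sequence[i]), con)
  }
  close(con)
  file.rename(tmp, pf)
  files["peptides.fa"] <- pf
  report <- list(summary = as.list(run$summary),
                 backend = .resolve_backend(run$config$backend,
                                            run$config$seed)$name,
                 seed = run$config$seed,
                 thresholds = list(ic50 = run$config$ic50_threshold,
                                   rank = run$config$rank_threshold,
                                   k_min = run$config$k_min,
                                   k_max = run$config$k_max))
  rp <- file.path(outdir, "run_report.json")
  jsonlite::write_json(report, rp, auto_unbox = TRUE, pretty = TRUE)
  files["run_report.json"] <- rp
  invisible(files)
}
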