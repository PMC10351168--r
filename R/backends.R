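# Pluggable MHC-I binding backends.
#
# A BindingBackend is a list with a name and a predict(peptides, alleles)
# function returning exactly one row per peptide x allele with columns
# peptide, allele, ic50 (nM), rank (percentile). Backends must be
# deterministic for fixed inputs and total: every pair is answered or the
# call fails loudly.

# 32-bit-safe polynomial string hash folded with a salt; pure double
# arithmetic, values stay < 2^53
.svneo_hash <- function(s, salt) {
  h <- (salt %% 2147483647) + 1
  for (code in utf8ToInt(s)) {
    h <- (h * 131 + code) %% 2147483647
  }
  # final scramble for better low-bit spread
  h <- (h * 2654435761) %% 2147483647
  h / 2147483647
}

#' Deterministic mock MHC binding backend
#'
#' Hashes (peptide, allele, seed) to a uniform IC50 in \[1, 50000\] nM and a
#' percentile rank in \[0, 100\]. The `"always"` mode returns calls passing
#' the default neoantigen thresholds for every pair, `"never"` calls that
#' always fail; both support round-trip tests without an external predictor.
#'
#' @param seed Integer seed mixed into the hash.
#' @param mode `"hash"`, `"always"`, or `"never"`.
#' @return A `BindingBackend`.
#' @export
mock_backend <- function(seed = 1L, mode = c("hash", "always", "never")) {
  mode <- match.arg(mode)
  predict_fun <- function(peptides, alleles) {
    grid <- expand.grid(peptide = peptides, allele = alleles,
                        stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    if (!nrow(grid)) {
      return(data.frame(peptide = character(0), allele = character(0),
                        ic50 = numeric(0), rank = numeric(0)))
    }
    if (mode == "always") {
      grid$ic50 <- 50; grid$rank <- 0.5
    } else if (mode == "never") {
      grid$ic50 <- 5000; grid$rank <- 50
    } else {
      key <- paste0(grid$peptide, "|", grid$allele)
      u1 <- vapply(key, .svneo_hash, numeric(1), salt = seed * 7919 + 13)
      u2 <- vapply(key, .svneo_hash, numeric(1), salt = seed * 104729 + 89)
      grid$ic50 <- 1 + u1 * 49999
      grid$rank <- u2 * 100
    }
    rownames(grid) <- NULL
    grid
  }
  structure(list(name = paste0("mock-", mode, "-seed", seed),
                 predict = predict_fun),
            class = "BindingBackend")
}

#' @export
#' @method print BindingBackend
print.BindingBackend <- function(x, ...) {
  cat("BindingBackend:", x$name, "\n")
  invisible(x)
}

#' Parse NetMHCpan-style tabular output
#'
#' Parses the whitespace-separated result block of the external binding
#' predictor: data lines start with a numeric position field and carry the
#' allele, peptide, affinity (nM) and percentile rank columns named in the
#' header. Used by [netmhcpan_backend()]; exposed for testing against
#' captured output fixtures.
#'
#' @param lines Character vector of raw output lines.
#' @return data.frame with columns peptide, allele, ic50, rank.
#' @export
parse_netmhcpan_output <- function(lines) {
  header_i <- grep("^\\s*Pos\\s", lines)
  if (!length(header_i)) stop("no header line found in predictor output")
  header <- strsplit(trimws(lines[header_i[1]]), "\\s+")[[1]]
  aff_col <- grep("^Aff|nM", header)
  rank_col <- grep("Rank_BA", header)[1]          # affinity rank when present
  if (is.na(rank_col)) rank_col <- grep("Rank", header)[1]
  pep_col <- match("Peptide", header)
  allele_col <- grep("HLA|Allele|MHC", header)[1]
  if (is.na(pep_col) || !length(aff_col) || is.na(rank_col) || is.na(allele_col)) {
    stop("unrecognized predictor output header: ", lines[header_i[1]])
  }
  data_lines <- lines[grepl("^\\s*[0-9]+\\s", lines)]
  out <- lapply(data_lines, function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(f) < max(aff_col[1], rank_col, pep_col, allele_col)) {
      stop("truncated data line in predictor output: ", l)
    }
    data.frame(peptide = f[pep_col], allele = f[allele_col],
               ic50 = as.numeric(f[aff_col[1]]),
               rank = as.numeric(f[rank_col]))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# shared driver for external predictor binaries
.external_predict <- function(binary, args_for, parser, peptides, alleles,
                              name) {
  if (!nzchar(Sys.which(binary))) {
    stop(name, " backend requires the '", binary, "' binary on PATH; ",
         "install it or use mock_backend() instead")
  }
  pepfile <- tempfile(fileext = ".pep")
  on.exit(unlink(pepfile), add = TRUE)
  writeLines(peptides, pepfile)
  out <- lapply(alleles, function(al) {
    res <- suppressWarnings(
      system2(binary, args_for(pepfile, al), stdout = TRUE, stderr = FALSE))
  status <- attr(res, "status")
    if (!is.null(status) && status != 0) {
      stop(name, " binary exited with status ", status)
    }
    parsed <- parser(res)
    if (nrow(parsed) != length(peptides)) {
      stop(name, " returned ", nrow(parsed), " rows for ", length(peptides),
           " peptides (allele ", al, "): refusing partial output")
    }
    parsed$peptide <- peptides       # positional mapping back to the query
    parsed$allele <- al
    parsed
  })
  do.call(rbind, out)
}

#' External NetMHCpan adapter backend
#'
#' Thin adapter around the NetMHCpan binary (binding affinity is not
#' modelled in this package). The binary is invoked in batch per allele and
#' its tabular output is mapped back to the query peptides positionally.
#'
#' @param binary Name or path of the executable.
#' @return A `BindingBackend`.
#' @export
netmhcpan_backend <- function(binary = "netMHCpan") {
  structure(list(
    name = paste0("netmhcpan:", binary),
    predict = function(peptides, alleles) {
      if (!length(peptides) || !length(alleles)) {
        return(data.frame(peptide = character(0), allele = character(0),
                          ic50 = numeric(0), rank = numeric(0)))
      }
      .external_predict(binary,
                        function(pf, al) c("-p", pf, "-a", al, "-BA"),
                        parse_netmhcpan_output, peptides, alleles,
                        "NetMHCpan")
    }), class = "BindingBackend")
}

#' Parse NetMHCstabPan-style tabular output
#'
#' @param lines Character vector of raw output lines.
#' @return data.frame with columns peptide, allele, half_life, stab_rank.
#' @export
parse_netmhcstabpan_output <- function(lines) {
  header_i <- grep("^\\s*Pos\\s", lines)
  if (!length(header_i)) stop("no header line found in predictor output")
  header <- strsplit(trimws(lines[header_i[1]]), "\\s+")[[1]]
  pep_col <- match("Peptide", header)
  allele_col <- grep("HLA|Allele|MHC", header)[1]
  thalf_col <- grep("Thalf|half", header)[1]
  rank_col <- grep("Rank", header)[1]
  if (is.na(pep_col) || is.na(thalf_col)) {
    stop("unrecognized stability output header: ", lines[header_i[1]])
  }
  data_lines <- lines[grepl("^\\s*[0-9]+\\s", lines)]
  do.call(rbind, c(lapply(data_lines, function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    data.frame(peptide = f[pep_col], allele = f[allele_col],
               half_life = as.numeric(f[thalf_col]),
               stab_rank = as.numeric(f[rank_col]))
  }), list(make.row.names = FALSE)))
}

#' Binding-stability scores (adapter-only)
#'
#' Passthrough to an external stability predictor (NetMHCstabPan-style) or a
#' deterministic mock; no stability model is implemented in this package.
#'
#' @param peptides Character vector of peptides.
#' @param alleles Character vector of MHC-I alleles.
#' @param backend `"mock"` for the seeded deterministic stand-in, or a
#'   binary name/path for the external adapter.
#' @param seed Seed for the mock.
#' @return data.frame with peptide, allele, half_life (hours), stab_rank.
#' @export
binding_stability <- function(peptides, alleles, backend = "mock", seed = 1L) {
  if (!length(peptides) || !length(alleles)) {
    return(data.frame(peptide = character(0), allele = character(0),
                      half_life = numeric(0), stab_rank = numeric(0)))
  }
  if (identical(backend, "mock")) {
    grid <- expand.grid(peptide = peptides, allele = alleles,
                        stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    key <- paste0(grid$peptide, "|", grid$allele)
    u1 <- vapply(key, .svneo_hash, numeric(1), salt = seed * 31337 + 7)
    u2 <- vapply(key, .svneo_hash, numeric(1), salt = seed * 271 + 3)
    grid$half_life <- u1 * 12          # hours
    grid$stab_rank <- u2 * 100
    rownames(grid) <- NULL
    return(grid)
  }
  .external_predict(backend, function(pf, al) c("-p", pf, "-a", al),
                    parse_netmhcstabpan_output, peptides, alleles,
                    "NetMHCstabPan")
}
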