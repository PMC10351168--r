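# SV VCF reading/writing and breakend canonicalization.
#
# Orientation semantics are side-retained: LEFT means reference bases <= pos
# are retained and joined at the junction; RIGHT means bases >= pos are
# retained. The four VCF bracket forms map as
#   t[p[  -> this LEFT,  mate RIGHT
#   t]p]  -> this LEFT,  mate LEFT
#   ]p]t  -> this RIGHT, mate LEFT
#   [p[t  -> this RIGHT, mate RIGHT

#' Construct a breakend
#' @param chrom Chromosome name.
#' @param pos 1-based reference coordinate of the retained boundary base.
#' @param orient `"LEFT"` or `"RIGHT"` (side retained).
#' @return A `Breakend`.
#' @export
breakend <- function(chrom, pos, orient) {
  stopifnot(pos >= 1, orient %in% c("LEFT", "RIGHT"))
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 orient = orient), class = "Breakend")
}

#' @export
#' @method print Breakend
print.Breakend <- function(x, ...) {
  cat(sprintf("Breakend %s:%d (%s)\n", x$chrom, x$pos, x$orient))
  invisible(x)
}

#' Construct a somatic SV junction (breakend pair)
#' @param id Record identifier.
#' @param first,second `Breakend`s.
#' @param declared_type Optional label from the source file (e.g. "DEL").
#' @param clonality `"CLONAL"`, `"SUBCLONAL"`, or `"UNKNOWN"`.
#' @param patient Sample identifier.
#' @param insseq Micro-homology/inserted sequence from the ALT, kept as
#'   metadata only.
#' @return An `SvBreakendPair`.
#' @export
sv_pair <- function(id, first, second, declared_type = NA_character_,
                    clonality = "UNKNOWN", patient = NA_character_,
                    insseq = NA_character_) {
  stopifnot(inherits(first, "Breakend"), inherits(second, "Breakend"))
  if (first$chrom == second$chrom && first$pos == second$pos &&
      first$orient == second$orient) {
    stop("breakend pair must join two distinct breakends")
  }
  structure(list(id = as.character(id), first = first, second = second,
                 declared_type = declared_type, clonality = clonality,
                 patient = patient, insseq = insseq),
            class = "SvBreakendPair")
}

#' @export
#' @method print SvBreakendPair
print.SvBreakendPair <- function(x, ...) {
  cat(sprintf("SvBreakendPair %s: %s:%d(%s) -- %s:%d(%s)%s\n", x$id,
              x$first$chrom, x$first$pos, x$first$orient,
              x$second$chrom, x$second$pos, x$second$orient,
              if (!is.na(x$declared_type)) paste0(" [", x$declared_type, "]") else ""))
  invisible(x)
}

# order-insensitive canonical key of a pair
.pair_key <- function(p) {
  k1 <- sprintf("%s:%d:%s", p$first$chrom, p$first$pos, p$first$orient)
  k2 <- sprintf("%s:%d:%s", p$second$chrom, p$second$pos, p$second$orient)
  paste(sort(c(k1, k2)), collapse = "|")
}

# decode a bracket ALT; returns list(this_orient, mate_chrom, mate_pos,
# mate_orient, insseq) or NULL if unparseable
.decode_bracket_alt <- function(alt) {
  m <- regmatches(alt, regexec(
    "^([ACGTNacgtn]*)([\\[\\]])([^\\[\\]:]+):([0-9]+)([\\[\\]])([ACGTNacgtn]*)$",
    alt, perl = TRUE))[[1]]
  if (!length(m)) return(NULL)
  pre <- m[2]; br1 <- m[3]; mchrom <- m[4]; mpos <- as.integer(m[5])
  br2 <- m[6]; post <- m[7]
  if (br1 != br2) return(NULL)
  if (nchar(pre) > 0 && nchar(post) > 0) return(NULL)
  if (nchar(pre) == 0 && nchar(post) == 0) return(NULL)
  if (nchar(pre) > 0) {          # t[p[ or t]p]
    this_orient <- "LEFT"
    mate_orient <- if (br1 == "[") "RIGHT" else "LEFT"
    ins <- if (nchar(pre) > 1) substr(pre, 2, nchar(pre)) else NA_character_
  } else {                       # ]p]t or [p[t
    this_orient <- "RIGHT"
    mate_orient <- if (br1 == "]") "LEFT" else "RIGHT"
    ins <- if (nchar(post) > 1) substr(post, 1, nchar(post) - 1) else NA_character_
  }
  list(this_orient = this_orient, mate_chrom = mchrom, mate_pos = mpos,
       mate_orient = mate_orient, insseq = ins)
}

# normalize a chromosome name against the genome's naming ("chr" prefix
# stripped/added); hard error when no variant matches
.normalize_chrom <- function(chrom, genome_names) {
  if (is.null(genome_names)) return(chrom)
  if (chrom %in% genome_names) return(chrom)
  alt <- if (startsWith(chrom, "chr")) sub("^chr", "", chrom)
         else paste0("chr", chrom)
  if (alt %in% genome_names) return(alt)
  stop("chromosome ", chrom,
       " not found in genome (after chr-prefix normalization)")
}

.parse_info_field <- function(info, key) {
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))[[1]]
  if (length(m) < 2) NA_character_ else m[2]
}

#' Parse somatic SVs from a VCF file
#'
#' Canonicalizes breakend (BND bracket notation) and symbolic
#' (`<DEL>`/`<DUP>`/`<INV>`/`<TRA>`) records into orientation-resolved
#' breakend pairs. Each junction appears exactly once: BND mates are
#' deduplicated via MATEID (or by coordinates for self-contained records).
#' Symbolic `<INV>` records expand into two pairs, the head-to-head
#' (`_h2h`) and tail-to-tail (`_t2t`) junctions. Records that cannot be
#' canonicalized are returned in `$rejects` with a reason, never silently
#' dropped.
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @param sample Optional sample/patient name attached to every pair;
#'   overridden by a per-record `PATIENT` INFO key when present.
#' @param genome Optional `GenomeSequence` used to normalize chromosome
#'   names (the "chr" prefix is stripped/added to match).
#' @return A list with `pairs` (list of `SvBreakendPair`) and `rejects`
#'   (data.frame id/reason).
#' @export
parse_sv_vcf <- function(path, sample = NULL, genome = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  gnames <- if (!is.null(genome)) genome_names(genome) else NULL
  pairs <- list()
  rejects <- data.frame(id = character(0), reason = character(0))
  reject <- function(id, reason) {
    rejects <<- rbind(rejects, data.frame(id = id, reason = reason))
  }
  if (is.null(fix) || nrow(fix) == 0) {
    return(list(pairs = pairs, rejects = rejects))
  }
  seen <- character(0)       # canonical pair keys already emitted
  id_of <- fix[, "ID"]
  bnd_ids <- character(0)
  for (r in seq_len(nrow(fix))) {
    chrom <- fix[r, "CHROM"]; pos <- as.integer(fix[r, "POS"])
    id <- fix[r, "ID"]; alt <- fix[r, "ALT"]; info <- fix[r, "INFO"]
    if (is.na(id) || id == ".") id <- sprintf("rec%d", r)
    svtype <- .parse_info_field(info, "SVTYPE")
    clon <- .parse_info_field(info, "CLONALITY")
    if (is.na(clon)) clon <- "UNKNOWN"
    pat <- .parse_info_field(info, "PATIENT")
    if (is.na(pat) && !is.null(sample)) pat <- sample
    is_symbolic <- grepl("^<.+>$", alt)
    emit <- function(p) {
      key <- .pair_key(p)
      if (!(key %in% seen)) {
        seen <<- c(seen, key)
        pairs[[length(pairs) + 1L]] <<- p
      }
    }
    if (is_symbolic) {
      sym <- sub("^<(.+)>$", "\\1", alt)
      endv <- suppressWarnings(as.integer(.parse_info_field(info, "END")))
      if (sym %in% c("DEL", "DUP", "INV") && is.na(endv)) {
        reject(id, "missing END"); next
      }
      tryCatch({
        chromn <- .normalize_chrom(chrom, gnames)
        if (sym == "DEL") {
          emit(sv_pair(id, breakend(chromn, pos, "LEFT"),
                       breakend(chromn, endv, "RIGHT"),
                       declared_type = "DEL", clonality = clon, patient = pat))
        } else if (sym == "DUP") {
          emit(sv_pair(id, breakend(chromn, pos, "RIGHT"),
                       breakend(chromn, endv, "LEFT"),
                       declared_type = "DUP", clonality = clon, patient = pat))
        } else if (sym == "INV") {
          emit(sv_pair(paste0(id, "_h2h"), breakend(chromn, pos, "LEFT"),
                       breakend(chromn, endv, "LEFT"),
                       declared_type = "INV", clonality = clon, patient = pat))
          emit(sv_pair(paste0(id, "_t2t"), breakend(chromn, pos, "RIGHT"),
                       breakend(chromn, endv, "RIGHT"),
                       declared_type = "INV", clonality = clon, patient = pat))
        } else if (sym == "TRA") {
          chr2 <- .parse_info_field(info, "CHR2")
          ct <- .parse_info_field(info, "CT")
          orients <- if (is.na(ct)) NULL else
            switch(ct,
                   "3to5" = c("LEFT", "RIGHT"),
                   "5to3" = c("RIGHT", "LEFT"),
                   "3to3" = c("LEFT", "LEFT"),
                   "5to5" = c("RIGHT", "RIGHT"),
                   NULL)
          if (is.na(chr2) || is.na(endv)) {
            reject(id, "missing CHR2/END")
          } else if (is.null(orients)) {
            reject(id, "missing CT")
          } else {
            emit(sv_pair(id, breakend(chromn, pos, orients[1]),
                         breakend(.normalize_chrom(chr2, gnames), endv,
                                  orients[2]),
                         declared_type = "TRA", clonality = clon, patient = pat))
          }
        } else {
          reject(id, paste0("unknown symbolic type <", sym, ">"))
        }
      }, error = function(e) reject(id, conditionMessage(e)))
    } else if (identical(svtype, "BND") ||
               grepl("[", alt, fixed = TRUE) || grepl("]", alt, fixed = TRUE)) {
      bnd_ids <- c(bnd_ids, id)
      dec <- .decode_bracket_alt(alt)
      if (is.null(dec)) { reject(id, "unparseable ALT"); next }
      mate <- .parse_info_field(info, "MATEID")
      if (!is.na(mate) && !(mate %in% id_of)) {
        reject(id, "unpaired BND"); next
      }
      tryCatch({
        chromn <- .normalize_chrom(chrom, gnames)
        mchromn <- .normalize_chrom(dec$mate_chrom, gnames)
        pid <- if (!is.na(mate)) {
          # mates conventionally share a stem + _1/_2 suffix; use the stem
          s1 <- unname(sub("_[12]$", "", id)); s2 <- unname(sub("_[12]$", "", mate))
          if (isTRUE(s1 == s2)) s1 else paste(sort(c(id, mate)), collapse = "_")
        } else id
        emit(sv_pair(pid, breakend(chromn, pos, dec$this_orient),
                     breakend(mchromn, dec$mate_pos, dec$mate_orient),
                     declared_type = "BND", clonality = clon, patient = pat,
                     insseq = dec$insseq))
      }, error = function(e) reject(id, conditionMessage(e)))
    } else {
      reject(id, paste0("unknown symbolic type ", alt))
    }
  }
  list(pairs = pairs, rejects = rejects)
}

#' Write breakend pairs as a BND-dialect VCF
#'
#' Each pair is emitted as its two mate records with bracket ALTs and MATEID
#' cross-references, so that re-parsing reproduces the same pair set.
#'
#' @param pairs List of `SvBreakendPair`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(pairs, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate breakend id\">",
           "##INFO=<ID=CLONALITY,Number=1,Type=String,Description=\"Clonality label\">",
           "##INFO=<ID=PATIENT,Number=1,Type=String,Description=\"Patient id\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                 sep = "\t"))
  rows <- character(0)
  bracket_alt <- function(this, mate) {
    core <- if (mate$orient == "RIGHT")
      sprintf("[%s:%d[", mate$chrom, mate$pos)
    else
      sprintf("]%s:%d]", mate$chrom, mate$pos)
    if (this$orient == "LEFT") paste0("N", core) else paste0(core, "N")
  }
  for (p in pairs) {
    ids <- paste0(p$id, c("_1", "_2"))
    extra <- sprintf(";CLONALITY=%s%s", p$clonality,
                     if (!is.na(p$patient)) paste0(";PATIENT=", p$patient) else "")
    rows <- c(rows,
      paste(p$first$chrom, p$first$pos, ids[1], "N",
            bracket_alt(p$first, p$second), ".", "PASS",
            paste0("SVTYPE=BND;MATEID=", ids[2], extra), sep = "\t"),
      paste(p$second$chrom, p$second$pos, ids[2], "N",
            bracket_alt(p$second, p$first), ".", "PASS",
            paste0("SVTYPE=BND;MATEID=", ids[1], extra), sep = "\t"))
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Flatten breakend pairs to a canonical junction table
#' @param pairs List of `SvBreakendPair`.
#' @return data.frame with one row per junction.
#' @export
pairs_to_table <- function(pairs) {
  if (!length(pairs)) {
    return(data.frame(id = character(0), chromA = character(0),
                      posA = integer(0), orientA = character(0),
                      chromB = character(0), posB = integer(0),
                      orientB = character(0), declared_type = character(0),
                      patient = character(0), clonality = character(0)))
  }
  do.call(rbind, lapply(pairs, function(p) data.frame(
    id = p$id, chromA = p$first$chrom, posA = p$first$pos,
    orientA = p$first$orient, chromB = p$second$chrom, posB = p$second$pos,
    orientB = p$second$orient, declared_type = p$declared_type,
    patient = p$patient, clonality = p$clonality)))
}
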