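## Template/primer ingestion, batch orchestration and report writing.

.FASTA_EXT <- "\\.(fa|fasta|fna|ffn|frn|fas)(\\.gz)?$"

#' Read a primer or probe list
#'
#' Accepts FASTA (gzip allowed), whitespace-delimited `id sequence`
#' lines, or a bare single column of sequences (which get synthetic ids
#' P1..Pn).  Sequences must be 12-500 nt of IUPAC codes; duplicate
#' sequences are retained as distinct entries, which is what repeat-panel
#' searches with near-identical primers require.
#'
#' @param path File to read.
#' @return Named [Biostrings::DNAStringSet-class].
#' @export
readPrimers <- function(path) {
  if (!file.exists(path)) stop(sprintf("primer file not found: %s", path),
                               call. = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  firstLines <- tryCatch(readLines(con, warn = FALSE),
                         finally = close(con))
  firstLines <- firstLines[nzchar(trimws(firstLines))]
  if (!length(firstLines)) stop(sprintf("primer file is empty: %s", path),
                                call. = FALSE)
  if (startsWith(trimws(firstLines[1L]), ">")) {
    dss <- Biostrings::readDNAStringSet(path)
    ids <- sub("\\s.*$", "", names(dss))
    seqs <- as.character(dss)
  } else {
    parts <- strsplit(trimws(firstLines), "\\s+")
    ncol1 <- lengths(parts)
    if (all(ncol1 >= 2L)) {
      ids <- vapply(parts, `[`, "", 1L)
      seqs <- vapply(parts, `[`, "", 2L)
    } else {
      ids <- paste0("P", seq_along(parts))
      seqs <- vapply(parts, `[`, "", 1L)
    }
  }
  seqs <- vapply(seq_along(seqs), function(i)
    normalizeSeq(seqs[i], what = sprintf("primer '%s'", ids[i])), "")
  w <- nchar(seqs)
  if (any(w < 12L | w > 500L)) {
    bad <- which(w < 12L | w > 500L)[1L]
    stop(sprintf("primer '%s' has length %d; allowed range is 12..500",
                 ids[bad], w[bad]), call. = FALSE)
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Enumerate template records across files and directories
#'
#' A directory counts as one genome: all FASTA files inside (plain or
#' gzip) are taken in sorted path order.  Records are listed, not loaded,
#' so genomes are later streamed record by record; ids are qualified as
#' `file:record` to stay unique across files.
#'
#' @param paths Files and/or directories.
#' @return data.frame manifest with columns `file`, `recno`, `id`,
#'   `width`.
#' @export
readTemplates <- function(paths) {
  files <- character()
  for (p in paths) {
    if (!file.exists(p)) stop(sprintf("template path not found: %s", p),
                              call. = FALSE)
    if (dir.exists(p)) {
      inside <- sort(list.files(p, full.names = TRUE))
      skip <- inside[!grepl(.FASTA_EXT, inside, ignore.case = TRUE)]
      for (s in skip)
        warning(sprintf("skipping non-FASTA file: %s", s), call. = FALSE)
      files <- c(files, setdiff(inside, skip))
    } else {
      files <- c(files, p)
    }
  }
  out <- list()
  for (f in files) {
    fai <- tryCatch(Biostrings::fasta.index(f),
                    error = function(e) stop(sprintf(
                      "cannot parse FASTA file %s: %s", f, conditionMessage(e)),
                      call. = FALSE))
    if (!nrow(fai)) {
      warning(sprintf("empty FASTA file skipped: %s", f), call. = FALSE)
      next
    }
    ids <- sub("\\s.*$", "", fai$desc)
    out[[f]] <- data.frame(file = f, recno = fai$recno,
                           id = paste0(basename(f), ":", ids),
                           width = fai$seqlength,
                           stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no template records found", call. = FALSE)
  res <- do.call(rbind, unname(out))
  rownames(res) <- NULL
  res
}

## load one record of a manifest row (one record resident at a time)
.loadTemplateRecord <- function(file, recno) {
  fai <- Biostrings::fasta.index(file)
  as.character(Biostrings::readDNAStringSet(fai[fai$recno == recno, ]))[[1L]]
}

#' Run an in silico PCR analysis
#'
#' Orchestrates the whole pipeline: build the primer k-mer index once,
#' stream every template record, scan for binding sites, and - unless in
#' probe mode - pair convergent hits into predicted products.  Output is
#' deterministic for fixed inputs.
#'
#' @param templates Template input: path(s) to FASTA files/directories, a
#'   named character vector of sequences, or a
#'   [Biostrings::DNAStringSet-class].
#' @param primers Primer input: path to a primer file (see
#'   [readPrimers]), named character vector, or DNAStringSet.
#' @param cfg A [SearchConfig-class].
#' @param roles `"primer"` or `"probe"` (defaults to `"probe"` when
#'   `cfg@probeMode`).
#' @return A [PCRReport-class].
#' @examples
#' inst <- plantSites(templateLength = 4000, nPairs = 2, seed = 7)
#' rep <- inSilicoPCR(stats::setNames(inst@template, inst@templateId),
#'                    as.character(inst@primers), searchConfig())
#' rep
#' @export
inSilicoPCR <- function(templates, primers, cfg = searchConfig(),
                        roles = NULL) {
  stopifnot(is(cfg, "SearchConfig"))
  if (is.null(roles)) roles <- if (cfg@probeMode) "probe" else "primer"
  if (cfg@probeMode &&
      (cfg@minLen != 50L || cfg@maxLen != 5000L))
    warning("probe mode: product size bounds are ignored", call. = FALSE)

  ## primers
  if (is.character(primers) && length(primers) == 1L &&
      file.exists(primers) && !dir.exists(primers)) {
    primers <- readPrimers(primers)
  }
  if (is.character(primers)) {
    nm <- names(primers)
    if (is.null(nm)) nm <- paste0("P", seq_along(primers))
    primers <- Biostrings::DNAStringSet(vapply(seq_along(primers), function(i)
      normalizeSeq(primers[i], sprintf("primer '%s'", nm[i])), ""))
    names(primers) <- nm
  }
  if (!length(primers)) stop("empty primer set", call. = FALSE)
  idx <- buildKmerIndex(primers, k = if (is.na(cfg@k)) NULL else cfg@k,
                        roles = roles)

  ## templates: manifest of (loader, id)
  fromFiles <- is.character(templates) && all(nchar(templates) < 500) &&
    all(file.exists(templates) | dir.exists(templates))
  if (fromFiles) {
    manifest <- readTemplates(templates)
  } else {
    if (is(templates, "DNAStringSet")) {
      seqs <- as.character(templates)
      names(seqs) <- names(templates)
    } else seqs <- templates
    if (is.null(names(seqs))) names(seqs) <- paste0("T", seq_along(seqs))
    manifest <- data.frame(file = "<memory>", recno = seq_along(seqs),
                           id = names(seqs), width = nchar(seqs),
                           stringsAsFactors = FALSE)
  }

  hitsL <- list(); ampL <- list()
  tplLen <- integer()
  sumRows <- list()
  for (f in unique(manifest$file)) {
    t0 <- proc.time()[["elapsed"]]
    sub <- manifest[manifest$file == f, , drop = FALSE]
    nHits <- 0L; nAmp <- 0L
    for (j in seq_len(nrow(sub))) {
      tpl <- if (fromFiles) .loadTemplateRecord(sub$file[j], sub$recno[j])
             else seqs[[sub$recno[j]]]
      id <- sub$id[j]
      h <- scanTemplate(tpl, idx, cfg, templateId = id)
      tplLen[id] <- nchar(tpl)
      if (length(h)) hitsL[[id]] <- h
      nHits <- nHits + length(h)
      if (!cfg@probeMode) {
        a <- pairHits(h, tpl, cfg)
        if (length(a)) ampL[[id]] <- a
        nAmp <- nAmp + length(a)
      }
    }
    sumRows[[f]] <- data.frame(
      file = f, records = nrow(sub), bases = sum(sub$width),
      hits = nHits, amplicons = nAmp,
      seconds = round(proc.time()[["elapsed"]] - t0, 3),
      stringsAsFactors = FALSE)
  }
  allHits <- if (length(hitsL)) suppressWarnings(do.call(c, unname(hitsL)))
             else GenomicRanges::GRanges()
  allAmp <- if (length(ampL)) suppressWarnings(do.call(c, unname(ampL)))
            else GenomicRanges::GRanges()
  new("PCRReport", hits = allHits, amplicons = allAmp,
      summary = do.call(rbind, unname(sumRows)), config = cfg,
      templateLengths = tplLen)
}

#' Write the machine-readable TSV report
#'
#' One row per amplicon (or per hit in probe mode), with 1-based
#' inclusive coordinates and temperatures at one decimal place.  Repeated
#' runs on identical inputs produce byte-identical files.
#'
#' @param report A [PCRReport-class].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeReportTsv <- function(report, path) {
  if (report@config@probeMode) {
    df <- probeReport(report@hits)
    df$tm <- sprintf("%.1f", df$tm)
  } else {
    gr <- report@amplicons
    mc <- S4Vectors::mcols(gr)
    df <- data.frame(
      template = if (length(gr)) as.character(GenomicRanges::seqnames(gr)) else character(),
      forward_primer = as.character(mc$fwdPrimer),
      reverse_primer = as.character(mc$revPrimer),
      start_1based = GenomicRanges::start(gr),
      end_1based = GenomicRanges::end(gr),
      length = mc$length,
      fwd_mismatches = mc$fwdMismatches,
      rev_mismatches = mc$revMismatches,
      fwd_tm = sprintf("%.1f", mc$fwdTm),
      rev_tm = sprintf("%.1f", mc$revTm),
      ta = sprintf("%.1f", mc$ta),
      wraps_origin = mc$wrapsOrigin,
      stringsAsFactors = FALSE)
    if (!is.null(mc$sequence)) df$sequence <- as.character(mc$sequence)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write extracted amplicon sequences as FASTA
#'
#' @param report A [PCRReport-class] produced with
#'   `extractSequences = TRUE`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeAmpliconFasta <- function(report, path) {
  gr <- report@amplicons
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$sequence))
    stop("report has no sequences; run with extractSequences = TRUE",
         call. = FALSE)
  ids <- sprintf("%s:%d-%d %s/%s len=%d",
                 as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr), GenomicRanges::end(gr),
                 mc$fwdPrimer, mc$revPrimer, mc$length)
  out <- Biostrings::DNAStringSet(as.character(mc$sequence))
  names(out) <- ids
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}

#' Write the human-readable text summary
#'
#' Per-file sections with amplicon rows, followed by a run summary table
#' (file, bases, amplicons, seconds).
#'
#' @param report A [PCRReport-class].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeReportText <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  gr <- report@amplicons
  tpl <- names(report@templateLengths)
  for (id in tpl) {
    sel <- if (length(gr)) as.character(GenomicRanges::seqnames(gr)) == id
           else logical()
    cat(sprintf("## %s (%d bp): %d amplicon(s)\n", id,
                report@templateLengths[[id]], sum(sel)), file = con)
    if (any(sel)) {
      mc <- S4Vectors::mcols(gr[sel])
      cat(sprintf("  %s x %s  %d..%d  %d bp  Ta=%.1fC%s\n",
                  mc$fwdPrimer, mc$revPrimer,
                  GenomicRanges::start(gr[sel]), GenomicRanges::end(gr[sel]),
                  mc$length, mc$ta,
                  ifelse(mc$wrapsOrigin, " (wraps origin)", "")),
          sep = "", file = con)
    }
  }
  cat("\n## run summary\n", file = con)
  s <- report@summary
  cat(sprintf("%s\t%d records\t%d bases\t%d amplicons\t%.3fs\n",
              s$file, s$records, s$bases, s$amplicons, s$seconds),
      sep = "", file = con)
  invisible(path)
}
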