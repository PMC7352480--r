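#' Read a MEME-format motif library
#'
#' Parses minimal MEME motif files (as distributed for RNAcompete RBP
#' motif collections): an optional `ALPHABET` line, then per motif a
#' `MOTIF <id> [<name>]` line followed by a `letter-probability matrix:`
#' header and one probability row per motif position. RNA alphabets (U)
#' are mapped to T. Rows whose probabilities are off unit sum by at most
#' 1e-3 are renormalized; larger deviations are an error.
#'
#' @param path path to a MEME-format motif file.
#' @return A named list of [PWMotif-class] objects.
#' @export
readMemeMotifs <- function(path) {
  if (!file.exists(path)) stop("motif file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  motifs <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[[i]])
    if (startsWith(line, "MOTIF")) {
      toks <- strsplit(line, "\\s+")[[1]]
      if (length(toks) < 2L)
        stop(sprintf("line %d: MOTIF line without an identifier", i))
      mid <- toks[2L]
      rbp <- if (length(toks) >= 3L) toks[3L] else mid
      # advance to the letter-probability header
      j <- i + 1L
      while (j <= n && !grepl("^letter-probability matrix", trimws(lines[[j]])))
        j <- j + 1L
      if (j > n)
        stop(sprintf("motif '%s' (line %d): no letter-probability matrix found",
                     mid, i))
      w <- NA_integer_
      wm <- regmatches(lines[[j]], regexpr("w=\\s*[0-9]+", lines[[j]]))
      if (length(wm)) w <- as.integer(sub("w=\\s*", "", wm))
      rows <- list()
      j <- j + 1L
      while (j <= n) {
        lr <- trimws(lines[[j]])
        if (lr == "" || startsWith(lr, "MOTIF") || grepl("^URL", lr)) break
        vals <- suppressWarnings(as.numeric(strsplit(lr, "\\s+")[[1]]))
        if (anyNA(vals)) break
        if (length(vals) != 4L)
          stop(sprintf("motif '%s', line %d: matrix row has %d columns (need 4)",
                       mid, j, length(vals)))
        rows[[length(rows) + 1L]] <- vals
        j <- j + 1L
      }
      if (!length(rows))
        stop(sprintf("motif '%s': empty probability matrix", mid))
      if (!is.na(w) && length(rows) != w)
        stop(sprintf("motif '%s': %d matrix rows but header declares w=%d",
                     mid, length(rows), w))
      m <- t(do.call(rbind, rows))  # 4 x k, rows in file alphabet order
      rownames(m) <- DNA_BASES     # A C G T; U column order == T
      cs <- colSums(m)
      if (any(abs(cs - 1) > 1e-3))
        stop(sprintf("motif '%s': position probabilities sum to %s (off by > 1e-3)",
                     mid, paste(signif(cs[abs(cs - 1) > 1e-3], 4), collapse = ", ")))
      motifs[[mid]] <- PWMotif(mid, m, rbp)
      i <- j
    } else {
      i <- i + 1L
    }
  }
  motifs
}

#' Write motifs in minimal MEME format
#'
#' @param motifs list of [PWMotif-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMemeMotifs <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s %s", motifId(m), rbpName(m)), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d",
                       motifLength(m)), con)
    apply(motifMatrix(m), 2, function(col)
      writeLines(paste(sprintf("%.6f", col), collapse = " "), con))
    writeLines("", con)
  }
  invisible(path)
}

#' Read a genome FASTA
#'
#' Wraps [Biostrings::readDNAStringSet()]: sequences are uppercased,
#' U is mapped to T, and IUPAC ambiguity codes other than N are
#' preserved as N. Duplicate headers and empty files are errors.
#'
#' @param path FASTA path.
#' @return A named [Biostrings::DNAStringSet].
#' @export
readGenomeFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (!length(raw)) stop("empty FASTA: ", path)
  nm <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(nm))
    stop("duplicate FASTA header(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  chr <- toupper(as.character(raw))
  chr <- chartr("U", "T", chr)
  chr <- gsub("[^ACGT]", "N", chr)
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- nm
  out
}

#' Write a DNAStringSet to FASTA
#'
#' @param seqs a [Biostrings::DNAStringSet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenomeFasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Read a splicing-event table
#'
#' The native dialect is a TSV with header columns `event_id`,
#' `gene_id`, `event_type`, `chrom`, `start`, `end` (0-based,
#' half-open), `strand`, `psi_control`, `psi_silenced`, `delta_psi`,
#' `posterior`, then one `reads_<condition>_<replicate>` column per
#' sample (`<condition>` in control/silenced). External tables can be
#' adapted via `col_map` (named character vector: native name ->
#' external name) and extra event-type labels via `type_alias`
#' (defaults map CE->ES, TE->APA, RI->IR, SES->ES, MES->MXE).
#'
#' The stored `delta_psi` is checked against `psi_silenced -
#' psi_control` to 1e-6 and recomputed exactly.
#'
#' @param path TSV path.
#' @param col_map optional named character vector remapping column names.
#' @param type_alias named character vector of extra event-type aliases.
#' @return A [SpliceEventSet-class].
#' @export
readEventTable <- function(path, col_map = NULL,
                           type_alias = EVENT_TYPE_ALIASES) {
  if (!file.exists(path)) stop("event table not found: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (native in names(col_map)) {
      ext <- col_map[[native]]
      if (!ext %in% colnames(df))
        stop("col_map column not in table: ", ext)
      colnames(df)[colnames(df) == ext] <- native
    }
  }
  fixed <- c("event_id", "gene_id", "event_type", "chrom", "start", "end",
             "strand", "psi_control", "psi_silenced", "delta_psi",
             "posterior")
  miss <- setdiff(fixed, colnames(df))
  if (length(miss))
    stop("event table missing column(s): ", paste(miss, collapse = ", "))
  readcols <- grep("^reads_", colnames(df), value = TRUE)
  if (!length(readcols)) stop("event table has no reads_<sample> columns")
  cond <- sub("^reads_([a-zA-Z]+)_.*$", "\\1", readcols)
  badc <- setdiff(unique(cond), c("control", "silenced"))
  if (length(badc))
    stop("reads_ columns with unknown condition label: ",
         paste(badc, collapse = ", "))

  et <- df$event_type
  aliased <- et %in% names(type_alias)
  et[aliased] <- unname(type_alias[et[aliased]])
  unknown <- !et %in% EVENT_TYPES
  if (any(unknown))
    stop(sprintf("row %d: unknown event_type '%s'; accepted: %s",
                 which(unknown)[1] + 1L, df$event_type[which(unknown)[1]],
                 paste(EVENT_TYPES, collapse = ", ")))
  df$event_type <- et
  for (col in c("psi_control", "psi_silenced", "posterior")) {
    bad <- df[[col]] < 0 | df[[col]] > 1
    if (any(bad))
      stop(sprintf("row %d: %s = %g outside [0,1]",
                   which(bad)[1] + 1L, col, df[[col]][which(bad)[1]]))
  }
  resid <- abs(df$delta_psi - (df$psi_silenced - df$psi_control))
  if (any(resid > 1e-6))
    stop(sprintf("row %d: delta_psi %g inconsistent with psi difference %g",
                 which(resid > 1e-6)[1] + 1L,
                 df$delta_psi[which(resid > 1e-6)[1]],
                 (df$psi_silenced - df$psi_control)[which(resid > 1e-6)[1]]))
  df$delta_psi <- df$psi_silenced - df$psi_control
  reads <- as.matrix(df[, readcols, drop = FALSE])
  colnames(reads) <- sub("^reads_", "", readcols)
  SpliceEventSet(df[, fixed], reads, cond)
}

#' Write a splicing-event table (native TSV dialect)
#'
#' Field-for-field inverse of [readEventTable()].
#'
#' @param x a [SpliceEventSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEventTable <- function(x, path) {
  gr <- SummarizedExperiment::rowRanges(x)
  rd <- SummarizedExperiment::rowData(x)
  reads <- readSupport(x)
  df <- data.frame(
    event_id = rd$event_id, gene_id = rd$gene_id,
    event_type = rd$event_type,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L, end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    psi_control = rd$psi_control, psi_silenced = rd$psi_silenced,
    delta_psi = rd$delta_psi, posterior = rd$posterior,
    check.names = FALSE
  )
  rdf <- as.data.frame(reads)
  colnames(rdf) <- paste0("reads_", colnames(reads))
  write.table(cbind(df, rdf), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a BED peak file into a GRanges peak set
#'
#' Accepts BED3+ (0-based half-open). The strand column (6th) is
#' honored when present, otherwise strand is set to `+`. Lines whose
#' start is not strictly below their end are rejected with the line
#' number. An empty file yields an empty peak set.
#'
#' @param path BED path.
#' @param study_id identifier stored in `metadata(x)$study_id`.
#' @return A [GenomicRanges::GRanges] with `study_id` metadata.
#' @export
readBedPeaks <- function(path, study_id = basename(path)) {
  if (!file.exists(path)) stop("BED not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (!length(lines)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::metadata(gr)$study_id <- study_id
    return(gr)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("line %d: BED requires >= 3 columns", which(nf < 3L)[1]))
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- as.numeric(vapply(fields, `[[`, "", 2L))
  end <- as.numeric(vapply(fields, `[[`, "", 3L))
  if (anyNA(start) || anyNA(end))
    stop(sprintf("line %d: non-numeric BED coordinates",
                 which(is.na(start) | is.na(end))[1]))
  bad <- start >= end
  if (any(bad))
    stop(sprintf("line %d: start %d >= end %d", which(bad)[1],
                 start[which(bad)[1]], end[which(bad)[1]]))
  strand <- rep("+", length(lines))
  has6 <- nf >= 6L
  strand[has6] <- vapply(fields[has6], `[[`, "", 6L)
  strand[!strand %in% c("+", "-")] <- "+"
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start + 1L, end),
                               strand = strand)
  S4Vectors::metadata(gr)$study_id <- study_id
  gr
}

#' Write scan regions as BED6 plus a FASTA of window sequences
#'
#' @param x a [ScanRegionSet-class].
#' @param bed_path,fasta_path output paths.
#' @return invisible NULL.
#' @export
writeScanRegions <- function(x, bed_path, fasta_path) {
  gr <- regionRanges(x)
  mc <- S4Vectors::mcols(gr)
  bed <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    name = mc$region_id,
    score = 0L,
    strand = as.character(BiocGenerics::strand(gr))
  )
  write.table(bed, bed_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  Biostrings::writeXStringSet(regionSequences(x), fasta_path, width = 70L)
  invisible(NULL)
}

#' Read an expression matrix with a condition-tagged header
#'
#' The dialect is a TSV whose first header row names the samples and
#' whose second row tags each sample with its condition (`control` /
#' `silenced` for two-group designs; arbitrary labels are preserved).
#' The first column holds row identifiers (isoforms, genes or 3'UTR
#' sites). `units = "PDUI"` additionally enforces values in [0, 1]
#' (missing allowed).
#'
#' @param path TSV path.
#' @param units declared value type: `"TPM"`, `"FPKM"` or `"PDUI"`.
#' @return list with `matrix` (numeric, rows x samples), `condition`
#'   (character per column) and `units`.
#' @export
readExpressionMatrix <- function(path, units = c("TPM", "FPKM", "PDUI")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("expression matrix not found: ", path)
  head2 <- readLines(path, n = 2L)
  if (length(head2) < 2L) stop("expression matrix needs a 2-row header")
  samples <- strsplit(head2[1], "\t", fixed = TRUE)[[1]][-1]
  condition <- strsplit(head2[2], "\t", fixed = TRUE)[[1]][-1]
  if (length(samples) != length(condition))
    stop("header rows disagree: ", length(samples), " samples vs ",
         length(condition), " condition labels")
  df <- read.delim(path, skip = 2L, header = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) != length(samples) + 1L)
    stop("data rows have ", ncol(df) - 1L, " value columns; header names ",
         length(samples), " samples")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  dimnames(m) <- list(df[[1]], samples)
  if (any(m < 0, na.rm = TRUE))
    stop("negative expression values are not allowed")
  if (units == "PDUI") checkProb(m[!is.na(m)], "PDUI")
  list(matrix = m, condition = condition, units = units)
}

#' Write an expression matrix with a condition-tagged header
#'
#' Inverse of [readExpressionMatrix()].
#'
#' @param m numeric matrix with row and column names.
#' @param condition per-column condition labels.
#' @param path output path.
#' @param id_label name for the identifier column.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(m, condition, path, id_label = "id") {
  stopifnot(ncol(m) == length(condition))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(id_label, colnames(m)), collapse = "\t"), con)
  writeLines(paste(c("condition", as.character(condition)),
                   collapse = "\t"), con)
  utils::write.table(m, con, sep = "\t", quote = FALSE,
                     col.names = FALSE, row.names = TRUE)
  invisible(path)
}

#' Read transcript models from a GTF-like TSV
#'
#' Columns: `transcript_id`, `gene_id`, `chrom`, `strand`,
#' `exon_starts`, `exon_ends` (comma-separated, 0-based half-open,
#' genomically sorted), `cds_start`, `cds_end` (0-based half-open;
#' empty/NA for non-coding). Exon consistency is validated and UTR
#' lengths are computed (see [utrLengths()]).
#'
#' @param path TSV path.
#' @return data.frame of models with `utr5_len` / `utr3_len` columns.
#' @export
readTranscriptModels <- function(path) {
  if (!file.exists(path)) stop("transcript model table not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "gene_id", "chrom", "strand",
            "exon_starts", "exon_ends", "cds_start", "cds_end")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("transcript model table missing column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(df$transcript_id))
    stop("duplicate transcript_id: ",
         df$transcript_id[duplicated(df$transcript_id)][1])
  utrLengths(df)
}
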