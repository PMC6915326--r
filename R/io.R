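# Readers and writers for the pipeline's plain-text interchange formats:
# FASTA 5' UTRs, annotation and 5'-end TSVs, Vienna-style structure files,
# and CLIP clusters as transcript-space BED6.

#' Read 5' UTR sequences with annotation
#'
#' Loads UTR sequences from FASTA (record id = transcript_id, via
#' \pkg{Biostrings}) and joins the annotation table into a list of
#' [transcript_record()]s.
#'
#' @param fasta_path FASTA file of 5' UTR sequences.
#' @param annot Optional annotation data.frame (columns `transcript_id`,
#'   `gene_symbol`, `is_rp` as 0/1 or logical) or path to such a TSV.
#' @return List of `transcript_record`s.
#' @export
read_utr_fasta <- function(fasta_path, annot = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (is.character(annot)) {
    annot <- utils::read.delim(annot, stringsAsFactors = FALSE)
  }
  lapply(seq_along(seqs), function(i) {
    gene <- NA_character_; rp <- FALSE
    if (!is.null(annot)) {
      j <- match(ids[i], annot$transcript_id)
      if (!is.na(j)) {
        gene <- annot$gene_symbol[j]
        rp <- as.logical(annot$is_rp[j])
      }
    }
    transcript_record(ids[i], as.character(seqs[[i]]), gene_symbol = gene,
                      is_rp = isTRUE(rp))
  })
}

#' Write transcripts to FASTA
#'
#' @param transcripts List of `transcript_record`s.
#' @param path Output FASTA path.
#' @export
write_utr_fasta <- function(transcripts, path) {
  seqs <- Biostrings::DNAStringSet(
    vapply(transcripts, function(t) t$utr5_seq, character(1)))
  names(seqs) <- vapply(transcripts, function(t) t$transcript_id, character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a Vienna-style multi-record structure file
#'
#' Each record is three lines: `>id`, sequence, dot-bracket. Structures are
#' validated with [parse_dotbracket()].
#'
#' @param path File path.
#' @return Named list of `secondary_structure` objects; sequences are attached
#'   as attribute `seq` on each element.
#' @export
read_vienna <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0L || any(diff(heads) != 3L) ||
      utils::tail(heads, 1) + 2L > length(lines)) {
    stop("malformed Vienna file: expected repeated (header, sequence, structure) triples",
         call. = FALSE)
  }
  out <- lapply(heads, function(h) {
    id <- sub("^>\\s*", "", lines[h])
    id <- sub("\\s.*$", "", id)
    st <- parse_dotbracket(trimws(lines[h + 2L]), seq = trimws(lines[h + 1L]),
                           transcript_id = id)
    attr(st, "seq") <- trimws(lines[h + 1L])
    st
  })
  names(out) <- vapply(out, function(s) s$transcript_id, character(1))
  out
}

#' Write structures as a Vienna-style file
#'
#' @param structures List of `secondary_structure`s.
#' @param seqs Named character vector of sequences (transcript_id to
#'   sequence); taken from the `seq` attribute when missing.
#' @param path Output path.
#' @export
write_vienna <- function(structures, path, seqs = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (st in structures) {
    s <- if (!is.null(seqs)) seqs[[st$transcript_id]] else attr(st, "seq")
    if (is.null(s)) {
      stop(sprintf("no sequence available for '%s'", st$transcript_id),
           call. = FALSE)
    }
    writeLines(c(paste0(">", st$transcript_id), s, st$dotbracket), con)
  }
  invisible(path)
}

#' Read CLIP clusters from transcript-space BED6
#'
#' BED columns: chrom = transcript_id, start, end (0-based half-open),
#' name = RBP, score (ignored), strand. An optional seventh column is read as
#' `dataset_id`.
#'
#' @param path BED file path.
#' @return data.frame with `rbp`, `transcript_id`, `start`, `end`,
#'   `dataset_id`.
#' @export
read_clip_bed <- function(path) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 4L) {
    stop("BED file needs at least 4 columns (transcript, start, end, rbp)",
         call. = FALSE)
  }
  data.frame(rbp = bed[[4]], transcript_id = bed[[1]],
             start = as.integer(bed[[2]]), end = as.integer(bed[[3]]),
             dataset_id = if (ncol(bed) >= 7L) bed[[7]] else "",
             stringsAsFactors = FALSE)
}

#' Write CLIP clusters as transcript-space BED6
#'
#' @param clusters data.frame as from [read_clip_bed()] or [gen_clip()].
#' @param path Output path.
#' @export
write_clip_bed <- function(clusters, path) {
  bed <- data.frame(clusters$transcript_id, clusters$start, clusters$end,
                    clusters$rbp, 0L, "+",
                    clusters$dataset_id %||% "")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read 5'-end observations
#'
#' TSV with columns `transcript_id`, `sample_label`, `end_pos` (0-based
#' coordinate of the observed 5' terminal on the reference UTR).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_five_prime_ends <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "sample_label", "end_pos")
  if (!all(need %in% names(df))) {
    stop(sprintf("5'-end table needs columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  df$end_pos <- as.integer(df$end_pos)
  df
}
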