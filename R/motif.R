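# CUIC motif scanning and positional classification on 5' UTR sequences.
#
# Coordinates are 0-based, half-open on the UTR, matching BED conventions:
# position L (the UTR length) is the first nucleotide of the initiation codon,
# so a hit ending at L has dist_to_start_codon == 0.

.IUPAC <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

# Uppercase, U -> T; error names the first offending position (1-based in the
# input string, as a reader would count).
.normalize_nt <- function(seq, what = "sequence") {
  seq <- gsub("[[:space:]]", "", seq)
  s <- chartr("u", "t", seq)
  s <- toupper(chartr("U", "T", s))
  bad <- regexpr("[^ACGT]", s)
  if (bad > 0L) {
    stop(sprintf("invalid nucleotide character '%s' at position %d of %s",
                 substr(seq, bad, bad), bad, what), call. = FALSE)
  }
  s
}

.normalize_consensus <- function(consensus) {
  if (length(consensus) != 1L || is.na(consensus) || !nzchar(consensus)) {
    stop("consensus must be a non-empty IUPAC string", call. = FALSE)
  }
  s <- toupper(chartr("uU", "tT", consensus))
  bad <- regexpr(paste0("[^", paste(names(.IUPAC), collapse = ""), "]"), s)
  if (bad > 0L) {
    stop(sprintf("invalid IUPAC code '%s' at position %d of consensus",
                 substr(consensus, bad, bad), bad), call. = FALSE)
  }
  s
}

#' Scan a 5' UTR for CUIC consensus matches
#'
#' Finds every (possibly overlapping) match of an IUPAC-degenerate consensus in
#' a 5' UTR sequence, reporting transcript coordinates and the distance of each
#' match to the initiation codon. The default consensus `YYYYTTYC` is the
#' pyrimidine-rich 8-mer characteristic of ribosomal-protein mRNA 5' UTRs
#' (CUIC: cis-element upstream of the initiation codon).
#'
#' Matching is case-insensitive and treats U and T identically. Coordinates are
#' 0-based half-open; the position equal to the UTR length is the A of the AUG,
#' so `dist_to_start_codon = nchar(utr5_seq) - end` and a motif abutting the
#' start codon has distance 0.
#'
#' @param utr5_seq Character scalar, the 5' UTR sequence (A/C/G/T/U, any case).
#' @param consensus IUPAC consensus string, default `"YYYYTTYC"`.
#' @return A data.frame with one row per hit, in 5' to 3' order: `start`,
#'   `end` (0-based half-open), `matched_seq`, and `dist_to_start_codon`.
#' @examples
#' utr <- paste0("cgcgctctcttcctgccagagttcagcgcgcactctttat",
#'               "cccggcgggaccggaaggaggaggtcttttcc")
#' scan_cuic(utr)
#' @export
scan_cuic <- function(utr5_seq, consensus = "YYYYTTYC") {
  cons <- .normalize_consensus(consensus)
  seq <- .normalize_nt(utr5_seq, "utr5_seq")
  L <- nchar(seq)
  k <- nchar(cons)
  empty <- data.frame(start = integer(0), end = integer(0),
                      matched_seq = character(0),
                      dist_to_start_codon = integer(0),
                      stringsAsFactors = FALSE)
  if (L < k) return(empty)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  cchars <- strsplit(cons, "", fixed = TRUE)[[1]]
  n_win <- L - k + 1L
  ok <- rep(TRUE, n_win)
  for (j in seq_len(k)) {
    allowed <- strsplit(.IUPAC[[cchars[j]]], "", fixed = TRUE)[[1]]
    ok <- ok & chars[seq_len(n_win) + j - 1L] %in% allowed
  }
  starts <- which(ok) - 1L
  if (length(starts) == 0L) return(empty)
  data.frame(
    start = starts,
    end = starts + k,
    matched_seq = substring(seq, starts + 1L, starts + k),
    dist_to_start_codon = L - (starts + k),
    stringsAsFactors = FALSE
  )
}

#' Count distinct words matching an IUPAC consensus
#'
#' Number of distinct DNA k-mers compatible with a degenerate consensus,
#' computed as the product of per-position degeneracies. `"YYYYTTYC"` admits
#' 32 of the 65,536 possible 8-mers.
#'
#' @param consensus IUPAC consensus string.
#' @return Integer count of matching words.
#' @export
count_consensus_words <- function(consensus) {
  cons <- .normalize_consensus(consensus)
  cchars <- strsplit(cons, "", fixed = TRUE)[[1]]
  prod(vapply(cchars, function(ch) nchar(.IUPAC[[ch]]), numeric(1)))
}

#' Classify a transcript as CUIC-containing
#'
#' A transcript is CUIC-positive when at least one consensus match lies
#' strictly less than `max_dist` nucleotides upstream of the initiation codon.
#' The best hit is the one closest to the start codon (smallest
#' `dist_to_start_codon`), ties broken in favour of the 3'-most start.
#'
#' @param utr5_seq 5' UTR sequence (or a `transcript_record`; its `utr5_seq`
#'   field is used).
#' @param max_dist Strict upper bound on distance to the start codon
#'   (default 100 nt).
#' @param consensus IUPAC consensus, default `"YYYYTTYC"`.
#' @return A list with `is_cuic` (logical) and `best_hit` (one-row data.frame
#'   as from [scan_cuic()], or `NULL` when no qualifying hit exists).
#' @export
classify_cuic_gene <- function(utr5_seq, max_dist = 100, consensus = "YYYYTTYC") {
  if (is.list(utr5_seq) && !is.null(utr5_seq$utr5_seq)) {
    utr5_seq <- utr5_seq$utr5_seq
  }
  hits <- scan_cuic(utr5_seq, consensus)
  hits <- hits[hits$dist_to_start_codon < max_dist, , drop = FALSE]
  if (nrow(hits) == 0L) {
    return(list(is_cuic = FALSE, best_hit = NULL))
  }
  ord <- order(hits$dist_to_start_codon, -hits$start)
  list(is_cuic = TRUE, best_hit = hits[ord[1L], , drop = FALSE])
}

#' Fraction of best hits within a distance band
#'
#' Fraction of transcripts whose best CUIC hit lies between `lo` and `hi`
#' nucleotides (inclusive) upstream of the initiation codon. In
#' ribosomal-protein mRNAs the motif sits immediately (20-80 nt) upstream of
#' the start codon in the large majority of transcripts.
#'
#' @param dists Numeric vector of best-hit distances (one per transcript), or a
#'   data.frame with a `dist_to_start_codon` column.
#' @param lo,hi Inclusive band limits, defaults 20 and 80.
#' @return Fraction in \[0, 1\].
#' @export
distance_band_fraction <- function(dists, lo = 20, hi = 80) {
  if (is.data.frame(dists)) dists <- dists$dist_to_start_codon
  if (length(dists) == 0L) {
    stop("distance_band_fraction is undefined for an empty hit set", call. = FALSE)
  }
  mean(dists >= lo & dists <= hi)
}

#' 5'-end positions relative to the CUIC motif
#'
#' For each observed transcript 5' terminal, the signed offset to the motif
#' start of that transcript's best CUIC hit: negative offsets place the 5' end
#' upstream of the motif, 0 at the motif start. Observations on transcripts
#' without a best hit are skipped with a warning reporting the count.
#'
#' @param obs data.frame of 5'-end observations with columns `transcript_id`,
#'   `sample_label`, `end_pos` (0-based position on the reference UTR).
#' @param hits data.frame mapping transcripts to best hits: columns
#'   `transcript_id` and `start`.
#' @return `obs` restricted to usable rows, with an added `offset` column; the
#'   number of skipped observations is attached as attribute `n_skipped`.
#' @export
relative_end_offsets <- function(obs, hits) {
  stopifnot(is.data.frame(obs), is.data.frame(hits))
  idx <- match(obs$transcript_id, hits$transcript_id)
  miss <- is.na(idx)
  if (any(miss)) {
    warning(sprintf("skipped %d observation(s) on transcripts without a CUIC hit",
                    sum(miss)), call. = FALSE)
  }
  out <- obs[!miss, , drop = FALSE]
  out$offset <- out$end_pos - hits$start[idx[!miss]]
  attr(out, "n_skipped") <- sum(miss)
  out
}

#' Call a 5' end truncated at the CUIC region
#'
#' A transcript isoform is called truncated at the CUIC region when its
#' observed 5' terminal falls within `tol` nucleotides of the motif start.
#'
#' @param offset Signed offset(s) from [relative_end_offsets()].
#' @param tol Inclusive tolerance in nucleotides (default 10).
#' @return Logical vector.
#' @export
classify_truncated_isoform <- function(offset, tol = 10) {
  abs(offset) <= tol
}

#' TOP-like 5' end classification
#'
#' A 5' terminal oligopyrimidine (TOP) mRNA starts with a cap-adjacent C
#' followed by an uninterrupted pyrimidine run. A sequence read from its 5'
#' end is TOP-like when its first nucleotide is C and its first `min_py_run`
#' nucleotides are all pyrimidines (C/T/U).
#'
#' @param seq_from_5prime Nucleotide sequence starting at the observed 5' end.
#' @param min_py_run Minimum pyrimidine run length (default 5).
#' @return Logical scalar.
#' @export
is_top_like <- function(seq_from_5prime, min_py_run = 5) {
  s <- .normalize_nt(seq_from_5prime, "seq_from_5prime")
  if (nchar(s) < min_py_run) {
    stop(sprintf("sequence length %d is shorter than min_py_run = %d",
                 nchar(s), min_py_run), call. = FALSE)
  }
  head_chars <- strsplit(substr(s, 1L, min_py_run), "", fixed = TRUE)[[1]]
  head_chars[1L] == "C" && all(head_chars %in% c("C", "T"))
}

#' Build a transcript record
#'
#' Plain container for a transcript's 5' UTR and annotation: the sequence,
#' whether the gene encodes a ribosomal protein, and per-sample abundance
#' (FPKM). Position `nchar(utr5_seq)` is the first nucleotide of the
#' initiation codon.
#'
#' @param transcript_id,gene_symbol Identifiers.
#' @param utr5_seq 5' UTR sequence (validated; U/T and case preserved as given).
#' @param is_rp Logical, ribosomal-protein gene flag.
#' @param species Species label.
#' @param abundance Named numeric vector, sample label to FPKM (non-negative).
#' @return A list of class `transcript_record`.
#' @export
transcript_record <- function(transcript_id, utr5_seq, gene_symbol = NA_character_,
                              is_rp = FALSE, species = NA_character_,
                              abundance = numeric(0)) {
  .normalize_nt(utr5_seq, sprintf("utr5_seq of %s", transcript_id))
  if (length(abundance) && any(abundance < 0)) {
    stop("abundance values must be non-negative", call. = FALSE)
  }
  structure(
    list(transcript_id = transcript_id, gene_symbol = gene_symbol,
         is_rp = isTRUE(is_rp), utr5_seq = gsub("[[:space:]]", "", utr5_seq),
         species = species, abundance = abundance),
    class = "transcript_record"
  )
}

#' @export
print.transcript_record <- function(x, ...) {
  cat(sprintf("<transcript_record> %s (%s)%s, 5' UTR %d nt\n",
              x$transcript_id,
              ifelse(is.na(x$gene_symbol), "?", x$gene_symbol),
              if (x$is_rp) " [RP]" else "",
              nchar(x$utr5_seq)))
  invisible(x)
}

#' Best CUIC hits for a set of transcripts
#'
#' Applies [classify_cuic_gene()] across transcripts and assembles the
#' per-transcript best-hit table used by downstream profile and CLIP scoring.
#'
#' @param transcripts List of `transcript_record`s (or named character vector
#'   of UTR sequences).
#' @inheritParams classify_cuic_gene
#' @return data.frame with columns `transcript_id`, `is_cuic`, `start`, `end`,
#'   `matched_seq`, `dist_to_start_codon`, `utr_length` (NA where no hit).
#' @export
best_cuic_hits <- function(transcripts, max_dist = 100, consensus = "YYYYTTYC") {
  if (is.character(transcripts)) {
    ids <- names(transcripts)
    seqs <- unname(transcripts)
  } else {
    ids <- vapply(transcripts, function(t) t$transcript_id, character(1))
    seqs <- vapply(transcripts, function(t) t$utr5_seq, character(1))
  }
  rows <- lapply(seq_along(seqs), function(i) {
    cls <- classify_cuic_gene(seqs[i], max_dist = max_dist, consensus = consensus)
    if (cls$is_cuic) {
      cbind(data.frame(transcript_id = ids[i], is_cuic = TRUE,
                       stringsAsFactors = FALSE),
            cls$best_hit,
            data.frame(utr_length = nchar(gsub("[[:space:]]", "", seqs[i]))))
    } else {
      data.frame(transcript_id = ids[i], is_cuic = FALSE, start = NA_integer_,
                 end = NA_integer_, matched_seq = NA_character_,
                 dist_to_start_codon = NA_integer_,
                 utr_length = nchar(gsub("[[:space:]]", "", seqs[i])),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
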