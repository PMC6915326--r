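# CLIP-cluster specificity scoring: for each RNA-binding protein, the fraction
# of its clusters on RP transcripts that overlap the CUIC region.

#' Half-open interval overlap
#'
#' Overlap test for 0-based half-open intervals on the same transcript:
#' `[start, end)` overlaps `[a, b)` iff `start < b` and `a < end`. Abutting
#' intervals do not overlap. Vectorized over the first interval.
#'
#' @param start,end Cluster interval (0-based half-open).
#' @param a,b Region interval (0-based half-open).
#' @return Logical vector.
#' @export
interval_overlaps <- function(start, end, a, b) {
  start < b & a < end
}

#' CUIC region of a motif hit
#'
#' The motif footprint extended by a symmetric flank and clipped to the UTR:
#' `[max(0, start - flank), min(L, end + flank))`. The flank width is a free
#' parameter of the analysis (default 10 nt) and should be reported with any
#' score computed from it.
#'
#' @param start,end Motif hit coordinates (0-based half-open).
#' @param utr_length UTR length L for clipping.
#' @param flank Flank width in nucleotides (default 10).
#' @return data.frame with columns `region_start`, `region_end`.
#' @export
cuic_region <- function(start, end, utr_length, flank = 10) {
  data.frame(region_start = pmax(0L, as.integer(start - flank)),
             region_end = pmin(as.integer(utr_length), as.integer(end + flank)))
}

#' Per-RBP CUIC binding-specificity scores
#'
#' For each RNA-binding protein, counts its CLIP clusters on
#' ribosomal-protein transcripts that overlap the transcript's CUIC region and
#' normalizes by the total number of that RBP's clusters on any region of
#' those transcripts:
#' `score = n_overlap_cuic / n_total`, a binding specificity in \[0, 1\].
#'
#' Clusters are de-duplicated on (rbp, transcript_id, start, end, dataset_id)
#' before counting. RBPs with fewer than `min_total` clusters on RP
#' transcripts are excluded with a warning (stability guard). Clusters on
#' transcripts outside `rp_transcripts` enter neither count; clusters on RP
#' transcripts lacking a CUIC region count toward `n_total` only (they lie on
#' the mRNA but cannot overlap a region).
#'
#' @param clusters data.frame of CLIP clusters: columns `rbp`,
#'   `transcript_id`, `start`, `end` (0-based half-open), optional
#'   `dataset_id`.
#' @param regions data.frame mapping transcripts to CUIC regions: columns
#'   `transcript_id`, `region_start`, `region_end` (e.g. built with
#'   [cuic_region()] from [best_cuic_hits()]).
#' @param rp_transcripts Character vector of RP transcript ids.
#' @param min_total Minimum `n_total` required to report a score (default 5).
#' @return data.frame with one row per retained RBP: `rbp`, `n_overlap_cuic`,
#'   `n_total`, `score`.
#' @export
specificity_scores <- function(clusters, regions, rp_transcripts, min_total = 5) {
  stopifnot(is.data.frame(clusters), is.data.frame(regions))
  if (!all(clusters$start < clusters$end)) {
    stop("all clusters must satisfy start < end", call. = FALSE)
  }
  if (is.null(clusters$dataset_id)) clusters$dataset_id <- ""
  key <- paste(clusters$rbp, clusters$transcript_id, clusters$start,
               clusters$end, clusters$dataset_id, sep = "\r")
  clusters <- clusters[!duplicated(key), , drop = FALSE]
  on_rp <- clusters[clusters$transcript_id %in% rp_transcripts, , drop = FALSE]
  ridx <- match(on_rp$transcript_id, regions$transcript_id)
  has_region <- !is.na(ridx)
  ov <- rep(FALSE, nrow(on_rp))
  ov[has_region] <- interval_overlaps(
    on_rp$start[has_region], on_rp$end[has_region],
    regions$region_start[ridx[has_region]], regions$region_end[ridx[has_region]]
  )
  n_total <- tapply(rep(1L, nrow(on_rp)), on_rp$rbp, sum)
  n_overlap <- tapply(as.integer(ov), on_rp$rbp, sum)
  out <- data.frame(rbp = names(n_total),
                    n_overlap_cuic = as.integer(n_overlap[names(n_total)]),
                    n_total = as.integer(n_total),
                    stringsAsFactors = FALSE)
  drop <- out$n_total < min_total
  if (any(drop)) {
    warning(sprintf("excluded %d RBP(s) with fewer than %d clusters on RP transcripts: %s",
                    sum(drop), min_total,
                    paste(out$rbp[drop], collapse = ", ")), call. = FALSE)
    out <- out[!drop, , drop = FALSE]
  }
  if (nrow(out) == 0L) {
    stop("no RBP has enough clusters on RP transcripts to score", call. = FALSE)
  }
  out$score <- out$n_overlap_cuic / out$n_total
  rownames(out) <- NULL
  out
}

#' Rank RBPs by CUIC specificity
#'
#' Orders a specificity-score table by descending score; ties are broken by
#' descending `n_total`, then by RBP name. Ranks are 1-based.
#'
#' @param scores data.frame from [specificity_scores()].
#' @return The table sorted, with a `rank` column added.
#' @export
rank_rbps <- function(scores) {
  if (!is.data.frame(scores) || nrow(scores) == 0L) {
    stop("rank_rbps requires at least one score", call. = FALSE)
  }
  ord <- order(-scores$score, -scores$n_total, scores$rbp)
  out <- scores[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
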