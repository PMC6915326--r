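# Secondary-structure handling: dot-bracket parsing, a maximum-base-pairing
# stand-in folder, and the motif-anchored double-stranded-fraction profile.

#' Parse a dot-bracket secondary structure
#'
#' Validates a Vienna-style dot-bracket string (plain `(`, `)`, `.` alphabet;
#' pseudoknot alphabets are rejected) against its sequence and derives the
#' per-nucleotide paired indicator.
#'
#' @param db Dot-bracket string.
#' @param seq Optional nucleotide sequence of the same length (checked when
#'   given).
#' @param transcript_id Optional identifier carried through.
#' @return A list of class `secondary_structure` with `transcript_id`,
#'   `dotbracket`, `paired` (0/1 integer vector) and `pairs` (two-column matrix
#'   of 1-based paired positions).
#' @export
parse_dotbracket <- function(db, seq = NULL, transcript_id = NA_character_) {
  if (!is.null(seq)) {
    seq2 <- gsub("[[:space:]]", "", seq)
    if (nchar(db) != nchar(seq2)) {
      stop(sprintf("structure length %d does not match sequence length %d",
                   nchar(db), nchar(seq2)), call. = FALSE)
    }
  }
  chars <- strsplit(db, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("(", ")", "."))
  if (length(bad)) {
    stop(sprintf("invalid structure character '%s' at position %d (only '(', ')', '.' allowed)",
                 chars[bad[1]], bad[1]), call. = FALSE)
  }
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0L) {
        stop(sprintf("unbalanced ')' at position %d", i), call. = FALSE)
      }
      pairs <- rbind(pairs, c(stack[length(stack)], i))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) {
    stop(sprintf("unbalanced '(' at position %d", stack[length(stack)]),
         call. = FALSE)
  }
  structure(
    list(transcript_id = transcript_id, dotbracket = db,
         paired = as.integer(chars != "."), pairs = pairs),
    class = "secondary_structure"
  )
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("<secondary_structure> %s: %d nt, %d base pairs\n",
              x$transcript_id, length(x$paired), nrow(x$pairs)))
  invisible(x)
}

.CAN_PAIR <- list(A = "T", T = c("A", "G"), G = c("C", "T"), C = "G")

#' Maximum-base-pairing folder (test stand-in)
#'
#' A deterministic Nussinov-style folder that maximizes the number of nested
#' Watson-Crick / wobble pairs (AU, GC, GU) subject to a minimum hairpin loop
#' size. It is a combinatorial stand-in for thermodynamic folding: the
#' pipeline's primary path consumes externally predicted dot-bracket
#' structures, and this folder exists so that structures can be produced
#' in self-contained analyses and tests.
#'
#' Traceback is deterministic: at each position the 5'-most base is paired
#' with the largest admissible partner whenever pairing attains the optimum.
#'
#' @param seq Nucleotide sequence (A/C/G/T/U, any case).
#' @param min_loop Minimum number of unpaired nucleotides enclosed by a pair
#'   (default 3), i.e. positions i and j may pair only when j - i > min_loop.
#' @return Dot-bracket string of the same length.
#' @export
fold_maxpair <- function(seq, min_loop = 3) {
  s <- .normalize_nt(seq, "seq")
  n <- nchar(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  if (n == 0L) stop("empty sequence", call. = FALSE)
  can <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    partners <- which(chars %in% .CAN_PAIR[[chars[i]]])
    can[i, partners] <- TRUE
  }
  M <- matrix(0L, n, n)
  if (n > min_loop + 1L) {
    for (span in (min_loop + 1L):(n - 1L)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        best <- M[i + 1L, j]
        ks <- seq.int(i + min_loop + 1L, j)
        ks <- ks[can[i, ks]]
        if (length(ks)) {
          inner <- ifelse(ks - 1L >= i + 1L, M[cbind(i + 1L, ks - 1L)], 0L)
          outer <- ifelse(ks + 1L <= j, M[cbind(pmin(ks + 1L, j), j)], 0L)
          outer[ks == j] <- 0L
          best <- max(best, 1L + inner + outer)
        }
        M[i, j] <- best
      }
    }
  }
  db <- rep(".", n)
  trace <- function(i, j) {
    while (i < j) {
      if (j - i <= min_loop || M[i, j] == 0L) return(invisible(NULL))
      paired_here <- FALSE
      for (k in rev(seq.int(i + min_loop + 1L, j))) {
        if (!can[i, k]) next
        inner <- if (k - 1L >= i + 1L) M[i + 1L, k - 1L] else 0L
        outer <- if (k + 1L <= j) M[k + 1L, j] else 0L
        if (M[i, j] == 1L + inner + outer) {
          db[i] <<- "("
          db[k] <<- ")"
          trace(i + 1L, k - 1L)
          i <- k + 1L
          paired_here <- TRUE
          break
        }
      }
      if (!paired_here) i <- i + 1L
    }
    invisible(NULL)
  }
  trace(1L, n)
  paste(db, collapse = "")
}

#' Motif-anchored double-stranded fraction profile
#'
#' For a set of secondary structures with a motif anchor on each transcript,
#' computes, at every offset in `-half_width .. +half_width` relative to the
#' anchor (anchor = motif start by default), the mean paired indicator across
#' the transcripts whose UTR covers that offset, followed by a centered moving
#' average across offsets. Around the CUIC motif of ribosomal-protein mRNAs
#' this profile shows a single-stranded dip: the motif tends to sit in a loop.
#'
#' The per-offset denominator counts only transcripts covering that offset;
#' counts are reported alongside the means. At profile edges the moving
#' average uses the available neighbours only.
#'
#' @param structures List of `secondary_structure` objects (see
#'   [parse_dotbracket()]).
#' @param anchors Named integer vector: transcript_id to 0-based anchor
#'   position (typically the motif start from [best_cuic_hits()]).
#' @param half_width Half-width H of the profile (default 50 nt).
#' @param window Odd moving-average window in offsets (default 7; 1 disables
#'   smoothing).
#' @return A list of class `paired_fraction_profile` with `offsets`,
#'   `mean_paired` (smoothed), `raw_mean`, `n_per_offset`, `window`.
#' @export
paired_fraction_profile <- function(structures, anchors, half_width = 50,
                                    window = 7) {
  if (length(structures) == 0L) {
    stop("paired_fraction_profile is undefined for an empty structure set",
         call. = FALSE)
  }
  if (window %% 2 != 1 || window < 1) {
    stop("window must be a positive odd integer", call. = FALSE)
  }
  offsets <- seq.int(-half_width, half_width)
  acc <- numeric(length(offsets))
  n <- integer(length(offsets))
  for (st in structures) {
    a <- anchors[[st$transcript_id]]
    if (is.null(a) || is.na(a)) {
      stop(sprintf("no anchor for transcript '%s'", st$transcript_id),
           call. = FALSE)
    }
    pos <- a + offsets + 1L  # 1-based index into paired vector
    inside <- pos >= 1L & pos <= length(st$paired)
    acc[inside] <- acc[inside] + st$paired[pos[inside]]
    n[inside] <- n[inside] + 1L
  }
  raw <- ifelse(n > 0L, acc / pmax(n, 1L), NA_real_)
  half_w <- (window - 1L) %/% 2L
  smooth <- vapply(seq_along(offsets), function(i) {
    lo <- max(1L, i - half_w)
    hi <- min(length(offsets), i + half_w)
    vals <- raw[lo:hi]
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  }, numeric(1))
  structure(
    list(offsets = offsets, mean_paired = smooth, raw_mean = raw,
         n_per_offset = n, window = as.integer(window)),
    class = "paired_fraction_profile"
  )
}

#' @export
print.paired_fraction_profile <- function(x, ...) {
  cat(sprintf("<paired_fraction_profile> offsets %d..%d, window %d, %s transcripts at offset 0\n",
              min(x$offsets), max(x$offsets), x$window,
              x$n_per_offset[x$offsets == 0]))
  invisible(x)
}

#' @method as.data.frame paired_fraction_profile
#' @export
as.data.frame.paired_fraction_profile <- function(x, ...) {
  data.frame(offset = x$offsets, mean_paired = x$mean_paired,
             raw_mean = x$raw_mean, n = x$n_per_offset)
}
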