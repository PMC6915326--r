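# Seeded synthetic-data generators with known ground truth for every pipeline
# stage: planted-motif transcripts, loop-over-motif structures, CLIP clusters
# with controlled region enrichment, toy peptide-RNA complexes with planted
# interface fractions, and abundance tables biased by interface-index.
#
# One global seed fans out to deterministic per-generator substreams so that
# adding a generator does not shift the outputs of existing ones.

#' Derive a deterministic substream seed
#'
#' Hashes a generator name together with a global seed into an independent
#' 31-bit seed, so each generator consumes its own reproducible random stream.
#'
#' @param seed Global integer seed.
#' @param name Substream name (e.g. `"transcripts"`).
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * (7 + seq_along(utf8ToInt(name)) * 13))
  as.integer(((abs(seed) %% 2147483647) * 16807 + h * 7919) %% 2147483646 + 1)
}

#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic benchmark. Defaults
#' follow the statistical structure of the biological system: about 80
#' ribosomal-protein genes, a CUIC motif present in ~70% of RP mRNAs at
#' 20-80 nt upstream of the start codon, and purine-only background sequence
#' so that planted pyrimidine motifs are the only consensus matches (set
#' `background = "uniform"` for a hard mode with spurious matches).
#'
#' @param seed Global seed; fans out to per-generator substreams.
#' @param n_rp,n_nonrp Numbers of RP and non-RP transcripts.
#' @param motif_prevalence Fraction of RP transcripts with a planted motif.
#' @param dist_lo,dist_hi Planted motif distance band (nt upstream of AUG),
#'   sampled uniformly; set `dist_lo == dist_hi` for a point distance.
#' @param utr_len_range Length range of simulated UTRs (default 100-300 nt).
#' @param background `"purine"` (A/G only) or `"uniform"`.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_rp = 80L, n_nonrp = 200L,
                       motif_prevalence = 0.7, dist_lo = 20L, dist_hi = 80L,
                       utr_len_range = c(100L, 300L),
                       background = c("purine", "uniform")) {
  background <- match.arg(background)
  if (motif_prevalence < 0 || motif_prevalence > 1) {
    stop("motif_prevalence must be in [0, 1]", call. = FALSE)
  }
  if (dist_lo > dist_hi || dist_lo < 0) {
    stop("need 0 <= dist_lo <= dist_hi", call. = FALSE)
  }
  if (utr_len_range[1] < dist_hi + 8L) {
    stop("UTRs must be long enough to hold the motif at dist_hi", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_rp = as.integer(n_rp),
                 n_nonrp = as.integer(n_nonrp),
                 motif_prevalence = motif_prevalence,
                 dist_lo = as.integer(dist_lo), dist_hi = as.integer(dist_hi),
                 utr_len_range = as.integer(utr_len_range),
                 background = background),
            class = "sim_config")
}

.consensus_words <- function(consensus = "YYYYTTYC") {
  cons <- .normalize_consensus(consensus)
  sets <- lapply(strsplit(cons, "")[[1]],
                 function(ch) strsplit(.IUPAC[[ch]], "")[[1]])
  do.call(paste0, expand.grid(sets, stringsAsFactors = FALSE))
}

#' Generate planted-motif transcripts
#'
#' Simulates 5' UTRs with known ground truth: background sequence (purine-only
#' by default, so the pyrimidine consensus has zero background hit rate), a
#' consensus word planted in a `motif_prevalence` fraction of RP transcripts
#' at a distance sampled from the configured band, and log-normal FPKM values
#' (RP transcripts drawn more abundant, as in axonal transcriptomes).
#'
#' @param cfg A [sim_config()].
#' @return List with `transcripts` (list of [transcript_record()]) and `truth`
#'   (data.frame: `transcript_id`, `is_rp`, `has_motif`, `planted_start`,
#'   `planted_dist`, `planted_seq`, `utr_length`).
#' @export
gen_transcripts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(substream_seed(cfg$seed, "transcripts"))
  words <- .consensus_words()
  n <- cfg$n_rp + cfg$n_nonrp
  ids <- c(sprintf("RP_%04d", seq_len(cfg$n_rp)),
           sprintf("NR_%04d", seq_len(cfg$n_nonrp)))
  is_rp <- rep(c(TRUE, FALSE), c(cfg$n_rp, cfg$n_nonrp))
  alphabet <- if (cfg$background == "purine") c("A", "G") else c("A", "C", "G", "T")
  transcripts <- vector("list", n)
  truth <- data.frame(transcript_id = ids, is_rp = is_rp, has_motif = FALSE,
                      planted_start = NA_integer_, planted_dist = NA_integer_,
                      planted_seq = NA_character_, utr_length = NA_integer_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    L <- sample(cfg$utr_len_range[1]:cfg$utr_len_range[2], 1L)
    seq <- paste(sample(alphabet, L, replace = TRUE), collapse = "")
    if (is_rp[i] && stats::runif(1) < cfg$motif_prevalence) {
      d <- if (cfg$dist_lo == cfg$dist_hi) cfg$dist_lo else
        sample(cfg$dist_lo:cfg$dist_hi, 1L)
      end0 <- L - d          # 0-based exclusive end of the motif
      start0 <- end0 - 8L
      word <- sample(words, 1L)
      substr(seq, start0 + 1L, end0) <- word
      truth$has_motif[i] <- TRUE
      truth$planted_start[i] <- start0
      truth$planted_dist[i] <- d
      truth$planted_seq[i] <- word
    }
    truth$utr_length[i] <- L
    fpkm <- stats::rlnorm(1, meanlog = if (is_rp[i]) log(200) else log(20),
                          sdlog = 1)
    transcripts[[i]] <- transcript_record(ids[i], seq,
                                          gene_symbol = ids[i],
                                          is_rp = is_rp[i],
                                          species = "synthetic",
                                          abundance = c(axon = fpkm))
  }
  list(transcripts = transcripts, truth = truth)
}

#' Generate secondary structures with a loop over the planted motif
#'
#' Builds positional ground-truth structures: for each transcript with a
#' planted motif, the motif footprint is forced single-stranded and the
#' immediately flanking positions are paired into a stem enclosing it
#' (pairing position `start - i` with `end + i - 1`, a properly nested
#' hairpin); all other positions are unpaired. These are structural
#' annotations constructed to carry an exact known signal, not thermodynamic
#' predictions — the pipeline consumes them exactly as it would consume
#' externally folded dot-bracket input.
#'
#' @param transcripts List of `transcript_record`s from [gen_transcripts()].
#' @param truth Matching truth table.
#' @param stem_len Maximum stem length on each side of the motif (default 15).
#' @return List of `secondary_structure` objects (motif-bearing transcripts
#'   only).
#' @export
gen_structures <- function(transcripts, truth, stem_len = 15L) {
  out <- list()
  for (i in seq_along(transcripts)) {
    if (!truth$has_motif[i]) next
    L <- truth$utr_length[i]
    s <- truth$planted_start[i]        # 0-based
    e <- s + 8L
    k <- min(s, L - e, stem_len)
    db <- rep(".", L)
    if (k > 0L) {
      db[(s - k + 1L):s] <- "("        # 1-based positions s-k+1..s  (0-based s-k..s-1)
      db[(e + 1L):(e + k)] <- ")"
    }
    db <- paste(db, collapse = "")
    out[[length(out) + 1L]] <- parse_dotbracket(
      db, seq = transcripts[[i]]$utr5_seq,
      transcript_id = truth$transcript_id[i])
  }
  out
}

#' Generate CLIP clusters with controlled CUIC-region enrichment
#'
#' For each RBP, places `n_clusters` clusters on the motif-bearing
#' transcripts: each cluster independently overlaps its transcript's CUIC
#' region with probability `rho[rbp]`, and otherwise is placed uniformly on
#' the UTR strictly outside the region, so the expected specificity score
#' equals rho exactly.
#'
#' @param rho Named numeric vector, RBP name to overlap probability in
#'   `[0, 1]`.
#' @param regions data.frame with `transcript_id`, `region_start`,
#'   `region_end`, `utr_length`.
#' @param n_clusters Clusters per RBP (default 100).
#' @param width Cluster width in nt (default 20).
#' @param seed Integer seed.
#' @return List with `clusters` (data.frame `rbp`, `transcript_id`, `start`,
#'   `end`, `dataset_id`) and `truth` (data.frame `rbp`, `rho`).
#' @export
gen_clip <- function(rho, regions, n_clusters = 100L, width = 20L, seed = 1L) {
  stopifnot(all(rho >= 0 & rho <= 1), !is.null(names(rho)))
  set.seed(substream_seed(seed, "clip"))
  rows <- vector("list", length(rho) * n_clusters)
  ri <- 0L
  for (rbp in names(rho)) {
    for (k in seq_len(n_clusters)) {
      tr <- regions[sample(nrow(regions), 1L), ]
      a <- tr$region_start; b <- tr$region_end; L <- tr$utr_length
      if (stats::runif(1) < rho[[rbp]]) {
        lo <- max(0L, a - width + 1L)
        hi <- min(L - width, b - 1L)
        start <- if (hi > lo) sample(lo:hi, 1L) else lo
      } else {
        left <- if (a - width >= 0L) 0L:(a - width) else integer(0)
        right <- if (b <= L - width) b:(L - width) else integer(0)
        cand <- c(left, right)
        if (length(cand) == 0L) {
          stop("UTR too short to place a non-overlapping cluster", call. = FALSE)
        }
        start <- if (length(cand) == 1L) cand else sample(cand, 1L)
      }
      ri <- ri + 1L
      rows[[ri]] <- data.frame(rbp = rbp, transcript_id = tr$transcript_id,
                               start = start, end = start + width,
                               dataset_id = sprintf("sim_%s", rbp),
                               stringsAsFactors = FALSE)
    }
  }
  clusters <- do.call(rbind, rows[seq_len(ri)])
  list(clusters = clusters,
       truth = data.frame(rbp = names(rho), rho = unname(rho),
                          stringsAsFactors = FALSE))
}

#' Generate a toy peptide-RNA complex with a planted interface fraction
#'
#' Builds an RNA chain as a straight phosphate-spaced backbone and a peptide
#' chain whose residues sit either within `near` angstrom of the backbone
#' (interface) or beyond `far` angstrom (non-interface), so the contact-mode
#' interface-index of the peptide equals `planted_fraction` exactly.
#'
#' @param n_residues Peptide residues.
#' @param planted_fraction Interface fraction; `n_residues * planted_fraction`
#'   must be an integer.
#' @param seed Seed for choosing which residues are interface.
#' @param near,far Distances (angstrom) of interface / non-interface residues
#'   from the RNA backbone axis (defaults 4 and 15; the contact criterion's
#'   default cutoff is 5).
#' @return List with `peptide` and `rna` (`chain_structure`s) and `truth`
#'   (data.frame `residue_id`, `is_interface`).
#' @export
gen_toy_complex <- function(n_residues = 10L, planted_fraction = 0.4,
                            seed = 1L, near = 4, far = 15) {
  k <- n_residues * planted_fraction
  if (abs(k - round(k)) > 1e-9) {
    stop("n_residues * planted_fraction must be an integer", call. = FALSE)
  }
  k <- as.integer(round(k))
  set.seed(substream_seed(seed, "toy_complex"))
  spacing <- 5.9  # approximate phosphate-phosphate spacing along the backbone
  n_rna <- n_residues + 4L
  rna_atoms <- data.frame(residue_id = seq_len(n_rna),
                          residue_name = "U", atom_name = "P", element = "P",
                          x = seq_len(n_rna) * spacing, y = 0, z = 0,
                          stringsAsFactors = FALSE)
  which_if <- sort(sample(n_residues, k))
  y <- ifelse(seq_len(n_residues) %in% which_if, near, far)
  pep_atoms <- data.frame(residue_id = seq_len(n_residues),
                          residue_name = "GLY", atom_name = "CA", element = "C",
                          x = (seq_len(n_residues) + 2L) * spacing, y = y, z = 0,
                          stringsAsFactors = FALSE)
  list(peptide = chain_structure("A", "protein", pep_atoms),
       rna = chain_structure("R", "rna", rna_atoms),
       truth = data.frame(residue_id = seq_len(n_residues),
                          is_interface = seq_len(n_residues) %in% which_if))
}

#' Rigid-body transform of chain structures
#'
#' Applies a rotation (about the x, y, z axes in turn) and translation to
#' every atom of one or more chains; used to verify that interface statistics
#' are invariant under rigid motion of the whole complex.
#'
#' @param chains A `chain_structure` or list of them.
#' @param angles Rotation angles in radians, length 3.
#' @param shift Translation vector, length 3.
#' @return The transformed object (same shape as the input).
#' @export
rigid_transform <- function(chains, angles = c(0, 0, 0), shift = c(0, 0, 0)) {
  rot <- function(a) {
    Rx <- matrix(c(1, 0, 0, 0, cos(a[1]), -sin(a[1]), 0, sin(a[1]), cos(a[1])),
                 3, 3, byrow = TRUE)
    Ry <- matrix(c(cos(a[2]), 0, sin(a[2]), 0, 1, 0, -sin(a[2]), 0, cos(a[2])),
                 3, 3, byrow = TRUE)
    Rz <- matrix(c(cos(a[3]), -sin(a[3]), 0, sin(a[3]), cos(a[3]), 0, 0, 0, 1),
                 3, 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  R <- rot(angles)
  one <- function(ch) {
    xyz <- as.matrix(ch$atoms[, c("x", "y", "z")]) %*% t(R)
    ch$atoms$x <- xyz[, 1] + shift[1]
    ch$atoms$y <- xyz[, 2] + shift[2]
    ch$atoms$z <- xyz[, 3] + shift[3]
    ch
  }
  if (inherits(chains, "chain_structure")) return(one(chains))
  lapply(chains, one)
}

#' Generate an abundance table biased by interface-index
#'
#' Assigns each ribosomal protein to the abundant class with probability
#' following a logistic function of its (centered) interface-index,
#' `p = plogis(qlogis(p_abundant) - beta * (index - mean(index)))`, then draws
#' FPKM log-normally within class on either side of `fpkm_cut`. `beta = 0` is
#' the null (no structure-abundance association); large `beta` depletes
#' high-index proteins from the abundant class.
#'
#' @param index_by_rp Named numeric vector of interface-indices.
#' @param beta Bias strength (per unit index).
#' @param seed Integer seed.
#' @param p_abundant Marginal abundant probability at the mean index
#'   (default 0.5).
#' @param fpkm_cut Class boundary on FPKM (default 100, strict).
#' @return List with `fpkm` (named vector), `abundant` (names) and `truth`
#'   (`beta`, `p_abundant`).
#' @export
gen_biased_abundance <- function(index_by_rp, beta, seed = 1L,
                                 p_abundant = 0.5, fpkm_cut = 100) {
  set.seed(substream_seed(seed, "abundance"))
  p <- stats::plogis(stats::qlogis(p_abundant) -
                       beta * (index_by_rp - mean(index_by_rp)))
  ab <- stats::runif(length(p)) < p
  n <- length(p)
  fpkm <- ifelse(ab,
                 fpkm_cut * exp(stats::runif(n, 0.05, 2)),
                 fpkm_cut * exp(-stats::runif(n, 0.05, 2)))
  names(fpkm) <- names(index_by_rp)
  list(fpkm = fpkm, abundant = names(index_by_rp)[ab],
       truth = list(beta = beta, p_abundant = p_abundant))
}

#' Generate groups with a planted fold-depletion of high-index proteins
#'
#' Draws interface-indices for `n_rp` proteins and a fixed-size abundant
#' group such that the expected fraction of high-index proteins is `fold`
#' times lower in the abundant group than in the non-abundant group, with the
#' overall high-index fraction held at `high_frac`. `fold = 1` is the null.
#'
#' @param n_rp Total proteins (default 80).
#' @param n_abundant Abundant group size (default 30).
#' @param high_frac Overall expected high-index fraction (default 0.25).
#' @param fold Planted fold depletion (default 5).
#' @param index_cut High/low index boundary (default 0.6).
#' @param seed Integer seed.
#' @return List with `index_by_rp` (named), `abundant` (names), `truth`.
#' @export
gen_depletion_groups <- function(n_rp = 80L, n_abundant = 30L,
                                 high_frac = 0.25, fold = 5, index_cut = 0.6,
                                 seed = 1L) {
  stopifnot(n_abundant < n_rp, fold > 0)
  set.seed(substream_seed(seed, "depletion"))
  n_non <- n_rp - n_abundant
  q_ab <- n_rp * high_frac / (n_abundant + fold * n_non)
  q_non <- fold * q_ab
  if (q_non > 1) stop("planted fold too large for high_frac", call. = FALSE)
  rp <- sprintf("RP_%03d", seq_len(n_rp))
  abundant <- sample(rp, n_abundant)
  q <- ifelse(rp %in% abundant, q_ab, q_non)
  high <- stats::runif(n_rp) < q
  index <- ifelse(high,
                  stats::runif(n_rp, index_cut + 0.05, 0.95),
                  stats::runif(n_rp, 0.05, index_cut - 0.05))
  names(index) <- rp
  list(index_by_rp = index, abundant = abundant,
       truth = list(q_abundant = q_ab, q_non_abundant = q_non, fold = fold))
}
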