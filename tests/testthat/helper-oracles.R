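# Independent oracles used across the suite. Each is written as a direct,
# brute-force restatement of the definition it checks, on a different code
# path from the package implementation.

# Window-by-window regex scan: each window is tested independently against a
# character-class regex built from the IUPAC code.
oracle_scan_starts <- function(seq, consensus = "YYYYTTYC") {
  iupac <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
             S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
             D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  s <- toupper(chartr("uU", "tT", gsub("[[:space:]]", "", seq)))
  pat <- paste0("^", paste(iupac[strsplit(consensus, "")[[1]]], collapse = ""), "$")
  k <- nchar(consensus)
  starts <- integer(0)
  for (i in seq_len(max(0L, nchar(s) - k + 1L))) {
    if (grepl(pat, substr(s, i, i + k - 1L))) starts <- c(starts, i - 1L)
  }
  starts
}

# Exhaustive enumeration of every nested structure (as an explicit pair list)
# with a minimum loop size; returns the maximum attainable pair count.
oracle_max_pairs <- function(seq, min_loop = 3) {
  chars <- strsplit(toupper(chartr("uU", "tT", seq)), "")[[1]]
  can <- function(a, b) paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  rec <- function(i, j) {
    if (i > j) return(list(matrix(integer(0), ncol = 2)))
    out <- rec(i + 1L, j)
    if (j >= i + min_loop + 1L) {
      for (k in (i + min_loop + 1L):j) {
        if (!can(chars[i], chars[k])) next
        for (A in rec(i + 1L, k - 1L)) {
          for (B in rec(k + 1L, j)) {
            out[[length(out) + 1L]] <- rbind(c(i, k), A, B)
          }
        }
      }
    }
    out
  }
  max(vapply(rec(1L, length(chars)), nrow, integer(1)))
}

# Full hypergeometric enumeration of the two-sided Fisher p for a 2x2 table:
# sum of the probabilities of all tables (same margins) no more probable than
# the observed one. The 1 + 1e-7 relative tolerance is the standard guard
# against ties broken by floating-point noise.
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  supp <- max(0L, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(supp, r1, n - r1, c1)
  p_obs <- dhyper(a, r1, n - r1, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Bitmask enumeration (not combn) of all label assignments for the two-sample
# KS D and the rank-sum U null distributions.
oracle_perm_stats <- function(x, y, stat) {
  pooled <- c(x, y)
  N <- length(pooled)
  n <- length(x)
  vals <- numeric(0)
  for (mask in 0:(2^N - 1)) {
    sel <- as.logical(bitwAnd(mask, 2^(0:(N - 1))))
    if (sum(sel) != n) next
    vals <- c(vals, stat(pooled[sel], pooled[!sel]))
  }
  vals
}

oracle_ks_D <- function(x, y) {
  f <- ecdf(x); g <- ecdf(y)
  pts <- c(x, y)
  max(abs(f(pts) - g(pts)))
}

oracle_U <- function(x, y) {
  # count of (x_i, y_j) pairs with x_i > y_j, ties counted half
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# O(n^2) all-pairs contact oracle: residue ids of `chain` with any atom within
# `cut` of any partner atom.
oracle_contact_residues <- function(chain, partners, cut = 5.0) {
  if (inherits(partners, "chain_structure")) partners <- list(partners)
  pat <- do.call(rbind, lapply(partners, function(p) p$atoms))
  hit <- character(0)
  for (i in seq_len(nrow(chain$atoms))) {
    for (j in seq_len(nrow(pat))) {
      d <- sqrt((chain$atoms$x[i] - pat$x[j])^2 +
                  (chain$atoms$y[i] - pat$y[j])^2 +
                  (chain$atoms$z[i] - pat$z[j])^2)
      if (d <= cut) {
        hit <- union(hit, as.character(chain$atoms$residue_id[i]))
        break
      }
    }
  }
  hit
}

# Random nucleotide sequence over a given alphabet.
random_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# A fixture for the dsasa-vs-contact distinction: residue 1 is a 12-atom
# shell fully enclosing residue 2's single carbon, so residue 2 has zero SASA
# whether or not partners are present; an RNA phosphate sits `gap` angstrom
# from residue 2's atom.
buried_residue_fixture <- function(gap = 4.9) {
  phi <- (1 + sqrt(5)) / 2
  verts <- rbind(
    expand.grid(x = c(-1, 1), y = c(-phi, phi), z = 0),
    expand.grid(x = 0, y = c(-1, 1), z = c(-phi, phi)),
    expand.grid(x = c(-phi, phi), y = 0, z = c(-1, 1))
  )
  verts <- as.matrix(verts)[, c("x", "y", "z")]
  verts <- verts / sqrt(rowSums(verts^2)) * 3.0
  shell <- data.frame(residue_id = 1L, residue_name = "GLY",
                      atom_name = paste0("C", seq_len(nrow(verts))),
                      element = "C", x = verts[, 1], y = verts[, 2],
                      z = verts[, 3])
  core <- data.frame(residue_id = 2L, residue_name = "GLY", atom_name = "CA",
                     element = "C", x = 0, y = 0, z = 0)
  prot <- chain_structure("A", "protein", rbind(shell, core))
  # place the phosphate along +x beyond the shell, at `gap` from the core atom
  rna <- chain_structure("R", "rna",
                         data.frame(residue_id = 1L, residue_name = "U",
                                    atom_name = "P", element = "P",
                                    x = gap, y = 0, z = 0))
  list(protein = prot, rna = rna)
}
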