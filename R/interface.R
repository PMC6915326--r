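# Interface-index of ribosomal proteins: the fraction of a protein chain's
# residues that interface with rRNA in the assembled ribosome, computed either
# from buried solvent-accessible surface area (dSASA) or from atomic contacts.

.ELEMENT_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

#' Build a chain structure
#'
#' A minimal heavy-atom representation of one chain of a protein-RNA complex:
#' an atom table with residue bookkeeping and a molecule class used to select
#' interface partners (protein chains are scored against rna chains).
#'
#' @param chain_id Chain identifier.
#' @param molecule_class `"protein"` or `"rna"`.
#' @param atoms data.frame with columns `residue_id`, `residue_name`,
#'   `atom_name`, `element` (C/N/O/S/P), `x`, `y`, `z` (angstrom).
#' @return A list of class `chain_structure` with van der Waals radii assigned
#'   by element (C 1.70, N 1.55, O 1.52, S 1.80, P 1.80 angstrom).
#' @export
chain_structure <- function(chain_id, molecule_class = c("protein", "rna"),
                            atoms) {
  molecule_class <- match.arg(molecule_class)
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1L)
  need <- c("residue_id", "residue_name", "atom_name", "element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) {
    stop(sprintf("atoms is missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("all atom coordinates must be finite", call. = FALSE)
  }
  unknown <- !atoms$element %in% names(.ELEMENT_RADII)
  if (any(unknown)) {
    stop(sprintf("unknown element for atom(s): %s",
                 paste(unique(paste0(atoms$residue_id, "/", atoms$atom_name,
                                     " (", atoms$element, ")")[unknown]),
                       collapse = ", ")), call. = FALSE)
  }
  atoms$radius <- .ELEMENT_RADII[atoms$element]
  structure(list(chain_id = chain_id, molecule_class = molecule_class,
                 atoms = atoms),
            class = "chain_structure")
}

#' @export
print.chain_structure <- function(x, ...) {
  cat(sprintf("<chain_structure> %s (%s): %d residues, %d atoms\n",
              x$chain_id, x$molecule_class,
              length(unique(x$atoms$residue_id)), nrow(x$atoms)))
  invisible(x)
}

# Deterministic quasi-uniform unit sphere points (golden-section spiral).
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom and per-residue SASA by sphere sampling: each atom's surface is
#' the sphere of radius (vdW radius + probe), sampled at `n_points`
#' quasi-uniform points; a point is accessible when it lies outside every
#' neighbouring atom's probe-expanded sphere.
#'
#' @param atoms Atom data.frame as in [chain_structure()] (a `chain_structure`
#'   or a list of them is also accepted; atoms are pooled).
#' @param probe Probe radius in angstrom (default 1.4, a water molecule).
#' @param n_points Sample points per atom (default 960).
#' @return List with `atom_area` (numeric per atom, angstrom^2) and
#'   `residue_area` (named by `residue_id`, summed over the residue's atoms;
#'   names combine chain and residue when a `chain_id` column is present).
#' @export
sasa <- function(atoms, probe = 1.4, n_points = 960) {
  atoms <- .pool_atoms(atoms)
  if (nrow(atoms) == 0L) stop("sasa requires at least one atom", call. = FALSE)
  unknown <- !atoms$element %in% names(.ELEMENT_RADII)
  if (any(unknown)) {
    stop(sprintf("unknown element for atom(s): %s",
                 paste(unique(atoms$element[unknown]), collapse = ", ")),
         call. = FALSE)
  }
  r <- .ELEMENT_RADII[atoms$element] + probe
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  pts <- .sphere_points(n_points)
  n <- nrow(xyz)
  area <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (r + r[i])^2 & seq_len(n) != i)
    surf <- sweep(pts * r[i], 2, xyz[i, ], `+`)
    if (length(nb)) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        dj2 <- (surf[, 1] - xyz[j, 1])^2 + (surf[, 2] - xyz[j, 2])^2 +
          (surf[, 3] - xyz[j, 3])^2
        free <- free & dj2 >= r[j]^2
        if (!any(free)) break
      }
      frac <- sum(free) / n_points
    } else {
      frac <- 1
    }
    area[i] <- frac * 4 * pi * r[i]^2
  }
  res_key <- if (!is.null(atoms$chain_id)) {
    paste(atoms$chain_id, atoms$residue_id, sep = ":")
  } else {
    as.character(atoms$residue_id)
  }
  residue_area <- tapply(area, res_key, sum)
  list(atom_area = area, residue_area = residue_area)
}

.pool_atoms <- function(x) {
  if (inherits(x, "chain_structure")) {
    at <- x$atoms
    at$chain_id <- x$chain_id
    return(at)
  }
  if (is.data.frame(x)) return(x)
  if (is.list(x)) {
    return(do.call(rbind, lapply(x, .pool_atoms)))
  }
  stop("cannot interpret atoms input", call. = FALSE)
}

#' Interface residues of a protein chain against RNA partners
#'
#' Identifies the residues of a protein chain that interface its RNA partners,
#' by one of two criteria:
#' \describe{
#'   \item{dsasa}{a residue is interface when its solvent-accessible surface
#'     area computed on the isolated chain exceeds its SASA in the complex
#'     (chain plus partners only) by more than `dsasa_cut` angstrom^2 — the
#'     buried-surface logic of standard interface-residue tools;}
#'   \item{contact}{a residue is interface when any of its heavy atoms lies
#'     within `contact_cut` angstrom of any partner heavy atom.}
#' }
#'
#' @param chain `chain_structure` with `molecule_class == "protein"`.
#' @param partners List of `chain_structure`s with `molecule_class == "rna"`
#'   (for small-subunit proteins the 18S rRNA; for large-subunit proteins the
#'   5S, 5.8S and 28S rRNAs).
#' @param mode `"dsasa"` (default) or `"contact"`.
#' @param dsasa_cut Buried-area cutoff, angstrom^2 (default 1.0).
#' @param contact_cut Distance cutoff, angstrom (default 5.0).
#' @param probe,n_points SASA parameters, see [sasa()].
#' @return Character vector of interface `residue_id`s.
#' @export
interface_residues <- function(chain, partners, mode = c("dsasa", "contact"),
                               dsasa_cut = 1.0, contact_cut = 5.0,
                               probe = 1.4, n_points = 960) {
  mode <- match.arg(mode)
  if (inherits(partners, "chain_structure")) partners <- list(partners)
  if (length(partners) == 0L) {
    stop("interface_residues requires at least one RNA partner chain",
         call. = FALSE)
  }
  stopifnot(inherits(chain, "chain_structure"),
            chain$molecule_class == "protein")
  for (p in partners) {
    stopifnot(inherits(p, "chain_structure"))
    if (p$molecule_class != "rna") {
      stop(sprintf("partner chain '%s' is not RNA", p$chain_id), call. = FALSE)
    }
  }
  res_ids <- unique(as.character(chain$atoms$residue_id))
  if (mode == "contact") {
    pxyz <- as.matrix(.pool_atoms(partners)[, c("x", "y", "z")])
    cxyz <- as.matrix(chain$atoms[, c("x", "y", "z")])
    mind2 <- vapply(seq_len(nrow(cxyz)), function(i) {
      min((pxyz[, 1] - cxyz[i, 1])^2 + (pxyz[, 2] - cxyz[i, 2])^2 +
            (pxyz[, 3] - cxyz[i, 3])^2)
    }, numeric(1))
    hit <- mind2 <= contact_cut^2
    return(res_ids[res_ids %in% as.character(chain$atoms$residue_id[hit])])
  }
  alone <- sasa(chain, probe = probe, n_points = n_points)$residue_area
  complexed <- sasa(c(list(chain), partners), probe = probe,
                    n_points = n_points)$residue_area
  key <- paste(chain$chain_id, res_ids, sep = ":")
  delta <- alone[key] - complexed[key]
  res_ids[!is.na(delta) & delta > dsasa_cut]
}

#' Interface-index of a ribosomal protein
#'
#' The interface-index of a protein chain is the fraction of its resolved
#' residues that interface rRNA partner chains:
#' `index = n_interface / n_residues`. Residues missing from the model do not
#' enter the denominator (only residues with at least one resolved heavy atom
#' count). Chains with index strictly above `class_cut` (default 0.6) are
#' classified `"penetrated"` — deeply embedded in, or threading through, the
#' rRNA core — and the rest `"surface"`.
#'
#' @inheritParams interface_residues
#' @param rp_name Ribosomal-protein name carried into the result.
#' @param class_cut Strict classification threshold on the index (default 0.6).
#' @return A list of class `interface_index_result`: `chain_id`, `rp_name`,
#'   `n_residues`, `n_interface`, `index`, `structural_class`,
#'   `interface_residues`, `mode`.
#' @export
interface_index <- function(chain, partners, mode = c("dsasa", "contact"),
                            rp_name = NA_character_, class_cut = 0.6,
                            dsasa_cut = 1.0, contact_cut = 5.0,
                            probe = 1.4, n_points = 960) {
  mode <- match.arg(mode)
  n_res <- length(unique(chain$atoms$residue_id))
  if (n_res == 0L) {
    stop("chain has no resolved residues", call. = FALSE)
  }
  ifres <- interface_residues(chain, partners, mode = mode,
                              dsasa_cut = dsasa_cut, contact_cut = contact_cut,
                              probe = probe, n_points = n_points)
  idx <- length(ifres) / n_res
  structure(
    list(chain_id = chain$chain_id, rp_name = rp_name,
         n_residues = n_res, n_interface = length(ifres), index = idx,
         structural_class = if (idx > class_cut) "penetrated" else "surface",
         interface_residues = ifres, mode = mode),
    class = "interface_index_result"
  )
}

#' @export
print.interface_index_result <- function(x, ...) {
  cat(sprintf("<interface_index_result> chain %s (%s): %d/%d residues interface rRNA, index %.3f (%s, %s mode)\n",
              x$chain_id, ifelse(is.na(x$rp_name), "?", x$rp_name),
              x$n_interface, x$n_residues, x$index, x$structural_class, x$mode))
  invisible(x)
}

#' Read a protein-RNA complex from a PDB or mmCIF file
#'
#' Loads heavy atoms from a PDB or mmCIF file via \pkg{bio3d} (format chosen
#' by file extension), keeps the highest-occupancy alternate conformer of
#' each atom, drops hydrogens, and splits the model into per-chain
#' [chain_structure()] objects using a chain-role table.
#'
#' @param path Structure file path (`.pdb`, or `.cif` for mmCIF).
#' @param roles data.frame with columns `chain_id`, `molecule_class`
#'   (`protein`/`rna`), optional `rp_name`, `subunit`. Chains absent from the
#'   table are skipped.
#' @return Named list of `chain_structure` objects; `rp_name` values are
#'   attached as an attribute `roles`.
#' @export
read_complex_pdb <- function(path, roles) {
  stopifnot(is.data.frame(roles), all(c("chain_id", "molecule_class") %in% names(roles)))
  pdb <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)) {
    bio3d::read.cif(path, verbose = FALSE)
  } else {
    bio3d::read.pdb(path)
  }
  at <- pdb$atom
  sym <- if (!is.null(at$elesy)) trimws(at$elesy) else ""
  fallback <- sub("^[0-9]*", "", trimws(at$elety))
  elem <- toupper(ifelse(is.na(sym) | sym == "", substr(fallback, 1, 1), sym))
  at$element <- elem
  at <- at[at$element != "H" & at$element != "D", , drop = FALSE]
  # highest-occupancy altloc per (chain, residue, atom name)
  if (!is.null(at$o)) {
    key <- paste(at$chain, at$resno, at$elety, sep = "\r")
    at <- at[order(key, -at$o), , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$elety, sep = "\r")), ,
             drop = FALSE]
  }
  out <- list()
  for (i in seq_len(nrow(roles))) {
    cid <- roles$chain_id[i]
    sub <- at[at$chain == cid, , drop = FALSE]
    if (nrow(sub) == 0L) next
    atoms <- data.frame(residue_id = sub$resno, residue_name = sub$resid,
                        atom_name = sub$elety, element = sub$element,
                        x = sub$x, y = sub$y, z = sub$z,
                        stringsAsFactors = FALSE)
    out[[cid]] <- chain_structure(cid, roles$molecule_class[i], atoms)
  }
  attr(out, "roles") <- roles
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
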