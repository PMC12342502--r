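# Reading structures and per-residue label files into the internal chain
# representation. Parsing and writing of PDB/mmCIF coordinate records is
# delegated to bio3d; this module owns the residue register: author-numbering
# gaps of size g insert g-1 placeholder positions with no coordinates, so
# sequence position i always means register position i, across chain breaks.

#' Construct a chain structure
#'
#' Internal representation of one protein chain: an ordered residue register
#' with author numbers, insertion codes, residue names, C-alpha coordinates
#' and presence flags. Positions where the chain is discontinuous are kept as
#' absent placeholders so that the register stays aligned with author
#' numbering.
#'
#' @param chain_id Chain identifier.
#' @param resno Integer author residue numbers.
#' @param icode Insertion codes ("" when none).
#' @param resid Three-letter residue names ("UNK" allowed).
#' @param xyz Numeric matrix (n x 3) of C-alpha coordinates; rows of NA for
#'   absent positions.
#' @param present Logical: is a C-alpha modelled at this position?
#'
#' @return An object of class `chain_structure`.
#' @export
chain_structure <- function(chain_id, resno, icode, resid, xyz, present) {
  n <- length(resno)
  stopifnot(n >= 1, length(icode) == n, length(resid) == n,
            nrow(xyz) == n, ncol(xyz) == 3, length(present) == n)
  if (any(present & !is.finite(rowSums(xyz))))
    stop("present residues must have finite coordinates")
  xyz[!present, ] <- NA_real_
  res <- data.frame(resno = as.integer(resno), icode = as.character(icode),
                    resid = as.character(resid),
                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    present = as.logical(present),
                    stringsAsFactors = FALSE)
  structure(list(chain_id = as.character(chain_id), residues = res),
            class = "chain_structure")
}

#' @export
print.chain_structure <- function(x, ...) {
  r <- x$residues
  cat(sprintf("<chain_structure> chain %s: %d register positions (%d modelled), author numbering %d..%d\n",
              x$chain_id, nrow(r), sum(r$present),
              r$resno[1], r$resno[nrow(r)]))
  invisible(x)
}

#' Number of register positions of a chain
#' @param chain A `chain_structure`.
#' @return Integer register length (including absent placeholder positions).
#' @export
chain_length <- function(chain) nrow(chain$residues)

# n x 3 coordinate matrix over the register (NA rows for absent positions).
chain_xyz <- function(chain) {
  as.matrix(chain$residues[, c("x", "y", "z")])
}

#' Read one chain from a PDB or mmCIF file
#'
#' Loads the C-alpha trace of a single chain. Files ending in `.cif`/`.mmcif`
#' are parsed as mmCIF, anything else as PDB (model 1 only). Residues are
#' ordered as encountered in the file; where consecutive author numbers jump
#' by g > 1, g - 1 absent placeholder positions are inserted so the register
#' matches sequence position across chain breaks. For alternate locations the
#' first-listed C-alpha conformer is taken.
#'
#' @param path Path to a PDB or mmCIF file.
#' @param chain_id Chain identifier to extract.
#'
#' @return A [chain_structure()].
#' @export
read_chain <- function(path, chain_id) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- suppressWarnings(
    if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE)
  )
  at <- pdb$atom
  if (!chain_id %in% unique(at$chain))
    stop("chain not found: '", chain_id, "' in ", path)
  at <- at[at$chain == chain_id & at$elety == "CA" &
             at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (nrow(at) == 0)
    stop("empty chain: no C-alpha atoms in chain '", chain_id, "'")
  ic <- at$insert
  ic[is.na(ic)] <- ""
  # first-listed altloc conformer per (author number, insertion code)
  keep <- !duplicated(paste(at$resno, ic, sep = "\r"))
  at <- at[keep, , drop = FALSE]
  ic <- ic[keep]

  resno <- integer(0); icode <- character(0); resid <- character(0)
  xyz <- matrix(numeric(0), ncol = 3); present <- logical(0)
  prev <- NA_integer_
  for (i in seq_len(nrow(at))) {
    rn <- at$resno[i]
    if (!is.na(prev) && rn > prev + 1L) {
      g <- rn - prev - 1L
      resno <- c(resno, prev + seq_len(g))
      icode <- c(icode, rep("", g))
      resid <- c(resid, rep("UNK", g))
      xyz <- rbind(xyz, matrix(NA_real_, g, 3))
      present <- c(present, rep(FALSE, g))
    }
    resno <- c(resno, rn)
    icode <- c(icode, ic[i])
    resid <- c(resid, at$resid[i])
    xyz <- rbind(xyz, c(at$x[i], at$y[i], at$z[i]))
    present <- c(present, TRUE)
    prev <- rn
  }
  chain_structure(chain_id, resno, icode, resid, xyz, present)
}

#' Read per-residue class labels aligned to a chain register
#'
#' Accepts either a two-column file of (author residue number, class) pairs —
#' whitespace- or comma-delimited — or a bare one-class-per-line list of the
#' chain's register length. Classes are integers 0 (non-solenoid),
#' 1 (beta-solenoid), 2 (alpha/beta-solenoid), 3 (alpha-solenoid),
#' 4 (missing). Absent register positions are forced to class 4.
#'
#' @param path Path to the label file.
#' @param chain The [chain_structure()] whose register the labels describe.
#'
#' @return Integer vector of classes, one per register position.
#' @export
read_labels <- function(path, chain) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sep <- if (any(grepl(",", lines))) "," else ""
  tab <- utils::read.table(text = lines, sep = sep, header = FALSE,
                           strip.white = TRUE)
  res <- chain$residues
  n <- nrow(res)
  check_values <- function(v) {
    if (any(!is.finite(v)) || any(v != floor(v)) || any(v < 0 | v > 4))
      stop("label value error: classes must be integers in 0..4")
    as.integer(v)
  }
  if (ncol(tab) >= 2) {
    rn <- tab[[1]]
    cls <- check_values(tab[[2]])
    if (anyDuplicated(rn))
      stop("label alignment error: duplicated author numbers in label file; ",
           "use the one-class-per-line format for chains with insertion codes")
    if (anyDuplicated(res$resno[res$present]))
      stop("label alignment error: chain has insertion-code duplicates; ",
           "use the one-class-per-line format")
    labels <- rep(4L, n)
    m <- match(rn, res$resno)
    if (any(is.na(m)))
      stop("label alignment error: author numbers not in the chain register: ",
           paste(utils::head(rn[is.na(m)], 3), collapse = ", "))
    labels[m] <- cls
    uncovered <- res$present & !(seq_len(n) %in% m)
    if (any(uncovered))
      stop("label alignment error: modelled residues without a label: ",
           paste(utils::head(res$resno[uncovered], 3), collapse = ", "))
  } else {
    cls <- check_values(tab[[1]])
    if (length(cls) != n)
      stop("label alignment error: ", length(cls), " labels for a register of ",
           n, " positions")
    labels <- cls
  }
  labels[!res$present] <- 4L
  labels
}

validate_labels <- function(labels, n = NULL) {
  if (!is.null(n) && length(labels) != n)
    stop("label alignment error: expected ", n, " labels, got ", length(labels))
  if (any(!labels %in% 0:4))
    stop("label value error: classes must be integers in 0..4")
  as.integer(labels)
}

#' Write the modelled residues of a chain as a PDB file
#'
#' Emits one C-alpha ATOM record per present register position, preserving
#' author numbering and insertion codes. Absent placeholder positions are
#' skipped, so re-reading the file reproduces the same register.
#'
#' @param chain A [chain_structure()].
#' @param path Output file path.
#' @param b Optional per-position numeric vector written to the B-factor
#'   column (register length; values at absent positions are ignored).
#'
#' @return `path`, invisibly.
#' @export
write_chain_pdb <- function(chain, path, b = NULL) {
  res <- chain$residues
  keep <- res$present
  if (!any(keep)) stop("empty chain: no modelled residues to write")
  bfac <- if (is.null(b)) rep(0, sum(keep)) else {
    stopifnot(length(b) == nrow(res))
    round(b[keep], 2)
  }
  xyz <- as.numeric(t(as.matrix(res[keep, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = res$resno[keep], resid = res$resid[keep],
                   chain = rep(chain$chain_id, sum(keep)),
                   insert = ifelse(nzchar(res$icode[keep]), res$icode[keep], ""),
                   elety = rep("CA", sum(keep)), b = bfac)
  invisible(path)
}

#' Write labels as a two-column TSV (author number, class)
#'
#' Only modelled positions are written; absent positions are reconstructed as
#' class 4 by [read_labels()].
#'
#' @param labels Integer class vector over the chain register.
#' @param chain The matching [chain_structure()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, chain, path) {
  labels <- validate_labels(labels, chain_length(chain))
  res <- chain$residues
  utils::write.table(data.frame(res$resno[res$present], labels[res$present]),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
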