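# Fixtures built in code: toy PDB texts and small shared objects.

# Write a minimal C-alpha-only PDB with given author numbers/coordinates.
write_toy_pdb <- function(resno, xyz, chain = "A", resid = "ALA",
                          elety = rep("CA", length(resno)),
                          path = tempfile(fileext = ".pdb")) {
  resid <- rep_len(resid, length(resno))
  lines <- vapply(seq_along(resno), function(i) {
    sprintf("ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, elety[i], resid[i], chain, resno[i],
            xyz[i, 1], xyz[i, 2], xyz[i, 3])
  }, "")
  writeLines(c(lines, "END"), path)
  path
}

# A small trained-free prediction_result built directly from classes.
fake_prediction <- function(classes, chain) {
  pos <- which(chain$residues$present)
  stopifnot(length(classes) == length(pos))
  structure(list(chain_id = chain$chain_id,
                 per_residue = data.frame(pos = pos,
                                          resno = chain$residues$resno[pos],
                                          icode = chain$residues$icode[pos],
                                          class = as.integer(classes),
                                          p0 = 0, p1 = 0, p2 = 0, p3 = 0),
                 n_register = chain_length(chain)),
            class = "prediction_result")
}

# A straight synthetic chain with all residues present (for geometry-free
# plumbing tests).
line_chain <- function(n, step = 3.8) {
  xyz <- cbind(0, 0, step * (seq_len(n) - 1))
  chain_structure("A", seq_len(n), rep("", n), rep("ALA", n), xyz,
                  rep(TRUE, n))
}
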