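# minimal fixed-width PDB ATOM line writer for hand-built parser fixtures
pdb_atom_line <- function(eleno, elety, resid, chain, resno, x, y, z,
                          occ = 1, b = 0, ele = substr(trimws(elety), 1, 1),
                          alt = " ", record = "ATOM") {
  name <- if (nchar(elety) < 4) sprintf(" %-3s", elety) else sprintf("%-4s", elety)
  sprintf("%-6s%5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, eleno, name, alt, resid, chain, resno, x, y, z, occ, b, ele)
}

write_pdb_fixture <- function(lines, file = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), file)
  file
}
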