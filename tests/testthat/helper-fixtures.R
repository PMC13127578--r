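# Shared fixtures, built in code at test time.

# two tiny constructs: K at 3, 23, 43, ...; S at 5, 25, ...; T at 9; Y at 13
fixture_sequences <- function() {
  c(PROTA = qxlms:::make_sequence(100),
    PROTB = qxlms:::make_sequence(60))
}

write_fasta_tmp <- function(sequences, path = tempfile(fileext = ".fasta")) {
  writeLines(paste0(">", names(sequences), "\n", unname(sequences)), path)
  path
}

# long-format quant rows for one (link, peptide species) across all
# (condition, replicate) pairs
quant_rows <- function(protein_a, site_a, protein_b, site_b, link_kind,
                       peptide, charge, intensities,
                       conditions = c("control", "treated"),
                       replicates = c("R1", "R2", "R3"),
                       candidate_sites = NA_character_) {
  grid <- expand.grid(replicate = replicates, condition = conditions,
                      stringsAsFactors = FALSE)[, 2:1]
  data.frame(protein_a = protein_a, site_a = site_a,
             protein_b = protein_b, site_b = site_b,
             link_kind = link_kind, peptide = peptide, charge = charge,
             condition = grid$condition, replicate = grid$replicate,
             intensity = intensities, retention_time = NA_real_,
             candidate_sites = candidate_sites, stringsAsFactors = FALSE)
}

# minimal valid peptide table: one interpeptide link + carriers, all
# intensities 100 (links) / 1000 (carriers)
fixture_peptides <- function() {
  rbind(
    quant_rows("PROTA", 3L, "PROTB", 23L, "interpeptide", "LGKVE", 2L,
               rep(100, 6)),
    quant_rows("PROTA", NA_integer_, NA_character_, NA_integer_, "unreacted",
               "ALGVEDRINQ", 2L, rep(1000, 6))
  )
}

write_quant_tmp <- function(df, path = tempfile(fileext = ".csv"), sep = ",") {
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  path
}

# model with explicit atom placement; atoms = data.frame(chain, resno,
# resid, elety, x, y, z)
toy_model <- function(atoms, id = "toy", role = "primary",
                      chain_map = NULL, offset = integer(0)) {
  m <- as_xlms_model(atoms, model_id = id, role = role)
  if (!is.null(chain_map)) m <- set_model_mapping(m, chain_map, offset)
  m
}

# n-residue Calpha-only zig-zag chain (non-collinear), 3.8 A spacing
zigzag_atoms <- function(n, chain = "A") {
  t <- seq_len(n)
  data.frame(chain = chain, resno = t, resid = "ALA", elety = "CA",
             elesy = "C",
             x = 3.8 * t, y = 2 * (t %% 2), z = 0.5 * (t %% 3),
             stringsAsFactors = FALSE)
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(9), 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

transform_model <- function(model, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  new <- sweep(xyz %*% t(rotation), 2, translation, `+`)
  model$atoms$x <- new[, 1]; model$atoms$y <- new[, 2]; model$atoms$z <- new[, 3]
  model
}

pdb_fixture_lines <- function(atoms) {
  vapply(seq_len(nrow(atoms)), function(i) {
    sprintf("ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
            i, atoms$elety[i], atoms$resid[i], atoms$chain[i], atoms$resno[i],
            atoms$x[i], atoms$y[i], atoms$z[i],
            substr(gsub("[0-9']", "", atoms$elety[i]), 1, 1))
  }, character(1))
}

write_pdb_tmp <- function(atoms, path = tempfile(fileext = ".pdb")) {
  writeLines(c(pdb_fixture_lines(atoms), "END"), path)
  path
}

# same content as an mmCIF atom_site loop
write_cif_tmp <- function(atoms, path = tempfile(fileext = ".cif")) {
  head <- c("data_toy", "loop_",
            paste0("_atom_site.",
                   c("group_PDB", "id", "type_symbol", "label_atom_id",
                     "label_alt_id", "label_comp_id", "label_asym_id",
                     "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                     "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                     "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                     "auth_comp_id", "auth_asym_id", "auth_atom_id",
                     "pdbx_PDB_model_num")))
  rows <- vapply(seq_len(nrow(atoms)), function(i) {
    el <- substr(gsub("[0-9']", "", atoms$elety[i]), 1, 1)
    sprintf("ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s %s %s 1",
            i, el, atoms$elety[i], atoms$resid[i], atoms$chain[i],
            atoms$resno[i], atoms$x[i], atoms$y[i], atoms$z[i],
            atoms$resno[i], atoms$resid[i], atoms$chain[i], atoms$elety[i])
  }, character(1))
  writeLines(c(head, rows), path)
  path
}
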