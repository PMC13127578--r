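three_res_atoms <- function() {
  data.frame(chain = "A", resno = 1:3, resid = c("ALA", "ALA", "LYS"),
             elety = "CA", elesy = "C",
             x = c(0, 3, 6), y = c(0, 4, 8), z = 0,
             stringsAsFactors = FALSE)
}

test_that("PDB and mmCIF readers agree and resolve altlocs by occupancy", {
  atoms <- three_res_atoms()
  m_pdb <- read_structure(write_pdb_tmp(atoms))
  expect_s3_class(m_pdb, "xlms_model")
  expect_identical(nrow(m_pdb$atoms), 3L)

  m_cif <- read_structure(write_cif_tmp(atoms))
  expect_equal(m_pdb$atoms[, c("x", "y", "z")],
               m_cif$atoms[, c("x", "y", "z")])
  expect_identical(m_pdb$atoms$resno, m_cif$atoms$resno)

  # altloc: highest occupancy wins
  alt <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA ALYS A   1       0.000   0.000   0.000  0.30  0.00           C",
    "ATOM      2  CA BLYS A   1       9.000   0.000   0.000  0.70  0.00           C",
    "END"), alt)
  m_alt <- read_structure(alt)
  expect_identical(nrow(m_alt$atoms), 1L)
  expect_equal(m_alt$atoms$x, 9)

  expect_error(read_structure(tempfile(fileext = ".pdb")), "not found")
})

test_that("model mapping translates construct numbering and validates chains", {
  m <- toy_model(three_res_atoms())
  expect_error(set_model_mapping(m, c(PROTA = "Z")), "absent from model")
  m <- set_model_mapping(m, c(PROTA = "A"), offset = c(PROTA = -10L))
  r <- qxlms:::resolve_model_residue(m, "PROTA", 12L)
  expect_identical(r$chain, "A")
  expect_identical(r$resno, 2L)
  expect_true(is.na(qxlms:::resolve_model_residue(m, "OTHER", 1L)$chain))
})

test_that("Calpha distances follow Euclid and survive rigid motions", {
  m <- toy_model(three_res_atoms())
  expect_equal(ca_distance(m, "A", 1, "A", 1), 0)
  expect_equal(ca_distance(m, "A", 1, "A", 2), 5)  # 3-4-5 triangle
  expect_equal(ca_distance(m, "A", 1, "A", 2), ca_distance(m, "A", 2, "A", 1))
  expect_true(is.na(ca_distance(m, "A", 1, "A", 9)))

  # rigid motion leaves every distance unchanged to 1e-9
  rot <- random_rotation(4)
  m2 <- transform_model(m, rot, c(10, -3, 2.5))
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(ca_distance(m2, "A", i, "A", j),
                 ca_distance(m, "A", i, "A", j), tolerance = 1e-9)
  }

  # CB-only model: Calpha lookup yields NA distance
  cb <- three_res_atoms(); cb$elety <- "CB"
  expect_true(is.na(ca_distance(toy_model(cb), "A", 1, "A", 2)))
})

test_that("reach annotation is inclusive at the 30 A boundary", {
  atoms <- data.frame(chain = "A",
                      resno = c(1, 11, 2, 12, 3, 13),
                      resid = "LYS", elety = "CA", elesy = "C",
                      x = c(0, 29.9, 0, 30.0, 0, 30.1),
                      y = rep(c(0, 100, 200), each = 2), z = 0,
                      stringsAsFactors = FALSE)
  m <- toy_model(atoms, chain_map = c(P = "A"))
  links <- data.frame(link = c("P:1--P:11", "P:2--P:12", "P:3--P:13"),
                      stringsAsFactors = FALSE)
  ann <- annotate_link_distances(links, list(m))
  expect_equal(ann$d_ca, c(29.9, 30.0, 30.1))
  expect_identical(ann$within_reach, c(TRUE, TRUE, FALSE))

  # monolinks are skipped; unmapped proteins give mapped = FALSE
  ann2 <- annotate_link_distances(
    data.frame(link = c("P:1", "Q:1--Q:2")), list(m))
  expect_identical(ann2$link, "Q:1--Q:2")
  expect_false(ann2$mapped)
  expect_true(is.na(ann2$within_reach))

  # ambiguous candidates: minimum distance over candidates decides reach
  links3 <- data.frame(link = "P:3--P:13", candidates_a = "1",
                       stringsAsFactors = FALSE)
  ann3 <- annotate_link_distances(links3, list(m))
  expect_equal(ann3$d_ca, 30.1)  # min over (3,13) and (1,13): 30.1 vs more
  linksr <- data.frame(link = "P:1--P:13", candidates_b = "11",
                       stringsAsFactors = FALSE)
  annr <- annotate_link_distances(linksr, list(m))
  expect_equal(annr$d_ca, ca_distance(m, "A", 1, "A", 11))
})

test_that("dynamics classification applies the reach-pattern rules exhaustively", {
  mk_diff <- function(link, dir, sig) {
    structure(data.frame(
      link = link, link_kind = "interpeptide",
      fold_change = if (dir == "increase") 4 else 0.25,
      direction = dir, p_value = if (sig) 0.001 else 0.4,
      significant = sig, stringsAsFactors = FALSE),
      class = c("xlms_diff", "data.frame"))
  }
  mk_ann <- function(link, role, model_id, d, mapped = TRUE) {
    data.frame(link = link, model_id = model_id, role = role,
               d_ca = d, mapped = mapped,
               within_reach = if (mapped) d <= 30 else NA,
               stringsAsFactors = FALSE)
  }
  # converter-L50 style: increase, within reach in both primary models
  d1 <- classify_dynamics(
    mk_diff("P:707--P:715", "increase", TRUE),
    rbind(mk_ann("P:707--P:715", "primary", "S1", 12),
          mk_ann("P:707--P:715", "primary", "S1m", 13)))
  expect_identical(d1$category, "stabilized_state")

  # RLC-loop1 style: increase, >30 in primaries, <30 in bent-lever model
  d2 <- classify_dynamics(
    mk_diff("P:115--P:206", "increase", TRUE),
    rbind(mk_ann("P:115--P:206", "primary", "S1", 45),
          mk_ann("P:115--P:206", "primary", "S1m", 44),
          mk_ann("P:115--P:206", "alternate", "BH", 22)))
  expect_identical(d2$category, "alternate_state_sampling")

  # increase beyond reach everywhere
  d3 <- classify_dynamics(
    mk_diff("P:1--P:2", "increase", TRUE),
    rbind(mk_ann("P:1--P:2", "primary", "S1", 45),
          mk_ann("P:1--P:2", "alternate", "BH", 40)))
  expect_identical(d3$category, "increased_dynamics")

  # ELC-NTD style exploratory loss: decrease, beyond reach
  d4 <- classify_dynamics(
    mk_diff("P:73--P:21", "decrease", TRUE),
    mk_ann("P:73--P:21", "primary", "S1", 38))
  expect_identical(d4$category, "lost_exploratory")

  # decrease within reach: redistribution
  d5 <- classify_dynamics(
    mk_diff("P:142--P:147", "decrease", TRUE),
    mk_ann("P:142--P:147", "primary", "S1", 11))
  expect_identical(d5$category, "redistribution")

  # not significant: no_change regardless of distances
  d6 <- classify_dynamics(
    mk_diff("P:1--P:2", "increase", FALSE),
    mk_ann("P:1--P:2", "primary", "S1", 11))
  expect_identical(d6$category, "no_change")

  # unmapped in every model: unannotated
  d7 <- classify_dynamics(
    mk_diff("P:5--P:6", "increase", TRUE),
    mk_ann("P:5--P:6", "primary", "S1", NA, mapped = FALSE))
  expect_identical(d7$category, "unannotated")
})

test_that("classification is total and order-invariant", {
  b <- simulate_dynamics_benchmark(cv = 0, seed = 3)
  q <- aggregate_links(b$peptides, compute_norm_factors(b$peptides))
  d <- differential_test(q, "control", "treated")
  ann <- annotate_link_distances(q$links, b$models)
  dyn <- classify_dynamics(d, ann)
  expect_identical(nrow(dyn), nrow(d))          # every link classified
  expect_identical(anyDuplicated(dyn$link), 0L) # exactly one category each
  expect_true(all(dyn$category %in% qxlms:::DYNAMICS_CATEGORIES))

  # shuffling link and annotation order leaves category counts unchanged
  set.seed(8)
  d_shuf <- d[sample(nrow(d)), ]
  ann_shuf <- ann[sample(nrow(ann)), ]
  dyn2 <- classify_dynamics(d_shuf, ann_shuf)
  expect_identical(table(dyn2$category), table(dyn$category))
  m <- merge(dyn, dyn2, by = "link")
  expect_identical(m$category.x, m$category.y)
})
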