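norm_fixture <- function(totals, conditions = c("c", "c", "t"),
                         replicates = c("R1", "R2", "R3")) {
  # one unreacted peptide per replicate carrying the stated total
  data.frame(protein_a = "PROTA", site_a = NA_integer_,
             protein_b = NA_character_, site_b = NA_integer_,
             link_kind = "unreacted", peptide = "ALGVE", charge = 2L,
             condition = conditions, replicate = replicates,
             intensity = totals, retention_time = NA_real_,
             candidate_sites = NA_character_, stringsAsFactors = FALSE)
}

test_that("normalization factors anchor on the geometric mean of unreacted totals", {
  # equal totals: all factors 1
  nf <- compute_norm_factors(norm_fixture(c(500, 500, 500)))
  expect_equal(nf$norm_factor, rep(1, 3))
  expect_identical(attr(nf, "anchor"), "geometric_mean")

  # totals (100, 200, 400): geometric mean 200, factors (0.5, 1, 2)
  nf2 <- compute_norm_factors(norm_fixture(c(100, 200, 400)))
  expect_equal(nf2$total_unreacted_signal, c(100, 200, 400))
  expect_equal(nf2$norm_factor, c(0.5, 1, 2))

  # replicate with zero unreacted signal: undefined
  expect_error(compute_norm_factors(norm_fixture(c(0, 200, 400))),
               "zero total unreacted")
})

test_that("normalized link intensities are invariant to replicate rescaling", {
  base <- fixture_peptides()
  base$intensity <- c(110, 95, 130, 240, 260, 250,    # link rows
                      1000, 900, 1100, 2000, 2100, 1900)  # carriers
  scaled <- base
  pick <- scaled$condition == "control" & scaled$replicate == "R2"
  scaled$intensity[pick] <- scaled$intensity[pick] * 7.3

  q1 <- aggregate_links(base, compute_norm_factors(base))
  q2 <- aggregate_links(scaled, compute_norm_factors(scaled))
  r1 <- q1$intensity / q2$intensity
  # all normalized intensities agree up to the shared geometric-mean
  # rescale, which cancels between replicates
  expect_equal(q1$intensity["PROTA:3--PROTB:23", "control.R2"] /
                 q1$intensity["PROTA:3--PROTB:23", "control.R1"],
               q2$intensity["PROTA:3--PROTB:23", "control.R2"] /
                 q2$intensity["PROTA:3--PROTB:23", "control.R1"],
               tolerance = 1e-12)
  expect_equal(max(r1) / min(r1), 1, tolerance = 1e-12)
})

test_that("aggregation sums normalized member intensities per residue pair", {
  peps <- rbind(
    quant_rows("PROTA", 3L, "PROTB", 23L, "interpeptide", "LGKVE", 2L,
               rep(100, 6)),
    quant_rows("PROTA", 3L, "PROTB", 23L, "interpeptide", "LGKVE", 3L,
               rep(50, 6)),
    norm_fixture(rep(1000, 6),
                 conditions = rep(c("control", "treated"), each = 3),
                 replicates = rep(c("R1", "R2", "R3"), 2))
  )
  nf <- compute_norm_factors(peps)
  q <- aggregate_links(peps, nf)
  expect_identical(nrow(q$links), 1L)
  expect_equal(unname(q$intensity[1, ]), rep(150, 6))
  expect_identical(q$links$n_member_peptides, 2L)

  # single member: aggregate equals member
  solo <- rbind(quant_rows("PROTA", 3L, NA_character_, NA_integer_,
                           "monolink", "LGKVE", 2L, rep(80, 6)),
                peps[13:18, ])
  qs <- aggregate_links(solo, compute_norm_factors(solo))
  expect_equal(unname(qs$intensity["PROTA:3", ]), rep(80, 6))

  # monolinked peptides of different lengths on the same K combine
  mono2 <- rbind(
    quant_rows("PROTA", 3L, NA_character_, NA_integer_, "monolink",
               "LGKVE", 2L, rep(80, 6)),
    quant_rows("PROTA", 3L, NA_character_, NA_integer_, "monolink",
               "ALGKVEDRI", 2L, rep(20, 6)),
    peps[13:18, ])
  qm <- aggregate_links(mono2, compute_norm_factors(mono2))
  expect_identical(nrow(qm$links), 1L)
  expect_equal(unname(qm$intensity["PROTA:3", ]), rep(100, 6))
})

test_that("aggregation conserves signal, ignores row order, and keeps NA semantics", {
  set.seed(11)
  sim <- simulate_quant_dataset(30, cv = 0.2, seed = 5,
                                loading_factors = c(1, 2, 0.5, 1.5, 1, 0.8))
  nf <- compute_norm_factors(sim$peptides)
  q <- aggregate_links(sim$peptides, nf)

  # conservation: per sample, aggregated sums equal normalized member sums
  px <- sim$peptides[sim$peptides$link_kind != "unreacted", ]
  fac <- setNames(nf$norm_factor, paste(nf$condition, nf$replicate, sep = "."))
  for (s in colnames(q$intensity)) {
    cond <- strsplit(s, ".", fixed = TRUE)[[1]]
    member_sum <- sum(px$intensity[px$condition == cond[1] &
                                     px$replicate == cond[2]]) / fac[s]
    expect_equal(sum(q$intensity[, s]), unname(member_sum), tolerance = 1e-12)
  }

  # permutation invariance
  perm <- sim$peptides[sample(nrow(sim$peptides)), ]
  q2 <- aggregate_links(perm, compute_norm_factors(perm))
  expect_equal(q$intensity, q2$intensity[rownames(q$intensity), ])

  # a cell is missing only if missing in all members
  peps <- rbind(
    quant_rows("PROTA", 3L, "PROTB", 23L, "interpeptide", "LGKVE", 2L,
               c(100, NA, 100, 100, 100, 100)),
    quant_rows("PROTA", 3L, "PROTB", 23L, "interpeptide", "LGKVE", 3L,
               c(50, 50, NA, 50, 50, 50)),
    quant_rows("PROTA", 43L, NA_character_, NA_integer_, "monolink",
               "KAAAA", 2L, c(NA, 70, 70, 70, 70, 70)),
    norm_fixture(rep(1000, 6),
                 conditions = rep(c("control", "treated"), each = 3),
                 replicates = rep(c("R1", "R2", "R3"), 2)))
  q3 <- aggregate_links(peps, compute_norm_factors(peps))
  expect_equal(unname(q3$intensity["PROTA:3--PROTB:23", ]),
               c(150, 50, 100, 150, 150, 150))
  expect_true(is.na(q3$intensity["PROTA:43", "control.R1"]))
})

test_that("ambiguous sites resolve to the most reactive, best-supported residue", {
  seqs <- fixture_sequences()  # K at 3,23,43,63,83; S at 5,25,...
  # K preferred over S
  expect_identical(resolve_ambiguous_site(c(23L, 25L), "PROTA", seqs), 23L)
  # among lysines, the one with most other-link evidence wins
  ev <- c("PROTA:23" = 5, "PROTA:43" = 2)
  expect_identical(resolve_ambiguous_site(c(23L, 43L), "PROTA", seqs, ev), 23L)
  expect_identical(resolve_ambiguous_site(c(23L, 43L), "PROTA", seqs,
                                          c("PROTA:43" = 9)), 43L)
  # ties break to the lowest index
  expect_identical(resolve_ambiguous_site(c(43L, 23L), "PROTA", seqs,
                                          c("PROTA:23" = 3, "PROTA:43" = 3)),
                   23L)
  # no reactive candidate: error (position 4 is filler, not N-terminal)
  expect_error(resolve_ambiguous_site(c(4L, 6L), "PROTA", seqs),
               "reactive")

  # table-level resolution feeds evidence from unambiguous rows
  peps <- rbind(
    quant_rows("PROTA", 23L, "PROTB", 23L, "interpeptide", "KVEDR", 2L,
               rep(100, 6), candidate_sites = "25"),
    quant_rows("PROTA", 43L, NA_character_, NA_integer_, "monolink",
               "KAAAA", 2L, rep(10, 6)),
    norm_fixture(rep(1000, 6),
                 conditions = rep(c("control", "treated"), each = 3),
                 replicates = rep(c("R1", "R2", "R3"), 2)))
  res <- resolve_ambiguous(peps, seqs)
  expect_true(all(is.na(res$candidate_sites)))
  expect_identical(unique(res$site_a[res$link_kind == "interpeptide"]), 23L)
  # aggregation refuses unresolved ambiguity
  expect_error(aggregate_links(peps, compute_norm_factors(peps)),
               "resolve_ambiguous")
})
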