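#' Compute per-replicate normalization factors
#'
#' Label-free qXL-MS runs are normalized on the total signal of peptides
#' bearing no cross-linker modification ("unreacted" carrier peptides),
#' which tracks sample loading independently of cross-linking yield. The
#' factor for replicate r is its unreacted total divided by the geometric
#' mean of all replicates' totals, so factors multiply to 1 and the anchor
#' cancels in any between-condition fold change. Normalized intensity is
#' raw intensity divided by the replicate's factor.
#'
#' @param peptides `xlms_peptides` table including `unreacted` rows.
#' @return `data.frame` (class `xlms_norm`) with one row per
#'   (condition, replicate): `total_unreacted_signal`, `norm_factor`;
#'   attribute `anchor = "geometric_mean"`.
#' @export
compute_norm_factors <- function(peptides) {
  un <- peptides[peptides$link_kind == "unreacted" & !is.na(peptides$intensity), ]
  reps <- unique(peptides[, c("condition", "replicate")])
  reps <- reps[order(reps$condition, reps$replicate), , drop = FALSE]
  rownames(reps) <- NULL
  key <- paste(reps$condition, reps$replicate, sep = "\r")
  totals <- setNames(rep(0, nrow(reps)), key)
  if (nrow(un)) {
    agg <- tapply(un$intensity, paste(un$condition, un$replicate, sep = "\r"), sum)
    totals[names(agg)] <- agg
  }
  if (any(totals <= 0)) {
    bad <- sub("\r", "/", names(totals)[totals <= 0])
    stop("replicate(s) with zero total unreacted signal (normalization undefined): ",
         paste(bad, collapse = ", "))
  }
  g <- exp(mean(log(totals)))
  out <- cbind(reps,
               total_unreacted_signal = unname(totals),
               norm_factor = unname(totals) / g)
  structure(out, class = c("xlms_norm", "data.frame"), anchor = "geometric_mean")
}

#' Resolve an ambiguous cross-linker site assignment
#'
#' When a peptide carries several reactive residues and chromatography or
#' MS2 evidence cannot localize the cross-linker, the site is assigned to
#' the most reactive residue: lysine is preferred over S/T/Y; among several
#' lysines, the one supported by the most other links/monolinks in the
#' dataset wins; remaining ties go to the lowest residue index, making the
#' rule deterministic.
#'
#' @param candidates Integer residue indices of the candidate sites.
#' @param protein Protein id the candidates lie on.
#' @param sequences Named sequences from [read_fasta()].
#' @param evidence Named numeric: count of other links/monolinks per site,
#'   names `"protein:site"`. Missing sites count 0.
#' @return The chosen residue index (integer scalar).
#' @export
resolve_ambiguous_site <- function(candidates, protein, sequences,
                                   evidence = numeric(0)) {
  seq <- sequences[[protein]]
  if (is.null(seq)) stop("unknown protein: ", protein)
  codes <- substring(seq, candidates, candidates)
  reactive <- codes %in% REACTIVE_RESIDUES | candidates == 1L
  if (!any(reactive)) {
    stop("no candidate site on '", protein,
         "' is cross-linker reactive (K/S/T/Y) or N-terminal: ",
         paste0(codes, candidates, collapse = ", "))
  }
  candidates <- candidates[reactive]
  codes <- codes[reactive]
  pool <- if (any(codes == "K")) candidates[codes == "K"] else candidates
  ev <- vapply(pool, function(s) {
    v <- evidence[paste0(protein, ":", s)]
    if (is.na(v)) 0 else unname(v)
  }, numeric(1))
  pool <- pool[ev == max(ev)]
  min(pool)
}

# Tally, for each candidate site, how many distinct other link species
# involve it -- the "reactivity evidence" used by the ambiguity rule.
link_evidence_counts <- function(peptides) {
  resolved <- peptides[peptides$link_kind != "unreacted", , drop = FALSE]
  keys <- unique(link_key(resolved$protein_a, resolved$site_a,
                          resolved$protein_b, resolved$site_b))
  sites <- unlist(lapply(keys, function(k) {
    s <- parse_link_key(k)
    paste0(s$protein, ":", s$site)
  }))
  table(sites)
}

#' Apply the ambiguous-site rule across a peptide table
#'
#' Rows whose `candidate_sites` column lists alternative positions for
#' `site_a` are reassigned to the winning candidate (see
#' [resolve_ambiguous_site()]); evidence counts are tallied from the
#' unambiguous rows of the same table.
#'
#' @param peptides `xlms_peptides` table.
#' @param sequences Named sequences from [read_fasta()].
#' @return The table with `site_a` resolved and `candidate_sites` cleared.
#' @export
resolve_ambiguous <- function(peptides, sequences) {
  amb <- which(!is.na(peptides$candidate_sites) &
                 peptides$candidate_sites != "")
  if (!length(amb)) return(peptides)
  ev_tab <- link_evidence_counts(peptides[-amb, , drop = FALSE])
  ev <- setNames(as.numeric(ev_tab), names(ev_tab))
  for (i in amb) {
    cands <- union(peptides$site_a[i],
                   parse_candidates(peptides$candidate_sites[i]))
    peptides$site_a[i] <- resolve_ambiguous_site(
      sort(cands), peptides$protein_a[i], sequences, ev)
    peptides$candidate_sites[i] <- NA_character_
  }
  peptides
}

#' Aggregate peptide-level signal to residue-resolved link species
#'
#' Signal is combined by summation of normalized intensities over all
#' member peptides sharing the same canonical residue pair (or single
#' residue for monolinks), regardless of peptide charge state or length.
#' A (condition, replicate) cell is missing only if it is missing in every
#' member peptide; otherwise missing members simply contribute nothing.
#'
#' @param peptides `xlms_peptides` table (ambiguous sites resolved).
#' @param norm `xlms_norm` factors from [compute_norm_factors()].
#' @return An `xlms_quant` object: list with `intensity` (links x samples
#'   matrix of normalized intensities, `NA` = missing), `links`
#'   (`data.frame`: `link`, `link_kind`, sites, `n_member_peptides`),
#'   `samples` (`data.frame`: `condition`, `replicate`), `norm`.
#' @export
aggregate_links <- function(peptides, norm) {
  px <- peptides[peptides$link_kind != "unreacted", , drop = FALSE]
  if (any(!is.na(px$candidate_sites) & px$candidate_sites != "")) {
    stop("peptides with unresolved ambiguous sites present; ",
         "run resolve_ambiguous() first")
  }
  if (!nrow(px)) stop("no cross-linked or monolinked peptides to aggregate")

  fac <- setNames(norm$norm_factor, paste(norm$condition, norm$replicate, sep = "\r"))
  scol <- paste(px$condition, px$replicate, sep = "\r")
  if (any(!scol %in% names(fac))) {
    stop("peptide rows reference (condition, replicate) pairs absent from norm factors")
  }
  px$norm_intensity <- px$intensity / unname(fac[scol])

  px$link <- link_key(px$protein_a, px$site_a, px$protein_b, px$site_b)
  samples <- paste(norm$condition, norm$replicate, sep = "\r")
  links <- sort(unique(px$link))

  m <- matrix(NA_real_, nrow = length(links), ncol = length(samples),
              dimnames = list(links, samples))
  present <- !is.na(px$norm_intensity)
  sums <- tapply(px$norm_intensity[present],
                 list(px$link[present], scol[present]), sum)
  m[rownames(sums), colnames(sums)] <- sums

  n_members <- tapply(paste(px$peptide, px$charge),
                      px$link, function(v) length(unique(v)))
  kind <- tapply(px$link_kind, px$link, function(v) v[1])
  parsed <- lapply(links, parse_link_key)
  link_df <- data.frame(
    link = links,
    link_kind = unname(kind[links]),
    protein_a = vapply(parsed, function(s) s$protein[1], character(1)),
    site_a = vapply(parsed, function(s) s$site[1], integer(1)),
    protein_b = vapply(parsed, function(s)
      if (nrow(s) == 2) s$protein[2] else NA_character_, character(1)),
    site_b = vapply(parsed, function(s)
      if (nrow(s) == 2) s$site[2] else NA_integer_, integer(1)),
    n_member_peptides = as.integer(unname(n_members[links])),
    stringsAsFactors = FALSE, row.names = NULL
  )
  sample_df <- data.frame(condition = norm$condition,
                          replicate = norm$replicate,
                          stringsAsFactors = FALSE)
  colnames(m) <- paste(sample_df$condition, sample_df$replicate, sep = ".")
  structure(list(intensity = m, links = link_df, samples = sample_df,
                 norm = norm),
            class = "xlms_quant")
}

#' @export
print.xlms_quant <- function(x, ...) {
  cat("xlms_quant: ", nrow(x$links), " link species x ",
      nrow(x$samples), " samples (",
      paste(unique(x$samples$condition), collapse = " vs "), ")\n", sep = "")
  print(table(x$links$link_kind))
  invisible(x)
}
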