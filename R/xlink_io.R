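#' @importFrom stats pt sd setNames
#' @importFrom utils read.delim write.table
#' @importFrom tools file_ext file_path_sans_ext
NULL

# Residues DSBU (and related NHS-ester cross-linkers) can react with.
REACTIVE_RESIDUES <- c("K", "S", "T", "Y")

#' Read construct sequences from a FASTA file
#'
#' Identifiers are taken from the first whitespace-delimited token of each
#' header line, as is conventional for search-engine exports.
#'
#' @param path Path to a FASTA file of protein sequences.
#' @return Named character vector, one sequence per protein identifier.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("Duplicate FASTA identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  setNames(as.character(set), ids)
}

#' Canonical key for a cross-link or monolink
#'
#' The unordered residue pair is canonicalized by lexicographic ordering on
#' (protein_id, residue_index); monolinks use their single site. The key is
#' the unique identity of a link species throughout the pipeline.
#'
#' @param protein_a,site_a First site (protein id, 1-based residue index).
#' @param protein_b,site_b Second site, or `NA` for monolinks.
#' @return Character vector of canonical link keys.
#' @export
link_key <- function(protein_a, site_a, protein_b = NA, site_b = NA) {
  n <- max(length(protein_a), length(site_a), length(protein_b), length(site_b))
  protein_a <- rep_len(protein_a, n); site_a <- rep_len(site_a, n)
  protein_b <- rep_len(protein_b, n); site_b <- rep_len(site_b, n)
  a <- paste0(protein_a, ":", site_a)
  b <- ifelse(is.na(protein_b) | protein_b == "", NA_character_,
              paste0(protein_b, ":", site_b))
  swap <- !is.na(b) &
    (protein_b < protein_a |
       (protein_b == protein_a & as.integer(site_b) < as.integer(site_a)))
  first <- ifelse(swap, b, a)
  second <- ifelse(swap, a, b)
  ifelse(is.na(second), first, paste0(first, "--", second))
}

validate_site <- function(protein, site, sequences, require_reactive = TRUE,
                          n_term_ok = TRUE) {
  if (!protein %in% names(sequences)) {
    return(sprintf("unknown protein '%s'", protein))
  }
  seq <- sequences[[protein]]
  n <- nchar(seq)
  if (is.na(site) || site < 1L || site > n) {
    return(sprintf("site %s out of range 1..%d for protein '%s'",
                   site, n, protein))
  }
  code <- substr(seq, site, site)
  if (require_reactive && !(code %in% REACTIVE_RESIDUES) &&
      !(n_term_ok && site == 1L)) {
    return(sprintf(
      "residue %s%d of '%s' is not cross-linker reactive (K/S/T/Y) nor the N-terminus",
      code, site, protein))
  }
  NA_character_
}

parse_candidates <- function(x) {
  if (is.na(x) || x == "") return(integer(0))
  as.integer(strsplit(as.character(x), ";", fixed = TRUE)[[1]])
}

#' Read a peptide-level quantification table
#'
#' One row per peptide species per (condition, replicate). Mandatory columns:
#' `protein_a`, `site_a`, `protein_b`, `site_b` (empty for monolinks),
#' `link_kind` (`interpeptide`, `intrapeptide`, `monolink`, or `unreacted`
#' for carrier peptides bearing no cross-linker modification), `peptide`,
#' `charge`, `condition`, `replicate`, `intensity`. Optional:
#' `retention_time`, `candidate_sites` (semicolon-separated alternative
#' residue indices for ambiguous site assignment). Comma or tab delimiters
#' are autodetected. Missing intensities are encoded as empty/NA cells and
#' kept as `NA`, never as zero.
#'
#' Every row is either accepted or reported in the rejection attribute;
#' rows failing site validation against `sequences` are collected (with
#' reasons) in `attr(x, "rejected")`, not silently dropped.
#'
#' @param path Delimited text file as above.
#' @param sequences Named character vector from [read_fasta()]; if `NULL`,
#'   site-vs-sequence validation is skipped.
#' @return A `data.frame` of class `xlms_peptides` with the columns above
#'   (types normalized), plus attribute `rejected`.
#' @export
read_quant_table <- function(path, sequences = NULL) {
  if (!file.exists(path)) stop("quant table not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  mandatory <- c("protein_a", "site_a", "protein_b", "site_b", "link_kind",
                 "peptide", "charge", "condition", "replicate", "intensity")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols)) {
    stop("quant table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$site_a <- as.integer(df$site_a)
  df$site_b <- as.integer(df$site_b)
  df$charge <- as.integer(df$charge)
  df$replicate <- as.character(df$replicate)
  df$condition <- as.character(df$condition)
  df$intensity <- as.numeric(df$intensity)
  if (!"candidate_sites" %in% names(df)) df$candidate_sites <- NA_character_
  df$candidate_sites <- as.character(df$candidate_sites)
  if (!"retention_time" %in% names(df)) df$retention_time <- NA_real_

  bad_kind <- !df$link_kind %in% c("interpeptide", "intrapeptide",
                                   "monolink", "unreacted")
  if (any(bad_kind)) {
    stop("unknown link_kind value(s): ",
         paste(unique(df$link_kind[bad_kind]), collapse = ", "))
  }

  reason <- rep(NA_character_, nrow(df))
  if (!is.null(sequences)) {
    for (i in seq_len(nrow(df))) {
      if (df$link_kind[i] == "unreacted") next
      r <- validate_site(df$protein_a[i], df$site_a[i], sequences)
      if (is.na(r) && df$link_kind[i] != "monolink") {
        r <- validate_site(df$protein_b[i], df$site_b[i], sequences)
      }
      reason[i] <- r
    }
  }
  rejected <- cbind(df[!is.na(reason), , drop = FALSE],
                    reason = reason[!is.na(reason)])
  ok <- df[is.na(reason), , drop = FALSE]
  rownames(ok) <- NULL
  if (nrow(rejected)) {
    warning(nrow(rejected), " row(s) failed site validation; see attr(x, 'rejected')")
  }
  structure(ok, class = c("xlms_peptides", "data.frame"), rejected = rejected)
}

#' Write a joined results table
#'
#' One row per link species: differential statistics joined with per-model
#' distance annotations and the dynamics call. Values are written at full
#' precision so that re-reading reproduces them exactly.
#'
#' @param results `data.frame` keyed by `link` (from [differential_test()],
#'   optionally merged with [annotate_link_distances()] and
#'   [classify_dynamics()] output).
#' @param path Output TSV path.
#' @export
write_results <- function(results, path) {
  stopifnot(is.data.frame(results), "link" %in% names(results))
  out <- results
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  out[num] <- lapply(out[num], function(v) ifelse(v == "nan", "NA", v))
  out[] <- lapply(out, function(v) ifelse(is.na(v) | v == "NA", NA, v))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read back a results table written by [write_results()]
#' @param path TSV path.
#' @return `data.frame` with numeric columns restored.
#' @export
read_results <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = "NA")
  df
}

# Colors encoding the dynamics categories in pseudobond exports
# (reds for increases, purples for decreases, grey otherwise).
DYNAMICS_COLORS <- c(
  stabilized_state = "red",
  alternate_state_sampling = "orange red",
  increased_dynamics = "firebrick",
  lost_exploratory = "purple",
  redistribution = "medium purple",
  no_change = "gray",
  unannotated = "dark gray"
)

#' Export cross-links as a pseudobond file for structure viewers
#'
#' Writes one line per cross-link in `/chain:resi@CA /chain:resi@CA  color`
#' syntax, the color encoding the dynamics category (reds for stabilized /
#' increased links, purples for decreased ones). Monolinks are skipped (no
#' atom pair to draw).
#'
#' @param annotations `data.frame` with columns `link` and optionally
#'   `category` (defaults to `no_change`).
#' @param model A structure model from [read_structure()] carrying a chain
#'   map and offsets (see [set_model_mapping()]).
#' @param path Output path.
#' @return Invisibly, the number of pseudobond lines written.
#' @export
write_pseudobonds <- function(annotations, model, path) {
  stopifnot(inherits(model, "xlms_model"))
  keys <- unique(annotations$link)
  cat_by_link <- if ("category" %in% names(annotations)) {
    setNames(as.character(annotations$category), annotations$link)
  } else {
    setNames(rep("no_change", length(keys)), keys)
  }
  lines <- character(0)
  for (key in keys) {
    sites <- parse_link_key(key)
    if (nrow(sites) != 2L) next  # monolink: nothing to draw
    addr <- character(2)
    for (j in 1:2) {
      res <- resolve_model_residue(model, sites$protein[j], sites$site[j])
      if (is.na(res$chain) ||
          is.null(ca_coords(model, res$chain, res$resno))) {
        stop("link ", key, ": residue ", sites$protein[j], ":", sites$site[j],
             " not resolvable in model '", model$model_id, "'")
      }
      addr[j] <- sprintf("/%s:%d@CA", res$chain, res$resno)
    }
    color <- DYNAMICS_COLORS[[cat_by_link[[key]] %||% "no_change"]]
    lines <- c(lines, paste0(addr[1], " ", addr[2], "  ", color))
  }
  writeLines(c(sprintf("; pseudobonds on model %s", model$model_id), lines),
             path)
  invisible(length(lines))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

#' Parse a canonical link key back into its residue sites
#' @param key Canonical key from [link_key()].
#' @return `data.frame` with columns `protein`, `site` (one row per site).
#' @export
parse_link_key <- function(key) {
  parts <- strsplit(key, "--", fixed = TRUE)[[1]]
  mat <- do.call(rbind, strsplit(parts, ":", fixed = TRUE))
  data.frame(protein = mat[, 1], site = as.integer(mat[, 2]),
             stringsAsFactors = FALSE)
}
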